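#' Simulate multi-condition cis-QTL phenotypes with known ground truth
#'
#' Each feature (gene or intron) receives one causal cis variant and an effect
#' pattern drawn from \code{pattern_mix}: \emph{shared} effects are identical
#' in all conditions, \emph{group} effects are identical within a designated
#' group of conditions and zero outside it, \emph{specific} effects are
#' nonzero in exactly one condition, and \emph{null} features have no genetic
#' effect. Where a feature is active in a condition, the effect size is scaled
#' so that the causal variant explains \code{qtl_h2} of the phenotypic
#' variance; residual noise is standard normal scaled to \code{1 - qtl_h2}.
#'
#' Feature anchors (the analogue of a TSS) are placed uniformly along each
#' chromosome and the causal variant is drawn from the variants within
#' \code{cis_window_bp} of the anchor.
#'
#' @param G a \code{\link{genotype_matrix}}; the same genotypes underlie every
#'   condition, as for one cohort assayed in multiple cell types.
#' @param n_conditions number of conditions (cell types).
#' @param pattern_mix named proportions over
#'   \code{c("shared","group","specific","null")}; must sum to 1.
#' @param qtl_h2 per-feature variance explained by the causal variant where
#'   active, in \[0, 1).
#' @param n_features number of features to simulate.
#' @param group integer indices of the conditions forming the designated
#'   group for the "group" pattern; default is the first half.
#' @param cis_window_bp half-width of the window around the feature anchor in
#'   which the causal variant is placed.
#' @param seed integer seed.
#'
#' @return list with elements:
#'   \item{phenotypes}{list of \code{n_conditions} feature x sample matrices;}
#'   \item{truth}{data.frame with one row per feature: \code{feature},
#'     \code{pattern}, \code{causal_variant}, \code{anchor_chrom},
#'     \code{anchor_pos}, \code{qtl_h2}, and one \code{beta_<condition>}
#'     column per condition;}
#'   \item{conditions}{condition labels.}
#' @export
simulate_qtl_phenotypes <- function(G, n_conditions,
                                    pattern_mix = c(shared = 0.25, group = 0.25,
                                                    specific = 0.25, null = 0.25),
                                    qtl_h2 = 0.1, n_features = 100,
                                    group = NULL, cis_window_bp = 1e6,
                                    seed = 1L) {
  if (qtl_h2 < 0 || qtl_h2 >= 1)
    stop("qtl_h2 must lie in [0, 1)", call. = FALSE)
  pm <- pattern_mix[c("shared", "group", "specific", "null")]
  pm[is.na(pm)] <- 0
  names(pm) <- c("shared", "group", "specific", "null")
  if (abs(sum(pm) - 1) > 1e-8)
    stop("pattern_mix must sum to 1", call. = FALSE)
  if (is.null(group)) group <- seq_len(max(1L, floor(n_conditions / 2)))
  conditions <- paste0("cond", seq_len(n_conditions))
  n <- length(G$samples)

  with_seed(seed, {
    patterns <- sample(names(pm), n_features, replace = TRUE, prob = pm)
    # anchors uniform over the span of each chromosome, chromosome chosen
    # proportional to its variant count
    vchr <- G$variants$chrom
    chrom_tab <- table(vchr)
    anchor_chrom <- sample(names(chrom_tab), n_features, replace = TRUE,
                           prob = as.numeric(chrom_tab))
    anchor_pos <- vapply(anchor_chrom, function(ch) {
      p <- G$variants$pos[vchr == ch]
      round(runif(1, min(p), max(p)))
    }, numeric(1))

    betas <- matrix(0, n_features, n_conditions,
                    dimnames = list(NULL, conditions))
    causal <- character(n_features)
    for (f in seq_len(n_features)) {
      cis <- which(vchr == anchor_chrom[f] &
                     abs(G$variants$pos - anchor_pos[f]) <= cis_window_bp)
      j <- if (length(cis) == 1) cis else sample(cis, 1)
      causal[f] <- G$variants$id[j]
      if (patterns[f] == "null") next
      x <- G$dosages[, j]
      vx <- stats::var(x)
      if (vx == 0) { patterns[f] <- "null"; next }  # monomorphic draw: demote
      b <- sample(c(-1, 1), 1) * sqrt(qtl_h2 / vx)
      active <- switch(patterns[f],
                       shared = seq_len(n_conditions),
                       group = group,
                       specific = sample.int(n_conditions, 1))
      betas[f, active] <- b
    }

    phenos <- lapply(seq_len(n_conditions), function(k) {
      Y <- matrix(NA_real_, n_features, n,
                  dimnames = list(paste0("feat", seq_len(n_features)),
                                  G$samples))
      for (f in seq_len(n_features)) {
        b <- betas[f, k]
        sd_e <- if (b != 0) sqrt(1 - qtl_h2) else 1
        mu <- if (b != 0) G$dosages[, match(causal[f], G$variants$id)] * b else 0
        Y[f, ] <- mu + rnorm(n, 0, sd_e)
      }
      Y
    })
    names(phenos) <- conditions

    truth <- data.frame(
      feature = paste0("feat", seq_len(n_features)),
      pattern = patterns, causal_variant = causal,
      anchor_chrom = anchor_chrom, anchor_pos = anchor_pos,
      qtl_h2 = ifelse(patterns == "null", 0, qtl_h2),
      stringsAsFactors = FALSE
    )
    truth <- cbind(truth, as.data.frame(betas) |>
                     stats::setNames(paste0("beta_", conditions)))
    rownames(truth) <- NULL
    list(phenotypes = phenos, truth = truth, conditions = conditions)
  })
}

#' Simulate GWAS summary statistics
#'
#' Simulates a quantitative trait with a single causal variant explaining
#' \code{h2_snp} of trait variance (or a pure-noise trait when \code{causal}
#' is \code{NULL}) and returns per-variant marginal association statistics.
#'
#' Two generation paths are provided. The individual-level path (default for
#' \code{n_gwas <= 50000}) draws a fresh genotype cohort of size
#' \code{n_gwas} from the same population model that produced \code{G}
#' (falling back to resampling rows of \code{G} when the generating
#' parameters are unavailable), simulates the trait, and computes marginal
#' OLS statistics per variant. The analytic path uses the marginal-effect
#' identity beta_j = r_jc * beta_c * sd(x_c)/sd(x_j) with LD and dosage
#' moments estimated from \code{G}, standard error sd(y)/(sd(x_j)*sqrt(n)),
#' and Gaussian sampling noise on the estimate. The two paths agree in
#' distribution; both are exercised by the test suite.
#'
#' @param G reference \code{\link{genotype_matrix}} defining the variant panel
#'   and LD structure.
#' @param causal variant id of the causal variant, or \code{NULL} for a null
#'   trait.
#' @param n_gwas GWAS sample size.
#' @param h2_snp trait variance explained by the causal variant, in \[0, 1).
#' @param seed integer seed.
#' @param method "individual", "analytic", or "auto" (individual-level when
#'   \code{n_gwas <= 50000}).
#'
#' @return data.frame of association statistics with columns \code{variant},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{beta},
#'   \code{se}, \code{p}, \code{n}.
#' @export
simulate_gwas_summary <- function(G, causal = NULL, n_gwas = 10000,
                                  h2_snp = 0.004, seed = 1L,
                                  method = c("auto", "individual", "analytic")) {
  method <- match.arg(method)
  if (h2_snp < 0 || h2_snp >= 1)
    stop("h2_snp must lie in [0, 1)", call. = FALSE)
  if (!is.null(causal) && !causal %in% G$variants$id)
    stop("causal variant not present in genotype panel", call. = FALSE)
  if (method == "auto")
    method <- if (n_gwas <= 50000) "individual" else "analytic"

  v <- G$variants
  out <- with_seed(seed, {
    if (method == "individual") {
      X <- draw_cohort_dosages(G, n_gwas)
      y <- rnorm(n_gwas)
      if (!is.null(causal) && h2_snp > 0) {
        xc <- X[, match(causal, v$id)]
        vx <- stats::var(xc)
        if (vx > 0) y <- xc * sqrt(h2_snp / vx) + rnorm(n_gwas, 0, sqrt(1 - h2_snp))
      }
      marginal_ols(X, y)
    } else {
      D <- G$dosages
      sdx <- apply(D, 2, stats::sd)
      sdx[sdx == 0] <- NA_real_
      if (is.null(causal) || h2_snp == 0) {
        bm <- rep(0, ncol(D)); vary <- 1
      } else {
        jc <- match(causal, v$id)
        bc <- sqrt(h2_snp) / sdx[jc]
        r <- suppressWarnings(stats::cor(D, D[, jc]))
        bm <- drop(r) * bc * sdx[jc] / sdx
        vary <- 1
      }
      se <- sqrt(vary) / (sdx * sqrt(n_gwas))
      beta <- rnorm(length(bm), bm, se)
      z <- beta / se
      data.frame(beta = beta, se = se, p = 2 * pnorm(-abs(z)))
    }
  })
  data.frame(variant = v$id, chrom = v$chrom, pos = v$pos,
             ref = v$ref, alt = v$alt,
             beta = out$beta, se = out$se, p = pmin(pmax(out$p, 1e-300), 1),
             n = n_gwas, stringsAsFactors = FALSE)
}

# Draw a fresh dosage cohort from the population model underlying G
# (sim_params attribute); falls back to row resampling with replacement.
draw_cohort_dosages <- function(G, n) {
  sp <- attr(G, "sim_params")
  if (is.null(sp)) {
    idx <- sample.int(nrow(G$dosages), n, replace = TRUE)
    return(G$dosages[idx, , drop = FALSE])
  }
  nv <- length(sp$mafs)
  thr <- qnorm(sp$mafs)
  lay <- sp$chrom_layout %||% stats::setNames(nv, "1")
  one_hap <- function() {
    z <- matrix(NA_real_, n, nv)
    j0 <- 0L
    for (k in lay) {
      z[, j0 + 1L] <- rnorm(n)
      if (k > 1) for (j in 2:k)
        z[, j0 + j] <- sp$ld_rho * z[, j0 + j - 1L] +
          sqrt(1 - sp$ld_rho^2) * rnorm(n)
      j0 <- j0 + k
    }
    z < rep(thr, each = n)
  }
  X <- one_hap() + one_hap()
  storage.mode(X) <- "double"
  colnames(X) <- G$variants$id
  X
}

# Vectorized per-variant marginal OLS of y on each column of X.
marginal_ols <- function(X, y) {
  n <- length(y)
  xm <- colMeans(X)
  xc <- sweep(X, 2, xm)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- drop(crossprod(xc, yc))
  beta <- sxy / sxx
  syy <- sum(yc^2)
  rss <- syy - beta * sxy
  df <- n - 2
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tt <- beta / se
  p <- 2 * pt(-abs(tt), df)
  beta[sxx == 0] <- NA_real_
  data.frame(beta = beta, se = se, p = p)
}
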