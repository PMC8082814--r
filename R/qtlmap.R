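# Cis-QTL mapping: nominal linear-model scan, permutation pass with a
# beta-distribution approximation of the minimum p-value, Storey q-values,
# and covariate-count selection.

# Project covariates (plus intercept) out of the columns of M.
# Errors on rank-deficient covariate matrices, naming the collinear columns.
residualize <- function(M, covariates = NULL) {
  n <- nrow(M)
  C <- cbind(`(intercept)` = rep(1, n), covariates)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    bad <- colnames(C)[qrC$pivot[(qrC$rank + 1):ncol(C)]]
    stop("covariates are rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  M - C %*% qr.coef(qrC, M)
}

#' Nominal cis-QTL scan
#'
#' For each feature, regresses the covariate-residualized phenotype on each
#' covariate-residualized cis variant dosage (simple OLS per variant, the
#' FastQTL nominal model). P-values use the t reference with n - k - 2
#' degrees of freedom, where k is the number of covariates: the intercept
#' and covariates are projected out of both sides, and one further degree is
#' spent on the genotype slope.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param Y feature x sample phenotype matrix (samples aligned with
#'   \code{G$samples}).
#' @param feature_pos data.frame with columns \code{feature}, \code{chrom},
#'   \code{pos} giving each feature's anchor (TSS for genes, cluster midpoint
#'   for introns).
#' @param covariates optional sample x k numeric matrix.
#' @param cis_window_bp half-width of the cis window around the anchor
#'   (default 1 Mb).
#' @return data.frame of association statistics: \code{feature},
#'   \code{variant}, \code{distance}, \code{beta}, \code{se}, \code{p},
#'   \code{n}. Features with no cis variant are skipped.
#' @export
nominal_scan <- function(G, Y, feature_pos, covariates = NULL,
                         cis_window_bp = 1e6) {
  stopifnot(ncol(Y) == length(G$samples))
  n <- ncol(Y)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  df <- n - k - 2L
  Xr <- residualize(G$dosages, covariates)
  Yr <- residualize(t(Y), covariates)  # samples x features

  res <- vector("list", nrow(feature_pos))
  for (i in seq_len(nrow(feature_pos))) {
    f <- feature_pos$feature[i]
    fi <- match(f, rownames(Y))
    if (is.na(fi)) next
    cis <- which(G$variants$chrom == feature_pos$chrom[i] &
                   abs(G$variants$pos - feature_pos$pos[i]) <= cis_window_bp)
    if (!length(cis)) next
    x <- Xr[, cis, drop = FALSE]
    y <- Yr[, fi]
    sxx <- colSums(x^2)
    sxy <- drop(crossprod(x, y))
    beta <- sxy / sxx
    rss <- sum(y^2) - beta * sxy
    se <- sqrt(pmax(rss, 0) / df / sxx)
    tt <- beta / se
    p <- 2 * pt(-abs(tt), df)
    ok <- sxx > 0
    res[[i]] <- data.frame(
      feature = f, variant = G$variants$id[cis],
      distance = G$variants$pos[cis] - feature_pos$pos[i],
      beta = beta, se = se, p = p, n = n,
      stringsAsFactors = FALSE
    )[ok, , drop = FALSE]
  }
  out <- data.table::rbindlist(res)
  as.data.frame(out)
}

# Fit Beta(a, b) to permutation minima by maximum likelihood with
# moment-matching initialization. Returns NULL on failure.
fit_beta_minp <- function(x) {
  eps <- 1e-12
  x <- pmin(pmax(x, eps), 1 - eps)
  m <- mean(x); v <- stats::var(x)
  if (!is.finite(v) || v <= 0) return(NULL)
  c0 <- m * (1 - m) / v - 1
  if (c0 <= 0) c0 <- 1
  init <- log(c(max(m * c0, 1e-3), max((1 - m) * c0, 1e-3)))
  nll <- function(lp) {
    a <- exp(lp[1]); b <- exp(lp[2])
    -sum(dbeta(x, a, b, log = TRUE))
  }
  fit <- tryCatch(stats::optim(init, nll, method = "Nelder-Mead"),
                  error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) return(NULL)
  exp(fit$par)
}

#' Permutation pass with beta approximation
#'
#' For each feature, permutes the (covariate-residualized) phenotype
#' \code{n_perm} times, records the minimal nominal p-value across cis
#' variants for each permutation, fits a beta distribution to the minima by
#' maximum likelihood, and reports the beta CDF evaluated at the observed
#' minimal p (\code{bpval}). Permuting residuals keeps the genotype LD
#' structure intact, mirroring the FastQTL permutation scheme. When the beta
#' fit fails, the empirical permutation p-value is used with a warning.
#'
#' @inheritParams nominal_scan
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed governing the permutations.
#' @return data.frame per feature: \code{feature}, \code{lead_variant},
#'   \code{n_cis}, \code{nominal_p} (observed minimum), \code{bpval},
#'   \code{perm_p} (empirical (1 + #better)/(1 + n_perm)), \code{beta_a},
#'   \code{beta_b}.
#' @export
permutation_pass <- function(G, Y, feature_pos, covariates = NULL,
                             cis_window_bp = 1e6, n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  n <- ncol(Y)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  df <- n - k - 2L
  Xr <- residualize(G$dosages, covariates)
  Yr <- residualize(t(Y), covariates)

  # standardize once: with x, y centered (residualized), the per-variant t
  # statistic is a monotone function of |cor|, so minima can be computed from
  # the correlation matrix of permuted phenotypes
  Xs <- sweep(Xr, 2, sqrt(colSums(Xr^2)), `/`)
  Xs[, colSums(Xr^2) == 0] <- 0

  out <- with_seed(seed, {
    perms <- replicate(n_perm, sample.int(n))
    res <- vector("list", nrow(feature_pos))
    for (i in seq_len(nrow(feature_pos))) {
      f <- feature_pos$feature[i]
      fi <- match(f, rownames(Y))
      if (is.na(fi)) next
      cis <- which(G$variants$chrom == feature_pos$chrom[i] &
                     abs(G$variants$pos - feature_pos$pos[i]) <= cis_window_bp)
      if (!length(cis)) next
      y <- Yr[, fi]
      ys <- y / sqrt(sum(y^2))
      x <- Xs[, cis, drop = FALSE]
      r_obs <- drop(crossprod(x, ys))
      p_obs <- r_to_p(r_obs, df)
      lead <- which.min(p_obs)
      Yp <- matrix(ys[perms], n, n_perm)
      r_perm <- crossprod(x, Yp)                     # n_cis x n_perm
      minp <- r_to_p(apply(abs(r_perm), 2, max), df) # smallest p = largest |r|
      ab <- fit_beta_minp(minp)
      obs <- min(p_obs)
      emp <- (1 + sum(minp <= obs)) / (1 + n_perm)
      if (is.null(ab)) {
        warning("beta fit failed for feature ", f,
                "; falling back to empirical permutation p")
        bp <- emp
        ab <- c(NA_real_, NA_real_)
      } else {
        bp <- pbeta(obs, ab[1], ab[2])
      }
      res[[i]] <- data.frame(
        feature = f, lead_variant = G$variants$id[cis[lead]],
        n_cis = length(cis), nominal_p = obs, bpval = max(bp, 1e-300),
        perm_p = emp, beta_a = ab[1], beta_b = ab[2],
        stringsAsFactors = FALSE
      )
    }
    data.table::rbindlist(res)
  })
  as.data.frame(out)
}

# p-value from |correlation| on df residual degrees of freedom
r_to_p <- function(r, df) {
  r <- pmin(abs(r), 1 - 1e-15)
  tt <- r * sqrt(df) / sqrt(1 - r^2)
  2 * pt(-tt, df)
}

#' Storey q-values and null-proportion estimate
#'
#' Estimates the proportion of true nulls pi0 on a lambda grid with a cubic
#' smoothing spline (the natural-spline smoother of the q-value method),
#' evaluated at the largest lambda; for fewer than 100 p-values a fixed
#' lambda of 0.5 is used instead. Q-values are the step-up quantities
#' pi0 * m * p / rank with monotone enforcement from the largest p downward.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @param lambda grid for the pi0 estimate.
#' @param pi0 optional fixed null proportion overriding the estimate (e.g. 1
#'   for plain Benjamini-Hochberg behaviour).
#' @return list with \code{qvalues} (aligned to input order) and \code{pi0}.
#' @export
storey_qvalues <- function(pvals, lambda = seq(0.05, 0.95, 0.05), pi0 = NULL) {
  if (!length(pvals)) stop("empty p-value vector", call. = FALSE)
  if (any(pvals <= 0 | pvals > 1 | !is.finite(pvals)))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  m <- length(pvals)
  if (!is.null(pi0)) {
    # keep the supplied value
  } else if (m < 100) {
    pi0 <- mean(pvals > 0.5) / 0.5
  } else {
    pi0_l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
    sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(sp, max(lambda))$y
  }
  pi0 <- min(max(pi0, 1e-8), 1)
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * pvals[o] / rank(pvals, ties.method = "max")[o]))
  list(qvalues = q[ro], pi0 = pi0)
}

#' Attach q-values and significance calls to a permutation pass
#'
#' @param perm_res output of \code{\link{permutation_pass}}.
#' @param q_cut significance threshold on the q-value (default 0.05).
#' @return \code{perm_res} with added \code{qvalue} and \code{significant}
#'   columns; the pi0 estimate is attached as attribute \code{pi0}.
#' @export
qtl_significance <- function(perm_res, q_cut = 0.05) {
  st <- storey_qvalues(perm_res$bpval)
  perm_res$qvalue <- st$qvalues
  perm_res$significant <- perm_res$qvalue < q_cut
  attr(perm_res, "pi0") <- st$pi0
  perm_res
}

#' Choose the phenotype-PC count that maximizes QTL discoveries
#'
#' Runs the permutation pass with 3 genotype principal components plus each
#' candidate number of phenotype PCs as covariates and returns the candidate
#' yielding the most features significant at q < 0.05, breaking ties toward
#' fewer PCs.
#'
#' @inheritParams permutation_pass
#' @param pc_grid integer vector of phenotype-PC counts to try.
#' @param n_geno_pc number of genotype PCs always included (default 3).
#' @param q_cut significance threshold (default 0.05).
#' @return list with \code{chosen} (element of \code{pc_grid}),
#'   \code{n_significant} (named vector over the grid).
#' @export
select_covariates <- function(G, Y, feature_pos, pc_grid, n_geno_pc = 3,
                              cis_window_bp = 1e6, n_perm = 200, seed = 1L,
                              q_cut = 0.05) {
  if (!length(pc_grid)) stop("pc_grid must be non-empty", call. = FALSE)
  Dstd <- scale(G$dosages)
  Dstd[, !is.finite(colSums(Dstd))] <- 0
  gpc <- stats::prcomp(Dstd, rank. = n_geno_pc)$x
  ypc <- stats::prcomp(scale(t(Y)), rank. = max(pc_grid))$x
  counts <- vapply(pc_grid, function(np) {
    cov <- if (np > 0) cbind(gpc, ypc[, seq_len(np), drop = FALSE]) else gpc
    pr <- permutation_pass(G, Y, feature_pos, covariates = cov,
                           cis_window_bp = cis_window_bp,
                           n_perm = n_perm, seed = seed)
    sum(qtl_significance(pr, q_cut)$significant)
  }, numeric(1))
  names(counts) <- pc_grid
  best <- max(counts)
  chosen <- min(pc_grid[counts == best])
  list(chosen = chosen, n_significant = counts)
}
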