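# Multivariate empirical-Bayes shrinkage of QTL effects across conditions
# (exchangeable-effects parameterization), local false sign rates, and the
# sharing statistics built on the posterior effects.

#' Build the "strong" and "random" effect panels
#'
#' The random panel is a uniform sample of the common test universe and
#' carries the null correlation structure; the strong panel holds, for each
#' feature, the variant with the smallest p-value across all tested variants
#' and all conditions, with effects and standard errors for that variant in
#' every condition (no missing cells).
#'
#' @param stats_list named list of association data.frames (one per
#'   condition) with columns \code{feature}, \code{variant}, \code{beta},
#'   \code{se}, \code{p}.
#' @param random_fraction fraction of the common universe sampled into the
#'   random panel (default 0.30).
#' @param seed integer seed for the random sample.
#' @return list of two panels, \code{strong} and \code{random}; each is a
#'   list with matrices \code{betas} and \code{ses} (rows named
#'   "feature|variant"), and \code{set_label}. Features absent from any
#'   condition are excluded from the strong panel with a message.
#' @export
build_strong_random_sets <- function(stats_list, random_fraction = 0.30,
                                     seed = 1L) {
  stopifnot(is.list(stats_list), length(stats_list) >= 2)
  if (random_fraction <= 0 || random_fraction > 1)
    stop("random_fraction must lie in (0, 1]", call. = FALSE)
  conds <- names(stats_list) %||% paste0("cond", seq_along(stats_list))
  keyed <- lapply(stats_list, function(d) {
    d$key <- paste(d$feature, d$variant, sep = "|")
    d
  })
  common <- Reduce(intersect, lapply(keyed, `[[`, "key"))
  if (!length(common)) stop("no common tests across conditions", call. = FALSE)

  get_mat <- function(keys, col) {
    m <- vapply(keyed, function(d) d[[col]][match(keys, d$key)],
                numeric(length(keys)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(keys))
    dimnames(m) <- list(keys, conds)
    m
  }

  rnd_keys <- with_seed(seed, {
    ns <- max(1L, round(random_fraction * length(common)))
    if (ns >= length(common)) common else sort(sample(common, ns))
  })

  # strong: per feature, argmin p over all variants and conditions
  pmat <- get_mat(common, "p")
  feat <- sub("\\|.*$", "", common)
  minp <- apply(pmat, 1, min)
  strong_keys <- vapply(split(seq_along(common), feat), function(ix) {
    common[ix[which.min(minp[ix])]]
  }, character(1))
  bet_s <- get_mat(strong_keys, "beta")
  ses_s <- get_mat(strong_keys, "se")
  drop_s <- !stats::complete.cases(bet_s) | !stats::complete.cases(ses_s)
  if (any(drop_s)) {
    message("excluding ", sum(drop_s),
            " feature(s) with missing effects from the strong set")
    strong_keys <- strong_keys[!drop_s]
    bet_s <- bet_s[!drop_s, , drop = FALSE]
    ses_s <- ses_s[!drop_s, , drop = FALSE]
  }

  bet_r <- get_mat(rnd_keys, "beta")
  ses_r <- get_mat(rnd_keys, "se")
  ok_r <- stats::complete.cases(bet_r) & stats::complete.cases(ses_r)
  list(
    strong = effect_panel(bet_s, ses_s, "strong"),
    random = effect_panel(bet_r[ok_r, , drop = FALSE],
                          ses_r[ok_r, , drop = FALSE], "random")
  )
}

#' Effect panel constructor
#'
#' @param betas,ses feature x condition matrices without missing values;
#'   \code{ses} strictly positive.
#' @param set_label "strong" or "random".
#' @return list with class \code{effect_panel}.
#' @export
effect_panel <- function(betas, ses, set_label = "strong") {
  betas <- as.matrix(betas); ses <- as.matrix(ses)
  stopifnot(all(dim(betas) == dim(ses)))
  if (anyNA(betas) || anyNA(ses)) stop("panel must have no missing values", call. = FALSE)
  if (any(ses <= 0)) stop("standard errors must be > 0", call. = FALSE)
  structure(list(betas = betas, ses = ses, set_label = set_label),
            class = "effect_panel")
}

# Clip a symmetric matrix to the PSD cone by zeroing negative eigenvalues.
psd_clip <- function(U) {
  e <- eigen((U + t(U)) / 2, symmetric = TRUE)
  if (all(e$values >= -1e-10)) return((U + t(U)) / 2)
  e$vectors %*% diag(pmax(e$values, 0), nrow(U)) %*% t(e$vectors)
}

# Normalize a covariance component so its largest diagonal entry is 1,
# making the scale grid comparable across components.
normalize_component <- function(U) {
  d <- max(diag(U))
  if (d <= 0) U else U / d
}

# Canonical covariance components: identity, per-condition singletons, and
# the rank-1 equal-effects (all-ones) matrix.
canonical_components <- function(R, conds) {
  comps <- list(identity = diag(R))
  for (r in seq_len(R)) {
    U <- matrix(0, R, R); U[r, r] <- 1
    comps[[paste0("singleton_", conds[r])]] <- U
  }
  comps$equal_effects <- matrix(1, R, R)
  comps
}

# Data-driven components from the strong-set z-scores: one rank-1 component
# per top eigenvector of the z covariance, plus the full empirical covariance.
data_driven_components <- function(Z, n_dd) {
  S <- stats::cov(Z)
  e <- eigen(S, symmetric = TRUE)
  k <- min(n_dd, ncol(Z))
  comps <- list()
  for (i in seq_len(k)) {
    if (e$values[i] <= 0) break
    v <- e$vectors[, i]
    comps[[paste0("pca_", i)]] <- e$values[i] * tcrossprod(v)
  }
  comps$empirical <- psd_clip(S)
  comps
}

#' Fit the multivariate shrinkage model
#'
#' Fits the exchangeable-effects (EE) mixture model to the random panel:
#' each observed effect vector is modelled as b_hat_j ~ N(0, S_j + w^2 U_k)
#' where S_j = diag(se_j) V diag(se_j) incorporates the null correlation V,
#' U_k ranges over canonical plus data-driven covariance components, and w
#' over a geometric scale grid; mixture weights (including a null point-mass
#' component) are estimated by EM on the random-set marginal likelihood.
#' Component likelihoods do not depend on the weights, so they are computed
#' once and the EM iterations only re-weight them.
#'
#' @param random,strong \code{\link{effect_panel}} objects sharing a
#'   condition set. Data-driven components are derived from the strong set;
#'   the model is fit on the random set.
#' @param n_dd_components number of eigenvector components derived from the
#'   strong-set z-score covariance (default 5).
#' @param scale_grid positive scale values w; default is a 10-point geometric
#'   sequence over \[0.05 M, 2 M\] with M the largest z-implied effect
#'   standard deviation sqrt(max(beta^2 - se^2, 0)) in the strong set.
#' @param null_z_max |z| threshold below which random-set rows are treated as
#'   null for estimating the null correlation V (default 2).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @return object of class \code{mash_fit}: covariance components, scale
#'   grid, mixture weights (named vector; first element \code{"null"}), null
#'   correlation, and the log-likelihood trace.
#' @export
fit_mash <- function(random, strong, n_dd_components = 5, scale_grid = NULL,
                     null_z_max = 2, tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(random, "effect_panel"), inherits(strong, "effect_panel"))
  R <- ncol(random$betas)
  if (R < 2) stop("need at least 2 conditions", call. = FALSE)
  conds <- colnames(random$betas)

  Zr <- random$betas / random$ses
  null_rows <- rowSums(abs(Zr) < null_z_max) == R
  V <- if (sum(null_rows) >= 20) {
    v <- stats::cor(Zr[null_rows, , drop = FALSE])
    v[!is.finite(v)] <- 0; diag(v) <- 1
    v <- psd_clip(v)
    if (any(diag(v) <= 0)) diag(R) else stats::cov2cor(v)
  } else diag(R)
  dimnames(V) <- list(conds, conds)

  Zs <- strong$betas / strong$ses
  comps <- c(canonical_components(R, conds),
             data_driven_components(Zs, n_dd_components))
  comps <- lapply(comps, function(U) normalize_component(psd_clip(U)))

  if (is.null(scale_grid)) {
    M <- sqrt(max(c(strong$betas^2 - strong$ses^2, 0)))
    if (M <= 0) M <- stats::median(strong$ses)
    scale_grid <- exp(seq(log(0.05 * M), log(2 * M), length.out = 10))
  }
  if (any(scale_grid <= 0)) stop("scale_grid must be positive", call. = FALSE)

  # one-time likelihood matrix: rows = observations, cols = null + comp x scale
  L <- mixture_loglik_matrix(random, comps, scale_grid, V)

  K <- ncol(L)
  w <- rep(1 / K, K)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lw <- sweep(L, 2, log(w), `+`)
    mx <- apply(lw, 1, max)
    lse <- mx + log(rowSums(exp(lw - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(lw - lse)
    w_new <- colMeans(resp)
    if (it > 1 && abs(ll - trace[it - 1]) < tol * (abs(trace[it - 1]) + 1e-8)) {
      w <- w_new; break
    }
    w <- w_new
  }

  structure(list(components = comps, scale_grid = scale_grid,
                 weights = stats::setNames(w, colnames(L)),
                 null_correlation = V, loglik_trace = trace,
                 conditions = conds),
            class = "mash_fit")
}

# Log-likelihood of each observation under each mixture component
# (null first, then each component x scale), N(0, S_j + w^2 U_k).
mixture_loglik_matrix <- function(panel, comps, scale_grid, V) {
  B <- panel$betas; S <- panel$ses
  n <- nrow(B); R <- ncol(B)
  labs <- c("null", as.vector(outer(names(comps), scale_grid,
                                    function(a, b) paste0(a, "@", signif(b, 4)))))
  L <- matrix(NA_real_, n, 1 + length(comps) * length(scale_grid),
              dimnames = list(rownames(B), labs))
  # group observations with identical se rows: common in balanced designs and
  # collapses the per-observation covariance work
  se_key <- apply(S, 1, paste, collapse = ",")
  groups <- split(seq_len(n), se_key)
  Sigma0 <- lapply(groups, function(ix) {
    d <- S[ix[1], ]
    d * t(d * t(V))  # diag(d) V diag(d)
  })
  col <- 1L
  for (ix in seq_along(groups)) {
    L[groups[[ix]], 1] <- dmvnorm0_log(B[groups[[ix]], , drop = FALSE],
                                       Sigma0[[ix]])
  }
  for (cu in seq_along(comps)) for (w in scale_grid) {
    col <- col + 1L
    Uw <- w^2 * comps[[cu]]
    for (ix in seq_along(groups)) {
      L[groups[[ix]], col] <- dmvnorm0_log(B[groups[[ix]], , drop = FALSE],
                                           Sigma0[[ix]] + Uw)
    }
  }
  L
}

# log N(x; 0, Sigma) for rows of X; Sigma fixed.
dmvnorm0_log <- function(X, Sigma) {
  R <- ncol(X)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    Sigma <- Sigma + diag(1e-10 * max(diag(Sigma), 1), R)
    ch <- chol(Sigma)
  }
  z <- backsolve(ch, t(X), transpose = TRUE)
  -0.5 * R * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' Posterior effects and local false sign rates
#'
#' Applies a fitted mixture to the strong panel: per observation, posterior
#' responsibilities over mixture components, mixture posterior means and
#' standard deviations, and the local false sign rate per condition. The
#' LFSR counts the null point mass toward both tails (a conservative
#' convention): lfsr = min(P(effect <= 0), P(effect >= 0)).
#'
#' @param fit a \code{\link{fit_mash}} result.
#' @param strong \code{\link{effect_panel}} with the same condition set.
#' @param weight_floor mixture weights below this are dropped before the
#'   posterior computation (default 1e-10).
#' @return object of class \code{posterior_effects}: matrices
#'   \code{post_mean}, \code{post_sd}, \code{lfsr} (feature x condition).
#' @export
posterior_effects <- function(fit, strong, weight_floor = 1e-10) {
  stopifnot(inherits(fit, "mash_fit"), inherits(strong, "effect_panel"))
  B <- strong$betas; S <- strong$ses
  n <- nrow(B); R <- ncol(B)
  V <- fit$null_correlation
  comps <- fit$components
  grid <- fit$scale_grid
  w <- fit$weights
  keep <- w > weight_floor
  w <- w / sum(w)

  L <- mixture_loglik_matrix(strong, comps, grid, V)
  lw <- sweep(L, 2, log(pmax(w, 1e-300)), `+`)
  lw[, !keep] <- -Inf
  mx <- apply(lw, 1, max)
  resp <- exp(lw - (mx + log(rowSums(exp(lw - mx)))))

  post_mean <- matrix(0, n, R, dimnames = dimnames(B))
  post_m2 <- matrix(0, n, R, dimnames = dimnames(B))
  p_neg <- matrix(0, n, R, dimnames = dimnames(B))
  p_pos <- matrix(0, n, R, dimnames = dimnames(B))
  # null component: point mass at zero in every condition
  p_neg <- p_neg + resp[, 1]
  p_pos <- p_pos + resp[, 1]

  se_key <- apply(S, 1, paste, collapse = ",")
  groups <- split(seq_len(n), se_key)
  col <- 1L
  for (cu in seq_along(comps)) for (wg in grid) {
    col <- col + 1L
    rc <- resp[, col]
    if (max(rc) < 1e-12) next
    Uw <- wg^2 * comps[[cu]]
    for (ix in groups) {
      d <- S[ix[1], ]
      Sig0 <- d * t(d * t(V))
      A <- Uw %*% solve(Sig0 + Uw)        # posterior mean operator
      Pcov <- Uw - A %*% Uw               # posterior covariance
      mu <- B[ix, , drop = FALSE] %*% t(A)
      sdv <- sqrt(pmax(diag(Pcov), 0))
      post_mean[ix, ] <- post_mean[ix, ] + rc[ix] * mu
      post_m2[ix, ] <- post_m2[ix, ] +
        rc[ix] * sweep(mu^2, 2, sdv^2, `+`)
      for (r in seq_len(R)) {
        if (sdv[r] > 0) {
          pn <- pnorm(0, mu[, r], sdv[r])
          p_neg[ix, r] <- p_neg[ix, r] + rc[ix] * pn
          p_pos[ix, r] <- p_pos[ix, r] + rc[ix] * (1 - pn)
        } else {
          zero <- mu[, r] == 0
          p_neg[ix, r] <- p_neg[ix, r] + rc[ix] * (zero | mu[, r] < 0)
          p_pos[ix, r] <- p_pos[ix, r] + rc[ix] * (zero | mu[, r] > 0)
        }
      }
    }
  }
  post_sd <- sqrt(pmax(post_m2 - post_mean^2, 0))
  lfsr <- pmin(pmax(pmin(p_neg, p_pos), 0), 1)
  structure(list(post_mean = post_mean, post_sd = post_sd, lfsr = lfsr),
            class = "posterior_effects")
}

#' Pairwise sharing statistics and per-feature activity
#'
#' Share-by-magnitude between two conditions is the fraction of features
#' significant (lfsr < \code{lfsr_cut}) in at least one of the two whose
#' posterior mean effects have the same sign and differ by no more than
#' \code{fold}-fold; share-by-sign requires only sign concordance.
#'
#' @param post a \code{\link{posterior_effects}} object.
#' @param fold fold-change threshold for share-by-magnitude (default 2).
#' @param lfsr_cut significance threshold on the LFSR (default 0.05).
#' @param subset optional logical or integer index of features to include
#'   (e.g. to exclude a genomic region such as the HLA band and compare).
#' @return list with matrices \code{pairwise_sign} and
#'   \code{pairwise_magnitude} (unit diagonal; NA where no feature is
#'   significant in either condition), vector \code{n_active_per_feature},
#'   and the thresholds used.
#' @export
sharing_stats <- function(post, fold = 2.0, lfsr_cut = 0.05, subset = NULL) {
  pm <- post$post_mean; lf <- post$lfsr
  if (!is.null(subset)) {
    pm <- pm[subset, , drop = FALSE]
    lf <- lf[subset, , drop = FALSE]
  }
  R <- ncol(pm)
  conds <- colnames(pm)
  sig <- lf < lfsr_cut
  mag <- sgn <- matrix(NA_real_, R, R, dimnames = list(conds, conds))
  for (a in seq_len(R)) for (b in seq_len(R)) {
    if (a == b) { mag[a, b] <- sgn[a, b] <- 1; next }
    idx <- sig[, a] | sig[, b]
    if (!any(idx)) next
    x <- pm[idx, a]; y <- pm[idx, b]
    same_sign <- sign(x) * sign(y) > 0
    ratio_ok <- same_sign &
      pmax(abs(x), abs(y)) <= fold * pmin(abs(x), abs(y))
    sgn[a, b] <- mean(same_sign)
    mag[a, b] <- mean(ratio_ok)
  }
  list(pairwise_sign = sgn, pairwise_magnitude = mag,
       n_active_per_feature = rowSums(sig),
       fold = fold, lfsr_cut = lfsr_cut)
}

#' Group conditions by eQTL sharing
#'
#' Average-linkage hierarchical clustering on distance 1 - sharing, cut into
#' \code{k} groups (the paper-style grouping of cell types into sharing
#' groups).
#'
#' @param pairwise_magnitude square symmetric sharing matrix in \[0, 1\].
#' @param k number of groups (default 6).
#' @return named integer vector: condition -> group label.
#' @export
group_cell_types <- function(pairwise_magnitude, k = 6) {
  M <- as.matrix(pairwise_magnitude)
  if (nrow(M) != ncol(M)) stop("sharing matrix must be square", call. = FALSE)
  if (k > nrow(M)) stop("k exceeds the number of conditions", call. = FALSE)
  M[is.na(M)] <- 0
  M <- (M + t(M)) / 2
  d <- stats::as.dist(1 - M)
  hc <- stats::hclust(d, method = "average")
  stats::cutree(hc, k = k)
}
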