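# Multivariate shrinkage: panel construction, EM fit, posteriors, LFSR,
# sharing statistics, and condition grouping.

# Build per-condition association tables over a small feature x variant grid
# with specified p-values / effects.
make_stats <- function(betas, ses, ps, features, variants, conds) {
  lapply(seq_along(conds), function(k) {
    data.frame(feature = rep(features, each = length(variants)),
               variant = rep(variants, length(features)),
               beta = as.vector(t(betas[, , k])),
               se = as.vector(t(ses[, , k])),
               p = as.vector(t(ps[, , k])), stringsAsFactors = FALSE)
  }) |> setNames(conds)
}

# Quick simulated effect panels with a given sharing structure.
sim_panels <- function(n_feat, R, se = 0.05, prop_null = 0.5,
                       pattern = "shared", beta_sd = 0.4, seed = 1) {
  set.seed(seed)
  n_sig <- round(n_feat * (1 - prop_null))
  true <- matrix(0, n_feat, R)
  if (n_sig > 0) {
    base <- rnorm(n_sig, 0, beta_sd)
    base <- sign(base) * pmax(abs(base), 0.15)  # effects bounded away from 0
    for (i in seq_len(n_sig)) {
      true[i, ] <- switch(pattern,
                          shared = base[i],
                          specific = { v <- rep(0, R); v[1 + (i %% R)] <- base[i]; v })
    }
  }
  ses <- matrix(se, n_feat, R)
  bh <- true + matrix(rnorm(n_feat * R, 0, se), n_feat, R)
  colnames(bh) <- colnames(ses) <- paste0("c", seq_len(R))
  # random panel mimics a uniform sample of the cis test universe: mostly null
  # tests, with the causal signals appearing diluted (one cis variant in ~10)
  n_sig_rows <- max(1L, round(n_feat / 10))
  rnd <- rbind(matrix(rnorm(n_feat * R, 0, se), n_feat, R),
               true[sample(n_feat, n_sig_rows), , drop = FALSE] +
                 matrix(rnorm(n_sig_rows * R, 0, se), n_sig_rows, R))
  colnames(rnd) <- colnames(bh)
  list(true = true,
       strong = effect_panel(bh, ses, "strong"),
       random = effect_panel(rnd, matrix(se, nrow(rnd), R,
                                         dimnames = dimnames(rnd)), "random"))
}

test_that("strong set picks the overall argmin-p variant per feature; random boundary works", {
  feats <- c("g1", "g2")
  vars <- c("v1", "v2", "v3")
  set.seed(61)
  ps <- array(runif(12, 0.1, 1), c(2, 3, 2))
  ps[1, 2, 2] <- 1e-8  # g1: best at v2 in condition 2
  ps[2, 3, 1] <- 1e-6  # g2: best at v3 in condition 1
  betas <- array(rnorm(12), c(2, 3, 2))
  ses <- array(0.1, c(2, 3, 2))
  stats <- make_stats(betas, ses, ps, feats, vars, c("A", "B"))
  sets <- build_strong_random_sets(stats, random_fraction = 1, seed = 1)
  # brute-force argmin oracle over the p tensor
  expect_setequal(rownames(sets$strong$betas), c("g1|v2", "g2|v3"))
  # random_fraction = 1 recovers the full universe
  expect_equal(nrow(sets$random$betas), 6)
  expect_false(anyNA(sets$strong$betas))
  expect_false(anyNA(sets$strong$ses))
})

test_that("EM log-likelihood is non-decreasing and a pure-null random set loads the null", {
  pans <- sim_panels(300, 4, prop_null = 1, seed = 62)
  # strong set needs some non-null rows for data-driven components; use a
  # separate signal panel
  sig <- sim_panels(200, 4, prop_null = 0, seed = 63)
  fit <- fit_mash(pans$random, sig$strong)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8 * abs(fit$loglik_trace[-1])))
  # weight on the null plus the smallest scale dominates for null data
  w <- fit$weights
  small_scale <- grepl(paste0("@", signif(fit$scale_grid[1], 4)), names(w))
  expect_gt(w[["null"]] + sum(w[small_scale]), 0.9)
})

test_that("one-condition-style conjugate shrinkage is recovered by the posterior", {
  # two conditions but a diagonal component and independent noise: condition 1
  # behaves as the conjugate normal-normal problem b * W/(W + se^2)
  R <- 2
  W <- 0.3^2
  se <- 0.1
  bh <- matrix(c(0.25, -0.1), 1, 2, dimnames = list("f", c("c1", "c2")))
  ses <- matrix(se, 1, 2, dimnames = dimnames(bh))
  fit <- structure(list(
    components = list(identity = diag(2)),
    scale_grid = sqrt(W),
    weights = c(null = 0, `identity@0.3` = 1),
    null_correlation = diag(2),
    conditions = c("c1", "c2")), class = "mash_fit")
  post <- posterior_effects(fit, effect_panel(bh, ses))
  expect_equal(post$post_mean[1, 1], 0.25 * W / (W + se^2), tolerance = 1e-10)
  expect_equal(post$post_mean[1, 2], -0.1 * W / (W + se^2), tolerance = 1e-10)
  # posterior sd matches the conjugate posterior variance
  expect_equal(post$post_sd[1, 1], sqrt(W * se^2 / (W + se^2)),
               tolerance = 1e-10)
})

test_that("posterior mean matches fine-grid numerical integration on a 2-component toy", {
  # mixture prior: w1 N(0, U1) + w2 N(0, U2) on 2 conditions; independent noise
  U1 <- diag(2)
  U2 <- matrix(c(1, 0.99, 0.99, 1), 2)
  w <- c(0.4, 0.6)
  scale <- 0.5
  se <- c(0.15, 0.2)
  bh <- c(0.3, 0.22)
  fit <- structure(list(
    components = list(A = U1, B = U2),
    scale_grid = scale,
    weights = c(null = 0, `A@0.5` = w[1], `B@0.5` = w[2]),
    null_correlation = diag(2),
    conditions = c("c1", "c2")), class = "mash_fit")
  panel <- effect_panel(matrix(bh, 1, 2, dimnames = list("f", c("c1", "c2"))),
                        matrix(se, 1, 2, dimnames = list("f", c("c1", "c2"))))
  post <- posterior_effects(fit, panel)

  # oracle: numerical integration on a fine grid over the true effect
  gr <- seq(-2, 2, length.out = 601)
  grid2 <- expand.grid(b1 = gr, b2 = gr)
  dens_prior <- function(U) {
    S <- scale^2 * U + diag(1e-12, 2)
    ch <- chol(S)
    z <- backsolve(ch, t(as.matrix(grid2)), transpose = TRUE)
    exp(-0.5 * colSums(z^2)) / (2 * pi * prod(diag(ch)))
  }
  prior <- w[1] * dens_prior(U1) + w[2] * dens_prior(U2)
  lik <- dnorm(bh[1], grid2$b1, se[1]) * dnorm(bh[2], grid2$b2, se[2])
  postd <- prior * lik
  postd <- postd / sum(postd)
  expect_equal(post$post_mean[1, 1], sum(grid2$b1 * postd), tolerance = 1e-3)
  expect_equal(post$post_mean[1, 2], sum(grid2$b2 * postd), tolerance = 1e-3)
})

test_that("no-information and symmetric limits behave correctly", {
  pans <- sim_panels(100, 3, prop_null = 0.5, seed = 64)
  fit <- fit_mash(pans$random, pans$strong)
  # enormous standard errors: full shrinkage to zero
  big <- effect_panel(matrix(0.3, 2, 3, dimnames = list(NULL, paste0("c", 1:3))),
                      matrix(50, 2, 3, dimnames = list(NULL, paste0("c", 1:3))))
  post <- posterior_effects(fit, big)
  expect_lt(max(abs(post$post_mean)), 1e-3)
  # lfsr = 0.5 when the posterior is symmetric about zero (b_hat = 0)
  zero <- effect_panel(matrix(0, 1, 3, dimnames = list(NULL, paste0("c", 1:3))),
                       matrix(0.1, 1, 3, dimnames = list(NULL, paste0("c", 1:3))))
  post0 <- posterior_effects(fit, zero)
  expect_true(all(abs(post0$lfsr - 0.5) < 0.51) & all(post0$lfsr >= 0.49))
})

test_that("shrinkage dominance: posterior RMSE beats raw RMSE; effects bounded by input range", {
  pans <- sim_panels(400, 5, se = 0.08, prop_null = 0.4, seed = 65)
  fit <- fit_mash(pans$random, pans$strong)
  post <- posterior_effects(fit, pans$strong)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(post$post_mean, pans$true), rmse(pans$strong$betas, pans$true))
  expect_lte(max(abs(post$post_mean)), max(abs(pans$strong$betas)) + 1e-9)
  expect_true(all(post$lfsr >= 0 & post$lfsr <= 1))
})

test_that("sharing thresholds implement the twofold rule and sign rule", {
  pm <- cbind(c1 = c(0.5, 0.5, 0.3), c2 = c(1.1, 0.9, -0.3))
  lf <- matrix(0, 3, 2, dimnames = list(NULL, c("c1", "c2")))
  post <- structure(list(post_mean = pm, post_sd = pm * 0 + 0.1, lfsr = lf),
                    class = "posterior_effects")
  sh <- sharing_stats(post)
  # 0.5 vs 1.1 -> ratio 2.2 not shared; 0.5 vs 0.9 shared; 0.3 vs -0.3 opposite
  expect_equal(sh$pairwise_magnitude["c1", "c2"], 1 / 3)
  expect_equal(sh$pairwise_sign["c1", "c2"], 2 / 3)
  expect_equal(diag(sh$pairwise_magnitude), c(c1 = 1, c2 = 1))
  # identical significant columns share fully
  post2 <- structure(list(post_mean = cbind(a = pm[, 1], b = pm[, 1]),
                          post_sd = pm * 0 + 0.1, lfsr = lf), class = "posterior_effects")
  sh2 <- sharing_stats(post2)
  expect_equal(sh2$pairwise_magnitude["a", "b"], 1)
})

test_that("sharing on a subset (region exclusion) is reportable and close to the full estimate", {
  pans <- sim_panels(600, 4, se = 0.05, prop_null = 0.3, seed = 66)
  fit <- fit_mash(pans$random, pans$strong)
  post <- posterior_effects(fit, pans$strong)
  sh_all <- sharing_stats(post)
  drop_idx <- seq_len(600) > 60  # exclude a 10% block of features
  sh_sub <- sharing_stats(post, subset = drop_idx)
  delta <- abs(sh_all$pairwise_magnitude - sh_sub$pairwise_magnitude)
  expect_lt(max(delta, na.rm = TRUE), 0.1)
})

test_that("condition grouping recovers block structure and handles boundaries", {
  # 6 conditions in 3 perfect blocks
  M <- matrix(0.05, 6, 6, dimnames = list(paste0("c", 1:6), paste0("c", 1:6)))
  blocks <- list(1:2, 3:4, 5:6)
  for (b in blocks) M[b, b] <- 1
  g <- group_cell_types(M, k = 3)
  # brute-force check: within-block equal labels, across-block distinct
  for (b in blocks) expect_equal(length(unique(g[b])), 1L)
  expect_equal(length(unique(g)), 3L)
  # duplicate conditions always co-cluster
  M2 <- matrix(1, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(length(unique(group_cell_types(M2, k = 1))), 1L)
  # k = n gives singletons; k > n errors
  expect_equal(length(unique(group_cell_types(M, k = 6))), 6L)
  expect_error(group_cell_types(M, k = 7), "exceeds")
})
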