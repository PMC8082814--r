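#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on genotype counts: conditional on the observed
#' allele counts, the p-value is the sum of the probabilities of all
#' heterozygote counts no more probable than the observed one. Preferred over
#' the chi-square test for robustness at low counts.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return exact two-sided p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  hets <- seq.int(rare %% 2, rare, by = 2)
  # log P(h heterozygotes | allele counts), up to a common constant
  lp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) -
      lgamma(n - h - hom_rare + 1) + h * log(2) -
      (lgamma(2 * n + 1) - lgamma(n_a + 1) - lgamma(n_b + 1))
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  if (is.na(obs)) return(1)  # impossible configuration given allele parity
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Variant quality-control filters
#'
#' Applies the standard association-study filters in a fixed order:
#' missingness, then minor allele frequency, then an exact Hardy-Weinberg
#' test on hard-called genotypes (dosages rounded to 0/1/2).
#'
#' @param G a \code{\link{genotype_matrix}}; dosages may contain \code{NA}.
#' @param maf_min minimum empirical minor allele frequency (default 0.05).
#' @param hwe_p_min minimum exact HWE p-value (default 1e-5).
#' @param miss_max maximum per-variant missing rate (default 0.05).
#' @param impute_missing impute surviving missing dosages to the per-variant
#'   mean (default TRUE), so downstream regressions see complete data.
#' @return filtered \code{\link{genotype_matrix}}; a warning (not an error)
#'   is emitted when no variant survives.
#' @export
filter_variants <- function(G, maf_min = 0.05, hwe_p_min = 1e-5,
                            miss_max = 0.05, impute_missing = TRUE) {
  D <- G$dosages
  miss <- colMeans(is.na(D))
  keep <- miss <= miss_max

  maf <- empirical_maf(D)
  keep <- keep & !is.na(maf) & maf >= maf_min

  hard <- round(D)
  hwe <- rep(1, ncol(D))
  for (j in which(keep)) {
    g <- hard[, j]
    g <- g[!is.na(g)]
    hwe[j] <- hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2))
  }
  keep <- keep & hwe >= hwe_p_min

  if (!any(keep)) {
    warning("no variants pass filters; returning empty genotype_matrix")
  }
  out <- subset_variants(G, which(keep))
  out$variants$maf <- pmax(pmin(maf[keep], 0.5), 1e-12)
  if (impute_missing && anyNA(out$dosages)) {
    for (j in seq_len(ncol(out$dosages))) {
      x <- out$dosages[, j]
      if (anyNA(x)) out$dosages[is.na(x), j] <- mean(x, na.rm = TRUE)
    }
  }
  out
}

#' Rank-based inverse-normal expression normalization
#'
#' Optionally rescales each sample (column) to a common library size, then
#' maps each feature (row) to standard-normal quantiles of its sample ranks
#' using the offset convention (rank - 0.5)/n with ties broken by average
#' rank. Output rows have mean ~0 and variance ~1 and pass normality checks
#' for moderate n.
#'
#' @param tpm non-negative feature x sample matrix (e.g. gene-level TPM).
#' @param library_scale scale each column to the mean column total before the
#'   rank transform (default TRUE). With TPM input this is nearly a no-op but
#'   guards against columns that do not sum to a common total.
#' @return normalized feature x sample matrix; constant features become
#'   all-zero rows with a warning.
#' @export
normalize_expression <- function(tpm, library_scale = TRUE) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be >= 0", call. = FALSE)
  if (library_scale) {
    tot <- colSums(tpm, na.rm = TRUE)
    tot[tot == 0] <- 1
    tpm <- sweep(tpm, 2, mean(tot) / tot, `*`)
  }
  n <- ncol(tpm)
  out <- t(apply(tpm, 1, function(x) {
    if (length(unique(x[!is.na(x)])) <= 1) return(rep(0, n))
    qnorm((rank(x, ties.method = "average", na.last = "keep") - 0.5) / sum(!is.na(x)))
  }))
  dimnames(out) <- dimnames(tpm)
  n_const <- sum(apply(tpm, 1, function(x) length(unique(x[!is.na(x)])) <= 1))
  if (n_const > 0)
    warning(n_const, " constant feature(s) set to all-zero rows")
  out
}
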