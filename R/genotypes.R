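#' Genotype matrix container
#'
#' Holds per-sample allele dosages together with variant metadata. This is the
#' common currency for LD computation, QTL scans and GWAS simulation.
#'
#' @param dosages numeric samples x variants matrix with entries in \[0, 2\]
#'   (missing values allowed as \code{NA}).
#' @param variants data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   (1-based), \code{ref}, \code{alt}, \code{maf}; one row per column of
#'   \code{dosages}.
#' @param samples character vector of sample ids, one per row of
#'   \code{dosages}.
#'
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{dosages}, \code{variants}, \code{samples}.
#' @export
genotype_matrix <- function(dosages, variants, samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosages)))
  stopifnot(
    ncol(dosages) == nrow(variants),
    length(samples) == nrow(dosages),
    all(c("id", "chrom", "pos", "ref", "alt", "maf") %in% names(variants))
  )
  if (anyDuplicated(variants$id))
    stop("duplicated variant ids", call. = FALSE)
  if (any(!is.na(variants$maf) & (variants$maf <= 0 | variants$maf > 0.5)))
    stop("variant maf must lie in (0, 0.5]", call. = FALSE)
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch,
           call. = FALSE)
  }
  if (length(dosages) && any(!is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2)
      stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  rownames(dosages) <- samples
  colnames(dosages) <- variants$id
  structure(
    list(dosages = dosages, variants = as.data.frame(variants),
         samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants on %s\n",
              length(x$samples), nrow(x$variants),
              paste(unique(x$variants$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# Subset a genotype_matrix by variant index/logical, keeping metadata aligned.
subset_variants <- function(G, idx) {
  keep_attrs <- attr(G, "sim_params")
  out <- genotype_matrix(G$dosages[, idx, drop = FALSE],
                         G$variants[idx, , drop = FALSE], G$samples)
  if (!is.null(keep_attrs)) {
    keep_attrs$mafs <- keep_attrs$mafs[idx]
    attr(out, "sim_params") <- keep_attrs
  }
  out
}

#' Simulate LD-structured genotype dosages
#'
#' Generates diploid dosages from a haplotype-level threshold model: each
#' sample carries two independent latent Gaussian haplotype processes with
#' first-order autoregressive correlation \code{ld_rho} between adjacent
#' variants; each latent value is thresholded at the normal quantile of the
#' variant's minor allele frequency, and the dosage is the sum of the two
#' haplotype alleles. Working at the haplotype level keeps genotype
#' frequencies at Hardy-Weinberg proportions by construction.
#'
#' @param n_samples number of diploid samples (>= 2).
#' @param n_variants total number of variants.
#' @param chrom_layout named integer vector giving variants per chromosome
#'   (names are chromosome labels); defaults to all variants on chromosome
#'   "1". The AR(1) process restarts at each chromosome boundary.
#' @param ld_rho latent AR(1) correlation between adjacent variants, in
#'   \[0, 1).
#' @param maf_range length-2 interval within (0, 0.5\] from which per-variant
#'   minor allele frequencies are drawn uniformly.
#' @param spacing_bp base-pair distance between adjacent variants.
#' @param start_bp position of the first variant on each chromosome.
#' @param seed integer seed; output is bit-identical for a fixed seed.
#'
#' @return A \code{\link{genotype_matrix}}. The generating parameters are
#'   attached as attribute \code{sim_params} so that downstream simulators
#'   (e.g. \code{\link{simulate_gwas_summary}}) can draw fresh cohorts from
#'   the same population.
#' @export
simulate_genotypes <- function(n_samples, n_variants, chrom_layout = NULL,
                               ld_rho = 0.5, maf_range = c(0.05, 0.5),
                               spacing_bp = 5000L, start_bp = 100000L,
                               seed = 1L) {
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  if (!is.numeric(ld_rho) || ld_rho < 0 || ld_rho >= 1)
    stop("ld_rho must lie in [0, 1)", call. = FALSE)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]", call. = FALSE)
  if (is.null(chrom_layout)) chrom_layout <- c("1" = as.integer(n_variants))
  if (sum(chrom_layout) != n_variants)
    stop("chrom_layout must sum to n_variants", call. = FALSE)

  with_seed(seed, {
    mafs <- runif(n_variants, maf_range[1], maf_range[2])
    thr <- qnorm(mafs)
    ar1_latent <- function() {
      z <- matrix(NA_real_, n_samples, n_variants)
      j0 <- 0L
      for (nv in chrom_layout) {
        z[, j0 + 1L] <- rnorm(n_samples)
        if (nv > 1) for (j in 2:nv)
          z[, j0 + j] <- ld_rho * z[, j0 + j - 1L] +
            sqrt(1 - ld_rho^2) * rnorm(n_samples)
        j0 <- j0 + nv
      }
      z
    }
    hap1 <- ar1_latent() < rep(thr, each = n_samples)
    hap2 <- ar1_latent() < rep(thr, each = n_samples)
    dos <- hap1 + hap2
    storage.mode(dos) <- "double"

    chroms <- rep(names(chrom_layout), chrom_layout)
    pos <- unlist(lapply(chrom_layout, function(nv)
      start_bp + spacing_bp * (seq_len(nv) - 1L)), use.names = FALSE)
    alleles <- c("A", "C", "G", "T")
    ref <- alleles[1 + (seq_len(n_variants) - 1L) %% 4L]
    alt <- alleles[1 + seq_len(n_variants) %% 4L]
    variants <- data.frame(
      id = sprintf("%s:%d:%s:%s", chroms, pos, ref, alt),
      chrom = chroms, pos = pos, ref = ref, alt = alt, maf = mafs,
      stringsAsFactors = FALSE
    )
    G <- genotype_matrix(dos, variants,
                         samples = sprintf("S%04d", seq_len(n_samples)))
    attr(G, "sim_params") <- list(ld_rho = ld_rho, mafs = mafs,
                                  chrom_layout = chrom_layout)
    G
  })
}

# Empirical minor allele frequency from dosages (folded).
empirical_maf <- function(dosages) {
  f <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Pairwise LD (r-squared) against a reference variant
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param ref_id variant id against which r2 is computed.
#' @return named numeric vector of squared Pearson dosage correlations.
#' @export
ld_r2 <- function(G, ref_id) {
  j <- match(ref_id, G$variants$id)
  if (is.na(j)) stop("variant not found: ", ref_id, call. = FALSE)
  x <- G$dosages[, j]
  if (stats::sd(x, na.rm = TRUE) == 0)
    stop("reference variant is monomorphic", call. = FALSE)
  r <- suppressWarnings(stats::cor(G$dosages, x, use = "pairwise.complete.obs"))
  out <- drop(r)^2
  names(out) <- G$variants$id
  out
}
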