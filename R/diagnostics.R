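# Diagnostics for cell-type specificity and for uncolocalized loci: LD-bin
# p-value profiles, pi1 replication with bootstrap confidence intervals,
# targeted lead-SNP association tests, and peak-overlap enrichment.

LD_BINS <- cbind(lower = c(0, 0.25, 0.5, 0.75),
                 upper = c(0.25, 0.5, 0.75, 1))

#' LD-bin p-value profile at a colocalized locus
#'
#' Bins all variants within \code{window_bp} of the locus lead by their LD
#' (r2 of dosages in the reference panel) with the lead, using the four bins
#' (0, 0.25\], (0.25, 0.5\], (0.5, 0.75\], (0.75, 1\], and records the
#' minimal QTL p-value per cell group per bin as -log10 p. When a shared
#' causal variant drives both the GWAS and the QTL in a group, the minimal
#' -log10 p should rise monotonically across bins; a flat or inverted
#' profile in a group indicates that group does not carry the signal.
#'
#' @param locus one row of a \code{\link{define_loci}} result.
#' @param feature feature id whose QTL statistics are profiled.
#' @param ref_genotypes \code{\link{genotype_matrix}} used for r2; the lead
#'   variant must be present and polymorphic.
#' @param qtl_stats_per_group named list of association data.frames (columns
#'   \code{feature}, \code{variant}, \code{p}), one per cell group.
#' @param window_bp window around the lead (default 1 Mb).
#' @return list with \code{profile} (group x bin matrix of -log10 minimal p;
#'   NA for empty bins), \code{bins}, \code{lead_to_strong_r2} (r2 between
#'   the lead and the variant with the smallest QTL p across groups), and
#'   \code{locus_id}, \code{feature}.
#' @export
ld_bin_profile <- function(locus, feature, ref_genotypes, qtl_stats_per_group,
                           window_bp = 1e6) {
  r2 <- ld_r2(ref_genotypes, locus$lead_variant)
  v <- ref_genotypes$variants
  in_win <- v$chrom == locus$chrom & abs(v$pos - locus$pos) <= window_bp
  groups <- names(qtl_stats_per_group)
  prof <- matrix(NA_real_, length(groups), nrow(LD_BINS),
                 dimnames = list(groups,
                                 sprintf("(%g,%g]", LD_BINS[, 1], LD_BINS[, 2])))
  best_p <- Inf; best_variant <- NA_character_
  for (gi in seq_along(groups)) {
    st <- qtl_stats_per_group[[gi]]
    st <- st[st$feature == feature & st$variant %in% v$id[in_win], ]
    if (!nrow(st)) next
    vr2 <- r2[st$variant]
    if (min(st$p) < best_p) {
      best_p <- min(st$p)
      best_variant <- st$variant[which.min(st$p)]
    }
    for (b in seq_len(nrow(LD_BINS))) {
      inb <- !is.na(vr2) & vr2 > LD_BINS[b, 1] & vr2 <= LD_BINS[b, 2]
      if (any(inb)) prof[gi, b] <- -log10(min(st$p[inb]))
    }
  }
  list(profile = prof, bins = LD_BINS,
       lead_to_strong_r2 = if (is.na(best_variant)) NA_real_ else
         unname(r2[best_variant]),
       locus_id = locus$locus_id, feature = feature)
}

#' Monotone-increase check for one LD-bin profile row
#'
#' Empty bins (NA) are skipped rather than counted against monotonicity.
#'
#' @param x numeric vector ordered from the lowest to the highest r2 bin.
#' @return TRUE when the non-missing values are non-decreasing.
#' @export
is_bin_monotone <- function(x) {
  x <- x[!is.na(x)]
  length(x) <= 1 || all(diff(x) >= 0)
}

#' pi1 replication statistic with bootstrap confidence interval
#'
#' pi1 = 1 - pi0, where pi0 is the Storey estimate of the null proportion
#' among the replication p-values of discovery-significant QTLs. The
#' confidence interval resamples discovery entries with replacement.
#'
#' @param replication_p p-values of the discovery hits in the replication
#'   dataset, aligned one-to-one with the discovery entries.
#' @param n_bootstrap bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return list: \code{pi1}, \code{ci_low}, \code{ci_high},
#'   \code{n_bootstrap}, \code{unstable} (TRUE when fewer than 20 entries).
#' @export
pi1_replication <- function(replication_p, n_bootstrap = 1000, seed = 1L,
                            conf = 0.95) {
  if (!length(replication_p)) stop("no replication p-values", call. = FALSE)
  est <- function(p) max(0, min(1, 1 - storey_qvalues(p)$pi0))
  pi1 <- est(replication_p)
  unstable <- length(replication_p) < 20
  if (unstable)
    warning("fewer than 20 entries; bootstrap interval is unstable")
  boots <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(i) {
      est(sample(replication_p, replace = TRUE))
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(a, 1 - a)))
  list(pi1 = pi1, ci_low = min(ci[1], pi1), ci_high = max(ci[2], pi1),
       n_bootstrap = n_bootstrap, unstable = unstable)
}

#' Targeted lead-SNP association at uncolocalized loci
#'
#' For each uncolocalized locus, tests only the lead variant against every
#' gene whose anchor lies within \code{window_bp}, excluding locus-gene
#' pairs already tested in colocalization. P-values are Bonferroni-adjusted
#' by the number of genes tested at the locus, and the best (smallest
#' adjusted p) gene per locus is reported, along with the proportion of loci
#' whose best adjusted p falls below 0.05. Testing a single variant per gene
#' gives this design far more power than a genome-wide scan, at the price of
#' only detecting effects at the lead.
#'
#' @param uncoloc_loci data.frame of loci (rows of \code{\link{define_loci}}
#'   output) previously classified uncolocalized.
#' @param G \code{\link{genotype_matrix}} of the QTL cohort.
#' @param Y feature x sample phenotype matrix.
#' @param feature_pos data.frame \code{feature}, \code{chrom}, \code{pos}.
#' @param covariates optional sample x k matrix.
#' @param window_bp gene-inclusion window around the lead (default 1 Mb).
#' @param already_tested optional data.frame with columns \code{locus_id},
#'   \code{feature} of pairs to exclude.
#' @return list with \code{per_locus} (data.frame: locus_id, best_feature,
#'   raw_p, n_genes, adj_p, significant) and \code{proportion_significant};
#'   loci with zero eligible genes are excluded from the denominator.
#' @export
targeted_lead_snp_test <- function(uncoloc_loci, G, Y, feature_pos,
                                   covariates = NULL, window_bp = 1e6,
                                   already_tested = NULL) {
  n <- ncol(Y)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  df <- n - k - 2L
  Xr <- residualize(G$dosages, covariates)
  Yr <- residualize(t(Y), covariates)
  rows <- list()
  for (i in seq_len(nrow(uncoloc_loci))) {
    loc <- uncoloc_loci[i, ]
    j <- match(loc$lead_variant, G$variants$id)
    if (is.na(j)) next
    genes <- feature_pos$feature[
      feature_pos$chrom == loc$chrom &
        abs(feature_pos$pos - loc$pos) <= window_bp]
    if (!is.null(already_tested)) {
      drop <- already_tested$feature[already_tested$locus_id == loc$locus_id]
      genes <- setdiff(genes, drop)
    }
    genes <- intersect(genes, rownames(Y))
    if (!length(genes)) next
    x <- Xr[, j]
    sxx <- sum(x^2)
    if (sxx == 0) next
    ps <- vapply(genes, function(g) {
      y <- Yr[, match(g, rownames(Y))]
      beta <- sum(x * y) / sxx
      rss <- sum(y^2) - beta^2 * sxx
      se <- sqrt(max(rss, 0) / df / sxx)
      2 * pt(-abs(beta / se), df)
    }, numeric(1))
    adj <- pmin(1, ps * length(genes))
    b <- which.min(adj)
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = loc$locus_id, best_feature = genes[b], raw_p = ps[b],
      n_genes = length(genes), adj_p = adj[b],
      significant = adj[b] < 0.05, stringsAsFactors = FALSE
    )
  }
  per_locus <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(), best_feature = character(),
               raw_p = numeric(), n_genes = integer(), adj_p = numeric(),
               significant = logical())
  rownames(per_locus) <- NULL
  list(per_locus = per_locus,
       proportion_significant = if (nrow(per_locus))
         mean(per_locus$significant) else NA_real_)
}

#' Peak-overlap enrichment of uncolocalized versus colocalized loci
#'
#' Builds the 2x2 table of colocalized/uncolocalized loci whose lead variant
#' falls inside/outside the peak set, tests it with a two-sided Fisher exact
#' test, and reports the log2 sample odds ratio with a bootstrap confidence
#' interval obtained by resampling the uncolocalized loci with replacement.
#' Variant positions are 1-based; peaks are 0-based half-open (BED), so a
#' variant at position p overlaps a peak when start <= p - 1 < end.
#'
#' @param coloc_loci,uncoloc_loci data.frames of loci with \code{chrom} and
#'   \code{pos} (lead variant coordinates).
#' @param peaks data.frame of BED intervals: \code{chrom}, \code{start},
#'   \code{end}.
#' @param n_bootstrap bootstrap replicates for the CI (default 1000).
#' @param seed integer seed.
#' @return list: \code{table} (2x2: rows uncoloc/coloc, cols in/out),
#'   \code{log2_odds_ratio}, \code{fisher_p}, \code{ci_low}, \code{ci_high},
#'   \code{haldane} (TRUE when the 0.5 correction was applied).
#' @export
peak_enrichment <- function(coloc_loci, uncoloc_loci, peaks,
                            n_bootstrap = 1000, seed = 1L) {
  if (is.null(peaks) || !nrow(peaks)) stop("empty peak set", call. = FALSE)
  overlaps <- function(loci) {
    vapply(seq_len(nrow(loci)), function(i) {
      p0 <- loci$pos[i] - 1L
      any(peaks$chrom == loci$chrom[i] & peaks$start <= p0 & p0 < peaks$end)
    }, logical(1))
  }
  ov_u <- overlaps(uncoloc_loci)
  ov_c <- overlaps(coloc_loci)
  tab <- matrix(c(sum(ov_u), sum(!ov_u), sum(ov_c), sum(!ov_c)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("uncoloc", "coloc"), c("in_peak", "out_peak")))
  lor <- function(a, b, c, d) {
    hald <- any(c(a, b, c, d) == 0)
    if (hald) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
    list(lor = log2(a * d / (b * c)), haldane = hald)
  }
  pt_est <- lor(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  fp <- stats::fisher.test(tab)$p.value
  boots <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(i) {
      ou <- sample(ov_u, replace = TRUE)
      lor(sum(ou), sum(!ou), sum(ov_c), sum(!ov_c))$lor
    }, numeric(1))
  })
  ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  list(table = tab, log2_odds_ratio = pt_est$lor, fisher_p = fp,
       ci_low = ci[1], ci_high = ci[2], haldane = pt_est$haldane)
}
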