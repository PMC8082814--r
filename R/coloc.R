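# GWAS locus definition by greedy clumping, QTL ascertainment, and
# colocalization posteriors from Wakefield approximate Bayes factors.

#' Define GWAS loci by greedy clumping
#'
#' Repeatedly takes the remaining variant with the smallest p-value as a
#' lead, removes all variants within \code{half_window_bp} on either side of
#' it (yielding a 1 Mb locus at the default), and stops when no variant
#' below \code{p_threshold} remains. Leads falling inside an exclusion
#' region (default: the HLA band, chromosome 6, 25-35 Mb) are recorded but
#' flagged excluded. Ties in p are broken toward the smaller genomic
#' coordinate, so the output is deterministic and independent of input row
#' order.
#'
#' @param gwas association data.frame with columns \code{variant},
#'   \code{chrom}, \code{pos}, \code{p} (and optionally \code{trait}).
#' @param p_threshold genome-wide lead threshold (default 1e-7).
#' @param half_window_bp half-width of the removal window (default 500 kb).
#' @param exclusions data.frame of regions (\code{chrom}, \code{start},
#'   \code{end}) whose leads are excluded; default HLA.
#' @param trait trait label attached to the output.
#' @return data.frame of loci: \code{trait}, \code{locus_id},
#'   \code{lead_variant}, \code{chrom}, \code{pos}, \code{p}, \code{start},
#'   \code{end}, \code{excluded}, \code{reason}, plus a list-column
#'   \code{members} of member variant ids.
#' @export
define_loci <- function(gwas, p_threshold = 1e-7, half_window_bp = 5e5,
                        exclusions = hla_region(), trait = "trait") {
  stopifnot(all(c("variant", "chrom", "pos", "p") %in% names(gwas)))
  g <- gwas[order(gwas$p, gwas$chrom, gwas$pos), ]
  active <- rep(TRUE, nrow(g))
  out <- list()
  li <- 0L
  repeat {
    cand <- which(active)[1]
    if (is.na(cand) || g$p[cand] >= p_threshold) break
    lead <- g[cand, ]
    in_win <- active & g$chrom == lead$chrom &
      abs(g$pos - lead$pos) <= half_window_bp
    members <- g$variant[in_win]
    active[in_win] <- FALSE
    excl <- in_region(lead$chrom, lead$pos, exclusions)
    li <- li + 1L
    out[[li]] <- data.frame(
      trait = trait, locus_id = sprintf("%s_locus%d", trait, li),
      lead_variant = lead$variant, chrom = lead$chrom, pos = lead$pos,
      p = lead$p, start = lead$pos - half_window_bp,
      end = lead$pos + half_window_bp,
      excluded = excl,
      reason = if (excl) "lead in exclusion region" else "",
      stringsAsFactors = FALSE
    )
    out[[li]]$members <- I(list(members))
  }
  if (!length(out)) {
    return(data.frame(trait = character(), locus_id = character(),
                      lead_variant = character(), chrom = character(),
                      pos = integer(), p = numeric(), start = integer(),
                      end = integer(), excluded = logical(),
                      reason = character()))
  }
  do.call(rbind, out)
}

#' The HLA exclusion region
#' @return data.frame with one region: chromosome 6, 25-35 Mb.
#' @export
hla_region <- function() {
  data.frame(chrom = "6", start = 25e6, end = 35e6, stringsAsFactors = FALSE)
}

in_region <- function(chrom, pos, regions) {
  if (is.null(regions) || !nrow(regions)) return(FALSE)
  any(regions$chrom == chrom & pos >= regions$start & pos <= regions$end)
}

#' Ascertain QTL features for colocalization at a locus
#'
#' A feature qualifies when its permutation significance passes
#' \code{bpval < bpval_max} and its anchor lies within \code{window_bp} of
#' the locus lead variant.
#'
#' @param locus one row of a \code{\link{define_loci}} result.
#' @param qtl_results data.frame from \code{\link{permutation_pass}}.
#' @param feature_pos data.frame with \code{feature}, \code{chrom},
#'   \code{pos} anchors.
#' @param bpval_max ascertainment threshold (default 0.01).
#' @param window_bp window around the lead (default 1 Mb).
#' @return character vector of qualifying feature ids (possibly empty).
#' @export
ascertain_features <- function(locus, qtl_results, feature_pos,
                               bpval_max = 0.01, window_bp = 1e6) {
  hit <- qtl_results$bpval < bpval_max
  fp <- feature_pos[match(qtl_results$feature, feature_pos$feature), ]
  in_win <- fp$chrom == locus$chrom & abs(fp$pos - locus$pos) <= window_bp
  qtl_results$feature[which(hit & in_win)]
}

#' Wakefield log approximate Bayes factor
#'
#' log ABF = 0.5 log(se^2/(se^2 + W^2)) + 0.5 z^2 W^2/(se^2 + W^2) with
#' z = beta/se and W the prior standard deviation of the effect.
#'
#' @param beta,se effect estimate and standard error (se > 0); vectorized.
#' @param W prior effect standard deviation (> 0).
#' @return log ABF (natural log).
#' @export
wakefield_log_abf <- function(beta, se, W = 0.15) {
  if (any(se <= 0)) stop("se must be > 0", call. = FALSE)
  if (any(W <= 0)) stop("W must be > 0", call. = FALSE)
  z2 <- (beta / se)^2
  r <- W^2 / (se^2 + W^2)
  0.5 * log(se^2 / (se^2 + W^2)) + 0.5 * z2 * r
}

#' Colocalization priors
#'
#' The standard single-causal-variant colocalization priors: p1 and p2 are
#' the per-variant probabilities of being causal for the GWAS trait and the
#' QTL respectively, p12 of being causal for both. W_gwas and W_qtl are the
#' prior effect standard deviations used in the ABFs (0.15 for quantitative
#' traits; 0.2 is conventional for binary traits on the log-odds scale).
#'
#' @param p1,p2,p12 prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @param W_gwas,W_qtl prior effect standard deviations (default 0.15).
#' @return list of priors.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         W_gwas = 0.15, W_qtl = 0.15) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p1 + p2 + p12 < 0.5)
  list(p1 = p1, p2 = p2, p12 = p12, W_gwas = W_gwas, W_qtl = W_qtl)
}

#' Colocalization posterior probabilities for one locus-feature pair
#'
#' Computes PP0-PP4, the posteriors over the five hypotheses (no
#' association; GWAS only; QTL only; two distinct causal variants; one
#' shared causal variant), from per-variant Wakefield ABFs combined with the
#' priors, using log-sum-exp throughout. Computation is restricted to
#' variants present in both statistics sets.
#'
#' @param gwas_stats,qtl_stats association data.frames (columns
#'   \code{variant}, \code{beta}, \code{se}) for the locus variants.
#' @param priors a \code{\link{coloc_priors}} list.
#' @return one-row data.frame: \code{PP0..PP4}, \code{top_variant} (the
#'   variant maximizing the shared-causal per-variant term), and
#'   \code{n_variants}.
#' @export
coloc_posteriors <- function(gwas_stats, qtl_stats, priors = coloc_priors()) {
  common <- intersect(gwas_stats$variant, qtl_stats$variant)
  if (!length(common))
    stop("no common variants between GWAS and QTL statistics", call. = FALSE)
  g <- gwas_stats[match(common, gwas_stats$variant), ]
  q <- qtl_stats[match(common, qtl_stats$variant), ]
  l1 <- wakefield_log_abf(g$beta, g$se, priors$W_gwas)
  l2 <- wakefield_log_abf(q$beta, q$se, priors$W_qtl)

  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)

  lH0 <- 0
  lH1 <- log(priors$p1) + s1
  lH2 <- log(priors$p2) + s2
  # sum over ordered pairs of distinct variants: sum_i sum_{j != i} = s1*s2 - s12
  lH3 <- log(priors$p1) + log(priors$p2) + logdiffexp(s1 + s2, s12)
  lH4 <- log(priors$p12) + s12

  lh <- c(lH0, lH1, lH2, lH3, lH4)
  pp <- exp(lh - logsumexp(lh))
  data.frame(PP0 = pp[1], PP1 = pp[2], PP2 = pp[3], PP3 = pp[4], PP4 = pp[5],
             top_variant = common[which.max(l1 + l2)],
             n_variants = length(common), stringsAsFactors = FALSE)
}

#' Harmonize two summary-statistic sets to a common variant panel
#'
#' Matches variants by chromosome, position, and allele pair regardless of
#' allele order; flips the sign of the second set's effect when its alleles
#' are swapped relative to the first. Strand-ambiguous variants (A/T, C/G)
#' are dropped by default because their orientation cannot be resolved from
#' summary data.
#'
#' @param a,b association data.frames with \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{beta}.
#' @param keep_ambiguous keep A/T and C/G variants (default FALSE).
#' @return list of the two harmonized data.frames, aligned row-for-row, with
#'   a shared \code{variant} key.
#' @export
harmonize_stats <- function(a, b, keep_ambiguous = FALSE) {
  key <- function(d) {
    al <- t(apply(cbind(d$ref, d$alt), 1, sort))
    paste(d$chrom, d$pos, al[, 1], al[, 2], sep = ":")
  }
  ambiguous <- function(d) {
    (d$ref == "A" & d$alt == "T") | (d$ref == "T" & d$alt == "A") |
      (d$ref == "C" & d$alt == "G") | (d$ref == "G" & d$alt == "C")
  }
  a$.key <- key(a); b$.key <- key(b)
  if (!keep_ambiguous) {
    a <- a[!ambiguous(a), ]
    b <- b[!ambiguous(b), ]
  }
  common <- intersect(a$.key, b$.key)
  a <- a[match(common, a$.key), ]
  b <- b[match(common, b$.key), ]
  flip <- a$ref != b$ref
  b$beta[flip] <- -b$beta[flip]
  tmp <- b$ref[flip]; b$ref[flip] <- b$alt[flip]; b$alt[flip] <- tmp
  a$variant <- b$variant <- a$.key
  a$.key <- b$.key <- NULL
  list(a = a, b = b)
}

#' Per-trait colocalization rates and modality classification
#'
#' A locus is colocalized when any tested feature reaches
#' \code{PP4 > pp4_min}; colocalized loci are classified eQTL-only,
#' sQTL-only, or both according to the modalities reaching the threshold.
#' The rate denominator is the set of non-excluded loci. Traits with 10 or
#' fewer loci are flagged as underpowered rather than dropped.
#'
#' @param loci \code{\link{define_loci}} output.
#' @param results data.frame of per-locus-feature rows with columns
#'   \code{locus_id}, \code{feature}, \code{modality} ("expression" or
#'   "splicing"), \code{PP4}. Duplicated rows are ignored.
#' @param pp4_min colocalization threshold (default 0.75).
#' @return one-row data.frame per trait: \code{trait}, \code{n_loci},
#'   \code{n_coloc}, \code{rate}, \code{n_eqtl_only}, \code{n_sqtl_only},
#'   \code{n_both}, \code{underpowered}.
#' @export
colocalization_rate <- function(loci, results, pp4_min = 0.75) {
  loci_ok <- loci[!loci$excluded, , drop = FALSE]
  results <- unique(results[c("locus_id", "feature", "modality", "PP4")])
  out <- lapply(split(loci_ok, loci_ok$trait), function(L) {
    res <- results[results$locus_id %in% L$locus_id & results$PP4 > pp4_min, ]
    by_locus <- split(res$modality, res$locus_id)
    has_e <- vapply(by_locus, function(m) "expression" %in% m, logical(1))
    has_s <- vapply(by_locus, function(m) "splicing" %in% m, logical(1))
    data.frame(
      trait = L$trait[1], n_loci = nrow(L), n_coloc = length(by_locus),
      rate = if (nrow(L)) length(by_locus) / nrow(L) else NA_real_,
      n_eqtl_only = sum(has_e & !has_s),
      n_sqtl_only = sum(has_s & !has_e),
      n_both = sum(has_e & has_s),
      underpowered = nrow(L) <= 10,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
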