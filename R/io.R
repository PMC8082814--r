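# Readers and writers for the plain-text exchange formats: dosage TSV,
# minimal VCF, phenotype/truth/GWAS TSVs.

#' Write a genotype matrix as a dosage TSV
#'
#' One row per variant: id, chrom, pos, ref, alt, maf, then one dosage
#' column per sample.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param path output file.
#' @export
write_dosage_tsv <- function(G, path) {
  d <- cbind(G$variants,
             as.data.frame(t(G$dosages), check.names = FALSE))
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' Read a dosage TSV written by \code{\link{write_dosage_tsv}}
#' @param path input file.
#' @return a \code{\link{genotype_matrix}}.
#' @export
read_dosage_tsv <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  meta_cols <- c("id", "chrom", "pos", "ref", "alt", "maf")
  variants <- d[meta_cols]
  variants$chrom <- as.character(variants$chrom)
  dos <- t(as.matrix(d[setdiff(names(d), meta_cols)]))
  genotype_matrix(dos, variants, samples = rownames(dos))
}

#' Write a genotype matrix as a minimal VCF
#'
#' VCFv4.2 with either a DS (dosage) or GT (hard-call, dosages rounded)
#' FORMAT field.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param path output file (uncompressed).
#' @param field "DS" or "GT".
#' @export
write_vcf <- function(G, path, field = c("DS", "GT")) {
  field <- match.arg(field)
  v <- G$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    if (field == "DS")
      '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">'
    else
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$samples), collapse = "\t")
  ), con)
  for (j in seq_len(nrow(v))) {
    x <- G$dosages[, j]
    gt <- if (field == "DS") format(x, trim = TRUE) else
      c("0/0", "0/1", "1/1")[pmin(pmax(round(x), 0), 2) + 1]
    gt[is.na(x)] <- if (field == "DS") "." else "./."
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", field, gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write/read association statistics TSV
#'
#' Long-format summary statistics with a fixed header (variant, chrom, pos,
#' ref, alt, beta, se, p, n), the exchange format for GWAS summary data.
#'
#' @param stats association data.frame.
#' @param path file path.
#' @export
write_assoc_tsv <- function(stats, path) {
  data.table::fwrite(stats, path, sep = "\t")
  invisible(path)
}

#' @rdname write_assoc_tsv
#' @export
read_assoc_tsv <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  if ("chrom" %in% names(d)) d$chrom <- as.character(d$chrom)
  d
}

#' Write/read a feature-by-sample matrix TSV
#'
#' @param m numeric matrix with feature rownames.
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- data.frame(feature = rownames(m), as.data.frame(m, check.names = FALSE))
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}
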