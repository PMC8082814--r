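#' Parse LeafCutter-style junction count tables
#'
#' Rows are keyed as \code{chrom:start:end:cluster_id} (coordinates 1-based
#' inclusive), columns are samples.
#'
#' @param x matrix or data.frame of junction counts with LeafCutter-style
#'   rownames (or a first column of ids), or a path to such a table.
#' @return list with \code{introns} (data.frame: intron_id, chrom, start,
#'   end, strand, cluster) and \code{counts} (intron x sample integer
#'   matrix). Strand is taken from a trailing \code{_+}/\code{_-} on the
#'   cluster id when present, otherwise \code{"*"}.
#' @export
read_junction_counts <- function(x) {
  if (is.character(x) && length(x) == 1) {
    dt <- data.table::fread(x, header = TRUE, data.table = FALSE)
    ids <- dt[[1]]
    counts <- as.matrix(dt[, -1, drop = FALSE])
    rownames(counts) <- ids
  } else {
    counts <- as.matrix(x)
    ids <- rownames(counts)
  }
  if (is.null(ids)) stop("junction table must carry row ids", call. = FALSE)
  parts <- strsplit(ids, ":", fixed = TRUE)
  if (any(lengths(parts) != 4))
    stop("junction ids must be chrom:start:end:cluster", call. = FALSE)
  m <- do.call(rbind, parts)
  clu <- m[, 4]
  strand <- ifelse(grepl("_[+-]$", clu), substring(clu, nchar(clu)), "*")
  introns <- data.frame(
    intron_id = ids, chrom = m[, 1],
    start = as.integer(m[, 2]), end = as.integer(m[, 3]),
    strand = strand, cluster = clu, stringsAsFactors = FALSE
  )
  if (any(counts < 0)) stop("junction counts must be non-negative", call. = FALSE)
  list(introns = introns, counts = counts)
}

#' Merge intron clusters across datasets and recompute usage
#'
#' Clusters from different datasets whose introns share a splice-site
#' coordinate (same chromosome and donor or acceptor position, on a
#' compatible strand) are unioned via connected components, and intron usage
#' is recomputed in every sample as the intron's count divided by the merged
#' cluster's total. This harmonizes splicing quantification across datasets
#' that clustered junctions independently.
#'
#' @param cluster_sets list of objects as returned by
#'   \code{\link{read_junction_counts}}, one per dataset. Sample columns are
#'   concatenated; an intron absent from a dataset contributes zero counts
#'   for that dataset's samples. Introns asserting conflicting strands for a
#'   shared splice site are rejected with a message.
#' @return list with \code{introns} (data.frame including the merged
#'   \code{cluster} assignment), \code{counts} (union intron x all-sample
#'   matrix) and \code{usage} (same shape; within-cluster fractions, NA where
#'   the cluster total for a sample is zero).
#' @export
merge_intron_clusters <- function(cluster_sets) {
  stopifnot(length(cluster_sets) >= 1)

  # union of introns keyed by coordinates+strand; accumulate counts
  all_samples <- unlist(lapply(cluster_sets, function(s) colnames(s$counts)))
  if (anyDuplicated(all_samples))
    all_samples <- make.unique(all_samples)
  key_of <- function(df) paste(df$chrom, df$start, df$end, sep = ":")
  rejected <- character(0)

  introns <- NULL
  for (s in cluster_sets) {
    df <- s$introns
    df$key <- key_of(df)
    if (is.null(introns)) {
      introns <- df[!duplicated(df$key), c("key", "chrom", "start", "end", "strand")]
    } else {
      new <- df[!df$key %in% introns$key & !duplicated(df$key), ]
      # strand conflicts for already-known introns
      known <- merge(df[c("key", "strand")], introns[c("key", "strand")], by = "key")
      bad <- known$key[known$strand.x != known$strand.y &
                         known$strand.x != "*" & known$strand.y != "*"]
      if (length(bad)) {
        rejected <- c(rejected, unique(bad))
        message("rejected ", length(unique(bad)),
                " intron record(s) with conflicting strand")
      }
      if (nrow(new))
        introns <- rbind(introns, new[c("key", "chrom", "start", "end", "strand")])
    }
  }
  introns <- introns[order(introns$chrom, introns$start, introns$end), ]
  ni <- nrow(introns)

  counts <- matrix(0, ni, length(all_samples),
                   dimnames = list(introns$key, all_samples))
  col0 <- 0L
  for (s in cluster_sets) {
    sk <- key_of(s$introns)
    ok <- !sk %in% rejected
    idx <- match(sk[ok], introns$key)
    cols <- col0 + seq_len(ncol(s$counts))
    cnt <- s$counts[ok, , drop = FALSE]
    # same intron listed twice within a dataset: counts accumulate
    for (r in seq_along(idx)) if (!is.na(idx[r]))
      counts[idx[r], cols] <- counts[idx[r], cols] + cnt[r, ]
    col0 <- col0 + ncol(s$counts)
  }

  # connected components over shared splice-site coordinates (donor or
  # acceptor), per chromosome/compatible strand; classic union-find
  parent <- seq_len(ni)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  site_key <- c(paste(introns$chrom, introns$start, sep = "@"),
                paste(introns$chrom, introns$end, sep = "@"))
  site_intron <- rep(seq_len(ni), 2)
  for (grp in split(site_intron, site_key)) {
    if (length(grp) > 1) for (i in grp[-1]) unite(grp[1], i)
  }
  roots <- vapply(seq_len(ni), find, integer(1))
  introns$cluster <- paste0("clu_", match(roots, unique(roots)))

  usage <- counts
  for (cl in split(seq_len(ni), introns$cluster)) {
    tot <- colSums(counts[cl, , drop = FALSE])
    u <- sweep(counts[cl, , drop = FALSE], 2, tot, `/`)
    u[, tot == 0] <- NA_real_
    usage[cl, ] <- u
  }

  introns$intron_id <- sprintf("%s:%s", introns$key, introns$cluster)
  rownames(counts) <- rownames(usage) <- introns$intron_id
  rownames(introns) <- NULL
  list(introns = introns[c("intron_id", "chrom", "start", "end", "strand", "cluster")],
       counts = counts, usage = usage)
}

#' Export intron coordinates as BED
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open, so \code{start} is decremented by one.
#'
#' @param introns data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{intron_id}, \code{strand}.
#' @param path output file.
#' @export
write_intron_bed <- function(introns, path) {
  bed <- data.frame(introns$chrom, introns$start - 1L, introns$end,
                    introns$intron_id, 0L, introns$strand)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
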