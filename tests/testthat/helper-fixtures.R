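# Shared fixtures and independent oracles used across test files.

# Tiny genotype_matrix from an explicit dosage matrix.
toy_genotypes <- function(dosages, chrom = "1", spacing = 10000L) {
  nv <- ncol(dosages)
  pos <- 100000L + spacing * (seq_len(nv) - 1L)
  maf <- pmin(pmax(colMeans(dosages, na.rm = TRUE) / 2, 1e-6), 1 - 1e-6)
  maf <- pmin(maf, 1 - maf)
  variants <- data.frame(
    id = sprintf("%s:%d:A:G", chrom, pos), chrom = chrom, pos = pos,
    ref = "A", alt = "G", maf = pmax(maf, 1e-6), stringsAsFactors = FALSE
  )
  genotype_matrix(dosages, variants)
}

# Independent colocalization oracle: exhaustive enumeration over all pairs of
# causal-variant configurations (including "none"), combining per-variant ABFs
# with the priors directly. Only feasible for small variant counts.
coloc_enumeration_oracle <- function(labf1, labf2, p1, p2, p12) {
  V <- length(labf1)
  abf1 <- exp(labf1); abf2 <- exp(labf2)
  h <- c(H0 = 1, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
  for (i in seq_len(V)) h["H1"] <- h["H1"] + p1 * abf1[i]
  for (j in seq_len(V)) h["H2"] <- h["H2"] + p2 * abf2[j]
  for (i in seq_len(V)) for (j in seq_len(V)) {
    if (i == j) h["H4"] <- h["H4"] + p12 * abf1[i] * abf2[i]
    else h["H3"] <- h["H3"] + p1 * p2 * abf1[i] * abf2[j]
  }
  h / sum(h)
}

# Independent greedy clumping oracle: literal sort-and-mask re-implementation.
clump_oracle <- function(chrom, pos, p, p_threshold, half_window) {
  ord <- order(p, chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]; p <- p[ord]
  taken <- rep(FALSE, length(p))
  leads <- integer(0)
  repeat {
    i <- which(!taken)[1]
    if (is.na(i) || p[i] >= p_threshold) break
    leads <- c(leads, i)
    taken[!taken & chrom == chrom[i] & abs(pos - pos[i]) <= half_window] <- TRUE
  }
  data.frame(chrom = chrom[leads], pos = pos[leads], p = p[leads])
}

# Independent two-sided Fisher p by hypergeometric enumeration
# (sum-of-smaller-probabilities convention) for a 2x2 table.
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  pr <- dhyper(xs, m, n, k)
  obs <- dhyper(a, m, n, k)
  p <- sum(pr[pr <= obs * (1 + 1e-7)])
  list(p = min(1, p), or = (a * d) / (b * c))
}

# Independent connected-component oracle over shared splice sites: repeated
# breadth-first search on an adjacency list (no union-find).
cluster_bfs_oracle <- function(introns) {
  ni <- nrow(introns)
  sites <- rbind(data.frame(i = seq_len(ni),
                            s = paste(introns$chrom, introns$start)),
                 data.frame(i = seq_len(ni),
                            s = paste(introns$chrom, introns$end)))
  adj <- lapply(seq_len(ni), function(i) integer(0))
  for (grp in split(sites$i, sites$s)) {
    grp <- unique(grp)
    if (length(grp) > 1)
      for (i in grp) adj[[i]] <- union(adj[[i]], setdiff(grp, i))
  }
  comp <- rep(NA_integer_, ni)
  cid <- 0L
  for (i in seq_len(ni)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  comp
}
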