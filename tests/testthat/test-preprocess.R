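# Variant QC, expression normalization, and intron-cluster harmonization.

test_that("variant filters apply the study defaults and remove failing variants", {
  expect_identical(formals(filter_variants)$maf_min, 0.05)
  expect_identical(formals(filter_variants)$hwe_p_min, 1e-5)
  expect_identical(formals(filter_variants)$miss_max, 0.05)

  # column 1: monomorphic; column 2: HWE-violating (no hets); column 3: fine;
  # column 4: too much missingness
  n <- 100
  d <- cbind(rep(0, n),
             c(rep(0, 50), rep(2, 50)),
             rbinom(n, 2, 0.3),
             c(rep(NA, 10), rbinom(n - 10, 2, 0.3)))
  set.seed(1)
  d[, 3] <- rbinom(n, 2, 0.3)
  G <- toy_genotypes(d)
  Gf <- filter_variants(G)
  expect_identical(Gf$variants$id, G$variants$id[3])
})

test_that("exact HWE test matches enumeration and flags extreme heterozygote deficits", {
  # oracle by direct enumeration: AA=50, Aa=0, aa=50 leaves essentially no
  # probability on zero heterozygotes given 100/100 alleles
  p <- hwe_exact_p(50, 0, 50)
  expect_lt(p, 1e-5)
  # balanced HWE-consistent counts are not significant
  expect_gt(hwe_exact_p(25, 50, 25), 0.5)
  # cross-check a moderate table against an independent enumeration
  enum_p <- function(naa, nab, nbb) {
    nA <- 2 * naa + nab; nB <- 2 * nbb + nab; N <- naa + nab + nbb
    rare <- min(nA, nB)
    hets <- seq(rare %% 2, rare, 2)
    pr <- vapply(hets, function(h) {
      hr <- (rare - h) / 2
      exp(lgamma(N + 1) - lgamma(hr + 1) - lgamma(h + 1) -
            lgamma(N - h - hr + 1) + h * log(2) -
            (lgamma(2 * N + 1) - lgamma(nA + 1) - lgamma(nB + 1)))
    }, numeric(1))
    sum(pr[pr <= pr[match(nab, hets)] + 1e-12])
  }
  for (tab in list(c(5, 10, 5), c(30, 10, 10), c(88, 10, 2))) {
    expect_equal(hwe_exact_p(tab[1], tab[2], tab[3]),
                 enum_p(tab[1], tab[2], tab[3]), tolerance = 1e-10)
  }
})

test_that("filter_variants is idempotent", {
  G <- simulate_genotypes(200, 50, ld_rho = 0.5, maf_range = c(0.02, 0.5),
                          seed = 21)
  G1 <- filter_variants(G)
  G2 <- filter_variants(G1)
  expect_identical(G1$variants$id, G2$variants$id)
  expect_equal(G1$dosages, G2$dosages)
})

test_that("filtering everything warns instead of erroring", {
  d <- matrix(0, 50, 3)
  G <- toy_genotypes(d)
  expect_warning(Gf <- filter_variants(G), "no variants")
  expect_equal(ncol(Gf$dosages), 0L)
})

test_that("inverse-normal transform reproduces the offset-rank quantiles and is monotone", {
  out <- normalize_expression(matrix(c(1, 2, 3, 4, 5), 1), library_scale = FALSE)
  expect_equal(drop(out), qnorm((1:5 - 0.5) / 5), tolerance = 1e-12)
  expect_equal(drop(out), c(-1.2816, -0.5244, 0, 0.5244, 1.2816),
               tolerance = 1e-4)

  set.seed(2)
  x <- matrix(rexp(200), 4, 50)
  out <- normalize_expression(x, library_scale = FALSE)
  for (i in 1:4)  # monotone: rank correlation is exactly 1
    expect_equal(cor(x[i, ], out[i, ], method = "spearman"), 1,
                 tolerance = 1e-12)
  expect_equal(rowMeans(out), rep(0, 4), tolerance = 1e-8)
})

test_that("normalized features pass a normality check at n >= 50", {
  set.seed(3)
  x <- matrix(rlnorm(100 * 60, 2, 1.5), 100, 60)
  out <- normalize_expression(x)
  sw <- apply(out, 1, function(r) shapiro.test(r)$p.value)
  expect_gt(mean(sw > 0.01), 0.95)
})

test_that("identical sample profiles produce identical output columns; constant features warn", {
  x <- cbind(c(1, 5, 2), c(4, 1, 9), c(1, 5, 2), c(2, 8, 3))  # cols 1 == 3
  out <- normalize_expression(x, library_scale = FALSE)
  expect_identical(out[, 1], out[, 3])
  expect_warning(outc <- normalize_expression(rbind(c(2, 2, 2)),
                                              library_scale = FALSE),
                 "constant")
  expect_equal(drop(outc), rep(0, 3))
})

# ---- intron clusters -------------------------------------------------------

make_cluster_set <- function(ids, counts) {
  rownames(counts) <- ids
  read_junction_counts(counts)
}

test_that("junction id parsing round-trips coordinates and clusters", {
  cnt <- matrix(1:6, 3, 2, dimnames = list(
    c("chr1:100:200:clu_1", "chr1:100:300:clu_1", "chr2:50:80:clu_2"),
    c("s1", "s2")))
  cs <- read_junction_counts(cnt)
  expect_equal(cs$introns$start, c(100L, 100L, 50L))
  expect_equal(cs$introns$cluster, c("clu_1", "clu_1", "clu_2"))
  expect_error(read_junction_counts(matrix(1, 1, 1,
                                           dimnames = list("bad_id", "s"))),
               "chrom:start:end:cluster")
})

test_that("clusters sharing a splice site merge; disjoint clusters stay separate", {
  # A:(100,200) and B:(100,300) share donor 100; C:(300,400) shares acceptor
  # 300 with B, so all three merge; D:(900,950) stays alone
  s1 <- make_cluster_set(c("chr1:100:200:clu_1", "chr1:100:300:clu_1"),
                         matrix(c(4, 6, 2, 8), 2, 2,
                                dimnames = list(NULL, c("a1", "a2"))))
  s2 <- make_cluster_set(c("chr1:300:400:clu_9", "chr1:900:950:clu_7"),
                         matrix(c(5, 5, 3, 7), 2, 2,
                                dimnames = list(NULL, c("b1", "b2"))))
  m <- merge_intron_clusters(list(s1, s2))
  cl <- m$introns$cluster
  names(cl) <- paste(m$introns$start, m$introns$end)
  expect_equal(length(unique(cl[c("100 200", "100 300", "300 400")])), 1L)
  expect_false(cl["900 950"] %in% cl[c("100 200")])

  # variant: when C is (100,400) instead and no site is shared with (300,400)
  s2b <- make_cluster_set("chr1:320:400:clu_9",
                          matrix(c(5, 3), 1, 2,
                                 dimnames = list(NULL, c("b1", "b2"))))
  m2 <- merge_intron_clusters(list(s1, s2b))
  cl2 <- m2$introns$cluster
  names(cl2) <- paste(m2$introns$start, m2$introns$end)
  expect_false(cl2["320 400"] == cl2["100 200"])
})

test_that("merged clustering matches the BFS connected-component oracle on random sets", {
  set.seed(4)
  for (rep in 1:20) {
    ni <- sample(5:25, 1)
    sites <- sample(seq(100, 800, 50), 12)
    introns <- data.frame(
      chrom = sample(c("chr1", "chr2"), ni, TRUE),
      start = sample(sites, ni, TRUE)
    )
    introns$end <- introns$start + sample(seq(50, 400, 50), ni, TRUE)
    introns <- unique(introns)
    ids <- sprintf("%s:%d:%d:clu_%d", introns$chrom, introns$start,
                   introns$end, seq_len(nrow(introns)))
    cnt <- matrix(rpois(nrow(introns) * 3, 10), nrow(introns), 3,
                  dimnames = list(ids, paste0("s", 1:3)))
    m <- merge_intron_clusters(list(read_junction_counts(cnt)))
    oracle <- cluster_bfs_oracle(m$introns)
    # same partition: cluster labels are a bijection of oracle components
    expect_equal(length(unique(m$introns$cluster)), length(unique(oracle)))
    expect_true(all(table(m$introns$cluster, oracle) %in%
                      c(0, table(oracle))))
  }
})

test_that("recomputed usages sum to one within merged clusters and merging is order-invariant", {
  set.seed(5)
  s1 <- make_cluster_set(c("chr1:100:200:clu_1", "chr1:100:300:clu_1"),
                         matrix(rpois(4, 20), 2, 2,
                                dimnames = list(NULL, c("a1", "a2"))))
  s2 <- make_cluster_set(c("chr1:200:500:clu_3", "chr1:600:700:clu_4"),
                         matrix(rpois(4, 20), 2, 2,
                                dimnames = list(NULL, c("b1", "b2"))))
  m12 <- merge_intron_clusters(list(s1, s2))
  m21 <- merge_intron_clusters(list(s2, s1))
  # order-invariant partitioning and usage values (up to row/col order)
  key <- function(m) {
    u <- m$usage[order(rownames(m$usage)), order(colnames(m$usage))]
    cl <- m$introns$cluster[order(m$introns$intron_id)]
    list(u = u, sizes = sort(as.integer(table(cl))))
  }
  expect_equal(key(m12)$u, key(m21)$u)
  expect_equal(key(m12)$sizes, key(m21)$sizes)
  for (cl in split(seq_len(nrow(m12$usage)), m12$introns$cluster)) {
    tot <- colSums(m12$counts[cl, , drop = FALSE])
    s <- colSums(m12$usage[cl, , drop = FALSE])
    expect_equal(unname(s[tot > 0]), rep(1, sum(tot > 0)), tolerance = 1e-12)
  }
})

test_that("single dataset with no shared sites across clusters is unchanged", {
  s1 <- make_cluster_set(c("chr1:100:200:clu_1", "chr1:400:500:clu_2"),
                         matrix(c(3, 9, 6, 2), 2, 2,
                                dimnames = list(NULL, c("a1", "a2"))))
  m <- merge_intron_clusters(list(s1))
  expect_equal(length(unique(m$introns$cluster)), 2L)
})

test_that("BED export shifts starts to 0-based half-open", {
  introns <- data.frame(chrom = "chr1", start = 101L, end = 200L,
                        intron_id = "x", strand = "+")
  f <- tempfile(fileext = ".bed")
  write_intron_bed(introns, f)
  bed <- read.table(f, sep = "\t")
  expect_equal(bed$V2, 100L)
  expect_equal(bed$V3, 200L)
  unlink(f)
})
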