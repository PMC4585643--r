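test_that("venn_counts partitions a three-set example correctly", {
  counts <- venn_counts(list(A = c("a", "b", "c"), B = c("b", "c", "d"),
                             C = c("c", "d", "e")))
  expect_equal(counts[["A"]], 1L)        # a
  expect_equal(counts[["B"]], 0L)
  expect_equal(counts[["C"]], 1L)        # e
  expect_equal(counts[["A&B"]], 1L)      # b
  expect_equal(counts[["B&C"]], 1L)      # d
  expect_equal(counts[["A&C"]], 0L)
  expect_equal(counts[["A&B&C"]], 1L)    # c
  expect_equal(sum(counts), 5L)          # |union|
  expect_equal(concordance_rate(counts), 20)
})

test_that("identical and disjoint sets are degenerate partitions", {
  s <- c("x", "y", "z")
  ident <- venn_counts(list(P = s, Q = s))
  expect_equal(ident[["P&Q"]], 3L)
  expect_equal(sum(ident), 3L)
  expect_equal(concordance_rate(ident), 100)
  disj <- venn_counts(list(P = c("x"), Q = c("y", "z")))
  expect_equal(disj[["P"]], 1L)
  expect_equal(disj[["Q"]], 2L)
  expect_equal(disj[["P&Q"]], 0L)
  expect_equal(concordance_rate(disj), 0)
  expect_error(venn_counts(list(A = "x")), "2 to 5")
  expect_true(is.na(concordance_rate(venn_counts(
    list(A = character(), B = character())))))
})

test_that("region counts sum to the union size and permute with set order", {
  set.seed(60)
  for (i in 1:20) {
    k <- sample(2:5, 1L)
    sets <- lapply(seq_len(k), function(j)
      as.character(sample.int(30, sample.int(20, 1L))))
    names(sets) <- LETTERS[seq_len(k)]
    counts <- venn_counts(sets)
    expect_equal(sum(counts), length(unique(unlist(sets))))
    perm <- sample(k)
    counts_p <- venn_counts(sets[perm])
    relabel <- function(lbl) paste(sort(strsplit(lbl, "&")[[1L]]),
                                   collapse = "&")
    a <- setNames(as.integer(counts), vapply(names(counts), relabel, ""))
    b <- setNames(as.integer(counts_p), vapply(names(counts_p), relabel, ""))
    expect_equal(a[sort(names(a))], b[sort(names(b))])
  }
})

test_that("non-SNV intervals cluster by the +/-10 bp overlap rule", {
  i1 <- data.frame(chrom = "chr1", start = 90, end = 110, source = "s1")
  i2 <- data.frame(chrom = "chr1", start = 105, end = 125, source = "s2")
  cl <- nonsnv_clusters(rbind(i1, i2), set_names = c("s1", "s2"))
  expect_equal(cl$counts[["s1&s2"]], 1L)
  expect_equal(sum(cl$counts), 1L)
  # pos 100 vs 130: gap > 20 bp, two singleton clusters
  i3 <- data.frame(chrom = "chr1", start = 120, end = 140, source = "s2")
  cl2 <- nonsnv_clusters(rbind(i1, i3), set_names = c("s1", "s2"))
  expect_equal(cl2$counts[["s1"]], 1L)
  expect_equal(cl2$counts[["s2"]], 1L)
  expect_equal(cl2$counts[["s1&s2"]], 0L)
  # same-position indels from 3 sources: one cluster in the full region
  iv <- do.call(rbind, lapply(c("a", "b", "c"), function(s)
    data.frame(chrom = "chr1", start = 90, end = 110, source = s)))
  cl3 <- nonsnv_clusters(iv, set_names = c("a", "b", "c"))
  expect_equal(cl3$counts[["a&b&c"]], 1L)
  expect_equal(sum(cl3$counts), 1L)
})

test_that("interval records build +/-10bp point intervals from non-SNVs only", {
  recs <- list(rec("chr1", 100, "AT", "A"),
               rec("chr1", 200, "C", "G"),        # SNV, skipped
               rec("chr2", 50, "G", "GAA"))
  iv <- nonsnv_intervals(recs, source = "s1")
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$start, c(90L, 40L))
  expect_equal(iv$end, c(110L, 60L))
  expect_equal(snv_keys(recs), "chr1:200:C:G")
})

test_that("sweep clustering matches the brute-force connected-components oracle", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(5:60, 1L)
    iv <- data.frame(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample.int(500, n, replace = TRUE),
      source = sample(c("s1", "s2", "s3"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    iv$end <- iv$start + 20L
    got <- nonsnv_clusters(iv, set_names = c("s1", "s2", "s3"))
    comp <- cluster_oracle(iv)
    # same partition of rows into clusters
    expect_equal(length(unique(got$clusters$cluster)),
                 length(unique(comp)))
    expect_true(all(tapply(got$clusters$cluster, comp, function(x)
      length(unique(x))) == 1L))
    # same venn counts from the oracle partition
    oracle_regions <- tapply(iv$source, comp, function(s)
      paste(c("s1", "s2", "s3")[sort(match(unique(s),
                                           c("s1", "s2", "s3")))],
            collapse = "&"))
    tab <- table(unlist(oracle_regions))
    for (lbl in names(got$counts)) {
      want <- if (lbl %in% names(tab)) as.integer(tab[[lbl]]) else 0L
      expect_equal(got$counts[[lbl]], want)
    }
  }
})

test_that("multiallelic SNVs contribute one key per alternate allele", {
  r <- rec("chr1", 10, "A", "G")
  r$alts <- c("G", "T")
  expect_equal(snv_keys(list(r)), c("chr1:10:A:G", "chr1:10:A:T"))
})

test_that("venn_vcfs ties normalization, classification and counting together", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 62, n_variants = 150, chrom_length = 40000,
                    snv_fraction = 0.6)
  g <- simulate_reference(cfg, dir)
  cs <- simulate_callsets(cfg, g, dir)
  res <- venn_vcfs(as.list(cs$caller_paths), g)
  truth_snv <- vapply(cs$truth$records, is_snv, logical(1L))
  labels <- colnames(cs$membership)
  # SNV region counts implied by the membership log + private FPs
  want <- membership_region_counts(
    cs$membership[truth_snv, , drop = FALSE],
    lapply(cs$fp_keys, function(k) k[startsWith(k, "S:")]))
  for (lbl in names(res$snv_counts)) {
    w <- if (lbl %in% names(want)) as.integer(want[[lbl]]) else 0L
    expect_equal(res$snv_counts[[lbl]], w, info = lbl)
  }
  # non-SNV cluster counts likewise (spaced loci: no cross-variant clusters)
  want_n <- membership_region_counts(
    cs$membership[!truth_snv, , drop = FALSE],
    lapply(cs$fp_keys, function(k) k[startsWith(k, "I:")]))
  for (lbl in names(res$nonsnv_counts)) {
    w <- if (lbl %in% names(want_n)) as.integer(want_n[[lbl]]) else 0L
    expect_equal(res$nonsnv_counts[[lbl]], w, info = lbl)
  }
  expect_equal(sum(res$snv_counts) + sum(res$nonsnv_counts),
               sum(apply(cs$membership, 1, any)) +
                 sum(lengths(cs$fp_keys)))
})
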