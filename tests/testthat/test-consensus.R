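test_that("caller priority ordering is fixed for known callers, stable for unknown", {
  expect_equal(caller_priority(c("varscan", "gatk", "samtools")),
               c("gatk", "samtools", "varscan"))
  expect_equal(caller_priority("freebayes"), "freebayes")
  expect_equal(caller_priority(c("customcallerB", "customcallerA")),
               c("customcallerB", "customcallerA"))
  expect_equal(caller_priority(c("SOAPsnp", "GATK-HC", "FreeBayes")),
               c("GATK-HC", "FreeBayes", "SOAPsnp"))
})

test_that("merge_records pools alts, keeps first qual/genotypes, applies the PASS rule", {
  r1 <- rec("chr1", 100, "A", "G", qual = 50, filters = "LowQual",
            gts = list(S = c(0L, 1L)), source = "file1")
  r2 <- rec("chr1", 100, "A", "T", qual = 30, filters = "PASS",
            gts = list(S = c(1L, 1L)), source = "file2")
  m <- merge_records(list(r1, r2))
  expect_equal(m$alts, c("G", "T"))
  expect_equal(m$qual, 50)
  expect_equal(m$filters, "PASS")
  expect_setequal(attr(m, "supporters"), c("file1", "file2"))
  expect_equal(m$genotypes$S$alleles, c(0L, 1L))
  # all filtered -> union of filter names
  r2b <- rec("chr1", 100, "A", "T", filters = "q10", source = "file2")
  m2 <- merge_records(list(rec("chr1", 100, "A", "G", filters = "LowQual",
                               source = "file1"), r2b))
  expect_setequal(m2$filters, c("LowQual", "q10"))
  # identical records: idempotent pooling
  m3 <- merge_records(list(r1, rec("chr1", 100, "A", "G", qual = 50,
                                   filters = "LowQual",
                                   gts = list(S = c(0L, 1L)),
                                   source = "file2")))
  expect_equal(m3$alts, "G")
  expect_length(attr(m3, "supporters"), 2L)
  # singleton is the identity
  m4 <- merge_records(list(r1))
  expect_equal(m4$alts, r1$alts)
  expect_equal(attr(m4, "supporters"), "file1")
  # mixed keys rejected
  expect_error(merge_records(list(r1, rec("chr1", 101, "A", "T"))),
               "merge key")
})

test_that("genotype indices are remapped onto the pooled alt list", {
  r1 <- rec("chr1", 50, "AT", "A", gts = list(S = c(0L, 1L)),
            source = "samtools")
  r2 <- rec("chr1", 50, "AT", "ATT", gts = list(S = c(1L, 1L)),
            source = "gatk")
  # priority puts gatk first: its alt comes first in the pool
  m <- merge_records(list(r2, r1))
  expect_equal(m$alts, c("ATT", "A"))
  expect_equal(m$genotypes$S$alleles, c(1L, 1L))
  # swap priority: samtools record first, its alt index stays valid
  m2 <- merge_records(list(r1, r2))
  expect_equal(m2$alts, c("A", "ATT"))
  expect_equal(m2$genotypes$S$alleles, c(0L, 1L))
})

make_two_caller_fixture <- function(seqs, dir) {
  g <- make_test_genome(seqs, dir)
  base1 <- substr(seqs$chr1, 100, 100)
  alt1 <- setdiff(c("A", "C", "G", "T"), base1)[1L]
  g1 <- list(S = c(0L, 1L))
  recs1 <- list(rec("chr1", 100, base1, alt1, gts = g1),
                rec("chr1", 300, substr(seqs$chr1, 300, 303),
                    substr(seqs$chr1, 300, 300), gts = g1),
                rec("chr1", 500, substr(seqs$chr1, 500, 500),
                    paste0(substr(seqs$chr1, 500, 500), "TT"), gts = g1))
  recs2 <- list(rec("chr1", 200, substr(seqs$chr1, 200, 200),
                    setdiff(c("A", "C", "G", "T"),
                            substr(seqs$chr1, 200, 200))[1L], gts = g1),
                rec("chr1", 400, substr(seqs$chr1, 400, 400),
                    setdiff(c("A", "C", "G", "T"),
                            substr(seqs$chr1, 400, 400))[1L], gts = g1))
  p1 <- file.path(dir, "a.vcf"); p2 <- file.path(dir, "b.vcf")
  write_vcf(new_vcf(samples = "S", records = recs1), p1)
  write_vcf(new_vcf(samples = "S", records = recs2), p2)
  list(genome = g, paths = c(gatk = p1, samtools = p2))
}

test_that("merging disjoint call sets yields the union with singleton support", {
  dir <- withr::local_tempdir()
  fx <- make_two_caller_fixture(random_seqs(1, 2000, seed = 41), dir)
  m <- merge_vcfs(fx$paths, fx$genome)
  expect_length(m$records, 5L)
  expect_true(all(vapply(m$records, function(r)
    length(record_supporters(r)), integer(1L)) == 1L))
  expect_true(all(vapply(m$records, function(r)
    r$info[["NCALLERS"]] == "1", logical(1L))))
})

test_that("the same deletion in two representations merges into one record", {
  seqs <- list(chr1 = paste0(strrep("A", 99), "TGGGC", strrep("T", 100)))
  dir <- withr::local_tempdir()
  g <- make_test_genome(seqs, dir)
  p1 <- file.path(dir, "c1.vcf"); p2 <- file.path(dir, "c2.vcf")
  write_vcf(new_vcf(samples = "S", records = list(
    rec("chr1", 100, "TGGG", "TGG", gts = list(S = c(0L, 1L))))), p1)
  write_vcf(new_vcf(samples = "S", records = list(
    rec("chr1", 100, "TG", "T", gts = list(S = c(0L, 1L))))), p2)
  m <- merge_vcfs(c(x = p1, y = p2), g)
  expect_length(m$records, 1L)
  expect_setequal(record_supporters(m$records[[1L]]), c("x", "y"))
})

test_that("an SNV and a deletion at the same position stay distinct records", {
  seqs <- random_seqs(1, 1000, seed = 43)
  dir <- withr::local_tempdir()
  g <- make_test_genome(seqs, dir)
  base <- substr(seqs$chr1, 500, 500)
  alt <- setdiff(c("A", "C", "G", "T"), base)[1L]
  p1 <- file.path(dir, "c1.vcf"); p2 <- file.path(dir, "c2.vcf")
  write_vcf(new_vcf(samples = "S", records = list(
    rec("chr1", 500, base, alt, gts = list(S = c(0L, 1L))))), p1)
  del_rec <- rec("chr1", 500, substr(seqs$chr1, 500, 502), base,
                 gts = list(S = c(0L, 1L)))
  write_vcf(new_vcf(samples = "S", records = list(del_rec)), p2)
  m <- merge_vcfs(c(x = p1, y = p2), g)
  expect_length(m$records, 2L)
})

test_that("consensus extraction filters by support and is monotone", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 44, n_variants = 100, chrom_length = 30000)
  g <- simulate_reference(cfg, dir)
  cs <- simulate_callsets(cfg, g, dir)
  m <- merge_vcfs(as.list(cs$caller_paths), g)
  prev <- NULL
  for (mm in 4:1) {
    cons <- extract_consensus(m, mm)
    keys <- vapply(cons$records, merge_key, character(1L))
    supp <- vapply(cons$records, function(r)
      length(record_supporters(r)), integer(1L))
    expect_true(all(supp >= mm))
    if (!is.null(prev)) expect_true(all(prev %in% keys))  # nesting
    prev <- keys
  }
  expect_equal(length(extract_consensus(m, 1)$records), length(m$records))
  expect_error(extract_consensus(m, 5), "exceeds")
  expect_error(extract_consensus(m, 0), "positive")
})

test_that("input order does not change the merged output under fixed priority", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 45, n_variants = 60, chrom_length = 20000)
  g <- simulate_reference(cfg, dir)
  cs <- simulate_callsets(cfg, g, dir)
  m1 <- merge_vcfs(as.list(cs$caller_paths), g)
  m2 <- merge_vcfs(as.list(rev(cs$caller_paths)), g)
  key1 <- vapply(m1$records, merge_key, character(1L))
  key2 <- vapply(m2$records, merge_key, character(1L))
  expect_equal(key1, key2)
  expect_equal(vapply(m1$records, `[[`, numeric(1L), "qual"),
               vapply(m2$records, `[[`, numeric(1L), "qual"))
  expect_equal(lapply(m1$records, function(r) sort(record_supporters(r))),
               lapply(m2$records, function(r) sort(record_supporters(r))))
})

test_that("multi-sample inputs are rejected by merge_vcfs and sample clashes flagged", {
  dir <- withr::local_tempdir()
  g <- make_test_genome(random_seqs(1, 1000, seed = 46), dir)
  ref <- fetch_reference(g, "chr1", 100, 100)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
  multi <- new_vcf(samples = c("S1", "S2"), records = list(
    rec("chr1", 100, ref, alt, gts = list(S1 = c(0L, 1L),
                                          S2 = c(0L, 0L)))))
  pm <- file.path(dir, "multi.vcf")
  write_vcf(multi, pm)
  expect_error(merge_vcfs(c(a = pm, b = pm), g), "split")
  s1 <- new_vcf(samples = "S1", records = list(
    rec("chr1", 100, ref, alt, gts = list(S1 = c(0L, 1L)))))
  s2 <- new_vcf(samples = "S2", records = list(
    rec("chr1", 100, ref, alt, gts = list(S2 = c(0L, 1L)))))
  expect_error(merge_vcfs(list(a = s1, b = s2), g), "disagreement")
  expect_silent(merge_vcfs(list(a = s1, b = s2), g, check_sample = FALSE))
})

test_that("split_and_recombine merges per sample and unions loci", {
  dir <- withr::local_tempdir()
  seqs <- random_seqs(1, 2000, seed = 47)
  g <- make_test_genome(seqs, dir)
  base <- function(p) substr(seqs$chr1, p, p)
  altof <- function(p) setdiff(c("A", "C", "G", "T"), base(p))[1L]
  # caller 1: locus 100 called in all three; locus 200 only in child
  v1 <- trio_vcf(list(
    trio_rec("chr1", 100, base(100), altof(100), c(0L, 1L), c(0L, 0L),
             c(0L, 1L)),
    trio_rec("chr1", 200, base(200), altof(200), NULL, NULL, c(1L, 1L))))
  # caller 2: locus 100 in parents only
  v2 <- trio_vcf(list(
    trio_rec("chr1", 100, base(100), altof(100), c(0L, 1L), c(0L, 1L),
             NULL)))
  m <- split_and_recombine(list(cal1 = v1, cal2 = v2), g)
  expect_length(m$records, 2L)
  keys <- vapply(m$records, function(r) r$pos, integer(1L))
  r100 <- m$records[[which(keys == 100L)]]
  r200 <- m$records[[which(keys == 200L)]]
  expect_setequal(record_supporters(r100), c("cal1", "cal2"))
  expect_equal(record_supporters(r200), "cal1")
  expect_true(gt_is_missing(r200$genotypes$FATHER))
  expect_true(gt_is_missing(r200$genotypes$MOTHER))
  expect_equal(r200$genotypes$CHILD$alleles, c(1L, 1L))
  # single sample, single caller: identity modulo provenance
  single <- new_vcf(samples = "S", records = list(
    rec("chr1", 100, base(100), altof(100), gts = list(S = c(0L, 1L)))))
  m1 <- split_and_recombine(list(only = single), g)
  expect_length(m1$records, 1L)
  expect_equal(record_supporters(m1$records[[1L]]), "only")
  # inconsistent sample sets are an error
  other <- new_vcf(samples = "OTHER", records = list(
    rec("chr1", 100, base(100), altof(100), gts = list(OTHER = c(0L, 1L)))))
  expect_error(split_and_recombine(list(a = v1, b = other), g), "absent|shared")
})
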