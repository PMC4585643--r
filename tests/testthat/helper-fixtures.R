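# Shared fixtures: tiny genomes and VCFs built in code.

write_test_fasta <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fasta <- file.path(dir, "ref.fa")
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), fasta)
  fasta
}

make_test_genome <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  read_genome(write_test_fasta(seqs, dir))
}

# deterministic random genome as plain character sequences
random_seqs <- function(n_chrom, len, seed) {
  set.seed(seed)
  seqs <- lapply(seq_len(n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""))
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  seqs
}

# write a VCF from raw body lines (header supplied)
write_test_vcf <- function(lines, samples = character(),
                           path = withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())) {
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", if (length(samples)) c("FORMAT", samples)),
                  collapse = "\t")
  writeLines(c("##fileformat=VCFv4.2", header, lines), path)
  path
}

# shorthand biallelic record
rec <- function(chrom, pos, ref, alt, qual = 50, filters = "PASS",
                info = character(), gts = NULL, source = "test") {
  genotypes <- list()
  if (!is.null(gts))
    genotypes <- lapply(gts, function(a)
      if (is.null(a)) genotype_call(NULL) else genotype_call(a))
  variant_record(chrom, pos, ref = ref, alt = alt, qual = qual,
                 filters = filters, info = info, genotypes = genotypes,
                 source = source)
}

trio_ids <- c(father = "FATHER", mother = "MOTHER", child = "CHILD")

# 3-sample record from allele pairs (NULL = missing)
trio_rec <- function(chrom, pos, ref, alt, f, m, c_, info = character()) {
  rec(chrom, pos, ref, alt, info = info,
      gts = list(FATHER = f, MOTHER = m, CHILD = c_))
}

trio_vcf <- function(records) {
  new_vcf(meta = "##fileformat=VCFv4.2",
          samples = c("FATHER", "MOTHER", "CHILD"), records = records)
}
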