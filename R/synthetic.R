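#' Simulation configuration
#'
#' Bundles the parameters of the seeded generators: reference shape, variant
#' counts and class mix, per-caller detection behaviour (sensitivity, false
#' positives, representation jitter), trio error injection rates and the
#' fraction of variants annotated as common.
#'
#' @param seed Integer RNG seed; every generator is fully deterministic
#'   given the configuration.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (>= 1000).
#' @param n_variants Number of truth variants.
#' @param snv_fraction Fraction of truth variants that are SNVs (the rest
#'   are 1-10 bp insertions/deletions).
#' @param callers List of caller specs, each a list with `label`,
#'   `sensitivity` (probability a truth variant is called), `fp` (count of
#'   caller-private false positives) and `jitter` (probability an indel is
#'   emitted in a padded, un-normalized but haplotype-equivalent
#'   representation).
#' @param adi_rate,ado_rate Per-locus probabilities of injecting an allele
#'   drop-in / drop-out event into the simulated trio (`adi_rate + ado_rate
#'   <= 1`).
#' @param missing_rate Per-genotype probability of masking a trio genotype
#'   as missing.
#' @param af_common_fraction Fraction of truth variants annotated with a
#'   common allele frequency (`AF=0.05`); half of the remainder get a rare
#'   `AF=0.001`, the rest stay unannotated (novel).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 42L, n_chrom = 2L, chrom_length = 100000L,
                       n_variants = 500L, snv_fraction = 0.8,
                       callers = default_callers(),
                       adi_rate = 0.01, ado_rate = 0.01,
                       missing_rate = 0.02, af_common_fraction = 0.3) {
  if (chrom_length < 1000L) stop("chrom_length must be >= 1000")
  if (n_chrom < 1L || n_variants < 1L) stop("counts must be positive")
  rates <- c(snv_fraction, adi_rate, ado_rate, missing_rate,
             af_common_fraction,
             unlist(lapply(callers, function(cl)
               c(cl$sensitivity, cl$jitter))))
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  if (adi_rate + ado_rate > 1)
    stop("adi_rate + ado_rate must not exceed 1")
  labs <- vapply(callers, `[[`, character(1L), "label")
  if (anyDuplicated(labs)) stop("duplicate caller labels")
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 chrom_length = as.integer(chrom_length),
                 n_variants = as.integer(n_variants),
                 snv_fraction = snv_fraction, callers = callers,
                 adi_rate = adi_rate, ado_rate = ado_rate,
                 missing_rate = missing_rate,
                 af_common_fraction = af_common_fraction),
            class = "sim_config")
}

#' Default four-caller specification
#' @return List of caller specs for [sim_config()].
#' @export
default_callers <- function() {
  list(list(label = "gatk", sensitivity = 0.95, fp = 10L, jitter = 0.3),
       list(label = "samtools", sensitivity = 0.9, fp = 15L, jitter = 0.3),
       list(label = "freebayes", sensitivity = 0.9, fp = 15L, jitter = 0.3),
       list(label = "varscan", sensitivity = 0.85, fp = 20L, jitter = 0.3))
}

#' Simulate a reference genome
#'
#' Uniform random A/C/G/T sequences, written as plain FASTA with a `.fai`
#' index. Byte-identical for a fixed configuration.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return A `ref_genome` (see [read_genome()]); the FASTA sits at
#'   `dir/ref.fa`.
#' @export
simulate_reference <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  seqs <- vapply(seq_len(config$n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                 replace = TRUE), collapse = ""), character(1L))
  names(seqs) <- paste0("chr", seq_len(config$n_chrom))
  fasta <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta,
                              width = 70L)
  if (file.exists(paste0(fasta, ".fai"))) file.remove(paste0(fasta, ".fai"))
  Rsamtools::indexFa(fasta)
  read_genome(fasta)
}

# draw n loci on the genome, each at least `spacing` bp from the others and
# `margin` bp from contig ends (normalization may shift indels left a little;
# spacing keeps distinct variants from sharing non-SNV overlap intervals)
.draw_loci <- function(genome, n, spacing = 40L, margin = 30L,
                       exclude = NULL) {
  gi <- genome$index
  grid <- do.call(rbind, lapply(seq_len(nrow(gi)), function(i) {
    p <- seq.int(margin, gi$length[i] - margin, by = spacing)
    data.frame(chrom = gi$name[i], pos = p, stringsAsFactors = FALSE)
  }))
  if (!is.null(exclude) && nrow(exclude)) {
    key <- paste(grid$chrom, grid$pos)
    grid <- grid[!key %in% paste(exclude$chrom, exclude$pos), , drop = FALSE]
  }
  if (n > nrow(grid))
    stop("requested ", n, " variants but only ", nrow(grid),
         " spaced positions are available")
  grid[sort(sample.int(nrow(grid), n)), , drop = FALSE]
}

.random_alt <- function(ref, avoid = character()) {
  sample(setdiff(c("A", "C", "G", "T"), c(ref, avoid)), 1L)
}

# build one truth variant (normalized) at a locus
.make_truth_variant <- function(genome, chrom, pos, snv) {
  refbase <- fetch_reference(genome, chrom, pos, pos)
  if (snv) {
    return(variant_record(chrom, pos, ref = refbase,
                          alts = .random_alt(refbase)))
  }
  len <- sample.int(10L, 1L)
  if (stats::runif(1) < 0.5) {  # deletion
    ref <- fetch_reference(genome, chrom, pos, pos + len)
    rec <- variant_record(chrom, pos, ref = ref, alts = refbase)
  } else {                      # insertion
    ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    rec <- variant_record(chrom, pos, ref = refbase,
                          alts = paste0(refbase, ins))
  }
  normalize_variant(rec, genome)
}

.af_annotation <- function(config) {
  u <- stats::runif(1)
  if (u < config$af_common_fraction) c(AF = "0.05")
  else if (u < config$af_common_fraction +
             (1 - config$af_common_fraction) / 2) c(AF = "0.001")
  else character()
}

#' Pad an indel into an equivalent un-normalized representation
#'
#' The inverse of [normalize_variant()]: appends matching reference bases at
#' the 3' end and/or prepends the reference base at `pos - 1`. The padded
#' record denotes the same haplotype change and normalizes back to the
#' input. SNVs are returned unchanged.
#'
#' @param record A normalized `variant_record`.
#' @param genome A `ref_genome`.
#' @param suffix Number of 3' reference bases to append (0-3 drawn at random
#'   when `NULL`).
#' @param prefix Number of 5' reference bases to prepend (at random when
#'   `NULL`).
#' @return A haplotype-equivalent `variant_record`.
#' @export
pad_representation <- function(record, genome, suffix = NULL,
                               prefix = NULL) {
  if (is_snv(record)) return(record)
  if (is.null(suffix)) suffix <- sample(0:3, 1L)
  if (is.null(prefix)) prefix <- sample(0:2, 1L)
  if (suffix == 0L && prefix == 0L) suffix <- 1L
  r <- record
  if (suffix > 0L) {
    tail_start <- r$pos + nchar(r$ref)
    chrom_len <- genome$index$length[match(r$chrom, genome$index$name)]
    suffix <- min(suffix, chrom_len - tail_start + 1L)
    if (suffix > 0L) {
      pad <- fetch_reference(genome, r$chrom, tail_start,
                             tail_start + suffix - 1L)
      r$ref <- paste0(r$ref, pad)
      r$alts <- paste0(r$alts, pad)
    }
  }
  while (prefix > 0L && r$pos > 1L) {
    base <- fetch_reference(genome, r$chrom, r$pos - 1L, r$pos - 1L)
    r$ref <- paste0(base, r$ref)
    r$alts <- paste0(base, r$alts)
    r$pos <- r$pos - 1L
    prefix <- prefix - 1L
  }
  r
}

.sim_meta <- function(genome) {
  c("##fileformat=VCFv4.2",
    paste0("##contig=<ID=", genome$index$name, ",length=",
           genome$index$length, ">"),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
}

#' Simulate multi-caller call sets with controlled concordance
#'
#' Generates `n_variants` truth variants (SNVs and 1-10 bp indels) at
#' spaced, distinct normalized positions, then one single-sample VCF per
#' configured caller: each truth variant is included independently with the
#' caller's `sensitivity`; each caller adds `fp` private false positives at
#' fresh positions; with probability `jitter` an included indel is written
#' in a padded, haplotype-equivalent representation
#' ([pad_representation()]), exercising normalization downstream.
#'
#' @param config A [sim_config()].
#' @param genome A `ref_genome` from [simulate_reference()].
#' @param dir Output directory.
#' @return List with `truth_path`, `caller_paths` (named), `membership`
#'   (logical matrix, truth variants x callers), `truth` (the truth
#'   `mule_vcf`), and `fp_keys` (list of per-caller false-positive merge
#'   keys).
#' @export
simulate_callsets <- function(config, genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 1L)
  n_callers <- length(config$callers)
  labels <- vapply(config$callers, `[[`, character(1L), "label")
  total_fp <- sum(vapply(config$callers, function(cl) as.integer(cl$fp),
                         integer(1L)))
  loci <- .draw_loci(genome, config$n_variants + total_fp)
  truth_idx <- sort(sample.int(nrow(loci), config$n_variants))
  fp_pool <- setdiff(seq_len(nrow(loci)), truth_idx)

  truth_recs <- vector("list", config$n_variants)
  for (i in seq_len(config$n_variants)) {
    li <- loci[truth_idx[i], ]
    rec <- .make_truth_variant(genome, li$chrom, li$pos,
                               snv = stats::runif(1) < config$snv_fraction)
    rec$info <- .af_annotation(config)
    rec$genotypes <- list(SAMPLE1 = genotype_call(
      if (stats::runif(1) < 0.7) c(0L, 1L) else c(1L, 1L),
      gq = sample(30:99, 1L)))
    rec$qual <- round(stats::runif(1, 30, 1000), 2)
    rec$filters <- "PASS"
    truth_recs[[i]] <- rec
  }
  truth <- new_vcf(meta = .sim_meta(genome), samples = "SAMPLE1",
                   records = sort_records(truth_recs, genome$index))
  truth_path <- file.path(dir, "truth.vcf")
  write_vcf(truth, truth_path, genome = genome$index)

  membership <- matrix(FALSE, nrow = config$n_variants, ncol = n_callers,
                       dimnames = list(NULL, labels))
  caller_paths <- character(n_callers)
  names(caller_paths) <- labels
  fp_keys <- vector("list", n_callers)
  names(fp_keys) <- labels
  fp_cursor <- 0L
  for (ci in seq_len(n_callers)) {
    spec <- config$callers[[ci]]
    carried <- stats::runif(config$n_variants) < spec$sensitivity
    membership[, ci] <- carried
    recs <- lapply(which(carried), function(i) {
      r <- truth_recs[[i]]
      if (!is_snv(r) && stats::runif(1) < spec$jitter)
        r <- pad_representation(r, genome)
      r$qual <- round(stats::runif(1, 30, 1000), 2)
      r
    })
    n_fp <- as.integer(spec$fp)
    if (n_fp > 0L) {
      idx <- fp_pool[fp_cursor + seq_len(n_fp)]
      fp_cursor <- fp_cursor + n_fp
      fps <- lapply(idx, function(j) {
        li <- loci[j, ]
        rec <- .make_truth_variant(genome, li$chrom, li$pos,
                                   snv = stats::runif(1) <
                                     config$snv_fraction)
        rec$genotypes <- list(SAMPLE1 = genotype_call(
          c(0L, 1L), gq = sample(10:60, 1L)))
        rec$qual <- round(stats::runif(1, 10, 100), 2)
        rec$filters <- "PASS"
        rec
      })
      fp_keys[[ci]] <- vapply(fps, merge_key, character(1L))
      recs <- c(recs, fps)
    } else {
      fp_keys[[ci]] <- character()
    }
    v <- new_vcf(meta = .sim_meta(genome), samples = "SAMPLE1",
                 records = sort_records(recs, genome$index))
    caller_paths[ci] <- file.path(dir, paste0(labels[ci], ".vcf"))
    write_vcf(v, caller_paths[ci], genome = genome$index)
  }
  list(truth_path = truth_path, caller_paths = caller_paths,
       membership = membership, truth = truth, fp_keys = fp_keys)
}

#' Simulate a family trio VCF with injected Mendelian errors
#'
#' Parent genotypes are drawn at random at each truth locus and the child
#' inherits one allele from each parent. At each locus, with probability
#' `adi_rate` one child allele is replaced by a third allele absent from
#' both parents (a logged allele drop-in); otherwise with probability
#' `ado_rate` the trio is constructed so that the child misses an obligately
#' transmitted allele while every child allele remains present in a parent
#' (a logged allele drop-out). Each genotype is then masked missing
#' independently with probability `missing_rate`. The injection log is the
#' ground truth for the trio statistics.
#'
#' @param config A [sim_config()].
#' @param genome A `ref_genome` from [simulate_reference()].
#' @param dir Output directory.
#' @return List with `path` (3-sample VCF: FATHER, MOTHER, CHILD), `vcf`
#'   (the `mule_vcf`), and `log` (data.frame: `chrom`, `pos`, `event` in
#'   none/adi/ado, `masked` — whether any member's genotype was masked).
#' @export
simulate_trio <- function(config, genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 2L)
  loci <- .draw_loci(genome, config$n_variants)
  n <- nrow(loci)
  recs <- vector("list", n)
  log <- data.frame(chrom = loci$chrom, pos = loci$pos,
                    event = character(n), masked = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    chrom <- loci$chrom[i]; pos <- loci$pos[i]
    refbase <- fetch_reference(genome, chrom, pos, pos)
    alt1 <- .random_alt(refbase)
    alts <- alt1
    u <- stats::runif(1)
    if (u < config$adi_rate) {
      event <- "adi"
      f <- sort(stats::rbinom(2L, 1L, 0.5))
      m <- sort(stats::rbinom(2L, 1L, 0.5))
      child <- c(sample(f, 1L), sample(m, 1L))
      alts <- c(alt1, .random_alt(refbase, avoid = alt1))
      child[sample.int(2L, 1L)] <- 2L
    } else if (u < config$adi_rate + config$ado_rate) {
      event <- "ado"
      a <- stats::rbinom(1L, 1L, 0.5)
      f <- c(a, a)
      m <- sample(c(a, 1L - a))
      child <- c(1L - a, 1L - a)
    } else {
      event <- "none"
      f <- sort(stats::rbinom(2L, 1L, 0.5))
      m <- sort(stats::rbinom(2L, 1L, 0.5))
      child <- c(sample(f, 1L), sample(m, 1L))
    }
    mask <- stats::runif(3L) < config$missing_rate
    gts <- list(
      FATHER = if (mask[1L]) genotype_call(NULL) else
        genotype_call(f, gq = sample(30:99, 1L)),
      MOTHER = if (mask[2L]) genotype_call(NULL) else
        genotype_call(m, gq = sample(30:99, 1L)),
      CHILD = if (mask[3L]) genotype_call(NULL) else
        genotype_call(child, gq = sample(30:99, 1L)))
    rec <- variant_record(chrom, pos, ref = refbase, alts = alts,
                          qual = round(stats::runif(1, 30, 1000), 2),
                          filters = "PASS", info = .af_annotation(config),
                          genotypes = gts)
    recs[[i]] <- rec
    log$event[i] <- event
    log$masked[i] <- any(mask)
  }
  ord <- order(.chrom_rank(log$chrom, genome$index), log$pos)
  log <- log[ord, , drop = FALSE]
  vcf <- new_vcf(meta = .sim_meta(genome),
                 samples = c("FATHER", "MOTHER", "CHILD"),
                 records = recs[ord])
  path <- file.path(dir, "trio.vcf")
  write_vcf(vcf, path, genome = genome$index)
  list(path = path, vcf = vcf, log = log)
}
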