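#' Normalize a variant to its left-aligned minimal representation
#'
#' Canonicalizes indel representation so that equivalent variants emitted by
#' different callers compare equal. The algorithm operates jointly on the
#' allele set `{ref} + alts` of the whole (possibly multiallelic) record:
#'
#' 1. While every allele ends in the same nucleotide, drop that nucleotide;
#'    if any allele becomes empty, prepend the reference base at `pos - 1` to
#'    every allele and decrement `pos`.
#' 2. While every allele begins with the same nucleotide and every allele has
#'    length >= 2, drop that first nucleotide and increment `pos`.
#'
#' The result is idempotent: no shared terminal nucleotide remains and no
#' further left shift is possible. SNVs are already minimal and pass through
#' unchanged. `N` bases participate in trimming like any fixed nucleotide.
#'
#' @param record A [variant_record()]; its `ref` must match the genome at
#'   `pos`.
#' @param genome A `ref_genome` from [read_genome()].
#' @return The normalized `variant_record` (genotypes, qual etc. unchanged).
#' @export
normalize_variant <- function(record, genome) {
  obs <- fetch_reference(genome, record$chrom, record$pos,
                         record$pos + nchar(record$ref) - 1L)
  if (obs != toupper(record$ref))
    stop("reference mismatch at ", record$chrom, ":", record$pos,
         ": record has '", record$ref, "', genome has '", obs, "'")
  alleles <- c(record$ref, record$alts)
  pos <- record$pos

  repeat {
    n <- nchar(alleles)
    last <- substr(alleles, n, n)
    if (length(unique(last)) != 1L) break
    alleles <- substr(alleles, 1L, n - 1L)
    if (any(nchar(alleles) == 0L)) {
      if (pos == 1L)
        stop("cannot left-extend past contig start at ", record$chrom, ":1")
      base <- fetch_reference(genome, record$chrom, pos - 1L, pos - 1L)
      alleles <- paste0(base, alleles)
      pos <- pos - 1L
    }
  }
  repeat {
    n <- nchar(alleles)
    if (any(n < 2L)) break
    first <- substr(alleles, 1L, 1L)
    if (length(unique(first)) != 1L) break
    alleles <- substr(alleles, 2L, n)
    pos <- pos + 1L
  }

  out <- record
  out$pos <- pos
  out$ref <- alleles[1L]
  out$alts <- alleles[-1L]
  out
}

#' Normalize every record of a VCF
#'
#' Applies [normalize_variant()] to each record and re-sorts the result in
#' genome order. The record count is preserved.
#'
#' @param vcf A `mule_vcf` object.
#' @param genome A `ref_genome`.
#' @return A `mule_vcf` with normalized, sorted records.
#' @export
normalize_vcf <- function(vcf, genome) {
  recs <- vector("list", length(vcf$records))
  for (i in seq_along(vcf$records)) {
    recs[[i]] <- tryCatch(
      normalize_variant(vcf$records[[i]], genome),
      error = function(e) {
        r <- vcf$records[[i]]
        stop("normalization failed for record ", i, " (", r$chrom, ":",
             r$pos, "): ", conditionMessage(e), call. = FALSE)
      })
  }
  vcf$records <- sort_records(recs, genome$index)
  vcf
}

#' Normalize a VCF file on disk
#'
#' File-level wrapper around [normalize_vcf()].
#'
#' @param vcf_path Input VCF path.
#' @param genome A `ref_genome` or a FASTA path.
#' @param out_path Output VCF path.
#' @return `out_path`, invisibly.
#' @export
normalize_file <- function(vcf_path, genome, out_path) {
  if (is.character(genome)) genome <- read_genome(genome)
  v <- read_vcf(vcf_path)
  write_vcf(normalize_vcf(v, genome), out_path, genome = genome$index)
  invisible(out_path)
}
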