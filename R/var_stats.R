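#' Transition/transversion counts and ratio
#'
#' Counts transitions (A<->G, C<->T) and transversions over the ref->alt
#' pairs of SNV records, one pair per alternate allele (alts of multiallelic
#' SNVs classified independently). Non-SNV records are ignored.
#'
#' @param records List of `variant_record`s.
#' @return List with `ti`, `tv`, and `ratio` (`ti/tv`; `NA` when `tv` is 0).
#' @export
titv_ratio <- function(records) {
  ti <- 0L; tv <- 0L
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  for (r in records) {
    if (!is_snv(r)) next
    for (a in r$alts) {
      expected <- transitions[[r$ref]]
      if (!is.null(expected) && identical(a, expected)) ti <- ti + 1L
      else tv <- tv + 1L
    }
  }
  list(ti = ti, tv = tv,
       ratio = if (tv > 0L) ti / tv else NA_real_)
}

#' Heterozygote/homozygote counts and ratio for one sample
#'
#' `het` counts genotypes with two distinct alleles; `hom_alt` genotypes
#' with two identical non-reference alleles. Homozygous-reference and
#' missing genotypes are excluded.
#'
#' @param records List of `variant_record`s.
#' @param sample Sample name.
#' @return List with `het`, `hom_alt`, `ratio` (`NA` when `hom_alt` is 0).
#' @export
het_hom_ratio <- function(records, sample) {
  het <- 0L; hom <- 0L
  seen <- FALSE
  for (r in records) {
    g <- r$genotypes[[sample]]
    if (is.null(g)) next
    seen <- TRUE
    if (gt_is_missing(g)) next
    a <- g$alleles
    if (a[1L] != a[2L]) het <- het + 1L
    else if (a[1L] != 0L) hom <- hom + 1L
  }
  if (!seen && length(records))
    stop("sample '", sample, "' not present in records")
  list(het = het, hom_alt = hom,
       ratio = if (hom > 0L) het / hom else NA_real_)
}

#' Filter records by annotated allele frequency
#'
#' Keeps records whose INFO annotation `af_key` is at most `threshold`, or
#' absent (unannotated variants are treated as novel and kept). Frequencies
#' are never recomputed; the annotation is expected to come from an upstream
#' annotation step.
#'
#' @param records List of `variant_record`s.
#' @param af_key INFO key holding the population allele frequency.
#' @param threshold Maximum frequency retained, in `[0, 1]`.
#' @return The retained sublist.
#' @export
maf_filter <- function(records, af_key = "AF", threshold = 0.01) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  keep <- vapply(records, function(r) {
    v <- r$info[af_key]
    if (!af_key %in% names(r$info) || is.na(v)) return(TRUE)
    af <- suppressWarnings(as.numeric(v))
    if (is.na(af))
      stop("unparseable ", af_key, " value '", v, "' at ", r$chrom, ":",
           r$pos)
    af <= threshold
  }, logical(1L))
  records[keep]
}

#' Summary statistics for a call set
#'
#' Convenience wrapper producing the toolkit's standard VCF report: record
#' and SNV counts, Ti/Tv and per-sample het/hom ratios.
#'
#' @param vcf A `mule_vcf`.
#' @param sample Optional sample name for the het/hom ratio (defaults to the
#'   first sample, if any).
#' @return List of class `vcf_stats`.
#' @export
vcf_stats <- function(vcf, sample = NULL) {
  recs <- vcf$records
  snv <- vapply(recs, is_snv, logical(1L))
  tt <- titv_ratio(recs)
  hh <- NULL
  if (is.null(sample) && length(vcf$samples)) sample <- vcf$samples[1L]
  if (!is.null(sample)) hh <- het_hom_ratio(recs, sample)
  structure(list(n_records = length(recs), n_snv = sum(snv),
                 n_nonsnv = sum(!snv), titv = tt, het_hom = hh,
                 sample = sample),
            class = "vcf_stats")
}

#' @export
print.vcf_stats <- function(x, ...) {
  cat("Call set statistics\n")
  cat("  records:", x$n_records, "(SNV", x$n_snv, "/ non-SNV", x$n_nonsnv,
      ")\n")
  cat(sprintf("  Ti/Tv: %d/%d = %s\n", x$titv$ti, x$titv$tv,
              ifelse(is.na(x$titv$ratio), "NA",
                     sprintf("%.3f", x$titv$ratio))))
  if (!is.null(x$het_hom))
    cat(sprintf("  het/hom-alt (%s): %d/%d = %s\n", x$sample,
                x$het_hom$het, x$het_hom$hom_alt,
                ifelse(is.na(x$het_hom$ratio), "NA",
                       sprintf("%.3f", x$het_hom$ratio))))
  invisible(x)
}
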