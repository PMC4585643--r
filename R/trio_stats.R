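#' Mendelian error classification at one locus
#'
#' Given non-missing diploid genotypes for father, mother and child,
#' considers the four possible transmissions (one allele from each parent)
#' and picks the one minimizing mismatches between the transmitted allele
#' pair and the child's allele pair. The `k` unmatched child alleles under
#' that optimum (0, 1 or 2) are the Mendelian errors at the locus; each is an
#' allele drop-in (ADI) if the allele appears in neither parent's genotype,
#' otherwise an allele drop-out (ADO, a violated obligate transmission).
#'
#' The split is deterministic: a child allele absent from both parents is
#' unmatched under every transmission, so ADI equals the count of such
#' alleles and ADO the remainder.
#'
#' @param father,mother,child [genotype_call()]s or length-2 integer vectors
#'   of allele indices.
#' @return Named integer vector `c(adi = ..., ado = ...)`.
#' @export
locus_mendel <- function(father, mother, child) {
  f <- .gt_alleles(father); m <- .gt_alleles(mother); c_ <- .gt_alleles(child)
  best_k <- 2L
  for (fi in f) for (mi in m) {
    k <- 2L - .multiset_overlap(c(fi, mi), c_)
    if (k < best_k) best_k <- k
  }
  parent_pool <- c(f, m)
  adi <- sum(!(c_ %in% parent_pool))
  if (adi > best_k) adi <- best_k  # cannot exceed total errors
  c(adi = as.integer(adi), ado = as.integer(best_k - adi))
}

.gt_alleles <- function(g) {
  if (inherits(g, "genotype_call")) {
    if (gt_is_missing(g)) stop("missing genotype passed to trio statistic")
    return(g$alleles)
  }
  g <- as.integer(g)
  if (length(g) != 2L || anyNA(g))
    stop("genotype must be two allele indices or a genotype_call")
  g
}

.multiset_overlap <- function(a, b) {
  n <- 0L
  for (x in a) {
    i <- match(x, b)
    if (!is.na(i)) { b <- b[-i]; n <- n + 1L }
  }
  n
}

#' Alleles identical by state with a parent
#'
#' Size of the multiset intersection of the child's and the parent's allele
#' pairs: 0, 1 or 2.
#'
#' @param child,parent [genotype_call()]s or length-2 integer vectors.
#' @return Integer in 0..2.
#' @export
ibs_with_parent <- function(child, parent) {
  .multiset_overlap(.gt_alleles(child), .gt_alleles(parent))
}

#' Trio Mendelian error summary over a multi-sample VCF
#'
#' Iterates the loci of a trio VCF. Loci where any member's genotype is
#' missing are excluded from every tally. For the remaining trio calls, the
#' per-locus Mendelian errors ([locus_mendel()]) and identity-by-state counts
#' with each parent ([ibs_with_parent()]) are accumulated. The error rate is
#' the ratio of all Mendelian errors (ADI + ADO) to the number of trio calls.
#'
#' @param vcf A multi-sample `mule_vcf`.
#' @param trio Named character vector with `father`, `mother`, `child`
#'   sample IDs.
#' @return An object of class `trio_counts`: list with `n_trio_calls`,
#'   `adi`, `ado`, `ibs_father`, `ibs_mother` (length-3 histograms over
#'   0,1,2 shared alleles), and `error_rate` (`NA` when there are no trio
#'   calls).
#' @export
trio_summary <- function(vcf, trio) {
  trio <- .check_trio(trio)
  absent <- setdiff(unname(trio), vcf$samples)
  if (length(absent))
    stop("sample(s) not in VCF: ", paste(absent, collapse = ", "))
  n <- 0L; adi <- 0L; ado <- 0L
  ibs_f <- c(`0` = 0L, `1` = 0L, `2` = 0L)
  ibs_m <- c(`0` = 0L, `1` = 0L, `2` = 0L)
  for (r in vcf$records) {
    gf <- r$genotypes[[trio[["father"]]]]
    gm <- r$genotypes[[trio[["mother"]]]]
    gc <- r$genotypes[[trio[["child"]]]]
    if (is.null(gf) || is.null(gm) || is.null(gc) ||
        gt_is_missing(gf) || gt_is_missing(gm) || gt_is_missing(gc)) next
    n <- n + 1L
    err <- locus_mendel(gf, gm, gc)
    adi <- adi + err[["adi"]]
    ado <- ado + err[["ado"]]
    i_f <- ibs_with_parent(gc, gf)
    i_m <- ibs_with_parent(gc, gm)
    ibs_f[i_f + 1L] <- ibs_f[i_f + 1L] + 1L
    ibs_m[i_m + 1L] <- ibs_m[i_m + 1L] + 1L
  }
  structure(list(n_trio_calls = n, adi = adi, ado = ado,
                 ibs_father = ibs_f, ibs_mother = ibs_m,
                 error_rate = if (n > 0L) (adi + ado) / n else NA_real_),
            class = "trio_counts")
}

#' @export
print.trio_counts <- function(x, ...) {
  cat("Trio Mendelian error summary\n")
  cat("  trio calls (no missing genotype):", x$n_trio_calls, "\n")
  cat("  allele drop-in (ADI): ", x$adi, "\n")
  cat("  allele drop-out (ADO):", x$ado, "\n")
  rate <- if (is.na(x$error_rate)) "NA" else
    sprintf("%.4f (%.2f%%)", x$error_rate, 100 * x$error_rate)
  cat("  Mendelian error rate: ", rate, "\n")
  cat("  IBS with father (0/1/2):", paste(x$ibs_father, collapse = "/"), "\n")
  cat("  IBS with mother (0/1/2):", paste(x$ibs_mother, collapse = "/"), "\n")
  invisible(x)
}

#' Trio summary restricted to rare/novel variants
#'
#' Runs [trio_summary()] on the records whose annotated allele frequency
#' (INFO key `af_key`) is at most `threshold` or absent (unannotated = novel
#' = kept); variants annotated as more common are discarded, the usual
#' MAF > 1\% filter when `threshold = 0.01`.
#'
#' @param vcf A multi-sample `mule_vcf`.
#' @param trio Named trio sample IDs.
#' @param af_key INFO key holding the population allele frequency.
#' @param threshold Maximum allele frequency retained, in `[0, 1]`.
#' @return A `trio_counts` object for the rare subset.
#' @export
maf_stratified_rate <- function(vcf, trio, af_key = "AF", threshold = 0.01) {
  vcf$records <- maf_filter(vcf$records, af_key, threshold)
  trio_summary(vcf, trio)
}
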