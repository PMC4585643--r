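#' Venn partition counts over k sets of variant keys
#'
#' Partitions the union of up to five key collections into the `2^k - 1`
#' Venn regions and counts members of each. Region names are the
#' `&`-joined names of the sets containing the element, in input order.
#'
#' @param sets Named list of 2 to 5 character vectors (variant keys;
#'   duplicates within a set are ignored).
#' @return Named integer vector over all `2^k - 1` regions (zeros included),
#'   summing to the size of the union.
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 5L) stop("venn_counts requires 2 to 5 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  if (length(universe) == 0L)
    member <- matrix(logical(), nrow = 0L, ncol = k)
  region_of <- apply(member, 1L, function(row)
    paste(names(sets)[row], collapse = "&"))
  labels <- .venn_region_labels(names(sets))
  counts <- integer(length(labels))
  names(counts) <- labels
  tab <- table(region_of)
  counts[names(tab)] <- as.integer(tab)
  counts
}

.venn_region_labels <- function(set_names) {
  k <- length(set_names)
  combos <- unlist(lapply(seq_len(k), function(size)
    utils::combn(set_names, size, paste, collapse = "&",
                 simplify = FALSE)), use.names = FALSE)
  combos
}

#' SNV keys of a record list
#'
#' One key per alternate allele of each SNV record:
#' `chrom:pos:ref:alt`. Non-SNV records contribute nothing.
#'
#' @param records List of `variant_record`s.
#' @return Character vector of keys.
#' @export
snv_keys <- function(records) {
  unlist(lapply(records, function(r) {
    if (!is_snv(r)) return(character())
    paste(r$chrom, r$pos, r$ref, r$alts, sep = ":")
  }), use.names = FALSE)
}

#' Intervalize non-SNV records
#'
#' Reduces each non-SNV record to its position point extended by `flank`
#' base pairs towards both ends: the closed interval
#' `[pos - flank, pos + flank]`. Reference and alternate alleles are
#' ignored. Records should be normalized first so that equivalent indels
#' land on the same position.
#'
#' @param records List of `variant_record`s.
#' @param source Label attached to the intervals.
#' @param flank Extension in bp on each side (default 10).
#' @return Data.frame with `chrom`, `start`, `end`, `source` (closed,
#'   1-based coordinates; `start` may go below 1 near contig edges).
#' @export
nonsnv_intervals <- function(records, source, flank = 10L) {
  keep <- !vapply(records, is_snv, logical(1L))
  recs <- records[keep]
  data.frame(
    chrom = vapply(recs, `[[`, character(1L), "chrom"),
    start = vapply(recs, `[[`, integer(1L), "pos") - as.integer(flank),
    end = vapply(recs, `[[`, integer(1L), "pos") + as.integer(flank),
    source = rep(source, length(recs)),
    stringsAsFactors = FALSE)
}

#' Single-linkage clusters of non-SNV intervals
#'
#' Two intervals overlap iff they share a chromosome and
#' `start1 <= end2 & start2 <= end1` (closed intervals). Clusters are the
#' connected components of the overlap graph (single linkage); each cluster
#' counts once towards the Venn region of the set of sources present in it.
#'
#' @param intervals Data.frame from [nonsnv_intervals()] (rows from several
#'   sources concatenated), columns `chrom`, `start`, `end`, `source`.
#' @param set_names Character vector of all source labels (fixes region
#'   label order; defaults to order of appearance).
#' @return List with `clusters` (data.frame: cluster id per interval row)
#'   and `counts` (named integer vector of Venn region counts; one unit per
#'   cluster).
#' @export
nonsnv_clusters <- function(intervals, set_names = NULL) {
  if (is.null(set_names)) set_names <- unique(intervals$source)
  n <- nrow(intervals)
  cluster <- integer(n)
  if (n > 0L) {
    ord <- order(intervals$chrom, intervals$start, intervals$end)
    cid <- 0L
    cur_chrom <- NA_character_
    cur_end <- -Inf
    for (i in ord) {
      if (!identical(intervals$chrom[i], cur_chrom) ||
          intervals$start[i] > cur_end) {
        cid <- cid + 1L
        cur_chrom <- intervals$chrom[i]
        cur_end <- intervals$end[i]
      } else {
        cur_end <- max(cur_end, intervals$end[i])
      }
      cluster[i] <- cid
    }
  }
  labels <- .venn_region_labels(set_names)
  counts <- integer(length(labels))
  names(counts) <- labels
  if (n > 0L) {
    present <- tapply(intervals$source, cluster, function(s)
      paste(set_names[sort(match(unique(s), set_names))], collapse = "&"))
    tab <- table(unlist(present))
    counts[names(tab)] <- as.integer(tab)
  }
  list(clusters = data.frame(intervals, cluster = cluster),
       counts = counts)
}

#' Concordance rate from Venn region counts
#'
#' The percentage of the union shared by all sets: 100 times the count of
#' the all-sources region over the sum of all region counts.
#'
#' @param counts Named region counts from [venn_counts()] or
#'   [nonsnv_clusters()].
#' @return Percentage in `[0, 100]`, or `NA` for an empty union.
#' @export
concordance_rate <- function(counts) {
  total <- sum(counts)
  if (total == 0L) return(NA_real_)
  # the all-sets region is the label with the most '&' separators
  full <- names(counts)[which.max(nchar(gsub("[^&]", "", names(counts))))]
  100 * counts[[full]] / total
}

#' Variant concordance across caller VCFs
#'
#' End-to-end wrapper: reads (or accepts) k call sets, normalizes them,
#' splits variants into SNVs and non-SNVs, and computes Venn region counts
#' and concordance rates for both classes. SNVs are matched by exact
#' chromosome/position/ref/alt keys; non-SNVs by single-linkage overlap of
#' their +/- `flank` bp intervals.
#'
#' @param paths Named vector/list of VCF paths or `mule_vcf` objects.
#' @param genome A `ref_genome` or FASTA path.
#' @param flank Interval extension for non-SNVs (default 10 bp).
#' @return List of class `venn_result` with `snv_counts`, `nonsnv_counts`,
#'   `snv_concordance`, `nonsnv_concordance`.
#' @export
venn_vcfs <- function(paths, genome, flank = 10L) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.null(names(paths))) stop("inputs must be named by source label")
  vcfs <- lapply(paths, function(x) {
    v <- if (inherits(x, "mule_vcf")) x else read_vcf(x)
    normalize_vcf(v, genome)
  })
  snv_sets <- lapply(vcfs, function(v) snv_keys(v$records))
  snv <- venn_counts(snv_sets)
  ivs <- do.call(rbind, lapply(names(vcfs), function(s)
    nonsnv_intervals(vcfs[[s]]$records, s, flank)))
  nonsnv <- nonsnv_clusters(ivs, set_names = names(vcfs))$counts
  structure(list(snv_counts = snv, nonsnv_counts = nonsnv,
                 snv_concordance = concordance_rate(snv),
                 nonsnv_concordance = concordance_rate(nonsnv)),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat("Variant concordance\n")
  cat("SNV regions:\n")
  print(x$snv_counts)
  cat(sprintf("SNV concordance: %s\n",
              ifelse(is.na(x$snv_concordance), "NA",
                     sprintf("%.2f%%", x$snv_concordance))))
  cat("non-SNV regions (clusters):\n")
  print(x$nonsnv_counts)
  cat(sprintf("non-SNV concordance: %s\n",
              ifelse(is.na(x$nonsnv_concordance), "NA",
                     sprintf("%.2f%%", x$nonsnv_concordance))))
  invisible(x)
}
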