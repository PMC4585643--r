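#' Canonical caller priority ordering
#'
#' Orders caller labels by the fixed priority
#' GATK > SAMtools > FreeBayes > VarScan > SOAPsnp (matched
#' case-insensitively, with a `gatk-hc`/`gatkhc` alias for GATK).
#' Unrecognized labels keep their given order and follow the recognized ones.
#'
#' @param sources Character vector of caller/source labels.
#' @return The labels reordered by priority.
#' @export
caller_priority <- function(sources) {
  known <- c("gatk", "samtools", "freebayes", "varscan", "soapsnp")
  norm <- tolower(sources)
  norm[norm %in% c("gatk-hc", "gatkhc", "gatk_hc")] <- "gatk"
  rank <- match(norm, known)
  rank[is.na(rank)] <- length(known) + 1L
  sources[order(rank, seq_along(sources))]
}

#' Merge key of a record
#'
#' SNVs overlap when chromosome and position agree; non-SNVs additionally
#' require the same reference allele. The key encodes this: `S:chrom:pos`
#' for SNVs, `I:chrom:pos:ref` for non-SNVs.
#'
#' @param record A `variant_record`.
#' @return Key string.
#' @export
merge_key <- function(record) {
  if (is_snv(record)) paste("S", record$chrom, record$pos, sep = ":")
  else paste("I", record$chrom, record$pos, record$ref, sep = ":")
}

#' Merge records sharing one key into a consensus record
#'
#' The records must share one [merge_key()] and be ordered by caller
#' priority. Chromosome, position and reference allele come from the first
#' record; alternate alleles are pooled across records in priority-then-
#' appearance order and deduplicated; quality and genotypes (including GQ)
#' come from the first record, with genotype allele indices remapped to the
#' pooled alt list. FILTER becomes `PASS` if at least one input record is
#' unfiltered (PASS or missing FILTER), otherwise the union of observed
#' filter names. The supporter set (source labels) is attached as attribute
#' `supporters`.
#'
#' @param records List of `variant_record`s sharing one merge key, ordered by
#'   priority.
#' @return A merged `variant_record` with a `supporters` attribute.
#' @export
merge_records <- function(records) {
  if (!length(records)) stop("no records to merge")
  keys <- vapply(records, merge_key, character(1L))
  if (length(unique(keys)) != 1L)
    stop("records do not share one merge key: ",
         paste(unique(keys), collapse = " vs "))
  first <- records[[1L]]
  pooled <- unique(unlist(lapply(records, `[[`, "alts")))
  out <- first
  out$alts <- pooled
  remap <- match(first$alts, pooled)
  out$genotypes <- lapply(first$genotypes, function(g) {
    if (gt_is_missing(g)) return(g)
    g$alleles <- ifelse(g$alleles == 0L, 0L, remap[g$alleles])
    g
  })
  if (any(vapply(records, is_unfiltered, logical(1L)))) {
    out$filters <- "PASS"
  } else {
    out$filters <- unique(unlist(lapply(records, `[[`, "filters")))
  }
  supporters <- unique(vapply(records, `[[`, character(1L), "source"))
  attr(out, "supporters") <- supporters
  out
}

#' Merge per-caller single-sample VCFs into one VCF with provenance
#'
#' Inputs are normalized, grouped by [merge_key()], merged with
#' [merge_records()] (records within a group ordered by [caller_priority()]
#' of their source), and sorted. Each output record carries INFO tags
#' `CALLERS` (supporting source labels) and `NCALLERS` (their count);
#' the header records the total number of input files.
#'
#' @param paths Named character vector or named list of VCF paths; names are
#'   the source labels (e.g. `c(gatk = "g.vcf", samtools = "s.vcf")`). A
#'   named list of `mule_vcf` objects is also accepted.
#' @param genome A `ref_genome` or FASTA path.
#' @param check_sample If `TRUE` (default), all inputs must carry the same
#'   single sample name.
#' @return A merged `mule_vcf`.
#' @export
merge_vcfs <- function(paths, genome, check_sample = TRUE) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("inputs must be named by source label")
  vcfs <- lapply(seq_along(paths), function(i) {
    x <- paths[[i]]
    v <- if (inherits(x, "mule_vcf")) x else read_vcf(x)
    lab <- names(paths)[i]
    v$records <- lapply(v$records, function(r) { r$source <- lab; r })
    v
  })
  names(vcfs) <- names(paths)
  for (v in vcfs) {
    if (length(v$samples) > 1L)
      stop("multi-sample input must be split before merging (samples: ",
           paste(v$samples, collapse = ", "), ")")
  }
  sample_names <- unique(unlist(lapply(vcfs, `[[`, "samples")))
  if (check_sample && length(sample_names) > 1L)
    stop("sample name disagreement across inputs: ",
         paste(sample_names, collapse = ", "),
         " (use check_sample = FALSE to override)")
  sample_name <- if (length(sample_names)) sample_names[1L] else character()

  vcfs <- lapply(vcfs, normalize_vcf, genome = genome)
  all_recs <- unlist(lapply(vcfs, `[[`, "records"), recursive = FALSE)
  merged <- .merge_record_pool(all_recs)
  merged <- sort_records(merged, genome$index)
  merged <- lapply(merged, .stamp_provenance)
  meta <- c("##fileformat=VCFv4.2",
            paste0("##mulekit_n_sources=", length(paths)),
            paste0("##mulekit_sources=", paste(names(paths),
                                               collapse = ",")),
            "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Supporting input sources\">",
            "##INFO=<ID=NCALLERS,Number=1,Type=Integer,Description=\"Number of supporting input sources\">")
  new_vcf(meta = meta, samples = sample_name, records = merged)
}

.merge_record_pool <- function(records) {
  if (!length(records)) return(list())
  keys <- vapply(records, merge_key, character(1L))
  sources <- vapply(records, `[[`, character(1L), "source")
  prio <- caller_priority(unique(sources))
  groups <- split(seq_along(records), keys)
  lapply(unname(groups), function(idx) {
    idx <- idx[order(match(sources[idx], prio))]
    merge_records(records[idx])
  })
}

.stamp_provenance <- function(r) {
  supp <- attr(r, "supporters")
  tags <- c(CALLERS = paste(supp, collapse = ","),
            NCALLERS = as.character(length(supp)))
  r$info <- c(tags, r$info[setdiff(names(r$info), names(tags))])
  r
}

#' Supporter labels of a merged record
#' @param record A merged `variant_record`.
#' @return Character vector of source labels.
#' @export
record_supporters <- function(record) {
  supp <- attr(record, "supporters")
  if (!is.null(supp)) return(supp)
  if ("CALLERS" %in% names(record$info))
    return(strsplit(record$info[["CALLERS"]], ",", fixed = TRUE)[[1L]])
  stop("record carries no supporter information")
}

#' Extract an M-out-of-N consensus call set
#'
#' Keeps exactly the merged records supported by at least `m` of the input
#' sources. Outputs are nested: the (m+1)-consensus is a subset of the
#' m-consensus.
#'
#' @param merged A merged `mule_vcf` from [merge_vcfs()] (or read back from
#'   disk; the provenance INFO tags suffice).
#' @param m Minimum number of supporting input files, `1 <= m <= n_sources`.
#' @return A `mule_vcf` with the consensus subset.
#' @export
extract_consensus <- function(merged, m) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be a positive integer")
  n_sources <- .n_sources(merged)
  if (!is.na(n_sources) && m > n_sources)
    stop("m = ", m, " exceeds the number of input sources (", n_sources, ")")
  keep <- vapply(merged$records,
                 function(r) length(record_supporters(r)) >= m, logical(1L))
  merged$records <- merged$records[keep]
  merged
}

.n_sources <- function(vcf) {
  line <- grep("^##mulekit_n_sources=", vcf$meta, value = TRUE)
  if (length(line)) as.integer(sub("^##mulekit_n_sources=", "", line[1L]))
  else NA_integer_
}

#' Merge multi-sample caller VCFs: split, merge per sample, recombine
#'
#' Each caller's multi-sample VCF is split into single-sample call sets (a
#' sample's call set contains the records where its genotype is non-missing),
#' each sample is merged across callers independently, and the per-sample
#' results are recombined into one multi-sample VCF over the union of loci.
#' A sample without a call at a locus gets a missing genotype.
#'
#' @param paths Named vector/list of multi-sample VCF paths (names = source
#'   labels), or named list of `mule_vcf` objects.
#' @param genome A `ref_genome` or FASTA path.
#' @return A multi-sample merged `mule_vcf` with provenance tags.
#' @export
split_and_recombine <- function(paths, genome) {
  if (is.character(genome)) genome <- read_genome(genome)
  vcfs <- lapply(paths, function(x)
    if (inherits(x, "mule_vcf")) x else read_vcf(x))
  sample_sets <- lapply(vcfs, `[[`, "samples")
  all_samples <- Reduce(union, sample_sets)
  common <- Reduce(intersect, sample_sets)
  if (!length(common)) stop("no samples shared across inputs")
  if (!all(vapply(sample_sets, function(s) setequal(s, all_samples),
                  logical(1L)))) {
    missing <- lapply(sample_sets, function(s) setdiff(all_samples, s))
    bad <- which(lengths(missing) > 0L)[1L]
    stop("sample(s) ", paste(missing[[bad]], collapse = ", "),
         " absent from input '", names(paths)[bad], "'")
  }
  samples <- sample_sets[[1L]]

  per_sample <- lapply(samples, function(s) {
    singles <- lapply(vcfs, .split_sample, sample = s)
    names(singles) <- names(paths)
    merge_vcfs(singles, genome)
  })
  names(per_sample) <- samples

  # union of keys across samples; recombine genotypes
  key_map <- new.env(parent = emptyenv())
  for (s in samples) {
    for (r in per_sample[[s]]$records) {
      k <- merge_key(r)
      ent <- key_map[[k]]
      if (is.null(ent)) ent <- list()
      ent[[s]] <- r
      key_map[[k]] <- ent
    }
  }
  prio <- caller_priority(names(paths))
  combined <- lapply(ls(key_map), function(k) {
    ent <- key_map[[k]]
    # order per-sample records by priority of their top supporter
    top <- vapply(ent, function(r) record_supporters(r)[1L], character(1L))
    ent <- ent[order(match(top, prio))]
    base <- ent[[1L]]
    pooled <- unique(unlist(lapply(ent, `[[`, "alts")))
    supp <- unique(unlist(lapply(ent, record_supporters)))
    gts <- lapply(samples, function(s) {
      r <- ent[[s]]
      if (is.null(r)) return(genotype_call(NULL))
      g <- r$genotypes[[s]]
      if (is.null(g) || gt_is_missing(g)) return(genotype_call(NULL))
      remap <- match(r$alts, pooled)
      g$alleles <- ifelse(g$alleles == 0L, 0L, remap[g$alleles])
      g
    })
    names(gts) <- samples
    out <- base
    out$alts <- pooled
    out$genotypes <- gts
    out$filters <- if (any(vapply(ent, is_unfiltered, logical(1L)))) "PASS"
                   else unique(unlist(lapply(ent, `[[`, "filters")))
    attr(out, "supporters") <- supp
    out
  })
  combined <- sort_records(combined, genome$index)
  combined <- lapply(combined, .stamp_provenance)
  meta <- c("##fileformat=VCFv4.2",
            paste0("##mulekit_n_sources=", length(paths)),
            paste0("##mulekit_sources=", paste(names(paths),
                                               collapse = ",")),
            "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Supporting input sources\">",
            "##INFO=<ID=NCALLERS,Number=1,Type=Integer,Description=\"Number of supporting input sources\">")
  new_vcf(meta = meta, samples = samples, records = combined)
}

.split_sample <- function(vcf, sample) {
  if (!sample %in% vcf$samples)
    stop("sample '", sample, "' not in VCF")
  keep <- vapply(vcf$records, function(r) {
    g <- r$genotypes[[sample]]
    !is.null(g) && !gt_is_missing(g)
  }, logical(1L))
  recs <- lapply(vcf$records[keep], function(r) {
    r$genotypes <- r$genotypes[sample]
    r
  })
  new_vcf(meta = vcf$meta, samples = sample, records = recs)
}
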