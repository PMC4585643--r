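#' Dynamic bin size for parallel variant calling
#'
#' The genome (or target region set) is split into equally sized bins, one
#' chunk of work per process per rotation. The bin size adapts to the total
#' number of base pairs and the process count, bounded below (to amortize
#' per-bin overhead) and above (to keep intervals fine-grained):
#' `clamp(ceil(total_bp / n_processes), min_bp, max_bp)`, with default
#' bounds 50 Kbp and 1 Mbp.
#'
#' @param total_bp Total base pairs to cover, >= 1.
#' @param n_processes Number of worker processes, >= 1.
#' @param min_bp,max_bp Bin size bounds in bp.
#' @return Integer bin size in `[min_bp, max_bp]`.
#' @export
compute_bin_size <- function(total_bp, n_processes, min_bp = 50000L,
                             max_bp = 1000000L) {
  if (total_bp < 1 || n_processes < 1)
    stop("total_bp and n_processes must be positive")
  if (min_bp < 1 || max_bp < min_bp)
    stop("invalid bin size bounds")
  size <- ceiling(total_bp / n_processes)
  as.integer(min(max(size, min_bp), max_bp))
}

#' Chop regions into equally sized bins
#'
#' Each region is walked left to right and cut into bins of exactly
#' `bin_size` bp; the terminal bin of a region may be shorter. Bins never
#' cross region (hence chromosome) boundaries, and their union reproduces
#' the input regions base-for-base. `global_index` ranks bins in genome
#' order (0-based).
#'
#' @param regions Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), sorted and non-overlapping; or a [genome_index()] to bin
#'   whole chromosomes.
#' @param bin_size Bin size in bp.
#' @return Data.frame of class `bin_set`: `chrom`, `start`, `end`,
#'   `global_index` (and `process` once assigned).
#' @export
generate_bins <- function(regions, bin_size) {
  if (inherits(regions, "genome_index"))
    regions <- data.frame(chrom = regions$name, start = 0L,
                          end = regions$length, stringsAsFactors = FALSE)
  if (bin_size < 1L) stop("bin_size must be positive")
  if (nrow(regions)) {
    if (any(regions$end <= regions$start)) stop("empty or inverted region")
    o <- order(regions$chrom, regions$start)
    for (ch in unique(regions$chrom)) {
      rr <- regions[regions$chrom == ch, , drop = FALSE]
      rr <- rr[order(rr$start), , drop = FALSE]
      if (nrow(rr) > 1L && any(rr$start[-1L] < rr$end[-nrow(rr)]))
        stop("overlapping regions on ", ch)
    }
  }
  pieces <- lapply(seq_len(nrow(regions)), function(i) {
    s <- regions$start[i]; e <- regions$end[i]
    starts <- seq.int(s, e - 1L, by = bin_size)
    ends <- pmin(starts + bin_size, e)
    data.frame(chrom = regions$chrom[i], start = as.integer(starts),
               end = as.integer(ends), stringsAsFactors = FALSE)
  })
  bins <- if (length(pieces)) do.call(rbind, pieces)
          else data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  bins$global_index <- seq_len(nrow(bins)) - 1L
  class(bins) <- c("bin_set", "data.frame")
  bins
}

#' Assign bins to processes by rotation
#'
#' Process of a bin = `global_index mod n_processes`. With two or more
#' processes no two consecutive bins share a process, spreading
#' uneven-coverage hotspots across workers; per-process total bp differs by
#' at most one bin.
#'
#' @param bins A `bin_set` from [generate_bins()].
#' @param n_processes Number of processes, >= 1.
#' @return The `bin_set` with a `process` column in `[0, n_processes)`.
#' @export
assign_bins <- function(bins, n_processes) {
  if (n_processes < 1L) stop("n_processes must be >= 1")
  bins$process <- bins$global_index %% as.integer(n_processes)
  attr(bins, "n_processes") <- as.integer(n_processes)
  bins
}

#' Write per-process BED files
#'
#' File `prefix.i.bed` receives exactly the bins of process `i` (0-based
#' half-open, genome-sorted). The concatenation of all files covers the
#' input regions exactly once.
#'
#' @param bins An assigned `bin_set` (from [assign_bins()]).
#' @param n_processes Number of processes (files written even if empty).
#' @param out_prefix Path prefix for the BED files.
#' @return Character vector of the file paths, invisibly.
#' @export
write_bin_beds <- function(bins, n_processes, out_prefix) {
  if (is.null(bins$process)) stop("bins must be assigned first")
  paths <- character(n_processes)
  for (p in seq_len(n_processes) - 1L) {
    paths[p + 1L] <- paste0(out_prefix, ".", p, ".bed")
    write_bed(bins[bins$process == p, , drop = FALSE], paths[p + 1L])
  }
  invisible(paths)
}

#' Count VCF records falling in a set of bins
#'
#' Scatter/gather helper: the per-bin record counts summed over all
#' processes equal the whole-region count.
#'
#' @param records List of `variant_record`s.
#' @param bins Data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return Integer count of records whose position falls in any bin.
#' @export
count_records_in_bins <- function(records, bins) {
  if (!length(records) || !nrow(bins)) return(0L)
  chroms <- vapply(records, `[[`, character(1L), "chrom")
  pos0 <- vapply(records, `[[`, integer(1L), "pos") - 1L
  n <- 0L
  for (i in seq_len(nrow(bins))) {
    n <- n + sum(chroms == bins$chrom[i] & pos0 >= bins$start[i] &
                   pos0 < bins$end[i])
  }
  as.integer(n)
}
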