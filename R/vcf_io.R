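#' Construct a genotype call
#'
#' A genotype call is one sample's genotype at one locus: a pair of allele
#' indices (0 = reference, 1..k = alternate alleles), a phasing flag, and
#' optional genotype quality (GQ) and read depth (DP). A missing genotype
#' carries no allele indices.
#'
#' @param alleles Integer vector of length 2 (allele indices), or `NULL` for a
#'   missing genotype.
#' @param phased Logical; was the genotype phased (`|` separator)?
#' @param gq Integer genotype quality, or `NA`.
#' @param dp Integer read depth, or `NA`.
#' @return An object of class `genotype_call`.
#' @export
genotype_call <- function(alleles = NULL, phased = FALSE, gq = NA_integer_,
                          dp = NA_integer_) {
  if (!is.null(alleles)) {
    alleles <- as.integer(alleles)
    if (length(alleles) != 2L || anyNA(alleles) || any(alleles < 0L))
      stop("genotype alleles must be two non-negative integers or NULL")
  }
  structure(list(alleles = alleles, phased = isTRUE(phased),
                 gq = as.integer(gq)[1L], dp = as.integer(dp)[1L]),
            class = "genotype_call")
}

#' Is a genotype call missing?
#' @param g A `genotype_call`.
#' @return Logical.
#' @export
gt_is_missing <- function(g) is.null(g$alleles)

#' Construct a variant record
#'
#' One VCF data line in the toolkit's data model: locus, alleles, quality,
#' filter status, INFO map and per-sample genotype calls, plus a `source`
#' label recording which file or caller the record came from.
#'
#' `filters` follows VCF semantics: `NA` for the missing value `.`, the single
#' token `"PASS"`, or a character vector of filter names.
#'
#' @param chrom Sequence name.
#' @param pos 1-based position (integer, >= 1).
#' @param ids Character vector of identifiers (empty for `.`).
#' @param ref Reference allele: non-empty string over A,C,G,T,N.
#' @param alts Character vector of alternate alleles (non-empty, no
#'   duplicates, none equal to `ref`).
#' @param qual Non-negative numeric quality or `NA`.
#' @param filters `NA`, `"PASS"`, or filter names.
#' @param info Named character vector (ordered); flag keys carry `NA` values.
#' @param genotypes Named list of [genotype_call()] objects, one per sample.
#' @param source Label of the originating file/caller.
#' @return An object of class `variant_record`.
#' @export
variant_record <- function(chrom, pos, ids = character(), ref, alts,
                           qual = NA_real_, filters = NA_character_,
                           info = character(), genotypes = list(),
                           source = NA_character_) {
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("pos must be an integer >= 1")
  if (!nzchar(ref)) stop("ref allele must be non-empty")
  .check_allele(ref, chrom, pos)
  if (length(alts) < 1L) stop("at least one alt allele required")
  for (a in alts) .check_allele(a, chrom, pos)
  if (anyDuplicated(alts)) stop("duplicate alt alleles at ", chrom, ":", pos)
  if (any(alts == ref)) stop("alt equals ref at ", chrom, ":", pos)
  qual <- as.numeric(qual)[1L]
  if (!is.na(qual) && qual < 0) stop("qual must be non-negative")
  for (g in genotypes) {
    if (!gt_is_missing(g) && any(g$alleles > length(alts)))
      stop("genotype allele index out of range at ", chrom, ":", pos)
  }
  structure(list(chrom = as.character(chrom), pos = pos,
                 ids = as.character(ids), ref = toupper(ref),
                 alts = toupper(as.character(alts)), qual = qual,
                 filters = filters, info = info, genotypes = genotypes,
                 source = source),
            class = "variant_record")
}

.check_allele <- function(a, chrom, pos) {
  if (!nzchar(a)) stop("empty allele at ", chrom, ":", pos)
  if (grepl("^<.*>$", a) || grepl("[][]", a))
    stop("symbolic/breakend alt alleles are not supported (", a, " at ",
         chrom, ":", pos, ")")
  if (grepl("[^ACGTNacgtn]", a))
    stop("allele contains non-ACGTN characters (", a, " at ", chrom, ":",
         pos, ")")
  invisible(TRUE)
}

#' Classify a record as SNV or non-SNV
#'
#' A record is an SNV when the reference allele and every alternate allele
#' are single bases. All merging, concordance and summary paths split
#' variants along this line.
#'
#' @param record A `variant_record`.
#' @return Logical.
#' @export
is_snv <- function(record) {
  nchar(record$ref) == 1L && all(nchar(record$alts) == 1L)
}

#' Is a record unfiltered (PASS or missing FILTER)?
#' @param record A `variant_record`.
#' @return Logical.
#' @export
is_unfiltered <- function(record) {
  f <- record$filters
  length(f) == 0L || all(is.na(f)) || identical(f, "PASS")
}

# ---------------------------------------------------------------------------
# VCF container

#' Construct a VCF container in memory
#'
#' @param meta Character vector of `##` header lines.
#' @param samples Character vector of sample names.
#' @param records List of [variant_record()]s.
#' @return A `mule_vcf` object.
#' @export
new_vcf <- function(meta = character(), samples = character(),
                    records = list()) {
  structure(list(meta = meta, samples = samples, records = records),
            class = "mule_vcf")
}

#' @export
print.mule_vcf <- function(x, ...) {
  cat("VCF:", length(x$records), "records,", length(x$samples), "sample(s)")
  if (length(x$samples)) cat(" [", paste(x$samples, collapse = ", "), "]",
                             sep = "")
  cat("\n")
  invisible(x)
}

#' Read a VCF file
#'
#' Parses a VCF 4.1/4.2 text file (plain or gzip) into a `mule_vcf` object
#' holding the header metadata, sample names, and one [variant_record()] per
#' data line, in file order. Multiallelic lines are kept as single records.
#'
#' Haploid genotypes (e.g. `1`) are promoted to homozygous diploid (`1/1`)
#' with a warning; ploidy above 2 is an error. Symbolic alternate alleles
#' (`<DEL>`, breakends) are rejected. Malformed data lines raise an error
#' naming the line number.
#'
#' @param path Path to the VCF file.
#' @param source Source label attached to every record; defaults to the file
#'   base name without extensions.
#' @return A `mule_vcf` object: list with `meta` (header `##` lines),
#'   `samples`, and `records`.
#' @export
read_vcf <- function(path, source = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(source)) source <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  is_meta <- startsWith(lines, "##")
  header_i <- which(startsWith(lines, "#CHROM"))
  if (length(header_i) != 1L) stop("missing #CHROM header line in ", path)
  header <- strsplit(lines[header_i], "\t", fixed = TRUE)[[1L]]
  samples <- if (length(header) > 9L) header[-(1:9)] else character()
  data_i <- which(!is_meta & !startsWith(lines, "#") & nzchar(lines))
  records <- vector("list", length(data_i))
  for (k in seq_along(data_i)) {
    i <- data_i[k]
    records[[k]] <- tryCatch(
      .parse_vcf_line(lines[i], samples, source),
      error = function(e) stop("VCF parse error at line ", i, " of ", path,
                               ": ", conditionMessage(e), call. = FALSE))
  }
  new_vcf(meta = lines[is_meta], samples = samples, records = records)
}

.parse_vcf_line <- function(line, samples, source) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  need <- if (length(samples)) 9L + length(samples) else 8L
  if (length(f) < need)
    stop("expected ", need, " columns, found ", length(f))
  if (f[4L] == "." || !nzchar(f[4L])) stop("missing REF allele")
  if (f[5L] == "." || !nzchar(f[5L])) stop("missing ALT allele")
  alts <- strsplit(f[5L], ",", fixed = TRUE)[[1L]]
  qual <- if (f[6L] == ".") NA_real_ else suppressWarnings(as.numeric(f[6L]))
  if (f[6L] != "." && is.na(qual)) stop("unparseable QUAL '", f[6L], "'")
  filters <- if (f[7L] == ".") NA_character_
             else strsplit(f[7L], ";", fixed = TRUE)[[1L]]
  info <- .parse_info(f[8L])
  genotypes <- list()
  if (length(samples)) {
    fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
    genotypes <- lapply(f[10:(9L + length(samples))], .parse_gt, fmt = fmt,
                        n_alts = length(alts))
    names(genotypes) <- samples
  }
  ids <- if (f[3L] == ".") character() else
    strsplit(f[3L], ";", fixed = TRUE)[[1L]]
  variant_record(chrom = f[1L], pos = f[2L], ids = ids, ref = f[4L],
                 alts = alts, qual = qual, filters = filters, info = info,
                 genotypes = genotypes, source = source)
}

.parse_info <- function(s) {
  if (s == "." || !nzchar(s)) return(character())
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  eq <- regexpr("=", parts, fixed = TRUE)
  keys <- ifelse(eq > 0L, substr(parts, 1L, eq - 1L), parts)
  vals <- ifelse(eq > 0L, substr(parts, eq + 1L, nchar(parts)), NA_character_)
  names(vals) <- keys
  vals
}

.parse_gt <- function(s, fmt, n_alts) {
  vals <- strsplit(s, ":", fixed = TRUE)[[1L]]
  names(vals) <- fmt[seq_along(vals)]
  gt <- vals[["GT"]]
  if (is.null(gt)) stop("sample field without GT")
  getnum <- function(key) {
    v <- if (key %in% names(vals)) vals[[key]] else NA_character_
    if (is.na(v) || v == ".") NA_integer_ else suppressWarnings(as.integer(v))
  }
  phased <- grepl("|", gt, fixed = TRUE)
  idx <- strsplit(gt, "[/|]")[[1L]]
  if (all(idx == ".")) {
    return(genotype_call(NULL, phased, getnum("GQ"), getnum("DP")))
  }
  if (any(idx == ".")) {
    # partially missing genotype treated as missing
    return(genotype_call(NULL, phased, getnum("GQ"), getnum("DP")))
  }
  a <- suppressWarnings(as.integer(idx))
  if (anyNA(a)) stop("unparseable GT '", gt, "'")
  if (length(a) == 1L) {
    warning("haploid genotype '", gt, "' promoted to homozygous diploid",
            call. = FALSE)
    a <- c(a, a)
  }
  if (length(a) != 2L) stop("unsupported ploidy ", length(a), " in GT '",
                            gt, "'")
  if (any(a > n_alts)) stop("GT allele index ", max(a),
                            " exceeds number of alt alleles (", n_alts, ")")
  genotype_call(a, phased, getnum("GQ"), getnum("DP"))
}

# ---------------------------------------------------------------------------
# Writing

.format_info <- function(info) {
  if (length(info) == 0L) return(".")
  paste(ifelse(is.na(info), names(info),
               paste0(names(info), "=", info)), collapse = ";")
}

.format_gt <- function(g, with_gq, with_dp) {
  sep <- if (g$phased) "|" else "/"
  s <- if (gt_is_missing(g)) paste(".", ".", sep = sep)
       else paste(g$alleles[1L], g$alleles[2L], sep = sep)
  if (with_gq) s <- paste0(s, ":", ifelse(is.na(g$gq), ".", g$gq))
  if (with_dp) s <- paste0(s, ":", ifelse(is.na(g$dp), ".", g$dp))
  s
}

.format_record <- function(r, samples) {
  filt <- if (length(r$filters) == 0L || all(is.na(r$filters))) "."
          else paste(r$filters, collapse = ";")
  qual <- if (is.na(r$qual)) "." else
    format(r$qual, scientific = FALSE, trim = TRUE)
  cols <- c(r$chrom, r$pos,
            if (length(r$ids)) paste(r$ids, collapse = ";") else ".",
            r$ref, paste(r$alts, collapse = ","), qual, filt,
            .format_info(r$info))
  if (length(samples)) {
    gts <- r$genotypes[samples]
    miss <- vapply(gts, is.null, logical(1L))
    gts[miss] <- list(genotype_call(NULL))
    with_gq <- any(vapply(gts, function(g) !is.na(g$gq), logical(1L)))
    with_dp <- any(vapply(gts, function(g) !is.na(g$dp), logical(1L)))
    fmt <- paste(c("GT", if (with_gq) "GQ", if (with_dp) "DP"),
                 collapse = ":")
    cols <- c(cols, fmt,
              vapply(gts, .format_gt, character(1L), with_gq, with_dp))
  }
  paste(cols, collapse = "\t")
}

#' Write a VCF file
#'
#' Serializes a `mule_vcf` object back to VCF text. Records must be sorted:
#' grouped by chromosome (in the order given by `genome`, or first appearance)
#' with non-decreasing positions within each chromosome; unsorted input is an
#' error naming the first out-of-order pair. Reading the file back reproduces
#' the records field-for-field on the modeled fields.
#'
#' @param vcf A `mule_vcf` object.
#' @param path Output path.
#' @param genome Optional [genome_index()] providing chromosome order.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vcf, path, genome = NULL) {
  .check_sorted(vcf$records, genome)
  meta <- vcf$meta
  if (!length(meta)) meta <- "##fileformat=VCFv4.2"
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO",
                    if (length(vcf$samples)) c("FORMAT", vcf$samples)),
                  collapse = "\t")
  lines <- vapply(vcf$records, .format_record, character(1L),
                  samples = vcf$samples)
  writeLines(c(meta, header, lines), path)
  invisible(path)
}

.chrom_rank <- function(chroms, genome) {
  u <- unique(chroms)
  if (!is.null(genome)) {
    r <- match(chroms, genome$name)
    if (anyNA(r)) stop("chromosome(s) absent from genome index: ",
                       paste(unique(chroms[is.na(r)]), collapse = ", "))
    return(r)
  }
  match(chroms, u)
}

.check_sorted <- function(records, genome = NULL) {
  if (length(records) < 2L) return(invisible(TRUE))
  chroms <- vapply(records, `[[`, character(1L), "chrom")
  pos <- vapply(records, `[[`, integer(1L), "pos")
  r <- .chrom_rank(chroms, genome)
  key <- r * 2^32 + pos
  bad <- which(diff(key) < 0)
  if (length(bad)) {
    i <- bad[1L]
    stop("records out of order: ", chroms[i], ":", pos[i], " precedes ",
         chroms[i + 1L], ":", pos[i + 1L])
  }
  invisible(TRUE)
}

#' Sort variant records in genome order
#'
#' @param records List of `variant_record`s.
#' @param genome Optional [genome_index()] giving chromosome order; defaults
#'   to order of first appearance.
#' @return Sorted list.
#' @export
sort_records <- function(records, genome = NULL) {
  if (length(records) < 2L) return(records)
  chroms <- vapply(records, `[[`, character(1L), "chrom")
  pos <- vapply(records, `[[`, integer(1L), "pos")
  records[order(.chrom_rank(chroms, genome), pos)]
}

# ---------------------------------------------------------------------------
# Reference genome and index

#' Read or build a genome index
#'
#' Parses a samtools-style `.fai` index into the toolkit's coordinate
#' authority: an ordered table of sequence names and lengths.
#'
#' @param path Path to a `.fai` file (or a FASTA whose `.fai` sits alongside).
#' @return A data.frame of class `genome_index` with columns `name`, `length`.
#' @export
genome_index <- function(path) {
  fai <- if (grepl("\\.fai$", path)) path else paste0(path, ".fai")
  if (!file.exists(fai)) stop("no .fai index at ", fai)
  tab <- utils::read.table(fai, sep = "\t", stringsAsFactors = FALSE)
  gi <- data.frame(name = as.character(tab[[1L]]),
                   length = as.integer(tab[[2L]]),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(gi$name)) stop("duplicate sequence names in ", fai)
  if (any(gi$length < 1L)) stop("non-positive sequence length in ", fai)
  class(gi) <- c("genome_index", "data.frame")
  gi
}

#' Load an indexed reference genome
#'
#' Reads a plain-text FASTA (indexing it with [Rsamtools::indexFa()] if no
#' `.fai` is present) and returns an object supporting [fetch_reference()].
#'
#' @param fasta Path to the FASTA file.
#' @return An object of class `ref_genome` with elements `seq`
#'   (a `DNAStringSet`) and `index` (a [genome_index()]).
#' @export
read_genome <- function(fasta) {
  if (!file.exists(fasta)) stop("no such file: ", fasta)
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  structure(list(seq = seqs, index = genome_index(fasta), path = fasta),
            class = "ref_genome")
}

#' Fetch a reference subsequence
#'
#' @param genome A `ref_genome` from [read_genome()].
#' @param chrom Sequence name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return Uppercase string of length `end - start + 1`.
#' @export
fetch_reference <- function(genome, chrom, start, end) {
  i <- match(chrom, genome$index$name)
  if (is.na(i)) stop("chromosome '", chrom, "' absent from genome index")
  len <- genome$index$length[i]
  if (start < 1L || end > len || start > end)
    stop("coordinates [", start, ",", end, "] out of bounds for ", chrom,
         " (length ", len, ")")
  toupper(as.character(Biostrings::subseq(genome$seq[[chrom]], start, end)))
}

# ---------------------------------------------------------------------------
# BED

#' Write intervals as BED (0-based half-open)
#' @param df Data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  if (nrow(df) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  utils::write.table(df[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 3+ column BED file (0-based half-open)
#' @param path BED path.
#' @return Data.frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = as.character(tab[[1L]]), start = as.integer(tab[[2L]]),
             end = as.integer(tab[[3L]]), stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# PLINK PED/MAP export

#' Export a trio VCF to PLINK PED/MAP
#'
#' Writes one MAP row per locus (`chrom`, locus id, 0, `pos`) and one PED row
#' per trio member with the six pedigree columns followed by two allele
#' columns per locus (allele bases; missing genotypes encoded `0 0`).
#'
#' @param records List of multi-sample `variant_record`s.
#' @param trio Named character vector with elements `father`, `mother`,
#'   `child`.
#' @param ped_path,map_path Output paths.
#' @param family Family identifier for the PED file.
#' @return Invisible list with the two paths.
#' @export
write_ped_map <- function(records, trio, ped_path, map_path,
                          family = "FAM1") {
  trio <- .check_trio(trio)
  for (r in records) {
    absent <- setdiff(unname(trio), names(r$genotypes))
    if (length(absent))
      stop("sample(s) ", paste(absent, collapse = ", "),
           " absent at ", r$chrom, ":", r$pos)
  }
  map <- vapply(records, function(r) {
    id <- if (length(r$ids)) r$ids[1L] else paste0(r$chrom, ":", r$pos)
    paste(r$chrom, id, 0L, r$pos, sep = "\t")
  }, character(1L))
  writeLines(map, map_path)

  allele_base <- function(r, idx) if (idx == 0L) r$ref else r$alts[idx]
  roles <- c(father = 1L, mother = 2L, child = 1L)  # sex codes (child unknown)
  ped <- character(3L)
  members <- c("father", "mother", "child")
  for (k in seq_along(members)) {
    m <- members[k]
    sid <- trio[[m]]
    pedcols <- c(family, sid,
                 if (m == "child") trio[["father"]] else "0",
                 if (m == "child") trio[["mother"]] else "0",
                 if (m == "father") "1" else if (m == "mother") "2" else "0",
                 "-9")
    gcols <- unlist(lapply(records, function(r) {
      g <- r$genotypes[[sid]]
      if (gt_is_missing(g)) c("0", "0")
      else c(allele_base(r, g$alleles[1L]), allele_base(r, g$alleles[2L]))
    }))
    ped[k] <- paste(c(pedcols, gcols), collapse = "\t")
  }
  writeLines(ped, ped_path)
  invisible(list(ped = ped_path, map = map_path))
}

.check_trio <- function(trio) {
  need <- c("father", "mother", "child")
  if (!all(need %in% names(trio)))
    stop("trio must name father, mother and child samples")
  trio[need]
}
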