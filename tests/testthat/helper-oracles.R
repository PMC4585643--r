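# Independent brute-force oracles used to cross-check the implementation.

# --- Mendelian classification oracle --------------------------------------
# Enumerates every transmission (one allele from each parent) and every
# assignment of the child's two alleles to the paternal/maternal slots,
# counts mismatched slots, and classifies each mismatched child allele by
# parent presence. Returns the set of optimal (adi, ado) pairs.
mendel_oracle <- function(f, m, c_) {
  results <- list()
  for (fi in f) for (mi in m) {
    for (perm in list(c(1L, 2L), c(2L, 1L))) {
      slot <- c(fi, mi)              # transmitted alleles
      kid <- c_[perm]                # child alleles assigned to slots
      mism <- which(slot != kid)
      adi <- sum(!(kid[mism] %in% c(f, m)))
      ado <- length(mism) - adi
      results[[length(results) + 1L]] <- c(err = length(mism),
                                           adi = adi, ado = ado)
    }
  }
  tab <- do.call(rbind, results)
  best <- tab[tab[, "err"] == min(tab[, "err"]), , drop = FALSE]
  unique(best[, c("adi", "ado"), drop = FALSE])
}

# --- normalization oracles -------------------------------------------------
# Apply a biallelic record to its chromosome sequence -> mutated haplotype.
apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1L, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

# Enumerate all representations (p, ref', alt') within a window that yield
# the same mutated haplotype; return the minimal-length, leftmost one.
minimal_rep_oracle <- function(seq, pos, ref, alt, window = 12L) {
  mutated <- apply_variant(seq, pos, ref, alt)
  n_s <- nchar(seq); n_m <- nchar(mutated)
  best <- NULL
  for (p in max(1L, pos - window):min(n_s, pos + window)) {
    for (lr in 1L:(window + 2L)) {
      if (p + lr - 1L > n_s) break
      cref <- substr(seq, p, p + lr - 1L)
      la <- lr + (n_m - n_s)
      if (la < 1L) next
      calt <- substr(mutated, p, p + la - 1L)
      if (cref == calt) next
      if (apply_variant(seq, p, cref, calt) != mutated) next
      cand <- list(pos = p, ref = cref, alt = calt, size = lr + la)
      if (is.null(best) || cand$size < best$size ||
          (cand$size == best$size && cand$pos < best$pos))
        best <- cand
    }
  }
  best
}

# --- consensus membership oracle -------------------------------------------
# Brute-force m-of-n call sets from per-source key vectors.
consensus_oracle <- function(key_sets, m) {
  keys <- unique(unlist(key_sets))
  support <- vapply(keys, function(k)
    sum(vapply(key_sets, function(s) k %in% s, logical(1L))), integer(1L))
  sort(keys[support >= m])
}

# --- single-linkage clustering oracle --------------------------------------
# Pairwise overlap graph + BFS connected components.
cluster_oracle <- function(intervals) {
  n <- nrow(intervals)
  if (n == 0L) return(integer(0))
  adj <- lapply(seq_len(n), function(i) {
    ov <- intervals$chrom == intervals$chrom[i] &
      intervals$start <= intervals$end[i] &
      intervals$start[i] <= intervals$end
    which(ov)
  })
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  comp
}

# Venn region counts implied by a truth membership matrix plus per-caller
# private false positives.
membership_region_counts <- function(membership, fp_keys) {
  labels <- colnames(membership)
  region <- apply(membership, 1L, function(row)
    paste(labels[row], collapse = "&"))
  region <- region[nzchar(region)]
  counts <- table(region)
  for (lab in labels) {
    k <- length(fp_keys[[lab]])
    if (k > 0L)
      counts[lab] <- (if (lab %in% names(counts)) counts[lab] else 0L) + k
  }
  counts
}
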