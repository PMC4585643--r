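---
title: "mulekit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mulekit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mulekit` implements the bespoke computational stages of a multi-caller
variant-calling workflow: representation normalization, consensus merging,
trio Mendelian error statistics, multi-set concordance, summary statistics,
and a cluster-free binning/scheduling core, together with the seeded
simulators used to validate them. This vignette records the methods, the
parameters that matter, and the design decisions taken where more than one
reasonable reading existed.

## Data model and conventions

A VCF data line becomes a `variant_record`: chromosome, 1-based position,
reference allele, an ordered deduplicated list of alternate alleles,
quality, filter status, an ordered INFO map, per-sample `genotype_call`s
and a `source` label naming the originating caller. A record is an **SNV**
when the reference and every alternate allele are single bases; everything
else (insertions, deletions, MNPs) is **non-SNV**. This binary split drives
every downstream rule.

Conventions worth stating explicitly:

* **Diploid-only statistics.** Haploid genotypes (`1`) are promoted to
  homozygous diploid (`1/1`) on read, with a warning; ploidy above two is
  an error. The trio statistics assume two alleles per individual, and we
  apply that assumption uniformly — including on sex chromosomes, where no
  special rule is defined (a documented limitation; see below).
* **Symbolic alleles** (`<DEL>`, breakends) are rejected outright: the
  normalization and merge rules operate on sequence alleles only, and
  silently passing symbolic records through would corrupt merges.
* **Filter semantics.** `FILTER` of `.` and `PASS` both mean *unfiltered*;
  any other value means filtered. This is the reading used by the PASS
  propagation rule in merging.
* **Coordinates.** VCF positions are 1-based; all BED output is 0-based
  half-open. Chromosome names are matched exactly — no silent `chr`
  aliasing, because aliasing corrupts merges undetectably.

VCF parsing is deliberately line-oriented and strict: a malformed data line
raises an error naming the line number, and the record count always equals
the number of data lines (nothing is dropped silently). The test suite
cross-checks the reader against `vcfR` on simulated files. FASTA access
goes through `Biostrings`/`Rsamtools`, with the `.fai` index as the
coordinate authority.

## Variant normalization

Different callers emit the same indel in different representations
(`TGGG>TGG` vs `TG>T` for a one-base G deletion in a G run). Before any
merging or concordance analysis, every record is rewritten to its
left-aligned minimal representation. The algorithm operates **jointly** on
the full allele set `{ref} ∪ alts` of a record:

1. while every allele ends in the same nucleotide, delete that nucleotide;
   if an allele becomes empty, prepend the reference base at `pos − 1` to
   all alleles and decrement `pos`;
2. while every allele begins with the same nucleotide and all alleles have
   length ≥ 2, delete that nucleotide and increment `pos`.

The output is idempotent and unique; the tests verify, by brute-force
enumeration of all equivalent representations in a window, that it is the
leftmost minimal representation, and that applying ref→alt to the
reference sequence yields the same mutated haplotype before and after.

Decisions:

* Multiallelic records are normalized **as a unit**, never split into
  biallelics — merging operates on whole records, so splitting would
  change the merge keys.
* `N` bases participate in trimming like any fixed base (the simplest
  consistent rule).
* Normalization runs on **all** inputs once, before any merging or
  concordance computation. For true SNVs it is a no-op, so including them
  costs nothing and removes an ordering question.
* A left-extension that would walk past position 1 is an error, not a
  silent truncation.

## Consensus merging

Overlap is defined per variant class: SNV records overlap when chromosome
and position agree; non-SNV records additionally require the same
reference allele. Records sharing a key are merged: chromosome, position
and reference come from the first record; alternate alleles are pooled in
priority-then-appearance order and deduplicated; quality and genotypes
(with GQ) come from the first record, with genotype indices remapped onto
the pooled alt list; `FILTER` becomes `PASS` iff at least one input record
was unfiltered, else the union of filter names.

"First" is defined by the fixed caller priority
GATK > SAMtools > FreeBayes > VarScan > SOAPsnp (unknown labels follow, in
given order): since inputs are sorted by priority before merging, the
highest-priority supporter is first **at every key**, not merely in the
first file globally. This makes the merged output invariant under
permutation of the input file order, which the tests check.

Each merged record carries `CALLERS`/`NCALLERS` INFO tags, so
*M*-out-of-*N* consensus extraction (`|supporters| ≥ m`) is re-runnable
from the merged file alone. Consensus membership is counted at the
**site** (merge-key) level, not per allele: a file "contains" a call if it
has any record with the same key. Multi-sample inputs are split into
per-sample call sets (a sample's call set holds the records where its
genotype is non-missing), merged per sample, and recombined over the union
of loci, with missing genotypes for samples without a call. The merged
output contains the normalized representation of each variant.

## Trio Mendelian error statistics

At a locus genotyped in all three members, consider the four possible
transmissions (one allele from each parent) and take the one minimizing
mismatches against the child's allele pair. The `k ∈ {0, 1, 2}` unmatched
child alleles are the Mendelian errors at that locus; each is classified
**ADI** (allele drop-in) if the allele occurs in neither parent's
genotype, else **ADO** (allele drop-out — an obligate transmission was
violated). The split is deterministic: an allele absent from both parents
is unmatched under *every* transmission, so ADI is simply the count of
parent-absent child alleles and ADO the remainder. One unmatched pair
counts as one error — never as both an ADI and an ADO — so the error total
equals the number of irreconcilable alleles, and a locus can contribute up
to two errors. The implementation is validated against an independent
enumeration of all transmissions and matchings, exhaustively over all 27
biallelic trio genotype combinations and on fuzzed multiallelic ones.

The error rate divides ADI + ADO by the number of **trio calls** — loci
with no missing genotype in any member; loci with any missing genotype are
excluded from every tally. Identity-by-state with each parent is the
multiset intersection size of the two allele pairs (0, 1 or 2),
accumulated as one histogram per parent (a per-parent tally was chosen
over a joint 3×3 table; the histograms are what the summary reports).

MAF stratification keeps records whose allele-frequency annotation (INFO
key, default `AF`) is at most the threshold (default 1%) **or absent** —
unannotated variants are treated as novel. Frequencies are never
recomputed; they are expected from an upstream annotation step.

## Concordance and Venn partitions

SNVs are compared exactly on (chrom, pos, ref, alt), one key per alternate
allele of a multiallelic record. Non-SNVs are first normalized, then
*intervalized*: the record reduces to its position point extended 10 bp
towards both ends, `[pos − 10, pos + 10]`, ignoring its alleles. Two
intervals overlap when they share a chromosome and their closed ranges
intersect; clusters are single-linkage connected components, and each
cluster contributes one unit to the Venn region of the source set present
in it. Cluster-level counting was chosen because interval overlap is not
transitive, so per-record counting would double-count chains; single
linkage keeps the partition deterministic. The sweep implementation is
checked against a brute-force overlap-graph/BFS oracle.

The point-based intervalization (rather than the span of the reference
allele ± 10 bp) was chosen as the simpler reading; it is isolated in
`nonsnv_intervals()` and would be a one-function swap. The concordance
rate is 100 × (all-sources region) / (sum of all regions) — the union is
the denominator.

## Binning and scheduling

The parallelization core splits the genome (or a BED of target regions)
into equally sized bins of
`clamp(ceil(total_bp / N), 50 Kbp, 1 Mbp)`. Only the bounds are fixed by
design; the `ceil(total/N)` interior was chosen so that small inputs give
one bin per process and large genomes saturate at the 1 Mbp maximum (the
fastest large-genome setting); both bounds are overridable. Bins never
cross region boundaries, the terminal bin of a region may be short, and
the union of bins reproduces the regions base-for-base. Assignment is by
rotation, `process = global_index mod N`, the minimal rule guaranteeing
that adjacent bins (which share coverage pathologies) never land on the
same process; it also balances per-process load to within one bin. The
correctness contract is scatter/gather equivalence: any per-region count
computed over the N per-process BEDs and summed equals the whole-region
answer, which the tests verify with simulated call sets.

Task graphs are ordered by Kahn's algorithm with lexicographic tie-breaks
(deterministic), and cycles are reported with the tasks involved. The
runner persists a line-oriented status file (`id TAB status TAB command`)
rewritten after every state change, so an interrupted run resumes by
skipping `finished` tasks and re-running interrupted ones; a corrupt or
mismatched status file is an error, never a silent restart. The executor
is an injected function; the shipped default runs shell commands locally
and sequentially (`max_parallel` caps how many tasks are claimed per
scheduling round so failures stop the run promptly). Cluster submission is
out of scope.

## Synthetic data: what it emulates, and what it does not

The simulators provide controlled ground truth:

* `simulate_reference` — uniform random A/C/G/T chromosomes with a `.fai`
  index; fully deterministic given the configuration (R's default RNG
  under `set.seed`).
* `simulate_callsets` — truth variants (SNVs and 1–10 bp indels, default
  80% SNVs) at spaced, distinct normalized positions; each caller carries
  each truth variant independently with its `sensitivity` (default 0.85 to
  0.95 across the four default callers), adds caller-private false
  positives, and with probability `jitter` (default 0.3) emits an indel in
  a padded, haplotype-equivalent representation — constructed as the exact
  inverse of normalization, which makes it double as the normalization
  test fixture. The membership log records which caller carries which
  truth variant and is the oracle for consensus and Venn counts.
* `simulate_trio` — random parental genotypes with Mendelian inheritance;
  per locus, an ADI event (default rate 1%) replaces a child allele with a
  third allele absent from both parents, an ADO event (default 1%)
  constructs a homozygous father and a child missing his obligate allele
  while both child alleles remain present in a parent — mirroring the
  ADI/ADO classification rule, so the log and the classifier must agree
  event-by-event. Genotypes are masked missing at 2% by default.

Variant loci are drawn on a 40 bp grid with a 30 bp margin so that
distinct variants never share a ±10 bp concordance interval even after
normalization shifts, keeping the membership log an exact oracle.

What the simulators do **not** model: read-level sequencing errors and
coverage (no FASTQ/BAM), base-composition bias, linkage between loci,
systematic (correlated) caller errors, and multi-nucleotide/complex
alleles. In particular, real callers err *dependently* — they share
alignment artifacts — so the binomial consensus-recovery check
(independent callers) validates the set machinery, not a claim about real
concordance rates. Passing tests demonstrate the algebra of the toolkit is
right; they do not by themselves predict performance on real sequencing
data.

## Problem sizes and numerical choices

The validation suite runs at deliberate scales: 1,000 jittered indels for
normalization round-trips; the exhaustive 27-combination Mendelian table;
20,000 trio loci at a 2% injected error rate (recovery within ±0.5
percentage points, ≈ 5 binomial standard errors; zero-injection runs must
give exactly zero errors); 20 random four-caller simulations checked
exactly against brute-force membership counting; 10,000 truth variants for
the 2-of-4 binomial recovery check (within 3 standard errors of
`Σ_{j≥2} C(4,j) 0.9^j 0.1^{4−j} ≈ 0.9963`); fuzzed region sets up to 3 Mbp
and DAGs up to 100 tasks; and an end-to-end command-line run on a
2-chromosome × 100 kb genome. `scripts/acceptance.R` recomputes all of
these from scratch with a caller-supplied seed.

Ties and degenerate inputs: empty VCFs round-trip to empty VCFs; an empty
union yields a missing concordance rate; a trio with zero trio calls
reports a missing error rate; `extract_consensus` rejects `m` above the
number of sources; unsorted records are rejected at write time naming the
first offending pair.

## Known limitations

* No bgzf/tabix random access or BCF; files are read whole. Fine for
  per-chromosome or exome-scale work, not for streaming a 30× WGS VCF.
* Sex chromosomes are treated as autosomal diploid in trio statistics;
  haploid calls are promoted with a warning. Users analysing chrX/chrY
  should interpret those loci accordingly.
* Consensus genotypes are taken from the highest-priority caller, not
  reconciled by vote; INFO fields other than the provenance tags are not
  unified.
* Venn rendering is left to plotting packages; the counts are the tested
  artifact.
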