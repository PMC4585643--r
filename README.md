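# mulekit

Variant calls from different callers disagree substantially, especially for
indels and for rare variants, and much of that disagreement is an artifact
of representation rather than biology. `mulekit` is an R toolkit for the
computational stages that sit *between* the callers and downstream analysis
in a multi-caller pipeline:

* **Indel normalization** — rewriting every variant to its left-aligned
  minimal representation so that equivalent calls (e.g. `TGGG>TGG` and
  `TG>T`, both a one-base G deletion) compare equal.
* **Consensus call sets** — merging per-caller VCFs at the record level
  (SNVs overlap on chromosome + position; non-SNVs on chromosome +
  position + reference allele), pooling alternate alleles, taking quality
  and genotypes from the highest-priority caller
  (GATK > SAMtools > FreeBayes > VarScan > SOAPsnp), propagating `PASS`
  when any input left the site unfiltered, and extracting *M*-out-of-*N*
  consensus subsets from the provenance tags.
* **Trio Mendelian error statistics** — allele drop-in (ADI: a child allele
  present in neither parent), allele drop-out (ADO: a violated obligate
  transmission), identity-by-state tallies against each parent, and the
  Mendelian error rate (ADI + ADO over the trio calls, i.e. loci not
  missing in any family member), with optional restriction to rare/novel
  variants (annotated MAF ≤ 1% or unannotated).
* **Concordance / Venn analysis** — partition counts over up to five call
  sets; SNVs matched exactly on chrom/pos/ref/alt, non-SNVs matched by
  single-linkage overlap of ±10 bp intervals around the normalized
  position.
* **Call-set statistics** — Ti/Tv ratio, het/hom-alt ratio, MAF filtering.
* **Cluster-free parallelization core** — splitting a genome or target
  region set into equally sized bins (size `clamp(ceil(total/N), 50 Kbp,
  1 Mbp)`), assigning bins to *N* processes by rotation so adjacent bins
  never share a process, writing per-process BED files, and running task
  dependency graphs in topological order with a resumable on-disk status
  file.
* **Synthetic data generators** — seeded reference genomes, multi-caller
  call sets with controlled sensitivity/false positives/representation
  jitter, and trio VCFs with logged ADI/ADO injections. The injection logs
  are the ground truth the test suite checks the statistics against.

## Worked example

```r
library(mulekit)

cfg <- sim_config(seed = 7, n_variants = 200)       # 2 chromosomes x 100 kb
genome  <- simulate_reference(cfg, "demo")
callset <- simulate_callsets(cfg, genome, "demo")   # gatk/samtools/freebayes/varscan

merged <- merge_vcfs(as.list(callset$caller_paths), genome)
merged
#> VCF: 260 records, 1 sample(s) [SAMPLE1]
length(extract_consensus(merged, 2)$records)
#> [1] 200

trio <- simulate_trio(cfg, genome, "demo")
trio_summary(trio$vcf, c(father = "FATHER", mother = "MOTHER", child = "CHILD"))
#> Trio Mendelian error summary
#>   trio calls (no missing genotype): 186
#>   allele drop-in (ADI):  3
#>   allele drop-out (ADO): 1
#>   Mendelian error rate:  0.0215 (2.15%)
#>   IBS with father (0/1/2): 1/88/97
#>   IBS with mother (0/1/2): 1/93/92
```

The merged set holds 260 records: the 200 truth variants plus 60
caller-private false positives; requiring support from at least 2 of the 4
callers removes every private call here. The trio summary counts only the
186 loci genotyped in all three members, and the 4 Mendelian errors match
the simulator's injection log (2.15% of trio calls at a 2% injection rate).

A command-line front end covering the same operations
(`simulate`, `normalize`, `merge`, `consensus`, `trio-stats`, `venn`,
`stats`, `bins`, `convert`) is installed at
`system.file("cli", "mulekit.R", package = "mulekit")`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","mulekit.R",package="mulekit"))') \
    merge --vcf gatk=g.vcf --vcf samtools=s.vcf --ref genome.fa --out merged.vcf
```

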