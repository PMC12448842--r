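# phasefilt

Consistency-based filtering of small variants for long-read phasing.

## The problem

Long nanopore reads span many heterozygous variant sites and are the raw
material of read-backed phasing. SNV calls from such data are excellent, but
INDEL calls are not: a substantial fraction are false positives, and feeding
them to a phaser (WhatsHap, Margin, HapCUT2, ...) lengthens phase blocks at
the cost of extra switch errors. Simple QUAL-threshold filtering buys
precision but discards many real, informative INDELs.

phasefilt filters variants by the signal phasing itself relies on. Tag each
read with a 0/1 allele at every het site it covers (REF = 0, ALT = 1). For a
pair of het sites co-covered by *N* reads, let *x* be the number of reads
with a discordant allele pattern (01 or 10) and *y* the concordant ones
(00 or 11), *x* + *y* = *N*. The pair's **consistency score** is

```
score = max(x, y) / (x + y)
```

Two true het variants sit on two haplotypes, so nearly all co-covering reads
agree on one orientation and the score approaches 1. A false call's alleles
are independent of haplotype, driving its scores toward 1/2. Sites whose
neighborhood consistency is poor are removed in three steps of increasing
stringency with thresholds `(p1, p2, p3) = (0.7, 0.8, 0.9)`:

1. remove sites with **no** neighbor pair score above `p1`;
2. recompute on the survivors, remove sites with **mean** score below `p2`;
3. recompute again, remove sites whose **best** pair score is still below `p3`.

Sites with no co-covering reads at all are judged by the VCF QUAL field
instead (kept iff QUAL ≥ 15 by default). Summaries are recomputed between
steps, so removing one bad site lets its neighbors' scores recover.

## Worked example

Everything below is simulated, truth-labeled data from the bundled
generator; no downloads needed.

```r
library(phasefilt)

# a diploid individual: 200 true het sites + 40 haplotype-independent false
# calls over 1 Mb, 30x of ~25 kb reads, 5% allele error
sim <- simulate_phasing(sim_config(seed = 101))
sim
#> phasing_sim: 240 sites ( 200 true / 40 fp / 0 fp_hom ), 1200 reads over 1000000 bp

vf <- filter_variants(sim$fm, filter_config(mode = "all_variants"))
vf
#> variant_filter: 240 VCF records, 240 het biallelic scored, 240 filterable (mode=all_variants)
#>   thresholds (p1, p2, p3) = (0.7, 0.8, 0.9), qual fallback >= 15
#>   decisions:
#>     kept                     186
#>     step1_max_le_p1          9
#>     step2_mean_lt_p2         44
#>     step3_max_lt_p3          1

precision_recall(vf, sim$truth)
#> filter_eval: tp=186 fp=0 fn=14  precision=1.0000 recall=0.9300 (n=240)
```

All 40 planted false sites are gone (precision 1.0, up from the unfiltered
200/240 ≈ 0.83) at the cost of 14 of 200 true sites. The downstream effect,
with the package's greedy reference phaser:

```r
truth_snv <- sim$sites$vcf_index[sim$truth$label == "true" & sim$sites$vtype == "SNV"]
indels    <- sim$sites$vcf_index[sim$sites$vtype == "INDEL"]
vfi       <- filter_variants(sim$fm, filter_config(mode = "indels_only"))
kept_ind  <- intersect(vfi$decisions$vcf_index[vfi$decisions$kept], indels)

switch_errors(greedy_phase(sim$fm, c(truth_snv, indels)),   sim$truth)  # raw INDELs: 2
switch_errors(greedy_phase(sim$fm, c(truth_snv, kept_ind)), sim$truth)  # filtered:  0
block_n50(greedy_phase(sim$fm, truth_snv))                  # SNVs alone: 220603 bp
block_n50(greedy_phase(sim$fm, c(truth_snv, kept_ind)))     # + filtered: 951022 bp
```

On files rather than in-memory objects:

```r
paths <- emit_fixtures(sim, "simdir")               # FASTA + BAM + VCF + fragments + truth
res <- consistency_filter(paths$vcf, bam = paths$bam)
write_filtered_vcf(res, paths$vcf, "filtered.vcf")  # kept records byte-identical
write_report(res, "report.tsv")                     # per-site scores + decision reasons
```

or from a shell via the installed script:

```sh
phasefilt run --vcf sim.vcf --bam reads.bam --out filtered.vcf --report report.tsv
phasefilt simulate --out-dir simdir --n-true 200 --n-fp 40 --seed 7
```

## Scope

phasefilt consumes allele tags, not raw signal: alignment is assumed done,
and structural variants, multi-allelic records and genotype re-calling are
out of scope. Hom-alt and multi-allelic records pass through unscored
(phasers ignore them) and are flagged in the report. The vignette
(`vignettes/consistency-filtering.Rmd`) documents the model, the parameter
choices and the known limitations — in particular the one false-call class a
consistency criterion cannot see (hom-as-het sites, which are perfectly
self-consistent).
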