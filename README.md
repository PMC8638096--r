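# msnstat

Adaptive classification of **negative** versus **unknown** somatic mutation
statuses in multi-sample next-generation sequencing comparisons.

## The problem

When the same mutation is examined across several related samples — multi-site
tumor biopsies, serial liquid biopsies, or two platform runs of one single
cell — a sample with zero mutant reads is either truly negative or simply
under-covered. The common fix, a **universal minimum coverage (UMC)** below
which non-positive cells become "unknown", uses one global depth cutoff for
every mutation, although the depth needed to rule a mutation out depends on
its relative abundance: a 56%-VAF mutation is ruled out by a handful of
wildtype reads, a 5%-VAF mutation by no fewer than dozens.

`msnstat` implements the **mutation-specific negative (MSN)** rule. For each
mutation, every non-positive sample is compared with every known positive
sample using Fisher's exact test on the 2x2 table of mutant and wildtype read
counts,

```
        mutant      wildtype
A       m_A         t_A - m_A
B       m_B         t_B - m_B
```

testing the null hypothesis that both samples carry the same VAF. The
non-positive sample is labelled **negative** only when it has zero mutant
reads and the null is rejected (p < alpha, default two-sided, no
multiple-testing adjustment) against **all** positive samples; otherwise it is
**unknown**. Positive statuses come from the user's own caller or threshold
and pass through untouched. The package also ships the UMC baseline, a
count-level simulator for benchmarking both rules across tumor-cell
fractions, a paired-platform concordance evaluator, TSV readers/writers, and
a command-line front end.

## Worked example

Two biopsies of one patient; the first carries EGFR T790M at 40/72 reads
(56% VAF) and C797S at 5/100 (5% VAF), the follow-up biopsy shows no mutant
reads at 15X and 30X:

```r
library(msnstat)
cm <- example_two_biopsy_counts()
cm
#> <count_matrix> 2 mutation(s) x 2 sample(s)
#> samples: biopsy1, biopsy2
#>                biopsy1 biopsy2
#> 7:55249071:C:T 40/72   0/15
#> 7:55249092:T:A 5/100   0/30

st <- classify_msn(cm, rule = positive_rule(2), cfg = msn_config(0.05),
                   audit = TRUE)
st$status
#>                biopsy1    biopsy2
#> 7:55249071:C:T "positive" "negative"
#> 7:55249092:T:A "positive" "unknown"

msn_audit(st)
#>         mutation  sample vs_positive mutant total pos_mutant pos_total      p_value rejected
#> 1 7:55249071:C:T biopsy2     biopsy1      0    15         40        72 3.008245e-05     TRUE
#> 2 7:55249092:T:A biopsy2     biopsy1      0    30          5       100 5.890330e-01    FALSE

classify_umc(cm, rule = positive_rule(2), cfg = umc_config(20))$status
#>                biopsy1    biopsy2
#> 7:55249071:C:T "positive" "unknown"
#> 7:55249092:T:A "positive" "negative"
```

Fifteen reads with no mutant allele are already incompatible with a ~56% VAF
(p = 3e-5), so the adaptive rule calls T790M negative; thirty reads cannot
distinguish absence from a 5% VAF (p = 0.59), so C797S stays unknown. The
fixed 20X floor reaches the opposite — and, for both mutations, the wrong —
conclusions.

The same interface works from the shell:

```sh
msnstat=$(Rscript -e 'cat(system.file("exec", "msnstat", package = "msnstat"))')
Rscript "$msnstat" fixture --kind two-biopsy --dir demo
Rscript "$msnstat" classify --counts demo/two_biopsy_counts.tsv --method msn \
    --min-mut-reads 2 --alpha 0.05 --out demo/status.tsv --audit demo/audit.tsv
```

See `vignettes/defining-negative-status.Rmd` for the model, the simulation
design, the paired-platform evaluation and all numerical conventions.

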