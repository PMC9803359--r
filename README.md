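# splicegrammar

Tools for analysing the sequence grammar of 5' splice sites (5'SS) and its
consequences for alternative splicing, written for transcriptomics
researchers studying splice-site selection — in particular the interplay
between U5 snRNA loop 1 (which pairs with the last exonic bases, consensus
AG at positions −2..−1) and the U6 snRNA ACAGA box (which pairs with the
intron, consensus RAG at +3..+5, with its central adenosine m⁶A-modified in
many species). The package also ships the surrounding pipeline such a study
needs: local alternative-splicing event extraction with per-event PSI
models, positional composition statistics, and a bulked-segregant scan for
mapping an EMS-induced mutant.

## What it computes

**Splice-site scoring.** All annotated donors are collected into
fixed-width windows (−3..−1 exonic, +1..+5 intronic; no position 0) and a
log₂-transformed position-specific scoring matrix (PSSM) is built with
pseudocount smoothing:

    freq(b, i) = (count(b, i) + c) / (n + 4c),     score(w) = Σᵢ log₂ freq(wᵢ, i)

The U5 score of a donor sums positions −2..−1, the U6 score +3..+5. Donors
fall into two overlapping major classes: //GURAG (strong U6 side) and
AG//GU (strong U5 side); discrete U5 (0–2) and U6 (0–3) classes count edits
from the AG and RAG consensi. Across a mixed donor population the two
scores are negatively correlated — sites strong on one side tend to be weak
on the other.

**Differential splicing.** A5/A3/RI/SE events are extracted from transcript
exon chains, PSIs are computed from transcript TPMs
(`PSI = TPM_inclusion / TPM_total`), and each event is fit by OLS:

    PSI ~ genotype + temperature + genotype:temperature

with temperature categorical (reference 20 °C), per-term partial F-tests,
and Benjamini–Hochberg correction within term.

**BSA mapping.** Pooled allele depths at EMS-consistent (G:C→A:T) SNPs are
contrasted between a phenotype-selected and a normal pool with per-SNP
2×2 G-tests, smoothed along the chromosome with a tri-cube kernel
(`w(d) = (1 − (|d|/h)³)³`, 2 Mb window), and the candidate interval is the
contiguous near-peak region.

**Simulators.** `simulate_sites()`, `simulate_psi()`, and `simulate_bsa()`
generate FASTA/GTF, PSI-matrix, and VCF fixtures with machine-readable
truth, so every stage is testable without external data.

## Worked example

```r
library(splicegrammar)
library(tibble)

sim <- simulate_sites(n_sites = 10000, mixture_aggu = 0.5, seed = 101)
w   <- tibble(site_kind = "five_prime", seq = sim$sites$seq)

sc <- score_sites(w)                 # adds u5_ll and u6_ll columns
score_correlation(sc)
#> # A tibble: 1 × 3
#>      rho  p.value     n
#>    <dbl>    <dbl> <int>
#> 1 -0.593        0 10000

mean(predict_major_class(w) == sim$sites$class)
#> [1] 0.9037
```

The Spearman rho of −0.59 is the anticorrelation between U5 and U6
interaction potential across a half-and-half mixture of the two donor
classes: a donor with a strong exonic AG tends to lack the intronic RAG
and vice versa. The 90% accuracy is how often the motif flags (with a
consensus-distance tie-break) recover the class each donor was drawn from.

```r
b  <- simulate_bsa(seed = 5)                  # 2000 SNPs on a 20 Mb chromosome
tr <- smooth_track(pool_g_test(b$variants))   # per-SNP G, tri-cube smoothed
call_interval(tr)
#> # A tibble: 1 × 5
#>   chrom   start     end peak_pos peak_g
#>   <chr>   <int>   <int>    <int>  <dbl>
#> 1 chr2  6514054 7461744  6977895   56.9
b$truth$causal_pos
#> [1] 7002145
```

The smoothed-G peak lands 24 kb from the planted causal locus; the
interval is the region within 95% of the peak.

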