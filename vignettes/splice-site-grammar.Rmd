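---
title: "Splice-site sequence grammar: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice-site sequence grammar: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicegrammar)
library(tibble)
```

## The scientific setting

During spliceosome assembly the 5' splice site (5'SS) is handed from U1
snRNP to two cooperating contacts: U5 snRNA loop 1 pairs with the last
bases of the upstream exon (consensus AG at positions −2..−1), and the U6
snRNA ACAGA box pairs with the start of the intron (consensus RAG at
positions +3..+5). In many eukaryotes the central adenosine of the ACAGA
box carries an m⁶A modification, and its loss shifts splice-site choice
toward donors with a strong U5-side match — most visibly flipping usage
between donors that differ at the +4 position (A versus U facing the
modified base). This package implements the quantitative machinery for
studying that grammar: PSSM scoring of the two contact regions, discrete
U5/U6 classes, alternative-splicing event statistics, and the
bulked-segregant scan used to map such a mutant in the first place.

## Window and coordinate conventions

All interval arithmetic is 0-based half-open internally; GFF3/GTF input
(1-based inclusive) is converted at the I/O boundary only, and VCF
positions stay 1-based as in the file. Donor windows cover −3..−1
(exonic) and +1..+5 (intronic), acceptor windows −5..−1 (intronic) and
+1..+2 (exonic); there is no position 0. Window sequences are reported in
the RNA alphabet and in transcription sense (minus-strand windows
reverse-complemented), so a donor string reads exactly like the motif
notation X//Y. Windows that would run off a chromosome end are discarded
with a logged count rather than padded — a padded base would be a
fabricated observation in every downstream frequency. Windows containing
N are excluded from matrix building but score as missing rather than
being dropped, and non-GU donors are counted and reported, never silently
removed.

## The PSSM model

Per position, `frequency = (count + c) / (n + 4c)` with pseudocount
`c = 1` per base per position by default, stored as log₂. The score of a
window is the summed log₂ frequency of its observed bases; the U5 score
uses positions −2..−1 and the U6 score +3..+5, both against PSSMs built
from one reference donor set.

Two modelling choices deserve a note, since only "log transformed" PSSMs
are conventional and the details vary between tools:

* **Pseudocount (default 1).** A zero count would give a −∞ score to any
  window carrying an unobserved base. The downstream statistics are
  rank-based (Spearman), and a property test verifies that the rank
  correlation of U5 versus U6 scores moves by less than 0.02 as the
  pseudocount varies over (0, 2].
* **Log base 2.** Bits are conventional; any base gives identical ranks,
  which a unit test asserts directly.
* **Junction deduplication.** Matrices are built from
  junction-deduplicated sites (one count per unique genomic donor), so a
  gene with many isoforms does not weight the matrix; the transcript-
  weighted alternative remains available by extracting introns with
  `dedup = FALSE`.

Classes are edit distances from the consensi: U5 class is the Hamming
distance of −2..−1 from AG (0–2); U6 class the distance of +3..+5 from
RAG with the degenerate R matching A or G at zero cost (0–3); N at a
classed position counts as one edit (conservative, and N sites are rare
and logged). The two major classes overlap — AG//GURAG satisfies both
`is_aggu()` and `is_gurag()` — so both flags are reported, and analyses
that need a partition use the //GURAG flag as the primary split with the
complement as "all other sites". `predict_major_class()` resolves
ambiguous windows by comparing the two consensus distances, with ties
going to the U5 side (the AG//GU core is the shorter motif, so a tie
carries no U6-side evidence).

## Event detection and PSI

Local events follow the usual A5/A3/RI/SE semantics but are detected
directly from exon chains, keeping the pipeline self-contained:
transcripts are assigned to event forms by containing the defining
junction (A5/A3), the intact intron-spanning exon (RI), or the exon plus
both flanking junctions (SE). Alternative-site pairs additionally require
the variant-side flanking exons of the two forms to overlap — without
this, the junction configuration of a skipped exon would be miscounted as
an A5-plus-A3 pair. Donors or acceptors with more than two alternatives
are decomposed into all pairs, matching pairwise downstream analyses.
Mutually-exclusive-exon and alternative-first/last-exon structures are
outside the analysed event set.

`PSI = TPM(inclusion) / TPM(inclusion + exclusion)`, missing when the
denominator falls below the expression floor (default 1 TPM summed over
the event's forms — a 0/0 PSI is meaningless and tiny denominators are
dominated by quantification noise). For A5/A3 the inclusion form is the
shorter-intron variant (more exonic sequence retained), for RI the
retaining form, for SE the exon-including form; swapping forms reflects
PSI about ½ exactly. Pairs are oriented upstream/downstream relative to
the strand of the parent gene.

## The per-event model

`PSI ~ genotype + temperature + genotype:temperature`, ordinary least
squares on raw PSI, temperature categorical with 20 °C (the growth
temperature) as reference. Choices made where the design was genuinely
open:

* **Gaussian OLS on raw PSI** rather than a binomial-type GLM: effect
  sizes are then reported directly in PSI units, which is how ΔPSI is
  interpreted. A logit-transformed fit is available behind
  `family = "logit"`; effect sizes stay on the PSI scale either way.
* **Temperature categorical, not continuous**: four unevenly spaced
  levels, and per-temperature contrasts are the quantity of interest.
* **Partial F-tests on nested models** (type II for the main effects,
  interaction against the additive model) rather than Wald z-tests:
  exact under the Gaussian model at these small per-cell sample sizes.
* **min_obs = 3 non-missing PSIs per genotype**: below that a two-group
  comparison is dominated by single observations; such events are
  flagged degenerate rather than tested. Zero-residual-variance rows
  (constant PSI) are likewise flagged with missing p-values.
* Missing PSIs are dropped — complete-case fitting, no imputation — and
  a test asserts this equals fitting on the explicitly subset data.

Benjamini–Hochberg correction is applied within term across events;
events are then partitioned by significant term (interaction taking
precedence), and for alternative pairs the sign of ΔPSI labels the
reduced-usage site "lost" and its partner "gained".

## Composition statistics

Logo-style frequency matrices are raw empirical probabilities without
pseudocount (display statistics, not scores). Composition differences
between site sets use G-tests, `G = 2 Σ O ln(O/E)` with expectations from
pooled margins, computed per position over −2..+5 and summed (statistic
and df are additive over positions; whole-table pooling was the
alternative reading and per-position summing was chosen as the more
granular option — the per-position decomposition is also returned).
Zero-observed cells contribute 0 and bases absent from both sets are
dropped from the df, which otherwise inflates on skewed fixtures. No
Williams correction by default (the intended use is annotation-scale
sets); it is available as a flag, and a permutation test verifies the
asymptotic p-values against a label-shuffling null on small fixtures.
Spearman correlations use tie-corrected ranks with the large-sample
p-value.

## The bulked-segregant scan

EMS induces G:C→A:T transitions, so the filter keeps G→A records and, by
default, C→T records as the reverse-strand representation of the same
lesion (`strict = TRUE` keeps literal G→A only). Each SNP's pooled
ref/alt depths form a 2×2 pool-by-allele G-test; the per-SNP statistics
are smoothed along the chromosome with a tri-cube kernel. The "2 Mb
window" is interpreted as the total kernel width (half-width h = 1 Mb),
with `half_width = TRUE` available for the other reading. Smoothing is
evaluated at SNP positions, not a uniform grid, matching a per-SNP track
overlaid on allele-fraction points; an isolated SNP's smoothed value
equals its raw value and every smoothed value is a convex combination of
raw values in its window. The candidate interval is the contiguous run of
SNPs around the global maximum staying within `peak_fraction` (default
0.95) of it; tied maxima yield the widest qualifying run with a warning,
and a flat track returns the whole chromosome with a warning. Variant
functional-impact annotation is out of scope; externally produced impact
labels can be joined onto the variant table.

## What the simulators emulate — and what they do not

**`simulate_sites()`** draws donors from a two-class mixture: an
AG//GU-like class (consensus AG at −2..−1 at probability 0.9 per
position, near-uniform +3..+5) and a //GURAG-like class (near-uniform
−2..−1, consensus RAG at +3..+5 at 0.9, R split evenly), with +1..+2 GU
at 0.98 per position and mixture weight 0.5. These emission
probabilities are a deliberate idealisation: real donor sets mix the two
classes with position-dependent, correlated base preferences, so the
simulated anticorrelation of U5/U6 scores (ρ ≈ −0.6) is stronger than
annotation-scale estimates in real genomes (≈ −0.2 to −0.4). Passing
tests therefore demonstrate that the scoring and correlation machinery
recovers a planted two-class structure, not that any particular genome
has one. The drawn windows are realised as a toy genome (one
single-intron, plus-strand gene per donor, fixed spacer blocks, 20 nt
exons and 40 nt introns ending in a pyrimidine-tract acceptor) so the
FASTA/GTF round trip through annotation parsing and window extraction is
exact and hand-checkable.

**`simulate_psi()`** uses the motivating study's design as its defaults:
six biological replicates of two genotypes at four temperatures (4, 12,
20, 28 °C), Gaussian noise σ = 0.05, a genotype effect of |ΔPSI| = 0.2
planted on 20% of 1000 events with random sign, and baselines kept 4σ
clear of the boundaries so clipping to [0, 1] is rare (the clip rate is
returned and is below 1% under defaults). An optional interaction
fraction adds the genotype effect again at 28 °C, mimicking
cryptic-donor activation at elevated temperature. Real PSI noise is
heteroscedastic and bounded, not Gaussian; the simulator's clean noise
makes the power and FDR numbers best-case calibrations of the model
code, not predictions for real data.

**`simulate_bsa()`** plants one causal locus on a 20 Mb chromosome with
2000 EMS SNPs, pools of 50 plants at 50× mean depth, and recessive
backcross-F2 segregation: the mutant pool is homozygous causal, the
normal pool carries the causal allele at expected fraction 1/3, and
linkage decays with Haldane recombination at 0.05 Morgan/Mb (the
*Arabidopsis* genome-wide average of ~5 cM/Mb). Expected allele
fractions are `1 − r` (mutant pool) and `(1 − r)/3 + 2r/3` (normal
pool), both → ½ as r → ½; note that on a single 20 Mb chromosome at
realistic recombination rates nothing is fully unlinked, so pool
fractions converge only at the chromosome ends. Depths are Poisson,
allele counts binomial over sampled pool chromosomes. There is no
read-level error model and no variant-calling noise.

All generators are seed-deterministic (byte-identical output under a
repeated seed) and emit truth tables consumed by the test suite.

## Problem sizes and numerical notes

The test suite and the acceptance script run entirely on generated data
at the sizes above (10⁴–10⁵ donors for correlation stability, 10³ events
for error-rate calibration at a resolution of ±0.01–0.02, twenty seeded
BSA replicates for the localization rate). Exact comparisons against
hand-computed oracles use tolerances at machine precision; Monte-Carlo
assertions use bands derived from binomial or Kolmogorov–Smirnov
sampling error at the stated n, not tuned constants. Ties in Spearman
correlations are rank-averaged; the large-sample p-value approximation
is used throughout, which is inaccurate below n ≈ 10 but no analysis
here operates at that size.

## Known limitations

* Event abundances are taken as given (TSV of transcript TPMs); there is
  no read-level junction counting, and no NMD/productivity annotation.
* The PSSM is positionally independent — no dependency-aware or
  maximum-entropy splice model, and no thermodynamic duplex scoring of
  the snRNA contacts.
* Linkage between alternative 3'SS choice and 5'SS choice is reported
  only as co-occurrence within a gene; no causal linkage model.
* Multi-species analyses are independent runs per genome; there is no
  phylogenetic weighting.
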