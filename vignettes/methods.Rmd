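---
title: "Models and methods behind ovipop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ovipop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovipop)
```

`ovipop` re-implements, as a tested library, the analytical core of an
archaeogenetic workflow for ancient domestic sheep: authenticating ancient
sequencing reads through their postmortem-damage signature, calling
pseudohaploid genotypes against a SNP panel, measuring population affinity
with outgroup-f3 and D-statistics under a weighted block jackknife,
projecting low-coverage samples into a PCA of modern breeds, inferring
molecular sex from X-to-autosome coverage, and classifying mitochondrial
haplogroups A–E from a short control-region fragment. A synthetic-data
module generates every input the pipeline consumes, so all downstream
behaviour can be validated against known simulation truth without any
external download.

This vignette records the models, the defaults and why they were chosen,
the numerical conventions, and the limits of what the synthetic experiments
demonstrate.

## The demographic simulator

Allele frequencies evolve down a user-defined population tree. Each branch
carries a drift coefficient $d \in [0,1)$, and a child's frequency is drawn
from the Balding–Nichols beta distribution with mean $f$ (the parent
frequency) and variance $d\,f(1-f)$:

$$f_{\text{child}} \sim \mathrm{Beta}\!\left(f\,\tfrac{1-d}{d},\; (1-f)\,\tfrac{1-d}{d}\right).$$

This parameterisation was chosen because its closed-form moments give
analytic oracles for tests (e.g. the mean squared frequency change on a
branch is exactly $d\,f(1-f)$). Frequencies that reach 0 or 1 are absorbed.
Root frequencies are uniform on [0.05, 0.95] by default, keeping sites
informative while allowing loss and fixation downstream.

`canonical_tree()` encodes the scenario the package is built around: a wild
outgroup (argali-like, a distinct species; branch drift 0.15) splits from
the domestic stem (0.02), which splits into a western and an eastern branch
(drift 0.08 each, the $F_{ST}$ scale separating present-day European-descent
from Asian-descent breed clusters). An ancient population attaches halfway
down one branch (sharing 0.04 of its drift) with 0.02 of private drift —
the natural reading of an early Anatolian individual ancestral on the
western side, or a central-Asian individual on the eastern side. These
values were fixed once on these population-genetic grounds; they are
arguments, not constants, so other scenarios (including wild-introgression
designs via extra attachment points) can be composed.

Genotypes are binomial: diploid moderns draw two alleles per site,
pseudohaploid ancients a single allele, stored internally on a haploid 0/1
scale and flagged, so that every frequency computation counts a
pseudohaploid individual as **one** observation. Only the EIGENSTRAT writer
expands such calls to the conventional 0/2 encoding. This avoids silently
doubling ancient sample sizes inside f-statistics.

Sites are exchangeable — there is no linkage, recombination or selection —
which is consistent with the site-wise f-statistics used downstream but
means the block jackknife's robustness to linkage is exercised only
structurally, not against real LD.

## The miniature reference and read simulator

`mini_reference()` builds a desk-scale genome that preserves the geometry
the sexing procedure relies on: 26 autosomes with lengths declining from
3.0 Mb to 0.5 Mb, an X of 2.0 Mb (inside the autosomal length range, so the
loess prediction at the X's length interpolates), and a 16,616-base
mitochondrial contig so that control-region position 15,534 exists.
Sequences are random with a fixed seed and are only materialised on
request; placement-level experiments (coverage, sexing) run on lengths
alone, which keeps one hundred 0.3× replicates of a ~47.5 Mb genome cheap.
Sequence-level behaviour (damage, genotyping, probes) is exercised on
smaller sequenced references of a few hundred kilobases.

Endogenous reads are placed uniformly with per-chromosome intensity
proportional to length × copy number (X copy number 1 in XY males, 2
otherwise), with log-normal fragment lengths (log-mean $\log 70$, log-sd
0.35) floored at 35 bp — the minimum retained by the filtering step, so the
simulator emits nothing the filter would instantly discard. Postmortem
deamination is applied on the strand as sequenced: C→T at 5' offsets and
G→A at 3' offsets with probability

$$p(\text{offset}) = \delta_{\max} e^{-\lambda\,\text{offset}} + b,$$

defaulting to $\delta_{\max}=0.30$ (the middle of the 20–42% terminal
damage range typical of authentic Neolithic material), background
$b = 0.01$, and decay $\lambda = 0.7$ per base. The decay default encodes
the standard working assumption behind 10-bp end-trimming: essentially all
deamination sits within the first few bases, so the retained interior is at
background level. Contaminant reads are emitted unaligned at rate
$1 - \text{endogenous fraction}$ (default endogenous fraction 0.02,
matching the median endogenous content of the libraries the scenario
emulates). Sequencing error beyond a uniform substitution rate, indels and
base qualities are not modelled.

## Read QC and authentication

`damage_profile()` tabulates per-offset C→T (5') and G→A (3') rates over
reference-C/G sites in read orientation for the first 60 positions.
`pmd_score()` is a simplified two-hypothesis log-likelihood ratio — damage
curve versus error-only null — summed over informative positions:
an observed T at a reference-C position at 5' offset $i$ contributes
$\log\frac{D_i + (1-D_i)\varepsilon}{\varepsilon}$, an observed C
contributes $\log(1 - D_i)$, mirrored for 3' G→A. The published PMD
formulation also conditions on base qualities; qualities are not simulated
here, so the score keeps the decision-boundary semantics of the
conventional "threshold 3" filter without the quality terms. A read
spanning no informative position scores exactly 0.

`filter_reads()` applies, in order: molecule-length filter (≥ 35 bp),
mismatch-ratio filter (> 10% removes), optional PMD-score filter
(keep ≥ 3), then end-trimming. Two conventions make the operation
idempotent, which re-running a pipeline should be: the length rule refers
to molecule length (a previously trimmed read is credited its trimmed
bases), and the alignment-based mismatch/PMD rules are applied only to
untrimmed input, because after end-trimming they would re-measure a
different, biased quantity on the clipped segment.

`authenticate_by_length()` reproduces the long-molecule contamination
check: reads are split at a length cut (default 90 bp, the scale at which
average ancient fragment length becomes suspicious), each class is
profiled and genotyped pseudohaploidly, and the outgroup-f3 vector of each
class against every modern population is correlated across classes. Both
Spearman and Pearson coefficients are reported — the two appear
interchangeably in practice for this comparison and neither is privileged
— and no contamination verdict is issued: the statistics are the output.

## f-statistics and their uncertainty

With population allele frequencies $o, a, b, \dots$ per site,

$$f_3(O; A, B) = \overline{(o-a)(o-b)}, \qquad
D(W,X;Y,Z) = \frac{\sum (w-x)(y-z)}{\sum (w+x-2wx)(y+z-2yz)}.$$

f3 is reported unnormalised (no outgroup-heterozygosity correction): in
outgroup-f3 usage only the relative ordering across modern partners
matters, and pseudohaploid outgroups make the usual normalisation
ill-defined. Sites missing in any involved population are excluded per
test. Standard errors come from a weighted delete-one-block jackknife
(Busing-style delete-m formulae) over contiguous physical blocks, default
5 Mb of the miniature genome — roughly 10–25 typical fragment-recombination
scales in real data; the original analyses do not state their block length,
so this default is declared rather than inferred. Z-scores are
estimate/SE and p-values two-sided normal tails, the convention of the
jackknife Z-score procedure; batches of tests are corrected with
Benjamini–Hochberg via `bh_adjust()`.

A property worth noting for interpretation: with the ancient attached to
the west branch, $D(\text{outgroup}, \text{ancient}; \text{west},
\text{east})$ is **negative** under the sign convention above (the second
population sharing excess drift with the third pulls the numerator down);
moving the ancient to the east branch flips the sign. The tests pin this
orientation explicitly.

## PCA and least-squares projection

`pca_fit()` standardises dosages per SNP by the mean and by
$\sqrt{\hat p(1-\hat p)}$ with $\hat p$ = mean dosage / 2 — the
drift-variance scaling smartpca applies — then eigendecomposes via SVD of
the standardised individuals × SNPs matrix. Monomorphic sites are dropped;
missing entries in the fit set are mean-imputed (simulated modern panels
are complete, so this path matters only for real data). Projection of a
low-coverage sample solves the least-squares problem restricted to the
sample's observed, model-known SNPs — no imputation at projection time, the
behaviour selected by `lsqproject` in smartpca. A complete individual from
the fit set projects back onto its fitted coordinates exactly (to numerical
tolerance), which the tests assert; heavily missing pseudohaploid samples
shrink toward the origin, which is why centroid *comparison*, not absolute
position, is the meaningful readout.

## Molecular sexing

Per-chromosome read counts are normalised by chromosome length; the
mitochondrial contig is excluded. A loess curve (span 0.80, degree 2) of
intensity against chromosome length is fitted on autosomes only — the X is
never part of the fit — and predicts the intensity an XX individual would
show at the X's length. The 95% interval is a t-based **prediction**
interval (fit standard error plus residual scale, degrees of freedom from
the loess residual df, floored at 2 — the df convention is not specified by
the source procedure, so it is declared here): an interval without the
residual term would not contain an XX individual's observed X ~95% of the
time, which is the operational meaning of the check. The XX expectation is
predicted at the X's physical length and ratios are formed afterwards; the
alternative convention (predicting at half-length) is not used, and the
choice is documented rather than silently assumed.

Labels: XX when the observed X intensity falls inside the interval; XY when
it falls outside **and** the observed/expected ratio lies in [0.35, 0.65]
around the single-X expectation of 0.5; anything else is ambiguous. The
source procedure tests only the XX null and never states an XY acceptance
band, so the band here is this package's own symmetric, conservative
choice — boundary cases return `ambiguous` rather than forcing a call.
At 0.3× on the miniature genome the XY ratio distribution is tight around
0.50 and the XX around 1.00; `sex_ratio_experiment()` reruns that
calibration end to end.

## Mitochondrial haplogroups

The classifier works on the 144-base control-region fragment at reference
positions 15,391–15,534 (1-based, inclusive). Diagnostic sites live in a
configuration table, not in code; the bundled
`diagnostic_sites_synthetic.tsv` is a synthetic five-site table (the
original supplementary site list is not redistributed) in which the
reference carries the haplogroup-B pattern and A, C, D, E each differ by
one transition at their own site, with A marked at two sites so all
patterns are pairwise distinct. Single convergent transitions can therefore
turn one pattern exactly into another — the misassignment mode the
replicate workflow exists to catch.

Per replicate: exact pattern match wins; otherwise the unique nearest
pattern at Hamming distance 1 over diagnostic sites is accepted (with the
discrepant sites reported as conflicts); ties or distance > 1 yield
`unassigned`; `N` mismatches every pattern. The distance-1 rescue is this
package's tie rule — the source workflow acknowledges convergent
transitions but states none — chosen as the most conservative rule that
still lets a single homoplasy be survived when it does not land on another
pattern. Consensus: ≥2 concordant replicates give a high-confidence call;
a discordant pair requires a third round and majority; a single replicate
is a low-confidence call; a mitogenome-derived call, when present,
overrides the fragment consensus and is flagged. Indels are rejected, not
realigned: fragment replicates must be length-true.

Frequencies carry Clopper–Pearson exact binomial 95% intervals (via
`binom.test`), the method that reproduces the worked 4-of-79 → 5% [1–12%]
example; Wilson intervals do not round to that interval, which is why the
exact method was selected. Group composition is compared with Fisher's
exact test (hypergeometric for 2×2, exact network enumeration for r×2) and
Cohen's $w = \sqrt{\chi^2/N}$ from the same contingency table.

## Problem sizes, tolerances and degenerate inputs

The test suite validates statistical behaviour at sizes a laptop handles in
minutes: 20,000-SNP panels with 10 diploid individuals per population and
100 replicates for the structure-recovery experiments; 100 replicates at
0.3× for the sexing calibration; tens of thousands of reads for damage
recovery. Implementation-correctness checks (f3/D against independent
per-site loops, jackknife against direct delete-one recomputation) are held
to 1e-12; stochastic recovery checks use three-binomial-SE bands around
their analytic expectations, and classification experiments demand ≥95%
replicate agreement. Degenerate inputs fail loudly and specifically: zero
usable sites, a delete-one block that empties the D denominator, fewer than
two jackknife blocks, fewer than five nonzero autosomes, a length class
with no genotypable site, zero replicates, all-zero contingency tables.

What passing these experiments does **not** show: robustness to real LD
structure, reference bias, ascertainment bias of array panels, library
qualities, or indel-bearing Sanger traces — none of which the generators
emulate. The package's claims are about the correctness of the statistics
and decision rules under their stated models.
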