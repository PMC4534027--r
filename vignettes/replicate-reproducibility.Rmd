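---
title: "Quantifying reproducibility and stability of replicated stool microbiome measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reproducibility and stability of replicated stool microbiome measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Population-scale microbiome studies must collect stool in the field, where
immediate freezing is rarely possible. Whether a measurement made on such a
specimen can be trusted is an empirical question about *technical
reproducibility*: if the same stool is aliquoted several times into the same
collection medium, how much of the variation in a microbiota metric reflects
real differences between people, and how much is measurement noise? And if
freezing is delayed for days at room temperature, does the measurement stay
stable?

`microrepro` implements this analysis for a replicated collection design:
each subject contributes technical-replicate aliquots under several
collection media (none, RNAlater alone, RNAlater plus kanamycin or
ciprofloxacin), frozen immediately or after a room-temperature delay. The
package takes an OTU count table, sample metadata, a rooted phylogeny and a
phylum map, and produces reproducibility and stability reports over 14
microbiota metrics, together with permutation inference.

# The model

## Intraclass correlation

The central statistic is the one-way random-effects intraclass correlation
coefficient. For a metric measured on replicate $j$ of subject $i$,

$$ y_{ij} = \mu + b_i + \varepsilon_{ij}, \qquad
   b_i \sim N(0, \sigma_b^2), \quad \varepsilon_{ij} \sim N(0, \sigma_\varepsilon^2), $$

$$ \mathrm{ICC} = \frac{\sigma_b^2}{\sigma_b^2 + \sigma_\varepsilon^2}. $$

An ICC of 1 means replicates agree perfectly relative to between-subject
spread; an ICC of 0 means the measurement carries no subject signal.
`icc_fit()` uses the ANOVA (method-of-moments) estimator: with $G$ groups of
sizes $n_g$ and $N = \sum n_g$,

$$ \widehat{\sigma_\varepsilon^2} = \mathrm{MSW}, \qquad
   \widehat{\sigma_b^2} = \max\!\left(0, \frac{\mathrm{MSB} - \mathrm{MSW}}{k_\mathrm{eff}}\right), \qquad
   k_\mathrm{eff} = \frac{N - \sum_g n_g^2 / N}{G - 1}, $$

and the reported ICC is
$(\mathrm{MSB}-\mathrm{MSW})/(\mathrm{MSB}+(k_\mathrm{eff}-1)\mathrm{MSW})$,
clamped to $[0,1]$ for reporting with the raw value retained. The moment
estimator (rather than REML) keeps the estimate in closed form, makes the
permutation test exact to rerun, and matches the classic ANOVA definition of
the ICC. In small samples the raw estimator can be negative; truncation
happens only at the reporting boundary so that simulation averages remain
unbiased diagnostics.

Inference for $\mathrm{ICC}=0$ ("values are random across replicates") is by
permutation: all values are shuffled across subjects with group sizes
preserved, and $p = (1 + \#\{\mathrm{ICC}^\ast \ge \mathrm{ICC}\}) / (B+1)$
with $B = 999$ by default. Comparing the ICC of the same metric between two
media uses the statistic $|\mathrm{ICC}_a - \mathrm{ICC}_b|$ with a null
built by swapping each subject's full replicate set between the conditions
independently with probability one half. The swap scheme is our design
choice — it preserves within-subject replicate structure exactly while
making the condition labels exchangeable under the null — and it is isolated
in `icc_diff_test()` so an alternative scheme can be substituted.

## Temporal stability

Stability between a delayed time point $t$ and immediate freezing is
measured by first averaging technical replicates per subject at each time,
then computing the same one-way ICC with each subject's pair (average at
$t$, average at 0) as its two "replicates" (`temporal_icc()`). Averaging
first removes replicate noise from the comparison, so the statistic isolates
the incubation effect.

## The 14 metrics and beta diversity

Reports cover: relative abundances of Actinobacteria, Bacteroidetes,
Firmicutes and Proteobacteria; four alpha-diversity metrics — observed
species, bias-corrected Chao1
($S_\mathrm{obs} + F_1(F_1-1)/(2(F_2+1))$), Shannon
($H = -\sum p_i \ln p_i$) and Faith's whole-tree phylogenetic diversity —
and the top three principal coordinates of the unweighted and weighted
UniFrac distance matrices. Alpha metrics are computed under rarefaction:
5000 reads drawn without replacement, 20 independent draws, metric averaged
over draws. Samples under the rarefaction depth are excluded with a warning
and downstream ICCs use the remaining replicates; no smaller draw is taken
silently.

Weighted UniFrac is the raw (non-normalized) form
$\sum_e \ell_e\,|P_A(e) - P_B(e)|$, where $P_X(e)$ is the fraction of
community $X$'s abundance descending through branch $e$; a normalized
variant is available via `normalized = TRUE`. Unweighted UniFrac is unique
branch length over occupied branch length. Both are computed by one
postorder pass per sample accumulating per-branch descendant abundance; the
tree is pruned to the table's OTU set first. The distance matrix is built
from a single rarefaction at the same depth (one seeded draw per sample) —
averaging 20 draws is reserved for alpha diversity, matching the common
single-rarefaction convention for beta diversity; `rarefy = FALSE` computes
on full counts.

PCoA Gower-centers the squared distances and eigendecomposes; negative
eigenvalues (non-Euclidean input) are dropped rather than corrected, and the
proportion explained is taken over positive eigenvalues only. Each axis is
oriented so that its largest-magnitude coordinate is positive, which makes
downstream ICCs of scores reproducible run to run. The ordination is
computed once over all samples jointly and strata are sliced from the shared
axes, so scores are comparable across conditions and times.

The subject-explained fraction of overall community variability is the
one-factor PERMANOVA decomposition
$R^2 = 1 - \mathrm{SS}_\mathrm{within}/\mathrm{SS}_\mathrm{total}$ on
squared UniFrac distances (`dist_r2()`), with the three sums of squares
exposed so the decomposition identity can be checked exactly.

## Abundance–reproducibility trend

Per-taxon ICCs of relative abundance (within one medium/time stratum) are
regressed on $\ln$ mean relative abundance by ordinary least squares,
restricted to taxa at or above a floor of 0.1 % (inclusive: a taxon at
0.11 % enters, one at 0.09 % does not). A positive slope means abundant taxa
are measured more reproducibly than rare ones. The taxonomic rank is a
parameter (`rank = "otu"` or `"phylum"`); we default to OTU level. The mean
(not median) abundance is the regressor and the filter variable, keeping
the filter and the regressor consistent.

# The synthetic study generator

No raw data accompany the design this package targets, so
`generate_study()` produces full studies with known ground truth. The
design is fixed: per subject, 3 no-media aliquots at day 0, plus 3
replicates at days 0, 3 and 7 for each of the three RNAlater-based media —
30 samples per subject, 300 for the default 10 subjects.

The generative hierarchy on per-OTU log abundance is

1. a deterministic template: OTUs are assigned to phyla (richness per phylum
   proportional to the cube root of its target abundance — abundant phyla
   carry more OTUs, sublinearly) with within-phylum Zipf($1.5$) abundances,
   scaled so expected phylum totals match the targets
   (Firmicutes 75.1 %, Bacteroidetes 14.6 %, Actinobacteria 2.1 %,
   Proteobacteria 0.6 %, remainder "other"); the power law puts roughly half
   the OTUs below 0.1 % so the abundance–ICC trend has support;
2. a subject effect $N(0, \sigma_b^2)$ per OTU;
3. a per-phylum medium effect (log fold-change) — by default the no-media
   condition depletes Bacteroidetes by 1.6 log units and Proteobacteria by
   0.4;
4. incubation drift $N(0, r_m^2 t)$ per OTU, realized once per
   (subject, medium, time) and shared by that aliquot set's replicates —
   drift is a between-time effect; making it per-aliquot would be
   indistinguishable from replicate noise;
5. replicate noise $N(0, \sigma_\varepsilon^2)$ per OTU, optionally
   inflated for rare taxa by $(p_{\max}/p)^{\theta}$
   (`rare_noise_exponent`, default 0);
6. softmax to a composition and multinomial sampling at the sequencing
   depth.

The log-normal–softmax–multinomial hierarchy was chosen over a
Dirichlet-multinomial so that $\sigma_b^2$ and $\sigma_\varepsilon^2$ live
on the same log scale as the ICC variance components: a single OTU's log
abundance then has true ICC
$\sigma_b^2/(\sigma_b^2+\sigma_\varepsilon^2)$, enabling parameter-recovery
tests. Defaults — $\sigma_b^2 = 1.0$, $\sigma_\varepsilon^2 = 0.1$ (per-OTU
baseline ICC $\approx 0.91$), drift s.d. per day 0.10 for RNAlater alone
and 0.35 for both antibiotic media, depth 20 000 reads — were chosen once to
mimic the qualitative structure of a well-preserved stool study: day-0 ICCs
near 0.9, mild 7-day drift under RNAlater alone
($0.10^2 \times 7 \approx 0.07$, small against $\sigma_b^2$), and strong
antibiotic-media drift ($0.35^2 \times 7 \approx 0.86$, comparable to
$\sigma_b^2$, which drags down stability ICCs for detection-sensitive
metrics). The effect sizes are illustrative: the direction, not the
magnitude, is calibrated.

Randomness is organized as one master seed with per-sample substreams
derived by counter and by a hash of the sample id, so adding subjects does
not reshuffle existing ones, results do not depend on table row order, and
identical parameters give byte-identical studies.

What the generator does *not* emulate: sequencing error and chimeras, PCR
bias, compositional correlation between taxa beyond the shared softmax
denominator, over-dispersion beyond log-normal, and real phylogenetic
signal in abundances (the tree is random). Passing tests on synthetic data
therefore demonstrate the statistical machinery, not robustness to
upstream artifacts of real sequencing.

# Numerical and degenerate-input choices

- **Rarefaction** is multivariate hypergeometric (reads subsampled without
  replacement). Reads are expanded in OTU-name order before sampling so the
  draw is invariant to column permutation under a fixed seed.
- **ICC degeneracies**: all values identical gives ICC 1 with a degenerate
  flag; a group with no values, fewer than 2 groups, or zero within-group
  degrees of freedom is an error. Negative variance estimates are truncated
  at zero in `sigma_b2_hat` while the raw ICC is kept.
- **Counting noise floor**: with $\sigma_\varepsilon^2 = 0$ the multinomial
  stage still leaves replicate-level noise, so detection-driven metrics
  (Chao1, unweighted ordination axes) do not reach ICC 1 at finite depth;
  abundance-weighted metrics do, to within a few percent. Tests assert
  exactly this pattern rather than the infinite-depth idealization.
- **Paired t-test** (no-media vs media phylum abundance, per-subject
  replicate averages, no multiplicity correction): zero-variance differences
  report p = 1 when the mean difference is 0 and are flagged degenerate
  otherwise.
- **Distance R2** with all-zero distances is NA (flaggedly undefined) rather
  than 1.
- **Permutation p-values** use the add-one correction, so the smallest
  attainable p is $1/(B+1)$.

# Problem sizes

The test suite and the acceptance script use: 500 one-way simulations per
variance setting (10 subjects × 3 replicates) for estimator recovery; 200
simulations × 199 permutations for test calibration; 100 random trees of up
to 16 leaves against an exhaustive branch-enumeration oracle; and 50
full-study simulations per qualitative direction (default generator
conditions, 300 samples × 200 OTUs each). These sizes give Monte-Carlo
standard errors well inside the asserted tolerances.

# Worked example

```{r, eval = FALSE}
library(microrepro)

study <- generate_study(synth_params(seed = 1))
rep0 <- reproducibility_report(study$counts, study$metadata, study$tree,
                               study$taxonomy, n_perm = 999, seed = 1)
print(rep0)

stab <- stability_report(study$counts, study$metadata, study$tree,
                         study$taxonomy, seed = 1)
print(stab)

media_comparison(study$counts, study$metadata, study$taxonomy)
```

# Known limitations

- Only the one-way (agreement-across-replicates) ICC is implemented; the
  two-way consistency/agreement variants and Fisher-transform confidence
  intervals are out of scope.
- Bray–Curtis, Jaccard and generalized UniFrac distances are not provided.
- The ICC-difference permutation scheme is one defensible operationalization
  among several; with 10 subjects its power is limited, and pairwise media
  comparisons on realistic effect sizes will often be non-significant.
- BIOM input is not parsed; plain-TSV exports are assumed.
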