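---
title: "Benchmarking DNA extraction methods with mock communities: models and methods"
author: "mockbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mockbench methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mockbench)
```

## Scope and rationale

`mockbench` scores DNA extraction / amplicon sequencing protocols against
a mock community of known composition. This vignette is the package's own
account of the statistical machinery: the models, their assumptions, the
parameters a user can reasonably touch, and the choices made where the
design was genuinely open. It states no empirical result that the test
suite or the acceptance script does not itself compute.

## Expected proportions from copy numbers

A community is an ordered list of taxa with 16S rRNA gene copy numbers
$g_i$ (copies per genome) and relative cell abundances $c_i$. Under
unbiased lysis and amplification each cell of taxon $i$ contributes $g_i$
amplifiable gene copies, so the expected read share is

$$\pi_i = \frac{c_i\,g_i}{\sum_j c_j\,g_j}.$$

Assumptions worth keeping in mind: chromosome copy number per cell is
treated as constant (in practice cells are harvested post-exponentially
to approximate this), and primer bias is assumed away (mitigated in
practice by degenerate primer mixtures; see the read-QC section). Copy
numbers are user inputs, not predictions; where databases report several
values for a species, the convention adopted is to take the larger.

All internal arithmetic is on fractions. Percentages appear only in
presentation layers, rounded half-up to one decimal (`round_half_up()`),
which reproduces the printed precision of the published benchmark tables
the fixtures derive from. Taxa order is the community file's row order,
and every downstream vector carries taxa names that are validated on use
— distance functions refuse silently reordered inputs.

## The overdispersed count model

Replicated amplicon counts are noticeably more variable than multinomial
sampling alone predicts: extraction, amplification and pooling all vary
between replicates. The package models a table of per-replicate counts
$x_{\cdot j}$ with depths $N_j$ as Dirichlet-multinomial (DM):

$$p_{\cdot j} \sim \mathrm{Dirichlet}(\theta\pi), \qquad
  x_{\cdot j} \mid p_{\cdot j} \sim \mathrm{Multinomial}(N_j, p_{\cdot j}),$$

with mean composition $\pi$ and concentration $\theta > 0$. Per-taxon
variance is $N\pi_i(1-\pi_i)\,(N+\theta)/(1+\theta)$, so small $\theta$
means strong overdispersion and $\theta \to \infty$ recovers the
multinomial; at $K = 2$ the DM is the beta-binomial, which the tests use
as a closed-form oracle. The DM is adopted as the standard exchangeable
overdispersion model for multivariate counts; it is deliberately isolated
behind the `overdispersed_model()` interface so a different density could
be swapped in without touching the test machinery. Zero proportions are
handled natively — $\pi_i = 0$ with positive counts yields $-\infty$
log-likelihood by contract, and no pseudocounts are used anywhere.

### Fitting

*Null model* (`fit_null()`): $\pi$ fixed at the expected proportions;
$\theta$ maximized by 1-D optimization of $\log\theta$ on
$[10^{-2}, 10^8]$. The upper bound is the declared "effectively
multinomial" ceiling: data exactly proportional to expectation drive
$\theta$ there, and the fit records the bound hit. Because the profile
log-likelihood is extremely flat near the ceiling and `lgamma`
differences lose precision at huge arguments, boundary promotion uses a
relative tolerance of $10^{-6}$.

*Alternative model* (`fit_alternative()`): joint MLE of $(\pi, \theta)$
via a monotone fixed-point iteration on the DM shape vector
$\alpha = \theta\pi$ (initialized at the pooled proportions with a
profiled $\theta$), stopping when the log-likelihood moves by less than
$10^{-8}$ or after 500 sweeps. The fixed point converges slowly along the
overall-concentration direction, so every 20th sweep is replaced by a 1-D
$\theta$-profile step; this is purely an acceleration and never decreases
the likelihood being tracked. Taxa with all-zero counts get $\hat\pi_i = 0$.
With $\theta$ supplied and held fixed, the composition is optimized
directly over softmax logits (BFGS); note that for finite fixed $\theta$
the composition MLE of a single replicate is *not* exactly the observed
proportions — that identity holds only in the multinomial limit, which is
how the package's tests exercise it.

### The bootstrapped likelihood-ratio test

`lrt_gof()` computes $\Lambda = 2(\hat\ell_{alt} - \hat\ell_{null})$,
clipped at zero (values within $10^{-6}$ of zero are optimizer noise).
With 8 replicates and 10 free parameters, the $\chi^2$ asymptotics are
unreliable, so the null distribution is estimated by parametric
bootstrap: $B$ datasets are simulated from the *fitted* null
(same depths, $\pi$ = expected, $\theta = \hat\theta_{null}$), both
models are refitted on each, and

$$p = \frac{1 + \#\{\Lambda^*_b \ge \Lambda\}}{B + 1},$$

which is never exactly zero and has floor $1/(B+1)$. The default
$B = 999$ balances resolution against runtime (the published benchmark
does not state its replication). One parent seed deterministically spawns
per-dataset sub-seeds, so results are bit-reproducible and independent of
execution order. $\theta$ is fitted per count table — i.e. per method —
which is the natural reading when each method's replicates form one
table. The test's type-I behaviour is verified by simulation in the
acceptance suite (200 null datasets at $\theta = 50$, depth 2000,
$B = 199$; rejection rate required to fall in $[0.01, 0.10]$ at
$\alpha = 0.05$).

## Representation, reproducibility, and method comparison

Representation is scored per replicate as the Euclidean distance between
observed and expected proportions; reproducibility as the distance to the
method's *grand* proportions, i.e. proportions of counts pooled across
replicates (not the mean of per-replicate proportions — deeper replicates
weigh more). Distances are computed on fractions; percent would only
rescale them by 100.

`compare_methods()` then runs: all-pairs Wilcoxon rank sum tests on
representation distances; all-pairs Fligner–Killeen tests on the
deviations from baseline (a variance comparison, matching the
interpretation of reproducibility as spread); within-method
experimenter and day splits compared by exact Wilcoxon (4 vs 4 in the
standard eight-replicate layout); and Spearman correlation of DNA yield
against representation distance, within and across methods. The
Bonferroni family is all $\binom{m}{2}$ pairs at the user's $\alpha$; the
published benchmark does not state its family sizes, so the package
documents this choice rather than guessing thresholds. Non-significant
correlations are reported as estimated, never zeroed — zeroing is a
presentation convention, not a statistic.

The Wilcoxon implementation uses the exact distribution when both samples
are tie-free and the pooled size is at most 20, otherwise the normal
approximation with tie and continuity corrections; which variant ran is
reported, since with eight replicates per arm either choice is defensible
and the published analysis does not say which it used.

## Yield analysis

Concentrations are natural-log transformed (base is irrelevant to F
tests) to meet normality/constant-variance assumptions; zeros are an
error directing the user to substitute a detection limit explicitly.
The balanced split-plot ANOVA uses closed-form sums of squares with
extraction method as the whole-plot factor tested against the
block × method stratum, and species and method × species tested against
the residual. Experimenter and day are collapsed into a single block
label because the two-experimenter/two-day layout confounds them.
Unbalanced tables are refused rather than approximated — REML-style
mixed-model estimation is out of scope.

Per-species pairwise comparisons use Tukey's HSD on a self-contained
one-way layout (per-sample error term) rather than the global split-plot
residual; the published benchmark does not state which stratum fed its
letters, and the one-way choice keeps each species' table reproducible in
isolation. Letters come from the insert-and-absorb construction, ordered
by descending mean, and satisfy the defining invariant — two methods
share a letter iff not significantly different — which is property-tested
on significance matrices realized from random clustered data (including
non-transitive chain patterns). Testing is on the log scale; displayed
means are raw-scale, matching how such tables are printed. Fold-ratio
summaries divide the top method's mean by the best *other* method's mean
("at least $x$-fold higher") and are reported at full precision plus
half-up 1-dp rounding for narration.

## Read QC

Reads are assumed to start with an 8-bp barcode, a 2-bp linker (`TC`),
and a forward primer. Filters run in the order barcode → primer → length
→ ambiguity → homopolymer, each rejection logging the *first* failing
rule; the kept set is order-independent (the criteria are conjunctive),
only the logged reasons depend on order. Defaults: barcode Hamming
distance ≤ 1 with ambiguity never guessed (zero or two candidates within
range → unassigned); ≤ 2 primer mismatches with IUPAC codes matching
their expansions at zero penalty; post-trim length ≥ 100 bp; < 2 `N`
bases (applied after trimming); homopolymer runs < 7 bp. Quality strings
are carried through untouched — platform-specific quality clipping and
alignment-position filters are out of scope, but `filter_reads()` accepts
an external per-read pass/fail vector so a pipeline can impose them.

## The synthetic-data generator

`simulate_counts()` mirrors the inference model exactly: the true
composition is the expected composition distorted by per-taxon extraction
efficiencies ($\rho_i \propto c_i g_i e_i$ — cell lysis bias is the
mechanism being benchmarked), replicate proportions are
Dirichlet($\theta\rho$), counts multinomial. Defaults state the
benchmark's world: 8 replicates per method in the
2 experimenters × 2 days × 2 extractions layout, depth 2000 per replicate
(per-replicate depths for the original 454 runs are unpublished; 2000 is
a plausible 454-era amplicon depth and keeps tests fast), $\theta = 50$
(moderate overdispersion consistent with the fitted values on the
reconstructed tables). Block effects enter only the yield model
(`simulate_yields()`: cell mean + experimenter effect + residual on the
log scale), because composition was found consistent across
experimenters. `simulate_reads()` turns every count into one barcoded
read with a randomly chosen degenerate-primer expansion and per-base
substitution errors, keeping ground truth in the read id; auto-generated
templates avoid ≥ 7-bp homopolymers so pristine reads pass QC by
construction.

`table4_fixture()` deserves a caveat it also carries in its
documentation: it *reconstructs* per-replicate counts from published
per-method means and SDs (truncated-normal jitter, renormalization,
largest-remainder integerization), because the raw counts are
unpublished. The printed SDs are targets in expectation only — a single
8-replicate fixture's mean carries jitter error up to
$\mathrm{sd}/\sqrt{8} \approx 0.033$ for the most variable taxon — so
expectation-level checks in the tests average over several fixture draws.
A green test on this fixture establishes that the pipeline reproduces the
benchmark's *conclusions* (every method rejected, method ranking by
distance), not that it reproduces unpublished raw data.

What the generator does not emulate: PCR chimeras, flowgram-specific
homopolymer miscalls, quality-score profiles, taxonomic misassignment,
and any correlation structure between taxa beyond the exchangeable
Dirichlet. Green tests therefore do not certify robustness to those
artifacts.

## Numerical choices, in one place

- $\theta$ search bounds $[10^{-2}, 10^8]$ on the log scale; $10^8$ is
  the declared multinomial ceiling; boundary promotion at $10^{-6}$
  relative likelihood tolerance.
- Alternative-fit convergence: $|\Delta\ell| < 10^{-8}$, max 500 sweeps,
  $\theta$-profile acceleration every 20th sweep; non-convergence is
  flagged and warned, never silent.
- $\Lambda$ clipped to zero below $10^{-6}$; bootstrap p uses the
  $(1 + \text{exceedances})/(B+1)$ estimator.
- Percent formatting: half-up rounding, 1 dp, presentation layer only.
- Largest-remainder apportionment when converting proportions to integer
  counts at fixed depth (columns sum exactly to the depth).
- Proportion vectors validated to sum to 1 within $10^{-9}$.

## Known limitations

The overdispersion model is a stand-in chosen for being the standard
exchangeable choice; if the original analysis used a different mixture
parameterization, fitted $\theta$ values are not directly comparable even
though the test logic is. Per-replicate depths, raw counts and raw yield
replicates behind the packaged summaries are unpublished, so every
count-level "reproduction" is a labelled reconstruction, and quantities
that depend on raw per-replicate spread (published pairwise p-values,
boxplot magnitudes) are covered by property-based calibration tests
rather than numeric reproduction. The split-plot ANOVA requires balance;
the Tukey letters use a per-sample error term by design. Exact Wilcoxon
is only attempted where R's exact machinery applies.
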