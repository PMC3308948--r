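---
title: "Methods: growth-curve fitness, sequence divergence and codon usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth-curve fitness, sequence divergence and codon usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platefit)
```

`platefit` measures the fitness cost of replacing an essential gene with a
heterologous ortholog, using microplate growth kinetics as the fitness
proxy and sequence-level divergence measures as candidate predictors. This
vignette is the package's own account of the methods: the model, the
estimation choices, the statistical conventions, what the simulator does
and does not emulate, and the numerical decisions a maintainer would want
written down.

## The growth model

A bacterial batch culture read hourly in a plate reader produces a sigmoid
OD600 trajectory: a lag/acceleration phase, a near-exponential rise, and a
saturation at carrying capacity. We model one well's readings with a
fixed-shape Richards curve,

$$
\mathrm{ABS}(t) \;=\; \mathrm{ABS}_{\min} +
  (\mathrm{ABS}_{\max} - \mathrm{ABS}_{\min})
  \left[\, 1 + m\, e^{-\mu_{\max}\, m\, (t - t_i)} \right]^{-1/m},
$$

which is the solution of the Richards growth equation
$\mathrm{d}A/\mathrm{d}t = \mu_{\max} A \left(1 - (A/K)^m\right)$ for the
above-baseline absorbance $A = \mathrm{ABS} - \mathrm{ABS}_{\min}$,
re-parameterised so that the time of inflection $t_i$ is itself a
parameter.

Properties that follow from this form, and that the test suite pins down:

* the curve is strictly increasing with limits
  $\mathrm{ABS}_{\min}$ ($t \to -\infty$) and $\mathrm{ABS}_{\max}$
  ($t \to +\infty$);
* its inflection (zero second derivative, maximal slope) falls *exactly* at
  $t = t_i$ — so TTI is estimated as a parameter, not read off a fitted
  curve afterwards;
* the maximal slope is
  $(\mathrm{ABS}_{\max}-\mathrm{ABS}_{\min})\,\mu_{\max}\, m\,(1+m)^{-(1+1/m)}$;
* as $m \to 1$ the curve becomes the symmetric logistic with inflection at
  half height; smaller $m$ pushes the inflection below half height, the
  asymmetry plate-reader curves actually show.

**Why this parameterisation.** With the equation written this way,
$\mu_{\max}$ is the exponential-phase specific growth rate of the
above-baseline signal — the quantity with units h⁻¹ that growth-rate
comparisons intend — rather than the raw maximal slope in OD/h. The choice
matters because the two conventions differ by a factor
$(\mathrm{ABS}_{\max}-\mathrm{ABS}_{\min})\, m\,(1+m)^{-(1+1/m)}$. At the
magnitudes typical of these experiments (µmax ≈ 0.65–0.75 h⁻¹, TTI ≈
6.5–9.5 h, OD range ≈ 0.05–1.0) the specific-rate reading produces curves
that rise over roughly ten hours and saturate within a 21–23 h run, which
is what the assays show; the max-slope reading would compress growth into
~2 h and leave hourly sampling with almost no informative points.

**The dampening parameter `m` is a constant, not a fitted parameter.** It
is fixed at 0.5 by default (`richards_params(..., m = 0.5)`); fixing the
shape is what makes µmax identifiable from absorbance data at hourly
resolution. Every report records the value in force.

## Fitting one well

`fit_richards()` minimises $\sum_t (\mathrm{OD}_t - \mathrm{ABS}(t))^2$
over the four free parameters by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`), with `m` fixed. Choices, all recorded in the object
or the pipeline log:

* **Raw OD is fitted** — no blank subtraction, no log transform. The model
  has an explicit $\mathrm{ABS}_{\min}$, so the blank is estimated rather
  than assumed; readers who prefer blank correction can apply it upstream.
* **Box constraints** keep asymptotes from running away on truncated
  curves: $\mathrm{ABS}_{\min} \in [0, \max \mathrm{OD}]$,
  $\mathrm{ABS}_{\max} \in (0, 2\max \mathrm{OD}]$,
  $\mu_{\max} \in (0, 5]$ h⁻¹, $t_i \in [0, 1.5\, t_{\mathrm{last}}]$.
* **Initialisation is read off the data** (`initialize_richards()`):
  asymptotes from the OD range, $t_i$ from the midpoint of the steepest
  discrete-slope interval (the *earliest* such interval on ties), µmax by
  inverting the maximal-slope identity above.
* **Deterministic restarts.** After the first attempt, six perturbed
  starting points (a fixed multiplicative grid — no RNG, so fits are
  bit-reproducible) are always tried and the best converged solution kept;
  up to 20 are tried if nothing converges. Convergence tolerance is
  $10^{-10}$ on the relative RSS change, 500 iterations per start.
* **No-growth guard.** A well whose OD dynamic range is below 0.05 OD
  (configurable) raises a classed "no-growth" error instead of returning a
  meaningless fit. `fit_growth_curves()` converts per-well failures into
  `converged = FALSE` rows with the message in a `note` column.
* A curve needs at least 6 distinct time points (four free parameters plus
  two) to be fitted at all.

Fits are per replicate well by default; the clone is the unit of
replication downstream. `fit_growth_curves(average_replicates = TRUE)`
switches to fitting each clone's replicate-averaged curve instead — the
two routes agree closely on clean data, but per-replicate fitting keeps
within-clone variability visible, so it is the default.

On noise-free model output the generating parameters are recovered to
better than $10^{-6}$ relative error; across 200 simulated curves at the
default noise (σ = 0.005 OD, hourly sampling 0–22 h) the mean bias of
µmax is below 1% and of $t_i$ below 0.05 h — the test suite and
`scripts/acceptance.R` recompute both.

## From fits to fitness

`summarise_fitness()` aggregates clone-first: each clone's value is the
mean over its replicate wells, so lineage SDs reflect clone-to-clone
variability (the biological question) rather than pipetting noise. Lineage
means are then expressed relative to the *within-plate* control
(`relative_to_control()`); control rows are set to exactly 1, the
convention under which this kind of experiment is reported. Ratios are
never taken across plates: each microplate is one experiment with its own
control.

The lineage contrast is a two-sided **Welch** (unequal-variance) t-test on
clone values, chosen because the design is strongly unbalanced (typically
23 test vs 5 control clones). The significance flag defaults to
α = 0.001, mirroring the asterisk convention of the reports this package
emulates; the α in force, the test used, and the absence of any
multiple-testing correction (contrasts are per-experiment) are all written
to the report log. Degenerate inputs follow fixed conventions: both groups
constant and equal means → p = 1; constant but different → p = 0.

One calibration caveat, documented here deliberately: with only five
control clones the Welch–Satterthwaite approximation is intrinsically
slightly liberal (its true type-I rate at α = 0.05 sits a little above
0.05). The suite's Monte-Carlo calibration check makes this visible rather
than hiding it; at the stringent α = 0.001 used for reporting, the
practical effect on the significance pattern is negligible.

`regress_fitness_on_covariate()` is ordinary least squares of one relative
parameter on one covariate, reporting slope, intercept, Pearson r, r², and
the slope's two-sided p-value; `screen_initial_density()` reuses it to ask
whether per-experiment mean µmax or TTI is explained by the starting
inoculum density — the classic artefact to rule out before interpreting
TTI differences as biology.

## Sequence divergence

`p_distance()` is the proportion of differing residues over aligned columns
where both sequences carry a standard amino acid. Columns with a gap in
either sequence are excluded — *complete deletion over the pair*, the
default; `protein_divergence(gap_policy = "complete")` instead drops every
column gapped anywhere in the set, so all pairs share one site set.
Alignment itself is an input (aligned FASTA); this package does not align.

`jtt_distance()` estimates the evolutionary distance $d$ (expected
substitutions per site) by maximising the pairwise likelihood
$\ell(d) = \sum_s \log\left[\pi_{a_s} P_{a_s b_s}(d)\right]$ under the JTT
empirical amino-acid model with uniform rates across sites.
$P(d) = e^{Qd}$ is computed from the packaged JTT-92 exchangeabilities and
equilibrium frequencies (`inst/extdata/jtt_rate_matrix.tsv`, provenance in
the file header), assembled into a reversible rate matrix normalised to
one expected substitution per unit distance and eigendecomposed once (via
the $\sqrt{\pi}$ symmetrisation, for numerical stability). Site patterns
are collapsed to a 20×20 count table before optimisation, so cost is
independent of alignment length. The one-dimensional maximisation uses
`stats::optimize` on $[10^{-9}, 10]$; estimates at the upper bound are
flagged `converged = FALSE` (saturation). A curvature-based standard error
$1/\sqrt{-\ell''(\hat d)}$ accompanies each estimate. Identical sequences
return $\hat d = 0$ exactly.

The estimator's behaviour is verified against simulation truth (median
within 5% at $d \in \{0.1, 0.27, 0.5, 1.0, 1.72\}$, the range spanned by
the rnpA heterolog pairs), against the $d \to 0$ limit where $\hat d$
collapses onto the p-distance, and — as an independent cross-check only —
against `phangorn::dist.ml`.

## Codon adaptation

`cai()` is the geometric mean of per-codon relative adaptiveness $w$
against a high-expression reference set. Conventions (CodonW-compatible,
all configurable or documented):

* stop codons are excluded; an internal stop triggers a warning naming the
  codon positions;
* Met (ATG) and Trp (TGG) are excluded from the mean — single-codon
  families carry no bias information;
* $w$ values of exactly zero (unobserved reference codons) are floored at
  0.01 so CAI never reaches zero; observed-but-rare codons keep their true
  small $w$;
* sequence length must be divisible by 3; U is accepted for T.

The packaged reference (`cai_weights_ecoli()`) is the classical *E. coli*
high-expression set; `relative_adaptiveness()` builds a $w$ table from any
user-supplied reference codon-usage counts (per amino acid,
$w = \mathrm{count}/\mathrm{count_{max}}$; every amino acid has exactly one
$w = 1$ codon in the packaged table, and ties in user tables simply yield
several $w = 1$ codons, with the alphabetically first treated as "the"
optimal codon by the gene generator).

## The synthetic-data module

`simulate_plate()` emulates the experimental design this analysis targets:
one test lineage × 23 clones and a control × 5 clones, in triplicate,
OD600 read every full hour for 22 h. Defaults are the design constants;
where the design leaves a quantity unstated, the default is a value chosen
once as realistic for this instrument class and scale:

| parameter | default | meaning |
|---|---|---|
| `noise_sd` | 0.005 OD | additive Gaussian reading noise, truncated at 0 |
| `clone_cv` | 0.02 | lognormal CV of clone-level µmax and t_i around lineage means (reproduces lineage SDs of ≈0.01–0.035 on µmax at these magnitudes) |
| `inoculum_sd` | 0.15 | lognormal sdlog of each clone's inoculum dilution factor |
| `inoculum_effect` | 0 | coupling of inoculum to TTI: a clone inoculated z-fold denser inflects `effect·log(z)/µmax` h earlier |

The clone draws are lognormal (mean-preserving) so parameters stay
positive. The emitted per-clone `initial_od` is the inoculum factor times
the noise-free model value at `t_start`; with `inoculum_effect = 0`
initial density varies but is independent of TTI, which is exactly the
negative result the initial-density screen should report — and with the
effect on, the screen detects the coupling. Everything is a pure function
of (arguments, seed), and the caller's RNG state is restored.

What the simulator does **not** emulate, and hence what passing tests do
not establish about real plates: mechanistic lag-phase physiology (the lag
is only the model's own early phase), edge/position effects and
well-to-well optical artefacts, heteroscedastic or autocorrelated reader
noise, condensation spikes, evaporation late in the run, and any
departure of real growth from the Richards shape itself. Parameter
recovery on simulated data bounds estimation error *given the model*; it
cannot validate the model against a particular instrument.

`simulate_jtt_pair()` draws ancestral sites from the JTT equilibrium and
descendants from $P(d)$ row-wise — the pair is aligned by construction and
its true distance is exactly $d$. `generate_biased_gene()` samples codons
from a mixture of the optimal codon (weight `bias`) and uniform synonymous
usage, giving a monotone handle on CAI.

## Problem sizes and run times

The test suite and acceptance script use sizes chosen to make the
statistical checks sharp while keeping a full run at desk scale: 200
curves for recovery bias, one full plate (84 wells) for end-to-end
recovery, alignments of 5,000–20,000 sites and 20 replicate seeds per
divergence for the JTT estimator, 10,000 null replications for the Welch
calibration and 1,000 for the regression-p uniformity check. A complete
`testthat` run and an acceptance-script run each finish in about a minute
on one core.

## Known limitations

* Absolute µmax and TTI values depend on strain, medium and instrument;
  the packaged per-experiment summary table is used for ratio arithmetic
  and as realistic simulator magnitudes, not as something the package can
  re-derive from raw data it does not have.
* Single-fit uncertainty is not propagated; inference lives at the clone
  level across a lineage (by design — see the aggregation section).
* The JTT distance assumes uniform rates across sites; no gamma
  heterogeneity, no nucleotide or codon models, no tree building.
* The Welch contrast is slightly liberal at n = 5 per the calibration note
  above; at the reporting threshold of α = 0.001 this is immaterial, but
  exact small-sample inference is out of scope.
* Carrying-capacity (ABS_max) comparisons are deliberately not part of the
  fitness report; the model estimates the asymptote but the pipeline
  treats µmax and TTI as the fitness proxies.
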