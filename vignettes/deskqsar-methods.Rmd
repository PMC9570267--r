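---
title: "Methods: reactivity descriptors, drug-likeness rules and small-n QSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reactivity descriptors, drug-likeness rules and small-n QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deskqsar)
```

# Scope

`deskqsar` implements the desk-scale computational chain used to evaluate a
small panel of thiouracil-based dihydroindenopyridopyrimidine (TUDHIPP)
anticancer candidates (compounds 2H, 6H, 7H, 9H, with etoposide as the
reference drug): quantum-method benchmarking against X-ray bond lengths,
conceptual-DFT global reactivity descriptors, drug-likeness screening,
docking-energy thermodynamics, and multilinear-regression (MLR) QSAR against
cytotoxicity IC50 values. The upstream electronic-structure and docking
computations (DFT geometry optimization, PCM solvation, AutoDock searches)
are out of scope: their outputs — orbital and total energies, binding
energies — are consumed as tabular inputs. The study tables are bundled as
CSV fixtures; a seeded synthetic generator provides arbitrarily large panels
with the same structure.

# Method benchmarking

Bond lengths computed by each method/basis combination are compared with
X-ray reference values through

$$A\% = 100 \cdot \frac{\operatorname{mean}_i |r_i^{\text{calc}} - r_i^{\text{exp}}|}{\operatorname{mean}_i\, r_i^{\text{exp}}},$$

a mean absolute deviation normalized by the mean experimental bond length.
The normalization makes $A\%$ invariant to a common unit change and zero
exactly when the method reproduces experiment. The formula admits a second
reading (mean of per-bond ratios instead of ratio of means); on the bundled
12-bond thiouracil table the two differ by less than 0.01, and the ratio of
means is used as the primary definition. Recomputing from the 3-decimal
table values gives 1.097 for B3LYP/6-311++G(d,p) against the published
1.102 — a discrepancy consistent with the authors computing from unrounded
values — so comparisons against printed $A\%$ use an absolute band of 0.02.
Ranking is a stable ascending sort; ties keep column order.

# Global reactivity descriptors

With the Koopmans-style identification $I = -E_{\text{HOMO}}$,
$A = -E_{\text{LUMO}}$ (hartree converted at 27.211386 eV/hartree):

$$E_g = I - A,\quad \chi = \tfrac{1}{2}(I + A),\quad V = -\chi,\quad
\eta = \tfrac{1}{2}(I - A),\quad S = \frac{1}{2\eta},\quad
\omega = \frac{\chi^2}{2\eta},\quad N = I_{\text{TCE}} - I.$$

Two choices deserve comment:

* **Softness.** The source prints the softness relation as $S = \eta/2$,
  which contradicts its own data ($\eta = 1.73$ alongside $S = 0.29$).
  The package implements $S = 1/(2\eta)$, which reproduces every printed
  softness value; the identity $S \cdot \eta = 1/2$ is enforced as a test
  invariant.
* **The nucleophilicity reference.** $I_{\text{TCE}}$, the ionization
  energy of tetracyanoethylene, is never printed. Every row of the
  descriptor table implies $I_{\text{TCE}} = N + I$, and all seven usable
  rows give 4.21 eV with zero spread (`calibrate_i_tce()`), so 4.21 eV is
  the default. This is an empirical fitted constant: it does not match
  typical computed ionization energies of tetracyanoethylene, and the
  package attaches no physical endorsement to it. It is exposed as an
  argument everywhere it enters.

All intermediates are kept at full precision; rounding to the table's two
decimals happens only at reporting. This matters: the 9H aqueous
electrophilicity is 6.83 from unrounded intermediates but 6.85 if $\chi$
and $\eta$ are first rounded.

The bundled orbital-energy table carries one flagged row: the source prints
two "aqueous" rows for compound 9H, the first a verbatim duplicate of the
7H aqueous row. The duplicate is stored with `suspect = TRUE` and skipped
by default; the 9H gas-phase orbital energies are unrecoverable. Solvation
energies are the aqueous-minus-gas total-energy differences in eV; all four
compounds come out stabilized in water (about $-0.8$ to $-1.0$ eV).

# Drug-likeness screening

Three rule engines operate on the physicochemical table:

* **Lipinski rule of five** — logP $\le 5$, MW $\le 500$ Da, H-bond donors
  $\le 5$, acceptors $\le 10$; inclusive thresholds per the rule's "$\le$"
  phrasing. The score counts satisfied criteria and a compound passes with
  at most one violation.
* **Veber criteria** — rotatable bonds $< 10$ and polar surface area
  $< 140$ Å²; strict thresholds per the rule's "under" phrasing. The PSA
  column is treated as TPSA, as the two are used interchangeably upstream.
  All study compounds sit far from both rule boundaries, so the
  inclusive/strict choices do not affect any fixture classification.
* **Golden Triangle** — membership in a triangle of the (logD$_{7.4}$, MW)
  plane. The exact geometry used upstream is not printed; the default
  policy uses the published construction — base on MW = 200 from logD $-2$
  to $5$, apex at $(1.5, 450)$ — with inclusive boundaries. This default
  reproduces all three documented classifications (2H and 7H inside, 9H
  outside) and additionally places 6H outside, a derived outcome the source
  is silent on. The point-in-triangle test uses sign-consistency of the
  three edge cross products, making it invariant to vertex ordering and to
  consistent affine rescaling of point and vertices.

# Binding thermodynamics

The docking tables report binding free energies and inhibition constants
without stating the conversion. The package adopts the AutoDock convention

$$K_i = e^{\Delta G / RT}, \qquad R = 1.98720425 \times 10^{-3}
\ \text{kcal mol}^{-1}\text{K}^{-1},\ T = 298.15\ \text{K},$$

which reproduces all ten published $K_i$ values within 1%. The default
verification tolerance of 1% relative is not arbitrary: $\Delta G$ is
printed to 2 decimals, and $\pm 0.005$ kcal/mol propagates to roughly
$\pm 0.85\%$ in $K_i$. Consistently, the same energy $-9.29$ kcal/mol is
printed with two different $K_i$ values (155.7 and 154.3 nM) that bracket
the exact conversion (155.0 nM).

# QSAR

Activities enter through one of four response transforms: IC50 itself,
$1/\text{IC50}$, $\log_{10}(1/\text{IC50})$ and $\log_{10}(\text{IC50})$
(the last two exact negations of one another, an identity carried through
to predictions). IC50 is in µM throughout; quantum descriptors enter in eV;
no standardization is applied, since the reported regression equations are
in raw units.

The regression is ordinary least squares with intercept, solved through the
SVD pseudoinverse. This is deliberate: the study panel has $n = 4$
compounds, while the reported equations carry 5–8 descriptors, so the
least-squares problem is underdetermined and ordinary solvers are
non-unique. The package returns the minimum-norm solution, sets an
`underdetermined` flag, computes $r^2$ on the fitted values (1 up to
numerical tolerance for exact interpolation), and leaves standard errors
and adjusted $r^2$ undefined. A constant response yields $r^2 = 0$ by
convention (no explainable variance); reported $r^2$ is clamped to $[0,1]$
with the raw value retained as an attribute.

The reported equations themselves are not reproducible from the reported
data: evaluating the first model's printed coefficients on the 2H gas
descriptors gives $\approx -171.1$, far from the observed 22.80 µM, and the
published $r^2$ values (0.9682, 0.9924) are inconsistent with exact
interpolation at $n = 4$. The regression behind them plausibly included
compounds whose descriptors are not printed. The package therefore treats
those equations as evaluable artifacts (`apply_model()`) without certifying
them, and the honest statistical behavior at $n = 4$ — interpolation with a
loud flag — is what the tests assert.

Forward stepwise selection greedily adds the candidate maximizing $r^2$,
stopping at `max_terms`, when the improvement drops below $10^{-6}$, or
before a step would make $p + 1 \ge n$; ties break by candidate order. A
model-acceptance gate of $r^2 > 0.6$ mirrors upstream practice for
considering a model for validation.

One phase note: quantum descriptors default to the gas phase in
`model_spec()`, but the four-compound design matrix can only be built from
aqueous-phase descriptors, because the gas-phase 9H row is the
unrecoverable duplicate. The pipeline default configuration therefore uses
the aqueous phase; the phase remains a per-model choice.

# Synthetic data generator

`simulate_compounds()` emulates the structure of the study tables:

* Orbital energies uniform on $E_{\text{HOMO}} \in [-0.26, -0.19]$,
  $E_{\text{LUMO}} \in [-0.13, -0.09]$ hartree — disjoint ranges spanning
  the observed values, so the orbital ordering holds by construction — and
  all derived descriptors computed through the same code path, so the
  identities $S\eta = 1/2$, $E_g = I - A$, $V = -\chi$ hold exactly.
* Physicochemical descriptors uniform over the observed four-compound
  min/max padded by 10% of the span (logP and MW use the wider conventional
  screening ranges $[-3, 3]$ and $[300, 500]$); count descriptors are
  sampled as integers. Uniform distributions are an explicit modelling
  choice: four observed compounds cannot support a distributional estimate.
* Activities from a configured true linear model on the transformed
  response scale plus Gaussian noise, back-transformed to IC50. The default
  transform is $\log_{10}(1/\text{IC50})$ (the pIC50 convention), which
  guarantees positive IC50 for any noise draw; identity/reciprocal
  configurations are validated and refused if they produce non-positive
  activities. Censoring removes exactly `round(n * fraction)` activities.

What the generator does *not* emulate: realistic correlation between
physicochemical descriptors (they are drawn independently; only the
quantum-descriptor identities induce dependence), measurement error in the
descriptors, and any relation between structure and activity beyond the
configured linear model. Recovery experiments therefore demonstrate the
correctness of the fitting machinery under its own assumptions, not the
realism of linear QSAR for real panels.

`recovery_experiment()` refits the true descriptor set over replicates
(replicate $r$ seeded at `base_seed + r`) and reports per-coefficient bias,
RMSE and empirical 95% t-interval coverage. At the default experiment size
used in the tests ($n = 200$ compounds, 3 coefficients,
$\sigma = 0.1$, 200 replicates — about 1.5 s) bias is below 0.002 and
coverage within 0.01 of nominal; RMSE scales as $\sigma/\sqrt{n}$, checked
at two grid points.

# Numerical and interface choices

* Hartree→eV fixed at 27.211386; comparisons with 2-decimal printed cells
  use a ±0.02 absolute band, with 3-decimal bond lengths ±0.02 on $A\%$.
* CSV dialect: comma-separated UTF-8, "." decimal, mandatory header;
  typeset minus (U+2212) normalized to ASCII on read; `"---"` and empty
  cells are explicit missing values, never zero.
* Fixture integrity is guarded by MD5 checksums in the test suite.
* Errors are classed conditions (`deskqsar_schema_error`,
  `deskqsar_validation_error`, ...) so callers can discriminate failure
  modes; the pipeline maps them to a shell-style status contract (0 ok,
  2 configuration, 3 data validation, 4 computation).
* The pipeline surface is the exported `run_pipeline()` (R list or YAML
  config) plus per-stage functions; this package is an analysis library,
  and R sessions/scripts are its intended entry points.

# Known limitations

* The gas-phase descriptors for compound 9H do not exist in the bundled
  data (transcription defect upstream); any gas-phase analysis covers three
  compounds.
* With four compounds, every multi-descriptor fit is underdetermined;
  nothing statistical can be concluded from such fits beyond what the flag
  says, and the package intentionally refuses to dress them up.
* The Golden-Triangle default geometry is validated only by agreement with
  the three documented classifications; other vertex conventions exist.
* $K_i$ verification assumes the AutoDock temperature convention; a
  different upstream $T$ would be absorbed by the 1% tolerance only
  partially.
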