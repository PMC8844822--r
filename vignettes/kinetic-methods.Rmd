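---
title: "Models and methods for multifunctional NAD(P)ase kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multifunctional NAD(P)ase kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadkin)
```

## The kinetic models

Multifunctional NAD(P) glycohydrolases consume one dinucleotide and release
two products in order: the pyridine base first, then the ADP-ribosyl moiety,
resolved by water (hydrolysis), intramolecular attack (cyclization) or a
free pyridine base (base exchange). `nadkin` works with five steady-state
rate laws for this family, all with fixed package-wide units — substrate and
inhibitor concentrations in µM, mass-specific rates in mU/mg
(1 U = 1 µmol/min, so mU/mg ≡ nmol·min⁻¹·mg⁻¹), turnover in s⁻¹,
efficiency in M⁻¹s⁻¹:

* **eq1**, the Michaelis–Menten hyperbola, describes enzymes without
  substrate inhibition (CD38-like, cyclase-like behaviour).
* **eq2** adds uncompetitive substrate inhibition at the catalytic site:
  $v = V_\max S / (K_m + S(1 + S/K_{is}))$. The rate peaks at
  $S_{opt} = \sqrt{K_m K_{is}}$ with
  $V_{opt} = V_\max/(1 + 2\sqrt{K_m/K_{is}})$ and decays as $1/S$ beyond.
* **eq3** multiplies in a second, allosteric-site inhibition term:
  $v = V_\max S / \big((K_m + S(1 + S/K_{is}))(1 + S/K_{ia})\big)$ —
  the model for an auto-inhibited enzyme whose regulatory domain also binds
  the substrate.
* **eq4** is the one-site dose response, activity $= 1/(1 + I/IC_{50})$.
* **eq5** is multi-site mixed inhibition,
  $v = V_\max S / \big(K_m(1 + (I/K_i)^n) + S(1 + (I/(aK_i))^n)\big)$,
  valid where substrate inhibition is negligible. The multiplier $a$
  encodes the type (competitive in the $a\to\infty$ limit, purely
  noncompetitive at $a = 1$, mixed otherwise) and the stoichiometry $n$ the
  number of inhibitor molecules binding.

Inhibition constants that the data cannot bound are a first-class concept:
they are stored as `Inf`, which makes the corresponding denominator term
exactly 1 in IEEE arithmetic, so eq3 reduces *exactly* to eq2 and eq1 in the
respective limits — there is no "large number" approximation anywhere, and
no instability from fitting near-infinite constants. In fitted results the
same state is reported as censored ("> 8000 µM", the conventional reporting
bound for these assays).

## Identifiability of the dual-site law

eq3 has a structural non-identifiability that any fitting strategy for it
must confront. When only one site is active, the two attributions coincide
exactly: a pure allosteric-site curve $(K_m, V_\max, K_{ia})$ equals a pure
catalytic-site curve with

$$K_{is}' = K_{ia} + K_m,\quad
  K_m' = \frac{K_m K_{ia}}{K_m + K_{ia}},\quad
  V_\max' = \frac{V_\max K_{ia}}{K_m + K_{ia}},$$

so single-site data determine only three parameter combinations and the
likelihood surface has an exact ridge. The inverse mapping has real
solutions only when $K_{is} \ge 4K_m'$; a catalytic-site curve violating
that bound (e.g. $K_{is} = 151$ µM with $K_m = 83.5$ µM) *cannot* be
represented allosterically, so such data do identify the site. Only when
both sites are genuinely finite does the $S^3$ term in the denominator make
all four parameters identifiable.

`fit_rate_model(..., "eq3")` therefore fits three variants — allosteric-only
($K_{is}$ fixed unbounded), catalytic-only ($K_{ia}$ fixed unbounded), and
the general model — and picks the best residual sum of squares, resolving
ties (relative 10⁻³, with an absolute floor so exact fits tie) in favour of
the reduced attributions, allosteric first. The allosteric-first order
reflects the biology of the auto-inhibited full-length enzyme, whose ARM
regulatory domain is the established low-affinity substrate binder; the
catalytic attribution still wins whenever the data demand it (the
$K_{is} < 4K_m$ regime), and the general model wins whenever it fits
strictly better. The tie-break is deterministic, so repeated fits of the
same data always return the same attribution.

## Fitting

All estimation is unweighted nonlinear least squares on untransformed rates
(box-constrained Levenberg–Marquardt, `minpack.lm`). Double-reciprocal
plots are diagnostics only, never used for estimation: OLS on reciprocals
would implicitly upweight the smallest rates.

**Initialization and multistart.** Starting values follow the curve shape:
$V_{\max,0}$ = maximum observed rate (doubled for substrate-inhibited
models, whose observed maximum underestimates $V_\max$); $K_{m,0}$ = the
substrate giving half the maximum rate; inhibition-constant starts = the
largest tested substrate; $K_{i,0}$ = the median inhibitor level; $a_0 = 1$,
$n_0 = 1$. Each fit is repeated over a deterministic 0.3× / 1× / 3× grid on
$K_m$ and the inhibition constants and the lowest RSS wins, ties to the
first start in order, so fits are exactly reproducible.

**Bounds and flags.** All parameters are constrained positive; $n$ is
constrained to [1, 6] (a sub-unity stoichiometry has no mechanistic meaning
here; estimates pinned at a bound are flagged, and $n$ is reported to two
decimals since non-integer values are allowed during fitting). An $a$
estimate pinned at its upper bound is the competitive limit and is flagged
censored. Inhibition constants above 8000 µM are reported censored.

**Model selection** among eq1/eq2/eq3 uses AICc
($n\log(\mathrm{RSS}/n) + 2k + 2k(k+1)/(n-k-1)$, $k$ counting the error
variance), preferring the simpler model whenever its AICc is within 2 of
the minimum. Selection requires a ≥ 30-fold substrate range — narrower
designs cannot distinguish the laws.

**Inhibition classification** follows the fitted $a$: competitive when $a$
is censored at its bound, noncompetitive when $a \in [0.8, 1.25]$ and
$n \in [0.9, 1.1]$, mixed otherwise. The verbal rule ($a = \infty$ / $a = 1$
/ otherwise) needs numeric tolerances to be decidable on noisy estimates;
these windows are wide enough to absorb 5% noise and narrow enough that
$a = 0.5$ is never called noncompetitive. Secondary replots (Lineweaver–Burk
slope and intercept against $I$) are flagged nonlinear when a quadratic term
improves the line (partial F-test, p < 0.05) — the signature of $n > 1$. On
the primary reciprocal plot the relevant alternative is different: substrate
inhibition contributes an $S/(V_\max K_{is})$ term to $1/v$, i.e. a
$1/(1/S)$ term, so the curvature test augments the line with that term
rather than a quadratic.

**Competition analysis.** The effector titration fits eq3 to each level
separately (no shared parameters — single-curve fits keep levels
independent), extracts $K_{ia}$ and the curve maximum per level, and
regresses both on effector concentration. The verdict is
"competitive-allosteric" iff the $K_{ia}$ slope is positive with two-sided
OLS p < 0.05 *and* the curve maxima increase monotonically; levels whose
$K_{ia}$ came back censored carry no point value and are excluded from the
replot (at least 3 bounded levels are required).

## Product accounting

Initial rates are taken over the longest prefix of time points with
cumulative consumption ≤ 20% of starting substrate (configurable) and total
product accumulation still linear, screened by the $R^2$ of an OLS line
with default threshold 0.98 — strict enough to reject visible curvature on
our fixtures while accepting exact lines; no formal statistic is implied,
it is a screening proxy. Rates are unweighted free-intercept OLS slopes.
Specific activity counts *products formed* (not substrate consumed), per
the unit definition: total product rate (µM/min = nmol·mL⁻¹·min⁻¹) divided
by protein (µg/mL) × 1000 gives mU/mg.

Mass balance compares consumed substrate, summed products and released base
at every time point (default tolerance 5%, configurable; the assays this
emulates match closely but publish no tolerance). Metabolite levels are
corrected by internal-standard recovery (spiked/recovered cAMP) with a
recovery floor of 0.5 as a QC guard — observed recoveries in practice are
≥ 96%, so the floor only catches failed extractions.

## The synthetic-data generator

The generator emulates the study design, not the chromatography:

* **Initial-rate grids.** Default 12 log-spaced substrate points from 15 to
  4000 µM (the assayed range) and 8 inhibitor points from 10 to 300 µM;
  mixed-inhibition grids use substrate 15–600 µM (where substrate inhibition
  is negligible) and inhibitor levels 0/25/50/80/120 µM. Noise is
  multiplicative, mean-one Gaussian with CV 0.05 by default — the paper-like
  scatter of replicate HPLC initial rates; the true replicate error
  structure (within- vs between-preparation) is not published, so a single
  multiplicative term is the stand-in. Rates are truncated at zero.
* **Progress curves.** Substrate depletion $dS/dt = -v(S)$ is integrated
  with `deSolve::ode` (lsoda, rtol = atol = 10⁻¹⁰); cumulative consumption
  is allocated to products by *constant* branch fractions, matching the
  observation that product proportions are independent of substrate
  concentration, and competition among supplied bases is deliberately not
  modelled. Released base equals total consumption, so conservation is
  exact by construction and every simulated course passes
  `check_mass_balance` at 10⁻⁶. Exchange into a free base is capped at the
  supplied amount: at exhaustion the branch reallocates pro rata to the
  remaining branches (event recorded), and if no branch remains consumption
  stops — a dinucleotide cannot be consumed without forming a product.

What passing tests on this generator do *not* show: robustness to
heteroscedastic or correlated measurement error, retention-time
misassignment, enzyme inactivation over long assays, or pH/temperature
effects (empirical profiles are handled by `normalize_profile`, never inside
the rate laws).

## Numerical choices

* `curve_maximum` for the dual-site law brackets the peak on a 512-point
  log grid over 10⁻²–10⁶ µM, then golden-section search on log S
  (`stats::optimize`, tol 10⁻¹²); the law has a single interior maximum, and
  the log grid guarantees the bracket. Numeric and closed-form optima agree
  to relative 10⁻⁶ in the single-site limits. Hyperbolic inputs signal
  "no maximum".
* $k_{cat} = V_\max \cdot M \cdot 10^{-3} / (60\,\phi)$ with $V_\max$ in
  mU/mg of crude preparation, molar mass $M$ in kg/mol and purity fraction
  $\phi$. The full-length construct mass used in examples, 80.4 kg/mol, is
  re-derived from the 724-residue sequence (79.4 kDa) plus a C-terminal
  FLAG tag (1.0 kDa).
* Degenerate inputs fail loudly: negative concentrations, all-zero
  profiles, zero-rate reciprocal transforms, windows with < 3 points,
  datasets with fewer than (free parameters + 2) observations, zero total
  activity, recovery below the floor.

## Problem sizes

The test suite and the acceptance script use 100-replicate recovery studies
for the headline constants (medians of refitted IC50, $K_i$, $K_m$,
$K_{ia}$, $K_{is}$), 40-replicate studies for secondary properties, and
16-point progress curves — sizes at which the medians are stable to well
under the 10% acceptance bands while the whole suite runs in well under a
minute. All randomness descends from explicit seeds; every simulated
dataset embeds its truth and seed as attributes, and every run report
embeds its config.

## Known limitations

* The rate laws are empirical steady-state forms; no derivation from
  elementary steps, and no mechanistic link between the eq5 stoichiometry
  $n$ and structural binding sites.
* The dual-site attribution convention (allosteric-first on ridge ties) is
  a modelling choice; on single-site data the reported $K_{ia}$ should be
  read as "the inhibition constant of the active site under the allosteric
  attribution", with $K_{ia} + K_m$ recoverable as the equivalent
  catalytic-site constant.
* Censoring uses the fixed 8000 µM reporting bound rather than
  profile-likelihood intervals; standard errors are asymptotic (from the
  Jacobian at the optimum) and can be optimistic near bounds.
* Global multi-curve fitting across effector levels is out of scope by
  design; each titration level is fitted independently.
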