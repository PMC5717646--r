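---
title: "Steady states and dose response in a kinetic proofreading model with phosphatase feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady states and dose response in a kinetic proofreading model with phosphatase feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(tcrkpr.quiet = TRUE)
library(tcrkpr)
```

## The model

A T cell decides within minutes whether a ligand bound to its receptor is
foreign.  The model implemented here captures the first stage of that
decision with two ingredients: *kinetic proofreading* — the bound
receptor–ligand complex must survive `N` sequential phosphorylation steps
before it signals — and *negative feedback* through the phosphatase SHP-1,
which is activated by singly phosphorylated complexes and dephosphorylates
all of them.

The state variables are the concentration `S` of active SHP-1 and the
concentrations `C0, ..., CN` (`D0, ..., DN`) of receptor complexes bound to
the agonist (antagonist) carrying `j` phosphorylations.  With mass-action
kinetics:

    S'  = alpha (C1 + D1)(ST - S) - beta S
    C0' = kappa (L1 - sum Cj)(R - sum Cj - sum Dj) + (b + gamma S) C1 - (phi + nu1) C0
    Cj' = phi C[j-1] + (b + gamma S) C[j+1] - (phi + b + gamma S + nu1) Cj
    CN' = phi C[N-1] - (b + gamma S + nu1) CN

and the analogous `D` equations with dissociation rate `nu2` and ligand
total `L2`.  The readout of activation is `CN` (or `CN + DN`), the
concentration of maximally phosphorylated complexes.  All quantities are in
arbitrary concentration/time units; no unit conversion layer is provided.

The **biologically feasible region** is the open set where all
concentrations and all conservation slacks (`ST - S`, unbound ligand,
unbound receptor) are strictly positive.  `feasibility()` reports these
margins and classifies states as interior, boundary or outside, with an
absolute boundary tolerance of `1e-10` (the model's scales in the shipped
examples are of order one or larger, so an absolute tolerance is
unambiguous there; pass `tol` for very small-scale instances).

Two boundary cases of the parameter domain are deliberately admitted:

* `b = 0` (no basal dephosphorylation): the tristable worked example uses
  it, and every formula remains regular because `b` only appears through
  `b + gamma S`.
* `alpha = 0` (no feedback): the kinetic proofreading limit.  With
  `S(0) = 0` the phosphatase stays off and the chain relaxes to a unique
  globally attracting profile; `enumerate_steady_states()` returns that
  single boundary equilibrium.

## Steady-state enumeration

At a steady state, the bound totals `Sigma1 = sum Cj` and `Sigma2 = sum Dj`
satisfy a closed pair of binding-balance equations whose sum reduces to one
scalar equation with a decreasing left side and an increasing right side —
hence a unique root, found by bracketed bisection to relative `1e-12`
(`solve_sigma()`; agonist-only instances use the closed-form quadratic).

With the totals fixed, the steady-state chain equations form a linear
three-term recurrence in `j`.  Normalizing the top of the chain to
`u_N(S) = 1` and back-substituting downwards expresses every `C_j` as
`C_N u_j(S)` with `u_j` a *polynomial* in `S` of degree `N - j` (`u_0` has
degree `N`).  Substituting the SHP-1 balance
`C1 = beta S / (alpha (ST - S))` and the total constraint
`sum C_j = Sigma*` and clearing denominators yields a single polynomial

    p(S) = phi^N [ beta S U(S) - alpha Sigma* u_1(S) (ST - S) ],   U = sum u_j

of degree `N + 1`, with `p(0) < 0` and leading coefficient
`beta gamma^N > 0`.  Its positive roots below `ST` are in one-to-one
correspondence with the positive steady states.  This exact
coefficient-arithmetic elimination was chosen over a sample-and-fit
reconstruction of the same rational expressions: the recurrence is already
polynomial, so interpolation would only add conditioning error.  For
`N <= 3` the package also carries explicit closed-form coefficient lists;
`s_polynomial()` computes both routes by default and raises a hard error if
they disagree beyond relative `1e-9`, a guard against transcription slips
in either form.

Roots are located with `polyroot()` (Jenkins–Traub; the R-native equivalent
of companion-matrix eigenvalues), polished by Newton iteration, filtered to
the positive axis with threshold `1e-14` times the root scale, and merged
when closer than `1e-8` times that scale (merged roots are reported with
multiplicity and flagged as near-multiple).  Descartes' rule of signs bounds
the count: for `N = 2` the coefficient sign pattern is always
`(-, -, +, +)` or `(-, +, +, +)`, so the steady state is unique; for
`N = 3` one or three positive roots can occur.  Back-substitution rejects
(with a warning) any root whose chain coordinates are not strictly positive
or whose full-system residual exceeds `1e-8` times the state scale.  States
are reported sorted by ascending `S`.

The tristable regime is reachable constructively: scaling
`ST = sbar_T / eps` and `nu1 = nubar_1 eps^4` (with `kappa` rescaled so
`nu1/kappa`, and hence `Sigma*`, is unchanged) makes `p(1) < 0` and
`p(eps^2) > 0` for small `eps`, certifying three positive roots
(`epsilon_family()`).

## Stability

`jacobian_matrix()` carries the analytic partial derivatives of the full
system; tests pin it against central finite differences.  `classify()`
labels each equilibrium from the eigenvalue sign pattern, with a
*relative* marginality tolerance (`1e-8` times the largest `|Re lambda|`)
so the decision is scale-free; spectra within the band are labelled
`marginal`, never silently stable.  The unstable-manifold dimension counts
eigenvalues with real part above `+tol` only.

For `N = 1` the limiting system on the invariant set `sum Cj = Sigma*` is
planar and every solution converges to the unique equilibrium, but the
approach can ring.  `find_damped_oscillation_params()` imposes the balance
`alpha C1 + beta = phi + b + gamma S + nu1` at the self-consistent steady
state — under that balance the characteristic discriminant of the 2x2
linearization collapses to `-4 alpha gamma (ST - S) C1 < 0`, forcing a
complex pair with negative real part.  The balance is solved by a nested
procedure: the inner problem (the steady state given `beta`) is the `N = 1`
quadratic; the outer residual is bracketed on a log grid in `beta` and
refined by bisection.  In the full (three-dimensional) system the slow
binding mode relaxes `Sigma1` towards `Sigma*` on a much longer timescale
than the focus spirals, so the demonstration trajectory starts *on* the
invariant set (`C0 + C1 = Sigma*`), where the planar dynamics are exact.

`oscillation_diagnostic()` flags a converged trajectory as showing damped
oscillation when the observable's derivative changes sign at least twice
and the extremum amplitudes (measured from the terminal value) decay, with
the median amplitude ratio below one.  Whether *sustained* oscillations
(periodic orbits) exist anywhere in parameter space is an open question;
the package only reports eigenvalue structure and trajectory diagnostics.

## Dynamics

`integrate_model()` wraps `deSolve::ode(method = "lsoda")` with the
analytic Jacobian, `rtol = 1e-9`, `atol = 1e-12`.  Because the shipped
parameter sets span ten orders of magnitude in rates, the default horizon
is adaptive: integration proceeds in geometrically growing chunks until the
right-hand-side norm falls below `1e-10` times the state scale, or until
`t = 1e6` model time units.  Feasibility margins are tracked along the
saved path; persistence (no approach to the boundary) is asserted in the
test suite on random interior starts.

Multistart basin sampling (`basin_sample()`) draws initial states uniformly
in a margin-respecting way — bound totals uniform under the conservation
caps, split across the chain by a uniform simplex draw, `S` uniform on
`(0, ST)` — and matches each terminal state to the nearest enumerated
equilibrium (relative distance below `1e-4`).  The seed is a required
argument: basin tables are meant to be bitwise reproducible.

## The response function

The steady-state chain admits the two-root parametrization
`Cj = a+ r+^j + a- r-^j`, where `r±` solve
`phi + (b + gamma S) r^2 = (phi + b + gamma S + nu) r` and satisfy
`r- < 1 < r+`.  The boundary conditions of the chain determine `a±` (both
positive) through the bracketed products `A` and `B` and the factor
identity `[phi - (b+gS+nu) r-][phi - (b+gS+nu) r+] = -phi^2 nu/(b+gS)`.
Two numerical precautions matter here: the discriminant is evaluated as
`(phi - b - gS - nu)^2 + 4 phi nu` (manifestly non-negative, no
cancellation), and the factor `phi - (b+gS+nu) r-`, which nearly cancels
when `nu` is small, is computed from its conjugate form.  Without these the
factor identity degrades to ~1e-5 relative error at small `nu`; with them
it holds to ~1e-10.

`response_function()` evaluates the (multi-valued) response
`log10 CN = F(log10 L1, nu1)` by full enumeration at every grid point,
labelling each branch's stability; branches are stitched across the grid by
nearest-neighbour matching in `log S`, and fold points appear as branch
births/deaths.  Two asymptotic companions are provided:

* **Small ligand** (`asymptotic_small_L1()`): `CN` is linear in `L1` with a
  computable prefactor (slope one on log-log axes).  The quadratic
  correction enters through a factor `1 + q L1/R` where only the bracket
  `-1/4 < q < 0` is available, so the result is reported as the `q = 0`
  leading term plus the `q = -1/4` end of the bracket, not as a point
  estimate.
* **Intermediate regime** (`asymptotic_intermediate()`): for large `ST` and
  small `L1/R`,
  `CN ≈ (phi beta/(alpha gamma ST))^(N/2) ((kR + nu1)/kR)^(N/2-1) L1^(1-N/2)`.
  For `N > 2` the exponent of `L1` is negative — more ligand, *less*
  response — and the `nu1` factor is increasing, which is what makes an
  interior optimum of the dissociation rate possible.  The smallness
  parameters `eta = (phi + nu1)/(b + gamma S)`,
  `eta' = max(eta, b/(gamma S))`, `eta'' = max(eta', L1/R)` are returned;
  the `regime_ok` flag drops when `eta'' > 0.25` (a conventional threshold:
  beyond it the leading-order error is no longer small).

With an antagonist present, both chains share `S` and the same recurrence
structure, differing only through `nu1` vs `nu2`.
`antagonist_steady_states()` substitutes both chain profiles into the
SHP-1 balance and locates *all* roots of the resulting scalar equation in
`S` by a dense sign scan — `1e4` log-spaced points across twelve decades
below `ST` plus a refinement ladder approaching `ST` — followed by
bisection.  A dense scan was preferred over continuation because up to
three solutions must not be missed and the scan is cheap at this dimension.
The intermediate-regime estimate for `CN + DN` follows from the agonist
formula by the replacement
`kR L1/(kR + nu1) -> kR L1/(kR + nu1) + kR L2/(kR + nu2)`; for `N = 3` it
is decreasing in `L2`, i.e. self-ligand suppresses the response to the
agonist through the shared feedback, and the exact solver agrees in sign.
Where the qualitative direction of the `L2` effect could be stated either
way, the package reports the computed sign rather than asserting one.

## Parameter sweeps

`scan_parameter()` sweeps one parameter, tracks branches with the same
nearest-neighbour rule, and brackets fold (saddle-node) points by bisection
on the root count to relative width `1e-3`.  Two of the shipped example
configurations deserve a note: the ligand-sweep configuration
(`example_fig2.yaml`, `nu1 = 1`) and the tristable text example
(`example_text_3steady.yaml`, `nu1 = 1e-4`) differ only in `nu1`, and both
are shipped as-is.  At `nu1 = 1` the package finds a single steady state for
every `L1` across twelve decades, whereas at `nu1 = 1e-4` the sweep shows a
clean fold (one-to-three states near `L1 ≈ 0.7`).  The branch-diagram
machinery is therefore demonstrated and tested on the `nu1 = 1e-4` sweep.

## Problem sizes and numerical defaults

The shipped analyses use: 100–120 point log-spaced `L1` grids for response
curves, 40-point `nu1` grids for the optimum search, `1e4`-point scans for
the two-ligand fixed point, 10–20 multistarts for basin tables, and
1000 randomized draws for the parametrization invariants.  These sizes were
chosen so that every documented result recomputes from scratch in seconds
on a single core while leaving the grids dense enough that no branch or
fold at the shipped parameter sets is missed; all are arguments, not
constants.

Randomized property tests draw rate constants log-uniformly over
`[1e-2, 10]` (binding and dissociation down to `1e-4`), totals over
`[0.1, 10]` with `ST` up to `100`, and `N` from 1 to 5 — wide enough to
cover the monostable, tristable and oscillatory regimes exercised by the
documented examples.  These draws emulate parameter uncertainty only; they
are not calibrated to measured rate constants, and passing them says
nothing about fit to any particular experimental system.

## Limitations

* Deterministic mass-action ODEs only: no chemical-master-equation noise,
  no spatial structure (receptor clustering, synapse formation), and no
  downstream signalling cascade.
* Steady-state counts for `N > 3` are reported, not certified: the
  polynomial degree grows with `N` and the scanner makes no claim that
  three is the maximum beyond `N = 3`.
* Stability is eigenvalue-based; no center-manifold analysis is attempted
  at marginal points, and periodic orbits are not searched for.
* The closed-form coefficient lists stop at `N = 3`; beyond that only the
  elimination route is available (it is the authoritative one in any
  case).
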