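---
title: "Second-derivative implicit integration of stiff reaction networks"
author: "sdsolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Second-derivative implicit integration of stiff reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdsolve)
```

## The problem

Mass-action and enzyme-kinetic models of biochemical networks are systems of
autonomous ODEs

$$\dot{x}(t) = f(x(t), p), \qquad x(t_0) = x_0,$$

with states $x \in \mathbb{R}^{n_x}$ (concentrations) and kinetic parameters
$p \in \mathbb{R}^{n_p}$.  Two structural facts shape this solver:

* **Stiffness.** Association/dissociation steps are orders of magnitude
  faster than catalysis, so explicit methods are useless and an A-stable
  implicit rule is mandatory.
* **Sparsity and analytic access.** Each $\dot{x}_i$ depends on few other
  species, so the Jacobian $J_f = \partial f/\partial x$ is sparse, and
  because models arrive as rate expressions we can differentiate them
  symbolically.  In particular the second time derivative
  $\ddot{x} = J_f f$ costs about as much as $f$ itself when generated as a
  closed form that re-uses the already-computed components of $f$.

In systems-identification settings one additionally needs the local
parameter sensitivities $s_k(t) = \partial x(t)/\partial p_k$, which obey
the linear ODE $\dot{s}_k = J_f s_k + \partial f/\partial p_k$ — an
$n_x(1+n_p)$-dimensional problem if integrated naively.

## The corrector rule

Because $\ddot{x}$ is cheap, the corrector interpolates values **and first
and second derivatives** at both endpoints of a single step:

$$x(t+h) \;=\; x(t) + \tfrac{h}{2}\bigl(\dot{x}(t) + \dot{x}(t+h)\bigr)
  + \tfrac{h^2}{12}\bigl(\ddot{x}(t) - \ddot{x}(t+h)\bigr).$$

This is the evaluation at $t+h$ of the degree-4 polynomial matching
$x, \dot{x}, \ddot{x}$ at $t$ and $\dot{x}, \ddot{x}$ at $t+h$.  Its leading
local defect is $\tfrac{1}{720}h^5 x^{(5)}$.  A degree-4 Adams–Moulton rule,
which must reach back over four steps to collect the same degree, has
constant $\tfrac{19}{720}$ — 19 times larger — because interpolation error
grows with the width of the stencil.  `truncation_constants()` measures both
defects on the monomial $t^5$ rather than hard-coding them:

```{r constants}
unlist(truncation_constants())
```

On the linear test equation the one-step amplification is
$R(z) = (1 + z/2 + z^2/12)/(1 - z/2 + z^2/12)$, the diagonal (2,2) Padé
approximant of $e^z$: A-stable, $|R(z)| < 1$ in the open left half-plane,
but $|R(z)| \to 1$ as $z \to -\infty$, i.e. the rule is **not stiffly
damped at infinity**.  The practical consequences for very stiff problems,
and how the implementation copes, are discussed under *Robustness* below.

The implicit relation is solved by **simplified Newton**: the iteration
matrix

$$M = \tfrac{h}{2} J_f - \tfrac{h^2}{12} J_{Jf} - I, \qquad
  J_{Jf} = \frac{\partial (J_f f)}{\partial x} = \frac{\partial J_f}{\partial x} f + J_f^2,$$

is evaluated once per attempted step at the predictor and factorized once
(QR); all iterations re-use the factorization.  Convergence is declared on
the weighted correction norm with a contraction-rate extrapolation
(`theta/(1-theta)` times the last correction below `newton_kappa`, default
0.1, of the acceptance threshold); divergence when the rate exceeds 0.9
twice or the correction grows.

## Error estimation with a reused factorization

Classical embedded estimates need a second Newton solve and, in general, a
second matrix factorization.  Here the reference solution is the degree-5
polynomial through the *same* nodes plus the second-to-last value
$x(t-h_{-1})$.  Its Newton matrix would carry endpoint-derivative weights of
$14/31$ and $2/31$ (equal steps) — close to the corrector's $1/2$ and
$1/12$ — so a **single Newton step toward the degree-5 solution, computed
with the corrector's already-factorized matrix**, is an adequate
first-order approximation of the difference:

$$\varepsilon = M^{-1}\bigl(g_5(t+h) - x(t+h)\bigr).$$

That is one extra back-substitution per step; the factorization counter
does not move.  All weights (`g4_weights()`, `g5_weights()`, the predictor)
are obtained by solving the Hermite–Birkhoff condition systems in the
scaled variable $s = (t'-t)/h$, not from hand-derived variable-step
formulas; exactness on monomials up to the rule degree (tested for 20
random step ratios) pins the solution down uniquely, and the printed
equal-step values above fall out as a special case:

```{r g5}
g5_weights(1, 1)$unit_weights * 31
```

**Acceptance and step control.** Errors are measured in a weighted RMS norm
with weights $\mathrm{atol} + \mathrm{rtol}\,|x|$, so the threshold is 1
and the tolerance $\tau$ is absorbed into the weights.  A step is accepted
when $\|\varepsilon\| \le \tau$; the next step is scaled by
$\sigma = (\tau/2\|\varepsilon\|)^{1/5}$ — targeting $\tau/2$ rather than
$\tau$, because aiming exactly at the tolerance would reject roughly half
of all steps.  $\sigma$ is clipped to $[0.1, 5]$ per attempt.  In closed
loop on a smooth problem the accepted estimates settle with geometric mean
between $\tau/4$ and $\tau$ (tested).  The first step has no history;
it uses a predictor-difference estimate flagged `"fallback"` with
controller exponent $1/3$, and the first-step size is chosen from the
scales of $f$ and $\ddot{x}$ at $x_0$, vetted by that first estimate.
Step ratios $h/h_{-1}$ outside $[10^{-3}, 10^3]$ make the degree-5 system
ill-conditioned; the guard falls back to the same lower-quality estimate.

## Staggered direct sensitivities

The states do not depend on the sensitivities, so each accepted state step
is followed by a sensitivity stage.  Applying the corrector to the
sensitivity ODE and isolating the unknown gives, for every parameter $k$,

$$\Bigl(I - \tfrac{h}{2}J_f + \tfrac{h^2}{12}J_{Jf}\Bigr) s_k(t+h)
  = s_k(t) + \tfrac{h}{2}\bigl(\dot{s}_k(t) + \tfrac{\partial f}{\partial p_k}\bigr)
  + \tfrac{h^2}{12}\bigl(\ddot{s}_k(t) - \tfrac{\partial \ddot{x}}{\partial p_k}\bigr),$$

with all Jacobians and parameter derivatives **freshly evaluated at the
converged state**.  The left-hand side is the same for every $k$: one
factorization serves all $n_p$ columns (a counter test asserts this).  An
iterative mode that re-uses the state step's factorization instead is kept
as a cross-validation path; the two agree to Newton tolerance on all
fixtures.  Because the Jacobians from the sensitivity stage are current at
the accepted state, `jacobian_reuse = TRUE` feeds them into the next step's
Newton matrix, roughly halving Jacobian evaluations at a result change
well inside the integration tolerance (tested).

Sensitivities are **excluded from the step-acceptance norm** by default:
the accepted step sequence with sensitivities on is bitwise identical to
the sequence with them off (tested).  Initial sensitivities default to
zero; pass `s0` when $x_0$ depends on $p$.  Rejected steps never run the
sensitivity stage.

## The symbolic compiler

`symbolic_model()` takes per-species rate expressions (R syntax);
`mass_action_model()` expands a stoichiometry/order-matrix description into
such expressions.  `compile_model()` then generates every evaluator by
symbolic differentiation with base R's `D()`:

* only **structurally non-zero** entries of $J_f$, $J_{Jf}$,
  $\partial f/\partial p$, $\partial\ddot{x}/\partial p$ are emitted and
  evaluated, and the sparsity pattern is recorded;
* the runtime $\ddot{x}$ evaluator computes $f$ once and contracts it with
  the non-zero $J_f$ entries — the closed-form "about as expensive as $f$"
  path; the fully expanded $\ddot{x}$ expressions are used only as input to
  further differentiation;
* expressions are *not* minimized beyond what `D()` does; the contract is
  correctness plus structural sparsity, not minimal operation count.

`conservation_laws()` returns an integer basis of the left null space of
the stoichiometry matrix (fraction-free Gauss–Jordan elimination), so
$v^\top f(x,p) = 0$ holds exactly and $v^\top x$ is conserved along exact
trajectories — and, because $v^\top J_f = 0$ identically, also along every
corrector step up to Newton tolerance.  Models can be saved to and loaded
from a versioned JSON schema (species/parameters/reactions; see
`read_model_json()`); an SBML importer is not provided.

## Robustness on very stiff problems

Two failure modes surfaced on the classic three-species stiff kinetics
benchmark (`make_fixture("robertson")`), both rooted in the fast,
quasi-steady component:

1. **Predictor breakdown.** The natural degree-4 predictor extrapolates the
   derivative history; for a quasi-steady stiff variable that history is
   dominated by fast-mode content and the extrapolant can miss by orders of
   magnitude (wrong sign included) as soon as the step grows.  Since the
   Newton matrix is frozen at the predictor, the iteration then fails at
   any step beyond the fast time scale.
2. **Estimator noise floor.** $\ddot{x}$ amplifies tolerance-level noise in
   the stiff component by $\lambda^2$; with a loose Newton tolerance this
   noise alone can reach the acceptance threshold.

The driver therefore attempts each step with a **predictor cascade** at
unchanged $h$: the degree-4 extrapolant first, then the first-order Taylor
predictor $x + h\dot{x}$ (extremely robust for quasi-steady components),
then a continuation from the last Newton iterate.  Each sub-attempt
evaluates and factorizes its own matrix and is counted as one attempted
(rejected) step, preserving the one-factorization-per-attempt accounting;
only when all fail is $h$ halved.  With this policy the benchmark runs to
$t = 10^4$ at `rtol = 1e-6` in a few hundred accepted steps with
final-state precision below $10^{-4}$ against an independent
tight-tolerance reference (tested).

## What the fixtures emulate — and what they do not

`make_fixture()` provides: the four-species enzyme scheme (conserved
totals, Jacobian non-zero fraction 5/8), scalar linear decay (closed
forms), the stiff kinetics benchmark, a Hill-repression ring oscillator
(non-polynomial rates), and seed-deterministic random mass-action networks
built from conversion/association/dissociation motifs (which keep
concentrations non-negative).  These cover stiffness, conservation,
non-polynomial kinetics and sparsity, but they are all small
($n_x \le 6$) and noise-free; passing tests say nothing about models with
events, discontinuous inputs, non-autonomous forcing, or the performance
regime $n_x \gtrsim 10^2$ where sparse factorization would matter.

## Numerical choices and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `rtol`, `atol` | `1e-6`, `1e-8` | weights $\mathrm{atol} + \mathrm{rtol}|x|$; threshold 1 |
| `newton_kappa` | 0.1 | Newton tolerance as a fraction of the threshold |
| `max_newton_iter` | 7 | per sub-attempt |
| `sigma_min`, `sigma_max` | 0.1, 5 | per-step scaling clip |
| `h_min` | `1e-13` of the span | repeated failures below this abort with a partial solution |
| `fixed_h` | off | constant-step debug mode for order measurements |

Dense output evaluates each accepted step's own degree-4 interpolant;
node queries return stored values bit-exactly, and requested
`output_times` never influence step selection (the final step is clamped
to land on $t_\mathrm{end}$).  Degenerate inputs: $f \equiv 0$ integrates
in a handful of steps; non-finite model output, singular Newton matrices
and blow-ups surface as classed conditions or a flagged partial solution.

The test suite keeps all problems at desk scale on purpose: order
measurements use $h \in [10^{-2}, 10^{-1}]$ on linear decay (below
$h \approx 3\cdot10^{-3}$ the $h^5$ local defect drops under double-precision
round-off), the enzyme scheme runs to $t = 100$, finite-difference
sensitivity oracles to $t = 10$, the work–precision sweep to $t = 20$
(where all four states are still numerically resolvable), and the stiff
benchmark to $t = 10^4$.

## Known limitations

* Autonomous systems only; time may enter only through the states.
* Dense linear algebra; the sparsity pattern is recorded but a sparse
  factorization path is not implemented.
* Not stiffly damped at infinity (see above): on extremely stiff problems
  the method takes more steps than an L-stable BDF at loose tolerances.
* No events, root-finding, DAEs, delays, or second-order parameter
  sensitivities; no SBML import (the JSON schema is the exchange format).
* Fixed order 4; no variable-order strategy.
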