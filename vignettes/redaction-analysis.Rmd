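---
title: "Redaction fragility of dichotomous outcome trials: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redaction fragility of dichotomous outcome trials: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roar)
```

## The problem

A dichotomous outcome trial reports four counts: `a` events and `b`
non-events in the experimental arm, `c` events and `d` non-events in the
control arm. Fragility indices ask how many event *recodings* would
overturn significance; this package asks the complementary question about
*redaction*: how many subjects, omitted from the reported analysis —
accidentally, through loss to follow-up, or deliberately — would suffice
to explain an apparently significant finding. Redaction is modelled by
*restoring* hypothetical subjects to the cells an opportunistic redactor
would have removed them from. For an elevated risk in the experimental
arm (RR > 1), a spurious effect is manufactured by dropping experimental
non-events and/or control events, so the restored table is
`(a, b + x; c + y, d)`; for RR < 1 the roles mirror to
`(a + x, b; c, d + y)`. Throughout, `x` is the redaction attributed to the
experimental arm and `y` to the control arm, both nonnegative reals.

## The region and its surface function

Writing the uncorrected Pearson chi-squared statistic of the restored
table minus the critical value $\nu_c$ (the $1-\alpha$ quantile of
$\chi^2_1$; 3.841459 at $\alpha = 0.05$) gives the surface function

$$g(x,y) \;=\; \frac{(n+x+y)\,\big(ad-(b+x)(c+y)\big)^2}
{(a\!+\!b\!+\!x)(c\!+\!d\!+\!y)(a\!+\!c\!+\!y)(b\!+\!d\!+\!x)} - \nu_c,$$

with cross-term $(a+x)(d+y)-bc$ and the column margins re-paired
accordingly in the RR < 1 case. The attainable-redaction region is
$\{(x,y)\ge 0 : g \le 0\}$: any such pair nullifies significance. The
denominator is strictly positive on the domain, so multiplying through by
it preserves signs and turns $g=0$ into a bivariate *cubic*
$P(x,y) = (n+x+y)\,\mathrm{cross}^2 - \nu_c\, r_1 r_2 c_1 c_2 = 0$, of
degree at most three in each variable with at most 15 monomials (the
$x^3y^3$ coefficient vanishes identically, since the margin product is
only quadratic per variable and the first term contributes $x^iy^j$ with
$\min(i,j)\le 2$).

The package never transcribes coefficient tables: `roar_surface()` expands
$P$ programmatically with exact dense polynomial arithmetic (integer cell
counts in double precision), and the test-suite asserts at random domain
points that the expansion equals the denominator-cleared rational form to
$10^{-9}$ relative — a property that determines the expansion uniquely.

## The minimal redaction vector

The headline statistic is the point of the region closest to the origin,
the FOCK point $(x_e, y_e)$, with $D = \sqrt{x^2+y^2}$ minimised subject
to $g = 0$. Lagrange multipliers give
$\partial_x D = \lambda\, \partial_x g$ and
$\partial_y D = \lambda\, \partial_y g$; eliminating $\lambda$ (it is
never materialised) and clearing the common factor $1/D$ yields

$$h(x,y) \;=\; y\,\frac{\partial g}{\partial x} -
x\,\frac{\partial g}{\partial y} \;=\; 0,$$

a second bivariate polynomial (at most 18 monomials, degree 4 total). The
FOCK point solves $g = 0,\ h = 0$. By Bézout's theorem the pair can have
up to 25 complex solutions; the solver keeps real, nonnegative candidates
and returns the minimum-norm one. A minimum may legitimately sit on an
axis (the pooled meta-analysis example comes within 0.32 of the x-axis);
there only $g = 0$ is required and the candidate coincides with an axis
intercept.

Derived summaries:

- $r_{\min} = \mathrm{round}(x_e + y_e)$, the minimal combined redaction
  count. The rounding is nearest-integer, not floor: the reference worked
  values (12 from a coordinate sum of ≈11.6, 14 from ≈14.3) are only
  reproduced by rounding, so the package adopts it and also reports the
  raw real sum.
- Axis intercepts $x_c$, $y_c$: smallest positive roots of the cubics
  $g(x,0)=0$ and $g(0,y)=0$ — minimal single-arm redactions.
- Tolerances $\rho_E = 1-\frac{a+b}{a+b+x_c}$,
  $\rho_C = 1-\frac{c+d}{c+d+y_c}$, $\rho_A = 1-\frac{n}{n+r_{\min}}$:
  the fractions of the experimental arm, control arm and total sample
  that must have been redacted. The real-valued intercepts feed
  $\rho_E,\rho_C$; the integer $r_{\min}$ feeds $\rho_A$. Reports also
  carry floor-based "subjects" counts for the intercepts, matching how
  the worked examples print them.

## Numerical scheme

**Cubic slices.** Fixing $x$ makes $P(x,\cdot)$ a univariate cubic whose
leading coefficient $(b+x)^2$ (or $(a+x)^2$) is strictly positive, so
every vertical line yields one to three real roots obtained in closed form
(trigonometric three-real-root branch, stable Cardano otherwise), polished
by three vectorised Newton steps. `stats::polyroot` — an independent
companion-matrix method — is the oracle for this solver in the tests.

**Global scan, then Newton.** `fock_point()` slices the boundary at 2000
positions across $[0, 1.25\,x_{\max}]$ (where $x_{\max}$ is the largest
positive axis root; the padding covers any bulge beyond it), takes the
closest sample as a seed, and runs damped Newton iteration on
$\{g=0, h=0\}$ with the analytic Jacobian (at most 100 iterations;
convergence when $|g|,|h| < 10^{-9}\,|P(0,0)|$). The axis intercepts are
always appended as candidates, each candidate must satisfy $g = 0$ within
tolerance, and the minimum-norm survivor wins. Failed polishing degrades
gracefully to the scan sample, flagged in the diagnostics.

**Conditioning.** All cubics are solved on max-normalised coefficients.
For a pooled table of $n \approx 4\times 10^4$ the polynomial constant
term reaches $\sim 10^{17}$, which double precision carries with relative
error $\sim 10^{-16}$; tolerances are therefore always relative to
$|P(0,0)|$. Cell counts are validated as integers at the boundary and
immediately coerced to doubles: 32-bit integer products would overflow on
exactly these large tables.

**Degenerate inputs.** Zero margins are rejected at construction; a zero
`a` or `c` cell leaves the risk ratio interval and direction undefined
and errors; RR exactly 1 has no direction (such a table is never
significant). A table that is *not* significant at $\alpha$ is a flagged
result with zeroed redaction fields, not an error, so batch and
meta-analysis callers can proceed.

## Meta-analysis gate

For $k$ studies the crude pooled risk ratio
$RR_C = \sum a_i \sum(c_i+d_i) \,/\, \sum c_i \sum(a_i+b_i)$ is compared
with the Cochran–Mantel–Haenszel ratio
$RR_{CMH} = \sum \frac{a_i(c_i+d_i)}{n_i} \,/\, \sum
\frac{c_i(a_i+b_i)}{n_i}$. When the confounding magnitude
$|1 - RR_{CMH}/RR_C|$ is strictly below the gate (default 10%, a
conventional minimal-confounding screen; configurable), crude pooling is
admissible and the redaction analysis runs on the exact cellwise-summed
pooled table — never on any weighted combination. Otherwise the analysis
is withheld. When only a pre-pooled table is published, the stratified
check cannot be recomputed; `gate_asserted = TRUE` (CLI `--pooled-only`)
records that the gate was established externally. Zero-cell studies are
accepted while pooled margins stay positive, with a warning, and no
continuity correction is applied. Study-level attribution of redaction,
heterogeneity statistics and random-effects pooling are out of scope.

## Oracles and the fixture generator

Two brute-force oracles ship in the package (the CLI exposes them via
`--oracle`; they never produce headline output). `grid_min_distance()`
re-derives the minimal distance purely by boundary sampling — a coarse
scan over the x-extent plus two local refinement passes around the
incumbent, so the oracle resolves minima even for marginally significant
tables whose region nearly touches the origin. Every sample is a true
boundary point, hence the scan converges to the FOCK distance from above.
`integer_min_redaction()` exhaustively scans integer pairs by total
$x+y$; its L1 minimum can sit *below* $r_{\min}$ (11 vs 12 on the first
worked example) because the Euclidean summary is not the integer
fewest-subjects count — the package reports the Euclidean statistic as the
headline and the integer scan as a diagnostic only.

`simulate_significant_tables()` generates test fixtures: total size
uniform on 40–400 (small-to-mid trial scale, where fragility is most
acute and every code path — both directions, near-axis minima, marginal
significance — is exercised), cells symmetric-multinomial, rejection
until all margins are positive and the table is significant at the target
level. It emulates null data conditioned on spurious significance; it
does not emulate true effects, correlated arms, or stratification, so
passing property tests certify the *solver* on realistic count
magnitudes, not any sampling property of real trials. The default
property-suite sizes (100 fixtures, 10⁴-slice oracle, 25 equivalence
points per fixture) keep the whole suite in tens of seconds while the
oracle tolerance ($10^{-3}$ relative) stays well inside the scan's
resolution.

## Known limitations

- The method applies to 2×2 dichotomous outcomes only and should not be
  applied to time-to-event data. Effect size is summarised as relative
  risk; odds-ratio variants are not implemented.
- Built on the uncorrected chi-squared statistic, results for very small
  trials with rare events can disagree with Fisher's exact test; no
  continuity correction or exact-test option is offered.
- The published worked values for the simulated example are internally
  consistent with a slightly lower effective threshold (≈3.81) than
  $\nu_c(0.05)=3.8415$; this package always derives $\nu_c$ from
  $\alpha$, so its FOCK coordinates and arm tolerances sit a few
  hundredths below those printed values (e.g. $x_e$ 6.83 vs 6.89,
  $\rho_E$ 9.44% vs 9.51%) while integer counts agree exactly. The
  discrepancy is documented rather than absorbed by tuning the threshold.
- Boundedness of the region holds for every table exercised, but is not
  proven here for pathological near-degenerate inputs; the grid and
  integer oracles are the recommended cross-check when in doubt
  (`roar oracle` from the CLI).

## Session info

```{r}
fit <- roar(70, 30, 50, 50)
glance(fit)
```
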