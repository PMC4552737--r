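---
title: "The ROSE-versus-fixed FNAB sampling cost model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ROSE-versus-fixed FNAB sampling cost model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosecost)
```

Fine-needle aspiration biopsy (FNAB) fails when no pass yields material
adequate for diagnosis, and a failed procedure is repeated — with its full
setup time, room, personnel and supplies. Rapid on-site evaluation (ROSE)
guards against that by having a cytologist assess each pass as it is made,
stopping once enough adequate samples have been seen. The trade is stark:
ROSE raises adequacy and cuts passes but adds a cytologist and lengthens
every pass. `rosecost` quantifies that trade as the expected cost per
case of each policy and their difference.

## Sampling model

Every pass is an independent Bernoulli trial with per-pass adequacy `p`
(constant across passes — a simplification known to be robust when the
true per-pass rate declines slowly with tissue disruption, but a
simplification nonetheless). A *fixed* protocol takes `n_fixed` passes:

$$A^F = 1 - (1-p)^{n_F}, \qquad \bar N^F_{pass} = n_F.$$

Under *ROSE*, the cytologist's call is itself a diagnostic test with
sensitivity `sn` and specificity `sp` against the final laboratory
assessment. Each pass draws a positive call with probability
$(1-sp)(1-p) + p\,sn$, so the pass count to the `n_rose`-th positive call
is negative binomial with mean

$$\bar N^R_{pass} = \frac{n_R}{(1-sp)(1-p) + p\,sn}.$$

A procedure fails only if every collected sample is inadequate and a
false-positive call ends the sampling; per stopping cycle the failure
odds are $(1-sp)(1-p)\,/\,(1 - sp(1-p))$, giving

$$A^R = 1 - \left[\frac{(1-sp)(1-p)}{1 - sp(1-p)}\right]^{n_R}.$$

Two consequences worth noting. $A^R$ does not depend on `sn`: a missed
adequate sample costs extra passes, never the case, because the material
is still processed. And the denominator $1 - sp(1-p)$ encodes exactly
that rescue — the alternative reading, in which only positively-called
samples are processed, would make the failure probability
$\bigl((1-sp)(1-p)/((1-sp)(1-p)+p\,sn)\bigr)^{n_R}$ and is inconsistent
with the closed form above; the package's simulator implements the rescue
semantics and its empirical failure rate confirms the formula (see the
test suite).

Failed procedures are repeated, so procedures per case are geometric:
$\bar N_{proc} = 1/A$. `n_rose` is a pre-set integer — the stopping rule a
cytologist commits to before sampling; adaptive stopping is out of scope.

## Time and cost model

The procedure has two periods, setup and sampling, with a common hourly
variable cost. Durations are minutes, rates currency per hour, and the
single minutes-to-hours conversion happens at the rate product:

$$\bar T_{samp} = \bar N_{pass}\, t_{pass}, \qquad
  \overline{TC}_{proc} = \frac{t_{setup} + \bar T_{samp}}{60}\, c_{var}
  + c_{fixed} + \bar N_{pass}\, \bar c_{np}, \qquad
  \overline{TC} = \overline{TC}_{proc}\, \bar N_{proc}.$$

`c_fixed` is the per-procedure cost independent of duration (final
cytopathology, special supplies); `c_np` is the *expected* cost attached
to one pass — supplies plus probability-weighted adverse events, taken as
a single input with no adverse-event sub-model behind it. The decision
quantity is $\Delta TC = \overline{TC}^R - \overline{TC}^F$; negative
values favor ROSE. Only the two-period model is implemented; resource
profiles with additional periods (cleanup, stepdown) and escalation to a
different procedure after failure are out of scope.

### Staffing composition

The effective hourly rate is composed as: non-cytologist team
(`rate_other`), plus the cytologist (`rate_cytologist`) under ROSE, plus
the patient's wage (`rate_patient`) under the societal perspective
(the default; the provider perspective drops it). `rate_other` carries
the *entire* non-cytologist team — specialist, assistants, room
opportunity cost — so for the packaged complex procedure the fixed-arm
rate is 260 + 20 = 280/hr and the ROSE arm 360 + 20 = 380/hr.

Simple palpation-guided procedures need a different composition: the
cytologist performs the aspiration, so ROSE adds no personnel and both
arms bill the same team rate. The catalogue expresses this through rate
overrides computed as `rate_other + rate_cytologist` (130/hr at base) for
*both* protocols, recomputed from the current component values so that
one-way and probabilistic variation of the components still flows into
the rates. Static overrides are also accepted (`cost_inputs()`), and the
`variant` configuration uses one to express a direct 310/hr ROSE total
for complex procedures.

## The scenario catalogue

`scenario_catalogue()` enumerates 2 procedure types × 2 adequacy levels ×
2 ROSE stopping rules (`n_rose` 1–2) × 4 fixed stopping rules (`n_fixed`
2–5) = 32 scenarios. Base values and plausible ranges come from the
`default` configuration:

| parameter | simple | complex | range |
|---|---|---|---|
| `p` (per pass) | 0.3 low / 0.6 high | same | ±0.1 |
| `sn` / `sp` | 0.95 / 0.975 | same | 0.90–1.00 / 0.95–1.00 |
| `t_setup` (min) | 4 | 30 | 3–5 / 20–30 |
| `t_pass_fixed` / `t_pass_rose` (min) | 2 / 9 | same | 1–3 / 6–12 |
| `c_var_o` / `c_var_c` (per hr) | 30 / 100 | 260 / 100 | ±~30% |
| `c_np` (per pass) | 0 | 30 | — / 15–45 |
| `c_fixed` (per procedure) | 150 | 300 | 100–200 / 150–450 |
| `c_pat` (per hr) | 20 | 20 | 15–25 |

The simple type emulates office palpation-guided FNAB (short setup, tiny
team); the complex type emulates EUS- or CT-guided FNAB (long setup,
specialist team, non-trivial per-pass morbidity cost). All computation is
carried at full precision; `base_case_table()` rounds exactly once, at
render time.

## Sensitivity analysis

`one_way_sensitivity()` moves one parameter to each end of its range with
the rest at base and reports $\Delta TC$ at both ends plus the span, in
tornado order (descending span, ties by name). The integer stopping rules
are excluded by default — they define the protocols being compared rather
than measure input uncertainty, and because a fixed protocol's pass count
enters both arms asymmetrically their spans would dominate every tornado
(~250 vs ~170 for the largest continuous parameter in the complex/low
scenario) and drown the informative ordering; `include_stopping_rules =
TRUE` restores them. A parameter with a zero-width range (the simple
procedure's `c_np`) simply contributes a zero span.

`psa()` draws the nine continuous model parameters (`p`, times, costs)
independently and uniformly over their ranges — the minimal-information
choice when only ranges are stated; the distribution is pluggable per
parameter — and pushes each draw through the full closed-form pipeline
(vectorized, so 10^5 draws take well under a second). The cytologist's
`sn`/`sp` and the stopping rules stay at base. The seed is mandatory:
every summary is reproducible, and summaries are recomputable from the
stored draws.

## The simulator as oracle

`simulate_procedures()` / `simulate_cases()` replay the sampling process
event by event: per-pass adequacy draws, per-pass cytologist calls, the
stopping rule, repeat-on-failure. `simulate_policy()` prices each
simulated case from its event counts. The suite checks the closed forms
against this brute force across a grid of 333 parameter combinations
(`p` 0.1–0.9, `sn`/`sp` 0.8–1, both stopping rules) at 10^5 cases each,
requiring agreement within 4 Monte Carlo standard errors; with the
suite's fixed seeds the worst observed deviation is about 3 SE. Safety
caps (10^4 passes per procedure, 10^3 procedures per case) make
pathological inputs terminate; hitting a cap is flagged as truncation in
the output, never silent.

What the simulator does *not* emulate: declining per-pass adequacy as
tissue is disrupted, cytologist learning or fatigue, adaptive stopping,
or correlated passes. Agreement between simulator and closed forms
validates the implementation of this model, not the model's fidelity to
any particular clinic's sampling process.

## Numerical and design choices

* Probabilities are validated to open/closed bounds (`0 < p < 1`,
  `0 < sn, sp <= 1`) and violations raise errors; nothing is clamped.
  `p = 0` would make expected passes infinite, `sp = 0` with `p < 1`
  makes the ROSE failure odds ill-defined.
* The degenerate `sn = 0` with `sp = 1` (sampling never stops) is
  unreachable through the constructors; the pass-rate guard in
  `expected_passes_rose()` documents the failure mode anyway.
* Currency is an abstract unit; no conversion or discounting.
* Report files carry a provenance header (package version, configuration
  name, seed) and no timestamp, so identical runs are byte-identical.
* Where published variants of the assumptions disagree (cytologist
  specificity 0.975 vs 0.99, complex setup 30 vs 20 min, ROSE complex
  rate 360 vs 310/hr), the `default` configuration keeps the set that is
  internally consistent with the benchmark outcome table, and the
  `variant` configuration ships the alternative. One published range in
  the source material (simple fixed-arm total variable cost "20–40"
  beside a 130 base) is an evident copy of the component row; the
  package varies components directly, implying the symmetric 95–165
  total.

## Limitations

The model prices repeat *identical* procedures; if failures escalate to a
costlier procedure (e.g. mediastinoscopy after a failed transbronchial
FNA), ROSE's savings are underestimated. Qualitative benefits of ROSE —
faster diagnosis, triage of material to ancillary testing — are outside
the costing. And every packaged number is illustrative: the intended use
is to re-run the catalogue, tornado and PSA with institution-specific
configuration, concentrating measurement effort on the three or four
parameters the tornado puts on top.
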