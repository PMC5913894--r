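---
title: "Prioritized multi-criteria planning on synthetic phantoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritized multi-criteria planning on synthetic phantoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The planning problem

Postoperative radiotherapy of advanced gastric cancer targets a large,
multi-concave planning target volume (PTV) wedged between the kidneys,
liver, spinal cord, heart and lungs, with a prescription of 45 Gy median PTV
dose in 25 fractions. `wishplan` implements the *prioritized* (wish-list)
formulation of this planning problem: a small set of hard maximum-dose
constraints that every plan must satisfy, plus an ordered list of objectives,
each with a priority, a cost function and a goal. The optimizer handles the
objectives strictly in priority order, so that target coverage can never be
traded away for organ sparing, and the kidney objectives can never be traded
away for lower-priority conformity goals.

The packaged gastric wish-list (`default_wishlist()`) contains:

* **Constraints** — PTV and patient maximum at 105% of the prescribed dose
  `Dp`, and a 39 mm PTV shell maximum at 50% of `Dp` (global conformity).
* **Objectives, priorities 1-9** — PTV coverage via LTCP (goal 0.4,
  `Dp` = 45 Gy, `alpha` = 4); a 3 mm PTV shell maximum at 90% of `Dp`
  (gradient); kidney mean dose (8 Gy); liver mean dose (15 Gy); heart gEUD
  (15 Gy, `k` = 6); spinal-cord gEUD (25 Gy, `k` = 12); an 18 mm shell
  maximum at 40% and a 21 mm skin ring maximum at 25% of `Dp`; and
  dose-volume goals for kidneys (V12Gy <= 25%), liver (V24Gy <= 30%) and
  lungs (V20Gy <= 50%).

The kidney and lung rows are printed as single entries covering both organs;
we implement them on the union structures `Kidneys` and `Lungs`. The two
priority-7 rows and the two priority-8 rows are processed sequentially in
listed order; whether the original optimizer treats equal priorities jointly
is not documented, and the sequential reading is the simplest faithful one.

## Cost functions

All costs weigh the voxels of a structure equally (masks are binary). For a
dose vector `d` over a structure of `N` voxels:

* **LTCP** (logarithmic tumor control probability), a convex exponential
  penalty on target underdose:
  `LTCP = (1/N) * sum_i exp(-alpha * (d_i - Dp))`.
  It equals 1 for a uniform dose at `Dp`, drops below 1 with overdose, and
  grows exponentially with underdose. The form follows the definition the
  planning literature attaches to this name (Alber & Reemtsen); the package
  computes it on the log scale (log-sum-exp) for numerical stability.
* **gEUD** (generalized equivalent uniform dose, after Niemierko), the power
  mean `((1/N) * sum_i d_i^k)^(1/k)` with `k >= 1`; `k = 1` is the mean dose,
  large `k` approaches the maximum.
* **mean**, **maximum**, and **dose-volume** (`V_T` = percent of voxels with
  `d_i >= T`; the threshold is inclusive, matching the DVH convention).

## The lexicographic epsilon-constraint algorithm

`solve_prioritized()` reconstructs the two-phase prioritized optimization in
the following form (the original platform's internal mechanics are not
published; this is a faithful-in-spirit reconstruction, and the code
documents it as such):

1. **Feasibility.** Fluence is nonnegative and all hard constraints are
   voxel-wise linear inequalities; the zero plan is always feasible. The
   warm start distributes weight over beamlets crossing the PTV and shrinks
   it to strict feasibility.
2. **Pass 1.** For each objective in priority order, minimize its cost
   subject to the hard constraints, nonnegativity, and bounds on all
   previously processed objectives. If the attained value `f*` meets the
   goal, the objective's bound is fixed at the *goal* (lower priorities may
   trade the surplus); otherwise at `f* * (1 + relaxation)` with a default
   relaxation slack of 0.03. The slack is not published; a small nonzero
   value prevents lower priorities from being paralyzed by numerically tight
   bounds.
3. **Pass 2.** Objectives that met their goals are re-minimized
   ("superseded") with all other bounds fixed, and their bounds tightened to
   `min(goal, f_new * (1 + relaxation))`. The cap at the goal keeps the
   phase-1 guarantee intact in the marginal case where the re-minimized
   value sits just under the goal.

**Maximum-dose objectives** are exact voxel-wise linear inequalities through
an auxiliary variable (minimize `t` subject to `d_i <= t`), never smooth
approximations. **Dose-volume objectives** are nonconvex; they use an
iterative hot-voxel-exemption scheme: exempt the hottest goal-percent of the
organ, constrain every other organ voxel to the threshold, re-identify the
exempt set from the new dose, and repeat (at most `dv_rounds = 10`, usually
2-3) until the set is stable. The surrogate objective inside each round is
the mean squared over-threshold excess. The exempt set recorded after the
step protects the attained dose-volume value against later steps.

### Numerical realization

Each step is solved by an augmented-Lagrangian loop over `L-BFGS-B`
(`stats::optim`) with the fluence box-constrained at zero:

* Every constraint is scaled by its limit, so tolerances are relative; the
  log-LTCP bound is scaled by its Lipschitz constant `alpha * Dp` (with a
  proportionally larger penalty weight), and penalty hinges are Huberized —
  quadratic near the boundary, linear for deep violations — which keeps the
  augmented-Lagrangian landscape well-conditioned for the line search.
* Each step solves against limits tightened by an interior margin
  (`constraint_margin`, default 0.2%), so the first-order method's residual
  infeasibility still lands strictly inside the true limits. The audit and
  the attained/bound ledger always use the true limits.
* The LTCP step uses a smoothing continuation: at `alpha = 4` the
  log-sum-exp is nearly a hard maximum over underdose and gradient descent
  zigzags on the coldest voxel; pre-solving at `alpha/8` and `alpha/2`
  (each stage convex) lifts the whole cold tail first.
* LTCP bounds are imposed on the log scale — a monotone transform with the
  same feasible set and far better conditioning.
* A lexicographic step is accepted only if it does not worsen its own
  objective and keeps the true-limit violation below `5 * feas_tol`;
  otherwise the incumbent (always feasible) is retained. This makes the
  priority ledger monotone by construction even when a step under-converges.
* Solver tolerance: `feas_tol = 1e-5` relative; determinism holds for a
  fixed solver configuration because nothing in the pipeline draws random
  numbers after phantom and influence generation.

The baseline (`solve_baseline()`) stands in for manual template-based
planning: one weighted sum of the same cost functions under the same hard
constraints, with weights fixed in advance. Because a weighted *log*-LTCP
term is unbounded below, the baseline uses a soft-plus-saturated coverage
term `log(1 + LTCP/goal_equivalent)` (on the log scale) that stops pushing
once coverage is comfortably met — the behaviour of a clinical template cost
function. The default study template deliberately under-weights the kidneys,
emulating a generic template not tuned to kidney sparing; the published
template itself is not available, so the weights are a configurable
stand-in, and the paired comparison should be read as "prioritized versus
kidney-blind template", not as a reconstruction of any clinic's template.

## The synthetic phantom

No imaging or plan data are deposited for this treatment site, so every
stage runs on seeded synthetic phantoms (`make_phantom()`):

* A voxelized elliptical body with nine structures. In `"clinical-like"`
  mode the PTV is a union of a gastric-bed blob, a para-aortic medial
  extension and a splenic-hilum extension, carved out around the spinal cord
  and the left kidney so it wraps both partially — reproducing the
  geometric challenge (large, multi-concave target abutting several organs)
  without claiming anatomical fidelity. `"easy"` mode is a single compact
  ellipsoid; the clinical-like PTV always has the larger
  surface-to-volume ratio.
* Inter-patient variability is seeded jitter of organ centers (±5 mm) and
  semi-axes (±8%); the magnitudes are configuration values, chosen once as
  plausible anatomical variation, since the cohort variability is not
  parameterized anywhere in the source material.
* The default grid is 32 x 32 x 16 voxels at 6 mm (desk scale: a full
  prioritized plan solves in about two minutes; a 2D single-slice mode
  supports the optimizer oracle tests). Shells at 3/18/39 mm and a 21 mm
  skin ring are derived by an exact Euclidean distance transform on voxel
  centers, with the structure surface taken half a voxel inside the nearest
  member voxel center — on a 6 mm grid the 3 mm shell is then exactly the
  first voxel ring, as intended for gradient control; a pure
  center-to-center definition would leave it empty on any grid coarser
  than 3 mm.

The influence matrix (`make_influence()`) is a pencil-beam surrogate for
coplanar dual-arc delivery: equiangular parallel-ray beams (default 9),
exponential depth attenuation (`mu` = 0.005/mm), and a lateral profile
equal to the beamlet's rectangular aperture (default 12 mm) convolved with
a Gaussian (`sigma` = 3 mm), so adjacent beamlets tile to a flat field.
There is no build-up, scatter, heterogeneity or deliverability modelling
(no MLC segmentation, control points or monitor units): plans live at the
fluence level. Consequences for interpretation: passing tests demonstrate
the *optimization and evaluation machinery* — constraint satisfaction,
priority protection, DVH/NTCP arithmetic, paired statistics — not dosimetric
realism; absolute dose metrics on phantoms are not comparable to values
reported for clinical patient cohorts, whose imaging and plan data are not
publicly available for this treatment site.

## Evaluation conventions

* DVHs are cumulative with `V(t)` = fraction of voxels at `>= t` Gy. Plan
  metrics use the exact step DVH, so after `normalize_plan()` the PTV
  `D_50%` equals the prescription to machine precision; binned DVHs
  (default bin width 0.05 Gy where binning is requested) agree with order
  statistics within one bin width. `D_q%` inverts the cumulative curve with
  linear interpolation; on step curves the vertical segments make step
  doses exact. The interpolation dialect is the package's own choice, since
  none is published.
* `HI = (D_2% - D_98%) / D_50%`; `CI = TV_RI^2 / (TV * V_RI)` with the
  reference isodose defaulting to 95% of the prescription (42.75 Gy). The
  reference level used in the source analysis is not printed; the default
  is configurable (`ci_reference_fraction`).
* Integral dose: body mean dose plus `V_5Gy`, `V_11.25Gy`, `V_22.5Gy`.
* NTCP: doses are first converted per voxel to the 1.5 Gy-per-fraction
  equivalent via the linear-quadratic relation
  `D_eq = D * (D/n_fx + alpha/beta) / (d_ref + alpha/beta)` with
  `alpha/beta = 2.5` Gy — the voxel-wise reading of "plans were first
  normalized"; a bin-wise mode exists for sensitivity checks and agrees to
  well under a percentage point on solved plans. The LKB model then reduces
  the differential DVH to `D_eff = (sum_i v_i * D_i^(1/n))^n` and evaluates
  `NTCP = Phi((D_eff - TD50/5) / (m * TD50/5))`. Presets: kidney
  `TD50/5 = 12` Gy, `n = 0.70`, `m = 0.26`; liver `TD50/5 = 30` Gy,
  `n = 0.32`, `m = 0.15`. Kidneys are evaluated per organ (left and right
  DVHs separately, matching the separate reporting rows), the liver as
  liver-minus-PTV.
* Statistics: paired two-sided Wilcoxon signed-rank tests, exact when there
  are no ties among absolute differences and `n <= 25`, otherwise a tie- and
  continuity-corrected normal approximation. Zero
  differences are dropped (the classic convention); the Pratt variant is
  available behind `zeros = "pratt"` since the original analysis software's
  convention is not stated. Summary SDs use the `n - 1` denominator, and
  paired differences are reported as baseline minus prioritized, so
  positive values favour the prioritized plans.

## Worked example

```{r example}
library(wishplan)

s <- expand_structures(make_phantom(1))
A <- make_influence(s, seed = 1)
wl <- resolve_limits(default_wishlist())

plan <- solve_prioritized(wl, A, s)
plan$ledger                       # attained value and bound per objective

plan <- normalize_plan(plan, s)   # PTV D50% = 45 Gy exactly
plan_metrics(plan, s)
organ_ntcp_report(plan, s)

## paired study: prioritized vs kidney-blind template, 3 subjects
res <- run_study(run_config(seed = 0, n_subjects = 3))
res$report
```

## Known limitations

* Fluence-level plans only; the deliverability chain (arc sequencing, MLC,
  Monte Carlo dose, delivery time) is out of scope by design.
* The phantom is a geometric surrogate; no claim of anatomical fidelity is
  made or tested.
* The augmented-Lagrangian solver trades exactness for robustness: attained
  values carry a relative tolerance of order `1e-4`-`1e-3`, and the interior
  constraint margin (0.2%) slightly over-satisfies hard limits. Exact
  optimality is verified only on tiny instances against exhaustive search.
* The baseline template weights are a stand-in, not a published template;
  only the qualitative direction of the paired comparison is meaningful.
* Monte-Carlo-grade dose accuracy, non-coplanar beams, motion and
  heterogeneity corrections are non-goals.
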