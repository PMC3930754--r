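---
title: "Multi-scale TGF-beta dynamics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale TGF-beta dynamics: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgfbms)
```

Transforming growth factor beta (TGF-beta) is the textbook "Jekyll and
Hyde" of carcinogenesis: in healthy epithelium it is cytostatic and
pro-apoptotic, while advanced tumor cells evade that control and turn the
same cytokine into a growth and survival signal. `tgfbms` implements a
deterministic multi-scale description of this switch for the mammary duct
and for the bone metastatic niche, as four coupled models: an intracellular
Smad signaling system, a cellular autocrine/paracrine exchange model, a
phenotype-structured tissue model, and a delay differential equation (DDE)
model of one bone remodeling cycle. A variance-based sensitivity module
works across all of them.

This vignette records the model equations in the package's notation, the
parameters that matter and their defaults, the numerical choices, and the
design decisions that were genuinely open — together with what the test
suite does and does not establish.

## The intracellular Smad module

Eight mass-action species: free ligand $B$, inactive and active receptor
$R_{in}, R_{act}$, cytoplasmic Smad $S_c$ and phospho-Smad $pS_c$, nuclear
phospho-Smad $pS_n$ and Smad $S_n$, and a transcriptional readout $m$.
Ligand binds receptor; the active complex phosphorylates cytoplasmic Smad
(consuming the complex — this is the signaling decay channel); phospho-Smad
translocates at rate $k_t$; a constant nuclear phosphatase pool $P$
dephosphorylates it; nuclear phospho-Smad drives transcription. Without
synthesis or degradation, total Smad material $S_c + pS_c + pS_n + S_n$ is
conserved, and without a ligand source $B$ and $R_{act}$ decay to zero
while the nuclear pools and $m$ settle to initial-condition-dependent
stationary values. The tests verify all of these properties against an
independently coded fixed-step Runge-Kutta oracle.

The running multi-scale model only needs the *order reduction*: holding
$S_c$ at its large resting value collapses the signaling consumption of the
internalized complex into a single first-order rate,

$$ r_{sgn} = k_{phos}\, S_c^0 = 0.003018\ \mathrm{s}^{-1}, $$

the tabulated Smad signaling rate. The individual constants are exposed in
`default_smad_rates()` with config override; the default pair
($k_{phos} = 3.018\times10^{-4}$ per nmol per s, $S_c^0 = 10$ nmol) is a
calibration chosen to reproduce the reduced rate exactly, and
`reduce_model()` makes the collapse explicit.

## The cellular exchange module

Each phenotype class $\varphi = 0$ (healthy) to $\Phi = 3$
(aggressive/malignant) carries sub-population averages of extracellular
ligand $B_e$, membrane receptor $R$, and internalized complex $B_i$; a
single shared pool $B_{dr}$ holds the ligand in the *diffusive region*,
where it loses the identity of its producer:

$$
\begin{aligned}
\dot B_e(\varphi) &= r_{syn}\beta_{sM}(\varphi) - r_b B_e R - r_{pc} B_e
  + r_{pc} B_{dr}/\textstyle\sum_\psi N(\psi) \\
\dot R(\varphi) &= r_{syn} R_{sM}(\varphi) - r_b B_e R \\
\dot B_i(\varphi) &= r_b B_e R - r_{sgn} B_i - r_u B_i\,\delta_{\varphi 0} \\
\dot B_{dr} &= \textstyle\sum_\varphi N(\varphi)\, r_{pc} B_e(\varphi)
  - r_{pc} B_{dr}
\end{aligned}
$$

Ubiquitination ($r_u$) is a healthy-cell-only loss: mutated cells have lost
the capacity to down-regulate their internalized ligand. The paracrine rate
follows from discretizing Fick's first law across the exchange surface
between the extracellular and diffusive regions,
$r_{pc} = D_{eff} S / (d\, V_{dr})$ (`derive_paracrine_rate()`), with the
effective diffusion coefficient absorbing the porosity of the extracellular
matrix. The ligand mass balance
$\frac{d}{dt}[\sum N(B_e + B_i) + B_{dr}] = \sum N r_{syn}\beta_{sM}
- r_{sgn}\sum N B_i - r_u N_0 B_i(0)$
holds identically and is asserted along every default trajectory.

Two open points were settled as follows. The return flux from the diffusive
region is split *equally* over all neighbour cells (the minimal assumption
consistent with a shared pool; the denominator is the total neighbour
count). And the per-phenotype synthesis term is exactly
$r_{syn}\beta_{sM}(\varphi)$ with no additional activation efficiency,
since none is tabulated. Gene-expression levels default to the
TGFB2/TGFBR3 isoform pair; `generate_expression_fixture()` supplies the
tabulated vectors (noise 0) or seed-reproducible multiplicative
perturbations of them (`"synthetic"`), emulating what a per-phenotype
microarray reanalysis would deliver. The synthetic fixtures reproduce the
*magnitudes and phenotype ordering* of expression-derived synthesis levels;
they do not emulate probe-level noise structure, batch effects, or
cross-isoform correlations, so tests passing on them say nothing about
normalization pipelines upstream.

A structural property worth noting: receptor expression exceeds ligand
expression for every phenotype ($R_{sM} > \beta_{sM}$), and the receptor
equation has no decay term, so $R$ grows secularly while $B_e \to 0$ and
the binding flux approaches the synthesis flux. The internalized pool
therefore has the clean asymptote
$B_i^\infty(\varphi) = r_{syn}\beta_{sM}(\varphi)/(r_{sgn} +
r_u\delta_{\varphi 0})$, reached within minutes, which makes the influx
passed upward essentially composition-independent.

## The tissue module

Cell counts $N(\varphi)$ in the neighbour volume follow

$$
\dot N(\varphi) = (1 - p_\Phi(1-\delta_{\varphi\Phi}))\,\mathrm{prolif}(\varphi)
 + \delta_{\varphi\Phi}\, p_\Phi \!\!\sum_{\psi<\Phi}\!\mathrm{prolif}(\psi)
 - \mathrm{death}(\varphi)
 - r_m N(\varphi)(1-\delta_{\varphi\Phi}) + r_m N(\varphi-1)(1-\delta_{\varphi 0})
$$

with capacity-limited proliferation
$\mathrm{prolif} = r_p(\varphi)\, x^{-g_p(\varphi)} N(\varphi)
(1 - \sum_\psi N(\psi)/C_\varphi)$ and death
$\mathrm{death} = r_a x^{g_a(\varphi)} N(\varphi) + r_d N(\varphi)$, where
$x = \gamma B_{in}(\varphi)/\alpha$ is the scaled TGF-beta influx entering
a cell. The power-law response encodes a serial amplification cascade
phenomenologically: positive exponents (healthy end, $g = 0.12$) mean the
cytokine suppresses division and promotes apoptosis; the negative malignant
entries ($-0.06$) flip both signs — the Jekyll-to-Hyde switch. Phenotype
only increases: the stepwise channel $r_m$ acts on standing populations,
and a fraction $p_\Phi$ of every non-malignant division is rerouted
directly to $\Phi$, representing rare catastrophic driver mutations during
proliferation. The malignant capacity $C_\Phi = 8 > 6$ encodes
multi-layering of neoplastic epithelium in the duct.

Open choices: the crowding term uses the *total* population over the
phenotype-specific capacity (volume exclusion in a shared duct volume); the
degradation rate $r_d$ applies to all phenotypes (it is tabulated as a
single rate); and $x$ is floored at $10^{-12}$ so a zero influx with a
negative exponent degrades gracefully instead of diverging (a numerical
guard, not biology; configurable as `response_floor`).

With neutral sensing ($g \equiv 0$) and the mutation channels off, the
model reduces to logistic growth and is checked against the closed form to
$10^{-6}$ relative.

## The multiscale coupling

Cellular rates ($10^{-3}$–$10^{2}\ \mathrm{s}^{-1}$) and tissue rates
($10^{-8}$–$10^{-6}\ \mathrm{s}^{-1}$) are separated by many orders of
magnitude, so the coupling is loose and mean-field: each coupling step
(default one month of tissue time) re-equilibrates the cellular model under
the current composition — passed as continuous averages, no rounding — and
hands the tissue the time-averaged per-cell influx
$B_{in}(\varphi) = r_{sgn}\langle B_i(\varphi)\rangle$, averaged over the
trailing 10% of a quarter-day cellular horizon (the exchange model relaxes
within minutes, so the window mean and the instantaneous quasi-steady value
agree to high accuracy; the window form is kept because it is robust to
slow secular drift). Halving the coupling step changes the 4-month
composition by well under 1%, and freezing a step's influx and replaying it
reproduces the same tissue increment — both tested.

`takeover_time()` reports when a phenotype first reaches a given share of
the local population. With the default tables the malignant share reaches
10% near month 10 and saturates well before month 24; the timing is highly
sensitive to the normalization of the influx signal entering the response
factor ($x$ is of order $10^2$ here), which is the least constrained
element of the tissue model. This is the one headline behaviour of the
coupled system for which the package's defaults and the published
parameter table do not reproduce the expected two-year calibration point;
the acceptance suite reports it without adjustment, and any recalibration
should go through the sensing exponents, which are exposed in the
configuration like every other entry.

## The bone niche module

One basic multicellular unit (BMU) remodeling cycle, as a DDE system over
osteocytes ($Ocy$), osteoclasts ($Oc$), lining/pre-osteoblast cells
($Lng$), mature osteoblasts ($Ob$), the signalling species RANKL, BMP and
CSF, bone mineral density $z$ (percent), and niche TGF-beta $\beta$, plus a
damage signal. A microfracture at $t = 0$ removes $D = Ocy_{max}/30 = 30$
osteocytes over one day (at the tabulated apoptosis rate of 30 per day).
Damaged osteocytes drive RANKL, BMP and CSF release; osteoclasts are
recruited by the RANKL–CSF product and deplete CSF as they work; lining
cells recruited by BMP mature into osteoblasts after the TGF-beta dependent
delay

$$ \tau(\beta) = \bar\tau + \Delta\,\frac{\beta}{\beta + \bar\beta}
   \in [6.02,\ 28.38]\ \text{days}, $$

a saturating Hill form — the minimal function that is positive, finite,
monotone, and uses exactly the three tabulated constants. In the control
run the niche TGF-beta released by resorption pushes $\tau$ to roughly
16 days at the height of the cycle, consistent with a circa-20-day
maturation lapse. Osteoblasts rebuild density, rebury as osteocytes
(factor $f_{Ocy}\kappa$), and the cycle closes.

Three design decisions deserve emphasis:

* **Damage clearance.** The damage signal is a state cleared by osteoclast
  resorption, $\dot{dmg} = \mathrm{pulse}(t) - k_{dmg}\,Oc\,dmg$: dead
  osteocytes signal until they are resorbed. A purely cumulative damage
  count would keep the osteocytic sources on forever and the cycle would
  never terminate; with clearance the run shows the canonical transient —
  RANKL/CSF rise, osteoclast wave, density dip, delayed osteoblast wave,
  recovery — and is essentially quiescent again by day 200. Setting
  `k_dmg = 0` restores the cumulative reading.
* **Maturation attrition.** The delayed maturation flux is
  $M(t) = m_{Lng}\, BMP(t-\tau)\, Lng(t-\tau)\, e^{-a_{Lng}\tau} / L_{ref}$.
  The attrition factor $e^{-a_{Lng}\tau}$ accounts for lining-cell death
  during the maturation transit. It is also what gives the delay its
  teeth: without it a longer delay would merely shift the osteoblast wave
  in time without changing the amount of bone rebuilt, and neither a
  cancerous lengthening nor a shortening of $\tau$ could move the final
  density.
* **Cancer coupling.** Cancer cells enter only the TGF-beta budget,
  $\dot\beta \mathrel{+}= c_{sec} N_c - c_{abs} N_c \beta$: they secrete
  the cytokine (pinning $\tau$ toward its upper bound, starving the
  osteoblast wave) and absorb part of it. The cell count $N_c$ is constant
  within a cycle, matching the early-metastasis regime where remodeling is
  faster than local tumor growth.

**Closure calibration.** Seven constants tie the signalling units to cell
counts and density points and are not tabulated: $k_{CSF}$, $k_{dmg}$,
$L_{ref}$, $s_f$, $s_r$, $c_{sec}$, $c_{abs}$. They were fixed by a one-off
calibration of the default cycle and then frozen in
`default_parameters()`: $s_r$ sets the gross resorption of a control cycle
to three density points, $s_f$ makes the control cycle balance-neutral
(|Δz| < 0.2 points, measured −0.00004), and $c_{sec}$ is the root at which
the default cancer load ($N_c = 2000$) loses one density point. Density
loss is monotone in $N_c$ over 0–2000, and scaling the release rate
$r_\beta$ down or up flips the balance to osteoblastic (+1.05) or
osteolytic (−0.98) — the mixed-lesion dichotomy. These are consequences of
the frozen constants, not separately tuned outcomes.

`mixed_lesion_index()` proxies spatially heterogeneous (mixed) lesions by
the standard deviation of per-cycle balances across independent BMUs whose
release intensity $r_\beta$ fluctuates randomly (log-normal by default,
seed-reproducible).

## Sensitivity analysis

`first_order_index()` estimates $S_i = \mathrm{Var}(E[Y\mid X_i]) /
\mathrm{Var}(Y)$ with a nested sampler: outer draws of the target, inner
draws of everything else, conditional means over the inner loop, total
variance from the pooled sample, and an inner-noise correction subtracted
from the numerator (tiny negatives clamp to zero with a log message). On
linear test models it matches the analytic variance decomposition within
Monte-Carlo error, and additive-model indices sum to at most one up to that
error — both tested.

The "10 per cent" prior-spread convention is ambiguous between a standard
deviation and a variance reading; the package defaults to *sd = 10% of the
nominal* (uniform on $\theta(1 \pm 0.1\sqrt3)$), which keeps every support
positive for the default values, and exposes `var10` and `halfwidth10` as
alternatives. Phenotype-vector parameters are sampled entry by entry.
Outputs are read at fixed observation times: 7200 s for the cellular model
(past its relaxation), 24 months for the tissue, end of cycle for the bone
model — all overridable.

At the defaults, the cellular indices reproduce the expected structure:
extracellular ligand and receptor levels are dominated by their own
gene-expression parameters, with the synthesis rate far behind (it enters
ligand and receptor sources symmetrically and largely cancels). In the
bone model our encoding concentrates density sensitivity on the
lining-cell apoptosis rate — because the delay acts through the attrition
factor $e^{-a_{Lng}\tau}$ — with the niche-TGF-beta parameters
($d_\beta$, $r_\beta$) behind it; an encoding that routes the delay effect
through a different channel would order these differently, and this is a
known limitation of the attrition design, recorded here deliberately.

## Numerics

All ODE systems use adaptive `lsoda` with absolute tolerance $10^{-10}$
(nmol scale) and relative $10^{-8}$; the rate constants span five orders of
magnitude and the cellular system is stiff once the receptor pool grows.
The DDE uses the method of steps with dense interpolated history
(`deSolve::dede`); before the initial time the history is the constant
pre-fracture steady state. Integrator undershoots below zero are treated as
zero inside right-hand sides, and any negative output entries are clipped
with a logged count — the default runs produce zero clips. The apoptosis
pulse is a boxcar; output grids are fine enough (0.25–0.5 day) that the
solver resolves its edges. Trajectory tables print 17 significant digits so
write–read–write is byte-identical.

Problem sizes throughout the tests and the acceptance script — 200-day
bone cycles, 24–30-month coupled runs with monthly re-equilibration,
nested sensitivity samples of a few hundred model evaluations — were
chosen as the smallest sizes at which every reported quantity is converged
(step-refinement and inner-refinement checks are part of the suite).

## What the tests do and do not show

The suite establishes internal correctness (oracle agreement, conservation
laws, closed forms, determinism, seed-reproducibility) and the qualitative
and quantitative behaviours described above *at the default tables*. It
does not validate the models against new experimental data: the
gene-expression fixtures are synthetic stand-ins for a reanalysis pipeline,
the bone closure constants are calibrated rather than measured, and the
tissue takeover timing depends on a response normalization that the
available parameterization does not pin down.
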