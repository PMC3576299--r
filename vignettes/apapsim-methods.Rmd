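---
title: "Methods: a whole-body model of acetaminophen metabolism, hepatotoxicity and NAC rescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a whole-body model of acetaminophen metabolism, hepatotoxicity and NAC rescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apapsim)
```

## The model

`apapsim` simulates the disposition and hepatic metabolism of acetaminophen
(APAP) in an adult human, and the liver damage that follows an overdose. The
body is divided into five well-mixed compartments — gut (1 L), plasma (3 L),
liver (1.5 L), peripheral tissue (30 L) and urine (1.5 L) — connected by
first-order transport. Every transfer between compartments carries the
volume ratio of the donor and recipient compartments, so that a flux removing
`k·c` µM/hr from a donor of volume `vD` adds `k·(vD/vR)·c` µM/hr to a
recipient of volume `vR` and moles are conserved exactly.

An oral dose enters the gut as an instantaneous concentration jump
(`dose × bioavailability / MW / vG`; 75% bioavailability, 151.16 g/mol,
1 L gut volume, so the standard 20 mg/kg dose for a 60 kg adult is about
6000 µM) and is absorbed into the liver with rate constant 4 /hr — a
half-life just over 10 minutes.

In the liver (and, at 20% of the liver Vmax, in peripheral tissue) APAP is
removed by three routes:

* **Sulfation** — bi-bi kinetics in APAP and the sulfate donor PAPS
  (`Vmax·S·P/((Km_S+S)(Km_P+P))`). The PAPS pool is small and resynthesized
  slowly (0.1 µM/hr in liver), so the sulfation route saturates at modest
  doses: it is donor-limited, not enzyme-limited.
* **Glucuronidation** — four UGT isoforms with heterogeneous kinetics:
  UGT1 is a Hill enzyme (n = 3.2), UGT3 is Michaelis–Menten, and UGT2 and
  UGT4 show substrate inhibition (`V·S/(Km + S(1+S/Ki))`), each with its own
  interior maximum at `S = sqrt(Km·Ki)`. This route carries most of an
  overdose.
* **P450 oxidation** — three cytochromes (CYP1A2, CYP2E1, CYP3A4) produce
  the reactive quinone imine NAPQI. Their summed Michaelis–Menten flux is
  multiplied by a substrate-activation Hill factor
  `1 + p·S^n/(d^n+S^n)` (p = 20, d = 18000 µM, n = 2): at saturating APAP
  the P450 flux is up to 21-fold its unactivated value. Without this
  activation the pathway cannot generate enough NAPQI at large overdoses to
  reproduce the observed toxicity; it is also why the fraction of a dose
  converted to NAPQI *grows* with dose.

NAPQI is detoxified by GST-catalyzed conjugation with glutathione
(`Vmax·N·G/((Km_N+N)(Km_G+G))`, Km 15 µM for NAPQI and 5200 µM for GSH).
Because the GSH Km is of the same order as the hepatic GSH pool, conjugation
capacity falls roughly in proportion to GSH depletion. NAPQI that escapes
conjugation binds liver protein reversibly (`k_bind` = 1000 /hr,
`k_rev` = 0.25 /hr); the covalent-binding concentration drives hepatocyte
death at rate `η·lcov·lh` (η = 0.213·10^−4.2 /hr/µM), against logistic
regeneration (r = 0.0417 /hr toward a carrying capacity of 1.6·10^11 cells)
and clearance of dead cells (0.2083 /hr). Liver failure ("death") is defined
as the functional-hepatocyte fraction falling below 30%.

Two bookkeeping choices are worth stating. The published equation list for
this model omits the liver-loss terms paired with the liver→plasma and
plasma→liver APAP gains; both loss terms are included here, since without
them the plasma–liver loop creates mass. Likewise the plasma→urine transfer
of the NAPQI–GSH conjugate is written without the `vP/vU` volume ratio the
other urine transfers carry; the default reproduces that form verbatim, and
`mass_consistent_urine_transfer = TRUE` applies the ratio uniformly — the
mole-conservation test runs in that mode with urinary elimination disabled,
and conserves the volume-weighted APAP moiety to 10⁻⁶ relative over 24 h.
The variable `unq` (urinary NAPQI) appears in the published variable table
but has no source reaction or equation, and is not carried. Transport
constants are dimensionally first-order and are treated as hr⁻¹.

## The glutathione surrogate

The APAP model consumes liver GSH through conjugation; what restores it is a
glutathione-metabolism model that the original presentation references but
does not restate. `apapsim` ships an explicit four-state surrogate (liver
GSH, plasma GSH, a hepatic cysteine/precursor pool, plasma NAC), built to be
the smallest structure that reproduces the integrated model's published GSH
behaviour. Its design choices, each load-bearing:

* **Synthesis with saturable precursor dependence and steep product
  feedback** — `V_syn = V_syn_max · c/(Km_cys+c) ·
  1/(1 + fb·(G/G₀)^m)` with a Hill-shaped feedback (m ≈ 12). Near baseline
  the feedback throttles synthesis almost completely, which is why even a
  therapeutic dose leaves GSH below its starting point for days; a third or
  more below baseline the throttle opens and resupply becomes strong. A
  linear feedback cannot do both: the ratio of net resupply at 70% to net
  resupply at 92% of baseline is bounded near 4.7 for any linear form,
  while the published chronic steady state (70% of baseline under 1 g q6h)
  combined with the slow tail of single-dose recovery requires a ratio
  severalfold larger.
* **Synthesis capacity scales with functional liver mass** — `V_syn` is
  multiplied by the functional-hepatocyte fraction: necrotic liver cannot
  synthesize GSH. Besides being physiological, this is what shapes the
  GSH time course after a 20 g overdose into a long depleted plateau whose
  minimum sits tens of hours after the dose — declining liver function and
  declining NAPQI release roughly cancel — rather than a V-shaped dip at
  ~5 h followed by a creeping rise.
* **Saturable sinusoidal export** of GSH to plasma
  (`V·G/(Km_exp+G)`, Km_exp ≈ 0.47·G₀), cleared from plasma first-order.
  A linear export would force the chronic plasma GSH steady state to equal
  the liver one; the observed pair (≈88% plasma vs ≈70% liver) pins the
  export Km through `0.7·(Km+G₀)/(Km+0.7·G₀) = 0.88`.
* **A finite precursor supply** — the cysteine pool is consumed
  stoichiometrically by synthesis, replenished at a constant rate `J_cys`,
  and catabolized with a substrate-induced (superlinear) clearance
  `k·c·(1+c/K_cat)`, mirroring the induction of cysteine dioxygenase by its
  substrate. The constant supply caps *sustained* synthesis during deep
  depletion (the depleted plateau after 15–20 g), and the superlinear
  catabolism is what makes a one-hour NAC bolus less efficient than the
  same amount infused slowly: bolus cysteine is disposed of
  disproportionately. This single nonlinearity reproduces the clinical
  protocol ordering (staged 21 h schedule ≥ 10 h constant infusion ≥ 1 h
  bolus) while leaving the 1 h bolus still clearly effective.
* **NAC as a cysteine source** — infused NAC enters plasma at the protocol
  rate (amounts in mmol distributed into the 3 L plasma volume; the
  standard 36 mmol over 1 h is a 12 mM/hr source), converts to hepatic
  cysteine first-order, and is cleared in parallel. The "36 mM" clinical
  dose is read as an amount (36 mmol into plasma volume), not an infusion-bag
  concentration.

`V_syn_max` and `J_cys` are not free: the constructor derives them from the
requirement that the drug-free baseline (`G = G₀ = 7000 µM`,
`c = c₀`) be an exact equilibrium. The baseline state is therefore analytic
— no pre-integration is needed — and the test suite verifies the fixed point
numerically.

The remaining constants were calibrated, once, against the integrated
model's published behaviours: ~10% liver-GSH depletion with slow recovery
after 1 g; near-complete depletion between 2 and 10 h after 15 g; recovery
onset near 40 h after 20 g; chronic steady states near 70% (liver) and 88%
(plasma) reached after roughly 150 h; the 22 g death/rescue grid with NAC
timing and protocol ordering; and the hepatocyte losses after 10 g with
halved and decimated UGT activity. The calibration was a staged grid search
over the turnover, feedback and precursor constants (deterministic; no
random numbers enter the model), and the shipped defaults are its result.
`gsh_calibrate()` re-verifies any parameter set against these targets and
can refine user modifications; `gsh_calibration_report()` writes the
targets, achieved values and parameters as JSON.

Two published statements are *not* reproducible under the published
constants, and the package does not pretend otherwise. Both trace to the
covalent-binding bookkeeping: with `k_bind/k_rev = 4000` and the GST slope
at most `Vmax/Km_NAPQI · G/(Km_G+G) ≈ 2750 /hr`, every µM of NAPQI produced
contributes at least `k_bind/(slope·k_rev) ≈ 1.45 µM·hr` of integrated
covalent exposure regardless of GSH status. Chaining this with the ~10%
GSH depletion per therapeutic dose (which fixes NAPQI production per 1 g at
roughly 500–700 µM) forces (a) a chronic-dosing necrosis of a few percent,
not the published "< 0.05%", and (b) ~10% hepatocyte loss after 10 g at
normal UGT activity, not "almost no damage". A tenfold smaller death-rate
constant η would fix both but would break the published UGT-polymorphism
and NAC-rescue outcomes, which the package does reproduce. The two
corresponding assertions are retained in the acceptance tests and fail
honestly.

A third compromise concerns the time the chronic simulation takes to
settle. With a 0.5%-per-day moving-mean detector, the shipped model
reaches its chronic steady state in about 82 h, versus roughly 150 h in
the original presentation. This is not a calibration accident: the slow
single-dose recovery (more than 48 h to regain the last few percent of
baseline) caps the net GSH resupply near 92% of baseline at about
9 µM/hr, while the chronic steady state at ~70% requires resupply near
95 µM/hr there — so the synthesis-versus-GSH curve must rise roughly
sevenfold over that interval, which makes the relaxation near the chronic
attractor fast for *any* monotone instantaneous feedback. Surrogate
variants with a lagged (transcriptional) feedback settle considerably
later, but delay the response to NAC enough to break the rescue
experiments, and were rejected; the settling time is reported as
computed.

Similarly, the shipped calibration leaves the 15 g nadir at 6–8% of
baseline rather than below 5%: pushing it lower requires weakening the
depleted-phase synthesis floor, which directly delays the 20 g recovery
onset past its published window. The shipped target for that metric is
`< 8%`, with the depleted window overlapping the published 2–10 h
interval.

## Numerics

The system is stiff (rate constants span 3.3·10⁻³ to 10³ /hr), so
integration uses `deSolve::lsoda` with `rtol = 1e-6`, `atol = 1e-9`.
Integration is piecewise between dose events: oral boluses restart the
integrator with a gut-concentration jump, and NAC infusion windows
contribute a constant source term per segment, so the solver never steps
across a discontinuity. Output is dense (10 samples/hr by default).
Hepatocytes are integrated as fractions of carrying capacity rather than
cell counts (~10¹¹), purely for conditioning; trajectories report both.
Solver undershoot below zero is clipped at evaluation time, with a warning
beyond −10⁻⁶. Halving the tolerances moves the minimum hepatocyte fraction
of the worst-case (22 g) scenario by less than 10⁻⁴.

Event times, infusion windows and protocol construction are exact
arithmetic; trajectories are deterministic and bit-reproducible for fixed
solver settings. Tests and the acceptance script use the problem sizes of
the published experiments themselves (single doses over 48–120 h, the
chronic regimen over 240 h, a survival boundary on a reduced grid of
presentation times), each a stiff integration of seconds on one CPU.

## What the simulations do and do not show

All experiments here are *in silico* reproductions of a mechanistic model:
the dosing scenarios (therapeutic 1 g, overdoses of 10–22 g, chronic 1 g
q6h, the three NAC protocols) are the study conditions, not fitted data.
Agreement of the package's outputs with the published curves shows that the
reimplementation and its glutathione surrogate reproduce the model — not
that the model is right about patients. In particular the surrogate
compresses an entire glutathione network into four states: it has no
methionine cycle, no transsulfuration, no oxidative-stress or GSSG redox
arm, and its "cysteine" pool is a lumped precursor whose constants are
fitted, not measured. The patient-level mortality comparison that
accompanied the original model (53 retrospective cases with externally
estimated doses and times) is out of scope; the survival-boundary curves
assume a protocol-1 rescue at presentation, a choice exposed as a
parameter.

## Parameters that matter most

| knob | default | unit | role |
|---|---|---|---|
| `cyp_fold` | 1 | – | scales all P450 activity (induction studies) |
| `ugt_fold` | 1 | – | scales all four UGT Vmax (polymorphism studies) |
| `bioavailability` | 0.75 | – | oral dose reaching the gut pool |
| `body_mass_kg` | 60 | kg | mg/kg ↔ mg conversion only |
| `eta` | 1.34·10⁻⁵ | /hr/µM | hepatocyte death per unit covalent binding |
| `lgsh_baseline` | 7000 | µM | hepatic GSH steady state (fitted) |
| `feedback_strength`, `feedback_hill` | 60, 12 | – | GSH feedback on synthesis |
| `k_cys_clear`, `Km_cys_catab` | 0.17, 1700 | /hr, µM | precursor catabolism (NAC efficiency) |
| `death threshold` | 0.30 | – | hepatocyte fraction defining liver failure |

(The glutathione defaults shown are the shipped calibration; construct
`gsh_parameters()` to see the full derived set.)
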