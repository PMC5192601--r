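---
title: "Modelling proton-coupled sucrose translocation in a growing plant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling proton-coupled sucrose translocation in a growing plant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plantflux)
```

## The scientific problem

Growing plants move carbon from photosynthetically active source tissue
(mesophyll) to heterotrophic sink tissue (roots) almost exclusively as
sucrose.  Export from the source is carried by SWEET-family facilitators
that follow the sucrose gradient and are independent of the proton motive
force; uptake into the phloem and into the sink is carried by SUC/STP-family
sucrose-proton symporters, which spend the transmembrane proton gradient
built by plasma-membrane H+-ATPases.  Whether a flux distribution is
consistent with this mechanism is therefore a question about the *proton
economy* of every tissue as much as about carbon: photosynthesis, aerobic
respiration, nitrate and sulphate reduction and the biosynthetic machinery
all produce or consume protons at known stoichiometries.

`plantflux` implements a multi-compartment stoichiometric model of a
growing C3 plant at steady state — mesophyll (with plastid and
mitochondrion), transport phloem, root (with mitochondrion), a shared
apoplast inside the plant, the external environment and a virtual vacuole
that accumulates biomass deposits — together with the analysis pipeline
applied to it:

* exact-rational elemental and charge consistency checking,
* topological analysis (degrees of freedom, conserved moieties as
  non-negative left-nullspace extreme rays, internal parallel routes,
  elementary flux modes at small scale),
* flux balance analysis (FBA): maximise biomass formation `Z = c'v`
  subject to `S v = 0` and flux bounds, under a light and a dark
  constraint preset, with parsimonious (minimal total flux) and
  variability variants,
* derived ledgers: precursor ratios, plastid ATP/NADPH exchange fractions,
  per-compartment ATP budgets and proton ledgers, and a sucrose
  translocation audit.

## Model structure and assumptions

The packaged network (`build_model()`) is a deliberately reduced
reconstruction (about 250 transformers) of the central carbon and energy
metabolism of *Arabidopsis thaliana*; linear biosynthetic routes are lumped
(documented per reaction in the source), while the energy- and
proton-relevant machinery is written at full mechanistic stoichiometry.
The assumptions mirror the source reconstruction: sucrose is the only
carbohydrate exchanged between tissues, and only from source to sink;
starch is formed exclusively in the light and is the only dark carbon
source; nutrient uptake is proton-symported at the root and routed
symplastically through the phloem; only GAP and maltose carry carbon
across the plastid envelope; gas exchange is passive and located at the
mesophyll.

Key stoichiometric commitments, with their rationale:

* **Linear electron transport** delivers 4 lumenal H+ per NADPH (2 from
  water oxidation at PSII, 2 at cytochrome b6f without a Q-cycle) and the
  plastid ATP synthase translocates 4 H+ per ATP, so non-cyclic flow yields
  ATP:NADPH = 1.0 exactly — the textbook value for this wiring.
* **Cyclic electron flow** (`FQR`) is modelled as an NDH-type
  proton-pumping ferredoxin-plastoquinone reductase: 2 H+ pumped per
  electron at the complex plus 1 H+ per electron at b6f, i.e. 1.5 ATP per
  electron pair.  A passive (non-pumping) cyclic path would place the
  plastid ATP self-sufficiency point far outside the scanned FQR/FNR range
  (near 0.85); with NDH-type pumping the packaged model becomes
  self-sufficient near FQR/FNR ≈ 0.33, in line with the reference
  behaviour (≈ 0.37), and NDH-1 is the proton-pumping cyclic route
  documented for chloroplasts.
* **Oxidative phosphorylation** pumps 10 H+ per NADH (complexes I+III+IV)
  and 6 per succinate-derived quinol, with a 4 H+/ATP synthase, giving the
  theoretical P/O of 5.0 per O2 for pure NADH oxidation and ≈ 4.7 for a
  running TCA cycle.
* **Electrons and one-electron carriers** (ferredoxin, plastocyanin,
  cytochrome c) are massless species carrying only charge, so
  photolysis and electron-transport half-reactions pass exact charge
  balance without fictitious elements.
* Each metabolite carries one fixed formula and charge chosen at pH 7;
  no pH-dependent speciation.
* The plastid nucleotide translocator counter-transports Pi
  (ATP in / ADP + Pi out), the canonical stoichiometry that keeps the
  stromal phosphate pool closed when the dark plastid imports ATP.
* Protons acquired with nutrients at the root travel to the shoot with the
  root-to-shoot stream (root → phloem → tissues).  Without this link the
  mesophyll could never net-import the protons its nitrate and sulphate
  reduction consume, and growth would be structurally infeasible — the
  whole-plant proton balance is the load-bearing part of this model.
* **Maintenance ATP** has no prescribed magnitude: an unforced cytosolic
  ATP hydrolysis reaction exists (default bounds `[0, Inf)`), and
  H+-ATPase activity emerges from the proton balance.  No growth-associated
  maintenance is charged; the model's intrinsic demands (proton pumping,
  monomer activation, translocation) reproduce the dark respiratory
  quotient on their own.

## Biomass

Whole-plant dry biomass is composed of 20 % cellulose, 20 % pectin, 10 %
starch, 12 % sucrose, 25 % protein, 9 % lipid, 1 % RNA and 3 % ash by
mass, split 85/15 between shoot and root; starch is assigned entirely to
the shoot (the root has no plastid) with the other polymers redistributed
so the whole-plant composition is preserved.  The packaged monomer tables
are documented averages: an eight-amino-acid protein composition
(N/C ≈ 0.30), the printed lipid monomer fractions renormalised from their
99.706 % total, and RNA base fractions 32/26/9/33 (A/U/C/G).

The ash fraction is realised as vacuolar nitrate and phosphate deposits
whose magnitudes are calibrated so the whole-plant elemental composition
matches the reconstruction targets N/C = 0.144 and P/C = 0.033 per carbon.
This calibration is forced by an internal tension of the source data: the
printed polymer composition cannot reach the printed elemental subscripts
(the oxygen subscript remains ~20 % high in any case, and the implied
deposit mass exceeds the nominal 3 % ash).  The tension is recorded rather
than hidden: `compose_biomass()` derives the formula from the packaged
tables, never asserts it.

All biomass coefficients are rounded to rationals (10^-6 precision) and
the tissue biomass formulas are then derived *exactly* from the rounded
coefficients, so the growth pseudo-reactions pass the same exact balance
check as every enzymatic reaction.

## Scenarios

`plant_scenario("light")` maximises biomass with the verbatim constraint
rows of the reference table: biomass capped at 5000 (an arbitrary scale;
all reported ratios are invariant to it, which the tests check at cap 50),
starch degradation and net CO2 efflux forbidden, photorespiration coupled
to carboxylation (`pr * RPC_plastide - RPC2_plastide = 0`, default
multiplier 0.25), and optionally one of: no cyclic flow (`FQR = 0`),
a self-sufficient plastid (`T.ADP.plastid - T.ATP.plastid = 0`), a fixed
cyclic/non-cyclic ratio (`r*FNR - FQR = 0`, r in [0, 0.5]), or
photorespiration off (`RPC2_plastide = 0`, `GLYK = 0`).
`plant_scenario("dark")` zeroes photon uptake, RuBisCO, photorespiration
and starch synthesis and lets starch be consumed.

All published-style reports are computed from **pfba** solutions (stage 1:
optimum; stage 2: minimal total absolute flux) so that degenerate optima
and futile cycles cannot leak into reported numbers; "total turnover" of a
metabolite is the gross sum of its positive production terms, which makes
exchange fractions well-defined.  One scenario detail deviates from the
derived contract on the paper's own authority: FNR is reversible, and in
darkness it runs in reverse (oxidative-PPP NADPH reduces ferredoxin to
feed nitrite and sulphate reduction), so a dark FVA shows FNR in
`[min < 0, 0]` while RuBisCO, PSII and FQR are fully blocked.

## Numerical choices

Stoichiometry, balance residuals and all topology kernels use exact
rational arithmetic on double-backed integers (hard failure beyond 2^53 —
never a silent loss of exactness); nullspace computations clear
denominators by row/column scaling first, which leaves the respective
kernels unchanged.  Conserved moieties are the extreme rays of
`{w >= 0 : w'S = 0}` enumerated by incremental double description with a
combinatorial adjacency test; enumeration beyond the configured ray limit
raises a resource error rather than truncating.  Only the linear programs
themselves are solved in floating point (SciPy's HiGHS backend through
a bundled helper; every reported solve carries a primal-dual certificate
checked to 1e-6 relative, and steady-state residuals are verified to 1e-6
of the flux scale).  Reversible transformers are split for elementary-mode
enumeration and re-merged with a lexicographic tie-break.

## What the synthetic generators establish — and what they do not

`gen_network()` plants conserved moieties (carrier pairs re-loaded through
an exchange step) and internal parallel routes (duplicated conversions) in
random networks over abstract elements; conversions are drawn as edges of
a random tree because *any* undirected cycle among balanced conversions is
automatically a flux cycle.  Degenerate draws are detected and re-drawn
with a logged seed advance.  `gen_lp()` constructs chain LPs whose optimum
is known by construction and certified by the chain of yields.  A green
test against these fixtures establishes that the detectors and the solver
recover *planted, verified* structure; it does not establish biological
realism of random networks — that is the packaged model's job — nor solver
performance at genome scale.

The miniature `toy_plant()` shares the full model's translocation
mechanism (SWEET efflux, sucrose-proton symport, H+-ATPase, environment
proton uptake at the sink) and exercises every analysis stage in well
under a second; its dark scenario is intentionally infeasible (it has no
starch) to exercise infeasibility handling.

## Known limitations

Exact reproduction of the reference reconstruction's inventory (400
transformers, 742 genes) is out of scope; counts are qualitative.  The
inner degrees of freedom (15 here vs 10) differ with the reduced model's
reversible organelle transports, while the outer degrees of freedom (5)
agree.  Percentage shares of ATP budgets and proton ledgers are
tolerance-level reproductions, sensitive to lumping.  The phloem is purely
a transport compartment (no own ATPase or catabolism).  Kinetics,
thermodynamic (ΔG) feasibility, membrane potential and quantitative ΔpH
are out of scope; pH enters only as ordinal ranks for gradient-direction
audits.
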