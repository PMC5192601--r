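# plantflux

Constraint-based modelling of proton-coupled sucrose translocation in a
growing C3 plant.

## What this package is for

In growing plants, sucrose made in the photosynthetic mesophyll (the
*source*) is exported into the apoplast by proton-independent SWEET
facilitators, loaded into the phloem and taken up by the heterotrophic
root (the *sink*) through sucrose–proton symporters (SUC/STP families)
that spend the transmembrane proton gradient built by plasma-membrane
H⁺-ATPases.  Whether a metabolic flux state can actually power this route
is a whole-plant bookkeeping question: photosynthesis, respiration,
nitrate/sulphate reduction and biosynthesis all produce or consume protons
with fixed stoichiometry, and the proton ledgers of mesophyll, phloem,
root and apoplast must close simultaneously with carbon, nitrogen, energy
and redox balances.

`plantflux` packages a reduced multi-compartment stoichiometric model of
*Arabidopsis thaliana* central carbon and energy metabolism — mesophyll
with plastid and mitochondrion, transport phloem, root with mitochondrion,
shared apoplast, environment, and a virtual vacuole for biomass deposits —
together with the full analysis pipeline applied to it.  It is aimed at
plant systems biologists who want a transparent, exactly balanced,
fully scriptable reconstruction of diel (light/dark) source–sink
metabolism, and at methods developers who need an exact-arithmetic
topology kernel with verified synthetic fixtures.

At its core is flux balance analysis: maximise biomass formation
*Z* = **c**ᵀ**v** subject to steady state **S·v = 0** and bounds
*ν*ᵢᵐⁱⁿ ≤ *v*ᵢ ≤ *ν*ᵢᵐᵃˣ, solved parsimoniously (minimal Σ|v| among
optima).  Around it:

* exact-rational elemental/charge balance checking of every transformer;
* topology: degrees of freedom, conserved moieties (extreme rays of
  {w ≥ 0 : wᵀS = 0} by double description), internal parallel routes,
  elementary flux modes on small networks;
* light/dark scenario presets with the published constraint rows
  (`0.25*RPC_plastide - RPC2_plastide = 0`, `T.hv.ext = 0`, ...), a
  scenario mini-language, FVA, and an FQR/FNR cyclic-electron-flow scan;
* derived reports: precursor ratios (photon/CO₂, P/O, ATP/NADPH, RQ),
  plastid exchange fractions, compartmental ATP budgets and proton
  ledgers, and a sucrose-translocation audit;
* synthetic generators with verified planted ground truth (moieties,
  cycles, LP optima) so every analysis stage is testable offline;
* SBML import/export and a command-line interface.

## Worked example

```r
library(plantflux)

net <- build_model()
net
#> <pf_network> 9 compartments, 275 species (265 balanced), 259 transformers
#>   reactions 157 | transports 88 | polymerizations 14 | reversible 89

sol <- pfba(net, plant_scenario("light", ratio = 0.37, net = net))
precursor_ratios(net, sol)
#> <ratio_report> scenario light
#>   photon_per_co2           16.46
#>   photon_per_no3           114.3
#>   co2_per_no3              6.943
#>   po_mes                   4.767
#>   po_root                  4.705
#>   atp_per_nadph_plastid    1.692
#>   atp_per_nadh_mito        2.383
#>   h_per_atp_plastid        4
```

Under the light preset (photorespiration/carboxylation 0.25, cyclic to
non-cyclic electron flow FQR/FNR = 0.37) the plant fixes one net CO₂ per
16.5 photons, takes up one nitrate per 6.9 CO₂, and runs its mitochondria
at P/O ≈ 4.7–4.8 — oxidative phosphorylation close to its theoretical
ceiling of 5, because in the light the mitochondrion mostly burns NADH
delivered by the malate/oxaloacetate shuttle rather than running the full
TCA cycle.  The plastid turns over 1.69 ATP per NADPH while its ATP
synthase translocates exactly 4 H⁺ per ATP.

```r
plastid_exchange_fractions(net, sol)
#> <exchange_fractions> light: T.ATP/ATP -0.022  T.NADPH/NADPH -0.001  T.H+/H+ +0.004

atp_crossing(net, ratios = seq(0.2, 0.5, by = 0.05))$estimate
#> [1] 0.331
```

At FQR/FNR = 0.37 the plastid is almost exactly self-sufficient in ATP
(2 % of turnover exported); scanning the ratio shows the import fraction
falling monotonically and crossing zero at ≈ 0.33 — below that the plastid
must import cytosolic ATP and export reduced equivalents through the
malate/oxaloacetate shuttle.

```r
sucrose_audit(net, sol)
#> <sucrose_audit> light: PASS
#>   [ok] single_source_tissue       1
#>   [ok] single_sink_tissue         1
#>   [ok] source_export_positive     3.135
#>   [ok] sink_import_positive       3.135
#>   [ok] efflux_proton_independent  2
#>   [ok] influx_proton_symport      2
#>   [ok] no_sink_reexport           0

dark <- pfba(net, plant_scenario("dark", net = net))
precursor_ratios(net, dark)$rq
#> [1] 1.79509
```

The audit certifies the translocation mechanism on the solved state:
exactly one net sucrose exporter (mesophyll) and one importer (root), all
efflux steps proton-independent, all uptake steps co-consuming at least
one proton per sucrose — and this holds in darkness too, when starch is
the sole carbon source and the whole-plant respiratory quotient is 1.80
(biomass plus nitrate reduction are more reduced than starch, so extra
CO₂ leaves without matching O₂ uptake).

Topology of the packaged model:

```r
conserved_moieties(net)$n            # 28 moieties, all biologically named:
#> [1] 28                            # NAD(P)H/NAD(P) per compartment, Fd,
                                     # PQ, PC, CoQ, cytochrome c, THF set,
                                     # CoA sets, organellar ATP/ADP pools
degrees_of_freedom(net)
#> $total 20  $inner 15  $outer 5
```

## Command line

```sh
Rscript inst/cli/plantflux.R build -o model.xml
Rscript inst/cli/plantflux.R validate model.xml
Rscript inst/cli/plantflux.R run --scenario light --fqr-fnr 0.37 --pr 0.25 --out run_light
Rscript inst/cli/plantflux.R scan --grid 0:0.5:0.05 --out scan.tsv
Rscript inst/cli/plantflux.R fixtures --seed 7 --moieties 2 --cycles 1
```

`run` writes a report directory with the flux table, ratio/exchange
reports, ATP budgets, proton ledger, sucrose audit, manifest and log.

## Further reading

`vignettes/plantflux-methods.Rmd` documents the model assumptions, the
biomass derivation and its calibration, the numerical design (exact
rational kernel, LP certification), what the synthetic generators do and
do not establish, and known limitations.
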