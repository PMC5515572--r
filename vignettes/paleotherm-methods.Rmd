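---
title: "Inferring fossil thermophysiology from apatite oxygen isotopes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring fossil thermophysiology from apatite oxygen isotopes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleotherm)
```

## The inference problem

The oxygen isotope composition of vertebrate bone and tooth apatite
phosphate (δ¹⁸Oₚ, ‰ V-SMOW) is set jointly by the animal's body temperature
and by the δ¹⁸O of its body water, which derives from local meteoric water
modified by the animal's ecology and physiology. An ectotherm's body
temperature tracks ambient temperature, which falls with latitude; an
endotherm's does not. Two animals buried in the same deposit drank from the
same waters, so the *difference* between their δ¹⁸Oₚ values cancels the
(poorly known) local meteoric-water composition and retains only two terms:
a thermal term and an ecology term. Plotted against palaeolatitude, the
difference between a constant-body-temperature animal and an
ambient-tracking one slopes with latitude, while the difference between two
animals of like physiology does not. `paleotherm` operationalises this
reading: it screens fossil apatite for diagenesis, aggregates measured
δ¹⁸Oₚ per taxon and locality, forms co-located pair differences with
propagated uncertainty, predicts the difference bands each physiological
scenario allows, and classifies each pair by band membership.

## The thermometer

The phosphate–water palaeothermometer is linear over the biological range:

$$ T\,(^{\circ}\mathrm{C}) = \alpha - \beta\,\big(\delta^{18}O_p - \delta^{18}O_{bw}\big), $$

with intercept α = 117.4 °C and slope β = 4.50 °C ‰⁻¹ by default
(`default_config()$thermometer`; both are configuration parameters, not
assertions — users working with a recalibrated thermometer should override
them). Inverting gives the predicted apatite composition
`predicted_d18Op()`: δ¹⁸Oₚ = δ¹⁸O_bw + (α − T)/β. One degree of body
temperature is therefore worth 1/4.5 ≈ 0.22 ‰, which sets the leverage of
the whole method: a 30 °C contrast between an endotherm at 37 °C and a
high-latitude ectotherm maps to ≈ 6.7 ‰ — far above analytical noise —
while near the equator the contrast shrinks toward the band-crossing point
and calls become genuinely ambiguous.

## Climate: the latitudinal gradient

Ambient (and hence ectotherm body) temperature is modelled linearly in
absolute palaeolatitude, `T = t_equator − g·|lat|`, with per-time-bin
defaults for the gradient g (°C per degree latitude):

| time bin | g | σ_g |
|---|---|---|
| permian | 0.6 | 0.1 |
| early_mid_triassic | 0.4 | 0.1 |
| mid_late_triassic | 0.5 | 0.1 |

The Permian value is the modern-type gradient; the Triassic bins use
flatter, warmer-world gradients. The equatorial anchor `t_equator`
defaults to 30 °C for every bin. Only the *difference structure* — not the
absolute temperatures — drives the band slopes, but the latitude at which
the endotherm-vs-ectotherm band crosses the same-physiology band does
depend on `t_equator` (ambient equals 37 °C at |lat| = (t_equator − 37)/g,
off-grid for the defaults), so this parameter is deliberately prominent in
the configuration. An optional clamp `tb_ecto_min` (disabled by default)
floors ectotherm body temperature to represent active-season
thermoregulation at high latitude; enabling it flattens the oblique bands
poleward of the clamp latitude. Both hemispheres are treated symmetrically:
the framework consumes |lat|.

## Ecology offsets

Habitat use shifts body water relative to local meteoric water: terrestrial
drinkers are evaporatively enriched, water-bound taxa sit at or below the
meteoric value. The defaults encode that ordering as ranges (‰):
terrestrial (0, +2), semi-aquatic (−2, 0), aquatic (−3, −1). These are
free parameters of the framework, exposed in
`default_config()$physio$ecology_offset`; the published inter-ecology
contrasts they stand in for are compilation values for modern mammals, and
any user with taxon-specific physiological models should replace them. The
focal (therapsid-side) animal is treated as terrestrial in all four
standard comparison scenarios.

## Envelopes and classification

For a co-located pair the predicted difference is

$$ \Delta^{18}O_p = \frac{T_{ref} - T_{focal}}{\beta} + (\varepsilon_{focal} - \varepsilon_{ref}), $$

with ε the ecology offsets. `build_envelopes()` evaluates this on a 1°
latitude grid for four scenarios — endotherm-vs-ectotherm and
same-physiology, each against a semi-aquatic and a terrestrial reference —
sweeping the corners of (g ± σ_g) × (offset ranges). Corner sweeping is
exact here because the map is linear and monotone in each swept parameter;
no Monte-Carlo is needed, and setting σ_g = 0 collapses the outer band onto
the core band by construction. Same-physiology bands lose the thermal term
entirely (both animals share whatever temperature applies), so they are
latitude-independent and their core and outer bands coincide.

`classify_pair()` tests whether the observation interval
delta ± k·σ_delta (k = 1 by default) overlaps the oblique and the vertical
outer band at the pair's palaeolatitude: one membership gives a decisive
call, both give `ambiguous`, neither gives `out-of-model`. When the
reference taxon is itself presumed endothermic the semantics flip: the
vertical band then supports focal endothermy, and the oblique band is
reflected about the vertical band's centre (the thermal term changes sign
when the roles swap, the ecology term does not). Reference presumptions are
interpretive *inputs*, shipped as an editable table
(`default_reference_thermo()`): stereospondyls and parareptiles
ectothermic, archosauriforms and basal sauropodomorphs endotherm-like.
Increasing k can only widen intervals, so calls move monotonically toward
ambiguity and never flip directly between the two decisive calls — a
property the test suite checks explicitly. Palaeolatitude uncertainty is
recorded with every pair but not folded into the membership test: the
band-overlap reading is made at the locality's central palaeolatitude.

## Uncertainty semantics

All "±" values are treated as 1σ standard errors and combined in
quadrature. Subsamples of one individual are averaged first; the taxon mean
is the unweighted mean across individuals, so a heavily subsampled specimen
cannot dominate. The standard error is floored at
`analytical_sigma/√n` with `analytical_sigma = 0.20 ‰` — the long-term
reproducibility of the NBS120c phosphorite standard — so a single-specimen
taxon carries se = 0.20 ‰ and two such taxa difference to
√2·0.20 ≈ 0.28 ‰ (printed "± 0.3"). The floor reconciles two requirements:
small samples may not report an se below what the instrument allows, while
multi-individual dispersion dominates as soon as it exceeds the analytical
term. The quadrature rule is verified in the tests against a 100,000-draw
Monte-Carlo resampling oracle across standard errors from 0.1 to 3 ‰.

## Diagenesis screening

Two independent criteria, both strict inequalities:

* structural carbonate content > 13.4 wt% — above the modern vertebrate
  range, indicating secondary inorganic carbonate;
* δ¹⁸O_c − δ¹⁸Oₚ > 14.7 ‰ — beyond the widest offset observed in living
  vertebrates, indicating microbially mediated alteration.

A failure discards the *carbonate* value only: low-temperature inorganic
alteration has little effect on phosphate δ¹⁸O, so `phosphate_usable`
remains `TRUE` unless the conservative switch
`drop_phosphate_on_cp_fail` is enabled (the offset rule is the
microbial-alteration signal, which does cast doubt on phosphate).
Samples missing the carbonate measurements are reported `not_evaluable`
rather than excluded — published phosphate-only data would otherwise be
lost. A 10⁻⁹ ‰ guard keeps samples sitting exactly at a threshold on the
passing side of the strict inequality when the offset is computed in
floating point.

## The forward simulator

`simulate_dataset()` runs the framework equations forwards so every stage
can be tested against known ground truth with no external data. Per
individual: body temperature from the simulated physiology (37 °C or
ambient at the locality); an ecology offset drawn *uniformly* within its
range (ranges, not distributions, are what the framework encodes); body
water = meteoric water (linear in latitude, default −0.30 ‰/° from 0 ‰ at
the equator — this cancels in all differences and exists only to keep
absolute values in the realistic 8–25 ‰ window); per subsample, Gaussian
analytical noise of 0.20 ‰ on both δ¹⁸Oₚ and δ¹⁸O_c, a pristine
carbonate–phosphate offset of 8 ‰ (centre of the modern-mammal 7–9 ‰
range) and baseline carbonate of 5 ± 1 wt%. A configurable fraction
(default 10%) of samples receives an additive diagenetic overprint of
+8 ‰ on δ¹⁸O_c and +12 wt% carbonate — secondary-calcite addition sized to
carry both screening statistics clearly past their thresholds — while
leaving phosphate intact, matching the robustness argument the screening
rules encode; a phosphate-attack mode exists but is off by default. The
default study design (`default_sim_design()`) is three localities at 20°,
40° and 60° with four taxa each, five individuals per taxon, the scale of
a single well-sampled assemblage-zone comparison.

What the simulator does *not* emulate: taphonomic and collection bias,
time-averaging within assemblage zones, bone-versus-tooth systematic
offsets, seasonal body-temperature cycles, humidity-driven structure in
meteoric water. Passing end-to-end tests therefore demonstrate that the
pipeline's inferences are correct *under the stated forward model*, not
that real assemblages satisfy that model.

## Numerical and design choices

* **Grids and interpolation.** Envelopes are tabulated at 1° steps; bands
  are linear in latitude, so the linear interpolation used when
  classifying from a re-read grid is exact, and an exported grid
  reproduces in-memory calls bit for bit.
* **Determinism.** All simulator randomness flows from one integer seed
  through R's RNG; the analysis stages are deterministic, and reruns with
  identical inputs produce byte-identical output files. The run manifest
  omits wall-clock timestamps by default for exactly this reason.
* **Degenerate inputs.** Empty sample sets, taxa without co-located
  references, and missing optional measurements all pass through with
  explicit empty results, warnings, or `not_evaluable` states rather than
  errors; hard errors are reserved for schema violations, non-co-located
  pair requests, unknown time bins and unresolvable reference taxa.
* **Problem sizes in the checks.** The shipped verification suite uses a
  108-row designed fixture, 1,000-sample screening worlds, 100,000-draw
  Monte-Carlo oracles, and 200 replicate simulated worlds of 24 samples
  each — sizes chosen so each check exercises the relevant asymptotics
  while the whole suite stays interactive.

## Known limitations

The linear gradient ignores continentality and seasonality; `t_equator`
and the endotherm set point are conventions that shift band crossings; the
ecology offsets are modern-mammal stand-ins applied to Permo-Triassic taxa;
and the band-overlap rule deliberately encodes no informal judgment about
borderline specimens — a pair sitting just inside the oblique band is
called decisively even when a human reader might want more samples first.
Single-specimen taxa inherit the analytical-floor uncertainty, which
understates true biological dispersion; their calls should be read
accordingly.

## A synthetic fixture, not the measured record

The packaged fixture (`inst/extdata/synthetic_sd1_*.csv`) is a *designed*
dataset: 108 subsample rows over 90 individuals and 11 localities whose
per-taxon means were constructed so the pipeline's arithmetic and call
pattern can be asserted exactly. It mirrors the layout of a real
Permo-Triassic collecting programme but contains no measured values, and
nothing in this package's tests constitutes a reanalysis of any published
specimen.
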