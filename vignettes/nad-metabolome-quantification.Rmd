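---
title: "Quantifying the NAD+ metabolome by isotope-dilution SRM: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the NAD+ metabolome by isotope-dilution SRM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadq)
```

## The measurement problem

NAD⁺ metabolites span roughly three orders of magnitude of intracellular
concentration (∼1 µM to ∼1 mM), many differ by a single Dalton (NAD⁺/NAAD,
NADH one mass unit above NAD⁺'s ¹³C isotope peak, carboxylic acid versus
carboxamide pairs), and several interconvert enzymatically within minutes
of lysis. A targeted triple-quadrupole assay addresses specificity by
monitoring one precursor→fragment transition per analyte at a
characteristic retention time, in two separations: an alkaline one
resolving 16 analytes and an acidic one for Nam, NA and NR. What a
transition trace gives you, however, is an *area in arbitrary counts*, and
the mapping from area to amount is corrupted by ionization suppression:
co-eluting matrix components damp an analyte's response by an unknown,
sample-dependent factor.

The assay's central idea is that a co-eluting heavy isotopologue of the
same analyte experiences the *same* suppression, so the light/heavy area
ratio times the known heavy amount is suppression-free. `nadq` implements
that idea end to end, plus everything around it: peak integration,
standard-curve calibration, internal-standard lot assignment, surrogate
correction factors, volume bookkeeping, QC statistics, and a simulator
that generates SRM runs with known ground truth.

## The assay registry

`load_registry()` packages the 20-channel panel: 19 quantifiable
metabolites plus NADPH, which is monitored (transition 745 > 729) but
flagged `quantifiable = FALSE` — its peak cannot be separated from
oxidation artefacts, so it may be simulated but is never reported. AMP is
deliberately absent: ATP and ADP fragment on-source to AMP, so an AMP
channel would measure biology plus artefact; validation rejects panels
declaring AMP quantifiable. NADPH has no published retention time; the
registry assigns an assumed 12.5 min (between NADP and NAD⁺) purely so its
channel can be simulated.

Heavy channels follow the labelling chemistry: +5 Da per ¹³C-ribose (one
ribose in nucleosides and mononucleotides, two — +10 Da — in
dinucleotides), +2 Da per ¹⁸O for the vitamin standards. Fragment-ion
offsets are stored explicitly per metabolite because some monitored
fragments shed the labelled ribose (e.g. ADP's 136 fragment is the bare
adenine); where a fragment keeps all labelled riboses the full offset
applies. This is a modelling decision: heavy MS² transitions are not
tabulated anywhere, and the offsets matter only for channel bookkeeping,
not for quantification.

## Peak processing

Traces are treated as baseline-corrected intensity series (negative
excursions from detector noise are legal; the integration baseline is
zero). Three numerical choices matter:

* **Noise** is 1.4826 × the median absolute deviation of intensities
  outside the expected peak windows — robust to the peaks themselves, and
  floored (default 1 count) so noise-free traces keep finite S/N.
* **Detection and bounds** run on a lightly smoothed copy (5-point moving
  average): local maxima above 3 × noise seed peaks, and bounds extend to
  the nearer of the first local minimum and the 2%-of-apex crossing. A raw
  local-maximum rule splits real peaks at noise wiggles on a flank, so
  adjacent detections whose claimed regions touch and whose connecting
  valley stays above half the smaller apex are merged back into one peak.
  Areas are trapezoidal integrals of the *raw* trace between those bounds;
  heights (for S/N) come from the smoothed trace, which costs ~4% of peak
  height at the default widths — irrelevant for quantification, a small
  conservative bias for LOQ estimation.
* **Peak selection** takes the apex nearest the registry retention time
  within ±0.3 min (ties → larger area). The default window is set just
  under the closest crosstalk spacing in the panel — the cytidine isotope
  peak sits 0.36 min before uridine — so crosstalk signal, which always
  appears at the *source* metabolite's retention time, is rejected by
  construction.

Capacity factors use `k' = (rt − t0)/t0` with a per-separation void time
defaulting to 1.40 min, the value implied by the panel's (RT, k') pairs
(e.g. NAMN at 4.2 min with k' = 2). One published row (NADH, k' = 12 at
12.98 min) is inconsistent with every other row's implied void time and is
treated as a typographical error rather than an anchor.

## Calibration, lot assignment and correction factors

Standard curves are unweighted ordinary least squares of light area on
on-column amount over the nonzero levels of the nine-point series, with a
free intercept; the zero level only informs noise. The series spans
0.125–250 pmol on column (µM × 0.5 mix fraction × 2.5 µl). The linear
range is the widest contiguous run of levels whose back-calculated amounts
sit within 15% of nominal — a common back-calculation convention, chosen
because the assay's own definition is not stated. With default simulator
settings the full 0.125–250 pmol range is recovered for low-LOQ analytes;
analytes whose designed LOQ exceeds the lowest levels (uridine at 3.1
pmol, NA, NMN, ATP) cannot be linear down to 0.125 pmol under an S/N = 10
LOQ definition — the two published claims are mutually inconsistent there,
and the package sides with the LOQ.

The internal-standard lot is assigned by interpolating each heavy channel's
areas, across all nine standard injections (each carries the same lot
aliquot), on that analyte's light curve; the mean is the assigned pmol,
reported with its CV. The ¹⁸O Nam and NR spikes are assigned the same way
against the light Nam/NR curves — deliberately ignoring their nominal
1.5 µM, since 10 mM light stocks are prepared far more accurately than
dilute labelled standards. Correction factors (IMP via NMN, NA via heavy
Nam) are means of response-factor ratios over standard levels where *both*
channels reach S/N ≥ 10; below that, area ratios are noise-dominated and
would inflate the factor's variance several-fold.

LOQ is the amount producing S/N = 10, found by log-linear interpolation of
amount against S/N. From the coarse nine-level curve (2–3.3× level
spacing) this is an order-of-magnitude estimate; measured the way LOQs are
measured in practice — a dedicated dilution series bracketing the
crossing — the estimator lands within 15% of the designed value, and that
is what the acceptance tests check. When every curve level already exceeds
S/N 10 the crossing is extrapolated below the lowest level and flagged.

## Quantification and volume bookkeeping

For each sample injection, own-channel analytes get
`pmol = A_light/A_heavy × lot`, surrogate analytes
`pmol = A_light/A_heavy(surrogate) × lot(surrogate)/cf` (flagged
`via_correction`). Amounts below the analyte's LOQ, or with no detected
light peak, are reported as a concentration *bound* (the LOQ pushed
through the same volume bookkeeping), never as a value. A missing heavy
peak makes the analyte unquantifiable in that injection (`excluded`), not
zero.

The bookkeeping itself: resuspension volume = dry mass/3.6 mg × 100 µl;
dilution to OD₂₆₀ = 14 multiplies volume by OD/14 (below-target samples
are processed undiluted and flagged — the protocol defines no
concentration step); intracellular volume = cell count × per-cell volume;
effective analyzed volume = intracellular × (2.5 µl × 0.5)/final volume.
For the demo prep (2×10⁷ cells × 2.5 pl, 3.6 mg, OD 14) that is
50 µl × 1.25% = 0.625 µl, so 1 pmol on column ↔ 1.6 µM intracellular.
Reports round to two significant figures, append NAD⁺/NADH (nearest
integer) and NAD⁺/NADP (one decimal), and carry two standing caveats: the
NADP peak may include oxidized NADPH, and Nam is membrane-permeable enough
that losses to supernatants are likely — a footnote, not a numeric
correction. Replicates aggregate as mean ± across-sample SD, the default
convention where the acquisition order is not recorded.

## The simulator: what it emulates, and what it does not

`simulate_injection()` generates every acquired channel of an injection as
Gaussian peaks (σ = 0.05 min) at registry retention times on a sampled
time grid (10 ms), with:

* **Shared suppression** — one factor per metabolite per injection,
  multiplying light and heavy areas identically. The default draw is a
  single factor per injection, uniform on (0.3, 1), modelling global
  matrix load; a per-metabolite named vector can be supplied. A randomly
  *per-metabolite* default would make the surrogate-corrected analytes
  (IMP, NA — which do not co-elute with their surrogates) unrecoverable by
  construction, which is a real limitation of correction factors worth
  studying deliberately, not a sensible default.
* **On-source fragmentation** — a fraction (default 0.10) of a source's
  signal (NR→Nam, NMN→Nam, NAR→NA, NAMN→NA) moves into the target channel
  at the source's retention time; the source retains 1 − fraction. Applied
  channel-wise (light→light, heavy→heavy where the heavy target exists).
* **Isotopologue bleed** — a fraction (default 0.05) of a light source
  channel's *entire content*, fragments included, is copied into the +1/+2
  Da neighbour channel (cytidine→uridine, Nam→NA) at the contributing
  peaks' retention times. Copying the whole content is what produces the
  observed multi-peak NA traces: an NA-channel peak at NR's retention time
  is the isotope peak of on-source-produced Nam.
* **Baseline noise** — mean-zero Gaussian (σ = 50 counts by default), with
  per-channel acquisition windows spanning the peaks ±1.2 min. Windows are
  computed from the panel's crosstalk map whether or not crosstalk is
  enabled, so a given seed yields the identical noise stream with
  crosstalk on or off — which is what makes the crosstalk-immunity
  comparison exact.
* **Replicate structure** — preparation CV (default 5%) perturbing true
  amounts per replicate, and injection-level response drift (default 2%)
  multiplying all areas of an injection jointly (and therefore cancelling
  in isotope ratios; it is visible only to curve-based back-calculation,
  which is why system RSD estimates it).

Default response factors are scaled so each channel's designed S/N = 10
crossing sits at the assay's published per-metabolite LOQ (0.01–3.1 pmol),
reproducing the published sensitivity ordering; the heavy lot defaults to
5 pmol per ¹³C metabolite (IMP: 0, its extract peak being unusable) and
the ¹⁸O spikes to 1.5 µM in the injected solution. The published
cell-line concentrations serve as the demo truth, with below-LOQ entries
entering as zero.

The simulator does *not* model: peak-shape distortion (tailing/fronting in
complex matrices — suppression is purely multiplicative here), retention
drift between runs, chemical degradation (NADH/NADPH instability),
carryover, or detector saturation. Passing tests therefore demonstrate the
*pipeline's* correctness under the assay's stated error model, not
robustness to every failure mode of real chromatography; with real data,
retention drift in particular would first show up as selection failures
inside the ±0.3 min windows.

## Problem sizes and determinism

All simulations in the test suite are sized for interactive runs: one
nine-level standard series per calibration, 20 seeds × 1 injection for the
recovery study, 200 seeds of the area-level fast path (analytic areas plus
area-equivalent noise, validated against full traces at a fixed seed) for
the RSD Monte-Carlo, and 3–5-level dedicated dilution series for LOQ
checks. Every stochastic entry point is a pure function of (configuration,
seed): the standard series, QC sets and experiments use fixed offsets from
the configured seed, and `cmd_simulate` datasets are byte-identical across
reruns.

## Known limitations

* The noise-free end-to-end identity is exact (1e-9) with crosstalk
  disabled; with crosstalk on, differential tails at neighbouring peaks
  move integration bounds by a grid step and the identity holds to ~1e-3 —
  the same order as the crosstalk-immunity bound itself.
* Correction-factor quantification is suppression-sensitive whenever
  target and surrogate are differentially suppressed; this is inherent to
  the surrogate design, and the suppression-invariance guarantees in the
  tests are scoped accordingly (own-channel analytes under per-metabolite
  suppression; all analytes under shared suppression).
* Curve-derived LOQs inherit the series' coarse spacing and extrapolation
  lever; treat the QC table's LOQ column as indicative and measure near
  the crossing when it matters.
* The ¹⁸O spike amount is defined as 1.5 µM in the injected solution; if a
  laboratory instead spikes before 1:1 mixing, assigned amounts shift by
  2× but all downstream quantification is unaffected, because assignment
  and use are consistent.
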