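---
title: "Dication ion-pairing adduct annotation for MSI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dication ion-pairing adduct annotation for MSI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msipair)
library(dplyr)
```

## The problem

Metabolomic mass spectrometry imaging (MSI) suffers from a polarity split:
fatty acids, glycerophosphates (PA) and other acidic lipids ionize as
`[M-H]-` in negative mode, while phosphatidylcholines (PC), di- and
triradylglycerols dominate positive mode. Acquiring both polarities doubles
instrument time and consumes scarce tissue. Doping a dicationic ion-pairing
reagent into the electrospray solvent offers a third route: the doubly
charged reagent pairs with a singly charged anion to form a net **+1**
adduct, so metabolites that would normally require negative mode become
visible in a positive-mode acquisition.

`msipair` implements the complete desk side of this strategy for the
1,5-pentanediyl-bis(1-butylpyrrolidinium) dication, abbreviated
C5(bpyr)2: exact-mass prediction of reagent and adduct ions, tissue-specific
peak finding on imzML pixel grids, mass-shift library annotation with
isotope (spectral-accuracy) validation, diagnostic MS/MS fragment
prediction, and coverage/ion-image reporting — all testable against a
ground-truthed synthetic data generator.

## Mass model

Everything reduces to exact monoisotopic mass algebra over elemental
formulas (C, H, N, O, P, S, F), with explicit electron-mass bookkeeping:

* ion m/z = (composition mass − z·mₑ)/|z|, mₑ = 0.000548579909 Da;
* `[M-H]-` = neutral mass − proton mass (1.00727647 Da);
* the reagent dication C21H44N2²⁺ has m/z
  `r round(ion_mz("C21H44N2", 2), 4)` (z = 2) and pairs with one fluoride to
  give C21H44N2F⁺ at `r round(ion_mz("C21H44N2F", 1), 4)`;
* the **adduct mass shift** is the dication mass
  `r round(dication_shift(), 4)` Da: an observed adduct candidate is
  stripped of this shift and the residual searched against a deprotonated
  metabolite library.

Electron correction matters: both reagent m/z values only reproduce at four
decimals when the two missing electrons are subtracted.

Isotope envelopes are computed by exact per-element convolution aggregated
by integer neutron offset; the m/z offset of each aggregated peak is the
abundance-weighted mean of its isotopologues, which is what a centroiding
high-resolution instrument reports when fine structure is unresolved. The
test suite checks the convolution against a brute-force enumeration of all
isotopologues.

### Carbon counting and spectral accuracy

An annotation gains confidence when the observed isotope distribution
matches theory ("spectral accuracy"). The package uses the conventional
shortcut: carbons ≈ (M+1 relative abundance) / 1.11%. Two constants coexist
deliberately:

* the packaged isotope table carries the tabulated ¹³C abundance (1.07%),
  used for **theoretical envelopes**;
* the carbon-count divisor defaults to 0.0111 (the ~1.11% conventionally
  quoted for this estimate), configurable via `c13_abundance`.

The slightly high divisor partly compensates the ²H/¹⁵N/¹⁷O contributions
to M+1, and in practice recovers the true carbon count within ±1 for every
bundled library formula up to C50 (an acceptance test). Spectral accuracy
passes when the observed M+1 relative abundance deviates from theory by at
most 20% (configurable `max_m1_deviation`); for adducted ions the envelope
is computed for the **full ion composition including the reagent's 21
carbons**, because that is what the detector sees.

## MS/MS fragmentation model

Collisional activation of an adduct consistently sheds the neutral
butylpyrrolidine arm C8H17N (127.1361 Da), giving
`[M-H+C5(bpyr)2-C8H17N]+`; the bare reagent additionally loses a hydrogen,
yielding the ubiquitous reagent fragment modeled as C13H26N⁺
(m/z `r round(ion_mz("C13H26N", 1), 4)`). This composition is the only one
within 2 mDa of the observed fragment that is consistent with
C21H44N2 − C8H17N − H.

For glycerophospholipids the ionic bond between headgroup and reagent
outlives the covalent bonds, producing class-diagnostic
`[headgroup + C5(bpyr)2 − C8H17N]+` fragments. The headgroup anion
compositions are data (an editable TSV), not code:

```{r}
headgroup_rules()
```

Two modeling decisions here were genuinely open:

* **PI headgroup.** The reported PI fragment m/z (456.2353) is consistent
  with a deprotonated inositol monophosphate anion C6H12O9P⁻ and *not* with
  the composition C6H10O8P sometimes quoted alongside it (which computes
  ≈18 Da lower — one water apart). We follow the m/z and model the PI
  headgroup as C6H12O9P⁻.
* **PE secondary fragment.** Loss of C2H5N (aziridine, 43.0422 Da) from the
  PE headgroup fragment collapses it onto the PA-type fragment at 294.18.
  We predict this secondary fragment whenever the rule defines the loss,
  rather than treating it as opportunistic.

PC deliberately has no headgroup rule: choline lipids appear protonated,
not adducted. Fragment matching uses an absolute tolerance (default
0.01 Da) rather than ppm because fragment spectra span a wide m/z range.
Validation tiers: **high** = reagent fragment + ≥1 class-specific fragment;
**medium** = generic neutral-loss evidence only; **low** otherwise. A
predicted-but-absent fragment (e.g. when a weak precursor suppresses its
neutral-loss peak) is reported as missing, never fatal.

## Pixel-grid pipeline

`read_imzml()`/`write_imzml()` implement imzML 1.1 (processed mode written,
continuous readable) with 64-bit float arrays so round trips are lossless.
No installed R package handles the imzML external-binary extension, so the
reader/writer is implemented directly over `xml2` and binary connections;
an independent Python parser cross-checks the writer in the test suite.
The ibd UUID is drawn from R's RNG, making seeded runs byte-identical —
reproducibility is preferred over universal uniqueness here.

**Peak clustering** is greedy and abundance-ranked: peaks are visited by
decreasing intensity; a peak joins the most abundant existing cluster whose
running abundance-weighted mean m/z lies within the tolerance (default
±2.5 ppm, a high-resolving-power Orbitrap mass-accuracy gate), subject to
one-peak-per-pixel per cluster; otherwise it seeds a new cluster.
Preferring the most abundant qualifying cluster over the nearest one keeps
a jittered peak cloud in a single consensus cluster instead of bifurcating
its tails into satellites. The procedure is deterministic and invariant to
pixel order.

**Tissue specificity** follows the on/off-ROI ratio rule: clusters are
built over the union of on- and off-tissue cells, per-region means include
zeros for pixels lacking the peak (penalizing sporadic noise), and a
cluster is retained when mean_on/mean_off ≥ 1.5 (default). When
mean_off = 0 the divisor falls back to the smallest positive off-tissue
mean among all clusters (then machine-tiny), avoiding infinite ratios
without discarding genuinely tissue-specific peaks.

**Isotope flagging.** A cluster one ¹³C spacing (or half of one, for z = 2)
above a stronger cluster is flagged as an envelope member — but only when
the child/parent abundance ratio is ≤ 0.85, the ceiling a genuine M+1/M
ratio can plausibly reach for ≤ C75 ions. Without the cap a genuine species
isobaric with an unrelated envelope member one spacing below would be
swallowed; with it, both the flagging and annotation survive such
collisions (which the synthetic data does produce).

**Annotation.** In adducted-positive polarity each non-isotope cluster is
searched under both `[M+H]+` and `[M-H+reagent]+` at ±2.5 ppm; for the
adduct label the error is evaluated on the stripped (`[M-H]-`) mass scale,
mirroring a deprotonated-library search. When the paired plain-positive
peak list is supplied, any peak also present there (species-level, i.e.
after deisotoping) is excluded from adduct assignment — an adduct must be
*only observed in adducted mode*. Without a paired run the assignment is
still made but the cross-polarity evidence flag stays `NA`. All candidates
within tolerance are returned; isomers are never collapsed. No
multiple-testing control is applied: annotation is candidate listing, not
hypothesis testing.

**Coverage** is reported as
`percent_increase = round(100 · n_adduct_new / n_positive)`; with the
worked-example counts (73 new adducted species over 167 positive-mode
species) this prints 44%. The report states its definition because other
plausible definitions (new/retained, or new/total) give slightly different
percentages.

## The synthetic data generator

`simulate_msi()` emulates the targeted acquisition design: a 20 × 20
on-tissue ROI beside a 10 × 10 off-tissue block at 150 µm pitch (the
bounding 30 × 20 rectangle is fully scanned), three modes (negative,
positive, adducted-positive) from one ground truth, Gaussian m/z jitter of
1 ppm (realistic for 240k resolving power, and comfortably inside the
±2.5 ppm gate), lognormal abundance noise at 20% CV (strictly positive and
heavy-tailed, as MSI intensities are), isotope envelopes to M+2, ten
background ions planted at equal intensity on and off tissue (so the 1.5×
filter removes them by construction), and — in adducted mode — the
reagent's own peaks in every pixel. The default m/z window c(150, 1800) is
the union of the two windows the design acquires per mode (150–600 and
450–1800), so a single simulated run covers the full range; a per-run
override exists. Ground truths draw from the bundled 74-species lipid
library with fatty acids weighted 3:1 among adduct formers, matching the
observed class composition (FAs with some PA/PE/PI); the default design
plants 20 adduct formers (15 also negative-detectable) and 30 positive-mode
species. Imaging tests use two disc ("follicle-like") spatial patterns.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: ionization suppression and matrix
effects, peak-shape/centroiding artifacts, detector saturation, chemical
noise with structured m/z (only uniform background is planted), adduct
formation efficiency (every planted adduct former is assumed to adduct),
and real isomer diversity beyond what the library encodes.

## Numerical choices and degenerate inputs

* Tolerances are config values defaulting to ±2.5 ppm (MMA), 1.5×
  (on/off ratio), 0.01 Da (MS/MS).
* ppm is always evaluated against the theoretical/cluster m/z, the
  conventional direction for mass measurement accuracy.
* An empty MS/MS spectrum validates at tier low with every fragment
  missing; a missing monoisotopic peak yields a "no match" spectral
  accuracy result, not an error.
* A formula subtraction that would drive an element negative, a
  metabolite without an abstractable proton, and an observed m/z at or
  below the mass shift are hard errors.
* Coordinate gaps inside a read imzML grid become empty pixels with a
  warning; empty pixels survive round trips.
* Grid coordinates are 0-based, row-major, (0, 0) top-left; exports are
  fixed-layout TSVs so seeded runs are byte-identical.

## Problem sizes

The shipped tests and examples run the full paired three-mode design at
its native size (600 pixels per mode, ~68k peaks in adducted mode, 50
planted species); end-to-end recovery completes in well under a minute.
Property-style checks use 15–50 random formulas of ≤30 atoms against the
brute-force isotopologue oracle, and 100-replicate noise simulations for
the spectral-accuracy and MS/MS robustness rates.

## Limitations

* Charge states beyond |z| = 2 and multiply-adducted (+2 with two
  reagents) species are out of scope, as are average (chemical) masses and
  resolved fine isotope structure.
* Acyl-chain-level MS/MS prediction is deliberately absent — under this
  fragmentation regime the usual chain-diagnostic product ions are not
  produced.
* The greedy clusterer is a tolerance-bin peak finder; equivalence with
  any particular external MSI peak-finding tool is not claimed.
* The bundled library is a compact offline stand-in for a metabolite
  database; real studies will swap in their own table via
  `metabolite_library(path)`.
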