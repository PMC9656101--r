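---
title: "Annotating aporphine alkaloids from LC-MS/MS spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating aporphine alkaloids from LC-MS/MS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aporphiner)
```

## The annotation problem

Aporphine alkaloids occur in plant extracts as two ionic forms: permanent
quaternary aporphinium cations, detected directly as [M]⁺, and neutral
tertiary or secondary amines, detected protonated as [M+H]⁺. Untargeted
data-dependent acquisition misses the low-abundance members, so the
practical workflow is targeted: build an inclusion list of plausible
precursor masses (a known scaffold plus common substituent modifications),
acquire MS² spectra by parallel reaction monitoring (PRM), and identify
each spectrum from its accurate precursor mass, retention time and
fragmentation pattern. This package implements the desk side of that
workflow end to end.

Three assumptions run through everything:

* all ions are singly charged positive species (negative mode and multiple
  charging are out of scope);
* spectra are centroided peak lists (no profile data, no isotope envelopes);
* fragment interpretation is precursor-relative: a multi-step fragmentation
  path is matched as the cumulative composition of its losses, not by
  fragmentation-tree search.

## Mass arithmetic

All masses are monoisotopic sums over an immutable atomic-mass table
(CODATA 2010 / IUPAC-CIAAW, ≥10 significant figures; ¹²C exact by
definition) with one electron mass (0.00054857990907 u) subtracted per
positive charge. The 0.5 mDa electron correction matters at the sub-ppm
accuracy of Orbitrap data: at *m/z* 342 it is 1.6 ppm, three times the
typical measurement error.

```{r}
monoisotopic_mz("C20H24NO4", charge = 1)     # intact aporphinium cation
monoisotopic_mz(protonate(parse_formula("C18H19NO2")))  # protonated amine
```

Reported masses are rounded half-away-from-zero to 4 decimals
(`round_mz()`); this convention, rather than banker's rounding, reproduces
boundary cases in the curated library such as 282.14886 → 282.1489 and
266.11756 → 266.1176.

## Tolerances: ppm with an absolute floor

Every matching step uses `mass_tolerance(ppm, floor)` with effective window
`max(ppm · m/10⁶, floor)`. Defaults are 5 ppm for precursors and 10 ppm for
fragments — standard Orbitrap processing settings — with a 1.5 mDa floor.
The floor exists because relative tolerances collapse at low mass: the
aporphine family ion C₃H₈N⁺ has exact *m/z* 58.0651 but is routinely
observed at 58.0658–58.0660, a 0.7–0.9 mDa (12–15 ppm) deviation that a
pure 10 ppm window would reject. 1.5 mDa covers the observed deviations of
all the reference fragments while staying far narrower than the 24 mDa gap
between the closest confusable rule pair (CH₃NH₂ at 31.0422 u versus CH₃O·
at 31.0184 u). The floor is configurable and can be set to 0.

## Formula decomposition

`decompose_mz()` enumerates every elemental composition whose ion mass
falls inside the window, under per-element bounds (defaults C≤30, H≤60,
N≤10, O≤20, the usual bounds for this compound class). The search loops
over the non-hydrogen count grid and solves the hydrogen count
arithmetically from the residual mass, so it is complete by construction;
`brute_force_decompose()` — a plain filter over the full count grid — is
kept as an independent oracle, and the test suite checks set equality on
1000 randomized masses under reduced bounds (C≤15, H≤25, N≤3, O≤6, chosen
to keep the full grid at ~11.6k compositions per call). No valence or
ring-double-bond filter is applied: the reference processing pipeline
declares none, and the curated library itself contains both even- and
odd-electron fragment compositions.

## The curated library and its errata

The packaged library (`load_curated_library()`) holds 70 identifications:
36 quaternary, 27 tertiary and 7 secondary compounds, each with retention
time, experimental precursor mass, resolved ion composition and reference
fragment list. Loading self-checks every entry: the recomputed theoretical
mass must agree with the recorded experimental mass within 5 ppm (the suite
measures a maximum of ~2.5 ppm).

Transcription of the source table required corrections, and none of them is
silent — `library_errata()` enumerates all of them. The recurring cases:

* **"+H" notation resolved by mass.** Several [M+H]⁺ entries print an ion
  formula whose hydrogen count already includes the proton (e.g. roemerine,
  neutral C₁₈H₁₇NO₂, printed as "C18H18NO2+H" with mass 280.1332 — the mass
  of C₁₈H₁₈NO₂⁺ itself). The loader stores the resolved ion composition;
  the convention per entry was decided by which interpretation reproduces
  the printed mass.
* **Formula/mass conflicts resolved by mass** (entries 40 and 70), and one
  entry (66) restored from the narrative description after being dropped
  from the printed table.
* **Truncated reference masses.** Nine entries print a theoretical mass
  truncated rather than rounded in the 4th decimal; they are flagged and
  excluded from exact-equality tests (the mass self-check covers them).
* **The not-novel flag.** One constituent of the 70 was known previously;
  no entry carries that compound's historical name, so the flag sits on the
  earliest-eluting oxoaporphine-type entry as a documented curation choice,
  excluded from automated checks.

## Candidate enumeration for PRM target design

`enumerate_candidates()` applies substituent transformations (±CH₂, ±O,
±CH₂O, methylene→ketone, methylenedioxy formation, O-acetylation,
glucosylation, ±H₂) to two scaffolds — magnoflorine as the quaternary [M]⁺
template and roemerine as the tertiary [M+H]⁺ template — up to a stacking
depth (default 2; the tree grows as 12ᵈ and the depth is deliberately a
flag). Branches that would drive an element count negative are silently
skipped; candidates are deduplicated by (ion formula, species), keeping the
shallowest provenance. Enumeration is for prospective screening and
inclusion-list design: it cannot reach all 70 curated identifications
(ring-opened +H₂ products and glucosides fall outside the base substituent
set), which is why the **curated library, not the generated set, is the
annotator's default target list**. `build_inclusion_list()` formats any
candidate table as a PRM target list with the 3.0 *m/z* isolation window
used on the reference instrument.

## Nitrogen-class classification

`classify_spectrum()` computes every precursor-relative loss, matches each
against the rulebase by exact mass (nearest rule within the window), and
records the family diagnostic ion. Assignment uses a specificity
precedence:

> secondary > tertiary > quaternary > N-acyl/oxo

i.e. the loss that demands the most N-bound hydrogen wins. This ordering is
an empirical property of the compound class: the C₂H₇N ring-opening loss
appears in the spectra of quaternary *and* protonated tertiary compounds
(the ionizing proton supplies the extra N–H), whereas CH₃NH₂ and NH₃ losses
occur only in their own classes. The reverse (quaternary-first) ordering
would misclassify the lirinidine reference standard, whose base peak at
*m/z* 237.09 lies exactly one C₂H₇N below the precursor. Cumulative
multi-step rules (e.g. C₂H₇N+CH₃OH+CO) are implication-neutral: they add
evidence but never set the class, which keeps accidental exact matches —
the dehydronuciferine group's *m/z* 217.0650 fragment sits precisely
C₂H₇N+CH₃OH below its precursor — from forcing a class.

Even with the specificity ordering, eight curated-tertiary library
compounds (the bolidine and isothebaine groups and N-methylnantenine) show
C₂H₇N as their *only* class-bearing loss and therefore classify as
quaternary. The fixture manifest enumerates these disagreements
(`class_agrees = FALSE`) rather than hiding them; they reflect a genuine
ambiguity of the loss-based rulebase, not a processing error.

## Annotation and isomer ranking

`annotate_spectrum()` filters peaks below the intensity floor (default
10000, the reference processing setting), retains library entries within
the precursor window, and ranks them by (1) reference fragments matched at
the fragment tolerance, (2) retention-time proximity, (3) absolute
precursor ppm error, (4) name. Positional isomers share both composition
and fragment list, so elution order is the only observable that separates
them; RT proximity is therefore used as a ranking tie-break whenever both
the spectrum and the library entry carry a retention time, independent of
whether the optional RT *filter* (`rt_window`) is enabled. With
library-order tie-breaking instead, a spectrum of the magnoflorine standard
would rank the earlier-eluting "magnoflorine isomer" entry first. ppm
errors are always computed against the unrounded theoretical mass; the
printed 4-decimal values are treated as display artifacts.

## What the fixture generator emulates — and what it does not

`build_fixture_set()` rebuilds one spectrum per library entry: precursor =
recorded experimental mass, RT = recorded elution time, fragments = the
entry's reference list (isomer groups share one printed list, so their
fixtures are identical up to precursor/RT). Intensities are synthetic —
rank-decreasing geometric decay from 10⁶ with ratio 0.7, keeping every peak
above the 10⁴ floor — except the four relative abundances printed for the
lirinidine-type spectra, which are used directly (scaled ×10⁴). Intensities
never influence annotation beyond the floor filter.

`jitter_spectra()` multiplies every m/z by 1 + ε/10⁶, ε ~ N(0, ppm_sd),
reproducibly under a seed; at the 1.5 ppm jitter used in the robustness
tests, at least 95% of fixtures stay annotated at 5 ppm (the worst library
entry already sits 2.5 ppm from its theoretical mass, leaving ~1.6 standard
deviations of headroom). `make_decoy_spectra()` draws precursors uniformly
over the 120–1000 acquisition range, rejecting anything within 10 ppm of a
library ion — sufficient because every library ion lies above *m/z* 266,
where the 1.5 mDa floor is under 6 ppm, so the 5 ppm annotation window
never reaches a decoy.

What the fixtures deliberately do **not** emulate: chromatographic peak
shape, isotope envelopes, co-isolation chimeras, electronic noise floors,
and real intensity structure. A green suite therefore demonstrates that the
arithmetic, the rulebase and the pipeline logic reproduce the reference
annotations from the reference peak lists — not that the pipeline is robust
to every artifact of real acquisitions.

## Numerical and degenerate-input choices

* Hydrogen counts in the decomposer are solved as an integer interval from
  the residual mass, then re-checked against the window to guard
  floating-point edges; the empty composition is excluded.
* Equal-deviation rule matches resolve to the smaller absolute deviation;
  annotation ties after all four ranking keys keep the library order.
* A spectrum whose peaks all fall below the intensity floor still receives
  precursor-only annotations with empty evidence; fragments at or above the
  precursor are skipped with a message; an MGF block without a precursor
  mass is skipped with a warning; a malformed peak line aborts with its
  line number.
* All randomized outputs (jitter, decoys) are pure functions of their
  parameters and seed, and the RNG state of the caller is restored.

## Problem sizes

The default test suite rebuilds all 70 fixtures, runs the full annotation
pipeline on them (plus 100 decoys and one jittered replicate), checks
decomposer/oracle equality on 1000 randomized masses under reduced bounds,
and property-tests the formula arithmetic on dozens of random compositions
— about 15–20 s in total. The acceptance script repeats the mass, pipeline
and library-error computations from scratch in a few seconds.

## Limitations

* Positional isomers are distinguished only by retention time, never by
  structure; the package carries no 2-D structure or SMILES handling.
* The rulebase is aporphine-specific; other alkaloid classes share some of
  the generic losses but not the class logic.
* mzML support is read-only and minimal (centroided MS2 with selected-ion
  m/z); vendor raw formats and MS1/XIC extraction are out of scope.
* No quantification, FDR estimation, or spectral-similarity scoring.
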