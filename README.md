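# aporphiner

Targeted identification of **aporphine alkaloids** from high-resolution
LC-MS/MS data.

Aporphine alkaloids are tetracyclic isoquinoline-derived natural products
found in many medicinal plants. In positive-mode electrospray they appear
either as permanent aporphinium cations ([M]⁺, quaternary nitrogen) or as
protonated amines ([M+H]⁺, tertiary or secondary nitrogen), and they
fragment in a highly regular way: a small amine-containing neutral is
ejected whose composition reports the substitution state of the ring
nitrogen,

| neutral loss | exact mass (u) | nitrogen class |
|---|---|---|
| C₂H₇N  | 45.0578 | quaternary (N,N-dimethyl aporphinium) |
| CH₃NH₂ | 31.0422 | tertiary (N-methyl) |
| NH₃    | 17.0266 | secondary (N-H) |
| NH / C₂H₅NO | 15.0109 / 59.0371 | N-oxo / N-acetyl |

while CH₃OH, CH₃O·, CO, H₂O and CH₃· recur across the family without class
information, and an iminium fragment at *m/z* 58.0651 (C₃H₈N⁺) marks the
family as a whole. `aporphiner` turns these regularities into a desk-scale
annotation pipeline for natural-product and metabolomics researchers:

* **Exact ion-mass arithmetic** — elemental compositions with monoisotopic
  masses pinned to CODATA/IUPAC values and electron-mass correction per
  charge: `parse_formula()`, `monoisotopic_mz()`, `ppm_error()`.
* **Formula decomposition** — complete enumeration of compositions within a
  ppm tolerance (with a 1.5 mDa absolute floor for low masses) under element
  bounds C≤30, H≤60, N≤10, O≤20: `decompose_mz()`, with
  `brute_force_decompose()` as its correctness oracle.
* **Curated library and PRM target design** — a 70-entry curated aporphine
  reference library (`load_curated_library()`, corrections documented in
  `library_errata()`), substituent-transformation candidate enumeration from
  the magnoflorine and roemerine scaffolds (`enumerate_candidates()`), and
  parallel-reaction-monitoring inclusion lists (`build_inclusion_list()`).
* **Nitrogen-class classification** — the neutral-loss/diagnostic-ion
  rulebase above, applied precursor-relative: `classify_spectrum()`.
* **Annotation pipeline** — MGF/mzML in, ranked Table-style report out:
  `read_mgf()`, `read_mzml()`, `annotate_run()`, `write_report()`.
* **Fixture generator** — rebuilds the 70 reference spectra from the curated
  library, plus seeded ppm jitter and decoy spectra for validation:
  `build_fixture_set()`, `jitter_spectra()`, `make_decoy_spectra()`.

## Worked example

Annotate the magnoflorine reference spectrum (precursor *m/z* 342.1703,
eluting at 7.58 min) against the curated library:

```r
library(aporphiner)

lib <- load_curated_library()
sp <- new_spectrum("std_magnoflorine", 342.1703, rt = 7.58,
                   peaks = data.frame(
                     mz = c(58.0658, 237.0905, 265.0852, 282.0877, 297.1123),
                     intensity = c(9e5, 4e5, 1e6, 3e5, 5e5)))

ann <- annotate_spectrum(sp, lib)
ann[1, c("identification", "species", "ion_formula", "theoretical_mz",
         "ppm_error", "assigned_class", "matched_fragments")]
#>  identification species ion_formula theoretical_mz ppm_error assigned_class matched_fragments
#>    magnoflorine    [M]+   C20H24NO4      342.16998      0.92     quaternary                 5
```

The precursor matches the intact C₂₀H₂₄NO₄⁺ cation within 0.92 ppm, all
five reference fragments are found at 10 ppm, and the class evidence shows
why the spectrum is quaternary:

```r
classify_spectrum(sp)
#> <class_evidence> class: quaternary  (family ion: present)
#>      rule_label fragment_mz loss_mass deviation_mda implication
#>  C2H7N+CH3OH+CO     237.090  105.0798      0.821403     generic
#>     C2H7N+CH3OH     265.085   77.0851      1.036023     generic
#>           C2H7N     297.112   45.0580      0.150771  quaternary
```

The fragment at *m/z* 297.1123 sits 45.0580 u below the precursor — the
C₂H₇N ring-opening loss, 0.15 mDa from its exact mass — and the 58.0658
peak is the aporphine family ion. The cumulative two- and three-step losses
(C₂H₇N then CH₃OH, then CO) are matched precursor-relative as supporting
evidence.

A shell front end wrapping the same functions ships in `inst/exec`:

```sh
aporphiner decompose 342.1703 --ppm 5
aporphiner annotate spectra.mgf --ppm-ms1 5 --ppm-ms2 10 --out report.csv
aporphiner enumerate --depth 2 --window 3.0 --out targets.csv
```

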