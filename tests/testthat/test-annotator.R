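# Library matching, isomer ranking, and run-level reporting.

test_that("the magnoflorine standard spectrum gets the right rank-1 annotation", {
  fx <- fixture_set()
  sp <- fx$spectra[[which(fx$manifest$peak_id == 27)]]
  ann <- annotate_spectrum(sp, curated_lib())
  expect_gt(nrow(ann), 0L)
  top <- ann[ann$rank == 1, ]
  expect_equal(top$identification, "magnoflorine")
  expect_equal(top$assigned_class, "quaternary")
  expect_lt(abs(top$ppm_error), 5)
})

test_that("isomers sharing a composition are all retained", {
  # three library entries share the C20H24NO4+ composition
  sp <- new_spectrum("q", 342.1703)
  ann <- annotate_spectrum(sp, curated_lib())
  expect_equal(nrow(ann), 3L)
  expect_equal(sort(unique(ann$ion_formula)), "C20H24NO4")

  # retention-time proximity breaks the tie among identical fragment scores:
  # each fixture spectrum ranks its own library entry first
  fx <- fixture_set()
  for (pid in c(19, 27, 42)) {
    sp <- fx$spectra[[which(fx$manifest$peak_id == pid)]]
    top <- annotate_spectrum(sp, curated_lib())[1, ]
    expect_equal(top$identification,
                 curated_lib()$name[curated_lib()$peak_id == pid])
  }
})

test_that("precursors outside the library yield no annotation", {
  expect_equal(nrow(annotate_spectrum(new_spectrum("x", 500.0), curated_lib())), 0L)
})

test_that("the RT window filters candidates when enabled", {
  sp <- new_spectrum("q", 342.1703, rt = 7.58)
  expect_equal(nrow(annotate_spectrum(sp, curated_lib())), 3L)
  ann <- annotate_spectrum(sp, curated_lib(), rt_window = 0.5)
  expect_equal(ann$identification, "magnoflorine")
})

test_that("the intensity floor drops weak peaks but keeps precursor-only annotation", {
  weak <- new_spectrum("weak", 342.1703,
                       peaks = data.frame(mz = c(58.0658, 297.1123),
                                          intensity = c(500, 900)))
  ann <- annotate_spectrum(weak, curated_lib())
  expect_gt(nrow(ann), 0L)
  expect_true(all(ann$matched_fragments == 0L))
  expect_true(all(ann$assigned_class == "unknown"))
})

test_that("shrinking the precursor tolerance never adds annotations", {
  fx <- fixture_set()
  set.seed(3)
  for (i in sample(seq_along(fx$spectra), 8)) {
    sp <- fx$spectra[[i]]
    tight <- annotate_spectrum(sp, curated_lib(), ms1_tol = mass_tolerance(2, floor = 0))
    loose <- annotate_spectrum(sp, curated_lib(), ms1_tol = mass_tolerance(5, floor = 0))
    key <- function(a) paste(a$identification, a$ion_formula)
    expect_true(all(key(tight) %in% key(loose)))
  }
})

test_that("run-level reports count spectra, order rows, and track bad records", {
  fx <- fixture_set()
  sub <- fx$spectra[1:5]
  rep <- annotate_run(sub, curated_lib())
  expect_s3_class(rep, "annotation_report")
  expect_equal(attr(rep, "n_spectra"), 5L)
  expect_equal(attr(rep, "n_annotated"), 5L)
  expect_true(!is.unsorted(rep$rt_min))

  # duplicates are counted as spectra, not compounds
  dup <- annotate_run(c(sub[1], sub[1]), curated_lib())
  expect_equal(attr(dup, "n_annotated"), 2L)

  # non-spectrum records are skipped and reported
  mixed <- annotate_run(c(sub[1], list("not a spectrum")), curated_lib())
  expect_equal(attr(mixed, "n_annotated"), 1L)
  expect_length(attr(mixed, "warnings"), 1L)
})

test_that("a +20 ppm shifted run annotates nothing at 5 ppm", {
  fx <- fixture_set()
  shifted <- lapply(fx$spectra, function(sp) {
    sp$precursor_mz <- sp$precursor_mz * (1 + 20e-6)
    sp
  })
  rep <- annotate_run(shifted, curated_lib(), ms1_tol = mass_tolerance(5, floor = 0))
  expect_equal(attr(rep, "n_annotated"), 0L)
})
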