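# Curated reference library, substituent enumeration, PRM inclusion lists.

test_that("the curated library loads 70 mass-consistent entries", {
  lib <- curated_lib()
  expect_s3_class(lib, "candidate_library")
  expect_equal(nrow(lib), 70L)
  expect_equal(sort(unique(lib$peak_id)), 1:70)

  # every recorded experimental mass is within the 5 ppm processing tolerance
  # of the mass recomputed from the resolved ion composition
  ppm <- ppm_error(lib$experimental_mz, lib$theoretical_mz)
  expect_true(all(abs(ppm) <= 5))

  # nitrogen-class partition: 36 quaternary, 27 tertiary, 7 secondary
  expect_equal(as.integer(table(lib$nitrogen_class)[c("quaternary", "tertiary", "secondary")]),
               c(36L, 27L, 7L))
  expect_equal(lib$peak_id[lib$n_acyl_or_oxo], c(54L, 63L, 66L, 68L, 69L))
  # a single prior-known constituent
  expect_equal(sum(!lib$novel_flag), 1L)
})

test_that("the magnoflorine entry carries the reference-standard fields", {
  e <- curated_lib()[curated_lib()$peak_id == 27, ]
  expect_equal(e$name, "magnoflorine")
  expect_equal(e$species, "[M]+")
  expect_equal(e$ion_formula, "C20H24NO4")
  expect_equal(e$nitrogen_class, "quaternary")
  expect_equal(e$reference_rt, 7.58)
  expect_identical(round_mz(e$theoretical_mz), 342.1700)
})

test_that("recomputed 4-dp masses equal the recorded values except documented truncations", {
  lib <- curated_lib()
  truncated <- c(5, 9, 10, 28, 47, 60, 62, 63, 70)  # see library_errata()
  chk <- lib[!is.na(lib$theoretical_mz_printed) & !lib$peak_id %in% truncated, ]
  expect_identical(round_mz(chk$theoretical_mz), chk$theoretical_mz_printed)
  # the truncated rows deviate by exactly one unit in the 4th decimal
  tr <- lib[lib$peak_id %in% truncated & !is.na(lib$theoretical_mz_printed), ]
  expect_true(all(round(round_mz(tr$theoretical_mz) - tr$theoretical_mz_printed, 5)
                  == 0.0001))
})

test_that("corrections are documented, never silent", {
  err <- library_errata()
  expect_true(all(c(40, 66, 53, 70) %in% err$peak_id))
  # row 40: the table formula is replaced by the narrative formula
  expect_equal(curated_lib()$ion_formula[curated_lib()$peak_id == 40], "C20H26NO3")
  # row 66 restored from the narrative with no printed theoretical mass
  expect_true(is.na(curated_lib()$theoretical_mz_printed[curated_lib()$peak_id == 66]))
})

test_that("substituent transformations generate the expected derivative masses", {
  cand <- enumerate_candidates(max_depth = 1)
  hydrox <- cand[cand$ion_formula == "C20H24NO5" & cand$scaffold == "magnoflorine", ]
  expect_equal(nrow(hydrox), 1L)
  expect_identical(round_mz(hydrox$theoretical_mz), 358.1649)
  demeth <- cand[cand$ion_formula == "C19H22NO3", ]
  expect_identical(round_mz(demeth$theoretical_mz), 312.1594)
})

test_that("enumeration deduplicates inverse transformation pairs", {
  cand <- enumerate_candidates(max_depth = 2)
  # demethylation + methylation returns to the scaffold: one entry survives
  expect_equal(sum(cand$ion_formula == "C20H24NO4" & cand$species == "[M]+"), 1L)
  expect_false(any(duplicated(cand[, c("ion_formula", "species")])))
  # deterministic mass-ascending order
  expect_true(!is.unsorted(cand$theoretical_mz))
})

test_that("transformation/inverse pairs cancel on the composition level", {
  tt <- transformations()
  inverses <- c(methylation = "demethylation", hydroxylation = "dehydroxylation",
                methoxylation = "demethoxylation", hydrogenation = "dehydrogenation")
  base <- parse_formula("C20H24NO4", charge = 1L)
  for (lab in names(inverses)) {
    d1 <- tt$delta[[which(tt$label == lab)]]
    d2 <- tt$delta[[which(tt$label == inverses[[lab]])]]
    expect_true(all(d1[order(names(d1))] + d2[order(names(d2))] == 0))
    # applying the gain then the loss returns to the scaffold composition
    plus <- chem_formula(d1, charge = 0L)
    out <- formula_subtract(formula_add(base, plus), plus)
    expect_equal(formula_string(out), formula_string(base))
  }
})

test_that("PRM inclusion lists carry one window per target, sorted by m/z", {
  lib <- curated_lib()
  inc <- build_inclusion_list(lib)
  expect_equal(nrow(inc), 70L)
  expect_true(all(inc$window_mz == 3.0))
  expect_true(!is.unsorted(inc$mz))

  # depth-2 enumeration keeps both scaffold target ions
  cand <- enumerate_candidates(max_depth = 2)
  inc2 <- build_inclusion_list(cand)
  expect_true(all(c(342.1700, 280.1332) %in% inc2$mz))

  empty <- build_inclusion_list(lib[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(names(empty), c("mz", "species", "window_mz", "name"))
})
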