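# Neutral-loss rulebase and nitrogen-class assignment.

test_that("class-bearing rule masses equal independently summed atomic masses", {
  rules <- neutral_loss_rules()
  # frozen hand sums of the pinned atomic masses (5 dp)
  expected <- c(C2H7N = 45.05785, CH5N = 31.04220, NH3 = 17.02655,
                NH = 15.01090, C2H5NO = 59.03711, CH4O = 32.02621,
                CH3O = 31.01839, CO = 27.99491, H2O = 18.01056, CH3 = 15.02348)
  got <- setNames(rules$exact_mass, rules$composition)[names(expected)]
  expect_equal(round(unname(got), 5), unname(expected))
  # the family diagnostic ion (electron-corrected)
  expect_equal(round(diagnostic_ions()$mz, 5), 58.06513)
})

test_that("nominal masses anchor to the integer loss values", {
  rules <- neutral_loss_rules()
  nom <- setNames(rules$nominal_mass, rules$composition)
  expect_identical(nom[["C2H7N"]], 45L)
  expect_identical(nom[["NH3"]], 17L)
  expect_identical(nom[["CH5N"]], 31L)
  expect_identical(nom[["CH4O"]], 32L)
  expect_identical(nom[["CO"]], 28L)
  expect_identical(nom[["H2O"]], 18L)
})

test_that("loss matching picks the nearest rule and disambiguates nominal ties", {
  # both CH3NH2 (31.0422) and CH3O (31.0184) share nominal mass 31
  expect_equal(match_loss(31.0422)$composition, "CH5N")
  expect_equal(match_loss(31.0184)$composition, "CH3O")
  expect_equal(match_loss(45.0578)$composition, "C2H7N")
  expect_null(match_loss(10.0))
  expect_error(match_loss(-1), "positive")
})

test_that("precursor-relative losses are extracted and out-of-range peaks skipped", {
  sp <- new_spectrum("magno", 342.1703,
                     peaks = data.frame(mz = c(297.1123, 58.0658),
                                        intensity = c(1e6, 9e5)))
  nl <- extract_neutral_losses(sp)
  expect_equal(round(nl$loss_mass[nl$fragment_mz == 297.1123], 4), 45.0580)

  sp2 <- new_spectrum("liri", 282.1495,
                      peaks = data.frame(mz = 251.1067, intensity = 1e5))
  expect_equal(round(extract_neutral_losses(sp2)$loss_mass, 4), 31.0428)

  empty <- new_spectrum("none", 300)
  expect_equal(nrow(extract_neutral_losses(empty)), 0L)

  high <- new_spectrum("hi", 300, peaks = data.frame(mz = c(100, 301), intensity = c(1, 1)))
  expect_message(nl3 <- extract_neutral_losses(high), "skipped")
  expect_equal(nrow(nl3), 1L)
})

test_that("the four reference standards classify to their nitrogen classes", {
  fx <- fixture_set()
  cls <- setNames(fx$manifest$assigned_class, fx$manifest$peak_id)
  expect_equal(cls[["27"]], "quaternary")   # magnoflorine
  expect_equal(cls[["45"]], "tertiary")     # lirinidine
  expect_equal(cls[["53"]], "tertiary")     # roemerine
  expect_equal(cls[["50"]], "secondary")    # N-nornuciferine
  # the quaternary standard also shows the family diagnostic ion
  expect_true(fx$manifest$family_ion_present[fx$manifest$peak_id == 27])
})

test_that("generic losses never assign a class", {
  sp <- new_spectrum("co_only", 300,
                     peaks = data.frame(mz = 300 - 27.9949, intensity = 1e5))
  ev <- classify_spectrum(sp)
  expect_equal(ev$assigned_class, "unknown")
  expect_equal(ev$matched_rules$rule_label, "CO")
})

test_that("unmatched noise peaks never change the assigned class", {
  fx <- fixture_set()
  set.seed(23)
  for (i in sample(seq_along(fx$spectra), 10)) {
    sp <- fx$spectra[[i]]
    noise <- data.frame(mz = runif(5, 60, sp$precursor_mz - 0.4),
                        intensity = 5e4)
    # nudge any noise peak that lands on a rule loss or the family ion
    loss <- sp$precursor_mz - noise$mz
    bad <- vapply(loss, function(l) !is.null(match_loss(l)), logical(1)) |
      abs(noise$mz - 58.065) < 0.01
    noise$mz[bad] <- noise$mz[bad] + 0.05
    noisy <- new_spectrum(sp$spectrum_id, sp$precursor_mz, sp$rt,
                          rbind(sp$peaks, noise))
    expect_equal(classify_spectrum(noisy)$assigned_class,
                 classify_spectrum(sp)$assigned_class)
  }
})

test_that("the N-acetyl compound shows a fragment supporting the C2H5NO loss", {
  fx <- fixture_set()
  sp <- fx$spectra[[which(fx$manifest$peak_id == 66)]]
  ev <- classify_spectrum(sp)
  expect_true("C2H5NO" %in% ev$matched_rules$rule_label)
  expect_equal(ev$assigned_class, "N_acyl_or_oxo")
})
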