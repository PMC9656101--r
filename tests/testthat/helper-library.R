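# Load-once caches for the curated library and fixture set; both are
# deterministic, so sharing them across tests is safe and keeps the suite fast.
.cache <- new.env(parent = emptyenv())

curated_lib <- function() {
  if (is.null(.cache$lib)) .cache$lib <- load_curated_library()
  .cache$lib
}

fixture_set <- function() {
  if (is.null(.cache$fx)) .cache$fx <- build_fixture_set(curated_lib())
  .cache$fx
}

# random valid compositions for property tests
random_formula <- function() {
  els <- sample(c("C", "H", "N", "O"), sample(1:4, 1))
  counts <- setNames(sample(1:30, length(els), replace = TRUE), els)
  chem_formula(counts, charge = sample(0:1, 1))
}
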