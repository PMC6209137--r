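# shared fixture builders and small conveniences for the test suite

branchFix <- function(...) makeFixture("branch", ...)
chainFix <- function(...) makeFixture("chain", ...)
cycleFix <- function(...) makeFixture("cycle", ...)

# pure tracer mixture helper
pureMix <- function(bundle, name) {
  fr <- setNames(1, name)
  tracerMixture(bundle$species, fr)
}

# design with a single evaluated group
singleGroupDesign <- function(bundle, group, nRep = 1L,
                              fractions = c(U = 0, `1C` = 1, `2C` = 0, UC = 0)) {
  gn <- vapply(bundle$setup@groups, function(g) g@name, "")
  reps <- setNames(rep(0L, length(gn)), gn)
  reps[group] <- as.integer(nRep)
  list(list(fractions = fractions[bundle$species$name], nRep = reps))
}

# labeling state at given free fluxes and mixture
labelAt <- function(bundle, freeValues, mixture) {
  solveLabeling(bundle$context@system,
                expandFluxState(bundle$param, freeValues, strict = FALSE),
                mixture)
}

expect_simplex <- function(x, tol = 1e-9) {
  expect_true(all(x >= -tol & x <= 1 + tol))
  expect_equal(sum(x), 1, tolerance = tol)
}
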