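test_that("cascade enumerates cumomer unknowns per weight level", {
  b <- branchFix()
  sys <- b$context@system
  expect_equal(sys@maxWeight, 2)
  expect_equal(sum(sys@unknowns$weight == 1), 4)  # two 2-carbon pools
  expect_equal(sum(sys@unknowns$weight == 2), 2)
  ch <- chainFix()
  expect_equal(ch$context@system@maxWeight, 2)
  expect_false("Sin" %in% ch$context@system@unknowns$pool)  # inputs excluded
})

test_that("carbon-free cofactors contribute no cumomer unknowns", {
  net <- loadNetwork(text = c(
    "metabolites:", "  S 2 input", "  A 2 balanced", "  ATP 0 balanced",
    "  X 2 output",
    "reactions:", "  in: S#ab + ATP -> A#ab", "  rec: A#ab -> A#ab + ATP",
    "  out: A#ab -> X#ab"))
  sys <- buildCumomerCascade(net)
  expect_false("ATP" %in% sys@unknowns$pool)
  expect_equal(nrow(sys@unknowns), 3)
})

test_that("a carbon-carrying metabolite without atom map is rejected", {
  net <- loadNetwork(text = c(
    "metabolites:", "  S 2 input", "  A 2 balanced", "  X 2 output",
    "reactions:", "  in: S -> A", "  out: A#ab -> X#ab"))
  expect_error(buildCumomerCascade(net), "lacks an atom map")
})

test_that("label is conserved along a linear chain", {
  ch <- chainFix()
  st <- labelAt(ch, c(out = 1), pureMix(ch, "1C"))
  for (pool in c("A", "B", "C")) {
    frac <- isotopomerFractions(st)[[pool]]
    expect_equal(frac, c(0, 1, 0, 0), tolerance = 1e-12)  # pure [1-13C]
  }
})

test_that("branch positional enrichment equals the flux split ratio", {
  b <- branchFix()
  st <- labelAt(b, c(r1 = 0.7), pureMix(b, "1C"))
  frac <- isotopomerFractions(st)[["P"]]
  expect_equal(frac[[2]], 0.7, tolerance = 1e-12)  # labeled at C1
  expect_equal(frac[[3]], 0.3, tolerance = 1e-12)  # labeled at C2
})

test_that("a 50/50 uniformly labeled mixture gives 50% enrichment everywhere", {
  ch <- chainFix()
  mix <- tracerMixture(ch$species, c(UC = 0.5, U = 0.5))
  st <- labelAt(ch, c(out = 1), mix)
  for (pool in c("A", "B", "C")) {
    cum <- cumomerValues(st)[[pool]]
    # weight-1 cumomers are the positional enrichments
    expect_equal(cum[[2]], 0.5, tolerance = 1e-12)
    expect_equal(cum[[3]], 0.5, tolerance = 1e-12)
  }
})

test_that("cumomer solutions equal the brute-force isotopomer oracle", {
  cases <- list(
    list(fix = chainFix(), free = c(out = 1), mix = c(`1C` = 0.6, UC = 0.4)),
    list(fix = branchFix(), free = c(r1 = 0.7),
         mix = c(`1C` = 0.5, `2C` = 0.2, U = 0.3)),
    list(fix = cycleFix(), free = c(r1 = 0.6, r2.xch = 0.5),
         mix = c(`1C` = 0.5, U = 0.5)),
    list(fix = cycleFix(), free = c(r1 = 0.3, r2.xch = 2),
         mix = c(`1C` = 0.25, `2C` = 0.25, UC = 0.5)))
  for (cs in cases) {
    mix <- tracerMixture(cs$fix$species, cs$mix)
    st <- labelAt(cs$fix, cs$free, mix)
    flux <- expandFluxState(cs$fix$param, cs$free, strict = FALSE)
    oracle <- bruteForceLabeling(cs$fix$network, flux, cs$fix$species, cs$mix)
    for (pool in names(oracle))
      expect_equal(isotopomerFractions(st)[[pool]], oracle[[pool]],
                   tolerance = 1e-8)
  }
})

test_that("mixture labeling is the fraction-weighted labeling of pure runs", {
  b <- cycleFix()
  free <- c(r1 = 0.6, r2.xch = 0.8)
  mix <- tracerMixture(b$species, c(`1C` = 0.3, `2C` = 0.2, UC = 0.5))
  st <- labelAt(b, free, mix)
  pure <- lapply(c("1C", "2C", "UC"), function(nm)
    labelAt(b, free, pureMix(b, nm)))
  for (pool in b$context@system@pools) {
    blend <- 0.3 * isotopomerFractions(pure[[1]])[[pool]] +
      0.2 * isotopomerFractions(pure[[2]])[[pool]] +
      0.5 * isotopomerFractions(pure[[3]])[[pool]]
    expect_equal(isotopomerFractions(st)[[pool]], blend, tolerance = 1e-10)
  }
})

test_that("isotopomer fractions are proper distributions", {
  set.seed(7)
  for (fix in list(chainFix(), branchFix(), cycleFix())) {
    for (i in 1:20) {
      fr <- runif(4); fr <- fr / sum(fr)
      mix <- tracerMixture(fix$species, setNames(fr, fix$species$name))
      free <- fix$refFree * runif(length(fix$refFree), 0.5, 1.5)
      st <- labelAt(fix, free, mix)
      for (pool in st@pools) {
        x <- isotopomerFractions(st)[[pool]]
        expect_true(all(x >= -1e-9 & x <= 1 + 1e-9))
        expect_equal(sum(x), 1, tolerance = 1e-9)
        expect_equal(cumomerValues(st)[[pool]][[1]], 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("a pool without outflux raises a degeneracy error naming it", {
  ch <- chainFix()
  expect_error(labelAt(ch, c(out = 0), pureMix(ch, "1C")), "no outflux: A")
})

test_that("the branch Jacobian is the exact split-ratio sensitivity", {
  b <- branchFix()
  J <- labelingJacobian(b$context@system, b$param, c(r1 = 0.7),
                        pureMix(b, "1C"), b$setup)
  expect_equal(J["P_nmr13c:C1", "r1"], 1, tolerance = 1e-7)
  expect_equal(unname(J[grep("P_ms", rownames(J)), "r1"]), rep(0, 3),
               tolerance = 1e-7)
})

test_that("chain labeling is insensitive to the flux value", {
  ch <- chainFix()
  for (v in c(0.5, 1, 2)) {
    J <- labelingJacobian(ch$context@system, ch$param, c(out = v),
                          pureMix(ch, "1C"), ch$setup)
    expect_lt(max(abs(J)), 1e-8)
  }
})

test_that("finite differences are step-converged (Richardson check)", {
  cyc <- cycleFix()
  mix <- tracerMixture(cyc$species, c(`1C` = 0.5, U = 0.5))
  J1 <- labelingJacobian(cyc$context@system, cyc$param, cyc$refFree, mix,
                         cyc$setup, h = 1e-5)
  J2 <- labelingJacobian(cyc$context@system, cyc$param, cyc$refFree, mix,
                         cyc$setup, h = 5e-6)
  expect_lt(max(abs(J1 - J2)) / max(abs(J1)), 1e-6)
})

test_that("a design point at the exchange boundary falls back to one-sided differences", {
  cyc <- cycleFix()
  mix <- tracerMixture(cyc$species, c(`1C` = 1))
  expect_warning(
    labelingJacobian(cyc$context@system, cyc$param, c(r1 = 0.6, r2.xch = 0),
                     mix, cyc$setup),
    "one-sided")
})

test_that("labeling states export as tidy tables", {
  b <- branchFix()
  tab <- isotopomerTable(labelAt(b, c(r1 = 0.7), pureMix(b, "1C")), "P")
  expect_equal(tab$isotopomer, c("00", "10", "01", "11"))
  expect_equal(tab$fraction[2], 0.7, tolerance = 1e-12)
})
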