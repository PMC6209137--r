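test_that("repair normalizes mixtures and rounds replicates", {
  b <- branchFix()
  bb <- designBounds(b$context)
  expect_equal(length(bb$lower), 4 + 2)     # 4 species + 2 groups, one CLE
  raw <- c(0.2, 0.2, 0.6, 0, 4.6, 1.2)
  d <- repairAndDecode(raw, b$context)[[1]]
  expect_equal(unname(d$fractions), c(0.2, 0.2, 0.6, 0))  # already on simplex
  expect_equal(unname(d$nRep), c(5L, 1L))                 # 4.6 -> 5
  d2 <- repairAndDecode(c(2, 1, 1, 0, 1, 1), b$context)[[1]]
  expect_equal(unname(d2$fractions), c(0.5, 0.25, 0.25, 0))
  # all-zero mixture block repaired to the uniform mixture
  d3 <- repairAndDecode(c(0, 0, 0, 0, 1, 1), b$context)[[1]]
  expect_equal(unname(d3$fractions), rep(0.25, 4))
  # out-of-box raw values are clipped
  d4 <- repairAndDecode(c(-1, 2, 0, 0, 99, -3), b$context)[[1]]
  expect_simplex(d4$fractions)
  expect_true(all(d4$nRep >= 0 & d4$nRep <= b$context@setup@nRepMax))
  expect_equal(encodeDesign(list(d), b$context)[1:4], unname(d$fractions))
})

test_that("the branch NMR design chains to its closed-form objective vector", {
  b <- branchFix()
  design <- singleGroupDesign(b, "P_nmr13c")
  r <- evaluateDesign(design, b$context)
  expect_equal(r$p, 1L)
  expect_equal(r$criteria$D, 0.01, tolerance = 1e-6)   # flux sd = sigma
  cp <- b$costParams
  handCost <- 5 * 150 + cp$Cexp + cp$tWorkExp * cp$Cwork +   # experimental
    cp$nSamples * cp$Csample + 1 * 1 * cp$tWorkAna * cp$Cwork  # analytical
  expect_equal(r$cost$total, handCost)
  expect_equal(unname(r$objectives),
               c(1, 1 / r$criteria$D, -handCost), tolerance = 1e-6)
})

test_that("a flux-blind MS-only design scores zero degrees of freedom", {
  b <- branchFix()
  r <- evaluateDesign(singleGroupDesign(b, "P_ms"), b$context)
  expect_equal(r$p, 0L)
  expect_equal(unname(r$objectives[["DoF"]]), 0)
  expect_equal(r$objectives[["D"]], 0)
})

test_that("a design without any evaluated group keeps its cost floor", {
  b <- branchFix()
  gn <- vapply(b$setup@groups, function(g) g@name, "")
  design <- list(list(fractions = c(U = 1, `1C` = 0, `2C` = 0, UC = 0),
                      nRep = setNames(rep(0L, length(gn)), gn)))
  r <- evaluateDesign(design, b$context)
  expect_equal(r$p, 0L)
  cp <- b$costParams
  expect_equal(r$cost$total,
               5 * 0.30 + cp$Cexp + cp$tWorkExp * cp$Cwork +
                 cp$nSamples * cp$Csample)
})

test_that("design evaluation is deterministic", {
  b <- branchFix()
  design <- singleGroupDesign(b, "P_nmr13c",
                              fractions = c(U = 0.3, `1C` = 0.5, `2C` = 0,
                                            UC = 0.2))
  r1 <- evaluateDesign(design, b$context)
  r2 <- evaluateDesign(design, b$context)
  expect_identical(r1$objectives, r2$objectives)
})

test_that("permuting the species order leaves objectives unchanged", {
  b <- branchFix()
  perm <- c(3, 1, 4, 2)
  ctxPerm <- designContext(b$network, b$refFree, b$species[perm, ],
                           b$setup, b$costParams, prefer = "r1")
  fr <- c(U = 0.3, `1C` = 0.5, `2C` = 0, UC = 0.2)
  gn <- vapply(b$setup@groups, function(g) g@name, "")
  reps <- setNames(c(1L, 0L), gn)
  d1 <- list(list(fractions = fr[b$species$name], nRep = reps))
  d2 <- list(list(fractions = fr[b$species$name[perm]], nRep = reps))
  r1 <- evaluateDesign(d1, b$context)
  r2 <- evaluateDesign(d2, ctxPerm)
  expect_equal(r1$objectives, r2$objectives, tolerance = 1e-12)
})

test_that("parallel labeling experiments concatenate their measurement blocks", {
  b <- branchFix(objectives = "5D")
  ctx2 <- designContext(b$network, b$refFree, b$species, b$setup,
                        b$costParams, nCle = 2L, objectives = "5D",
                        prefer = "r1")
  one <- singleGroupDesign(b, "P_nmr13c")
  both <- rep(one, 2)
  r1 <- evaluateDesign(one, b$context)
  r2 <- evaluateDesign(both, ctx2)
  expect_equal(r2$p, 1L)
  # two identical CLEs halve the variance and double the cost
  expect_equal(r2$criteria$A, r1$criteria$A / 2, tolerance = 1e-6)
  expect_equal(-r2$objectives[["negCost"]], -2 * r1$objectives[["negCost"]])
  expect_equal(names(r2$objectives), c("DoF", "D", "A", "E", "negCost"))
})
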