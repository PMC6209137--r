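test_that("mass isotopomer distributions on the branch are flux-blind", {
  b <- branchFix()
  for (r1 in c(0.2, 0.7)) {
    st <- labelAt(b, c(r1 = r1), pureMix(b, "1C"))
    pred <- predictMeasurements(st, b$setup)
    mid <- pred$value[pred$group == "P_ms"]
    expect_equal(mid, c(0, 1, 0), tolerance = 1e-10)
  }
})

test_that("positional groups read the split ratio directly", {
  b <- branchFix()
  st <- labelAt(b, c(r1 = 0.7), pureMix(b, "1C"))
  pred <- predictMeasurements(st, b$setup)
  expect_equal(pred$value[pred$group == "P_nmr13c" & pred$label == "C1"],
               0.7, tolerance = 1e-10)
})

test_that("groups with the normalize flag are scaled to sum 1", {
  b <- branchFix()
  st <- labelAt(b, c(r1 = 0.7), pureMix(b, "1C"))
  g <- measurementGroup("ms", "two", "P",
                        rbind(a = rep(0.05, 4), b = rep(0.05, 4)),
                        normalize = TRUE)
  setup <- measurementSetup(list(g), errorModels = b$setup@errorModels)
  pred <- predictMeasurements(st, setup)
  expect_equal(pred$value, c(0.5, 0.5))    # raw (0.2, 0.2) normalized
})

test_that("a normalized group with zero mass is a degenerate-group error", {
  b <- branchFix()
  st <- labelAt(b, c(r1 = 0.7), pureMix(b, "1C"))
  rows <- matrix(c(0, 0, 0, 1), 1)         # selects the absent M+2 species
  g <- measurementGroup("ms", "dead", "P", rows, normalize = TRUE)
  setup <- measurementSetup(list(g), errorModels = b$setup@errorModels)
  expect_error(predictMeasurements(st, setup), "zero total mass")
})

test_that("groups with zero replicates are excluded from predictions", {
  b <- branchFix()
  st <- labelAt(b, c(r1 = 0.7), pureMix(b, "1C"))
  setup <- setReplicates(b$setup, c(P_ms = 0L))
  pred <- predictMeasurements(st, setup)
  expect_false("P_ms" %in% pred$group)
})

test_that("the linear error model reproduces its closed forms", {
  vals <- data.frame(group = "g", device = "d", label = c("a", "b"),
                     value = c(0.1, 0.9), nRep = 1L)
  # constant-precision model: 0.4 mol% regardless of the measured value
  m <- errorModel("d", b1 = 0, b2 = 0.004, repScaling = function(n) rep(1, length(n)))
  out <- evaluateErrorModel(vals, m)
  expect_equal(out$sd, c(0.004, 0.004))
  expect_equal(out$var, out$sd^2)
  # proportional model at eta = 0.5
  m2 <- errorModel("d", b1 = 0.004, b2 = 0.002, repScaling = function(n) rep(1, length(n)))
  vals$value <- 0.5
  expect_equal(evaluateErrorModel(vals, m2)$sd, rep(0.004, 2))
})

test_that("replicate scaling is capped, non-increasing and tends to 1", {
  m <- errorModel("d", b1 = 0, b2 = 1)
  a <- m@repScaling(1:1000)
  expect_equal(a[1], 2)                       # single-replicate cap
  expect_true(all(diff(a) <= 0))
  expect_true(all(a >= 1))
  expect_lt(abs(a[1000] - 1), 1e-3)
  # sigma therefore strictly positive and non-increasing in nRep
  vals <- data.frame(group = "g", device = "d", label = "a", value = 0.5,
                     nRep = 1L)
  sds <- vapply(1:10, function(n) {
    vals$nRep <- n
    evaluateErrorModel(vals, m)$sd
  }, 0)
  expect_true(all(sds > 0))
  expect_true(all(diff(sds) <= 0))
})

test_that("platform templates enumerate the expected observation rows", {
  ms <- makeDeviceTemplates("X", 3, type = "MS")
  expect_equal(nrow(ms@rows), 4)              # M+0 .. M+3
  expect_true(ms@normalize)
  msms <- makeDeviceTemplates("X", 3, type = "MSMS", fragment = 2:3)
  expect_equal(nrow(msms@rows), 6)            # feasible (precursor, fragment) pairs
  # each isotopomer contributes to exactly one joint mass pair
  expect_equal(colSums(msms@rows), rep(1, 8))
  nmr <- makeDeviceTemplates("X", 3, type = "NMR13C")
  expect_equal(rownames(nmr@rows), c("C1", "C2", "C3"))
  expect_false(nmr@normalize)
  h <- makeDeviceTemplates("X", 3, type = "NMR1H", positions = 2)
  expect_equal(nrow(h@rows), 1)
  irms <- makeDeviceTemplates("X", 3, type = "IRMS")
  expect_equal(nrow(irms@rows), 1)
  expect_equal(unname(irms@rows[1, 8]), 1)            # fully labeled isotopomer
  expect_error(makeDeviceTemplates("X", 3, type = "MSMS", fragment = c(1, 3)),
               "contiguous")
})

test_that("tandem-MS joint rows carry positional information", {
  b <- branchFix()
  msms <- makeDeviceTemplates("P", 2, device = "ms", type = "MSMS",
                              fragment = 2)
  setup <- measurementSetup(list(msms), errorModels = b$setup@errorModels)
  st <- labelAt(b, c(r1 = 0.7), pureMix(b, "1C"))
  pred <- predictMeasurements(st, setup)
  # the (M+1, fragment m+1) row is exactly the C2 path = r2
  expect_equal(pred$value[pred$label == "M+1/m+1"], 0.3, tolerance = 1e-10)
})

test_that("measurement configurations round-trip through YAML", {
  b <- branchFix()
  dir <- withr::local_tempdir()
  files <- writeFixtureFiles(b, dir)
  setup <- readMeasurementConfig(files[["devices"]], b$network)
  expect_equal(vapply(setup@groups, function(g) g@name, ""),
               vapply(b$setup@groups, function(g) g@name, ""))
  expect_equal(setup@nRep, b$setup@nRep)
  m <- setup@errorModels[["nmr"]]
  expect_equal(m@b2, 0.01)
  expect_equal(m@repScaling(1:3), rep(1, 3))  # constant scaling preserved
})
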