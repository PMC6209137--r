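test_that("dominance follows the componentwise definition", {
  expect_true(dominates(c(2, 3), c(1, 3)))
  expect_false(dominates(c(2, 1), c(1, 2)))
  expect_false(dominates(c(1, 2), c(2, 1)))   # incomparable both ways
  expect_false(dominates(c(1, 1), c(1, 1)))   # needs a strict improvement
  expect_error(dominates(c(a = 1, b = 2), c(b = 2, a = 1)), "objective sets")
  expect_error(dominates(1, c(1, 2)), "different lengths")
})

test_that("pareto filtering keeps exactly the non-dominated points", {
  pts <- rbind(c(1, 1), c(2, 3), c(3, 2), c(2, 2))
  expect_equal(paretoFilter(pts), c(2, 3))
  same <- rbind(c(1, 2), c(1, 2), c(1, 2))
  expect_equal(paretoFilter(same), 1:3)       # equal points all retained
  chain <- cbind(1:5, 1:5)
  expect_equal(paretoFilter(chain), 5L)       # totally ordered: one maximum
  expect_equal(paretoFilter(matrix(numeric(), 0, 2)), integer())
})

test_that("crowding distance marks the boundary points untruncatable", {
  pts <- cbind(c(0, 0.5, 1), c(1, 0.5, 0))
  cd <- crowdingDistance(pts)
  expect_equal(cd[c(1, 3)], c(Inf, Inf))
  expect_true(is.finite(cd[2]))
})

test_that("2D hypervolume matches a hand-computed staircase", {
  pts <- rbind(c(1, 2), c(2, 1))
  expect_equal(hypervolume2d(pts, c(0, 0)), 3)  # 2x1 + 1x1
  expect_equal(hypervolume2d(rbind(c(1, 1)), c(1, 1)), 0)
})

test_that("SMPSO recovers the analytic bi-objective front", {
  # maximize (x, 1 - x^2) on [0, 1]: every feasible point lies on the front
  fn <- function(x) list(objectives = c(f1 = x[1], f2 = 1 - x[1]^2))
  params <- swarmParams(swarmSize = 40, maxIter = 60, archiveCapacity = 50,
                        seed = 42)
  arch <- smpso(fn, lower = 0, upper = 1, params)
  obj <- archiveObjectives(arch)
  expect_gt(nrow(obj), 10)
  # archive points lie within 1e-3 of the closed-form front f2 = 1 - f1^2
  expect_lt(max(abs(obj[, "f2"] - (1 - obj[, "f1"]^2))), 1e-3)
  # mutual non-domination
  expect_equal(paretoFilter(obj), seq_len(nrow(obj)))
  # determinism under the seed
  arch2 <- smpso(fn, lower = 0, upper = 1, params)
  expect_identical(archiveObjectives(arch2), obj)
  # hypervolume is non-decreasing over iterations (up to the marginal area
  # a bounded archive sheds when crowding truncation drops an interior point)
  hv <- vapply(arch@meta$log, `[[`, 0, "hypervolume")
  expect_true(all(diff(hv) >= -1e-5 * max(hv)))
  expect_gte(hv[length(hv)], hv[1])
})

test_that("archive truncation respects its capacity on a dense front", {
  fn <- function(x) list(objectives = c(f1 = x[1], f2 = 1 - x[1]))
  arch <- smpso(fn, 0, 1, swarmParams(swarmSize = 30, maxIter = 30,
                                      archiveCapacity = 20, seed = 7))
  expect_equal(length(arch@entries), 20)
  expect_error(smpso(fn, 0, 1, swarmParams(swarmSize = 0)), "swarmSize")
})

test_that("the exhaustive grid oracle equals a brute-force filter", {
  b <- branchFix()
  species2 <- b$species[b$species$name %in% c("1C", "U"), ]
  setup1 <- measurementSetup(list(b$setup@groups[[1]]),
                             errorModels = b$setup@errorModels)
  ctx <- designContext(b$network, b$refFree, species2, setup1,
                       b$costParams, prefer = "r1")
  grid <- seq(0, 1, by = 0.1)
  ex <- exhaustiveFront(ctx, fractionGrid = grid, repLevels = c(1L, 3L))
  # independent enumeration of the same raw grid + brute-force filter
  evals <- list()
  for (f1 in grid) for (f2 in grid) for (rp in c(1L, 3L)) {
    d <- repairAndDecode(c(f1, f2, rp), ctx, grid, c(1L, 3L))
    evals[[length(evals) + 1L]] <- evaluateDesign(d, ctx)
  }
  M <- do.call(rbind, lapply(evals, `[[`, "objectives"))
  keyset <- function(m) unique(sort(apply(round(m, 8), 1, paste,
                                          collapse = ",")))
  expect_equal(keyset(ex$objectives), keyset(M[paretoFilter(M), ]))
  expect_error(exhaustiveFront(ctx, seq(0, 1, 1e-4), 0:9), "guard")
})

test_that("the swarm recovers at least 90% of the exhaustive grid front", {
  b <- branchFix()
  species2 <- b$species[b$species$name %in% c("1C", "U"), ]
  setup1 <- measurementSetup(list(b$setup@groups[[1]]),
                             errorModels = b$setup@errorModels)
  ctx <- designContext(b$network, b$refFree, species2, setup1,
                       b$costParams, prefer = "r1")
  grid <- seq(0, 1, by = 0.25)
  reps <- c(1L, 3L)
  ex <- exhaustiveFront(ctx, fractionGrid = grid, repLevels = reps)
  arch <- optimizeDesign(ctx, swarmParams(swarmSize = 30, maxIter = 40,
                                          archiveCapacity = 60, seed = 42),
                         fractionGrid = grid, repLevels = reps)
  obj <- archiveObjectives(arch)
  key <- function(m) apply(round(m, 9), 1, paste, collapse = ",")
  exKeys <- unique(key(ex$objectives))
  gotKeys <- unique(key(obj))
  recovered <- mean(exKeys %in% gotKeys)
  expect_gte(recovered, 0.9)
  # every archive point is weakly dominated by or equal to a front point
  for (i in seq_len(nrow(obj))) {
    onFront <- any(vapply(seq_len(nrow(ex$objectives)), function(j)
      all(ex$objectives[j, ] >= obj[i, ] - 1e-9), TRUE))
    expect_true(onFront)
  }
})

test_that("archives round-trip through their tabular file format", {
  b <- branchFix()
  arch <- optimizeDesign(b$context, swarmParams(swarmSize = 10, maxIter = 5,
                                                archiveCapacity = 20,
                                                seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  writeArchive(arch, path)
  back <- readArchive(path)
  expect_equal(archiveObjectives(back), archiveObjectives(arch),
               tolerance = 1e-10)
  expect_equal(back@entries[[1]]$design[[1]]$fractions,
               arch@entries[[1]]$design[[1]]$fractions, tolerance = 1e-10)
  expect_equal(vapply(back@entries, `[[`, 0L, "p"),
               vapply(arch@entries, `[[`, 0L, "p"))
})
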