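# build a small synthetic archive without running the optimizer
fakeEntry <- function(fractions, D, cost, p = 1L, nRep = c(g = 1L)) {
  list(design = list(list(fractions = fractions,
                          nRep = setNames(as.integer(nRep), names(nRep)))),
       objectives = c(DoF = as.numeric(p), D = D, negCost = -cost),
       p = as.integer(p), frozen = character(),
       cost = list(experimental = cost * 0.8, analytical = cost * 0.2,
                   total = cost))
}

fakeArchive <- function(entries) {
  new("ParetoArchive", entries = entries, capacity = length(entries),
      meta = list(seed = 1))
}

twoGroupArchive <- function() {
  a <- c(A = 0.9, B = 0.1, C = 0)
  b <- c(A = 0.1, B = 0.8, C = 0.1)
  fakeArchive(list(
    fakeEntry(a, 10, 100), fakeEntry(a + c(0.02, -0.02, 0), 11, 110),
    fakeEntry(b, 30, 300), fakeEntry(b + c(-0.02, 0.02, 0), 31, 310)))
}

test_that("well-separated compositions cluster into their group means", {
  cl <- clusterMixtures(twoGroupArchive(), k = 2)
  expect_equal(sort(unique(cl$assignments)), 1:2)
  expect_equal(cl$assignments[1], cl$assignments[2])
  expect_equal(cl$assignments[3], cl$assignments[4])
  for (g in cl$clusters) {
    expect_simplex(g$meanComposition)
    expect_equal(g$frequency, 0.5)
    # cluster mean equals its members' hand average
    expect_equal(unname(g$meanComposition)[1],
                 mean(c(0.9, 0.92, 0.1, 0.08)[g$members]))
    # sub-1% components suppressed in the display composition
    expect_true(all(g$displayComposition >= 0.01))
  }
})

test_that("identical designs collapse to one cluster at merge distance 0", {
  e <- fakeEntry(c(A = 0.5, B = 0.5, C = 0), 10, 100)
  cl <- clusterMixtures(fakeArchive(list(e, e, e)), k = 1)
  expect_equal(unname(cl$assignments), rep(1L, 3))
  expect_equal(cl$merges$height, rep(0, 2))
  expect_equal(unname(cl$clusters[[1]]$meanComposition),
               c(0.5, 0.5, 0))
})

test_that("clustering is invariant to archive row order and filters by p", {
  arch <- twoGroupArchive()
  rev_arch <- fakeArchive(rev(arch@entries))
  c1 <- clusterMixtures(arch, k = 2)
  c2 <- clusterMixtures(rev_arch, k = 2)
  m1 <- lapply(c1$clusters, `[[`, "meanComposition")
  m2 <- rev(lapply(c2$clusters, `[[`, "meanComposition"))
  expect_equal(m1[order(vapply(m1, `[`, 0, 1))],
               m2[order(vapply(m2, `[`, 0, 1))])
  # entries with lower p are excluded by the default filter
  mixed <- fakeArchive(c(arch@entries,
                         list(fakeEntry(c(A = 1, B = 0, C = 0), 0, 50,
                                        p = 0L))))
  expect_equal(length(clusterMixtures(mixed, k = 2)$assignments), 4)
  expect_equal(length(clusterMixtures(fakeArchive(list()))$clusters), 0)
})

test_that("robustness sampling is seeded and degenerates to the reference", {
  b <- branchFix()
  design <- singleGroupDesign(b, "P_nmr13c")
  r <- evaluateDesign(design, b$context)
  rep1 <- robustnessSample(design, r$fim, b$context, n = 50, seed = 9)
  rep2 <- robustnessSample(design, r$fim, b$context, n = 50, seed = 9)
  expect_identical(rep1$values, rep2$values)
  expect_equal(rep1$n, 50)
  # zero-covariance limit: every sample sits at the reference point
  fr0 <- r$fim
  fr0@cov <- matrix(0, 1, 1, dimnames = dimnames(r$fim@cov))
  rep0 <- robustnessSample(design, fr0, b$context, n = 10, seed = 1)
  expect_equal(rep0$values, rep(rep0$values[1], 10))
  expect_equal(rep0$values[1], 1 / r$criteria$D, tolerance = 1e-6)
  expect_error(robustnessSample(design, r$fim, b$context, n = 0), "n must")
})

test_that("Monte-Carlo robustness summaries are self-consistent across sizes", {
  cyc <- cycleFix()
  gn <- vapply(cyc$setup@groups, function(g) g@name, "")
  reps <- setNames(rep(0L, length(gn)), gn)
  reps[c("A_nmr13c", "B_nmr13c")] <- 1L
  design <- list(list(fractions = c(U = 0.3, `1C` = 0.7, `2C` = 0, UC = 0),
                      nRep = reps))
  r <- evaluateDesign(design, cyc$context)
  small <- robustnessSample(design, r$fim, cyc$context, n = 100, seed = 2)
  big <- robustnessSample(design, r$fim, cyc$context, n = 400, seed = 3)
  expect_gt(sd(small$values), 0)   # the criterion genuinely varies here
  se <- sd(small$values) / sqrt(small$n)
  expect_lte(abs(small$mean - big$mean), 3 * se)
  expect_true(all(small$values >= 0))
})

test_that("export tables carry chord links, histograms and scaling", {
  # 10 designs over 4 species, all species above the 1% threshold
  set.seed(1)
  entries <- lapply(1:10, function(i) {
    fr <- runif(4, 0.05, 1); fr <- fr / sum(fr)
    names(fr) <- c("A", "B", "C", "D")
    fakeEntry(fr, D = i, cost = 100 + 10 * i,
              nRep = c(g1 = i %% 3, g2 = 3L))
  })
  out <- exportResults(fakeArchive(entries))
  expect_equal(nrow(out$chordLinks), 40)
  pct <- out$chordLinks[, grep("Pct$", names(out$chordLinks))]
  expect_true(all(pct >= 0 & pct <= 100))
  expect_equal(nrow(out$front), 10)
  expect_equal(out$front$costTotal, 100 + 10 * (1:10))
  expect_equal(sum(out$replicateHist$count[out$replicateHist$group == "g2"]),
               10)
  hist <- out$mixtureHist
  expect_equal(sum(hist$frequency[hist$species == "A"]), 1)
})

test_that("species below 1% of a mixture are omitted from the link table", {
  entries <- list(
    fakeEntry(c(A = 0.995, B = 0.005, C = 0), 10, 100),
    fakeEntry(c(A = 0.5, B = 0.3, C = 0.2), 20, 200))
  out <- suppressMessages(exportResults(fakeArchive(entries)))
  expect_false(any(out$chordLinks$designId == 1 &
                     out$chordLinks$species == "B"))
  expect_equal(nrow(out$chordLinks), 4)
})

test_that("ternary coordinates appear exactly for three active species", {
  entries <- list(
    fakeEntry(c(A = 0.6, B = 0.3, C = 0.1), 10, 100),
    fakeEntry(c(A = 0.2, B = 0.3, C = 0.5), 20, 200))
  out <- exportResults(fakeArchive(entries))
  expect_false(is.null(out$ternary))
  expect_equal(out$ternary$A + out$ternary$B + out$ternary$C, c(1, 1))
  two <- list(fakeEntry(c(A = 0.5, B = 0.5, C = 0), 1, 10),
              fakeEntry(c(A = 0.4, B = 0.6, C = 0), 2, 20))
  expect_message(out2 <- exportResults(fakeArchive(two)), "skipped")
  expect_null(out2$ternary)
})

test_that("written export tables re-read exactly", {
  dir <- withr::local_tempdir()
  out <- exportResults(twoGroupArchive(), dir = dir)
  back <- read.csv(file.path(dir, "front.csv"))
  expect_equal(back$D, out$front$D)
  expect_equal(back$negCost, out$front$negCost)
})
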