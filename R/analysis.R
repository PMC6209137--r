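#' Hierarchical clustering of Pareto-optimal tracer mixtures
#'
#' Groups the archive's designs by similarity of their tracer composition
#' together with their information value and cost.  Feature vectors are the
#' per-species mixture fractions (averaged over parallel experiments), the
#' D-information value and the total cost, each min-max scaled to [0, 1];
#' distances are Euclidean with average linkage.
#'
#' @param archive a \linkS4class{ParetoArchive} from
#'   \code{\link{optimizeDesign}}
#' @param k number of clusters to cut into (or give \code{h})
#' @param h height to cut the dendrogram at
#' @param p restrict to entries of this effective dimension (default: the
#'   archive's maximum)
#' @param displayThreshold compositions below this fraction are suppressed
#'   in the display composition (default 1\%)
#' @return list with \code{assignments}, \code{clusters} (each with
#'   \code{members}, \code{meanComposition}, \code{displayComposition},
#'   \code{infoRange}, \code{costRange}, \code{frequency}) and
#'   \code{merges} (dendrogram merge table with heights)
#' @export
clusterMixtures <- function(archive, k = NULL, h = NULL, p = NULL,
                            displayThreshold = 0.01) {
  ent <- archive@entries
  if (!length(ent))
    return(list(assignments = integer(), clusters = list(),
                merges = data.frame()))
  ps <- vapply(ent, function(e) e$p, 0L)
  if (is.null(p)) p <- max(ps)
  ent <- ent[ps == p]
  if (!length(ent))
    return(list(assignments = integer(), clusters = list(),
                merges = data.frame()))
  comp <- do.call(rbind, lapply(ent, .meanComposition))
  info <- vapply(ent, function(e) e$objectives[["D"]], 0)
  cost <- vapply(ent, function(e) -e$objectives[["negCost"]], 0)
  feat <- cbind(comp, info = info, cost = cost)
  scaled <- apply(feat, 2, function(x) {
    r <- max(x) - min(x)
    if (r > 0) (x - min(x)) / r else rep(0, length(x))
  })
  if (nrow(feat) == 1L) {
    cl <- 1L
    merges <- data.frame(left = integer(), right = integer(),
                         height = numeric())
  } else {
    hc <- stats::hclust(stats::dist(scaled), method = "average")
    cl <- if (!is.null(k)) stats::cutree(hc, k = k)
      else if (!is.null(h)) stats::cutree(hc, h = h)
      else stats::cutree(hc, k = min(4L, nrow(feat)))
    merges <- data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
                         height = hc$height)
  }
  clusters <- lapply(sort(unique(cl)), function(g) {
    idx <- which(cl == g)
    mc <- colMeans(comp[idx, , drop = FALSE])
    disp <- mc[mc >= displayThreshold]
    list(members = idx, meanComposition = mc, displayComposition = disp,
         infoRange = range(info[idx]), costRange = range(cost[idx]),
         frequency = length(idx) / length(ent))
  })
  list(assignments = cl, clusters = clusters, merges = merges)
}

.meanComposition <- function(entry) {
  frs <- do.call(rbind, lapply(entry$design, `[[`, "fractions"))
  colMeans(frs)
}

#' Robustness of a design to deviations from the reference fluxes
#'
#' Samples flux vectors uniformly in the axis-aligned bounding box of the
#' confidence ellipsoid (half-widths \code{z * sqrt(diag(Cov))} around the
#' reference values of the retained free fluxes), rejecting infeasible
#' draws, and recomputes the D-information value of the design at each
#' sampled flux distribution with the retained free-flux set held fixed.
#'
#' @param design decoded design, see \code{\link{repairAndDecode}}
#' @param fimResult \linkS4class{FimResult} of the design at the reference
#'   point (p >= 1)
#' @param context a \linkS4class{DesignContext}
#' @param n number of samples (> 0)
#' @param seed RNG seed; the report is reproducible under it
#' @param z bounding-box half-width in standard deviations
#' @return list with \code{n}, \code{values} (per-sample D-information),
#'   \code{mean}, \code{quantiles}, \code{fracUpperThird} (fraction of
#'   samples in the top tercile of the sampled criterion range) and
#'   \code{nRejected}
#' @export
robustnessSample <- function(design, fimResult, context, n, seed = 1L,
                             z = 1.96) {
  if (n < 1) .stopf("n must be >= 1")
  if (fimResult@p < 1) .stopf("fimResult has p = 0; nothing to sample")
  set.seed(seed)
  retained <- fimResult@retained
  half <- z * sqrt(pmax(diag(fimResult@cov), 0))
  names(half) <- retained
  ref <- context@refFree
  isXch <- grepl("\\.xch$", retained)
  cles <- lapply(design, function(d)
    list(mixture = tracerMixture(context@species, d$fractions),
         setup = setReplicates(context@setup, d$nRep)))
  evalAt <- function(free) {
    blocks <- lapply(cles, function(cl) {
      pred <- predictMeasurements(
        solveLabeling(context@system,
                      expandFluxState(context@param, free, strict = FALSE),
                      cl$mixture), cl$setup)
      if (!nrow(pred)) return(NULL)
      pred <- evaluateErrorModel(pred, cl$setup@errorModels)
      J <- suppressWarnings(
        labelingJacobian(context@system, context@param, free, cl$mixture,
                         cl$setup, freeSet = retained))
      list(J = J, sd = pred$sd)
    })
    blocks <- Filter(Negate(is.null), blocks)
    if (!length(blocks)) return(0)
    fim <- computeFim(do.call(rbind, lapply(blocks, `[[`, "J")),
                      unlist(lapply(blocks, `[[`, "sd")))
    ev <- eigen(fim, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(0)
    # D-information of cov = fim^-1: 1 / det(cov)^(1/2p)
    exp(sum(log(ev)) / (2 * length(ev)))
  }
  degenerate <- all(half <= 0)
  values <- numeric(n)
  nRejected <- 0L
  for (i in seq_len(n)) {
    if (degenerate) { values[i] <- evalAt(ref); next }
    ok <- FALSE
    for (try in seq_len(1000L)) {
      free <- ref
      free[retained] <- ref[retained] +
        stats::runif(length(retained), -half, half)
      if (any(isXch & free[retained] < 0)) { nRejected <- nRejected + 1L; next }
      st <- expandFluxState(context@param, free, strict = FALSE)
      if (!is.null(attr(st, "violations")) && nrow(attr(st, "violations"))) {
        nRejected <- nRejected + 1L; next
      }
      ok <- TRUE
      break
    }
    if (!ok) .stopf("could not draw a feasible flux sample in 1000 tries")
    values[i] <- evalAt(free)
  }
  rng <- range(values)
  thr <- rng[1] + 2 / 3 * (rng[2] - rng[1])
  list(n = n, values = values, mean = mean(values),
       quantiles = stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1)),
       fracUpperThird = mean(values >= thr), nRejected = nRejected)
}

#' Export analysis tables of a Pareto archive
#'
#' Produces the tables behind the standard result graphics: the Pareto
#' front scatter table with cost breakdown, the chord-diagram link table
#' (one row per design and contributing species, with objectives min-max
#' scaled to 0-100\%), per-species mixture-proportion histograms,
#' per-group replicate histograms and (when exactly three species are
#' active) ternary coordinates.  Species contributing less than
#' \code{activeThreshold} to a mixture are omitted from the link table.
#'
#' @param archive a \linkS4class{ParetoArchive} from
#'   \code{\link{optimizeDesign}}
#' @param dir optional directory; tables are written as CSV files there
#' @param activeThreshold minimum fraction for a species to count as
#'   contributing (default 1\%)
#' @param binWidth mixture-proportion histogram bin width (default 5\%)
#' @return list of data.frames: \code{front}, \code{chordLinks},
#'   \code{mixtureHist}, \code{replicateHist}, \code{ternary} (NULL unless
#'   exactly 3 active species)
#' @export
exportResults <- function(archive, dir = NULL, activeThreshold = 0.01,
                          binWidth = 0.05) {
  ent <- archive@entries
  if (!length(ent)) .stopf("archive is empty")
  obj <- archiveObjectives(archive)
  front <- data.frame(designId = seq_along(ent), obj,
                      p = vapply(ent, function(e) e$p, 0L))
  cost <- lapply(ent, `[[`, "cost")
  if (!any(vapply(cost, is.null, TRUE))) {
    front$costExperimental <- vapply(cost, `[[`, 0, "experimental")
    front$costAnalytical <- vapply(cost, `[[`, 0, "analytical")
    front$costTotal <- vapply(cost, `[[`, 0, "total")
  }
  scaled <- apply(obj, 2, function(x) {
    r <- max(x) - min(x)
    if (r > 0) 100 * (x - min(x)) / r else rep(0, length(x))
  })
  scaled <- matrix(scaled, nrow = nrow(obj),
                   dimnames = list(NULL, paste0(colnames(obj), "Pct")))
  comp <- do.call(rbind, lapply(ent, .meanComposition))
  links <- list()
  for (i in seq_along(ent))
    for (s in colnames(comp))
      if (comp[i, s] >= activeThreshold)
        links[[length(links) + 1L]] <- data.frame(
          designId = i, species = s, fraction = comp[i, s],
          as.list(scaled[i, ]), stringsAsFactors = FALSE)
  chordLinks <- if (length(links))
    do.call(rbind, c(links, list(make.row.names = FALSE)))
  else data.frame()
  breaks <- seq(0, 1 + binWidth, by = binWidth)
  mixtureHist <- do.call(rbind, lapply(colnames(comp), function(s) {
    bin <- findInterval(comp[, s], breaks, rightmost.closed = FALSE)
    counts <- tabulate(bin, nbins = length(breaks) - 1L)
    data.frame(species = s, binLow = breaks[-length(breaks)],
               binHigh = breaks[-1], count = counts,
               frequency = counts / nrow(comp))
  }))
  reps <- do.call(rbind, lapply(seq_along(ent), function(i)
    do.call(rbind, lapply(seq_along(ent[[i]]$design), function(cle)
      data.frame(designId = i, cle = cle,
                 group = names(ent[[i]]$design[[cle]]$nRep),
                 nRep = as.integer(ent[[i]]$design[[cle]]$nRep))))))
  replicateHist <- stats::aggregate(
    cbind(count = rep(1, nrow(reps))) ~ group + nRep, data = reps, FUN = sum)
  replicateHist <- replicateHist[order(replicateHist$group, replicateHist$nRep), ]
  active <- colnames(comp)[apply(comp, 2, max) >= activeThreshold]
  ternary <- NULL
  if (length(active) == 3) {
    tc <- comp[, active, drop = FALSE]
    tc <- tc / rowSums(tc)
    ternary <- data.frame(designId = seq_along(ent), tc,
                          x = tc[, 2] + tc[, 3] / 2,
                          y = sqrt(3) / 2 * tc[, 3])
  } else {
    message(sprintf("ternary export skipped: %d active species (need exactly 3)",
                    length(active)))
  }
  out <- list(front = front, chordLinks = chordLinks,
              mixtureHist = mixtureHist, replicateHist = replicateHist,
              ternary = ternary)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out))
      if (!is.null(out[[nm]]) && nrow(out[[nm]]))
        utils::write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                         row.names = FALSE)
  }
  out
}

#' Write a Pareto archive to a tabular file
#'
#' One row per design: objective columns, effective dimension, frozen
#' fluxes, and the serialized design (per experiment:
#' \code{species=fraction} and \code{group=replicates} maps); a metadata
#' header records seed and swarm parameters.
#'
#' @param archive a \linkS4class{ParetoArchive}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeArchive <- function(archive, path) {
  ent <- archive@entries
  obj <- archiveObjectives(archive)
  ser <- vapply(ent, function(e) paste(vapply(e$design, function(d) paste(
    paste(sprintf("%s=%.12g", names(d$fractions), d$fractions), collapse = ","),
    paste(sprintf("%s=%d", names(d$nRep), d$nRep), collapse = ","),
    sep = ";"), ""), collapse = "|"), "")
  tab <- data.frame(obj,
                    p = vapply(ent, function(e) e$p, 0L),
                    frozen = vapply(ent, function(e)
                      paste(e$frozen, collapse = ";"), ""),
                    design = ser, stringsAsFactors = FALSE)
  hdr <- c(sprintf("# seed: %s", archive@meta$seed %||% NA),
           sprintf("# capacity: %d", archive@capacity),
           sprintf("# objectives: %s", paste(colnames(obj), collapse = ",")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Read a Pareto archive written by \code{\link{writeArchive}}
#'
#' @param path archive file
#' @return a \linkS4class{ParetoArchive} (objectives, p, frozen fluxes and
#'   decoded designs; evaluation reports are not stored in the file)
#' @export
readArchive <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (i in hdr) {
    kv <- regmatches(lines[i], regexec("^# ([^:]+): (.*)$", lines[i]))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- kv[3]
  }
  tab <- utils::read.csv(text = lines[-hdr], stringsAsFactors = FALSE)
  objCols <- setdiff(names(tab), c("p", "frozen", "design"))
  entries <- lapply(seq_len(nrow(tab)), function(i) {
    design <- lapply(strsplit(tab$design[i], "|", fixed = TRUE)[[1]],
                     function(cle) {
      parts <- strsplit(cle, ";", fixed = TRUE)[[1]]
      parseMap <- function(s) {
        kv <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
        stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                        vapply(kv, `[`, "", 1))
      }
      fr <- parseMap(parts[1])
      rp <- parseMap(parts[2])
      list(fractions = fr, nRep = stats::setNames(as.integer(rp), names(rp)))
    })
    list(objectives = stats::setNames(as.numeric(tab[i, objCols]), objCols),
         p = tab$p[i],
         frozen = if (!is.na(tab$frozen[i]) && nzchar(as.character(tab$frozen[i])))
           strsplit(as.character(tab$frozen[i]), ";", fixed = TRUE)[[1]]
         else character(),
         design = design)
  })
  new("ParetoArchive", entries = entries,
      capacity = as.integer(meta$capacity %||% length(entries)),
      meta = meta)
}
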