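#' Built-in toy fixtures
#'
#' Deterministic, hand-derivable desk-scale networks exercising the three
#' qualitative situations of labeling-based flux inference:
#' \describe{
#'   \item{chain}{a linear pathway; labeling is independent of the flux
#'     value, so every measurement Jacobian vanishes.}
#'   \item{branch}{two parallel paths from a 2-carbon substrate to one
#'     product, one preserving carbon order and one swapping C1/C2: the
#'     split ratio is identifiable from positional data but invisible to
#'     mass isotopomer distributions.}
#'   \item{cycle}{a loop with carbon scrambling and one reversible step;
#'     the exchange flux is the only free coordinate and is identifiable
#'     only with informative (non-uniform) tracers.}
#' }
#' Each bundle carries the network, its parametrization, reference free
#' fluxes, tracer species (idealized purity 1 for labeled species so the
#' hand derivations are exact), measurement groups with constant-sigma
#' error models (replicate scaling a(n) = 1), cost parameters, an
#' assembled \linkS4class{DesignContext} and a ledger of hand-derived
#' expected values with derivation notes (verified by the test suite).
#'
#' @param name one of \code{"chain"}, \code{"branch"}, \code{"cycle"}
#' @param objectives objective set for the bundled context
#' @return a fixture bundle (list)
#' @export
makeFixture <- function(name = c("chain", "branch", "cycle"),
                        objectives = "3D") {
  name <- tryCatch(match.arg(name), error = function(e)
    .stopf("unknown fixture '%s' (available: chain, branch, cycle)",
           paste(name, collapse = ",")))
  switch(name,
         chain = .chainFixture(objectives),
         branch = .branchFixture(objectives),
         cycle = .cycleFixture(objectives))
}

.fixtureSpecies <- function(pool) {
  data.frame(
    name = c("U", "1C", "2C", "UC"),
    pool = pool,
    pattern = c("00", "10", "01", "11"),
    purity = c(0.98, 1, 1, 1),
    price = c(0.30, 150, 900, 250),
    stringsAsFactors = FALSE)
}

.fixtureModels <- function(devices, b2 = 0.01) {
  ms <- lapply(devices, function(d)
    errorModel(d, b1 = 0, b2 = b2, repScaling = function(n) rep(1, length(n))))
  names(ms) <- devices
  ms
}

.chainFixture <- function(objectives) {
  net <- loadNetwork(text = c(
    "network chain",
    "metabolites:",
    "  Sin 2 input", "  A 2 balanced", "  B 2 balanced", "  C 2 balanced",
    "  Sout 2 output",
    "reactions:",
    "  upt: Sin#ab -> A#ab",
    "  r1: A#ab -> B#ab",
    "  r2: B#ab -> C#ab",
    "  out: C#ab -> Sout#ab"))
  species <- .fixtureSpecies("Sin")
  groups <- list(
    makeDeviceTemplates("C", 2, device = "nmr", type = "NMR13C"),
    makeDeviceTemplates("C", 2, device = "ms", type = "MS"))
  setup <- measurementSetup(groups, errorModels = .fixtureModels(c("nmr", "ms")))
  refFree <- c(out = 1)
  ctx <- designContext(net, refFree, species, setup, makeCostParams(),
                       objectives = objectives)
  list(name = "chain", network = net, param = ctx@param, refFree = refFree,
       species = species, setup = setup, costParams = ctx@costParams,
       context = ctx,
       expected = data.frame(
         quantity = c("dof", "maxWeight", "jacobianNorm"),
         value = c(1, 2, 0),
         note = c("4 reactions minus rank-3 balance system",
                  "largest balanced pool has 2 carbons",
                  "labeling on a linear chain is flux independent"),
         stringsAsFactors = FALSE))
}

.branchFixture <- function(objectives) {
  net <- loadNetwork(text = c(
    "network branch",
    "metabolites:",
    "  Sin 2 input", "  A 2 balanced", "  P 2 balanced", "  Sout 2 output",
    "reactions:",
    "  upt: Sin#ab -> A#ab",
    "  r1: A#ab -> P#ab",
    "  r2: A#ab -> P#ba",
    "  out: P#ab -> Sout#ab",
    "rates:",
    "  upt = 1"))
  species <- .fixtureSpecies("Sin")
  groups <- list(
    # single positional observation: eta = r1 exactly, flux sd = sigma
    makeDeviceTemplates("P", 2, device = "nmr", type = "NMR13C",
                        positions = 1),
    makeDeviceTemplates("P", 2, device = "ms", type = "MS"))
  setup <- measurementSetup(groups, errorModels = .fixtureModels(c("nmr", "ms")))
  refFree <- c(r1 = 0.7)
  ctx <- designContext(net, refFree, species, setup, makeCostParams(),
                       objectives = objectives, prefer = "r1")
  list(name = "branch", network = net, param = ctx@param, refFree = refFree,
       species = species, setup = setup, costParams = ctx@costParams,
       context = ctx,
       expected = data.frame(
         quantity = c("dofPinned", "dofUnpinned", "etaC1", "etaC2",
                      "dEtaC1dR1", "midM1", "fluxSd"),
         value = c(1, 2, 0.7, 0.3, 1, 1, 0.01),
         note = c(
           "rank-3 system (2 balances + pinned uptake) on 4 reactions",
           "rank-2 balance system without the uptake rate",
           "P C1 keeps the label iff the molecule came via the order-preserving path: eta = r1",
           "A-pool balance: r2 = 1 - r1 = 0.3 routes the label to C2",
           "eta = r1 exactly, so the sensitivity is 1",
           "exactly one labeled carbon survives on either path: M+1 fraction = 1 for any split",
           "J = 1, sigma = b2 = 0.01 with a(n)=1 => sd = sigma"),
         stringsAsFactors = FALSE))
}

.cycleFixture <- function(objectives) {
  # interconversion loop: r1 feeds B order-preserving, the reversible r2
  # exchanges A and B with a C1/C2 swap, so back-flux scrambles label
  # between the two pools (the motif behind exchange-flux identifiability)
  net <- loadNetwork(text = c(
    "network cycle",
    "metabolites:",
    "  Sin 2 input", "  A 2 balanced", "  B 2 balanced", "  Sout 2 output",
    "reactions:",
    "  upt: Sin#ab -> A#ab",
    "  r1: A#ab -> B#ab",
    "  r2: A#ab <-> B#ba",
    "  out: B#ab -> Sout#ab",
    "rates:",
    "  upt = 1"))
  species <- .fixtureSpecies("Sin")
  groups <- list(
    makeDeviceTemplates("A", 2, device = "nmr", type = "NMR13C",
                        name = "A_nmr13c"),
    makeDeviceTemplates("B", 2, device = "nmr", type = "NMR13C",
                        name = "B_nmr13c"),
    makeDeviceTemplates("B", 2, device = "ms", type = "MS"))
  setup <- measurementSetup(groups, errorModels = .fixtureModels(c("nmr", "ms")))
  refFree <- c(r1 = 0.6, r2.xch = 0.5)
  ctx <- designContext(net, refFree, species, setup, makeCostParams(),
                       objectives = objectives, prefer = "r1")
  list(name = "cycle", network = net, param = ctx@param, refFree = refFree,
       species = species, setup = setup, costParams = ctx@costParams,
       context = ctx,
       expected = data.frame(
         quantity = c("dofNet", "freeCount", "totalCarbons"),
         value = c(1, 2, 4),
         note = c(
           "4 reactions, rank-3 system with the uptake pinned",
           "one free net flux (r1) plus the r2 exchange flux",
           "balanced pools carry 2+2 carbons (brute-force oracle feasible)"),
         stringsAsFactors = FALSE))
}

#' Write a fixture bundle as ordinary input files
#'
#' Emits the network schema file plus YAML tracer, device and cost
#' configurations, so the command-line path can be exercised end-to-end on
#' the same models the tests use.
#'
#' @param bundle from \code{\link{makeFixture}}
#' @param dir output directory (created if needed)
#' @return named character vector of the files written
#' @export
writeFixtureFiles <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(network = file.path(dir, "network.txt"),
             tracers = file.path(dir, "tracers.yaml"),
             devices = file.path(dir, "devices.yaml"),
             costs = file.path(dir, "costs.yaml"),
             config = file.path(dir, "config.yaml"))
  writeNetwork(bundle$network, files[["network"]])
  yaml::write_yaml(list(species = lapply(seq_len(nrow(bundle$species)),
    function(i) as.list(bundle$species[i, ]))), files[["tracers"]])
  devs <- lapply(bundle$setup@errorModels, function(m)
    list(b1 = m@b1, b2 = m@b2, repScaling = "constant"))
  grps <- lapply(bundle$setup@groups, function(g) {
    type <- .groupType(g)
    out <- list(name = g@name, device = g@device, pool = g@pool,
                type = type, nRep = unname(bundle$setup@nRep[[g@name]]))
    if (type %in% c("NMR13C", "NMR1H"))
      out$positions <- as.integer(sub("^[CH]", "", rownames(g@rows)))
    out
  })
  yaml::write_yaml(list(devices = devs, groups = grps,
                        nRepMax = bundle$setup@nRepMax), files[["devices"]])
  cp <- bundle$costParams
  cp$tracerPrices <- as.list(cp$tracerPrices)
  yaml::write_yaml(cp, files[["costs"]])
  yaml::write_yaml(list(
    network = "network.txt", tracers = "tracers.yaml",
    devices = "devices.yaml", costs = "costs.yaml",
    refFree = as.list(bundle$refFree),
    prefer = as.list(bundle$param@freeNet),
    nCle = bundle$context@nCle,
    objectives = bundle$context@objectives), files[["config"]])
  files
}

# recover the template type of a fixture group from its name suffix
.groupType <- function(g) {
  if (grepl("nmr13c$|_nmr13c", g@name)) "NMR13C"
  else if (grepl("_msms", g@name)) "MSMS"
  else if (grepl("_irms", g@name)) "IRMS"
  else if (grepl("_nmr1h", g@name)) "NMR1H"
  else "MS"
}
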