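#' Read an atom-mapped network description
#'
#' Parses the package's structured text schema for atom-mapped metabolic
#' networks and returns a validated \linkS4class{MetabolicNetwork}.
#'
#' @details The schema has four sections introduced by
#' \code{metabolites:}, \code{reactions:}, \code{rates:}, \code{bounds:} and
#' \code{inequalities:} headers; \code{#} starts a comment. Metabolite lines
#' are \code{name carbons role} with role one of
#' \code{balanced}/\code{input}/\code{output}. Reaction lines use atom
#' strings: \preformatted{ r1: A#ab + B#c -> C#abc
#'  r2: D#ab <-> E#ba }
#' where each letter names one carbon and the letters define the atom-wise
#' educt-to-product bijection; \code{<->} marks a reversible reaction.
#' Carbon-free cofactors are written without \code{#} (optionally with a
#' leading stoichiometric coefficient, e.g. \code{2 ATP}). Rate lines
#' (\code{upt = 1.0}) are measured extracellular rates entered as equality
#' rows of the flux system. Bound lines are \code{name in [lo, hi]};
#' inequality lines are linear combinations like \code{1*r1 - 1*r2 <= 0.5}.
#'
#' @param path file path, or a character vector of lines via \code{text}.
#' @param text optional character vector with the document's lines.
#' @return a \linkS4class{MetabolicNetwork}
#' @seealso \code{\link{writeNetwork}}, \code{\link{stoichiometricAnalysis}}
#' @export
loadNetwork <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- sub("#.*$", "", ifelse(grepl("^\\s*#", lines), "", .protectAtoms(lines)))
  lines <- .unprotectAtoms(lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  name <- "network"
  mets <- list(); rxns <- list(); rates <- numeric()
  bounds <- list(); ineqs <- list()
  for (ln in lines) {
    low <- tolower(ln)
    if (grepl("^network\\b", low)) { name <- trimws(sub("^network", "", ln)); next }
    if (low %in% c("metabolites:", "reactions:", "rates:", "bounds:", "inequalities:")) {
      section <- sub(":$", "", low); next
    }
    if (is.na(section)) .stopf("line outside any section: '%s'", ln)
    switch(section,
      metabolites = {
        f <- strsplit(ln, "\\s+")[[1]]
        if (length(f) != 3) .stopf("bad metabolite line: '%s'", ln)
        mets[[length(mets) + 1L]] <- data.frame(
          name = f[1], carbons = as.integer(f[2]), role = tolower(f[3]),
          stringsAsFactors = FALSE)
      },
      reactions = rxns[[length(rxns) + 1L]] <- .parseReaction(ln),
      rates = {
        f <- strsplit(ln, "=")[[1]]
        if (length(f) != 2) .stopf("bad rate line: '%s'", ln)
        rates[trimws(f[1])] <- as.numeric(f[2])
      },
      bounds = {
        m <- regmatches(ln, regexec(
          "^(\\S+)\\s+in\\s+\\[\\s*([^,]+),\\s*([^\\]]+)\\]$", ln))[[1]]
        if (length(m) != 4) .stopf("bad bound line: '%s'", ln)
        bounds[[length(bounds) + 1L]] <- data.frame(
          reaction = m[2], lower = as.numeric(m[3]), upper = as.numeric(m[4]),
          stringsAsFactors = FALSE)
      },
      inequalities = ineqs[[length(ineqs) + 1L]] <- ln
    )
  }
  met <- if (length(mets)) do.call(rbind, mets) else
    data.frame(name = character(), carbons = integer(), role = character())
  net <- new("MetabolicNetwork",
    metabolites = met, reactions = rxns, rates = rates,
    ineq = .parseInequalities(ineqs, vapply(rxns, `[[`, "", "name")),
    bounds = .defaultBounds(rxns, if (length(bounds)) do.call(rbind, bounds) else NULL),
    name = if (nzchar(name)) name else "network")
  validObject(net)
  net
}

# '#' introduces both comments and atom strings; temporarily mask atom '#'
.protectAtoms <- function(lines) gsub("#([A-Za-z]+)", "\001\\1", lines)
.unprotectAtoms <- function(lines) gsub("\001", "#", lines)

.parseReaction <- function(ln) {
  f <- strsplit(ln, ":", fixed = TRUE)[[1]]
  if (length(f) < 2) .stopf("bad reaction line (missing 'name:'): '%s'", ln)
  rname <- trimws(f[1])
  body <- trimws(paste(f[-1], collapse = ":"))
  reversible <- grepl("<->", body, fixed = TRUE)
  sides <- strsplit(body, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) .stopf("bad reaction body in '%s'", rname)
  parseSide <- function(s) {
    parts <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    lapply(parts, function(p) {
      coef <- 1
      m <- regmatches(p, regexec("^([0-9.]+)\\s+(.*)$", p))[[1]]
      if (length(m) == 3) { coef <- as.numeric(m[2]); p <- m[3] }
      if (grepl("#", p, fixed = TRUE)) {
        mp <- strsplit(p, "#", fixed = TRUE)[[1]]
        list(met = trimws(mp[1]), coef = coef,
             labels = strsplit(mp[2], "")[[1]])
      } else list(met = trimws(p), coef = coef, labels = NULL)
    })
  }
  list(name = rname, educts = parseSide(sides[1]),
       products = parseSide(sides[2]), reversible = reversible)
}

.parseInequalities <- function(ineqs, rnames) {
  if (!length(ineqs))
    return(list(A = matrix(0, 0, length(rnames), dimnames = list(NULL, rnames)),
                b = numeric()))
  A <- matrix(0, length(ineqs), length(rnames), dimnames = list(NULL, rnames))
  b <- numeric(length(ineqs))
  for (i in seq_along(ineqs)) {
    f <- strsplit(ineqs[[i]], "<=", fixed = TRUE)[[1]]
    if (length(f) != 2) .stopf("bad inequality line: '%s'", ineqs[[i]])
    b[i] <- as.numeric(f[2])
    lhs <- gsub("-", "+-", gsub("\\s", "", f[1]))
    for (term in strsplit(lhs, "+", fixed = TRUE)[[1]]) {
      if (!nzchar(term)) next
      tf <- strsplit(term, "*", fixed = TRUE)[[1]]
      if (length(tf) == 1) { coef <- if (startsWith(tf, "-")) -1 else 1
        rn <- sub("^-", "", tf) }
      else { coef <- as.numeric(tf[1]); rn <- tf[2] }
      if (!rn %in% rnames) .stopf("inequality references unknown reaction '%s'", rn)
      A[i, rn] <- A[i, rn] + coef
    }
  }
  list(A = A, b = b)
}

.defaultBounds <- function(rxns, userBounds) {
  rn <- vapply(rxns, `[[`, "", "name")
  rev <- vapply(rxns, `[[`, TRUE, "reversible")
  out <- data.frame(reaction = rn,
                    lower = ifelse(rev, -Inf, 0), upper = Inf,
                    stringsAsFactors = FALSE)
  if (!is.null(userBounds)) {
    bad <- setdiff(userBounds$reaction, rn)
    if (length(bad)) .stopf("bounds reference unknown reaction(s): %s",
                            paste(bad, collapse = ", "))
    i <- match(userBounds$reaction, out$reaction)
    out$lower[i] <- userBounds$lower
    out$upper[i] <- userBounds$upper
  }
  out
}

#' Write a network back to the schema format
#'
#' Serialization is round-trip stable with \code{\link{loadNetwork}}.
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param path output file; if \code{NULL} the lines are returned invisibly
#' @return character vector of lines, invisibly
#' @export
writeNetwork <- function(network, path = NULL) {
  fmtSide <- function(side) paste(vapply(side, function(p) {
    pre <- if (p$coef != 1) paste0(format(p$coef), " ") else ""
    if (is.null(p$labels)) paste0(pre, p$met)
    else paste0(pre, p$met, "#", paste(p$labels, collapse = ""))
  }, ""), collapse = " + ")
  out <- c(paste("network", network@name), "metabolites:")
  out <- c(out, sprintf("  %s %d %s", network@metabolites$name,
                        network@metabolites$carbons, network@metabolites$role))
  out <- c(out, "reactions:")
  out <- c(out, vapply(network@reactions, function(rx)
    sprintf("  %s: %s %s %s", rx$name, fmtSide(rx$educts),
            if (rx$reversible) "<->" else "->", fmtSide(rx$products)), ""))
  if (length(network@rates))
    out <- c(out, "rates:", sprintf("  %s = %.12g", names(network@rates),
                                    network@rates))
  bdef <- .defaultBounds(network@reactions, NULL)
  ch <- network@bounds$lower != bdef$lower | network@bounds$upper != bdef$upper
  if (any(ch))
    out <- c(out, "bounds:", sprintf("  %s in [%g, %g]",
                                     network@bounds$reaction[ch],
                                     network@bounds$lower[ch],
                                     network@bounds$upper[ch]))
  if (nrow(network@ineq$A)) {
    out <- c(out, "inequalities:")
    for (i in seq_len(nrow(network@ineq$A))) {
      co <- network@ineq$A[i, ]
      term <- paste(sprintf("%+g*%s", co[co != 0], names(co)[co != 0]),
                    collapse = " ")
      out <- c(out, sprintf("  %s <= %g", term, network@ineq$b[i]))
    }
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
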