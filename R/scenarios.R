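#' Time strata used by the shipped dispersal scenarios
#'
#' Five half-open intervals in age: 0-3, 3-20, 20-30, 30-40 and 40-120 mya.
#' A boundary age belongs to the stratum whose lower bound it is (so age 3.0
#' falls in the 3-20 stratum).
#'
#' @return Data frame with columns `index`, `younger_bound`, `older_bound`.
#' @export
default_strata <- function() {
  b <- c(0, 3, 20, 30, 40, 120)
  data.frame(index = seq_len(5L), younger_bound = b[-6], older_bound = b[-1])
}

#' Build a time-strata table from boundary ages
#'
#' @param bounds Strictly increasing ages starting at 0; consecutive pairs
#'   delimit the strata.
#' @return Data frame as in [default_strata()].
#' @export
make_strata <- function(bounds) {
  bounds <- as.numeric(bounds)
  if (length(bounds) < 2L || bounds[1] != 0 || any(diff(bounds) <= 0))
    stop("bounds must start at 0 and be strictly increasing")
  k <- length(bounds) - 1L
  data.frame(index = seq_len(k), younger_bound = bounds[-(k + 1L)],
             older_bound = bounds[-1])
}

#' Pairwise connectivity specification
#'
#' A symmetric classification of ordered area pairs into `adjacent-land`,
#' `across-water` and `non-adjacent`.  The baseline dispersal multipliers
#' derived from it are 0.5 for adjacent land, 0.25 across water, and (since
#' only those two tiers are defined) 0.25 for non-adjacent pairs as well.
#'
#' @param areas Character vector of area names.
#' @param adjacent Two-column matrix or data frame of adjacent-land pairs.
#' @param water Optional two-column collection of across-water pairs;
#'   anything not listed as adjacent or water is `non-adjacent`.
#' @return A `connectivity` object: character matrix of relations with unit
#'   `"self"` diagonal.
#' @export
connectivity_spec <- function(areas, adjacent, water = NULL) {
  n <- length(areas)
  rel <- matrix("non-adjacent", n, n, dimnames = list(areas, areas))
  diag(rel) <- "self"
  set_pairs <- function(rel, pairs, value) {
    if (is.null(pairs) || NROW(pairs) == 0L) return(rel)
    pairs <- as.matrix(pairs)
    for (r in seq_len(nrow(pairs))) {
      i <- match(pairs[r, 1], areas); j <- match(pairs[r, 2], areas)
      if (is.na(i) || is.na(j)) stop("unknown area in connectivity pair: ",
                                     paste(pairs[r, ], collapse = "-"))
      rel[i, j] <- value; rel[j, i] <- value
    }
    rel
  }
  rel <- set_pairs(rel, water, "across-water")
  rel <- set_pairs(rel, adjacent, "adjacent-land")
  structure(rel, class = c("connectivity", "matrix"))
}

baseline_multipliers <- function(connectivity) {
  m <- matrix(0.25, nrow(connectivity), ncol(connectivity),
              dimnames = dimnames(connectivity))
  m[connectivity == "adjacent-land"] <- 0.5
  diag(m) <- 1
  m
}

#' Shipped scenario names
#' @export
scenario_names <- function() c("null", "panama", "closing_americas", "gaarlandia")

#' Build a time-stratified dispersal scenario
#'
#' Constructs one of the four shipped scenarios over the given strata:
#' \describe{
#'   \item{null}{all multipliers 1 in every stratum.}
#'   \item{panama}{baseline multipliers from connectivity (land 0.5, water
#'     0.25) in every stratum; Mesoamerica-Pacific reduced to 0.01 in all
#'     strata older than the isthmus closure at 3 mya.}
#'   \item{closing_americas}{as panama in the youngest stratum;
#'     Mesoamerica-Pacific 0.5 in the 3-20 mya stratum (overwater proximity)
#'     and 0.01 in all older strata.}
#'   \item{gaarlandia}{as closing_americas, plus Caribbean routes raised to
#'     `gaarlandia_mult` in the 30-40 mya stratum (the hypothesized
#'     Greater Antilles-Aves Ridge connection); older strata revert to the
#'     closing_americas values.}
#' }
#' The multipliers scale the dispersal rate `d` multiplicatively.
#'
#' @param name One of [scenario_names()].
#' @param areas Character vector of area names.
#' @param connectivity A [connectivity_spec()] over `areas`.
#' @param strata Strata table as from [default_strata()].
#' @param gateway Length-2 character vector naming the Central/South America
#'   gateway pair whose multiplier the panama/closing_americas scenarios vary.
#' @param caribbean Name of the Caribbean area (gaarlandia scenario).
#' @param gaarlandia_mult Elevated Caribbean multiplier in the 30-40 mya
#'   stratum; the hypothesis specifies only an increase, not a value, so
#'   this defaults to the adjacent-land multiplier 0.5 and is configurable.
#' @return A `dispersal_scenario` object: list with `name`, `strata`,
#'   `multipliers` (one area-by-area matrix per stratum).
#' @export
build_scenario <- function(name, areas, connectivity = NULL,
                           strata = default_strata(),
                           gateway = c("Mesoamerica", "Pacific"),
                           caribbean = "Caribbean",
                           gaarlandia_mult = 0.5) {
  name <- match.arg(name, scenario_names())
  n <- length(areas)
  k <- nrow(strata)
  if (name == "null") {
    one <- matrix(1, n, n, dimnames = list(areas, areas))
    mats <- rep(list(one), k)
  } else {
    if (is.null(connectivity)) stop("scenario '", name, "' needs a connectivity spec")
    if (!identical(rownames(connectivity), areas))
      stop("connectivity areas do not match 'areas'")
    base <- baseline_multipliers(connectivity)
    gi <- match(gateway, areas)
    if (anyNA(gi)) stop("gateway areas not found: ", paste(gateway, collapse = ", "))
    mats <- rep(list(base), k)
    older_than <- function(age) which(strata$younger_bound >= age)
    set_gate <- function(m, v) { m[gi[1], gi[2]] <- v; m[gi[2], gi[1]] <- v; m }
    if (name == "panama") {
      for (s in older_than(3)) mats[[s]] <- set_gate(mats[[s]], 0.01)
    } else {                      # closing_americas and gaarlandia
      for (s in which(strata$younger_bound >= 3 & strata$older_bound <= 20))
        mats[[s]] <- set_gate(mats[[s]], 0.5)
      for (s in older_than(20)) mats[[s]] <- set_gate(mats[[s]], 0.01)
      if (name == "gaarlandia") {
        ci <- match(caribbean, areas)
        if (is.na(ci)) stop("Caribbean area '", caribbean, "' not found")
        for (s in which(strata$younger_bound == 30)) {
          m <- mats[[s]]
          m[ci, ] <- pmax(m[ci, ], gaarlandia_mult)
          m[, ci] <- pmax(m[, ci], gaarlandia_mult)
          m[ci, ci] <- 1
          mats[[s]] <- m
        }
      }
    }
  }
  structure(list(name = name, areas = areas, strata = strata,
                 multipliers = mats),
            class = "dispersal_scenario")
}

#' @export
print.dispersal_scenario <- function(x, ...) {
  cat("Dispersal scenario '", x$name, "': ", length(x$areas), " areas, ",
      nrow(x$strata), " time strata\n", sep = "")
  for (s in seq_len(nrow(x$strata)))
    cat(sprintf("  stratum %d: %g-%g mya (multipliers in [%g, %g])\n",
                s, x$strata$younger_bound[s], x$strata$older_bound[s],
                min(x$multipliers[[s]]), max(x$multipliers[[s]])))
  invisible(x)
}

#' Look up a dispersal multiplier at a given age
#'
#' @param scenario A `dispersal_scenario`.
#' @param from,to Area names.
#' @param age Age in mya; must be younger than the oldest stratum bound.
#'   Boundary ages fall in the stratum whose lower bound they are.
#' @return The multiplier (nonnegative scalar).
#' @export
multiplier <- function(scenario, from, to, age) {
  st <- scenario$strata
  if (age < 0 || age >= st$older_bound[nrow(st)])
    stop("age ", age, " outside the covered span [0, ",
         st$older_bound[nrow(st)], ")")
  s <- findInterval(age, c(st$younger_bound, st$older_bound[nrow(st)]))
  i <- match(from, scenario$areas); j <- match(to, scenario$areas)
  if (is.na(i) || is.na(j)) stop("unknown area name")
  scenario$multipliers[[s]][i, j]
}

#' Write / read a scenario as a plain-text config
#'
#' Serializes the strata table and per-stratum multiplier matrices to a
#' simple key-value text format that round-trips losslessly.
#'
#' @param scenario A `dispersal_scenario`.
#' @param path Output (input) path.
#' @export
write_scenario <- function(scenario, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("name:", scenario$name),
               paste("areas:", paste(scenario$areas, collapse = " ")),
               paste("bounds:", paste(c(scenario$strata$younger_bound,
                                        scenario$strata$older_bound[nrow(scenario$strata)]),
                                      collapse = " "))), con)
  for (s in seq_along(scenario$multipliers)) {
    writeLines(paste("stratum:", s), con)
    m <- scenario$multipliers[[s]]
    writeLines(apply(m, 1, function(r) paste(format(r, digits = 12), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  lines <- readLines(path)
  val <- function(key) sub(paste0("^", key, ": ?"), "",
                           grep(paste0("^", key, ":"), lines, value = TRUE)[1])
  name <- val("name")
  areas <- strsplit(val("areas"), "\\s+")[[1]]
  bounds <- as.numeric(strsplit(val("bounds"), "\\s+")[[1]])
  strata <- make_strata(bounds)
  n <- length(areas)
  starts <- grep("^stratum:", lines)
  mats <- lapply(starts, function(i) {
    m <- do.call(rbind, lapply(lines[(i + 1):(i + n)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    dimnames(m) <- list(areas, areas)
    m
  })
  structure(list(name = name, areas = areas, strata = strata, multipliers = mats),
            class = "dispersal_scenario")
}
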