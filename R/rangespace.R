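#' Enumerate the geographic-range state space
#'
#' Builds the full set of geographic ranges (subsets of operational areas) of
#' size at most `max_range_size`, plus the null (empty) range.  The null range
#' is a legal interior state of the anagenetic Markov process -- a lineage can
#' lose its last area along a branch -- but it is never a legal observation at
#' a tip.  States are ordered deterministically: the null range first, then by
#' range size, then lexicographically on area indices, so that state indices
#' are stable across runs and platforms.
#'
#' @param areas Character vector of unique operational-area names, in the
#'   order that defines the bit encoding of geography files.
#' @param max_range_size Maximum number of areas a range may contain
#'   (\eqn{1 \le} `max_range_size` \eqn{\le} number of areas).
#' @return An object of class `state_space`: a list with elements `areas`,
#'   `max_range_size`, `sets` (list of integer vectors of 1-based area
#'   indices; the first element is the empty null range), `labels` (compact
#'   state labels such as `"A+B"`), and `n_states`.
#' @examples
#' ss <- build_state_space(c("A", "B", "C"), max_range_size = 2)
#' ss$n_states  # 1 + 3 + 3
#' @export
build_state_space <- function(areas, max_range_size) {
  areas <- as.character(areas)
  if (length(areas) < 1L) stop("at least one area is required")
  if (anyDuplicated(areas)) stop("area names must be unique")
  n <- length(areas)
  max_range_size <- as.integer(max_range_size)
  if (is.na(max_range_size) || max_range_size < 1L || max_range_size > n)
    stop("max_range_size must lie in 1..", n)
  sets <- list(integer(0))
  for (k in seq_len(max_range_size)) {
    cmb <- utils::combn(n, k)
    # combn emits columns in lexicographic order already
    sets <- c(sets, lapply(seq_len(ncol(cmb)), function(j) as.integer(cmb[, j])))
  }
  labels <- vapply(sets, function(s)
    if (length(s) == 0L) "null" else paste(areas[s], collapse = "+"), "")
  structure(list(areas = areas, max_range_size = max_range_size,
                 sets = sets, labels = labels, n_states = length(sets)),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("Geographic range state space\n")
  cat("  areas:", length(x$areas), paste0("(", paste(x$areas, collapse = ", "), ")"), "\n")
  cat("  max range size:", x$max_range_size, "\n")
  cat("  states:", x$n_states, "(incl. null range)\n")
  invisible(x)
}

#' Find the state index of a set of areas
#'
#' @param space A `state_space`.
#' @param areas Character vector of area names (or integer area indices).
#' @return Integer state index into `space$sets`.
#' @export
range_index <- function(space, areas) {
  idx <- if (is.character(areas)) match(areas, space$areas) else as.integer(areas)
  if (anyNA(idx)) stop("unknown area name(s): ",
                       paste(setdiff(areas, space$areas), collapse = ", "))
  idx <- sort(unique(idx))
  key <- paste(idx, collapse = ",")
  keys <- vapply(space$sets, paste, "", collapse = ",")
  i <- match(key, keys)
  if (is.na(i)) stop("range {", paste(space$areas[idx], collapse = ","),
                     "} is not in the state space (size > max_range_size?)")
  i
}

# bitstring helpers for the Lagrange/PHYLIP-style geography dialect
range_to_bits <- function(space, state_index) {
  b <- rep.int(0L, length(space$areas))
  b[space$sets[[state_index]]] <- 1L
  paste(b, collapse = "")
}

bits_to_range <- function(space, bits) {
  v <- as.integer(strsplit(bits, "")[[1]])
  if (length(v) != length(space$areas) || anyNA(v) || any(v > 1L))
    stop("malformed presence-absence string '", bits, "'")
  range_index(space, which(v == 1L))
}

#' Read a tip-geography file
#'
#' Reads the Lagrange/PHYLIP-style dialect: a header line
#' `"<n_taxa> <n_areas> (<area names...>)"` followed by one
#' `"<taxon> <binary string>"` line per taxon.  Area names in the header must
#' match the state space's area order.
#'
#' @param path Path to the geography file.
#' @param space A `state_space` whose area order defines the bit decoding.
#' @return A `geography` object: named integer vector of state indices with
#'   the state space attached as attribute `space`.
#' @export
read_geography <- function(path, space) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("geography file needs a header and >= 1 taxon line")
  hd <- regmatches(lines[1], regexec("^\\s*(\\d+)\\s+(\\d+)\\s*\\(([^)]*)\\)", lines[1]))[[1]]
  if (length(hd) != 4L) stop("malformed geography header: ", lines[1])
  n_taxa <- as.integer(hd[2]); n_areas <- as.integer(hd[3])
  nm <- strsplit(trimws(hd[4]), "\\s+")[[1]]
  if (n_areas != length(space$areas))
    stop("header declares ", n_areas, " areas; state space has ", length(space$areas))
  if (!identical(nm, space$areas))
    stop("area names/order in header do not match the state space")
  body <- lines[-1]
  if (length(body) != n_taxa)
    stop("header declares ", n_taxa, " taxa but file has ", length(body), " rows")
  parts <- strsplit(trimws(body), "\\s+")
  taxa <- vapply(parts, `[`, "", 1L)
  bits <- vapply(parts, `[`, "", 2L)
  if (anyDuplicated(taxa)) stop("duplicate taxon labels in geography file")
  states <- vapply(bits, function(b) bits_to_range(space, b), 0L, USE.NAMES = FALSE)
  if (any(lengths(space$sets[states]) == 0L))
    stop("taxon coded with the all-zero (null) range: ",
         paste(taxa[lengths(space$sets[states]) == 0L], collapse = ", "))
  geography(stats::setNames(states, taxa), space)
}

#' Construct a geography object
#'
#' @param states Named integer vector of state indices (names are taxa), or a
#'   named list of character vectors of area names.
#' @param space The `state_space`.
#' @return A `geography` object.
#' @export
geography <- function(states, space) {
  if (is.list(states))
    states <- vapply(states, function(a) range_index(space, a), 0L)
  states <- vapply(states, as.integer, 0L)
  if (is.null(names(states)) || anyDuplicated(names(states)))
    stop("states must be uniquely named by taxon")
  if (any(states < 1L | states > space$n_states)) stop("state index out of range")
  if (any(lengths(space$sets[states]) == 0L)) stop("tips may not carry the null range")
  structure(states, space = space, class = "geography")
}

#' @export
print.geography <- function(x, ...) {
  sp <- attr(x, "space")
  cat("Tip geography:", length(x), "taxa over", length(sp$areas), "areas\n")
  lab <- sp$labels[as.integer(x)]
  for (i in seq_along(x)) cat(sprintf("  %-28s %s\n", names(x)[i], lab[i]))
  invisible(x)
}

#' Write a tip-geography file
#'
#' Writes the same Lagrange/PHYLIP-style dialect accepted by
#' [read_geography()].
#'
#' @param geo A `geography` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_geography <- function(geo, path) {
  sp <- attr(geo, "space")
  hdr <- sprintf("%d %d (%s)", length(geo), length(sp$areas),
                 paste(sp$areas, collapse = " "))
  rows <- vapply(seq_along(geo), function(i)
    paste(names(geo)[i], range_to_bits(sp, geo[[i]])), "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read geography from CSV
#'
#' Two-column CSV `taxon,areas` where `areas` holds comma-separated area
#' names (quoted).  Equivalent to the presence-absence dialect.
#'
#' @inheritParams read_geography
#' @return A `geography` object.
#' @export
read_geography_csv <- function(path, space) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "areas") %in% names(df)))
    stop("CSV must have columns 'taxon' and 'areas'")
  sets <- lapply(strsplit(df$areas, ","), trimws)
  geography(stats::setNames(lapply(sets, identity), df$taxon), space)
}

#' @rdname read_geography_csv
#' @param geo A `geography` object.
#' @export
write_geography_csv <- function(geo, path) {
  sp <- attr(geo, "space")
  areas <- vapply(as.integer(geo), function(i)
    paste(sp$areas[sp$sets[[i]]], collapse = ","), "")
  utils::write.csv(data.frame(taxon = names(geo), areas = areas),
                   path, row.names = FALSE)
  invisible(path)
}
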