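#' Validate an ultrametric chronogram
#'
#' Checks that a tree is rooted, strictly bifurcating, has nonnegative branch
#' lengths, and is ultrametric (all root-to-tip path lengths equal within
#' `tol * root_age`).  Branch lengths are interpreted as time in millions of
#' years; node ages (mya before present, tips at 0) are attached.
#'
#' @param phy An [ape::phylo] tree with branch lengths.
#' @param tol Relative ultrametricity tolerance; the default `1e-6` (of the
#'   root age) absorbs decimal rounding of printed node ages.
#' @return `phy`, with attribute `node_ages`: numeric vector of ages indexed
#'   by ape node number (tips `1..n`, then internal nodes).
#' @export
as_chronogram <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape 'phylo' tree")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy))
    stop("tree contains polytomies; the cladogenesis model is defined for bifurcating trees")
  depth <- ape::node.depth.edgelength(phy)      # root-to-node path lengths
  n <- ape::Ntip(phy)
  root_age <- max(depth[seq_len(n)])
  if (root_age <= 0) stop("tree has zero depth")
  if (max(depth[seq_len(n)]) - min(depth[seq_len(n)]) > tol * root_age)
    stop("tree is not ultrametric within tolerance ",
         format(tol * root_age), " my")
  ages <- root_age - depth
  ages[seq_len(n)] <- 0                          # snap rounded tip ages to 0
  attr(phy, "node_ages") <- ages
  phy
}

#' Read and validate a chronogram from a Newick file or string
#'
#' @param x Path to a Newick file, or a Newick string (containing `";"`).
#' @inheritParams as_chronogram
#' @return A validated `phylo` with node ages (see [as_chronogram()]).
#' @export
read_chronogram <- function(x, tol = 1e-6) {
  phy <- if (grepl(";", x, fixed = TRUE)) ape::read.tree(text = x) else ape::read.tree(x)
  if (is.null(phy)) stop("could not parse Newick input")
  as_chronogram(phy, tol = tol)
}

#' Node ages of a chronogram
#'
#' @param phy A tree validated by [as_chronogram()] (ages are recomputed if
#'   the attribute is absent).
#' @return Numeric vector of ages in mya, indexed by ape node number.
#' @export
node_ages <- function(phy) {
  a <- attr(phy, "node_ages")
  if (is.null(a)) a <- attr(as_chronogram(phy), "node_ages")
  a
}

#' Cut a branch into per-stratum segments
#'
#' Splits the time interval covered by one branch at stratum boundary ages.
#' Strata are half-open in age, `[lower, upper)`, so a boundary age belongs to
#' the stratum whose lower bound it is; zero-length segments are never
#' produced.  Segments are returned rootward to tipward.
#'
#' @param parent_age,child_age Ages (mya) of the branch ends,
#'   `parent_age > child_age >= 0`.
#' @param boundaries Strictly increasing interior boundary ages (mya); the
#'   implied strata are `[0,b1), [b1,b2), ...` with an oldest bound given by
#'   `oldest`.
#' @param oldest Age (mya) of the top of the oldest stratum; branches may not
#'   extend beyond it.
#' @return A data frame with columns `older_age`, `younger_age`,
#'   `stratum` (1 = youngest stratum).
#' @examples
#' slice_branch(25, 1, c(3, 20, 30, 40))
#' @export
slice_branch <- function(parent_age, child_age, boundaries, oldest = 120) {
  if (!(parent_age > child_age) || child_age < 0)
    stop("need parent_age > child_age >= 0")
  if (length(boundaries) && any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing")
  if (parent_age > oldest)
    stop("branch extends beyond the oldest stratum bound (", oldest, " mya)")
  cuts <- boundaries[boundaries > child_age & boundaries < parent_age]
  pts <- c(parent_age, rev(cuts), child_age)
  lower <- c(0, boundaries)
  data.frame(older_age = pts[-length(pts)],
             younger_age = pts[-1],
             stratum = findInterval(pts[-1], lower))
}

#' Write a chronogram to Newick
#'
#' @param phy A `phylo`.
#' @param path Output path.
#' @export
write_chronogram <- function(phy, path) {
  ape::write.tree(phy, file = path, digits = 12)
  invisible(path)
}
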