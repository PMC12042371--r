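#' Anagenetic rate matrix for the DEC-family process
#'
#' Builds the generator of range evolution along branches shared by DEC,
#' DIVALIKE and BAYAREALIKE.  For a range `R` and an area `k` not in `R`
#' (with `|R| <` max range size), the gain rate is
#' `d * sum_{a in R} m[a, k]` where `m` is the dispersal-multiplier matrix of
#' the stratum; each occupied area is lost at rate `e` (extirpation is not
#' scenario-modified).  The null range is absorbing: a lineage that loses its
#' last area is extinct.
#'
#' @param space A [build_state_space()] object.
#' @param d Dispersal (area-gain) rate, events per lineage-my.
#' @param e Extirpation (area-loss) rate, events per lineage-my.
#' @param multipliers Area-by-area nonnegative multiplier matrix (defaults to
#'   all ones).
#' @return Square rate matrix over the states (rows sum to zero), with state
#'   labels as dimnames.
#' @export
build_rate_matrix <- function(space, d, e, multipliers = NULL) {
  n_areas <- length(space$areas)
  if (is.null(multipliers))
    multipliers <- matrix(1, n_areas, n_areas)
  if (!all(dim(multipliers) == n_areas))
    stop("multiplier matrix must be ", n_areas, "x", n_areas)
  if (any(multipliers < 0)) stop("multipliers must be nonnegative")
  if (d < 0 || e < 0) stop("rates must be nonnegative")
  S <- space$n_states
  key <- vapply(space$sets, paste, "", collapse = ",")
  idx <- function(set) match(paste(set, collapse = ","), key)
  Q <- matrix(0, S, S, dimnames = list(space$labels, space$labels))
  for (i in seq_len(S)) {
    R <- space$sets[[i]]
    if (length(R) == 0L) next                     # null range absorbing
    if (length(R) < space$max_range_size) {
      for (k in setdiff(seq_len(n_areas), R)) {
        j <- idx(sort(c(R, k)))
        Q[i, j] <- Q[i, j] + d * sum(multipliers[R, k])
      }
    }
    for (a in R) {
      j <- idx(setdiff(R, a))
      Q[i, j] <- Q[i, j] + e
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

model_bases <- c("DEC", "DIVALIKE", "BAYAREALIKE")

#' Parse a model label such as `"DIVALIKE+J"`
#'
#' @param model Character label: one of `DEC`, `DIVALIKE`, `BAYAREALIKE`,
#'   optionally suffixed with `+J`.
#' @return List with `base` and logical `with_j`.
#' @export
parse_model <- function(model) {
  with_j <- grepl("\\+J$", model)
  base <- sub("\\+J$", "", model)
  base <- match.arg(base, model_bases)
  list(base = base, with_j = with_j)
}

#' Cladogenetic event table
#'
#' Enumerates the ordered daughter-range pairs allowed at a speciation node
#' for each ancestral range, with their probabilities.  Event classes and
#' per-base weights (the referenced-framework convention, all fixed at 1):
#' \itemize{
#'   \item narrow sympatry `(A, A)` for single-area ancestors -- all bases;
#'   \item range copy `(R, R)` for widespread ancestors -- BAYAREALIKE only;
#'   \item subset sympatry `(R, A)` / `(A, R)`, `A` in `R` -- DEC only;
#'   \item vicariance: ordered bipartitions of `R`; DEC requires one daughter
#'     to be a single area, DIVALIKE allows any bipartition -- not BAYAREALIKE;
#'   \item founder-event jump `(R, {k})` / `({k}, R)`, `k` outside `R`,
#'     weight `j` (present only when `j > 0`).
#' }
#' Probabilities are the event weights normalized per ancestor.  The null
#' range has no events.
#'
#' @param space A `state_space`.
#' @param base One of `"DEC"`, `"DIVALIKE"`, `"BAYAREALIKE"`.
#' @param j Founder-event weight in `[0, 3]`; 0 disables jumps and reproduces
#'   the base model exactly.
#' @return A `clado_table`: list with integer vectors `anc`, `left`, `right`
#'   and numeric `prob` (rows grouped by ancestor, probabilities summing to 1
#'   per ancestor), plus `base`, `j`, `n_states`.
#' @export
cladogenesis_table <- function(space, base, j = 0) {
  base <- match.arg(base, model_bases)
  clado_with_j(clado_proto(space, base), j)
}

# full event structure with unit base weights and jump events flagged; the
# per-j table is a cheap reweighting of this (j varies at every optimizer
# step for +J fits)
clado_proto <- function(space, base) {
  key <- vapply(space$sets, paste, "", collapse = ",")
  idx <- function(set) match(paste(sort(set), collapse = ","), key)
  n_areas <- length(space$areas)
  anc <- left <- right <- integer(0); jump <- logical(0)
  push <- function(a, l, r, jp) {
    anc <<- c(anc, a); left <<- c(left, l); right <<- c(right, r)
    jump <<- c(jump, jp)
  }
  for (i in seq_len(space$n_states)) {
    R <- space$sets[[i]]
    sz <- length(R)
    if (sz == 0L) next
    if (sz == 1L) {
      push(i, i, i, FALSE)                              # narrow sympatry
    } else {
      if (base == "BAYAREALIKE") push(i, i, i, FALSE)   # range copy
      if (base == "DEC")
        for (a in R) {
          ai <- idx(a)
          push(i, i, ai, FALSE); push(i, ai, i, FALSE)  # subset sympatry
        }
      if (base %in% c("DEC", "DIVALIKE")) {             # vicariance
        for (m in seq_len(floor(sz / 2))) {
          halves <- utils::combn(R, m, simplify = FALSE)
          for (h in halves) {
            rest <- setdiff(R, h)
            if (base == "DEC" && min(length(h), length(rest)) != 1L) next
            li <- idx(h); ri <- idx(rest)
            push(i, li, ri, FALSE); push(i, ri, li, FALSE)
          }
        }
      }
    }
    for (k in setdiff(seq_len(n_areas), R)) {
      ki <- idx(k)
      push(i, i, ki, TRUE); push(i, ki, i, TRUE)        # founder-event jump
    }
  }
  # when a bipartition has equal halves, combn enumerates it from both sides,
  # so the ordered rows are pushed twice; drop the duplicates
  keep <- !duplicated(paste(anc, left, right, jump))
  list(anc = anc[keep], left = left[keep], right = right[keep],
       jump = jump[keep], base = base, n_states = space$n_states)
}

clado_with_j <- function(proto, j) {
  if (j < 0 || j > 3) stop("j must lie in [0, 3]")
  w <- ifelse(proto$jump, j, 1)
  keep <- w > 0
  anc <- proto$anc[keep]; w <- w[keep]
  tot <- vapply(split(w, anc), sum, 0)
  prob <- unname(w / tot[as.character(anc)])
  structure(list(anc = anc, left = proto$left[keep],
                 right = proto$right[keep], prob = prob,
                 base = proto$base, j = j, n_states = proto$n_states),
            class = "clado_table")
}

#' @export
print.clado_table <- function(x, ...) {
  cat("Cladogenesis table:", x$base,
      if (x$j > 0) sprintf("+J (j = %g)", x$j) else "",
      "-", length(x$anc), "events over", x$n_states, "states\n")
  invisible(x)
}

#' Transition probability matrix over a time interval
#'
#' `exp(Q * dt)`, with tiny negative entries from roundoff clipped to zero and
#' rows renormalized to sum to one.
#'
#' @param Q Rate matrix from [build_rate_matrix()].
#' @param dt Duration in my (`>= 0`).
#' @return Stochastic matrix of the same dimension.
#' @export
transition_matrix <- function(Q, dt) {
  if (dt < 0) stop("dt must be nonnegative")
  if (dt == 0) return(diag(nrow(Q)))
  P <- as.matrix(Matrix::expm(Q * dt))
  P[P < 0] <- 0
  P / rowSums(P)
}

# Transition matrices for many durations from one generator.
# Primary path: eigendecomposition of Q, so each extra duration costs two
# dense multiplies; falls back to expm() per duration when Q is close to
# defective (reconstruction check on the longest interval).
transition_set <- function(Q, dts) {
  S <- nrow(Q)
  out <- vector("list", length(dts))
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      tmax <- max(dts)
      Pm <- eg$vectors %*% (exp(eg$values * tmax) * Vi)
      Pref <- as.matrix(Matrix::expm(Q * tmax))
      if (max(abs(Re(Pm) - Pref)) < 1e-9) use_eigen <- TRUE
    }
  }
  for (i in seq_along(dts)) {
    P <- if (dts[i] == 0) diag(S)
         else if (use_eigen) Re(eg$vectors %*% (exp(eg$values * dts[i]) * Vi))
         else as.matrix(Matrix::expm(Q * dts[i]))
    P[P < 0] <- 0
    out[[i]] <- P / rowSums(P)
  }
  out
}
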