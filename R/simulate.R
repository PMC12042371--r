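# run expr under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a Yule (pure-birth) chronogram
#'
#' Forward simulation conditioned on the number of tips: starting from the
#' root split (two lineages), each epoch with `k` lineages lasts an
#' exponential time with rate `lambda * k` and ends with a uniformly chosen
#' lineage splitting; after the `n`-th lineage appears one final epoch runs
#' to the present.  The expected root age is `sum_{k=2..n} 1/(lambda k)`.
#' Deterministic for a fixed seed.
#'
#' @param n_tips Number of tips (`>= 2`).
#' @param birth_rate Speciation rate `lambda` (per lineage per my).
#' @param seed Integer seed.
#' @return An ultrametric `phylo` with tips `t1..tn`, validated by
#'   [as_chronogram()].
#' @export
simulate_yule_tree <- function(n_tips, birth_rate, seed = 1) {
  n_tips <- as.integer(n_tips)
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  with_seed(seed, {
    recs <- list(list(birth = 0, split = NA_real_, kids = NULL),
                 list(birth = 0, split = NA_real_, kids = NULL))
    active <- c(1L, 2L)
    t <- 0
    for (k in 2:n_tips) {
      t <- t + stats::rexp(1L, rate = birth_rate * k)
      if (k == n_tips) break
      i <- active[sample.int(length(active), 1L)]
      recs[[i]]$split <- t
      recs[[length(recs) + 1L]] <- list(birth = t, split = NA_real_, kids = NULL)
      recs[[length(recs) + 1L]] <- list(birth = t, split = NA_real_, kids = NULL)
      recs[[i]]$kids <- c(length(recs) - 1L, length(recs))
      active <- c(setdiff(active, i), recs[[i]]$kids)
    }
    H <- t
    counter <- 0L
    emit <- function(i) {
      r <- recs[[i]]
      len <- (if (is.null(r$kids)) H else r$split) - r$birth
      if (is.null(r$kids)) {
        counter <<- counter + 1L
        sprintf("t%d:%.12g", counter, len)
      } else {
        sprintf("(%s,%s):%.12g", emit(r$kids[1]), emit(r$kids[2]), len)
      }
    }
    nwk <- sprintf("(%s,%s);", emit(1L), emit(2L))
    as_chronogram(ape::read.tree(text = nwk), tol = 1e-4)
  })
}

#' Forward-simulate range evolution on a chronogram
#'
#' Gillespie simulation of the anagenetic process along every branch (one
#' rate matrix per time stratum, switching at stratum boundaries) with one
#' cladogenetic event drawn from the model's event table at every internal
#' node.  A lineage that loses its last area is extinct; datasets with any
#' extinct tip are rejected and resimulated with an incremented seed, and
#' the rejection count is reported so conditioning bias stays visible.
#'
#' @param tree Ultrametric `phylo`.
#' @param model Model label (see [parse_model()]).
#' @param scenario A `dispersal_scenario`, or `NULL` for an unstratified null
#'   scenario spanning the tree.
#' @param d,e,j Process parameters.
#' @param space A `state_space`; its areas must match the scenario's.
#' @param root_range Character vector of area names (or integer indices) for
#'   the root state; must be non-null.
#' @param seed Integer seed.
#' @param max_tries Maximum consecutive rejected datasets.
#' @return Object of class `biogeo_sim`: list with `tree`, `geography`
#'   (tips), `node_states` (state index at each internal node immediately
#'   before cladogenesis), `event_log` (data frame: `age`, `edge`, `kind`,
#'   `from`, `to` as state indices), `seed` (the accepted seed),
#'   `rejections`.
#' @export
simulate_ranges <- function(tree, model = "DEC", scenario = NULL, d, e, j = 0,
                            space, root_range, seed = 1, max_tries = 1000L) {
  tree <- as_chronogram(tree)
  if (is.null(scenario)) scenario <- null_scenario_for(tree, space)
  ms <- parse_model(model)
  clado <- cladogenesis_table(space, ms$base, if (ms$with_j) j else 0)
  root_state <- range_index(space, root_range)
  if (root_state == 1L) stop("root_range must not be the null range")
  ages <- node_ages(tree)
  n <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  edges_pre <- rev(seq_len(nrow(po$edge)))       # preorder edge sweep
  strata <- scenario$strata
  Qs <- lapply(scenario$multipliers, function(m) build_rate_matrix(space, d, e, m))
  clado_by_anc <- split(seq_along(clado$anc), clado$anc)
  for (try in seq_len(max_tries)) {
    res <- with_seed(seed, {
      state <- integer(n + tree$Nnode)           # state at node (before clado)
      top_state <- integer(nrow(po$edge))        # state at top of each edge
      state[n + 1L] <- root_state
      log_age <- numeric(0)
      log_edge <- log_from <- log_to <- integer(0)
      log_kind <- character(0)
      note <- function(a, ed, k, f, t) {
        log_age <<- c(log_age, a); log_edge <<- c(log_edge, ed)
        log_kind <<- c(log_kind, k); log_from <<- c(log_from, f)
        log_to <<- c(log_to, t)
      }
      extinct <- FALSE
      # draw clado events at internal nodes in preorder, then evolve edges
      node_done <- logical(n + tree$Nnode)
      for (ei in edges_pre) {
        p <- po$edge[ei, 1L]; ch <- po$edge[ei, 2L]
        if (!node_done[p]) {
          node_done[p] <- TRUE
          s <- state[p]
          if (s == 1L) {                         # extinct before splitting
            kids <- which(po$edge[, 1L] == p)
            top_state[kids] <- 1L
          } else {
            rows <- clado_by_anc[[as.character(s)]]
            ev <- rows[sample.int(length(rows), 1L,
                                  prob = clado$prob[rows])]
            kids <- which(po$edge[, 1L] == p)
            top_state[kids[1L]] <- clado$left[ev]
            top_state[kids[2L]] <- clado$right[ev]
            note(ages[p], kids[1L], "cladogenesis", s, clado$left[ev])
            note(ages[p], kids[2L], "cladogenesis", s, clado$right[ev])
          }
        }
        # anagenesis along edge ei from ages[p] down to ages[ch]
        s <- top_state[ei]
        t_now <- ages[p]
        t_end <- ages[ch]
        while (s != 1L && t_now > t_end) {
          st <- findInterval(t_now, strata$younger_bound)
          seg_end <- max(t_end, strata$younger_bound[st])
          # t_now sitting exactly on a lower bound belongs to that stratum,
          # but evolution continues below it in the next (younger) one
          if (seg_end == t_now) {
            st <- st - 1L
            seg_end <- max(t_end, strata$younger_bound[st])
          }
          Q <- Qs[[st]]
          repeat {
            rate <- -Q[s, s]
            if (rate <= 0) { t_now <- seg_end; break }
            dt <- stats::rexp(1L, rate)
            if (t_now - dt <= seg_end) { t_now <- seg_end; break }
            t_now <- t_now - dt
            probs <- Q[s, ]; probs[s] <- 0
            s_new <- sample.int(length(probs), 1L, prob = probs)
            kind <- if (s_new == 1L) "extinction"
                    else if (length(space$sets[[s_new]]) > length(space$sets[[s]]))
                      "dispersal" else "extirpation"
            note(t_now, ei, kind, s, s_new)
            s <- s_new
            if (s == 1L) break
          }
        }
        state[ch] <- s
        if (ch <= n && s == 1L) extinct <- TRUE
      }
      list(extinct = extinct, state = state,
           log = data.frame(age = log_age, edge = log_edge, kind = log_kind,
                            from = log_from, to = log_to))
    })
    if (!res$extinct) {
      geo <- geography(stats::setNames(res$state[seq_len(n)], po$tip.label), space)
      node_states <- stats::setNames(res$state[(n + 1L):(n + tree$Nnode)],
                                     (n + 1L):(n + tree$Nnode))
      out <- list(tree = tree, edge = po$edge, geography = geo,
                  node_states = node_states, event_log = res$log,
                  seed = seed, rejections = try - 1L)
      class(out) <- "biogeo_sim"
      return(out)
    }
    seed <- seed + 1L
  }
  stop("simulation rejected ", max_tries,
       " consecutive datasets (parameters too extinction-prone)")
}

#' @export
print.biogeo_sim <- function(x, ...) {
  cat("Simulated biogeographic dataset:", ape::Ntip(x$tree), "tips,",
      nrow(x$event_log), "logged events, seed", x$seed, "\n")
  if (x$rejections > 0)
    cat("  (", x$rejections, " extinct datasets rejected before acceptance)\n", sep = "")
  invisible(x)
}

#' Replay an event log to recover tip states
#'
#' Deterministically replays a simulation's event log from the root range,
#' returning the implied state at every node; used to verify simulator
#' consistency.
#'
#' @param sim A `biogeo_sim`.
#' @return Integer vector of state indices per node (ape numbering).
#' @export
replay_events <- function(sim) {
  n <- ape::Ntip(sim$tree)
  state <- integer(n + sim$tree$Nnode)
  state[n + 1L] <- sim$node_states[1L]
  log <- sim$event_log
  top <- integer(nrow(sim$edge))
  for (ei in rev(seq_len(nrow(sim$edge)))) {     # preorder
    ev <- log[log$edge == ei, , drop = FALSE]
    cl <- ev[ev$kind == "cladogenesis", , drop = FALSE]
    s <- if (nrow(cl)) cl$to[1L] else state[sim$edge[ei, 1L]]
    an <- ev[ev$kind != "cladogenesis", , drop = FALSE]
    if (nrow(an)) {
      an <- an[order(-an$age), , drop = FALSE]
      for (r in seq_len(nrow(an))) {
        stopifnot(an$from[r] == s)
        s <- an$to[r]
      }
    }
    state[sim$edge[ei, 2L]] <- s
  }
  state
}

#' Lineage-time spent in a state within an age window
#'
#' Reconstructs the piecewise-constant state path of every branch from a
#' simulation's event log and accumulates the total lineage-time spent in
#' `state` between ages `lo` (younger) and `hi` (older).  Useful for
#' normalizing event counts into per-lineage-my rates, e.g. when checking
#' realized dispersal frequencies against stratum multipliers.
#'
#' @param sim A `biogeo_sim`.
#' @param state Integer state index.
#' @param lo,hi Age window in mya, `lo < hi`.
#' @return Total lineage-time (my).
#' @export
state_occupancy <- function(sim, state, lo, hi) {
  ages <- node_ages(sim$tree)
  log <- sim$event_log
  tot <- 0
  for (ei in seq_len(nrow(sim$edge))) {
    pa <- ages[sim$edge[ei, 1L]]; pb <- ages[sim$edge[ei, 2L]]
    ev <- log[log$edge == ei, , drop = FALSE]
    cl <- ev[ev$kind == "cladogenesis", , drop = FALSE]
    s <- if (nrow(cl)) cl$to[1L] else
      sim$node_states[[as.character(sim$edge[ei, 1L])]]
    an <- ev[ev$kind != "cladogenesis", , drop = FALSE]
    an <- an[order(-an$age), , drop = FALSE]
    piece_hi <- c(pa, an$age); piece_lo <- c(an$age, pb)
    keep <- c(s, an$to) == state
    tot <- tot + sum(pmax(0, pmin(piece_hi[keep], hi) -
                            pmax(piece_lo[keep], lo)))
  }
  tot
}

#' Parameter-recovery experiment
#'
#' Simulates replicate datasets (Yule tree + range evolution) under known
#' parameters and refits the model to each, reporting per-replicate truth
#' and estimates with relative errors.
#'
#' @param replicates Number of replicates.
#' @param n_tips Tips per replicate tree.
#' @param d,e,j True parameter values.
#' @param model Model label used both to simulate and to fit.
#' @param space State space for the simulation.
#' @param root_range Root range (area names).
#' @param birth_rate Yule speciation rate.
#' @param seed Base seed; replicate `i` derives seeds `seed + 2i` (tree) and
#'   `seed + 2i + 1` (ranges).
#' @return Data frame (one row per replicate) with true and estimated
#'   parameters, relative error of `d`, lnL and convergence flag; the median
#'   relative errors are attached as attribute `summary`.
#' @export
recovery_experiment <- function(replicates, n_tips, d, e, j = 0,
                                model = "DEC", space, root_range,
                                birth_rate = 0.2, seed = 1) {
  rows <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    row <- tryCatch({
      tr <- simulate_yule_tree(n_tips, birth_rate, seed = seed + 2L * i)
      sim <- simulate_ranges(tr, model = model, d = d, e = e, j = j,
                             space = space, root_range = root_range,
                             seed = seed + 2L * i + 1L)
      fit <- fit_biogeo(tr, sim$geography, model = model)
      data.frame(rep = i, true_d = d, true_e = e, true_j = j,
                 est_d = unname(fit$params["d"]), est_e = unname(fit$params["e"]),
                 est_j = unname(fit$params["j"]), lnL = fit$lnL,
                 rel_err_d = abs(fit$params[["d"]] - d) / d,
                 converged = fit$converged, error = NA_character_)
    }, error = function(err)
      data.frame(rep = i, true_d = d, true_e = e, true_j = j,
                 est_d = NA_real_, est_e = NA_real_, est_j = NA_real_,
                 lnL = NA_real_, rel_err_d = NA_real_, converged = FALSE,
                 error = conditionMessage(err)))
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(
    median_rel_err_d = stats::median(out$rel_err_d, na.rm = TRUE),
    median_est_j = stats::median(out$est_j, na.rm = TRUE))
  out
}
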