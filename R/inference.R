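# Likelihood engine ----------------------------------------------------------
#
# The pruning data structure is computed once per (tree, scenario): postorder
# edge traversal, per-edge branch segments cut at stratum boundaries, tip
# state indicators.  Each likelihood evaluation then builds one rate matrix
# per stratum, turns every segment into a transition matrix (shared
# eigendecomposition per stratum; see transition_set), chains segments along
# each branch, and runs Felsenstein pruning with the cladogenetic event table
# applied at each internal node.  Conditional-likelihood vectors are
# renormalized at every node with accumulated log factors so that 56-state
# vectors do not underflow on deep trees.

build_pruning_data <- function(tree, geo, scenario) {
  space <- attr(geo, "space")
  ages <- node_ages(tree)
  n <- ape::Ntip(tree)
  tipmap <- match(tree$tip.label, names(geo))
  if (anyNA(tipmap))
    stop("tips missing from geography: ",
         paste(tree$tip.label[is.na(tipmap)], collapse = ", "))
  bounds <- scenario$strata
  oldest <- bounds$older_bound[nrow(bounds)]
  interior <- bounds$younger_bound[-1]
  if (ages[n + 1L] > oldest)
    stop("tree root age ", signif(ages[n + 1L], 6),
         " exceeds the scenario span (", oldest, " mya)")
  po <- ape::reorder.phylo(tree, "postorder")
  segs <- lapply(seq_len(nrow(po$edge)), function(i) {
    p <- po$edge[i, 1L]; c0 <- po$edge[i, 2L]
    if (ages[p] <= ages[c0]) {
      # zero-length branch: identity propagation in the child's stratum
      data.frame(older_age = ages[p], younger_age = ages[c0],
                 stratum = findInterval(ages[c0], bounds$younger_bound))
    } else slice_branch(ages[p], ages[c0], interior, oldest = oldest)
  })
  list(space = space, scenario = scenario, edge = po$edge,
       n_tip = n, root = n + 1L, n_node = tree$Nnode,
       tip_state = as.integer(geo)[tipmap], segs = segs, ages = ages)
}

# per-evaluation transition matrices for every edge
edge_transitions <- function(pd, d, e) {
  S <- pd$space$n_states
  n_strat <- nrow(pd$scenario$strata)
  # gather segment durations per stratum
  all_seg <- do.call(rbind, lapply(seq_along(pd$segs), function(i)
    cbind(edge = i, pd$segs[[i]])))
  all_seg$dt <- all_seg$older_age - all_seg$younger_age
  Pseg <- vector("list", nrow(all_seg))
  for (s in seq_len(n_strat)) {
    rows <- which(all_seg$stratum == s)
    if (!length(rows)) next
    Q <- build_rate_matrix(pd$space, d, e, pd$scenario$multipliers[[s]])
    dts <- all_seg$dt[rows]
    u <- sort(unique(dts))
    Pu <- transition_set(Q, u)
    Pseg[rows] <- Pu[match(dts, u)]
  }
  # chain segments per edge, rootward first (rows = older state)
  Pe <- vector("list", length(pd$segs))
  for (i in seq_along(pd$segs)) {
    rows <- which(all_seg$edge == i)            # already rootward->tipward
    P <- Pseg[[rows[1L]]]
    for (r in rows[-1L]) P <- P %*% Pseg[[r]]
    Pe[[i]] <- P
  }
  Pe
}

# downpass; returns per-node normalized conditional likelihoods, log scalers,
# and per-edge W vectors (branch-top likelihoods) for reuse in the uppass
prune_down <- function(pd, clado, Pe) {
  S <- pd$space$n_states
  n <- pd$n_tip
  CL <- matrix(0, n + pd$n_node, S)
  logscale <- 0
  for (i in seq_len(n)) CL[i, pd$tip_state[i]] <- 1
  W <- matrix(NA_real_, nrow(pd$edge), S)
  child_edges <- split(seq_len(nrow(pd$edge)), pd$edge[, 1L])
  # postorder edges: process each internal node when both child edges seen
  anc <- clado$anc; lf <- clado$left; rg <- clado$right; pr <- clado$prob
  nodes <- unique(pd$edge[, 1L])                 # postorder parents
  for (v in nodes) {
    es <- child_edges[[as.character(v)]]
    for (ei in es) {
      ch <- pd$edge[ei, 2L]
      W[ei, ] <- Pe[[ei]] %*% CL[ch, ]
    }
    wv <- pr * W[es[1L], lf] * W[es[2L], rg]
    cl <- numeric(S)
    agg <- rowsum(wv, anc)
    cl[as.integer(rownames(agg))] <- agg
    f <- sum(cl)
    if (!is.finite(f) || f <= 0) return(NULL)    # impossible data
    CL[v, ] <- cl / f
    logscale <- logscale + log(f)
  }
  list(CL = CL, W = W, logscale = logscale)
}

engine_loglik <- function(pd, clado, d, e, root_prior) {
  Pe <- edge_transitions(pd, d, e)
  dn <- prune_down(pd, clado, Pe)
  if (is.null(dn)) return(-Inf)
  lik <- sum(root_prior * dn$CL[pd$root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + dn$logscale
}

default_root_prior <- function(space) {
  pi <- c(0, rep(1 / (space$n_states - 1), space$n_states - 1L))
  pi
}

#' Log-likelihood of tip geography under a stratified DEC-family model
#'
#' Felsenstein pruning over the range state space: tip vectors are indicators
#' of the observed ranges; conditional likelihoods are propagated along each
#' branch through the product of per-segment transition matrices (segments
#' cut at stratum boundaries, each using its stratum's dispersal multipliers)
#' and combined at each internal node through the cladogenetic event table.
#' The root sums over a prior that is uniform over non-null ranges by
#' default.
#'
#' @param tree Ultrametric `phylo` (validated via [as_chronogram()]).
#' @param geo A [geography()] covering all tips.
#' @param model Model label, e.g. `"DEC"`, `"DIVALIKE+J"`.
#' @param scenario A [build_scenario()] object; `NULL` means an unstratified
#'   null scenario (all multipliers 1) spanning the tree.
#' @param d,e,j Parameter values (see [build_rate_matrix()] and
#'   [cladogenesis_table()]).
#' @param root_prior Optional probability vector over states.
#' @return Log-likelihood (`-Inf` when the data have probability zero).
#' @export
biogeo_loglik <- function(tree, geo, model = "DEC", scenario = NULL,
                          d, e, j = 0, root_prior = NULL) {
  tree <- as_chronogram(tree)
  space <- attr(geo, "space")
  if (is.null(scenario)) scenario <- null_scenario_for(tree, space)
  ms <- parse_model(model)
  if (!ms$with_j && j != 0) stop("model without +J requires j = 0")
  pd <- build_pruning_data(tree, geo, scenario)
  clado <- cladogenesis_table(space, ms$base, j)
  if (is.null(root_prior)) root_prior <- default_root_prior(space)
  engine_loglik(pd, clado, d, e, root_prior)
}

null_scenario_for <- function(tree, space) {
  root_age <- max(node_ages(tree))
  build_scenario("null", space$areas,
                 strata = make_strata(c(0, root_age * (1 + 1e-8) + 1e-9)))
}

# Model fitting ---------------------------------------------------------------

#' Fit a DEC-family biogeographic model by maximum likelihood
#'
#' Maximizes the stratified pruning likelihood over `d`, `e` (and `j` for +J
#' models) with bounded quasi-Newton (`L-BFGS-B` on log10-transformed
#' parameters) from three deterministic starts, so fits are reproducible
#' without random seeds.  Bounds: `d, e` in `[1e-12, 5]` events/lineage-my,
#' `j` in `[1e-5, 3]`.
#'
#' @inheritParams biogeo_loglik
#' @param starts Matrix of starting values (columns `d`, `e`, and `j` for +J
#'   models); the default three rows are `d = e` in `{1e-3, 1e-2, 1e-1}`
#'   crossed with `j` in `{1e-4, 0.5, 2}`.
#' @param control Passed to [stats::optim()] (merged over defaults).
#' @return Object of class `biogeo_fit`: list with `model`, `scenario_name`,
#'   `params` (named vector `d`, `e`, `j`), `lnL`, `k` (free parameters),
#'   `n` (tips), `AICc`, `converged`, plus the inputs needed by methods.
#' @seealso [logLik.biogeo_fit()], [predict.biogeo_fit()],
#'   [simulate.biogeo_fit()], [run_model_grid()]
#' @export
fit_biogeo <- function(tree, geo, model = "DEC", scenario = NULL,
                       root_prior = NULL, starts = NULL, control = list()) {
  tree <- as_chronogram(tree)
  space <- attr(geo, "space")
  if (is.null(scenario)) scenario <- null_scenario_for(tree, space)
  ms <- parse_model(model)
  pd <- build_pruning_data(tree, geo, scenario)
  if (is.null(root_prior)) root_prior <- default_root_prior(space)
  k <- if (ms$with_j) 3L else 2L
  if (is.null(starts)) {
    starts <- cbind(d = c(1e-3, 1e-2, 1e-1), e = c(1e-3, 1e-2, 1e-1))
    if (ms$with_j) starts <- cbind(starts, j = c(1e-4, 0.5, 2))
  }
  lower <- c(-12, -12, -5)[seq_len(k)]
  upper <- c(log10(5), log10(5), log10(3))[seq_len(k)]
  ctl <- utils::modifyList(list(maxit = 300L, factr = 1e7), control)
  proto <- clado_proto(space, ms$base)
  nll <- function(lp) {
    p <- 10^lp
    ll <- engine_loglik(pd, clado_with_j(proto, if (k == 3L) p[3] else 0),
                        p[1], p[2], root_prior)
    if (!is.finite(ll)) 1e10 else -ll
  }
  best <- NULL
  conv <- FALSE
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(log10(starts[r, seq_len(k)]), nll, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = ctl),
      error = function(err) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      conv <- fit$convergence == 0L
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  j_zero <- FALSE
  if (ms$with_j) {
    # the j lower bound is strictly positive, so the base model sits on the
    # boundary; profile j = 0 explicitly to keep +J exactly nested
    clado0 <- clado_with_j(proto, 0)
    nll0 <- function(lp) {
      p <- 10^lp
      ll <- engine_loglik(pd, clado0, p[1], p[2], root_prior)
      if (!is.finite(ll)) 1e10 else -ll
    }
    for (r in seq_len(nrow(starts))) {
      fit <- tryCatch(
        stats::optim(log10(starts[r, 1:2]), nll0, method = "L-BFGS-B",
                     lower = lower[1:2], upper = upper[1:2], control = ctl),
        error = function(err) NULL)
      if (!is.null(fit) && fit$value < best$value) {
        best <- fit
        conv <- fit$convergence == 0L
        j_zero <- TRUE
      }
    }
  }
  p <- unname(10^best$par)
  params <- c(d = p[1], e = p[2],
              j = if (k == 3L && !j_zero) p[3] else 0)
  lnL <- -best$value
  n <- ape::Ntip(tree)
  structure(list(model = model, scenario_name = scenario$name,
                 params = params, lnL = lnL, k = k, n = n,
                 AICc = aicc(lnL, k, n), converged = conv,
                 tree = tree, geo = geo, scenario = scenario,
                 root_prior = root_prior),
            class = "biogeo_fit")
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)` with `n` the number of tips.
#'
#' @param lnL Log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (tips).
#' @return AICc value.
#' @export
aicc <- function(lnL, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined for n <= k + 1")
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights over a set of fitted models
#'
#' Adds `delta_AICc` and `AICc_wt = exp(-delta/2) / sum(exp(-delta/2))` and
#' sorts ascending by AICc (ties broken by fewer parameters, then model
#' name).
#'
#' @param results Data frame with columns `AICc`, `k`, `model` (e.g. from
#'   [run_model_grid()]), or a list of `biogeo_fit` objects.
#' @return The data frame, sorted, with `delta_AICc` and `AICc_wt` columns.
#' @export
model_weights <- function(results) {
  if (!is.data.frame(results)) results <- grid_table(results)
  ok <- is.finite(results$AICc)
  if (!any(ok)) {
    results$delta_AICc <- NA_real_
    results$AICc_wt <- NA_real_
    return(results)
  }
  delta <- results$AICc - min(results$AICc[ok])
  w <- exp(-delta / 2)
  w[!ok] <- 0
  results$delta_AICc <- delta
  results$AICc_wt <- w / sum(w)
  o <- order(results$AICc, results$k, results$model)
  results <- results[o, , drop = FALSE]
  rownames(results) <- NULL
  results
}

grid_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(scenario = f$scenario_name, model = f$model,
               d = f$params["d"], e = f$params["e"], j = f$params["j"],
               lnL = f$lnL, k = f$k, AICc = f$AICc,
               converged = f$converged, row.names = NULL)))
}

#' The scenario-by-model grid specification
#'
#' @param scenarios,models Labels to cross; defaults give the full
#'   4 x 6 = 24-model grid.
#' @return Data frame with columns `scenario`, `model`, `label`.
#' @export
model_grid_specs <- function(scenarios = scenario_names(),
                             models = c("DEC", "DEC+J", "DIVALIKE",
                                        "DIVALIKE+J", "BAYAREALIKE",
                                        "BAYAREALIKE+J")) {
  g <- expand.grid(model = models, scenario = scenarios,
                   stringsAsFactors = FALSE)[, c("scenario", "model")]
  g$label <- paste(g$scenario, g$model)
  g
}

#' Fit the full scenario-by-model grid
#'
#' Fits every combination of the requested dispersal scenarios with the three
#' cladogenesis bases and their +J variants (4 scenarios x 3 bases x 2 = 24
#' models by default) and ranks them by AICc weight.  Individual model
#' failures are recorded per row; the grid completes.
#'
#' @inheritParams fit_biogeo
#' @param connectivity A [connectivity_spec()]; required for non-null
#'   scenarios.
#' @param scenarios Character vector of scenario names, or a list of
#'   prebuilt `dispersal_scenario` objects.
#' @param models Character vector of model labels.
#' @param strata Strata table used when building named scenarios.
#' @param verbose Print one line per fitted model.
#' @return Object of class `biogeo_grid`: the ranked comparison data frame
#'   (columns scenario, model, d, e, j, lnL, k, AICc, delta_AICc, AICc_wt)
#'   with the list of fits in attribute `fits`.
#' @export
run_model_grid <- function(tree, geo, connectivity = NULL,
                           scenarios = scenario_names(),
                           models = c("DEC", "DEC+J", "DIVALIKE", "DIVALIKE+J",
                                      "BAYAREALIKE", "BAYAREALIKE+J"),
                           strata = default_strata(), verbose = FALSE, ...) {
  space <- attr(geo, "space")
  if (is.character(scenarios))
    scenarios <- lapply(scenarios, build_scenario, areas = space$areas,
                        connectivity = connectivity, strata = strata)
  fits <- list()
  for (sc in scenarios) for (m in models) {
    f <- tryCatch(fit_biogeo(tree, geo, model = m, scenario = sc, ...),
                  error = function(err)
                    structure(list(model = m, scenario_name = sc$name,
                                   params = c(d = NA_real_, e = NA_real_, j = NA_real_),
                                   lnL = NA_real_, k = if (grepl("J$", m)) 3L else 2L,
                                   n = ape::Ntip(tree), AICc = Inf,
                                   converged = FALSE, error = conditionMessage(err)),
                              class = "biogeo_fit"))
    if (verbose)
      cat(sprintf("%-18s %-14s lnL = %10.4f  AICc = %10.4f\n",
                  sc$name, m, f$lnL, f$AICc))
    fits[[paste(sc$name, m)]] <- f
  }
  tab <- model_weights(grid_table(fits))
  structure(tab, fits = fits, class = c("biogeo_grid", "data.frame"))
}

#' @export
print.biogeo_grid <- function(x, digits = 4, ...) {
  cat("Biogeographic model comparison (", nrow(x), " models, n = ",
      attr(x, "fits")[[1]]$n, " tips)\n\n", sep = "")
  df <- as.data.frame(x)
  df$d <- signif(df$d, digits); df$e <- signif(df$e, digits)
  df$j <- signif(df$j, digits)
  df$lnL <- round(df$lnL, digits); df$AICc <- round(df$AICc, digits)
  df$delta_AICc <- round(df$delta_AICc, digits)
  df$AICc_wt <- round(df$AICc_wt, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a model-comparison table to TSV
#'
#' @param grid A `biogeo_grid`.
#' @param path Output path.
#' @export
write_grid_tsv <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Ancestral ranges -------------------------------------------------------------

#' Marginal ancestral-range probabilities
#'
#' Combines tipward (downpass) and rootward (uppass) partial likelihoods to
#' give, for every internal node, the marginal probability of each range
#' immediately before cladogenesis at that node, normalized per node.
#'
#' @param tree,geo,model,scenario,root_prior As in [biogeo_loglik()].
#' @param params Named vector with `d`, `e` and optionally `j`.
#' @return Matrix (internal nodes x states) of probabilities, rows summing
#'   to 1; rownames are ape node numbers, colnames the state labels.
#' @export
ancestral_ranges <- function(tree, geo, model = "DEC", scenario = NULL,
                             params, root_prior = NULL) {
  tree <- as_chronogram(tree)
  space <- attr(geo, "space")
  if (is.null(scenario)) scenario <- null_scenario_for(tree, space)
  ms <- parse_model(model)
  pd <- build_pruning_data(tree, geo, scenario)
  j <- if (ms$with_j) unname(params["j"]) else 0
  clado <- cladogenesis_table(space, ms$base, j)
  if (is.null(root_prior)) root_prior <- default_root_prior(space)
  Pe <- edge_transitions(pd, unname(params["d"]), unname(params["e"]))
  dn <- prune_down(pd, clado, Pe)
  if (is.null(dn)) stop("data have zero likelihood under these parameters")
  S <- space$n_states
  n <- pd$n_tip
  O <- matrix(0, n + pd$n_node, S)
  O[pd$root, ] <- root_prior
  anc <- clado$anc; lf <- clado$left; rg <- clado$right; pr <- clado$prob
  child_edges <- split(seq_len(nrow(pd$edge)), pd$edge[, 1L])
  nodes <- rev(unique(pd$edge[, 1L]))           # preorder internal nodes
  for (v in nodes) {
    es <- child_edges[[as.character(v)]]
    for (side in 1:2) {
      ei <- es[side]; sib <- es[3L - side]
      ch <- pd$edge[ei, 2L]
      if (ch <= n) next                          # marginals only at internal nodes
      this_d <- if (side == 1L) lf else rg
      other_d <- if (side == 1L) rg else lf
      contrib <- O[v, anc] * pr * dn$W[sib, other_d]
      otop <- numeric(S)
      agg <- rowsum(contrib, this_d)
      otop[as.integer(rownames(agg))] <- agg
      ov <- as.vector(crossprod(Pe[[ei]], otop))  # t(P) %*% otop
      f <- sum(ov)
      O[ch, ] <- if (f > 0) ov / f else 0
    }
  }
  idx <- (n + 1L):(n + pd$n_node)
  M <- O[idx, , drop = FALSE] * dn$CL[idx, , drop = FALSE]
  M[pd$root - n, ] <- root_prior * dn$CL[pd$root, ]
  M <- M / rowSums(M)
  dimnames(M) <- list(idx, space$labels)
  M
}

#' Write per-node range probabilities to TSV
#'
#' @param anc Matrix from [ancestral_ranges()] (or [predict.biogeo_fit()]).
#' @param path Output path.
#' @export
write_ancestral_tsv <- function(anc, path) {
  df <- data.frame(node = rownames(anc), as.data.frame(anc),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
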