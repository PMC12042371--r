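# Independent oracles, kept deliberately separate from the package's
# computational path: a series-expansion matrix exponential and an
# exhaustive enumeration of the joint likelihood over all internal-node
# states and cladogenetic events (feasible for <= 4 tips, <= 3 areas).

series_expm <- function(Q, t) {
  A <- Q * t
  s <- max(0L, ceiling(log2(max(1, max(abs(A)) * nrow(A)))))
  A <- A / 2^s
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in 1:30) {
    term <- term %*% A / k
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

brute_force_biogeo <- function(tree, geo, base, j, d, e, scenario = NULL,
                               root_prior = NULL) {
  tree <- as_chronogram(tree)
  space <- attr(geo, "space")
  if (is.null(scenario))
    scenario <- build_scenario("null", space$areas,
                               strata = make_strata(c(0, max(node_ages(tree)) + 1)))
  clado <- cladogenesis_table(space, base, j)
  if (is.null(root_prior))
    root_prior <- c(0, rep(1 / (space$n_states - 1), space$n_states - 1L))
  ages <- node_ages(tree)
  n <- ape::Ntip(tree)
  interior <- scenario$strata$younger_bound[-1]
  oldest <- scenario$strata$older_bound[nrow(scenario$strata)]
  Pe <- lapply(seq_len(nrow(tree$edge)), function(i) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    sg <- slice_branch(ages[p], ages[ch], interior, oldest)
    P <- diag(space$n_states)
    for (r in seq_len(nrow(sg))) {
      Q <- build_rate_matrix(space, d, e, scenario$multipliers[[sg$stratum[r]]])
      P <- P %*% series_expm(Q, sg$older_age[r] - sg$younger_age[r])
    }
    P
  })
  internal <- (n + 1):(n + tree$Nnode)
  combos <- do.call(expand.grid,
                    lapply(internal, function(v) seq_along(clado$anc)))
  tipstate <- as.integer(geo)[match(tree$tip.label, names(geo))]
  marg <- matrix(0, tree$Nnode, space$n_states)
  total <- 0
  child_edges <- lapply(internal, function(v) which(tree$edge[, 1] == v))
  for (ci in seq_len(nrow(combos))) {
    rows <- as.integer(combos[ci, ])
    term <- root_prior[clado$anc[rows[1]]]      # node n+1 is the root
    if (term == 0) next
    ok <- TRUE
    for (vi in seq_along(internal)) {
      r <- rows[vi]
      term <- term * clado$prob[r]
      es <- child_edges[[vi]]
      tops <- c(clado$left[r], clado$right[r])
      for (side in 1:2) {
        ch <- tree$edge[es[side], 2]
        bottom <- if (ch <= n) tipstate[ch] else clado$anc[rows[ch - n]]
        term <- term * Pe[[es[side]]][tops[side], bottom]
      }
      if (term == 0) { ok <- FALSE; break }
    }
    if (!ok) next
    total <- total + term
    for (vi in seq_along(internal))
      marg[vi, clado$anc[rows[vi]]] <- marg[vi, clado$anc[rows[vi]]] + term
  }
  list(lnL = unname(log(total)), marg = unname(marg / total))
}
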