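#' @export
print.biogeo_fit <- function(x, digits = 4, ...) {
  cat("DEC-family biogeographic model fit\n")
  cat("  model:   ", x$model, "   scenario: ", x$scenario_name, "\n", sep = "")
  cat("  tips:    ", x$n, "\n", sep = "")
  if (!is.null(x$error)) {
    cat("  FAILED: ", x$error, "\n", sep = "")
    return(invisible(x))
  }
  p <- signif(x$params, digits)
  cat("  d = ", p["d"], ", e = ", p["e"],
      if (x$k == 3L) paste0(", j = ", p["j"]) else "", "\n", sep = "")
  cat("  lnL = ", round(x$lnL, digits), "  (k = ", x$k, ")",
      "  AICc = ", round(x$AICc, digits), "\n", sep = "")
  if (!x$converged) cat("  note: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
summary.biogeo_fit <- function(object, ...) {
  print(object, ...)
  sp <- attr(object$geo, "space")
  cat("  state space: ", sp$n_states, " ranges over ",
      length(sp$areas), " areas (max size ", sp$max_range_size, ")\n", sep = "")
  cat("  strata:      ", nrow(object$scenario$strata), "\n", sep = "")
  invisible(object)
}

#' @export
coef.biogeo_fit <- function(object, ...) {
  object$params[seq_len(object$k)]
}

#' @export
logLik.biogeo_fit <- function(object, ...) {
  structure(object$lnL, df = object$k, nobs = object$n, class = "logLik")
}

#' Marginal ancestral ranges from a fitted model
#'
#' @param object A `biogeo_fit`.
#' @param ... Unused.
#' @return See [ancestral_ranges()].
#' @export
predict.biogeo_fit <- function(object, ...) {
  ancestral_ranges(object$tree, object$geo, model = object$model,
                   scenario = object$scenario, params = object$params,
                   root_prior = object$root_prior)
}

#' Simulate datasets from a fitted model
#'
#' Forward-simulates range evolution on the fitted tree under the fitted
#' parameters and scenario (see [simulate_ranges()]).
#'
#' @param object A `biogeo_fit`.
#' @param nsim Number of datasets.
#' @param seed Integer seed; replicate `i` uses `seed + i - 1`.
#' @param root_range Root range for the simulation; defaults to the most
#'   probable root range under the fit.
#' @param ... Passed to [simulate_ranges()].
#' @return A list of `nsim` simulated datasets.
#' @export
simulate.biogeo_fit <- function(object, nsim = 1, seed = 1,
                                root_range = NULL, ...) {
  if (is.null(root_range)) {
    anc <- predict(object)
    sp <- attr(object$geo, "space")
    root_range <- sp$sets[[which.max(anc[1, ])]]
  }
  lapply(seq_len(nsim), function(i)
    simulate_ranges(object$tree, model = object$model,
                    scenario = object$scenario,
                    d = object$params["d"], e = object$params["e"],
                    j = object$params["j"],
                    space = attr(object$geo, "space"),
                    root_range = root_range, seed = seed + i - 1L, ...))
}

#' Plot a fitted model as node pies on the chronogram
#'
#' Draws the tree with per-node marginal range probabilities as pie charts
#' (ape machinery); ranges are colored by their first area, widespread
#' ranges shown with mixed wedges.
#'
#' @param x A `biogeo_fit`.
#' @param cex Pie size.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.biogeo_fit <- function(x, cex = 0.5, ...) {
  anc <- predict(x)
  sp <- attr(x$geo, "space")
  pal <- grDevices::hcl.colors(length(sp$areas), "Dark 3")
  state_col <- c("grey70", pal[vapply(sp$sets[-1], `[`, 0L, 1L)])
  ape::plot.phylo(x$tree, cex = cex, ...)
  ape::nodelabels(pie = anc, piecol = state_col, cex = cex)
  invisible(x)
}
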