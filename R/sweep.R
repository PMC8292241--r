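#' Parameter grid for the benchmarking sweep
#'
#' Cartesian grid over side length `L`, critical distance `mu` and
#' steepness `lambda`, at fixed area `A` and patch count `N`. The defaults
#' are the benchmark grid used to fit generated networks to empirical
#' habitat networks: `A = 25`, six side lengths, five `mu` values and nine
#' `lambda` values — 270 combinations.
#'
#' @param A landscape area (fixed across the grid).
#' @param L_values,mu_values,lambda_values finite, non-empty value sets.
#' @param N patch count, matched to the target network.
#' @return An object of class `"ahn_grid"`: a `data.frame` with one row per
#'   combination, ordered by `L`, then `mu`, then `lambda`.
#' @examples
#' nrow(sweep_grid(N = 30))  # 270
#' @export
sweep_grid <- function(A = 25,
                       L_values = c(5, 10, 15, 20, 25, 30),
                       mu_values = c(0.1, 2, 5, 7, 10),
                       lambda_values = c(0.001, 0.1, 0.15, 0.35, 0.4,
                                         0.75, 1.25, 5, 30),
                       N = 30) {
  stopifnot(length(L_values) > 0, length(mu_values) > 0,
            length(lambda_values) > 0)
  grid <- expand.grid(lambda = lambda_values, mu = mu_values, L = L_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("L", "mu", "lambda")]  # grid order: L, then mu, then lambda
  grid$A <- A
  grid$N <- as.integer(N)
  rownames(grid) <- NULL
  class(grid) <- c("ahn_grid", "data.frame")
  grid
}

#' Run the benchmarking sweep
#'
#' Generates one connected, weighted habitat network per grid combination
#' and computes its structural metrics. Per-combination seeds are derived
#' from the master seed and the grid row index, so the sweep is
#' reproducible and individual rows can be regenerated in isolation.
#'
#' @param grid an [sweep_grid()] object.
#' @param seed master seed for the sweep.
#' @return A `data.frame`: the grid columns plus `seed`, `n_edges`,
#'   `clustering`, `modularity`, `diameter`.
#' @examples
#' small <- sweep_grid(L_values = c(5, 10), mu_values = 5,
#'                     lambda_values = c(0.1, 30), N = 15)
#' run_sweep(small, seed = 1)
#' @export
run_sweep <- function(grid, seed = 1L) {
  stopifnot(inherits(grid, "ahn_grid"))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    ps <- derive_seed(seed, paste0("sweep-", k))
    net <- generate_network(ahn_params(A = grid$A[k], L = grid$L[k],
                                       N = grid$N[k], lambda = grid$lambda[k],
                                       mu = grid$mu[k], connected = TRUE,
                                       weighted = TRUE, seed = ps))
    m <- network_metrics(net)
    data.frame(L = grid$L[k], mu = grid$mu[k], lambda = grid$lambda[k],
               A = grid$A[k], N = grid$N[k], seed = ps,
               n_edges = m$n_edges, clustering = m$clustering,
               modularity = m$modularity, diameter = m$diameter)
  })
  do.call(rbind, rows)
}

#' Best-fitting parameter combination for one metric
#'
#' Selects the grid row whose generated network most closely approximates
#' the target value of the named metric (smallest absolute deviation).
#' Exact ties are broken by grid order (`L`, then `mu`, then `lambda`).
#'
#' @param sweep_table output of [run_sweep()].
#' @param metric one of `"clustering"`, `"modularity"`, `"diameter"`.
#' @param target_value the target network's value of that metric.
#' @return The winning row of `sweep_table`, with columns `metric`,
#'   `target_value` and `deviation` appended.
#' @export
best_fit <- function(sweep_table, metric, target_value) {
  metric <- match.arg(metric, c("clustering", "modularity", "diameter"))
  stopifnot(nrow(sweep_table) > 0, is.finite(target_value))
  dev <- abs(sweep_table[[metric]] - target_value)
  k <- which.min(dev)  # first minimum = earliest grid order
  out <- sweep_table[k, , drop = FALSE]
  out$metric <- metric
  out$target_value <- target_value
  out$deviation <- sweep_table[[metric]][k] - target_value
  rownames(out) <- NULL
  out
}

#' Replicate evaluation of a best-fitting parameter set
#'
#' Regenerates `n_reps` independent networks under one parameter
#' combination and reports how far each replicate's metric deviates from
#' the target (replicate metric minus target). Deviation distributions
#' summarize how reliably a parameter set reproduces a target structure.
#'
#' @param fit a one-row result of [best_fit()] (any data.frame carrying
#'   `A`, `L`, `N`, `mu`, `lambda`, `metric`, `target_value` works).
#' @param n_reps number of replicate networks (`>= 1`).
#' @param seed master seed; replicate seeds are derived from it.
#' @return An object of class `"ahn_fit"`: a list with elements `metric`,
#'   `target_value`, `params` (the fitted combination), `deviations`
#'   (length `n_reps`), `mean_deviation`, `sd_deviation` and `values`.
#' @export
replicate_eval <- function(fit, n_reps = 15L, seed = 1L) {
  stopifnot(n_reps >= 1, nrow(fit) == 1L)
  metric <- fit$metric
  vals <- vapply(seq_len(n_reps), function(r) {
    ps <- derive_seed(seed, paste0("rep-", r))
    net <- generate_network(ahn_params(A = fit$A, L = fit$L, N = fit$N,
                                       lambda = fit$lambda, mu = fit$mu,
                                       connected = TRUE, weighted = TRUE,
                                       seed = ps))
    network_metrics(net)[[metric]]
  }, numeric(1))
  dev <- vals - fit$target_value
  structure(list(metric = metric, target_value = fit$target_value,
                 params = fit[, c("A", "L", "N", "mu", "lambda")],
                 values = vals, deviations = dev,
                 mean_deviation = mean(dev), sd_deviation = stats::sd(dev)),
            class = "ahn_fit")
}

#' @export
print.ahn_fit <- function(x, ...) {
  cat(sprintf("Replicate fit for %s (target %.4g)\n", x$metric,
              x$target_value))
  cat(sprintf("  best parameters: A=%g, L=%g, N=%d, mu=%g, lambda=%g\n",
              x$params$A, x$params$L, x$params$N, x$params$mu,
              x$params$lambda))
  cat(sprintf("  %d replicates: deviation %.4g +/- %.4g (mean +/- sd)\n",
              length(x$deviations), x$mean_deviation,
              if (is.na(x$sd_deviation)) 0 else x$sd_deviation))
  invisible(x)
}

#' Fit generator parameters to a target network
#'
#' Convenience wrapper around the full benchmarking procedure: run the
#' sweep with `N` matched to the target, pick the best-fitting combination
#' for each of the three metrics independently, and evaluate each with
#' replicate networks.
#'
#' @param target an igraph habitat network (connected), or a one-row
#'   data.frame/list with fields `n_nodes`, `clustering`, `modularity`,
#'   `diameter`.
#' @param grid an [sweep_grid()]; its `N` is overridden by the target's
#'   node count.
#' @param n_reps replicates per best fit.
#' @param seed master seed.
#' @return A list with elements `sweep` (the sweep table) and `fits` (one
#'   `"ahn_fit"` per metric).
#' @export
fit_network <- function(target, grid = sweep_grid(), n_reps = 15L,
                        seed = 1L) {
  tm <- if (igraph::is_igraph(target)) network_metrics(target)
        else as.data.frame(target)
  grid$N <- as.integer(tm$n_nodes)
  tab <- run_sweep(grid, seed = seed)
  fits <- lapply(c("clustering", "modularity", "diameter"), function(m) {
    bf <- best_fit(tab, m, tm[[m]])
    replicate_eval(bf, n_reps = n_reps,
                   seed = derive_seed(seed, paste0("eval-", m)))
  })
  names(fits) <- c("clustering", "modularity", "diameter")
  list(sweep = tab, fits = fits)
}
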