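#' Parameters for the agent-based movement + SIR simulation
#'
#' Individuals move among the patches of a weighted, connected habitat
#' network and transmit a pathogen to co-located susceptibles. Defaults
#' follow the reference experiment: 100 individuals, staying probability
#' `p_stay = 0.5` (medium mobility), per-contact per-timestep infection
#' probability `pi = 0.05`, per-timestep recovery probability
#' `rho = 0.01`, 500 timesteps, 100 replicates, and a single initially
#' infectious individual (1% of the population).
#'
#' @param n_individuals population size.
#' @param p_stay probability of staying at the current patch each timestep;
#'   with probability `1 - p_stay` the individual moves to a neighbouring
#'   patch chosen proportionally to link weights.
#' @param pi probability that an infectious individual infects each
#'   co-located susceptible per timestep.
#' @param rho per-timestep recovery (and immunity acquisition) probability.
#' @param timesteps number of timesteps per run.
#' @param n_reps number of replicate runs.
#' @param n_seed_infected initially infectious individuals (chosen
#'   uniformly without replacement).
#' @param seed optional master seed.
#' @return An object of class `"sir_params"`.
#' @export
epidemic_params <- function(n_individuals = 100L, p_stay = 0.5, pi = 0.05,
                            rho = 0.01, timesteps = 500L, n_reps = 100L,
                            n_seed_infected = 1L, seed = NULL) {
  chk_prob <- function(p, nm)
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", nm), call. = FALSE)
  chk_prob(p_stay, "p_stay"); chk_prob(pi, "pi"); chk_prob(rho, "rho")
  if (n_individuals < 1 || n_seed_infected < 1 ||
      n_seed_infected > n_individuals)
    stop("need 1 <= n_seed_infected <= n_individuals", call. = FALSE)
  if (timesteps < 1 || n_reps < 1)
    stop("'timesteps' and 'n_reps' must be >= 1", call. = FALSE)
  structure(list(n_individuals = as.integer(n_individuals), p_stay = p_stay,
                 pi = pi, rho = rho, timesteps = as.integer(timesteps),
                 n_reps = as.integer(n_reps),
                 n_seed_infected = as.integer(n_seed_infected), seed = seed),
            class = "sir_params")
}

#' @export
print.sir_params <- function(x, ...) {
  cat(sprintf(paste0("SIR simulation: %d individuals (%d initially ",
                     "infectious), p_stay=%g, pi=%g, rho=%g, %d timesteps, ",
                     "%d replicates\n"),
              x$n_individuals, x$n_seed_infected, x$p_stay, x$pi, x$rho,
              x$timesteps, x$n_reps))
  invisible(x)
}

#' Per-patch movement probabilities
#'
#' The probability vector governing one individual's movement from patch
#' `node`: it stays with probability `p_stay`, and moves to each
#' neighbouring patch `j` with probability
#' `(1 - p_stay) * w_ij / sum_j(w_ij)`.
#'
#' @param g a weighted, connected habitat network.
#' @param node a vertex index (or name).
#' @param p_stay staying probability.
#' @return A named numeric vector over `c(node, neighbours)`, summing to 1.
#' @examples
#' net <- generate_network(ahn_params(N = 10, seed = 3))
#' sum(movement_kernel(net, 1, 0.5))  # 1
#' @export
movement_kernel <- function(g, node, p_stay) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::ecount(g) > 0L && !"weight" %in% igraph::edge_attr_names(g))
    stop("movement requires a weighted network", call. = FALSE)
  v <- as.integer(igraph::V(g)[node])
  eids <- igraph::incident(g, v)
  if (length(eids) == 0L) {
    if (igraph::vcount(g) > 1L && p_stay < 1)
      stop("isolated patch in a supposedly connected network", call. = FALSE)
    return(stats::setNames(1, igraph::V(g)$name[v]))
  }
  nb <- as.integer(igraph::ends(g, eids, names = FALSE))
  nb <- matrix(nb, ncol = 2L)
  other <- ifelse(nb[, 1L] == v, nb[, 2L], nb[, 1L])
  w <- igraph::E(g)$weight[as.integer(eids)]
  p <- c(p_stay, (1 - p_stay) * w / sum(w))
  stats::setNames(p, igraph::V(g)$name[c(v, other)])
}

# Precompute per-node neighbour indices and movement weights for fast
# simulation. Returns list of lists: nbrs[[i]], wts[[i]] (normalized).
movement_tables <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::ends(g, igraph::E(g), names = FALSE)
  w <- igraph::E(g)$weight
  nbrs <- vector("list", n); wts <- vector("list", n)
  for (i in seq_len(n)) { nbrs[[i]] <- integer(); wts[[i]] <- numeric() }
  for (k in seq_len(nrow(el))) {
    a <- el[k, 1L]; b <- el[k, 2L]
    nbrs[[a]] <- c(nbrs[[a]], b); wts[[a]] <- c(wts[[a]], w[k])
    nbrs[[b]] <- c(nbrs[[b]], a); wts[[b]] <- c(wts[[b]], w[k])
  }
  for (i in seq_len(n)) {
    s <- sum(wts[[i]])
    if (s > 0) wts[[i]] <- wts[[i]] / s
  }
  list(nbrs = nbrs, wts = wts)
}

# One synchronous timestep. Status codes: 0 = S, 1 = I, 2 = R.
# Phase 1: everyone moves; phase 2: transmission from individuals
# infectious at the start of the step to co-located susceptibles
# (escape probability (1 - pi)^k under k infectious contacts);
# phase 3: start-of-step infectious recover with probability rho.
# Newly infected individuals neither transmit nor recover this step.
sir_step <- function(loc, status, tables, p_stay, pi, rho) {
  n <- length(loc)
  move <- runif(n) >= p_stay
  if (any(move)) {
    for (i in unique(loc[move])) {
      who <- which(move & loc == i)
      nb <- tables$nbrs[[i]]
      if (length(nb) == 0L) {
        if (length(tables$nbrs) == 1L) next  # single-patch network: stay
        stop("isolated patch in a supposedly connected network",
             call. = FALSE)
      }
      loc[who] <- if (length(nb) == 1L) nb
                  else nb[sample.int(length(nb), length(who), replace = TRUE,
                                     prob = tables$wts[[i]])]
    }
  }
  infectious0 <- status == 1L
  if (any(infectious0) && pi > 0) {
    inf_count <- tabulate(loc[infectious0], nbins = length(tables$nbrs))
    sus <- which(status == 0L)
    k <- inf_count[loc[sus]]
    at_risk <- sus[k > 0L]
    if (length(at_risk)) {
      p_inf <- 1 - (1 - pi)^k[k > 0L]
      newly <- at_risk[runif(length(at_risk)) < p_inf]
      status[newly] <- 1L
    }
  }
  if (any(infectious0) && rho > 0) {
    rec <- which(infectious0)[runif(sum(infectious0)) < rho]
    status[rec] <- 2L
  }
  list(loc = loc, status = status)
}

#' Run one agent-based SIR epidemic on a habitat network
#'
#' Individuals are first placed uniformly at random over patches and
#' `n_seed_infected` of them set infectious. Each timestep then proceeds
#' synchronously: all individuals move (stay with probability `p_stay`,
#' otherwise step to a neighbour proportionally to link weights); each
#' individual infectious at the start of the timestep independently infects
#' each co-located susceptible with probability `pi` (a susceptible exposed
#' to `k` infectious patch-mates escapes with probability `(1 - pi)^k`);
#' and each start-of-step infectious individual recovers with probability
#' `rho`. Newly infected individuals neither transmit nor recover within
#' the timestep in which they are infected. There is no birth, death,
#' emigration or immigration, and no reinfection.
#'
#' @param g a connected, weighted habitat network.
#' @param params an [epidemic_params()] object.
#' @param seed optional seed overriding `params$seed`.
#' @return A `data.frame` of class `"sir_trajectory"` with one row per
#'   timestep `t = 0, ..., timesteps`: counts `S`, `I`, `R`, the
#'   percentage of currently infectious individuals `pct_infected`, and
#'   cumulative incidence `pct_ever_infected` (`= 100 (I + R) / n`).
#' @export
run_epidemic <- function(g, params = epidemic_params(), seed = NULL) {
  stopifnot(igraph::is_igraph(g), inherits(params, "sir_params"))
  if (igraph::ecount(g) > 0L &&
      !"weight" %in% igraph::edge_attr_names(g))
    stop("the epidemic model requires a weighted network", call. = FALSE)
  if (!igraph::is_connected(g))
    stop("the epidemic model requires a connected network", call. = FALSE)
  if (is.null(seed)) seed <- params$seed
  n <- params$n_individuals
  nv <- igraph::vcount(g)
  tables <- movement_tables(g)
  with_seed(seed, {
    loc <- sample.int(nv, n, replace = TRUE)
    status <- integer(n)
    status[sample.int(n, params$n_seed_infected)] <- 1L
    S <- I <- R <- integer(params$timesteps + 1L)
    S[1L] <- sum(status == 0L); I[1L] <- sum(status == 1L)
    R[1L] <- sum(status == 2L)
    for (t in seq_len(params$timesteps)) {
      st <- sir_step(loc, status, tables, params$p_stay, params$pi,
                     params$rho)
      loc <- st$loc; status <- st$status
      S[t + 1L] <- sum(status == 0L); I[t + 1L] <- sum(status == 1L)
      R[t + 1L] <- sum(status == 2L)
    }
    out <- data.frame(t = 0:params$timesteps, S = S, I = I, R = R,
                      pct_infected = 100 * I / n,
                      pct_ever_infected = 100 * (I + R) / n)
    class(out) <- c("sir_trajectory", "data.frame")
    out
  })
}

#' Replicated epidemics with per-timestep summary
#'
#' Runs `params$n_reps` independent epidemics and summarizes the
#' percentage of infectious individuals per timestep across replicates.
#' When `net` is an [ahn_params()] object, a fresh habitat network is
#' generated for every replicate (new coordinate and filtering draws),
#' treating the landscape scenario as a population of networks; when `net`
#' is an igraph object, the same fixed network is reused in every
#' replicate.
#'
#' @param net either an igraph habitat network or an [ahn_params()]
#'   object describing networks to generate per replicate.
#' @param params an [epidemic_params()] object.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @return A list with elements `summary` (a `data.frame` with `t`,
#'   `mean_pct_infected`, `sd_pct_infected`, `mean_pct_ever_infected`) and
#'   `trajectories` (a list of `"sir_trajectory"` objects, one per
#'   replicate).
#' @export
run_replicates <- function(net, params = epidemic_params(), seed = 1L) {
  stopifnot(inherits(params, "sir_params"))
  fresh <- inherits(net, "ahn_params")
  if (!fresh && !igraph::is_igraph(net))
    stop("'net' must be an igraph network or an ahn_params object",
         call. = FALSE)
  trajs <- lapply(seq_len(params$n_reps), function(r) {
    g <- if (fresh) {
      p <- net; p$seed <- derive_seed(seed, paste0("net-", r))
      generate_network(p)
    } else net
    run_epidemic(g, params, seed = derive_seed(seed, paste0("sir-", r)))
  })
  pct <- vapply(trajs, function(tr) tr$pct_infected,
                numeric(params$timesteps + 1L))
  ever <- vapply(trajs, function(tr) tr$pct_ever_infected,
                 numeric(params$timesteps + 1L))
  pct <- matrix(pct, ncol = params$n_reps)
  ever <- matrix(ever, ncol = params$n_reps)
  summary <- data.frame(
    t = 0:params$timesteps,
    mean_pct_infected = rowMeans(pct),
    sd_pct_infected = apply(pct, 1L, stats::sd),
    mean_pct_ever_infected = rowMeans(ever))
  if (params$n_reps == 1L) summary$sd_pct_infected <- 0
  list(summary = summary, trajectories = trajs)
}
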