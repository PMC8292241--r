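test_that("reciprocal distance kernel and its domain", {
  expect_equal(link_weight(1), 1)
  expect_equal(link_weight(2), 0.5)
  expect_equal(link_weight(0.1), 10)
  expect_error(link_weight(0), "positive")
  expect_error(link_weight(-2), "positive")
})

test_that("sigmoidal removal probability: midpoint, closed form, flat limit", {
  # midpoint P(mu) = 0.5 exactly, any steepness
  for (lam in c(0.001, 0.35, 30)) {
    expect_identical(removal_probability(5, lam, 5), 0.5)
    expect_identical(removal_probability(-3, lam, -3), 0.5)
  }
  # closed form at D = 7, lambda = 0.35, mu = 5
  expect_equal(removal_probability(7, 0.35, 5), 1 / (1 + exp(-0.7)),
               tolerance = 1e-15)
  # near-flat limit: |P - 0.5| <= lambda * |D - mu| / 4 (max sigmoid slope)
  D <- seq(0.01, 59.99, length.out = 200)
  p <- removal_probability(D, 0.001, 5)
  expect_true(all(abs(p - 0.5) <= 0.001 * abs(D - 5) / 4 + 1e-12))
  expect_true(all(abs(p - 0.5) < 0.015))
  # strictly increasing in D
  grid <- sort(runif(100, -10, 70))
  expect_true(all(diff(removal_probability(grid, 0.35, 5)) > 0))
  expect_error(removal_probability(1, 0, 5), "positive")
  expect_error(removal_probability(1, -1, 5), "positive")
})

test_that("complete graph has all pairs weighted by reciprocal distance", {
  land <- landscape(25, 5)
  two <- validate_layout(land, data.frame(x = c(0, 2), y = c(0, 0)))
  g2 <- build_complete_graph(two)
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(igraph::E(g2)$weight, 0.5)

  four <- fixed_layout(4, seed = 2)
  expect_equal(igraph::ecount(build_complete_graph(four)), 6)

  tri <- validate_layout(land, data.frame(x = c(0, 1, 0), y = c(0, 0, 1)))
  g3 <- build_complete_graph(tri)
  expect_equal(sort(igraph::E(g3)$weight), sort(c(1, 1, 1 / sqrt(2))))

  dup <- data.frame(x = c(1, 1), y = c(1, 1))
  expect_error(validate_layout(land, dup), "duplicate")
})

test_that("deterministic filtering thresholds at the critical distance", {
  lay <- fixed_layout(15, seed = 4)
  g <- build_complete_graph(lay)
  # mu beyond the landscape diagonal: every link shorter than mu, all kept
  kept <- filter_links(g, lambda = 1, mu = 10, deterministic = TRUE)
  expect_equal(igraph::ecount(kept), igraph::ecount(g))
  # links longer than mu are removed, links at D <= mu retained
  f <- filter_links(g, lambda = 2, mu = 2.5, deterministic = TRUE)
  ends <- igraph::ends(f, igraph::E(f), names = FALSE)
  d <- sqrt((igraph::V(f)$x[ends[, 1]] - igraph::V(f)$x[ends[, 2]])^2 +
            (igraph::V(f)$y[ends[, 1]] - igraph::V(f)$y[ends[, 2]])^2)
  expect_true(all(d <= 2.5))
  all_d <- complete_dists(lay)
  expect_equal(igraph::ecount(f), sum(all_d <= 2.5))
})

test_that("steep filtering with mu below all distances removes every link", {
  # union bound: P(any link survives) <= N^2 exp(-lambda * delta), delta >= 1
  land <- landscape(100, 10)
  lay <- validate_layout(land, data.frame(x = c(0, 3, 6, 9), y = c(0, 0, 0, 0)))
  g <- build_complete_graph(lay)
  f <- filter_links(g, lambda = 30, mu = 2, seed = 5)
  expect_equal(igraph::ecount(f), 0)
})

test_that("shared filtering seed makes retention monotone in mu", {
  lay <- fixed_layout(20, seed = 6)
  g <- build_complete_graph(lay)
  for (s in c(1, 2, 3)) {
    prev <- NULL
    for (mu in c(0.5, 2, 4, 6, 9)) {
      kept <- canonical_edges(filter_links(g, lambda = 0.75, mu = mu, seed = s))
      if (!is.null(prev) && nrow(prev)) {
        prev_keys <- paste(prev[, 1], prev[, 2])
        kept_keys <- paste(kept[, 1], kept[, 2])
        expect_true(all(prev_keys %in% kept_keys))
      }
      prev <- kept
    }
  }
})

test_that("rewiring joins closest components with minimal links", {
  land <- landscape(25, 5)
  # connected input is untouched
  lay <- fixed_layout(10, seed = 8)
  g <- build_complete_graph(lay)
  expect_identical(canonical_edges(rewire_components(g)), canonical_edges(g))

  # three isolated patches on a line: chain with reciprocal weights
  line <- validate_layout(land, data.frame(x = c(0, 1, 5), y = c(0, 0, 0)))
  empty <- igraph::delete_edges(build_complete_graph(line), 1:3)
  r <- rewire_components(empty, eta = 1)
  expect_equal(canonical_edges(r), rbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(sort(igraph::E(r)$weight), sort(c(1, 1 / 4)))
  expect_true(all(igraph::E(r)$rewired))
  # eta rescales rewired links only
  r2 <- rewire_components(empty, eta = 2)
  expect_equal(sort(igraph::E(r2)$weight), sort(c(1, 1 / 16)))

  # eta never touches surviving within-component weights
  g20 <- build_complete_graph(fixed_layout(20, seed = 12))
  f <- filter_links(g20, lambda = 5, mu = 1.5, seed = 3)
  r3 <- rewire_components(f, eta = 3)
  old <- !igraph::E(r3)$rewired
  expect_equal(igraph::E(r3)$weight[old], igraph::E(f)$weight)
})

test_that("rewiring an edgeless layout reproduces the Euclidean MST", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    lay <- fixed_layout(n, seed = 1000 + rep)
    empty <- igraph::delete_edges(build_complete_graph(lay),
                                  seq_len(choose(n, 2)))
    r <- rewire_components(empty)
    expect_equal(igraph::ecount(r), n - 1)
    expect_equal(canonical_edges(r), oracle_mst_edges(lay$x, lay$y))
  }
})

test_that("rewiring adds exactly components-minus-one links", {
  for (s in 1:10) {
    g <- build_complete_graph(fixed_layout(25, seed = 50 + s))
    f <- filter_links(g, lambda = 5, mu = 1, seed = s)
    ncomp <- igraph::components(f)$no
    r <- rewire_components(f)
    expect_true(igraph::is_connected(r))
    expect_equal(igraph::ecount(r) - igraph::ecount(f), ncomp - 1)
  }
})

test_that("full generation pipeline composes the stages reproducibly", {
  p <- ahn_params(A = 25, L = 5, N = 30, lambda = 0.35, mu = 5, seed = 21)
  net <- generate_network(p)
  expect_equal(igraph::vcount(net), 30)
  expect_true(igraph::is_connected(net))
  expect_true(all(igraph::E(net)$weight > 0))
  # same seed, identical network
  again <- generate_network(p)
  expect_identical(canonical_edges(net), canonical_edges(again))
  expect_identical(igraph::E(net)$weight, igraph::E(again)$weight)

  # degenerate single patch
  solo <- generate_network(ahn_params(N = 1, seed = 1))
  expect_equal(igraph::vcount(solo), 1)
  expect_equal(igraph::ecount(solo), 0)

  # deterministic mu -> -inf proxy: all links cut, rewired to the MST
  pl <- ahn_params(A = 25, L = 5, N = 12, lambda = 1, mu = -1e6,
                   deterministic = TRUE, connected = TRUE, seed = 31)
  mstnet <- generate_network(pl)
  expect_equal(igraph::ecount(mstnet), 11)
  expect_equal(canonical_edges(mstnet),
               oracle_mst_edges(igraph::V(mstnet)$x, igraph::V(mstnet)$y))

  # unweighted output strips the weight attribute
  uw <- generate_network(ahn_params(N = 10, weighted = FALSE, seed = 2))
  expect_false("weight" %in% igraph::edge_attr_names(uw))

  # parameter validation
  expect_error(ahn_params(lambda = 0), "positive")
  expect_error(ahn_params(eta = 0.5), ">= 1")
})
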