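# Connectivity vectors, distances, Gcst, band tests, tvDFC, centrality
# and hub detection.

mask_result <- function(mask) structure(list(mask = mask),
                                        class = "significance_result")

test_that("connectivity vectors zero out non-significant pairs", {
  mp <- c(0.9, 0.4, 0.7)
  expect_equal(connectivity_vector(mask_result(c(TRUE, FALSE, TRUE)), mp),
               c(0.9, 0, 0.7))
  expect_equal(connectivity_vector(mask_result(rep(FALSE, 3)), mp),
               c(0, 0, 0))
  expect_equal(connectivity_vector(mask_result(rep(TRUE, 3)), mp), mp)
  expect_error(connectivity_vector(mask_result(c(TRUE, FALSE)), mp),
               "disagree in length")
})

test_that("group-pair distances are Euclidean over all C(k,2) pairs", {
  v <- list(a = c(0, 0, 0), b = c(3, 4, 0), c = c(0, 0, 0))
  d <- group_pair_distances(v)
  expect_equal(nrow(d), 3)
  expect_equal(d$distance[d$group_a == "a" & d$group_b == "b"], 5)
  expect_equal(d$distance[d$group_a == "a" & d$group_b == "c"], 0)
  v8 <- setNames(lapply(1:8, function(i) rnorm(10)), letters[1:8])
  expect_equal(nrow(group_pair_distances(v8)), 28)
  expect_error(group_pair_distances(list(1:3, 1:4)), "differ in length")
  # distance axioms
  withr::with_seed(6, {
    x <- rnorm(12); y <- rnorm(12)
    dd <- group_pair_distances(list(p = x, q = y, r = x))
    expect_gte(min(dd$distance), 0)
    expect_equal(dd$distance[dd$group_a == "p" & dd$group_b == "r"], 0)
  })
})

test_that("segment pooling averages distances per group pair", {
  tab <- expand.grid(segment = 0:8, group_a = "1", group_b = "2",
                     stringsAsFactors = FALSE)
  tab$band <- "alpha"
  tab$distance <- 1:9
  out <- band_average_distances(tab, "alpha")
  expect_equal(out$distance, 5)
  tab2 <- tab[tab$segment != 4, ]
  expect_error(band_average_distances(tab2, "alpha"), "expected 9")
  expect_error(band_average_distances(tab, "gamma"), "no distances")
})

test_that("Gcst is the grand mean across bands and group pairs", {
  avgs <- lapply(1:6, function(b)
    data.frame(group_a = "x", group_b = "y", distance = rep(b, 28)))
  names(avgs) <- eeg_bands()$name
  expect_equal(global_threshold(avgs), 3.5)
  expect_equal(global_threshold(rep(1, 168)), 1)
})

test_that("band-selection t-test matches the closed form", {
  r <- band_selection_test(c(9, 10, 11), gcst = 8, n_bands = 1)
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$cohens_d, 2)
  # all values at Gcst: t = 0, d = 0 (jitter to avoid zero variance)
  r0 <- band_selection_test(c(8 - 1e-9, 8, 8 + 1e-9), gcst = 8)
  expect_equal(r0$t, 0, tolerance = 1e-3)
  expect_equal(r0$cohens_d, 0, tolerance = 1e-3)
  expect_error(band_selection_test(c(8, 8, 8), gcst = 8), "zero variance")
  # 28 distances (8 groups) give df = 27, Bonferroni over 6 bands
  withr::with_seed(10, x <- rnorm(28, 9))
  r28 <- band_selection_test(x, gcst = 8, n_bands = 6)
  expect_equal(r28$df, 27)
  expect_equal(r28$p, min(1, r28$p_raw * 6))
})

test_that("paired band comparison equals a one-sample t on differences", {
  withr::with_seed(11, {
    a <- rnorm(28, 10); b <- rnorm(28, 9.5)
  })
  r <- paired_band_comparison(a, b)
  ref <- stats::t.test(a - b)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$df, 27)
  expect_equal(r$p, ref$p.value)
  expect_equal(r$ci95, as.numeric(ref$conf.int), tolerance = 1e-9)
  expect_equal(paired_band_comparison(a, a)$t, 0)
  expect_error(paired_band_comparison(a, b[-1]), "differ in length")
})

test_that("tvDFC identities", {
  expect_equal(temporal_variability(matrix(1, 9, 5)), 0)
  expect_equal(temporal_variability(rbind(c(0, 0), c(3, 4))), 5)
  u <- c(1, 2, 0); v <- c(4, 6, 0)
  alt <- do.call(rbind, rep(list(u, v), 4))
  expect_equal(temporal_variability(alt), sqrt(sum((u - v)^2)))
  # invariant to a common permutation of coordinates
  withr::with_seed(13, {
    M <- matrix(rnorm(9 * 8), 9, 8)
    p <- sample(8)
    expect_equal(temporal_variability(M), temporal_variability(M[, p]))
  })
  expect_error(temporal_variability(matrix(1, 1, 3)), "at least 2")
})

test_that("eigenvector centrality: star, complete graph, oracle match", {
  A <- matrix(0, 5, 5); A[1, 2:5] <- 1; A <- A + t(A)
  s <- eigenvector_centrality(A)
  expect_equal(which.max(s), 1)
  expect_true(all(s[1] > s[2:5]))
  K <- matrix(1, 6, 6) - diag(6)
  expect_equal(unname(eigenvector_centrality(K)), rep(1 / sqrt(6), 6))
  expect_error(eigenvector_centrality(matrix(0, 3, 3)), "empty graph")
  expect_error(eigenvector_centrality(matrix(c(0, 1, 0, 0), 2)),
               "symmetric")
  # power-iteration oracle + igraph cross-check on random graphs
  power_iter <- function(A, iters = 4000) {
    v <- rep(1, nrow(A))
    for (i in seq_len(iters)) v <- A %*% v / sqrt(sum((A %*% v)^2))
    as.numeric(v)
  }
  withr::with_seed(19, {
    for (rep in 1:5) {
      n <- sample(8:20, 1)
      A <- matrix(0, n, n)
      A[upper.tri(A)] <- (runif(n * (n - 1) / 2) < 0.4) * runif(n * (n - 1) / 2)
      A <- A + t(A)
      if (all(A == 0)) next
      s <- eigenvector_centrality(A)
      comp <- s > 0
      if (sum(comp) < 2) next
      pi_ref <- power_iter(A[comp, comp, drop = FALSE])
      expect_equal(s[comp], pi_ref / sqrt(sum(pi_ref^2)),
                   tolerance = 1e-8, ignore_attr = TRUE)
      ig <- igraph::graph_from_adjacency_matrix(A, "undirected",
                                                weighted = TRUE)
      ec <- igraph::eigen_centrality(ig, weights = igraph::E(ig)$weight)$vector
      ec <- ec[comp] / sqrt(sum(ec[comp]^2))
      expect_equal(unname(s[comp]), unname(ec), tolerance = 1e-6)
    }
  })
})

test_that("hub detection flags an embedded star and is seed-stable", {
  withr::with_seed(23, {
    n <- 14
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- (runif(n * (n - 1) / 2) < 0.08) * 0.5
    A[1, 2:8] <- 0.9                     # strong star at node 1
    A <- A + t(A)
    rownames(A) <- colnames(A) <- paste0("ch", 1:n)
  })
  h1 <- hub_significance(A, n_random = 400, alpha = 0.05, seed = 31)
  expect_true(h1$is_hub[1])
  h2 <- hub_significance(A, n_random = 400, alpha = 0.05, seed = 31)
  expect_identical(h1, h2)
  expect_error(hub_significance(matrix(0, 4, 4), n_random = 10),
               "degenerate")
  expect_error(hub_significance(matrix(1, 4, 4) - diag(4), n_random = 10),
               "degenerate")
})

test_that("hub rate on pure random graphs stays near the nominal level", {
  frac <- withr::with_seed(29, {
    vapply(1:40, function(r) {
      n <- 12
      A <- matrix(0, n, n)
      A[upper.tri(A)] <- as.numeric(runif(n * (n - 1) / 2) < 0.3)
      A <- A + t(A)
      if (sum(A) == 0) return(0)
      h <- hub_significance(A, n_random = 250, alpha = 0.05,
                            seed = 100 + r)
      mean(h$is_hub)
    }, numeric(1))
  })
  expect_lte(mean(frac), 0.05 + 0.02)
})
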