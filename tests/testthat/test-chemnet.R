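test_that("clr transform satisfies its defining identities", {
  u <- matrix(0.25, 1, 4, dimnames = list("a", paste0("x", 1:4)))
  expect_equal(unname(clr_transform(u)), matrix(0, 1, 4))
  # two-part composition (e*g, g/e): clr = (+1, -1)
  two <- matrix(c(exp(1), exp(-1)), 1,
                dimnames = list("a", c("x", "y")))
  expect_equal(unname(clr_transform(two)), matrix(c(1, -1), 1))
  # zero handling equals hand-done multiplicative replacement
  row <- c(0.5, 0.5, 0)
  delta <- 1e-5
  hand <- c(0.5, 0.5) * (1 - delta) / 1
  hand <- c(hand, delta)
  hand_clr <- log(hand) - mean(log(hand))
  m <- matrix(row, 1, dimnames = list("a", c("x", "y", "z")))
  expect_equal(unname(clr_transform(m, delta = delta))[1, ],
               unname(hand_clr))
  expect_error(clr_transform(m, zero_strategy = "error"), "zeros")
  # rows always sum to zero
  pt <- gen_chc_profiles(scenario_config(seed = 31))
  expect_true(all(abs(rowSums(clr_transform(pt))) < 1e-9))
})

test_that("clr PCA: variance percentages and reconstruction identity", {
  set.seed(1)
  # collinear data -> PC1 explains everything
  base <- rnorm(6)
  line <- t(vapply(seq(-2, 2, length.out = 9), function(a) a * base,
                   numeric(6)))
  rownames(line) <- paste0("s", 1:9)
  p_line <- pca_clr(line)
  expect_equal(p_line$eigen_pct[1], 100, tolerance = 1e-8)
  # reconstruction: scores %*% t(loadings) + center reproduces the data
  x <- matrix(rnorm(80), 10, 8, dimnames = list(paste0("s", 1:10), NULL))
  p <- pca_clr(x)
  rec <- p$scores %*% t(p$loadings)
  expect_equal(rec + matrix(p$center, 10, 8, byrow = TRUE), x,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(abs(crossprod(p$scores)[upper.tri(diag(8))]) < 1e-6))
  expect_error(pca_clr(x[1, , drop = FALSE]), "2 samples")
})

test_that("axis category rule: drop <5, two in [5,10], else pct/5", {
  ac <- axis_categories(c(40, 7, 4.9))
  expect_equal(ac$axis, c(1L, 2L))
  expect_equal(ac$k, c(8L, 2L))
  expect_equal(axis_categories(10)$k, 2L)
  expect_equal(axis_categories(c(58.75, 22))$k, c(12L, 4L))
  expect_error(axis_categories(c(4, 3)), "no PC axis")
})

test_that("score discretization hits the end points and rounds half-even", {
  s <- matrix(c(0, 1, 2, 3), 4, 1)
  expect_equal(as.vector(discretize_scores(s, 2L)), c(0L, 0L, 1L, 1L))
  s2 <- matrix(seq(-1, 1, length.out = 5), 5, 1)
  cat4 <- discretize_scores(s2, 4L)
  expect_equal(cat4[1, 1], 0L)     # axis minimum
  expect_equal(cat4[5, 1], 3L)     # axis maximum -> k - 1
  expect_error(discretize_scores(matrix(1, 3, 1), 2L), "constant")
  expect_error(discretize_scores(s, c(2L, 2L)), "one entry per")
})

test_that("chemical types collapse by identical category sequence", {
  m <- matrix(c(0, 1, 0, 1, 1, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  ty <- collapse_chemical_types(m)
  expect_equal(nrow(ty), 2L)
  expect_equal(ty$n, c(2L, 1L))
  expect_setequal(ty$members[[1]], c("a", "b"))
  all_same <- collapse_chemical_types(matrix(1, 5, 2))
  expect_equal(nrow(all_same), 1L)
  expect_equal(all_same$n, 5L)
  all_diff <- collapse_chemical_types(matrix(1:6, 3, 2))
  expect_equal(nrow(all_diff), 3L)
  expect_true(all(all_diff$singleton))
})

test_that("type distance is the summed per-axis absolute difference", {
  expect_equal(type_distance(c(0L, 0L), c(2L, 1L)), 3L)
  expect_equal(type_distance(c(1L, 1L), c(1L, 1L)), 0L)
  set.seed(2)
  for (i in 1:20) {
    a <- sample(0:5, 4, TRUE); b <- sample(0:5, 4, TRUE)
    expect_identical(type_distance(a, b), type_distance(b, a))
  }
  expect_error(type_distance(1L, c(1L, 2L)), "length")
})

test_that("minimum spanning network: small cases and igraph cross-check", {
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  net2 <- build_msn(c("A", "B"), d2)
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$weight, 3)

  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  net3 <- build_msn(LETTERS[1:3], d3)
  expect_equal(sum(net3$edges$weight[net3$edges$in_mst]), 2)

  set.seed(3)
  for (i in 1:20) {
    n <- sample(3:7, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- sample(1:9, n * (n - 1) / 2, TRUE)
    d <- d + t(d)
    labs <- paste0("N", 1:n)
    dimnames(d) <- list(labs, labs)
    ours <- sum(build_msn(labs, d)$edges$weight)
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    ig <- sum(igraph::E(igraph::mst(g))$weight)
    expect_equal(ours, ig)
  }
})

test_that("alternative links have weight equal to the path maximum", {
  # square with a tie: A-B-C-D chain plus an equal-cost diagonal
  labs <- LETTERS[1:4]
  d <- matrix(c(0, 1, 2, 1,
                1, 0, 1, 2,
                2, 1, 0, 1,
                1, 2, 1, 0), 4, dimnames = list(labs, labs))
  net <- build_msn(labs, d, include_alternatives = TRUE)
  alts <- net$edges[net$edges$alternative, ]
  expect_gt(nrow(alts), 0)
  expect_true(all(alts$weight == 1))
  # without the flag, only the tree remains
  net0 <- build_msn(labs, d)
  expect_equal(nrow(net0$edges), 3L)
})

test_that("network pipeline is invariant to sample order and scaling", {
  cfg <- scenario_config(n_colonies_per_chemotype = 15, seed = 32)
  pt <- gen_chc_profiles(cfg)
  net1 <- chemical_network(pt)
  # permute samples
  perm <- sample(nrow(pt$abundance))
  pt2 <- peak_table(pt$abundance[perm, ], pt$substances,
                    pt$samples[perm, ])
  net2 <- chemical_network(pt2)
  a1 <- dplyr::arrange(net1$assignments, sample)
  a2 <- dplyr::arrange(net2$assignments, sample)
  expect_equal(adjusted_rand_index(a1$type, a2$type), 1)
  # rescale one sample's raw abundances: clr+PCA unchanged
  ab <- pt$abundance; ab[3, ] <- ab[3, ] * 50
  net3 <- chemical_network(peak_table(ab, pt$substances, pt$samples))
  a3 <- dplyr::arrange(net3$assignments, sample)
  expect_equal(adjusted_rand_index(a1$type, a3$type), 1)
})

test_that("cutting the longest MST edge separates the two chemotypes", {
  cfg <- scenario_config(seed = 33)
  pt <- gen_chc_profiles(cfg)
  flt <- filter_substances(pt, "chemotype")
  net <- chemical_network(flt)
  cut <- cut_network(net, n_cut = 1)
  truth <- flt$samples$chemotype[match(cut$sample, flt$samples$sample)]
  expect_equal(adjusted_rand_index(cut$component, truth), 1)
  # agreement with an independent ARI implementation
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(adjusted_rand_index(cut$component, truth),
                 mclust::adjustedRandIndex(cut$component, truth))
  }
})
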