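#' Centered log-ratio transformation
#'
#' Maps closed compositions to clr coordinates:
#' `clr(x)_i = ln(x_i) - mean_j ln(x_j)`, so each row sums to zero.  Zeros
#' are handled by multiplicative replacement: zeros become `delta`, non-zero
#' parts are shrunk proportionally so the row stays closed, then clr is
#' taken; or an error is raised under `zero_strategy = "error"`.
#'
#' @param x a closed composition matrix (rows sum to 1) or a [peak_table()]
#'   (closure applied).
#' @param zero_strategy `"multiplicative"` (default) or `"error"`.
#' @param delta replacement value for zeros (default 1e-5, below the 0.1%
#'   filtering floor).
#' @return A numeric matrix of clr coordinates, rows summing to 0.
#' @export
#' @examples
#' clr_transform(matrix(c(.25, .25, .25, .25), 1,
#'                      dimnames = list("s1", paste0("x", 1:4))))
clr_transform <- function(x, zero_strategy = c("multiplicative", "error"),
                          delta = 1e-5) {
  zero_strategy <- match.arg(zero_strategy)
  if (inherits(x, "peak_table")) x <- x$abundance
  x <- normalize_closure(x)
  if (any(x == 0)) {
    if (zero_strategy == "error")
      abort("zeros present in composition under zero_strategy = 'error'")
    x <- t(apply(x, 1, function(row) {
      z <- row == 0
      if (!any(z)) return(row)
      row[z] <- delta
      row[!z] <- row[!z] * (1 - sum(z) * delta) / sum(row[!z])
      row / sum(row)
    }))
  }
  lx <- log(x)
  sweep(lx, 1, rowMeans(lx), "-")
}

#' Covariance PCA of clr coordinates
#'
#' Column-centered, unscaled PCA of the clr matrix.  Eigenvalues are
#' reported as percentages of total variance (`eigen_pct`), the scale on
#' which the network's category rule operates.  A deterministic sign
#' convention is applied: on each axis the loading entry of largest
#' magnitude is made positive.
#'
#' @param clr samples-by-substances clr matrix (rows sum to 0).
#' @return An object of class `chc_pca` with elements `scores`, `loadings`,
#'   `eigen_pct`, `center`, `sdev`.
#' @export
pca_clr <- function(clr) {
  if (nrow(clr) < 2) abort("PCA needs at least 2 samples")
  p <- prcomp(clr, center = TRUE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2, flip, "*")
  p$x <- sweep(p$x, 2, flip, "*")
  ev <- p$sdev^2
  structure(
    list(scores = p$x, loadings = p$rotation,
         eigen_pct = 100 * ev / sum(ev), center = p$center,
         sdev = p$sdev),
    class = "chc_pca")
}

#' @export
print.chc_pca <- function(x, ...) {
  cat(sprintf("<chc_pca> %d samples, %d axes\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  variance explained (%):",
      paste(sprintf("%.1f", head(x$eigen_pct, 5)), collapse = ", "),
      if (length(x$eigen_pct) > 5) "..." else "", "\n")
  invisible(x)
}

#' @method tidy chc_pca
#' @export
tidy.chc_pca <- function(x, ...) {
  as_tibble(x$scores, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "axis", values_to = "score")
}

#' @method glance chc_pca
#' @export
glance.chc_pca <- function(x, ...) {
  tibble(n_axes = length(x$eigen_pct),
         pc1_pct = x$eigen_pct[1],
         pc2_pct = if (length(x$eigen_pct) > 1) x$eigen_pct[2] else NA_real_)
}

#' Category counts per retained PC axis
#'
#' Implements the axis-retention/category rule of the chemical-network
#' algorithm on the percentage-of-variance scale: axes explaining less than
#' 5% are dropped; axes between 5% and 10% get two categories; otherwise the
#' category count is the explained percentage divided by 5, rounded
#' (half-to-even).
#'
#' @param eigen_pct numeric vector of per-axis percentages of explained
#'   variance.
#' @return A tibble with columns `axis` (index), `eigen_pct`, `k`.
#' @export
#' @examples
#' axis_categories(c(40, 7, 4.9))  # k = 8, k = 2, dropped
axis_categories <- function(eigen_pct) {
  keep <- which(eigen_pct >= 5)
  if (length(keep) == 0)
    abort("no PC axis explains >= 5% of variance; nothing to retain")
  k <- ifelse(eigen_pct[keep] <= 10, 2L,
              as.integer(round_half_even(eigen_pct[keep] / 5)))
  tibble(axis = keep, eigen_pct = eigen_pct[keep], k = k)
}

#' Discretize PC scores into category sequences
#'
#' Per retained axis, each score is mapped to an integer category by
#' normalizing its distance to the axis minimum by the axis range and
#' scaling to `k - 1` before rounding (half-to-even):
#' `c = round((s - min) / (max - min) * (k - 1))`.  The sample at the axis
#' minimum gets category 0 and the sample at the maximum gets `k - 1`.
#'
#' @param scores samples-by-axes score matrix (already restricted to the
#'   retained axes, in the order of `k_per_axis`).
#' @param k_per_axis integer vector of category counts per axis.
#' @return Integer matrix of categories, same shape as `scores`.
#' @export
discretize_scores <- function(scores, k_per_axis) {
  scores <- as.matrix(scores)
  if (ncol(scores) != length(k_per_axis))
    abort("`k_per_axis` must have one entry per score column")
  out <- matrix(0L, nrow(scores), ncol(scores),
                dimnames = dimnames(scores))
  for (j in seq_len(ncol(scores))) {
    s <- scores[, j]
    rng <- range(s)
    if (diff(rng) == 0)
      abort(sprintf("axis %d is constant (max = min); cannot discretize", j))
    out[, j] <- as.integer(
      round_half_even((s - rng[1]) / diff(rng) * (k_per_axis[j] - 1L)))
  }
  out
}

#' Collapse identical category sequences into chemical types
#'
#' Samples with identical category vectors form one chemical type (the
#' compositional analogue of collapsing identical sequences into
#' haplotypes).  Types are labeled `T1`, `T2`, ... by decreasing membership,
#' ties broken lexicographically by category vector.
#'
#' @param categories integer matrix of category sequences (rows = samples).
#' @return A tibble with columns `type`, `n`, `members` (list-column of
#'   sample ids), `sequence` (list-column of the category vector),
#'   `singleton`.
#' @export
collapse_chemical_types <- function(categories) {
  categories <- as.matrix(categories)
  ids <- rownames(categories) %||% as.character(seq_len(nrow(categories)))
  key <- apply(categories, 1, paste, collapse = "-")
  groups <- split(ids, key)
  seqs <- lapply(names(groups), function(k)
    as.integer(strsplit(k, "-", fixed = TRUE)[[1]]))
  ord <- order(-lengths(groups), names(groups))
  sizes <- unname(lengths(groups)[ord])
  tibble(
    type = paste0("T", seq_along(ord)),
    n = sizes,
    members = unname(groups[ord]),
    sequence = seqs[ord],
    singleton = sizes == 1L)
}

#' Integer L1 distance between category sequences
#'
#' Per axis the (one-dimensional) Euclidean distance between two categories
#' is their absolute difference; the type distance is the sum over axes.
#'
#' @param a,b integer category vectors of equal length.
#' @return A single non-negative integer.
#' @export
type_distance <- function(a, b) {
  if (length(a) != length(b)) abort("category sequences differ in length")
  as.integer(sum(abs(a - b)))
}

type_distance_matrix <- function(types) {
  n <- nrow(types)
  d <- matrix(0L, n, n, dimnames = list(types$type, types$type))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- type_distance(types$sequence[[i]],
                                          types$sequence[[j]])
    }
  }
  d
}

#' Minimum spanning network over node distances
#'
#' Kruskal's algorithm with a deterministic tie-break (edges of equal weight
#' are taken in lexicographic order of their node-label pair), yielding a
#' globally minimal spanning tree.  With `include_alternatives = TRUE`,
#' every non-tree edge whose weight equals the maximum edge weight on the
#' tree path between its endpoints is added as an alternative link, turning
#' the tree into a minimum spanning network.
#'
#' @param nodes tibble of nodes (needs a `type` label column and an `n`
#'   membership count; [collapse_chemical_types()] output works directly),
#'   or a character vector of labels.
#' @param d symmetric non-negative distance matrix over the node labels.
#' @param include_alternatives add equal-cost alternative links?
#' @return An object of class `chem_network`: list with `nodes` (tibble)
#'   and `edges` (tibble `from,to,weight,in_mst,alternative`).
#' @export
build_msn <- function(nodes, d, include_alternatives = FALSE) {
  if (is.character(nodes)) nodes <- tibble(type = nodes, n = 1L)
  labels <- nodes$type
  stopifnot(nrow(d) == length(labels))
  assert_symmetric_dist(d)
  dimnames(d) <- list(labels, labels)
  n <- length(labels)
  edges <- tibble(from = character(), to = character(), weight = numeric(),
                  in_mst = logical(), alternative = logical())
  if (n > 1) {
    idx <- which(upper.tri(d), arr.ind = TRUE)
    cand <- tibble(from = labels[idx[, 1]], to = labels[idx[, 2]],
                   weight = d[idx])
    cand <- arrange(cand, .data$weight, .data$from, .data$to)
    parent <- seq_len(n); names(parent) <- labels
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    in_mst <- logical(nrow(cand))
    for (e in seq_len(nrow(cand))) {
      ri <- find(match(cand$from[e], labels))
      rj <- find(match(cand$to[e], labels))
      if (ri != rj) { parent[ri] <- rj; in_mst[e] <- TRUE }
    }
    edges <- mutate(cand, in_mst = in_mst, alternative = FALSE)
    if (include_alternatives && any(!in_mst)) {
      g <- igraph::graph_from_data_frame(
        edges[edges$in_mst, c("from", "to", "weight")],
        directed = FALSE, vertices = labels)
      for (e in which(!in_mst)) {
        path <- igraph::shortest_paths(
          g, edges$from[e], edges$to[e], weights = NA,
          output = "epath")$epath[[1]]
        if (length(path) > 0 &&
            max(igraph::E(g)$weight[as.integer(path)]) == edges$weight[e])
          edges$alternative[e] <- TRUE
      }
    }
    edges <- edges[edges$in_mst | edges$alternative, ]
  }
  structure(list(nodes = nodes, edges = edges), class = "chem_network")
}

#' @export
print.chem_network <- function(x, ...) {
  cat(sprintf("<chem_network> %d nodes, %d edges (%d MST, %d alternative)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$in_mst),
              sum(x$edges$alternative)))
  invisible(x)
}

#' @method tidy chem_network
#' @export
tidy.chem_network <- function(x, ...) x$edges

#' @method glance chem_network
#' @export
glance.chem_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes),
         n_singletons = sum(x$nodes$n == 1L),
         mst_weight = sum(x$edges$weight[x$edges$in_mst]))
}

#' Chemical network of CHC chemotypes
#'
#' Runs the full chemical-network algorithm on a closed CHC composition:
#' clr transformation, covariance PCA, axis retention and category counts
#' from percent variance explained, per-axis discretization of scores,
#' collapsing of identical category sequences into chemical types, integer
#' L1 distances between types, and a minimum spanning network over the
#' types.
#'
#' @param x a [peak_table()] or closed composition matrix.
#' @param include_alternatives add equal-cost alternative links to the MST?
#' @param zero_strategy,delta passed to [clr_transform()].
#' @return A `chem_network` with extra elements `pca` (the [pca_clr()]
#'   fit), `axes` (the [axis_categories()] tibble), `assignments` (tibble
#'   `sample`, `type`) and `distances` (type distance matrix).
#' @export
#' @examples
#' pt <- gen_chc_profiles(scenario_config(seed = 1))
#' net <- chemical_network(pt)
#' glance(net)
chemical_network <- function(x, include_alternatives = FALSE,
                             zero_strategy = "multiplicative",
                             delta = 1e-5) {
  clr <- clr_transform(x, zero_strategy = zero_strategy, delta = delta)
  pca <- pca_clr(clr)
  axes <- axis_categories(pca$eigen_pct)
  cats <- discretize_scores(pca$scores[, axes$axis, drop = FALSE], axes$k)
  types <- collapse_chemical_types(cats)
  d <- type_distance_matrix(types)
  net <- build_msn(types, d, include_alternatives = include_alternatives)
  net$pca <- pca
  net$axes <- axes
  net$assignments <- tibble(
    sample = unlist(types$members),
    type = rep(types$type, types$n))
  net$distances <- d
  net
}

#' Partition a network by cutting its heaviest MST edges
#'
#' Removes the `n_cut` largest-weight MST edges (deterministic tie-break by
#' label pair) and returns the resulting connected components — the
#' network-based cluster assignment used to compare chemotypes against
#' ground truth.
#'
#' @param net a `chem_network` from [chemical_network()] or [build_msn()].
#' @param n_cut number of heaviest edges to remove (default 1).
#' @return A tibble `type`, `component`; if the network carries sample
#'   assignments, also a `sample`-level tibble in attribute `"samples"`
#'   (and merged in when available).
#' @export
cut_network <- function(net, n_cut = 1) {
  stopifnot(inherits(net, "chem_network"))
  mst <- net$edges[net$edges$in_mst, ]
  mst <- arrange(mst, dplyr::desc(.data$weight), .data$from, .data$to)
  keep <- mst[-seq_len(min(n_cut, nrow(mst))), ]
  g <- igraph::graph_from_data_frame(keep[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = net$nodes$type)
  comp <- igraph::components(g)$membership
  out <- tibble(type = names(comp), component = as.integer(comp))
  if (!is.null(net$assignments))
    out <- left_join(net$assignments, out, by = "type")
  out
}

#' Export a chemical network
#'
#' @param net a `chem_network`.
#' @param graphml,nodes_csv,edges_csv optional output paths; GraphML via
#'   igraph, CSV node/edge lists via readr.
#' @return Invisibly, the igraph representation.
#' @export
write_network <- function(net, graphml = NULL, nodes_csv = NULL,
                          edges_csv = NULL) {
  stopifnot(inherits(net, "chem_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "weight")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes$type, size = net$nodes$n))
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(nodes_csv))
    readr::write_csv(select(net$nodes, -dplyr::any_of(c("members",
                                                        "sequence"))),
                     nodes_csv)
  if (!is.null(edges_csv)) readr::write_csv(net$edges, edges_csv)
  invisible(g)
}

#' @describeIn chemical_network ggplot of the network: nodes sized by
#'   membership, MST edges solid, alternative links dashed, hatch-mark
#'   counts (= edge weight) as labels.
#' @param object a `chem_network`.
#' @param ... unused.
#' @method autoplot chem_network
#' @export
autoplot.chem_network <- function(object, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges[, c("from", "to", "weight")], directed = FALSE,
    vertices = object$nodes$type)
  set.seed(1)
  xy <- igraph::layout_with_fr(g)
  pos <- tibble(type = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  nd <- left_join(object$nodes, pos, by = "type")
  ed <- object$edges |>
    left_join(rename(pos, xf = "x", yf = "y"), by = c(from = "type")) |>
    left_join(rename(pos, xt = "x", yt = "y"), by = c(to = "type"))
  ggplot() +
    ggplot2::geom_segment(
      data = ed,
      aes(x = .data$xf, y = .data$yf, xend = .data$xt, yend = .data$yt,
          linetype = .data$alternative)) +
    ggplot2::geom_label(
      data = mutate(ed, mx = (.data$xf + .data$xt) / 2,
                    my = (.data$yf + .data$yt) / 2),
      aes(x = .data$mx, y = .data$my, label = .data$weight), size = 2.5) +
    ggplot2::geom_point(data = nd,
                        aes(x = .data$x, y = .data$y, size = .data$n)) +
    ggplot2::geom_text(data = nd,
                       aes(x = .data$x, y = .data$y, label = .data$type),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_linetype_manual(
      values = c(`FALSE` = "solid", `TRUE` = "dashed"), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(size = "colonies")
}
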