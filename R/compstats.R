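#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` between non-negative
#' abundance rows; in \[0, 1\] with 0 for identical rows and 1 for disjoint
#' supports.
#'
#' @param x a [peak_table()] or non-negative samples-by-variables matrix.
#' @return Symmetric matrix with zero diagonal and the sample ids as
#'   dimnames.
#' @export
bray_curtis <- function(x) {
  if (inherits(x, "peak_table")) x <- x$abundance
  if (any(x < 0)) abort("Bray-Curtis needs non-negative data")
  zero <- rowSums(x) == 0
  if (sum(zero) >= 2)
    abort(sprintf(
      "Bray-Curtis undefined for all-zero sample pairs (e.g. '%s', '%s')",
      rownames(x)[which(zero)[1]], rownames(x)[which(zero)[2]]))
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance for a single grouping
#' factor.  With `SS_total = (1/n) * sum_{i<j} d_ij^2` and
#' `SS_within = sum_g (1/n_g) * sum_{i<j in g} d_ij^2`, the statistic is
#' `pseudo_F = ((SS_total - SS_within)/(g - 1)) / (SS_within/(n - g))` and
#' the p-value counts whole-row label permutations with `F >= F_obs`, with
#' the add-one convention `p = (1 + #exceed) / (n_perm + 1)`.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param groups group label per row of `d` (>= 2 groups).
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return A one-row tibble: `pseudo_F`, `df_between`, `df_within`, `p`,
#'   `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  assert_symmetric_dist(d)
  groups <- as.factor(groups)
  n <- nrow(d)
  if (length(groups) != n) abort("one group label per sample required")
  g <- nlevels(droplevels(groups))
  if (g < 2) abort("PERMANOVA needs >= 2 groups")
  if (n - g <= 0) abort("no residual degrees of freedom (n - g <= 0)")
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  f_stat <- function(lab) {
    ss_within <- 0
    for (lev in levels(lab)) {
      idx <- which(lab == lev)
      if (length(idx) > 1)
        ss_within <- ss_within +
          sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
  }
  obs <- f_stat(groups)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(i) f_stat(sample(groups)) >= obs, logical(1)))
  })
  tibble(pseudo_F = obs, df_between = g - 1L, df_within = n - g,
         p = (1 + exceed) / (n_perm + 1), n_perm = as.integer(n_perm))
}

#' Jitter substance classes that are absent from several samples
#'
#' PERMANOVA on class aggregates cannot handle pairs of samples at zero
#' distance; classes that are absent from several samples produce such
#' pairs.  This adds minute normally distributed random numbers (mean and
#' sd 1e-8, truncated at zero) to the affected class columns for *all*
#' samples so no two rows are exactly identical.
#'
#' @param x wide numeric data frame/tibble or matrix of per-sample class
#'   abundances (id columns are left untouched).
#' @param classes character vector of class columns to jitter; `NULL`
#'   (default) auto-detects columns that are zero in more than one sample.
#' @param mean,sd parameters of the normal jitter (defaults 1e-8).
#' @param seed optional integer seed.
#' @return The input with jitter added to the selected columns.
#' @export
jitter_zero_classes <- function(x, classes = NULL, mean = 1e-8, sd = 1e-8,
                                seed = NULL) {
  is_df <- is.data.frame(x)
  num_cols <- if (is_df) names(x)[vapply(x, is.numeric, logical(1))]
              else colnames(x)
  if (is.null(classes)) {
    classes <- num_cols[vapply(num_cols, function(cl) {
      v <- if (is_df) x[[cl]] else x[, cl]
      sum(v == 0) > 1
    }, logical(1))]
  }
  if (length(classes) == 0) return(x)
  n <- if (is_df) nrow(x) else nrow(x)
  with_seed(seed, {
    for (cl in classes) {
      eps <- pmax(rnorm(n, mean, sd), 0)
      if (is_df) x[[cl]] <- x[[cl]] + eps else x[, cl] <- x[, cl] + eps
    }
  })
  x
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries, with a
#' one-sided (greater) permutation p-value obtained by jointly permuting
#' rows and columns of the second matrix;
#' `p = (1 + #{r_perm >= r}) / (n_perm + 1)`.
#'
#' @param d1,d2 symmetric distance matrices over the same ids in the same
#'   order (n >= 4).
#' @param n_perm number of permutations (default 9999).
#' @param seed optional integer seed.
#' @return A one-row tibble: `r`, `p`, `n_perm`, `n`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  assert_symmetric_dist(d1, "d1"); assert_symmetric_dist(d2, "d2")
  n <- nrow(d1)
  if (nrow(d2) != n) abort("distance matrices differ in size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    abort("distance matrix ids do not match")
  if (n < 4) abort("Mantel test needs n >= 4")
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  if (sd(v1) == 0 || sd(d2[lt]) == 0)
    abort("zero variance in a distance triangle")
  obs <- cor(v1, d2[lt])
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      pr <- sample.int(n)
      cor(v1, d2[pr, pr][lt]) >= obs
    }, logical(1)))
  })
  tibble(r = obs, p = (1 + exceed) / (n_perm + 1),
         n_perm = as.integer(n_perm), n = n)
}

#' Euclidean geographic distances from GPS coordinates
#'
#' Plain Euclidean distance in degree space between longitude/latitude
#' pairs (the convention used for the isolation-by-distance Mantel tests);
#' a great-circle option is available but off by default.
#'
#' @param lon,lat numeric coordinate vectors (degrees), or a data frame
#'   with `lon`/`lat` columns as first argument.
#' @param ids optional labels for the dimnames.
#' @param method `"euclidean"` (default) or `"greatcircle"` (km, haversine).
#' @return Symmetric distance matrix.
#' @export
geo_distance <- function(lon, lat = NULL, ids = NULL,
                         method = c("euclidean", "greatcircle")) {
  method <- match.arg(method)
  if (is.data.frame(lon)) {
    df <- lon
    ids <- ids %||% df[["sample"]] %||% rownames(df)
    lat <- df[["lat"]]; lon <- df[["lon"]]
  }
  if (anyNA(lon) || anyNA(lat)) abort("missing coordinates")
  if (method == "euclidean") {
    d <- as.matrix(dist(cbind(lon, lat)))
  } else {
    n <- length(lon)
    rad <- pi / 180
    d <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j) {
        dl <- (lon[j] - lon[i]) * rad; dp <- (lat[j] - lat[i]) * rad
        a <- sin(dp / 2)^2 +
          cos(lat[i] * rad) * cos(lat[j] * rad) * sin(dl / 2)^2
        d[i, j] <- d[j, i] <- 6371 * 2 * asin(pmin(1, sqrt(a)))
      }
    }
  }
  if (!is.null(ids)) dimnames(d) <- list(ids, ids)
  d
}
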