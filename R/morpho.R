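#' Measurement reliability by intraclass correlation
#'
#' One-way random-effects ICC(1,1) per variable from repeated measurements:
#' `ICC = (MS_between - MS_within) / (MS_between + (k - 1) * MS_within)`
#' with `k` repeats per individual.  Variables with ICC below `threshold`
#' (default 0.85) are flagged for removal.
#'
#' @param data long tibble with columns `individual`, `rep`, `variable`,
#'   `value` (output of [gen_morphometrics()] or equivalent CSV).
#' @param threshold reliability cut-off (default 0.85).
#' @return A tibble `variable`, `icc`, `k`, `n_individuals`, `keep`.
#' @export
icc_reliability <- function(data, threshold = 0.85) {
  data <- as_tibble(data)
  need <- c("individual", "rep", "variable", "value")
  if (!all(need %in% names(data)))
    abort("`data` needs columns individual, rep, variable, value")
  out <- data |>
    group_by(.data$variable) |>
    summarise(res = list({
      df <- dplyr::pick(dplyr::everything())
      counts <- table(df$individual)
      if (length(counts) < 2 || any(counts < 2))
        abort("ICC needs >= 2 repeats for >= 2 individuals per variable")
      if (var(df$value) == 0) {
        tibble(icc = 1, k = as.numeric(counts[1]),
               n_individuals = length(counts))
      } else {
        k <- mean(counts)  # balanced designs expected
        fit <- aov(value ~ factor(individual), data = df)
        ms <- summary(fit)[[1]][["Mean Sq"]]
        tibble(icc = (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2]),
               k = k, n_individuals = length(counts))
      }
    }), .groups = "drop") |>
    tidyr::unnest("res") |>
    mutate(keep = .data$icc >= threshold)
  out
}

#' Average technical repeats into a wide measurement matrix
#'
#' Replaces each individual/variable pair by the mean of its repeats and
#' optionally drops unreliable variables.
#'
#' @param data long tibble as in [icc_reliability()]; extra metadata
#'   columns (`species`, `location`) are carried through.
#' @param keep optional character vector of variables to retain (e.g.
#'   `icc_reliability(data)$variable[icc_reliability(data)$keep]`).
#' @return A wide tibble: one row per individual, metadata columns, then
#'   one column per measurement variable.
#' @export
average_repeats <- function(data, keep = NULL) {
  data <- as_tibble(data)
  if (!is.null(keep)) data <- filter(data, .data$variable %in% keep)
  meta_cols <- intersect(c("species", "location"), names(data))
  meta <- distinct(data, dplyr::across(dplyr::all_of(c("individual",
                                                       meta_cols))))
  wide <- data |>
    group_by(.data$individual, .data$variable) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value")
  left_join(meta, wide, by = "individual")
}

measurement_matrix <- function(data) {
  if (is.matrix(data)) return(data)
  data <- as_tibble(data)
  num <- vapply(data, is.numeric, logical(1))
  m <- as.matrix(data[num])
  rn <- data[["individual"]] %||% rownames(data)
  if (!is.null(rn)) rownames(m) <- rn
  m
}

#' Isometric size: the geometric mean of an individual's measurements
#'
#' @param data wide tibble or matrix of positive measurements (numeric
#'   columns are used; an `individual` column provides names).
#' @return Named numeric vector of geometric means,
#'   `g = (prod x_j)^(1/p) = exp(mean(log x))`.
#' @export
#' @examples
#' isometric_size(matrix(c(2, 8), 1))  # 4
isometric_size <- function(data) {
  m <- measurement_matrix(data)
  if (any(m <= 0)) abort("non-positive measurement; geometric mean undefined")
  exp(rowMeans(log(m)))
}

#' Shape PCA: principal components orthogonal to isometric size
#'
#' Log-transforms the measurements, projects each individual onto the
#' orthocomplement of the isometric direction `u = (1, ..., 1)/sqrt(p)`,
#' and performs covariance PCA of the projected data.  Shape scores are
#' exactly invariant to multiplying any individual's raw measurements by a
#' positive constant, so body shape is compared irrespective of isometric
#' body size.  Sign convention as in [pca_clr()].
#'
#' @param data wide tibble or matrix of positive measurements (>= 3
#'   individuals, >= 2 variables).
#' @return An object of class `shape_pca`: `iso_size`, `log_iso_size`,
#'   `scores`, `loadings`, `eigen_pct`, `center`, plus the metadata columns
#'   of `data` in `$meta`.
#' @export
shape_pca <- function(data) {
  m <- measurement_matrix(data)
  if (nrow(m) < 3) abort("shape PCA needs >= 3 individuals")
  if (ncol(m) < 2) abort("shape PCA needs >= 2 variables")
  if (any(m <= 0)) abort("non-positive measurement")
  lx <- log(m)
  p <- ncol(lx)
  # remove the isometric component row-wise: subtract each row's mean
  # (projection onto the complement of u = 1/sqrt(p))
  shape <- sweep(lx, 1, rowMeans(lx), "-")
  pc <- prcomp(shape, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  ev <- pc$sdev^2
  meta <- if (is.data.frame(data)) {
    data[!vapply(data, is.numeric, logical(1))]
  } else NULL
  structure(
    list(iso_size = exp(rowMeans(lx)), log_iso_size = rowMeans(lx),
         scores = pc$x, loadings = pc$rotation,
         eigen_pct = 100 * ev / sum(ev), center = pc$center,
         log_data = lx, meta = meta),
    class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("<shape_pca> %d individuals, %d variables\n",
              nrow(x$scores), nrow(x$loadings)))
  cat("  shape variance explained (%):",
      paste(sprintf("%.1f", head(x$eigen_pct, 4)), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy shape_pca
#' @export
tidy.shape_pca <- function(x, ...) {
  out <- as_tibble(x$scores[, 1:min(4, ncol(x$scores)), drop = FALSE],
                   rownames = "individual") |>
    mutate(iso_size = unname(x$iso_size))
  if (!is.null(x$meta)) out <- bind_cols(out, as_tibble(x$meta))
  out
}

#' @method glance shape_pca
#' @export
glance.shape_pca <- function(x, ...) {
  tibble(n = nrow(x$scores), p = nrow(x$loadings),
         shape_pc1_pct = x$eigen_pct[1], shape_pc2_pct = x$eigen_pct[2])
}

#' PCA ratio spectrum of a shape axis
#'
#' Orders the variables by their loading on one shape PC; the ratio of the
#' two extreme variables is the axis's best single-ratio interpretation.
#' Percentile bootstrap confidence intervals (default 68%, 1,000
#' replicates) are obtained by resampling individuals, refitting the shape
#' PCA and re-extracting the axis loadings with the sign aligned to the
#' original axis (dot-product sign).
#'
#' @param sp a fitted [shape_pca()].
#' @param axis which shape PC (default 1).
#' @param n_boot bootstrap replicates; 0 gives point estimates only.
#' @param conf CI coverage (default 0.68).
#' @param seed optional integer seed.
#' @return A tibble ordered by loading: `variable`, `loading`, `lower`,
#'   `upper` (CIs `NA` when `n_boot = 0`).
#' @export
pca_ratio_spectrum <- function(sp, axis = 1, n_boot = 1000, conf = 0.68,
                               seed = NULL) {
  stopifnot(inherits(sp, "shape_pca"))
  if (axis < 1 || axis > ncol(sp$loadings))
    abort(sprintf("axis %d out of range (1..%d)", axis, ncol(sp$loadings)))
  ref <- sp$loadings[, axis]
  lower <- upper <- rep(NA_real_, length(ref))
  if (n_boot > 0) {
    m <- exp(sp$log_data)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(m), replace = TRUE)
        fit <- try(shape_pca(m[idx, , drop = FALSE]), silent = TRUE)
        if (inherits(fit, "try-error")) return(ref)
        v <- fit$loadings[, axis]
        v * sign(sum(v * ref))
      }, numeric(length(ref)))
    })
    qs <- apply(boots, 1, quantile,
                probs = c((1 - conf) / 2, 1 - (1 - conf) / 2))
    lower <- qs[1, ]; upper <- qs[2, ]
  }
  tibble(variable = names(ref), loading = unname(ref),
         lower = unname(lower), upper = unname(upper)) |>
    arrange(dplyr::desc(.data$loading))
}

#' Two-factor MANOVA on shape scores
#'
#' Additive two-factor MANOVA (species + location) on the first shape PCs,
#' using Pillai's trace with its standard F approximation and sequential
#' (type-I) sums of squares with species entered first.
#'
#' @param scores numeric matrix/data frame of response columns (e.g. the
#'   first two shape PCs).
#' @param species,location factors, one value per row of `scores`;
#'   `location` may be `NULL` for a one-factor analysis.
#' @return A tibble with one row per factor: `term`, `pillai`, `df`,
#'   `approx_F`, `num_df`, `den_df`, `p`.
#' @export
shape_manova <- function(scores, species, location = NULL) {
  y <- as.matrix(scores)
  if (ncol(y) < 2) abort("MANOVA needs >= 2 response columns")
  species <- droplevels(as.factor(species))
  df <- data.frame(species = species)
  form <- y ~ species
  if (!is.null(location)) {
    df$location <- droplevels(as.factor(location))
    form <- y ~ species + location
  }
  fit <- manova(form, data = df)
  s <- summary(fit, test = "Pillai")$stats
  terms_kept <- setdiff(rownames(s), "Residuals")
  tibble(term = terms_kept,
         pillai = s[terms_kept, "Pillai"],
         df = s[terms_kept, "Df"],
         approx_F = s[terms_kept, "approx F"],
         num_df = s[terms_kept, "num Df"],
         den_df = s[terms_kept, "den Df"],
         p = s[terms_kept, "Pr(>F)"])
}

#' Welch two-sample t test
#'
#' Welch statistic with Satterthwaite degrees of freedom, two-sided; used
#' to compare isometric size between cryptic species.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @return A one-row tibble: `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("need >= 2 values per group")
  if (var(x) == 0 && var(y) == 0)
    abort("zero variance in both groups; t undefined")
  ht <- t.test(x, y, var.equal = FALSE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' @describeIn shape_pca scatter plot of a shape PC against isometric size,
#'   colored by the first metadata factor if present.
#' @param object a `shape_pca`.
#' @param pc which shape PC to plot on the y axis.
#' @param ... unused.
#' @method autoplot shape_pca
#' @export
autoplot.shape_pca <- function(object, pc = 1, ...) {
  df <- tidy(object)
  pc_col <- paste0("PC", pc)
  aes_args <- aes(x = .data$iso_size, y = .data[[pc_col]])
  gg <- ggplot(df, aes_args)
  if (!is.null(object$meta) && "species" %in% names(df)) {
    gg <- gg + ggplot2::geom_point(aes(colour = .data$species,
                                       shape = .data$species))
  } else {
    gg <- gg + ggplot2::geom_point()
  }
  gg + ggplot2::labs(x = "isometric size (geometric mean, µm)",
                     y = sprintf("shape PC%d", pc)) +
    ggplot2::theme_minimal()
}
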