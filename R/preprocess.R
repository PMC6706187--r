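#' Linear (temperature-programmed) retention index
#'
#' Converts a retention time into a Kovats-style retention index against an
#' n-alkane ladder using the linear van den Dool-Kratz form appropriate for
#' temperature-programmed GC runs:
#' `RI = 100 * (n + (rt - rt_n) / (rt_{n+1} - rt_n))` for the bracketing
#' standards with carbon numbers `n` and `n+1`.
#'
#' @param rt retention time(s) in minutes; must lie within the ladder span.
#' @param alkane_ladder data frame with columns `carbon` and `rt`, one row
#'   per n-alkane standard; `rt` must be strictly increasing with `carbon`.
#' @return Numeric vector of retention indices (100 units per carbon).
#' @export
#' @examples
#' ladder <- data.frame(carbon = c(25, 26), rt = c(10, 12))
#' kovats_index(11.5, ladder)  # 2575
kovats_index <- function(rt, alkane_ladder) {
  ld <- as_tibble(alkane_ladder)
  if (!all(c("carbon", "rt") %in% names(ld)))
    abort("`alkane_ladder` needs columns `carbon` and `rt`")
  ld <- arrange(ld, .data$carbon)
  if (nrow(ld) < 2) abort("ladder needs at least two standards")
  if (any(diff(ld$rt) <= 0))
    abort("ladder retention times must be strictly increasing")
  vapply(rt, function(t1) {
    if (is.na(t1) || t1 < ld$rt[1] || t1 > ld$rt[nrow(ld)])
      abort(sprintf("rt = %s outside ladder span [%g, %g]",
                    format(t1), ld$rt[1], ld$rt[nrow(ld)]))
    i <- max(which(ld$rt <= t1))
    if (i == nrow(ld)) i <- i - 1L
    100 * (ld$carbon[i] +
             (ld$carbon[i + 1] - ld$carbon[i]) *
             (t1 - ld$rt[i]) / (ld$rt[i + 1] - ld$rt[i]))
  }, numeric(1))
}

#' Parse shorthand CHC substance names
#'
#' Understands the compact naming grammar used for cuticular hydrocarbons:
#' `C<chain>` (n-alkane), `C<chain>:<db>` (unsaturated), and methyl-branch
#' prefixes `<pos>(,<pos>)*-Me|DiMe|TriMe` as in `"13-MeC29"`,
#' `"13,23-DiMeC37"` or `"13-MeC37:1"`.  The grammar (EBNF) is:
#'
#' ```
#' name     = [ positions "-" branch ] "C" chain [ ":" dbonds ]
#' positions = integer { "," integer }
#' branch   = "Me" | "DiMe" | "TriMe"
#' ```
#'
#' @param name character vector of shorthand names.
#' @return A tibble with columns `name`, `chain_length`, `n_methyl`,
#'   `n_double_bonds`, `class`.
#' @export
#' @examples
#' parse_substance_name(c("C29", "13,23-DiMeC37", "13-MeC37:1"))
parse_substance_name <- function(name) {
  pat <- "^(?:(\\d+(?:,\\d+)*)-(Me|DiMe|TriMe))?C(\\d+)(?::(\\d+))?$"
  m <- regmatches(name, regexec(pat, name))
  rows <- purrr::map2(name, m, function(nm, parts) {
    if (length(parts) == 0) {
      bad <- regexpr("[^0-9A-Za-z,:-]|^$", nm)
      abort(sprintf(
        "cannot parse substance name '%s' (first offending position: %d)",
        nm, max(1L, bad)))
    }
    positions <- parts[2]; branch <- parts[3]
    chain <- as.integer(parts[4])
    db <- if (nzchar(parts[5])) as.integer(parts[5]) else 0L
    n_me <- if (!nzchar(branch)) 0L else
      c(Me = 1L, DiMe = 2L, TriMe = 3L)[[branch]]
    if (nzchar(positions)) {
      npos <- length(strsplit(positions, ",", fixed = TRUE)[[1]])
      if (npos != n_me)
        abort(sprintf(
          "name '%s': %d branch position(s) but prefix implies %d",
          nm, npos, n_me))
    }
    tibble(name = nm, chain_length = chain, n_methyl = n_me,
           n_double_bonds = db,
           class = substance_class(n_me, db))
  })
  bind_rows(rows)
}

#' Close rows of an abundance matrix to proportions
#'
#' Divides each sample row by its total so rows sum to one.  Closure is
#' idempotent and scale-invariant; it is required before clr transformation
#' and before the proportion-based filtering thresholds apply.
#'
#' @param x a [peak_table()] or a non-negative numeric matrix.
#' @return Same shape as the input with closed rows (a `peak_table` stays a
#'   `peak_table`).
#' @export
normalize_closure <- function(x) {
  if (inherits(x, "peak_table")) {
    x$abundance <- normalize_closure(x$abundance)
    return(x)
  }
  totals <- rowSums(x)
  zero <- which(totals <= 0)
  if (length(zero) > 0)
    abort(sprintf("sample '%s' has zero total abundance",
                  rownames(x)[zero[1]] %||% as.character(zero[1])))
  sweep(x, 1, totals, "/")
}

#' Filter substances by the abundance/presence rules
#'
#' Applies the standard CHC inclusion rules on closed proportions:
#' non-hydrocarbons are always removed; a hydrocarbon is removed only if in
#' *every* chemotype group its mean proportion is below `min_mean` *or* its
#' presence (fraction of samples with non-zero abundance) is below
#' `min_presence` — i.e. a substance passing both thresholds in at least one
#' group is kept for all samples.  Exception: substances with two or more
#' double bonds are retained whenever any retained unsaturated substance
#' (>= 1 double bond) of the same chain length exists, because double-bond
#' counts can vary between colonies.
#'
#' @param pt a [peak_table()]; rows are closed to proportions internally.
#' @param groups factor/character of group (chemotype) labels, one per
#'   sample, or the name of a column of `pt$samples`.
#' @param min_mean minimum within-group mean proportion (default 0.001,
#'   i.e. 0.1%).
#' @param min_presence minimum within-group presence fraction (default 0.20).
#' @return The filtered `peak_table` (rows re-closed), with a
#'   `filter_report` attribute: a tibble of dropped/kept substances and the
#'   reason.  Retrieve it with [filter_report()].
#' @export
filter_substances <- function(pt, groups, min_mean = 0.001,
                              min_presence = 0.20) {
  stopifnot(inherits(pt, "peak_table"))
  if (is.character(groups) && length(groups) == 1 &&
      groups %in% names(pt$samples))
    groups <- pt$samples[[groups]]
  if (length(groups) != nrow(pt$abundance))
    abort("`groups` must supply one label per sample")
  if (anyNA(groups)) abort("missing group label(s)")
  prop <- normalize_closure(pt$abundance)
  sub <- pt$substances
  is_hc <- sub$class != "non-hydrocarbon"

  gl <- split(seq_len(nrow(prop)), groups)
  pass_any <- rep(FALSE, ncol(prop))
  for (idx in gl) {
    gm <- colMeans(prop[idx, , drop = FALSE])
    pres <- colMeans(prop[idx, , drop = FALSE] > 0)
    pass_any <- pass_any | (gm >= min_mean & pres >= min_presence)
  }
  keep <- is_hc & pass_any

  # polyunsaturated exception: keep >=2 double bonds if a retained
  # unsaturated substance of the same chain length exists
  rescued <- rep(FALSE, ncol(prop))
  repeat {
    unsat_chains <- unique(sub$chain_length[keep & sub$n_double_bonds >= 1])
    cand <- is_hc & !keep & sub$n_double_bonds >= 2 &
      sub$chain_length %in% unsat_chains
    if (!any(cand)) break
    keep[cand] <- TRUE
    rescued[cand] <- TRUE
  }

  if (!any(keep)) abort("all substances dropped by filtering")
  reason <- dplyr::case_when(
    !is_hc ~ "non-hydrocarbon",
    rescued ~ "kept: polyunsaturated exception",
    keep ~ "kept: passes thresholds in >= 1 group",
    .default = "below mean/presence thresholds in all groups")
  report <- tibble(id = sub$id, name = sub$name, class = sub$class,
                   chain_length = sub$chain_length, kept = keep,
                   reason = reason)
  out <- peak_table(
    normalize_closure(pt$abundance[, keep, drop = FALSE]),
    sub[keep, ], pt$samples)
  attr(out, "filter_report") <- report
  out
}

#' @rdname filter_substances
#' @export
filter_report <- function(pt) attr(pt, "filter_report")

#' Aggregate a composition by substance class and chain length
#'
#' Pools the closed proportions of each sample by (class, chain length),
#' the summary used to compare chemotype profiles class by class.  Total
#' abundance is conserved: each sample's aggregate sums to 1.
#'
#' @param pt a [peak_table()] with closed rows (closure is applied if
#'   needed).
#' @param groups optional group labels (or a `pt$samples` column name); if
#'   given, group means are included in the result.
#' @return A tibble with columns `sample`, `class`, `chain_length`,
#'   `proportion` (and `group`, `group_mean` when `groups` is supplied).
#' @export
aggregate_by_class <- function(pt, groups = NULL) {
  stopifnot(inherits(pt, "peak_table"))
  if (anyNA(pt$substances$class) || anyNA(pt$substances$chain_length))
    abort("unannotated substance (missing class or chain length)")
  long <- tidy(normalize_closure(pt))
  agg <- long |>
    group_by(.data$sample, .data$class, .data$chain_length) |>
    summarise(proportion = sum(.data$abundance), .groups = "drop")
  if (!is.null(groups)) {
    if (is.character(groups) && length(groups) == 1 &&
        groups %in% names(pt$samples))
      groups <- pt$samples[[groups]]
    gmap <- tibble(sample = rownames(pt$abundance),
                   group = as.character(groups))
    agg <- left_join(agg, gmap, by = "sample") |>
      group_by(.data$group, .data$class, .data$chain_length) |>
      mutate(group_mean = mean(.data$proportion)) |>
      ungroup()
  }
  agg
}

#' Per-sample class totals (summed over chain lengths)
#'
#' @param pt a [peak_table()].
#' @return A wide tibble: one row per sample, one column per substance
#'   class, entries summing to 1 per row.
#' @export
class_totals <- function(pt) {
  aggregate_by_class(pt) |>
    group_by(.data$sample, .data$class) |>
    summarise(proportion = sum(.data$proportion), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "class", values_from = "proportion",
                       values_fill = 0)
}
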