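#' CHC substance classes
#'
#' The nine recognized annotation classes: the eight hydrocarbon classes
#' found on ant cuticles (straight-chain alkanes, mono-/di-/trimethyl
#' alkanes, alkenes with one to three double bonds, and methyl-branched
#' alkenes) plus `"non-hydrocarbon"` for co-eluting polar substances that
#' are always removed by [filter_substances()].
#'
#' @return Character vector of class names.
#' @export
substance_classes <- function() {
  c("n-alkane", "monomethyl alkane", "dimethyl alkane", "trimethyl alkane",
    "alkene", "alkadiene", "alkatriene", "methyl-branched alkene",
    "non-hydrocarbon")
}

#' Infer the substance class from structural counts
#'
#' @param n_methyl number of methyl branches (0-3+).
#' @param n_double_bonds number of C=C double bonds (0-3).
#' @param hydrocarbon logical; `FALSE` forces `"non-hydrocarbon"`.
#' @return Character vector of classes, consistent with the annotation
#'   invariant: saturated unbranched chains are n-alkanes, branched
#'   unsaturated chains are methyl-branched alkenes, and so on.
#' @export
#' @examples
#' substance_class(0, 0)  # "n-alkane"
#' substance_class(2, 0)  # "dimethyl alkane"
#' substance_class(1, 1)  # "methyl-branched alkene"
substance_class <- function(n_methyl, n_double_bonds, hydrocarbon = TRUE) {
  stopifnot(length(n_methyl) == length(n_double_bonds))
  out <- character(length(n_methyl))
  for (i in seq_along(out)) {
    m <- n_methyl[i]; d <- n_double_bonds[i]
    out[i] <- if (!isTRUE(hydrocarbon[min(i, length(hydrocarbon))])) {
      "non-hydrocarbon"
    } else if (d == 0 && m == 0) {
      "n-alkane"
    } else if (d == 0) {
      c("monomethyl alkane", "dimethyl alkane",
        "trimethyl alkane")[min(m, 3L)]
    } else if (m >= 1) {
      "methyl-branched alkene"
    } else {
      c("alkene", "alkadiene", "alkatriene")[min(d, 3L)]
    }
  }
  out
}

#' Construct a peak table
#'
#' A peak table couples a samples-by-substances abundance matrix with a
#' substance annotation table and per-sample metadata; it is the common
#' input of the preprocessing, chemical-network and compositional-statistics
#' stages.
#'
#' @param abundance numeric matrix, samples in rows (rownames = sample ids),
#'   substances in columns (colnames = substance ids); non-negative.
#' @param substances tibble with at least columns `id`, `name`,
#'   `chain_length`, `n_methyl`, `n_double_bonds`, `class`; optional
#'   `rt` (minutes) and `retention_index`.
#' @param samples tibble with at least a `sample` column matching the
#'   abundance rownames; typically also `chemotype`, `population`, `lon`,
#'   `lat`.
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(abundance, substances, samples = NULL) {
  if (!is.matrix(abundance) || !is.numeric(abundance))
    abort("`abundance` must be a numeric matrix")
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    abort("`abundance` must have sample rownames and substance colnames")
  if (anyDuplicated(rownames(abundance)))
    abort("duplicated sample ids in `abundance`")
  if (anyDuplicated(colnames(abundance)))
    abort("duplicated substance ids in `abundance`")
  neg <- which(abundance < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf(
      "negative abundance at sample '%s', substance '%s'",
      rownames(abundance)[neg[1, 1]], colnames(abundance)[neg[1, 2]]))
  }
  substances <- as_tibble(substances)
  need <- c("id", "name", "chain_length", "n_methyl", "n_double_bonds",
            "class")
  miss <- setdiff(need, names(substances))
  if (length(miss) > 0)
    abort(paste0("`substances` lacks column(s): ",
                 paste(miss, collapse = ", ")))
  unannotated <- setdiff(colnames(abundance), substances$id)
  if (length(unannotated) > 0)
    abort(paste0("missing annotation for substance(s): ",
                 paste(unannotated, collapse = ", ")))
  substances <- substances[match(colnames(abundance), substances$id), ]
  if (is.null(samples)) {
    samples <- tibble(sample = rownames(abundance))
  } else {
    samples <- as_tibble(samples)
    if (!"sample" %in% names(samples))
      abort("`samples` must contain a `sample` column")
    if (!setequal(samples$sample, rownames(abundance)))
      abort("`samples$sample` must match the abundance rownames")
    samples <- samples[match(rownames(abundance), samples$sample), ]
  }
  structure(
    list(abundance = abundance, substances = substances, samples = samples),
    class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d samples x %d substances\n",
              nrow(x$abundance), ncol(x$abundance)))
  cat("  classes:",
      paste(unique(x$substances$class), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$abundance)

#' Long tidy view of a peak table
#'
#' @param x a [peak_table()].
#' @param ... unused.
#' @return A tibble with one row per (sample, substance) pair: abundance
#'   plus the substance annotation columns.
#' @method tidy peak_table
#' @export
tidy.peak_table <- function(x, ...) {
  long <- as_tibble(x$abundance, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "id",
                        values_to = "abundance")
  left_join(long, x$substances, by = "id")
}

#' Read / write a peak table as CSV + annotation sidecar
#'
#' The abundance CSV has a `sample` id column followed by one column per
#' substance; the sidecar carries the substance annotations
#' (`id,name,chain_length,n_methyl,n_double_bonds,class,rt`).  Writing then
#' reading reproduces the abundances exactly (values are serialized at full
#' precision).
#'
#' @param peaks_csv path of the abundance CSV.
#' @param annotations_csv path of the substance annotation CSV.
#' @param samples_csv optional path of a sample metadata CSV.
#' @return [read_peak_table()] returns a [peak_table()];
#'   [write_peak_table()] invisibly returns the paths written.
#' @export
read_peak_table <- function(peaks_csv, annotations_csv,
                            samples_csv = NULL) {
  ab <- readr::read_csv(peaks_csv, show_col_types = FALSE)
  if (!"sample" %in% names(ab)) abort("peak CSV must have a `sample` column")
  m <- as.matrix(ab[setdiff(names(ab), "sample")])
  rownames(m) <- ab$sample
  annot <- readr::read_csv(annotations_csv, show_col_types = FALSE)
  samples <- if (!is.null(samples_csv))
    readr::read_csv(samples_csv, show_col_types = FALSE)
  peak_table(m, annot, samples)
}

#' @param pt a [peak_table()].
#' @rdname read_peak_table
#' @export
write_peak_table <- function(pt, peaks_csv, annotations_csv,
                             samples_csv = NULL) {
  stopifnot(inherits(pt, "peak_table"))
  ab <- bind_cols(tibble(sample = rownames(pt$abundance)),
                  as_tibble(pt$abundance))
  readr::write_csv(ab, peaks_csv)
  readr::write_csv(pt$substances, annotations_csv)
  if (!is.null(samples_csv)) readr::write_csv(pt$samples, samples_csv)
  invisible(c(peaks_csv, annotations_csv, samples_csv))
}
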