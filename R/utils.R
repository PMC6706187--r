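# internal helpers shared across modules

# deterministic child seed from a global seed; keeps values < 2^31
child_seed <- function(seed, stage) {
  stages <- c(
    chc = 1L, coi = 2L, morpho = 3L, env = 4L,
    jitter = 5L, permanova = 6L, mantel = 7L, fst = 8L, boot = 9L,
    pipeline = 10L
  )
  k <- stages[[stage]]
  (as.integer(seed) %% 1000003L) * 1009L + k
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# round half to even at integer precision (base round() already does this,
# but make the convention explicit and guard against FP representation noise)
round_half_even <- function(x) round(x + 0, digits = 0)

assert_symmetric_dist <- function(d, arg = "d") {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    abort(sprintf("`%s` must be a square matrix", arg))
  if (max(abs(d - t(d))) > 1e-8)
    abort(sprintf("`%s` must be symmetric", arg))
  if (any(d < -1e-12))
    abort(sprintf("`%s` must be non-negative", arg))
  if (max(abs(diag(d))) > 1e-8)
    abort(sprintf("`%s` must have a zero diagonal", arg))
  invisible(d)
}

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < 1e-12) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Adjusted Rand index between two partitions
#'
#' Measures agreement between two labelings of the same samples, corrected
#' for chance; 1 means identical partitions, values near 0 mean agreement no
#' better than random.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
adjusted_rand_index <- function(a, b) ari(a, b)
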