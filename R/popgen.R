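# COI population genetics: haplotypes, networks, TN93, PhiST, Tajima's D.

aln_char <- function(aln) {
  if (inherits(aln, "DNAbin")) {
    m <- as.character(as.matrix(aln))
  } else if (is.matrix(aln) && is.character(aln)) {
    m <- aln
  } else {
    abort("`aln` must be a DNAbin object or character matrix")
  }
  if (nrow(m) == 0) abort("empty alignment")
  tolower(m)
}

# sites where every sequence has an unambiguous base (complete deletion)
complete_sites <- function(m) {
  which(apply(m, 2, function(col) all(col %in% c("a", "c", "g", "t"))))
}

hamming_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

#' Collapse aligned sequences into haplotypes
#'
#' Sites containing gaps or ambiguity codes in any sequence are excluded
#' from comparison (complete deletion); sequences identical over the
#' retained sites are merged.  Haplotypes are labeled `H1`, `H2`, ... by
#' decreasing frequency, ties broken by first occurrence in the alignment.
#'
#' @param aln an `ape::DNAbin` matrix or character matrix of equal-length
#'   sequences (rownames = sample ids).
#' @param popmap optional tibble `sample`, `population` (and `species`)
#'   used to tabulate per-population haplotype counts.
#' @return An object of class `haplotype_set`: tibble `haplotypes`
#'   (`haplotype`, `n`, `members` list-column), `assignments`
#'   (`sample`, `haplotype`), `seq` (character matrix of one row per
#'   haplotype over retained sites), `sites` (retained site indices) and,
#'   with a popmap, `pop_counts` (haplotype-by-population counts).
#' @export
collapse_haplotypes <- function(aln, popmap = NULL) {
  m <- aln_char(aln)
  sites <- complete_sites(m)
  if (length(sites) == 0) abort("no fully resolved sites in alignment")
  mm <- m[, sites, drop = FALSE]
  key <- apply(mm, 1, paste, collapse = "")
  first <- match(unique(key), key)
  groups <- split(rownames(m), factor(key, levels = key[first]))
  ord <- order(-lengths(groups), match(names(groups), key[first]))
  groups <- groups[ord]
  labels <- paste0("H", seq_along(groups))
  haplos <- tibble(haplotype = labels, n = unname(lengths(groups)),
                   members = unname(groups))
  assignments <- tibble(sample = unlist(groups),
                        haplotype = rep(labels, lengths(groups)))
  seqm <- mm[vapply(groups, function(g) g[1], character(1)), ,
             drop = FALSE]
  rownames(seqm) <- labels
  out <- list(haplotypes = haplos, assignments = assignments,
              seq = seqm, sites = sites)
  if (!is.null(popmap)) {
    pm <- as_tibble(popmap)
    out$pop_counts <- assignments |>
      left_join(pm, by = "sample") |>
      count(.data$haplotype, .data$population) |>
      tidyr::pivot_wider(names_from = "population", values_from = "n",
                         values_fill = 0L) |>
      arrange(match(.data$haplotype, labels))
  }
  structure(out, class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes from %d samples (%d sites)\n",
              nrow(x$haplotypes), nrow(x$assignments), ncol(x$seq)))
  invisible(x)
}

#' @method tidy haplotype_set
#' @export
tidy.haplotype_set <- function(x, ...) {
  select(x$haplotypes, -"members")
}

#' Haplotype network as a minimum spanning network
#'
#' Builds a minimum spanning network over the Hamming distances between
#' haplotypes (an approximation of statistical-parsimony networks: the MST
#' preserves clade separation and the hatch-mark counts, which equal the
#' edge weights).  Edges longer than `max_link` are removed afterwards,
#' possibly disconnecting deeply divergent clades.
#'
#' @param hs a [collapse_haplotypes()] result.
#' @param max_link optional integer: drop edges with more substitutions
#'   than this.
#' @param include_alternatives passed to [build_msn()].
#' @return A `chem_network` whose nodes are haplotypes.
#' @export
haplotype_network <- function(hs, max_link = NULL,
                              include_alternatives = FALSE) {
  stopifnot(inherits(hs, "haplotype_set"))
  d <- hamming_matrix(hs$seq)
  nodes <- rename(hs$haplotypes, type = "haplotype")
  net <- build_msn(nodes, d, include_alternatives = include_alternatives)
  if (!is.null(max_link))
    net$edges <- filter(net$edges, .data$weight <= max_link)
  net$assignments <- rename(hs$assignments, type = "haplotype")
  net$distances <- d
  net
}

#' Tamura-Nei (TN93) pairwise genetic distances
#'
#' TN93 distances from transition proportions (purine and pyrimidine
#' separately), transversion proportion and empirical base frequencies,
#' with pairwise deletion of ambiguous sites.  Pairs whose distance is
#' undefined (log argument <= 0 under saturation) are returned as `NaN`
#' and listed in the `"undefined_pairs"` attribute.
#'
#' @param aln an `ape::DNAbin` matrix or character matrix.
#' @return Symmetric numeric matrix of distances (substitutions per site).
#' @export
tamura_nei_distance <- function(aln) {
  if (!inherits(aln, "DNAbin")) aln <- ape::as.DNAbin(aln_char(aln))
  d <- suppressWarnings(
    as.matrix(ape::dist.dna(aln, model = "TN93",
                            pairwise.deletion = TRUE)))
  diag(d) <- 0
  und <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
  attr(d, "undefined_pairs") <-
    if (nrow(und) > 0)
      tibble(id1 = rownames(d)[und[, 1]], id2 = colnames(d)[und[, 2]])
    else tibble(id1 = character(), id2 = character())
  d
}

phi_st <- function(d, groups) {
  # two-level AMOVA variance components on (squared) pairwise distances
  groups <- as.factor(groups)
  n <- nrow(d)
  g <- nlevels(droplevels(groups))
  ss_total <- sum(d[upper.tri(d)]) / n
  ss_within <- 0
  sizes <- as.numeric(table(droplevels(groups)))
  for (lev in levels(droplevels(groups))) {
    idx <- which(groups == lev)
    if (length(idx) > 1)
      ss_within <- ss_within +
        sum(d[idx, idx][upper.tri(d[idx, idx])]) / length(idx)
  }
  ms_among <- (ss_total - ss_within) / (g - 1)
  ms_within <- ss_within / (n - g)
  n0 <- (n - sum(sizes^2) / n) / (g - 1)
  sigma_a <- (ms_among - ms_within) / n0
  denom <- sigma_a + ms_within
  if (denom == 0) return(0)
  sigma_a / denom
}

#' Pairwise PhiST between populations with permutation tests
#'
#' AMOVA-based PhiST on the number of differing sites between sequences
#' (complete deletion), computed for every population pair:
#' `PhiST = sigma2_among / (sigma2_among + sigma2_within)` from the
#' standard two-level variance components; values may be negative.
#' Significance comes from permuting individuals between the two
#' populations with the add-one convention.  A haplotype-frequency-only
#' variant (0/1 distances, GST-like) is available via
#' `distance = "haplotype"`.
#'
#' @param aln an `ape::DNAbin` or character matrix.
#' @param popmap tibble `sample`, `population` covering all sequences.
#' @param n_perm permutations per pair (default 1000).
#' @param seed optional integer seed.
#' @param distance `"differences"` (default; pairwise number of differing
#'   sites) or `"haplotype"` (identity only).
#' @return An object of class `phist_result`: `phist` and `p` matrices
#'   (populations in rows/columns; `p` is `NA` where a population has
#'   fewer than 2 samples) plus `n_perm`.  `tidy()` gives the
#'   lower-triangle pairs as a tibble.
#' @export
pairwise_phist <- function(aln, popmap, n_perm = 1000, seed = NULL,
                           distance = c("differences", "haplotype")) {
  distance <- match.arg(distance)
  m <- aln_char(aln)
  pm <- as_tibble(popmap)
  if (!all(rownames(m) %in% pm$sample))
    abort("popmap does not cover all sequences")
  pops <- pm$population[match(rownames(m), pm$sample)]
  mm <- m[, complete_sites(m), drop = FALSE]
  d <- hamming_matrix(mm)
  if (distance == "haplotype") d <- (d > 0) + 0L
  levs <- sort(unique(pops))
  k <- length(levs)
  if (k < 2) abort("need >= 2 populations")
  phist <- pmat <- matrix(NA_real_, k, k, dimnames = list(levs, levs))
  diag(phist) <- 0
  with_seed(seed, {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      idx <- which(pops %in% c(levs[i], levs[j]))
      sub_d <- d[idx, idx]
      sub_g <- pops[idx]
      obs <- phi_st(sub_d, sub_g)
      phist[i, j] <- phist[j, i] <- obs
      sizes <- table(sub_g)
      if (min(sizes) >= 2 && n_perm >= 1) {
        exceed <- sum(vapply(seq_len(n_perm), function(b) {
          phi_st(sub_d, sample(sub_g)) >= obs
        }, logical(1)))
        pmat[i, j] <- pmat[j, i] <- (1 + exceed) / (n_perm + 1)
      }
    }
  })
  structure(list(phist = phist, p = pmat, n_perm = as.integer(n_perm)),
            class = "phist_result")
}

#' @export
print.phist_result <- function(x, ...) {
  cat("<phist_result> pairwise PhiST\n")
  print(round(x$phist, 3))
  invisible(x)
}

#' @method tidy phist_result
#' @export
tidy.phist_result <- function(x, ...) {
  levs <- rownames(x$phist)
  pairs <- which(lower.tri(x$phist), arr.ind = TRUE)
  tibble(pop1 = levs[pairs[, 2]], pop2 = levs[pairs[, 1]],
         phist = x$phist[pairs], p = x$p[pairs])
}

#' Tajima's D with the beta-distribution approximation
#'
#' Standardized difference between nucleotide diversity (mean pairwise
#' differences, pi) and Watterson's estimator `S/a1`:
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S - 1))` with the usual constants
#' `a1 = sum 1/i`, `a2 = sum 1/i^2` (i < n), `b1 = (n+1)/(3(n-1))`,
#' `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`,
#' `e2 = c2/(a1^2 + a2)`.  The two-sided p-value uses the scaled beta
#' approximation of the null distribution of D.
#'
#' @param aln an `ape::DNAbin` or character matrix with >= 4 sequences;
#'   ambiguous sites are removed by complete deletion.
#' @return A one-row tibble: `D`, `S`, `pi`, `n`, `p`.  With no
#'   segregating sites, `D` and `p` are `NA` and a message records why.
#' @export
tajimas_d <- function(aln) {
  m <- aln_char(aln)
  n <- nrow(m)
  if (n < 4) abort("Tajima's D needs >= 4 sequences")
  mm <- m[, complete_sites(m), drop = FALSE]
  S <- sum(apply(mm, 2, function(col) length(unique(col)) > 1))
  d <- hamming_matrix(mm)
  pi_hat <- mean(d[upper.tri(d)])
  if (S == 0) {
    return(tibble(D = NA_real_, S = 0L, pi = 0, n = n, p = NA_real_,
                  note = "no segregating sites"))
  }
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  dmin <- (2 / n - 1 / a1) / sqrt(e2)
  dmax <- ((n + 1) / (2 * n) - 1 / a1) / sqrt(e2)
  tmp <- 1 + dmin * dmax
  alpha <- -tmp * dmax / (dmax - dmin)
  beta <- tmp * dmin / (dmax - dmin)
  pr <- pbeta((D - dmin) / (dmax - dmin), beta, alpha)
  p <- 2 * min(pr, 1 - pr)
  tibble(D = D, S = as.integer(S), pi = pi_hat, n = n, p = p,
         note = NA_character_)
}

#' Read a FASTA alignment and population map
#'
#' @param fasta path to an aligned FASTA file.
#' @param popmap_csv optional CSV with columns `sample`, `population`
#'   (and `species`).
#' @return A list `alignment` (DNAbin matrix) and `popmap` (tibble or
#'   `NULL`).
#' @export
read_alignment <- function(fasta, popmap_csv = NULL) {
  aln <- ape::read.FASTA(fasta)
  aln <- as.matrix(aln)
  pm <- if (!is.null(popmap_csv))
    readr::read_csv(popmap_csv, show_col_types = FALSE)
  list(alignment = aln, popmap = pm)
}
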