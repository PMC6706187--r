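# Independent oracles and tiny fixture builders used across test files.

# brute-force minimum spanning tree weight: enumerate all (n-1)-edge
# subsets and keep the lightest one that connects the graph
brute_force_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 1) return(0)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  m <- nrow(pairs)
  best <- Inf
  for (comb in utils::combn(m, n - 1, simplify = FALSE)) {
    adj <- matrix(FALSE, n, n)
    for (e in comb) {
      adj[pairs[e, 1], pairs[e, 2]] <- TRUE
      adj[pairs[e, 2], pairs[e, 1]] <- TRUE
    }
    reach <- logical(n); reach[1] <- TRUE
    repeat {
      nxt <- reach | apply(adj[, reach, drop = FALSE], 1, any)
      if (all(nxt == reach)) break
      reach <- nxt
    }
    if (all(reach)) {
      w <- sum(d[pairs[comb, , drop = FALSE]])
      if (w < best) best <- w
    }
  }
  best
}

# direct-formula Tajima's D on a character matrix, written independently of
# the package implementation (explicit per-site loops)
direct_tajimas_d <- function(m) {
  m <- toupper(m)
  n <- nrow(m)
  S <- 0L
  for (j in seq_len(ncol(m))) {
    if (length(unique(m[, j])) > 1) S <- S + 1L
  }
  total <- 0; npairs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    total <- total + sum(m[i, ] != m[j, ])
    npairs <- npairs + 1
  }
  pi_hat <- total / npairs
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_hat - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# direct TN93 evaluation from the published formula (empirical averaged
# base frequencies, purine/pyrimidine transition proportions P1/P2 and
# transversion proportion Q)
direct_tn93 <- function(s1, s2) {
  s1 <- tolower(s1); s2 <- tolower(s2)
  ok <- s1 %in% c("a", "c", "g", "t") & s2 %in% c("a", "c", "g", "t")
  s1 <- s1[ok]; s2 <- s2[ok]
  L <- length(s1)
  f <- (table(factor(s1, c("a", "c", "g", "t"))) +
          table(factor(s2, c("a", "c", "g", "t")))) / (2 * L)
  gA <- f[["a"]]; gC <- f[["c"]]; gG <- f[["g"]]; gT <- f[["t"]]
  gR <- gA + gG; gY <- gC + gT
  diff <- s1 != s2
  P1 <- mean(diff & ((s1 == "a" & s2 == "g") | (s1 == "g" & s2 == "a")))
  P2 <- mean(diff & ((s1 == "c" & s2 == "t") | (s1 == "t" & s2 == "c")))
  Q <- mean(diff) - P1 - P2
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

# balanced repeated-measurement simulator for ICC checks
sim_icc_repeats <- function(n, k, var_between, var_within, seed) {
  set.seed(seed)
  truth <- rnorm(n, 100, sqrt(var_between))
  tibble::tibble(
    individual = rep(sprintf("i%03d", 1:n), each = k),
    rep = rep(1:k, n),
    variable = "v1",
    value = rep(truth, each = k) + rnorm(n * k, 0, sqrt(var_within)))
}

toy_alignment <- function() {
  path <- system.file("extdata", "toy_coi.fasta", package = "chemotaxa")
  as.matrix(ape::read.FASTA(path))
}

# small hand-made peak table: 4 samples x 5 substances
tiny_peak_table <- function() {
  annot <- tibble::tibble(
    id = paste0("s", 1:5),
    name = c("C29", "13-MeC29", "C35:1", "C35:2", "C31"),
    chain_length = c(29L, 29L, 35L, 35L, 31L),
    n_methyl = c(0L, 1L, 0L, 0L, 0L),
    n_double_bonds = c(0L, 0L, 1L, 2L, 0L),
    class = c("n-alkane", "monomethyl alkane", "alkene", "alkadiene",
              "n-alkane"))
  ab <- matrix(c(
    0.40, 0.30, 0.20, 0.05, 0.05,
    0.35, 0.35, 0.20, 0.00, 0.10,
    0.10, 0.20, 0.40, 0.10, 0.20,
    0.15, 0.15, 0.45, 0.00, 0.25), 4, 5, byrow = TRUE,
    dimnames = list(paste0("c", 1:4), annot$id))
  peak_table(ab, annot,
             tibble::tibble(sample = paste0("c", 1:4),
                            chemotype = c("A", "A", "B", "B")))
}
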