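# Synthetic-data generators.  Each is a pure function of its
# scenario_config: the global seed expands deterministically into one child
# seed per generator, so stages are reproducible in isolation.

sample_ids <- function(cfg) {
  n <- 2L * cfg$n_colonies_per_chemotype
  sprintf("col%03d", seq_len(n))
}

population_codes <- function(cfg) {
  paste0("P", seq_len(cfg$n_populations))
}

# deterministic substance annotation catalogue: cycles over the eight
# hydrocarbon classes and odd chain lengths 25-41
synth_substances <- function(n_substances) {
  classes <- substance_classes()[1:8]
  chains <- seq(25L, 41L, by = 2L)
  grid <- expand.grid(class = classes, chain_length = chains,
                      stringsAsFactors = FALSE)
  # enough combinations for typical n; recycle with shifted branch
  # positions if more are requested
  reps <- ceiling(n_substances / nrow(grid))
  grid <- grid[rep(seq_len(nrow(grid)), reps)[seq_len(n_substances)], ]
  variant <- (seq_len(n_substances) - 1) %/% nrow(grid)
  name <- character(n_substances)
  n_me <- integer(n_substances); n_db <- integer(n_substances)
  for (i in seq_len(n_substances)) {
    ch <- grid$chain_length[i]
    pos1 <- 3L + 2L * variant[i]   # branch positions vary per recycle pass
    switch(grid$class[i],
      "n-alkane" = { name[i] <- paste0("C", ch) },
      "monomethyl alkane" = {
        n_me[i] <- 1L; name[i] <- sprintf("%d-MeC%d", pos1 + 10L, ch) },
      "dimethyl alkane" = {
        n_me[i] <- 2L
        name[i] <- sprintf("%d,%d-DiMeC%d", pos1 + 10L, pos1 + 20L, ch) },
      "trimethyl alkane" = {
        n_me[i] <- 3L
        name[i] <- sprintf("%d,%d,%d-TriMeC%d", pos1, pos1 + 10L,
                           pos1 + 20L, ch) },
      "alkene" = { n_db[i] <- 1L; name[i] <- sprintf("C%d:1", ch) },
      "alkadiene" = { n_db[i] <- 2L; name[i] <- sprintf("C%d:2", ch) },
      "alkatriene" = { n_db[i] <- 3L; name[i] <- sprintf("C%d:3", ch) },
      "methyl-branched alkene" = {
        n_me[i] <- 1L; n_db[i] <- 1L
        name[i] <- sprintf("%d-MeC%d:1", pos1 + 10L, ch) })
  }
  tibble(
    id = sprintf("s%02d", seq_len(n_substances)),
    name = name, chain_length = grid$chain_length,
    n_methyl = n_me, n_double_bonds = n_db, class = grid$class,
    rt = 2 * (grid$chain_length - 24) + 0.05 * n_me + 0.02 * n_db)
}

#' Simulate a two-chemotype CHC peak table
#'
#' Logistic-normal compositions: each chemotype has a mean log-abundance
#' vector, the second chemotype's marker substances are offset by
#' `chemotype_shift`; colony profiles add iid `N(0, within_noise_sd)` noise
#' on the log scale and are closed to proportions.  Proportions below
#' `detection_limit` are then zeroed to exercise downstream zero handling.
#' Substance annotations (chain length 25-41, the eight hydrocarbon
#' classes, double-bond counts) are attached, and the generating chemotype
#' is recorded in `$samples$chemotype` as ground truth.
#'
#' @param config a [scenario_config()].
#' @return A [peak_table()].
#' @export
gen_chc_profiles <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  with_seed(child_seed(cfg$seed, "chc"), {
    n_per <- cfg$n_colonies_per_chemotype
    p <- cfg$n_substances
    ids <- sample_ids(cfg)
    chemotype <- rep(c("A", "B"), each = n_per)
    mu <- rnorm(p, mean = 0, sd = 1)
    markers <- seq_len(cfg$n_marker_substances)
    mu_b <- mu
    mu_b[markers] <- mu_b[markers] + cfg$chemotype_shift
    loga <- matrix(NA_real_, 2 * n_per, p)
    for (i in seq_len(2 * n_per)) {
      base <- if (chemotype[i] == "A") mu else mu_b
      loga[i, ] <- base + rnorm(p, 0, cfg$within_noise_sd)
    }
    ab <- exp(loga)
    ab <- ab / rowSums(ab)
    ab[ab < cfg$detection_limit] <- 0
    subs <- synth_substances(p)
    dimnames(ab) <- list(ids, subs$id)
    pops <- rep_len(population_codes(cfg), 2 * n_per)
    peak_table(ab, subs,
               tibble(sample = ids, chemotype = chemotype,
                      population = pops))
  })
}

mutate_sites <- function(seq, sites, bases = c("a", "c", "g", "t")) {
  for (s in sites) {
    seq[s] <- sample(setdiff(bases, seq[s]), 1)
  }
  seq
}

#' Simulate a two-clade COI alignment with population structure
#'
#' One random ancestral sequence; the second species clade differs at
#' exactly `fixed_snps_between_species` distinct sites.  Within each
#' species, every population founder carries Poisson(`theta`) private
#' substitutions, and each colony starts from a founder (its own
#' population's with probability `1 - migration`, a random population's
#' otherwise) and adds Poisson(`theta`) further private substitutions — a
#' star-genealogy approximation of within-species variation.
#'
#' @param config a [scenario_config()].
#' @return A list: `alignment` (an `ape::DNAbin` matrix) and `popmap`
#'   (tibble `sample`, `population`, `species`).
#' @export
gen_coi_alignment <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  with_seed(child_seed(cfg$seed, "coi"), {
    bases <- c("a", "c", "g", "t")
    L <- cfg$seq_length
    anc <- sample(bases, L, replace = TRUE)
    fixed_sites <- sample.int(L, cfg$fixed_snps_between_species)
    anc_b <- mutate_sites(anc, fixed_sites)
    ids <- sample_ids(cfg)
    species <- rep(c("A", "B"), each = cfg$n_colonies_per_chemotype)
    pops <- rep_len(population_codes(cfg), length(ids))
    founders <- list()
    for (sp in c("A", "B")) {
      root <- if (sp == "A") anc else anc_b
      for (pp in population_codes(cfg)) {
        k <- rpois(1, cfg$theta)
        founders[[paste(sp, pp)]] <-
          if (k > 0) mutate_sites(root, sample.int(L, k)) else root
      }
    }
    seqs <- matrix("a", length(ids), L, dimnames = list(ids, NULL))
    for (i in seq_along(ids)) {
      pop_i <- if (runif(1) < cfg$migration)
        sample(population_codes(cfg), 1) else pops[i]
      s <- founders[[paste(species[i], pop_i)]]
      k <- rpois(1, cfg$theta)
      if (k > 0) s <- mutate_sites(s, sample.int(L, k))
      seqs[i, ] <- s
    }
    list(alignment = ape::as.DNAbin(seqs),
         popmap = tibble(sample = ids, population = pops,
                         species = species))
  })
}

#' Simulate a morphometric table with technical repeats
#'
#' Log-measurements are built as baseline + isometric size scalar (same on
#' every variable) + a species shape offset on the first three variables +
#' an allometric term (`allometry_slope * size`) on the first variable +
#' iid noise; two technical repeats per individual add repeat noise of sd
#' `repeat_noise_sd` on the log scale.  Values are reported in micrometres.
#'
#' @param config a [scenario_config()].
#' @return A long tibble: `individual`, `species`, `location`, `rep`,
#'   `variable`, `value` (µm).
#' @export
gen_morphometrics <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  with_seed(child_seed(cfg$seed, "morpho"), {
    n <- cfg$n_individuals_morpho
    p <- cfg$n_morpho_vars
    species <- rep(c("A", "B"), length.out = n)
    loc <- rep_len(population_codes(cfg), n)
    ids <- sprintf("ind%03d", seq_len(n))
    vars <- sprintf("M%02d", seq_len(p))
    baseline <- log(round(runif(p, 200, 1500)))
    size <- rnorm(n, 0, 0.15)
    offset_vars <- seq_len(min(3L, p))
    logx <- matrix(NA_real_, n, p, dimnames = list(ids, vars))
    for (i in seq_len(n)) {
      row <- baseline + size[i]
      if (species[i] == "B") row[offset_vars] <- row[offset_vars] +
          cfg$shape_offset
      row[1] <- row[1] + cfg$allometry_slope * size[i]
      logx[i, ] <- row + rnorm(p, 0, 0.05)
    }
    reps <- purrr::map(1:2, function(r) {
      noisy <- logx + matrix(rnorm(n * p, 0, cfg$repeat_noise_sd), n, p)
      as_tibble(exp(noisy), rownames = "individual") |>
        tidyr::pivot_longer(-"individual", names_to = "variable",
                            values_to = "value") |>
        mutate(rep = r)
    })
    meta <- tibble(individual = ids, species = species, location = loc)
    left_join(bind_rows(reps), meta, by = "individual") |>
      select("individual", "species", "location", "rep", "variable",
             "value")
  })
}

#' Simulate an environment table on a climate gradient
#'
#' Colonies are placed along a longitude axis; a single latent climate
#' gradient (standardized longitude) generates 19 correlated bioclim-style
#' variables with variable-specific loadings and noise
#' (`climate_noise_sd`).  Species occurrence is drawn from a logistic model
#' with coefficient `climate_slope` on the latent gradient; canopy cover,
#' five plant-presence flags and partner chemotype are generated with no
#' effect.
#'
#' @param config a [scenario_config()].
#' @return A tibble: `sample`, `lon`, `lat`, `bio01`..`bio19`, `canopy`,
#'   plant flags, `partner`, `latent` (the generating gradient),
#'   `species` (binary ground truth) and `species_label`.
#' @export
gen_env_table <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  with_seed(child_seed(cfg$seed, "env"), {
    ids <- sample_ids(cfg)
    n <- length(ids)
    lon <- runif(n, -54.5, -52.0)
    lat <- runif(n, 4.0, 5.5)
    latent <- as.numeric(scale(lon))
    loadings <- runif(19, 0.5, 1) * sample(c(-1, 1), 19, replace = TRUE)
    # bioclim-flavoured locations/scales: first 11 temperature-like (deg C),
    # last 8 precipitation-like (mm)
    centers <- c(rep(25, 11), rep(3000, 8))
    scales <- c(rep(1.5, 11), rep(600, 8))
    clim <- vapply(1:19, function(k) {
      centers[k] + scales[k] *
        (loadings[k] * latent + rnorm(n, 0, cfg$climate_noise_sd))
    }, numeric(n))
    colnames(clim) <- sprintf("bio%02d", 1:19)
    species <- rbinom(n, 1, plogis(cfg$climate_slope * latent))
    tibble(sample = ids, lon = lon, lat = lat) |>
      bind_cols(as_tibble(clim)) |>
      mutate(
        canopy = rbeta(n, 5, 1.5),
        philodendron = rbinom(n, 1, 0.4),
        aechmea = rbinom(n, 1, 0.4),
        codonanthe = rbinom(n, 1, 0.3),
        peperomia = rbinom(n, 1, 0.3),
        anthurium = rbinom(n, 1, 0.2),
        partner = sample(c("A", "B"), n, replace = TRUE),
        latent = latent,
        species = species,
        species_label = ifelse(species == 1, "PS", "PAT"))
  })
}

#' Write all synthetic inputs of a scenario to disk
#'
#' Emits the four file families the pipeline reads: peak table CSV with a
#' substance-annotation sidecar and sample metadata, a FASTA alignment with
#' a population map CSV, a long-format morphometrics CSV, and an
#' environment CSV.  All files have header rows; missing values are written
#' as empty fields.
#'
#' @param config a [scenario_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_scenario <- function(config, dir) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pt <- gen_chc_profiles(config)
  coi <- gen_coi_alignment(config)
  paths <- c(
    peaks = file.path(dir, "peaks.csv"),
    annotations = file.path(dir, "substances.csv"),
    samples = file.path(dir, "samples.csv"),
    alignment = file.path(dir, "coi.fasta"),
    popmap = file.path(dir, "popmap.csv"),
    morpho = file.path(dir, "morphometrics.csv"),
    env = file.path(dir, "environment.csv"))
  write_peak_table(pt, paths["peaks"], paths["annotations"],
                   paths["samples"])
  ape::write.FASTA(coi$alignment, paths["alignment"])
  readr::write_csv(coi$popmap, paths["popmap"])
  readr::write_csv(gen_morphometrics(config), paths["morpho"])
  readr::write_csv(gen_env_table(config), paths["env"])
  invisible(paths)
}
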