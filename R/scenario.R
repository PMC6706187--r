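#' Scenario configuration for the synthetic two-species study
#'
#' Bundles every parameter of the synthetic-data generators into one
#' validated object.  The defaults describe the study conditions the whole
#' test suite runs under: two chemotypes of 60 colonies each with 40 CHC
#' substances of which 10 are chemotype markers shifted by 2 clr units; a
#' 449-bp COI alignment whose two species clades are separated by 16 fixed
#' SNPs; 80 measured individuals with a small species shape offset; and a
#' logistic climate gradient with slope 2 on climate PC1.
#'
#' @param n_colonies_per_chemotype colonies simulated per chemotype (>= 1).
#' @param n_substances number of CHC substances in the peak table.
#' @param n_marker_substances substances whose mean log-abundance differs
#'   between the chemotypes; must not exceed `n_substances`.
#' @param chemotype_shift mean log-ratio offset (clr units) applied to the
#'   marker substances in the second chemotype.
#' @param within_noise_sd sd (clr units) of the iid colony-level log-scale
#'   noise; must be > 0.
#' @param n_populations number of sampling populations for the COI stage.
#' @param fixed_snps_between_species substitutions fixed between the two
#'   species clades (distinct sites).
#' @param theta population-scaled mutation rate: each colony carries
#'   Poisson(`theta`) private substitutions (star-genealogy approximation).
#' @param migration probability in \[0, 1\] that a colony draws its founder
#'   haplotype from a random population instead of its own; 1 mixes the
#'   populations completely, 0 keeps them fixed for private founders.
#' @param n_individuals_morpho individuals in the morphometric table (split
#'   evenly between species).
#' @param shape_offset log-unit offset added to a fixed subset of three
#'   measurements in the second species (the species shape signal).
#' @param allometry_slope slope of the allometric term linking log isometric
#'   size to the first measurement.
#' @param climate_slope logistic-regression coefficient of species occurrence
#'   on the latent climate gradient (climate PC1).
#' @param climate_noise_sd sd of the variable-specific noise around the
#'   latent climate gradient (latent-gradient units); 0 makes all 19 climate
#'   variables perfectly collinear.
#' @param detection_limit proportions below this fraction of a sample's total
#'   are zeroed to mimic the GC-MS detection floor.
#' @param seq_length length (bp) of the simulated COI alignment.
#' @param n_morpho_vars number of linear measurements.
#' @param repeat_noise_sd sd (log units) of the technical repeat error.
#' @param seed integer global seed; each generator derives its own child
#'   seed deterministically so stages are independently reproducible.
#'
#' @return An object of class `scenario_config` (a validated named list).
#' @export
#' @examples
#' cfg <- scenario_config(seed = 42)
#' pt <- gen_chc_profiles(cfg)
scenario_config <- function(n_colonies_per_chemotype = 60L,
                            n_substances = 40L,
                            n_marker_substances = 10L,
                            chemotype_shift = 2,
                            within_noise_sd = 0.5,
                            n_populations = 4L,
                            fixed_snps_between_species = 16L,
                            theta = 1,
                            migration = 0.2,
                            n_individuals_morpho = 80L,
                            shape_offset = 0.1,
                            allometry_slope = 0.1,
                            climate_slope = 2,
                            climate_noise_sd = 0.5,
                            detection_limit = 1e-4,
                            seq_length = 449L,
                            n_morpho_vars = 10L,
                            repeat_noise_sd = 0.01,
                            seed = 1L) {
  cfg <- list(
    n_colonies_per_chemotype = as.integer(n_colonies_per_chemotype),
    n_substances = as.integer(n_substances),
    n_marker_substances = as.integer(n_marker_substances),
    chemotype_shift = as.numeric(chemotype_shift),
    within_noise_sd = as.numeric(within_noise_sd),
    n_populations = as.integer(n_populations),
    fixed_snps_between_species = as.integer(fixed_snps_between_species),
    theta = as.numeric(theta),
    migration = as.numeric(migration),
    n_individuals_morpho = as.integer(n_individuals_morpho),
    shape_offset = as.numeric(shape_offset),
    allometry_slope = as.numeric(allometry_slope),
    climate_slope = as.numeric(climate_slope),
    climate_noise_sd = as.numeric(climate_noise_sd),
    detection_limit = as.numeric(detection_limit),
    seq_length = as.integer(seq_length),
    n_morpho_vars = as.integer(n_morpho_vars),
    repeat_noise_sd = as.numeric(repeat_noise_sd),
    seed = as.integer(seed)
  )
  counts <- c("n_colonies_per_chemotype", "n_substances",
              "n_marker_substances", "n_populations",
              "n_individuals_morpho", "seq_length", "n_morpho_vars")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      abort(sprintf("`%s` must be a count >= 1", nm))
  }
  if (cfg$n_marker_substances > cfg$n_substances)
    abort("`n_marker_substances` must not exceed `n_substances`")
  if (!is.finite(cfg$within_noise_sd) || cfg$within_noise_sd <= 0)
    abort("`within_noise_sd` must be > 0")
  if (cfg$migration < 0 || cfg$migration > 1)
    abort("`migration` must lie in [0, 1]")
  if (cfg$theta < 0) abort("`theta` must be >= 0")
  if (cfg$fixed_snps_between_species >= cfg$seq_length)
    abort("`fixed_snps_between_species` must be smaller than `seq_length`")
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
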