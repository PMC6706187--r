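# End-to-end orchestration: simulate (or read) inputs, then run the
# preprocessing, chemical-network, compositional-statistics, morphometric,
# population-genetic and environmental-association stages, emitting one
# machine-readable manifest.

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full cryptic-species analysis pipeline
#'
#' Executes all stages on synthetic inputs generated from a
#' [scenario_config()]: substance filtering and class aggregation with
#' zero-class jitter + PERMANOVA, the chemical network with ground-truth
#' recovery, Bray-Curtis/Mantel compositional statistics, ICC screening +
#' shape PCA + MANOVA + Welch t, haplotype collapsing + network + pairwise
#' PhiST + Tajima's D + TN93/geography Mantel, and the partner chi-squared
#' + climate-PCA logistic association with stepwise AIC reduction.  Every
#' stochastic stage derives its seed from the scenario seed, so a fixed
#' config yields a byte-identical manifest.
#'
#' @param config a [scenario_config()].
#' @param out_dir optional directory; when given, `manifest.json` (stable
#'   key order) and `report.txt` are written there.
#' @param n_perm permutations for PERMANOVA and PhiST tests (default 199).
#' @param mantel_perm permutations for Mantel tests (default 999).
#' @param n_boot bootstrap replicates for the PCA ratio spectrum
#'   (default 200).
#' @return The manifest: a named list of per-stage results (numbers and
#'   small tables), invisibly carrying the fitted objects in
#'   `attr(, "objects")`.
#' @export
run_pipeline <- function(config, out_dir = NULL, n_perm = 199,
                         mantel_perm = 999, n_boot = 200) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- config$seed

  # --- inputs -------------------------------------------------------------
  pt <- gen_chc_profiles(config)
  coi <- gen_coi_alignment(config)
  morpho <- gen_morphometrics(config)
  env <- gen_env_table(config)

  # --- CHC preprocessing --------------------------------------------------
  flt <- filter_substances(pt, groups = "chemotype")
  classes <- class_totals(flt)
  class_mat <- as.matrix(classes[-1])
  rownames(class_mat) <- classes$sample
  class_mat <- jitter_zero_classes(class_mat,
                                   seed = child_seed(seed, "jitter"))
  class_perm <- permanova(bray_curtis(class_mat),
                          flt$samples$chemotype, n_perm = n_perm,
                          seed = child_seed(seed, "permanova"))

  # --- chemical network ---------------------------------------------------
  net <- chemical_network(flt)
  cut <- cut_network(net, n_cut = 1)
  truth <- flt$samples$chemotype[match(cut$sample, flt$samples$sample)]
  net_ari <- ari(cut$component, truth)

  # --- compositional statistics -------------------------------------------
  chc_dist <- bray_curtis(normalize_closure(flt)$abundance)
  geo <- geo_distance(env$lon, env$lat, ids = env$sample)
  mantel_chc_geo <- mantel_test(chc_dist, geo, n_perm = mantel_perm,
                                seed = child_seed(seed, "mantel"))

  # --- morphometrics ------------------------------------------------------
  icc <- icc_reliability(morpho)
  wide <- average_repeats(morpho, keep = icc$variable[icc$keep])
  sp <- shape_pca(wide)
  man <- shape_manova(sp$scores[, 1:2], wide$species, wide$location)
  size_t <- welch_t(sp$iso_size[wide$species == "A"],
                    sp$iso_size[wide$species == "B"])
  spectrum <- pca_ratio_spectrum(sp, axis = 1, n_boot = n_boot,
                                 seed = child_seed(seed, "boot"))

  # --- population genetics ------------------------------------------------
  hs <- collapse_haplotypes(coi$alignment, coi$popmap)
  hnet <- haplotype_network(hs)
  species_phist <- pairwise_phist(
    coi$alignment,
    dplyr::transmute(coi$popmap, sample = .data$sample,
                     population = .data$species),
    n_perm = n_perm, seed = child_seed(seed, "fst"))
  idx_b <- coi$popmap$sample[coi$popmap$species == "B"]
  taj_b <- tajimas_d(as.matrix(coi$alignment)[idx_b, ])
  tn93 <- tamura_nei_distance(coi$alignment)
  mantel_gen_geo <- mantel_test(tn93, geo, n_perm = mantel_perm,
                                seed = child_seed(seed, "mantel"))

  # --- environmental association ------------------------------------------
  partner_tab <- table(env$species_label, env$partner)
  partner_chisq <- contingency_chisq(unclass(partner_tab))
  cpca <- climate_pca(env)
  glm_data <- mutate(env, climate_pc1 = cpca$scores[, 1])
  # separation in the saturated interaction model is expected at small n
  # and recorded via the manifest flag, so its warnings are muted here
  full <- suppressWarnings(fit_binomial_glm(
    species ~ climate_pc1 * (canopy + partner + philodendron + aechmea +
                               codonanthe + peperomia + anthurium),
    glm_data))
  reduced <- suppressWarnings(stepwise_aic(full))
  climate_test <- deviance_term_test(
    suppressWarnings(fit_binomial_glm(species ~ climate_pc1, glm_data)),
    suppressWarnings(fit_binomial_glm(species ~ 1, glm_data)))

  manifest <- list(
    meta = list(seed = seed, config_hash = config_hash(config),
                n_colonies = 2L * config$n_colonies_per_chemotype),
    chc = list(
      n_substances_kept = ncol(flt$abundance),
      n_substances_dropped =
        sum(!attr(flt, "filter_report")$kept),
      class_permanova_F = class_perm$pseudo_F,
      class_permanova_p = class_perm$p),
    chemnet = list(
      n_chemical_types = nrow(net$nodes),
      n_singletons = sum(net$nodes$singleton),
      retained_axes = nrow(net$axes),
      variance_explained_retained = sum(net$axes$eigen_pct),
      recovery_ari = net_ari),
    compstats = list(
      mantel_chc_geo_r = mantel_chc_geo$r,
      mantel_chc_geo_p = mantel_chc_geo$p),
    morpho = list(
      n_variables_kept = sum(icc$keep),
      min_icc = min(icc$icc),
      shape_pc1_pct = sp$eigen_pct[1],
      manova_species_F = man$approx_F[man$term == "species"],
      manova_species_p = man$p[man$term == "species"],
      welch_t = size_t$t, welch_p = size_t$p,
      spectrum_top = spectrum$variable[1],
      spectrum_bottom = spectrum$variable[nrow(spectrum)]),
    popgen = list(
      n_haplotypes = nrow(hs$haplotypes),
      species_phist = species_phist$phist["A", "B"],
      species_phist_p = species_phist$p["A", "B"],
      tajimas_d_B = taj_b$D,
      mantel_gen_geo_r = mantel_gen_geo$r,
      mantel_gen_geo_p = mantel_gen_geo$p),
    ecoassoc = list(
      partner_chi2 = partner_chisq$chi2,
      partner_p = partner_chisq$p,
      climate_pc1_pct = cpca$eigen_pct[1],
      climate_chi2 = climate_test$chi2,
      climate_p = climate_test$p,
      final_model_terms =
        paste(attr(terms(reduced), "term.labels"), collapse = " + "),
      glm_separation = attr(full, "separation")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(render_report(manifest), file.path(out_dir, "report.txt"))
  }
  attr(manifest, "objects") <- list(
    peak_table = flt, network = net, shape_pca = sp, haplotypes = hs,
    haplotype_network = hnet, climate_pca = cpca, glm = reduced)
  invisible(manifest)
}

render_report <- function(m) {
  c(sprintf("cryptic-species pipeline (seed %d, config %s)",
            m$meta$seed, m$meta$config_hash),
    sprintf("colonies analysed: %d", m$meta$n_colonies),
    sprintf("CHC filtering: kept %d substances, dropped %d",
            m$chc$n_substances_kept, m$chc$n_substances_dropped),
    sprintf("substance-class PERMANOVA: pseudo-F = %.2f, p = %.4f",
            m$chc$class_permanova_F, m$chc$class_permanova_p),
    sprintf(paste0("chemical network: %d types (%d singletons), %d PC",
                   " axes (%.1f%% variance), recovery ARI = %.3f"),
            m$chemnet$n_chemical_types, m$chemnet$n_singletons,
            m$chemnet$retained_axes,
            m$chemnet$variance_explained_retained,
            m$chemnet$recovery_ari),
    sprintf("Mantel CHC~geography: r = %.3f, p = %.4f",
            m$compstats$mantel_chc_geo_r, m$compstats$mantel_chc_geo_p),
    sprintf("morphometrics: %d reliable variables, shape MANOVA F = %.2f (p = %.4g), Welch t = %.2f",
            m$morpho$n_variables_kept, m$morpho$manova_species_F,
            m$morpho$manova_species_p, m$morpho$welch_t),
    sprintf("COI: %d haplotypes, species PhiST = %.3f, Tajima's D (B) = %.3f",
            m$popgen$n_haplotypes, m$popgen$species_phist,
            m$popgen$tajimas_d_B),
    sprintf("partner association: chi2 = %.2f, p = %.3f",
            m$ecoassoc$partner_chi2, m$ecoassoc$partner_p),
    sprintf("climate GLM: PC1 explains %.1f%%, term chi2 = %.2f (p = %.4g)",
            m$ecoassoc$climate_pc1_pct, m$ecoassoc$climate_chi2,
            m$ecoassoc$climate_p),
    sprintf("final association model: %s", m$ecoassoc$final_model_terms))
}
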