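#' Default simulated study design
#'
#' A compact stand-in for a Permo-Triassic collecting programme: three
#' southern-hemisphere localities spanning 20-60 degrees of palaeolatitude in
#' one time bin, each yielding an endothermic therapsid, an ectothermic
#' therapsid, a semi-aquatic stereospondyl and a terrestrial parareptile,
#' five individuals per taxon per locality. Taxa without a `locality_id`
#' column are placed at every locality.
#'
#' @param time_bin Time bin for all localities.
#' @return A list with `localities` and `taxa` tibbles.
#' @export
default_sim_design <- function(time_bin = "permian") {
  list(
    localities = tibble(
      locality_id = c("SIM-L20", "SIM-L40", "SIM-L60"),
      palaeolat_deg = c(-20, -40, -60),
      palaeolat_sigma_deg = 3,
      time_bin = time_bin,
      region = "simulated"
    ),
    taxa = tibble(
      taxon = c("Simendotherium", "Simectotherium",
                "Simamphibius", "Simreptilius"),
      group = c("therapsid", "therapsid", "stereospondyl", "parareptile"),
      thermo_truth = c("endotherm", "ectotherm", "ectotherm", "ectotherm"),
      ecology = c("terrestrial", "terrestrial", "semi_aquatic", "terrestrial"),
      n_individuals = 5,
      subsamples_per_individual = 1
    )
  )
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of the forward generator. Defaults
#' emulate the measured data: 0.20 permil Gaussian analytical noise (NBS120c
#' reproducibility), a carbonate-phosphate offset of 8 permil (the centre of
#' the 7-9 permil modern-mammal range), a meteoric-water latitudinal gradient
#' of -0.30 permil per degree from 0 permil at the equator (cancels in
#' co-located differences; kept for realistic absolute values), baseline
#' structural carbonate of 5 +/- 1 wt%, and a diagenetic overprint hitting
#' 10% of samples with +8 permil on the carbonate delta and +12 wt%
#' carbonate — secondary-calcite addition that drives both screening
#' statistics past their thresholds while leaving phosphate intact. A
#' phosphate-attack mode (`phosphate_shift`) exists but is off by default.
#'
#' @param seed Integer RNG seed; all randomness in [simulate_dataset()] flows
#'   from it.
#' @param localities Locality tibble (`locality_id`, `palaeolat_deg`,
#'   `palaeolat_sigma_deg`, `time_bin`).
#' @param taxa Taxa tibble (`taxon`, `group`, `thermo_truth`, `ecology`,
#'   `n_individuals`, `subsamples_per_individual`, optional `locality_id`).
#' @param noise_sigma Analytical noise (1 s.d., permil).
#' @param meteoric_water List: `d18Omw_equator` (permil), `mw_gradient`
#'   (permil per degree of latitude).
#' @param diagenesis List: `fraction` of samples overprinted, `d18Oc_shift`
#'   (permil), `carbonate_shift` (wt%), `phosphate_shift` (permil).
#' @param baseline_carbonate List: `mean`, `sd` (wt%).
#' @param baseline_cp_offset Pristine carbonate-phosphate offset (permil).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       localities = default_sim_design()$localities,
                       taxa = default_sim_design()$taxa,
                       noise_sigma = 0.20,
                       meteoric_water = list(d18Omw_equator = 0, mw_gradient = -0.30),
                       diagenesis = list(fraction = 0.10, d18Oc_shift = 8,
                                         carbonate_shift = 12, phosphate_shift = 0),
                       baseline_carbonate = list(mean = 5, sd = 1),
                       baseline_cp_offset = 8.0) {
  if (is.null(diagenesis$phosphate_shift)) diagenesis$phosphate_shift <- 0
  cfg <- list(seed = as.integer(seed), localities = as_tibble(localities),
              taxa = as_tibble(taxa), noise_sigma = noise_sigma,
              meteoric_water = meteoric_water, diagenesis = diagenesis,
              baseline_carbonate = baseline_carbonate,
              baseline_cp_offset = baseline_cp_offset)
  stopifnot(
    nrow(cfg$localities) > 0, nrow(cfg$taxa) > 0,
    cfg$noise_sigma > 0,
    cfg$diagenesis$fraction >= 0, cfg$diagenesis$fraction <= 1,
    all(cfg$taxa$thermo_truth %in% c("endotherm", "ectotherm")),
    all(cfg$taxa$ecology %in% PT_ECOLOGIES),
    all(cfg$taxa$n_individuals >= 1),
    all(cfg$taxa$subsamples_per_individual >= 1)
  )
  validate_localities(cfg$localities)
  cfg$localities$palaeolat_abs <- abs(cfg$localities$palaeolat_deg)
  cfg
}

#' Forward-simulate an isotope dataset with known ground truth
#'
#' Generates a per-subsample table by running the framework equations
#' forwards. For each individual: body temperature is `tb_endotherm` for
#' endotherms or the ambient temperature of its locality for ectotherms;
#' body water is local meteoric water (linear in latitude) plus an ecology
#' offset drawn uniformly within the ecology's range; each subsample's
#' phosphate value is the thermometer prediction plus Gaussian analytical
#' noise; the carbonate value sits `baseline_cp_offset` above phosphate with
#' its own noise; structural carbonate content is Gaussian about its
#' baseline. A configured fraction of samples then receives the additive
#' diagenetic overprint. Every latent quantity is recorded in the truth
#' table.
#'
#' @param cfg A [sim_config()] list.
#' @param config Pipeline configuration supplying the thermometer, climate
#'   and ecology-offset parameters.
#' @return A list with `samples`, `localities` and `truth` tibbles.
#' @export
simulate_dataset <- function(cfg, config = default_config()) {
  withr::with_seed(cfg$seed, simulate_dataset_impl(cfg, config))
}

simulate_dataset_impl <- function(cfg, config) {
  loc <- cfg$localities
  taxa <- cfg$taxa
  if (!"locality_id" %in% names(taxa)) {
    taxa <- tidyr::crossing(taxa, locality_id = loc$locality_id)
  }
  mw <- cfg$meteoric_water
  dia <- cfg$diagenesis

  rows <- purrr::map_dfr(seq_len(nrow(taxa)), function(i) {
    t_i <- taxa[i, ]
    l_i <- loc[loc$locality_id == t_i$locality_id, ]
    stopifnot(nrow(l_i) == 1)
    climate <- config$climate[[l_i$time_bin]]
    lat <- l_i$palaeolat_abs
    d18Omw <- mw$d18Omw_equator + mw$mw_gradient * lat
    eco_range <- config$physio$ecology_offset[[t_i$ecology]]
    tb <- if (t_i$thermo_truth == "endotherm") {
      config$physio$tb_endotherm
    } else {
      body_temp_ectotherm(lat, climate, config$physio)
    }
    purrr::map_dfr(seq_len(t_i$n_individuals), function(ind) {
      epsilon <- runif(1, eco_range[1], eco_range[2])
      d18Op_true <- predicted_d18Op(tb, d18Omw + epsilon, config$thermometer)
      nsub <- t_i$subsamples_per_individual
      specimen <- sprintf("%s_%s_i%02d", t_i$taxon, t_i$locality_id, ind)
      tibble(
        sample_id = sprintf("%s_s%d", specimen, seq_len(nsub)),
        specimen_id = specimen,
        taxon = t_i$taxon, group = t_i$group, ecology = t_i$ecology,
        material = sample(PT_MATERIALS, nsub, replace = TRUE,
                          prob = c(0.6, 0.4)),
        locality_id = t_i$locality_id,
        thermo_truth = t_i$thermo_truth,
        palaeolat_abs = lat, time_bin = l_i$time_bin,
        tb = tb, d18Omw = d18Omw, epsilon = epsilon,
        d18Op_true = d18Op_true,
        d18Op = d18Op_true + rnorm(nsub, 0, cfg$noise_sigma),
        d18Oc = d18Op_true + cfg$baseline_cp_offset +
          rnorm(nsub, 0, cfg$noise_sigma),
        carbonate_wt_pct = pmax(0, rnorm(nsub, cfg$baseline_carbonate$mean,
                                         cfg$baseline_carbonate$sd))
      )
    })
  })

  rows$diagenetic <- runif(nrow(rows)) < dia$fraction
  rows$d18Oc <- rows$d18Oc + ifelse(rows$diagenetic, dia$d18Oc_shift, 0)
  rows$carbonate_wt_pct <- rows$carbonate_wt_pct +
    ifelse(rows$diagenetic, dia$carbonate_shift, 0)
  rows$d18Op <- rows$d18Op + ifelse(rows$diagenetic, dia$phosphate_shift, 0)

  sample_cols <- c("sample_id", "specimen_id", "taxon", "group", "ecology",
                   "material", "locality_id", "d18Op", "d18Oc",
                   "carbonate_wt_pct")
  truth_cols <- c("sample_id", "specimen_id", "taxon", "group", "ecology",
                  "locality_id", "palaeolat_abs", "time_bin", "thermo_truth",
                  "tb", "d18Omw", "epsilon", "d18Op_true", "diagenetic")
  list(samples = rows[, sample_cols],
       localities = loc,
       truth = rows[, truth_cols])
}

#' Compare classification calls with simulated ground truth
#'
#' Scores pair-level calls against the simulated thermophysiology of each
#' therapsid taxon. Out-of-model pairs are excluded from the accuracy
#' denominator; ambiguous pairs stay in it (they are not correct calls) and
#' are also reported separately.
#'
#' @param truth Truth tibble from [simulate_dataset()].
#' @param calls Calls tibble from [classify_all()].
#' @return A list: `confusion` (truth x call counts), `accuracy`,
#'   `n_pairs`, `n_scored`, `n_ambiguous`, `n_out_of_model`,
#'   `false_endotherm_rate` (endotherm-like calls among truly ectothermic
#'   therapsid pairs, out-of-model excluded).
#' @export
recovery_report <- function(truth, calls) {
  key <- truth %>%
    dplyr::distinct(.data$taxon, .data$thermo_truth)
  unknown <- setdiff(unique(calls$therapsid_taxon), key$taxon)
  if (length(unknown) > 0) {
    abort(paste0("calls contain taxa absent from the truth table: ",
                 paste(unknown, collapse = ", ")),
          class = "paleotherm_recovery_error")
  }
  scored <- calls %>%
    left_join(key, by = c(therapsid_taxon = "taxon")) %>%
    mutate(predicted = dplyr::recode(.data$call,
                                     "endotherm-like" = "endotherm",
                                     "ectotherm-like" = "ectotherm",
                                     .default = .data$call))
  confusion <- scored %>% count(.data$thermo_truth, .data$call, name = "n")
  in_model <- scored[scored$call != "out-of-model", , drop = FALSE]
  n_scored <- nrow(in_model)
  accuracy <- if (n_scored == 0) NA_real_ else {
    mean(in_model$predicted == in_model$thermo_truth)
  }
  ecto_pairs <- in_model[in_model$thermo_truth == "ectotherm", , drop = FALSE]
  false_endo <- if (nrow(ecto_pairs) == 0) NA_real_ else {
    mean(ecto_pairs$predicted == "endotherm")
  }
  list(confusion = confusion, accuracy = accuracy,
       n_pairs = nrow(calls), n_scored = n_scored,
       n_ambiguous = sum(scored$call == "ambiguous"),
       n_out_of_model = sum(scored$call == "out-of-model"),
       false_endotherm_rate = false_endo)
}
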