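# Shared fixtures and small simulated study designs.

sd1_samples_path <- function() {
  system.file("extdata", "synthetic_sd1_samples.csv", package = "paleotherm")
}
sd1_localities_path <- function() {
  system.file("extdata", "synthetic_sd1_localities.csv", package = "paleotherm")
}

# Minimal valid sample table for unit tests.
make_samples <- function(d18Op, taxon = "TaxonA", group = "therapsid",
                         ecology = "terrestrial", locality_id = "L1",
                         specimen_id = NULL, d18Oc = NA_real_,
                         carbonate_wt_pct = NA_real_) {
  n <- length(d18Op)
  tibble::tibble(
    sample_id = paste0(taxon, "_", locality_id, "_s", seq_len(n)),
    specimen_id = if (is.null(specimen_id)) {
      paste0(taxon, "_", locality_id, "_i", seq_len(n))
    } else specimen_id,
    taxon = taxon, group = group, ecology = ecology,
    material = rep_len(c("bone", "tooth"), n),
    locality_id = locality_id,
    d18Op = d18Op,
    d18Oc = rep_len(d18Oc, n),
    carbonate_wt_pct = rep_len(carbonate_wt_pct, n)
  )
}

make_locality <- function(locality_id = "L1", lat = -50, time_bin = "permian",
                          sigma = 3) {
  tibble::tibble(locality_id = locality_id, palaeolat_deg = lat,
                 palaeolat_sigma_deg = sigma, time_bin = time_bin,
                 region = "test", palaeolat_abs = abs(lat))
}

# Two-locality, well-separated world: |thermal term| >> delta_sigma.
separated_design <- function(lats = c(-40, -60), n_individuals = 3) {
  list(
    localities = tibble::tibble(
      locality_id = paste0("W", abs(lats)),
      palaeolat_deg = lats,
      palaeolat_sigma_deg = 3,
      time_bin = "permian",
      region = "sim"
    ),
    taxa = tibble::tibble(
      taxon = c("EndoTher", "EctoTher", "RefAmph", "RefRept"),
      group = c("therapsid", "therapsid", "stereospondyl", "parareptile"),
      thermo_truth = c("endotherm", "ectotherm", "ectotherm", "ectotherm"),
      ecology = c("terrestrial", "terrestrial", "semi_aquatic", "terrestrial"),
      n_individuals = n_individuals,
      subsamples_per_individual = 1
    )
  )
}

all_ecto_design <- function(lats = c(-40, -60), n_individuals = 3) {
  d <- separated_design(lats, n_individuals)
  d$taxa$thermo_truth <- "ectotherm"
  d
}

# Run the in-memory pipeline on a simulated world and score it.
simulate_and_classify <- function(seed, design, diag_fraction = 0,
                                  config = default_config()) {
  cfg <- sim_config(seed = seed, localities = design$localities,
                    taxa = design$taxa,
                    diagenesis = list(fraction = diag_fraction,
                                      d18Oc_shift = 8, carbonate_shift = 12,
                                      phosphate_shift = 0))
  sim <- simulate_dataset(cfg, config)
  scr <- screen_dataset(sim$samples, config)
  st <- taxon_stats(sim$samples, scr$results,
                    analytical_sigma = config$stats$analytical_sigma)
  pr <- all_pairs(st, sim$localities)
  env <- build_envelopes(unique(design$localities$time_bin), config)
  cl <- classify_all(pr, env, k_sigma = config$classify$k_sigma)
  list(sim = sim, pairs = pr, calls = cl$calls,
       report = recovery_report(sim$truth, cl$calls))
}
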