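#' Ectotherm body temperature from the latitudinal gradient
#'
#' An ectotherm's body temperature is taken as the mean ambient air
#' temperature of its locality, modelled as a linear latitudinal gradient
#' `T = t_equator - gradient_g * |lat|`. An optional lower clamp
#' (`physio$tb_ecto_min`) represents active-season thermoregulation at high
#' latitude; it is disabled by default.
#'
#' @param lat_abs Absolute palaeolatitude in degrees (vectorised).
#' @param climate One time-bin climate block, e.g.
#'   `default_config()$climate$permian`.
#' @param physio Physiology block; only `tb_ecto_min` is used here.
#' @param gradient_g Optional gradient override (degC per degree latitude);
#'   defaults to `climate$gradient_g`.
#' @return Body temperature(s) in degC.
#' @export
#' @examples
#' body_temp_ectotherm(50, default_config()$climate$permian)  # 30 - 0.6*50 = 0
body_temp_ectotherm <- function(lat_abs, climate, physio = NULL,
                                gradient_g = NULL) {
  stopifnot(all(lat_abs >= 0), all(lat_abs <= 90))
  g <- if (is.null(gradient_g)) climate$gradient_g else gradient_g
  tb <- climate$t_equator - g * lat_abs
  clamp <- physio$tb_ecto_min
  if (!is.null(clamp)) tb <- pmax(tb, clamp)
  tb
}

#' Predicted apatite phosphate delta-18-O
#'
#' Inverts the linear phosphate-water palaeothermometer
#' `T = intercept - slope * (d18Op - d18Obw)` to give the apatite value
#' precipitated at body temperature `tb` from body water `d18Obw`:
#' `d18Op = d18Obw + (intercept - tb) / slope`.
#'
#' @param tb Body temperature in degC (vectorised).
#' @param d18Obw Body-water delta-18-O in permil V-SMOW.
#' @param thermo Thermometer block, e.g. `default_config()$thermometer`.
#' @return Predicted phosphate delta-18-O in permil V-SMOW.
#' @export
predicted_d18Op <- function(tb, d18Obw = 0, thermo = default_config()$thermometer) {
  d18Obw + (thermo$intercept - tb) / thermo$slope
}

#' Apatite crystallisation temperature from the thermometer
#'
#' The forward direction of the phosphate-water thermometer; inverse of
#' [predicted_d18Op()].
#'
#' @param d18Op Phosphate delta-18-O (permil V-SMOW).
#' @param d18Obw Body-water delta-18-O (permil V-SMOW).
#' @param thermo Thermometer block.
#' @return Temperature in degC.
#' @export
apatite_temperature <- function(d18Op, d18Obw = 0,
                                thermo = default_config()$thermometer) {
  thermo$intercept - thermo$slope * (d18Op - d18Obw)
}

#' Predicted range of a co-located pair difference
#'
#' For two co-located animals, local meteoric water cancels and the expected
#' therapsid-minus-reference difference reduces to a thermal term plus an
#' ecology term:
#'
#' `delta = (Tb_ref - Tb_therapsid) / slope + (eps_therapsid - eps_ref)`
#'
#' where `eps` is each animal's body-water offset relative to local meteoric
#' water, drawn from its ecology's (low, high) range. Endotherms have fixed
#' body temperature `tb_endotherm`; ectotherms track ambient temperature at
#' the locality. The returned (min, max) band sweeps the corners of the
#' ecology ranges and, when `use_gradient_sigma = TRUE`, the gradient
#' `g +/- gradient_sigma` — exact for this monotone linear map. The focal
#' (therapsid) animal is terrestrial by default, matching the framework's
#' comparison scenarios.
#'
#' @param lat_abs Absolute palaeolatitude in degrees (vectorised).
#' @param therapsid_thermo `"endotherm"` or `"ectotherm"` for the focal taxon.
#' @param reference_thermo Same, for the reference taxon.
#' @param reference_ecology One of `terrestrial`, `semi_aquatic`, `aquatic`.
#' @param config Configuration list.
#' @param time_bin Time bin selecting the climate block.
#' @param therapsid_ecology Ecology of the focal taxon.
#' @param use_gradient_sigma Sweep the gradient uncertainty (outer band) or
#'   hold the gradient at its central value (core band).
#' @return A tibble with `lat`, `delta_min`, `delta_max` (permil).
#' @export
predicted_pair_delta <- function(lat_abs, therapsid_thermo, reference_thermo,
                                 reference_ecology,
                                 config = default_config(),
                                 time_bin = "permian",
                                 therapsid_ecology = "terrestrial",
                                 use_gradient_sigma = TRUE) {
  stopifnot(therapsid_thermo %in% c("endotherm", "ectotherm"),
            reference_thermo %in% c("endotherm", "ectotherm"))
  climate <- config$climate[[time_bin]]
  if (is.null(climate)) {
    abort(paste0("unknown time_bin: ", time_bin), class = "paleotherm_config_error")
  }
  offs <- config$physio$ecology_offset
  eco_rng <- function(eco) {
    o <- offs[[eco]]
    if (is.null(o)) {
      abort(paste0("unknown ecology: ", eco), class = "paleotherm_config_error")
    }
    o
  }
  e_th <- eco_rng(therapsid_ecology)
  e_ref <- eco_rng(reference_ecology)
  eco_lo <- e_th[1] - e_ref[2]
  eco_hi <- e_th[2] - e_ref[1]

  gs <- if (use_gradient_sigma) {
    climate$gradient_g + c(-1, 0, 1) * climate$gradient_sigma
  } else {
    climate$gradient_g
  }
  slope <- config$thermometer$slope
  tb_endo <- config$physio$tb_endotherm

  thermal <- vapply(gs, function(g) {
    amb <- body_temp_ectotherm(lat_abs, climate, config$physio, gradient_g = g)
    tb_th <- if (therapsid_thermo == "endotherm") rep(tb_endo, length(lat_abs)) else amb
    tb_ref <- if (reference_thermo == "endotherm") rep(tb_endo, length(lat_abs)) else amb
    (tb_ref - tb_th) / slope
  }, numeric(length(lat_abs)))
  thermal <- matrix(thermal, nrow = length(lat_abs))

  tibble(
    lat = lat_abs,
    delta_min = apply(thermal, 1, min) + eco_lo,
    delta_max = apply(thermal, 1, max) + eco_hi
  )
}

#' Build the four theoretical difference envelopes
#'
#' Constructs the predicted therapsid-minus-reference difference bands versus
#' absolute palaeolatitude for the four comparison scenarios:
#'
#' * `endo_vs_ecto_semiaquatic` — endothermic terrestrial therapsid vs
#'   ectothermic semi-aquatic reference (oblique band);
#' * `endo_vs_ecto_terrestrial` — same vs ectothermic terrestrial reference
#'   (oblique band);
#' * `same_thermo_semiaquatic` — both animals share a thermophysiology,
#'   semi-aquatic reference (vertical band, latitude-independent);
#' * `same_thermo_terrestrial` — shared thermophysiology, terrestrial
#'   reference (vertical band).
#'
#' The core band uses the central temperature gradient for the time bin; the
#' outer band additionally sweeps the gradient by its uncertainty. For
#' same-thermophysiology scenarios the thermal term cancels, so core and
#' outer coincide and the band does not depend on latitude.
#'
#' @param time_bin One of `permian`, `early_mid_triassic`, `mid_late_triassic`.
#' @param config Configuration list.
#' @param lat_step Latitude grid step in degrees (grid spans 0..90).
#' @param ecologies Reference ecologies to build scenarios for.
#' @return A tibble with columns `time_bin`, `scenario`, `lat`, `core_min`,
#'   `core_max`, `outer_min`, `outer_max`.
#' @export
build_envelopes <- function(time_bin, config = default_config(), lat_step = 1,
                            ecologies = c("semi_aquatic", "terrestrial")) {
  stopifnot(lat_step > 0, lat_step <= 1)
  lat <- seq(0, 90, by = lat_step)
  purrr::map_dfr(ecologies, function(eco) {
    sfx <- scenario_suffix(eco)
    oblique_core <- predicted_pair_delta(lat, "endotherm", "ectotherm", eco,
                                         config, time_bin,
                                         use_gradient_sigma = FALSE)
    oblique_outer <- predicted_pair_delta(lat, "endotherm", "ectotherm", eco,
                                          config, time_bin,
                                          use_gradient_sigma = TRUE)
    same <- predicted_pair_delta(lat, "ectotherm", "ectotherm", eco,
                                 config, time_bin, use_gradient_sigma = TRUE)
    bind_rows(
      tibble(time_bin = time_bin,
             scenario = paste0("endo_vs_ecto_", sfx), lat = lat,
             core_min = oblique_core$delta_min, core_max = oblique_core$delta_max,
             outer_min = oblique_outer$delta_min, outer_max = oblique_outer$delta_max),
      tibble(time_bin = time_bin,
             scenario = paste0("same_thermo_", sfx), lat = lat,
             core_min = same$delta_min, core_max = same$delta_max,
             outer_min = same$delta_min, outer_max = same$delta_max)
    )
  })
}

#' Export an envelope grid
#'
#' Writes the band grid produced by [build_envelopes()] as a TSV; the
#' classification stage can run off the re-read grid with identical results
#' (bands are linear in latitude, so grid interpolation is exact).
#'
#' @param envelopes An envelope tibble.
#' @param path Output path.
#' @param meta Optional metadata for the header comment line.
#' @return `path`, invisibly.
#' @export
export_envelope_grid <- function(envelopes, path, meta = NULL) {
  write_table_with_meta(envelopes, path, meta)
}

# Linear interpolation of one scenario's outer band at a latitude.
envelope_band_at <- function(envelopes, scenario, time_bin, lat) {
  grid <- envelopes[envelopes$scenario == scenario &
                      envelopes$time_bin == time_bin, , drop = FALSE]
  if (nrow(grid) == 0) {
    abort(paste0("no envelope for scenario '", scenario, "' in time bin '",
                 time_bin, "'"), class = "paleotherm_envelope_error")
  }
  c(
    min = approx(grid$lat, grid$outer_min, xout = lat, rule = 2)$y,
    max = approx(grid$lat, grid$outer_max, xout = lat, rule = 2)$y
  )
}
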