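#' Default pipeline configuration
#'
#' Returns the full set of physical, climatic, ecological and procedural
#' parameters used by the screening, aggregation, envelope and classification
#' stages. Every value can be overridden through [read_config()] or by editing
#' the returned list.
#'
#' The parameter blocks are:
#'
#' \describe{
#'   \item{`thermometer`}{Linear phosphate-water palaeothermometer,
#'     `T (degC) = intercept - slope * (d18Op - d18Obw)` with `intercept`
#'     117.4 degC and `slope` 4.50 degC per permil by default.}
#'   \item{`climate`}{Per time-bin latitudinal air-temperature gradient
#'     (`gradient_g`, degC per degree of latitude), its uncertainty
#'     (`gradient_sigma`) and the equatorial mean air temperature
#'     (`t_equator`, degC). Defaults: permian 0.6 +/- 0.1, early-middle
#'     Triassic 0.4 +/- 0.1, middle-late Triassic 0.5 +/- 0.1; `t_equator`
#'     30 degC for all bins.}
#'   \item{`physio`}{Endotherm body temperature `tb_endotherm` (37 degC),
#'     optional low clamp on ectotherm body temperature `tb_ecto_min`
#'     (disabled when `NULL`), and per-ecology body-water offsets
#'     `ecology_offset` (permil ranges relative to local meteoric water).}
#'   \item{`screening`}{Diagenesis thresholds: maximum structural carbonate
#'     content `carbonate_max_wt_pct` (13.4 wt%) and maximum carbonate-
#'     phosphate offset `cp_diff_max` (14.7 permil); both strict
#'     inequalities. `drop_phosphate_on_cp_fail` additionally discards the
#'     phosphate value of samples failing the offset rule (off by default).}
#'   \item{`stats`}{`analytical_sigma` (0.20 permil), the analytical
#'     reproducibility used as the standard-error floor; and
#'     `stratify_by_material` to aggregate bone and tooth separately.}
#'   \item{`classify`}{`k_sigma`, the half-width multiplier of the
#'     observation interval used in the band-overlap test (1 by default).}
#' }
#'
#' @return A nested named list of parameters.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$climate$permian$gradient_g
default_config <- function() {
  list(
    thermometer = list(intercept = 117.4, slope = 4.50),
    climate = list(
      permian            = list(gradient_g = 0.6, gradient_sigma = 0.1, t_equator = 30),
      early_mid_triassic = list(gradient_g = 0.4, gradient_sigma = 0.1, t_equator = 30),
      mid_late_triassic  = list(gradient_g = 0.5, gradient_sigma = 0.1, t_equator = 30)
    ),
    physio = list(
      tb_endotherm = 37,
      tb_ecto_min = NULL,
      ecology_offset = list(
        terrestrial  = c(0, 2),
        semi_aquatic = c(-2, 0),
        aquatic      = c(-3, -1)
      )
    ),
    screening = list(
      carbonate_max_wt_pct = 13.4,
      cp_diff_max = 14.7,
      drop_phosphate_on_cp_fail = FALSE
    ),
    stats = list(analytical_sigma = 0.20, stratify_by_material = FALSE),
    classify = list(k_sigma = 1.0)
  )
}

#' Read a configuration file
#'
#' Reads a JSON parameter file and merges it over [default_config()], so a
#' file needs to list only the parameters it changes. Nested blocks are merged
#' recursively; ecology offsets given as two-element arrays replace the
#' default range for that ecology.
#'
#' @param path Path to a JSON file, or `NULL` for the defaults.
#' @return A validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(paste0("config file not found: ", path), class = "paleotherm_io_error")
    }
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
  cfg
}

# Recursive list merge; atomic user values replace defaults wholesale.
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$thermometer$slope > 0,
    all(vapply(cfg$climate, function(b) b$gradient_g > 0, logical(1))),
    all(vapply(cfg$climate, function(b) b$gradient_sigma >= 0, logical(1)))
  )
  offs <- cfg$physio$ecology_offset
  for (eco in names(offs)) {
    o <- offs[[eco]]
    if (length(o) != 2 || any(!is.finite(o)) || o[1] > o[2]) {
      abort(paste0("ecology_offset for '", eco,
                   "' must be a finite (low, high) pair with low <= high"),
            class = "paleotherm_config_error")
    }
  }
  if (!all(PT_TIME_BINS %in% names(cfg$climate))) {
    abort("climate block must define all time bins", class = "paleotherm_config_error")
  }
  invisible(cfg)
}

#' Stable hash of a configuration
#'
#' Used to stamp output files so results can be traced back to the exact
#' parameter set that produced them.
#'
#' @param config A configuration list.
#' @return A character scalar hash.
#' @export
config_hash <- function(config) rlang::hash(config)
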