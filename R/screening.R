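#' Screen samples for diagenetic alteration
#'
#' Applies the two preservation criteria for fossil bioapatite:
#'
#' 1. **Carbonate content**: structural carbonate in modern vertebrate
#'    apatite stays below about 13.4 wt%; a fossil exceeding this most likely
#'    carries secondary inorganic carbonate precipitated from diagenetic
#'    fluids, so its carbonate isotope value is discarded.
#' 2. **Carbonate-phosphate offset**: in living vertebrates the carbonate
#'    delta-18-O sits above the phosphate value of the same specimen by a
#'    bounded amount (7-9 permil in mammals, up to 14.7 permil in sharks);
#'    offsets above 14.7 permil indicate microbially mediated alteration and
#'    the sample is considered doubtful.
#'
#' Both thresholds are strict inequalities: a sample sitting exactly at 13.4
#' wt% or at an offset of exactly 14.7 permil passes. Each rule evaluates to
#' `pass`, `fail` or `not_evaluable` when the needed measurements are absent;
#' the two rules are independent. Low-temperature inorganic alteration of
#' carbonate has little effect on phosphate delta-18-O, so a carbonate
#' failure does not by itself discard the phosphate value:
#' `phosphate_usable` stays `TRUE` unless `drop_phosphate_on_cp_fail` is set,
#' in which case samples failing the offset rule (the microbial-alteration
#' signal) have their phosphate value dropped too.
#'
#' @param samples A samples tibble (see [read_samples()]).
#' @param carbonate_max_wt_pct Carbonate-content threshold in wt%.
#' @param cp_diff_max Carbonate-phosphate offset threshold in permil.
#' @param drop_phosphate_on_cp_fail Also mark phosphate unusable when the
#'   offset rule fails.
#' @return A tibble with one row per sample: `sample_id`, `carbonate_ok`,
#'   `cp_diff`, `cp_diff_ok`, `phosphate_usable`.
#' @export
#' @examples
#' s <- tibble::tibble(
#'   sample_id = "a", specimen_id = "a", taxon = "t", group = "therapsid",
#'   ecology = "terrestrial", material = "bone", locality_id = "L1",
#'   d18Op = 20, d18Oc = 36, carbonate_wt_pct = 5
#' )
#' screen_samples(s)  # cp_diff 16 > 14.7: offset rule fails
screen_samples <- function(samples,
                           carbonate_max_wt_pct = 13.4,
                           cp_diff_max = 14.7,
                           drop_phosphate_on_cp_fail = FALSE) {
  carb <- samples$carbonate_wt_pct
  cp_diff <- ifelse(!is.na(samples$d18Oc) & !is.na(samples$d18Op),
                    samples$d18Oc - samples$d18Op, NA_real_)

  # strict inequality with a tiny guard so values sitting exactly at a
  # threshold pass even when reached through floating-point subtraction
  tri <- function(value, threshold) {
    dplyr::case_when(
      is.na(value)             ~ "not_evaluable",
      value > threshold + 1e-9 ~ "fail",
      TRUE                     ~ "pass"
    )
  }
  carbonate_ok <- tri(carb, carbonate_max_wt_pct)
  cp_diff_ok <- tri(cp_diff, cp_diff_max)

  phosphate_usable <- rep(TRUE, nrow(samples))
  if (isTRUE(drop_phosphate_on_cp_fail)) {
    phosphate_usable <- cp_diff_ok != "fail"
  }

  tibble(
    sample_id = samples$sample_id,
    carbonate_ok = carbonate_ok,
    cp_diff = cp_diff,
    cp_diff_ok = cp_diff_ok,
    phosphate_usable = phosphate_usable
  )
}

#' Screen a single sample
#'
#' Convenience wrapper around [screen_samples()] for one sample row.
#'
#' @inheritParams screen_samples
#' @param sample A one-row samples tibble.
#' @return A one-row screening tibble.
#' @export
screen_sample <- function(sample,
                          carbonate_max_wt_pct = 13.4,
                          cp_diff_max = 14.7,
                          drop_phosphate_on_cp_fail = FALSE) {
  stopifnot(nrow(sample) == 1)
  screen_samples(sample, carbonate_max_wt_pct, cp_diff_max,
                 drop_phosphate_on_cp_fail)
}

#' Screen a whole dataset and summarise outcomes
#'
#' Runs [screen_samples()] with the thresholds in `config$screening` and
#' tallies pass/fail/not-evaluable counts per rule.
#'
#' @param samples A samples tibble.
#' @param config A configuration list (see [default_config()]).
#' @return A list with `results` (per-sample screening tibble) and `summary`
#'   (a tibble of counts per rule and outcome).
#' @export
screen_dataset <- function(samples, config = default_config()) {
  sc <- config$screening
  results <- screen_samples(samples,
                            carbonate_max_wt_pct = sc$carbonate_max_wt_pct,
                            cp_diff_max = sc$cp_diff_max,
                            drop_phosphate_on_cp_fail = sc$drop_phosphate_on_cp_fail)
  outcomes <- c("pass", "fail", "not_evaluable")
  summary <- bind_rows(
    tibble(rule = "carbonate_content", outcome = outcomes,
           n = as.integer(table(factor(results$carbonate_ok, levels = outcomes)))),
    tibble(rule = "cp_offset", outcome = outcomes,
           n = as.integer(table(factor(results$cp_diff_ok, levels = outcomes))))
  )
  list(results = results, summary = summary)
}
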