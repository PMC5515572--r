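#' Per-taxon, per-locality phosphate delta-18-O statistics
#'
#' Aggregates screened phosphate delta-18-O values hierarchically: subsamples
#' of one individual (shared `specimen_id`) are averaged first, then the
#' taxon mean is the unweighted mean across individuals. This keeps heavily
#' subsampled specimens from dominating a taxon mean; the individual is the
#' biological unit.
#'
#' Dispersion is computed across individual means: `sd_d18Op` is `NA` for a
#' single individual. The standard error `se_d18Op` is never missing: it is
#' `sd / sqrt(n_individuals)`, floored at `analytical_sigma / sqrt(n)` so it
#' can never fall below what analytical reproducibility allows, and equal to
#' `analytical_sigma` itself for single-individual taxa. The default floor of
#' 0.20 permil is the long-term reproducibility of the NBS120c phosphorite
#' standard.
#'
#' @param samples A samples tibble.
#' @param screening Optional screening tibble from [screen_samples()]; rows
#'   with `phosphate_usable == FALSE` are excluded.
#' @param analytical_sigma Analytical reproducibility (1 s.d., permil) used
#'   as the standard-error floor.
#' @param stratify_by_material If `TRUE`, aggregate bone and tooth values
#'   separately (adds a `material` column); by default they are pooled.
#' @return A tibble with one row per (taxon, locality): `taxon`,
#'   `locality_id`, `group`, `ecology`, `n_samples`, `n_individuals`,
#'   `mean_d18Op`, `sd_d18Op`, `se_d18Op`.
#' @export
taxon_stats <- function(samples, screening = NULL, analytical_sigma = 0.20,
                        stratify_by_material = FALSE) {
  stopifnot(analytical_sigma > 0)
  x <- samples
  if (!is.null(screening)) {
    usable <- screening$sample_id[screening$phosphate_usable]
    x <- x[x$sample_id %in% usable, , drop = FALSE]
  }
  x <- x[!is.na(x$d18Op), , drop = FALSE]
  if (nrow(x) == 0) {
    inform("taxon_stats: no usable samples; returning empty table")
    return(tibble(taxon = character(), locality_id = character(),
                  group = character(), ecology = character(),
                  n_samples = integer(), n_individuals = integer(),
                  mean_d18Op = double(), sd_d18Op = double(),
                  se_d18Op = double()))
  }

  keys <- c("taxon", "locality_id", if (stratify_by_material) "material")

  indiv <- x %>%
    group_by(dplyr::across(dplyr::all_of(c(keys, "specimen_id")))) %>%
    summarise(
      group = .data$group[1],
      ecology = .data$ecology[1],
      n_sub = dplyr::n(),
      indiv_mean = mean(.data$d18Op),
      .groups = "drop"
    )

  indiv %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(
      group = .data$group[1],
      ecology = .data$ecology[1],
      n_samples = as.integer(sum(.data$n_sub)),
      n_individuals = dplyr::n(),
      mean_d18Op = mean(.data$indiv_mean),
      sd_d18Op = ifelse(dplyr::n() >= 2, sd(.data$indiv_mean), NA_real_),
      .groups = "drop"
    ) %>%
    mutate(
      se_d18Op = pmax(
        ifelse(is.na(.data$sd_d18Op), 0,
               .data$sd_d18Op / sqrt(.data$n_individuals)),
        analytical_sigma / sqrt(.data$n_individuals)
      )
    )
}

#' Difference between two co-located taxon means
#'
#' Forms the therapsid-minus-reference phosphate delta-18-O difference for
#' two taxa from the same locality. Printed "+/-" values throughout the
#' pipeline are 1-sigma standard errors; the uncertainty of a difference is
#' the quadrature sum `sqrt(se_a^2 + se_b^2)`. Two single-specimen taxa with
#' the 0.20 permil analytical floor therefore combine to 0.28 permil.
#'
#' @param a One-row [taxon_stats()] tibble for the therapsid taxon.
#' @param b One-row [taxon_stats()] tibble for the reference taxon.
#' @param locality One-row locality tibble (see [read_localities()]); must
#'   match both taxa's `locality_id`.
#' @return A one-row tibble: `therapsid_taxon`, `reference_taxon`,
#'   `reference_group`, `reference_ecology`, `locality_id`, `palaeolat_abs`,
#'   `palaeolat_sigma_deg`, `delta`, `delta_sigma`, `time_bin`.
#' @export
pair_difference <- function(a, b, locality) {
  stopifnot(nrow(a) == 1, nrow(b) == 1, nrow(locality) == 1)
  if (a$locality_id != b$locality_id) {
    abort(paste0("pair_difference: taxa are not co-located (",
                 a$locality_id, " vs ", b$locality_id, ")"),
          class = "paleotherm_pairing_error")
  }
  if (locality$locality_id != a$locality_id) {
    abort("pair_difference: locality row does not match the taxa",
          class = "paleotherm_pairing_error")
  }
  tibble(
    therapsid_taxon = a$taxon,
    reference_taxon = b$taxon,
    reference_group = b$group,
    reference_ecology = b$ecology,
    locality_id = a$locality_id,
    palaeolat_abs = locality$palaeolat_abs,
    palaeolat_sigma_deg = locality$palaeolat_sigma_deg,
    delta = a$mean_d18Op - b$mean_d18Op,
    delta_sigma = sqrt(a$se_d18Op^2 + b$se_d18Op^2),
    time_bin = locality$time_bin
  )
}

#' All therapsid-vs-reference pair differences
#'
#' Emits one [pair_difference()] row for every (therapsid, non-therapsid)
#' taxon pair sharing a locality, sorted by time bin and absolute
#' palaeolatitude. Therapsid taxa with no co-located reference produce a
#' warning and no rows.
#'
#' @param stats A [taxon_stats()] tibble.
#' @param localities A localities tibble.
#' @param therapsid_group Group label identifying the focal clade.
#' @return A tibble of pair differences.
#' @export
all_pairs <- function(stats, localities, therapsid_group = "therapsid") {
  ther <- stats[stats$group == therapsid_group, , drop = FALSE]
  refs <- stats[stats$group != therapsid_group, , drop = FALSE]

  orphan <- setdiff(ther$locality_id, refs$locality_id)
  if (length(orphan) > 0) {
    orphan_taxa <- unique(ther$taxon[ther$locality_id %in% orphan])
    warn(paste0("therapsid taxa with no co-located reference taxon: ",
                paste(orphan_taxa, collapse = ", ")))
  }
  if (nrow(ther) == 0 || nrow(refs) == 0) {
    return(empty_pairs())
  }

  pairs <- purrr::map_dfr(seq_len(nrow(ther)), function(i) {
    a <- ther[i, , drop = FALSE]
    co <- refs[refs$locality_id == a$locality_id, , drop = FALSE]
    if (nrow(co) == 0) return(NULL)
    loc <- localities[localities$locality_id == a$locality_id, , drop = FALSE]
    if (nrow(loc) != 1) {
      abort(paste0("all_pairs: locality '", a$locality_id,
                   "' absent from locality table"),
            class = "paleotherm_pairing_error")
    }
    purrr::map_dfr(seq_len(nrow(co)),
                   function(j) pair_difference(a, co[j, , drop = FALSE], loc))
  })
  if (nrow(pairs) == 0) return(empty_pairs())
  pairs %>%
    mutate(time_bin = factor(.data$time_bin, levels = PT_TIME_BINS)) %>%
    arrange(.data$time_bin, .data$palaeolat_abs,
            .data$therapsid_taxon, .data$reference_taxon) %>%
    mutate(time_bin = as.character(.data$time_bin))
}

empty_pairs <- function() {
  tibble(therapsid_taxon = character(), reference_taxon = character(),
         reference_group = character(), reference_ecology = character(),
         locality_id = character(), palaeolat_abs = double(),
         palaeolat_sigma_deg = double(), delta = double(),
         delta_sigma = double(), time_bin = character())
}
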