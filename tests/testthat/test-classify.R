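cfg <- default_config()
env_perm <- build_envelopes("permian", cfg)

make_pair <- function(delta, sigma = 0.3, lat = 55, eco = "semi_aquatic",
                      group = "stereospondyl", bin = "permian") {
  tibble::tibble(
    therapsid_taxon = "Ther", reference_taxon = "Ref",
    reference_group = group, reference_ecology = eco,
    locality_id = "L1", palaeolat_abs = lat, palaeolat_sigma_deg = 3,
    delta = delta, delta_sigma = sigma, time_bin = bin
  )
}

test_that("band membership maps onto the four calls against an ectotherm reference", {
  # at 55 deg permian the oblique semi-aquatic band is far negative, the
  # vertical band is the ecology offset difference [0, 4]
  ecto <- classify_pair(make_pair(2.0), env_perm, "ectotherm")
  expect_true(ecto$in_same_thermo_band && !ecto$in_endo_band)
  expect_equal(ecto$call, "ectotherm-like")

  endo <- classify_pair(make_pair(-6.0), env_perm, "ectotherm")
  expect_true(endo$in_endo_band && !endo$in_same_thermo_band)
  expect_equal(endo$call, "endotherm-like")

  # interval spanning both bands is ambiguous
  amb <- classify_pair(make_pair(-2.0, sigma = 2.0), env_perm, "ectotherm")
  expect_true(amb$in_endo_band && amb$in_same_thermo_band)
  expect_equal(amb$call, "ambiguous")

  none <- classify_pair(make_pair(15.0), env_perm, "ectotherm")
  expect_false(none$in_endo_band || none$in_same_thermo_band)
  expect_equal(none$call, "out-of-model")
})

test_that("membership semantics flip against a presumed-endotherm reference", {
  env_tri <- build_envelopes("early_mid_triassic", cfg)
  # a near-zero difference vs an endotherm: shared thermophysiology
  p <- make_pair(0.4, lat = 33, eco = "terrestrial", group = "archosauriform",
                 bin = "early_mid_triassic")
  call <- classify_pair(p, env_tri, "endotherm")
  expect_true(call$in_same_thermo_band)
  expect_equal(call$call, "endotherm-like")
  # a strongly positive difference vs an endotherm: the focal taxon ran hotter
  # apatite, i.e. colder body: the reflected oblique band, ectotherm-like
  p2 <- make_pair(4.5, lat = 33, eco = "terrestrial", group = "archosauriform",
                  bin = "early_mid_triassic")
  call2 <- classify_pair(p2, env_tri, "endotherm")
  expect_true(call2$in_endo_band && !call2$in_same_thermo_band)
  expect_equal(call2$call, "ectotherm-like")
})

test_that("growing k_sigma only widens calls toward ambiguity", {
  ranks <- c("endotherm-like" = 1, "ambiguous" = 0, "out-of-model" = 0,
             "ectotherm-like" = -1)
  for (delta in seq(-8, 4, by = 0.5)) {
    calls <- vapply(c(0.5, 1, 2, 4, 8), function(k) {
      classify_pair(make_pair(delta, sigma = 0.5), env_perm, "ectotherm",
                    k_sigma = k)$call
    }, character(1))
    decisive <- calls[calls %in% c("endotherm-like", "ectotherm-like")]
    # never both directions along the k path
    expect_lte(length(unique(decisive)), 1)
    # once ambiguous, stays ambiguous as k grows further
    amb_idx <- which(calls == "ambiguous")
    if (length(amb_idx) > 0) {
      expect_true(all(calls[seq(min(amb_idx), length(calls))] == "ambiguous"))
    }
  }
})

test_that("calls are invariant to a constant shift of both taxa's values", {
  loc <- make_locality(lat = -55)
  build_calls <- function(shift) {
    s <- dplyr::bind_rows(
      make_samples(c(11.8, 12.2) + shift),
      make_samples(c(17.8, 18.2) + shift, taxon = "Ref",
                   group = "stereospondyl", ecology = "semi_aquatic")
    )
    pr <- all_pairs(taxon_stats(s), loc)
    classify_all(pr, env_perm)$calls
  }
  c0 <- build_calls(0)
  c5 <- build_calls(5)
  expect_equal(c0$call, c5$call)
  expect_equal(c0$delta, c5$delta)
})

test_that("classify_all resolves reference physiology and reports gaps", {
  loc <- make_locality(lat = -55)
  s <- dplyr::bind_rows(
    make_samples(c(11.8, 12.2)),
    make_samples(c(17.8, 18.2), taxon = "Ref", group = "stereospondyl",
                 ecology = "semi_aquatic")
  )
  pr <- all_pairs(taxon_stats(s), loc)
  out <- classify_all(pr, env_perm)
  expect_equal(out$calls$reference_presumed_thermo, "ectotherm")
  expect_equal(out$calls$call, "endotherm-like")
  expect_equal(out$summary$n, 1L)

  # per-taxon override beats the group default
  over <- classify_all(pr, env_perm,
                       taxon_thermo = tibble::tibble(
                         taxon = "Ref", presumed_thermo = "endotherm"))
  expect_equal(over$calls$reference_presumed_thermo, "endotherm")

  # unknown group with no override errors, naming the taxon
  bad <- classify_all  # keep line width down
  missing_tbl <- default_reference_thermo()
  missing_tbl <- missing_tbl[missing_tbl$group != "stereospondyl", ]
  expect_error(bad(pr, env_perm, reference_table = missing_tbl), "Ref",
               class = "paleotherm_reference_error")

  # empty input gives empty, well-formed output
  none <- classify_all(pr[0, ], env_perm)
  expect_equal(nrow(none$calls), 0)
})

test_that("classification is deterministic for identical inputs", {
  p <- make_pair(-5.5)
  expect_identical(classify_pair(p, env_perm, "ectotherm"),
                   classify_pair(p, env_perm, "ectotherm"))
})

test_that("an unavailable scenario raises an envelope error", {
  p <- make_pair(1.0, eco = "aquatic")
  expect_error(classify_pair(p, env_perm, "ectotherm"),
               class = "paleotherm_envelope_error")
  env_aq <- build_envelopes("permian", cfg,
                            ecologies = c("semi_aquatic", "terrestrial", "aquatic"))
  expect_no_error(classify_pair(p, env_aq, "ectotherm"))
})
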