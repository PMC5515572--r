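cfg <- default_config()

test_that("ectotherm body temperature follows the linear gradient with optional clamp", {
  perm <- cfg$climate$permian
  expect_equal(body_temp_ectotherm(0, perm), perm$t_equator)
  expect_equal(body_temp_ectotherm(50, perm), 0)  # 30 - 0.6 * 50
  physio <- cfg$physio
  physio$tb_ecto_min <- 10
  expect_equal(body_temp_ectotherm(50, perm, physio), 10)
  expect_equal(body_temp_ectotherm(c(0, 20, 50), perm, physio),
               c(30, 18, 10))
})

test_that("the thermometer and its inverse are consistent", {
  th <- cfg$thermometer
  expect_equal(predicted_d18Op(th$intercept, 0, th), 0)  # fixed point
  expect_equal(predicted_d18Op(37, 0, th), 17.87, tolerance = 0.005)
  for (tb in seq(0, 60, by = 7.5)) {
    for (w in c(-8, 0, 3)) {
      expect_equal(apatite_temperature(predicted_d18Op(tb, w, th), w, th), tb,
                   tolerance = 1e-10)
    }
  }
})

test_that("pair-delta predictions reduce to known arithmetic", {
  # identical physiology and ecology: band centred at 0, latitude-independent
  same <- predicted_pair_delta(c(0, 30, 60, 90), "endotherm", "endotherm",
                               "terrestrial", cfg)
  expect_equal(same$delta_min, rep(-2, 4))
  expect_equal(same$delta_max, rep(2, 4))
  expect_equal(same$delta_min, -same$delta_max)

  # thermal term at 50 deg, permian central gradient: (0 - 37)/4.5
  point <- predicted_pair_delta(50, "endotherm", "ectotherm", "terrestrial",
                                cfg, use_gradient_sigma = FALSE)
  eco <- cfg$physio$ecology_offset$terrestrial
  thermal <- (0 - 37) / 4.5
  expect_equal(point$delta_min, thermal + eco[1] - eco[2])
  expect_equal(point$delta_max, thermal + eco[2] - eco[1])
  expect_equal(thermal, -8.2222, tolerance = 1e-4)

  # at the latitude where ambient equals endotherm Tb the thermal term is 0
  lat_cross <- (cfg$climate$permian$t_equator - cfg$physio$tb_endotherm) /
    cfg$climate$permian$gradient_g  # negative: bands cross only off-grid
  expect_lt(lat_cross, 0)
  at0 <- predicted_pair_delta(0, "endotherm", "ectotherm", "terrestrial",
                              cfg, use_gradient_sigma = FALSE)
  expect_equal((at0$delta_min + at0$delta_max) / 2,
               (cfg$climate$permian$t_equator - 37) / 4.5)

  expect_error(predicted_pair_delta(10, "endotherm", "ectotherm", "marine", cfg),
               "ecology", class = "paleotherm_config_error")
})

test_that("envelope centerlines match a brute-force two-animal evaluation", {
  # oracle: difference of two predicted_d18Op values at mid-range offsets,
  # arbitrary meteoric water (must cancel)
  lat <- seq(0, 90, by = 0.5)
  for (bin in c("permian", "early_mid_triassic", "mid_late_triassic")) {
    climate <- cfg$climate[[bin]]
    for (eco in c("terrestrial", "semi_aquatic")) {
      mw <- -0.25 * lat + 2  # arbitrary; cancels between co-located animals
      e_th <- mean(cfg$physio$ecology_offset$terrestrial)
      e_ref <- mean(cfg$physio$ecology_offset[[eco]])
      amb <- body_temp_ectotherm(lat, climate)
      oracle <- predicted_d18Op(37, mw + e_th, cfg$thermometer) -
        predicted_d18Op(amb, mw + e_ref, cfg$thermometer)
      band <- predicted_pair_delta(lat, "endotherm", "ectotherm", eco, cfg,
                                   time_bin = bin, use_gradient_sigma = FALSE)
      centre <- (band$delta_min + band$delta_max) / 2
      expect_equal(centre, oracle, tolerance = 1e-10)
      # centerline slope is -g / thermometer slope per degree
      fit <- lm(centre ~ lat)
      expect_equal(unname(coef(fit)[2]),
                   -climate$gradient_g / cfg$thermometer$slope,
                   tolerance = 1e-10)
    }
  }
})

test_that("envelope grids nest, collapse and count as constructed", {
  env <- build_envelopes("permian", cfg)
  expect_equal(nrow(env), 4 * 91)
  expect_setequal(unique(env$scenario),
                  c("endo_vs_ecto_semiaquatic", "endo_vs_ecto_terrestrial",
                    "same_thermo_semiaquatic", "same_thermo_terrestrial"))
  expect_true(all(env$core_min <= env$core_max))
  expect_true(all(env$outer_min <= env$outer_max))
  # outer band contains the core band everywhere
  expect_true(all(env$outer_min <= env$core_min + 1e-12))
  expect_true(all(env$outer_max >= env$core_max - 1e-12))
  # oblique scenarios strictly widen away from the equator
  obl <- env[env$scenario == "endo_vs_ecto_terrestrial" & env$lat > 0, ]
  expect_true(all(obl$outer_min < obl$core_min))
  # vertical scenarios are latitude-independent with outer == core
  vert <- env[env$scenario == "same_thermo_semiaquatic", ]
  expect_equal(length(unique(vert$core_min)), 1L)
  expect_equal(vert$outer_min, vert$core_min)
  expect_equal(vert$outer_max, vert$core_max)
  # symmetric same-ecology band
  st <- env[env$scenario == "same_thermo_terrestrial", ]
  expect_equal(st$core_min, -st$core_max)

  # zero gradient uncertainty collapses outer onto core
  cfg0 <- cfg
  cfg0$climate$permian$gradient_sigma <- 0
  env0 <- build_envelopes("permian", cfg0)
  expect_equal(env0$outer_min, env0$core_min)
  expect_equal(env0$outer_max, env0$core_max)
})

test_that("time bins differ only through their climate block", {
  cfg2 <- cfg
  cfg2$climate$early_mid_triassic <- cfg2$climate$permian
  a <- build_envelopes("permian", cfg2)
  b <- build_envelopes("early_mid_triassic", cfg2)
  expect_equal(a[setdiff(names(a), "time_bin")],
               b[setdiff(names(b), "time_bin")])
})

test_that("an exported grid re-reads to identical band lookups", {
  env <- build_envelopes("permian", cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_envelope_grid(env, f, meta = c(config_hash = config_hash(cfg)))
  env2 <- read_result_table(f)
  expect_equal(as.data.frame(env2), as.data.frame(env), tolerance = 1e-12)
})
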