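test_that("kill fraction has the saturating hyperbola's anchors", {
  cfg <- sim_config(n_compounds = 80, seed = 1)
  expect_equal(kill_fraction(0, 1, 1, cfg), 0)
  expect_equal(kill_fraction(cfg$kill_k, 1, 1, cfg), cfg$kill_fmax / 2)
  expect_lt(abs(kill_fraction(1e9, 1, 1, cfg) - cfg$kill_fmax), 1e-6)
  r <- c(0.5, 1, 3, 9, 27, 81)
  expect_true(all(diff(kill_fraction(r, 1, 1, cfg)) > 0))
  expect_true(all(kill_fraction(r, 3, 1, cfg) > kill_fraction(r, 1, 1, cfg)))
  # potency scales the achievable plateau
  expect_equal(kill_fraction(1e9, 1, 0.5, cfg), 0.5 * cfg$kill_fmax,
               tolerance = 1e-6)
})

test_that("noise-free well model hits its closed-form anchors", {
  cfg <- sim_config(n_compounds = 80, noise_cv = 0, seed = 2)
  expect_equal(simulate_well("negative_control", "target_alone",
                             config = cfg, noise = FALSE),
               cfg$base_spontaneous)
  expect_equal(simulate_well("compound", "target_alone", toxic_fraction = 1,
                             config = cfg, noise = FALSE),
               cfg$base_maximal)
  expect_equal(simulate_well("positive_control", "target_alone",
                             config = cfg, noise = FALSE),
               cfg$base_maximal)
  # co-culture compound fold-change over DMSO in closed form
  e <- 2.5
  f_e <- kill_fraction(cfg$compound_et, e, 1, cfg)
  f_0 <- kill_fraction(cfg$compound_et, 1, 1, cfg)
  dyn <- cfg$base_maximal - cfg$base_spontaneous
  want_fc <- (cfg$base_spontaneous + f_e * dyn) /
    (cfg$base_spontaneous + f_0 * dyn)
  got_fc <- simulate_well("compound", "coculture", effect = e,
                          config = cfg, noise = FALSE) /
    simulate_well("negative_control", "coculture", config = cfg,
                  noise = FALSE)
  expect_equal(got_fc, want_fc)
})

test_that("every zero-noise simulated RLU equals its expected value", {
  cfg <- sim_config(n_compounds = 160, noise_cv = 0, plate_gain_cv = 0,
                    seed = 3)
  sim <- simulate_screen(cfg)
  tr <- sim$truth
  for (i in sample(nrow(sim$reads), 200)) {
    row <- sim$reads[i, ]
    lay <- plate_layout(sim$layout, row$plate_id, row$condition)
    role <- lay$role[lay$well == row$well]
    cid <- lay$compound_id[lay$well == row$well]
    pl <- tr$plates[tr$plates$plate_id == row$plate_id &
                      tr$plates$replicate_id == row$replicate_id &
                      tr$plates$condition == row$condition, ]
    eff <- 1; tox <- 0
    if (!is.na(cid)) {
      cmp <- tr$compounds[tr$compounds$compound_id == cid, ]
      eff <- cmp$effect; tox <- cmp$toxic_fraction
    }
    expect_equal(row$rlu,
                 expected_well_rlu(role, row$condition, eff, tox,
                                   pl$potency, pl$spontaneous, cfg))
  }
})

test_that("simulation is deterministic and plate substreams reproduce", {
  cfg <- sim_config(n_compounds = 160, seed = 42)
  s1 <- simulate_screen(cfg)
  s2 <- simulate_screen(sim_config(n_compounds = 160, seed = 42))
  expect_identical(s1$reads, s2$reads)
  f1 <- tempfile(); f2 <- tempfile()
  write_plate_reads(s1$reads, f1)
  write_plate_reads(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_screen(sim_config(n_compounds = 160, seed = 43))
  expect_false(identical(s1$reads$rlu, s3$reads$rlu))
})

test_that("pre-seed drift lowers co-culture Z' on later plates", {
  zdiffs <- vapply(1:5, function(s) {
    cfg <- sim_config(n_compounds = 1200, seed = 500 + s,
                      seed_interval_min = 20, replicates = 1)
    sim <- simulate_screen(cfg)
    qc <- screen_qc_report(sim$reads, sim$layout)
    co <- qc$per_plate[qc$per_plate$condition == "coculture", ]
    co <- co[order(co$plate_id), ]
    mean(co$z_prime[1:5]) - mean(co$z_prime[11:15])
  }, numeric(1))
  expect_gt(mean(zdiffs), 0)
})

test_that("later plates also show inflated spontaneous release", {
  cfg <- sim_config(n_compounds = 1200, seed = 77, seed_interval_min = 20)
  drift <- nkscreen:::plate_drift((15 - 1) * cfg$seed_interval_min, cfg)
  expect_lt(drift$potency, 1)
  expect_gt(drift$spont, cfg$base_spontaneous)
  early <- nkscreen:::plate_drift(60, cfg)
  expect_equal(early$potency, 1)
  expect_equal(early$spont, cfg$base_spontaneous)
})

test_that("hit-calling sensitivity rises with planted effect size", {
  sens <- vapply(c(1.6, 2.5, 4), function(effect) {
    hits <- 0; total <- 0
    for (s in 1:3) {
      ids <- sprintf("C%04d", 1:160)
      enh <- stats::setNames(rep(effect, 4), ids[c(10, 50, 90, 130)])
      cfg <- sim_config(n_compounds = 160, enhancer_effects = enh,
                        toxic_compounds = NULL, seed = 600 + s)
      sim <- simulate_screen(cfg)
      fc <- fold_change_screen(sim$reads, sim$layout)
      ht <- call_hits(dplyr::filter(fc, condition == "coculture"),
                      dplyr::filter(fc, condition == "target_alone"))
      hits <- hits + sum(ht$status[ht$compound_id %in% names(enh)] == "hit")
      total <- total + length(enh)
    }
    hits / total
  }, numeric(1))
  expect_lte(sens[1], sens[2])
  expect_lte(sens[1], sens[3])
  expect_gt(sens[3], sens[1])
})

test_that("simulated dose-response emits a complete, well-formed table", {
  cfg <- sim_config(n_compounds = 80, noise_cv = 0.05, seed = 21)
  eff <- stats::setNames(c(1, 1, 3, 3, 3), c(0, 1, 5, 10, 20))
  reads <- simulate_dose_response(eff, config = cfg)
  expect_equal(sum(reads$role == "experimental"), 5 * 2 * 3)
  expect_equal(sum(reads$role == "spontaneous"), 5 * 3)
  expect_equal(sum(reads$role == "maximal"), 3)
  dr <- dose_response_lysis(reads)
  sm <- dose_response_summary(dr)
  # higher E:T gives at least as much killing in every dose row
  wide <- split(sm$mean_lysis, sm$et_ratio)
  expect_true(all(wide[["3"]] > wide[["1"]]))
  # monotone effect in dose implies monotone mean lysis at zero noise
  cfg0 <- sim_config(n_compounds = 80, noise_cv = 0, seed = 21)
  eff_mono <- stats::setNames(c(1, 1.5, 2, 3, 4), c(0, 1, 5, 10, 20))
  sm0 <- dose_response_summary(
    dose_response_lysis(simulate_dose_response(eff_mono, config = cfg0)))
  for (r in unique(sm0$et_ratio)) {
    block <- sm0[sm0$et_ratio == r, ]
    block <- block[order(block$dose_uM), ]
    expect_true(all(diff(block$mean_lysis) > 0))
  }
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(sim_config(n_compounds = 80), "seed")
  expect_error(sim_config(n_compounds = 80, base_spontaneous = 500,
                          base_maximal = 400, seed = 1))
  expect_error(sim_config(n_compounds = 80, seed = 1,
                          enhancer_effects = c(nope = 2)), "known compound")
  expect_error(sim_config(n_compounds = 80, seed = 1,
                          enhancer_effects = stats::setNames(0.5, "C0001")),
               "> 1")
  expect_error(sim_config(n_compounds = 80, seed = 1,
                          toxic_compounds = stats::setNames(1.5, "C0001")),
               "\\[0, 1\\]")
  expect_warning(sim_config(
    n_compounds = 80, seed = 1,
    enhancer_effects = stats::setNames(2, "C0001"),
    toxic_compounds = stats::setNames(0.3, "C0001")),
    "both enhancer and toxic")
})
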