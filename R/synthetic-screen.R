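# Generative model of the full luciferase-release screen.
#
# The simulator emits plate reads with known ground truth so that QC, hit
# calling and dose-response validation can be exercised end to end without
# external data. The well model:
#
#   expected RLU = spont + f_total * (maximal - spont)
#
# where f_total combines NK killing (co-culture wells only) with direct
# compound toxicity to the target cells (both conditions) as independent
# lysis routes: f_total = 1 - (1 - f_kill) * (1 - f_toxic). NK killing
# follows a saturating hyperbola in the effector:target ratio,
#
#   f_kill = potency * kill_fmax * (effect * r) / (kill_k + effect * r)
#
# with an enhancer acting as a multiplier on the effective E:T ratio and
# plate-level effector potency scaling the achievable plateau (the
# functional capacity NK cells lose while waiting at room temperature
# before seeding). Potency is 1 up to `drift_onset_min` of pre-seed wait
# and then declines linearly; spontaneous release inflates slightly over
# the same window. Observed RLU = expected * plate gain * multiplicative
# lognormal well noise.

#' Simulation configuration for a synthetic screen
#'
#' Defaults emulate a two-day screen of a 1200-compound library at 10 uM:
#' 15 paired plates per condition, compounds at E:T = 1 in co-culture,
#' digitonin or 9:1 E:T positive controls, multiplicative well noise with
#' 10% CV, and effector-potency decay once plates wait more than 120 min
#' before seeding.
#'
#' @param n_compounds Library size (default 1200; 80 compounds per plate).
#' @param compound_ids Compound identifiers (default `"C0001"`...).
#' @param enhancer_effects Named numeric vector: killing multiplier (> 1)
#'   per enhancer compound. Defaults to [default_truth()] placement.
#' @param toxic_compounds Named numeric vector: direct target-lysis
#'   fraction (0-1) per toxic compound.
#' @param base_spontaneous Mean RLU of intact target cells (default 1000).
#' @param base_maximal Mean RLU of digitonin-lysed targets (default 21000).
#' @param kill_fmax Plateau kill fraction of the saturating hyperbola
#'   (default 0.9).
#' @param kill_k Half-saturation E:T ratio (default 3): E:T = 1 then gives
#'   minimal but detectable killing while E:T = 81 is saturated.
#' @param compound_et E:T ratio in compound and DMSO co-culture wells
#'   (default 1).
#' @param positive_et E:T ratio of the co-culture positive control
#'   (default 9).
#' @param noise_cv Lognormal well-noise coefficient of variation
#'   (default 0.1).
#' @param plate_gain_cv Lognormal per-plate gain CV (default 0.05).
#' @param drift_onset_min Pre-seed wait (minutes) after which effector
#'   potency starts to decay (default 120).
#' @param drift_rate_per_min Linear potency loss per minute past onset
#'   (default 1/240: a 240-min wait halves potency).
#' @param spont_drift_rate_per_min Relative spontaneous-release inflation
#'   per minute past onset (default 5e-4).
#' @param seed_interval_min Minutes between seeding consecutive plates of a
#'   screening day (default 12).
#' @param replicates Number of screening days (default 2).
#' @param seed Integer RNG seed (required).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_compounds = 1200,
                       compound_ids = sprintf("C%04d", seq_len(n_compounds)),
                       enhancer_effects = NULL,
                       toxic_compounds = NULL,
                       base_spontaneous = 1000,
                       base_maximal = 21000,
                       kill_fmax = 0.9,
                       kill_k = 3,
                       compound_et = 1,
                       positive_et = 9,
                       noise_cv = 0.1,
                       plate_gain_cv = 0.05,
                       drift_onset_min = 120,
                       drift_rate_per_min = 1 / 240,
                       spont_drift_rate_per_min = 5e-4,
                       seed_interval_min = 12,
                       replicates = 2,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    stop("sim_config() requires an explicit integer seed", call. = FALSE)
  }
  if (length(compound_ids) != n_compounds) {
    stop("compound_ids must have length n_compounds", call. = FALSE)
  }
  if (is.null(enhancer_effects) && is.null(toxic_compounds)) {
    truth <- default_truth(compound_ids)
    enhancer_effects <- truth$enhancer_effects
    toxic_compounds <- truth$toxic_compounds
  }
  enhancer_effects <- enhancer_effects %||% stats::setNames(numeric(0), NULL)
  toxic_compounds <- toxic_compounds %||% stats::setNames(numeric(0), NULL)

  stopifnot(
    n_compounds >= 1,
    base_maximal > base_spontaneous, base_spontaneous >= 0,
    kill_fmax > 0, kill_fmax <= 1, kill_k > 0,
    compound_et > 0, positive_et > 0,
    noise_cv >= 0, plate_gain_cv >= 0,
    drift_onset_min >= 0, drift_rate_per_min >= 0,
    spont_drift_rate_per_min >= 0, seed_interval_min >= 0,
    replicates >= 1
  )
  if (length(enhancer_effects) > 0) {
    if (is.null(names(enhancer_effects)) ||
        !all(names(enhancer_effects) %in% compound_ids)) {
      stop("enhancer_effects must be named by known compound_ids",
           call. = FALSE)
    }
    if (any(enhancer_effects <= 1)) {
      stop("enhancer effects must be > 1 (killing multipliers)",
           call. = FALSE)
    }
  }
  if (length(toxic_compounds) > 0) {
    if (is.null(names(toxic_compounds)) ||
        !all(names(toxic_compounds) %in% compound_ids)) {
      stop("toxic_compounds must be named by known compound_ids",
           call. = FALSE)
    }
    if (any(toxic_compounds < 0 | toxic_compounds > 1)) {
      stop("toxic fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  overlap <- intersect(names(enhancer_effects), names(toxic_compounds))
  if (length(overlap) > 0) {
    warning("compounds both enhancer and toxic: ",
            paste(overlap, collapse = ", "), call. = FALSE)
  }

  structure(
    list(n_compounds = as.integer(n_compounds),
         compound_ids = as.character(compound_ids),
         enhancer_effects = enhancer_effects,
         toxic_compounds = toxic_compounds,
         base_spontaneous = base_spontaneous,
         base_maximal = base_maximal,
         kill_fmax = kill_fmax, kill_k = kill_k,
         compound_et = compound_et, positive_et = positive_et,
         noise_cv = noise_cv, plate_gain_cv = plate_gain_cv,
         drift_onset_min = drift_onset_min,
         drift_rate_per_min = drift_rate_per_min,
         spont_drift_rate_per_min = spont_drift_rate_per_min,
         seed_interval_min = seed_interval_min,
         replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default planted ground truth for a simulated library
#'
#' Plants enhancers at evenly spaced library positions (so planted actives
#' sample the whole seeding-order drift range) with killing multipliers
#' cycling through `effects`, and toxic compounds at evenly spaced positions
#' among the remaining library. With the default assay parameters the
#' effect multipliers 2, 3 and 4 produce co-culture fold-changes of about
#' 1.5, 1.8 and 2.05 — the upper range observed for genuine screen hits.
#'
#' @param compound_ids Character vector of library compound ids.
#' @param n_enhancers Number of planted enhancers (default 15).
#' @param effects Killing multipliers cycled over the enhancers
#'   (default `c(2, 3, 4)`).
#' @param n_toxic Number of planted directly toxic compounds (default 5).
#' @param toxic_fraction Direct target-lysis fraction of toxic compounds
#'   (default 0.3).
#' @return List with named numeric vectors `enhancer_effects` and
#'   `toxic_compounds`.
#' @export
default_truth <- function(compound_ids, n_enhancers = 15,
                          effects = c(2, 3, 4), n_toxic = 5,
                          toxic_fraction = 0.3) {
  n <- length(compound_ids)
  stopifnot(n_enhancers + n_toxic <= n)
  enh_idx <- unique(round(seq(1, n, length.out = n_enhancers + 2)))
  enh_idx <- enh_idx[-c(1, length(enh_idx))]
  enh_idx <- enh_idx[seq_len(min(n_enhancers, length(enh_idx)))]
  remaining <- setdiff(seq_len(n), enh_idx)
  tox_pos <- unique(round(seq(1, length(remaining), length.out = n_toxic)))
  tox_idx <- remaining[tox_pos]
  list(
    enhancer_effects = stats::setNames(
      rep_len(effects, length(enh_idx)), compound_ids[enh_idx]),
    toxic_compounds = stats::setNames(
      rep(toxic_fraction, length(tox_idx)), compound_ids[tox_idx])
  )
}

#' Saturating NK kill fraction
#'
#' @param e_t_ratio Effector:target ratio (>= 0).
#' @param effect Enhancer multiplier on the effective E:T ratio (>= 1 for
#'   enhancers, 1 for inert compounds).
#' @param potency Effector potency in `[0, 1]` scaling the achievable kill
#'   plateau.
#' @param config A `sim_config` (supplies `kill_fmax`, `kill_k`).
#' @return Kill fraction in `[0, 1)`; 0 at ratio 0, approaching
#'   `potency * kill_fmax` as the ratio grows.
#' @export
kill_fraction <- function(e_t_ratio, effect = 1, potency = 1, config) {
  stopifnot(all(e_t_ratio >= 0), all(effect >= 0),
            all(potency >= 0), all(potency <= 1))
  r_eff <- effect * e_t_ratio
  potency * config$kill_fmax * r_eff / (config$kill_k + r_eff)
}

# potency and spontaneous level after `wait_min` minutes at room temperature
plate_drift <- function(wait_min, config) {
  over <- pmax(0, wait_min - config$drift_onset_min)
  list(
    potency = pmax(0, 1 - config$drift_rate_per_min * over),
    spont = config$base_spontaneous *
      (1 + config$spont_drift_rate_per_min * over)
  )
}

# mean-1 lognormal multiplicative noise
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

# deterministic per-plate RNG substream seed below 2^31
plate_seed <- function(seed, replicate, condition_idx, plate_idx) {
  m <- 2147483647
  s <- seed %% m
  s <- (s * 48271) %% m
  s <- (s + replicate * 1000003 + condition_idx * 10007 + plate_idx * 101) %% m
  s <- (s * 48271) %% m
  as.integer(s)
}

#' Expected (noise-free) luminescence of one well
#'
#' @param role Well role: `"compound"`, `"negative_control"`, or
#'   `"positive_control"`.
#' @param condition `"target_alone"` or `"coculture"`.
#' @param effect Enhancer multiplier (inert = 1).
#' @param toxic_fraction Direct target-lysis fraction (inert = 0).
#' @param potency Plate effector potency in `[0, 1]`.
#' @param spontaneous Current spontaneous release level (defaults to the
#'   configured baseline; drifted plates pass their inflated value).
#' @param config A `sim_config`.
#' @return Expected RLU.
#' @export
expected_well_rlu <- function(role, condition, effect = 1, toxic_fraction = 0,
                              potency = 1,
                              spontaneous = config$base_spontaneous, config) {
  stopifnot(role %in% c("compound", "negative_control", "positive_control"),
            condition %in% SCREEN_CONDITIONS)
  dyn <- config$base_maximal - spontaneous
  if (condition == "target_alone") {
    f <- switch(role,
      negative_control = 0,
      positive_control = NA_real_, # digitonin: full lysis, handled below
      compound = toxic_fraction
    )
    if (role == "positive_control") return(config$base_maximal)
    return(spontaneous + f * dyn)
  }
  # co-culture
  f_kill <- switch(role,
    negative_control = kill_fraction(config$compound_et, 1, potency, config),
    positive_control = kill_fraction(config$positive_et, 1, potency, config),
    compound = kill_fraction(config$compound_et, effect, potency, config)
  )
  f_tox <- if (role == "compound") toxic_fraction else 0
  f_total <- 1 - (1 - f_kill) * (1 - f_tox)
  spontaneous + f_total * dyn
}

#' Simulate one well
#'
#' Draws from the well model at the given drift state, using the current
#' RNG state for the noise term.
#'
#' @inheritParams expected_well_rlu
#' @param noise If `FALSE`, return the expected value exactly.
#' @return Simulated RLU.
#' @export
simulate_well <- function(role, condition, effect = 1, toxic_fraction = 0,
                          potency = 1,
                          spontaneous = config$base_spontaneous, config,
                          noise = TRUE) {
  mu <- expected_well_rlu(role, condition, effect, toxic_fraction, potency,
                          spontaneous, config)
  if (!noise) return(mu)
  mu * lognormal_noise(1, config$noise_cv)
}

#' Simulate the full screen
#'
#' Generates plate reads for every (plate, condition, replicate day) of the
#' configured screen, alongside the layout and the planted ground truth.
#' Plates are seeded sequentially within a day: plate `i` waits
#' `(i - 1) * seed_interval_min` minutes, which sets its effector potency
#' and spontaneous-release level via the drift model. Each
#' (replicate, condition, plate) has its own deterministic RNG substream
#' with noise drawn in fixed well order, so results do not depend on
#' processing order and identical configurations reproduce byte-identical
#' output.
#'
#' @param config A `sim_config`.
#' @return List of class `sim_screen`: `reads` (long tibble `plate_id`,
#'   `replicate_id`, `condition`, `well`, `rlu`), `layout`
#'   (a `screen_layout`), `truth` (list of `compounds` and `plates`
#'   tibbles), and `config`.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- build_screen_layout(config$compound_ids)
  idx <- compound_index(layout)
  plate_ids <- unique(idx$plate_id)
  all_wells <- plate_wells("row_major")

  effect_of <- stats::setNames(rep(1, config$n_compounds), config$compound_ids)
  effect_of[names(config$enhancer_effects)] <- config$enhancer_effects
  tox_of <- stats::setNames(rep(0, config$n_compounds), config$compound_ids)
  tox_of[names(config$toxic_compounds)] <- config$toxic_compounds

  reads <- list()
  plate_truth <- list()
  for (rep_id in seq_len(config$replicates)) {
    for (p in seq_along(plate_ids)) {
      pid <- plate_ids[p]
      wait <- (p - 1) * config$seed_interval_min
      drift <- plate_drift(wait, config)
      for (ci in seq_along(SCREEN_CONDITIONS)) {
        cond <- SCREEN_CONDITIONS[ci]
        lay <- plate_layout(layout, pid, cond)
        lay <- dplyr::filter(lay, .data$role != "empty")
        eff <- ifelse(is.na(lay$compound_id), 1, effect_of[lay$compound_id])
        tox <- ifelse(is.na(lay$compound_id), 0, tox_of[lay$compound_id])
        mu <- vapply(seq_len(nrow(lay)), function(i) {
          expected_well_rlu(lay$role[i], cond, eff[i], tox[i],
                            drift$potency, drift$spont, config)
        }, numeric(1))
        set.seed(plate_seed(config$seed, rep_id, ci, p))
        gain <- lognormal_noise(1, config$plate_gain_cv)
        noise96 <- lognormal_noise(WELLS_PER_PLATE, config$noise_cv)
        rlu <- mu * gain * noise96[match(lay$well, all_wells)]
        reads[[length(reads) + 1]] <- tibble::tibble(
          plate_id = pid, replicate_id = rep_id, condition = cond,
          well = lay$well, rlu = rlu)
        plate_truth[[length(plate_truth) + 1]] <- tibble::tibble(
          plate_id = pid, replicate_id = rep_id, condition = cond,
          wait_min = wait, potency = drift$potency,
          spontaneous = drift$spont, gain = gain)
      }
    }
  }

  compounds <- tibble::tibble(
    compound_id = config$compound_ids,
    is_enhancer = config$compound_ids %in% names(config$enhancer_effects),
    effect = unname(effect_of),
    is_toxic = config$compound_ids %in% names(config$toxic_compounds),
    toxic_fraction = unname(tox_of),
    plate_id = idx$plate_id[match(config$compound_ids, idx$compound_id)],
    well = idx$well[match(config$compound_ids, idx$compound_id)]
  )

  structure(
    list(reads = dplyr::bind_rows(reads), layout = layout,
         truth = list(compounds = compounds,
                      plates = dplyr::bind_rows(plate_truth)),
         config = config),
    class = "sim_screen"
  )
}

#' Simulate a dose-response validation experiment
#'
#' Emits long-format reads (`drug_id`, `dose_uM`, `et_ratio`, `replicate`,
#' `role`, `rlu`) for one drug across doses and E:T ratios, with
#' dose-matched target-alone spontaneous wells and digitonin maximal wells,
#' ready for [dose_response_lysis()].
#'
#' @param effect_by_dose Named numeric vector mapping dose (uM, as names)
#'   to the killing multiplier at that dose; must include dose 0 (vehicle,
#'   effect 1).
#' @param et_ratios E:T ratios assayed (default `c(1, 3)`).
#' @param replicates Wells per (dose, ratio) cell (default 3).
#' @param config A `sim_config` (assay parameters, noise CV, seed).
#' @param drug_id Label for the simulated drug.
#' @param toxic_by_dose Optional named numeric vector of direct target-lysis
#'   fractions per dose (default: none).
#' @return Long tibble of simulated reads.
#' @export
simulate_dose_response <- function(effect_by_dose, et_ratios = c(1, 3),
                                   replicates = 3, config,
                                   drug_id = "drug", toxic_by_dose = NULL) {
  stopifnot(inherits(config, "sim_config"))
  doses <- as.numeric(names(effect_by_dose))
  if (any(is.na(doses))) {
    stop("effect_by_dose must be named by numeric doses", call. = FALSE)
  }
  if (!0 %in% doses) {
    stop("effect_by_dose must include dose 0 (vehicle)", call. = FALSE)
  }
  if (any(effect_by_dose < 1)) {
    stop("dose effects are killing multipliers >= 1", call. = FALSE)
  }
  tox <- stats::setNames(rep(0, length(doses)), names(effect_by_dose))
  if (!is.null(toxic_by_dose)) tox[names(toxic_by_dose)] <- toxic_by_dose

  grid <- expand.grid(dose_uM = doses, et_ratio = et_ratios,
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  # kill_fraction at the cell's own E:T ratio, not the screen's compound_et
  mu_exp <- vapply(seq_len(nrow(grid)), function(i) {
    d <- as.character(grid$dose_uM[i])
    f_kill <- kill_fraction(grid$et_ratio[i], effect_by_dose[[d]], 1, config)
    f_total <- 1 - (1 - f_kill) * (1 - tox[[d]])
    config$base_spontaneous +
      f_total * (config$base_maximal - config$base_spontaneous)
  }, numeric(1))

  spont_grid <- expand.grid(dose_uM = doses, replicate = seq_len(replicates),
                            KEEP.OUT.ATTRS = FALSE)
  mu_spont <- vapply(seq_len(nrow(spont_grid)), function(i) {
    d <- as.character(spont_grid$dose_uM[i])
    config$base_spontaneous +
      tox[[d]] * (config$base_maximal - config$base_spontaneous)
  }, numeric(1))

  set.seed(plate_seed(config$seed, 1, 3, 1)) # dedicated substream
  out <- dplyr::bind_rows(
    tibble::tibble(drug_id = drug_id, dose_uM = grid$dose_uM,
                   et_ratio = grid$et_ratio, replicate = grid$replicate,
                   role = "experimental",
                   rlu = mu_exp * lognormal_noise(nrow(grid),
                                                  config$noise_cv)),
    tibble::tibble(drug_id = drug_id, dose_uM = spont_grid$dose_uM,
                   et_ratio = NA_real_, replicate = spont_grid$replicate,
                   role = "spontaneous",
                   rlu = mu_spont * lognormal_noise(nrow(spont_grid),
                                                    config$noise_cv)),
    tibble::tibble(drug_id = drug_id, dose_uM = NA_real_,
                   et_ratio = NA_real_, replicate = seq_len(replicates),
                   role = "maximal",
                   rlu = config$base_maximal *
                     lognormal_noise(replicates, config$noise_cv))
  )
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
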