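# Seeded synthetic-cohort generator. Draws per-cell VAS ratings from
# mean-matched truncated normal distributions, builds 2 Hz six-channel skin
# temperature traces with an analytically controlled weighted mean, and
# supports injection of hygrosensory-loss participants.

#' Default per-cell wetness distributions
#'
#' Static-baseline wetness distribution for every (site, quality) cell.
#' Means are calibrated so that, after adding the site's dynamic increment,
#' the dynamic-mode thermoneutral cells reproduce the pooled control
#' normative means (forehead cold/neutral/warm 53.7/40.6/41.3 mm, finger pad
#' 67.7/51.7/47.6 mm); SDs are the normative SDs. No normative data exist
#' for the forearm, whose cells are set once to values intermediate between
#' the two instrumented sites.
#'
#' @return Tibble with columns `site`, `quality`, `mean_mm`, `sd_mm`.
#' @export
default_cell_distributions <- function() {
  inc <- default_dynamic_increments()
  norm <- ctr_normative_summary()
  dyn <- tibble::tibble(
    site = c(rep("FOREARM", 3)),
    quality = c("COLD_WET", "NEUTRAL_WET", "WARM_WET"),
    mean_mm = c(58, 48, 44),
    sd_mm = c(26, 26, 26)
  )
  base <- dplyr::bind_rows(
    dplyr::select(norm, "site", "quality", mean_mm = "mean_mm", sd_mm = "sd_mm"),
    dyn
  )
  base$mean_mm <- unname(base$mean_mm - inc[base$site])
  dplyr::arrange(base, .data$site, .data$quality)
}

#' Default dynamic-minus-static wetness increments per site
#'
#' Mean wetness increase (mm) produced by moving the wet probe, relative to
#' static contact: 15.5 (finger pad), 12.4 (forearm), 19.7 (forehead).
#'
#' @return Named numeric vector keyed by site.
#' @export
default_dynamic_increments <- function() {
  c(FINGER_PAD = 15.5, FOREARM = 12.4, FOREHEAD = 19.7)
}

#' Default session configurations
#'
#' Session-level simulation targets: weighted mean skin temperature reached
#' during the QST window (thermoneutral 30.9, heat 34.8, cold 26.5 degC),
#' additive wetness shifts (0, +4.75, -4.75 mm, so that HEAT - COLD is
#' 9.5 mm), ambient chamber conditions and per-sample thermistor noise.
#'
#' @return Tibble with columns `session`, `target_mean_tsk`, `tsk_noise_sd`,
#'   `wetness_shift`, `ambient_temp`, `ambient_rh`.
#' @export
default_session_configs <- function() {
  tibble::tibble(
    session = c("NEUTRAL", "HEAT", "COLD"),
    target_mean_tsk = c(30.9, 34.8, 26.5),
    tsk_noise_sd = 0.2,
    wetness_shift = c(0, 4.75, -4.75),
    ambient_temp = c(24.0, 38.8, 12.9),
    ambient_rh = c(49.5, 49.5, 46.5)
  )
}

# thermal-sensation generator constants (VAS 0 cold .. 100 hot): quality
# anchors, attenuation of dynamic stimuli toward neutral, and session shifts
# (feeling colder under HEAT, warmer under COLD).
thermal_base_mean <- c(COLD_WET = 25, NEUTRAL_WET = 45, WARM_WET = 65)
thermal_sd <- 15
thermal_dynamic_attenuation <- 0.15
thermal_session_shift <- c(NEUTRAL = 0, HEAT = -4.4, COLD = 4.4)

#' Build a loss-injection table
#'
#' Designates (participant, site, quality) cells whose wetness ratings are
#' to be replaced by draws from a near-floor distribution, emulating a
#' participant with hygrosensory loss at those cells.
#'
#' @param participant_id,site,quality Vectors (recycled to common length)
#'   identifying the cells.
#' @param floor_mean,floor_sd Location and spread (mm) of the truncated
#'   floor distribution; defaults 2 and 2.
#' @return Tibble usable as the `injections` field of [simulation_config()].
#' @export
loss_injections <- function(participant_id, site, quality,
                            floor_mean = 2, floor_sd = 2) {
  tibble::tibble(
    participant_id = as.character(participant_id),
    site = parse_enum(site, qst_levels()$site, "site"),
    quality = parse_enum(quality, qst_levels()$quality, "quality"),
    floor_mean = floor_mean,
    floor_sd = floor_sd
  )
}

#' Configuration for synthetic-cohort generation
#'
#' @param seed Integer seed; mandatory, fixed Mersenne-Twister/inversion
#'   generator for cross-platform reproducibility.
#' @param n_ms,n_ctr Group sizes (defaults 12 and 11, the study design).
#' @param cell_distributions Static-baseline wetness distribution per
#'   (site, quality); see [default_cell_distributions()].
#' @param session_configs Per-session targets; see
#'   [default_session_configs()].
#' @param dynamic_increment Named per-site dynamic wetness increments (mm).
#' @param injections Optional [loss_injections()] table.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed, n_ms = 12, n_ctr = 11,
                              cell_distributions = default_cell_distributions(),
                              session_configs = default_session_configs(),
                              dynamic_increment = default_dynamic_increments(),
                              injections = NULL) {
  if (missing(seed) || length(seed) != 1 || is.na(seed)) {
    rlang::abort("A single integer seed is mandatory",
                 class = "hygro_invalid_config")
  }
  stopifnot(n_ms >= 0, n_ctr >= 0)
  cd <- tibble::as_tibble(cell_distributions)
  check_columns(cd, c("site", "quality", "mean_mm", "sd_mm"), "cell_distributions")
  cd$site <- parse_enum(cd$site, qst_levels()$site, "site")
  cd$quality <- parse_enum(cd$quality, qst_levels()$quality, "quality")
  if (anyDuplicated(paste(cd$site, cd$quality)) ||
      nrow(cd) != length(qst_levels()$site) * length(qst_levels()$quality)) {
    rlang::abort("Need exactly one cell distribution per (site, quality)",
                 class = "hygro_invalid_config")
  }
  if (any(cd$sd_mm < 0) || any(cd$mean_mm < 0 | cd$mean_mm > 100)) {
    rlang::abort("Cell distributions need sd >= 0 and mean in [0, 100]",
                 class = "hygro_invalid_config")
  }
  sc <- tibble::as_tibble(session_configs)
  check_columns(sc, c("session", "target_mean_tsk", "tsk_noise_sd",
                      "wetness_shift", "ambient_temp", "ambient_rh"),
                "session_configs")
  sc$session <- parse_enum(sc$session, qst_levels()$session, "session")
  if (!setequal(sc$session, qst_levels()$session) || nrow(sc) != 3) {
    rlang::abort("session_configs must have one row per session",
                 class = "hygro_invalid_config")
  }
  if (any(sc$target_mean_tsk <= 20 | sc$target_mean_tsk >= 40)) {
    rlang::abort("target_mean_tsk must lie in (20, 40) degC",
                 class = "hygro_invalid_config")
  }
  if (!is.null(injections)) {
    injections <- tibble::as_tibble(injections)
    check_columns(injections,
                  c("participant_id", "site", "quality", "floor_mean", "floor_sd"),
                  "injections")
  }
  structure(
    list(seed = as.integer(seed), n_ms = as.integer(n_ms),
         n_ctr = as.integer(n_ctr), cell_distributions = cd,
         session_configs = sc,
         dynamic_increment = dynamic_increment[qst_levels()$site],
         injections = injections,
         generator = "hygrosense-truncnorm-1"),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  seed %d | n_ms %d | n_ctr %d | injections %d\n",
              x$seed, x$n_ms, x$n_ctr,
              if (is.null(x$injections)) 0L else nrow(x$injections)))
  cat(sprintf("  generator: %s\n", x$generator))
  invisible(x)
}

# --- truncated-normal machinery ---------------------------------------------

truncnorm_mean <- function(mu, sd, lo = 0, hi = 100) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  # evaluate the normalizer in the stable tail to avoid cancellation
  z <- if (a > 0) {
    stats::pnorm(a, lower.tail = FALSE) - stats::pnorm(b, lower.tail = FALSE)
  } else {
    stats::pnorm(b) - stats::pnorm(a)
  }
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Solve for the latent normal mean such that the [lo, hi]-truncated mean
# equals `target`; plain truncation would bias cell means by >1 mm for the
# wide VAS distributions used here.
solve_latent_mean <- function(target, sd, lo = 0, hi = 100) {
  if (sd == 0) return(min(max(target, lo), hi))
  target <- min(max(target, lo + 1e-6), hi - 1e-6)
  f <- function(mu) truncnorm_mean(mu, sd, lo, hi) - target
  lower <- target - 2 * sd
  upper <- target + 2 * sd
  for (i in 1:20) {
    if (f(lower) <= 0) break
    lower <- lower - 2 * sd
  }
  for (i in 1:20) {
    if (f(upper) >= 0) break
    upper <- upper + 2 * sd
  }
  stats::uniroot(f, lower = lower, upper = upper, tol = 1e-10)$root
}

# rejection sampler; sd = 0 degenerates to the clamped mean
rtrunc_norm <- function(n, mu, sd, lo = 0, hi = 100) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(min(max(mu, lo), hi), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    x <- stats::rnorm(length(need), mu, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# deterministic per-(participant, session) sub-seed below 2^31
derive_seed <- function(seed, ...) {
  key <- paste(..., sep = "/")
  v <- as.numeric(utf8ToInt(key))
  h <- sum(v * seq_along(v) * 2654435) %% 2147483647
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

local_fixed_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(seed, .rng_kind = "Mersenne-Twister",
                    .rng_normal_kind = "Inversion",
                    .rng_sample_kind = "Rejection", .local_envir = env)
}

# --- generation --------------------------------------------------------------

#' Generate a synthetic QST cohort
#'
#' Draws a complete dataset with the statistical structure the downstream
#' analysis assumes: per-cell wetness ratings from normal distributions
#' truncated to \[0, 100\] mm whose truncated means equal the configured cell
#' means (dynamic cells shifted by the site's dynamic increment, sessions by
#' their wetness shift), thermal ratings anchored by stimulus quality, and
#' optionally six-channel 2 Hz temperature traces hitting the session's
#' target mean skin temperature. Deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @param include_temperatures Generate temperature traces as well
#'   (default `TRUE`; rating-only cohorts are much faster for simulation
#'   studies).
#' @param hz Temperature sampling rate in Hz (default 2).
#' @return A validated [hygro_dataset()] with provenance attributes
#'   `seed`, `config_hash` and `generator`.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1, n_ms = 2, n_ctr = 2)
#' d <- generate_cohort(cfg, include_temperatures = FALSE)
#' range(d$ratings$wetness_mm)
generate_cohort <- function(cfg, include_temperatures = TRUE, hz = 2) {
  stopifnot(inherits(cfg, "simulation_config"))
  local_fixed_seed(cfg$seed)
  participants <- generate_participants(cfg)
  ratings <- generate_ratings(cfg, participants$id)
  temperatures <- empty_temperatures()
  if (include_temperatures) {
    grid <- tidyr::expand_grid(id = participants$id,
                               session = qst_levels()$session)
    temperatures <- purrr::pmap(grid, function(id, session) {
      generate_temperatures(cfg, id, session, hz = hz)
    }) |> dplyr::bind_rows()
  }
  d <- hygro_dataset(participants, ratings, temperatures)
  if (!is.null(cfg$injections) && nrow(cfg$injections) > 0) {
    d <- inject_loss(d, cfg$injections, seed = derive_seed(cfg$seed, "inject"))
  }
  attr(d, "seed") <- cfg$seed
  attr(d, "config_hash") <- rlang::hash(unclass(cfg))
  attr(d, "generator") <- cfg$generator
  d
}

generate_participants <- function(cfg) {
  n <- cfg$n_ms + cfg$n_ctr
  grp <- rep(c("MS", "CTR"), c(cfg$n_ms, cfg$n_ctr))
  ids <- c(sprintf("MS%02d", seq_len(cfg$n_ms)),
           sprintf("CTR%02d", seq_len(cfg$n_ctr)))
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  tibble::tibble(
    id = ids,
    group = grp,
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.42, 0.58)),
    age_yr = round(clamp(stats::rnorm(n, 48, 11), 20, 70)),
    height_m = round(clamp(stats::rnorm(n, 1.72, 0.11), 1.45, 2.05), 2),
    mass_kg = round(clamp(stats::rnorm(n, 76, 17), 45, 120), 1),
    ethnicity = sample(c("WE", "A"), n, replace = TRUE, prob = c(0.85, 0.15)),
    edss = ifelse(grp == "MS",
                  sample(seq(1, 7, by = 0.5), n, replace = TRUE), NA_real_),
    ms_type = ifelse(grp == "MS",
                     sample(c("RR", "PP", "SP"), n, replace = TRUE,
                            prob = c(7, 4, 1)), NA_character_),
    medications = NA_character_
  )
}

generate_ratings <- function(cfg, ids) {
  lv <- qst_levels()
  grid <- tidyr::expand_grid(
    participant_id = ids, session = lv$session, site = lv$site,
    quality = lv$quality, mode = lv$mode
  )
  cells <- cfg$cell_distributions
  key <- paste(grid$site, grid$quality)
  ckey <- paste(cells$site, cells$quality)
  idx <- match(key, ckey)
  shift <- cfg$session_configs$wetness_shift[
    match(grid$session, cfg$session_configs$session)]
  w_target <- cells$mean_mm[idx] +
    ifelse(grid$mode == "DYNAMIC", cfg$dynamic_increment[grid$site], 0) + shift
  w_sd <- cells$sd_mm[idx]
  t_target <- thermal_base_mean[grid$quality] +
    ifelse(grid$mode == "DYNAMIC",
           thermal_dynamic_attenuation * (50 - thermal_base_mean[grid$quality]),
           0) +
    thermal_session_shift[grid$session]

  grid$wetness_mm <- draw_cells(w_target, w_sd)
  grid$thermal_mm <- draw_cells(t_target, rep(thermal_sd, nrow(grid)))
  grid
}

# grouped mean-matched truncated draws, deterministic in grid order
draw_cells <- function(target, sd) {
  out <- numeric(length(target))
  pkey <- paste(signif(target, 12), signif(sd, 12))
  for (k in unique(pkey)) {
    i <- which(pkey == k)
    mu <- solve_latent_mean(target[i[1]], sd[i[1]])
    out[i] <- rtrunc_norm(length(i), mu, sd[i[1]])
  }
  out
}

#' Generate a six-channel skin temperature trace for one session
#'
#' Builds a 50-min series sampled at `hz` in which ambient-driven changes in
#' skin temperature ramp linearly from the thermoneutral baseline to the
#' session target over the first 35 min and hold steady during the final
#' 15-min QST window. Channel offsets are solved so the weighted mean skin
#' temperature equals the session target exactly when `tsk_noise_sd` is
#' zero; the rectal channel stays near 37 degC in every session.
#' Deterministic given the config seed, participant and session.
#'
#' @param cfg A [simulation_config()].
#' @param participant_id Participant identifier (labels the rows).
#' @param session One of `"NEUTRAL"`, `"HEAT"`, `"COLD"`.
#' @param hz Sampling rate (default 2 Hz, i.e. 6000 samples).
#' @return Temperatures tibble in the [hygro_dataset()] schema.
#' @export
generate_temperatures <- function(cfg, participant_id, session, hz = 2) {
  stopifnot(inherits(cfg, "simulation_config"))
  session <- parse_enum(session, qst_levels()$session, "session")
  sc <- cfg$session_configs
  row <- sc[sc$session == session, ]
  baseline <- sc$target_mean_tsk[sc$session == "NEUTRAL"]
  local_fixed_seed(derive_seed(cfg$seed, participant_id, session))

  duration <- 3000
  ramp_end <- 2100
  t <- seq(0, duration - 1 / hz, by = 1 / hz)
  traj <- baseline + (row$target_mean_tsk - baseline) * pmin(t / ramp_end, 1)

  w <- tsk_weights()
  # physiological channel offsets around the weighted mean; weighted sum 0
  off <- c(cheek = 0.6, chest = 1.2, forearm = -0.8, hand = -2.2, thigh = 0.8)
  off["back"] <- -sum(w[names(off)] * off) / w[["back"]]
  noise <- function() stats::rnorm(length(t), 0, row$tsk_noise_sd)
  tibble::tibble(
    participant_id = participant_id,
    session = session,
    time_s = t,
    cheek_c = traj + off[["cheek"]] + noise(),
    chest_c = traj + off[["chest"]] + noise(),
    forearm_c = traj + off[["forearm"]] + noise(),
    hand_c = traj + off[["hand"]] + noise(),
    thigh_c = traj + off[["thigh"]] + noise(),
    back_c = traj + off[["back"]] + noise(),
    rectal_c = 37 + stats::rnorm(length(t), 0, min(row$tsk_noise_sd, 0.1))
  )
}

#' Inject hygrosensory-loss cells into a dataset
#'
#' Replaces the wetness ratings of the designated (participant, site,
#' quality) cells — across all sessions and modes — with draws from a
#' truncated near-floor distribution, leaving every other cell untouched.
#'
#' @param d A `hygro_dataset`.
#' @param injections A [loss_injections()] table.
#' @param seed Optional integer seed for reproducible standalone use; when
#'   `NULL` the current RNG stream is used.
#' @return The modified, revalidated dataset.
#' @export
inject_loss <- function(d, injections, seed = NULL) {
  stopifnot(inherits(d, "hygro_dataset"))
  injections <- tibble::as_tibble(injections)
  if (nrow(injections) == 0) return(d)
  check_columns(injections,
                c("participant_id", "site", "quality", "floor_mean", "floor_sd"),
                "injections")
  if (!is.null(seed)) local_fixed_seed(seed)
  r <- d$ratings
  for (i in seq_len(nrow(injections))) {
    inj <- injections[i, ]
    hit <- r$participant_id == inj$participant_id &
      r$site == inj$site & r$quality == inj$quality
    if (!any(hit)) {
      rlang::abort(
        sprintf("Injection targets absent cell: %s/%s/%s",
                inj$participant_id, inj$site, inj$quality),
        class = "hygro_unknown_cell"
      )
    }
    r$wetness_mm[hit] <- rtrunc_norm(sum(hit), inj$floor_mean, inj$floor_sd)
  }
  d$ratings <- r
  validate_dataset(d)
}
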