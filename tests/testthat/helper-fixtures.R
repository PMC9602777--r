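# Shared builders for small in-code fixtures.

tiny_participants <- function() {
  tibble::tibble(
    id = c("P1", "P2"),
    group = c("MS", "CTR"),
    sex = c("M", "F"),
    age_yr = c(40, 41),
    height_m = c(1.70, 1.65),
    mass_kg = c(70, 62),
    ethnicity = c("WE", "A"),
    edss = c(3.5, NA),
    ms_type = c("RR", NA),
    medications = c(NA, NA)
  )
}

tiny_rating <- function(participant_id = "P1", wetness = 54, thermal = 30) {
  tibble::tibble(
    participant_id = participant_id, session = "NEUTRAL", site = "FOREHEAD",
    quality = "COLD_WET", mode = "DYNAMIC",
    wetness_mm = wetness, thermal_mm = thermal
  )
}

tiny_temperature <- function(participant_id = "P1", time_s = 0, base = 30) {
  tibble::tibble(
    participant_id = participant_id, session = "NEUTRAL", time_s = time_s,
    cheek_c = base + 1, chest_c = base + 2, forearm_c = base + 3,
    hand_c = base + 4, thigh_c = base + 5, back_c = base + 6,
    rectal_c = 37
  )
}

tiny_dataset <- function() {
  hygro_dataset(tiny_participants(), tiny_rating(), tiny_temperature())
}

# long-format mixed-design data from a subject x within matrix
long_design <- function(y, groups, levels = paste0("W", seq_len(ncol(y)))) {
  n <- nrow(y)
  tibble::tibble(
    subject = rep(sprintf("S%03d", seq_len(n)), each = ncol(y)),
    group = rep(groups, each = ncol(y)),
    within = rep(levels, n),
    response = as.vector(t(y))
  )
}

noiseless_sim_config <- function(seed = 1, n_ms = 1, n_ctr = 1) {
  sc <- default_session_configs()
  sc$tsk_noise_sd <- 0
  simulation_config(seed = seed, n_ms = n_ms, n_ctr = n_ctr,
                    session_configs = sc)
}
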