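# Weighted mean skin temperature, QST analysis-window extraction, and
# group/session summaries of the body-temperature response.

#' Six-site weighting coefficients for mean skin temperature
#'
#' Fixed regional weights for estimating whole-body mean skin temperature
#' from six local thermistors: cheek 0.14, upper chest 0.19, outer mid
#' lower arm 0.11, hand dorsum 0.05, anterior thigh 0.32, lower lateral
#' back 0.19. Weights are positive and sum to 1.
#'
#' @return Named numeric vector (`cheek`, `chest`, `forearm`, `hand`,
#'   `thigh`, `back`).
#' @export
tsk_weights <- function() {
  c(cheek = 0.14, chest = 0.19, forearm = 0.11, hand = 0.05,
    thigh = 0.32, back = 0.19)
}

tsk_channel_cols <- c(cheek = "cheek_c", chest = "chest_c",
                      forearm = "forearm_c", hand = "hand_c",
                      thigh = "thigh_c", back = "back_c")

#' Weighted mean skin temperature
#'
#' Computes the fixed-weight sum of the six local skin temperatures. As a
#' convex combination the result always lies within the range of the six
#' channels.
#'
#' @param x Either a temperatures tibble (columns `cheek_c` ... `back_c`) or
#'   a named numeric vector/list with elements `cheek`, `chest`, `forearm`,
#'   `hand`, `thigh`, `back`.
#' @param weights Channel weights; must be named for all six channels,
#'   positive, and sum to 1 (default [tsk_weights()]).
#' @return Numeric vector of mean skin temperatures (degC), one per row.
#' @export
#' @examples
#' mean_tsk(c(cheek = 31, chest = 32, forearm = 33, hand = 34,
#'            thigh = 35, back = 36))
mean_tsk <- function(x, weights = tsk_weights()) {
  ch <- names(tsk_channel_cols)
  if (!setequal(names(weights), ch) || any(weights <= 0) ||
      abs(sum(weights) - 1) > 1e-12) {
    rlang::abort("weights must cover the six channels, be positive and sum to 1",
                 class = "hygro_invalid_weights")
  }
  if (is.data.frame(x)) {
    missing <- setdiff(unname(tsk_channel_cols), names(x))
    if (length(missing) > 0) {
      rlang::abort(sprintf("Missing temperature channel(s): %s",
                           paste(missing, collapse = ", ")),
                   class = "hygro_missing_channel")
    }
    m <- as.matrix(x[unname(tsk_channel_cols[ch])])
  } else {
    x <- unlist(x)
    if (!all(ch %in% names(x))) {
      rlang::abort(sprintf("Missing temperature channel(s): %s",
                           paste(setdiff(ch, names(x)), collapse = ", ")),
                   class = "hygro_missing_channel")
    }
    m <- matrix(x[ch], nrow = 1)
  }
  if (anyNA(m)) {
    rlang::abort("Missing channel value", class = "hygro_missing_channel")
  }
  drop(m %*% weights[ch])
}

#' Average body temperatures over an analysis window
#'
#' For each participant x session series, averages the per-sample weighted
#' mean skin temperature and rectal temperature over `[start, end)` seconds
#' from session start. The default window is the final 15 min of the 50-min
#' exposure (2100-3000 s), the timeframe in which the sensory test is
#' delivered. Gaps are not interpolated; they simply reduce `n_samples`.
#'
#' @param temperatures Temperatures tibble (or a `hygro_dataset`).
#' @param window Numeric `c(start, end)` in seconds; half-open.
#' @param weights Channel weights passed to [mean_tsk()].
#' @return Tibble with `participant_id`, `session`, `mean_tsk`, `mean_trec`,
#'   `n_samples`, `window_start`, `window_end`.
#' @export
window_average <- function(temperatures, window = c(2100, 3000),
                           weights = tsk_weights()) {
  if (inherits(temperatures, "hygro_dataset")) {
    temperatures <- temperatures$temperatures
  }
  check_columns(temperatures, temperature_cols, "temperatures")
  stopifnot(length(window) == 2, window[1] < window[2])
  inside <- temperatures$time_s >= window[1] & temperatures$time_s < window[2]
  tt <- temperatures[inside, ]
  if (nrow(tt) == 0) {
    rlang::abort("No samples inside the analysis window",
                 class = "hygro_empty_window")
  }
  tt$.tsk <- mean_tsk(tt, weights)
  tt |>
    dplyr::group_by(.data$participant_id, .data$session) |>
    dplyr::summarise(
      mean_tsk = mean(.data$.tsk),
      mean_trec = mean(.data$rectal_c),
      n_samples = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(window_start = window[1], window_end = window[2])
}

#' Group and session summary of body-temperature responses
#'
#' Summarizes window-averaged mean skin and rectal temperatures per
#' (group, session) cell and computes the marginal pairwise session
#' contrasts (HEAT-NEUTRAL, COLD-NEUTRAL, HEAT-COLD) as paired
#' within-participant differences pooled across groups, with t-based 95%
#' confidence intervals. Participants missing a session are excluded from
#' the paired contrasts with a warning.
#'
#' @param summaries Output of [window_average()].
#' @param participants Participants tibble (or `hygro_dataset`) supplying
#'   group labels.
#' @param conf Confidence level (default 0.95).
#' @return List with `cells` (per group x session mean/SD/n) and
#'   `contrasts` (session pair, mean difference, CI, t p-value) for both
#'   `mean_tsk` and `mean_trec`.
#' @export
session_group_summary <- function(summaries, participants, conf = 0.95) {
  if (inherits(participants, "hygro_dataset")) {
    participants <- participants$participants
  }
  s <- dplyr::inner_join(
    summaries,
    dplyr::select(participants, participant_id = "id", "group"),
    by = "participant_id"
  )
  cells <- s |>
    dplyr::group_by(.data$group, .data$session) |>
    dplyr::summarise(
      n = dplyr::n(),
      tsk_mean = mean(.data$mean_tsk), tsk_sd = stats::sd(.data$mean_tsk),
      trec_mean = mean(.data$mean_trec), trec_sd = stats::sd(.data$mean_trec),
      .groups = "drop"
    )
  n_cells <- length(unique(s$group)) * length(unique(s$session))
  if (nrow(cells) < n_cells || nrow(cells) == 0) {
    rlang::abort("Every (group, session) cell needs at least one participant",
                 class = "hygro_empty_group")
  }

  complete <- s |>
    dplyr::count(.data$participant_id) |>
    dplyr::filter(.data$n == length(unique(s$session)))
  dropped <- setdiff(unique(s$participant_id), complete$participant_id)
  if (length(dropped) > 0) {
    rlang::warn(sprintf("Excluding participant(s) missing a session: %s",
                        paste(dropped, collapse = ", ")))
    s <- dplyr::filter(s, .data$participant_id %in% complete$participant_id)
  }

  pairs <- list(c("HEAT", "NEUTRAL"), c("COLD", "NEUTRAL"), c("HEAT", "COLD"))
  contrast_one <- function(var, a, b) {
    wide <- tidyr::pivot_wider(
      dplyr::select(s, "participant_id", "session", value = dplyr::all_of(var)),
      names_from = "session", values_from = "value"
    )
    if (!all(c(a, b) %in% names(wide))) return(NULL)
    pc <- paired_contrast(wide[[a]], wide[[b]], conf = conf)
    pc$variable <- var
    pc$comparison <- paste(a, "-", b)
    pc
  }
  contrasts <- purrr::map(pairs, function(p) {
    dplyr::bind_rows(contrast_one("mean_tsk", p[1], p[2]),
                     contrast_one("mean_trec", p[1], p[2]))
  }) |> dplyr::bind_rows()
  contrasts <- dplyr::select(contrasts, "variable", "comparison",
                             dplyr::everything())
  list(cells = cells, contrasts = contrasts)
}
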