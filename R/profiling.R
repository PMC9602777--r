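# Individual hygrosensory profiling: log10 transform, z-transformation
# against pooled normative references, strict +/-1.96 gain/loss
# classification, and cohort abnormality summaries.
#
# The procedure standardizes each patient's (log-transformed) perception
# against the normative mean and SD; z below -threshold marks loss of
# function (less intense perception than the normative 95% interval),
# z above +threshold marks gain.

#' Profiling configuration
#'
#' @param log_offset Offset (mm) added before the log10 transform so that a
#'   raw rating of 0 mm maps to a finite value; default 1 (log10(x + 1)).
#'   Must be > 0 when any rating can be 0.
#' @param threshold Abnormality threshold in z units (default 1.96, the
#'   two-sided 95% bound of the standard normal). Strict inequalities:
#'   exactly +/- threshold is classified NORMAL.
#' @param transform `"LOG10"` (default) or `"RAW"`.
#' @return Object of class `profiling_config`.
#' @export
profiling_config <- function(log_offset = 1, threshold = 1.96,
                             transform = c("LOG10", "RAW")) {
  transform <- match.arg(toupper(transform[1]), c("LOG10", "RAW"))
  if (threshold <= 0 || log_offset < 0) {
    rlang::abort("threshold must be > 0 and log_offset >= 0",
                 class = "hygro_invalid_config")
  }
  structure(list(log_offset = log_offset, threshold = threshold,
                 transform = transform),
            class = "profiling_config")
}

#' Perceptual transform used for z-scoring
#'
#' `log10(x + log_offset)` under the LOG10 transform, identity under RAW.
#'
#' @param x Raw VAS ratings (mm), all >= 0.
#' @param cfg A [profiling_config()].
#' @return Transformed values.
#' @export
#' @examples
#' log_transform(c(0, 99), profiling_config())  # 0 and 2
log_transform <- function(x, cfg = profiling_config()) {
  if (any(x < 0)) {
    rlang::abort("Ratings must be >= 0", class = "hygro_out_of_range")
  }
  if (cfg$transform == "RAW") return(x)
  if (any(x + cfg$log_offset <= 0)) {
    rlang::abort("x + log_offset must be > 0 for the log10 transform",
                 class = "hygro_out_of_range")
  }
  log10(x + cfg$log_offset)
}

#' Build a normative reference for one (site, quality) cell
#'
#' Pools raw control ratings for a cell and computes raw- and
#' transformed-scale sample mean and SD (n-1 denominator). Summaries are
#' always recomputed from the raw values: the transformed-scale moments
#' cannot be derived from printed raw-scale summaries.
#'
#' @param values Raw control ratings (mm) in \[0, 100\]; at least 2, not all
#'   identical.
#' @param site,quality Cell labels.
#' @param cfg A [profiling_config()].
#' @return Object of class `normative_reference`.
#' @export
build_normative <- function(values, site = NA_character_,
                            quality = NA_character_,
                            cfg = profiling_config()) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    rlang::abort("Need >= 2 normative values", class = "hygro_degenerate_ref")
  }
  if (any(is.na(values)) || any(values < 0 | values > 100)) {
    rlang::abort("Normative values must lie in [0, 100] mm",
                 class = "hygro_out_of_range")
  }
  lx <- log_transform(values, cfg)
  sd_t <- stats::sd(lx)
  if (sd_t == 0) {
    rlang::abort("All normative values identical: zero SD, cannot profile",
                 class = "hygro_degenerate_ref")
  }
  structure(
    list(site = site, quality = quality, values = values, n = length(values),
         mean_raw = mean(values), sd_raw = stats::sd(values),
         mean_t = mean(lx), sd_t = sd_t, cfg = cfg),
    class = "normative_reference"
  )
}

#' @export
print.normative_reference <- function(x, ...) {
  cat(sprintf(
    "<normative_reference> %s/%s n=%d raw %.1f (%.1f) %s %.3f (%.3f)\n",
    x$site, x$quality, x$n, x$mean_raw, x$sd_raw,
    tolower(x$cfg$transform), x$mean_t, x$sd_t))
  invisible(x)
}

#' Build normative references from a ratings table
#'
#' One [build_normative()] call per (site, quality) cell present in a table
#' of control observations (columns `site`, `quality`, `value_mm`).
#'
#' @param data Tibble of control observations.
#' @param cfg A [profiling_config()].
#' @return Named list of `normative_reference` objects keyed `"site.quality"`.
#' @export
build_normative_table <- function(data, cfg = profiling_config()) {
  check_columns(data, c("site", "quality", "value_mm"), "normative")
  data$site <- parse_enum(data$site, qst_levels()$site, "site")
  data$quality <- parse_enum(data$quality, qst_levels()$quality, "quality")
  split(data, paste(data$site, data$quality, sep = ".")) |>
    purrr::map(function(g) {
      build_normative(g$value_mm, g$site[1], g$quality[1], cfg)
    })
}

#' Derive normative references from a dataset's control group
#'
#' Convenience wrapper pooling the control group's wetness ratings from a
#' given session and stimulation mode into per-cell normative references.
#'
#' @param d A `hygro_dataset`.
#' @param group Reference group (default `"CTR"`).
#' @param session,mode Which ratings feed the reference (defaults
#'   `"NEUTRAL"` / `"DYNAMIC"`, matching the profiling convention).
#' @param cfg A [profiling_config()].
#' @return Named list of `normative_reference` objects.
#' @export
normative_from_ratings <- function(d, group = "CTR", session = "NEUTRAL",
                                   mode = "DYNAMIC",
                                   cfg = profiling_config()) {
  stopifnot(inherits(d, "hygro_dataset"))
  ids <- d$participants$id[d$participants$group == group]
  r <- dplyr::filter(d$ratings, .data$participant_id %in% ids,
                     .data$session == !!session, .data$mode == !!mode)
  build_normative_table(
    tibble::tibble(site = r$site, quality = r$quality, value_mm = r$wetness_mm),
    cfg
  )
}

#' Sensitivity z-score against a normative reference
#'
#' `z = (transform(x) - normative mean) / normative SD` on the transformed
#' scale. Less intense perception than the normative mean gives a negative
#' z (candidate loss of function); more intense gives positive z.
#'
#' @param x Raw rating(s), mm.
#' @param ref A [build_normative()] reference.
#' @param cfg Profiling config; defaults to the one stored in `ref`.
#' @return z-score(s).
#' @export
z_score <- function(x, ref, cfg = ref$cfg) {
  stopifnot(inherits(ref, "normative_reference"))
  if (ref$sd_t <= 0) {
    rlang::abort("Degenerate normative reference", class = "hygro_degenerate_ref")
  }
  (log_transform(x, cfg) - ref$mean_t) / ref$sd_t
}

#' Classify z-scores into loss / normal / gain
#'
#' Strict inequalities: `LOSS` iff z < -threshold, `GAIN` iff
#' z > +threshold, otherwise `NORMAL` (values exactly at the threshold are
#' NORMAL).
#'
#' @param z Numeric z-scores (finite).
#' @param cfg A [profiling_config()].
#' @return Character vector of labels.
#' @export
#' @examples
#' classify_z(c(-16.47, 0, 1.96, 2.2))
classify_z <- function(z, cfg = profiling_config()) {
  if (any(!is.finite(z))) {
    rlang::abort("z must be finite", class = "hygro_out_of_range")
  }
  out <- rep("NORMAL", length(z))
  out[z < -cfg$threshold] <- "LOSS"
  out[z > cfg$threshold] <- "GAIN"
  out
}

#' Hygrosensory profile of one participant
#'
#' Produces the per-cell z-score grid for a single participant: one row per
#' rated (site, quality) cell that has a normative reference, with raw
#' value, z-score and gain/normal/loss label. Cells without a reference
#' (e.g. the forearm, for which no normative data exist) are skipped with a
#' warning; a duplicated cell raises an error.
#'
#' @param ratings Tibble with one row per cell: columns `participant_id`,
#'   `site`, `quality`, `wetness_mm`.
#' @param refs Named list of references from [build_normative_table()].
#' @param cfg A [profiling_config()].
#' @return Tibble of class `sensory_profile`: `participant_id`, `site`,
#'   `quality`, `raw_value`, `z`, `label`.
#' @export
profile_participant <- function(ratings, refs, cfg = profiling_config()) {
  check_columns(ratings, c("participant_id", "site", "quality", "wetness_mm"),
                "ratings")
  if (length(unique(ratings$participant_id)) > 1) {
    rlang::abort("profile_participant() expects a single participant",
                 class = "hygro_invalid_field")
  }
  key <- paste(ratings$site, ratings$quality, sep = ".")
  if (anyDuplicated(key)) {
    rlang::abort("Duplicate (site, quality) cell for participant",
                 class = "hygro_duplicate_key")
  }
  have <- key %in% names(refs)
  if (any(!have)) {
    rlang::warn(sprintf("No normative reference for cell(s): %s; skipped",
                        paste(unique(key[!have]), collapse = ", ")))
  }
  r <- ratings[have, ]
  z <- purrr::map2_dbl(r$wetness_mm, key[have],
                       function(x, k) z_score(x, refs[[k]], cfg))
  out <- tibble::tibble(
    participant_id = r$participant_id,
    site = r$site, quality = r$quality,
    raw_value = r$wetness_mm,
    z = z,
    label = classify_z(z, cfg)
  )
  class(out) <- c("sensory_profile", class(out))
  out
}

#' Profile every participant of a group in a dataset
#'
#' Applies [profile_participant()] to each member of `group`, using their
#' ratings from the given session and mode.
#'
#' @param d A `hygro_dataset`.
#' @param refs Normative references.
#' @param group Group to profile (default `"MS"`).
#' @param session,mode Rating selection (defaults `"NEUTRAL"`/`"DYNAMIC"`).
#' @param cfg A [profiling_config()].
#' @return A `sensory_profile` tibble covering all profiled participants.
#' @export
profile_cohort <- function(d, refs, group = "MS", session = "NEUTRAL",
                           mode = "DYNAMIC", cfg = profiling_config()) {
  stopifnot(inherits(d, "hygro_dataset"))
  ids <- d$participants$id[d$participants$group == group]
  r <- dplyr::filter(d$ratings, .data$participant_id %in% ids,
                     .data$session == !!session, .data$mode == !!mode)
  out <- r |>
    dplyr::group_split(.data$participant_id) |>
    purrr::map(function(g) {
      profile_participant(
        tibble::tibble(participant_id = g$participant_id, site = g$site,
                       quality = g$quality, wetness_mm = g$wetness_mm),
        refs, cfg
      )
    }) |>
    dplyr::bind_rows()
  class(out) <- c("sensory_profile", class(out))
  out
}

#' Summarize sensory abnormalities across profiles
#'
#' A participant is flagged iff at least one cell is labelled LOSS or GAIN.
#' For each flagged participant the pattern lists the distinct sites and
#' stimulus qualities involved.
#'
#' @param profiles A `sensory_profile` tibble (one or many participants).
#' @param group_size Denominator for the proportion; defaults to the number
#'   of distinct profiled participants.
#' @return List of class `abnormality_summary`: `flagged` (per-participant
#'   pattern tibble), `flagged_participants`, `n_flagged`, `n_assessed`,
#'   `proportion`.
#' @export
summarize_abnormalities <- function(profiles, group_size = NULL) {
  check_columns(profiles, c("participant_id", "site", "quality", "z", "label"),
                "profiles")
  if (nrow(profiles) == 0) {
    rlang::abort("Need >= 1 profile", class = "hygro_empty_group")
  }
  n_assessed <- length(unique(profiles$participant_id))
  if (is.null(group_size)) group_size <- n_assessed
  abn <- dplyr::filter(profiles, .data$label != "NORMAL")
  flagged <- abn |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_abnormal_cells = dplyr::n(),
      n_sites = length(unique(.data$site)),
      n_qualities = length(unique(.data$quality)),
      sites = paste(sort(unique(.data$site)), collapse = ";"),
      qualities = paste(sort(unique(.data$quality)), collapse = ";"),
      labels = paste(sort(unique(.data$label)), collapse = ";"),
      .groups = "drop"
    )
  structure(
    list(flagged = flagged,
         flagged_participants = flagged$participant_id,
         n_flagged = nrow(flagged),
         n_assessed = n_assessed,
         proportion = nrow(flagged) / group_size),
    class = "abnormality_summary"
  )
}

#' @export
print.abnormality_summary <- function(x, ...) {
  cat("<abnormality_summary>\n")
  if (x$n_flagged == 0) {
    cat("  none flagged\n")
  } else {
    cat(sprintf("  flagged %d of %d assessed (%.0f%%): %s\n",
                x$n_flagged, x$n_assessed, 100 * x$proportion,
                paste(x$flagged_participants, collapse = ", ")))
  }
  invisible(x)
}
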