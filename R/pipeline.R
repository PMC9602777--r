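# End-to-end orchestration: read -> body-temperature summaries -> group
# ANOVAs -> individual profiling -> abnormality summary -> rendered report.

#' Assemble a pipeline configuration
#'
#' @param participants,ratings,temperatures Paths to the dataset CSVs
#'   (`temperatures` may be `NULL`).
#' @param normative Optional path to a normative CSV with columns
#'   `site,quality,value_mm` (one row per control observation). When absent
#'   the references are pooled from the dataset's own CTR group.
#' @param log_offset,threshold,transform Profiling parameters, see
#'   [profiling_config()].
#' @param window Body-temperature analysis window in seconds.
#' @param seed Seed recorded in provenance (and used by any simulation
#'   steps).
#' @param output_dir Optional directory; when set, [run_pipeline()] renders
#'   the report there.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(participants, ratings, temperatures = NULL,
                            normative = NULL, log_offset = 1,
                            threshold = 1.96, transform = "LOG10",
                            window = c(2100, 3000), seed = 1L,
                            output_dir = NULL) {
  structure(
    list(participants = participants, ratings = ratings,
         temperatures = temperatures, normative = normative,
         profiling = profiling_config(log_offset, threshold, transform),
         window = window, seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value YAML mirroring the arguments of [pipeline_config()];
#' relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p) && file.exists(file.path(base, p))) {
      file.path(base, p)
    } else {
      p
    }
  }
  pipeline_config(
    participants = resolve(y$participants),
    ratings = resolve(y$ratings),
    temperatures = resolve(y$temperatures),
    normative = resolve(y$normative),
    log_offset = y$log_offset %||% 1,
    threshold = y$threshold %||% 1.96,
    transform = y$transform %||% "LOG10",
    window = unlist(y$window %||% c(2100, 3000)),
    seed = y$seed %||% 1L,
    output_dir = y$output_dir
  )
}

stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("[stage: %s] %s", label, conditionMessage(e)),
                 class = "hygro_stage_error", parent = e)
  })
}

#' Run the full QST analysis pipeline
#'
#' Executes, in order: dataset reading and validation; cohort summary;
#' body-temperature window averaging and group/session summary (with a
#' group x session mixed ANOVA on mean skin and rectal temperature);
#' group x mode mixed ANOVAs on thermoneutral wetness per (site, quality);
#' a group x session mixed ANOVA on dynamic wetness collapsed over site and
#' quality; normative reference construction; individual hygrosensory
#' profiling of the MS group; and the abnormality summary. Deterministic
#' given identical inputs; any stage failure aborts with a stage-labelled
#' error.
#'
#' @param cfg A [pipeline_config()] or path to its YAML file.
#' @return Object of class `run_report` (see [render_report()]).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))

  d <- stage("read", read_dataset(cfg$participants, cfg$ratings,
                                  cfg$temperatures))
  groups_present <- intersect(qst_levels()$group, d$participants$group)
  cohort <- stage("cohort", summarize_cohort(d, groups = groups_present))

  temp <- NULL
  if (nrow(d$temperatures) > 0) {
    temp <- stage("temperature", {
      wa <- window_average(d, window = cfg$window)
      sg <- session_group_summary(wa, d)
      tsk_anova <- with_group_session_anova(wa, d, "mean_tsk")
      trec_anova <- with_group_session_anova(wa, d, "mean_trec")
      list(window = wa, summary = sg, tsk_anova = tsk_anova,
           trec_anova = trec_anova)
    })
  }

  anovas <- stage("anova", {
    mode_tabs <- mode_anovas(d)
    session_tab <- session_anova_collapsed(d)
    list(mode = mode_tabs, session = session_tab)
  })

  refs <- stage("normative", {
    if (!is.null(cfg$normative)) {
      nt <- read_table_file(cfg$normative, "normative")
      build_normative_table(nt, cfg$profiling)
    } else {
      normative_from_ratings(d, cfg = cfg$profiling)
    }
  })

  profiling <- stage("profiling", {
    profiles <- profile_cohort(d, refs, group = "MS", cfg = cfg$profiling)
    n_ms <- sum(d$participants$group == "MS")
    list(profiles = profiles,
         abnormalities = summarize_abnormalities(profiles,
                                                 group_size = n_ms))
  })

  report <- structure(
    list(cohort = cohort, temperature = temp, anovas = anovas,
         profiles = profiling$profiles,
         abnormalities = profiling$abnormalities,
         provenance = list(
           package_version = as.character(utils::packageVersion("hygrosense")),
           seed = cfg$seed,
           config_hash = rlang::hash(unclass(cfg)),
           profiling = unclass(cfg$profiling),
           window = cfg$window
         )),
    class = "run_report"
  )
  if (!is.null(cfg$output_dir)) render_report(report, cfg$output_dir)
  report
}

with_group_session_anova <- function(wa, d, var) {
  df <- dplyr::inner_join(
    wa, dplyr::select(d$participants, participant_id = "id", "group"),
    by = "participant_id"
  )
  mixed_anova(df, subject = "participant_id", group = "group",
              within = "session", response = var)
}

mode_anovas <- function(d) {
  r <- dplyr::filter(d$ratings, .data$session == "NEUTRAL")
  r <- dplyr::inner_join(
    r, dplyr::select(d$participants, participant_id = "id", "group"),
    by = "participant_id"
  )
  cells <- dplyr::distinct(r, .data$site, .data$quality)
  purrr::pmap(cells, function(site, quality) {
    sub <- r[r$site == site & r$quality == quality, ]
    tab <- mixed_anova(sub, subject = "participant_id", group = "group",
                       within = "mode", response = "wetness_mm")
    list(site = site, quality = quality, table = tab)
  })
}

session_anova_collapsed <- function(d) {
  r <- dplyr::filter(d$ratings, .data$mode == "DYNAMIC")
  r <- dplyr::inner_join(
    r, dplyr::select(d$participants, participant_id = "id", "group"),
    by = "participant_id"
  )
  collapsed <- r |>
    dplyr::group_by(.data$participant_id, .data$group, .data$session) |>
    dplyr::summarise(wetness_mm = mean(.data$wetness_mm), .groups = "drop")
  mixed_anova(collapsed, subject = "participant_id", group = "group",
              within = "session", response = "wetness_mm")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  cohort groups: %s\n", paste(x$cohort$group, collapse = ", ")))
  cat(sprintf("  mode ANOVAs: %d | temperatures: %s\n",
              length(x$anovas$mode),
              if (is.null(x$temperature)) "absent" else "present"))
  print(x$abnormalities)
  invisible(x)
}

fmt1 <- function(x) formatC(x, format = "f", digits = 1)
fmt2 <- function(x) formatC(x, format = "f", digits = 2)

anova_lines <- function(tab, label) {
  eff <- tab[!is.na(tab$f), ]
  den <- ifelse(eff$effect == "group",
                attr(tab, "df_error")[["between"]],
                attr(tab, "epsilon") * attr(tab, "df_error")[["within"]])
  c(sprintf("**%s** (GG epsilon %.3f)", label, attr(tab, "epsilon")),
    sprintf("- %s: F(%s, %s) = %s, P = %s, %s%% of total variation",
            eff$effect, fmt1(eff$df_corrected), fmt1(den),
            fmt2(eff$f), format.pval(eff$p, digits = 3),
            fmt2(eff$pct_total)),
    "")
}

#' Render a pipeline report to files
#'
#' Writes a human-readable `report.md` plus machine-readable CSVs
#' (`cohort_summary.csv`, `tsk_sessions.csv`, `profiles.csv`,
#' `abnormalities.csv`, `anova_tables.csv`). Lengths are formatted at 1
#' decimal (mm, degC) and z-scores at 2 decimals. Report bodies carry no
#' timestamps, so identical inputs render byte-identical files.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @param format Subset of `c("markdown", "csv")`.
#' @return Character vector of written paths, invisibly.
#' @export
render_report <- function(report, dir, format = c("markdown", "csv")) {
  stopifnot(inherits(report, "run_report"))
  format <- match.arg(format, c("markdown", "csv"), several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  if ("csv" %in% format) {
    w <- function(x, f) {
      p <- file.path(dir, f)
      readr::write_csv(x, p, na = "")
      p
    }
    paths <- c(paths, w(report$cohort, "cohort_summary.csv"))
    if (!is.null(report$temperature)) {
      paths <- c(paths, w(report$temperature$summary$cells, "tsk_sessions.csv"))
    }
    prof <- report$profiles
    prof$z <- round(prof$z, 2)
    paths <- c(paths, w(prof, "profiles.csv"))
    paths <- c(paths, w(report$abnormalities$flagged, "abnormalities.csv"))
    atab <- purrr::map(report$anovas$mode, function(m) {
      tab <- tibble::as_tibble(m$table)
      tab$analysis <- paste0("mode:", m$site, "/", m$quality)
      tab
    })
    stab <- tibble::as_tibble(report$anovas$session)
    stab$analysis <- "session:collapsed_dynamic"
    paths <- c(paths,
               w(dplyr::bind_rows(c(atab, list(stab))), "anova_tables.csv"))
  }

  if ("markdown" %in% format) {
    lines <- c(
      "# Hygrosensory QST report", "",
      "## Cohort", "",
      paste0("- ", report$cohort$group, ": n = ", report$cohort$n,
             ", age ", fmt1(report$cohort$age_mean),
             " (", fmt1(report$cohort$age_sd), ") yr"),
      ""
    )
    if (!is.null(report$temperature)) {
      cells <- report$temperature$summary$cells
      lines <- c(lines, "## Body temperature (analysis window)", "",
                 sprintf("- %s/%s: mean Tsk %s (%s) degC, Trec %s degC",
                         cells$group, cells$session, fmt1(cells$tsk_mean),
                         fmt1(cells$tsk_sd), fmt1(cells$trec_mean)),
                 "")
      ctr <- report$temperature$summary$contrasts
      ctr <- ctr[ctr$variable == "mean_tsk", ]
      lines <- c(lines,
                 sprintf("- mean Tsk %s: %s degC [95%% CI %s, %s]",
                         ctr$comparison, fmt1(ctr$diff), fmt1(ctr$lo),
                         fmt1(ctr$hi)),
                 "")
      lines <- c(lines,
                 anova_lines(report$temperature$tsk_anova,
                             "Mean Tsk: group x session"))
    }
    lines <- c(lines, "## Group-level wetness ANOVAs", "")
    for (m in report$anovas$mode) {
      lines <- c(lines,
                 anova_lines(m$table,
                             sprintf("NEUTRAL %s/%s: group x mode",
                                     m$site, m$quality)))
    }
    lines <- c(lines,
               anova_lines(report$anovas$session,
                           "Dynamic wetness (collapsed): group x session"))
    lines <- c(lines, "## Individual hygrosensory profiles", "")
    ab <- report$abnormalities
    if (ab$n_flagged == 0) {
      lines <- c(lines, "none flagged", "")
    } else {
      lines <- c(lines,
                 sprintf("Flagged %d of %d assessed (%.0f%%).",
                         ab$n_flagged, ab$n_assessed, 100 * ab$proportion),
                 "",
                 sprintf("- ID %s: %d cell(s), %d site(s) [%s], %d qualit%s [%s]",
                         ab$flagged$participant_id,
                         ab$flagged$n_abnormal_cells, ab$flagged$n_sites,
                         ab$flagged$sites, ab$flagged$n_qualities,
                         ifelse(ab$flagged$n_qualities == 1, "y", "ies"),
                         ab$flagged$qualities),
                 "")
    }
    prof <- report$profiles
    lines <- c(lines, "### Per-cell z-scores (MS group)", "",
               "| participant | site | quality | raw (mm) | z | label |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %s | %s | %s |",
                       prof$participant_id, prof$site, prof$quality,
                       fmt1(prof$raw_value), fmt2(prof$z), prof$label),
               "")
    lines <- c(lines, "## Provenance", "",
               sprintf("- package version: %s",
                       report$provenance$package_version),
               sprintf("- seed: %d", report$provenance$seed),
               sprintf("- config hash: %s", report$provenance$config_hash),
               sprintf("- transform: %s (offset %g), threshold %g",
                       report$provenance$profiling$transform,
                       report$provenance$profiling$log_offset,
                       report$provenance$profiling$threshold),
               "")
    p <- file.path(dir, "report.md")
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
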