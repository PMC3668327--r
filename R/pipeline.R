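# End-to-end study replica on synthetic data: simulate cohort, build (and
# optionally score) recordings, quantify architecture per phase/day,
# normalize to baseline, and run the biomarker statistics.

#' Study configuration
#'
#' @param sim A [sim_params()] object.
#' @param cohort A [cohort_params()] object.
#' @param days Recording days to simulate (subset of baseline/0/1/55).
#' @param score_signals Also synthesize EEG/EMG and score every recording
#'   with the staging pipeline (slower; default uses ground-truth hypnograms
#'   only).
#' @param seed Master seed; propagates deterministically to every stage.
#' @return List of class `study_config`.
#' @export
study_config <- function(sim = sim_params(), cohort = cohort_params(),
                         days = c("baseline", "0", "1", "55"),
                         score_signals = FALSE, seed = 1L) {
  days <- match.arg(days, several.ok = TRUE)
  sim$seed <- as.integer(seed)
  cohort$seed <- as.integer(seed) + 1L
  structure(list(sim = sim, cohort = cohort, days = days,
                 score_signals = score_signals, seed = as.integer(seed)),
            class = "study_config")
}

#' Load a study configuration from a YAML file
#'
#' Recognized top-level keys: `seed`, `days`, `score_signals`, plus any
#' argument of [sim_params()] under `sim:` and of [cohort_params()] under
#' `cohort:`.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
study_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configurations")
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_params, as.list(y$sim))
  coh <- do.call(cohort_params, as.list(y$cohort))
  study_config(sim = sim, cohort = coh,
               days = if (is.null(y$days)) c("baseline", "0", "1", "55")
                      else as.character(y$days),
               score_signals = isTRUE(y$score_signals),
               seed = if (is.null(y$seed)) 1L else y$seed)
}

# long architecture table over animals/days, with baseline-normalized values
study_long_table <- function(hyps, groups, days) {
  rows <- list()
  for (a in names(hyps)) {
    for (d in intersect(days, names(hyps[[a]]))) {
      arch <- architecture_summary(hyps[[a]][[d]],
                                   exclude_phase1 = (d == "0"))
      arch$animal <- a
      arch$group <- groups[[a]]
      arch$day <- d
      rows[[paste(a, d)]] <- arch
    }
  }
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  tbl$variable <- paste(tbl$variable, tbl$state, sep = ".")
  tbl <- tbl[, c("animal", "group", "day", "phase", "excluded",
                 "variable", "value")]

  base <- tbl[tbl$day == "baseline", ]
  bm <- stats::aggregate(value ~ group + phase + variable, base, mean)
  names(bm)[names(bm) == "value"] <- "baseline_mean"
  tbl <- merge(tbl, bm, all.x = TRUE, sort = FALSE)
  tbl$normalized <- ifelse(is.finite(tbl$baseline_mean) & tbl$baseline_mean > 0,
                           100 * tbl$value / tbl$baseline_mean, NA_real_)
  tbl[order(tbl$animal, tbl$day, tbl$phase, tbl$variable), ]
}

#' Run the full synthetic study
#'
#' Simulates the cohort, builds per-animal/day ground-truth hypnograms
#' (optionally synthesizing and scoring EEG/EMG as well, so scoring error is
#' visible next to the truth), summarizes architecture per Zeitgeber phase
#' with baseline normalization (day-0 phase I excluded), and runs the
#' statistics: the group x day repeated-measures analysis of phase-IV
#' occupancies and the baseline REMS-continuity vs startle correlations.
#'
#' @param cfg A [study_config()].
#' @param out_dir Optional output directory for CSVs and a text report.
#' @return List with `cohort`, `architecture` (long table), optional
#'   `architecture_scored`, `rm_phase4`, `correlations`, and `report` lines.
#' @export
run_study <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  cohort <- simulate_cohort(cfg$cohort, cfg$sim)
  groups <- stats::setNames(cohort$table$group, cohort$table$animal)
  hyps <- cohort_hypnograms(cohort, days = cfg$days)
  arch <- study_long_table(hyps, groups, cfg$days)

  arch_scored <- NULL
  if (cfg$score_signals) {
    scored <- lapply(names(hyps), function(a) {
      lapply(hyps[[a]], function(h) {
        rec <- synthesize_signals(h, cfg$sim,
                                  seed = (cfg$seed + sum(utf8ToInt(a))) %%
                                    .Machine$integer.max)
        score_recording(rec)
      })
    })
    names(scored) <- names(hyps)
    arch_scored <- study_long_table(scored, groups, cfg$days)
  }

  rm_phase4 <- NULL
  if (length(cfg$days) >= 2 && "baseline" %in% cfg$days) {
    rm_tbl <- arch[!arch$excluded, ]
    rm_phase4 <- rm_group_day_analysis(
      rm_tbl, variables = c("occupancy_pct.WAKE", "occupancy_pct.NREMS",
                            "occupancy_pct.REMS"),
      phase = "IV")
  }

  tab <- cohort$table
  correlations <- list()
  for (g in unique(tab$group)) {
    sub <- tab[tab$group == g, ]
    if (nrow(sub) < 3) next
    correlations[[g]] <- list(
      episodes_asr = correlation(sub$baseline_rems_episodes, sub$asr_115),
      transitions_asr = correlation(sub$baseline_nrems_to_rems_transitions,
                                    sub$asr_115),
      episodes_freezing = correlation(sub$baseline_rems_episodes,
                                      sub$freezing_chamber),
      r2_episodes_asr = variance_explained(sub$baseline_rems_episodes,
                                           sub$asr_115),
      persistence = if (all(c("1", "55") %in% cfg$days))
        correlation(sub$rems_change_day1, sub$rems_change_day55) else NULL
    )
  }

  report <- c(
    sprintf("synthetic trauma study: %d animals per group, seed %d",
            cfg$cohort$n_per_group, cfg$seed),
    sprintf("days simulated: %s", paste(cfg$days, collapse = ", ")),
    if (!is.null(rm_phase4)) sprintf(
      "phase IV occupancy multivariate tests: %s",
      paste(sprintf("%s p=%.4g", rm_phase4$multivariate$effect,
                    rm_phase4$multivariate$p_value), collapse = "; ")),
    vapply(names(correlations), function(g) sprintf(
      "%s: r(episodes, ASR115)=%.3f, r(NREMS->REMS, ASR115)=%.3f, r2=%.3f",
      g, correlations[[g]]$episodes_asr$estimate,
      correlations[[g]]$transitions_asr$estimate,
      correlations[[g]]$r2_episodes_asr), "")
  )

  out <- list(cohort = cohort, architecture = arch,
              architecture_scored = arch_scored,
              rm_phase4 = rm_phase4, correlations = correlations,
              report = report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort$table, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(arch, file.path(out_dir, "architecture_true.csv"),
                     row.names = FALSE)
    if (!is.null(arch_scored))
      utils::write.csv(arch_scored,
                       file.path(out_dir, "architecture_scored.csv"),
                       row.names = FALSE)
    writeLines(report, file.path(out_dir, "report.txt"))
  }
  out
}
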