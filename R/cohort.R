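# Trauma-cohort simulation: latent-trait model linking baseline phase-IV
# REMS continuity to post-trauma startle, shock-induced REMS elevation with
# day-1/day-55 persistence, and freezing endpoints independent of sleep.

chol_or_fail <- function(sigma) {
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("requested correlation matrix is not positive semi-definite")
  sigma
}

#' Simulate a trauma cohort
#'
#' Per animal, a trivariate standard-normal latent draw with the configured
#' correlation structure generates the baseline phase-IV REMS episode count,
#' the baseline NREMS-to-REMS transition count, and the 115-dB acoustic
#' startle amplitude; in the shocked group the sleep/startle correlations are
#' `rho_rems_asr` / `rho_trans_asr`, in controls `rho_controls`. Phase-IV
#' REMS on post-shock days is elevated by `rems_shock_effect` in shocked
#' animals only, with day-1 and day-55 baseline-normalized changes correlated
#' at `persistence_rho`. Freezing percentages are generated independently of
#' all sleep traits in both groups.
#'
#' @param cp A [cohort_params()] object.
#' @param sp A [sim_params()] object (carried along for downstream signal
#'   generation).
#' @param seed Optional seed override (defaults to `cp$seed`).
#' @return List of class `cohort` with elements `table` (one row per animal)
#'   and the two parameter objects.
#' @export
simulate_cohort <- function(cp, sp = sim_params(), seed = NULL) {
  validate_cohort_params(cp)
  validate_sim_params(sp)
  set.seed(if (is.null(seed)) cp$seed else seed)
  n <- cp$n_per_group

  draw_group <- function(group) {
    shocked <- group == "shocked"
    r_ea <- if (shocked) cp$rho_rems_asr else cp$rho_controls
    r_ta <- if (shocked) cp$rho_trans_asr else cp$rho_controls
    sigma <- chol_or_fail(matrix(c(
      1, cp$rho_episodes_trans, r_ea,
      cp$rho_episodes_trans, 1, r_ta,
      r_ea, r_ta, 1), 3, 3))
    z <- MASS::mvrnorm(n, mu = rep(0, 3), Sigma = sigma)
    episodes <- pmax(1L, as.integer(round(cp$episode_mean + cp$episode_sd * z[, 1])))
    transitions <- pmax(0L, as.integer(round(cp$trans_mean + cp$trans_sd * z[, 2])))
    asr115 <- pmax(0, cp$asr_mean[[group]] + cp$asr_noise_sd * z[, 3])

    effect <- if (shocked) 100 * cp$rems_shock_effect else 100
    sig2 <- chol_or_fail(matrix(c(1, cp$persistence_rho,
                                  cp$persistence_rho, 1), 2, 2))
    zc <- MASS::mvrnorm(n, mu = rep(0, 2), Sigma = sig2)
    change_day1 <- effect + cp$rems_change_sd * zc[, 1]
    change_day55 <- effect + cp$rems_change_sd * zc[, 2]
    change_day0 <- effect + cp$rems_change_sd * stats::rnorm(n)

    asr_scale <- c(control = 0.06, `75` = 0.25, `90` = 0.5, `105` = 0.8)
    asr_other <- sapply(names(asr_scale), function(k)
      pmax(0, asr_scale[[k]] * cp$asr_mean[[group]] +
             0.5 * cp$asr_noise_sd * stats::rnorm(n)))
    fr <- cp$freezing_params
    freezing <- sapply(FREEZING_CONTEXTS, function(ctx)
      pmin(100, pmax(0, stats::rnorm(n, fr$mean[group, ctx], fr$sd))))

    data.frame(
      group = group,
      baseline_rems_episodes = episodes,
      baseline_nrems_to_rems_transitions = transitions,
      asr_control = asr_other[, "control"], asr_75 = asr_other[, "75"],
      asr_90 = asr_other[, "90"], asr_105 = asr_other[, "105"],
      asr_115 = asr115,
      freezing_cylinder = freezing[, "cylinder"],
      freezing_tone = freezing[, "tone"],
      freezing_hexagon = freezing[, "hexagon"],
      freezing_chamber = freezing[, "chamber"],
      rems_change_day0 = change_day0,
      rems_change_day1 = change_day1,
      rems_change_day55 = change_day55
    )
  }

  tab <- rbind(draw_group("non_shocked"), draw_group("shocked"))
  tab <- cbind(animal = sprintf("m%02d", seq_len(nrow(tab))), tab)
  structure(list(table = tab, cohort_params = cp, sim_params = sp),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d animals per group>\n", x$cohort_params$n_per_group))
  print(utils::head(x$table))
  invisible(x)
}

#' Per-animal hypnograms for the recorded study days
#'
#' Builds one 24-h ground-truth hypnogram per animal and day. Each animal's
#' baseline phase-IV REMS occupancy is set so its expected REMS episode count
#' matches the cohort table (occupancy = episodes x REMS dwell / phase
#' epochs); on post-shock days the phase-IV REMS fraction is scaled by the
#' animal's baseline-normalized change, with WAKE/NREMS absorbing the
#' difference proportionally. Shocked and non-shocked animals use the same
#' machinery; controls' changes hover around 100%.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param days Character subset of `c("baseline", "0", "1", "55")`.
#' @return Nested list `hyps[[animal]][[day]]` of `hypnogram` objects.
#' @export
cohort_hypnograms <- function(cohort, days = c("baseline", "0", "1", "55")) {
  stopifnot(inherits(cohort, "cohort"))
  days <- match.arg(days, several.ok = TRUE)
  sp <- cohort$sim_params
  tab <- cohort$table
  epochs_per_phase <- 6 * 3600 / sp$epoch_len
  change_col <- c(baseline = NA, `0` = "rems_change_day0",
                  `1` = "rems_change_day1", `55` = "rems_change_day55")
  out <- list()
  for (i in seq_len(nrow(tab))) {
    p_rems_base <- tab$baseline_rems_episodes[i] *
      sp$dwell_means[["REMS"]] / epochs_per_phase
    per_day <- list()
    for (d in days) {
      mult <- if (d == "baseline") 1 else tab[[change_col[[d]]]][i] / 100
      occ <- sp$phase_occupancy
      p_rems <- min(p_rems_base * mult, 0.9)
      other <- occ["IV", c("WAKE", "NREMS")]
      occ["IV", "REMS"] <- p_rems
      occ["IV", c("WAKE", "NREMS")] <- other / sum(other) * (1 - p_rems)
      spi <- sp
      spi$phase_occupancy <- occ
      per_day[[d]] <- simulate_hypnogram(
        spi, n_days = 1,
        seed = (sp$seed + 7919L * i + 104729L * match(d, names(change_col))) %% .Machine$integer.max)
    }
    out[[tab$animal[i]]] <- per_day
  }
  out
}
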