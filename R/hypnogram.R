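#' Construct a hypnogram
#'
#' A hypnogram is a per-epoch sequence of vigilance-state labels on the 4-s
#' epoch grid, annotated with its Zeitgeber start time and provenance (ground
#' truth from the simulator vs. scored by the staging algorithm).
#'
#' @param states Character vector or factor of labels from
#'   WAKE/MA/NREMS/REMS.
#' @param epoch_len Epoch length in seconds (default 4).
#' @param zeitgeber_start Zeitgeber hour of the first epoch, in [0, 24).
#' @param provenance `"true"` or `"scored"`.
#' @return Object of class `hypnogram`.
#' @export
hypnogram <- function(states, epoch_len = 4, zeitgeber_start = 0,
                      provenance = c("true", "scored")) {
  provenance <- match.arg(provenance)
  states <- as.character(states)
  bad <- setdiff(unique(states), VIGILANCE_STATES)
  if (length(bad))
    stop("unknown vigilance states: ", paste(bad, collapse = ", "))
  if (zeitgeber_start < 0 || zeitgeber_start >= 24)
    stop("zeitgeber_start must lie in [0, 24)")
  structure(
    list(states = factor(states, levels = VIGILANCE_STATES),
         epoch_len = epoch_len,
         zeitgeber_start = zeitgeber_start,
         provenance = provenance),
    class = "hypnogram"
  )
}

#' @export
length.hypnogram <- function(x) length(x$states)

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram: %d epochs of %gs (%.1f h), %s, ZT start %g>\n",
              length(x), x$epoch_len, length(x) * x$epoch_len / 3600,
              x$provenance, x$zeitgeber_start))
  print(round(100 * table(x$states) / length(x), 2))
  invisible(x)
}

#' Zeitgeber hour of each epoch (start-of-epoch convention)
#' @param h A `hypnogram`.
#' @return Numeric vector in [0, 24).
#' @export
zeitgeber_hours <- function(h) {
  (h$zeitgeber_start + (seq_len(length(h)) - 1) * h$epoch_len / 3600) %% 24
}

# Per-phase chain settings: leave probability r_s = 1/m_s; on leaving, the
# next state is redrawn from mu_s proportional to p_s / m_s (the redraw may
# return the current state, which just extends the bout). The stationary
# occupancy of this chain is exactly p.
solve_phase_chain <- function(occ, dwell) {
  mu <- occ / dwell
  tot <- sum(mu)
  if (tot <= 0)
    stop("infeasible occupancy/dwell combination: no state has positive mass")
  list(leave = 1 / dwell, mu = mu / tot)
}

#' Simulate a ground-truth hypnogram
#'
#' Generates a per-epoch WAKE/NREMS/REMS sequence from a phase-dependent
#' Markov chain with geometric bout lengths whose stationary occupancy in
#' each 6-h Zeitgeber phase equals the configured target, then relabels
#' brief WAKE runs (< 3 epochs) as microarousals so the ground truth uses the
#' same 4-state alphabet as scored hypnograms.
#'
#' @param params A [sim_params()] object.
#' @param n_days Number of simulated 24-h days (>= 1).
#' @param seed Optional seed override (defaults to `params$seed`).
#' @return A `hypnogram` with provenance `"true"` starting at Zeitgeber 0.
#' @export
simulate_hypnogram <- function(params, n_days = 1, seed = NULL) {
  validate_sim_params(params)
  if (n_days < 1) stop("n_days must be >= 1")
  set.seed(if (is.null(seed)) params$seed else seed)

  epochs_per_hour <- 3600 / params$epoch_len
  epochs_per_phase <- as.integer(6 * epochs_per_hour)
  occ <- params$phase_occupancy
  dwell <- params$dwell_means[SIM_STATES]
  chains <- lapply(seq_len(4), function(ph)
    solve_phase_chain(occ[ph, SIM_STATES], dwell))

  n_epochs <- as.integer(n_days * 4L * epochs_per_phase)
  states <- integer(n_epochs)
  # initial state from phase-I occupancy
  cur <- sample.int(3L, 1L, prob = pmax(occ[1, ], 0))
  k <- 0L
  for (day in seq_len(n_days)) {
    for (ph in seq_len(4)) {
      ch <- chains[[ph]]
      # a state carried across a phase boundary may have zero mass here;
      # force an immediate redraw in that case
      if (ch$mu[cur] == 0 && occ[ph, cur] == 0)
        cur <- sample.int(3L, 1L, prob = ch$mu)
      leave <- ch$leave
      mu <- ch$mu
      u <- stats::runif(epochs_per_phase)
      for (i in seq_len(epochs_per_phase)) {
        states[k + i] <- cur
        if (u[i] < leave[cur])
          cur <- sample.int(3L, 1L, prob = mu)
      }
      k <- k + epochs_per_phase
    }
  }
  h <- hypnogram(SIM_STATES[states], epoch_len = params$epoch_len,
                 zeitgeber_start = 0, provenance = "true")
  h <- mark_microarousals(h)
  h$provenance <- "true"
  h
}
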