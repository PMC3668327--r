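# shared fixtures built in code

# a small feature table with chosen band powers (one row per epoch)
make_features <- function(bands, emg_rms = rep(1, nrow(bands))) {
  stopifnot(ncol(bands) == 5)
  colnames(bands) <- names(EEG_BANDS)
  df <- data.frame(epoch_index = seq_len(nrow(bands)) - 1L,
                   zeitgeber_hour = (seq_len(nrow(bands)) - 1) * 4 / 3600,
                   bands, emg_rms = emg_rms)
  composite_features(df)
}

# a single-state hypnogram of n epochs
flat_hypnogram <- function(state, n, zt = 0) {
  hypnogram(rep(state, n), zeitgeber_start = zt, provenance = "true")
}

# params with a uniform occupancy useful for quick mixed recordings
quick_params <- function(seed = 1) {
  occ <- matrix(rep(c(0.4, 0.45, 0.15), each = 4), nrow = 4,
                dimnames = list(c("I", "II", "III", "IV"), SIM_STATES))
  sim_params(phase_occupancy = occ, seed = seed)
}

# brute-force run-length encoder used as an oracle for find_episodes
brute_episodes <- function(states) {
  out <- list()
  start <- 1
  for (i in seq_along(states)[-1]) {
    if (states[i] != states[i - 1]) {
      out[[length(out) + 1]] <- c(start = start, len = i - start)
      start <- i
    }
  }
  out[[length(out) + 1]] <- c(start = start, len = length(states) - start + 1)
  do.call(rbind, out)
}

# random 4-state hypnogram for property tests
random_hypnogram <- function(n, seed) {
  set.seed(seed)
  hypnogram(sample(VIGILANCE_STATES, n, replace = TRUE,
                   prob = c(0.35, 0.05, 0.45, 0.15)),
            zeitgeber_start = 0, provenance = "scored")
}

# balanced null long table for the repeated-measures analysis
null_long_table <- function(n_per_group = 8, variables = c("v1", "v2"),
                            days = c("baseline", "0", "1", "55")) {
  animals <- sprintf("a%02d", seq_len(2 * n_per_group))
  grid <- expand.grid(animal = animals, day = days, variable = variables,
                      stringsAsFactors = FALSE)
  grid$group <- rep(c("non_shocked", "shocked"),
                    each = n_per_group)[match(grid$animal, animals)]
  grid$value <- stats::rnorm(nrow(grid))
  grid
}
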