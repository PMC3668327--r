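# threshold fitting, rule-based classification, microarousal relabelling

test_that("otsu split matches a brute-force scan and lands between clusters", {
  set.seed(7)
  x <- c(stats::rnorm(300, 0, 0.3), stats::rnorm(200, 4, 0.3))
  thr <- otsu_split(x)
  expect_gt(thr, 1)
  expect_lt(thr, 3)

  brute <- function(x) {
    x <- sort(x)
    cands <- (x[-length(x)] + x[-1]) / 2
    bcv <- vapply(cands, function(cc) {
      lo <- x < cc
      if (!any(lo) || all(lo)) return(-Inf)
      mean(lo) * mean(!lo) * (mean(x[lo]) - mean(x[!lo]))^2
    }, 0)
    cands[which.max(bcv)]
  }
  for (seed in 1:5) {
    set.seed(seed)
    y <- c(stats::rnorm(80, 0, 1), stats::rnorm(60, 3, 0.5))
    expect_equal(otsu_split(y), brute(y))
  }
  expect_true(is.na(otsu_split(rep(2, 50))))
})

test_that("degenerate feature distributions trigger the median fallback", {
  f <- make_features(matrix(rep(c(4, 1, 2, 2, 2), each = 150), ncol = 5),
                     emg_rms = rep(1, 150))
  w <- capture_warnings(thr <- fit_thresholds(f))
  expect_true(all(grepl("degenerate", w)) && length(w) == 3)
  expect_s3_class(thr, "thresholds")
  expect_equal(thr$emg_thr, 1)
})

test_that("manual overrides are honored and partial overrides stay auto", {
  set.seed(3)
  b <- exp(matrix(stats::rnorm(750), ncol = 5)) *
    rep(c(4, 1, 2, 2, 2), each = 150)
  f <- make_features(matrix(b, ncol = 5),
                     emg_rms = exp(c(stats::rnorm(75, 0), stats::rnorm(75, 2))))
  thr <- suppressWarnings(fit_thresholds(f, emg_thr = 1.23))
  expect_equal(thr$emg_thr, 1.23)
  expect_equal(thr$method, "auto")
  thr2 <- fit_thresholds(f, emg_thr = 1, delta_thr = 2, theta_thr = 3)
  expect_equal(thr2$method, "manual")
  expect_error(fit_thresholds(f[1:50, ]), "at least 100 epochs")
  expect_error(thresholds(-1, 1, 1), "positive")
})

test_that("classification agrees with the exhaustive rule table", {
  thr <- thresholds(1, 1, 1, method = "manual")
  hi <- 2; lo <- 0.5
  # all 8 side-combinations of (emg, delta', theta') vs their thresholds
  grid <- expand.grid(emg = c(lo, hi), delta = c(lo, hi), theta = c(lo, hi))
  expected <- with(grid, ifelse(emg > 1, "WAKE",
                    ifelse(delta < 1 & theta > 1, "REMS", "NREMS")))
  # band powers engineered so composites equal the requested values:
  # delta' = (d*a)/(e*b), theta' = t^2/(d*a); use a=e=b=1, d=delta,
  # t = sqrt(theta*delta)
  f <- make_features(cbind(grid$delta, sqrt(grid$theta * grid$delta),
                           1, 1, 1),
                     emg_rms = grid$emg)
  h <- classify_epochs(f, thr)
  expect_equal(as.character(h$states), expected)
})

test_that("indeterminate epochs inherit the previous label", {
  thr <- thresholds(1, 1, 1, method = "manual")
  b <- rbind(c(0.5, 2, 1, 1, 1),   # REMS (delta'=0.5, theta'=8)
             c(0.5, 2, 1, 0, 1),   # indeterminate -> inherits REMS
             c(4, 1, 1, 1, 1))     # NREMS
  f <- make_features(b, emg_rms = c(0.5, 0.5, 0.5))
  h <- classify_epochs(f, thr)
  expect_equal(as.character(h$states), c("REMS", "REMS", "NREMS"))
  # leading indeterminate epoch defaults to NREMS
  f2 <- make_features(rbind(c(1, 1, 1, 0, 1), c(0.5, 2, 1, 1, 1)),
                      emg_rms = c(0.5, 0.5))
  expect_equal(as.character(classify_epochs(f2, thr)$states),
               c("NREMS", "REMS"))
})

test_that("raising thresholds never increases WAKE or REMS counts", {
  set.seed(11)
  f <- make_features(matrix(exp(stats::rnorm(500)), ncol = 5),
                     emg_rms = exp(stats::rnorm(100)))
  count <- function(emg_t, theta_t, state) {
    h <- classify_epochs(f, thresholds(emg_t, 1, theta_t, method = "manual"))
    sum(h$states == state)
  }
  emg_grid <- c(0.3, 0.7, 1, 1.5, 3)
  wake <- vapply(emg_grid, count, 0, theta_t = 1, state = "WAKE")
  expect_true(all(diff(wake) <= 0))
  theta_grid <- c(0.3, 0.7, 1, 1.5, 3)
  rems <- vapply(theta_grid, function(tt) count(1, tt, "REMS"), 0)
  expect_true(all(diff(rems) <= 0))
})

test_that("microarousal relabelling follows the 3-epoch rule", {
  relab <- function(s) as.character(mark_microarousals(
    hypnogram(s, provenance = "scored"))$states)
  expect_equal(relab(c("NREMS", "WAKE", "WAKE", "NREMS")),
               c("NREMS", "MA", "MA", "NREMS"))
  expect_equal(relab(c("NREMS", "WAKE", "WAKE", "WAKE", "NREMS")),
               c("NREMS", "WAKE", "WAKE", "WAKE", "NREMS"))
  # boundary runs are eligible
  expect_equal(relab(c("WAKE", "WAKE", "NREMS")), c("MA", "MA", "NREMS"))
  expect_error(mark_microarousals(
    hypnogram(c("NREMS", "MA"), provenance = "scored")), "already contains")
})

test_that("the 4-state output never contains a WAKE run shorter than 3 epochs", {
  for (seed in 1:20) {
    set.seed(seed)
    s <- sample(SIM_STATES, 200, replace = TRUE, prob = c(0.4, 0.45, 0.15))
    h4 <- mark_microarousals(hypnogram(s, provenance = "scored"))
    r <- rle(as.character(h4$states))
    expect_true(all(r$lengths[r$values == "WAKE"] >= 3))
    # sleep labels untouched
    keep <- s != "WAKE"
    expect_equal(as.character(h4$states)[keep], s[keep])
  }
})

test_that("a single-state recording is scored correctly under carried-over thresholds", {
  # thresholds are set once per animal on a full mixed recording, then
  # applied to slices; an NREMS-only slice must come back essentially NREMS
  sp <- quick_params(seed = 51)
  href <- simulate_hypnogram(sp, n_days = 1)
  href <- hypnogram(as.character(href$states[1:2700]), provenance = "true")
  ref <- synthesize_signals(href, sp)
  thr <- fit_thresholds(composite_features(epoch_spectra(bandpass_eeg(ref))))

  hn <- flat_hypnogram("NREMS", 450)
  scored <- score_recording(synthesize_signals(hn, sp, seed = 77), thr = thr)
  expect_gte(mean(scored$states == "NREMS"), 0.95)
  expect_error(score_recording(recording(numeric(0), numeric(0), 64)), "empty")
})

test_that("the full pipeline recovers simulated vigilance states accurately", {
  sp <- sim_params(seed = 61)
  h <- simulate_hypnogram(sp, n_days = 1)
  rec <- synthesize_signals(h, sp)
  scored <- score_recording(rec, verbose = FALSE)
  expect_length(scored, length(h))
  truth <- as.character(h$states); truth[truth == "MA"] <- "WAKE"
  est <- as.character(scored$states); est[est == "MA"] <- "WAKE"
  expect_gte(mean(truth == est), 0.90)
  # determinism: same features + thresholds give identical hypnograms
  scored2 <- score_recording(rec, thr = attr(scored, "thresholds"))
  expect_identical(scored$states, scored2$states)
})

test_that("REMS/NREMS confusion shrinks as the theta/delta contrast grows", {
  confusion <- function(theta_w) {
    sp <- quick_params(seed = 71)
    sp$band_profiles$REMS["theta"] <- theta_w
    h <- simulate_hypnogram(sp, n_days = 1)
    h <- hypnogram(as.character(h$states[1:2700]), provenance = "true")
    rec <- synthesize_signals(h, sp, seed = 72)
    scored <- score_recording(rec)
    truth <- as.character(h$states)
    est <- as.character(scored$states)
    sleep <- truth %in% c("NREMS", "REMS")
    mean(truth[sleep] != est[sleep])
  }
  errs <- vapply(c(1.2, 1.8, 3.0), confusion, 0)
  expect_true(all(diff(errs) <= 0.005))
  expect_lt(errs[3], 0.05)
})
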