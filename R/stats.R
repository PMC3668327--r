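# The study's statistical surface: pooled-variance t tests, Pearson/Spearman
# correlations with t-transform p values, OLS variance explained, and the
# group x day repeated-measures analysis (Wilks' lambda multivariate tests,
# univariate follow-ups, Bonferroni-corrected contrasts).

test_result <- function(statistic, df, p_value, tail = "two",
                        correction = "none", adjusted_alpha = NA_real_,
                        estimate = NULL, method = NULL) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 tail = tail, correction = correction,
                 adjusted_alpha = adjusted_alpha, estimate = estimate,
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s: stat %.4g, df %s, %s-tailed p %.4g%s%s>\n",
              if (is.null(x$method)) "test" else x$method,
              x$statistic, paste(signif(x$df, 4), collapse = ","), x$tail,
              x$p_value,
              if (!is.null(x$estimate)) sprintf(", estimate %.4g", x$estimate) else "",
              if (x$correction != "none")
                sprintf(", %s alpha %.4g", x$correction, x$adjusted_alpha) else ""))
  invisible(x)
}

#' Bonferroni-adjusted significance level
#'
#' @param n_contrasts Size of the contrast family.
#' @param alpha Nominal level (default 0.05). Four day contrasts give 0.0125
#'   and six give ~0.0083, the conventions used for group-vs-group and
#'   day-vs-baseline comparisons respectively.
#' @export
bonferroni_alpha <- function(n_contrasts, alpha = 0.05) alpha / n_contrasts

#' Independent-samples t test with pooled variance
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param tail `"two"` or `"one"`; the one-tailed p is for the alternative
#'   that the mean of `x` exceeds the mean of `y`.
#' @return A `test_result` with the t statistic and degrees of freedom.
#' @export
ttest_independent <- function(x, y, tail = c("two", "one")) {
  tail <- match.arg(tail)
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs n >= 2")
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- if (tail == "two") 2 * stats::pt(-abs(tval), df)
       else stats::pt(tval, df, lower.tail = FALSE)
  test_result(tval, df, p, tail = tail, method = "t (pooled variance)",
              estimate = mean(x) - mean(y))
}

#' Pearson or Spearman correlation with t-transform p value
#'
#' Spearman is Pearson on average ranks; both use the two-tailed p value from
#' t = r * sqrt((n - 2) / (1 - r^2)).
#'
#' @param x,y Numeric vectors, n >= 3, finite.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `test_result` with `estimate` = r.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3) stop("need n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  n <- length(x)
  if (is.na(r)) stop("correlation undefined (zero variance)")
  if (abs(r) >= 1) {
    p <- 0
    tval <- sign(r) * Inf
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  test_result(tval, n - 2, p, tail = "two", estimate = r, method = method)
}

#' Variance explained by a simple linear fit
#'
#' Coefficient of determination of ordinary least squares `y ~ x`; equals the
#' squared Pearson correlation for a single predictor.
#'
#' @param x,y Numeric vectors, n >= 3.
#' @return r^2 in `[0, 1]`, or NA with a warning if `x` is constant.
#' @export
variance_explained <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need paired n >= 3")
  if (stats::var(x) == 0) {
    warning("constant predictor; r^2 undefined")
    return(NA_real_)
  }
  summary(stats::lm(y ~ x))$r.squared
}

# reshape a long table into an animals x (variable:day) wide matrix,
# checking balance
rm_wide <- function(tbl, variables, days) {
  animals <- sort(unique(tbl$animal))
  wide <- list()
  for (v in variables) {
    m <- matrix(NA_real_, length(animals), length(days),
                dimnames = list(animals, days))
    sub <- tbl[tbl$variable == v, ]
    for (i in seq_len(nrow(sub))) {
      a <- as.character(sub$animal[i]); d <- as.character(sub$day[i])
      if (!is.na(m[a, d]))
        stop("duplicate value for (", a, ", ", d, ", ", v, ")")
      m[a, d] <- sub$value[i]
    }
    if (anyNA(m)) {
      miss <- which(is.na(m), arr.ind = TRUE)
      stop("missing cells for variable ", v, ": ",
           paste(animals[miss[, 1]], days[miss[, 2]],
                 sep = "/", collapse = ", "))
    }
    wide[[v]] <- m
  }
  list(animals = animals, wide = wide)
}

# multivariate (Wilks) intercept and group rows for a response matrix; a
# single-column response reduces to the exact univariate F (Wilks' lambda is
# then SSE / (SSE + SSH))
mv_rows <- function(Y, group) {
  Y <- as.matrix(Y)
  if (ncol(Y) >= 2) {
    an <- stats::anova(stats::lm(Y ~ group), test = "Wilks")
    get <- function(row) {
      i <- match(row, rownames(an))
      data.frame(effect = row, wilks = an$Wilks[i], F = an$`approx F`[i],
                 df1 = an$`num Df`[i], df2 = an$`den Df`[i],
                 p_value = an$`Pr(>F)`[i])
    }
    rbind(get("(Intercept)"), get("group"))
  } else {
    fit <- stats::lm(Y[, 1] ~ group)
    co <- summary(fit)$coefficients
    an <- stats::anova(fit)
    dfres <- fit$df.residual
    tint <- co["(Intercept)", "t value"]
    sse <- an["Residuals", "Sum Sq"]
    rbind(
      data.frame(effect = "(Intercept)", wilks = dfres / (dfres + tint^2),
                 F = tint^2, df1 = 1, df2 = dfres,
                 p_value = co["(Intercept)", "Pr(>|t|)"]),
      data.frame(effect = "group", wilks = sse / (sse + an["group", "Sum Sq"]),
                 F = an["group", "F value"], df1 = 1, df2 = dfres,
                 p_value = an["group", "Pr(>F)"])
    )
  }
}

#' Group x day repeated-measures analysis of sleep-architecture variables
#'
#' Multivariate tests (Wilks' lambda) for the between-subject group effect
#' (on day-averaged variables), the within-subject day effect and the
#' group x day interaction (on day-minus-baseline contrast variables),
#' followed -- when the multivariate tests reach `alpha` -- by univariate
#' mixed-model F tests per variable and Bonferroni-corrected contrasts
#' (each day vs baseline within group, six contrasts, alpha/6; shocked vs
#' non-shocked per day, four contrasts, alpha/4). No sphericity correction
#' is applied.
#'
#' @param tbl Long-format data.frame with columns `animal`, `group`, `day`,
#'   `variable`, `value` (and optionally `phase`, see `phase`); complete
#'   balanced cases, >= 2 animals per group.
#' @param variables Character vector of variables forming one multivariate
#'   subgroup (kept small to avoid collinearity; the number of contrast
#'   variables must stay below the number of animals minus 2).
#' @param phase Optional phase label to filter on when `tbl` has a `phase`
#'   column.
#' @param alpha Nominal level gating the follow-ups (default 0.05).
#' @param gate Run follow-ups only if a multivariate effect is significant
#'   (default TRUE, as in the original analysis plan).
#' @return List with `multivariate`, `univariate`, `contrasts` data.frames
#'   and `gated` flag.
#' @export
rm_group_day_analysis <- function(tbl, variables, phase = NULL, alpha = 0.05,
                                  gate = TRUE) {
  if (!is.null(phase) && "phase" %in% names(tbl))
    tbl <- tbl[tbl$phase == phase, ]
  need <- c("animal", "group", "day", "variable", "value")
  if (!all(need %in% names(tbl)))
    stop("tbl must have columns ", paste(need, collapse = ", "))
  tbl <- tbl[tbl$variable %in% variables, ]
  if (nrow(tbl) == 0) stop("no rows for the requested variables")

  day_levels <- intersect(c("baseline", "0", "1", "55"),
                          unique(as.character(tbl$day)))
  if (!"baseline" %in% day_levels) stop("table must contain baseline day")
  if (length(day_levels) < 2) stop("need at least two days")

  w <- rm_wide(tbl, variables, day_levels)
  groups <- tbl$group[match(w$animals, tbl$animal)]
  group <- factor(as.character(groups))
  if (nlevels(group) != 2 || any(table(group) < 2))
    stop("need two groups with >= 2 animals each")
  contrasts(group) <- stats::contr.sum(2)

  n <- length(w$animals)
  p <- length(variables)
  d <- length(day_levels)

  # between-subject multivariate test on day-averaged variables
  Ybar <- sapply(w$wide, rowMeans)
  if (p >= n - 1)
    stop("singular cross-product matrix: too many variables for ", n, " animals")
  mv_between <- mv_rows(Ybar, group)

  # within-subject tests on day-minus-baseline contrasts
  D <- do.call(cbind, lapply(w$wide, function(m)
    m[, -1, drop = FALSE] - m[, 1]))
  if (ncol(D) >= n - 1)
    stop("singular cross-product matrix: too many day contrasts for ",
         n, " animals")
  mv_within <- mv_rows(D, group)

  multivariate <- rbind(
    mv_between[mv_between$effect == "group", ],
    within(mv_within[mv_within$effect == "(Intercept)", ], effect <- "day"),
    within(mv_within[mv_within$effect == "group", ], effect <- "group:day")
  )
  rownames(multivariate) <- NULL

  any_sig <- any(multivariate$p_value < alpha)
  out <- list(multivariate = multivariate,
              univariate = NULL, contrasts = NULL,
              gated = gate && !any_sig)
  if (out$gated) return(out)

  # univariate mixed-model follow-ups, Bonferroni over the variable family
  long <- tbl
  long$day <- factor(as.character(long$day), levels = day_levels)
  long$animal <- factor(long$animal)
  uni <- list()
  for (v in variables) {
    sub <- long[long$variable == v, ]
    fit <- stats::aov(value ~ group * day + Error(animal), data = sub)
    s <- summary(fit)
    between <- s[["Error: animal"]][[1]]
    within <- s[["Error: Within"]][[1]]
    grab <- function(tab, term, effect) {
      i <- grep(paste0("^", term, "\\s*$"), rownames(tab))
      data.frame(variable = v, effect = effect,
                 F = tab[i, "F value"], df1 = tab[i, "Df"],
                 df2 = tab[nrow(tab), "Df"], p_value = tab[i, "Pr(>F)"])
    }
    uni[[v]] <- rbind(grab(between, "group", "group"),
                      grab(within, "day", "day"),
                      grab(within, "group:day", "group:day"))
  }
  univariate <- do.call(rbind, uni)
  univariate$adjusted_alpha <- bonferroni_alpha(p, alpha)
  rownames(univariate) <- NULL

  # contrasts: day vs baseline within group; group difference per day
  ctr <- list()
  post_days <- day_levels[-1]
  a_day <- bonferroni_alpha(length(post_days) * nlevels(group), alpha)
  a_grp <- bonferroni_alpha(length(day_levels), alpha)
  for (v in variables) {
    m <- w$wide[[v]]
    for (g in levels(group)) {
      sel <- group == g
      for (dd in post_days) {
        tt <- stats::t.test(m[sel, dd], m[sel, "baseline"], paired = TRUE)
        ctr[[length(ctr) + 1]] <- data.frame(
          variable = v, contrast = paste0(g, ": day ", dd, " vs baseline"),
          statistic = unname(tt$statistic), df = unname(tt$parameter),
          p_value = tt$p.value, adjusted_alpha = a_day,
          significant = tt$p.value < a_day)
      }
    }
    for (dd in day_levels) {
      g1 <- m[group == levels(group)[1], dd]
      g2 <- m[group == levels(group)[2], dd]
      tt <- ttest_independent(g1, g2)
      ctr[[length(ctr) + 1]] <- data.frame(
        variable = v,
        contrast = paste0(levels(group)[1], " vs ", levels(group)[2],
                          ", day ", dd),
        statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
        adjusted_alpha = a_grp, significant = tt$p_value < a_grp)
    }
  }
  out$univariate <- univariate
  out$contrasts <- do.call(rbind, ctr)
  rownames(out$contrasts) <- NULL
  out
}
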