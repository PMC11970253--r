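# CGM-derived glycemic metrics: level, variability, time-in-ranges, MAGE
# (classical turning-point algorithm), estimated A1C, high blood glucose
# index, fasting/postprandial summaries, high-variance flagging, and
# autoregressive order selection.

#' Glycemic metric panel for one day profile
#'
#' Computes, over present slots: mean, SD, CV, time in/above/below range
#' (70-180 / >180 / <70 mg/dL, as fractions of present time), MAGE (mean
#' amplitude of excursions exceeding 1 SD between consecutive turning
#' points), estimated A1C `(mean + 46.7) / 28.7` (%), the high blood
#' glucose index, trapezoidal AUC, fasting-window SD, and the maximal
#' postprandial glycemic rate (peak rise over time-to-peak across meals,
#' mg/dL per minute).
#'
#' @param day A `cgm_day` with at least 10% of slots present.
#' @param meal_times Meal onsets in minutes of day (default
#'   07:30/12:30/18:30) used for the postprandial windows.
#' @param fasting_window Fasting window in minutes of day, default
#'   00:00-06:00.
#' @param postprandial_min Length of the postprandial window after each
#'   meal, minutes (default 120).
#' @return A one-row data.frame of class `cgm_metrics`.
#' @examples
#' m <- compute_metrics(day_profile(rep(100, 288)))
#' m$tir; m$mage
#' @export
compute_metrics <- function(day, meal_times = c(450, 750, 1110),
                            fasting_window = c(0, 360),
                            postprandial_min = 120) {
  stopifnot(inherits(day, "cgm_day"))
  n_present <- sum(day$present)
  if (n_present < 0.1 * N_SLOTS) {
    stop_glycodyn("insufficient coverage: ", n_present, "/", N_SLOTS,
                  " slots present (need >= 10%)",
                  class = "glycodyn_validation_error")
  }
  g <- day$values[day$present]
  tmin <- (which(day$present) - 1L) * SLOT_MIN
  mean_g <- mean(g)
  sd_g <- sd(g)
  if (is.na(sd_g)) sd_g <- 0
  tir <- mean(g > HYPO_MGDL - 1e-9 & g <= HYPER_MGDL)
  tar <- mean(g > HYPER_MGDL)
  tbr <- mean(g < HYPO_MGDL - 1e-9)

  fast_idx <- tmin >= fasting_window[1] & tmin < fasting_window[2]
  fasting_sd <- if (sum(fast_idx) >= 2) sd(g[fast_idx]) else NA_real_

  pp_rate <- max_postprandial_rate(day, meal_times, postprandial_min)

  data.frame(subject_id = day$subject_id, date = day$date,
             mean = mean_g, sd = sd_g,
             cv = if (mean_g > 0) sd_g / mean_g else NA_real_,
             tir = tir, tar = tar, tbr = tbr,
             mage = mage(day),
             ea1c = (mean_g + 46.7) / 28.7,
             hbgi = hbgi(g),
             auc = trapz_auc(tmin, g),
             fasting_sd = fasting_sd,
             postprandial_rate = pp_rate,
             stringsAsFactors = FALSE)
}

trapz_auc <- function(tmin, g) {
  if (length(g) < 2L) return(0)
  sum(diff(tmin) * (head(g, -1) + tail(g, -1)) / 2)
}

# High blood glucose index (risk-transform mean of hyperglycemic stress).
hbgi <- function(g) {
  f <- 1.509 * (log(g)^1.084 - 5.381)
  rh <- ifelse(f > 0, 10 * f^2, 0)
  mean(rh)
}

#' Mean amplitude of glycemic excursions (classical algorithm)
#'
#' Scans the present-slot series for turning points (strict local extrema
#' after collapsing flat runs), keeps excursions between consecutive
#' turning points whose absolute amplitude exceeds one within-day SD, and
#' returns their mean absolute amplitude (0 if none qualify).
#'
#' @param day A `cgm_day`.
#' @return Nonnegative scalar, mg/dL.
#' @export
mage <- function(day) {
  g <- day$values[day$present]
  if (length(g) < 3L) return(0)
  s <- sd(g)
  if (is.na(s) || s == 0) return(0)
  tp <- turning_points(g)
  if (length(tp) < 2L) return(0)
  amps <- abs(diff(g[tp]))
  amps <- amps[amps > s]
  if (!length(amps)) return(0)
  mean(amps)
}

# Indices of turning points (first, local extrema, last) of a series with
# flat runs collapsed to their first index.
turning_points <- function(g) {
  keep <- c(TRUE, diff(g) != 0)
  idx <- which(keep)
  x <- g[idx]
  n <- length(x)
  if (n < 3L) return(idx[c(1L, n)][!duplicated(c(1L, n))])
  d <- sign(diff(x))
  ext <- which(d[-1] != d[-(n - 1)]) + 1L
  idx[c(1L, ext, n)]
}

max_postprandial_rate <- function(day, meal_times, postprandial_min) {
  rates <- vapply(meal_times, function(mt) {
    slot0 <- snap_to_slot(mt)
    # pre-meal value: nearest present slot at or before the meal
    pre_idx <- max(which(day$present[seq_len(slot0)]), -Inf)
    if (!is.finite(pre_idx)) return(NA_real_)
    win <- seq(slot0, min(slot0 + postprandial_min / SLOT_MIN, N_SLOTS))
    win <- win[day$present[win]]
    if (length(win) < 2L) return(NA_real_)
    peak_slot <- win[which.max(day$values[win])]
    dt <- (peak_slot - pre_idx) * SLOT_MIN
    if (dt <= 0) return(NA_real_)
    (day$values[peak_slot] - day$values[pre_idx]) / dt
  }, 0)
  if (all(is.na(rates))) NA_real_ else max(rates, na.rm = TRUE)
}

#' Metric panels for a list of days
#'
#' @param days List of `cgm_day`.
#' @param ... Passed to [compute_metrics()].
#' @return A data.frame with one row per subject-day.
#' @export
cohort_metrics <- function(days, ...) {
  do.call(rbind, lapply(days, compute_metrics, ...))
}

#' Flag high-variance subjects (HV screening)
#'
#' Flags subjects whose fasting-window SD and postprandial glycemic rate
#' both exceed the configured cohort percentiles — the signature of
#' normal-glucose-tolerance individuals with unusually variable fasting
#' glucose and steep post-meal rises.
#'
#' @param metrics Data.frame from [cohort_metrics()] (>= 10 subjects).
#' @param thresholds Percentile thresholds `c(fasting_sd, rate)`,
#'   default both 0.75.
#' @return A data.frame: `subject_id`, `fasting_sd_pct`, `rate_pct`,
#'   `is_hv`.
#' @export
flag_hv <- function(metrics, thresholds = c(0.75, 0.75)) {
  agg <- stats::aggregate(
    metrics[, c("fasting_sd", "postprandial_rate")],
    by = list(subject_id = metrics$subject_id),
    FUN = function(x) mean(x, na.rm = TRUE))
  if (nrow(agg) < 10L) {
    stop_glycodyn("need >= 10 subjects to rank variability",
                  class = "glycodyn_validation_error")
  }
  pct <- function(x) (rank(x, ties.method = "average") - 0.5) / length(x)
  fs <- pct(agg$fasting_sd)
  rt <- pct(agg$postprandial_rate)
  out <- data.frame(subject_id = agg$subject_id,
                    fasting_sd_pct = fs, rate_pct = rt,
                    is_hv = fs > thresholds[1] & rt > thresholds[2],
                    stringsAsFactors = FALSE)
  out[order(out$subject_id), ]
}

#' Autoregressive order selection for a day profile
#'
#' Fits AR(p) models by conditional least squares for p = 1..`max_order`
#' on the 5-minute series and selects the order minimizing an information
#' criterion, using a common estimation sample (the first `max_order`
#' points are conditioned on for every candidate). BIC is the default:
#' on null (white-noise) days it keeps the selected order at 1-2 while
#' still recovering strong high-order structure; the laxer AICc/AIC are
#' config-exposed. The selected order is also reported in hours
#' (`order * 5 / 60`) — the memory span of the glucose dynamics.
#'
#' @param day A fully present `cgm_day` (missing slots are linearly
#'   interpolated first).
#' @param max_order Maximum candidate order (<= 72, i.e. 6 hours).
#' @param criterion `"bic"` (default), `"aicc"` or `"aic"`.
#' @return A list: `order`, `order_hours`, `criterion` values per order.
#' @export
ar_order_selection <- function(day, max_order = 24L,
                               criterion = c("bic", "aicc", "aic")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(day, "cgm_day"))
  check_scalar_number(max_order, "max_order", 1, 72)
  max_order <- as.integer(max_order)
  x <- day$values
  if (!all(day$present)) {
    x[!day$present] <- impute_linear(day, which(!day$present))
  }
  if (sd(x) < 1e-12) {
    warning("constant series: autoregressive order 0")
    return(list(order = 0L, order_hours = 0, criterion = NULL))
  }
  x <- x - mean(x)
  n_eff <- length(x) - max_order
  y <- x[(max_order + 1):length(x)]
  lagmat <- sapply(seq_len(max_order), function(j) {
    x[(max_order + 1 - j):(length(x) - j)]
  })
  crit <- vapply(seq_len(max_order), function(p) {
    X <- lagmat[, seq_len(p), drop = FALSE]
    fit <- stats::lm.fit(cbind(1, X), y)
    rss <- sum(fit$residuals^2)
    k <- p + 2  # coefficients + intercept + variance
    base <- n_eff * log(rss / n_eff)
    switch(criterion,
           bic = base + log(n_eff) * k,
           aicc = base + 2 * k + 2 * k * (k + 1) / pmax(n_eff - k - 1, 1),
           aic = base + 2 * k)
  }, 0)
  best <- which.min(crit)
  list(order = as.integer(best), order_hours = best * SLOT_MIN / 60,
       criterion = crit)
}
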