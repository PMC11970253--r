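# Synthetic CGM cohort simulator: circadian baseline, gamma-shaped meal
# excursions, AR(1) sensor noise, slot-wise missingness, and archetype
# parameterizations emulating normal / impaired-regulation / type-2-like
# glycemic states.

#' Archetype parameters for the synthetic CGM simulator
#'
#' Returns the generative parameters of one of the three built-in
#' archetypes. Defaults place the basal means at 95 (normal), 130
#' (IGR-like) and 180 (T2D-like) mg/dL so that the archetypes are
#' separable but overlapping.
#'
#' @param name One of `"normal"`, `"igr_like"`, `"t2d_like"`.
#' @param ... Named overrides of individual fields (`basal_mean`,
#'   `basal_amplitude`, `meal_peak_mean`, `meal_peak_sd`,
#'   `decay_halflife`, `noise_sd`, `noise_phi`, `missing_rate`).
#' @return A list of class `cgm_archetype`.
#' @examples
#' archetype_params("t2d_like")$basal_mean
#' @export
archetype_params <- function(name = c("normal", "igr_like", "t2d_like"),
                             ...) {
  name <- match.arg(name)
  p <- switch(name,
    normal = list(basal_mean = 95, basal_amplitude = 8,
                  meal_peak_mean = 55, meal_peak_sd = 10,
                  decay_halflife = 35, noise_sd = 5, noise_phi = 0.7,
                  missing_rate = 0.03),
    igr_like = list(basal_mean = 130, basal_amplitude = 10,
                    meal_peak_mean = 78, meal_peak_sd = 16,
                    decay_halflife = 55, noise_sd = 7, noise_phi = 0.7,
                    missing_rate = 0.03),
    t2d_like = list(basal_mean = 180, basal_amplitude = 12,
                    meal_peak_mean = 88, meal_peak_sd = 22,
                    decay_halflife = 75, noise_sd = 10, noise_phi = 0.75,
                    missing_rate = 0.05))
  p$name <- name
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) {
    stop_glycodyn("unknown archetype fields: ",
                  paste(unknown, collapse = ", "),
                  class = "glycodyn_validation_error")
  }
  p[names(over)] <- over
  validate_archetype(p)
  structure(p, class = "cgm_archetype")
}

validate_archetype <- function(p) {
  check_scalar_number(p$basal_mean, "basal_mean", 60, 250)
  check_scalar_number(p$basal_amplitude, "basal_amplitude", 0, Inf)
  check_scalar_number(p$meal_peak_mean, "meal_peak_mean", 0, Inf)
  check_scalar_number(p$meal_peak_sd, "meal_peak_sd", 0, Inf)
  check_scalar_number(p$decay_halflife, "decay_halflife", 1, Inf)
  check_scalar_number(p$noise_sd, "noise_sd", 0, Inf)
  check_scalar_number(p$noise_phi, "noise_phi", 0, 1 - 1e-12)
  check_scalar_number(p$missing_rate, "missing_rate", 0, 0.5)
  invisible(p)
}

# Peak-normalized gamma-shaped (shape 2) meal response kernel.
# k(u) = (u/theta) exp(1 - u/theta) for u >= 0; peak 1 at u = theta;
# tail half-life = decay_halflife (theta = halflife / ln 2).
meal_kernel <- function(minutes_since_meal, decay_halflife) {
  theta <- decay_halflife / log(2)
  u <- pmax(minutes_since_meal, 0)
  ifelse(minutes_since_meal < 0, 0, (u / theta) * exp(1 - u / theta))
}

# Circadian acrophase: minute-of-day at which sin() peaks (16:00), giving
# a nadir near 04:00.
CIRCADIAN_T0 <- 600

#' Simulate one subject-day of CGM data
#'
#' Generates a 288-slot glucose profile as circadian sinusoid + meal
#' excursions + AR(1) sensor noise, clipped to `[40, 300]` mg/dL, with
#' i.i.d. slot missingness, plus a nutrition descriptor per meal.
#'
#' @param params A `cgm_archetype` from [archetype_params()].
#' @param meal_times Strictly increasing meal onsets, minutes of day in
#'   `[0, 1440)`.
#' @param subject_id,date Identifiers stamped on the profile.
#' @param gap Optional contiguous missing gap, `c(start_slot, length)` in
#'   slots, or `NULL`.
#' @return A list with `day` (a `cgm_day`) and `meals` (a data.frame of
#'   meal descriptors: `minute`, `kcal`, `carb_g`, `protein_g`, `fat_g`,
#'   `fiber_g`).
#' @examples
#' p <- archetype_params("normal", noise_sd = 0, missing_rate = 0)
#' sim <- simulate_day(p, meal_times = c(450, 750, 1110))
#' range(sim$day$values)
#' @export
simulate_day <- function(params, meal_times = c(450, 750, 1110),
                         subject_id = "s1", date = "2020-01-01",
                         gap = NULL) {
  validate_archetype(params)
  if (length(meal_times)) {
    if (any(meal_times < 0 | meal_times >= 1440)) {
      stop_glycodyn("meal times must lie in [0, 1440) minutes, got ",
                    paste(round(meal_times, 1), collapse = ", "),
                    class = "glycodyn_validation_error")
    }
    if (is.unsorted(meal_times, strictly = TRUE)) {
      stop_glycodyn("meal times must be strictly increasing",
                    class = "glycodyn_validation_error")
    }
  }
  tmin <- (seq_len(N_SLOTS) - 1L) * SLOT_MIN
  g <- params$basal_mean +
    params$basal_amplitude * sin(2 * pi * (tmin - CIRCADIAN_T0) / 1440)

  meals <- NULL
  if (length(meal_times)) {
    peaks <- pmax(rnorm(length(meal_times), params$meal_peak_mean,
                        params$meal_peak_sd), 0)
    for (i in seq_along(meal_times)) {
      g <- g + peaks[i] * meal_kernel(tmin - meal_times[i],
                                      params$decay_halflife)
    }
    meals <- draw_meal_descriptors(meal_times)
  }

  if (params$noise_sd > 0) {
    # stationary AR(1): marginal SD = noise_sd, innovation SD scaled down
    innov_sd <- params$noise_sd * sqrt(1 - params$noise_phi^2)
    n0 <- rnorm(1, 0, params$noise_sd)
    eps <- rnorm(N_SLOTS - 1L, 0, innov_sd)
    rest <- as.numeric(stats::filter(eps, params$noise_phi,
                                     method = "recursive", init = n0))
    g <- g + c(n0, rest)
  }
  g <- pmin(pmax(g, GLUCOSE_MIN), GLUCOSE_MAX)

  miss <- rep(FALSE, N_SLOTS)
  if (params$missing_rate > 0) {
    miss <- runif(N_SLOTS) < params$missing_rate
  }
  if (!is.null(gap)) {
    stopifnot(length(gap) == 2L)
    idx <- seq(gap[1L], min(gap[1L] + gap[2L] - 1L, N_SLOTS))
    miss[idx] <- TRUE
  }
  g[miss] <- NA_real_

  list(day = day_profile(g, subject_id = subject_id, date = date),
       meals = meals)
}

# Meal kcal in [300, 900]; macronutrient grams follow 4/4/9 kcal/g energy
# densities for carbohydrate/protein/fat within +-10%, fiber 2-10 g.
draw_meal_descriptors <- function(meal_times) {
  n <- length(meal_times)
  kcal <- runif(n, 300, 900)
  ratios <- matrix(runif(3 * n, c(0.40, 0.15, 0.20), c(0.60, 0.30, 0.40)),
                   nrow = n, byrow = TRUE)
  ratios <- ratios / rowSums(ratios)
  jitter <- function(n) runif(n, 0.9, 1.1)
  data.frame(minute = meal_times,
             kcal = kcal,
             carb_g = kcal * ratios[, 1] / 4 * jitter(n),
             protein_g = kcal * ratios[, 2] / 4 * jitter(n),
             fat_g = kcal * ratios[, 3] / 9 * jitter(n),
             fiber_g = runif(n, 2, 10))
}

#' Simulate a labeled synthetic CGM cohort
#'
#' Draws `n_subjects` subjects per archetype, each with its own parameter
#' perturbation around the archetype means, and `days_per_subject` days
#' per subject. Meal times default to 07:30/12:30/18:30 with +-30 min
#' jitter per day. Fully deterministic given `seed`.
#'
#' @param n_subjects Subjects per archetype (>= 1).
#' @param days_per_subject Days per subject (>= 1).
#' @param seed Integer seed.
#' @param archetypes Character vector of archetype names to include.
#' @param gap_prob Probability that a day carries one contiguous missing
#'   gap of 1-2 hours (exercises PAD handling).
#' @return A list of class `cgm_cohort`: `days` (list of `cgm_day`),
#'   `labels` (named character vector subject -> archetype), `meal_log`
#'   (data.frame), `subject_params` (per-subject draws), `seed`.
#' @examples
#' co <- simulate_cohort(2, 2, seed = 1)
#' length(co$days)
#' @export
simulate_cohort <- function(n_subjects, days_per_subject, seed = 1L,
                            archetypes = c("normal", "igr_like", "t2d_like"),
                            gap_prob = 0.3) {
  check_scalar_number(n_subjects, "n_subjects", lower = 1)
  check_scalar_number(days_per_subject, "days_per_subject", lower = 1)
  with_rng_seed(seed, {
    days <- list()
    labels <- character(0)
    meal_rows <- list()
    subject_params <- list()
    for (arch in archetypes) {
      base <- archetype_params(arch)
      for (i in seq_len(n_subjects)) {
        sid <- sprintf("%s_%03d", arch, i)
        p <- base
        p$basal_mean <- min(max(rnorm(1, base$basal_mean, 6), 60), 250)
        p$meal_peak_mean <- max(rnorm(1, base$meal_peak_mean, 8), 5)
        p$decay_halflife <- max(rnorm(1, base$decay_halflife, 8), 10)
        p$noise_sd <- max(rnorm(1, base$noise_sd, 1), 0.5)
        subject_params[[sid]] <- p
        labels[sid] <- arch
        for (d in seq_len(days_per_subject)) {
          date <- format(as.Date("2020-01-01") + (d - 1L), "%Y-%m-%d")
          mt <- sort(round(c(450, 750, 1110) + runif(3, -30, 30)))
          gap <- NULL
          if (runif(1) < gap_prob) {
            gap <- c(sample.int(N_SLOTS - 24L, 1L), sample(12:24, 1L))
          }
          sim <- simulate_day(p, meal_times = mt, subject_id = sid,
                              date = date, gap = gap)
          days[[length(days) + 1L]] <- sim$day
          m <- sim$meals
          m$subject_id <- sid
          m$timestamp <- paste0(date, "T", fmt_time_of_day(m$minute))
          meal_rows[[length(meal_rows) + 1L]] <- m
        }
      }
    }
    meal_log <- do.call(rbind, meal_rows)
    meal_log <- meal_log[, c("subject_id", "timestamp", "minute", "kcal",
                             "carb_g", "protein_g", "fat_g", "fiber_g")]
    structure(list(days = days, labels = labels, meal_log = meal_log,
                   subject_params = subject_params, seed = seed),
              class = "cgm_cohort")
  })
}

#' @export
print.cgm_cohort <- function(x, ...) {
  cat(sprintf("<cgm_cohort> %d days, %d subjects (%s), seed %d\n",
              length(x$days), length(x$labels),
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = ", "), x$seed))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits the CGM CSV dialect, a label table (`subject_id,label`) and the
#' meal log.
#'
#' @param cohort A `cgm_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cgm_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cgm_path <- file.path(dir, "cgm.csv")
  lab_path <- file.path(dir, "labels.csv")
  meal_path <- file.path(dir, "meals.csv")
  write_cgm_csv(cohort$days, cgm_path)
  write.csv(data.frame(subject_id = names(cohort$labels),
                       label = unname(cohort$labels)),
            lab_path, row.names = FALSE, quote = FALSE)
  ml <- cohort$meal_log
  ml$minute <- NULL
  write.csv(ml, meal_path, row.names = FALSE, quote = FALSE)
  invisible(c(cgm = cgm_path, labels = lab_path, meals = meal_path))
}
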