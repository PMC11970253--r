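# Parsing of CGM and meal CSVs, day segmentation onto the 5-minute grid,
# clipping to the physiological range, and missingness handling.

#' Construct a single-day CGM profile
#'
#' A day profile holds one subject-day of glucose values on the fixed
#' 288-slot 5-minute grid (00:00 to 23:55), with a logical mask marking
#' which slots carry a measurement. Present values must lie in the clipped
#' physiological range of 40 to 300 mg/dL.
#'
#' @param values Numeric vector of length 288; `NA` at missing slots.
#' @param subject_id Subject identifier string.
#' @param date Calendar date string (`"YYYY-MM-DD"`).
#' @param clip If `TRUE`, clip present values into `[40, 300]` instead of
#'   rejecting out-of-range input.
#' @return An object of class `cgm_day` with fields `subject_id`, `date`,
#'   `values` and `present`.
#' @examples
#' d <- day_profile(rep(100, 288))
#' sum(d$present)
#' @export
day_profile <- function(values, subject_id = "s1", date = "2020-01-01",
                        clip = FALSE) {
  if (length(values) != N_SLOTS) {
    stop_glycodyn("a day profile must have exactly ", N_SLOTS,
                  " slots, got ", length(values),
                  class = "glycodyn_validation_error")
  }
  values <- as.numeric(values)
  present <- !is.na(values)
  if (clip) {
    values[present] <- pmin(pmax(values[present], GLUCOSE_MIN), GLUCOSE_MAX)
  }
  bad <- present & (values < GLUCOSE_MIN | values > GLUCOSE_MAX)
  if (any(bad)) {
    stop_glycodyn("present glucose values must lie in [", GLUCOSE_MIN, ", ",
                  GLUCOSE_MAX, "] mg/dL (", sum(bad), " violations); ",
                  "use clip = TRUE to clip",
                  class = "glycodyn_validation_error")
  }
  structure(list(subject_id = as.character(subject_id),
                 date = as.character(date),
                 values = values,
                 present = present),
            class = "cgm_day")
}

#' @export
print.cgm_day <- function(x, ...) {
  cat(sprintf("<cgm_day> %s %s: %d/%d slots present, mean %.1f mg/dL\n",
              x$subject_id, x$date, sum(x$present), N_SLOTS,
              mean(x$values[x$present])))
  invisible(x)
}

#' Parse a long-format CGM CSV
#'
#' Reads the package CSV dialect with header
#' `subject_id,timestamp,glucose_mg_dl` (ISO-8601 timestamps, one row per
#' measurement) into per-subject records. Rows are sorted by time within
#' subject; duplicate timestamps are collapsed by their mean.
#'
#' @param path Path to the CSV file.
#' @return A named list of `cgm_record` objects, one per subject, each with
#'   fields `subject_id`, `time` (POSIXct) and `glucose`.
#' @export
parse_cgm_csv <- function(path) {
  if (!file.exists(path)) {
    stop_glycodyn("CGM file not found: ", path,
                  class = "glycodyn_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("subject_id", "timestamp", "glucose_mg_dl")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_glycodyn("CGM CSV header must contain ",
                  paste(required, collapse = ","), "; missing: ",
                  paste(missing_cols, collapse = ","),
                  class = "glycodyn_io_error")
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning("ignoring unknown CGM columns: ", paste(extra, collapse = ", "))
  }
  tm <- parse_iso_timestamp(df$timestamp)
  if (anyNA(tm)) {
    bad <- which(is.na(tm))[1L]
    stop_glycodyn("malformed timestamp at data row ", bad, ": '",
                  df$timestamp[bad], "'", class = "glycodyn_io_error")
  }
  gl <- suppressWarnings(as.numeric(df$glucose_mg_dl))
  if (anyNA(gl)) {
    bad <- which(is.na(gl))[1L]
    stop_glycodyn("malformed glucose value at data row ", bad, ": '",
                  df$glucose_mg_dl[bad], "'", class = "glycodyn_io_error")
  }
  out <- lapply(split(seq_len(nrow(df)), df$subject_id), function(idx) {
    t_i <- tm[idx]; g_i <- gl[idx]
    o <- order(t_i)
    t_i <- t_i[o]; g_i <- g_i[o]
    # collapse duplicate timestamps by mean
    key <- format(t_i, "%Y-%m-%d %H:%M:%S")
    if (anyDuplicated(key)) {
      g_i <- as.numeric(tapply(g_i, factor(key, levels = unique(key)), mean))
      t_i <- t_i[!duplicated(key)]
    }
    structure(list(subject_id = df$subject_id[idx[1L]],
                   time = t_i, glucose = g_i),
              class = "cgm_record")
  })
  out[order(names(out))]
}

parse_iso_timestamp <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  tm <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  retry <- is.na(tm)
  if (any(retry)) {
    tm[retry] <- as.POSIXct(strptime(x[retry], "%Y-%m-%d %H:%M",
                                     tz = "UTC"))
  }
  tm
}

#' Split a CGM record into day profiles on the 5-minute grid
#'
#' Segments a record into calendar days (00:00 to 23:59). The first and
#' last calendar days of the record are dropped as incomplete edge days.
#' Remaining samples are snapped to the nearest 5-minute slot (ties to the
#' earlier slot), multiple samples in one slot are averaged, slots without
#' a measurement are masked missing, and values are clipped to
#' `[40, 300]` mg/dL.
#'
#' @param record A `cgm_record` from [parse_cgm_csv()].
#' @param drop_edge_days Drop the first and last calendar day (default
#'   `TRUE`, the preprocessing rule). Set `FALSE` to grid every day, e.g.
#'   for round-trip checks on synthetic data.
#' @return A list of `cgm_day` profiles (possibly empty). A record spanning
#'   fewer than three calendar days yields an empty list with a message.
#' @export
split_days <- function(record, drop_edge_days = TRUE) {
  stopifnot(inherits(record, "cgm_record"))
  if (length(record$time) == 0L) {
    stop_glycodyn("empty CGM record", class = "glycodyn_validation_error")
  }
  dates <- format(record$time, "%Y-%m-%d")
  udates <- sort(unique(dates))
  if (drop_edge_days) {
    if (length(udates) < 3L) {
      message("record for ", record$subject_id, " spans ", length(udates),
              " calendar day(s); no complete interior days")
      return(list())
    }
    udates <- udates[-c(1L, length(udates))]
  }
  lapply(udates, function(d) {
    idx <- which(dates == d)
    mins <- as.numeric(record$time[idx]) / 60
    mod <- mins - floor(mins / 1440) * 1440  # minutes of day
    slot <- snap_to_slot(mod)
    vals <- rep(NA_real_, N_SLOTS)
    g <- pmin(pmax(record$glucose[idx], GLUCOSE_MIN), GLUCOSE_MAX)
    agg <- tapply(g, slot, mean)
    vals[as.integer(names(agg))] <- as.numeric(agg)
    day_profile(vals, subject_id = record$subject_id, date = d)
  })
}

# Nearest 5-minute slot (1-based), ties to the earlier slot; the last slot
# (23:55) absorbs the tail of the day.
snap_to_slot <- function(minutes_of_day) {
  k <- floor(minutes_of_day / SLOT_MIN)
  r <- minutes_of_day - k * SLOT_MIN
  k <- ifelse(r > SLOT_MIN / 2, k + 1, k)
  as.integer(pmin(k, N_SLOTS - 1L)) + 1L
}

#' Downsample a day profile to a coarser measurement interval
#'
#' Emulates devices with sparser sampling (e.g. 15-minute flash monitors)
#' by keeping every `interval/5`-th slot and masking the rest. The grid
#' length stays 288.
#'
#' @param day A `cgm_day`.
#' @param interval Target interval in minutes; positive multiple of 5.
#' @return A `cgm_day` with the coarser mask.
#' @export
downsample_day <- function(day, interval) {
  stopifnot(inherits(day, "cgm_day"))
  check_scalar_number(interval, "interval", lower = 5)
  if (interval %% SLOT_MIN != 0) {
    stop_glycodyn("interval must be a positive multiple of ", SLOT_MIN,
                  " minutes, got ", interval,
                  class = "glycodyn_validation_error")
  }
  step <- as.integer(interval / SLOT_MIN)
  keep <- ((seq_len(N_SLOTS) - 1L) %% step) == 0L
  vals <- day$values
  vals[!keep] <- NA_real_
  day_profile(vals, subject_id = day$subject_id, date = day$date)
}

#' Write day profiles to the CGM CSV dialect
#'
#' @param days List of `cgm_day` profiles.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(days, path) {
  rows <- lapply(days, function(d) {
    idx <- which(d$present)
    if (!length(idx)) return(NULL)
    data.frame(subject_id = d$subject_id,
               timestamp = paste0(d$date, "T",
                                  fmt_time_of_day((idx - 1L) * SLOT_MIN)),
               glucose_mg_dl = d$values[idx],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse a subject label CSV (`subject_id,label`)
#'
#' @param path CSV path.
#' @return Named character vector of labels keyed by subject id.
#' @export
parse_label_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(df))) {
    stop_glycodyn("label CSV must have header subject_id,label",
                  class = "glycodyn_io_error")
  }
  setNames(as.character(df$label), as.character(df$subject_id))
}

#' Parse a meal-log CSV
#'
#' Dialect: `subject_id,timestamp,kcal,carb_g,protein_g,fat_g,fiber_g`.
#'
#' @param path CSV path.
#' @return A data.frame with parsed timestamps (`time`, POSIXct).
#' @export
parse_meal_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "timestamp", "kcal", "carb_g", "protein_g",
                "fat_g", "fiber_g")
  if (!all(required %in% names(df))) {
    stop_glycodyn("meal CSV must have header ",
                  paste(required, collapse = ","),
                  class = "glycodyn_io_error")
  }
  df$time <- parse_iso_timestamp(df$timestamp)
  if (anyNA(df$time)) {
    stop_glycodyn("malformed meal timestamp at data row ",
                  which(is.na(df$time))[1L], class = "glycodyn_io_error")
  }
  df
}
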