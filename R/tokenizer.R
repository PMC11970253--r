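# Glucose tokenization over a fixed 260-level vocabulary and
# TF-IDF-weighted mask planning for masked-token pretraining.

#' The glucose token vocabulary
#'
#' Glucose in the clipped range `[40, 300]` mg/dL is discretized into 260
#' one-mg/dL levels. The clipped range contains 261 integers; the top value
#' 300 shares the top bin with 299, so bin `i` (1-based) covers level
#' `40 + i - 1` and the representative (lower-edge) level of the top bin
#' is 299. Three special tokens follow the glucose ids: `PAD` (missing
#' slot), `CLS` (sequence head) and `MASK`.
#'
#' @return A list of class `cgm_vocab` with fields `n_glucose` (260),
#'   `size` (263), special ids `pad`, `cls`, `mask`, and `levels`
#'   (representative mg/dL level of each glucose id).
#' @examples
#' v <- token_vocabulary()
#' v$size
#' @export
token_vocabulary <- function() {
  n <- 260L
  structure(list(n_glucose = n,
                 size = n + 3L,
                 pad = n + 1L,
                 cls = n + 2L,
                 mask = n + 3L,
                 levels = seq.int(40L, 299L)),
            class = "cgm_vocab")
}

#' Map glucose values (mg/dL) to glucose token ids
#'
#' @param glucose Numeric vector in `[40, 300]`.
#' @param vocab A `cgm_vocab`.
#' @return Integer token ids in `1..260`.
#' @export
glucose_to_id <- function(glucose, vocab = token_vocabulary()) {
  if (any(glucose < GLUCOSE_MIN | glucose > GLUCOSE_MAX, na.rm = TRUE)) {
    stop_glycodyn("glucose outside the clipped range [", GLUCOSE_MIN, ", ",
                  GLUCOSE_MAX, "]", class = "glycodyn_validation_error")
  }
  id <- as.integer(floor(glucose)) - 40L + 1L
  pmin(id, vocab$n_glucose)  # 300 mg/dL shares the top (299) bin
}

#' Map glucose token ids back to representative levels (bin lower edge)
#'
#' @param id Integer glucose token ids in `1..260`.
#' @param vocab A `cgm_vocab`.
#' @return Numeric mg/dL levels.
#' @export
id_to_glucose <- function(id, vocab = token_vocabulary()) {
  if (any(id < 1L | id > vocab$n_glucose)) {
    stop_glycodyn("id outside the glucose token range 1..", vocab$n_glucose,
                  class = "glycodyn_validation_error")
  }
  vocab$levels[id]
}

#' Tokenize a day profile into the 289-token sequence
#'
#' Prepends a `CLS` token, maps present slots to glucose tokens and
#' missing slots to `PAD`, giving a sequence of length 289 ordered by
#' time.
#'
#' @param day A `cgm_day`.
#' @param vocab A `cgm_vocab`.
#' @return A list of class `cgm_tokens` with `ids` (integer length 289),
#'   `subject_id`, `date`.
#' @examples
#' seq <- tokenize_day(day_profile(rep(100, 288)))
#' length(seq$ids)
#' @export
tokenize_day <- function(day, vocab = token_vocabulary()) {
  stopifnot(inherits(day, "cgm_day"))
  ids <- rep(vocab$pad, N_SLOTS)
  ids[day$present] <- glucose_to_id(day$values[day$present], vocab)
  structure(list(ids = c(vocab$cls, ids),
                 subject_id = day$subject_id,
                 date = day$date),
            class = "cgm_tokens")
}

#' Reconstruct a day profile from a token sequence
#'
#' Glucose tokens map to their bin's representative level (the lower bin
#' edge; 300 mg/dL round-trips to 299); `PAD` maps to missing.
#'
#' @param seq A `cgm_tokens` sequence.
#' @param vocab A `cgm_vocab`.
#' @return A `cgm_day`.
#' @export
detokenize <- function(seq, vocab = token_vocabulary()) {
  stopifnot(inherits(seq, "cgm_tokens"))
  ids <- seq$ids
  if (length(ids) != N_SLOTS + 1L || ids[1L] != vocab$cls) {
    stop_glycodyn("token sequence must have length 289 with CLS first",
                  class = "glycodyn_validation_error")
  }
  body <- ids[-1L]
  if (any(body > vocab$size | body < 1L | body == vocab$cls |
            body == vocab$mask)) {
    stop_glycodyn("unknown or non-decodable token id in sequence body",
                  class = "glycodyn_validation_error")
  }
  vals <- rep(NA_real_, N_SLOTS)
  is_g <- body <= vocab$n_glucose
  vals[is_g] <- id_to_glucose(body[is_g], vocab)
  day_profile(vals, subject_id = seq$subject_id, date = seq$date)
}

#' TF-IDF weights for adaptive masking
#'
#' Computes per-day, per-position masking weights: term frequency of the
#' token within the day times smoothed inverse document frequency across
#' the corpus (`idf = ln((1 + N) / (1 + df)) + 1`). Tokens encoding
#' abnormal glycemia (hyperglycemia, level > 180 mg/dL; hypoglycemia,
#' level < 70 mg/dL) are boosted by `abnormal_boost` so the model is asked
#' about them more often. `CLS` and `PAD` positions get weight 0.
#'
#' @param corpus Non-empty list of `cgm_tokens`.
#' @param vocab A `cgm_vocab`.
#' @param abnormal_boost Multiplier for hypo/hyperglycemia token weights
#'   (default 2; a stand-in, configuration-exposed).
#' @return A list with `position_weights` (list of length-289 numeric
#'   vectors aligned to each sequence) and `idf` (per-glucose-token idf).
#' @export
tfidf_token_weights <- function(corpus, vocab = token_vocabulary(),
                                abnormal_boost = 2) {
  if (!length(corpus)) {
    stop_glycodyn("corpus must be non-empty",
                  class = "glycodyn_validation_error")
  }
  check_scalar_number(abnormal_boost, "abnormal_boost", lower = 0)
  n_doc <- length(corpus)
  df <- integer(vocab$n_glucose)
  for (s in corpus) {
    g <- unique(s$ids[s$ids <= vocab$n_glucose])
    df[g] <- df[g] + 1L
  }
  idf <- log((1 + n_doc) / (1 + df)) + 1
  boost <- rep(1, vocab$n_glucose)
  boost[vocab$levels > HYPER_MGDL | vocab$levels < HYPO_MGDL] <-
    abnormal_boost
  position_weights <- lapply(corpus, function(s) {
    w <- numeric(length(s$ids))
    is_g <- s$ids <= vocab$n_glucose
    gids <- s$ids[is_g]
    tf <- tabulate(gids, nbins = vocab$n_glucose)
    w[is_g] <- tf[gids] * idf[gids] * boost[gids]
    w
  })
  list(position_weights = position_weights, idf = idf, boost = boost)
}

#' Mask a token sequence for pretraining
#'
#' Draws a target masking fraction uniformly from `fraction_range`, then
#' samples that share of the maskable (non-`PAD`, non-`CLS`) positions
#' without replacement with probability proportional to the supplied
#' weights, and replaces them with the `MASK` token. The plan records the
#' ground truth for the loss.
#'
#' @param seq A `cgm_tokens` sequence.
#' @param weights Length-289 nonnegative weights (e.g. one element of
#'   `tfidf_token_weights()$position_weights`); `NULL` for uniform.
#' @param fraction_range Two-element range within `[0, 1]`; default the
#'   pretraining range `c(0.45, 0.60)`.
#' @param vocab A `cgm_vocab`.
#' @param gap_prob Probability that part of the masked budget is spent on
#'   one contiguous run of `gap_len` slots (device-dropout realism; the
#'   realized masked fraction still falls in `fraction_range`). Default 0:
#'   pure weighted random masking.
#' @param gap_len Length of the contiguous run, in slots.
#' @return A list with `masked` (a `cgm_tokens` with `MASK` substituted)
#'   and `plan` (class `cgm_mask_plan`: `positions`, `target_ids`,
#'   `mask_fraction`).
#' @export
apply_masking <- function(seq, weights = NULL,
                          fraction_range = c(0.45, 0.60),
                          vocab = token_vocabulary(),
                          gap_prob = 0, gap_len = 12L) {
  stopifnot(inherits(seq, "cgm_tokens"))
  if (length(fraction_range) != 2L || any(!is.finite(fraction_range)) ||
      any(fraction_range < 0) || any(fraction_range > 1) ||
      fraction_range[1] > fraction_range[2]) {
    stop_glycodyn("fraction_range must be an increasing pair within [0, 1]",
                  class = "glycodyn_validation_error")
  }
  ids <- seq$ids
  maskable <- which(ids != vocab$pad & ids != vocab$cls)
  if (!length(maskable)) {
    stop_glycodyn("no maskable (non-PAD) position in sequence",
                  class = "glycodyn_validation_error")
  }
  if (is.null(weights)) {
    w <- rep(1, length(maskable))
  } else {
    stopifnot(length(weights) == length(ids))
    w <- weights[maskable]
    if (any(w < 0) || any(!is.finite(w))) {
      stop_glycodyn("weights must be finite and nonnegative",
                    class = "glycodyn_validation_error")
    }
    if (all(w == 0)) w <- rep(1, length(maskable))
  }
  frac <- runif(1, fraction_range[1], fraction_range[2])
  n_mask <- round(frac * length(maskable))
  forced <- integer(0)
  if (n_mask > gap_len && gap_prob > 0 && runif(1) < gap_prob) {
    # spend part of the budget on one contiguous run of slots
    start <- sample.int(length(maskable) - gap_len + 1L, 1L)
    forced <- maskable[start:(start + gap_len - 1L)]
  }
  n_rest <- n_mask - length(forced)
  if (n_rest > 0) {
    free <- setdiff(maskable, forced)
    wf <- w[match(free, maskable)]
    if (all(wf == 0)) wf <- rep(1, length(free))
    pos <- sort(c(forced, free[sample.int(length(free), n_rest,
                                          prob = wf)]))
  } else {
    pos <- sort(forced)
  }
  masked <- seq
  masked$ids[pos] <- vocab$mask
  plan <- structure(list(positions = pos,
                         target_ids = ids[pos],
                         mask_fraction = length(pos) / length(maskable)),
                    class = "cgm_mask_plan")
  list(masked = masked, plan = plan)
}

#' Serialize the vocabulary as JSON
#'
#' Writes the id-to-level table and the special-token ids, so external
#' tools can interpret token sequences.
#'
#' @param vocab A `cgm_vocab`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_vocab_json <- function(vocab = token_vocabulary(), path) {
  jsonlite::write_json(
    list(n_glucose = vocab$n_glucose, size = vocab$size,
         special = list(pad = vocab$pad, cls = vocab$cls,
                        mask = vocab$mask),
         table = data.frame(id = seq_len(vocab$n_glucose),
                            level_mg_dl = vocab$levels)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a vocabulary serialized by [write_vocab_json()]
#'
#' @param path JSON path.
#' @return A `cgm_vocab`.
#' @export
read_vocab_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- token_vocabulary()
  if (!identical(as.integer(j$n_glucose), v$n_glucose) ||
      !identical(as.integer(j$size), v$size)) {
    stop_glycodyn("vocabulary file does not match the fixed 260-level, ",
                  "3-special-token scheme", class = "glycodyn_io_error")
  }
  v
}
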