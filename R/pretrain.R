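# Self-supervised pretraining and the masked-imputation benchmark against
# linear-interpolation and KNN baselines, stratified by glycemic range.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Pretraining run configuration
#'
#' @param epochs Training epochs.
#' @param batch_size Sequences per optimizer step.
#' @param learning_rate Adam step size.
#' @param warmup_steps Linear learning-rate warmup steps.
#' @param lr_schedule `"cosine"` (decay to ~0 over the run after warmup)
#'   or `"constant"`.
#' @param fraction_range Masked fraction range per sequence.
#' @param val_fraction Share of the corpus held out for validation.
#' @param abnormal_boost TF-IDF boost for hypo/hyperglycemia tokens.
#' @param gap_prob Per-sequence probability that part of the masked
#'   budget forms one contiguous `gap_len`-slot run (teaches the model
#'   device-dropout gap filling; realized fraction stays in range).
#' @param gap_len Contiguous-run length in slots (12 = 1 hour).
#' @param seed Run seed (masking, shuffling).
#' @return A list of class `cgm_pretrain_config`.
#' @export
pretrain_config <- function(epochs = 3L, batch_size = 8L,
                            learning_rate = 2.5e-3, warmup_steps = 100L,
                            lr_schedule = c("cosine", "constant"),
                            fraction_range = c(0.45, 0.60),
                            val_fraction = 0.1, abnormal_boost = 2,
                            gap_prob = 0.5, gap_len = 12L,
                            seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  check_scalar_number(epochs, "epochs", lower = 1)
  check_scalar_number(batch_size, "batch_size", lower = 1)
  check_scalar_number(learning_rate, "learning_rate", lower = 1e-12)
  check_scalar_number(val_fraction, "val_fraction", 0, 0.9)
  if (any(fraction_range <= 0) || any(fraction_range > 1)) {
    stop_glycodyn("fraction_range must lie within (0, 1]",
                  class = "glycodyn_validation_error")
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 warmup_steps = as.integer(warmup_steps),
                 lr_schedule = lr_schedule,
                 fraction_range = fraction_range,
                 val_fraction = val_fraction,
                 abnormal_boost = abnormal_boost,
                 gap_prob = gap_prob, gap_len = as.integer(gap_len),
                 seed = as.integer(seed)),
            class = "cgm_pretrain_config")
}

draw_batch_masks <- function(seqs, weights, fraction_range, vocab,
                             gap_prob = 0, gap_len = 12L) {
  plans <- vector("list", length(seqs))
  masked <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    mk <- apply_masking(seqs[[i]], weights[[i]], fraction_range, vocab,
                        gap_prob = gap_prob, gap_len = gap_len)
    plans[[i]] <- mk$plan
    masked[[i]] <- mk$masked
  }
  list(masked = masked, plans = plans)
}

#' Masked-token pretraining loop
#'
#' Pretrains the encoder with TF-IDF-weighted masking and Adam (linear
#' warmup), logging per-epoch training and validation loss and retaining
#' the best-validation weights. Fully deterministic given the run seed.
#'
#' @param corpus List of `cgm_tokens` (unmasked).
#' @param run_config A `cgm_pretrain_config`.
#' @param checkpoint Starting `cgm_checkpoint`; default fresh
#'   initialization with the default architecture.
#' @param vocab A `cgm_vocab`.
#' @param verbose Print per-epoch losses.
#' @return A `cgm_checkpoint` whose `history` holds the loss trajectory
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
pretrain <- function(corpus, run_config = pretrain_config(),
                     checkpoint = NULL, vocab = token_vocabulary(),
                     verbose = FALSE) {
  stopifnot(inherits(run_config, "cgm_pretrain_config"))
  if (is.null(checkpoint)) checkpoint <- init_encoder(encoder_config())
  if (length(corpus) < run_config$batch_size) {
    stop_glycodyn("corpus smaller than one batch",
                  class = "glycodyn_validation_error")
  }
  tw <- tfidf_token_weights(corpus, vocab, run_config$abnormal_boost)
  with_rng_seed(run_config$seed, {
    n <- length(corpus)
    n_val <- max(0L, round(run_config$val_fraction * n))
    idx <- sample.int(n)
    val_idx <- head(idx, n_val)
    train_idx <- setdiff(idx, val_idx)
    # fixed validation masks for comparable epoch-to-epoch losses
    val_masks <- if (n_val > 0) {
      draw_batch_masks(corpus[val_idx], tw$position_weights[val_idx],
                       run_config$fraction_range, vocab,
                       run_config$gap_prob, run_config$gap_len)
    } else {
      NULL
    }
    val_loss_fn <- function(params) {
      ck <- checkpoint
      ck$params <- params
      masked_lm_eval(val_masks$masked, val_masks$plans, ck)
    }

    params <- checkpoint$params
    opt <- adam_init(params)
    history <- NULL
    best <- list(loss = Inf, params = params)
    init_val <- if (n_val > 0) val_loss_fn(params) else NA_real_
    step <- 0L
    total_steps <- run_config$epochs *
      ceiling(length(train_idx) / run_config$batch_size)
    cfg <- unclass(checkpoint$config)
    for (ep in seq_len(run_config$epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / run_config$batch_size))
      ep_loss <- 0
      for (b in batches) {
        mk <- draw_batch_masks(corpus[b], tw$position_weights[b],
                               run_config$fraction_range, vocab,
                               run_config$gap_prob, run_config$gap_len)
        toks <- seq_id_matrix(mk$masked)
        fb <- cpp_masked_lm_fb(
          toks,
          lapply(mk$plans, function(p) p$positions),
          lapply(mk$plans, function(p) p$target_ids),
          params, cfg, checkpoint$pos, TRUE)
        if (!is.finite(fb$loss)) {
          stop_glycodyn("non-finite pretraining loss at epoch ", ep,
                        class = "glycodyn_training_error")
        }
        step <- step + 1L
        lr <- run_config$learning_rate *
          min(1, step / max(1L, run_config$warmup_steps))
        if (run_config$lr_schedule == "cosine") {
          lr <- lr * 0.5 * (1 + cos(pi * step / total_steps))
        }
        up <- adam_step(params, fb$grads, opt, lr)
        params <- up$params
        opt <- up$state
        ep_loss <- ep_loss + fb$loss * length(b)
      }
      ep_loss <- ep_loss / length(ord)
      vl <- if (n_val > 0) val_loss_fn(params) else NA_real_
      history <- rbind(history,
                       data.frame(epoch = ep, train_loss = ep_loss,
                                  val_loss = vl))
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %.4f", ep, ep_loss, vl))
      }
      if (!is.na(vl) && vl < best$loss) {
        best <- list(loss = vl, params = params)
      }
    }
    out <- checkpoint
    out$params <- if (n_val > 0) best$params else params
    out$history <- history
    attr(out$history, "init_val_loss") <- init_val
    out$checkpoint_id <- sprintf("pretrain-seed%d-ep%d",
                                 run_config$seed, run_config$epochs)
    out
  })
}

# Mean masked-LM loss of already-masked sequences (no gradient).
masked_lm_eval <- function(masked_seqs, plans, checkpoint) {
  toks <- seq_id_matrix(masked_seqs)
  cpp_masked_lm_fb(toks,
                   lapply(plans, function(p) p$positions),
                   lapply(plans, function(p) p$target_ids),
                   checkpoint$params, unclass(checkpoint$config),
                   checkpoint$pos, FALSE)$loss
}

#' Linear-interpolation imputation baseline
#'
#' Fills target slots by linear interpolation between the nearest present
#' anchor values; boundary gaps take the nearest present value.
#'
#' @param day A `cgm_day`.
#' @param target_slots Slots (1..288) to impute; they are treated as
#'   unobserved even if present in `day`.
#' @return Numeric vector of imputed values, one per target slot.
#' @export
impute_linear <- function(day, target_slots) {
  stopifnot(inherits(day, "cgm_day"))
  anchors <- which(day$present & !(seq_len(N_SLOTS) %in% target_slots))
  if (length(anchors) < 2L) {
    stop_glycodyn("need at least 2 present anchor points",
                  class = "glycodyn_validation_error")
  }
  approx(x = anchors, y = day$values[anchors], xout = target_slots,
         method = "linear", rule = 2)$y
}

#' K-nearest-neighbour imputation baseline
#'
#' For each target slot, finds the `k` corpus days closest to the query
#' day in mean squared difference over mutually observed (non-target)
#' slots, and averages their values at that slot. Falls back to the linear
#' baseline when no neighbour observes the slot.
#'
#' @param day A `cgm_day`.
#' @param corpus List of `cgm_day` candidates (the day itself may be
#'   included; exact duplicates are legitimate neighbours).
#' @param target_slots Slots to impute.
#' @param k Number of neighbours.
#' @return Numeric vector of imputed values.
#' @export
impute_knn <- function(day, corpus, target_slots, k = 5L) {
  stopifnot(inherits(day, "cgm_day"), length(corpus) >= 1L, k >= 1L)
  obs <- day$present & !(seq_len(N_SLOTS) %in% target_slots)
  dists <- vapply(corpus, function(cand) {
    both <- obs & cand$present
    if (!any(both)) return(Inf)
    mean((day$values[both] - cand$values[both])^2)
  }, 0)
  ord <- order(dists)  # stable: ties keep corpus order
  ord <- ord[is.finite(dists[ord])]
  k <- min(k, length(ord))
  if (k == 0L) return(impute_linear(day, target_slots))
  nb <- corpus[ord[seq_len(k)]]
  vapply(target_slots, function(s) {
    vals <- unlist(lapply(nb, function(cand) {
      if (cand$present[s]) cand$values[s] else NULL
    }))
    if (!length(vals)) {
      impute_linear(day, s)
    } else {
      mean(vals)
    }
  }, 0)
}

stratum_of <- function(glucose) {
  cut(glucose, breaks = c(-Inf, HYPO_MGDL - 1e-9, HYPER_MGDL, Inf),
      labels = c("hypo", "eu", "hyper"))
}

#' Masked-imputation evaluation with baselines
#'
#' Masks evaluation days (random TF-IDF-free masking or contiguous
#' device-dropout gaps), predicts the masked glucose with the encoder
#' (argmax decoding by default), and reports mean absolute error per
#' glycemic stratum of the true value (hypo < 70, eu 70-180,
#' hyper > 180 mg/dL) for the model and the linear / KNN baselines.
#'
#' @param checkpoint A trained `cgm_checkpoint`.
#' @param eval_days List of `cgm_day`.
#' @param mode `"random"` (pretraining-style masking at `fraction_range`)
#'   or `"gap"` (one contiguous gap per day).
#' @param fraction_range Masked fraction range for `mode = "random"`.
#' @param gap_slots Gap length in slots for `mode = "gap"` (12 = 1 hour).
#' @param k Neighbours for the KNN baseline.
#' @param seed Masking seed.
#' @param decoding `"argmax"` or `"expected"` (probability-weighted mean
#'   level).
#' @return A list of class `cgm_imputation_report`: `table` (data.frame
#'   method x stratum MAE plus overall) and `per_day` (per-day overall MAE
#'   by method, for paired tests).
#' @export
evaluate_imputation <- function(checkpoint, eval_days,
                                mode = c("random", "gap"),
                                fraction_range = c(0.45, 0.60),
                                gap_slots = 12L, k = 5L, seed = 1L,
                                decoding = c("argmax", "expected")) {
  mode <- match.arg(mode)
  decoding <- match.arg(decoding)
  stopifnot(length(eval_days) >= 1L)
  vocab <- token_vocabulary()
  # per-day masking seed derived from the day's identity, so the report is
  # invariant to evaluation-day order
  day_seed <- function(day) {
    key <- paste(day$subject_id, day$date, sep = "|")
    (seed + sum(utf8ToInt(key) * seq_len(nchar(key)))) %% 2147483647L
  }
  local({
    per_day <- NULL
    errs <- list(model = NULL, linear = NULL, knn = NULL)
    truths <- NULL
    seqs <- lapply(eval_days, tokenize_day, vocab = vocab)
    for (i in seq_along(eval_days)) {
      day <- eval_days[[i]]
      present <- which(day$present)
      if (length(present) < 20L) next
      mk_info <- with_rng_seed(day_seed(day), {
        if (mode == "random") {
          mk <- apply_masking(seqs[[i]], NULL, fraction_range, vocab)
          list(slots = mk$plan$positions - 1L, masked = mk$masked)
        } else {
          cands <- present[present <= N_SLOTS - gap_slots]
          if (!length(cands)) {
            NULL
          } else {
            start <- cands[sample.int(length(cands), 1L)]
            slots <- intersect(seq(start, start + gap_slots - 1L), present)
            ms <- seqs[[i]]
            ms$ids[slots + 1L] <- vocab$mask
            list(slots = slots, masked = ms)
          }
        }
      })
      if (is.null(mk_info) || !length(mk_info$slots)) next
      slots <- mk_info$slots
      masked_seq <- mk_info$masked
      truth <- day$values[slots]

      q <- encoder_forward(masked_seq, checkpoint,
                           prob_positions = slots + 1L,
                           want_states = FALSE)$probs[[1L]]
      qg <- q[, seq_len(vocab$n_glucose), drop = FALSE]
      qg <- qg / rowSums(qg)
      pred_model <- if (decoding == "argmax") {
        vocab$levels[max.col(qg, ties.method = "first")]
      } else {
        as.numeric(qg %*% vocab$levels)
      }
      pred_linear <- impute_linear(day, slots)
      pred_knn <- impute_knn(day, eval_days[-i], slots, k = k)

      errs$model <- c(errs$model, abs(pred_model - truth))
      errs$linear <- c(errs$linear, abs(pred_linear - truth))
      errs$knn <- c(errs$knn, abs(pred_knn - truth))
      truths <- c(truths, truth)
      per_day <- rbind(per_day, data.frame(
        day = i,
        model = mean(abs(pred_model - truth)),
        linear = mean(abs(pred_linear - truth)),
        knn = mean(abs(pred_knn - truth))))
    }
    if (is.null(truths)) {
      stop_glycodyn("no evaluable day (too few present slots)",
                    class = "glycodyn_validation_error")
    }
    strat <- stratum_of(truths)
    tab <- do.call(rbind, lapply(names(errs), function(m) {
      e <- errs[[m]]
      data.frame(method = m,
                 hypo = if (any(strat == "hypo")) mean(e[strat == "hypo"]) else NA_real_,
                 eu = if (any(strat == "eu")) mean(e[strat == "eu"]) else NA_real_,
                 hyper = if (any(strat == "hyper")) mean(e[strat == "hyper"]) else NA_real_,
                 overall = mean(e))
    }))
    structure(list(table = tab, per_day = per_day, mode = mode,
                   n_days = nrow(per_day)),
              class = "cgm_imputation_report")
  })
}

#' @export
print.cgm_imputation_report <- function(x, ...) {
  cat(sprintf("<cgm_imputation_report> mode=%s over %d days (MAE, mg/dL)\n",
              x$mode, x$n_days))
  print(x$table, row.names = FALSE)
  invisible(x)
}
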