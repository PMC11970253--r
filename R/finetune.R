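# Supervised fine-tuning: a task-specific transformer block appended to
# the pretrained encoder, a one-layer softmax classification head over the
# mean-pooled states, cross-entropy training with partial freezing.

#' Fine-tuning configuration
#'
#' @param epochs Training epochs.
#' @param batch_size Sequences per optimizer step.
#' @param learning_rate Adam step size.
#' @param freeze_blocks Indices of pretrained encoder blocks to freeze
#'   (default the first two; the token embedding is frozen whenever any
#'   block is). The task block and head always train.
#' @param class_weights If `TRUE`, balance classes by inverse-frequency
#'   oversampling during batch construction.
#' @param seed Run seed.
#' @return A list of class `cgm_finetune_config`.
#' @export
finetune_config <- function(epochs = 2L, batch_size = 8L,
                            learning_rate = 1e-3, freeze_blocks = 1:2,
                            class_weights = FALSE, seed = 1L) {
  check_scalar_number(epochs, "epochs", lower = 1)
  if (length(freeze_blocks) &&
      any(freeze_blocks != seq_along(freeze_blocks))) {
    stop_glycodyn("freeze_blocks must be a leading run 1..k (or empty)",
                  class = "glycodyn_validation_error")
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 freeze_blocks = as.integer(freeze_blocks),
                 class_weights = isTRUE(class_weights),
                 seed = as.integer(seed)),
            class = "cgm_finetune_config")
}

# Extend encoder params with a task block (layer n_layers + 1) and a
# classification head, seeded.
add_task_head <- function(checkpoint, n_classes, seed) {
  cfg <- checkpoint$config
  with_rng_seed(seed, {
    shapes <- param_shapes(cfg, n_blocks = cfg$n_layers + 1L,
                           n_classes = n_classes)
    new_names <- setdiff(names(shapes), names(checkpoint$params))
    new_params <- lapply(setNames(new_names, new_names),
                         function(nm) init_param(nm, shapes[[nm]]))
    c(checkpoint$params, new_params)
  })
}

#' Fine-tune the encoder for a labelled classification task
#'
#' Appends a task-specific transformer block and a one-layer softmax head,
#' then minimizes the cross-entropy of the day labels over the trainable
#' parameters. Frozen blocks retain their pretrained weights bit-exactly.
#'
#' @param checkpoint Pretrained (or freshly initialized) `cgm_checkpoint`.
#' @param seqs List of `cgm_tokens` training days.
#' @param labels Character/factor vector of day labels aligned with
#'   `seqs`, or a named vector keyed by `subject_id`.
#' @param config A `cgm_finetune_config`.
#' @param verbose Print per-epoch loss.
#' @return A list of class `cgm_classifier`: `params`, `config` (encoder),
#'   `task` (`label_set`, fine-tune config), `pos`, `history`.
#' @export
finetune_classifier <- function(checkpoint, seqs, labels,
                                config = finetune_config(),
                                verbose = FALSE) {
  stopifnot(inherits(checkpoint, "cgm_checkpoint"),
            inherits(config, "cgm_finetune_config"))
  if (!is.null(names(labels))) {
    sid <- vapply(seqs, function(s) s$subject_id, "")
    miss <- setdiff(unique(sid), names(labels))
    if (length(miss)) {
      stop_glycodyn("label missing for subject(s): ",
                    paste(miss, collapse = ", "),
                    class = "glycodyn_validation_error")
    }
    labels <- labels[sid]
  }
  if (length(labels) != length(seqs)) {
    stop_glycodyn("labels must align with sequences",
                  class = "glycodyn_validation_error")
  }
  label_set <- sort(unique(as.character(labels)))
  if (length(label_set) < 1L) {
    stop_glycodyn("need at least one class", class = "glycodyn_validation_error")
  }
  y <- match(as.character(labels), label_set)
  params <- add_task_head(checkpoint, length(label_set), config$seed)
  frozen <- frozen_param_names(checkpoint$config, config$freeze_blocks)
  ecfg <- unclass(checkpoint$config)
  freeze_below <- length(config$freeze_blocks)

  with_rng_seed(config$seed + 1L, {
    opt <- adam_init(params)
    history <- NULL
    n <- length(seqs)
    for (ep in seq_len(config$epochs)) {
      ord <- if (config$class_weights) {
        w <- 1 / table(y)[as.character(y)]
        sample.int(n, n, replace = TRUE, prob = as.numeric(w))
      } else {
        sample.int(n)
      }
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (b in batches) {
        toks <- seq_id_matrix(seqs[b])
        fb <- cpp_classifier_fb(toks, y[b], params, ecfg, checkpoint$pos,
                                freeze_below, TRUE)
        if (!is.finite(fb$loss)) {
          stop_glycodyn("non-finite fine-tuning loss",
                        class = "glycodyn_training_error")
        }
        grads <- fb$grads[setdiff(names(fb$grads), frozen)]
        up <- adam_step(params, grads, opt, config$learning_rate)
        params <- up$params
        opt <- up$state
        ep_loss <- ep_loss + fb$loss * length(b)
      }
      history <- rbind(history, data.frame(epoch = ep,
                                           train_loss = ep_loss / n))
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, ep_loss / n))
    }
    structure(list(params = params, config = checkpoint$config,
                   pos = checkpoint$pos,
                   task = list(label_set = label_set,
                               finetune_config = config),
                   history = history,
                   checkpoint_id = paste0(checkpoint$checkpoint_id,
                                          "+finetune")),
              class = "cgm_classifier")
  })
}

frozen_param_names <- function(encoder_config, freeze_blocks) {
  if (!length(freeze_blocks)) return(character(0))
  nms <- c("emb")
  for (l in freeze_blocks) {
    nms <- c(nms, sprintf("l%d_%s", l,
                          c("ln1_g", "ln1_b", "Wq", "Wk", "Wv", "Wo",
                            "bq", "bk", "bv", "bo", "ln2_g", "ln2_b",
                            "W1", "b1", "W2", "b2")))
  }
  nms
}

#' Predict labels for day sequences
#'
#' Produces one probability distribution per day; subject-level
#' predictions are the mean of the subject's day distributions.
#'
#' @param classifier A `cgm_classifier`.
#' @param seqs List of `cgm_tokens`.
#' @return A list of class `cgm_classifier_output`: `day_probs` (matrix,
#'   rows sum to 1), `day_label`, `subject_probs`, `subject_label`.
#' @export
predict_labels <- function(classifier, seqs) {
  stopifnot(inherits(classifier, "cgm_classifier"))
  toks <- seq_id_matrix(seqs)
  probs <- cpp_classifier_forward(toks, classifier$params,
                                  unclass(classifier$config),
                                  classifier$pos)
  colnames(probs) <- classifier$task$label_set
  sid <- vapply(if (inherits(seqs, "cgm_tokens")) list(seqs) else seqs,
                function(s) s$subject_id, "")
  rownames(probs) <- NULL
  sp <- do.call(rbind, lapply(split(seq_along(sid), sid), function(idx) {
    colMeans(probs[idx, , drop = FALSE])
  }))
  lab <- classifier$task$label_set
  structure(list(day_probs = probs,
                 day_label = lab[max.col(probs, ties.method = "first")],
                 day_subject = sid,
                 subject_probs = sp,
                 subject_label = lab[max.col(sp, ties.method = "first")]),
            class = "cgm_classifier_output")
}

#' Evaluate classifier output
#'
#' Accuracy, per-class one-vs-rest AUROC (rank statistic, mid-ranked
#' ties), macro AUROC, and per-class precision/recall.
#'
#' @param probs Matrix of predicted distributions (columns named by
#'   class), e.g. `predict_labels()$day_probs` or `$subject_probs`.
#' @param truth Character vector of true labels aligned with rows.
#' @return A list: `accuracy`, `auroc` (per class), `macro_auroc`,
#'   `precision`, `recall`, `confusion`.
#' @export
evaluate_classifier <- function(probs, truth) {
  truth <- as.character(truth)
  stopifnot(nrow(probs) == length(truth))
  classes <- colnames(probs)
  pred <- classes[max.col(probs, ties.method = "first")]
  acc <- mean(pred == truth)
  if (length(unique(truth)) < 2L) {
    warning("single-class truth: AUROC undefined")
    aucs <- setNames(rep(NA_real_, length(classes)), classes)
  } else {
    aucs <- vapply(classes, function(cl) {
      if (!any(truth == cl) || all(truth == cl)) return(NA_real_)
      auroc(probs[, cl], truth == cl)
    }, 0)
  }
  conf <- table(factor(truth, classes), factor(pred, classes),
                dnn = c("truth", "pred"))
  precision <- diag(conf) / pmax(colSums(conf), 1)
  recall <- diag(conf) / pmax(rowSums(conf), 1)
  list(accuracy = acc, auroc = aucs,
       macro_auroc = mean(aucs, na.rm = TRUE),
       precision = precision, recall = recall, confusion = conf)
}

#' ROC curve points for one class
#'
#' Sweeps every distinct score as a threshold and reports the true- and
#' false-positive rates, for plotting or CSV export.
#'
#' @param scores Numeric predicted scores (higher = positive).
#' @param positive Logical truth vector.
#' @return A data.frame with `threshold`, `tpr`, `fpr`, ordered from the
#'   most permissive to the strictest threshold.
#' @export
roc_points <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  th <- sort(unique(scores))
  out <- do.call(rbind, lapply(th, function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               tpr = sum(pred & positive) / max(sum(positive), 1),
               fpr = sum(pred & !positive) / max(sum(!positive), 1))
  }))
  rbind(data.frame(threshold = -Inf, tpr = 1, fpr = 1), out,
        data.frame(threshold = Inf, tpr = 0, fpr = 0))
}
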