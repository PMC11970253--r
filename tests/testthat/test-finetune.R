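# Fine-tuning mechanics on small configurations: degenerate labels,
# freezing, prediction aggregation, and classifier metrics.

make_labeled_seqs <- function(n_per_class, seed, means = c(90, 200)) {
  withr::with_seed(seed, {
    days <- list()
    labels <- character(0)
    for (cl in seq_along(means)) {
      for (i in seq_len(n_per_class)) {
        v <- pmin(pmax(rnorm(288, means[cl], 8), 40), 300)
        sid <- sprintf("c%d_s%02d", cl, i)
        days[[length(days) + 1L]] <- day_profile(v, subject_id = sid)
        labels <- c(labels, c("low", "high")[cl])
      }
    }
    list(seqs = lapply(days, tokenize_day), labels = labels)
  })
}

test_that("an all-one-class training set collapses onto that class", {
  fx <- make_labeled_seqs(6, seed = 1)
  keep <- fx$labels == "low"
  ck <- init_encoder(small_real_config())
  clf <- finetune_classifier(ck, fx$seqs[keep], fx$labels[keep],
                             finetune_config(epochs = 4L, batch_size = 4L,
                                             freeze_blocks = integer(0),
                                             seed = 2L))
  out <- predict_labels(clf, fx$seqs)
  expect_true(all(out$day_label == "low"))
  expect_lt(tail(clf$history$train_loss, 1), 0.05)
})

test_that("frozen blocks stay bit-identical through fine-tuning", {
  fx <- make_labeled_seqs(4, seed = 3)
  ck <- init_encoder(encoder_config(n_layers = 3L, n_heads = 2L,
                                    d_model = 8L, d_ff = 16L, seed = 3L))
  clf <- finetune_classifier(ck, fx$seqs, fx$labels,
                             finetune_config(epochs = 2L, batch_size = 4L,
                                             freeze_blocks = 1:2,
                                             seed = 4L))
  frozen <- glycodyn:::frozen_param_names(ck$config, 1:2)
  for (nm in frozen) {
    expect_identical(clf$params[[nm]], ck$params[[nm]])
  }
  # unfrozen block 3 must have moved
  expect_false(identical(clf$params$l3_Wq, ck$params$l3_Wq))
})

test_that("predictions are distributions and aggregate by subject mean", {
  fx <- make_labeled_seqs(3, seed = 5)
  ck <- init_encoder(small_real_config())
  clf <- finetune_classifier(ck, fx$seqs, fx$labels,
                             finetune_config(epochs = 1L, batch_size = 4L,
                                             seed = 6L))
  # duplicate days for one subject to exercise aggregation
  seqs <- c(fx$seqs, lapply(fx$seqs[1:2], function(s) {
    s$date <- "2020-01-02"
    s
  }))
  out <- predict_labels(clf, seqs)
  expect_equal(rowSums(out$day_probs), rep(1, length(seqs)),
               tolerance = 1e-6)
  out2 <- predict_labels(clf, seqs)
  expect_identical(out$day_probs, out2$day_probs)  # eval-mode determinism
  sid <- out$day_subject
  for (s in unique(sid)) {
    manual <- colMeans(out$day_probs[sid == s, , drop = FALSE])
    expect_equal(unname(out$subject_probs[s, ]), unname(manual))
  }
})

test_that("classifier metrics: perfect, random, and OvR decomposition", {
  truth <- rep(c("a", "b", "c"), each = 40)
  perfect <- t(vapply(truth, function(cl) {
    p <- c(a = 0.01, b = 0.01, c = 0.01)
    p[cl] <- 0.98
    p
  }, numeric(3)))
  ev <- evaluate_classifier(perfect, truth)
  expect_equal(ev$accuracy, 1)
  expect_equal(unname(ev$auroc), rep(1, 3))

  # label-independent scores -> AUROC near 0.5 (3 SE band)
  n <- 4000
  truth2 <- rep(c("a", "b"), each = n / 2)
  probs2 <- withr::with_seed(11, {
    p <- runif(n)
    cbind(a = p, b = 1 - p)
  })
  ev2 <- evaluate_classifier(probs2, truth2)
  se <- sqrt((n + 1) / (12 * (n / 2)^2))
  expect_lt(abs(ev2$auroc[["a"]] - 0.5), 3 * se)

  # macro AUROC equals the mean of independently computed binary AUROCs
  probs3 <- withr::with_seed(12, {
    m <- matrix(runif(120 * 3), 120)
    m / rowSums(m)
  })
  colnames(probs3) <- c("a", "b", "c")
  ev3 <- evaluate_classifier(probs3, truth)
  oracle <- mean(vapply(c("a", "b", "c"), function(cl) {
    auroc_paircount(probs3[, cl], truth == cl)
  }, 0))
  expect_equal(ev3$macro_auroc, oracle, tolerance = 1e-12)

  expect_warning(evaluate_classifier(probs2[1:5, ], rep("a", 5)),
                 "single-class")
})

test_that("held-out loss does not rise when training labels duplicate", {
  fx <- make_labeled_seqs(5, seed = 7)
  held <- make_labeled_seqs(8, seed = 8)
  ck <- init_encoder(small_real_config())
  heldout_celoss <- function(clf) {
    probs <- predict_labels(clf, held$seqs)$day_probs
    -mean(log(probs[cbind(seq_along(held$labels),
                          match(held$labels, colnames(probs)))]))
  }
  cfg <- finetune_config(epochs = 2L, batch_size = 4L, seed = 9L)
  l1 <- heldout_celoss(finetune_classifier(ck, fx$seqs, fx$labels, cfg))
  l2 <- heldout_celoss(finetune_classifier(ck, c(fx$seqs, fx$seqs),
                                           c(fx$labels, fx$labels), cfg))
  expect_lte(l2, l1 + 1e-6)
})

test_that("missing subject labels are rejected", {
  fx <- make_labeled_seqs(2, seed = 10)
  ck <- init_encoder(small_real_config())
  named <- c(c1_s01 = "low")
  expect_error(finetune_classifier(ck, fx$seqs, named),
               "label missing for subject")
})

test_that("ROC points integrate to the rank AUROC (trapezoid oracle)", {
  withr::with_seed(20, {
    scores <- c(rnorm(60, 1), rnorm(60, 0))
    truth <- rep(c(TRUE, FALSE), each = 60)
  })
  pts <- roc_points(scores, truth)
  expect_true(all(diff(pts$fpr) <= 0) && all(diff(pts$tpr) <= 0))
  o <- order(pts$fpr, pts$tpr)  # staircase order (ties resolved upward)
  auc_trap <- sum(diff(pts$fpr[o]) * (head(pts$tpr[o], -1) +
                                        tail(pts$tpr[o], -1)) / 2)
  expect_equal(auc_trap, auroc(scores, truth), tolerance = 1e-9)
})
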