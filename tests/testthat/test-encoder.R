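# Encoder structure, closed-form losses, pooling identities, and an
# analytic-vs-finite-difference gradient check on a tiny configuration.

test_that("positional encoding has the sinusoidal closed form", {
  pe <- positional_encoding(289, 128)
  expect_equal(dim(pe), c(289L, 128L))
  # position 0: sin terms are 0, cos terms are 1
  expect_equal(pe[1, seq(1, 128, 2)], rep(0, 64))
  expect_equal(pe[1, seq(2, 128, 2)], rep(1, 64))
  expect_true(all(pe >= -1 & pe <= 1))
  # continuity of the time representation
  cs <- function(i, j) {
    sum(pe[i, ] * pe[j, ]) / sqrt(sum(pe[i, ]^2) * sum(pe[j, ]^2))
  }
  expect_gt(cs(11, 12), cs(11, 151))
})

test_that("forward pass yields distributions, attention rows sum to 1", {
  ck <- init_encoder(encoder_config(seed = 2))
  day <- withr::with_seed(1, day_profile({
    v <- rnorm(288, 120, 20)
    v[50:60] <- NA
    pmin(pmax(v, 40), 300)
  }))
  seq <- tokenize_day(day)
  out <- encoder_forward(seq, ck, prob_positions = list(c(2L, 100L)),
                         want_attn = TRUE)
  q <- out$probs[[1]]
  expect_equal(dim(q), c(2L, 263L))
  expect_equal(rowSums(q), c(1, 1), tolerance = 1e-6)
  expect_true(all(q >= 0))
  for (l in seq_along(out$attn[[1]])) {
    a <- out$attn[[1]][[l]]
    expect_equal(dim(a), c(289L, 289L, 8L))
    expect_equal(max(abs(apply(a, 3, rowSums) - 1)), 0, tolerance = 1e-5)
    expect_true(all(a >= 0))
  }
  # evaluation-mode determinism
  out2 <- encoder_forward(seq, ck, prob_positions = list(c(2L, 100L)))
  expect_identical(out$states[[1]], out2$states[[1]])
  expect_identical(q, out2$probs[[1]])
})

test_that("masked-LM loss has its closed forms", {
  plan2 <- structure(list(positions = c(5L, 9L), target_ids = c(3L, 7L),
                          mask_fraction = NA_real_),
                     class = "cgm_mask_plan")
  # uniform over 260 glucose tokens -> ln 260
  q_unif <- matrix(1 / 260, 2, 260)
  expect_equal(masked_lm_loss(q_unif, plan2), log(260), tolerance = 1e-12)
  expect_equal(log(260), 5.5607, tolerance = 1e-4)
  # probability 1 on the truth -> 0
  q_perfect <- matrix(0, 2, 260)
  q_perfect[1, 3] <- 1
  q_perfect[2, 7] <- 1
  expect_equal(masked_lm_loss(q_perfect, plan2), 0)
  # two positions with losses a and b -> (a + b) / 2
  q <- matrix(0, 2, 260)
  q[1, ] <- 0.8 / 259
  q[1, 3] <- 0.2
  q[2, ] <- 0.05 / 259
  q[2, 7] <- 0.95
  a <- -log(q[1, 3])
  b <- -log(q[2, 7])
  expect_equal(masked_lm_loss(q, plan2), (a + b) / 2)
  expect_error(masked_lm_loss(q, structure(
    list(positions = integer(0), target_ids = integer(0),
         mask_fraction = 0), class = "cgm_mask_plan")), "empty")
})

test_that("day embedding is the mean of final-layer states (pooling oracle)", {
  ck <- init_encoder(encoder_config(seed = 5))
  seq <- tokenize_day(day_profile(rep(c(90, 180), 144)))
  emb <- day_embedding(seq, ck)
  expect_length(emb$vector, 128L)
  states <- encoder_forward(seq, ck)$states[[1]]
  manual <- vapply(seq_len(128), function(j) mean(states[, j]), 0)
  expect_equal(emb$vector, manual, tolerance = 1e-12)
  # identical days give identical embeddings
  emb2 <- day_embedding(tokenize_day(day_profile(rep(c(90, 180), 144))), ck)
  expect_identical(emb$vector, emb2$vector)
})

test_that("sample embedding averages day embeddings", {
  mk <- function(v, sid = "s1") {
    structure(list(vector = v, subject_id = sid, date = "d",
                   checkpoint_id = "x"), class = "cgm_day_embedding")
  }
  v1 <- rnorm(128)
  v2 <- rnorm(128)
  v3 <- rnorm(128)
  expect_equal(sample_embedding(list(mk(v1)))$vector, v1)
  expect_equal(sample_embedding(list(mk(v1), mk(v2)))$vector, (v1 + v2) / 2)
  s_abc <- sample_embedding(list(mk(v1), mk(v2), mk(v3)))$vector
  s_cba <- sample_embedding(list(mk(v3), mk(v1), mk(v2)))$vector
  expect_equal(s_abc, s_cba)
  expect_error(sample_embedding(list(mk(v1), mk(v2, "other"))),
               "mix subjects")
})

test_that("analytic gradients match finite differences (tiny config)", {
  cfg <- tiny_config()
  ck <- init_encoder(cfg)
  toks <- matrix(c(11L, 3L, 12L, 10L, 5L, 12L, 2L), 1)
  mp <- list(c(3L, 6L))
  ti <- list(c(4L, 7L))
  lossfn <- function(params) {
    cpp_masked_lm_fb(toks, mp, ti, params, unclass(cfg), ck$pos, FALSE)$loss
  }
  fb <- cpp_masked_lm_fb(toks, mp, ti, ck$params, unclass(cfg), ck$pos,
                         TRUE)
  eps <- 1e-3
  withr::with_seed(42, {
    for (nm in names(fb$grads)) {
      g <- fb$grads[[nm]]
      for (j in sample(length(g), min(4, length(g)))) {
        p2 <- ck$params
        p2[[nm]][j] <- p2[[nm]][j] + eps
        lp <- lossfn(p2)
        p2[[nm]][j] <- p2[[nm]][j] - 2 * eps
        lm <- lossfn(p2)
        fd <- (lp - lm) / (2 * eps)
        expect_lt(abs(fd - g[j]) / max(1e-3, abs(fd) + abs(g[j])), 0.02)
      }
    }
  })
})

test_that("classifier gradients match finite differences", {
  cfg <- tiny_config()
  ck <- init_encoder(cfg)
  params <- withr::with_seed(1, {
    shapes <- glycodyn:::param_shapes(cfg, n_blocks = cfg$n_layers + 1L,
                                      n_classes = 3L)
    nms <- setdiff(names(shapes), names(ck$params))
    c(ck$params, lapply(setNames(nms, nms), function(nm) {
      glycodyn:::init_param(nm, shapes[[nm]])
    }))
  })
  toks <- matrix(c(11L, 3L, 8L, 10L, 5L, 1L, 2L), 1)
  lossfn <- function(p) {
    cpp_classifier_fb(toks, 2L, p, unclass(cfg), ck$pos, 0L, FALSE)$loss
  }
  fb <- cpp_classifier_fb(toks, 2L, params, unclass(cfg), ck$pos, 0L, TRUE)
  eps <- 1e-3
  withr::with_seed(43, {
    for (nm in c("clf_W", "clf_b", "l3_Wq", "l1_W1", "emb", "lnf_g")) {
      g <- fb$grads[[nm]]
      for (j in sample(length(g), min(4, length(g)))) {
        p2 <- params
        p2[[nm]][j] <- p2[[nm]][j] + eps
        lp <- lossfn(p2)
        p2[[nm]][j] <- p2[[nm]][j] - 2 * eps
        lm <- lossfn(p2)
        fd <- (lp - lm) / (2 * eps)
        expect_lt(abs(fd - g[j]) / max(1e-3, abs(fd) + abs(g[j])), 0.02)
      }
    }
  })
})

test_that("intra-subject embedding similarity exceeds inter-subject", {
  ck <- shared_checkpoint()
  co <- shared_eval_cohort()
  seqs <- lapply(co$days, tokenize_day)
  emb <- embed_days(seqs, ck)
  sid <- vapply(seqs, function(s) s$subject_id, "")
  norm <- emb / sqrt(rowSums(emb^2))
  sim <- tcrossprod(norm)
  same <- outer(sid, sid, "==")
  diag(same) <- NA
  intra <- sim[same & upper.tri(sim)]
  inter <- sim[!same & upper.tri(sim)]
  tt <- t.test(intra, inter, alternative = "greater")
  expect_lt(tt$p.value, 0.05)
})
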