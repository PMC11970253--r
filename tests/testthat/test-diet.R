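# Postprandial diet model: construction oracles, rollout equivalence,
# gradient check, causality, and the perturbation experiment.

random_diet_model <- function(t = 4L, l = 6L, seed = 1L) {
  init_diet_model(diet_config(latent_dim = l, embedding_dim = 8L, t = t,
                              seed = seed),
                  glucose_mean = 120, glucose_sd = 30)
}

test_that("pulse encoding places the meal in the final column only", {
  expect_equal(encode_pulse(c(0, 0, 0, 0, 0), 4), matrix(0, 5, 4))
  D <- withr::with_seed(1, runif(5, 0, 100))
  for (t in c(1L, 4L, 7L)) {
    m <- encode_pulse(D, t)
    oracle <- matrix(0, 5, t)
    for (r in 1:5) oracle[r, t] <- D[r]   # brute-force construction
    expect_equal(m, oracle)
    expect_equal(colSums(m)[t], sum(D))
    if (t > 1) expect_equal(colSums(m)[1:(t - 1)], rep(0, t - 1),
                            ignore_attr = TRUE)
  }
  expect_error(encode_pulse(c(-1, 0, 0, 0, 0), 4), "nonnegative")
  expect_error(encode_pulse(c(1, 2, 3), 4), "length-5")
})

test_that("input stacking puts glucose in row 1 and the pulse below", {
  GB <- c(100, 105, 102, 99)
  D <- c(600, 70, 25, 20, 4)
  Tm <- build_input_matrix(GB, encode_pulse(D, 4))
  expect_equal(dim(Tm), c(6L, 4L))
  expect_equal(Tm[1, ], GB)
  expect_equal(Tm[2:6, ], encode_pulse(D, 4))
  zero <- build_input_matrix(GB, encode_pulse(rep(0, 5), 4))
  expect_equal(zero[2:6, ], matrix(0, 5, 4))
  expect_error(build_input_matrix(c(1, 2), encode_pulse(D, 4)),
               "length")
})

test_that("rollout shapes: G_pred has 3t-1 values, G^P has 2t", {
  for (t in c(2L, 4L, 6L)) {
    model <- random_diet_model(t = t, seed = 2)
    v_s <- withr::with_seed(3, rnorm(8))
    Tm <- build_input_matrix(rep(110, t), encode_pulse(c(500, 60, 20, 15, 3), t))
    out <- diet_forward(model, v_s, Tm)
    expect_length(out$g_pred, 3L * t - 1L)
    expect_length(out$GP, 2L * t)
    expect_equal(out$g_pred[(t):(3L * t - 1L)], out$GP)
    # deterministic replay
    out2 <- diet_forward(model, v_s, Tm)
    expect_identical(out$g_pred, out2$g_pred)
  }
})

test_that("rollout equals a hand-unrolled recurrent oracle", {
  t <- 4L
  l <- 5L
  model <- random_diet_model(t = t, l = l, seed = 4)
  w <- model$weights
  sc <- model$scaling
  v_s <- withr::with_seed(5, rnorm(8))
  GB <- c(100, 108, 112, 105)
  D <- c(640, 80, 25, 18, 6)
  Tm <- build_input_matrix(GB, encode_pulse(D, t))

  # independent step-by-step unroll with plain R arithmetic
  sig <- function(x) 1 / (1 + exp(-x))
  h <- as.numeric(w$Wenc %*% v_s + w$benc)
  cc <- rep(0, l)
  preds <- numeric(0)
  g_prev <- NA
  for (k in 1:(3 * t - 1)) {
    if (k <= t) {
      x <- c((Tm[1, k] - sc$g_mean) / sc$g_sd,
             Tm[2:6, k] / c(1000, 100, 100, 100, 100))
    } else {
      x <- c((g_prev - sc$g_mean) / sc$g_sd, rep(0, 5))
    }
    a <- as.numeric(w$Wx %*% x + w$Wh %*% h + w$b)
    i <- sig(a[1:l]); f <- sig(a[(l + 1):(2 * l)])
    o <- sig(a[(2 * l + 1):(3 * l)]); g_c <- tanh(a[(3 * l + 1):(4 * l)])
    cc <- f * cc + i * g_c
    h <- o * tanh(cc)
    g_prev <- as.numeric(w$Wdec %*% h + w$bdec)
    preds <- c(preds, g_prev)
  }
  out <- diet_forward(model, v_s, Tm)
  expect_equal(out$g_pred, preds, tolerance = 1e-12)
})

test_that("diet loss is plain MSE over all 3t-1 positions", {
  expect_equal(diet_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(diet_loss(c(2, 3, 4), c(1, 2, 3)), 1)
  withr::with_seed(6, {
    a <- rnorm(11)
    b <- rnorm(11)
    expect_equal(diet_loss(a, b), mean((a - b)^2))
  })
  expect_error(diet_loss(1:10, 1:11), "length mismatch")
  # time-ordering sensitivity: shuffling predictions changes the loss
  a <- c(1, 5, 9, 2, 8, 3, 7, 4, 6, 0, 10)
  b <- sort(a)
  expect_false(isTRUE(all.equal(diet_loss(a, b), diet_loss(rev(a), b))))
})

test_that("backward pass matches finite differences", {
  t <- 4L
  model <- random_diet_model(t = t, l = 4L, seed = 7)
  v_s <- withr::with_seed(8, rnorm(8))
  GB <- c(100, 104, 99, 103)
  D <- c(550, 65, 20, 17, 4)
  Tm <- build_input_matrix(GB, encode_pulse(D, t))
  target <- withr::with_seed(9, rnorm(11, 120, 20))
  lossfn <- function(weights) {
    m2 <- model
    m2$weights <- weights
    diet_loss(diet_forward(m2, v_s, Tm)$g_pred, target)
  }
  fw <- diet_forward(model, v_s, Tm, cache = TRUE)
  bk <- glycodyn:::diet_backward(model, fw, target)
  expect_equal(bk$loss, lossfn(model$weights))
  eps <- 1e-6
  withr::with_seed(10, {
    for (nm in names(bk$grads)) {
      g <- bk$grads[[nm]]
      for (j in sample(length(g), min(4, length(g)))) {
        w2 <- model$weights
        w2[[nm]][j] <- w2[[nm]][j] + eps
        lp <- lossfn(w2)
        w2[[nm]][j] <- w2[[nm]][j] - 2 * eps
        lm <- lossfn(w2)
        fd <- (lp - lm) / (2 * eps)
        expect_lt(abs(fd - g[j]) / max(1e-6, abs(fd) + abs(g[j])), 1e-4)
      }
    }
  })
})

test_that("pulse causality: the meal affects only steps at its column on", {
  t <- 4L
  model <- random_diet_model(t = t, seed = 11)
  v_s <- withr::with_seed(12, rnorm(8))
  GB <- c(100, 102, 104, 101)
  out0 <- diet_forward(model, v_s,
                       build_input_matrix(GB, encode_pulse(rep(0, 5), t)))
  out1 <- diet_forward(model, v_s,
                       build_input_matrix(GB, encode_pulse(
                         c(800, 100, 30, 25, 8), t)))
  # predictions g_2..g_t come from steps 1..t-1, before the pulse column
  expect_equal(out0$g_pred[1:(t - 1)], out1$g_pred[1:(t - 1)])
  expect_false(isTRUE(all.equal(out0$g_pred[t:length(out0$g_pred)],
                                out1$g_pred[t:length(out1$g_pred)])))
})

test_that("five examples can be memorized (capacity sanity)", {
  t <- 4L
  examples <- withr::with_seed(13, lapply(1:5, function(i) {
    GB <- rnorm(t, 110, 5)
    peak <- 30 + 10 * i
    curve <- 110 + peak * exp(-((1:(2 * t)) - 3)^2 / 6)
    list(v_s = rnorm(8), GB = GB, D = c(500 + 20 * i, 60, 20, 15, 4),
         G_hat = c(GB[2:t], curve))
  }))
  model <- train_diet(examples,
                      diet_config(latent_dim = 16L, embedding_dim = 8L,
                                  t = t, seed = 14),
                      epochs = 800L, learning_rate = 1e-2,
                      val_fraction = 0, seed = 15, allow_small = TRUE)
  final <- mean(vapply(examples, function(e) {
    fw <- diet_forward(model, e$v_s,
                       build_input_matrix(e$GB, encode_pulse(e$D, t)))
    diet_loss(fw$g_pred, e$G_hat)
  }, 0))
  expect_lt(final, 1)
})

test_that("training is seed-deterministic", {
  t <- 4L
  examples <- withr::with_seed(16, lapply(1:12, function(i) {
    GB <- rnorm(t, 110, 5)
    list(v_s = rnorm(8), GB = GB, D = c(600, 70, 20, 18, 5),
         G_hat = rnorm(3 * t - 1, 120, 10))
  }))
  cfg <- diet_config(latent_dim = 6L, embedding_dim = 8L, t = t, seed = 2)
  m1 <- train_diet(examples, cfg, epochs = 10L, seed = 17)
  m2 <- train_diet(examples, cfg, epochs = 10L, seed = 17)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
})

test_that("perturbation experiment: four meals, zero change vs itself", {
  model <- random_diet_model(t = 4L, seed = 18)
  v_s <- withr::with_seed(19, rnorm(8))
  rep <- perturb_in_silico(model, v_s, GB = c(110, 112, 108, 111),
                           kcal = 600)
  expect_equal(nrow(rep), 4L)
  expect_setequal(rep$meal_id,
                  c("standard", "low_carb", "high_protein", "high_fat"))
  std <- rep[rep$meal_id == "standard", ]
  for (m in c("d_Mean", "d_PG120", "d_Max", "d_SD", "d_AUC")) {
    expect_equal(std[[m]], 0)
  }
  bad <- default_meal_set()
  bad$carb_ratio[2] <- 0.9
  expect_error(perturb_in_silico(model, v_s, c(110, 112, 108, 111),
                                 meal_set = bad), "sum to 1")
  expect_error(perturb_in_silico(model, v_s, c(110, 112, 108, 111),
                                 meal_set = default_meal_set()[-1, ]),
               "standard")
})
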