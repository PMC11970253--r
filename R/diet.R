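# Postprandial glucose prediction: a linear encoder maps the individual
# embedding into the recurrent latent space, a gated (LSTM) cell consumes
# pre-meal glucose plus the pulse-encoded meal, and the rollout continues
# autoregressively for two hours after the meal.

#' Pulse-encode a meal descriptor
#'
#' Places the 5-component nutrition vector `D = (H, C, P, F, B)` (kcal,
#' carbohydrate g, protein g, fat g, fiber g) in the last of `t` time
#' columns — a dietary impulse at the meal time — and zeros elsewhere.
#'
#' @param D Numeric length-5 nonnegative nutrition vector.
#' @param t Measurements per hour (pulse column).
#' @return A `5 x t` matrix.
#' @examples
#' encode_pulse(c(600, 75, 30, 20, 5), t = 4)
#' @export
encode_pulse <- function(D, t) {
  if (length(D) != 5L || any(!is.finite(D))) {
    stop_glycodyn("D must be a finite length-5 nutrition vector",
                  class = "glycodyn_validation_error")
  }
  if (any(D < 0)) {
    stop_glycodyn("nutrients must be nonnegative",
                  class = "glycodyn_validation_error")
  }
  check_scalar_number(t, "t", lower = 1)
  m <- matrix(0, 5L, t)
  m[, t] <- D
  m
}

#' Stack pre-meal glucose and the meal pulse into the model input
#'
#' Row 1 carries the before-meal glucose; rows 2-6 the pulse-encoded
#' meal.
#'
#' @param GB Numeric length-`t` pre-meal glucose (mg/dL).
#' @param Dhat A `5 x t` pulse matrix from [encode_pulse()].
#' @return A `6 x t` matrix.
#' @export
build_input_matrix <- function(GB, Dhat) {
  if (!is.matrix(Dhat) || nrow(Dhat) != 5L) {
    stop_glycodyn("Dhat must be a 5 x t matrix",
                  class = "glycodyn_validation_error")
  }
  if (length(GB) != ncol(Dhat)) {
    stop_glycodyn("length(GB) must equal ncol(Dhat)",
                  class = "glycodyn_validation_error")
  }
  rbind(matrix(GB, 1L), Dhat)
}

#' Diet model configuration
#'
#' @param latent_dim Recurrent latent width `l`.
#' @param embedding_dim Width of the individual embedding (128 for the
#'   default encoder).
#' @param t Measurements per hour (4 for 15-minute flash monitoring).
#' @param seed Initialization seed.
#' @return A list of class `cgm_diet_config`.
#' @export
diet_config <- function(latent_dim = 32L, embedding_dim = 128L, t = 4L,
                        seed = 1L) {
  check_scalar_number(latent_dim, "latent_dim", lower = 1)
  check_scalar_number(t, "t", lower = 2)
  structure(list(latent_dim = as.integer(latent_dim),
                 embedding_dim = as.integer(embedding_dim),
                 t = as.integer(t), seed = as.integer(seed)),
            class = "cgm_diet_config")
}

# Fixed input scaling: glucose is z-scored by training statistics;
# nutrients by reference magnitudes (kcal/1000, grams/100).
NUTR_SCALE <- c(1000, 100, 100, 100, 100)

#' Initialize the diet model
#'
#' @param config A `cgm_diet_config`.
#' @param glucose_mean,glucose_sd Standardization statistics (set from
#'   the training set by [train_diet()]).
#' @return A list of class `cgm_diet_model` with `weights`, `config`,
#'   `scaling`.
#' @export
init_diet_model <- function(config = diet_config(), glucose_mean = 120,
                            glucose_sd = 40) {
  l <- config$latent_dim
  d <- config$embedding_dim
  with_rng_seed(config$seed, {
    gl <- function(r, c) {
      matrix(runif(r * c, -sqrt(6 / (r + c)), sqrt(6 / (r + c))), r, c)
    }
    b_lstm <- rep(0, 4 * l)
    b_lstm[(l + 1):(2 * l)] <- 1  # forget-gate bias
    # decoder bias starts at the glucose mean so that an untrained model
    # predicts physiologic values instead of clipping at the range floor
    weights <- list(Wenc = gl(l, d), benc = rep(0, l),
                    Wx = gl(4 * l, 6L), Wh = gl(4 * l, l), b = b_lstm,
                    Wdec = gl(1, l) * 10, bdec = glucose_mean)
    structure(list(weights = weights, config = config,
                   scaling = list(g_mean = glucose_mean,
                                  g_sd = glucose_sd)),
              class = "cgm_diet_model")
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

scale_input_col <- function(col, scaling) {
  c((col[1] - scaling$g_mean) / scaling$g_sd, col[2:6] / NUTR_SCALE)
}

#' Recurrent rollout of the diet model
#'
#' Encodes the individual embedding as the initial latent state, consumes
#' the `t` observed input columns (pre-meal glucose + meal pulse), then
#' rolls forward autoregressively for `2t` further steps feeding each
#' predicted glucose back as the next input with zero meal rows. Returns
#' all predictions `g_2..g_3t` and the postprandial block `G^P`
#' (`g_{t+1}..g_{3t}`, the 2-hour prediction).
#'
#' @param model A `cgm_diet_model`.
#' @param v_s Individual embedding vector.
#' @param Tmat `6 x t` input from [build_input_matrix()].
#' @param cache Keep intermediate states for backpropagation.
#' @return A list: `g_pred` (length `3t - 1`), `GP` (length `2t`),
#'   `GP_clipped` (reporting scale, clipped to `[40, 300]`), and `cache`
#'   when requested.
#' @export
diet_forward <- function(model, v_s, Tmat, cache = FALSE) {
  stopifnot(inherits(model, "cgm_diet_model"))
  cfg <- model$config
  t <- cfg$t
  if (!is.matrix(Tmat) || nrow(Tmat) != 6L || ncol(Tmat) != t) {
    stop_glycodyn("Tmat must be 6 x t with t = ", t,
                  class = "glycodyn_validation_error")
  }
  if (length(v_s) != cfg$embedding_dim) {
    stop_glycodyn("v_s must have length ", cfg$embedding_dim,
                  class = "glycodyn_validation_error")
  }
  w <- model$weights
  sc <- model$scaling
  l <- cfg$latent_dim
  K <- 3L * t - 1L  # recurrent steps; step k emits g_{k+1}
  h <- w$Wenc %*% as.numeric(v_s) + w$benc
  cc <- rep(0, l)
  X <- matrix(0, 6L, K)
  H <- matrix(0, l, K + 1L)  # H[, k] = h_k
  C <- matrix(0, l, K + 1L)
  H[, 1L] <- h
  gates <- array(0, c(4L * l, K))
  tanhc <- matrix(0, l, K)
  g <- rep(NA_real_, K + 1L)  # g[k] = prediction g_k (g[1] unused)
  for (k in seq_len(K)) {
    x <- if (k <= t) {
      scale_input_col(Tmat[, k], sc)
    } else {
      c((g[k] - sc$g_mean) / sc$g_sd, rep(0, 5L))
    }
    X[, k] <- x
    a <- as.numeric(w$Wx %*% x + w$Wh %*% H[, k] + w$b)
    i <- sigmoid(a[1:l]); f <- sigmoid(a[(l + 1):(2 * l)])
    o <- sigmoid(a[(2 * l + 1):(3 * l)]); gc <- tanh(a[(3 * l + 1):(4 * l)])
    C[, k + 1L] <- f * C[, k] + i * gc
    tanhc[, k] <- tanh(C[, k + 1L])
    H[, k + 1L] <- o * tanhc[, k]
    gates[, k] <- c(i, f, o, gc)
    g[k + 1L] <- as.numeric(w$Wdec %*% H[, k + 1L] + w$bdec)
    if (!is.finite(g[k + 1L])) {
      stop_glycodyn("non-finite state at rollout step ", k,
                    class = "glycodyn_training_error")
    }
  }
  GP <- g[(t + 1L):(3L * t)]
  out <- list(g_pred = g[-1L], GP = GP,
              GP_clipped = pmin(pmax(GP, GLUCOSE_MIN), GLUCOSE_MAX))
  if (cache) {
    out$cache <- list(X = X, H = H, C = C, gates = gates, tanhc = tanhc,
                      g = g, v_s = as.numeric(v_s))
  }
  out
}

#' Diet model training loss
#'
#' Mean squared error between the `3t - 1` rollout predictions and the
#' observed concatenation of pre-meal glucose (positions 2..t) and the
#' 2-hour postprandial curve.
#'
#' @param predictions Numeric vector `g_2..g_3t` (length `3t - 1`).
#' @param target Numeric vector of the same length (`G_hat`).
#' @return Scalar MSE (mg/dL squared).
#' @export
diet_loss <- function(predictions, target) {
  if (length(predictions) != length(target)) {
    stop_glycodyn("prediction/target length mismatch: ",
                  length(predictions), " vs ", length(target),
                  class = "glycodyn_validation_error")
  }
  mean((predictions - target)^2)
}

# Backpropagation through the rollout (including the autoregressive
# feedback path). Returns loss and gradients for all weights.
diet_backward <- function(model, fwd, target) {
  w <- model$weights
  cfg <- model$config
  sc <- model$scaling
  l <- cfg$latent_dim
  t <- cfg$t
  K <- 3L * t - 1L
  ch <- fwd$cache
  pred <- ch$g[-1L]
  resid <- pred - target
  loss <- mean(resid^2)
  dg_loss <- 2 * resid / K              # dL/dg_{k+1}, k = 1..K

  gr <- list(Wenc = w$Wenc * 0, benc = w$benc * 0, Wx = w$Wx * 0,
             Wh = w$Wh * 0, b = w$b * 0, Wdec = w$Wdec * 0, bdec = 0)
  dh_next <- rep(0, l)    # dL/dh_{k+1} from steps > k
  dc_next <- rep(0, l)    # dL/dc_{k+1} from steps > k
  dg_feedback <- rep(0, K + 1L)  # extra dL/dg_k via autoregressive input
  for (k in K:1) {
    dg <- dg_loss[k] + dg_feedback[k + 1L]
    dh <- as.numeric(t(w$Wdec)) * dg + dh_next
    gr$Wdec <- gr$Wdec + dg * matrix(ch$H[, k + 1L], 1L)
    gr$bdec <- gr$bdec + dg
    i <- ch$gates[1:l, k]; f <- ch$gates[(l + 1):(2 * l), k]
    o <- ch$gates[(2 * l + 1):(3 * l), k]
    gc <- ch$gates[(3 * l + 1):(4 * l), k]
    tc <- ch$tanhc[, k]
    dc <- dh * o * (1 - tc^2) + dc_next
    di <- dc * gc * i * (1 - i)
    df <- dc * ch$C[, k] * f * (1 - f)
    do_ <- dh * tc * o * (1 - o)
    dgc <- dc * i * (1 - gc^2)
    da <- c(di, df, do_, dgc)
    gr$Wx <- gr$Wx + da %o% ch$X[, k]
    gr$Wh <- gr$Wh + da %o% ch$H[, k]
    gr$b <- gr$b + da
    dx <- as.numeric(t(w$Wx) %*% da)
    if (k > t) {
      # input glucose was the previous prediction, standardized
      dg_feedback[k] <- dx[1L] / sc$g_sd
    }
    dh_next <- as.numeric(t(w$Wh) %*% da)
    dc_next <- dc * f
  }
  gr$Wenc <- gr$Wenc + dh_next %o% ch$v_s
  gr$benc <- gr$benc + dh_next
  list(loss = loss, grads = gr)
}

#' Assemble diet training examples from simulated or parsed data
#'
#' @param v_s Matrix of individual embeddings (rows named by subject) or
#'   a single vector reused for all examples.
#' @param GB Matrix (`n x t`) of pre-meal glucose.
#' @param D Matrix (`n x 5`) of nutrition vectors.
#' @param G_hat Matrix (`n x (3t - 1)`) of target concatenations.
#' @param subject Optional subject ids per example.
#' @return List of diet examples.
#' @export
make_diet_examples <- function(v_s, GB, D, G_hat, subject = NULL) {
  n <- nrow(GB)
  if (is.null(dim(v_s))) v_s <- matrix(v_s, n, length(v_s), byrow = TRUE)
  stopifnot(nrow(v_s) == n, nrow(D) == n, nrow(G_hat) == n)
  lapply(seq_len(n), function(i) {
    list(v_s = v_s[i, ], GB = GB[i, ], D = D[i, ], G_hat = G_hat[i, ],
         subject = if (is.null(subject)) NA_character_ else subject[i])
  })
}

#' Train the diet model
#'
#' Minimizes the rollout MSE with Adam; retains the best-validation
#' weights. Standardization statistics are set from the training split.
#'
#' @param examples List of examples from [make_diet_examples()]
#'   (>= 10 unless `allow_small`).
#' @param config A `cgm_diet_config`.
#' @param epochs,learning_rate,batch_size Optimization settings.
#' @param val_fraction Held-out share for validation.
#' @param seed Run seed.
#' @param allow_small Permit < 10 examples (overfit sanity checks).
#' @return A `cgm_diet_model` with a `history` data.frame attached.
#' @export
train_diet <- function(examples, config = diet_config(), epochs = 200L,
                       learning_rate = 5e-3, batch_size = 16L,
                       val_fraction = 0.15, seed = 1L,
                       allow_small = FALSE) {
  if (length(examples) < 10L && !allow_small) {
    stop_glycodyn("need >= 10 examples", class = "glycodyn_validation_error")
  }
  t <- config$t
  glucose_pool <- unlist(lapply(examples, function(e) c(e$GB, e$G_hat)))
  model <- init_diet_model(config, glucose_mean = mean(glucose_pool),
                           glucose_sd = max(sd(glucose_pool), 1))
  with_rng_seed(seed, {
    n <- length(examples)
    n_val <- if (n >= 10L) max(1L, round(val_fraction * n)) else 0L
    idx <- sample.int(n)
    val_idx <- head(idx, n_val)
    train_idx <- setdiff(idx, val_idx)
    opt <- adam_init(model$weights)
    best <- list(loss = Inf, weights = model$weights)
    history <- NULL
    eval_loss <- function(weights, which_idx) {
      m2 <- model
      m2$weights <- weights
      mean(vapply(examples[which_idx], function(e) {
        fw <- diet_forward(m2, e$v_s, build_input_matrix(
          e$GB, encode_pulse(e$D, t)))
        diet_loss(fw$g_pred, e$G_hat)
      }, 0))
    }
    for (ep in seq_len(epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0
      for (b in batches) {
        acc <- NULL
        bl <- 0
        for (i in b) {
          e <- examples[[i]]
          fw <- diet_forward(model, e$v_s, build_input_matrix(
            e$GB, encode_pulse(e$D, t)), cache = TRUE)
          bk <- diet_backward(model, fw, e$G_hat)
          bl <- bl + bk$loss
          if (is.null(acc)) {
            acc <- bk$grads
          } else {
            for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + bk$grads[[nm]]
          }
        }
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(b)
        if (!is.finite(bl)) {
          stop_glycodyn("non-finite diet loss", class = "glycodyn_training_error")
        }
        up <- adam_step(model$weights, acc, opt, learning_rate)
        model$weights <- up$params
        opt <- up$state
        ep_loss <- ep_loss + bl
      }
      vl <- if (n_val > 0) eval_loss(model$weights, val_idx) else NA_real_
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = ep_loss / length(train_idx),
        val_loss = vl))
      if (!is.na(vl) && vl < best$loss) {
        best <- list(loss = vl, weights = model$weights)
      }
    }
    if (n_val > 0) model$weights <- best$weights
    model$history <- history
    model
  })
}

#' In-silico meal perturbation experiment
#'
#' Builds simulated meals at fixed calories with varying macronutrient
#' energy ratios (4/4/9 kcal/g for carbohydrate/protein/fat), predicts
#' each meal's 2-hour postprandial curve, summarizes it (Mean, PG120,
#' Max, SD, AUC), and reports each metric's rate of change relative to
#' the standard balanced meal: `(m_meal - m_std) / m_std`.
#'
#' @param model A trained `cgm_diet_model`.
#' @param v_s Individual embedding.
#' @param GB Pre-meal glucose (length `t`).
#' @param kcal Fixed meal calories.
#' @param meal_set Data.frame with columns `meal_id`, `carb_ratio`,
#'   `protein_ratio`, `fat_ratio`; ratios must sum to 1. Default: the
#'   four-meal set (standard 50/20/30, low-carb 30/30/40, high-protein
#'   40/35/25, high-fat 40/15/45).
#' @param standard Which `meal_id` is the reference meal.
#' @return A data.frame, one row per meal, with the curve metrics and
#'   `d_*` rate-of-change columns.
#' @export
perturb_in_silico <- function(model, v_s, GB, kcal = 600,
                              meal_set = default_meal_set(),
                              standard = "standard") {
  stopifnot(inherits(model, "cgm_diet_model"))
  ratios <- meal_set[, c("carb_ratio", "protein_ratio", "fat_ratio")]
  if (any(abs(rowSums(ratios) - 1) > 1e-6)) {
    stop_glycodyn("energy ratios must sum to 1 for every meal",
                  class = "glycodyn_validation_error")
  }
  if (!standard %in% meal_set$meal_id) {
    stop_glycodyn("meal_set must include the standard meal '", standard,
                  "'", class = "glycodyn_validation_error")
  }
  t <- model$config$t
  dt_min <- 60 / t
  rows <- lapply(seq_len(nrow(meal_set)), function(i) {
    D <- c(kcal,
           kcal * meal_set$carb_ratio[i] / 4,
           kcal * meal_set$protein_ratio[i] / 4,
           kcal * meal_set$fat_ratio[i] / 9,
           0)
    fw <- diet_forward(model, v_s, build_input_matrix(
      GB, encode_pulse(D, t)))
    gp <- fw$GP_clipped
    data.frame(meal_id = meal_set$meal_id[i],
               carb_ratio = meal_set$carb_ratio[i],
               protein_ratio = meal_set$protein_ratio[i],
               fat_ratio = meal_set$fat_ratio[i],
               Mean = mean(gp), PG120 = gp[length(gp)], Max = max(gp),
               SD = sd(gp),
               AUC = trapz_auc(seq(0, by = dt_min,
                                   length.out = length(gp)), gp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  std <- out[out$meal_id == standard, , drop = FALSE]
  for (m in c("Mean", "PG120", "Max", "SD", "AUC")) {
    out[[paste0("d_", m)]] <- (out[[m]] - std[[m]]) / std[[m]]
  }
  out
}

#' The default four-meal perturbation set
#'
#' Energy-supply ratios (carbohydrate/protein/fat): standard balanced
#' 50/20/30, low-carbohydrate 30/30/40, high-protein 40/35/25, high-fat
#' 40/15/45.
#'
#' @return A data.frame of meals.
#' @export
default_meal_set <- function() {
  data.frame(meal_id = c("standard", "low_carb", "high_protein",
                         "high_fat"),
             carb_ratio = c(0.50, 0.30, 0.40, 0.40),
             protein_ratio = c(0.20, 0.30, 0.35, 0.15),
             fat_ratio = c(0.30, 0.40, 0.25, 0.45))
}
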