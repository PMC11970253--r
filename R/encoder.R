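# R-side interface to the transformer encoder: configuration, seeded
# initialization, sinusoidal positions, forward pass, masked-token loss,
# and day/sample embedding extraction.

#' Encoder configuration
#'
#' Defaults follow the reference architecture: 4 encoder blocks, 8
#' attention heads, model width 128, feedforward width 4 x 128, vocabulary
#' of 260 glucose tokens plus 3 special tokens, 289 positions.
#'
#' @param n_layers Number of encoder blocks.
#' @param n_heads Attention heads per block; must divide `d_model`.
#' @param d_model Model (embedding) width.
#' @param d_ff Feedforward width (default `4 * d_model`).
#' @param vocab_size Token vocabulary size.
#' @param max_positions Sequence length (CLS + 288 slots).
#' @param dropout Dropout fraction; only 0 is supported (desk-scale runs
#'   do not overfit; the field is kept for forward compatibility).
#' @param tie_weights Share the token-embedding matrix with the output
#'   projection (transposed). Speeds desk-scale convergence; the untied
#'   head remains the default.
#' @param ordinal_init Initialize glucose-token embeddings with their
#'   mg/dL level encoded in the leading coordinates (plus random rest),
#'   so adjacent levels start out similar instead of orthogonal — the
#'   glucose analog of fixed sinusoidal positions. Default `TRUE`.
#' @param seed Initialization seed.
#' @param vocab A `cgm_vocab` supplying the special-token ids.
#' @return A list of class `cgm_encoder_config`.
#' @export
encoder_config <- function(n_layers = 4L, n_heads = 8L, d_model = 128L,
                           d_ff = 4L * d_model, vocab_size = NULL,
                           max_positions = N_SLOTS + 1L, dropout = 0,
                           tie_weights = FALSE, ordinal_init = TRUE,
                           seed = 1L, vocab = token_vocabulary()) {
  if (is.null(vocab_size)) vocab_size <- vocab$size
  if (d_model %% n_heads != 0) {
    stop_glycodyn("d_model must be divisible by n_heads",
                  class = "glycodyn_validation_error")
  }
  if (dropout != 0) {
    stop_glycodyn("only dropout = 0 is supported",
                  class = "glycodyn_validation_error")
  }
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model),
                 d_ff = as.integer(d_ff),
                 vocab_size = as.integer(vocab_size),
                 max_positions = as.integer(max_positions),
                 dropout = dropout,
                 tie_weights = isTRUE(tie_weights),
                 ordinal_init = isTRUE(ordinal_init),
                 seed = as.integer(seed),
                 pad_id = vocab$pad, cls_id = vocab$cls,
                 mask_id = vocab$mask),
            class = "cgm_encoder_config")
}

#' Sinusoidal positional encoding
#'
#' Standard fixed encoding: for position `p` (0-based) and channel pair
#' `2i`, `PE[p, 2i+1] = sin(p / 10000^(2i/d))` and
#' `PE[p, 2i+2] = cos(p / 10000^(2i/d))`, ensuring that nearby time points
#' receive similar position vectors (continuity of time representation).
#'
#' @param max_positions Number of positions.
#' @param d_model Encoding width (even).
#' @return A `max_positions` x `d_model` matrix with entries in `[-1, 1]`.
#' @examples
#' pe <- positional_encoding(289, 128)
#' pe[1, 1:4]   # sin(0), cos(0), sin(0), cos(0)
#' @export
positional_encoding <- function(max_positions, d_model) {
  check_scalar_number(max_positions, "max_positions", lower = 1)
  check_scalar_number(d_model, "d_model", lower = 2)
  p <- seq_len(max_positions) - 1
  i <- seq_len(ceiling(d_model / 2)) - 1
  ang <- outer(p, 1 / 10000^(2 * i / d_model))
  pe <- matrix(0, max_positions, d_model)
  pe[, seq(1, d_model, by = 2)] <- sin(ang)[, seq_along(seq(1, d_model, by = 2))]
  pe[, seq(2, d_model, by = 2)] <- cos(ang)[, seq_along(seq(2, d_model, by = 2))]
  pe
}

# Parameter template: list of name -> dim for a given config (encoder
# only; task layer and classifier head are added by the fine-tuner).
param_shapes <- function(config, n_blocks = config$n_layers,
                         n_classes = NULL) {
  d <- config$d_model; dff <- config$d_ff; V <- config$vocab_size
  shapes <- list(emb = c(V, d))
  for (l in seq_len(n_blocks)) {
    nm <- function(s) sprintf("l%d_%s", l, s)
    shapes[[nm("ln1_g")]] <- c(d, 1); shapes[[nm("ln1_b")]] <- c(d, 1)
    for (s in c("Wq", "Wk", "Wv", "Wo")) shapes[[nm(s)]] <- c(d, d)
    for (s in c("bq", "bk", "bv", "bo")) shapes[[nm(s)]] <- c(d, 1)
    shapes[[nm("ln2_g")]] <- c(d, 1); shapes[[nm("ln2_b")]] <- c(d, 1)
    shapes[[nm("W1")]] <- c(d, dff); shapes[[nm("b1")]] <- c(dff, 1)
    shapes[[nm("W2")]] <- c(dff, d); shapes[[nm("b2")]] <- c(d, 1)
  }
  shapes$lnf_g <- c(d, 1); shapes$lnf_b <- c(d, 1)
  if (!isTRUE(config$tie_weights)) shapes$Wout <- c(d, V)
  shapes$bout <- c(V, 1)
  if (!is.null(n_classes)) {
    shapes$clf_W <- c(d, n_classes); shapes$clf_b <- c(n_classes, 1)
  }
  shapes
}

init_param <- function(name, dim) {
  n_in <- dim[1]; n_out <- dim[2]
  if (grepl("ln", name) && grepl("_g$", name)) {
    matrix(1, dim[1], dim[2])
  } else if (dim[2] == 1 || grepl("^b|_b", name)) {
    matrix(0, dim[1], dim[2])
  } else {
    # Xavier/Glorot uniform
    lim <- sqrt(6 / (n_in + n_out))
    matrix(runif(prod(dim), -lim, lim), dim[1], dim[2])
  }
}

#' Initialize encoder weights
#'
#' Seeded Xavier-uniform initialization for projection matrices, zeros for
#' biases, ones/zeros for layer-norm gains/offsets. Wrapped with the
#' fixed positional encoding into a checkpoint object.
#'
#' @param config A `cgm_encoder_config`.
#' @return A list of class `cgm_checkpoint` with `params`, `config`,
#'   `pos` (positional matrix), `history` (empty) and `checkpoint_id`.
#' @export
init_encoder <- function(config = encoder_config()) {
  stopifnot(inherits(config, "cgm_encoder_config"))
  params <- with_rng_seed(config$seed, {
    shapes <- param_shapes(config)
    p <- lapply(setNames(names(shapes), names(shapes)),
                function(nm) init_param(nm, shapes[[nm]]))
    if (isTRUE(config$ordinal_init)) {
      # smooth ordinal prior over glucose levels: adjacent mg/dL bins
      # start out similar (several scaled basis curves of the level),
      # remaining coordinates keep their random initialization
      n_g <- min(260L, config$vocab_size - 3L)
      lev <- (seq_len(n_g) - (n_g + 1) / 2) / (n_g / 2)  # in ~[-1, 1]
      basis <- cbind(lev, lev^2 - mean(lev^2), sin(pi * lev),
                     cos(pi * lev))
      k <- min(ncol(basis), config$d_model)
      p$emb[seq_len(n_g), seq_len(k)] <- basis[, seq_len(k)] * 0.5
    }
    p
  })
  structure(list(params = params, config = config,
                 pos = positional_encoding(config$max_positions,
                                           config$d_model),
                 history = NULL,
                 checkpoint_id = sprintf("init-seed%d", config$seed)),
            class = "cgm_checkpoint")
}

#' @export
print.cgm_checkpoint <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf(
    "<cgm_checkpoint> %s: %d blocks x %d heads, d_model %d, %d parameters\n",
    x$checkpoint_id, x$config$n_layers, x$config$n_heads,
    x$config$d_model, np))
  invisible(x)
}

seq_id_matrix <- function(seqs) {
  if (inherits(seqs, "cgm_tokens")) seqs <- list(seqs)
  do.call(rbind, lapply(seqs, function(s) s$ids))
}

#' Encoder forward pass
#'
#' Runs token sequences through the encoder in evaluation mode and returns
#' per-position final-layer states, predicted token distributions at
#' requested positions, and (optionally) per-layer attention maps.
#'
#' @param seqs A `cgm_tokens` or list thereof (typically masked sequences).
#' @param checkpoint A `cgm_checkpoint`.
#' @param prob_positions `NULL`, or a list (one element per sequence) of
#'   1-based positions at which the predicted distribution `q` over the
#'   vocabulary is wanted; `"all"` for every position.
#' @param want_states Return final-layer hidden states (default `TRUE`).
#' @param want_attn Return attention maps (`L x L x heads` per layer).
#' @return A list with `states` (list of 289 x d matrices), `probs` (list
#'   of matrices, rows summing to 1) and `attn`.
#' @export
encoder_forward <- function(seqs, checkpoint, prob_positions = NULL,
                            want_states = TRUE, want_attn = FALSE) {
  stopifnot(inherits(checkpoint, "cgm_checkpoint"))
  toks <- seq_id_matrix(seqs)
  if (ncol(toks) != checkpoint$config$max_positions) {
    stop_glycodyn("sequence length ", ncol(toks), " does not match config",
                  class = "glycodyn_validation_error")
  }
  pp <- NULL
  if (!is.null(prob_positions)) {
    if (identical(prob_positions, "all")) {
      pp <- rep(list(seq_len(ncol(toks))), nrow(toks))
    } else {
      if (!is.list(prob_positions)) prob_positions <- list(prob_positions)
      if (length(prob_positions) != nrow(toks)) {
        stop_glycodyn("prob_positions must have one element per sequence",
                      class = "glycodyn_validation_error")
      }
      pp <- lapply(prob_positions, as.integer)
    }
  }
  cpp_encoder_forward(toks, checkpoint$params,
                      unclass(checkpoint$config), checkpoint$pos,
                      pp, want_states, want_attn)
}

#' Masked-token cross-entropy loss
#'
#' `loss = -(1/|T_mask|) * sum over masked positions of log q(true token)`:
#' the standard minimized cross-entropy, averaged over the masked set.
#'
#' @param q Matrix of predicted distributions, one row per masked
#'   position (columns over the vocabulary).
#' @param plan A `cgm_mask_plan` whose `target_ids` align with the rows
#'   of `q`.
#' @return Nonnegative scalar loss.
#' @examples
#' q <- matrix(1 / 260, 2, 260)
#' plan <- structure(list(positions = 2:3, target_ids = c(5L, 9L),
#'                        mask_fraction = NA), class = "cgm_mask_plan")
#' masked_lm_loss(q, plan)  # ln 260
#' @export
masked_lm_loss <- function(q, plan) {
  stopifnot(inherits(plan, "cgm_mask_plan"))
  if (!length(plan$positions)) {
    stop_glycodyn("mask plan is empty", class = "glycodyn_validation_error")
  }
  if (nrow(q) != length(plan$target_ids)) {
    stop_glycodyn("q must have one row per masked position",
                  class = "glycodyn_validation_error")
  }
  if (any(q < 0) || any(abs(rowSums(q) - 1) > 1e-6)) {
    stop_glycodyn("q rows must be probability distributions",
                  class = "glycodyn_validation_error")
  }
  p_true <- q[cbind(seq_len(nrow(q)), plan$target_ids)]
  -mean(log(p_true))
}

#' Day embedding: mean of final-layer token states
#'
#' Encodes an unmasked token sequence and averages the final-layer states
#' over all 289 positions, yielding the d_model-dimensional latent
#' representation of the recorded day.
#'
#' @param seq A `cgm_tokens` (unmasked).
#' @param checkpoint A `cgm_checkpoint`.
#' @return A list of class `cgm_day_embedding` with `vector`,
#'   `subject_id`, `date`, `checkpoint_id`.
#' @export
day_embedding <- function(seq, checkpoint) {
  out <- encoder_forward(seq, checkpoint, want_states = TRUE)
  structure(list(vector = colMeans(out$states[[1L]]),
                 subject_id = seq$subject_id, date = seq$date,
                 checkpoint_id = checkpoint$checkpoint_id),
            class = "cgm_day_embedding")
}

#' Day embeddings for a list of sequences (batched)
#'
#' @param seqs List of `cgm_tokens`.
#' @param checkpoint A `cgm_checkpoint`.
#' @return Matrix with one row per day (rownames `subject_id|date`).
#' @export
embed_days <- function(seqs, checkpoint) {
  out <- encoder_forward(seqs, checkpoint, want_states = TRUE)
  m <- do.call(rbind, lapply(out$states, colMeans))
  rownames(m) <- vapply(seqs, function(s) {
    paste(s$subject_id, s$date, sep = "|")
  }, "")
  m
}

#' Sample embedding: mean of one subject's day embeddings
#'
#' @param days Non-empty list of `cgm_day_embedding` from one subject.
#' @return A list of class `cgm_sample_embedding` with `vector`,
#'   `subject_id`, `n_days`.
#' @export
sample_embedding <- function(days) {
  if (!length(days)) {
    stop_glycodyn("need at least one day embedding",
                  class = "glycodyn_validation_error")
  }
  sids <- unique(vapply(days, function(d) d$subject_id, ""))
  if (length(sids) != 1L) {
    stop_glycodyn("day embeddings mix subjects: ",
                  paste(sids, collapse = ", "),
                  class = "glycodyn_validation_error")
  }
  vecs <- do.call(rbind, lapply(days, function(d) d$vector))
  structure(list(vector = colMeans(vecs), subject_id = sids,
                 n_days = length(days)),
            class = "cgm_sample_embedding")
}

#' Subject-level embeddings for a cohort of day sequences
#'
#' Groups day embeddings by subject and averages them.
#'
#' @param seqs List of `cgm_tokens`.
#' @param checkpoint A `cgm_checkpoint`.
#' @return Matrix of sample embeddings, one row per subject.
#' @export
embed_samples <- function(seqs, checkpoint) {
  dm <- embed_days(seqs, checkpoint)
  sid <- vapply(seqs, function(s) s$subject_id, "")
  m <- do.call(rbind, lapply(split(seq_along(sid), sid), function(idx) {
    colMeans(dm[idx, , drop = FALSE])
  }))
  m
}
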