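# Independent oracles used across tests. These deliberately re-derive
# quantities with the simplest possible code, separate from the package
# implementation paths they check.

# Adjusted Rand index between two partitions.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Tiny encoder configuration for numerically exact / fast tests.
tiny_config <- function(seed = 3L, n_layers = 2L, d_model = 8L) {
  encoder_config(n_layers = n_layers, n_heads = 2L, d_model = d_model,
                 d_ff = 2L * d_model, vocab_size = 12L, max_positions = 7L,
                 seed = seed,
                 vocab = list(pad = 10L, cls = 11L, mask = 12L, size = 12L))
}

# Small "real" encoder for training-based unit tests (full 289 grid,
# real vocabulary, but one narrow block so tests stay fast).
small_real_config <- function(seed = 1L) {
  encoder_config(n_layers = 1L, n_heads = 2L, d_model = 16L, d_ff = 32L,
                 seed = seed)
}

# Brute-force MAGE: enumerate every local extremum by direct comparison,
# take absolute differences of consecutive extrema, filter by 1 SD.
mage_bruteforce <- function(values) {
  g <- values[!is.na(values)]
  s <- sd(g)
  r <- rle(g)$values  # collapse flat runs
  n <- length(r)
  if (n < 3) return(0)
  is_ext <- c(TRUE, vapply(2:(n - 1), function(i) {
    (r[i] > r[i - 1] && r[i] > r[i + 1]) ||
      (r[i] < r[i - 1] && r[i] < r[i + 1])
  }, TRUE), TRUE)
  ext <- r[is_ext]
  amps <- abs(diff(ext))
  amps <- amps[amps > s]
  if (!length(amps)) 0 else mean(amps)
}

# Monte-Carlo oracle for successive weighted sampling without
# replacement: empirical per-position inclusion rate.
weighted_inclusion_oracle <- function(weights, n_draw, reps, seed) {
  counts <- numeric(length(weights))
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      chosen <- sample.int(length(weights), n_draw, prob = weights)
      counts[chosen] <- counts[chosen] + 1
    }
  })
  counts / reps
}

# Independent rank-based AUROC (explicit pair counting).
auroc_paircount <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  cmp <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Deterministic fully present day from a function of minutes-of-day.
day_from_fn <- function(fn, subject_id = "s1", date = "2020-01-01") {
  tmin <- (0:287) * 5
  day_profile(fn(tmin), subject_id = subject_id, date = date)
}

# Six-blob embedding fixture with hierarchical structure: one super-group
# for Normal, one containing two sub-blobs (Pre_I), one containing three
# (Pre_II). Returns embeddings, the planted labels, clinical labels and
# mean-glucose covariate consistent with the taxonomy ordering.
make_planted_blobs <- function(per_blob = 8L, dim = 32L, seed = 7L,
                               within_sd = 0.005) {
  withr::with_seed(seed, {
    super <- matrix(rnorm(3 * dim), 3)
    super <- super / sqrt(rowSums(super^2))
    offsets <- matrix(rnorm(6 * dim, sd = 0.03), 6)
    centers <- rbind(super[1, ],
                     super[2, ] + offsets[2, ], super[2, ] + offsets[3, ],
                     super[3, ] + offsets[4, ], super[3, ] + offsets[5, ],
                     super[3, ] + offsets[6, ])
    blob <- rep(1:6, each = per_blob)
    emb <- centers[blob, ] + matrix(rnorm(6 * per_blob * dim,
                                          sd = within_sd),
                                    6 * per_blob)
    igr_prob <- c(0.05, 0.4, 0.4, 0.8, 0.8, 0.8)[blob]
    clinical <- ifelse(runif(length(blob)) < igr_prob, "IGR", "NGT")
    mean_glucose <- c(95, 105, 112, 118, 126, 133)[blob] +
      rnorm(length(blob), sd = 1)
    list(embeddings = emb, blob = blob, clinical = clinical,
         mean_glucose = mean_glucose)
  })
}
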