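# Vocabulary structure, bin mapping, TF-IDF weights and the masking
# contract.

test_that("vocabulary has 260 glucose ids plus 3 disjoint special ids", {
  v <- token_vocabulary()
  expect_equal(v$n_glucose, 260L)
  expect_equal(v$size, 263L)
  specials <- c(v$pad, v$cls, v$mask)
  expect_length(unique(specials), 3L)
  expect_true(all(specials > v$n_glucose))
  # id_of(level_of(id)) = id for every glucose id
  expect_identical(glucose_to_id(id_to_glucose(1:260)), 1:260)
})

test_that("bin mapping is exhaustive over the 261 clipped integer values", {
  # 261 integers in [40, 300] map onto 260 bins; 300 shares the top bin
  ids <- glucose_to_id(40:300)
  expect_identical(ids[1], 1L)            # 40 mg/dL -> first bin
  expect_identical(ids[261], 260L)        # 300 mg/dL -> top bin
  expect_identical(ids[260], 260L)        # shared with 299
  expect_identical(unique(diff(ids[1:260])), 1L)  # one bin per mg/dL
  expect_identical(sort(unique(ids)), 1:260)
  expect_error(glucose_to_id(301), "outside the clipped range")
  expect_error(glucose_to_id(39.5), "outside the clipped range")
})

test_that("tokenization yields 289 tokens with CLS first, PAD at gaps", {
  v <- token_vocabulary()
  full <- tokenize_day(day_profile(rep(100, 288)))
  expect_length(full$ids, 289L)
  expect_identical(full$ids[1], v$cls)
  expect_equal(sum(full$ids <= v$n_glucose), 288L)

  empty <- tokenize_day(day_profile(rep(NA_real_, 288)))
  expect_identical(empty$ids, c(v$cls, rep(v$pad, 288)))
})

test_that("detokenization round-trips integer days; 300 becomes 299", {
  vals <- withr::with_seed(1, sample(40:299, 288, replace = TRUE))
  day <- day_profile(vals)
  expect_equal(detokenize(tokenize_day(day))$values, as.numeric(vals))

  top <- day_profile(c(300, rep(100, 287)))
  expect_equal(detokenize(tokenize_day(top))$values[1], 299)

  empty <- tokenize_day(day_profile(rep(NA_real_, 288)))
  expect_true(all(is.na(detokenize(empty)$values)))

  bad <- tokenize_day(day_profile(rep(100, 288)))
  bad$ids[5] <- 999L
  expect_error(detokenize(bad), "unknown")
})

test_that("tf-idf weights match a direct counting recomputation", {
  v <- token_vocabulary()
  mk_day <- function(vals) tokenize_day(day_profile(vals))
  corpus <- list(mk_day(rep(c(100, 150), 144)),
                 mk_day(rep(c(100, 200), 144)),
                 mk_day(rep(100, 288)))
  tw <- tfidf_token_weights(corpus, abnormal_boost = 2)
  # token 100 mg/dL appears in every day: smoothed idf = ln(4/4)+1 = 1
  id100 <- glucose_to_id(100)
  expect_equal(tw$idf[id100], 1)
  # direct recomputation for day 2, token 200 (hyperglycemic, boosted)
  id200 <- glucose_to_id(200)
  df200 <- 1                                 # appears in one of 3 days
  idf200 <- log((1 + 3) / (1 + df200)) + 1
  tf200 <- 144                               # occurrences within day 2
  pos200 <- which(corpus[[2]]$ids == id200)[1]
  expect_equal(tw$position_weights[[2]][pos200], tf200 * idf200 * 2)
  # boost: weight equals exactly boost x the unboosted weight
  tw1 <- tfidf_token_weights(corpus, abnormal_boost = 1)
  expect_equal(tw$position_weights[[2]][pos200],
               2 * tw1$position_weights[[2]][pos200])
  # single-day corpus with identical tokens: all weights equal
  tw_one <- tfidf_token_weights(list(mk_day(rep(120, 288))))
  w <- tw_one$position_weights[[1]][-1]
  expect_equal(length(unique(w)), 1L)
  expect_error(tfidf_token_weights(list()), "non-empty")
})

test_that("masking respects the fraction range and never hits CLS/PAD", {
  v <- token_vocabulary()
  vals <- rep(100, 288)
  vals[1:48] <- NA  # PAD block
  seq <- tokenize_day(day_profile(vals))
  mk <- withr::with_seed(2, apply_masking(seq))
  expect_false(1L %in% mk$plan$positions)
  expect_true(all(seq$ids[mk$plan$positions] != v$pad))
  expect_true(all(mk$masked$ids[mk$plan$positions] == v$mask))
  expect_identical(mk$plan$target_ids,
                   seq$ids[mk$plan$positions])
  expect_true(mk$plan$mask_fraction >= 0.45 - 0.01 &&
                mk$plan$mask_fraction <= 0.60 + 0.01)

  none <- withr::with_seed(2, apply_masking(seq, fraction_range = c(0, 0)))
  expect_length(none$plan$positions, 0L)
  expect_identical(none$masked$ids, seq$ids)

  expect_error(apply_masking(seq, fraction_range = c(0.2, 1.4)),
               "fraction_range")
  all_pad <- tokenize_day(day_profile(rep(NA_real_, 288)))
  expect_error(apply_masking(all_pad), "no maskable")
})

test_that("mean realized masked fraction lies in [0.45, 0.60]", {
  seq <- tokenize_day(day_profile(rep(100, 288)))
  fracs <- withr::with_seed(3, vapply(1:300, function(i) {
    apply_masking(seq)$plan$mask_fraction
  }, 0))
  expect_gte(mean(fracs), 0.45)
  expect_lte(mean(fracs), 0.60)
})

test_that("equal weights reduce to uniform position sampling", {
  # chi-squared goodness of fit of inclusion counts against uniform
  seq <- tokenize_day(day_profile(rep(100, 288)))
  counts <- withr::with_seed(4, {
    cnt <- numeric(288)
    for (i in 1:2000) {
      pos <- apply_masking(seq, fraction_range = c(0.1, 0.1))$plan$positions
      cnt[pos - 1L] <- cnt[pos - 1L] + 1
    }
    cnt
  })
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("boosted tokens are masked about boost-times more often", {
  # uniform tf-idf by construction (every level appears 12 times in a
  # single-day corpus) so the weights differ only by the boost; low
  # masking fraction keeps successive sampling near-proportional
  levels_mix <- c(seq(100, 155, by = 5), seq(185, 240, by = 5))
  vals <- rep(levels_mix, each = 12)
  day <- day_profile(vals)
  hyper_slots <- which(vals > 180)
  seq <- tokenize_day(day)
  tw <- tfidf_token_weights(list(seq), abnormal_boost = 2)
  w <- tw$position_weights[[1]]
  # implementation-side empirical inclusion rates
  cnt <- withr::with_seed(5, {
    cnt <- numeric(289)
    for (i in 1:4000) {
      pos <- apply_masking(seq, w, fraction_range = c(0.1, 0.1))$plan$positions
      cnt[pos] <- cnt[pos] + 1
    }
    cnt / 4000
  })
  hyper_pos <- hyper_slots + 1L
  eu_pos <- setdiff(2:289, hyper_pos)
  ratio <- mean(cnt[hyper_pos]) / mean(cnt[eu_pos])
  # independent Monte-Carlo oracle of the same sampling weights
  oracle <- weighted_inclusion_oracle(w[-1L], n_draw = round(0.1 * 288),
                                      reps = 4000, seed = 99)
  oracle_ratio <- mean(oracle[hyper_pos - 1L]) / mean(oracle[eu_pos - 1L])
  expect_lt(abs(ratio - oracle_ratio) / oracle_ratio, 0.1)
  expect_gt(ratio, 1.5)  # boost 2 with mild saturation
})

test_that("vocabulary round-trips through its JSON serialization", {
  path <- withr::local_tempfile(fileext = ".json")
  write_vocab_json(token_vocabulary(), path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$n_glucose, 260L)
  expect_equal(nrow(j$table), 260L)
  expect_equal(j$table$level_mg_dl[260], 299L)
  v <- read_vocab_json(path)
  expect_identical(v, token_vocabulary())
})
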