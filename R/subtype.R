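# Non-diabetes subtyping: two-stage hierarchical clustering of sample
# embeddings on cosine distance, the six-label taxonomy, and assignment of
# new samples by argmax mean cosine similarity.

SUBTYPE_TAXONOMY <- c("Normal", "Pre_Ia", "Pre_Ib",
                      "Pre_IIa", "Pre_IIb", "Pre_IIc")

#' Fit the six-subtype reference by two-stage hierarchical clustering
#'
#' Stage 1 clusters the labelled (NGT/IGR) sample embeddings on cosine
#' distance (`1 - cosine similarity`) and cuts the tree at three clusters,
#' named `Normal`, `Pre_I`, `Pre_II` by increasing IGR fraction. Stage 2
#' re-clusters `Pre_I` into two and `Pre_II` into three sub-clusters,
#' named `a`/`b`(/`c`) by ascending mean glucose of their members, giving
#' the six-subtype taxonomy.
#'
#' @param embeddings Numeric matrix, one row per sample (e.g. from
#'   [embed_samples()]).
#' @param clinical_labels Character vector (`"NGT"`/`"IGR"`) per sample,
#'   used for stage-1 naming.
#' @param mean_glucose Numeric vector of per-sample mean glucose (mg/dL),
#'   used for deterministic stage-2 naming.
#' @param profiles Optional list of per-sample `cgm_day` lists for median
#'   profiles.
#' @param linkage Agglomeration method (default `"average"`).
#' @return A list of class `cgm_subtype_reference`: `embeddings`,
#'   `subtype` (factor over the six labels), `clinical_labels`,
#'   `mean_glucose`, `profiles`, `linkage`.
#' @export
fit_subtype_reference <- function(embeddings, clinical_labels,
                                  mean_glucose, profiles = NULL,
                                  linkage = "average") {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n < 6L) {
    stop_glycodyn("need at least 6 samples to fit six subtypes",
                  class = "glycodyn_validation_error")
  }
  stopifnot(length(clinical_labels) == n, length(mean_glucose) == n)
  sim <- cosine_sim_matrix(embeddings)
  d <- 1 - sim
  if (max(d) < 1e-12) {
    stop_glycodyn("degenerate input: all embeddings are identical ",
                  "(cosine distances all zero); cannot cut three clusters",
                  class = "glycodyn_degenerate_error")
  }
  cl3 <- cutree(hclust(as.dist(d), method = linkage), k = 3L)
  # name stage-1 clusters by increasing IGR fraction (ties: mean glucose)
  igr_frac <- vapply(1:3, function(k) {
    mean(clinical_labels[cl3 == k] == "IGR")
  }, 0)
  mg3 <- vapply(1:3, function(k) mean(mean_glucose[cl3 == k]), 0)
  stage1_names <- c("Normal", "Pre_I", "Pre_II")[order(order(igr_frac, mg3))]
  stage1 <- stage1_names[cl3]

  subtype <- character(n)
  subtype[stage1 == "Normal"] <- "Normal"
  for (spec in list(list(parent = "Pre_I", k = 2L, suffix = c("a", "b")),
                    list(parent = "Pre_II", k = 3L,
                         suffix = c("a", "b", "c")))) {
    idx <- which(stage1 == spec$parent)
    if (length(idx) < spec$k) {
      stop_glycodyn("cluster ", spec$parent, " has ", length(idx),
                    " member(s); cannot split into ", spec$k,
                    " sub-clusters", class = "glycodyn_degenerate_error")
    }
    dsub <- d[idx, idx, drop = FALSE]
    if (max(dsub) < 1e-12) {
      stop_glycodyn("degenerate cluster ", spec$parent,
                    ": identical embeddings",
                    class = "glycodyn_degenerate_error")
    }
    sub <- cutree(hclust(as.dist(dsub), method = linkage), k = spec$k)
    # a/b/c by ascending mean glucose of sub-cluster members
    mg <- vapply(seq_len(spec$k), function(k) {
      mean(mean_glucose[idx[sub == k]])
    }, 0)
    sub_names <- paste0(spec$parent, spec$suffix)[order(order(mg))]
    subtype[idx] <- sub_names[sub]
  }
  subtype <- factor(subtype, levels = SUBTYPE_TAXONOMY)
  if (any(table(subtype) == 0L)) {
    stop_glycodyn("fitting did not produce six non-empty subtypes",
                  class = "glycodyn_degenerate_error")
  }
  structure(list(embeddings = embeddings, subtype = subtype,
                 clinical_labels = clinical_labels,
                 mean_glucose = mean_glucose, profiles = profiles,
                 linkage = linkage),
            class = "cgm_subtype_reference")
}

#' @export
print.cgm_subtype_reference <- function(x, ...) {
  cat("<cgm_subtype_reference>\n")
  print(table(x$subtype))
  invisible(x)
}

#' Assign a sample to a subtype by mean cosine similarity
#'
#' Scores each subtype `t` as `|sum of cosine similarities to the members
#' of t| / |t|` and assigns the argmax; ties break in fixed taxonomy
#' order (Normal first) with a warning.
#'
#' @param sample A `cgm_sample_embedding`, or a numeric vector.
#' @param ref A fitted `cgm_subtype_reference`.
#' @param absolute Apply the absolute value to the summed similarity (the
#'   printed rule; set `FALSE` to rank by the signed mean).
#' @return A list of class `cgm_subtype_assignment`: `subtype`, `scores`
#'   (named per-subtype mean similarity), `subject_id`.
#' @export
assign_subtype <- function(sample, ref, absolute = TRUE) {
  stopifnot(inherits(ref, "cgm_subtype_reference"))
  v <- if (inherits(sample, "cgm_sample_embedding")) sample$vector else
    as.numeric(sample)
  if (length(v) != ncol(ref$embeddings)) {
    stop_glycodyn("sample dimension ", length(v),
                  " does not match reference dimension ",
                  ncol(ref$embeddings),
                  class = "glycodyn_validation_error")
  }
  if (sqrt(sum(v^2)) == 0) {
    stop_glycodyn("zero-norm sample vector",
                  class = "glycodyn_validation_error")
  }
  sims <- apply(ref$embeddings, 1L, cosine_sim, y = v)
  scores <- vapply(SUBTYPE_TAXONOMY, function(t) {
    s <- sum(sims[ref$subtype == t])
    if (absolute) abs(s) / sum(ref$subtype == t) else
      s / sum(ref$subtype == t)
  }, 0)
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    warning("subtype score tie; breaking in taxonomy order (Normal first)")
  }
  structure(list(subtype = SUBTYPE_TAXONOMY[best[1L]],
                 scores = scores,
                 subject_id = if (inherits(sample, "cgm_sample_embedding"))
                   sample$subject_id else NA_character_),
            class = "cgm_subtype_assignment")
}

#' Slot-wise median CGM profile of a subtype
#'
#' @param ref A `cgm_subtype_reference` fitted with `profiles`.
#' @param subtype_label One of the six taxonomy labels.
#' @return A `cgm_day` holding the slot-wise median over the member days
#'   (present slots only; a slot missing everywhere stays missing).
#' @export
median_profile <- function(ref, subtype_label) {
  stopifnot(inherits(ref, "cgm_subtype_reference"))
  subtype_label <- match.arg(subtype_label, SUBTYPE_TAXONOMY)
  if (is.null(ref$profiles)) {
    stop_glycodyn("reference was fitted without day profiles",
                  class = "glycodyn_validation_error")
  }
  idx <- which(ref$subtype == subtype_label)
  if (!length(idx)) {
    stop_glycodyn("subtype ", subtype_label, " is empty",
                  class = "glycodyn_validation_error")
  }
  days <- unlist(ref$profiles[idx], recursive = FALSE)
  vals <- vapply(seq_len(N_SLOTS), function(s) {
    x <- unlist(lapply(days, function(d) {
      if (d$present[s]) d$values[s] else NULL
    }))
    if (length(x)) median(x) else NA_real_
  }, 0)
  day_profile(vals, subject_id = paste0("median_", subtype_label),
              date = "median")
}
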