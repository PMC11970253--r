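# Internal helpers shared across modules.

N_SLOTS <- 288L          # 5-minute slots per day
SLOT_MIN <- 5L           # grid spacing, minutes
GLUCOSE_MIN <- 40        # physiological clip range, mg/dL
GLUCOSE_MAX <- 300
HYPO_MGDL <- 70          # hypoglycemia threshold (exclusive)
HYPER_MGDL <- 180        # hyperglycemia threshold (exclusive)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' restoring the caller's RNG state on exit so that library calls do not
#' perturb user-level reproducibility.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_rng_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_glycodyn <- function(..., class = "glycodyn_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_glycodyn(name, " must be a finite numeric scalar",
                  class = "glycodyn_validation_error")
  }
  if (x < lower || x > upper) {
    stop_glycodyn(name, " must be in [", lower, ", ", upper, "], got ", x,
                  class = "glycodyn_validation_error")
  }
  invisible(x)
}

#' Cosine similarity between vectors
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar cosine similarity.
#' @keywords internal
cosine_sim <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop_glycodyn("cosine similarity undefined for zero-norm vector",
                  class = "glycodyn_validation_error")
  }
  sum(x * y) / (nx * ny)
}

# Pairwise cosine similarity matrix for rows of a matrix.
cosine_sim_matrix <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    stop_glycodyn("cosine similarity undefined for zero-norm row",
                  class = "glycodyn_validation_error")
  }
  s <- tcrossprod(m / nrm)
  s[s > 1] <- 1
  s[s < -1] <- -1
  s
}

#' Area under the ROC curve by rank statistic
#'
#' Computes the one-vs-rest AUROC for a numeric score against a binary
#' truth using the Mann-Whitney rank statistic with mid-ranks for ties.
#'
#' @param scores Numeric vector of predicted scores (higher = positive).
#' @param positive Logical vector marking positive cases.
#' @return Scalar AUROC in `[0, 1]`, or `NA` if truth is single-class.
#' @export
auroc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    warning("AUROC undefined for single-class truth; returning NA")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Format minutes-of-day as HH:MM:SS
fmt_time_of_day <- function(minutes) {
  h <- floor(minutes / 60)
  m <- floor(minutes %% 60)
  s <- round((minutes %% 1) * 60)
  sprintf("%02d:%02d:%02d", h, m, s)
}
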