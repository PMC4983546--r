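# Label-swapping max-statistic permutation threshold for the correlated
# family of PRS association tests.
#
# Per permutation, one shared random permutation is applied to the sample
# indices of every PRS column (breaking all PRS-outcome links while
# preserving outcome-covariate structure and inter-PRS correlation), every
# test in the family is refit, and the maximum |z| is recorded. The
# empirical (1 - alpha) quantile of these maxima is the family-wise
# significance cutoff.

#' Permutation configuration
#'
#' @param n_perm Number of label-swapping permutations (default 10000).
#' @param alpha Family-wise error level (default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @return A `perm_config` list.
#' @export
perm_config <- function(n_perm = 10000, alpha = 0.05, seed = 1L) {
  stopifnot(n_perm >= 1, alpha > 0, alpha < 1)
  structure(list(n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed)),
            class = "perm_config")
}

#' Specify one test of a permutation family
#'
#' An OLS test contributes the t-statistic of the PRS coefficient from
#' `y ~ covariates + prs`; a multinomial test contributes the z-statistic
#' of the PRS coefficient for one non-reference involvement level.
#'
#' @param type "ols" or "multinom".
#' @param outcome Outcome vector (continuous for "ols", 0-based levels for
#'   "multinom").
#' @param prs_col Name or index of the PRS column within the PRS matrix
#'   handed to [permute_family()].
#' @param covars Optional numeric covariate matrix.
#' @param level For "multinom": which non-reference level's z to report
#'   (1-based).
#' @param label Optional label carried into results.
#' @return A `perm_test` list.
#' @export
perm_test <- function(type = c("ols", "multinom"), outcome, prs_col,
                      covars = NULL, level = 1L, label = NULL) {
  type <- match.arg(type)
  structure(list(type = type, outcome = outcome, prs_col = prs_col,
                 covars = covars, level = as.integer(level),
                 label = label %||% paste0(type, ":", prs_col)),
            class = "perm_test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Precompute what an OLS test needs so each permutation is two small
# matrix-vector products: t = <x_perp, y> * sqrt(df) / sqrt(|x_perp|^2 rss).
prep_ols <- function(test, n) {
  x0 <- cbind(rep(1, n), test$covars)
  qx <- qr(x0)
  q <- qr.Q(qx)
  y <- as.numeric(test$outcome)
  y_perp <- y - q %*% crossprod(q, y)
  list(q = q, y = y, y_perp = y_perp, yp2 = sum(y_perp^2),
       df = n - ncol(x0) - 1)
}

ols_z <- function(prep, x) {
  x_perp <- x - prep$q %*% crossprod(prep$q, x)
  xp2 <- sum(x_perp^2)
  if (xp2 <= 0) return(0)
  bxy <- sum(x_perp * prep$y)
  rss <- prep$yp2 - bxy^2 / xp2
  if (rss <= 0) return(Inf)
  bxy / sqrt(xp2) / sqrt(rss / prep$df)
}

multinom_z <- function(test, x) {
  fit <- tryCatch(
    multinomial_fit(test$outcome, x, covars = test$covars,
                    standardize = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  fit$prs$z[test$level]
}

#' Max-|z| label-swapping permutation threshold
#'
#' @param prs Numeric matrix of PRS columns (samples x scores); each column
#'   is z-scored before use so multinomial refits skip re-standardization.
#' @param tests List of [perm_test()] specifications.
#' @param config A [perm_config()].
#' @return A `perm_threshold`: z_crit (empirical (1-alpha) quantile of the
#'   null maxima, taken as the ceiling((1-alpha) n_perm)-th order
#'   statistic), null_max_abs_z, alpha, n_perm, seed, observed z per test,
#'   and n_failed (permuted fits that failed to converge; they contribute
#'   |z| = 0 and are counted).
#' @export
permute_family <- function(prs, tests, config = perm_config()) {
  if (!length(tests)) stop("the test family is empty")
  prs <- as.matrix(prs)
  n <- nrow(prs)
  prs <- scale(prs)
  preps <- lapply(tests, function(tt) {
    if (tt$type == "ols") prep_ols(tt, n) else NULL
  })
  get_z <- function(tt, prep, x) {
    if (tt$type == "ols") ols_z(prep, x) else multinom_z(tt, x)
  }
  observed <- vapply(seq_along(tests), function(i) {
    get_z(tests[[i]], preps[[i]], prs[, tests[[i]]$prs_col])
  }, numeric(1))
  if (anyNA(observed))
    stop("a family test failed to fit on the observed data")
  n_failed <- 0L
  null_max <- withr::with_seed(config$seed, {
    vapply(seq_len(config$n_perm), function(b) {
      idx <- sample.int(n)
      zs <- vapply(seq_along(tests), function(i) {
        z <- get_z(tests[[i]], preps[[i]], prs[idx, tests[[i]]$prs_col])
        if (is.na(z)) {
          n_failed <<- n_failed + 1L
          0
        } else abs(z)
      }, numeric(1))
      max(zs)
    }, numeric(1))
  })
  z_crit <- sort(null_max)[ceiling((1 - config$alpha) * config$n_perm)]
  structure(list(z_crit = z_crit, null_max_abs_z = null_max,
                 alpha = config$alpha, n_perm = config$n_perm,
                 seed = config$seed, observed = observed,
                 labels = vapply(tests, `[[`, "", "label"),
                 n_failed = n_failed),
            class = "perm_threshold")
}

#' Flag results against a permutation threshold
#'
#' Adds a logical `significant` column: `|z| >= z_crit` (the threshold
#' itself counts as significant).
#'
#' @param results data.frame containing a `z` column (may be empty).
#' @param threshold A `perm_threshold` from [permute_family()].
#' @return `results` with a `significant` column appended.
#' @export
apply_threshold <- function(results, threshold) {
  results$significant <- if (nrow(results) == 0) logical(0) else
    abs(results$z) >= threshold$z_crit
  results
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf(
    "Permutation threshold: |z| >= %.4f (alpha = %g, %d permutations)\n",
    x$z_crit, x$alpha, x$n_perm))
  if (x$n_failed > 0)
    cat(x$n_failed, "permuted fits failed and contributed |z| = 0\n")
  invisible(x)
}
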