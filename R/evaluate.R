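#' Stratified train/test split
#'
#' Partitions tumor and normal samples independently: a fraction
#' \code{train_fraction} of each stratum (rounded to the nearest integer,
#' at least 1 and at most n-1) is assigned to \code{train}, the rest to
#' \code{test}. Deterministic given \code{seed}; the caller's RNG state is
#' left untouched.
#'
#' @param labels Label data frame.
#' @param train_fraction Proportion in (0, 1); default 0.75.
#' @param seed Integer seed.
#' @return \code{labels} with a \code{cohort} column added/replaced.
#' @export
stratified_split <- function(labels, train_fraction = 0.75, seed) {
  stopifnot(train_fraction > 0, train_fraction < 1, !missing(seed))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  labels$cohort <- NA_character_
  for (st in c("tumor", "normal")) {
    idx <- which(labels$status == st)
    n <- length(idx)
    if (n == 0L) next
    if (n < 2L) {
      stop("stratum '", st, "' has fewer than 2 samples; cannot split",
           call. = FALSE)
    }
    n_train <- floor(n * train_fraction + 0.5)
    n_train <- min(max(n_train, 1L), n - 1L)
    train_idx <- sample(idx, n_train)
    labels$cohort[train_idx] <- "train"
    labels$cohort[setdiff(idx, train_idx)] <- "test"
  }
  labels
}

#' Wilson score confidence interval for a proportion
#'
#' Score interval without continuity correction (the \code{conf.int} of
#' \code{\link[stats]{prop.test}} with \code{correct = FALSE}).
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level; default 0.95.
#' @return Numeric vector \code{c(lower, upper)} in \[0, 1\].
#' @examples
#' wilson_ci(89, 101)  # ~ (0.804, 0.931)
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n,
            level > 0, level < 1)
  # prop.test's chi-squared warning concerns its test statistic at small
  # counts, not the score interval extracted here
  ci <- suppressWarnings(
    stats::prop.test(successes, n, conf.level = level,
                     correct = FALSE))$conf.int
  c(lower = ci[1L], upper = ci[2L])
}

# Integer percent, half-up (display rounding; round() is banker's).
percent_half_up <- function(p) {
  as.integer(floor(p * 100 + 0.5))
}

#' Evaluate a fitted combination set on a labelled cohort
#'
#' Classifies each cohort sample with [predict.hit_cover()] and reports
#' confusion counts, sensitivity TP/(TP+FN), specificity TN/(TN+FP) and
#' Wilson 95\% score intervals. A cohort with no tumor (normal) samples
#' yields \code{NA} sensitivity (specificity) rather than zero.
#'
#' @param object A fitted \code{hit_cover} object.
#' @param x Binary mutation matrix containing the cohort samples.
#' @param labels Label data frame.
#' @param cohort Restrict to this \code{cohort} value (\code{"train"} /
#'   \code{"test"}); \code{NULL} uses every labelled sample present in
#'   \code{x}.
#' @param level Confidence level for the intervals; default 0.95.
#' @return An object of class \code{"hit_eval"}: list with \code{counts}
#'   (tp/fp/tn/fn), \code{sensitivity}, \code{specificity},
#'   \code{sensitivity_ci}, \code{specificity_ci}, \code{n_tumor},
#'   \code{n_normal}, \code{cohort}.
#' @export
evaluate_cover <- function(object, x, labels, cohort = NULL,
                           level = 0.95) {
  lab <- labels
  if (!is.null(cohort)) {
    stopifnot("cohort" %in% names(lab))
    lab <- lab[lab$cohort == cohort, , drop = FALSE]
  }
  lab <- lab[lab$sample_id %in% rownames(x), , drop = FALSE]
  if (nrow(lab) == 0L) stop("empty evaluation cohort", call. = FALSE)
  pred <- predict(object, x[lab$sample_id, , drop = FALSE])
  is_t <- lab$status == "tumor"
  called_t <- as.character(pred) == "tumor"
  counts <- c(tp = sum(is_t & called_t), fp = sum(!is_t & called_t),
              tn = sum(!is_t & !called_t), fn = sum(is_t & !called_t))
  sens_from_counts(counts, level = level, cohort = cohort)
}

# Shared constructor: evaluation result from raw confusion counts.
sens_from_counts <- function(counts, level = 0.95, cohort = NULL) {
  n_t <- counts[["tp"]] + counts[["fn"]]
  n_n <- counts[["tn"]] + counts[["fp"]]
  sens <- if (n_t > 0) counts[["tp"]] / n_t else NA_real_
  spec <- if (n_n > 0) counts[["tn"]] / n_n else NA_real_
  structure(list(
    counts = counts,
    sensitivity = sens, specificity = spec,
    sensitivity_ci = if (n_t > 0) wilson_ci(counts[["tp"]], n_t, level)
                     else c(lower = NA_real_, upper = NA_real_),
    specificity_ci = if (n_n > 0) wilson_ci(counts[["tn"]], n_n, level)
                     else c(lower = NA_real_, upper = NA_real_),
    n_tumor = n_t, n_normal = n_n, level = level, cohort = cohort
  ), class = "hit_eval")
}

#' Evaluation result from printed confusion counts
#'
#' Builds a [evaluate_cover()]-style result directly from confusion
#' counts, e.g. to recompute a published table row.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @param level Confidence level.
#' @return A \code{hit_eval} object.
#' @examples
#' r <- eval_from_counts(tp = 89, fn = 12, tn = 74, fp = 12)
#' r$sensitivity       # 89/101
#' @export
eval_from_counts <- function(tp, fp, tn, fn, level = 0.95) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  sens_from_counts(c(tp = tp, fp = fp, tn = tn, fn = fn), level = level)
}

#' @export
print.hit_eval <- function(x, ...) {
  fmt_ci <- function(ci) {
    if (anyNA(ci)) return("NA")
    sprintf("%d–%d%%", percent_half_up(ci[["lower"]]),
            percent_half_up(ci[["upper"]]))
  }
  fmt_pt <- function(p) if (is.na(p)) "NA" else
    sprintf("%d%%", percent_half_up(p))
  if (!is.null(x$cohort)) cat("Cohort:", x$cohort, "\n")
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d (%d tumor, %d normal)\n",
              x$counts[["tp"]], x$counts[["fp"]], x$counts[["tn"]],
              x$counts[["fn"]], x$n_tumor, x$n_normal))
  cat(sprintf("Sensitivity: %s (%.0f%% CI %s)\n", fmt_pt(x$sensitivity),
              100 * x$level, fmt_ci(x$sensitivity_ci)))
  cat(sprintf("Specificity: %s (%.0f%% CI %s)\n", fmt_pt(x$specificity),
              100 * x$level, fmt_ci(x$specificity_ci)))
  invisible(x)
}

#' Aggregate evaluation results by summing confusion counts
#'
#' Combines per-cancer-type (or otherwise disjoint) evaluations into a
#' single result with summed counts, i.e. a "Total" row.
#'
#' @param ... \code{hit_eval} objects, or a single list of them.
#' @return A \code{hit_eval} object with aggregated counts.
#' @export
aggregate_evals <- function(...) {
  evs <- list(...)
  if (length(evs) == 1L && !inherits(evs[[1L]], "hit_eval")) {
    evs <- evs[[1L]]
  }
  stopifnot(length(evs) >= 1L,
            all(vapply(evs, inherits, TRUE, "hit_eval")))
  counts <- Reduce(`+`, lapply(evs, `[[`, "counts"))
  sens_from_counts(counts, level = evs[[1L]]$level)
}
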