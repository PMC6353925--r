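#' @export
print.hit_cover <- function(x, ...) {
  cat("Multi-hit combination model (greedy weighted set cover)\n")
  cat(sprintf("  %d combination(s) of %d gene(s), alpha = %g\n",
              length(x$combinations), x$config$h, x$config$alpha))
  cat(sprintf("  fitted on %d tumor / %d normal samples",
              x$n_tumor, x$n_normal))
  if (!is.null(x$config$cohort)) cat(sprintf(" (%s cohort)", x$config$cohort))
  cat("\n")
  if (length(x$uncoverable) > 0L) {
    cat(sprintf("  %d tumor sample(s) uncoverable\n", length(x$uncoverable)))
  }
  cat(sprintf("  total weight W = %.4f\n", x$total_weight))
  if (length(x$combinations) > 0L) {
    cat("  combinations:", paste(vapply(x$combinations, paste, "",
                                        collapse = "+"),
                                 collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.hit_cover <- function(object, ...) {
  tab <- object$table
  structure(list(
    n_combinations = length(object$combinations),
    table = tab,
    total_weight = object$total_weight,
    n_tumor = object$n_tumor, n_normal = object$n_normal,
    uncoverable = object$uncoverable,
    training_tpr = if (object$n_tumor > 0)
      1 - length(object$uncoverable) / object$n_tumor else NA_real_,
    config = object$config
  ), class = "summary.hit_cover")
}

#' @export
print.summary.hit_cover <- function(x, ...) {
  cat("Greedy weighted set cover solution\n\n")
  cat(sprintf("Combinations selected : %d\n", x$n_combinations))
  cat(sprintf("Total weight W        : %.4f\n", x$total_weight))
  cat(sprintf("Cohort                : %d tumor / %d normal\n",
              x$n_tumor, x$n_normal))
  cat(sprintf("Training coverage     : %.1f%% of tumors\n",
              100 * x$training_tpr))
  if (length(x$uncoverable) > 0L) {
    cat(sprintf("Uncoverable tumors    : %s\n",
                paste(x$uncoverable, collapse = ", ")))
  }
  cat("\nPer-iteration selection trace:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Extract the selected combinations
#'
#' @param object A fitted \code{hit_cover} object.
#' @param ... Unused.
#' @return The per-iteration selection table (one row per combination,
#'   with confusion counts and weight at selection time).
#' @export
coef.hit_cover <- function(object, ...) {
  object$table
}

#' Classify samples with a fitted combination set
#'
#' A sample is called \code{tumor} when it is covered by (mutated in all
#' genes of) at least one selected combination, else \code{normal}. An
#' empty solution predicts \code{normal} for every sample. Genes of the
#' model absent from \code{newdata}'s columns are treated as unmutated,
#' with a warning.
#'
#' @param object A fitted \code{hit_cover} object.
#' @param newdata Binary mutation matrix to classify.
#' @param ... Unused.
#' @return Factor with levels \code{normal}, \code{tumor}, named by
#'   sample.
#' @export
predict.hit_cover <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  hit <- rep(FALSE, nrow(newdata))
  model_genes <- unique(unlist(object$combinations))
  absent <- setdiff(model_genes, colnames(newdata))
  if (length(absent) > 0L) {
    warning("model gene(s) absent from newdata treated as unmutated: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  for (g in object$combinations) {
    present <- intersect(g, colnames(newdata))
    if (length(present) < length(g)) next  # an absent gene can't be covered
    hit <- hit | rowSums(newdata[, present, drop = FALSE]) == length(g)
  }
  factor(ifelse(hit, "tumor", "normal"), levels = c("normal", "tumor")) |>
    stats::setNames(rownames(newdata))
}

#' Plot a fitted combination set
#'
#' Barplot of the fraction of fitting-cohort tumors newly covered at each
#' greedy iteration, annotated with the selected gene pair and its weight.
#'
#' @param x A fitted \code{hit_cover} object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.hit_cover <- function(x, ...) {
  tab <- x$table
  if (nrow(tab) == 0L) {
    stop("empty solution: nothing to plot", call. = FALSE)
  }
  frac <- tab$n_covered_tumor / x$n_tumor
  bp <- graphics::barplot(frac, names.arg = tab$genes, las = 2,
                          ylab = "fraction of tumors newly covered",
                          main = "Greedy cover selection order", ...)
  graphics::text(bp, frac, labels = sprintf("w=%.2f", tab$weight),
                 pos = 3, cex = 0.7, xpd = NA)
  invisible(x)
}

#' Residual-style misclassification indicator
#'
#' For each sample of \code{newdata} with a label, 0 when the predicted
#' class matches the label and 1 otherwise.
#'
#' @param object A fitted \code{hit_cover} object.
#' @param newdata Binary mutation matrix.
#' @param labels Label data frame.
#' @param ... Unused.
#' @return Named integer vector of 0/1 misclassification indicators.
#' @export
residuals.hit_cover <- function(object, newdata, labels, ...) {
  pred <- predict(object, newdata)
  truth <- labels$status[match(names(pred), labels$sample_id)]
  res <- as.integer(as.character(pred) != truth)
  names(res) <- names(pred)
  res
}
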