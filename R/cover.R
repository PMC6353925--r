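#' Does a sample cover a gene combination?
#'
#' A sample is covered by a combination when it carries a protein-altering
#' mutation in \emph{every} gene of the combination.
#'
#' @param sample_row Named binary vector (one row of a mutation matrix) or
#'   a single-row matrix.
#' @param genes Character vector of combination genes (length >= 1).
#' @return \code{TRUE} iff all combination genes are mutated.
#' @export
covers <- function(sample_row, genes) {
  if (is.matrix(sample_row)) sample_row <- sample_row[1L, ]
  stopifnot(length(genes) >= 1L)
  absent <- setdiff(genes, names(sample_row))
  if (length(absent) > 0L) {
    stop("gene(s) not in matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  all(sample_row[genes] == 1L)
}

#' Confusion counts for a combination over a cohort
#'
#' Tumor samples covered by all genes of the combination are true
#' positives, uncovered tumors false negatives; normal samples covered are
#' false positives, uncovered normals true negatives. Counts are taken over
#' the \code{active} sample subset only (all samples by default); an empty
#' active set yields all-zero counts.
#'
#' @param genes Character vector of combination genes.
#' @param x Binary mutation matrix (samples x genes).
#' @param labels Label data frame covering the matrix samples.
#' @param active Character vector of active sample ids (subset of
#'   \code{rownames(x)}); default all.
#' @return Named integer vector \code{c(tp, fp, tn, fn)}.
#' @export
confusion_counts <- function(genes, x, labels, active = rownames(x)) {
  stopifnot(all(active %in% rownames(x)))
  absent <- setdiff(genes, colnames(x))
  if (length(absent) > 0L) {
    stop("gene(s) not in matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (length(active) == 0L) {
    return(c(tp = 0L, fp = 0L, tn = 0L, fn = 0L))
  }
  covered <- rowSums(x[active, genes, drop = FALSE]) == length(genes)
  status <- labels$status[match(active, labels$sample_id)]
  if (anyNA(status)) {
    stop("active sample(s) missing from labels", call. = FALSE)
  }
  is_t <- status == "tumor"
  c(tp = sum(covered & is_t), fp = sum(covered & !is_t),
    tn = sum(!covered & !is_t), fn = sum(!covered & is_t))
}

#' Weight of a combination
#'
#' The inverse of the scaled accuracy metric,
#' \deqn{w = \left(\frac{\alpha\,TP + TN}{N_t + N_n}\right)^{-1},}
#' where \eqn{N_t} and \eqn{N_n} are the active tumor and normal totals and
#' \eqn{0 \le \alpha \le 1} balances sensitivity against specificity.
#' Lower weight means higher likelihood that the combination is
#' carcinogenic. When \eqn{\alpha TP + TN = 0} the weight is
#' \code{Inf} (the combination is useless).
#'
#' @param tp,tn True-positive and true-negative counts.
#' @param n_tumor,n_normal Active tumor and normal sample totals.
#' @param alpha Scaling factor in \[0, 1\]; default 0.1.
#' @return Positive numeric weight, possibly \code{Inf}.
#' @examples
#' combination_weight(tp = 10, tn = 10, n_tumor = 10, n_normal = 10,
#'                    alpha = 0.1)  # 20/11
#' @export
combination_weight <- function(tp, tn, n_tumor, n_normal, alpha = 0.1) {
  stopifnot(alpha >= 0, alpha <= 1, tp >= 0, tn >= 0,
            n_tumor + n_normal >= 1, tp <= n_tumor, tn <= n_normal)
  denom <- alpha * tp + tn
  ifelse(denom == 0, Inf, (n_tumor + n_normal) / denom)
}

#' Number of candidate multi-hit combinations
#'
#' \eqn{M = \sum_{c=2}^{h_{max}} \binom{G}{c}}: the candidate count for up
#' to \code{h_max} hits over \code{G} genes. Returned as a double; for
#' genome-scale G the value far exceeds exact integer range but retains 15
#' significant digits, ample for the order-of-magnitude accounting this
#' quantity is used for.
#'
#' @param G Gene count.
#' @param h_max Maximum hits (>= 2).
#' @return Numeric candidate count.
#' @examples
#' search_space_size(20000, 8)   # ~6e29
#' search_space_size(4, 2)       # 6
#' @export
search_space_size <- function(G, h_max) {
  stopifnot(G >= h_max, h_max >= 2)
  sum(choose(G, 2:h_max))
}

#' Greedy cover complexity product
#'
#' The greedy algorithm recomputes all \eqn{M} candidate weights for each
#' of at most \eqn{N} iterations, so its complexity is \eqn{O(NM)}.
#'
#' @param G Gene count.
#' @param N Tumor sample count.
#' @param h_max Maximum hits.
#' @return Numeric \eqn{N \cdot M}.
#' @examples
#' greedy_complexity(20000, N = 200, h_max = 2)  # ~4e10
#' @export
greedy_complexity <- function(G, N, h_max = 2) {
  N * search_space_size(G, h_max)
}

#' Enumerate candidate gene combinations
#'
#' Yields every sorted h-tuple of distinct genes that covers at least one
#' active tumor sample (TP >= 1), in lexicographic order. Tuples that
#' cover no tumor can never enter a cover and are pruned exactly.
#'
#' @param x Binary mutation matrix.
#' @param labels Label data frame.
#' @param active Active sample ids; default all.
#' @param h Hits per combination (>= 1).
#' @return Character matrix with \code{h} rows, one column per candidate
#'   (the \code{combn} layout); zero columns when no candidate exists.
#' @export
enumerate_candidates <- function(x, labels, active = rownames(x), h = 2) {
  stopifnot(h >= 1)
  status <- labels$status[match(active, labels$sample_id)]
  tum <- active[status == "tumor"]
  xt <- x[tum, , drop = FALSE]
  # only genes mutated in >=1 active tumor can appear in a TP>=1 tuple
  gene_pool <- sort(colnames(x)[colSums(xt) > 0L])
  if (length(gene_pool) < h) {
    return(matrix(character(0), nrow = h, ncol = 0))
  }
  cand <- utils::combn(gene_pool, h)
  tp <- apply(cand, 2L, function(g) {
    sum(rowSums(xt[, g, drop = FALSE]) == h)
  })
  cand[, tp >= 1L, drop = FALSE]
}

# Score all gene pairs over the active samples in one shot.
# Returns list(pairs = 2 x M character, tp, fp, weight) in lexicographic
# pair order. Cross products of the binary tumor/normal submatrices give
# TP and FP for every pair at once.
.score_pairs <- function(x, tum, nor, alpha) {
  genes <- colnames(x)
  xt <- x[tum, , drop = FALSE]
  keep <- colSums(xt) > 0L          # TP>=1 requires both genes tumor-mutated
  xt <- xt[, keep, drop = FALSE]
  xn <- x[nor, keep, drop = FALSE]
  g <- colnames(xt)
  ng <- length(g)
  if (ng < 2L) {
    return(list(pairs = matrix(character(0), 2, 0),
                tp = integer(0), fp = integer(0), weight = numeric(0)))
  }
  ord <- order(g)
  xt <- xt[, ord, drop = FALSE]; xn <- xn[, ord, drop = FALSE]
  g <- g[ord]
  tp_mat <- crossprod(xt)
  fp_mat <- crossprod(xn)
  ut <- upper.tri(tp_mat)
  idx <- which(ut, arr.ind = TRUE)
  # column-major order of upper triangle == lexicographic pair order
  tp <- tp_mat[ut]
  fp <- fp_mat[ut]
  sel <- tp >= 1L
  idx <- idx[sel, , drop = FALSE]; tp <- tp[sel]; fp <- fp[sel]
  tn <- length(nor) - fp
  w <- combination_weight(tp, tn, length(tum), length(nor), alpha)
  list(pairs = rbind(g[idx[, 1L]], g[idx[, 2L]]),
       tp = as.integer(tp), fp = as.integer(fp), weight = w)
}

# Generic candidate scoring for arbitrary h (used for h != 2).
.score_tuples <- function(x, tum, nor, alpha, h) {
  cand <- enumerate_candidates(
    x, data.frame(sample_id = c(tum, nor),
                  status = rep(c("tumor", "normal"),
                               c(length(tum), length(nor))),
                  stringsAsFactors = FALSE),
    active = c(tum, nor), h = h)
  m <- ncol(cand)
  if (m == 0L) {
    return(list(pairs = cand, tp = integer(0), fp = integer(0),
                weight = numeric(0)))
  }
  xt <- x[tum, , drop = FALSE]
  xn <- x[nor, , drop = FALSE]
  tp <- integer(m); fp <- integer(m)
  for (j in seq_len(m)) {
    g <- cand[, j]
    tp[j] <- sum(rowSums(xt[, g, drop = FALSE]) == h)
    fp[j] <- sum(rowSums(xn[, g, drop = FALSE]) == h)
  }
  tn <- length(nor) - fp
  w <- combination_weight(tp, tn, length(tum), length(nor), alpha)
  list(pairs = cand, tp = tp, fp = fp, weight = w)
}

# Deterministic, order-independent pick among scored candidates:
# minimum weight, then maximum TP, then lexicographically smallest tuple.
.pick_best <- function(sc) {
  if (length(sc$weight) == 0L) return(NULL)
  best_w <- min(sc$weight)
  cand <- if (is.finite(best_w)) which(sc$weight == best_w) else
    seq_along(sc$weight)
  cand <- cand[sc$tp[cand] == max(sc$tp[cand])]
  if (length(cand) > 1L) {
    keys <- apply(sc$pairs[, cand, drop = FALSE], 2L, paste,
                  collapse = "\r")
    cand <- cand[order(keys, method = "radix")[1L]]
  }
  list(genes = sc$pairs[, cand], tp = sc$tp[cand], fp = sc$fp[cand],
       weight = sc$weight[cand])
}

#' Fit a multi-hit combination model by greedy weighted set cover
#'
#' Maps tumor/normal discrimination to weighted set cover: the universe is
#' the set of (training) tumor samples, each candidate h-gene combination
#' covers the tumors mutated in all of its genes, and its weight is the
#' inverse scaled accuracy \eqn{((\alpha TP + TN)/(N_t+N_n))^{-1}}
#' computed over the samples still active. Each iteration recomputes all
#' candidate weights over the unselected samples, greedily takes the
#' lowest-weight combination (ties: larger TP, then lexicographically
#' smallest gene tuple), then excludes the samples it covers — covered
#' tumors always, covered normals when
#' \code{exclude_covered_normals = TRUE} — and repeats until every tumor is
#' covered. On the fitting cohort the solution therefore attains a true
#' positive rate of 1.0 whenever every tumor is coverable; tumors with
#' fewer than \code{h} mutated genes are reported as uncoverable and the
#' partial solution is returned.
#'
#' @param x Binary mutation matrix (samples x genes), e.g. from
#'   [build_mutation_matrix()] or [simulate_cohort()].
#' @param labels Label data frame with \code{sample_id} and \code{status};
#'   if it has a \code{cohort} column and \code{cohort} is not \code{NULL},
#'   fitting is restricted to that partition.
#' @param alpha Scaling factor in \[0, 1\] balancing sensitivity against
#'   specificity; default 0.1.
#' @param h Genes per combination; default 2. Genome-scale \code{h >= 3} is
#'   computationally out of reach for this exhaustive-enumeration fitter.
#' @param cohort Which labelled partition to fit on (\code{"train"} by
#'   default when labels carry a \code{cohort} column, otherwise all
#'   samples).
#' @param exclude_covered_normals Exclude covered normal samples from
#'   later iterations (default \code{TRUE}); set \code{FALSE} to keep all
#'   normals active throughout.
#' @param min_tumor_freq Optional pre-filter: drop genes mutated in fewer
#'   than this fraction of fitting-cohort tumors before enumeration
#'   (default 0 = no pre-filter).
#' @return An object of class \code{"hit_cover"}: a list with
#'   \code{combinations} (list of gene vectors, selection order),
#'   \code{table} (per-iteration data frame: genes, active totals,
#'   tp/fp/tn/fn at selection, weight, newly covered tumors),
#'   \code{total_weight}, \code{uncoverable} (tumor ids left uncovered),
#'   \code{config}, \code{n_tumor}, \code{n_normal}, \code{samples},
#'   \code{call}.
#' @seealso [predict.hit_cover()], [evaluate_cover()],
#'   [exhaustive_best_step()]
#' @examples
#' sim <- simulate_cohort(n_genes = 20, n_comb = 2, n_tumor = 10,
#'                        n_normal = 10, p_background = 0, seed = 1)
#' fit <- hit_cover(sim$matrix, sim$labels)
#' fit
#' @export
hit_cover <- function(x, labels, alpha = 0.1, h = 2, cohort = NULL,
                      exclude_covered_normals = TRUE,
                      min_tumor_freq = 0) {
  stopifnot(is.matrix(x), all(x %in% c(0L, 1L)),
            alpha >= 0, alpha <= 1, h >= 1)
  cl <- match.call()
  if (is.null(cohort) && "cohort" %in% names(labels)) cohort <- "train"
  lab <- labels
  if (!is.null(cohort)) {
    if (!"cohort" %in% names(lab)) {
      stop("labels have no 'cohort' column; use stratified_split() first ",
           "or pass cohort = NULL", call. = FALSE)
    }
    lab <- lab[lab$cohort == cohort, , drop = FALSE]
  }
  lab <- lab[lab$sample_id %in% rownames(x), , drop = FALSE]
  tum <- lab$sample_id[lab$status == "tumor"]
  nor <- lab$sample_id[lab$status == "normal"]
  if (length(tum) == 0L) {
    sol <- .empty_solution(alpha, h, cohort, exclude_covered_normals,
                           length(tum), length(nor), lab$sample_id, cl)
    return(sol)
  }
  if (min_tumor_freq > 0) {
    freq <- colSums(x[tum, , drop = FALSE]) / length(tum)
    x <- x[, freq >= min_tumor_freq, drop = FALSE]
  }
  # tumors with < h mutated genes can never be covered
  coverable <- rowSums(x[tum, , drop = FALSE]) >= h
  uncoverable <- tum[!coverable]
  if (length(uncoverable) > 0L) {
    warning(length(uncoverable), " tumor sample(s) have fewer than ", h,
            " mutated genes and cannot be covered", call. = FALSE)
  }
  active_t <- tum[coverable]
  active_n <- nor
  combos <- list()
  rows <- list()
  it <- 0L
  while (length(active_t) > 0L) {
    it <- it + 1L
    sc <- if (h == 2L) .score_pairs(x, active_t, active_n, alpha)
          else .score_tuples(x, active_t, active_n, alpha, h)
    best <- .pick_best(sc)
    if (is.null(best)) {
      # no candidate covers any remaining tumor (possible after pre-filter)
      uncoverable <- c(uncoverable, active_t)
      warning(length(active_t), " active tumor sample(s) not coverable by ",
              "any candidate; returning partial solution", call. = FALSE)
      break
    }
    g <- best$genes
    cov_t <- active_t[rowSums(x[active_t, g, drop = FALSE]) == h]
    cov_n <- active_n[rowSums(x[active_n, g, drop = FALSE]) == h]
    rows[[it]] <- data.frame(
      iteration = it,
      genes = paste(g, collapse = "+"),
      n_active_tumor = length(active_t),
      n_active_normal = length(active_n),
      tp = best$tp, fp = best$fp,
      tn = length(active_n) - best$fp,
      fn = length(active_t) - best$tp,
      weight = best$weight,
      n_covered_tumor = length(cov_t),
      stringsAsFactors = FALSE
    )
    combos[[it]] <- g
    active_t <- setdiff(active_t, cov_t)
    if (exclude_covered_normals) active_n <- setdiff(active_n, cov_n)
  }
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    .empty_trace()
  structure(list(
    combinations = combos,
    table = tab,
    total_weight = sum(tab$weight),
    uncoverable = uncoverable,
    config = list(alpha = alpha, h = h, cohort = cohort,
                  exclude_covered_normals = exclude_covered_normals,
                  min_tumor_freq = min_tumor_freq),
    n_tumor = length(tum), n_normal = length(nor),
    samples = lab$sample_id,
    call = cl
  ), class = "hit_cover")
}

.empty_trace <- function() {
  data.frame(iteration = integer(0), genes = character(0),
             n_active_tumor = integer(0), n_active_normal = integer(0),
             tp = integer(0), fp = integer(0), tn = integer(0),
             fn = integer(0), weight = numeric(0),
             n_covered_tumor = integer(0), stringsAsFactors = FALSE)
}

.empty_solution <- function(alpha, h, cohort, excl, nt, nn, samples, cl) {
  structure(list(
    combinations = list(), table = .empty_trace(), total_weight = 0,
    uncoverable = character(0),
    config = list(alpha = alpha, h = h, cohort = cohort,
                  exclude_covered_normals = excl, min_tumor_freq = 0),
    n_tumor = nt, n_normal = nn, samples = samples, call = cl
  ), class = "hit_cover")
}

#' Brute-force minimum-weight combination over active samples
#'
#' Independent exhaustive scorer for one greedy step: evaluates every
#' h-tuple of distinct genes by direct per-tuple confusion counting and
#' returns the minimum-weight one under the same deterministic tie rule as
#' [hit_cover()] (larger TP, then lexicographically smallest tuple).
#' Intended as a per-iteration oracle on small instances.
#'
#' @param x Binary mutation matrix.
#' @param labels Label data frame.
#' @param active Active sample ids.
#' @param alpha Scaling factor.
#' @param h Hits per combination.
#' @param max_candidates Refuse instances with more candidate tuples than
#'   this cap (default 10000).
#' @return List with \code{genes}, \code{tp}, \code{fp}, \code{weight}.
#' @export
exhaustive_best_step <- function(x, labels, active = rownames(x),
                                 alpha = 0.1, h = 2,
                                 max_candidates = 10000) {
  n_cand <- choose(ncol(x), h)
  if (n_cand > max_candidates) {
    stop("instance too large for exhaustive scoring (", n_cand,
         " candidate tuples > cap ", max_candidates, ")", call. = FALSE)
  }
  status <- labels$status[match(active, labels$sample_id)]
  n_t <- sum(status == "tumor")
  n_n <- sum(status == "normal")
  cand <- utils::combn(sort(colnames(x)), h)
  tp <- integer(0); fp <- integer(0); w <- numeric(0)
  keep <- matrix(character(0), nrow = h, ncol = 0)
  for (j in seq_len(ncol(cand))) {
    g <- cand[, j]
    cc <- confusion_counts(g, x, labels, active)
    if (cc[["tp"]] < 1L) next
    keep <- cbind(keep, g)
    tp <- c(tp, cc[["tp"]]); fp <- c(fp, cc[["fp"]])
    w <- c(w, combination_weight(cc[["tp"]], cc[["tn"]], n_t, n_n, alpha))
  }
  best <- .pick_best(list(pairs = keep, tp = tp, fp = fp, weight = w))
  if (is.null(best) || !is.finite(best$weight)) {
    stop("no usable candidate combination (all weights infinite or TP=0)",
         call. = FALSE)
  }
  best
}
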