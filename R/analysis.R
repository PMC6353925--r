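#' Pearson correlation between gene mutation profiles
#'
#' For each gene in a combination, form the 0/1 vector of per-sample
#' mutation status over one cohort (normal samples by default — a
#' correlation there suggests a shared non-carcinogenic cause such as a
#' passenger process or a structural chromosomal event) and correlate the
#' two genes. A zero-variance vector makes the coefficient undefined: it
#' is returned as \code{NA} with a warning, never coerced to 0.
#'
#' @param gene1,gene2 Gene symbols (matrix columns).
#' @param x Binary mutation matrix.
#' @param labels Label data frame.
#' @param cohort_status Which samples to correlate over: \code{"normal"}
#'   (default) or \code{"tumor"}.
#' @return Pearson r in \[-1, 1\], or \code{NA}.
#' @export
gene_correlation <- function(gene1, gene2, x, labels,
                             cohort_status = c("normal", "tumor")) {
  cohort_status <- match.arg(cohort_status)
  absent <- setdiff(c(gene1, gene2), colnames(x))
  if (length(absent) > 0L) {
    stop("gene(s) not in matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  ids <- labels$sample_id[labels$status == cohort_status]
  ids <- intersect(ids, rownames(x))
  if (length(ids) < 2L) stop("need >= 2 samples in cohort", call. = FALSE)
  v1 <- x[ids, gene1]
  v2 <- x[ids, gene2]
  if (stats::var(v1) == 0 || stats::var(v2) == 0) {
    warning("zero-variance mutation vector; correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(v1, v2)
}

#' Correlation report for all genes within each selected combination
#'
#' @param object A fitted \code{hit_cover} object.
#' @param x Binary mutation matrix.
#' @param labels Label data frame.
#' @param threshold Flag pairs with |r| at or above this value as
#'   correlated; default 0.25.
#' @param cohort_status Cohort to correlate over; default \code{"normal"}.
#' @return Data frame with one row per within-combination gene pair:
#'   genes, r, and a \code{correlated} flag.
#' @export
combination_correlations <- function(object, x, labels, threshold = 0.25,
                                     cohort_status = "normal") {
  rows <- lapply(object$combinations, function(g) {
    prs <- utils::combn(sort(g), 2)
    data.frame(
      combination = paste(g, collapse = "+"),
      gene1 = prs[1L, ], gene2 = prs[2L, ],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$r <- mapply(function(a, b) {
    suppressWarnings(gene_correlation(a, b, x, labels,
                                      cohort_status = cohort_status))
  }, out$gene1, out$gene2)
  out$correlated <- !is.na(out$r) & abs(out$r) >= threshold
  out
}

#' Occurrence and overlap statistics of selected combinations
#'
#' For each combination, the fraction of tumor samples covered (fractions
#' can sum past 100\% because one tumor can carry several combinations);
#' plus the distribution of combinations per tumor and the fraction of
#' tumors carrying two or more.
#'
#' @param object A fitted \code{hit_cover} object (non-empty).
#' @param x Binary mutation matrix.
#' @param labels Label data frame.
#' @param cohort Restrict to this cohort partition; \code{NULL} = all.
#' @return List with \code{occurrence} (data frame: combination, n
#'   covered, fraction), \code{per_sample} (integer vector: combinations
#'   per tumor), \code{overlap_histogram} (table over counts) and
#'   \code{multi_fraction}.
#' @export
combination_statistics <- function(object, x, labels, cohort = NULL) {
  stopifnot(length(object$combinations) > 0L)
  lab <- labels
  if (!is.null(cohort)) lab <- lab[lab$cohort == cohort, , drop = FALSE]
  tum <- intersect(lab$sample_id[lab$status == "tumor"], rownames(x))
  xt <- x[tum, , drop = FALSE]
  cov <- vapply(object$combinations, function(g) {
    present <- intersect(g, colnames(xt))
    if (length(present) < length(g)) return(rep(FALSE, length(tum)))
    rowSums(xt[, present, drop = FALSE]) == length(g)
  }, logical(length(tum)))
  cov <- matrix(cov, nrow = length(tum))  # tumors x combinations
  per_sample <- rowSums(cov)
  names(per_sample) <- tum
  occurrence <- data.frame(
    combination = vapply(object$combinations, paste, "", collapse = "+"),
    n_covered = colSums(cov),
    fraction = colSums(cov) / length(tum),
    stringsAsFactors = FALSE
  )
  list(
    occurrence = occurrence,
    per_sample = per_sample,
    overlap_histogram = table(per_sample),
    multi_fraction = mean(per_sample >= 2)
  )
}

#' Same-chromosome flag for each selected combination
#'
#' Genes of a combination on one chromosome would hint at a shared
#' structural cause rather than independent hits; this flags such
#' combinations given a gene-location table.
#'
#' @param object A fitted \code{hit_cover} object.
#' @param locations Data frame with columns \code{gene} and
#'   \code{chromosome} (extra columns such as start/end are ignored).
#' @return List with \code{flags} (data frame: combination,
#'   same_chromosome — \code{NA} when any gene lacks a location) and
#'   \code{n_same_chromosome} (count over combinations with known
#'   locations).
#' @export
chromosome_colocation <- function(object, locations) {
  stopifnot(all(c("gene", "chromosome") %in% names(locations)))
  same <- vapply(object$combinations, function(g) {
    chr <- locations$chromosome[match(g, locations$gene)]
    if (anyNA(chr)) return(NA)
    length(unique(chr)) == 1L
  }, logical(1L))
  if (anyNA(same)) {
    warning(sum(is.na(same)), " combination(s) with unknown gene ",
            "location excluded from the same-chromosome summary",
            call. = FALSE)
  }
  list(
    flags = data.frame(
      combination = vapply(object$combinations, paste, "", collapse = "+"),
      same_chromosome = same,
      stringsAsFactors = FALSE
    ),
    n_same_chromosome = sum(same, na.rm = TRUE)
  )
}

#' Tumor-versus-normal locus contrast within a combination gene
#'
#' Among samples covered by a combination, tabulates per-position
#' protein-altering variant counts in one of its genes separately for
#' tumor and normal samples, and partitions the observed positions into
#' tumor-exclusive (candidate drivers), shared (candidate passengers) and
#' normal-exclusive. Positions are genomic (chromosome, 1-based
#' coordinate), a proxy for protein residue positions: consequence
#' annotation is outside this package's scope.
#'
#' @param gene A gene belonging to \code{combination}.
#' @param combination Character vector of combination genes.
#' @param records Variant-record data frame (tumor and normal calls, see
#'   [read_maf()]) with an \code{is_tumor} column.
#' @param x Binary mutation matrix used to determine coverage.
#' @param labels Label data frame.
#' @return List of class \code{"locus_profile"}: \code{positions} (data
#'   frame: chromosome, position, n_tumor, n_normal, class),
#'   \code{tumor_exclusive}, \code{shared}, \code{normal_exclusive}
#'   (character keys "chromosome:position"), \code{gene},
#'   \code{combination}.
#' @export
locus_contrast <- function(gene, combination, records, x, labels) {
  stopifnot(gene %in% combination)
  covered_ids <- rownames(x)[
    rowSums(x[, combination, drop = FALSE]) == length(combination)]
  rec <- records[records$gene == gene &
                   records$sample_id %in% covered_ids &
                   is_protein_altering(records$variant_classification), ,
                 drop = FALSE]
  if (nrow(rec) == 0L) {
    pos <- data.frame(chromosome = character(0), position = integer(0),
                      n_tumor = integer(0), n_normal = integer(0),
                      class = character(0), stringsAsFactors = FALSE)
    return(structure(list(positions = pos, tumor_exclusive = character(0),
                          shared = character(0),
                          normal_exclusive = character(0),
                          gene = gene, combination = combination),
                     class = "locus_profile"))
  }
  status <- labels$status[match(rec$sample_id, labels$sample_id)]
  key <- paste0(rec$chromosome, ":", rec$position)
  tab_t <- table(key[status == "tumor"])
  tab_n <- table(key[status == "normal"])
  keys <- sort(unique(key))
  n_t <- as.integer(tab_t[keys]); n_t[is.na(n_t)] <- 0L
  n_n <- as.integer(tab_n[keys]); n_n[is.na(n_n)] <- 0L
  cls <- ifelse(n_t > 0L & n_n == 0L, "tumor_exclusive",
                ifelse(n_t > 0L & n_n > 0L, "shared", "normal_exclusive"))
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  pos <- data.frame(chromosome = parts[, 1L],
                    position = as.integer(parts[, 2L]),
                    n_tumor = n_t, n_normal = n_n, class = cls,
                    stringsAsFactors = FALSE)
  structure(list(positions = pos,
                 tumor_exclusive = keys[cls == "tumor_exclusive"],
                 shared = keys[cls == "shared"],
                 normal_exclusive = keys[cls == "normal_exclusive"],
                 gene = gene, combination = combination),
            class = "locus_profile")
}

#' @export
print.locus_profile <- function(x, ...) {
  cat(sprintf("Locus contrast for %s in combination %s\n", x$gene,
              paste(x$combination, collapse = "+")))
  cat(sprintf("  %d position(s): %d tumor-exclusive (candidate drivers), ",
              nrow(x$positions), length(x$tumor_exclusive)))
  cat(sprintf("%d shared (candidate passengers), %d normal-exclusive\n",
              length(x$shared), length(x$normal_exclusive)))
  if (nrow(x$positions) > 0L) print(x$positions, row.names = FALSE)
  invisible(x)
}
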