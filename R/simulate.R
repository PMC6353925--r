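#' Simulate a tumor/normal cohort with planted multi-hit combinations
#'
#' Generates binary gene-mutation profiles under a planted-signal model:
#' each tumor sample receives one planted h-gene combination (all of its
#' genes set mutated), drawn according to \code{weights}, plus a second
#' distinct combination with probability \code{p_multi} (emulating tumors
#' that carry multiple combinations); every sample, tumor and normal,
#' additionally receives independent passenger background mutations at
#' per-gene rate \code{p_background}. Normal samples never receive a
#' planted combination. Background is independent across genes and
#' samples: no mutational-signature or clonal structure is modelled.
#' Deterministic given \code{seed}; the caller's RNG state is untouched.
#'
#' @param n_genes Number of genes G.
#' @param n_comb Number of planted combinations K (disjoint gene sets;
#'   requires \code{K * h <= G}).
#' @param h Genes per planted combination; default 2.
#' @param n_tumor,n_normal Cohort sizes.
#' @param p_background Per-sample, per-gene passenger mutation
#'   probability; default 0.05.
#' @param p_multi Probability a tumor carries a second planted
#'   combination; default 0.3.
#' @param weights Assignment weights over the K combinations (recycled /
#'   normalized); default uniform.
#' @param seed Integer seed (required: cohorts are meant to be
#'   reproducible).
#' @return List with \code{matrix} (binary, samples x all G genes),
#'   \code{labels}, \code{planted} (list of K gene vectors),
#'   \code{truth} (data frame: tumor sample, primary and optional
#'   secondary planted combination index).
#' @examples
#' sim <- simulate_cohort(n_genes = 30, n_comb = 3, n_tumor = 20,
#'                        n_normal = 20, p_background = 0, seed = 7)
#' table(sim$labels$status)
#' @export
simulate_cohort <- function(n_genes = 60, n_comb = 5, h = 2,
                            n_tumor = 80, n_normal = 60,
                            p_background = 0.05, p_multi = 0.3,
                            weights = NULL, seed) {
  stopifnot(!missing(seed), n_comb >= 1, h >= 1,
            p_background >= 0, p_background <= 1,
            p_multi >= 0, p_multi <= 1,
            n_tumor >= 0, n_normal >= 0)
  if (n_comb * h > n_genes) {
    stop("infeasible model: n_comb * h = ", n_comb * h, " > n_genes = ",
         n_genes, call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, n_comb)
  stopifnot(length(weights) == n_comb, all(weights >= 0),
            sum(weights) > 0)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  genes <- sprintf("G%0*d", nchar(n_genes), seq_len(n_genes))
  planted_genes <- sample(genes, n_comb * h)
  planted <- lapply(seq_len(n_comb), function(k) {
    sort(planted_genes[((k - 1L) * h + 1L):(k * h)])
  })
  tum_ids <- sprintf("TUMOR%0*d", nchar(n_tumor), seq_len(n_tumor))
  nor_ids <- sprintf("NORM%0*d", nchar(n_normal), seq_len(n_normal))
  samples <- c(tum_ids, nor_ids)
  m <- matrix(
    as.integer(stats::runif(length(samples) * n_genes) < p_background),
    nrow = length(samples), ncol = n_genes,
    dimnames = list(samples, genes))

  primary <- if (n_tumor > 0)
    sample.int(n_comb, n_tumor, replace = TRUE, prob = weights)
  else integer(0)
  secondary <- rep(NA_integer_, n_tumor)
  for (i in seq_len(n_tumor)) {
    m[tum_ids[i], planted[[primary[i]]]] <- 1L
    if (n_comb > 1L && stats::runif(1) < p_multi) {
      k2 <- sample(setdiff(seq_len(n_comb), primary[i]), 1L)
      m[tum_ids[i], planted[[k2]]] <- 1L
      secondary[i] <- k2
    }
  }
  # sorted sample rows, matching the deterministic layout of
  # build_mutation_matrix so MAF round-trips are identity
  ord <- order(rownames(m))
  m <- m[ord, , drop = FALSE]
  labels <- cohort_labels(samples,
                          rep(c("tumor", "normal"),
                              c(n_tumor, n_normal)))
  labels <- labels[order(labels$sample_id), , drop = FALSE]
  rownames(labels) <- NULL
  list(matrix = m, labels = labels, planted = planted,
       truth = data.frame(sample_id = tum_ids, primary = primary,
                          secondary = secondary,
                          stringsAsFactors = FALSE))
}

# Deterministic per-gene annotation used when writing a synthetic MAF:
# chromosome, locus and a protein-altering classification, all fixed by
# the gene's position in the sorted gene list so round-trips are stable.
.gene_annotation <- function(genes) {
  idx <- seq_along(genes)
  classes <- protein_altering_classes()
  data.frame(
    gene = genes,
    chromosome = as.character((idx - 1L) %% 22L + 1L),
    position = idx * 1000L,
    variant_classification = classes[(idx - 1L) %% length(classes) + 1L],
    stringsAsFactors = FALSE
  )
}

#' Write a mutation matrix as a MAF-dialect file
#'
#' Emits one variant row per nonzero (sample, gene) entry with a
#' deterministic protein-altering \code{Variant_Classification} and a
#' deterministic synthetic chromosome/position per gene, so that reading
#' the file back with [read_maf()] and [build_mutation_matrix()]
#' reproduces the matrix (restricted to genes with at least one mutated
#' sample — an all-zero gene column has no variant rows to carry it).
#'
#' @param x Binary mutation matrix.
#' @param labels Optional label data frame; when given, every matrix
#'   sample must be labelled.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_maf <- function(x, labels = NULL, path) {
  if (!is.null(labels)) {
    missing_ids <- setdiff(rownames(x), labels$sample_id)
    if (length(missing_ids) > 0L) {
      stop("matrix sample(s) missing from labels: ",
           paste(utils::head(missing_ids, 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  idx <- which(x == 1L, arr.ind = TRUE)
  ann <- .gene_annotation(colnames(x))
  rows <- data.frame(
    Hugo_Symbol = colnames(x)[idx[, "col"]],
    Chromosome = ann$chromosome[idx[, "col"]],
    Start_Position = ann$position[idx[, "col"]],
    Variant_Classification = ann$variant_classification[idx[, "col"]],
    Tumor_Sample_Barcode = rownames(x)[idx[, "row"]],
    stringsAsFactors = FALSE
  )
  rows <- rows[order(rows$Tumor_Sample_Barcode, rows$Hugo_Symbol), ,
               drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#version synthetic-maf-dialect", con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Gene-location table for a synthetic cohort
#'
#' The deterministic chromosome/locus assignment used by [write_maf()],
#' in the gene-location TSV layout consumed by
#' [chromosome_colocation()].
#'
#' @param genes Character vector of gene symbols.
#' @return Data frame with columns gene, chromosome, start, end.
#' @export
synthetic_gene_locations <- function(genes) {
  ann <- .gene_annotation(genes)
  data.frame(gene = ann$gene, chromosome = ann$chromosome,
             start = ann$position, end = ann$position + 999L,
             stringsAsFactors = FALSE)
}
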