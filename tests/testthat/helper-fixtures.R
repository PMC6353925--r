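# In-code fixtures shared across test files.

# Binary matrix from a named list of per-sample mutated gene sets.
toy_matrix <- function(profiles, genes = sort(unique(unlist(profiles)))) {
  samples <- names(profiles)
  m <- matrix(0L, nrow = length(samples), ncol = length(genes),
              dimnames = list(samples, genes))
  for (s in samples) m[s, intersect(profiles[[s]], genes)] <- 1L
  m
}

toy_labels <- function(tumors, normals) {
  cohort_labels(c(tumors, normals),
                rep(c("tumor", "normal"),
                    c(length(tumors), length(normals))))
}

# Write a minimal MAF-dialect file; rows = list of character vectors
# (sample, gene, chrom, pos, classification).
write_toy_maf <- function(rows, path, comment = NULL) {
  header <- paste("Hugo_Symbol", "Chromosome", "Start_Position",
                  "Variant_Classification", "Tumor_Sample_Barcode",
                  sep = "\t")
  lines <- vapply(rows, function(r) {
    paste(r[2L], r[3L], r[4L], r[5L], r[1L], sep = "\t")
  }, "")
  writeLines(c(comment, header, lines), path)
  path
}

# Random labelled instance for property-style tests (small, dense).
random_instance <- function(n_genes, n_tumor, n_normal, p = 0.3) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  samples <- c(sprintf("t%02d", seq_len(n_tumor)),
               sprintf("n%02d", seq_len(n_normal)))
  m <- matrix(rbinom(length(samples) * n_genes, 1L, p),
              nrow = length(samples),
              dimnames = list(samples, genes))
  storage.mode(m) <- "integer"
  list(matrix = m,
       labels = toy_labels(samples[seq_len(n_tumor)],
                           samples[n_tumor + seq_len(n_normal)]))
}

# Replay a fitted greedy solution step by step, returning for each
# iteration the active tumor/normal sets as the algorithm would see them.
replay_active_sets <- function(fit, x, labels) {
  lab <- labels
  if (!is.null(fit$config$cohort) && "cohort" %in% names(lab)) {
    lab <- lab[lab$cohort == fit$config$cohort, , drop = FALSE]
  }
  tum <- lab$sample_id[lab$status == "tumor"]
  nor <- lab$sample_id[lab$status == "normal"]
  h <- fit$config$h
  tum <- tum[rowSums(x[tum, , drop = FALSE]) >= h]
  steps <- list()
  for (i in seq_along(fit$combinations)) {
    steps[[i]] <- list(tumor = tum, normal = nor)
    g <- fit$combinations[[i]]
    cov_t <- tum[rowSums(x[tum, g, drop = FALSE]) == h]
    cov_n <- nor[rowSums(x[nor, g, drop = FALSE]) == h]
    tum <- setdiff(tum, cov_t)
    if (fit$config$exclude_covered_normals) nor <- setdiff(nor, cov_n)
  }
  steps
}

# Closed-form Wilson score interval, written independently of the
# implementation path (which goes through prop.test).
wilson_reference <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(centre - half, centre + half) / (1 + z^2 / n)
}
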