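#' Protein-altering variant classifications
#'
#' The default set of MAF \code{Variant_Classification} terms treated as
#' protein-altering: non-synonymous substitutions, nonsense/nonstop,
#' exonic insertions/deletions (frameshift and in-frame), and
#' translation-start changes. Splice-site and all non-coding classes
#' (silent, intronic, UTR, flank, IGR, RNA) are excluded: the
#' classification scheme is exon/protein-centric. Matching is
#' case-insensitive.
#'
#' @return Character vector of classification terms.
#' @export
protein_altering_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Translation_Start_Site")
}

#' Is a variant classification protein-altering?
#'
#' @param variant_classification Character vector of MAF
#'   \code{Variant_Classification} terms.
#' @param classes Character vector of terms counted as protein-altering;
#'   defaults to [protein_altering_classes()]. Override to include e.g.
#'   \code{"Splice_Site"}.
#' @return Logical vector; unrecognized terms are \code{FALSE}.
#' @examples
#' is_protein_altering(c("Missense_Mutation", "Silent", "Intron"))
#' @export
is_protein_altering <- function(variant_classification,
                                classes = protein_altering_classes()) {
  tolower(variant_classification) %in% tolower(classes)
}

.maf_required <- c("Hugo_Symbol", "Chromosome", "Start_Position",
                   "Variant_Classification", "Tumor_Sample_Barcode")

#' Read a MAF-dialect variant table
#'
#' Reads a tab-separated somatic variant table (one row per variant call)
#' with at least the columns \code{Hugo_Symbol}, \code{Chromosome},
#' \code{Start_Position}, \code{Variant_Classification} and
#' \code{Tumor_Sample_Barcode}. Lines starting with \code{#} are comments.
#' Extra columns are ignored; row order is preserved. Chromosome labels are
#' kept verbatim and positions are 1-based (MAF convention).
#'
#' @param path Path to the file.
#' @param is_tumor Logical: do these calls come from tumor samples?
#' @return A data frame of variant records with columns \code{sample_id},
#'   \code{gene}, \code{chromosome}, \code{position},
#'   \code{variant_classification}, \code{is_tumor}.
#' @export
read_maf <- function(path, is_tumor = TRUE) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  raw <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           colClasses = "character",
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(.maf_required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("MAF file '", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("MAF file '", path, "' contains no data rows", call. = FALSE)
  }
  out <- data.frame(
    sample_id = raw$Tumor_Sample_Barcode,
    gene = raw$Hugo_Symbol,
    chromosome = raw$Chromosome,
    position = as.integer(raw$Start_Position),
    variant_classification = raw$Variant_Classification,
    is_tumor = rep(isTRUE(is_tumor), nrow(raw)),
    stringsAsFactors = FALSE
  )
  bad <- which(!nzchar(out$gene) | is.na(out$position) | out$position < 1L)
  if (length(bad) > 0L) {
    stop("MAF file '", path, "' has invalid gene/position at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a sample-label table
#'
#' Tab-separated with columns \code{sample_id}, \code{status} (one of
#' \code{tumor}/\code{normal}), optionally \code{cancer_type} and
#' \code{cohort} (\code{train}/\code{test}).
#'
#' @param path Path to the TSV file.
#' @return A label data frame (see [cohort_labels()]).
#' @export
read_labels <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sample_id", "status")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("label file '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cohort_labels(raw$sample_id, raw$status,
                cancer_type = if ("cancer_type" %in% names(raw)) raw$cancer_type,
                cohort = if ("cohort" %in% names(raw)) raw$cohort)
}

#' Construct a cohort label table
#'
#' @param sample_id Character vector of unique sample barcodes.
#' @param status Character vector, \code{"tumor"} or \code{"normal"}.
#' @param cancer_type Optional character vector of cancer-type codes.
#' @param cohort Optional character vector, \code{"train"} or \code{"test"}.
#' @return A data frame with one row per sample.
#' @export
cohort_labels <- function(sample_id, status, cancer_type = NULL,
                          cohort = NULL) {
  stopifnot(length(sample_id) == length(status))
  if (anyDuplicated(sample_id)) {
    stop("duplicated sample_id in labels: ",
         paste(unique(sample_id[duplicated(sample_id)])[1:3], collapse = ", "),
         call. = FALSE)
  }
  status <- match.arg(tolower(status), c("tumor", "normal"),
                      several.ok = TRUE)
  out <- data.frame(sample_id = as.character(sample_id), status = status,
                    stringsAsFactors = FALSE)
  if (!is.null(cancer_type)) out$cancer_type <- as.character(cancer_type)
  if (!is.null(cohort)) {
    cohort <- match.arg(tolower(cohort), c("train", "test"),
                        several.ok = TRUE)
    out$cohort <- cohort
  }
  out
}

#' Build a binary mutation matrix from variant records
#'
#' Collapses per-variant calls to per-sample, per-gene presence/absence of
#' protein-altering mutations. An entry is 1 iff the sample carries at
#' least one protein-altering variant in the gene; repeated variants do not
#' accumulate (the set-cover formulation only tests membership). Genes with
#' no mutated sample are dropped unless a gene universe is pinned via
#' \code{genes}. Samples and genes are sorted for a deterministic layout;
#' all labelled samples appear as rows even when they carry no variant.
#'
#' @param records Variant-record data frame as returned by [read_maf()].
#' @param labels Label data frame; every record's \code{sample_id} must
#'   appear in it.
#' @param classes Protein-altering vocabulary passed to
#'   [is_protein_altering()].
#' @param genes Optional character vector fixing the full gene set
#'   (columns), including genes with no mutated sample.
#' @return Integer 0/1 matrix, samples in rows, genes in columns.
#' @export
build_mutation_matrix <- function(records, labels,
                                  classes = protein_altering_classes(),
                                  genes = NULL) {
  stopifnot(is.data.frame(records), is.data.frame(labels))
  unlabeled <- setdiff(unique(records$sample_id), labels$sample_id)
  if (length(unlabeled) > 0L) {
    stop("variant record(s) with unlabeled sample barcode: ",
         paste(utils::head(unlabeled, 5L), collapse = ", "), call. = FALSE)
  }
  keep <- is_protein_altering(records$variant_classification, classes)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " variant record(s) with non-protein-altering ",
            "classification dropped")
  }
  rec <- records[keep, , drop = FALSE]
  samples <- sort(unique(labels$sample_id))
  gene_set <- if (is.null(genes)) sort(unique(rec$gene)) else sort(unique(genes))
  m <- matrix(0L, nrow = length(samples), ncol = length(gene_set),
              dimnames = list(samples, gene_set))
  if (nrow(rec) > 0L) {
    rec <- rec[rec$gene %in% gene_set, , drop = FALSE]
    m[cbind(match(rec$sample_id, samples), match(rec$gene, gene_set))] <- 1L
  }
  m
}

#' Write / read a binary mutation matrix as TSV
#'
#' Samples in rows, genes in columns, 0/1 entries, first column
#' \code{sample_id}.
#'
#' @param x Binary mutation matrix.
#' @param path Output (input) path.
#' @return \code{write_matrix} returns \code{path} invisibly;
#'   \code{read_matrix} returns the integer matrix.
#' @export
write_matrix <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample_id
  m
}

#' Write a label table as TSV
#'
#' @param labels Label data frame.
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
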