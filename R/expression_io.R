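#' Read a gene-by-sample count matrix from TSV
#'
#' Parses a tab-separated file whose header row holds sample identifiers
#' (first cell `gene_id`) and whose first column holds gene identifiers.
#' Lines starting with `#` are treated as comments and skipped. Row and
#' column order are preserved exactly as in the file; nothing is sorted.
#'
#' @param path Path to a TSV file.
#' @return Integer matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids).
#' @details Counts must be non-negative integers. Duplicated gene or sample
#'   identifiers, negative or non-integer cells (reported with their
#'   row/column coordinates) and ragged rows are errors, never silently
#'   repaired.
#' @seealso [write_counts()], [size_factors()], [to_expression_units()]
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L)
    stop("count matrix file must contain a header row and at least one gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1L]])
  if (width < 3L)
    stop("count matrix must have at least 2 sample columns, found ", width - 1L)
  bad <- which(lengths(fields) != width)
  if (length(bad))
    stop("ragged row(s) in count matrix at line(s) ",
         paste(line_no[bad], collapse = ", "),
         ": expected ", width, " fields")
  samples <- fields[[1L]][-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample identifier(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- fields[-1L]
  genes <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(cells))
  # row-major as read; coordinates are (gene row, sample column)
  mat <- matrix(vals, nrow = length(genes), ncol = width - 1L, byrow = TRUE,
                dimnames = list(genes, samples))
  bad_cell <- which(is.na(mat) | mat < 0 | mat != floor(mat), arr.ind = TRUE)
  if (nrow(bad_cell)) {
    i <- bad_cell[1L, 1L]; j <- bad_cell[1L, 2L]
    stop("invalid count at gene '", genes[i], "' (row ", i, "), sample '",
         samples[j], "' (column ", j, "'): value '", mat[i, j],
         "' is not a non-negative integer")
  }
  storage.mode(mat) <- "integer"
  mat
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(m, f))` returns `m`.
#'
#' @param counts Integer gene x sample matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a count matrix
#'
#' @param counts Matrix to check.
#' @return `counts`, invisibly, if valid; otherwise an error.
#' @keywords internal
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids as rownames and sample ids as colnames")
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    stop("counts must have at least 1 gene and 2 samples")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers in counts")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  invisible(counts)
}

.valid_roles <- c("parent1", "parent2", "hybrid")

#' Read a sample design sheet
#'
#' Reads a CSV with columns `sample`, `group`, `role`, mapping each sample
#' to a biological group and each group to its role in the cross
#' (`parent1`, `parent2` or `hybrid`). When a count matrix is supplied the
#' design is checked against its sample columns.
#'
#' @param path Path to a CSV file with header `sample,group,role`.
#' @param counts Optional count matrix to validate against.
#' @return A data.frame with columns `sample`, `group`, `role`.
#' @export
read_sample_design <- function(path, counts = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample", "group", "role")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("design sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, need]
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$sample))
    stop("duplicate sample(s) in design: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  bad_role <- setdiff(unique(df$role), .valid_roles)
  if (length(bad_role))
    stop("invalid role(s): ", paste(bad_role, collapse = ", "),
         " (must be one of ", paste(.valid_roles, collapse = ", "), ")")
  # a group must not claim two roles
  gr <- unique(df[, c("group", "role")])
  if (anyDuplicated(gr$group))
    stop("group(s) assigned more than one role: ",
         paste(unique(gr$group[duplicated(gr$group)]), collapse = ", "))
  if (!is.null(counts)) validate_design(df, counts)
  df
}

#' Check a design against a count matrix
#'
#' @param design Data.frame from [read_sample_design()].
#' @param counts Count matrix whose columns must all be described.
#' @return `design`, invisibly.
#' @keywords internal
validate_design <- function(design, counts) {
  orphan <- setdiff(colnames(counts), design$sample)
  if (length(orphan))
    stop("sample(s) in count matrix but absent from design: ",
         paste(orphan, collapse = ", "))
  invisible(design)
}

#' Resolve the group filling each cross role
#'
#' For classification exactly one group must carry each of the roles
#' `parent1`, `parent2` and `hybrid`.
#'
#' @param design Sample design data.frame.
#' @return Named character vector `c(parent1=, parent2=, hybrid=)`.
#' @export
role_groups <- function(design) {
  gr <- unique(design[, c("group", "role")])
  out <- vapply(.valid_roles, function(r) {
    g <- gr$group[gr$role == r]
    if (length(g) == 0L)
      stop("no group carries role '", r, "'")
    if (length(g) > 1L)
      stop("two groups claim role '", r, "' in one analysis: ",
           paste(g, collapse = ", "))
    g
  }, character(1L))
  out
}

#' Median-of-ratios size factors
#'
#' Library-size factors in the median-of-ratios style: each gene's
#' geometric mean across samples serves as a pseudo-reference, each
#' sample's factor is the median of its count/reference ratios, and the
#' factors are rescaled to geometric mean 1. Genes containing any zero are
#' excluded from the reference. If no gene is expressed in every sample
#' the function falls back to total-count scaling (factors proportional to
#' column sums) with a warning.
#'
#' @param counts Count matrix.
#' @return Named positive numeric vector, one factor per sample, geometric
#'   mean 1.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  cs <- colSums(counts)
  if (any(cs == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[cs == 0], collapse = ", "))
  keep <- rowSums(counts == 0) == 0L
  if (!any(keep)) {
    warning("no gene expressed in all samples; falling back to total-count scaling")
    sf <- cs / exp(mean(log(cs)))
    return(sf)
  }
  lc <- log(counts[keep, , drop = FALSE])
  logref <- rowMeans(lc)
  sf <- exp(apply(lc - logref, 2L, stats::median))
  sf / exp(mean(log(sf)))
}

#' Size-factor-normalized counts
#'
#' @param counts Count matrix.
#' @param sf Size factors; computed with [size_factors()] when omitted.
#' @return Numeric matrix of normalized counts (counts divided by their
#'   sample's factor).
#' @export
normalized_counts <- function(counts, sf = size_factors(counts)) {
  if (!all(colnames(counts) %in% names(sf)))
    stop("size factors missing for sample(s): ",
         paste(setdiff(colnames(counts), names(sf)), collapse = ", "))
  sweep(counts, 2L, sf[colnames(counts)], "/")
}

#' Read gene lengths from TSV
#'
#' @param path TSV with columns `gene_id`, `length_bp` (header required).
#' @return Named numeric vector of lengths in base pairs.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("gene length file needs columns gene_id, length_bp")
  len <- as.numeric(df[[2L]])
  names(len) <- as.character(df[[1L]])
  if (anyDuplicated(names(len)))
    stop("duplicate gene id(s) in length file")
  len
}

#' Convert counts to FPKM or TPM
#'
#' FPKM divides each count by gene length (kb) and library size (millions):
#' `counts * 1e9 / (length * colsum)`. TPM first forms the length-normalized
#' rate `counts/length`, then scales each sample so the column sums to one
#' million; TPM columns therefore always sum to 1e6.
#'
#' @param counts Count matrix.
#' @param lengths Named numeric vector of gene lengths in bp covering every
#'   gene in `counts`.
#' @param unit `"TPM"` or `"FPKM"`.
#' @return Numeric matrix in the requested unit, with attribute `unit`.
#' @export
to_expression_units <- function(counts, lengths, unit = c("TPM", "FPKM")) {
  unit <- match.arg(unit)
  validate_counts(counts)
  missing_len <- setdiff(rownames(counts), names(lengths))
  if (length(missing_len))
    stop("missing length for gene(s): ", paste(missing_len, collapse = ", "))
  len <- lengths[rownames(counts)]
  if (any(!is.finite(len)) || any(len <= 0))
    stop("gene lengths must be positive and finite")
  cs <- colSums(counts)
  if (any(cs == 0))
    stop("zero column sum for sample(s): ",
         paste(colnames(counts)[cs == 0], collapse = ", "))
  out <- if (unit == "FPKM") {
    sweep(counts / len, 2L, cs, "/") * 1e9
  } else {
    rate <- counts / len
    sweep(rate, 2L, colSums(rate), "/") * 1e6
  }
  attr(out, "unit") <- unit
  out
}
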