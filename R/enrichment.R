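#' Read a GMT gene-set collection
#'
#' Standard GMT: one term per tab-separated line — term id, description,
#' then member genes. Duplicate genes within a line are dropped with a
#' warning; duplicate term ids and lines with fewer than three fields are
#' errors.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (term id -> member genes) with
#'   attribute `term_names` (term id -> description).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines)
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields at line(s) ",
         paste(line_no[short], collapse = ", "))
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicate term id(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(seq_along(fields), function(i) {
    genes <- fields[[i]][-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) within term '", ids[i], "'; deduplicated")
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- ids
  attr(sets, "term_names") <- stats::setNames(
    vapply(fields, `[[`, character(1L), 2L), ids)
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of gene vectors, optionally with a `term_names`
#'   attribute.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  nm <- attr(sets, "term_names")
  if (is.null(nm)) nm <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, nm[[id]], sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' Over-representation p-value: for a universe of `N` genes containing a
#' term of `K` members, and a query of `n` genes with `k` of them in the
#' term, returns `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, evaluated
#' through the stable log-space tail of the hypergeometric distribution.
#'
#' @param k Observed overlap (vectorized).
#' @param K Term size within the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return Upper-tail probability in `[0, 1]`.
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  bad <- k < 0 | k > pmin(K, n) | K > N | n > N | K < 0 | n < 0
  if (any(bad))
    stop("invalid hypergeometric arguments: need 0 <= k <= min(K, n), ",
         "K <= N, n <= N")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' Tests each term of a GMT collection for enrichment of a query gene list
#' within a background universe. Terms are first intersected with the
#' universe, then filtered by size; the hypergeometric upper tail gives
#' each surviving term's p-value, BH adjustment runs across the surviving
#' terms only, and rows are sorted by `(p, term_id)` so output is fully
#' deterministic.
#'
#' @param query Character vector of genes of interest (must be a subset of
#'   `universe`).
#' @param universe Character vector: the background gene set.
#' @param sets Collection from [read_gmt()] (or any named list of gene
#'   vectors).
#' @param min_size,max_size Term-size filters after universe intersection.
#' @param q_threshold Threshold for the `significant` column.
#' @return Data.frame with columns `term_id`, `name`, `k`, `K`, `n`, `N`,
#'   `p`, `q`, `significant`, sorted by increasing p.
#' @export
enrich <- function(query, universe, sets, min_size = 5, max_size = 2000,
                   q_threshold = 0.05) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0L) stop("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query gene(s) not in universe: ",
         paste(utils::head(outside, 20L), collapse = ", "))
  nm <- attr(sets, "term_names")
  if (is.null(nm)) nm <- stats::setNames(names(sets), names(sets))
  members <- lapply(sets, intersect, universe)
  K <- lengths(members)
  keep <- K >= min_size & K <= max_size
  if (!any(keep)) {
    out <- data.frame(term_id = character(0), name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    return(out)
  }
  members <- members[keep]
  K <- K[keep]
  k <- vapply(members, function(g) length(intersect(g, query)), integer(1L))
  n <- length(query)
  N <- length(universe)
  p <- hypergeometric_tail(k, K, n, N)
  q <- bh_adjust(p)
  out <- data.frame(term_id = names(members),
                    name = unname(nm[names(members)]),
                    k = k, K = as.integer(K), n = n, N = N,
                    p = p, q = q, significant = q < q_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$term_id), , drop = FALSE]
}

#' Write an enrichment table to TSV
#'
#' @param rows Data.frame from [enrich()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
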