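#' Read a gene network from a TSV edge list
#'
#' Each non-comment line holds \code{from<TAB>to} (unweighted) or
#' \code{from<TAB>to<TAB>weight}.  Lines starting with \code{#} and blank
#' lines are ignored.  Edges are symmetrized, duplicates collapsed to the
#' maximum weight, self-loops dropped with a warning.
#'
#' @param path file path.
#' @param weighted logical; expect a third weight column.
#' @return a \code{\link{gene_network}}.
#' @export
read_edge_list <- function(path, weighted = FALSE) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(gene_network(NULL, genes = character(0)))
  parts <- strsplit(lines, "[\t ]+")
  want <- if (weighted) 3L else 2L
  bad <- which(lengths(parts) < want)
  if (length(bad))
    stop("malformed edge at line ", lineno[bad[1L]], " of ", path,
         " (expected ", want, " fields)")
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  if (weighted) {
    w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(w))
      stop("non-numeric weight at line ", lineno[which(is.na(w))[1L]],
           " of ", path)
    if (any(w < 0))
      stop("negative weight at line ", lineno[which(w < 0)[1L]], " of ", path)
    gene_network(data.frame(from = from, to = to, weight = w))
  } else {
    gene_network(data.frame(from = from, to = to))
  }
}

#' Write a gene network as a canonical TSV edge list
#'
#' One line per undirected edge, endpoints sorted lexicographically and
#' rows sorted, so that reading and re-writing a file is idempotent.
#'
#' @param network a \code{\link{gene_network}}.
#' @param path output file.
#' @param weighted include the weight column.
#' @export
write_edge_list <- function(network, path, weighted = FALSE) {
  stopifnot_network(network)
  A <- network$adjacency
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  from <- pmin(network$genes[idx[, 1L]], network$genes[idx[, 2L]])
  to <- pmax(network$genes[idx[, 1L]], network$genes[idx[, 2L]])
  ord <- order(from, to)
  df <- if (weighted)
    data.frame(from = from, to = to, weight = A[idx])[ord, , drop = FALSE]
  else data.frame(from = from, to = to)[ord, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene set (one ID per line)
#'
#' \code{#} comments and blank lines are ignored; duplicates are dropped
#' (order preserving) with a warning; CRLF endings are accepted.
#'
#' @param path file path.
#' @return character vector of gene IDs.
#' @export
read_gene_set <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  lines <- trimws(lines)
  lines <- lines[!grepl("^(#|$)", lines)]
  if (!length(lines)) stop("no gene IDs in ", path)
  if (anyDuplicated(lines)) {
    warning("duplicate gene ID(s) in ", path, ", keeping first occurrence")
    lines <- unique(lines)
  }
  lines
}

#' Read an expression matrix (genes x samples TSV)
#'
#' First column = gene ID, header row = sample IDs.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene IDs in ", path)
  x <- as.matrix(df[, -1L, drop = FALSE])
  if (ncol(x) < 2L) stop("expression matrix needs at least 2 samples")
  storage.mode(x) <- "double"
  rownames(x) <- genes
  x
}

#' Co-expression network from an expression matrix
#'
#' Genes are linked by an (unweighted) edge when the Pearson correlation
#' of their expression profiles is strictly greater than
#' \code{threshold}.  Zero-variance genes cannot be correlated and are
#' excluded from edges with a warning (they remain as isolated nodes).
#'
#' @param expr numeric matrix, genes x samples, gene rownames.
#' @param threshold PCC cutoff, default 0.5.
#' @return a \code{\link{gene_network}} over all genes of \code{expr}.
#' @export
coexpression_network <- function(expr, threshold = 0.5) {
  if (is.null(rownames(expr))) stop("expression matrix needs gene rownames")
  if (ncol(expr) < 3L)
    stop("need >= 3 samples for a meaningful correlation network")
  v <- apply(expr, 1L, stats::var)
  flat <- v == 0 | !is.finite(v)
  if (any(flat))
    warning("zero-variance gene(s) excluded from edges: ",
            paste(utils::head(rownames(expr)[flat], 5L), collapse = ", "))
  genes <- rownames(expr)
  keep <- which(!flat)
  A <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  if (length(keep) >= 2L) {
    cc <- stats::cor(t(expr[keep, , drop = FALSE]))
    adj <- (cc > threshold) * 1
    diag(adj) <- 0
    A[keep, keep] <- adj
  }
  structure(list(genes = genes, adjacency = A), class = "gene_network")
}

#' Read pathway membership (two-column TSV: pathway, gene)
#'
#' @param path file path.
#' @return named list mapping pathway name to character gene vector.
#' @export
read_pathways <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("pathway file needs two columns (pathway, gene)")
  split(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Pathway co-participation network
#'
#' Links every pair of genes that co-participate in at least one pathway:
#' the union over pathways of the clique on each pathway's gene set.
#'
#' @param membership named list mapping pathway name to gene vector.
#' @return a \code{\link{gene_network}} (unweighted).
#' @export
pathway_network <- function(membership) {
  if (!length(membership)) stop("empty pathway membership")
  genes <- sort(unique(unlist(membership, use.names = FALSE)))
  A <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (pw in membership) {
    idx <- match(unique(pw), genes)
    if (length(idx) >= 2L) A[idx, idx] <- 1
  }
  diag(A) <- 0
  structure(list(genes = genes, adjacency = A), class = "gene_network")
}
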