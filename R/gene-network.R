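#' Construct a gene network
#'
#' A gene network is an undirected, optionally weighted graph over a set of
#' gene identifiers, stored as a symmetric adjacency matrix with zero
#' diagonal.  It is the common input to all graph node kernels.
#'
#' Edges may be given as a two- or three-column data frame (\code{from},
#' \code{to}, optional \code{weight}).  Edges are symmetrized, duplicate
#' edges are collapsed to the maximum weight, and self-loops are dropped
#' with a warning.
#'
#' @param edges data frame with columns \code{from}, \code{to} and
#'   optionally \code{weight} (positive reals); or \code{NULL} for an
#'   edgeless network.
#' @param genes character vector of gene identifiers.  Defaults to the
#'   genes appearing in \code{edges}; supply explicitly to include
#'   isolated genes.
#' @return An object of class \code{"gene_network"}: a list with elements
#'   \code{genes} (ordered character vector) and \code{adjacency}
#'   (symmetric numeric matrix, zero diagonal, nonnegative weights).
#' @examples
#' net <- gene_network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' net$genes
#' @export
gene_network <- function(edges = NULL, genes = NULL) {
  if (!is.null(edges)) {
    edges <- as.data.frame(edges)
    if (ncol(edges) < 2L)
      stop("'edges' needs at least two columns (from, to)")
    from <- as.character(edges[[1L]])
    to <- as.character(edges[[2L]])
    w <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(1, length(from))
    if (anyNA(w) || any(!is.finite(w)))
      stop("edge weights must be finite numbers")
    if (any(w < 0))
      stop("negative edge weights are not allowed")
  } else {
    from <- to <- character(0)
    w <- numeric(0)
  }
  if (is.null(genes)) genes <- unique(c(from, to))
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers in 'genes'")
  missing <- setdiff(c(from, to), genes)
  if (length(missing))
    stop("edge endpoints absent from 'genes': ", paste(missing, collapse = ", "))

  self <- from == to
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped")
    from <- from[!self]; to <- to[!self]; w <- w[!self]
  }

  n <- length(genes)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  if (length(from)) {
    i <- match(from, genes)
    j <- match(to, genes)
    # collapse duplicates (either orientation) to the max weight
    for (e in seq_along(i)) {
      A[i[e], j[e]] <- max(A[i[e], j[e]], w[e])
      A[j[e], i[e]] <- A[i[e], j[e]]
    }
  }
  structure(list(genes = genes, adjacency = A), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  ne <- sum(x$adjacency[upper.tri(x$adjacency)] > 0)
  cat("gene_network:", length(x$genes), "genes,", ne, "edges\n")
  invisible(x)
}

is_gene_network <- function(x) inherits(x, "gene_network")

stopifnot_network <- function(network) {
  if (!is_gene_network(network))
    stop("expected a 'gene_network' object")
  A <- network$adjacency
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-12)))
    stop("adjacency matrix is not symmetric")
  if (any(diag(A) != 0))
    stop("adjacency matrix has nonzero diagonal")
  if (any(A < 0))
    stop("adjacency matrix has negative weights")
  invisible(network)
}

#' Graph Laplacian of a gene network
#'
#' Returns \code{L = D - A} where \code{D} is the diagonal matrix of
#' (weighted) node degrees.  \code{L} is symmetric positive semi-definite
#' with zero row sums; it underlies all graph node kernels in the package.
#'
#' @param network a \code{gene_network}.
#' @return symmetric numeric matrix with gene dimnames.
#' @export
laplacian <- function(network) {
  stopifnot_network(network)
  A <- network$adjacency
  diag(rowSums(A), nrow(A)) - A
}

#' Restrict a network to a gene subset
#'
#' @param network a \code{gene_network}.
#' @param genes character vector of genes to keep (order respected).
#' @return a \code{gene_network} on \code{genes}.
#' @export
restrict_network <- function(network, genes) {
  stopifnot_network(network)
  missing <- setdiff(genes, network$genes)
  if (length(missing))
    stop("genes not in network: ", paste(missing, collapse = ", "))
  idx <- match(genes, network$genes)
  structure(list(genes = as.character(genes),
                 adjacency = network$adjacency[idx, idx, drop = FALSE]),
            class = "gene_network")
}

#' Align several networks to a common gene universe
#'
#' Multi-source integration assumes all data sources describe the same
#' gene set.  By default the universe is the intersection of the node sets
#' (\code{mode = "intersection"}); \code{mode = "union"} keeps every gene,
#' zero-padding sources where it is absent.
#'
#' @param networks list of \code{gene_network} objects.
#' @param mode \code{"intersection"} (default) or \code{"union"}.
#' @return list of aligned \code{gene_network}s sharing an identical
#'   ordered gene vector.
#' @export
align_networks <- function(networks, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  if (!length(networks)) stop("empty network list")
  lapply(networks, stopifnot_network)
  gene_sets <- lapply(networks, `[[`, "genes")
  universe <- if (mode == "intersection") Reduce(intersect, gene_sets)
              else Reduce(union, gene_sets)
  universe <- sort(universe)
  if (!length(universe)) stop("empty common gene universe")
  lapply(networks, function(net) {
    if (mode == "union") {
      extra <- setdiff(universe, net$genes)
      if (length(extra)) {
        n <- length(net$genes); k <- length(extra)
        A <- rbind(cbind(net$adjacency, matrix(0, n, k)),
                   matrix(0, k, n + k))
        g <- c(net$genes, extra)
        dimnames(A) <- list(g, g)
        net <- structure(list(genes = g, adjacency = A), class = "gene_network")
      }
    }
    restrict_network(net, universe)
  })
}
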