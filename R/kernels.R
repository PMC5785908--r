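#' Graph node kernels
#'
#' Positive semi-definite node-similarity matrices computed from a gene
#' network, the building blocks of the multiple-kernel gene prioritizer.
#' Four families are provided, all standard in network-based
#' guilt-by-association analysis:
#'
#' \describe{
#'   \item{MEDK}{Markov exponential diffusion kernel,
#'     \eqn{K = \exp(\beta M)} with \eqn{M = I - L/N}.  Replacing the
#'     adjacency matrix by the Markov-type matrix \eqn{M} removes the bias
#'     of plain exponential diffusion towards high-degree hub genes.}
#'   \item{MDK}{Markov diffusion kernel, \eqn{K = Z(t) Z(t)^\top} with
#'     \eqn{Z(t) = \frac{1}{t}\sum_{\tau=1}^{t} P^\tau} and
#'     \eqn{P = D^{-1}A} the random-walk transition matrix.  Similarity is
#'     high for nodes whose \eqn{t}-step diffusion patterns agree.}
#'   \item{RLK}{regularized Laplacian kernel,
#'     \eqn{K = (I + \alpha L)^{-1}}, a normalized random-walk-with-restart
#'     model counting paths of all lengths with geometric damping.}
#'   \item{heat diffusion}{\eqn{K = \exp(-\beta L)}, the classical
#'     diffusion kernel: similarity is the amount of heat flowing between
#'     two nodes.}
#' }
#'
#' All kernels are computed densely via spectral decomposition / direct
#' solves, targeting networks up to a few thousand genes.
#'
#' @param network a \code{\link{gene_network}}.
#' @param beta nonnegative diffusion parameter.
#' @param t positive integer number of diffusion steps (MDK).
#' @param alpha nonnegative regularization parameter (RLK).
#' @return An object of class \code{"kernel_matrix"}: a symmetric PSD
#'   numeric matrix with gene dimnames and attributes \code{family} and
#'   \code{parameter}.
#' @seealso \code{\link{cosine_normalize}}, \code{\link{kernel_bank}}
#' @examples
#' net <- gene_network(data.frame(from = "a", to = "b"))
#' medk(net, 0.04)
#' rlk(net, 1)
#' @name graph_node_kernels
NULL

kernel_matrix <- function(values, genes, family, parameter) {
  dimnames(values) <- list(genes, genes)
  structure(values, family = family, parameter = parameter,
            class = c("kernel_matrix", "matrix", "array"))
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix [%s, parameter=%g]: %d genes\n",
              attr(x, "family"), attr(x, "parameter"), nrow(x)))
  invisible(x)
}

# exp(S) for symmetric S via spectral decomposition; symmetrized result
sym_expm <- function(S) {
  if (any(!is.finite(S))) stop("non-finite entries in matrix exponential input")
  e <- eigen(S, symmetric = TRUE)
  K <- e$vectors %*% (exp(e$values) * t(e$vectors))
  (K + t(K)) / 2
}

#' @rdname graph_node_kernels
#' @export
medk <- function(network, beta) {
  stopifnot_network(network)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("'beta' must be a single nonnegative number")
  N <- length(network$genes)
  M <- diag(N) - laplacian(network) / N
  kernel_matrix(sym_expm(beta * M), network$genes, "MEDK", beta)
}

#' @rdname graph_node_kernels
#' @export
mdk <- function(network, t) {
  stopifnot_network(network)
  if (!is.numeric(t) || length(t) != 1L || t < 1 || t != round(t))
    stop("'t' must be a single integer >= 1")
  A <- network$adjacency
  deg <- rowSums(A)
  P <- A / ifelse(deg > 0, deg, 1)
  P[deg == 0, ] <- 0  # walker vanishes at isolated genes
  Z <- matrix(0, nrow(A), ncol(A))
  Pt <- diag(nrow(A))
  for (tau in seq_len(t)) {
    Pt <- Pt %*% P
    Z <- Z + Pt
  }
  Z <- Z / t
  kernel_matrix(tcrossprod(Z), network$genes, "MDK", as.integer(t))
}

#' @rdname graph_node_kernels
#' @export
rlk <- function(network, alpha) {
  stopifnot_network(network)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || !is.finite(alpha))
    stop("'alpha' must be a single finite nonnegative number")
  L <- laplacian(network)
  if (any(!is.finite(L))) stop("non-finite entries in Laplacian")
  K <- solve(diag(nrow(L)) + alpha * L)
  kernel_matrix((K + t(K)) / 2, network$genes, "RLK", alpha)
}

#' @rdname graph_node_kernels
#' @export
diffusion_kernel <- function(network, beta) {
  stopifnot_network(network)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("'beta' must be a single nonnegative number")
  kernel_matrix(sym_expm(-beta * laplacian(network)), network$genes, "DIFF", beta)
}

#' Cosine-normalize a kernel matrix
#'
#' Rescales a kernel to unit diagonal,
#' \eqn{K'_{ij} = K_{ij} / \sqrt{K_{ii} K_{jj}}}, so that kernels computed
#' from sources with different scales contribute comparably to the learned
#' combination.  PSD is preserved (it is a congruence by a positive
#' diagonal matrix).
#'
#' @param K a \code{kernel_matrix} (or plain symmetric matrix) with
#'   strictly positive diagonal.
#' @return the normalized kernel, same class and attributes.
#' @export
cosine_normalize <- function(K) {
  d <- diag(K)
  if (any(d <= 0)) {
    bad <- rownames(K)[d <= 0]
    stop("cannot cosine-normalize: nonpositive diagonal for gene(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  s <- 1 / sqrt(d)
  Kn <- K * tcrossprod(s)
  attributes(Kn) <- attributes(K)
  Kn
}

# tolerant variant used when building banks: genes with zero diagonal
# (e.g. isolated genes under MDK, whose similarities are identically zero)
# are left at zero instead of raising
cosine_normalize_tolerant <- function(K) {
  d <- diag(K)
  s <- ifelse(d > 0, 1 / sqrt(pmax(d, .Machine$double.eps)), 0)
  Kn <- K * tcrossprod(s)
  attributes(Kn) <- attributes(K)
  Kn
}

#' Write / read a kernel matrix as TSV
#'
#' Serializes a kernel with a header row and first column of gene IDs.
#'
#' @param K kernel matrix with gene dimnames.
#' @param path file path.
#' @export
write_kernel_tsv <- function(K, path) {
  df <- data.frame(gene = rownames(K), as.data.frame(unclass(K)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel_tsv
#' @export
read_kernel_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  K <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(K) <- list(genes, genes)
  K
}
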