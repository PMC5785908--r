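#' Build a bank of graph node kernels from several network sources
#'
#' Applies a grid of kernel families/parameters to each input network,
#' producing the ordered kernel collection consumed by the MKL solver.
#' With \code{L} sources and \code{H} kernels per source the bank holds
#' \code{R = L * H} matrices, each tagged with its provenance (source,
#' family, parameter).  The default grids follow standard practice for
#' these kernels: \eqn{\beta \in \{0.01, 0.04, 0.07\}} for MEDK,
#' \eqn{t \in \{2, 4, 6\}} for MDK and \eqn{\alpha \in \{1, 10, 100\}}
#' for RLK.
#'
#' Every kernel is cosine-normalized by default so that sources on
#' different scales are comparable before combination.
#'
#' @param networks list of \code{\link{gene_network}}s over a common gene
#'   universe (see \code{\link{align_networks}}); names are used as source
#'   labels.
#' @param kernels named list mapping a family (\code{"medk"},
#'   \code{"mdk"}, \code{"rlk"}, \code{"diffusion"}) to its parameter
#'   grid.  All listed kernels are applied to every source.
#' @param normalize logical; cosine-normalize each kernel (default TRUE).
#' @return An object of class \code{"kernel_bank"}: list with
#'   \code{genes}, \code{kernels} (list of matrices) and
#'   \code{provenance} (data frame with columns source, family,
#'   parameter).
#' @examples
#' net <- gene_network(data.frame(from = c("a", "a"), to = c("b", "c")))
#' bank <- kernel_bank(list(ppi = net), kernels = list(medk = c(0.01, 0.04, 0.07)))
#' bank$provenance
#' @export
kernel_bank <- function(networks,
                        kernels = list(medk = c(0.01, 0.04, 0.07)),
                        normalize = TRUE) {
  if (is_gene_network(networks)) networks <- list(networks)
  if (!length(networks)) stop("empty source list")
  lapply(networks, stopifnot_network)
  if (!length(kernels)) stop("empty kernel grid")
  genes <- networks[[1L]]$genes
  for (net in networks)
    if (!identical(net$genes, genes))
      stop("all networks must share an identical ordered gene universe; ",
           "see align_networks()")
  src_names <- names(networks)
  if (is.null(src_names)) src_names <- paste0("source", seq_along(networks))
  src_names[src_names == ""] <- paste0("source", which(src_names == ""))

  fams <- names(kernels)
  if (is.null(fams) || any(fams == ""))
    stop("'kernels' must be a named list, e.g. list(medk = c(0.01, 0.04, 0.07))")
  fams <- match.arg(fams, c("medk", "mdk", "rlk", "diffusion"),
                    several.ok = TRUE)

  mats <- list()
  prov <- list()
  for (s in seq_along(networks)) {
    for (f in seq_along(kernels)) {
      fun <- switch(fams[f], medk = medk, mdk = mdk, rlk = rlk,
                    diffusion = diffusion_kernel)
      for (p in kernels[[f]]) {
        K <- fun(networks[[s]], p)
        if (normalize) K <- cosine_normalize_tolerant(K)
        mats[[length(mats) + 1L]] <- K
        prov[[length(prov) + 1L]] <-
          data.frame(source = src_names[s], family = toupper(fams[f]),
                     parameter = as.numeric(p))
      }
    }
  }
  structure(list(genes = genes, kernels = mats,
                 provenance = do.call(rbind, prov)),
            class = "kernel_bank")
}

#' Assemble a kernel bank from precomputed matrices
#'
#' Lower-level constructor used when kernels are supplied directly
#' (e.g. read from TSV or built synthetically) rather than computed from
#' networks.
#'
#' @param kernels list of symmetric PSD matrices with identical gene
#'   dimnames.
#' @param provenance optional data frame (source, family, parameter) with
#'   one row per kernel.
#' @return a \code{kernel_bank}.
#' @export
as_kernel_bank <- function(kernels, provenance = NULL) {
  if (!length(kernels)) stop("empty kernel list")
  genes <- rownames(kernels[[1L]])
  if (is.null(genes)) stop("kernels must carry gene dimnames")
  for (K in kernels)
    if (!identical(rownames(K), genes))
      stop("all kernels must share identical ordered gene dimnames")
  if (is.null(provenance))
    provenance <- data.frame(source = paste0("kernel", seq_along(kernels)),
                             family = NA_character_,
                             parameter = NA_real_)
  structure(list(genes = genes, kernels = kernels, provenance = provenance),
            class = "kernel_bank")
}

#' @export
print.kernel_bank <- function(x, ...) {
  cat("kernel_bank:", length(x$kernels), "kernels over",
      length(x$genes), "genes\n")
  print(x$provenance)
  invisible(x)
}

#' Number of kernels in a bank
#' @param bank a \code{kernel_bank}.
#' @export
n_kernels <- function(bank) length(bank$kernels)

#' Linear combination of bank kernels on a gene sub-block
#'
#' Computes \eqn{\sum_r \eta_r K_r[\mathrm{rows}, \mathrm{cols}]}.  With
#' \code{rows = cols} spanning all genes and convex weights the result is
#' symmetric PSD.
#'
#' @param bank a \code{kernel_bank}.
#' @param eta numeric weight vector, length \code{n_kernels(bank)}.
#' @param rows,cols character vectors of gene IDs (default: all genes).
#' @return numeric matrix \code{length(rows) x length(cols)}.
#' @export
combine_kernels <- function(bank, eta, rows = bank$genes, cols = bank$genes) {
  if (length(eta) != length(bank$kernels))
    stop("'eta' length must equal the number of kernels in the bank")
  ri <- match(rows, bank$genes)
  ci <- match(cols, bank$genes)
  if (anyNA(ri))
    stop("unknown gene(s) in rows: ",
         paste(utils::head(rows[is.na(ri)], 5L), collapse = ", "))
  if (anyNA(ci))
    stop("unknown gene(s) in cols: ",
         paste(utils::head(cols[is.na(ci)], 5L), collapse = ", "))
  out <- matrix(0, length(ri), length(ci), dimnames = list(rows, cols))
  for (r in seq_along(eta)) {
    if (eta[r] == 0) next
    out <- out + eta[r] * bank$kernels[[r]][ri, ci, drop = FALSE]
  }
  out
}
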