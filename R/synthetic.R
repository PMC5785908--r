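#' Simulate a planted-module gene network
#'
#' Generates an undirected network over \code{n_genes} genes in which a
#' random module of \code{module_size} genes is densely connected
#' (within-module edge probability \code{p_in}) against a sparse
#' background (probability \code{p_out}), mimicking the
#' guilt-by-association structure a disease module induces in functional
#' networks.  Gene IDs are zero-padded (\code{g001}, ...) so lexicographic
#' tie-breaking is deterministic.
#'
#' @param n_genes number of genes N.
#' @param module_size module size (<= N).
#' @param p_in within-module edge probability.
#' @param p_out background edge probability (<= \code{p_in}).
#' @param seed integer seed; the draw is fully reproducible.
#' @return list with \code{network} (a \code{\link{gene_network}}) and
#'   \code{module} (character vector of module gene IDs).
#' @export
simulate_planted_network <- function(n_genes, module_size, p_in, p_out,
                                     seed = 1L) {
  check_planted_spec(n_genes, module_size, p_in, p_out)
  genes <- sprintf(paste0("g%0", nchar(n_genes), "d"), seq_len(n_genes))
  with_seed(seed, {
    module <- sort(sample(genes, module_size))
    net <- draw_planted_edges(genes, module, p_in, p_out)
    list(network = net, module = module)
  })
}

check_planted_spec <- function(n_genes, module_size, p_in, p_out) {
  if (module_size > n_genes) stop("module_size must not exceed n_genes")
  if (module_size < 1L || n_genes < 2L) stop("invalid sizes")
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1)
    stop("edge probabilities must lie in [0, 1]")
  if (p_out > p_in) stop("p_out must not exceed p_in")
  invisible(TRUE)
}

# draw the upper-triangle Bernoulli edges for a fixed module (uses the
# current RNG stream)
draw_planted_edges <- function(genes, module, p_in, p_out) {
  n <- length(genes)
  in_mod <- genes %in% module
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  ut <- which(upper.tri(A), arr.ind = TRUE)
  p <- ifelse(in_mod[ut[, 1L]] & in_mod[ut[, 2L]], p_in, p_out)
  e <- stats::runif(nrow(ut)) < p
  A[ut[e, , drop = FALSE]] <- 1
  A <- A + t(A)
  structure(list(genes = genes, adjacency = A), class = "gene_network")
}

#' Simulate multiple noisy views of a planted-module network
#'
#' Produces \code{n_sources} independent network draws sharing the same
#' planted module (each source is a fresh Bernoulli draw, optionally with
#' a fraction of its edges rewired to random non-edges), emulating
#' heterogeneous data sources that carry the same underlying disease
#' signal.  Optionally appends one pure-noise Erdos-Renyi source with the
#' same expected density and no module signal.  A single master seed
#' drives per-source substreams, so adding sources never perturbs earlier
#' ones.
#'
#' @param n_genes,module_size,p_in,p_out as in
#'   \code{\link{simulate_planted_network}}.
#' @param n_sources number of signal-carrying sources.
#' @param rewire_frac fraction of each source's edges rewired uniformly
#'   (in [0, 1]).
#' @param include_noise_source append a matched-density Erdos-Renyi
#'   source (named \code{"noise"}).
#' @param seed master integer seed.
#' @return list with \code{networks} (named list of
#'   \code{gene_network}s) and \code{module}.
#' @export
simulate_multisource <- function(n_genes, module_size, p_in, p_out,
                                 n_sources = 2L, rewire_frac = 0,
                                 include_noise_source = FALSE, seed = 1L) {
  check_planted_spec(n_genes, module_size, p_in, p_out)
  if (rewire_frac < 0 || rewire_frac > 1)
    stop("'rewire_frac' must lie in [0, 1]")
  genes <- sprintf(paste0("g%0", nchar(n_genes), "d"), seq_len(n_genes))
  # per-source substream seeds drawn once from the master seed
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                    n_sources + 2L))
  module <- with_seed(sub[1L], sort(sample(genes, module_size)))
  networks <- list()
  for (s in seq_len(n_sources)) {
    networks[[paste0("signal", s)]] <- with_seed(sub[1L + s], {
      net <- draw_planted_edges(genes, module, p_in, p_out)
      if (rewire_frac > 0) net <- rewire_network(net, rewire_frac)
      net
    })
  }
  if (include_noise_source) {
    k <- module_size
    dens <- (choose(k, 2) * p_in + (choose(n_genes, 2) - choose(k, 2)) * p_out) /
      choose(n_genes, 2)
    networks[["noise"]] <- with_seed(sub[n_sources + 2L],
      draw_planted_edges(genes, character(0), dens, dens))
  }
  list(networks = networks, module = module)
}

# move a fraction of edges to uniformly chosen non-edge pairs (current RNG)
rewire_network <- function(network, frac) {
  A <- network$adjacency
  ut <- which(upper.tri(A), arr.ind = TRUE)
  vals <- A[ut]
  edges <- which(vals > 0)
  holes <- which(vals == 0)
  k <- floor(frac * length(edges))
  if (k > 0 && length(holes) >= k) {
    drop <- sample(edges, k)
    add <- sample(holes, k)
    vals[drop] <- 0
    vals[add] <- 1
    A[ut] <- 0
    A[ut[vals > 0, , drop = FALSE]] <- 1
    A[lower.tri(A)] <- 0
    A <- A + t(A)
  }
  structure(list(genes = network$genes, adjacency = A),
            class = "gene_network")
}

#' Split module genes into revealed positives and hidden positives
#'
#' Emulates the positive-unlabelled setting: a seeded subset of the
#' planted module is revealed as the positive training set P and the rest
#' are hidden among the candidates, to be retrieved by the model.
#'
#' @param module_genes character vector of module gene IDs.
#' @param n_pos number of revealed positives (< module size).
#' @param seed integer seed.
#' @return list with \code{positives} and \code{hidden}.
#' @export
split_positives <- function(module_genes, n_pos, seed = 1L) {
  if (n_pos >= length(module_genes))
    stop("'n_pos' must be smaller than the module size")
  if (n_pos < 1L) stop("'n_pos' must be >= 1")
  positives <- with_seed(seed, sort(sample(module_genes, n_pos)))
  list(positives = positives, hidden = setdiff(module_genes, positives))
}
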