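#' Prioritize candidate disease genes by multiple kernel learning
#'
#' \code{scuba()} is the package's main fitting function.  Starting from
#' one or more gene networks and a set of known disease genes (the
#' positive set P), it (i) aligns the networks to a common gene universe,
#' (ii) builds a bank of graph node kernels per source, (iii) selects the
#' positive-class regularization \eqn{\lambda_+} by k-fold
#' cross-validation if requested, (iv) fits the two-stage unbalanced MKL
#' model and (v) scores and ranks the candidate genes.
#'
#' The learning problem is positive-unlabelled: candidates are treated as
#' unlabelled rather than negative, their example weights are pinned at
#' the uniform distribution, and only the positive-class weights
#' \eqn{\gamma_+} are optimized — which makes the solve quadratic in the
#' number of positives and independent of the candidate count.
#'
#' @param networks a \code{\link{gene_network}} or (optionally named)
#'   list of them, one per data source.
#' @param positives character vector of known disease gene IDs.
#' @param candidates character vector of candidate gene IDs, or
#'   \code{NULL} for genome-wide prioritization (every non-positive gene
#'   in the universe).
#' @param kernels named list of kernel families and parameter grids, as
#'   in \code{\link{kernel_bank}}.
#' @param lambda \code{"auto"} (k-fold CV over \code{lambda_grid}) or a
#'   single nonnegative value.
#' @param lambda_grid candidate \eqn{\lambda_+} values for CV; default
#'   \code{seq(0, 1, by = 0.1)}.
#' @param folds number of CV folds (default 5; reduced to m with a
#'   warning when m < folds).
#' @param normalize cosine-normalize each kernel (default TRUE).
#' @param universe \code{"intersection"} (default) or \code{"union"}
#'   alignment of the source node sets.
#' @param seed integer seed driving CV fold assignment.
#' @return An object of class \code{"scuba"}: list with \code{ranking}
#'   (data frame: gene, score, rank, normalized_rank), \code{fit}
#'   (\code{\link{scuba_fit}}), \code{eta}, \code{lambda_pos},
#'   \code{lambda_cv} (CV table or NULL), \code{bank}, \code{genes},
#'   \code{call}.
#' @examples
#' sim <- simulate_planted_network(n_genes = 60, module_size = 8,
#'                                 p_in = 0.9, p_out = 0.05, seed = 7)
#' mod <- scuba(sim$network, positives = sim$module[1:4],
#'              kernels = list(medk = c(0.01, 0.04, 0.07)), lambda = 0.5)
#' head(mod$ranking)
#' @export
scuba <- function(networks, positives, candidates = NULL,
                  kernels = list(medk = c(0.01, 0.04, 0.07)),
                  lambda = "auto", lambda_grid = seq(0, 1, by = 0.1),
                  folds = 5L, normalize = TRUE,
                  universe = c("intersection", "union"), seed = 1L) {
  cl <- match.call()
  if (is_gene_network(networks)) networks <- list(networks)
  networks <- align_networks(networks, match.arg(universe))
  genes <- networks[[1L]]$genes

  positives <- unique(as.character(positives))
  missing_pos <- setdiff(positives, genes)
  if (length(missing_pos)) {
    warning("positive gene(s) absent from the network universe, dropped: ",
            paste(missing_pos, collapse = ", "))
    positives <- setdiff(positives, missing_pos)
  }
  if (!length(positives)) stop("no positive genes left in the gene universe")

  if (is.null(candidates)) {
    candidates <- setdiff(genes, positives)
  } else {
    candidates <- unique(as.character(candidates))
    missing_cand <- setdiff(candidates, genes)
    if (length(missing_cand)) {
      warning("candidate gene(s) absent from the network universe, dropped: ",
              paste(missing_cand, collapse = ", "))
      candidates <- setdiff(candidates, missing_cand)
    }
    candidates <- setdiff(candidates, positives)
  }
  if (!length(candidates)) stop("no candidate genes to prioritize")

  bank <- kernel_bank(networks, kernels = kernels, normalize = normalize)
  sets <- labeled_gene_sets(positives, candidates)

  lambda_cv <- NULL
  if (identical(lambda, "auto")) {
    sel <- select_lambda(bank, sets, folds = folds, grid = lambda_grid,
                         seed = seed)
    lambda_pos <- sel$lambda
    lambda_cv <- sel$cv
  } else {
    if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
      stop("'lambda' must be \"auto\" or a single nonnegative number")
    lambda_pos <- lambda
  }

  fit <- scuba_fit(bank, sets, lambda_pos)
  scores <- score_with_bank(fit, bank, candidates)
  ranking <- rank_candidates(scores)

  structure(list(ranking = ranking, fit = fit, eta = fit$eta,
                 lambda_pos = lambda_pos, lambda_cv = lambda_cv,
                 bank = bank, genes = genes, sets = sets, call = cl),
            class = "scuba")
}

# deterministic ranking: decreasing score, ties broken by gene ID
rank_candidates <- function(scores) {
  gene <- names(scores)
  ord <- order(-scores, gene)
  data.frame(gene = gene[ord],
             score = unname(scores[ord]),
             rank = seq_along(ord),
             normalized_rank = seq_along(ord) / length(ord),
             stringsAsFactors = FALSE)
}

#' Select the positive-class regularization by cross-validation
#'
#' For each grid value, the positive set is split into k folds; the model
#' is refit on the retained positives (with the full unlabelled set) and
#' the held-out positives are scored against the fold's unlabelled pool.
#' The grid value maximizing the mean held-out AUC is returned.  Fold
#' assignment is seeded, so the choice is deterministic given
#' \code{(data, seed)}.
#'
#' @param bank a \code{\link{kernel_bank}}.
#' @param sets a \code{\link{labeled_gene_sets}}.
#' @param folds number of folds k (>= 2); reduced to m with a warning
#'   when m < k.
#' @param grid candidate \eqn{\lambda_+} values (non-empty).
#' @param seed integer seed for fold assignment.
#' @return list with \code{lambda} (chosen value) and \code{cv} (data
#'   frame: lambda, mean_auc).
#' @export
select_lambda <- function(bank, sets, folds = 5L,
                          grid = seq(0, 1, by = 0.1), seed = 1L) {
  if (!length(grid)) stop("empty lambda grid")
  grid <- as.numeric(grid)
  if (length(grid) == 1L)
    return(list(lambda = grid,
                cv = data.frame(lambda = grid, mean_auc = NA_real_)))
  m <- sets$m
  if (folds < 2L) stop("'folds' must be >= 2")
  if (m < folds) {
    warning("fewer positives (", m, ") than folds (", folds,
            "); reducing folds to ", m)
    folds <- m
  }
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), m)))

  auc_mat <- matrix(NA_real_, folds, length(grid))
  for (k in seq_len(folds)) {
    held <- sets$positives[fold_id == k]
    train_pos <- sets$positives[fold_id != k]
    if (!length(held) || !length(train_pos)) next
    sets_k <- labeled_gene_sets(train_pos, sets$unlabelled)
    blocks_k <- scuba_blocks(bank, sets_k)
    for (j in seq_along(grid)) {
      fit_k <- scuba_fit(blocks_k, lambda_pos = grid[j])
      s_held <- score_with_bank(fit_k, bank, held)
      s_pool <- score_with_bank(fit_k, bank, sets$unlabelled)
      auc_mat[k, j] <- auc_scores(s_held, s_pool)
    }
  }
  mean_auc <- colMeans(auc_mat, na.rm = TRUE)
  best <- which.max(mean_auc)  # ties: first (smallest lambda)
  list(lambda = grid[best],
       cv = data.frame(lambda = grid, mean_auc = mean_auc))
}

#' @export
print.scuba <- function(x, ...) {
  cat("scuba prioritization\n")
  cat("  gene universe:", length(x$genes), "genes;",
      x$sets$m, "positives,", x$sets$n, "candidates\n")
  cat("  kernels:", length(x$eta), " lambda_pos:", x$lambda_pos, "\n")
  cat("  top candidates:\n")
  print(utils::head(x$ranking, 5L), row.names = FALSE)
  invisible(x)
}

#' @export
summary.scuba <- function(object, ...) {
  eta_by_source <- tapply(object$eta, object$bank$provenance$source, sum)
  out <- list(n_genes = length(object$genes), m = object$sets$m,
              n = object$sets$n, lambda_pos = object$lambda_pos,
              eta = coef(object), eta_by_source = eta_by_source,
              lambda_cv = object$lambda_cv,
              top = utils::head(object$ranking, 10L))
  class(out) <- "summary.scuba"
  out
}

#' @export
print.summary.scuba <- function(x, ...) {
  cat("scuba model summary\n")
  cat(sprintf("  universe %d genes | m = %d positives | n = %d candidates | lambda_pos = %g\n",
              x$n_genes, x$m, x$n, x$lambda_pos))
  cat("  kernel weights (eta):\n")
  print(round(x$eta, 4))
  cat("  eta mass by source:\n")
  print(round(x$eta_by_source, 4))
  if (!is.null(x$lambda_cv)) {
    cat("  lambda_pos cross-validation (mean held-out AUC):\n")
    print(transform(x$lambda_cv, mean_auc = round(mean_auc, 4)),
          row.names = FALSE)
  }
  cat("  top candidates:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.scuba <- function(object, ...) coef(object$fit)

#' @export
fitted.scuba <- function(object, ...)
  stats::setNames(object$ranking$score, object$ranking$gene)

#' Score genes with a fitted scuba model
#'
#' Returns decision scores (and optionally a ranking) for arbitrary genes
#' of the model's universe, using the fitted kernel weights and example
#' distribution.
#'
#' @param object a fitted \code{\link{scuba}} model.
#' @param genes character vector of gene IDs to score; default: the
#'   model's candidate set.
#' @param type \code{"score"} (named numeric vector) or \code{"ranking"}
#'   (data frame as in \code{object$ranking}).
#' @param ... unused.
#' @export
predict.scuba <- function(object, genes = NULL,
                          type = c("score", "ranking"), ...) {
  type <- match.arg(type)
  if (is.null(genes)) genes <- object$sets$unlabelled
  scores <- score_with_bank(object$fit, object$bank, as.character(genes))
  if (type == "score") scores else rank_candidates(scores)
}

#' @export
plot.scuba <- function(x, highlight = NULL, ...) {
  graphics::plot(x$ranking$rank, x$ranking$score, type = "l",
                 xlab = "rank", ylab = "score",
                 main = "scuba candidate scores", ...)
  if (!is.null(highlight)) {
    idx <- match(highlight, x$ranking$gene)
    idx <- idx[!is.na(idx)]
    graphics::points(x$ranking$rank[idx], x$ranking$score[idx],
                     col = "red", pch = 19)
  }
  invisible(x)
}

#' Write a ranking to TSV
#'
#' @param x a \code{scuba} model or a ranking data frame.
#' @param path output file.
#' @export
write_ranking <- function(x, path) {
  ranking <- if (inherits(x, "scuba")) x$ranking else x
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
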