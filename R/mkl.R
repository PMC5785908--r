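#' Positive/unlabelled training sets
#'
#' Bundles the positive gene set P (known disease genes, size m) and the
#' unlabelled set U (candidates, size n) with their +1/-1 labels.  In the
#' positive-unlabelled view only P is trusted: U may hide undiscovered
#' disease genes, which is why the solver regularizes the two classes
#' differently.
#'
#' @param positives character vector of positive gene IDs (size m >= 1).
#' @param unlabelled character vector of unlabelled gene IDs (size n >= 1),
#'   disjoint from \code{positives}.
#' @return object of class \code{"labeled_gene_sets"} with elements
#'   \code{positives}, \code{unlabelled}, \code{m}, \code{n},
#'   \code{labels} (+1 for P then -1 for U).
#' @export
labeled_gene_sets <- function(positives, unlabelled) {
  positives <- as.character(positives)
  unlabelled <- as.character(unlabelled)
  if (!length(positives)) stop("positive set is empty")
  if (!length(unlabelled)) stop("unlabelled set is empty")
  if (anyDuplicated(positives) || anyDuplicated(unlabelled))
    stop("duplicate gene IDs within a set")
  if (length(intersect(positives, unlabelled)))
    stop("positive and unlabelled sets overlap: ",
         paste(utils::head(intersect(positives, unlabelled), 5L), collapse = ", "))
  structure(list(positives = positives, unlabelled = unlabelled,
                 m = length(positives), n = length(unlabelled),
                 labels = c(rep(1, length(positives)),
                            rep(-1, length(unlabelled)))),
            class = "labeled_gene_sets")
}

#' @export
print.labeled_gene_sets <- function(x, ...) {
  cat("labeled_gene_sets: m =", x$m, "positives, n =", x$n, "unlabelled\n")
  invisible(x)
}

# Euclidean projection onto the probability simplex (sort-based algorithm)
project_simplex <- function(v) {
  n <- length(v)
  if (n == 1L) return(1)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_len(n) > 0))
  pmax(v - (css[rho] - 1) / rho, 0)
}

# Projected gradient descent for a convex quadratic over a product of
# simplices.  obj/grad are closures; project maps a free vector onto the
# feasible set.  Backtracking line search; stops when the objective
# decrease falls below tol.
pgd_minimize <- function(obj, grad, project, x0,
                         max_iter = 10000L, tol = 1e-10) {
  x <- project(x0)
  f <- obj(x)
  step <- 1
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- grad(x)
    repeat {
      xn <- project(x - step * g)
      dx <- xn - x
      fn <- obj(xn)
      if (fn <= f + sum(g * dx) + sum(dx * dx) / (2 * step) + 1e-15 ||
          step < 1e-16) break
      step <- step / 2
    }
    if (f - fn < tol) {
      if (fn <= f) { x <- xn; f <- fn }
      converged <- TRUE
      break
    }
    x <- xn
    f <- fn
    step <- step * 1.5
  }
  list(x = x, objective = f, iterations = it, converged = converged)
}

#' Solve the positive-unlabelled margin-distribution problem
#'
#' Minimizes over the m-simplex the reduced objective
#' \deqn{\gamma_+^\top K^+ \gamma_+ - 2\,\gamma_+^\top c
#'       + \lambda_+ \gamma_+^\top \gamma_+}
#' where \eqn{K^+} is the positive-positive block of the combined training
#' kernel and \eqn{c = K^{+-} u} with \eqn{u} the uniform distribution
#' over the unlabelled genes.  This is the unbalanced reformulation in
#' which the unlabelled-class weights are fixed at \eqn{\gamma_- = u}
#' (maximal entropy on the unreliable class), so the solver only ever
#' touches the \eqn{m \times m} positive block and an m-vector per
#' kernel — complexity quadratic in the number of positives, independent
#' of the candidate count.
#'
#' \code{lambda_pos = Inf} returns the uniform distribution analytically.
#'
#' @param K_pos m x m positive-block kernel matrix.
#' @param c_vec m-vector, row-means of the positive-unlabelled kernel
#'   block.
#' @param lambda_pos nonnegative regularization for the positive class
#'   (may be \code{Inf}).
#' @return object of class \code{"gamma_distribution"}: \code{gamma_pos}
#'   (m-simplex vector), \code{objective}, \code{iterations},
#'   \code{converged}, \code{lambda_pos}.
#' @export
solve_scuba <- function(K_pos, c_vec, lambda_pos) {
  K_pos <- as.matrix(K_pos)
  m <- nrow(K_pos)
  if (m == 0L) stop("no positive examples")
  if (length(c_vec) != m) stop("length(c_vec) must equal nrow(K_pos)")
  if (any(!is.finite(K_pos)) || any(!is.finite(c_vec)))
    stop("non-finite kernel entries")
  if (!is.numeric(lambda_pos) || length(lambda_pos) != 1L || lambda_pos < 0)
    stop("'lambda_pos' must be a single nonnegative number (or Inf)")

  obj_at <- function(g) {
    base <- drop(g %*% K_pos %*% g) - 2 * sum(g * c_vec)
    if (is.infinite(lambda_pos)) base else base + lambda_pos * sum(g * g)
  }
  if (is.infinite(lambda_pos) || m == 1L) {
    g <- rep(1 / m, m)
    return(structure(list(gamma_pos = g, objective = obj_at(g),
                          iterations = 0L, converged = TRUE,
                          lambda_pos = lambda_pos),
                     class = "gamma_distribution"))
  }
  grad <- function(g) 2 * (drop(K_pos %*% g) - c_vec + lambda_pos * g)
  res <- pgd_minimize(obj_at, grad, project_simplex, rep(1 / m, m))
  res$x <- unname(res$x)
  structure(list(gamma_pos = res$x, objective = res$objective,
                 iterations = res$iterations, converged = res$converged,
                 lambda_pos = lambda_pos),
            class = "gamma_distribution")
}

#' @export
print.gamma_distribution <- function(x, ...) {
  cat("gamma_distribution over", length(x$gamma_pos),
      "positives; objective", format(x$objective), "\n")
  invisible(x)
}

#' Solve the balanced margin-distribution (EasyMKL) problem
#'
#' Minimizes \eqn{(1-\lambda)\,\gamma^\top Y K^s Y \gamma +
#' \lambda\,\gamma^\top\gamma} over the domain where the positive part and
#' negative part of \eqn{\gamma} each lie on a unit simplex.  This is the
#' fully supervised baseline the unbalanced solver specializes:
#' \eqn{\lambda = 0} gives the hard-margin nearest-points solution,
#' \eqn{\lambda = 1} the class-centroid solution.
#'
#' @param K_sum combined (summed) training kernel, genes ordered P then U.
#' @param sets a \code{\link{labeled_gene_sets}}.
#' @param lam regularization in [0, 1].
#' @return \code{"gamma_distribution"} with \code{gamma_pos},
#'   \code{gamma_neg}, \code{objective}.
#' @export
solve_easymkl <- function(K_sum, sets, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0 || lam > 1)
    stop("'lam' must lie in [0, 1]")
  K_sum <- as.matrix(K_sum)
  m <- sets$m; n <- sets$n
  if (nrow(K_sum) != m + n)
    stop("K_sum must be (m + n) x (m + n) in P-then-U order")
  y <- sets$labels
  YKY <- K_sum * tcrossprod(y)
  obj <- function(g) (1 - lam) * drop(g %*% YKY %*% g) + lam * sum(g * g)
  grad <- function(g) 2 * ((1 - lam) * drop(YKY %*% g) + lam * g)
  project <- function(g)
    c(project_simplex(g[seq_len(m)]), project_simplex(g[m + seq_len(n)]))
  res <- pgd_minimize(obj, grad, project, c(rep(1 / m, m), rep(1 / n, n)))
  res$x <- unname(res$x)
  structure(list(gamma_pos = res$x[seq_len(m)],
                 gamma_neg = res$x[m + seq_len(n)],
                 objective = res$objective, iterations = res$iterations,
                 converged = res$converged, lambda = lam),
            class = "gamma_distribution")
}

#' Per-kernel training summaries for the unbalanced solver
#'
#' One streaming pass over the bank extracts, for each kernel
#' \eqn{K_r}, the positive block \eqn{K^+_r}, the m-vector
#' \eqn{c_r = K^{+-}_r u} and the scalar \eqn{d_r = u^\top K^-_r u}.
#' These summaries are all the solver and the kernel-weight formula ever
#' need, so at most one full kernel is resident alongside the
#' accumulators.
#'
#' @param bank a \code{\link{kernel_bank}}.
#' @param sets a \code{\link{labeled_gene_sets}}; genes must exist in the
#'   bank.
#' @return object of class \code{"scuba_blocks"}: lists \code{K_pos} and
#'   \code{c_vec} (per kernel), numeric \code{d} (per kernel), plus
#'   \code{sets}.
#' @export
scuba_blocks <- function(bank, sets) {
  pi <- match(sets$positives, bank$genes)
  ui <- match(sets$unlabelled, bank$genes)
  if (anyNA(pi))
    stop("positive gene(s) missing from kernel bank: ",
         paste(utils::head(sets$positives[is.na(pi)], 5L), collapse = ", "))
  if (anyNA(ui))
    stop("unlabelled gene(s) missing from kernel bank: ",
         paste(utils::head(sets$unlabelled[is.na(ui)], 5L), collapse = ", "))
  R <- length(bank$kernels)
  K_pos <- vector("list", R)
  c_vec <- vector("list", R)
  d <- numeric(R)
  for (r in seq_len(R)) {
    K <- bank$kernels[[r]]
    K_pos[[r]] <- K[pi, pi, drop = FALSE]
    c_vec[[r]] <- rowMeans(K[pi, ui, drop = FALSE])
    d[r] <- mean(K[ui, ui])
  }
  structure(list(K_pos = K_pos, c_vec = c_vec, d = d, sets = sets,
                 provenance = bank$provenance),
            class = "scuba_blocks")
}

# kernel weights from block summaries, valid when gamma_neg is uniform:
# q_r = (Y gamma)' K_r (Y gamma) = g'K+g - 2 g'c + d
weights_from_blocks <- function(blocks, gamma_pos) {
  q <- vapply(seq_along(blocks$K_pos), function(r) {
    drop(gamma_pos %*% blocks$K_pos[[r]] %*% gamma_pos) -
      2 * sum(gamma_pos * blocks$c_vec[[r]]) + blocks$d[r]
  }, numeric(1))
  q <- pmax(q, 0)  # guard tiny negative values from round-off
  if (sum(q) == 0) {
    warning("all kernel quadratic forms are zero; falling back to uniform weights")
    return(rep(1 / length(q), length(q)))
  }
  q / sum(q)
}

#' Optimal kernel combination weights
#'
#' Given a solved example distribution \eqn{\gamma}, the weight of kernel
#' \eqn{K_r} is its normalized quadratic form
#' \deqn{\eta_r = \frac{(Y\gamma)^\top K_r (Y\gamma)}
#'                     {\sum_s (Y\gamma)^\top K_s (Y\gamma)},}
#' i.e. kernels under which the learned positive and unlabelled
#' representative points are far apart receive large weight.  Each
#' quadratic form is nonnegative because the kernels are PSD; if all
#' vanish the weights fall back to uniform with a warning.
#'
#' @param gamma a \code{gamma_distribution} (if \code{gamma_neg} is
#'   absent, the uniform distribution over U is used).
#' @param sets a \code{\link{labeled_gene_sets}}.
#' @param bank a \code{\link{kernel_bank}}.
#' @return nonnegative weight vector summing to 1, length
#'   \code{n_kernels(bank)}.
#' @export
compute_kernel_weights <- function(gamma, sets, bank) {
  gneg <- if (!is.null(gamma$gamma_neg)) gamma$gamma_neg
          else rep(1 / sets$n, sets$n)
  train <- c(sets$positives, sets$unlabelled)
  ti <- match(train, bank$genes)
  if (anyNA(ti)) stop("training gene(s) missing from kernel bank")
  z <- c(gamma$gamma_pos, -gneg)  # Y gamma
  q <- vapply(bank$kernels, function(K)
    drop(z %*% K[ti, ti, drop = FALSE] %*% z), numeric(1))
  q <- pmax(q, 0)
  if (sum(q) == 0) {
    warning("all kernel quadratic forms are zero; falling back to uniform weights")
    return(rep(1 / length(q), length(q)))
  }
  q / sum(q)
}

#' Fit the two-stage unbalanced MKL model
#'
#' Stage 1 solves the positive-unlabelled problem on the unweighted kernel
#' sum \eqn{K^s}; stage 2 converts the resulting \eqn{\gamma} into kernel
#' weights \eqn{\eta}; stage 3 re-solves on the \eqn{\eta}-weighted
#' combination \eqn{K^*} to obtain the final distribution.
#'
#' @param x a \code{\link{kernel_bank}} or precomputed
#'   \code{\link{scuba_blocks}}.
#' @param sets a \code{\link{labeled_gene_sets}} (ignored, taken from the
#'   blocks, when \code{x} is a \code{scuba_blocks}).
#' @param lambda_pos nonnegative regularization for the positive class
#'   (\code{Inf} allowed).
#' @return object of class \code{"scuba_fit"}: \code{gamma_pos},
#'   \code{gamma_neg} (uniform over U), \code{eta}, \code{lambda_pos},
#'   \code{sets}, \code{objective}, \code{provenance}.
#' @export
scuba_fit <- function(x, sets = NULL, lambda_pos = 1) {
  blocks <- if (inherits(x, "scuba_blocks")) x
            else scuba_blocks(x, sets)
  sets <- blocks$sets
  R <- length(blocks$K_pos)

  # stage 1: plain sum K^s
  Ks <- Reduce(`+`, blocks$K_pos)
  cs <- Reduce(`+`, blocks$c_vec)
  g1 <- solve_scuba(Ks, cs, lambda_pos)

  # stage 2: kernel weights from stage-1 distribution
  eta <- weights_from_blocks(blocks, g1$gamma_pos)

  # stage 3: re-solve on the weighted combination K*
  Kw <- matrix(0, sets$m, sets$m)
  cw <- numeric(sets$m)
  for (r in seq_len(R)) {
    if (eta[r] == 0) next
    Kw <- Kw + eta[r] * blocks$K_pos[[r]]
    cw <- cw + eta[r] * blocks$c_vec[[r]]
  }
  g3 <- solve_scuba(Kw, cw, lambda_pos)

  structure(list(gamma_pos = g3$gamma_pos,
                 gamma_neg = rep(1 / sets$n, sets$n),
                 eta = eta, lambda_pos = lambda_pos, sets = sets,
                 objective = g3$objective, stage1 = g1,
                 provenance = blocks$provenance),
            class = "scuba_fit")
}

#' @export
print.scuba_fit <- function(x, ...) {
  cat("scuba_fit: m =", x$sets$m, "positives, n =", x$sets$n,
      "unlabelled, R =", length(x$eta), "kernels, lambda_pos =",
      x$lambda_pos, "\n")
  cat("kernel weights eta:", paste(format(round(x$eta, 4)), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.scuba_fit <- function(object, ...) {
  stats::setNames(object$eta,
                  paste(object$provenance$source, object$provenance$family,
                        object$provenance$parameter, sep = ":"))
}

#' Score test genes against a fitted model
#'
#' Implements the decision function
#' \eqn{s_i = \sum_j y_j \gamma_j K^{t*}_{ij}}: the weighted contrast
#' between a test gene's similarity to the positive representative point
#' and to the unlabelled centroid.  Higher scores mean more disease-like.
#'
#' @param fit a \code{\link{scuba_fit}}.
#' @param test_rows numeric matrix, test genes x training genes, columns
#'   aligned with P then U under the combined kernel \eqn{K^*}.
#' @return numeric score vector, one per test row.
#' @export
scuba_score <- function(fit, test_rows) {
  test_rows <- rbind(test_rows)
  if (ncol(test_rows) != fit$sets$m + fit$sets$n)
    stop("test_rows must have m + n columns aligned with P then U")
  drop(test_rows %*% (fit$sets$labels * c(fit$gamma_pos, fit$gamma_neg)))
}

# score genes incrementally over the bank: s = sum_r eta_r (K_r[test,P] g+ -
# rowmean K_r[test,U]); avoids materializing the combined kernel
score_with_bank <- function(fit, bank, test_genes) {
  ti <- match(test_genes, bank$genes)
  if (anyNA(ti))
    stop("test gene(s) missing from kernel bank: ",
         paste(utils::head(test_genes[is.na(ti)], 5L), collapse = ", "))
  pi <- match(fit$sets$positives, bank$genes)
  ui <- match(fit$sets$unlabelled, bank$genes)
  s <- numeric(length(ti))
  for (r in seq_along(fit$eta)) {
    if (fit$eta[r] == 0) next
    K <- bank$kernels[[r]]
    s <- s + fit$eta[r] *
      (drop(K[ti, pi, drop = FALSE] %*% fit$gamma_pos) -
         rowMeans(K[ti, ui, drop = FALSE]))
  }
  stats::setNames(s, test_genes)
}
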