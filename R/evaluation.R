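#' Decision score of a held-out gene
#'
#' The fraction of candidate genes scored strictly below the test gene:
#' a value in [0, 1], where 1 means the gene outranks every candidate.
#' Ties count as not outranked (pessimistic convention), so the score is
#' deterministic.
#'
#' @param test_score numeric scalar, the held-out gene's model score.
#' @param candidate_scores numeric vector of candidate-pool scores
#'   (non-empty).
#' @return numeric in [0, 1].
#' @export
decision_score <- function(test_score, candidate_scores) {
  if (!length(candidate_scores)) stop("empty candidate score pool")
  mean(candidate_scores < test_score)
}

#' Filter disease classes by minimum size
#'
#' @param classes named list of gene vectors.
#' @param min_size minimum class size to retain.
#' @return the filtered named list.
#' @export
filter_disease_classes <- function(classes, min_size) {
  classes[lengths(classes) >= min_size]
}

#' Leave-one-out cross-validation protocol over disease classes
#'
#' For each disease class, the positive set P is the class itself and the
#' unlabelled set U is a seeded random sample of out-of-class disease
#' genes of size \eqn{\lceil m/2 \rceil} (disease genes outside the class
#' are the least likely hidden positives).  Every gene of the training
#' set is then held out in turn, the model is refit on the remainder, and
#' the held-out gene is scored alongside all non-disease genes; its
#' decision score is the fraction of that pool it outranks.  Decision
#' scores are pooled across classes and the protocol AUC — the
#' probability that a random held-out gene outranks a random non-disease
#' gene — equals the mean pooled decision score.
#'
#' @param bank a \code{\link{kernel_bank}} over the full gene universe.
#' @param classes named list of disease-class gene vectors (each within
#'   the bank's universe).
#' @param disease_genes character vector of all known disease genes (the
#'   sampling frame for U).
#' @param non_disease_genes character vector of genes associated to no
#'   disease (the candidate scoring pool).
#' @param lambda_pos positive-class regularization used for every refit.
#' @param seed integer seed for the U samples.
#' @return list of class \code{"loocv_report"}: \code{scores} (data
#'   frame: class, gene, held-out role, decision_score), \code{auc},
#'   \code{n_pos}, \code{n_neg}.
#' @export
loocv_protocol <- function(bank, classes, disease_genes, non_disease_genes,
                           lambda_pos = 1, seed = 1L) {
  if (!length(classes)) stop("no disease classes")
  non_disease_genes <- as.character(non_disease_genes)
  if (!length(non_disease_genes)) stop("empty non-disease candidate pool")
  rows <- list()
  for (cls in names(classes)) {
    P <- as.character(classes[[cls]])
    m <- length(P)
    out_frame <- setdiff(as.character(disease_genes), P)
    n_u <- ceiling(m / 2)
    if (length(out_frame) < n_u)
      stop("class '", cls, "': only ", length(out_frame),
           " out-of-class disease genes, need ", n_u)
    U <- with_seed(seed + match(cls, names(classes)),
                   sort(sample(out_frame, n_u)))
    train <- c(P, U)
    for (g in train) {
      P_t <- setdiff(P, g)
      U_t <- setdiff(U, g)
      if (!length(P_t) || !length(U_t))
        stop("class '", cls, "': training set too small for leave-one-out")
      sets_t <- labeled_gene_sets(P_t, U_t)
      fit_t <- scuba_fit(bank, sets_t, lambda_pos)
      s <- score_with_bank(fit_t, bank, c(g, non_disease_genes))
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, gene = g,
        role = if (g %in% P) "positive" else "unlabelled",
        decision_score = decision_score(s[[1L]], s[-1L]),
        stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, rows)
  structure(list(scores = scores,
                 auc = mean(scores$decision_score),
                 n_pos = nrow(scores),
                 n_neg = length(non_disease_genes)),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat("loocv_report:", x$n_pos, "held-out genes vs",
      x$n_neg, "non-disease candidates\n")
  cat("  pooled AUC:", format(round(x$auc, 4)), "\n")
  invisible(x)
}

#' Summary metrics over normalized ranks
#'
#' Given the normalized ranks of test genes from independent
#' prioritizations (rank divided by the number of ranked genes, in
#' (0, 1]), computes the rank median, mean and standard deviation, the
#' true positive rate at the 5\%, 10\% and 30\% thresholds (fraction of
#' test genes ranked within the top \eqn{\tau}) and the averaged AUC.
#' Per prioritization, the AUC is the fraction of the other ranked
#' candidates the test gene outranks, \eqn{(n - r)/(n - 1)}; when the
#' ranking sizes \code{n_ranked} are not supplied it falls back to the
#' large-n approximation \eqn{1 - r/n}.
#'
#' @param normalized_ranks numeric vector in (0, 1].
#' @param n_ranked optional integer vector of ranking sizes, recycled.
#' @param thresholds TPR thresholds, default \code{c(0.05, 0.10, 0.30)}.
#' @return list of class \code{"rank_report"}: \code{median},
#'   \code{mean}, \code{sd}, \code{tpr} (named vector of fractions),
#'   \code{auc}.
#' @export
rank_metrics <- function(normalized_ranks, n_ranked = NULL,
                         thresholds = c(0.05, 0.10, 0.30)) {
  q <- as.numeric(normalized_ranks)
  if (any(q <= 0 | q > 1) || anyNA(q))
    stop("normalized ranks must lie in (0, 1]")
  tpr <- vapply(thresholds, function(tau) mean(q <= tau), numeric(1))
  names(tpr) <- paste0("top", thresholds * 100, "%")
  if (!is.null(n_ranked)) {
    n <- rep_len(as.numeric(n_ranked), length(q))
    r <- round(q * n)
    auc <- mean(ifelse(n > 1, (n - r) / (n - 1), 1))
  } else {
    auc <- mean(1 - q)
  }
  structure(list(median = stats::median(q), mean = mean(q),
                 sd = stats::sd(q), tpr = tpr, auc = auc),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, ...) {
  cat(sprintf("rank_report: median %.4f | mean %.4f +/- %.4f | AUC %.4f\n",
              x$median, x$mean, x$sd, x$auc))
  cat("  TPR:", paste(sprintf("%s %.1f%%", names(x$tpr), 100 * x$tpr),
                      collapse = " | "), "\n")
  invisible(x)
}

#' Hanley-McNeil test for the difference of two AUCs
#'
#' Compares two areas under independent ROC curves using the 1982
#' Hanley-McNeil standard error
#' \deqn{SE^2 = \frac{A(1-A) + (n_+ - 1)(Q_1 - A^2) + (n_- - 1)(Q_2 - A^2)}
#'                   {n_+ n_-}}
#' with \eqn{Q_1 = A/(2-A)} and \eqn{Q_2 = 2A^2/(1+A)};
#' \eqn{z = (A_1 - A_2)/\sqrt{SE_1^2 + SE_2^2}} is referred to the
#' standard normal (two-sided).
#'
#' @param auc1,auc2 the two AUCs, in [0, 1].
#' @param n_pos,n_neg positive and negative sample sizes (>= 2), common
#'   to both curves.
#' @return list with \code{z}, \code{p}, \code{se1}, \code{se2}.
#' @export
hanley_mcneil <- function(auc1, auc2, n_pos, n_neg) {
  if (auc1 < 0 || auc1 > 1 || auc2 < 0 || auc2 > 1)
    stop("AUCs must lie in [0, 1]")
  if (n_pos < 2 || n_neg < 2) stop("need n_pos, n_neg >= 2")
  se <- function(A) {
    Q1 <- A / (2 - A)
    Q2 <- 2 * A^2 / (1 + A)
    sqrt((A * (1 - A) + (n_pos - 1) * (Q1 - A^2) +
            (n_neg - 1) * (Q2 - A^2)) / (n_pos * n_neg))
  }
  se1 <- se(auc1)
  se2 <- se(auc2)
  if (auc1 == auc2) return(list(z = 0, p = 1, se1 = se1, se2 = se2))
  denom <- sqrt(se1^2 + se2^2)
  if (denom == 0) stop("zero combined standard error with unequal AUCs")
  z <- (auc1 - auc2) / denom
  list(z = z, p = 2 * stats::pnorm(-abs(z)), se1 = se1, se2 = se2)
}

#' Paired Wilcoxon signed-rank comparison of two rank vectors
#'
#' Two-sided signed-rank test on paired differences (e.g. normalized
#' ranks of the same test genes under two methods).  Zero differences are
#' dropped.  For up to 25 non-zero differences the exact permutation null
#' of the signed-rank statistic is used (computed by dynamic programming
#' over the observed, possibly tied, ranks); above that, the normal
#' approximation with continuity correction.
#'
#' @param ranks_a,ranks_b equal-length numeric vectors (length >= 5).
#' @return two-sided p-value.
#' @export
paired_rank_test <- function(ranks_a, ranks_b) {
  if (length(ranks_a) != length(ranks_b))
    stop("rank vectors must have equal length")
  if (length(ranks_a) < 5L) stop("need at least 5 pairs")
  d <- ranks_a - ranks_b
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero")
    return(1)
  }
  n <- length(d)
  if (n > 25L) {
    res <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = TRUE))
    return(unname(res$p.value))
  }
  # exact sign-flip null: distribution of W+ over all 2^n sign patterns of
  # the observed ranks; doubled ranks are integers even under ties
  r <- rank(abs(d))
  w2 <- as.integer(round(2 * r))
  W2 <- as.integer(round(2 * sum(r[d > 0])))
  total <- sum(w2)
  cnt <- numeric(total + 1L)
  cnt[1L] <- 1
  for (w in w2)
    cnt <- cnt + c(rep(0, w), cnt[seq_len(total + 1L - w)])
  probs <- cnt / 2^n
  p_le <- sum(probs[seq_len(W2 + 1L)])
  p_ge <- sum(probs[(W2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}
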