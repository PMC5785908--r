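# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ROC AUC of positive scores against negative scores (pROC, trapezoid)
auc_scores <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores))
    stop("need at least one positive and one negative score")
  r <- pROC::roc(response = c(rep(1L, length(pos_scores)),
                              rep(0L, length(neg_scores))),
                 predictor = c(pos_scores, neg_scores),
                 levels = c(0L, 1L), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}
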