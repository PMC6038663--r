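#' Tie-corrected AUC from two score sets
#'
#' The probability that a randomly drawn test score exceeds a randomly
#' drawn candidate score, counting ties as one half -- the Mann-Whitney
#' rank statistic.
#'
#' @param test_scores,candidate_scores non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(test_scores, candidate_scores) {
  n1 <- length(test_scores); n0 <- length(candidate_scores)
  if (n1 == 0L || n0 == 0L) stop("both score sets must be non-empty")
  r <- rank(c(test_scores, candidate_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC points over all score thresholds
#'
#' One (FPR, TPR) point per distinct score value (threshold "score >=
#' t"), bracketed by (0, 0) and (1, 1).  Both rates are nondecreasing
#' along the returned curve, and its trapezoidal area equals the
#' tie-corrected rank AUC.
#'
#' @param test_scores,candidate_scores non-empty numeric vectors.
#' @return data.frame with columns `fpr` and `tpr`.
#' @export
roc_points <- function(test_scores, candidate_scores) {
  if (length(test_scores) == 0L || length(candidate_scores) == 0L) {
    stop("both score sets must be non-empty")
  }
  thr <- sort(unique(c(test_scores, candidate_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(test_scores >= t), 0)
  fpr <- vapply(thr, function(t) mean(candidate_scores >= t), 0)
  out <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (out$fpr[nrow(out)] != 1 || out$tpr[nrow(out)] != 1) {
    out <- rbind(out, data.frame(fpr = 1, tpr = 1))
  }
  out
}

#' Trapezoidal area under a ROC curve
#' @param roc data.frame with `fpr`, `tpr` as from [roc_points()].
#' @return Area in `[0, 1]`.
#' @export
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# Within-disease candidate-percentile transform: each cell's score is
# replaced by the fraction of that disease's candidate cells it beats
# (ties counted half).  Monotone per disease, so with a single disease
# ranks -- and hence the AUC -- are unchanged.
.per_disease_percentile <- function(fad, known) {
  out <- fad
  for (i in seq_len(nrow(fad))) {
    cand <- fad[i, !known[i, ]]
    if (length(cand) == 0L) { out[i, ] <- NA_real_; next }
    out[i, ] <- vapply(fad[i, ], function(s) {
      (sum(cand < s) + 0.5 * sum(cand == s)) / length(cand)
    }, 0)
  }
  out
}

#' Leave-one-out evaluation of a score matrix
#'
#' Scores never depend on the gold-standard pairs, so they are computed
#' once; "leaving out" a gold pair just means ranking it against the
#' candidate pairs (all disease-lncRNA cells not in the gold standard).
#' Under the `"global"` policy every gold pair is ranked in the single
#' pooled candidate set; under `"per_disease"` scores are first mapped
#' to within-disease candidate percentiles, so each pair is effectively
#' ranked against candidates of its own disease.
#'
#' @param fad D x L score matrix with disease row names and lncRNA
#'   column names.
#' @param gold `assoc_table` of known disease-lncRNA pairs; every pair
#'   must map to a cell of `fad`.
#' @param policy `"global"` (default) or `"per_disease"`.
#' @return Object of class `loocv_result`: list with `per_test_ranks`
#'   (data.frame: disease, lncrna, score, rank among candidates,
#'   candidate count), `roc` (data.frame fpr/tpr), `auc`, and the
#'   settings.
#' @export
loocv_evaluate <- function(fad, gold, policy = c("global", "per_disease")) {
  policy <- match.arg(policy)
  pairs <- gold_pairs(gold)
  if (nrow(pairs) == 0L) stop("gold standard is empty; nothing to evaluate")
  bad_d <- !(pairs$disease %in% rownames(fad))
  bad_l <- !(pairs$lncrna %in% colnames(fad))
  if (any(bad_d | bad_l)) {
    k <- which(bad_d | bad_l)[1L]
    stop("gold pair (", pairs$disease[k], ", ", pairs$lncrna[k],
         ") is outside the score matrix")
  }
  known <- matrix(FALSE, nrow(fad), ncol(fad), dimnames = dimnames(fad))
  known[cbind(pairs$disease, pairs$lncrna)] <- TRUE
  if (all(known)) stop("no candidate pairs: every cell is a gold pair")
  scores <- if (policy == "per_disease") {
    .per_disease_percentile(fad, known)
  } else fad
  pos <- scores[cbind(pairs$disease, pairs$lncrna)]
  neg <- scores[!known]
  neg <- neg[!is.na(neg)]
  if (any(is.na(pos))) {
    stop("a gold pair's disease has no candidate pairs to rank against")
  }
  if (policy == "global") {
    ranks <- vapply(pos, function(s) 1 + sum(neg > s) + 0.5 * sum(neg == s), 0)
    n_cand <- rep(length(neg), length(pos))
  } else {
    ranks <- n_cand <- numeric(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      cand <- fad[pairs$disease[k], !known[pairs$disease[k], ]]
      s <- fad[pairs$disease[k], pairs$lncrna[k]]
      ranks[k] <- 1 + sum(cand > s) + 0.5 * sum(cand == s)
      n_cand[k] <- length(cand)
    }
  }
  structure(
    list(
      per_test_ranks = data.frame(
        disease = pairs$disease, lncrna = pairs$lncrna,
        score = fad[cbind(pairs$disease, pairs$lncrna)],
        rank = ranks, n_candidates = n_cand,
        stringsAsFactors = FALSE
      ),
      roc = roc_points(pos, neg),
      auc = rank_auc(pos, neg),
      settings = list(policy = policy)
    ),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("loocv_result: %d gold pairs vs %d candidates, AUC = %.4f (%s)\n",
              nrow(x$per_test_ranks), x$per_test_ranks$n_candidates[1L],
              x$auc, x$settings$policy))
  invisible(x)
}

#' Similarity-weighting ablation
#'
#' Evaluates the two arms of the method on identical inputs: raw scores
#' (`FAD = C13`) versus similarity-weighted scores
#' (`FAD = FSD %*% C13 %*% FSL`).
#'
#' @param net `tripartite_network`.
#' @param fsd,fsl functional similarity matrices aligned to the
#'   network's disease and lncRNA order.
#' @param gold gold-standard `assoc_table`.
#' @param r radius (default 6).
#' @param policy ranking policy, see [loocv_evaluate()].
#' @return Named list `auc_with_similarity`, `auc_without`, plus the two
#'   full `loocv_result` objects.
#' @export
ablation_compare <- function(net, fsd, fsl, gold, r = 6L,
                             policy = c("global", "per_disease")) {
  policy <- match.arg(policy)
  spm <- shortest_path_matrix(net, r)
  c13 <- extract_c13(association_degree(build_dccm(spm)), net)
  with_sim <- loocv_evaluate(final_scores(c13, fsd, fsl), gold, policy)
  without <- loocv_evaluate(c13, gold, policy)
  list(auc_with_similarity = with_sim$auc, auc_without = without$auc,
       with_similarity = with_sim, without_similarity = without)
}

#' Top-ranked predictions
#'
#' Flattens the score matrix, sorts descending, and returns the top
#' fraction of all disease-lncRNA pairs.  Ties are broken by (disease
#' name, lncRNA name) lexicographic order so the list is reproducible.
#'
#' @param fad D x L score matrix.
#' @param fraction fraction of all D x L pairs to return, in `(0, 1]`
#'   (default 0.005); the list has `ceiling(fraction * D * L)` rows.
#' @param gold optional gold-standard `assoc_table` used to flag already
#'   known pairs.
#' @return data.frame with columns disease, lncrna, score, rank, known.
#' @export
top_fraction <- function(fad, fraction = 0.005, gold = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  df <- data.frame(
    disease = rep(rownames(fad), times = ncol(fad)),
    lncrna = rep(colnames(fad), each = nrow(fad)),
    score = as.vector(fad),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$score, df$disease, df$lncrna), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$known <- FALSE
  if (!is.null(gold)) {
    pairs <- gold_pairs(gold)
    df$known <- paste(df$disease, df$lncrna, sep = "\r") %in%
      paste(pairs$disease, pairs$lncrna, sep = "\r")
  }
  n_top <- ceiling(fraction * nrow(df))
  rownames(df) <- NULL
  df[seq_len(n_top), , drop = FALSE]
}
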