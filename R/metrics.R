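#' Confusion counts
#'
#' @param y_true,y_pred Label vectors (`"positive"`/`"negative"`).
#' @return Named vector `TP, TN, FP, FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  c(TP = sum(y_true == "positive" & y_pred == "positive"),
    TN = sum(y_true == "negative" & y_pred == "negative"),
    FP = sum(y_true == "negative" & y_pred == "positive"),
    FN = sum(y_true == "positive" & y_pred == "negative"))
}

#' ROC-AUC of a score
#'
#' Area under the sensitivity versus (1 - specificity) curve, computed via
#' the Mann-Whitney rank identity (ties count one half).
#'
#' @param y_true Labels (`"positive"`/`"negative"`).
#' @param y_score Higher = more positive.
#' @return AUC in `[0, 1]`, or `NA` if one class is absent.
#' @export
roc_auc <- function(y_true, y_score) {
  pos <- y_true == "positive"
  n1 <- as.numeric(sum(pos)); n0 <- as.numeric(sum(!pos))
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(y_score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall AUC (average precision)
#'
#' Area under the precision-recall curve summed as
#' `sum (R_i - R_{i-1}) P_i` over distinct score thresholds (descending).
#'
#' @inheritParams roc_auc
#' @return PR-AUC in `[0, 1]`, or `NA` if one class is absent.
#' @export
pr_auc <- function(y_true, y_score) {
  pos <- y_true == "positive"
  n1 <- sum(pos)
  if (n1 == 0 || n1 == length(y_true)) return(NA_real_)
  ord <- order(y_score, decreasing = TRUE)
  pos <- pos[ord]; sc <- y_score[ord]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- c(sc[-1] != sc[-length(sc)], TRUE)  # block ends of tied scores
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Classification metric set
#'
#' Accuracy, sensitivity (recall), specificity, F1, precision from the
#' confusion counts, plus ROC-AUC and PR-AUC from the score. The positive
#' class is `"positive"` (responder / facilitation). With a single-class
#' truth vector the AUCs are flagged `NA`.
#'
#' @param y_true,y_pred Labels.
#' @param y_score Continuous score (higher = more positive).
#' @return Named numeric vector `accuracy, sensitivity, specificity, f1,
#'   precision, roc_auc, pr_auc`.
#' @export
evaluate_metrics <- function(y_true, y_pred, y_score) {
  cc <- confusion_counts(y_true, y_pred)
  tp <- cc["TP"]; tn <- cc["TN"]; fp <- cc["FP"]; fn <- cc["FN"]
  out <- c(
    accuracy = unname((tp + tn) / sum(cc)),
    sensitivity = unname(tp / (tp + fn)),
    specificity = unname(tn / (fp + tn)),
    f1 = unname(2 * tp / (2 * tp + fp + fn)),
    precision = unname(tp / (tp + fp)),
    roc_auc = roc_auc(y_true, y_score),
    pr_auc = pr_auc(y_true, y_score))
  out
}
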