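#' Regression error metrics
#'
#' Root-mean-square error, mean absolute error (both kcal/mol) and the
#' Pearson correlation between predicted and experimental ddG. The
#' correlation is `NA` for zero-variance input or n < 2.
#'
#' @param pred,obs Equal-length numeric vectors.
#' @return Named list: `rmse`, `mae`, `pcc`.
#' @export
regression_metrics <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  pcc <- if (length(obs) >= 2L && stats::sd(pred) > 0 &&
               stats::sd(obs) > 0) {
    stats::cor(pred, obs)
  } else NA_real_
  list(rmse = sqrt(mean((pred - obs)^2)),
       mae = mean(abs(pred - obs)),
       pcc = pcc)
}

#' Binary classification metrics at a ddG threshold
#'
#' The positive class is stabilizing: observed (and predicted) ddG
#' strictly above `threshold`. Returns sensitivity (TPR), specificity
#' (TNR), positive and negative predictive values, accuracy and the
#' Matthews correlation coefficient. By the usual convention MCC is 0
#' when any confusion-matrix marginal is zero.
#'
#' @param pred,obs Equal-length numeric vectors.
#' @param threshold Classification threshold in kcal/mol (default 0).
#' @return Named list: `sen`, `spe`, `ppv`, `npv`, `acc`, `mcc`, plus
#'   the confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
binary_metrics <- function(pred, obs, threshold = 0) {
  stopifnot(length(pred) == length(obs))
  p <- pred > threshold
  o <- obs > threshold
  tp <- sum(p & o); fp <- sum(p & !o)
  fn <- sum(!p & o); tn <- sum(!p & !o)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  mden <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(sen = safe(tp, tp + fn), spe = safe(tn, tn + fp),
       ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn),
       acc = (tp + tn) / length(pred),
       mcc = if (mden == 0) 0 else (tp * tn - fp * fn) / mden,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' ROC and precision-recall curves with AUC
#'
#' Sweeps every distinct score cut (ties grouped) using the predicted
#' ddG as score (higher = more stabilizing) and labels from the observed
#' ddG at `threshold`. Areas are trapezoidal; the ROC area equals the
#' concordance probability with half credit for score ties. The
#' precision-recall baseline (positive prevalence) is reported because
#' PRC is the more informative view on unbalanced data.
#'
#' @param pred,obs Equal-length numeric vectors.
#' @param threshold Label threshold in kcal/mol.
#' @return List: `roc` (`data.frame` fpr/tpr), `prc` (`data.frame`
#'   recall/precision), `auc_roc`, `auc_prc`, `prevalence`.
#' @export
roc_prc <- function(pred, obs, threshold = 0) {
  stopifnot(length(pred) == length(obs))
  lab <- obs > threshold
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC/PRC need both classes present")
  }
  o <- order(pred, decreasing = TRUE)
  s <- pred[o]; l <- lab[o]
  # group ties: cumulative counts at each distinct score
  last <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc_roc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  # PRC starts at recall of the first cut with its precision
  rec2 <- c(0, rec)
  prec2 <- c(prec[1], prec)
  auc_prc <- sum(diff(rec2) * (utils::head(prec2, -1) +
                                 utils::tail(prec2, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       prc = data.frame(recall = rec2, precision = prec2),
       auc_roc = auc_roc, auc_prc = auc_prc,
       prevalence = n_pos / length(lab))
}

#' Three-state classification of prediction errors
#'
#' Mutations are destabilizing when ddG <= -1 kcal/mol, stabilizing when
#' ddG >= +1, neutral in between (boundary values go to the non-neutral
#' classes). Observed and predicted vectors are coded 0/1/2; `sc` is the
#' percentage predicted in the correct class, `of1` off by one class
#' (e.g. destabilizing predicted neutral), `of2` the
#' destabilizing/stabilizing confusions. The three always sum to 100.
#'
#' @param pred,obs Equal-length numeric vectors (kcal/mol).
#' @return Named list: `sc`, `of1`, `of2` (percentages).
#' @export
three_state <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  code <- function(x) ifelse(x <= -1, 0L, ifelse(x >= 1, 2L, 1L))
  d <- abs(code(pred) - code(obs))
  list(sc = 100 * mean(d == 0L),
       of1 = 100 * mean(d == 1L),
       of2 = 100 * mean(d == 2L))
}

#' Anti-symmetry diagnostics of direct vs reverse predictions
#'
#' For paired predictions of each mutation and its reverse: `r_sym` is
#' the absolute Pearson correlation between the two vectors (1 for a
#' perfectly anti-symmetric predictor) and `delta` the mean of their
#' sums in kcal/mol (0 without systematic bias).
#'
#' @param direct_pred,reverse_pred Paired numeric vectors.
#' @return Named list: `r_sym`, `delta`.
#' @export
antisymmetry <- function(direct_pred, reverse_pred) {
  stopifnot(length(direct_pred) == length(reverse_pred))
  r <- if (length(direct_pred) >= 2L && stats::sd(direct_pred) > 0 &&
             stats::sd(reverse_pred) > 0) {
    abs(stats::cor(direct_pred, reverse_pred))
  } else NA_real_
  list(r_sym = r, delta = mean(direct_pred + reverse_pred))
}

#' Floor extreme predictions
#'
#' Clamps predictions from below at `floor` kcal/mol — a utility for
#' comparing external predictors that occasionally emit runaway
#' destabilizing values (e.g. from hard clashes). Off by default in all
#' pipelines.
#'
#' @param pred Numeric vector.
#' @param floor Lower clamp in kcal/mol.
#' @return `pmax(pred, floor)`.
#' @export
cap_predictions <- function(pred, floor = -8) {
  pmax(pred, floor)
}

#' Full evaluation report
#'
#' Assembles every performance measure — regression errors, binary
#' classification at `threshold`, ROC/PRC areas, the three-state
#' percentages, and (when reverse predictions are supplied) the
#' anti-symmetry diagnostics — into one flat list.
#'
#' @param pred,obs Predicted and experimental ddG (kcal/mol).
#' @param reverse_pred Optional paired reverse-mutation predictions.
#' @param threshold Binary threshold (kcal/mol).
#' @return Named list of all metrics plus `n`.
#' @export
eval_report <- function(pred, obs, reverse_pred = NULL, threshold = 0) {
  out <- c(regression_metrics(pred, obs),
           binary_metrics(pred, obs, threshold)[
             c("sen", "spe", "ppv", "npv", "acc", "mcc")],
           roc_prc(pred, obs, threshold)[
             c("auc_roc", "auc_prc", "prevalence")],
           three_state(pred, obs))
  if (!is.null(reverse_pred)) out <- c(out, antisymmetry(pred, reverse_pred))
  out$n <- length(pred)
  out
}
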