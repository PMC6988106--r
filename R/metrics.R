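# Surface-node evaluation: scar Dice, generalized Dice over all labels,
# accuracy / sensitivity / specificity, plus the correlation analysis
# between LA segmentation quality and scar segmentation quality.

#' Surface-node segmentation metrics
#'
#' Confusion-count metrics over mesh nodes, comparing a predicted 0/1 node
#' labeling against the projected ground truth: `Dice(scar) =
#' 2TP / (2TP + FP + FN)`, accuracy, sensitivity, specificity, and the
#' generalized Dice
#' `GDice = 2 * sum_k |S_k_auto  n  S_k_manual| / sum_k (|S_k_auto| + |S_k_manual|)`
#' over the `N_k = 2` labels. When the truth has no scar nodes the
#' sensitivity is reported as `NA` (not 0).
#'
#' @param pred,truth Binary (0/1) node label vectors of equal length.
#' @return Object of class `metrics_report`: `dice_scar`, `gdice`,
#'   `accuracy`, `sensitivity`, `specificity`, `n_nodes`, and the per-label
#'   counts `overlap`, `size_auto`, `size_manual` (index 1 = label 0).
#' @export
surface_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors must match in length")
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  if (any(!pred %in% 0:1) || any(!truth %in% 0:1))
    stop("labels must be binary 0/1")
  n <- length(pred)
  tp <- sum(pred == 1L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  overlap <- c(tn, tp)
  size_auto <- c(tn + fn, tp + fp)
  size_manual <- c(tn + fp, tp + fn)
  dice_scar <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NaN
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(dice_scar = dice_scar,
                 gdice = 2 * sum(overlap) / (sum(size_auto) + sum(size_manual)),
                 accuracy = (tp + tn) / n,
                 sensitivity = sens,
                 specificity = spec,
                 n_nodes = n,
                 overlap = overlap, size_auto = size_auto,
                 size_manual = size_manual),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> n = %d nodes | Dice(scar) %.3f | ",
                     "GDice %.3f | acc %.3f | sens %s | spec %s\n"),
              x$n_nodes, x$dice_scar, x$gdice, x$accuracy,
              formatC(x$sensitivity, digits = 3, format = "f"),
              formatC(x$specificity, digits = 3, format = "f")))
  invisible(x)
}

#' Correlation between LA segmentation and scar segmentation quality
#'
#' Pearson and Spearman correlations of per-case scar Dice against LA Dice,
#' plus the R-squared of the ordinary least-squares fit of scar Dice on LA
#' Dice. Quantifies how strongly scar quantification accuracy depends on the
#' quality of the automatic LA segmentation.
#'
#' @param dice_la,dice_scar Per-case Dice scores (equal length >= 3).
#' @return List with `pearson`, `spearman`, `r_squared`, `slope`,
#'   `intercept`, `n`.
#' @export
correlation_report <- function(dice_la, dice_scar) {
  if (length(dice_la) != length(dice_scar)) stop("lengths must match")
  if (length(dice_la) < 3) stop("need at least 3 cases")
  if (stats::sd(dice_la) == 0 || stats::sd(dice_scar) == 0)
    stop("zero variance input: correlation undefined")
  fit <- stats::lm(dice_scar ~ dice_la)
  list(pearson = stats::cor(dice_la, dice_scar),
       spearman = stats::cor(dice_la, dice_scar, method = "spearman"),
       r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(dice_la))
}
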