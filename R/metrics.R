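#' Segmentation accuracy metrics
#'
#' Foreground accuracy is the percentage of true foreground pixels
#' classified as foreground (sensitivity), background accuracy the
#' percentage of true background pixels classified as background
#' (specificity).  The overall accuracy is their unweighted mean, which
#' counters the bias toward the typically much larger background class.
#' The Dice coefficient `2 TP / (2 TP + FP + FN)` is reported alongside.
#'
#' The package-wide mask rule is `phi >= 0` = foreground: the measure-zero
#' set `phi = 0` counts as foreground everywhere (extraction and metrics
#' use the same rule).
#'
#' @param pred,truth Binary matrices (nonzero = foreground) of equal shape;
#'   `truth` must contain at least one foreground and one background pixel.
#' @return An object of class `"accuracy_report"`: list with `fg`, `bg`,
#'   `overall` (percent), `dice` (fraction) and the counts `tp`, `fp`,
#'   `tn`, `fn`.
#' @examples
#' truth <- matrix(0, 10, 10); truth[3:6, 3:6] <- 1
#' accuracy_report(truth, truth)$overall  # 100
#' @export
accuracy_report <- function(pred, truth) {
  assert_same_dim(pred, truth, "pred and truth")
  p <- pred != 0; t <- truth != 0
  if (!any(t) || all(t))
    stop("degenerate truth: needs foreground and background pixels",
         call. = FALSE)
  tp <- sum(p & t); fn <- sum(!p & t)
  tn <- sum(!p & !t); fp <- sum(p & !t)
  fg <- 100 * tp / (tp + fn)
  bg <- 100 * tn / (tn + fp)
  structure(list(fg = fg, bg = bg, overall = (fg + bg) / 2,
                 dice = 2 * tp / (2 * tp + fp + fn),
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("FG %.1f%%  BG %.1f%%  overall %.1f%%  Dice %.4f\n",
              x$fg, x$bg, x$overall, x$dice))
  invisible(x)
}

#' @export
as.data.frame.accuracy_report <- function(x, ...) {
  data.frame(fg = x$fg, bg = x$bg, overall = x$overall, dice = x$dice,
             tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn)
}

#' Dice coefficient
#'
#' @inheritParams accuracy_report
#' @return Dice overlap in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  assert_same_dim(pred, truth, "pred and truth")
  p <- pred != 0; t <- truth != 0
  2 * sum(p & t) / (sum(p) + sum(t))
}
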