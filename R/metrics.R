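#' Confusion matrix from binary predictions and truth
#'
#' Tallies true/false positives and negatives for two equal-length binary
#' label vectors. Labels may be logical, 0/1 numeric, or a two-level factor
#' or character vector; anything truthy (`TRUE`, `1`, `"1"`, `"yes"`,
#' `"positive"`, case-insensitive) counts as the positive class.
#'
#' @param predictions predicted labels.
#' @param truth reference labels, same length.
#' @return an object of class `kg_confusion`: a list with integer fields
#'   `tp`, `tn`, `fp`, `fn`.
#' @examples
#' cm <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' mcc(cm)
#' @export
confusion <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    stop("`predictions` and `truth` must have the same length (",
         length(predictions), " vs ", length(truth), ")", call. = FALSE)
  }
  p <- as_binary_label(predictions, "predictions")
  t <- as_binary_label(truth, "truth")
  new_confusion(
    tp = sum(p & t), tn = sum(!p & !t),
    fp = sum(p & !t), fn = sum(!p & t)
  )
}

#' Construct a confusion matrix from its four counts
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return a `kg_confusion` object.
#' @examples
#' new_confusion(tp = 272, tn = 272, fp = 23, fn = 23)
#' @export
new_confusion <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  counts <- stats::setNames(as.integer(round(counts)), names(counts))
  structure(as.list(counts), class = "kg_confusion")
}

#' @export
print.kg_confusion <- function(x, ...) {
  cat("<kg_confusion>  tp:", x$tp, " tn:", x$tn, " fp:", x$fp, " fn:", x$fn, "\n")
  invisible(x)
}

as_binary_label <- function(x, what) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) {
      stop("`", what, "` must be binary (0/1, logical, or yes/no)", call. = FALSE)
    }
    return(x == 1)
  }
  lx <- tolower(as.character(x))
  pos <- lx %in% c("1", "true", "yes", "positive", "pos")
  neg <- lx %in% c("0", "false", "no", "negative", "neg")
  if (!all(pos | neg)) {
    stop("`", what, "` contains labels that are not recognisably binary",
         call. = FALSE)
  }
  pos
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, computed in double
#' precision. When any factor of the denominator is zero the coefficient is
#' undefined; the common convention of returning 0 is used so that pipelines
#' stay total on degenerate inputs.
#'
#' @param cm a `kg_confusion` object (or anything coercible via its counts).
#' @return a number in \[-1, 1\].
#' @examples
#' mcc(new_confusion(272, 272, 23, 23)) # 0.844
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "kg_confusion"))
  tp <- as.numeric(cm$tp); tn <- as.numeric(cm$tn)
  fp <- as.numeric(cm$fp); fn <- as.numeric(cm$fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Full evaluation report from a confusion matrix
#'
#' Computes the six metrics used throughout the pipeline: sensitivity
#' (recall), specificity, precision, accuracy, F1-score, and the Matthews
#' correlation coefficient. Proportions are returned on the 0-1 scale at
#' full precision; ratios with a zero denominator are reported as 0 and
#' flagged in the `degenerate` attribute.
#'
#' @param cm a `kg_confusion` object.
#' @return a one-row tibble with columns `tp`, `tn`, `fp`, `fn`,
#'   `sensitivity`, `specificity`, `precision`, `accuracy`, `f1`, `mcc`.
#' @examples
#' metrics_report(new_confusion(141, 139, 13, 11))
#' @export
metrics_report <- function(cm) {
  stopifnot(inherits(cm, "kg_confusion"))
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  if (tp + tn + fp + fn == 0) {
    stop("cannot compute metrics for an empty confusion matrix", call. = FALSE)
  }
  degenerate <- character(0)
  if (tp + fn == 0) degenerate <- c(degenerate, "sensitivity")
  if (tn + fp == 0) degenerate <- c(degenerate, "specificity")
  if (tp + fp == 0) degenerate <- c(degenerate, "precision")
  if (2 * tp + fp + fn == 0) degenerate <- c(degenerate, "f1")
  out <- tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, tn + fp),
    precision   = safe_ratio(tp, tp + fp),
    accuracy    = (tp + tn) / (tp + tn + fp + fn),
    f1          = safe_ratio(2 * tp, 2 * tp + fp + fn),
    mcc         = mcc(cm)
  )
  attr(out, "degenerate") <- degenerate
  out
}

#' F1 score directly from label vectors
#'
#' @inheritParams confusion
#' @return the F1 score (0 when the harmonic mean is degenerate).
#' @export
f1_score <- function(predictions, truth) {
  metrics_report(confusion(predictions, truth))$f1
}

#' @rdname metrics_report
#' @param x a `kg_confusion` object.
#' @param ... unused.
#' @export
tidy.kg_confusion <- function(x, ...) {
  metrics_report(x) |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "metric", values_to = "value")
}

#' @rdname metrics_report
#' @export
glance.kg_confusion <- function(x, ...) metrics_report(x)

#' Plot a confusion matrix as a tile heatmap
#'
#' @param object a `kg_confusion`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.kg_confusion <- function(object, ...) {
  df <- tibble::tibble(
    truth = factor(c("positive", "negative", "negative", "positive"),
                   levels = c("positive", "negative")),
    predicted = factor(c("positive", "negative", "positive", "negative"),
                       levels = c("positive", "negative")),
    count = c(object$tp, object$tn, object$fp, object$fn)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(x = "predicted", y = "truth", title = "Confusion matrix")
}
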