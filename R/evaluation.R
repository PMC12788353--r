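#' Confusion matrix between truth and prediction
#'
#' Counts are `counts[c1, c2] = #` pixels with truth class `c1` predicted
#' as `c2`. Background pixels (truth 0) are always excluded; supply `mask`
#' to further restrict to evaluation pixels (e.g. held-out test pixels).
#' A prediction label outside the truth vocabulary is an error.
#'
#' @param truth,pred `M x N` integer matrices or [label_map()]s, or plain
#'   integer vectors of equal length.
#' @param mask optional logical matrix/vector selecting evaluation pixels.
#' @param class_ids class vocabulary; defaults to the sorted positive truth
#'   labels.
#' @return object of class `ConfusionMatrix`: `counts` (K x K), `class_ids`.
#' @export
confusion <- function(truth, pred, mask = NULL, class_ids = NULL) {
  tv <- if (inherits(truth, "LabelMap")) truth$labels else truth
  pv <- if (inherits(pred, "LabelMap")) pred$labels else pred
  tv <- as.vector(tv); pv <- as.vector(pv)
  if (length(tv) != length(pv)) stop("truth and prediction shapes differ")
  keep <- tv > 0L
  if (!is.null(mask)) keep <- keep & as.vector(mask)
  tv <- tv[keep]; pv <- pv[keep]
  if (is.null(class_ids)) class_ids <- sort(unique(tv))
  if (any(!pv %in% c(0L, class_ids)))
    stop("prediction contains labels outside the class vocabulary")
  f <- factor(tv, levels = class_ids)
  g <- factor(pv, levels = class_ids)
  counts <- table(truth = f, prediction = g)
  structure(list(counts = unclass(as.matrix(counts)),
                 class_ids = as.integer(class_ids)),
            class = "ConfusionMatrix")
}

#' Accuracy metrics from a confusion matrix
#'
#' Overall accuracy `OA = 100 * trace / total`; average accuracy `AA` is
#' the unweighted mean of per-class recalls (classes with no evaluation
#' pixels are dropped with a warning); Cohen's kappa
#' `(po - pe) / (1 - pe)` with `po = trace / total` and
#' `pe = sum_k row_k * col_k / total^2`. When `pe == 1` kappa is undefined
#' and reported as `NA` with a warning.
#'
#' @param cm a [confusion()] result.
#' @return object of class `EvalReport`: `oa`, `aa` (percent), `kappa`,
#'   `per_class` (percent, named by class id), `n`.
#' @export
eval_metrics <- function(cm) {
  stopifnot(inherits(cm, "ConfusionMatrix"))
  counts <- cm$counts
  total <- sum(counts)
  if (total <= 0) stop("empty confusion matrix")
  po <- sum(diag(counts)) / total
  row_tot <- rowSums(counts)
  col_tot <- colSums(counts)
  pe <- sum(row_tot * col_tot) / total^2
  kappa <- if (abs(1 - pe) < 1e-15) {
    warning("expected chance agreement is 1; kappa undefined")
    NA_real_
  } else (po - pe) / (1 - pe)
  has_truth <- row_tot > 0
  if (any(!has_truth))
    warning(sprintf("%d class(es) with no evaluation pixels dropped from AA",
                    sum(!has_truth)))
  per_class <- rep(NA_real_, length(row_tot))
  per_class[has_truth] <- 100 * diag(counts)[has_truth] / row_tot[has_truth]
  names(per_class) <- cm$class_ids
  structure(list(oa = 100 * po, aa = mean(per_class[has_truth]),
                 kappa = kappa, per_class = per_class, n = total),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport (%d pixels): OA %.2f%%  AA %.2f%%  kappa %.4f\n",
              x$n, x$oa, x$aa, x$kappa))
  for (i in seq_along(x$per_class))
    cat(sprintf("  class %s: %.2f%%\n", names(x$per_class)[i], x$per_class[i]))
  invisible(x)
}
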