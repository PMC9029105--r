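#' Confusion-matrix metrics for user-level predictions
#'
#' Computes TP/TN/FP/FN and the derived indicators with the suicidal class as
#' positive:
#' accuracy `(TP+TN)/(TP+FN+FP+TN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and F1 `2PR/(P+R)`. Accuracy alone is misleading under class
#' imbalance — predicting everyone as the majority class already scores high —
#' so F1 is the primary indicator and accuracy is reported for reference.
#'
#' Any 0/0 ratio (e.g. no predicted positives) is reported as 0 and flagged in
#' the `zero_division` column, with a warning, so degenerate runs stay
#' visible.
#'
#' @param data A data frame of predictions.
#' @param truth,estimate Names of the columns holding true and predicted
#'   labels (canonical label strings or 0/1).
#' @return A one-row tibble with `tp`, `tn`, `fp`, `fn`, `accuracy`,
#'   `precision`, `recall`, `f1`, `zero_division`.
#' @examples
#' d <- data.frame(label = c("suicidal", "non_suicidal"),
#'                 .pred = c("suicidal", "non_suicidal"))
#' compute_metrics(d)
#' @export
compute_metrics <- function(data, truth = "label", estimate = ".pred") {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    stop("predictions must be a non-empty data frame", call. = FALSE)
  }
  y <- as_binary_label(data[[truth]])
  p <- as_binary_label(data[[estimate]])
  if (anyNA(y) || anyNA(p)) stop("labels must not be missing", call. = FALSE)
  tp <- sum(y == 1L & p == 1L)
  tn <- sum(y == 0L & p == 0L)
  fp <- sum(y == 0L & p == 1L)
  fn <- sum(y == 1L & p == 0L)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  zero_division <- anyNA(c(precision, recall, f1))
  if (zero_division) {
    warning("0/0 encountered in precision/recall/F1; reporting 0",
            call. = FALSE)
  }
  tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = precision %|NA|% 0,
    recall = recall %|NA|% 0,
    f1 = f1 %|NA|% 0,
    zero_division = zero_division
  )
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x

#' Compare several classification runs on the same test set
#'
#' @param runs A named list of prediction data frames, each with the same
#'   user set (column `user_id`), identical true labels, and columns named in
#'   `truth`/`estimate`.
#' @inheritParams compute_metrics
#' @return A tibble with one row per method (`method`, `accuracy`, `f1`,
#'   `precision`, `recall`), sorted by F1 descending, with attribute `deltas`:
#'   all ordered method pairs and their accuracy/F1 differences in percentage
#'   points (the field's convention for reporting method gains, e.g. an
#'   accuracy step from 93.94% to 95.75% is a +1.81 point delta). Retrieve it
#'   with [method_deltas()].
#' @export
compare_methods <- function(runs, truth = "label", estimate = ".pred") {
  if (!length(runs) || is.null(names(runs)) || any(!nzchar(names(runs)))) {
    stop("runs must be a non-empty named list", call. = FALSE)
  }
  ref <- sort(runs[[1]][["user_id"]])
  for (nm in names(runs)) {
    if (!identical(sort(runs[[nm]][["user_id"]]), ref)) {
      stop("run '", nm, "' was evaluated on a different test user set",
           call. = FALSE)
    }
  }
  rows <- lapply(names(runs), function(nm) {
    m <- compute_metrics(runs[[nm]], truth = truth, estimate = estimate)
    dplyr::bind_cols(tibble(method = nm), m[, c("accuracy", "f1",
                                                "precision", "recall")])
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$f1))
  pairs <- expand.grid(method_a = out$method, method_b = out$method,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$method_a != pairs$method_b, , drop = FALSE]
  ia <- match(pairs$method_a, out$method)
  ib <- match(pairs$method_b, out$method)
  deltas <- tibble(
    method_a = pairs$method_a, method_b = pairs$method_b,
    accuracy_delta_pp = 100 * (out$accuracy[ia] - out$accuracy[ib]),
    f1_delta_pp = 100 * (out$f1[ia] - out$f1[ib])
  )
  attr(out, "deltas") <- deltas
  class(out) <- c("dhesd_comparison", class(out))
  out
}

#' @rdname compare_methods
#' @param comparison A [compare_methods()] result.
#' @export
method_deltas <- function(comparison) {
  d <- attr(comparison, "deltas")
  if (is.null(d)) stop("no deltas attribute; not a comparison table",
                       call. = FALSE)
  d
}

#' Write a metrics report or comparison table
#'
#' @param x A tibble from [compute_metrics()] or [compare_methods()].
#' @param path Output path; `.json` writes JSON, anything else TSV.
#' @export
write_metrics <- function(x, path) {
  if (grepl("\\.json$", path)) {
    writeLines(jsonlite::toJSON(as.data.frame(x), dataframe = "rows",
                                auto_unbox = TRUE, digits = NA), path)
  } else {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @method autoplot dhesd_comparison
#' @export
autoplot.dhesd_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("method", "accuracy", "f1")],
    cols = c("accuracy", "f1"), names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(
    x = stats::reorder(.data$method, -.data$value),
    y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score", fill = NULL,
                  title = "Method comparison on the shared test set") +
    ggplot2::theme_minimal()
}
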