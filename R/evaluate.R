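#' Half-up rounding for report display
#'
#' Rounds halves away from zero (0.765 -> 0.77 at 2 dp), the convention used
#' for displayed report values; base `round()` rounds half to even. Guarded
#' against binary floating-point representation of decimal inputs.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Per-class confusion metrics for a binary prevalence classifier
#'
#' Assigns class `"improved"` where the predicted probability is at or above
#' the threshold and computes precision, recall and F1 treating each class
#' in turn as the positive one, plus overall accuracy.
#'
#' @param y Observed class, character `"improved"`/`"unimproved"` (or 0/1
#'   with 1 = improved).
#' @param p_hat Predicted probability of the improved class.
#' @param threshold Classification threshold in (0, 1), default 0.5.
#' @return A list: `per_class` tibble (`class`, `obs`, `pct`, `precision`,
#'   `recall`, `f1`) and scalar `accuracy`.
#' @export
confusion_metrics <- function(y, p_hat, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1, length(y) == length(p_hat))
  if (is.numeric(y)) y <- ifelse(y == 1, "improved", "unimproved")
  stopifnot(all(y %in% c("improved", "unimproved")))
  pred <- ifelse(p_hat >= threshold, "improved", "unimproved")
  n <- length(y)
  per_class <- purrr::map_dfr(c("unimproved", "improved"), function(cls) {
    tp <- sum(y == cls & pred == cls)
    fp <- sum(y != cls & pred == cls)
    fn <- sum(y == cls & pred != cls)
    obs <- sum(y == cls)
    if (obs == 0) {
      warning("class '", cls, "' absent from y; its recall is undefined", call. = FALSE)
      recall <- NA_real_
    } else recall <- tp / (tp + fn)
    precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) NA_real_
          else 2 * precision * recall / (precision + recall)
    tibble::tibble(class = cls, obs = obs, pct = 100 * obs / n,
                   precision = precision, recall = recall, f1 = f1)
  })
  list(per_class = per_class, accuracy = mean(y == pred), n = n)
}

#' Macro average of a per-class metric
#'
#' Unweighted mean over classes; missing class values are dropped.
#'
#' @param values Per-class metric values.
#' @return Scalar mean.
#' @export
macro_average <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("all class values are missing", call. = FALSE)
  mean(v)
}

#' Observation-weighted average of a per-class metric
#'
#' `sum(value_c * obs_c) / sum(obs_c)`: the weighted-macro average where
#' weights are class observation counts.
#'
#' @param values Per-class metric values.
#' @param obs Per-class observation counts (>= 0, summing to > 0).
#' @return Scalar weighted mean.
#' @export
weighted_average <- function(values, obs) {
  stopifnot(length(values) == length(obs), all(obs >= 0))
  keep <- !is.na(values)
  if (sum(obs[keep]) == 0) stop("total observation count is zero", call. = FALSE)
  sum(values[keep] * obs[keep]) / sum(obs[keep])
}

#' Rank-based ROC-AUC
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties counting one half (equivalent to the
#' Mann-Whitney statistic).
#'
#' @param y Binary outcome: 1/`"improved"` positive.
#' @param p_hat Scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y, p_hat) {
  if (is.character(y) || is.factor(y)) y <- as.numeric(as.character(y) == "improved")
  stopifnot(all(y %in% c(0, 1)), length(y) == length(p_hat))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(p_hat, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Summarize per-class evaluation inputs into the report layout
#'
#' Given per-class observation counts and metrics (one row per component x
#' class), recomputes the class percentage shares and the macro and
#' observation-weighted averages of each metric. Useful for reproducing a
#' published-style evaluation table from its per-class entries; a worked
#' example ships as `example_class_metrics.csv` in `inst/extdata`.
#'
#' @param class_metrics Data frame with columns `component`, `class`,
#'   `obs`, and one or more metric columns (e.g. `precision`, `recall`,
#'   `f1`).
#' @return A tibble: per component, one row per class (with `pct`), plus
#'   `macro-average` and `weighted average` rows for each metric.
#' @export
summarize_class_metrics <- function(class_metrics) {
  cm <- tibble::as_tibble(class_metrics)
  metric_cols <- setdiff(names(cm), c("component", "class", "obs"))
  purrr::map_dfr(unique(cm$component), function(comp) {
    sub <- cm[cm$component == comp, ]
    n <- sum(sub$obs)
    rows <- dplyr::mutate(sub, pct = 100 * .data$obs / n, .after = "obs")
    avg <- function(f, label) {
      out <- tibble::tibble(component = comp, class = label, obs = NA_real_, pct = NA_real_)
      for (m in metric_cols) out[[m]] <- f(sub[[m]], sub$obs)
      out
    }
    dplyr::bind_rows(
      rows,
      avg(function(v, o) macro_average(v), "macro-average"),
      avg(function(v, o) weighted_average(v, o), "weighted average")
    )
  })
}

#' Evaluation report across dwelling components
#'
#' Assembles, per component, the per-class observation counts and
#' percentages, precision/recall/F1, the macro and weighted-average rows,
#' accuracy and ROC-AUC — the standard layout for reporting classification
#' performance of prevalence models — plus a feature-importance table (time
#' excluded by default to keep the geographic covariates comparable).
#'
#' @param results Named list (by component) of lists with elements `y`
#'   (observed class) and `p_hat` (predicted probability); components with
#'   `NULL` entries are omitted with a warning.
#' @param fits Optional named list of `dwell_fit` objects for the
#'   importance table.
#' @param threshold Classification threshold.
#' @return A list: `metrics` tibble (long layout: component, row label,
#'   obs, pct, precision, recall, f1, roc_auc, accuracy) and `importance`
#'   tibble (or `NULL`).
#' @export
evaluation_report <- function(results, fits = NULL, threshold = 0.5) {
  rows <- list()
  for (comp in names(results)) {
    res <- results[[comp]]
    if (is.null(res)) { warning("no results for component '", comp, "'", call. = FALSE); next }
    cm <- confusion_metrics(res$y, res$p_hat, threshold)
    auc <- roc_auc(res$y, res$p_hat)
    pc <- cm$per_class
    rows[[comp]] <- dplyr::bind_rows(
      tibble::tibble(component = comp, row = "total", obs = cm$n, pct = 100,
                     precision = NA, recall = NA, f1 = NA,
                     roc_auc = auc, accuracy = cm$accuracy),
      tibble::tibble(component = comp, row = pc$class, obs = pc$obs, pct = pc$pct,
                     precision = pc$precision, recall = pc$recall, f1 = pc$f1,
                     roc_auc = NA, accuracy = NA),
      tibble::tibble(component = comp, row = "macro-average", obs = NA, pct = NA,
                     precision = macro_average(pc$precision),
                     recall = macro_average(pc$recall),
                     f1 = macro_average(pc$f1), roc_auc = NA, accuracy = NA),
      tibble::tibble(component = comp, row = "weighted average", obs = NA, pct = NA,
                     precision = weighted_average(pc$precision, pc$obs),
                     recall = weighted_average(pc$recall, pc$obs),
                     f1 = weighted_average(pc$f1, pc$obs), roc_auc = NA, accuracy = NA)
    )
  }
  importance <- NULL
  if (!is.null(fits)) {
    importance <- purrr::imap_dfr(fits, function(f, comp) {
      if (is.null(f)) return(NULL)
      dplyr::mutate(posterior_fixed_effects(f), component = comp, .before = 1)
    })
    importance <- importance[!importance$term %in% c("(Intercept)", "log_time"), ]
    importance <- dplyr::arrange(importance, .data$component, dplyr::desc(.data$importance))
  }
  list(metrics = dplyr::bind_rows(rows), importance = importance)
}
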