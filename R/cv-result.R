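#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s classifier, %d pairs, seed %s)\n",
              x$config$folds, x$config$classifier, x$config$n_pairs,
              x$config$seed))
  m <- x$summary$mean
  s <- x$summary$sd
  for (nm in names(m)) {
    cat(sprintf("  %-5s %.4f +/- %.4f\n", nm, m[[nm]], s[[nm]]))
  }
  invisible(x)
}

#' Per-fold metrics of a cross-validation result
#' @param x A `cv_result` from [cross_validate()].
#' @param ... Unused.
#' @return Tibble with one row per fold.
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' One-row summary (mean and sd of every metric) of a cross-validation
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One-row tibble with `<metric>_mean` and `<metric>_sd` columns.
#' @export
glance.cv_result <- function(x, ...) {
  m <- as.list(x$summary$mean)
  s <- as.list(x$summary$sd)
  names(m) <- paste0(names(m), "_mean")
  names(s) <- paste0(names(s), "_sd")
  tibble::as_tibble(c(m, s))
}

# ROC sweep (FPR, TPR) of one fold's held-out predictions.
roc_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]
  tp <- cumsum(labels)
  fp <- cumsum(1 - labels)
  keep <- which(!duplicated(scores[ord], fromLast = TRUE))
  tibble::tibble(
    fpr = c(0, fp[keep] / sum(1 - labels)),
    tpr = c(0, tp[keep] / sum(labels))
  )
}

#' ROC curves of the held-out folds
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object: one ROC curve per fold with the mean AUC in
#'   the subtitle.
#' @export
autoplot.cv_result <- function(object, ...) {
  curves <- dplyr::bind_rows(lapply(
    split(object$predictions, object$predictions$fold),
    function(d) dplyr::mutate(roc_points(d$label, d$score), fold = d$fold[1L])
  ))
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr,
                                       colour = factor(.data$fold))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate", colour = "Fold",
      title = sprintf("%d-fold ROC (%s)", object$config$folds,
                      object$config$classifier),
      subtitle = sprintf("mean AUC = %.4f +/- %.4f",
                         object$summary$mean[["auc"]],
                         object$summary$sd[["auc"]])
    ) +
    ggplot2::theme_minimal()
}

#' Write a cross-validation report to JSON or CSV
#'
#' The JSON report carries the full configuration snapshot (classifier,
#' folds, seeds, thresholds and any upstream hyperparameters attached by
#' the pipeline driver) alongside per-fold and summary metrics, so a run
#' can be reproduced from its report alone.
#'
#' @param cv A `cv_result`.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(cv, path) {
  stopifnot(inherits(cv, "cv_result"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(
        config = cv$config,
        folds = cv$folds,
        mean = as.list(cv$summary$mean),
        sd = as.list(cv$summary$sd)
      ),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  } else if (grepl("\\.csv$", path)) {
    utils::write.csv(cv$folds, path, row.names = FALSE)
  } else {
    abort("`path` must end in .json or .csv.")
  }
  invisible(path)
}
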