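#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a metrics report into long form
#'
#' @param x a `cogscreen_metrics` tibble (from [evaluate()] or [kfold_cv()]).
#' @param ... unused.
#' @return tibble with columns `metric`, `value`.
#' @exportS3Method generics::tidy
tidy.cogscreen_metrics <- function(x, ...) {
  tibble::tibble(metric = names(x), value = as.numeric(x[1, ]))
}

#' @rdname tidy.cogscreen_metrics
#' @exportS3Method generics::glance
glance.cogscreen_metrics <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cogscreen_metrics")
  out
}

#' Tidy an ensemble's member list
#'
#' @param x a `cogscreen_ensemble` (or its config).
#' @param ... unused.
#' @return tibble with `member`, `learner`, `boost_rounds`, `pca_vc`.
#' @exportS3Method generics::tidy
tidy.cogscreen_ensemble <- function(x, ...) tidy(x$config)

#' @rdname tidy.cogscreen_ensemble
#' @exportS3Method generics::tidy
tidy.cogscreen_ensemble_config <- function(x, ...) {
  purrr::map_dfr(seq_along(x$members), function(i) {
    m <- x$members[[i]]
    tibble::tibble(member = i, learner = m$spec$name,
                   boost_rounds = m$boost_rounds %||% NA_integer_,
                   pca_vc = m$spec$pca_vc %||% NA_real_)
  })
}

#' Tidy a task score
#'
#' @param x a `cogscreen_score`.
#' @param ... unused.
#' @return one-row tibble with the points and scalar auxiliaries.
#' @exportS3Method generics::tidy
tidy.cogscreen_score <- function(x, ...) {
  aux <- x$aux[vapply(x$aux, function(v) is.numeric(v) && length(v) == 1, logical(1))]
  dplyr::bind_cols(
    tibble::tibble(task_id = x$task_id, points = x$points, max_points = x$max_points),
    tibble::as_tibble(aux))
}

#' Plot a metrics report
#'
#' Confusion-matrix tile plot; when pooled cross-validation predictions
#' are attached (as [kfold_cv()] does), the ROC curve is drawn instead
#' with the AUC in the subtitle.
#'
#' @param object a `cogscreen_metrics` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cogscreen_metrics <- function(object, ...) {
  preds <- attr(object, "predictions")
  if (!is.null(preds) && !anyNA(preds$p1)) {
    ord <- order(preds$p1, decreasing = TRUE)
    yy <- preds$y_true[ord]
    df <- tibble::tibble(
      fpr = c(0, cumsum(1 - yy) / sum(1 - yy)),
      tpr = c(0, cumsum(yy) / sum(yy)))
    return(ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
             ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
             ggplot2::geom_abline(linetype = 3) +
             ggplot2::labs(x = "False positive rate", y = "True positive rate",
                           title = "Pooled cross-validated ROC",
                           subtitle = sprintf("weighted AUC = %.3f", object$auc_roc)) +
             ggplot2::theme_minimal())
  }
  cm <- attr(object, "confusion")
  df <- tibble::as_tibble(as.data.frame(cm))
  names(df) <- c("truth", "prediction", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$prediction, .data$truth, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white", size = 5) +
    ggplot2::scale_fill_gradient(low = "#4393c3", high = "#d6604d", guide = "none") +
    ggplot2::labs(x = "Predicted class", y = "True class",
                  title = sprintf("Accuracy %.2f%%, kappa %.3f",
                                  object$accuracy_pct, object$kappa)) +
    ggplot2::theme_minimal()
}

#' Overlay a drawn trajectory on its reference curve
#'
#' @param drawn trajectory or curve drawn by the subject.
#' @param reference reference curve (e.g. the displayed spiral).
#' @return a ggplot object annotated with the discrete Frechet distance.
#' @export
plot_trajectory_match <- function(drawn, reference) {
  d <- as_curve(drawn); r <- as_curve(reference)
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(r), which = "reference"),
    dplyr::mutate(tibble::as_tibble(d), which = "drawn"))
  fd <- discrete_frechet(d, r)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$which)) +
    ggplot2::geom_path(linewidth = 0.6) +
    ggplot2::scale_y_reverse() +   # screen coordinates: y grows downward
    ggplot2::coord_equal() +
    ggplot2::scale_colour_manual(values = c(reference = "grey55", drawn = "#b2182b")) +
    ggplot2::labs(title = sprintf("Discrete Frechet distance: %.1f px", fd),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Feature-group separation overview for a labeled feature table
#'
#' Standardized mean difference (impaired minus healthy) of every feature,
#' summarized per schema group.
#'
#' @param table labeled feature table.
#' @param schema feature schema.
#' @return a ggplot object.
#' @export
plot_group_separation <- function(table, schema = feature_schema()) {
  tab <- impute_features(table, schema)
  smd <- vapply(schema$feature, function(f) {
    v <- tab[[f]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(0)
    (mean(v[tab$label == 1]) - mean(v[tab$label == 0])) / s
  }, numeric(1))
  df <- tibble::tibble(feature = schema$feature, group = schema$group, smd = smd)
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$smd)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Standardized mean difference (impaired - healthy)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
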