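#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cluster model: one row per user
#'
#' @param x A `sleeprec_cluster_model`.
#' @param ... Unused.
#' @return Tibble `user_id`, `cluster`, `silhouette`, `ambiguous`.
#' @export
tidy.sleeprec_cluster_model <- function(x, ...) x$labels

#' One-row cluster model summary
#'
#' @param x A `sleeprec_cluster_model`.
#' @param ... Unused.
#' @export
glance.sleeprec_cluster_model <- function(x, ...) {
  tibble::tibble(k = x$k,
                 silhouette = x$silhouette_by_k$silhouette[
                   x$silhouette_by_k$k == x$k],
                 n_features = length(x$retained),
                 n_components = x$pca$m,
                 variance_explained = sum(x$pca$ev_ratio[seq_len(x$pca$m)]),
                 n_users = nrow(x$labels),
                 n_ambiguous = sum(x$labels$ambiguous),
                 inertia = x$inertia)
}

#' Tidy a trained ranker: the per-epoch history
#'
#' @param x A `sleeprec_ranker`.
#' @param ... Unused.
#' @export
tidy.sleeprec_ranker <- function(x, ...) x$history

#' One-row ranker summary
#'
#' @param x A `sleeprec_ranker`.
#' @param ... Unused.
#' @export
glance.sleeprec_ranker <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 val_loss = x$val_loss, n_items = length(x$items),
                 seed = x$seed)
}

#' Tidy an evaluation report: per-seed, per-model metrics
#'
#' @param x A `sleeprec_eval_report`.
#' @param ... Unused.
#' @export
tidy.sleeprec_eval_report <- function(x, ...) x$by_seed

#' Seed-averaged evaluation summary
#'
#' @param x A `sleeprec_eval_report`.
#' @param ... Unused.
#' @export
glance.sleeprec_eval_report <- function(x, ...) x$summary

#' PCA-space cluster scatter
#'
#' First two principal-component scores colored by cluster, ambiguous users
#' hollow.
#'
#' @param object A `sleeprec_cluster_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sleeprec_cluster_model <- function(object, ...) {
  df <- tibble::as_tibble(object$pca$scores[, 1:min(2, object$pca$m),
                                            drop = FALSE],
                          .name_repair = ~ c("PC1", "PC2")[seq_along(.x)])
  if (!"PC2" %in% names(df)) df$PC2 <- 0
  df$cluster <- factor(object$labels$cluster)
  df$ambiguous <- object$labels$ambiguous
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   color = .data$cluster,
                                   shape = .data$ambiguous)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(title = sprintf("K-means in PCA space (k = %d)", object$k),
                  shape = "ambiguous") +
    ggplot2::theme_minimal()
}

#' Training-history curve
#'
#' @param object A `sleeprec_ranker`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sleeprec_ranker <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(title = "Ranker training history") +
    ggplot2::theme_minimal()
}

#' Model-comparison bars with seed SD error bars
#'
#' @param object A `sleeprec_eval_report`.
#' @param metric `"map"` or `"f1"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sleeprec_eval_report <- function(object, metric = c("map", "f1"),
                                          ...) {
  metric <- match.arg(metric)
  s <- object$summary
  mcol <- paste0(ifelse(metric == "map", "map", "f1"), "_mean")
  scol <- paste0(ifelse(metric == "map", "map", "f1"), "_sd")
  ggplot2::ggplot(s, ggplot2::aes(.data$model, .data[[mcol]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                        ymax = .data[[mcol]] + .data[[scol]]),
                           width = 0.2) +
    ggplot2::labs(y = toupper(metric),
                  title = "Recommendation performance by configuration") +
    ggplot2::theme_minimal()
}

#' Per-k silhouette curve
#'
#' @param model A `sleeprec_cluster_model`.
#' @return A ggplot.
#' @export
plot_silhouette_by_k <- function(model) {
  ggplot2::ggplot(model$silhouette_by_k,
                  ggplot2::aes(.data$k, .data$silhouette)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_point(data = model$silhouette_by_k[
      model$silhouette_by_k$k == model$k, ], color = "red", size = 3) +
    ggplot2::labs(title = "Silhouette score by number of clusters") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
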