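#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_step geom_line
#'   geom_point geom_col scale_fill_gradient labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Consensus CDF curves across k
#'
#' The empirical CDF of upper-triangle consensus values per k; a curve
#' hugging 0 and 1 (flat middle) indicates stable clustering at that k.
#'
#' @param object a `consensus_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, ...) {
  df <- purrr::map_dfr(as.character(object$k_range), function(k) {
    v <- object$consensus[[k]]
    v <- sort(v[upper.tri(v)])
    tibble::tibble(k = k, value = v, cdf = seq_along(v) / length(v))
  })
  ggplot(df, aes(x = .data$value, y = .data$cdf, colour = .data$k)) +
    geom_step() +
    labs(x = "consensus value", y = "CDF", colour = "k",
         title = "Consensus CDF by cluster count") +
    theme_minimal()
}

#' Consensus matrix heatmap at one k
#'
#' Samples are ordered by the final consensus tree so co-clustering blocks
#' appear on the diagonal.
#'
#' @param result a `consensus_result`.
#' @param k which cluster count to show.
#' @return A ggplot object.
#' @export
plot_consensus_matrix <- function(result, k) {
  stopifnot(inherits(result, "consensus_result"))
  m <- result$consensus[[as.character(k)]]
  ord <- hclust(as.dist(1 - m), method = result$params$linkage)$order
  m <- m[ord, ord]
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    consensus = as.vector(m)
  )
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$consensus)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "navy", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, title = paste0("Consensus matrix, k = ", k)) +
    theme_minimal()
}

#' Kaplan-Meier curves by group
#'
#' @param object a `km_logrank` object.
#' @param ... unused.
#' @return A ggplot object of the product-limit estimates.
#' @method autoplot km_logrank
#' @export
autoplot.km_logrank <- function(object, ...) {
  df <- tidy(object)
  start <- dplyr::distinct(df, .data$group)
  start$time <- 0; start$estimate <- 1
  df <- dplyr::bind_rows(start[, c("group", "time", "estimate")],
                         df[, c("group", "time", "estimate")])
  ggplot(df, aes(x = .data$time, y = .data$estimate, colour = .data$group)) +
    geom_step() +
    labs(x = "months", y = "recurrence-free survival",
         subtitle = paste0("log-rank p = ", signif(object$p_value, 3))) +
    theme_minimal()
}

#' Genome-wide copy-number summary profile
#'
#' Cross-sample mean of the (smoothed, centered) marker values along the
#' genome, with detected peaks marked.
#'
#' @param cohort a `cn_cohort`.
#' @param peaks optional peak tibble from [peel_and_repeat()].
#' @return A ggplot object.
#' @export
plot_cn_profile <- function(cohort, peaks = NULL) {
  stopifnot(inherits(cohort, "cn_cohort"))
  df <- dplyr::bind_cols(cohort$markers,
                         tibble::tibble(mean_cn = rowMeans(cohort$values)))
  df$index <- seq_len(nrow(df))
  p <- ggplot(df, aes(x = .data$index, y = .data$mean_cn)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~chrom, scales = "free_x", nrow = 1) +
    labs(x = "marker", y = "mean log2 copy number") +
    theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    pk <- dplyr::left_join(peaks,
                           dplyr::mutate(cohort$markers,
                                         index = dplyr::row_number()),
                           by = c(peak_marker = "marker_id", "chrom"))
    pk$mean_cn <- df$mean_cn[match(pk$peak_marker, df$marker_id)]
    p <- p + geom_point(data = pk, colour = "red")
  }
  p
}

#' Silhouette width bar plot
#'
#' @param silhouette tibble from [silhouette_core_samples()].
#' @return A ggplot object; negative bars mark non-core samples.
#' @export
plot_silhouette <- function(silhouette) {
  df <- dplyr::arrange(silhouette, .data$subtype, dplyr::desc(.data$sil_width))
  df$rank <- seq_len(nrow(df))
  ggplot(df, aes(x = .data$rank, y = .data$sil_width, fill = .data$subtype)) +
    geom_col(width = 1) +
    labs(x = NULL, y = "silhouette width") +
    theme_minimal()
}
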