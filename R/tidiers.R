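#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy consensus clustering diagnostics
#'
#' @param x a `consensus_result`.
#' @param ... unused.
#' @return The per-k diagnostics tibble (area, delta-area, PAC, label
#'   tracking).
#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) {
  x$diagnostics
}

#' Per-sample consensus labels in long form
#'
#' @param x a `consensus_result`.
#' @param ... unused.
#' @return Tibble: sample_id, k, label.
#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$labels),
    k_min = min(x$k_range), k_max = max(x$k_range),
    n_resamples = x$params$n_resamples,
    item_fraction = x$params$item_fraction
  )
}

#' Tidy a trained subtype model
#'
#' @param x a `subtype_model`.
#' @param ... unused.
#' @return The classifier gene tibble (gene_id, class, score).
#' @method tidy subtype_model
#' @export
tidy.subtype_model <- function(x, ...) {
  x$genes
}

#' One-row model summary
#'
#' @param x a `subtype_model`.
#' @param ... unused.
#' @return Tibble with class count, gene counts and the winning CV error.
#' @method glance subtype_model
#' @export
glance.subtype_model <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    genes_per_class = x$genes_per_class,
    n_genes = nrow(x$genes),
    cv_error = if (is.null(x$cv)) NA_real_ else min(x$cv$cv_error),
    distance_metric = x$distance_metric
  )
}

#' Tidy SAM-style differential expression results
#'
#' @param x a `sam_result`.
#' @param ... unused.
#' @return Per-gene tibble: gene_id, d, called.
#' @method tidy sam_result
#' @export
tidy.sam_result <- function(x, ...) {
  x$genes
}

#' One-row SAM summary
#'
#' @param x a `sam_result`.
#' @param ... unused.
#' @return Tibble with cutoff, called count and estimated median FDR.
#' @method glance sam_result
#' @export
glance.sam_result <- function(x, ...) {
  tibble::tibble(
    cutoff = x$cutoff, n_called = x$n_called, median_fdr = x$median_fdr,
    s0 = x$s0, n_perm = x$n_perm, fdr_threshold = x$fdr_threshold
  )
}

#' Tidy Kaplan-Meier curves
#'
#' @param x a `km_logrank` object.
#' @param ... unused.
#' @return Tibble: group, time, n_risk, n_event, estimate (the product-limit
#'   survival), std_error. Every group's estimate is 1 at time 0.
#' @method tidy km_logrank
#' @export
tidy.km_logrank <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(x$groups[1], length(s$time)) else
    sub("^g=", "", as.character(s$strata))
  tibble::tibble(group = grp, time = s$time, n_risk = s$n.risk,
                 n_event = s$n.event, estimate = s$surv,
                 std_error = s$std.err)
}

#' One-row log-rank summary
#'
#' @param x a `km_logrank` object.
#' @param ... unused.
#' @return Tibble: statistic, df, p_value.
#' @method glance km_logrank
#' @export
glance.km_logrank <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Tidy a cross-study centroid distance matrix
#'
#' @param x a `centroid_distance` matrix.
#' @param ... unused.
#' @return Long tibble: subtype_a, subtype_b, distance.
#' @method tidy centroid_distance
#' @export
tidy.centroid_distance <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    subtype_a = rep(rownames(m), times = ncol(m)),
    subtype_b = rep(colnames(m), each = nrow(m)),
    distance = as.vector(m)
  )
}
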