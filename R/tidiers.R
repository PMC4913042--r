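#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a call set into its call table
#'
#' @param x `st_callset` from [sv_call_targeted()] or [sv_call_wgs()].
#' @param all return the full ranked junction table instead of the collapsed
#'   passed calls (default `FALSE`).
#' @param ... unused.
#' @return tibble of calls.
#' @method tidy st_callset
#' @export
tidy.st_callset <- function(x, all = FALSE, ...) {
  out <- if (all) x$all_calls else x$calls
  drop <- intersect(c("seq"), names(out))
  out[, setdiff(names(out), drop)]
}

#' One-row summary of a call set
#'
#' @param x `st_callset`.
#' @param ... unused.
#' @return tibble: `mode`, `threshold`, `n_candidates`, `n_junctions`,
#'   `n_passed`, `n_calls`, `max_log10_S`.
#' @method glance st_callset
#' @export
glance.st_callset <- function(x, ...) {
  tibble(
    mode = x$config$mode,
    threshold = x$config$threshold,
    n_candidates = nrow(x$candidates),
    n_junctions = nrow(x$junctions),
    n_passed = sum(x$all_calls$passed),
    n_calls = nrow(x$calls),
    max_log10_S = if (nrow(x$all_calls)) max(x$all_calls$log10_S) else NA_real_
  )
}

#' Tidy a replica run into its per-sample summary
#' @param x `st_replica` from [run_replica()].
#' @param ... unused.
#' @method tidy st_replica
#' @export
tidy.st_replica <- function(x, ...) x$per_sample

#' One-row summary of a replica run
#' @param x `st_replica`.
#' @param ... unused.
#' @method glance st_replica
#' @export
glance.st_replica <- function(x, ...) {
  ev <- x$evaluation
  tibble(n_samples = ev$n_samples, n_truth = nrow(x$truth),
         threshold = x$threshold, sensitivity = ev$sensitivity,
         exact_sensitivity = ev$exact_sensitivity, ppv = ev$ppv,
         n_type_correct = ev$n_type_correct)
}

#' Support-score plot for a call set
#'
#' Jittered `log10(S)` per junction, grouped by SV class, with the decision
#' threshold drawn as a dashed line (the shaded-region view of the support
#' distribution).
#'
#' @param object `st_callset`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot st_callset
#' @export
autoplot.st_callset <- function(object, ...) {
  d <- object$all_calls
  d <- d[is.finite(d$log10_S), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sv_class, y = .data$log10_S,
                                  colour = .data$passed)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 2) +
    ggplot2::geom_hline(yintercept = object$config$threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(log[10](S)),
                  colour = "passed") +
    ggplot2::theme_minimal()
}

#' Per-sample support plot for a replica run
#'
#' @param object `st_replica`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot st_replica
#' @export
autoplot.st_replica <- function(object, ...) {
  d <- object$calls
  d <- d[is.finite(d$log10_S), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$sample_id),
                                  y = .data$log10_S,
                                  colour = .data$passed)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "sample", y = expression(log[10](S)),
                  colour = "passed") +
    ggplot2::theme_minimal()
}
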