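## ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   facet_wrap labs scale_x_log10 scale_y_log10 geom_errorbar theme_minimal
NULL

#' Plot volume probability profiles
#'
#' @param object An [volume_probability()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdp_profiles <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"z",
                              names_to = "group", values_to = "P")
  ggplot(long, aes(x = .data$z, y = .data$P, colour = .data$group)) +
    geom_line() +
    labs(x = "z from midplane (Å)", y = "volume probability",
         colour = NULL) +
    theme_minimal()
}

#' Plot a contrast profile
#'
#' @param object A [contrast_profile()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdp_contrast <- function(object, ...) {
  unit <- if (attr(object, "probe") == "xray") "e/Å³"
          else "10⁻⁶ Å⁻²"
  ggplot(tibble::as_tibble(object), aes(x = .data$z, y = .data$drho)) +
    geom_line() +
    labs(x = "z from midplane (Å)",
         y = paste0("contrast (", unit, ")")) +
    theme_minimal()
}

#' Plot an ensemble fit against its data
#'
#' Overlays the center-of-mass model curve (with per-dataset profiled scale
#' and background) on every contrast, log-log.
#'
#' @param object An `sdp_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdp_fit <- function(object, ...) {
  est <- stats::setNames(object$estimates$estimate, object$estimates$term)
  details <- attr(object$cost, "details")(est)
  model <- model_from_fit(object)
  pieces <- list()
  for (i in seq_along(object$study$datasets)) {
    d <- object$study$datasets[[i]]
    nm <- attr(d, "name")
    win <- attr(d, "q_window")
    keep <- d$q >= win[1] & d$q <= win[2]
    ff <- form_factor_analytic(model, attr(d, "probe"), attr(d, "x_D"),
                               d$q[keep])
    I_model <- intensity(ff, scale = details$scale[i],
                         background = details$background[i])$I
    pieces[[nm]] <- tibble::tibble(
      dataset = nm, q = d$q[keep], I = d$I[keep], I_model = I_model)
  }
  df <- dplyr::bind_rows(pieces)
  ggplot(df, aes(x = .data$q)) +
    geom_point(aes(y = .data$I), size = 0.4, alpha = 0.5) +
    geom_line(aes(y = .data$I_model), colour = "#c0392b") +
    facet_wrap(~dataset, scales = "free_y") +
    scale_x_log10() + scale_y_log10() +
    labs(x = "q (Å⁻¹)", y = "intensity (arb.)") +
    theme_minimal()
}

#' Plot per-parameter ensemble distributions
#'
#' @param fit An `sdp_fit`.
#' @param parameters Which parameters to show (default all).
#' @return A ggplot of run histograms.
#' @export
plot_parameter_histograms <- function(fit, parameters = NULL) {
  runs <- fit$runs[fit$runs$converged, , drop = FALSE]
  pcols <- setdiff(names(runs), c("run", "seed", "cost", "converged"))
  if (!is.null(parameters)) pcols <- intersect(pcols, parameters)
  long <- tidyr::pivot_longer(runs[, pcols, drop = FALSE],
                              dplyr::everything(),
                              names_to = "term", values_to = "value")
  ggplot(long, aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 25) +
    facet_wrap(~term, scales = "free") +
    labs(x = NULL, y = "runs") +
    theme_minimal()
}

#' Plot dimer statistics
#'
#' @param object A [dimer_statistics()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dimer_stats <- function(object, ...) {
  ggplot(object$summary,
         aes(x = .data$class, y = .data$mean_count, fill = .data$kind)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "time-averaged dimer count", fill = NULL) +
    theme_minimal()
}
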