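#' Tidy per-site summary of an HMRF fit
#'
#' @param x An `hmrf_fit`.
#' @param ... Unused.
#' @return A tibble with one row per site: carrier counts, candidacy, solo
#'   evidence `m`, region posterior `r`, elevated probability `p_e`, the ICM
#'   score and the selection indicator.
#' @export
tidy.hmrf_fit <- function(x, ...) {
  tibble(site = seq_along(x$X), site_id = x$site_ids,
         case_carriers = as.integer(x$carriers$a),
         control_carriers = as.integer(x$carriers$b),
         candidate = x$carriers$cand, m = x$m, r = x$r, p_e = x$p_e,
         score = x$score, selected = x$X == 1L)
}

#' One-row model summary of an HMRF fit
#'
#' @param x An `hmrf_fit`.
#' @param ... Unused.
#' @return A one-row tibble of fitted parameters, gate statistic, convergence
#'   information and selection size.
#' @export
glance.hmrf_fit <- function(x, ...) {
  tibble(mu = x$params$mu, theta = x$params$theta,
         rate_bg = x$params$rate_bg, rate_e = x$params$rate_e,
         w1 = x$params$w1, pi = x$params$pi, gate = x$gate,
         gate_pass = x$gate_pass, converged = x$converged,
         iterations = x$iterations,
         loglik = tail(x$loglik_trace, 1),
         n_selected = length(x$selected_sites))
}

#' Plot the per-site selection landscape of a fit
#'
#' Region posterior and ICM score along the site axis, with selected sites
#' highlighted and interval boundaries drawn.
#'
#' @param object An `hmrf_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hmrf_fit <- function(object, ...) {
  td <- tidy(object)
  td_long <- tidyr::pivot_longer(td, c("r", "score"), names_to = "panel",
                                 values_to = "value")
  boundaries <- object$intervals$start[-1]
  ggplot2::ggplot(td_long, ggplot2::aes(x = .data$site, y = .data$value)) +
    ggplot2::geom_vline(xintercept = boundaries + 0.5, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 1) +
    ggplot2::facet_wrap(~ .data$panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey65",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "site", y = NULL, colour = "selected") +
    ggplot2::theme_minimal()
}

#' Plot power and error rates of a simulation study
#'
#' @param object A `rareburden_study` from [run_simulation_study()].
#' @param ... Unused.
#' @return A ggplot object with power, type-I and type-II rates against the
#'   group PAR.
#' @export
autoplot.rareburden_study <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary, c("power", "type_i", "type_ii"),
                              names_to = "metric", values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group_par, y = .data$rate,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "group PAR", y = "rate", colour = NULL) +
    ggplot2::theme_minimal()
}
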