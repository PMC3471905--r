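#' Plot a response ensemble in the order-parameter plane
#'
#' Relaxation trajectories (if recorded) as curves in the
#' (relative d24 change, dihedral change) plane, deformed starting states
#' as open circles and endpoints as filled points colored by cluster --
#' the standard projection of the domain-motion phase portrait.
#'
#' @param object an `en_ensemble`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.en_ensemble <- function(object, ...) {
  res <- object$realizations
  ref <- object$reference
  p <- ggplot2::ggplot(res, ggplot2::aes(x = .data$dd24_rel, y = .data$dphi))
  if (!is.null(object$trajectories)) {
    tr <- dplyr::bind_rows(purrr::imap(object$trajectories, function(t, i) {
      dplyr::mutate(t, id = i, dd24_rel = (.data$d24 - ref$d24) / ref$d24,
                    dphi = wrap_angle(.data$phi - ref$phi))
    }))
    p <- p + ggplot2::geom_path(data = tr,
                                ggplot2::aes(group = .data$id),
                                color = "firebrick", alpha = 0.4,
                                linewidth = 0.3)
  }
  p +
    ggplot2::geom_point(ggplot2::aes(x = .data$deformed_dd24_rel,
                                     y = .data$deformed_dphi),
                        shape = 1, alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(color = factor(.data$cluster)),
                        size = 2, na.rm = TRUE) +
    ggplot2::labs(x = expression(Delta * d[24] / d[24]),
                  y = expression(Delta * phi ~ "(deg)"),
                  color = "endpoint\ncluster") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity scan
#'
#' Maximum dihedral and relative-d24 responses per probed residue, with
#' the sensitivity thresholds drawn as dashed lines and the sensitive
#' residues highlighted.
#'
#' @param object an `en_sensitivity` tibble from [scan_nbp()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.en_sensitivity <- function(object, ...) {
  thr <- attr(object, "thresholds")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$max_dd24_rel,
                                       y = .data$max_dphi)) +
    ggplot2::geom_vline(xintercept = thr[["dd24"]], linetype = 2,
                        color = "grey50") +
    ggplot2::geom_hline(yintercept = thr[["dphi"]], linetype = 2,
                        color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(color = .data$sensitive), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue), vjust = -0.8,
                       size = 3) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(max ~ "|" * Delta * d[24] * "|" / d[24]),
                  y = expression(max ~ "|" * Delta * phi * "|" ~ "(deg)")) +
    ggplot2::theme_minimal()
}

#' Plot a thermal d24 distribution
#'
#' @param object an `en_thermal` object.
#' @param binwidth histogram bin width, Angstrom.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.en_thermal <- function(object, binwidth = NULL, ...) {
  ggplot2::ggplot(object$samples, ggplot2::aes(x = .data$d24)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(.data$density)),
                            binwidth = binwidth, fill = "grey70",
                            color = "grey30") +
    ggplot2::labs(x = expression(d[24] ~ "(" * ring(A) * ")"),
                  y = "probability density") +
    ggplot2::theme_minimal()
}

#' Plot a relaxation-rate spectrum
#'
#' Eigenvalues of the linearized network in ascending order; zero
#' (rigid-body) modes marked.
#'
#' @param object a `normal_mode_set`.
#' @param n_modes how many of the slowest modes to show.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.normal_mode_set <- function(object, n_modes = 30L, ...) {
  d <- utils::head(tidy(object), n_modes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mode, y = .data$eigenvalue,
                                  color = .data$zero)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey20",
                                           `TRUE` = "firebrick"),
                                labels = c(`FALSE` = "internal",
                                           `TRUE` = "rigid body")) +
    ggplot2::labs(x = "mode", y = "relaxation rate", color = NULL) +
    ggplot2::theme_minimal()
}
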