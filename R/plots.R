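# ggplot2 methods for the main result types. Plots are utilitarian: quick
# visual checks of profiles, isotherms and groove geometry.

#' @method autoplot ets_isotherm
#' @export
autoplot.ets_isotherm <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$conc,
                                            y = .data$fraction_bound)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "protein concentration (M)", y = "fraction bound",
                  title = unique(object$label)[1])
  if (!is.null(fit) && inherits(fit, "ets_fit") && fit$converged) {
    grid <- tibble::tibble(conc = 10^seq(log10(min(object$conc)),
                                         log10(max(object$conc)),
                                         length.out = 200))
    grid$fraction_bound <- hill_model(grid$conc, fit$kd, fit$hill, fit$bmax)
    p <- p + ggplot2::geom_line(data = grid)
  }
  p
}

#' @method autoplot ets_fit
#' @export
autoplot.ets_fit <- function(object, ...) {
  autoplot.ets_isotherm(object$data, fit = object, ...)
}

#' @method autoplot ets_bprofile
#' @export
autoplot.ets_bprofile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$resno, y = .data$norm_b)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue number", y = "normalized B-factor (A^2)",
                  title = unique(object$label)[1])
}

#' Overlay several B-factor profiles (e.g. apo vs DNA-bound)
#' @param ... `ets_bprofile` tibbles.
#' @return a ggplot object.
#' @export
plot_bprofiles <- function(...) {
  df <- dplyr::bind_rows(...)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resno, y = .data$norm_b,
                                   colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue number", y = "normalized B-factor (A^2)",
                  colour = NULL)
}

#' @method autoplot ets_grooves
#' @export
autoplot.ets_grooves <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object)[, c("pair_index", "minor", "major")],
                            c("minor", "major"),
                            names_to = "groove", values_to = "width")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_index, y = .data$width,
                                   colour = .data$groove)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "base-pair level", y = "cross-strand P-P width (A)",
                  colour = NULL)
}

#' @method autoplot ets_contact_map
#' @export
autoplot.ets_contact_map <- function(object, ...) {
  df <- object$contacts |>
    dplyr::count(.data$resno1, .data$kind)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resno1, y = .data$n,
                                   fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "protein residue number", y = "contacts", fill = NULL)
}
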