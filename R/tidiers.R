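# broom-style accessors and ggplot2 views of the model/report objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an SSD model
#'
#' @param x an `ssd_model`.
#' @param ... unused.
#' @return tibble with one row per component: `component`, `eigenvalue`
#'   (in-band to out-of-band power ratio), `retained`.
#' @method tidy ssd_model
#' @export
tidy.ssd_model <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigvals),
    eigenvalue = x$eigvals,
    retained = seq_along(x$eigvals) <= x$k
  )
}

#' Tidy a PCO model
#'
#' @param x a `pco_model`.
#' @param ... unused.
#' @return tibble with `component` and `mvl`.
#' @method tidy pco_model
#' @export
tidy.pco_model <- function(x, ...) {
  tibble::tibble(component = seq_along(x$mvls), mvl = x$mvls)
}

#' Tidy an ITPC report
#'
#' @param x an `itpc_report`.
#' @param ... unused.
#' @return tibble with `channel`, `itpc`, `significant`.
#' @method tidy itpc_report
#' @export
tidy.itpc_report <- function(x, ...) {
  tibble::tibble(channel = seq_along(x$itpc), itpc = x$itpc,
                 significant = x$significant)
}

#' One-row summary of a fitted PCD model
#'
#' @param x a `pcd_model`.
#' @param ... unused.
#' @return tibble with the band center/width, retained SSD dimension `k`,
#'   removed component count `m`, and the top MVL.
#' @method glance pcd_model
#' @export
glance.pcd_model <- function(x, ...) {
  tibble::tibble(
    fc = x$band$fc, dfc = x$band$dfc,
    k = x$ssd$k, m = x$selection$m,
    top_mvl = x$pco$mvls[1]
  )
}

#' MVL trace plot for a PCO model
#'
#' The descending mean-vector-length trace whose elbow separates artifactual
#' from neural components.
#'
#' @param object a `pco_model`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pco_model
#' @export
autoplot.pco_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$mvl)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "PCO component", y = "mean vector length") +
    ggplot2::theme_minimal()
}

#' Per-channel ITPC plot
#'
#' @param object an `itpc_report`.
#' @param ... unused.
#' @return a ggplot with the significance threshold marked.
#' @method autoplot itpc_report
#' @export
autoplot.itpc_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$itpc,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "channel", y = "ITPC (audio coupling)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
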