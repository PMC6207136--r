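## broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a theta estimate
#'
#' @param x a `theta_estimate`.
#' @param ... unused.
#' @return One row per audit component that is scalar, plus the estimate.
#' @method tidy theta_estimate
#' @export
tidy.theta_estimate <- function(x, ...) {
  comps <- x$components
  scal <- comps[vapply(comps, function(z) is.numeric(z) && length(z) == 1, TRUE)]
  tibble::tibble(
    term = c("theta", names(scal)),
    estimate = c(x$value, unlist(scal, use.names = FALSE))
  )
}

#' @rdname tidy.theta_estimate
#' @method glance theta_estimate
#' @export
glance.theta_estimate <- function(x, ...) {
  tibble::tibble(estimator = x$estimator, theta = x$value,
                 n = x$n, ploidy = x$ploidy)
}

#' Tidy a neutrality test result
#'
#' @param x a `neutrality_test`.
#' @param ... unused.
#' @return Tibble with the statistic, numerator, denominator and the
#'   component theta estimates.
#' @method tidy neutrality_test
#' @export
tidy.neutrality_test <- function(x, ...) {
  comps <- x$components
  tibble::tibble(
    term = c(x$statistic_name, "numerator", "denominator", "n_eff",
             names(comps)),
    estimate = c(x$statistic, x$numerator, x$denominator, x$n_eff,
                 unlist(comps, use.names = FALSE))
  )
}

#' @rdname tidy.neutrality_test
#' @method glance neutrality_test
#' @export
glance.neutrality_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic_name, value = x$statistic,
                 numerator = x$numerator, denominator = x$denominator,
                 n_eff = x$n_eff, S = x$components$S)
}

#' Plot a site frequency spectrum
#'
#' @param object a `polysfs_sfs` tibble from [empirical_sfs()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot polysfs_sfs
#' @export
autoplot.polysfs_sfs <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$j, .data$count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "derived allele count j",
                  y = "number of sites",
                  title = sprintf("SFS (n = %d, ploidy = %d)",
                                  attr(object, "n"), attr(object, "ploidy")))
}

#' Plot a joint site frequency/dosage spectrum
#'
#' Tiles frequency class j against the heterozygous DD key.
#'
#' @param object a `polysfs_sfds` tibble from [empirical_sfds()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot polysfs_sfds
#' @export
autoplot.polysfs_sfds <- function(object, ...) {
  p <- attr(object, "ploidy")
  key <- apply(as.matrix(object[, het_colnames(p), drop = FALSE]), 1L,
               paste, collapse = ",")
  df <- tibble::tibble(j = object$j, dd = key, mass = object$mass)
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$dd,
                                   fill = .data$mass)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "derived allele count j",
                  y = "heterozygous DD (I1,...)",
                  fill = if (attr(object, "normalized")) "fraction" else "sites")
}

#' Plot a dosage-distribution perturbation
#'
#' @param object an `hw_perturbation`.
#' @param ... unused.
#' @return A ggplot of the signed deviations per dosage class.
#' @method autoplot hw_perturbation
#' @export
autoplot.hw_perturbation <- function(object, ...) {
  f <- attr(object, "frequency")
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$dosage), .data$delta)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$delta > 0),
                      show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "#b2182b")) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "allelic dosage k", y = expression(Delta * I[k]),
                  title = sprintf("HW violation: %s%s",
                                  attr(object, "scenario"),
                                  if (is.na(f)) "" else paste0(" at f = ", f)))
}
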