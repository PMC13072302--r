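# broom-style methods and plotting for fitted objects

#' Tidy a neutrality fit
#'
#' @param x A [neutrality_fit()] object.
#' @param ... Unused.
#' @return A tibble with one row per regression term (estimate, standard
#'   error, statistic, p-value, 95% confidence bounds).
#' @exportS3Method generics::tidy
tidy.neutrality_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  ci <- confint(x$fit, level = 0.95)
  tibble(
    term = c("intercept", "gc3"),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4]),
    conf.low = unname(ci[, 1]),
    conf.high = unname(ci[, 2])
  )
}

#' One-row summary of a neutrality fit
#'
#' @param x A [neutrality_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble `(n, r, p_r, intercept, slope, slope_low,
#'   slope_high, r.squared, verdict)`.
#' @exportS3Method generics::glance
glance.neutrality_fit <- function(x, ...) {
  tibble(
    n = x$n, r = x$r, p_r = x$p_r,
    intercept = x$a, slope = x$b,
    slope_low = x$b_ci[1], slope_high = x$b_ci[2],
    r.squared = x$r2, verdict = x$verdict
  )
}

#' Augment neutrality points with fitted values
#'
#' @param x A [neutrality_fit()] object.
#' @param ... Unused.
#' @return The point tibble with `.fitted` and `.resid` columns.
#' @exportS3Method generics::augment
augment.neutrality_fit <- function(x, ...) {
  x$points %>%
    mutate(
      .fitted = unname(stats::fitted(x$fit)),
      .resid = unname(stats::residuals(x$fit))
    )
}

#' Neutrality plot
#'
#' GC12 against GC3 with the fitted regression line (solid) and the
#' mutation-equilibrium diagonal GC12 = GC3 (dashed).
#'
#' @param object A [neutrality_fit()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.neutrality_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$gc3, y = .data$gc12)) +
    ggplot2::geom_point(alpha = 0.7, colour = "steelblue") +
    ggplot2::geom_abline(
      intercept = object$a, slope = object$b,
      colour = "firebrick"
    ) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "GC3 (%)", y = "GC12 (%)",
      subtitle = sprintf(
        "GC12 = %.3g + %.3g GC3; r = %.3g, p = %.2g (%s)",
        object$a, object$b, object$r, object$p_r, object$verdict
      )
    ) +
    ggplot2::theme_minimal()
}

#' ENC-GC3s plot
#'
#' Observed ENC against GC3s with Wright's expected curve.
#'
#' @param enc_table A tibble with columns `gc3s` (percent) and `enc_obs`.
#' @param code A [genetic_code()] (caps the y axis).
#' @return A ggplot.
#' @export
plot_enc_gc3 <- function(enc_table, code = genetic_code(2)) {
  curve <- tibble(
    gc3s = seq(1, 99, by = 0.5),
    enc = pmin(enc_expected(seq(1, 99, by = 0.5) / 100), code$max_enc)
  )
  ggplot2::ggplot(enc_table, ggplot2::aes(x = .data$gc3s, y = .data$enc_obs)) +
    ggplot2::geom_line(
      data = curve, ggplot2::aes(y = .data$enc),
      colour = "grey30"
    ) +
    ggplot2::geom_point(colour = "firebrick", alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 35, linetype = "dashed") +
    ggplot2::labs(x = "GC3s (%)", y = "ENC") +
    ggplot2::theme_minimal()
}

#' PR2 bias plot
#'
#' Third-position A/(A+T) against G/(G+C) with the parity centre (0.5, 0.5).
#'
#' @param pr2_table A tibble from [pr2()].
#' @return A ggplot.
#' @export
plot_pr2 <- function(pr2_table) {
  ggplot2::ggplot(pr2_table, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(colour = "firebrick", alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "G3 / (G3 + C3)", y = "A3 / (A3 + T3)") +
    ggplot2::theme_minimal()
}

#' RSCU heatmap
#'
#' Tile heatmap of an RSCU matrix with rows in dendrogram leaf order.
#'
#' @param mat A species-by-codon RSCU matrix.
#' @param tree Optional `upgma` tree used for row ordering.
#' @return A ggplot.
#' @export
plot_rscu_heatmap <- function(mat, tree = NULL) {
  tb <- if (is.null(tree)) {
    as_tibble(mat, rownames = "species")
  } else {
    heatmap_table(mat, tree)
  }
  long <- tidyr::pivot_longer(tb, -"species", names_to = "codon", values_to = "rscu")
  long$species <- factor(long$species, levels = rev(tb$species))
  long$codon <- factor(long$codon, levels = setdiff(names(tb), "species"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$codon, y = .data$species, fill = .data$rscu)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "navy", mid = "white", high = "firebrick") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "RSCU")
}
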