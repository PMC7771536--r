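# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a delay-model fit
#'
#' Observed (s, g) pairs with the fitted model curve; the dashed vertical
#' line marks the fitted breakpoint between the recombination-bound and
#' linear regimes.
#'
#' @param object A `delay_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.delay_fit <- function(object, ...) {
  df <- object$data
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$g))
  if ("class" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$class),
                                 alpha = 0.6)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6, colour = "steelblue")
  }
  if (!isTRUE(object$non_identifiable)) {
    sg <- seq(0, max(df$s), length.out = 200)
    curve <- tibble(s = sg, g = predict(object, sg))
    p <- p + ggplot2::geom_line(data = curve, colour = "red") +
      ggplot2::geom_vline(xintercept = object$breakpoint_s,
                          linetype = "dashed", colour = "grey40")
  }
  p + ggplot2::labs(
    x = "core-gene sequence divergence, s (subst/site)",
    y = "gene-content divergence, g (events/gene)",
    title = sprintf("recombination-delay model: r = %.3f, delta = %.2f",
                    object$r, object$delta))
}

#' Linear recruitment plot
#'
#' Recruited reads by genome position and percent identity, with the
#' species threshold marked.
#'
#' @param object A `recruitment_profile`.
#' @param species_threshold Identity line to draw (percent).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recruitment_profile <- function(object, species_threshold = 95, ...) {
  h <- object$hits
  ggplot2::ggplot(h, ggplot2::aes(x = .data$position,
                                  y = .data$identity_pct)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = species_threshold, linetype = "dashed") +
    ggplot2::labs(x = "genome position (bp)", y = "read identity (%)",
                  title = sprintf("%s vs %s", object$genome_id,
                                  object$sample_id))
}

#' Plot a read-identity histogram
#'
#' @param hist Tibble from [identity_histogram()].
#' @return A ggplot (relative percent per 1%% identity bin, species
#'   threshold dashed).
#' @export
plot_identity_histogram <- function(hist) {
  thr <- attr(hist, "species_threshold")
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$bin_lo + 0.5,
                                     y = .data$rel_pct)) +
    ggplot2::geom_col(width = 0.9, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "read identity (%)", y = "aligned reads (%)")
}

#' Plot a cumulative GC-skew profile
#'
#' @param skew Result of [gc_skew_extrema()].
#' @return A ggplot with origin/terminus marked.
#' @export
plot_gc_skew <- function(skew) {
  ggplot2::ggplot(skew$profile, ggplot2::aes(x = .data$window_start,
                                             y = .data$cum_skew)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = skew$origin_pos, colour = "darkgreen",
                        linetype = "dotted") +
    ggplot2::geom_vline(xintercept = skew$terminus_pos, colour = "firebrick",
                        linetype = "dotted") +
    ggplot2::labs(x = "genome position (bp)", y = "cumulative GC skew")
}
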