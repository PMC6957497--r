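#' Tidy an ancestry matrix into long format
#'
#' @param x An [ancestry_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `marker`, `id`, `dosage` and, when
#'   present, `quality`.
#' @export
tidy.ancestry_matrix <- function(x, ...) {
  out <- tibble::as_tibble(x$dosage, rownames = "marker")
  out <- tidyr::pivot_longer(out, -"marker", names_to = "id",
                             values_to = "dosage")
  if (!is.null(x$quality)) {
    q <- tidyr::pivot_longer(
      tibble::as_tibble(x$quality, rownames = "marker"),
      -"marker", names_to = "id", values_to = "quality"
    )
    out$quality <- q$quality
  }
  out
}

#' Per-locus change records of a correction
#'
#' @param x An `ancestry_correction` from [correct_all()].
#' @param ... Unused.
#' @return The `changes` tibble: one row per corrected locus (or block
#'   locus) with the number of calls changed, winner and runner-up log
#'   probabilities, escalation/failure flags, and the triggering reasons.
#' @export
tidy.ancestry_correction <- function(x, ...) {
  x$changes
}

#' One-row summary of a correction
#'
#' @param x An `ancestry_correction` from [correct_all()].
#' @param ... Unused.
#' @return A one-row tibble: loci and individuals processed, `epsilon`
#'   used, flagged/corrected locus counts, calls changed, Mendelian error
#'   loci before and after, and unresolved loci.
#' @export
glance.ancestry_correction <- function(x, ...) {
  x$summary
}

#' Heatmap of an ancestry dosage matrix
#'
#' Markers along the x axis, individuals along y, fill = dosage. With
#' thousands of markers the tiles degrade gracefully into a banded track
#' plot resembling standard local-ancestry karyograms.
#'
#' @param object An [ancestry_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ancestry_matrix <- function(object, ...) {
  long <- tidy(object)
  long$marker <- factor(long$marker, rownames(object$dosage))
  ggplot2::ggplot(long, ggplot2::aes(
    x = as.integer(.data$marker), y = .data$id, fill = .data$dosage
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "#f7f7e8", high = "#1b6ca8",
                                 limits = c(0, 2)) +
    ggplot2::labs(x = "marker index", y = NULL, fill = "dosage") +
    ggplot2::theme_minimal()
}

#' Before/after view of a correction
#'
#' @param object An `ancestry_correction` from [correct_all()].
#' @param ... Unused.
#' @return A ggplot object: original and corrected dosage tracks, with
#'   flagged loci marked along the top strip.
#' @export
autoplot.ancestry_correction <- function(object, ...) {
  a <- tidy(object$original)
  a$step <- "original"
  b <- tidy(object$corrected)
  b$step <- "corrected"
  long <- dplyr::bind_rows(a, b)
  long$step <- factor(long$step, c("original", "corrected"))
  long$marker <- factor(long$marker, rownames(object$original$dosage))
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = as.integer(.data$marker), y = .data$id, fill = .data$dosage
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "#f7f7e8", high = "#1b6ca8",
                                 limits = c(0, 2)) +
    ggplot2::facet_wrap(~step, ncol = 1) +
    ggplot2::labs(x = "marker index", y = NULL, fill = "dosage") +
    ggplot2::theme_minimal()
  if (nrow(object$flags)) {
    marks <- dplyr::distinct(
      tibble::as_tibble(object$flags)[, c("locus", "reason")]
    )
    p <- p + ggplot2::geom_rug(
      data = marks,
      ggplot2::aes(x = .data$locus, colour = .data$reason),
      inherit.aes = FALSE, sides = "t"
    )
  }
  p
}
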