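# Spray-coverage evaluation statistics. Coverages are fractions in [0, 1]
# internally; percentages appear only at I/O.

#' Film coverage of an assessed area
#'
#' \deqn{\eta = A_l / A_t}: the liquid-film area divided by the total
#' assessed area.
#'
#' @param Al Film-covered area (m^2 or any consistent unit).
#' @param At Total assessed area (same unit); must be positive.
#' @return Coverage fraction in `[0, 1]`.
#' @examples
#' film_coverage(0.2, 0.5)
#' @export
film_coverage <- function(Al, At) {
  check_positive(At, "At")
  check_nonneg(Al, "Al")
  if (any(Al > At)) stop_domain("film area `Al` cannot exceed total area `At`")
  Al / At
}

#' Pixel coverage of a rectangle on a binary stain image
#'
#' \deqn{\eta = y_{num} / t_{num}}: stained pixels over total pixels within
#' the rectangle.
#'
#' @param img A [stain_image()].
#' @param area A rectangle: named vector or one-row data frame with `xmin`,
#'   `xmax`, `ymin`, `ymax` in metres (same frame as the image layout).
#' @return Coverage fraction in `[0, 1]`.
#' @export
pixel_coverage <- function(img, area) {
  w <- .area_window(img, area)
  if (length(w$cols) == 0 || length(w$rows) == 0) {
    stop_domain("empty assessment area: no pixels inside the rectangle")
  }
  mean(img$pixels[w$rows, w$cols])
}

#' Inter-area coverage variance
#'
#' Population variance of the three area coverages,
#' \deqn{\sigma = \tfrac13[(\eta_t-\bar\eta)^2 + (\eta_{cl}-\bar\eta)^2 +
#' (\eta_{cr}-\bar\eta)^2].} A large value means the sheltered test area
#' received much less spray than the open controls, i.e. the leaves
#' retained the herbicide.
#'
#' @param eta_t Coverage of the sheltered test area (fraction).
#' @param eta_cl,eta_cr Coverages of the left and right control areas.
#' @return Variance (dimensionless; fractions squared).
#' @examples
#' coverage_variance(0.16, 0.72, 0.68)
#' @export
coverage_variance <- function(eta_t, eta_cl, eta_cr) {
  e <- c(eta_t, eta_cl, eta_cr)
  if (any(!is.finite(e)) || any(e < 0) || any(e > 1)) {
    stop_domain("coverages must be fractions in [0, 1]")
  }
  mean((e - mean(e))^2)
}

#' Normalized mean absolute error
#'
#' \deqn{NMAE = \frac1n \sum_i \frac{|y_{t,i} - y_{sim,i}|}{y_{sim,i}},}
#' the mean absolute deviation of test values from model predictions,
#' normalized by the prediction at each point (note the asymmetry: the
#' denominator is the simulated value). A model is conventionally taken to
#' predict the test data when NMAE < 30%.
#'
#' @param test Observed values.
#' @param sim Model predictions (same length, all nonzero).
#' @return NMAE (dimensionless fraction).
#' @examples
#' nmae(c(1, 3), c(2, 2))  # 0.5
#' @export
nmae <- function(test, sim) {
  if (length(test) != length(sim) || length(test) < 1) {
    stop_domain("`test` and `sim` must have equal length >= 1")
  }
  if (any(sim == 0)) stop_domain("`sim` values must be nonzero")
  mean(abs(test - sim) / abs(sim))
}

#' Predictive-adequacy flag for an NMAE value
#'
#' @param x NMAE fraction.
#' @param threshold Adequacy threshold (default 0.30).
#' @return `TRUE` when the model is adequate (`x < threshold`).
#' @export
nmae_adequate <- function(x, threshold = 0.30) {
  check_nonneg(x, "x")
  x < threshold
}

#' Coverage report over the three assessed areas
#'
#' Collects the test and control coverages, their mean, the inter-area
#' variance, and optionally the NMAE against reference coverages.
#'
#' @param eta_t,eta_cl,eta_cr Area coverages (fractions).
#' @param reference Optional length-3 reference coverages (e.g. simulated
#'   values when reporting a field test) for the NMAE.
#' @return A one-row tibble of class `coverage_report` with `eta_t`,
#'   `eta_cl`, `eta_cr`, `eta_mean`, `sigma`, and (when a reference is
#'   given) `nmae` and `adequate`.
#' @examples
#' coverage_report(0.16, 0.72, 0.68)
#' @export
coverage_report <- function(eta_t, eta_cl, eta_cr, reference = NULL) {
  out <- tibble(
    eta_t = eta_t, eta_cl = eta_cl, eta_cr = eta_cr,
    eta_mean = mean(c(eta_t, eta_cl, eta_cr)),
    sigma = coverage_variance(eta_t, eta_cl, eta_cr)
  )
  if (!is.null(reference)) {
    out$nmae <- nmae(c(eta_t, eta_cl, eta_cr), reference)
    out$adequate <- nmae_adequate(out$nmae)
  }
  structure(out, class = c("coverage_report", class(out)))
}

#' Measure a coverage report directly from a stain image
#'
#' Applies [pixel_coverage()] to the three rectangles of the image's area
#' layout.
#'
#' @param img A [stain_image()] whose layout has areas `test`,
#'   `control_left`, `control_right`.
#' @param reference Optional reference coverages for the NMAE.
#' @return A [coverage_report()].
#' @export
measure_coverage <- function(img, reference = NULL) {
  lay <- img$layout
  get <- function(a) pixel_coverage(img, lay[lay$area == a, ])
  coverage_report(get("test"), get("control_left"), get("control_right"),
                  reference = reference)
}
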