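# Overlay scaling of a model profile against a transfection-efficiency
# profile, and the synthetic efficiency generator used as a stand-in
# fixture for measured data.

#' Least-squares overlay scale between a model profile and efficiency data
#'
#' Formalizes the "vertical axis adjusted so the curves overlap" comparison
#' of a computed radial profile with a normalized transfection-efficiency
#' profile: within the window, the model series is interpolated linearly
#' onto the efficiency radii and the single scale factor minimizing
#' \eqn{\sum (s\,y(r) - \eta(r))^2} is returned in closed form,
#' \eqn{s = \sum y\eta / \sum y^2}, together with the root-mean-square
#' residual of the scaled fit.
#'
#' @param model A data frame with the model series: radii in `r_mm` and the
#'   profile value in the column named by `value_col`.
#' @param efficiency A data frame with columns `r_mm` and `eta` (see
#'   [read_efficiency()] / [synth_efficiency()]).
#' @param window Numeric `c(r_min, r_max)` in mm. The published comparison
#'   windows are `c(0, 1.6)` for the cell profile, `c(0.2, 0.5)` for the
#'   circuit-model buffer profile and `c(0.4, 1.6)` for the uniform-medium
#'   buffer profile.
#' @param value_col Name of the model value column (default: the first
#'   column other than `r_mm`).
#' @return A one-row tibble of class `overlay_result`: `scale`, `r_min`,
#'   `r_max`, `n_points`, `residual` (RMS misfit in efficiency units).
#' @examples
#' eff <- synth_efficiency(noise_sd = 0)
#' model <- data.frame(r_mm = eff$r_mm, y = 2 * eff$eta)
#' overlay_scale(model, eff, window = c(0, 3.2))$scale  # 0.5
#' @export
overlay_scale <- function(model, efficiency, window, value_col = NULL) {
  stopifnot(is.numeric(window), length(window) == 2, window[1] < window[2])
  if (is.null(value_col))
    value_col <- setdiff(names(model), "r_mm")[1]
  if (!all(c("r_mm", value_col) %in% names(model)))
    stop("model series needs columns r_mm and ", value_col, call. = FALSE)
  if (!all(c("r_mm", "eta") %in% names(efficiency)))
    stop("efficiency profile needs columns r_mm and eta", call. = FALSE)

  # efficiency points inside the window and inside the model's own radial
  # range (the model cannot be interpolated outside it)
  sel <- efficiency$r_mm >= window[1] & efficiency$r_mm <= window[2] &
    efficiency$r_mm >= min(model$r_mm) & efficiency$r_mm <= max(model$r_mm)
  if (!any(sel))
    stop("empty window overlap: no efficiency points in [",
         window[1], ", ", window[2], "] mm within the model series",
         call. = FALSE)
  r_eff <- efficiency$r_mm[sel]
  eta <- efficiency$eta[sel]
  y <- stats::approx(model$r_mm, model[[value_col]], xout = r_eff,
                     ties = "ordered")$y
  if (all(y == 0))
    stop("model values are all zero in the overlay window", call. = FALSE)

  s <- sum(y * eta) / sum(y^2)
  out <- tibble::tibble(
    scale = s, r_min = window[1], r_max = window[2],
    n_points = length(y),
    residual = sqrt(mean((s * y - eta)^2))
  )
  class(out) <- c("overlay_result", class(out))
  out
}

#' Synthetic transfection-efficiency profile
#'
#' Generates a radial efficiency profile with the shape observed in the
#' microdischarge-plasma experiments: an approximately flat plateau out to
#' a drop radius (1.6 mm by default), a sharp fall to near zero beyond it,
#' plus additive Gaussian noise truncated at zero. It stands in for
#' measured profiles (available only as supplementary spreadsheets) and is
#' labelled synthetic; measured data can be supplied through
#' [read_efficiency()].
#'
#' The fall is a logistic edge of full width `edge_width`: the noise-free
#' profile is within 1 % of the plateau for `r < drop_radius - edge_width`
#' and below 1 % of it for `r > drop_radius + edge_width`.
#'
#' @param r_max Largest radius, mm.
#' @param drop_radius Radius where the efficiency collapses, mm.
#' @param noise_sd Standard deviation of the additive noise (efficiency
#'   units; 0 for a noise-free profile).
#' @param seed Optional integer; fixes the noise realization.
#' @param dr Radial spacing of the points, mm.
#' @param plateau Plateau efficiency value.
#' @param edge_width Full width of the fall-off edge, mm.
#' @return A tibble of class `efficiency_profile` with strictly increasing
#'   `r_mm` and non-negative `eta`.
#' @examples
#' synth_efficiency(noise_sd = 0.05, seed = 1)
#' @export
synth_efficiency <- function(r_max = 3.2, drop_radius = 1.6, noise_sd = 0,
                             seed = NULL, dr = 0.1, plateau = 1,
                             edge_width = 0.3) {
  stopifnot(drop_radius < r_max, noise_sd >= 0, edge_width > 0)
  r <- seq(dr / 2, r_max, by = dr)
  eta <- plateau / (1 + exp(8 * (r - drop_radius) / edge_width))
  if (noise_sd > 0) {
    draw <- function() stats::rnorm(length(r), 0, noise_sd)
    noise <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    eta <- eta + noise
  }
  out <- tibble::tibble(r_mm = r, eta = pmax(eta, 0))
  class(out) <- c("efficiency_profile", class(out))
  out
}
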