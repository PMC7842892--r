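# Model parameters: materials, geometry, discretization, drive signal.
# Everything is SI internally (m, S/m, F/m, V, Hz); configuration files may
# use mm/um through explicit unit-suffixed keys (see read_parameters()).

#' Vacuum permittivity used throughout the package
#'
#' Fixed at 8.854e-12 F/m (4 significant figures).
#' @keywords internal
EPS0 <- 8.854e-12

#' Model parameters for the plasma-exposed well
#'
#' Constructs the complete parameter set for the equivalent-circuit model of a
#' plasma-exposed 96-well culture well: material constants, layer heights,
#' radial discretization and the sinusoidal drive signal. The defaults are the
#' operating conditions of the microdischarge-plasma transfection setup the
#' model describes: a TE/PBS buffer of conductivity 0.376 S/m dripped over a
#' confluent fibroblast monolayer (50 um cell layer enclosed by 0.5 um
#' membrane layers) adhering to a polystyrene well bottom (1.5 mm, relative
#' permittivity 2.4), driven by a 15 kV peak-to-peak, 20 kHz sinusoid
#' delivered by the plasma column at the well centre.
#'
#' The well bottom is divided into `n_segments` concentric rings of radial
#' width `delta_r`; each ring is lumped into one vertical stack of circuit
#' elements, linked radially to its neighbours (see [build_network()]).
#'
#' The default buffer height `H_b = 50` mm is the printed model value; the
#' buffer height implied by the dispensed volume (6 uL over the well bottom)
#' is about 0.19 mm and can be computed with [buffer_height_from_volume()]
#' and passed as `H_b`. Both choices give a valid model; see the package
#' vignette for the discussion.
#'
#' @param sigma_b Buffer (TE/PBS) conductivity, S/m.
#' @param eps_m_rel Membrane relative permittivity (multiples of
#'   \eqn{\varepsilon_0}).
#' @param sigma_c Cytoplasm conductivity, S/m.
#' @param eps_w_rel Plate (polystyrene) relative permittivity.
#' @param H_w Plate thickness, m.
#' @param H_c Cell-layer height, m (fibroblast diameter).
#' @param H_m Membrane-layer height, m (1/100 of `H_c` by default).
#' @param H_b Buffer-layer height, m.
#' @param n_segments Number of radial segments (rings).
#' @param delta_r Radial width of one segment, m.
#' @param v_pp Source peak-to-peak voltage, V.
#' @param frequency Drive frequency, Hz.
#'
#' @return An object of class `well_parameters`: a list with components
#'   `materials` (`sigma_b`, `eps_m_rel`, `sigma_c`, `eps_w_rel`, `eps0`),
#'   `geometry` (`H_w`, `H_c`, `H_m`, `H_b`), `disc` (`n_segments`,
#'   `delta_r`) and `drive` (`v_pp`, `frequency`, derived `omega` and
#'   `v_rms = v_pp / (2 sqrt 2)`).
#'
#' @examples
#' p <- well_parameters()
#' p$drive$v_rms              # ~5303 V RMS
#' radial_positions(p) * 1e3  # ring centres in mm: 0.1, 0.3, ..., 3.1
#' @export
well_parameters <- function(sigma_b = 0.376,
                            eps_m_rel = 30,
                            sigma_c = 1,
                            eps_w_rel = 2.4,
                            H_w = 1.5e-3,
                            H_c = 50e-6,
                            H_m = 0.5e-6,
                            H_b = 50e-3,
                            n_segments = 16L,
                            delta_r = 0.2e-3,
                            v_pp = 15e3,
                            frequency = 20e3) {
  params <- structure(
    list(
      materials = list(sigma_b = sigma_b, eps_m_rel = eps_m_rel,
                       sigma_c = sigma_c, eps_w_rel = eps_w_rel,
                       eps0 = EPS0),
      geometry = list(H_w = H_w, H_c = H_c, H_m = H_m, H_b = H_b),
      disc = list(n_segments = as.integer(n_segments), delta_r = delta_r),
      drive = list(v_pp = v_pp, frequency = frequency,
                   omega = 2 * pi * frequency,
                   v_rms = v_pp / (2 * sqrt(2)))
    ),
    class = "well_parameters"
  )
  validate_parameters(params)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of a [well_parameters()] object
#' (positivity of conductivities, heights, drive amplitude and frequency;
#' relative permittivities at least 1; the membrane layers fitting inside the
#' cell layer, `H_c > 2 H_m`; consistency of the derived `omega` and `v_rms`)
#' and reports the first violated invariant by name.
#'
#' @param params A `well_parameters` object.
#' @return `params`, unchanged, if all invariants hold.
#' @export
validate_parameters <- function(params) {
  if (!inherits(params, "well_parameters"))
    stop("`params` must be a well_parameters object", call. = FALSE)
  m <- params$materials; g <- params$geometry
  d <- params$disc; s <- params$drive
  fail <- function(what) stop(what, " violated", call. = FALSE)

  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (nm in c("sigma_b", "eps_m_rel", "sigma_c", "eps_w_rel", "eps0"))
    if (!num1(m[[nm]])) fail(paste(nm, "is a finite number"))
  for (nm in c("H_w", "H_c", "H_m", "H_b"))
    if (!num1(g[[nm]])) fail(paste(nm, "is a finite number"))

  if (!(m$sigma_b > 0)) fail("sigma_b > 0")
  if (!(m$sigma_c > 0)) fail("sigma_c > 0")
  if (!(m$eps_m_rel >= 1)) fail("eps_m_rel >= 1")
  if (!(m$eps_w_rel >= 1)) fail("eps_w_rel >= 1")
  if (m$eps0 != EPS0) fail("eps0 fixed at 8.854e-12 F/m")

  if (!(g$H_w > 0)) fail("H_w > 0")
  if (!(g$H_b > 0)) fail("H_b > 0")
  if (!(g$H_m > 0)) fail("H_m > 0")
  if (!(g$H_c > 2 * g$H_m)) fail("H_c > 2*H_m")

  if (!(is.numeric(d$n_segments) && d$n_segments >= 2))
    fail("n_segments >= 2")
  if (!(num1(d$delta_r) && d$delta_r > 0)) fail("delta_r > 0")

  if (!(num1(s$v_pp) && s$v_pp > 0)) fail("v_pp > 0")
  if (!(num1(s$frequency) && s$frequency > 0)) fail("frequency > 0")
  if (abs(s$omega - 2 * pi * s$frequency) > 1e-9 * s$omega)
    fail("omega = 2*pi*frequency")
  if (abs(s$v_rms * 2 * sqrt(2) - s$v_pp) > 1e-12 * s$v_pp)
    fail("v_rms = v_pp/(2*sqrt(2))")

  params
}

#' Ring-centre radii of the radial discretization
#'
#' The n-th segment is the ring centred at \eqn{r_n = (n - 1/2)\Delta r}.
#'
#' @param x A `well_parameters` object, or a discretization list with
#'   components `n_segments` and `delta_r`.
#' @return Numeric vector of length `n_segments`, in metres, strictly
#'   increasing, starting at `delta_r / 2`.
#' @export
radial_positions <- function(x) {
  d <- if (inherits(x, "well_parameters")) x$disc else x
  stopifnot(is.numeric(d$n_segments), d$n_segments >= 1, d$delta_r > 0)
  (seq_len(d$n_segments) - 0.5) * d$delta_r
}

#' Buffer height implied by the dispensed liquid volume
#'
#' The alternative to the printed 50 mm buffer height: the height of the
#' liquid film obtained by dividing the dispensed buffer volume by the area
#' of the well bottom. With the experimental 6 uL over a 3.2 mm-radius disc
#' this gives about 0.19 mm.
#'
#' @param volume_uL Dispensed buffer volume, microlitres.
#' @param well_radius Well bottom radius, m.
#' @return Height in metres.
#' @examples
#' buffer_height_from_volume()  # ~1.87e-4 m
#' @export
buffer_height_from_volume <- function(volume_uL = 6, well_radius = 3.2e-3) {
  stopifnot(volume_uL > 0, well_radius > 0)
  volume_uL * 1e-9 / (pi * well_radius^2)
}

#' @export
print.well_parameters <- function(x, ...) {
  cat("<well_parameters>\n")
  cat(sprintf("  materials: sigma_b = %g S/m, eps_m = %g eps0, sigma_c = %g S/m, eps_w = %g eps0\n",
              x$materials$sigma_b, x$materials$eps_m_rel,
              x$materials$sigma_c, x$materials$eps_w_rel))
  cat(sprintf("  geometry:  H_w = %g mm, H_c = %g um, H_m = %g um, H_b = %g mm\n",
              x$geometry$H_w * 1e3, x$geometry$H_c * 1e6,
              x$geometry$H_m * 1e6, x$geometry$H_b * 1e3))
  cat(sprintf("  disc:      %d segments of delta_r = %g mm\n",
              x$disc$n_segments, x$disc$delta_r * 1e3))
  cat(sprintf("  drive:     %g kVpp at %g kHz (v_rms = %.1f V)\n",
              x$drive$v_pp / 1e3, x$drive$frequency / 1e3, x$drive$v_rms))
  invisible(x)
}

# ---- configuration files ---------------------------------------------------

.len_keys <- function(base) {
  stats::setNames(c(1, 1e-3, 1e-6), paste0(base, c("", "_mm", "_um")))
}

#' Read model parameters from a JSON configuration file
#'
#' The file holds up to four sections, `materials`, `geometry`,
#' `discretization` and `drive`; every field is optional and defaults to the
#' values of [well_parameters()]. Length fields accept an explicit unit
#' suffix: for example `H_b` (metres), `H_b_mm` or `H_b_um`. Unknown sections
#' or keys are rejected so that a typo cannot silently fall back to a
#' default.
#'
#' @param path Path to a JSON file.
#' @return A validated `well_parameters` object.
#' @export
read_parameters <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(cfg)) stop("configuration must be a JSON object", call. = FALSE)
  known_sections <- c("materials", "geometry", "discretization", "drive")
  bad <- setdiff(names(cfg), known_sections)
  if (length(bad))
    stop("unknown configuration section: ", paste(bad, collapse = ", "),
         call. = FALSE)

  args <- list()
  take_plain <- function(section, keys) {
    sec <- cfg[[section]]
    bad <- setdiff(names(sec), keys)
    if (length(bad))
      stop("unknown key in [", section, "]: ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (k in intersect(names(sec), keys)) args[[k]] <<- sec[[k]]
  }
  take_plain("materials", c("sigma_b", "eps_m_rel", "sigma_c", "eps_w_rel"))
  take_plain("drive", c("v_pp", "frequency"))

  take_lengths <- function(section, bases, extra_plain = character()) {
    sec <- cfg[[section]]
    keymap <- unlist(lapply(bases, .len_keys))
    allowed <- c(names(keymap), extra_plain)
    bad <- setdiff(names(sec), allowed)
    if (length(bad))
      stop("unknown key in [", section, "]: ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (base in bases) {
      km <- .len_keys(base)
      hits <- intersect(names(sec), names(km))
      if (length(hits) > 1)
        stop("conflicting unit-suffixed keys for ", base, call. = FALSE)
      if (length(hits) == 1) args[[base]] <<- sec[[hits]] * km[[hits]]
    }
    for (k in intersect(names(sec), extra_plain)) args[[k]] <<- sec[[k]]
  }
  take_lengths("geometry", c("H_w", "H_c", "H_m", "H_b"))
  take_lengths("discretization", "delta_r", extra_plain = "n_segments")

  do.call(well_parameters, args)
}
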