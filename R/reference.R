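# Axisymmetric finite-difference electro-quasistatic solver for the
# uniform-medium comparison model: buffer solution over the polystyrene
# plate, with the microdischarge plasma attached over r < 0.4 mm at the
# buffer top. No cells in this model by construction — it is the prior,
# cell-free description the circuit network replaces.
#
# Conservative finite-volume discretization of div((sigma + j omega eps)
# grad phi) = 0 on a cell-centred r-z grid with harmonic-mean face
# conductivities. The ground plane under the plate is Dirichlet 0; the
# axis, outer wall and undriven top surface carry zero normal current.
# Two drive modes for the plasma contact disc:
#   * "uniform_current" (default): the discharge current is supplied
#     uniformly over the disc area, as a prescribed influx on the top
#     faces. Total current defaults to the plate-dominated admittance of
#     the whole well times v_rms, so magnitudes are comparable to the
#     circuit model and exactly linear in v_pp.
#   * "potential": the disc is an equipotential at v_rms behind a row of
#     conducting plasma cells (sigma = 1 S/m); this produces the classic
#     current concentration at the disc edge.
# The complex sparse system is solved as an equivalent real system of
# twice the size, with iterative refinement.

#' Build the axisymmetric uniform-medium grid
#'
#' Cell-centred grid over \eqn{r \in [0, r_{max}]},
#' \eqn{z \in [0, H_w + H_b]}: plate cells (complex conductivity
#' \eqn{j\omega\varepsilon_w}) below \eqn{z = H_w} and buffer cells
#' (\eqn{\sigma_b}) above. The plasma contact disc covers the top faces
#' with \eqn{r <} `plasma_radius`; see the drive modes above.
#'
#' @param params A [well_parameters()] object (geometry `H_w`, `H_b`,
#'   materials and drive are used).
#' @param nr,nz Number of radial / vertical cells (each at least 8).
#' @param r_max Outer radius of the modelled region, m.
#' @param plasma_radius Radius of the plasma contact disc, m.
#' @param plasma_sigma Plasma conductivity (S/m; `"potential"` mode only).
#' @param drive `"uniform_current"` or `"potential"`.
#' @param total_current Total complex RMS current injected in
#'   `"uniform_current"` mode; default
#'   \eqn{v_\mathrm{rms}\,\omega\varepsilon_w \pi r_{max}^2 / H_w}
#'   (the well's plate-dominated admittance).
#' @param include_plate If `FALSE`, the whole depth is buffer (degenerate
#'   configurations for verification; the default total current then uses
#'   the buffer conductance instead).
#' @return An object of class `axisym_grid`: a transparent list with `dr`,
#'   `dz`, `nr`, `nz`, `r` and `z` cell-centre vectors, the `region`
#'   character matrix (`nr` x `nz`), the complex `kappa` matrix (S/m), the
#'   per-column top-face Dirichlet flags or influx currents, `v_drive` and
#'   `omega`.
#' @export
build_axisym_grid <- function(params, nr = 64, nz = 64,
                              r_max = 3.2e-3,
                              plasma_radius = 0.4e-3,
                              plasma_sigma = 1,
                              drive = c("uniform_current", "potential"),
                              total_current = NULL,
                              include_plate = TRUE) {
  validate_parameters(params)
  drive <- match.arg(drive)
  stopifnot(nr >= 8, nz >= 8)
  g <- params$geometry; m <- params$materials
  height <- g$H_b + if (include_plate) g$H_w else 0
  dr <- r_max / nr
  dz <- height / nz
  if (include_plate && (g$H_w < dz || g$H_b < dz))
    stop("grid too coarse: a layer is thinner than one cell (dz = ",
         signif(dz, 3), " m)", call. = FALSE)

  r <- (seq_len(nr) - 0.5) * dr
  z <- (seq_len(nz) - 0.5) * dz
  omega <- params$drive$omega
  v_rms <- params$drive$v_rms

  region <- matrix("buffer", nr, nz)
  if (include_plate) region[, z < g$H_w] <- "plate"
  disc_cols <- r < plasma_radius
  if (!any(disc_cols))
    stop("plasma disc narrower than one radial cell", call. = FALSE)

  kap <- matrix(complex(real = m$sigma_b, imaginary = 0), nr, nz)
  kap[region == "plate"] <- complex(real = 0,
                                    imaginary = omega * m$eps_w_rel * m$eps0)

  dirichlet_top <- rep(FALSE, nr)
  influx <- rep(0 + 0i, nr)
  if (drive == "potential") {
    region[disc_cols, nz] <- "plasma"
    kap[region == "plasma"] <- complex(real = plasma_sigma, imaginary = 0)
    dirichlet_top <- disc_cols
  } else {
    if (is.null(total_current)) {
      total_current <- if (include_plate) {
        v_rms * omega * m$eps_w_rel * m$eps0 * pi * r_max^2 / g$H_w
      } else {
        v_rms * m$sigma_b * pi * r_max^2 / height
      }
    }
    face_area <- 2 * pi * r[disc_cols] * dr
    influx[disc_cols] <- total_current * face_area / sum(face_area)
  }

  structure(
    list(dr = dr, dz = dz, nr = nr, nz = nz, r = r, z = z,
         r_max = r_max, height = height,
         region = region, kappa = kap,
         drive_mode = drive,
         dirichlet_top = dirichlet_top,
         influx = influx,
         v_drive = v_rms, omega = omega,
         include_plate = include_plate,
         H_w = if (include_plate) g$H_w else 0, H_b = g$H_b),
    class = "axisym_grid"
  )
}

.harm <- function(a, b) 2 * a * b / (a + b)

# Face conductances of the finite-volume stencil: triplets for east/north
# neighbour couplings plus the Dirichlet boundary conductance vectors.
.axisym_conductances <- function(grid) {
  nr <- grid$nr; nz <- grid$nz; dr <- grid$dr; dz <- grid$dz
  kap <- grid$kappa
  id <- function(i, j) (j - 1L) * nr + i

  # east faces between (i, j) and (i+1, j): area 2*pi*(i*dr)*dz
  ie <- rep(seq_len(nr - 1), nz)
  je <- rep(seq_len(nz), each = nr - 1)
  Ge <- 2 * pi * (ie * dr) * dz *
    .harm(kap[cbind(ie, je)], kap[cbind(ie + 1, je)]) / dr

  # north faces between (i, j) and (i, j+1): area 2*pi*r_i*dr
  inn <- rep(seq_len(nr), nz - 1)
  jn <- rep(seq_len(nz - 1), each = nr)
  Gn <- 2 * pi * grid$r[inn] * dr *
    .harm(kap[cbind(inn, jn)], kap[cbind(inn, jn + 1)]) / dz

  # ground plane under row 1 (half-cell distance)
  Gbot <- 2 * pi * grid$r * dr * kap[, 1] / (dz / 2)
  # driven top faces (potential mode only)
  Gtop <- ifelse(grid$dirichlet_top,
                 2 * pi * grid$r * dr * kap[, nz] / (dz / 2), 0 + 0i)

  list(id = id,
       east = list(p = id(ie, je), q = id(ie + 1, je), G = Ge),
       north = list(p = id(inn, jn), q = id(inn, jn + 1), G = Gn),
       Gbot = Gbot, Gtop = Gtop)
}

# Sparse complex solve via the equivalent real system, with iterative
# refinement.
.solve_complex_sparse <- function(ti, tj, tv, b) {
  N <- length(b)
  i2 <- c(ti, ti, ti + N, ti + N)
  j2 <- c(tj, tj + N, tj, tj + N)
  x2 <- c(Re(tv), -Im(tv), Im(tv), Re(tv))
  A <- Matrix::sparseMatrix(i = i2, j = j2, x = x2, dims = c(2 * N, 2 * N))
  rhs <- c(Re(b), Im(b))
  lu <- Matrix::lu(A)
  x <- as.numeric(as.matrix(Matrix::solve(lu, rhs)))
  for (step in 1:2) {
    resid <- rhs - as.numeric(A %*% x)
    x <- x + as.numeric(as.matrix(Matrix::solve(lu, resid)))
  }
  complex(real = x[seq_len(N)], imaginary = x[N + seq_len(N)])
}

#' Solve the uniform-medium potential
#'
#' Direct sparse solve of the discrete conservation equations on an
#' [build_axisym_grid()] grid.
#'
#' @param grid An `axisym_grid`.
#' @return An object of class `axisym_solution`: list with `phi` (complex
#'   `nr` x `nz` matrix of cell-centre potentials, RMS phasors) and the
#'   `grid`.
#' @export
solve_axisym_potential <- function(grid) {
  stopifnot(inherits(grid, "axisym_grid"))
  nr <- grid$nr; nz <- grid$nz
  N <- nr * nz
  con <- .axisym_conductances(grid)
  driven <- any(Mod(con$Gtop) > 0) || any(Mod(grid$influx) > 0)
  if (!driven)
    stop("singular system: no driven cells", call. = FALSE)

  ti <- tj <- integer(0); tv <- complex(0)
  for (f in list(con$east, con$north)) {
    ti <- c(ti, f$p, f$q, f$p, f$q)
    tj <- c(tj, f$p, f$q, f$q, f$p)
    tv <- c(tv, f$G, f$G, -f$G, -f$G)
  }
  bot_idx <- con$id(seq_len(nr), 1L)
  top_idx <- con$id(seq_len(nr), nz)
  ti <- c(ti, bot_idx, top_idx)
  tj <- c(tj, bot_idx, top_idx)
  tv <- c(tv, con$Gbot, con$Gtop)

  b <- rep(0 + 0i, N)
  b[top_idx] <- con$Gtop * grid$v_drive + grid$influx

  phi <- matrix(.solve_complex_sparse(ti, tj, tv, b), nr, nz)
  structure(list(phi = phi, grid = grid), class = "axisym_solution")
}

.axisym_injected <- function(solution, con) {
  grid <- solution$grid
  top_idx <- con$id(seq_len(grid$nr), grid$nz)
  sum(con$Gtop * (grid$v_drive - as.vector(solution$phi)[top_idx])) +
    sum(grid$influx)
}

#' Discrete conservation residual of a solved grid
#'
#' Recomputes the net current leaving every cell through its faces
#' (including the boundary faces) from the solved potential and returns the
#' maximum magnitude relative to the total injected current.
#'
#' @param solution An `axisym_solution`.
#' @return A non-negative number (round-off small for a direct solve).
#' @export
axisym_divergence_residual <- function(solution) {
  grid <- solution$grid; phi <- as.vector(solution$phi)
  nr <- grid$nr; nz <- grid$nz
  con <- .axisym_conductances(grid)
  net <- rep(0 + 0i, nr * nz)
  for (f in list(con$east, con$north)) {
    flow <- f$G * (phi[f$p] - phi[f$q])
    net[f$p] <- net[f$p] + flow
    net[f$q] <- net[f$q] - flow
  }
  bot_idx <- con$id(seq_len(nr), 1L)
  net[bot_idx] <- net[bot_idx] + con$Gbot * (phi[bot_idx] - 0)
  top_idx <- con$id(seq_len(nr), nz)
  net[top_idx] <- net[top_idx] +
    con$Gtop * (phi[top_idx] - grid$v_drive) - grid$influx
  max(Mod(net)) / Mod(.axisym_injected(solution, con))
}

#' Current balance between the plasma disc and the ground plane
#'
#' Total complex current entering the domain through the driven disc versus
#' the total leaving through the ground plane; for a solved grid the two
#' agree to solver precision.
#'
#' @param solution An `axisym_solution`.
#' @return List with `current_in`, `current_out` (complex A) and
#'   `relative_mismatch`.
#' @export
axisym_current_balance <- function(solution) {
  grid <- solution$grid; phi <- solution$phi
  nr <- grid$nr
  con <- .axisym_conductances(grid)
  i_in <- .axisym_injected(solution, con)
  i_out <- sum(con$Gbot * (phi[cbind(seq_len(nr), 1L)] - 0))
  list(current_in = i_in, current_out = i_out,
       relative_mismatch = Mod(i_in - i_out) / Mod(i_in))
}

#' Buffer current-density profile of the uniform-medium model
#'
#' Samples \eqn{|J| = |\kappa \nabla \phi|} along a horizontal line at a
#' fractional depth of the buffer layer and returns it per radial cell —
#' the uniform-medium counterpart of the circuit model's buffer profile.
#'
#' @param solution An `axisym_solution`.
#' @param depth_frac Sampling height above the buffer bottom as a fraction
#'   of the buffer thickness (default 0.5: mid-buffer).
#' @return A tibble with `r_mm` and `J_b_A_per_m2`.
#' @export
buffer_current_profile <- function(solution, depth_frac = 0.5) {
  grid <- solution$grid; phi <- solution$phi
  stopifnot(depth_frac > 0, depth_frac < 1)
  z_target <- grid$H_w + depth_frac * grid$H_b
  j <- which.min(abs(grid$z - z_target))
  nr <- grid$nr; nz <- grid$nz

  # central differences (one-sided at boundaries) at cell centres of row j
  dphidr <- rep(0 + 0i, nr)
  dphidr[2:(nr - 1)] <- (phi[3:nr, j] - phi[1:(nr - 2), j]) / (2 * grid$dr)
  dphidr[1] <- (phi[2, j] - phi[1, j]) / grid$dr
  dphidr[nr] <- (phi[nr, j] - phi[nr - 1, j]) / grid$dr
  jlo <- max(1L, j - 1L); jhi <- min(nz, j + 1L)
  dphidz <- (phi[, jhi] - phi[, jlo]) / ((jhi - jlo) * grid$dz)

  kap <- grid$kappa[, j]
  Jmag <- sqrt(Mod(kap * dphidr)^2 + Mod(kap * dphidz)^2)
  tibble::tibble(r_mm = grid$r * 1e3, J_b_A_per_m2 = Jmag)
}

#' @export
print.axisym_grid <- function(x, ...) {
  cat("<axisym_grid>\n")
  cat(sprintf("  %d x %d cells over r <= %g mm, height %g mm (dr = %g um, dz = %g um)\n",
              x$nr, x$nz, x$r_max * 1e3, x$height * 1e3,
              x$dr * 1e6, x$dz * 1e6))
  cat(sprintf("  drive: %s over %d top cells; %.1f V RMS at %g kHz\n",
              x$drive_mode, sum(x$dirichlet_top) + sum(Mod(x$influx) > 0),
              x$v_drive, x$omega / 2 / pi / 1e3))
  invisible(x)
}
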