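# Structured-grid state container and source terms.
#
# The conserved vector q has 12 + 6N components per cell, ordered
# (F11,F12,F13,F21,F22,F23,F31,F32,F33, v1,v2,v3, S1v..., SNv...) with each
# memory tensor stored as 6 components (11,12,13,22,23,33). Velocity thus
# occupies slots 10-12, so that slot 9+2 addresses v2. The field is stored
# as a (ncomp x ncells) matrix over a grid that includes `ghost` layers per
# side; cell centres sit at integer multiples of the mesh size.

#' Create a structured-grid state field
#'
#' Allocates a 1D/2D/3D block of cells at rest in the undeformed reference
#' configuration (F = identity, v = 0, memory variables zero), surrounded by
#' ghost layers used for boundary extrapolation. 2D problems are represented
#' with `nz = 1`; sweeps along singleton axes are skipped by the solver.
#'
#' @param nx,ny,nz interior cell counts per axis.
#' @param dx,dy,dz mesh sizes (m).
#' @param n_relax number of viscoelastic memory tensors carried per cell.
#' @param ghost ghost layers per side (>= 1; 2 required for MUSCL).
#' @param origin coordinates (m) of the centre of interior cell (1,1,1).
#'   Default centres the domain on the origin so that a cell sits at X = 0
#'   when the axis has an odd cell count.
#' @param bc boundary treatment: "outflow" (constant extrapolation,
#'   non-reflecting) or "periodic".
#' @return an object of class `state_field`.
#' @export
state_field <- function(nx, ny = 1L, nz = 1L, dx, dy = dx, dz = dx,
                        n_relax = 0L, ghost = 2L, origin = NULL,
                        bc = c("outflow", "periodic")) {
  bc <- match.arg(bc)
  stopifnot(nx >= 1, ny >= 1, nz >= 1, dx > 0, dy > 0, dz > 0, ghost >= 1)
  ncomp <- 12L + 6L * n_relax
  dims <- c(nx, ny, nz) + 2L * ghost * (c(nx, ny, nz) > 1L)
  gh <- ghost * (c(nx, ny, nz) > 1L)  # no ghosts along singleton axes
  ntot <- prod(dims)
  q <- matrix(0, ncomp, ntot)
  q[c(1L, 5L, 9L), ] <- 1  # F = identity
  if (is.null(origin))
    origin <- -c(dx, dy, dz) * floor((c(nx, ny, nz) - 1L) / 2)
  f <- list(q = q, ncomp = ncomp, n_relax = n_relax,
            nx = nx, ny = ny, nz = nz, dims = dims, ghost = gh,
            mesh = c(dx, dy, dz), origin = origin, bc = bc,
            speeds = NULL)
  class(f) <- "state_field"
  f
}

#' @export
print.state_field <- function(x, ...) {
  cat(sprintf("state_field: %d x %d x %d cells (+%s ghosts), %d components, bc = %s\n",
              x$nx, x$ny, x$nz, paste(x$ghost, collapse = "/"),
              x$ncomp, x$bc))
  invisible(x)
}

# column index array over the full (ghosted) grid
.col_array <- function(field) array(seq_len(prod(field$dims)), dim = field$dims)

# columns of the interior cells, in (i,j,k) order
.interior_cols <- function(field) {
  g <- field$ghost
  idx <- .col_array(field)
  as.vector(idx[g[1] + seq_len(field$nx),
                g[2] + seq_len(field$ny),
                g[3] + seq_len(field$nz)])
}

#' Cell-centre coordinates
#'
#' @param field a [state_field()].
#' @return list of numeric vectors `x`, `y`, `z` over interior cells.
#' @export
grid_coords <- function(field) {
  list(x = field$origin[1] + (seq_len(field$nx) - 1L) * field$mesh[1],
       y = field$origin[2] + (seq_len(field$ny) - 1L) * field$mesh[2],
       z = field$origin[3] + (seq_len(field$nz) - 1L) * field$mesh[3])
}

# nearest interior cell index triplet for a physical position
.cell_of <- function(field, pos) {
  co <- grid_coords(field)
  c(which.min(abs(co$x - pos[1])),
    which.min(abs(co$y - pos[2])),
    which.min(abs(co$z - pos[3])))
}

#' Fill ghost cells
#'
#' Copies boundary data into the ghost layers: constant extrapolation of the
#' nearest interior cell for outflow (non-reflecting) boundaries, or
#' wrap-around for periodic ones. Idempotent.
#'
#' @param field a [state_field()].
#' @param axis axis to fill (1 = X, 2 = Y, 3 = Z), or NULL for all
#'   non-singleton axes.
#' @return the field with ghosts filled.
#' @export
fill_ghosts <- function(field, axis = NULL) {
  axes <- if (is.null(axis)) which(c(field$nx, field$ny, field$nz) > 1L) else axis
  idx <- .col_array(field)
  for (a in axes) {
    g <- field$ghost[a]
    if (g == 0L) next
    n <- field$dims[a]
    lo <- seq_len(g); hi <- n - g + seq_len(g)
    if (field$bc == "outflow") {
      src_lo <- rep(g + 1L, g); src_hi <- rep(n - g, g)
    } else {
      src_lo <- n - 2L * g + seq_len(g); src_hi <- g + seq_len(g)
    }
    dst <- .axis_slice(idx, a, c(lo, hi))
    src <- .axis_slice(idx, a, c(src_lo, src_hi))
    field$q[, dst] <- field$q[, src, drop = FALSE]
  }
  field
}

# flatten the columns of `idx` selected by positions `pos` along axis `a`
.axis_slice <- function(idx, a, pos) {
  if (a == 1L) as.vector(idx[pos, , , drop = FALSE])
  else if (a == 2L) as.vector(idx[, pos, , drop = FALSE])
  else as.vector(idx[, , pos, drop = FALSE])
}

#' Source signal
#'
#' Smooth sinusoidal pulse of exactly one fundamental period,
#' \eqn{s(t) = A(\sin\Omega t - \tfrac12 \sin 2\Omega t)} for
#' \eqn{0 \le \Omega t \le 2\pi} and zero outside. The signal and its first
#' derivative vanish at both endpoints.
#'
#' @param t time (s), vectorised.
#' @param Omega fundamental angular frequency (rad/s).
#' @param A amplitude multiplier.
#' @return signal values (m^2/s^2).
#' @export
source_signal <- function(t, Omega, A = 1) {
  th <- Omega * t
  ifelse(th >= 0 & th <= 2 * pi, A * (sin(th) - 0.5 * sin(2 * th)), 0)
}

#' Forcing term specification
#'
#' Describes one of the three supported source geometries: a point source at
#' a given position, a vertical ring (cylindrical surface of circular
#' cross-section) of radius R, or a truncated Gaussian sphere of standard
#' deviation `sigma` cut at radius `cutoff * sigma`. All sources inject the
#' signal [source_signal()] into one velocity slot.
#'
#' @param kind "point", "ring" or "gaussian_sphere".
#' @param amplitude dimensionless amplitude multiplying the signal.
#' @param Omega fundamental angular frequency (rad/s).
#' @param slot velocity component receiving the forcing (1, 2 or 3).
#' @param position point-source position (m), length 3.
#' @param R ring radius (m).
#' @param sigma Gaussian standard deviation (m).
#' @param cutoff Gaussian truncation radius in units of sigma.
#' @return an object of class `source_spec`.
#' @export
source_spec <- function(kind = c("point", "ring", "gaussian_sphere"),
                        amplitude = 1, Omega, slot = 2L,
                        position = c(0, 0, 0), R = NULL,
                        sigma = NULL, cutoff = 3.25) {
  kind <- match.arg(kind)
  if (kind == "ring" && (is.null(R) || R < 0)) stop("ring source needs a radius R >= 0")
  if (kind == "gaussian_sphere" && (is.null(sigma) || sigma <= 0))
    stop("gaussian_sphere source needs sigma > 0")
  structure(list(kind = kind, amplitude = amplitude, Omega = Omega,
                 slot = as.integer(slot), position = position, R = R,
                 sigma = sigma, cutoff = cutoff),
            class = "source_spec")
}

#' Ring source cell selection
#'
#' Cells receiving the ring forcing: for each of
#' \eqn{M = \lceil 2\pi R/\min(\Delta x,\Delta y)\rceil} equally spaced
#' angles, the (i, j) cell column whose centre is nearest to the circle
#' point is selected; duplicates are removed. A zero radius degenerates to
#' the single centre column.
#'
#' @param src a ring [source_spec()].
#' @param field a [state_field()].
#' @return integer matrix with columns `i`, `j` (interior indices).
#' @export
ring_cells <- function(src, field) {
  stopifnot(src$kind == "ring")
  co <- grid_coords(field)
  if (src$R == 0) {
    ij <- .cell_of(field, c(0, 0, 0))[1:2]
    return(matrix(ij, 1L, 2L, dimnames = list(NULL, c("i", "j"))))
  }
  M <- ceiling(2 * pi * src$R / min(field$mesh[1:2]))
  th <- 2 * pi * (seq_len(M) - 1L) / M
  px <- src$R * cos(th); py <- src$R * sin(th)
  ii <- vapply(px, function(x) which.min(abs(co$x - x)), integer(1))
  jj <- vapply(py, function(y) which.min(abs(co$y - y)), integer(1))
  if (any(px < min(co$x)) || any(px > max(co$x)) ||
      any(py < min(co$y)) || any(py > max(co$y)))
    stop("ring source lies outside the domain")
  sel <- !duplicated(cbind(ii, jj))
  cbind(i = ii[sel], j = jj[sel])
}

#' Truncated Gaussian source weights
#'
#' Evaluates the normalised 3D Gaussian of standard deviation sigma,
#' truncated at radius `cutoff * sigma` and renormalised by
#' \eqn{\mathrm{erf}(R/\sqrt2) - R\sqrt{2/\pi}\,e^{-R^2/2}} so that its
#' volume integral is one, at every interior cell centre.
#'
#' @param src a gaussian_sphere [source_spec()].
#' @param field a [state_field()].
#' @return numeric vector of weights (1/m^3) over interior cells.
#' @export
gaussian_weights <- function(src, field) {
  stopifnot(src$kind == "gaussian_sphere")
  co <- grid_coords(field)
  r2 <- outer(outer(co$x^2, co$y^2, `+`), co$z^2, `+`)
  s <- src$sigma; R <- src$cutoff
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  norm_c <- erf(R / sqrt(2)) - R * sqrt(2 / pi) * exp(-R^2 / 2)
  w <- exp(-r2 / (2 * s^2)) / ((2 * pi)^1.5 * s^3 * norm_c)
  w[sqrt(r2) / s >= R] <- 0
  as.vector(w)
}

#' Inject a source into the state field
#'
#' Adds the forcing evaluated at the end-of-step time to the configured
#' velocity slot, following the discrete injection rules of the scheme:
#' point sources add \eqn{s(t)\,\Delta t/\Delta x}, ring sources add
#' \eqn{s(t)\,\Delta t/(\Delta x \Delta y)} to every selected cell column,
#' and Gaussian-sphere sources add \eqn{\Delta t\, s(t)\, G(X)} with the
#' normalised truncated Gaussian G.
#'
#' @param field a [state_field()].
#' @param t_next end-of-step time (s) at which the signal is evaluated.
#' @param dt time step (s).
#' @param src a [source_spec()].
#' @param cache optional precomputed geometry (ring cell list or Gaussian
#'   weights) from [ring_cells()]/[gaussian_weights()].
#' @return the updated field.
#' @export
apply_source <- function(field, t_next, dt, src, cache = NULL) {
  s <- source_signal(t_next, src$Omega, src$amplitude)
  if (s == 0) return(field)
  row <- 9L + src$slot
  cols_int <- .interior_cols(field)
  if (src$kind == "point") {
    ijk <- .cell_of(field, src$position)
    co <- grid_coords(field)
    if (max(abs(c(co$x[ijk[1]], co$y[ijk[2]], co$z[ijk[3]]) - src$position)) >
        max(field$mesh))
      stop("point source position lies outside the domain")
    col <- cols_int[ijk[1] + field$nx * (ijk[2] - 1L + field$ny * (ijk[3] - 1L))]
    field$q[row, col] <- field$q[row, col] + s * dt / field$mesh[1]
  } else if (src$kind == "ring") {
    ij <- if (is.null(cache)) ring_cells(src, field) else cache
    for (k in seq_len(field$nz)) {
      cols <- cols_int[ij[, 1L] + field$nx * (ij[, 2L] - 1L + field$ny * (k - 1L))]
      field$q[row, cols] <- field$q[row, cols] +
        s * dt / (field$mesh[1] * field$mesh[2])
    }
  } else {
    w <- if (is.null(cache)) gaussian_weights(src, field) else cache
    field$q[row, cols_int] <- field$q[row, cols_int] + dt * s * w
  }
  field
}
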