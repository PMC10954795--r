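# Terrain derivatives from a DEM matrix: slope/aspect (Horn's method) and the
# 3x3-neighbourhood roughness and position indices.

# shift a matrix by (dr, dc) padding with NA
shift_na <- function(m, dr, dc) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(NA_real_, ny, nx)
  rs <- seq_len(ny) + dr; cs <- seq_len(nx) + dc
  ok_r <- rs >= 1L & rs <= ny; ok_c <- cs >= 1L & cs <= nx
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# shift with edge replication (for Horn gradients at grid edges)
shift_rep <- function(m, dr, dc) {
  ri <- pmin(pmax(seq_len(nrow(m)) + dr, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m)) + dc, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Terrain grids from a DEM
#'
#' Computes, over a 3x3 moving neighbourhood:
#' * `slope`: degrees, from Horn's eight-neighbour gradient (edge cells use
#'   replicated edge values);
#' * `aspect`: downslope azimuth classified into quadrants N = \[315, 45),
#'   E = \[45, 135), S = \[135, 225), W = \[225, 315); flat cells (zero
#'   gradient) are assigned "N" and flagged in `aspect_flat`;
#' * `tri`: terrain ruggedness index, the mean absolute elevation difference
#'   between a cell and its neighbours (edge cells use the neighbours that
#'   exist);
#' * `tpi`: topographic position index, the cell elevation minus the mean of
#'   its neighbours (positive on hilltops, negative in valleys).
#'
#' Matrix row 1 is the northern edge.
#'
#' @param dem elevation matrix (metres), at least 3x3.
#' @param cell_size cell size in metres.
#' @return list of matrices: `slope`, `aspect` (integer codes 1..4 =
#'   N, E, S, W), `aspect_flat` (logical), `tri`, `tpi`.
#' @export
compute_terrain <- function(dem, cell_size = 10) {
  if (nrow(dem) < 3L || ncol(dem) < 3L) stop("DEM must be at least 3x3 cells")

  # Horn gradients; row index grows southward, so north is dr = -1
  zN  <- shift_rep(dem, -1L,  0L); zS  <- shift_rep(dem,  1L,  0L)
  zE  <- shift_rep(dem,  0L,  1L); zW  <- shift_rep(dem,  0L, -1L)
  zNE <- shift_rep(dem, -1L,  1L); zNW <- shift_rep(dem, -1L, -1L)
  zSE <- shift_rep(dem,  1L,  1L); zSW <- shift_rep(dem,  1L, -1L)
  gx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * cell_size)
  gy <- ((zNW + 2 * zN + zNE) - (zSW + 2 * zS + zSE)) / (8 * cell_size)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi

  flat <- gx == 0 & gy == 0
  az <- (atan2(-gx, -gy) * 180 / pi) %% 360  # azimuth of steepest descent
  acode <- matrix(1L, nrow(dem), ncol(dem))  # N
  acode[az >= 45 & az < 135] <- 2L           # E
  acode[az >= 135 & az < 225] <- 3L          # S
  acode[az >= 225 & az < 315] <- 4L          # W
  acode[flat] <- 1L

  # TRI / TPI over available neighbours
  sum_nb <- matrix(0, nrow(dem), ncol(dem))
  sum_abs <- matrix(0, nrow(dem), ncol(dem))
  n_nb <- matrix(0, nrow(dem), ncol(dem))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    z <- shift_na(dem, dr, dc)
    ok <- !is.na(z)
    sum_nb[ok] <- sum_nb[ok] + z[ok]
    sum_abs[ok] <- sum_abs[ok] + abs(dem[ok] - z[ok])
    n_nb[ok] <- n_nb[ok] + 1
  }
  tri <- sum_abs / n_nb
  tpi <- dem - sum_nb / n_nb

  list(slope = slope, aspect = acode, aspect_flat = flat, tri = tri, tpi = tpi)
}
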