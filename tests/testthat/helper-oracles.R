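# Brute-force oracles, independent of the package's vectorized paths.

# TRI/TPI with explicit double loops over available neighbours
brute_tri_tpi <- function(dem) {
  ny <- nrow(dem); nx <- ncol(dem)
  tri <- matrix(NA_real_, ny, nx); tpi <- matrix(NA_real_, ny, nx)
  for (r in seq_len(ny)) for (c in seq_len(nx)) {
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= ny && cc >= 1 && cc <= nx)
        nb <- c(nb, dem[rr, cc])
    }
    tri[r, c] <- mean(abs(dem[r, c] - nb))
    tpi[r, c] <- dem[r, c] - mean(nb)
  }
  list(tri = tri, tpi = tpi)
}

# Horn slope with replicated edges, cell by cell
brute_slope <- function(dem, cs) {
  ny <- nrow(dem); nx <- ncol(dem)
  g <- function(r, c) dem[min(max(r, 1), ny), min(max(c, 1), nx)]
  sl <- matrix(NA_real_, ny, nx)
  for (r in seq_len(ny)) for (c in seq_len(nx)) {
    gx <- ((g(r - 1, c + 1) + 2 * g(r, c + 1) + g(r + 1, c + 1)) -
           (g(r - 1, c - 1) + 2 * g(r, c - 1) + g(r + 1, c - 1))) / (8 * cs)
    gy <- ((g(r - 1, c - 1) + 2 * g(r - 1, c) + g(r - 1, c + 1)) -
           (g(r + 1, c - 1) + 2 * g(r + 1, c) + g(r + 1, c + 1))) / (8 * cs)
    sl[r, c] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  }
  sl
}

# point-to-polygon-boundary distance over explicit segments
brute_boundary_dist <- function(px, py, poly) {
  poly <- rbind(poly, poly[1, ])
  best <- Inf
  for (s in seq_len(nrow(poly) - 1)) {
    ax <- poly[s, 1]; ay <- poly[s, 2]
    bx <- poly[s + 1, 1]; by <- poly[s + 1, 2]
    l2 <- (bx - ax)^2 + (by - ay)^2
    t <- if (l2 == 0) 0 else
      min(1, max(0, ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / l2))
    qx <- ax + t * (bx - ax); qy <- ay + t * (by - ay)
    best <- min(best, sqrt((px - qx)^2 + (py - qy)^2))
  }
  best
}

# rank correlation as Pearson correlation of hand-computed ranks
rank_cor_oracle <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}
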