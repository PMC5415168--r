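# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals; used as oracles for the fast code.

oracle_median3d <- function(a) {
  d <- dim(a)
  out <- array(0L, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    zz <- pmin(pmax(z + (-1:1), 1), d[1])
    yy <- pmin(pmax(y + (-1:1), 1), d[2])
    xx <- pmin(pmax(x + (-1:1), 1), d[3])
    out[z, y, x] <- as.integer(sum(a[zz, yy, xx]) >= 14)
  }
  out
}

oracle_erode_cross <- function(a) {
  d <- dim(a)
  out <- array(0L, d)
  offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    keep <- TRUE
    for (k in seq_len(nrow(offs))) {
      p <- c(z, y, x) + offs[k, ]
      if (any(p < 1) || any(p > d) || a[p[1], p[2], p[3]] == 0L) {
        keep <- FALSE; break
      }
    }
    out[z, y, x] <- as.integer(keep)
  }
  out
}

oracle_flood26 <- function(a, seed) {
  d <- dim(a)
  stopifnot(a[seed[1], seed[2], seed[3]] == 1L)
  vis <- array(FALSE, d)
  vis[seed[1], seed[2], seed[3]] <- TRUE
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  frontier <- matrix(seed, 1)
  while (nrow(frontier) > 0) {
    nxt <- NULL
    for (i in seq_len(nrow(frontier))) {
      for (j in seq_len(nrow(offs))) {
        p <- frontier[i, ] + offs[j, ]
        if (any(p < 1) || any(p > d)) next
        if (!vis[p[1], p[2], p[3]] && a[p[1], p[2], p[3]] == 1L) {
          vis[p[1], p[2], p[3]] <- TRUE
          nxt <- rbind(nxt, p)
        }
      }
    }
    frontier <- if (is.null(nxt)) matrix(0, 0, 3) else nxt
  }
  array(as.integer(vis), d)
}

# intermeans residual |T - (mean(v <= T) + mean(v > T)) / 2|
intermeans_residual <- function(v, t) {
  m1 <- if (any(v <= t)) mean(v[v <= t]) else min(v)
  m2 <- if (any(v > t)) mean(v[v > t]) else max(v)
  abs(t - (m1 + m2) / 2)
}

rand_binary <- function(dims, p, seed) {
  set.seed(seed)
  array(as.integer(runif(prod(dims)) < p), dims)
}

# solid axial cylinder along z, centered in the cross-section
make_cylinder <- function(nz, ny, nx, z_from, z_to, radius,
                          cy = (ny + 1) / 2, cx = (nx + 1) / 2) {
  a <- array(0L, c(nz, ny, nx))
  for (y in seq_len(ny)) for (x in seq_len(nx))
    if ((y - cy)^2 + (x - cx)^2 <= radius^2) a[z_from:z_to, y, x] <- 1L
  a
}

# quick vertical-root phantom for end-to-end tests (small, fast)
small_root_phantom <- function(dims = c(64L, 48L, 48L), voxel_um = 100,
                               diameter_um = 600, seed = 7, ...) {
  ext <- dims * voxel_um / 1000
  seg <- root_segment(c(1.5, ext[2] / 2, ext[3] / 2),
                      c(ext[1] - 1.5, ext[2] / 2, ext[3] / 2), diameter_um)
  phantom_spec(dims, voxel_um, list(seg), rng_seed = seed, ...)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
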