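# Independent oracles and small fixtures used across the suite.

# Scaled-down phantom for unit tests: 32x32x12 DKI grid, 64x64x60 mm FOV.
small_geometry <- function(include_tumor = TRUE) {
  tumor_center <- c(14, -9, 0)
  comps <- list(
    list(name = "tumor_core", type = "ellipsoid", center = tumor_center,
         semi = c(5, 5, 5)),
    list(name = "tumor_rim", type = "ellipsoid_shell", center = tumor_center,
         semi_outer = c(8, 8, 8), semi_inner = c(5, 5, 5)),
    list(name = "csf", type = "ellipsoid", center = c(0, 0, 2),
         semi = c(7, 5, 6)),
    list(name = "gm", type = "ellipsoid_shell", center = c(0, 0, 0),
         semi_outer = c(28, 28, 26), semi_inner = c(22, 22, 20)),
    list(name = "wm", type = "ellipsoid", center = c(0, 0, 0),
         semi = c(22, 22, 20))
  )
  if (!include_tumor)
    comps <- comps[!vapply(comps, function(c.)
      startsWith(c.$name, "tumor"), logical(1))]
  comps
}

small_spec <- function(seed = 1L, snr = Inf, include_tumor = TRUE,
                       geometry = small_geometry(include_tumor), ...) {
  phantom_spec(grid_shape = c(32, 32, 12), voxel_size = c(2, 2, 5),
               anat_voxel_size = c(1, 1, 3), geometry = geometry,
               snr = snr, seed = seed, ...)
}

# Brute-force 26-connected component labelling by BFS flood fill.
oracle_flood_fill <- function(x) {
  d <- dim(x)
  labels <- array(0L, d)
  current <- 0L
  idx_all <- which(x)
  for (start in idx_all) {
    if (labels[start] > 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        nx <- co[1] + dx; ny <- co[2] + dy; nz <- co[3] + dz
        if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] ||
            nz < 1 || nz > d[3]) next
        lin <- (nz - 1L) * d[1] * d[2] + (ny - 1L) * d[1] + nx
        if (x[lin] && labels[lin] == 0L) {
          labels[lin] <- current
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

# Set-based Dice via explicit voxel coordinate sets.
oracle_dice <- function(a, b) {
  sa <- apply(which(a, arr.ind = TRUE), 1, paste, collapse = ",")
  sb <- apply(which(b, arr.ind = TRUE), 1, paste, collapse = ",")
  if (length(sa) + length(sb) == 0) return(1.0)
  2 * length(intersect(sa, sb)) / (length(sa) + length(sb))
}

# Ray-casting point-in-polygon (closed polygon, n x 2 vertex matrix).
oracle_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- (yi > py) != (yj > py) &
             px < (xj - xi) * (py - yi) / (yj - yi) + xi
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# First moment of the Rician distribution by numerical quadrature.
oracle_rician_mean <- function(nu, sigma) {
  f <- function(x) {
    z <- x * nu / sigma^2
    x * (x / sigma^2) * besselI(z, 0, expon.scaled = TRUE) *
      exp(-(x - nu)^2 / (2 * sigma^2))
  }
  stats::integrate(f, 0, nu + 12 * sigma, rel.tol = 1e-10)$value
}

# Independent per-direction log-quadratic fit via lm(): a genuinely separate
# solver path from the package's closed-form normal equations.
oracle_lm_fit <- function(signals, scheme, k_max = 3, d_max = 5) {
  groups <- kurtosig:::scheme_direction_groups(scheme)
  d_app <- k_app <- numeric(length(groups$directions))
  for (g in seq_along(groups$directions)) {
    vols <- c(groups$b0, groups$directions[[g]])
    bm <- scheme$bvals[vols] * 1e-3
    y <- log(signals[vols])
    co <- stats::coef(stats::lm(y ~ I(-bm) + I(bm^2)))
    d <- min(max(co[[2]], 1e-6), d_max)
    k <- min(max(6 * co[[3]] / d^2, 0), k_max)
    d_app[g] <- d; k_app[g] <- k
  }
  list(md = mean(d_app), mk = mean(k_app), d_app = d_app, k_app = k_app)
}

# Random boolean mask on a small grid.
random_mask <- function(grid, p = 0.3) {
  seg_mask(array(stats::runif(prod(grid$shape)) < p, grid$shape), grid)
}
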