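#' Multi-shell diffusion acquisition scheme
#'
#' Builds the gradient table of a multi-shell diffusion-weighted acquisition:
#' one b = 0 volume followed by every nonzero shell in ascending b order, each
#' shell holding the same set of `n_directions` encoding directions.  The
#' directions are a deterministic spherical Fibonacci lattice, which is
#' near-uniform on the sphere and reproducible without iterative
#' electrostatic optimisation.  The b = 0 volume carries a zero gradient
#' vector and anchors the non-diffusion-weighted signal S0 for every
#' direction's decay series.
#'
#' @param b_values numeric vector of b-values in s/mm^2; must contain 0.
#'   Duplicates are collapsed.
#' @param n_directions number of encoding directions per nonzero shell
#'   (at least 6).
#' @return an object of class `dki_scheme` with per-volume `bvals` (s/mm^2),
#'   `bvecs` (3 x n matrix of unit vectors, zero column at b = 0) and
#'   `dir_index` (0 for the b = 0 volume, otherwise the direction id shared
#'   across shells).
#' @examples
#' sch <- make_scheme(c(0, 500, 1000, 1500, 2000, 2500), 30)
#' length(sch$bvals)  # 1 + 5 * 30 volumes
#' @export
make_scheme <- function(b_values = c(0, 500, 1000, 1500, 2000, 2500),
                        n_directions = 30L) {
  b_values <- sort(unique(as.numeric(b_values)))
  if (any(b_values < 0)) stop("b-values must be nonnegative", call. = FALSE)
  if (!any(b_values == 0))
    stop("scheme must include b = 0 (S0 anchor required)", call. = FALSE)
  n_directions <- as.integer(n_directions)
  if (n_directions < 6L)
    stop("at least 6 encoding directions are required", call. = FALSE)
  shells <- b_values[b_values > 0]
  if (length(shells) < 3L)
    stop("kurtosis fitting needs at least 3 distinct nonzero b-values",
         call. = FALSE)

  dirs <- fibonacci_directions(n_directions)
  n_vol <- 1L + length(shells) * n_directions
  bvals <- c(0, rep(shells, each = n_directions))
  bvecs <- cbind(c(0, 0, 0), dirs[, rep(seq_len(n_directions),
                                        times = length(shells))])
  dir_index <- c(0L, rep(seq_len(n_directions), times = length(shells)))
  new_scheme(bvals, bvecs, dir_index)
}

new_scheme <- function(bvals, bvecs, dir_index) {
  structure(list(bvals = as.numeric(bvals),
                 bvecs = unname(as.matrix(bvecs)),
                 dir_index = as.integer(dir_index),
                 shells = sort(unique(bvals[bvals > 0])),
                 n_directions = max(dir_index)),
            class = "dki_scheme")
}

#' @export
print.dki_scheme <- function(x, ...) {
  cat("<dki_scheme> ", length(x$bvals), " volumes: b = {",
      paste(c(0, x$shells), collapse = ", "), "} s/mm^2, ",
      x$n_directions, " directions/shell\n", sep = "")
  invisible(x)
}

n_volumes <- function(scheme) length(scheme$bvals)

# Spherical Fibonacci lattice: n unit vectors, deterministic and near-uniform.
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(r * cos(phi), r * sin(phi), z)
}

# Volumes grouped by encoding direction: a list with the b = 0 volume indices
# and, per direction, the nonzero-b volume indices.  Used by the fitter to
# assemble each direction's b-series (shared b = 0 sample).
scheme_direction_groups <- function(scheme) {
  b0 <- which(scheme$bvals == 0)
  if (length(b0) == 0L)
    stop("scheme has no b = 0 volume", call. = FALSE)
  groups <- split(which(scheme$dir_index > 0L),
                  scheme$dir_index[scheme$dir_index > 0L])
  for (g in groups) {
    if (length(unique(scheme$bvals[g])) < 3L)
      stop("every direction needs >= 3 distinct nonzero b-values",
           call. = FALSE)
  }
  list(b0 = b0, directions = groups)
}

# Reconstruct per-volume direction ids by matching bvec columns (used when a
# scheme is assembled from .bval/.bvec files rather than by make_scheme()).
infer_dir_index <- function(bvals, bvecs, digits = 6L) {
  dir_index <- integer(length(bvals))
  nz <- bvals > 0
  key <- apply(round(bvecs[, nz, drop = FALSE], digits), 2, paste,
               collapse = ",")
  dir_index[nz] <- as.integer(factor(key, levels = unique(key)))
  dir_index
}
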