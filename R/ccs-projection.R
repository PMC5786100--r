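# Projection-approximation CCS: orientation-averaged projected area of the
# union of hard disks of the per-element collision radii.

# uniform random rotation matrices from normalized quaternions
.random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Monte Carlo area of a union of disks: darts in the bounding box
.projected_area_darts <- function(xy, radii, n_darts) {
  lo <- apply(xy - radii, 2, min)
  hi <- apply(xy + radii, 2, max)
  box <- prod(hi - lo)
  dx <- runif(n_darts, lo[1], hi[1])
  dy <- runif(n_darts, lo[2], hi[2])
  inside <- rep(FALSE, n_darts)
  for (i in seq_len(nrow(xy))) {
    inside <- inside | ((dx - xy[i, 1])^2 + (dy - xy[i, 2])^2 <= radii[i]^2)
  }
  mean(inside) * box
}

# dense-grid rasterization of the same union (test oracle; O(grid^2))
.projected_area_grid <- function(xy, radii, pitch = 0.01) {
  lo <- apply(xy - radii, 2, min)
  hi <- apply(xy + radii, 2, max)
  gx <- seq(lo[1] + pitch / 2, hi[1], by = pitch)
  gy <- seq(lo[2] + pitch / 2, hi[2], by = pitch)
  inside <- matrix(FALSE, length(gx), length(gy))
  for (i in seq_len(nrow(xy))) {
    dx2 <- (gx - xy[i, 1])^2
    dy2 <- (gy - xy[i, 2])^2
    inside <- inside | outer(dx2, dy2, `+`) <= radii[i]^2
  }
  sum(inside) * pitch^2
}

#' Projection-approximation collision cross section
#'
#' Estimates the orientation-averaged projected area of the molecule, each
#' atom drawn as a hard disk of its element's combined atom-gas collision
#' radius.  Areas per orientation come from uniform dart throwing in the
#' bounding box; the standard error is taken over orientations.
#'
#' @param coords N x 3 coordinate matrix (angstrom).
#' @param elements length-N element symbols.
#' @param gas a [gas_model()] supplying per-element hard-sphere radii.
#' @param n_orientations uniformly random orientations to average over.
#' @param n_darts darts per orientation.
#' @param seed integer RNG seed.
#' @param radius_override optional length-N numeric; non-`NA` entries
#'   replace the element radii (angstrom).
#' @return object of class `ccs_result`: `method`, `gas`, `omega`
#'   (angstrom^2), `standard_error`, `n_samples`.
#' @export
ccs_projection <- function(coords, elements, gas, n_orientations = 300,
                           n_darts = 4000, seed = 1,
                           radius_override = NULL) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(elements), ncol(coords) == 3)
  radii <- .gas_atom_params(elements, gas, "rhs", radius_override)
  coords <- sweep(coords, 2, colMeans(coords))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  areas <- vapply(seq_len(n_orientations), function(i) {
    rot <- .random_rotation()
    xy <- (coords %*% t(rot))[, 1:2, drop = FALSE]
    .projected_area_darts(xy, radii, n_darts)
  }, 0)
  structure(
    list(
      method = "projection",
      gas = gas$name,
      omega = mean(areas),
      standard_error = sd(areas) / sqrt(n_orientations),
      n_samples = n_orientations,
      n_failed = 0L
    ),
    class = "ccs_result"
  )
}

#' @export
print.ccs_result <- function(x, ...) {
  cat(sprintf(
    "CCS (%s, %s): %.2f +/- %.2f A^2 (n = %d)\n",
    x$method, x$gas, x$omega, x$standard_error, x$n_samples
  ))
  invisible(x)
}

# save/restore the global RNG state so engine seeds do not disturb callers
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
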