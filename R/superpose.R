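# Rigid-body superposition (Kabsch), RMSD and RMSF.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the coordinate RMSD
#' of `mobile` onto `reference` over the masked atoms, and applies it to all
#' atoms of `mobile`.
#'
#' @param reference N x 3 reference coordinates (angstrom).
#' @param mobile N x 3 coordinates to superpose.
#' @param mask logical or integer atom selection used in the fit (default
#'   all atoms).
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   and `aligned` (N x 3; `aligned = mobile %*% t(rotation) + translation`
#'   row-wise).
#' @export
superpose <- function(reference, mobile, mask = NULL) {
  reference <- as.matrix(reference)
  mobile <- as.matrix(mobile)
  if (!all(dim(reference) == dim(mobile)) || ncol(reference) != 3) {
    stop("reference and mobile must be conformable N x 3 matrices")
  }
  if (is.null(mask)) mask <- seq_len(nrow(reference))
  a <- reference[mask, , drop = FALSE]
  b <- mobile[mask, , drop = FALSE]
  if (nrow(a) < 3) stop("superposition needs >= 3 masked atoms")
  ca <- colMeans(a)
  cb <- colMeans(b)
  a0 <- sweep(a, 2, ca)
  b0 <- sweep(b, 2, cb)
  # collinearity check: the fit is degenerate when masked atoms span < 2 dims
  if (sum(svd(a0)$d > 1e-8) < 2 || sum(svd(b0)$d > 1e-8) < 2) {
    stop("degenerate geometry: masked atoms are collinear or coincident")
  }
  h <- crossprod(b0, a0)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  corr <- diag(c(1, 1, d))
  rot <- s$v %*% corr %*% t(s$u)
  trans <- ca - as.vector(rot %*% cb)
  aligned <- mobile %*% t(rot)
  aligned <- sweep(aligned, 2, trans, "+")
  list(rotation = rot, translation = trans, aligned = aligned)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b conformable N x 3 coordinate matrices (angstrom).
#' @param mask atom selection (default all).
#' @param fit superpose `b` onto `a` (Kabsch) before measuring?
#' @return RMSD in angstrom.
#' @export
rmsd <- function(a, b, mask = NULL, fit = FALSE) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3) {
    stop("coordinate sets are not conformable")
  }
  if (is.null(mask)) mask <- seq_len(nrow(a))
  if (fit) b <- superpose(a, b, mask)$aligned
  d <- a[mask, , drop = FALSE] - b[mask, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

# logical mask of non-hydrogen atoms
heavy_mask <- function(ensemble) ensemble$atoms$element != "H"

#' Per-atom root-mean-square fluctuation
#'
#' Conformers are superposed to the ensemble-mean structure, iterating the
#' mean-structure fit to self-consistency; the RMSF of atom i is the root
#' mean square of its displacement from the converged mean position.
#'
#' @param ensemble a [conformer_ensemble()] with M >= 2 conformers.
#' @param mask fit/report selection; default heavy atoms.
#' @param tol convergence tolerance on the mean structure (angstrom).
#' @param max_iter iteration cap for the mean-fit cycle.
#' @return numeric vector of per-atom RMSF (angstrom) over the masked atoms,
#'   named by atom index (0-based).
#' @export
rmsf <- function(ensemble, mask = NULL, tol = 1e-6, max_iter = 50) {
  m <- n_conformers(ensemble)
  if (m < 2) stop("RMSF needs at least two conformers")
  if (is.null(mask)) mask <- heavy_mask(ensemble)
  mask <- which(if (is.logical(mask)) mask else seq_len(nrow(ensemble$atoms)) %in% mask)
  coords <- ensemble$coords
  ref <- coords[[1]]
  for (it in seq_len(max_iter)) {
    aligned <- lapply(coords, function(x) superpose(ref, x, mask)$aligned)
    newmean <- Reduce(`+`, aligned) / m
    shift <- max(abs(newmean[mask, ] - ref[mask, ]))
    ref <- newmean
    if (shift < tol) break
  }
  aligned <- lapply(coords, function(x) superpose(ref, x, mask)$aligned)
  meanx <- Reduce(`+`, aligned) / m
  dev2 <- Reduce(`+`, lapply(aligned, function(x) rowSums((x - meanx)^2))) / m
  setNames(sqrt(dev2[mask]), mask - 1L)
}
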