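# RMSD-threshold conformational clustering and population-weighted CCS
# distributions.
#
# The partition mirrors the radius-limited k-means used for trajectory
# snapshots: all conformers are superposed to the first one, k-means runs on
# the flattened heavy-atom coordinates, and k grows by splitting until every
# member lies within the RMSD threshold of its cluster centroid.  The
# cluster representative ("center structure") is the medoid — an actual
# conformer — because a physical structure is needed for CCS computation.

#' Cluster an ensemble at an RMSD threshold
#'
#' Deterministic radius-limited k-means.  Splitting rule: the cluster with
#' the largest member-to-centroid RMSD is split by seeding two centroids at
#' its two most distant members; Lloyd iterations then run to convergence;
#' splitting repeats until the radius criterion holds everywhere or the
#' cluster cap binds.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param threshold RMSD radius in angstrom (2.5 for coarse conformer
#'   families; 0.5 for fine CCS distributions).
#' @param mask atom selection used for superposition and distances; default
#'   heavy atoms.
#' @param max_clusters cap on the cluster count (default 2625); a warning is
#'   issued if the cap binds before the radius criterion is met.
#' @param max_iter Lloyd iteration cap per split.
#' @return object of class `cluster_set`: list with `threshold`, `n` (M),
#'   `assignment` (length-M integer cluster ids, 1-based), `clusters` (list
#'   of `members` (0-based conformer indices), `medoid` (0-based), `weight`),
#'   and `aligned` (the superposed masked coordinate matrix used).
#' @export
cluster_ensemble <- function(ensemble, threshold, mask = NULL,
                             max_clusters = 2625, max_iter = 100) {
  m <- n_conformers(ensemble)
  if (m < 1) stop("empty ensemble")
  if (is.null(mask)) mask <- heavy_mask(ensemble)
  idx <- which(if (is.logical(mask)) mask else seq_len(nrow(ensemble$atoms)) %in% mask)
  if (length(idx) == 0) stop("empty atom mask")
  ref <- ensemble$coords[[1]]
  flat <- t(vapply(
    ensemble$coords,
    function(x) {
      if (m > 1 || TRUE) x <- superpose(ref, x, idx)$aligned
      as.vector(t(x[idx, , drop = FALSE]))
    },
    numeric(3 * length(idx))
  ))
  natom <- length(idx)
  # RMSD between flattened rows = euclidean distance / sqrt(natom)
  rms_to <- function(rows, center) {
    sqrt(rowSums(sweep(flat[rows, , drop = FALSE], 2, center)^2) / natom)
  }

  assignment <- rep(1L, m)
  centroids <- matrix(colMeans(flat), nrow = 1)
  repeat {
    # radius check
    radii <- vapply(seq_len(nrow(centroids)), function(k) {
      rows <- which(assignment == k)
      if (length(rows) == 0) {
        return(0)
      }
      max(rms_to(rows, centroids[k, ]))
    }, 0)
    if (all(radii <= threshold)) break
    if (nrow(centroids) >= max_clusters) {
      warning(sprintf(
        "cluster cap (%d) reached with max radius %.3f A > threshold %.3f A",
        max_clusters, max(radii), threshold
      ))
      break
    }
    worst <- which.max(radii)
    rows <- which(assignment == worst)
    # seed the split at the two most distant members of the worst cluster
    sub <- flat[rows, , drop = FALSE]
    d <- as.matrix(stats::dist(sub))
    far <- which(d == max(d), arr.ind = TRUE)[1, ]
    centroids[worst, ] <- sub[far[1], ]
    centroids <- rbind(centroids, sub[far[2], ])
    # Lloyd to convergence over all clusters
    for (it in seq_len(max_iter)) {
      d2 <- outer(rowSums(flat^2), rep(1, nrow(centroids))) -
        2 * flat %*% t(centroids) +
        outer(rep(1, m), rowSums(centroids^2))
      newassign <- max.col(-d2, ties.method = "first")
      if (identical(newassign, assignment)) break
      assignment <- newassign
      for (k in seq_len(nrow(centroids))) {
        rows_k <- which(assignment == k)
        if (length(rows_k) > 0) {
          centroids[k, ] <- colMeans(flat[rows_k, , drop = FALSE])
        }
      }
    }
    # drop empty clusters
    keep <- sort(unique(assignment))
    centroids <- centroids[keep, , drop = FALSE]
    assignment <- match(assignment, keep)
  }

  clusters <- lapply(sort(unique(assignment)), function(k) {
    rows <- which(assignment == k)
    if (length(rows) == 1) {
      med <- rows
    } else {
      d <- as.matrix(stats::dist(flat[rows, , drop = FALSE])) / sqrt(natom)
      med <- rows[which.min(rowMeans(d))]
    }
    list(
      members = rows - 1L,
      medoid = med - 1L,
      weight = length(rows) / m
    )
  })
  ord <- order(vapply(clusters, function(cl) -cl$weight, 0),
    vapply(clusters, function(cl) cl$medoid, 0L)
  )
  structure(
    list(
      threshold = threshold, n = m,
      clusters = clusters[ord],
      assignment = match(assignment, sort(unique(assignment))[ord])
    ),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "Cluster set: %d conformers in %d cluster(s) at threshold %.2f A\n",
    x$n, length(x$clusters), x$threshold
  ))
  w <- vapply(x$clusters, `[[`, 0, "weight")
  cat("weights:", paste(sprintf("%.3f", w), collapse = " "), "\n")
  invisible(x)
}

#' Cluster weights
#' @param clusterset a `cluster_set`.
#' @return numeric vector of population weights (sums to 1).
#' @export
cluster_weights <- function(clusterset) {
  vapply(clusterset$clusters, `[[`, 0, "weight")
}

#' Medoid conformer indices
#' @param clusterset a `cluster_set`.
#' @return integer vector of 0-based medoid conformer indices.
#' @export
cluster_medoids <- function(clusterset) {
  vapply(clusterset$clusters, `[[`, 0L, "medoid")
}

#' Major conformers above a population cutoff
#'
#' @param clusterset a `cluster_set`.
#' @param min_fraction population cutoff (default 0.10: clusters holding
#'   more than 10 percent of the ensemble).
#' @return data frame with `medoid` (0-based conformer index) and `weight`,
#'   sorted by descending weight; zero rows when nothing passes.
#' @export
major_conformers <- function(clusterset, min_fraction = 0.10) {
  w <- cluster_weights(clusterset)
  keep <- which(w > min_fraction)
  keep <- keep[order(-w[keep])]
  data.frame(
    medoid = cluster_medoids(clusterset)[keep],
    weight = w[keep]
  )
}

#' Population-weighted CCS distribution
#'
#' Attaches a per-cluster CCS (computed for each medoid structure) to the
#' cluster populations: each medoid CCS is weighted by the fraction of
#' conformers in its cluster.
#'
#' @param clusterset a `cluster_set`.
#' @param medoid_ccs numeric vector of CCS values (angstrom^2), one per
#'   cluster in `clusterset$clusters` order, or a list of `ccs_result`
#'   objects of the same length.
#' @param bin_width histogram bin width in angstrom^2 (default 5).
#' @return object of class `ccs_distribution`: `support` (data frame omega,
#'   weight), `breaks`, `masses`, `mean` (population-weighted mean CCS).
#' @export
weighted_ccs_distribution <- function(clusterset, medoid_ccs, bin_width = 5) {
  k <- length(clusterset$clusters)
  if (is.list(medoid_ccs)) {
    medoid_ccs <- vapply(medoid_ccs, function(r) r$omega, 0)
  }
  if (length(medoid_ccs) != k || any(!is.finite(medoid_ccs))) {
    stop("need one finite CCS value per cluster (", k, " clusters)")
  }
  w <- cluster_weights(clusterset)
  lo <- floor(min(medoid_ccs) / bin_width) * bin_width - bin_width / 2
  hi <- ceiling(max(medoid_ccs) / bin_width) * bin_width + bin_width / 2
  breaks <- seq(lo, hi, by = bin_width)
  bins <- findInterval(medoid_ccs, breaks, rightmost.closed = TRUE)
  masses <- vapply(seq_len(length(breaks) - 1), function(b) sum(w[bins == b]), 0)
  structure(
    list(
      support = data.frame(omega = medoid_ccs, weight = w),
      breaks = breaks, masses = masses,
      mean = sum(w * medoid_ccs)
    ),
    class = "ccs_distribution"
  )
}

#' @export
print.ccs_distribution <- function(x, ...) {
  cat(sprintf(
    "CCS distribution: %d support point(s), weighted mean %.1f A^2\n",
    nrow(x$support), x$mean
  ))
  invisible(x)
}
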