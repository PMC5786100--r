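# Geometric hydrogen-bond detection, residue-pair occupancy maps and
# inter-arm category summaries.
#
# Criterion (donor-centered): a donor heavy atom X bearing hydrogen H and
# an acceptor heavy atom Y form an H-bond when R_XY < R_max and the angle
# between the X-H bond vector and the X-Y vector is < theta_max.  The
# common alternative (the X-H...Y angle at H) is deliberately not used.

#' Hydrogen-bond criteria
#'
#' @param r_max heavy-atom distance cutoff R_XY in angstrom (default 3.5).
#' @param theta_max donor-centered angle cutoff in degrees (default 30).
#' @param elements donor/acceptor heavy-atom element set (default N, O).
#' @param exclude_intra_residue drop donor/acceptor pairs within one
#'   residue (default TRUE).
#' @return list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(r_max = 3.5, theta_max = 30,
                           elements = c("N", "O"),
                           exclude_intra_residue = TRUE) {
  stopifnot(r_max > 0, theta_max > 0, theta_max < 90)
  structure(
    list(
      r_max = r_max, theta_max = theta_max, elements = elements,
      exclude_intra_residue = exclude_intra_residue
    ),
    class = "hbond_criteria"
  )
}

#' Assign hydrogens to their covalent donor heavy atoms
#'
#' Each hydrogen is attached to the nearest donor-element heavy atom within
#' 1.2 angstrom.
#'
#' @param ensemble a [conformer_ensemble()] containing hydrogens.
#' @param conformer 0-based conformer index.
#' @param criteria a [hbond_criteria()] (supplies the donor element set).
#' @return data frame with 0-based `donor` and `hydrogen` atom indices and
#'   the covalent `distance`.
#' @export
assign_donors_hydrogens <- function(ensemble, conformer = 0,
                                    criteria = hbond_criteria()) {
  x <- ensemble$coords[[conformer + 1L]]
  el <- ensemble$atoms$element
  h_idx <- which(el == "H")
  if (length(h_idx) == 0) stop("structure contains no hydrogens")
  d_idx <- which(el %in% criteria$elements)
  if (length(d_idx) == 0) stop("no donor-element heavy atoms present")
  dd <- matrix(0, length(h_idx), length(d_idx))
  for (k in seq_along(d_idx)) {
    dd[, k] <- sqrt(rowSums(sweep(
      x[h_idx, , drop = FALSE], 2, x[d_idx[k], ]
    )^2))
  }
  nearest <- max.col(-dd, ties.method = "first")
  dist <- dd[cbind(seq_along(h_idx), nearest)]
  orphan <- dist > 1.2
  if (any(orphan)) {
    stop(
      "hydrogen(s) with no donor heavy atom within 1.2 A: atom index ",
      paste(h_idx[orphan] - 1L, collapse = ", ")
    )
  }
  data.frame(
    donor = d_idx[nearest] - 1L,
    hydrogen = h_idx - 1L,
    distance = dist
  )
}

#' Detect hydrogen bonds in one conformer
#'
#' All (donor X, hydrogen H, acceptor Y) triples with R_XY below the
#' distance cutoff and the donor-centered angle below the angle cutoff;
#' both X and Y must be in the donor/acceptor element set, X != Y, and
#' intra-residue pairs are excluded by default.
#'
#' @param ensemble a [conformer_ensemble()] with hydrogens.
#' @param conformer 0-based conformer index.
#' @param criteria a [hbond_criteria()].
#' @return data frame with 0-based atom indices `donor`, `hydrogen`,
#'   `acceptor`, plus `donor_residue`, `acceptor_residue`, `distance`
#'   (angstrom), `angle` (degrees) and `conformer`.
#' @export
detect_hbonds <- function(ensemble, conformer = 0,
                          criteria = hbond_criteria()) {
  x <- ensemble$coords[[conformer + 1L]]
  el <- ensemble$atoms$element
  res <- ensemble$atoms$residue_index
  dh <- assign_donors_hydrogens(ensemble, conformer, criteria)
  acc_idx <- which(el %in% criteria$elements)
  out <- vector("list", nrow(dh))
  for (i in seq_len(nrow(dh))) {
    d1 <- dh$donor[i] + 1L
    h1 <- dh$hydrogen[i] + 1L
    xv <- x[d1, ]
    hv <- x[h1, ] - xv
    acc <- acc_idx[acc_idx != d1]
    dvec <- sweep(x[acc, , drop = FALSE], 2, xv)
    r <- sqrt(rowSums(dvec^2))
    keep <- r < criteria$r_max
    if (criteria$exclude_intra_residue) {
      keep <- keep & res[acc] != res[d1]
    }
    if (!any(keep)) next
    acc <- acc[keep]
    dvec <- dvec[keep, , drop = FALSE]
    r <- r[keep]
    cosang <- (dvec %*% hv) / (r * sqrt(sum(hv^2)))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    sel <- ang < criteria$theta_max
    if (!any(sel)) next
    out[[i]] <- data.frame(
      donor = d1 - 1L, hydrogen = h1 - 1L, acceptor = acc[sel] - 1L,
      donor_residue = res[d1], acceptor_residue = res[acc[sel]],
      distance = r[sel], angle = ang[sel], conformer = conformer
    )
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) {
    return(data.frame(
      donor = integer(0), hydrogen = integer(0), acceptor = integer(0),
      donor_residue = integer(0), acceptor_residue = integer(0),
      distance = numeric(0), angle = numeric(0), conformer = integer(0)
    ))
  }
  do.call(rbind, out)
}

#' Residue-pair hydrogen-bond occupancy map
#'
#' Occupancy of a residue pair (i, j) is the fraction of conformers with at
#' least one H-bond between i and j in either direction.
#'
#' @param ensemble a [conformer_ensemble()] with hydrogens.
#' @param criteria a [hbond_criteria()].
#' @param annotation optional `residue_annotation` (coverage-checked when
#'   given).
#' @return object of class `hbond_map`: symmetric `occupancy` matrix with
#'   residue labels, `mean_count` matrix (mean bonds per conformer per
#'   pair), `n_conformers`, and `bonds` (pooled per-conformer bond table).
#' @export
hbond_occupancy_map <- function(ensemble, criteria = hbond_criteria(),
                                annotation = NULL) {
  if (!is.null(annotation)) .check_annotation_coverage(ensemble, annotation)
  m <- n_conformers(ensemble)
  residues <- sort(unique(ensemble$atoms$residue_index))
  k <- length(residues)
  occ <- matrix(0, k, k, dimnames = list(residues, residues))
  cnt <- matrix(0, k, k, dimnames = list(residues, residues))
  bonds <- vector("list", m)
  for (f in seq_len(m)) {
    hb <- detect_hbonds(ensemble, f - 1L, criteria)
    bonds[[f]] <- hb
    if (nrow(hb) == 0) next
    i <- match(hb$donor_residue, residues)
    j <- match(hb$acceptor_residue, residues)
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    for (b in seq_along(lo)) cnt[lo[b], hi[b]] <- cnt[lo[b], hi[b]] + 1
    seen <- unique(cbind(lo, hi))
    occ[seen] <- occ[seen] + 1
  }
  occ <- occ / m
  cnt <- cnt / m
  occ[lower.tri(occ)] <- t(occ)[lower.tri(occ)]
  cnt[lower.tri(cnt)] <- t(cnt)[lower.tri(cnt)]
  structure(
    list(
      occupancy = occ, mean_count = cnt, n_conformers = m,
      bonds = do.call(rbind, bonds), criteria = criteria
    ),
    class = "hbond_map"
  )
}

#' @export
print.hbond_map <- function(x, ...) {
  cat(sprintf(
    "H-bond map over %d conformer(s); %d residue(s); %d pooled bond(s)\n",
    x$n_conformers, nrow(x$occupancy), nrow(x$bonds)
  ))
  invisible(x)
}

# category of one bond from the unit labels of its two residues
.hbond_category <- function(unit_i, unit_j) {
  u <- c(unit_i, unit_j)
  u[u == "PA-tag"] <- "core-chitobiose" # PA tag counts with the core
  if (any(u == "fucose")) {
    return("other")
  }
  if (u[1] == u[2]) {
    return("intra-arm")
  }
  s <- sort(u)
  if (identical(s, c("alpha1-6-arm", "core-chitobiose"))) {
    return("core-alpha1-6")
  }
  if (identical(s, c("alpha1-3-arm", "core-chitobiose"))) {
    return("core-alpha1-3")
  }
  "alpha1-3-alpha1-6"
}

.hbond_categories <- c(
  "core-alpha1-6", "core-alpha1-3", "alpha1-3-alpha1-6", "intra-arm"
)

#' Categorize hydrogen bonds by structural unit
#'
#' Pools all detected bonds across conformers and assigns each to one
#' inter-arm category from the unit labels of its donor and acceptor
#' residues: core-chitobiose vs alpha1-6 arm, core vs alpha1-3 arm,
#' alpha1-3 vs alpha1-6, or intra-arm (same unit).  The PA tag counts with
#' the core; fucose-involving bonds are reported under "other" and excluded
#' from the four-way percentages.
#'
#' @param map an `hbond_map` from [hbond_occupancy_map()], or a bond table
#'   as returned by [detect_hbonds()] together with `n_conformers`.
#' @param annotation a `residue_annotation` covering every residue.
#' @param n_conformers required when `map` is a raw bond table.
#' @return object of class `hbond_category_summary`: `mean_count`
#'   (average bonds per conformer, categorized bonds), `percent` (named
#'   vector over the four categories, sums to 100), `n_other` (fucose-
#'   involving bonds), `n_bonds`.
#' @export
categorize_hbonds <- function(map, annotation, n_conformers = NULL) {
  if (inherits(map, "hbond_map")) {
    bonds <- map$bonds
    n_conformers <- map$n_conformers
  } else {
    bonds <- map
    if (is.null(n_conformers)) stop("n_conformers required with a bond table")
  }
  all_res <- unique(c(bonds$donor_residue, bonds$acceptor_residue))
  absent <- setdiff(all_res, as.integer(names(annotation)))
  if (length(absent) > 0) {
    stop(
      "annotation does not cover residue(s): ",
      paste(absent, collapse = ", ")
    )
  }
  ann <- function(r) unname(annotation[as.character(r)])
  cats <- vapply(
    seq_len(nrow(bonds)),
    function(b) {
      .hbond_category(
        ann(bonds$donor_residue[b]),
        ann(bonds$acceptor_residue[b])
      )
    },
    ""
  )
  n_other <- sum(cats == "other")
  cats <- cats[cats != "other"]
  counts <- table(factor(cats, levels = .hbond_categories))
  pct <- if (length(cats) > 0) 100 * as.numeric(counts) / length(cats) else
    rep(0, length(.hbond_categories))
  structure(
    list(
      mean_count = length(cats) / n_conformers,
      percent = setNames(pct, .hbond_categories),
      n_other = n_other,
      n_bonds = length(cats),
      n_conformers = n_conformers
    ),
    class = "hbond_category_summary"
  )
}

#' @export
print.hbond_category_summary <- function(x, ...) {
  cat(sprintf(
    "H-bonds: %.2f per conformer (categorized), %d other\n",
    x$mean_count, x$n_other
  ))
  for (k in names(x$percent)) {
    cat(sprintf("  %-20s %5.1f%%\n", k, x$percent[[k]]))
  }
  invisible(x)
}

#' Globular-minus-rod hydrogen-bond differences
#'
#' Per-field difference (globular minus rod-like) between two category
#' summaries computed with the same criteria: the average per-conformer
#' bond count and each category percentage.
#'
#' @param summary_globular,summary_rod `hbond_category_summary` objects.
#' @return list with `mean_count_diff` and `percent_diff` (named vector).
#' @export
compare_shape_hbonds <- function(summary_globular, summary_rod) {
  stopifnot(
    inherits(summary_globular, "hbond_category_summary"),
    inherits(summary_rod, "hbond_category_summary")
  )
  list(
    mean_count_diff = summary_globular$mean_count - summary_rod$mean_count,
    percent_diff = summary_globular$percent - summary_rod$percent
  )
}
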