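# Reading, writing and validating multi-conformer structure ensembles.
#
# A ConformerEnsemble couples one shared atom table (element, residue,
# partial charge) with M coordinate sets in angstroms.  Gas-phase only: no
# box, no periodicity.

.known_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Br", "I", "Fe", "Zn", "Se"
)

.unit_labels <- c(
  "core-chitobiose", "alpha1-3-arm", "alpha1-6-arm", "fucose", "PA-tag"
)

#' Construct a conformational ensemble
#'
#' Bundles a shared atom table with one or more coordinate sets.  All
#' downstream analyses (clustering, RMSF, CCS, hydrogen bonds) consume this
#' container.
#'
#' @param atoms data frame with columns `element`, `atom_name`,
#'   `residue_index`, `residue_name`, and optionally `charge` (elementary
#'   charges, default 0) and `radius_override` (angstrom, default `NA`).
#' @param coords list of numeric N x 3 matrices (angstrom), one per
#'   conformer, all with the same atom order as `atoms`.
#' @param labels optional character vector of per-conformer tags.
#' @return object of class `conformer_ensemble` with elements `atoms`,
#'   `coords`, `labels`.
#' @export
conformer_ensemble <- function(atoms, coords, labels = NULL) {
  stopifnot(is.data.frame(atoms))
  required <- c("element", "atom_name", "residue_index", "residue_name")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$radius_override)) atoms$radius_override <- NA_real_
  bad <- setdiff(unique(atoms$element), .known_elements)
  if (length(bad) > 0) {
    stop("unrecognized element symbol(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(atoms$charge))) stop("non-finite partial charge")
  if (!is.list(coords) || length(coords) < 1) {
    stop("ensemble must contain at least one conformer (M >= 1)")
  }
  n <- nrow(atoms)
  for (m in seq_along(coords)) {
    x <- coords[[m]]
    if (!is.matrix(x) || ncol(x) != 3 || nrow(x) != n) {
      stop(sprintf(
        "conformer %d has %s coordinate rows; expected %d x 3",
        m, if (is.matrix(x)) nrow(x) else "invalid", n
      ))
    }
    if (any(!is.finite(x))) stop(sprintf("conformer %d has non-finite coordinates", m))
    coords[[m]] <- unname(x)
  }
  if (!is.null(labels) && length(labels) != length(coords)) {
    stop("labels length must equal conformer count")
  }
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, coords = coords, labels = labels),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf(
    "Conformer ensemble: %d atoms, %d conformer(s), %d residue(s)\n",
    nrow(x$atoms), length(x$coords), length(unique(x$atoms$residue_index))
  ))
  invisible(x)
}

#' Number of conformers in an ensemble
#' @param ensemble a `conformer_ensemble`.
#' @return integer conformer count M.
#' @export
n_conformers <- function(ensemble) length(ensemble$coords)

# Map a PDB atom name to an element symbol when the element column is blank.
.element_from_name <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  two <- toupper(substr(nm, 1, 2))
  two <- paste0(substr(two, 1, 1), tolower(substr(two, 2, 2)))
  ifelse(two %in% c("Cl", "Br", "Fe", "Zn", "Se", "Na", "Mg"),
    two, toupper(substr(nm, 1, 1))
  )
}

#' Read a conformational ensemble from disk
#'
#' Supports multi-model PDB (MODEL/ENDMDL blocks; parsed with bio3d) and
#' concatenated XYZ (repeated natom/comment/atom-line frames).  All models
#' must share the same atom count and order; serial numbers are discarded in
#' favour of 0-based internal indices.
#'
#' @param path file path.
#' @param format `"pdb"` (multi-model) or `"xyz"` (concatenated frames).
#' @return a [conformer_ensemble()].
#' @export
read_ensemble <- function(path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") .read_ensemble_pdb(path) else .read_ensemble_xyz(path)
}

.read_ensemble_pdb <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  model_starts <- grepl("^MODEL", lines)
  if (any(model_starts)) {
    # line-scan validation so a short model is reported by index
    model_id <- cumsum(model_starts)
    counts <- table(model_id[is_atom & model_id > 0])
    if (length(unique(as.integer(counts))) > 1) {
      ref <- as.integer(counts[1])
      off <- names(counts)[which(as.integer(counts) != ref)[1]]
      stop(sprintf(
        "structural inconsistency: model %s has %d atoms, expected %d",
        off, as.integer(counts[off]), ref
      ))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  n <- nrow(pdb$atom)
  m <- nrow(xyz)
  elesy <- pdb$atom$elesy
  blank <- is.na(elesy) | elesy == ""
  if (any(blank)) {
    warning("element column absent for ", sum(blank),
      " atom(s); inferred from atom names")
    elesy[blank] <- .element_from_name(pdb$atom$elety[blank])
  }
  elesy <- paste0(
    toupper(substr(elesy, 1, 1)),
    tolower(substr(elesy, 2, 2))
  )
  bad <- setdiff(unique(elesy), .known_elements)
  if (length(bad) > 0) {
    stop("unrecognized element symbol(s) in PDB: ", paste(bad, collapse = ", "))
  }
  atoms <- data.frame(
    element = elesy,
    atom_name = pdb$atom$elety,
    residue_index = pdb$atom$resno,
    residue_name = pdb$atom$resid,
    charge = 0,
    radius_override = NA_real_,
    stringsAsFactors = FALSE
  )
  coords <- lapply(seq_len(m), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  conformer_ensemble(atoms, coords)
}

.read_ensemble_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > length(lines))]
  coords <- list()
  elements <- NULL
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i])) {
      i <- i + 1L
      next
    }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) stop("malformed XYZ frame header at line ", i)
    frame <- frame + 1L
    if (i + 1L + n > length(lines)) {
      stop(sprintf("structural inconsistency: frame %d truncated", frame))
    }
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(vapply(parts, length, 0L) < 4)) {
      stop(sprintf("structural inconsistency: frame %d has short atom lines", frame))
    }
    el <- vapply(parts, `[[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      stop(sprintf("non-numeric coordinates in frame %d", frame))
    }
    if (is.null(elements)) {
      elements <- el
    } else {
      if (length(el) != length(elements)) {
        stop(sprintf(
          "structural inconsistency: frame %d has %d atoms, expected %d",
          frame, length(el), length(elements)
        ))
      }
      if (!identical(el, elements)) {
        stop(sprintf("structural inconsistency: frame %d changes atom order", frame))
      }
    }
    coords[[frame]] <- xyz
    i <- i + 2L + n
  }
  if (frame == 0L) stop("no frames found in ", path)
  bad <- setdiff(unique(elements), .known_elements)
  if (length(bad) > 0) {
    stop("unrecognized element symbol(s) in XYZ: ", paste(bad, collapse = ", "))
  }
  atoms <- data.frame(
    element = elements,
    atom_name = elements,
    residue_index = seq_along(elements),
    residue_name = "UNK",
    charge = 0,
    radius_override = NA_real_,
    stringsAsFactors = FALSE
  )
  conformer_ensemble(atoms, coords)
}

#' Write a conformational ensemble to disk
#'
#' Multi-model PDB output goes through bio3d (coordinates at PDB's three
#' decimals); XYZ keeps six decimals.  Round-tripping through
#' [read_ensemble()] preserves topology exactly and coordinates within the
#' format precision.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param path output file path.
#' @param format `"pdb"` or `"xyz"`.
#' @return invisibly, `path`.
#' @export
write_ensemble <- function(ensemble, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (length(ensemble$coords) < 1) stop("refusing to write an empty ensemble")
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("cannot write to ", path, ": directory does not exist")
  if (format == "pdb") {
    # bio3d formats each model; MODEL/ENDMDL wrappers are written here so
    # even M = 1 files carry an explicit model block
    out <- character(0)
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    for (m in seq_along(ensemble$coords)) {
      bio3d::write.pdb(
        file = tmp,
        xyz = as.vector(t(ensemble$coords[[m]])),
        resno = ensemble$atoms$residue_index,
        resid = ensemble$atoms$residue_name,
        eleno = seq_len(nrow(ensemble$atoms)),
        elety = ensemble$atoms$atom_name,
        elesy = ensemble$atoms$element
      )
      body <- readLines(tmp)
      body <- body[!grepl("^(END|MODEL|ENDMDL)", body)]
      out <- c(out, sprintf("MODEL     %4d", m), body, "ENDMDL")
    }
    writeLines(c(out, "END"), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (m in seq_along(ensemble$coords)) {
      writeLines(as.character(nrow(ensemble$atoms)), con)
      writeLines(sprintf("frame %d", m), con)
      writeLines(sprintf(
        "%-2s %12.6f %12.6f %12.6f",
        ensemble$atoms$element,
        ensemble$coords[[m]][, 1],
        ensemble$coords[[m]][, 2],
        ensemble$coords[[m]][, 3]
      ), con)
    }
  }
  invisible(path)
}

#' Read a per-atom partial-charge sidecar table
#'
#' Two columns (0-based atom index, charge in elementary charges), white-
#' space or comma delimited, optional header.
#'
#' @param path file path.
#' @param n_atoms if given, coverage of indices `0:(n_atoms-1)` is enforced.
#' @return named numeric vector of charges, names are 0-based atom indices.
#' @export
read_charge_table <- function(path, n_atoms = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  parts <- strsplit(trimws(raw), "[,[:space:]]+")
  # drop a header row if the first field is not numeric
  if (length(parts) > 0 &&
    is.na(suppressWarnings(as.numeric(parts[[1]][1])))) {
    parts <- parts[-1]
  }
  if (any(vapply(parts, length, 0L) < 2)) stop("charge table rows need 2 columns")
  idx <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1)))
  chg <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  if (any(is.na(idx))) stop("non-integer atom index in charge table")
  if (any(is.na(chg))) stop("non-numeric charge in charge table")
  if (anyDuplicated(idx)) stop("duplicate atom index in charge table")
  if (!is.null(n_atoms)) {
    absent <- setdiff(0:(n_atoms - 1), idx)
    if (length(absent) > 0) {
      stop(
        "charge table does not cover atom index(es): ",
        paste(head(absent, 10), collapse = ", ")
      )
    }
  }
  setNames(chg, idx)
}

#' Attach sidecar charges to an ensemble
#'
#' @param ensemble a [conformer_ensemble()].
#' @param charges named numeric vector from [read_charge_table()].
#' @return the ensemble with `atoms$charge` filled.
#' @export
set_charges <- function(ensemble, charges) {
  n <- nrow(ensemble$atoms)
  absent <- setdiff(0:(n - 1), as.integer(names(charges)))
  if (length(absent) > 0) {
    stop(
      "charge set does not cover atom index(es): ",
      paste(head(absent, 10), collapse = ", ")
    )
  }
  ensemble$atoms$charge <- unname(charges[as.character(0:(n - 1))])
  ensemble
}

#' Read a residue-to-structural-unit annotation
#'
#' Key-value config mapping residue ranges to the five structural units of a
#' PA-glycan: core chitobiose, the two mannose arms, fucose, and the
#' 2-aminopyridine (PA) tag.  Lines look like `1-2: core-chitobiose` or
#' `7: fucose`.
#'
#' @param path file path (used when `lines` is NULL).
#' @param lines optional character vector of config lines (overrides `path`).
#' @return named character vector: names are residue indices, values unit
#'   labels; class `residue_annotation`.
#' @export
read_residue_annotation <- function(path = NULL, lines = NULL) {
  if (is.null(lines)) {
    if (is.null(path) || !file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- integer(0)
  labels <- character(0)
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed annotation line: ", ln)
    label <- trimws(kv[2])
    if (!label %in% .unit_labels) {
      stop(
        "unknown unit label '", label, "'; allowed: ",
        paste(.unit_labels, collapse = ", ")
      )
    }
    rng <- trimws(kv[1])
    if (grepl("-", rng)) {
      ab <- as.integer(strsplit(rng, "-")[[1]])
      if (length(ab) != 2 || any(is.na(ab)) || ab[1] > ab[2]) {
        stop("malformed residue range: ", rng)
      }
      res <- ab[1]:ab[2]
    } else {
      res <- as.integer(rng)
      if (is.na(res)) stop("malformed residue index: ", rng)
    }
    clash <- intersect(res, out)
    if (length(clash) > 0) {
      stop(
        "residue(s) assigned to more than one unit: ",
        paste(clash, collapse = ", ")
      )
    }
    out <- c(out, res)
    labels <- c(labels, rep(label, length(res)))
  }
  structure(setNames(labels, out), class = "residue_annotation")
}

#' Build a residue annotation from vectors
#' @param residue_index integer residue indices.
#' @param unit character unit labels, one of the five allowed values.
#' @return a `residue_annotation`.
#' @export
residue_annotation <- function(residue_index, unit) {
  stopifnot(length(residue_index) == length(unit))
  if (anyDuplicated(residue_index)) stop("residue assigned to more than one unit")
  bad <- setdiff(unique(unit), .unit_labels)
  if (length(bad) > 0) stop("unknown unit label(s): ", paste(bad, collapse = ", "))
  structure(setNames(unit, residue_index), class = "residue_annotation")
}

# Check an annotation against the residues actually present.
.check_annotation_coverage <- function(ensemble, annotation) {
  res <- unique(ensemble$atoms$residue_index)
  absent <- setdiff(res, as.integer(names(annotation)))
  if (length(absent) > 0) {
    stop(
      "annotation does not cover residue(s): ",
      paste(absent, collapse = ", ")
    )
  }
  invisible(TRUE)
}
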