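.PYRIMIDINE_RESIDUES <- c("DC", "DT", "DU", "C", "T", "U", "5CM", "5MC")
.WATER_RESIDUES <- c("HOH", "WAT", "H2O", "DOD")
.RING_ATOMS <- c("N1", "C2", "N3", "C4", "C5", "C6")

#' Read a nucleosome coordinate file
#'
#' Parses a PDB-format coordinate file into a tidy atom table. Waters are
#' excluded and alternate locations are resolved by keeping the highest
#' occupancy (ties go to the first record). Only the PDB format is supported.
#'
#' @param path Path to a PDB file.
#' @return A tibble of class `nucleosome_structure` with one row per atom:
#'   `atom_serial`, `atom_name`, `altloc`, `residue_name`, `chain_id`,
#'   `residue_number`, `x`, `y`, `z` (angstrom), `occupancy`, `b_factor`,
#'   `element`, `is_dna`.
#' @family structure
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  parse_structure(readLines(path, warn = FALSE))
}

#' Parse PDB-format text into an atom table
#'
#' @param pdb_text Character vector of PDB lines (or one string with
#'   newlines).
#' @inherit read_structure return
#' @family structure
#' @export
parse_structure <- function(pdb_text) {
  lines <- unlist(strsplit(pdb_text, "\n", fixed = TRUE), use.names = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records found", call. = FALSE)

  # validate coordinate fields up-front so a malformed record is reported by
  # line number instead of surfacing as NAs downstream
  coord_txt <- substr(lines[is_atom], 31, 54)
  bad <- which(is.na(suppressWarnings(as.numeric(substr(coord_txt, 1, 8)))) |
                 is.na(suppressWarnings(as.numeric(substr(coord_txt, 9, 16)))) |
                 is.na(suppressWarnings(as.numeric(substr(coord_txt, 17, 24)))))
  if (length(bad) > 0) {
    lineno <- which(is_atom)[bad[1]]
    stop("non-numeric coordinate on line ", lineno, ": ", lines[lineno],
         call. = FALSE)
  }

  pdb_file <- tempfile(fileext = ".pdb")
  on.exit(unlink(pdb_file))
  writeLines(lines, pdb_file)
  pdb <- bio3d::read.pdb(pdb_file, verbose = FALSE)
  a <- pdb$atom

  atoms <- tibble::tibble(
    atom_serial = as.integer(a$eleno),
    atom_name = a$elety,
    altloc = ifelse(is.na(a$alt), "", a$alt),
    residue_name = a$resid,
    chain_id = ifelse(is.na(a$chain), "", a$chain),
    residue_number = as.integer(a$resno),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b_factor = ifelse(is.na(a$b), NA_real_, a$b),
    element = if ("elesy" %in% names(a)) a$elesy else NA_character_
  )
  atoms <- atoms[!atoms$residue_name %in% .WATER_RESIDUES, , drop = FALSE]
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates after parsing", call. = FALSE)
  }

  # altloc resolution: highest occupancy per (chain, residue, atom name),
  # ties broken by file order
  atoms <- atoms[order(-atoms$occupancy), , drop = FALSE]
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$residue_name,
               atoms$atom_name, sep = "\r")
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  atoms <- atoms[order(atoms$atom_serial), , drop = FALSE]

  atoms$is_dna <- atoms$residue_name %in%
    c("DA", "DC", "DG", "DT", "DU", "DI", "A", "C", "G", "T", "U", "I",
      "5CM", "5MC")
  class(atoms) <- c("nucleosome_structure", class(atoms))
  atoms
}

#' Chains that contain DNA residues
#'
#' @param atoms An atom table from [parse_structure()].
#' @return Character vector of chain ids.
#' @family structure
#' @export
dna_chains <- function(atoms) {
  sort(unique(atoms$chain_id[atoms$is_dna]))
}

#' Estimate the nucleosome disc normal (superhelix axis)
#'
#' The DNA of a nucleosome wraps in a flat left-handed superhelix, so the
#' cloud of backbone phosphorus atoms forms a disc. The disc normal --- the
#' superhelix axis --- is the eigenvector of the smallest eigenvalue of the
#' phosphorus coordinate covariance, anchored at the phosphorus centroid.
#' The direction is signed to have positive dot product with the laboratory
#' +z axis (ties broken toward +x).
#'
#' @param atoms An atom table with at least 10 DNA phosphorus atoms
#'   (`atom_name == "P"`).
#' @return An object of class `superhelix_axis`: list with `origin` and unit
#'   `direction` (length-3 numerics).
#' @family structure
#' @export
superhelix_axis <- function(atoms) {
  p <- atoms[atoms$atom_name == "P", , drop = FALSE]
  if ("is_dna" %in% names(p) && any(p$is_dna)) p <- p[p$is_dna, , drop = FALSE]
  if (nrow(p) < 10) {
    stop("need at least 10 DNA phosphorus atoms, found ", nrow(p), call. = FALSE)
  }
  xyz <- cbind(p$x, p$y, p$z)
  origin <- colMeans(xyz)
  ev <- eigen(stats::cov(xyz), symmetric = TRUE)
  # spherical cloud: no unique minor axis
  if ((ev$values[2] - ev$values[3]) <= 1e-6 * ev$values[1]) {
    stop("degenerate covariance: phosphorus cloud has no unique flat normal",
         call. = FALSE)
  }
  direction <- ev$vectors[, 3]
  s <- direction[3]
  if (abs(s) < 1e-12) s <- direction[1]
  if (abs(s) < 1e-12) s <- direction[2]
  if (s < 0) direction <- -direction
  structure(list(origin = origin, direction = direction / sqrt(sum(direction^2))),
            class = "superhelix_axis")
}

#' @export
print.superhelix_axis <- function(x, ...) {
  cat(sprintf("Superhelix axis: origin (%.2f, %.2f, %.2f), direction (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

# atoms of one residue, as a named coordinate lookup
residue_coords <- function(atoms, chain, resno) {
  r <- atoms[atoms$chain_id == chain & atoms$residue_number == resno, , drop = FALSE]
  stats::setNames(lapply(seq_len(nrow(r)), function(i) c(r$x[i], r$y[i], r$z[i])),
                  r$atom_name)
}

#' Base orientation relative to the histone surface
#'
#' For each pyrimidine residue, computes the angle between (a) the vector
#' bisecting the base ring from the C6-N1 edge to the N3-C4 edge (midpoint of
#' C6/N1 to midpoint of N3/C4, pointing across the ring toward the
#' major-groove C4 edge) and (b) the outward perpendicular to the histone
#' core surface, realized as the cylindrical radial unit vector from the
#' superhelix axis to the ring centroid. An angle of 0 degrees means the base
#' edge faces directly away from the histone core; 180 degrees, directly
#' toward it.
#'
#' @param atoms An atom table from [parse_structure()].
#' @param axis A `superhelix_axis`; estimated from `atoms` when `NULL`.
#' @param residues Optional data frame with columns `chain_id` and
#'   `residue_number` selecting residues; defaults to every pyrimidine
#'   residue in `atoms`.
#' @return A tibble with `chain_id`, `residue_number`, `residue_name`,
#'   `angle_deg` in `[0, 180]` and `radial_distance_A`.
#' @family structure
#' @export
base_orientation <- function(atoms, axis = NULL, residues = NULL) {
  if (is.null(axis)) axis <- superhelix_axis(atoms)
  if (is.null(residues)) {
    pyr <- atoms[atoms$residue_name %in% .PYRIMIDINE_RESIDUES, , drop = FALSE]
    residues <- unique(pyr[, c("chain_id", "residue_number")])
  }
  if (nrow(residues) == 0) stop("no pyrimidine residues selected", call. = FALSE)

  rows <- lapply(seq_len(nrow(residues)), function(i) {
    ch <- residues$chain_id[i]
    rn <- residues$residue_number[i]
    res <- atoms[atoms$chain_id == ch & atoms$residue_number == rn, , drop = FALSE]
    if (nrow(res) == 0) stop("residue ", ch, ":", rn, " not found", call. = FALSE)
    if (!res$residue_name[1] %in% .PYRIMIDINE_RESIDUES) {
      stop("residue ", ch, ":", rn, " (", res$residue_name[1],
           ") is not a pyrimidine", call. = FALSE)
    }
    co <- residue_coords(atoms, ch, rn)
    missing_atoms <- setdiff(.RING_ATOMS, names(co))
    if (length(missing_atoms) > 0) {
      stop("residue ", ch, ":", rn, " is missing ring atom(s): ",
           paste(missing_atoms, collapse = ", "), call. = FALSE)
    }
    bisect <- (co$N3 + co$C4) / 2 - (co$C6 + co$N1) / 2
    centroid <- Reduce(`+`, co[.RING_ATOMS]) / 6
    rel <- centroid - axis$origin
    radial <- rel - sum(rel * axis$direction) * axis$direction
    radial_distance <- sqrt(sum(radial^2))
    if (radial_distance < 1e-9) {
      stop("residue ", ch, ":", rn, " lies on the superhelix axis", call. = FALSE)
    }
    cosang <- sum(bisect * radial) / (sqrt(sum(bisect^2)) * radial_distance)
    tibble::tibble(
      chain_id = ch, residue_number = rn, residue_name = res$residue_name[1],
      angle_deg = acos(pmin(1, pmax(-1, cosang))) * 180 / pi,
      radial_distance_A = radial_distance
    )
  })
  dplyr::bind_rows(rows)
}

#' Mean temperature factor per nucleotide
#'
#' Unweighted mean crystallographic B-factor over all atoms of each residue
#' (base, sugar and phosphate), a per-nucleotide flexibility proxy.
#'
#' @param atoms An atom table from [parse_structure()].
#' @return A tibble with `chain_id`, `residue_number`, `residue_name`,
#'   `mean_b`, `n_atoms`.
#' @family structure
#' @export
mean_b_factors <- function(atoms) {
  a <- atoms[!is.na(atoms$b_factor), , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms with B-factors", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(a, .data$chain_id, .data$residue_number, .data$residue_name),
    mean_b = mean(.data$b_factor),
    n_atoms = dplyr::n(),
    .groups = "drop"
  )
}

#' Signed dihedral angle of four points
#'
#' Standard four-point torsion: the angle between the plane of `p1,p2,p3`
#' and the plane of `p2,p3,p4`, signed by the right-hand rule about the
#' `p2 -> p3` axis, in degrees in `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinates.
#' @return Angle in degrees.
#' @family structure
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  b2_hat <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross(n1, n2) * b2_hat), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Photodimer geometry of an adjacent pyrimidine pair
#'
#' For two sequential pyrimidines on one strand (`resno_j` the 3' neighbour
#' of `resno_i`), computes the two quantities that gauge how well the C5-C6
#' double bonds are poised for [2+2] photocycloaddition: the distance between
#' the C5-C6 bond midpoints, and the improper torsion
#' C5(i)-C6(i)-C6(j)-C5(j). An eclipsed stack gives a torsion of 0 degrees.
#'
#' @param atoms An atom table from [parse_structure()].
#' @param chain_id Chain identifier.
#' @param resno_i 5' residue number.
#' @param resno_j 3' residue number; must equal `resno_i + 1`.
#' @return A one-row tibble: `chain_id`, `resno_i`, `resno_j`,
#'   `interbond_distance_A`, `improper_torsion_deg`.
#' @family structure
#' @export
photodimer_geometry <- function(atoms, chain_id, resno_i, resno_j = resno_i + 1) {
  if (resno_j != resno_i + 1) {
    stop("residues are not sequential on one strand: ", resno_i, " and ", resno_j,
         call. = FALSE)
  }
  get_res <- function(rn) {
    res <- atoms[atoms$chain_id == chain_id & atoms$residue_number == rn, , drop = FALSE]
    if (nrow(res) == 0) stop("residue ", chain_id, ":", rn, " not found", call. = FALSE)
    if (!res$residue_name[1] %in% .PYRIMIDINE_RESIDUES) {
      stop("residue ", chain_id, ":", rn, " (", res$residue_name[1],
           ") is not a pyrimidine", call. = FALSE)
    }
    co <- residue_coords(atoms, chain_id, rn)
    if (!all(c("C5", "C6") %in% names(co))) {
      stop("residue ", chain_id, ":", rn, " is missing C5/C6 atoms", call. = FALSE)
    }
    co
  }
  ci <- get_res(resno_i)
  cj <- get_res(resno_j)
  mid_i <- (ci$C5 + ci$C6) / 2
  mid_j <- (cj$C5 + cj$C6) / 2
  tibble::tibble(
    chain_id = chain_id,
    resno_i = resno_i,
    resno_j = resno_j,
    interbond_distance_A = sqrt(sum((mid_i - mid_j)^2)),
    improper_torsion_deg = dihedral_angle(ci$C5, ci$C6, cj$C6, cj$C5)
  )
}
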