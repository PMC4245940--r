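with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code() else withr::with_seed(seed, code())
}

#' Simulate a deamination gel time course
#'
#' Generates band intensities for one site under the model the analysis
#' assumes. The true deaminated fraction at time t is
#' `f(t) = cpd_yield * (1 - (1 - f0) * exp(-k t))` with `f0` the fraction of
#' CPDs already deaminated at t = 0 (deamination during workup makes the
#' initial thymine amount nonzero and variable). Band intensities get
#' independent multiplicative log-normal noise per band, the natural model
#' for positive phosphorimager counts with a roughly constant coefficient of
#' variation. One terminal aliquot is generated at complete deamination
#' (`f = cpd_yield`).
#'
#' When `times_h` is not supplied, aliquot times follow the design of the
#' assay itself --- sampling is matched to the process: multiples
#' `{0, 0.2, 0.5, 1, 1.5, 2, 2.5}` of the true half-life, so that every
#' course covers the observable decay window regardless of how fast the site
#' deaminates.
#'
#' @param k True first-order rate constant, h^-1.
#' @param cpd_yield True photoproduct yield, a fraction in (0, 1].
#' @param initial_deaminated Fraction of CPDs already deaminated at t = 0,
#'   in `[0, 1)`.
#' @param times_h Sampling times in hours; default is half-life-proportional
#'   (see Details).
#' @param noise_sigma SD of the per-band log-normal intensity noise.
#' @param total_signal Total label per aliquot, arbitrary units.
#' @param site_id Site label for the output.
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return A tibble with columns `site_id`, `time_h`, `intensity_mC`,
#'   `intensity_T`, `is_terminal`, ready for [fit_deamination()].
#' @family synthetic data
#' @export
generate_time_course <- function(k, cpd_yield, initial_deaminated = 0.05,
                                 times_h = NULL, noise_sigma = 0.05,
                                 total_signal = 1000, site_id = "synthetic",
                                 seed = NULL) {
  stopifnot(k > 0, cpd_yield > 0, cpd_yield <= 1,
            initial_deaminated >= 0, initial_deaminated < 1,
            noise_sigma >= 0, total_signal > 0)
  if (is.null(times_h)) {
    times_h <- (log(2) / k) * c(0, 0.2, 0.5, 1, 1.5, 2, 2.5)
  }
  if (any(times_h < 0)) stop("times_h must be nonnegative", call. = FALSE)

  with_optional_seed(seed, function() {
    f <- cpd_yield * (1 - (1 - initial_deaminated) * exp(-k * times_h))
    n <- length(times_h)
    eps_T <- exp(stats::rnorm(n, 0, noise_sigma))
    eps_C <- exp(stats::rnorm(n, 0, noise_sigma))
    term_T <- total_signal * cpd_yield * exp(stats::rnorm(1, 0, noise_sigma))
    term_C <- total_signal * (1 - cpd_yield) * exp(stats::rnorm(1, 0, noise_sigma))
    tibble::tibble(
      site_id = site_id,
      time_h = c(times_h, NA_real_),
      intensity_mC = c(total_signal * (1 - f) * eps_C, term_C),
      intensity_T = c(total_signal * f * eps_T, term_T),
      is_terminal = c(rep(0L, n), 1L)
    ) |>
      dplyr::mutate(time_h = ifelse(.data$is_terminal == 1, Inf, .data$time_h))
  })
}

#' Simulate a sinusoidal cleavage profile
#'
#' `baseline + amplitude * cos(2 * pi * (position - phase_bp) / period_bp)`
#' plus Gaussian noise, clipped at zero: the single-harmonic idealization of
#' a hydroxyl-radical footprint.
#'
#' @param period_bp Helical repeat in bp.
#' @param phase_bp Position of a maximum.
#' @param amplitude,baseline Oscillation parameters; `baseline > amplitude`
#'   keeps intensities positive.
#' @param noise_sigma SD of additive Gaussian noise.
#' @param length Number of positions (1-based).
#' @param seed Optional integer seed.
#' @return A tibble with `position`, `intensity`.
#' @family synthetic data
#' @export
generate_profile <- function(period_bp = 10.4, phase_bp = 76, amplitude = 20,
                             baseline = 50, noise_sigma = 0, length = 147,
                             seed = NULL) {
  stopifnot(period_bp > 0, amplitude >= 0, baseline > amplitude, length >= 2,
            noise_sigma >= 0)
  with_optional_seed(seed, function() {
    position <- seq_len(length)
    intensity <- baseline +
      amplitude * cos(2 * pi * (position - phase_bp) / period_bp) +
      stats::rnorm(length, 0, noise_sigma)
    tibble::tibble(position = position, intensity = pmax(intensity, 0))
  })
}

#' Simulate a protection-trough cleavage profile
#'
#' Real nucleosome footprints are not symmetric cosines: cleavage protection
#' where the backbone contacts the histone core appears as narrow periodic
#' troughs cut into a broad plateau. This generator superimposes Gaussian
#' troughs of width `trough_sd` every `period_bp` on a constant plateau,
#' reproducing the shape from which inside/outside orientation is read.
#'
#' @param trough_start Position of one protection minimum; further minima
#'   repeat every `period_bp` in both directions.
#' @param period_bp Helical repeat in bp.
#' @param plateau Cleavage intensity away from contacts.
#' @param depth Depth of each trough.
#' @param trough_sd Gaussian width of each trough, bp.
#' @param length Number of positions.
#' @param noise_sigma SD of additive Gaussian noise.
#' @param seed Optional integer seed.
#' @return A tibble with `position`, `intensity`.
#' @family synthetic data
#' @export
generate_protection_profile <- function(trough_start = 70.8, period_bp = 10.4,
                                        plateau = 100, depth = 60,
                                        trough_sd = 0.9, length = 147,
                                        noise_sigma = 0, seed = NULL) {
  stopifnot(period_bp > 0, plateau > 0, depth >= 0, depth <= plateau,
            trough_sd > 0, noise_sigma >= 0)
  with_optional_seed(seed, function() {
    position <- seq_len(length)
    k_range <- ceiling(length / period_bp)
    centres <- trough_start + period_bp * seq(-k_range, k_range)
    intensity <- rep(plateau, length)
    for (ct in centres) {
      intensity <- intensity - depth * exp(-(position - ct)^2 / (2 * trough_sd^2))
    }
    intensity <- intensity + stats::rnorm(length, 0, noise_sigma)
    tibble::tibble(position = position, intensity = pmax(intensity, 0))
  })
}

#' Idealized DNA-on-superhelix coordinates
#'
#' Builds a single-strand placeholder duplex wrapped on a superhelix: one
#' phosphorus and the six pyrimidine ring atoms per base pair, with the base
#' "outwardness" rotating once per `bp_per_turn` so that exactly one face of
#' the helix points away from the histone core per helical turn. The ring
#' atoms are placed so the C6/N1-to-N3/C4 bisecting vector points along the
#' outward direction of each base, and each atom's B-factor placeholder is
#' its radial distance from the superhelix axis (so the temperature-factor
#' maximum coincides with the outward-facing position by construction).
#'
#' The coordinates are expressed in the frame in which the phosphorus disc
#' normal is exactly the laboratory +z axis and the phosphorus centroid is
#' the origin (construction happens on a pitched arc, whose flat normal is
#' tilted from the winding axis; a final rigid rotation into the disc frame
#' leaves every internal geometric quantity unchanged).
#'
#' @param radius_A Superhelix radius, angstrom.
#' @param pitch_A Superhelix pitch (rise per superhelical turn), angstrom.
#' @param bp_per_turn Double-helical repeat, bp per turn.
#' @param n_bp Number of base pairs.
#' @param outward_bp Base pair whose base faces exactly outward; defaults to
#'   the central position.
#' @param rise_A Contour rise per bp along the superhelical path, angstrom.
#' @param chain_id Chain label for the output atoms.
#' @param noise_A SD of isotropic Gaussian coordinate jitter, angstrom.
#' @param seed Optional integer seed (used when `noise_A > 0`).
#' @return An atom tibble of class `nucleosome_structure` (see
#'   [parse_structure()]); residues are `DT` placeholders numbered `1:n_bp`.
#' @family synthetic data
#' @export
generate_helix <- function(radius_A = 41.9, pitch_A = 25.9, bp_per_turn = 10.4,
                           n_bp = 147, outward_bp = NULL, rise_A = 3.4,
                           chain_id = "I", noise_A = 0, seed = NULL) {
  stopifnot(radius_A > 0, pitch_A > 0, bp_per_turn > 0, n_bp >= 12,
            rise_A > 0, noise_A >= 0)
  if (is.null(outward_bp)) outward_bp <- (n_bp + 1) %/% 2

  with_optional_seed(seed, function() {
    i <- seq_len(n_bp) - outward_bp
    c_pitch <- pitch_A / (2 * pi)
    dphi <- rise_A / sqrt(radius_A^2 + c_pitch^2)
    phi <- i * dphi
    axis_pt <- cbind(radius_A * cos(phi), radius_A * sin(phi), c_pitch * phi)
    u <- cbind(cos(phi), sin(phi), 0) # outward radial of the winding axis
    tang <- cbind(-radius_A * sin(phi), radius_A * cos(phi),
                  rep(c_pitch, n_bp))
    tang <- tang / sqrt(rowSums(tang^2))
    w <- cbind(u[, 2] * tang[, 3] - u[, 3] * tang[, 2],
               u[, 3] * tang[, 1] - u[, 1] * tang[, 3],
               u[, 1] * tang[, 2] - u[, 2] * tang[, 1])
    psi <- 2 * pi * i / bp_per_turn # rotational phase; 0 = outward
    d <- u * cos(psi) + w * sin(psi)

    # phosphorus offset from the duplex axis at the base's own rotational
    # phase (placeholder backbone; keeps every atom of a residue at one
    # phase, so per-residue means are phase-pure); ring centroid displaced
    # outward along d
    p_xyz <- axis_pt + 8.9 * d
    centroid <- axis_pt + 2.0 * d

    ring_names <- .RING_ATOMS
    theta <- (-150 + 60 * (seq_along(ring_names) - 1)) * pi / 180
    atoms_per_res <- 1 + length(ring_names)
    xyz <- matrix(NA_real_, nrow = n_bp * atoms_per_res, ncol = 3)
    name <- character(n_bp * atoms_per_res)
    resno <- integer(n_bp * atoms_per_res)
    for (b in seq_len(n_bp)) {
      base_row <- (b - 1) * atoms_per_res
      xyz[base_row + 1, ] <- p_xyz[b, ]
      name[base_row + 1] <- "P"
      resno[base_row + 1] <- b
      for (j in seq_along(ring_names)) {
        xyz[base_row + 1 + j, ] <- centroid[b, ] +
          1.4 * (cos(theta[j]) * d[b, ] + sin(theta[j]) * tang[b, ])
        name[base_row + 1 + j] <- ring_names[j]
        resno[base_row + 1 + j] <- b
      }
    }
    if (noise_A > 0) {
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_A), ncol = 3)
    }

    # B placeholder: distance from the superhelix winding axis (construction
    # z-axis), a pure function of the rotational phase, so the per-residue
    # B maximum sits at the outward-facing base by construction
    radial_dist <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)

    # re-express in the disc frame: P centroid at the origin, P-cloud flat
    # normal exactly +z (rigid motion; internal geometry unchanged)
    p_rows <- which(name == "P")
    ctr <- colMeans(xyz[p_rows, , drop = FALSE])
    ev <- eigen(stats::cov(xyz[p_rows, , drop = FALSE]), symmetric = TRUE)
    normal <- ev$vectors[, 3]
    if (normal[3] < 0) normal <- -normal
    rot <- rotation_onto(normal, c(0, 0, 1))
    xyz <- t(rot %*% (t(xyz) - ctr))
    atoms <- tibble::tibble(
      atom_serial = seq_along(name),
      atom_name = name,
      altloc = "",
      residue_name = "DT",
      chain_id = chain_id,
      residue_number = resno,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1,
      b_factor = radial_dist,
      element = substr(name, 1, 1),
      is_dna = TRUE
    )
    class(atoms) <- c("nucleosome_structure", class(atoms))
    atoms
  })
}

# rotation matrix taking unit vector a onto unit vector b
rotation_onto <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c0 <- sum(a * b)
  if (abs(1 + c0) < 1e-12) { # antiparallel: rotate 180 about any perpendicular
    perp <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- perp - sum(perp * a) * a
    perp <- perp / sqrt(sum(perp^2))
    return(2 * outer(perp, perp) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2],
                 v[3], 0, -v[1],
                 -v[2], v[1], 0), nrow = 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c0)
}

#' Write an atom table as a PDB file
#'
#' @param atoms An atom table (e.g. from [generate_helix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @family structure
#' @export
write_structure_pdb <- function(atoms, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(cbind(atoms$x, atoms$y, atoms$z))),
    resno = atoms$residue_number,
    resid = atoms$residue_name,
    eleno = atoms$atom_serial,
    elety = atoms$atom_name,
    chain = atoms$chain_id,
    o = atoms$occupancy,
    b = atoms$b_factor
  )
  invisible(path)
}

#' Reference site table: yields and deamination half-lives
#'
#' Measured CPD photoproduct yields and deamination half-lives for a
#' T(mC)G dinucleotide stepped through the ten consecutive rotational
#' positions at the dyad axis of a nucleosome core particle, together with
#' the free-DNA control and the T(mC)A flanking-sequence variants at the
#' innermost (position 1) and outermost (position 6) settings. Fold-change
#' columns are kept as printed strings (`*_printed`) so their precision is
#' known; derived quantities should be recomputed from the yield and
#' half-life columns rather than from the rounded folds.
#'
#' @return A tibble with 14 rows and columns `site`, `dna`
#'   (`"free"`/`"ncp"`), `context` (`"TmCG"`/`"TmCA"`), `position`
#'   (rotational position 1-10; `NA` for free DNA), `yield_percent`,
#'   `yield_fold_printed`, `half_life_h`, `half_life_se_h`,
#'   `half_life_fold_printed`.
#' @family synthetic data
#' @export
deamination_site_data <- function() {
  tibble::tribble(
    ~site,          ~dna,   ~context, ~position, ~yield_percent, ~yield_fold_printed, ~half_life_h, ~half_life_se_h, ~half_life_fold_printed,
    "Free ds1-10",  "free", "TmCG",   NA,        12,             NA,                  13,           1,               NA,
    "NCP ds1",      "ncp",  "TmCG",   1L,        6.9,            "0.6",               41,           2,               "3.1",
    "NCP ds2",      "ncp",  "TmCG",   2L,        7.6,            "0.6",               39,           3,               "3.0",
    "NCP ds3",      "ncp",  "TmCG",   3L,        13,             "1.1",               15,           2,               "1.2",
    "NCP ds4",      "ncp",  "TmCG",   4L,        14,             "1.2",               9,            1,               "0.7",
    "NCP ds5",      "ncp",  "TmCG",   5L,        19,             "1.6",               5,            1,               "0.4",
    "NCP ds6",      "ncp",  "TmCG",   6L,        22,             "1.9",               3.5,          0.3,             "0.3",
    "NCP ds7",      "ncp",  "TmCG",   7L,        20,             "1.7",               3.6,          0.3,             "0.3",
    "NCP ds8",      "ncp",  "TmCG",   8L,        14,             "1.2",               10,           0.5,             "0.8",
    "NCP ds9",      "ncp",  "TmCG",   9L,        12,             "1.0",               12,           0.5,             "0.9",
    "NCP ds10",     "ncp",  "TmCG",   10L,       8.4,            "0.7",               36,           2,               "2.8",
    "Free ds1A",    "free", "TmCA",   NA,        14,             NA,                  85,           6,               NA,
    "NCP ds1A",     "ncp",  "TmCA",   1L,        12,             "0.8",               117,          7,               "1.3",
    "Free ds6A",    "free", "TmCA",   NA,        14,             NA,                  90,           3,               NA,
    "NCP ds6A",     "ncp",  "TmCA",   6L,        24,             "1.7",               28,           0.6,             "0.32"
  )
}
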