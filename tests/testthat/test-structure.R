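test_that("PDB text parses into a tidy atom table", {
  txt <- c(
    pdb_line(1, "P", "DT", "I", 1, 1.5, -2.25, 3.125, b = 10),
    pdb_line(2, "C5", "DT", "I", 1, 0, 0, 1, b = 20),
    pdb_line(3, "C6", "DT", "I", 1, 1, 0, 1, b = 30)
  )
  atoms <- parse_structure(txt)
  expect_equal(nrow(atoms), 3)
  expect_equal(atoms$x, c(1.5, 0, 1))
  expect_equal(atoms$y, c(-2.25, 0, 0))
  expect_equal(atoms$z, c(3.125, 1, 1))
  expect_equal(atoms$atom_name, c("P", "C5", "C6"))
  expect_equal(atoms$b_factor, c(10, 20, 30))
  expect_true(all(atoms$is_dna))
})

test_that("altlocs resolve to the highest occupancy and waters are dropped", {
  txt <- c(
    pdb_line(1, "C5", "DC", "I", 1, 0, 0, 0, occ = 0.6, alt = "A"),
    pdb_line(2, "C5", "DC", "I", 1, 9, 9, 9, occ = 0.4, alt = "B"),
    pdb_line(3, "O", "HOH", "W", 2, 5, 5, 5, record = "HETATM"),
    pdb_line(4, "N1", "DC", "I", 1, 1, 1, 1)
  )
  atoms <- parse_structure(txt)
  expect_equal(nrow(atoms), 2)
  c5 <- atoms[atoms$atom_name == "C5", ]
  expect_equal(c(c5$x, c5$y, c5$z), c(0, 0, 0)) # occupancy 0.6 wins
  expect_false(any(atoms$residue_name == "HOH"))
  # equal occupancies: the first record wins
  tie <- parse_structure(c(
    pdb_line(1, "C5", "DC", "I", 1, 0, 0, 0, occ = 0.5, alt = "A"),
    pdb_line(2, "C5", "DC", "I", 1, 9, 9, 9, occ = 0.5, alt = "B")
  ))
  expect_equal(tie$x, 0)
})

test_that("malformed coordinates are reported by line number", {
  txt <- c(
    pdb_line(1, "C5", "DC", "I", 1, 0, 0, 0),
    sub("   0.000", "  banana", pdb_line(2, "C6", "DC", "I", 1, 0, 0, 0))
  )
  expect_error(parse_structure(txt), "line 2")
  expect_error(parse_structure("REMARK nothing here"), "no ATOM")
})

test_that("the disc normal of a cylinder of points is recovered exactly", {
  ang <- 2 * pi * (0:39) / 40
  xyz <- rbind(cbind(10 * cos(ang), 10 * sin(ang), -5),
               cbind(10 * cos(ang), 10 * sin(ang), 5))
  axis <- superhelix_axis(p_cloud(xyz))
  expect_equal(axis$direction, c(0, 0, 1), tolerance = 1e-6)
  expect_equal(axis$origin, c(0, 0, 0), tolerance = 1e-9)
  # equivariance: a rigidly rotated cloud gives the rotated normal
  rot <- withr::with_seed(4, random_rotation())
  axis2 <- superhelix_axis(p_cloud(xyz %*% t(rot)))
  dir2 <- as.numeric(rot %*% c(0, 0, 1))
  if (sum(dir2 * axis2$direction) < 0) dir2 <- -dir2
  expect_equal(axis2$direction, dir2, tolerance = 1e-6)
})

test_that("degenerate or undersized phosphorus clouds are refused", {
  expect_error(superhelix_axis(p_cloud(icosahedron())), "degenerate")
  expect_error(superhelix_axis(p_cloud(matrix(runif(9 * 3), ncol = 3))),
               "at least 10")
})

test_that("base orientation measures the angle to the outward radial", {
  # bisecting vector along +x, base centred at (10, 0, 0), axis = z:
  # the base faces exactly outward
  outward <- ring_atoms(c(10, 0, 0), c(1, 0, 0), c(0, 1, 0))
  ori <- base_orientation(outward, manual_axis())
  expect_equal(ori$angle_deg, 0, tolerance = 1e-9)
  expect_equal(ori$radial_distance_A, 10, tolerance = 1e-9)
  # rotated 180 degrees about the local helix axis: faces the core
  inward <- ring_atoms(c(10, 0, 0), c(-1, 0, 0), c(0, 1, 0))
  expect_equal(base_orientation(inward, manual_axis())$angle_deg, 180,
               tolerance = 1e-9)
  # bisecting vector orthogonal to the radial
  side <- ring_atoms(c(10, 0, 0), c(0, 0, 1), c(0, 1, 0))
  expect_equal(base_orientation(side, manual_axis())$angle_deg, 90,
               tolerance = 1e-9)
})

test_that("base orientation validates residue identity and atoms", {
  ring <- ring_atoms(c(10, 0, 0), c(1, 0, 0), c(0, 1, 0))
  purine <- ring
  purine$residue_name <- "DG"
  expect_error(
    base_orientation(purine, manual_axis(),
                     residues = data.frame(chain_id = "I", residue_number = 1)),
    "not a pyrimidine"
  )
  expect_error(base_orientation(purine, manual_axis()), "no pyrimidine")
  broken <- ring[ring$atom_name != "N3", ]
  expect_error(
    base_orientation(broken, manual_axis(),
                     residues = data.frame(chain_id = "I", residue_number = 1)),
    "missing ring atom"
  )
})

test_that("mean temperature factors average all atoms of a nucleotide", {
  atoms <- atom_table(c("P", "C5"), "DT", "I", c(1, 1),
                      rbind(c(0, 0, 0), c(1, 1, 1)), b = c(10, 20))
  expect_equal(mean_b_factors(atoms)$mean_b, 15)
  single <- atom_table("C5", "DT", "I", 1, rbind(c(0, 0, 0)), b = 7.3)
  expect_equal(mean_b_factors(single)$mean_b, 7.3)
  flat <- atom_table(c("P", "C5", "C6", "N1"), "DT", "I", rep(1, 4),
                     matrix(rnorm(12), ncol = 3), b = 4.4)
  expect_equal(mean_b_factors(flat)$mean_b, 4.4)
})

test_that("photodimer geometry: eclipsed and anti stacks", {
  # two parallel C5-C6 bonds stacked 3.4 A apart, eclipsed
  eclipsed <- atom_table(
    c("C5", "C6", "C5", "C6"), "DT", "I", c(1, 1, 2, 2),
    rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 0, 3.4), c(1.5, 0, 3.4))
  )
  g <- photodimer_geometry(eclipsed, "I", 1)
  expect_equal(g$interbond_distance_A, 3.4, tolerance = 1e-12)
  expect_equal(g$improper_torsion_deg, 0, tolerance = 1e-9)
  # translating the upper base within the stacking plane moves the midpoint
  shifted <- eclipsed
  shifted$x[3:4] <- shifted$x[3:4] + 1
  g2 <- photodimer_geometry(shifted, "I", 1)
  expect_equal(g2$interbond_distance_A, sqrt(1 + 3.4^2), tolerance = 1e-12)
  expect_equal(g2$improper_torsion_deg, 0, tolerance = 1e-9)
  # anti-eclipsed: upper bond reversed
  anti <- eclipsed
  anti$x[3:4] <- c(1.5, 0)
  g3 <- photodimer_geometry(anti, "I", 1)
  expect_equal(abs(g3$improper_torsion_deg), 180, tolerance = 1e-9)
})

test_that("photodimer geometry validates residues", {
  atoms <- atom_table(
    c("C5", "C6", "C5", "C6"), "DT", "I", c(1, 1, 3, 3),
    rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 0, 3.4), c(1.5, 0, 3.4))
  )
  expect_error(photodimer_geometry(atoms, "I", 1, 3), "not sequential")
  incomplete <- atoms[atoms$atom_name != "C6" | atoms$residue_number != 1, ]
  incomplete$residue_number[incomplete$residue_number == 3] <- 2L
  expect_error(photodimer_geometry(incomplete, "I", 1), "missing C5/C6")
})

test_that("dihedral agrees with an independent torsion implementation", {
  set.seed(12)
  for (i in 1:25) {
    pts <- matrix(rnorm(12, sd = 3), ncol = 3)
    mine <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    oracle <- bio3d::torsion.xyz(as.numeric(t(pts)))
    oracle <- oracle[!is.na(oracle)]
    expect_equal(mine, as.numeric(oracle), tolerance = 1e-6)
  }
})

test_that("dihedral is reversal-invariant and mirror-antisymmetric", {
  set.seed(21)
  for (i in 1:10) {
    pts <- matrix(rnorm(12, sd = 3), ncol = 3)
    d <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    d_rev <- dihedral_angle(pts[4, ], pts[3, ], pts[2, ], pts[1, ])
    expect_equal(d_rev, d, tolerance = 1e-9)
    mirror <- pts
    mirror[, 3] <- -mirror[, 3]
    d_mir <- dihedral_angle(mirror[1, ], mirror[2, ], mirror[3, ], mirror[4, ])
    expect_equal(d_mir, -d, tolerance = 1e-9)
  }
})

test_that("geometry is invariant under rigid motions of the structure", {
  helix <- generate_helix(n_bp = 52)
  axis <- superhelix_axis(helix)
  ori <- base_orientation(helix, axis)
  geom <- photodimer_geometry(helix, "I", 26)
  bfac <- mean_b_factors(helix)
  withr::with_seed(8, {
    for (i in 1:5) {
      rot <- random_rotation()
      shift <- stats::runif(3, -50, 50)
      moved <- rigid_transform(helix, rot, shift)
      axis_m <- superhelix_axis(moved)
      ori_m <- base_orientation(moved, axis_m)
      expect_equal(ori_m$angle_deg, ori$angle_deg, tolerance = 1e-6)
      expect_equal(ori_m$radial_distance_A, ori$radial_distance_A,
                   tolerance = 1e-6)
      geom_m <- photodimer_geometry(moved, "I", 26)
      expect_equal(geom_m$interbond_distance_A, geom$interbond_distance_A,
                   tolerance = 1e-9)
      expect_equal(geom_m$improper_torsion_deg, geom$improper_torsion_deg,
                   tolerance = 1e-6)
      expect_equal(mean_b_factors(moved)$mean_b, bfac$mean_b)
    }
  })
})

test_that("angle outputs stay in range and structures list their DNA chains", {
  helix <- generate_helix(n_bp = 40)
  ori <- base_orientation(helix)
  expect_true(all(ori$angle_deg >= 0 & ori$angle_deg <= 180))
  expect_true(all(ori$radial_distance_A > 0))
  expect_equal(dna_chains(helix), "I")
})
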