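# shared builders for synthetic structures and handcrafted PDB text

pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     occ = 1, b = 0, alt = "", record = "ATOM  ") {
  sprintf("%s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, paste0(" ", name), alt, resn, chain, resno,
          x, y, z, occ, b)
}

# atom tibble with the columns structure functions expect
atom_table <- function(name, resn, chain, resno, xyz, b = 0, occ = 1) {
  n <- length(name)
  out <- tibble::tibble(
    atom_serial = seq_len(n),
    atom_name = name,
    altloc = "",
    residue_name = resn,
    chain_id = chain,
    residue_number = as.integer(resno),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = rep_len(occ, n),
    b_factor = rep_len(b, n),
    element = substr(name, 1, 1),
    is_dna = TRUE
  )
  class(out) <- c("nucleosome_structure", class(out))
  out
}

# phosphorus-only cloud for axis estimation
p_cloud <- function(xyz) {
  atom_table(rep("P", nrow(xyz)), "DT", "I", seq_len(nrow(xyz)), xyz)
}

# planar pyrimidine ring (hexagon, radius 1.4 A) whose C6/N1 -> N3/C4
# bisecting vector points along d_hat; ring plane spanned by d_hat and t_hat
ring_atoms <- function(centroid, d_hat, t_hat, resno = 1, chain = "I",
                       resn = "DC") {
  theta <- (-150 + 60 * (0:5)) * pi / 180
  xyz <- t(vapply(theta, function(th) {
    centroid + 1.4 * (cos(th) * d_hat + sin(th) * t_hat)
  }, numeric(3)))
  atom_table(c("N1", "C2", "N3", "C4", "C5", "C6"), resn, chain,
             rep(resno, 6), xyz)
}

manual_axis <- function(origin = c(0, 0, 0), direction = c(0, 0, 1)) {
  structure(list(origin = origin, direction = direction / sqrt(sum(direction^2))),
            class = "superhelix_axis")
}

random_rotation <- function() {
  th <- stats::runif(3, 0, 2 * pi)
  rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1])),
               3, byrow = TRUE)
  ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0, -sin(th[2]), 0, cos(th[2])),
               3, byrow = TRUE)
  rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0, 0, 0, 1),
               3, byrow = TRUE)
  rz %*% ry %*% rx
}

rigid_transform <- function(atoms, rot, shift) {
  m <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  atoms$x <- m[, 1] + shift[1]
  atoms$y <- m[, 2] + shift[2]
  atoms$z <- m[, 3] + shift[3]
  atoms
}

# icosahedron vertices: an exactly isotropic point cloud (spherical covariance)
icosahedron <- function(scale = 10) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(phi, 0, -1), c(-phi, 0, 1), c(-phi, 0, -1)
  )
  scale * v / sqrt(1 + phi^2)
}
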