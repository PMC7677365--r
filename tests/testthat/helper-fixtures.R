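# In-code fixtures shared across test files.

# minimal STAR particle table text
star_fixture <- function(extra_col = NULL, drop_tube = FALSE,
                         origins_px = FALSE, bad_cell = FALSE) {
  tags <- c("_rlnMicrographName", "_rlnCoordinateX", "_rlnCoordinateY",
            "_rlnAnglePsi", "_rlnAngleTilt", "_rlnAngleRot",
            "_rlnDefocusU", "_rlnDefocusV", "_rlnImagePixelSize")
  if (!drop_tube) tags <- append(tags, "_rlnHelicalTubeID", after = 1)
  if (origins_px) tags <- c(tags, "_rlnOriginX", "_rlnOriginY")
  if (!is.null(extra_col)) tags <- c(tags, extra_col)
  rows <- lapply(1:3, function(i) {
    v <- c(sprintf("mic1.mrc"),
           if (!drop_tube) "1",
           sprintf("%.1f", 100 + 26 * i), "200.0",
           "12.5", "90.0", sprintf("%.1f", 10 * i),
           if (bad_cell && i == 2) "oops" else "15000.0",
           "14800.0", "1.045")
    if (origins_px) v <- c(v, "2.0", "-1.0")
    if (!is.null(extra_col)) v <- c(v, sprintf("%d", i))
    paste(v, collapse = " ")
  })
  c("data_particles", "", "loop_",
    sprintf("%s #%d", tags, seq_along(tags)), unlist(rows))
}

write_star_fixture <- function(..., file = tempfile(fileext = ".star")) {
  writeLines(star_fixture(...), file)
  file
}

# one PDB ATOM line with correct fixed columns
pdb_line <- function(serial, name, resn, chain, resi, x, y, z,
                     occ = 1, b = 0, elem, alt = " ", het = FALSE) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, nm, alt, resn, chain,
          resi, x, y, z, occ, b, elem)
}

# three-atom model as PDB text
pdb_fixture <- function() {
  c(pdb_line(1, "N", "ALA", "A", 10, 11.104, 6.134, -6.504,
             1, 10.5, "N"),
    pdb_line(2, "CA", "ALA", "A", 10, 12.560, 6.351, -6.510,
             1, 11.0, "C"),
    pdb_line(3, "SG", "CYS", "A", 11, 13.000, 7.900, -5.000,
             1, 12.0, "S", het = FALSE),
    "END")
}

# the same three atoms as mmCIF text
mmcif_fixture <- function() {
  c("data_fixture", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "ATOM 1 N N  . ALA A 10 11.104 6.134 -6.504 1.00 10.50",
    "ATOM 2 C CA . ALA A 10 12.560 6.351 -6.510 1.00 11.00",
    "ATOM 3 S SG . CYS A 11 13.000 7.900 -5.000 1.00 12.00")
}

# build a particle_set for one straight filament along +y
# (psi = 0 means the filament axis unit vector is (0, 1))
straight_filament_set <- function(n = 5, spacing_px = 26,
                                  pixel_size = 1.045,
                                  defocus = rep(15000, n),
                                  psi = rep(0, n), tilt = rep(90, n),
                                  rot = NULL, origin_y = rep(0, n)) {
  if (is.null(rot)) rot <- wrap_angle(seq_len(n) * -166.7)
  particle_set(data.frame(
    micrograph_id = "m1.mrc", tube_id = 1,
    coord_x = 100, coord_y = 100 + (seq_len(n) - 1) * spacing_px,
    psi = psi, tilt = tilt, rot = rot,
    origin_x = 0, origin_y = origin_y,
    defocus_u = defocus, defocus_v = defocus,
    pixel_size = pixel_size))
}

# filament object from a set (single tube)
one_filament <- function(set) group_filaments(set)[[1]]

# rotation matrix about an arbitrary axis (degrees)
rot_about <- function(axis, deg) {
  a <- axis / sqrt(sum(axis^2)); th <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# brute-force minimum centred RMSD over a rotation grid (axis lattice x
# angle grid), via the Rodrigues decomposition R = I + s K + (1-c) K^2
# so the whole angle sweep is closed-form per axis
grid_rmsd_min <- function(mobile, ref, n_axes = 2000, step_deg = 1) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(ref, 2, colMeans(ref))
  th <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  s <- sin(th); c2 <- 1 - cos(th)
  # Fibonacci axis lattice (hemisphere suffices; theta covers the rest)
  k <- seq_len(n_axes) - 0.5
  z <- k / n_axes
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  axes <- cbind(r * cos(phi), r * sin(phi), z)
  n <- nrow(A)
  best <- Inf
  for (i in seq_len(n_axes)) {
    a <- axes[i, ]
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    AK <- A %*% K           # = -A %*% t(K)
    AK2 <- A %*% (K %*% K)  # K^2 is symmetric
    E0 <- A - B
    # E(theta) = E0 - s*AK + (1-c)*AK2, expanded into scalar products
    cost <- sum(E0^2) + s^2 * sum(AK^2) + c2^2 * sum(AK2^2) -
      2 * s * sum(E0 * AK) + 2 * c2 * sum(E0 * AK2) -
      2 * s * c2 * sum(AK * AK2)
    best <- min(best, min(cost))
  }
  sqrt(max(0, best) / n)
}

# independent OLS oracle used against trimmed_linefit
ols_oracle <- function(x, y) {
  fit <- stats::lm(y ~ x)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

# brute-force trimmed fit: drop one max and one min by value
# (later-indexed ties) then OLS
trimmed_oracle <- function(x, y) {
  i_max <- max(which(y == max(y)))
  rest <- setdiff(seq_along(y), i_max)
  i_min <- rest[max(which(y[rest] == min(y[rest])))]
  keep <- setdiff(seq_along(y), c(i_max, i_min))
  ols_oracle(x[keep], y[keep])
}

# aromatic-ring residue (TYR ring geometry, planar in z = 0)
tyr_ring <- function() {
  structure3d(data.frame(
    element = "C",
    atom_name = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    residue_name = "TYR", residue_number = 1, chain_id = "A",
    x = c(0, 1.2, -1.2, 1.2, -1.2, 0),
    y = c(0, 0.7, 0.7, 2.1, 2.1, 2.8), z = 0))
}

single_atom <- function(x = 0, y = 0, z = 0, elem = "C", name = "C1",
                        resn = "LIG", resi = 1, chain = "A", b = 0) {
  structure3d(data.frame(element = elem, atom_name = name,
                         residue_name = resn, residue_number = resi,
                         chain_id = chain, x = x, y = y, z = z,
                         b_factor = b))
}
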