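test_that("read_structure parses a hand-written PDB fixture", {
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb_fixture(), f)
  s <- read_structure(f)
  expect_s3_class(s, "structure3d")
  expect_equal(nrow(s), 3)
  expect_equal(s$atom_name, c("N", "CA", "SG"))
  expect_equal(s$x, c(11.104, 12.560, 13.000))
  expect_equal(s$b_factor, c(10.5, 11.0, 12.0))
  expect_equal(s$element, c("N", "C", "S"))
})

test_that("PDB and mmCIF readers yield the same structure", {
  fp <- tempfile(fileext = ".pdb"); fc <- tempfile(fileext = ".cif")
  writeLines(pdb_fixture(), fp); writeLines(mmcif_fixture(), fc)
  a <- read_structure(fp); b <- read_structure(fc)
  for (col in c("element", "atom_name", "residue_name",
                "residue_number", "chain_id", "b_factor"))
    expect_equal(a[[col]], b[[col]], label = col)
  expect_equal(as.matrix(a[c("x", "y", "z")]),
               as.matrix(b[c("x", "y", "z")]), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("highest-occupancy altloc wins", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, 0.6, 10, "C", alt = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 5, 0, 0, 0.4, 20, "C", alt = "B"),
    "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s), 1)
  expect_equal(s$x, 0)
  expect_equal(s$occupancy, 0.6)
})

test_that("selector text expressions resolve deterministically", {
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb_fixture(), f)
  s <- read_structure(f)
  expect_equal(select_atoms(s, "chain A and resi 10"), c(1L, 2L))
  expect_equal(select_atoms(s, "name CA"), 2L)
  expect_equal(select_atoms(s, "resi 10-11 and elem S"), 3L)
  expect_equal(select_atoms(s, "sidechain"), 3L)   # SG only
  expect_equal(select_atoms(s, "backbone"), c(1L, 2L))
  expect_length(select_atoms(s, "chain B"), 0)
  expect_error(parse_selection("wibble 3"), "unknown clause")
})

test_that("kabsch handles congruent, translated and rotated sets", {
  set.seed(4)
  m <- matrix(rnorm(12), 4, 3)
  sp0 <- kabsch_superpose(m, m)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(sp0$translation, rep(0, 3), tolerance = 1e-9)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-9)

  spt <- kabsch_superpose(m, sweep(m, 2, c(5, 0, 0), "+"))
  expect_equal(spt$rmsd, 0, tolerance = 1e-9)
  expect_equal(spt$translation, c(5, 0, 0), tolerance = 1e-9)

  R <- rot_about(c(0, 0, 1), 90)
  spr <- kabsch_superpose(m, m %*% t(R))
  ang <- acos((sum(diag(spr$rotation)) - 1) / 2) * 180 / pi
  expect_equal(ang, 90, tolerance = 1e-6)
  expect_lt(spr$rmsd, 1e-9)
  expect_equal(det(spr$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_superpose(m, m[1:3, ]), "counts differ")
})

test_that("kabsch rmsd agrees with a rotation-grid brute force", {
  set.seed(6)
  for (rep in 1:3) {
    ref <- matrix(rnorm(15), 5, 3)
    R <- rot_about(rnorm(3), runif(1, 10, 170))
    mobile <- sweep(ref %*% t(R), 2, rnorm(3), "+") +
      matrix(rnorm(15, 0, 0.05), 5, 3)
    sp <- kabsch_superpose(mobile, ref)
    best <- grid_rmsd_min(mobile, ref)
    # Kabsch must never exceed the grid optimum, and the grid optimum
    # must approach it to within the grid resolution
    expect_lte(sp$rmsd, best + 1e-12)
    expect_lt(best - sp$rmsd, 0.05)
  }
})

test_that("rmsd_selection matches atoms by identity and supports no-fit mode", {
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb_fixture(), f)
  a <- read_structure(f)
  expect_equal(rmsd_selection(a, a, NULL, superpose = FALSE), 0)
  # displace one atom of four by 1 A, no superposition -> sqrt(1/4)
  base <- data.frame(element = "C",
                     atom_name = c("C1", "C2", "C3", "C4"),
                     residue_name = "LIG", residue_number = 1:4,
                     chain_id = "A",
                     x = c(0, 3, 0, 3), y = c(0, 0, 3, 3), z = 0)
  b2 <- base; b2$z[2] <- 1
  expect_equal(rmsd_selection(structure3d(base), structure3d(b2), NULL,
                              superpose = FALSE), 0.5)
  expect_error(rmsd_selection(a, a, "chain Q"), "no matched")
})

test_that("isolated-sphere SASA matches the closed form within 0.5%", {
  s <- single_atom()
  a <- sasa(s)
  expect_equal(a, 4 * pi * 3.1^2, tolerance = 0.005)
  # two far-apart atoms are each isolated
  two <- structure3d(data.frame(
    element = "C", atom_name = c("C1", "C2"), residue_name = "LIG",
    residue_number = 1:2, chain_id = "A", x = c(0, 100), y = 0, z = 0))
  expect_equal(sasa(two), rep(4 * pi * 3.1^2, 2), tolerance = 0.005)
})

test_that("a caged atom loses more than 99% of its surface", {
  off <- expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2), z = c(-2, 0, 2))
  df <- data.frame(element = "C",
                   atom_name = sprintf("C%d", seq_len(nrow(off))),
                   residue_name = "LIG",
                   residue_number = seq_len(nrow(off)), chain_id = "A",
                   off)
  s <- structure3d(df)
  center <- which(off$x == 0 & off$y == 0 & off$z == 0)
  a <- sasa(s)
  expect_lt(a[center], 0.01 * 4 * pi * 3.1^2)
})

test_that("SASA is invariant under rotation and translation", {
  set.seed(12)
  df <- data.frame(element = sample(c("C", "N", "O"), 20, TRUE),
                   atom_name = sprintf("X%d", 1:20),
                   residue_name = "LIG", residue_number = 1:20,
                   chain_id = "A",
                   x = rnorm(20, 0, 3), y = rnorm(20, 0, 3),
                   z = rnorm(20, 0, 3))
  s <- structure3d(df)
  a0 <- sum(sasa(s))
  R <- rot_about(c(1, 2, 3), 37)
  xyz <- as.matrix(df[c("x", "y", "z")]) %*% t(R) + 10
  df2 <- df; df2$x <- xyz[, 1]; df2$y <- xyz[, 2]; df2$z <- xyz[, 3]
  expect_equal(sum(sasa(structure3d(df2))), a0, tolerance = 0.005)
})

test_that("adding an atom never increases existing per-atom SASA", {
  set.seed(13)
  df <- data.frame(element = "C", atom_name = sprintf("C%d", 1:8),
                   residue_name = "LIG", residue_number = 1:8,
                   chain_id = "A", x = rnorm(8, 0, 2.5),
                   y = rnorm(8, 0, 2.5), z = rnorm(8, 0, 2.5))
  a0 <- sasa(structure3d(df))
  df2 <- rbind(df, data.frame(element = "C", atom_name = "C9",
                              residue_name = "LIG", residue_number = 9,
                              chain_id = "A", x = 1, y = 0.5, z = -0.5))
  a1 <- sasa(structure3d(df2))
  expect_true(all(a1[1:8] <= a0 + 1e-9))
})

test_that("unknown elements need an override radius", {
  s <- single_atom(elem = "FE", name = "FE", resn = "HEM")
  expect_error(sasa(s), "FE")
  expect_equal(sasa(s, vdw_override = c(FE = 2.0)),
               4 * pi * 3.4^2, tolerance = 0.005)
})

test_that("buried_area matches the analytic spherical cap", {
  # two identical carbons in contact: each loses a cap of area
  # 2*pi*R*(R - d/2) from its expanded sphere (R = 1.7 + 1.4, d = 1.7)
  two <- structure3d(data.frame(
    element = "C", atom_name = c("C1", "C2"), residue_name = "LIG",
    residue_number = 1:2, chain_id = "A", x = c(0, 1.7), y = 0, z = 0))
  R <- 3.1; d <- 1.7
  cap <- 2 * pi * R * (R - d / 2)
  got <- buried_area(two, selector(resi = 1))
  expect_equal(got, cap, tolerance = 0.01)
  # isolated group buries nothing
  far <- structure3d(data.frame(
    element = "C", atom_name = c("C1", "C2"), residue_name = "LIG",
    residue_number = 1:2, chain_id = "A", x = c(0, 50), y = 0, z = 0))
  expect_equal(buried_area(far, selector(resi = 1)), 0,
               tolerance = 0.5)
})

test_that("group_sasa of the whole structure equals total SASA", {
  set.seed(14)
  df <- data.frame(element = "C", atom_name = sprintf("C%d", 1:10),
                   residue_name = "LIG", residue_number = 1:10,
                   chain_id = "A", x = rnorm(10, 0, 3),
                   y = rnorm(10, 0, 3), z = rnorm(10, 0, 3))
  s <- structure3d(df)
  expect_equal(group_sasa(s, NULL), sum(sasa(s)))
  expect_error(group_sasa(s, selector(chain = "Z")), "empty")
})

test_that("a free cysteine side chain has SASA on the order of 100 A^2", {
  # CB + SG with backbone present; order-of-magnitude check only
  cys <- structure3d(data.frame(
    element = c("N", "C", "C", "O", "C", "S"),
    atom_name = c("N", "CA", "C", "O", "CB", "SG"),
    residue_name = "CYS", residue_number = 1, chain_id = "A",
    x = c(-0.5, 0.9, 1.6, 1.1, 1.4, 0.6),
    y = c(1.2, 1.1, 2.4, 3.4, -0.1, -1.6),
    z = c(0, 0.4, 0.9, 0.9, 1.3, 1.9)))
  a <- group_sasa(cys, selector(part = "sidechain"))
  expect_gt(a, 30); expect_lt(a, 300)
})

test_that("min_group_distance returns the arg-min pair", {
  df <- data.frame(element = "C", atom_name = c("A1", "A2", "B1"),
                   residue_name = "LIG", residue_number = c(1, 1, 2),
                   chain_id = "A", x = c(0, 4, 7), y = 0, z = 0)
  s <- structure3d(df)
  r <- min_group_distance(s, selector(resi = 1), selector(resi = 2))
  expect_equal(r$distance, 3)
  expect_equal(r$pair$atom_name, c("A2", "B1"))
  two <- min_group_distance(s, selector(name = "A1"),
                            selector(name = "B1"))
  expect_equal(two$distance, 7)
  expect_error(min_group_distance(s, selector(chain = "Q"),
                                  selector(resi = 2)), "empty")
})

test_that("B-factor percent difference is exact arithmetic", {
  a <- single_atom(b = 53.65)
  b <- single_atom(b = 50)
  expect_identical(bfactor_group_percent_diff(a, a, NULL), 0)
  expect_equal(bfactor_group_percent_diff(a, b, NULL), 7.3)
  expect_error(bfactor_group_percent_diff(a, b, "chain Q"), "empty")
})

test_that("clash_scan applies the overlap arithmetic and is symmetric", {
  a <- single_atom(0, 0, 0)
  b_no <- single_atom(3.4, 0, 0, resi = 2, chain = "B")
  b_yes <- single_atom(2.9, 0, 0, resi = 2, chain = "B")
  expect_equal(nrow(clash_scan(a, b_no)), 0)     # overlap exactly 0
  r <- clash_scan(a, b_yes)
  expect_equal(nrow(r), 1)
  expect_equal(r$overlap, 0.5)
  expect_equal(r$distance, 2.9)
  # symmetry: swapped scan reports the same pair set
  r2 <- clash_scan(b_yes, a)
  expect_equal(sort(paste(r$atom_a, r$atom_b)),
               sort(paste(r2$atom_b, r2$atom_a)))
  # hydrogens excluded
  h <- single_atom(1.0, 0, 0, elem = "H", name = "H1", resi = 3)
  expect_equal(nrow(clash_scan(a, h)), 0)
})

test_that("clash_scan sorts multi-clash reports by overlap", {
  a <- structure3d(data.frame(
    element = "C", atom_name = c("C1", "C2"), residue_name = "LIG",
    residue_number = 1:2, chain_id = "A", x = c(0, 10), y = 0, z = 0))
  b <- structure3d(data.frame(
    element = "C", atom_name = c("D1", "D2"), residue_name = "LIG",
    residue_number = 3:4, chain_id = "B", x = c(2.5, 12.9), y = 0,
    z = 0))
  r <- clash_scan(a, b)
  expect_equal(nrow(r), 2)
  expect_equal(r$overlap, c(0.9, 0.5))
})

test_that("sidechain_rotation measures constructed ring rotations", {
  rA <- tyr_ring()
  expect_equal(sidechain_rotation(rA, rA), 0, tolerance = 1e-9)
  rot_ring <- function(deg) {
    R <- rot_about(c(1, 0, 0), deg)   # in-plane axis of the z=0 ring
    xyz <- as.matrix(as.data.frame(rA)[c("x", "y", "z")]) %*% t(R)
    d <- as.data.frame(rA); d$x <- xyz[, 1]; d$y <- xyz[, 2]
    d$z <- xyz[, 3]
    structure3d(d)
  }
  expect_equal(sidechain_rotation(rA, rot_ring(90)), 90,
               tolerance = 1e-6)
  expect_equal(sidechain_rotation(rA, rot_ring(44.1)), 44.1,
               tolerance = 1e-6)
  # plane-normal angles fold into [0, 90]
  expect_equal(sidechain_rotation(rA, rot_ring(130)), 50,
               tolerance = 1e-6)
})

test_that("vector-mode rotation uses CB -> terminal heavy atom", {
  lys <- function(nz) structure3d(data.frame(
    element = c("C", "N"), atom_name = c("CB", "NZ"),
    residue_name = "LYS", residue_number = 1, chain_id = "A",
    x = c(0, nz[1]), y = c(0, nz[2]), z = c(0, nz[3])))
  a <- lys(c(0, 0, 4))
  b <- lys(c(0, 4, 0))
  expect_equal(sidechain_rotation(a, b), 90, tolerance = 1e-9)
  expect_equal(sidechain_rotation(a, lys(c(0, 0, -4))), 180,
               tolerance = 1e-9)
})

test_that("sidechain_rotation errors without enough ring atoms", {
  d <- as.data.frame(tyr_ring())[1:2, ]
  expect_error(sidechain_rotation(structure3d(d), structure3d(d)),
               "ring atoms")
})
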