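# Geometric and statistical atomic-model comparisons: Kabsch
# superposition, selection RMSD, Shrake-Rupley SASA, buried area, group
# distances, B-factor comparison, van der Waals clash scanning and
# side-chain rotation angles.

# Bondi van der Waals radii (Angstrom)
.vdw_default <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
                  H = 1.2)

.vdw_radii <- function(elements, override = NULL) {
  tab <- .vdw_default
  if (!is.null(override)) tab[names(override)] <- override
  r <- tab[toupper(elements)]
  if (any(is.na(r)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "),
         " (supply vdw_override)", call. = FALSE)
  unname(r)
}

#' Optimal superposition of two coordinate sets (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `mobile` onto `reference`. A reflection-only optimum is corrected to
#' a proper rotation (determinant +1).
#'
#' @param mobile,reference n x 3 matrices with matched rows, n >= 3 and
#'   not all collinear.
#' @return a `superposition`: list with `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd` (post-fit, Angstrom), `n_atoms`. The fit maps a
#'   mobile point p to `rotation %*% p + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("kabsch_superpose: coordinate counts differ")
  if (nrow(mobile) < 3)
    stop("kabsch_superpose: need at least 3 atom pairs")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cr - drop(R %*% cm)
  fitted <- sweep(mobile %*% t(R), 2, t_vec, "+")
  structure(list(rotation = R, translation = t_vec,
                 rmsd = sqrt(mean(rowSums((fitted - reference)^2))),
                 n_atoms = nrow(mobile)),
            class = "superposition")
}

#' Apply a superposition to coordinates or a structure
#'
#' @param x n x 3 matrix or a `structure3d`.
#' @param sp a `superposition`.
#' @return transformed object of the same type.
#' @export
apply_superposition <- function(x, sp) {
  stopifnot(inherits(sp, "superposition"))
  if (inherits(x, "structure3d")) {
    xyz <- .coords(x)
    xyz <- sweep(xyz %*% t(sp$rotation), 2, sp$translation, "+")
    x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
    x
  } else {
    sweep(as.matrix(x) %*% t(sp$rotation), 2, sp$translation, "+")
  }
}

# match atoms of two structures by (chain, residue number, atom name)
.match_pairs <- function(a, b, sel = NULL) {
  ia <- select_atoms(a, sel); ib <- select_atoms(b, sel)
  key <- function(s, i) paste(s$chain_id[i], s$residue_number[i],
                              s$atom_name[i], sep = "\r")
  ka <- key(a, ia); kb <- key(b, ib)
  m <- match(ka, kb)
  ok <- !is.na(m)
  list(ia = ia[ok], ib = ib[m[ok]])
}

#' RMSD between matched atoms of two structures
#'
#' Atoms are paired by (chain, residue number, atom name) within the
#' selection; the root-mean-square deviation is computed over the pairs,
#' after a Kabsch fit of the matched atoms when `superpose` is TRUE.
#'
#' @param a,b `structure3d` objects.
#' @param sel a `selector`/expression restricting the comparison
#'   (e.g. `"name CA"` for alpha-carbons), or NULL for all atoms.
#' @param superpose fit `a` onto `b` first (default TRUE).
#' @return RMSD in Angstrom.
#' @export
rmsd_selection <- function(a, b, sel = NULL, superpose = TRUE) {
  mp <- .match_pairs(a, b, sel)
  if (length(mp$ia) == 0)
    stop("rmsd_selection: no matched atom pairs in selection")
  pa <- .coords(a, mp$ia); pb <- .coords(b, mp$ib)
  if (superpose) {
    sp <- kabsch_superpose(pa, pb)
    return(sp$rmsd)
  }
  sqrt(mean(rowSums((pa - pb)^2)))
}

# deterministic quasi-uniform unit-sphere lattice (Fibonacci spiral)
.sphere_lattice <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, test points are placed on a deterministic spiral
#' lattice on the sphere of radius `r_vdw + probe`; the accessible area
#' is the exposed-point fraction times `4 * pi * (r_vdw + probe)^2`.
#' No randomness is involved, so results are exactly reproducible.
#'
#' @param s a `structure3d`.
#' @param probe probe radius, Angstrom (water: 1.4).
#' @param n_dots lattice points per atom (default 960; lattice error on
#'   an isolated sphere is below 0.5 percent).
#' @param vdw_override named numeric vector of per-element radius
#'   overrides, Angstrom.
#' @return numeric vector of per-atom areas (Angstrom^2).
#' @export
sasa <- function(s, probe = 1.4, n_dots = 960, vdw_override = NULL) {
  stopifnot(inherits(s, "structure3d"), probe >= 0, n_dots >= 12)
  xyz <- .coords(s)
  rad <- .vdw_radii(s$element, vdw_override) + probe
  n <- nrow(xyz)
  dots <- .sphere_lattice(n_dots)
  areas <- numeric(n)
  rmax <- max(rad)
  for (i in seq_len(n)) {
    di <- xyz[i, ]
    # neighbours whose expanded sphere can reach atom i's surface
    dd <- sqrt(colSums((t(xyz) - di)^2))
    nb <- which(dd < rad[i] + rmax & seq_len(n) != i)
    nb <- nb[dd[nb] < rad[i] + rad[nb]]
    pts <- sweep(dots * rad[i], 2, di, "+")
    exposed <- rep(TRUE, n_dots)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- pts[exposed, , drop = FALSE]
      d2 <- (dj[, 1] - xyz[j, 1])^2 + (dj[, 2] - xyz[j, 2])^2 +
            (dj[, 3] - xyz[j, 3])^2
      exposed[exposed] <- d2 >= rad[j]^2
    }
    areas[i] <- mean(exposed) * 4 * pi * rad[i]^2
  }
  areas
}

#' SASA of an atom group within a context
#'
#' Computes per-atom SASA with all `context` atoms present and sums it
#' over the `sel` atoms. Use it for questions like "how accessible is
#' this side chain inside the filament".
#'
#' @param s a `structure3d`.
#' @param sel selector/expression for the group (non-empty, within
#'   context).
#' @param context selector/expression for the atoms present during the
#'   calculation (default NULL: whole structure).
#' @inheritParams sasa
#' @return total area of the group, Angstrom^2.
#' @export
group_sasa <- function(s, sel, context = NULL, probe = 1.4,
                       n_dots = 960, vdw_override = NULL) {
  ictx <- select_atoms(s, context)
  isel <- select_atoms(s, sel)
  if (length(isel) == 0) stop("group_sasa: empty selection")
  if (!all(isel %in% ictx))
    stop("group_sasa: selection not contained in context")
  sub <- .new_structure(as.data.frame(s)[ictx, , drop = FALSE],
                        attr(s, "source"))
  a <- sasa(sub, probe, n_dots, vdw_override)
  sum(a[match(isel, ictx)])
}

#' Buried area of a group
#'
#' The SASA the group loses upon incorporation: its SASA computed in
#' isolation minus its SASA within the full structure. Non-negative up
#' to lattice tolerance.
#'
#' @param s a `structure3d`.
#' @param group selector/expression for the group.
#' @inheritParams sasa
#' @return buried area, Angstrom^2.
#' @export
buried_area <- function(s, group, probe = 1.4, n_dots = 960,
                        vdw_override = NULL) {
  idx <- select_atoms(s, group)
  if (length(idx) == 0) stop("buried_area: empty group")
  alone <- .new_structure(as.data.frame(s)[idx, , drop = FALSE],
                          attr(s, "source"))
  sum(sasa(alone, probe, n_dots, vdw_override)) -
    group_sasa(s, group, NULL, probe, n_dots, vdw_override)
}

#' Minimum distance between two atom groups
#'
#' @param s a `structure3d`.
#' @param selA,selB selectors/expressions, both non-empty.
#' @return list with `distance` (Angstrom) and `pair` (two-row
#'   data.frame of the arg-min atoms).
#' @export
min_group_distance <- function(s, selA, selB) {
  ia <- select_atoms(s, selA); ib <- select_atoms(s, selB)
  if (length(ia) == 0 || length(ib) == 0)
    stop("min_group_distance: empty selection")
  pa <- .coords(s, ia); pb <- .coords(s, ib)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  k <- arrayInd(which.min(d2), dim(d2))
  list(distance = sqrt(max(0, d2[k])),
       pair = as.data.frame(s)[c(ia[k[1]], ib[k[2]]), , drop = FALSE])
}

#' Percent B-factor difference between two structures over a selection
#'
#' `100 * (mean_B(a) - mean_B(b)) / mean_B(b)`, with the mean taken over
#' all atoms of the selected residues in each structure.
#'
#' @param a,b `structure3d` objects.
#' @param sel selector/expression resolvable in both structures.
#' @return percent difference (positive when `a` is higher).
#' @export
bfactor_group_percent_diff <- function(a, b, sel) {
  ia <- select_atoms(a, sel); ib <- select_atoms(b, sel)
  if (length(ia) == 0 || length(ib) == 0)
    stop("bfactor_group_percent_diff: empty selection")
  ma <- mean(a$b_factor[ia]); mb <- mean(b$b_factor[ib])
  100 * (ma - mb) / mb
}

#' Van der Waals clash scan between two structures
#'
#' Reports every cross pair of heavy atoms whose van der Waals overlap
#' `(r_A + r_B) - distance` exceeds `overlap_threshold`, sorted by
#' overlap descending. The structures must already share a frame (apply
#' a [kabsch_superpose()] fit first if needed).
#'
#' @param a,b `structure3d` objects in a common frame.
#' @param overlap_threshold Angstrom (default 0.4, a common strong-
#'   contact criterion).
#' @param vdw_override named per-element radius overrides.
#' @return data.frame with one row per clash: atom descriptors for both
#'   partners, `distance` and `overlap` (Angstrom).
#' @export
clash_scan <- function(a, b, overlap_threshold = 0.4,
                       vdw_override = NULL) {
  ha <- which(a$element != "H"); hb <- which(b$element != "H")
  desc <- function(s, i) sprintf("%s/%s%d/%s", s$chain_id[i],
                                 s$residue_name[i], s$residue_number[i],
                                 s$atom_name[i])
  empty <- data.frame(atom_a = character(0), atom_b = character(0),
                      distance = numeric(0), overlap = numeric(0))
  if (!length(ha) || !length(hb)) return(empty)
  ra <- .vdw_radii(a$element[ha], vdw_override)
  rb <- .vdw_radii(b$element[hb], vdw_override)
  pa <- .coords(a, ha); pb <- .coords(b, hb)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d <- sqrt(pmax(d2, 0))   # pmax(d2, .) keeps the matrix dim
  ov <- outer(ra, rb, "+") - d
  hit <- which(ov > overlap_threshold, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  out <- data.frame(
    atom_a = desc(a, ha[hit[, 1]]),
    atom_b = desc(b, hb[hit[, 2]]),
    distance = d[hit], overlap = ov[hit])
  out[order(-out$overlap), , drop = FALSE]
}

# ring atom names used for aromatic plane fits
.ring_atoms <- list(
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

# terminal heavy atom per residue type for vector-mode rotation
.terminal_atoms <- c(
  LYS = "NZ", ARG = "CZ", GLU = "CD", GLN = "CD", ASP = "CG",
  ASN = "CG", MET = "CE", CYS = "SG", SER = "OG", THR = "OG1",
  VAL = "CG1", LEU = "CG", ILE = "CD1", PRO = "CG")

.plane_normal <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(c0)
  sv$v[, 3]
}

#' Rotation angle of a side chain between two models
#'
#' Measures how much a residue's side chain has rotated between two
#' structures after their backbones are brought into a common frame.
#' For aromatic residues (or when `mode = "plane"`) the angle between
#' best-fit ring-plane normals is returned, folded into [0, 90] degrees;
#' otherwise the angle between the CB-to-terminal-heavy-atom vectors,
#' in [0, 180] degrees.
#'
#' @param resA,resB `structure3d` objects (or subsets) containing one
#'   residue each with shared atom names.
#' @param frame a `superposition` mapping `resA`'s frame onto `resB`'s,
#'   or NULL when they already share a frame.
#' @param mode `"auto"`, `"plane"` or `"vector"`.
#' @return rotation angle in degrees.
#' @export
sidechain_rotation <- function(resA, resB, frame = NULL,
                               mode = c("auto", "plane", "vector")) {
  mode <- match.arg(mode)
  if (!is.null(frame)) resA <- apply_superposition(resA, frame)
  resn <- resB$residue_name[1]
  if (mode == "auto")
    mode <- if (resn %in% names(.ring_atoms)) "plane" else "vector"
  get_xyz <- function(s, names) {
    i <- match(names, s$atom_name)
    if (any(is.na(i))) return(NULL)
    .coords(s, i)
  }
  if (mode == "plane") {
    ring <- .ring_atoms[[resn]]
    if (is.null(ring)) ring <- intersect(resA$atom_name, resB$atom_name)
    xa <- get_xyz(resA, ring); xb <- get_xyz(resB, ring)
    if (is.null(xa) || is.null(xb) || nrow(xa) < 3)
      stop("sidechain_rotation: need >= 3 shared ring atoms for a ",
           "plane fit", call. = FALSE)
    na <- .plane_normal(xa); nb <- .plane_normal(xb)
    cosang <- abs(sum(na * nb))
    return(acos(pmin(1, cosang)) * 180 / pi)
  }
  term <- .terminal_atoms[[resn]]
  if (is.null(term) || is.na(term)) {
    sc <- setdiff(intersect(resA$atom_name, resB$atom_name),
                  c(.backbone_names, "CB"))
    if (!length(sc))
      stop("sidechain_rotation: no terminal side-chain atom", call. = FALSE)
    term <- sc[length(sc)]
  }
  va <- get_xyz(resA, c("CB", term)); vb <- get_xyz(resB, c("CB", term))
  if (is.null(va) || is.null(vb))
    stop("sidechain_rotation: CB/terminal atom missing", call. = FALSE)
  da <- va[2, ] - va[1, ]; db <- vb[2, ] - vb[1, ]
  cosang <- sum(da * db) / sqrt(sum(da^2) * sum(db^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}
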