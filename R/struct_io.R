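# Atomic-model reading (PDB and mmCIF) and atom selection.
#
# A structure is a data.frame of atoms; only the fields the metrics need
# are kept: element, atom name, residue name/number, chain, xyz
# (Angstrom), B-factor, occupancy. Altloc duplicates are resolved to
# the highest-occupancy conformer at parse time.

.backbone_names <- c("N", "CA", "C", "O", "OXT")

.new_structure <- function(df, source = "in-memory") {
  need <- c("element", "atom_name", "residue_name", "residue_number",
            "chain_id", "x", "y", "z", "b_factor", "occupancy")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("structure: missing field(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)[need]
  df$residue_number <- as.integer(df$residue_number)
  for (f in c("x", "y", "z", "b_factor", "occupancy"))
    df[[f]] <- as.numeric(df[[f]])
  if (any(!is.finite(as.matrix(df[c("x", "y", "z")]))))
    stop("structure: non-finite coordinates")
  attr(df, "source") <- source
  class(df) <- c("structure3d", "data.frame")
  df
}

#' Build a structure from atom fields
#'
#' @param df data.frame with `element`, `atom_name`, `residue_name`,
#'   `residue_number`, `chain_id`, `x`, `y`, `z`, and optionally
#'   `b_factor` (default 0) and `occupancy` (default 1).
#' @param source provenance label.
#' @return object of class `structure3d`.
#' @export
structure3d <- function(df, source = "in-memory") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$b_factor)) df$b_factor <- 0
  if (is.null(df$occupancy)) df$occupancy <- 1
  .new_structure(df, source)
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %d atoms, %d chain(s), source: %s\n",
              nrow(x), length(unique(x$chain_id)), attr(x, "source")))
  invisible(x)
}

# resolve altlocs: keep the highest-occupancy conformer per atom site
# (ties: first in file order)
.resolve_altlocs <- function(df, altloc) {
  key <- paste(df$chain_id, df$residue_number, df$residue_name,
               df$atom_name, sep = "\r")
  has_alt <- !altloc %in% c("", " ", ".", "?")
  if (!any(has_alt & duplicated(key) | has_alt & duplicated(key, fromLast = TRUE)))
    return(df)
  keep <- rep(TRUE, nrow(df))
  for (g in split(seq_len(nrow(df)), key)) {
    if (length(g) > 1) {
      best <- g[which.max(df$occupancy[g])]
      keep[setdiff(g, best)] <- FALSE
    }
  }
  df[keep, , drop = FALSE]
}

.read_pdb <- function(lines, path) {
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("read_structure: no ATOM/HETATM records in ", path)
  ln <- lines[sel]
  fw <- function(a, b) trimws(substr(ln, a, b))
  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(fw(a, b)))
    bad <- which(is.na(v) & fw(a, b) != "")
    if (length(bad))
      stop("read_structure: malformed ", what, " in ATOM record ",
           bad[1], " of ", path, call. = FALSE)
    v
  }
  elem <- fw(77, 78)
  # fall back to the atom-name field when the element column is absent
  guess <- sub("^[0-9]*", "", fw(13, 16))
  elem <- ifelse(elem == "", substr(guess, 1, 1), elem)
  occ <- num(55, 60, "occupancy"); occ[is.na(occ)] <- 1
  bf <- num(61, 66, "B-factor"); bf[is.na(bf)] <- 0
  df <- data.frame(
    element = toupper(elem),
    atom_name = fw(13, 16),
    residue_name = fw(18, 20),
    residue_number = as.integer(num(23, 26, "residue number")),
    chain_id = fw(22, 22),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    b_factor = bf, occupancy = occ,
    stringsAsFactors = FALSE)
  .resolve_altlocs(df, fw(17, 17))
}

.read_mmcif <- function(lines, path) {
  loop <- .star_read_loop(lines,
    want = function(tags) any(grepl("^_atom_site\\.", tags)))
  if (is.null(loop))
    stop("read_structure: no _atom_site loop in ", path)
  m <- loop$rows
  colnames(m) <- sub("^_atom_site\\.", "", colnames(m))
  col <- function(opts, default = NULL) {
    hit <- intersect(opts, colnames(m))
    if (length(hit)) m[, hit[1]]
    else if (!is.null(default)) rep(default, nrow(m))
    else stop("read_structure: mmCIF lacks column ", opts[1], " in ",
              path, call. = FALSE)
  }
  numcol <- function(opts, default = NULL) {
    v <- col(opts, default)
    out <- suppressWarnings(as.numeric(v))
    out[v %in% c(".", "?")] <- NA
    out
  }
  df <- data.frame(
    element = toupper(col(c("type_symbol"))),
    atom_name = col(c("auth_atom_id", "label_atom_id")),
    residue_name = col(c("auth_comp_id", "label_comp_id")),
    residue_number = as.integer(numcol(c("auth_seq_id", "label_seq_id"))),
    chain_id = col(c("auth_asym_id", "label_asym_id")),
    x = numcol("Cartn_x"), y = numcol("Cartn_y"), z = numcol("Cartn_z"),
    b_factor = numcol("B_iso_or_equiv", 0),
    occupancy = numcol("occupancy", 1),
    stringsAsFactors = FALSE)
  df$b_factor[is.na(df$b_factor)] <- 0
  df$occupancy[is.na(df$occupancy)] <- 1
  .resolve_altlocs(df, col(c("label_alt_id"), "."))
}

#' Read an atomic model from PDB or mmCIF
#'
#' Format is auto-detected from the extension (`.cif`/`.mmcif` vs
#' anything else) and, failing that, from the content. All ATOM and
#' HETATM records are parsed; for alternate-location duplicates the
#' highest-occupancy conformer is kept.
#'
#' @param path path to a PDB or mmCIF file.
#' @return a `structure3d`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("read_structure: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE) ||
    (!any(grepl("^(ATOM  |HETATM)", lines)) &&
       any(grepl("^_atom_site\\.", lines)))
  df <- if (is_cif) .read_mmcif(lines, path) else .read_pdb(lines, path)
  .new_structure(df, source = path)
}

# -- selections ------------------------------------------------------------

#' Atom selector
#'
#' Conjunctive atom selection: an atom matches when it satisfies every
#' non-NULL criterion.
#'
#' @param chain character vector of chain ids, or NULL (any).
#' @param resi integer vector of residue numbers, or NULL.
#' @param resn character vector of residue names, or NULL.
#' @param name character vector of atom names, or NULL.
#' @param elem character vector of element symbols, or NULL.
#' @param part `"any"`, `"sidechain"` (non-backbone heavy atoms;
#'   backbone = N, CA, C, O, OXT) or `"backbone"`.
#' @return a `selector`.
#' @export
selector <- function(chain = NULL, resi = NULL, resn = NULL, name = NULL,
                     elem = NULL, part = c("any", "sidechain", "backbone")) {
  part <- match.arg(part)
  structure(list(chain = chain, resi = resi, resn = resn, name = name,
                 elem = if (is.null(elem)) NULL else toupper(elem),
                 part = part),
            class = "selector")
}

#' Parse a text selection expression
#'
#' Accepts conjunctions of clauses joined by `and`:
#' `chain A`, `resi 373-375` (ranges and comma lists), `resn PYA`,
#' `name CA+CB` (or comma lists), `elem S`, `sidechain`, `backbone`.
#' Example: `"chain A and resi 373-375 and sidechain"`.
#'
#' @param text selection expression.
#' @return a `selector`.
#' @export
parse_selection <- function(text) {
  clauses <- strsplit(trimws(text), "\\s+and\\s+")[[1]]
  sel <- selector()
  split_list <- function(v) unlist(strsplit(v, "[+,]"))
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    kw <- tolower(toks[1])
    arg <- if (length(toks) > 1) paste(toks[-1], collapse = "") else ""
    if (kw == "chain") sel$chain <- split_list(arg)
    else if (kw == "resi") {
      parts <- split_list(arg)
      sel$resi <- unlist(lapply(parts, function(p) {
        r <- as.integer(strsplit(p, "-")[[1]])
        if (length(r) == 2) seq(r[1], r[2]) else r
      }))
    }
    else if (kw == "resn") sel$resn <- split_list(arg)
    else if (kw == "name") sel$name <- split_list(arg)
    else if (kw == "elem") sel$elem <- toupper(split_list(arg))
    else if (kw == "sidechain") sel$part <- "sidechain"
    else if (kw == "backbone") sel$part <- "backbone"
    else stop("parse_selection: unknown clause: ", cl, call. = FALSE)
  }
  sel
}

#' Resolve a selector to atom indices
#'
#' @param s a `structure3d`.
#' @param sel a `selector`, a selection expression string, or NULL
#'   (all atoms).
#' @return integer vector of row indices of `s`.
#' @export
select_atoms <- function(s, sel = NULL) {
  stopifnot(inherits(s, "structure3d"))
  if (is.null(sel)) return(seq_len(nrow(s)))
  if (is.character(sel)) sel <- parse_selection(sel)
  keep <- rep(TRUE, nrow(s))
  if (!is.null(sel$chain)) keep <- keep & s$chain_id %in% sel$chain
  if (!is.null(sel$resi)) keep <- keep & s$residue_number %in% sel$resi
  if (!is.null(sel$resn)) keep <- keep & s$residue_name %in% sel$resn
  if (!is.null(sel$name)) keep <- keep & s$atom_name %in% sel$name
  if (!is.null(sel$elem)) keep <- keep & s$element %in% sel$elem
  if (sel$part == "sidechain")
    keep <- keep & !(s$atom_name %in% .backbone_names) & s$element != "H"
  if (sel$part == "backbone")
    keep <- keep & s$atom_name %in% .backbone_names
  which(keep)
}

# coordinates of selected atoms as an n x 3 matrix
.coords <- function(s, idx = seq_len(nrow(s)))
  unname(as.matrix(s[idx, c("x", "y", "z")]))
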