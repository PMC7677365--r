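# STAR particle-table I/O (RELION column dialect).
#
# A particle set is a data.frame with canonical numeric columns plus
# verbatim passthrough columns for everything the curation math does not
# touch, so that writing a curated table never destroys refinement
# metadata.

# canonical field -> STAR tag used on output
.star_out_tags <- c(
  micrograph_id = "_rlnMicrographName",
  tube_id       = "_rlnHelicalTubeID",
  coord_x       = "_rlnCoordinateX",
  coord_y       = "_rlnCoordinateY",
  rot           = "_rlnAngleRot",
  tilt          = "_rlnAngleTilt",
  psi           = "_rlnAnglePsi",
  origin_x      = "_rlnOriginXAngst",
  origin_y      = "_rlnOriginYAngst",
  defocus_u     = "_rlnDefocusU",
  defocus_v     = "_rlnDefocusV",
  defocus_angle = "_rlnDefocusAngle",
  pixel_size    = "_rlnImagePixelSize"
)

# accepted input tags per canonical field (first match wins)
.star_in_tags <- list(
  micrograph_id = "_rlnMicrographName",
  tube_id       = "_rlnHelicalTubeID",
  coord_x       = "_rlnCoordinateX",
  coord_y       = "_rlnCoordinateY",
  rot           = "_rlnAngleRot",
  tilt          = "_rlnAngleTilt",
  psi           = "_rlnAnglePsi",
  origin_x      = c("_rlnOriginXAngst", "_rlnOriginX"),
  origin_y      = c("_rlnOriginYAngst", "_rlnOriginY"),
  defocus_u     = "_rlnDefocusU",
  defocus_v     = "_rlnDefocusV",
  defocus_angle = "_rlnDefocusAngle",
  pixel_size    = c("_rlnImagePixelSize", "_rlnPixelSize",
                    "_rlnDetectorPixelSize")
)

.star_required <- c("micrograph_id", "tube_id", "coord_x", "coord_y",
                    "psi", "defocus_u")

#' Construct a particle set
#'
#' Builds the canonical in-memory table of helical segment metadata used
#' by all curation operations. Missing optional fields receive neutral
#' defaults (tilt 90 deg, rot 0, origins 0, `defocus_v = defocus_u`,
#' astigmatism angle 0).
#'
#' @param df data.frame with at least `micrograph_id`, `tube_id`,
#'   `coord_x`, `coord_y`, `psi`, `defocus_u`; optionally `tilt`, `rot`,
#'   `origin_x`, `origin_y` (Angstrom, subtractive convention),
#'   `defocus_v`, `defocus_angle`, `pixel_size` (Angstrom/pixel).
#' @param extra data.frame of verbatim passthrough columns (same row
#'   count), or `NULL`.
#' @param provenance character note on where the records came from.
#' @return object of class `particle_set` (a data.frame).
#' @export
particle_set <- function(df, extra = NULL, provenance = "in-memory") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  miss <- setdiff(.star_required, names(df))
  if (length(miss))
    stop("particle_set: missing required field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(df)
  defaults <- list(tilt = 90, rot = 0, origin_x = 0, origin_y = 0,
                   defocus_angle = 0, pixel_size = NA_real_)
  for (f in names(defaults))
    if (is.null(df[[f]])) df[[f]] <- rep(defaults[[f]], n)
  if (is.null(df[["defocus_v"]])) df$defocus_v <- df$defocus_u
  num_fields <- setdiff(names(.star_out_tags), "micrograph_id")
  for (f in num_fields) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- which(is.na(v) & !is.na(df[[f]]))
    if (length(bad))
      stop("particle_set: malformed numeric value in '", f,
           "' at row ", bad[1], call. = FALSE)
    df[[f]] <- v
  }
  df$micrograph_id <- as.character(df$micrograph_id)
  df$tube_id <- as.integer(round(df$tube_id))
  if (any(df$tube_id < 1L)) stop("particle_set: tube_id must be >= 1")
  if (any(!is.na(df$defocus_u) & df$defocus_u <= 0) ||
      any(!is.na(df$defocus_v) & df$defocus_v <= 0))
    stop("particle_set: defocus values must be positive")
  if (any(!is.na(df$pixel_size) & df$pixel_size <= 0))
    stop("particle_set: pixel_size must be positive")
  key <- paste(df$micrograph_id, df$tube_id, df$coord_x, df$coord_y)
  if (anyDuplicated(key))
    stop("particle_set: duplicate (micrograph, tube, x, y) record at row ",
         which(duplicated(key))[1], call. = FALSE)
  out <- df[names(.star_out_tags)]
  if (!is.null(extra)) {
    extra <- as.data.frame(extra, stringsAsFactors = FALSE)
    stopifnot(nrow(extra) == n || n == 0)
    for (nm in names(extra)) extra[[nm]] <- as.character(extra[[nm]])
  } else {
    extra <- data.frame(row.names = seq_len(n))
  }
  attr(out, "extra") <- extra
  attr(out, "provenance") <- provenance
  class(out) <- c("particle_set", "data.frame")
  out
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles, %d micrograph(s), %d passthrough column(s)\n",
              nrow(x), length(unique(x$micrograph_id)),
              ncol(attr(x, "extra"))))
  cat("provenance:", attr(x, "provenance"), "\n")
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Verbatim passthrough columns of a particle set
#' @param set a `particle_set`.
#' @return data.frame of character columns named by their STAR tags.
#' @export
particle_extra <- function(set) attr(set, "extra")

# -- low-level STAR loop parsing ------------------------------------------

# Split one STAR/CIF data line into tokens, honouring single/double quotes.
.star_tokens <- function(line) {
  out <- character(0)
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      out <- c(out, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L))
      i <- j
    }
  }
  out
}

# Parse the first loop_ block whose tags satisfy `want` (predicate on the
# character vector of tags). Returns list(tags=, rows=character matrix).
.star_read_loop <- function(lines, want = function(tags) TRUE) {
  i <- 1L; n <- length(lines)
  strip <- function(x) sub("\\s+$", "", sub("^\\s+", "", x))
  while (i <= n) {
    if (strip(lines[i]) == "loop_") {
      j <- i + 1L
      tags <- character(0)
      while (j <= n && grepl("^\\s*_", lines[j])) {
        tag <- .star_tokens(strip(lines[j]))[1]
        tag <- sub("\\s*#.*$", "", tag)
        tags <- c(tags, tag)
        j <- j + 1L
      }
      rows <- list()
      while (j <= n) {
        ln <- strip(lines[j])
        if (ln == "" || grepl("^#", ln)) { j <- j + 1L; next }
        if (grepl("^(data_|loop_|_)", ln)) break
        toks <- .star_tokens(ln)
        if (length(toks) != length(tags))
          stop("STAR parse error: row ", length(rows) + 1L,
               " has ", length(toks), " value(s), expected ",
               length(tags), call. = FALSE)
        rows[[length(rows) + 1L]] <- toks
        j <- j + 1L
      }
      if (want(tags)) {
        m <- if (length(rows)) do.call(rbind, rows)
             else matrix(character(0), 0, length(tags))
        colnames(m) <- tags
        return(list(tags = tags, rows = m))
      }
      i <- j
    } else i <- i + 1L
  }
  NULL
}

#' Read a STAR particle table
#'
#' Parses the first particle loop of a RELION-dialect STAR file into a
#' [particle_set()]. Origin shifts given in pixels
#' (`_rlnOriginX`/`_rlnOriginY`) are converted to Angstrom using the
#' pixel size; the dialect seen is recorded in the provenance string.
#' Columns not used by the curation math are preserved verbatim and
#' re-emitted by [write_particles()].
#'
#' @param path path to a STAR file containing one particle loop.
#' @param pixel_size fallback Angstrom/pixel value used when the table
#'   carries no pixel-size column (default `NA`: left unknown).
#' @return a `particle_set`.
#' @export
read_particles <- function(path, pixel_size = NA_real_) {
  if (!file.exists(path)) stop("read_particles: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  loop <- .star_read_loop(lines,
    want = function(tags) "_rlnCoordinateX" %in% tags)
  if (is.null(loop))
    loop <- .star_read_loop(lines)
  if (is.null(loop))
    stop("read_particles: no particle loop found in ", path)
  tags <- loop$tags
  m <- loop$rows

  pick <- function(field) {
    hit <- intersect(.star_in_tags[[field]], tags)
    if (length(hit)) hit[1] else NA_character_
  }
  used <- character(0)
  df <- list()
  for (f in names(.star_in_tags)) {
    tag <- pick(f)
    if (is.na(tag)) next
    used <- c(used, tag)
    df[[f]] <- m[, tag]
  }
  miss <- setdiff(.star_required, names(df))
  if (length(miss)) {
    stop("read_particles: required column(s) missing: ",
         paste(vapply(miss, function(f) .star_in_tags[[f]][1], ""),
               collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  numf <- setdiff(names(df), "micrograph_id")
  for (f in numf) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("read_particles: malformed numeric cell in column '", pick(f),
           "', row ", bad[1], call. = FALSE)
    df[[f]] <- v
  }

  origin_dialect <- "angstrom"
  if (!is.na(pick("origin_x")) && pick("origin_x") == "_rlnOriginX") {
    origin_dialect <- "pixel"
    px <- if (!is.null(df$pixel_size)) df$pixel_size else pixel_size
    if (any(is.na(px)))
      stop("read_particles: pixel-valued origins need a pixel size ",
           "(column or pixel_size= argument)", call. = FALSE)
    df$origin_x <- df$origin_x * px
    df$origin_y <- if (!is.null(df$origin_y)) df$origin_y * px else 0
  }
  if (is.null(df$pixel_size) && !is.na(pixel_size))
    df$pixel_size <- rep(pixel_size, nrow(df))

  extra_tags <- setdiff(tags, used)
  extra <- as.data.frame(m[, extra_tags, drop = FALSE],
                         stringsAsFactors = FALSE)
  particle_set(df, extra = extra,
               provenance = sprintf("%s (origins: %s dialect)",
                                    path, origin_dialect))
}

.star_fmt_num <- function(x) {
  # fixed 6-decimal formatting: deterministic and round-trips the
  # Angstrom/degree magnitudes used here well beyond 6 significant digits
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 6))
}

#' Write a STAR particle table
#'
#' Emits one `data_particles` loop. Canonical columns are written under
#' their RELION names (origins in Angstrom), followed by the passthrough
#' columns byte-for-byte as read. Output is deterministic: a
#' write/read/write cycle reproduces the file exactly.
#'
#' @param set a non-empty `particle_set`.
#' @param path output path.
#' @export
write_particles <- function(set, path) {
  stopifnot(inherits(set, "particle_set"))
  if (nrow(set) == 0)
    stop("write_particles: refusing to write an empty particle set")
  extra <- particle_extra(set)
  fields <- names(.star_out_tags)
  if (all(is.na(set$pixel_size))) fields <- setdiff(fields, "pixel_size")
  cols <- lapply(fields, function(f) {
    if (f == "micrograph_id") set[[f]]
    else if (f == "tube_id") as.character(set[[f]])
    else .star_fmt_num(set[[f]])
  })
  names(cols) <- fields
  tags <- unname(.star_out_tags[fields])
  if (ncol(extra)) {
    tags <- c(tags, names(extra))
    cols <- c(cols, as.list(extra))
  }
  body <- do.call(paste, c(unname(cols), list(sep = "\t")))
  hdr <- c("", "data_particles", "", "loop_",
           sprintf("%s #%d", tags, seq_along(tags)))
  ok <- tryCatch({
    suppressWarnings(writeLines(c(hdr, body, ""), path))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("write_particles: cannot write ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}
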