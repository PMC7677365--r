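# Filament grouping, ordering, polarity checks and segment windowing.

#' Group particles into filaments
#'
#' Partitions a particle set by `(micrograph_id, tube_id)` and orders
#' each filament's particles along its axis. The ordering axis is the
#' principal axis of the segment coordinate cloud (robust to polarity
#' flips in psi), oriented so the first-listed particle projects lowest;
#' equal projections are tie-broken by `coord_x` then `coord_y`.
#'
#' @param set a `particle_set`.
#' @return list of `filament` objects; each is a list with
#'   `micrograph_id`, `tube_id`, `particles` (data.frame of records in
#'   axial order), `row_idx` (rows of `set`), `order_axis` (unit
#'   2-vector), `consistent` (logical, filled by
#'   [check_polarity_consistency()], initially all `TRUE`).
#' @export
group_filaments <- function(set) {
  stopifnot(inherits(set, "particle_set"))
  key <- paste(set$micrograph_id, set$tube_id, sep = "\r")
  idx <- split(seq_len(nrow(set)), factor(key, levels = unique(key)))
  lapply(idx, function(rows) {
    p <- as.data.frame(set)[rows, , drop = FALSE]
    if (anyDuplicated(paste(p$coord_x, p$coord_y)))
      stop("group_filaments: duplicate coordinates within tube ",
           p$tube_id[1], " of ", p$micrograph_id[1], call. = FALSE)
    xy <- cbind(p$coord_x, p$coord_y)
    if (nrow(xy) > 1) {
      c0 <- sweep(xy, 2, colMeans(xy))
      ax <- eigen(crossprod(c0), symmetric = TRUE)$vectors[, 1]
      proj <- drop(c0 %*% ax)
      # orient axis so the first-listed particle sits at the low end
      if (proj[1] > (min(proj) + max(proj)) / 2) {
        ax <- -ax; proj <- -proj
      }
      ord <- order(proj, p$coord_x, p$coord_y)
    } else {
      ax <- c(1, 0)
      ord <- 1L
    }
    f <- list(micrograph_id = p$micrograph_id[1],
              tube_id = p$tube_id[1],
              particles = p[ord, , drop = FALSE],
              row_idx = rows[ord],
              order_axis = as.numeric(ax),
              consistent = rep(TRUE, nrow(p)),
              inconsistent_reason = rep("none", nrow(p)))
    class(f) <- "filament"
    f
  }) |> unname()
}

#' @export
print.filament <- function(x, ...) {
  cat(sprintf("<filament> %s tube %d: %d particle(s), %.1f%% consistent\n",
              x$micrograph_id, x$tube_id, nrow(x$particles),
              100 * mean(x$consistent)))
  invisible(x)
}

# circular median of angles in degrees: the data point minimising the
# summed absolute wrapped deviation (deterministic: first minimiser)
.circ_median <- function(deg) {
  if (length(deg) == 1) return(deg)
  cost <- vapply(deg, function(c0) sum(abs(wrap_angle(deg - c0))), 0)
  deg[which.min(cost)]
}

#' Flag polarity-inconsistent particles in a filament
#'
#' A particle is consistent when its in-plane angle psi lies within
#' `psi_tol` of the filament's circular-median psi (after wrapping to
#' (-180, 180]) and its tilt is within `tilt_tol` of 90 degrees (helical
#' segments refine near tilt 90). A psi deviation within `psi_tol` of
#' 180 degrees is a polarity flip. Reasons recorded per particle:
#' `"flip"`, `"psi"`, `"tilt"`, or `"none"`.
#'
#' @param f a `filament`.
#' @param psi_tol tolerance on psi deviation, degrees in (0, 90).
#' @param tilt_tol tolerance on |tilt - 90|, degrees.
#' @return `f` with `consistent`/`inconsistent_reason` filled and
#'   `fraction_consistent` added; singleton filaments return fraction 1
#'   with a warning code in `f$warning`.
#' @export
check_polarity_consistency <- function(f, psi_tol = 15, tilt_tol = 30) {
  stopifnot(inherits(f, "filament"), psi_tol > 0, psi_tol < 90)
  n <- nrow(f$particles)
  if (n < 2) {
    f$consistent <- rep(TRUE, n)
    f$inconsistent_reason <- rep("none", n)
    f$fraction_consistent <- 1.0
    f$warning <- "singleton"
    return(f)
  }
  psi <- f$particles$psi
  med <- .circ_median(psi)
  dev <- abs(wrap_angle(psi - med))
  flip <- dev >= 180 - psi_tol
  bad_psi <- dev > psi_tol & !flip
  bad_tilt <- abs(f$particles$tilt - 90) > tilt_tol
  reason <- rep("none", n)
  reason[bad_tilt] <- "tilt"
  reason[bad_psi] <- "psi"
  reason[flip] <- "flip"
  f$consistent <- reason == "none"
  f$inconsistent_reason <- reason
  f$fraction_consistent <- mean(f$consistent)
  f
}

#' Build a filament trace
#'
#' @param polyline two-column matrix of 2D points (pixels), >= 2 points.
#' @param micrograph_id label.
#' @param width,height micrograph dimensions in pixels.
#' @return a `filament_trace`.
#' @export
filament_trace <- function(polyline, micrograph_id = "mic",
                           width = Inf, height = Inf) {
  polyline <- as.matrix(polyline)
  stopifnot(ncol(polyline) == 2, nrow(polyline) >= 2)
  seg <- diff(polyline)
  len <- sqrt(rowSums(seg^2))
  if (sum(len) <= 0) stop("filament_trace: zero arc length")
  structure(list(micrograph_id = micrograph_id, polyline = polyline,
                 seg_len = len, arc = c(0, cumsum(len)),
                 width = width, height = height),
            class = "filament_trace")
}

# point at arc position s on a piecewise-linear trace
.trace_point <- function(trace, s) {
  arc <- trace$arc
  k <- findInterval(s, arc, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), length(arc) - 1L)
  t <- (s - arc[k]) / trace$seg_len[k]
  p0 <- trace$polyline[k, , drop = FALSE]
  p1 <- trace$polyline[k + 1L, , drop = FALSE]
  p0 + (p1 - p0) * t
}

#' Window a filament trace into overlapping segment boxes
#'
#' Places square extraction boxes along the trace: centers at arc
#' positions `box_px/2 + k * step_px` for k = 0, 1, ... while the center
#' stays at least `box_px/2` from the trace end. Centers whose
#' axis-aligned box would extend beyond the micrograph bounds are
#' dropped. With a 328-pixel box stepped by one 26-pixel subunit each
#' box covers 12 whole subunit steps.
#'
#' @param trace a `filament_trace`.
#' @param box_px box side, pixels.
#' @param step_px translation per segment, pixels.
#' @return matrix of center coordinates (pixels), possibly 0-row; a
#'   trace shorter than `box_px` yields an empty result with a warning.
#' @export
window_filament <- function(trace, box_px, step_px) {
  stopifnot(inherits(trace, "filament_trace"), box_px > 0, step_px > 0)
  if (box_px > min(trace$width, trace$height))
    stop("window_filament: box larger than micrograph")
  total <- trace$arc[length(trace$arc)]
  if (total < box_px) {
    warning("window_filament: trace shorter than box; no segments")
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("x", "y"))))
  }
  s <- seq(box_px / 2, total - box_px / 2 + 1e-9, by = step_px)
  centers <- .trace_point(trace, s)
  half <- box_px / 2
  ok <- centers[, 1] - half >= 0 & centers[, 1] + half <= trace$width &
        centers[, 2] - half >= 0 & centers[, 2] + half <= trace$height
  centers <- centers[ok, , drop = FALSE]
  colnames(centers) <- c("x", "y")
  centers
}

#' Whole subunit steps spanned by one segment box
#'
#' @param box_px box side in pixels.
#' @param step_px subunit step in pixels.
#' @return integer `floor(box_px / step_px)`.
#' @export
subunits_per_box <- function(box_px, step_px) {
  stopifnot(box_px > 0, step_px > 0)
  as.integer(floor(box_px / step_px))
}
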