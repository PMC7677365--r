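# Per-filament defocus smoothing by min/max-trimmed local regression.
#
# Defocus estimated per segment is noisy, but a filament is a continuous
# object, so its true local defocus must vary smoothly along the tube.
# Each particle's mean defocus is re-fitted from the five consecutive
# filament positions centred on it: the single highest and single lowest
# values in the window are discarded and an ordinary least-squares line
# through the remaining three is evaluated at the particle's own arc
# position. Astigmatism (defocus_u - defocus_v, and the angle) is
# preserved exactly.

#' Min/max-trimmed least-squares line fit
#'
#' Removes exactly one maximum-value and one minimum-value point (by
#' value, not abscissa; ties remove the later-indexed point) and fits an
#' ordinary least-squares line through the remainder. If all values are
#' identical the line is flat at that value.
#'
#' @param x abscissas (length >= 5, not all identical).
#' @param y values, same length.
#' @return list with `slope` and `intercept`.
#' @export
trimmed_linefit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5)
    stop("trimmed_linefit: need at least 5 points")
  if (diff(range(y)) == 0)
    return(list(slope = 0, intercept = y[1]))
  # later-indexed tie-break: last index attaining the extreme
  i_max <- max(which(y == max(y)))
  i_min <- max(which(y[-i_max] == min(y[-i_max])))
  i_min <- seq_along(y)[-i_max][i_min]
  keep <- setdiff(seq_along(y), c(i_max, i_min))
  xs <- x[keep]; ys <- y[keep]
  if (diff(range(xs)) == 0)
    stop("trimmed_linefit: abscissas of retained points are identical")
  b <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  a <- mean(ys) - b * mean(xs)
  list(slope = b, intercept = a)
}

#' Smooth defocus along one filament
#'
#' Applies the trimmed-regression smoother to every particle of an
#' ordered filament. The abscissa is the particle's arc position along
#' the filament in Angstrom (cumulative distance between segment
#' centres, `coord * pixel_size`); for the evenly spaced segments
#' produced by windowed extraction this is an affine function of the
#' particle index. Windows are clamped at filament ends, so the two
#' terminal particles are extrapolated from the terminal window.
#' Filaments with fewer than `window` particles are returned unchanged.
#'
#' @param f a `filament` (particles in axial order).
#' @param window window size; must be odd and equal to 5 (the trimmed
#'   fit removes one extreme each side and needs 3 survivors).
#' @return list with `defocus_u`, `defocus_v` (smoothed, Angstrom),
#'   `windows` (list of index vectors), `changed` (logical), `skipped`
#'   (TRUE when the filament was below window size).
#' @export
smooth_filament_ctf <- function(f, window = 5) {
  stopifnot(inherits(f, "filament"))
  if (window %% 2 != 1 || window < 5)
    stop("smooth_filament_ctf: window must be odd and >= 5")
  p <- f$particles
  n <- nrow(p)
  d_mean <- (p$defocus_u + p$defocus_v) / 2
  if (n < window) {
    return(list(defocus_u = p$defocus_u, defocus_v = p$defocus_v,
                windows = lapply(seq_len(n), function(i) i),
                changed = rep(FALSE, n), skipped = TRUE))
  }
  px <- p$pixel_size
  if (any(is.na(px))) px <- rep(1, n)  # arc scale cancels in the fit
  xy <- cbind(p$coord_x * px, p$coord_y * px)
  arc <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
  half <- (window - 1) / 2
  smoothed <- numeric(n)
  wins <- vector("list", n)
  for (i in seq_len(n)) {
    lo <- min(max(1L, i - half), n - window + 1L)
    w <- lo:(lo + window - 1L)
    fit <- trimmed_linefit(arc[w], d_mean[w])
    smoothed[i] <- fit$intercept + fit$slope * arc[i]
    wins[[i]] <- w
  }
  half_astig <- (p$defocus_u - p$defocus_v) / 2
  list(defocus_u = smoothed + half_astig,
       defocus_v = smoothed - half_astig,
       windows = wins,
       changed = abs(smoothed - d_mean) > 1e-9,
       skipped = FALSE)
}

#' Smooth defocus across a whole particle set
#'
#' Convenience wrapper: groups the set into filaments, smooths each, and
#' returns a new particle set with updated defocus columns plus a
#' per-filament report of the root-mean-square deviation of the mean
#' defocus from its local fitted line before and after smoothing.
#'
#' @param set a `particle_set`.
#' @param window passed to [smooth_filament_ctf()].
#' @return list with `set` (smoothed `particle_set`) and `report`
#'   (data.frame: micrograph_id, tube_id, n, rms_before, rms_after,
#'   skipped).
#' @export
smooth_ctf <- function(set, window = 5) {
  fils <- group_filaments(set)
  out <- as.data.frame(set)
  rep_rows <- vector("list", length(fils))
  for (k in seq_along(fils)) {
    f <- fils[[k]]
    res <- smooth_filament_ctf(f, window)
    before <- (f$particles$defocus_u + f$particles$defocus_v) / 2
    after <- (res$defocus_u + res$defocus_v) / 2
    out$defocus_u[f$row_idx] <- res$defocus_u
    out$defocus_v[f$row_idx] <- res$defocus_v
    rep_rows[[k]] <- data.frame(
      micrograph_id = f$micrograph_id, tube_id = f$tube_id,
      n = nrow(f$particles),
      rms_change = sqrt(mean((after - before)^2)),
      skipped = res$skipped)
  }
  newset <- particle_set(out, extra = particle_extra(set),
                         provenance = paste0(attr(set, "provenance"),
                                             " + ctf-smoothed"))
  list(set = newset, report = do.call(rbind, rep_rows))
}
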