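# Per-step helical rise/twist estimation, statistics, outlier rejection
# and confidence-band particle selection.
#
# A "step" joins two consecutive polarity-consistent particles of one
# ordered filament. Its rise is the displacement of the refined segment
# centre projected on the in-plane filament axis implied by psi; its
# twist is the wrapped difference of the rot Euler angles. Curation
# removes steps beyond a standard-deviation multiple of the dataset
# mean, then keeps steps inside a Gaussian confidence band recomputed on
# the survivors; a particle is kept only if every valid step it touches
# is kept.

#' Wrap an angle to (-180, 180]
#'
#' @param delta angle(s) in degrees.
#' @return equivalent angle(s) modulo 360 in the half-open interval
#'   (-180, 180].
#' @export
wrap_angle <- function(delta) {
  w <- delta - 360 * floor(delta / 360 + 0.5)
  w[w == -180] <- 180
  w
}

# in-plane filament axis unit vector: u(0 deg) = (0, 1), rotating
# counter-clockwise with psi
.psi_axis <- function(psi_deg) {
  r <- psi_deg * pi / 180
  cbind(-sin(r), cos(r))
}

# circular mean of two psi angles (degrees)
.psi_pair_mean <- function(a, b) a + wrap_angle(b - a) / 2

#' Compute helical steps along a filament
#'
#' For each consecutive particle pair (i, i+1) the refined centre is
#' `p = coord * pixel_size - origin` (subtractive origin convention;
#' set `origin_sign = +1` for the additive dialect). Rise is
#' `(p[i+1] - p[i])` projected on the axis unit vector of the circular
#' mean of the two psis, divided by `n_subunit_steps` (1 when the
#' extraction step is one subunit). Twist is
#' `wrap_angle(rot[i+1] - rot[i])`, optionally re-wrapped to the branch
#' nearest `expected_twist`. Pairs involving a polarity-inconsistent
#' particle yield invalid steps carrying the reason.
#'
#' @param f a `filament`, ordered and (ideally) polarity-checked.
#' @param expected_twist optional degrees; when given, twists are
#'   wrapped to the 360-degree branch nearest this value.
#' @param n_subunit_steps subunit steps between consecutive boxes.
#' @param origin_sign -1 (subtractive, default) or +1 (additive).
#' @return data.frame with one row per particle pair: `i`, `j` (row
#'   indices into `f$particles`), `rise` (Angstrom), `twist` (degrees),
#'   `valid`, `reason` (`"flip"`, `"tilt"`, `"inconsistent"`, or
#'   `"none"`).
#' @export
compute_steps <- function(f, expected_twist = NULL, n_subunit_steps = 1,
                          origin_sign = -1) {
  stopifnot(inherits(f, "filament"), n_subunit_steps >= 1,
            origin_sign %in% c(-1, 1))
  p <- f$particles
  n <- nrow(p)
  if (n < 2)
    return(data.frame(i = integer(0), j = integer(0), rise = numeric(0),
                      twist = numeric(0), valid = logical(0),
                      reason = character(0)))
  if (any(is.na(p$pixel_size)))
    stop("compute_steps: pixel_size unknown; supply it at read time",
         call. = FALSE)
  centers <- cbind(p$coord_x, p$coord_y) * p$pixel_size +
    origin_sign * cbind(p$origin_x, p$origin_y)
  cons <- f$consistent
  reason_of <- f$inconsistent_reason
  i <- seq_len(n - 1L); j <- i + 1L
  psi_m <- .psi_pair_mean(p$psi[i], p$psi[j])
  u <- .psi_axis(psi_m)
  d <- centers[j, , drop = FALSE] - centers[i, , drop = FALSE]
  rise <- rowSums(d * u) / n_subunit_steps
  twist <- wrap_angle(p$rot[j] - p$rot[i]) / n_subunit_steps
  if (!is.null(expected_twist))
    twist <- expected_twist + wrap_angle(twist - expected_twist)
  valid <- cons[i] & cons[j]
  reason <- rep("none", n - 1L)
  bad <- !valid
  pick <- ifelse(!cons[i], reason_of[i], reason_of[j])
  reason[bad] <- ifelse(pick[bad] %in% c("flip", "tilt"),
                        pick[bad], "inconsistent")
  rise[bad] <- NA_real_; twist[bad] <- NA_real_
  data.frame(i = i, j = j, rise = rise, twist = twist,
             valid = valid, reason = reason)
}

#' Compute steps for every filament of a particle set
#'
#' Groups, polarity-checks and step-computes the whole set. Filaments
#' with fewer than two consistent particles contribute no valid steps.
#'
#' @param set a `particle_set`.
#' @inheritParams compute_steps
#' @param psi_tol,tilt_tol passed to [check_polarity_consistency()].
#' @return data.frame of steps across all filaments, with
#'   `micrograph_id`, `tube_id` and global particle row indices
#'   `row_i`, `row_j` added.
#' @export
dataset_steps <- function(set, expected_twist = NULL, n_subunit_steps = 1,
                          origin_sign = -1, psi_tol = 15, tilt_tol = 30) {
  fils <- group_filaments(set)
  out <- lapply(fils, function(f) {
    if (nrow(f$particles) >= 2)
      f <- check_polarity_consistency(f, psi_tol, tilt_tol)
    s <- compute_steps(f, expected_twist, n_subunit_steps, origin_sign)
    if (nrow(s) == 0) return(NULL)
    s$micrograph_id <- f$micrograph_id
    s$tube_id <- f$tube_id
    s$row_i <- f$row_idx[s$i]
    s$row_j <- f$row_idx[s$j]
    s
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Mean and standard deviation of valid helical steps
#'
#' Sample statistics (n-1 denominator) over valid steps only, computed
#' separately for rise and twist. Twist is averaged on the wrapped
#' branch around its circular mean; if any valid twist deviates from
#' that circular mean by more than 90 degrees the branch is ambiguous
#' and an error is raised.
#'
#' @param steps step data.frame from [compute_steps()] or
#'   [dataset_steps()].
#' @return list with `mean_rise`, `sd_rise`, `mean_twist`, `sd_twist`,
#'   `n_steps`.
#' @export
dataset_stats <- function(steps) {
  v <- steps[steps$valid, , drop = FALSE]
  if (nrow(v) == 0) stop("dataset_stats: no valid steps")
  rise <- v$rise
  tw <- v$twist
  rad <- tw * pi / 180
  circ <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  dev <- wrap_angle(tw - circ)
  if (any(abs(dev) > 90))
    stop("dataset_stats: twist dispersion exceeds 90 degrees about the ",
         "circular mean; branch is ambiguous", call. = FALSE)
  tw_branch <- circ + dev
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  list(mean_rise = mean(rise), sd_rise = sd0(rise),
       mean_twist = mean(tw_branch), sd_twist = sd0(tw_branch),
       n_steps = nrow(v))
}

#' Two-stage step/particle selection
#'
#' Stage 1 removes every valid step whose rise or twist deviates from
#' the dataset mean by more than `sd_mult` standard deviations. Stage 2
#' recomputes the statistics on the survivors and keeps steps within
#' `mean +/- z(ci_level) * sd` on both parameters
#' (`z(0.95) = 1.959964`). A particle is kept iff every valid step it
#' participates in survives both stages; particles with no valid step
#' are `removed_inconsistent`. When an sd is zero that gate passes
#' trivially.
#'
#' @param steps step data.frame (must carry `row_i`/`row_j` global
#'   indices, as from [dataset_steps()], or per-filament `i`/`j`).
#' @param stats output of [dataset_stats()] on the same steps.
#' @param sd_mult positive multiplier for stage 1 (default 2).
#' @param ci_level confidence level in (0, 1) for stage 2 (default
#'   0.95).
#' @param n_particles total particle count (defaults to the largest
#'   index seen; pass explicitly for sets with trailing stepless
#'   particles).
#' @return a `selection_report`: list with `decision` (factor per
#'   particle: keep / removed_outlier / removed_ci /
#'   removed_inconsistent), `step_kept_stage1`, `step_kept_stage2`
#'   (logical per step, NA for invalid steps), `stats_stage1` (input
#'   stats), `stats_stage2` (recomputed), `counts`.
#' @export
select_particles <- function(steps, stats, sd_mult = 2.0,
                             ci_level = 0.95, n_particles = NULL) {
  if (sd_mult <= 0) stop("select_particles: sd_mult must be positive")
  if (ci_level <= 0 || ci_level >= 1)
    stop("select_particles: ci_level must be in (0, 1)")
  ri <- if (!is.null(steps$row_i)) steps$row_i else steps$i
  rj <- if (!is.null(steps$row_j)) steps$row_j else steps$j
  if (is.null(n_particles)) n_particles <- max(ri, rj)
  val <- steps$valid

  # sd indistinguishable from 0 at double precision passes trivially
  gate <- function(x, m, s, width) {
    tol0 <- sqrt(.Machine$double.eps) * max(1, abs(m))
    s <= tol0 | abs(x - m) <= width * s
  }
  k1 <- rep(NA, nrow(steps))
  k1[val] <- gate(steps$rise[val], stats$mean_rise, stats$sd_rise, sd_mult) &
             gate(steps$twist[val], stats$mean_twist, stats$sd_twist, sd_mult)

  surv <- steps[val & k1 %in% TRUE, , drop = FALSE]
  if (nrow(surv) == 0)
    stop("select_particles: stage 1 removed every valid step")
  st2 <- dataset_stats(surv)
  z <- stats::qnorm((1 + ci_level) / 2)
  k2 <- rep(NA, nrow(steps))
  sel <- val & k1 %in% TRUE
  k2[sel] <- gate(steps$rise[sel], st2$mean_rise, st2$sd_rise, z) &
             gate(steps$twist[sel], st2$mean_twist, st2$sd_twist, z)

  has_valid <- rep(FALSE, n_particles)
  bad1 <- rep(FALSE, n_particles)
  bad2 <- rep(FALSE, n_particles)
  for (s in seq_len(nrow(steps))) {
    if (!val[s]) next
    pr <- c(ri[s], rj[s])
    has_valid[pr] <- TRUE
    if (!isTRUE(k1[s])) bad1[pr] <- TRUE
    else if (!isTRUE(k2[s])) bad2[pr] <- TRUE
  }
  decision <- rep("keep", n_particles)
  decision[!has_valid] <- "removed_inconsistent"
  decision[has_valid & bad2] <- "removed_ci"
  decision[has_valid & bad1] <- "removed_outlier"
  decision <- factor(decision, levels = c("keep", "removed_outlier",
                                          "removed_ci",
                                          "removed_inconsistent"))
  structure(list(decision = decision,
                 step_kept_stage1 = k1, step_kept_stage2 = k2,
                 stats_stage1 = stats, stats_stage2 = st2,
                 counts = table(decision)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  print(x$counts)
  with(x$stats_stage2, cat(sprintf(
    "stage-2 stats: rise %.3f +/- %.3f A, twist %.3f +/- %.3f deg (n=%d)\n",
    mean_rise, sd_rise, mean_twist, sd_twist, n_steps)))
  invisible(x)
}

#' One-call curation of a particle set
#'
#' Runs the full pipeline: polarity check, step computation, dataset
#' statistics, two-stage selection. Returns the kept subset and the
#' report.
#'
#' @inheritParams dataset_steps
#' @inheritParams select_particles
#' @return list with `kept` (a `particle_set`), `removed` (ditto, may
#'   have zero rows), `report` (a `selection_report`), `steps`,
#'   `stats`.
#' @export
curate_particles <- function(set, expected_twist = NULL,
                             n_subunit_steps = 1, origin_sign = -1,
                             psi_tol = 15, tilt_tol = 30, sd_mult = 2.0,
                             ci_level = 0.95) {
  steps <- dataset_steps(set, expected_twist, n_subunit_steps,
                         origin_sign, psi_tol, tilt_tol)
  stats <- dataset_stats(steps)
  rep <- select_particles(steps, stats, sd_mult, ci_level,
                          n_particles = nrow(set))
  keep <- rep$decision == "keep"
  subset_ps <- function(mask) {
    d <- as.data.frame(set)[mask, , drop = FALSE]
    e <- particle_extra(set)[mask, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    particle_set(d, extra = e, provenance = attr(set, "provenance"))
  }
  list(kept = subset_ps(keep), removed = subset_ps(!keep),
       report = rep, steps = steps, stats = stats)
}
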