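# Synthetic filament metadata and toy atomic models with known ground
# truth.
#
# The generator lays straight filaments at random orientations on
# virtual micrographs and emits segment records exactly as a windowed
# helical extraction would: boxes one subunit step apart, psi encoding
# polarity, rot incrementing by the true twist, origins encoding the
# deviation of each refined centre from the box grid. Planted defects
# (gross rise outliers, polarity flips, defocus spikes) are labelled so
# curation decisions can be scored against truth.

#' Synthetic dataset configuration
#'
#' Defaults emulate the regime of a helical actin-filament dataset:
#' 328-pixel boxes stepped by one 26-pixel subunit at 1.045 Angstrom per
#' pixel (hence a true rise of 27.17 Angstrom), canonical twist -166.7
#' degrees, and defocus in the 1-2.5 micrometre range varying smoothly
#' along each filament.
#'
#' @param n_micrographs,filaments_per_micrograph,particles_per_filament
#'   dataset shape; `particles_per_filament` must be >= 2.
#' @param true_rise Angstrom per subunit step.
#' @param true_twist degrees per subunit step.
#' @param pixel_size Angstrom/pixel.
#' @param box_px,step_px extraction box and step, pixels.
#' @param angular_noise_sd Gaussian noise on psi, tilt and rot, degrees.
#' @param origin_noise_sd Gaussian noise per origin component, Angstrom.
#' @param outlier_fraction fraction of particles whose incoming step
#'   rise is shifted by `outlier_rise_shift`.
#' @param outlier_rise_shift Angstrom.
#' @param flip_fraction fraction of particles with a 180-degree polarity
#'   flip (psi + 180, rot negated).
#' @param defocus_base mean defocus, Angstrom.
#' @param defocus_gradient defocus change per Angstrom of arc along a
#'   filament (Angstrom/Angstrom).
#' @param defocus_spike_fraction fraction of particles with a +5000
#'   Angstrom defocus spike (the defect CTF smoothing removes).
#' @param seed integer RNG seed; identical configs generate
#'   byte-identical STAR output.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_micrographs = 5,
                             filaments_per_micrograph = 4,
                             particles_per_filament = 50,
                             true_rise = 27.17,
                             true_twist = -166.7,
                             pixel_size = 1.045,
                             box_px = 328, step_px = 26,
                             angular_noise_sd = 1,
                             origin_noise_sd = 0.5,
                             outlier_fraction = 0.05,
                             outlier_rise_shift = 10,
                             flip_fraction = 0.02,
                             defocus_base = 15000,
                             defocus_gradient = 0.3,
                             defocus_spike_fraction = 0.02,
                             seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(cfg$outlier_fraction, cfg$flip_fraction,
          cfg$defocus_spike_fraction)
  if (any(fr < 0 | fr >= 1))
    stop("synthetic_config: fractions must lie in [0, 1)")
  if (cfg$outlier_fraction + cfg$flip_fraction >= 1)
    stop("synthetic_config: outlier_fraction + flip_fraction must be < 1")
  if (cfg$particles_per_filament < 2)
    stop("synthetic_config: particles_per_filament must be >= 2")
  stopifnot(cfg$pixel_size > 0, cfg$box_px > 0, cfg$step_px > 0,
            cfg$angular_noise_sd >= 0, cfg$origin_noise_sd >= 0,
            cfg$defocus_base > 0)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic particle dataset with ground truth
#'
#' @param cfg a [synthetic_config()].
#' @return list with `set` (a `particle_set`) and `truth` (list of
#'   `particles`: per-particle data.frame with `label`
#'   (clean/outlier/flipped/defocus_spike) and `true_defocus`; `steps`:
#'   per-step data.frame with `row_i`, `row_j`, `true_rise`,
#'   `true_twist`, `is_outlier`, `crosses_flip`).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n_per <- cfg$particles_per_filament
  recs <- list(); truth_p <- list(); truth_s <- list()
  row0 <- 0L
  for (m in seq_len(cfg$n_micrographs)) {
    mic <- sprintf("mic_%03d.mrc", m)
    defocus_mic <- cfg$defocus_base + stats::runif(1, -4000, 4000)
    for (t in seq_len(cfg$filaments_per_micrograph)) {
      theta <- stats::runif(1, 0, 2 * pi)
      d <- c(cos(theta), sin(theta))
      start <- stats::runif(2, 1200, 2800)
      psi0 <- atan2(-d[1], d[2]) * 180 / pi
      rot0 <- stats::runif(1, -180, 180)

      k <- seq_len(n_per) - 1L
      # defect labels: outlier and flip mutually exclusive per particle;
      # particle 1 has no incoming step so it cannot be an outlier
      u <- stats::runif(n_per)
      is_out <- u < cfg$outlier_fraction & k > 0
      is_flip <- u >= cfg$outlier_fraction &
        u < cfg$outlier_fraction + cfg$flip_fraction
      is_spike <- stats::runif(n_per) < cfg$defocus_spike_fraction

      step_rise <- rep(cfg$true_rise, n_per - 1L)
      step_rise[is_out[-1]] <- step_rise[is_out[-1]] + cfg$outlier_rise_shift
      t_ax <- c(0, cumsum(step_rise))          # true axial positions, A

      coords <- sweep(outer(k * cfg$step_px, d), 2, start, "+")
      p_true <- sweep(outer(t_ax, d), 2, start * cfg$pixel_size, "+")
      origin <- coords * cfg$pixel_size - p_true +
        matrix(stats::rnorm(2 * n_per, 0, cfg$origin_noise_sd), n_per)

      psi <- psi0 + stats::rnorm(n_per, 0, cfg$angular_noise_sd)
      tilt <- 90 + stats::rnorm(n_per, 0, cfg$angular_noise_sd)
      rot <- rot0 + k * cfg$true_twist +
        stats::rnorm(n_per, 0, cfg$angular_noise_sd)
      psi[is_flip] <- psi[is_flip] + 180
      rot[is_flip] <- -rot[is_flip]
      psi <- wrap_angle(psi); rot <- wrap_angle(rot)

      arc <- t_ax - t_ax[1]
      defocus_true <- defocus_mic + cfg$defocus_gradient * arc
      defocus <- defocus_true + ifelse(is_spike, 5000, 0)

      recs[[length(recs) + 1L]] <- data.frame(
        micrograph_id = mic, tube_id = t,
        coord_x = coords[, 1], coord_y = coords[, 2],
        psi = psi, tilt = tilt, rot = rot,
        origin_x = origin[, 1], origin_y = origin[, 2],
        defocus_u = defocus + 150, defocus_v = defocus - 150,
        defocus_angle = 30, pixel_size = cfg$pixel_size)

      label <- rep("clean", n_per)
      label[is_spike] <- "defocus_spike"
      label[is_out] <- "outlier"
      label[is_flip] <- "flipped"
      truth_p[[length(truth_p) + 1L]] <- data.frame(
        micrograph_id = mic, tube_id = t, label = label,
        true_defocus = defocus_true)
      truth_s[[length(truth_s) + 1L]] <- data.frame(
        micrograph_id = mic, tube_id = t,
        row_i = row0 + seq_len(n_per - 1L),
        row_j = row0 + seq_len(n_per - 1L) + 1L,
        true_rise = step_rise, true_twist = cfg$true_twist,
        is_outlier = is_out[-1],
        crosses_flip = is_flip[-n_per] | is_flip[-1])
      row0 <- row0 + n_per
    }
  }
  set <- particle_set(do.call(rbind, recs),
                      provenance = sprintf("synthetic seed=%d", cfg$seed))
  list(set = set,
       truth = list(particles = do.call(rbind, truth_p),
                    steps = do.call(rbind, truth_s)))
}

# fixed asymmetric heavy-atom cluster used as one toy subunit
.toy_subunit <- function() {
  data.frame(
    atom_name = c("N", "CA", "C", "O", "CB"),
    element = c("N", "C", "C", "O", "C"),
    x = c(0.0, 1.46, 2.20, 1.70, 1.95),
    y = c(0.0, 0.30, 1.55, 2.65, -0.75),
    z = c(0.0, 0.95, 0.60, 0.80, 2.10))
}

#' Generate a toy helical polymer structure
#'
#' Repeats an asymmetric atom cluster by the screw operation (rotation
#' `twist` about z, translation `rise` along z). Each subunit becomes
#' one residue on chain A with residue number equal to its subunit
#' index. Useful as a download-free stand-in for filament models when
#' exercising superposition, RMSD and B-factor metrics.
#'
#' @param n_subunits number of subunits (>= 1).
#' @param rise Angstrom per subunit.
#' @param twist degrees per subunit.
#' @param b_factors optional vector of per-subunit B-factors (recycled
#'   over the subunit's atoms); default 50 everywhere.
#' @param subunit optional data.frame replacing the built-in 5-atom
#'   cluster (`atom_name`, `element`, `x`, `y`, `z`); must contain at
#'   least 3 distinct positions.
#' @return a `structure3d` (synthetic).
#' @export
generate_toy_polymer <- function(n_subunits, rise, twist,
                                 b_factors = NULL, subunit = NULL) {
  stopifnot(n_subunits >= 1)
  base <- if (is.null(subunit)) .toy_subunit() else subunit
  xyz0 <- as.matrix(base[c("x", "y", "z")])
  if (nrow(unique(round(xyz0, 9))) < 3)
    stop("generate_toy_polymer: degenerate subunit cluster")
  if (is.null(b_factors)) b_factors <- rep(50, n_subunits)
  b_factors <- rep_len(b_factors, n_subunits)
  subs <- lapply(seq_len(n_subunits), function(s) {
    ang <- (s - 1) * twist * pi / 180
    R <- matrix(c(cos(ang), sin(ang), 0,
                  -sin(ang), cos(ang), 0,
                  0, 0, 1), 3, 3)
    xyz <- xyz0 %*% t(R)
    xyz[, 3] <- xyz[, 3] + (s - 1) * rise
    data.frame(element = base$element, atom_name = base$atom_name,
               residue_name = "TOY", residue_number = s,
               chain_id = "A",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               b_factor = b_factors[s], occupancy = 1)
  })
  .new_structure(do.call(rbind, subs), source = "synthetic toy polymer")
}
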