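#' Specification for a synthetic multi-temperature trajectory
#'
#' Emulates the statistical structure of a temperature-stepped simulation:
#' per-residue isotropic Gaussian fluctuations whose standard deviation grows
#' linearly with temperature, contaminated by per-frame rigid-body motion
#' that a correct superposition must remove.
#'
#' Per residue i and window temperature T, the per-coordinate standard
#' deviation is `sigma_i(T) = a_i + b_i * (T - T0)` with `T0` the first
#' window's temperature. Every frame is
#' `r_i(t) = R(t) (mu_i + eta_i(t)) + d(t)` with `eta_i(t)` an independent
#' 3-D Gaussian of per-coordinate sd `sigma_i(T)`, `R(t)` a random rotation
#' and `d(t)` a random translation.
#'
#' @param n_residues Number of residues.
#' @param temperatures_C Window temperatures, strictly increasing (degC).
#' @param frames_per_window Frames per window.
#' @param analysis_fraction Trailing fraction of each window analysed.
#' @param base_sigma `a_i`: scalar or per-residue vector (Angstrom) at `T0`.
#' @param thermal_coefficient `b_i`: scalar or per-residue vector
#'   (Angstrom per degC, >= 0).
#' @param rigid_rotation_deg Per-frame random rotation amplitude (degrees).
#' @param rigid_translation Per-frame random translation sd (Angstrom).
#' @param frame_spacing ns per frame (metadata).
#' @param seed Single integer seed; same seed gives identical output (R's
#'   default Mersenne-Twister stream).
#' @return A `synth_traj_spec` list.
#' @export
synth_traj_spec <- function(n_residues = 100,
                            temperatures_C = c(10, 27, 47, 72),
                            frames_per_window = 625,
                            analysis_fraction = 0.8,
                            base_sigma = 0.1,
                            thermal_coefficient = 0.005,
                            rigid_rotation_deg = 8,
                            rigid_translation = 3,
                            frame_spacing = 0.04,
                            seed = 1L) {
  stopifnot(all(diff(temperatures_C) > 0), frames_per_window >= 2)
  a <- rep_len(base_sigma, n_residues)
  b <- rep_len(thermal_coefficient, n_residues)
  if (any(b < 0)) stop("synth_traj_spec: thermal_coefficient must be >= 0")
  t0 <- temperatures_C[1]
  sigma <- matrix(a, n_residues, length(temperatures_C)) +
    outer(b, temperatures_C - t0)
  if (any(sigma <= 0))
    stop("synth_traj_spec: sigma_i(T) must be positive in every window")
  structure(list(n_residues = n_residues, temperatures_C = temperatures_C,
                 frames_per_window = frames_per_window,
                 analysis_fraction = analysis_fraction,
                 base_sigma = a, thermal_coefficient = b, t0 = t0,
                 sigma = sigma,
                 rigid_rotation_deg = rigid_rotation_deg,
                 rigid_translation = rigid_translation,
                 frame_spacing = frame_spacing, seed = as.integer(seed)),
            class = "synth_traj_spec")
}

random_rotation <- function(max_deg) {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  theta <- stats::runif(1, -max_deg, max_deg) * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Generate a synthetic trajectory with a closed-form manifest
#'
#' Draws frames according to a [synth_traj_spec()] around a mean structure
#' (default: an ideal helix backbone of the requested length). The same
#' residue's atoms share one fluctuation vector per frame, so CA-based and
#' backbone-based statistics see the same per-residue sigma.
#'
#' The manifest carries the generator's closed forms, the quantities a
#' correct analysis should recover:
#' * `expected_rmsf[i, w]` = `sigma_i(T_w) * sqrt(3)`
#' * `expected_window_rmsd[w]` = `sqrt(3 * mean_i(sigma_i(T_w)^2))`
#'   (backbone RMSD against the noiseless mean structure)
#' * `expected_slope` = OLS slope of `expected_window_rmsd` on temperature
#'
#' @param spec A `synth_traj_spec`.
#' @param mean_structure Optional `structure_model` supplying the mean
#'   coordinates (must have `spec$n_residues` residues).
#' @return List with `trajectory`, `schedule` (a [window_schedule()]),
#'   `reference` (noiseless mean coordinates, atoms x 3) and `manifest`.
#' @export
make_trajectory <- function(spec, mean_structure = NULL) {
  stopifnot(inherits(spec, "synth_traj_spec"))
  set.seed(spec$seed)
  if (is.null(mean_structure))
    mean_structure <- build_backbone(spec$n_residues, "ideal_helix")
  a <- protein_atoms(mean_structure)
  res_ids <- unique(a$resno)
  stopifnot(length(res_ids) == spec$n_residues)
  res_index <- match(a$resno, res_ids)
  mu <- as.matrix(a[, c("x", "y", "z")])
  n_at <- nrow(mu)
  nw <- length(spec$temperatures_C)
  nf <- nw * spec$frames_per_window
  coords <- array(NA_real_, c(n_at, 3, nf))
  f <- 0L
  for (w in seq_len(nw)) {
    for (k in seq_len(spec$frames_per_window)) {
      f <- f + 1L
      eta <- matrix(stats::rnorm(3 * spec$n_residues, sd = spec$sigma[, w]),
                    spec$n_residues, 3)
      frame <- mu + eta[res_index, , drop = FALSE]
      if (spec$rigid_rotation_deg > 0 || spec$rigid_translation > 0) {
        R <- random_rotation(spec$rigid_rotation_deg)
        d <- stats::rnorm(3, sd = spec$rigid_translation)
        frame <- sweep(frame %*% t(R), 2, -d, FUN = "-")
      }
      coords[, , f] <- frame
    }
  }
  atom_table <- data.frame(name = a$name, resname = a$resname,
                           chain = a$chain, resno = a$resno,
                           element = a$element, stringsAsFactors = FALSE)
  traj <- new_trajectory(coords, atom_table, spec$frame_spacing)
  starts <- (seq_len(nw) - 1L) * spec$frames_per_window + 1L
  schedule <- window_schedule(starts, starts + spec$frames_per_window - 1L,
                              spec$temperatures_C, spec$analysis_fraction)
  expected_rmsd <- sqrt(3 * colMeans(spec$sigma^2))
  expected_slope <- unname(stats::coef(
    stats::lm(expected_rmsd ~ spec$temperatures_C))[2])
  manifest <- list(
    sigma = spec$sigma,
    expected_rmsf = spec$sigma * sqrt(3),
    expected_window_rmsd = expected_rmsd,
    expected_slope = expected_slope,
    temperatures_C = spec$temperatures_C,
    resno = res_ids
  )
  list(trajectory = traj, schedule = schedule, reference = mu,
       manifest = manifest)
}

#' Generate replica trajectories
#'
#' Same spec, distinct derived seeds, emulating independent simulation
#' replicas started from different velocity seeds.
#'
#' @param spec A `synth_traj_spec`.
#' @param n_replicas Number of replicas.
#' @param mean_structure Optional shared mean structure.
#' @return List of [make_trajectory()] bundles.
#' @export
make_replicas <- function(spec, n_replicas = 3, mean_structure = NULL) {
  lapply(seq_len(n_replicas), function(r) {
    s <- spec
    s$seed <- (spec$seed * 131L + r) %% .Machine$integer.max
    make_trajectory(s, mean_structure = mean_structure)
  })
}
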