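#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `reference`
#' via SVD of the cross-covariance matrix, with the reflection guard
#' (determinant forced to +1). Errors on degenerate (collinear or < 3 point)
#' masks, where the rotation is not unique.
#'
#' @param mobile,reference n x 3 coordinate matrices with matching rows.
#' @param mask Optional row indices used to compute the fit (the transform is
#'   still applied to nothing here; only fit quality is returned).
#' @return List with `R` (3 x 3 rotation), `t` (translation), `rmsd`
#'   (post-fit RMSD over masked atoms). Transformed mobile coordinates are
#'   `sweep(mobile %*% t(R), 2, -t)`, i.e. `R x + t` per row.
#' @export
superpose <- function(mobile, reference, mask = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, all(dim(mobile) == dim(reference)))
  if (is.null(mask)) mask <- seq_len(nrow(mobile))
  if (length(mask) < 3) stop("superpose: need >= 3 atoms in mask")
  P <- mobile[mask, , drop = FALSE]
  Q <- reference[mask, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (svd(Pc)$d[2] < 1e-8 * max(1, svd(Pc)$d[1]))
    stop("superpose: degenerate (collinear) atom mask")
  s <- svd(crossprod(Pc, Qc))  # t(Pc) %*% Qc = U D V'
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cq - as.numeric(R %*% cp)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(R = R, t = t_vec, rmsd = rmsd)
}

apply_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% t(fit$R), 2, -fit$t, FUN = "-")
}

#' Select trajectory atoms by name
#'
#' @param traj A `trajectory`.
#' @param atoms Atom names to keep (default backbone N, CA, C).
#' @return Integer indices into the trajectory's atom table.
#' @export
atom_mask <- function(traj, atoms = c("N", "CA", "C")) {
  which(traj$atoms$name %in% atoms)
}

#' Per-frame backbone RMSD series
#'
#' Superposes every frame onto a fixed reference over the masked atoms and
#' records the post-fit RMSD. With a [window_schedule()], window means are
#' taken over only the trailing analysis fraction of each window (the
#' equilibrated tail).
#'
#' @param traj A `trajectory`.
#' @param reference `"first_frame"`, a frame index, or an n_mask x 3 (or
#'   n_atoms x 3) coordinate matrix such as a generator's noiseless mean
#'   structure.
#' @param mask Atom indices (default: backbone N, CA, C).
#' @param schedule Optional `window_schedule`.
#' @param replica Optional replica identifier carried into reports.
#' @return An `rmsd_series`: list with `rmsd` (per frame), `window`
#'   (per-window means with temperatures; NULL without a schedule),
#'   `replica`.
#' @export
rmsd_series <- function(traj, reference = "first_frame",
                        mask = atom_mask(traj), schedule = NULL,
                        replica = 1L) {
  nf <- n_frames(traj)
  ref <- resolve_reference(traj, reference, mask)
  vals <- vapply(seq_len(nf), function(f) {
    superpose(traj$coords[mask, , f], ref)$rmsd
  }, numeric(1))
  window <- NULL
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "window_schedule"))
    if (max(schedule$end) > nf)
      stop("rmsd_series: schedule exceeds trajectory frames")
    window <- schedule
    window$mean_rmsd <- vapply(seq_len(nrow(schedule)), function(i)
      mean(vals[analysis_frames(schedule, i)]), numeric(1))
  }
  structure(list(rmsd = vals, window = window, replica = replica),
            class = "rmsd_series")
}

resolve_reference <- function(traj, reference, mask) {
  if (is.character(reference) && identical(reference, "first_frame"))
    return(traj$coords[mask, , 1])
  if (is.numeric(reference) && length(reference) == 1L)
    return(traj$coords[mask, , as.integer(reference)])
  reference <- as.matrix(reference)
  if (nrow(reference) == dim(traj$coords)[1]) return(reference[mask, , drop = FALSE])
  if (nrow(reference) == length(mask)) return(reference)
  stop("rmsd_series: reference rows match neither the full atom set nor the mask")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("rmsd_series: %d frames, mean %.3f A (replica %s)\n",
              length(x$rmsd), mean(x$rmsd), x$replica))
  if (!is.null(x$window))
    print(x$window[, c("temperature_C", "mean_rmsd")], row.names = FALSE)
  invisible(x)
}

#' Thermal-sensitivity regression of RMSD on temperature
#'
#' Window-mean RMSD values are averaged across replicas per temperature and
#' fitted by ordinary least squares against temperature. The slope
#' (Angstrom per degree C) is the thermal-sensitivity descriptor: a lower
#' slope means the fold gains less flexibility per degree of heating, the
#' hallmark of a heat-tolerant scaffold; per-replica slopes are retained to
#' show dispersion.
#'
#' @param series A single `rmsd_series` (with windows) or a list of them,
#'   one per replica.
#' @return A `temp_regression`: list with `points` (temperature, mean RMSD),
#'   `slope`, `intercept`, `r_squared`, `per_replica_slopes`.
#' @export
temperature_regression <- function(series) {
  if (inherits(series, "rmsd_series")) series <- list(series)
  stopifnot(length(series) >= 1,
            all(vapply(series, function(s) !is.null(s$window), logical(1))))
  temps <- series[[1]]$window$temperature_C
  if (length(temps) < 2) stop("temperature_regression: need >= 2 windows")
  mat <- vapply(series, function(s) {
    stopifnot(identical(s$window$temperature_C, temps))
    s$window$mean_rmsd
  }, numeric(length(temps)))
  mat <- matrix(mat, nrow = length(temps))
  pts <- data.frame(temperature_C = temps, mean_rmsd = rowMeans(mat))
  fit <- stats::lm(mean_rmsd ~ temperature_C, data = pts)
  per_rep <- apply(mat, 2, function(y)
    unname(stats::coef(stats::lm(y ~ temps))[2]))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((pts$mean_rmsd - mean(pts$mean_rmsd))^2)
  r2 <- if (ss_tot <= .Machine$double.xmin) 1 else 1 - ss_res / ss_tot
  structure(list(points = pts,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 per_replica_slopes = per_rep,
                 fit = fit),
            class = "temp_regression")
}

#' @export
print.temp_regression <- function(x, ...) {
  cat(sprintf("temp_regression: slope %.4g A/degC, intercept %.3g, R^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Plot RMSD against temperature with the fitted line
#'
#' @param x A `temp_regression`.
#' @param ... Passed to [plot()].
#' @export
plot.temp_regression <- function(x, ...) {
  plot(x$points$temperature_C, x$points$mean_rmsd,
       xlab = "Temperature (degC)", ylab = "Mean backbone RMSD (A)",
       pch = 19, ...)
  graphics::abline(x$fit, lty = 2)
  graphics::mtext(sprintf("slope = %.4g A/degC, R2 = %.3f", x$slope,
                          x$r_squared), side = 3, line = 0.2, cex = 0.8)
}

#' Per-residue RMSF over a frame set
#'
#' Two-pass procedure: frames are superposed onto the first selected frame,
#' the mean structure is computed, frames are re-superposed onto that mean
#' and the mean is refreshed; RMSF is the root mean square displacement of
#' each masked atom about its refreshed mean position.
#'
#' @param traj A `trajectory`.
#' @param frames Frame indices (default all; pass a window's analysis frames
#'   for windowed profiles).
#' @param mask Atom indices; default one CA per residue.
#' @return An `rmsf_profile`: data frame with `chain`, `resno`, `resname`,
#'   `rmsf` plus attribute `frames`.
#' @export
rmsf <- function(traj, frames = seq_len(n_frames(traj)),
                 mask = atom_mask(traj, "CA")) {
  stopifnot(length(frames) >= 2, length(mask) >= 3)
  sel <- traj$coords[mask, , frames, drop = FALSE]
  nfr <- length(frames)
  fitted <- sel
  for (f in seq_len(nfr))
    fitted[, , f] <- apply_transform(sel[, , f],
                                     superpose(sel[, , f], sel[, , 1]))
  mean1 <- apply(fitted, c(1, 2), mean)
  for (f in seq_len(nfr))
    fitted[, , f] <- apply_transform(sel[, , f],
                                     superpose(sel[, , f], mean1))
  mean2 <- apply(fitted, c(1, 2), mean)
  dev2 <- vapply(seq_len(nfr), function(f)
    rowSums((fitted[, , f] - mean2)^2), numeric(nrow(mean2)))
  vals <- sqrt(rowMeans(matrix(dev2, nrow = nrow(mean2))))
  out <- data.frame(chain = traj$atoms$chain[mask],
                    resno = traj$atoms$resno[mask],
                    resname = traj$atoms$resname[mask],
                    rmsf = vals, stringsAsFactors = FALSE)
  attr(out, "frames") <- frames
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' Windowed RMSF profiles
#'
#' One [rmsf()] profile per schedule window, each over that window's
#' analysis frames, with superposition performed per window.
#'
#' @param traj A `trajectory`.
#' @param schedule A `window_schedule`.
#' @param mask Atom indices (default CA).
#' @return Named list of `rmsf_profile`s, names = temperature (degC).
#' @export
rmsf_windows <- function(traj, schedule, mask = atom_mask(traj, "CA")) {
  stopifnot(inherits(schedule, "window_schedule"))
  out <- lapply(seq_len(nrow(schedule)), function(i)
    rmsf(traj, frames = analysis_frames(schedule, i), mask = mask))
  names(out) <- as.character(schedule$temperature_C)
  out
}

#' Change in RMSF between two temperatures with significance flags
#'
#' Computes per-residue `delta = rmsf_high - rmsf_low` and flags residues
#' whose delta is at or above `threshold` (default 0.5 Angstrom, the
#' customary significance cut for a comparable temperature rise). When a
#' `panel` (named list of residue-number vectors, e.g. catalytic and
#' substrate-binding sets) is given, the report is restricted to those
#' residues and annotated with the subset name.
#'
#' @param profile_low,profile_high `rmsf_profile`s on the same residues.
#' @param threshold Significance threshold in Angstrom (> 0).
#' @param panel Optional named list of residue-number vectors (author
#'   numbering).
#' @return A `residue_panel` data frame: `chain`, `resno`, `resname`,
#'   `subset`, `rmsf_low`, `rmsf_high`, `delta`, `flagged`.
#' @export
delta_rmsf <- function(profile_low, profile_high, threshold = 0.5,
                       panel = NULL) {
  stopifnot(threshold > 0,
            nrow(profile_low) == nrow(profile_high),
            all(profile_low$resno == profile_high$resno))
  out <- data.frame(chain = profile_low$chain, resno = profile_low$resno,
                    resname = profile_low$resname,
                    subset = "all",
                    rmsf_low = profile_low$rmsf,
                    rmsf_high = profile_high$rmsf,
                    stringsAsFactors = FALSE)
  out$delta <- out$rmsf_high - out$rmsf_low
  out$flagged <- out$delta >= threshold
  if (!is.null(panel)) {
    stopifnot(is.list(panel), !is.null(names(panel)))
    pieces <- lapply(names(panel), function(nm) {
      hit <- out[out$resno %in% panel[[nm]], , drop = FALSE]
      missing <- setdiff(panel[[nm]], out$resno)
      if (length(missing))
        stop("delta_rmsf: panel '", nm, "' names absent residues: ",
             paste(missing, collapse = ", "))
      hit$subset <- nm
      hit
    })
    out <- do.call(rbind, pieces)
  }
  rownames(out) <- NULL
  class(out) <- c("residue_panel", "data.frame")
  out
}
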