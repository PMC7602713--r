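test_that("superposition removes rigid motion exactly", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  f0 <- superpose(X, X)
  expect_equal(f0$rmsd, 0, tolerance = 1e-12)
  expect_equal(f0$R, diag(3), tolerance = 1e-9)
  R <- random_rotation_matrix()
  Y <- sweep(X %*% t(R), 2, c(3, -1, 5), FUN = "+")
  f <- superpose(Y, X)
  expect_lt(f$rmsd, 1e-6)
  back <- adaptsig:::apply_transform(Y, f)
  expect_equal(back, X, tolerance = 1e-9)
})

test_that("Kabsch RMSD agrees with the quaternion oracle on noisy toys", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    X <- matrix(rnorm(3 * n), n, 3)
    Y <- sweep(X %*% t(random_rotation_matrix()), 2, rnorm(3), FUN = "+") +
      matrix(rnorm(3 * n, sd = 0.3), n, 3)
    expect_equal(superpose(Y, X)$rmsd, quaternion_fit_rmsd(Y, X),
                 tolerance = 1e-6)
  }
})

test_that("the reflection guard keeps rotations proper", {
  set.seed(3)
  for (i in 1:10) {
    X <- matrix(rnorm(15), 5, 3)
    Y <- X; Y[, 1] <- -Y[, 1]   # mirrored target tempts a reflection
    f <- superpose(Y, X)
    expect_equal(det(f$R), 1, tolerance = 1e-9)
  }
})

test_that("degenerate masks are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), ">= 3")
})

test_that("a static trajectory has zero RMSD and zero RMSF", {
  m <- build_backbone(10, "ideal_helix")
  a <- protein_atoms(m)
  coords <- array(rep(as.matrix(a[, c("x", "y", "z")]), 5),
                  c(nrow(a), 3, 5))
  traj <- adaptsig:::new_trajectory(coords, a[, c("name", "resname", "chain",
                                                  "resno", "element")])
  expect_equal(max(rmsd_series(traj)$rmsd), 0, tolerance = 1e-12)
  expect_equal(max(rmsf(traj)$rmsf), 0, tolerance = 1e-12)
})

test_that("rigid-body-only motion leaves no residual RMSD", {
  spec <- synth_traj_spec(n_residues = 15, temperatures_C = c(10, 27),
                          frames_per_window = 10, base_sigma = 1e-12,
                          thermal_coefficient = 0, seed = 5)
  b <- make_trajectory(spec)
  s <- rmsd_series(b$trajectory, reference = b$reference)
  expect_lt(max(s$rmsd), 1e-6)
})

test_that("window-mean RMSD matches the Gaussian closed form", {
  spec <- synth_traj_spec(n_residues = 60, frames_per_window = 300,
                          analysis_fraction = 1, base_sigma = 0.2,
                          thermal_coefficient = 0.004, seed = 9)
  b <- make_trajectory(spec)
  s <- rmsd_series(b$trajectory, reference = b$reference, schedule = b$schedule)
  expect_equal(s$window$mean_rmsd, b$manifest$expected_window_rmsd,
               tolerance = 0.05)
  expect_true(all(diff(s$window$mean_rmsd) > 0))  # grows with temperature
})

test_that("regression on exact collinear points is exact", {
  s <- structure(list(
    rmsd = numeric(0),
    window = data.frame(temperature_C = c(10, 27, 47, 72),
                        mean_rmsd = c(0.10, 0.27, 0.47, 0.72)),
    replica = 1L), class = "rmsd_series")
  reg <- temperature_regression(s)
  expect_equal(reg$slope, 0.01, tolerance = 1e-12)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
  s$window$mean_rmsd <- rep(0.3, 4)
  expect_equal(temperature_regression(s)$slope, 0, tolerance = 1e-12)
})

test_that("replica window means are averaged before the fit", {
  mk <- function(y) structure(list(
    rmsd = numeric(0),
    window = data.frame(temperature_C = c(10, 30), mean_rmsd = y),
    replica = 1L), class = "rmsd_series")
  reg <- temperature_regression(list(mk(c(0.1, 0.3)), mk(c(0.3, 0.5))))
  expect_equal(reg$points$mean_rmsd, c(0.2, 0.4))
  expect_equal(reg$slope, 0.01)
  expect_length(reg$per_replica_slopes, 2L)
  expect_equal(unname(reg$per_replica_slopes), c(0.01, 0.01))
})

test_that("isotropic jitter gives RMSF near sigma * sqrt(3)", {
  spec <- synth_traj_spec(n_residues = 40, temperatures_C = c(10, 47),
                          frames_per_window = 400, analysis_fraction = 1,
                          base_sigma = 0.25, thermal_coefficient = 0,
                          rigid_rotation_deg = 0, rigid_translation = 0,
                          seed = 13)
  b <- make_trajectory(spec)
  prof <- rmsf(b$trajectory, frames = 1:400)
  expect_equal(mean(prof$rmsf), 0.25 * sqrt(3), tolerance = 0.05)
})

test_that("a planted flexible loop carries the highest RMSF", {
  a <- rep(0.1, 50); a[20:26] <- 0.45
  spec <- synth_traj_spec(n_residues = 50, temperatures_C = c(10, 27),
                          frames_per_window = 200, base_sigma = a,
                          thermal_coefficient = 0.002, seed = 21)
  b <- make_trajectory(spec)
  prof <- rmsf(b$trajectory, frames = adaptsig:::analysis_frames(b$schedule, 1))
  top <- order(-prof$rmsf)[1:7]
  expect_true(all(prof$resno[top] %in% 20:26))
})

test_that("duplicating the frame set leaves RMSF unchanged", {
  spec <- synth_traj_spec(n_residues = 10, temperatures_C = c(10, 27),
                          frames_per_window = 30, seed = 2)
  b <- make_trajectory(spec)
  one <- rmsf(b$trajectory, frames = 1:30)
  two <- rmsf(b$trajectory, frames = c(1:30, 1:30))
  expect_equal(one$rmsf, two$rmsf, tolerance = 1e-12)
})

test_that("flexibility descriptors are invariant under a global rigid motion", {
  spec <- synth_traj_spec(n_residues = 12, temperatures_C = c(10, 47),
                          frames_per_window = 40, seed = 31)
  b <- make_trajectory(spec)
  set.seed(99)
  R <- random_rotation_matrix(); t <- c(4, -2, 9)
  moved <- b$trajectory
  for (f in seq_len(dim(moved$coords)[3]))
    moved$coords[, , f] <- sweep(moved$coords[, , f] %*% t(R), 2, t, FUN = "+")
  ref_moved <- sweep(b$reference %*% t(R), 2, t, FUN = "+")
  s1 <- rmsd_series(b$trajectory, reference = b$reference, schedule = b$schedule)
  s2 <- rmsd_series(moved, reference = ref_moved, schedule = b$schedule)
  expect_equal(s2$rmsd, s1$rmsd, tolerance = 1e-9)
  expect_equal(rmsf(moved, frames = 1:40)$rmsf,
               rmsf(b$trajectory, frames = 1:40)$rmsf, tolerance = 1e-9)
})

test_that("delta-RMSF flags exactly the residues at or above the threshold", {
  low <- structure(data.frame(chain = "A", resno = 1:10, resname = "ALA",
                              rmsf = rep(0.4, 10)),
                   class = c("rmsf_profile", "data.frame"))
  high <- low
  high$rmsf <- low$rmsf + c(rep(0.1, 5), 0.6, 0.49, 0.5, 0.51, 0.1)
  panel <- delta_rmsf(low, high, threshold = 0.5)
  expect_equal(panel$resno[panel$flagged], c(6, 8, 9))
  expect_false(panel$flagged[panel$resno == 7])   # 0.49 stays below
  none <- delta_rmsf(low, low)
  expect_false(any(none$flagged))
})

test_that("residue panels restrict and annotate the report", {
  low <- structure(data.frame(chain = "A", resno = 1:20, resname = "ALA",
                              rmsf = rep(0.3, 20)),
                   class = c("rmsf_profile", "data.frame"))
  high <- low; high$rmsf[3] <- 0.9
  out <- delta_rmsf(low, high, panel = list(catalytic = c(3, 7),
                                            binding = c(1, 2, 10)))
  expect_equal(nrow(out), 5L)
  expect_equal(sort(unique(out$subset)), c("binding", "catalytic"))
  expect_true(out$flagged[out$resno == 3])
  expect_error(delta_rmsf(low, high, panel = list(catalytic = 99)), "absent")
})
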