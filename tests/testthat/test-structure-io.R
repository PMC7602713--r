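test_that("a minimal one-residue file parses to 1 residue, 5 atoms", {
  path <- write_lines_pdb(ala_pdb_lines())
  m <- read_pdb(path)
  expect_equal(nrow(m$atoms), 5L)
  expect_equal(nrow(residues(m)), 1L)
  expect_equal(residues(m)$resname, "ALA")
})

test_that("altloc policies keep the right copy", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       1.500   0.100   0.000  0.40  0.00           C",
    "END")
  m <- read_pdb(write_lines_pdb(lines), altloc_policy = "highest_occupancy")
  ca <- m$atoms[m$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$altloc, "A")
  expect_equal(ca$occ, 0.6)
  m2 <- read_pdb(write_lines_pdb(lines), altloc_policy = "first")
  expect_equal(m2$atoms[m2$atoms$name == "CA", "altloc"], "A")
})

test_that("malformed fixed columns fail with the offending line number", {
  lines <- ala_pdb_lines()
  lines[3] <- "ATOM      3  C   ALA A   1       xx.009   1.420   0.000  1.00"
  expect_error(read_pdb(write_lines_pdb(lines)), "line 3")
})

test_that("a protein-free file is rejected", {
  lines <- c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
             "END")
  expect_error(read_pdb(write_lines_pdb(lines)), "no protein")
})

test_that("read-write-read round trip preserves atoms and coordinates", {
  b <- make_structure(synth_structure_spec(
    12, "ideal_helix",
    planted_contacts = data.frame(type = "salt_bridge", res_i = 2,
                                  res_j = 6, distance = 3.0)))
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_pdb(b$model, f1)
  m1 <- read_pdb(f1)
  write_pdb(m1, f2)
  m2 <- read_pdb(f2)
  expect_equal(nrow(m2$atoms), nrow(b$model$atoms))
  expect_equal(m2$atoms$name, m1$atoms$name)
  expect_equal(m2$atoms$chain, m1$atoms$chain)
  expect_equal(m2$atoms$x, m1$atoms$x)  # second pass is lossless
  # against the source model, fidelity is bounded by PDB precision
  expect_true(max(abs(m2$atoms$x - b$model$atoms$x)) <= 5e-4 + 1e-12)
})

test_that("assembly with the identity operator reproduces the input", {
  m <- build_backbone(10, "ideal_helix")
  out <- build_assembly(m, ops = list(list(R = diag(3), t = c(0, 0, 0))))
  expect_equal(nrow(out$atoms), nrow(m$atoms))
  expect_equal(out$atoms$x, m$atoms$x)
  expect_equal(unique(out$atoms$chain), "A")
})

test_that("k operators multiply targeted protein atoms by k, copies superpose exactly", {
  m <- build_backbone(10, "ideal_helix")
  rotz <- function(deg) {
    th <- deg * pi / 180
    matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
           byrow = TRUE)
  }
  ops <- lapply(c(0, 120, 240), function(a)
    list(R = rotz(a), t = as.numeric(rotz(a) %*% c(20, 0, 0))))
  out <- build_assembly(m, ops = ops)
  expect_equal(nrow(out$atoms), 3L * nrow(m$atoms))
  chains <- unique(out$atoms$chain)
  expect_length(chains, 3L)
  xyz <- function(ch) as.matrix(out$atoms[out$atoms$chain == ch, c("x", "y", "z")])
  fit <- superpose(xyz(chains[2]), xyz(chains[1]))
  expect_lt(fit$rmsd, 1e-8)
})

test_that("missing operators give an instructive error", {
  m <- build_backbone(5, "extended")
  expect_error(build_assembly(m), "supply `ops`")
})

test_that("seqres and atom sequences differ by unmodelled residues only", {
  dep <- get_test_deposit()
  f <- tempfile(fileext = ".pdb")
  write_pdb(dep$model, f)
  m <- read_pdb(f)
  s_full <- extract_sequence(m, source = "seqres")
  s_atom <- extract_sequence(m, source = "atom")
  expect_equal(nchar(s_full$sequence), 700L)
  expect_equal(nchar(s_atom$sequence), 668L)
  # the modelled sequence is the full sequence with the gap regions removed
  gaps <- sort(unlist(dep$manifest$gap_regions))
  expect_equal(s_atom$sequence,
               paste(strsplit(s_full$sequence, "")[[1]][-gaps], collapse = ""))
})

test_that("nonstandard residues map to X with a warning", {
  lines <- c(ala_pdb_lines()[1:5],
    "HETATM    6  SE  MSE A   2       5.000   0.000   0.000  1.00  0.00          SE",
    "ATOM      7  CA  MSE A   2       5.500   1.000   0.000  1.00  0.00           C",
    "END")
  m <- read_pdb(write_lines_pdb(lines))
  expect_warning(s <- extract_sequence(m, source = "atom"), "mapped to X")
  expect_equal(s$sequence, "AX")
})

test_that("FASTA round trip, duplicates, case and empty files behave", {
  recs <- list(adaptsig:::new_sequence_record("a", strrep("ACDEFGHIKL", 70)),
               adaptsig:::new_sequence_record("b", "MKV"))
  f <- tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(back[[1]]$sequence, recs[[1]]$sequence)
  expect_equal(vapply(back, `[[`, "", "id"), c("a", "b"))
  # wrapped at 60 columns
  expect_true(all(nchar(grep("^[^>]", readLines(f), value = TRUE)) <= 60))
  writeLines(c(">x", "acd", ">x", "MKV"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">x", "acdef"), f)
  expect_warning(lower <- read_fasta(f), "uppercased")
  expect_equal(lower[[1]]$sequence, "ACDEF")
  file.create(f2 <- tempfile())
  expect_equal(read_fasta(f2), list())
})

test_that("multi-model trajectories read back with constant atom order", {
  b <- make_trajectory(synth_traj_spec(n_residues = 5, temperatures_C = c(10, 27),
                                       frames_per_window = 3, seed = 2))
  f <- tempfile(fileext = ".pdb")
  write_trajectory(b$trajectory, f)
  t2 <- read_trajectory(f)
  expect_equal(dim(t2$coords), dim(b$trajectory$coords))
  expect_equal(t2$coords, b$trajectory$coords, tolerance = 1e-3)
  expect_equal(t2$atoms$name, b$trajectory$atoms$name)
})

test_that("three identical models give three frames with zero displacement", {
  block <- ala_pdb_lines()[1:5]
  lines <- c("MODEL        1", block, "ENDMDL",
             "MODEL        2", block, "ENDMDL",
             "MODEL        3", block, "ENDMDL", "END")
  traj <- read_trajectory(write_lines_pdb(lines))
  expect_equal(dim(traj$coords)[3], 3L)
  expect_equal(max(abs(traj$coords[, , 2] - traj$coords[, , 1])), 0)
})

test_that("a truncated frame is reported with its index", {
  block <- ala_pdb_lines()[1:5]
  lines <- c("MODEL        1", block, "ENDMDL",
             "MODEL        2", block[1:3], "ENDMDL", "END")
  expect_error(read_trajectory(write_lines_pdb(lines)), "frame 2")
})

test_that("whitespace XYZ frames parse and validate", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("3", "frame 1", "C 0 0 0", "C 1 0 0", "N 0 1 0",
               "3", "frame 2", "C 0 0 0.5", "C 1 0 0.5", "N 0 1 0.5"), f)
  traj <- read_trajectory(f, format = "xyz")
  expect_equal(dim(traj$coords), c(3L, 3L, 2L))
  expect_equal(traj$coords[1, 3, 2], 0.5)
  writeLines(c("3", "frame 1", "C 0 0 0", "C 1 0 0"), f)
  expect_error(read_trajectory(f, format = "xyz"), "frame 1")
})

test_that("window schedules enforce ordering, bounds and fractions", {
  s <- window_schedule(c(1, 101), c(100, 200), c(10, 27), 0.2)
  expect_s3_class(s, "window_schedule")
  expect_equal(adaptsig:::analysis_frames(s, 1), 81:100)
  expect_error(window_schedule(c(1, 50), c(100, 200), c(10, 27)), "overlap")
  expect_error(window_schedule(c(1, 101), c(100, 200), c(27, 10)),
               "strictly increasing")
  expect_error(window_schedule(1, 100, 10, analysis_fraction = 0), "analysis_fraction")
})
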