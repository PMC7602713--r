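# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; nothing is read from disk except files the tests write
# themselves.

# minimal structure model from an atom table sketch
tiny_model <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(serial = i, name = r$name, element = r$element %||% substr(r$name, 1, 1),
               altloc = r$altloc %||% "", resname = r$resname %||% "ALA",
               chain = r$chain %||% "A", resno = r$resno %||% 1L,
               icode = "", x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               occ = r$occ %||% 1, b = 0, is_het = isTRUE(r$is_het),
               stringsAsFactors = FALSE)
  }))
  adaptsig:::new_structure_model(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quaternion (Horn) absolute-orientation oracle, independent of the Kabsch
# SVD route used by superpose()
quaternion_fit_rmsd <- function(mobile, reference) {
  P <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  Q <- sweep(as.matrix(reference), 2, colMeans(reference))
  M <- crossprod(P, Q)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

# two flat zigzag strands, the second rotated 180 degrees about the strand
# axis and offset so alternating cross-strand amide bonds form
make_sheet_fixture <- function(n = 8, d = 4.2, slide = 0, rise = -0.5) {
  strandA <- build_backbone(n, "extended", phi = -180, psi = 180)
  A <- strandA$atoms
  ca <- as.matrix(A[A$name == "CA", c("x", "y", "z")])
  u <- ca[n, ] - ca[1, ]; u <- u / sqrt(sum(u^2))
  p0 <- colMeans(ca)
  w <- c(u[2], -u[1], 0); w <- w / sqrt(sum(w^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R180 <- diag(3) + 2 * (K %*% K)   # Rodrigues at theta = pi
  xyz <- sweep(as.matrix(A[, c("x", "y", "z")]), 2, p0)
  xyz <- sweep(xyz %*% t(R180), 2,
               p0 + d * w + slide * u + c(0, 0, rise), FUN = "+")
  B <- A
  B$x <- xyz[, 1]; B$y <- xyz[, 2]; B$z <- xyz[, 3]
  B$resno <- B$resno + 20L
  comb <- strandA
  comb$atoms <- rbind(A, B)
  comb$atoms$serial <- seq_len(nrow(comb$atoms))
  comb
}

# deposit generation is the most expensive fixture; build it once per run
deposit_cache <- new.env(parent = emptyenv())
get_test_deposit <- function() {
  if (is.null(deposit_cache$dep))
    deposit_cache$dep <- synthetic_deposit()
  deposit_cache$dep
}

write_lines_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

# hand-written one-residue PDB (ALA, 5 atoms) in strict fixed columns
ala_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "END")
}
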