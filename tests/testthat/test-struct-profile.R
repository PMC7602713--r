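test_that("isolated-sphere SASA matches the analytic area within 1%", {
  m <- tiny_model(list(name = "CA", element = "C", xyz = c(0, 0, 0)))
  analytic <- 4 * pi * (1.7 + 1.4)^2
  s <- sasa(m, n_points = 960)
  expect_lt(abs(s$total / analytic - 1), 0.01)
  # other elements and probe radii too
  m2 <- tiny_model(list(name = "O", element = "O", xyz = c(0, 0, 0)))
  expect_lt(abs(sasa(m2, probe_radius = 1.2)$total /
                (4 * pi * (1.52 + 1.2)^2) - 1), 0.01)
})

test_that("distant atoms contribute independent areas", {
  m <- tiny_model(list(name = "CA", element = "C", xyz = c(0, 0, 0)),
                  list(name = "CA", element = "C", xyz = c(100, 0, 0),
                       resno = 2L))
  expect_equal(sasa(m)$total, 2 * 4 * pi * 3.1^2, tolerance = 0.01)
})

test_that("an enclosed residue has zero accessible area and is buried", {
  b <- make_structure(synth_structure_spec(9, "extended", planted_burial = 5L))
  sr <- sasa(b$model)
  caged <- sr$residue[sr$residue$resno == 5, ]
  expect_equal(caged$area, 0)
  sp <- classify_surface(sr)
  expect_false(sp$residue$surface[sp$residue$resno == 5])
  # chain ends away from the cage stay exposed
  expect_true(sp$residue$surface[sp$residue$resno == 1])
})

test_that("SASA is invariant under rigid motion and monotone in occlusion", {
  m <- build_backbone(8, "ideal_helix")
  s1 <- sasa(m, n_points = 480)
  set.seed(3)
  R <- random_rotation_matrix()
  m2 <- m
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
  m2$atoms$x <- xyz[, 1] + 5; m2$atoms$y <- xyz[, 2] - 3; m2$atoms$z <- xyz[, 3] + 1
  s2 <- sasa(m2, n_points = 480)
  # the deterministic point grid is not rotated with the molecule, so areas
  # agree to sampling resolution rather than exactly
  expect_equal(s2$total, s1$total, tolerance = 0.01)
  # adding a neighbour can only remove area from existing atoms
  m3 <- m
  extra <- m$atoms[1, ]; extra$serial <- 99L; extra$resno <- 99L
  extra$x <- mean(m$atoms$x); extra$y <- mean(m$atoms$y); extra$z <- mean(m$atoms$z)
  m3$atoms <- rbind(m3$atoms, extra)
  s3 <- sasa(m3, n_points = 480)
  shared <- seq_len(nrow(m$atoms))
  expect_true(all(s3$atom$area[shared] <= s1$atom$area[shared] + 1e-9))
})

test_that("unknown elements are reported by name", {
  m <- tiny_model(list(name = "XX", element = "XX", xyz = c(0, 0, 0)))
  expect_error(sasa(m), "XX")
})

test_that("raising the surface threshold never adds surface residues", {
  b <- make_structure(synth_structure_spec(20, "ideal_helix"))
  sr <- sasa(b$model, n_points = 480)
  prev <- classify_surface(sr, threshold = 0.05)$n_surface
  for (thr in c(0.10, 0.25, 0.50, 0.90)) {
    cur <- classify_surface(sr, threshold = thr)$n_surface
    expect_lte(cur, prev)
    prev <- cur
  }
  expect_false(any(classify_surface(sr, 0.10)$residue$rel_acc[
    !classify_surface(sr, 0.10)$residue$surface] > 0.10))
})

test_that("an ideal backbone amide pair is a hydrogen bond inside the cutoffs", {
  # C=O of residue 1 and N(-H) of residue 30 (different chain ends folded
  # close): build explicitly from two dipeptides
  mk_pair <- function(d_no) {
    # acceptor: C at origin, O along +x; donor N at distance d_no from O
    # with its CA and preceding C placed for a near-linear N-H...O angle
    tiny_model(
      list(name = "CA", element = "C", xyz = c(-1.5, 0, 0), resno = 1L),
      list(name = "C", element = "C", xyz = c(0, 0, 0), resno = 1L),
      list(name = "O", element = "O", xyz = c(1.23, 0, 0), resno = 1L),
      list(name = "N", element = "N", xyz = c(1.23 + d_no, 0, 0), resno = 5L),
      list(name = "CA", element = "C", xyz = c(1.23 + d_no + 1.0, 1.0, 0), resno = 5L),
      list(name = "C", element = "C", xyz = c(1.23 + d_no + 2.2, 0.6, 0), resno = 5L),
      # previous residue's C=O defining the amide H direction
      list(name = "C", element = "C", xyz = c(1.23 + d_no + 0.8, -1.0, 0), resno = 4L),
      list(name = "O", element = "O", xyz = c(1.23 + d_no + 1.6, -1.8, 0), resno = 4L),
      list(name = "CA", element = "C", xyz = c(1.23 + d_no - 0.5, -1.8, 0), resno = 4L))
  }
  hb <- hydrogen_bonds(mk_pair(2.9))
  pair <- hb$hydrogen_bonds[hb$hydrogen_bonds$donor_resno == 5 &
                            hb$hydrogen_bonds$acceptor_resno == 1, ]
  expect_equal(nrow(pair), 1L)
  expect_gt(pair$angle, 120)
  hb_far <- hydrogen_bonds(mk_pair(4.2))
  expect_equal(nrow(hb_far$hydrogen_bonds[
    hb_far$hydrogen_bonds$donor_resno == 5 &
    hb_far$hydrogen_bonds$acceptor_resno == 1, ]), 0L)
})

test_that("salt bridges obey the N-O distance rule and pair uniqueness", {
  mk <- function(d) tiny_model(
    list(name = "NZ", element = "N", xyz = c(0, 0, 0), resname = "LYS", resno = 1L),
    list(name = "OD1", element = "O", xyz = c(d, 0, 0), resname = "ASP", resno = 9L),
    list(name = "OD2", element = "O", xyz = c(d, 1.2, 0), resname = "ASP", resno = 9L))
  expect_equal(nrow(salt_bridges(mk(3.0))$salt_bridges), 1L)  # one per pair
  expect_equal(nrow(salt_bridges(mk(5.0))$salt_bridges), 0L)
  sb <- salt_bridges(mk(3.0))$salt_bridges
  expect_equal(sb$min_distance, 3.0)
})

test_that("histidine counts as basic only on request", {
  m <- tiny_model(
    list(name = "ND1", element = "N", xyz = c(0, 0, 0), resname = "HIS", resno = 1L),
    list(name = "OE1", element = "O", xyz = c(2.9, 0, 0), resname = "GLU", resno = 5L))
  expect_equal(nrow(salt_bridges(m)$salt_bridges), 0L)
  expect_equal(nrow(salt_bridges(m, include_his = TRUE)$salt_bridges), 1L)
})

test_that("planted contacts are recovered exactly, inside and outside cutoffs", {
  pc <- data.frame(type = c("hbond", "hbond", "salt_bridge", "salt_bridge"),
                   res_i = c(2, 10, 20, 28),
                   res_j = c(6, 14, 24, 32),
                   distance = c(2.9, 4.2, 3.0, 4.5))
  b <- make_structure(synth_structure_spec(36, "extended", planted_contacts = pc))
  hb <- hydrogen_bonds(b$model)
  sb <- salt_bridges(b$model)
  # positives: one planted hbond + the ion pair (which satisfies both rules)
  expect_equal(nrow(hb$hydrogen_bonds), b$manifest$n_hbonds + b$manifest$n_salt_bridges)
  expect_equal(nrow(sb$salt_bridges), b$manifest$n_salt_bridges)
  expect_equal(b$manifest$n_hbonds, 1L)
  expect_equal(b$manifest$n_salt_bridges, 1L)
})

test_that("contacts are invariant under a global rigid motion", {
  pc <- data.frame(type = c("hbond", "salt_bridge"), res_i = c(2, 10),
                   res_j = c(6, 14), distance = c(2.9, 3.0))
  b <- make_structure(synth_structure_spec(18, "extended", planted_contacts = pc))
  set.seed(11)
  R <- random_rotation_matrix()
  m2 <- b$model
  xyz <- as.matrix(m2$atoms[, c("x", "y", "z")]) %*% t(R)
  m2$atoms$x <- xyz[, 1] + 7; m2$atoms$y <- xyz[, 2] + 1; m2$atoms$z <- xyz[, 3] - 4
  expect_equal(nrow(hydrogen_bonds(m2)$hydrogen_bonds),
               nrow(hydrogen_bonds(b$model)$hydrogen_bonds))
  expect_equal(nrow(salt_bridges(m2)$salt_bridges),
               nrow(salt_bridges(b$model)$salt_bridges))
})

test_that("an ideal helix is assigned >= 90% helix", {
  ss <- secondary_structure(build_backbone(20, "ideal_helix"))
  expect_gte(ss$helix_pct, 90)
  expect_equal(ss$strand_pct, 0)
})

test_that("an isolated extended chain has no helix and no strand", {
  ss <- secondary_structure(build_backbone(20, "extended"))
  expect_equal(ss$helix_pct, 0)
  expect_equal(ss$strand_pct, 0)
})

test_that("a two-strand fixture yields strand labels on inner residues", {
  ss <- secondary_structure(make_sheet_fixture())
  labs <- ss$residue
  inner <- labs$label[labs$resno %in% c(3, 5, 7)]
  expect_true(any(inner == "E"))
  expect_equal(sum(ss$labels == "E") %% 2, 0)  # symmetric across strands
  expect_equal(ss$helix_pct, 0)
})

test_that("interface burial is zero at infinite separation and matches caps in contact", {
  a <- tiny_model(list(name = "CA", element = "C", xyz = c(0, 0, 0)))
  b_far <- tiny_model(list(name = "CA", element = "C", xyz = c(500, 0, 0)))
  asm_far <- a
  asm_far$atoms <- rbind(a$atoms, transform(b_far$atoms, serial = 2L, chain = "B"))
  ib0 <- interface_burial(asm_far)
  expect_equal(ib0$buried_area, 0, tolerance = 1e-9)
  # two identical spheres at distance d: each loses a cap 2*pi*R*(R - d/2)
  d <- 4.0; R <- 1.7 + 1.4
  asm <- a
  asm$atoms <- rbind(a$atoms, transform(a$atoms, serial = 2L, chain = "B", x = d))
  ib <- interface_burial(asm)
  expect_equal(ib$buried_area, 2 * 2 * pi * R * (R - d / 2), tolerance = 0.02)
  expect_gte(ib$buried_area, 0)
})
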