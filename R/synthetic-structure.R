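# Internal-coordinate (NeRF) atom placement: position D given bonded chain
# A-B-C, the C-D bond length, the B-C-D angle and the A-B-C-D dihedral
# (degrees).
place_atom <- function(a, b, c, length, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(dih),
          length * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ca_cb = 1.53,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.5, ang_n_ca_cb = 110.5)

#' Build an ideal polypeptide backbone
#'
#' Deterministic full-backbone (N, CA, C, O, plus CB except glycine) chain
#' from standard bond geometry and fixed dihedrals:
#' `ideal_helix` phi/psi = -57/-47, `extended` -139/135, `ring` an extended
#' chain closed smoothly into a circle by distributing the turn over the psi
#' dihedrals.
#'
#' @param n_residues Number of residues.
#' @param geometry `"ideal_helix"`, `"extended"` or `"ring"`.
#' @param sequence Optional one-letter sequence (defaults to poly-alanine).
#' @param chain Chain identifier.
#' @param phi,psi Optional dihedral overrides (degrees) replacing the
#'   geometry preset, e.g. `phi = -180, psi = 180` for a flat zigzag strand.
#' @return A `structure_model`.
#' @export
build_backbone <- function(n_residues,
                           geometry = c("ideal_helix", "extended", "ring"),
                           sequence = NULL, chain = "A",
                           phi = NULL, psi = NULL) {
  geometry <- match.arg(geometry)
  if (is.null(sequence)) sequence <- strrep("A", n_residues)
  if (inherits(sequence, "sequence_record")) sequence <- sequence$sequence
  stopifnot(nchar(sequence) == n_residues)
  aa1 <- strsplit(sequence, "")[[1]]
  if (geometry == "ring" && is.null(phi))
    return(build_ring(n_residues, aa1, chain))
  phi <- phi %||% switch(geometry, ideal_helix = -57, extended = -139,
                         ring = -139)
  psi <- psi %||% switch(geometry, ideal_helix = -47, extended = 135,
                         ring = 135)
  psi_vec <- rep(psi, n_residues)

  g <- BB_GEOM
  pos <- list()
  # residue 1 seeded explicitly
  N1 <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  C1 <- place_atom(c(-1, 1, 0), N1, CA1, g$ca_c, g$ang_n_ca_c, phi)
  pos[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n_residues)[-1]) {
    pr <- pos[[i - 1]]
    Ni <- place_atom(pr$N, pr$CA, pr$C, g$c_n, g$ang_ca_c_n, psi_vec[i - 1])
    CAi <- place_atom(pr$CA, pr$C, Ni, g$n_ca, g$ang_c_n_ca, 180)
    Ci <- place_atom(pr$C, Ni, CAi, g$ca_c, g$ang_n_ca_c, phi)
    pos[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  rows <- list()
  for (i in seq_len(n_residues)) {
    p <- pos[[i]]
    # carbonyl O opposite the next amide (psi + 180)
    O <- place_atom(p$N, p$CA, p$C, g$c_o, g$ang_ca_c_o, psi_vec[i] + 180)
    res <- list(N = p$N, CA = p$CA, C = p$C, O = O)
    if (aa1[i] != "G")
      res$CB <- place_atom(p$C, p$N, p$CA, g$ca_cb, g$ang_n_ca_cb, -122)
    rows[[i]] <- res
  }
  atoms_from_positions(rows, aa1, chain = chain)
}

# closed circular chain: CA sites on a circle at ideal CA-CA spacing, local
# backbone atoms along the tangent so consecutive C-N distances stay
# peptide-like; the chain's last residue neighbours its first
build_ring <- function(n_residues, aa1, chain = "A") {
  radius <- n_residues * 3.8 / (2 * pi)
  rows <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    th <- 2 * pi * (i - 1) / n_residues
    radial <- c(cos(th), sin(th), 0)
    tangent <- c(-sin(th), cos(th), 0)
    ca <- radius * radial
    res <- list(N = ca - 1.2 * tangent, CA = ca, C = ca + 1.2 * tangent,
                O = ca + 1.2 * tangent + 1.1 * radial)
    if (aa1[i] != "G") res$CB <- ca + c(0, 0, 1.1) - 0.9 * radial
    rows[[i]] <- res
  }
  atoms_from_positions(rows, aa1, chain = chain)
}

atoms_from_positions <- function(rows, aa1, chain = "A",
                                 resno = seq_along(rows)) {
  recs <- list()
  serial <- 0L
  for (i in seq_along(rows)) {
    for (nm in names(rows[[i]])) {
      serial <- serial + 1L
      p <- rows[[i]][[nm]]
      recs[[serial]] <- data.frame(
        serial = serial, name = nm,
        element = substr(nm, 1, 1), altloc = "",
        resname = unname(AA3[aa1[i]]), chain = chain, resno = resno[i],
        icode = "", x = p[1], y = p[2], z = p[3], occ = 1, b = 0,
        is_het = FALSE, stringsAsFactors = FALSE)
    }
  }
  new_structure_model(do.call(rbind, recs))
}

#' Specification for a synthetic structure with planted ground truth
#'
#' @param n_residues Chain length.
#' @param geometry Backbone geometry, see [build_backbone()].
#' @param planted_contacts Data frame with columns `type` ("hbond" or
#'   "salt_bridge"), `res_i`, `res_j`, `distance` (target heavy-atom
#'   distance, Angstrom). Distances inside the detector's cutoff plant
#'   positives; distances outside plant negatives.
#' @param planted_burial Residue numbers to enclose in an occluding cage.
#' @param sequence Optional sequence (defaults to poly-alanine).
#' @param seed Integer seed (reserved; the construction is deterministic).
#' @return A `synth_structure_spec` list.
#' @export
synth_structure_spec <- function(n_residues, geometry = "ideal_helix",
                                 planted_contacts = NULL,
                                 planted_burial = integer(),
                                 sequence = NULL, seed = 1L) {
  if (!is.null(planted_contacts)) {
    stopifnot(all(c("type", "res_i", "res_j", "distance") %in%
                  names(planted_contacts)),
              all(planted_contacts$type %in% c("hbond", "salt_bridge")),
              all(planted_contacts$res_i <= n_residues),
              all(planted_contacts$res_j <= n_residues),
              all(planted_contacts$res_i != planted_contacts$res_j))
  }
  structure(list(n_residues = n_residues, geometry = geometry,
                 planted_contacts = planted_contacts,
                 planted_burial = as.integer(planted_burial),
                 sequence = sequence, seed = as.integer(seed)),
            class = "synth_structure_spec")
}

# Re-type a residue and attach planted side-chain atoms. `role` decides the
# residue identity: hbond donor -> SER OG, hbond acceptor -> ASN OD1,
# salt-bridge basic -> LYS NZ, salt-bridge acidic -> ASP OD1.
plant_atom_spec <- function(type, side) {
  if (type == "hbond") {
    if (side == 1) list(resname = "SER", atom = "OG")
    else list(resname = "ASN", atom = "OD1")
  } else {
    if (side == 1) list(resname = "LYS", atom = "NZ")
    else list(resname = "ASP", atom = "OD1")
  }
}

add_planted_atom <- function(model, resno, chain, resname, atom_name, pos) {
  atoms <- model$atoms
  sel <- atoms$resno == resno & atoms$chain == chain
  atoms$resname[sel] <- resname
  new_row <- atoms[which(sel)[1], ]
  new_row$name <- atom_name
  new_row$element <- substr(atom_name, 1, 1)
  new_row$x <- pos[1]; new_row$y <- pos[2]; new_row$z <- pos[3]
  atoms <- rbind(atoms, new_row)
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  model$atoms <- atoms
  model
}

# unit vector from CA to CB (zero vector for glycine)
side_chain_direction <- function(model, resno, chain = NULL) {
  a <- model$atoms
  if (is.null(chain)) chain <- a$chain[1]
  sel <- a[a$resno == resno & a$chain == chain, , drop = FALSE]
  ca <- sel[sel$name == "CA", , drop = FALSE]
  cb <- sel[sel$name == "CB", , drop = FALSE]
  if (!nrow(cb) || !nrow(ca)) return(c(0, 0, 0))
  v <- c(cb$x[1] - ca$x[1], cb$y[1] - ca$y[1], cb$z[1] - ca$z[1])
  v / sqrt(sum(v^2))
}

residue_anchor <- function(model, resno, chain = NULL) {
  a <- model$atoms
  if (is.null(chain)) chain <- a$chain[1]
  sel <- a[a$resno == resno & a$chain == chain, , drop = FALSE]
  cb <- sel[sel$name == "CB", , drop = FALSE]
  if (!nrow(cb)) cb <- sel[sel$name == "CA", , drop = FALSE]
  c(cb$x[1], cb$y[1], cb$z[1])
}

#' Generate a synthetic structure with known contacts and burial
#'
#' Builds the requested backbone, then plants each contact by re-typing the
#' two residues and attaching minimal side-chain atoms along the line
#' between the residues' anchor points at exactly the requested heavy-atom
#' distance (hydrogen bonds: Ser OG donor to Asn OD1 acceptor; salt bridges:
#' Lys NZ to Asp OD1). Buried residues are enclosed in a cage of glycine
#' backbone units dense enough that no probe-sized sphere reaches them.
#'
#' The returned manifest records the exact expected detector output:
#' positive planted hydrogen-bond and salt-bridge counts (planted distances
#' within the default cutoffs) and the buried residue set.
#'
#' @param spec A [synth_structure_spec()].
#' @return List with `model` (a `structure_model`) and `manifest`.
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "synth_structure_spec"))
  model <- build_backbone(spec$n_residues, spec$geometry, spec$sequence)
  manifest <- list(n_hbonds = 0L, n_salt_bridges = 0L,
                   buried = spec$planted_burial,
                   contacts = spec$planted_contacts)
  pc <- spec$planted_contacts
  if (!is.null(pc)) {
    for (k in seq_len(nrow(pc))) {
      ai <- residue_anchor(model, pc$res_i[k])
      aj <- residue_anchor(model, pc$res_j[k])
      u <- aj - ai
      gap <- sqrt(sum(u^2))
      u <- u / gap
      # lift the contact pair off the anchor-anchor line along the mean
      # side-chain direction so planted atoms clear the backbone in between
      lift <- side_chain_direction(model, pc$res_i[k]) +
        side_chain_direction(model, pc$res_j[k])
      lift <- lift - sum(lift * u) * u
      nl <- sqrt(sum(lift^2))
      mid <- (ai + aj) / 2
      if (nl > 1e-6) mid <- mid + lift / nl * 2.5
      p1 <- mid - u * pc$distance[k] / 2
      p2 <- mid + u * pc$distance[k] / 2
      s1 <- plant_atom_spec(pc$type[k], 1)
      s2 <- plant_atom_spec(pc$type[k], 2)
      model <- add_planted_atom(model, pc$res_i[k], "A", s1$resname, s1$atom, p1)
      model <- add_planted_atom(model, pc$res_j[k], "A", s2$resname, s2$atom, p2)
      if (pc$type[k] == "hbond" && pc$distance[k] <= 3.5)
        manifest$n_hbonds <- manifest$n_hbonds + 1L
      if (pc$type[k] == "salt_bridge" && pc$distance[k] <= 3.2)
        manifest$n_salt_bridges <- manifest$n_salt_bridges + 1L
    }
  }
  for (r in spec$planted_burial) model <- cage_residue(model, r)
  list(model = model, manifest = manifest)
}

# Enclose a residue's atoms in two concentric shells of glycine backbone
# units so that no probe-accessible point survives on it.
cage_residue <- function(model, resno, chain = "A") {
  a <- model$atoms
  sel <- a[a$resno == resno & a$chain == chain, , drop = FALSE]
  centre <- c(mean(sel$x), mean(sel$y), mean(sel$z))
  spread <- max(sqrt((sel$x - centre[1])^2 + (sel$y - centre[2])^2 +
                     (sel$z - centre[3])^2))
  next_resno <- max(a$resno) + 1L
  rows <- list(); aa <- character()
  for (radius in c(spread + 3.4, spread + 5.4)) {
    n_pts <- ceiling(4 * pi * radius^2 / 4.5)
    pts <- fibonacci_sphere(n_pts) * radius
    for (p in seq_len(n_pts)) {
      site <- centre + pts[p, ]
      rows[[length(rows) + 1L]] <- list(
        N = site + c(-0.6, 0, 0), CA = site, C = site + c(0.6, 0, 0),
        O = site + c(0.9, 0.8, 0))
      aa <- c(aa, "G")
    }
  }
  cage <- atoms_from_positions(rows, aa, chain = chain,
                               resno = next_resno + seq_along(rows) - 1L)
  atoms <- rbind(a, cage$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  model$atoms <- atoms
  model
}
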