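# Donor/acceptor dictionaries for hydrogen-bond detection. Antecedent atoms
# give a crude directionality check when an explicit hydrogen cannot be
# inferred (side-chain donors); the backbone amide H is inferred from the
# preceding peptide geometry.
SIDECHAIN_DONORS <- list(
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  ASN = c(ND2 = "CG"), GLN = c(NE2 = "CD"), LYS = c(NZ = "CE"),
  ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  HIS = c(ND1 = "CG", NE2 = "CD2"), TRP = c(NE1 = "CD1")
)

SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2")
)

BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
BASIC_ATOMS_HIS <- c(BASIC_ATOMS, list(HIS = c("ND1", "NE2")))
ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

atom_key <- function(a) paste(a$chain, a$resno, a$icode, sep = "|")

# Inferred backbone amide H positions: H sits 1 A from N along the bisector
# of the two in-plane directions away from CA and away from the preceding C.
infer_amide_h <- function(atoms) {
  n_idx <- which(atoms$name == "N" & !atoms$is_het)
  out <- matrix(NA_real_, nrow(atoms), 3)
  key <- atom_key(atoms)
  ca <- atoms[atoms$name == "CA", ]
  cc <- atoms[atoms$name == "C", ]
  key_ca <- atom_key(ca); key_c <- atom_key(cc)
  for (i in n_idx) {
    if (atoms$resname[i] == "PRO") next
    k <- key[i]
    ica <- match(k, key_ca)
    if (is.na(ica)) next
    npos <- c(atoms$x[i], atoms$y[i], atoms$z[i])
    # preceding residue's C: nearest C atom within peptide-bond range
    dc <- sqrt((cc$x - npos[1])^2 + (cc$y - npos[2])^2 + (cc$z - npos[3])^2)
    prev <- which(key_c != k & dc < 1.6)
    v1 <- npos - c(ca$x[ica], ca$y[ica], ca$z[ica])
    v1 <- v1 / sqrt(sum(v1^2))
    if (length(prev)) {
      j <- prev[which.min(dc[prev])]
      v2 <- npos - c(cc$x[j], cc$y[j], cc$z[j])
      v2 <- v2 / sqrt(sum(v2^2))
      h_dir <- v1 + v2
    } else {
      h_dir <- v1  # chain start: point away from CA
    }
    nrm <- sqrt(sum(h_dir^2))
    if (nrm < 1e-6) next
    out[i, ] <- npos + h_dir / nrm
  }
  out
}

collect_donors <- function(atoms) {
  key <- atom_key(atoms)
  rows <- integer(); ante <- integer(); kind <- character()
  bb_n <- which(atoms$name == "N" & !atoms$is_het & atoms$resname != "PRO")
  rows <- c(rows, bb_n); ante <- c(ante, rep(NA_integer_, length(bb_n)))
  kind <- c(kind, rep("backbone", length(bb_n)))
  for (rn in names(SIDECHAIN_DONORS)) {
    spec <- SIDECHAIN_DONORS[[rn]]
    idx <- which(atoms$resname == rn & atoms$name %in% names(spec) & !atoms$is_het)
    if (!length(idx)) next
    a_idx <- vapply(idx, function(i) {
      want <- spec[[atoms$name[i]]]
      hit <- which(key == key[i] & atoms$name == want)
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    rows <- c(rows, idx); ante <- c(ante, a_idx)
    kind <- c(kind, rep("sidechain", length(idx)))
  }
  data.frame(idx = rows, ante = ante, kind = kind, stringsAsFactors = FALSE)
}

collect_acceptors <- function(atoms) {
  idx <- which((atoms$name %in% c("O", "OXT") & !atoms$is_het))
  for (rn in names(SIDECHAIN_ACCEPTORS))
    idx <- c(idx, which(atoms$resname == rn &
                        atoms$name %in% SIDECHAIN_ACCEPTORS[[rn]] &
                        !atoms$is_het))
  unique(idx)
}

vec_angle <- function(a, b) {
  # angle at the midpoint of a->0->b triples, degrees
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2)) * sqrt(rowSums(b^2))
  acos(pmin(1, pmax(-1, num / den))) * 180 / pi
}

#' Enumerate hydrogen bonds
#'
#' Geometric criterion: donor and acceptor heavy atoms (N/O) within `d_max`,
#' plus a directionality test. For backbone amide donors the hydrogen is
#' inferred from the peptide geometry and the D-H...A angle must be at least
#' `angle_min`; for side-chain donors the antecedent-donor-acceptor angle
#' must be at least 90 degrees (rotatable hydrogens make a sharper test
#' unreliable without placed hydrogens). Same-residue pairs and directly
#' bonded backbone neighbours are excluded. Each bond is flagged intra- or
#' inter-chain.
#'
#' @param model A `structure_model`.
#' @param d_max Donor-acceptor heavy-atom cutoff, Angstrom (default 3.5).
#' @param angle_min Minimum D-H...A angle in degrees for backbone donors
#'   (default 120).
#' @return A `contact_set` whose `hydrogen_bonds` element is a data frame
#'   with donor/acceptor identities, distance, angle and `inter_chain`.
#' @export
hydrogen_bonds <- function(model, d_max = 3.5, angle_min = 120) {
  atoms <- model$atoms[model$atoms$resname != "HOH", , drop = FALSE]
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  don <- collect_donors(atoms)
  acc <- collect_acceptors(atoms)
  bonds <- empty_hbond_df()
  if (nrow(don) && length(acc)) {
    hpos <- infer_amide_h(atoms)
    dxyz <- as.matrix(atoms[don$idx, c("x", "y", "z")])
    axyz <- as.matrix(atoms[acc, c("x", "y", "z")])
    pairs <- close_pairs(dxyz, axyz, d_max)
    if (nrow(pairs)) {
      di <- don$idx[pairs[, 1]]
      ai <- acc[pairs[, 2]]
      keep <- rep(TRUE, length(di))
      key <- atom_key(atoms)
      # same residue out; bonded backbone neighbours (N_i+1 ... O_i) out
      keep[key[di] == key[ai]] <- FALSE
      adjacent_bb <- atoms$name[di] == "N" & atoms$name[ai] == "O" &
        atoms$chain[di] == atoms$chain[ai] &
        abs(atoms$resno[di] - atoms$resno[ai]) == 1L
      keep[adjacent_bb & atoms$resno[di] > atoms$resno[ai]] <- FALSE
      angle <- rep(NA_real_, length(di))
      for (q in which(keep)) {
        i <- di[q]; j <- ai[q]
        apos <- c(atoms$x[j], atoms$y[j], atoms$z[j])
        if (don$kind[pairs[q, 1]] == "backbone") {
          if (!is.na(hpos[i, 1])) {
            h <- hpos[i, ]
            ang <- vec_angle(matrix(c(atoms$x[i], atoms$y[i], atoms$z[i]) - h, 1),
                             matrix(apos - h, 1))
            angle[q] <- ang
            if (ang < angle_min) keep[q] <- FALSE
          }
        } else {
          anteq <- don$ante[pairs[q, 1]]
          if (!is.na(anteq)) {
            dpos <- c(atoms$x[i], atoms$y[i], atoms$z[i])
            ang <- vec_angle(matrix(c(atoms$x[anteq], atoms$y[anteq],
                                      atoms$z[anteq]) - dpos, 1),
                             matrix(apos - dpos, 1))
            angle[q] <- ang
            if (ang < 90) keep[q] <- FALSE
          }
        }
      }
      sel <- which(keep)
      bonds <- data.frame(
        donor_chain = atoms$chain[di[sel]], donor_resno = atoms$resno[di[sel]],
        donor_resname = atoms$resname[di[sel]], donor_atom = atoms$name[di[sel]],
        acceptor_chain = atoms$chain[ai[sel]],
        acceptor_resno = atoms$resno[ai[sel]],
        acceptor_resname = atoms$resname[ai[sel]],
        acceptor_atom = atoms$name[ai[sel]],
        distance = pairs[sel, 3], angle = angle[sel],
        inter_chain = atoms$chain[di[sel]] != atoms$chain[ai[sel]],
        stringsAsFactors = FALSE)
    }
  }
  new_contact_set(hydrogen_bonds = bonds)
}

empty_hbond_df <- function() {
  data.frame(donor_chain = character(), donor_resno = integer(),
             donor_resname = character(), donor_atom = character(),
             acceptor_chain = character(), acceptor_resno = integer(),
             acceptor_resname = character(), acceptor_atom = character(),
             distance = numeric(), angle = numeric(),
             inter_chain = logical(), stringsAsFactors = FALSE)
}

empty_sb_df <- function() {
  data.frame(basic_chain = character(), basic_resno = integer(),
             basic_resname = character(), acidic_chain = character(),
             acidic_resno = integer(), acidic_resname = character(),
             min_distance = numeric(), inter_chain = logical(),
             stringsAsFactors = FALSE)
}

new_contact_set <- function(hydrogen_bonds = empty_hbond_df(),
                            salt_bridges = empty_sb_df()) {
  structure(list(hydrogen_bonds = hydrogen_bonds,
                 salt_bridges = salt_bridges),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  hb <- x$hydrogen_bonds; sb <- x$salt_bridges
  cat(sprintf("contact_set: %d hydrogen bond(s) (%d inter-chain), %d salt bridge(s) (%d inter-chain)\n",
              nrow(hb), sum(hb$inter_chain), nrow(sb), sum(sb$inter_chain)))
  invisible(x)
}

#' Enumerate salt bridges
#'
#' A basic residue (Lys NZ; Arg NH1/NH2/NE; optionally His ND1/NE2) and an
#' acidic residue (Asp OD1/OD2, Glu OE1/OE2) form a salt bridge when any of
#' their side-chain N-O distances is at most `cutoff`. Each residue pair is
#' counted once, with the minimum N-O distance reported and an
#' intra-/inter-chain flag.
#'
#' @param model A `structure_model`.
#' @param cutoff Side-chain N-O distance cutoff, Angstrom (default 3.2, the
#'   common trajectory-analysis convention).
#' @param include_his Treat histidine as basic (default FALSE).
#' @return A `contact_set` whose `salt_bridges` element is a per-residue-pair
#'   data frame.
#' @export
salt_bridges <- function(model, cutoff = 3.2, include_his = FALSE) {
  atoms <- model$atoms[!model$atoms$is_het & model$atoms$resname != "HOH", ,
                       drop = FALSE]
  basic_spec <- if (include_his) BASIC_ATOMS_HIS else BASIC_ATOMS
  bi <- integer(); ai <- integer()
  for (rn in names(basic_spec))
    bi <- c(bi, which(atoms$resname == rn & atoms$name %in% basic_spec[[rn]]))
  for (rn in names(ACIDIC_ATOMS))
    ai <- c(ai, which(atoms$resname == rn & atoms$name %in% ACIDIC_ATOMS[[rn]]))
  if (!length(bi) || !length(ai)) return(new_contact_set())
  pairs <- close_pairs(as.matrix(atoms[bi, c("x", "y", "z")]),
                       as.matrix(atoms[ai, c("x", "y", "z")]), cutoff)
  if (!nrow(pairs)) return(new_contact_set())
  b <- bi[pairs[, 1]]; a <- ai[pairs[, 2]]
  pair_key <- paste(atom_key(atoms)[b], atom_key(atoms)[a], sep = "::")
  # one bridge per residue pair: keep the minimum-distance atom pair
  o <- order(pairs[, 3])
  first <- o[!duplicated(pair_key[o])]
  sb <- data.frame(
    basic_chain = atoms$chain[b[first]], basic_resno = atoms$resno[b[first]],
    basic_resname = atoms$resname[b[first]],
    acidic_chain = atoms$chain[a[first]],
    acidic_resno = atoms$resno[a[first]],
    acidic_resname = atoms$resname[a[first]],
    min_distance = pairs[first, 3],
    inter_chain = atoms$chain[b[first]] != atoms$chain[a[first]],
    stringsAsFactors = FALSE)
  new_contact_set(salt_bridges = sb)
}

#' Summarise contact counts
#'
#' Emits total, intra- and inter-chain counts. Hydrogen bonds are counted
#' both as donor-acceptor atom pairs and as distinct residue pairs, because
#' published counts do not always state which convention they use. Per-chain
#' inter-chain counts give, for each chain, the number of inter-chain
#' contacts that touch it (the natural "per chain" reading for an oligomer).
#'
#' @param hb A `contact_set` from [hydrogen_bonds()] (or a combined set).
#' @param sb Optional `contact_set` from [salt_bridges()]; defaults to `hb`.
#' @return List of counts.
#' @export
contact_counts <- function(hb, sb = hb) {
  h <- hb$hydrogen_bonds; s <- sb$salt_bridges
  res_pair <- unique(data.frame(
    a = paste(h$donor_chain, h$donor_resno),
    b = paste(h$acceptor_chain, h$acceptor_resno),
    inter = h$inter_chain))
  per_chain <- function(df, c1, c2, inter) {
    chains <- sort(unique(c(df[[c1]], df[[c2]])))
    vapply(chains, function(ch)
      sum(df[[inter]] & (df[[c1]] == ch | df[[c2]] == ch)), numeric(1))
  }
  list(
    hbond_atom_pairs = nrow(h),
    hbond_residue_pairs = nrow(res_pair),
    hbond_intra = sum(!h$inter_chain),
    hbond_inter = sum(h$inter_chain),
    hbond_inter_per_chain = if (nrow(h))
      per_chain(h, "donor_chain", "acceptor_chain", "inter_chain") else numeric(0),
    salt_bridges_total = nrow(s),
    salt_bridges_intra = sum(!s$inter_chain),
    salt_bridges_inter = sum(s$inter_chain),
    salt_bridges_inter_per_chain = if (nrow(s))
      per_chain(s, "basic_chain", "acidic_chain", "inter_chain") else numeric(0)
  )
}
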