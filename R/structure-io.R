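#' @useDynLib adaptsig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_structure_model <- function(atoms, seqres = list(), assembly_ops = list(),
                                source = NA_character_) {
  stopifnot(is.data.frame(atoms))
  needed <- c("serial", "name", "element", "altloc", "resname", "chain",
              "resno", "icode", "x", "y", "z", "occ", "b", "is_het")
  missing <- setdiff(needed, names(atoms))
  if (length(missing))
    stop("structure_model: missing atom columns: ", paste(missing, collapse = ", "))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("structure_model: non-finite coordinates")
  structure(list(atoms = atoms, seqres = seqres, assembly_ops = assembly_ops,
                 source = source),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  prot <- protein_atoms(x)
  res <- residues(x)
  cat(sprintf("structure_model: %d atoms (%d protein), %d protein residues, chains %s\n",
              nrow(x$atoms), nrow(prot), nrow(res),
              paste(unique(prot$chain), collapse = ",")))
  if (length(x$assembly_ops))
    cat(sprintf("  %d assembly operator(s) available\n",
                length(x$assembly_ops[[1]]$ops)))
  invisible(x)
}

#' Protein atoms of a model
#'
#' Standard-residue (non-HETATM, non-water) atoms. Nonstandard residues
#' recorded as HETATM (e.g. selenomethionine) stay excluded here; they are
#' still visible through `model$atoms`.
#'
#' @param model A `structure_model`.
#' @param heavy_only Drop hydrogens (default TRUE; crystal structures
#'   normally carry none anyway).
#' @return Data frame of atom records.
#' @export
protein_atoms <- function(model, heavy_only = TRUE) {
  a <- model$atoms
  a <- a[!a$is_het & a$resname != "HOH", , drop = FALSE]
  if (heavy_only) a <- a[a$element != "H", , drop = FALSE]
  a
}

#' Protein residue table of a model
#'
#' One row per protein residue bearing coordinates, in file order, keyed by
#' (chain, residue number, insertion code) in author numbering.
#'
#' @param model A `structure_model`.
#' @return Data frame with columns `chain`, `resno`, `icode`, `resname`,
#'   `aa1`.
#' @export
residues <- function(model) {
  a <- protein_atoms(model)
  key <- paste(a$chain, a$resno, a$icode, sep = "|")
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    icode = a$icode[first], resname = a$resname[first],
                    stringsAsFactors = FALSE)
  out$aa1 <- aa3_to_1(out$resname)
  out
}

resolve_altloc <- function(atoms, policy) {
  has_alt <- atoms$altloc != ""
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    if (policy == "highest_occupancy") {
      # ties broken by altloc letter order
      ord <- order(-atoms$occ[idx], atoms$altloc[idx])
    } else {
      ord <- seq_along(idx)
    }
    keep[idx[-ord[1]]] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

parse_remark350 <- function(lines) {
  r350 <- lines[startsWith(lines, "REMARK 350")]
  if (!length(r350)) return(list())
  assemblies <- list()
  cur_id <- NULL; cur_chains <- character(); ops <- list()
  flush_op <- function(rows) {
    if (length(rows) != 3L) stop("REMARK 350: incomplete BIOMT operator")
    m <- do.call(rbind, rows)
    list(R = m[, 1:3, drop = FALSE], t = m[, 4])
  }
  pending <- list()  # op index -> list of numeric rows
  finalize <- function() {
    if (is.null(cur_id)) return()
    oplist <- lapply(pending, flush_op)
    assemblies[[as.character(cur_id)]] <<- list(chains = cur_chains, ops = oplist)
  }
  for (ln in r350) {
    if (grepl("BIOMOLECULE:", ln)) {
      finalize()
      cur_id <- as.integer(sub(".*BIOMOLECULE:\\s*", "", ln))
      cur_chains <- character(); pending <- list()
    } else if (grepl("TO CHAINS:", ln)) {
      ch <- sub(".*TO CHAINS:\\s*", "", ln)
      cur_chains <- c(cur_chains, trimws(strsplit(ch, ",")[[1]]))
    } else if (grepl("BIOMT[123]", ln)) {
      row_no <- as.integer(sub(".*BIOMT([123]).*", "\\1", ln))
      rest <- sub(".*BIOMT[123]\\s+", "", ln)
      vals <- as.numeric(strsplit(trimws(rest), "\\s+")[[1]])
      op_no <- as.integer(vals[1])
      key <- as.character(op_no)
      if (is.null(pending[[key]])) pending[[key]] <- vector("list", 3L)
      pending[[key]][[row_no]] <- vals[2:5]
    }
  }
  finalize()
  assemblies
}

validate_pdb_lines <- function(lines) {
  is_coord <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  idx <- which(is_coord)
  if (!length(idx)) return(invisible(NULL))
  xs <- suppressWarnings(as.numeric(substr(lines[idx], 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(lines[idx], 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(lines[idx], 47, 54)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs) | nchar(lines[idx]) < 54)
  if (length(bad))
    stop(sprintf("malformed fixed-column coordinate field at line %d", idx[bad[1]]))
  invisible(NULL)
}

#' Read a PDB file into a structure model
#'
#' Parses fixed-column ATOM/HETATM records (through bio3d), captures SEQRES
#' when present, and captures REMARK 350 biological-assembly operators for
#' later use by [build_assembly()]. Alternate locations are resolved
#' according to `altloc_policy`; waters and heteroatoms are kept but flagged
#' and excluded from protein-residue iteration.
#'
#' @param path PDB file path.
#' @param altloc_policy `"highest_occupancy"` (ties broken by altloc letter
#'   order) or `"first"`.
#' @param model_policy `"first"` keeps model 1 of a multi-model file; use
#'   [read_trajectory()] when all models are wanted as frames.
#' @return A `structure_model`.
#' @export
read_pdb <- function(path,
                     altloc_policy = c("highest_occupancy", "first"),
                     model_policy = c("first", "all")) {
  altloc_policy <- match.arg(altloc_policy)
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("read_pdb: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines)
  multi <- model_policy == "all"
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = multi,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     guess_element(at$elety), toupper(at$elesy)),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = at$resid,
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    is_het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- resolve_altloc(atoms, altloc_policy)
  seqres <- list()
  if (!is.null(pdb$seqres) && length(pdb$seqres)) {
    for (ch in unique(names(pdb$seqres)))
      seqres[[ch]] <- unname(pdb$seqres[names(pdb$seqres) == ch])
  }
  model <- new_structure_model(atoms, seqres = seqres,
                               assembly_ops = parse_remark350(lines),
                               source = path)
  if (nrow(protein_atoms(model)) == 0L)
    stop("read_pdb: file contains no protein atoms: ", path)
  model
}

guess_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  two <- toupper(substr(nm, 1, 2))
  el <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("SE", "FE", "ZN", "MG", "MN"), two, el)
}

format_atom_name <- function(name, element) {
  out <- character(length(name))
  for (i in seq_along(name)) {
    nm <- name[i]
    if (nchar(nm) >= 4L) out[i] <- substr(nm, 1, 4)
    else if (nchar(element[i]) == 2L) out[i] <- sprintf("%-4s", nm)
    else out[i] <- sprintf(" %-3s", nm)
  }
  out
}

pdb_atom_lines <- function(atoms) {
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(atoms$is_het, "HETATM", "ATOM"),
          atoms$serial %% 100000L,
          format_atom_name(atoms$name, atoms$element),
          ifelse(atoms$altloc == "", " ", atoms$altloc),
          atoms$resname, atoms$chain, atoms$resno %% 10000L,
          ifelse(atoms$icode == "", " ", atoms$icode),
          atoms$x, atoms$y, atoms$z, atoms$occ, atoms$b,
          sprintf("%2s", atoms$element))
}

seqres_lines <- function(seqres) {
  out <- character()
  for (ch in names(seqres)) {
    res <- seqres[[ch]]
    n <- length(res)
    starts <- seq(1, n, by = 13)
    for (k in seq_along(starts)) {
      chunk <- res[starts[k]:min(starts[k] + 12, n)]
      out <- c(out, sprintf("SEQRES %3d %1s %4d  %s", k, ch, n,
                            paste(sprintf("%-3s", chunk), collapse = " ")))
    }
  }
  out
}

remark350_lines <- function(assembly_ops) {
  out <- character()
  for (id in names(assembly_ops)) {
    asm <- assembly_ops[[id]]
    out <- c(out, sprintf("REMARK 350 BIOMOLECULE: %s", id),
             sprintf("REMARK 350 APPLY THE FOLLOWING TO CHAINS: %s",
                     paste(asm$chains, collapse = ", ")))
    for (k in seq_along(asm$ops)) {
      op <- asm$ops[[k]]
      for (r in 1:3)
        out <- c(out, sprintf("REMARK 350   BIOMT%d %3d%10.6f%10.6f%10.6f%16.5f",
                              r, k, op$R[r, 1], op$R[r, 2], op$R[r, 3], op$t[r]))
    }
  }
  out
}

#' Write a structure model as a PDB file
#'
#' Emits REMARK 350 operators and SEQRES records when the model carries them,
#' then fixed-column ATOM/HETATM records. Coordinates are written at PDB
#' precision (3 decimals), which bounds round-trip fidelity.
#'
#' @param model A `structure_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  lines <- c(remark350_lines(model$assembly_ops),
             seqres_lines(model$seqres),
             pdb_atom_lines(model$atoms),
             "END")
  writeLines(lines, path)
  invisible(path)
}

#' Build a biological assembly from symmetry operators
#'
#' Applies rotation + translation operators to the targeted chains and
#' returns a model whose operator-generated copies carry fresh chain
#' identifiers. With k operators the protein atom count of the targeted
#' chains is multiplied exactly by k. Crystallographic entries of oligomeric
#' proteins often deposit a single monomer; this reconstructs the oligomer
#' (e.g. a homotrimer) that the REMARK 350 operators describe.
#'
#' @param model A `structure_model`.
#' @param assembly_id Which stored assembly to build (default first).
#' @param ops Optional manual operator list, each `list(R = 3x3, t = length-3)`,
#'   overriding stored operators (required when the file carries none).
#' @param chains Chains to transform when `ops` is supplied manually
#'   (default: all chains).
#' @return A `structure_model` holding the assembly.
#' @export
build_assembly <- function(model, assembly_id = NULL, ops = NULL, chains = NULL) {
  if (is.null(ops)) {
    if (!length(model$assembly_ops))
      stop("build_assembly: no assembly operators in file; supply `ops` ",
           "as a list of list(R = <3x3>, t = <length-3>) matrices")
    id <- if (is.null(assembly_id)) names(model$assembly_ops)[1]
          else as.character(assembly_id)
    asm <- model$assembly_ops[[id]]
    if (is.null(asm)) stop("build_assembly: no assembly with id ", id)
    ops <- asm$ops
    chains <- asm$chains
  }
  if (is.null(chains)) chains <- unique(model$atoms$chain)
  target <- model$atoms$chain %in% chains
  base <- model$atoms[target, , drop = FALSE]
  rest <- model$atoms[!target, , drop = FALSE]
  used <- unique(model$atoms$chain)
  pool <- setdiff(c(LETTERS, letters, as.character(0:9)), used)
  pieces <- list()
  for (k in seq_along(ops)) {
    op <- ops[[k]]
    stopifnot(all(dim(op$R) == c(3, 3)), length(op$t) == 3)
    xyz <- as.matrix(base[, c("x", "y", "z")]) %*% t(op$R)
    piece <- base
    piece$x <- xyz[, 1] + op$t[1]
    piece$y <- xyz[, 2] + op$t[2]
    piece$z <- xyz[, 3] + op$t[3]
    if (k > 1L) {
      remap <- stats::setNames(pool[seq_along(chains)], chains)
      pool <- pool[-seq_along(chains)]
      piece$chain <- unname(remap[piece$chain])
    }
    pieces[[k]] <- piece
  }
  atoms <- do.call(rbind, c(pieces, list(rest)))
  atoms$serial <- seq_len(nrow(atoms))
  new_structure_model(atoms, seqres = model$seqres, assembly_ops = list(),
                      source = model$source)
}

new_sequence_record <- function(id, sequence) {
  stopifnot(is.character(id), nzchar(id), is.character(sequence),
            nzchar(sequence))
  bad <- setdiff(strsplit(sequence, "")[[1]], c(AA1, "X"))
  if (length(bad))
    stop("sequence_record: letters outside 20 canonical + X: ",
         paste(unique(bad), collapse = ", "))
  structure(list(id = id, sequence = sequence), class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("sequence_record %s (%d aa)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

#' Extract a chain sequence from a structure model
#'
#' `source = "seqres"` returns the full deposited sequence; `source = "atom"`
#' returns the modelled subset (residues bearing coordinates), so the two can
#' differ by unmodelled (disordered) regions. Nonstandard residues map to X
#' with a warning.
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier; default: first protein chain.
#' @param source `"seqres"` or `"atom"`.
#' @return A `sequence_record`.
#' @export
extract_sequence <- function(model, chain = NULL,
                             source = c("seqres", "atom")) {
  source <- match.arg(source)
  res <- residues(model)
  if (is.null(chain)) chain <- res$chain[1]
  if (source == "seqres") {
    if (is.null(model$seqres[[chain]]))
      stop("extract_sequence: no SEQRES for chain ", chain)
    aa3 <- model$seqres[[chain]]
  } else {
    res <- res[res$chain == chain, , drop = FALSE]
    if (!nrow(res)) stop("extract_sequence: no such chain: ", chain)
    aa3 <- res$resname
  }
  aa1 <- aa3_to_1(aa3)
  n_x <- sum(aa1 == "X")
  if (n_x)
    warning(sprintf("%d nonstandard residue(s) in chain %s mapped to X", n_x, chain))
  new_sequence_record(id = paste0(basename_noext(model$source), "_", chain),
                      sequence = paste(aa1, collapse = ""))
}

basename_noext <- function(path) {
  if (is.na(path)) return("model")
  tools::file_path_sans_ext(basename(path))
}

#' Read FASTA sequence records
#'
#' Wraps seqinr's FASTA reader with the package's record contract: duplicate
#' identifiers are an error, lowercase letters are uppercased with a warning,
#' and an empty file yields an empty list.
#'
#' @param path FASTA file.
#' @return List of `sequence_record`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  if (file.size(path) == 0L) return(list())
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  ids <- names(seqs)
  if (anyDuplicated(ids))
    stop("read_fasta: duplicate ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    if (grepl("[a-z]", s)) {
      warning("read_fasta: lowercase letters uppercased in record ", ids[i])
      s <- toupper(s)
    }
    new_sequence_record(ids[i], s)
  })
}

#' Write FASTA sequence records
#'
#' Sequences are wrapped at 60 columns; a read/write round trip preserves
#' each sequence byte-for-byte.
#'
#' @param records List of `sequence_record` (a single record is accepted).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "sequence_record")) records <- list(records)
  seqinr::write.fasta(lapply(records, function(r) strsplit(r$sequence, "")[[1]]),
                      names = vapply(records, `[[`, "", "id"),
                      file.out = path, nbchar = 60)
  invisible(path)
}

new_trajectory <- function(coords, atom_table, frame_spacing = 0.1) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            frame_spacing > 0)
  stopifnot(dim(coords)[1] == nrow(atom_table))
  structure(list(coords = coords, atoms = atom_table,
                 frame_spacing = frame_spacing),
            class = "trajectory")
}

n_frames <- function(traj) dim(traj$coords)[3]

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, %.3g ns/frame\n",
              n_frames(x), dim(x$coords)[1], x$frame_spacing))
  invisible(x)
}

#' Read a trajectory
#'
#' Multi-model PDB (canonical exchange dialect of this package) or
#' whitespace-separated XYZ frames. All frames must carry the same atoms in
#' the same order; a truncated or inconsistent frame is an error naming the
#' frame index.
#'
#' @param path Trajectory file.
#' @param format `"pdb"` or `"xyz"`.
#' @param frame_spacing Time per frame in ns (metadata only).
#' @return A `trajectory` with coordinates as an atoms x 3 x frames array.
#' @export
read_trajectory <- function(path, format = c("pdb", "xyz"),
                            frame_spacing = 0.1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_trajectory: no such file: ", path)
  if (format == "pdb") read_trajectory_pdb(path, frame_spacing)
  else read_trajectory_xyz(path, frame_spacing)
}

read_trajectory_pdb <- function(path, frame_spacing) {
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines)
  model_starts <- which(startsWith(lines, "MODEL"))
  if (!length(model_starts)) model_starts <- 1L
  is_coord <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  frame_of <- findInterval(which(is_coord), model_starts)
  counts <- tabulate(frame_of, nbins = length(model_starts))
  if (length(unique(counts)) > 1L)
    stop(sprintf("read_trajectory: frame %d has %d atoms, expected %d",
                 which(counts != counts[1])[1],
                 counts[which(counts != counts[1])[1]], counts[1]))
  n_at <- counts[1]
  coord_lines <- lines[is_coord]
  xyz <- cbind(as.numeric(substr(coord_lines, 31, 38)),
               as.numeric(substr(coord_lines, 39, 46)),
               as.numeric(substr(coord_lines, 47, 54)))
  nf <- length(model_starts)
  coords <- array(NA_real_, c(n_at, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- xyz[frame_of == f, , drop = FALSE]
  first <- coord_lines[frame_of == 1]
  atom_table <- data.frame(
    name = trimws(substr(first, 13, 16)),
    resname = trimws(substr(first, 18, 20)),
    chain = substr(first, 22, 22),
    resno = as.integer(substr(first, 23, 26)),
    element = trimws(substr(first, 77, 78)),
    stringsAsFactors = FALSE
  )
  atom_table$element[atom_table$element == ""] <-
    guess_element(atom_table$name[atom_table$element == ""])
  new_trajectory(coords, atom_table, frame_spacing)
}

read_trajectory_xyz <- function(path, frame_spacing) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L; frames <- list(); f <- 0L; n_at <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    f <- f + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("read_trajectory: bad atom count header at frame ", f)
    if (is.na(n_at)) n_at <- n
    if (n != n_at)
      stop(sprintf("read_trajectory: frame %d has %d atoms, expected %d", f, n, n_at))
    block <- lines[(i + 2L):(i + 1L + n)]
    if (length(block) < n || anyNA(block))
      stop("read_trajectory: truncated frame ", f)
    toks <- strsplit(trimws(block), "\\s+")
    if (any(lengths(toks) < 4L)) stop("read_trajectory: truncated frame ", f)
    m <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (anyNA(m)) stop("read_trajectory: malformed coordinates in frame ", f)
    frames[[f]] <- list(el = vapply(toks, `[[`, "", 1L), xyz = m)
    i <- i + 2L + n
  }
  if (!f) stop("read_trajectory: empty XYZ file")
  coords <- array(NA_real_, c(n_at, 3, f))
  for (k in seq_len(f)) coords[, , k] <- frames[[k]]$xyz
  atom_table <- data.frame(name = frames[[1]]$el, resname = "UNK",
                           chain = "A", resno = seq_len(n_at),
                           element = toupper(frames[[1]]$el),
                           stringsAsFactors = FALSE)
  new_trajectory(coords, atom_table, frame_spacing)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj A `trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  at <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     seq_len(nrow(at)) %% 100000L,
                     format_atom_name(at$name, at$element),
                     at$resname, at$chain, at$resno %% 10000L,
                     traj$coords[, 1, f], traj$coords[, 2, f],
                     traj$coords[, 3, f], 1, 0, sprintf("%2s", at$element))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Temperature window schedule for a trajectory
#'
#' Maps frame ranges to simulation temperatures and records which trailing
#' fraction of each window enters analyses (the equilibrated tail; the
#' leading remainder is treated as re-equilibration after the temperature
#' step).
#'
#' @param start,end Integer frame ranges (inclusive, 1-based), one per window.
#' @param temperature_C Strictly increasing temperatures, one per window.
#' @param analysis_fraction Trailing fraction of each window analysed,
#'   in (0, 1].
#' @return A `window_schedule` data frame.
#' @export
#' @examples
#' window_schedule(c(1, 101), c(100, 200), c(10, 27), 0.2)
window_schedule <- function(start, end, temperature_C, analysis_fraction = 0.2) {
  stopifnot(length(start) == length(end),
            length(start) == length(temperature_C))
  if (length(analysis_fraction) == 1L)
    analysis_fraction <- rep(analysis_fraction, length(start))
  stopifnot(all(analysis_fraction > 0), all(analysis_fraction <= 1))
  if (any(end < start)) stop("window_schedule: end < start")
  if (any(diff(temperature_C) <= 0))
    stop("window_schedule: temperatures must be strictly increasing")
  o <- order(start)
  if (any(start[o][-1] <= end[o][-length(end)]))
    stop("window_schedule: windows overlap")
  structure(data.frame(start = as.integer(start), end = as.integer(end),
                       temperature_C = temperature_C,
                       analysis_fraction = analysis_fraction),
            class = c("window_schedule", "data.frame"))
}

analysis_frames <- function(schedule, i) {
  w <- schedule[i, ]
  len <- w$end - w$start + 1L
  n_keep <- max(1L, floor(len * w$analysis_fraction))
  seq.int(w$end - n_keep + 1L, w$end)
}
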