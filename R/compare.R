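METRIC_LABELS <- c(
  pi = "Isoelectric point (pI)",
  gravy = "Grand average hydrophobicity",
  aliphatic = "Aliphatic amino acids, Ala, Ile, Leu, Val (%)",
  positive = "Positively charged amino acids, R, K and H (%)",
  negative = "Negatively charged amino acids, D and E (%)",
  small = "Small amino acids, G and A (%)",
  hydrophobic = "Hydrophobic residues, F, I, L, V, M (%)",
  polar_uncharged = "Polar uncharged residues (%)",
  nonpolar = "Non-polar residues (%)",
  aspartate = "Aspartic acids (%)",
  glutamate = "Glutamic acids (%)",
  aromatic = "Aromatic residues (%)",
  proline = "Proline amino acids (%)",
  arginine = "Arginine amino acids (%)",
  epsilon_280 = "Extinction coefficient at 280 nm (M-1 cm-1)",
  acidic_excess = "Acidic excess, (D+E) - (R+K+H) (% points)",
  surf_positive = "Positive residues among total number of surface residues (%)",
  surf_negative = "Negative residues among total number of surface residues (%)",
  surf_polar = "Polar residues among total number of surface residues (%)",
  surf_nonpolar = "Non-polar residues among total number of surface residues (%)",
  surf_aromatic = "Aromatic residues among total number of surface residues (%)",
  surf_bulky = "Amino acids with bulky hydrophobic side chains (F, I, L) in the protein surface (%)",
  surf_lysine = "Lysine residues among surface residues (%)",
  surf_arginine = "Arginine residues among surface residues (%)",
  helix = "Amino acids that form helices (%)",
  strand = "Amino acids that form strands (%)",
  hbonds_all = "Hydrogen bonds (all)",
  hbonds_inter = "Hydrogen bonds (inter-chain, per chain)",
  salt_bridges_all = "Salt bridges (all)",
  salt_bridges_inter = "Salt bridges (inter-chain, per chain)",
  rmsd_slope = "Thermal-sensitivity slope (A per degC)",
  rmsd_r2 = "RMSD-temperature regression R2"
)

#' Comparison configuration
#'
#' Declarative description of a comparative run: groups of member proteins
#' (each with a sequence and/or structure, optionally trajectory replicas
#' plus a window schedule), the focal member every other member is compared
#' against, and the analysis parameters. Every tunable that published
#' comparisons leave ambiguous lives here with an explicit default:
#' the residue-class scheme, SASA probe/points, the surface
#' relative-accessibility threshold, contact cutoffs, and the trajectory
#' window schedule.
#'
#' @param groups Named list; each element is a list of members, and each
#'   member a list with `label` and any of `sequence` (FASTA path),
#'   `structure` (PDB path), `trajectories` (character vector of multi-model
#'   PDB paths, one per replica).
#' @param focal Label of the focal member.
#' @param surface_threshold Relative-accessibility surface cutoff.
#' @param probe_radius,n_points SASA parameters.
#' @param hbond_d_max,hbond_angle_min,salt_bridge_cutoff Contact criteria.
#' @param schedule A [window_schedule()] applied to member trajectories.
#' @param build_assembly_first Build the stored biological assembly before
#'   structural metrics when operators are present.
#' @param scheme A [residue_scheme()].
#' @return A `compare_config` list.
#' @export
compare_config <- function(groups, focal,
                           surface_threshold = 0.10,
                           probe_radius = 1.4, n_points = 960,
                           hbond_d_max = 3.5, hbond_angle_min = 120,
                           salt_bridge_cutoff = 3.2,
                           schedule = NULL,
                           build_assembly_first = TRUE,
                           scheme = residue_scheme()) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  labels <- unlist(lapply(groups, function(g)
    vapply(g, `[[`, "", "label")))
  if (anyDuplicated(labels))
    stop("compare_config: duplicate member labels")
  if (!focal %in% labels)
    stop("compare_config: focal member '", focal, "' not among members")
  for (g in groups) for (m in g) {
    for (f in c("sequence", "structure"))
      if (!is.null(m[[f]]) && !file.exists(m[[f]]))
        stop("compare_config: missing file for '", m$label, "': ", m[[f]])
    for (p in m$trajectories %||% character())
      if (!file.exists(p))
        stop("compare_config: missing trajectory for '", m$label, "': ", p)
  }
  structure(list(groups = groups, focal = focal,
                 surface_threshold = surface_threshold,
                 probe_radius = probe_radius, n_points = n_points,
                 hbond_d_max = hbond_d_max,
                 hbond_angle_min = hbond_angle_min,
                 salt_bridge_cutoff = salt_bridge_cutoff,
                 schedule = schedule,
                 build_assembly_first = build_assembly_first,
                 scheme = scheme),
            class = "compare_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a comparison configuration from YAML
#'
#' Schema: top-level `focal`, optional numeric parameters matching the
#' [compare_config()] arguments, optional `schedule` (lists `start`, `end`,
#' `temperature_C`, `analysis_fraction`), and `groups`: a mapping from group
#' name to a list of members (`label`, `sequence`, `structure`,
#' `trajectories`). Paths are resolved relative to the YAML file.
#'
#' @param path YAML file.
#' @return A `compare_config`.
#' @export
read_compare_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$groups) || is.null(y$focal))
    stop("config: 'groups' and 'focal' are required")
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p)) NULL else
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  groups <- lapply(y$groups, function(g) lapply(g, function(m) {
    list(label = m$label, sequence = resolve(m$sequence),
         structure = resolve(m$structure),
         trajectories = if (is.null(m$trajectories)) NULL
                        else unname(vapply(m$trajectories, resolve, "")))
  }))
  schedule <- NULL
  if (!is.null(y$schedule))
    schedule <- window_schedule(y$schedule$start, y$schedule$end,
                                y$schedule$temperature_C,
                                y$schedule$analysis_fraction %||% 0.2)
  args <- y[intersect(names(y), c("surface_threshold", "probe_radius",
                                  "n_points", "hbond_d_max",
                                  "hbond_angle_min", "salt_bridge_cutoff",
                                  "build_assembly_first"))]
  do.call(compare_config, c(list(groups = groups, focal = y$focal,
                                 schedule = schedule), args))
}

member_metrics <- function(member, config) {
  out <- stats::setNames(rep(NA_real_, length(METRIC_LABELS)),
                         names(METRIC_LABELS))
  model <- NULL
  seq_rec <- NULL
  if (!is.null(member$structure)) {
    model <- read_pdb(member$structure)
    seq_rec <- tryCatch(
      suppressWarnings(extract_sequence(model, source = "seqres")),
      error = function(e) suppressWarnings(extract_sequence(model, source = "atom")))
  }
  if (!is.null(member$sequence)) {
    recs <- read_fasta(member$sequence)
    if (length(recs)) seq_rec <- recs[[1]]
  }
  if (!is.null(seq_rec)) {
    prof <- composition(seq_rec, scheme = config$scheme)
    for (cls in c("aliphatic", "positive", "negative", "small",
                  "hydrophobic", "polar_uncharged", "nonpolar",
                  "aspartate", "glutamate", "aromatic", "proline",
                  "arginine"))
      out[cls] <- prof$class_pct[[cls]]
    out["pi"] <- prof$pi
    out["gravy"] <- prof$gravy
    out["epsilon_280"] <- prof$epsilon_280
    out["acidic_excess"] <- prof$acidic_excess
  }
  if (!is.null(model)) {
    target <- model
    if (config$build_assembly_first && length(model$assembly_ops))
      target <- build_assembly(model)
    sr <- sasa(target, probe_radius = config$probe_radius,
               n_points = config$n_points)
    surf <- classify_surface(sr, threshold = config$surface_threshold,
                             scheme = config$scheme)
    out["surf_positive"] <- surf$class_pct[["positive"]]
    out["surf_negative"] <- surf$class_pct[["negative"]]
    out["surf_polar"] <- surf$class_pct[["polar_uncharged"]]
    out["surf_nonpolar"] <- surf$class_pct[["nonpolar"]]
    out["surf_aromatic"] <- surf$class_pct[["aromatic"]]
    out["surf_bulky"] <- surf$class_pct[["bulky_hydrophobic"]]
    out["surf_lysine"] <- surf$class_pct[["lysine"]]
    out["surf_arginine"] <- surf$class_pct[["arginine"]]
    ss <- secondary_structure(target)
    out["helix"] <- ss$helix_pct
    out["strand"] <- ss$strand_pct
    hb <- hydrogen_bonds(target, d_max = config$hbond_d_max,
                         angle_min = config$hbond_angle_min)
    sb <- salt_bridges(target, cutoff = config$salt_bridge_cutoff)
    cc <- contact_counts(hb, sb)
    out["hbonds_all"] <- cc$hbond_atom_pairs
    out["hbonds_inter"] <- if (length(cc$hbond_inter_per_chain))
      mean(cc$hbond_inter_per_chain) else 0
    out["salt_bridges_all"] <- cc$salt_bridges_total
    out["salt_bridges_inter"] <- if (length(cc$salt_bridges_inter_per_chain))
      mean(cc$salt_bridges_inter_per_chain) else 0
  }
  if (!is.null(member$trajectories) && !is.null(config$schedule)) {
    series <- lapply(seq_along(member$trajectories), function(r) {
      traj <- read_trajectory(member$trajectories[r])
      rmsd_series(traj, schedule = config$schedule, replica = r)
    })
    reg <- temperature_regression(series)
    out["rmsd_slope"] <- reg$slope
    out["rmsd_r2"] <- reg$r_squared
  }
  out
}

#' Run a grouped adaptation-signature comparison
#'
#' Computes the full metric panel for every member (sequence metrics need a
#' sequence or a structure with SEQRES; structural metrics need a structure;
#' flexibility metrics need trajectories plus a schedule in the config) and
#' aggregates groups as unweighted means over members, the convention of
#' published comparison tables. Metrics a member lacks input for are NA with
#' a warning, never an abort.
#'
#' @param config A [compare_config()] or path to a YAML config.
#' @return A `comparison_report`: list with `members` (metrics x members
#'   data frame), `groups` (metrics x groups), `focal`, `deltas`
#'   (member minus focal), `labels`.
#' @export
run_comparison <- function(config) {
  if (is.character(config)) config <- read_compare_config(config)
  stopifnot(inherits(config, "compare_config"))
  members <- list(); group_of <- character(0)
  for (gname in names(config$groups)) {
    for (m in config$groups[[gname]]) {
      members[[m$label]] <- suppressWarnings(member_metrics(m, config))
      group_of[m$label] <- gname
    }
  }
  mem_mat <- do.call(cbind, members)
  na_members <- colnames(mem_mat)[colSums(is.na(mem_mat)) > 0]
  if (length(na_members))
    warning("metrics unavailable (missing inputs) for: ",
            paste(na_members, collapse = ", "))
  grp_mat <- vapply(unique(group_of), function(g)
    rowMeans(mem_mat[, group_of == g, drop = FALSE], na.rm = TRUE),
    numeric(nrow(mem_mat)))
  grp_mat[is.nan(grp_mat)] <- NA_real_
  focal_vec <- mem_mat[, config$focal]
  deltas <- mem_mat - focal_vec
  structure(list(members = as.data.frame(mem_mat),
                 groups = as.data.frame(grp_mat),
                 group_of = group_of,
                 focal = config$focal, deltas = as.data.frame(deltas),
                 labels = METRIC_LABELS),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: %d member(s) in %d group(s), focal = %s\n",
              ncol(x$members), ncol(x$groups), x$focal))
  tab <- round(x$groups, 1)
  rownames(tab) <- unname(x$labels[rownames(x$groups)])
  print(tab)
  invisible(x)
}

#' Render a comparison report to TSV and JSON
#'
#' TSV rows carry the fixed human-readable labels (byte-stable order across
#' runs); numeric values are written at one decimal in the TSV (published
#' table style) and full precision in the JSON. A JSON written here can be
#' read back into an equivalent report with [read_report_json()].
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("tsv", "json")`.
#' @return Invisible character vector of files written.
#' @export
render_report <- function(report, dir, formats = c("tsv", "json")) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if ("tsv" %in% formats) {
    for (piece in c("members", "groups")) {
      tab <- report[[piece]]
      df <- data.frame(metric = unname(METRIC_LABELS[rownames(tab)]),
                       round(tab, 1), check.names = FALSE)
      f <- file.path(dir, paste0(piece, ".tsv"))
      utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, f)
    }
  }
  if ("json" %in% formats) {
    f <- file.path(dir, "report.json")
    jsonlite::write_json(
      list(focal = report$focal,
           group_of = as.list(report$group_of),
           members = report$members,
           groups = report$groups),
      f, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    written <- c(written, f)
  }
  invisible(written)
}

#' Read a rendered JSON report back
#'
#' @param path JSON file written by [render_report()].
#' @return A `comparison_report` (deltas recomputed against the focal).
#' @export
read_report_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  members <- as.data.frame(j$members)
  rownames(members) <- names(METRIC_LABELS)
  groups <- as.data.frame(j$groups)
  rownames(groups) <- names(METRIC_LABELS)
  structure(list(members = members, groups = groups,
                 group_of = unlist(j$group_of),
                 focal = j$focal,
                 deltas = members - members[, j$focal],
                 labels = METRIC_LABELS),
            class = "comparison_report")
}
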