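#' Deterministic unit-sphere point set (Fibonacci spiral)
#'
#' Quasi-uniform points used by the Shrake-Rupley sampler. Deterministic by
#' construction, so SASA values are reproducible run to run and across
#' platforms (no RNG involved).
#'
#' @param n Number of points (>= 60 recommended; 960 is the package default).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n) - 1L
  z <- 1 - 2 * (k + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the van der Waals spheres of all heavy atoms by
#' sampling each expanded atom sphere with a deterministic spiral point set
#' and counting points not occluded by any neighbouring expanded sphere.
#' Water is excluded; nonstandard (HETATM) residues and ligands act as
#' occluders but are not reported as protein residues.
#'
#' @param model A `structure_model`.
#' @param probe_radius Probe radius in Angstrom (water: 1.4).
#' @param n_points Sphere sample points per atom; accuracy of an isolated
#'   sphere is within ~1% at 960 points.
#' @param radii Named per-element radius table, see [vdw_radii()].
#' @param max_asa Per-residue-type reference maxima for relative
#'   accessibility, see [max_asa_theoretical()].
#' @return A `sasa_result`: list with `atom` (data frame of per-atom areas),
#'   `residue` (per-residue area and relative accessibility), `total`,
#'   `probe_radius`, `n_points`.
#' @export
sasa <- function(model, probe_radius = 1.4, n_points = 960,
                 radii = vdw_radii(), max_asa = max_asa_theoretical()) {
  stopifnot(probe_radius > 0, n_points >= 60)
  a <- model$atoms
  a <- a[a$resname != "HOH" & a$element != "H", , drop = FALSE]
  if (!nrow(a)) stop("sasa: no heavy atoms")
  r <- radii[a$element]
  if (anyNA(r)) {
    unknown <- unique(a$element[is.na(r)])
    stop("sasa: no radius for element(s): ", paste(unknown, collapse = ", "))
  }
  area <- sasa_kernel(as.matrix(a[, c("x", "y", "z")]), unname(r),
                      probe_radius, fibonacci_sphere(n_points))
  atom_tab <- data.frame(serial = a$serial, chain = a$chain, resno = a$resno,
                         icode = a$icode, resname = a$resname, name = a$name,
                         element = a$element, is_het = a$is_het, area = area,
                         stringsAsFactors = FALSE)
  prot <- atom_tab[!atom_tab$is_het, , drop = FALSE]
  key <- paste(prot$chain, prot$resno, prot$icode, sep = "|")
  agg <- rowsum(prot$area, key, reorder = FALSE)
  first <- !duplicated(key)
  res_tab <- data.frame(chain = prot$chain[first], resno = prot$resno[first],
                        icode = prot$icode[first],
                        resname = prot$resname[first],
                        area = agg[, 1], stringsAsFactors = FALSE)
  res_tab$aa1 <- aa3_to_1(res_tab$resname)
  res_tab$rel_acc <- res_tab$area / max_asa[res_tab$aa1]
  rownames(res_tab) <- NULL
  structure(list(atom = atom_tab, residue = res_tab,
                 total = sum(atom_tab$area),
                 probe_radius = probe_radius, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: total %.1f A^2 over %d atoms (%d residues); probe %.2f A, %d points\n",
              x$total, nrow(x$atom), nrow(x$residue), x$probe_radius,
              x$n_points))
  invisible(x)
}

#' Classify residues as surface or buried and profile the surface
#'
#' A residue is on the surface when its relative accessibility (SASA over the
#' residue type's reference maximum) is strictly greater than `threshold`
#' (default 10%). Per-class percentages are computed over surface residues
#' only; halophilic proteins typically show a strongly acidic surface by this
#' measure.
#'
#' @param sasa_result A [sasa()] result.
#' @param threshold Relative-accessibility cutoff, default 0.10.
#' @param scheme A [residue_scheme()] for the per-class percentages.
#' @return A `surface_profile`: list with `residue` (classification table),
#'   `n_surface`, `n_buried`, `class_pct` (percent of surface residues per
#'   class), `threshold`.
#' @export
classify_surface <- function(sasa_result, threshold = 0.10,
                             scheme = residue_scheme()) {
  stopifnot(inherits(sasa_result, "sasa_result"), threshold >= 0)
  res <- sasa_result$residue
  res <- res[res$aa1 != "X", , drop = FALSE]
  res$surface <- res$rel_acc > threshold
  surf <- res[res$surface, , drop = FALSE]
  class_pct <- vapply(scheme, function(cls)
    if (nrow(surf)) 100 * sum(surf$aa1 %in% cls) / nrow(surf) else NA_real_,
    numeric(1))
  structure(list(residue = res, n_surface = nrow(surf),
                 n_buried = nrow(res) - nrow(surf),
                 class_pct = class_pct, threshold = threshold),
            class = "surface_profile")
}

#' @export
print.surface_profile <- function(x, ...) {
  cat(sprintf("surface_profile: %d surface / %d buried residues (rel. acc. > %.0f%%)\n",
              x$n_surface, x$n_buried, 100 * x$threshold))
  cat(sprintf("  acidic %.1f%% | basic %.1f%% | nonpolar %.1f%% | aromatic %.1f%%\n",
              x$class_pct[["negative"]], x$class_pct[["positive"]],
              x$class_pct[["nonpolar"]], x$class_pct[["aromatic"]]))
  invisible(x)
}

#' Solvent-accessible area buried in an oligomer interface
#'
#' Buried area is the sum of the isolated chains' SASA minus the assembly
#' SASA. Two fraction conventions are reported because the denominator is
#' ambiguous in comparative tables: buried area over the assembly SASA and
#' over the summed isolated-monomer SASA.
#'
#' @param assembly A `structure_model` holding the oligomer.
#' @param monomers Optional list of `structure_model`s for the isolated
#'   chains; by default the assembly is split by chain.
#' @param ... Passed to [sasa()] (probe radius, point count, tables).
#' @return List with `buried_area`, `assembly_area`, `monomer_area_sum`,
#'   `fraction_of_assembly`, `fraction_of_monomers`, and the per-chain areas.
#' @export
interface_burial <- function(assembly, monomers = NULL, ...) {
  if (is.null(monomers)) {
    chains <- unique(protein_atoms(assembly)$chain)
    monomers <- lapply(chains, function(ch) {
      atoms <- assembly$atoms[assembly$atoms$chain == ch, , drop = FALSE]
      new_structure_model(atoms, source = assembly$source)
    })
    names(monomers) <- chains
  }
  asm_area <- sasa(assembly, ...)$total
  mono_areas <- vapply(monomers, function(m) sasa(m, ...)$total, numeric(1))
  buried <- sum(mono_areas) - asm_area
  list(buried_area = buried,
       assembly_area = asm_area,
       monomer_area_sum = sum(mono_areas),
       fraction_of_assembly = buried / asm_area,
       fraction_of_monomers = buried / sum(mono_areas),
       per_chain = mono_areas)
}
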