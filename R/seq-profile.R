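#' Residue-class scheme
#'
#' Defines the named residue classes used throughout composition reports.
#' Class membership is explicit configuration, not hard-coded behaviour:
#' the comparative literature disagrees on edge cases (whether histidine
#' counts as aromatic, whether glycine is polar), so every class is a plain
#' character vector of one-letter codes that the caller may override.
#'
#' Defaults:
#' * `aliphatic` A, I, L, V
#' * `positive` R, K, H
#' * `negative` D, E
#' * `small` G, A
#' * `hydrophobic` F, I, L, V, M
#' * `polar_uncharged` S, T, N, Q
#' * `nonpolar` A, V, L, I, P, F, M, W, G, C
#' * `aromatic` F, W, Y
#' * `bulky_hydrophobic` F, I, L
#' * single-residue classes `proline`, `arginine`, `lysine`, `aspartate`,
#'   `glutamate`
#'
#' @param ... Named character vectors replacing or adding classes, e.g.
#'   `aromatic = c("F", "W", "Y", "H")`.
#' @return An object of class `residue_scheme`: a named list of character
#'   vectors.
#' @export
#' @examples
#' sch <- residue_scheme()
#' sch$negative
#' residue_scheme(aromatic = c("F", "W", "Y", "H"))$aromatic
residue_scheme <- function(...) {
  scheme <- list(
    aliphatic        = c("A", "I", "L", "V"),
    positive         = c("R", "K", "H"),
    negative         = c("D", "E"),
    small            = c("G", "A"),
    hydrophobic      = c("F", "I", "L", "V", "M"),
    polar_uncharged  = c("S", "T", "N", "Q"),
    nonpolar         = c("A", "V", "L", "I", "P", "F", "M", "W", "G", "C"),
    aromatic         = c("F", "W", "Y"),
    bulky_hydrophobic = c("F", "I", "L"),
    proline          = "P",
    arginine         = "R",
    lysine           = "K",
    aspartate        = "D",
    glutamate        = "E"
  )
  override <- list(...)
  for (nm in names(override)) {
    stopifnot(is.character(override[[nm]]))
    bad <- setdiff(override[[nm]], AA1)
    if (length(bad))
      stop("residue_scheme: non-canonical letters in class '", nm, "': ",
           paste(bad, collapse = ", "))
    scheme[[nm]] <- override[[nm]]
  }
  structure(scheme, class = "residue_scheme")
}

clean_sequence <- function(seq, warn = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  letters <- strsplit(toupper(seq), "")[[1]]
  keep <- letters %in% AA1
  dropped <- sum(!keep)
  if (dropped && warn)
    warning(sprintf("%d non-canonical letter(s) excluded from profiling", dropped))
  letters[keep]
}

#' Residue-class composition of a sequence
#'
#' Counts each configured residue class and reports it as a percentage of the
#' canonical residues in the sequence. Ambiguous letters (B, Z, X, ...) are
#' excluded from both numerator and denominator. Percentages are stored at
#' full precision; rounding to one decimal happens only in rendered reports.
#'
#' @param seq Character scalar, one-letter amino-acid sequence (or a
#'   `sequence_record`).
#' @param scheme A [residue_scheme()].
#' @return An object of class `composition_profile`: list with `n` (canonical
#'   residue count), `counts` (per-letter counts), `class_pct` (named numeric,
#'   percent per class), `gravy`, `pi`, `epsilon_280`, `acidic_excess`,
#'   `lys_pct`, `arg_pct`.
#' @export
#' @examples
#' p <- composition("ACDEFGHIKLMNPQRSTVWY")
#' p$class_pct[["negative"]]  # 10: D + E out of 20
composition <- function(seq, scheme = residue_scheme()) {
  if (inherits(seq, "sequence_record")) seq <- seq$sequence
  letters <- clean_sequence(seq)
  n <- length(letters)
  if (n < 1L) stop("composition: no canonical residues in sequence")
  counts <- table(factor(letters, levels = AA1))
  counts <- stats::setNames(as.integer(counts), AA1)
  class_pct <- vapply(scheme, function(cls) 100 * sum(counts[cls]) / n,
                      numeric(1))
  profile <- list(
    n = n,
    counts = counts,
    class_pct = class_pct,
    gravy = gravy(seq, warn = FALSE),
    pi = isoelectric_point(seq),
    epsilon_280 = extinction_coefficient(seq),
    lys_pct = 100 * counts[["K"]] / n,
    arg_pct = 100 * counts[["R"]] / n
  )
  profile$acidic_excess <- class_pct[["negative"]] - class_pct[["positive"]]
  structure(profile, class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("Composition profile over %d canonical residues\n", x$n))
  cat(sprintf("  GRAVY %.2f | pI %.1f | eps280 %s M-1cm-1 | acidic excess %.1f pts\n",
              x$gravy, x$pi, format(x$epsilon_280, big.mark = ","),
              x$acidic_excess))
  pct <- sort(round(x$class_pct, 1), decreasing = TRUE)
  for (nm in names(pct)) cat(sprintf("  %-18s %5.1f%%\n", nm, pct[[nm]]))
  invisible(x)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of Kyte-Doolittle hydropathy values over the canonical
#' residues of a sequence. More negative values indicate a more hydrophilic
#' protein; strong negative GRAVY is a recurrent halophilic signature.
#'
#' @param seq Sequence string or `sequence_record`.
#' @param scale Named hydropathy scale; defaults to [kyte_doolittle_scale()].
#' @param warn Warn when non-canonical letters are skipped.
#' @return Numeric scalar.
#' @export
#' @examples
#' gravy("AAA")  # 1.8
gravy <- function(seq, scale = kyte_doolittle_scale(), warn = TRUE) {
  if (inherits(seq, "sequence_record")) seq <- seq$sequence
  letters <- clean_sequence(seq, warn = warn)
  if (!length(letters)) stop("gravy: no canonical residues")
  mean(scale[letters])
}

net_charge_at_ph <- function(counts, pH, pka) {
  pos_groups <- c(Nterm = 1, H = counts[["H"]], K = counts[["K"]],
                  R = counts[["R"]])
  neg_groups <- c(Cterm = 1, D = counts[["D"]], E = counts[["E"]],
                  C = counts[["C"]], Y = counts[["Y"]])
  pos <- sum(pos_groups / (1 + 10^(pH - pka[names(pos_groups)])))
  neg <- sum(neg_groups / (1 + 10^(pka[names(neg_groups)] - pH)))
  pos - neg
}

#' Isoelectric point by bisection
#'
#' Models per-group protonation with Henderson-Hasselbalch terms (termini plus
#' D, E, C, Y, H, K, R side chains) and finds the pH at which the net charge
#' crosses zero. Net charge is strictly decreasing in pH, so bisection on
#' pH 0..14 converges unconditionally.
#'
#' @param seq Sequence string or `sequence_record`.
#' @param pka Named pKa vector, see [pka_bjellqvist()].
#' @param tol Bisection stops when |net charge| < `tol`.
#' @return pH at zero net charge.
#' @export
#' @examples
#' isoelectric_point("DDDD") < 7
#' isoelectric_point("KKKK") > 7
isoelectric_point <- function(seq, pka = pka_bjellqvist(), tol = 1e-4) {
  if (inherits(seq, "sequence_record")) seq <- seq$sequence
  letters <- clean_sequence(seq, warn = FALSE)
  if (!length(letters)) stop("isoelectric_point: no canonical residues")
  counts <- table(factor(letters, levels = AA1))
  counts <- stats::setNames(as.integer(counts), AA1)
  lo <- 0; hi <- 14
  if (net_charge_at_ph(counts, lo, pka) < 0 ||
      net_charge_at_ph(counts, hi, pka) > 0)
    stop("isoelectric_point: net charge does not cross zero in pH 0..14")
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge_at_ph(counts, mid, pka)
    if (abs(q) < tol || (hi - lo) < 1e-12) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Molar extinction coefficient at 280 nm
#'
#' Pace increments: 5500 per tryptophan, 1490 per tyrosine, and, in
#' `all_paired` mode, 125 per cystine (Cys pairs, floor(nCys/2)). `reduced`
#' mode counts no cystine contribution.
#'
#' @param seq Sequence string or `sequence_record`.
#' @param cystine_mode `"reduced"` (default) or `"all_paired"`.
#' @return Extinction coefficient in M^-1 cm^-1.
#' @export
#' @examples
#' extinction_coefficient("W")                    # 5500
#' extinction_coefficient("WYCC", "all_paired")   # 5500 + 1490 + 125
extinction_coefficient <- function(seq,
                                   cystine_mode = c("reduced", "all_paired")) {
  cystine_mode <- match.arg(cystine_mode)
  if (inherits(seq, "sequence_record")) seq <- seq$sequence
  letters <- clean_sequence(seq, warn = FALSE)
  eps <- EPS_TRP * sum(letters == "W") + EPS_TYR * sum(letters == "Y")
  if (cystine_mode == "all_paired")
    eps <- eps + EPS_CYSTINE * (sum(letters == "C") %/% 2L)
  eps
}

#' Acidic excess of a composition profile
#'
#' Difference, in percentage points, between the negative (D+E) and positive
#' (R+K+H) residue-class percentages. A persistent excess of acidic over
#' basic residues is the classic sequence-level halophily signature.
#'
#' @param x A `composition_profile` (or a sequence, which is profiled first).
#' @return Numeric scalar in percentage points.
#' @export
#' @examples
#' acidic_excess("EEEE")  # 100
#' acidic_excess("DEKR")  # 0
acidic_excess <- function(x) {
  if (!inherits(x, "composition_profile")) x <- composition(x)
  x$acidic_excess
}
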