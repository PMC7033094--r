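# In-silico trypsin digestion, peptide/protein mass prediction and matching
# of predicted masses against observed MALDI peaks.

# Standard residue masses (Da), IUPAC/Unimod values.
MONO_RESIDUE_MASS <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
AVG_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MONO <- 18.010565
WATER_AVG <- 18.01528
PROTON_MASS <- 1.007276
HYDROGEN_MONO <- 1.0078250319
HYDROGEN_AVG <- 1.00794

#' Residue and small-molecule mass constants
#'
#' @return List with elements `monoisotopic` and `average` (named numeric
#'   vectors over the 20 residues), `water_monoisotopic`, `water_average`,
#'   and `proton`.
#' @export
mass_constants <- function() {
  list(monoisotopic = MONO_RESIDUE_MASS, average = AVG_RESIDUE_MASS,
       water_monoisotopic = WATER_MONO, water_average = WATER_AVG,
       proton = PROTON_MASS)
}

.residues <- function(seq, context) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(MONO_RESIDUE_MASS))
  if (length(bad) > 0) {
    stop(sprintf("%s: residue '%s' at position %d has no defined mass",
                 context, chars[bad[1]], bad[1]), call. = FALSE)
  }
  chars
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P. With
#' `missed_cleavages = m`, all concatenations of up to `m + 1` adjacent
#' fully-cleaved peptides are additionally reported.
#'
#' @param protein Mature protein sequence (character scalar; no `*` or `X`).
#' @param missed_cleavages Non-negative integer, default 0 (complete
#'   digestion).
#' @param parent_id Optional identifier recorded with each peptide.
#' @return `data.frame` with columns `parent_id`, `start` (0-based offset in
#'   the parent), `peptide`, `mono_mass` and `avg_mass` (neutral Da),
#'   ordered N-terminal to C-terminal, then by length.
#' @export
#' @examples
#' tryptic_digest("GKAR")$peptide    # "GK" "AR"
#' tryptic_digest("AKPGR")$peptide   # "AKPGR" (KP suppression)
tryptic_digest <- function(protein, missed_cleavages = 0L, parent_id = NA_character_) {
  stopifnot(length(protein) == 1, missed_cleavages >= 0)
  chars <- .residues(protein, "tryptic_digest")
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | chars[pmin(cut_after + 1, n)] != "P"]
  bounds <- unique(c(0L, cut_after, n)) # fragment boundaries, 0-based
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  pick <- list()
  for (w in seq_len(missed_cleavages + 1)) {
    if (w > length(starts)) break
    idx <- seq_len(length(starts) - w + 1)
    pick[[w]] <- data.frame(start = starts[idx], end = ends[idx + w - 1])
  }
  frags <- do.call(rbind, pick)
  frags <- frags[order(frags$start, frags$end), , drop = FALSE]
  pep <- substring(protein, frags$start + 1, frags$end)
  data.frame(parent_id = parent_id, start = frags$start, peptide = pep,
             mono_mass = vapply(pep, peptide_mass, numeric(1),
                                kind = "monoisotopic", charge = 0),
             avg_mass = vapply(pep, peptide_mass, numeric(1),
                               kind = "average", charge = 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Peptide mass
#'
#' Neutral mass is the sum of residue masses plus water; for `charge >= 1`
#' the m/z `(neutral + z * proton) / z` is returned.
#'
#' @param peptide Peptide sequence (character scalar, standard residues).
#' @param kind `"monoisotopic"` or `"average"`.
#' @param charge Non-negative integer; 0 (default) returns the neutral mass.
#' @return Mass in Da (numeric scalar).
#' @export
#' @examples
#' round(peptide_mass("GGAAGK", "monoisotopic", charge = 1), 2)
peptide_mass <- function(peptide, kind = c("monoisotopic", "average"),
                         charge = 0L) {
  kind <- match.arg(kind)
  stopifnot(length(peptide) == 1, charge >= 0)
  chars <- .residues(peptide, "peptide_mass")
  tab <- if (kind == "monoisotopic") MONO_RESIDUE_MASS else AVG_RESIDUE_MASS
  water <- if (kind == "monoisotopic") WATER_MONO else WATER_AVG
  neutral <- sum(tab[chars]) + water
  if (charge == 0) neutral else (neutral + charge * PROTON_MASS) / charge
}

#' Whole-protein mass
#'
#' Neutral chain mass; each disulfide bond subtracts the mass of two
#' hydrogen atoms. The default is the reduced chain (`disulfides = 0`).
#'
#' @param protein Protein sequence (character scalar, standard residues).
#' @param kind `"average"` (MALDI linear mode convention, default) or
#'   `"monoisotopic"`.
#' @param disulfides Number of disulfide bonds, default 0.
#' @return Mass in Da.
#' @export
protein_mass <- function(protein, kind = c("average", "monoisotopic"),
                         disulfides = 0L) {
  kind <- match.arg(kind)
  stopifnot(disulfides >= 0)
  h <- if (kind == "monoisotopic") HYDROGEN_MONO else HYDROGEN_AVG
  peptide_mass(protein, kind, charge = 0L) - disulfides * 2 * h
}

# Kyte-Doolittle hydropathy scale
KD_HYDROPATHY <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8, G = -0.4,
  T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2, E = -3.5,
  Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)
SMALL_RESIDUES <- c("A", "G", "S", "C", "T")

#' Split a precursor into signal peptide and mature chain
#'
#' With an explicit `cleavage_index`, the mature chain is the suffix
#' starting at that (0-based) index. Otherwise a heuristic scans candidate
#' cleavage positions 15..35, requires small residues (A, G, S, C, T) at
#' the -3 and -1 positions relative to the cut, and among qualifying
#' positions picks the one maximizing the mean Kyte-Doolittle hydropathy of
#' the 10 residues preceding the -3 position (the hydrophobic core of a
#' secretion signal).
#'
#' @param protein Precursor protein sequence (character scalar).
#' @param cleavage_index Optional 0-based index of the first mature residue.
#' @return List with elements `signal`, `mature`, `cleavage_index`, and
#'   `method` (`"explicit"` or `"heuristic"`).
#' @export
strip_signal <- function(protein, cleavage_index = NULL) {
  stopifnot(length(protein) == 1)
  n <- nchar(protein)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  if (!is.null(cleavage_index)) {
    k <- as.integer(cleavage_index)
    if (!(k > 0 && k < n)) stop("cleavage_index must satisfy 0 < index < length",
                                call. = FALSE)
    method <- "explicit"
  } else {
    cand <- 15:min(35, n - 1)
    cand <- cand[cand >= 14] # need the 10-residue window before -3
    ok <- vapply(cand, function(k) {
      chars[k - 2] %in% SMALL_RESIDUES && chars[k] %in% SMALL_RESIDUES
    }, logical(1)) # 0-based k-3, k-1 are 1-based k-2, k
    cand <- cand[ok]
    if (length(cand) == 0) {
      stop("no signal-cleavage candidate satisfies the -3/-1 small-residue ",
           "rule; supply an explicit cleavage_index", call. = FALSE)
    }
    score <- vapply(cand, function(k) {
      win <- chars[(k - 12):(k - 3)] # 0-based positions k-13 .. k-4
      mean(KD_HYDROPATHY[win], na.rm = TRUE)
    }, numeric(1))
    k <- cand[which.max(score)]
    method <- "heuristic"
  }
  list(signal = substr(protein, 1, k), mature = substr(protein, k + 1, n),
       cleavage_index = k, method = method)
}

#' Match predicted masses against observed peaks
#'
#' A pair is reported when `|predicted - mz| <= tolerance`; all qualifying
#' pairs are returned sorted by absolute delta.
#'
#' @param predicted Numeric vector of predicted masses (Da).
#' @param peaks `data.frame` with columns `mz` and `tolerance`.
#' @return `data.frame` with columns `predicted`, `mz`, `tolerance`,
#'   `delta` (`predicted - mz`).
#' @export
#' @examples
#' match_peaks(6516.8, data.frame(mz = 6518, tolerance = 5))
match_peaks <- function(predicted, peaks) {
  if (length(predicted) == 0 || is.null(peaks) || nrow(peaks) == 0) {
    return(data.frame(predicted = numeric(0), mz = numeric(0),
                      tolerance = numeric(0), delta = numeric(0)))
  }
  stopifnot(all(c("mz", "tolerance") %in% names(peaks)),
            all(peaks$mz > 0), all(peaks$tolerance >= 0))
  grid <- expand.grid(p = seq_along(predicted), q = seq_len(nrow(peaks)))
  delta <- predicted[grid$p] - peaks$mz[grid$q]
  keep <- abs(delta) <= peaks$tolerance[grid$q]
  out <- data.frame(predicted = predicted[grid$p][keep],
                    mz = peaks$mz[grid$q][keep],
                    tolerance = peaks$tolerance[grid$q][keep],
                    delta = delta[keep])
  out[order(abs(out$delta)), , drop = FALSE]
}

#' Check whether a satellite peak is a multiply-charged version of a parent
#'
#' For charge `z`, the implied neutral mass of the satellite is
#' `z * (mz - proton)`; the peak is consistent when that implied mass is
#' within `z * tolerance` of the parent neutral mass.
#'
#' @param mz Observed satellite m/z (Da).
#' @param tolerance Satellite tolerance (+/- Da on the m/z scale).
#' @param parent_neutral Parent neutral mass (Da).
#' @param z Charge hypothesis, integer >= 2.
#' @return List with `consistent` (logical), `implied_neutral`, and `delta`
#'   (`implied_neutral - parent_neutral`).
#' @export
charge_consistency <- function(mz, tolerance, parent_neutral, z = 2L) {
  if (z < 2) stop("z must be >= 2 for a satellite check", call. = FALSE)
  stopifnot(mz > 0, tolerance >= 0, parent_neutral > 0)
  implied <- z * (mz - PROTON_MASS)
  delta <- implied - parent_neutral
  list(consistent = abs(delta) <= z * tolerance,
       implied_neutral = implied, delta = delta)
}

#' Read a MALDI peak list from TSV
#'
#' Expects 2-3 columns: `mz`, `tolerance` and optionally `intensity`
#' (header required).
#'
#' @param path Path to a tab-separated peak list.
#' @return `data.frame` with columns `mz`, `tolerance` (and `intensity` if
#'   present).
#' @export
read_peak_list <- function(path) {
  peaks <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "tolerance") %in% names(peaks))) {
    stop("peak list must have columns mz and tolerance", call. = FALSE)
  }
  stopifnot(all(peaks$mz > 0), all(peaks$tolerance >= 0))
  peaks
}
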