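# Candidate characterization: molar amino-acid composition in the
# amino-acid-analysis convention (Asx pooled, Cys excluded) and detection
# of glycine-initial tripeptide-repeat tracts.

COMPOSITION_CATEGORIES <- list(
  Asx = c("D", "N"), Ser = "S", Gly = "G", Thr = "T", Ala = "A",
  Pro = "P", Val = "V", Lys = "K", Arg = "R",
  Other = c("M", "L", "I", "Q", "E", "Y", "F", "H"))

# round half up, as composition tables are conventionally printed
.round_half_up <- function(x) floor(x + 0.5)

#' Molar amino-acid composition, Cys excluded
#'
#' Categories follow the amino-acid-analysis convention: Asx pools Asp and
#' Asn, Glx is pooled into `Other` together with Met, Leu, Ile, Tyr, Phe
#' and His. Cys is excluded from numerator and denominator; Trp is likewise
#' excluded by default (set `include_trp = TRUE` to count it in `Other`).
#' Unrounded mol% values sum to 100; `display` is rounded half-up to
#' integers.
#'
#' @param protein Protein sequence (character scalar).
#' @param include_trp Count Trp in `Other` instead of excluding it.
#' @return `data.frame` with columns `category`, `count`, `mol_percent`
#'   (unrounded), `display` (integer), one row per category.
#' @export
#' @examples
#' composition_mol_percent("GGGA")
composition_mol_percent <- function(protein, include_trp = FALSE) {
  stopifnot(length(protein) == 1, nchar(protein) >= 1)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  if (!all(chars %in% AA20)) {
    stop("composition requires standard residues only", call. = FALSE)
  }
  cats <- COMPOSITION_CATEGORIES
  excluded <- if (include_trp) "C" else c("C", "W")
  if (include_trp) cats$Other <- c(cats$Other, "W")
  counted <- chars[!chars %in% excluded]
  if (length(counted) == 0) {
    stop("composition undefined: no counted residues (chain is all Cys/Trp)",
         call. = FALSE)
  }
  count <- vapply(cats, function(res) sum(counted %in% res), integer(1))
  mol <- 100 * count / length(counted)
  data.frame(category = names(cats), count = unname(count),
             mol_percent = unname(mol),
             display = unname(.round_half_up(mol)),
             stringsAsFactors = FALSE)
}

# all maximal runs of >= min_repeats consecutive G-initial triplets, for
# every reading phase; returns 0-based half-open residue intervals
.tract_candidates <- function(chars, min_repeats) {
  n <- length(chars)
  rows <- list()
  for (phase in 0:2) {
    if (phase + 3 > n) next
    starts <- seq.int(phase + 1, n - 2, by = 3)
    g <- chars[starts] == "G"
    r <- rle(g)
    ends <- cumsum(r$lengths)
    begs <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_repeats)) {
      first <- starts[begs[k]]
      rows[[length(rows) + 1]] <- data.frame(
        start = first - 1L, end = first - 1L + 3L * r$lengths[k],
        n_repeats = r$lengths[k], phase = phase)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_repeats = integer(0), phase = integer(0)))
  }
  do.call(rbind, rows)
}

#' Detect Gly-aa2-aa3 tripeptide-repeat tracts
#'
#' A tract is a maximal run of consecutive in-frame triplets each beginning
#' with Gly, at least `min_repeats` triplets long. Candidate runs are
#' collected over all three phases and the scan greedily keeps the longest
#' non-overlapping tracts (ties: leftmost, then lowest phase). A tract is
#' GG-type when more than half of its triplets also have Gly in the second
#' position.
#'
#' @param protein Protein sequence (character scalar).
#' @param min_repeats Minimum triplets per tract (default 2).
#' @return List of class `tract_summary` with `tracts` (`data.frame`:
#'   `start`, `end` 0-based half-open, `n_repeats`, `gg_type`, `phase`),
#'   `n_tracts`, and `n_gg_type`.
#' @export
#' @examples
#' find_tripeptide_tracts("GGAGGAGGA")
find_tripeptide_tracts <- function(protein, min_repeats = 2L) {
  stopifnot(length(protein) == 1, min_repeats >= 2)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  cand <- .tract_candidates(chars, min_repeats)
  cand <- cand[order(-cand$n_repeats, cand$start, cand$phase), , drop = FALSE]
  chosen <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    c_i <- cand[i, ]
    if (!any(c_i$start < chosen$end & chosen$start < c_i$end)) {
      chosen <- rbind(chosen, c_i)
    }
  }
  chosen <- chosen[order(chosen$start), , drop = FALSE]
  gg <- vapply(seq_len(nrow(chosen)), function(i) {
    second <- chars[seq.int(chosen$start[i] + 2, chosen$end[i], by = 3)]
    sum(second == "G") > chosen$n_repeats[i] / 2
  }, logical(1))
  chosen$gg_type <- gg
  rownames(chosen) <- NULL
  structure(list(tracts = chosen[c("start", "end", "n_repeats", "gg_type",
                                   "phase")],
                 n_tracts = nrow(chosen), n_gg_type = sum(gg)),
            class = "tract_summary")
}

#' @export
print.tract_summary <- function(x, ...) {
  cat("Gly-aa2-aa3 tract summary:", x$n_tracts, "tract(s),",
      x$n_gg_type, "GG-type\n")
  if (x$n_tracts > 0) print(x$tracts)
  invisible(x)
}
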