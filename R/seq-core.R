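# Sequence substrate: FASTA I/O, six-frame translation, regional GC.
# Sequences are plain named character vectors (names = record ids, values =
# upper-case residue strings); coordinates are 0-based half-open throughout.

NUC_ALPHABET <- c("A", "C", "G", "T", "N")
PROT_ALPHABET <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")
AA20 <- setdiff(PROT_ALPHABET, c("X", "*"))

.check_alphabet <- function(seqs, alphabet, what) {
  allowed <- if (alphabet == "nucleotide") NUC_ALPHABET else PROT_ALPHABET
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% allowed)
    if (length(bad) > 0) {
      stop(sprintf("illegal %s character '%s' in record '%s' at position %d",
                   what, chars[bad[1]],
                   if (is.null(names(seqs))) as.character(i) else names(seqs)[i],
                   bad[1]), call. = FALSE)
    }
  }
  invisible(seqs)
}

#' Read a FASTA file into a named character vector
#'
#' Residues are upper-cased and validated against the nucleotide alphabet
#' `A,C,G,T,N` or the protein alphabet (20 amino acids plus `X` and `*`).
#' Record order is preserved and ids must be unique.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return Named character vector of sequences, one element per record.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "acgt"), fa)
#' read_fasta(fa, "nucleotide")
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no records in FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  seqs <- setNames(toupper(as.character(set)), ids)
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for record '", ids[nchar(seqs) == 0][1], "'",
         call. = FALSE)
  }
  .check_alphabet(seqs, alphabet, alphabet)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), length(seqs) >= 1, !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Reverse complement of nucleotide sequences
#'
#' `N` maps to `N`; applying the operation twice returns the input.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("ATGC")
reverse_complement <- function(seq) {
  .check_alphabet(seq, "nucleotide", "nucleotide")
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  setNames(out, names(seq))
}

# standard-code codon table, shared by translation and reverse translation
.codon_table <- function() Biostrings::GENETIC_CODE

# byte-level translation machinery: bases map to 0..3 (N -> 4) and codons
# index a precomputed 5x5x5 lookup of amino-acid character codes, so
# six-frame scans over large EST collections stay cheap
.trans <- local({
  base_map <- rep(NA_integer_, 128)
  base_map[utf8ToInt("A") + 1] <- 0L
  base_map[utf8ToInt("C") + 1] <- 1L
  base_map[utf8ToInt("G") + 1] <- 2L
  base_map[utf8ToInt("T") + 1] <- 3L
  base_map[utf8ToInt("N") + 1] <- 4L
  aa_codes <- rep(utf8ToInt("X"), 125)
  bases <- c("A", "C", "G", "T")
  code <- Biostrings::GENETIC_CODE
  for (i in 0:3) for (j in 0:3) for (k in 0:3) {
    aa <- code[[paste0(bases[i + 1], bases[j + 1], bases[k + 1])]]
    aa_codes[25 * i + 5 * j + k + 1] <- utf8ToInt(aa)
  }
  list(base_map = base_map, aa_codes = aa_codes)
})

# s: upper-case validated nucleotide string; returns base codes 0..4
.base_codes <- function(s) .trans$base_map[utf8ToInt(s) + 1]

.rc_nocheck <- function(s) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
}

# translate base codes starting at 0-based offset; trailing codon dropped
.translate_codes <- function(codes, offset) {
  n <- length(codes) - offset
  n_codon <- if (n > 0) n %/% 3 else 0L
  if (n_codon == 0) return("")
  p <- offset + seq_len(n_codon) * 3 - 2
  intToUtf8(.trans$aa_codes[25 * codes[p] + 5 * codes[p + 1] +
                              codes[p + 2] + 1])
}

#' Translate one reading frame
#'
#' Frames 1-3 are forward offsets 0-2; frames 4-6 are offsets 0-2 of the
#' reverse complement. The trailing partial codon is dropped, stop codons
#' become `*`, and any codon containing `N` becomes `X` so downstream
#' positions are preserved.
#'
#' @param seq Single nucleotide sequence (character scalar).
#' @param frame Integer in 1..6.
#' @return Protein sequence (character scalar; may be empty for very short
#'   inputs).
#' @export
#' @examples
#' translate_frame("ATGGGA", 1) # "MG"
#' translate_frame("ATGGGA", 2) # "W"
translate_frame <- function(seq, frame) {
  stopifnot(length(seq) == 1)
  if (!(length(frame) == 1 && frame %in% 1:6)) {
    stop("frame must be an integer in 1..6", call. = FALSE)
  }
  .check_alphabet(seq, "nucleotide", "nucleotide")
  s <- if (frame >= 4) .rc_nocheck(seq) else unname(seq)
  .translate_codes(.base_codes(s), (frame - 1) %% 3)
}

#' Six-frame translation
#'
#' @param seq Single nucleotide sequence.
#' @return Character vector of six translations named `"1"`..`"6"`.
#' @export
six_frame <- function(seq) {
  stopifnot(length(seq) == 1)
  .check_alphabet(seq, "nucleotide", "nucleotide")
  fwd <- .base_codes(unname(seq))
  rev <- .base_codes(.rc_nocheck(unname(seq)))
  out <- c(vapply(0:2, function(o) .translate_codes(fwd, o), character(1)),
           vapply(0:2, function(o) .translate_codes(rev, o), character(1)))
  setNames(out, as.character(1:6))
}

#' GC content of a sequence interval
#'
#' Computed as `100 * (G + C) / (A + C + G + T)` over the interval; `N`
#' bases are excluded from both numerator and denominator. Reported to one
#' decimal place.
#'
#' @param seq Single nucleotide sequence.
#' @param start,end Optional 0-based half-open interval; the whole sequence
#'   by default.
#' @return GC percentage (numeric scalar).
#' @export
#' @examples
#' gc_content("ATGC") # 50
gc_content <- function(seq, start = NULL, end = NULL) {
  stopifnot(length(seq) == 1)
  .check_alphabet(seq, "nucleotide", "nucleotide")
  n <- nchar(seq)
  if (is.null(start)) start <- 0L
  if (is.null(end)) end <- n
  if (!(start >= 0 && end <= n && start < end)) {
    stop("invalid interval [", start, ",", end, ") for sequence of length ",
         n, call. = FALSE)
  }
  chars <- strsplit(substr(seq, start + 1, end), "", fixed = TRUE)[[1]]
  denom <- sum(chars != "N")
  if (denom == 0) stop("GC content undefined: no unambiguous bases in interval",
                       call. = FALSE)
  round(100 * sum(chars %in% c("G", "C")) / denom, 1)
}

#' Read region annotations (5'UTR / CDS / 3'UTR) from TSV
#'
#' Expects four columns: `seq_id`, `region` (one of `five_utr`, `cds`,
#' `three_utr`), `start`, `end` (0-based half-open).
#'
#' @param path Path to a tab-separated annotation file (with header).
#' @return `data.frame` with columns `seq_id`, `region`, `start`, `end`.
#' @export
read_region_annotations <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("seq_id", "region", "start", "end")
  if (!all(required %in% names(ann))) {
    stop("annotation file must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  validate_regions(ann)
  ann[required]
}

#' Validate a region annotation table
#'
#' Checks region names, interval sanity, the 5'UTR < CDS < 3'UTR ordering,
#' non-overlap, and (when sequences are supplied) that intervals lie within
#' the sequence.
#'
#' @param ann Annotation `data.frame` as in [read_region_annotations()].
#' @param seqs Optional named character vector of sequences to check bounds
#'   against.
#' @return `ann`, invisibly.
#' @export
validate_regions <- function(ann, seqs = NULL) {
  ok_regions <- c("five_utr", "cds", "three_utr")
  if (!all(ann$region %in% ok_regions)) {
    stop("unknown region name: ",
         setdiff(unique(ann$region), ok_regions)[1], call. = FALSE)
  }
  if (any(ann$start < 0 | ann$end <= ann$start)) {
    stop("region intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  for (id in unique(ann$seq_id)) {
    sub <- ann[ann$seq_id == id, ]
    if (anyDuplicated(sub$region)) {
      stop("duplicate region for sequence '", id, "'", call. = FALSE)
    }
    ord <- match(ok_regions, sub$region)
    present <- sub[ord[!is.na(ord)], ]
    if (nrow(present) > 1 &&
        any(diff(as.vector(rbind(present$start, present$end))) < 0)) {
      stop("regions for '", id,
           "' must be ordered 5'UTR < CDS < 3'UTR and non-overlapping",
           call. = FALSE)
    }
    if (!is.null(seqs)) {
      if (!id %in% names(seqs)) stop("annotation refers to unknown sequence '",
                                     id, "'", call. = FALSE)
      if (max(sub$end) > nchar(seqs[[id]])) {
        stop("region exceeds length of sequence '", id, "'", call. = FALSE)
      }
    }
  }
  invisible(ann)
}
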