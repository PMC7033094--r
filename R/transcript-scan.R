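# Core inference: scan six-frame EST translations for MS/MS peptide
# strings (I/L collapsed), extract containing ORFs, and rank candidates.

#' Collapse isobaric Ile/Leu to a common placeholder
#'
#' Tandem-MS sequencing cannot distinguish isoleucine from leucine, so both
#' are mapped to `J` before substring matching. Idempotent.
#'
#' @param s Character vector of residue strings.
#' @return Character vector with every `I` and `L` replaced by `J`.
#' @export
#' @examples
#' collapse_il(c("GLK", "GIK")) # both "GJK"
collapse_il <- function(s) chartr("IL", "JJ", s)

#' Build a peptide query table from MS/MS-derived strings
#'
#' @param peptides Character vector of residue strings (length >= 3, 20
#'   standard amino acids).
#' @param source_mass Optional numeric vector of observed monoisotopic
#'   \[M+H\]+ masses, recycled against `peptides` (`NA` when unknown).
#' @return `data.frame` with columns `raw`, `canonical` (I/L collapsed),
#'   `source_mass`.
#' @export
peptide_queries <- function(peptides, source_mass = NA_real_) {
  stopifnot(is.character(peptides), length(peptides) >= 1)
  peptides <- toupper(peptides)
  if (any(nchar(peptides) < 3)) {
    stop("peptide queries must be at least 3 residues long", call. = FALSE)
  }
  bad <- !vapply(strsplit(peptides, "", fixed = TRUE),
                 function(ch) all(ch %in% AA20), logical(1))
  if (any(bad)) stop("peptide query '", peptides[bad][1],
                     "' contains a non-standard residue", call. = FALSE)
  data.frame(raw = peptides, canonical = collapse_il(peptides),
             source_mass = rep_len(source_mass, length(peptides)),
             stringsAsFactors = FALSE)
}

#' Read peptide queries from a plain-text list
#'
#' One peptide per line, optionally followed by a tab and its observed
#' monoisotopic \[M+H\]+ mass. Blank lines and `#` comments are skipped.
#'
#' @param path Path to the peptide list.
#' @return Query `data.frame` as from [peptide_queries()].
#' @export
read_peptide_queries <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no peptide queries in ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  peps <- vapply(parts, `[`, character(1), 1)
  mass <- vapply(parts, function(p) {
    if (length(p) >= 2) suppressWarnings(as.numeric(p[2])) else NA_real_
  }, numeric(1))
  peptide_queries(peps, mass)
}

#' Scan six-frame EST translations for peptide queries
#'
#' Exact substring search of each canonical (I/L-collapsed) query against
#' the collapsed six-frame translations of every EST. `X` residues (from
#' ambiguous codons) never match. Every occurrence is reported.
#'
#' @param ests Named character vector of nucleotide sequences.
#' @param queries Query `data.frame` from [peptide_queries()].
#' @return `data.frame` with columns `est_id`, `frame` (1-6), `aa_offset`
#'   (0-based position in the frame translation), `query` (raw string),
#'   `canonical`.
#' @export
scan_ests <- function(ests, queries) {
  if (is.null(queries) || nrow(queries) == 0) {
    stop("query list must be non-empty", call. = FALSE)
  }
  stopifnot(is.character(ests), !is.null(names(ests)))
  hits <- vector("list", length(ests))
  for (i in seq_along(ests)) {
    frames <- collapse_il(six_frame(ests[[i]]))
    rows <- list()
    for (f in 1:6) {
      for (q in seq_len(nrow(queries))) {
        pos <- as.integer(gregexpr(queries$canonical[q], frames[[f]],
                                   fixed = TRUE)[[1]])
        if (pos[1] != -1) {
          rows[[length(rows) + 1]] <- data.frame(
            est_id = names(ests)[i], frame = f, aa_offset = pos - 1L,
            query = queries$raw[q], canonical = queries$canonical[q],
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows)) hits[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(est_id = character(0), frame = integer(0),
                      aa_offset = integer(0), query = character(0),
                      canonical = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Find open reading frames in one frame of an EST
#'
#' ORFs are maximal stop-free runs of the frame translation. Each run is
#' trimmed to its first ATG-encoded Met when one exists (`has_start`
#' `TRUE`); otherwise it is reported from the run start (`has_start`
#' `FALSE`), supporting 5'-truncated ESTs. `nt_start`/`nt_end` are 0-based
#' half-open coordinates on the forward strand of the EST (the stop codon
#' is included when present).
#'
#' @param est Single nucleotide sequence.
#' @param frame Integer 1-6.
#' @param min_codons Minimum protein length in codons (default 30).
#' @return `data.frame` with columns `frame`, `aa_start`, `aa_end`
#'   (0-based, half-open, in frame-translation coordinates), `nt_start`,
#'   `nt_end`, `protein`, `has_start`, `has_stop`, sorted by protein length
#'   descending.
#' @export
find_orfs <- function(est, frame, min_codons = 30L) {
  stopifnot(length(est) == 1, min_codons >= 1)
  aa <- translate_frame(est, frame)
  n_aa <- nchar(aa)
  empty <- data.frame(frame = integer(0), aa_start = integer(0),
                      aa_end = integer(0), nt_start = integer(0),
                      nt_end = integer(0), protein = character(0),
                      has_start = logical(0), has_stop = logical(0),
                      stringsAsFactors = FALSE)
  if (n_aa == 0) return(empty)
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  is_stop <- chars == "*"
  r <- rle(is_stop)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  rows <- list()
  for (k in which(!r$values)) {
    s <- run_start[k]; e <- run_end[k] # 1-based inclusive aa positions
    seg <- chars[s:e]
    m <- which(seg == "M")
    has_start <- length(m) > 0
    if (has_start) s <- s + m[1] - 1
    has_stop <- e < n_aa # run is followed by a stop codon
    prot_len <- e - s + 1
    if (prot_len < min_codons) next
    aa_start <- as.integer(s - 1); aa_end <- as.integer(e) # 0-based half-open
    offset <- as.integer((frame - 1) %% 3)
    nts <- offset + 3L * aa_start
    nte <- offset + 3L * aa_end + if (has_stop) 3L else 0L
    if (frame >= 4) { # map reverse-complement coordinates to forward strand
      L <- nchar(est)
      tmp <- nts
      nts <- L - nte
      nte <- L - tmp
    }
    rows[[length(rows) + 1]] <- data.frame(
      frame = as.integer(frame), aa_start = aa_start, aa_end = aa_end,
      nt_start = nts, nt_end = nte,
      protein = paste0(seg[(s - run_start[k] + 1):length(seg)], collapse = ""),
      has_start = has_start, has_stop = has_stop, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-nchar(out$protein), out$aa_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ORFs for every frame in which an EST has hits
.orfs_for_hits <- function(ests, hits, min_codons) {
  key <- unique(hits[c("est_id", "frame")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    o <- find_orfs(ests[[key$est_id[i]]], key$frame[i], min_codons)
    if (nrow(o)) cbind(est_id = key$est_id[i], o, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(est_id = character(0), frame = integer(0),
                      aa_start = integer(0), aa_end = integer(0),
                      nt_start = integer(0), nt_end = integer(0),
                      protein = character(0), has_start = logical(0),
                      has_stop = logical(0), stringsAsFactors = FALSE)
  }
  out
}

# distinct queries of `hits` falling inside one ORF row
.queries_in_orf <- function(hits, orf) {
  h <- hits[hits$frame == orf$frame &
              hits$aa_offset >= orf$aa_start &
              hits$aa_offset + nchar(hits$canonical) <= orf$aa_end, ,
            drop = FALSE]
  unique(h$canonical)
}

#' Rank ESTs by peptide-hit evidence concentrated in a single ORF
#'
#' Primary key: number of distinct queries hit within one ORF; secondary:
#' total matched residue length; tertiary: ORF length; ties broken by EST
#' id (lexicographic), so the ranking is a deterministic total order
#' invariant under permutation of the input.
#'
#' @param hits Hit `data.frame` from [scan_ests()].
#' @param orfs ORF `data.frame` with an `est_id` column (e.g. rows of
#'   [find_orfs()] bound per EST).
#' @return `data.frame` with columns `est_id`, `n_queries`, `matched_aa`,
#'   `orf_len`, `frame`, `aa_start`, `aa_end`, ordered best first.
#' @export
rank_candidates <- function(hits, orfs) {
  ids <- sort(unique(hits$est_id))
  rows <- lapply(ids, function(id) {
    h <- hits[hits$est_id == id, , drop = FALSE]
    o <- orfs[orfs$est_id == id, , drop = FALSE]
    best <- data.frame(est_id = id, n_queries = 0L, matched_aa = 0L,
                       orf_len = 0L, frame = NA_integer_,
                       aa_start = NA_integer_, aa_end = NA_integer_,
                       stringsAsFactors = FALSE)
    for (j in seq_len(nrow(o))) {
      q <- .queries_in_orf(h, o[j, ])
      cand <- c(length(q), sum(nchar(q)), nchar(o$protein[j]))
      cur <- c(best$n_queries, best$matched_aa, best$orf_len)
      better <- (cand[1] > cur[1]) ||
        (cand[1] == cur[1] && cand[2] > cur[2]) ||
        (cand[1] == cur[1] && cand[2] == cur[2] && cand[3] > cur[3])
      if (better) {
        best$n_queries <- cand[1]; best$matched_aa <- cand[2]
        best$orf_len <- cand[3]; best$frame <- o$frame[j]
        best$aa_start <- o$aa_start[j]; best$aa_end <- o$aa_end[j]
      }
    }
    best
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_queries, -out$matched_aa, -out$orf_len, out$est_id),
             , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identify candidate AFP transcripts in an EST collection
#'
#' Runs the full evidence chain: six-frame peptide scan, ORF extraction on
#' hit frames, signal-peptide stripping, tryptic digestion with
#' monoisotopic/average mass prediction, matching of predicted peptide
#' \[M+H\]+ masses against the queries' observed masses and of the
#' predicted whole-chain average mass against MALDI peaks, amino-acid
#' composition, Gly-tripeptide tract detection, and ranking.
#'
#' @param ests Named character vector of EST nucleotide sequences.
#' @param queries Query `data.frame` from [peptide_queries()].
#' @param peaks Optional MALDI peak `data.frame` (`mz`, `tolerance`); when
#'   `NULL` the whole-mass section is omitted.
#' @param min_codons Minimum ORF length in codons (default 30).
#' @param peptide_tol_da Tolerance for peptide-mass matching (default
#'   0.02 Da).
#' @param missed_cleavages Missed cleavages for the digest (default 0).
#' @param signal_cleavage `"auto"` for the heuristic, or a 0-based integer
#'   cleavage index applied to every candidate.
#' @return Object of class `afp_report`: list with `status`
#'   (`"ok"`/`"no candidates"`), `candidates` (ranked `data.frame`),
#'   `hits`, and `details` (per-candidate list with `orf`, `signal`,
#'   `mature`, `signal_method`, `digest`, `peptide_matches`,
#'   `whole_mass`, `whole_mass_matches`, `composition`, `tracts`).
#' @export
identify_afp_transcripts <- function(ests, queries, peaks = NULL,
                                     min_codons = 30L, peptide_tol_da = 0.02,
                                     missed_cleavages = 0L,
                                     signal_cleavage = "auto") {
  hits <- scan_ests(ests, queries)
  if (nrow(hits) == 0) {
    return(structure(list(status = "no candidates",
                          candidates = NULL, hits = hits, details = list()),
                     class = "afp_report"))
  }
  orfs <- .orfs_for_hits(ests, hits, min_codons)
  candidates <- rank_candidates(hits, orfs)
  details <- list()
  for (i in seq_len(nrow(candidates))) {
    id <- candidates$est_id[i]
    row <- candidates[i, ]
    det <- list(est_id = id)
    if (!is.na(row$frame)) {
      o <- orfs[orfs$est_id == id & orfs$frame == row$frame &
                  orfs$aa_start == row$aa_start, , drop = FALSE][1, ]
      det$orf <- o
      prot <- o$protein
      split <- if (identical(signal_cleavage, "auto")) {
        tryCatch(strip_signal(prot),
                 error = function(e) list(signal = "", mature = prot,
                                          cleavage_index = 0L, method = "none"))
      } else {
        strip_signal(prot, cleavage_index = signal_cleavage)
      }
      det$signal <- split$signal
      det$mature <- split$mature
      det$signal_method <- split$method
      det$digest <- tryCatch(
        tryptic_digest(split$mature, missed_cleavages, parent_id = id),
        error = function(e) NULL)
      if (!is.null(det$digest)) {
        qmass <- queries$source_mass[!is.na(queries$source_mass)]
        det$peptide_matches <- match_peaks(
          det$digest$mono_mass + PROTON_MASS,
          if (length(qmass)) data.frame(mz = qmass,
                                        tolerance = peptide_tol_da) else NULL)
        det$whole_mass <- protein_mass(split$mature, "average")
        det$whole_mass_matches <- match_peaks(det$whole_mass, peaks)
      }
      det$composition <- tryCatch(composition_mol_percent(split$mature),
                                  error = function(e) NULL)
      det$tracts <- find_tripeptide_tracts(split$mature)
    }
    details[[id]] <- det
  }
  structure(list(status = "ok", candidates = candidates, hits = hits,
                 details = details),
            class = "afp_report")
}

#' @export
print.afp_report <- function(x, ...) {
  cat("AFP transcript scan report\n")
  cat("status:", x$status, "\n")
  if (x$status == "no candidates") return(invisible(x))
  cat(nrow(x$hits), "peptide hits across", nrow(x$candidates),
      "candidate EST(s)\n\n")
  print(head(x$candidates, 10))
  top <- x$details[[x$candidates$est_id[1]]]
  if (!is.null(top$mature)) {
    cat("\ntop candidate:", top$est_id, "\n")
    cat("  ORF frame", top$orf$frame, "| protein", nchar(top$orf$protein),
        "aa | signal cleavage:", top$signal_method,
        "| mature", nchar(top$mature), "aa\n")
    if (!is.null(top$whole_mass)) {
      cat(sprintf("  predicted whole mass (average, reduced): %.1f Da\n",
                  top$whole_mass))
      if (nrow(top$whole_mass_matches)) {
        m <- top$whole_mass_matches[1, ]
        cat(sprintf("  matches observed peak %.1f Da (delta %+.1f)\n",
                    m$mz, m$delta))
      }
    }
    if (!is.null(top$tracts)) {
      cat("  Gly-aa2-aa3 tracts:", top$tracts$n_tracts,
          "(", top$tracts$n_gg_type, "GG-type )\n")
    }
  }
  invisible(x)
}

#' Write an AFP scan report to disk
#'
#' Writes `report.txt` (human-readable), `candidates.tsv`, `hits.tsv`, and
#' `candidates.jsonl` (one JSON object per candidate) into `dir`.
#'
#' @param report An `afp_report` from [identify_afp_transcripts()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_afp_report <- function(report, dir) {
  stopifnot(inherits(report, "afp_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w"); sink(con); print(report); sink(); close(con)
  write.table(report$hits, file.path(dir, "hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(report$candidates)) {
    write.table(report$candidates, file.path(dir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jl <- vapply(report$candidates$est_id, function(id) {
      d <- report$details[[id]]
      jsonlite::toJSON(list(
        est_id = id,
        n_queries = report$candidates$n_queries[report$candidates$est_id == id],
        mature_length = if (!is.null(d$mature)) nchar(d$mature) else NA,
        whole_mass = if (!is.null(d$whole_mass)) round(d$whole_mass, 2) else NA,
        n_tracts = if (!is.null(d$tracts)) d$tracts$n_tracts else NA),
        auto_unbox = TRUE, na = "null")
    }, character(1))
    writeLines(jl, file.path(dir, "candidates.jsonl"))
  }
  invisible(dir)
}
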