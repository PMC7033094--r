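# Fixture builders and independent brute-force oracles used across tests.

random_nuc <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_prot <- function(n, alphabet = c("A", "R", "N", "D", "C", "E", "Q",
                                        "G", "H", "I", "L", "K", "M", "F",
                                        "P", "S", "T", "W", "Y", "V")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

tmp_fasta <- function(lines) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(lines, fa)
  fa
}

# trypsin oracle: test every position against the K/R-not-before-P rule
brute_digest <- function(protein) {
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(ch)
  frags <- character(0)
  cur <- ""
  for (i in seq_len(n)) {
    cur <- paste0(cur, ch[i])
    cleave <- ch[i] %in% c("K", "R") && (i == n || ch[i + 1] != "P")
    if (cleave || i == n) {
      frags <- c(frags, cur)
      cur <- ""
    }
  }
  frags
}

# peptide scan oracle: test every (est, frame, offset) pair explicitly
brute_scan <- function(ests, queries) {
  rows <- list()
  for (id in names(ests)) {
    for (f in 1:6) {
      aa <- collapse_il(translate_frame(ests[[id]], f))
      for (q in seq_len(nrow(queries))) {
        qs <- queries$canonical[q]
        L <- nchar(qs)
        if (nchar(aa) < L) next
        for (off in 0:(nchar(aa) - L)) {
          if (substr(aa, off + 1, off + L) == qs) {
            rows[[length(rows) + 1]] <- data.frame(
              est_id = id, frame = f, aa_offset = off,
              query = queries$raw[q], stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(est_id = character(0), frame = integer(0),
                      aa_offset = integer(0), query = character(0))
  }
  out[order(out$est_id, out$frame, out$aa_offset, out$query), , drop = FALSE]
}

# dot plot oracle: exhaustive double loop over window starts
brute_dotplot <- function(a, b, window, threshold) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  rows <- list()
  for (i in 0:(length(ca) - window)) {
    for (j in 0:(length(cb) - window)) {
      wa <- ca[(i + 1):(i + window)]
      wb <- cb[(j + 1):(j + window)]
      ident <- 100 * sum(wa == wb & wa != "N" & wb != "N") / window
      if (ident > threshold) rows[[length(rows) + 1]] <- c(i, j)
    }
  }
  if (length(rows) == 0) return(data.frame(i = integer(0), j = integer(0)))
  m <- do.call(rbind, rows)
  data.frame(i = m[, 1], j = m[, 2])
}

sort_points <- function(df) {
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  df
}

small_params <- function(seed, ...) {
  args <- list(seed = seed, n_decoys = 25L,
               decoy_length_range = c(150L, 400L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(afp_generator_params, args)
}
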