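# Seeded ground-truth generator: a glycine-rich secreted AFP coding
# sequence (signal peptide + tract/turn mature chain, Cys in turns)
# embedded in a cDNA with AT-rich UTRs and higher-GC CDS, planted among
# random decoy ESTs, plus simulated peptide detections and MALDI peaks.

TRACT_AA2 <- c(A = 0.4, S = 0.15, T = 0.15, N = 0.15, V = 0.15)
TRACT_AA3 <- c(A = 0.35, V = 0.15, T = 0.15, S = 0.15, N = 0.1, K = 0.1)
TURN_AA <- c(S = 0.2, T = 0.2, N = 0.15, D = 0.15, A = 0.1, P = 0.1, E = 0.1)

#' Parameters for the synthetic AFP study generator
#'
#' Defaults describe the emulated study conditions: one planted transcript
#' among 500 decoy ESTs of 300-900 bp, AT-rich UTRs (GC target 30%) around
#' a higher-GC coding sequence (55%), a mature chain of six Gly-aa2-aa3
#' tracts (half of the aa2 positions Gly, so about half the tracts are
#' GG-type) separated by Gly-free turns carrying four Cys, peptide
#' detection probability 0.8, mass noise sd 2 Da with a 5 Da tolerance
#' floor, and isoform whole-mass offsets of 0/51/74/594 Da.
#'
#' @param seed Integer seed; fully determines every generated object.
#' @param n_decoys Number of decoy ESTs.
#' @param decoy_length_range,decoy_gc_range Decoy length (bp) and GC (%)
#'   ranges, drawn uniformly per decoy.
#' @param utr_gc_target,cds_gc_target Regional GC targets (%).
#' @param five_utr_length_range,three_utr_length_range UTR length ranges (bp).
#' @param n_tracts Number of Gly-aa2-aa3 tracts in the mature chain.
#' @param repeats_per_tract_range Triplet repeats per tract.
#' @param turn_length_range Turn length range (residues) between tracts.
#' @param aa2_gly_fraction Probability that a triplet's second residue is Gly.
#' @param n_cys Cysteines placed in turn regions (default 4).
#' @param signal_length_range Signal-peptide length range (residues).
#' @param isoform_mass_offsets Da offsets of isoform whole masses relative
#'   to the planted chain.
#' @param mass_noise_sd Gaussian noise sd (Da) on MALDI peak positions.
#' @param detection_prob Per-tryptic-peptide detection probability.
#' @param satellites Also emit doubly-charged satellite peaks.
#' @return Validated parameter list of class `afp_generator_params`.
#' @export
afp_generator_params <- function(seed,
                                 n_decoys = 500L,
                                 decoy_length_range = c(300L, 900L),
                                 decoy_gc_range = c(35, 55),
                                 utr_gc_target = 30,
                                 cds_gc_target = 55,
                                 five_utr_length_range = c(40L, 120L),
                                 three_utr_length_range = c(80L, 250L),
                                 n_tracts = 6L,
                                 repeats_per_tract_range = c(4L, 6L),
                                 turn_length_range = c(3L, 4L),
                                 aa2_gly_fraction = 0.5,
                                 n_cys = 4L,
                                 signal_length_range = c(18L, 24L),
                                 isoform_mass_offsets = c(0, 51, 74, 594),
                                 mass_noise_sd = 2,
                                 detection_prob = 0.8,
                                 satellites = FALSE) {
  stopifnot(length(seed) == 1, is.finite(seed), abs(seed) < 2^31,
            n_decoys >= 0,
            diff(decoy_length_range) >= 0, diff(repeats_per_tract_range) >= 0,
            diff(turn_length_range) >= 0, diff(signal_length_range) >= 0,
            aa2_gly_fraction >= 0, aa2_gly_fraction <= 1,
            detection_prob >= 0, detection_prob <= 1,
            n_tracts >= 2, n_cys >= 0, mass_noise_sd >= 0,
            repeats_per_tract_range[1] >= 2,
            turn_length_range[1] >= 3, signal_length_range[1] >= 15,
            signal_length_range[2] <= 35)
  p <- as.list(environment())
  structure(p, class = "afp_generator_params")
}

.sample_weighted <- function(n, weights) {
  sample(names(weights), n, replace = TRUE, prob = weights)
}

# choose codons for `protein` (+ terminal stop) greedily steering GC toward
# target_pct; errors when the target is outside the achievable range
.reverse_translate <- function(protein, target_pct) {
  code <- .codon_table()
  by_aa <- split(names(code), unname(code))
  chars <- c(strsplit(protein, "", fixed = TRUE)[[1]], "*")
  gc_of <- function(codon) {
    vapply(strsplit(codon, "", fixed = TRUE),
           function(x) sum(x %in% c("G", "C")), integer(1))
  }
  lo <- sum(vapply(chars, function(a) min(gc_of(by_aa[[a]])), numeric(1)))
  hi <- sum(vapply(chars, function(a) max(gc_of(by_aa[[a]])), numeric(1)))
  n_nt <- 3 * length(chars)
  target <- target_pct / 100
  if (target < lo / n_nt || target > hi / n_nt) {
    stop(sprintf(
      "cds_gc_target %.1f%% infeasible for this protein; achievable range %.1f-%.1f%%",
      target_pct, 100 * lo / n_nt, 100 * hi / n_nt), call. = FALSE)
  }
  gc_run <- 0; nt_run <- 0
  codons <- character(length(chars))
  for (i in seq_along(chars)) {
    opts <- by_aa[[chars[i]]]
    g <- gc_of(opts)
    dev <- abs((gc_run + g) / (nt_run + 3) - target)
    best <- opts[dev == min(dev)]
    codons[i] <- if (length(best) > 1) sample(best, 1) else best
    gc_run <- gc_run + gc_of(codons[i]); nt_run <- nt_run + 3
  }
  paste0(codons, collapse = "")
}

.random_nt <- function(n, gc_pct) {
  p <- gc_pct / 100
  paste0(sample(c("G", "C", "A", "T"), n, replace = TRUE,
                prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2)),
         collapse = "")
}

#' Generate a synthetic AFP gene with ground truth
#'
#' Builds a mature chain of alternating Gly-aa2-aa3 tracts and Gly-free
#' turns (turns terminate alternately in Lys/Arg so the tryptic digest has
#' a known fragment structure; `n_cys` cysteines are placed in turn
#' interiors), prepends a signal peptide with a hydrophobic core and small
#' residues at the -3/-1 positions, reverse-translates toward the CDS GC
#' target, and flanks the coding sequence with AT-rich UTRs.
#'
#' @param params An [afp_generator_params()] object.
#' @return Object of class `synthetic_truth`: list with `cdna` (named
#'   character), `regions` (annotation `data.frame`), `frame` (reading
#'   frame of the ORF on the cDNA), `signal`, `mature`, `precursor`,
#'   `tract_intervals` (0-based half-open intervals of the planted tracts
#'   in the mature chain), `peptides` (tryptic digest with masses),
#'   `whole_mass_avg`, `whole_mass_mono`, `isoform_masses`, `params`.
#' @export
make_afp_gene <- function(params) {
  stopifnot(inherits(params, "afp_generator_params"))
  with_seed(params$seed, {
    n_t <- params$n_tracts
    reps <- sample(seq(params$repeats_per_tract_range[1],
                       params$repeats_per_tract_range[2]), n_t, replace = TRUE)
    tracts <- lapply(reps, function(r) {
      aa2 <- ifelse(runif(r) < params$aa2_gly_fraction, "G",
                    .sample_weighted(r, TRACT_AA2))
      aa3 <- .sample_weighted(r, TRACT_AA3)
      paste0("G", aa2, aa3, collapse = "")
    })
    turn_lens <- sample(seq(params$turn_length_range[1],
                            params$turn_length_range[2]), n_t - 1,
                        replace = TRUE)
    # each turn offers (length - 1) interior slots for Cys (the terminal
    # K/R is reserved); lengthen turns round-robin until n_cys fits
    deficit <- params$n_cys - sum(turn_lens - 1)
    i <- 1
    while (deficit > 0) {
      turn_lens[i] <- turn_lens[i] + 1L
      deficit <- deficit - 1
      i <- i %% (n_t - 1) + 1
    }
    turns <- lapply(seq_len(n_t - 1), function(i) {
      body <- .sample_weighted(turn_lens[i] - 1, TURN_AA)
      paste0(paste0(body, collapse = ""), if (i %% 2 == 1) "K" else "R")
    })
    # interleave tracts and turns; record tract intervals in mature coords
    pieces <- character(2 * n_t - 1)
    pieces[seq(1, 2 * n_t - 1, by = 2)] <- unlist(tracts)
    if (n_t > 1) pieces[seq(2, 2 * n_t - 2, by = 2)] <- unlist(turns)
    lens <- nchar(pieces)
    starts <- cumsum(c(0, lens[-length(lens)]))
    tract_idx <- seq(1, 2 * n_t - 1, by = 2)
    tract_intervals <- data.frame(start = starts[tract_idx],
                                  end = starts[tract_idx] + lens[tract_idx])
    mature <- paste0(pieces, collapse = "")
    # place Cys in turn interiors (never the terminal K/R)
    if (params$n_cys > 0) {
      turn_idx <- seq(2, 2 * n_t - 2, by = 2)
      slots <- unlist(lapply(turn_idx, function(k) {
        seq(starts[k] + 1, starts[k] + lens[k] - 1) # 1-based, interior
      }))
      if (length(slots) < params$n_cys) {
        stop("not enough turn interior positions for n_cys cysteines",
             call. = FALSE)
      }
      put <- sort(sample(slots, params$n_cys))
      m <- strsplit(mature, "", fixed = TRUE)[[1]]
      m[put] <- "C"
      mature <- paste0(m, collapse = "")
    }
    # signal peptide: Met + Leu core with an A-P-A cleavage motif, so the
    # -3/-1 small-residue rule holds and the hydrophobic-core score of the
    # true cut strictly dominates any downstream candidate
    s_len <- sample(seq(params$signal_length_range[1],
                        params$signal_length_range[2]), 1)
    sig <- c("M", rep("L", s_len - 1))
    sig[s_len - 2] <- "A" # -3 relative to the cut
    sig[s_len - 1] <- "P" # -2
    sig[s_len] <- "A"     # -1
    signal <- paste0(sig, collapse = "")
    precursor <- paste0(signal, mature)
    cds <- .reverse_translate(precursor, params$cds_gc_target)
    utr3 <- .random_nt(sample(seq(params$three_utr_length_range[1],
                                  params$three_utr_length_range[2]), 1),
                       params$utr_gc_target)
    # the planted transcript must present the designed precursor as its
    # ORF (no upstream in-frame ATG left open), so ORF extraction and
    # signal stripping reconstruct the planted chain; resample the 5'UTR
    # until the ORF in the CDS frame is exactly the precursor
    for (try in 1:100) {
      utr5 <- .random_nt(sample(seq(params$five_utr_length_range[1],
                                    params$five_utr_length_range[2]), 1),
                         params$utr_gc_target)
      frame <- (nchar(utr5) %% 3) + 1L
      cand_cdna <- paste0(utr5, cds, utr3)
      orfs <- find_orfs(cand_cdna, frame, min_codons = 1L)
      if (any(orfs$protein == precursor)) break
      if (try == 100) stop("could not embed an open-reading-frame-clean ",
                           "5'UTR after 100 draws", call. = FALSE)
    }
    cdna <- setNames(cand_cdna, "AFP_PLANTED")
    regions <- data.frame(
      seq_id = "AFP_PLANTED",
      region = c("five_utr", "cds", "three_utr"),
      start = c(0L, nchar(utr5), nchar(utr5) + nchar(cds)),
      end = c(nchar(utr5), nchar(utr5) + nchar(cds), nchar(cdna)),
      stringsAsFactors = FALSE)
    peptides <- tryptic_digest(mature, 0L, parent_id = "AFP_PLANTED")
    structure(list(
      cdna = cdna, regions = regions,
      frame = frame,
      signal = signal, mature = mature, precursor = precursor,
      tract_intervals = tract_intervals,
      peptides = peptides,
      whole_mass_avg = protein_mass(mature, "average"),
      whole_mass_mono = protein_mass(mature, "monoisotopic"),
      isoform_masses = protein_mass(mature, "average") +
        params$isoform_mass_offsets,
      params = params), class = "synthetic_truth")
  })
}

#' Generate an EST collection with the synthetic gene planted in it
#'
#' Decoys are i.i.d. nucleotide draws at per-decoy random length/GC,
#' rejection-checked so that no decoy contains any true tryptic peptide in
#' any reading frame (under I/L collapse); the planted cDNA is inserted at
#' a seed-determined position and all records get uniform
#' pseudo-accession-style ids.
#'
#' @param truth A `synthetic_truth` from [make_afp_gene()].
#' @param params The same [afp_generator_params()] object.
#' @param max_retries Rejection-sampling retries per decoy (default 50).
#' @return List with `ests` (named character vector) and `planted_id`.
#' @export
make_est_collection <- function(truth, params, max_retries = 50L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(params, "afp_generator_params"))
  true_queries <- peptide_queries(truth$peptides$peptide)
  with_seed(params$seed + 1L, {
    n <- params$n_decoys
    decoys <- character(n)
    for (i in seq_len(n)) {
      for (try in seq_len(max_retries)) {
        len <- sample(seq(params$decoy_length_range[1],
                          params$decoy_length_range[2]), 1)
        gc <- runif(1, params$decoy_gc_range[1], params$decoy_gc_range[2])
        cand <- .random_nt(len, gc)
        clean <- nrow(scan_ests(setNames(cand, "d"), true_queries)) == 0
        if (clean) break
        if (try == max_retries) {
          stop("could not generate a decoy free of true peptides after ",
               max_retries, " retries", call. = FALSE)
        }
      }
      decoys[i] <- cand
    }
    pos <- sample(seq_len(n + 1), 1)
    seqs <- append(decoys, unname(truth$cdna), after = pos - 1)
    ids <- sprintf("SYN%05d", seq_len(n + 1))
    list(ests = setNames(seqs, ids), planted_id = ids[pos])
  })
}

#' Simulate MS/MS peptide detections and a MALDI peak list
#'
#' Each true tryptic peptide is detected with probability
#' `detection_prob`, carrying its monoisotopic \[M+H\]+ as `source_mass`.
#' MALDI peaks are the true whole (average, reduced) mass plus the isoform
#' offsets, perturbed by Gaussian noise of sd `mass_noise_sd`; tolerances
#' are `max(5, 3 * sd)` Da. With `satellites = TRUE`, doubly-charged
#' satellites at `(m + 2 * proton) / 2` are appended.
#'
#' @param truth A `synthetic_truth` from [make_afp_gene()].
#' @param params The same [afp_generator_params()] object.
#' @return List with `queries` (peptide query `data.frame`; empty with a
#'   warning if nothing was detected) and `peaks` (`data.frame` with `mz`,
#'   `tolerance`, `charge`).
#' @export
simulate_observations <- function(truth, params) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(params, "afp_generator_params"))
  with_seed(params$seed + 2L, {
    detected <- runif(nrow(truth$peptides)) < params$detection_prob
    queries <- if (any(detected)) {
      peptide_queries(truth$peptides$peptide[detected],
                      truth$peptides$mono_mass[detected] + PROTON_MASS)
    } else {
      warning("no tryptic peptides were detected at this seed/detection_prob")
      data.frame(raw = character(0), canonical = character(0),
                 source_mass = numeric(0), stringsAsFactors = FALSE)
    }
    tol <- max(5, 3 * params$mass_noise_sd)
    mz <- truth$isoform_masses + rnorm(length(truth$isoform_masses),
                                       sd = params$mass_noise_sd)
    peaks <- data.frame(mz = mz, tolerance = tol, charge = NA_integer_)
    if (isTRUE(params$satellites)) {
      sat <- data.frame(mz = (truth$isoform_masses + 2 * PROTON_MASS) / 2 +
                          rnorm(length(truth$isoform_masses),
                                sd = params$mass_noise_sd / 2),
                        tolerance = tol / 2, charge = 2L)
      peaks <- rbind(peaks, sat)
    }
    list(queries = queries, peaks = peaks)
  })
}

#' Simulate a complete synthetic AFP study
#'
#' Convenience wrapper: [make_afp_gene()] + [make_est_collection()] +
#' [simulate_observations()] under one parameter set.
#'
#' @param params An [afp_generator_params()] object (or a bare seed, which
#'   selects all defaults).
#' @return List with `truth`, `ests`, `planted_id`, `queries`, `peaks`.
#' @export
#' @examples
#' study <- simulate_afp_study(afp_generator_params(seed = 1, n_decoys = 5))
#' names(study)
simulate_afp_study <- function(params) {
  if (is.numeric(params)) params <- afp_generator_params(seed = params)
  truth <- make_afp_gene(params)
  coll <- make_est_collection(truth, params)
  obs <- simulate_observations(truth, params)
  list(truth = truth, ests = coll$ests, planted_id = coll$planted_id,
       queries = obs$queries, peaks = obs$peaks)
}

#' Write a simulated study to disk
#'
#' Writes `ests.fasta`, `peptides.txt`, `peaks.tsv`, `regions.tsv` and
#' `truth.json` into `dir`.
#'
#' @param study Output of [simulate_afp_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_afp_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(study$ests, file.path(dir, "ests.fasta"))
  writeLines(sprintf("%s\t%.5f", study$queries$raw, study$queries$source_mass),
             file.path(dir, "peptides.txt"))
  write.table(study$peaks, file.path(dir, "peaks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  regions <- study$truth$regions
  regions$seq_id <- study$planted_id
  write.table(regions, file.path(dir, "regions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    planted_id = study$planted_id, frame = study$truth$frame,
    signal = study$truth$signal, mature = study$truth$mature,
    whole_mass_avg = study$truth$whole_mass_avg,
    peptides = study$truth$peptides$peptide,
    isoform_masses = study$truth$isoform_masses),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
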