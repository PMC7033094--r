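test_that("I/L collapse is the designed isobaric equivalence", {
  expect_identical(collapse_il("GLK"), "GJK")
  expect_identical(collapse_il("GIK"), collapse_il("GLK"))
  expect_identical(collapse_il("GGAAGK"), "GGAAGK") # fixed point
  expect_identical(collapse_il(collapse_il("ILIL")), collapse_il("ILIL"))
})

test_that("peptide queries are validated and canonicalized", {
  q <- peptide_queries(c("GGAAGK", "ALK"), c(460.25, NA))
  expect_identical(q$canonical, c("GGAAGK", "AJK"))
  expect_error(peptide_queries("GK"), "at least 3")
  expect_error(peptide_queries("GBKX"), "non-standard")

  f <- tempfile()
  writeLines(c("# detected peptides", "GGAAGK\t460.25", "", "ALK"), f)
  rq <- read_peptide_queries(f)
  expect_identical(rq$raw, c("GGAAGK", "ALK"))
  expect_equal(rq$source_mass, c(460.25, NA))
})

test_that("EST scanning finds canonical query occurrences in six frames", {
  ests <- c(e1 = "GGAGGAGCAGCAGGAAAA") # frame 1: GGAAGK
  q <- peptide_queries("GGAAGK")
  hits <- scan_ests(ests, q)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$frame, 1L)
  expect_identical(hits$aa_offset, 0L)

  expect_identical(nrow(scan_ests(ests, peptide_queries("ALK"))), 0L)

  # I/L collapse by construction: EST codes AIK, query says ALK
  ests2 <- c(e2 = paste0("GCTATTAAA", "TTT"))
  expect_identical(nrow(scan_ests(ests2, peptide_queries("ALK"))), 1L)

  expect_error(scan_ests(ests, NULL), "non-empty")
})

test_that("scanning agrees with the exhaustive (frame, offset) oracle", {
  set.seed(47)
  for (rep in 1:5) {
    ests <- setNames(vapply(1:12, function(i) random_nuc(sample(60:250, 1)),
                            character(1)), sprintf("e%02d", 1:12))
    # queries sampled from real translations (guaranteed hits) plus decoys
    qs <- character(0)
    for (k in 1:3) {
      id <- sample(names(ests), 1)
      aa <- translate_frame(ests[[id]], sample(1:6, 1))
      aa <- gsub("[*X]", "A", aa)
      if (nchar(aa) >= 6) {
        s <- sample(nchar(aa) - 5, 1)
        qs <- c(qs, substr(aa, s, s + sample(3:5, 1)))
      }
    }
    qs <- unique(c(qs, random_prot(4), random_prot(5)))
    qs <- qs[nchar(qs) >= 3]
    queries <- peptide_queries(qs)
    got <- scan_ests(ests, queries)
    got <- got[order(got$est_id, got$frame, got$aa_offset, got$query),
               c("est_id", "frame", "aa_offset", "query")]
    rownames(got) <- NULL
    want <- brute_scan(ests, queries)
    rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("every hit re-translates to its query under I/L collapse", {
  set.seed(53)
  ests <- setNames(vapply(1:20, function(i) random_nuc(sample(90:300, 1)),
                          character(1)), sprintf("s%02d", 1:20))
  id <- sample(names(ests), 1)
  aa <- gsub("[*X]", "G", translate_frame(ests[[id]], 3))
  queries <- peptide_queries(substr(aa, 3, 8))
  hits <- scan_ests(ests, queries)
  expect_gt(nrow(hits), 0)
  for (r in seq_len(nrow(hits))) {
    tr <- translate_frame(ests[[hits$est_id[r]]], hits$frame[r])
    frag <- substr(tr, hits$aa_offset[r] + 1,
                   hits$aa_offset[r] + nchar(hits$canonical[r]))
    expect_identical(collapse_il(frag), hits$canonical[r])
  }
})

test_that("ORF finding trims to ATG when present and tolerates truncation", {
  # frame 3 of this sequence reads ATG GGA TAA
  o <- find_orfs("AAATGGGATAAAA", 3, min_codons = 1)
  expect_identical(o$protein, "MG")
  expect_true(o$has_start && o$has_stop)
  expect_identical(o$nt_start, 2L)
  expect_identical(o$nt_end, 11L) # stop codon included

  o2 <- find_orfs("GGAGGAGGA", 1, min_codons = 1)
  expect_identical(o2$protein, "GGG")
  expect_false(o2$has_start || o2$has_stop)

  expect_identical(nrow(find_orfs("TAATAATAA", 1, min_codons = 1)), 0L)
})

test_that("ORF nucleotide intervals re-translate to the ORF protein", {
  set.seed(61)
  for (i in 1:12) {
    est <- random_nuc(sample(120:400, 1))
    f <- sample(1:6, 1)
    orfs <- find_orfs(est, f, min_codons = 5)
    for (r in seq_len(nrow(orfs))) {
      sub <- substr(est, orfs$nt_start[r] + 1, orfs$nt_end[r])
      if (f >= 4) sub <- unname(reverse_complement(sub))
      tr <- translate_frame(sub, 1)
      expect_identical(sub("\\*$", "", tr), orfs$protein[r])
      if (orfs$has_stop[r]) expect_match(tr, "\\*$")
    }
  }
})

test_that("candidate ranking follows the documented key order", {
  orfs <- data.frame(
    est_id = c("A", "B", "C"), frame = 1L, aa_start = 0L, aa_end = 40L,
    nt_start = 0L, nt_end = 120L,
    protein = c(strrep("G", 40), strrep("G", 40), strrep("G", 40)),
    has_start = TRUE, has_stop = FALSE, stringsAsFactors = FALSE)
  hit <- function(id, off, q) data.frame(est_id = id, frame = 1L,
                                         aa_offset = off, query = q,
                                         canonical = collapse_il(q),
                                         stringsAsFactors = FALSE)
  # A: 2 distinct queries; B: 1 query; C: 1 longer query
  hits <- rbind(hit("A", 0, "GGGG"), hit("A", 10, "GGGGG"),
                hit("B", 0, "GGGG"), hit("C", 0, "GGGGGGGG"))
  r <- rank_candidates(hits, orfs)
  expect_identical(r$est_id, c("A", "C", "B")) # count, then matched length

  # full tie broken lexicographically by id
  hits2 <- rbind(hit("B", 0, "GGGG"), hit("A", 0, "GGGG"))
  r2 <- rank_candidates(hits2, orfs[orfs$est_id %in% c("A", "B"), ])
  expect_identical(r2$est_id, c("A", "B"))
})

test_that("ranking is invariant under permutation of the EST collection", {
  st <- simulate_afp_study(small_params(101))
  rep1 <- identify_afp_transcripts(st$ests, st$queries, st$peaks)
  set.seed(1)
  shuffled <- st$ests[sample(length(st$ests))]
  rep2 <- identify_afp_transcripts(shuffled, st$queries, st$peaks)
  expect_identical(rep1$candidates, rep2$candidates)
})

test_that("the pipeline recovers a planted transcript and reports evidence", {
  st <- simulate_afp_study(small_params(202))
  rep <- identify_afp_transcripts(st$ests, st$queries, st$peaks)
  expect_identical(rep$status, "ok")
  expect_identical(rep$candidates$est_id[1], st$planted_id)

  top <- rep$details[[st$planted_id]]
  expect_identical(top$mature, st$truth$mature)
  expect_identical(top$digest$peptide, st$truth$peptides$peptide)
  expect_equal(top$whole_mass, st$truth$whole_mass_avg, tolerance = 1e-9)
  expect_gt(top$composition$mol_percent[top$composition$category == "Gly"], 35)

  out <- tempfile()
  write_afp_report(rep, out)
  expect_true(all(file.exists(file.path(out, c("report.txt", "hits.tsv",
                                               "candidates.tsv",
                                               "candidates.jsonl")))))
})

test_that("a decoy-only collection yields an explicit no-candidate status", {
  st <- simulate_afp_study(small_params(303))
  decoys <- st$ests[names(st$ests) != st$planted_id]
  rep <- identify_afp_transcripts(decoys, st$queries, st$peaks)
  expect_identical(rep$status, "no candidates")
  expect_identical(nrow(rep$hits), 0L)
})

test_that("a noise-free peak at the true mass matches with zero delta", {
  p <- small_params(404, mass_noise_sd = 0, isoform_mass_offsets = 0)
  st <- simulate_afp_study(p)
  rep <- identify_afp_transcripts(st$ests, st$queries, st$peaks)
  wm <- rep$details[[st$planted_id]]$whole_mass_matches
  expect_gt(nrow(wm), 0)
  expect_equal(wm$delta[1], 0, tolerance = 1e-9)
})
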