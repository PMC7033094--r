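test_that("tryptic digestion applies the K/R-not-before-P rule", {
  expect_identical(tryptic_digest("GKAR")$peptide, c("GK", "AR"))
  expect_identical(tryptic_digest("AKPGR")$peptide, "AKPGR") # KP suppressed
  expect_identical(tryptic_digest("GKAR")$start, c(0L, 2L))

  # missed cleavages add windows of adjacent fragments
  d1 <- tryptic_digest("GKARVVK", missed_cleavages = 1)
  expect_setequal(d1$peptide, c("GK", "AR", "VVK", "GKAR", "ARVVK"))

  expect_error(tryptic_digest("GXK"), "no defined mass")
})

test_that("digestion agrees with a brute-force positional scanner", {
  set.seed(23)
  for (i in 1:30) {
    p <- random_prot(sample(3:30, 1))
    expect_identical(tryptic_digest(p)$peptide, brute_digest(p), label = p)
  }
})

test_that("digestion conserves the chain and its mass", {
  set.seed(31)
  for (i in 1:15) {
    p <- random_prot(sample(5:60, 1))
    d <- tryptic_digest(p)
    expect_identical(paste0(d$peptide, collapse = ""), p)
    # sum of fragment neutral masses = chain mass + (n-1) waters
    k <- mass_constants()
    expect_equal(sum(d$mono_mass),
                 protein_mass(p, "monoisotopic") +
                   (nrow(d) - 1) * k$water_monoisotopic,
                 tolerance = 1e-9)
    expect_equal(sum(d$avg_mass),
                 protein_mass(p, "average") + (nrow(d) - 1) * k$water_average,
                 tolerance = 1e-9)
  }
})

test_that("peptide masses match residue-table summation", {
  expect_equal(peptide_mass("G", "monoisotopic", charge = 1), 76.04,
               tolerance = 0.005)
  expect_equal(peptide_mass("GK", "monoisotopic", charge = 1), 204.13,
               tolerance = 0.005)
  expect_equal(peptide_mass("GGAAGK", "monoisotopic", charge = 1), 460.24,
               tolerance = 0.02)
  expect_equal(protein_mass("G", "average"), 75.07, tolerance = 0.005)
  expect_error(peptide_mass("GBK"), "no defined mass")
})

test_that("mass is strictly monotone in residues and mono < average", {
  k <- mass_constants()
  expect_true(all(k$monoisotopic < k$average))
  expect_setequal(names(k$monoisotopic), names(k$average))
  set.seed(3)
  for (i in 1:10) {
    p <- random_prot(sample(1:20, 1))
    extra <- paste0(p, random_prot(1))
    expect_gt(peptide_mass(extra, "monoisotopic"),
              peptide_mass(p, "monoisotopic"))
    expect_gt(peptide_mass(extra, "average"), peptide_mass(p, "average"))
  }
})

test_that("disulfides subtract two hydrogens each", {
  p <- random_prot(30)
  expect_equal(protein_mass(p, "average", disulfides = 2),
               protein_mass(p, "average") - 4.03, tolerance = 0.01)
})

test_that("signal stripping honors explicit indices and the -3/-1 heuristic", {
  p <- paste0(random_prot(20), "GGAGGA")
  s <- strip_signal(p, cleavage_index = 20)
  expect_identical(s$mature, "GGAGGA")
  expect_identical(nchar(s$signal), 20L)
  expect_identical(s$method, "explicit")
  expect_error(strip_signal(p, cleavage_index = 0), "cleavage_index")

  # constructed secretion signal: Leu core, small residues at -3/-1
  sig <- paste0("M", strrep("L", 16), "APA")
  mature <- "GGAGGAGGAGNAGSTK"
  h <- strip_signal(paste0(sig, mature))
  expect_identical(h$method, "heuristic")
  expect_identical(h$mature, mature)

  # poly-D amino terminus offers no small-residue site
  expect_error(strip_signal(paste0(strrep("D", 40), "GGAGGA")),
               "explicit index|cleavage_index")
})

test_that("peak matching reports qualifying pairs sorted by delta", {
  m <- match_peaks(6516.8, data.frame(mz = 6518, tolerance = 5))
  expect_identical(nrow(m), 1L)
  expect_equal(m$delta, -1.2)

  expect_identical(nrow(match_peaks(7000, data.frame(mz = 6518, tolerance = 5))),
                   0L)
  exact <- match_peaks(6518, data.frame(mz = 6518, tolerance = 5))
  expect_equal(exact$delta, 0)

  several <- match_peaks(c(100, 103, 200),
                         data.frame(mz = c(101, 199), tolerance = c(2.5, 2.5)))
  expect_equal(several$delta, sort(several$delta[order(abs(several$delta))]),
               tolerance = 1e-12)
  expect_true(all(abs(several$delta) <= several$tolerance))
})

test_that("peak matching is invariant under a common mass shift", {
  set.seed(19)
  predicted <- runif(10, 400, 8000)
  peaks <- data.frame(mz = runif(8, 400, 8000), tolerance = runif(8, 1, 25))
  base <- match_peaks(predicted, peaks)
  shifted <- match_peaks(predicted + 37.5,
                         transform(peaks, mz = mz + 37.5))
  expect_identical(nrow(base), nrow(shifted))
  expect_equal(base$delta, shifted$delta, tolerance = 1e-9)
})

test_that("doubly-charged satellites are checked by implied neutral mass", {
  # 8448 m/z vs the 16887 Da species: implied neutral ~ 16894, within 2x10
  r <- charge_consistency(8448, 10, 16887, z = 2)
  expect_true(r$consistent)
  expect_equal(r$delta, 2 * (8448 - 1.007276) - 16887, tolerance = 1e-6)

  # 3354 m/z vs the 7112 Da species: implied neutral ~ 6706 -- inconsistent
  r2 <- charge_consistency(3354, 10, 7112, z = 2)
  expect_false(r2$consistent)
  expect_lt(r2$implied_neutral, 6707)

  parent <- 9000
  exact <- charge_consistency((parent + 2 * 1.007276) / 2, 5, parent, z = 2)
  expect_true(exact$consistent)
  expect_equal(exact$delta, 0, tolerance = 1e-9)

  expect_error(charge_consistency(3354, 10, 7112, z = 1), "z must be")
})

test_that("peak lists round-trip through TSV", {
  peaks <- data.frame(mz = c(6518, 7112), tolerance = c(5, 5),
                      intensity = c(100, 40))
  tsv <- tempfile(fileext = ".tsv")
  write.table(peaks, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_peak_list(tsv), peaks)
})
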