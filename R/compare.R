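# Pairwise evolutionary comparison: global alignment statistics and
# windowed dot-matrix comparison of cDNAs with per-region GC content.

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Global protein alignment with identity/similarity/gap statistics
#'
#' Needleman-Wunsch global alignment with affine gap penalties (end gaps
#' penalized), using BLOSUM62 with gap open 10 and gap extend 0.5 by
#' default. `positives` counts aligned pairs with a positive substitution
#' score; `gap_runs` counts maximal gap-character runs across both rows
#' (gap openings).
#'
#' @param a,b Protein sequences (character scalars, non-empty).
#' @param substitution_matrix Name of a Biostrings substitution matrix or a
#'   matrix (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return Object of class `alignment_stats`: list with `aligned_a`,
#'   `aligned_b`, `alignment_length`, `identities`, `positives`,
#'   `gap_runs`, `identity_pct`, `similarity_pct`, `score`.
#' @export
#' @examples
#' global_align("GGAG", "GGAG")$identity_pct # 100
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  stopifnot(length(a) == 1, length(b) == 1)
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop("global_align requires non-empty sequences", call. = FALSE)
  }
  submat <- if (is.character(substitution_matrix) &&
                identical(substitution_matrix, "BLOSUM62")) {
    .blosum62()
  } else substitution_matrix
  # canonical argument order: co-optimal tracebacks may differ between
  # (a, b) and (b, a), so align in a fixed order and swap rows back --
  # identity/similarity statistics are then invariant under argument swap
  swapped <- a > b
  pair <- if (swapped) c(b, a) else c(a, b)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pair[1]), Biostrings::AAString(pair[2]),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  row_a <- as.character(Biostrings::alignedPattern(pa))
  row_b <- as.character(Biostrings::alignedSubject(pa))
  if (swapped) { tmp <- row_a; row_a <- row_b; row_b <- tmp }
  ca <- strsplit(row_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(row_b, "", fixed = TRUE)[[1]]
  alen <- length(ca)
  aligned <- ca != "-" & cb != "-"
  identities <- sum(aligned & ca == cb)
  pos_score <- rep(FALSE, alen)
  if (any(aligned)) {
    pos_score[aligned] <- submat[cbind(ca[aligned], cb[aligned])] > 0
  }
  positives <- sum(pos_score)
  runs <- function(chars) { r <- rle(chars == "-"); sum(r$values) }
  structure(list(aligned_a = row_a, aligned_b = row_b,
                 alignment_length = alen, identities = identities,
                 positives = positives,
                 gap_runs = runs(ca) + runs(cb),
                 identity_pct = 100 * identities / alen,
                 similarity_pct = 100 * positives / alen,
                 score = Biostrings::score(pa)),
            class = "alignment_stats")
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat(sprintf(
    "global alignment: length %d | identity %.1f%% | similarity %.1f%% | %d gap run(s) | score %.1f\n",
    x$alignment_length, x$identity_pct, x$similarity_pct, x$gap_runs,
    x$score))
  w <- 60
  for (s in seq(1, x$alignment_length, by = w)) {
    e <- min(s + w - 1, x$alignment_length)
    cat(substr(x$aligned_a, s, e), "\n", substr(x$aligned_b, s, e), "\n\n",
        sep = "")
  }
  invisible(x)
}

#' Windowed dot-matrix comparison of two nucleotide sequences
#'
#' Every pair of window-start coordinates `(i, j)` (0-based) is scored by
#' the percent identity of `a[i, i+window)` against `b[j, j+window)`; a
#' point is emitted when the identity strictly exceeds `threshold`. `N`
#' never matches anything (including another `N`).
#'
#' @param a,b Nucleotide sequences (character scalars).
#' @param window Window size in bp (default 20).
#' @param threshold Percent-identity threshold (default 50, strict `>`).
#' @param ann Optional region annotation `data.frame` (as in
#'   [read_region_annotations()]) carried for plotting.
#' @return Object of class `dotplot`: list with `points` (`data.frame` of
#'   0-based `i`, `j`), `window`, `threshold`, `id_a`, `id_b`, `len_a`,
#'   `len_b`, `ann`.
#' @export
dotplot <- function(a, b, window = 20L, threshold = 50, ann = NULL) {
  stopifnot(length(a) == 1, length(b) == 1)
  .check_alphabet(c(a, b), "nucleotide", "nucleotide")
  la <- nchar(a); lb <- nchar(b)
  if (window > la || window > lb) {
    stop("window exceeds a sequence length", call. = FALSE)
  }
  if (!(threshold > 0 && threshold <= 100)) {
    stop("threshold must be in (0, 100]", call. = FALSE)
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  match_mat <- outer(ca, cb, "==") & ca != "N" &
    matrix(cb != "N", nrow = la, ncol = lb, byrow = TRUE)
  na <- la - window + 1; nb <- lb - window + 1
  acc <- matrix(0L, na, nb)
  for (k in 0:(window - 1)) {
    acc <- acc + match_mat[k + seq_len(na), k + seq_len(nb), drop = FALSE]
  }
  hit <- which(100 * acc / window > threshold, arr.ind = TRUE)
  structure(list(points = data.frame(i = hit[, 1] - 1L, j = hit[, 2] - 1L),
                 window = as.integer(window), threshold = threshold,
                 id_a = if (!is.null(names(a))) names(a) else "a",
                 id_b = if (!is.null(names(b))) names(b) else "b",
                 len_a = la, len_b = lb, ann = ann),
            class = "dotplot")
}

#' @export
print.dotplot <- function(x, ...) {
  cat(sprintf("dot plot: %s (%d bp) vs %s (%d bp), window %d, threshold >%g%%: %d point(s)\n",
              x$id_a, x$len_a, x$id_b, x$len_b, x$window, x$threshold,
              nrow(x$points)))
  invisible(x)
}

#' Plot a dot-matrix comparison
#'
#' @param x A `dotplot` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dotplot <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, x$len_a), ylim = c(0, x$len_b),
                 xlab = paste0(x$id_a, " (bp)"), ylab = paste0(x$id_b, " (bp)"),
                 main = sprintf("window %d bp, identity > %g%%",
                                x$window, x$threshold), ...)
  if (nrow(x$points)) {
    graphics::points(x$points$i, x$points$j, pch = ".", cex = 2)
  }
  invisible(x)
}

#' Fraction of a region covered by near-diagonal dot-plot points
#'
#' For each window-start position of `region_a`, checks whether some point
#' `(i, j)` exists with `j` in `region_b` and the two offsets within
#' `slack` bp of the region diagonal. Summarizes conserved (high coverage)
#' versus divergent (low coverage) regions.
#'
#' @param plot A `dotplot` object.
#' @param region_a,region_b 0-based half-open intervals `c(start, end)` on
#'   the two axes.
#' @param slack Diagonal band half-width in bp (default 3).
#' @return Fraction in 0..1.
#' @export
diagonal_coverage <- function(plot, region_a, region_b, slack = 3L) {
  stopifnot(inherits(plot, "dotplot"), length(region_a) == 2,
            length(region_b) == 2)
  w <- plot$window
  if (region_a[2] - region_a[1] < w || region_b[2] - region_b[1] < w) {
    stop("region shorter than the dot-plot window", call. = FALSE)
  }
  if (region_a[1] < 0 || region_a[2] > plot$len_a ||
      region_b[1] < 0 || region_b[2] > plot$len_b) {
    stop("region outside the dot-plot axes", call. = FALSE)
  }
  istarts <- seq.int(region_a[1], region_a[2] - w)
  if (nrow(plot$points) == 0) return(0)
  p <- plot$points[plot$points$j >= region_b[1] &
                     plot$points$j <= region_b[2] - w, , drop = FALSE]
  covered <- vapply(istarts, function(i) {
    any(p$i == i & abs((i - region_a[1]) - (p$j - region_b[1])) <= slack)
  }, logical(1))
  mean(covered)
}

#' Per-region GC content of an annotated cDNA
#'
#' Applies [gc_content()] to each annotated region; regions absent from the
#' annotation are reported with `present = FALSE` and `gc = NA`.
#'
#' @param seq Single named (or unnamed) nucleotide sequence.
#' @param ann Region annotation `data.frame`; rows whose `seq_id` matches
#'   the sequence name are used (all rows when the sequence is unnamed).
#' @return `data.frame` with columns `region`, `present`, `start`, `end`,
#'   `gc`.
#' @export
region_gc_report <- function(seq, ann) {
  stopifnot(length(seq) == 1)
  id <- names(seq)
  rows <- if (!is.null(id)) ann[ann$seq_id == id, , drop = FALSE] else ann
  validate_regions(rows, if (!is.null(id)) seq else NULL)
  regions <- c("five_utr", "cds", "three_utr")
  out <- data.frame(region = regions, present = FALSE, start = NA_integer_,
                    end = NA_integer_, gc = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in regions) {
    hit <- rows[rows$region == r, , drop = FALSE]
    if (nrow(hit) == 1) {
      k <- which(out$region == r)
      out$present[k] <- TRUE
      out$start[k] <- hit$start
      out$end[k] <- hit$end
      out$gc[k] <- gc_content(unname(seq), hit$start, hit$end)
    }
  }
  out
}
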