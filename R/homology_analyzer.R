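# Terminal homology of distal-passage chimeras: 2 kb end windows, two-strand
# Smith-Waterman alignment, direct/inverted repeat verdicts, matched random
# control pairs, and repeat-annotation matching of chimera ends.

homology_sub_matrix <- function(match = 5, mismatch = -4) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- match
  m["N", "N"] <- mismatch   # N never matches, not even itself
  m
}

#' Smith-Waterman local alignment score
#'
#' Affine-gap local alignment with the scoring scheme of the classic EMBOSS
#' Water defaults: match +5, mismatch -4, gap opening 10, gap extension 0.5
#' (a gap of length L costs `gap_open + L * gap_ext`). `N` scores as a
#' mismatch against every base including itself. An empty sequence scores 0.
#'
#' @param a,b Character scalars or `DNAString`s over A/C/G/T/N.
#' @param match,mismatch,gap_open,gap_ext Scoring parameters.
#' @return The optimal local alignment score (numeric, >= 0).
#' @export
local_align <- function(a, b, match = 5, mismatch = -4,
                        gap_open = 10, gap_ext = 0.5) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0 || nchar(b) == 0) return(0)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = homology_sub_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext)
  max(0, Biostrings::score(pa))
}

#' Extract read-centred end windows of chimeras
#'
#' For each chimera end, a `window`-bp genomic segment centred on the read
#' midpoint is cut out on the plus strand; windows are clipped at chromosome
#' edges and flagged when clipped.
#'
#' @param chimeras Chimera `data.frame` from [load_chimeras()].
#' @param genome Named DNAStringSet.
#' @param window Window width in bp (default 2000).
#' @return A list with `up_windows`, `down_windows` (GRanges), `up_seq`,
#'   `down_seq` (DNAStringSet, plus strand) and `clipped` (logical per
#'   chimera).
#' @export
extract_end_windows <- function(chimeras, genome, window = 2000L) {
  sl <- genome_seqlengths(genome)
  up <- end_windows_gr(chimeras, "up", window, seqlengths = sl)
  down <- end_windows_gr(chimeras, "down", window, seqlengths = sl)
  list(up_windows = up, down_windows = down,
       up_seq = interval_seq(genome, up),
       down_seq = interval_seq(genome, down),
       clipped = GenomicRanges::width(up) < window |
         GenomicRanges::width(down) < window)
}

#' Classify repeat orientation from end-window sequence pairs
#'
#' For each pair, the upstream plus-strand sequence is aligned against the
#' downstream plus-strand sequence (`score_pp`) and against its reverse
#' complement (`score_pm`). The verdict is `direct` when
#' `score_pp > score_pm + margin`, `inverted` when
#' `score_pm > score_pp + margin`, else `ambiguous`; it is withheld (NA)
#' when both windows are shorter than `min_window` bp after clipping.
#'
#' @param up_seq,down_seq DNAStringSets (plus strand), parallel vectors.
#' @param margin Ambiguity margin in score units (default 5, one match).
#' @param min_window Minimum usable window length in bp (default 200).
#' @param ... Scoring parameters passed to [local_align()].
#' @return `data.frame` with `score_pp`, `score_pm`, `max_score`, `verdict`.
#' @export
classify_repeat_orientation <- function(up_seq, down_seq, margin = 5,
                                        min_window = 200L, ...) {
  stopifnot(length(up_seq) == length(down_seq))
  n <- length(up_seq)
  score_pp <- score_pm <- rep(NA_real_, n)
  verdict <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (Biostrings::width(up_seq)[i] < min_window &&
        Biostrings::width(down_seq)[i] < min_window) next
    rc <- Biostrings::reverseComplement(down_seq[[i]])
    score_pp[i] <- local_align(up_seq[[i]], down_seq[[i]], ...)
    score_pm[i] <- local_align(up_seq[[i]], rc, ...)
    verdict[i] <- if (score_pp[i] > score_pm[i] + margin) "direct"
      else if (score_pm[i] > score_pp[i] + margin) "inverted"
      else "ambiguous"
  }
  data.frame(score_pp = score_pp, score_pm = score_pm,
             max_score = pmax(score_pp, score_pm),
             verdict = verdict, stringsAsFactors = FALSE)
}

#' End-window homology calls for a chimera set
#'
#' Convenience wrapper: extracts 2 kb end windows and classifies each pair
#' with [classify_repeat_orientation()].
#'
#' @inheritParams extract_end_windows
#' @param ... Passed to [classify_repeat_orientation()].
#' @return The chimera `data.frame` with `score_pp`, `score_pm`, `max_score`
#'   and `verdict` columns appended.
#' @export
homology_calls <- function(chimeras, genome, window = 2000L, ...) {
  ew <- extract_end_windows(chimeras, genome, window)
  cbind(chimeras, classify_repeat_orientation(ew$up_seq, ew$down_seq, ...))
}

#' Concordance between read orientation and repeat verdict
#'
#' Builds the 2x2 table {RF/FR, FF/RR} x {direct, inverted} (ambiguous or
#' withheld verdicts are excluded), runs Fisher's exact test, and reports
#' the concordance rate: the fraction of chimeras where RF/FR pairs with a
#' direct verdict and FF/RR with an inverted one.
#'
#' @param calls Chimera `data.frame` with `orientation` and `verdict`
#'   columns (e.g. from [homology_calls()]).
#' @return List with `table` (2x2 matrix), `fisher_p`, `concordance` and
#'   `n`.
#' @export
concordance <- function(calls) {
  ok <- !is.na(calls$verdict) & calls$verdict %in% c("direct", "inverted")
  if (!any(ok)) stop("no direct/inverted verdicts to compare")
  ogrp <- ifelse(calls$orientation[ok] %in% c("RF", "FR"), "RF/FR", "FF/RR")
  tab <- table(factor(ogrp, c("RF/FR", "FF/RR")),
               factor(calls$verdict[ok], c("direct", "inverted")))
  fp <- tryCatch(stats::fisher.test(tab)$p.value, error = function(e) NA_real_)
  conc <- (tab["RF/FR", "direct"] + tab["FF/RR", "inverted"]) / sum(tab)
  list(table = unclass(tab), fisher_p = fp, concordance = as.numeric(conc),
       n = sum(tab))
}

#' Random control end-window pairs
#'
#' Draws `n` pairs of `window`-bp segments from one chromosome such that the
#' pair separation is at most `max_span` bp and each window's assembly-gap
#' (N) coverage is below `max_gap_frac`; rejection-sampled with a fixed
#' seed.
#'
#' @param genome Named DNAStringSet.
#' @param n Number of control pairs.
#' @param seed Integer seed.
#' @param chrom Chromosome to sample from (default: the longest).
#' @param window Window width in bp (default 2000).
#' @param max_span Maximum pair separation in bp (default 2 Mb).
#' @param max_gap_frac Maximum tolerated N fraction per window (default
#'   0.20, exclusive).
#' @param max_try Rejection budget per pair.
#' @return A `data.frame` shaped like a chimera table (windows as ends, with
#'   `span`), suitable for [homology_calls()].
#' @export
control_chimeras <- function(genome, n, seed, chrom = NULL, window = 2000L,
                             max_span = 2e6, max_gap_frac = 0.20,
                             max_try = 100L) {
  sl <- genome_seqlengths(genome)
  if (is.null(chrom)) chrom <- names(sl)[which.max(sl)]
  L <- sl[[chrom]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  gap_frac <- function(mid) {
    s <- pmax(1L, mid - window %/% 2L)
    e <- pmin(L, s + window - 1L)
    seqs <- interval_seq(genome, GenomicRanges::GRanges(
      chrom, IRanges::IRanges(s, e)))
    as.numeric(Biostrings::letterFrequency(seqs, "N")) / (e - s + 1)
  }
  res <- list()
  for (i in seq_len(n)) {
    ok <- FALSE
    for (k in seq_len(max_try)) {
      a <- floor(stats::runif(1, window, L - window))
      b <- a + sample(c(-1, 1), 1) * floor(stats::runif(1, window, max_span))
      if (b < window || b > L - window) next
      if (max(gap_frac(a), gap_frac(b)) >= max_gap_frac) next
      ok <- TRUE; break
    }
    if (!ok) stop("chromosome too gappy: could not draw control pair ", i)
    up <- min(a, b); down <- max(a, b)
    res[[i]] <- data.frame(chrom = chrom,
                           start_up = up - 50L, end_up = up + 49L,
                           strand_up = "+",
                           start_down = down - 50L, end_down = down + 49L,
                           strand_down = "+",
                           span = down - up, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$orientation <- "FF"
  out$span_class <- classify_span(out$span)
  out
}

#' Match chimera ends against a repeat annotation
#'
#' A chimera receives a repeat label when both of its end windows overlap
#' intervals of the same name in the annotation; otherwise it is
#' `"unassigned"`. Single-end hits are reported in separate columns.
#'
#' @param chimeras Chimera `data.frame`.
#' @param repeats GRanges with a `name` mcol (e.g. read from a repeat BED),
#'   or NULL for no annotation.
#' @param window End-matching window in bp (default 2000).
#' @return `chimeras` with `repeat_up`, `repeat_down` (comma-collapsed
#'   single-end hits, NA when none) and `repeat_label` columns.
#' @export
annotate_ends <- function(chimeras, repeats = NULL, window = 2000L) {
  n <- nrow(chimeras)
  hits_for <- function(which) {
    out <- vector("list", n)
    if (is.null(repeats) || !length(repeats)) return(out)
    win <- end_windows_gr(chimeras, which, window)
    hit <- GenomicRanges::findOverlaps(win, repeats, ignore.strand = TRUE)
    for (i in seq_along(hit)) {
      q <- S4Vectors::queryHits(hit)[i]
      out[[q]] <- c(out[[q]], repeats$name[S4Vectors::subjectHits(hit)[i]])
    }
    out
  }
  up <- hits_for("up")
  down <- hits_for("down")
  lab <- vapply(seq_len(n), function(i) {
    shared <- intersect(up[[i]], down[[i]])
    if (length(shared)) shared[1] else "unassigned"
  }, character(1))
  chimeras$repeat_up <- vapply(up, function(x) {
    if (length(x)) paste(unique(x), collapse = ",") else NA_character_
  }, character(1))
  chimeras$repeat_down <- vapply(down, function(x) {
    if (length(x)) paste(unique(x), collapse = ",") else NA_character_
  }, character(1))
  chimeras$repeat_label <- lab
  chimeras
}
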