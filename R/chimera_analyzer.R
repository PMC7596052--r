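# eTIPb arm: chimera loading and canonicalization, toposite-end assignment,
# combination statistics (observed vs expected under random end pairing),
# span classification into PSP/DSP/noise, and read-orientation tables.

#' Span-class boundaries (bp)
#'
#' Proximal strand passage (PSP) is shorter than 3 kb; distal strand passage
#' (DSP) runs from 3 kb to 2 Mb inclusive; anything longer is treated as
#' inter-complex noise.
#' @keywords internal
span_limits <- c(psp = 3000, noise = 2e6)

#' Classify chimera spans into PSP / DSP / noise
#'
#' @param span Numeric vector of spans in bp (midpoint-to-midpoint distance
#'   of the two reads). Must be non-negative.
#' @return Character vector over `{"PSP", "DSP", "noise"}`: PSP iff
#'   `span < 3000`, DSP iff `3000 <= span <= 2e6`, noise otherwise.
#' @export
classify_span <- function(span) {
  if (any(is.na(span)) || any(span < 0)) stop("spans must be non-negative")
  ifelse(span < span_limits[["psp"]], "PSP",
         ifelse(span <= span_limits[["noise"]], "DSP", "noise"))
}

#' Load and canonicalize chimera read pairs
#'
#' Drops pairs with a ligation adaptor at a 5' end or a non-uniquely mapped
#' mate; keeps intra-chromosomal pairs only (the inter-chromosomal count is
#' reported in the `n_inter_chromosomal` attribute). Ends are sorted by
#' genomic coordinate; the span is the distance between the two read
#' midpoints and the orientation is the strand combination ordered
#' upstream to downstream with `+` = F and `-` = R.
#'
#' @param pairs Read-pair `data.frame`; an optional `id` column is carried
#'   through.
#' @return A chimera `data.frame` with columns `chrom`, `start_up`, `end_up`,
#'   `strand_up`, `start_down`, `end_down`, `strand_down`, `span`,
#'   `orientation`, `span_class` (and `id` if present), plus attributes
#'   `n_dropped` and `n_inter_chromosomal`.
#' @export
load_chimeras <- function(pairs) {
  keep <- pairs$unique1 & pairs$unique2 & !pairs$adaptor1 & !pairs$adaptor2
  n_dropped <- sum(!keep)
  df <- pairs[keep, , drop = FALSE]
  intra <- df$chrom1 == df$chrom2
  n_inter <- sum(!intra)
  df <- df[intra, , drop = FALSE]

  mid1 <- (df$start1 + df$end1) %/% 2L
  mid2 <- (df$start2 + df$end2) %/% 2L
  up_is_1 <- mid1 <= mid2
  out <- data.frame(
    chrom = df$chrom1,
    start_up = ifelse(up_is_1, df$start1, df$start2),
    end_up = ifelse(up_is_1, df$end1, df$end2),
    strand_up = ifelse(up_is_1, df$strand1, df$strand2),
    start_down = ifelse(up_is_1, df$start2, df$start1),
    end_down = ifelse(up_is_1, df$end2, df$end1),
    strand_down = ifelse(up_is_1, df$strand2, df$strand1),
    stringsAsFactors = FALSE)
  out$span <- abs(mid2 - mid1)
  out$orientation <- paste0(ifelse(out$strand_up == "+", "F", "R"),
                            ifelse(out$strand_down == "+", "F", "R"))
  out$span_class <- if (nrow(out)) classify_span(out$span) else character(0)
  if (!is.null(df$id)) out$id <- df$id
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_inter_chromosomal") <- n_inter
  out
}

end_windows_gr <- function(chimeras, which = c("up", "down"),
                           window = 2000L, seqlengths = NULL) {
  which <- match.arg(which)
  s <- chimeras[[paste0("start_", which)]]
  e <- chimeras[[paste0("end_", which)]]
  mid <- (s + e) %/% 2L
  start <- mid - window %/% 2L
  end <- start + window - 1L
  if (!is.null(seqlengths)) {
    start <- pmax(1L, start)
    end <- pmin(seqlengths[chimeras$chrom], end)
  } else {
    start <- pmax(1L, start)
  }
  GenomicRanges::GRanges(chimeras$chrom, IRanges::IRanges(start, end))
}

#' Assign toposite classes to chimera ends
#'
#' Each end's read-centred window (default 2 kb, matching the window used
#' for terminal-homology extraction) is intersected with the toposite set;
#' ties between several overlapping toposites are resolved by nearest
#' summit, then largest overlap, then lowest q-value. The unordered class
#' combination is recorded; chimeras with any unassigned end get combo
#' `"unassigned"` and are excluded from combination statistics.
#'
#' @param chimeras Chimera `data.frame` from [load_chimeras()].
#' @param toposites Toposite GRanges with `class`, `summit` and (optionally)
#'   `qvalue` mcols.
#' @param window End-matching window in bp (default 2000).
#' @return `chimeras` with added columns `class_up`, `class_down`, `combo`.
#' @export
assign_ends <- function(chimeras, toposites, window = 2000L) {
  assign_one <- function(which) {
    win <- end_windows_gr(chimeras, which, window)
    hit <- GenomicRanges::findOverlaps(win, toposites, ignore.strand = TRUE)
    cls <- rep(NA_character_, nrow(chimeras))
    if (length(hit)) {
      q <- S4Vectors::queryHits(hit)
      s <- S4Vectors::subjectHits(hit)
      mid <- (GenomicRanges::start(win) + GenomicRanges::end(win))[q] %/% 2L
      d_summit <- abs(toposites$summit[s] - mid)
      ov <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(win)[q], GenomicRanges::ranges(toposites)[s]))
      qv <- if (is.null(toposites$qvalue)) rep(0, length(s)) else
        toposites$qvalue[s]
      ord <- order(q, d_summit, -ov, qv)
      first <- !duplicated(q[ord])
      cls[q[ord][first]] <- toposites$class[s[ord][first]]
    }
    cls
  }
  chimeras$class_up <- assign_one("up")
  chimeras$class_down <- assign_one("down")
  both <- !is.na(chimeras$class_up) & !is.na(chimeras$class_down)
  combo <- rep("unassigned", nrow(chimeras))
  if (any(both)) {
    combo[both] <- paste(
      pmin(chimeras$class_up[both], chimeras$class_down[both]),
      pmax(chimeras$class_up[both], chimeras$class_down[both]), sep = "-")
  }
  chimeras$combo <- combo
  chimeras
}

all_combos <- function(classes = c("Ts1", "Ts2", "Ts3")) {
  idx <- which(upper.tri(diag(length(classes)), diag = TRUE), arr.ind = TRUE)
  paste(classes[idx[, 1]], classes[idx[, 2]], sep = "-")
}

#' Observed vs expected toposite combinations of chimeras
#'
#' Expected counts follow the experimental end frequencies: with `f_i` the
#' fraction of class-i ends among all `2N` assigned ends, the expected count
#' is `N f_i^2` for a homologous combination and `2 N f_i f_j` for a
#' heterologous one (the null of random end re-pairing). Each combination is
#' tested by a 1-df chi-squared test of (observed, N - observed) against
#' (expected, N - expected); p-values are Benjamini-Hochberg corrected
#' across the six combinations. Combinations with zero expectation are
#' reported untested (NA).
#'
#' @param chimeras Chimera `data.frame` after [assign_ends()] (rows with
#'   combo `"unassigned"` are ignored).
#' @return `data.frame` with columns `combo`, `observed`, `expected`,
#'   `chisq`, `pvalue`, `qvalue`, `minus_log10_q`,
#'   `observed_less_than_expected`.
#' @export
combination_stats <- function(chimeras) {
  asg <- chimeras[chimeras$combo != "unassigned", , drop = FALSE]
  n <- nrow(asg)
  if (n == 0) stop("no assigned chimeras")
  classes <- c("Ts1", "Ts2", "Ts3")
  ends <- c(asg$class_up, asg$class_down)
  f <- vapply(classes, function(cl) mean(ends == cl), numeric(1))
  combos <- all_combos(classes)
  expected <- vapply(combos, function(cb) {
    p <- strsplit(cb, "-")[[1]]
    if (p[1] == p[2]) n * f[p[1]]^2 else 2 * n * f[p[1]] * f[p[2]]
  }, numeric(1))
  observed <- vapply(combos, function(cb) sum(asg$combo == cb), numeric(1))
  chisq <- pval <- rep(NA_real_, length(combos))
  testable <- expected > 0
  # cells with zero expectation contribute nothing (a combination expected
  # to absorb all N chimeras is tested on its own cell only)
  chisq[testable] <- (observed[testable] - expected[testable])^2 /
    expected[testable] +
    ifelse(expected[testable] < n,
           (observed[testable] - expected[testable])^2 /
             (n - expected[testable]), 0)
  pval[testable] <- stats::pchisq(chisq[testable], df = 1, lower.tail = FALSE)
  qval <- rep(NA_real_, length(combos))
  qval[testable] <- stats::p.adjust(pval[testable], method = "BH")
  data.frame(combo = combos, observed = observed, expected = expected,
             chisq = chisq, pvalue = pval, qvalue = qval,
             minus_log10_q = -log10(pmax(qval, .Machine$double.xmin)),
             observed_less_than_expected = observed < expected,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tabulate read-orientation combinations
#'
#' Counts of RF/FR/FF/RR per span class and toposite combination, with
#' per-cell fractions. Homologous Ts1 chimeras in the DSP range carry no
#' orientation preference and are flagged noise-equivalent.
#'
#' @param chimeras Chimera `data.frame` (after [load_chimeras()]; combos are
#'   used if [assign_ends()] has run, otherwise a single `"all"` stratum).
#' @return `data.frame` with columns `span_class`, `combo`, `n`, `RF`, `FR`,
#'   `FF`, `RR`, the corresponding `frac_*` columns and `noise_equivalent`.
#' @export
orientation_table <- function(chimeras) {
  combo <- if (is.null(chimeras$combo)) rep("all", nrow(chimeras)) else
    chimeras$combo
  strata <- unique(data.frame(span_class = chimeras$span_class, combo = combo,
                              stringsAsFactors = FALSE))
  strata <- strata[order(strata$span_class, strata$combo), , drop = FALSE]
  orients <- c("RF", "FR", "FF", "RR")
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    sel <- chimeras$span_class == strata$span_class[i] &
      combo == strata$combo[i]
    cnt <- vapply(orients, function(o) {
      sum(chimeras$orientation[sel] == o)
    }, numeric(1))
    out <- data.frame(span_class = strata$span_class[i],
                      combo = strata$combo[i], n = sum(sel),
                      stringsAsFactors = FALSE)
    for (o in orients) out[[o]] <- cnt[[o]]
    for (o in orients) out[[paste0("frac_", o)]] <- cnt[[o]] / max(sum(sel), 1)
    out$noise_equivalent <- strata$span_class[i] == "DSP" &&
      strata$combo[i] == "Ts1-Ts1"
    out
  })
  do.call(rbind, rows)
}
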