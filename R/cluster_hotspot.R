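# Sliding-window density maps, high-density toposite / chimera clusters,
# and their integration into hotspots; overlap reporting against partner
# binding sites.

#' Sliding-window density track
#'
#' Counts item midpoints per window on a fixed grid (default 100 kb window,
#' 10 kb step). The midpoint convention (half-open on window bounds) counts
#' every item exactly once per covering window and avoids double counting
#' across non-overlapping windows.
#'
#' @param items GRanges of items (toposites or chimera ends).
#' @param seqlengths Named chromosome lengths (taken from `items` when
#'   absent there only if supplied here).
#' @param window Window size in bp (must be a multiple of `step`).
#' @param step Step size in bp.
#' @return A `data.frame` (`chrom`, `start`, `end`, `count`; 1-based closed
#'   windows) with attributes `window` and `step`.
#' @export
sliding_density <- function(items, seqlengths = NULL, window = 100000L,
                            step = 10000L) {
  if (step > window) stop("step must not exceed window")
  if (window %% step != 0) stop("window must be a multiple of step")
  if (is.null(seqlengths)) seqlengths <- GenomeInfoDb::seqlengths(items)
  if (any(is.na(seqlengths))) stop("seqlengths required")
  mid <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(items),
    IRanges::IRanges((GenomicRanges::start(items) +
                        GenomicRanges::end(items)) %/% 2L, width = 1L))
  out <- lapply(names(seqlengths), function(chr) {
    L <- seqlengths[[chr]]
    starts <- seq.int(1L, max(1L, L - step + 1L), by = step)
    ends <- pmin(starts + window - 1L, L)
    win <- GenomicRanges::GRanges(chr, IRanges::IRanges(starts, ends))
    # closed integer window [start, start + window - 1] == half-open
    # [start, start + window): a midpoint on the next grid start is counted
    # by the next window only
    cnt <- GenomicRanges::countOverlaps(win, mid, ignore.strand = TRUE)
    data.frame(chrom = chr, start = starts, end = ends, count = cnt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "seqlengths") <- seqlengths
  out
}

#' Call high-density clusters from a density track
#'
#' Windows with `count >= threshold` are kept and overlapping or adjacent
#' kept windows are merged into maximal regions.
#'
#' @param track Density track from [sliding_density()].
#' @param threshold Minimum window count (closed bound; > 0).
#' @param class Optional class label stored on the result.
#' @return GRanges of clusters with mcols `class`, `peak_density` (maximum
#'   member window count) and `n_windows`.
#' @export
call_clusters <- function(track, threshold, class = NA_character_) {
  if (threshold <= 0) stop("threshold must be positive")
  keep <- track[track$count >= threshold, , drop = FALSE]
  sl <- attr(track, "seqlengths")
  if (!nrow(keep)) {
    gr <- GenomicRanges::GRanges(seqlengths = sl)
    gr$class <- character(0); gr$peak_density <- numeric(0)
    gr$n_windows <- integer(0)
    return(gr)
  }
  win <- GenomicRanges::GRanges(keep$chrom,
                                IRanges::IRanges(keep$start, keep$end),
                                seqlengths = sl)
  merged <- GenomicRanges::reduce(win, min.gapwidth = 1L)
  hit <- GenomicRanges::findOverlaps(merged, win)
  peak <- vapply(split(keep$count[S4Vectors::subjectHits(hit)],
                       S4Vectors::queryHits(hit)), max, numeric(1))
  nw <- vapply(split(S4Vectors::subjectHits(hit),
                     S4Vectors::queryHits(hit)), length, integer(1))
  merged$class <- class
  merged$peak_density <- as.numeric(peak)
  merged$n_windows <- as.integer(nw)
  merged
}

#' Integrate toposite clusters and chimera clusters into hotspots
#'
#' Same-class cluster pairs sharing at least 1 bp are merged (transitive
#' closure) into a hotspot spanning their union. A merged region qualifies
#' only if it contains at least one cluster of each kind.
#'
#' @param toposite_clusters GRanges with a `class` mcol (values Ts2/Ts3).
#' @param dsp_clusters GRanges with a `class` mcol (the chimera class the
#'   cluster was built from).
#' @return GRanges of hotspots with mcols `class`, `n_toposite_clusters`,
#'   `n_dsp_clusters`.
#' @export
define_hotspots <- function(toposite_clusters, dsp_clusters) {
  classes <- intersect(unique(toposite_clusters$class),
                       unique(dsp_clusters$class))
  out <- list()
  for (cl in sort(classes)) {
    tc <- toposite_clusters[toposite_clusters$class == cl]
    dc <- dsp_clusters[dsp_clusters$class == cl]
    if (!length(tc) || !length(dc)) next
    merged <- GenomicRanges::reduce(
      c(GenomicRanges::granges(tc), GenomicRanges::granges(dc)),
      min.gapwidth = 0L, ignore.strand = TRUE)
    nt <- GenomicRanges::countOverlaps(merged, tc, ignore.strand = TRUE)
    nd <- GenomicRanges::countOverlaps(merged, dc, ignore.strand = TRUE)
    keep <- merged[nt >= 1 & nd >= 1]
    if (!length(keep)) next
    keep$class <- cl
    keep$n_toposite_clusters <- nt[nt >= 1 & nd >= 1]
    keep$n_dsp_clusters <- nd[nt >= 1 & nd >= 1]
    out[[length(out) + 1L]] <- keep
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges(
      seqlengths = GenomeInfoDb::seqlengths(toposite_clusters))
    gr$class <- character(0)
    gr$n_toposite_clusters <- integer(0)
    gr$n_dsp_clusters <- integer(0)
    return(gr)
  }
  GenomicRanges::sort(do.call(c, out), ignore.strand = TRUE)
}

#' Per-class overlap percentages against partner binding sites
#'
#' Reports, for each class of `x`, the percentage of items sharing at least
#' 1 bp with any partner interval.
#'
#' @param x GRanges with an optional `class` mcol (a single class `"all"` is
#'   used when absent).
#' @param partner GRanges of partner-protein binding sites.
#' @return `data.frame` with `class`, `n`, `n_overlapping`, `percent`.
#' @export
overlap_report <- function(x, partner) {
  cls <- if (is.null(x$class)) rep("all", length(x)) else x$class
  flags <- IRanges::overlapsAny(x, partner, ignore.strand = TRUE)
  res <- lapply(sort(unique(cls)), function(cl) {
    sel <- cls == cl
    data.frame(class = cl, n = sum(sel), n_overlapping = sum(flags[sel]),
               percent = 100 * mean(flags[sel]), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Chimera end windows as class-labelled GRanges
#'
#' Expands each chimera into its two read-centred end windows (default 2 kb,
#' the unit used for partner-site overlap reporting). For homologous combos
#' the chimera's toposite class is attached as `class`.
#'
#' @param chimeras Chimera `data.frame` (after [assign_ends()] if class
#'   labels are wanted).
#' @param window Window width in bp.
#' @param seqlengths Optional chromosome lengths for clipping.
#' @return GRanges of end windows with mcols `class` and `which_end`
#'   ("up"/"down").
#' @export
chimera_end_windows <- function(chimeras, window = 2000L, seqlengths = NULL) {
  cls <- if (is.null(chimeras$combo)) rep(NA_character_, nrow(chimeras)) else {
    ifelse(grepl("^(Ts[123])-\\1$", chimeras$combo),
           sub("-.*$", "", chimeras$combo), NA_character_)
  }
  up <- end_windows_gr(chimeras, "up", window, seqlengths)
  down <- end_windows_gr(chimeras, "down", window, seqlengths)
  up$class <- cls; up$which_end <- "up"
  down$class <- cls; down$which_end <- "down"
  c(up, down)
}
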