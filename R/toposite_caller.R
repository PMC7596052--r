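# eTIPa arm: read-pair filtering, pileup tracks, per-fraction peak calling,
# toposite classification (Ts1/Ts2/Ts3) and genomic-region annotation.

#' Filter aligned read pairs for peak calling
#'
#' Keeps a pair iff both mates map uniquely, the pair is convergent (the
#' upstream mate on "+", the downstream mate on "-"), both mates are on the
#' same chromosome, and the insert (outermost span) is shorter than
#' `max_insert` bp. The filter is idempotent.
#'
#' @param pairs Read-pair `data.frame` (see [read_pair_table()]).
#' @param max_insert Maximum insert in bp (exclusive bound; default 500).
#' @return The kept subset of `pairs`.
#' @export
filter_read_pairs <- function(pairs, max_insert = 500L) {
  if (!nrow(pairs)) return(pairs)
  same_chrom <- pairs$chrom1 == pairs$chrom2
  up_is_1 <- pairs$start1 <= pairs$start2
  up_strand <- ifelse(up_is_1, pairs$strand1, pairs$strand2)
  down_strand <- ifelse(up_is_1, pairs$strand2, pairs$strand1)
  insert <- pmax(pairs$end1, pairs$end2) - pmin(pairs$start1, pairs$start2) + 1L
  keep <- same_chrom & pairs$unique1 & pairs$unique2 &
    up_strand == "+" & down_strand == "-" & insert < max_insert
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a strand-extended pileup track from read pairs
#'
#' Each mate is extended to `extension` bp in its strand direction from its
#' 5' end and per-base pileup is accumulated, so the track total equals
#' `extension` x number of reads minus bases clipped at chromosome edges.
#'
#' @param pairs Filtered read-pair `data.frame`.
#' @param seqlengths Named vector of chromosome lengths (or a genome
#'   DNAStringSet).
#' @param extension Extension length in bp (default 200).
#' @return A named [S4Vectors::RleList] of per-base coverage.
#' @export
coverage_track <- function(pairs, seqlengths, extension = 200L) {
  if (is(seqlengths, "DNAStringSet")) seqlengths <- genome_seqlengths(seqlengths)
  chrom <- c(pairs$chrom1, pairs$chrom2)
  strand <- c(pairs$strand1, pairs$strand2)
  five_p <- c(ifelse(pairs$strand1 == "+", pairs$start1, pairs$end1),
              ifelse(pairs$strand2 == "+", pairs$start2, pairs$end2))
  start <- ifelse(strand == "+", five_p, five_p - extension + 1L)
  end <- start + extension - 1L
  start <- pmax(start, 1L)
  end <- pmin(end, seqlengths[chrom])
  keep <- start <= end & chrom %in% names(seqlengths)
  gr <- GenomicRanges::GRanges(chrom[keep],
                               IRanges::IRanges(start[keep], end[keep]),
                               seqlengths = seqlengths)
  GenomicRanges::coverage(gr)
}

tiled_windows <- function(len, window, step) {
  starts <- seq.int(1L, max(1L, len - window + 1L), by = step)
  IRanges::IRanges(starts, width = pmin(window, len - starts + 1L))
}

window_counts <- function(cov, window, step, extension) {
  lapply(names(cov), function(chr) {
    win <- tiled_windows(length(cov[[chr]]), window, step)
    list(chrom = chr, windows = win,
         count = IRanges::viewSums(IRanges::Views(cov[[chr]], win)) / extension)
  })
}

local_lambda <- function(rle, win, scale, window, extension) {
  centers <- (IRanges::start(win) + IRanges::end(win)) %/% 2L
  s <- pmax(1L, centers - scale %/% 2L)
  e <- pmin(length(rle), centers + scale %/% 2L)
  IRanges::viewSums(IRanges::Views(rle, IRanges::IRanges(s, e))) /
    (e - s + 1) * window / extension
}

#' Call enriched peaks on a pileup track
#'
#' Two callers over fixed sliding windows (default 200 bp window, 50 bp
#' step):
#'
#' * `"local-poisson"` (default): each window count is tested against a
#'   Poisson null with rate `max(global, 5 kb local, 10 kb local)`;
#'   Benjamini-Hochberg across all windows; windows with q below `q_cutoff`
#'   are merged into maximal peaks.
#' * `"zinb"`: a two-component zero-inflated negative-binomial mixture is
#'   fitted to the window counts by EM and a window is enriched iff its
#'   posterior probability of the enriched component is at least
#'   `posterior_threshold` (default 0.5).
#'
#' Peak summits are the maximal-pileup base of each merged region.
#'
#' @param cov Pileup RleList from [coverage_track()].
#' @param mode `"local-poisson"` or `"zinb"`.
#' @param window,step Window size and step in bp.
#' @param extension Read extension used to build the track (converts pileup
#'   sums back to read counts).
#' @param q_cutoff BH q-value cutoff (local-poisson mode).
#' @param local_scales Local background scales in bp (local-poisson mode).
#' @param posterior_threshold Posterior cutoff for the enriched component
#'   (zinb mode).
#' @return A GRanges of peaks with mcols `summit`, `score` (fold enrichment
#'   over the null rate at the summit window) and `qvalue` (minimum member
#'   q; in zinb mode, 1 - posterior).
#' @export
call_peaks <- function(cov, mode = c("local-poisson", "zinb"),
                       window = 200L, step = 50L, extension = 200L,
                       q_cutoff = 0.01, local_scales = c(5000L, 10000L),
                       posterior_threshold = 0.5) {
  mode <- match.arg(mode)
  sl <- vapply(cov, length, integer(1))
  total <- sum(vapply(cov, function(x) sum(as.numeric(x)), numeric(1)))
  if (total == 0) {
    return(GenomicRanges::GRanges(seqlengths = sl))
  }
  wc <- window_counts(cov, window, step, extension)
  counts <- unlist(lapply(wc, `[[`, "count"))

  if (mode == "local-poisson") {
    lambda_g <- total / sum(as.numeric(sl)) * window / extension
    lam <- lapply(wc, function(w) {
      l <- rep(lambda_g, length(w$count))
      for (sc in local_scales) {
        l <- pmax(l, local_lambda(cov[[w$chrom]], w$windows, sc, window,
                                  extension))
      }
      l
    })
    lambda <- unlist(lam)
    pval <- stats::ppois(floor(counts), lambda, lower.tail = FALSE)
    qval <- stats::p.adjust(pval, method = "BH")
    sig <- qval < q_cutoff
  } else {
    fit <- fit_zinb_mixture(round(counts))
    post <- zinb_posterior(round(counts), fit)
    qval <- 1 - post
    lambda <- rep(max(mean(counts), 1e-9), length(counts))
    sig <- post >= posterior_threshold
  }

  offs <- cumsum(c(0L, vapply(wc, function(w) length(w$count), integer(1))))
  peaks <- list()
  for (i in seq_along(wc)) {
    idx <- which(sig[(offs[i] + 1):offs[i + 1]])
    if (!length(idx)) next
    w <- wc[[i]]$windows[idx]
    merged <- IRanges::reduce(w)
    hit <- IRanges::findOverlaps(merged, w)
    qmin <- vapply(split(qval[offs[i] + idx][S4Vectors::subjectHits(hit)],
                         S4Vectors::queryHits(hit)), min, numeric(1))
    lam_m <- vapply(split(lambda[offs[i] + idx][S4Vectors::subjectHits(hit)],
                          S4Vectors::queryHits(hit)), max, numeric(1))
    v <- IRanges::Views(cov[[wc[[i]]$chrom]], merged)
    summit <- IRanges::viewWhichMaxs(v)
    score <- IRanges::viewMaxs(v) / pmax(lam_m * extension / window, 1e-9)
    gr <- GenomicRanges::GRanges(wc[[i]]$chrom, merged, seqlengths = sl)
    gr$summit <- summit
    gr$score <- as.numeric(score)
    gr$qvalue <- as.numeric(qmin)
    peaks[[length(peaks) + 1L]] <- gr
  }
  if (!length(peaks)) return(GenomicRanges::GRanges(seqlengths = sl))
  GenomicRanges::sort(do.call(c, peaks), ignore.strand = TRUE)
}

# EM fit of pi0 * I(0) + pi_b * NB(mu_b, size_b) + pi_e * NB(mu_e, size_e)
fit_zinb_mixture <- function(counts, max_iter = 100L, tol = 1e-6) {
  counts <- as.integer(counts)
  nz <- counts[counts > 0]
  if (!length(nz)) stop("degenerate track: no nonzero window counts")
  par <- list(pi = c(z = mean(counts == 0) / 2, b = NA, e = NA),
              mu = c(b = max(stats::median(nz), 0.5),
                     e = max(stats::quantile(nz, 0.995), 2 * stats::median(nz) + 1)),
              size = c(b = 5, e = 5))
  par$pi["b"] <- (1 - par$pi["z"]) * 0.98
  par$pi["e"] <- 1 - par$pi["z"] - par$pi["b"]
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dz <- ifelse(counts == 0, par$pi["z"], 0)
    db <- par$pi["b"] * stats::dnbinom(counts, mu = par$mu["b"],
                                       size = par$size["b"])
    de <- par$pi["e"] * stats::dnbinom(counts, mu = par$mu["e"],
                                       size = par$size["e"])
    tot <- dz + db + de
    tot[tot == 0] <- .Machine$double.xmin
    rz <- dz / tot; rb <- db / tot; re <- de / tot
    par$pi <- c(z = mean(rz), b = mean(rb), e = mean(re))
    wmean <- function(r) sum(r * counts) / sum(r)
    par$mu <- c(b = max(wmean(rb), 1e-3), e = max(wmean(re), 1e-3))
    wsize <- function(r, mu) {
      f <- function(s) -sum(r * stats::dnbinom(counts, mu = mu, size = s,
                                               log = TRUE))
      stats::optimize(f, c(0.05, 1000))$minimum
    }
    par$size <- c(b = wsize(rb, par$mu["b"]), e = wsize(re, par$mu["e"]))
    if (par$mu["e"] < par$mu["b"]) {  # keep the enriched component on top
      par$mu <- rev(par$mu); par$size <- rev(par$size)
      par$pi[c("b", "e")] <- par$pi[c("e", "b")]
      names(par$mu) <- names(par$size) <- c("b", "e")
    }
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }
  par
}

zinb_posterior <- function(counts, par) {
  dz <- ifelse(counts == 0, par$pi["z"], 0)
  db <- par$pi["b"] * stats::dnbinom(counts, mu = par$mu["b"],
                                     size = par$size["b"])
  de <- par$pi["e"] * stats::dnbinom(counts, mu = par$mu["e"],
                                     size = par$size["e"])
  tot <- dz + db + de
  tot[tot == 0] <- .Machine$double.xmin
  as.numeric(de / tot)
}

#' Default evidence-to-class map for toposites
#'
#' Resealed (relaxation-type) complexes elute from the beads at high salt and
#' therefore leave P2-fraction evidence only (Ts1); covalent-only sites stay
#' bead-bound (P1-only, Ts2); sites with both kinds of evidence are the
#' stable class (Ts3). The map is a configuration knob of
#' [classify_toposites()].
#'
#' @return Named character vector over evidence labels
#'   `P1-only`, `P2-only`, `both`.
#' @export
default_evidence_map <- function() {
  c("P2-only" = "Ts1", "P1-only" = "Ts2", "both" = "Ts3")
}

#' Classify toposites from P1/P2 peak calls
#'
#' Peaks of the two fractions are partitioned by >= 1 bp overlap into
#' evidence classes (`P1-only`, `P2-only`, `both`); overlapping P1/P2 peaks
#' are merged (union of the transitive overlap closure) and reported once.
#' Classes are assigned through `map`, which must be a bijection onto
#' Ts1/Ts2/Ts3.
#'
#' @param p1,p2 Peak GRanges from [call_peaks()] for the P1 and P2 fractions.
#' @param map Evidence-to-class map (see [default_evidence_map()]).
#' @return GRanges of toposites with mcols `class`, `evidence`, `summit`,
#'   `score`, `qvalue`.
#' @export
classify_toposites <- function(p1, p2, map = default_evidence_map()) {
  if (!setequal(names(map), c("P1-only", "P2-only", "both")) ||
      !setequal(unname(map), c("Ts1", "Ts2", "Ts3"))) {
    stop("evidence map must be a bijection from ",
         "{P1-only, P2-only, both} onto {Ts1, Ts2, Ts3}")
  }
  hit <- GenomicRanges::findOverlaps(p1, p2, ignore.strand = TRUE)
  p1_both <- unique(S4Vectors::queryHits(hit))
  p2_both <- unique(S4Vectors::subjectHits(hit))

  mk <- function(gr, evidence) {
    if (!length(gr)) {
      out <- GenomicRanges::GRanges(seqlengths = GenomeInfoDb::seqlengths(gr))
      out$class <- character(0); out$evidence <- character(0)
      out$summit <- integer(0); out$score <- numeric(0)
      out$qvalue <- numeric(0)
      return(out)
    }
    out <- GenomicRanges::granges(gr)
    out$class <- unname(map[[evidence]])
    out$evidence <- evidence
    out$summit <- gr$summit
    out$score <- gr$score
    out$qvalue <- gr$qvalue
    out
  }

  only1 <- mk(p1[setdiff(seq_along(p1), p1_both)], "P1-only")
  only2 <- mk(p2[setdiff(seq_along(p2), p2_both)], "P2-only")

  both <- GenomicRanges::GRanges(seqlengths = GenomeInfoDb::seqlengths(p1))
  if (length(p1_both) || length(p2_both)) {
    members <- c(GenomicRanges::granges(p1[p1_both]),
                 GenomicRanges::granges(p2[p2_both]))
    stat <- rbind(
      data.frame(summit = p1$summit[p1_both], score = p1$score[p1_both],
                 qvalue = p1$qvalue[p1_both]),
      data.frame(summit = p2$summit[p2_both], score = p2$score[p2_both],
                 qvalue = p2$qvalue[p2_both]))
    merged <- GenomicRanges::reduce(members, ignore.strand = TRUE)
    mh <- GenomicRanges::findOverlaps(merged, members, ignore.strand = TRUE)
    pick <- vapply(split(S4Vectors::subjectHits(mh),
                         S4Vectors::queryHits(mh)),
                   function(i) i[which.max(stat$score[i])], integer(1))
    both <- merged
    both$class <- unname(map[["both"]])
    both$evidence <- "both"
    both$summit <- stat$summit[pick]
    both$score <- stat$score[pick]
    both$qvalue <- stat$qvalue[pick]
  }
  out <- c(only1, only2, both)
  out <- GenomicRanges::sort(out, ignore.strand = TRUE)
  if (length(out)) out$name <- sprintf("toposite_%05d", seq_along(out))
  out
}

#' Annotate toposites by genomic region and report densities
#'
#' Region classes: the TSS zone is the strand-aware transcription start
#' +/- `tss_flank` bp; the genic region (GR) is gene bodies with TSS zones
#' excluded; the intergenic region (IR) is the remainder of the genome. A
#' site is labelled `TSS` if it overlaps any TSS zone, else `GR` if it
#' overlaps a gene body, else `IR`, so the labels partition the sites.
#' Densities are sites per 100 kb of each region class's total length.
#'
#' @param sites Toposite GRanges (with `class` mcol).
#' @param genes Gene GRanges with strand and seqlengths.
#' @param tss_flank Flank around the TSS in bp (default 2000).
#' @return List with `sites` (input plus `region` mcol) and `density`
#'   (`data.frame`: region, length_bp, and per-class site counts and
#'   densities per 100 kb).
#' @export
annotate_regions <- function(sites, genes, tss_flank = 2000L) {
  if (any(GenomicRanges::width(genes) < 1)) stop("gene with end <= start")
  sl <- GenomeInfoDb::seqlengths(genes)
  if (any(is.na(sl))) stop("gene annotation must carry seqlengths")
  tss <- ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                GenomicRanges::start(genes), GenomicRanges::end(genes))
  zone <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(pmax(1L, tss - tss_flank),
                     pmin(sl[as.character(GenomicRanges::seqnames(genes))],
                          tss + tss_flank)),
    seqlengths = sl)
  zone_r <- GenomicRanges::reduce(zone, ignore.strand = TRUE)
  body_r <- GenomicRanges::reduce(GenomicRanges::granges(genes),
                                  ignore.strand = TRUE)
  gr_region <- GenomicRanges::setdiff(body_r, zone_r, ignore.strand = TRUE)
  genome_gr <- GenomicRanges::GRanges(names(sl), IRanges::IRanges(1L, sl),
                                      seqlengths = sl)
  ir_region <- GenomicRanges::setdiff(
    genome_gr, GenomicRanges::union(zone_r, gr_region, ignore.strand = TRUE),
    ignore.strand = TRUE)

  region <- rep("IR", length(sites))
  region[IRanges::overlapsAny(sites, body_r, ignore.strand = TRUE)] <- "GR"
  region[IRanges::overlapsAny(sites, zone_r, ignore.strand = TRUE)] <- "TSS"
  sites$region <- region

  lens <- c(TSS = sum(GenomicRanges::width(zone_r)),
            GR = sum(GenomicRanges::width(gr_region)),
            IR = sum(GenomicRanges::width(ir_region)))
  classes <- sort(unique(sites$class))
  dens <- data.frame(region = names(lens), length_bp = as.numeric(lens),
                     stringsAsFactors = FALSE)
  for (cl in classes) {
    n <- vapply(names(lens), function(r) {
      sum(sites$class == cl & region == r)
    }, numeric(1))
    dens[[paste0("n_", cl)]] <- n
    dens[[paste0("density_", cl)]] <- n / as.numeric(lens) * 1e5
  }
  list(sites = sites, density = dens)
}
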