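#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps countOverlaps reduce resize mid granges mcols mcols<-
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny coverage Views
#'   viewSums viewMaxs viewWhichMaxs slice restrict
#' @importFrom S4Vectors queryHits subjectHits Rle runValue runLength mcols
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#'   keepSeqlevels sortSeqlevels
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement letterFrequency subseq
#'   pairwiseAlignment score
#' @importFrom stats ppois p.adjust chisq.test fisher.test wilcox.test
#'   rnbinom rpois runif rnorm rbinom dnbinom optimize median quantile sd
#'   setNames complete.cases aggregate
#' @importFrom utils read.table write.table head tail
NULL

# ---------------------------------------------------------------------------
# Genome sequences
# ---------------------------------------------------------------------------

#' Read a genome FASTA into a named DNAStringSet
#'
#' Assembly gaps are represented as runs of `N`. Sequence names are truncated
#' at the first whitespace, following common practice for FASTA headers.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a genome to FASTA with 60-column wrapping
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' Sequence lengths of a genome
#' @param genome A named DNAStringSet.
#' @return Named integer vector of chromosome lengths.
#' @export
genome_seqlengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

check_genome_bounds <- function(gr, genome) {
  sl <- genome_seqlengths(genome)
  chr <- as.character(GenomicRanges::seqnames(gr))
  bad_chr <- !(chr %in% names(sl))
  if (any(bad_chr)) {
    stop("interval(s) on unknown chromosome: ",
         paste(unique(chr[bad_chr]), collapse = ", "))
  }
  if (any(GenomicRanges::start(gr) < 1L) ||
      any(GenomicRanges::end(gr) > sl[chr])) {
    stop("interval(s) out of chromosome bounds")
  }
  invisible(TRUE)
}

#' Extract interval sequences from a genome
#'
#' Sequences are always returned on the plus strand regardless of the strand
#' of `gr`; callers needing minus-strand sequence reverse-complement
#' explicitly.
#'
#' @param genome Named DNAStringSet.
#' @param gr A [GenomicRanges::GRanges] of intervals (1-based, closed, as is
#'   conventional for GRanges).
#' @return A DNAStringSet, one sequence per interval.
#' @export
interval_seq <- function(genome, gr) {
  check_genome_bounds(gr, genome)
  chr <- as.character(GenomicRanges::seqnames(gr))
  out <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    as.character(Biostrings::subseq(genome[[chr[i]]],
                                    start = GenomicRanges::start(gr)[i],
                                    end = GenomicRanges::end(gr)[i]))
  }, character(1)))
  out
}

#' GC content of genomic intervals
#'
#' Computes (G + C) / (A + C + G + T) per interval. `N` bases (assembly gaps)
#' are excluded from the denominator; an interval consisting entirely of `N`
#' has no defined GC content and raises an error. Intervals that are more
#' than 50% `N` are flagged in the `high_n` attribute.
#'
#' @param gr GRanges of intervals.
#' @param genome Named DNAStringSet.
#' @return Numeric vector of GC fractions in `[0, 1]`, with a logical
#'   attribute `high_n` marking intervals with > 50% `N`.
#' @export
gc_content <- function(gr, genome) {
  seqs <- interval_seq(genome, gr)
  freq <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T", "N"))
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  if (any(acgt == 0)) stop("GC content undefined for all-N interval(s)")
  gc <- rowSums(freq[, c("G", "C"), drop = FALSE]) / acgt
  attr(gc, "high_n") <- freq[, "N"] / rowSums(freq) > 0.5
  gc
}

# ---------------------------------------------------------------------------
# Interval overlap
# ---------------------------------------------------------------------------

#' Flag intervals of one set that overlap another
#'
#' An interval of `a` is "overlapping" iff it shares at least 1 bp with any
#' interval of `b`. Empty sets are allowed.
#'
#' @param a,b GRanges.
#' @param ignore_strand Ignore strand when testing overlap (default TRUE).
#' @return A list with `flags` (logical, one per interval of `a`),
#'   `n_overlapping`, and `fraction` (`percent` = 100 * fraction).
#' @export
interval_overlap <- function(a, b, ignore_strand = TRUE) {
  flags <- IRanges::overlapsAny(a, b, ignore.strand = ignore_strand)
  list(flags = flags,
       n_overlapping = sum(flags),
       fraction = if (length(a)) mean(flags) else NA_real_,
       percent = if (length(a)) 100 * mean(flags) else NA_real_)
}

# ---------------------------------------------------------------------------
# BED / bedGraph
# ---------------------------------------------------------------------------

#' Read a BED (3-6 column) file as GRanges
#'
#' File coordinates are 0-based half-open (BED convention); the returned
#' GRanges is 1-based closed as usual in R.
#'
#' @param path Path to BED file.
#' @param genome Optional genome (DNAStringSet) used to validate bounds.
#' @return GRanges with optional `name` and `score` metadata columns.
#' @export
read_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::start(gr) < 1L)) stop("BED record with negative start")
  if (!is.null(genome)) check_genome_bounds(gr, genome)
  gr
}

#' Write GRanges to BED
#'
#' Emits 0-based half-open coordinates. Re-reading with [read_bed()] is the
#' identity on ranges, names and scores.
#'
#' @param gr GRanges; `name` and `score` metadata columns are written if
#'   present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Records must be sorted by (chrom, start) and non-overlapping; violations
#' are rejected with the offending record index.
#'
#' @param path Path to bedGraph file.
#' @return GRanges with a numeric `score` column.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  chr <- as.character(GenomicRanges::seqnames(gr))
  for (c1 in unique(chr)) {
    g <- gr[chr == c1]
    if (length(g) > 1) {
      s <- GenomicRanges::start(g)
      e <- GenomicRanges::end(g)
      if (is.unsorted(s)) {
        stop("bedGraph not sorted by start on ", c1, " (record ",
             which(diff(s) < 0)[1] + 1L, ")")
      }
      if (any(s[-1] <= e[-length(e)])) {
        stop("bedGraph has overlapping intervals on ", c1, " (record ",
             which(s[-1] <= e[-length(e)])[1] + 1L, ")")
      }
    }
  }
  gr
}

#' Write a coverage track to bedGraph
#'
#' @param cov A GRanges with `score`, or a named [S4Vectors::RleList] of
#'   per-base coverage.
#' @param path Output path.
#' @param drop_zero Omit zero-coverage runs (default TRUE).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(cov, path, drop_zero = TRUE) {
  if (is(cov, "RleList")) cov <- rle_to_granges(cov, drop_zero = drop_zero)
  cov <- GenomicRanges::sort(cov)
  rtracklayer::export(cov, path, format = "bedGraph")
  invisible(path)
}

#' Convert a per-base coverage RleList to run-length GRanges
#' @param cov Named RleList (one Rle per chromosome).
#' @param drop_zero Omit zero runs.
#' @return GRanges with a `score` column.
#' @export
rle_to_granges <- function(cov, drop_zero = TRUE) {
  gr <- GenomicRanges::GRanges(cov)
  if (drop_zero) gr <- gr[gr$score != 0]
  gr
}

# ---------------------------------------------------------------------------
# Read-pair tables
# ---------------------------------------------------------------------------

read_pair_cols <- c("chrom1", "start1", "end1", "strand1", "unique1", "adaptor1",
                    "chrom2", "start2", "end2", "strand2", "unique2", "adaptor2")

#' Construct a read-pair table
#'
#' The table is the package's aligned-read interchange format: one row per
#' read pair, with per-mate interval, strand, mapping-uniqueness flag and
#' 5'-adaptor flag. Coordinates are 1-based closed in memory (0-based
#' half-open on disk).
#'
#' @param chrom1,start1,end1,strand1 Mate 1 location (strand "+" or "-").
#' @param chrom2,start2,end2,strand2 Mate 2 location.
#' @param unique1,unique2 Logical; mate mapped uniquely.
#' @param adaptor1,adaptor2 Logical; ligation adaptor at the mate's 5' end.
#' @return A `data.frame` with the twelve standard columns.
#' @export
read_pair_table <- function(chrom1, start1, end1, strand1,
                            chrom2, start2, end2, strand2,
                            unique1 = TRUE, unique2 = TRUE,
                            adaptor1 = FALSE, adaptor2 = FALSE) {
  df <- data.frame(chrom1 = as.character(chrom1),
                   start1 = as.integer(start1), end1 = as.integer(end1),
                   strand1 = as.character(strand1),
                   unique1 = as.logical(unique1), adaptor1 = as.logical(adaptor1),
                   chrom2 = as.character(chrom2),
                   start2 = as.integer(start2), end2 = as.integer(end2),
                   strand2 = as.character(strand2),
                   unique2 = as.logical(unique2), adaptor2 = as.logical(adaptor2),
                   stringsAsFactors = FALSE)
  validate_read_pairs(df)
  df[read_pair_cols]
}

validate_read_pairs <- function(df) {
  bad <- which(df$start1 < 1L | df$end1 < df$start1 |
               df$start2 < 1L | df$end2 < df$start2)
  if (length(bad)) stop("invalid read-pair coordinates at row ", bad[1])
  bad <- which(!(df$strand1 %in% c("+", "-")) | !(df$strand2 %in% c("+", "-")))
  if (length(bad)) stop("invalid strand at row ", bad[1])
  invisible(TRUE)
}

#' Read a read-pair table
#'
#' Supports the package's tab-separated dialect (`format = "tsv"`; 0-based
#' half-open on disk) and, when \pkg{Rsamtools} is available, name-paired
#' SAM/BAM records (`format = "sam"`), where mapping uniqueness is taken as
#' MAPQ > 0 and adaptor flags are unavailable (FALSE).
#'
#' @param path Input path.
#' @param format `"tsv"` (default) or `"sam"`.
#' @return Read-pair `data.frame` (see [read_pair_table()]).
#' @export
read_read_pairs <- function(path, format = c("tsv", "sam")) {
  format <- match.arg(format)
  if (format == "sam") return(read_read_pairs_sam(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(read_pair_cols, names(df))
  if (length(missing)) {
    stop("read-pair table missing column(s): ", paste(missing, collapse = ", "))
  }
  df$start1 <- df$start1 + 1L   # disk is 0-based half-open
  df$start2 <- df$start2 + 1L
  validate_read_pairs(df)
  df[read_pair_cols]
}

read_read_pairs_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading SAM/BAM requires the Rsamtools package")
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "strand", "mapq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(x$pos) & !bitwAnd(x$flag, 4L)
  d <- data.frame(qname = x$qname, chrom = as.character(x$rname),
                  start = x$pos, end = x$pos + x$qwidth - 1L,
                  strand = as.character(x$strand),
                  unique = x$mapq > 0,
                  first = bitwAnd(x$flag, 64L) > 0,
                  stringsAsFactors = FALSE)[keep, ]
  m1 <- d[d$first, ]
  m2 <- d[!d$first, ]
  m2 <- m2[match(m1$qname, m2$qname), ]
  ok <- stats::complete.cases(m2)
  read_pair_table(m1$chrom[ok], m1$start[ok], m1$end[ok], m1$strand[ok],
                  m2$chrom[ok], m2$start[ok], m2$end[ok], m2$strand[ok],
                  unique1 = m1$unique[ok], unique2 = m2$unique[ok])
}

#' Write a read-pair table (0-based half-open on disk)
#' @param df Read-pair `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_read_pairs <- function(df, path) {
  validate_read_pairs(df)
  out <- df[read_pair_cols]
  out$start1 <- out$start1 - 1L
  out$start2 <- out$start2 - 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Chimera BEDPE dialect
# ---------------------------------------------------------------------------

chimera_bedpe_cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                        "name", "score", "strand1", "strand2",
                        "span_class", "toposite_combo", "orientation_combo")

#' Write a chimera table as extended BEDPE
#'
#' Standard ten BEDPE columns plus `span_class`, `toposite_combo` and
#' `orientation_combo`. Disk coordinates are 0-based half-open.
#'
#' @param chimeras A chimera `data.frame` (see [load_chimeras()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chimera_bedpe <- function(chimeras, path) {
  n <- nrow(chimeras)
  out <- data.frame(
    chrom1 = chimeras$chrom, start1 = chimeras$start_up - 1L,
    end1 = chimeras$end_up,
    chrom2 = chimeras$chrom, start2 = chimeras$start_down - 1L,
    end2 = chimeras$end_down,
    name = if (is.null(chimeras$name)) sprintf("chimera_%d", seq_len(n)) else chimeras$name,
    score = 0L,
    strand1 = chimeras$strand_up, strand2 = chimeras$strand_down,
    span_class = if (is.null(chimeras$span_class)) "." else chimeras$span_class,
    toposite_combo = if (is.null(chimeras$combo)) "unassigned" else chimeras$combo,
    orientation_combo = chimeras$orientation,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an extended chimera BEDPE written by [write_chimera_bedpe()]
#' @param path Input path.
#' @return Chimera `data.frame` with 1-based closed coordinates.
#' @export
read_chimera_bedpe <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(chimera_bedpe_cols, names(df))
  if (length(missing)) {
    stop("chimera BEDPE missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$chrom1 != df$chrom2)) {
    stop("chimera BEDPE contains inter-chromosomal record(s) at row ",
         which(df$chrom1 != df$chrom2)[1])
  }
  out <- data.frame(chrom = df$chrom1,
                    start_up = df$start1 + 1L, end_up = df$end1,
                    strand_up = df$strand1,
                    start_down = df$start2 + 1L, end_down = df$end2,
                    strand_down = df$strand2,
                    name = df$name,
                    orientation = df$orientation_combo,
                    span_class = df$span_class,
                    combo = df$toposite_combo,
                    stringsAsFactors = FALSE)
  mid_up <- (out$start_up + out$end_up) %/% 2L
  mid_down <- (out$start_down + out$end_down) %/% 2L
  out$span <- abs(mid_down - mid_up)
  out
}
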