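# Shared fixtures and independent oracles used across the suite.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# A tiny hand-built genome: two chromosomes with a known N gap on chr1.
make_test_genome <- function() {
  set.seed(11)
  chr1 <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                collapse = "")
  # plant an assembly gap at 4001..4200
  substr(chr1, 4001, 4200) <- paste(rep("N", 200), collapse = "")
  chr2 <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                collapse = "")
  DNAStringSet(c(chr1 = chr1, chr2 = chr2))
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent quadratic-DP Smith-Waterman with affine gaps; a gap of length
# L costs open + ext * L (same convention as the package scoring). Pure R,
# O(nm); kept deliberately separate from the implementation under test.
sw_align_ref <- function(a, b, match = 5, mismatch = -4, open = 10,
                         ext = 0.5) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) return(0)
  H <- matrix(0, n + 1, m + 1)   # best score ending at (i, j)
  E <- matrix(-Inf, n + 1, m + 1) # gap in x (consuming y)
  F <- matrix(-Inf, n + 1, m + 1) # gap in y (consuming x)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == "N" || y[j - 1] == "N") mismatch else
        if (x[i - 1] == y[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# O(n^2) brute-force overlap oracle: flags intervals of a sharing >= 1 bp
# with any interval of b (1-based closed coordinates).
brute_overlap_flags <- function(a, b) {
  vapply(seq_along(a), function(i) {
    any(as.character(seqnames(b)) == as.character(seqnames(a))[i] &
          start(b) <= end(a)[i] & end(b) >= start(a)[i])
  }, logical(1))
}

# Brute-force sliding-window midpoint counts for one chromosome.
brute_window_counts <- function(mids, starts, window) {
  vapply(starts, function(s) sum(mids >= s & mids < s + window), numeric(1))
}

# Percent positional identity between two equal-length sequences (the
# simulator's substitution-only divergence model preserves alignment).
positional_identity <- function(a, b) {
  x <- strsplit(as.character(a), "")[[1]]
  y <- strsplit(as.character(b), "")[[1]]
  stopifnot(length(x) == length(y))
  mean(x == y)
}

# Toy chimera table builder (1-based closed read coordinates).
chimera_row <- function(chrom, up_mid, down_mid, orientation, rl = 100L) {
  st <- c(substr(orientation, 1, 1), substr(orientation, 2, 2))
  st <- ifelse(st == "F", "+", "-")
  s1 <- up_mid - rl %/% 2L
  s2 <- down_mid - rl %/% 2L
  df <- data.frame(chrom = chrom, start_up = s1, end_up = s1 + rl - 1L,
                   strand_up = st[1], start_down = s2,
                   end_down = s2 + rl - 1L, strand_down = st[2],
                   stringsAsFactors = FALSE)
  df$span <- abs(down_mid - up_mid)
  df$orientation <- orientation
  df$span_class <- classify_span(df$span)
  df
}
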