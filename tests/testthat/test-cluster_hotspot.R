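test_that("sliding density equals the brute-force window scan", {
  sl <- c(chr1 = 500000L)
  set.seed(3)
  items <- GRanges("chr1", IRanges(sample(490000, 400), width = 400),
                   seqlengths = sl)
  track <- sliding_density(items, sl, window = 100000, step = 10000)
  mids <- (start(items) + end(items)) %/% 2
  brute <- brute_window_counts(mids, track$start, 100000)
  expect_equal(track$count, brute)
  # 30 items at one locus: every covering window counts all 30
  pile <- GRanges("chr1", IRanges(rep(250000, 30), width = 100),
                  seqlengths = sl)
  t2 <- sliding_density(pile, sl, window = 100000, step = 10000)
  expect_true(all(t2$count[t2$count > 0] == 30))
  # empty input: all-zero track
  t0 <- sliding_density(items[0], sl, window = 100000, step = 10000)
  expect_true(all(t0$count == 0))
  expect_error(sliding_density(items, sl, window = 100, step = 200), "step")
  expect_error(sliding_density(items, sl, window = 250, step = 100),
               "multiple")
})

test_that("a boundary midpoint is counted by exactly one stride window", {
  sl <- c(chr1 = 100000L)
  # midpoint exactly on a window-start grid position
  item <- GRanges("chr1", IRanges(20001 - 50, width = 101), seqlengths = sl)
  expect_equal((start(item) + end(item)) %/% 2, 20001)
  track <- sliding_density(item, sl, window = 10000, step = 10000)
  expect_equal(sum(track$count), 1)
  expect_equal(track$start[track$count == 1], 20001)
})

test_that("non-overlapping stride windows conserve the item count", {
  sl <- c(chr1 = 200000L)
  set.seed(5)
  items <- GRanges("chr1", IRanges(sample(190000, 300), width = 200),
                   seqlengths = sl)
  track <- sliding_density(items, sl, window = 20000, step = 20000)
  expect_equal(sum(track$count), length(items))
})

test_that("cluster calling honours the threshold and merges adjacency", {
  sl <- c(chr1 = 1000000L)
  mk_track <- function(counts) {
    starts <- seq(1L, 1000000L - 10000L + 1L, by = 10000L)
    tr <- data.frame(chrom = "chr1", start = starts,
                     end = pmin(starts + 99999, 1000000L),
                     count = 0)
    tr$count[seq_along(counts)] <- counts
    attr(tr, "window") <- 100000L; attr(tr, "step") <- 10000L
    attr(tr, "seqlengths") <- sl
    tr
  }
  # single window exactly at threshold 15: one cluster (closed bound)
  tr <- mk_track(c(0, 15, 0))
  cl <- call_clusters(tr, 15, class = "Ts2")
  expect_equal(length(cl), 1)
  expect_equal(cl$peak_density, 15)
  # 14 everywhere: none
  expect_equal(length(call_clusters(mk_track(rep(14, 20)), 15)), 0)
  # two superthreshold windows 10 kb apart merge (windows overlap)
  tr2 <- mk_track(c(20, 0, 20))   # windows starting at 1 and 20001
  cl2 <- call_clusters(tr2, 15, class = "Ts2")
  expect_equal(length(cl2), 1)
  expect_equal(cl2$n_windows, 2L)
  expect_error(call_clusters(tr2, 0), "positive")
})

test_that("cluster calling is monotone in the threshold", {
  sl <- c(chr1 = 1000000L)
  set.seed(9)
  items <- GRanges("chr1", IRanges(sample(990000, 600), width = 200),
                   seqlengths = sl)
  track <- sliding_density(items, sl)
  prev <- NULL
  for (th in c(2, 4, 8, 16)) {
    cl <- call_clusters(track, th)
    if (!is.null(prev)) {
      # every cluster at the higher threshold lies inside one at the lower
      expect_true(all(overlapsAny(cl, prev)))
      expect_lte(sum(width(cl)), sum(width(prev)))
      expect_lte(length(cl), length(prev) + 5)  # clusters can only split
    }
    prev <- cl
  }
})

test_that("hotspot integration equals a transitive-closure oracle", {
  sl <- c(chr1 = 1000000L)
  mkgr <- function(starts, widths, class) {
    gr <- GRanges("chr1", IRanges(starts, width = widths), seqlengths = sl)
    gr$class <- class
    gr
  }
  # same-class overlap -> union
  tc <- mkgr(100000, 50000, "Ts2")
  dc <- mkgr(140000, 30000, "Ts2")
  hs <- define_hotspots(tc, dc)
  expect_equal(length(hs), 1)
  expect_equal(start(hs), 100000)
  expect_equal(end(hs), 169999)
  # class mismatch -> none
  expect_equal(length(define_hotspots(tc, mkgr(140000, 30000, "Ts3"))), 0)
  # chain A-B-C merges into one hotspot
  tc2 <- mkgr(c(100000, 180000), c(50000, 50000), "Ts3")   # A, C
  dc2 <- mkgr(140000, 60000, "Ts3")                        # B overlaps both
  hs2 <- define_hotspots(tc2, dc2)
  expect_equal(length(hs2), 1)
  expect_equal(c(start(hs2), end(hs2)), c(100000, 229999))

  # randomized trials against a graph-components oracle
  set.seed(11)
  for (trial in 1:100) {
    nt <- sample(1:6, 1); nd <- sample(1:6, 1)
    tcr <- mkgr(sample(900000, nt), sample(20000:80000, nt, TRUE), "Ts2")
    dcr <- mkgr(sample(900000, nd), sample(20000:80000, nd, TRUE), "Ts2")
    hs <- define_hotspots(tcr, dcr)
    # oracle: connected components of the overlap graph over all clusters
    all_gr <- c(granges(tcr), granges(dcr))
    kind <- rep(c("t", "d"), c(nt, nd))
    n <- length(all_gr)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      adj[i, j] <- start(all_gr)[i] <= end(all_gr)[j] &&
        end(all_gr)[i] >= start(all_gr)[j]
    }
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          comp[c(i, j)] <- min(comp[i], comp[j]); changed <- TRUE
        }
      }
      if (!changed) break
    }
    expected <- 0L
    for (cp in unique(comp)) {
      members <- which(comp == cp)
      if (any(kind[members] == "t") && any(kind[members] == "d")) {
        expected <- expected + 1L
      }
    }
    expect_equal(length(hs), expected, info = sprintf("trial %d", trial))
  }
})

test_that("hotspots are invariant under input order", {
  sl <- c(chr1 = 1000000L)
  set.seed(13)
  tc <- GRanges("chr1", IRanges(sample(900000, 5), width = 60000),
                seqlengths = sl)
  tc$class <- "Ts2"
  dc <- GRanges("chr1", IRanges(sample(900000, 5), width = 60000),
                seqlengths = sl)
  dc$class <- "Ts2"
  h1 <- define_hotspots(tc, dc)
  h2 <- define_hotspots(rev(tc), rev(dc))
  expect_identical(granges(h1), granges(h2))
})

test_that("overlap report percentages match brute force per class", {
  sl <- c(chr1 = 100000L)
  set.seed(15)
  x <- GRanges("chr1", IRanges(sample(95000, 60), width = 300),
               seqlengths = sl)
  x$class <- sample(c("Ts1", "Ts2"), 60, TRUE)
  partner <- GRanges("chr1", IRanges(sample(95000, 30), width = 300),
                     seqlengths = sl)
  rep <- overlap_report(x, partner)
  flags <- brute_overlap_flags(x, partner)
  for (cl in c("Ts1", "Ts2")) {
    expect_equal(rep$percent[rep$class == cl],
                 100 * mean(flags[x$class == cl]))
  }
  expect_equal(overlap_report(x, x)$percent, c(100, 100))
  none <- GRanges("chr1", IRanges(1, 10), seqlengths = sl)
  x2 <- x[start(x) > 2000]
  expect_true(all(overlap_report(x2, none)$percent == 0))
})
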