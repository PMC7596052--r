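test_that("pair filter enforces uniqueness, convergence and insert bound", {
  base <- read_pair_table("chr1", 1000, 1099, "+", "chr1", 1201, 1300, "-")
  expect_equal(nrow(filter_read_pairs(base)), 1)          # insert 301, kept
  long <- read_pair_table("chr1", 1000, 1099, "+", "chr1", 1501, 1600, "-")
  expect_equal(nrow(filter_read_pairs(long)), 0)          # insert 601
  multi <- base; multi$unique2 <- FALSE
  expect_equal(nrow(filter_read_pairs(multi)), 0)
  diverg <- read_pair_table("chr1", 1000, 1099, "-", "chr1", 1201, 1300, "+")
  expect_equal(nrow(filter_read_pairs(diverg)), 0)
  # mate order does not matter: mate1 may be the downstream read
  swapped <- read_pair_table("chr1", 1201, 1300, "-", "chr1", 1000, 1099, "+")
  expect_equal(nrow(filter_read_pairs(swapped)), 1)
  # idempotent, never grows
  mix <- rbind(base, long, multi, diverg, swapped)
  once <- filter_read_pairs(mix)
  expect_identical(filter_read_pairs(once), once)
  expect_lte(nrow(once), nrow(mix))
})

test_that("coverage track extends reads by 200 bp and conserves mass", {
  sl <- c(chr1 = 5000L)
  one <- read_pair_table("chr1", 1000, 1099, "+", "chr1", 1201, 1300, "-")
  cov <- coverage_track(one, sl)
  v <- as.integer(cov$chr1)
  # + mate: [1000, 1199]; - mate 5' end at 1300: [1101, 1300]
  expect_equal(which(v > 0), 1000:1300)
  expect_equal(v[1000:1099], rep(1L, 100))
  expect_equal(sum(v), 400)
  # empty input: all-zero track
  expect_equal(sum(as.integer(coverage_track(one[0, ], sl)$chr1)), 0)
})

test_that("coverage mass equals 200 x reads minus edge clipping (oracle)", {
  set.seed(21)
  sl <- c(chr1 = 20000L)
  n <- 500
  s1 <- sample(19000, n)
  pairs <- read_pair_table("chr1", s1, s1 + 99, "+",
                           "chr1", pmin(s1 + 250, 19900),
                           pmin(s1 + 349, 19999), "-")
  cov <- coverage_track(pairs, sl)
  # exact accounting oracle: per-read extension clipped at [1, L]
  five_p <- c(ifelse(pairs$strand1 == "+", pairs$start1, pairs$end1),
              ifelse(pairs$strand2 == "+", pairs$start2, pairs$end2))
  strand <- c(pairs$strand1, pairs$strand2)
  lo <- pmax(ifelse(strand == "+", five_p, five_p - 199L), 1L)
  hi <- pmin(ifelse(strand == "+", five_p + 199L, five_p), 20000L)
  expect_equal(sum(as.numeric(cov$chr1)), sum(hi - lo + 1))
})

test_that("a point pileup yields exactly one peak containing it", {
  sl <- c(chr1 = 50000L)
  s <- rep(10000L, 60)
  pairs <- read_pair_table("chr1", s, s + 99, "+", "chr1", s + 201, s + 300,
                           "-")
  cov <- coverage_track(pairs, sl)
  pk <- call_peaks(cov)
  expect_equal(length(pk), 1)
  expect_true(start(pk) <= 10000 && end(pk) >= 10000)
  expect_true(pk$summit >= 10000 && pk$summit <= 10300)
})

test_that("degenerate flat track produces an empty call set", {
  sl <- c(chr1 = 10000L)
  empty <- read_pair_table("chr1", 1, 100, "+", "chr1", 201, 300, "-")[0, ]
  expect_equal(length(call_peaks(coverage_track(empty, sl))), 0)
})

test_that("false-positive window rate under a uniform null stays bounded", {
  set.seed(31)
  sl <- c(chr1 = 500000L)
  n <- 5000   # uniform background only
  s1 <- sample(499000L, n)
  pairs <- read_pair_table("chr1", s1, s1 + 99, "+", "chr1",
                           pmin(s1 + 201, 499900), pmin(s1 + 300, 499999),
                           "-")
  pk <- call_peaks(coverage_track(pairs, sl), q_cutoff = 0.01)
  n_windows <- length(seq.int(1L, 500000L - 200L + 1L, by = 50L))
  # each merged peak of width w spans about (w - 200) / 50 + 1 windows
  n_sig <- if (length(pk)) sum((width(pk) - 200) / 50 + 1) else 0
  fp_rate <- n_sig / n_windows
  # BH at q < 0.01 plus 3 sigma slack
  expect_lte(fp_rate, 0.01 + 3 * sqrt(0.01 * 0.99 / n_windows))
})

test_that("planted enrichment is recovered with an accurate summit", {
  set.seed(41)
  sl <- c(chr1 = 200000L)
  s1 <- sample(199000L, 3000)
  bg <- read_pair_table("chr1", s1, s1 + 99, "+", "chr1",
                        pmin(s1 + 201, 199900), pmin(s1 + 300, 199999), "-")
  center <- 100000L
  sp <- round(rnorm(300, center, 100))
  site <- read_pair_table("chr1", sp - 150, sp - 51, "+", "chr1", sp + 51,
                          sp + 150, "-")
  cov <- coverage_track(rbind(bg, site), sl)
  for (mode in c("local-poisson", "zinb")) {
    pk <- call_peaks(cov, mode = mode)
    hit <- pk[start(pk) <= center & end(pk) >= center]
    expect_equal(length(hit), 1)
    expect_lte(abs(hit$summit - center), 100)
  }
})

test_that("local-poisson and zinb agree on strong planted peaks", {
  set.seed(51)
  sl <- c(chr1 = 300000L)
  s1 <- sample(299000L, 6000)
  bg <- read_pair_table("chr1", s1, s1 + 99, "+", "chr1",
                        pmin(s1 + 201, 299900), pmin(s1 + 300, 299999), "-")
  centers <- seq(20000, 280000, by = 20000)
  sp <- round(rnorm(14 * 200, rep(centers, each = 200), 100))
  site <- read_pair_table("chr1", sp - 150, sp - 51, "+", "chr1", sp + 51,
                          sp + 150, "-")
  cov <- coverage_track(rbind(bg, site), sl)
  p1 <- call_peaks(cov, mode = "local-poisson")
  p2 <- call_peaks(cov, mode = "zinb")
  inter <- sum(width(GenomicRanges::intersect(p1, p2, ignore.strand = TRUE)))
  uni <- sum(width(GenomicRanges::union(p1, p2, ignore.strand = TRUE)))
  expect_gte(inter / uni, 0.8)
})

test_that("toposite classification follows the evidence map", {
  sl <- c(chr1 = 100000L)
  mkpk <- function(starts, width = 400) {
    gr <- GRanges("chr1", IRanges(starts, width = width), seqlengths = sl)
    gr$summit <- as.integer(starts + width / 2)
    gr$score <- 10
    gr$qvalue <- 1e-6
    gr
  }
  p1 <- mkpk(c(1000, 30000))
  p2 <- mkpk(c(30200, 60000))   # 30200 overlaps the 30000 P1 peak
  ts <- classify_toposites(p1, p2)
  expect_setequal(ts$class, c("Ts2", "Ts3", "Ts1"))
  expect_equal(ts$class[ts$evidence == "P1-only"], "Ts2")
  expect_equal(ts$class[ts$evidence == "P2-only"], "Ts1")
  both <- ts[ts$evidence == "both"]
  expect_equal(start(both), 30000)      # union interval
  expect_equal(end(both), 30599)
  # empty P1: only Ts1 under the default map
  ts2 <- classify_toposites(p1[0], p2)
  expect_setequal(ts2$class, "Ts1")
  # swapped custom map
  m <- c("P1-only" = "Ts1", "P2-only" = "Ts2", "both" = "Ts3")
  ts3 <- classify_toposites(p1, p2, map = m)
  expect_equal(ts3$class[ts3$evidence == "P1-only"], "Ts1")
  expect_error(classify_toposites(p1, p2, map = c("P1-only" = "Ts1")),
               "bijection")
  expect_error(
    classify_toposites(p1, p2, map = c("P1-only" = "Ts1",
                                       "P2-only" = "Ts1", "both" = "Ts3")),
    "bijection")
})

test_that("region annotation partitions sites and the genome", {
  sl <- c(chrA = 300000L, chrB = 50000L)
  genes <- GRanges(c("chrA", "chrA"), IRanges(c(100000, 200000),
                                              c(130000, 240000)),
                   strand = c("+", "-"), seqlengths = sl)
  sites <- GRanges(c("chrA", "chrA", "chrA", "chrB"),
                   IRanges(c(99000, 115000, 50000, 10000), width = 200),
                   seqlengths = sl)
  sites$class <- c("Ts1", "Ts1", "Ts2", "Ts2")
  ann <- annotate_regions(sites, genes)
  # TSS of + gene at 100000: zone [98000, 102000] captures the first site
  expect_equal(ann$sites$region, c("TSS", "GR", "IR", "IR"))
  # labels partition the sites and lengths partition the genome
  expect_equal(sum(ann$density$length_bp), sum(as.numeric(sl)))
  expect_equal(sum(ann$density$n_Ts1, ann$density$n_Ts2), length(sites))
  # TSS zone of the - gene is at its end coordinate
  s2 <- GRanges("chrA", IRanges(239500, 239700), seqlengths = sl)
  s2$class <- "Ts1"
  expect_equal(annotate_regions(s2, genes)$sites$region, "TSS")
  bad <- GRanges("chrA", IRanges(10, 9), seqlengths = sl)
  expect_error(annotate_regions(sites, bad), "end")
})
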