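# The generator is first-class code: these tests pin its statistical
# contracts (identity of planted repeats, orientation rules, fraction
# weights, conservation, reproducibility).

small_spec <- function(seed = 1L, ...) {
  sim_spec(seed = seed,
           chrom_lengths = c(chr1 = 600000, chr2 = 200000),
           n_sites = c(Ts1 = 30L, Ts2 = 30L, Ts3 = 30L),
           n_genes = 60L, n_clusters = c(Ts2 = 2L, Ts3 = 2L),
           cluster_sd = 8000, depth = 4,
           repeat_families = data.frame(
             family = c("dir1", "inv1"),
             orientation = c("direct", "inverted"),
             class = c("Ts2", "Ts3"), n_copies = c(4L, 4L),
             unit_length = c(800L, 800L), identity = c(0.85, 0.9),
             stringsAsFactors = FALSE),
           chimera_plan = c(psp = 150L, dsp_direct = 150L,
                            dsp_inverted = 100L),
           ...)
}

test_that("a fixed seed reproduces every artifact byte for byte", {
  spec <- small_spec(seed = 42L)
  g1 <- simulate_genome(spec)
  g2 <- simulate_genome(spec)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  t1 <- simulate_toposites(spec, g1)
  t2 <- simulate_toposites(spec, g2)
  expect_identical(t1$toposites, t2$toposites)
  r1 <- simulate_etipa_reads(spec, t1$toposites, g1$genome)
  r2 <- simulate_etipa_reads(spec, t2$toposites, g2$genome)
  expect_identical(r1, r2)
  c1 <- simulate_chimeras(spec, t1$toposites, g1)
  c2 <- simulate_chimeras(spec, t2$toposites, g2)
  expect_identical(c1, c2)
})

test_that("planted repeat identity tracks the specification", {
  spec <- small_spec(seed = 3L)
  gs <- simulate_genome(spec)
  genome <- gs$genome
  for (fam in c("dir1", "inv1")) {
    r <- gs$repeats[gs$repeats$family == fam, ]
    master <- r[r$copy == 1, ]
    seq_of <- function(row) {
      s <- subseq(genome[[row$chrom]], row$start, row$end)
      if (row$strand == "-") s <- reverseComplement(s)
      as.character(s)
    }
    target <- spec$repeat_families$identity[
      spec$repeat_families$family == fam]
    ids <- vapply(which(r$copy > 1), function(i) {
      positional_identity(seq_of(master), seq_of(r[i, ]))
    }, numeric(1))
    expect_true(all(abs(ids - target) <= 0.02),
                info = sprintf("%s identities: %s", fam,
                               paste(round(ids, 3), collapse = ",")))
  }
  # perfect-identity direct family: the two loci are byte-identical
  spec2 <- small_spec(seed = 5L)
  spec2$repeat_families <- data.frame(
    family = "perf", orientation = "direct", class = "Ts2", n_copies = 2L,
    unit_length = 500L, identity = 1.0, stringsAsFactors = FALSE)
  gs2 <- simulate_genome(spec2)
  r <- gs2$repeats
  expect_identical(
    as.character(subseq(gs2$genome[[1]], r$start[1], r$end[1])),
    as.character(subseq(gs2$genome[[1]], r$start[2], r$end[2])))
  # no repeat families: nothing planted
  spec3 <- small_spec(seed = 6L)
  spec3$repeat_families <- spec3$repeat_families[0, ]
  gs3 <- simulate_genome(spec3)
  expect_null(gs3$repeats)
  expect_null(gs3$repeat_pairs)
})

test_that("inverted-family copies are reverse complemented", {
  spec <- small_spec(seed = 8L)
  gs <- simulate_genome(spec)
  inv <- gs$repeats[gs$repeats$family == "inv1", ]
  expect_true(any(inv$strand == "-") && any(inv$strand == "+"))
  pairs <- gs$repeat_pairs
  expect_setequal(unique(pairs$pair_orientation[pairs$family == "inv1"]),
                  c("direct", "inverted"))
  expect_true(all(pairs$pair_orientation[pairs$family == "dir1"] ==
                    "direct"))
})

test_that("fraction weights steer reads: zero-weight class gets no pileup", {
  spec <- small_spec(seed = 4L)
  spec$depth <- 2
  gs <- simulate_genome(spec)
  ts <- simulate_toposites(spec, gs)
  rd <- simulate_etipa_reads(spec, ts$toposites, gs$genome)
  ts1 <- ts$toposites[ts$toposites$class == "Ts1"]
  win <- GenomicRanges::resize(ts1, 400, fix = "center")
  count_in <- function(pairs, win) {
    gr <- GRanges(pairs$chrom1, IRanges(pairs$start1, pairs$end2))
    sum(countOverlaps(win, gr))
  }
  n1 <- count_in(rd$P1, win)  # Ts1 has P1 weight 0: background only
  n2 <- count_in(rd$P2, win)  # P2 weight 1: 10x enrichment
  expect_gt(n2, 4 * n1)
  # all mates are 100 bp and kept pairs convergent with insert < 500
  expect_true(all(rd$P1$end1 - rd$P1$start1 + 1L == 100L))
  filt <- filter_read_pairs(rd$P1)
  insert <- pmax(filt$end1, filt$end2) - pmin(filt$start1, filt$start2) + 1
  expect_true(all(insert < 500))
})

test_that("chimera emission obeys plan counts, truth tracing and rules", {
  spec <- small_spec(seed = 9L, noise_frac = 0.2)
  gs <- simulate_genome(spec)
  ts <- simulate_toposites(spec, gs)
  cs <- simulate_chimeras(spec, ts$toposites, gs)
  n_spec <- sum(spec$chimera_plan)
  n_noise <- round(spec$noise_frac / (1 - spec$noise_frac) * n_spec)
  expect_equal(nrow(cs$pairs), n_spec + n_noise)
  # truth partitions the set: one record per emitted chimera
  expect_identical(sort(cs$truth$id), sort(cs$pairs$id))
  expect_equal(sum(table(cs$truth$event)),
               n_spec + n_noise)
  chim <- load_chimeras(cs$pairs)
  m <- merge(chim, cs$truth[, c("id", "event", "orientation")], by = "id",
             suffixes = c("", ".truth"))
  expect_true(all(m$orientation == m$orientation.truth))
  expect_true(all(m$orientation[m$event == "PSP"] == "RF"))
  expect_true(all(m$orientation[m$event == "DSP_DIRECT"] %in%
                    c("RF", "FR")))
  expect_true(all(m$orientation[m$event == "DSP_INVERTED"] %in%
                    c("FF", "RR")))
  expect_true(all(m$span[m$event == "PSP"] < 3000))
  expect_true(all(m$span[m$event == "DSP_DIRECT"] >= 3000 &
                    m$span[m$event == "DSP_DIRECT"] <= 2e6))
  # distal ends fall inside matching-class toposites
  m2 <- merge(chim, cs$truth[, c("id", "event", "class")], by = "id",
              suffixes = c("", ".truth"))
  dsp <- m2[m2$event %in% c("DSP_DIRECT", "DSP_INVERTED"), ][1:25, ]
  asg <- assign_ends(dsp, ts$toposites)
  expect_true(all(asg$combo == paste(dsp$class, dsp$class, sep = "-")))
})

test_that("noise chimeras have near-uniform orientation", {
  spec <- small_spec(seed = 10L, noise_frac = 0.75)
  gs <- simulate_genome(spec)
  ts <- simulate_toposites(spec, gs)
  cs <- simulate_chimeras(spec, ts$toposites, gs)
  noise <- cs$truth[cs$truth$event == "inter-complex", ]
  expect_gt(nrow(noise), 1000)
  tab <- table(factor(noise$orientation, c("RF", "FR", "FF", "RR")))
  p <- chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("requesting distal chimeras without suitable repeats errors", {
  spec <- small_spec(seed = 2L)
  spec$repeat_families <- spec$repeat_families[
    spec$repeat_families$orientation == "direct", , drop = FALSE]
  gs <- simulate_genome(spec)
  ts <- simulate_toposites(spec, gs)
  expect_error(simulate_chimeras(spec, ts$toposites, gs), "inverted")
})

test_that("nucleus truth records the exact planted condensed fraction", {
  spec <- sim_spec(seed = 12L, nucleus_dim = c(32L, 32L, 15L),
                   nucleus_plan = data.frame(
                     condition = c("zero", "third", "full"),
                     n = c(2L, 2L, 1L),
                     condensed_fraction = c(0, 0.3, 1.0)))
  ns <- simulate_nuclei(spec)
  expect_equal(nrow(ns$truth), 5)
  expect_equal(ns$truth$condensed_fraction[ns$truth$condition == "zero"],
               c(0, 0))
  expect_equal(ns$truth$condensed_fraction[ns$truth$condition == "full"], 1)
  third <- ns$truth[ns$truth$condition == "third", ]
  expect_equal(third$condensed_fraction,
               round(0.3 * third$volume_voxels) / third$volume_voxels)
  # bright voxels really are brighter: the planted fraction is recoverable
  # from the raw voxel values
  st <- ns$stacks[[which(ns$truth$condition == "third")[1]]]
  expect_equal(attr(st, "condition"), "third")
})
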