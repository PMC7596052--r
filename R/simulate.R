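# Synthetic eTIP-seq data generator.
#
# Emits a toy genome with planted homologous repeat families, toposites of the
# three classes, P1/P2 fraction read pairs, ligation chimeras obeying the
# orientation rules (RF for proximal strand passage; RF/FR on direct repeats,
# FF/RR on inverted repeats for distal strand passage; uniform orientation for
# inter-complex noise), and 3D nucleus image stacks with a planted condensed
# chromatin fraction. Every emitted record traces to a truth record.

#' Simulation specification
#'
#' Bundles every tunable of the synthetic-data generator with defaults that
#' emulate the statistical structure of a two-fraction topoisomerase
#' immunoprecipitation experiment at desk scale: a few-megabase genome,
#' class-dependent P1/P2 enrichment at planted toposites, chimera spans
#' covering the proximal (< 3 kb) and distal (3 kb - 2 Mb) regimes, and
#' repeat families whose orientation drives chimera read orientation.
#'
#' @param seed Integer master seed. Each artifact derives its own stream from
#'   `seed` plus a fixed per-artifact salt, so modules are individually
#'   reproducible.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param background_gc Background GC fraction of simulated sequence.
#' @param repeat_families `data.frame` with columns `family`, `orientation`
#'   ("direct"/"inverted"), `class` ("Ts2"/"Ts3"), `n_copies`, `unit_length`,
#'   `identity` (pairwise identity fraction in (0.5, 1]).
#' @param n_sites Named vector: planted toposite count per class.
#' @param site_width Toposite width in bp.
#' @param n_genes Number of simulated gene bodies (for TSS-linked Ts1
#'   placement and region annotation).
#' @param n_clusters Named vector: number of placement clusters for Ts2/Ts3.
#' @param cluster_sd Within-cluster placement s.d. in bp.
#' @param depth Background raw-base sequencing depth per fraction.
#' @param enrichment Read-density fold enrichment at a toposite relative to
#'   background, for a fraction with weight 1.
#' @param fraction_weights 3x2 matrix (rows Ts1/Ts2/Ts3, cols P1/P2) of
#'   relative fraction weights. The default encodes the evidence model:
#'   resealed sites elute in P2 only (Ts1), covalent-only sites stay in P1
#'   (Ts2), stable sites appear in both (Ts3).
#' @param read_length Mate length in bp.
#' @param corrupt_frac Fraction of eTIPa read pairs corrupted (wrong
#'   orientation, long insert, or multi-mapping flag) to exercise filters.
#' @param chimera_plan Named vector: events per generator class
#'   (`psp`, `dsp_direct`, `dsp_inverted`).
#' @param noise_frac Inter-complex noise fraction of the emitted chimera set.
#' @param adaptor_frac Fraction of chimera pairs flagged with a 5' ligation
#'   adaptor (discarded by the loader).
#' @param psp_span,dsp_span Two-element span ranges (bp) for the log-uniform
#'   span laws of proximal and distal events.
#' @param nucleus_plan `data.frame` with columns `condition`, `n`,
#'   `condensed_fraction` describing the imaging conditions.
#' @param nucleus_dim Integer (x, y, z) stack dimensions.
#' @param voxel_size Numeric (xy, z) voxel edge lengths in micrometres.
#' @return An object of class `etip_sim_spec` (a validated list).
#' @export
sim_spec <- function(seed = 1L,
                     chrom_lengths = c(chr1 = 3e6, chr2 = 1e6),
                     background_gc = 0.42,
                     repeat_families = default_repeat_families(),
                     n_sites = c(Ts1 = 200L, Ts2 = 200L, Ts3 = 200L),
                     site_width = 400L,
                     n_genes = 300L,
                     n_clusters = c(Ts2 = 4L, Ts3 = 6L),
                     cluster_sd = 30000,
                     depth = 30,
                     enrichment = 10,
                     fraction_weights = default_fraction_weights(),
                     read_length = 100L,
                     corrupt_frac = 0.05,
                     chimera_plan = c(psp = 1000L, dsp_direct = 600L,
                                      dsp_inverted = 200L),
                     noise_frac = 0.1,
                     adaptor_frac = 0,
                     psp_span = c(200, 3000),
                     dsp_span = c(3000, 2e6),
                     nucleus_plan = default_nucleus_plan(),
                     nucleus_dim = c(48L, 48L, 25L),
                     voxel_size = c(xy = 0.1, z = 0.275)) {
  spec <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
               background_gc = background_gc,
               repeat_families = repeat_families,
               n_sites = n_sites, site_width = as.integer(site_width),
               n_genes = as.integer(n_genes), n_clusters = n_clusters,
               cluster_sd = cluster_sd, depth = depth,
               enrichment = enrichment,
               fraction_weights = fraction_weights,
               read_length = as.integer(read_length),
               corrupt_frac = corrupt_frac,
               chimera_plan = chimera_plan, noise_frac = noise_frac,
               adaptor_frac = adaptor_frac,
               psp_span = psp_span, dsp_span = dsp_span,
               nucleus_plan = nucleus_plan,
               nucleus_dim = as.integer(nucleus_dim),
               voxel_size = voxel_size)
  stopifnot(length(spec$seed) == 1L, !is.na(spec$seed),
            all(spec$chrom_lengths > 0),
            spec$background_gc > 0, spec$background_gc < 1,
            spec$noise_frac >= 0, spec$noise_frac <= 1,
            spec$adaptor_frac >= 0, spec$adaptor_frac < 1,
            all(c("Ts1", "Ts2", "Ts3") %in% names(spec$n_sites)))
  if (nrow(spec$repeat_families)) {
    stopifnot(all(spec$repeat_families$identity > 0.5),
              all(spec$repeat_families$identity <= 1),
              all(spec$repeat_families$orientation %in%
                    c("direct", "inverted")),
              all(spec$repeat_families$class %in% c("Ts2", "Ts3")))
  }
  class(spec) <- "etip_sim_spec"
  spec
}

#' @rdname sim_spec
#' @export
default_repeat_families <- function() {
  data.frame(family = c("dirA", "dirB", "invA"),
             orientation = c("direct", "direct", "inverted"),
             class = c("Ts2", "Ts3", "Ts3"),
             n_copies = c(6L, 6L, 4L),
             unit_length = c(1000L, 1000L, 1000L),
             identity = c(0.85, 0.90, 0.90),
             stringsAsFactors = FALSE)
}

#' @rdname sim_spec
#' @export
default_fraction_weights <- function() {
  matrix(c(0, 1, 1, 1, 0, 1), nrow = 3,
         dimnames = list(c("Ts1", "Ts2", "Ts3"), c("P1", "P2")))
}

#' @rdname sim_spec
#' @export
default_nucleus_plan <- function() {
  data.frame(condition = c("D1", "D5", "D5+"),
             n = c(30L, 30L, 30L),
             condensed_fraction = c(0.45, 0.30, 0.43),
             stringsAsFactors = FALSE)
}

# Per-artifact salts keep the streams independent but jointly seeded.
sim_salt <- c(genome = 101L, sites = 211L, reads_p1 = 307L, reads_p2 = 401L,
              chimeras = 503L, nuclei = 601L)

with_sim_seed <- function(spec, artifact, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((spec$seed + sim_salt[[artifact]]) %% .Machine$integer.max)
  expr
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  x <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(x)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    x[hit] <- vapply(x[hit], function(b) sample(setdiff(bases, b), 1L),
                     character(1))
  }
  paste(x, collapse = "")
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Sample n non-overlapping start positions for features of width `w` inside
# [lo, hi], at least `gap` bp from previously occupied starts.
place_nonoverlapping <- function(n, w, lo, hi, occupied_starts, occupied_ends,
                                 gap = 0L, max_try = 200L) {
  starts <- integer(0)
  s0 <- occupied_starts; e0 <- occupied_ends
  for (i in seq_len(n)) {
    ok <- FALSE
    for (k in seq_len(max_try)) {
      s <- floor(stats::runif(1, lo, hi - w))
      if (!length(s0) || all(s + w + gap <= s0 | s >= e0 + gap)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place feature ", i, " of ", n,
                  ": region too crowded")
    starts <- c(starts, s)
    s0 <- c(s0, s); e0 <- c(e0, s + w)
  }
  starts
}

# ---------------------------------------------------------------------------
# Genome with planted repeat families
# ---------------------------------------------------------------------------

#' Simulate a genome with planted homologous repeat families
#'
#' Background sequence is i.i.d. with the specified GC content. Each repeat
#' family is a master unit copied `n_copies` times into a confined region of
#' chr1; copy 1 is the master itself and later copies carry i.i.d.
#' substitutions at rate `1 - identity` (no indels), so the planted pairwise
#' identity to the master is analytically controlled. Inverted-family copies
#' with even index are inserted reverse-complemented.
#'
#' @param spec An [sim_spec()] object.
#' @return A list with `genome` (DNAStringSet), `repeats` (truth table of
#'   planted copies: family, orientation, class, chrom, start, end, strand),
#'   and `repeat_pairs` (all within-family copy pairs, ordered up/down, with
#'   the pair's relative orientation: "direct" if the two copies are on the
#'   same strand, "inverted" otherwise).
#' @export
simulate_genome <- function(spec) {
  with_sim_seed(spec, "genome", {
    genome <- Biostrings::DNAStringSet(vapply(
      spec$chrom_lengths, function(L) random_dna(L, spec$background_gc),
      character(1)))
    names(genome) <- names(spec$chrom_lengths)

    fams <- spec$repeat_families
    rep_truth <- NULL
    if (!is.null(fams) && nrow(fams)) {
      # Each class's families live inside that class's cluster territory so
      # that distal chimera ends coincide with clustered toposites.
      terr <- class_territories(spec)
      occupied_s <- integer(0); occupied_e <- integer(0)
      recs <- list()
      for (i in seq_len(nrow(fams))) {
        f <- fams[i, ]
        unit <- random_dna(f$unit_length, spec$background_gc)
        band <- terr[[f$class]]
        starts <- place_nonoverlapping(f$n_copies, f$unit_length,
                                       band[1], band[2],
                                       occupied_s, occupied_e, gap = 4000L)
        occupied_s <- c(occupied_s, starts)
        occupied_e <- c(occupied_e, starts + f$unit_length)
        for (j in seq_len(f$n_copies)) {
          s <- if (j == 1) unit else mutate_dna(unit, 1 - f$identity)
          strand <- "+"
          if (f$orientation == "inverted" && j %% 2 == 0) {
            s <- revcomp_chr(s)
            strand <- "-"
          }
          genome[["chr1"]] <- Biostrings::replaceAt(
            genome[["chr1"]],
            IRanges::IRanges(starts[j] + 1L, starts[j] + f$unit_length),
            Biostrings::DNAStringSet(s)[[1]])
          recs[[length(recs) + 1L]] <- data.frame(
            family = f$family, orientation = f$orientation, class = f$class,
            chrom = "chr1", start = starts[j] + 1L,
            end = starts[j] + f$unit_length, strand = strand,
            copy = j, stringsAsFactors = FALSE)
        }
      }
      rep_truth <- do.call(rbind, recs)
    }
    list(genome = genome,
         repeats = rep_truth,
         repeat_pairs = repeat_pairs_from_truth(rep_truth))
  })
}

# Territories on chr1 where each class's clusters (and repeat families) live;
# chosen so any within-family pair lies in the distal (< 2 Mb) regime and the
# two classes are mutually exclusive, as observed for the real site clusters.
class_territories <- function(spec) {
  L <- spec$chrom_lengths[["chr1"]]
  list(Ts2 = c(round(0.06 * L), round(0.52 * L)),
       Ts3 = c(round(0.55 * L), round(0.97 * L)))
}

repeat_pairs_from_truth <- function(rep_truth) {
  if (is.null(rep_truth) || !nrow(rep_truth)) return(NULL)
  out <- list()
  for (fam in unique(rep_truth$family)) {
    r <- rep_truth[rep_truth$family == fam, ]
    r <- r[order(r$start), ]
    if (nrow(r) < 2) next
    idx <- utils::combn(nrow(r), 2)
    for (k in seq_len(ncol(idx))) {
      a <- r[idx[1, k], ]; b <- r[idx[2, k], ]
      out[[length(out) + 1L]] <- data.frame(
        family = fam, class = a$class, chrom = a$chrom,
        start_up = a$start, end_up = a$end, strand_up = a$strand,
        start_down = b$start, end_down = b$end, strand_down = b$strand,
        pair_orientation = if (a$strand == b$strand) "direct" else "inverted",
        span = abs((b$start + b$end) %/% 2L - (a$start + a$end) %/% 2L),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# Toposites and genes
# ---------------------------------------------------------------------------

#' Simulate gene annotation and planted toposites
#'
#' Ts1 sites are placed in TSS zones of randomly chosen genes; Ts2 and Ts3
#' sites are drawn around a small number of cluster centres inside their
#' class territory on chr1, with every planted repeat copy additionally
#' hosting a toposite of the family's class (so distal chimera ends fall in
#' matching-class sites).
#'
#' @param spec An [sim_spec()] object.
#' @param genome_sim Output of [simulate_genome()].
#' @return A list with `toposites` (GRanges, mcols `class` and `summit`) and
#'   `genes` (GRanges with strand; the TSS is the strand-aware 5' end).
#' @export
simulate_toposites <- function(spec, genome_sim) {
  with_sim_seed(spec, "sites", {
    sl <- genome_seqlengths(genome_sim$genome)
    w <- spec$site_width

    # genes: non-overlapping bodies over all chromosomes, sized so bodies
    # occupy roughly a third of the genome
    mean_len <- 0.35 * sum(sl) / spec$n_genes
    glen <- pmax(2000, round(stats::rlnorm(spec$n_genes, log(mean_len), 0.6)))
    glen <- pmin(glen, round(0.02 * sum(sl)))
    gchr <- sample(names(sl), spec$n_genes, replace = TRUE,
                   prob = sl / sum(sl))
    # stick-breaking placement per chromosome: random gaps fill the free
    # space exactly, so any occupancy below 100% places successfully
    gstart <- integer(spec$n_genes)
    for (c1 in names(sl)) {
      i <- which(gchr == c1)
      if (!length(i)) next
      usable <- sl[[c1]] - 10000
      if (sum(glen[i]) >= usable) stop("gene plan exceeds chromosome ", c1)
      gaps <- stats::runif(length(i) + 1)
      gaps <- gaps / sum(gaps) * (usable - sum(glen[i]))
      gstart[i] <- 5000 + round(cumsum(gaps[-length(gaps)]) +
                                  cumsum(c(0, glen[i][-length(i)])))
    }
    genes <- GenomicRanges::GRanges(
      gchr, IRanges::IRanges(gstart + 1L, gstart + glen),
      strand = sample(c("+", "-"), spec$n_genes, replace = TRUE),
      seqlengths = sl)
    genes$name <- sprintf("gene_%03d", seq_len(spec$n_genes))

    # Ts1: around TSS of sampled genes
    tss <- ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                  GenomicRanges::start(genes), GenomicRanges::end(genes))
    pick <- sample(length(genes), spec$n_sites[["Ts1"]], replace = TRUE)
    s1 <- tss[pick] + round(stats::runif(length(pick), -1500, 1500)) - w %/% 2
    site_list <- list(data.frame(
      chrom = as.character(GenomicRanges::seqnames(genes))[pick],
      start = s1, class = "Ts1", stringsAsFactors = FALSE))

    # Ts2/Ts3: clustered in the class territory; repeat copies host sites too
    terr <- class_territories(spec)
    for (cl in c("Ts2", "Ts3")) {
      reps <- genome_sim$repeats
      reps <- if (is.null(reps)) NULL else reps[reps$class == cl, ]
      n_rep <- if (is.null(reps)) 0L else nrow(reps)
      n_free <- max(0L, spec$n_sites[[cl]] - n_rep)
      centers <- round(stats::runif(spec$n_clusters[[cl]],
                                    terr[[cl]][1], terr[[cl]][2]))
      cc <- sample(centers, n_free, replace = TRUE)
      s <- round(cc + stats::rnorm(n_free, 0, spec$cluster_sd)) - w %/% 2
      s <- pmin(pmax(s, 1000), spec$chrom_lengths[["chr1"]] - w - 1000)
      df <- data.frame(chrom = "chr1", start = s, class = cl,
                       stringsAsFactors = FALSE)
      if (n_rep) {
        mid <- (reps$start + reps$end) %/% 2L
        df <- rbind(df, data.frame(chrom = reps$chrom, start = mid - w %/% 2,
                                   class = cl, stringsAsFactors = FALSE))
      }
      site_list[[length(site_list) + 1L]] <- df
    }
    sites <- do.call(rbind, site_list)
    gr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$start,
                                                  width = w),
                                 seqlengths = sl)
    gr$class <- sites$class
    gr$summit <- GenomicRanges::start(gr) + w %/% 2L
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    gr$name <- sprintf("site_%04d", seq_along(gr))
    list(toposites = gr, genes = genes)
  })
}

# ---------------------------------------------------------------------------
# eTIPa fraction reads
# ---------------------------------------------------------------------------

emit_pairs_at <- function(centers, chrom, sl, read_len) {
  n <- length(centers)
  frag <- round(stats::runif(n, 2 * read_len + 20, 480))
  s1 <- pmax(1L, round(centers - frag / 2))
  e2 <- pmin(sl[chrom], s1 + frag - 1L)
  s1 <- pmax(1L, e2 - frag + 1L)
  data.frame(chrom1 = chrom, start1 = s1, end1 = s1 + read_len - 1L,
             strand1 = "+", unique1 = TRUE, adaptor1 = FALSE,
             chrom2 = chrom, start2 = e2 - read_len + 1L, end2 = e2,
             strand2 = "-", unique2 = TRUE, adaptor2 = FALSE,
             stringsAsFactors = FALSE)
}

#' Simulate P1/P2 fraction read pairs
#'
#' Background fragments fall uniformly on the genome at `depth` raw-base
#' coverage; each toposite additionally receives fragments centred
#' Normal(summit, width/4) so that its local read density is
#' `enrichment` x background, scaled by the class-by-fraction weight matrix.
#' All pairs are 100 bp mates, convergent, insert < 500 bp, except a
#' `corrupt_frac` fraction altered to exercise the pair filter.
#'
#' @param spec An [sim_spec()] object.
#' @param sites Toposite truth GRanges from [simulate_toposites()].
#' @param genome Genome DNAStringSet (for lengths).
#' @return List with read-pair `data.frame`s `P1` and `P2`.
#' @export
simulate_etipa_reads <- function(spec, sites, genome) {
  sl <- genome_seqlengths(genome)
  glen <- sum(sl)
  rl <- spec$read_length
  n_bg <- round(spec$depth * glen / (2 * rl))
  bg_density <- n_bg / glen   # pairs per bp
  out <- list()
  for (fr in c("P1", "P2")) {
    out[[fr]] <- with_sim_seed(spec, paste0("reads_", tolower(fr)), {
      chrom_bg <- sample(names(sl), n_bg, replace = TRUE, prob = sl / sum(sl))
      centers_bg <- floor(stats::runif(n_bg, 250, sl[chrom_bg] - 250))
      bg <- emit_pairs_at(centers_bg, chrom_bg, sl, rl)

      wts <- spec$fraction_weights[sites$class, fr]
      n_site <- round((spec$enrichment - 1) * bg_density *
                        GenomicRanges::width(sites) * wts)
      idx <- rep(seq_along(sites), n_site)
      centers <- round(sites$summit[idx] +
                         stats::rnorm(length(idx), 0,
                                      GenomicRanges::width(sites)[idx] / 4))
      chrom_s <- as.character(GenomicRanges::seqnames(sites))[idx]
      centers <- pmin(pmax(centers, 300), sl[chrom_s] - 300)
      df <- rbind(bg, emit_pairs_at(centers, chrom_s, sl, rl))

      if (spec$corrupt_frac > 0) {
        bad <- which(stats::runif(nrow(df)) < spec$corrupt_frac)
        kind <- sample(3, length(bad), replace = TRUE)
        df$strand1[bad[kind == 1]] <- "-"           # divergent / same strand
        long <- bad[kind == 2]                      # insert >= 500 bp
        shift <- 500L + round(stats::runif(length(long), 0, 2000))
        df$start2[long] <- pmin(df$start2[long] + shift,
                                sl[df$chrom2[long]] - rl)
        df$end2[long] <- df$start2[long] + rl - 1L
        df$unique1[bad[kind == 3]] <- FALSE         # multi-mapping mate
      }
      rownames(df) <- NULL
      df
    })
  }
  out
}

# ---------------------------------------------------------------------------
# Chimeras
# ---------------------------------------------------------------------------

orient_strands <- function(orientation) {
  # orientation letters are ordered upstream -> downstream; F = "+", R = "-"
  up <- substr(orientation, 1, 1)
  dn <- substr(orientation, 2, 2)
  cbind(up = ifelse(up == "F", "+", "-"), down = ifelse(dn == "F", "+", "-"))
}

rloguniform <- function(n, lo, hi) {
  exp(stats::runif(n, log(lo), log(hi)))
}

#' Simulate ligation chimera read pairs with truth labels
#'
#' Event classes: proximal strand passage (`psp`; span log-uniform on
#' `psp_span`, both ends around one Ts1 toposite, orientation RF),
#' distal strand passage on a planted direct repeat pair (`dsp_direct`;
#' ends inside the two copies, RF or FR with equal odds), distal strand
#' passage on an inverted pair (`dsp_inverted`; FF or RR), and inter-complex
#' noise (uniform genomic ends on one chromosome, uniform orientation,
#' span unconstrained). The noise count is chosen so noise makes up
#' `noise_frac` of the emitted set.
#'
#' @param spec An [sim_spec()] object.
#' @param sites Toposite truth GRanges.
#' @param genome_sim Output of [simulate_genome()] (for repeat pairs).
#' @return List with `pairs` (read-pair `data.frame` with an extra `id`
#'   column; mate order randomized) and `truth` (`data.frame` keyed by `id`
#'   with the generating event, family and class).
#' @export
simulate_chimeras <- function(spec, sites, genome_sim) {
  with_sim_seed(spec, "chimeras", {
    sl <- spec$chrom_lengths
    rl <- spec$read_length
    plan <- spec$chimera_plan
    n_spec <- sum(plan)
    n_noise <- if (spec$noise_frac >= 1) {
      stop("noise_frac must be < 1 when specific chimeras are planned")
    } else round(spec$noise_frac / (1 - spec$noise_frac) * n_spec)

    recs <- list()
    add <- function(chrom, up_mid, down_mid, orientation, event, family,
                    class) {
      recs[[length(recs) + 1L]] <<- data.frame(
        chrom = chrom, up_mid = round(up_mid), down_mid = round(down_mid),
        orientation = orientation, event = event, family = family,
        class = class, stringsAsFactors = FALSE)
    }

    # PSP: both ends around a Ts1 toposite
    if (plan[["psp"]] > 0) {
      ts1 <- sites[sites$class == "Ts1"]
      if (!length(ts1)) stop("PSP chimeras requested but no Ts1 sites")
      k <- sample(length(ts1), plan[["psp"]], replace = TRUE)
      span <- rloguniform(plan[["psp"]], spec$psp_span[1],
                          spec$psp_span[2] - 1)
      mid <- ts1$summit[k]
      chrom <- as.character(GenomicRanges::seqnames(ts1))[k]
      up <- pmax(rl, mid - span / 2)
      add(chrom, up, up + span, "RF", "PSP", NA_character_, "Ts1")
    }

    # DSP on planted repeat pairs
    rp <- genome_sim$repeat_pairs
    for (ev in c("dsp_direct", "dsp_inverted")) {
      n_ev <- plan[[ev]]
      if (n_ev <= 0) next
      want <- sub("dsp_", "", ev)
      cand <- if (is.null(rp)) NULL else {
        rp[rp$pair_orientation == want &
             rp$span >= spec$dsp_span[1] & rp$span <= spec$dsp_span[2], ]
      }
      if (is.null(cand) || !nrow(cand)) {
        stop("chimera plan requests ", ev, " events but no planted ",
             want, " repeat pair lies in the distal span range")
      }
      k <- sample(nrow(cand), n_ev, replace = TRUE)
      orientation <- if (want == "direct") {
        sample(c("RF", "FR"), n_ev, replace = TRUE)
      } else {
        sample(c("FF", "RR"), n_ev, replace = TRUE)
      }
      jit <- function(s, e) {
        round(stats::runif(n_ev, (s + e) / 2 - (e - s) / 2 + rl,
                           (s + e) / 2 + (e - s) / 2 - rl))
      }
      add(cand$chrom[k],
          jit(cand$start_up[k], cand$end_up[k]),
          jit(cand$start_down[k], cand$end_down[k]),
          orientation, toupper(sub("dsp", "DSP", ev)), cand$family[k],
          cand$class[k])
    }

    # inter-complex noise: uniform ends, uniform orientation
    if (n_noise > 0) {
      chrom <- sample(names(sl), n_noise, replace = TRUE, prob = sl / sum(sl))
      a <- floor(stats::runif(n_noise, rl, sl[chrom] - rl))
      b <- floor(stats::runif(n_noise, rl, sl[chrom] - rl))
      add(chrom, pmin(a, b), pmax(a, b),
          sample(c("RF", "FR", "FF", "RR"), n_noise, replace = TRUE),
          "inter-complex", NA_character_, NA_character_)
    }

    ev <- do.call(rbind, recs)
    ev$id <- sprintf("chim_%05d", seq_len(nrow(ev)))
    st <- orient_strands(ev$orientation)
    up_start <- round(ev$up_mid - rl / 2)
    down_start <- round(ev$down_mid - rl / 2)

    adaptor <- stats::runif(nrow(ev)) < spec$adaptor_frac
    # randomize mate order so loaders must canonicalize
    flip <- stats::runif(nrow(ev)) < 0.5
    m1s <- ifelse(flip, down_start, up_start)
    m1strand <- ifelse(flip, st[, "down"], st[, "up"])
    m2s <- ifelse(flip, up_start, down_start)
    m2strand <- ifelse(flip, st[, "up"], st[, "down"])
    pairs <- data.frame(
      chrom1 = ev$chrom, start1 = m1s, end1 = m1s + rl - 1L,
      strand1 = m1strand, unique1 = TRUE, adaptor1 = adaptor,
      chrom2 = ev$chrom, start2 = m2s, end2 = m2s + rl - 1L,
      strand2 = m2strand, unique2 = TRUE, adaptor2 = FALSE,
      id = ev$id, stringsAsFactors = FALSE)
    truth <- ev[, c("id", "event", "family", "class", "chrom", "up_mid",
                    "down_mid", "orientation")]
    list(pairs = pairs, truth = truth)
  })
}

# ---------------------------------------------------------------------------
# Nucleus stacks
# ---------------------------------------------------------------------------

ellipsoid_mask <- function(dim, semi) {
  x <- seq_len(dim[1]) - (dim[1] + 1) / 2
  y <- seq_len(dim[2]) - (dim[2] + 1) / 2
  z <- seq_len(dim[3]) - (dim[3] + 1) / 2
  xa <- array(rep(x, times = dim[2] * dim[3]), dim)
  ya <- array(rep(rep(y, each = dim[1]), times = dim[3]), dim)
  za <- array(rep(z, each = dim[1] * dim[2]), dim)
  (xa / semi[1])^2 + (ya / semi[2])^2 + (za / semi[3])^2 <= 1
}

#' Simulate 3D nucleus stacks with a planted condensed fraction
#'
#' Each nucleus is an ellipsoid of dim euchromatin intensity with bright
#' heterochromatic foci grown as spherical blobs until exactly the planted
#' fraction of nuclear voxels is condensed; surrounding background is dark.
#' The recorded truth is the exact planted bright-voxel fraction.
#'
#' @param spec An [sim_spec()] object (fields `nucleus_plan`, `nucleus_dim`,
#'   `voxel_size`).
#' @return A list with `stacks` (list of numeric (x, y, z) arrays, each with
#'   attributes `condition` and `voxel_size`) and `truth` (`data.frame`:
#'   nucleus, condition, condensed_fraction, volume_voxels).
#' @export
simulate_nuclei <- function(spec) {
  with_sim_seed(spec, "nuclei", {
    dim <- spec$nucleus_dim
    plan <- spec$nucleus_plan
    stacks <- list()
    truth <- list()
    nid <- 0L
    for (i in seq_len(nrow(plan))) {
      for (j in seq_len(plan$n[i])) {
        nid <- nid + 1L
        semi <- c(stats::runif(1, 0.28, 0.33) * dim[1],
                  stats::runif(1, 0.26, 0.31) * dim[2],
                  stats::runif(1, 0.30, 0.36) * dim[3])
        mask <- ellipsoid_mask(dim, semi)
        n_mask <- sum(mask)
        target <- round(plan$condensed_fraction[i] * n_mask)

        # grow spherical foci inside the mask until the bright-voxel count
        # reaches the target exactly
        idx <- which(mask, arr.ind = TRUE)
        bright <- logical(n_mask)
        while (sum(bright) < target) {
          c_i <- idx[sample(n_mask, 1L), ]
          r <- stats::runif(1, 1.6, 3.2)
          d2 <- (idx[, 1] - c_i[1])^2 + (idx[, 2] - c_i[2])^2 +
            ((idx[, 3] - c_i[3]) * 1.5)^2
          bright <- bright | d2 <= r^2
        }
        excess <- sum(bright) - target
        if (excess > 0) bright[sample(which(bright), excess)] <- FALSE

        # broad, overlapping class distributions: stained chromatin is a
        # continuum, not two spikes
        arr <- array(stats::rnorm(prod(dim), 20, 5), dim)
        vox <- stats::rnorm(n_mask, 95, 15)
        vox[bright] <- stats::rnorm(sum(bright), 185, 20)
        arr[mask] <- vox
        arr[arr < 0] <- 0
        attr(arr, "condition") <- plan$condition[i]
        attr(arr, "voxel_size") <- spec$voxel_size
        stacks[[nid]] <- arr
        truth[[nid]] <- data.frame(
          nucleus = nid, condition = plan$condition[i],
          condensed_fraction = target / n_mask,
          volume_voxels = n_mask, stringsAsFactors = FALSE)
      }
    }
    list(stacks = stacks, truth = do.call(rbind, truth))
  })
}
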