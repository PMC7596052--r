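# Chromatin condensation from 3D nuclear stain stacks: intensity
# normalization, mean filtering, Otsu segmentation with largest-component
# selection and hole filling, per-nucleus 256-level histograms, the
# cross-condition isosbestic point, condensed fraction and nuclear volume,
# and two-group Mann-Whitney comparison.

#' Linearly stretch voxel intensities to the 0-255 range
#'
#' Order-preserving affine map taking the stack minimum to 0 and maximum to
#' 255. Idempotent up to rounding; a constant stack has no defined stretch
#' and raises an error.
#'
#' @param stack Numeric 3D array (x, y, z).
#' @return Array of the same shape with values in `[0, 255]`.
#' @export
normalize_stack <- function(stack) {
  rng <- range(stack)
  if (rng[1] == rng[2]) stop("constant stack: intensity stretch undefined")
  out <- (stack - rng[1]) / (rng[2] - rng[1]) * 255
  attributes(out) <- attributes(stack)
  out
}

#' In-plane mean filter
#'
#' Smooths each z-slice with a `k x k` mean kernel (default 3x3; the z axis
#' is left unfiltered because axial sampling is much coarser than lateral).
#'
#' @param stack Numeric 3D array.
#' @param k Kernel side length (odd; default 3).
#' @return Smoothed array of the same shape.
#' @export
mean_filter_stack <- function(stack, k = 3L) {
  kern <- matrix(1 / (k * k), k, k)
  out <- EBImage::filter2(stack, kern, boundary = "replicate")
  out <- as.array(out)
  attributes(out) <- attributes(stack)
  out
}

# Frontier BFS over a voxel neighbourhood given by integer displacement
# triples; returns the set of reachable indices from `seeds` within
# `allowed`. Bounds are checked per axis so no neighbour wraps across rows,
# columns or slices.
grow_region <- function(dim, allowed, seeds, disp) {
  n <- prod(dim)
  offs <- disp[, 1] + disp[, 2] * dim[1] + disp[, 3] * dim[1] * dim[2]
  m <- nrow(disp)
  reached <- logical(n)
  frontier <- seeds[allowed[seeds]]
  reached[frontier] <- TRUE
  while (length(frontier)) {
    co <- arrayInd(frontier, dim)
    cand <- rep(frontier, each = m) + offs
    nx <- rep(co[, 1], each = m) + disp[, 1]
    ny <- rep(co[, 2], each = m) + disp[, 2]
    nz <- rep(co[, 3], each = m) + disp[, 3]
    ok <- nx >= 1 & nx <= dim[1] & ny >= 1 & ny <= dim[2] &
      nz >= 1 & nz <= dim[3]
    cand <- unique(cand[ok])
    cand <- cand[allowed[cand] & !reached[cand]]
    reached[cand] <- TRUE
    frontier <- cand
  }
  reached
}

disp_26 <- local({
  d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  unname(d[rowSums(d == 0) < 3, , drop = FALSE])
})

disp_6 <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))

# Label 26-connected foreground components of a logical 3D array.
label_components_3d <- function(bw) {
  dim <- dim(bw)
  labels <- integer(prod(dim))
  lab <- 0L
  todo <- bw
  repeat {
    seed <- which(todo)[1]
    if (is.na(seed)) break
    lab <- lab + 1L
    comp <- grow_region(dim, as.vector(bw), seed, disp_26)
    labels[comp] <- lab
    todo[comp] <- FALSE
  }
  array(labels, dim)
}

# Fill cavities: background voxels not 6-connected to the array border.
fill_holes_3d <- function(mask) {
  dim <- dim(mask)
  ix <- arrayInd(seq_len(prod(dim)), dim)
  border <- which(ix[, 1] %in% c(1L, dim[1]) | ix[, 2] %in% c(1L, dim[2]) |
                    ix[, 3] %in% c(1L, dim[3]))
  outside <- grow_region(dim, !as.vector(mask), border, disp_6)
  array(mask | !outside, dim)
}

#' Segment the nucleus in a normalized stack
#'
#' Otsu threshold on the mean-filtered stack, selection of the largest
#' 26-connected foreground component, and 3D hole filling.
#'
#' @param stack Normalized 3D array (see [normalize_stack()]).
#' @param smooth Apply the in-plane mean filter before thresholding
#'   (default TRUE).
#' @return Logical 3D mask.
#' @export
segment_nucleus <- function(stack, smooth = TRUE) {
  sm <- if (smooth) mean_filter_stack(stack) else stack
  # one global threshold over all slices (otsu() thresholds frame-wise, so
  # feed the whole stack as a single frame)
  th <- EBImage::otsu(EBImage::Image(matrix(as.vector(sm) / 255, ncol = 1L)),
                      range = c(0, 1), levels = 256) * 255
  bw <- sm > th
  if (!any(bw)) stop("no foreground voxels after thresholding")
  labels <- label_components_3d(bw)
  sizes <- tabulate(labels[labels > 0])
  fill_holes_3d(labels == which.max(sizes))
}

#' Per-nucleus 256-level intensity histogram
#'
#' Counts mask voxels per integer gray level 0-255 and scales by the
#' nucleus's total masked intensity, so nuclei of different brightness and
#' size are comparable.
#'
#' @param stack Normalized (optionally filtered) 3D array.
#' @param mask Logical mask from [segment_nucleus()].
#' @return Numeric vector of length 256 (levels 0-255), scaled counts; the
#'   raw counts are in attribute `counts` and the total intensity in
#'   `total_intensity`.
#' @export
nucleus_histogram <- function(stack, mask) {
  if (!any(mask)) stop("empty mask")
  v <- pmin(pmax(floor(stack[mask]), 0), 255)
  counts <- tabulate(v + 1L, nbins = 256L)
  total <- sum(stack[mask])
  out <- counts / total
  attr(out, "counts") <- counts
  attr(out, "total_intensity") <- total
  out
}

#' Median intensity-frequency curve per condition
#'
#' @param histograms List of per-nucleus scaled histograms
#'   (see [nucleus_histogram()]).
#' @param condition Character vector, one condition label per nucleus.
#' @return Matrix with 256 rows (levels 0-255) and one column per
#'   condition: the per-level median of the scaled frequencies.
#' @export
condition_curves <- function(histograms, condition) {
  stopifnot(length(histograms) == length(condition))
  conds <- unique(condition)
  mat <- vapply(conds, function(cn) {
    h <- do.call(cbind, histograms[condition == cn])
    apply(h, 1, stats::median)
  }, numeric(256))
  rownames(mat) <- 0:255
  mat
}

#' Locate the isosbestic point of condition curves
#'
#' The isosbestic point is the gray level where the per-condition
#' intensity-frequency curves intersect: the boundary between dispersed
#' (darker) and condensed (brighter) chromatin. Within the search band the
#' function requires a sign change of some pairwise curve difference and
#' returns the crossing level with minimal total cross-condition spread.
#'
#' @param curves 256-row matrix from [condition_curves()] (>= 2 columns).
#' @param band Search band of gray levels (default 30-220; the extreme
#'   tails cross trivially where all curves vanish).
#' @param smooth_width Running-mean width (levels) applied to each curve
#'   before crossing detection; per-level median curves are jagged because
#'   nuclei are stretched individually.
#' @param flank Width (levels) of the dominance flanks: a crossing is
#'   structural only if one condition dominates on the left flank and the
#'   order flips on the right flank.
#' @return List with `level` (gray level) and `spread` (cross-condition
#'   range of the smoothed curves at the level).
#' @export
find_isosbestic <- function(curves, band = c(30L, 220L), smooth_width = 11L,
                            flank = 20L) {
  if (ncol(curves) < 2) stop("need at least two condition curves")
  if (all(apply(curves, 1, function(x) max(x) == min(x)))) {
    stop("identical curves: no unique crossing")
  }
  sm <- apply(curves, 2, function(x) {
    as.numeric(stats::filter(x, rep(1 / smooth_width, smooth_width),
                             sides = 2))
  })
  lv <- band[1]:band[2]
  pairs <- utils::combn(ncol(curves), 2)
  crossing <- rep(FALSE, length(lv))
  for (k in seq_len(ncol(pairs))) {
    d <- sm[, pairs[1, k]] - sm[, pairs[2, k]]
    eps <- 0.02 * max(abs(d), na.rm = TRUE)
    for (i in seq_along(lv)) {
      b <- lv[i]
      left <- d[pmax(1L, b - flank):b + 1L]
      right <- d[b:pmin(255L, b + flank) + 1L]
      ml <- mean(left, na.rm = TRUE); mr <- mean(right, na.rm = TRUE)
      if (!is.na(ml) && !is.na(mr) && abs(ml) > eps && abs(mr) > eps &&
          sign(ml) != sign(mr)) {
        crossing[i] <- TRUE
      }
    }
  }
  if (!any(crossing)) stop("no curve crossing inside the search band")
  spread <- apply(sm[lv + 1L, , drop = FALSE], 1,
                  function(x) max(x) - min(x))
  cand <- which(crossing)
  best <- cand[which.min(spread[cand])]
  list(level = lv[best], spread = spread[best])
}

#' Condensed chromatin fraction of a nucleus
#'
#' @param stack Normalized 3D array.
#' @param mask Logical nucleus mask.
#' @param level Boundary gray level (e.g. the isosbestic point).
#' @return Fraction of mask voxels with intensity strictly above `level`.
#' @export
condensed_fraction <- function(stack, mask, level) {
  if (!any(mask)) stop("empty mask")
  mean(stack[mask] > level)
}

#' Nuclear volume from a segmentation mask
#'
#' @param mask Logical 3D mask.
#' @param voxel_size Numeric `(xy, z)` voxel edge lengths in micrometres.
#' @return Volume in cubic micrometres.
#' @export
nucleus_volume <- function(mask, voxel_size = c(xy = 0.1, z = 0.275)) {
  sum(mask) * voxel_size[[1]]^2 * voxel_size[[2]]
}

#' End-to-end chromatin condensation analysis
#'
#' Runs the full imaging pipeline on a list of nucleus stacks: stretch to
#' 256 gray levels, in-plane mean filter, Otsu segmentation with
#' largest-component and hole-fill, per-nucleus scaled histograms, the
#' cross-condition isosbestic point, per-nucleus condensed fraction and
#' volume, and two-sided Mann-Whitney tests between all condition pairs.
#'
#' @param stacks List of numeric 3D arrays; condition labels are taken from
#'   each array's `condition` attribute unless `condition` is given.
#' @param condition Optional character vector of condition labels.
#' @param voxel_size Numeric `(xy, z)` voxel sizes in micrometres.
#' @param band Isosbestic search band.
#' @return List with `per_nucleus` (`data.frame`: nucleus, condition,
#'   volume_um3, condensed_fraction), `curves`, `isosbestic`, and `tests`
#'   (`data.frame` of pairwise Mann-Whitney p-values for fraction and
#'   volume).
#' @export
analyze_nuclei <- function(stacks, condition = NULL,
                           voxel_size = c(xy = 0.1, z = 0.275),
                           band = c(30L, 220L)) {
  if (is.null(condition)) {
    condition <- vapply(stacks, function(s) {
      cn <- attr(s, "condition")
      if (is.null(cn)) NA_character_ else cn
    }, character(1))
  }
  if (any(is.na(condition))) stop("every stack needs a condition label")
  n <- length(stacks)
  hists <- vector("list", n)
  masks <- vector("list", n)
  norm <- vector("list", n)
  vol <- numeric(n)
  for (i in seq_len(n)) {
    nm <- normalize_stack(stacks[[i]])
    mask <- segment_nucleus(nm)   # smoothing happens inside segmentation
    hists[[i]] <- nucleus_histogram(nm, mask)
    masks[[i]] <- mask
    norm[[i]] <- nm
    vol[i] <- nucleus_volume(mask, voxel_size)
  }
  curves <- condition_curves(hists, condition)
  iso <- find_isosbestic(curves, band)
  frac <- vapply(seq_len(n), function(i) {
    condensed_fraction(norm[[i]], masks[[i]], iso$level)
  }, numeric(1))
  per_nucleus <- data.frame(nucleus = seq_len(n), condition = condition,
                            volume_um3 = vol, condensed_fraction = frac,
                            stringsAsFactors = FALSE)
  conds <- unique(condition)
  tests <- NULL
  if (length(conds) > 1) {
    pr <- utils::combn(conds, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pr)), function(k) {
      a <- pr[1, k]; b <- pr[2, k]
      data.frame(
        condition_a = a, condition_b = b,
        p_fraction = stats::wilcox.test(frac[condition == a],
                                        frac[condition == b],
                                        exact = FALSE)$p.value,
        p_volume = stats::wilcox.test(vol[condition == a],
                                      vol[condition == b],
                                      exact = FALSE)$p.value,
        stringsAsFactors = FALSE)
    }))
  }
  list(per_nucleus = per_nucleus, curves = curves, isosbestic = iso,
       tests = tests)
}
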