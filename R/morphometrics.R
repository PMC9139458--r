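# Image morphometrics: cell segmentation, micropattern coverage, spread-area
# and mean-intensity time series, and a simple opening-based protrusion
# (filopodia-like) detector on binary shapes.

#' Triangle threshold of a grayscale image
#'
#' Histogram-geometric threshold suited to weakly bimodal histograms with a
#' dominant background peak: the threshold maximizes the distance between the
#' histogram and the straight line joining the histogram peak to the far end
#' of its longer tail.
#'
#' @param image Numeric matrix.
#' @param n_bins Histogram bins. Default 256.
#' @return Threshold on the intensity scale of `image`.
#' @export
threshold_triangle <- function(image, n_bins = 256L) {
  v <- as.vector(image)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(floor((v - rng[1]) / diff(rng) * n_bins) + 1L, 1L),
                     n_bins), nbins = n_bins)
  pk <- which.max(h)
  lo <- which(h > 0)[1]
  hi <- rev(which(h > 0))[1]
  # work on the longer tail side of the peak
  if ((hi - pk) >= (pk - lo)) { a <- pk; b <- hi } else { a <- pk; b <- lo }
  idx <- if (a <= b) a:b else b:a
  # distance from each histogram point to the peak-to-tail chord
  x1 <- a; y1 <- h[a]; x2 <- b; y2 <- h[b]
  d <- abs((y2 - y1) * idx - (x2 - x1) * h[idx] + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  t_bin <- idx[which.max(d)]
  rng[1] + (t_bin - 0.5) / n_bins * diff(rng)
}

#' Segment cells in a single-channel image
#'
#' Gaussian smoothing followed by automatic grey-level thresholding (triangle
#' or Otsu) and connected-component labeling; components smaller than
#' `min_area_um2` are removed.
#'
#' @param image Numeric matrix.
#' @param pixel_size_um Pixel size, um.
#' @param method `"triangle"` (default) or `"otsu"`.
#' @param sigma_px Smoothing sigma in pixels. Default 2.
#' @param min_area_um2 Minimum component area, um^2. Default 1.
#' @return Integer label matrix (0 = background), relabeled 1..k.
#' @export
segment_cells <- function(image, pixel_size_um, method = c("triangle", "otsu"),
                          sigma_px = 2, min_area_um2 = 1) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), pixel_size_um > 0)
  rng <- range(image)
  if (diff(rng) == 0) return(matrix(0L, nrow(image), ncol(image)))
  norm <- (image - rng[1]) / diff(rng)
  sm <- as.matrix(EBImage::gblur(norm, sigma = sigma_px))
  thr <- switch(method,
                triangle = threshold_triangle(sm),
                otsu = EBImage::otsu(EBImage::Image(sm)))
  mask <- sm > thr
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (max(lab) > 0) {
    sizes <- tabulate(lab, nbins = max(lab))
    min_px <- min_area_um2 / pixel_size_um^2
    drop <- which(sizes < min_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- matrix(as.integer(factor(lab, levels = c(0, setdiff(sort(unique(as.vector(lab))), 0)))) - 1L,
                  nrow(lab), ncol(lab))
  }
  lab
}

#' Percent micropattern area coverage
#'
#' `100 * |cell mask intersect pattern mask| / |pattern mask|`: the fraction
#' of the adhesive micropattern covered by cells.
#'
#' @param cell_mask Logical/numeric matrix; nonzero = cell.
#' @param pattern_mask Logical/numeric matrix of the same dimensions;
#'   nonzero = patterned area.
#' @return Coverage percentage in \[0, 100\].
#' @export
percent_pattern_coverage <- function(cell_mask, pattern_mask) {
  if (!all(dim(cell_mask) == dim(pattern_mask)))
    stop("cell and pattern masks must have identical dimensions")
  pat <- pattern_mask > 0
  if (!any(pat)) stop("undefined coverage: pattern mask is empty")
  100 * sum(cell_mask > 0 & pat) / sum(pat)
}

#' Spread-area and mean-intensity time series of one cell
#'
#' Per-frame segmentation in which the previous frame's mask seeds the next:
#' among the current frame's components, the one overlapping the previous
#' mask most is followed (frame 1 starts from the largest component). Returns
#' the tracked area and in-mask mean fluorescence intensity (MFI) per frame.
#' If the cell is lost (no overlapping component), the series is truncated
#' and flagged via the `"truncated"` attribute.
#'
#' @param stack Numeric array height x width x frames.
#' @param pixel_size_um Pixel size, um.
#' @param method,sigma_px,min_area_um2 Passed to [segment_cells()].
#' @return Data.frame `frame` (0-based), `area_um2`, `mfi`; attribute
#'   `"truncated"` TRUE if the cell was lost before the last frame.
#' @export
area_timeseries <- function(stack, pixel_size_um, method = "otsu",
                            sigma_px = 2, min_area_um2 = 1) {
  stopifnot(length(dim(stack)) == 3L)
  nf <- dim(stack)[3]
  prev <- NULL
  rows <- list()
  truncated <- FALSE
  for (f in seq_len(nf)) {
    img <- stack[, , f]
    lab <- segment_cells(img, pixel_size_um, method = method,
                         sigma_px = sigma_px, min_area_um2 = min_area_um2)
    if (max(lab) == 0) { truncated <- TRUE; break }
    if (is.null(prev)) {
      pick <- which.max(tabulate(lab[lab > 0], nbins = max(lab)))
    } else {
      ov <- tabulate(lab[prev & lab > 0], nbins = max(lab))
      if (!length(ov) || max(ov) == 0) { truncated <- TRUE; break }
      pick <- which.max(ov)
    }
    mask <- lab == pick
    prev <- mask
    rows[[f]] <- data.frame(frame = f - 1L,
                            area_um2 = sum(mask) * pixel_size_um^2,
                            mfi = mean(img[mask]))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), area_um2 = numeric(), mfi = numeric())
  attr(out, "truncated") <- truncated || nrow(out) < nf
  out
}

# geodesic distance within a binary component from a set of source pixels,
# 8-connected chamfer propagation iterated to convergence
.geodesic_dist <- function(comp, src) {
  d <- matrix(Inf, nrow(comp), ncol(comp))
  d[src] <- 0
  d[!comp] <- NA
  h <- nrow(comp); w <- ncol(comp)
  steps <- list(c(-1, 0, 1), c(1, 0, 1), c(0, -1, 1), c(0, 1, 1),
                c(-1, -1, sqrt(2)), c(-1, 1, sqrt(2)),
                c(1, -1, sqrt(2)), c(1, 1, sqrt(2)))
  repeat {
    changed <- FALSE
    for (s in steps) {
      rs <- max(1, 1 + s[1]):min(h, h + s[1])
      rt <- rs - s[1]
      cs <- max(1, 1 + s[2]):min(w, w + s[2])
      ct <- cs - s[2]
      cand <- d[rs, cs, drop = FALSE] + s[3]
      cur <- d[rt, ct, drop = FALSE]
      upd <- !is.na(cur) & !is.na(cand) & cand < cur - 1e-9
      if (any(upd)) {
        cur[upd] <- cand[upd]
        d[rt, ct] <- cur
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  d
}

#' Detect protrusions (filopodia-like extensions) on a binary cell shape
#'
#' Morphological opening with a disc of radius `core_fraction` times the
#' shape's equivalent radius defines the cell core; connected components of
#' the difference that touch the core are protrusions. Each protrusion's
#' length is the geodesic distance from its base (pixels adjacent to the
#' core) to its farthest pixel, in um; protrusions shorter than
#' `min_length_um` are not reported.
#'
#' @param mask Logical/numeric matrix of one cell (nonzero = cell).
#' @param pixel_size_um Pixel size, um.
#' @param core_fraction Opening radius as a fraction of the equivalent
#'   radius. Default 0.6.
#' @param min_length_um Minimum reported protrusion length. Default 0.3 um.
#' @return Data.frame: `protrusion_id`, `base_x_um`, `base_y_um`, `tip_x_um`,
#'   `tip_y_um`, `length_um`.
#' @export
detect_protrusions <- function(mask, pixel_size_um, core_fraction = 0.6,
                               min_length_um = 0.3) {
  mask <- mask > 0
  stopifnot(any(mask), pixel_size_um > 0)
  r_eq <- sqrt(sum(mask) / pi)
  r_core <- max(1L, round(core_fraction * r_eq))
  brush <- EBImage::makeBrush(2L * r_core + 1L, shape = "disc")
  core <- as.matrix(EBImage::opening(mask * 1, brush)) > 0
  diffm <- mask & !core
  if (!any(diffm)) return(.empty_protrusions())
  lab <- matrix(as.integer(EBImage::bwlabel(diffm)), nrow(mask), ncol(mask))
  core_dil <- as.matrix(EBImage::dilate(core * 1, EBImage::makeBrush(3, "box"))) > 0
  ps <- pixel_size_um
  rows <- list()
  pid <- 0L
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    base <- comp & core_dil
    if (!any(base)) next # not attached to the core
    d <- .geodesic_dist(comp, base)
    finite <- which(is.finite(d) & comp, arr.ind = TRUE)
    if (!nrow(finite)) next
    vals <- d[cbind(finite[, 1], finite[, 2])]
    tip <- finite[which.max(vals), ]
    len <- max(vals) * ps
    if (len < min_length_um) next
    bidx <- which(base, arr.ind = TRUE)
    bc <- colMeans(bidx)
    pid <- pid + 1L
    rows[[pid]] <- data.frame(
      protrusion_id = pid,
      base_x_um = (bc[2] - 1) * ps, base_y_um = (bc[1] - 1) * ps,
      tip_x_um = (tip[2] - 1) * ps, tip_y_um = (tip[1] - 1) * ps,
      length_um = len)
  }
  if (!length(rows)) return(.empty_protrusions())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_protrusions <- function() {
  data.frame(protrusion_id = integer(), base_x_um = numeric(),
             base_y_um = numeric(), tip_x_um = numeric(), tip_y_um = numeric(),
             length_um = numeric())
}
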