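#' Circle/ring compartment geometry
#'
#' High-content compartmental analysis scores each cell in two regions
#' derived from its segmented nucleus: a \emph{circle} obtained by eroding
#' the nucleus by \code{inner_offset} px (so the measurement avoids the
#' nuclear rim and any cytoplasmic overlap), and a \emph{ring}, the annulus
#' between \code{ring_inner} and \code{ring_outer} px outside the nuclear
#' edge, sampling perinuclear cytoplasm. Defaults follow the standard
#' circle \code{x = -4} / ring \code{1..8} px configuration.
#'
#' @param inner_offset erosion of the nucleus in px (>= 0).
#' @param ring_inner,ring_outer annulus bounds in px outside the nuclear
#'   edge; \code{0 < ring_inner < ring_outer}.
#' @export
compartment_geometry <- function(inner_offset = 4, ring_inner = 1,
                                 ring_outer = 8) {
  if (inner_offset < 0) stop("inner_offset must be >= 0")
  if (!(ring_inner > 0 && ring_inner < ring_outer))
    stop("need 0 < ring_inner < ring_outer")
  structure(list(inner_offset = inner_offset, ring_inner = ring_inner,
                 ring_outer = ring_outer), class = "compartment_geometry")
}

#' Isodata (iterative intermeans) threshold
#'
#' Starting from the midpoint of the data range, iterates
#' \code{t <- (mean(x[x <= t]) + mean(x[x > t])) / 2} until the threshold
#' stabilizes: at convergence the threshold equals the mean of the two
#' class means.
#'
#' @param x numeric vector or matrix of intensities.
#' @param tol convergence tolerance on the threshold.
#' @param max_iter iteration cap.
#' @return the converged threshold (scalar). For a constant input the
#'   input value itself is returned, so that strict thresholding selects
#'   nothing.
#' @export
isodata_threshold <- function(x, tol = 1e-6, max_iter = 500) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no finite values")
  r <- range(x)
  if (diff(r) < .Machine$double.eps) return(r[1])
  t <- mean(r)
  for (i in seq_len(max_iter)) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (length(lo) == 0 || length(hi) == 0) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < tol) return(t_new)
    t <- t_new
  }
  t
}

#' Segment nuclei from a nuclear-stain channel
#'
#' Background is estimated by a morphological (grayscale) opening with a
#' disc of radius \code{background_radius} and subtracted; the residual is
#' thresholded with the isodata algorithm; connected components are
#' labelled and components below the minimum-area floor (a disk of radius
#' 3 px by default, well below any plausible nucleus) are discarded.
#'
#' @param nuclear_channel non-negative intensity matrix.
#' @param background_radius radius of the opening structuring element, px.
#' @param min_area minimum component area in px; default \code{pi * 3^2}.
#' @return integer label matrix (0 = background, labels 1..n).
#' @export
segment_nuclei <- function(nuclear_channel, background_radius = 15,
                           min_area = NULL) {
  x <- as.matrix(nuclear_channel)
  if (any(x < 0)) stop("nuclear channel must be non-negative")
  if (is.null(min_area)) min_area <- pi * 3^2
  if (diff(range(x)) < .Machine$double.eps)
    return(matrix(0L, nrow(x), ncol(x)))
  brush <- EBImage::makeBrush(2 * background_radius + 1, shape = "disc")
  bg <- EBImage::opening(x, brush)
  sub <- pmax(x - bg, 0)
  th <- isodata_threshold(sub)
  mask <- sub > th
  if (!any(mask)) return(matrix(0L, nrow(x), ncol(x)))
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  out <- matrix(0L, nrow(x), ncol(x))
  if (length(keep) > 0) {
    remap <- integer(length(areas))
    remap[keep] <- seq_along(keep)
    nz <- lab > 0
    out[nz] <- remap[lab[nz]]
  }
  out
}

crop_box <- function(mask_idx, dims, pad) {
  rc <- arrayInd(mask_idx, dims)
  list(r = max(1, min(rc[, 1]) - pad):min(dims[1], max(rc[, 1]) + pad),
       c = max(1, min(rc[, 2]) - pad):min(dims[2], max(rc[, 2]) + pad))
}

#' Build per-nucleus circle and ring compartment masks
#'
#' For each label: the circle is the nucleus eroded by
#' \code{inner_offset} px; the ring is the region between the
#' \code{ring_inner}- and \code{ring_outer}-px dilations of the nucleus,
#' clipped at the image border. Every nucleus and the
#' \code{ring_inner}-px boundary band around \emph{any} nucleus are
#' excluded from all rings (those pixels are rim-contaminated no matter
#' which cell they would be credited to). Pixels contested by the rings
#' of several nuclei are assigned to the nucleus nearest in Euclidean
#' distance, ties going to the lower label id. Nuclei too small to
#' survive the erosion get an empty circle and are flagged.
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param geom a [compartment_geometry()].
#' @return list with integer matrices \code{circle} and \code{ring}
#'   (labelled like \code{labels}) and \code{empty_circle}, the ids whose
#'   circle vanished.
#' @export
build_compartments <- function(labels, geom = compartment_geometry()) {
  labels <- as.matrix(labels)
  dims <- dim(labels)
  n_lab <- max(labels)
  circle <- matrix(0L, dims[1], dims[2])
  ring <- matrix(0L, dims[1], dims[2])
  if (n_lab == 0)
    return(list(circle = circle, ring = ring, empty_circle = integer()))
  ring_dist <- matrix(Inf, dims[1], dims[2])
  any_nuc <- labels > 0
  excl <- EBImage::dilate(any_nuc * 1,
                          EBImage::makeBrush(2 * geom$ring_inner + 1,
                                             shape = "disc")) > 0
  er_brush <- if (geom$inner_offset > 0)
    EBImage::makeBrush(2 * geom$inner_offset + 1, shape = "disc")
  out_brush <- EBImage::makeBrush(2 * geom$ring_outer + 1, shape = "disc")
  empty <- integer()
  for (i in seq_len(n_lab)) {
    idx <- which(labels == i)
    box <- crop_box(idx, dims, geom$ring_outer + 1)
    sub <- (labels[box$r, box$c] == i) * 1
    circ <- if (is.null(er_brush)) sub else EBImage::erode(sub, er_brush)
    if (!any(circ > 0)) empty <- c(empty, i)
    cl <- circle[box$r, box$c]
    cl[circ > 0] <- i
    circle[box$r, box$c] <- cl
    dil_out <- EBImage::dilate(sub, out_brush)
    rmask <- dil_out > 0 & !excl[box$r, box$c]
    if (any(rmask)) {
      dmap <- EBImage::distmap(1 - sub)  # distance to this nucleus
      rd <- ring_dist[box$r, box$c]
      rl <- ring[box$r, box$c]
      win <- rmask & dmap < rd           # strict: ties keep the lower id
      rl[win] <- i
      rd[win] <- dmap[win]
      ring[box$r, box$c] <- rl
      ring_dist[box$r, box$c] <- rd
    }
  }
  list(circle = circle, ring = ring, empty_circle = empty)
}

#' Measure per-cell compartment intensities
#'
#' Segments the nuclear channel, builds circle/ring compartments and
#' returns the mean and total marker intensity in each compartment for
#' every cell. This is the shared measurement step behind both negative
#' control calibration and scoring.
#'
#' @param image an \code{image_bundle} (or a list with
#'   \code{nuclear_channel} and \code{marker_channel} matrices).
#' @param geom a [compartment_geometry()].
#' @param background_radius passed to [segment_nuclei()].
#' @return data.frame: id, cx, cy (label centroid, px), circle/ring areas,
#'   means and totals.
#' @export
measure_compartments <- function(image, geom = compartment_geometry(),
                                 background_radius = 15) {
  labels <- segment_nuclei(image$nuclear_channel, background_radius)
  comp <- build_compartments(labels, geom)
  n_lab <- max(labels)
  if (n_lab == 0)
    return(data.frame(id = integer(), cx = numeric(), cy = numeric(),
                      circle_area = numeric(), ring_area = numeric(),
                      circle_mean = numeric(), ring_mean = numeric(),
                      circle_total = numeric(), ring_total = numeric()))
  m <- image$marker_channel
  stat_by <- function(mask) {
    tot <- rep(0, n_lab); area <- rep(0, n_lab)
    nz <- mask > 0
    if (any(nz)) {
      tot_t <- tapply(m[nz], mask[nz], sum)
      area_t <- tapply(m[nz], mask[nz], length)
      ids <- as.integer(names(tot_t))
      tot[ids] <- tot_t; area[ids] <- area_t
    }
    list(total = tot, area = area, mean = ifelse(area > 0, tot / area, NA_real_))
  }
  circ <- stat_by(comp$circle)
  ring <- stat_by(comp$ring)
  nz <- labels > 0
  rows <- row(labels)[nz]; cols <- col(labels)[nz]; labs <- labels[nz]
  cx <- tapply(cols, labs, mean)[as.character(seq_len(n_lab))]
  cy <- tapply(rows, labs, mean)[as.character(seq_len(n_lab))]
  data.frame(id = seq_len(n_lab), cx = as.numeric(cx), cy = as.numeric(cy),
             circle_area = circ$area, ring_area = ring$area,
             circle_mean = circ$mean, ring_mean = ring$mean,
             circle_total = circ$total, ring_total = ring$total)
}

#' Calibrate positivity limits from a negative control
#'
#' Sets the circle and ring fluorescence limits to the maximum observed in
#' the negative-control cells, so that by construction no negative cell
#' scores positive at the calibrated limits.
#'
#' @param neg_cells per-cell table from [measure_compartments()] run on a
#'   preparation with no marker expression.
#' @param statistic which per-cell statistic the limits apply to.
#' @return list of class \code{limits}: \code{circle_limit},
#'   \code{ring_limit}, \code{statistic}.
#' @export
calibrate_limits <- function(neg_cells, statistic = c("mean", "total")) {
  statistic <- match.arg(statistic)
  if (is.null(neg_cells) || nrow(neg_cells) == 0)
    stop("calibration requires at least one negative-control cell")
  cols <- paste0(c("circle_", "ring_"), statistic)
  structure(list(circle_limit = max(neg_cells[[cols[1]]], na.rm = TRUE),
                 ring_limit = max(neg_cells[[cols[2]]], na.rm = TRUE),
                 statistic = statistic),
            class = "limits")
}

#' Score nuclear and cytoplasmic marker positivity per cell
#'
#' Runs the compartmental analysis and applies the calibrated limits: a
#' cell is nuclear-positive when its circle statistic exceeds
#' \code{circle_limit} and cytoplasmic-positive when its ring statistic
#' exceeds \code{ring_limit}. Since every marker-expressing cell shows
#' cytoplasmic signal, the cytoplasmic-positive count doubles as the total
#' number of expressing cells, and
#' \code{percent_nuclear = 100 * nuclear_positive / cytoplasmic_positive}.
#'
#' @param image an \code{image_bundle}.
#' @param limits a [calibrate_limits()] result.
#' @param geom a [compartment_geometry()].
#' @param background_radius passed to [segment_nuclei()].
#' @return list of class \code{quant_summary}: \code{cells} (per-cell
#'   table with positivity calls) and \code{summary} (total_cells,
#'   cytoplasmic_positive, nuclear_positive, percent_nuclear; the percent
#'   is NA with a warning when no cell is cytoplasmic-positive).
#' @export
quantify_localization <- function(image, limits,
                                  geom = compartment_geometry(),
                                  background_radius = 15) {
  stopifnot(inherits(limits, "limits"))
  cells <- measure_compartments(image, geom, background_radius)
  cols <- paste0(c("circle_", "ring_"), limits$statistic)
  cells$nuclear_positive <- !is.na(cells[[cols[1]]]) &
    cells[[cols[1]]] > limits$circle_limit
  cells$cytoplasmic_positive <- !is.na(cells[[cols[2]]]) &
    cells[[cols[2]]] > limits$ring_limit
  n_nuc <- sum(cells$nuclear_positive)
  n_cyt <- sum(cells$cytoplasmic_positive)
  pct <- if (n_cyt > 0) 100 * n_nuc / n_cyt else {
    warning("no cytoplasmic-positive cells: percent_nuclear undefined")
    NA_real_
  }
  structure(list(cells = cells,
                 summary = list(total_cells = nrow(cells),
                                cytoplasmic_positive = n_cyt,
                                nuclear_positive = n_nuc,
                                percent_nuclear = pct)),
            class = "quant_summary")
}

#' @export
print.quant_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "quant_summary: %d nuclei, %d cytoplasmic+, %d nuclear+, percent nuclear = %s\n",
    s$total_cells, s$cytoplasmic_positive, s$nuclear_positive,
    ifelse(is.na(s$percent_nuclear), "NA", sprintf("%.1f", s$percent_nuclear))))
  invisible(x)
}
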