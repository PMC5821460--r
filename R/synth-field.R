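#' Generate a synthetic 2-D cell field with optional daughter-cell pairs
#'
#' Emulates the spatial structure seen in fixed fields of L1-expressing
#' cells: most cells are scattered at random, while a fraction of the
#' nuclear-ORF1p-positive cells sit as post-mitotic daughter pairs in close
#' proximity. Non-paired cells are placed uniformly at random in the
#' \code{width x height} window; paired cells are placed as two points
#' around a uniformly random centre, separated by a truncated-normal
#' distance, both members nuclear-positive.
#'
#' @param n_cells total number of cells (>= 0).
#' @param frac_nuclear expected fraction of nuclear-positive cells
#'   (default 0.26, the typical fraction of cells showing nuclear ORF1p).
#' @param frac_paired fraction of nuclear-positive cells arranged as
#'   daughter pairs.
#' @param pair_sep_mean,pair_sep_sd mean and sd of the within-pair
#'   separation, micrometres (truncated at > 0).
#' @param width,height field dimensions, micrometres.
#' @param seed integer seed.
#' @return An object of class \code{cell_field}: a list with \code{cells}
#'   (data.frame: id, x, y, nuclear_positive, pair_id), \code{width},
#'   \code{height} and a \code{params} attribute echoing the call.
#' @examples
#' f <- gen_cell_field(200, frac_nuclear = 0.2, frac_paired = 0.8, seed = 3)
#' table(f$cells$nuclear_positive)
#' @export
gen_cell_field <- function(n_cells, frac_nuclear = 0.26, frac_paired = 0,
                           pair_sep_mean = 15, pair_sep_sd = 5,
                           width = 1000, height = 1000, seed = 1) {
  if (n_cells < 0 || width <= 0 || height <= 0)
    stop("n_cells must be >= 0 and field dimensions positive")
  if (frac_nuclear < 0 || frac_nuclear > 1 || frac_paired < 0 || frac_paired > 1)
    stop("frac_nuclear and frac_paired must be fractions in [0, 1]")
  cells <- withr::with_seed(seed, {
    n_nuc <- stats::rbinom(1, n_cells, frac_nuclear)
    n_pairs <- floor(frac_paired * n_nuc / 2)
    n_free <- n_cells - 2 * n_pairs
    x <- stats::runif(n_free, 0, width)
    y <- stats::runif(n_free, 0, height)
    nuc <- c(rep(TRUE, n_nuc - 2 * n_pairs), rep(FALSE, n_free - (n_nuc - 2 * n_pairs)))
    pair_id <- rep(NA_integer_, n_free)
    if (n_pairs > 0) {
      px <- py <- qx <- qy <- numeric(n_pairs)
      for (i in seq_len(n_pairs)) {
        repeat {
          sep <- stats::rnorm(1, pair_sep_mean, pair_sep_sd)
          if (sep > 0) break
        }
        repeat {
          cx <- stats::runif(1, 0, width); cy <- stats::runif(1, 0, height)
          th <- stats::runif(1, 0, 2 * pi)
          dx <- cos(th) * sep / 2; dy <- sin(th) * sep / 2
          if (cx - abs(dx) >= 0 && cx + abs(dx) <= width &&
              cy - abs(dy) >= 0 && cy + abs(dy) <= height) break
        }
        px[i] <- cx - dx; py[i] <- cy - dy
        qx[i] <- cx + dx; qy[i] <- cy + dy
      }
      x <- c(x, as.vector(rbind(px, qx)))
      y <- c(y, as.vector(rbind(py, qy)))
      nuc <- c(nuc, rep(TRUE, 2 * n_pairs))
      pair_id <- c(pair_id, rep(seq_len(n_pairs), each = 2))
    }
    if (n_cells > 0) {
      ord <- sample.int(n_cells)  # shuffle so ids carry no structure
      data.frame(id = seq_len(n_cells), x = x[ord], y = y[ord],
                 nuclear_positive = nuc[ord], pair_id = pair_id[ord])
    } else {
      data.frame(id = integer(), x = numeric(), y = numeric(),
                 nuclear_positive = logical(), pair_id = integer())
    }
  })
  structure(list(cells = cells, width = width, height = height),
            params = list(n_cells = n_cells, frac_nuclear = frac_nuclear,
                          frac_paired = frac_paired,
                          pair_sep_mean = pair_sep_mean,
                          pair_sep_sd = pair_sep_sd, seed = seed),
            class = "cell_field")
}

#' @export
print.cell_field <- function(x, ...) {
  cat(sprintf("cell_field: %d cells (%d nuclear-positive) in %g x %g um\n",
              nrow(x$cells), sum(x$cells$nuclear_positive), x$width, x$height))
  invisible(x)
}

#' Intensity parameters for the synthetic two-channel image generator
#'
#' @param nuclear_marker_mean marker intensity added over the nuclear disk
#'   of nuclear-positive cells (a.u.).
#' @param cyto_marker_mean marker intensity added over the cytoplasmic
#'   annulus of every cell (a.u.).
#' @param background constant background added to both channels (a.u.).
#' @param noise_sd sd of the additive Gaussian read noise (a.u.).
#' @param nuclear_dye intensity of the nuclear-stain disk in the nuclear
#'   channel (a.u.).
#' @param cyto_width width of the cytoplasmic annulus, px.
#' @export
image_intensity_params <- function(nuclear_marker_mean = 800,
                                   cyto_marker_mean = 500,
                                   background = 100, noise_sd = 20,
                                   nuclear_dye = 1000, cyto_width = 8) {
  p <- list(nuclear_marker_mean = nuclear_marker_mean,
            cyto_marker_mean = cyto_marker_mean, background = background,
            noise_sd = noise_sd, nuclear_dye = nuclear_dye,
            cyto_width = cyto_width)
  if (any(unlist(p) < 0)) stop("intensity parameters must be non-negative")
  p
}

disk_offsets <- function(r) {
  d <- expand.grid(dx = -r:r, dy = -r:r)
  d[d$dx^2 + d$dy^2 <= r^2, ]
}

#' Render a cell field as a two-channel synthetic microscopy image
#'
#' Stand-in for fixed, stained high-content imaging fields: the nuclear
#' channel holds bright disks (nuclear stain) on a dark background; the
#' marker channel holds a cytoplasmic annulus for every cell plus a nuclear
#' disk only for nuclear-positive cells. Additive Gaussian noise is applied
#' to both channels and a ground-truth table is returned alongside.
#' Nucleus overlap is resolved by a bounded push-apart relaxation; a field
#' too dense to separate raises an error.
#'
#' @param field a [gen_cell_field()] result.
#' @param pixel_size micrometres per pixel (> 0).
#' @param nucleus_radius nucleus radius in px (>= 2).
#' @param intensity an [image_intensity_params()] list.
#' @param seed integer seed for the noise.
#' @param max_iter maximum relaxation sweeps before giving up on placement.
#' @return Object of class \code{image_bundle}: list with
#'   \code{nuclear_channel} and \code{marker_channel} (matrices, a.u.),
#'   \code{pixel_size}, and \code{truth} (per-cell table with centroids in
#'   px, nucleus radius and the noise-free compartment means).
#' @export
gen_image <- function(field, pixel_size = 1, nucleus_radius = 6,
                      intensity = image_intensity_params(), seed = 1,
                      max_iter = 200) {
  stopifnot(inherits(field, "cell_field"))
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (nucleus_radius < 2) stop("nucleus_radius must be >= 2 px")
  W <- max(ceiling(field$width / pixel_size), 2 * nucleus_radius + 2)
  H <- max(ceiling(field$height / pixel_size), 2 * nucleus_radius + 2)
  cells <- field$cells
  n <- nrow(cells)
  r_out <- nucleus_radius + intensity$cyto_width
  cx <- pmin(pmax(cells$x / pixel_size, r_out + 1), W - r_out)
  cy <- pmin(pmax(cells$y / pixel_size, r_out + 1), H - r_out)
  # push-apart relaxation: keep each cell's cytoplasmic annulus clear of
  # every other cell's nuclear interior (annulus reaches d < 2r + cyto_w - 4)
  min_sep <- 2 * nucleus_radius + 6
  if (n > 1) {
    for (it in seq_len(max_iter)) {
      d <- as.matrix(stats::dist(cbind(cx, cy)))
      diag(d) <- Inf
      bad <- which(d < min_sep, arr.ind = TRUE)
      bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
      if (nrow(bad) == 0) break
      for (k in seq_len(nrow(bad))) {
        i <- bad[k, 1]; j <- bad[k, 2]
        dx <- cx[j] - cx[i]; dy <- cy[j] - cy[i]
        cur <- sqrt(dx^2 + dy^2)
        if (cur < 1e-9) { dx <- 1; dy <- 0; cur <- 1 }
        push <- (min_sep - cur) / 2 + 0.5
        cx[i] <- cx[i] - dx / cur * push; cy[i] <- cy[i] - dy / cur * push
        cx[j] <- cx[j] + dx / cur * push; cy[j] <- cy[j] + dy / cur * push
      }
      cx <- pmin(pmax(cx, r_out + 1), W - r_out)
      cy <- pmin(pmax(cy, r_out + 1), H - r_out)
      if (it == max_iter) stop("field too dense: could not place non-overlapping nuclei")
    }
  }
  nuc_ch <- matrix(intensity$background, nrow = H, ncol = W)
  mrk_ch <- matrix(intensity$background, nrow = H, ncol = W)
  disk <- disk_offsets(nucleus_radius)
  ann_all <- disk_offsets(r_out)
  ann <- ann_all[ann_all$dx^2 + ann_all$dy^2 > nucleus_radius^2, ]
  px <- round(cx); py <- round(cy)
  for (i in seq_len(n)) {
    di <- cbind(py[i] + disk$dy, px[i] + disk$dx)
    nuc_ch[di] <- nuc_ch[di] + intensity$nuclear_dye
    ai <- cbind(py[i] + ann$dy, px[i] + ann$dx)
    ai <- ai[ai[, 1] >= 1 & ai[, 1] <= H & ai[, 2] >= 1 & ai[, 2] <= W, , drop = FALSE]
    mrk_ch[ai] <- mrk_ch[ai] + intensity$cyto_marker_mean
    if (n > 0 && cells$nuclear_positive[i])
      mrk_ch[di] <- mrk_ch[di] + intensity$nuclear_marker_mean
  }
  if (intensity$noise_sd > 0) {
    withr::with_seed(seed, {
      nuc_ch <- nuc_ch + matrix(stats::rnorm(H * W, 0, intensity$noise_sd), H, W)
      mrk_ch <- mrk_ch + matrix(stats::rnorm(H * W, 0, intensity$noise_sd), H, W)
    })
    nuc_ch <- pmax(nuc_ch, 0)
    mrk_ch <- pmax(mrk_ch, 0)
  }
  truth <- data.frame(
    id = cells$id, cx = px, cy = py,
    nucleus_radius = rep(nucleus_radius, n),
    nuclear_positive = cells$nuclear_positive,
    nuclear_marker_mean = intensity$background +
      ifelse(cells$nuclear_positive, intensity$nuclear_marker_mean, 0),
    cytoplasm_marker_mean = rep(intensity$background +
                                  intensity$cyto_marker_mean, n))
  structure(list(nuclear_channel = nuc_ch, marker_channel = mrk_ch,
                 pixel_size = pixel_size, truth = truth),
            params = c(intensity, list(nucleus_radius = nucleus_radius,
                                       pixel_size = pixel_size, seed = seed)),
            class = "image_bundle")
}

#' @export
print.image_bundle <- function(x, ...) {
  cat(sprintf("image_bundle: %d x %d px (%g um/px), %d cells\n",
              nrow(x$nuclear_channel), ncol(x$nuclear_channel),
              x$pixel_size, nrow(x$truth)))
  invisible(x)
}
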