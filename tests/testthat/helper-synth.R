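# shared helpers: brute-force oracles and fixture builders

# O(n^2) nearest-neighbour oracle
brute_nn <- function(xy) {
  n <- nrow(xy)
  vapply(seq_len(n), function(i) {
    min(sqrt((xy[i, 1] - xy[-i, 1])^2 + (xy[i, 2] - xy[-i, 2])^2))
  }, numeric(1))
}

# brute-force isodata iteration
brute_isodata <- function(x, iters = 200) {
  t <- mean(range(x))
  for (i in seq_len(iters)) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) break
    t <- (mean(lo) + mean(hi)) / 2
  }
  t
}

# a negative-control calibration from several marker-free fields,
# mirroring a multi-field no-induction preparation
make_negative_limits <- function(n_fields = 3, n_cells = 50, width = 400,
                                 height = 400, seed = 9000,
                                 geom = compartment_geometry()) {
  neg_int <- image_intensity_params(nuclear_marker_mean = 0,
                                    cyto_marker_mean = 0)
  tabs <- lapply(seq_len(n_fields), function(i) {
    f <- gen_cell_field(n_cells, frac_nuclear = 0, width = width,
                        height = height, seed = seed + i)
    measure_compartments(gen_image(f, intensity = neg_int, seed = seed + 100 + i),
                         geom)
  })
  calibrate_limits(do.call(rbind, tabs))
}

# random valid phase fractions
random_fractions <- function() {
  f <- stats::runif(3)
  f <- f / sum(f)
  phase_fractions(f[1], f[2], f[3])
}
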