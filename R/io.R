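#' Read and write the package's delimited table formats
#'
#' Cell fields, flow-cytometry event tables and peptide tables serialize
#' to CSV with a header row; a YAML sidecar (\code{<path>.yaml}) records
#' the generating parameters and seed whenever they are known.
#' Image bundles serialize to one 16-bit TIFF per channel plus a CSV
#' ground-truth table.
#'
#' @param field,facs,tab,bundle objects to serialize.
#' @param path output file path (CSV for tables; a path prefix for image
#'   bundles, which write \code{<path>_nuclear.tif},
#'   \code{<path>_marker.tif} and \code{<path>_truth.csv}).
#' @param max_intensity intensity mapped to the top of the 16-bit range.
#' @name l1cycle-io
NULL

write_sidecar <- function(obj, path) {
  p <- attr(obj, "params")
  if (!is.null(p)) yaml::write_yaml(p, paste0(path, ".yaml"))
}

#' @rdname l1cycle-io
#' @export
write_cell_field <- function(field, path) {
  stopifnot(inherits(field, "cell_field"))
  df <- field$cells
  df$x <- round(df$x, 3); df$y <- round(df$y, 3)
  utils::write.csv(df, path, row.names = FALSE)
  write_sidecar(field, path)
  invisible(path)
}

#' @rdname l1cycle-io
#' @param width,height field dimensions when reading a bare CSV.
#' @export
read_cell_field <- function(path, width = NULL, height = NULL) {
  df <- utils::read.csv(path)
  need <- c("id", "x", "y", "nuclear_positive")
  if (!all(need %in% names(df)))
    stop("cell-field CSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$pair_id)) df$pair_id <- NA_integer_
  df$nuclear_positive <- as.logical(df$nuclear_positive)
  structure(list(cells = df,
                 width = if (is.null(width)) max(df$x, 1) else width,
                 height = if (is.null(height)) max(df$y, 1) else height),
            class = "cell_field")
}

#' @rdname l1cycle-io
#' @export
write_facs_table <- function(facs, path) {
  stopifnot(inherits(facs, "facs_table"))
  utils::write.csv(facs$events, path, row.names = FALSE)
  write_sidecar(facs, path)
  invisible(path)
}

#' @rdname l1cycle-io
#' @export
read_facs_table <- function(path) {
  ev <- utils::read.csv(path)
  if (!all(c("blue", "red", "dna") %in% names(ev)))
    stop("FACS CSV must have columns blue, red, dna")
  if (is.null(ev$true_phase)) ev$true_phase <- NA
  if (is.null(ev$true_event_time)) ev$true_event_time <- NA_real_
  structure(list(events = ev), class = "facs_table")
}

#' @rdname l1cycle-io
#' @export
write_peptide_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname l1cycle-io
#' @param sep field separator; the reader sniffs comma vs tab by default.
#' @export
read_peptide_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (is.null(tab$protein_id)) {
    idcol <- grep("accession|uniprot|protein", names(tab), ignore.case = TRUE)
    if (length(idcol) == 0) stop("no protein id column found")
    names(tab)[idcol[1]] <- "protein_id"
  }
  fill_zero(tab)
}

#' @rdname l1cycle-io
#' @export
write_image_bundle <- function(bundle, path, max_intensity = NULL) {
  stopifnot(inherits(bundle, "image_bundle"))
  if (is.null(max_intensity))
    max_intensity <- max(bundle$nuclear_channel, bundle$marker_channel, 1)
  to16 <- function(m) pmin(pmax(m / max_intensity, 0), 1)
  EBImage::writeImage(to16(t(bundle$nuclear_channel)),
                      paste0(path, "_nuclear.tif"), bits.per.sample = 16)
  EBImage::writeImage(to16(t(bundle$marker_channel)),
                      paste0(path, "_marker.tif"), bits.per.sample = 16)
  utils::write.csv(bundle$truth, paste0(path, "_truth.csv"), row.names = FALSE)
  yaml::write_yaml(c(attr(bundle, "params"),
                     list(max_intensity = max_intensity)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname l1cycle-io
#' @param pixel_size um per px when the sidecar is absent.
#' @export
read_image_bundle <- function(path, pixel_size = 1) {
  sidecar <- paste0(path, ".yaml")
  max_intensity <- 1
  if (file.exists(sidecar)) {
    p <- yaml::read_yaml(sidecar)
    if (!is.null(p$max_intensity)) max_intensity <- p$max_intensity
    if (!is.null(p$pixel_size)) pixel_size <- p$pixel_size
  }
  rd <- function(f) t(as.matrix(EBImage::readImage(f))) * max_intensity
  truth_f <- paste0(path, "_truth.csv")
  structure(list(nuclear_channel = rd(paste0(path, "_nuclear.tif")),
                 marker_channel = rd(paste0(path, "_marker.tif")),
                 pixel_size = pixel_size,
                 truth = if (file.exists(truth_f)) utils::read.csv(truth_f)
                         else NULL),
            class = "image_bundle")
}
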