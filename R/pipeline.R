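#' Run a configured analysis step and write its artifacts
#'
#' Dispatcher behind the command-line interface: takes a configuration
#' (subcommand, parameters, seed, output directory), runs the matching
#' package operation, writes its outputs (CSV/TIFF tables, JSON reports)
#' and echoes the fully resolved configuration as \code{config.yaml} next
#' to them. Identical configurations produce identical outputs.
#'
#' Subcommands: \code{synth_field}, \code{synth_image}, \code{synth_facs},
#' \code{synth_timecourse}, \code{synth_peptides}, \code{quantify},
#' \code{proximity}, \code{deconvolve}, \code{slopes}, \code{ft_estimate},
#' \code{gate}, \code{fucci}, \code{western}, \code{interactome},
#' \code{demo}.
#'
#' @param config list with elements \code{subcommand}, \code{params}
#'   (named list), \code{seed} (integer), \code{outdir}.
#' @return (invisibly) a named list of the paths written.
#' @examples
#' out <- tempfile()
#' run_config(list(subcommand = "synth_field",
#'                 params = list(n_cells = 50), seed = 7, outdir = out))
#' @export
run_config <- function(config) {
  need <- c("subcommand", "outdir")
  if (!all(need %in% names(config)))
    stop("config must contain: ", paste(need, collapse = ", "))
  sub <- config$subcommand
  params <- config$params %||% list()
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  handlers <- list(
    synth_field = h_synth_field, synth_image = h_synth_image,
    synth_facs = h_synth_facs, synth_timecourse = h_synth_timecourse,
    synth_peptides = h_synth_peptides, quantify = h_quantify,
    proximity = h_proximity, deconvolve = h_deconvolve, slopes = h_slopes,
    ft_estimate = h_ft_estimate, gate = h_gate, fucci = h_fucci,
    western = h_western, interactome = h_interactome, demo = h_demo)
  if (is.null(handlers[[sub]]))
    stop("unknown subcommand: ", sub, " (known: ",
         paste(names(handlers), collapse = ", "), ")")
  paths <- tryCatch(handlers[[sub]](params, seed, outdir), error = function(e) {
    stop("subcommand '", sub, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  resolved <- list(subcommand = sub, params = params, seed = seed,
                   outdir = outdir,
                   package_version = as.character(utils::packageVersion("l1cycle")))
  yaml::write_yaml(resolved, file.path(outdir, "config.yaml"))
  invisible(c(paths, config = file.path(outdir, "config.yaml")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

call_with <- function(fn, params, seed = NULL) {
  args <- params[names(params) %in% names(formals(fn))]
  if (!is.null(seed) && "seed" %in% names(formals(fn))) args$seed <- seed
  do.call(fn, args)
}

default_model <- function(params) {
  if (!is.null(params$d_G1))
    cell_cycle_model(params$d_G1, params$d_S, params$d_G2M)
  else hela_cycle_model()
}

h_synth_field <- function(params, seed, outdir) {
  params$n_cells <- params$n_cells %||% 500
  f <- call_with(gen_cell_field, params, seed)
  list(field = write_cell_field(f, file.path(outdir, "field.csv")))
}

h_synth_image <- function(params, seed, outdir) {
  params$n_cells <- params$n_cells %||% 50
  params$width <- params$width %||% 400
  params$height <- params$height %||% 400
  f <- call_with(gen_cell_field, params, seed)
  img <- call_with(gen_image, c(list(field = f), params), seed)
  list(field = write_cell_field(f, file.path(outdir, "field.csv")),
       image = write_image_bundle(img, file.path(outdir, "image")))
}

h_synth_facs <- function(params, seed, outdir) {
  params$n <- params$n %||% 10000
  model <- default_model(params)
  if (!is.null(params$mixture))
    params$mixture <- do.call(phase_fractions,
                              c(as.list(params$mixture), list(normalize = TRUE)))
  f <- call_with(gen_facs_snapshot, c(list(model = model), params), seed)
  list(facs = write_facs_table(f, file.path(outdir, "facs.csv")))
}

h_synth_timecourse <- function(params, seed, outdir) {
  model <- default_model(params)
  params$timepoints <- params$timepoints %||% seq(0, 24, 3)
  params$n_cells <- params$n_cells %||% 10000
  tc <- call_with(gen_timecourse, c(list(model = model), params), seed)
  df <- data.frame(time = tc$timepoints, gfp_percent = tc$gfp_percent)
  p <- file.path(outdir, "timecourse.csv")
  utils::write.csv(df, p, row.names = FALSE)
  utils::write.csv(tc$truth, file.path(outdir, "timecourse_truth.csv"),
                   row.names = FALSE)
  list(timecourse = p)
}

h_synth_peptides <- function(params, seed, outdir) {
  tab <- call_with(gen_peptide_table, params, seed)
  list(peptides = write_peptide_table(tab, file.path(outdir, "peptides.csv")))
}

h_quantify <- function(params, seed, outdir) {
  img <- read_image_bundle(params$input)
  geom <- call_with(compartment_geometry, params)
  limits <- if (!is.null(params$negative_control)) {
    neg <- read_image_bundle(params$negative_control)
    calibrate_limits(measure_compartments(neg, geom))
  } else {
    structure(list(circle_limit = params$circle_limit,
                   ring_limit = params$ring_limit, statistic = "mean"),
              class = "limits")
  }
  q <- quantify_localization(img, limits, geom)
  utils::write.csv(q$cells, file.path(outdir, "cells.csv"), row.names = FALSE)
  jsonlite::write_json(q$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  list(cells = file.path(outdir, "cells.csv"),
       summary = file.path(outdir, "summary.json"))
}

h_proximity <- function(params, seed, outdir) {
  field <- read_cell_field(params$input)
  rep <- proximity_test(field,
                        selection_p = params$selection_p %||% 0.1,
                        n_perm = params$n_perm %||% 1000,
                        null_source = params$null_source %||% "non_nuclear",
                        seed = seed)
  utils::write.csv(cbind(rep$per_cell,
                         selected = seq_len(rep$k) %in% rep$selected),
                   file.path(outdir, "per_cell.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(k = rep$k, n_selected = length(rep$selected),
         ranksum_p = rep$ranksum_p, ranksum_p_all = rep$ranksum_p_all,
         ranksum_p_calibrated = rep$ranksum_p_calibrated,
         null_source = rep$null_source, seed = seed),
    file.path(outdir, "proximity.json"), auto_unbox = TRUE, digits = NA)
  list(per_cell = file.path(outdir, "per_cell.csv"),
       report = file.path(outdir, "proximity.json"))
}

h_deconvolve <- function(params, seed, outdir) {
  facs <- read_facs_table(params$input)
  fit <- deconvolve_dna(facs$events$dna)
  jsonlite::write_json(
    list(fractions = as.list(unclass(fit$fractions)), mu_2n = fit$mu_2n,
         cv = fit$cv, logLik = fit$logLik, converged = fit$converged,
         n_events = fit$n_events),
    file.path(outdir, "dna_fit.json"), auto_unbox = TRUE, digits = NA)
  list(fit = file.path(outdir, "dna_fit.json"))
}

h_slopes <- function(params, seed, outdir) {
  tc <- utils::read.csv(params$input)
  windows <- if (!is.null(params$phase_windows))
    utils::read.csv(params$phase_windows)
  else phase_windows_from_model(default_model(params))
  ss <- slope_analysis(tc[[1]], tc[[2]], windows)
  utils::write.csv(ss$intervals, file.path(outdir, "slopes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(peak_interval = ss$peak_interval,
                            peak_phase = ss$peak_phase, no_peak = ss$no_peak),
                       file.path(outdir, "slopes.json"), auto_unbox = TRUE,
                       digits = NA)
  list(slopes = file.path(outdir, "slopes.csv"))
}

h_ft_estimate <- function(params, seed, outdir) {
  params$n <- params$n %||% 500
  traces <- call_with(gen_ft_traces, params, seed)
  est <- estimate_conversion_time(traces)
  onset <- gen_onset_times(params$n_onset %||% 10000, seed = seed + 1L)
  oq <- onset_quantiles(onset_curve(onset))
  jsonlite::write_json(
    list(conversion_mean_h = est$mean, conversion_sd_h = est$sd,
         n_used = est$n_used, t50_h = oq[["t50"]], t90_h = oq[["t90"]]),
    file.path(outdir, "ft_estimate.json"), auto_unbox = TRUE, digits = NA)
  list(estimate = file.path(outdir, "ft_estimate.json"))
}

h_gate <- function(params, seed, outdir) {
  facs <- read_facs_table(params$input)
  g <- gate_ft(facs, params$blue_threshold %||% "auto",
               params$red_split %||% "median")
  utils::write.csv(cbind(facs$events, gate = as.character(g$labels)),
                   file.path(outdir, "gated.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(blue_threshold = g$blue_threshold, red_threshold = g$red_threshold,
         counts = as.list(table(g$labels))),
    file.path(outdir, "gates.json"), auto_unbox = TRUE, digits = NA)
  list(gated = file.path(outdir, "gated.csv"))
}

h_fucci <- function(params, seed, outdir) {
  cells <- utils::read.csv(params$input)
  fc <- fucci_contingency(as.logical(cells$nuclear_orf1p), cells$nucleus_color)
  jsonlite::write_json(
    list(total = fc$total,
         counts = as.list(stats::setNames(as.vector(fc$table),
                                          outer(rownames(fc$table),
                                                colnames(fc$table),
                                                paste, sep = "_")))),
    file.path(outdir, "fucci.json"), auto_unbox = TRUE, digits = NA)
  list(fucci = file.path(outdir, "fucci.json"))
}

h_western <- function(params, seed, outdir) {
  ws <- utils::read.csv(params$input)
  out <- normalize_westerns(ws[[1]], ws[[2]], ws[[3]])
  p <- file.path(outdir, "western_relative.csv")
  utils::write.csv(out, p, row.names = FALSE)
  list(western = p)
}

h_interactome <- function(params, seed, outdir) {
  tab <- read_peptide_table(params$input)
  rep <- classify_confidence(tab, params$min_unique %||% 2)
  utils::write.csv(rep$proteins, file.path(outdir, "classified.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(class_counts = as.list(rep$class_counts),
         exclusive_counts = as.list(rep$exclusive_counts)),
    file.path(outdir, "interactome.json"), auto_unbox = TRUE, digits = NA)
  list(classified = file.path(outdir, "classified.csv"))
}

# end-to-end demo: field -> image -> calibrate -> quantify -> proximity
h_demo <- function(params, seed, outdir) {
  field <- gen_cell_field(params$n_cells %||% 60,
                          frac_nuclear = params$frac_nuclear %||% 0.3,
                          frac_paired = params$frac_paired %||% 0.7,
                          pair_sep_mean = 15, pair_sep_sd = 5,
                          width = params$width %||% 400,
                          height = params$height %||% 400, seed = seed)
  img <- gen_image(field, seed = seed + 1L)
  neg_field <- gen_cell_field(params$n_cells %||% 60, frac_nuclear = 0,
                              width = params$width %||% 400,
                              height = params$height %||% 400,
                              seed = seed + 2L)
  neg_img <- gen_image(neg_field,
                       intensity = image_intensity_params(
                         nuclear_marker_mean = 0, cyto_marker_mean = 0),
                       seed = seed + 3L)
  geom <- compartment_geometry()
  limits <- calibrate_limits(measure_compartments(neg_img, geom))
  q <- quantify_localization(img, limits, geom)
  prox <- proximity_test(field, seed = seed)
  utils::write.csv(q$cells, file.path(outdir, "cells.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(quantification = q$summary,
         proximity = list(k = prox$k, ranksum_p = prox$ranksum_p,
                          ranksum_p_all = prox$ranksum_p_all)),
    file.path(outdir, "demo.json"), auto_unbox = TRUE, digits = NA)
  list(demo = file.path(outdir, "demo.json"))
}
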