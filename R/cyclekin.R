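#' Deconvolve a DNA-content histogram into G1/S/G2-M fractions
#'
#' Fits a three-part mixture to DNA-stain intensities by maximum
#' likelihood on a binned (multinomial) histogram: a Gaussian at the 2N
#' position (free mean and CV), a Gaussian at 4N with mean constrained to
#' twice the 2N mean, and an S-phase bridge modelled as a fixed number of
#' equal-weight broadened steps between 2N and 4N sharing the same CV
#' (the classic step-decomposition approach to S-phase). Optimization is
#' bounded quasi-Newton with multiple data-derived starts for the 2N
#' position.
#'
#' @param dna numeric vector of DNA-stain intensities (a.u.); at least
#'   ~1000 events are recommended for a stable fit.
#' @param n_steps number of S-phase steps (default 8).
#' @param n_bins histogram bins used for the multinomial likelihood.
#' @param n_restarts bounded restarts over 2N starting positions.
#' @return list of class \code{dna_fit}: \code{fractions}
#'   ([phase_fractions()]), \code{mu_2n}, \code{cv}, \code{logLik},
#'   \code{converged}, \code{n_events}.
#' @examples
#' m <- hela_cycle_model()
#' f <- gen_facs_snapshot(m, n = 20000, event_rule = "fixed_phase_mixture",
#'                        mixture = phase_fractions(0.5, 0.3, 0.2), seed = 1)
#' deconvolve_dna(f$events$dna)$fractions
#' @export
deconvolve_dna <- function(dna, n_steps = 8, n_bins = 256, n_restarts = 4) {
  dna <- dna[is.finite(dna)]
  n <- length(dna)
  if (n == 0) stop("no DNA-content events")
  if (n < 1000)
    warning("fewer than 1000 events: the mixture fit may be unstable")
  if (diff(range(dna)) < sqrt(.Machine$double.eps))
    return(structure(list(fractions = phase_fractions(1, 0, 0),
                          mu_2n = dna[1], cv = 0, logLik = 0,
                          converged = TRUE, n_events = n),
                     class = "dna_fit"))
  br <- seq(min(dna), max(dna), length.out = n_bins + 1)
  counts <- tabulate(findInterval(dna, br, rightmost.closed = TRUE),
                     nbins = n_bins)
  mids <- (br[-1] + br[-(n_bins + 1)]) / 2
  centers <- c(1, 1 + (seq_len(n_steps) - 0.5) / n_steps, 2)  # in units of mu
  comp_of <- c(1L, rep(2L, n_steps), 3L)  # G1, S steps, G2M
  mix_probs <- function(mu, cv, w) {
    cw <- c(w[1], rep(w[2] / n_steps, n_steps), w[3])
    dens <- rowSums(vapply(seq_along(centers), function(j) {
      cw[j] * stats::dnorm(mids, centers[j] * mu, cv * centers[j] * mu)
    }, numeric(length(mids))))
    p <- dens + 1e-12
    p / sum(p)
  }
  nll <- function(par) {
    mu <- exp(par[1]); cv <- exp(par[2])
    ew <- exp(c(par[3], 0, par[4]))
    w <- ew / sum(ew)
    -sum(counts * log(mix_probs(mu, cv, w)))
  }
  med <- stats::median(dna)
  mu_starts <- unique(pmin(pmax(
    c(stats::quantile(dna, 0.005), med, med / 1.5, med / 2),
    0.36 * med), 1.25 * med))[seq_len(min(4, n_restarts))]
  lower <- c(log(0.35 * med), log(0.005), -15, -15)
  upper <- c(log(1.3 * med), log(0.3), 15, 15)
  best <- NULL
  for (mu0 in mu_starts) {
    fit <- try(stats::optim(c(log(mu0), log(0.05), 0, 0), nll,
                            method = "L-BFGS-B", lower = lower, upper = upper,
                            control = list(maxit = 400)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("DNA-content mixture fit failed to converge after restarts")
  mu <- exp(best$par[1]); cv <- exp(best$par[2])
  ew <- exp(c(best$par[3], 0, best$par[4]))
  w <- ew / sum(ew)
  structure(list(fractions = phase_fractions(w[1], w[2], w[3], normalize = TRUE),
                 mu_2n = mu, cv = cv, logLik = -best$value,
                 converged = best$convergence == 0, n_events = n),
            class = "dna_fit")
}

#' @export
print.dna_fit <- function(x, ...) {
  f <- x$fractions
  cat(sprintf(
    "dna_fit: G1 %.1f%% | S %.1f%% | G2/M %.1f%%  (2N at %.1f, CV %.1f%%, n = %d)\n",
    100 * f["G1"], 100 * f["S"], 100 * f["G2M"], x$mu_2n, 100 * x$cv,
    x$n_events))
  invisible(x)
}

#' Cell-cycle phase windows for a synchronized release
#'
#' Wall-clock phase windows of a cohort released from mitosis at time
#' zero: G1 from 0 to d_G1, then S, then G2/M up to the doubling time.
#'
#' @param model a [cell_cycle_model()].
#' @param offset release offset in hours added to all boundaries.
#' @return data.frame with columns \code{phase}, \code{start}, \code{end}.
#' @export
phase_windows_from_model <- function(model, offset = 0) {
  stopifnot(inherits(model, "cell_cycle_model"))
  b <- offset + cumsum(c(0, model$d_G1, model$d_S, model$d_G2M))
  data.frame(phase = c("G1", "S", "G2M"), start = b[1:3], end = b[2:4])
}

#' Slope analysis of a reporter-positive time course
#'
#' Computes forward finite-difference slopes of the percent-positive curve
#' between consecutive timepoints. A linear rise (unbiased
#' retrotransposition) gives flat slopes; a burst concentrated in one
#' cell-cycle stage produces a peak at the interval where most events are
#' detected. The peak interval is the argmax slope; a "no peak" flag is
#' raised when the maximum slope is below \code{peak_ratio} times the
#' median slope. When phase windows are supplied each interval is
#' annotated with the phase occupying the majority of it.
#'
#' @param timepoints strictly increasing measurement times, hours
#'   (>= 3 points).
#' @param gfp_percent percent reporter-positive cells per timepoint.
#' @param phase_windows optional data.frame (phase, start, end), e.g. from
#'   [phase_windows_from_model()] or a PI series.
#' @param peak_ratio no-peak threshold on max/median slope (default 1.5).
#' @return list of class \code{slope_series}: \code{intervals}
#'   (data.frame: t_start, t_end, slope in percent/h, phase),
#'   \code{peak_interval} (c(t_i, t_{i+1})), \code{peak_phase},
#'   \code{no_peak}.
#' @export
slope_analysis <- function(timepoints, gfp_percent, phase_windows = NULL,
                           peak_ratio = 1.5) {
  if (length(timepoints) < 3) stop("need at least 3 timepoints")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (length(gfp_percent) != length(timepoints))
    stop("gfp_percent and timepoints lengths differ")
  slopes <- diff(gfp_percent) / diff(timepoints)
  t1 <- timepoints[-length(timepoints)]
  t2 <- timepoints[-1]
  phase <- rep(NA_character_, length(slopes))
  if (!is.null(phase_windows)) {
    for (i in seq_along(slopes)) {
      ov <- pmin(t2[i], phase_windows$end) - pmax(t1[i], phase_windows$start)
      ov[ov < 0] <- 0
      if (any(ov > 0)) phase[i] <- phase_windows$phase[which.max(ov)]
    }
  }
  peak_i <- which.max(slopes)
  no_peak <- max(slopes) < peak_ratio * stats::median(slopes)
  structure(list(intervals = data.frame(t_start = t1, t_end = t2,
                                        slope = slopes, phase = phase),
                 peak_interval = c(t1[peak_i], t2[peak_i]),
                 peak_phase = phase[peak_i], no_peak = no_peak),
            class = "slope_series")
}

#' Normalize a series to its first value
#'
#' Relative-units convention for treatment time courses: the value at
#' time zero is set to 1.
#'
#' @param values numeric vector; first element must be non-zero.
#' @export
relative_to_t0 <- function(values) {
  if (length(values) == 0 || !is.finite(values[1]) || values[1] == 0)
    stop("first value must be finite and non-zero")
  values / values[1]
}

#' Deterministic fluorescent-timer trace
#'
#' Closed-form blue/red kinetics of the timer. Under \code{constant_burst}
#' a fixed blue pool \code{blue0} decays into red at rate \code{k_mat}:
#' \code{red(t) = blue0 (1 - exp(-k t))}, so the red half-rise (the
#' conversion time) is \code{log(2)/k_mat}. Under
#' \code{ongoing_transcription} blue is replenished at constant rate
#' \code{rate} and the steady state carries both a blue population of
#' young protein and a growing red population of aged protein.
#'
#' @param kin an [ft_kinetics()] object.
#' @param times increasing sample times, hours.
#' @param blue_source production model.
#' @param blue0 initial blue pool (constant burst), a.u.
#' @param rate production rate (ongoing transcription), a.u./h.
#' @return object of class \code{ft_trace}: times, blue, red,
#'   conversion_time (analytic half-rise for the constant burst, NA
#'   otherwise).
#' @export
ft_trace <- function(kin, times,
                     blue_source = c("constant_burst", "ongoing_transcription"),
                     blue0 = 1, rate = 1) {
  stopifnot(inherits(kin, "ft_kinetics"))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  blue_source <- match.arg(blue_source)
  k <- kin$k_mat
  if (blue_source == "constant_burst") {
    blue <- blue0 * exp(-k * times)
    red <- blue0 * (1 - exp(-k * times))
    conv <- log(2) / k
  } else {
    blue <- rate / k * (1 - exp(-k * times))
    red <- rate * times - blue
    conv <- NA_real_
  }
  structure(list(times = times, blue = blue, red = red,
                 conversion_time = conv),
            class = "ft_trace")
}

half_rise_time <- function(times, red, smooth = 3, plateau = NULL) {
  if (smooth > 1 && length(red) >= smooth) {
    red <- as.numeric(stats::filter(red, rep(1 / smooth, smooth), sides = 2))
    ok <- !is.na(red)
    times <- times[ok]; red <- red[ok]
  }
  n <- length(red)
  if (n < 4) return(NA_real_)
  if (is.null(plateau)) {
    tail_idx <- times >= times[1] + 0.8 * (times[n] - times[1])
    plateau <- mean(red[tail_idx])
    # a trace still rising at the end has no plateau to halve
    mid <- red[which.min(abs(times - (times[1] + 0.6 * (times[n] - times[1]))))]
    if (mid <= 0 || plateau > 1.15 * mid) return(NA_real_)
  }
  # plateau must be (nearly) reached, otherwise the trace is still rising
  if (max(red) < 0.8 * plateau || max(red) <= 0) return(NA_real_)
  half <- plateau / 2
  above <- which(red >= half)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  if (i == 1) return(times[1])
  t0 <- times[i - 1]; t1 <- times[i]
  y0 <- red[i - 1]; y1 <- red[i]
  if (y1 == y0) return(t1)
  t0 + (half - y0) / (y1 - y0) * (t1 - t0)
}

trace_plateau <- function(tr) {
  # constant-burst traces conserve the fluorophore pool: red plateau =
  # mean(blue + red). Fall back to the tail mean when blue is absent or
  # still abundant at the end (ongoing production).
  if (!is.null(tr$blue) && utils::tail(tr$blue, 1) < 0.2 * max(tr$blue))
    mean(tr$blue + tr$red)
  else NULL
}

#' Estimate the blue-to-red conversion time from timer traces
#'
#' Per-trace conversion time is the half-rise of the red signal: the first
#' time (linearly interpolated between samples, after a light moving-
#' average smoothing) at which red exceeds half its plateau. Traces whose
#' red signal has not plateaued are excluded and counted in the
#' diagnostics.
#'
#' @param traces list of \code{ft_trace} objects (>= 1; >= 10 recommended).
#' @param smooth moving-average window (samples) applied before crossing
#'   detection; 1 disables smoothing.
#' @return list: \code{mean}, \code{sd}, \code{per_trace} (hours),
#'   \code{n_used}, \code{n_excluded}.
#' @export
estimate_conversion_time <- function(traces, smooth = 3) {
  if (inherits(traces, "ft_trace")) traces <- list(traces)
  if (length(traces) == 0) stop("no traces supplied")
  ct <- vapply(traces,
               function(tr) half_rise_time(tr$times, tr$red, smooth,
                                           plateau = trace_plateau(tr)),
               numeric(1))
  used <- ct[!is.na(ct)]
  if (length(used) == 0) stop("no trace reached a red plateau")
  list(mean = mean(used), sd = if (length(used) > 1) stats::sd(used) else 0,
       per_trace = ct, n_used = length(used), n_excluded = sum(is.na(ct)))
}

#' Onset quantiles of a cumulative fraction-visible curve
#'
#' Linear-interpolated times at which the nondecreasing fraction-visible
#' curve crosses the requested levels (default 50\% and 90\%). A level the
#' curve never reaches yields NA with a warning.
#'
#' @param times increasing time grid, hours.
#' @param fraction nondecreasing fraction visible in \[0, 1\], or a
#'   data.frame from [onset_curve()] as first argument.
#' @param levels crossing levels.
#' @return named numeric vector (t50, t90, ...).
#' @export
onset_quantiles <- function(times, fraction = NULL, levels = c(0.5, 0.9)) {
  if (is.data.frame(times)) { fraction <- times$fraction; times <- times$time }
  if (length(times) != length(fraction)) stop("times/fraction lengths differ")
  if (any(diff(fraction) < -1e-9)) stop("fraction-visible curve must be nondecreasing")
  out <- vapply(levels, function(lv) {
    i <- which(fraction >= lv)[1]
    if (is.na(i)) {
      warning("curve never reaches level ", lv)
      return(NA_real_)
    }
    if (i == 1) return(times[1])
    y0 <- fraction[i - 1]; y1 <- fraction[i]
    if (y1 == y0) return(times[i])
    times[i - 1] + (lv - y0) / (y1 - y0) * (times[i] - times[i - 1])
  }, numeric(1))
  stats::setNames(out, paste0("t", round(100 * levels)))
}

#' Gate fluorescent-timer flow events
#'
#' Partitions events into blue-negative, blue-positive/red-low and
#' blue-positive/red-high. \code{blue_threshold = "auto"} mirrors the
#' negative-control limit rule used in imaging: the threshold is the
#' maximum blue intensity among events with no event
#' (\code{true_event_time} NA). The red low/high split defaults to the
#' median red intensity of the blue-positive events.
#'
#' @param facs a \code{facs_table} from [gen_facs_snapshot()], or a
#'   data.frame with blue/red columns.
#' @param blue_threshold numeric, or \code{"auto"}.
#' @param red_split numeric threshold, or \code{"median"}.
#' @return list of class \code{gate_labels}: \code{labels} (factor per
#'   event), \code{blue_threshold}, \code{red_threshold}.
#' @export
gate_ft <- function(facs, blue_threshold = "auto", red_split = "median") {
  ev <- if (inherits(facs, "facs_table")) facs$events else facs
  if (nrow(ev) == 0) stop("empty event table")
  if (identical(blue_threshold, "auto")) {
    neg <- is.na(ev$true_event_time)
    if (!any(neg)) stop("auto blue threshold needs events without a true event")
    blue_threshold <- max(ev$blue[neg])
  }
  blue_pos <- ev$blue > blue_threshold
  if (!any(blue_pos)) {
    warning("no blue-positive events at this threshold")
    red_threshold <- NA_real_
    labels <- factor(rep("blue_neg", nrow(ev)),
                     levels = c("blue_neg", "blue_pos_red_low", "blue_pos_red_high"))
  } else {
    red_threshold <- if (identical(red_split, "median"))
      stats::median(ev$red[blue_pos]) else red_split
    labels <- factor(ifelse(!blue_pos, "blue_neg",
                            ifelse(ev$red <= red_threshold,
                                   "blue_pos_red_low", "blue_pos_red_high")),
                     levels = c("blue_neg", "blue_pos_red_low", "blue_pos_red_high"))
  }
  structure(list(labels = labels, blue_threshold = blue_threshold,
                 red_threshold = red_threshold), class = "gate_labels")
}

#' Cross-tabulate nuclear marker positivity against cell-cycle indicator colour
#'
#' Builds the 2x2 contingency table of nuclear marker status against the
#' two-colour cell-cycle indicator readout (red nucleus = G1; green
#' nucleus = S/G2/M).
#'
#' @param nuclear_orf1p logical vector.
#' @param nucleus_color character/factor with values "green" or "red".
#' @return list of class \code{fucci_counts}: \code{table} (2x2),
#'   \code{total}.
#' @export
fucci_contingency <- function(nuclear_orf1p, nucleus_color) {
  if (length(nuclear_orf1p) != length(nucleus_color))
    stop("input lengths differ")
  nucleus_color <- as.character(nucleus_color)
  bad <- setdiff(unique(nucleus_color), c("green", "red"))
  if (length(bad) > 0)
    stop("unknown nucleus colour label(s): ", paste(bad, collapse = ", "))
  tab <- table(nuclear_orf1p = factor(nuclear_orf1p, levels = c(FALSE, TRUE)),
               nucleus_color = factor(nucleus_color, levels = c("green", "red")))
  structure(list(table = tab, total = sum(tab)), class = "fucci_counts")
}

#' Normalize western-blot band intensities to a loading control
#'
#' Each timepoint's target intensity is divided by its loading-control
#' (histone H3) intensity and the series is scaled so the relative units
#' at the first timepoint equal 1.
#'
#' @param timepoints measurement times, hours.
#' @param target target-band intensities, a.u.
#' @param loading loading-control intensities, a.u. (> 0).
#' @return data.frame: timepoints, relative_units.
#' @export
normalize_westerns <- function(timepoints, target, loading) {
  if (length(target) != length(loading) || length(target) != length(timepoints))
    stop("timepoints, target and loading must have equal length")
  if (length(target) == 0) stop("need at least one timepoint")
  if (any(loading <= 0)) stop("loading intensities must be positive")
  ratio <- target / loading
  data.frame(timepoints = timepoints, relative_units = ratio / ratio[1])
}
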