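#' Fluorescent-timer reporter kinetics
#'
#' Parameters of the fast fluorescent-timer (fast-FT) reporter model: newly
#' translated protein fluoresces blue and matures into the red form by a
#' first-order process at rate \code{k_mat}, while the delay between
#' transcriptional induction and first visible fluorescence follows a
#' lognormal onset law.
#'
#' Defaults are calibrated to the measured reporter behaviour: the mean
#' blue-to-red conversion time (half-rise of the red signal for a fixed
#' blue pool) is 2.35 h, i.e. \code{k_mat = log(2)/2.35}; the onset law is
#' the lognormal whose cumulative visible-fraction curve crosses 50\% at
#' 2.71 h and 90\% at 8.01 h.
#'
#' @param onset_meanlog,onset_sdlog lognormal parameters of the
#'   expression-onset delay (hours).
#' @param k_mat blue-to-red maturation rate, 1/h (> 0).
#' @param blue_detect,red_detect detection thresholds, a.u. (>= 0).
#' @return list of class \code{ft_kinetics}.
#' @export
ft_kinetics <- function(onset_meanlog = log(2.71),
                        onset_sdlog = log(8.01 / 2.71) / stats::qnorm(0.9),
                        k_mat = log(2) / 2.35,
                        blue_detect = 50, red_detect = 50) {
  if (k_mat <= 0) stop("k_mat must be positive")
  if (blue_detect < 0 || red_detect < 0) stop("detection thresholds must be >= 0")
  structure(list(onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
                 k_mat = k_mat, blue_detect = blue_detect,
                 red_detect = red_detect),
            class = "ft_kinetics")
}

#' Draw expression-onset delays from the reporter onset law
#'
#' @param n number of cells.
#' @param kin an [ft_kinetics()] object.
#' @param seed integer seed.
#' @return numeric vector of onset delays, hours.
#' @export
gen_onset_times <- function(n, kin = ft_kinetics(), seed = 1) {
  stopifnot(inherits(kin, "ft_kinetics"), n >= 0)
  withr::with_seed(seed, stats::rlnorm(n, kin$onset_meanlog, kin$onset_sdlog))
}

#' Cumulative fraction-visible curve from simulated onset delays
#'
#' @param onset_times delays from [gen_onset_times()].
#' @param times evaluation grid (hours); defaults to a fine grid covering
#'   the observed range.
#' @return data.frame with columns \code{time} and \code{fraction}.
#' @export
onset_curve <- function(onset_times, times = NULL) {
  if (length(onset_times) == 0) stop("no onset times supplied")
  if (is.null(times))
    times <- seq(0, max(onset_times) * 1.02, length.out = 4096)
  data.frame(time = times, fraction = stats::ecdf(onset_times)(times))
}

#' Simulate noisy single-cell fluorescent-timer traces
#'
#' Each cell receives a fixed blue pool at time zero (constant-burst model)
#' that matures into red at a per-cell first-order rate. Per-cell
#' conversion times are drawn around the kinetic default
#' (\code{log(2)/k_mat}) with biological spread \code{conv_sd}, and
#' Gaussian measurement noise proportional to the red plateau is added at
#' every sample.
#'
#' @param n number of traces.
#' @param kin an [ft_kinetics()] object; its \code{k_mat} sets the mean
#'   conversion time.
#' @param times sampling grid, hours.
#' @param conv_sd cell-to-cell sd of the conversion time, hours
#'   (default 0.52, the measured spread; truncated at > 0.2 h).
#' @param noise_sd measurement noise as a fraction of the red plateau.
#' @param blue0 size of the initial blue pool, a.u.
#' @param seed integer seed.
#' @return list of \code{ft_trace} objects (see [ft_trace()]), each with a
#'   \code{true_conversion} attribute.
#' @export
gen_ft_traces <- function(n, kin = ft_kinetics(), times = seq(0, 12, 0.25),
                          conv_sd = 0.52, noise_sd = 0.05, blue0 = 1000,
                          seed = 1) {
  stopifnot(inherits(kin, "ft_kinetics"), n >= 1)
  conv_mean <- log(2) / kin$k_mat
  withr::with_seed(seed, {
    conv <- stats::rnorm(n, conv_mean, conv_sd)
    while (any(conv <= 0.2)) {
      bad <- conv <= 0.2
      conv[bad] <- stats::rnorm(sum(bad), conv_mean, conv_sd)
    }
    lapply(seq_len(n), function(i) {
      k <- log(2) / conv[i]
      red <- blue0 * (1 - exp(-k * times)) +
        stats::rnorm(length(times), 0, noise_sd * blue0)
      blue <- blue0 * exp(-k * times) +
        stats::rnorm(length(times), 0, noise_sd * blue0)
      structure(list(times = times, blue = pmax(blue, 0), red = pmax(red, 0),
                     conversion_time = NA_real_),
                true_conversion = conv[i], class = "ft_trace")
    })
  })
}

delay_none <- function() list(dist = "none")
delay_lognormal <- function(meanlog, sdlog) {
  list(dist = "lognormal", meanlog = meanlog, sdlog = sdlog)
}

#' Detection-delay laws for the time-course generator
#'
#' \code{delay_none()} gives instantaneous detection (reporter visible at
#' the retrotransposition event itself); \code{delay_lognormal()} adds a
#' lognormal expression-onset delay; \code{delay_from_kinetics()} takes the
#' onset law of an [ft_kinetics()] object.
#'
#' @param kin an [ft_kinetics()] object.
#' @name detect_delay
#' @aliases delay_none delay_lognormal delay_from_kinetics
#' @export delay_none delay_lognormal
#' @export
delay_from_kinetics <- function(kin = ft_kinetics()) {
  delay_lognormal(kin$onset_meanlog, kin$onset_sdlog)
}

draw_delay <- function(law, n) {
  switch(law$dist,
         none = numeric(n),
         lognormal = stats::rlnorm(n, law$meanlog, law$sdlog),
         stop("unknown detection-delay law: ", law$dist))
}

#' Simulate a snapshot flow-cytometry event table
#'
#' Generates per-event blue/red reporter intensities and DNA content with
#' ground-truth phase labels. DNA content is \code{2N * N(1, dna_cv)} for
#' G1 cells, \code{4N * N(1, dna_cv)} for G2/M cells, and a uniform bridge
#' between 2N and 4N (noise applied) for S cells. Under the kinetic event
#' rules, a fraction of cells acquires a retrotransposition event in the
#' current cycle, reporter expression begins after a lognormal onset delay,
#' and the red signal is the first-order matured portion of the
#' continuously produced blue pool.
#'
#' @param model a [cell_cycle_model()].
#' @param kin an [ft_kinetics()] object (kinetic rules only).
#' @param n number of events.
#' @param event_rule \code{"uniform_in_S"} (events uniform over the S
#'   window already traversed), \code{"uniform_in_cycle"}, or
#'   \code{"fixed_phase_mixture"} (phases drawn from \code{mixture}, no
#'   reporter kinetics).
#' @param mixture a [phase_fractions()] vector; required for
#'   \code{"fixed_phase_mixture"}.
#' @param event_prob probability that a cell carries an event this cycle.
#' @param dna_2n DNA-stain intensity of a 2N cell, a.u.
#' @param dna_cv coefficient of variation of the DNA stain (default 0.05).
#' @param production blue-protein production rate after onset, a.u./h.
#' @param background mean autofluorescence in blue and red channels, a.u.
#' @param seed integer seed.
#' @return list of class \code{facs_table} with \code{events}: data.frame
#'   (blue, red, dna, true_phase, true_event_time) where
#'   \code{true_event_time} is hours elapsed since the event (NA when the
#'   cell has no detected event).
#' @export
gen_facs_snapshot <- function(model, kin = ft_kinetics(), n,
                              event_rule = c("uniform_in_S", "uniform_in_cycle",
                                             "fixed_phase_mixture"),
                              mixture = NULL, event_prob = 0.3,
                              dna_2n = 100, dna_cv = 0.05,
                              production = 200, background = 10, seed = 1) {
  stopifnot(inherits(model, "cell_cycle_model"), n >= 0)
  event_rule <- match.arg(event_rule)
  if (event_rule == "fixed_phase_mixture") {
    if (is.null(mixture)) stop("fixed_phase_mixture requires a mixture")
    if (!inherits(mixture, "phase_fractions"))
      mixture <- phase_fractions(mixture[[1]], mixture[[2]], mixture[[3]])
  } else if (!is.null(mixture)) {
    stop("mixture is only used with event_rule = 'fixed_phase_mixture'")
  }
  ev <- withr::with_seed(seed, {
    if (event_rule == "fixed_phase_mixture") {
      phase <- factor(sample(c("G1", "S", "G2M"), n, replace = TRUE,
                             prob = unclass(mixture)),
                      levels = c("G1", "S", "G2M"))
      s_prog <- stats::runif(n)
      dna_base <- ifelse(phase == "G1", 1, ifelse(phase == "G2M", 2, 1 + s_prog))
      dna <- dna_2n * dna_base * stats::rnorm(n, 1, dna_cv)
      blue <- pmax(stats::rnorm(n, background, background / 3), 0)
      red <- pmax(stats::rnorm(n, background, background / 3), 0)
      data.frame(blue = blue, red = red, dna = pmax(dna, 0), true_phase = phase,
                 true_event_time = NA_real_)
    } else {
      ages <- -model$T * log2(1 - stats::runif(n) / 2)
      phase <- phase_from_age(model, ages)
      s_entry <- model$d_G1; s_exit <- model$d_G1 + model$d_S
      prog <- pmin(pmax((ages - s_entry) / model$d_S, 0), 1)
      dna_base <- ifelse(phase == "G1", 1, ifelse(phase == "G2M", 2, 1 + prog))
      dna <- pmax(dna_2n * dna_base * stats::rnorm(n, 1, dna_cv), 0)
      has_ev <- stats::runif(n) < event_prob
      ev_age <- rep(NA_real_, n)
      if (event_rule == "uniform_in_S") {
        can <- has_ev & ages > s_entry
        ev_age[can] <- stats::runif(sum(can), s_entry, pmin(ages[can], s_exit))
      } else {
        can <- has_ev
        ev_age[can] <- stats::runif(sum(can), 0, ages[can])
      }
      onset <- draw_delay(delay_from_kinetics(kin), n)
      expr_t <- pmax(ages - ev_age - onset, 0)  # time expressing the reporter
      k <- kin$k_mat
      blue_sig <- ifelse(is.na(ev_age), 0,
                         production / k * (1 - exp(-k * expr_t)))
      red_sig <- ifelse(is.na(ev_age), 0,
                        production * (expr_t - (1 - exp(-k * expr_t)) / k))
      blue <- pmax(blue_sig + stats::rnorm(n, background, background / 3), 0)
      red <- pmax(red_sig + stats::rnorm(n, background, background / 3), 0)
      t_since <- ifelse(expr_t > 0, ages - ev_age, NA_real_)
      data.frame(blue = blue, red = red, dna = dna, true_phase = phase,
                 true_event_time = t_since)
    }
  })
  structure(list(events = ev),
            params = list(event_rule = event_rule, n = n, dna_2n = dna_2n,
                          dna_cv = dna_cv, event_prob = event_prob, seed = seed),
            class = "facs_table")
}

#' @export
print.facs_table <- function(x, ...) {
  cat(sprintf("facs_table: %d events (%d with an event)\n",
              nrow(x$events), sum(!is.na(x$events$true_event_time))))
  invisible(x)
}

#' Simulate a retrotransposition reporter time course
#'
#' Synchronized mode emulates a mitotic shake-off and release: every cell
#' starts at age zero of G1, acquires at most one retrotransposition event
#' (with probability \code{event_prob}) at a uniformly random position in
#' its S phase, and becomes reporter-positive once the event plus the
#' detection delay has elapsed. The non-synchronized control uses a
#' steady-state renewal approximation in which S-phase entry times are
#' uniform over one doubling time, giving the expected near-linear
#' cumulative rise.
#'
#' @param model a [cell_cycle_model()].
#' @param timepoints increasing measurement times, hours (>= 2 points).
#' @param n_cells cohort size.
#' @param event_prob per-cell, per-cycle event probability.
#' @param detect_delay a detection-delay law (see [delay_none()]).
#' @param synchronized logical; FALSE simulates the asynchronous control.
#' @param seed integer seed.
#' @return list of class \code{timecourse_truth}: \code{timepoints},
#'   \code{gfp_percent} (measured percent positive per timepoint),
#'   \code{truth} (per-cell event and detection times, NA when no event),
#'   \code{n_cells}.
#' @export
gen_timecourse <- function(model, timepoints, n_cells, event_prob = 0.05,
                           detect_delay = delay_none(), synchronized = TRUE,
                           seed = 1) {
  stopifnot(inherits(model, "cell_cycle_model"))
  if (length(timepoints) < 2) stop("need at least two timepoints")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  tr <- withr::with_seed(seed, {
    has_ev <- stats::runif(n_cells) < event_prob
    ev <- rep(NA_real_, n_cells)
    ne <- sum(has_ev)
    if (synchronized) {
      ev[has_ev] <- model$d_G1 + stats::runif(ne, 0, model$d_S)
    } else {
      # steady-state renewal: S entry uniform over one doubling time
      ev[has_ev] <- (stats::runif(ne, 0, model$T) +
                       stats::runif(ne, 0, model$d_S)) %% model$T
    }
    det <- ev
    det[has_ev] <- ev[has_ev] + draw_delay(detect_delay, ne)
    data.frame(cell = seq_len(n_cells), event_time = ev, detect_time = det)
  })
  gfp <- vapply(timepoints,
                function(t) 100 * mean(!is.na(tr$detect_time) & tr$detect_time <= t),
                numeric(1))
  structure(list(timepoints = timepoints, gfp_percent = gfp, truth = tr,
                 n_cells = n_cells),
            params = list(event_prob = event_prob, synchronized = synchronized,
                          seed = seed),
            class = "timecourse_truth")
}
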