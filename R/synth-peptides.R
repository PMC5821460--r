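#' Generate a synthetic IP-MS unique-peptide count table with planted classes
#'
#' Emulates the structure of a sequential co-immunoprecipitation /
#' mass-spectrometry experiment scored in four channels: bait IP in two
#' biological replicates (\code{V5_1}, \code{V5_2}) and matched IgG
#' controls (\code{IgG_1}, \code{IgG_2}). Each planted confidence class is
#' constructed to satisfy its classification rule exactly:
#' \describe{
#'   \item{red}{identified in both bait IPs, zero peptides in both IgG
#'     controls (high-confidence interactor);}
#'   \item{orange}{identified in both bait IPs, some IgG peptides;}
#'   \item{yellow}{identified in exactly one bait IP, zero IgG peptides;}
#'   \item{gray}{background: either below the two-unique-peptide floor in
#'     every bait channel, or single-experiment with IgG contamination.}
#' }
#'
#' @param n_per_class named counts for red, orange, yellow, gray.
#' @param count_lambda Poisson intensity of the peptide-count law.
#' @param seed integer seed.
#' @return data.frame of class \code{peptide_table} with columns
#'   \code{protein_id}, \code{V5_1}, \code{V5_2}, \code{IgG_1},
#'   \code{IgG_2}, \code{planted_class}.
#' @export
gen_peptide_table <- function(n_per_class = c(red = 5, orange = 5,
                                              yellow = 5, gray = 5),
                              count_lambda = 4, seed = 1) {
  need <- c("red", "orange", "yellow", "gray")
  if (!all(need %in% names(n_per_class)))
    n_per_class <- stats::setNames(rep_len(n_per_class, 4), need)
  if (any(n_per_class < 0)) stop("class counts must be >= 0")
  n_tot <- sum(n_per_class)
  tab <- withr::with_seed(seed, {
    hit <- function(m) 2 + stats::rpois(m, count_lambda)     # passes the >=2 filter
    weak <- function(m) 1 + stats::rpois(m, 1)
    rows <- list()
    mk <- function(m, v1, v2, g1, g2, cls) {
      if (m == 0) return(NULL)
      data.frame(V5_1 = v1, V5_2 = v2, IgG_1 = g1, IgG_2 = g2,
                 planted_class = cls)
    }
    m <- n_per_class[["red"]]
    rows$red <- mk(m, hit(m), hit(m), integer(m), integer(m), "red")
    m <- n_per_class[["orange"]]
    if (m > 0) {
      g1 <- weak(m); g2 <- weak(m)
      drop2 <- stats::runif(m) < 0.5  # some oranges contaminated in one control only
      g2[drop2] <- 0L
      rows$orange <- mk(m, hit(m), hit(m), g1, g2, "orange")
    }
    m <- n_per_class[["yellow"]]
    if (m > 0) {
      in1 <- stats::runif(m) < 0.5
      v1 <- ifelse(in1, hit(m), 0L); v2 <- ifelse(in1, 0L, hit(m))
      rows$yellow <- mk(m, v1, v2, integer(m), integer(m), "yellow")
    }
    m <- n_per_class[["gray"]]
    if (m > 0) {
      low <- stats::runif(m) < 0.5  # below filter floor vs contaminated single-exp
      v1 <- ifelse(low, stats::rbinom(m, 1, 0.5), hit(m))
      v2 <- integer(m)
      g1 <- ifelse(low, 0L, weak(m))
      rows$gray <- mk(m, v1, v2, g1, integer(m), "gray")
    }
    do.call(rbind, rows)
  })
  if (is.null(tab))
    tab <- data.frame(V5_1 = integer(), V5_2 = integer(), IgG_1 = integer(),
                      IgG_2 = integer(), planted_class = character())
  tab <- cbind(protein_id = sprintf("SYN%04d", seq_len(nrow(tab))), tab)
  rownames(tab) <- NULL
  class(tab) <- c("peptide_table", "data.frame")
  tab
}
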