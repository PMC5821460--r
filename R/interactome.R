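#' Minimum-unique-peptide filter for IP-MS tables
#'
#' Retains proteins identified by at least \code{min_unique} unique
#' peptides. By default the floor applies overall: a protein passes when
#' any bait (V5) channel reaches the floor. \code{per_experiment = TRUE}
#' is a strict mode requiring the floor within each experiment for that
#' experiment to count.
#'
#' @param tab data.frame with columns V5_1, V5_2, IgG_1, IgG_2 (missing
#'   cells are treated as zero).
#' @param min_unique minimum unique peptides (default 2).
#' @param per_experiment strict per-experiment mode.
#' @return the filtered table (rows preserved in order).
#' @export
filter_min_unique <- function(tab, min_unique = 2, per_experiment = FALSE) {
  tab <- fill_zero(tab)
  if (nrow(tab) == 0) return(tab)
  keep <- if (per_experiment)
    tab$V5_1 >= min_unique | tab$V5_2 >= min_unique
  else
    pmax(tab$V5_1, tab$V5_2) >= min_unique
  tab[keep, , drop = FALSE]
}

fill_zero <- function(tab) {
  for (ch in c("V5_1", "V5_2", "IgG_1", "IgG_2")) {
    if (is.null(tab[[ch]])) stop("missing channel column: ", ch)
    tab[[ch]][is.na(tab[[ch]])] <- 0
    if (any(tab[[ch]] < 0) || any(tab[[ch]] != floor(tab[[ch]])))
      stop("peptide counts must be non-negative integers (", ch, ")")
  }
  tab
}

#' Proteins exclusive to the bait IP of one experiment
#'
#' A protein is an exclusive interactor in an experiment when it has at
#' least one peptide in that experiment's bait (V5) channel and none in
#' the matched IgG control. Apply [filter_min_unique()] first.
#'
#' @param tab filtered peptide table.
#' @param experiment 1 or 2.
#' @return character vector of protein ids.
#' @export
exclusive_interactors <- function(tab, experiment) {
  if (!experiment %in% c(1, 2)) stop("experiment must be 1 or 2")
  tab <- fill_zero(tab)
  v5 <- tab[[paste0("V5_", experiment)]]
  igg <- tab[[paste0("IgG_", experiment)]]
  as.character(tab$protein_id[v5 > 0 & igg == 0])
}

#' Classify interactor confidence from a four-channel peptide table
#'
#' Applies the minimum-unique-peptide filter, then assigns every input
#' protein exactly one confidence class:
#' \describe{
#'   \item{red}{bait peptides in both experiments, zero IgG peptides in
#'     both — high-confidence interactor;}
#'   \item{orange}{bait peptides in both experiments, IgG peptides in at
#'     least one — possible interactor;}
#'   \item{yellow}{bait peptides in exactly one experiment, zero IgG
#'     peptides — low-confidence interactor;}
#'   \item{gray}{everything else, including proteins failing the peptide
#'     floor and single-experiment identifications with IgG peptides.}
#' }
#'
#' @param tab peptide table (protein_id + four channels).
#' @param min_unique peptide floor passed to [filter_min_unique()].
#' @param per_experiment strict filter mode (see [filter_min_unique()]).
#' @return list of class \code{interactor_report}: \code{proteins}
#'   (input table + \code{class} column), \code{class_counts},
#'   \code{exclusive_counts} (exclusive interactors per experiment among
#'   filtered proteins).
#' @export
classify_confidence <- function(tab, min_unique = 2, per_experiment = FALSE) {
  tab <- fill_zero(tab)
  if (anyDuplicated(tab$protein_id)) stop("protein ids must be unique")
  passed <- filter_min_unique(tab, min_unique, per_experiment)
  in_pass <- tab$protein_id %in% passed$protein_id
  in1 <- tab$V5_1 > 0
  in2 <- tab$V5_2 > 0
  igg_any <- tab$IgG_1 > 0 | tab$IgG_2 > 0
  cls <- rep("gray", nrow(tab))
  both <- in_pass & in1 & in2
  cls[both & !igg_any] <- "red"
  cls[both & igg_any] <- "orange"
  cls[in_pass & xor(in1, in2) & !igg_any] <- "yellow"
  tab$class <- factor(cls, levels = c("red", "orange", "yellow", "gray"))
  excl <- c(exp1 = length(exclusive_interactors(passed, 1)),
            exp2 = length(exclusive_interactors(passed, 2)))
  structure(list(proteins = tab, class_counts = table(tab$class),
                 exclusive_counts = excl),
            class = "interactor_report")
}

#' @export
print.interactor_report <- function(x, ...) {
  cc <- x$class_counts
  cat(sprintf(
    "interactor_report: %d proteins (red %d, orange %d, yellow %d, gray %d)\n",
    sum(cc), cc["red"], cc["orange"], cc["yellow"], cc["gray"]))
  cat(sprintf("  exclusive interactors: %d (exp 1), %d (exp 2)\n",
              x$exclusive_counts["exp1"], x$exclusive_counts["exp2"]))
  invisible(x)
}
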