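## Nonselective clone-assay outcome estimator.
##
## Pipeline (in this fixed order):
##   1. per-class percentages from clone counts (raw),
##   2. uninduced percentages subtracted from induced (background removal),
##   3. class I + II + III renormalized to 100%,
##   4. repair-type frequencies = class percent x plug fraction,
##   5. weighted binomial SEM per type, with documented edge-case rules;
##      chromosome-loss SEM from replicate inductions.

#' Clone counts for one culture
#'
#' Clones are phenotyped for three heterozygous chromosome markers.  Cut
#' (hygromycin-sensitive) clones fall into genetic classes: class I
#' (Leu+ HygS Ura+, repair retaining both arms), class II (Leu+ HygS Ura-,
#' repair losing the right-arm marker), class III (Leu- HygS Ura-,
#' chromosome loss) and a rare fourth phenotype (Leu- HygS Ura+) that is
#' excluded from frequency calculations.
#'
#' @param condition `"induced"` or `"uninduced"`.
#' @param n_scored Total clones scored.
#' @param n_hygS Clones with the cut phenotype (`<= n_scored`).
#' @param class_I,class_II,class_III,class_other Per-class counts; they must
#'   sum to `n_hygS`.
#' @return Object of class `clone_assay_counts`.
#' @export
clone_assay_counts <- function(condition = c("induced", "uninduced"),
                               n_scored, n_hygS,
                               class_I, class_II, class_III,
                               class_other = 0L) {
  condition <- match.arg(condition)
  counts <- c(n_scored = n_scored, n_hygS = n_hygS, class_I = class_I,
              class_II = class_II, class_III = class_III,
              class_other = class_other)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("all counts must be non-negative integers")
  }
  if (n_hygS > n_scored) stop("n_hygS cannot exceed n_scored")
  if (class_I + class_II + class_III + class_other != n_hygS) {
    stop("class counts must sum to n_hygS")
  }
  structure(list(condition = condition, n_scored = as.integer(n_scored),
                 n_hygS = as.integer(n_hygS),
                 class_counts = c(I = as.integer(class_I),
                                  II = as.integer(class_II),
                                  III = as.integer(class_III),
                                  OTHER = as.integer(class_other))),
            class = "clone_assay_counts")
}

#' Plug survey: rearrangement-type counts per genetic class
#'
#' A random subset of repair clones from each genetic class is embedded in
#' agarose plugs and classified into rearrangement types by pulsed-field gel
#' electrophoresis.  A `(class, type)` row with count 0 declares the type
#' *eligible* in that class (it could have been observed); types are only
#' attributed to the classes for which rows exist.
#'
#' @param data `data.frame` with columns `class` (`"I"`/`"II"`), `type`
#'   (one of the outcome types, see Details) and `count` (>= 0).
#' @return Object of class `plug_survey` with per-class totals.
#' @details Recognised types: `ALLELIC`, `INTERNAL_DELETION`,
#'   `INTRA_TY_DELETION`, `TY_GC`, `ISOCHROMOSOME`, `RING`, `TRANSLOCATION`,
#'   `OTHER`.
#' @export
plug_survey <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("class", "type", "count") %in% names(data)))
  data <- data.frame(class = as.character(data$class),
                     type = as.character(data$type),
                     count = as.numeric(data$count),
                     stringsAsFactors = FALSE)
  if (!all(data$class %in% c("I", "II"))) stop("class must be 'I' or 'II'")
  if (!all(data$type %in% OUTCOME_TYPES)) {
    stop("unknown outcome type(s): ",
         paste(setdiff(data$type, OUTCOME_TYPES), collapse = ", "))
  }
  if (any(data$count < 0) || any(data$count != round(data$count))) {
    stop("counts must be non-negative integers")
  }
  if (anyDuplicated(data[c("class", "type")])) {
    stop("duplicate (class, type) rows")
  }
  totals <- vapply(c(I = "I", II = "II"),
                   function(cl) sum(data$count[data$class == cl]),
                   numeric(1))
  structure(list(data = data, totals = totals), class = "plug_survey")
}

new_class_frequencies <- function(freqs, stage) {
  structure(list(freqs = freqs, stage = stage), class = "class_frequencies")
}

#' Construct class frequencies directly from percentages
#'
#' Useful for feeding published percentages (rather than raw counts) into
#' the downstream estimator steps, e.g. reproducing a printed worked example.
#'
#' @param percents Named numeric vector with entries `I`, `II`, `III`
#'   (percent scale).
#' @param stage One of `"RAW"`, `"BACKGROUND_SUBTRACTED"`, `"NORMALIZED"`.
#' @return A `class_frequencies` object.
#' @export
as_class_frequencies <- function(percents,
                                 stage = c("RAW", "BACKGROUND_SUBTRACTED",
                                           "NORMALIZED")) {
  stage <- match.arg(stage)
  stopifnot(is.numeric(percents), all(c("I", "II", "III") %in% names(percents)),
            all(percents >= 0))
  new_class_frequencies(percents[c("I", "II", "III")], stage)
}

#' Per-class percentages from clone counts
#'
#' The default denominator is the number of cut (HygS) clones, matching the
#' worked-example convention of the assay; `"scored"` divides by all scored
#' clones instead, which is the right denominator for uninduced cultures
#' (where the background event rate among all cells is wanted) and is what
#' [estimate_outcomes()] uses for them.  The rare fourth phenotype class is
#' excluded before any percentage is formed.
#'
#' @param counts A [clone_assay_counts()].
#' @param denominator `"hygS"` (default) or `"scored"`.
#' @return A `class_frequencies` object (stage `"RAW"`) holding percents for
#'   classes I, II, III.
#' @export
class_frequencies <- function(counts, denominator = c("hygS", "scored")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(counts, "clone_assay_counts"))
  denom <- if (denominator == "hygS") counts$n_hygS else counts$n_scored
  cc <- counts$class_counts[c("I", "II", "III")]
  if (denom == 0L) {
    if (denominator == "hygS") stop("no cut clones (n_hygS == 0)")
    if (any(cc > 0)) stop("no clones scored but class counts are nonzero")
    return(new_class_frequencies(c(I = 0, II = 0, III = 0), "RAW"))
  }
  new_class_frequencies(100 * cc / denom, "RAW")
}

#' Subtract uninduced (background) class frequencies from induced ones
#'
#' Removes events that occurred before induction.  Cultures whose uninduced
#' HygS fraction exceeds `max_background` are rejected outright (high
#' pre-induction cutting makes the subtraction meaningless).  Negative
#' differences are clamped to 0 with a warning.
#'
#' @param induced,uninduced `class_frequencies` at stage `"RAW"`.
#' @param uninduced_counts Optional [clone_assay_counts()] for the uninduced
#'   culture, used for the background QC check.
#' @param max_background Maximum tolerated uninduced HygS fraction
#'   (default 0.5).
#' @return A `class_frequencies` at stage `"BACKGROUND_SUBTRACTED"`.
#' @export
background_subtract <- function(induced, uninduced, uninduced_counts = NULL,
                                max_background = 0.5) {
  stopifnot(inherits(induced, "class_frequencies"),
            inherits(uninduced, "class_frequencies"))
  if (induced$stage != "RAW" || uninduced$stage != "RAW") {
    stop("background_subtract expects RAW-stage frequencies")
  }
  if (!is.null(uninduced_counts)) {
    stopifnot(inherits(uninduced_counts, "clone_assay_counts"))
    if (uninduced_counts$n_scored > 0L) {
      frac <- uninduced_counts$n_hygS / uninduced_counts$n_scored
      if (frac > max_background) {
        stop(sprintf(
          "culture rejected: uninduced HygS fraction %.3f exceeds %.2f",
          frac, max_background))
      }
    }
  }
  diff <- induced$freqs - uninduced$freqs
  if (any(diff < 0)) {
    warning("negative background-subtracted class frequency clamped to 0 (",
            paste(names(diff)[diff < 0], collapse = ", "), ")")
    diff[diff < 0] <- 0
  }
  new_class_frequencies(diff, "BACKGROUND_SUBTRACTED")
}

#' Normalize class frequencies to sum to 100
#'
#' @param freqs A `class_frequencies` at stage `"BACKGROUND_SUBTRACTED"`.
#' @return A `class_frequencies` at stage `"NORMALIZED"` whose three classes
#'   sum to 100.
#' @export
normalize_classes <- function(freqs) {
  stopifnot(inherits(freqs, "class_frequencies"))
  if (freqs$stage != "BACKGROUND_SUBTRACTED") {
    stop("normalize_classes expects BACKGROUND_SUBTRACTED-stage frequencies")
  }
  total <- sum(freqs$freqs)
  if (total <= 0) stop("class frequencies sum to 0; nothing to normalize")
  new_class_frequencies(freqs$freqs * 100 / total, "NORMALIZED")
}

#' Weighted binomial SEM for one repair-type frequency within one class
#'
#' Two-step error model: the initial SEM is `sqrt(p * q / n)` with
#' `p = plugs_of_type / plugs_total`, `q = 1 - p` and `n = plugs_total`; the
#' final SEM weights the initial SEM by the genetic-class percentage, giving
#' a result on the percent scale.  Edge cases (the assigned-count rules):
#'
#' * `ALL_OF_CLASS` (every plug is this type): recompute with count
#'   `plugs_total - 1`, i.e. assume the next plug would *not* be this type.
#' * `ZERO_OF_TYPE` (no plug is this type, plugs exist): assign count 1,
#'   i.e. assume the next plug *would* be this type; result is an upper
#'   bound.
#' * `CLASS_ZERO` (class frequency is 0): same assigned count; the class
#'   weight makes the final SEM 0, flagged as a bound.
#' * `NO_PLUGS` (no plugs analyzed): assigned count 1 of an effective single
#'   plug; degenerate SEM 0, flagged as a bound.
#'
#' For outcomes fed by both genetic classes, compute one final SEM per class
#' and add them ([estimate_outcomes()] does this).
#'
#' @param class_freq Genetic-class percentage (0-100 scale).
#' @param plugs_total Plugs analyzed in the class.
#' @param plugs_of_type Plugs of this type (`<= plugs_total`).
#' @return List with `sem` (percent), `bound` (logical), `edge_case`.
#' @export
#' @examples
#' outcome_sem(85.7, 32, 5)$sem  # 5.5 at one decimal
outcome_sem <- function(class_freq, plugs_total, plugs_of_type) {
  stopifnot(is.numeric(class_freq), length(class_freq) == 1L,
            class_freq >= 0,
            plugs_total >= 0, plugs_of_type >= 0,
            plugs_total == round(plugs_total),
            plugs_of_type == round(plugs_of_type))
  if (plugs_total > 0L && plugs_of_type > plugs_total) {
    stop("plugs_of_type cannot exceed plugs_total")
  }
  edge <- "NONE"
  bound <- FALSE
  n <- plugs_total
  e <- plugs_of_type
  if (plugs_total == 0L) {
    edge <- "NO_PLUGS"; bound <- TRUE; e <- 1; n <- 1
  } else if (class_freq == 0) {
    edge <- "CLASS_ZERO"; bound <- TRUE; e <- 1
  } else if (plugs_of_type == 0L) {
    edge <- "ZERO_OF_TYPE"; bound <- TRUE; e <- 1
  } else if (plugs_of_type == plugs_total) {
    edge <- "ALL_OF_CLASS"; e <- plugs_total - 1
  }
  p <- e / n
  initial <- sqrt(p * (1 - p) / n)
  list(sem = initial * class_freq, bound = bound, edge_case = edge)
}

#' SEM of the chromosome-loss frequency across replicate inductions
#'
#' `SD / sqrt(n)` where SD is the sample standard deviation of the class-III
#' percentage across independent induction experiments.
#'
#' @param loss_percents Numeric vector of per-replicate loss percentages
#'   (length >= 2).
#' @return SEM in percent.
#' @export
#' @examples
#' loss_sem(c(10, 20, 30))  # 5.77
loss_sem <- function(loss_percents) {
  stopifnot(is.numeric(loss_percents))
  if (length(loss_percents) < 2L) {
    stop("need >= 2 replicate inductions for a loss SEM")
  }
  sd(loss_percents) / sqrt(length(loss_percents))
}

#' Plug-weighted repair-type frequencies
#'
#' `frequency(type) = sum over eligible classes of
#' class_percent * plugs_of_type / plugs_total`.  Types eligible in both
#' classes sum their contributions.  The class-III percentage is reported
#' directly as the chromosome-loss frequency.  A type whose estimated
#' frequency is 0 while an eligible class has nonzero percentage is flagged
#' as a bound ("< x" style entry): its reported value is 0 and `bound_value`
#' carries the assigned-count upper bound
#' `sum(class_percent / max(plugs_total, 1))`.
#'
#' @param class_freqs A `class_frequencies` at stage `"NORMALIZED"`.
#' @param survey A [plug_survey()].
#' @return Object of class `outcome_table`: a `data.frame` with one row per
#'   outcome type present in the survey plus a `CHROMOSOME_LOSS` row, and
#'   columns `type`, `frequency`, `sem` (`NA` here; filled by
#'   [estimate_outcomes()]), `bound`, `bound_value`.
#' @export
repair_type_frequencies <- function(class_freqs, survey) {
  stopifnot(inherits(class_freqs, "class_frequencies"),
            inherits(survey, "plug_survey"))
  if (class_freqs$stage != "NORMALIZED") {
    stop("repair_type_frequencies expects NORMALIZED-stage frequencies")
  }
  cf <- class_freqs$freqs
  types <- intersect(OUTCOME_TYPES, unique(survey$data$type))
  rows <- lapply(types, function(tp) {
    sub <- survey$data[survey$data$type == tp, , drop = FALSE]
    freq <- 0
    ub <- 0
    for (k in seq_len(nrow(sub))) {
      cl <- sub$class[k]
      tot <- survey$totals[[cl]]
      pct <- cf[[cl]]
      if (tot > 0L) freq <- freq + pct * sub$count[k] / tot
      ub <- ub + pct / max(tot, 1)
    }
    is_bound <- freq == 0 && any(cf[unique(sub$class)] > 0)
    data.frame(type = tp, frequency = freq, sem = NA_real_,
               bound = is_bound,
               bound_value = if (is_bound) ub else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(type = LOSS_TYPE, frequency = cf[["III"]],
                               sem = NA_real_, bound = FALSE,
                               bound_value = NA_real_,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("outcome_table", "data.frame")
  out
}

#' Construct an outcome table from per-type frequencies
#'
#' Builds the machine twin of a published outcome-frequency table row, e.g.
#' for feeding [bdr_total()] or [categorize_copy_number()] with printed
#' values.
#'
#' @param data `data.frame` with columns `type`, `frequency` and optionally
#'   `sem`, `bound`, `bound_value`.
#' @return An `outcome_table`.
#' @export
as_outcome_table <- function(data) {
  stopifnot(is.data.frame(data), all(c("type", "frequency") %in% names(data)))
  if (!all(data$type %in% c(OUTCOME_TYPES, LOSS_TYPE))) {
    stop("unknown outcome type(s): ",
         paste(setdiff(data$type, c(OUTCOME_TYPES, LOSS_TYPE)),
               collapse = ", "))
  }
  if (anyDuplicated(data$type)) stop("duplicate outcome types")
  n <- nrow(data)
  out <- data.frame(type = as.character(data$type),
                    frequency = as.numeric(data$frequency),
                    sem = if ("sem" %in% names(data))
                      as.numeric(data$sem) else rep(NA_real_, n),
                    bound = if ("bound" %in% names(data))
                      as.logical(data$bound) else rep(FALSE, n),
                    bound_value = if ("bound_value" %in% names(data))
                      as.numeric(data$bound_value) else rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (any(out$frequency < 0)) stop("frequencies must be >= 0")
  class(out) <- c("outcome_table", "data.frame")
  out
}

#' @export
print.outcome_table <- function(x, ...) {
  y <- data.frame(type = x$type,
                  frequency = sprintf("%.1f", x$frequency),
                  sem = ifelse(is.na(x$sem), "", sprintf("%.1f", x$sem)),
                  bound = ifelse(x$bound,
                                 sprintf("<%.1f", x$bound_value), ""))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

table_freq <- function(table, types) {
  sum(table$frequency[table$type %in% types])
}

#' Total break-distal rearrangement (BDR) frequency
#'
#' Sum of the internal-deletion, isochromosome, ring and translocation
#' frequencies, i.e. all rearrangements initiated from break-distal repeat
#' recipients.  Bound ("< x") entries contribute 0.
#'
#' @param outcome_table An `outcome_table`.
#' @return Integer percent (rounded for reporting); the unrounded value is
#'   attached as attribute `"raw"`.
#' @export
bdr_total <- function(outcome_table) {
  stopifnot(inherits(outcome_table, "outcome_table"))
  raw <- table_freq(outcome_table,
                    c("INTERNAL_DELETION", "ISOCHROMOSOME", "RING",
                      "TRANSLOCATION"))
  structure(round(raw), raw = raw)
}

#' Categorize outcomes by effect on gene copy number
#'
#' Outcomes that change gene copy number: inter-Ty (internal) deletions,
#' translocations, rings, isochromosomes, other rearrangements and
#' chromosome loss.  Outcomes that preserve it: intra-Ty deletions, Ty gene
#' conversion and allelic repair.  Bound entries contribute 0.
#'
#' @param outcome_table An `outcome_table`.
#' @param dsb_in_repeat Logical metadata flag recording whether the
#'   break site lay inside the repeat cluster (the categorization itself is
#'   identical; intra-Ty deletion and Ty gene conversion rows simply do not
#'   occur for breaks in unique sequence).
#' @return List with `change_percent` and `no_change_percent` (integer
#'   percents, unrounded values as attribute `"raw"`), and `dsb_in_repeat`.
#' @export
categorize_copy_number <- function(outcome_table, dsb_in_repeat = FALSE) {
  stopifnot(inherits(outcome_table, "outcome_table"))
  change <- table_freq(outcome_table,
                       c("INTERNAL_DELETION", "TRANSLOCATION", "RING",
                         "ISOCHROMOSOME", "OTHER", LOSS_TYPE))
  no_change <- table_freq(outcome_table,
                          c("INTRA_TY_DELETION", "TY_GC", "ALLELIC"))
  list(change_percent = structure(round(change), raw = change),
       no_change_percent = structure(round(no_change), raw = no_change),
       dsb_in_repeat = dsb_in_repeat)
}

#' Full clone-assay estimation pipeline
#'
#' Runs the fixed pipeline raw percentages -> background subtraction ->
#' normalization -> plug weighting -> weighted SEMs.  Induced percentages use
#' the cut-clone (HygS) denominator; uninduced percentages use the scored
#' denominator (see [class_frequencies()]).  Per-type SEMs follow
#' [outcome_sem()], with cross-class outcomes adding their per-class final
#' SEMs; the chromosome-loss SEM comes from replicate inductions when
#' `loss_replicates` is supplied.
#'
#' @param induced,uninduced [clone_assay_counts()] for the induced and
#'   uninduced cultures.
#' @param survey A [plug_survey()].
#' @param loss_replicates Optional numeric vector of per-replicate loss
#'   percentages for [loss_sem()].
#' @param max_background Passed to [background_subtract()].
#' @return An `outcome_table` with frequencies and SEMs.
#' @export
estimate_outcomes <- function(induced, uninduced, survey,
                              loss_replicates = NULL, max_background = 0.5) {
  stopifnot(inherits(induced, "clone_assay_counts"),
            inherits(uninduced, "clone_assay_counts"),
            inherits(survey, "plug_survey"))
  raw_ind <- class_frequencies(induced, "hygS")
  raw_un <- class_frequencies(uninduced, "scored")
  norm <- normalize_classes(
    background_subtract(raw_ind, raw_un, uninduced_counts = uninduced,
                        max_background = max_background))
  out <- repair_type_frequencies(norm, survey)
  cf <- norm$freqs
  for (i in seq_len(nrow(out))) {
    tp <- out$type[i]
    if (tp == LOSS_TYPE) {
      out$sem[i] <- if (!is.null(loss_replicates))
        loss_sem(loss_replicates) else NA_real_
      next
    }
    sub <- survey$data[survey$data$type == tp, , drop = FALSE]
    out$sem[i] <- sum(vapply(seq_len(nrow(sub)), function(k) {
      outcome_sem(cf[[sub$class[k]]], survey$totals[[sub$class[k]]],
                  sub$count[k])$sem
    }, numeric(1)))
  }
  out
}
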