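## Seeded synthetic-data generators: repeat families evolved from a common
## ancestor under uniform or clustered point-mutation divergence (optionally
## with indels), and clone assays drawn multinomially from a known
## outcome-frequency truth with pre-induction background and per-class plug
## subsampling.

#' Configuration for evolving a synthetic repeat family
#'
#' Defaults describe a full-length Ty-like family: a 5.9 kb ancestor, 50
#' copies (the size of the full-length Ty1/Ty2 complement) and a per-site
#' substitution probability of 0.02 per copy, which yields pairwise
#' identities around the mid-90s as observed within the Ty1 family.  Under
#' `"clustered"` divergence the same expected number of substitutions is
#' confined to family-level cluster windows, leaving long clean stretches
#' between them, so uniform-vs-clustered comparisons isolate block-length
#' effects at matched overall identity.
#'
#' @param ancestor_length Ancestor length in nt (330 is LTR-like).
#' @param n_copies Number of family members.
#' @param substitution_prob Per-site, per-copy substitution probability in
#'   `[0, 1)`.
#' @param clustering `"uniform"` or `"clustered"`.
#' @param cluster_fraction Fraction of the ancestor covered by mutation
#'   clusters (clustered mode).
#' @param n_clusters Number of cluster windows (clustered mode).
#' @param indel_prob Per-site, per-copy indel initiation probability.
#' @param indel_mean_length Mean indel length (geometric).
#' @param family Family label for the generated elements.
#' @return A list of class `family_evolution_config`.
#' @export
family_evolution_config <- function(ancestor_length = 5900L, n_copies = 50L,
                                    substitution_prob = 0.02,
                                    clustering = c("uniform", "clustered"),
                                    cluster_fraction = 0.1,
                                    n_clusters = 5L,
                                    indel_prob = 0,
                                    indel_mean_length = 3,
                                    family = "TY1") {
  clustering <- match.arg(clustering)
  stopifnot(ancestor_length > 0, n_copies >= 1,
            substitution_prob >= 0, substitution_prob < 1,
            cluster_fraction > 0, cluster_fraction <= 1,
            n_clusters >= 1, indel_prob >= 0, indel_prob < 1,
            indel_mean_length >= 1, family %in% FAMILY_LEVELS)
  structure(list(ancestor_length = as.integer(ancestor_length),
                 n_copies = as.integer(n_copies),
                 substitution_prob = substitution_prob,
                 clustering = clustering,
                 cluster_fraction = cluster_fraction,
                 n_clusters = as.integer(n_clusters),
                 indel_prob = indel_prob,
                 indel_mean_length = indel_mean_length,
                 family = family),
            class = "family_evolution_config")
}

mutate_copy <- function(ancestor, config, allowed_sites) {
  bases <- c("A", "C", "G", "T")
  s <- ancestor
  L <- length(s)
  n_sub <- rbinom(1L, L, config$substitution_prob)
  n_sub <- min(n_sub, length(allowed_sites))
  if (n_sub > 0L) {
    sites <- sample(allowed_sites, n_sub)
    for (i in sites) {
      s[i] <- sample(setdiff(bases, s[i]), 1L)
    }
  }
  if (config$indel_prob > 0) {
    n_indel <- rbinom(1L, L, config$indel_prob)
    for (k in seq_len(n_indel)) {
      len <- 1L + stats::rgeom(1L, 1 / config$indel_mean_length)
      pos <- sample.int(length(s), 1L)
      if (stats::runif(1L) < 0.5) {
        s <- s[-(pos:min(pos + len - 1L, length(s)))]
        if (!length(s)) s <- sample(bases, 1L)  # keep sequences non-empty
      } else {
        s <- append(s, sample(bases, len, replace = TRUE), after = pos)
      }
    }
  }
  paste(s, collapse = "")
}

#' Evolve a synthetic repeat family from a common ancestor
#'
#' Draws a random ancestor and mutates each copy independently.  Uniform
#' mode scatters substitutions across the whole sequence; clustered mode
#' confines the same expected number of substitutions to cluster windows
#' drawn once per family, so all copies stay identical between windows.
#' Fully reproducible under a fixed seed.
#'
#' @param config A [family_evolution_config()].
#' @param seed Optional integer seed (sets the session RNG).
#' @return A [repeat_catalog()] with `n_copies` elements placed head-to-tail
#'   on a synthetic chromosome.
#' @export
evolve_family <- function(config = family_evolution_config(), seed = NULL) {
  stopifnot(inherits(config, "family_evolution_config"))
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  L <- config$ancestor_length
  ancestor <- sample(bases, L, replace = TRUE)
  allowed <- seq_len(L)
  if (config$clustering == "clustered") {
    win <- max(1L, floor(L * config$cluster_fraction / config$n_clusters))
    starts <- sort(sample.int(max(L - win + 1L, 1L), config$n_clusters))
    allowed <- unique(unlist(lapply(starts, function(st)
      st:min(st + win - 1L, L))))
  }
  seqs <- vapply(seq_len(config$n_copies),
                 function(i) mutate_copy(ancestor, config, allowed),
                 character(1))
  ids <- sprintf("syn_%s_%03d", config$family, seq_len(config$n_copies))
  names(seqs) <- ids
  widths <- nchar(seqs)
  starts <- cumsum(c(0L, widths[-length(widths)] + 500L))
  elements <- data.frame(element_id = ids, family = config$family,
                         chromosome = "chrSYN",
                         start = starts, end = starts + widths,
                         strand = "+", stringsAsFactors = FALSE)
  repeat_catalog(elements, seqs,
                 sprintf(paste0("synthetic family: L=%d n=%d d=%g %s",
                                " indel_prob=%g"),
                         L, config$n_copies, config$substitution_prob,
                         config$clustering, config$indel_prob))
}

#' Expected pairwise identity under the substitution model
#'
#' Two copies independently mutated from the ancestor at per-site
#' probability `d` (uniform mode, no indels) match at a site when neither
#' mutated, or both mutated to the same of the 3 alternative bases:
#' `(1-d)^2 + d^2 / 3`.
#'
#' @param d Per-site substitution probability.
#' @return Expected identity as a percent.
#' @export
expected_pairwise_identity <- function(d) {
  100 * ((1 - d)^2 + d^2 / 3)
}

#' Design of a simulated clone assay
#'
#' Defaults mirror the scale of the hybrid wild-type experiment: 955 induced
#' cut clones, 18 class-I and 52 class-II plugs, with a 500-clone uninduced
#' control and no background by default.
#'
#' @param n_induced_clones Number of induced cut clones.
#' @param n_uninduced_clones Number of uninduced clones scored.
#' @param plugs_class_I,plugs_class_II Plugs sampled per genetic class.
#' @param background_event_prob Per-clone probability of a pre-induction
#'   event in the uninduced culture.
#' @return A list of class `assay_design`.
#' @export
assay_design <- function(n_induced_clones = 955L, n_uninduced_clones = 500L,
                         plugs_class_I = 18L, plugs_class_II = 52L,
                         background_event_prob = 0) {
  stopifnot(n_induced_clones >= 0, n_uninduced_clones >= 0,
            plugs_class_I >= 0, plugs_class_II >= 0,
            background_event_prob >= 0, background_event_prob <= 1)
  structure(list(n_induced_clones = as.integer(n_induced_clones),
                 n_uninduced_clones = as.integer(n_uninduced_clones),
                 plugs_class_I = as.integer(plugs_class_I),
                 plugs_class_II = as.integer(plugs_class_II),
                 background_event_prob = background_event_prob),
            class = "assay_design")
}

#' True outcome-frequency vector for simulation
#'
#' @param probs Named numeric vector over outcome types (subset of the
#'   recognised types plus `CHROMOSOME_LOSS`) summing to 1.
#' @return Named numeric vector of class `outcome_truth`.
#' @export
outcome_truth <- function(probs) {
  stopifnot(is.numeric(probs), !is.null(names(probs)))
  if (!all(names(probs) %in% c(OUTCOME_TYPES, LOSS_TYPE))) {
    stop("unknown outcome type(s): ",
         paste(setdiff(names(probs), c(OUTCOME_TYPES, LOSS_TYPE)),
               collapse = ", "))
  }
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    stop("probabilities must be >= 0 and sum to 1")
  }
  structure(probs, class = "outcome_truth")
}

#' Convert an outcome table's frequencies into a simulation truth vector
#'
#' @param table An `outcome_table` whose frequencies (plus bounds treated as
#'   0) sum to ~100.
#' @return An [outcome_truth()].
#' @export
outcome_truth_from_table <- function(table) {
  stopifnot(inherits(table, "outcome_table"))
  p <- setNames(table$frequency, table$type)
  outcome_truth(p / sum(p))
}

## Default outcome -> genetic-class mapping (hybrid-diploid convention:
## allelic repair yields a changed chromosome size and scores as class II).
default_class_map <- function() {
  c(INTERNAL_DELETION = "I", INTRA_TY_DELETION = "I", TY_GC = "I",
    ISOCHROMOSOME = "II", RING = "II", TRANSLOCATION = "II",
    ALLELIC = "II", OTHER = "II", CHROMOSOME_LOSS = "III")
}

#' Simulate one clone assay from a known truth
#'
#' Induced clones are drawn multinomially from the truth vector; genetic
#' classes are derived from the outcome -> class map.  Uninduced clones
#' suffer a background event with probability
#' `design$background_event_prob`, drawn from the same truth.  Plug surveys
#' subsample the requested number of clones per class without replacement
#' (truncated with a warning when fewer class members were simulated).
#'
#' @param truth An [outcome_truth()].
#' @param design An [assay_design()].
#' @param class_map Named character vector outcome type -> `"I"`/`"II"`/
#'   `"III"`.
#' @param seed Optional integer seed.
#' @return List with `induced`, `uninduced` ([clone_assay_counts()]) and
#'   `survey` ([plug_survey()]).
#' @export
simulate_clone_assay <- function(truth, design = assay_design(),
                                 class_map = default_class_map(),
                                 seed = NULL) {
  stopifnot(inherits(truth, "outcome_truth"), inherits(design, "assay_design"))
  if (!is.null(seed)) set.seed(seed)
  types <- names(truth)
  if (!all(types %in% names(class_map))) {
    stop("class_map lacks type(s): ",
         paste(setdiff(types, names(class_map)), collapse = ", "))
  }
  cls <- class_map[types]

  draw <- function(n) {
    if (n == 0L) return(setNames(integer(length(types)), types))
    setNames(as.integer(rmultinom(1L, n, truth)), types)
  }
  ind_counts <- draw(design$n_induced_clones)
  class_sum <- function(counts, cl) sum(counts[cls == cl])
  induced <- clone_assay_counts(
    "induced",
    n_scored = design$n_induced_clones, n_hygS = design$n_induced_clones,
    class_I = class_sum(ind_counts, "I"),
    class_II = class_sum(ind_counts, "II"),
    class_III = class_sum(ind_counts, "III"))

  n_bg <- rbinom(1L, design$n_uninduced_clones, design$background_event_prob)
  bg_counts <- draw(n_bg)
  uninduced <- clone_assay_counts(
    "uninduced",
    n_scored = design$n_uninduced_clones, n_hygS = n_bg,
    class_I = class_sum(bg_counts, "I"),
    class_II = class_sum(bg_counts, "II"),
    class_III = class_sum(bg_counts, "III"))

  sample_plugs <- function(cl, n_plugs) {
    eligible <- types[cls == cl]
    if (!length(eligible)) {
      return(data.frame(class = character(), type = character(),
                        count = integer(), stringsAsFactors = FALSE))
    }
    members <- rep(types[cls == cl], ind_counts[cls == cl])
    if (n_plugs > length(members)) {
      warning("requested ", n_plugs, " class-", cl, " plugs but only ",
              length(members), " clones simulated; truncating")
      n_plugs <- length(members)
    }
    picked <- if (n_plugs > 0L) sample(members, n_plugs) else character()
    data.frame(class = cl, type = eligible,
               count = as.integer(table(factor(picked, levels = eligible))),
               stringsAsFactors = FALSE)
  }
  survey <- plug_survey(rbind(sample_plugs("I", design$plugs_class_I),
                              sample_plugs("II", design$plugs_class_II)))
  list(induced = induced, uninduced = uninduced, survey = survey)
}

#' Parameter-recovery experiment for the outcome estimator
#'
#' Simulates `n_replicates` clone assays at the generating truth, runs the
#' full estimator on each, and summarizes per-outcome recovery: mean
#' estimate, bias, empirical SD of the estimates, mean bespoke SEM, and the
#' Monte-Carlo standard error of the mean estimate.
#'
#' @param truth An [outcome_truth()].
#' @param design An [assay_design()].
#' @param n_replicates Number of replicates (>= 2).
#' @param seed Optional integer seed.
#' @param class_map Outcome -> class map, as in [simulate_clone_assay()].
#' @return Object of class `recovery_report`: a `data.frame` with columns
#'   `type`, `truth_percent`, `mean_estimate`, `bias`, `empirical_sd`,
#'   `mean_sem`, `mc_se`, plus attribute `n_replicates`.
#' @export
recovery_experiment <- function(truth, design = assay_design(),
                                n_replicates = 200L, seed = NULL,
                                class_map = default_class_map()) {
  stopifnot(n_replicates >= 2L)
  if (!is.null(seed)) set.seed(seed)
  types <- c(setdiff(names(truth), LOSS_TYPE),
             if (LOSS_TYPE %in% names(truth)) LOSS_TYPE)
  est <- matrix(NA_real_, n_replicates, length(types),
                dimnames = list(NULL, types))
  sems <- matrix(NA_real_, n_replicates, length(types),
                 dimnames = list(NULL, types))
  for (r in seq_len(n_replicates)) {
    sim <- simulate_clone_assay(truth, design, class_map)
    tab <- estimate_outcomes(sim$induced, sim$uninduced, sim$survey)
    est[r, ] <- tab$frequency[match(types, tab$type)]
    sems[r, ] <- tab$sem[match(types, tab$type)]
  }
  out <- data.frame(
    type = types,
    truth_percent = 100 * as.numeric(truth[types]),
    mean_estimate = colMeans(est),
    empirical_sd = apply(est, 2L, sd),
    mean_sem = colMeans(sems),
    stringsAsFactors = FALSE)
  out$bias <- out$mean_estimate - out$truth_percent
  out$mc_se <- out$empirical_sd / sqrt(n_replicates)
  rownames(out) <- NULL
  structure(out[c("type", "truth_percent", "mean_estimate", "bias",
                  "empirical_sd", "mean_sem", "mc_se")],
            n_replicates = n_replicates,
            class = c("recovery_report", "data.frame"))
}
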