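## Pairwise homology metrics between repeat elements:
##   * overall (global) percent identity under Needleman-Wunsch affine gaps,
##   * longest block of uninterrupted (100%) identity,
##   * local Smith-Waterman score, rescaled to a Karlin-Altschul bit score.

#' Alignment parameters for the homology metrics
#'
#' Defaults follow the conventions of the classic DNA aligners: the global
#' aligner uses gap open 10 / gap extension 0.5 with the full DNA matrix
#' (match +5, mismatch -4); the local aligner uses BLAST-style match +1 /
#' mismatch -3 with affine gap costs open 1, extension 1 (a gap of length L
#' costs `1 + L`).  Gap penalties are expressed as non-negative costs.
#' Bit-score constants default to the ungapped Karlin-Altschul values for the
#' +1/-3 scheme (lambda = 1.374, K = 0.711); these are approximations of a
#' gapped search's statistics, so rankings should additionally consult the
#' raw score, which is constant-free.
#'
#' @param global_gap_open,global_gap_extend Non-negative global gap costs.
#' @param global_match,global_mismatch Global substitution scores.
#' @param local_match,local_mismatch Local substitution scores.
#' @param local_gap_open,local_gap_extend Non-negative local gap costs.
#' @param bitscore_lambda,bitscore_K Karlin-Altschul constants (> 0).
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(global_gap_open = 10, global_gap_extend = 0.5,
                             global_match = 5, global_mismatch = -4,
                             local_match = 1, local_mismatch = -3,
                             local_gap_open = 1, local_gap_extend = 1,
                             bitscore_lambda = 1.374, bitscore_K = 0.711) {
  p <- list(global_gap_open = global_gap_open,
            global_gap_extend = global_gap_extend,
            global_match = global_match, global_mismatch = global_mismatch,
            local_match = local_match, local_mismatch = local_mismatch,
            local_gap_open = local_gap_open,
            local_gap_extend = local_gap_extend,
            bitscore_lambda = bitscore_lambda, bitscore_K = bitscore_K)
  if (!all(vapply(p, function(x) is.numeric(x) && is.finite(x), logical(1)))) {
    stop("all alignment parameters must be finite numbers")
  }
  if (bitscore_lambda <= 0 || bitscore_K <= 0) {
    stop("bitscore_lambda and bitscore_K must be positive")
  }
  if (global_gap_open < 0 || global_gap_extend < 0 ||
      local_gap_open < 0 || local_gap_extend < 0) {
    stop("gap costs must be non-negative")
  }
  structure(p, class = "alignment_params")
}

## 5x5 substitution matrix over ACGTN.  N scores as a mismatch against
## everything, including another N, so ambiguous bases never count as matches.
substitution_matrix <- function(match, mismatch) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m)[1:4] <- match
  m
}

check_seq <- function(s, what = "sequence") {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop(what, " must be a single string")
  }
  s <- toupper(s)
  if (nchar(s) == 0L) stop(what, " must be non-empty")
  if (grepl("[^ACGTN]", s)) stop("non-ACGTN character in ", what)
  s
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## Count identical aligned columns (both bases in ACGT and equal) and the
## total number of columns of an alignment given its two gapped strings.
alignment_columns <- function(pat, sub) {
  a <- strsplit(pat, "", fixed = TRUE)[[1L]]
  b <- strsplit(sub, "", fixed = TRUE)[[1L]]
  acgt <- c("A", "C", "G", "T")
  list(matches = sum(a == b & a %in% acgt),
       length = length(a),
       columns = ifelse(a == "-" | b == "-", "-",
                        ifelse(a == b & a %in% acgt, "M", "X")))
}

#' Global percent identity between two sequences
#'
#' Optimal Needleman-Wunsch global alignment with affine gaps; identity is
#' `100 * identical columns / total alignment columns`, gap columns included
#' in the denominator.  Arguments are ordered canonically (lexicographically)
#' before aligning so the metric is exactly symmetric.
#'
#' @param seq_a,seq_b Nucleotide strings (non-empty).
#' @param params An [alignment_params()].
#' @param denominator `"alignment"` (default: all alignment columns) or
#'   `"shorter"` (length of the shorter sequence), for sensitivity analysis.
#' @return List with `identity` (percent in \[0, 100\]), `alignment_length`,
#'   `matches` and `score`.
#' @export
#' @examples
#' global_identity("ACGTACGT", "ACGT")$identity  # 50
global_identity <- function(seq_a, seq_b, params = alignment_params(),
                            denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  seq_a <- check_seq(seq_a, "seq_a")
  seq_b <- check_seq(seq_b, "seq_b")
  if (seq_a > seq_b) { tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = substitution_matrix(params$global_match,
                                             params$global_mismatch),
    gapOpening = params$global_gap_open,
    gapExtension = params$global_gap_extend)
  cols <- alignment_columns(as.character(Biostrings::alignedPattern(aln)),
                            as.character(Biostrings::alignedSubject(aln)))
  denom <- if (denominator == "alignment") cols$length else
    min(nchar(seq_a), nchar(seq_b))
  list(identity = 100 * cols$matches / denom,
       alignment_length = cols$length,
       matches = cols$matches,
       score = Biostrings::score(aln))
}

#' Longest block of uninterrupted identity between two sequences
#'
#' Exact longest common substring by dynamic programming: an exact-match run
#' is by definition the longest possible contiguous block of matching
#' nucleotides, so this is the reference semantics for the block metric
#' ([block_from_hits()] is the alignment-hit-scanning heuristic and can only
#' be shorter).  `N` never matches anything, including another `N`.
#'
#' @param seq_a,seq_b Nucleotide strings (non-empty).
#' @param strand_mode `"best_of_both"` (default) also tests `seq_b` reverse
#'   complemented and returns the larger block, or `"forward_only"`.
#' @return List with `block_length` (integer) and `strand_used`
#'   (`"FORWARD"` or `"REVCOMP"`).
#' @export
#' @examples
#' longest_perfect_block("ACGTTTACGG", "CCGTTTACAA")$block_length  # 7
longest_perfect_block <- function(seq_a, seq_b,
                                  strand_mode = c("best_of_both",
                                                  "forward_only")) {
  strand_mode <- match.arg(strand_mode)
  seq_a <- check_seq(seq_a, "seq_a")
  seq_b <- check_seq(seq_b, "seq_b")
  fwd <- lcs_length_cpp(seq_a, seq_b)
  if (strand_mode == "forward_only") {
    return(list(block_length = fwd, strand_used = "FORWARD"))
  }
  rev <- lcs_length_cpp(seq_a, revcomp(seq_b))
  if (rev > fwd) list(block_length = rev, strand_used = "REVCOMP")
  else list(block_length = fwd, strand_used = "FORWARD")
}

#' Best local alignment(s) between two sequences
#'
#' Smith-Waterman local alignment under the BLAST-style scoring scheme in
#' `params`.  Returns the single best hit (input sizes here are a few kb, so
#' an exhaustive DP replaces seeded heuristics).  A hit records the aligned
#' intervals (1-based inclusive) on both sequences, the raw score and a
#' per-column string (`M` match / `X` mismatch / `-` gap) from which the
#' score can be recomputed.
#'
#' @param seq_a,seq_b Nucleotide strings (non-empty).
#' @param params An [alignment_params()].
#' @return List of hits (possibly empty when no positive-scoring local
#'   alignment exists); each hit is a list with `start_a`, `end_a`,
#'   `start_b`, `end_b`, `score`, `columns`.
#' @export
local_hits <- function(seq_a, seq_b, params = alignment_params()) {
  seq_a <- check_seq(seq_a, "seq_a")
  seq_b <- check_seq(seq_b, "seq_b")
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "local",
    substitutionMatrix = substitution_matrix(params$local_match,
                                             params$local_mismatch),
    gapOpening = params$local_gap_open,
    gapExtension = params$local_gap_extend)
  sc <- Biostrings::score(aln)
  if (sc <= 0) return(list())
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  cols <- alignment_columns(as.character(pat), as.character(sub))
  list(list(start_a = Biostrings::start(pat), end_a = Biostrings::end(pat),
            start_b = Biostrings::start(sub), end_b = Biostrings::end(sub),
            score = sc, columns = cols$columns))
}

#' Recompute a local hit's raw score from its aligned columns
#'
#' Used by tests to assert the `score` invariant of [local_hits()].
#'
#' @param columns Character vector of per-column codes (`M`/`X`/`-`).
#' @param params An [alignment_params()].
#' @return Numeric raw score.
#' @export
score_from_columns <- function(columns, params = alignment_params()) {
  r <- rle(columns)
  sum(ifelse(r$values == "M", r$lengths * params$local_match,
             ifelse(r$values == "X", r$lengths * params$local_mismatch,
                    -(params$local_gap_open +
                        r$lengths * params$local_gap_extend))))
}

#' Karlin-Altschul bit score
#'
#' `bits = (lambda * raw_score - ln K) / ln 2`; strictly increasing in the
#' raw score at fixed constants.
#'
#' @param raw_score Finite numeric raw alignment score(s).
#' @param params An [alignment_params()] supplying `bitscore_lambda` and
#'   `bitscore_K`.
#' @return Numeric bit score(s).
#' @export
bitscore <- function(raw_score, params = alignment_params()) {
  if (!is.numeric(raw_score) || any(!is.finite(raw_score))) {
    stop("raw_score must be finite")
  }
  (params$bitscore_lambda * raw_score - log(params$bitscore_K)) / log(2)
}

#' Longest run of match columns across a set of local hits
#'
#' The alignment-hit-scanning route to the block metric: scan each hit's
#' aligned columns for the maximal run of matches and return the maximum over
#' hits.  Guaranteed `<=` [longest_perfect_block()] on the same pair, with
#' equality when the best local alignment covers the longest shared exact
#' block (e.g. planted-motif constructions).
#'
#' @param hits Result of [local_hits()].
#' @return Integer block length (0 for an empty hit collection).
#' @export
block_from_hits <- function(hits) {
  if (!length(hits)) return(0L)
  max(vapply(hits, function(h) {
    r <- rle(h$columns)
    runs <- r$lengths[r$values == "M"]
    if (length(runs)) max(runs) else 0L
  }, integer(1)))
}

## Compute one metric for one pair of sequences, honouring strand_mode.
pair_metric <- function(seq_a, seq_b, metric, params, strand_mode) {
  if (metric == "longest_block") {
    res <- longest_perfect_block(seq_a, seq_b, strand_mode)
    return(list(value = res$block_length, strand_used = res$strand_used))
  }
  compute <- function(b) {
    switch(metric,
      overall_identity = global_identity(seq_a, b, params)$identity,
      local_score = {
        h <- local_hits(seq_a, b, params)
        if (length(h)) h[[1L]]$score else 0
      },
      local_bitscore = {
        h <- local_hits(seq_a, b, params)
        bitscore(if (length(h)) h[[1L]]$score else 0, params)
      },
      stop("unknown metric: ", metric))
  }
  fwd <- compute(seq_b)
  if (strand_mode == "forward_only") {
    return(list(value = fwd, strand_used = "FORWARD"))
  }
  rev <- compute(revcomp(seq_b))
  if (rev > fwd) list(value = rev, strand_used = "REVCOMP")
  else list(value = fwd, strand_used = "FORWARD")
}

#' All-vs-all homology matrix over a catalog
#'
#' Computes one metric for every unordered element pair from
#' [enumerate_pairs()] and stores it symmetrically with an `NA` diagonal
#' (no self-comparisons: `n` elements yield `n(n-1)/2` distinct values).
#'
#' @param catalog A [repeat_catalog()].
#' @param metric One of `"longest_block"`, `"overall_identity"`,
#'   `"local_score"`, `"local_bitscore"`.
#' @param params An [alignment_params()].
#' @param strand_mode `"best_of_both"` (default) or `"forward_only"`.
#' @param families Optional family filter, as in [enumerate_pairs()].
#' @param progress Emit a progress message every `progress` pairs (0 = quiet).
#' @return Object of class `homology_matrix`: list with `metric`, `ids`,
#'   `values` (symmetric numeric matrix, `NA` diagonal), `strand` (character
#'   matrix) and `params`.
#' @export
pairwise_matrix <- function(catalog,
                            metric = c("longest_block", "overall_identity",
                                       "local_score", "local_bitscore"),
                            params = alignment_params(),
                            strand_mode = c("best_of_both", "forward_only"),
                            families = NULL, progress = 0L) {
  metric <- match.arg(metric)
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(catalog, "repeat_catalog"))
  pairs <- enumerate_pairs(catalog, families)
  ids <- sort(unique(c(pairs$id_a, pairs$id_b,
                       if (is.null(families)) catalog$elements$element_id
                       else catalog$elements$element_id[
                         catalog$elements$family %in% families])),
              method = "radix")
  if (length(ids) < 2L) stop("need at least 2 selected elements")
  values <- matrix(NA_real_, length(ids), length(ids),
                   dimnames = list(ids, ids))
  strand <- matrix(NA_character_, length(ids), length(ids),
                   dimnames = list(ids, ids))
  for (k in seq_len(nrow(pairs))) {
    ia <- pairs$id_a[k]; ib <- pairs$id_b[k]
    res <- tryCatch(
      pair_metric(catalog_sequence(catalog, ia),
                  catalog_sequence(catalog, ib),
                  metric, params, strand_mode),
      error = function(e) stop("pair (", ia, ", ", ib, "): ",
                               conditionMessage(e), call. = FALSE))
    values[ia, ib] <- values[ib, ia] <- res$value
    strand[ia, ib] <- strand[ib, ia] <- res$strand_used
    if (progress > 0L && k %% progress == 0L) {
      message("computed ", k, "/", nrow(pairs), " pairs")
    }
  }
  structure(list(metric = metric, ids = ids, values = values,
                 strand = strand, params = params,
                 strand_mode = strand_mode),
            class = "homology_matrix")
}

#' @export
print.homology_matrix <- function(x, ...) {
  cat("homology_matrix:", x$metric, "over", length(x$ids), "elements (",
      length(x$ids) * (length(x$ids) - 1L) / 2L, "pairs )\n")
  invisible(x)
}

#' Long-form view of a homology matrix
#'
#' @param hm A `homology_matrix`.
#' @return `data.frame` with columns `id_a`, `id_b`, `metric`, `value`,
#'   `strand_used`, one row per unordered pair.
#' @export
homology_long <- function(hm) {
  stopifnot(inherits(hm, "homology_matrix"))
  idx <- which(upper.tri(hm$values), arr.ind = TRUE)
  out <- data.frame(id_a = hm$ids[idx[, 1L]], id_b = hm$ids[idx[, 2L]],
                    metric = hm$metric, value = hm$values[idx],
                    strand_used = hm$strand[idx],
                    stringsAsFactors = FALSE)
  out[order(out$id_a, out$id_b, method = "radix"), , drop = FALSE]
}
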