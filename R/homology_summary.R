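## Summaries over homology matrices: MEPS binning of block lengths, family
## identity statistics, heat-map tables and recipient -> donor rankings.

#' Bin a block length into MEPS-style intervals
#'
#' Half-open bins `[k*w, (k+1)*w)` with `bin_index = floor(length / w)`;
#' with the default width of 250 bp (the approximate yeast MEPS), a block of
#' 249 falls in bin 0 and a block of 250 in bin 1.
#'
#' @param length Non-negative block length(s) in nucleotides.
#' @param bin_width Bin width in nucleotides (default 250).
#' @return Integer bin index/indices.
#' @export
#' @examples
#' bin_block_length(c(0, 249, 250, 1877))  # 0 0 1 7
bin_block_length <- function(length, bin_width = 250) {
  stopifnot(is.numeric(length), is.numeric(bin_width), bin_width > 0)
  if (any(length < 0)) stop("block length must be >= 0")
  as.integer(floor(length / bin_width))
}

#' Fraction of pairs with a perfect-identity block at or above the MEPS
#'
#' Counts unordered pairs whose longest block of uninterrupted identity is
#' `>= threshold` (inclusive).  The matrix must carry the `longest_block`
#' metric.
#'
#' @param block_matrix A `homology_matrix` with metric `"longest_block"`.
#' @param threshold MEPS threshold in nucleotides (default 250).
#' @return List with `count_at_or_above`, `total` and `fraction`.
#' @export
meps_fraction <- function(block_matrix, threshold = 250) {
  stopifnot(inherits(block_matrix, "homology_matrix"))
  if (block_matrix$metric != "longest_block") {
    stop("meps_fraction requires a longest_block matrix, got: ",
         block_matrix$metric)
  }
  stopifnot(threshold > 0)
  v <- block_matrix$values[upper.tri(block_matrix$values)]
  list(count_at_or_above = sum(v >= threshold),
       total = length(v),
       fraction = sum(v >= threshold) / length(v))
}

#' Mean and SD of percent identity within or between families
#'
#' Within-family statistics (`family_a == family_b`) use all unordered pairs
#' inside the family (`k(k-1)/2` of them); between-family statistics use all
#' cross pairs (`k * m`).  The population SD (divide by n) is the default
#' convention; sample SD is available for sensitivity analysis.
#'
#' @param identity_matrix A `homology_matrix` with metric
#'   `"overall_identity"`.
#' @param catalog The [repeat_catalog()] supplying family labels.
#' @param family_a,family_b Family labels (`family_b` defaults to
#'   `family_a`).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return List with `family_a`, `family_b`, `mean`, `sd`, `n_pairs`.
#' @export
family_identity_stats <- function(identity_matrix, catalog, family_a,
                                  family_b = family_a,
                                  sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(identity_matrix, "homology_matrix"),
            inherits(catalog, "repeat_catalog"))
  if (identity_matrix$metric != "overall_identity") {
    stop("family_identity_stats requires an overall_identity matrix, got: ",
         identity_matrix$metric)
  }
  ids_a <- catalog$elements$element_id[catalog$elements$family == family_a]
  ids_b <- catalog$elements$element_id[catalog$elements$family == family_b]
  ids_a <- intersect(ids_a, identity_matrix$ids)
  ids_b <- intersect(ids_b, identity_matrix$ids)
  if (family_a == family_b) {
    if (length(ids_a) < 2L) {
      stop("family ", family_a, " has < 2 members with matrix entries")
    }
    sub <- identity_matrix$values[ids_a, ids_a, drop = FALSE]
    vals <- sub[upper.tri(sub)]
  } else {
    if (!length(ids_a) || !length(ids_b)) {
      stop("empty family selection for between-family stats")
    }
    vals <- as.vector(identity_matrix$values[ids_a, ids_b, drop = FALSE])
  }
  n <- length(vals)
  m <- mean(vals)
  s <- if (sd_type == "population") sqrt(sum((vals - m)^2) / n) else sd(vals)
  list(family_a = family_a, family_b = family_b,
       mean = m, sd = s, n_pairs = n)
}

#' Rank candidate donors for a recipient element
#'
#' For each requested metric, donors are ordered by decreasing metric value,
#' ties broken lexicographically by donor id; rank 1 is the best donor.  The
#' recipient is excluded from its own ranking.  By default the candidate set
#' follows the family-compatibility rule of the assay: full-length (TY1/TY2)
#' recipients rank against all other full-length elements, LTR recipients
#' against all other LTRs.
#'
#' @param recipient_id Element id of the recipient.
#' @param catalog The [repeat_catalog()].
#' @param matrices Named list of `homology_matrix` objects (names are used as
#'   metric labels in the output).
#' @param donor_families Optional explicit character vector of donor family
#'   labels overriding the compatibility rule.
#' @return `data.frame` with columns `recipient`, `metric`, `rank`,
#'   `donor_id`, `value`.
#' @export
rank_donors <- function(recipient_id, catalog, matrices,
                        donor_families = NULL) {
  stopifnot(inherits(catalog, "repeat_catalog"), is.list(matrices),
            length(matrices) >= 1L)
  el <- catalog$elements
  if (!recipient_id %in% el$element_id) {
    stop("unknown recipient: ", recipient_id)
  }
  if (is.null(donor_families)) {
    fam <- el$family[el$element_id == recipient_id]
    donor_families <- if (fam %in% c("TY1", "TY2")) c("TY1", "TY2") else fam
  }
  donors <- setdiff(el$element_id[el$family %in% donor_families],
                    recipient_id)
  if (!length(donors)) stop("no candidate donors for ", recipient_id)
  if (is.null(names(matrices))) {
    names(matrices) <- vapply(matrices, `[[`, character(1), "metric")
  }
  out <- lapply(names(matrices), function(mn) {
    hm <- matrices[[mn]]
    stopifnot(inherits(hm, "homology_matrix"))
    miss <- setdiff(c(recipient_id, donors), hm$ids)
    if (length(miss)) {
      stop("matrix ", mn, " lacks element(s): ", paste(miss, collapse = ", "))
    }
    vals <- hm$values[recipient_id, donors]
    ord <- order(-vals, donors, method = "radix")
    data.frame(recipient = recipient_id, metric = mn,
               rank = seq_along(donors), donor_id = donors[ord],
               value = unname(vals[ord]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Binned heat-map table of a longest-block matrix
#'
#' @param block_matrix A `homology_matrix` with metric `"longest_block"`.
#' @param bin_width Bin width in nucleotides (default 250).
#' @return List with `bins` (square integer matrix of bin indices, `NA`
#'   diagonal) and `legend` (`data.frame` mapping each occupied bin index to
#'   its half-open interval `[lower, upper)`).
#' @export
heatmap_table <- function(block_matrix, bin_width = 250) {
  stopifnot(inherits(block_matrix, "homology_matrix"))
  if (block_matrix$metric != "longest_block") {
    stop("heatmap_table requires a longest_block matrix, got: ",
         block_matrix$metric)
  }
  bins <- block_matrix$values
  bins[] <- ifelse(is.na(block_matrix$values), NA_integer_,
                   bin_block_length(ifelse(is.na(block_matrix$values), 0,
                                           block_matrix$values), bin_width))
  occupied <- sort(unique(bins[!is.na(bins)]))
  legend <- data.frame(bin = occupied,
                       lower = occupied * bin_width,
                       upper = (occupied + 1L) * bin_width)
  list(bins = bins, legend = legend)
}
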