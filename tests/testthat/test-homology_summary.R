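test_that("bin_block_length uses half-open 250 bp bins", {
  expect_equal(bin_block_length(0), 0L)
  expect_equal(bin_block_length(249), 0L)
  expect_equal(bin_block_length(250), 1L)
  expect_equal(bin_block_length(1877), 7L)  # floor(1877 / 250)
  expect_equal(bin_block_length(c(100, 600), bin_width = 100), c(1L, 6L))
  expect_error(bin_block_length(-1), ">= 0")
})

make_block_matrix <- function(values, ids = letters[seq_len(nrow(values))]) {
  dimnames(values) <- list(ids, ids)
  diag(values) <- NA_real_
  structure(list(metric = "longest_block", ids = ids, values = values,
                 strand = NULL, params = NULL, strand_mode = NULL),
            class = "homology_matrix")
}

test_that("meps_fraction counts inclusive >= threshold over all pairs", {
  # identical 600-mer family of 10 -> all 45 pairs above the MEPS
  same <- rand_seq(600L)
  ids <- sprintf("e%02d", 1:10)
  cat10 <- repeat_catalog(
    data.frame(element_id = ids, family = "TY1", chromosome = "chrI",
               start = seq(0L, by = 700L, length.out = 10L),
               end = seq(600L, by = 700L, length.out = 10L), strand = "+"),
    setNames(rep(same, 10L), ids))
  hm <- pairwise_matrix(cat10, "longest_block")
  fr <- meps_fraction(hm)
  expect_equal(fr$count_at_or_above, 45L)
  expect_equal(fr$total, 45L)
  expect_equal(fr$fraction, 1)

  # boundary: a pair at exactly the threshold counts
  m <- matrix(c(0, 250, 249, 250, 0, 100, 249, 100, 0), 3L, 3L)
  fr2 <- meps_fraction(make_block_matrix(m))
  expect_equal(fr2$count_at_or_above, 1L)
  expect_equal(fr2$total, 3L)

  # wrong metric is an error
  fam <- evolve_family(family_evolution_config(ancestor_length = 80L,
                                               n_copies = 3L), seed = 1L)
  ident <- pairwise_matrix(fam, "overall_identity")
  expect_error(meps_fraction(ident), "longest_block")
})

test_that("meps_fraction is consistent with the binned heat-map table", {
  fam <- evolve_family(family_evolution_config(
    ancestor_length = 700L, n_copies = 8L, substitution_prob = 0.01),
    seed = 7L)
  hm <- pairwise_matrix(fam, "longest_block")
  fr <- meps_fraction(hm, threshold = 250)
  ht <- heatmap_table(hm, bin_width = 250)
  # threshold is a bin boundary: pairs >= 250 are exactly those in bin >= 1
  bins <- ht$bins[upper.tri(ht$bins)]
  expect_equal(sum(bins >= 1L), fr$count_at_or_above)
  # spot-check entries and legend intervals
  expect_equal(ht$bins[1L, 2L],
               bin_block_length(hm$values[1L, 2L]))
  expect_equal(ht$legend$upper - ht$legend$lower,
               rep(250, nrow(ht$legend)))
  expect_true(all(is.na(diag(ht$bins))))
  expect_equal(dim(ht$bins), c(8L, 8L))
})

test_that("family_identity_stats: arithmetic, conventions, bookkeeping", {
  # two families with known identities
  ids <- c("t1", "t2", "l1", "l2")
  el <- data.frame(element_id = ids, family = c("TY1", "TY1", "LTR", "LTR"),
                   chromosome = "chrI", start = c(0L, 10L, 20L, 30L),
                   end = c(4L, 14L, 24L, 34L), strand = "+")
  cat_ <- repeat_catalog(el, setNames(c("ACGT", "ACGT", "AAAA", "AAAA"), ids))
  v <- matrix(NA_real_, 4L, 4L, dimnames = list(ids, ids))
  v["t1", "t2"] <- v["t2", "t1"] <- 90
  v["l1", "l2"] <- v["l2", "l1"] <- 100
  v["t1", "l1"] <- v["l1", "t1"] <- 50
  v["t1", "l2"] <- v["l2", "t1"] <- 60
  v["t2", "l1"] <- v["l1", "t2"] <- 70
  v["t2", "l2"] <- v["l2", "t2"] <- 80
  im <- structure(list(metric = "overall_identity", ids = ids, values = v),
                  class = "homology_matrix")
  # {90, 100} -> 95 +/- 5 under population SD
  both <- family_identity_stats(im, cat_, "TY1")
  expect_equal(both$mean, 90)
  expect_equal(both$n_pairs, 1L)
  # fold all four elements into one family: n_pairs bookkeeping k(k-1)/2
  el2 <- el
  el2$family <- "TY1"
  cat2 <- repeat_catalog(el2, setNames(c("ACGT", "ACGT", "AAAA", "AAAA"), ids))
  v2 <- v
  v2[] <- 95
  v2[cbind(c("t1", "t2"), c("t2", "t1"))] <- 100
  v2[cbind(c("l1", "l2"), c("l2", "l1"))] <- 90
  diag(v2) <- NA
  im2 <- structure(list(metric = "overall_identity", ids = ids,
                        values = v2), class = "homology_matrix")
  s2 <- family_identity_stats(im2, cat2, "TY1")
  expect_equal(s2$n_pairs, 6L)  # k(k-1)/2
  # {90, 100, 95, 95, 95, 95}: population SD convention
  expect_equal(s2$mean, 95)
  expect_equal(s2$sd, sqrt(mean((c(90, 100, rep(95, 4)) - 95)^2)))
  # between-family: k*m pairs
  btw <- family_identity_stats(im, cat_, "TY1", "LTR")
  expect_equal(btw$n_pairs, 4L)
  expect_equal(btw$mean, mean(c(50, 60, 70, 80)))
  # identical elements -> 100 +/- 0
  same <- rand_seq(50L)
  cat_same <- repeat_catalog(
    data.frame(element_id = c("a", "b", "c"), family = "TY2",
               chromosome = "chrI", start = c(0L, 60L, 120L),
               end = c(50L, 110L, 170L), strand = "+"),
    c(a = same, b = same, c = same))
  st <- family_identity_stats(pairwise_matrix(cat_same, "overall_identity"),
                              cat_same, "TY2")
  expect_equal(st$mean, 100)
  expect_equal(st$sd, 0)
  # < 2 members is an error
  expect_error(family_identity_stats(im, cat_, "OTHER"), "< 2 members")
  expect_error(family_identity_stats(im, cat_, "TY1", sd_type = "nope"))
})

test_that("evolved two-family identity matches the closed-form expectation", {
  d <- 0.05
  fam <- evolve_family(family_evolution_config(
    ancestor_length = 600L, n_copies = 12L, substitution_prob = d),
    seed = 202L)
  im <- pairwise_matrix(fam, "overall_identity", strand_mode = "forward_only")
  st <- family_identity_stats(im, fam, "TY1")
  expect_equal(st$mean, expected_pairwise_identity(d), tolerance = 0.01)
})

test_that("rank_donors orders by value with lexicographic ties", {
  set.seed(61)
  recip <- rand_seq(300L)
  near <- paste0(substr(recip, 1L, 290L), rand_seq(10L))
  far <- rand_seq(300L)
  ids <- c("recip", "copy", "near", "far")
  cat_ <- repeat_catalog(
    data.frame(element_id = ids, family = "TY1", chromosome = "chrI",
               start = seq(0L, by = 400L, length.out = 4L),
               end = seq(300L, by = 400L, length.out = 4L), strand = "+"),
    setNames(c(recip, recip, near, far), ids))
  mats <- list(longest_block = pairwise_matrix(cat_, "longest_block"),
               overall_identity = pairwise_matrix(cat_, "overall_identity"),
               local_bitscore = pairwise_matrix(cat_, "local_bitscore"))
  rk <- rank_donors("recip", cat_, mats)
  # exact copy is rank 1 under every metric; recipient excluded
  for (m in names(mats)) {
    sub <- rk[rk$metric == m, ]
    expect_equal(sub$donor_id[sub$rank == 1L], "copy")
    expect_false("recip" %in% sub$donor_id)
    expect_true(all(diff(sub$value) <= 0))
  }
  # ties broken lexicographically ("copy" vs a tied duplicate)
  v <- mats$longest_block$values
  v["recip", "far"] <- v["far", "recip"] <- v["recip", "copy"]
  tied <- structure(list(metric = "longest_block", ids = ids, values = v),
                    class = "homology_matrix")
  rk2 <- rank_donors("recip", cat_, list(longest_block = tied))
  expect_equal(rk2$donor_id[1:2], c("copy", "far"))
  expect_error(rank_donors("ghost", cat_, mats), "unknown recipient")
})

test_that("rankings are invariant to positive rescaling (bitscore vs raw)", {
  fam <- evolve_family(family_evolution_config(
    ancestor_length = 250L, n_copies = 6L, substitution_prob = 0.08),
    seed = 71L)
  raw <- pairwise_matrix(fam, "local_score")
  bits <- pairwise_matrix(fam, "local_bitscore")
  rid <- fam$elements$element_id[1L]
  r1 <- rank_donors(rid, fam, list(m = raw))
  r2 <- rank_donors(rid, fam, list(m = bits))
  expect_equal(r1$donor_id, r2$donor_id)
})

test_that("planted catalog separates best-bitscore from best-block donors", {
  set.seed(81)
  recip <- rand_seq(400L)
  # donor Y: one long perfect block (180 nt), diverged elsewhere
  blockY <- paste0(substr(recip, 1L, 180L), rand_seq(220L))
  # donor X: many dispersed well-matching segments -> higher total local
  # score, but no long perfect run
  chunks <- substring(recip, seq(1L, 381L, by = 20L),
                      seq(20L, 400L, by = 20L))
  mutate1 <- function(s) {
    i <- sample(nchar(s), 1L)
    paste0(substr(s, 1L, i - 1L),
           sample(setdiff(BASES, substr(s, i, i)), 1L),
           substr(s, i + 1L, nchar(s)))
  }
  donorX <- paste(vapply(chunks, mutate1, character(1)), collapse = "")
  ids <- c("recip", "X", "Y")
  cat_ <- repeat_catalog(
    data.frame(element_id = ids, family = "TY1", chromosome = "chrI",
               start = c(0L, 500L, 1000L), end = c(400L, 900L, 1400L),
               strand = "+"),
    setNames(c(recip, donorX, blockY), ids))
  blocks <- pairwise_matrix(cat_, "longest_block")
  bits <- pairwise_matrix(cat_, "local_bitscore")
  rk_block <- rank_donors("recip", cat_, list(b = blocks))
  rk_bits <- rank_donors("recip", cat_, list(b = bits))
  expect_equal(rk_block$donor_id[rk_block$rank == 1L], "Y")
  expect_equal(rk_bits$donor_id[rk_bits$rank == 1L], "X")
})
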