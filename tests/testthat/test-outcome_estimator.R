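test_that("class_frequencies: percentages, denominators, validation", {
  cc <- clone_assay_counts("induced", n_scored = 1100, n_hygS = 1000,
                           class_I = 857, class_II = 100, class_III = 43)
  f <- class_frequencies(cc)
  expect_equal(f$freqs, c(I = 85.7, II = 10.0, III = 4.3))
  expect_equal(f$stage, "RAW")
  # scored denominator
  f2 <- class_frequencies(cc, "scored")
  expect_equal(unname(f2$freqs[["I"]]), 100 * 857 / 1100)
  # all-loss culture
  f3 <- class_frequencies(clone_assay_counts("induced", 60, 50, 0, 0, 50))
  expect_equal(f3$freqs, c(I = 0, II = 0, III = 100))
  # no cut clones
  expect_error(
    class_frequencies(clone_assay_counts("induced", 10, 0, 0, 0, 0)),
    "no cut clones")
  # count invariants
  expect_error(clone_assay_counts("induced", 10, 11, 11, 0, 0), "exceed")
  expect_error(clone_assay_counts("induced", 10, 5, 1, 1, 1), "sum to")
})

test_that("background_subtract: zero background, QC rejection, clamping", {
  ind <- as_class_frequencies(c(I = 85.7, II = 10, III = 4.3), "RAW")
  zero <- as_class_frequencies(c(I = 0, II = 0, III = 0), "RAW")
  out <- background_subtract(ind, zero)
  expect_equal(unname(out$freqs), unname(ind$freqs))
  expect_equal(out$stage, "BACKGROUND_SUBTRACTED")
  # >50% HygS in the uninduced culture rejects the whole culture
  bad <- clone_assay_counts("uninduced", n_scored = 100, n_hygS = 60,
                            class_I = 30, class_II = 20, class_III = 10)
  expect_error(
    background_subtract(ind, class_frequencies(bad, "scored"),
                        uninduced_counts = bad),
    "rejected.*0.600")
  # negative differences clamp to 0 with a warning
  ind2 <- as_class_frequencies(c(I = 1.0, II = 50, III = 49), "RAW")
  un2 <- as_class_frequencies(c(I = 1.5, II = 0, III = 0), "RAW")
  expect_warning(res <- background_subtract(ind2, un2), "clamped")
  expect_equal(unname(res$freqs[["I"]]), 0)
  # stage checking
  expect_error(background_subtract(out, zero), "RAW")
})

test_that("normalize_classes rescales to 100 and rejects degenerate input", {
  bs <- as_class_frequencies(c(I = 40.5, II = 40.5, III = 9),
                             "BACKGROUND_SUBTRACTED")
  n <- normalize_classes(bs)
  expect_equal(n$freqs, c(I = 45, II = 45, III = 10))
  expect_equal(sum(n$freqs), 100)
  already <- as_class_frequencies(c(I = 40, II = 40, III = 20),
                                  "BACKGROUND_SUBTRACTED")
  expect_equal(normalize_classes(already)$freqs, c(I = 40, II = 40, III = 20))
  expect_error(normalize_classes(as_class_frequencies(
    c(I = 0, II = 0, III = 0), "BACKGROUND_SUBTRACTED")), "sum to 0")
  expect_error(normalize_classes(as_class_frequencies(
    c(I = 1, II = 1, III = 1), "RAW")), "BACKGROUND_SUBTRACTED")
})

test_that("subtract-then-normalize differs from the reversed order", {
  # raw induced percentages need not sum to 100 (the excluded fourth class),
  # so the two orders genuinely disagree
  ind <- as_class_frequencies(c(I = 80, II = 10, III = 5), "RAW")
  un <- as_class_frequencies(c(I = 10, II = 0, III = 0), "RAW")
  correct <- normalize_classes(background_subtract(ind, un))$freqs
  # the unsupported order, done by hand
  ind_norm <- ind$freqs * 100 / sum(ind$freqs)
  wrong <- ind_norm - un$freqs
  wrong <- wrong * 100 / sum(wrong)
  expect_false(isTRUE(all.equal(unname(correct), unname(wrong))))
})

test_that("repair_type_frequencies reproduces the worked example", {
  cf <- as_class_frequencies(c(I = 85.7, II = 13.3, III = 1.0), "NORMALIZED")
  sv <- plug_survey(data.frame(
    class = c("I", "I", "II", "II"),
    type = c("INTERNAL_DELETION", "ALLELIC", "ISOCHROMOSOME", "ALLELIC"),
    count = c(5, 27, 11, 35)))
  tab <- repair_type_frequencies(cf, sv)
  # 5/32 x 85.7% = 13.4%
  expect_equal(tab$frequency[tab$type == "INTERNAL_DELETION"],
               85.7 * 5 / 32)
  expect_equal(round(tab$frequency[tab$type == "INTERNAL_DELETION"], 1L),
               13.4)
  # cross-class additivity: 30% x 10/20 + 20% x 5/10 = 25%
  cf2 <- as_class_frequencies(c(I = 30, II = 20, III = 50), "NORMALIZED")
  sv2 <- plug_survey(data.frame(
    class = c("I", "I", "II", "II"),
    type = c("ALLELIC", "OTHER", "ALLELIC", "OTHER"),
    count = c(10, 10, 5, 5)))
  tab2 <- repair_type_frequencies(cf2, sv2)
  expect_equal(tab2$frequency[tab2$type == "ALLELIC"], 25)
  # class III goes straight to the loss row
  expect_equal(tab2$frequency[tab2$type == "CHROMOSOME_LOSS"], 50)
  # class with zero percent: its types report 0 and are flagged as bounds
  cf3 <- as_class_frequencies(c(I = 80, II = 0, III = 20), "NORMALIZED")
  sv3 <- plug_survey(data.frame(class = c("I", "II"),
                                type = c("ALLELIC", "RING"),
                                count = c(10, 0)))
  tab3 <- repair_type_frequencies(cf3, sv3)
  expect_equal(tab3$frequency[tab3$type == "RING"], 0)
  expect_false(tab3$bound[tab3$type == "RING"])  # class II percent is 0 too
  # zero count in a class with nonzero percent -> bound
  sv4 <- plug_survey(data.frame(class = c("I", "I"),
                                type = c("ALLELIC", "RING"),
                                count = c(10, 0)))
  tab4 <- repair_type_frequencies(cf3, sv4)
  expect_true(tab4$bound[tab4$type == "RING"])
  expect_equal(tab4$bound_value[tab4$type == "RING"], 80 / 10)
  expect_error(repair_type_frequencies(cf$freqs, sv))
})

test_that("outcome_sem reproduces published cells and edge rules", {
  # worked example: p = 5/32, n = 32, class weight 85.7% -> 5.5
  res <- outcome_sem(85.7, 32, 5)
  expect_equal(res$sem, sqrt((5 / 32) * (27 / 32) / 32) * 85.7)
  expect_equal(round(res$sem, 1L), 5.5)
  expect_equal(res$edge_case, "NONE")
  expect_false(res$bound)
  # ALL_OF_CLASS: hybrid internal deletions, 18/18 plugs, weight 60.6 -> 3.3
  all_of <- outcome_sem(60.6, 18, 18)
  expect_equal(all_of$edge_case, "ALL_OF_CLASS")
  expect_equal(round(all_of$sem, 1L), 3.3)
  # ZERO_OF_TYPE: assigned count 1 (upper bound)
  z <- outcome_sem(85.7, 32, 0)
  expect_equal(z$edge_case, "ZERO_OF_TYPE")
  expect_true(z$bound)
  expect_equal(z$sem, sqrt((1 / 32) * (31 / 32) / 32) * 85.7)
  expect_equal(z$sem, 2.636, tolerance = 1e-3)
  # CLASS_ZERO and NO_PLUGS degenerate to 0 but stay flagged
  expect_true(outcome_sem(0, 20, 0)$bound)
  expect_equal(outcome_sem(0, 20, 0)$edge_case, "CLASS_ZERO")
  np <- outcome_sem(50, 0, 0)
  expect_equal(np$edge_case, "NO_PLUGS")
  expect_true(np$bound)
  expect_equal(np$sem, 0)
  # monotone decrease in n at fixed p and weight
  sems <- vapply(c(8, 16, 32, 64, 128), function(n)
    outcome_sem(50, n, n / 4)$sem, numeric(1))
  expect_true(all(diff(sems) < 0))
  expect_error(outcome_sem(50, 10, 11), "exceed")
})

test_that("loss_sem is sample SD over sqrt(replicates)", {
  expect_equal(loss_sem(c(20, 22)), sd(c(20, 22)) / sqrt(2))
  expect_equal(round(loss_sem(c(20, 22)), 1L), 1.0)
  expect_equal(loss_sem(c(15, 15, 15)), 0)
  expect_equal(loss_sem(c(10, 20, 30)), 5.7735, tolerance = 1e-4)
  expect_error(loss_sem(42), ">= 2 replicate")
})

test_that("full pipeline reproduces the reconstructed purebred wild-type row", {
  fx <- worked_example()
  tab <- estimate_outcomes(fx$induced, fx$uninduced, fx$survey)
  got <- setNames(round(tab$frequency, 1L), tab$type)
  expect_equal(got[["INTERNAL_DELETION"]], 13.4)
  expect_equal(got[["ALLELIC"]], 81.5)
  expect_equal(got[["ISOCHROMOSOME"]], 3.2)
  expect_equal(got[["RING"]], 0.3)
  expect_equal(got[["TRANSLOCATION"]], 0.3)
  expect_equal(got[["OTHER"]], 0.3)
  expect_equal(got[["CHROMOSOME_LOSS"]], 1.0)
  sems <- setNames(round(tab$sem, 1L), tab$type)
  expect_equal(sems[["INTERNAL_DELETION"]], 5.5)
  expect_equal(sems[["ALLELIC"]], 6.4)      # cross-class: class I + class II
  expect_equal(sems[["ISOCHROMOSOME"]], 0.8)
  expect_equal(sems[["RING"]], 0.3)
  expect_equal(sems[["OTHER"]], 2.9)        # zero-count bound + class II
  # conservation: frequencies + loss sum to 100
  expect_equal(sum(tab$frequency), 100, tolerance = 1e-9)
})

test_that("bdr_total and categorize_copy_number reproduce published sums", {
  m60 <- published_table("MH3360")
  m59 <- published_table("MH3359")
  m68 <- published_table("MH3768")
  expect_equal(as.integer(bdr_total(m60)), 76L)
  expect_equal(as.integer(bdr_total(m59)), 17L)
  expect_equal(attr(bdr_total(m59), "raw"), 17.2)
  cn60 <- categorize_copy_number(m60)
  cn68 <- categorize_copy_number(m68, dsb_in_repeat = TRUE)
  expect_equal(as.integer(cn60$change_percent), 97L)
  expect_equal(as.integer(cn68$change_percent), 19L)
  # bounds contribute 0: MH3768 OTHER/ALLELIC are "<" entries
  expect_equal(attr(cn68$change_percent, "raw"), 18.7)
  # all-allelic table
  allal <- as_outcome_table(data.frame(
    type = c("ALLELIC", "CHROMOSOME_LOSS"), frequency = c(100, 0)))
  cn <- categorize_copy_number(allal)
  expect_equal(as.integer(cn$change_percent), 0L)
  expect_equal(as.integer(cn$no_change_percent), 100L)
  expect_equal(as.integer(bdr_total(allal)), 0L)
  # empty table
  expect_equal(as.integer(bdr_total(as_outcome_table(
    data.frame(type = character(), frequency = numeric())))), 0L)
})
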