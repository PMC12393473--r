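conds <- autopod_conditions()
meta <- condition_meta(conds)

test_that("atlas construction enforces its invariants", {
  els <- interval_set("chrA", c(0, 600), c(500, 1100),
                      name = c("e1", "e2"))
  m <- matrix(c(TRUE, FALSE), 2, length(conds))
  expect_error(accessibility_atlas(els, conds, m),
               "at least one condition")
  m[2, 1] <- TRUE
  a <- accessibility_atlas(els, conds, m)
  expect_equal(rownames(a$matrix), c("e1", "e2"))
  # serialisation round-trip
  bp <- withr::local_tempfile(fileext = ".bed")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_atlas(a, bp, mp)
  back <- read_atlas(bp, mp)
  expect_equal(back$matrix, a$matrix)
  expect_equal(as.data.frame(back$elements), as.data.frame(a$elements))
})

test_that("brain_filter drops whole elements on any overlap", {
  a <- toy_atlas(list(conds[1], conds[2], conds[3]))
  # elements at 0-500, 600-1100, 1200-1700
  expect_identical(brain_filter(a, interval_set()), a)
  expect_equal(nrow(brain_filter(a, interval_set("chrA", 0, 5000))$elements),
               0L)
  filt <- brain_filter(a, interval_set("chrA", 1099, 1100))
  expect_setequal(filt$elements$name, c("el_001", "el_003"))
  # random atlas vs brute-force non-overlap scan
  withr::local_seed(21)
  combos <- replicate(100, sample(conds, sample(1:5, 1)),
                      simplify = FALSE)
  big <- toy_atlas(combos)
  brain <- random_intervals(10, chroms = "chrA", max_pos = 60000)
  surv <- brain_filter(big, brain)$elements$name
  expected <- big$elements$name[oracle_intersect_count(big$elements,
                                                       brain) == 0L]
  expect_identical(surv, expected)
})

test_that("specificity classification follows tissue collapsing rules", {
  a <- toy_atlas(list(
    c("foot.V.phalanges.early", "foot.V.phalanges.late"), # one tissue, 2 tp
    c("hand.I.phalanges.early", "hand.I.metapodial.early"), # two tissues
    "hand.III.metapodial.late"))
  femur <- interval_set("chrA", 0, 10) # overlaps element 1 only
  cls <- classify_specificity(a, list(femur))
  expect_equal(cls$shared_with_skeleton, c(TRUE, FALSE, FALSE))
  expect_equal(cls$autopod_specific, c(FALSE, TRUE, TRUE))
  expect_equal(cls$tissue_and_timepoint_specific, c(TRUE, FALSE, TRUE))
  # empty skeleton list -> everything autopod-specific
  cls0 <- classify_specificity(a)
  expect_true(all(cls0$autopod_specific))
})

test_that("random classification matches brute force", {
  withr::local_seed(31)
  combos <- replicate(80, sample(conds, sample(1:6, 1)), simplify = FALSE)
  a <- toy_atlas(combos)
  skel <- list(random_intervals(8, chroms = "chrA", max_pos = 50000),
               random_intervals(8, chroms = "chrA", max_pos = 50000))
  cls <- classify_specificity(a, skel)
  ov <- oracle_intersect_count(a$elements, skel[[1]]) +
    oracle_intersect_count(a$elements, skel[[2]])
  expect_equal(cls$autopod_specific, ov == 0L)
  n_tissue <- vapply(combos, function(cc) {
    length(unique(meta$tissue[match(unique(cc), conds)]))
  }, 0L)
  expect_equal(cls$tissue_and_timepoint_specific, n_tissue == 1L)
})

test_that("axis partitions are a disjoint cover with correct labels", {
  a <- toy_atlas(list(
    "hand.III.phalanges.early",
    c("hand.I.phalanges.early", "foot.I.phalanges.early"),
    c("foot.II.metapodial.late", "foot.IV.metapodial.late")))
  lp <- partition_by_axis(a, "limb")
  expect_equal(lp$subsets$hand_only$name, "el_001")
  expect_equal(lp$subsets$foot_only$name, "el_003")
  expect_equal(lp$subsets$shared$name, "el_002")
  rp <- partition_by_axis(a, "region")
  expect_setequal(rp$subsets$phalanges_only$name, c("el_001", "el_002"))
  tp <- partition_by_axis(a, "timepoint")
  expect_setequal(tp$subsets$early_only$name, c("el_001", "el_002"))
  expect_equal(tp$subsets$late_only$name, "el_003")
  # disjoint cover invariant
  all_names <- unlist(lapply(lp$subsets, function(s) s$name))
  expect_setequal(all_names, a$elements$name)
  expect_equal(anyDuplicated(all_names), 0L)
  expect_error(partition_by_axis(a, "digit"), "unknown axis")
})

test_that("sharing_profile groups exact combinations above the threshold", {
  one <- c("hand.I.phalanges.early", "hand.II.phalanges.early",
           "foot.I.phalanges.early", "hand.I.phalanges.late",
           "foot.III.metapodial.late")
  a <- toy_atlas(rep(list(one), 7)) # 3 early + 2 late tissues
  prof <- sharing_profile(a, min_combination_size = 5)
  expect_equal(prof, data.frame(n_early = 3L, n_late = 2L,
                                n_elements = 7L),
               ignore_attr = TRUE)
  # a 4-element combination is excluded at the default threshold
  a4 <- toy_atlas(rep(list(one), 4))
  expect_equal(nrow(sharing_profile(a4, 5)), 0L)
  expect_equal(sharing_profile(a4, 4)$n_elements, 4L)
})

test_that("random sharing_profile equals a dictionary-of-combinations oracle", {
  withr::local_seed(41)
  pool <- list(conds[1:4], conds[c(2, 21)], conds[30], conds[1:4])
  combos <- sample(pool, 60, replace = TRUE)
  a <- toy_atlas(combos)
  prof <- sharing_profile(a, min_combination_size = 5)
  keys <- vapply(combos, function(cc) {
    paste(sort(match(unique(cc), conds)), collapse = ",")
  }, "")
  sizes <- table(keys)
  expected_total <- sum(sizes[sizes >= 5])
  expect_equal(sum(prof$n_elements), expected_total)
  # totals bounded by the element count, equality iff nothing was dropped
  expect_lte(sum(prof$n_elements), nrow(a$elements))
})

test_that("cross-species sharing counts lifted overlaps", {
  a <- toy_atlas(list(conds[1], conds[2], conds[3]))
  same <- a$elements
  res <- cross_species_shared(a, same)
  expect_equal(res$n_shared, 3L)
  expect_equal(res$fraction, 1)
  res0 <- cross_species_shared(a, interval_set("chrZ", 0, 10))
  expect_equal(res0$n_shared, 0L)
  spec <- c(TRUE, FALSE, TRUE)
  res2 <- cross_species_shared(a, interval_set("chrA", 0, 10),
                               autopod_specific = spec)
  expect_equal(res2$n_shared, 1L)
  expect_equal(res2$n_shared_specific, 1L)
  expect_equal(res2$fraction_specific, 0.5)
})
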