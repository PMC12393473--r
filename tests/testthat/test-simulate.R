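test_that("null simulation yields three identical genomes and identity chains", {
  sim <- simulate_trio(trio_sim_params(chrom_length = 2000,
                                       n_target_fixed = 0,
                                       n_sister_fixed = 0,
                                       n_polymorphic = 0, seed = 4))
  expect_equal(as.character(sim$target$seq[[1]]),
               as.character(sim$sister$seq[[1]]))
  expect_equal(as.character(sim$target$seq[[1]]),
               as.character(sim$outgroup$seq[[1]]))
  b <- sim$chain_sister$blocks
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$s_start, b$s_end, b$t_start, b$t_end), c(0, 2000, 0, 2000))
})

test_that("planted substitutions are recovered by a full genome scan", {
  sim <- simulate_trio(trio_sim_params(chrom_length = 1000,
                                       n_target_fixed = 5,
                                       n_sister_fixed = 3,
                                       n_polymorphic = 0, seed = 11))
  t <- strsplit(as.character(sim$target$seq[[1]]), "")[[1]]
  s <- strsplit(as.character(sim$sister$seq[[1]]), "")[[1]]
  o <- strsplit(as.character(sim$outgroup$seq[[1]]), "")[[1]]
  expect_equal(which(t != s & s == o) - 1, sim$truth$target_fixed)
  expect_equal(which(s != t & t == o) - 1, sim$truth$sister_fixed)
  expect_length(sim$truth$target_fixed, 5L)
  expect_length(sim$truth$sister_fixed, 3L)
})

test_that("identical seeds give identical truth; params are validated", {
  p <- trio_sim_params(chrom_length = 3000, n_target_fixed = 10,
                       n_sister_fixed = 10, n_polymorphic = 20, seed = 9)
  expect_identical(simulate_trio(p)$truth, simulate_trio(p)$truth)
  expect_error(trio_sim_params(chrom_length = 10, n_target_fixed = 8,
                               n_sister_fixed = 8),
               "more planted substitutions than positions")
  expect_error(trio_sim_params(chrom_length = 100, n_target_fixed = 0,
                               n_sister_fixed = 0,
                               indel_blocks = list(c(90, 20))),
               "outside chromosome")
})

test_that("indel blocks shorten sister/outgroup and puncture the chain", {
  sim <- simulate_trio(trio_sim_params(chrom_length = 1000,
                                       n_target_fixed = 0,
                                       n_sister_fixed = 0,
                                       n_polymorphic = 0,
                                       indel_blocks = list(c(100, 50),
                                                           c(400, 10)),
                                       seed = 2))
  expect_equal(unname(seq_lengths(sim$sister)), 940)
  expect_equal(unname(seq_lengths(sim$target)), 1000)
  expect_equal(nrow(sim$chain_sister$blocks), 3L)
  r <- liftover_interval(interval_set("chrS", 110, 140), sim$chain_sister)
  expect_equal(r$reason, "no_coverage")
  # bases after a deletion shift left by the cumulative deleted length
  m <- map_positions(sim$chain_sister, "chrS", c(0, 99, 150, 500))
  expect_equal(m$t_pos, c(0, 99, 100, 440))
})

test_that("simulated trio round-trips through its file formats", {
  sim <- simulate_trio(trio_sim_params(chrom_length = 500,
                                       n_target_fixed = 3,
                                       n_sister_fixed = 2,
                                       n_polymorphic = 5,
                                       indel_blocks = list(c(200, 20)),
                                       seed = 6))
  dir <- withr::local_tempdir()
  write_trio(sim, dir)
  expect_equal(as.character(read_fasta(file.path(dir, "sister.fa"))$seq),
               as.character(sim$sister$seq))
  expect_equal(read_chain(file.path(dir, "target_sister.tsv"))$blocks,
               sim$chain_sister$blocks)
  expect_equal(read_chain(file.path(dir, "target_sister.chain"))$blocks,
               sim$chain_sister$blocks, ignore_attr = TRUE)
  cat_back <- read_variant_catalog(file.path(dir, "snps_target.tsv"))
  expect_equal(cat_back$pos, sim$catalogs$target$pos)
  expect_equal(cat_back$maf, sim$catalogs$target$maf)
})

test_that("simulate_atlas honours the sharing specification", {
  conds <- autopod_conditions()
  # everything accessible everywhere
  res <- simulate_atlas(20, sharing_spec = list(
    list(combination = conds, prob = 1)), seed = 3)
  expect_true(all(res$atlas$matrix))
  # planted hand-only combination is recovered by the limb partition
  hand <- conds[condition_meta(conds)$limb == "hand"]
  res2 <- simulate_atlas(50, sharing_spec = list(
    list(combination = hand, prob = 0.4),
    list(combination = conds, prob = 0.6)), seed = 8)
  part <- partition_by_axis(res2$atlas, "limb")
  planted <- res2$atlas$elements$name[res2$combo_index == 1L]
  expect_setequal(part$subsets$hand_only$name, planted)
  expect_equal(nrow(part$subsets$foot_only), 0L)
})

test_that("combination draws fall within binomial 99% bounds", {
  conds <- autopod_conditions()
  spec <- list(list(combination = conds[1:10], prob = 0.5),
               list(combination = conds[11:20], prob = 0.3),
               list(combination = conds[21:30], prob = 0.2))
  res <- simulate_atlas(1000, sharing_spec = spec, seed = 123)
  counts <- tabulate(res$combo_index, 3L)
  for (k in 1:3) {
    bounds <- stats::qbinom(c(0.005, 0.995), 1000, spec[[k]]$prob)
    expect_gte(counts[k], bounds[1])
    expect_lte(counts[k], bounds[2])
  }
})

test_that("score-track simulation plants a detectable shift", {
  # empty constrained set -> background only
  tr0 <- simulate_score_track(integer(0), shift = 5, noise_sd = 0.5,
                              seed = 1, background_positions = 0:99)
  expect_equal(nrow(tr0), 100L)
  expect_lt(abs(mean(tr0$score)), 0.5)
  # planted shift 1.0, sd 0.5, n = 1000/group
  tr <- simulate_score_track(1000:1999, shift = 1, noise_sd = 0.5,
                             seed = 2, background_positions = 0:999)
  bg <- fetch_scores(tr, "chrS", 0:999)
  fg <- fetch_scores(tr, "chrS", 1000:1999)
  expect_lt(stats::wilcox.test(fg, bg)$p.value, 0.01)
  expect_gt(mean(fg) - mean(bg), 0.8)
})

test_that("measurement simulation plants known percent change", {
  tab <- simulate_measurements(n_per_species = 30,
                               scale = list(human = 0.85, gorilla = 1.1),
                               cv = 0.02, seed = 5)
  pc <- percent_change(combine_phalanges(tab), "human", "chimpanzee")
  expect_true(all(abs(pc$percent - 85) < 3))
})
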