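surveyed <- function(target, sister, outgroup, start = 0) {
  t <- strsplit(target, "")[[1]]
  s <- strsplit(sister, "")[[1]]
  o <- strsplit(outgroup, "")[[1]]
  structure(list(interval = interval_set("chr1", start,
                                         start + length(t)),
                 target_seq = t, sister_seq = s, outgroup_seq = o,
                 identity_sister = sequence_identity(t, s),
                 identity_outgroup = sequence_identity(t, o),
                 rejection = NA_character_),
            class = "surveyed_fragment")
}

test_that("standardisation centres on the midpoint at fixed length", {
  cl <- c(chr1 = 1e6)
  std <- standardize_to_length(interval_set("chr1", 1000, 1200), 500, cl)
  expect_equal(c(std$accepted$start, std$accepted$end), c(850, 1350))
  # already the right length: unchanged
  std2 <- standardize_to_length(interval_set("chr1", 2000, 2500), 500, cl)
  expect_equal(c(std2$accepted$start, std2$accepted$end), c(2000, 2500))
  # near the chromosome start: rejected, never clamped
  std3 <- standardize_to_length(interval_set("chr1", 90, 110), 500, cl)
  expect_equal(nrow(std3$accepted), 0L)
  expect_equal(nrow(std3$rejected), 1L)
  # odd input length: floor of the midpoint
  std4 <- standardize_to_length(interval_set("chr1", 1000, 1201), 500, cl)
  expect_equal(std4$accepted$start, 1100 - 250)
})

test_that("masking removes common SNPs from any species and blacklist", {
  els <- interval_set("chr1", 0, 500, name = "el")
  cats <- list(target = variant_catalog("t", "chr1", 250, 0.2),
               sister = variant_catalog("s"),
               outgroup = variant_catalog("o"))
  frags <- mask_and_fragment(els, cats)
  expect_equal(frags$start, c(0, 251))
  expect_equal(frags$end, c(250, 500))
  expect_equal(frags$end - frags$start, c(250, 249))
  expect_equal(frags$name, c("el", "el"))
  # rare variant (MAF <= 0.05) is kept
  rare <- list(target = variant_catalog("t", "chr1", 250, 0.05),
               sister = variant_catalog("s"), outgroup = variant_catalog("o"))
  expect_equal(nrow(mask_and_fragment(els, rare)), 1L)
  # blacklist subtraction
  bl <- mask_and_fragment(els, rare, blacklist = interval_set("chr1", 0, 100))
  expect_equal(bl$start, 100)
  # no variants, no blacklist: unchanged
  none <- list(target = variant_catalog("t"), sister = variant_catalog("s"),
               outgroup = variant_catalog("o"))
  expect_equal(as.data.frame(mask_and_fragment(els, none)),
               as.data.frame(els))
})

test_that("sequence identity excludes N positions", {
  expect_equal(sequence_identity("ACGT", "ACGT"), 1)
  expect_equal(sequence_identity("AAAA", "CCCC"), 0)
  expect_equal(sequence_identity("ACGT", "ACGA"), 0.75)
  expect_equal(sequence_identity("ACGN", "ACTN"), 2 / 3)
  expect_true(is.na(sequence_identity("NN", "NN")))
  expect_error(sequence_identity("ACG", "AC"), "mismatch")
})

test_that("derived calls follow two-outgroup parsimony", {
  sf <- surveyed("AAGT", "ACGT", "ACGT")
  expect_equal(call_derived_positions(sf, "target"), 1)
  expect_equal(call_derived_positions(sf, "sister"), numeric(0))
  # three-way disagreement is parsimony-uninformative
  sf2 <- surveyed("AAGT", "AGGT", "ACGT")
  expect_equal(call_derived_positions(sf2, "target"), numeric(0))
  expect_equal(call_derived_positions(sf2, "sister"), numeric(0))
  # sister-derived site
  sf3 <- surveyed("ACGT", "ACTT", "ACGT", start = 100)
  expect_equal(call_derived_positions(sf3, "sister"), 102)
  # N at any of the three suppresses the call
  sf4 <- surveyed("AAGT", "ANGT", "ACGT")
  expect_equal(call_derived_positions(sf4, "target"), numeric(0))
})

test_that("fragment mapping demands full-length single-locus liftover", {
  sim <- simulate_trio(trio_sim_params(chrom_length = 2000,
                                       n_target_fixed = 4,
                                       n_sister_fixed = 0,
                                       n_polymorphic = 0,
                                       indel_blocks = list(c(1000, 100)),
                                       seed = 13))
  ctx <- trio_context_from_sim(sim)
  ok <- map_fragment_to_trio(interval_set("chrS", 0, 500), ctx)
  expect_true(is.na(ok$rejection))
  expect_equal(length(ok$sister_seq), 500L)
  expect_gt(ok$identity_outgroup, 0.99) # 4 planted substitutions on 2 kb
  gap <- map_fragment_to_trio(interval_set("chrS", 950, 1150), ctx)
  expect_equal(gap$rejection, "unmappable_sister")
})

test_that("clean simulations are recovered exactly; swapping lineages swaps", {
  sim <- simulate_trio(trio_sim_params(chrom_length = 20000,
                                       n_target_fixed = 30,
                                       n_sister_fixed = 20,
                                       n_polymorphic = 0, seed = 17))
  ctx <- trio_context_from_sim(sim)
  starts <- seq(0, 20000 - 500, by = 500)
  els <- interval_set("chrS", starts, starts + 500)
  rep <- run_divergence(list(all = els), ctx)
  expect_equal(rep$summary$derived_count, c(30L, 20L))
  expect_equal(rep$derived$all$target, sim$truth$target_fixed)
  expect_equal(rep$derived$all$sister, sim$truth$sister_fixed)
  expect_equal(rep$summary$rate_per_bp, c(30, 20) / 20000)
  # swapping target and sister genomes swaps the two columns
  ctx_sw <- trio_context(sim$sister, sim$target, sim$outgroup,
                         sim$chain_sister, sim$chain_outgroup,
                         sim$catalogs)
  rep_sw <- run_divergence(list(all = els), ctx_sw)
  expect_equal(rep_sw$summary$derived_count, c(20L, 30L))
  # identical genomes give zero everywhere
  null <- simulate_trio(trio_sim_params(chrom_length = 5000,
                                        n_target_fixed = 0,
                                        n_sister_fixed = 0,
                                        n_polymorphic = 0, seed = 1))
  rep0 <- run_divergence(list(all = interval_set("chrS", 0, 500)),
                         trio_context_from_sim(null))
  expect_equal(rep0$summary$derived_count, c(0L, 0L))
})

test_that("adding masked variants never increases the surveyed counts", {
  sim <- simulate_trio(trio_sim_params(chrom_length = 10000,
                                       n_target_fixed = 20,
                                       n_sister_fixed = 10,
                                       n_polymorphic = 0, seed = 23))
  els <- interval_set("chrS", seq(0, 9500, by = 500),
                      seq(500, 10000, by = 500))
  base <- run_divergence(list(all = els), trio_context_from_sim(sim))
  withr::local_seed(29)
  grow <- sim
  prev_bp <- base$summary$bp_surveyed[1]
  prev_n <- base$summary$derived_count
  for (extra in c(50, 200)) {
    pos <- sort(sample(0:9999, extra))
    grow$catalogs$target <- variant_catalog("target", "chrS", pos,
                                            rep(0.3, extra))
    rep <- run_divergence(list(all = els), trio_context_from_sim(grow))
    expect_lte(rep$summary$bp_surveyed[1], prev_bp)
    expect_true(all(rep$summary$derived_count <= prev_n))
    prev_bp <- rep$summary$bp_surveyed[1]
    prev_n <- rep$summary$derived_count
  }
})

test_that("the identity gate excludes fragments but never flips calls", {
  sim <- simulate_trio(trio_sim_params(chrom_length = 4000,
                                       n_target_fixed = 15,
                                       n_sister_fixed = 5,
                                       n_polymorphic = 0, seed = 31))
  ctx <- trio_context_from_sim(sim)
  els <- interval_set("chrS", seq(0, 3500, by = 500),
                      seq(500, 4000, by = 500))
  strict <- run_divergence(list(all = els), ctx,
                           divergence_config(min_identity = 0.25))
  loose <- run_divergence(list(all = els), ctx,
                          divergence_config(min_identity = 1e-9))
  expect_equal(strict$derived, loose$derived)
  # min_identity = 1 with at least one mismatch per fragment rejects all
  gated <- run_divergence(list(all = els), ctx,
                          divergence_config(min_identity = 1))
  rej <- gated$rejections
  n_accepted <- gated$summary$bp_surveyed[1] / 500
  expect_equal(sum(rej$n[rej$reason == "low_identity"]),
               nrow(els) - n_accepted)
  # fragments surviving a perfect-identity gate carry no derived calls
  expect_equal(gated$summary$derived_count, c(0L, 0L))
})

test_that("conservation shift test reports means and rank-sum p", {
  same <- c(0.1, 0.4, -0.2, 0.8, 0.3)
  res <- conservation_shift_test(same, same)
  expect_equal(res$p_value, 1)
  expect_equal(res$mean_target, res$mean_sister)
  # complete separation, n = 50 each: astronomically small exact p
  res2 <- conservation_shift_test(51:100, 1:50)
  expect_lt(res2$p_value, 1e-15)
  # NA scores are excluded and counted
  res3 <- conservation_shift_test(c(1, 2, NA), c(0, 1))
  expect_equal(res3$n_missing, 1L)
  expect_equal(res3$n_target, 2L)
  expect_error(conservation_shift_test(numeric(0), 1:3), "non-empty")
  # planted shift detected
  withr::local_seed(37)
  x <- stats::rnorm(1000, 1, 0.5)
  y <- stats::rnorm(1000, 0, 0.5)
  expect_lt(conservation_shift_test(x, y)$p_value, 0.01)
})
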