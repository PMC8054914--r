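test_that("stick-breaking architectures respect sizes and CCF bounds", {
  a0 <- draw_architecture(0, 1000, 1)
  expect_equal(a0$n_subclones, 0L)
  expect_equal(sum(a0$cluster_sizes), 1000L)
  a1 <- draw_architecture(2, 800, 0.8, rng_seed = 1)
  expect_equal(sum(a1$cluster_sizes[-1]), 200L)  # 800 * 0.2 / 0.8
  expect_error(draw_architecture(1, 100, 1), "f_clonal")
  # property over seeds: sizes partition N_subclonal, CCFs in (0.1, 0.9)
  set.seed(99)
  for (s in sample.int(1e6, 200)) {
    a <- draw_architecture(2, 1000, 0.8, rng_seed = s)
    expect_equal(sum(a$cluster_sizes[-1]), 250L)
    expect_true(all(a$cluster_sizes >= 1))
    expect_true(all(a$cluster_ccfs[-1] > 0.1 & a$cluster_ccfs[-1] < 0.9))
    expect_false(anyDuplicated(a$cluster_ccfs) > 0)
  }
})

test_that("read model reproduces the analytic expected VAF", {
  # C=100, rho=0.5, psi=2, clonal single copy on (1,1): ct=cn=25,
  # E_rm=25, E_rw=75 -> expected VAF 0.25
  prof <- test_profile(0.5, 100)
  cn <- test_genome()
  arch <- architecture_spec(c(1), 20000)
  sim <- simulate_reads(arch, cn, prof, rng_seed = 1, keep_filtered = TRUE)
  expect_equal(unique(round(sim$expected_vaf, 10)), 0.25)
  vafs <- sim$alt_count / pmax(sim$total_count, 1)
  se <- sd(vafs) / sqrt(nrow(sim))
  expect_lt(abs(mean(vafs) - 0.25), 3 * se + 1e-4)
  # fully mutated pure case: rho=1, f=1, mm=2 on (2,0) -> VAF 1
  pure <- sample_profile(1, 2, coverage = 60)
  cn20 <- caller_copy_profile("t", data.frame(
    chrom = "1", start = 0, end = 1e7, major = 2, minor = 0,
    is_clonal = TRUE))
  arch2 <- architecture_spec(c(1), 500, multiplicity_rate = 100)  # clamp to 2
  sim2 <- simulate_reads(arch2, cn20, pure, rng_seed = 2)
  expect_true(all(sim2$multiplicity == 2))
  expect_equal(unique(round(sim2$expected_vaf, 10)), 1)
})

test_that("detection filter truncates from below and biases CCF upward", {
  prof <- test_profile(0.5, 20)   # low power: nrpcc 5
  cn <- test_genome()
  arch <- architecture_spec(c(1, 0.3), c(2000, 2000))
  sim <- simulate_reads(arch, cn, prof, rng_seed = 3, keep_filtered = TRUE)
  expect_true(all(sim$alt_count[sim$detected] >= 3))
  sub <- sim[sim$cluster == 2, ]
  # conditional mean above unconditional mean (truncation from below)
  expect_gt(mean(sub$alt_count[sub$detected]), mean(sub$alt_count))
  # observed CCF biased above truth
  det <- sub[sub$detected, ]
  est <- snv_ccf(det$alt_count / det$total_count, prof,
                 det$major_cn + det$minor_cn)
  expect_gt(mean(est$ccf), 0.3)
})

test_that("grid has 600 cells and two-pass sampling covers ~462", {
  g <- build_grid()
  expect_equal(nrow(g), 600L)
  expect_equal(length(unique(g$purity)), 6L)
  expect_true(1e5 %in% g$n_clonal)
  expect_true(0.995 %in% g$f_clonal)
  expect_equal(attr(g, "coverage"), 48.46621)
  expect_length(two_pass_sample(g, 0, 0), 0L)
  s <- two_pass_sample(g, rng_seed = 1)
  expect_length(s, 700L)
  # pass 2 draws only from cells uncovered after pass 1
  p1 <- s[1:600]
  p2 <- s[601:700]
  expect_length(intersect(unique(p1), p2), 0L)
  set.seed(10)
  cover <- vapply(1:300, function(i)
    length(unique(two_pass_sample(g))), numeric(1))
  expect_lt(abs(mean(cover) - 462), 5)
})

test_that("calibration finds an input count within 5% of target", {
  prof <- test_profile(0.5, 30)
  cn <- test_genome()
  # low-CCF subclone: filtering removes some, so n_input > target
  arch <- architecture_spec(c(1, 0.3), c(300, 300))
  cal <- calibrate_n_input(400, arch, cn, prof, n_sims = 4, rng_seed = 5)
  expect_true(cal$converged)
  expect_lt(abs(cal$mean_output - 400), 400 / 20)
  expect_gte(cal$n_input, 400)
  # high power: nothing filtered, n_input ~ target
  prof_hi <- test_profile(0.9, 120)
  cal_hi <- calibrate_n_input(400, architecture_spec(c(1), 400), cn,
                              prof_hi, n_sims = 4, rng_seed = 6)
  expect_equal(cal_hi$n_input, 400)
})

test_that("diploid twin purity preserves nrpcc exactly", {
  for (rho in c(0.3, 0.55, 0.9)) for (psi in c(1.8, 2.7, 3.9)) {
    prof <- sample_profile(rho, psi, coverage = 48.46621)
    rho_d <- diploid_twin_purity(rho, psi)
    twin <- sample_profile(rho_d, 2, coverage = 48.46621)
    expect_lt(abs(compute_nrpcc(prof) - compute_nrpcc(twin)), 1e-6)
  }
  expect_equal(diploid_twin_purity(0.8, 4, formula = "ploidy_ratio"), 0.4)
})

test_that("expected allele fraction covers both copy-number cases", {
  expect_equal(phylogicsim_expected_af(1, 1, purity = 1, cn_clonal = 2),
               0.5)
  expect_equal(phylogicsim_expected_af(1, 1, purity = 0.5, cn_clonal = 2),
               0.25)
  # case b with ccf_scna = 0 reduces to case a
  for (ccf in c(0.3, 1)) {
    a <- phylogicsim_expected_af(ccf, 1, purity = 0.6, cn_clonal = 3)
    b <- phylogicsim_expected_af(ccf, purity = 0.6, cn_clonal = 3,
                                 cn_sub = 4, ccf_scna = 0, mult_cl = 1)
    expect_equal(a, b)
  }
  expect_error(
    phylogicsim_expected_af(0.5, purity = 0.6, cn_clonal = 2, cn_sub = 3,
                            ccf_scna = 0.3, mult_cl = 1, mult_sub = 1),
    "constraint")
  # beta-binomial coverage has the right mean
  set.seed(7)
  cov <- sample_coverage(8, 72, n = 500, n_sites = 4000)
  expect_lt(abs(mean(cov) - 500 * 8 / 80), 2)
})

test_that("noisy caller purity stays in (0, 1]", {
  set.seed(8)
  p <- noisy_purity(rep(0.98, 1000), mad = 0.05)
  expect_true(all(p > 0 & p <= 1))
  expect_lt(max(abs(p - 0.98)), 0.051)
})
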