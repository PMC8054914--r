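test_that("pair classification follows the haplotype rules", {
  # in-cis with one-direction support on major = 1: collinear, SNV1 first
  r <- classify_pair(phase_pair_evidence(3, 2, 0, 1, 0), violations = 0.2)
  expect_equal(r$label, "collinear")
  expect_equal(r$ancestral, 1L)
  # mutually exclusive on clonal 1+0: branching
  expect_equal(classify_pair(phase_pair_evidence(0, 2, 2, 1, 0))$label,
               "branching")
  # below thresholds: unpowered
  expect_equal(classify_pair(phase_pair_evidence(1, 1, 0, 1, 1))$label,
               "unpowered")
  # in-cis but wrong copy-number context: uninformative
  expect_equal(classify_pair(phase_pair_evidence(4, 3, 0, 2, 1))$label,
               "phased_cis_uninformative")
  # infinite-sites violations block collinear unless haploid
  expect_equal(classify_pair(phase_pair_evidence(3, 2, 0, 1, 1),
                             violations = 2)$label,
               "phased_cis_uninformative")
  expect_equal(classify_pair(phase_pair_evidence(3, 2, 0, 1, 0),
                             violations = 2)$label, "collinear")
  # mutually exclusive in a diploid region: trans, not branching
  expect_equal(classify_pair(phase_pair_evidence(0, 3, 3, 1, 1))$label,
               "trans_diploid")
  # all three haplotypes on one copy: inconsistent
  expect_equal(classify_pair(phase_pair_evidence(3, 2, 2, 1, 0))$label,
               "inconsistent")
  expect_error(phase_pair_evidence(-1, 0, 0, 1, 0), "counts")
})

test_that("classification is symmetric up to the reported direction", {
  swap <- function(ev) phase_pair_evidence(ev$n_mutmut, ev$n_wtmut,
                                           ev$n_mutwt, ev$major_cn,
                                           ev$minor_cn, ev$is_clonal)
  cases <- list(phase_pair_evidence(3, 2, 0, 1, 0),
                phase_pair_evidence(0, 2, 2, 1, 0),
                phase_pair_evidence(0, 4, 2, 1, 1),
                phase_pair_evidence(1, 1, 1, 1, 0))
  for (ev in cases) {
    a <- classify_pair(ev, 0)
    b <- classify_pair(swap(ev), 0)
    expect_equal(a$label, b$label)
    if (a$label == "collinear") {
      expect_equal(a$ancestral, 3L - b$ancestral)
    }
  }
})

test_that("simulated pairs from known trees are labeled perfectly", {
  set.seed(71)
  n_ok <- 0
  for (i in 1:200) {
    topo <- if (i %% 2 == 0) "linear" else "branching"
    ev <- simulate_phase_pair(topo, depth = 60,
                              ccf_a = runif(1, 0.4, 0.7),
                              ccf_b = runif(1, 0.15, 0.35))
    lab <- classify_pair(ev, violations = 0)$label
    # only score pairs meeting the count thresholds
    powered <- if (topo == "linear") {
      ev$n_mutmut >= 2 && xor(ev$n_mutwt >= 2, ev$n_wtmut >= 2)
    } else {
      ev$n_mutmut == 0 && ev$n_mutwt >= 2 && ev$n_wtmut >= 2
    }
    if (!powered) next
    n_ok <- n_ok + 1
    expect_equal(lab, if (topo == "linear") "collinear" else "branching",
                 info = paste("case", i))
  }
  expect_gt(n_ok, 100)   # most cases are powered at depth 60
})

test_that("infinite-sites expectation matches exact slot enumeration", {
  # 2 SNVs, one context, 4 positions x 2 alleles: P(double hit) = 1/7
  r <- infinite_sites_rate(c(ACA = 2), c(ACA = 4), n_sims = 30000,
                           rng_seed = 72)
  expect_lt(abs(r$expected_double_hits - 1 / 7), 0.01)
  # single SNV never violates
  r1 <- infinite_sites_rate(c(ACA = 1), c(ACA = 10), n_sims = 50,
                            rng_seed = 73)
  expect_equal(r1$expected_double_hits, 0)
  # doubling the callable genome roughly halves the rate
  r_small <- infinite_sites_rate(c(ACA = 20), c(ACA = 200), n_sims = 3000,
                                 rng_seed = 74)
  r_big <- infinite_sites_rate(c(ACA = 20), c(ACA = 400), n_sims = 3000,
                               rng_seed = 75)
  expect_gt(r_small$expected_double_hits,
            1.6 * r_big$expected_double_hits)
  expect_warning(infinite_sites_rate(c(XXX = 2), c(ACA = 5), n_sims = 2),
                 "skipped")
})

test_that("tree odds distinguish star, chain and balanced topologies", {
  star <- list(c(0, 1, 1, 1))          # root + 3 siblings
  expect_equal(tree_odds(star, n_reps = 50, rng_seed = 76)$odds, Inf)
  chain <- list(c(0, 1, 2))            # root -> A -> B
  expect_equal(tree_odds(chain, n_reps = 50, rng_seed = 77)$odds, 0)
  # balanced tree: nodes 2,3 under root; leaves 4,5 under 2 and 6,7 under 3.
  # Exhaustive tally over the C(6,2) = 15 subclone pairs: siblings (2,3),
  # (4,5), (6,7); parent-child (2,4), (2,5), (3,6), (3,7); cousins/other
  # excluded from both tallies -> long-run odds 3/4.
  bal <- c(0, 1, 1, 2, 2, 3, 3)
  r <- tree_odds(rep(list(bal), 60), n_reps = 800, rng_seed = 78)
  expect_lt(abs(r$odds - 3 / 4), 0.15)
  expect_true(r$ci[1] <= r$odds && r$odds <= r$ci[2])
})

test_that("branching odds come with a bootstrap interval", {
  labels <- c(rep("branching", 30), rep("collinear", 10),
              rep("phased_cis_uninformative", 100))
  r <- branching_odds(labels, n_boot = 500, rng_seed = 80)
  expect_equal(r$odds, 3)
  expect_equal(r$n_branching, 30)
  expect_equal(r$n_linear, 10)
  expect_true(r$ci[1] < 3 && r$ci[2] > 3)
  # no linear pairs: infinite odds, flagged
  inf <- branching_odds(rep("branching", 5), n_boot = 10, rng_seed = 81)
  expect_true(is.infinite(inf$odds))
  expect_true(inf$degenerate)
})
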