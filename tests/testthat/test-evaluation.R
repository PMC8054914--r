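hard_clustering <- function(props, locs, labels = NULL, scale = "CCF") {
  cl <- clustering(props, locs, scale = scale)
  if (!is.null(labels)) {
    z <- matrix(0, length(labels), length(cl$locations))
    z[cbind(seq_along(labels), labels)] <- 1
    cl$assignments <- z
  }
  cl
}

test_that("perfect reconstructions score (1, 1, 1)", {
  labels <- rep(c(1L, 2L), c(30, 70))
  truth <- hard_clustering(c(0.3, 0.7), c(0.4, 1), labels)
  s <- score_reconstruction(truth, truth, purity = 0.8)
  expect_equal(unname(s), c(1, 1, 1))
})

test_that("NCD is asymmetric, favoring underestimation", {
  expect_equal(ncd(2, 3), 1 - abs(exp(-1 / 3) - 1))
  expect_equal(round(ncd(2, 3), 4), 0.7165)
  expect_lt(ncd(4, 3), ncd(2, 3))
  # NCD(C_O = C_T) = 1 and strictly decreasing in |C_O - C_T|, both sides;
  # overestimation by k always scores below underestimation by k
  for (ct in 2:10) {
    expect_equal(ncd(ct, ct), 1)
    for (k in seq_len(ct - 1)) {
      expect_lt(ncd(ct + k, ct), ncd(ct + k - 1, ct))
      expect_lt(ncd(ct - k, ct), ncd(ct - k + 1, ct))
      expect_lt(ncd(ct + k, ct), ncd(ct - k, ct))
    }
  }
  # the clipped metric inside score_reconstruction agrees where positive
  t3 <- hard_clustering(rep(1 / 3, 3), c(0.3, 0.6, 1))
  c2 <- hard_clustering(c(0.5, 0.5), c(0.4, 1))
  expect_equal(unname(score_reconstruction(t3, c2, 0.8)["ncd"]),
               ncd(2, 3))
})

test_that("RMSE term has its closed form under constant CP error", {
  n <- 200
  labels <- rep(1L, n)
  truth <- hard_clustering(1, 0.8, labels, scale = "CP")
  call <- hard_clustering(1, 0.7, labels, scale = "CP")
  s <- score_reconstruction(truth, call, purity = 0.5)
  expect_equal(unname(s["rmse"]), 1 - 0.1 / 0.5)
  # invariant to SNV order (assignments permuted consistently)
  labels2 <- rep(c(1L, 2L), each = 100)
  t2 <- hard_clustering(c(0.5, 0.5), c(0.3, 1), labels2)
  c2 <- hard_clustering(c(0.5, 0.5), c(0.35, 0.95), labels2)
  perm <- sample(200)
  t2p <- t2; t2p$assignments <- t2$assignments[perm, ]
  c2p <- c2; c2p$assignments <- c2$assignments[perm, ]
  expect_equal(score_reconstruction(t2, c2, 0.8)["rmse"],
               score_reconstruction(t2p, c2p, 0.8)["rmse"])
})

test_that("missing truth clonal fraction yields NA CFC", {
  truth <- hard_clustering(1, 0.4)   # no clonal cluster
  call <- hard_clustering(1, 1)
  expect_true(is.na(score_reconstruction(truth, call, 0.8)["cfc"]))
})

test_that("rank normalization orients best = 1 and handles ties", {
  # metric scores for 3 methods on 1 sample: ranks (3, 1, 2) -> (1, 0, 0.5)
  arr <- array(NA_real_, c(1, 3, 1))
  arr[1, , 1] <- c(0.9, 0.2, 0.5)
  r <- rank_methods(arr)
  expect_equal(as.numeric(r$normalized[1, , 1]), c(1, 0, 0.5))
  # all tied: everyone gets 1
  arr[1, , 1] <- c(0.4, 0.4, 0.4)
  expect_equal(as.numeric(rank_methods(arr)$normalized[1, , 1]),
               c(1, 1, 1))
})

test_that("pairwise similarities match their formulas", {
  a <- hard_clustering(c(0.5, 0.5), c(0.4, 1))
  expect_equal(unname(method_similarity(a, a, 0.8)[c("cf_sim", "nc_sim")]),
               c(1, 1))
  # N_i = 2, N_j = 4 -> nc similarity 1/3
  b <- hard_clustering(rep(0.25, 4), c(0.2, 0.4, 0.7, 1))
  expect_equal(unname(method_similarity(a, b, 0.8)["nc_sim"]), 1 / 3)
})

test_that("weighted median interpolates and reduces to the plain median", {
  expect_equal(weighted_median(c(1, 2, 3, 4)), 2.5)
  expect_equal(weighted_median(c(1, 2, 3)), 2)
  expect_equal(weighted_median(c(1, 2, 3), c(0, 0, 1)), 3)
  expect_equal(weighted_median(c(1, 2), c(1, 3)), 2)
  # lower-tie convention used by the consensus internals
  expect_equal(weighted_median(c(1, 2), c(1, 1), interpolate = FALSE), 1)
})

test_that("permutation test separates groups and respects weights", {
  set.seed(101)
  # identical groups: p near 1
  same <- clonality_permutation_test(runif(20), runif(20), n_perm = 300,
                                     rng_seed = 1)
  expect_gt(same$p, 0.2)
  # complete separation (continuous values: point masses make the median
  # statistic degenerate under permutation): p at the resolution floor
  set.seed(7)
  hi <- 0.9 + rnorm(20, 0, 0.01)
  lo <- 0.1 + rnorm(20, 0, 0.01)
  sep <- clonality_permutation_test(hi, lo, n_perm = 2000, rng_seed = 2)
  expect_lte(sep$p, 1 / 2000 + 1e-9)
  expect_gt(sep$delta, 0.75)
  # uniform weights reduce to the unweighted test
  a <- runif(15); b <- runif(15)
  u <- clonality_permutation_test(a, b, n_perm = 500, rng_seed = 3)
  w <- clonality_permutation_test(a, b, rep(2, 15), rep(2, 15),
                                  n_perm = 500, rng_seed = 3)
  expect_equal(u$delta, w$delta)
  expect_equal(u$p, w$p)
  # tiny groups are skipped
  expect_true(clonality_permutation_test(0.5, c(0.1, 0.2))$skipped)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.5)),
               p.adjust(c(0.01, 0.02, 0.5), method = "BH"))
})

test_that("consensus outperforms the median individual method on
           simulated tumors", {
  set.seed(102)
  prof <- test_profile(0.6, 50)
  cn <- test_genome()
  totals <- matrix(NA_real_, 12, 4,
                   dimnames = list(NULL, c("weme", "m1", "m2", "stick")))
  for (i in 1:12) {
    arch <- architecture_spec(c(1, runif(1, 0.3, 0.6)),
                              c(500, sample(250:400, 1)))
    sim <- simulate_reads(arch, cn, prof, rng_seed = 200 + i)
    est <- snv_ccf(sim$alt_count / sim$total_count, prof,
                   sim$major_cn + sim$minor_cn)
    ccfs <- pmin(est$ccf, 1.5)
    jit <- function() pmin(pmax(ccfs + rnorm(length(ccfs), 0, 0.02), 0),
                           1.5)
    methods <- list(m1 = reference_cluster(ccfs),
                    m2 = reference_cluster(jit()),
                    m3 = reference_cluster(jit()),
                    stick = randomclone(ccfs, "stick"))
    cons <- weme_consensus(methods)
    truth <- clustering(arch$cluster_sizes / sum(arch$cluster_sizes),
                        arch$cluster_ccfs)
    score <- function(cl) {
      s <- score_reconstruction(truth, cl, 0.6)
      mean(s[c("cfc", "ncd")], na.rm = TRUE)
    }
    totals[i, ] <- c(score(cons), score(methods$m1), score(methods$m2),
                     score(methods$stick))
  }
  med_individual <- apply(totals[, -1], 1, median)
  expect_gte(mean(totals[, 1]), mean(med_individual) - 0.02)
  # and the consensus clearly beats the random baseline
  expect_gt(mean(totals[, 1]), mean(totals[, 4]))
})
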