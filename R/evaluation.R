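#' Score a subclonal reconstruction against truth
#'
#' Three complementary metrics, each rescaled so 1 is perfect:
#' * CFC (relative clonal fraction change): `1 - |F_O - F_T| / F_T`, where F
#'   is the fraction of mutations in the clonal cluster.
#' * NCD (relative number-of-clusters difference):
#'   `1 - |exp((C_O - C_T)/C_T) - 1|`; the exponent makes the metric punish
#'   overestimation slightly more than underestimation, matching the
#'   lower-bound reporting philosophy for subclone counts.
#' * RMSE score: `1 - sqrt(mean((phi_O - phi_T)^2)) / purity` over per-SNV
#'   cellular prevalences on the shared SNV set.
#'
#' All three are clipped to \[0, 1\].
#'
#' @param truth,call [clustering()] objects with per-SNV assignments (CP for
#'   the RMSE term is `purity * location` of the assigned cluster).
#' @param purity Sample purity.
#' @param clonal_threshold Locations at or above this (CCF scale) count as
#'   clonal (default 0.9).
#' @return Named numeric vector `c(cfc, ncd, rmse)`; `cfc` is NA when the
#'   truth has no clonal mutations.
#' @export
score_reconstruction <- function(truth, call, purity,
                                 clonal_threshold = 0.9) {
  clonal_frac <- function(cl) {
    sum(cl$proportions[cl$locations >= clonal_threshold])
  }
  f_t <- clonal_frac(truth)
  f_o <- clonal_frac(call)
  cfc <- if (f_t == 0) NA_real_ else 1 - abs(f_o - f_t) / f_t
  ncd_val <- ncd(n_clusters(call), n_clusters(truth))
  rmse <- NA_real_
  if (!is.null(truth$assignments) && !is.null(call$assignments) &&
      nrow(truth$assignments) == nrow(call$assignments)) {
    cp_of <- function(cl) {
      loc_cp <- if (cl$scale == "CP") cl$locations else purity * cl$locations
      as.numeric(cl$assignments %*% loc_cp)
    }
    rmse <- 1 - sqrt(mean((cp_of(call) - cp_of(truth))^2)) / purity
  }
  clip <- function(x) if (is.na(x)) x else min(max(x, 0), 1)
  c(cfc = clip(cfc), ncd = clip(ncd_val), rmse = clip(rmse))
}

#' Relative number-of-clusters difference (unclipped)
#'
#' \deqn{NCD = 1 - |e^{(C_O - C_T)/C_T} - 1|}
#' Equal counts score 1; the exponential makes overestimating the cluster
#' number cost strictly more than underestimating it by the same amount,
#' matching a lower-bound reporting philosophy for subclone counts.
#'
#' @param c_obs Reported number of clusters.
#' @param c_true True number of clusters (>= 1).
#' @return Unclipped score in (-Inf, 1]; [score_reconstruction()] clips to
#'   \[0, 1\].
#' @export
ncd <- function(c_obs, c_true) {
  if (any(c_true < 1)) stop("c_true must be >= 1")
  1 - abs(exp((c_obs - c_true) / c_true) - 1)
}

#' Normalized ranks and total score across methods
#'
#' Within each sample and metric, methods are ranked (best score first) and
#' the rank is normalized to \[0, 1\] with 1 = best:
#' `R = (r - min r) / (max r - min r)` after orienting so the best method
#' gets 1. The total score is the mean normalized rank over metrics, then
#' over samples. When all methods tie on a metric, every method gets rank 1
#' by convention.
#'
#' @param scores 3-d array \[sample, method, metric\] or a list of per-sample
#'   matrices (method x metric).
#' @return List with `normalized` (sample x method x metric array) and
#'   `total` (named method means, 1 = best).
#' @export
rank_methods <- function(scores) {
  if (is.list(scores)) {
    arr <- simplify2array(scores)        # method x metric x sample
    arr <- aperm(arr, c(3, 1, 2))
  } else {
    arr <- scores
  }
  ns <- dim(arr)[1]
  nm <- dim(arr)[2]
  nk <- dim(arr)[3]
  norm_rank <- array(NA_real_, dim(arr), dimnames = dimnames(arr))
  for (i in seq_len(ns)) for (k in seq_len(nk)) {
    x <- arr[i, , k]
    if (all(is.na(x))) next
    r <- rank(x, na.last = "keep")       # higher score -> higher rank
    rng <- range(r, na.rm = TRUE)
    norm_rank[i, , k] <- if (diff(rng) == 0) {
      rep(1, nm)                          # all tied: everyone best
    } else {
      (r - rng[1]) / (rng[2] - rng[1])
    }
  }
  total <- apply(norm_rank, 2, mean, na.rm = TRUE)
  list(normalized = norm_rank, total = total)
}

#' Pairwise similarity of two reconstructions (no truth needed)
#'
#' Normalized differences over averages: clonal-fraction similarity
#' `1 - 2|F_i - F_j| / (F_i + F_j)`, cluster-number similarity
#' `1 - 2|N_i - N_j| / (N_i + N_j)`, and an RMSE similarity
#' `1 - sqrt(mean((phi_i - phi_j)^2)) / purity` over shared per-SNV CPs.
#'
#' @param c1,c2 [clustering()] objects (assignments required for the RMSE
#'   term).
#' @param purity Sample purity.
#' @param clonal_threshold CCF at or above which a cluster is clonal.
#' @return Named vector `c(cf_sim, nc_sim, rmse_sim)`.
#' @export
method_similarity <- function(c1, c2, purity, clonal_threshold = 0.9) {
  cf <- function(cl) sum(cl$proportions[cl$locations >= clonal_threshold])
  f1 <- cf(c1); f2 <- cf(c2)
  cf_sim <- if (f1 + f2 == 0) 1 else 1 - 2 * abs(f1 - f2) / (f1 + f2)
  n1 <- n_clusters(c1); n2 <- n_clusters(c2)
  nc_sim <- 1 - 2 * abs(n1 - n2) / (n1 + n2)
  rmse_sim <- NA_real_
  if (!is.null(c1$assignments) && !is.null(c2$assignments) &&
      nrow(c1$assignments) == nrow(c2$assignments)) {
    cp_of <- function(cl) {
      loc_cp <- if (cl$scale == "CP") cl$locations else purity * cl$locations
      as.numeric(cl$assignments %*% loc_cp)
    }
    rmse_sim <- 1 - sqrt(mean((cp_of(c1) - cp_of(c2))^2)) / purity
  }
  c(cf_sim = cf_sim, nc_sim = nc_sim, rmse_sim = rmse_sim)
}

#' Standardize a metric vector to the unit interval
#'
#' `(M - min M) / (max M - min M)`; constant vectors map to 1.
#'
#' @param m Numeric vector.
#' @return Rescaled vector in \[0, 1\].
#' @export
standardize_metric <- function(m) {
  rng <- range(m, na.rm = TRUE)
  if (diff(rng) == 0) return(rep(1, length(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Weighted-median permutation test for a difference in subclonal probability
#'
#' Compares the nrpcc-weighted median subclonal probability between two
#' groups of events (e.g. candidate driver versus passenger structural
#' variants). The null distribution is built by permuting group labels; the
#' p value is the fraction of permutations whose absolute weighted-median
#' difference is at least the observed one.
#'
#' @param probs_a,probs_b Subclonal probabilities per event in each group.
#' @param weights_a,weights_b Non-negative per-event weights (nrpcc-derived).
#' @param n_perm Permutations (default 10000).
#' @param rng_seed Optional seed.
#' @return List with `delta` (observed weighted-median difference), `p`
#'   and the group sizes; `p` is NA (test skipped) when either group has
#'   fewer than 2 events.
#' @export
clonality_permutation_test <- function(probs_a, probs_b,
                                       weights_a = rep(1, length(probs_a)),
                                       weights_b = rep(1, length(probs_b)),
                                       n_perm = 10000, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n_a <- length(probs_a)
  n_b <- length(probs_b)
  if (n_a < 2 || n_b < 2) {
    return(list(delta = NA_real_, p = NA_real_, n_a = n_a, n_b = n_b,
                skipped = TRUE))
  }
  delta <- weighted_median(probs_a, weights_a) -
    weighted_median(probs_b, weights_b)
  pool_p <- c(probs_a, probs_b)
  pool_w <- c(weights_a, weights_b)
  n <- n_a + n_b
  hits <- 0L
  for (i in seq_len(n_perm)) {
    ix <- sample.int(n, n_a)
    d <- weighted_median(pool_p[ix], pool_w[ix]) -
      weighted_median(pool_p[-ix], pool_w[-ix])
    if (abs(d) >= abs(delta) - 1e-12) hits <- hits + 1L
  }
  list(delta = delta, p = hits / n_perm, n_a = n_a, n_b = n_b,
       skipped = FALSE)
}

#' Benjamini-Hochberg adjustment of permutation p values across loci
#'
#' Thin wrapper over [stats::p.adjust()] kept for a uniform interface.
#'
#' @param p Numeric vector of p values.
#' @return BH-adjusted q values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
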