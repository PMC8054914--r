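#' Pseudo-time ordering of SNVs and binning of mutation spectra
#'
#' Orders SNVs by average mutation copy number per cell (the product of
#' cellular prevalence and local copy number), descending, as a proxy for
#' relative time of occurrence: early mutations sit at high mutation copy
#' number. Quantization noise on the VAF is removed by resampling each VAF
#' from its Beta(alt + 1, ref + 1) posterior. The ordered SNVs are cut into
#' consecutive bins of `bin_size` (the last bin may be smaller) and each
#' bin's 96-channel trinucleotide spectrum is tallied.
#'
#' @param snvs `data.frame` with `alt_count`, `total_count`, `channel`
#'   (trinucleotide class, integer 1..96 or factor with 96 levels) and
#'   optionally `tumor_cn` (default 2).
#' @param profile A [sample_profile()].
#' @param bin_size SNVs per bin (default 100).
#' @param min_snvs Minimum SNVs required (default 200, i.e. two bins).
#' @param rng_seed Seed for the posterior resampling.
#' @return Object of class `pseudo_timeline`: list with `order` (SNV row
#'   indices, early first), `bins` (bin index per ordered SNV), `counts`
#'   (bins x 96 matrix) and `bin_mcn` (mean mutation copy number per bin).
#' @export
build_timeline <- function(snvs, profile, bin_size = 100, min_snvs = 200,
                           rng_seed = NULL) {
  stopifnot(inherits(profile, "sample_profile"))
  n <- nrow(snvs)
  if (n < min_snvs) {
    stop("need at least ", min_snvs, " SNVs to build a timeline (got ",
         n, ")")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  tumor_cn <- if (!is.null(snvs$tumor_cn)) snvs$tumor_cn else rep(2, n)
  ref <- snvs$total_count - snvs$alt_count
  vaf_post <- stats::rbeta(n, snvs$alt_count + 1, ref + 1)
  rho <- profile$purity
  # mutation copies per tumor cell, the pseudo-time coordinate
  mcn <- vaf_post / rho * (rho * tumor_cn + (1 - rho) * 2)
  ord <- order(mcn, decreasing = TRUE)
  bins <- ceiling(seq_len(n) / bin_size)
  channel <- as.integer(snvs$channel)[ord]
  counts <- matrix(0L, max(bins), 96)
  for (b in seq_len(max(bins))) {
    tab <- tabulate(channel[bins == b], nbins = 96)
    counts[b, ] <- tab
  }
  structure(list(order = ord, bins = bins, counts = counts,
                 bin_mcn = as.numeric(tapply(mcn[ord], bins, mean)),
                 n_snvs = n),
            class = "pseudo_timeline")
}

## EM for fixed-component multinomial mixture weights on one count vector
fit_mixture_weights <- function(x, catalog, n_iter = 500, tol = 1e-10) {
  s <- ncol(catalog)
  if (s == 1L) return(1)
  pi_ <- rep(1 / s, s)
  x <- as.numeric(x)
  for (i in seq_len(n_iter)) {
    mix <- as.numeric(catalog %*% pi_)          # 96-vector
    mix[mix <= 0] <- 1e-300
    resp <- sweep(catalog, 2, pi_, "*") / mix    # 96 x S responsibilities
    new_pi <- as.numeric(crossprod(resp, x))
    new_pi <- new_pi / sum(new_pi)
    if (max(abs(new_pi - pi_)) < tol) {
      pi_ <- new_pi
      break
    }
    pi_ <- new_pi
  }
  pi_
}

## multinomial mixture log-likelihood of count vector x at weights pi
mixture_loglik <- function(x, catalog, pi_) {
  mix <- as.numeric(catalog %*% pi_)
  mix[mix <= 0] <- 1e-300
  sum(x * log(mix))
}

#' Fit signature activity trajectories along a pseudo-timeline
#'
#' At each time point a mixture of multinomials is fitted by EM, with the
#' component distributions fixed to the active signatures in the catalog;
#' the mixture weights are the per-bin signature activities and sum to 1.
#'
#' @param timeline A [build_timeline()] result, or a bins x 96 count matrix.
#' @param catalog 96 x S matrix of signature distributions (columns sum
#'   to 1); column names are signature ids.
#' @return Object of class `activity_trajectory`: matrix (bins x S) of
#'   activities with the catalog kept as an attribute.
#' @export
fit_activities <- function(timeline, catalog) {
  counts <- if (inherits(timeline, "pseudo_timeline")) timeline$counts
    else timeline
  catalog <- as.matrix(catalog)
  if (nrow(catalog) != 96) stop("catalog must have 96 rows")
  if (any(abs(colSums(catalog) - 1) > 1e-6)) {
    stop("catalog columns must each sum to 1")
  }
  if (ncol(catalog) > 1) {
    cc <- stats::cor(catalog)
    if (any(cc[upper.tri(cc)] > 0.999)) {
      warning("near-duplicate signatures in catalog; ",
              "activities are not identifiable")
    }
  }
  act <- t(apply(counts, 1, fit_mixture_weights, catalog = catalog))
  if (ncol(catalog) == 1L) act <- matrix(1, nrow(counts), 1)
  colnames(act) <- colnames(catalog)
  structure(act, class = c("activity_trajectory", "matrix"),
            catalog = catalog, counts = counts)
}

## segment cost for change-point detection: -2 x mixture log-likelihood of
## the pooled counts of bins lo..hi
segment_cost_factory <- function(counts, catalog) {
  # prefix sums let each segment's pooled spectrum be formed in O(96)
  prefix <- apply(counts, 2, cumsum)
  prefix <- rbind(0, prefix)
  function(lo, hi) {
    x <- prefix[hi + 1L, ] - prefix[lo, ]
    pi_ <- fit_mixture_weights(x, catalog, n_iter = 200)
    -2 * mixture_loglik(x, catalog, pi_)
  }
}

#' Detect signature activity change points (PELT)
#'
#' Optimal penalized segmentation of the binned mutation spectra: the cost of
#' a segment is -2 times the maximized multinomial-mixture log-likelihood of
#' its pooled counts, and each additional segment pays a Bayesian
#' information criterion penalty of `(S - 1) * log(N)` (S active signatures,
#' N total mutations). The Pruned Exact Linear Time algorithm returns the
#' same optimum as exhaustive dynamic programming.
#'
#' @param trajectory An [fit_activities()] result (carries counts and
#'   catalog), or a list with `counts` and `catalog`.
#' @param penalty Per-segment penalty; default `(S - 1) * log(N)`.
#' @param min_change Minimum absolute activity change (on the 0..1 scale)
#'   for a change point to be reported (default 0.05).
#' @return Integer vector of change points (a change point at b means a new
#'   segment starts at bin b + 1), possibly empty; attribute `all` keeps the
#'   unfiltered optimum.
#' @export
detect_changepoints <- function(trajectory, penalty = NULL,
                                min_change = 0.05) {
  counts <- attr(trajectory, "counts")
  catalog <- attr(trajectory, "catalog")
  if (is.null(counts)) {
    counts <- trajectory$counts
    catalog <- trajectory$catalog
  }
  n_bins <- nrow(counts)
  if (n_bins < 4) return(integer(0))
  s <- ncol(catalog)
  if (is.null(penalty)) penalty <- max(s - 1, 1) * log(sum(counts))
  cost <- segment_cost_factory(counts, catalog)

  # PELT: F(t) = min over last change s < t of F(s) + C(s+1, t) + penalty
  f <- c(-penalty, rep(Inf, n_bins))
  last <- integer(n_bins)
  candidates <- 0L
  cost_cache <- new.env(hash = TRUE)
  cseg <- function(lo, hi) {
    key <- paste0(lo, ":", hi)
    v <- cost_cache[[key]]
    if (is.null(v)) {
      v <- cost(lo, hi)
      cost_cache[[key]] <- v
    }
    v
  }
  for (t in seq_len(n_bins)) {
    vals <- vapply(candidates, function(s0)
      f[s0 + 1L] + cseg(s0 + 1L, t) + penalty, numeric(1))
    best <- which.min(vals)
    f[t + 1L] <- vals[best]
    last[t] <- candidates[best]
    # prune candidates that can never win again (K = 0)
    keep <- vals <= f[t + 1L] + penalty
    candidates <- c(candidates[keep], t)
  }
  cps <- integer(0)
  t <- n_bins
  while (t > 0) {
    s0 <- last[t]
    if (s0 > 0) cps <- c(s0, cps)
    t <- s0
  }
  act <- if (inherits(trajectory, "activity_trajectory")) {
    unclass(trajectory)
  } else {
    t(apply(counts, 1, fit_mixture_weights, catalog = catalog))
  }
  keep <- vapply(cps, function(b) {
    max(abs(act[b + 1L, ] - act[b, ])) >= min_change
  }, logical(1))
  out <- cps[keep]
  attr(out, "all") <- cps
  out
}

#' Exhaustive optimal segmentation (dynamic programming oracle)
#'
#' Same objective as [detect_changepoints()] solved by plain O(n^2) dynamic
#' programming without pruning; used to verify the PELT optimum.
#'
#' @inheritParams detect_changepoints
#' @return Integer vector of change points (unfiltered).
#' @export
segment_exhaustive <- function(trajectory, penalty = NULL) {
  counts <- attr(trajectory, "counts")
  catalog <- attr(trajectory, "catalog")
  if (is.null(counts)) {
    counts <- trajectory$counts
    catalog <- trajectory$catalog
  }
  n_bins <- nrow(counts)
  s <- ncol(catalog)
  if (is.null(penalty)) penalty <- max(s - 1, 1) * log(sum(counts))
  cost <- segment_cost_factory(counts, catalog)
  cmat <- matrix(NA_real_, n_bins, n_bins)
  for (lo in seq_len(n_bins)) for (hi in lo:n_bins) {
    cmat[lo, hi] <- cost(lo, hi)
  }
  f <- c(-penalty, rep(Inf, n_bins))
  last <- integer(n_bins)
  for (t in seq_len(n_bins)) {
    vals <- vapply(0:(t - 1L), function(s0)
      f[s0 + 1L] + cmat[s0 + 1L, t] + penalty, numeric(1))
    f[t + 1L] <- min(vals)
    last[t] <- which.min(vals) - 1L
  }
  cps <- integer(0)
  t <- n_bins
  while (t > 0) {
    s0 <- last[t]
    if (s0 > 0) cps <- c(s0, cps)
    t <- s0
  }
  cps
}

#' Fraction of subclone boundaries supported by activity change points
#'
#' A boundary (in bin units) is supported when a change point lies within
#' `window` time points. The random-null fraction repeats the computation
#' `n_random` times with the same number of change points placed uniformly
#' at random on the timeline.
#'
#' @param change_points Integer change-point bins.
#' @param cluster_boundaries Integer boundary bins.
#' @param n_bins Timeline length in bins.
#' @param window Support window in time points (default 3).
#' @param n_random Random placements for the null (default 1000).
#' @param rng_seed Optional seed.
#' @return List with `supported_fraction` and `random_null_fraction`.
#' @export
boundary_support <- function(change_points, cluster_boundaries, n_bins,
                             window = 3, n_random = 1000, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (length(cluster_boundaries) == 0L) {
    return(list(supported_fraction = NA_real_,
                random_null_fraction = NA_real_))
  }
  supp_frac <- function(cps) {
    if (length(cps) == 0L) return(0)
    mean(vapply(cluster_boundaries, function(b)
      any(abs(cps - b) <= window), logical(1)))
  }
  obs <- supp_frac(change_points)
  null_frac <- if (length(change_points) == 0L) 0 else {
    mean(vapply(seq_len(n_random), function(i)
      supp_frac(sample.int(n_bins, length(change_points), replace = TRUE)),
      numeric(1)))
  }
  list(supported_fraction = obs, random_null_fraction = null_frac)
}

#' Bootstrap uncertainty of per-bin signature activities
#'
#' Resamples the mutations within each bin `n_boot` times and refits the
#' activities, returning the per-bin, per-signature standard error. Changes
#' below roughly twice the typical standard error should not be
#' interpreted; the default reporting threshold downstream is a 5% absolute
#' change, with an overall-change flag at 10%.
#'
#' @param timeline A [build_timeline()] result.
#' @param catalog 96 x S signature matrix.
#' @param n_boot Bootstrap replicates (default 30).
#' @param rng_seed Optional seed.
#' @return Matrix (bins x S) of bootstrap standard errors.
#' @export
activity_bootstrap_se <- function(timeline, catalog, n_boot = 30,
                                  rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  counts <- timeline$counts
  s <- ncol(catalog)
  ses <- matrix(NA_real_, nrow(counts), s)
  for (b in seq_len(nrow(counts))) {
    x <- counts[b, ]
    n <- sum(x)
    if (n == 0) next
    acts <- matrix(NA_real_, n_boot, s)
    for (r in seq_len(n_boot)) {
      resampled <- tabulate(
        sample(rep.int(seq_len(96), x), n, replace = TRUE), nbins = 96)
      acts[r, ] <- fit_mixture_weights(resampled, catalog, n_iter = 200)
    }
    ses[b, ] <- apply(acts, 2, stats::sd)
  }
  colnames(ses) <- colnames(catalog)
  ses
}

#' Load a COSMIC-format signature catalog
#'
#' Reads a tab-separated 96 x S matrix whose first column is the mutation
#' type label and remaining columns are signature distributions; columns are
#' renormalized to sum to 1.
#'
#' @param path TSV file path.
#' @return 96 x S numeric matrix with signature-id column names.
#' @export
read_signature_catalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (nrow(m) != 96) stop("expected 96 mutation-type rows, got ", nrow(m))
  sweep(m, 2, colSums(m), "/")
}
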