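#' Mean of the truncated binomial distribution
#'
#' The truncated binomial places zero mass on counts <= T and renormalizes
#' the remaining Binomial(n, p) mass by 1 - CDF(T). Its mean is computed by
#' direct summation over the support.
#'
#' @param p Success probability in (0, 1).
#' @param n Number of trials.
#' @param T_trunc Truncation point: counts <= T are censored (default 2,
#'   matching a 3-variant-read detection requirement).
#' @return The truncated mean (>= T + 1 always, > the untruncated mean n*p).
#' @examples
#' trunc_binom_mean(0.5, 4, 1)  # 28/11
#' @export
trunc_binom_mean <- function(p, n, T_trunc = 2) {
  if (T_trunc >= n) stop("truncation point must be below n")
  x <- (T_trunc + 1):n
  mass <- stats::dbinom(x, n, p)
  tail_p <- sum(mass)
  if (tail_p <= 0) return(n)  # p ~ 1 numerical edge
  sum(x * mass) / tail_p
}

#' Analytic winner's-curse correction (truncated-binomial moment matching)
#'
#' Under the simplifying assumptions that every variant sits on a single copy
#' in a region at the average sample copy number and is sequenced at the
#' average depth, a cluster's cellular prevalence theta maps to a per-read
#' variant probability \eqn{p_v = \theta / (\rho\psi + 2(1-\rho))}. Detection
#' censors variants with at most `T_trunc` supporting reads, so the observed
#' mean success probability is the truncated-binomial mean. The method finds
#' p* whose truncated mean over n = rounded mean depth matches p_v, reports
#' the corrected CP = p* times the average copy number, and estimates the
#' ratio of true to observed variants \eqn{sf = 1 / (1 - CDF(T; p^*, n))}.
#'
#' @param cluster_cp Observed cluster cellular prevalence theta.
#' @param purity,ploidy Sample purity rho and tumor ploidy psi.
#' @param mean_depth Mean read depth of the cluster's variants.
#' @param T_trunc Censoring threshold (default 2: detected iff >= 3 reads).
#' @param n_snvs_observed Observed mutation count (optional; enables the
#'   corrected count).
#' @return Object of class `correction_result`: list with `cp_observed`,
#'   `cp_corrected`, `ccf_observed`, `ccf_corrected`, `sf`,
#'   `n_snvs_observed`, `n_snvs_corrected`, `method`, `ok` and `diagnostic`.
#' @export
spoilsport_correct <- function(cluster_cp, purity, ploidy, mean_depth,
                               T_trunc = 2, n_snvs_observed = NA_real_) {
  if (!(cluster_cp > 0)) stop("cluster CP must be positive")
  if (mean_depth < 1) stop("mean depth must be >= 1")
  avg_cn <- purity * ploidy + 2 * (1 - purity)
  p_v <- cluster_cp / avg_cn
  n <- round(mean_depth)
  floor_pv <- (T_trunc + 1) / n   # truncated mean / n as p -> 0
  if (p_v <= floor_pv) {
    return(correction_result(
      cp_observed = cluster_cp, cp_corrected = 0, purity = purity,
      sf = Inf, n_snvs_observed = n_snvs_observed, method = "spoilsport",
      ok = FALSE,
      diagnostic = "observed CP below the truncation floor; even p -> 0 cannot match"))
  }
  obj <- function(p) abs(trunc_binom_mean(p, n, T_trunc) / n - p_v)
  opt <- stats::optimize(obj, interval = c(1e-6, 1 - 1e-6), tol = 1e-8)
  p_star <- opt$minimum
  sf <- 1 / (1 - stats::pbinom(T_trunc, n, p_star))
  correction_result(
    cp_observed = cluster_cp, cp_corrected = p_star * avg_cn,
    purity = purity, sf = sf, n_snvs_observed = n_snvs_observed,
    method = "spoilsport", ok = TRUE, diagnostic = NULL)
}

correction_result <- function(cp_observed, cp_corrected, purity, sf,
                              n_snvs_observed, method, ok, diagnostic) {
  n_corr <- if (is.finite(sf) && !is.na(n_snvs_observed)) {
    n_snvs_observed * sf
  } else NA_real_
  structure(
    list(cp_observed = cp_observed, cp_corrected = cp_corrected,
         ccf_observed = cp_observed / purity,
         ccf_corrected = cp_corrected / purity,
         sf = sf, n_snvs_observed = n_snvs_observed,
         n_snvs_corrected = n_corr, method = method, ok = ok,
         diagnostic = diagnostic),
    class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result:%s> ccf %.4f -> %.4f  sf = %.3f",
              x$method, x$ccf_observed, x$ccf_corrected, x$sf))
  if (!is.na(x$n_snvs_observed)) {
    cat(sprintf("  n %.0f -> %.1f", x$n_snvs_observed, x$n_snvs_corrected))
  }
  cat("\n")
  if (!x$ok) cat("  !", x$diagnostic, "\n")
  invisible(x)
}

#' Simulation-search winner's-curse correction
#'
#' Starting from the observed (biased-up) cluster CCF, candidate true CCFs
#' are tried on a 0.01 grid moving downward. For each candidate, mutations
#' are simulated under the read-count model on the sample's copy-number
#' profile, the caller detection rule (`alt_count >= min_count`) is applied,
#' and the mean CCF of the detected mutations is computed. The first
#' candidate whose detected CCF matches the observed cluster position within
#' 0.01 is reported, together with the implied true mutation count
#' (observed count / detection fraction).
#'
#' @param observed_ccf Observed cluster CCF.
#' @param n_snvs_observed Observed mutation count in the cluster.
#' @param cn_profile A [caller_copy_profile()].
#' @param profile A [sample_profile()].
#' @param min_count Detection threshold (default 3).
#' @param n_sim Mutations simulated per candidate step (>= 1000 recommended).
#' @param ccf_tol Match tolerance (default 0.01).
#' @param rng_seed Optional seed (common random numbers across steps).
#' @return A `correction_result` with `method = "simsearch"`.
#' @export
phylogic_correct_bias <- function(observed_ccf, n_snvs_observed, cn_profile,
                                  profile, min_count = 3, n_sim = 2000,
                                  ccf_tol = 0.01, rng_seed = NULL) {
  stopifnot(inherits(profile, "sample_profile"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  seeds <- sample.int(.Machine$integer.max, 1)
  detected_ccf <- function(cand) {
    set.seed(seeds)  # common random numbers: smooth in cand
    f <- min(cand, 1)
    sizes <- if (f >= 1) c(n_sim, 1) else c(1, n_sim)
    ccfs <- if (f >= 1) c(1, 0.5) else c(1, f)
    sp <- architecture_spec(ccfs, sizes)
    sim <- simulate_reads(sp, cn_profile, profile, min_count = min_count)
    target_cluster <- if (f >= 1) 1L else 2L
    sim <- sim[sim$cluster == target_cluster, , drop = FALSE]
    if (nrow(sim) == 0L) return(list(ccf = 0, frac = 0))
    tot <- sim$major_cn + sim$minor_cn
    est <- snv_ccf(sim$alt_count / pmax(sim$total_count, 1), profile, tot)
    list(ccf = mean(est$ccf), frac = nrow(sim) / n_sim)
  }
  grid <- seq(round(observed_ccf, 2), 0.01, by = -0.01)
  best <- NULL
  for (cand in grid) {
    d <- detected_ccf(cand)
    if (d$frac == 0) break
    gap <- abs(d$ccf - observed_ccf)
    if (gap <= ccf_tol) {
      if (is.null(best) || gap < best$gap) {
        best <- list(cand = cand, gap = gap, frac = d$frac)
      } else {
        break   # past the matching band: the fit is getting worse again
      }
    } else if (!is.null(best)) {
      break
    }
  }
  if (!is.null(best)) {
    return(correction_result(
      cp_observed = observed_ccf * profile$purity,
      cp_corrected = best$cand * profile$purity, purity = profile$purity,
      sf = 1 / best$frac, n_snvs_observed = n_snvs_observed,
      method = "simsearch", ok = TRUE, diagnostic = NULL))
  }
  correction_result(
    cp_observed = observed_ccf * profile$purity, cp_corrected = NA_real_,
    purity = profile$purity, sf = NA_real_,
    n_snvs_observed = n_snvs_observed, method = "simsearch", ok = FALSE,
    diagnostic = "no candidate CCF in (0, observed] reproduces the observation")
}

#' Combine winner's-curse corrections from several methods
#'
#' The consensus CCF shift is the arithmetic mean of the per-method shifts
#' (corrected - observed); the consensus corrected mutation count is the
#' geometric mean of the per-method counts. Failed methods are dropped; if
#' all failed, the failure propagates.
#'
#' @param results List of `correction_result` objects for the same cluster.
#' @return A combined `correction_result` with `method = "consensus"`.
#' @export
combine_corrections <- function(results) {
  stopifnot(length(results) >= 1)
  ok <- vapply(results, function(r) isTRUE(r$ok), logical(1))
  if (!any(ok)) {
    r <- results[[1]]
    return(correction_result(r$cp_observed, NA_real_, r$cp_observed /
                               r$ccf_observed, NA_real_, r$n_snvs_observed,
                             "consensus", FALSE, "all methods failed"))
  }
  rs <- results[ok]
  purity <- rs[[1]]$cp_observed / rs[[1]]$ccf_observed
  ccf_obs <- rs[[1]]$ccf_observed
  shifts <- vapply(rs, function(r) r$ccf_corrected - r$ccf_observed,
                   numeric(1))
  ccf_corr <- ccf_obs + mean(shifts)
  counts <- vapply(rs, `[[`, numeric(1), "n_snvs_corrected")
  n_corr <- if (all(is.finite(counts))) exp(mean(log(counts))) else NA_real_
  out <- correction_result(ccf_obs * purity, ccf_corr * purity, purity,
                           NA_real_, rs[[1]]$n_snvs_observed, "consensus",
                           TRUE, NULL)
  out$n_snvs_corrected <- n_corr
  out$sf <- if (!is.na(n_corr) && !is.na(out$n_snvs_observed)) {
    n_corr / out$n_snvs_observed
  } else NA_real_
  out
}
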