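#' Reference mixture clusterer of CCF values
#'
#' Clusters per-SNV cancer cell fractions into subclones with a finite
#' mixture, selecting the number of components (1..`max_components`) by BIC,
#' merging components that are not separated, and collapsing all clusters
#' with mean above `clonal_collapse_threshold` into a single clonal cluster
#' located at exactly 1.0.
#'
#' Two engines are available. The Gaussian engine fits 1-d Gaussian mixtures
#' to the CCF values directly and merges adjacent components whose mixture
#' density shows no dip between their means (no local minimum below
#' `merge_dip_frac` times the smaller peak). The binomial engine — used
#' automatically when `alt_count`/`total_count` are supplied — models each
#' SNV's variant read count as Binomial(depth, location / ccf_factor), the
#' exact observation model of sequencing noise; this resolves much closer
#' clusters than Gaussian point-estimate clustering because the
#' heteroscedastic read-sampling noise is handled exactly.
#'
#' @param ccfs Numeric vector of per-SNV CCF estimates (>= 20 values).
#' @param alt_count,total_count Optional per-SNV variant and total read
#'   counts (binomial engine).
#' @param ccf_factor Per-SNV factor c_i converting a cluster location m to
#'   that SNV's expected VAF m / c_i; for an SNV with multiplicity m_i at
#'   total tumor copy number n_t in a sample of purity rho,
#'   c_i = (rho n_t + (1 - rho) n_n) / (rho m_i). Required with read counts.
#' @param engine `"auto"` (binomial when counts are given), `"gaussian"` or
#'   `"binomial"`.
#' @param max_components Maximum mixture size considered (default 7).
#' @param clonal_collapse_threshold Means above this are clonal (default 0.9).
#' @param merge_dip_frac Density-dip fraction for the Gaussian unimodal
#'   merge (default 0.95).
#' @param min_separation Binomial engine: adjacent fitted components closer
#'   than this are treated as one cluster (default 0.06, just below the
#'   empirical resolution limit of bulk subclonal reconstruction).
#' @return A [clustering()] on the CCF scale, with per-SNV assignment
#'   probabilities.
#' @export
reference_cluster <- function(ccfs, alt_count = NULL, total_count = NULL,
                              ccf_factor = NULL,
                              engine = c("auto", "gaussian", "binomial"),
                              max_components = 7,
                              clonal_collapse_threshold = 0.9,
                              merge_dip_frac = 0.95, min_separation = 0.06) {
  engine <- match.arg(engine)
  if (length(ccfs) < 20) stop("need at least 20 CCF values")
  n <- length(ccfs)
  if (engine == "auto") {
    engine <- if (!is.null(alt_count)) "binomial" else "gaussian"
  }
  if (engine == "binomial") {
    if (is.null(alt_count) || is.null(total_count) || is.null(ccf_factor)) {
      stop("binomial engine needs alt_count, total_count and ccf_factor")
    }
    return(binomial_cluster_fit(alt_count, total_count, ccf_factor,
                                max_components, clonal_collapse_threshold,
                                min_separation))
  }
  if (stats::sd(ccfs) < 1e-12) {
    # degenerate all-identical input: one cluster, no error
    loc <- if (ccfs[1] > clonal_collapse_threshold) 1.0 else ccfs[1]
    return(clustering(1, loc, scale = "CCF",
                      assignments = matrix(1, n, 1), n_snvs_total = n))
  }
  fit <- Mclust(ccfs, G = seq_len(max_components), modelNames = "V",
                verbose = FALSE)
  if (is.null(fit)) fit <- Mclust(ccfs, G = 1, verbose = FALSE)
  means <- as.numeric(fit$parameters$mean)
  vars <- fit$parameters$variance$sigmasq
  if (length(vars) == 1L) vars <- rep(vars, length(means))
  weights <- fit$parameters$pro
  z <- fit$z
  ord <- order(means)
  means <- means[ord]; vars <- vars[ord]; weights <- weights[ord]
  z <- z[, ord, drop = FALSE]

  # unimodal merge of adjacent components
  groups <- seq_along(means)
  if (length(means) > 1) {
    mix_dens <- function(x) {
      rowSums(vapply(seq_along(means), function(k)
        weights[k] * stats::dnorm(x, means[k], sqrt(vars[k])),
        numeric(length(x))))
    }
    for (k in seq_len(length(means) - 1L)) {
      xs <- seq(means[k], means[k + 1], length.out = 64)
      d <- mix_dens(xs)
      dip <- min(d[-c(1, length(d))])
      peaks <- min(d[1], d[length(d)])
      if (dip >= peaks * merge_dip_frac) {
        groups[groups == groups[k + 1]] <- groups[k]
      }
    }
  }
  # clonal collapse: component means above the threshold form one cluster
  key <- match(groups, unique(groups))
  g_means <- vapply(split(seq_along(means), key), function(ix)
    sum(weights[ix] * means[ix]) / sum(weights[ix]), numeric(1))
  clonal <- g_means > clonal_collapse_threshold
  final_key <- key
  if (any(clonal)) {
    clonal_groups <- which(clonal)
    final_key[key %in% clonal_groups] <- clonal_groups[1]
  }
  final_key <- match(final_key, unique(final_key))
  zf <- t(rowsum(t(z), final_key))
  props <- colMeans(zf)
  locs <- vapply(split(seq_along(means), final_key), function(ix) {
    gm <- sum(weights[ix] * means[ix]) / sum(weights[ix])
    if (gm > clonal_collapse_threshold) 1.0 else gm
  }, numeric(1))
  clustering(props / sum(props), locs, scale = "CCF",
             assignments = zf / rowSums(zf), n_snvs_total = n)
}

## EM for a binomial mixture in CCF space: component k has location m_k and
## SNV i an expected VAF of m_k / cfac_i. Deterministic (quantile and
## split-component initialisations only).
binom_mix_em <- function(a, d, cfac, m_init, n_iter = 150, tol = 1e-6) {
  n <- length(a)
  k <- length(m_init)
  m <- m_init
  w <- rep(1 / k, k)
  ll_old <- -Inf
  r <- NULL
  for (it in seq_len(n_iter)) {
    p <- pmin(pmax(outer(1 / cfac, m), 1e-9), 1 - 1e-9)   # n x k
    dens <- stats::dbinom(a, d, p) * rep(w, each = n)
    dim(dens) <- c(n, k)
    tot <- rowSums(dens)
    tot[tot <= 0] <- 1e-300
    ll <- sum(log(tot))
    r <- dens / tot
    w <- colMeans(r)
    # unbiased estimating equation: sum_i r_ik (a_i - d_i m / c_i) = 0
    m <- pmax(colSums(r * a) / pmax(colSums(r * d / cfac), 1e-12), 1e-4)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(m = m, w = w, r = r, ll = ll)
}

binomial_cluster_fit <- function(a, d, cfac, max_components, collapse,
                                 min_separation) {
  n <- length(a)
  stopifnot(length(d) == n, length(cfac) == n)
  ccf_pt <- ifelse(d > 0, a / d, 0) * cfac
  if (stats::sd(ccf_pt) < 1e-12) {
    loc <- if (ccf_pt[1] > collapse) 1.0 else ccf_pt[1]
    return(clustering(1, loc, scale = "CCF",
                      assignments = matrix(1, n, 1), n_snvs_total = n))
  }
  fits <- vector("list", max_components)
  fits[[1]] <- binom_mix_em(a, d, cfac, stats::median(ccf_pt))
  for (k in 2:max_components) {
    prev <- fits[[k - 1]]
    # candidate starts: quantile spread plus a split of every previous
    # component; screen each with a short EM run, converge only the best
    cands <- list(stats::quantile(ccf_pt, (2 * seq_len(k) - 1) / (2 * k),
                                  names = FALSE))
    for (j in seq_len(k - 1)) {
      cands[[length(cands) + 1L]] <-
        sort(c(prev$m[-j], prev$m[j] - 0.08, prev$m[j] + 0.08))
    }
    short <- lapply(cands, function(ini)
      binom_mix_em(a, d, cfac, pmax(ini, 1e-3), n_iter = 25))
    best_start <- short[[which.max(vapply(short, `[[`, numeric(1), "ll"))]]
    fits[[k]] <- binom_mix_em(a, d, cfac, best_start$m)
  }
  bic <- vapply(seq_len(max_components), function(k)
    2 * fits[[k]]$ll - (2 * k - 1) * log(n), numeric(1))
  f <- fits[[which.max(bic)]]
  o <- order(f$m)
  m <- f$m[o]
  w <- f$w[o]
  r <- f$r[, o, drop = FALSE]
  # merge components that landed closer than the resolution limit
  repeat {
    k <- length(m)
    if (k == 1) break
    j <- which(diff(m) < min_separation)[1]
    if (is.na(j)) break
    wj <- w[j] + w[j + 1]
    m[j] <- (w[j] * m[j] + w[j + 1] * m[j + 1]) / wj
    w[j] <- wj
    r[, j] <- r[, j] + r[, j + 1]
    m <- m[-(j + 1)]
    w <- w[-(j + 1)]
    r <- r[, -(j + 1), drop = FALSE]
  }
  clonal <- m > collapse
  key <- seq_along(m)
  if (any(clonal)) key[clonal] <- which(clonal)[1]
  key <- match(key, unique(key))
  zf <- t(rowsum(t(r), key))
  props <- colMeans(zf)
  locs <- vapply(split(seq_along(m), key), function(ix) {
    gm <- sum(w[ix] * m[ix]) / sum(w[ix])
    if (gm > collapse) 1.0 else gm
  }, numeric(1))
  clustering(props / sum(props), locs, scale = "CCF",
             assignments = zf / rowSums(zf), n_snvs_total = n)
}

#' Per-SNV CCF conversion factor for the binomial clustering engine
#'
#' The factor c_i with expected VAF = CCF / c_i:
#' \eqn{c_i = (\rho n_{tot,t} + (1-\rho) n_{tot,n}) / (\rho m_i)}.
#'
#' @param profile A [sample_profile()].
#' @param tumor_total_cn Total tumor copy number per SNV.
#' @param multiplicity Mutation multiplicity per SNV (default 1).
#' @param normal_total_cn Normal copy number (default 2).
#' @return Numeric vector of factors.
#' @export
ccf_conversion_factor <- function(profile, tumor_total_cn, multiplicity = 1,
                                  normal_total_cn = 2) {
  stopifnot(inherits(profile, "sample_profile"))
  rho <- profile$purity
  (rho * tumor_total_cn + (1 - rho) * normal_total_cn) /
    (rho * pmax(multiplicity, 1))
}

#' Random baseline subclonal reconstructions
#'
#' Three deliberately naive reconstruction baselines that bound what a real
#' method must beat:
#' * `"stick"`: draws K ~ 1 + U\{0..6\} clusters, orders the mutations by CCF
#'   and iteratively breaks off randomly sized chunks of the ordered list;
#'   each chunk is a cluster located at its mean CCF.
#' * `"informed"`: runs 100 stick draws and keeps the one minimizing the
#'   proportion of mutations poorly explained by a beta model around each
#'   cluster location (outermost 5% of the per-cluster distribution).
#' * `"single"`: one cluster at the mean CCF.
#' * `"single_clonal"`: one cluster forced to CCF 1.
#'
#' Baselines never fail, whatever the input.
#'
#' @param ccfs Per-SNV CCF values (>= 1).
#' @param mode One of `"stick"`, `"informed"`, `"single"`, `"single_clonal"`.
#' @param rng_seed Optional seed.
#' @param overdispersion Beta overdispersion (on the proportion scale) used by
#'   the informed score (default 0.01).
#' @param n_informed_runs Stick draws scored in informed mode (default 100).
#' @return A [clustering()] on the CCF scale with hard assignments.
#' @export
randomclone <- function(ccfs, mode = c("stick", "informed", "single",
                                       "single_clonal"),
                        rng_seed = NULL, overdispersion = 0.01,
                        n_informed_runs = 100) {
  mode <- match.arg(mode)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- length(ccfs)
  stopifnot(n >= 1)
  hard_assign <- function(labels, k) {
    z <- matrix(0, n, k)
    z[cbind(seq_len(n), labels)] <- 1
    z
  }
  if (mode == "single") {
    return(clustering(1, mean(ccfs), scale = "CCF",
                      assignments = hard_assign(rep(1L, n), 1),
                      n_snvs_total = n))
  }
  if (mode == "single_clonal") {
    return(clustering(1, 1.0, scale = "CCF",
                      assignments = hard_assign(rep(1L, n), 1),
                      n_snvs_total = n))
  }
  stick_once <- function() {
    k <- sample.int(7, 1)  # 1 + U{0..6}
    k <- min(k, n)
    ord <- order(ccfs)
    sizes <- integer(k)
    remaining <- n
    if (k > 1) {
      for (j in seq_len(k - 1L)) {
        chunk <- max(1L, round(runif(1) * remaining))
        chunk <- min(chunk, remaining - (k - j))
        sizes[j] <- chunk
        remaining <- remaining - chunk
      }
    }
    sizes[k] <- remaining
    labels_sorted <- rep(seq_len(k), sizes)
    labels <- integer(n)
    labels[ord] <- labels_sorted
    locs <- vapply(seq_len(k), function(j) mean(ccfs[labels == j]), numeric(1))
    list(labels = labels, locs = locs, sizes = sizes)
  }
  as_clustering <- function(s) {
    # chunks that landed on the same mean CCF merge into one cluster
    uniq <- unique(sort(s$locs))
    grp <- match(s$locs, uniq)
    sizes <- vapply(seq_along(uniq), function(g)
      sum(s$sizes[grp == g]), numeric(1))
    clustering(sizes / n, uniq, scale = "CCF",
               assignments = hard_assign(grp[s$labels], length(uniq)),
               n_snvs_total = n)
  }
  if (mode == "stick") return(as_clustering(stick_once()))

  # informed: keep the stick draw with the fewest poorly explained mutations
  poorly_explained <- function(s) {
    rho <- overdispersion
    frac <- 0
    for (j in seq_along(s$locs)) {
      f <- min(max(s$locs[j], 0.01), 0.99)
      a <- f * (1 - rho) / rho
      b <- (1 - f) * (1 - rho) / rho
      x <- pmin(pmax(ccfs[s$labels == j], 0), 1)
      lo <- stats::qbeta(0.025, a, b)
      hi <- stats::qbeta(0.975, a, b)
      frac <- frac + sum(x < lo | x > hi)
    }
    frac / length(ccfs)
  }
  best <- NULL
  best_score <- Inf
  for (r in seq_len(n_informed_runs)) {
    s <- stick_once()
    sc <- poorly_explained(s)
    if (sc < best_score) {
      best_score <- sc
      best <- s
    }
  }
  as_clustering(best)
}

#' Pseudo-SNV observation encoding a copy-number event's cellular prevalence
#'
#' A copy-number alteration enters an SNV-based phylogeny model as a
#' "pseudo-SNV" whose variant reads `v = 0.5 * p * d` and depth `d` are chosen
#' so that the implied cellular-prevalence standard error matches the
#' alteration's. The per-event depth is `d_i = L_kb * R * D` (length in kb
#' times heterozygous-SNP rate times mean depth); merged clonal events are
#' capped at `A * D`, the confidence of a cluster of `A` average-depth SNVs.
#'
#' @param cna_cp Cellular prevalence p of the event, in \[0, 1\].
#' @param l_kb Event length(s) in kb.
#' @param het_snp_rate Heterozygous SNPs per kb (default 0.7, i.e. 7 per
#'   10 kb).
#' @param mean_depth Mean read depth D.
#' @param cap_snvs Cap A in SNV-equivalents for merged clonal events
#'   (default 3000).
#' @param merge_clonal If TRUE treat all events as one merged clonal event
#'   (depths summed then capped).
#' @return `data.frame` with columns `v` (variant reads), `d` (depth) and
#'   `se` (implied standard error).
#' @export
cna_pseudo_ssm <- function(cna_cp, l_kb, het_snp_rate = 0.7, mean_depth,
                           cap_snvs = 3000, merge_clonal = FALSE) {
  if (any(cna_cp < 0 | cna_cp > 1)) stop("cna_cp must be in [0, 1]")
  if (any(l_kb <= 0) || het_snp_rate <= 0 || mean_depth <= 0) {
    stop("l_kb, het_snp_rate and mean_depth must be positive")
  }
  d <- l_kb * het_snp_rate * mean_depth
  if (merge_clonal) {
    d <- min(round(sum(d)), cap_snvs * mean_depth)
    p <- cna_cp[1]
    return(data.frame(v = 0.5 * p * d, d = d, se = binomial_se(p, d)))
  }
  data.frame(v = 0.5 * cna_cp * d, d = d, se = binomial_se(cna_cp, d))
}

#' Binomial standard error of an implied cellular prevalence
#'
#' \deqn{e = \sqrt{p(1-p)/(d+1)}}
#'
#' @param p Success probability in \[0, 1\].
#' @param d Read depth (>= 0).
#' @return Standard error; decreases as 1/sqrt(d).
#' @examples
#' binomial_se(0.8, 3000 * 50)  # ~0.001
#' @export
binomial_se <- function(p, d) {
  if (any(d < 0)) stop("depth must be >= 0")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  sqrt(p * (1 - p) / (d + 1))
}
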