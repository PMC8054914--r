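#' Step-function CDF of a clustering
#'
#' The CDF of a clustering \{(p_k, f_k)\} is the right-continuous step
#' function F(x) = sum of p_k over clusters with f_k <= x.
#'
#' @param cl A [clustering()].
#' @return List with `breakpoints` (sorted locations) and `heights`
#'   (cumulative proportions, ending at 1).
#' @export
clustering_cdf <- function(cl) {
  stopifnot(inherits(cl, "clustering"))
  list(breakpoints = cl$locations, heights = cumsum(cl$proportions))
}

## evaluate a step CDF at points x (right-continuous)
cdf_eval <- function(cdf, x) {
  idx <- findInterval(x, cdf$breakpoints)
  c(0, cdf$heights)[idx + 1L]
}

#' Earth mover distance between two 1-d clusterings
#'
#' The Wasserstein-1 distance between the two discrete distributions, equal to
#' the integral of the absolute difference of their CDFs. Computed exactly as
#' a sum of rectangles over the union of cluster locations.
#'
#' @param c1,c2 [clustering()] objects on the same scale.
#' @return Non-negative distance; zero iff the CDFs coincide.
#' @examples
#' a <- clustering(1, 0.2); b <- clustering(1, 0.6)
#' emd(a, b)  # 0.4
#' @export
emd <- function(c1, c2) {
  stopifnot(inherits(c1, "clustering"), inherits(c2, "clustering"))
  if (abs(sum(c1$proportions) - 1) > 1e-9 ||
      abs(sum(c2$proportions) - 1) > 1e-9) {
    stop("clusterings must be normalized")
  }
  f1 <- clustering_cdf(c1)
  f2 <- clustering_cdf(c2)
  xs <- sort(unique(c(f1$breakpoints, f2$breakpoints)))
  if (length(xs) == 1L) return(0)
  h <- abs(cdf_eval(f1, xs) - cdf_eval(f2, xs))
  sum(h[-length(h)] * diff(xs))
}

#' Pointwise-median clustering of a set of clusterings
#'
#' The unconstrained consensus that minimizes the sum of EMDs to all members:
#' its CDF is the pointwise median of the member CDFs, with breakpoints at the
#' union of all cluster locations.
#'
#' @param clusterings List of [clustering()] objects.
#' @return A [clustering()] (zero-mass locations dropped).
#' @export
median_clustering <- function(clusterings) {
  stopifnot(length(clusterings) >= 1)
  cdfs <- lapply(clusterings, clustering_cdf)
  xs <- sort(unique(unlist(lapply(cdfs, `[[`, "breakpoints"))))
  med <- vapply(xs, function(x)
    stats::median(vapply(cdfs, cdf_eval, numeric(1), x = x)), numeric(1))
  med <- cummax(med)            # guard against fp non-monotonicity
  med[length(med)] <- 1
  props <- diff(c(0, med))
  keep <- props > 1e-12
  clustering(props[keep] / sum(props[keep]), xs[keep],
             scale = clusterings[[1]]$scale)
}

## locations for a candidate proportion vector: each step's location is the
## weighted median of the median-clustering locations within the step's
## y-range, ties broken toward the lower location
weme_locations <- function(med, props) {
  qs <- cumsum(props)
  med_q <- cumsum(med$proportions)
  med_q0 <- c(0, med_q[-length(med_q)])
  locs <- numeric(length(props))
  lo <- 0
  for (k in seq_along(props)) {
    hi <- qs[k]
    # overlap of each median cluster's y-range with (lo, hi]
    w <- pmax(0, pmin(med_q, hi) - pmax(med_q0, lo))
    if (sum(w) <= 0) {
      locs[k] <- if (k > 1) locs[k - 1] else med$locations[1]
    } else {
      locs[k] <- weighted_median(med$locations, w, interpolate = FALSE)
    }
    lo <- hi
  }
  locs
}

#' Weighted-median (WeMe) consensus of clusterings
#'
#' Robust consensus of several subclonal architecture summaries. Outlier
#' clusterings (the `outlier_frac` highest EMDs to the all-method median
#' clustering, rounded down, never leaving fewer than 2 inliers) are removed;
#' the median clustering of the inliers is recomputed; K is set to the
#' ceiling of the median inlier cluster count; and the K-constrained median
#' clustering is found by searching proportion vectors (simplex grid with
#' step `grid_step` for K <= 4, coordinate-descent refinement from the best
#' grid start for larger K) with locations set per proportion vector to the
#' weighted median of the median-clustering steps.
#'
#' @param clusterings List of >= 2 [clustering()] objects on one scale.
#' @param outlier_frac Fraction of clusterings discarded as outliers
#'   (default 0.2).
#' @param grid_step Proportion grid resolution (default 0.05).
#' @return A [clustering()] with at most K clusters.
#' @export
weme_consensus <- function(clusterings, outlier_frac = 0.2,
                           grid_step = 0.05) {
  if (length(clusterings) < 2) {
    warning("single input clustering returned unchanged")
    return(clusterings[[1]])
  }
  med_all <- median_clustering(clusterings)
  emds <- vapply(clusterings, emd, numeric(1), c2 = med_all)
  n_drop <- min(floor(outlier_frac * length(clusterings)),
                length(clusterings) - 2L)
  inliers <- clusterings
  if (n_drop > 0) {
    keep <- order(emds)[seq_len(length(clusterings) - n_drop)]
    inliers <- clusterings[sort(keep)]
  }
  med <- median_clustering(inliers)
  k <- ceiling(stats::median(vapply(inliers, n_clusters, numeric(1))))
  k <- min(k, length(med$locations))
  if (k == length(med$locations)) return(med)

  units <- round(1 / grid_step)
  score <- function(props) {
    locs <- weme_locations(med, props)
    emd(med, clustering_collapse(props, locs, med$scale))
  }
  best_p <- NULL
  best_s <- Inf
  consider <- function(props) {
    s <- score(props)
    if (s < best_s - 1e-12) {
      best_s <<- s
      best_p <<- props
    }
  }
  if (k <= 4) {
    grid <- compositions(units, k) / units
    for (i in seq_len(nrow(grid))) consider(grid[i, ])
  } else {
    # coordinate descent on the unit simplex from an equal split
    cur <- rep(floor(units / k), k)
    cur[1] <- cur[1] + units - sum(cur)
    consider(cur / units)
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (i == j || cur[i] <= 1) next
        cand <- cur
        cand[i] <- cand[i] - 1L
        cand[j] <- cand[j] + 1L
        s <- score(cand / units)
        if (s < best_s - 1e-12) {
          best_s <- s
          best_p <- cand / units
          cur <- cand
          improved <- TRUE
        }
      }
    }
  }
  # inlier proportion vectors with <= k clusters are valid candidates too;
  # with locations re-optimized they can only improve the fit
  for (cl in inliers) {
    if (n_clusters(cl) <= k) consider(cl$proportions)
  }
  locs <- weme_locations(med, best_p)
  clustering_collapse(best_p, locs, med$scale)
}

## build a clustering allowing coincident locations (merged by constructor)
clustering_collapse <- function(props, locs, scale) {
  clustering(props, locs, scale = scale)
}

#' Assignment-vector (CICC) consensus clustering
#'
#' Each SNV carries a vector of cluster labels across methods (-1 where
#' unassigned). Unique assignment vectors U_l with multiplicities N_l are
#' compared by the per-coordinate disagreement count d(U_i, U_j) — a
#' coordinate counts 1 when the labels differ or both are -1 — scaled to the
#' extended distance \eqn{d_{ij} = 10 \max_l N_l \cdot d(U_i,U_j) -
#' \max(N_i, N_j)}, and clustered hierarchically (Ward). The cut level K is
#' the median method K when below 3, otherwise chosen by the Proportion of
#' Ambiguous Clusters (PAC) over method bootstraps. Consensus per-SNV CCFs use
#' the floor of the median multiplicity across methods.
#'
#' @param assignments Integer matrix (SNVs x methods) of hard cluster labels,
#'   -1 for unassigned. SNVs unassigned by every method are dropped.
#' @param snv_table `data.frame` with per-SNV `vaf`, `tumor_cn` (consensus
#'   total tumor copy number), optional `normal_cn` (default 2) and optional
#'   `mult` columns; `mult`, if absent, is the floor of the median of
#'   per-method multiplicities in `mult_per_method`.
#' @param profile A [sample_profile()] holding the consensus purity.
#' @param mult_per_method Optional matrix (SNVs x methods) of per-method
#'   multiplicities.
#' @param n_boot PAC bootstrap count (default 100).
#' @param pac_bounds Consensus-index interval for PAC (default c(0.1, 0.9)).
#' @param clamp_negative Zero-truncate negative extended distances
#'   (default FALSE, as the formula prints).
#' @param rng_seed Seed for the PAC bootstrap.
#' @return A [clustering()] on the CCF scale with hard assignments; the
#'   cluster CP is `purity * CCF`.
#' @export
cicc_consensus <- function(assignments, snv_table, profile,
                           mult_per_method = NULL, n_boot = 100,
                           pac_bounds = c(0.1, 0.9), clamp_negative = FALSE,
                           rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  stopifnot(is.matrix(assignments), inherits(profile, "sample_profile"))
  if (ncol(assignments) < 2) stop("need >= 2 methods")
  assigned <- rowSums(assignments != -1L) > 0
  if (!any(assigned)) stop("no SNV assigned by any method")
  A <- assignments[assigned, , drop = FALSE]
  snv <- snv_table[assigned, , drop = FALSE]
  H <- ncol(A)

  key <- apply(A, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  U <- A[uniq, , drop = FALSE]
  Nl <- as.integer(table(key)[key[uniq]])
  L <- nrow(U)
  u_of_snv <- match(key, key[uniq])

  if (L == 1L) {
    labels <- rep(1L, nrow(A))
  } else {
    d_pair <- matrix(0, L, L)
    for (h in seq_len(H)) {
      lab <- U[, h]
      diff_h <- outer(lab, lab, "!=") | (lab == -1L)  # both -1 counts too
      d_pair <- d_pair + diff_h
    }
    maxN <- max(Nl)
    D <- 10 * maxN * d_pair - outer(Nl, Nl, pmax)
    if (clamp_negative) D <- pmax(D, 0)
    diag(D) <- 0
    hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")

    k_methods <- apply(A, 2, function(a) length(unique(a[a != -1L])))
    kmax <- stats::median(k_methods)
    if (kmax < 3) {
      kopt <- max(1L, min(ceiling(kmax), L))
    } else {
      kmax <- min(ceiling(kmax), L)
      pac <- vapply(2:kmax, function(k) {
        co <- matrix(0, L, L)
        for (b in seq_len(n_boot)) {
          hb <- sample.int(H, H, replace = TRUE)
          db <- matrix(0, L, L)
          for (h in hb) {
            lab <- U[, h]
            db <- db + (outer(lab, lab, "!=") | (lab == -1L))
          }
          Db <- 10 * maxN * db - outer(Nl, Nl, pmax)
          if (clamp_negative) Db <- pmax(Db, 0)
          diag(Db) <- 0
          cb <- stats::cutree(
            stats::hclust(stats::as.dist(Db), method = "ward.D2"), k = k)
          co <- co + outer(cb, cb, "==")
        }
        co <- co / n_boot
        vals <- co[upper.tri(co)]
        if (length(vals) == 0L) return(0)
        mean(vals > pac_bounds[1] & vals < pac_bounds[2])
      }, numeric(1))
      kopt <- (2:kmax)[which.min(pac)]
    }
    labels_u <- stats::cutree(hc, k = kopt)
    labels <- labels_u[u_of_snv]
  }

  # consensus per-SNV CCF with floored median multiplicity
  normal_cn <- if (!is.null(snv$normal_cn)) snv$normal_cn else 2
  if (!is.null(snv$mult)) {
    m <- snv$mult
  } else if (!is.null(mult_per_method)) {
    mm <- mult_per_method[assigned, , drop = FALSE]
    m <- floor(apply(mm, 1, stats::median, na.rm = TRUE))
  } else {
    m <- snv_ccf(snv$vaf, profile, snv$tumor_cn, normal_cn)$multiplicity
  }
  m <- pmax(1, m)
  rho <- profile$purity
  ccf_i <- snv$vaf / (rho * m) * (rho * snv$tumor_cn + (1 - rho) * normal_cn)

  k_final <- sort(unique(labels))
  locs <- vapply(k_final, function(k)
    stats::median(ccf_i[labels == k]), numeric(1))
  props <- vapply(k_final, function(k) mean(labels == k), numeric(1))
  lab_remap <- match(labels, k_final[order(locs)])
  z <- matrix(0, length(labels), length(k_final))
  z[cbind(seq_along(labels), lab_remap)] <- 1
  cl <- clustering(props[order(locs)], sort(locs), scale = "CCF",
                   assignments = z, n_snvs_total = length(labels))
  attr(cl, "cluster_cp") <- rho * cl$locations
  attr(cl, "snv_ccf") <- ccf_i
  cl
}

## small non-negative matrix factorization with an L1 penalty on the code
## matrix (multiplicative updates); M (N x N) ~ W (N x k) %*% A (k x N)
nmf_sparse <- function(M, k, n_iter = 200, l1 = 0.01, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- nrow(M)
  W <- matrix(runif(n * k, 0.1, 1), n, k)
  A <- matrix(runif(k * n, 0.1, 1), k, n)
  eps <- 1e-10
  for (i in seq_len(n_iter)) {
    A <- A * (t(W) %*% M) / (t(W) %*% W %*% A + l1 + eps)
    W <- W * (M %*% t(A)) / (W %*% A %*% t(A) + eps)
  }
  list(W = W, A = A, residual = sum((M - W %*% A)^2))
}

#' Co-clustering matrix (CSR) consensus clustering
#'
#' Averages the binary co-clustering matrices of all methods, zeroes entries
#' below threshold `T` (a pair supported by too few methods carries no
#' signal), factorizes the result into a low-rank part via non-negative
#' matrix factorization, and k-means clusters the code columns. Post-merges:
#' superclonal clusters (CP above purity) are merged into the nearest
#' non-superclonal cluster; clusters closer than the median of per-method
#' shortest inter-cluster distances (fallback 0.05) are merged; clusters
#' smaller than the median of per-method smallest cluster sizes (fallback 5%
#' of SNVs, or 50 when fewer than 1000 SNVs) are dropped and their SNVs
#' reassigned to the nearest cluster. Inputs above `subsample_above` SNVs are
#' downsampled to `subsample_to` by taking a prefix of the (pre-shuffled)
#' SNV list.
#'
#' @param assignments Integer matrix (SNVs x methods) of hard labels, -1 for
#'   unassigned.
#' @param cp_per_method Numeric matrix (SNVs x methods) of per-method per-SNV
#'   cellular prevalences; the consensus per-SNV CP is the row median.
#' @param purity Consensus purity.
#' @param K Number of clusters; default is the rounded-up median of
#'   per-method cluster counts.
#' @param threshold Co-clustering threshold T (default 0.2).
#' @param subsample_above,subsample_to Hypermutator downsampling bounds
#'   (defaults 30000 and 25000).
#' @param rng_seed Seed (NMF init + k-means).
#' @return A [clustering()] on the CP scale with hard assignments.
#' @export
csr_consensus <- function(assignments, cp_per_method, purity, K = NULL,
                          threshold = 0.2, subsample_above = 30000,
                          subsample_to = 25000, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  stopifnot(is.matrix(assignments), nrow(assignments) == nrow(cp_per_method))
  H <- ncol(assignments)
  if (H < 2) stop("need >= 2 methods")
  n_all <- nrow(assignments)
  idx <- seq_len(n_all)
  if (n_all > subsample_above) idx <- idx[seq_len(subsample_to)]
  A_lab <- assignments[idx, , drop = FALSE]
  cp_m <- cp_per_method[idx, , drop = FALSE]
  n <- nrow(A_lab)

  M <- matrix(0, n, n)
  for (h in seq_len(H)) {
    lab <- A_lab[, h]
    ok <- lab != -1L
    Mh <- outer(lab, lab, "==")
    Mh[!ok, ] <- FALSE
    Mh[, !ok] <- FALSE
    M <- M + Mh
  }
  M <- M / H
  M[M < threshold] <- 0

  k_methods <- apply(A_lab, 2, function(a) length(unique(a[a != -1L])))
  if (is.null(K)) K <- ceiling(stats::median(k_methods))
  n_patterns <- nrow(unique(M))
  if (K > n_patterns) {
    warning("K reduced from ", K, " to ", n_patterns,
            " (distinct co-clustering patterns)")
    K <- n_patterns
  }
  K <- max(1L, K)

  if (K == 1L) {
    labels <- rep(1L, n)
  } else {
    fac <- nmf_sparse(M, K)
    feat <- t(fac$A)                     # N x K feature rows
    km <- stats::kmeans(feat, centers = K, nstart = 5, iter.max = 50)
    labels <- km$cluster
  }

  cp_i <- apply(cp_m, 1, stats::median, na.rm = TRUE)
  cluster_cp <- function(labels) {
    ks <- sort(unique(labels))
    vapply(ks, function(k) mean(cp_i[labels == k]), numeric(1))
  }

  # --- post-processing ---
  relabel <- function(labels) match(labels, sort(unique(labels)))
  labels <- relabel(labels)

  # 1) merge superclonal clusters (CP > purity) into nearest non-superclonal
  repeat {
    cps <- cluster_cp(labels)
    super <- which(cps > purity)
    if (length(super) == 0L || length(cps) == 1L) break
    non_super <- which(cps <= purity)
    if (length(non_super) == 0L) {
      # everything superclonal: merge all into one clonal cluster
      labels[] <- 1L
      break
    }
    s <- super[1]
    target <- non_super[which.min(abs(cps[non_super] - cps[s]))]
    labels[labels == s] <- target
    labels <- relabel(labels)
  }

  # 2) merge clusters closer than the per-method minimum distance
  min_dist <- {
    dd <- vapply(seq_len(H), function(h) {
      lab <- A_lab[, h]
      ks <- unique(lab[lab != -1L])
      if (length(ks) < 2) return(NA_real_)
      cen <- vapply(ks, function(k)
        mean(cp_m[lab == k, h], na.rm = TRUE), numeric(1))
      min(diff(sort(cen)))
    }, numeric(1))
    if (sum(!is.na(dd)) >= H / 2) stats::median(dd, na.rm = TRUE) else 0.05
  }
  repeat {
    cps <- cluster_cp(labels)
    if (length(cps) < 2) break
    ord <- order(cps)
    gaps <- diff(cps[ord])
    if (min(gaps) >= min_dist) break
    j <- which.min(gaps)
    a <- sort(unique(labels))[ord][j]
    b <- sort(unique(labels))[ord][j + 1]
    labels[labels == b] <- a
    labels <- relabel(labels)
  }

  # 3) drop tiny clusters, reassigning members to the nearest survivor
  min_size <- {
    ss <- vapply(seq_len(H), function(h) {
      lab <- A_lab[, h]
      lab <- lab[lab != -1L]
      if (length(lab) == 0L) return(NA_real_)
      min(table(lab))
    }, numeric(1))
    most_single <- stats::median(k_methods) <= 1
    if (!most_single && sum(!is.na(ss)) >= H / 2) {
      stats::median(ss, na.rm = TRUE)
    } else if (n < 1000) 50 else 0.05 * n
  }
  repeat {
    cps <- cluster_cp(labels)
    sizes <- as.integer(table(factor(labels, levels = sort(unique(labels)))))
    if (length(cps) < 2 || min(sizes) >= min_size) break
    tiny <- sort(unique(labels))[which.min(sizes)]
    keep_ks <- setdiff(sort(unique(labels)), tiny)
    keep_cp <- cluster_cp(labels)[match(keep_ks, sort(unique(labels)))]
    nearest <- keep_ks[max.col(-abs(outer(cp_i[labels == tiny], keep_cp,
                                          "-")))]
    labels[labels == tiny] <- nearest
    labels <- relabel(labels)
  }

  cps <- cluster_cp(labels)
  ord <- order(cps)
  props <- as.numeric(table(factor(labels,
                                   levels = sort(unique(labels))))[ord]) / n
  lab_remap <- match(labels, sort(unique(labels))[ord])
  z <- matrix(0, n, length(cps))
  z[cbind(seq_len(n), lab_remap)] <- 1
  cl <- clustering(props, cps[ord], scale = "CP", assignments = z,
                   n_snvs_total = n)
  attr(cl, "snv_cp") <- cp_i
  attr(cl, "subsampled_idx") <- idx
  cl
}

#' Probabilistic assignment of mutations to consensus clusters
#'
#' Each mutation's likelihood under cluster k is a beta-binomial on its
#' variant read count with mean equal to the expected VAF at the cluster's
#' CCF (given the mutation's copy-number context and multiplicity), weighted
#' by the cluster-size prior. Mutations in regions with unknown copy number
#' are assigned with a flag and should be excluded from location updates.
#'
#' @param consensus A [clustering()] on the CCF scale.
#' @param snvs `data.frame` with `alt_count`, `total_count`, `major_cn`,
#'   `minor_cn` (NA copy number = unknown).
#' @param profile A [sample_profile()].
#' @param overdispersion Beta-binomial overdispersion on the proportion scale
#'   (default 0.01).
#' @return Matrix (SNVs x clusters) of posterior probabilities, rows summing
#'   to 1; attribute `flagged` marks unknown-copy-number mutations.
#' @export
assign_mutations <- function(consensus, snvs, profile,
                             overdispersion = 0.01) {
  stopifnot(inherits(consensus, "clustering"),
            inherits(profile, "sample_profile"))
  rho <- profile$purity
  n <- nrow(snvs)
  k <- n_clusters(consensus)
  tot_cn <- snvs$major_cn + snvs$minor_cn
  unknown <- is.na(tot_cn)
  tot_cn[unknown] <- 2
  vaf <- ifelse(snvs$total_count > 0, snvs$alt_count / snvs$total_count, 0)
  mult <- snv_ccf(vaf, profile, tot_cn)$multiplicity
  denom <- rho * tot_cn + (1 - rho) * 2
  loglik <- matrix(0, n, k)
  rho_od <- overdispersion
  for (j in seq_len(k)) {
    f <- consensus$locations[j]
    p_exp <- pmin(pmax(f * mult * rho / denom, 1e-6), 1 - 1e-6)
    a <- p_exp * (1 - rho_od) / rho_od
    b <- (1 - p_exp) * (1 - rho_od) / rho_od
    loglik[, j] <- lbeta(snvs$alt_count + a,
                         snvs$total_count - snvs$alt_count + b) - lbeta(a, b)
  }
  logprior <- log(consensus$proportions)
  lp <- sweep(loglik, 2, logprior, "+")
  lp <- lp - apply(lp, 1, max)
  post <- exp(lp)
  post <- post / rowSums(post)
  attr(post, "flagged") <- unknown
  post
}
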