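# Independent oracles and fixture builders shared across tests.

# Random clustering with locations snapped to the 1/1024 grid: exact binary
# fractions, so the dense-grid oracles below incur no floating-point error.
random_clustering <- function(max_k = 5, loc_max = 1.5) {
  k <- sample.int(max_k, 1)
  locs <- sort(sample.int(round(loc_max * 1024), k)) / 1024
  p <- runif(k, 0.05, 1)
  clustering(p / sum(p), locs)
}

# Dense-grid numerical integration of |F1 - F2|: midpoint rule at step
# 2^-13, exact for locations on the 1/1024 grid (every cell of the grid
# holds a constant integrand and midpoints never touch a breakpoint).
emd_oracle <- function(c1, c2, loc_max = 1.6, step = 2^-13) {
  xs <- (seq_len(round(loc_max / step)) - 0.5) * step
  f <- function(cl, x) {
    h <- cumsum(cl$proportions)
    c(0, h)[findInterval(x, cl$locations) + 1L]
  }
  sum(abs(f(c1, xs) - f(c2, xs))) * step
}

# Pointwise CDF-median clustering computed by brute force on the 1/1024
# grid (a superset of all candidate breakpoint locations).
median_clustering_oracle <- function(clusterings, step = 1 / 1024,
                                     loc_max = 1.6) {
  xs <- sort(unique(c(seq(0, round(loc_max / step)) * step,
                      unlist(lapply(clusterings, `[[`, "locations")))))
  f <- function(cl, x) {
    h <- cumsum(cl$proportions)
    c(0, h)[findInterval(x, cl$locations) + 1L]
  }
  med <- apply(vapply(clusterings, f, numeric(length(xs)), x = xs), 1,
               median)
  jumps <- which(diff(c(0, med)) > 1e-12)
  clustering(diff(c(0, med))[jumps] / med[length(med)], xs[jumps])
}

# Truncated binomial mean by explicit enumeration of the support.
trunc_binom_mean_oracle <- function(p, n, T_trunc) {
  x <- 0:n
  probs <- dbinom(x, n, p)
  probs[x <= T_trunc] <- 0
  probs <- probs / sum(probs)
  sum(x * probs)
}

# Per-base scan oracle for consensus breakpoints: coverage is evaluated at
# every integer position, the leftmost qualifying position defines the
# intersection, and the locus choice replicates the gap-rank rule naively.
breakpoint_oracle <- function(segmentations, conservative, delta,
                              min_any = 3, min_conservative = 2) {
  ivs <- list()
  for (nm in names(segmentations)) {
    s <- segmentations[[nm]][order(segmentations[[nm]]$start), ]
    if (nrow(s) < 2) next
    gaps <- s$start[-1] - s$end[-nrow(s)]
    g <- ecdf(gaps)(gaps)
    for (i in seq_len(nrow(s) - 1)) {
      ivs[[length(ivs) + 1L]] <- list(
        method = nm, lo = s$end[i] - delta, hi = s$start[i + 1] + delta,
        end_locus = s$end[i], start_locus = s$start[i + 1], g = g[i])
    }
  }
  out <- numeric(0)
  while (length(ivs)) {
    los <- vapply(ivs, `[[`, numeric(1), "lo")
    his <- vapply(ivs, `[[`, numeric(1), "hi")
    meth <- vapply(ivs, `[[`, character(1), "method")
    xs <- seq(min(los), max(his))
    # exhaustive per-position evaluation of the support rule
    cover <- outer(xs, los, ">=") & outer(xs, his, "<=")   # pos x interval
    n_meth <- vapply(unique(meth), function(mm)
      rowSums(cover[, meth == mm, drop = FALSE]) > 0, logical(length(xs)))
    n_any <- rowSums(n_meth)
    n_cons <- rowSums(n_meth[, colnames(n_meth) %in% conservative,
                             drop = FALSE])
    qual <- which(n_any >= min_any | n_cons >= min_conservative)
    found <- FALSE
    for (xi in qual[1]) {
      if (is.na(xi)) break
      x <- xs[xi]
      active <- which(cover[xi, ])
      lo <- max(los[active])
      hi <- min(his[active])
      cand <- data.frame(pos = numeric(0), g = numeric(0),
                         is_end = logical(0))
      for (v in ivs[active]) {
        if (v$end_locus >= lo && v$end_locus <= hi) {
          cand <- rbind(cand, data.frame(pos = v$end_locus, g = v$g,
                                         is_end = TRUE))
        }
        if (v$start_locus >= lo && v$start_locus <= hi) {
          cand <- rbind(cand, data.frame(pos = v$start_locus, g = v$g,
                                         is_end = FALSE))
        }
      }
      pos <- if (nrow(cand) == 0) lo else {
        cand <- cand[order(cand$g, !cand$is_end, cand$pos), ]
        cand$pos[1]
      }
      out <- c(out, pos)
      ivs <- ivs[-active]
      found <- TRUE
      break
    }
    if (!found) break
  }
  sort(out)
}

# Two-signature catalog with orthogonal support (channels 1-48 vs 49-96).
orthogonal_catalog <- function() {
  m <- matrix(0, 96, 2, dimnames = list(NULL, c("S1", "S2")))
  m[1:48, 1] <- 1 / 48
  m[49:96, 2] <- 1 / 48
  m
}

# Small diploid sample + genome used by several closed-loop tests.
test_profile <- function(purity = 0.5, coverage = 100) {
  sample_profile(purity, 2, coverage = coverage)
}

test_genome <- function(seed = 11, diploid = TRUE) {
  synthetic_cn_profile(genome_length = 1e8, n_chroms = 2,
                       diploid = diploid, rng_seed = seed)
}
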