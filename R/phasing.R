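#' Evidence for one phaseable SNV pair
#'
#' Read-pair haplotype counts for two nearby SNVs plus the copy-number
#' context at the locus. `n_mutmut` counts read pairs carrying both mutant
#' alleles (in-cis evidence), `n_mutwt` / `n_wtmut` pairs carrying only the
#' first / second mutant allele.
#'
#' @param n_mutmut,n_mutwt,n_wtmut Non-negative read-pair counts.
#' @param major_cn,minor_cn Allele-specific copy number at the locus.
#' @param is_clonal Whether the copy-number state is clonal.
#' @param cluster1,cluster2 Optional cluster assignments of the two SNVs.
#' @return Object of class `phase_pair_evidence`.
#' @export
phase_pair_evidence <- function(n_mutmut, n_mutwt, n_wtmut,
                                major_cn, minor_cn, is_clonal = TRUE,
                                cluster1 = NA, cluster2 = NA) {
  if (any(c(n_mutmut, n_mutwt, n_wtmut) < 0)) stop("counts must be >= 0")
  if (major_cn < minor_cn) stop("major_cn must be >= minor_cn")
  structure(list(n_mutmut = n_mutmut, n_mutwt = n_mutwt, n_wtmut = n_wtmut,
                 major_cn = major_cn, minor_cn = minor_cn,
                 is_clonal = is_clonal,
                 cluster1 = cluster1, cluster2 = cluster2),
            class = "phase_pair_evidence")
}

#' Classify a phased SNV pair as linear or branching phylogeny evidence
#'
#' Collinear (linear) evolution requires: at least `min_pairs` read pairs
#' supporting both mutant alleles, at least `min_pairs` pairs supporting
#' exactly one of the two mutant alleles (not both directions), major allele
#' copy number 1, and either an infinite-sites violation estimate below 1 or
#' minor copy number 0 on a clonal segment. Branching evolution requires: no
#' Mut-Mut pairs, at least `min_pairs` pairs in each single-mutant direction,
#' and a clonal haploid (1+0) segment. In-cis pairs outside the informative
#' copy-number context are `phased_cis_uninformative`; mutually exclusive
#' pairs in a diploid region are `trans_diploid`; all three haplotypes on a
#' haploid segment are `inconsistent`; anything below the read thresholds is
#' `unpowered`.
#'
#' @param ev A [phase_pair_evidence()].
#' @param violations Expected infinite-sites violations for the sample (see
#'   [infinite_sites_rate()]).
#' @param min_pairs Read-pair support threshold (default 2).
#' @return List with `label` and, for collinear pairs with a one-SNV
#'   haplotype, `ancestral` (1 or 2).
#' @export
classify_pair <- function(ev, violations = 0, min_pairs = 2) {
  stopifnot(inherits(ev, "phase_pair_evidence"))
  mm <- ev$n_mutmut
  mw <- ev$n_mutwt
  wm <- ev$n_wtmut
  haploid <- ev$major_cn == 1 && ev$minor_cn == 0 && isTRUE(ev$is_clonal)
  isa_ok <- violations < 1 || (ev$minor_cn == 0 && isTRUE(ev$is_clonal))

  if (mm >= min_pairs) {
    one_dir <- xor(mw >= min_pairs, wm >= min_pairs)
    both_dir <- mw >= min_pairs && wm >= min_pairs
    if (both_dir && haploid) {
      return(list(label = "inconsistent", ancestral = NA_integer_))
    }
    if (one_dir && ev$major_cn == 1 && isa_ok) {
      return(list(label = "collinear",
                  ancestral = if (mw >= min_pairs) 1L else 2L))
    }
    return(list(label = "phased_cis_uninformative", ancestral = NA_integer_))
  }
  if (mm == 0 && mw >= min_pairs && wm >= min_pairs) {
    if (haploid) {
      return(list(label = "branching", ancestral = NA_integer_))
    }
    return(list(label = "trans_diploid", ancestral = NA_integer_))
  }
  list(label = "unpowered", ancestral = NA_integer_)
}

#' Expected infinite-sites violations by context-preserving permutation
#'
#' Each simulation scatters the sample's SNVs uniformly over the callable
#' positions of their own trinucleotide context, two allele slots per
#' position, without replacement (no position-allele slot is hit twice). A
#' violation ("double hit") is a position whose two allele slots are both
#' hit. The mean count over `n_sims` simulations is a lower bound on the
#' true violation rate, since real mutation rates are non-uniform.
#'
#' @param context_counts Named integer vector: SNVs per trinucleotide
#'   context.
#' @param callable_positions Named integer vector: callable positions per
#'   context.
#' @param n_sims Number of simulations (default 1000).
#' @param rng_seed Optional seed.
#' @return List with `expected_double_hits` and `n_sims`.
#' @export
infinite_sites_rate <- function(context_counts, callable_positions,
                                n_sims = 1000, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  contexts <- names(context_counts)
  missing_ctx <- setdiff(contexts, names(callable_positions))
  if (length(missing_ctx)) {
    warning("contexts absent from callable regions skipped: ",
            paste(missing_ctx, collapse = ", "))
    contexts <- setdiff(contexts, missing_ctx)
  }
  total <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    hits <- 0
    for (ctx in contexts) {
      k <- context_counts[[ctx]]
      if (k < 2) next
      n_pos <- callable_positions[[ctx]]
      slots <- sample.int(2L * n_pos, min(k, 2L * n_pos))
      pos <- (slots - 1L) %/% 2L
      hits <- hits + sum(duplicated(pos))
    }
    total[s] <- hits
  }
  list(expected_double_hits = mean(total), n_sims = n_sims)
}

#' Odds of branching versus linear evolution from pair labels
#'
#' Restricted to pair labels from contexts where both calls are possible
#' (clonal haploid regions) and, typically, to subclone-subclone pairs.
#' The odds are the branching count over the collinear count; a percentile
#' bootstrap over the labels gives the confidence interval.
#'
#' @param labels Character vector of pair labels (`"branching"` /
#'   `"collinear"`; other labels are ignored).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param rng_seed Optional seed.
#' @return List with `odds`, `ci` (length 2; may contain Inf) and counts.
#' @export
branching_odds <- function(labels, n_boot = 1000, conf = 0.95,
                           rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  labels <- labels[labels %in% c("branching", "collinear")]
  n_b <- sum(labels == "branching")
  n_l <- sum(labels == "collinear")
  odds <- if (n_l == 0) Inf else n_b / n_l
  ci <- c(NA_real_, NA_real_)
  if (length(labels) > 0) {
    reps <- vapply(seq_len(n_boot), function(i) {
      lb <- sample(labels, length(labels), replace = TRUE)
      nl <- sum(lb == "collinear")
      if (nl == 0) Inf else sum(lb == "branching") / nl
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE,
                                 type = 1))
  }
  list(odds = odds, ci = ci, n_branching = n_b, n_linear = n_l,
       degenerate = n_l == 0)
}

#' Sibling versus parent-child odds from phylogenetic trees
#'
#' In each repetition, one random pair of subclones is sampled from every
#' tree and classified as sibling (same parent), parent-child (direct edge)
#' or neither (cousins and deeper relations, which are excluded from both
#' numerator and denominator). The per-repetition odds are the sibling tally
#' over the parent-child tally; the median and percentile interval over
#' repetitions are reported.
#'
#' @param trees List of integer parent vectors: `parent[i]` is the parent of
#'   node i, 0 for the root (the clonal population). Subclones are nodes
#'   2..n.
#' @param n_reps Repetitions (default 1000).
#' @param conf Confidence level.
#' @param rng_seed Optional seed.
#' @return List with `odds` (median over reps), `ci`, and the pooled tally.
#' @export
tree_odds <- function(trees, n_reps = 1000, conf = 0.95, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  classify <- function(parent, a, b) {
    if (parent[a] == b || parent[b] == a) return("parent_child")
    if (parent[a] == parent[b]) return("sibling")
    "other"
  }
  reps <- vapply(seq_len(n_reps), function(r) {
    n_sib <- 0
    n_pc <- 0
    for (parent in trees) {
      subclones <- setdiff(seq_along(parent), which(parent == 0))
      if (length(subclones) < 2) next
      pair <- sample(subclones, 2)
      rel <- classify(parent, pair[1], pair[2])
      if (rel == "sibling") n_sib <- n_sib + 1
      if (rel == "parent_child") n_pc <- n_pc + 1
    }
    if (n_pc == 0) {
      if (n_sib == 0) NA_real_ else Inf
    } else n_sib / n_pc
  }, numeric(1))
  reps_ok <- reps[!is.na(reps)]
  alpha <- (1 - conf) / 2
  list(odds = stats::median(reps_ok),
       ci = unname(stats::quantile(reps_ok, c(alpha, 1 - alpha),
                                   names = FALSE, type = 1)),
       n_reps = n_reps)
}

#' Simulate read-pair phasing evidence from a two-subclone tree
#'
#' Closed-loop fixture generator: cell populations are drawn for a known
#' linear (clone -> subclone A -> subclone B) or branching (two sibling
#' subclones) topology, haplotypes are assigned per population, and read
#' pairs covering both SNV loci are sampled with Poisson coverage. Intended
#' for testing the classifier, not for modeling real libraries.
#'
#' @param topology `"linear"` or `"branching"`.
#' @param depth Mean read-pair coverage of the pair locus.
#' @param ccf_a,ccf_b CCFs of the two subclones carrying SNV 1 and SNV 2
#'   (linear: b nested within a, requires `ccf_b <= ccf_a`).
#' @param rng_seed Optional seed.
#' @return A [phase_pair_evidence()] on a clonal 1+0 segment.
#' @export
simulate_phase_pair <- function(topology = c("linear", "branching"),
                                depth = 60, ccf_a = 0.6, ccf_b = 0.3,
                                rng_seed = NULL) {
  topology <- match.arg(topology)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (topology == "linear" && ccf_b > ccf_a) {
    stop("linear topology requires ccf_b <= ccf_a")
  }
  n_pairs <- stats::rpois(1, depth)
  u <- stats::runif(n_pairs)
  if (topology == "linear") {
    # cells: [0, ccf_b): both SNVs; [ccf_b, ccf_a): SNV1 only; rest: none
    mm <- sum(u < ccf_b)
    mw <- sum(u >= ccf_b & u < ccf_a)
    wm <- 0L
  } else {
    # disjoint sibling populations
    mm <- 0L
    mw <- sum(u < ccf_a)
    wm <- sum(u >= ccf_a & u < ccf_a + ccf_b)
  }
  phase_pair_evidence(mm, mw, wm, major_cn = 1, minor_cn = 0,
                      is_clonal = TRUE, cluster1 = "A", cluster2 = "B")
}
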