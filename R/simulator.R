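#' Subclonal architecture specification
#'
#' Describes the truth of a simulated tumor: a clonal cluster at CCF 1 plus
#' `n_subclones` subclonal clusters at CCFs in (0, 1), with per-cluster SNV
#' counts.
#'
#' @param cluster_ccfs CCF per cluster; the first entry must be 1 (clonal).
#' @param cluster_sizes SNV count per cluster (>= 1 each).
#' @param multiplicity_rate Poisson mean for clonal mutation multiplicity
#'   (default 1); subclonal mutations always sit on a single copy.
#' @return Object of class `architecture_spec`.
#' @export
architecture_spec <- function(cluster_ccfs, cluster_sizes,
                              multiplicity_rate = 1) {
  stopifnot(length(cluster_ccfs) == length(cluster_sizes),
            length(cluster_ccfs) >= 1)
  if (cluster_ccfs[1] != 1) stop("first cluster must be clonal (CCF 1)")
  sub <- cluster_ccfs[-1]
  if (length(sub) && any(sub <= 0 | sub >= 1)) {
    stop("subclonal CCFs must lie strictly in (0, 1)")
  }
  if (any(cluster_sizes < 1)) stop("cluster sizes must be >= 1")
  structure(
    list(n_subclones = length(cluster_ccfs) - 1L,
         cluster_ccfs = cluster_ccfs,
         cluster_sizes = as.integer(cluster_sizes),
         f_clonal = cluster_sizes[1] / sum(cluster_sizes),
         multiplicity_rate = multiplicity_rate),
    class = "architecture_spec"
  )
}

#' Draw a random subclonal architecture (stick-breaking cluster sizes)
#'
#' Subclone CCFs are drawn uniformly on (0.1, 0.9). The total subclonal SNV
#' count is `N_subclonal = n_clonal * (1 - f_clonal) / f_clonal`, partitioned
#' by a stick-breaking procedure: a proportion U(0.1, 0.9) of the remaining
#' SNVs is split off for each subclone in turn, and the resulting chunk sizes
#' are assigned to subclones in random order.
#'
#' @param n_subclones Number of subclones (>= 0).
#' @param n_clonal Number of clonal SNVs.
#' @param f_clonal Fraction of mutations that are clonal, in (0, 1].
#' @param rng_seed Optional integer seed.
#' @param min_ccf_sep Minimum separation enforced between subclone CCFs when
#'   redrawing collisions (default 1e-3, merely to keep locations distinct).
#' @return An [architecture_spec()].
#' @export
draw_architecture <- function(n_subclones, n_clonal, f_clonal,
                              rng_seed = NULL, min_ccf_sep = 1e-3) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (!(f_clonal > 0 && f_clonal <= 1)) stop("f_clonal must be in (0, 1]")
  if (n_subclones > 0 && f_clonal == 1) {
    stop("cannot place subclones when f_clonal = 1")
  }
  if (n_subclones == 0L) {
    return(architecture_spec(1, n_clonal))
  }
  n_sub_total <- round(n_clonal * (1 - f_clonal) / f_clonal)
  n_sub_total <- max(n_sub_total, n_subclones)  # at least one SNV per subclone
  ccfs <- runif(n_subclones, 0.1, 0.9)
  while (anyDuplicated(round(ccfs / min_ccf_sep))) {
    ccfs <- runif(n_subclones, 0.1, 0.9)
  }
  sizes <- integer(n_subclones)
  remaining <- n_sub_total
  if (n_subclones > 1) {
    for (j in seq_len(n_subclones - 1L)) {
      # keep at least one SNV for each unfilled subclone
      chunk <- round(runif(1, 0.1, 0.9) * remaining)
      chunk <- min(max(chunk, 1L), remaining - (n_subclones - j))
      sizes[j] <- chunk
      remaining <- remaining - chunk
    }
  }
  sizes[n_subclones] <- remaining
  # random assignment of chunks to subclones (sample.int avoids the
  # length-one sample() surprise)
  sizes <- sizes[sample.int(n_subclones)]
  architecture_spec(c(1, ccfs), c(n_clonal, sizes))
}

#' Synthetic allele-specific copy-number profile
#'
#' Parametric stand-in for sampling copy-number profiles from a real cohort:
#' segment lengths are log-uniform between `min_len` and `max_len` and states
#' are drawn from a configurable distribution over common (major, minor)
#' states. This emulates the broad structure of somatic copy-number profiles
#' (a diploid backbone with gains and losses), not any particular cohort.
#'
#' @param genome_length Total genome length to cover (default 3e9).
#' @param n_chroms Number of chromosomes to spread segments over.
#' @param states Matrix/data.frame of candidate (major, minor) states.
#' @param state_probs Sampling weights for `states`.
#' @param min_len,max_len Log-uniform segment length bounds.
#' @param diploid If TRUE, emit a single (1,1) segment per chromosome.
#' @param rng_seed Optional seed.
#' @return A [caller_copy_profile()] with `caller_id = "synthetic"`.
#' @export
synthetic_cn_profile <- function(genome_length = 3e9, n_chroms = 22,
                                 states = rbind(c(1, 1), c(2, 1), c(2, 2),
                                                c(1, 0), c(3, 1), c(2, 0),
                                                c(3, 2), c(4, 2)),
                                 state_probs = c(0.45, 0.18, 0.12, 0.08,
                                                 0.07, 0.04, 0.03, 0.03),
                                 min_len = 1e6, max_len = 2e8,
                                 diploid = FALSE, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  chrom_len <- genome_length / n_chroms
  segs <- list()
  for (ch in seq_len(n_chroms)) {
    if (diploid) {
      segs[[ch]] <- data.frame(chrom = as.character(ch), start = 0,
                               end = chrom_len, major = 1, minor = 1)
      next
    }
    pos <- 0
    rows <- list()
    while (pos < chrom_len) {
      len <- exp(runif(1, log(min_len), log(max_len)))
      len <- min(len, chrom_len - pos)
      st <- states[sample.int(nrow(states), 1, prob = state_probs), ]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(ch), start = pos, end = pos + len,
        major = st[[1]], minor = st[[2]])
      pos <- pos + len
    }
    segs[[ch]] <- do.call(rbind, rows)
  }
  segments <- do.call(rbind, segs)
  segments$is_clonal <- TRUE
  caller_copy_profile("synthetic", segments)
}

## reads per chromosome copy for tumor and normal cells
reads_per_copy <- function(profile) {
  denom <- profile$purity * profile$tumor_ploidy + 2 * (1 - profile$purity)
  list(ct = profile$coverage * profile$purity / denom,
       cn = profile$coverage * (1 - profile$purity) / denom)
}

#' Simulate SNV read counts for a subclonal architecture
#'
#' For each mutation the expected mutant read count is
#' \eqn{E(r_m) = m_m f c_t} and the expected wild-type count
#' \eqn{E(r_w) = 2 c_n + m_w c_t + m_m (1-f) c_t}, where \eqn{c_t} and
#' \eqn{c_n} are reads per tumor / normal chromosome copy, \eqn{m_m} the
#' multiplicity, \eqn{f} the cluster CCF, and \eqn{m_w} the tumor copies not
#' carrying the mutation in mutated cells. Total depth is Poisson and the
#' mutant count binomial. Mutations with fewer than `min_count` mutant reads
#' are dropped, reproducing the caller detection limit.
#'
#' Clonal multiplicity is Poisson(`multiplicity_rate`) clamped to
#' \[1, major\]; subclonal mutations always have multiplicity 1 (and require a
#' segment with at least one copy). Mutations are assigned to segments with
#' probability proportional to segment length.
#'
#' @param spec An [architecture_spec()].
#' @param cn_profile A [caller_copy_profile()] giving the genome-wide clonal
#'   copy-number states.
#' @param profile A [sample_profile()] (purity, tumor ploidy, coverage).
#' @param min_count Detection threshold on mutant reads (default 3).
#' @param rng_seed Optional seed.
#' @param keep_filtered If TRUE, undetected mutations are returned as well
#'   with `detected = FALSE`.
#' @return `data.frame` with one row per simulated SNV: `chrom`, `pos`,
#'   `alt_count`, `total_count`, `major_cn`, `minor_cn`, `cluster`,
#'   `true_ccf`, `multiplicity`, `expected_vaf`, `detected`.
#' @export
simulate_reads <- function(spec, cn_profile, profile, min_count = 3,
                           rng_seed = NULL, keep_filtered = FALSE) {
  stopifnot(inherits(spec, "architecture_spec"),
            inherits(cn_profile, "caller_copy_profile"),
            inherits(profile, "sample_profile"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  rc <- reads_per_copy(profile)
  segs <- cn_profile$segments
  seg_len <- segs$end - segs$start
  n_total <- sum(spec$cluster_sizes)
  cl_id <- rep(seq_along(spec$cluster_ccfs), spec$cluster_sizes)
  f <- spec$cluster_ccfs[cl_id]
  is_clonal <- cl_id == 1L

  seg_idx <- sample.int(nrow(segs), n_total, replace = TRUE, prob = seg_len)
  # subclonal mutations need at least one tumor copy to sit on
  tot_cn <- segs$major[seg_idx] + segs$minor[seg_idx]
  bad <- !is_clonal & tot_cn < 1
  while (any(bad)) {
    seg_idx[bad] <- sample.int(nrow(segs), sum(bad), replace = TRUE,
                               prob = seg_len)
    tot_cn <- segs$major[seg_idx] + segs$minor[seg_idx]
    bad <- !is_clonal & tot_cn < 1
  }
  major <- segs$major[seg_idx]

  mm <- rep(1L, n_total)
  mm[is_clonal] <- pmin(pmax(rpois(sum(is_clonal), spec$multiplicity_rate),
                             1L), pmax(major[is_clonal], 1L))
  # wild-type tumor copies: clonal -> total - mm; subclonal -> total - 1
  # inside the subclone (non-carrier cells are covered by the (1 - f) term)
  mw <- ifelse(is_clonal, tot_cn - mm, tot_cn - 1L)

  e_rm <- mm * f * rc$ct
  e_rw <- 2 * rc$cn + mw * rc$ct + mm * (1 - f) * rc$ct
  e_tot <- e_rm + e_rw
  rd <- rpois(n_total, e_tot)
  rm_ <- rbinom(n_total, rd, ifelse(e_tot > 0, e_rm / e_tot, 0))

  pos <- floor(segs$start[seg_idx] +
                 runif(n_total) * (segs$end[seg_idx] - segs$start[seg_idx]))
  out <- data.frame(
    chrom = segs$chrom[seg_idx], pos = pos + 1,  # 1-based at the boundary
    alt_count = rm_, total_count = rd,
    major_cn = segs$major[seg_idx], minor_cn = segs$minor[seg_idx],
    cluster = cl_id, true_ccf = f, multiplicity = mm,
    expected_vaf = ifelse(e_tot > 0, e_rm / e_tot, 0),
    detected = rm_ >= min_count,
    stringsAsFactors = FALSE
  )
  if (!keep_filtered) out <- out[out$detected, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The simulation grid design (6 x 5 x 5 x 4 = 600 cells)
#'
#' Cartesian grid over purity (6 levels), number of clonal SNVs (5 levels, one
#' fixed at 1e5 to cover hypermutators), fraction of clonal SNVs (5 levels,
#' one fixed at 0.995 to cover the melanoma-like corner case) and number of
#' subclones (0, 1, 2, "3+", where "3+" is drawn uniformly from 3..7 at
#' simulation time). Coverage is fixed at 48.46621 for every cell.
#'
#' @param purity_levels,n_clonal_levels,f_clonal_levels Grid levels; defaults
#'   are fixed representative values spanning the range seen in large WGS
#'   cohorts, with the two anchored corner-case levels included.
#' @return Object of class `grid_design`: a `data.frame` of 600 cells with
#'   attributes `coverage` and `subclone_levels`.
#' @export
build_grid <- function(purity_levels = c(0.24, 0.38, 0.52, 0.66, 0.80, 0.93),
                       n_clonal_levels = c(2000, 6000, 12000, 30000, 1e5),
                       f_clonal_levels = c(0.55, 0.70, 0.85, 0.95, 0.995)) {
  stopifnot(length(purity_levels) == 6, length(n_clonal_levels) == 5,
            length(f_clonal_levels) == 5)
  g <- expand.grid(purity = purity_levels, n_clonal = n_clonal_levels,
                   f_clonal = f_clonal_levels,
                   n_subclones = c("0", "1", "2", "3+"),
                   stringsAsFactors = FALSE)
  attr(g, "coverage") <- 48.46621
  attr(g, "subclone_levels") <- c("0", "1", "2", "3+")
  class(g) <- c("grid_design", class(g))
  g
}

#' Two-pass with-replacement sampling of grid cells
#'
#' Pass one draws `n1` cells with replacement from the whole grid; pass two
#' draws `n2` more with replacement, restricted to the cells not covered by
#' pass one. The two-pass strategy maximizes grid coverage while keeping the
#' design hard to reverse-engineer from the sampled tumors.
#'
#' @param grid A [build_grid()] result (or anything with `nrow`).
#' @param n1,n2 Draw counts for the two passes (defaults 600 and 100).
#' @param rng_seed Optional seed.
#' @return Integer vector of length `n1 + n2` of sampled cell indices.
#' @export
two_pass_sample <- function(grid, n1 = 600, n2 = 100, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n_cells <- nrow(grid)
  if (n1 == 0 && n2 == 0) return(integer(0))
  pass1 <- if (n1 > 0) sample.int(n_cells, n1, replace = TRUE) else integer(0)
  uncovered <- setdiff(seq_len(n_cells), unique(pass1))
  if (n2 == 0) return(pass1)
  if (length(uncovered) == 0L) uncovered <- seq_len(n_cells)
  pass2 <- uncovered[sample.int(length(uncovered), n2, replace = TRUE)]
  c(pass1, pass2)
}

#' Calibrate the simulator input SNV count to hit a target output count
#'
#' The detection filter (`alt_count >= min_count`) removes low-frequency
#' mutations, so the number of emitted SNVs is below the number simulated. A
#' dichotomic (bisection) search finds `n_input` such that the mean emitted
#' count over `n_sims` simulations falls within +/- 5% of `target_n_output`.
#'
#' @param target_n_output Desired mean emitted SNV count (>= 50).
#' @param spec_template An [architecture_spec()] whose cluster sizes are
#'   rescaled at each candidate `n_input` (proportions preserved).
#' @param cn_profile,profile Passed to [simulate_reads()].
#' @param min_count Detection threshold.
#' @param n_sims Simulations per candidate (default 10).
#' @param max_iter Bisection iteration cap.
#' @param rng_seed Optional seed.
#' @return List with `n_input`, `mean_output` and `converged`.
#' @export
calibrate_n_input <- function(target_n_output, spec_template, cn_profile,
                              profile, min_count = 3, n_sims = 10,
                              max_iter = 25, rng_seed = NULL) {
  if (target_n_output < 50) stop("target must be >= 50")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  props <- spec_template$cluster_sizes / sum(spec_template$cluster_sizes)
  mean_out <- function(n_input) {
    sizes <- pmax(1L, round(props * n_input))
    sp <- architecture_spec(spec_template$cluster_ccfs, sizes,
                            spec_template$multiplicity_rate)
    mean(vapply(seq_len(n_sims), function(i) {
      nrow(simulate_reads(sp, cn_profile, profile, min_count = min_count))
    }, numeric(1)))
  }
  lo <- target_n_output
  m_lo <- mean_out(lo)
  if (abs(m_lo - target_n_output) <= target_n_output / 20) {
    return(list(n_input = lo, mean_output = m_lo, converged = TRUE))
  }
  hi <- lo
  m_hi <- m_lo
  for (i in 1:12) {           # expand upper bracket
    hi <- hi * 2
    m_hi <- mean_out(hi)
    if (m_hi >= target_n_output) break
  }
  if (m_hi < target_n_output) {
    stop("calibration target unreachable: detection power too low ",
         "(mean output ", round(m_hi), " at n_input ", hi, ")")
  }
  for (i in seq_len(max_iter)) {
    mid <- round((lo + hi) / 2)
    m <- mean_out(mid)
    if (abs(m - target_n_output) <= target_n_output / 20) {
      return(list(n_input = mid, mean_output = m, converged = TRUE))
    }
    if (m < target_n_output) lo <- mid else hi <- mid
    if (hi - lo <= 1) break
  }
  list(n_input = hi, mean_output = mean_out(hi), converged = FALSE)
}

#' Purity of the diploid re-simulation twin
#'
#' When an aneuploid simulation is re-run on a fully diploid genome, the twin
#' purity is chosen to preserve the original nrpcc. The nrpcc-preserving form
#' is \eqn{\rho_d = 2\rho / (\rho\psi_t + 2(1-\rho))}; an alternative literal
#' reading \eqn{\rho_d = (2/\psi_t)\rho} is available behind the `formula`
#' flag.
#'
#' @param purity,tumor_ploidy Original sample values.
#' @param formula `"nrpcc_preserving"` (default) or `"ploidy_ratio"`.
#' @return The diploid twin purity.
#' @export
diploid_twin_purity <- function(purity, tumor_ploidy,
                                formula = c("nrpcc_preserving",
                                            "ploidy_ratio")) {
  formula <- match.arg(formula)
  switch(formula,
    nrpcc_preserving = 2 * purity / (purity * tumor_ploidy + 2 * (1 - purity)),
    ploidy_ratio     = (2 / tumor_ploidy) * purity)
}

#' Add uniform noise to the purity passed to downstream callers
#'
#' The purity handed to reconstruction methods is the true simulation purity
#' plus U(-mad, mad) noise, clamped to (0, 1].
#'
#' @param purity_in True purity.
#' @param mad Half-width of the uniform noise (default 0.05).
#' @param rng_seed Optional seed.
#' @return Noisy purity in (0, 1].
#' @export
noisy_purity <- function(purity_in, mad = 0.05, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  out <- purity_in + runif(length(purity_in), -mad, mad)
  pmin(pmax(out, 1e-6), 1)
}

#' Expected allele fraction under the clonal/subclonal copy-number model
#'
#' Case (a), no subclonal copy-number alteration:
#' \deqn{af = CCF_{mut}\,mult\,\rho \,/\, (2(1-\rho) + \rho\,CN_{cl})}
#' Case (b), subclonal copy-number alteration at the locus: the effective
#' multiplicity is \eqn{mult = mult_{sub} CCF_{scna} + mult_{cl}(1-CCF_{scna})}
#' and the denominator mixes the subclonal and clonal total copy number by
#' \eqn{CCF_{scna}}. Case (b) requires \eqn{CCF_{mut} \in \{1, CCF_{scna},
#' 1 - CCF_{scna}\}} with the matching multiplicity constrained to zero.
#'
#' @param ccf_mut Mutation CCF.
#' @param mult Multiplicity (case a) — ignored in case b.
#' @param purity Sample purity in (0, 1].
#' @param cn_clonal Total copy number of the clonal fraction.
#' @param cn_sub Total copy number of the subclonal fraction (case b).
#' @param ccf_scna CCF of the subclonal copy-number event (0 = none).
#' @param mult_cl,mult_sub Multiplicity on the clonal / subclonal state.
#' @param tol Tolerance for the case-b CCF constraint.
#' @return Expected allele fraction in \[0, 1\].
#' @export
phylogicsim_expected_af <- function(ccf_mut, mult = 1, purity, cn_clonal = 2,
                                    cn_sub = NULL, ccf_scna = 0,
                                    mult_cl = mult, mult_sub = 0,
                                    tol = 1e-9) {
  if (!(purity > 0 && purity <= 1)) stop("purity must be in (0, 1]")
  if (ccf_scna == 0 || is.null(cn_sub)) {
    af <- ccf_mut * mult * purity / (2 * (1 - purity) + purity * cn_clonal)
  } else {
    ok <- abs(ccf_mut - 1) < tol ||
      (abs(ccf_mut - ccf_scna) < tol && abs(mult_cl) < tol) ||
      (abs(ccf_mut - (1 - ccf_scna)) < tol && abs(mult_sub) < tol)
    if (!ok) {
      stop("case-b constraint violated: ccf_mut must be 1, ccf_scna ",
           "(with mult_cl = 0) or 1 - ccf_scna (with mult_sub = 0)")
    }
    m_eff <- mult_sub * ccf_scna + mult_cl * (1 - ccf_scna)
    af <- ccf_mut * m_eff * purity /
      (2 * (1 - purity) + cn_sub * ccf_scna * purity +
         cn_clonal * purity * (1 - ccf_scna))
  }
  min(max(af, 0), 1)
}

#' Beta-binomial coverage draw
#'
#' Sequencing depth per site modeled as Binomial(n, p) with
#' p ~ Beta(alpha, beta), the overdispersed coverage model fitted to normal
#' genome coverage profiles.
#'
#' @param alpha,beta Beta parameters.
#' @param n Binomial size (default 500).
#' @param n_sites Number of independent draws.
#' @param rng_seed Optional seed.
#' @return Integer vector of depths.
#' @export
sample_coverage <- function(alpha, beta, n = 500, n_sites = 1,
                            rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  p <- rbeta(n_sites, alpha, beta)
  rbinom(n_sites, n, p)
}
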