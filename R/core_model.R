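#' Sample profile: purity, ploidy, coverage and sex of one tumor sample
#'
#' Bundles the global parameters of a bulk tumor sequencing sample that anchor
#' all conversions between variant allele frequency (VAF), cancer cell
#' fraction (CCF) and cellular prevalence (CP), as well as the detection-power
#' metric [compute_nrpcc()].
#'
#' @param purity Fraction of cells in the sample that are tumor cells, in
#'   (0, 1].
#' @param tumor_ploidy Mean number of chromosome copies per tumor cell (> 0).
#' @param normal_ploidy Copies per normal cell; 2 unless explicitly overridden
#'   (e.g. haploid sex chromosomes in XY samples).
#' @param coverage Mean sequencing reads per base (>= 0).
#' @param sex `"XX"` or `"XY"`.
#' @return An object of class `sample_profile`.
#' @examples
#' sp <- sample_profile(purity = 0.8, tumor_ploidy = 2, coverage = 60)
#' compute_nrpcc(sp)
#' @export
sample_profile <- function(purity, tumor_ploidy = 2, normal_ploidy = 2,
                           coverage = 0, sex = c("XX", "XY")) {
  sex <- match.arg(sex)
  stopifnot(is.numeric(purity), length(purity) == 1L)
  if (!(purity > 0 && purity <= 1)) {
    stop("purity must be in (0, 1], got ", purity)
  }
  if (!(tumor_ploidy > 0)) stop("tumor_ploidy must be > 0")
  if (!(normal_ploidy > 0)) stop("normal_ploidy must be > 0")
  if (coverage < 0) stop("coverage must be >= 0")
  structure(
    list(purity = purity, tumor_ploidy = tumor_ploidy,
         normal_ploidy = normal_ploidy, coverage = coverage, sex = sex),
    class = "sample_profile"
  )
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf(
    "<sample_profile> purity=%.3f ploidy_t=%.2f ploidy_n=%.2f cov=%.1f sex=%s\n",
    x$purity, x$tumor_ploidy, x$normal_ploidy, x$coverage, x$sex))
  if (x$coverage > 0) cat(sprintf("  nrpcc = %.2f\n", compute_nrpcc(x)))
  invisible(x)
}

#' Number of reads per tumor chromosomal copy (nrpcc)
#'
#' Power metric combining purity, ploidy and coverage:
#' \deqn{nrpcc = \rho \cdot cov / (\rho\psi_t + (1-\rho)\psi_n)}
#' It quantifies how many reads an average single tumor chromosome copy
#' receives, and hence the power to detect subclonal mutations.
#'
#' @param profile A [sample_profile()].
#' @return Reads per haploid tumor copy (>= 0).
#' @export
compute_nrpcc <- function(profile) {
  stopifnot(inherits(profile, "sample_profile"))
  if (profile$coverage <= 0) stop("coverage must be positive to compute nrpcc")
  with(profile,
       purity * coverage / (purity * tumor_ploidy + (1 - purity) * normal_ploidy))
}

#' Minimum detectable cancer cell fraction at a read-count detection limit
#'
#' A mutation needs at least `min_variant_reads` supporting reads to be
#' called; a clone at CCF f on a single copy yields on average `f * nrpcc`
#' variant reads, so the detection limit is `min_variant_reads / nrpcc`.
#' Values above 1 mean no subclone is detectable at all.
#'
#' @param nrpcc Reads per tumor chromosomal copy (> 0).
#' @param min_variant_reads Caller detection threshold (>= 1); the standard
#'   variant-calling pipeline modeled here requires 3.
#' @return CCF detection limit (fraction, may exceed 1).
#' @examples
#' min_detectable_ccf(10, 3)  # 0.30
#' @export
min_detectable_ccf <- function(nrpcc, min_variant_reads = 3) {
  if (!(nrpcc > 0)) stop("nrpcc must be > 0")
  if (min_variant_reads < 1) stop("min_variant_reads must be >= 1")
  min_variant_reads / nrpcc
}

#' Mutation multiplicity and cancer cell fraction from VAF
#'
#' Converts an observed variant allele frequency into a mutation copy number
#' \deqn{u = \frac{f}{\rho}\left[\rho\,n_{tot,t} + (1-\rho)\,n_{tot,n}\right]}
#' then derives the multiplicity m (copies per carrying cell) by rounding and
#' the CCF as u/m.
#'
#' @param vaf Variant allele frequency in \[0, 1\].
#' @param profile A [sample_profile()].
#' @param tumor_total_cn Total tumor copy number at the locus.
#' @param normal_total_cn Total normal copy number at the locus (default 2).
#' @param rounding Multiplicity convention. `"nearest"` (default): m = 1 when
#'   u < 1, otherwise round half away from zero; `"clip"`:
#'   m = max(1, round(u)).
#' @param ccf_ceiling CCF values above this are flagged with a warning (they
#'   indicate purity/copy-number inconsistencies) but returned uncapped so
#'   downstream clustering can see them.
#' @return List with elements `multiplicity`, `ccf`, `mutation_cn` (u) and
#'   `cp` (= purity * ccf). Vectorised over `vaf` and the copy numbers.
#' @examples
#' sp <- sample_profile(purity = 0.5, coverage = 60)
#' snv_ccf(0.125, sp, tumor_total_cn = 2)  # ccf 0.5 on one copy
#' @export
snv_ccf <- function(vaf, profile, tumor_total_cn, normal_total_cn = 2,
                    rounding = c("nearest", "clip"), ccf_ceiling = 1.5) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(profile, "sample_profile"))
  if (any(vaf < 0 | vaf > 1)) stop("vaf must be in [0, 1]")
  if (any(tumor_total_cn < 0) || any(normal_total_cn < 0)) {
    stop("copy numbers must be >= 0")
  }
  if (any(tumor_total_cn == 0 & vaf > 0)) {
    stop("vaf > 0 with tumor_total_cn = 0 is inconsistent")
  }
  rho <- profile$purity
  u <- vaf / rho * (rho * tumor_total_cn + (1 - rho) * normal_total_cn)
  m <- switch(rounding,
    nearest = ifelse(u < 1, 1, round_half_away(u)),
    clip    = pmax(1, round_half_away(u))
  )
  ccf <- ifelse(u > 0, u / m, 0)
  if (any(ccf > ccf_ceiling)) {
    warning(sum(ccf > ccf_ceiling), " SNV(s) exceed the super-clonal CCF ",
            "ceiling of ", ccf_ceiling, "; check purity/copy number inputs")
  }
  list(multiplicity = as.integer(m), ccf = ccf, mutation_cn = u,
       cp = rho * ccf)
}

## round-half-away-from-zero ("nearest integer" reading of the multiplicity
## rounding; base round() would round 2.5 to 2)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Whole-genome duplication classification from caller copy-number profiles
#'
#' Each caller's profile is summarised by the genome fraction in clonal (1,1)
#' and clonal (2,2) states. A caller votes "diploid" when the (1,1) fraction
#' reaches 20%, "tetraploid" when the (2,2) fraction does, and "unknown"
#' otherwise. The sample is WGD-certain only when all callers cast the same
#' diploid or tetraploid vote.
#'
#' @param profiles List of caller profiles; each is a `data.frame` with
#'   columns `chrom`, `start`, `end`, `major`, `minor` and logical
#'   `is_clonal`.
#' @param threshold Genome-fraction threshold for a caller verdict (0.20).
#' @return List with `sample` (`"diploid"`, `"tetraploid"` or
#'   `"WGD-uncertain"`) and `callers` (character vector of per-caller
#'   verdicts).
#' @export
classify_wgd <- function(profiles, threshold = 0.20) {
  if (length(profiles) == 0L) stop("empty caller list")
  verdicts <- vapply(profiles, function(p) {
    len <- p$end - p$start
    tot <- sum(len)
    if (!(tot > 0)) stop("caller profile covers zero bases")
    f11 <- sum(len[p$is_clonal & p$major == 1 & p$minor == 1]) / tot
    f22 <- sum(len[p$is_clonal & p$major == 2 & p$minor == 2]) / tot
    if (f11 >= threshold) "diploid"
    else if (f22 >= threshold) "tetraploid"
    else "unknown"
  }, character(1))
  sample_call <- if (all(verdicts == "diploid")) "diploid"
    else if (all(verdicts == "tetraploid")) "tetraploid"
    else "WGD-uncertain"
  list(sample = sample_call, callers = verdicts)
}

#' Probability that a set of driver mutations is all-clonal, all-subclonal or
#' mixed
#'
#' Given independent per-mutation clonality probabilities p_i, the probability
#' that all n mutations are clonal is the product of the p_i, all-subclonal is
#' the product of (1 - p_i), and "mixed" (at least one clonal and one
#' subclonal) is the complement.
#'
#' @param clonal_probs Numeric vector of per-mutation clonal probabilities in
#'   \[0, 1\].
#' @return Named numeric vector `c(p_all_clonal, p_all_subclonal, p_mixed)`
#'   summing to 1.
#' @examples
#' clonality_profile(c(0.5, 0.5))  # 0.25 / 0.25 / 0.50
#' @export
clonality_profile <- function(clonal_probs) {
  if (length(clonal_probs) == 0L) stop("empty probability list")
  if (any(clonal_probs < 0 | clonal_probs > 1)) {
    stop("probabilities must be in [0, 1]")
  }
  p_cl <- prod(clonal_probs)
  p_sub <- prod(1 - clonal_probs)
  c(p_all_clonal = p_cl, p_all_subclonal = p_sub,
    p_mixed = 1 - p_cl - p_sub)
}

#' Subclonal architecture summary (clustering of 1-d CCF/CP data)
#'
#' A clustering is the currency of all consensus methods: an ordered set of
#' pairs (proportion p_k, location f_k), where f_k is the cancer cell fraction
#' or cellular prevalence of cluster k and p_k the fraction of SNVs assigned
#' to it.
#'
#' @param proportions Cluster proportions, positive and summing to 1.
#' @param locations Cluster locations (>= 0), same length.
#' @param scale `"CCF"` or `"CP"`.
#' @param assignments Optional per-SNV cluster probability matrix (rows sum
#'   to 1, one column per cluster).
#' @param n_snvs_total Optional SNV count behind the summary.
#' @return An object of class `clustering`, canonicalized so that locations
#'   are strictly increasing (co-located clusters are merged).
#' @export
clustering <- function(proportions, locations, scale = c("CCF", "CP"),
                       assignments = NULL, n_snvs_total = NA_integer_) {
  scale <- match.arg(scale)
  stopifnot(length(proportions) == length(locations), length(locations) > 0)
  if (any(proportions <= 0)) stop("cluster proportions must be positive")
  if (any(locations < 0)) stop("cluster locations must be >= 0")
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("cluster proportions must sum to 1 (got ", sum(proportions), ")")
  }
  proportions <- unname(proportions)
  locations <- unname(locations)
  ord <- order(locations)
  locations <- locations[ord]
  proportions <- proportions[ord]
  if (!is.null(assignments)) assignments <- assignments[, ord, drop = FALSE]
  # merge duplicate locations so the CDF breakpoints are strictly increasing
  if (anyDuplicated(locations)) {
    key <- match(locations, unique(locations))
    proportions <- as.numeric(tapply(proportions, key, sum))
    if (!is.null(assignments)) {
      assignments <- t(rowsum(t(assignments), key))
    }
    locations <- unique(locations)
  }
  structure(
    list(proportions = proportions, locations = locations, scale = scale,
         assignments = assignments, n_snvs_total = n_snvs_total),
    class = "clustering"
  )
}

#' @export
print.clustering <- function(x, ...) {
  cat(sprintf("<clustering> %d cluster(s) on %s scale\n",
              length(x$locations), x$scale))
  print(data.frame(cluster = seq_along(x$locations),
                   location = x$locations, proportion = x$proportions),
        row.names = FALSE)
  invisible(x)
}

#' @export
format.clustering <- function(x, ...) {
  paste(sprintf("(%.3g @ %.3g)", x$proportions, x$locations), collapse = " ")
}

#' Number of clusters of a clustering
#' @param x A [clustering()].
#' @return Integer cluster count.
#' @export
n_clusters <- function(x) {
  stopifnot(inherits(x, "clustering"))
  length(x$locations)
}

#' Per-caller allele-specific copy-number profile
#'
#' Light container for one copy-number caller's segmentation with clonal or
#' subclonal states, used by WGD classification and the consensus procedures.
#'
#' @param caller_id Caller label.
#' @param segments `data.frame` with columns `chrom`, `start`, `end`,
#'   `major`, `minor`, `is_clonal` and optionally `ccf` (CCF of the minority
#'   state when subclonal). Coordinates are 0-based half-open internally.
#' @param purity,ploidy Caller's own purity/ploidy estimates.
#' @return Object of class `caller_copy_profile`.
#' @export
caller_copy_profile <- function(caller_id, segments, purity = NA_real_,
                                ploidy = NA_real_) {
  req <- c("chrom", "start", "end", "major", "minor")
  if (!all(req %in% names(segments))) {
    stop("segments must have columns ", paste(req, collapse = ", "))
  }
  if (is.null(segments$is_clonal)) segments$is_clonal <- TRUE
  if (any(segments$major < segments$minor)) {
    stop("major allele copy number must be >= minor")
  }
  if (any(segments$minor < 0)) stop("copy numbers must be >= 0")
  # non-overlap within chromosome
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    s <- s[order(s$start), ]
    if (any(s$start[-1] < s$end[-nrow(s)])) {
      stop("overlapping segments in caller ", caller_id, " chrom ", ch)
    }
  }
  structure(list(caller_id = caller_id, segments = segments,
                 purity = purity, ploidy = ploidy),
            class = "caller_copy_profile")
}
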