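#' Consensus segment breakpoints across copy-number callers
#'
#' Each caller's segmentation implies, for every gap between adjacent
#' segments, a plausible breakpoint interval `(E_i - delta, S_(i+1) + delta)`
#' scored by the empirical-CDF rank of the gap size within that caller
#' (small gap = confident placement). Scanning each chromosome from the
#' start, the first intersection of intervals supported by the threshold
#' rule — at least `min_any` callers, or at least `min_conservative` of the
#' callers tagged conservative — yields one consensus breakpoint: the
#' candidate segment-start/end locus inside the intersection with the
#' smallest gap rank (ties prefer end loci; if no locus falls inside, the
#' upstream end of the intersection). Contributing intervals are removed and
#' the scan repeats. Optionally, structural-variant breakpoints within
#' `sv_radius` replace the nearest consensus breakpoint (and unmatched SVs
#' are added), and centromere/telomere anchors are enforced.
#'
#' @param segmentations Named list of `data.frame`s (one per caller) with
#'   columns `chrom`, `start`, `end`, sorted and non-overlapping.
#' @param conservative Character vector of caller names counted as
#'   conservative.
#' @param delta Slack added on both sides of each gap (default 50000).
#' @param min_any,min_conservative The "any 3, or any 2 conservative" rule.
#' @param sv_breakpoints Optional `data.frame` with `chrom`, `pos`.
#' @param sv_radius SV replacement radius (default 1e5).
#' @param centromeres Optional `data.frame` with `chrom`, `start`, `end`.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @param anchor_radius Centromere/telomere anchor distance (default 1e6).
#' @return `data.frame` with `chrom`, `pos`, `source`
#'   (`"consensus"`, `"sv"`, `"anchor"`).
#' @export
consensus_breakpoints <- function(segmentations, conservative = character(0),
                                  delta = 5e4, min_any = 3,
                                  min_conservative = 2,
                                  sv_breakpoints = NULL, sv_radius = 1e5,
                                  centromeres = NULL, chrom_lengths = NULL,
                                  anchor_radius = 1e6) {
  stopifnot(length(segmentations) >= 1)
  if (is.null(names(segmentations))) {
    names(segmentations) <- paste0("m", seq_along(segmentations))
  }
  for (nm in names(segmentations)) {
    s <- segmentations[[nm]]
    for (ch in unique(s$chrom)) {
      sc <- s[s$chrom == ch, ]
      sc <- sc[order(sc$start), ]
      if (any(sc$start[-1] < sc$end[-nrow(sc)])) {
        stop("method ", nm, " has overlapping segments on chrom ", ch)
      }
    }
  }
  # per-caller breakpoint intervals with gap-rank scores (ranks are computed
  # genome-wide within each caller)
  ivs <- list()
  for (nm in names(segmentations)) {
    s <- segmentations[[nm]]
    rows <- list()
    for (ch in unique(s$chrom)) {
      sc <- s[s$chrom == ch, ]
      sc <- sc[order(sc$start), ]
      if (nrow(sc) < 2) next
      e <- sc$end[-nrow(sc)]
      st <- sc$start[-1]
      rows[[ch]] <- data.frame(method = nm, chrom = ch,
                               lo = e - delta, hi = st + delta,
                               end_locus = e, start_locus = st,
                               gap = st - e, stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      iv <- do.call(rbind, rows)
      iv$g <- stats::ecdf(iv$gap)(iv$gap)
      ivs[[nm]] <- iv
    }
  }
  iv_all <- if (length(ivs)) do.call(rbind, ivs) else NULL
  out <- list()
  for (ch in unique(unlist(lapply(segmentations, function(s) s$chrom)))) {
    active <- if (is.null(iv_all)) NULL else
      iv_all[iv_all$chrom == ch, , drop = FALSE]
    repeat {
      hit <- find_first_intersection(active, conservative, min_any,
                                     min_conservative)
      if (is.null(hit)) break
      sel <- active[hit$rows, , drop = FALSE]
      # candidate loci inside the intersection, smallest gap rank wins;
      # ties prefer end loci over start loci
      cand <- rbind(
        data.frame(pos = sel$end_locus, g = sel$g, is_end = TRUE),
        data.frame(pos = sel$start_locus, g = sel$g, is_end = FALSE))
      cand <- cand[cand$pos >= hit$lo & cand$pos <= hit$hi, , drop = FALSE]
      pos <- if (nrow(cand) == 0L) {
        hit$lo
      } else {
        cand <- cand[order(cand$g, !cand$is_end, cand$pos), , drop = FALSE]
        cand$pos[1]
      }
      out[[length(out) + 1L]] <- data.frame(chrom = ch, pos = pos,
                                            source = "consensus",
                                            stringsAsFactors = FALSE)
      active <- active[-hit$rows, , drop = FALSE]
    }
  }
  bp <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), pos = numeric(0), source = character(0))

  # SV merge: replace consensus breakpoints by nearby SVs, add unmatched SVs
  if (!is.null(sv_breakpoints) && nrow(sv_breakpoints)) {
    for (i in seq_len(nrow(sv_breakpoints))) {
      svc <- sv_breakpoints$chrom[i]
      svp <- sv_breakpoints$pos[i]
      near <- which(bp$chrom == svc & abs(bp$pos - svp) <= sv_radius &
                      bp$source == "consensus")
      if (length(near)) {
        j <- near[which.min(abs(bp$pos[near] - svp))]
        bp$pos[j] <- svp
        bp$source[j] <- "sv"
      } else {
        bp <- rbind(bp, data.frame(chrom = svc, pos = svp, source = "sv",
                                   stringsAsFactors = FALSE))
      }
    }
  }

  # centromere / telomere anchors; all edges are checked against the
  # pre-anchor breakpoint set so one anchor never suppresses another
  if (!is.null(centromeres) && nrow(centromeres)) {
    for (i in seq_len(nrow(centromeres))) {
      ch <- centromeres$chrom[i]
      cs <- centromeres$start[i]
      ce <- centromeres$end[i]
      inside <- which(bp$chrom == ch & bp$pos > cs & bp$pos < ce)
      for (j in inside) {
        bp$pos[j] <- if (bp$pos[j] - cs <= ce - bp$pos[j]) cs else ce
      }
    }
  }
  bp0 <- bp
  add_anchor <- function(ch, edge) {
    if (!any(bp0$chrom == ch & abs(bp0$pos - edge) <= anchor_radius)) {
      bp <<- rbind(bp, data.frame(chrom = ch, pos = edge,
                                  source = "anchor",
                                  stringsAsFactors = FALSE))
    }
  }
  if (!is.null(centromeres) && nrow(centromeres)) {
    for (i in seq_len(nrow(centromeres))) {
      add_anchor(centromeres$chrom[i], centromeres$start[i])
      add_anchor(centromeres$chrom[i], centromeres$end[i])
    }
  }
  if (!is.null(chrom_lengths)) {
    for (ch in names(chrom_lengths)) {
      add_anchor(ch, 1)
      add_anchor(ch, chrom_lengths[[ch]])
    }
  }
  bp <- bp[order(bp$chrom, bp$pos), , drop = FALSE]
  rownames(bp) <- NULL
  bp
}

## leftmost point at which the interval set satisfies the support rule;
## returns the qualifying intersection [max starts, min ends] and the rows of
## the intervals covering it
find_first_intersection <- function(iv, conservative, min_any,
                                    min_conservative) {
  if (is.null(iv) || nrow(iv) == 0L) return(NULL)
  pts <- sort(unique(iv$lo))
  for (x in pts) {
    rows <- which(iv$lo <= x & iv$hi >= x)
    methods <- unique(iv$method[rows])
    ok <- length(methods) >= min_any ||
      sum(unique(iv$method[rows]) %in% conservative) >= min_conservative
    if (!ok) next
    lo <- max(iv$lo[rows])
    hi <- min(iv$hi[rows])
    return(list(rows = rows, lo = lo, hi = hi))
  }
  NULL
}

#' Consensus copy-number call for one segment (agreement levels a-i)
#'
#' Per-caller states for a single consensus segment are reduced to one call
#' by walking an ordered ladder of agreement levels:
#' a — all callers agree on a clonal state; b — leave-one-out agreement;
#' c — agreement after excluding callers whose sample ploidy was overruled;
#' d — majority of available callers agree on a clonal state; e — complete or
#' leave-one-out agreement over the rounded-subclonal state inventory;
#' f — majority over the inventory; g — the best caller's call, required to
#' match a single-allele consensus when one exists (else fall through);
#' h — the next-best caller's call; i — expert-panel-unresolved flag. Levels
#' a-c earn 3 stars, d-f 2 stars, g-i 1 star.
#'
#' @param calls List, one element per caller: each a list with `caller`,
#'   `states` (matrix/data.frame of candidate (major, minor) rows — one row
#'   for a clonal call, several for the rounded subclonal inventory),
#'   `is_clonal` (logical) and optional `ploidy_overruled` (logical).
#' @param best_method_ranking Character vector of caller names from best to
#'   worst (levels g/h).
#' @param panel_unresolved If TRUE the sample's expert review failed; every
#'   segment is marked level `"i"`.
#' @param quorum Number of callers expected to report on this chromosome
#'   (defaults to `length(calls)`; reduce for X/Y).
#' @return List with `major`, `minor`, `level` (`"a"`..`"i"` or `"no-call"`)
#'   and `stars` (3, 2, 1 or NA).
#' @export
segment_agreement <- function(calls, best_method_ranking = NULL,
                              panel_unresolved = FALSE,
                              quorum = length(calls)) {
  if (length(calls) == 0L || all(vapply(calls, is.null, logical(1)))) {
    return(list(major = NA_real_, minor = NA_real_, level = "no-call",
                stars = NA_integer_))
  }
  calls <- calls[!vapply(calls, is.null, logical(1))]
  H <- length(calls)
  state_key <- function(m) paste(m[, 1], m[, 2], sep = "/")
  clonal_state <- vapply(calls, function(cl) {
    if (isTRUE(cl$is_clonal)) state_key(rbind(as.numeric(cl$states[1, ])))
    else NA_character_
  }, character(1))
  overruled <- vapply(calls, function(cl)
    isTRUE(cl$ploidy_overruled), logical(1))
  finish <- function(key, level) {
    mm <- as.numeric(strsplit(key, "/")[[1]])
    stars <- if (level %in% c("a", "b", "c")) 3L
      else if (level %in% c("d", "e", "f")) 2L else 1L
    if (panel_unresolved) {
      level <- "i"
      stars <- 1L
    }
    list(major = mm[1], minor = mm[2], level = level, stars = stars)
  }
  # a: unanimous clonal agreement
  if (!anyNA(clonal_state) && length(unique(clonal_state)) == 1L) {
    return(finish(clonal_state[1], "a"))
  }
  # b: leave-one-out clonal agreement (needs >= 3 callers)
  if (H >= 3) {
    for (drop in seq_len(H)) {
      rest <- clonal_state[-drop]
      if (!anyNA(rest) && length(unique(rest)) == 1L) {
        return(finish(rest[1], "b"))
      }
    }
  }
  # c: agreement after excluding ploidy-overruled profiles
  if (any(overruled) && sum(!overruled) >= 2) {
    rest <- clonal_state[!overruled]
    if (!anyNA(rest) && length(unique(rest)) == 1L) {
      return(finish(rest[1], "c"))
    }
  }
  # d: clonal majority of available methods
  maj_n <- floor(quorum / 2) + 1
  tab <- table(clonal_state[!is.na(clonal_state)])
  if (length(tab) && max(tab) >= maj_n) {
    return(finish(names(tab)[which.max(tab)], "d"))
  }
  # e/f: rounded-subclonal inventory; a caller supports a state if the state
  # appears among its candidates
  inventory <- unique(unlist(lapply(calls, function(cl)
    state_key(cl$states))))
  support <- vapply(inventory, function(st) {
    sum(vapply(calls, function(cl) st %in% state_key(cl$states), logical(1)))
  }, integer(1))
  if (length(inventory)) {
    best <- which(support == max(support))[1]
    if (support[best] >= H - 1 && H >= 3) {
      return(finish(inventory[best], "e"))
    }
    if (support[best] >= maj_n) {
      return(finish(inventory[best], "f"))
    }
  }
  # single-allele consensus for the g-level constraint
  allele_consensus <- function(col) {
    vals <- unlist(lapply(calls, function(cl) unique(cl$states[, col])))
    tab <- table(vals)
    if (length(tab) && max(tab) >= maj_n) {
      as.numeric(names(tab)[which.max(tab)])
    } else NA_real_
  }
  cons_major <- allele_consensus(1)
  cons_minor <- allele_consensus(2)
  # g/h: iterate best-to-worst callers
  ranking <- if (is.null(best_method_ranking)) {
    vapply(calls, `[[`, character(1), "caller")
  } else best_method_ranking
  first <- TRUE
  for (nm in ranking) {
    idx <- which(vapply(calls, `[[`, character(1), "caller") == nm)
    if (!length(idx) || overruled[idx]) {
      first <- FALSE
      next
    }
    st <- as.numeric(calls[[idx]]$states[1, ])
    agrees <- (is.na(cons_major) || st[1] == cons_major) &&
      (is.na(cons_minor) || st[2] == cons_minor)
    if (first && !agrees) {
      # best method conflicts with the established allele consensus;
      # fall through to the next method (level h)
      first <- FALSE
      next
    }
    level <- if (first) "g" else "h"
    return(finish(paste(st[1], st[2], sep = "/"), level))
  }
  if (panel_unresolved) {
    st <- as.numeric(calls[[1]]$states[1, ])
    return(finish(paste(st[1], st[2], sep = "/"), "i"))
  }
  list(major = NA_real_, minor = NA_real_, level = "no-call",
       stars = NA_integer_)
}

#' Rank copy-number callers by agreement with the a-f consensus
#'
#' The fraction of consensus-called genome (levels a-f) on which each
#' caller's clonal state matches the consensus state, excluding
#' ploidy-overruled profiles; used to order callers for levels g/h.
#'
#' @param per_segment List over segments; each element a list with `width`,
#'   `consensus` (state key `"major/minor"` or NA) and `caller_states`
#'   (named character vector of per-caller state keys).
#' @param overruled Named logical vector of ploidy-overruled callers.
#' @return Character vector of caller names, best first (ties broken by
#'   caller id).
#' @export
rank_callers <- function(per_segment, overruled = NULL) {
  callers <- unique(unlist(lapply(per_segment, function(s)
    names(s$caller_states))))
  if (!is.null(overruled)) {
    callers <- setdiff(callers, names(overruled)[overruled])
  }
  frac <- vapply(callers, function(nm) {
    num <- 0
    den <- 0
    for (s in per_segment) {
      if (is.na(s$consensus)) next
      den <- den + s$width
      if (!is.na(s$caller_states[nm]) && s$caller_states[nm] == s$consensus) {
        num <- num + s$width
      }
    }
    if (den > 0) num / den else 0
  }, numeric(1))
  callers[order(-frac, callers)]
}

#' Consensus purity from copy-number and SNV-based calls
#'
#' Ploidy-overruled copy-number callers are excluded; purity calls differing
#' by more than `outlier_delta` from every other surviving call in their
#' group are dropped (separately for copy-number-based and SNV-based calls);
#' when less than `min_frac_altered` of the genome is altered the density is
#' computed over SNV-based calls only; the consensus is the surviving call
#' closest to the mode of a Gaussian kernel density (Silverman bandwidth) and
#' the confidence is the median absolute deviation of the survivors.
#'
#' @param cna_purities Named numeric vector of copy-number-based calls.
#' @param snv_purities Named numeric vector of SNV-based calls.
#' @param frac_genome_altered Fraction of the genome with non-diploid
#'   consensus state.
#' @param cna_ploidies Optional named vector of caller ploidies.
#' @param ref_ploidy Optional reference ploidy; callers with
#'   `|ploidy - ref| > 0.25 * ref` are overruled.
#' @param outlier_delta Pairwise-difference filter (default 0.2).
#' @param min_frac_altered Threshold below which only SNV calls are used
#'   (default 0.08).
#' @return List with `purity`, `mad`, `used` (surviving calls) and
#'   `filtered` (named reasons for dropped calls).
#' @export
consensus_purity <- function(cna_purities, snv_purities = numeric(0),
                             frac_genome_altered = 1,
                             cna_ploidies = NULL, ref_ploidy = NULL,
                             outlier_delta = 0.2, min_frac_altered = 0.08) {
  filtered <- character(0)
  if (!is.null(cna_ploidies) && !is.null(ref_ploidy)) {
    bad <- abs(cna_ploidies - ref_ploidy) > 0.25 * ref_ploidy
    for (nm in names(cna_ploidies)[bad]) filtered[nm] <- "ploidy_overruled"
    cna_purities <- cna_purities[!names(cna_purities) %in%
                                   names(filtered)]
  }
  drop_outliers <- function(x) {
    if (length(x) < 2) return(x)
    keep <- vapply(seq_along(x), function(i)
      any(abs(x[i] - x[-i]) <= outlier_delta), logical(1))
    for (nm in names(x)[!keep]) filtered[nm] <<- "purity_outlier"
    x[keep]
  }
  cna_purities <- drop_outliers(cna_purities)
  snv_purities <- drop_outliers(snv_purities)
  pool <- if (frac_genome_altered < min_frac_altered &&
                length(snv_purities) > 0) {
    snv_purities
  } else {
    c(cna_purities, snv_purities)
  }
  if (length(pool) == 0L) {
    stop("all purity calls filtered out; audit: ",
         paste(names(filtered), filtered, sep = "=", collapse = ", "))
  }
  if (length(pool) == 1L) {
    return(list(purity = unname(pool), mad = NA_real_, used = pool,
                filtered = filtered, low_confidence = TRUE))
  }
  dens <- stats::density(pool, bw = "nrd0")
  mode_x <- dens$x[which.max(dens$y)]
  purity <- pool[which.min(abs(pool - mode_x))]
  list(purity = unname(purity), mad = stats::mad(pool), used = pool,
       filtered = filtered, low_confidence = FALSE)
}
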