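seg_from_bps <- function(bps, L = 1e7, gaps = 0) {
  # breakpoints given as segment-junction midpoints; gaps spread symmetric
  e <- bps - gaps / 2
  s <- bps + gaps / 2
  data.frame(chrom = "1", start = c(0, s), end = c(e, L))
}

test_that("breakpoint consensus honors the any3 / any2-conservative rule", {
  s3 <- list(a = seg_from_bps(5e6), b = seg_from_bps(5e6),
             c = seg_from_bps(5e6))
  bp <- consensus_breakpoints(s3)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$pos, 5e6)
  # two liberal methods agreeing: no call
  s2 <- list(l1 = seg_from_bps(5e6), l2 = seg_from_bps(5e6))
  expect_equal(nrow(consensus_breakpoints(s2)), 0)
  # two conservative methods agreeing: call
  expect_equal(nrow(consensus_breakpoints(
    s2, conservative = c("l1", "l2"))), 1)
  # overlapping segments rejected
  bad <- list(a = data.frame(chrom = "1", start = c(0, 4e6),
                             end = c(5e6, 1e7)))
  expect_error(consensus_breakpoints(bad), "overlapping")
})

test_that("smallest gap rank wins inside an intersection, end loci on ties", {
  # three methods around 5e6; method b places a tight gap -> its locus wins
  s <- list(
    a = seg_from_bps(5.00e6, gaps = 8e4),
    b = seg_from_bps(5.02e6, gaps = 1e4),
    c = seg_from_bps(4.98e6, gaps = 8e4))
  bp <- consensus_breakpoints(s)
  expect_equal(nrow(bp), 1)
  # b's loci are end 5.015e6 / start 5.025e6; tie on rank prefers the end
  expect_equal(bp$pos, 5.02e6 - 5e3)
})

test_that("breakpoint consensus equals the per-base scan oracle on
           randomized toys", {
  set.seed(61)
  delta <- 20
  for (case in 1:150) {
    n_m <- sample(3:5, 1)
    L <- 2000
    segs <- list()
    for (m in seq_len(n_m)) {
      k <- sample(4:10, 1)
      bps <- sort(sample(seq(60, L - 60), k))
      while (min(diff(c(0, bps, L))) < 30) {
        bps <- sort(sample(seq(60, L - 60), k))
      }
      gaps <- sample(seq(0, 16, by = 2), k, replace = TRUE)
      e <- bps - gaps / 2
      s <- bps + gaps / 2
      segs[[paste0("m", m)]] <- data.frame(chrom = "1", start = c(0, s),
                                           end = c(e, L))
    }
    cons_m <- sample(names(segs), 2)
    got <- consensus_breakpoints(segs, conservative = cons_m,
                                 delta = delta)
    want <- breakpoint_oracle(segs, cons_m, delta)
    expect_equal(sort(got$pos), want,
                 info = paste("case", case))
  }
})

test_that("duplicating a method never removes a breakpoint", {
  set.seed(62)
  for (case in 1:20) {
    segs <- list(
      a = seg_from_bps(sort(sample(seq(1e6, 9e6, by = 1e5), 3))),
      b = seg_from_bps(sort(sample(seq(1e6, 9e6, by = 1e5), 3))),
      c = seg_from_bps(sort(sample(seq(1e6, 9e6, by = 1e5), 3))))
    before <- consensus_breakpoints(segs)$pos
    segs$dup <- segs$a
    after <- consensus_breakpoints(segs)$pos
    expect_true(all(before %in% after))
  }
})

test_that("SV and centromere/telomere handling adjust the breakpoint set", {
  s <- list(a = seg_from_bps(5e6), b = seg_from_bps(5e6),
            c = seg_from_bps(5e6))
  sv <- data.frame(chrom = "1", pos = c(5.05e6, 8e6))
  bp <- consensus_breakpoints(s, sv_breakpoints = sv)
  # nearby SV replaces the consensus position; distant SV is added
  expect_true(5.05e6 %in% bp$pos)
  expect_false(5e6 %in% bp$pos)
  expect_true(8e6 %in% bp$pos)
  # centromere anchors appear when nothing is nearby; inside moves to edge
  cent <- data.frame(chrom = "1", start = 2e6, end = 3e6)
  bp2 <- consensus_breakpoints(s, centromeres = cent,
                               chrom_lengths = c("1" = 1e7))
  expect_true(all(c(2e6, 3e6, 1, 1e7) %in% bp2$pos))
})

test_that("agreement ladder assigns levels and stars in order", {
  clonal <- function(major, minor, caller, over = FALSE) {
    list(caller = caller, states = rbind(c(major, minor)), is_clonal = TRUE,
         ploidy_overruled = over)
  }
  six <- lapply(1:6, function(i) clonal(2, 1, paste0("m", i)))
  r <- segment_agreement(six)
  expect_equal(r[c("level", "stars")], list(level = "a", stars = 3L))
  # one disagrees -> leave-one-out, still 3 stars
  six_b <- six
  six_b[[6]] <- clonal(3, 1, "m6")
  expect_equal(segment_agreement(six_b)$level, "b")
  expect_equal(segment_agreement(six_b)$stars, 3L)
  # ploidy-overruled caller excluded at level c
  six_c <- six
  six_c[[6]] <- clonal(4, 2, "m6", over = TRUE)
  six_c[[5]] <- clonal(2, 1, "m5")
  r_c <- segment_agreement(six_c)
  expect_true(r_c$level %in% c("b", "c"))   # b also matches by construction
  # majority only -> level d, 2 stars
  four_two <- c(lapply(1:4, function(i) clonal(2, 1, paste0("m", i))),
                list(clonal(3, 1, "m5"), clonal(2, 2, "m6")))
  r_d <- segment_agreement(four_two)
  expect_equal(r_d$level, "d")
  expect_equal(r_d$stars, 2L)
  # rounded-subclonal inventory: all three callers support (2,1) after
  # rounding, i.e. complete rounded agreement -> level e, 2 stars
  sub <- function(caller) {
    list(caller = caller, states = rbind(c(2, 1), c(3, 1)),
         is_clonal = FALSE)
  }
  mix <- list(sub("m1"), sub("m2"), clonal(2, 1, "m3"))
  r_e <- segment_agreement(mix)
  expect_equal(r_e$level, "e")
  expect_equal(r_e$stars, 2L)
  expect_equal(c(r_e$major, r_e$minor), c(2, 1))
  # rounded majority only (3 of 5, below leave-one-out) -> level f
  mix_f <- list(sub("m1"), sub("m2"), clonal(2, 1, "m3"),
                clonal(4, 0, "m4"), clonal(1, 0, "m5"))
  r_f <- segment_agreement(mix_f)
  expect_equal(r_f$level, "f")
  expect_equal(r_f$stars, 2L)
  expect_equal(c(r_f$major, r_f$minor), c(2, 1))
  # no agreement at all: best method's call, level g, 1 star
  spread <- list(clonal(1, 1, "m1"), clonal(2, 0, "m2"), clonal(3, 2, "m3"))
  r_g <- segment_agreement(spread, best_method_ranking = c("m2", "m1",
                                                           "m3"))
  expect_equal(r_g$level, "g")
  expect_equal(r_g$stars, 1L)
  expect_equal(c(r_g$major, r_g$minor), c(2, 0))
  # no caller covers the segment
  expect_equal(segment_agreement(list())$level, "no-call")
  # panel-unresolved samples are re-marked level i
  r_i <- segment_agreement(six, panel_unresolved = TRUE)
  expect_equal(r_i$level, "i")
  expect_equal(r_i$stars, 1L)
})

test_that("level assignment is order-independent", {
  clonal <- function(major, minor, caller) {
    list(caller = caller, states = rbind(c(major, minor)),
         is_clonal = TRUE)
  }
  calls <- list(clonal(2, 1, "m1"), clonal(2, 1, "m2"), clonal(3, 1, "m3"),
                clonal(2, 1, "m4"))
  r1 <- segment_agreement(calls, best_method_ranking = paste0("m", 1:4))
  r2 <- segment_agreement(rev(calls), best_method_ranking = paste0("m", 1:4))
  expect_equal(r1, r2)
})

test_that("caller ranking orders by fraction of consensus genome matched", {
  per_seg <- list(
    list(width = 10, consensus = "2/1",
         caller_states = c(a = "2/1", b = "2/1", c = "3/1")),
    list(width = 30, consensus = "1/1",
         caller_states = c(a = "1/1", b = "2/2", c = "1/1")),
    list(width = 5, consensus = NA,
         caller_states = c(a = "9/9", b = "9/9", c = "9/9")))
  r <- rank_callers(per_seg)
  expect_equal(r, c("a", "c", "b"))
})

test_that("consensus purity takes the density mode and filters outliers", {
  r <- consensus_purity(c(a = 0.60, b = 0.61, c = 0.59, d = 0.95))
  expect_lt(abs(r$purity - 0.60), 0.015)
  expect_equal(unname(r$filtered["d"]), "purity_outlier")
  # unanimous callers: exact value, zero MAD
  r2 <- consensus_purity(c(a = 0.7, b = 0.7, c = 0.7))
  expect_equal(r2$purity, 0.7)
  expect_equal(r2$mad, 0)
  # quiet genome: only SNV-based calls enter the density
  r3 <- consensus_purity(c(a = 0.9, b = 0.9),
                         snv_purities = c(x = 0.5, y = 0.51, z = 0.49),
                         frac_genome_altered = 0.05)
  expect_lt(abs(r3$purity - 0.5), 0.02)
  # ploidy overrule removes a caller before the density
  r4 <- consensus_purity(c(a = 0.6, b = 0.62, c = 0.3),
                         cna_ploidies = c(a = 2, b = 2.1, c = 4.5),
                         ref_ploidy = 2)
  expect_equal(unname(r4$filtered["c"]), "ploidy_overruled")
})
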