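test_that("count_loh applies the 15 Mb / whole-chromosome rules", {
  g <- geom1()
  # fully heterozygous diploid chromosome
  expect_equal(count_loh(prof(seg(0, 100 * Mb, 1, 1)), g), 0L)
  # interstitial 30 Mb LOH run
  p <- prof(seg(0, 20 * Mb, 1, 1), seg(20 * Mb, 50 * Mb, 2, 0),
            seg(50 * Mb, 100 * Mb, 1, 1))
  expect_equal(count_loh(p, g), 1L)
  # whole-chromosome LOH is excluded
  expect_equal(count_loh(prof(seg(0, 100 * Mb, 2, 0)), g), 0L)
  # 10 Mb is below the threshold; exactly 15 Mb is too (strict >)
  expect_equal(count_loh(prof(seg(20 * Mb, 30 * Mb, 1, 0)), g), 0L)
  expect_equal(count_loh(prof(seg(20 * Mb, 35 * Mb, 1, 0)), g), 0L)
  expect_equal(count_loh(prof(seg(20 * Mb, 35 * Mb + 1, 1, 0)), g), 1L)
})

test_that("abutting LOH segments with different major CN form one region", {
  g <- geom1()
  p <- prof(seg(10 * Mb, 20 * Mb, 1, 0), seg(20 * Mb, 30 * Mb, 2, 0))
  expect_equal(count_loh(p, g), 1L)
  expect_equal(count_loh(p, g, merge_runs = FALSE), 0L)  # two 10 Mb runs
})

test_that("count_tai requires a telomeric anchor off the centromere", {
  g <- geom1()  # centromere 40-45 Mb
  # balanced genome
  expect_equal(count_tai(prof(seg(0, 50 * Mb, 2, 2),
                              seg(50 * Mb, 100 * Mb, 1, 1)), g), 0L)
  # AI run anchored at the p telomere, ends before the centromere
  expect_equal(count_tai(prof(seg(0, 30 * Mb, 2, 1),
                              seg(30 * Mb, 100 * Mb, 1, 1)), g), 1L)
  # interstitial AI run crossing the centromere: neither anchored nor clear
  expect_equal(count_tai(prof(seg(30 * Mb, 60 * Mb, 2, 1)), g), 0L)
  # anchored but crossing the centromere still fails
  expect_equal(count_tai(prof(seg(0, 60 * Mb, 2, 1)), g), 0L)
  # runs on both arms count separately
  p2 <- prof(seg(0, 30 * Mb, 2, 1), seg(30 * Mb, 70 * Mb, 1, 1),
             seg(70 * Mb, 100 * Mb, 3, 1))
  expect_equal(count_tai(p2, g), 2L)
})

test_that("TAI run contiguity is state-level by default", {
  g <- geom1()
  # 2/1 abutting 3/1: one telomeric AI run at state level, two segment-level
  # runs of which only the first is anchored
  p <- prof(seg(0, 15 * Mb, 2, 1), seg(15 * Mb, 30 * Mb, 3, 1))
  expect_equal(count_tai(p, g), 1L)
  expect_equal(count_tai(p, g, state_level = FALSE), 1L)
  # with a minimum length of 20 Mb only the merged run qualifies
  expect_equal(count_tai(p, g, min_len = 20 * Mb), 1L)
  expect_equal(count_tai(p, g, min_len = 20 * Mb, state_level = FALSE), 0L)
})

test_that("telomere tolerance admits runs near position 0 or L", {
  g <- geom1()
  p <- prof(seg(500, 30 * Mb, 2, 1))
  expect_equal(count_tai(p, g, tel_tol = 0), 0L)
  expect_equal(count_tai(p, g, tel_tol = 1000), 1L)
})

test_that("count_lst counts >= 10 Mb breakpoint pairs after smoothing", {
  g <- geom1()
  # one uniform segment: no breakpoints
  expect_equal(count_lst(prof(seg(0, 100 * Mb, 1, 1)), g), 0L)
  # two >= 10 Mb segments with differing states on one arm
  p <- prof(seg(0, 20 * Mb, 1, 1), seg(20 * Mb, 40 * Mb, 2, 1))
  expect_equal(count_lst(p, g), 1L)
  # a 2 Mb interruption between equal-state flanks is smoothed away
  p2 <- prof(seg(0, 20 * Mb, 1, 1), seg(20 * Mb, 22 * Mb, 2, 2),
             seg(22 * Mb, 40 * Mb, 1, 1))
  expect_equal(count_lst(p2, g), 0L)
  # an 8 Mb flank does not qualify
  p3 <- prof(seg(0, 20 * Mb, 1, 1), seg(20 * Mb, 28 * Mb, 2, 1))
  expect_equal(count_lst(p3, g), 0L)
  # exactly 10 Mb flanks qualify (inclusive), across a <= 3 Mb gap
  p4 <- prof(seg(10 * Mb, 20 * Mb, 1, 1), seg(23 * Mb, 33 * Mb, 2, 1))
  expect_equal(count_lst(p4, g), 1L)
  p5 <- prof(seg(10 * Mb, 20 * Mb, 1, 1), seg(24 * Mb, 34 * Mb, 2, 1))
  expect_equal(count_lst(p5, g), 0L)  # 4 Mb gap: not adjacent
})

test_that("LST breakpoints at or across the centromere do not count", {
  g <- geom1()  # centromere 40-45 Mb
  # state change exactly at a centromere boundary: pieces are on different
  # arms, no pair
  p <- prof(seg(0, 40 * Mb, 1, 1), seg(40 * Mb, 100 * Mb, 2, 1))
  expect_equal(count_lst(p, g), 0L)
  # segment spanning the centromere is truncated; its arm pieces pair with
  # neighbours inside each arm
  p2 <- prof(seg(0, 30 * Mb, 1, 1), seg(30 * Mb, 60 * Mb, 2, 1),
             seg(60 * Mb, 100 * Mb, 1, 1))
  # p arm: 30 + 10 (truncated); q arm: 15 (truncated) + 40 -> 2 breakpoints
  expect_equal(count_lst(p2, g), 2L)
  # but if the truncated piece drops under 10 Mb the pair is lost
  p3 <- prof(seg(0, 31 * Mb, 1, 1), seg(31 * Mb, 60 * Mb, 2, 1),
             seg(60 * Mb, 100 * Mb, 1, 1))
  expect_equal(count_lst(p3, g), 1L)  # p-arm piece 31-40 is 9 Mb
})

test_that("hrd_score sums the components and propagates the threshold", {
  g <- geom1()
  p <- prof(seg(0, 30 * Mb, 2, 1),              # TAI
            seg(30 * Mb, 34 * Mb, 2, 2),        # buffer
            seg(34 * Mb, 64 * Mb, 1, 0),        # LOH (30 Mb)
            seg(64 * Mb, 68 * Mb, 2, 2),        # buffer
            seg(68 * Mb, 100 * Mb, 1, 1))
  s <- hrd_score(p, g)
  expect_equal(s$loh, 1L)
  expect_equal(s$tai, 1L)
  expect_equal(s$lst, 0L)
  expect_equal(s$hrd, s$loh + s$tai + s$lst)
  expect_false(s$hrd_positive)
  # strict > threshold semantics
  expect_false(hrd_score(p, g, threshold = 2)$hrd_positive)
  expect_true(hrd_score(p, g, threshold = 1)$hrd_positive)
  # diploid genome scores (0, 0, 0)
  s0 <- hrd_score(prof(seg(0, 100 * Mb, 1, 1)), g)
  expect_equal(c(s0$loh, s0$tai, s0$lst, s0$hrd), c(0L, 0L, 0L, 0L))
})

test_that("counters error on chromosomes missing from the geometry", {
  g <- geom1()
  p <- prof(seg(0, 30 * Mb, 2, 1, chrom = "chr9"))
  expect_error(count_loh(p, g), "absent from geometry: chr9")
  expect_error(count_tai(p, g), "absent from geometry: chr9")
  expect_error(count_lst(p, g), "absent from geometry: chr9")
})

test_that("counters match the per-base oracle on random profiles", {
  set.seed(11)
  for (rep in 1:250) {
    g <- rand_geometry()
    p <- rand_profile(g)
    sm <- smooth_profile(p, min_len = 3)
    want <- oracle_scores(p, g)
    expect_identical(count_loh(sm, g, min_len = 15), want[["loh"]])
    expect_identical(count_tai(sm, g, tel_tol = 0), want[["tai"]])
    expect_identical(
      count_lst(p, g, min_adjacent = 10, filter_len = 3), want[["lst"]])
  }
})

test_that("counters are additive across chromosomes", {
  set.seed(13)
  for (rep in 1:40) {
    g <- rand_geometry(3)
    p <- smooth_profile(rand_profile(g), min_len = 3)
    per_chrom <- vapply(g$chrom, function(cc) {
      sub <- segment_profile(sample_id(p),
                             as.data.frame(p)[p$chrom == cc, , drop = FALSE])
      c(count_loh(sub, g, min_len = 15),
        count_tai(sub, g, tel_tol = 0),
        count_lst(sub, g, min_adjacent = 10, filter_len = 3))
    }, numeric(3))
    expect_equal(count_loh(p, g, min_len = 15), sum(per_chrom[1, ]))
    expect_equal(count_tai(p, g, tel_tol = 0), sum(per_chrom[2, ]))
    expect_equal(count_lst(p, g, min_adjacent = 10, filter_len = 3),
                 sum(per_chrom[3, ]))
  }
})

test_that("an extra interstitial LOH run raises loh by 1, tai unchanged", {
  set.seed(17)
  g <- genome_geometry("chr1", 300, 140, 150)
  for (rep in 1:25) {
    # random base profile confined to [0, 180)
    base <- rand_profile(genome_geometry("chr1", 180, 140, 150))
    base_sm <- smooth_profile(base, min_len = 3)
    loh0 <- count_loh(base_sm, g, min_len = 15)
    tai0 <- count_tai(base_sm, g, tel_tol = 0)
    # insert a detached LOH run of length in (15, L) well away from the rest
    run_len <- sample(16:40, 1)
    extra <- seg(200, 200 + run_len, 1, 0)
    aug <- segment_profile("S1", rbind(as.data.frame(base_sm), extra))
    expect_equal(count_loh(aug, g, min_len = 15), loh0 + 1L)
    expect_equal(count_tai(aug, g, tel_tol = 0), tai0)
  }
})

test_that("counts are invariant under coordinate and threshold scaling", {
  set.seed(19)
  for (rep in 1:25) {
    g <- rand_geometry()
    p <- rand_profile(g)
    sm <- smooth_profile(p, min_len = 3)
    gb <- genome_geometry(g$chrom, g$length * 1e6, g$cen_start * 1e6,
                          g$cen_end * 1e6)
    scale_prof <- function(q) {
      segment_profile(sample_id(q), data.frame(
        chrom = q$chrom, start = q$start * 1e6, end = q$end * 1e6,
        cn_major = q$cn_major, cn_minor = q$cn_minor))
    }
    expect_identical(count_loh(sm, g, min_len = 15),
                     count_loh(scale_prof(sm), gb, min_len = 15e6))
    expect_identical(count_tai(sm, g, tel_tol = 0),
                     count_tai(scale_prof(sm), gb, tel_tol = 0))
    expect_identical(
      count_lst(p, g, min_adjacent = 10, filter_len = 3),
      count_lst(scale_prof(p), gb, min_adjacent = 10e6, filter_len = 3e6))
  }
})
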