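# Merge abutting flagged segments into maximal runs.
# state_key: NULL for state-level merging (any flagged segments that abut
# belong to one run), otherwise a vector; abutting segments stay in one run
# only when their keys are equal.
flag_runs <- function(s, e, flag, state_key = NULL) {
  idx <- which(flag)
  if (!length(idx)) return(list(start = numeric(0), end = numeric(0)))
  rs <- s[idx[1]]; re <- e[idx[1]]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(idx) > 1L) {
    for (k in 2:length(idx)) {
      i <- idx[k]; prev <- idx[k - 1L]
      joined <- (i == prev + 1L) && (s[i] == re) &&
        (is.null(state_key) || state_key[i] == state_key[prev])
      if (joined) {
        re <- e[i]
      } else {
        out_s <- c(out_s, rs); out_e <- c(out_e, re)
        rs <- s[i]; re <- e[i]
      }
    }
  }
  list(start = c(out_s, rs), end = c(out_e, re))
}

#' Count loss-of-heterozygosity (LOH) scar events
#'
#' An LOH region is a maximal run of abutting segments with
#' `cn_minor == 0` and `cn_major >= 1`. A region scores if it is longer than
#' `min_len` (default 15 Mb) and shorter than the whole chromosome: runs that
#' span the chromosome end to end (within `whole_chrom_tol` of both
#' telomeres) are excluded.
#'
#' The profile is expected to be smoothed already (see [smooth_profile()]);
#' this counter does not re-smooth.
#'
#' @param profile a [segment_profile], smoothed.
#' @param geometry a [genome_geometry] covering every chromosome in the
#'   profile.
#' @param min_len minimal region length in bp, strict (default 15 Mb).
#' @param merge_runs if `TRUE` (default) abutting LOH segments with different
#'   `cn_major` (e.g. 1/0 next to 2/0) form one LOH region; if `FALSE` runs
#'   break wherever `cn_major` changes.
#' @param whole_chrom_tol telomere tolerance in bp for the whole-chromosome
#'   exclusion (default 0: only runs literally covering the chromosome are
#'   excluded).
#' @return Integer count of qualifying LOH regions.
#' @export
count_loh <- function(profile, geometry, min_len = 15e6,
                      merge_runs = TRUE, whole_chrom_tol = 0) {
  count_loh_impl(validate_profile(profile), geometry, min_len, merge_runs,
                 whole_chrom_tol)
}

count_loh_impl <- function(p, geometry, min_len = 15e6, merge_runs = TRUE,
                           whole_chrom_tol = 0) {
  n_total <- 0L
  for (cc in unique(p$chrom)) {
    gi <- match(cc, geometry$chrom)
    if (is.na(gi)) stop("chromosome absent from geometry: ", cc)
    L <- geometry$length[gi]
    k <- p$chrom == cc
    s <- p$start[k]; e <- p$end[k]
    flag <- p$cn_minor[k] == 0 & p$cn_major[k] >= 1
    runs <- flag_runs(s, e, flag,
                      state_key = if (merge_runs) NULL else p$cn_major[k])
    len <- runs$end - runs$start
    whole <- runs$start <= whole_chrom_tol & runs$end >= L - whole_chrom_tol
    n_total <- n_total + sum(len > min_len & !whole)
  }
  as.integer(n_total)
}

#' Count telomeric allelic imbalance (TAI) scar events
#'
#' An allelic-imbalance (AI) region is a maximal run of abutting segments
#' with `cn_major != cn_minor`. A region scores if it reaches a chromosome
#' end (run start within `tel_tol` of position 0 or run end within `tel_tol`
#' of the chromosome length), does not intersect the centromere interval,
#' and is longer than `min_len` (default 0: no minimum, none is defined for
#' this scar class).
#'
#' @inheritParams count_loh
#' @param min_len minimal region length in bp, strict (default 0).
#' @param tel_tol telomere tolerance in bp for the "reaches a chromosome
#'   end" condition (default 1 kb; real profiles rarely reach literal
#'   position 0).
#' @param state_level if `TRUE` (default) contiguity of the imbalanced state
#'   defines a run even when the specific `(cn_major, cn_minor)` pair changes
#'   inside it; if `FALSE` runs break at every state change.
#' @return Integer count of qualifying TAI regions.
#' @export
count_tai <- function(profile, geometry, min_len = 0, tel_tol = 1000,
                      state_level = TRUE) {
  count_tai_impl(validate_profile(profile), geometry, min_len, tel_tol,
                 state_level)
}

count_tai_impl <- function(p, geometry, min_len = 0, tel_tol = 1000,
                           state_level = TRUE) {
  n_total <- 0L
  for (cc in unique(p$chrom)) {
    gi <- match(cc, geometry$chrom)
    if (is.na(gi)) stop("chromosome absent from geometry: ", cc)
    k <- p$chrom == cc
    flag <- p$cn_major[k] != p$cn_minor[k]
    key <- if (state_level) NULL else
      paste(p$cn_major[k], p$cn_minor[k], sep = "/")
    runs <- flag_runs(p$start[k], p$end[k], flag, state_key = key)
    if (!length(runs$start)) next
    telomeric <- runs$start <= tel_tol |
      runs$end >= geometry$length[gi] - tel_tol
    crosses_cen <- runs$start < geometry$cen_end[gi] &
      runs$end > geometry$cen_start[gi]
    len <- runs$end - runs$start
    n_total <- n_total + sum(telomeric & !crosses_cen & len > min_len)
  }
  as.integer(n_total)
}

# Split one chromosome's segments at the centromere into per-arm pieces.
split_at_centromere <- function(s, e, a, b, cen_start, cen_end, L) {
  clip <- function(lo, hi) {
    cs <- pmax(s, lo); ce <- pmin(e, hi)
    k <- cs < ce
    list(start = cs[k], end = ce[k], cn_major = a[k], cn_minor = b[k])
  }
  list(p = clip(0, cen_start), q = clip(cen_end, L))
}

#' Count large-scale state transitions (LST)
#'
#' A large-scale state transition is a chromosome breakpoint -- a change in
#' copy number or allelic content -- between adjacent regions each of at
#' least `min_adjacent` (10 Mb), obtained after smoothing away small-scale
#' variation shorter than `filter_len` (3 Mb). "Adjacent" tolerates a gap of
#' up to `filter_len` between the two regions. Breakpoints are evaluated per
#' chromosome arm: segments are truncated at the centromere boundaries and
#' breakpoints inside the centromere are not counted.
#'
#' The raw profile is expected; smoothing with `filter_len` is applied
#' internally (set `smooth = FALSE` if the profile is already smoothed at
#' that scale -- smoothing is idempotent, so this is an optimisation only).
#'
#' @inheritParams count_loh
#' @param min_adjacent minimal length of each flanking region in bp
#'   (default 10 Mb, inclusive).
#' @param filter_len smoothing scale and maximal gap between adjacent
#'   regions, bp (default 3 Mb).
#' @param smooth apply [smooth_profile()] internally (default `TRUE`).
#' @return Integer genome-wide LST count.
#' @export
count_lst <- function(profile, geometry, min_adjacent = 10e6,
                      filter_len = 3e6, smooth = TRUE) {
  p <- validate_profile(profile)
  if (smooth) p <- smooth_impl(p, filter_len)
  count_lst_impl(p, geometry, min_adjacent, filter_len)
}

count_lst_impl <- function(p, geometry, min_adjacent = 10e6,
                           filter_len = 3e6) {
  n_total <- 0L
  for (cc in unique(p$chrom)) {
    gi <- match(cc, geometry$chrom)
    if (is.na(gi)) stop("chromosome absent from geometry: ", cc)
    k <- p$chrom == cc
    arms <- split_at_centromere(p$start[k], p$end[k], p$cn_major[k],
                                p$cn_minor[k], geometry$cen_start[gi],
                                geometry$cen_end[gi], geometry$length[gi])
    for (arm in arms) {
      n <- length(arm$start)
      if (n < 2L) next
      for (i in seq_len(n - 1L)) {
        gap <- arm$start[i + 1L] - arm$end[i]
        differ <- arm$cn_major[i] != arm$cn_major[i + 1L] ||
          arm$cn_minor[i] != arm$cn_minor[i + 1L]
        long_enough <-
          (arm$end[i] - arm$start[i]) >= min_adjacent &&
          (arm$end[i + 1L] - arm$start[i + 1L]) >= min_adjacent
        if (gap <= filter_len && differ && long_enough) {
          n_total <- n_total + 1L
        }
      }
    }
  }
  as.integer(n_total)
}

#' HRD score: LOH + TAI + LST
#'
#' Computes the three genomic-scar components and their sum for one sample.
#' The raw profile is smoothed at `filter_len` once; LOH and TAI are counted
#' on the smoothed profile and LST on the raw profile (its counter smooths
#' internally at the same scale). A sample is HRD-positive when the summed
#' score strictly exceeds `threshold` (default 26; a score of exactly 26 is
#' HRD-negative).
#'
#' @inheritParams count_loh
#' @param loh_min LOH minimal region length, bp (default 15 Mb, strict).
#' @param tai_min TAI minimal region length, bp (default 0).
#' @param lst_min LST minimal flanking-region length, bp (default 10 Mb,
#'   inclusive).
#' @param filter_len smoothing scale, bp (default 3 Mb).
#' @param tel_tol TAI telomere tolerance, bp (default 1 kb).
#' @param threshold HRD-positive threshold (strict `>`; default 26).
#' @return One-row data frame with columns `sample_id`, `loh`, `tai`, `lst`,
#'   `hrd`, `hrd_positive`.
#' @export
hrd_score <- function(profile, geometry, loh_min = 15e6, tai_min = 0,
                      lst_min = 10e6, filter_len = 3e6, tel_tol = 1000,
                      whole_chrom_tol = 0, threshold = 26) {
  p <- validate_profile(profile)
  sm <- smooth_impl(p, filter_len)
  loh <- count_loh_impl(sm, geometry, min_len = loh_min,
                        whole_chrom_tol = whole_chrom_tol)
  tai <- count_tai_impl(sm, geometry, min_len = tai_min, tel_tol = tel_tol)
  # smoothing is idempotent, so counting LST on the already-smoothed profile
  # equals smoothing internally from the raw profile
  lst <- count_lst_impl(sm, geometry, min_adjacent = lst_min,
                        filter_len = filter_len)
  hrd <- loh + tai + lst
  data.frame(sample_id = sample_id(profile), loh = loh, tai = tai,
             lst = lst, hrd = hrd, hrd_positive = hrd > threshold,
             stringsAsFactors = FALSE)
}

#' Score a cohort of segment profiles
#'
#' Applies [hrd_score()] to every profile and stacks the results.
#'
#' @param profiles list of [segment_profile] objects (as returned by
#'   [read_segments()] or [simulate_profiles()]).
#' @inheritParams hrd_score
#' @param ... passed on to [hrd_score()].
#' @return Data frame with one row per sample: `sample_id`, `loh`, `tai`,
#'   `lst`, `hrd`, `hrd_positive`.
#' @export
score_cohort <- function(profiles, geometry, ...) {
  if (!length(profiles)) stop("empty cohort: no segment profiles to score")
  rows <- lapply(profiles, hrd_score, geometry = geometry, ...)
  data.frame(
    sample_id = vapply(rows, function(r) r$sample_id, character(1)),
    loh = vapply(rows, function(r) r$loh, integer(1)),
    tai = vapply(rows, function(r) r$tai, integer(1)),
    lst = vapply(rows, function(r) r$lst, integer(1)),
    hrd = vapply(rows, function(r) r$hrd, integer(1)),
    hrd_positive = vapply(rows, function(r) r$hrd_positive, logical(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
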