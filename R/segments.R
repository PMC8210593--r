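#' Allele-specific copy-number segment profile
#'
#' A `segment_profile` holds one sample's allele-specific copy-number
#' segments: a data frame with columns `chrom`, `start`, `end` (bp, 0-based
#' half-open), `cn_major`, `cn_minor` (non-negative integers with
#' `cn_minor <= cn_major`), plus a `sample_id` attribute. Segments are kept
#' sorted by chromosome and start, must not overlap within a chromosome, and
#' may leave gaps (uncovered regions carry no state).
#'
#' Derived notions used throughout the scar counters: segment length is
#' `end - start`; loss of heterozygosity (LOH) means `cn_minor == 0` and
#' `cn_major >= 1`; allelic imbalance (AI) means `cn_major != cn_minor`.
#'
#' @param sample_id sample identifier.
#' @param segments data frame with columns `chrom`, `start`, `end`,
#'   `cn_major`, `cn_minor`.
#' @return A validated `segment_profile`.
#' @export
segment_profile <- function(sample_id, segments) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  validate_profile(structure(segments,
                             sample_id = as.character(sample_id),
                             class = c("segment_profile", "data.frame")))
}

#' @export
print.segment_profile <- function(x, ...) {
  cat("segment_profile for sample", attr(x, "sample_id"),
      "with", nrow(x), "segments\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Sample identifier of a segment profile
#' @param profile a [segment_profile].
#' @return The sample id string.
#' @export
sample_id <- function(profile) attr(profile, "sample_id")

validate_profile <- function(profile) {
  req <- c("chrom", "start", "end", "cn_major", "cn_minor")
  if (!all(req %in% names(profile))) {
    stop("profile needs columns ", paste(req, collapse = ", "))
  }
  p <- profile
  if (nrow(p)) {
    if (any(p$start >= p$end)) {
      stop("segment with start >= end in sample ", attr(profile, "sample_id"))
    }
    if (any(p$cn_major < 0) || any(p$cn_minor < 0)) {
      stop("negative copy number in sample ", attr(profile, "sample_id"))
    }
    if (any(p$cn_minor > p$cn_major)) {
      stop("cn_minor > cn_major in sample ", attr(profile, "sample_id"))
    }
    o <- order(match(p$chrom, unique(p$chrom)), p$start)
    p <- p[o, , drop = FALSE]
    rownames(p) <- NULL
    by_chr <- split(seq_len(nrow(p)), p$chrom)
    for (idx in by_chr) {
      if (length(idx) > 1L) {
        s <- p$start[idx]; e <- p$end[idx]
        if (any(s[-1] < e[-length(e)])) {
          stop("overlapping segments on ", p$chrom[idx[1]],
               " in sample ", attr(profile, "sample_id"))
        }
      }
    }
  }
  structure(p, sample_id = attr(profile, "sample_id"),
            class = c("segment_profile", "data.frame"))
}

#' Read allele-specific segment profiles from an ASCAT-style TSV
#'
#' Expects a header with columns `sample`, `chrom`, `start`, `end`,
#' `nMajor`, `nMinor`. The common seg-file dialect stores 1-based inclusive
#' coordinates (`coords = "onebased"`, the default); internally everything is
#' converted to 0-based half-open, so a 1-based row `(start = 1, end = 100)`
#' becomes `(0, 100)` with length 100. Overlapping segments within one
#' sample and chromosome, negative copy numbers, `start >= end` (after
#' conversion) and -- when a geometry is supplied -- unknown chromosomes or
#' segments exceeding the chromosome all raise errors with row context.
#'
#' @param path TSV path.
#' @param geometry optional [genome_geometry] used to validate chromosome
#'   names and bounds.
#' @param coords `"onebased"` (1-based inclusive input, default) or
#'   `"zerobased"` (already 0-based half-open).
#' @return Named list of [segment_profile] objects, one per sample, in order
#'   of first appearance.
#' @export
read_segments <- function(path, geometry = NULL,
                          coords = c("onebased", "zerobased")) {
  coords <- match.arg(coords)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "chrom", "start", "end", "nMajor", "nMinor")
  if (!all(req %in% names(tab))) {
    stop("segment file needs columns ", paste(req, collapse = ", "))
  }
  start <- as.numeric(tab$start)
  end <- as.numeric(tab$end)
  if (coords == "onebased") start <- start - 1
  for (i in seq_len(nrow(tab))) {
    if (is.na(start[i]) || is.na(end[i]) || start[i] >= end[i]) {
      stop("row ", i, " (sample ", tab$sample[i], "): start >= end")
    }
    if (tab$nMajor[i] < 0 || tab$nMinor[i] < 0) {
      stop("row ", i, " (sample ", tab$sample[i], "): negative copy number")
    }
    if (!is.null(geometry)) {
      j <- match(tab$chrom[i], geometry$chrom)
      if (is.na(j)) {
        stop("row ", i, " (sample ", tab$sample[i],
             "): unknown chromosome ", tab$chrom[i])
      }
      if (end[i] > geometry$length[j]) {
        stop("row ", i, " (sample ", tab$sample[i],
             "): segment exceeds chromosome ", tab$chrom[i])
      }
    }
  }
  samples <- unique(tab$sample)
  out <- lapply(samples, function(s) {
    k <- tab$sample == s
    segment_profile(s, data.frame(
      chrom = tab$chrom[k], start = start[k], end = end[k],
      cn_major = as.integer(tab$nMajor[k]),
      cn_minor = as.integer(tab$nMinor[k]),
      stringsAsFactors = FALSE
    ))
  })
  names(out) <- samples
  out
}

#' Write segment profiles to an ASCAT-style TSV
#'
#' Inverse of [read_segments()]; with the default `coords = "onebased"` a
#' write/read round trip reproduces coordinates and copy numbers exactly.
#'
#' @param profiles a [segment_profile] or list of them.
#' @param path output TSV path.
#' @param coords output coordinate dialect, as in [read_segments()].
#' @return `path`, invisibly.
#' @export
write_segments <- function(profiles, path,
                           coords = c("onebased", "zerobased")) {
  coords <- match.arg(coords)
  if (inherits(profiles, "segment_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    if (!nrow(p)) return(NULL)
    data.frame(
      sample = sample_id(p), chrom = p$chrom,
      start = if (coords == "onebased") p$start + 1 else p$start,
      end = p$end, nMajor = p$cn_major, nMinor = p$cn_minor,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      nMajor = integer(), nMinor = integer())
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Smoothing of one chromosome's segments; vectors sorted by start.
# `covered[i]` tracks whether the interval between kept segment i and i+1 is
# abutting or consists only of dropped segments (then a later equal-state
# merge may absorb it). Original uncovered gaps are never absorbed.
smooth_chrom <- function(s, e, a, b, min_len) {
  n <- length(s)
  covered <- if (n > 1L) s[-1L] == e[-n] else logical(0)
  merge_pass <- function() {
    any_merged <- FALSE
    i <- 1L
    while (i < length(s)) {
      if (covered[i] && a[i] == a[i + 1L] && b[i] == b[i + 1L]) {
        e[i] <<- e[i + 1L]
        s <<- s[-(i + 1L)]; e <<- e[-(i + 1L)]
        a <<- a[-(i + 1L)]; b <<- b[-(i + 1L)]
        covered <<- covered[-i]
        any_merged <- TRUE
      } else {
        i <- i + 1L
      }
    }
    any_merged
  }
  # canonicalize first: abutting equal-state rows are one region, and must
  # not be dropped piecewise
  merge_pass()
  repeat {
    n <- length(s)
    if (!n) break
    changed <- FALSE
    drop <- (e - s) < min_len
    if (any(drop)) {
      changed <- TRUE
      keep <- which(!drop)
      if (!length(keep)) {
        s <- e <- a <- b <- numeric(0)
        covered <- logical(0)
        break
      }
      nk <- length(keep)
      new_cov <- logical(max(nk - 1L, 0L))
      if (nk > 1L) {
        for (j in seq_len(nk - 1L)) {
          new_cov[j] <- all(covered[keep[j]:(keep[j + 1L] - 1L)])
        }
      }
      s <- s[keep]; e <- e[keep]; a <- a[keep]; b <- b[keep]
      covered <- new_cov
    }
    if (merge_pass()) changed <- TRUE
    if (!changed) break
  }
  list(start = s, end = e, cn_major = a, cn_minor = b)
}

#' Smooth and filter small-scale copy-number variation
#'
#' Implements the preprocessing the LST definition requires: iterate to a
#' fixpoint (1) dropping segments shorter than `min_len` and (2) merging
#' adjacent same-chromosome segments with identical `(cn_major, cn_minor)`
#' state that abut directly or are separated only by dropped segments (the
#' dropped interval is absorbed into the merged segment). A dropped interval
#' whose flanks differ in state remains a gap; original uncovered gaps are
#' never bridged.
#'
#' After smoothing no segment is shorter than `min_len` and no two abutting
#' segments share an identical state; the operation is idempotent.
#'
#' @param profile a [segment_profile].
#' @param min_len minimum segment length in bp (default 3 Mb).
#' @return A smoothed [segment_profile].
#' @export
smooth_profile <- function(profile, min_len = 3e6) {
  smooth_impl(validate_profile(profile), min_len)
}

# smoothing core; assumes a validated (sorted, non-overlapping) profile and
# skips re-validation of the (by construction valid) result
smooth_impl <- function(p, min_len) {
  if (!nrow(p)) return(p)
  chrom <- character(0); s <- numeric(0); e <- numeric(0)
  a <- numeric(0); b <- numeric(0)
  for (cc in unique(p$chrom)) {
    k <- p$chrom == cc
    sm <- smooth_chrom(p$start[k], p$end[k], p$cn_major[k], p$cn_minor[k],
                       min_len)
    if (!length(sm$start)) next
    chrom <- c(chrom, rep(cc, length(sm$start)))
    s <- c(s, sm$start); e <- c(e, sm$end)
    a <- c(a, sm$cn_major); b <- c(b, sm$cn_minor)
  }
  structure(
    data.frame(chrom = chrom, start = s, end = e, cn_major = a,
               cn_minor = b, stringsAsFactors = FALSE),
    sample_id = attr(p, "sample_id"),
    class = c("segment_profile", "data.frame")
  )
}
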