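# Brute-force per-base oracles for the scar counters, plus random fixture
# generators. Tests run them on small profiles whose coordinates are in
# 1 Mb units (the counters are scale invariant), so a chromosome is a vector
# of a few hundred positions.

# encode an allele-specific state as one integer; NA = uncovered
enc <- function(maj, minr) {
  ifelse(is.na(maj), NA_integer_, as.integer(maj * 1000L + minr))
}

# materialize one chromosome of a profile as per-position state vectors
chrom_vectors <- function(profile, chrom, L) {
  maj <- rep(NA_integer_, L)
  minr <- rep(NA_integer_, L)
  k <- which(profile$chrom == chrom)
  for (i in k) {
    idx <- (profile$start[i] + 1L):profile$end[i]
    maj[idx] <- profile$cn_major[i]
    minr[idx] <- profile$cn_minor[i]
  }
  list(maj = maj, minr = minr)
}

# per-position replica of the smoothing fixpoint: drop short constant-state
# runs, then fill dropped stretches whose immediate flanks share a state;
# original gaps are never filled
oracle_smooth_code <- function(code, min_len) {
  dropped <- rep(FALSE, length(code))
  repeat {
    changed <- FALSE
    key <- ifelse(is.na(code), ifelse(dropped, -1L, -2L), code)
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in seq_along(r$values)) {
      if (!is.na(r$values[q]) && r$values[q] >= 0L &&
          r$lengths[q] < min_len) {
        code[starts[q]:ends[q]] <- NA_integer_
        dropped[starts[q]:ends[q]] <- TRUE
        changed <- TRUE
      }
    }
    key <- ifelse(is.na(code), ifelse(dropped, -1L, -2L), code)
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in seq_along(r$values)) {
      if (r$values[q] == -1L && q > 1L && q < length(r$values) &&
          r$values[q - 1L] >= 0L &&
          r$values[q - 1L] == r$values[q + 1L]) {
        code[starts[q]:ends[q]] <- r$values[q - 1L]
        dropped[starts[q]:ends[q]] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  code
}

# runs of TRUE in a logical vector -> 0-based half-open intervals
flag_intervals <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- which(r$values)
  cbind(start = starts[k] - 1L, end = ends[k])
}

oracle_loh_chrom <- function(maj, minr, L, min_len, tol = 0) {
  loh <- !is.na(minr) & minr == 0L & maj >= 1L
  iv <- flag_intervals(loh)
  if (!nrow(iv)) return(0L)
  len <- iv[, 2] - iv[, 1]
  whole <- iv[, 1] <= tol & iv[, 2] >= L - tol
  sum(len > min_len & !whole)
}

oracle_tai_chrom <- function(maj, minr, L, cs, ce, tel_tol = 0,
                             min_len = 0) {
  ai <- !is.na(maj) & maj != minr
  iv <- flag_intervals(ai)
  if (!nrow(iv)) return(0L)
  telomeric <- iv[, 1] <= tel_tol | iv[, 2] >= L - tel_tol
  crosses <- iv[, 1] < ce & iv[, 2] > cs
  len <- iv[, 2] - iv[, 1]
  sum(telomeric & !crosses & len > min_len)
}

oracle_lst_chrom <- function(maj, minr, L, cs, ce, min_adjacent,
                             filter_len) {
  code <- oracle_smooth_code(enc(maj, minr), filter_len)
  code[(cs + 1L):ce] <- NA_integer_  # truncate at the centromere
  count_arm <- function(idx) {
    v <- code[idx]
    key <- ifelse(is.na(v), -1L, v)
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs <- which(r$values >= 0L)
    if (length(segs) < 2L) return(0L)
    n <- 0L
    for (q in seq_len(length(segs) - 1L)) {
      i1 <- segs[q]; i2 <- segs[q + 1L]
      gap <- starts[i2] - 1L - ends[i1]
      if (gap <= filter_len && r$values[i1] != r$values[i2] &&
          r$lengths[i1] >= min_adjacent && r$lengths[i2] >= min_adjacent) {
        n <- n + 1L
      }
    }
    n
  }
  count_arm(seq_len(cs)) + if (ce < L) count_arm((ce + 1L):L) else 0L
}

oracle_scores <- function(profile, geometry, min_loh = 15, min_adj = 10,
                          filter_len = 3, tel_tol = 0) {
  loh <- tai <- lst <- 0L
  for (j in seq_len(nrow(geometry))) {
    L <- geometry$length[j]
    v <- chrom_vectors(profile, geometry$chrom[j], L)
    sm <- oracle_smooth_code(enc(v$maj, v$minr), filter_len)
    smaj <- ifelse(is.na(sm), NA_integer_, sm %/% 1000L)
    sminr <- ifelse(is.na(sm), NA_integer_, sm %% 1000L)
    loh <- loh + oracle_loh_chrom(smaj, sminr, L, min_loh)
    tai <- tai + oracle_tai_chrom(smaj, sminr, L, geometry$cen_start[j],
                                  geometry$cen_end[j], tel_tol)
    lst <- lst + oracle_lst_chrom(v$maj, v$minr, L, geometry$cen_start[j],
                                  geometry$cen_end[j], min_adj, filter_len)
  }
  c(loh = loh, tai = tai, lst = lst)
}

# random small geometry in 1 Mb units: up to 3 chromosomes of 40..120 units
rand_geometry <- function(n_chrom = sample(1:3, 1)) {
  L <- sample(40:120, n_chrom, replace = TRUE)
  cs <- vapply(L, function(l) sample(5:(l - 12), 1), numeric(1))
  ce <- cs + vapply(L - cs - 1, function(room) {
    sample(seq_len(min(room, 8)), 1)
  }, numeric(1))
  genome_geometry(paste0("chr", seq_len(n_chrom)), L, cs, ce)
}

# random profile with <= max_segs segments across the geometry; coordinates
# integer (1 Mb units), states cn_major 0..3 with cn_minor <= cn_major;
# segments may start at 0 or reach the chromosome end
rand_profile <- function(geometry, max_segs = 12, sid = "T1") {
  n_segs <- sample(0:max_segs, 1)
  rows <- list()
  per_chrom <- table(sample(geometry$chrom, n_segs, replace = TRUE))
  for (cc in names(per_chrom)) {
    L <- geometry$length[geometry$chrom == cc]
    k <- per_chrom[[cc]]
    pos <- if (stats::runif(1) < 0.5) 0 else sample(0:5, 1)
    for (i in seq_len(k)) {
      if (pos >= L) break
      len <- sample(1:35, 1)
      e <- min(pos + len, L)
      if (stats::runif(1) < 0.25) e <- L  # sometimes reach the telomere
      maj <- sample(0:3, 1)
      minr <- sample(0:maj, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cc, start = pos, end = e, cn_major = maj, cn_minor = minr,
        stringsAsFactors = FALSE)
      pos <- e
      if (stats::runif(1) < 0.4) pos <- pos + sample(1:10, 1)  # gap
      if (pos >= L) break
    }
  }
  segs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               cn_major = integer(), cn_minor = integer())
  segment_profile(sid, segs)
}

# rebuild per-position vectors from a (smoothed) profile for comparison
profile_codes <- function(profile, geometry) {
  lapply(seq_len(nrow(geometry)), function(j) {
    v <- chrom_vectors(profile, geometry$chrom[j], geometry$length[j])
    enc(v$maj, v$minr)
  })
}
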