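#' Simulation configuration
#'
#' Bundles every parameter of the synthetic cohort generator. Defaults state
#' a scaled-down but structurally faithful world: a 3-chromosome genome
#' ([default_geometry()]), Poisson scar rates per sample, six chemokine-like
#' genes whose log2 TPM rises linearly with the sample's true HRD burden,
#' and exponential survival whose hazard depends on the expression-high
#' group of the first responsive gene (hazard ratio `exp(gamma)`, default
#' about 1/3 in favour of expression-high).
#'
#' @param seed integer seed; all per-sample and per-stage substreams are
#'   derived from it deterministically.
#' @param n_samples number of samples.
#' @param geometry a [genome_geometry] (default [default_geometry()]).
#' @param lambda_loh,lambda_tai,lambda_lst Poisson means of planted
#'   interstitial LOH regions, telomeric AI regions and qualifying
#'   large-scale breakpoints per sample (defaults 2, 1.5, 2: scar rates of
#'   real HRD-high tumours scaled to a toy genome that is roughly 15% of a
#'   real one, and jointly feasible on it).
#' @param n_genes total genes in the expression matrix (default 200).
#' @param n_responsive number of scar-responsive chemokine-like genes
#'   (default 6, named `chemo01` ...).
#' @param beta expression link slope, log2-TPM units per HRD point
#'   (default 0.15).
#' @param sigma expression noise standard deviation, log2 scale
#'   (default 0.5).
#' @param alpha_responsive baseline log2 TPM of responsive genes (default 5).
#' @param gamma log hazard ratio of the expression-high group
#'   (default -1.1, HR about 1/3).
#' @param h0 baseline hazard per month (default 0.05).
#' @param censoring target censoring probability in `[0, 1)` (default 0.2).
#' @param mut_base,mut_slope Poisson somatic-mutation-count covariate:
#'   mean `mut_base + mut_slope * HRD`.
#' @param fga_slope,msi_slope effect sizes of the fraction-genome-altered
#'   and MSI-like covariates per HRD point (defaults sized so the extreme
#'   HRD quintiles of an n = 100 cohort separate by about 3 noise SDs).
#' @param response_high,response_low multinomial probabilities over the
#'   response categories CR/PR/SD/PD for expression-high and -low samples.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_samples = 100,
                       geometry = default_geometry(),
                       lambda_loh = 2, lambda_tai = 1.5, lambda_lst = 2,
                       n_genes = 200, n_responsive = 6,
                       beta = 0.15, sigma = 0.5, alpha_responsive = 5,
                       gamma = -1.1, h0 = 0.05, censoring = 0.2,
                       mut_base = 10, mut_slope = 3,
                       fga_slope = 0.25, msi_slope = 0.5,
                       response_high = c(0.15, 0.25, 0.30, 0.30),
                       response_low = c(0.03, 0.07, 0.20, 0.70)) {
  stopifnot(lambda_loh >= 0, lambda_tai >= 0, lambda_lst >= 0,
            sigma > 0, censoring >= 0, censoring < 1,
            n_responsive >= 1, n_genes > n_responsive, n_samples >= 1)
  geometry <- validate_geometry(geometry)
  cfg <- list(
    seed = as.integer(seed), n_samples = n_samples, geometry = geometry,
    lambda_loh = lambda_loh, lambda_tai = lambda_tai, lambda_lst = lambda_lst,
    n_genes = n_genes, n_responsive = n_responsive,
    responsive_genes = sprintf("chemo%02d", seq_len(n_responsive)),
    beta = beta, sigma = sigma, alpha_responsive = alpha_responsive,
    gamma = gamma, h0 = h0, censoring = censoring,
    mut_base = mut_base, mut_slope = mut_slope,
    fga_slope = fga_slope, msi_slope = msi_slope,
    response_high = response_high, response_low = response_low
  )
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic 31-bit substream seed; all operands stay below 2^53 so the
# arithmetic is exact in doubles.
derive_seed <- function(seed, i, salt) {
  as.integer((((seed %% 1000003) + 1) * 2147 + i * 7919 + salt * 104729) %%
               2147483647)
}

# Geometric constants of the planting scheme. Buffer segments (balanced 2/2,
# 4 Mb: longer than the 3 Mb smoothing scale, shorter than the 10 Mb LST
# flank minimum) isolate every planted event so it contributes to exactly
# one scar class; SPACING_BP of diploid background between footprints keeps
# background fragments above the smoothing scale. Event length caps are
# chosen so the default Poisson rates fit the 3-chromosome toy genome with
# a placement-failure rate low enough that count-level rejection leaves the
# Poisson means essentially unbiased.
BUFFER_BP <- 4e6
SPACING_BP <- 4e6
TAI_MAX_BP <- 25e6
LOH_MAX_BP <- 40e6
LST_FLANK_MAX_BP <- 15e6

# free-interval check against parallel vectors of occupied [start, end)
is_free <- function(os, oe, lo, hi) {
  !length(os) || all(hi <= os | lo >= oe)
}

# insert a disjoint interval keeping the occupancy vectors sorted by start
occ_insert <- function(v, x, pos) append(v, x, after = pos)

# Plain-vector view of a geometry, shared by all placement calls of a run.
geometry_env <- function(geometry) {
  list(n = nrow(geometry), length = geometry$length,
       cs = geometry$cen_start, ce = geometry$cen_end,
       arm_chrom = rep(seq_len(nrow(geometry)), each = 2L),
       arm_is_p = rep(c(TRUE, FALSE), nrow(geometry)))
}

# Sample a footprint start position uniformly over all admissible positions
# in [lo, hi] given the (disjoint) occupied intervals occ; u is a uniform
# draw. Returns NA when no free interval can host a footprint of length flen.
sample_free_pos <- function(os, oe, lo, hi, flen, u) {
  if (!length(os)) {
    if (hi - lo < flen) return(NA_real_)
    return(lo + u * (hi - lo - flen))
  }
  # occupancy vectors are kept sorted on insertion
  gs <- pmax.int(c(lo, oe), lo)
  ge <- pmin.int(c(os, hi), hi)
  cap <- ge - gs - flen
  ok <- cap >= 0
  if (!any(ok)) return(NA_real_)
  w <- cap[ok]
  total <- sum(w)
  if (total == 0) return(gs[ok][1])
  x <- u * total
  cw <- cumsum(w)
  g <- which(x <= cw)[1]
  gs[ok][g] + (x - c(0, cw)[seq_along(cw)][g])
}

# Attempt to place one sample's events; returns NULL if any event cannot be
# placed (caller redraws the counts), else a list of segment rows
# c(start, end, cn_major, cn_minor, chrom_index). Event lengths are drawn by
# rejection; positions are sampled uniformly over the free space that can
# host the event, so placement only fails when the genome genuinely cannot
# host it.
place_sample_events <- function(ge, n_loh, n_tai, n_lst, tries = 64) {
  n_arms <- length(ge$arm_chrom)
  if (n_tai > n_arms) return(NULL)
  occ_s <- rep(list(numeric(0)), ge$n)
  occ_e <- rep(list(numeric(0)), ge$n)
  segs <- vector("list", 4L * (n_loh + n_tai + n_lst))
  nseg <- 0L
  add_seg <- function(j, s, e, a, b) {
    nseg <<- nseg + 1L
    segs[[nseg]] <<- c(s, e, a, b, j)
  }

  # TAI: allelic-imbalance run anchored at a telomere, capped by a balanced
  # buffer before the centromere. Position is fixed by the anchor, so only
  # the arm and run length are drawn.
  for (k in seq_len(n_tai)) {
    placed <- FALSE
    ais <- sample.int(n_arms, tries, replace = TRUE)
    us <- stats::runif(tries)
    for (m in seq_len(tries)) {
      ai <- ais[m]
      j <- ge$arm_chrom[ai]
      cap <- if (ge$arm_is_p[ai]) ge$cs[j] else ge$length[j] - ge$ce[j]
      max_len <- min(cap - BUFFER_BP, TAI_MAX_BP)
      if (max_len <= 10e6) next
      len <- 10e6 + us[m] * (max_len - 10e6)
      if (ge$arm_is_p[ai]) {
        run <- c(0, len); buf <- c(len, len + BUFFER_BP)
        fp <- c(0, len + BUFFER_BP + SPACING_BP)
      } else {
        L <- ge$length[j]
        run <- c(L - len, L); buf <- c(L - len - BUFFER_BP, L - len)
        fp <- c(L - len - BUFFER_BP - SPACING_BP, L)
      }
      if (!is_free(occ_s[[j]], occ_e[[j]], fp[1], fp[2])) next
      pos <- findInterval(fp[1], occ_s[[j]])
      occ_s[[j]] <- occ_insert(occ_s[[j]], fp[1], pos)
      occ_e[[j]] <- occ_insert(occ_e[[j]], fp[2], pos)
      add_seg(j, run[1], run[2], 2L, 1L)
      add_seg(j, buf[1], buf[2], 2L, 2L)
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }

  # LOH: interstitial 1/0 run longer than 15 Mb, allowed to cross the
  # centromere, flanked by buffers so its edges never qualify as LST
  # breakpoints.
  for (k in seq_len(n_loh)) {
    placed <- FALSE
    js <- sample.int(ge$n, tries, replace = TRUE)
    us <- matrix(stats::runif(2L * tries), tries, 2L)
    for (m in seq_len(tries)) {
      j <- js[m]
      max_len <- min(0.8 * ge$length[j], LOH_MAX_BP)
      if (max_len <= 15e6) next
      len <- 15e6 + us[m, 1] * (max_len - 15e6)
      flen <- len + 2 * (BUFFER_BP + SPACING_BP)
      fs <- sample_free_pos(occ_s[[j]], occ_e[[j]], 0, ge$length[j], flen,
                            us[m, 2])
      if (is.na(fs)) next
      a <- fs + SPACING_BP + BUFFER_BP
      pos <- findInterval(fs, occ_s[[j]])
      occ_s[[j]] <- occ_insert(occ_s[[j]], fs, pos)
      occ_e[[j]] <- occ_insert(occ_e[[j]], fs + flen, pos)
      add_seg(j, a - BUFFER_BP, a, 2L, 2L)
      add_seg(j, a, a + len, 1L, 0L)
      add_seg(j, a + len, a + len + BUFFER_BP, 2L, 2L)
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }

  # LST: one breakpoint between two >= 10 Mb regions of differing state,
  # inside one arm, isolated by buffers on both sides.
  for (k in seq_len(n_lst)) {
    placed <- FALSE
    ais <- sample.int(n_arms, tries, replace = TRUE)
    us <- matrix(stats::runif(3L * tries), tries, 3L)
    for (m in seq_len(tries)) {
      ai <- ais[m]
      j <- ge$arm_chrom[ai]
      arm_lo <- if (ge$arm_is_p[ai]) 0 else ge$ce[j]
      arm_hi <- if (ge$arm_is_p[ai]) ge$cs[j] else ge$length[j]
      l1 <- 10e6 + us[m, 1] * (LST_FLANK_MAX_BP - 10e6)
      l2 <- 10e6 + us[m, 2] * (LST_FLANK_MAX_BP - 10e6)
      total <- 2 * BUFFER_BP + l1 + l2
      flen <- total + 2 * SPACING_BP
      fs <- sample_free_pos(occ_s[[j]], occ_e[[j]], arm_lo, arm_hi, flen,
                            us[m, 3])
      if (is.na(fs)) next
      a <- fs + SPACING_BP
      pos <- findInterval(fs, occ_s[[j]])
      occ_s[[j]] <- occ_insert(occ_s[[j]], fs, pos)
      occ_e[[j]] <- occ_insert(occ_e[[j]], fs + flen, pos)
      add_seg(j, a, a + BUFFER_BP, 2L, 2L)
      add_seg(j, a + BUFFER_BP, a + BUFFER_BP + l1, 2L, 1L)
      add_seg(j, a + BUFFER_BP + l1, a + BUFFER_BP + l1 + l2, 3L, 1L)
      add_seg(j, a + BUFFER_BP + l1 + l2, a + total, 2L, 2L)
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  segs[seq_len(nseg)]
}

# Fill diploid 1/1 background around planted event segments. Rows are
# emitted in sorted order and the result is valid by construction, so the
# data frame is assembled directly instead of through the validating
# constructor.
events_to_profile <- function(sid, segs, geometry) {
  ev <- if (length(segs)) do.call(rbind, segs) else
    matrix(numeric(0), 0, 5)
  n_guess <- 2L * nrow(ev) + 2L * nrow(geometry)
  chrom <- character(n_guess); s <- e <- numeric(n_guess)
  a <- b <- integer(n_guess)
  n <- 0L
  for (j in seq_len(nrow(geometry))) {
    L <- geometry$length[j]
    cc <- geometry$chrom[j]
    k <- which(ev[, 5] == j)
    pos <- 0
    if (length(k)) {
      o <- k[order(ev[k, 1])]
      for (i in o) {
        if (ev[i, 1] > pos) {
          n <- n + 1L
          chrom[n] <- cc; s[n] <- pos; e[n] <- ev[i, 1]
          a[n] <- 1L; b[n] <- 1L
        }
        n <- n + 1L
        chrom[n] <- cc; s[n] <- ev[i, 1]; e[n] <- ev[i, 2]
        a[n] <- as.integer(ev[i, 3]); b[n] <- as.integer(ev[i, 4])
        pos <- ev[i, 2]
      }
    }
    if (pos < L) {
      n <- n + 1L
      chrom[n] <- cc; s[n] <- pos; e[n] <- L; a[n] <- 1L; b[n] <- 1L
    }
  }
  idx <- seq_len(n)
  structure(
    list(chrom = chrom[idx], start = s[idx], end = e[idx],
         cn_major = a[idx], cn_minor = b[idx]),
    names = c("chrom", "start", "end", "cn_major", "cn_minor"),
    row.names = c(NA_integer_, -n),
    sample_id = sid,
    class = c("segment_profile", "data.frame")
  )
}

#' Simulate allele-specific segment profiles with planted scar events
#'
#' For each sample, event counts are drawn from Poisson distributions
#' (`lambda_loh`, `lambda_tai`, `lambda_lst`) and placed disjointly on a
#' diploid 1/1 background by rejection sampling. Every planted event is
#' isolated by short balanced buffer segments so it contributes to exactly
#' one scar class; scoring the emitted profiles therefore recovers the
#' planted counts exactly. A sample whose drawn counts cannot be placed
#' (e.g. more telomeric AI events than telomere-anchored arms) is redrawn;
#' if the geometry cannot host the requested rates at all, an error suggests
#' larger chromosomes.
#'
#' @param config a [sim_config].
#' @return List with `profiles` (named list of [segment_profile]) and
#'   `truth` (data frame `sample_id`, `n_loh`, `n_tai`, `n_lst`, `hrd`).
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$geometry
  ge <- geometry_env(g)
  ids <- sprintf("S%04d", seq_len(config$n_samples))
  profiles <- vector("list", config$n_samples)
  truth <- matrix(0L, config$n_samples, 3)
  for (i in seq_len(config$n_samples)) {
    set.seed(derive_seed(config$seed, i, 1L))
    segs <- NULL
    # a failed arrangement is retried with the same counts before the counts
    # themselves are redrawn, so the Poisson count distribution is distorted
    # only by genuinely unplaceable draws
    for (attempt in seq_len(40L)) {
      n_loh <- stats::rpois(1, config$lambda_loh)
      n_tai <- stats::rpois(1, config$lambda_tai)
      n_lst <- stats::rpois(1, config$lambda_lst)
      for (arrangement in seq_len(10L)) {
        segs <- place_sample_events(ge, n_loh, n_tai, n_lst)
        if (!is.null(segs)) break
      }
      if (!is.null(segs)) break
    }
    if (is.null(segs)) {
      stop("geometry too small to place requested events for sample ",
           ids[i], "; use larger chromosomes or lower scar rates")
    }
    profiles[[i]] <- events_to_profile(ids[i], segs, g)
    truth[i, ] <- c(n_loh, n_tai, n_lst)
  }
  names(profiles) <- ids
  list(profiles = profiles,
       truth = data.frame(sample_id = ids, n_loh = truth[, 1],
                          n_tai = truth[, 2], n_lst = truth[, 3],
                          hrd = rowSums(truth), stringsAsFactors = FALSE))
}

#' Simulate a TPM expression matrix linked to scar burden
#'
#' Responsive (chemokine-like) genes get
#' `log2 TPM = alpha_responsive + beta * HRD + Normal(0, sigma)`; null genes
#' get a gene-specific baseline (uniform on the log2 scale from -10 to 10,
#' so a realistic fraction of genes sits below the TPM > 1 filter) plus the
#' same noise. Columns are rescaled to sum to one million, as TPM requires.
#'
#' @param config a [sim_config].
#' @param scores data frame with `sample_id` and `hrd` (e.g. from
#'   [score_cohort()]).
#' @return List with `tpm` (genes x samples matrix) and `truth`
#'   (data frame `gene`, `baseline`, `beta`).
#' @export
simulate_expression <- function(config, scores) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(scores)
  genes <- c(config$responsive_genes,
             sprintf("g%04d", seq_len(config$n_genes - config$n_responsive)))
  set.seed(derive_seed(config$seed, 0L, 2L))
  baseline <- c(rep(config$alpha_responsive, config$n_responsive),
                stats::runif(config$n_genes - config$n_responsive, -10, 10))
  beta_g <- c(rep(config$beta, config$n_responsive),
              rep(0, config$n_genes - config$n_responsive))
  log2tpm <- baseline + outer(beta_g, scores$hrd) +
    matrix(stats::rnorm(config$n_genes * n, 0, config$sigma),
           config$n_genes, n)
  raw <- 2^log2tpm
  tpm <- sweep(raw, 2, colSums(raw), "/") * 1e6
  rownames(tpm) <- genes
  colnames(tpm) <- scores$sample_id
  list(tpm = tpm,
       truth = data.frame(gene = genes, baseline = baseline, beta = beta_g,
                          stringsAsFactors = FALSE))
}

#' Simulate clinical outcomes and instability covariates
#'
#' Survival is exponential with hazard `h0 * exp(gamma)` for samples in the
#' expression-high half (median split of the first responsive gene) and `h0`
#' otherwise. Censoring is independent: each subject is censored with
#' probability `censoring` at a uniform time before its event. Instability
#' covariates increase in the sample's HRD score (Poisson mutation count,
#' logistic-scale fraction genome altered, gamma-noise MSI-like score), and
#' a four-level response category (CR/PR/SD/PD) is drawn from
#' expression-group-dependent multinomial probabilities.
#'
#' @param config a [sim_config].
#' @param tpm expression matrix from [simulate_expression()].
#' @param scores data frame with `sample_id` and `hrd`.
#' @return List with `clinical` (data frame `sample_id`, `time`, `event`,
#'   `expr_group`, `mutation_count`, `fga`, `msi`, `response`) and `truth`
#'   (per-group hazards).
#' @export
simulate_clinical <- function(config, tpm, scores) {
  stopifnot(inherits(config, "sim_config"))
  gene <- config$responsive_genes[1]
  if (!gene %in% rownames(tpm)) stop("indicator gene missing: ", gene)
  expr <- log2(tpm[gene, scores$sample_id] + 1)
  grp <- split_by_expression(expr)
  n <- nrow(scores)
  set.seed(derive_seed(config$seed, 0L, 3L))
  hazard <- config$h0 * exp(config$gamma * (grp == "high"))
  t_event <- stats::rexp(n, rate = hazard)
  cens <- stats::rbinom(n, 1, config$censoring)
  time <- ifelse(cens == 1, stats::runif(n) * t_event, t_event)
  hrd <- scores$hrd
  mutation_count <- stats::rpois(n, config$mut_base + config$mut_slope * hrd)
  fga <- stats::plogis(stats::qlogis(0.1) + config$fga_slope * hrd +
                         stats::rnorm(n, 0, 0.5))
  msi <- config$msi_slope * hrd + stats::rgamma(n, shape = 2, rate = 2)
  cats <- c("CR", "PR", "SD", "PD")
  cum_low <- cumsum(config$response_low / sum(config$response_low))
  cum_high <- cumsum(config$response_high / sum(config$response_high))
  u <- stats::runif(n)
  response <- vapply(seq_len(n), function(i) {
    cum <- if (grp[i] == "high") cum_high else cum_low
    cats[which(u[i] <= cum + 1e-12)[1]]
  }, character(1))
  list(
    clinical = data.frame(
      sample_id = scores$sample_id, time = time, event = 1 - cens,
      expr_group = as.character(grp), mutation_count = mutation_count,
      fga = fga, msi = msi, response = response, stringsAsFactors = FALSE
    ),
    truth = data.frame(group = c("low", "high"),
                       hazard = config$h0 * exp(config$gamma * c(0, 1)))
  )
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: profiles, scores, expression, clinical, and the
#' joined sample-level cohort table.
#'
#' @param config a [sim_config].
#' @return List with `profiles`, `truth`, `scores`, `tpm`, `expr_truth`,
#'   `clinical`, `cohort` (the joined table, one row per sample).
#' @export
simulate_cohort <- function(config) {
  sim <- simulate_profiles(config)
  scores <- score_cohort(sim$profiles, config$geometry)
  expr <- simulate_expression(config, scores)
  clin <- simulate_clinical(config, expr$tpm, scores)
  gene <- config$responsive_genes[1]
  cohort <- merge(scores, clin$clinical, by = "sample_id", sort = TRUE)
  cohort[[gene]] <- log2(expr$tpm[gene, cohort$sample_id] + 1)
  list(profiles = sim$profiles, truth = sim$truth, scores = scores,
       tpm = expr$tpm, expr_truth = expr$truth, clinical = clin$clinical,
       cohort = cohort)
}
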