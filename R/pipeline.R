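write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

pkg_version <- function() {
  as.character(utils::packageVersion("hrdscar"))
}

run_stage <- function(name, fun) {
  tryCatch(fun(), error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full HRD analysis pipeline
#'
#' Chains the stages score -> classify -> stratify (bottom/top `fraction`) ->
#' DEG cascade -> survival and correlation reports on either a simulated
#' cohort (`config` given) or user-supplied inputs (`inputs` given: paths
#' `segments`, `geometry`, `tpm`, and optionally `clinical`). Every stage
#' writes a TSV into `outdir`; a `manifest.json` records the tool version,
#' seed, per-stage parameters and md5 checksums of every input and output
#' file, so that a rerun with the same seed and configuration reproduces
#' byte-identical stage outputs.
#'
#' @param outdir output directory (created if needed).
#' @param config a [sim_config] for a simulated run, or `NULL`.
#' @param inputs named list of input paths for a real-data run
#'   (ignored when `config` is given).
#' @param fraction extreme-quantile fraction for stratification
#'   (default 0.2).
#' @param threshold HRD-positive threshold (default 26).
#' @param fc,alpha,min_tpm,mad_keep DEG cascade thresholds, see
#'   [deg_cascade()].
#' @param survival_gene gene whose median expression split drives the
#'   survival analysis; default the first responsive gene of the config, or
#'   the first gene of the matrix.
#' @param quiet suppress stage log lines on stderr.
#' @return Invisibly, a list with the manifest and the paths of all stage
#'   outputs.
#' @export
run_pipeline <- function(outdir, config = NULL, inputs = NULL,
                         fraction = 0.2, threshold = 26, fc = 1.5,
                         alpha = 0.05, min_tpm = 1, mad_keep = 0.75,
                         survival_gene = NULL, quiet = FALSE) {
  if (is.null(config) && is.null(inputs)) {
    stop("either a sim_config or an inputs list is required")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(stage, ...) {
    if (!quiet) message("[hrdscar:", stage, "] ", ...)
  }
  paths <- list()
  input_files <- character(0)

  if (!is.null(config)) {
    log_msg("simulate", "seeded cohort of ", config$n_samples, " samples")
    sim <- run_stage("simulate", function() simulate_cohort(config))
    geometry <- config$geometry
    profiles <- sim$profiles
    tpm <- sim$tpm
    clinical <- sim$clinical
    paths$segments <- write_tsv_segments(profiles, file.path(outdir, "seg.tsv"))
    paths$geometry <- write_geometry(geometry, file.path(outdir, "geom.tsv"))
    paths$expression <- write_tsv(
      data.frame(gene = rownames(tpm), tpm, check.names = FALSE,
                 row.names = NULL),
      file.path(outdir, "expr.tsv"))
    paths$clinical <- write_tsv(clinical, file.path(outdir, "clinical.tsv"))
    paths$truth <- write_tsv(sim$truth, file.path(outdir, "truth.tsv"))
    if (is.null(survival_gene)) survival_gene <- config$responsive_genes[1]
  } else {
    for (nm in c("segments", "geometry", "tpm")) {
      if (is.null(inputs[[nm]])) stop("inputs$", nm, " is required")
    }
    input_files <- unlist(inputs)
    geometry <- run_stage("read", function() read_geometry(inputs$geometry))
    profiles <- run_stage("read", function() {
      read_segments(inputs$segments, geometry)
    })
    tpm <- run_stage("read", function() read_tpm(inputs$tpm))
    clinical <- if (!is.null(inputs$clinical)) {
      utils::read.delim(inputs$clinical, stringsAsFactors = FALSE)
    }
    if (is.null(survival_gene)) survival_gene <- rownames(tpm)[1]
  }

  log_msg("score", length(profiles), " profiles")
  scores <- run_stage("score", function() {
    classify_hrd(score_cohort(profiles, geometry), threshold)
  })
  paths$scores <- write_tsv(scores, file.path(outdir, "scores.tsv"))

  log_msg("stratify", "fraction ", fraction)
  groups <- run_stage("stratify", function() {
    stratify_extremes(scores, by = "hrd", fraction = fraction)
  })
  group_tab <- data.frame(
    sample_id = c(groups$low, groups$high),
    group = rep(c("low", "high"), c(length(groups$low), length(groups$high))),
    stringsAsFactors = FALSE
  )
  paths$groups <- write_tsv(group_tab, file.path(outdir, "groups.tsv"))

  log_msg("deg", "cascade on ", nrow(tpm), " genes")
  deg <- run_stage("deg", function() {
    miss <- setdiff(group_tab$sample_id, colnames(tpm))
    if (length(miss)) {
      stop("expression matrix lacks columns: ", paste(miss, collapse = ", "))
    }
    deg_cascade(tpm, groups$low, groups$high, fc = fc, alpha = alpha,
                min_tpm = min_tpm, mad_keep = mad_keep)
  })
  paths$deg <- write_tsv(deg, file.path(outdir, "deg.tsv"))

  stats_rows <- list()
  if (!is.null(clinical)) {
    log_msg("survive", "median split on ", survival_gene)
    surv <- run_stage("survive", function() {
      if (!all(c("time", "event") %in% names(clinical))) {
        stop("clinical table needs columns time, event")
      }
      if (!survival_gene %in% rownames(tpm)) {
        stop("survival gene not in expression matrix: ", survival_gene)
      }
      expr <- log2(tpm[survival_gene, clinical$sample_id] + 1)
      grp <- split_by_expression(expr)
      km <- km_estimate(clinical$time, clinical$event, grp)
      lr <- logrank_test(clinical$time, clinical$event, grp)
      list(km = km, lr = lr, expr = expr)
    })
    paths$km <- write_tsv(surv$km, file.path(outdir, "km.tsv"))
    stats_rows$logrank <- data.frame(
      analysis = paste0("logrank_", survival_gene, "_median_split"),
      statistic = surv$lr$statistic, p.value = surv$lr$p.value,
      estimate = NA_real_, stringsAsFactors = FALSE)
    rho <- correlate(surv$expr[scores$sample_id], scores$hrd,
                     method = "spearman")
    stats_rows$correlation <- data.frame(
      analysis = paste0("spearman_", survival_gene, "_vs_hrd"),
      statistic = NA_real_, p.value = rho$p.value,
      estimate = rho$estimate, stringsAsFactors = FALSE)
  }
  if (length(stats_rows)) {
    paths$stats <- write_tsv(do.call(rbind, stats_rows),
                             file.path(outdir, "stats.tsv"))
  }

  out_files <- unlist(paths)
  manifest <- list(
    tool = "hrdscar", version = pkg_version(),
    seed = if (!is.null(config)) config$seed else NA,
    parameters = list(fraction = fraction, threshold = threshold, fc = fc,
                      alpha = alpha, min_tpm = min_tpm, mad_keep = mad_keep,
                      survival_gene = survival_gene),
    config = if (!is.null(config)) {
      config[setdiff(names(config), "geometry")]
    },
    inputs = as.list(if (length(input_files)) {
      tools::md5sum(input_files)
    } else character(0)),
    outputs = as.list(tools::md5sum(out_files)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  log_msg("done", "outputs in ", outdir)
  invisible(list(manifest = manifest, paths = c(paths,
                                                manifest = manifest_path)))
}

write_tsv_segments <- function(profiles, path) {
  write_segments(profiles, path)
  path
}

#' Read a TPM (or counts) expression matrix from TSV
#'
#' First column `gene`, remaining columns samples.
#'
#' @param path TSV path.
#' @return Numeric matrix, genes x samples.
#' @export
read_tpm <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (names(tab)[1] != "gene") stop("expression TSV must start with 'gene'")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene
  storage.mode(m) <- "double"
  m
}
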