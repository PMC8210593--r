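#' Convert a read-count matrix to TPM
#'
#' Transcripts per million: reads are first divided by gene length, then each
#' sample column is scaled to sum to one million. A sample with zero counts
#' everywhere stays all-zero (with a warning) rather than producing NaN.
#'
#' @param counts non-negative matrix, genes x samples, with rownames.
#' @param lengths gene lengths in bp: named vector covering every gene in
#'   `counts` (a missing length is an error), or an unnamed vector aligned
#'   with the rows.
#' @return TPM matrix of the same shape; every non-degenerate column sums to
#'   1e6.
#' @export
counts_to_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(lengths))) {
    miss <- setdiff(rownames(counts), names(lengths))
    if (length(miss)) {
      stop("length missing for gene: ", paste(miss, collapse = ", "))
    }
    lengths <- lengths[rownames(counts)]
  } else if (length(lengths) != nrow(counts)) {
    stop("lengths must be named or match the number of genes")
  }
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  rate <- counts / lengths
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning("sample with zero counts: ",
            paste(colnames(counts)[zero], collapse = ", "))
    denom[zero] <- 1
  }
  sweep(rate, 2, denom, "/") * 1e6
}

#' Filter genes by median absolute deviation
#'
#' Computes each gene's MAD across samples on the `log2(TPM + 1)` scale
#' (unscaled, i.e. without the 1.4826 consistency constant -- the ranking is
#' unaffected) and keeps the top `keep_fraction` of genes ranked by MAD
#' descending; count kept is `floor(keep_fraction * G)`, ties broken by gene
#' id.
#'
#' @param tpm TPM matrix, genes x samples, with rownames; needs >= 2 samples.
#' @param keep_fraction fraction of genes to keep (default 0.75).
#' @param log take `log2(tpm + 1)` before computing MAD (default `TRUE`).
#' @return Character vector of kept gene ids.
#' @export
mad_filter <- function(tpm, keep_fraction = 0.75, log = TRUE) {
  tpm <- as.matrix(tpm)
  if (ncol(tpm) < 2) stop("mad_filter needs at least 2 samples")
  if (keep_fraction <= 0 || keep_fraction > 1) {
    stop("keep_fraction must be in (0, 1]")
  }
  x <- if (log) log2(tpm + 1) else tpm
  mads <- apply(x, 1, function(v) stats::median(abs(v - stats::median(v))))
  genes <- rownames(tpm)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(tpm)))
  n_keep <- floor(keep_fraction * nrow(tpm))
  o <- order(-mads, genes)
  sort(genes[o][seq_len(n_keep)])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH: sort p ascending, multiply by `m / rank`, enforce monotonicity
#' by a cumulative minimum from the largest p downward, cap at 1. The result
#' is returned in the original gene order.
#'
#' @param pvalues numeric vector in `[0, 1]` (NA not allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  o <- order(pvalues)
  adj <- pvalues[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Per-gene differential test between two sample groups
#'
#' Built-in stand-in for an external count-model DE tool: the fold change is
#' `log2((mean TPM_high + c) / (mean TPM_low + c))` with pseudocount `c = 1`,
#' and the p-value comes from a Welch t-test on `log2(TPM + 1)`. A gene with
#' zero variance in both groups gets `p = 1` (no evidence assessable).
#' Precomputed `(log2FC, p)` tables from an external tool can be ingested
#' directly by [deg_cascade()] instead.
#'
#' @param tpm TPM matrix, genes x samples, with colnames.
#' @param group_low,group_high character vectors of sample ids (columns),
#'   each of size >= 2.
#' @param pseudocount fold-change pseudocount (default 1).
#' @return Data frame `gene`, `log2fc` (high vs low), `pvalue`.
#' @export
differential_test <- function(tpm, group_low, group_high, pseudocount = 1) {
  tpm <- as.matrix(tpm)
  miss <- setdiff(c(group_low, group_high), colnames(tpm))
  if (length(miss)) stop("samples not in matrix: ", paste(miss, collapse = ", "))
  if (length(group_low) < 2 || length(group_high) < 2) {
    stop("both groups need >= 2 samples")
  }
  lo <- tpm[, group_low, drop = FALSE]
  hi <- tpm[, group_high, drop = FALSE]
  log2fc <- log2((rowMeans(hi) + pseudocount) /
                   (rowMeans(lo) + pseudocount))
  x <- log2(lo + 1); y <- log2(hi + 1)
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(1, nrow(tpm))
  ok <- se2 > 0
  tstat <- (m2[ok] - m1[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * stats::pt(-abs(tstat), df)
  genes <- rownames(tpm)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(tpm)))
  data.frame(gene = genes, log2fc = unname(log2fc), pvalue = p,
             stringsAsFactors = FALSE)
}

#' Differential-expression filter cascade
#'
#' Screens for differentially expressed genes between the low and high groups
#' with four conjunctive filters: absolute fold change above `fc` (i.e.
#' `|log2FC| > log2(fc)`), BH-adjusted p below `alpha`, mean TPM across all
#' cohort samples above `min_tpm`, and membership in the top `mad_keep`
#' fraction of genes by median absolute deviation ([mad_filter()]). Defaults
#' follow the cascade fold change > 1.5, adj. p < 0.05, TPM > 1, top 75% of
#' MAD. Direction is the sign of the fold change (high vs low).
#'
#' @inheritParams differential_test
#' @param fc fold-change threshold on the natural scale (default 1.5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_tpm mean-TPM threshold across all samples (default 1).
#' @param mad_keep MAD keep fraction (default 0.75).
#' @param de_table optional precomputed data frame `gene`, `log2fc`,
#'   `pvalue` (e.g. from an external count-model DE run); when supplied the
#'   built-in test is skipped and the cascade is applied to it.
#' @return Data frame with one row per gene: `gene`, `log2fc`, `pvalue`,
#'   `padj`, `mean_tpm`, `mad`, pass flags `pass_fc`, `pass_p`, `pass_tpm`,
#'   `pass_mad`, the final `deg` flag (conjunction of the four) and
#'   `direction` (`"up"`, `"down"`, or `NA` for non-DEGs).
#' @export
deg_cascade <- function(tpm, group_low, group_high, fc = 1.5, alpha = 0.05,
                        min_tpm = 1, mad_keep = 0.75, de_table = NULL) {
  tpm <- as.matrix(tpm)
  genes <- rownames(tpm)
  if (is.null(genes)) {
    genes <- as.character(seq_len(nrow(tpm)))
    rownames(tpm) <- genes
  }
  if (is.null(de_table)) {
    de_table <- differential_test(tpm, group_low, group_high)
  } else {
    req <- c("gene", "log2fc", "pvalue")
    if (!all(req %in% names(de_table))) {
      stop("de_table needs columns ", paste(req, collapse = ", "))
    }
    de_table <- de_table[match(genes, de_table$gene), req]
    if (anyNA(de_table$gene)) stop("de_table missing genes from the matrix")
  }
  padj <- bh_adjust(de_table$pvalue)
  mean_tpm <- rowMeans(tpm)
  logx <- log2(tpm + 1)
  mads <- apply(logx, 1, function(v) stats::median(abs(v - stats::median(v))))
  kept <- mad_filter(tpm, keep_fraction = mad_keep)
  pass_fc <- abs(de_table$log2fc) > log2(fc)
  pass_p <- padj < alpha
  pass_tpm <- mean_tpm > min_tpm
  pass_mad <- genes %in% kept
  deg <- pass_fc & pass_p & pass_tpm & pass_mad
  data.frame(
    gene = genes, log2fc = de_table$log2fc, pvalue = de_table$pvalue,
    padj = padj, mean_tpm = unname(mean_tpm), mad = unname(mads),
    pass_fc = pass_fc, pass_p = pass_p, pass_tpm = unname(pass_tpm),
    pass_mad = pass_mad, deg = deg,
    direction = ifelse(deg, ifelse(de_table$log2fc > 0, "up", "down"),
                       NA_character_),
    stringsAsFactors = FALSE
  )
}
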