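#' Genome geometry: chromosome lengths and centromere intervals
#'
#' A `genome_geometry` is a data frame with one row per chromosome and columns
#' `chrom`, `length`, `cen_start`, `cen_end`. Coordinates are 0-based
#' half-open base-pair positions; the centromere interval
#' `[cen_start, cen_end)` must lie strictly inside its chromosome. The
#' geometry defines the telomere and centromere logic used by the telomeric
#' allelic imbalance (TAI) counter and the per-arm splitting of the
#' large-scale state transition (LST) counter.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length chromosome lengths in bp.
#' @param cen_start,cen_end centromere interval per chromosome, bp,
#'   0-based half-open.
#' @return A `genome_geometry` object (a validated data frame).
#' @examples
#' genome_geometry("chr1", 100e6, 40e6, 45e6)
#' @export
genome_geometry <- function(chrom, length, cen_start, cen_end) {
  gg <- data.frame(
    chrom = as.character(chrom),
    length = as.numeric(length),
    cen_start = as.numeric(cen_start),
    cen_end = as.numeric(cen_end),
    stringsAsFactors = FALSE
  )
  validate_geometry(gg)
}

validate_geometry <- function(gg) {
  if (!all(c("chrom", "length", "cen_start", "cen_end") %in% names(gg))) {
    stop("geometry needs columns chrom, length, cen_start, cen_end")
  }
  if (anyDuplicated(gg$chrom)) {
    stop("duplicate chromosome name: ",
         paste(unique(gg$chrom[duplicated(gg$chrom)]), collapse = ", "))
  }
  bad <- !(gg$cen_start > 0 & gg$cen_start < gg$cen_end &
             gg$cen_end < gg$length)
  if (any(bad)) {
    stop("centromere interval not strictly inside chromosome: ",
         paste(gg$chrom[bad], collapse = ", "))
  }
  class(gg) <- c("genome_geometry", "data.frame")
  gg
}

#' Read a genome geometry file
#'
#' Plain TSV, two kinds of lines: `chrom<TAB>length` (chromosome size) and
#' `chrom<TAB>cen_start<TAB>cen_end` (centromere interval, 0-based
#' half-open). Blank lines and lines starting with `#` are ignored. Every
#' chromosome must have exactly one centromere line.
#'
#' @param path file path.
#' @return A [genome_geometry] object.
#' @export
read_geometry <- function(path) {
  lines <- readLines(path)
  sizes <- list()
  cens <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (length(f) == 2L) {
      if (is.na(vals[1])) stop("malformed geometry line ", i, ": ", ln)
      if (!is.null(sizes[[f[1]]])) {
        stop("duplicate chromosome name: ", f[1], " (line ", i, ")")
      }
      sizes[[f[1]]] <- vals[1]
    } else if (length(f) == 3L) {
      if (anyNA(vals)) stop("malformed geometry line ", i, ": ", ln)
      if (!is.null(cens[[f[1]]])) {
        stop("duplicate centromere for chromosome: ", f[1],
             " (line ", i, ")")
      }
      cens[[f[1]]] <- vals
    } else {
      stop("malformed geometry line ", i, ": expected 2 or 3 fields")
    }
  }
  if (!length(sizes)) stop("geometry file has no chromosome size lines")
  if (anyDuplicated(names(sizes))) {
    stop("duplicate chromosome name: ",
         names(sizes)[duplicated(names(sizes))][1])
  }
  missing_cen <- setdiff(names(sizes), names(cens))
  if (length(missing_cen)) {
    stop("missing centromere for chromosome: ",
         paste(missing_cen, collapse = ", "))
  }
  orphan <- setdiff(names(cens), names(sizes))
  if (length(orphan)) {
    stop("centromere for unknown chromosome: ", paste(orphan, collapse = ", "))
  }
  cen <- do.call(rbind, cens[names(sizes)])
  genome_geometry(names(sizes), unlist(sizes), cen[, 1], cen[, 2])
}

#' Write a genome geometry file
#'
#' Inverse of [read_geometry()].
#'
#' @param geometry a [genome_geometry].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  geometry <- validate_geometry(geometry)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s\t%s", geometry$chrom,
                     format(geometry$length, scientific = FALSE)), con)
  writeLines(sprintf("%s\t%s\t%s", geometry$chrom,
                     format(geometry$cen_start, scientific = FALSE),
                     format(geometry$cen_end, scientific = FALSE)), con)
  invisible(path)
}

#' Default toy genome used by the simulator and examples
#'
#' Three chromosomes of 100/150/200 Mb with centromeres at 40-45, 60-65 and
#' 95-100 Mb: small enough that test oracles can scan per-megabase state
#' vectors, large enough to host several 15 Mb+ scar events per chromosome.
#'
#' @return A [genome_geometry] with chromosomes `chr1`, `chr2`, `chr3`.
#' @export
default_geometry <- function() {
  genome_geometry(
    chrom = c("chr1", "chr2", "chr3"),
    length = c(100e6, 150e6, 200e6),
    cen_start = c(40e6, 60e6, 95e6),
    cen_end = c(45e6, 65e6, 100e6)
  )
}

geometry_row <- function(geometry, chrom) {
  i <- match(chrom, geometry$chrom)
  if (is.na(i)) stop("chromosome absent from geometry: ", chrom)
  geometry[i, , drop = FALSE]
}
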