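# terse constructors for hand-built fixtures

seg <- function(start, end, maj, minr, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, cn_major = maj,
             cn_minor = minr, stringsAsFactors = FALSE)
}

prof <- function(..., sid = "S1") {
  segment_profile(sid, do.call(rbind, list(...)))
}

geom1 <- function(L = 100e6, cs = 40e6, ce = 45e6) {
  genome_geometry("chr1", L, cs, ce)
}

Mb <- 1e6

write_tmp_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
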