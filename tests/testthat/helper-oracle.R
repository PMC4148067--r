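# Per-base bitmap oracle for interval arithmetic on a single toy
# chromosome: coverage is a plain logical vector, one element per base.
# Deliberately independent of the IRanges-backed implementation.

bitmap_cover <- function(x, chrom, len) {
  cov <- logical(len)
  rows <- which(x$chrom == chrom)
  for (i in rows) {
    if (x$end[i] > x$start[i]) cov[(x$start[i] + 1):x$end[i]] <- TRUE
  }
  cov
}

bitmap_to_intervals <- function(cov, chrom) {
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(chrom = chrom, start = starts[r$values],
                 end = ends[r$values])
}

random_intervals <- function(n, len, max_len = 500, chrom = "toy") {
  if (n == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  start <- floor(runif(n, 0, len - 1))
  width <- 1 + floor(runif(n, 0, max_len))
  tibble::tibble(chrom = chrom, start = start,
                 end = pmin(start + width, len))
}
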