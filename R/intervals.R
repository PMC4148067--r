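#' Construct a table of genomic intervals
#'
#' Intervals are the currency of the whole pipeline: clone placements,
#' repeat hits and gene spans are all tables with at least `chrom`, `start`
#' and `end` columns. Coordinates are 0-based half-open (`start` inclusive,
#' `end` exclusive), so the length in bp of an interval is `end - start`.
#' File readers convert from each format's native convention at the
#' boundary (BED is already half-open; RepeatMasker `.out` and GFF3 are
#' 1-based inclusive).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-like base offsets, 0-based half-open.
#' @param ... Further columns carried along (e.g. `clone_id`).
#' @return A tibble with columns `chrom`, `start`, `end` and any extras.
#' @examples
#' gi_intervals("chrI", c(10, 15), c(20, 30))
#' @export
gi_intervals <- function(chrom, start, end, ...) {
  x <- tibble(chrom = as.character(chrom),
              start = as.numeric(start),
              end = as.numeric(end), ...)
  validate_intervals(x)
}

#' Validate an interval table
#'
#' Checks the half-open interval invariants (`0 <= start < end`, non-empty
#' `chrom`) and fails identifying the first offending row.
#'
#' @param x A data frame with `chrom`, `start`, `end`.
#' @param what Label used in error messages.
#' @return `x`, invisibly unchanged, as a tibble.
#' @export
validate_intervals <- function(x, what = "interval") {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("interval table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bad <- which(is.na(x$chrom) | x$chrom == "" |
                 !is.finite(x$start) | !is.finite(x$end) |
                 x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    i <- bad[1]
    abort(sprintf(
      "malformed %s at row %d: chrom='%s' start=%s end=%s (need 0 <= start < end, non-empty chrom)",
      what, i, as.character(x$chrom[i]), format(x$start[i]), format(x$end[i])))
  }
  x
}

## IRanges bridge: half-open 0-based <-> 1-based closed, per chromosome.
as_iranges_list <- function(x) {
  x <- validate_intervals(x)
  lapply(split(x[c("start", "end")], x$chrom), function(d) {
    IRanges::IRanges(start = d$start + 1, end = d$end)
  })
}

from_iranges <- function(ir, chrom) {
  tibble(chrom = chrom,
         start = as.numeric(IRanges::start(ir)) - 1,
         end = as.numeric(IRanges::end(ir)))
}

empty_intervals <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric())
}

#' Merge an interval set into canonical disjoint form
#'
#' Computes the per-base union of coverage. Overlapping and book-ended
#' (abutting) intervals collapse into one; the result is sorted and
#' pairwise disjoint with at least 1 bp between consecutive intervals
#' per chromosome.
#'
#' @param x Interval table.
#' @return Tibble of merged intervals (`chrom`, `start`, `end`).
#' @examples
#' gi_merge(gi_intervals("chrI", c(10, 15), c(20, 30)))
#' @export
gi_merge <- function(x) {
  irl <- as_iranges_list(x)
  if (length(irl) == 0) return(empty_intervals())
  out <- purrr::imap(irl, function(ir, chr) {
    from_iranges(IRanges::reduce(ir), chr)
  })
  dplyr::arrange(bind_rows(out), .data$chrom, .data$start)
}

per_chrom_setop <- function(a, b, f) {
  ia <- as_iranges_list(a)
  ib <- as_iranges_list(b)
  chroms <- union(names(ia), names(ib))
  out <- lapply(chroms, function(chr) {
    ra <- if (chr %in% names(ia)) IRanges::reduce(ia[[chr]]) else IRanges::IRanges()
    rb <- if (chr %in% names(ib)) IRanges::reduce(ib[[chr]]) else IRanges::IRanges()
    from_iranges(f(ra, rb), chr)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) return(empty_intervals())
  dplyr::arrange(res, .data$chrom, .data$start)
}

#' Subtract one interval set from another
#'
#' Returns the bases covered by `a` and not by `b`; this is the operation
#' that turns raw YAC spans into YAC-exclusive ("gap") segments once `b`
#' is the merged cosmid/fosmid coverage.
#'
#' @param a,b Interval tables.
#' @return Tibble of intervals covering exactly `a \ b`, merged form.
#' @export
gi_subtract <- function(a, b) {
  per_chrom_setop(a, b, IRanges::setdiff)
}

#' Intersect two interval sets
#'
#' @param a,b Interval tables.
#' @return Tibble of intervals covering exactly the bases in both sets.
#' @export
gi_intersect <- function(a, b) {
  per_chrom_setop(a, b, IRanges::intersect)
}

#' Total covered bases of an interval set
#'
#' The per-base union size (overlaps counted once), i.e. the "total
#' coverage (bp)" of a clone library.
#'
#' @param x Interval table.
#' @return A single base count.
#' @export
gi_total_bp <- function(x) {
  m <- gi_merge(x)
  sum(m$end - m$start)
}

#' Fraction of each interval covered by a set
#'
#' For every row of `a`, the number of its bases covered by the union of
#' `b`, divided by its length. Used to compute per-YAC end-overlap
#' fractions with finished sequence.
#'
#' @param a Interval table (queries, one fraction per row).
#' @param b Interval table (the covering set).
#' @return Numeric vector in `[0, 1]`, aligned with the rows of `a`.
#' @export
gi_overlap_fraction <- function(a, b) {
  a <- validate_intervals(a)
  if (nrow(a) == 0) return(numeric())
  b <- validate_intervals(b)
  out <- numeric(nrow(a))
  for (chr in unique(a$chrom)) {
    idx <- which(a$chrom == chr)
    bi <- which(b$chrom == chr)
    if (length(bi) == 0) next
    # merge b on this chromosome with a sort-and-sweep, then answer each
    # query from cumulative covered-bases arithmetic (O(log n) per query)
    o <- order(b$start[bi])
    s <- b$start[bi][o]
    e <- cummax(b$end[bi][o])
    new_run <- c(TRUE, s[-1] > e[-length(e)])
    ms <- s[new_run]
    me <- e[which(c(new_run[-1], TRUE))]
    cumw <- cumsum(me - ms)
    covered_before <- function(x) {
      i <- findInterval(x, ms)
      j <- pmax(i, 1)
      ifelse(i == 0, 0, cumw[j] - pmax(0, me[j] - x))
    }
    out[idx] <- covered_before(a$end[idx]) - covered_before(a$start[idx])
  }
  out / (a$end - a$start)
}
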