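#' Assign clones to extreme or middle chromosome quarters
#'
#' Each chromosome is partitioned into four equal-size quarters; the two
#' extreme quarters (chromosome arms, repeat-rich in C. elegans) are
#' summarized together and so are the two middle ones. A clone is
#' assigned by the relative position of its midpoint
#' `p = (start + end) / 2 / chrom_length`: `p < 0.25` or `p >= 0.75` is
#' `extreme`, otherwise `middle` (half-open boundaries, so a midpoint at
#' exactly 25% falls in `middle`).
#'
#' @param clones Clone table.
#' @param sizes Chromosome sizes tibble.
#' @return `clones` with added columns `rel_mid` and `quartile`.
#' @export
locate_quartile <- function(clones, sizes) {
  clones <- validate_intervals(clones, what = "clone record")
  x <- left_join(clones, rename(sizes, .chrom_len = "length"), by = "chrom")
  if (anyNA(x$.chrom_len)) {
    abort(paste0("locate_quartile: chromosome not in sizes table: ",
                 x$chrom[which(is.na(x$.chrom_len))[1]]))
  }
  if (any(x$end > x$.chrom_len)) {
    i <- which(x$end > x$.chrom_len)[1]
    abort(sprintf("locate_quartile: clone beyond chromosome end at row %d (%s)",
                  i, x$chrom[i]))
  }
  x %>%
    mutate(rel_mid = (.data$start + .data$end) / 2 / .data$.chrom_len,
           quartile = if_else(.data$rel_mid < 0.25 | .data$rel_mid >= 0.75,
                              "extreme", "middle")) %>%
    select(-".chrom_len")
}

#' Histogram of clone start positions along chromosomes
#'
#' Converts start positions to percent of chromosome length, bins them
#' into 100 one-percent bins and, with `weight = "equal"`, averages the
#' per-chromosome distributions with equal chromosome weight (chromosomes
#' without clones are skipped); `weight = "pooled"` pools all clones so
#' chromosomes weigh in proportion to their clone counts. The cumulative
#' column gives, for each percent point, the fraction of clones starting
#' at that point or further.
#'
#' @param clones Clone table.
#' @param sizes Chromosome sizes tibble.
#' @param weight Chromosome weighting, `"equal"` (default) or `"pooled"`.
#' @return A `location_histogram` tibble with `bin` (0-99), `fraction`
#'   and `cumulative`.
#' @export
location_histogram <- function(clones, sizes, weight = c("equal", "pooled")) {
  weight <- match.arg(weight)
  clones <- validate_intervals(clones, what = "clone record")
  if (nrow(clones) == 0) abort("location_histogram: no clones")
  x <- left_join(clones, rename(sizes, .chrom_len = "length"), by = "chrom")
  if (anyNA(x$.chrom_len)) abort("location_histogram: chromosome not in sizes table")
  x$bin <- pmin(99, floor(100 * x$start / x$.chrom_len))
  per_chrom <- x %>%
    count(.data$chrom, .data$bin) %>%
    group_by(.data$chrom) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup()
  grid <- tidyr::expand_grid(chrom = unique(x$chrom), bin = 0:99)
  per_chrom <- left_join(grid, per_chrom, by = c("chrom", "bin")) %>%
    mutate(fraction = dplyr::coalesce(.data$fraction, 0),
           n = dplyr::coalesce(.data$n, 0L))
  out <- if (weight == "equal") {
    per_chrom %>%
      group_by(.data$bin) %>%
      summarise(fraction = mean(.data$fraction), .groups = "drop")
  } else {
    per_chrom %>%
      group_by(.data$bin) %>%
      summarise(n = sum(.data$n), .groups = "drop") %>%
      mutate(fraction = .data$n / sum(.data$n)) %>%
      select("bin", "fraction")
  }
  out <- arrange(out, .data$bin) %>%
    mutate(cumulative = rev(cumsum(rev(.data$fraction))))
  class(out) <- c("location_histogram", class(out))
  out
}

#' Split clones at the median length
#'
#' The median is the lower of the two middle order statistics for even
#' sample sizes; clones strictly shorter than it go in the `below` group,
#' the rest in `above_or_equal`. Mirrors a comparison of clones below vs
#' over the median length of their clone type.
#'
#' @param clones Clone table (>= 2 rows).
#' @return `clones` with an added `length_group` column; the median used
#'   is attached as attribute `median_length`.
#' @export
split_by_median_length <- function(clones) {
  clones <- validate_intervals(clones, what = "clone record")
  if (nrow(clones) < 2) abort("split_by_median_length: need at least 2 clones")
  len <- clones$end - clones$start
  m <- sort(len)[ceiling(length(len) / 2)]
  out <- mutate(clones,
                length_group = if_else(.data$end - .data$start < m,
                                       "below", "above_or_equal"))
  attr(out, "median_length") <- m
  out
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided t-test with the Welch-Satterthwaite degrees of freedom. By
#' convention, two groups with zero variance get `p = 1` when their means
#' are equal and `p = 0` otherwise.
#'
#' @param a,b Numeric vectors (each of length >= 2, finite).
#' @return One-row tibble with `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2 || !all(is.finite(c(a, b)))) {
    abort("welch_t: each group needs >= 2 finite values")
  }
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  d <- mean(a) - mean(b)
  if (va + vb == 0) {
    return(tibble(statistic = if (d == 0) 0 else sign(d) * Inf,
                  df = NA_real_, p_value = if (d == 0) 1 else 0,
                  mean_a = mean(a), mean_b = mean(b)))
  }
  tstat <- d / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  tibble(statistic = tstat, df = df,
         p_value = 2 * pt(abs(tstat), df, lower.tail = FALSE),
         mean_a = mean(a), mean_b = mean(b))
}
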