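#' Flag 21U piRNA genes
#'
#' A gene is a 21U-RNA (C. elegans PIWI-interacting RNA) record when its
#' category is `ncRNA` and either its identifier follows the `21ur-`
#' naming convention (case-insensitive) or its biotype is `piRNA`. A
#' `21ur-` identifier on a non-ncRNA record is never flagged and triggers
#' a warning, enforcing the category invariant.
#'
#' @param genes Gene table with `gene_id`, `category` and optionally
#'   `biotype`.
#' @return Logical vector aligned with the rows of `genes`.
#' @export
is_21u <- function(genes) {
  named_21u <- grepl("^21ur-", genes$gene_id, ignore.case = TRUE)
  bio_piRNA <- if ("biotype" %in% names(genes)) {
    !is.na(genes$biotype) & genes$biotype == "piRNA"
  } else {
    rep(FALSE, nrow(genes))
  }
  hit <- named_21u | bio_piRNA
  bad <- hit & genes$category != "ncRNA"
  if (any(bad)) {
    warn(paste0("21U-named gene(s) not categorized as ncRNA, not flagged: ",
                paste(head(genes$gene_id[bad], 5), collapse = ", ")))
  }
  hit & genes$category == "ncRNA"
}

#' Assign genes to clone libraries
#'
#' A gene belongs to a library when, by default, its interval midpoint
#' lies inside any clone of that library; since the finished
#' (cosmid/fosmid) and YAC-exclusive interval sets are disjoint after
#' trimming, a gene lands in at most one of those two, and is never
#' duplicated within a library. Alternatives: `"contained"` requires the
#' whole gene inside the merged library coverage, `"any-overlap"` a
#' single shared base.
#'
#' @param genes Gene table ([read_gff3_genes()]).
#' @param clones Clone table with a `clone_type` (or `library`) column.
#' @param assign Assignment rule.
#' @return `genes` with an added `library` column (`NA` for genes covered
#'   by no clone).
#' @export
assign_genes_to_library <- function(genes, clones,
                                    assign = c("midpoint", "contained",
                                               "any-overlap")) {
  assign <- match.arg(assign)
  genes <- validate_intervals(genes, what = "gene record")
  libcol <- if ("library" %in% names(clones)) "library" else "clone_type"
  libs <- unique(clones[[libcol]])
  genes$library <- NA_character_
  for (lib in libs) {
    cov <- gi_merge(clones[clones[[libcol]] == lib, ])
    inside <- switch(assign,
      midpoint = {
        mids <- gi_intervals(genes$chrom, floor((genes$start + genes$end) / 2),
                             floor((genes$start + genes$end) / 2) + 1)
        gi_overlap_fraction(mids, cov) == 1
      },
      contained = gi_overlap_fraction(genes, cov) == 1,
      `any-overlap` = gi_overlap_fraction(genes, cov) > 0)
    genes$library <- if_else(inside & is.na(genes$library), lib, genes$library)
  }
  genes
}

#' Gene density per megabase
#'
#' @param count Gene count.
#' @param coverage_bp Library coverage in bp (> 0).
#' @return Genes per MB: `count / (coverage_bp / 1e6)`.
#' @examples
#' density_per_mb(10799, 22327861) # ~ 484 ncRNAs/MB
#' @export
density_per_mb <- function(count, coverage_bp) {
  if (any(coverage_bp <= 0)) abort("density_per_mb: coverage must be > 0")
  count / (coverage_bp / 1e6)
}

#' Percent composition of a subset
#'
#' @param sub_count Subset count (e.g. 21U genes).
#' @param total_count Total count (> 0).
#' @return Percent, `100 * sub_count / total_count`.
#' @examples
#' composition_fraction(4713, 11108) # ~ 42.4% of cosmid ncRNAs are 21U
#' @export
composition_fraction <- function(sub_count, total_count) {
  if (any(total_count <= 0)) abort("composition_fraction: total must be > 0")
  100 * sub_count / total_count
}

#' Recompute library ratios excluding one chromosome
#'
#' Drops one chromosome from a per-chromosome count table and recomputes
#' library totals, densities (when per-chromosome coverage is supplied)
#' and the ratio of the first to the second library. Mirrors asking how
#' the cosmid:YAC ncRNA balance changes when the piRNA-cluster chromosome
#' is removed.
#'
#' @param counts Tibble with columns `chrom`, `library`, `count` and
#'   optionally `coverage_bp`.
#' @param chrom Chromosome to exclude (must be present).
#' @param libraries Length-2 character vector; the ratio reported is
#'   `libraries[1] : libraries[2]`.
#' @return One-row tibble with per-library totals (and densities when
#'   coverage is present) and `ratio`.
#' @export
exclude_chromosome <- function(counts, chrom,
                               libraries = c("cosmid", "yac")) {
  if (!chrom %in% counts$chrom) {
    abort(paste0("exclude_chromosome: unknown chromosome '", chrom, "'"))
  }
  kept <- filter(counts, .data$chrom != .env$chrom,
                 .data$library %in% libraries)
  tot <- kept %>%
    group_by(.data$library) %>%
    summarise(count = sum(.data$count),
              coverage_bp = if ("coverage_bp" %in% names(kept))
                sum(.data$coverage_bp) else NA_real_,
              .groups = "drop")
  get <- function(lib, col) {
    v <- tot[[col]][tot$library == lib]
    if (length(v) == 0) 0 else v
  }
  c1 <- get(libraries[1], "count")
  c2 <- get(libraries[2], "count")
  out <- tibble(excluded_chrom = chrom,
                count_1 = c1, count_2 = c2,
                ratio = if (c2 > 0) c1 / c2 else NA_real_)
  names(out)[2:3] <- paste0("count_", libraries)
  if (!anyNA(tot$coverage_bp)) {
    out[[paste0("density_", libraries[1])]] <-
      density_per_mb(c1, get(libraries[1], "coverage_bp"))
    out[[paste0("density_", libraries[2])]] <-
      density_per_mb(c2, get(libraries[2], "coverage_bp"))
  }
  out
}

#' Repeat-masked percent of named regions
#'
#' For each region (e.g. a piRNA cluster), the per-base union of repeat
#' annotations within it as a percent of its length; used to ask whether
#' piRNA clusters are less repetitive than their chromosome at large.
#'
#' @param regions Interval table (a `name` column is carried through).
#' @param repeats Repeat annotation table.
#' @return `regions` with an added `masked_pct` column.
#' @export
region_masked_pct <- function(regions, repeats) {
  regions <- validate_intervals(regions, what = "region")
  pct <- vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, c("chrom", "start", "end")]
    100 * gi_total_bp(gi_intersect(repeats, r)) / (r$end - r$start)
  }, numeric(1))
  mutate(regions, masked_pct = pct)
}

#' Length statistics of a gene set
#'
#' Count, mean, median and standard deviation (n-1 denominator) of gene
#' lengths. Respects existing `dplyr` grouping, so
#' `genes |> group_by(library, category) |> gene_length_stats()` yields
#' one row per library and gene category.
#'
#' @param genes Gene table (>= 1 row per group).
#' @return Tibble with `n`, `mean_length`, `median_length`, `sd_length`.
#' @export
gene_length_stats <- function(genes) {
  if (nrow(genes) == 0) abort("gene_length_stats: empty gene set")
  genes %>%
    summarise(n = n(),
              mean_length = mean(.data$end - .data$start),
              median_length = median(.data$end - .data$start),
              sd_length = if (n() > 1) sd(.data$end - .data$start) else 0,
              .groups = "drop")
}

#' Format a density the way the source tables print it
#'
#' Densities above 10 are printed as integers, smaller ones with one
#' decimal.
#'
#' @param x Numeric vector of densities.
#' @return Character vector.
#' @export
format_density <- function(x) {
  if_else(x > 10, sprintf("%.0f", x), sprintf("%.1f", x))
}
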