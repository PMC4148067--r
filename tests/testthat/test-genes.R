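test_that("density, composition and ratio operations reproduce published numbers", {
  counts <- published_counts()
  yac <- counts[counts$library == "yac", ]
  cos <- counts[counts$library == "cosmid", ]
  expect_equal(format_density(density_per_mb(yac$ncrna, yac$coverage_bp)),
               "484")
  expect_equal(format_density(density_per_mb(cos$ncrna, cos$coverage_bp)),
               "143")
  expect_equal(format_density(density_per_mb(yac$trna, yac$coverage_bp)),
               "4.2")
  expect_equal(format_density(density_per_mb(cos$trna, cos$coverage_bp)),
               "1.5")
  expect_equal(round(density_per_mb(yac$rrna, yac$coverage_bp), 2), 0.45)
  expect_equal(round(composition_fraction(cos$ncrna_21u, cos$ncrna), 1), 42.4)
  expect_equal(round(composition_fraction(yac$ncrna_21u, yac$ncrna)), 91)
  expect_equal(round(cos$ncrna_excl_chrIV / yac$ncrna_excl_chrIV, 1), 8.8)
  expect_equal(density_per_mb(0, 1e6), 0)
  expect_error(density_per_mb(1, 0), "coverage")
  expect_error(composition_fraction(1, 0), "total")
})

test_that("excluding a chromosome recomputes counts and ratios", {
  counts <- tibble::tibble(
    chrom = rep(c("chrIV", "rest"), each = 2),
    library = rep(c("cosmid", "yac"), 2),
    count = c(11108 - 6182, 10799 - 702, 6182, 702))
  r <- exclude_chromosome(counts, "chrIV")
  expect_equal(r$count_cosmid, 6182)
  expect_equal(r$count_yac, 702)
  expect_equal(round(r$ratio, 1), 8.8)
  # excluding a chromosome with zero features changes nothing
  zero <- dplyr::bind_rows(counts,
                           tibble::tibble(chrom = "empty",
                                          library = c("cosmid", "yac"),
                                          count = c(0, 0)))
  r2 <- exclude_chromosome(zero, "empty")
  all_ratio <- sum(counts$count[counts$library == "cosmid"]) /
    sum(counts$count[counts$library == "yac"])
  expect_equal(r2$ratio, all_ratio)
  expect_error(exclude_chromosome(counts, "chrX"), "unknown")
})

test_that("21U flagging follows the naming convention and the ncRNA invariant", {
  g <- tibble::tibble(gene_id = c("21ur-1523", "mir-35", "21UR-2"),
                      category = c("ncRNA", "ncRNA", "ncRNA"))
  expect_equal(is_21u(g), c(TRUE, FALSE, TRUE))
  bad <- tibble::tibble(gene_id = "21ur-1", category = "tRNA")
  expect_warning(flag <- is_21u(bad), "not categorized")
  expect_false(flag)
  bio <- tibble::tibble(gene_id = "px-9", category = "ncRNA", biotype = "piRNA")
  expect_true(is_21u(bio))
})

test_that("genes are assigned by midpoint to at most one disjoint library", {
  clones <- tibble::tibble(chrom = "chrI", start = c(0, 100),
                           end = c(100, 200),
                           clone_id = c("C1", "Y1"),
                           clone_type = c("cosmid", "yac"))
  genes <- tibble::tibble(gene_id = c("in_cos", "straddle", "outside"),
                          chrom = "chrI", start = c(10, 80, 300),
                          end = c(30, 140, 350),
                          category = "CDS", is_21u = FALSE)
  a <- assign_genes_to_library(genes, clones)
  expect_equal(a$library, c("cosmid", "yac", NA)) # straddler's midpoint is 110
  cont <- assign_genes_to_library(genes, clones, assign = "contained")
  expect_equal(cont$library, c("cosmid", NA, NA))
  any_ov <- assign_genes_to_library(genes, clones, assign = "any-overlap")
  expect_equal(any_ov$library[3], NA_character_)
  expect_equal(any_ov$library[1], "cosmid")
})

test_that("region masked percent matches the bitmap oracle", {
  reg <- tibble::tibble(chrom = "toy", start = 1000, end = 3000)
  expect_equal(region_masked_pct(reg, reg[0, ])$masked_pct, 0)
  expect_equal(region_masked_pct(reg, reg)$masked_pct, 100)
  withr::with_seed(88, {
    for (case in 1:10) {
      ann <- random_intervals(40, 10000, max_len = 300)
      got <- region_masked_pct(reg, ann)$masked_pct
      cov <- bitmap_cover(ann, "toy", 10000)
      expect_equal(got, 100 * sum(cov[1001:3000]) / 2000)
    }
  })
})

test_that("gene length statistics use the n-1 standard deviation", {
  one <- gene_length_stats(tibble::tibble(chrom = "c", start = 0, end = 948))
  expect_equal(one$mean_length, 948)
  expect_equal(one$median_length, 948)
  expect_equal(one$sd_length, 0)
  three <- gene_length_stats(tibble::tibble(chrom = "c", start = c(0, 0, 0),
                                            end = c(800, 1000, 1200)))
  expect_equal(three$mean_length, 1000)
  expect_equal(three$median_length, 1000)
  expect_equal(three$sd_length, 200)
  expect_error(gene_length_stats(one[0, ]), "empty")
})

test_that("planted gene structure is recovered from the default bundle", {
  b <- default_bundle()
  cfg_21u_len <- 21
  trim <- derive_exclusive(dplyr::filter(b$clones, clone_type == "yac"),
                           dplyr::filter(b$clones, clone_type != "yac"))
  libs <- dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(b$clones, clone_type == "cosmid"),
                  library = "cosmid"),
    dplyr::mutate(trim$exclusive, library = "yac"))
  assigned <- assign_genes_to_library(b$genes, libs)
  nc <- dplyr::filter(assigned, category == "ncRNA", !is.na(library))

  # counting is exact: every planted cluster piRNA lands in the YAC library
  expect_equal(sum(nc$is_21u & nc$library == "yac"),
               b$truth$cluster_n_pirna)
  expect_true(all(nc$end[nc$is_21u] - nc$start[nc$is_21u] == cfg_21u_len))

  # per-chromosome counts sum to the library totals exactly
  by_chrom <- dplyr::count(nc, chrom, library)
  tot <- dplyr::count(nc, library)
  expect_equal(dplyr::count(by_chrom, library, wt = n), tot)

  # background ncRNA lengths recover the generator's mean within 2 SE
  bg <- dplyr::filter(nc, !is_21u, library == "cosmid")
  lens <- bg$end - bg$start
  expect_gt(nrow(bg), 300)
  expect_lt(abs(mean(lens) - (21 + 33)), 2 * stats::sd(lens) / sqrt(nrow(bg)))

  # density is homogeneous: doubling count and coverage changes nothing
  expect_equal(density_per_mb(10, 1e6), density_per_mb(20, 2e6))

  # excluding the cluster chromosome flips the ncRNA density ratio
  cov_by_chrom <- function(cl) {
    gi_merge(cl) |>
      dplyr::group_by(chrom) |>
      dplyr::summarise(coverage_bp = sum(end - start), .groups = "drop")
  }
  counts <- dplyr::count(nc, chrom, library, name = "count") |>
    tidyr::complete(chrom = b$sizes$chrom, library = c("cosmid", "yac"),
                    fill = list(count = 0L)) |>
    dplyr::left_join(dplyr::bind_rows(
      dplyr::mutate(cov_by_chrom(dplyr::filter(libs, library == "cosmid")),
                    library = "cosmid"),
      dplyr::mutate(cov_by_chrom(dplyr::filter(libs, library == "yac")),
                    library = "yac")),
      by = c("chrom", "library")) |>
    dplyr::mutate(coverage_bp = dplyr::coalesce(coverage_bp, 0))
  dummy <- tibble::tibble(chrom = ".none", library = c("cosmid", "yac"),
                          count = 0L, coverage_bp = 0)
  all_r <- exclude_chromosome(dplyr::bind_rows(counts, dummy), ".none",
                              libraries = c("yac", "cosmid"))
  excl_r <- exclude_chromosome(counts, b$truth$cluster_chrom,
                               libraries = c("yac", "cosmid"))
  expect_gt(all_r$density_yac / all_r$density_cosmid, 1)
  expect_lt(excl_r$density_yac / excl_r$density_cosmid, 1)
})
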