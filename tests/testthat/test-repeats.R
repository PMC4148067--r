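test_that("repeat classes map onto summary categories", {
  got <- classify_repeat(c("DNA/PiggyBac", "Low_complexity", "LINE/CR1",
                           "LTR/Pao", "RC/Helitron", "Satellite",
                           "Simple_repeat", "tRNA", "Unknown"))
  expect_equal(got$category,
               c("DNA_transposons", "Low_complexity", "Retroelements",
                 "Retroelements", "Rolling_circles", "Satellites",
                 "Simple_repeats", "Small_RNA", "Unclassified"))
  expect_equal(got$subclass[1], "PiggyBac")
  expect_warning(fb <- classify_repeat("FooBar"), "FooBar")
  expect_equal(fb$category, "Unclassified")
})

mk_repeats <- function(chrom, start, end, class) {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 repeat_name = paste0("r", seq_along(start)),
                 repeat_class = class)
}

test_that("a clone without repeats profiles to all zeros", {
  clone <- gi_intervals("chrI", 0, 1000, clone_id = "C1")
  p <- profile_clones(clone, mk_repeats("chrII", 0, 100, "DNA/hAT"))
  expect_true(all(p$bp == 0))
  expect_true(all(p$pct == 0))
  expect_true(all(p$n_elements == 0))
})

test_that("element counts follow rows while bp uses the union", {
  clone <- gi_intervals("chrI", 0, 1000, clone_id = "C1")
  p <- profile_clones(clone, mk_repeats("chrI", c(0, 50), c(100, 150),
                                        c("DNA/hAT", "DNA/hAT")))
  dna <- p[p$category == "DNA_transposons", ]
  expect_equal(dna$n_elements, 2L)
  expect_equal(dna$bp, 150)
  expect_equal(dna$pct, 15)
  expect_equal(p$bp[p$category == "Bases_masked"], 150)
  expect_equal(p$bp[p$category == "Total_interspersed"], 150)
})

test_that("boundary-spanning elements are clipped to the clone", {
  clone <- gi_intervals("chrI", 100, 200, clone_id = "C1")
  p <- profile_clones(clone, mk_repeats("chrI", 150, 350, "Satellite"))
  sat <- p[p$category == "Satellites", ]
  expect_equal(sat$n_elements, 1L)
  expect_equal(sat$bp, 50)
})

test_that("per-category bp matches the bitmap oracle on random annotations", {
  len <- 10000
  classes <- c("DNA/hAT", "LINE/CR1", "Satellite", "Simple_repeat", "Unknown")
  withr::with_seed(404, {
    for (case in 1:20) {
      ann <- random_intervals(50, len, max_len = 400)
      ann$repeat_name <- paste0("r", 1:50)
      ann$repeat_class <- sample(classes, 50, replace = TRUE)
      clone <- tibble::tibble(chrom = "toy", start = 2000, end = 8000,
                              clone_id = "C1")
      p <- profile_clones(clone, ann)
      cat_of <- classify_repeat(ann$repeat_class)$category
      clone_cov <- function(rows) {
        cov <- bitmap_cover(ann[rows, ], "toy", len)
        sum(cov[2001:8000])
      }
      for (cat in unique(cat_of)) {
        expect_equal(p$bp[p$category == cat], clone_cov(cat_of == cat))
      }
      expect_equal(p$bp[p$category == "Bases_masked"],
                   clone_cov(rep(TRUE, 50)))
      intersp <- cat_of %in% c("Retroelements", "DNA_transposons",
                               "Rolling_circles", "Unclassified")
      expect_equal(p$bp[p$category == "Total_interspersed"],
                   clone_cov(intersp))
      # category bp never undershoots the masked union
      expect_gte(sum(p$bp[!p$category %in%
                            c("Bases_masked", "Total_interspersed")]),
                 p$bp[p$category == "Bases_masked"])
    }
  })
})

test_that("percent fields are invariant under coordinate translation", {
  withr::with_seed(505, {
    ann <- random_intervals(30, 10000, max_len = 300)
    ann$repeat_name <- paste0("r", 1:30)
    ann$repeat_class <- "DNA/hAT"
  })
  clone <- tibble::tibble(chrom = "toy", start = 1000, end = 9000,
                          clone_id = "C1")
  p1 <- profile_clones(clone, ann)
  shift <- 123456
  p2 <- profile_clones(dplyr::mutate(clone, start = start + shift,
                                     end = end + shift),
                       dplyr::mutate(ann, start = start + shift,
                                     end = end + shift))
  expect_equal(p1$pct, p2$pct)
  expect_equal(p1$n_elements, p2$n_elements)
})

test_that("library summaries aggregate mean, median, extremes and non-zero mean", {
  clones <- gi_intervals("chrI", c(0, 2000), c(1000, 3000),
                         clone_id = c("A", "B"))
  # A carries one 100 bp DNA element (10%), B carries none
  p <- profile_clones(clones, mk_repeats("chrI", 100, 200, "DNA/hAT"))
  s <- summarize_library(p, "demo")
  dna <- dplyr::filter(tidy(s), category == "DNA_transposons", field == "pct")
  expect_equal(dna$mean, 5)
  expect_equal(dna$nonzero_mean, 10)
  expect_equal(dna$min, 0)
  expect_equal(dna$max, 10)
  expect_equal(glance(s)$n_clones, 2)
  expect_equal(glance(s)$total_bp, 2000)

  one <- summarize_library(profile_clones(clones[1, ],
                                          mk_repeats("chrI", 100, 200,
                                                     "DNA/hAT")))
  d1 <- dplyr::filter(tidy(one), category == "DNA_transposons", field == "pct")
  expect_equal(d1$mean, d1$median)
  expect_equal(d1$min, d1$max)
  expect_error(summarize_library(p[0, ]), "empty")
})

test_that("a planted 2x DNA-transposon gap contrast is recovered", {
  # flat background: no arm or cluster effect, one DNA family at density d
  # outside gaps and 2d inside
  cfg <- synthetic_config(
    seed = 2001, arm_multiplier = 1, cluster_repeat_multiplier = 1,
    repeat_table = tibble::tibble(repeat_name = "TC1A",
                                  repeat_class = "DNA/Tc1-Mariner",
                                  elem_len = 250, density_per_kb = 0.12,
                                  gap_mult = 2),
    cds_per_mb = c(nongap = 0, gap = 0),
    ncrna_per_mb = c(nongap = 0, gap = 0),
    trna_per_mb = c(nongap = 0, gap = 0),
    rrna_per_mb = c(nongap = 0, gap = 0),
    cluster_n_pirna = 10)
  b <- generate_synthetic_bundle(cfg)
  yacs <- dplyr::filter(b$clones, clone_type == "yac")
  fin <- dplyr::filter(b$clones, clone_type != "yac")
  trim <- derive_exclusive(yacs, fin)
  cosmids <- dplyr::filter(b$clones, clone_type == "cosmid")
  expect_gte(nrow(cosmids) + nrow(trim$exclusive), 200)
  yac_pct <- library_mean_pct(profile_clones(trim$exclusive, b$repeats),
                              "DNA_transposons")
  cos_pct <- library_mean_pct(profile_clones(cosmids, b$repeats),
                              "DNA_transposons")
  expect_lt(abs(yac_pct / cos_pct - 2), 0.2)
})

test_that("random libraries of different clone sizes have matching repeat content", {
  # uniform annotations: an emulated YAC-sized and cosmid-sized random
  # library should be statistically indistinguishable
  sizes <- tibble::tibble(chrom = "toy", length = 2e6)
  ann <- plant_feature_track(tibble::tibble(chrom = "toy", start = 0,
                                            end = 2e6),
                             density_per_kb = 0.4, lengths = 200, seed = 99)
  ann_set <- gi_merge(ann)
  masked_fracs <- function(lib) gi_overlap_fraction(lib, ann_set)
  yac_model <- structure(list(n = 200, mean = 24000, sd = 6000, floor = 500),
                         class = "length_model")
  cos_model <- structure(list(n = 200, mean = 32500, sd = 4000, floor = 500),
                         class = "length_model")
  a <- masked_fracs(sample_random_library(sizes, yac_model, seed = 301))
  b <- masked_fracs(sample_random_library(sizes, cos_model, seed = 302))
  expect_gt(welch_t(a, b)$p_value, 0.01)
})
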