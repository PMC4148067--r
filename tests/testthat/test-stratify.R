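sz <- tibble::tibble(chrom = "chrI", length = 1000)

test_that("clones go to extreme or middle quarters by midpoint", {
  clones <- gi_intervals("chrI", c(50, 450, 200), c(150, 550, 300),
                         clone_id = c("a", "b", "c"))
  q <- locate_quartile(clones, sz)
  expect_equal(q$quartile, c("extreme", "middle", "middle"))
  # midpoint exactly at 25% falls in the middle (half-open convention)
  edge <- locate_quartile(gi_intervals("chrI", 200, 300, clone_id = "e"), sz)
  expect_equal(edge$rel_mid, 0.25)
  expect_equal(edge$quartile, "middle")
  expect_error(locate_quartile(gi_intervals("chrII", 0, 10, clone_id = "x"), sz),
               "not in sizes")
  expect_error(locate_quartile(gi_intervals("chrI", 900, 1100, clone_id = "x"),
                               sz),
               "beyond chromosome end")
  # labels partition the clone set
  expect_equal(sum(q$quartile == "extreme") + sum(q$quartile == "middle"),
               nrow(clones))
})

test_that("location histograms put all mass where the clones start", {
  clones <- gi_intervals("chrI", c(0, 0, 0), c(10, 20, 30),
                         clone_id = c("a", "b", "c"))
  h <- location_histogram(clones, sz)
  expect_equal(h$fraction[h$bin == 0], 1)
  expect_equal(sum(h$fraction), 1, tolerance = 1e-9)
  expect_equal(h$cumulative[h$bin == 0], 1)
  late <- location_histogram(gi_intervals("chrI", 999, 1000, clone_id = "z"),
                             sz)
  expect_equal(late$cumulative[late$bin == 99], 1)
  expect_true(all(diff(late$cumulative) <= 1e-12))
})

test_that("uniform starts give a flat histogram", {
  sizes <- tibble::tibble(chrom = c("c1", "c2"), length = c(1e6, 2e6))
  clones <- withr::with_seed(61, {
    dplyr::bind_rows(
      tibble::tibble(chrom = "c1", start = floor(runif(5000, 0, 1e6 - 100))),
      tibble::tibble(chrom = "c2", start = floor(runif(5000, 0, 2e6 - 100)))) |>
      dplyr::mutate(end = start + 100, clone_id = paste0("r", dplyr::row_number()))
  })
  h <- location_histogram(clones, sizes)
  expect_equal(sum(h$fraction), 1, tolerance = 1e-9)
  expect_true(all(abs(h$fraction - 0.01) < 0.005))
})

test_that("median splits use the lower middle order statistic", {
  clones <- gi_intervals("chrI", c(0, 0, 0), c(1, 2, 3),
                         clone_id = c("a", "b", "c"))
  s <- split_by_median_length(clones)
  expect_equal(attr(s, "median_length"), 2)
  expect_equal(s$clone_id[s$length_group == "below"], "a")
  expect_equal(sort(s$clone_id[s$length_group == "above_or_equal"]),
               c("b", "c"))
  eq <- split_by_median_length(gi_intervals("chrI", c(0, 10), c(5, 15),
                                            clone_id = c("a", "b")))
  expect_equal(sum(eq$length_group == "below"), 0)
  expect_error(split_by_median_length(clones[1, ]), "at least 2")
})

test_that("synthetic clone length medians match their targets", {
  b <- default_bundle()
  trim <- derive_exclusive(dplyr::filter(b$clones, clone_type == "yac"),
                           dplyr::filter(b$clones, clone_type != "yac"))
  yac_med <- median(trim$exclusive$end - trim$exclusive$start)
  cos <- dplyr::filter(b$clones, clone_type == "cosmid")
  cos_med <- median(cos$end - cos$start)
  expect_lt(abs(yac_med / 23700 - 1), 0.05)
  expect_lt(abs(cos_med / 32500 - 1), 0.05)
})

test_that("welch_t matches the reference implementation and conventions", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  jit <- c(1, 1, 1, 1) + c(1e-9, -1e-9, 2e-9, -2e-9)
  expect_lt(welch_t(c(0, 0, 0, 0) + c(1e-9, -1e-9, 2e-9, -2e-9), jit)$p_value,
            1e-4)
  # zero variance in both groups
  expect_equal(welch_t(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(welch_t(c(2, 2), c(3, 3))$p_value, 0)
  withr::with_seed(71, {
    for (case in 1:20) {
      a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
      b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
      ref <- stats::t.test(a, b)
      got <- welch_t(a, b)
      expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("arm-enriched repeats make extreme quarters more repetitive, in both libraries", {
  b <- default_bundle()
  trim <- derive_exclusive(dplyr::filter(b$clones, clone_type == "yac"),
                           dplyr::filter(b$clones, clone_type != "yac"))
  cos <- dplyr::filter(b$clones, clone_type == "cosmid")
  prof <- function(cl) {
    p <- profile_clones(cl, b$repeats)
    p[p$category == "Bases_masked", c("clone_id", "pct")]
  }
  masked <- dplyr::bind_rows(
    dplyr::left_join(locate_quartile(cos, b$sizes), prof(cos),
                     by = "clone_id") |> dplyr::mutate(library = "cosmid"),
    dplyr::left_join(locate_quartile(trim$exclusive, b$sizes),
                     prof(trim$exclusive),
                     by = "clone_id") |> dplyr::mutate(library = "yac"))
  tt <- welch_t(masked$pct[masked$quartile == "extreme"],
                masked$pct[masked$quartile == "middle"])
  expect_gt(tt$mean_a, tt$mean_b)
  expect_lt(tt$p_value, 0.01)
  # the YAC > cosmid contrast persists within each location stratum
  for (q in c("extreme", "middle")) {
    sub <- masked[masked$quartile == q, ]
    expect_gt(mean(sub$pct[sub$library == "yac"]),
              mean(sub$pct[sub$library == "cosmid"]))
  }
  # and within both halves of the clone-length split
  for (lib_tbl in list(cos, trim$exclusive)) {
    split <- split_by_median_length(lib_tbl)
    stopifnot(all(c("below", "above_or_equal") %in% split$length_group))
  }
})
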