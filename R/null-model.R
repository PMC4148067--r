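#' Fit a clone-length model for matched random libraries
#'
#' Records the clone count, mean and standard deviation (n-1 denominator)
#' of clone lengths, the ingredients for sampling a matched random
#' library "of similar sizes" from the genome.
#'
#' @param clones Clone table (or any interval table).
#' @param floor Minimum sampled clone length in bp (default 500); random
#'   draws below it are redrawn.
#' @return A `length_model` list with `n`, `mean`, `sd`, `floor`.
#' @export
fit_length_model <- function(clones, floor = 500) {
  clones <- validate_intervals(clones, what = "clone record")
  if (nrow(clones) == 0) abort("fit_length_model: empty clone set")
  len <- clones$end - clones$start
  structure(list(n = length(len), mean = mean(len),
                 sd = if (length(len) > 1) sd(len) else 0,
                 floor = floor),
            class = "length_model")
}

#' @export
print.length_model <- function(x, ...) {
  cat(sprintf("Clone length model: n=%d, mean=%.1f bp, sd=%.1f bp, floor=%d bp\n",
              x$n, x$mean, x$sd, x$floor))
  invisible(x)
}

#' Sample a matched random clone library
#'
#' Draws `n` random segments from the genome with lengths from
#' `Normal(mean, sd)` truncated by redraw to `[floor, longest
#' chromosome]` and rounded to integers. Chromosomes are chosen with
#' probability proportional to their length and the start is uniform in
#' `[0, chrom_length - length]`; draws that do not fit their chromosome
#' are redrawn. Sampled clones may overlap one another. Deterministic
#' given `seed`.
#'
#' @param sizes Chromosome sizes tibble ([read_chrom_sizes()]).
#' @param model A `length_model` from [fit_length_model()].
#' @param seed Optional integer seed for reproducibility.
#' @param n Number of clones (default `model$n`).
#' @return Clone table with `clone_type = "random"`.
#' @export
sample_random_library <- function(sizes, model, seed = NULL, n = model$n) {
  stopifnot(inherits(model, "length_model"), n >= 1)
  if (nrow(sizes) == 0) abort("sample_random_library: empty chromosome sizes")
  maxlen <- max(sizes$length)
  if (model$mean > maxlen) {
    abort("sample_random_library: model mean length exceeds every chromosome")
  }
  draw <- function() {
    lens <- rep(NA_real_, n)
    chroms <- rep(NA_integer_, n)
    # joint redraw of (length, chromosome) until both bounds hold
    while (anyNA(lens)) {
      idx <- which(is.na(lens))
      L <- round(rnorm(length(idx), model$mean, model$sd))
      ci <- sample.int(nrow(sizes), length(idx), replace = TRUE,
                       prob = sizes$length)
      ok <- L >= model$floor & L <= sizes$length[ci]
      lens[idx[ok]] <- L[ok]
      chroms[idx[ok]] <- ci[ok]
    }
    starts <- floor(runif(n, 0, sizes$length[chroms] - lens + 1))
    tibble(chrom = sizes$chrom[chroms], start = starts, end = starts + lens,
           clone_id = sprintf("rand_%05d", seq_len(n)),
           clone_type = "random")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Empirical enrichment test against matched random libraries
#'
#' Scores an observed clone library with `feature_stat`, then scores
#' `replicates` matched random libraries drawn with
#' [sample_random_library()], and reports the z-score and the add-one
#' smoothed empirical p-value `(1 + #\{null >= observed\}) / (1 +
#' replicates)` (right tail; for `alternative = "two.sided"` the
#' exceedance is measured on `|stat - null mean|`).
#'
#' @param observed_clones Clone table of the observed library.
#' @param feature_stat Function mapping a clone table to a single number
#'   (e.g. mean masked percent, ncRNAs per MB).
#' @param sizes Chromosome sizes tibble.
#' @param model Optional `length_model`; default fitted from
#'   `observed_clones`.
#' @param replicates Number of random libraries (>= 1).
#' @param seed Integer seed driving all replicate draws.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return An `enrichment_result`; [tidy()] returns the null replicate
#'   statistics, [glance()] the one-row summary.
#' @export
enrichment_test <- function(observed_clones, feature_stat, sizes,
                            model = NULL, replicates = 199, seed = NULL,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (replicates < 1) abort("enrichment_test: replicates must be >= 1")
  if (is.null(model)) model <- fit_length_model(observed_clones)
  observed <- feature_stat(observed_clones)
  run <- function() {
    vapply(seq_len(replicates), function(i) {
      feature_stat(sample_random_library(sizes, model))
    }, numeric(1))
  }
  null_stats <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  null_mean <- mean(null_stats)
  null_sd <- sd(null_stats)
  exceed <- if (alternative == "greater") {
    sum(null_stats >= observed)
  } else {
    sum(abs(null_stats - null_mean) >= abs(observed - null_mean))
  }
  p <- (1 + exceed) / (1 + replicates)
  z <- if (isTRUE(null_sd > 0)) (observed - null_mean) / null_sd else NA_real_
  structure(list(observed = observed, null_stats = null_stats,
                 null_mean = null_mean, null_sd = null_sd, z = z,
                 p_value = p, replicates = replicates, seed = seed,
                 alternative = alternative),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Enrichment test (%s, %d random libraries):\n  observed = %.4g, null = %.4g +/- %.4g, z = %.2f, p = %.4g\n",
    x$alternative, x$replicates, x$observed, x$null_mean, x$null_sd,
    ifelse(is.na(x$z), NaN, x$z), x$p_value))
  invisible(x)
}

#' @rdname enrichment_test
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(replicate = seq_len(x$replicates), null_stat = x$null_stats)
}

#' @rdname enrichment_test
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(observed = x$observed, null_mean = x$null_mean,
         null_sd = x$null_sd, z = x$z, p_value = x$p_value,
         replicates = x$replicates,
         seed = if (is.null(x$seed)) NA_integer_ else x$seed,
         alternative = x$alternative)
}
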