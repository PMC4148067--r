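#' Default repeat families planted by the synthetic generator
#'
#' One row per planted repeat family: its RepeatMasker-style class
#' string, fixed element length, base density (elements per kb in the
#' middle quarters outside gaps) and the gap-region density multiplier.
#' DNA transposons, unclassified repeats and satellites are planted
#' denser inside gap regions, mirroring what bacteria-unclonable
#' C. elegans sequence looks like; the arm multiplier of the config is
#' applied on top for the extreme chromosome quarters.
#'
#' @return Tibble with `repeat_name`, `repeat_class`, `elem_len`,
#'   `density_per_kb`, `gap_mult`.
#' @export
default_repeat_table <- function() {
  tibble::tribble(
    ~repeat_name, ~repeat_class,     ~elem_len, ~density_per_kb, ~gap_mult,
    "TC1A",       "DNA/Tc1-Mariner", 250,       0.12,            2,
    "PBAC1",      "DNA/PiggyBac",    250,       0.04,            3,
    "HAT2",       "DNA/hAT",         250,       0.06,            2,
    "CR1A",       "LINE/CR1",        300,       0.02,            1,
    "PAO1",       "LTR/Pao",         300,       0.015,           1,
    "HELI1",      "RC/Helitron",     200,       0.01,            1,
    "UNKN1",      "Unknown",         200,       0.05,            3,
    "SATC1",      "Satellite",       300,       0.02,            5,
    "SIMP1",      "Simple_repeat",   60,        0.25,            1.5,
    "LOWC1",      "Low_complexity",  50,        0.12,            1,
    "TRNAR",      "tRNA",            75,        0.005,           1)
}

#' Configuration of the synthetic genome bundle
#'
#' Defines the toy genome the generator emits: five 1 Mb chromosomes;
#' per-chromosome gap regions (bacteria-unclonable sequence bridged by
#' YACs) with lognormal lengths (median ~23.7 kb) preferentially placed
#' on the repeat-rich extreme quarters; cosmids tiling all non-gap
#' sequence (mean 32.5 kb); YACs spanning each gap with Beta-distributed
#' end-overlap into finished sequence (mean total overlap 7%) plus a few
#' YACs fully covered by cosmids; repeats from [default_repeat_table()]
#' with a 2x arm multiplier; and genes (protein-coding, ncRNA, tRNA,
#' rRNA) at per-MB densities, including one dense piRNA cluster of 21
#' bp 21U genes inside a large gap on `chrIV` whose repeat density is
#' suppressed.
#'
#' @param seed Integer seed (mandatory); the whole bundle is a
#'   deterministic function of the config including the seed.
#' @param ... Overrides for any default field.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed, ...) {
  if (missing(seed) || !is.numeric(seed)) {
    abort("synthetic_config: an integer seed is mandatory")
  }
  cfg <- list(
    seed = as.integer(seed),
    chrom_lengths = setNames(rep(1e6, 5), paste0("chr", c("I", "II", "III", "IV", "V"))),
    # gap regions (future YAC-exclusive sequence)
    n_gaps = 10,
    gap_len_meanlog = log(23700),
    gap_len_sdlog = 0.35,
    gap_arm_prob = 0.75,
    gap_margin = 5000,
    gap_min_spacing = 15000,
    # piRNA cluster chromosome
    cluster_chrom = "chrIV",
    cluster_gap = c(460000, 790000),
    cluster_span = c(500000, 750000),
    cluster_n_pirna = 800,
    cluster_repeat_multiplier = 0.4,
    n_gaps_cluster_chrom = 3,
    # clone libraries
    cosmid_len_mean = 32500,
    cosmid_len_sd = 4000,
    cosmid_overlap = c(15000, 25000),
    n_fosmids = 15,
    fosmid_len_mean = 17000,
    fosmid_len_sd = 2000,
    yac_overlap_mean = 0.07,
    yac_overlap_shape1 = 2,
    n_covered_yacs = 3,
    # repeats
    repeat_table = default_repeat_table(),
    arm_multiplier = 2,
    # genes (densities per MB)
    cds_per_mb = c(nongap = 238, gap = 182),
    cds_len_meanlog = log(948),
    cds_len_sdlog = 0.45,
    ncrna_per_mb = c(nongap = 500, gap = 250),
    ncrna_21u_frac_nongap = 0.45,
    ncrna_extra_len_mean = 33,
    pirna_len = 21,
    trna_per_mb = c(nongap = 1.5, gap = 4.2),
    trna_len = 75,
    rrna_per_mb = c(nongap = 0.15, gap = 0.45),
    rrna_len = 150)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("synthetic_config: unknown field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  cl <- cfg$chrom_lengths
  if (any(cl <= 0) || is.null(names(cl))) {
    abort("synthetic_config: chromosome lengths must be named and positive")
  }
  if (!cfg$cluster_chrom %in% names(cl)) {
    abort("synthetic_config: cluster chromosome not among chromosomes")
  }
  if (cfg$cluster_gap[2] > cl[[cfg$cluster_chrom]] ||
      cfg$cluster_span[1] < cfg$cluster_gap[1] ||
      cfg$cluster_span[2] > cfg$cluster_gap[2]) {
    abort("synthetic_config: cluster span must sit inside the cluster gap, inside its chromosome")
  }
  structure(cfg, class = "synthetic_config")
}

#' Plant features at a Poisson density inside regions
#'
#' Plants features independently region by region: the count in a region
#' is Poisson with mean `density_per_kb / 1000` times the number of
#' admissible start positions, and each feature is placed uniformly so
#' that it lies entirely inside its region (features never cross region
#' boundaries). `lengths` is either a fixed element length or a function
#' `function(n)` drawing `n` lengths (lengths longer than the region are
#' truncated to it).
#'
#' @param regions Interval table.
#' @param density_per_kb Features per kb.
#' @param lengths Fixed length (scalar) or sampler `function(n)`.
#' @param seed Optional seed.
#' @return Interval tibble of planted features.
#' @export
plant_feature_track <- function(regions, density_per_kb, lengths, seed = NULL) {
  regions <- validate_intervals(regions, what = "region")
  run <- function() {
    out <- vector("list", nrow(regions))
    for (i in seq_len(nrow(regions))) {
      rs <- regions$start[i]
      re <- regions$end[i]
      rlen <- re - rs
      if (is.function(lengths)) {
        n <- rpois(1, density_per_kb / 1000 * rlen)
        if (n == 0) next
        L <- pmin(round(lengths(n)), rlen)
        L <- pmax(L, 1)
        st <- floor(runif(n, rs, re - L + 1))
        out[[i]] <- tibble(chrom = regions$chrom[i], start = st, end = st + L)
      } else {
        L <- lengths
        if (rlen <= L) next
        n <- rpois(1, density_per_kb / 1000 * (rlen - L + 1))
        if (n == 0) next
        st <- floor(runif(n, rs, re - L + 1))
        out[[i]] <- tibble(chrom = regions$chrom[i], start = st, end = st + L)
      }
    }
    res <- bind_rows(out)
    if (nrow(res) == 0) empty_intervals() else res
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

## extreme-quarter (arm) intervals of each chromosome
arm_intervals <- function(sizes) {
  bind_rows(
    tibble(chrom = sizes$chrom, start = 0, end = floor(sizes$length * 0.25)),
    tibble(chrom = sizes$chrom, start = ceiling(sizes$length * 0.75),
           end = sizes$length))
}

place_gaps_one_chrom <- function(chrom, len, n, cfg, fixed = NULL) {
  gaps <- fixed
  for (i in seq_len(n)) {
    L <- round(rlnorm(1, cfg$gap_len_meanlog, cfg$gap_len_sdlog))
    placed <- FALSE
    for (attempt in 1:400) {
      in_arm <- runif(1) < cfg$gap_arm_prob
      center <- if (in_arm) {
        if (runif(1) < 0.5) runif(1, 0, 0.25 * len) else runif(1, 0.75 * len, len)
      } else {
        runif(1, 0.25 * len, 0.75 * len)
      }
      s <- round(center - L / 2)
      e <- s + L
      if (s < cfg$gap_margin || e > len - cfg$gap_margin) next
      if (!is.null(gaps) && nrow(gaps) > 0 &&
          any(pmax(gaps$start - e, s - gaps$end) < cfg$gap_min_spacing)) next
      gaps <- bind_rows(gaps, tibble(chrom = chrom, start = s, end = e))
      placed <- TRUE
      break
    }
    if (!placed) {
      abort(sprintf("synthetic: could not place gap %d on %s (config too dense)", i, chrom))
    }
  }
  gaps
}

roman_id <- function(chrom) sub("^chr", "", chrom)

#' Generate the synthetic genome bundle
#'
#' Builds a fully self-contained toy genome with the statistical
#' structure the clone-library analysis assumes: gap regions uncovered by
#' cosmids and bridged by YACs with partial end-overlap, repeats
#' concentrated on chromosome arms and denser inside gaps, a dense 21U
#' piRNA cluster in low-repeat sequence on one chromosome, and gene
#' tracks per category. The returned `truth` list records every planted
#' quantity, including analytic expectations of the library-level
#' contrasts (expected masked and DNA-transposon percents per library are
#' computed from the planted Poisson densities via the coverage formula
#' `1 - exp(-lambda * L)`, averaged over the generated clone geometry),
#' so downstream recovery can be checked against it.
#'
#' The bundle is a deterministic function of the config (same seed, same
#' bytes). With `outdir` set, writes `chrom.sizes`, `clones.tsv`,
#' `repeats.out`, `genes.gff3`, `gaps.tsv`, `cluster.bed`, `truth.tsv`
#' and (optionally) `genome.fa` with uniform random bases.
#'
#' @param config A [synthetic_config()].
#' @param outdir Optional output directory.
#' @param write_fasta Also write the random-base FASTA (default FALSE;
#'   the analyses never read sequence).
#' @return List with `sizes`, `clones`, `repeats`, `genes`, `gaps`,
#'   `cluster`, `truth` (named list), and `files` when written.
#' @export
generate_synthetic_bundle <- function(config, outdir = NULL,
                                      write_fasta = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  bundle <- withr::with_seed(config$seed, build_bundle(config))
  if (!is.null(outdir)) {
    bundle$files <- write_bundle(bundle, config, outdir, write_fasta)
  }
  bundle
}

build_bundle <- function(cfg) {
  sizes <- tibble(chrom = names(cfg$chrom_lengths),
                  length = unname(cfg$chrom_lengths))

  ## -- gap regions -------------------------------------------------------
  gaps <- NULL
  for (i in seq_len(nrow(sizes))) {
    chrom <- sizes$chrom[i]
    len <- sizes$length[i]
    if (chrom == cfg$cluster_chrom) {
      fixed <- tibble(chrom = chrom, start = cfg$cluster_gap[1],
                      end = cfg$cluster_gap[2])
      gaps <- bind_rows(gaps,
                        place_gaps_one_chrom(chrom, len, cfg$n_gaps_cluster_chrom,
                                             cfg, fixed = fixed))
    } else {
      gaps <- bind_rows(gaps, place_gaps_one_chrom(chrom, len, cfg$n_gaps, cfg))
    }
  }
  gaps <- arrange(gaps, .data$chrom, .data$start)

  ## -- YACs bridging each gap, with end overlap into finished sequence ---
  shape2 <- cfg$yac_overlap_shape1 * (1 - cfg$yac_overlap_mean) / cfg$yac_overlap_mean
  yacs <- gaps %>%
    group_by(.data$chrom) %>%
    mutate(.prev_end = lag(.data$end, default = 0),
           .next_start = dplyr::lead(.data$start),
           .gap_i = row_number()) %>%
    ungroup()
  yacs <- left_join(yacs, sizes, by = "chrom")
  yacs$.next_start[is.na(yacs$.next_start)] <-
    yacs$length[is.na(yacs$.next_start)]
  f <- pmin(rbeta(nrow(yacs), cfg$yac_overlap_shape1, shape2), 0.6)
  u <- runif(nrow(yacs))
  ext <- (yacs$end - yacs$start) * f / (1 - f)
  e1 <- round(ext * u)
  e2 <- round(ext * (1 - u))
  avail1 <- pmax(0, yacs$start - yacs$.prev_end - 1000)
  avail2 <- pmax(0, yacs$.next_start - yacs$end - 1000)
  yac_tbl <- tibble(
    chrom = yacs$chrom,
    start = yacs$start - pmin(e1, avail1),
    end = yacs$end + pmin(e2, avail2),
    clone_id = sprintf("Y%s_%02d", roman_id(yacs$chrom), yacs$.gap_i),
    clone_type = "yac")

  ## -- cosmids tiling every non-gap segment ------------------------------
  segments <- gi_subtract(tibble(chrom = sizes$chrom, start = 0,
                                 end = sizes$length), gaps)
  cosmids <- vector("list", 0)
  k <- 0
  for (i in seq_len(nrow(segments))) {
    a <- segments$start[i]
    b <- segments$end[i]
    pos <- a
    repeat {
      L <- max(8000, round(rnorm(1, cfg$cosmid_len_mean, cfg$cosmid_len_sd)))
      k <- k + 1
      if (b - a <= L) {
        cosmids[[k]] <- tibble(chrom = segments$chrom[i], start = a, end = b)
        break
      }
      if (pos + L >= b) {
        cosmids[[k]] <- tibble(chrom = segments$chrom[i], start = b - L, end = b)
        break
      }
      cosmids[[k]] <- tibble(chrom = segments$chrom[i], start = pos, end = pos + L)
      adv <- max(2000, L - round(runif(1, cfg$cosmid_overlap[1],
                                       cfg$cosmid_overlap[2])))
      pos <- pos + adv
    }
  }
  cosmid_tbl <- bind_rows(cosmids) %>%
    mutate(clone_id = sprintf("C%04d", row_number()), clone_type = "cosmid")

  ## -- fosmids, fully inside non-gap segments ----------------------------
  fos <- vector("list", cfg$n_fosmids)
  for (i in seq_len(cfg$n_fosmids)) {
    j <- sample(nrow(segments), 1, prob = segments$end - segments$start)
    L <- max(2000, round(rnorm(1, cfg$fosmid_len_mean, cfg$fosmid_len_sd)))
    a <- segments$start[j]
    b <- segments$end[j]
    if (b - a <= L) {
      fos[[i]] <- tibble(chrom = segments$chrom[j], start = a, end = b)
    } else {
      s <- floor(runif(1, a, b - L + 1))
      fos[[i]] <- tibble(chrom = segments$chrom[j], start = s, end = s + L)
    }
  }
  fosmid_tbl <- bind_rows(fos) %>%
    mutate(clone_id = sprintf("F%03d", row_number()), clone_type = "fosmid")

  ## -- YACs fully covered by finished sequence ---------------------------
  cov_yacs <- vector("list", cfg$n_covered_yacs)
  for (i in seq_len(cfg$n_covered_yacs)) {
    for (attempt in 1:400) {
      j <- sample(nrow(segments), 1, prob = segments$end - segments$start)
      L <- round(rlnorm(1, cfg$gap_len_meanlog, cfg$gap_len_sdlog))
      a <- segments$start[j] + 1000
      b <- segments$end[j] - 1000
      if (b - a <= L) next
      s <- floor(runif(1, a, b - L + 1))
      cov_yacs[[i]] <- tibble(chrom = segments$chrom[j], start = s, end = s + L,
                              clone_id = sprintf("Ycov%s_%d",
                                                 roman_id(segments$chrom[j]), i),
                              clone_type = "yac")
      break
    }
    if (is.null(cov_yacs[[i]])) abort("synthetic: could not place covered YAC")
  }
  cov_tbl <- bind_rows(cov_yacs)

  clones <- bind_rows(cosmid_tbl, fosmid_tbl, yac_tbl, cov_tbl) %>%
    select("chrom", "start", "end", "clone_id", "clone_type")

  ## -- atomic pieces: arm/gap/cluster strata -----------------------------
  cluster <- tibble(chrom = cfg$cluster_chrom, start = cfg$cluster_span[1],
                    end = cfg$cluster_span[2], name = "piRNA_cluster_1")
  pieces <- vector("list", nrow(sizes))
  for (i in seq_len(nrow(sizes))) {
    chrom <- sizes$chrom[i]
    len <- sizes$length[i]
    cuts <- c(0, floor(0.25 * len), ceiling(0.75 * len), len,
              gaps$start[gaps$chrom == chrom], gaps$end[gaps$chrom == chrom])
    if (chrom == cfg$cluster_chrom) cuts <- c(cuts, cfg$cluster_span)
    cuts <- sort(unique(cuts))
    p <- tibble(chrom = chrom, start = head(cuts, -1), end = tail(cuts, -1))
    mid <- (p$start + p$end) / 2
    p$in_arm <- mid < 0.25 * len | mid >= 0.75 * len
    p$in_gap <- gi_overlap_fraction(p, gaps) > 0.5
    p$in_cluster <- chrom == cfg$cluster_chrom &
      mid >= cfg$cluster_span[1] & mid < cfg$cluster_span[2]
    pieces[[i]] <- p
  }
  pieces <- bind_rows(pieces)

  ## -- repeats planted per piece and family ------------------------------
  rt <- cfg$repeat_table
  rep_out <- vector("list", 0)
  lamL_all <- numeric(nrow(pieces))
  lamL_dna <- numeric(nrow(pieces))
  for (r in seq_len(nrow(rt))) {
    mult <- ifelse(pieces$in_arm, cfg$arm_multiplier, 1) *
      ifelse(pieces$in_gap, rt$gap_mult[r], 1) *
      ifelse(pieces$in_cluster, cfg$cluster_repeat_multiplier, 1)
    dens <- rt$density_per_kb[r] * mult
    lamL <- dens / 1000 * rt$elem_len[r]
    lamL_all <- lamL_all + lamL
    if (startsWith(rt$repeat_class[r], "DNA")) lamL_dna <- lamL_dna + lamL
    for (p in seq_len(nrow(pieces))) {
      feats <- plant_feature_track(pieces[p, c("chrom", "start", "end")],
                                   dens[p], rt$elem_len[r])
      if (nrow(feats) > 0) {
        feats$repeat_name <- rt$repeat_name[r]
        feats$repeat_class <- rt$repeat_class[r]
        rep_out[[length(rep_out) + 1]] <- feats
      }
    }
  }
  repeats <- bind_rows(rep_out)
  if (nrow(repeats) == 0) {
    repeats <- tibble(chrom = character(), start = numeric(), end = numeric(),
                      repeat_name = character(), repeat_class = character())
  }
  repeats <- arrange(repeats, .data$chrom, .data$start) %>%
    mutate(score = 1000)
  pieces$cov_all <- 1 - exp(-lamL_all)
  pieces$cov_dna <- 1 - exp(-lamL_dna)

  ## -- genes -------------------------------------------------------------
  nongap <- segments
  gid <- local({
    counter <- 0
    function(prefix, n) {
      ids <- sprintf("%s%05d", prefix, counter + seq_len(n))
      counter <<- counter + n
      ids
    }
  })
  cds_len <- function(n) rlnorm(n, cfg$cds_len_meanlog, cfg$cds_len_sdlog)
  mk_genes <- function(feats, prefix, category, type_21u = FALSE) {
    if (nrow(feats) == 0) return(NULL)
    feats$gene_id <- gid(prefix, nrow(feats))
    feats$category <- category
    feats$is_21u <- type_21u
    feats
  }
  g <- list(
    mk_genes(plant_feature_track(nongap, cfg$cds_per_mb[["nongap"]] / 1000, cds_len),
             "cds", "CDS"),
    mk_genes(plant_feature_track(gaps, cfg$cds_per_mb[["gap"]] / 1000, cds_len),
             "cds", "CDS"),
    mk_genes(plant_feature_track(gaps, cfg$trna_per_mb[["gap"]] / 1000, cfg$trna_len),
             "trna", "tRNA"),
    mk_genes(plant_feature_track(nongap, cfg$trna_per_mb[["nongap"]] / 1000, cfg$trna_len),
             "trna", "tRNA"),
    mk_genes(plant_feature_track(gaps, cfg$rrna_per_mb[["gap"]] / 1000, cfg$rrna_len),
             "rrna", "rRNA"),
    mk_genes(plant_feature_track(nongap, cfg$rrna_per_mb[["nongap"]] / 1000, cfg$rrna_len),
             "rrna", "rRNA"))
  ## background ncRNAs outside gaps: a 21U fraction scattered genome-wide
  nc_bg <- plant_feature_track(
    nongap, cfg$ncrna_per_mb[["nongap"]] / 1000,
    function(n) 21 + stats::rgeom(n, 1 / (1 + cfg$ncrna_extra_len_mean)))
  if (nrow(nc_bg) > 0) {
    u21 <- runif(nrow(nc_bg)) < cfg$ncrna_21u_frac_nongap
    p21 <- nc_bg[u21, ]
    if (nrow(p21) > 0) p21$end <- p21$start + cfg$pirna_len
    g <- c(g, list(mk_genes(p21, "21ur-b", "ncRNA", TRUE),
                   mk_genes(nc_bg[!u21, ], "ncb", "ncRNA")))
  }
  ## background ncRNAs inside gaps: none are 21U
  g <- c(g, list(
    mk_genes(plant_feature_track(
      gaps, cfg$ncrna_per_mb[["gap"]] / 1000,
      function(n) 21 + stats::rgeom(n, 1 / (1 + cfg$ncrna_extra_len_mean))),
      "ncg", "ncRNA")))
  ## the piRNA cluster: an exact count of 21 bp 21U genes
  cl_start <- floor(runif(cfg$cluster_n_pirna, cfg$cluster_span[1],
                          cfg$cluster_span[2] - cfg$pirna_len + 1))
  g <- c(g, list(mk_genes(
    tibble(chrom = cfg$cluster_chrom, start = cl_start,
           end = cl_start + cfg$pirna_len),
    "21ur-c", "ncRNA", TRUE)))
  genes <- bind_rows(g) %>%
    select("gene_id", "chrom", "start", "end", "category", "is_21u") %>%
    arrange(.data$chrom, .data$start, .data$gene_id)

  ## -- truth: planted quantities and analytic expectations ---------------
  gap_bp <- gi_total_bp(gaps)
  gap_mb <- gap_bp / 1e6
  exp_lib <- function(clone_tbl, col) {
    ov <- overlap_join(clone_tbl, pieces)
    per <- ov %>%
      mutate(ebp = (.data$end - .data$start) * .data[[col]]) %>%
      group_by(.data$clone_id) %>%
      summarise(ebp = sum(.data$ebp), .groups = "drop") %>%
      left_join(tibble(clone_id = clone_tbl$clone_id,
                       len = clone_tbl$end - clone_tbl$start),
                by = "clone_id")
    mean(100 * per$ebp / per$len)
  }
  gap_clones <- mutate(gaps, clone_id = sprintf("gap%03d", row_number()))
  exp_masked_yac <- exp_lib(gap_clones, "cov_all")
  exp_masked_cosmid <- exp_lib(cosmid_tbl, "cov_all")
  exp_dna_yac <- exp_lib(gap_clones, "cov_dna")
  exp_dna_cosmid <- exp_lib(cosmid_tbl, "cov_dna")
  yac_all <- bind_rows(yac_tbl, cov_tbl)
  realized_overlap <- 1 - gi_overlap_fraction(yac_all, gaps)
  exp_yac_ncrna <- (cfg$cluster_n_pirna + cfg$ncrna_per_mb[["gap"]] * gap_mb) / gap_mb
  exp_cos_ncrna <- cfg$ncrna_per_mb[["nongap"]]
  exp_yac_21u <- cfg$cluster_n_pirna / gap_mb
  exp_cos_21u <- cfg$ncrna_per_mb[["nongap"]] * cfg$ncrna_21u_frac_nongap
  truth <- list(
    seed = cfg$seed,
    n_gaps = nrow(gaps),
    gap_bp = gap_bp,
    n_yacs = nrow(yac_all),
    n_cosmids = nrow(cosmid_tbl),
    n_fosmids = nrow(fosmid_tbl),
    target_mean_overlap = cfg$yac_overlap_mean,
    realized_mean_overlap = mean(realized_overlap),
    realized_mean_overlap_bridging = mean(realized_overlap[realized_overlap < 1]),
    cluster_chrom = cfg$cluster_chrom,
    cluster_start = cfg$cluster_span[1],
    cluster_end = cfg$cluster_span[2],
    cluster_n_pirna = cfg$cluster_n_pirna,
    expected_masked_pct_yac = exp_masked_yac,
    expected_masked_pct_cosmid = exp_masked_cosmid,
    expected_masked_ratio = exp_masked_yac / exp_masked_cosmid,
    expected_dna_pct_yac = exp_dna_yac,
    expected_dna_pct_cosmid = exp_dna_cosmid,
    expected_dna_ratio = exp_dna_yac / exp_dna_cosmid,
    expected_yac_ncrna_per_mb = exp_yac_ncrna,
    expected_cosmid_ncrna_per_mb = exp_cos_ncrna,
    expected_ncrna_density_ratio = exp_yac_ncrna / exp_cos_ncrna,
    expected_pirna_density_ratio = exp_yac_21u / exp_cos_21u)

  list(sizes = sizes, clones = clones, repeats = repeats, genes = genes,
       gaps = gaps, cluster = cluster, truth = truth, pieces = pieces)
}

write_bundle <- function(bundle, cfg, outdir, write_fasta) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- list()
  files$chrom_sizes <- file.path(outdir, "chrom.sizes")
  writeLines(sprintf("%s\t%d", bundle$sizes$chrom,
                     as.integer(bundle$sizes$length)),
             files$chrom_sizes)
  files$clones <- file.path(outdir, "clones.tsv")
  writeLines(c("# chrom\tstart\tend\tclone_id\tclone_type",
               sprintf("%s\t%d\t%d\t%s\t%s", bundle$clones$chrom,
                       as.integer(bundle$clones$start),
                       as.integer(bundle$clones$end),
                       bundle$clones$clone_id, bundle$clones$clone_type)),
             files$clones)
  files$repeats <- file.path(outdir, "repeats.out")
  write_repeatmasker_out(bundle$repeats, files$repeats)
  files$genes <- file.path(outdir, "genes.gff3")
  write_gff3_genes(bundle$genes, files$genes)
  files$gaps <- file.path(outdir, "gaps.tsv")
  writeLines(c("# truth: planted gap regions (chrom\tstart\tend)",
               sprintf("%s\t%d\t%d", bundle$gaps$chrom,
                       as.integer(bundle$gaps$start),
                       as.integer(bundle$gaps$end))),
             files$gaps)
  files$cluster <- file.path(outdir, "cluster.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s", bundle$cluster$chrom,
                     as.integer(bundle$cluster$start),
                     as.integer(bundle$cluster$end), bundle$cluster$name),
             files$cluster)
  files$truth <- file.path(outdir, "truth.tsv")
  tr <- bundle$truth
  vals <- vapply(tr, function(v) {
    if (is.numeric(v)) sprintf("%.10g", v) else as.character(v)
  }, character(1))
  writeLines(c("key\tvalue", paste(names(tr), vals, sep = "\t")), files$truth)
  if (write_fasta) {
    files$fasta <- file.path(outdir, "genome.fa")
    con <- file(files$fasta, open = "wt")
    for (i in seq_len(nrow(bundle$sizes))) {
      writeLines(paste0(">", bundle$sizes$chrom[i]), con)
      n <- bundle$sizes$length[i]
      # sequence content is irrelevant to the pipeline; fixed-stream bases
      bases <- withr::with_seed(cfg$seed + i, {
        sample(c("A", "C", "G", "T"), n, replace = TRUE)
      })
      writeLines(substring(paste(bases, collapse = ""),
                           seq(1, n, 70), pmin(seq(1, n, 70) + 69, n)), con)
    }
    close(con)
  }
  files
}

## write gene records as GFF3 (1-based inclusive at the boundary)
write_gff3_genes <- function(genes, path) {
  type <- case_when(
    genes$category == "CDS" ~ "gene",
    genes$category == "ncRNA" & genes$is_21u ~ "piRNA",
    genes$category == "ncRNA" ~ "ncRNA",
    TRUE ~ genes$category)
  bio <- case_when(
    genes$category == "CDS" ~ "protein_coding",
    genes$category == "ncRNA" & genes$is_21u ~ "piRNA",
    genes$category == "ncRNA" ~ "ncRNA",
    TRUE ~ genes$category)
  lines <- sprintf("%s\tsynth\t%s\t%d\t%d\t.\t+\t.\tID=%s;biotype=%s",
                   genes$chrom, type, as.integer(genes$start + 1),
                   as.integer(genes$end), genes$gene_id, bio)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
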