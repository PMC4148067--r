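stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  })
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9176) %% 2147483647)
}

#' Run the full clone-library comparison pipeline
#'
#' Executes every stage of the analysis on one set of input files:
#' trimming YACs against finished sequence, per-library repeat profiling
#' (real libraries plus matched random controls and enrichment tests),
#' chromosome-quarter and clone-length stratification with Welch t-tests,
#' location histograms, and gene/21U analyses (densities, composition,
#' chromosome exclusion, cluster repetitiveness, longest segments). All
#' reports are written as TSV under `outdir` together with a JSON
#' manifest of input digests and parameters; a rerun with identical
#' inputs and seed is byte-identical.
#'
#' @param chrom_sizes,clones,repeats,genes Paths to the four inputs
#'   (chrom.sizes, 5-column clone TSV, RepeatMasker `.out`, GFF3).
#' @param outdir Output directory.
#' @param seed Integer seed driving the random-control libraries.
#' @param replicates Random libraries per enrichment test.
#' @param clusters Optional BED of named cluster regions to score for
#'   repetitiveness.
#' @param exclude_chrom Optional chromosome excluded in the ncRNA
#'   re-ratio analysis (e.g. the piRNA-cluster chromosome).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all result tables and the manifest.
#' @export
run_clonability <- function(chrom_sizes, clones, repeats, genes, outdir,
                            seed = 1L, replicates = 100L, clusters = NULL,
                            exclude_chrom = NULL, quiet = FALSE) {
  inputs <- c(chrom_sizes = chrom_sizes, clones = clones,
              repeats = repeats, genes = genes,
              if (!is.null(clusters)) c(clusters = clusters))
  for (nm in names(inputs)) {
    if (!file.exists(inputs[[nm]])) {
      abort(paste0("input file for '", nm, "' not found: ", inputs[[nm]]))
    }
  }
  say <- function(...) if (!quiet) message(...)

  say("reading inputs")
  sizes <- stage("read", read_chrom_sizes(chrom_sizes))
  clone_tbl <- stage("read", read_clone_table(clones, sizes))
  rep_tbl <- stage("read", read_repeatmasker_out(repeats))
  gene_tbl <- stage("read", read_gff3_genes(genes))

  say("trimming YACs against finished sequence")
  finished <- filter(clone_tbl, .data$clone_type %in% c("cosmid", "fosmid"))
  yacs <- filter(clone_tbl, .data$clone_type == "yac")
  trim <- stage("trim", derive_exclusive(yacs, finished))
  libraries <- list(
    cosmid = filter(clone_tbl, .data$clone_type == "cosmid"),
    fosmid = filter(clone_tbl, .data$clone_type == "fosmid"),
    yac = trim$exclusive)
  libraries <- libraries[vapply(libraries, nrow, 0L) > 0]

  say("profiling repeat content per library")
  profiles <- stage("profile", purrr::map(libraries, profile_clones, rep_tbl))
  summaries <- purrr::imap(profiles, function(p, nm) summarize_library(p, nm))
  table1 <- stage("profile", bind_rows(purrr::imap(summaries, function(s, nm) {
    mutate(tidy(s), library = nm, n_clones = s$n_clones, total_bp = s$total_bp)
  })) %>% select("library", "n_clones", "total_bp", everything()))

  say("profiling matched random control libraries")
  controls <- stage("controls", bind_rows(purrr::imap(libraries, function(lib, nm) {
    model <- fit_length_model(lib)
    rand <- sample_random_library(sizes, model,
                                  seed = derive_seed(seed, match(nm, names(libraries))))
    s <- summarize_library(profile_clones(rand, rep_tbl), paste0("random_", nm))
    mutate(tidy(s), library = paste0("random_", nm),
           n_clones = s$n_clones, total_bp = s$total_bp)
  })) %>% select("library", "n_clones", "total_bp", everything()))

  say("enrichment tests against resampling nulls")
  masked_stat <- function(cl) {
    library_mean_pct(profile_clones(cl, rep_tbl), "Bases_masked")
  }
  dna_stat <- function(cl) {
    library_mean_pct(profile_clones(cl, rep_tbl), "DNA_transposons")
  }
  enrich <- stage("nulltest", bind_rows(
    mutate(glance(enrichment_test(trim$exclusive, masked_stat, sizes,
                                  replicates = replicates,
                                  seed = derive_seed(seed, 101))),
           statistic = "yac_masked_pct"),
    mutate(glance(enrichment_test(trim$exclusive, dna_stat, sizes,
                                  replicates = replicates,
                                  seed = derive_seed(seed, 102))),
           statistic = "yac_dna_pct")) %>%
      select("statistic", everything(), -"seed", -"alternative"))

  say("stratifying by chromosome quarter and clone length")
  strat <- stage("stratify", {
    masked <- function(p) filter(p, .data$category == "Bases_masked")
    both <- bind_rows(
      mutate(locate_quartile(libraries$cosmid, sizes), library = "cosmid"),
      mutate(locate_quartile(libraries$yac, sizes), library = "yac"))
    bymask <- both %>%
      left_join(bind_rows(purrr::imap(
        profiles[c("cosmid", "yac")],
        function(p, nm) mutate(masked(p), library = nm))),
        by = c("clone_id", "library")) %>%
      select("library", "clone_id", "quartile", "pct")
    cells <- bymask %>%
      group_by(.data$library, .data$quartile) %>%
      summarise(n_clones = n(), mean_masked_pct = mean(.data$pct),
                .groups = "drop")
    tt_loc <- welch_t(bymask$pct[bymask$quartile == "extreme"],
                      bymask$pct[bymask$quartile == "middle"])
    tt_lib <- welch_t(bymask$pct[bymask$library == "yac"],
                      bymask$pct[bymask$library == "cosmid"])
    list(cells = cells,
         tests = bind_rows(
           mutate(tt_loc, comparison = "extreme_vs_middle"),
           mutate(tt_lib, comparison = "yac_vs_cosmid")) %>%
           select("comparison", everything()),
         bymask = bymask)
  })
  lenstrat <- stage("stratify", bind_rows(purrr::imap(
    profiles[intersect(c("cosmid", "yac"), names(profiles))],
    function(p, nm) {
      lib <- split_by_median_length(libraries[[nm]])
      p %>%
        filter(.data$category == "Bases_masked") %>%
        left_join(select(lib, "clone_id", "length_group"), by = "clone_id") %>%
        group_by(.data$length_group) %>%
        summarise(n_clones = n(), mean_masked_pct = mean(.data$pct),
                  .groups = "drop") %>%
        mutate(library = nm, median_length = attr(lib, "median_length")) %>%
        select("library", "median_length", everything())
    })))
  hists <- stage("stratify", purrr::imap(
    libraries[intersect(c("cosmid", "yac"), names(libraries))],
    function(lib, nm) location_histogram(lib, sizes)))

  say("gene content per library")
  genes_out <- stage("genes", {
    assigned <- assign_genes_to_library(
      gene_tbl, bind_rows(purrr::imap(libraries, ~ mutate(.x, library = .y))))
    lib_bp <- purrr::imap(libraries, ~ gi_total_bp(.x))
    table2 <- assigned %>%
      filter(!is.na(.data$library)) %>%
      group_by(.data$library, .data$category) %>%
      gene_length_stats() %>%
      left_join(tibble(library = names(lib_bp),
                       coverage_bp = unlist(lib_bp)), by = "library") %>%
      mutate(per_mb = density_per_mb(.data$n, .data$coverage_bp))
    comp <- assigned %>%
      filter(!is.na(.data$library), .data$category == "ncRNA") %>%
      group_by(.data$library) %>%
      summarise(n_ncrna = n(), n_21u = sum(.data$is_21u), .groups = "drop") %>%
      mutate(pct_21u = composition_fraction(.data$n_21u, .data$n_ncrna))
    by_chrom <- assigned %>%
      filter(!is.na(.data$library), .data$category == "ncRNA") %>%
      count(.data$chrom, .data$library, name = "count")
    excl <- if (!is.null(exclude_chrom)) {
      cov_by_chrom <- bind_rows(purrr::imap(libraries, function(lib, nm) {
        gi_merge(lib) %>%
          group_by(.data$chrom) %>%
          summarise(coverage_bp = sum(.data$end - .data$start),
                    .groups = "drop") %>%
          mutate(library = nm)
      }))
      ratios <- left_join(
        tidyr::complete(by_chrom, chrom = unique(cov_by_chrom$chrom),
                        library = names(libraries), fill = list(count = 0L)),
        cov_by_chrom, by = c("chrom", "library")) %>%
        mutate(coverage_bp = dplyr::coalesce(.data$coverage_bp, 0))
      # an empty dummy chromosome lets the same code path report the
      # all-chromosome totals
      dummy <- tibble(chrom = ".none", library = names(libraries),
                      count = 0L, coverage_bp = 0)
      bind_rows(
        exclude_chromosome(bind_rows(ratios, dummy), ".none") %>%
          mutate(analysis = "all_chromosomes", excluded_chrom = NA_character_),
        exclude_chromosome(ratios, exclude_chrom) %>%
          mutate(analysis = paste0("excluding_", exclude_chrom))) %>%
        select("analysis", everything())
    } else NULL
    longest <- trim$exclusive %>%
      mutate(length_kb = (.data$end - .data$start) / 1000) %>%
      arrange(dplyr::desc(.data$length_kb)) %>%
      head(15) %>%
      select("clone_id", "parent_id", "chrom", "start", "end", "length_kb")
    cluster_rep <- if (!is.null(clusters)) {
      regs <- readr::read_tsv(clusters, comment = "#",
                              col_names = c("chrom", "start", "end", "name"),
                              col_types = "cddc", progress = FALSE)
      chrom_regs <- tibble(chrom = sizes$chrom, start = 0, end = sizes$length,
                           name = paste0("whole_", sizes$chrom))
      region_masked_pct(bind_rows(regs, chrom_regs), rep_tbl) %>%
        select("name", "chrom", "start", "end", "masked_pct")
    } else NULL
    list(table2 = ungroup(table2), composition = comp, by_chrom = by_chrom,
         exclusion = excl, longest = longest, cluster_rep = cluster_rep)
  })

  say("writing reports")
  tables <- list(
    overlap_stats = tidy(trim),
    trim_summary = glance(trim),
    table1_repeats = table1,
    random_controls = controls,
    enrichment = enrich,
    stratify_quartile = strat$cells,
    stratify_tests = strat$tests,
    stratify_length = lenstrat,
    histogram_cosmid = as_tibble(hists$cosmid),
    histogram_yac = as_tibble(hists$yac),
    table2_genes = genes_out$table2,
    gene_composition = genes_out$composition,
    ncrna_by_chrom = genes_out$by_chrom,
    table3_longest = genes_out$longest)
  if (!is.null(genes_out$exclusion)) tables$chrom_exclusion <- genes_out$exclusion
  if (!is.null(genes_out$cluster_rep)) tables$cluster_masked <- genes_out$cluster_rep
  paths <- write_report(tables, outdir)

  manifest <- list(
    tool = "clonability",
    version = as.character(utils::packageVersion("clonability")),
    seed = as.integer(seed),
    replicates = as.integer(replicates),
    exclude_chrom = exclude_chrom,
    inputs = lapply(as.list(inputs), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    reports = basename(paths))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done")
  invisible(c(tables, list(manifest = manifest, trim = trim,
                           summaries = summaries)))
}
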