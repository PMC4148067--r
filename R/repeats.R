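repeat_categories <- c("Retroelements", "DNA_transposons", "Rolling_circles",
                       "Unclassified", "Small_RNA", "Satellites",
                       "Simple_repeats", "Low_complexity")

interspersed_categories <- c("Retroelements", "DNA_transposons",
                             "Rolling_circles", "Unclassified")

#' Map RepeatMasker class/family strings to summary categories
#'
#' Deterministic mapping of the `class/family` column onto the top-level
#' rows of a per-library repeat summary: `LINE`/`SINE`/`LTR` prefixes are
#' Retroelements, `DNA` is DNA_transposons (with the text after `/` as
#' subclass, e.g. PiggyBac), `RC` is Rolling_circles,
#' `Unknown`/`Unspecified` are Unclassified, the small structural RNA
#' classes (`snRNA`, `tRNA`, `rRNA`, `scRNA`, `srpRNA`) are Small_RNA, and
#' `Satellite`, `Simple_repeat`, `Low_complexity` map to themselves. Any
#' unrecognized class is kept as Unclassified with a warning (never
#' dropped).
#'
#' @param repeat_class Character vector of class/family strings.
#' @return Tibble with columns `category` and `subclass` (NA when the
#'   class string has no `/` part), one row per input element.
#' @examples
#' classify_repeat(c("DNA/PiggyBac", "LINE/CR1", "Low_complexity"))
#' @export
classify_repeat <- function(repeat_class) {
  top <- sub("/.*$", "", repeat_class)
  subclass <- ifelse(grepl("/", repeat_class, fixed = TRUE),
                     sub("^[^/]*/", "", repeat_class), NA_character_)
  category <- case_when(
    top %in% c("LINE", "SINE", "LTR") ~ "Retroelements",
    top == "DNA" ~ "DNA_transposons",
    top == "RC" ~ "Rolling_circles",
    top %in% c("Unknown", "Unspecified") ~ "Unclassified",
    top %in% c("snRNA", "tRNA", "rRNA", "scRNA", "srpRNA") ~ "Small_RNA",
    top == "Satellite" ~ "Satellites",
    top == "Simple_repeat" ~ "Simple_repeats",
    top == "Low_complexity" ~ "Low_complexity",
    TRUE ~ NA_character_)
  if (anyNA(category)) {
    unknown <- unique(repeat_class[is.na(category)])
    warn(paste0("unmapped repeat class(es) treated as Unclassified: ",
                paste(unknown, collapse = ", ")))
    category[is.na(category)] <- "Unclassified"
  }
  tibble(category = category, subclass = subclass)
}

## union of [start, end) spans within groups; df needs group cols + start/end
union_bp_by <- function(df, groups) {
  if (nrow(df) == 0) {
    out <- df[, groups, drop = FALSE]
    out$bp <- numeric(0)
    return(as_tibble(out))
  }
  df %>%
    group_by(across(all_of(groups))) %>%
    arrange(.data$start, .data$end, .by_group = TRUE) %>%
    mutate(.prev = lag(cummax(.data$end)),
           .run = cumsum(is.na(.data$.prev) | .data$start > .data$.prev)) %>%
    group_by(across(all_of(c(groups, ".run")))) %>%
    summarise(.bp = max(.data$end) - min(.data$start), .groups = "drop") %>%
    group_by(across(all_of(groups))) %>%
    summarise(bp = sum(.data$.bp), .groups = "drop")
}

#' Profile the repeat content of each clone
#'
#' For every clone, computes per repeat category the number of overlapping
#' annotation rows (an element overlapping by a single base counts, with
#' its span clipped to the clone), the bases occupied (per-base union
#' within the category), and the percentage of the clone sequence. Two
#' summary rows are appended per clone: `Bases_masked` (union across all
#' categories) and `Total_interspersed` (union across retroelements, DNA
#' transposons, rolling-circles and unclassified interspersed repeats,
#' i.e. excluding small RNA, satellites, simple repeats and low
#' complexity).
#'
#' @param clones Clone table (`chrom`, `start`, `end`, `clone_id`).
#' @param repeats Repeat annotation table from [read_repeatmasker_out()].
#' @return Long tibble with one row per clone and category:
#'   `clone_id`, `length`, `category`, `n_elements`, `bp`, `pct`.
#' @export
profile_clones <- function(clones, repeats) {
  clones <- validate_intervals(clones, what = "clone record")
  if (anyDuplicated(clones$clone_id)) {
    abort("profile_clones: duplicate clone_id in clone table")
  }
  repeats <- validate_intervals(repeats, what = "repeat annotation")
  repeats$category <- classify_repeat(repeats$repeat_class)$category

  hits <- overlap_join(clones, repeats)
  n_tbl <- hits %>% count(.data$clone_id, .data$category, name = "n_elements")
  bp_tbl <- union_bp_by(hits, c("clone_id", "category"))
  masked <- union_bp_by(hits, "clone_id") %>%
    mutate(category = "Bases_masked") %>%
    left_join(count(hits, .data$clone_id, name = "n_elements"), by = "clone_id")
  intersp <- hits %>%
    filter(.data$category %in% interspersed_categories)
  intersp_bp <- union_bp_by(intersp, "clone_id") %>%
    mutate(category = "Total_interspersed") %>%
    left_join(count(intersp, .data$clone_id, name = "n_elements"),
              by = "clone_id")

  grid <- tidyr::expand_grid(
    clone_id = clones$clone_id,
    category = c(repeat_categories, "Bases_masked", "Total_interspersed"))
  per_cat <- left_join(n_tbl, bp_tbl, by = c("clone_id", "category"))
  out <- grid %>%
    left_join(bind_rows(per_cat, masked, intersp_bp),
              by = c("clone_id", "category")) %>%
    mutate(n_elements = dplyr::coalesce(.data$n_elements, 0L),
           bp = dplyr::coalesce(.data$bp, 0)) %>%
    left_join(tibble(clone_id = clones$clone_id,
                     length = clones$end - clones$start),
              by = "clone_id") %>%
    mutate(pct = 100 * .data$bp / .data$length) %>%
    select("clone_id", "length", "category", "n_elements", "bp", "pct")
  out$category <- factor(out$category,
                         levels = c(repeat_categories, "Bases_masked",
                                    "Total_interspersed"))
  arrange(out, match(.data$clone_id, clones$clone_id), .data$category)
}

## clip annotations to overlapping clones; returns one row per (clone, hit)
overlap_join <- function(clones, feats) {
  out <- vector("list", 0)
  for (chr in unique(clones$chrom)) {
    ci <- which(clones$chrom == chr)
    fi <- which(feats$chrom == chr)
    if (length(fi) == 0) next
    qr <- IRanges::IRanges(clones$start[ci] + 1, clones$end[ci])
    fr <- IRanges::IRanges(feats$start[fi] + 1, feats$end[fi])
    h <- IRanges::findOverlaps(qr, fr)
    if (length(h) == 0) next
    qi <- ci[S4Vectors::queryHits(h)]
    si <- fi[S4Vectors::subjectHits(h)]
    piece <- feats[si, setdiff(names(feats), c("chrom", "start", "end"))]
    piece$clone_id <- clones$clone_id[qi]
    piece$start <- pmax(feats$start[si], clones$start[qi])
    piece$end <- pmin(feats$end[si], clones$end[qi])
    out[[length(out) + 1]] <- piece
  }
  if (length(out) == 0) {
    return(tibble(clone_id = character(), category = character(),
                  start = numeric(), end = numeric()))
  }
  bind_rows(out)
}

#' Summarize clone repeat profiles into a library-level table
#'
#' Aggregates per-clone profiles across a clone library, reporting for
#' each category and field (element count, bp occupied, percent of
#' sequence) the mean, median, minimum, maximum and the mean over clones
#' with a strictly positive value ("non-zero mean").
#'
#' @param profiles Long profile tibble from [profile_clones()].
#' @param library Optional library name stored in the result.
#' @return An object of class `repeat_library_summary`: [tidy()] gives
#'   the per-category statistics table, [glance()] the clone count and
#'   total coverage (sum of clone lengths; exclusive segments within a
#'   library are disjoint after trimming).
#' @export
summarize_library <- function(profiles, library = NA_character_) {
  clones <- distinct(profiles, .data$clone_id, .data$length)
  if (nrow(clones) == 0) abort("summarize_library: empty library")
  nzmean <- function(x) if (any(x > 0)) mean(x[x > 0]) else 0
  stats <- profiles %>%
    tidyr::pivot_longer(c("n_elements", "bp", "pct"),
                        names_to = "field", values_to = "value") %>%
    group_by(.data$category, .data$field) %>%
    summarise(mean = mean(.data$value), median = median(.data$value),
              min = min(.data$value), max = max(.data$value),
              nonzero_mean = nzmean(.data$value), .groups = "drop")
  structure(list(stats = stats, library = library,
                 n_clones = nrow(clones), total_bp = sum(clones$length)),
            class = "repeat_library_summary")
}

#' @export
print.repeat_library_summary <- function(x, ...) {
  cat(sprintf("Repeat library summary%s: %d clones, %s bp total coverage\n",
              if (is.na(x$library)) "" else paste0(" (", x$library, ")"),
              x$n_clones, format(x$total_bp, big.mark = ",")))
  print(tidyr::pivot_wider(
    filter(x$stats, .data$field == "pct"),
    names_from = "field", values_from = c("mean", "median", "max")), ...)
  invisible(x)
}

#' @rdname summarize_library
#' @param x A `repeat_library_summary`.
#' @param ... Unused.
#' @method tidy repeat_library_summary
#' @export
tidy.repeat_library_summary <- function(x, ...) {
  x$stats
}

#' @rdname summarize_library
#' @method glance repeat_library_summary
#' @export
glance.repeat_library_summary <- function(x, ...) {
  masked <- filter(x$stats, .data$category == "Bases_masked",
                   .data$field == "pct")
  tibble(library = x$library, n_clones = x$n_clones, total_bp = x$total_bp,
         mean_masked_pct = masked$mean)
}

#' Mean percent of clone sequence in one category of a summary
#'
#' Convenience accessor for the per-clone mean "percentage of sequence"
#' of one category (e.g. `"Bases_masked"`, `"DNA_transposons"`).
#'
#' @param summary A `repeat_library_summary` or the tidy profile tibble.
#' @param category Category name.
#' @return A single number (mean percent across clones).
#' @export
library_mean_pct <- function(summary, category) {
  if (inherits(summary, "repeat_library_summary") ||
      "field" %in% names(summary)) {
    stats <- if (inherits(summary, "repeat_library_summary")) summary$stats
             else summary
    row <- filter(stats, .data$category == .env$category, .data$field == "pct")
    if (nrow(row) == 0) abort(paste0("no category '", category, "' in summary"))
    return(row$mean)
  }
  pct <- summary$pct[summary$category == category]
  if (length(pct) == 0) abort(paste0("no category '", category, "' in profile"))
  mean(pct)
}
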