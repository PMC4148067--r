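#' Derive YAC-exclusive segments by trimming finished-sequence overlap
#'
#' YACs bridge genomic regions that no cosmid or fosmid could recover, and
#' their ends typically overlap finished (bacteria-clonable) sequence by
#' a few percent. This removes every base of each YAC that is covered by
#' the merged cosmid/fosmid set, keeping the remaining maximal
#' sub-intervals as "YAC-exclusive" segments attributed to their parent
#' YAC. A YAC covered in its middle yields multiple exclusive pieces, all
#' retained. YACs completely covered by finished sequence yield no pieces
#' and are reported in the fully-covered list.
#'
#' @param yacs Clone table of YACs (`chrom`, `start`, `end`, `clone_id`).
#' @param finished Clone table of cosmids and fosmids (may be empty).
#' @return An object of class `yac_trim` with elements:
#'   * `exclusive`: tibble of exclusive pieces (`chrom`, `start`, `end`,
#'     `clone_id`, `clone_type = "yac"`, `parent_id`);
#'   * `overlap`: per-YAC tibble (`clone_id`, `length`,
#'     `overlap_fraction`, `n_pieces`, `fully_covered`).
#'   [tidy()] returns the per-YAC table, [glance()] the library-level
#'   summary (mean overlap fraction, fully-covered count, etc.).
#' @examples
#' yac <- gi_intervals("chrI", 0, 100, clone_id = "Y1", clone_type = "yac")
#' cos <- gi_intervals("chrI", c(0, 90), c(10, 100),
#'                     clone_id = c("C1", "C2"), clone_type = "cosmid")
#' trim <- derive_exclusive(yac, cos)
#' trim$exclusive
#' glance(trim)
#' @export
derive_exclusive <- function(yacs, finished) {
  yacs <- validate_intervals(yacs, what = "YAC record")
  if (anyDuplicated(yacs$clone_id)) {
    abort(sprintf("duplicate YAC clone_id '%s'",
                  yacs$clone_id[anyDuplicated(yacs$clone_id)]))
  }
  fin <- if (nrow(finished) > 0) gi_merge(finished) else empty_intervals()
  ovfrac <- gi_overlap_fraction(yacs, fin)

  pieces <- purrr::map(seq_len(nrow(yacs)), function(i) {
    res <- gi_subtract(yacs[i, c("chrom", "start", "end")], fin)
    if (nrow(res) == 0) return(NULL)
    res$parent_id <- yacs$clone_id[i]
    res
  })
  pieces <- bind_rows(pieces)
  if (nrow(pieces) == 0) {
    pieces <- tibble(chrom = character(), start = numeric(), end = numeric(),
                     parent_id = character())
  }
  pieces <- pieces %>%
    group_by(.data$parent_id) %>%
    mutate(clone_id = if (n() == 1) .data$parent_id
           else paste0(.data$parent_id, ".", row_number())) %>%
    ungroup() %>%
    mutate(clone_type = "yac") %>%
    select("chrom", "start", "end", "clone_id", "clone_type", "parent_id")

  npieces <- table(pieces$parent_id)
  overlap <- tibble(
    clone_id = yacs$clone_id,
    length = yacs$end - yacs$start,
    overlap_fraction = ovfrac,
    n_pieces = as.integer(ifelse(yacs$clone_id %in% names(npieces),
                                 npieces[yacs$clone_id], 0L)),
    fully_covered = ovfrac >= 1)
  structure(list(exclusive = pieces, overlap = overlap), class = "yac_trim")
}

#' @export
print.yac_trim <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "YAC trimming: %d YACs, %d with exclusive pieces (%d pieces), %d fully covered\n",
    g$n_yacs, g$n_with_pieces, nrow(x$exclusive), g$n_fully_covered))
  cat(sprintf("mean overlap fraction with finished sequence: %.4f\n",
              g$mean_overlap_fraction))
  invisible(x)
}

#' @rdname derive_exclusive
#' @param x A `yac_trim` object.
#' @param ... Unused.
#' @method tidy yac_trim
#' @export
tidy.yac_trim <- function(x, ...) {
  x$overlap
}

#' @rdname derive_exclusive
#' @method glance yac_trim
#' @export
glance.yac_trim <- function(x, ...) {
  tibble(
    n_yacs = nrow(x$overlap),
    n_with_pieces = sum(x$overlap$n_pieces > 0),
    n_fully_covered = sum(x$overlap$fully_covered),
    mean_overlap_fraction = mean(x$overlap$overlap_fraction),
    exclusive_bp = sum(x$exclusive$end - x$exclusive$start),
    fully_covered_ids = paste(x$overlap$clone_id[x$overlap$fully_covered],
                              collapse = ","))
}
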