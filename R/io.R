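#' Read a chromosome sizes table
#'
#' UCSC-style `chrom.sizes`: two whitespace-separated columns, chromosome
#' name and length in bp. Duplicate chromosomes and non-integer lengths
#' are rejected with the offending line number.
#'
#' @param path Path to the file.
#' @return Tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  keep <- which(trimws(lines) != "")
  if (length(keep) == 0) {
    warn(paste0("empty chrom.sizes file: ", path))
    return(tibble(chrom = character(), length = numeric()))
  }
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  out <- tibble(chrom = character(length(keep)), length = numeric(length(keep)))
  seen <- character()
  for (i in seq_along(keep)) {
    f <- fields[[i]]
    if (length(f) != 2) {
      abort(sprintf("chrom.sizes line %d: expected 2 fields, got %d", keep[i], length(f)))
    }
    len <- suppressWarnings(as.numeric(f[2]))
    if (is.na(len) || len != round(len) || len <= 0) {
      abort(sprintf("chrom.sizes line %d: non-integer or non-positive length '%s'", keep[i], f[2]))
    }
    if (f[1] %in% seen) {
      abort(sprintf("chrom.sizes line %d: duplicate chromosome '%s'", keep[i], f[1]))
    }
    seen <- c(seen, f[1])
    out$chrom[i] <- f[1]
    out$length[i] <- len
  }
  out
}

clone_types <- c("cosmid", "fosmid", "yac")

#' Read a clone placement table
#'
#' BED-like TSV with five columns: `chrom`, `start` (0-based), `end`
#' (exclusive), `clone_id`, `clone_type`. Clone types are matched
#' case-insensitively against cosmid / fosmid / yac. Lines starting with
#' `#` are skipped. When a sizes table is given, intervals beyond the
#' chromosome end (or on unknown chromosomes) are rejected.
#'
#' @param path Path to the TSV.
#' @param sizes Optional tibble from [read_chrom_sizes()] for validation.
#' @return Tibble with `chrom`, `start`, `end`, `clone_id`, `clone_type`.
#' @export
read_clone_table <- function(path, sizes = NULL) {
  x <- readr::read_tsv(path, comment = "#",
                       col_names = c("chrom", "start", "end", "clone_id", "clone_type"),
                       col_types = "cddcc", progress = FALSE)
  x$clone_type <- tolower(x$clone_type)
  bad <- which(!x$clone_type %in% clone_types)
  if (length(bad) > 0) {
    abort(sprintf("clone table row %d: unknown clone_type '%s' (expected cosmid/fosmid/yac)",
                  bad[1], x$clone_type[bad[1]]))
  }
  x <- validate_intervals(x, what = "clone record")
  if (!is.null(sizes)) {
    x2 <- left_join(x, sizes, by = "chrom")
    bad <- which(is.na(x2$length) | x2$end > x2$length)
    if (length(bad) > 0) {
      i <- bad[1]
      abort(sprintf("clone table row %d: clone '%s' exceeds chromosome '%s' bounds",
                    i, x$clone_id[i], x$chrom[i]))
    }
  }
  x
}

#' Read RepeatMasker `.out` annotations
#'
#' Parses the standard `.out` layout: three header lines, then
#' whitespace-separated data lines with SW score, divergence columns, the
#' query sequence and 1-based inclusive query coordinates, strand (`+` or
#' `C`, ignored), repeat name and class/family. A trailing `*` column is
#' accepted. Coordinates are converted to 0-based half-open.
#'
#' @param path Path to the `.out` file.
#' @return Tibble with `chrom`, `start`, `end`, `repeat_name`,
#'   `repeat_class`, `score`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) <= 3) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  repeat_name = character(), repeat_class = character(),
                  score = numeric()))
  }
  data_idx <- seq(4, length(lines))
  data_idx <- data_idx[trimws(lines[data_idx]) != ""]
  n <- length(data_idx)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    i <- data_idx[k]
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 11) {
      abort(sprintf("RepeatMasker .out line %d: expected >= 11 columns, got %d", i, length(f)))
    }
    qbegin <- suppressWarnings(as.numeric(f[6]))
    qend <- suppressWarnings(as.numeric(f[7]))
    score <- suppressWarnings(as.numeric(f[1]))
    if (is.na(qbegin) || is.na(qend)) {
      abort(sprintf("RepeatMasker .out line %d: non-numeric query coordinates", i))
    }
    out[[k]] <- tibble(chrom = f[5], start = qbegin - 1, end = qend,
                       repeat_name = f[10], repeat_class = f[11], score = score)
  }
  validate_intervals(bind_rows(out), what = "repeat annotation")
}

#' Write RepeatMasker-style `.out` annotations
#'
#' Emits the three standard header lines followed by one whitespace-aligned
#' data line per annotation (divergence columns written as 0.0, strand
#' `+`). Round-trips through [read_repeatmasker_out()].
#'
#' @param x Tibble with `chrom`, `start`, `end`, `repeat_name`,
#'   `repeat_class` and optionally `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(x, path) {
  header <- c(
    "   SW   perc perc perc  query     position in query    matching  repeat       position in repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat    class/family begin end (left) ID",
    "")
  if (nrow(x) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  score <- if ("score" %in% names(x)) x$score else rep(1000, nrow(x))
  lines <- sprintf("%6d %4.1f %4.1f %4.1f %-10s %8d %8d (%d) + %-12s %-16s 1 %d (0) %d",
                   as.integer(score), 0, 0, 0, x$chrom,
                   as.integer(x$start + 1), as.integer(x$end), 0L,
                   x$repeat_name, x$repeat_class,
                   as.integer(x$end - x$start), seq_len(nrow(x)))
  writeLines(c(header, lines), path)
  invisible(path)
}

gff_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)\\s*", key, "=([^;]*)"), attrs))
  vapply(m, function(g) if (length(g) == 2) g[2] else NA_character_, character(1))
}

ncrna_types <- c("ncRNA", "piRNA", "snoRNA", "snRNA", "miRNA", "lincRNA")

#' Read gene records from a GFF3 file
#'
#' Extracts one record per gene-level feature and assigns each a product
#' category in `{CDS, ncRNA, tRNA, rRNA, other}`:
#' * feature types `tRNA` / `rRNA` map to themselves;
#' * `gene` features with `biotype`/`gene_biotype` `protein_coding`, or
#'   with an `mRNA`/`CDS` child, map to `CDS`;
#' * ncRNA-like feature types (`ncRNA`, `piRNA`, `snoRNA`, `snRNA`,
#'   `miRNA`, `lincRNA`) or a biotype containing "RNA" map to `ncRNA`
#'   (with `tRNA`/`rRNA` biotypes mapping to their own categories);
#' * anything else is `other`.
#'
#' 21U piRNA genes are flagged via [is_21u()] (a `21ur-` identifier or
#' `piRNA` biotype on an ncRNA gene). A `21ur-` name on a non-ncRNA
#' feature is not flagged and triggers a warning.
#'
#' @param path Path to the GFF3 file.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `category`,
#'   `is_21u` (0-based half-open coordinates).
#' @export
read_gff3_genes <- function(path) {
  lines <- readLines(path)
  idx <- which(!startsWith(lines, "#") & trimws(lines) != "")
  if (length(idx) == 0) {
    return(tibble(gene_id = character(), chrom = character(), start = numeric(),
                  end = numeric(), category = character(), is_21u = logical()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol != 9)) {
    i <- which(ncol != 9)[1]
    abort(sprintf("GFF3 line %d: expected 9 tab-separated columns, got %d", idx[i], ncol[i]))
  }
  m <- do.call(rbind, fields)
  attrs <- m[, 9]
  bad <- which(!grepl("=", attrs, fixed = TRUE) & attrs != ".")
  if (length(bad) > 0) {
    abort(sprintf("GFF3 line %d: unparseable attribute column '%s'", idx[bad[1]], attrs[bad[1]]))
  }
  type <- m[, 3]
  ids <- gff_attr(attrs, "ID")
  parents <- gff_attr(attrs, "Parent")
  biotype <- gff_attr(attrs, "biotype")
  gb <- gff_attr(attrs, "gene_biotype")
  biotype <- ifelse(is.na(biotype), gb, biotype)
  name <- gff_attr(attrs, "Name")

  # parents with an mRNA/CDS child are protein-coding
  cds_parents <- unique(unlist(strsplit(
    parents[type %in% c("mRNA", "CDS") & !is.na(parents)], ",", fixed = TRUE)))

  keep <- type == "gene" | (type %in% c("tRNA", "rRNA", ncrna_types) & is.na(parents))
  ki <- which(keep)
  ktype <- type[ki]
  kbio <- biotype[ki]
  category <- character(length(ki))
  for (j in seq_along(ki)) {
    tt <- ktype[j]
    bt <- kbio[j]
    category[j] <-
      if (tt == "tRNA") "tRNA"
      else if (tt == "rRNA") "rRNA"
      else if (tt %in% ncrna_types) "ncRNA"
      else if (!is.na(bt) && bt == "protein_coding") "CDS"
      else if (!is.na(bt) && bt == "tRNA") "tRNA"
      else if (!is.na(bt) && bt == "rRNA") "rRNA"
      else if (!is.na(bt) && grepl("RNA", bt)) "ncRNA"
      else if (!is.na(ids[ki[j]]) && ids[ki[j]] %in% cds_parents) "CDS"
      else "other"
  }
  gene_id <- ifelse(is.na(ids[ki]), name[ki], ids[ki])
  gene_id <- sub("^gene:", "", gene_id)
  out <- tibble(
    gene_id = gene_id,
    chrom = m[ki, 1],
    start = suppressWarnings(as.numeric(m[ki, 4])) - 1,
    end = suppressWarnings(as.numeric(m[ki, 5])),
    category = category,
    biotype = kbio)
  if (anyNA(out$start) || anyNA(out$end)) {
    i <- which(is.na(out$start) | is.na(out$end))[1]
    abort(sprintf("GFF3: non-numeric coordinates for feature '%s'", out$gene_id[i]))
  }
  out <- validate_intervals(out, what = "gene record")
  out$is_21u <- is_21u(out)
  select(out, -"biotype")
}

#' Write a report bundle of TSV tables
#'
#' Writes each named table in `tables` to `<dir>/<name>.tsv` with
#' deterministic column order and fixed decimal formatting: columns whose
#' names contain `pct`, `percent` or `fraction` are printed with 2
#' decimals, other non-integer numeric columns with 4 decimals. Identical
#' inputs produce byte-identical files.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    df <- as.data.frame(tables[[nm]])
    for (col in names(df)) {
      v <- df[[col]]
      if (is.numeric(v)) {
        if (grepl("pct|percent|fraction", col)) {
          df[[col]] <- sprintf("%.2f", v)
        } else if (all(is.finite(v) & v == round(v))) {
          df[[col]] <- sprintf("%d", as.integer(round(v)))
        } else {
          df[[col]] <- sprintf("%.4f", v)
        }
      }
    }
    con <- file(path, open = "wb")
    writeLines(c(paste(names(df), collapse = "\t"),
                 if (nrow(df) > 0) do.call(paste, c(df, sep = "\t"))),
               con, sep = "\n")
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}
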