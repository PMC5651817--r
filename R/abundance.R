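#' Construct a taxon-abundance table
#'
#' Rows are taxa (identified by Greengenes-style lineage strings with rank
#' prefixes, e.g. `"k__Bacteria;p__Firmicutes;..."`), columns are samples,
#' and values are nonnegative counts or proportions.
#'
#' @param values Nonnegative numeric matrix, taxa x samples.
#' @param taxa Character vector of lineage strings (row labels).
#' @param samples Character vector of sample ids (column labels).
#' @param is_relative Whether columns are proportions summing to 1.
#' @return An `abundance_table`.
#' @export
abundance_table <- function(values, taxa, samples, is_relative = FALSE) {
  values <- as.matrix(values)
  taxa <- as.character(taxa)
  samples <- as.character(samples)
  if (nrow(values) != length(taxa) || ncol(values) != length(samples)) {
    stop("values must be taxa x samples")
  }
  if (anyDuplicated(taxa)) stop("taxon ids must be unique")
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  if (anyNA(values) || any(values < 0)) {
    bad <- which(is.na(values) | values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative or missing abundance at taxon '%s', sample '%s'",
                 taxa[bad[1]], samples[bad[2]]))
  }
  if (is_relative) {
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-8)) {
      stop("is_relative = TRUE but some column sums differ from 1")
    }
  }
  dimnames(values) <- list(taxa, samples)
  structure(list(taxa = taxa, samples = samples, values = values,
                 is_relative = isTRUE(is_relative)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance table: %d taxa x %d samples (%s)\n",
              length(x$taxa), length(x$samples),
              if (x$is_relative) "relative" else "counts"))
  invisible(x)
}

#' Read a taxon-abundance table
#'
#' TSV layout: first column holds taxon lineage strings, remaining columns
#' are numeric abundances with sample ids in the header. Counts versus
#' proportions are detected from column sums (all within 1e-6 of 1 means
#' proportions). BIOM-JSON files are read through the biomformat package.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"biom-json"`.
#' @return An `abundance_table`.
#' @export
read_abundance <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    values <- as.matrix(biomformat::biom_data(b))
    return(abundance_table(values, rownames(values), colnames(values)))
  }
  lines <- readLines(path)
  if (length(lines) < 2) stop("abundance TSV needs a header and >= 1 row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expected <- length(fields[[1]])
  samples <- fields[[1]][-1]
  taxa <- character(length(lines) - 1)
  values <- matrix(NA_real_, length(lines) - 1, length(samples))
  for (k in seq_along(lines)[-1]) {
    row <- fields[[k]]
    if (length(row) != ncol_expected) {
      stop(sprintf("row %d ('%s') has %d fields, expected %d",
                   k, row[1], length(row), ncol_expected))
    }
    taxa[k - 1] <- row[1]
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v)) {
      stop(sprintf("malformed numeric value in row %d ('%s'), column '%s'",
                   k, row[1], samples[which(is.na(v))[1]]))
    }
    values[k - 1, ] <- v
  }
  cs <- colSums(values)
  is_rel <- all(abs(cs - 1) < 1e-6) && any(values %% 1 != 0)
  abundance_table(values, taxa, samples, is_relative = is_rel)
}

#' Write a taxon-abundance table to TSV
#' @param table An `abundance_table`.
#' @param path Output file.
#' @param id_column Header of the lineage column.
#' @export
write_abundance <- function(table, path, id_column = "taxonomy") {
  header <- paste(c(id_column, table$samples), collapse = "\t")
  rows <- vapply(seq_along(table$taxa), function(i) {
    paste(c(table$taxa[i],
            format(table$values[i, ], trim = TRUE, digits = 15,
                   scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

rank_prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__",
                   species = "s__")

lineage_rank <- function(lineages, level) {
  prefix <- rank_prefixes[[level]]
  vapply(strsplit(lineages, ";", fixed = TRUE), function(parts) {
    parts <- trimws(parts)
    hit <- parts[startsWith(parts, prefix)]
    if (length(hit) == 0) return(NA_character_)
    label <- sub(prefix, "", hit[1], fixed = TRUE)
    if (nzchar(label)) label else NA_character_
  }, character(1))
}

#' Aggregate taxa to a taxonomic rank
#'
#' Rows whose lineage carries the same label at the requested rank are
#' summed; lineages without a (nonempty) label at that rank are pooled into
#' `"unclassified"`. A bare label with no rank prefixes at all is treated as
#' already being at the requested rank. Column sums are conserved exactly.
#'
#' @param table An `abundance_table`.
#' @param level Rank name: one of kingdom, phylum, class, order, family,
#'   genus, species.
#' @return Aggregated `abundance_table` with rank labels as taxon ids.
#' @export
aggregate_taxa <- function(table, level = "phylum") {
  level <- match.arg(level, names(rank_prefixes))
  labels <- lineage_rank(table$taxa, level)
  bare <- !grepl("__", table$taxa, fixed = TRUE)
  labels[bare] <- table$taxa[bare]
  has_prefix <- grepl(rank_prefixes[[level]], table$taxa, fixed = TRUE)
  if (all(is.na(labels)) && !any(has_prefix)) {
    stop(sprintf("no lineage carries a %s label", level))
  }
  labels[is.na(labels)] <- "unclassified"
  groups <- sort(unique(labels))
  values <- do.call(rbind, lapply(groups, function(g) {
    colSums(table$values[labels == g, , drop = FALSE])
  }))
  abundance_table(values, groups, table$samples,
                  is_relative = table$is_relative)
}

#' Convert to relative abundances with a detection floor
#'
#' Each sample column is divided by its sum; zero entries are then replaced
#' by the detection floor and the column renormalized, so every taxon keeps
#' a strictly positive pseudo-abundance. The floor keeps downstream
#' equilibrium estimates interior, which the stability analysis and the
#' analytic elimination of growth rates both require.
#'
#' @param table An `abundance_table` of counts or proportions.
#' @param floor Pseudo-proportion replacing zeros (default `1e-4`).
#' @return A relative `abundance_table` (columns sum to 1).
#' @export
relative_abundance <- function(table, floor = 1e-4) {
  values <- table$values
  cs <- colSums(values)
  if (any(cs == 0) && floor == 0) {
    stop(sprintf("sample '%s' is all zeros and floor = 0",
                 table$samples[which(cs == 0)[1]]))
  }
  for (j in seq_along(cs)) {
    col <- if (cs[j] > 0) values[, j] / cs[j] else rep(0, nrow(values))
    if (floor > 0) {
      col[col == 0] <- floor
      col <- col / sum(col)
    }
    values[, j] <- col
  }
  abundance_table(values, table$taxa, table$samples, is_relative = TRUE)
}

#' Construct sample metadata
#'
#' @param sample Character vector of sample ids (must be unique).
#' @param subject Subject (e.g. mouse) identifier per sample.
#' @param week Numeric week of age per sample.
#' @param group Treatment-group label per sample.
#' @return A `sample_metadata` data frame.
#' @export
sample_metadata <- function(sample, subject, week, group) {
  if (anyDuplicated(sample)) stop("sample ids must be unique")
  structure(data.frame(sample = as.character(sample),
                       subject = as.character(subject),
                       week = as.numeric(week),
                       group = as.character(group),
                       stringsAsFactors = FALSE),
            class = c("sample_metadata", "data.frame"))
}

#' Read sample metadata from TSV (columns sample, subject, week, group)
#' @param path Input file.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "subject", "week", "group")
  if (!all(need %in% names(df))) {
    stop("metadata must have columns sample, subject, week, group")
  }
  sample_metadata(df$sample, df$subject, df$week, df$group)
}

#' Write sample metadata to TSV
#' @param meta A `sample_metadata`.
#' @param path Output file.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Estimate the equilibrium composition from longitudinal data
#'
#' The steady-state abundance vector is estimated as the per-taxon
#' arithmetic mean of relative abundances over every (subject, week) sample
#' of the chosen group falling inside the week window. With the detection
#' floor applied upstream by [relative_abundance()] the estimate is strictly
#' positive (interior), as the stability analysis requires.
#'
#' @param table A relative `abundance_table`.
#' @param meta Matching `sample_metadata`.
#' @param group Group label to select.
#' @param window Numeric `c(first, last)` week-of-age range (inclusive);
#'   `NULL` uses the full series.
#' @return An `equilibrium_state`: list with `taxa`, `y_bar`, `window`,
#'   `n_samples`.
#' @export
estimate_equilibrium <- function(table, meta, group, window = NULL) {
  if (!table$is_relative) {
    stop("estimate_equilibrium needs relative abundances; ",
         "call relative_abundance() first")
  }
  if (!all(table$samples %in% meta$sample)) {
    stop("every table sample must appear in the metadata")
  }
  m <- meta[match(table$samples, meta$sample), ]
  keep <- m$group == group
  if (!is.null(window)) {
    keep <- keep & m$week >= window[1] & m$week <= window[2]
  }
  if (sum(keep) < 2) {
    stop(sprintf("need >= 2 samples of group '%s' in the window, found %d",
                 group, sum(keep)))
  }
  y_bar <- rowMeans(table$values[, keep, drop = FALSE])
  # standard error of the mean from subject-level means (samples within a
  # subject are correlated; subjects are the independent replicates)
  subj <- m$subject[keep]
  subj_means <- vapply(unique(subj), function(s) {
    rowMeans(table$values[, keep[subj == s], drop = FALSE])
  }, numeric(length(table$taxa)))
  se <- if (length(unique(subj)) > 1) {
    apply(subj_means, 1, stats::sd) / sqrt(length(unique(subj)))
  } else {
    0.05 * y_bar
  }
  structure(list(taxa = table$taxa, y_bar = y_bar,
                 y_bar_se_rel = pmax(se / y_bar, 1e-3),
                 window = if (is.null(window)) range(m$week[keep]) else window,
                 n_samples = sum(keep)),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf(
    "equilibrium estimate from %d samples, weeks [%g, %g]:\n",
    x$n_samples, x$window[1], x$window[2]))
  print(round(x$y_bar, 4))
  invisible(x)
}
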