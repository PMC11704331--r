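#' Read a cell-detection table
#'
#' Reads a CSV of cell detections as exported by whole-slide analysis
#' tools. Column names vary between export dialects, so a column map
#' translates them; rows with non-finite coordinates are dropped with a
#' message stating the count. Duplicate cell ids or a missing mapped column
#' are errors.
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping the canonical names
#'   `cell_id`, `x_um`, `y_um`, `class` to the file's column names.
#' @return data.frame with columns `cell_id`, `x_um`, `y_um`, `class`.
#' @export
read_cell_table <- function(path,
                            column_map = c(cell_id = "cell_id", x_um = "x_um",
                                           y_um = "y_um", class = "class")) {
  if (!file.exists(path)) stop_spatsig("file not found: ", path)
  needed <- c("cell_id", "x_um", "y_um", "class")
  stopifnot(all(needed %in% names(column_map)))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(column_map[needed]), names(raw))
  if (length(missing) > 0L) {
    stop_spatsig("missing mapped column(s): ", paste(missing, collapse = ", "))
  }
  cells <- data.frame(
    cell_id = as.character(raw[[column_map[["cell_id"]]]]),
    x_um = as.numeric(raw[[column_map[["x_um"]]]]),
    y_um = as.numeric(raw[[column_map[["y_um"]]]]),
    class = as.character(raw[[column_map[["class"]]]]),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(cells$x_um) | !is.finite(cells$y_um)
  if (any(bad)) {
    message("dropped ", sum(bad), " row(s) with non-finite coordinates")
    cells <- cells[!bad, , drop = FALSE]
  }
  if (anyDuplicated(cells$cell_id)) stop_spatsig("duplicate cell ids in ", path)
  if (any(!nzchar(cells$class))) stop_spatsig("empty class labels in ", path)
  rownames(cells) <- NULL
  cells
}

#' Write a cell table as CSV
#' @param cells Cell table data.frame.
#' @param path Output path.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells[, c("cell_id", "x_um", "y_um", "class")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then gene identifiers, tab
#' separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; the description is kept in the
#'   `"description"` attribute of each element.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_spatsig("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop_spatsig("malformed GMT record at line ", i,
                   ": need name, description and at least one gene")
    }
    genes <- parts[-c(1L, 2L)]
    attr(genes, "description") <- parts[2L]
    sets[[parts[1L]]] <- genes
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors (or a single
#'   `gene_signature`).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_signature")) {
    sets <- stats::setNames(list(sets$genes), sets$name)
  }
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read peak intervals in BED format
#'
#' Minimal BED: `chrom`, `start`, `end` (0-based half-open), extra columns
#' ignored. Records with `start >= end` are rejected with their line
#' number.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_spatsig("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1L), 1L),
    start = as.integer(vapply(parts, `[`, character(1L), 2L)),
    end = as.integer(vapply(parts, `[`, character(1L), 3L)),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.finite(out$start) | !is.finite(out$end) | out$start >= out$end)
  if (length(bad) > 0L) {
    stop_spatsig("invalid BED interval (start >= end or non-numeric) at line ",
                 bad[1L])
  }
  if (any(!nzchar(out$chrom))) stop_spatsig("empty chromosome name in ", path)
  out
}

#' Read a gene x sample expression matrix from TSV
#'
#' First column holds gene identifiers (must be unique), remaining columns
#' one sample each; the table must be rectangular.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop_spatsig("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_spatsig("expression table needs gene ids plus >= 1 sample")
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes)) stop_spatsig("duplicate gene ids in ", path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_spatsig("non-numeric expression values in ", path)
  rownames(m) <- genes
  m
}

#' Write a gene x sample expression matrix as TSV
#' @param expr Numeric matrix with gene rownames.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a survival table from CSV
#'
#' Columns `sample_id`, `time`, `event`; times must be positive and the
#' event indicator binary, violations are reported with their line number.
#'
#' @param path CSV path.
#' @return data.frame `sample_id`, `time`, `event`.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop_spatsig("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "time", "event")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L) {
    stop_spatsig("missing column(s): ", paste(missing, collapse = ", "))
  }
  bad_t <- which(!is.finite(tab$time) | tab$time <= 0)
  if (length(bad_t) > 0L) {
    stop_spatsig("non-positive or missing survival time at line ", bad_t[1L] + 1L)
  }
  bad_e <- which(!tab$event %in% c(0, 1))
  if (length(bad_e) > 0L) {
    stop_spatsig("event indicator not in {0, 1} at line ", bad_e[1L] + 1L)
  }
  tab[, needed]
}

#' Read a per-read dual-alignment score table from TSV
#'
#' Columns `read_id`, `score_a`, `score_b` and optionally `gene_a`,
#' `gene_b`; empty fields become `NA` (an unmapped alignment). Reads with
#' neither score are rejected.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_alignment_pairs <- function(path) {
  if (!file.exists(path)) stop_spatsig("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  needed <- c("read_id", "score_a", "score_b")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L) {
    stop_spatsig("missing column(s): ", paste(missing, collapse = ", "))
  }
  both <- which(is.na(tab$score_a) & is.na(tab$score_b))
  if (length(both) > 0L) {
    stop_spatsig("read with no score on either genome at line ", both[1L] + 1L)
  }
  if (anyDuplicated(tab$read_id)) stop_spatsig("duplicate read ids in ", path)
  tab
}

#' Write a hotspot set as GeoJSON
#'
#' Each region becomes a Polygon feature in micrometer coordinates with the
#' class label, region id and area as properties.
#'
#' @param hotspots A `hotspot_set`.
#' @param path Output path.
#' @export
write_hotspots_geojson <- function(hotspots, path) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  features <- lapply(hotspots$regions, function(r) {
    rings <- lapply(r$rings, function(ring) {
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1L], ring[i, 2L]))
    })
    list(
      type = "Feature",
      properties = list(class_label = hotspots$class_label,
                        region_id = r$region_id, area_um2 = r$area_um2),
      geometry = list(type = "Polygon", coordinates = rings)
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a density map as a TSV grid plus JSON header
#'
#' @param density A `density_map`.
#' @param path Grid TSV path; the header is written alongside as
#'   `<path>.json` (origin, pixel size, bandwidth, source-cell count).
#' @export
write_density_map <- function(density, path) {
  stopifnot(inherits(density, "density_map"))
  utils::write.table(density$grid, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(origin_x = density$origin_x, origin_y = density$origin_y,
         pixel_size = density$pixel_size, bandwidth = density$bandwidth,
         n_source_cells = density$n_source_cells,
         n_rows = nrow(density$grid), n_cols = ncol(density$grid)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
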