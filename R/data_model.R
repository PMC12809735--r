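#' Default column-name schema for tree tables
#'
#' Maps the internal field names to the column names expected in a trees CSV.
#' Override individual entries to read files with other headers.
#'
#' @return Named list with entries `plot_id`, `species`, `dbh_cm`, `height_m`.
#' @export
tree_schema <- function(plot_id = "plot_id", species = "species",
                        dbh_cm = "dbh_cm", height_m = "height_m") {
  list(plot_id = plot_id, species = species, dbh_cm = dbh_cm,
       height_m = height_m)
}

#' Default column-name schema for plot tables
#'
#' Only `plot_id` and `area_ha` are required in a plots CSV; every other
#' column present is carried along as a plot-level covariate (e.g. elevation_m,
#' slope_deg, soc_g_kg, MAT, MAP, ...).
#'
#' @return Named list with entries `plot_id` and `area_ha`.
#' @export
plot_schema <- function(plot_id = "plot_id", area_ha = "area_ha") {
  list(plot_id = plot_id, area_ha = area_ha)
}

.parse_numeric_column <- function(x, col, path) {
  raw <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(out) & !is.na(raw) & nzchar(raw) &
                 !(toupper(raw) %in% c("NA", "NAN")))
  if (length(bad)) {
    stop(sprintf(
      "parse error in '%s': column '%s' has non-numeric value \"%s\" on data line %d",
      path, col, raw[bad[1]], bad[1] + 1L), call. = FALSE)
  }
  out
}

#' Read a tree-level table from CSV
#'
#' Reads one row per measured stem: plot identifier, species code, diameter at
#' breast height (cm) and total height (m, may be missing). Rows violating the
#' domain constraints (dbh <= 0, or height <= 1.3 m, the breast-height offset
#' below which the allometric model is undefined) are flagged in the returned
#' `flags` attribute, not dropped.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Column-name mapping, see [tree_schema()].
#' @return A data.frame with columns `plot_id`, `species`, `dbh_cm`,
#'   `height_m` and an attribute `"flags"` (data.frame of row/field/message).
#' @export
read_trees <- function(path, schema = tree_schema()) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  required <- c("plot_id", "species", "dbh_cm")
  for (fld in c(required, "height_m")) {
    col <- schema[[fld]]
    if (!col %in% names(raw)) {
      if (fld %in% required) {
        stop(sprintf("schema error: required column '%s' (field %s) not found in '%s'",
                     col, fld, path), call. = FALSE)
      }
      raw[[col]] <- NA_character_
    }
  }
  trees <- data.frame(
    plot_id  = trimws(raw[[schema$plot_id]]),
    species  = trimws(raw[[schema$species]]),
    dbh_cm   = .parse_numeric_column(raw[[schema$dbh_cm]], schema$dbh_cm, path),
    height_m = .parse_numeric_column(raw[[schema$height_m]], schema$height_m, path),
    stringsAsFactors = FALSE
  )
  attr(trees, "flags") <- .flag_trees(trees)
  trees
}

.flag_trees <- function(trees) {
  flags <- list()
  bad_d <- which(!is.na(trees$dbh_cm) & trees$dbh_cm <= 0)
  if (length(bad_d)) {
    flags[[length(flags) + 1L]] <- data.frame(
      row = bad_d, field = "dbh_cm",
      message = "dbh_cm must be positive", stringsAsFactors = FALSE)
  }
  bad_h <- which(!is.na(trees$height_m) & trees$height_m <= 1.3)
  if (length(bad_h)) {
    flags[[length(flags) + 1L]] <- data.frame(
      row = bad_h, field = "height_m",
      message = "height_m must exceed breast height (1.3 m)",
      stringsAsFactors = FALSE)
  }
  if (length(flags)) do.call(rbind, flags) else
    data.frame(row = integer(), field = character(), message = character(),
               stringsAsFactors = FALSE)
}

#' Read a plot-level table from CSV
#'
#' Requires `plot_id` and `area_ha`; all other columns are parsed as numeric
#' plot covariates. Hard validation failures (duplicate plot ids, non-positive
#' area, slope outside [0, 90), soil texture fractions not summing to
#' 95--105%) raise errors naming the offending plot.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Column-name mapping, see [plot_schema()].
#' @return A data.frame keyed by `plot_id` with `area_ha` and all covariates.
#' @export
read_plots <- function(path, schema = plot_schema()) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  for (fld in c("plot_id", "area_ha")) {
    col <- schema[[fld]]
    if (!col %in% names(raw)) {
      stop(sprintf("schema error: required column '%s' (field %s) not found in '%s'",
                   col, fld, path), call. = FALSE)
    }
  }
  plots <- data.frame(plot_id = trimws(raw[[schema$plot_id]]),
                      stringsAsFactors = FALSE)
  for (col in setdiff(names(raw), schema$plot_id)) {
    nm <- if (col == schema$area_ha) "area_ha" else col
    plots[[nm]] <- .parse_numeric_column(raw[[col]], col, path)
  }
  dup <- unique(plots$plot_id[duplicated(plots$plot_id)])
  if (length(dup)) {
    stop(sprintf("duplicate plot_id in '%s': %s", path,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  .check_plots(plots)
  plots
}

.check_plots <- function(plots) {
  problems <- character()
  bad <- which(!is.na(plots$area_ha) & plots$area_ha <= 0)
  if (length(bad)) problems <- c(problems, sprintf(
    "plot %s: area_ha must be positive", plots$plot_id[bad]))
  if ("slope_deg" %in% names(plots)) {
    bad <- which(!is.na(plots$slope_deg) &
                   (plots$slope_deg < 0 | plots$slope_deg >= 90))
    if (length(bad)) problems <- c(problems, sprintf(
      "plot %s: slope_deg outside [0, 90)", plots$plot_id[bad]))
  }
  tex <- c("sand_pct", "silt_pct", "clay_pct")
  if (all(tex %in% names(plots))) {
    s <- plots$sand_pct + plots$silt_pct + plots$clay_pct
    bad <- which(!is.na(s) & (s < 95 | s > 105))
    if (length(bad)) problems <- c(problems, sprintf(
      "plot %s: sand+silt+clay = %.1f%% outside [95, 105]%%",
      plots$plot_id[bad], s[bad]))
  }
  if (length(problems)) {
    stop(paste(c("plot validation failure:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  invisible(plots)
}

#' Assemble trees and plots into a forest dataset
#'
#' @param trees Tree table as returned by [read_trees()] (or an equivalent
#'   data.frame).
#' @param plots Plot table as returned by [read_plots()].
#' @param species_registry Optional character vector of expected species codes.
#' @return An object of class `forest_dataset`: a list with elements `trees`,
#'   `plots`, `species_registry`.
#' @export
forest_dataset <- function(trees, plots, species_registry = NULL) {
  stopifnot(is.data.frame(trees), is.data.frame(plots))
  if (is.null(species_registry)) {
    species_registry <- sort(unique(trees$species))
  }
  orphans <- setdiff(unique(trees$plot_id), plots$plot_id)
  if (length(orphans)) {
    warning(sprintf("%d tree(s) reference unknown plots: %s",
                    sum(trees$plot_id %in% orphans),
                    paste(orphans, collapse = ", ")), call. = FALSE)
  }
  structure(list(trees = trees, plots = plots,
                 species_registry = species_registry),
            class = "forest_dataset")
}

#' @export
print.forest_dataset <- function(x, ...) {
  cat(sprintf("forest_dataset: %d trees in %d plots, %d species (%s)\n",
              nrow(x$trees), nrow(x$plots), length(x$species_registry),
              paste(x$species_registry, collapse = ", ")))
  invisible(x)
}

#' Validate a forest dataset
#'
#' Report-only check: lists trees referencing unknown plots, out-of-range
#' values, and species whose tree count falls below `min_species_n` (these are
#' marked for exclusion from per-species fits, mirroring the survey practice
#' of excluding species with insufficient data). Never modifies the input.
#'
#' @param ds A [forest_dataset()].
#' @param min_species_n Minimum trees per species for inclusion in
#'   species-level modelling (default 100).
#' @return A list of class `hd_validation` with elements `orphan_trees`
#'   (integer row indices), `out_of_range` (data.frame), `excluded_species`
#'   (character), `n_issues`.
#' @export
validate_dataset <- function(ds, min_species_n = 100) {
  stopifnot(inherits(ds, "forest_dataset"))
  trees <- ds$trees
  orphan <- which(!(trees$plot_id %in% ds$plots$plot_id))
  oor <- .flag_trees(trees)
  counts <- table(trees$species)
  excluded <- names(counts)[counts < min_species_n]
  structure(list(
    orphan_trees = orphan,
    out_of_range = oor,
    excluded_species = excluded,
    species_counts = as.list(counts),
    n_issues = length(orphan) + nrow(oor) + length(excluded)
  ), class = "hd_validation")
}

#' @export
print.hd_validation <- function(x, ...) {
  if (x$n_issues == 0) {
    cat("dataset valid: no issues found\n")
    return(invisible(x))
  }
  cat(sprintf("dataset validation: %d issue(s)\n", x$n_issues))
  if (length(x$orphan_trees)) {
    cat(sprintf("  %d orphan tree(s) at rows: %s\n", length(x$orphan_trees),
                paste(utils::head(x$orphan_trees, 10), collapse = ", ")))
  }
  if (nrow(x$out_of_range)) {
    cat(sprintf("  %d out-of-range value(s)\n", nrow(x$out_of_range)))
  }
  if (length(x$excluded_species)) {
    cat(sprintf("  species below threshold (excluded from fits): %s\n",
                paste(x$excluded_species, collapse = ", ")))
  }
  invisible(x)
}

#' Extract the modelling subset of trees
#'
#' Keeps trees with dbh above the survey threshold (default 5 cm), a usable
#' height (> 1.3 m), a resolvable plot, and a species with at least
#' `min_species_n` trees. Exclusions are reported to standard error.
#'
#' @inheritParams validate_dataset
#' @param min_dbh_cm Diameter threshold in cm (default 5, the survey rule).
#' @return Tree data.frame restricted to the modelling subset.
#' @export
modelling_subset <- function(ds, min_dbh_cm = 5, min_species_n = 100) {
  stopifnot(inherits(ds, "forest_dataset"))
  trees <- ds$trees
  keep <- trees$plot_id %in% ds$plots$plot_id &
    !is.na(trees$dbh_cm) & trees$dbh_cm >= min_dbh_cm &
    !is.na(trees$height_m) & trees$height_m > 1.3
  counts <- table(trees$species[keep])
  small <- names(counts)[counts < min_species_n]
  keep <- keep & !(trees$species %in% small)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("modelling_subset: excluded %d of %d trees (%s)",
                    n_drop, nrow(trees),
                    if (length(small))
                      paste("species below threshold:",
                            paste(small, collapse = ", "))
                    else "range/height/orphan rules"))
  }
  trees[keep, , drop = FALSE]
}

.format_full <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE)
    }, character(1))
    trimws(out)
  } else as.character(x)
}

#' Write tree / plot tables to CSV at full numeric precision
#'
#' Numeric fields are serialized with 17 significant digits so a write/read
#' round trip reproduces every double exactly.
#'
#' @param x Tree or plot data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_full <- function(x, path) {
  out <- as.data.frame(lapply(x, .format_full), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(x)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Serialize a validation report to JSON
#'
#' @param report An `hd_validation` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(report, path) {
  stopifnot(inherits(report, "hd_validation"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
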