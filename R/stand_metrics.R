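#' Basal area of a single stem
#'
#' Cross-sectional area at breast height, `pi * (dbh / 200)^2`, in square
#' metres for dbh in centimetres.
#'
#' @param dbh_cm Diameter(s) at breast height, cm; must be positive.
#' @return Basal area(s), m^2.
#' @export
tree_basal_area <- function(dbh_cm) {
  if (length(dbh_cm) == 0) return(numeric(0))
  if (any(is.na(dbh_cm)) || any(dbh_cm <= 0)) {
    stop("tree_basal_area: dbh_cm must be positive", call. = FALSE)
  }
  pi * (dbh_cm / 200)^2
}

#' Quadratic mean diameter
#'
#' `sqrt(mean(D^2))`, the diameter of the tree of mean basal area; a standard
#' stand developmental-stage indicator.
#'
#' @param dbh_cm Vector of diameters, cm; non-empty and positive.
#' @return QMD in cm.
#' @export
compute_qmd <- function(dbh_cm) {
  if (length(dbh_cm) == 0) stop("compute_qmd: empty diameter list", call. = FALSE)
  if (any(is.na(dbh_cm)) || any(dbh_cm <= 0)) {
    stop("compute_qmd: diameters must be positive", call. = FALSE)
  }
  sqrt(mean(dbh_cm^2))
}

#' Basal area of larger trees (BAL)
#'
#' For each tree, the summed basal area of all trees in the plot with strictly
#' greater diameter, per hectare. Trees of equal diameter contribute nothing to
#' each other, so the (unique) largest tree has BAL exactly 0.
#'
#' @param dbh_cm Vector of diameters, cm.
#' @param area_ha Plot area, ha; positive.
#' @return Vector of BAL values (m^2/ha) aligned with `dbh_cm`.
#' @export
compute_bal <- function(dbh_cm, area_ha) {
  if (is.na(area_ha) || area_ha <= 0) {
    stop("compute_bal: area_ha must be positive", call. = FALSE)
  }
  n <- length(dbh_cm)
  if (n == 0) return(numeric(0))
  ba <- tree_basal_area(dbh_cm)
  ord <- order(dbh_cm, decreasing = TRUE)
  d_sorted <- dbh_cm[ord]
  cum <- cumsum(ba[ord])
  first <- match(d_sorted, d_sorted)  # first index of each tie group
  bal_sorted <- ifelse(first == 1L, 0, cum[pmax(first - 1L, 1L)])
  out <- numeric(n)
  out[ord] <- bal_sorted / area_ha
  out
}

.check_abundances <- function(abundances, fn) {
  x <- as.numeric(abundances)
  if (length(x) == 0 || any(is.na(x)) || any(x < 0) || sum(x) <= 0) {
    stop(sprintf("%s: abundances must be non-negative with positive total", fn),
         call. = FALSE)
  }
  x
}

#' Simpson species-diversity index (Gini--Simpson form)
#'
#' `1 - sum(p_i^2)` with `p_i` the relative abundance of species i. The
#' Gini--Simpson form makes a pure (single-species) stand score exactly 0.
#'
#' @param abundances Named vector or list of per-species counts.
#' @return Index in `[0, 1 - 1/k]` for k species.
#' @export
simpson_index <- function(abundances) {
  x <- .check_abundances(abundances, "simpson_index")
  p <- x / sum(x)
  1 - sum(p^2)
}

#' Shannon species-diversity index
#'
#' `-sum(p_i * log(p_i))` over species with positive abundance; 0 for a pure
#' stand, `log(k)` at maximal evenness over k species.
#'
#' @inheritParams simpson_index
#' @return Index in `[0, log(k)]`.
#' @export
shannon_index <- function(abundances) {
  x <- .check_abundances(abundances, "shannon_index")
  p <- x / sum(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Stage slope-elevation transforms
#'
#' Combines slope and elevation into the interaction terms
#' `SIE = sin(SL) * ln(EL)` and `CIE = cos(SL) * ln(EL)`; slope is recorded in
#' degrees and converted to radians before the trigonometric call.
#'
#' @param slope_deg Slope in degrees.
#' @param elevation_m Elevation in metres; must exceed 1 m (log domain).
#' @return List with elements `sie` and `cie`.
#' @export
stage_transforms <- function(slope_deg, elevation_m) {
  if (any(is.na(elevation_m)) || any(elevation_m <= 1)) {
    stop("stage_transforms: elevation_m must exceed 1 m", call. = FALSE)
  }
  rad <- slope_deg * pi / 180
  list(sie = sin(rad) * log(elevation_m),
       cie = cos(rad) * log(elevation_m))
}

#' de Martonne aridity index
#'
#' `M = MAP / (MAT + 10)`; larger values indicate moister conditions.
#'
#' @param map_mm Mean annual precipitation, mm (non-negative).
#' @param mat_c Mean annual temperature, degrees C; must exceed -10.
#' @return The index (mm/degree C).
#' @export
de_martonne <- function(map_mm, mat_c) {
  if (any(is.na(mat_c)) || any(mat_c <= -10)) {
    stop("de_martonne: MAT must exceed -10 C", call. = FALSE)
  }
  if (any(map_mm < 0, na.rm = TRUE)) {
    stop("de_martonne: MAP must be non-negative", call. = FALSE)
  }
  map_mm / (mat_c + 10)
}

#' Annual heat:moisture index
#'
#' `AHM = (MAT + 10) / (MAP / 1000)`; larger values indicate hotter/drier
#' climates.
#'
#' @inheritParams de_martonne
#' @return The index.
#' @export
annual_heat_moisture <- function(mat_c, map_mm) {
  if (any(is.na(map_mm)) || any(map_mm <= 0)) {
    stop("annual_heat_moisture: MAP must be positive", call. = FALSE)
  }
  if (any(mat_c <= -10, na.rm = TRUE)) {
    stop("annual_heat_moisture: MAT must exceed -10 C", call. = FALSE)
  }
  (mat_c + 10) / (map_mm / 1000)
}

#' Dominant height of a plot
#'
#' Arithmetic mean, over the species present, of the maximum tree height per
#' species.
#'
#' @param trees_in_plot Data.frame with columns `species` and `height_m`.
#' @return Dominant height, m.
#' @export
dominant_height <- function(trees_in_plot) {
  h <- trees_in_plot$height_m
  keep <- !is.na(h)
  if (!any(keep)) stop("dominant_height: no measured heights", call. = FALSE)
  maxima <- tapply(h[keep], trees_in_plot$species[keep], max)
  mean(maxima)
}

#' Compute all stand, site and diversity metrics for one plot
#'
#' Assembles quadratic mean diameter (QMD), arithmetic mean diameter (MD),
#' basal area per hectare (BA), stem density (N), dominant height (DH),
#' Simpson (SIM) and Shannon (SHI) diversity, the Stage transforms (SIE, CIE),
#' the de Martonne index (M), the annual heat:moisture index (AHM) and
#' per-tree BAL. Site/climate composites are `NA` when the plot table lacks
#' the needed covariates.
#'
#' @param ds A [forest_dataset()].
#' @param plot_id Plot identifier.
#' @param min_dbh_cm Diameter threshold defining which stems enter the
#'   metrics (default 5 cm, the survey rule).
#' @return List of class `stand_metrics`.
#' @export
compute_stand_metrics <- function(ds, plot_id, min_dbh_cm = 5) {
  stopifnot(inherits(ds, "forest_dataset"))
  prow <- ds$plots[ds$plots$plot_id == plot_id, , drop = FALSE]
  if (nrow(prow) != 1) {
    stop(sprintf("compute_stand_metrics: unknown plot '%s'", plot_id),
         call. = FALSE)
  }
  tr <- ds$trees[ds$trees$plot_id == plot_id &
                   !is.na(ds$trees$dbh_cm) &
                   ds$trees$dbh_cm >= min_dbh_cm, , drop = FALSE]
  if (nrow(tr) == 0) {
    stop(sprintf("compute_stand_metrics: plot '%s' has no trees >= %g cm",
                 plot_id, min_dbh_cm), call. = FALSE)
  }
  area <- prow$area_ha
  d <- tr$dbh_cm
  counts <- table(tr$species)
  getcov <- function(nm) if (nm %in% names(prow)) prow[[nm]] else NA_real_
  slope <- getcov("slope_deg"); elev <- getcov("elevation_m")
  stage <- if (!is.na(slope) && !is.na(elev) && elev > 1) {
    stage_transforms(slope, elev)
  } else list(sie = NA_real_, cie = NA_real_)
  mat <- getcov("MAT"); map <- getcov("MAP")
  m_index <- if (!is.na(mat) && !is.na(map) && mat > -10) {
    de_martonne(map, mat)
  } else NA_real_
  ahm <- if (!is.na(mat) && !is.na(map) && map > 0 && mat > -10) {
    annual_heat_moisture(mat, map)
  } else NA_real_
  dh <- if (any(!is.na(tr$height_m))) dominant_height(tr) else NA_real_
  bal <- compute_bal(d, area)
  names(bal) <- rownames(tr)
  structure(list(
    plot_id = plot_id,
    n_trees = nrow(tr),
    qmd_cm = compute_qmd(d),
    md_cm = mean(d),
    ba_m2_ha = sum(tree_basal_area(d)) / area,
    n_per_ha = nrow(tr) / area,
    dh_m = dh,
    sim = simpson_index(counts),
    shi = shannon_index(counts),
    sie = stage$sie, cie = stage$cie,
    m_index = m_index, ahm = ahm,
    bal_by_tree = bal
  ), class = "stand_metrics")
}

#' @export
print.stand_metrics <- function(x, ...) {
  cat(sprintf(
    "stand_metrics for plot %s: %d trees, QMD %.2f cm, MD %.2f cm, BA %.2f m2/ha, SIM %.3f\n",
    x$plot_id, x$n_trees, x$qmd_cm, x$md_cm, x$ba_m2_ha, x$sim))
  invisible(x)
}

#' Per-plot metrics table
#'
#' One row per plot with every scalar stand metric; column names are stable.
#'
#' @inheritParams compute_stand_metrics
#' @return data.frame with one row per plot.
#' @export
plot_metrics_table <- function(ds, min_dbh_cm = 5) {
  rows <- lapply(ds$plots$plot_id, function(p) {
    m <- compute_stand_metrics(ds, p, min_dbh_cm = min_dbh_cm)
    data.frame(plot_id = p, n_trees = m$n_trees, QMD = m$qmd_cm, MD = m$md_cm,
               BA = m$ba_m2_ha, N = m$n_per_ha, DH = m$dh_m, SIM = m$sim,
               SHI = m$shi, SIE = m$sie, CIE = m$cie, M = m$m_index,
               AHM = m$ahm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-tree BAL table
#'
#' @inheritParams compute_stand_metrics
#' @return data.frame with plot_id, species, dbh_cm and BAL (m^2/ha) per tree.
#' @export
tree_bal_table <- function(ds, min_dbh_cm = 5) {
  rows <- lapply(ds$plots$plot_id, function(p) {
    tr <- ds$trees[ds$trees$plot_id == p &
                     !is.na(ds$trees$dbh_cm) &
                     ds$trees$dbh_cm >= min_dbh_cm, , drop = FALSE]
    if (nrow(tr) == 0) return(NULL)
    area <- ds$plots$area_ha[ds$plots$plot_id == p]
    data.frame(plot_id = p, species = tr$species, dbh_cm = tr$dbh_cm,
               BAL = compute_bal(tr$dbh_cm, area), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
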