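# Bedding-plane census maps: one row per fossil specimen (taxon label,
# planar position in metres, optional morphometrics), plus an observation
# window. Files are plain CSV with an optional WKT polygon sidecar.

MORPHO_COLS <- c("disc_width", "disc_length", "disc_orientation",
                 "stem_length", "stem_width", "frond_length", "frond_width")
GROUP_CLASSES <- c("described_taxon", "bin_group", "taphomorph", "organ_taxon")

#' Construct a bedding-plane census map
#'
#' @param records data.frame with at least `taxon`, `x`, `y`; optional
#'   `specimen_id`, `group_class` (one of described_taxon, bin_group,
#'   taphomorph, organ_taxon) and morphometric columns (`disc_width`,
#'   `disc_length`, `disc_orientation`, `stem_length`, `stem_width`,
#'   `frond_length`, `frond_width`), all lengths in metres.
#' @param window an [sppa_window][owin_rect]; defaults to the bounding box of
#'   the records.
#' @param surface_name label for the surface.
#' @param on_outside what to do with records outside the window: `"error"`
#'   (default) or `"drop"`, which drops them with a warning and attaches the
#'   rejected rows as attribute `"rejected"`.
#' @return An object of class `bed_map`.
#' @export
bed_map <- function(records, window = NULL, surface_name = "surface",
                    on_outside = c("error", "drop")) {
  on_outside <- match.arg(on_outside)
  records <- as.data.frame(records)
  if (nrow(records) > 0) {
    for (col in c("taxon", "x", "y"))
      if (is.null(records[[col]]))
        stop_sppa(paste0("missing mandatory column: ", col),
                  "sppa_format_error")
    bad <- !is.finite(records$x) | !is.finite(records$y)
    if (any(bad))
      stop_sppa(paste0("non-finite coordinates at rows: ",
                       paste(which(bad), collapse = ", ")),
                "sppa_parse_error")
    if (any(!nzchar(records$taxon))) stop("empty taxon labels")
  }
  if (is.null(records$specimen_id))
    records$specimen_id <- if (nrow(records)) seq_len(nrow(records)) else integer(0)
  if (anyDuplicated(records$specimen_id))
    stop("specimen_id values must be unique")
  if (is.null(records$group_class))
    records$group_class <- rep("described_taxon", nrow(records))
  if (nrow(records) > 0 && !all(records$group_class %in% GROUP_CLASSES))
    stop("group_class must be one of: ", paste(GROUP_CLASSES, collapse = ", "))
  dims <- intersect(setdiff(MORPHO_COLS, "disc_orientation"), names(records))
  for (col in dims)
    if (any(records[[col]] < 0, na.rm = TRUE))
      stop("negative specimen dimension in column ", col)
  if (is.null(window)) {
    if (nrow(records) == 0) stop("need a window for an empty map")
    pad <- 1e-9
    window <- owin_rect(range(records$x) + c(-pad, pad),
                        range(records$y) + c(-pad, pad))
  }
  rejected <- NULL
  if (nrow(records) > 0) {
    inside <- window_contains(window, records$x, records$y)
    if (!all(inside)) {
      if (on_outside == "error")
        stop_sppa(paste0(sum(!inside), " record(s) outside the window (rows ",
                         paste(head(which(!inside), 10), collapse = ", "), ")"),
                  "sppa_outside_window")
      rejected <- records[!inside, , drop = FALSE]
      warning(sum(!inside), " record(s) outside the window were dropped")
      records <- records[inside, , drop = FALSE]
    }
  }
  out <- structure(list(surface_name = surface_name, records = records,
                        window = window, units = "m"),
                   class = "bed_map")
  attr(out, "rejected") <- rejected
  out
}

#' @export
print.bed_map <- function(x, ...) {
  cat(sprintf("<bed_map '%s': %d specimens, %d taxa, window %.3f m2>\n",
              x$surface_name, nrow(x$records),
              length(unique(x$records$taxon)), window_area(x$window)))
  invisible(x)
}

#' Number of specimens per taxon
#' @param map a `bed_map`.
#' @export
taxon_counts <- function(map) {
  if (nrow(map$records) == 0) return(integer(0))
  sort(table(map$records$taxon), decreasing = TRUE)
}

#' Coordinates of one taxon (or all specimens) as a two-column matrix
#' @param map a `bed_map`.
#' @param taxon taxon label, or `NULL` for all specimens.
#' @export
taxon_points <- function(map, taxon = NULL) {
  rec <- map$records
  if (!is.null(taxon)) rec <- rec[rec$taxon == taxon, , drop = FALSE]
  cbind(x = rec$x, y = rec$y)
}

#' Read a bedding-plane map from CSV
#'
#' Expected columns: `taxon`, `x_m`, `y_m` (or `x`, `y`), optional
#' `specimen_id`, `group_class` and morphometrics. The observation window is
#' taken from (in order of precedence) the `window` argument (an
#' `sppa_window`, a `c(xmin, ymin, xmax, ymax)` bounding box, or a path to a
#' WKT POLYGON file), a `<path>.wkt` sidecar, or the bounding box of the
#' points.
#'
#' @param path CSV file path.
#' @param format_spec optional named character vector remapping non-standard
#'   column names, e.g. `c(taxon = "species", x = "easting", y = "northing")`.
#' @param window see Description.
#' @param surface_name label; defaults to the file name.
#' @param on_outside passed to [bed_map()]; reading defaults to `"drop"` so
#'   out-of-window records are reported, not fatal.
#' @return A `bed_map`.
#' @export
read_surface_map <- function(path, format_spec = NULL, window = NULL,
                             surface_name = NULL, on_outside = "drop") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(format_spec))
    for (std in names(format_spec)) {
      if (!format_spec[[std]] %in% names(df))
        stop_sppa(paste0("mapped column not in file: ", format_spec[[std]]),
                  "sppa_format_error")
      names(df)[names(df) == format_spec[[std]]] <- std
    }
  if ("x_m" %in% names(df)) names(df)[names(df) == "x_m"] <- "x"
  if ("y_m" %in% names(df)) names(df)[names(df) == "y_m"] <- "y"
  if (nrow(df) > 0) {
    for (col in c("taxon", "x", "y"))
      if (is.null(df[[col]]))
        stop_sppa(paste0("missing mandatory column: ", col),
                  "sppa_format_error")
    for (col in c("x", "y")) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      if (any(is.na(v) & !is.na(df[[col]])))
        stop_sppa(paste0("non-numeric ", col, " at row(s): ",
                         paste(which(is.na(v) & !is.na(df[[col]])),
                               collapse = ", ")), "sppa_parse_error")
      df[[col]] <- v
    }
  } else {
    df <- data.frame(taxon = character(0), x = numeric(0), y = numeric(0))
  }
  if (is.null(window)) {
    sidecar <- paste0(path, ".wkt")
    if (file.exists(sidecar)) window <- read_wkt_polygon(sidecar)
  } else if (is.character(window)) {
    window <- read_wkt_polygon(window)
  } else if (is.numeric(window) && length(window) == 4) {
    window <- owin_rect(window[c(1, 3)], window[c(2, 4)])
  }
  if (is.null(surface_name))
    surface_name <- sub("\\.[^.]*$", "", basename(path))
  bed_map(df, window = window, surface_name = surface_name,
          on_outside = on_outside)
}

#' Write a bedding-plane map to CSV (plus WKT window sidecar)
#'
#' Optional morphometric columns that are entirely missing are omitted from
#' the file. The window polygon is written to `<path>.wkt` so that
#' [read_surface_map()] round-trips the map exactly.
#'
#' @param map a `bed_map`.
#' @param path output CSV path.
#' @param window_sidecar write the `<path>.wkt` sidecar (default `TRUE`).
#' @export
write_surface_map <- function(map, path, window_sidecar = TRUE) {
  rec <- map$records
  keep <- c("specimen_id", "taxon", "group_class", "x", "y",
            intersect(MORPHO_COLS, names(rec)))
  rec <- rec[, intersect(keep, names(rec)), drop = FALSE]
  drop <- vapply(rec, function(col) all(is.na(col)), logical(1)) &
    names(rec) %in% MORPHO_COLS
  rec <- rec[, !drop, drop = FALSE]
  names(rec)[names(rec) == "x"] <- "x_m"
  names(rec)[names(rec) == "y"] <- "y_m"
  write.csv(rec, path, row.names = FALSE)
  if (window_sidecar) write_wkt_polygon(map$window, paste0(path, ".wkt"))
  invisible(path)
}

# Minimal WKT POLYGON reader/writer (outer ring only; closed ring; metres).
read_wkt_polygon <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  m <- regmatches(txt, regexpr("POLYGON\\s*\\(\\(([^)]*)\\)\\)", txt))
  if (length(m) == 0) stop_sppa("no POLYGON found in WKT file",
                                "sppa_format_error")
  body <- sub(".*\\(\\(", "", sub("\\)\\).*", "", m))
  pairs <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
  xy <- do.call(rbind, lapply(pairs, as.numeric))
  if (nrow(xy) >= 2 && all(xy[1, ] == xy[nrow(xy), ]))
    xy <- xy[-nrow(xy), , drop = FALSE]
  owin_poly(xy[, 1], xy[, 2])
}

write_wkt_polygon <- function(w, path) {
  v <- w$vertices
  ring <- rbind(v, v[1, , drop = FALSE])
  coords <- paste(sprintf("%.12g %.12g", ring[, 1], ring[, 2]),
                  collapse = ", ")
  writeLines(sprintf("POLYGON ((%s))", coords), path)
  invisible(path)
}

#' Restrict a map to the analysis taxa
#'
#' Removes taphomorphs, organ taxa, bin groups, and described taxa whose
#' abundance falls below the threshold. The census convention is that a taxon
#' is abundant when `n >= abundance_threshold` (the default of 30 retains a
#' taxon with exactly 30 specimens; sparse surfaces may lower the threshold
#' to 16). A per-class removal report is attached as attribute `"removed"`.
#'
#' @param map a `bed_map`.
#' @param abundance_threshold minimum retained abundance (default 30).
#' @return Filtered `bed_map` (idempotent).
#' @export
filter_analysis_taxa <- function(map, abundance_threshold = 30) {
  stopifnot(abundance_threshold >= 1)
  rec <- map$records
  removed <- list()
  for (cls in c("taphomorph", "organ_taxon", "bin_group")) {
    hit <- rec$group_class == cls
    if (any(hit)) removed[[cls]] <- unique(rec$taxon[hit])
    rec <- rec[!hit, , drop = FALSE]
  }
  if (nrow(rec) > 0) {
    counts <- table(rec$taxon)
    rare <- names(counts)[counts < abundance_threshold]
    if (length(rare)) removed[["low_abundance"]] <- rare
    rec <- rec[!(rec$taxon %in% rare), , drop = FALSE]
  }
  out <- bed_map(rec, window = map$window, surface_name = map$surface_name)
  attr(out, "removed") <- removed
  out
}

#' Clip a map to an axis-aligned rectangle
#'
#' @param map a `bed_map`.
#' @param rect numeric `c(xmin, ymin, xmax, ymax)` or an `sppa_window`
#'   rectangle, contained in the window's bounding region.
#' @return A `bed_map` whose window is the rectangle.
#' @export
extract_rect_subwindow <- function(map, rect) {
  if (inherits(rect, "sppa_window")) {
    stopifnot(rect$is_rect)
    w <- rect
  } else {
    stopifnot(length(rect) == 4)
    w <- owin_rect(rect[c(1, 3)], rect[c(2, 4)])
  }
  bb <- window_bbox(map$window)
  if (w$xrange[1] < bb[1] - 1e-9 || w$yrange[1] < bb[2] - 1e-9 ||
      w$xrange[2] > bb[3] + 1e-9 || w$yrange[2] > bb[4] + 1e-9)
    stop("rectangle extends beyond the window's bounding region")
  rec <- map$records
  keep <- window_contains(w, rec$x, rec$y)
  bed_map(rec[keep, , drop = FALSE], window = w,
          surface_name = map$surface_name)
}
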