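#' Ordered coastline survey datasets
#'
#' A coastline dataset is an ordered chain of shoreline survey points, one row
#' per point, carrying projected planar coordinates (meters), continuous
#' environmental predictors (mean sea-surface temperature, mean and minimum
#' wave height), categorical predictors (slope class 1-5, geology, substrate
#' type) and one binary presence/absence column per habitat. Row order is the
#' spatial order along the coast; the `index` column numbers points 0..n-1
#' from the start of the chain (northern end by convention).
#'
#' @param data data.frame with columns `x`, `y`, `sst_avg`, `wh_avg`,
#'   `wh_min`, `slope_class`, `geology`, `substrate`, plus one 0/1 column per
#'   habitat code. An `index` column is added (or rewritten) as 0..n-1.
#' @param habitat_codes character vector naming the habitat columns. Defaults
#'   to the intersection of `names(data)` with the study's standard codes
#'   (`"Riv"`, `"Lby"`, `"Tro"`, `"Neo"`, `"Hph"`, `"Cme"`); shorter lists are
#'   accepted.
#' @param check_chain logical; verify that consecutive points are spatial
#'   near-neighbours (no inter-point gap above 5x the median spacing) and warn
#'   otherwise.
#'
#' @return A `coastline` object: a data.frame with attribute
#'   `habitat_codes`.
#' @export
coastline <- function(data, habitat_codes = NULL, check_chain = TRUE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  if (nrow(data) == 0L) stop("empty dataset: no coastline points")

  required <- c("x", "y", "sst_avg", "wh_avg", "wh_min",
                "slope_class", "geology", "substrate")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(habitat_codes)) {
    habitat_codes <- intersect(standard_habitat_codes(), names(data))
  }
  missing_hab <- setdiff(habitat_codes, names(data))
  if (length(missing_hab) > 0L) {
    stop("missing habitat column(s): ", paste(missing_hab, collapse = ", "))
  }

  # Coerce habitat columns to 0/1 integers; anything else is a data error.
  for (h in habitat_codes) {
    v <- data[[h]]
    if (is.logical(v)) v <- as.integer(v)
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad) > 0L) {
      stop(sprintf("habitat '%s' has non-binary value at row %d", h, bad[1L]))
    }
    data[[h]] <- as.integer(v)
  }

  # Drop rows with missing predictors (count reported).
  pred_na <- rowSums(is.na(data[required])) > 0
  if (any(pred_na)) {
    message(sprintf("dropping %d row(s) with missing predictor values",
                    sum(pred_na)))
    data <- data[!pred_na, , drop = FALSE]
    if (nrow(data) == 0L) stop("all rows had missing predictor values")
  }

  if (!all(data$slope_class %in% 1:5)) {
    stop("slope_class values must be in 1..5")
  }
  data$slope_class <- as.integer(data$slope_class)
  data$geology <- as.character(data$geology)
  data$substrate <- as.character(data$substrate)

  data$index <- seq_len(nrow(data)) - 1L
  rownames(data) <- NULL
  front <- c("index", required)
  data <- data[c(front, setdiff(names(data), front))]

  if (check_chain && nrow(data) > 2L) {
    d <- sqrt(diff(data$x)^2 + diff(data$y)^2)
    med <- stats::median(d)
    if (med > 0 && any(d > 5 * med)) {
      warning(sprintf(
        "%d inter-point gap(s) exceed 5x the median spacing; %s",
        sum(d > 5 * med),
        "rows may not be in coastline order (see order_chain())"))
    }
  }

  structure(data,
            habitat_codes = habitat_codes,
            class = c("coastline", "data.frame"))
}

#' Standard habitat column codes
#'
#' Default habitat identifiers: the five codes used in the source database
#' legend (Riv, Lby, Tro, Neo, Hph) plus `Cme` for the *Cystoseira
#' mediterranea* habitat, whose column code is not given in the legend.
#'
#' @return character vector of length 6.
#' @export
standard_habitat_codes <- function() {
  c("Riv", "Lby", "Tro", "Neo", "Hph", "Cme")
}

#' Habitat codes of a coastline dataset
#' @param data a `coastline` object.
#' @return character vector of habitat column names.
#' @export
habitat_codes <- function(data) attr(data, "habitat_codes")

#' @export
print.coastline <- function(x, n = 6L, ...) {
  cat(sprintf("<coastline> %d points, %d habitat layer(s): %s\n",
              nrow(x), length(habitat_codes(x)),
              paste(habitat_codes(x), collapse = ", ")))
  print(utils::head(as.data.frame(x), n), ...)
  if (nrow(x) > n) cat(sprintf("# ... %d more points\n", nrow(x) - n))
  invisible(x)
}

#' Read a coastline dataset from CSV or XLSX
#'
#' Reads a one-row-per-point table in the study's tabular layout and validates
#' it into a [coastline] object. Column names are mapped through `col_map`, so
#' files with different headers can be ingested without editing them.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"xlsx"`. XLSX requires
#'   the readxl package.
#' @param habitat_codes habitat columns to load (post-mapping names); defaults
#'   to whichever of the standard codes are present.
#' @param col_map named character vector mapping standard names (the names)
#'   to the file's column names (the values), e.g.
#'   `c(sst_avg = "SST_mean")`. Unmapped columns keep their file names.
#' @inheritParams coastline
#' @return a [coastline] object.
#' @export
read_coastline <- function(path, format = c("auto", "csv", "xlsx"),
                           habitat_codes = NULL, col_map = NULL,
                           check_chain = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  df <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading xlsx requires the 'readxl' package")
      }
      as.data.frame(readxl::read_excel(path))
    })
  if (nrow(df) == 0L) stop("empty file: ", path)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      from <- col_map[[std]]
      if (!from %in% names(df)) {
        stop("mapped column not found in file: ", from)
      }
      names(df)[names(df) == from] <- std
    }
  }
  coastline(df, habitat_codes = habitat_codes, check_chain = check_chain)
}

#' Write a coastline dataset to CSV
#'
#' @param data a [coastline] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coastline <- function(data, path) {
  stopifnot(inherits(data, "coastline"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Reorder rows into a nearest-neighbour coastal chain
#'
#' Survey tables exported from GIS are not always in along-shore order. This
#' rebuilds the chain greedily: start at the northernmost point (maximum `y`)
#' and repeatedly step to the nearest unvisited point. Indices are reassigned
#' 0..n-1. Ties (duplicate coordinates) are broken by original row order with
#' a warning. The result is idempotent for data already in chain order with
#' monotone progression.
#'
#' @param data a [coastline] object.
#' @return a [coastline] object with rows permuted into chain order.
#' @export
order_chain <- function(data) {
  stopifnot(inherits(data, "coastline"))
  n <- nrow(data)
  if (n <= 2L) return(data)
  x <- data$x
  y <- data$y
  if (anyDuplicated(cbind(x, y)) > 0L) {
    warning("duplicate coordinates present; ties broken by original row order")
  }
  remaining <- seq_len(n)
  ord <- integer(n)
  # which.max returns the first maximum -> original-order tie-break
  cur <- which.max(y)
  ord[1L] <- cur
  remaining <- remaining[remaining != cur]
  for (i in 2:n) {
    d2 <- (x[remaining] - x[cur])^2 + (y[remaining] - y[cur])^2
    cur <- remaining[which.min(d2)]
    ord[i] <- cur
    remaining <- remaining[remaining != cur]
  }
  out <- as.data.frame(data)[ord, , drop = FALSE]
  coastline(out, habitat_codes = habitat_codes(data), check_chain = FALSE)
}

#' Write a scenario results table to CSV
#'
#' Writes the per-scenario metric table in the layout used for the study's
#' supplementary result tables: one row per habitat x scenario with training
#' sample size and prevalence, explained deviance, AUC, threshold, sensitivity
#' and specificity. Numeric metrics are written with 4 decimals.
#'
#' @param rows data.frame of scenario results (see [run_scenario()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0L) stop("no result rows to write")
  cols <- c("habitat", "strategy", "case", "fraction", "n_train", "F_train",
            "D2", "AUC", "threshold", "sensitivity", "specificity", "status")
  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols) > 0L) {
    stop("result rows missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- rows[cols]
  num4 <- c("fraction", "F_train", "D2", "AUC", "threshold",
            "sensitivity", "specificity")
  for (cc in num4) {
    v <- out[[cc]]
    out[[cc]] <- ifelse(is.na(v), NA, sprintf("%.4f", as.numeric(v)))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a scenario results table written by [write_results()]
#' @param path CSV path.
#' @return data.frame with numeric metric columns.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write coastline points with predictions as GeoJSON
#'
#' Emits a GeoJSON `FeatureCollection` of point features, one per coastline
#' point, carrying any extra columns (e.g. predicted probability and binary
#' class) as properties. Coordinates are written as-is (projected meters).
#'
#' @param points data.frame with `x`, `y` and property columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(points, path) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  props <- setdiff(names(points), c("x", "y"))
  features <- lapply(seq_len(nrow(points)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(points$x[i], points$y[i])),
      properties = as.list(points[i, props, drop = FALSE])
    )
  })
  obj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
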