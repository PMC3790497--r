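#' Localization tables
#'
#' A localization table is the lingua franca of the pipeline: one row per
#' single-molecule localization with the estimated position in nanometres,
#' plus acquisition metadata. Columns follow the canonical dialect
#' `frame, x_nm, y_nm, channel, photons, width_x_nm, width_y_nm, background,
#' uncertainty_nm`; internally the table is a data frame with columns
#' `frame, x, y, channel, photons, width_x, width_y, background, uncertainty`
#' (all lengths in nm).
#'
#' @param records data frame with at least `frame`, `x`, `y`, `channel`;
#'   missing optional columns are filled with defaults (`photons = 1`,
#'   widths 150 nm, `background = 0`, `uncertainty = 0`).
#' @param pixel_size camera pixel size in nm, or `NA` if unknown.
#' @param n_frames declared number of frames in the source movie, or `NA`.
#' @param channels declared channel set; defaults to the channels present.
#' @param provenance free-text note on where the table came from.
#' @return object of class `localization_table` (a data frame).
#' @export
localization_table <- function(records,
                               pixel_size = NA_real_,
                               n_frames = NA_integer_,
                               channels = NULL,
                               provenance = "") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("frame", "x", "y", "channel")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("localization table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  defaults <- list(photons = 1, width_x = 150, width_y = 150,
                   background = 0, uncertainty = 0)
  for (nm in names(defaults)) {
    if (is.null(records[[nm]])) {
      records[[nm]] <- rep(defaults[[nm]], nrow(records))
    }
  }
  records <- records[, c("frame", "x", "y", "channel", "photons",
                         "width_x", "width_y", "background", "uncertainty")]
  records$frame <- as.integer(records$frame)
  records$channel <- as.character(records$channel)
  for (nm in c("x", "y", "photons", "width_x", "width_y",
               "background", "uncertainty")) {
    records[[nm]] <- as.numeric(records[[nm]])
  }
  if (is.null(channels)) channels <- sort(unique(records$channel))

  tab <- structure(records,
                   class = c("localization_table", "data.frame"),
                   pixel_size = pixel_size,
                   n_frames = as.integer(n_frames),
                   channels = channels,
                   provenance = provenance)
  validate_localization_table(tab)
  tab
}

validate_localization_table <- function(tab) {
  if (nrow(tab) > 0L) {
    num <- c("x", "y", "width_x", "width_y", "uncertainty")
    for (nm in num) {
      if (!all(is.finite(tab[[nm]]))) {
        stop("non-finite values in column '", nm, "'", call. = FALSE)
      }
    }
    if (any(tab$photons <= 0)) stop("photons must be > 0", call. = FALSE)
    if (any(tab$frame < 0L)) stop("frame indices must be >= 0", call. = FALSE)
    if (any(tab$uncertainty < 0)) {
      stop("uncertainty must be >= 0", call. = FALSE)
    }
    bad <- setdiff(unique(tab$channel), attr(tab, "channels"))
    if (length(bad) > 0L) {
      stop("channel(s) not in declared channel set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    nf <- attr(tab, "n_frames")
    if (!is.na(nf) && any(tab$frame >= nf)) {
      stop("frame index >= declared frame count", call. = FALSE)
    }
  }
  invisible(tab)
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("<localization_table> %d localizations, %d channel(s): %s\n",
              nrow(x), length(attr(x, "channels")),
              paste(attr(x, "channels"), collapse = ", ")))
  if (nrow(x) > 0L) {
    cat(sprintf("  x: [%.1f, %.1f] nm  y: [%.1f, %.1f] nm\n",
                min(x$x), max(x$x), min(x$y), max(x$y)))
  }
  invisible(x)
}

canonical_loc_columns <- c(frame = "frame", x = "x_nm", y = "y_nm",
                           channel = "channel", photons = "photons",
                           width_x = "width_x_nm", width_y = "width_y_nm",
                           background = "background",
                           uncertainty = "uncertainty_nm")

#' Column-mapping dialect for localization files
#'
#' Describes how the columns of a delimited localization file map onto the
#' canonical fields, and in which units the coordinates are stored.
#'
#' @param columns named character vector mapping canonical field names
#'   (`frame`, `x`, `y`, `channel`, optionally `photons`, `width_x`,
#'   `width_y`, `background`, `uncertainty`) to header names in the file.
#' @param units `"nm"` or `"px"`; pixel-unit coordinates (and widths and
#'   uncertainties) are converted using `pixel_size`.
#' @param pixel_size nm per camera pixel; required when `units = "px"`.
#' @param sep field separator.
#' @export
loc_dialect <- function(columns = canonical_loc_columns,
                        units = c("nm", "px"),
                        pixel_size = NA_real_,
                        sep = ",") {
  units <- match.arg(units)
  required <- c("frame", "x", "y", "channel")
  missing_map <- setdiff(required, names(columns))
  if (length(missing_map) > 0L) {
    stop("dialect must map required column(s): ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  if (units == "px" && !isTRUE(is.finite(pixel_size) && pixel_size > 0)) {
    stop("pixel-unit dialect requires a positive pixel_size", call. = FALSE)
  }
  structure(list(columns = columns, units = units,
                 pixel_size = pixel_size, sep = sep),
            class = "loc_dialect")
}

#' Read a localization table from delimited text
#'
#' @param path file path.
#' @param dialect a [loc_dialect()]; the default reads the canonical dialect
#'   written by [write_localizations()].
#' @param n_frames,provenance metadata passed to [localization_table()].
#' @return a [localization_table()].
#' @export
read_localizations <- function(path, dialect = loc_dialect(),
                               n_frames = NA_integer_, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA)
  cols <- dialect$columns
  missing_cols <- setdiff(unname(cols[c("frame", "x", "y", "channel")]),
                          names(raw))
  if (length(missing_cols) > 0L) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (field in names(cols)) {
    if (cols[[field]] %in% names(raw)) out[[field]] <- raw[[cols[[field]]]]
  }
  for (field in setdiff(names(out), "channel")) {
    v <- out[[field]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      if (anyNA(conv) && !anyNA(v)) {
        bad_row <- which(is.na(conv))[1L]
        stop("non-numeric value in column '", cols[[field]],
             "' at data row ", bad_row, call. = FALSE)
      }
      out[[field]] <- conv
    }
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  px <- dialect$pixel_size
  if (dialect$units == "px") {
    for (field in intersect(c("x", "y", "width_x", "width_y", "uncertainty"),
                            names(out))) {
      out[[field]] <- out[[field]] * px
    }
  }
  localization_table(out, pixel_size = px, n_frames = n_frames,
                     provenance = provenance)
}

#' Write a localization table as canonical delimited text
#'
#' Writes the canonical comma-separated dialect with header
#' `frame,x_nm,y_nm,channel,photons,width_x_nm,width_y_nm,background,uncertainty_nm`.
#' The round trip through [read_localizations()] is lossless.
#'
#' @param table a [localization_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  validate_localization_table(table)
  out <- as.data.frame(table)
  names(out) <- unname(canonical_loc_columns[names(out)])
  ok <- tryCatch({
    utils::write.table(out, path, sep = ",", row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

loc_filter_fields <- c("photons", "uncertainty", "width_x", "width_y",
                       "background", "frame", "channel")

#' Filter a localization table
#'
#' All criteria are combined with AND. Numeric fields take a `c(lo, hi)`
#' range (use `Inf`/`-Inf` for open ends, or a single number meaning a lower
#' bound); `channel` takes a set of channel labels to keep. The mapping
#' pipeline applies no default quality filter — filtering is always explicit.
#'
#' @param table a [localization_table()].
#' @param criteria named list over `photons`, `uncertainty`, `width_x`,
#'   `width_y`, `background`, `frame`, `channel`.
#' @return filtered [localization_table()] with metadata preserved.
#' @export
filter_localizations <- function(table, criteria = list()) {
  validate_localization_table(table)
  unknown <- setdiff(names(criteria), loc_filter_fields)
  if (length(unknown) > 0L) {
    stop("unknown filter field(s): ", paste(unknown, collapse = ", "),
         "; known fields are ", paste(loc_filter_fields, collapse = ", "),
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(table))
  for (field in names(criteria)) {
    crit <- criteria[[field]]
    if (field == "channel") {
      keep <- keep & table$channel %in% crit
    } else {
      if (!is.numeric(crit) || !length(crit) %in% 1:2 || anyNA(crit)) {
        stop("criterion for '", field,
             "' must be a numeric bound or c(lo, hi)", call. = FALSE)
      }
      lo <- crit[1L]
      hi <- if (length(crit) == 2L) crit[2L] else Inf
      keep <- keep & table[[field]] >= lo & table[[field]] <= hi
    }
  }
  out <- table[keep, , drop = FALSE]
  attributes(out)[c("pixel_size", "n_frames", "channels", "provenance")] <-
    attributes(table)[c("pixel_size", "n_frames", "channels", "provenance")]
  class(out) <- class(table)
  out
}
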