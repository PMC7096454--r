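#' Localization tables
#'
#' A localization table is the atomic input of the pipeline: one point set
#' per staining round and spectral channel, with world coordinates in
#' nanometres.  Internally it is a `data.frame` with columns
#' `x_nm`, `y_nm`, `z_nm`, `frame`, `intensity` and attributes carrying the
#' acquisition metadata (staining round, channel, target name, field extent
#' and total frame count).
#'
#' Conventions: world units are nm throughout; the image convention is
#' x to the right and y downwards; frames are 0-based; staining rounds are
#' 1-based (round 1 = "SR1").
#'
#' @param records data.frame with columns `x_nm`, `y_nm`, `z_nm`, `frame`,
#'   `intensity` (missing `z_nm`/`intensity` columns are filled with 0/1).
#' @param round_index staining-round number, integer >= 1.
#' @param channel spectral channel label (e.g. "Ch1").
#' @param target protein / label name.
#' @param field_extent numeric length 2, field width and height in nm.
#' @param n_frames total number of acquisition frames (frames are 0-based,
#'   so all `frame` values must be `< n_frames`).
#'
#' @return An object of class `loc_table` (a data.frame).
#' @export
loc_table <- function(records,
                      round_index = 1L,
                      channel = "Ch1",
                      target = "unknown",
                      field_extent = NULL,
                      n_frames = 20000L) {
  records <- as.data.frame(records)
  if (is.null(records$z_nm)) records$z_nm <- 0
  if (is.null(records$intensity)) records$intensity <- 1
  need <- c("x_nm", "y_nm", "z_nm", "frame", "intensity")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("localization records lack mandatory column(s): ",
         paste(miss, collapse = ", "))
  records <- records[need]
  if (is.null(field_extent)) {
    field_extent <- c(
      max(records$x_nm, 1, na.rm = TRUE),
      max(records$y_nm, 1, na.rm = TRUE)
    )
  }
  obj <- structure(records,
    class = c("loc_table", "data.frame"),
    round_index = as.integer(round_index),
    channel = as.character(channel),
    target = as.character(target),
    field_extent = as.numeric(field_extent),
    n_frames = as.integer(n_frames)
  )
  validate_loc_table(obj)
  obj
}

#' Validate a localization table
#'
#' Checks the invariants: finite x/y, integer frames in `[0, n_frames)`,
#' non-negative intensities, and records within the field extent.
#'
#' @param x a `loc_table`.
#' @param strict_extent error (TRUE) or warn (FALSE, default) when records
#'   fall outside the field extent; registration shifts legitimately move
#'   points slightly out of the nominal field.
#' @return `x`, invisibly.
#' @export
validate_loc_table <- function(x, strict_extent = FALSE) {
  stopifnot(inherits(x, "loc_table"))
  if (nrow(x)) {
    if (!all(is.finite(x$x_nm)) || !all(is.finite(x$y_nm)))
      stop("non-finite x/y coordinates in localization table")
    if (any(x$frame < 0) || any(x$frame != floor(x$frame)))
      stop("frame indices must be integers >= 0")
    if (any(x$frame >= attr(x, "n_frames")))
      stop("frame index beyond n_frames")
    if (any(x$intensity < 0))
      stop("negative intensities in localization table")
    fe <- attr(x, "field_extent")
    out <- x$x_nm < 0 | x$x_nm > fe[1] | x$y_nm < 0 | x$y_nm > fe[2]
    if (any(out)) {
      msg <- sprintf("%d localization(s) outside field extent", sum(out))
      if (strict_extent) stop(msg) else warning(msg, call. = FALSE)
    }
  }
  if (attr(x, "round_index") < 1L) stop("round_index must be >= 1")
  invisible(x)
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf(
    "<loc_table> %d localizations | SR%d %s | target '%s' | %g x %g nm | %d frames\n",
    nrow(x), attr(x, "round_index"), attr(x, "channel"), attr(x, "target"),
    attr(x, "field_extent")[1], attr(x, "field_extent")[2],
    attr(x, "n_frames")
  ))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

loc_meta <- function(x) {
  list(
    round_index = attr(x, "round_index"), channel = attr(x, "channel"),
    target = attr(x, "target"), field_extent = attr(x, "field_extent"),
    n_frames = attr(x, "n_frames")
  )
}

#' Read a localization table from delimited text
#'
#' Two dialects are supported: `"csv-header"`, a comma-separated file with
#' header `x_nm,y_nm,z_nm,frame,intensity` (the package's own writer
#' format; extra columns are ignored), and `"rapidstorm-txt"`,
#' whitespace-delimited columns with a `#`-comment header line naming the
#' fields; only x/y/z/frame/intensity (identified by name fragments
#' "x", "y", "z", "frame"/"ImageNumber", "intensity"/"Amplitude") are
#' mapped, other columns are ignored.
#'
#' Rows with non-finite or missing x/y/frame values are dropped, counted
#' and reported via a message and the `n_bad_rows` attribute — never
#' silently.
#'
#' @param path file to read.
#' @param dialect `"csv-header"` or `"rapidstorm-txt"`.
#' @inheritParams loc_table
#' @return a [loc_table()] with attribute `n_bad_rows`.
#' @export
read_localizations <- function(path, dialect = c("csv-header", "rapidstorm-txt"),
                               round_index = 1L, channel = "Ch1",
                               target = "unknown", field_extent = NULL,
                               n_frames = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "csv-header") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(df) <- sub("^x$", "x_nm", sub("^y$", "y_nm", sub("^z$", "z_nm", names(df))))
  } else {
    lines <- readLines(path, warn = FALSE)
    hdr <- grep("^#", lines, value = TRUE)
    body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    if (!length(body)) stop("empty localization file: ", path)
    cols <- if (length(hdr)) strsplit(trimws(sub("^#+\\s*", "", hdr[1])), "\\s+")[[1]] else NULL
    df <- utils::read.table(text = body, header = FALSE, stringsAsFactors = FALSE)
    if (!is.null(cols) && length(cols) == ncol(df)) names(df) <- cols
    pick <- function(patterns) {
      for (p in patterns) {
        j <- grep(p, names(df), ignore.case = TRUE)
        if (length(j)) return(j[1])
      }
      NA_integer_
    }
    jx <- pick(c("^x", "Position-0")); jy <- pick(c("^y", "Position-1"))
    jz <- pick(c("^z", "Position-2"))
    jf <- pick(c("frame", "ImageNumber")); ji <- pick(c("intensity", "Amplitude"))
    if (is.na(jx) || is.na(jy) || is.na(jf)) {
      # no usable header: assume canonical column order x y z frame intensity
      if (ncol(df) < 4) stop("format error: cannot identify x/y/frame columns")
      jx <- 1; jy <- 2; jz <- if (ncol(df) >= 5) 3 else NA
      jf <- if (ncol(df) >= 5) 4 else 3
      ji <- if (ncol(df) >= 5) 5 else NA
    }
    df <- data.frame(
      x_nm = as.numeric(df[[jx]]), y_nm = as.numeric(df[[jy]]),
      z_nm = if (!is.na(jz)) as.numeric(df[[jz]]) else 0,
      frame = as.numeric(df[[jf]]),
      intensity = if (!is.na(ji)) as.numeric(df[[ji]]) else 1
    )
  }
  for (col in c("x_nm", "y_nm", "frame")) {
    if (is.null(df[[col]]))
      stop(sprintf("format error: missing mandatory column '%s' in %s", col, path))
  }
  if (!nrow(df)) stop("empty localization table in file: ", path)
  if (is.null(df$z_nm)) df$z_nm <- 0
  if (is.null(df$intensity)) df$intensity <- 1
  suppressWarnings({
    for (col in names(df)) df[[col]] <- as.numeric(df[[col]])
  })
  ok <- is.finite(df$x_nm) & is.finite(df$y_nm) & is.finite(df$frame)
  n_bad <- sum(!ok)
  if (n_bad > 0)
    message(sprintf("read_localizations: dropped %d malformed row(s) from %s",
                    n_bad, path))
  df <- df[ok, , drop = FALSE]
  if (!nrow(df)) stop("no valid localizations in file: ", path)
  if (is.null(n_frames)) n_frames <- max(df$frame) + 1L
  out <- loc_table(df, round_index = round_index, channel = channel,
                   target = target, field_extent = field_extent,
                   n_frames = n_frames)
  attr(out, "n_bad_rows") <- n_bad
  out
}

#' Write a localization table as CSV
#'
#' Writes the documented header `x_nm,y_nm,z_nm,frame,intensity` followed by
#' one line per localization.  Coordinates are printed with fixed 6-decimal
#' precision (1e-6 nm), which makes the writer idempotent: re-writing a
#' table read back from disk reproduces the file byte for byte.
#'
#' @param table a [loc_table()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  stopifnot(inherits(table, "loc_table"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines("x_nm,y_nm,z_nm,frame,intensity", con)
  if (nrow(table)) {
    writeLines(sprintf("%.6f,%.6f,%.6f,%d,%.6f",
                       table$x_nm, table$y_nm, table$z_nm,
                       as.integer(table$frame), table$intensity), con)
  }
  invisible(path)
}
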