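#' Pen recordings
#'
#' A pen recording is a tibble with one row per sample and columns
#' `t` (seconds), `x`, `y` (millimetres) and `contact` (logical pen-surface
#' contact). Times are strictly increasing. The coordinate convention is
#' x rightward, y upward, origin at the sheet lower-left (a y-down source can
#' declare itself in the file header and is flipped on read). Metadata
#' (identifier, device label, nominal sampling rate) is carried in the
#' `"meta"` attribute.
#'
#' @param t,x,y Numeric vectors: time in seconds, position in mm.
#' @param contact Logical (or 0/1, or pressure: any value > 0 is contact).
#' @param meta Named list of metadata (`id`, `device`, `fs`).
#' @return A tibble of class `rey_recording`.
#' @examples
#' rec <- recording(t = 0:4 / 100, x = 0:4, y = rep(0, 5),
#'                  contact = c(1, 1, 0, 1, 1))
#' segment_strokes(rec)
#' @export
recording <- function(t, x, y, contact, meta = list()) {
  contact <- as_contact(contact)
  rec <- tibble::tibble(t = as.numeric(t), x = as.numeric(x),
                        y = as.numeric(y), contact = contact)
  validate_recording(rec)
  attr(rec, "meta") <- utils::modifyList(list(id = NA_character_,
                                              device = NA_character_,
                                              fs = NA_real_), meta)
  class(rec) <- c("rey_recording", class(tibble::tibble()))
  rec
}

as_contact <- function(contact) {
  if (is.logical(contact)) return(contact)
  as.numeric(contact) > 0
}

validate_recording <- function(rec) {
  need <- c("t", "x", "y", "contact")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0) {
    stop("recording is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(rec$t)) || any(rec$t < 0)) {
    stop("sample times must be finite and non-negative", call. = FALSE)
  }
  bad <- which(diff(rec$t) <= 0)
  if (length(bad) > 0) {
    stop("sample times must be strictly increasing (first violation at row ",
         bad[1] + 1, ")", call. = FALSE)
  }
  if (any(!is.finite(rec$x)) || any(!is.finite(rec$y))) {
    stop("positions must be finite", call. = FALSE)
  }
  invisible(rec)
}

#' Read a pen recording from a delimited text file
#'
#' The native dialect is a CSV with header `t,x,y,contact` (seconds, mm, mm,
#' 0/1 or pressure), optionally preceded by `#`-comment header lines of the
#' form `# key: value`. Recognised header keys: `id`, `device`, `fs`
#' (nominal rate, Hz), `y_axis` (`up`, the default, or `down`, in which case
#' y is flipped to the y-up convention on read), `sheet_height` (mm, used for
#' the y-down flip; default 297).
#'
#' A structured-text (JSON) variant carries the same fields:
#' `{"meta": {...}, "samples": {"t": [...], "x": [...], "y": [...],
#' "contact": [...]}}`.
#'
#' @param path File path.
#' @param dialect Format tag: `"csv"` (default) or `"json"`.
#' @return A [recording()].
#' @export
read_recording <- function(path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    s <- obj$samples
    miss <- setdiff(c("t", "x", "y", "contact"), names(s))
    if (length(miss) > 0) {
      stop("recording file ", path, " is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    return(recording(s$t, s$x, s$y, s$contact, meta = as.list(obj$meta)))
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- parse_comment_header(hdr)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  miss <- setdiff(c("t", "x", "y", "contact"), names(df))
  if (length(miss) > 0) {
    stop("recording file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  y <- df$y
  if (identical(meta$y_axis, "down")) {
    sheet <- if (!is.null(meta$sheet_height)) as.numeric(meta$sheet_height) else 297
    y <- sheet - y
  }
  recording(df$t, df$x, y, df$contact,
            meta = meta[intersect(names(meta), c("id", "device", "fs"))])
}

parse_comment_header <- function(hdr) {
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      key <- m[2]
      val <- trimws(m[3])
      if (key == "fs") val <- as.numeric(val)
      meta[[key]] <- val
    }
  }
  meta
}

#' Write a pen recording
#'
#' Writes the native CSV dialect read by [read_recording()]. Coordinates and
#' times are written with 6 decimal places, which round-trips bit-exactly at
#' the declared precision.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @param dialect `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  validate_recording(rec)
  meta <- attr(rec, "meta")
  if (dialect == "json") {
    jsonlite::write_json(
      list(meta = meta[!vapply(meta, function(v) is.null(v) || all(is.na(v)),
                               logical(1))],
           samples = list(t = round(rec$t, 6), x = round(rec$x, 6),
                          y = round(rec$y, 6),
                          contact = as.integer(rec$contact))),
      path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path, call. = FALSE)
  on.exit(close(con))
  for (key in c("id", "device", "fs")) {
    val <- meta[[key]]
    if (!is.null(val) && !is.na(val)) writeLines(sprintf("# %s: %s", key, val), con)
  }
  writeLines("t,x,y,contact", con)
  if (nrow(rec) > 0) {
    writeLines(sprintf("%.6f,%.6f,%.6f,%d", rec$t, rec$x, rec$y,
                       as.integer(rec$contact)), con)
  }
  invisible(path)
}

#' Segment a recording into substrokes
#'
#' A raw stroke is a maximal run of contact samples (pen-down to the next
#' pen-up). Initially every stroke is a single substroke; [split_substroke()]
#' refines the table when one pen trace implements several figure elements.
#'
#' @param rec A [recording()].
#' @return A tibble with columns `substroke_id`, `stroke_id`, `start`, `end`
#'   (inclusive sample indices into `rec`), `t_on`, `t_off`. Ordered by onset;
#'   zero rows when the recording has no contact samples.
#' @export
segment_strokes <- function(rec) {
  validate_recording(rec)
  r <- rle(rec$contact)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  starts <- starts[keep]
  ends <- ends[keep]
  tibble::tibble(
    substroke_id = seq_along(starts),
    stroke_id = seq_along(starts),
    start = as.integer(starts),
    end = as.integer(ends),
    t_on = rec$t[starts],
    t_off = rec$t[ends]
  )
}

#' Split one substroke in two
#'
#' The boundary sample is assigned to the earlier part (deterministic
#' tie-break). Substroke ids are renumbered to reflect drawing order.
#'
#' @param subs Substroke table from [segment_strokes()].
#' @param id Substroke id to split.
#' @param boundary Sample index strictly inside the substroke's range.
#' @param rec The parent [recording()] (for onset/offset times).
#' @return The substroke table with `id` replaced by two contiguous rows.
#' @export
split_substroke <- function(subs, id, boundary, rec) {
  row <- which(subs$substroke_id == id)
  if (length(row) != 1) stop("no substroke with id ", id, call. = FALSE)
  s <- subs$start[row]
  e <- subs$end[row]
  if (!(boundary > s && boundary < e)) {
    stop("split boundary must lie strictly inside (", s, ", ", e, ")",
         call. = FALSE)
  }
  first <- subs[row, ]
  second <- subs[row, ]
  first$end <- as.integer(boundary)
  second$start <- as.integer(boundary + 1)
  first$t_off <- rec$t[boundary]
  second$t_on <- rec$t[boundary + 1]
  out <- dplyr::bind_rows(subs[-row, , drop = FALSE], first, second)
  out <- out[order(out$t_on), ]
  out$substroke_id <- seq_len(nrow(out))
  out
}

#' Resample each contact run onto a uniform time grid
#'
#' Each pen-down run is linearly interpolated independently onto a grid at
#' `fs`; pen-up gaps are preserved as gaps (no interpolation across a pen
#' lift). A single non-contact sample is kept between runs so downstream
#' segmentation still sees the pen-up events. Runs need at least 2 samples.
#'
#' @param rec A [recording()].
#' @param fs Target rate, Hz. Must exceed twice the 7 Hz smoothing cut-off.
#' @return A resampled [recording()].
#' @export
resample_uniform <- function(rec, fs = 100) {
  if (fs < 14) {
    stop("resampling rate must be at least twice the 7 Hz filter cut-off",
         call. = FALSE)
  }
  validate_recording(rec)
  subs <- segment_strokes(rec)
  if (nrow(subs) == 0) return(rec)
  pieces <- vector("list", 2 * nrow(subs))
  for (i in seq_len(nrow(subs))) {
    idx <- subs$start[i]:subs$end[i]
    if (length(idx) < 2) stop("contact run ", i, " has fewer than 2 samples",
                              call. = FALSE)
    tt <- rec$t[idx]
    grid <- seq(tt[1], tt[length(tt)], by = 1 / fs)
    if (grid[length(grid)] < tt[length(tt)] - 1e-12) {
      grid <- c(grid, tt[length(tt)])
    }
    pieces[[2 * i - 1]] <- tibble::tibble(
      t = grid,
      x = stats::approx(tt, rec$x[idx], xout = grid)$y,
      y = stats::approx(tt, rec$y[idx], xout = grid)$y,
      contact = TRUE
    )
    if (i < nrow(subs)) {
      # one pen-up marker between runs, at the lift position
      gap_t <- (subs$t_off[i] + subs$t_on[i + 1]) / 2
      pieces[[2 * i]] <- tibble::tibble(
        t = gap_t, x = rec$x[subs$end[i]], y = rec$y[subs$end[i]],
        contact = FALSE
      )
    }
  }
  out <- dplyr::bind_rows(pieces)
  recording(out$t, out$x, out$y, out$contact, meta = utils::modifyList(
    as.list(attr(rec, "meta")), list(fs = fs)))
}

#' @export
print.rey_recording <- function(x, ...) {
  meta <- attr(x, "meta")
  n_runs <- nrow(segment_strokes(x))
  cat(sprintf("<rey_recording: %d samples, %d stroke(s)%s>\n", nrow(x), n_runs,
              if (!is.null(meta$id) && !is.na(meta$id)) paste0(", id=", meta$id) else ""))
  NextMethod()
}
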