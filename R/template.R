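#' The canonical reference figure
#'
#' The Rey Complex Figure is decomposed into 48 basic elements (44 line
#' segments, 3 points and one circle), grouped into the 18 classical
#' geometric units and into 4 constitutive structures: the base rectangle,
#' the main substructure (diagonals and medians), the outer configurations
#' and the inner details. Elements of the base rectangle and main
#' substructure carry primary relevance; the rest secondary.
#'
#' The published figure fixes the taxonomy but not coordinates, so the
#' geometry here is the package's own canonical layout: base rectangle
#' 80 x 56 mm centred at the origin, all sub-figures placed to match the
#' conventional proportions, millimetre units, y up. Point/circle elements
#' occupy ids 25-28, so the linear elements are exactly ids 1-24 and 29-48.
#'
#' @return A tibble with one row per element: `id`, `kind` (`segment`,
#'   `point`, `circle`), geometry columns (`x1`,`y1`,`x2`,`y2` for segments;
#'   `x1`,`y1` for points; `x1`,`y1`,`r` for circles), `unit` (1-18),
#'   `structure`, `linear`, `relevance` (derived: primary iff the structure
#'   is the base rectangle or main substructure).
#' @examples
#' tpl <- canonical_template()
#' dplyr::count(tpl, structure)
#' @export
canonical_template <- function() {
  seg <- function(id, x1, y1, x2, y2, unit, structure) {
    tibble::tibble(id = id, kind = "segment", x1 = x1, y1 = y1, x2 = x2,
                   y2 = y2, r = NA_real_, unit = unit, structure = structure)
  }
  pnt <- function(id, x, y, unit, structure) {
    tibble::tibble(id = id, kind = "point", x1 = x, y1 = y, x2 = NA_real_,
                   y2 = NA_real_, r = NA_real_, unit = unit, structure = structure)
  }
  circ <- function(id, x, y, r, unit, structure) {
    tibble::tibble(id = id, kind = "circle", x1 = x, y1 = y, x2 = NA_real_,
                   y2 = NA_real_, r = r, unit = unit, structure = structure)
  }
  BR <- "base_rectangle"; MS <- "main_substructure"
  OC <- "outer_configuration"; ID <- "inner_detail"

  # hatching in the upper-left quadrant ends on the descending diagonal
  hx <- function(y) -40 + (28 - y) * 80 / 56
  # descending diagonal in the lower-right quadrant
  dy <- function(x) 28 - 0.7 * (x + 40)
  u <- c(0.8192319, -0.5734623)   # unit vector along the descending diagonal
  p <- c(0.5734623, 0.8192319)    # its perpendicular
  hatch12 <- function(id, x0, half) {
    y0 <- dy(x0)
    seg(id, x0 - half * p[1], y0 - half * p[2],
        x0 + half * p[1], y0 + half * p[2], 12, ID)
  }

  tpl <- dplyr::bind_rows(
    # base rectangle (unit 2)
    seg(1, -40, 28, 40, 28, 2, BR),
    seg(2, 40, 28, 40, -28, 2, BR),
    seg(3, 40, -28, -40, -28, 2, BR),
    seg(4, -40, -28, -40, 28, 2, BR),
    # diagonal cross (unit 3), horizontal and vertical medians (units 4, 5)
    seg(5, -40, 28, 40, -28, 3, MS),
    seg(6, -40, -28, 40, 28, 3, MS),
    seg(7, -40, 0, 40, 0, 4, MS),
    seg(8, 0, 28, 0, -28, 5, MS),
    # outer cross, upper left (unit 1): bar, crossbar, attachment stem
    seg(9, -32, 36, -32, 48, 1, OC),
    seg(10, -38, 42, -26, 42, 1, OC),
    seg(11, -32, 28, -32, 36, 1, OC),
    # four parallel hatching lines, upper-left quadrant (unit 8)
    seg(12, -40, 24.5, hx(24.5), 24.5, 8, ID),
    seg(13, -40, 21.0, hx(21.0), 21.0, 8, ID),
    seg(14, -40, 17.5, hx(17.5), 17.5, 8, ID),
    seg(15, -40, 14.0, hx(14.0), 14.0, 8, ID),
    # small triangle above the upper right (unit 9)
    seg(16, 12, 28, 20, 36, 9, OC),
    seg(17, 20, 36, 28, 28, 9, OC),
    # short vertical line hanging from the top edge below it (unit 10)
    seg(18, 20, 28, 20, 20, 10, ID),
    # small rectangle with diagonals, lower left (unit 6)
    seg(19, -30, -4, -10, -4, 6, ID),
    seg(20, -10, -4, -10, -24, 6, ID),
    seg(21, -10, -24, -30, -24, 6, ID),
    seg(22, -30, -24, -30, -4, 6, ID),
    seg(23, -30, -4, -10, -24, 6, ID),
    seg(24, -30, -24, -10, -4, 6, ID),
    # circle with three dots, upper right quadrant (unit 11)
    pnt(25, 28.5, 17.5, 11, ID),
    pnt(26, 31.5, 17.5, 11, ID),
    pnt(27, 30.0, 14.5, 11, ID),
    circ(28, 30, 16, 4, 11, ID),
    # short line above the small rectangle (unit 7)
    seg(29, -26, -4.5, -14, -4.5, 7, ID),
    # five parallel lines crossing the descending diagonal (unit 12)
    hatch12(30, 8, 4),
    hatch12(31, 14, 4),
    hatch12(32, 20, 4),
    hatch12(33, 26, 4),
    hatch12(34, 32, 4),
    # right-hand triangle (unit 13) and its interior lines (units 15, 16)
    seg(35, 40, 28, 56, 0, 13, OC),
    seg(36, 56, 0, 40, -28, 13, OC),
    seg(37, 56, 0, 62, 6, 14, OC),
    seg(38, 62, 6, 68, 0, 14, OC),
    seg(39, 68, 0, 62, -6, 14, OC),
    seg(40, 62, -6, 56, 0, 14, OC),
    seg(41, 48, 14, 48, -14, 15, ID),
    seg(42, 40, 0, 56, 0, 16, ID),
    # cross below the bottom edge (unit 17): stem, bar, crossbar
    seg(43, -12, -28, -12, -36, 17, OC),
    seg(44, -12, -36, -12, -44, 17, OC),
    seg(45, -18, -40, -6, -40, 17, OC),
    # square attached outside the lower-left corner (unit 18)
    seg(46, -40, -14, -54, -14, 18, OC),
    seg(47, -54, -14, -54, -28, 18, OC),
    seg(48, -54, -28, -40, -28, 18, OC)
  )
  tpl$linear <- tpl$kind == "segment"
  tpl$relevance <- ifelse(tpl$structure %in% c(BR, MS), "primary", "secondary")
  validate_template(tpl)
  tpl
}

#' Validate a template table
#'
#' Checks every structural invariant of the reference figure and reports all
#' violations at once: 48 unique ids, 44 segments + 3 points + 1 circle,
#' units covering 1-18 with none empty, every element in exactly one of the
#' four structures, the linear flag consistent with kind, segment endpoints
#' distinct, and relevance consistent with structure.
#'
#' @param tpl A template tibble.
#' @return `tpl`, invisibly; errors with all violations otherwise.
#' @export
validate_template <- function(tpl) {
  problems <- character()
  note <- function(...) problems <<- c(problems, sprintf(...))
  if (nrow(tpl) != 48) note("expected 48 elements, found %d", nrow(tpl))
  missing_ids <- setdiff(1:48, tpl$id)
  if (length(missing_ids) > 0) {
    note("missing element id(s): %s", paste(missing_ids, collapse = ", "))
  }
  if (anyDuplicated(tpl$id)) {
    note("duplicate element id(s): %s",
         paste(unique(tpl$id[duplicated(tpl$id)]), collapse = ", "))
  }
  kinds <- table(factor(tpl$kind, levels = c("segment", "point", "circle")))
  if (!identical(as.integer(kinds), c(44L, 3L, 1L))) {
    note("expected 44 segments, 3 points, 1 circle; found %d/%d/%d",
         kinds[["segment"]], kinds[["point"]], kinds[["circle"]])
  }
  empty_units <- setdiff(1:18, tpl$unit)
  if (length(empty_units) > 0) {
    note("empty unit(s): %s", paste(empty_units, collapse = ", "))
  }
  ok_struct <- c("base_rectangle", "main_substructure", "outer_configuration",
                 "inner_detail")
  if (!all(tpl$structure %in% ok_struct)) note("unknown structure label")
  if ("linear" %in% names(tpl) && !identical(tpl$linear, tpl$kind == "segment")) {
    note("linear flag must hold exactly for segments")
  }
  segs <- tpl[tpl$kind == "segment", ]
  degen <- segs$id[segs$x1 == segs$x2 & segs$y1 == segs$y2]
  if (length(degen) > 0) {
    note("segment(s) with coincident endpoints: %s", paste(degen, collapse = ", "))
  }
  if ("relevance" %in% names(tpl)) {
    want <- ifelse(tpl$structure %in% c("base_rectangle", "main_substructure"),
                   "primary", "secondary")
    if (!identical(tpl$relevance, want)) note("relevance must derive from structure")
  }
  if (length(problems) > 0) {
    stop("invalid template:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(tpl)
}

#' Load a template from a structured text file
#'
#' The file is a CSV with the same columns as [canonical_template()] minus
#' the derived `linear`/`relevance` columns, which are re-derived on load.
#' The shipped canonical file is at
#' `system.file("extdata", "rcf_template.csv", package = "reyscore")`.
#'
#' @param path CSV path; default the shipped canonical file.
#' @return A validated template tibble.
#' @export
load_template <- function(path = system.file("extdata", "rcf_template.csv",
                                             package = "reyscore")) {
  df <- utils::read.csv(path, comment.char = "#")
  tpl <- tibble::as_tibble(df)
  tpl$linear <- tpl$kind == "segment"
  tpl$relevance <- ifelse(tpl$structure %in% c("base_rectangle", "main_substructure"),
                          "primary", "secondary")
  validate_template(tpl)
  tpl
}

#' Write a template to its structured text form
#'
#' @param tpl Template tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_template <- function(tpl, path) {
  validate_template(tpl)
  out <- tpl[, c("id", "kind", "x1", "y1", "x2", "y2", "r", "unit", "structure")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Template checksum
#'
#' A deterministic digest of the element geometry (coordinates rounded to
#' 1e-6 mm) recorded in score reports so scores remain traceable to the
#' exact reference figure used.
#'
#' @param tpl Template tibble.
#' @return A character scalar.
#' @export
template_checksum <- function(tpl) {
  geo <- tpl[order(tpl$id),
             c("id", "kind", "x1", "y1", "x2", "y2", "r", "unit", "structure")]
  txt <- paste(apply(geo, 1, function(row) paste(row, collapse = "|")),
               collapse = ";")
  # polynomial rolling hash mod a Mersenne prime; stable across platforms
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Audit geometric connectivity of a template
#'
#' Checks that the figure's elements form a single connected component:
#' every element lies within `tol` of at least one other element and the
#' contact graph is connected. Segment-segment distance is exact; the circle
#' is treated as a disk so the interior dots count as attached to it.
#'
#' @param tpl Template tibble.
#' @param tol Contact tolerance in mm.
#' @return A list with `connected` (logical), `n_components`, and
#'   `component` (integer component label per element id).
#' @export
template_connectivity <- function(tpl, tol = 1) {
  n <- nrow(tpl)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adj[i, j] <- adj[j, i] <-
        element_distance(tpl[i, ], tpl[j, ]) <= tol
    }
  }
  comp <- integer(n)
  cur <- 0
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cur <- cur + 1
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0))
    }
  }
  list(connected = max(comp) == 1, n_components = max(comp),
       component = stats::setNames(comp, tpl$id))
}

element_distance <- function(a, b) {
  if (a$kind == "circle" || b$kind == "circle") {
    if (a$kind != "circle") { tmp <- a; a <- b; b <- tmp }
    ctr <- c(a$x1, a$y1)
    d <- switch(b$kind,
      point = sqrt(sum((c(b$x1, b$y1) - ctr)^2)),
      segment = point_segment_distance(ctr, c(b$x1, b$y1), c(b$x2, b$y2)),
      circle = sqrt(sum((c(b$x1, b$y1) - ctr)^2)))
    return(max(0, d - a$r))  # disk: interior counts as distance 0
  }
  if (a$kind == "point" && b$kind == "point") {
    return(sqrt((a$x1 - b$x1)^2 + (a$y1 - b$y1)^2))
  }
  if (a$kind == "point") { tmp <- a; a <- b; b <- tmp }
  if (b$kind == "point") {
    return(point_segment_distance(c(b$x1, b$y1), c(a$x1, a$y1), c(a$x2, a$y2)))
  }
  segment_segment_distance(c(a$x1, a$y1), c(a$x2, a$y2),
                           c(b$x1, b$y1), c(b$x2, b$y2))
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  tt <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((a + tt * ab - p)^2))
}

segments_intersect <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0 && d3 * d4 < 0)
}

segment_segment_distance <- function(p1, p2, q1, q2) {
  if (segments_intersect(p1, p2, q1, q2)) return(0)
  min(point_segment_distance(p1, q1, q2), point_segment_distance(p2, q1, q2),
      point_segment_distance(q1, p1, p2), point_segment_distance(q2, p1, p2))
}
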