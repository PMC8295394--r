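#' Label categories
#'
#' Each substroke carries one label: it implements one of the 48 basic
#' elements (`element`), an `incomplete` or `repeated` rendition of an
#' element, or it is `unclassified` (unrecognisable). Only `unclassified`
#' carries no element id.
#'
#' @name labels
NULL

label_categories <- c("element", "incomplete", "repeated", "unclassified")

#' Attach labels to a substroke table
#'
#' Validates the label table against the substroke table (keys must match
#' exactly) and returns the joined classification with per-category counts
#' as an attribute.
#'
#' @param subs Substroke table from [segment_strokes()].
#' @param labels A tibble with columns `substroke_id`, `category`
#'   (one of element/incomplete/repeated/unclassified) and `element_id`
#'   (1-48; NA iff unclassified).
#' @return A classification tibble: the substroke table joined with its
#'   labels, ordered by onset.
#' @export
apply_labels <- function(subs, labels) {
  stopifnot(all(c("substroke_id", "category", "element_id") %in% names(labels)))
  missing <- setdiff(subs$substroke_id, labels$substroke_id)
  if (length(missing) > 0) {
    stop("label table is missing substroke id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(labels$substroke_id, subs$substroke_id)
  if (length(unknown) > 0) {
    stop("label table refers to unknown substroke id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(labels$substroke_id)) {
    stop("each substroke must be labeled exactly once", call. = FALSE)
  }
  bad_cat <- setdiff(unique(labels$category), label_categories)
  if (length(bad_cat) > 0) {
    stop("unknown label category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  uncl <- labels$category == "unclassified"
  if (any(!is.na(labels$element_id[uncl]))) {
    stop("unclassified labels must not carry an element id", call. = FALSE)
  }
  if (any(is.na(labels$element_id[!uncl])) ||
      any(!labels$element_id[!uncl] %in% 1:48)) {
    stop("classified labels need an element id in 1-48", call. = FALSE)
  }
  cls <- dplyr::left_join(subs, labels, by = "substroke_id")
  cls <- cls[order(cls$t_on), ]
  attr(cls, "category_counts") <- table(factor(cls$category,
                                               levels = label_categories))
  cls
}

#' Read / write a label table
#'
#' Delimited text with header `substroke_id,category,element_id`; the format
#' emitted by the simulator and consumed by the scoring pipeline.
#'
#' @param path File path.
#' @return A label tibble.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path)
  tibble::tibble(substroke_id = as.integer(df$substroke_id),
                 category = as.character(df$category),
                 element_id = suppressWarnings(as.integer(df$element_id)))
}

#' @rdname read_labels
#' @param labels Label tibble.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels[, c("substroke_id", "category", "element_id")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Propose element labels by greedy template matching
#'
#' An advisory assist for manual classification: after a coarse bounding-box
#' alignment of the drawing onto the template, each substroke is assigned to
#' the element minimising the mean point-to-element distance of its samples;
#' substrokes farther than `threshold` from every element are proposed as
#' unclassified. The proposal is never applied silently - pass it through
#' [apply_labels()] after review.
#'
#' @param rec A [recording()].
#' @param subs Substroke table.
#' @param tpl Template tibble.
#' @param threshold Distance above which a substroke is left unclassified, mm.
#' @return A label tibble (with a `mean_distance` column for review).
#' @export
auto_match <- function(rec, subs, tpl, threshold = 10) {
  if (nrow(subs) == 0) stop("need at least one substroke", call. = FALSE)
  contact <- rec[rec$contact, ]
  # coarse alignment: map drawing bounding box onto template bounding box
  tx <- range(c(tpl$x1, tpl$x2), na.rm = TRUE)
  ty <- range(c(tpl$y1, tpl$y2), na.rm = TRUE)
  dx <- range(contact$x); dy <- range(contact$y)
  sx <- diff(tx) / max(diff(dx), 1e-9)
  sy <- diff(ty) / max(diff(dy), 1e-9)
  map_x <- function(x) tx[1] + (x - dx[1]) * sx
  map_y <- function(y) ty[1] + (y - dy[1]) * sy
  first <- auto_match_pass(rec, subs, tpl, threshold, map_x, map_y)
  # refine: fit the global transform on the confident matches and re-match
  conf <- first[first$category == "element" & first$mean_distance < threshold / 2, ]
  if (nrow(conf) >= 8) {
    obs <- purrr::map_dfr(seq_len(nrow(conf)), function(k) {
      i <- match(conf$substroke_id[k], subs$substroke_id)
      idx <- subs$start[i]:subs$end[i]
      observation_row(conf$element_id[k],
                      c(rec$x[idx[1]], rec$y[idx[1]]),
                      c(rec$x[idx[length(idx)]], rec$y[idx[length(idx)]]))
    })
    obs <- obs[obs$element_id %in% tpl$id[tpl$kind == "segment"], ]
    f <- tryCatch(fit_global_transform(obs, tpl), error = function(e) NULL)
    if (!is.null(f)) {
      return(auto_match_pass(rec, subs, tpl, threshold, transform = f))
    }
  }
  first
}

auto_match_pass <- function(rec, subs, tpl, threshold, map_x = NULL,
                            map_y = NULL, transform = NULL) {
  out <- purrr::map(seq_len(nrow(subs)), function(i) {
    idx <- subs$start[i]:subs$end[i]
    pts <- if (is.null(transform)) {
      cbind(map_x(rec$x[idx]), map_y(rec$y[idx]))
    } else {
      transform_points(cbind(rec$x[idx], rec$y[idx]), transform$theta,
                       transform$sx, transform$sy, transform$tx, transform$ty)
    }
    # cost blends trace-to-element distance with chord-endpoint mismatch,
    # which separates closely spaced parallel elements of different extent
    p1 <- pts[1, ]; p2 <- pts[nrow(pts), ]
    dists <- vapply(seq_len(nrow(tpl)), function(j) {
      el <- tpl[j, ]
      base <- mean(points_to_element_distance(pts, el))
      ep <- if (el$kind == "segment") {
        a <- c(el$x1, el$y1); b <- c(el$x2, el$y2)
        min(mean(c(sqrt(sum((p1 - a)^2)), sqrt(sum((p2 - b)^2)))),
            mean(c(sqrt(sum((p1 - b)^2)), sqrt(sum((p2 - a)^2)))))
      } else base
      (base + ep) / 2
    }, numeric(1))
    dists
  })
  cost <- do.call(rbind, out)
  # greedy one-to-one assignment in global cost order, so near-duplicate
  # candidates (e.g. the three dots) cannot all claim the same element;
  # substrokes left over once every element is taken fall back to their
  # cheapest element (repeated drawings are legitimate)
  assigned <- rep(NA_integer_, nrow(subs))
  best_cost <- rep(NA_real_, nrow(subs))
  ord <- order(cost)
  taken <- rep(FALSE, nrow(tpl))
  done <- rep(FALSE, nrow(subs))
  for (k in ord) {
    i <- (k - 1) %% nrow(subs) + 1
    j <- (k - 1) %/% nrow(subs) + 1
    if (done[i] || taken[j]) next
    assigned[i] <- j
    best_cost[i] <- cost[i, j]
    done[i] <- TRUE
    taken[j] <- TRUE
    if (all(done)) break
  }
  for (i in which(!done)) {
    assigned[i] <- which.min(cost[i, ])
    best_cost[i] <- cost[i, assigned[i]]
  }
  unclassified <- best_cost > threshold
  tibble::tibble(
    substroke_id = subs$substroke_id,
    category = ifelse(unclassified, "unclassified", "element"),
    element_id = ifelse(unclassified, NA_integer_,
                        as.integer(tpl$id[assigned])),
    mean_distance = best_cost)
}

points_to_element_distance <- function(pts, el) {
  if (el$kind == "segment") {
    a <- c(el$x1, el$y1); b <- c(el$x2, el$y2)
    apply(pts, 1, point_segment_distance, a = a, b = b)
  } else if (el$kind == "point") {
    sqrt((pts[, 1] - el$x1)^2 + (pts[, 2] - el$y1)^2)
  } else {
    abs(sqrt((pts[, 1] - el$x1)^2 + (pts[, 2] - el$y1)^2) - el$r)
  }
}

#' Drawing-order visits
#'
#' Drops unclassified substrokes, merges runs of consecutive substrokes on
#' the same element into one visit, and annotates each visit with its unit,
#' structure and relevance. Consecutive visits therefore always have
#' distinct element ids.
#'
#' @param cls Classification tibble from [apply_labels()].
#' @param tpl Template tibble.
#' @return A visit tibble: `element_id`, `unit`, `structure`, `relevance`,
#'   `t_on`, `t_off`, ordered by onset. Zero rows when nothing is classified.
#' @export
visit_sequence <- function(cls, tpl) {
  keep <- cls[cls$category != "unclassified", ]
  if (nrow(keep) == 0) {
    return(tibble::tibble(element_id = integer(), unit = integer(),
                          structure = character(), relevance = character(),
                          t_on = numeric(), t_off = numeric()))
  }
  keep <- keep[order(keep$t_on), ]
  run <- cumsum(c(1L, as.integer(diff(keep$element_id) != 0)))
  visits <- dplyr::summarise(dplyr::group_by(keep, run = run),
                             element_id = dplyr::first(.data$element_id),
                             t_on = min(.data$t_on), t_off = max(.data$t_off),
                             .groups = "drop")
  visits <- dplyr::left_join(visits,
                             tpl[, c("id", "unit", "structure", "relevance")],
                             by = c(element_id = "id"))
  visits[order(visits$t_on),
         c("element_id", "unit", "structure", "relevance", "t_on", "t_off")]
}

#' Eligible elements / substrokes per scoring purpose
#'
#' Spatial scoring uses only linear elements drawn correctly (at least one
#' complete rendition, no incomplete or repeated label for that element).
#' Procedural scoring uses all classified substrokes (unclassified dropped).
#' Kinematic scoring uses the entire drawing.
#'
#' @param cls Classification tibble.
#' @param tpl Template tibble.
#' @param purpose One of `"spatial"`, `"procedural"`, `"kinematic"`.
#' @return For `"spatial"`, an integer vector of eligible element ids; for
#'   the other purposes, the eligible rows of `cls`.
#' @export
eligible_elements <- function(cls, tpl, purpose = c("spatial", "procedural",
                                                    "kinematic")) {
  purpose <- match.arg(purpose)
  if (purpose == "kinematic") return(cls)
  if (purpose == "procedural") return(cls[cls$category != "unclassified", ])
  linear_ids <- tpl$id[tpl$linear]
  by_el <- split(cls$category, cls$element_id)
  ok <- vapply(by_el, function(cats) {
    any(cats == "element") && !any(cats %in% c("incomplete", "repeated"))
  }, logical(1))
  ids <- as.integer(names(by_el))[ok]
  sort(intersect(ids, linear_ids))
}
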