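#' The 12 performance indices
#'
#' Four spatial indices (sHP, sVP, sLG, sIC) quantify accuracy in the
#' relative placement, length and inclination of the figure's elements after
#' global distortion removal; higher values mean lower accuracy. Four
#' procedural indices (pBR, pID, pOR, pFR) quantify the organisation of the
#' drawing order: priority given to the base rectangle and to the inner
#' details on a 0-100 pen-down time scale, interruptions of primary-relevance
#' drawing, and fragmentation of the units. Four kinematic indices (kVL,
#' kAC, kDC, kPK) summarise the smoothed velocity profile per stroke: mean
#' velocity (mm/s), mean acceleration and deceleration magnitude (mm/s^2),
#' and velocity peaks per stroke (fluency; ideally 1).
#'
#' @name indices
NULL

index_names <- c("sHP", "sVP", "sLG", "sIC", "pBR", "pID", "pOR", "pFR",
                 "kVL", "kAC", "kDC", "kPK")

#' Spatial indices
#'
#' Per eligible element the deviation is observed minus template value
#' (midpoint x for sHP, midpoint y for sVP, chord length for sLG,
#' inclination wrapped to (-90, 90] degrees for sIC); each index is the
#' population standard deviation of its deviations about their own mean.
#'
#' @param obs Transformed observation tibble (see [apply_transform()]).
#' @param tpl Template tibble.
#' @return A tibble with columns `sHP`, `sVP`, `sLG`, `sIC` (mm, mm, mm,
#'   degrees).
#' @export
spatial_indices <- function(obs, tpl) {
  if (nrow(obs) < 2) {
    stop("spatial indices need at least 2 eligible elements", call. = FALSE)
  }
  tchords <- template_observations(tpl)
  m <- dplyr::inner_join(obs, tchords, by = "element_id",
                         suffix = c("", "_tpl"))
  tibble::tibble(
    sHP = pop_sd(m$mx - m$mx_tpl),
    sVP = pop_sd(m$my - m$my_tpl),
    sLG = pop_sd(m$length - m$length_tpl),
    sIC = pop_sd(wrap_angle_90(m$inclination - m$inclination_tpl))
  )
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# wrap undirected-line angle differences into (-90, 90]
wrap_angle_90 <- function(d) {
  d <- d %% 180
  ifelse(d > 90, d - 180, d)
}

#' Pen-down progress scale
#'
#' Maps each contact sample onto a 0-100 scale of cumulative pen-down time:
#' 0 at the first pen-paper contact, 100 at the last; pen-up intervals
#' contribute nothing. A drawn-path-length scale is available as an option
#' (`by = "length"`).
#'
#' @param rec A [recording()].
#' @param by Progress measure: cumulative pen-down `"time"` (default) or
#'   cumulative drawn `"length"`.
#' @return A tibble with `sample` (row index into `rec`), `t`, `progress`.
#' @export
progress_scale <- function(rec, by = c("time", "length")) {
  by <- match.arg(by)
  subs <- segment_strokes(rec)
  if (nrow(subs) == 0 || sum(subs$end - subs$start + 1) < 2) {
    stop("progress scale needs at least 2 contact samples", call. = FALSE)
  }
  idx <- unlist(purrr::map2(subs$start, subs$end, seq))
  run <- rep(seq_len(nrow(subs)), subs$end - subs$start + 1)
  dt <- if (by == "time") c(0, diff(rec$t[idx])) else
    c(0, sqrt(diff(rec$x[idx])^2 + diff(rec$y[idx])^2))
  dt[c(TRUE, diff(run) != 0)] <- 0  # no credit across pen-up gaps
  cum <- cumsum(dt)
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate recording: no elapsed pen-down time",
                       call. = FALSE)
  tibble::tibble(sample = idx, t = rec$t[idx], progress = 100 * cum / total)
}

#' Priority of a structure on the progress scale
#'
#' The time-weighted average progress value over the contact samples spent
#' drawing elements of the given structure. `pBR` is the value for the base
#' rectangle, `pID` for the inner details; higher values mean lower
#' priority.
#'
#' @param rec A [recording()].
#' @param cls Classification tibble.
#' @param tpl Template tibble.
#' @param structure Structure tag.
#' @param progress Optionally a precomputed [progress_scale()] table.
#' @return Mean progress in [0, 100], or `NA` if the structure was never
#'   drawn (reported missing, never zero).
#' @export
structure_priority <- function(rec, cls, tpl, structure,
                               progress = progress_scale(rec)) {
  elig <- eligible_elements(cls, tpl, "procedural")
  ids <- tpl$id[tpl$structure == structure]
  rows <- elig[elig$element_id %in% ids, ]
  if (nrow(rows) == 0) return(NA_real_)
  samp <- unlist(purrr::map2(rows$start, rows$end, seq))
  vals <- progress$progress[match(samp, progress$sample)]
  mean(vals, na.rm = TRUE)
}

#' Organisation by relevance (pOR)
#'
#' Counts the transitions from a primary-relevance visit (base rectangle or
#' main substructure) to a secondary-relevance visit that occur while at
#' least one primary element seen in the sequence has not yet been visited -
#' interrupting primary work to draw secondary elements. A drawer who
#' finishes all primary elements before any secondary element scores 0.
#'
#' @param visits Visit tibble from [visit_sequence()].
#' @return Integer count.
#' @export
organisation_by_relevance <- function(visits) {
  if (nrow(visits) == 0) stop("empty visit sequence", call. = FALSE)
  prim_ids <- unique(visits$element_id[visits$relevance == "primary"])
  if (length(prim_ids) == 0) return(0L)
  seen <- logical(length(prim_ids))
  names(seen) <- prim_ids
  count <- 0L
  for (i in seq_len(nrow(visits))) {
    if (visits$relevance[i] == "primary") {
      seen[as.character(visits$element_id[i])] <- TRUE
    }
    if (i < nrow(visits) && visits$relevance[i] == "primary" &&
        visits$relevance[i + 1] == "secondary" && !all(seen)) {
      count <- count + 1L
    }
  }
  count
}

#' Fragmentation (pFR)
#'
#' Over the unit sequence of the visits (consecutive same-unit visits
#' merged), counts how many times the reproduction of a unit is interrupted
#' to draw elements of other units: the sum over units of (number of maximal
#' runs of that unit - 1).
#'
#' @param visits Visit tibble.
#' @param by Count runs of `"unit"` (default) or of `"element"`.
#' @return Integer count.
#' @export
fragmentation <- function(visits, by = c("unit", "element")) {
  by <- match.arg(by)
  if (nrow(visits) == 0) stop("empty visit sequence", call. = FALSE)
  key <- if (by == "unit") visits$unit else visits$element_id
  runs <- rle(key)$values
  as.integer(length(runs) - length(unique(runs)))
}

#' Smoothed speed profile
#'
#' Tangential speed from central differences of position, smoothed per
#' contact run with a zero-phase 4th-order Butterworth low-pass at 7 Hz
#' (forward-backward filtering with reflective padding). Requires uniform
#' sampling; runs shorter than the filter pad are skipped with a warning.
#'
#' @param rec A uniformly resampled [recording()] (see [resample_uniform()]).
#' @param fs Sampling rate, Hz (>= 20).
#' @param cutoff Low-pass cut-off, Hz.
#' @return A tibble with `sample`, `run`, `t`, `x`, `y`, `speed` (mm/s) for
#'   each contact sample of the retained runs.
#' @export
speed_profile <- function(rec, fs = recording_fs(rec), cutoff = 7) {
  if (is.na(fs) || fs < 20) {
    stop("speed profile needs uniform sampling at >= 20 Hz", call. = FALSE)
  }
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  subs <- segment_strokes(rec)
  min_len <- 15L
  purrr::map_dfr(seq_len(nrow(subs)), function(i) {
    idx <- subs$start[i]:subs$end[i]
    n <- length(idx)
    if (n < min_len) {
      warning("contact run ", i, " too short to filter (", n,
              " samples); skipped", call. = FALSE)
      return(NULL)
    }
    vx <- central_diff(rec$x[idx], 1 / fs)
    vy <- central_diff(rec$y[idx], 1 / fs)
    sp <- sqrt(vx^2 + vy^2)
    tibble::tibble(sample = idx, run = i, t = rec$t[idx],
                   x = rec$x[idx], y = rec$y[idx],
                   speed = filtfilt_padded(bf, sp))
  })
}

recording_fs <- function(rec) {
  fs <- attr(rec, "meta")$fs
  if (is.null(fs)) NA_real_ else as.numeric(fs)
}

central_diff <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d
}

filtfilt_padded <- function(bf, x) {
  n <- length(x)
  pad <- min(n - 1, 30L)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1):(pad + n)]
}

#' Parse the speed profile into kinematic strokes
#'
#' Near zero-crossings of the smoothed speed (below `threshold` mm/s) define
#' stroke limits: each interior low-speed region splits its contact run at
#' the region's speed minimum, while low-speed tails abutting a pen event
#' remain inside the first/last stroke. Strokes whose drawn path length does
#' not exceed `min_length` mm are discarded.
#'
#' @param profile Speed profile from [speed_profile()].
#' @param threshold Near-zero speed bound, mm/s.
#' @param min_length Minimum path length, mm.
#' @return A tibble with one row per kinematic stroke: `run`, `start_idx`,
#'   `end_idx` (row indices into `profile`), `t_on`, `t_off`,
#'   `path_length`. Zero rows when no stroke qualifies.
#' @export
kinematic_segments <- function(profile, threshold = 5, min_length = 10) {
  empty <- tibble::tibble(run = integer(), start_idx = integer(),
                          end_idx = integer(), t_on = numeric(),
                          t_off = numeric(), path_length = numeric())
  if (nrow(profile) == 0) return(empty)
  out <- purrr::map_dfr(unique(profile$run), function(r) {
    rows <- which(profile$run == r)
    sp <- profile$speed[rows]
    n <- length(sp)
    low <- sp < threshold
    # interior low-speed regions (not touching the run ends) -> cut points
    rl <- rle(low)
    rends <- cumsum(rl$lengths)
    rstarts <- rends - rl$lengths + 1
    cuts <- integer()
    for (k in seq_along(rl$values)) {
      if (rl$values[k] && rstarts[k] > 1 && rends[k] < n) {
        reg <- rstarts[k]:rends[k]
        cuts <- c(cuts, reg[which.min(sp[reg])])
      }
    }
    bounds <- unique(c(1L, cuts, n))
    purrr::map_dfr(seq_len(length(bounds) - 1), function(b) {
      s <- bounds[b]; e <- bounds[b + 1]
      seg <- rows[s:e]
      len <- sum(sqrt(diff(profile$x[seg])^2 + diff(profile$y[seg])^2))
      tibble::tibble(run = r, start_idx = seg[1], end_idx = seg[length(seg)],
                     t_on = profile$t[seg[1]], t_off = profile$t[seg[length(seg)]],
                     path_length = len)
    })
  })
  out[out$path_length > min_length, ]
}

#' Kinematic indices
#'
#' Per-stroke statistics of the smoothed speed profile, averaged across
#' strokes: mean velocity (kVL); mean magnitude of the speed's time
#' derivative over the acceleration (kAC) and deceleration (kDC) phases; and
#' the number of velocity peaks (kPK), a peak being a local maximum of the
#' speed series (a decrease following an increase; a monotone profile counts
#' its boundary maximum, so a stroke always has at least one peak).
#'
#' @param profile Speed profile from [speed_profile()].
#' @param strokes Kinematic stroke table from [kinematic_segments()].
#' @param fs Sampling rate, Hz.
#' @param prominence Optional minimum prominence (mm/s) for a peak; default 0
#'   (the 7 Hz smoothing is the noise control).
#' @return A tibble with `kVL`, `kAC`, `kDC`, `kPK` (all `NA` with zero
#'   strokes).
#' @export
kinematic_indices <- function(profile, strokes, fs, prominence = 0) {
  if (nrow(strokes) == 0) {
    return(tibble::tibble(kVL = NA_real_, kAC = NA_real_, kDC = NA_real_,
                          kPK = NA_real_))
  }
  per <- purrr::map_dfr(seq_len(nrow(strokes)), function(i) {
    sp <- profile$speed[strokes$start_idx[i]:strokes$end_idx[i]]
    acc <- central_diff(sp, 1 / fs)
    tibble::tibble(
      vl = mean(sp),
      ac = if (any(acc > 0)) mean(acc[acc > 0]) else NA_real_,
      dc = if (any(acc < 0)) mean(abs(acc[acc < 0])) else NA_real_,
      pk = count_speed_peaks(sp, prominence)
    )
  })
  tibble::tibble(kVL = mean(per$vl), kAC = mean(per$ac, na.rm = TRUE),
                 kDC = mean(per$dc, na.rm = TRUE), kPK = mean(per$pk))
}

count_speed_peaks <- function(sp, prominence = 0) {
  n <- length(sp)
  if (n < 3) return(1L)
  d <- diff(sp)
  # strict + -> - sign changes of the derivative (plateaus collapse)
  s <- sign(d)
  s <- s[s != 0]
  peaks <- sum(s[-length(s)] > 0 & s[-1] < 0)
  if (prominence > 0 && peaks > 0) {
    idx <- which(diff(sign(diff(sp))) < 0) + 1
    peaks <- sum(sp[idx] - min(sp) >= prominence)
  }
  max(peaks, 1L)  # monotone profile: the boundary maximum is the peak
}

#' Score one drawing
#'
#' Orchestrates the full per-drawing pipeline: eligibility, element
#' observation, global transform fit, and the 12 indices. Degenerate inputs
#' yield missing index values with a reason recorded in `diagnostics`, never
#' fabricated zeros.
#'
#' @param rec A [recording()].
#' @param cls Classification tibble from [apply_labels()] (or the raw label
#'   tibble, which is applied to `segment_strokes(rec)`).
#' @param tpl Template tibble.
#' @param fs Resampling rate for the kinematic chain, Hz.
#' @return An object of class `rey_scores`: a list with `indices` (1-row,
#'   12-column tibble), `transform`, `eligibility` (counts per purpose),
#'   `template_checksum`, `diagnostics`.
#' @examples
#' tpl <- canonical_template()
#' sim <- simulate_drawing(tpl, drawing_config(seed = 1))
#' scores <- score_drawing(sim$recording, sim$labels, tpl)
#' scores$indices
#' @export
score_drawing <- function(rec, cls, tpl, fs = 100) {
  if (!"start" %in% names(cls)) {
    cls <- apply_labels(segment_strokes(rec), cls)
  }
  diagnostics <- character()
  idx <- stats::setNames(rep(NA_real_, 12), index_names)

  # --- spatial chain ---
  transform <- NULL
  spatial_ids <- eligible_elements(cls, tpl, "spatial")
  if (length(spatial_ids) >= 3) {
    obs <- observe_elements(rec, cls, tpl, spatial_ids)
    transform <- tryCatch(fit_global_transform(obs, tpl),
                          error = function(e) {
                            diagnostics <<- c(diagnostics, conditionMessage(e))
                            NULL
                          })
    if (!is.null(transform)) {
      sp <- spatial_indices(apply_transform(transform, obs), tpl)
      idx[c("sHP", "sVP", "sLG", "sIC")] <- as.numeric(sp[1, ])
    }
  } else {
    diagnostics <- c(diagnostics, "fewer than 3 spatial-eligible elements")
  }

  # --- procedural chain ---
  prog <- tryCatch(progress_scale(rec), error = function(e) NULL)
  if (!is.null(prog)) {
    idx["pBR"] <- structure_priority(rec, cls, tpl, "base_rectangle", prog)
    idx["pID"] <- structure_priority(rec, cls, tpl, "inner_detail", prog)
  } else {
    diagnostics <- c(diagnostics, "progress scale undefined")
  }
  visits <- visit_sequence(cls, tpl)
  if (nrow(visits) > 0) {
    idx["pOR"] <- organisation_by_relevance(visits)
    idx["pFR"] <- fragmentation(visits)
  } else {
    diagnostics <- c(diagnostics, "no classified substrokes for visits")
  }

  # --- kinematic chain ---
  unif <- resample_uniform(rec, fs)
  profile <- withCallingHandlers(
    speed_profile(unif, fs = fs),
    warning = function(w) {
      diagnostics <<- c(diagnostics, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  strokes <- kinematic_segments(profile)
  kin <- kinematic_indices(profile, strokes, fs)
  idx[c("kVL", "kAC", "kDC", "kPK")] <- as.numeric(kin[1, ])
  if (nrow(strokes) == 0) diagnostics <- c(diagnostics, "no kinematic stroke")

  structure(list(
    indices = tibble::as_tibble(as.list(idx)),
    transform = transform,
    eligibility = tibble::tibble(
      spatial_elements = length(spatial_ids),
      procedural_substrokes = nrow(eligible_elements(cls, tpl, "procedural")),
      kinematic_substrokes = nrow(cls),
      kinematic_strokes = nrow(strokes)
    ),
    template_checksum = template_checksum(tpl),
    n_visits = nrow(visits),
    diagnostics = diagnostics
  ), class = "rey_scores")
}

#' @export
print.rey_scores <- function(x, ...) {
  cat("<rey_scores>\n")
  print(x$indices)
  if (!is.null(x$transform)) print(x$transform)
  if (length(x$diagnostics) > 0) {
    cat("diagnostics:", paste(x$diagnostics, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Tidy a scored drawing into index/value rows
#'
#' @param x A `rey_scores` object.
#' @param ... Unused.
#' @return A tibble with `index`, `dimension`, `value`.
#' @method tidy rey_scores
#' @export
tidy.rey_scores <- function(x, ...) {
  tibble::tibble(
    index = index_names,
    dimension = rep(c("spatial", "procedural", "kinematic"), each = 4),
    value = as.numeric(x$indices[1, index_names])
  )
}

#' One-row summary of a scored drawing
#'
#' @param x A `rey_scores` object.
#' @param ... Unused.
#' @return A 1-row tibble: the 12 indices plus eligibility counts and the
#'   transform residual.
#' @method glance rey_scores
#' @export
glance.rey_scores <- function(x, ...) {
  dplyr::bind_cols(x$indices, x$eligibility,
                   tibble::tibble(transform_rss = if (is.null(x$transform))
                     NA_real_ else x$transform$rss))
}

#' Write / read a score report
#'
#' Structured-text (JSON) report with the 12 indices, eligibility counts,
#' fitted transform (theta in degrees) and the template checksum.
#'
#' @param scores A `rey_scores` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(scores, path) {
  tr <- scores$transform
  rep <- list(
    software = paste0("reyscore ", as.character(utils::packageVersion("reyscore"))),
    template_checksum = scores$template_checksum,
    indices = as.list(scores$indices),
    eligibility = as.list(scores$eligibility),
    transform = if (is.null(tr)) NULL else list(
      theta_deg = tr$theta * 180 / pi, sx = tr$sx, sy = tr$sy,
      tx = tr$tx, ty = tr$ty, rss = tr$rss),
    diagnostics = scores$diagnostics
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
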