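#' Drawing simulator configuration
#'
#' The simulator emulates the behaviours the indices quantify: per-element
#' placement/length/inclination jitter, organised versus fragmented drawing
#' orders, and bell-shaped per-stroke speed profiles with a controllable
#' number of extra submovements.
#'
#' Defaults describe a clean, organised, fluent copy: no spatial jitter, no
#' global distortion, structure-ordered drawing with contiguous units,
#' 60 mm/s peak speed, single-bump velocity profiles, 0.3 s inter-stroke
#' pauses, 100 Hz sampling.
#'
#' @param sigma_hp,sigma_vp Midpoint jitter SD along x / y, mm.
#' @param sigma_lg Length jitter SD, mm.
#' @param sigma_ic Inclination jitter SD, degrees.
#' @param theta,sx,sy,tx,ty Global distortion (applied last; see
#'   [distort_recording()] for the convention). `theta` in radians.
#' @param strategy `"organized"` or `"fragmented"`.
#' @param fragment_prob For the fragmented strategy, the probability that an
#'   element is split into two separately drawn substrokes.
#' @param shuffle_strength Order-shuffle strength in `[0, 1]`: 0 keeps the
#'   organised order, 1 is a fully random order (rank noise).
#' @param peak_speed Half-sine peak speed, mm/s.
#' @param submovement_rate Mean count (Poisson) of extra submovement bumps
#'   superposed per stroke.
#' @param pause Inter-stroke pen-up duration, s.
#' @param fs Sampling rate, Hz (>= 20).
#' @param seed Integer seed; all simulator randomness flows from it.
#' @return A `drawing_config` list.
#' @export
drawing_config <- function(sigma_hp = 0, sigma_vp = 0, sigma_lg = 0,
                           sigma_ic = 0, theta = 0, sx = 1, sy = 1,
                           tx = 0, ty = 0,
                           strategy = c("organized", "fragmented"),
                           fragment_prob = 0.3, shuffle_strength = 0.15,
                           peak_speed = 60, submovement_rate = 0,
                           pause = 0.3, fs = 100, seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(sigma_hp >= 0, sigma_vp >= 0, sigma_lg >= 0, sigma_ic >= 0,
            sx > 0, sy > 0, fragment_prob >= 0, fragment_prob <= 1,
            shuffle_strength >= 0, shuffle_strength <= 1,
            peak_speed > 0, submovement_rate >= 0, pause > 0, fs >= 20)
  structure(list(sigma_hp = sigma_hp, sigma_vp = sigma_vp, sigma_lg = sigma_lg,
                 sigma_ic = sigma_ic, theta = theta, sx = sx, sy = sy,
                 tx = tx, ty = ty, strategy = strategy,
                 fragment_prob = fragment_prob,
                 shuffle_strength = shuffle_strength, peak_speed = peak_speed,
                 submovement_rate = submovement_rate, pause = pause, fs = fs,
                 seed = seed), class = "drawing_config")
}

structure_order <- c("base_rectangle", "main_substructure",
                     "outer_configuration", "inner_detail")

#' Simulate one drawing with known ground truth
#'
#' Per element, the template chord is perturbed directly in the observed
#' quantities (midpoint x/y, length, inclination) with the configured SDs,
#' so the implied population values are exactly recoverable; the realised
#' deviations are returned in the truth record. Elements are ordered
#' according to the strategy, traced with a half-sine speed profile (plus
#' Poisson-many smaller superposed submovement bumps), and the global
#' distortion is applied last.
#'
#' @param tpl Template tibble.
#' @param cfg A [drawing_config()].
#' @return A list: `recording`, `labels` (ground-truth label table, one row
#'   per substroke, never unclassified), and `truth` (realised per-element
#'   deviations `d_hp`, `d_vp`, `d_lg`, `d_ic`, plus the drawn task order
#'   and kinematic parameters).
#' @export
simulate_drawing <- function(tpl, cfg = drawing_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  segs <- tpl[tpl$kind == "segment", ]

  # --- realised spatial perturbation per linear element ---
  n <- nrow(segs)
  d_hp <- stats::rnorm(n, 0, cfg$sigma_hp)
  d_vp <- stats::rnorm(n, 0, cfg$sigma_vp)
  d_lg <- stats::rnorm(n, 0, cfg$sigma_lg)
  d_ic <- stats::rnorm(n, 0, cfg$sigma_ic)
  drawn <- purrr::map_dfr(seq_len(n), function(i) {
    mx <- (segs$x1[i] + segs$x2[i]) / 2 + d_hp[i]
    my <- (segs$y1[i] + segs$y2[i]) / 2 + d_vp[i]
    len0 <- sqrt((segs$x2[i] - segs$x1[i])^2 + (segs$y2[i] - segs$y1[i])^2)
    len <- max(1, len0 + d_lg[i])
    ang <- atan2(segs$y2[i] - segs$y1[i], segs$x2[i] - segs$x1[i]) +
      d_ic[i] * pi / 180
    tibble::tibble(
      element_id = segs$id[i],
      x1 = mx - cos(ang) * len / 2, y1 = my - sin(ang) * len / 2,
      x2 = mx + cos(ang) * len / 2, y2 = my + sin(ang) * len / 2)
  })

  # --- task list: one or two substroke tasks per element, ordered ---
  base <- tpl[order(match(tpl$structure, structure_order), tpl$unit, tpl$id), ]
  tasks <- purrr::map_dfr(seq_len(nrow(base)), function(i) {
    el <- base[i, ]
    frag <- cfg$strategy == "fragmented" && el$kind == "segment" &&
      stats::runif(1) < cfg$fragment_prob
    tibble::tibble(element_id = el$id, kind = el$kind,
                   part = if (frag) 1:2 else 1L,
                   n_parts = if (frag) 2L else 1L)
  })
  if (cfg$strategy == "fragmented" && cfg$shuffle_strength > 0) {
    noise <- stats::rnorm(nrow(tasks), 0, cfg$shuffle_strength * nrow(tasks))
    tasks <- tasks[order(seq_len(nrow(tasks)) + noise), ]
  }

  # --- trace each task as one pen-down stroke ---
  t0 <- 0
  pieces <- list()
  labels <- list()
  sid <- 0
  for (i in seq_len(nrow(tasks))) {
    task <- tasks[i, ]
    el <- tpl[tpl$id == task$element_id, ]
    path <- task_path(task, el, drawn)
    trace <- trace_path(path, cfg, t0)
    sid <- sid + 1
    labels[[sid]] <- tibble::tibble(substroke_id = sid, category = "element",
                                    element_id = as.integer(task$element_id))
    pieces[[length(pieces) + 1]] <- trace
    t0 <- max(trace$t) + cfg$pause
    # pen-up marker midway through the pause, at the lift position
    pieces[[length(pieces) + 1]] <- tibble::tibble(
      t = max(trace$t) + cfg$pause / 2,
      x = trace$x[nrow(trace)], y = trace$y[nrow(trace)], contact = FALSE)
  }
  pieces[[length(pieces)]] <- NULL  # no trailing pen-up after the last stroke
  samples <- dplyr::bind_rows(pieces)
  rec <- recording(samples$t, samples$x, samples$y, samples$contact,
                   meta = list(id = "synthetic", device = "simulator",
                               fs = cfg$fs))
  rec <- distort_recording(rec, cfg$theta, cfg$sx, cfg$sy, cfg$tx, cfg$ty)

  truth <- list(
    deviations = tibble::tibble(element_id = segs$id, d_hp = d_hp, d_vp = d_vp,
                                d_lg = d_lg, d_ic = d_ic),
    realized_sd = tibble::tibble(sHP = pop_sd(d_hp), sVP = pop_sd(d_vp),
                                 sLG = pop_sd(d_lg), sIC = pop_sd(d_ic)),
    task_order = tasks,
    peak_speed = cfg$peak_speed,
    submovement_rate = cfg$submovement_rate,
    config = cfg
  )
  list(recording = rec, labels = dplyr::bind_rows(labels), truth = truth)
}

# waypoints (straight chord, circle polyline, or dot) for one task
task_path <- function(task, el, drawn) {
  if (el$kind == "segment") {
    d <- drawn[drawn$element_id == el$id, ]
    p1 <- c(d$x1, d$y1); p2 <- c(d$x2, d$y2)
    if (task$n_parts == 2L) {
      mid <- (p1 + p2) / 2
      if (task$part == 1L) rbind(p1, mid) else rbind(mid, p2)
    } else {
      rbind(p1, p2)
    }
  } else if (el$kind == "point") {
    # a dot: a tiny tick, long enough to sample but far below the 10 mm
    # kinematic length floor
    rbind(c(el$x1, el$y1), c(el$x1 + 0.8, el$y1 + 0.4))
  } else {
    ang <- seq(0, 2 * pi, length.out = 65)
    cbind(el$x1 + el$r * cos(ang), el$y1 + el$r * sin(ang))
  }
}

# trace waypoints with a half-sine speed profile; extra submovements are
# hesitation dips that extend the stroke duration (each dip turns one
# velocity peak into two and lowers the stroke's mean velocity)
trace_path <- function(path, cfg, t0) {
  seglen <- sqrt(rowSums((path[-1, , drop = FALSE] -
                            path[-nrow(path), , drop = FALSE])^2))
  L <- sum(seglen)
  V <- cfg$peak_speed
  if (L < 2) V <- min(V, 10)  # dots are drawn slowly
  n_dips <- stats::rpois(1, cfg$submovement_rate)
  # profile shape on unit time: half-sine times multiplicative dips
  centres <- if (n_dips > 0) stats::runif(n_dips, 0.2, 0.8) else numeric()
  width <- if (n_dips > 0) min(0.12, 0.5 / (n_dips + 1)) else 0
  shape <- function(u) {
    f <- sin(pi * u)
    for (cc in centres) {
      inreg <- abs(u - cc) < width / 2
      f[inreg] <- f[inreg] *
        (1 - 0.6 * sin(pi * (u[inreg] - cc + width / 2) / width))
    }
    f
  }
  uu <- seq(0, 1, length.out = 512)
  I1 <- mean(shape(uu)) # integral of the shape over unit time
  TT <- L / (V * I1)                        # duration so the profile covers L
  TT <- max(TT, 14 / cfg$fs)                # at least a filterable run
  tt <- seq(0, TT, by = 1 / cfg$fs)
  if (tt[length(tt)] < TT - 1e-12) tt <- c(tt, TT)
  v <- V * shape(tt / TT)
  # arc-length positions from the profile, normalised exactly to L
  s <- cumsum(c(0, (v[-1] + v[-length(v)]) / 2 * diff(tt)))
  s <- s / s[length(s)] * L
  cum <- c(0, cumsum(seglen))
  x <- stats::approx(cum, path[, 1], xout = s, rule = 2)$y
  y <- stats::approx(cum, path[, 2], xout = s, rule = 2)$y
  tibble::tibble(t = t0 + tt, x = x, y = y, contact = TRUE)
}

#' Cohort simulator configuration
#'
#' Index matrices are drawn from the orthogonal factor model
#' `Z = F %*% t(loadings) + E %*% diag(sqrt(uniqueness))` with standard
#' normal factors. The default target loading matrix assigns the four
#' spatial indices to one factor, the four procedural to a second and the
#' four kinematic to a third (kPK negatively), loadings 0.8 - the simple
#' structure this family of drawing indices exhibits.
#'
#' @param n Number of participants.
#' @param loadings 12 x 3 target loading matrix, rownames the 12 index
#'   names; entries in `[-1, 1]`.
#' @param uniqueness Per-variable uniqueness; default `1 - rowSums(loadings^2)`.
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n = 100, loadings = default_loadings(),
                          uniqueness = NULL, seed = NULL) {
  stopifnot(nrow(loadings) == 12, ncol(loadings) == 3,
            all(abs(loadings) <= 1))
  if (is.null(uniqueness)) uniqueness <- pmax(0, 1 - rowSums(loadings^2))
  if (length(uniqueness) == 1) uniqueness <- rep(uniqueness, 12)
  implied <- loadings %*% t(loadings) + diag(uniqueness)
  ev <- eigen(implied, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("implied correlation matrix is not positive semi-definite",
         call. = FALSE)
  }
  structure(list(n = n, loadings = loadings, uniqueness = uniqueness,
                 seed = seed), class = "cohort_config")
}

#' Default 3-factor target loading matrix
#'
#' @param loading Primary loading magnitude.
#' @return A 12 x 3 matrix with rownames the 12 index names and columns
#'   SPA / PRO / KIN.
#' @export
default_loadings <- function(loading = 0.8) {
  L <- matrix(0, 12, 3, dimnames = list(index_names, c("SPA", "PRO", "KIN")))
  L[c("sHP", "sVP", "sLG", "sIC"), "SPA"] <- loading
  L[c("pBR", "pID", "pOR", "pFR"), "PRO"] <- loading
  L[c("kVL", "kAC", "kDC"), "KIN"] <- loading
  L["kPK", "KIN"] <- -loading
  L
}

#' Simulate a cohort index matrix
#'
#' @param cfg A [cohort_config()].
#' @return A list: `scores` (n x 12 tibble named by the 12 indices) and
#'   `structure` (the generating loading matrix and uniquenesses).
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  FF <- matrix(stats::rnorm(cfg$n * 3), cfg$n, 3)
  E <- matrix(stats::rnorm(cfg$n * 12), cfg$n, 12)
  Z <- FF %*% t(cfg$loadings) + E %*% diag(sqrt(cfg$uniqueness))
  colnames(Z) <- index_names
  list(scores = tibble::as_tibble(Z),
       structure = list(loadings = cfg$loadings, uniqueness = cfg$uniqueness))
}
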