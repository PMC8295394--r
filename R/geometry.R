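#' Observe drawn elements
#'
#' For each spatial-eligible element, the drawn chord is the pair of
#' substroke-extremity samples with maximal mutual distance (an element may
#' be drawn in several substrokes). The observation carries the chord
#' endpoints, their midpoint, the Euclidean length, and the undirected
#' inclination in degrees in [0, 180).
#'
#' @param rec A [recording()].
#' @param cls Classification tibble.
#' @param tpl Template tibble.
#' @param element_ids Element ids to observe; default the spatial-eligible set.
#' @return Observation tibble: `element_id`, `ex1`,`ey1`,`ex2`,`ey2`,
#'   `mx`,`my`, `length`, `inclination`.
#' @export
observe_elements <- function(rec, cls, tpl,
                             element_ids = eligible_elements(cls, tpl, "spatial")) {
  purrr::map_dfr(element_ids, function(eid) {
    rows <- cls[!is.na(cls$element_id) & cls$element_id == eid &
                  cls$category == "element", ]
    # extremity samples of every substroke implementing the element
    ext <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
      tibble::tibble(x = rec$x[c(rows$start[i], rows$end[i])],
                     y = rec$y[c(rows$start[i], rows$end[i])])
    })
    n_samples <- sum(rows$end - rows$start + 1)
    if (n_samples < 2) stop("element ", eid, " has fewer than 2 samples",
                            call. = FALSE)
    dmat <- as.matrix(stats::dist(ext))
    if (max(dmat) == 0) stop("element ", eid, " is degenerate (all samples coincide)",
                             call. = FALSE)
    ij <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
    observation_row(eid, c(ext$x[ij[1]], ext$y[ij[1]]),
                    c(ext$x[ij[2]], ext$y[ij[2]]))
  })
}

observation_row <- function(eid, p1, p2) {
  tibble::tibble(
    element_id = as.integer(eid),
    ex1 = p1[1], ey1 = p1[2], ex2 = p2[1], ey2 = p2[2],
    mx = (p1[1] + p2[1]) / 2, my = (p1[2] + p2[2]) / 2,
    length = sqrt(sum((p2 - p1)^2)),
    inclination = chord_inclination(p1, p2)
  )
}

chord_inclination <- function(p1, p2) {
  ang <- atan2(p2[2] - p1[2], p2[1] - p1[1]) * 180 / pi
  ang %% 180
}

#' Template chords for the linear elements
#'
#' @param tpl Template tibble.
#' @return Observation-shaped tibble of the template's segment geometry.
#' @export
template_observations <- function(tpl) {
  segs <- tpl[tpl$kind == "segment", ]
  purrr::map_dfr(seq_len(nrow(segs)), function(i) {
    observation_row(segs$id[i], c(segs$x1[i], segs$y1[i]),
                    c(segs$x2[i], segs$y2[i]))
  })
}

#' Fit the global distortion-removing transform
#'
#' Finds the rotation, axis-aligned anisotropic scaling (template axes) and
#' translation mapping the drawn element endpoints onto the template
#' endpoints in the least-squares sense:
#' `p -> diag(sx, sy) %*% R(theta) %*% p + c(tx, ty)`.
#' Per element the endpoint pairing (drawn direction is arbitrary) is chosen
#' to minimise that element's cost; pairing and transform are alternated to
#' convergence. Given the rotation the optimal scales and translations are
#' closed-form per axis, so the optimisation is one-dimensional in theta.
#'
#' @param obs Observation tibble from [observe_elements()].
#' @param tpl Template tibble.
#' @param theta_range Search interval for the rotation, radians.
#' @return A list of class `rey_transform`: `theta` (radians), `sx`, `sy`,
#'   `tx`, `ty`, `rss` (final residual sum of squares), `n_elements`.
#' @export
fit_global_transform <- function(obs, tpl, theta_range = c(-pi / 3, pi / 3)) {
  tchords <- template_observations(tpl)
  m <- dplyr::inner_join(obs, tchords, by = "element_id",
                         suffix = c("", "_tpl"))
  if (nrow(m) < 3) {
    stop("global fit needs at least 3 eligible elements", call. = FALSE)
  }
  mids <- cbind(m$mx, m$my)
  if (qr(sweep(mids, 2, colMeans(mids)))$rank < 2) {
    stop("eligible elements are collinear; global fit is degenerate",
         call. = FALSE)
  }
  drawn1 <- cbind(m$ex1, m$ey1); drawn2 <- cbind(m$ex2, m$ey2)
  tpl1 <- cbind(m$ex1_tpl, m$ey1_tpl); tpl2 <- cbind(m$ex2_tpl, m$ey2_tpl)

  solve_given_pairing <- function(P, Q) {
    # P: drawn endpoints (2n x 2), Q: template endpoints (2n x 2)
    cost_theta <- function(theta) axis_ls(P, Q, theta)$rss
    opt <- stats::optimize(cost_theta, interval = theta_range, tol = 1e-12)
    # polish around the optimum (optimize's tol is on the argument)
    fit <- axis_ls(P, Q, opt$minimum)
    c(list(theta = opt$minimum), fit)
  }

  swap <- rep(FALSE, nrow(m))
  fit <- NULL
  for (iter in 1:10) {
    P <- rbind(ifelse_rows(swap, drawn2, drawn1),
               ifelse_rows(swap, drawn1, drawn2))
    Q <- rbind(tpl1, tpl2)
    fit <- solve_given_pairing(P, Q)
    # re-pair under the fitted transform
    tf <- function(pts) transform_points(pts, fit$theta, fit$sx, fit$sy,
                                         fit$tx, fit$ty)
    c1 <- rowSums((tf(drawn1) - tpl1)^2) + rowSums((tf(drawn2) - tpl2)^2)
    c2 <- rowSums((tf(drawn2) - tpl1)^2) + rowSums((tf(drawn1) - tpl2)^2)
    new_swap <- c2 < c1
    if (identical(new_swap, swap)) break
    swap <- new_swap
  }
  structure(list(theta = fit$theta, sx = fit$sx, sy = fit$sy,
                 tx = fit$tx, ty = fit$ty, rss = fit$rss,
                 n_elements = nrow(m)),
            class = "rey_transform")
}

# closed-form per-axis scale+translation given rotation
axis_ls <- function(P, Q, theta) {
  Pr <- P %*% t(rot2(theta))
  fx <- axis_fit(Pr[, 1], Q[, 1])
  fy <- axis_fit(Pr[, 2], Q[, 2])
  list(sx = fx$s, sy = fy$s, tx = fx$t, ty = fy$t, rss = fx$rss + fy$rss)
}

axis_fit <- function(p, q) {
  pm <- mean(p); qm <- mean(q)
  vp <- sum((p - pm)^2)
  s <- if (vp == 0) 1 else sum((p - pm) * (q - qm)) / vp
  if (s <= 0) s <- 1e-6  # scales are positive by contract
  t <- qm - s * pm
  list(s = s, t = t, rss = sum((s * p + t - q)^2))
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

ifelse_rows <- function(flag, a, b) {
  out <- b
  out[flag, ] <- a[flag, ]
  out
}

transform_points <- function(pts, theta, sx, sy, tx, ty) {
  r <- pts %*% t(rot2(theta))
  cbind(sx * r[, 1] + tx, sy * r[, 2] + ty)
}

#' Apply a global transform to observations
#'
#' Endpoints are mapped through the transform; midpoint, length and
#' inclination are re-derived from the mapped endpoints.
#'
#' @param transform A `rey_transform` (or a list with fields `theta`, `sx`,
#'   `sy`, `tx`, `ty`).
#' @param obs Observation tibble.
#' @return The transformed observation tibble.
#' @export
apply_transform <- function(transform, obs) {
  p1 <- transform_points(cbind(obs$ex1, obs$ey1), transform$theta,
                         transform$sx, transform$sy, transform$tx, transform$ty)
  p2 <- transform_points(cbind(obs$ex2, obs$ey2), transform$theta,
                         transform$sx, transform$sy, transform$tx, transform$ty)
  purrr::map_dfr(seq_len(nrow(obs)), function(i) {
    observation_row(obs$element_id[i], p1[i, ], p2[i, ])
  })
}

#' Apply a global distortion to a recording (simulation side)
#'
#' Distortions act in the inverse order of the corrective transform so the
#' correction family can undo them exactly: scale in template axes, then
#' rotate, then translate (`p -> R(theta) %*% diag(sx, sy) %*% p + t`).
#'
#' @param rec A [recording()].
#' @param theta Rotation, radians.
#' @param sx,sy Scales.
#' @param tx,ty Translation, mm.
#' @return The distorted recording.
#' @export
distort_recording <- function(rec, theta = 0, sx = 1, sy = 1, tx = 0, ty = 0) {
  pts <- cbind(sx * rec$x, sy * rec$y) %*% t(rot2(theta))
  recording(rec$t, pts[, 1] + tx, pts[, 2] + ty, rec$contact,
            meta = as.list(attr(rec, "meta")))
}

#' @export
print.rey_transform <- function(x, ...) {
  cat(sprintf(
    "<rey_transform: theta = %.3f deg, sx = %.4f, sy = %.4f, t = (%.2f, %.2f) mm, rss = %.3g (%d elements)>\n",
    x$theta * 180 / pi, x$sx, x$sy, x$tx, x$ty, x$rss, x$n_elements))
  invisible(x)
}
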