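#' Plot the final graphic result
#'
#' The drawn trace as it appears on the sheet (pen-down samples only).
#'
#' @param rec A [recording()].
#' @return A ggplot.
#' @export
plot_graphic <- function(rec) {
  subs <- segment_strokes(rec)
  df <- contact_samples(rec, subs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$run)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", title = "Graphic output") +
    ggplot2::theme_minimal()
}

#' Plot the velocity output
#'
#' The trace coloured by smoothed tangential speed, light yellow near zero
#' to dark red at and above 100 mm/s (the scale saturates there).
#'
#' @param rec A [recording()].
#' @param fs Resampling rate, Hz.
#' @return A ggplot.
#' @export
plot_velocity <- function(rec, fs = 100) {
  unif <- resample_uniform(rec, fs)
  prof <- suppressWarnings(speed_profile(unif, fs = fs))
  prof$speed_capped <- pmin(prof$speed, 100)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$speed_capped,
                                     group = .data$run)) +
    ggplot2::geom_path(linewidth = 0.6) +
    ggplot2::scale_colour_gradient(low = "#FFF7BC", high = "#67000D",
                                   limits = c(0, 100),
                                   name = "speed (mm/s)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", title = "Velocity output") +
    ggplot2::theme_minimal()
}

structure_colours <- c(base_rectangle = "#2CA02C", main_substructure = "#1F77B4",
                       outer_configuration = "#FFD700", inner_detail = "#D62728")
relevance_colours <- c(primary = "black", secondary = "grey60")

#' Frame cut points along cumulative drawn length
#'
#' The six frames of the procedure output are keyed to cumulative drawn path
#' length (independent of the pen-down time scale used by pBR/pID): the
#' samples at which 1/6, 2/6, ..., 6/6 of the total length has been
#' reproduced.
#'
#' @param rec A [recording()].
#' @param fractions Cumulative-length fractions.
#' @return A tibble: `fraction`, `sample` (row index into `rec`), `t`
#'   (elapsed time, s), `t_pen_down` (elapsed pen-down time, s).
#' @export
procedure_frames <- function(rec, fractions = (1:6) / 6) {
  subs <- segment_strokes(rec)
  df <- contact_samples(rec, subs)
  step <- sqrt(diff(df$x)^2 + diff(df$y)^2)
  step[diff(df$run) != 0] <- 0
  cum <- c(0, cumsum(step))
  total <- cum[length(cum)]
  dt <- c(0, diff(df$t))
  dt[c(TRUE, diff(df$run) != 0)] <- 0
  cum_pd <- cumsum(dt)
  purrr::map_dfr(fractions, function(f) {
    i <- which(cum >= f * total - 1e-9)[1]
    tibble::tibble(fraction = f, sample = df$sample[i],
                   t = df$t[i] - df$t[1], t_pen_down = cum_pd[i])
  })
}

#' Plot the procedure output
#'
#' Six cumulative frames at equal fractions of drawn length, the trace
#' coloured by the structure being drawn (base rectangle green, main
#' substructure blue, outer configurations yellow, inner details red), with
#' elapsed total and pen-down-only times annotated, plus structure and
#' relevance (primary black / secondary grey) progression bars on the
#' 0-100 pen-down progress scale.
#'
#' @param rec A [recording()].
#' @param cls Classification tibble.
#' @param tpl Template tibble.
#' @return A ggplot (frames faceted; bars beneath).
#' @export
plot_procedure <- function(rec, cls, tpl) {
  subs <- segment_strokes(rec)
  df <- contact_samples(rec, subs)
  lab <- cls[, c("substroke_id", "element_id")]
  samp2sub <- rep(cls$substroke_id, cls$end - cls$start + 1)
  names(samp2sub) <- unlist(purrr::map2(cls$start, cls$end, seq))
  df$element_id <- lab$element_id[match(samp2sub[as.character(df$sample)],
                                        lab$substroke_id)]
  df <- dplyr::left_join(df, tpl[, c("id", "structure", "relevance")],
                         by = c(element_id = "id"))
  frames <- procedure_frames(rec)
  framed <- purrr::map_dfr(seq_len(nrow(frames)), function(k) {
    upto <- df[seq_len(which(df$sample == frames$sample[k])), ]
    upto$frame <- sprintf("%.0f%%  t=%.1fs (%.1fs)", 100 * frames$fraction[k],
                          frames$t[k], frames$t_pen_down[k])
    upto
  })
  framed$frame <- factor(framed$frame, levels = unique(framed$frame))
  ggplot2::ggplot(framed,
                  ggplot2::aes(x = .data$x, y = .data$y, group = .data$run,
                               colour = .data$structure)) +
    ggplot2::geom_path(linewidth = 0.4, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = structure_colours, na.value = "grey80") +
    ggplot2::facet_wrap(~frame, nrow = 1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = "Procedure output") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Structure / relevance progression bars
#'
#' The 0-100 pen-down progress scale coloured by the structure (or
#' relevance) being drawn at each instant.
#'
#' @param rec A [recording()].
#' @param cls Classification tibble.
#' @param tpl Template tibble.
#' @return A ggplot with two bars.
#' @export
plot_progress_bars <- function(rec, cls, tpl) {
  prog <- progress_scale(rec)
  samp2sub <- rep(cls$substroke_id, cls$end - cls$start + 1)
  names(samp2sub) <- unlist(purrr::map2(cls$start, cls$end, seq))
  prog$element_id <- cls$element_id[match(samp2sub[as.character(prog$sample)],
                                          cls$substroke_id)]
  prog <- dplyr::left_join(prog, tpl[, c("id", "structure", "relevance")],
                           by = c(element_id = "id"))
  long <- dplyr::bind_rows(
    tibble::tibble(progress = prog$progress, bar = "structure",
                   value = prog$structure),
    tibble::tibble(progress = prog$progress, bar = "relevance",
                   value = prog$relevance))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$progress, y = .data$bar,
                                     fill = .data$value)) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::scale_fill_manual(values = c(structure_colours, relevance_colours),
                               na.value = "grey90", name = NULL) +
    ggplot2::labs(x = "drawing progression (% pen-down time)", y = NULL) +
    ggplot2::theme_minimal()
}

contact_samples <- function(rec, subs) {
  idx <- unlist(purrr::map2(subs$start, subs$end, seq))
  run <- rep(seq_len(nrow(subs)), subs$end - subs$start + 1)
  tibble::tibble(sample = idx, run = run, t = rec$t[idx],
                 x = rec$x[idx], y = rec$y[idx])
}

#' Render the three graphical outputs to files
#'
#' @param rec A [recording()].
#' @param cls Classification tibble.
#' @param tpl Template tibble.
#' @param dir Output directory.
#' @param width,height,dpi Image geometry (inches / dots per inch).
#' @param device Image device passed to [ggplot2::ggsave()] (e.g. `"png"`,
#'   `"pdf"`).
#' @return Character vector of the written paths.
#' @export
render_outputs <- function(rec, cls, tpl, dir, width = 7, height = 5,
                           dpi = 150, device = "png") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  plots <- list(graphic = plot_graphic(rec),
                velocity = plot_velocity(rec),
                procedure = plot_procedure(rec, cls, tpl))
  paths <- character()
  for (nm in names(plots)) {
    path <- file.path(dir, paste0(nm, ".", device))
    ggplot2::ggsave(path, plots[[nm]], width = width, height = height,
                    dpi = dpi)
    paths <- c(paths, path)
  }
  paths
}

#' @rdname plot_graphic
#' @param object A `rey_scores` object (autoplot shows its tidy indices).
#' @param ... Unused.
#' @method autoplot rey_scores
#' @export
autoplot.rey_scores <- function(object, ...) {
  df <- tidy.rey_scores(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value,
                                   fill = .data$dimension)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~dimension, scales = "free") +
    ggplot2::labs(x = NULL, y = "index value") +
    ggplot2::theme_minimal()
}

#' @rdname plot_graphic
#' @method autoplot rey_pca
#' @export
autoplot.rey_pca <- function(object, ...) {
  df <- tidy.rey_pca(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$variable,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$loading)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
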