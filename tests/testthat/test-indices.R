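test_that("spatial indices are population SDs of deviations about their mean", {
  # 10 elements on the horizontal median family: nine exact, one shifted +3 mm in x
  ids <- the_template$id[the_template$kind == "segment"][1:10]
  tch <- template_observations(the_template)
  obs <- purrr::map_dfr(seq_along(ids), function(i) {
    row <- tch[tch$element_id == ids[i], ]
    dx <- if (i == 10) 3 else 0
    observation_row(ids[i], c(row$ex1 + dx, row$ey1), c(row$ex2 + dx, row$ey2))
  })
  sp <- spatial_indices(obs, the_template)
  # oracle: mean 0.3, population SD sqrt((9*0.09 + 7.29)/10) = 0.9
  expect_equal(sp$sHP, 0.9, tolerance = 1e-12)
  expect_equal(sp$sVP, 0, tolerance = 1e-12)
  expect_equal(sp$sLG, 0, tolerance = 1e-12)
  expect_equal(sp$sIC, 0, tolerance = 1e-12)

  expect_error(spatial_indices(obs[1, ], the_template), "at least 2")
})

test_that("inclination deviations wrap to the acute difference", {
  expect_equal(wrap_angle_90(170 - 10), -20)
  expect_equal(wrap_angle_90(10 - 170), 20)
  expect_equal(wrap_angle_90(90), 90)
  expect_equal(wrap_angle_90(-90), 90)
  # enumeration oracle: wrapped difference is the smallest rotation taking
  # one undirected line onto the other
  set.seed(8)
  for (rep in 1:100) {
    a <- runif(1, 0, 180); b <- runif(1, 0, 180)
    w <- wrap_angle_90(a - b)
    oracle <- min(abs(a - b), 180 - abs(a - b))
    expect_equal(abs(w), oracle, tolerance = 1e-9)
  }
})

test_that("progress scale is linear in pen-down time and ignores pen-ups", {
  rec <- line_recording(c(0, 0), c(50, 0), duration = 2, fs = 50)
  p <- progress_scale(rec)
  expect_equal(p$progress[1], 0)
  expect_equal(p$progress[nrow(p)], 100)
  expect_equal(p$progress, seq(0, 100, length.out = nrow(p)), tolerance = 1e-9)

  # pen-up exclusion: the same contact samples with a 10 s versus a 0.5 s
  # pen-up gap give identical progress values
  with_gap <- function(gap_len) {
    r1 <- line_recording(c(0, 0), c(25, 0), duration = 1, fs = 50)
    r2 <- line_recording(c(25, 0), c(50, 0), duration = 1, fs = 50,
                         t0 = 1 + gap_len)
    gap <- tibble::tibble(t = 1 + gap_len / 2, x = 25, y = 0, contact = FALSE)
    both <- dplyr::bind_rows(tibble::as_tibble(r1), gap, tibble::as_tibble(r2))
    recording(both$t, both$x, both$y, both$contact)
  }
  p10 <- progress_scale(with_gap(10))
  p05 <- progress_scale(with_gap(0.5))
  expect_equal(p10$progress, p05$progress, tolerance = 1e-9)

  # length-based scale: progress follows drawn distance, not time
  slow_then_fast <- recording(c(0, 1, 1.1, 1.2), c(0, 10, 20, 30),
                              rep(0, 4), rep(TRUE, 4))
  pl <- progress_scale(slow_then_fast, by = "length")
  expect_equal(pl$progress, c(0, 100 / 3, 200 / 3, 100), tolerance = 1e-9)

  # irregular sampling: cumulative-time oracle
  set.seed(13)
  tt <- sort(runif(100, 0, 3))
  ri <- recording(tt, seq_along(tt), rep(0, 100), rep(TRUE, 100))
  pi <- progress_scale(ri)
  oracle <- 100 * (tt - tt[1]) / (tt[100] - tt[1])
  expect_equal(pi$progress, oracle, tolerance = 1e-9)
})

test_that("structure priority is the mean progress over that structure", {
  # base rectangle occupies exactly the first 20% of contact time
  fs <- 100
  r_br <- line_recording(c(-40, 28), c(40, 28), duration = 2, fs = fs)
  r_id <- line_recording(c(-30, -4), c(-10, -4), duration = 8, fs = fs,
                         t0 = 2 + 1 / fs)
  rec <- recording(c(r_br$t, r_id$t), c(r_br$x, r_id$x), c(r_br$y, r_id$y),
                   rep(TRUE, nrow(r_br) + nrow(r_id)))
  subs <- segment_strokes(rec)
  split <- split_substroke(subs, 1, nrow(r_br), rec)
  cls <- apply_labels(split, tibble::tibble(
    substroke_id = 1:2, category = "element", element_id = c(1L, 19L)))
  pBR <- structure_priority(rec, cls, the_template, "base_rectangle")
  pID <- structure_priority(rec, cls, the_template, "inner_detail")
  expect_equal(pBR, 10, tolerance = 0.5)
  expect_gt(pID, 55)

  # never-drawn structure reports missing, not zero
  expect_true(is.na(structure_priority(rec, cls, the_template,
                                       "outer_configuration")))
})

test_that("inner details confined to the final 10% average near 95", {
  fs <- 100
  r_other <- line_recording(c(-40, 28), c(40, 28), duration = 9, fs = fs)
  r_id <- line_recording(c(-30, -4), c(-10, -4), duration = 1, fs = fs,
                         t0 = 9 + 1 / fs)
  rec <- recording(c(r_other$t, r_id$t), c(r_other$x, r_id$x),
                   c(r_other$y, r_id$y), rep(TRUE, nrow(r_other) + nrow(r_id)))
  subs <- segment_strokes(rec)
  split <- split_substroke(subs, 1, nrow(r_other), rec)
  cls <- apply_labels(split, tibble::tibble(
    substroke_id = 1:2, category = "element", element_id = c(1L, 19L)))
  expect_equal(structure_priority(rec, cls, the_template, "inner_detail"),
               95, tolerance = 0.5)
})

test_that("pOR counts interruptions of pending primary work", {
  # organised extreme: all primary then all secondary
  v <- visits_from_relevance(c("P", "P", "P", "S", "S"))
  expect_equal(organisation_by_relevance(v), 0L)

  # P S P S P with 3 distinct primary elements -> 2
  v2 <- visits_from_relevance(c("P", "S", "P", "S", "P"))
  expect_equal(organisation_by_relevance(v2), 2L)

  # returning to finished primaries creates no pending work
  v3 <- visits_from_relevance(c("P", "P", "S", "P", "S"),
                              element_ids = c(1L, 2L, 101L, 1L, 102L))
  expect_equal(organisation_by_relevance(v3), 0L)
})

test_that("pFR counts unit-run interruptions", {
  mk <- function(units) {
    tibble::tibble(element_id = seq_along(units), unit = units,
                   structure = "inner_detail", relevance = "secondary",
                   t_on = seq_along(units), t_off = seq_along(units) + 0.5)
  }
  expect_equal(fragmentation(mk(c(1, 1, 2, 2, 3))), 0L)
  expect_equal(fragmentation(mk(c(1, 2, 1))), 1L)
  expect_equal(fragmentation(mk(c(1, 2, 1, 2, 1))), 3L)
})

test_that("pOR and pFR match brute-force enumerators on random sequences", {
  set.seed(17)
  ok <- vapply(1:2000, function(rep) {
    v <- random_visits(sample(2:25, 1))
    identical(as.integer(organisation_by_relevance(v)),
              as.integer(oracle_por(v$relevance, v$element_id))) &&
      identical(as.integer(fragmentation(v)), as.integer(oracle_pfr(v$unit)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("the 7 Hz smoothing passes 2 Hz and blocks 20 Hz", {
  fs <- 100
  tt <- seq(0, 4, by = 1 / fs)
  for (freq in c(2, 20)) {
    sp_true <- 30 + 20 * sin(2 * pi * freq * tt)
    # feed the filter directly through a constant-velocity x plus oscillation
    bf <- signal::butter(4, 7 / (fs / 2), type = "low")
    filtered <- filtfilt_padded(bf, sp_true)
    amp <- (max(filtered[100:300]) - min(filtered[100:300])) / 2
    if (freq == 2) expect_gt(amp / 20, 0.98) else expect_lt(amp / 20, 0.05)
  }
})

test_that("stationary pen gives identically zero speed", {
  rec <- recording(seq(0, 1, by = 0.01), rep(5, 101), rep(5, 101),
                   rep(TRUE, 101), meta = list(fs = 100))
  prof <- speed_profile(rec)
  expect_true(all(abs(prof$speed) < 1e-9))
})

test_that("kinematic segmentation splits at interior stops and drops short strokes", {
  # one bell-shaped 60 mm stroke
  rec1 <- speed_driven_recording(function(t) 60 * pi / 2 * sin(pi * t), 1, fs = 100)
  prof1 <- speed_profile(rec1, fs = 100)
  ks1 <- kinematic_segments(prof1)
  expect_equal(nrow(ks1), 1)
  expect_gt(ks1$path_length, 50)

  # a mid-course full stop splits the run in two
  vfun <- function(t) ifelse(t < 1, 60 * sin(pi * t), 60 * sin(pi * (t - 1)))
  rec2 <- speed_driven_recording(function(t) pmax(vfun(t), 0), 2, fs = 100)
  prof2 <- speed_profile(rec2, fs = 100)
  ks2 <- kinematic_segments(prof2)
  expect_equal(nrow(ks2), 2)

  # an 8 mm micro-stroke is discarded
  rec3 <- speed_driven_recording(function(t) 8 * pi / 2 * sin(pi * t), 1, fs = 100)
  prof3 <- speed_profile(rec3, fs = 100)
  expect_equal(nrow(kinematic_segments(prof3)), 0)
})

test_that("half-sine strokes reproduce the closed-form kinematics", {
  V <- 60; TT <- 0.5; fs <- 200
  rec <- speed_driven_recording(function(t) V * sin(pi * t / TT), TT, fs = fs)
  prof <- speed_profile(rec, fs = fs)
  ks <- kinematic_segments(prof)
  ki <- kinematic_indices(prof, ks, fs)
  expect_equal(ki$kVL, 2 * V / pi, tolerance = 0.02)
  expect_equal(ki$kAC, 2 * V / TT, tolerance = 0.05)
  expect_equal(ki$kDC, 2 * V / TT, tolerance = 0.05)
  expect_equal(ki$kPK, 1)
})

test_that("averaging two identical strokes equals the single-stroke value", {
  V <- 60; TT <- 0.5; fs <- 200
  one <- speed_driven_recording(function(t) V * sin(pi * t / TT), TT, fs = fs)
  gap <- tibble::tibble(t = TT + 0.15, x = max(one$x), y = 0, contact = FALSE)
  two_t <- one$t + TT + 0.3
  both <- dplyr::bind_rows(tibble::as_tibble(one), gap,
                           tibble::tibble(t = two_t, x = one$x + max(one$x) + 5,
                                          y = 0, contact = TRUE))
  rec <- recording(both$t, both$x, both$y, both$contact, meta = list(fs = fs))
  prof <- speed_profile(rec, fs = fs)
  ks <- kinematic_segments(prof)
  expect_equal(nrow(ks), 2)
  ki <- kinematic_indices(prof, ks, fs)
  one_prof <- speed_profile(one, fs = fs)
  ki1 <- kinematic_indices(one_prof, kinematic_segments(one_prof), fs)
  expect_equal(ki$kVL, ki1$kVL, tolerance = 1e-6)
  expect_equal(ki$kPK, ki1$kPK)
})

test_that("peak counting follows derivative sign changes", {
  # three analytic local maxima within one stroke
  vfun <- function(t) 40 + 20 * sin(2 * pi * 3 * t / 2)  # 3 peaks over 2 s
  rec <- speed_driven_recording(vfun, 2, fs = 100)
  prof <- speed_profile(rec, fs = 100)
  ks <- kinematic_segments(prof)
  ki <- kinematic_indices(prof, ks, fs = 100)
  expect_equal(ki$kPK, 3)
})

test_that("score_drawing on a fragmented disorganised simulation moves the dials", {
  sim <- simulate_drawing(the_template, drawing_config(
    strategy = "fragmented", fragment_prob = 0.6, shuffle_strength = 0.4,
    seed = 55))
  sc <- score_drawing(sim$recording, sim$labels, the_template)
  expect_gt(sc$indices$pFR, 0)
  expect_gt(sc$indices$pOR, 0)
})

test_that("kVL scales with spatial magnification at fixed timing; kPK does not", {
  sim <- simulate_drawing(the_template, drawing_config(seed = 56))
  rec <- sim$recording
  big <- recording(rec$t, 2 * rec$x, 2 * rec$y, rec$contact,
                   meta = as.list(attr(rec, "meta")))
  s1 <- score_drawing(rec, sim$labels, the_template)
  s2 <- score_drawing(big, sim$labels, the_template)
  expect_equal(s2$indices$kVL / s1$indices$kVL, 2, tolerance = 0.05)
  expect_equal(s2$indices$kPK, s1$indices$kPK, tolerance = 0.05)
})

test_that("procedural indices survive time rescaling and pen-up insertion", {
  sim <- simulate_drawing(the_template, drawing_config(
    strategy = "fragmented", fragment_prob = 0.5, shuffle_strength = 0.3,
    seed = 57))
  rec <- sim$recording
  slow <- recording(rec$t * 3, rec$x, rec$y, rec$contact,
                    meta = as.list(attr(rec, "meta")))
  s1 <- score_drawing(rec, sim$labels, the_template)
  s2 <- score_drawing(slow, sim$labels, the_template)
  expect_equal(s2$indices$pBR, s1$indices$pBR, tolerance = 1e-6)
  expect_equal(s2$indices$pID, s1$indices$pID, tolerance = 1e-6)
  expect_equal(s2$indices$pOR, s1$indices$pOR)
  expect_equal(s2$indices$pFR, s1$indices$pFR)
})
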