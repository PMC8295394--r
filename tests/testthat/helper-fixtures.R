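# shared fixtures and independent oracles, built in code

the_template <- canonical_template()

# straight-line contact run traced at constant speed
line_recording <- function(p1, p2, duration = 1, fs = 100, t0 = 0) {
  tt <- seq(0, duration, by = 1 / fs)
  recording(t0 + tt,
            p1[1] + (p2[1] - p1[1]) * tt / duration,
            p1[2] + (p2[2] - p1[2]) * tt / duration,
            rep(TRUE, length(tt)), meta = list(fs = fs))
}

# a recording moving along x with a prescribed speed profile v(t)
speed_driven_recording <- function(v_fun, duration, fs = 200) {
  tt <- seq(0, duration, by = 1 / fs)
  v <- v_fun(tt)
  s <- cumsum(c(0, (v[-1] + v[-length(v)]) / 2 * diff(tt)))
  recording(tt, s, rep(0, length(tt)), rep(TRUE, length(tt)),
            meta = list(fs = fs))
}

# visit tibble from relevance letters ("P"/"S") with distinct elements;
# primary elements reuse ids when a letter index repeats
visits_from_relevance <- function(letters_vec, element_ids = seq_along(letters_vec)) {
  tibble::tibble(
    element_id = element_ids,
    unit = element_ids,
    structure = ifelse(letters_vec == "P", "base_rectangle", "inner_detail"),
    relevance = ifelse(letters_vec == "P", "primary", "secondary"),
    t_on = seq_along(letters_vec),
    t_off = seq_along(letters_vec) + 0.5
  )
}

# independent brute-force counter for primary->secondary interruptions:
# for each transition, scan the whole sequence for a primary element whose
# first visit lies strictly after the transition point
oracle_por <- function(relevance, element_id) {
  n <- length(relevance)
  count <- 0
  for (i in seq_len(n - 1)) {
    if (relevance[i] == "primary" && relevance[i + 1] == "secondary") {
      prim <- unique(element_id[relevance == "primary"])
      pending <- vapply(prim, function(e) {
        first <- which(element_id == e & relevance == "primary")[1]
        first > i
      }, logical(1))
      if (any(pending)) count <- count + 1
    }
  }
  count
}

# independent run-counting oracle for unit fragmentation
oracle_pfr <- function(units) {
  merged <- units[c(TRUE, diff(units) != 0)]
  total <- 0
  for (u in unique(merged)) total <- total + sum(merged == u) - 1
  total
}

# random visit sequences over a mix of primary/secondary elements
random_visits <- function(n_visits, n_primary = 4, n_secondary = 6) {
  ids <- sample(c(seq_len(n_primary), 100 + seq_len(n_secondary)),
                n_visits, replace = TRUE)
  ids <- ids[c(TRUE, diff(ids) != 0)]  # visits: consecutive ids distinct
  tibble::tibble(
    element_id = ids,
    unit = ifelse(ids > 100, ids - 100 + n_primary, ids),
    structure = ifelse(ids > 100, "inner_detail", "base_rectangle"),
    relevance = ifelse(ids > 100, "secondary", "primary"),
    t_on = seq_along(ids), t_off = seq_along(ids) + 0.5)
}
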