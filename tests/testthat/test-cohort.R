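test_that("4-SD outlier exclusion removes exactly the planted rows", {
  set.seed(61)
  sim <- simulate_cohort(cohort_config(n = 100, seed = 61))
  M <- sim$scores
  excl0 <- exclude_outliers(M)
  # all |z| < 4 in a clean standard-normal-ish sample of 100: no exclusions
  expect_equal(nrow(excl0$retained) + nrow(excl0$excluded), 100)

  # plant one row at 5 SD on one index
  M2 <- M
  M2$sHP[17] <- mean(M$sHP) + 5 * stats::sd(M$sHP)
  excl2 <- exclude_outliers(M2)
  expect_false(excl2$mask[17])
  expect_gte(sum(excl2$mask), 98)
})

test_that("a 102-row cohort with 5 planted outliers retains 97", {
  set.seed(62)
  sim <- simulate_cohort(cohort_config(n = 102, seed = 62))
  M <- sim$scores
  planted <- c(5, 23, 41, 77, 100)
  for (i in seq_along(planted)) {
    col <- index_names[i]
    M[[col]][planted[i]] <- mean(M[[col]]) + 6 * stats::sd(M[[col]])
  }
  excl <- exclude_outliers(M)
  expect_equal(nrow(excl$retained), 97)
  expect_setequal(which(!excl$mask), planted)
})

test_that("KMO matches its closed forms", {
  # p = 2: partial equals marginal, MSA = 0.5 for any r != 0
  R2 <- matrix(c(1, 0.37, 0.37, 1), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(kmo(R2)$overall, 0.5, tolerance = 1e-12)

  # p = 3 equicorrelated rho = 0.5: partials are 1/3, MSA = 0.6923
  R3 <- matrix(0.5, 3, 3); diag(R3) <- 1
  colnames(R3) <- rownames(R3) <- c("a", "b", "c")
  expect_equal(kmo(R3)$overall, 0.6923, tolerance = 1e-4)
  expect_equal(unname(kmo(R3)$per_variable), rep(0.6923, 3), tolerance = 1e-4)

  # identity correlations: MSA undefined
  expect_error(kmo(diag(3)), "undefined")
})

test_that("Bartlett's sphericity follows the chi-square formula", {
  # identity R -> statistic 0, p = 1
  set.seed(63)
  Rid <- diag(4); colnames(Rid) <- rownames(Rid) <- letters[1:4]
  res <- bartlett_sphericity(Rid, n = 50)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # p = 2, r = 0.5, n = 20: chi2 = 17.5 * (-log 0.75)
  R2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  colnames(R2) <- rownames(R2) <- c("a", "b")
  res2 <- bartlett_sphericity(R2, n = 20)
  expect_equal(res2$statistic, 17.5 * (-log(0.75)), tolerance = 1e-10)
  expect_equal(res2$df, 1)

  # 11 variables give df = 55
  set.seed(64)
  Z <- as.data.frame(matrix(rnorm(100 * 11), 100, 11))
  expect_equal(bartlett_sphericity(Z)$df, 55)
})

test_that("varimax PCA satisfies the communality identity and recovers structure", {
  sim <- simulate_cohort(cohort_config(n = 100, seed = 65))
  res <- pca_varimax(sim$scores, 3)
  expect_lt(max(abs(res$h2 + res$u2 - 1)), 1e-10)
  expect_equal(sum(res$eigenvalues), 12, tolerance = 1e-8)

  cong <- tucker_congruence(res$loadings, sim$structure$loadings)
  expect_true(all(cong$congruence > 0.95))
})

test_that("a single-nonzero-loading variable has complexity 1", {
  # build data with one variable loading on exactly one latent
  set.seed(66)
  f <- matrix(rnorm(300), 100, 3)
  z <- cbind(f[, 1] , f[, 1] + 0.1 * rnorm(100), f[, 2], f[, 2] + 0.1 * rnorm(100),
             f[, 3], f[, 3] + 0.1 * rnorm(100))
  colnames(z) <- paste0("v", 1:6)
  res <- pca_varimax(as.data.frame(z), 3)
  expect_lt(max(res$com), 1.2)
  expect_equal(min(res$com), 1, tolerance = 0.05)
})

test_that("parallel analysis is deterministic under a seed and retains true factors", {
  sim <- simulate_cohort(cohort_config(n = 100, seed = 67))
  pa1 <- parallel_analysis(sim$scores, n_sims = 200, seed = 99)
  pa2 <- parallel_analysis(sim$scores, n_sims = 200, seed = 99)
  expect_identical(pa1$reference, pa2$reference)
  expect_gte(pa1$retained, 2)
  expect_equal(pa1$kaiser, 3)

  # single dominant factor
  L1 <- matrix(0, 12, 3, dimnames = list(index_names, c("A", "B", "C")))
  L1[, 1] <- 0.85
  sim1 <- simulate_cohort(cohort_config(n = 100, loadings = L1, seed = 68))
  pa <- parallel_analysis(sim1$scores, n_sims = 200, seed = 100)
  expect_equal(pa$retained, 1)
})

test_that("loading-based assignment mirrors the printed decision rules", {
  res <- structure(list(
    loadings = matrix(c(0.84, 0.20, 0.03,
                        0.69, 0.39, 0.17,
                        0.10, 0.05, 0.40), 3, 3, byrow = TRUE,
                      dimnames = list(c("good", "crossing", "weak"),
                                      c("C1", "C2", "C3"))),
    h2 = c(good = 0.75, crossing = 0.66, weak = 0.18),
    u2 = c(good = 0.25, crossing = 0.34, weak = 0.82),
    com = c(1.1, 1.7, 1.2), k = 3), class = "rey_pca")
  asg <- assign_indices(res)
  expect_equal(asg$status[asg$variable == "good"], "assigned")
  expect_equal(asg$component[asg$variable == "good"], "C1")
  expect_equal(asg$status[asg$variable == "crossing"], "cross_dropped")
  expect_equal(asg$status[asg$variable == "weak"], "unassigned")
  expect_true(asg$low_communality[asg$variable == "weak"])
})

test_that("composites average assigned z-scores with declared flips", {
  set.seed(70)
  sim <- simulate_cohort(cohort_config(n = 200, seed = 70))
  res <- pca_varimax(sim$scores, 3)
  asg <- assign_indices(res)
  comp <- composite_scores(sim$scores, asg)
  expect_setequal(names(comp), c("SPA", "PRO", "KIN"))
  # all-zero scores give all-zero composites
  z0 <- sim$scores
  asg_kin <- asg[asg$status == "assigned" &
                   substr(asg$variable, 1, 1) == "k", ]
  # hand-build the KIN composite from the definition (before final reverse,
  # KIN is not in the reverse set)
  Z <- scale(as.matrix(sim$scores))
  hand <- rowMeans(sweep(Z[, asg_kin$variable, drop = FALSE], 2,
                         sign(asg_kin$loading), "*"))
  expect_equal(comp$KIN, hand, tolerance = 1e-12, ignore_attr = TRUE)
  # SPA and PRO are reverse-scored at the end: higher = better
  asg_spa <- asg[asg$status == "assigned" & substr(asg$variable, 1, 1) == "s", ]
  hand_spa <- -rowMeans(sweep(Z[, asg_spa$variable, drop = FALSE], 2,
                              sign(asg_spa$loading), "*"))
  expect_equal(comp$SPA, hand_spa, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("perturbing one index moves only its own composite, linearly", {
  set.seed(71)
  sim <- simulate_cohort(cohort_config(n = 150, seed = 71))
  res <- pca_varimax(sim$scores, 3)
  asg <- assign_indices(res)
  comp1 <- composite_scores(sim$scores, asg)
  # add a constant to one participant's kVL *after* standardisation would be
  # circular; instead verify linearity through the z-scale directly
  Z <- scale(as.matrix(sim$scores))
  a <- asg[asg$status == "assigned", ]
  kin_vars <- a$variable[a$component == a$component[a$variable == "kVL"]]
  delta <- 2
  Z2 <- Z; Z2[5, "kVL"] <- Z2[5, "kVL"] + delta
  kin1 <- rowMeans(sweep(Z[, kin_vars, drop = FALSE], 2,
                         sign(a$loading[match(kin_vars, a$variable)]), "*"))
  kin2 <- rowMeans(sweep(Z2[, kin_vars, drop = FALSE], 2,
                         sign(a$loading[match(kin_vars, a$variable)]), "*"))
  flip <- unname(sign(a$loading[a$variable == "kVL"]))
  expect_equal(unname(kin2[5] - kin1[5]), delta * flip / length(kin_vars),
               tolerance = 1e-12)
  expect_equal(kin2[-5], kin1[-5], tolerance = 1e-12)
})

test_that("Cronbach's alpha matches closed forms and simulation limits", {
  set.seed(72)
  x <- rnorm(500)
  ident <- cbind(x, x, x)
  expect_equal(cronbach_alpha(ident), 1, tolerance = 1e-12)

  # two items with correlation r: alpha = 2r / (1 + r)
  r <- 0.6
  y <- r * x + sqrt(1 - r^2) * rnorm(500)
  # use the empirical r in the closed form so the identity is exact
  remp <- stats::cor(x, y)
  # standardise items so the closed form applies exactly
  two <- cbind(scale(x), scale(y))
  expect_equal(cronbach_alpha(two), 2 * remp / (1 + remp), tolerance = 1e-12)

  # independent items: alpha near 0
  set.seed(73)
  ind <- matrix(rnorm(10000 * 2), 10000, 2)
  expect_lt(abs(cronbach_alpha(ind)), 0.1)
})

test_that("partial correlation reduces to Pearson and matches a two-stage oracle", {
  set.seed(74)
  x <- rnorm(80); y <- 0.5 * x + rnorm(80)
  plain <- partial_correlation(x, y)
  expect_equal(plain$estimate, stats::cor(x, y), tolerance = 1e-12)
  expect_equal(plain$df, 78)

  # y = x exactly with a covariate
  c1 <- rnorm(80)
  exact <- partial_correlation(x, x + 0 * c1, covariates = cbind(c1))
  expect_equal(exact$estimate, 1, tolerance = 1e-9)

  # two-stage regression oracle
  c2 <- rnorm(80)
  yy <- 0.4 * x + 0.7 * c1 - 0.2 * c2 + rnorm(80)
  got <- partial_correlation(x, yy, covariates = cbind(c1, c2))
  rx <- stats::resid(stats::lm(x ~ c1 + c2))
  ry <- stats::resid(stats::lm(yy ~ c1 + c2))
  expect_equal(got$estimate, stats::cor(rx, ry), tolerance = 1e-10)
  expect_equal(got$df, 80 - 2 - 2)
  # one-tailed p halves the two-tailed p for a positive estimate
  one <- partial_correlation(x, yy, covariates = cbind(c1, c2),
                             alternative = "greater")
  expect_equal(one$p_value, got$p_value / 2, tolerance = 1e-12)

  expect_error(partial_correlation(rep(1, 10), rnorm(10)), "constant")
})

test_that("split-sample validation halves the sample and reproduces structure", {
  sim <- simulate_cohort(cohort_config(n = 98, seed = 75))
  sp <- split_sample_validation(sim$scores, seed = 7)
  expect_equal(sum(sp$split), 49)
  expect_equal(sum(!sp$split), 49)
  expect_true(all(sp$congruence$congruence > 0.9))

  sp2 <- split_sample_validation(sim$scores, seed = 7)
  expect_identical(sp$split, sp2$split)

  # odd n: halves differ by one
  simo <- simulate_cohort(cohort_config(n = 97, seed = 76))
  spo <- split_sample_validation(simo$scores, seed = 8)
  expect_equal(abs(sum(spo$split) - sum(!spo$split)), 1)
})

test_that("the full cohort pipeline recovers a 3-component simple structure", {
  sim <- simulate_cohort(cohort_config(n = 100, seed = 77))
  res <- score_cohort(sim$scores, n_sims = 200, seed = 78)
  expect_equal(res$pca$k, 3)
  expect_length(res$dropped_cross, 0)
  expect_setequal(names(res$alpha), c("SPA", "PRO", "KIN"))
  expect_true(all(res$alpha > 0.6))
  expect_equal(nrow(res$composites), nrow(res$retained))
  # trace conservation
  expect_equal(sum(res$pca$eigenvalues), ncol(res$retained), tolerance = 1e-8)
})

test_that("composites are invariant to affine rescaling of raw indices", {
  sim <- simulate_cohort(cohort_config(n = 120, seed = 79))
  res <- pca_varimax(sim$scores, 3)
  asg <- assign_indices(res)
  comp1 <- composite_scores(sim$scores, asg)
  rescaled <- purrr::map2_dfc(sim$scores, seq_len(12),
                              function(col, i) col * (i + 1) - 3 * i)
  names(rescaled) <- names(sim$scores)
  comp2 <- composite_scores(rescaled, asg)
  expect_equal(as.data.frame(comp1), as.data.frame(comp2), tolerance = 1e-10)
})

test_that("an index uncorrelated with the rest is dropped by the MSA screen", {
  set.seed(80)
  sim <- simulate_cohort(cohort_config(n = 100, seed = 80))
  M <- sim$scores
  M$pID <- rnorm(100)  # sever pID from everything
  res <- score_cohort(M, n_sims = 150, seed = 81)
  expect_true("pID" %in% res$dropped_msa)
  expect_equal(ncol(res$retained), 12)
  expect_false("pID" %in% rownames(res$pca$loadings))
})
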