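#' Exclude multivariate outliers by the k-SD rule
#'
#' A participant is excluded when any index deviates more than `k` standard
#' deviations from that index's mean. Single pass: means and SDs come from
#' the full sample and are not re-estimated after removal.
#'
#' @param scores Participant-by-index data frame.
#' @param k SD multiple (default 4, the conservative rule of thumb for
#'   samples larger than 80).
#' @return A list: `retained` (tibble), `excluded` (tibble), `mask`
#'   (logical, TRUE = retained).
#' @export
exclude_outliers <- function(scores, k = 4) {
  M <- as.matrix(scores)
  if (nrow(M) < 2) stop("need at least 2 rows", call. = FALSE)
  mu <- colMeans(M)
  sd <- apply(M, 2, stats::sd)
  zero <- sd == 0
  if (any(zero)) {
    warning("zero-variance column(s) skipped: ",
            paste(colnames(M)[zero], collapse = ", "), call. = FALSE)
  }
  use <- which(!zero)
  z <- sweep(sweep(M[, use, drop = FALSE], 2, mu[use]), 2, sd[use], "/")
  mask <- apply(abs(z) <= k, 1, all)
  list(retained = tibble::as_tibble(scores)[mask, ],
       excluded = tibble::as_tibble(scores)[!mask, ],
       mask = mask)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall and per-variable MSA from the marginal correlations and the
#' anti-image partial correlations. Per-variable values below 0.5 flag
#' indices unsuitable for the component analysis.
#'
#' @param x Data frame of scores, or a correlation matrix.
#' @return A list: `overall`, `per_variable` (named vector).
#' @export
kmo <- function(x) {
  R <- as_cor(x)
  p <- ncol(R)
  S <- try(solve(R), silent = TRUE)
  if (inherits(S, "try-error")) {
    stop("correlation matrix is singular; KMO is undefined ",
         "(drop collinear variables first)", call. = FALSE)
  }
  Pp <- -S / sqrt(outer(diag(S), diag(S)))  # anti-image partial correlations
  diag(Pp) <- 0
  R0 <- R; diag(R0) <- 0
  sr <- sum(R0^2); sp <- sum(Pp^2)
  if (sr + sp == 0) stop("all correlations are zero; MSA is undefined (0/0)",
                         call. = FALSE)
  per <- rowSums(R0^2) / (rowSums(R0^2) + rowSums(Pp^2))
  names(per) <- colnames(R)
  list(overall = sr / (sr + sp), per_variable = per)
}

as_cor <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == ncol(x) && isTRUE(all.equal(unname(diag(x)), rep(1, ncol(x)))) &&
      isTRUE(all.equal(x, t(x)))) {
    return(x)
  }
  stats::cor(x)
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is an identity:
#' `chi2 = -(n - 1 - (2p + 5)/6) * log(det(R))` with `p(p-1)/2` degrees of
#' freedom.
#'
#' @param x Data frame of scores, or a correlation matrix (then `n` is
#'   required).
#' @param n Sample size.
#' @return A tibble: `statistic`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(x, n = nrow(x)) {
  R <- as_cor(x)
  p <- ncol(R)
  if (n <= p) stop("sample size must exceed the number of variables",
                   call. = FALSE)
  detR <- det(R)
  if (detR <= 0) stop("correlation matrix is not positive definite",
                      call. = FALSE)
  stat <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  tibble::tibble(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' PCA with varimax rotation
#'
#' Principal components of the correlation matrix; the first `k` component
#' loadings (eigenvector times square root of eigenvalue) are rotated with
#' Kaiser-normalised varimax. Components are ordered by rotated variance
#' and sign-fixed so each component's largest-magnitude loading is
#' positive. Per variable: communality `h2` (row sum of squared loadings),
#' uniqueness `u2 = 1 - h2`, and Hoffman's complexity
#' `com = (sum lambda^2)^2 / sum lambda^4`.
#'
#' @param z Column-standardised data frame (or any data frame; correlations
#'   are scale-free).
#' @param k Number of components to retain.
#' @return An object of class `rey_pca`: `loadings` (variables x k),
#'   `eigenvalues` (all p), `h2`, `u2`, `com`, `variance_share` (per rotated
#'   component), `rotation = "varimax"`, `n`, `k`.
#' @export
pca_varimax <- function(z, k = 3) {
  R <- as_cor(z)
  p <- ncol(R)
  if (k < 1 || k > p) stop("k must be between 1 and the number of variables",
                           call. = FALSE)
  ei <- eigen(R, symmetric = TRUE)
  if (k > sum(ei$values > 1e-10)) stop("k exceeds the rank of the data",
                                       call. = FALSE)
  L <- ei$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ei$values[seq_len(k)]), k)
  if (k > 1) {
    rot <- stats::varimax(L, normalize = TRUE)
    L <- unclass(rot$loadings)
  }
  # order by rotated variance, sign-fix
  ss <- colSums(L^2)
  ord <- order(ss, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  ss <- ss[ord]
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- colnames(R)
  colnames(L) <- paste0("C", seq_len(k))
  h2 <- rowSums(L^2)
  structure(list(loadings = L, eigenvalues = ei$values, h2 = h2, u2 = 1 - h2,
                 com = rowSums(L^2)^2 / rowSums(L^4),
                 variance_share = ss / p, rotation = "varimax",
                 n = if (is.data.frame(z) || (is.matrix(z) && nrow(z) != ncol(z)))
                   nrow(z) else NA_integer_,
                 k = k), class = "rey_pca")
}

#' @export
print.rey_pca <- function(x, digits = 2, ...) {
  cat(sprintf("<rey_pca: %d components, %s rotation>\n", x$k, x$rotation))
  tab <- cbind(round(x$loadings, digits), h2 = round(x$h2, digits),
               u2 = round(x$u2, digits), com = round(x$com, 1))
  print(tab)
  cat("variance shares:", paste(sprintf("%.1f%%", 100 * x$variance_share),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Tidy PCA loadings into long form
#'
#' @param x A `rey_pca` object.
#' @param ... Unused.
#' @return A tibble with `variable`, `component`, `loading`, and per-variable
#'   `h2`, `u2`, `com`.
#' @method tidy rey_pca
#' @export
tidy.rey_pca <- function(x, ...) {
  long <- tibble::as_tibble(x$loadings, rownames = "variable")
  long <- tidyr::pivot_longer(long, -"variable", names_to = "component",
                              values_to = "loading")
  info <- tibble::tibble(variable = rownames(x$loadings), h2 = x$h2,
                         u2 = x$u2, com = x$com)
  dplyr::left_join(long, info, by = "variable")
}

#' One-row PCA summary
#'
#' @param x A `rey_pca` object.
#' @param ... Unused.
#' @return A 1-row tibble: retained components, total variance explained,
#'   first eigenvalues.
#' @method glance rey_pca
#' @export
glance.rey_pca <- function(x, ...) {
  tibble::tibble(k = x$k,
                 total_variance = sum(x$variance_share),
                 eigen1 = x$eigenvalues[1],
                 eigen2 = if (length(x$eigenvalues) > 1) x$eigenvalues[2] else NA_real_,
                 eigen3 = if (length(x$eigenvalues) > 2) x$eigenvalues[3] else NA_real_)
}

#' Horn's parallel analysis and the Kaiser criterion
#'
#' Compares the observed correlation-matrix eigenvalues with the mean (or a
#' quantile) of eigenvalues from `n_sims` standard-normal datasets of
#' identical shape. Components are retained while the observed eigenvalue
#' exceeds its simulated reference, counting from the first; the Kaiser
#' count (eigenvalues greater than 1) is reported alongside.
#'
#' @param z Data frame of scores.
#' @param n_sims Number of simulated datasets (>= 100).
#' @param quantile `NULL` for the mean reference (default), or a probability
#'   (e.g. 0.95) for a quantile reference.
#' @param seed Integer seed; fixed seed gives bit-identical references.
#' @return A list: `observed`, `reference`, `retained`, `kaiser`.
#' @export
parallel_analysis <- function(z, n_sims = 1000, quantile = NULL, seed = NULL) {
  if (n_sims < 100) stop("n_sims must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(z); p <- ncol(z)
  observed <- eigen(stats::cor(as.matrix(z)), symmetric = TRUE,
                    only.values = TRUE)$values
  sims <- matrix(NA_real_, n_sims, p)
  for (s in seq_len(n_sims)) {
    sims[s, ] <- eigen(stats::cor(matrix(stats::rnorm(n * p), n, p)),
                       symmetric = TRUE, only.values = TRUE)$values
  }
  reference <- if (is.null(quantile)) colMeans(sims) else
    apply(sims, 2, stats::quantile, probs = quantile)
  above <- observed > reference
  retained <- if (above[1]) which(c(!above, TRUE))[1] - 1L else 0L
  list(observed = observed, reference = reference, retained = retained,
       kaiser = sum(observed > 1))
}

#' Assign indices to components by their loadings
#'
#' Each variable is assigned to its largest-magnitude component when that
#' loading reaches `primary`; variables loading at least `cross` on two or
#' more components are flagged cross-loading and dropped from the
#' assignment; communalities below `communality` are flagged.
#'
#' @param res A `rey_pca` object.
#' @param primary Primary-loading threshold.
#' @param cross Cross-loading threshold.
#' @param communality Low-communality flag threshold.
#' @return A tibble with `variable`, `component` (NA when unassigned or
#'   dropped), `loading` (the signed primary loading), `cross_loading`,
#'   `low_communality`, `status` (`assigned` / `cross_dropped` /
#'   `unassigned`).
#' @export
assign_indices <- function(res, primary = 0.50, cross = 0.30,
                           communality = 0.50) {
  L <- res$loadings
  purrr::map_dfr(seq_len(nrow(L)), function(i) {
    lam <- L[i, ]
    j <- which.max(abs(lam))
    crossing <- sum(abs(lam) >= cross) >= 2
    assigned <- abs(lam[j]) >= primary && !crossing
    tibble::tibble(
      variable = rownames(L)[i],
      component = if (assigned) colnames(L)[j] else NA_character_,
      loading = lam[j],
      cross_loading = crossing,
      low_communality = res$h2[i] < communality,
      status = if (crossing) "cross_dropped" else
        if (assigned) "assigned" else "unassigned")
  })
}

#' Composite SPA / PRO / KIN scores
#'
#' Each composite is the mean of its assigned standardised indices, with
#' negative-loading indices reverse-scored first; composites listed in
#' `final_reverse` are then multiplied by -1 so that higher always means
#' better (higher spatial accuracy, organisation, movement control).
#'
#' @param scores Participant-by-index data frame (raw or standardised;
#'   standardisation is applied internally).
#' @param assignment Assignment tibble from [assign_indices()] (rows with
#'   `status == "assigned"` are used), or a named list
#'   `component -> character vector of index names` with an attached
#'   `flip` attribute.
#' @param final_reverse Composites to reverse-score at the end.
#' @param component_names Optional renaming of components, e.g.
#'   `c(C1 = "KIN", C2 = "PRO", C3 = "SPA")`; by default components are
#'   named by the dimension prefix (s/p/k) of the majority of their indices.
#' @return A tibble with one column per composite, rows = participants.
#' @export
composite_scores <- function(scores, assignment,
                             final_reverse = c("SPA", "PRO"),
                             component_names = NULL) {
  Z <- scale(as.matrix(scores))
  asg <- assignment[assignment$status == "assigned", ]
  if (nrow(asg) == 0) stop("no assigned indices", call. = FALSE)
  miss <- setdiff(asg$variable, colnames(Z))
  if (length(miss) > 0) {
    stop("score matrix is missing index column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  comps <- split(asg, asg$component)
  out <- purrr::map(comps, function(a) {
    zi <- Z[, a$variable, drop = FALSE]
    zi <- sweep(zi, 2, sign(a$loading), "*")  # reverse negative loadings
    rowMeans(zi)
  })
  nm <- if (!is.null(component_names)) unname(component_names[names(out)]) else
    unname(component_name_map(asg)[names(out)])
  names(out) <- nm
  res <- tibble::as_tibble(out)
  for (cn in intersect(final_reverse, names(res))) res[[cn]] <- -res[[cn]]
  res[, order(match(names(res), c("SPA", "PRO", "KIN")))]
}

# name each component by the dimension prefix (s/p/k) of the majority of
# its assigned indices
component_name_map <- function(assignment) {
  asg <- assignment[assignment$status == "assigned", ]
  vapply(split(asg, asg$component), function(a) {
    prefix <- names(sort(table(substr(a$variable, 1, 1)), decreasing = TRUE))[1]
    c(s = "SPA", p = "PRO", k = "KIN")[[prefix]]
  }, character(1))
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a cumulative scale:
#' `alpha = k/(k-1) * (1 - sum(var_i) / var_total)`. Items should already be
#' oriented as they enter the composite (negative-loading items flipped).
#'
#' @param items Participant-by-item matrix or data frame (>= 2 items).
#' @return Numeric alpha.
#' @export
cronbach_alpha <- function(items) {
  M <- as.matrix(items)
  k <- ncol(M)
  if (k < 2) stop("alpha needs at least 2 items", call. = FALSE)
  vt <- stats::var(rowSums(M))
  if (vt == 0) stop("total score has zero variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(M, 2, stats::var)) / vt)
}

#' Partial Pearson correlation
#'
#' Correlation of `x` and `y` after linearly removing the covariates from
#' both; `df = n - n_covariates - 2`. With no covariates this is the plain
#' Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame / matrix of covariates (or NULL).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return A tibble: `estimate`, `statistic`, `df`, `p_value`.
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input", call. = FALSE)
  }
  ncov <- if (is.null(covariates)) 0 else ncol(as.matrix(covariates))
  n <- length(x)
  if (n <= ncov + 2) stop("too few observations for the covariate count",
                          call. = FALSE)
  if (ncov > 0) {
    C <- as.matrix(covariates)
    x <- stats::resid(stats::lm(x ~ C))
    y <- stats::resid(stats::lm(y ~ C))
  }
  r <- stats::cor(x, y)
  df <- n - ncov - 2
  tstat <- r * sqrt(df / (1 - r^2))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
              greater = stats::pt(tstat, df, lower.tail = FALSE),
              less = stats::pt(tstat, df))
  tibble::tibble(estimate = r, statistic = tstat, df = df, p_value = p)
}

#' Tucker's congruence coefficient
#'
#' Cosine similarity between two loading vectors (or columnwise between two
#' loading matrices after greedy best matching).
#'
#' @param a,b Numeric vectors or matrices with equal row counts.
#' @return For vectors, a scalar; for matrices, a tibble with the matched
#'   pairs and their absolute congruence.
#' @export
tucker_congruence <- function(a, b) {
  if (is.null(dim(a))) {
    return(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  }
  ka <- ncol(a); kb <- ncol(b)
  phi <- matrix(NA_real_, ka, kb)
  for (i in seq_len(ka)) for (j in seq_len(kb)) {
    phi[i, j] <- abs(sum(a[, i] * b[, j]) /
                       sqrt(sum(a[, i]^2) * sum(b[, j]^2)))
  }
  pairs <- list()
  used_a <- used_b <- integer()
  for (step in seq_len(min(ka, kb))) {
    phi2 <- phi
    phi2[used_a, ] <- -Inf
    phi2[, used_b] <- -Inf
    ij <- which(phi2 == max(phi2), arr.ind = TRUE)[1, ]
    pairs[[step]] <- tibble::tibble(component_a = ij[1], component_b = ij[2],
                                    congruence = phi[ij[1], ij[2]])
    used_a <- c(used_a, ij[1]); used_b <- c(used_b, ij[2])
  }
  dplyr::bind_rows(pairs)
}

#' Split-sample validation of the component solution
#'
#' Randomly halves the sample (sizes differ by at most 1), refits the
#' varimax-rotated PCA on each half, and reports the Tucker congruence
#' between matched components.
#'
#' @param z Data frame of scores (>= 20 rows).
#' @param k Components.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return A list: `pca1`, `pca2`, `congruence` (matched-pair tibble),
#'   `split` (logical, TRUE = first half).
#' @export
split_sample_validation <- function(z, k = 3, seed = NULL) {
  n <- nrow(z)
  if (n < 20) stop("split-sample validation needs at least 20 rows",
                   call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  first <- sample(n, floor(n / 2))
  split <- seq_len(n) %in% first
  p1 <- pca_varimax(z[split, , drop = FALSE], k)
  p2 <- pca_varimax(z[!split, , drop = FALSE], k)
  list(pca1 = p1, pca2 = p2,
       congruence = tucker_congruence(p1$loadings, p2$loadings),
       split = split)
}

#' Run the full cohort pipeline
#'
#' The end-to-end reduction of an index matrix to composite scores:
#' 4-SD outlier exclusion; per-variable MSA screening (variables below
#' `msa_min` dropped, the data-driven path that typically removes pID);
#' Bartlett's sphericity; retention counts from the Kaiser criterion and
#' parallel analysis; varimax PCA; loading-based assignment with iterative
#' removal of cross-loading variables and refit; composite SPA/PRO/KIN
#' scores; Cronbach's alpha per scale.
#'
#' @param scores Participant-by-index data frame (the 12 indices).
#' @param k Components to retain (default: Kaiser count of the screened
#'   matrix).
#' @param msa_min Per-variable MSA threshold.
#' @param n_sims Parallel-analysis simulations.
#' @param seed Integer seed (parallel analysis).
#' @return An object of class `rey_cohort`: a list with `retained`,
#'   `dropped_msa`, `dropped_cross`, `kmo`, `bartlett`, `parallel`, `pca`,
#'   `assignment`, `composites`, `alpha`.
#' @export
score_cohort <- function(scores, k = NULL, msa_min = 0.5, n_sims = 1000,
                         seed = NULL) {
  excl <- exclude_outliers(scores)
  full <- excl$retained
  kept <- full
  # MSA screening (iterate: dropping a variable changes the others' MSA)
  dropped_msa <- character()
  repeat {
    km <- kmo(kept)
    low <- names(which(km$per_variable < msa_min))
    if (length(low) == 0) break
    worst <- names(which.min(km$per_variable))
    dropped_msa <- c(dropped_msa, worst)
    kept <- kept[, setdiff(names(kept), worst)]
  }
  bart <- bartlett_sphericity(kept)
  pa <- parallel_analysis(kept, n_sims = n_sims, seed = seed)
  if (is.null(k)) k <- max(pa$kaiser, 1L)
  # fit, drop cross-loading variables, refit until clean
  dropped_cross <- character()
  fit_vars <- names(kept)
  repeat {
    pca <- pca_varimax(kept[, fit_vars, drop = FALSE], k)
    asg <- assign_indices(pca)
    crossing <- asg$variable[asg$status == "cross_dropped"]
    if (length(crossing) == 0) break
    worst <- crossing[1]
    dropped_cross <- c(dropped_cross, worst)
    fit_vars <- setdiff(fit_vars, worst)
  }
  comp <- composite_scores(kept, asg)
  Z <- scale(as.matrix(kept))
  alpha <- purrr::map_dbl(split(asg[asg$status == "assigned", ],
                                asg$component[asg$status == "assigned"]),
                          function(a) {
    zi <- sweep(Z[, a$variable, drop = FALSE], 2, sign(a$loading), "*")
    cronbach_alpha(zi)
  })
  names(alpha) <- unname(component_name_map(asg)[names(alpha)])
  structure(list(retained = full, n_excluded = sum(!excl$mask),
                 dropped_msa = dropped_msa, dropped_cross = dropped_cross,
                 kmo = kmo(kept[, fit_vars, drop = FALSE]),
                 bartlett = bart, parallel = pa, pca = pca,
                 assignment = asg, composites = comp, alpha = alpha),
            class = "rey_cohort")
}

#' @export
print.rey_cohort <- function(x, ...) {
  cat(sprintf("<rey_cohort: %d retained (%d excluded), %d component(s)>\n",
              nrow(x$retained), x$n_excluded, x$pca$k))
  if (length(x$dropped_msa) > 0)
    cat("dropped (MSA):", paste(x$dropped_msa, collapse = ", "), "\n")
  if (length(x$dropped_cross) > 0)
    cat("dropped (cross-loading):", paste(x$dropped_cross, collapse = ", "), "\n")
  print(x$pca)
  cat("Cronbach's alpha:",
      paste(sprintf("%s = %.2f", names(x$alpha), x$alpha), collapse = ", "), "\n")
  invisible(x)
}
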