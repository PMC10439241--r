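#' Cyclic LOESS normalization of a log2 intensity matrix
#'
#' Between-sample normalization by locally weighted regression on M-A pairs.
#' For every pair of samples (iterated cyclically), M = x_i - x_j is
#' regressed on A = (x_i + x_j)/2 over the features observed in both
#' samples, and half of the fitted trend is subtracted from sample i and
#' added to sample j. Missing values are left untouched.
#'
#' @param x numeric matrix (features x samples, log2 scale) or an
#'   [expression_matrix()].
#' @param span LOESS span (fraction of features in each local window).
#' @param iterations number of full cycles over all sample pairs.
#' @return Same container as `x`, normalized.
#' @export
cyclic_loess_normalize <- function(x, span = 0.7, iterations = 3) {
  vals <- .as_values(x)
  if (ncol(vals) < 2) stop("cyclic LOESS requires at least 2 samples")
  stopifnot(span > 0, span <= 1, iterations >= 1)
  n <- ncol(vals)
  for (iter in seq_len(iterations)) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        ok <- stats::complete.cases(vals[, c(i, j), drop = FALSE])
        if (sum(ok) < 10) next
        M <- vals[ok, i] - vals[ok, j]
        A <- (vals[ok, i] + vals[ok, j]) / 2
        if (stats::sd(A) == 0 || stats::sd(M) < 1e-10) {
          fit <- rep(mean(M), sum(ok))
        } else {
          lo <- stats::loess(M ~ A, span = span, degree = 1,
                             family = "symmetric")
          fit <- stats::fitted(lo)
          if (anyNA(fit)) fit <- rep(mean(M), sum(ok))
        }
        vals[ok, i] <- vals[ok, i] - fit / 2
        vals[ok, j] <- vals[ok, j] + fit / 2
      }
    }
  }
  .restore_values(x, vals)
}

#' Robust linear regression (RLR) normalization
#'
#' Each sample is regressed against the feature-wise median reference with
#' an iteratively reweighted least-squares M-estimator (Huber weights), and
#' the fitted linear distortion is inverted: x_norm = (x - intercept)/slope.
#' A sample that already equals the reference is returned unchanged.
#'
#' @param x numeric matrix (features x samples, log2 scale) or
#'   [expression_matrix()].
#' @return Same container as `x`, normalized.
#' @export
rlr_normalize <- function(x) {
  vals <- .as_values(x)
  if (ncol(vals) < 2) stop("RLR normalization requires at least 2 samples")
  ref <- apply(vals, 1, stats::median, na.rm = TRUE)
  out <- vals
  for (j in seq_len(ncol(vals))) {
    ok <- !is.na(vals[, j]) & !is.na(ref)
    if (sum(ok) < 3)
      stop(sprintf("sample %s shares fewer than 3 features with the reference",
                   colnames(vals)[j]))
    ols <- stats::lm(vals[ok, j] ~ ref[ok])
    if (stats::sd(stats::residuals(ols)) < 1e-10) {
      cf <- stats::coef(ols)       # exact linear relation: IRLS unneeded
    } else {
      cf <- stats::coef(MASS::rlm(vals[ok, j] ~ ref[ok], maxit = 200))
    }
    b0 <- unname(cf[1]); b1 <- unname(cf[2])
    if (!is.finite(b1) || abs(b1) < 1e-8)
      stop("degenerate robust fit (zero slope) for sample ", colnames(vals)[j])
    out[, j] <- (vals[, j] - b0) / b1
  }
  .restore_values(x, out)
}

#' Remove per-batch (plex) offsets by per-feature linear regression
#'
#' For each feature, a linear model of log2 intensity on the biological
#' group (time point) and the batch factor is fitted using sum-to-zero
#' batch contrasts, and the estimated batch effect of each sample's batch
#' is subtracted from that feature's values. Features with too few observed
#' values for a full-rank fit are passed through unchanged.
#'
#' @param x numeric matrix or [expression_matrix()].
#' @param batch factor/vector of batch (plex) labels, one per sample.
#' @param group factor/vector of biological group labels (e.g. day), one per
#'   sample.
#' @return Same container as `x`, batch-corrected.
#' @export
remove_batch_effects <- function(x, batch, group) {
  vals <- .as_values(x)
  batch <- factor(batch); group <- factor(group)
  if (length(batch) != ncol(vals) || length(group) != ncol(vals))
    stop("`batch` and `group` must have one entry per sample")
  if (nlevels(batch) < 2) return(x)
  mm <- stats::model.matrix(~ group + batch,
                            contrasts.arg = list(batch = "contr.sum"))
  if (qr(mm)$rank < ncol(mm))
    stop("batch is confounded with group: the design of factor `batch` is ",
         "not estimable alongside `group`")
  bcols <- grep("^batch", colnames(mm))
  # per-sample batch effect implied by the sum-to-zero contrast coding
  bmat <- mm[, bcols, drop = FALSE]
  out <- vals
  for (i in seq_len(nrow(vals))) {
    y <- vals[i, ]
    ok <- !is.na(y)
    if (sum(ok) < ncol(mm)) next
    mm_i <- mm[ok, , drop = FALSE]
    if (qr(mm_i)$rank < ncol(mm_i)) next
    cf <- stats::lm.fit(mm_i, y[ok])$coefficients
    out[i, ] <- y - as.vector(bmat %*% cf[bcols])
  }
  .restore_values(x, out)
}

#' Paired t-test on two matched value series
#'
#' Differences are formed over pairs where both values are observed;
#' the statistic is mean(d)/(sd(d)/sqrt(n)) with n-1 degrees of freedom and
#' a two-sided p-value. With fewer than 2 complete pairs no statistic is
#' produced. A zero-variance difference with nonzero mean yields a
#' p-value at the smallest representable positive double, with a warning.
#'
#' @param x,y numeric vectors of equal length (log2 scale); `NA` allowed.
#' @return one-row data.frame: `estimate` (mean difference), `statistic`,
#'   `df`, `p_value`, `n_valid`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2)
    return(data.frame(estimate = NA_real_, statistic = NA_real_,
                      df = NA_real_, p_value = NA_real_, n_valid = n))
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    if (m == 0)
      return(data.frame(estimate = 0, statistic = 0, df = n - 1,
                        p_value = 1, n_valid = n))
    warning("zero-variance differences with nonzero mean; p reported as ",
            "smallest positive double")
    return(data.frame(estimate = m, statistic = sign(m) * Inf, df = n - 1,
                      p_value = .Machine$double.xmin, n_valid = n))
  }
  tstat <- m / (s / sqrt(n))
  data.frame(estimate = m, statistic = tstat, df = n - 1,
             p_value = 2 * stats::pt(-abs(tstat), n - 1), n_valid = n)
}

# ---- empirical-Bayes variance shrinkage (moderated t) ----------------------

# Newton solve of trigamma(y) = x (monotone decreasing); vectorized.
.trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y), na.rm = TRUE) < 1e-8) break
  }
  y
}

# Moment-match a scaled F / scaled inverse-chi-square prior to observed
# residual variances s2 with df degrees of freedom. `covariate` (average
# log2 intensity) switches on an intensity-dependent prior (trend).
.fit_f_dist <- function(s2, df, covariate = NULL, span = 0.7) {
  ok <- is.finite(s2) & df > 0 & s2 >= 0
  # guard against exactly-zero sample variances (e.g. duplicated imputed
  # values): offset them to a small fraction of the median variance so the
  # log-scale moments stay finite
  m <- stats::median(s2[ok])
  if (!is.finite(m) || m == 0) m <- 1
  z <- log(pmax(s2[ok], 1e-5 * m))
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  if (!is.null(covariate)) {
    a <- covariate[ok]
    if (stats::sd(a) > 0 && sum(ok) >= 10) {
      lo <- stats::loess(e ~ a, span = span, degree = 1, family = "symmetric",
                         control = stats::loess.control(surface = "direct"))
      emean_vec <- stats::fitted(lo)
      # extrapolate to all features for prediction
      emean_all <- stats::predict(lo, newdata = data.frame(a = covariate))
      emean_all[is.na(emean_all)] <- mean(emean_vec)
    } else {
      emean_vec <- rep(mean(e), length(e))
      emean_all <- rep(mean(e), length(s2))
    }
  } else {
    emean_vec <- rep(mean(e), length(e))
    emean_all <- rep(mean(e), length(s2))
  }
  resid_e <- e - emean_vec
  evar <- sum(resid_e^2) / max(1, length(e) - 1) -
    mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * .trigamma_inverse(evar)
    s2_prior <- exp(emean_all + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    # no excess variability beyond sampling: variances are exchangeable and
    # the pooled (mean) variance is the prior
    df_prior <- Inf
    s2_prior <- if (is.null(covariate))
      rep(mean(pmax(s2[ok], 1e-5 * m)), length(s2))
    else exp(emean_all)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

#' Empirical-Bayes moderated t-test across features
#'
#' Per-feature linear models are fitted by least squares; the residual
#' variances are shrunk toward a common (or, with `trend = TRUE`,
#' intensity-dependent) prior estimated by moment matching of the
#' log residual variances against a scaled inverse-chi-square model
#' (digamma/trigamma matching). The moderated t statistic uses the
#' posterior variance and gains the prior degrees of freedom.
#'
#' @param x numeric matrix (features x samples, log2) or
#'   [expression_matrix()]. Rows with missing values are fitted on their
#'   observed samples when the design remains full rank.
#' @param design model matrix (samples x coefficients).
#' @param coef which coefficient to test (index or name); default the last.
#' @param trend logical; make the prior variance a smooth function of the
#'   feature's average log2 intensity.
#' @param prior_df optional override of the estimated prior degrees of
#'   freedom: `0` reproduces the ordinary per-feature t-test, `Inf` fully
#'   shrinks every variance to the prior.
#' @return data.frame with one row per feature: `feature_id`, `estimate`
#'   (log2 fold change for `coef`), `statistic`, `df`, `p_value`, `q_value`
#'   (Benjamini-Hochberg across features), `n_valid`, `s2_post`, `amean`.
#' @export
moderated_t_test <- function(x, design, coef = NULL, trend = FALSE,
                             prior_df = NULL) {
  vals <- .as_values(x)
  if (is.null(rownames(vals)))
    rownames(vals) <- paste0("f", seq_len(nrow(vals)))
  design <- as.matrix(design)
  if (nrow(design) != ncol(vals))
    stop("`design` must have one row per sample")
  if (qr(design)$rank < ncol(design)) stop("design matrix is not full rank")
  if (ncol(vals) <= ncol(design))
    stop("saturated design: no residual degrees of freedom")
  if (is.null(coef)) coef <- ncol(design)
  if (is.character(coef)) coef <- match(coef, colnames(design))
  nf <- nrow(vals)
  est <- stat <- s2 <- dfres <- unscaled <- amean <- rep(NA_real_, nf)
  nv <- integer(nf)
  for (i in seq_len(nf)) {
    y <- vals[i, ]
    ok <- !is.na(y)
    nv[i] <- sum(ok)
    X <- design[ok, , drop = FALSE]
    if (nv[i] <= ncol(design) || qr(X)$rank < ncol(X)) next
    fit <- stats::lm.fit(X, y[ok])
    rdf <- nv[i] - ncol(X)
    est[i] <- fit$coefficients[coef]
    s2[i] <- sum(fit$residuals^2) / rdf
    dfres[i] <- rdf
    XtXinv <- chol2inv(chol(crossprod(X)))
    unscaled[i] <- sqrt(XtXinv[coef, coef])
    amean[i] <- mean(y[ok])
  }
  fitted_rows <- which(is.finite(s2) & s2 > 0)
  if (length(fitted_rows) < 2) stop("fewer than 2 features could be fitted")
  pri <- .fit_f_dist(s2, dfres, covariate = if (trend) amean else NULL)
  df_prior <- if (!is.null(prior_df)) prior_df else pri$df_prior
  s2_prior <- pri$s2_prior
  s2_post <- if (!is.finite(df_prior)) s2_prior
             else if (df_prior == 0) s2
             else (df_prior * s2_prior + dfres * s2) / (df_prior + dfres)
  # total df is capped at the pooled residual df: with an effectively
  # infinite prior the evidence is still bounded by the data
  df_total <- pmin(dfres + df_prior, sum(dfres, na.rm = TRUE))
  stat <- est / (unscaled * sqrt(s2_post))
  p <- 2 * stats::pt(-abs(stat), df_total)
  data.frame(
    feature_id = rownames(vals), estimate = est, statistic = stat,
    df = df_total, p_value = p, q_value = bh_adjust(p), n_valid = nv,
    s2_post = s2_post, amean = amean, row.names = NULL
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NA` propagated and not
#'   counted toward the number of tests.
#' @return vector of adjusted values (q-values), capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Fisher exact over-representation of annotation terms
#'
#' For every term annotated on the background, a 2x2 Fisher exact test of
#' term membership in the feature set versus the rest of the background.
#' Each feature counts once regardless of how often it carries the term.
#'
#' @param feature_set character vector, subset of `background`.
#' @param background character vector of all eligible features.
#' @param annotation_map named list: feature id -> character vector of terms.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return data.frame of `EnrichmentRow`s: `term`, `k_in_set`, `set_size`,
#'   `K_in_background`, `background_size`, `fold_enrichment`, `p_value`,
#'   `q_value` (BH across terms), sorted by p-value.
#' @export
fisher_enrichment <- function(feature_set, background, annotation_map,
                              alternative = "two.sided") {
  background <- unique(background)
  feature_set <- unique(feature_set)
  if (length(background) == 0) stop("empty background")
  if (!all(feature_set %in% background))
    stop("`feature_set` must be a subset of `background`")
  ann <- annotation_map[intersect(names(annotation_map), background)]
  terms <- sort(unique(unlist(ann, use.names = FALSE)))
  n_set <- length(feature_set); n_bg <- length(background)
  rows <- lapply(terms, function(tm) {
    with_term <- names(ann)[vapply(ann, function(v) tm %in% v, logical(1))]
    K <- length(with_term)
    k <- length(intersect(feature_set, with_term))
    tab <- matrix(c(k, n_set - k, K - k, (n_bg - n_set) - (K - k)), nrow = 2)
    p <- stats::fisher.test(tab, alternative = alternative)$p.value
    fold <- if (K > 0) (k / n_set) / (K / n_bg) else NA_real_
    data.frame(term = tm, k_in_set = k, set_size = n_set,
               K_in_background = K, background_size = n_bg,
               fold_enrichment = fold, p_value = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), k_in_set = integer(),
                      set_size = integer(), K_in_background = integer(),
                      background_size = integer(),
                      fold_enrichment = numeric(), p_value = numeric(),
                      q_value = numeric()))
  out$q_value <- bh_adjust(out$p_value)
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Hierarchical clustering of temporal profiles
#'
#' Distance is 1 - Spearman correlation between profiles; agglomeration is
#' complete linkage; the tree is cut into `k` clusters. Profiles with zero
#' variance (undefined correlation) are split off into their own singleton
#' clusters, numbered after the `k` regular ones, with a warning.
#'
#' @param profiles numeric matrix, one profile per row (>= 3 points each).
#' @param k number of clusters for the variable profiles.
#' @return named integer vector of cluster assignments (names = rownames).
#' @export
hierarchical_cluster <- function(profiles, k) {
  stopifnot(is.matrix(profiles), ncol(profiles) >= 3)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("f", seq_len(nrow(profiles)))
  sds <- apply(profiles, 1, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const))
    warning(sum(const), " constant profile(s) assigned to singleton clusters")
  var_profiles <- profiles[!const, , drop = FALSE]
  if (nrow(var_profiles) < k)
    stop("fewer variable profiles (", nrow(var_profiles),
         ") than clusters requested (", k, ")")
  assign <- integer(nrow(profiles))
  names(assign) <- rownames(profiles)
  if (k == 1) {
    assign[!const] <- 1L
  } else {
    d <- stats::as.dist(1 - stats::cor(t(var_profiles), method = "spearman"))
    hc <- stats::hclust(d, method = "complete")
    assign[!const] <- stats::cutree(hc, k = k)
  }
  if (any(const)) assign[const] <- k + seq_len(sum(const))
  assign
}

#' Mean silhouette width over a range of cluster counts
#'
#' Companion diagnostic for [hierarchical_cluster()]: for each candidate k
#' the tree is cut and the mean silhouette width under the same
#' 1 - Spearman distance is reported, supporting a data-driven choice of k.
#'
#' @param profiles numeric matrix of profiles (rows).
#' @param k_range integer vector of candidate cluster counts.
#' @return data.frame with columns `k` and `mean_silhouette`.
#' @export
cluster_silhouette <- function(profiles, k_range = 2:12) {
  dm <- as.matrix(1 - stats::cor(t(profiles), method = "spearman"))
  hc <- stats::hclust(stats::as.dist(dm), method = "complete")
  res <- lapply(k_range, function(k) {
    cl <- stats::cutree(hc, k = k)
    sil <- vapply(seq_along(cl), function(i) {
      own <- cl == cl[i]; own[i] <- FALSE
      a <- if (any(own)) mean(dm[i, own]) else 0
      others <- setdiff(unique(cl), cl[i])
      b <- min(vapply(others, function(g) mean(dm[i, cl == g]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    data.frame(k = k, mean_silhouette = mean(sil))
  })
  do.call(rbind, res)
}

#' Minimum-value imputation
#'
#' Replaces every missing value with the global minimum observed value,
#' the convention for left-censored label-based intensity data where a
#' missing value indicates signal below the detection floor.
#'
#' @param x numeric matrix or [expression_matrix()].
#' @return Same container, with `NA` replaced by the global minimum.
#' @export
impute_min <- function(x) {
  vals <- .as_values(x)
  if (all(is.na(vals))) stop("cannot impute an all-missing matrix")
  vals[is.na(vals)] <- min(vals, na.rm = TRUE)
  .restore_values(x, vals)
}

#' Scaled-minimum ("MinProp") imputation
#'
#' Replaces missing values with the global minimum observed value scaled by
#' `proportion`, i.e. imputed slightly below the detection floor when
#' `proportion < 1`.
#'
#' @param x numeric matrix or [expression_matrix()].
#' @param proportion positive scale applied to the global minimum
#'   (default 1, equivalent to [impute_min()]).
#' @return Same container, imputed.
#' @export
impute_minprop <- function(x, proportion = 1.0) {
  stopifnot(is.numeric(proportion), proportion > 0)
  vals <- .as_values(x)
  if (all(is.na(vals))) stop("cannot impute an all-missing matrix")
  vals[is.na(vals)] <- min(vals, na.rm = TRUE) * proportion
  .restore_values(x, vals)
}
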