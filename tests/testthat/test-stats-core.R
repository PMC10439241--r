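test_that("bh_adjust matches the hand step-up oracle and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(1:10, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    # adjustment preserves the p-value ordering
    expect_true(all(diff(q[order(p)]) >= 0))
  }
  expect_equal(bh_adjust(c(0.1, NA, 0.5))[2], NA_real_)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fisher_enrichment p equals exhaustive hypergeometric enumeration for N <= 20", {
  set.seed(7)
  for (i in 1:40) {
    N <- sample(4:20, 1)
    n_set <- sample(1:(N - 1), 1)
    K <- sample(1:N, 1)
    bg <- sprintf("g%02d", seq_len(N))
    fset <- sample(bg, n_set)
    with_term <- sample(bg, K)
    ann <- setNames(lapply(bg, function(g)
      if (g %in% with_term) "T1" else character(0)), bg)
    row <- fisher_enrichment(fset, bg, ann)
    k <- length(intersect(fset, with_term))
    expect_equal(row$p_value[row$term == "T1"],
                 oracle_fisher_two_sided(k, n_set, K, N), tolerance = 1e-12)
    expect_equal(row$k_in_set[row$term == "T1"], k)
    expect_equal(row$fold_enrichment[row$term == "T1"],
                 (k / n_set) / (K / N))
  }
})

test_that("fisher_enrichment handles whole-background and planted-ratio cases", {
  bg <- sprintf("g%d", 1:4)
  ann_all <- setNames(as.list(rep("T", 4)), bg)
  row <- fisher_enrichment(bg[1:2], bg, ann_all)
  expect_equal(row$fold_enrichment, 1)
  expect_equal(row$p_value, 1)
  # set frequency 0.5 vs background frequency 0.25 => fold enrichment 2
  bg8 <- sprintf("g%d", 1:8)
  ann <- setNames(lapply(bg8, function(g)
    if (g %in% bg8[1:2]) "T" else character(0)), bg8)
  row <- fisher_enrichment(c(bg8[1], bg8[3], bg8[4], bg8[5]), bg8, ann)
  expect_equal(row$fold_enrichment[row$term == "T"], (1 / 4) / (2 / 8))
  # 2-in-2 vs 2-in-4 example: one-sided tail is 1/6 by drawing enumeration
  bg4 <- sprintf("g%d", 1:4)
  ann4 <- setNames(lapply(bg4, function(g)
    if (g %in% bg4[1:2]) "T" else character(0)), bg4)
  one_sided <- fisher_enrichment(bg4[1:2], bg4, ann4, alternative = "greater")
  expect_equal(one_sided$p_value[one_sided$term == "T"], 1 / 6,
               tolerance = 1e-12)
  expect_error(fisher_enrichment("a", character(0), list()), "background")
})

test_that("paired_t_test reproduces hand-computed values and symmetries", {
  r <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$estimate, 2)
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-4) # 3.4641
  expect_equal(r$df, 2)
  r_neg <- paired_t_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r_neg$statistic, -r$statistic)
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$estimate, 0)
  expect_equal(same$p_value, 1)
  expect_warning(z <- paired_t_test(c(2, 3, 4), c(1, 2, 3)), "zero-variance")
  expect_lt(z$p_value, 1e-300)
  short <- paired_t_test(c(1, NA, NA), c(1, 2, 3))
  expect_true(is.na(short$statistic))
  expect_equal(short$n_valid, 1)
})

test_that("cyclic LOESS removes constant offsets and curved M-A trends", {
  set.seed(1)
  base <- rnorm(400, 20, 2)
  x <- cbind(s1 = base, s2 = base + 1.0)
  rownames(x) <- paste0("f", 1:400)
  norm <- cyclic_loess_normalize(x)
  expect_lt(abs(median(norm[, "s2"] - norm[, "s1"])), 1e-6)
  # identical samples are left alone
  xi <- cbind(s1 = base, s2 = base)
  rownames(xi) <- paste0("f", 1:400)
  expect_equal(cyclic_loess_normalize(xi), xi, tolerance = 1e-9)
  # curved (here linear-in-A) distortion: M = 0.5 A - 2
  A <- base
  M <- 0.5 * A - 2
  xc <- cbind(s1 = A + M / 2, s2 = A - M / 2)
  rownames(xc) <- paste0("f", 1:400)
  nc <- cyclic_loess_normalize(xc)
  M2 <- nc[, "s1"] - nc[, "s2"]
  A2 <- (nc[, "s1"] + nc[, "s2"]) / 2
  slope_after <- coef(lm(M2 ~ A2))[2]
  expect_lt(abs(slope_after), 0.02)
  expect_error(cyclic_loess_normalize(x[, 1, drop = FALSE]), "2 samples")
  # missingness pattern is preserved
  xm <- x; xm[c(3, 50), 1] <- NA
  expect_equal(is.na(cyclic_loess_normalize(xm)), is.na(xm))
})

test_that("RLR normalization inverts linear distortions and resists outliers", {
  set.seed(2)
  ref_profile <- rnorm(300, 22, 2)
  x <- cbind(s1 = ref_profile, s2 = ref_profile, s3 = ref_profile)
  x[, 3] <- 1.2 * ref_profile + 0.3
  rownames(x) <- paste0("f", 1:300)
  norm <- rlr_normalize(x)
  ref <- apply(norm, 1, median)
  fit <- lm(norm[, 3] ~ ref)
  expect_lt(abs(coef(fit)[1]), 1e-3)
  expect_lt(abs(coef(fit)[2] - 1), 1e-3)
  # a sample equal to the reference stays put
  expect_equal(norm[, 1], x[, 1], tolerance = 1e-9)
  # 10% gross outliers barely move the normalized medians
  xo <- x
  out_idx <- sample(300, 30)
  xo[out_idx, 3] <- xo[out_idx, 3] + 8
  no <- rlr_normalize(xo)
  expect_lt(abs(median(no[-out_idx, 3]) - median(norm[-out_idx, 3])), 0.05)
  expect_error(rlr_normalize(x[1:2, ]), "fewer than 3")
})

test_that("remove_batch_effects removes injected offsets and is identity-safe", {
  em <- toy_expression_matrix(n_features = 40, plexes = 2, days = c(0, 3, 6))
  vals <- matrix(20, 40, 6, dimnames = dimnames(em$values))
  offs <- c(1, -1)[em$design$plex]
  em$values <- sweep(vals, 2, offs, "+")
  corr <- remove_batch_effects(em, em$design$plex, em$design$timepoint_days)
  m1 <- mean(corr$values[, em$design$plex == 1])
  m2 <- mean(corr$values[, em$design$plex == 2])
  expect_lt(abs(m1 - m2), 1e-9)
  # zero batch effect: output equals input
  em$values <- vals
  corr0 <- remove_batch_effects(em, em$design$plex, em$design$timepoint_days)
  expect_equal(corr0$values, vals, tolerance = 1e-9)
  # confounded design is refused with a message naming the factor
  expect_error(
    remove_batch_effects(em, em$design$plex, em$design$plex),
    "confounded"
  )
})

test_that("re-estimated batch coefficients vanish after correction", {
  cfg <- sim_config(n_features = 200, frac_regulated = 0.2, noise_sd = 0.3,
                    batch_sd = 1, missing_rate = 0, seed = 21)
  sim <- simulate_tmt(cfg)
  em <- sim$matrix
  corr <- remove_batch_effects(em, em$design$plex, em$design$timepoint_days)
  mm <- model.matrix(~ factor(em$design$timepoint_days) +
                       factor(em$design$plex),
                     contrasts.arg = list(
                       `factor(em$design$plex)` = "contr.sum"))
  bcols <- grep("plex", colnames(mm))
  coefs <- t(apply(corr$values, 1, function(y)
    lm.fit(mm, y)$coefficients[bcols]))
  expect_lt(mean(abs(coefs)), 0.02)
})

test_that("moderated t collapses to the ordinary t when the prior df is zero", {
  set.seed(5)
  x <- matrix(rnorm(50 * 6, sd = 0.5), 50, 6,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:6)))
  g <- gl(2, 3)
  design <- model.matrix(~g)
  res <- moderated_t_test(x, design, coef = 2, prior_df = 0)
  for (i in c(1, 17, 50)) {
    o <- oracle_two_group_t(x[i, ], g)
    expect_equal(res$estimate[i], unname(o["estimate"]), tolerance = 1e-9)
    expect_equal(res$statistic[i], unname(o["statistic"]), tolerance = 1e-9)
    expect_equal(res$p_value[i], unname(o["p"]), tolerance = 1e-9)
  }
})

test_that("moderated t with infinite prior df pins every variance to the prior", {
  set.seed(6)
  x <- matrix(rnorm(80 * 6, sd = 0.5), 80, 6,
              dimnames = list(paste0("f", 1:80), paste0("s", 1:6)))
  design <- model.matrix(~gl(2, 3))
  res <- moderated_t_test(x, design, coef = 2, prior_df = Inf)
  expect_equal(length(unique(round(res$s2_post, 12))), 1)
})

test_that("empirical-Bayes moment estimators agree with an independent implementation", {
  skip_if_not_installed("limma")
  set.seed(8)
  x <- matrix(rnorm(200 * 6, mean = 20, sd = sqrt(0.2)), 200, 6,
              dimnames = list(paste0("f", 1:200), paste0("s", 1:6)))
  x[1:40, 4:6] <- x[1:40, 4:6] + 1   # some real effects
  design <- model.matrix(~gl(2, 3))
  res <- moderated_t_test(x, design, coef = 2, trend = FALSE)
  fit <- limma::eBayes(limma::lmFit(x, design), trend = FALSE)
  expect_equal(res$statistic, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(res$p_value, unname(fit$p.value[, 2]), tolerance = 1e-6)
  expect_equal(res$s2_post, unname(fit$s2.post), tolerance = 1e-6)
})

test_that("hierarchical clustering matches a brute-force complete-linkage oracle", {
  set.seed(9)
  profiles <- matrix(rnorm(10 * 6), 10, 6,
                     dimnames = list(paste0("f", 1:10), NULL))
  d <- 1 - cor(t(profiles), method = "spearman")
  for (k in 2:5) {
    got <- hierarchical_cluster(profiles, k = k)
    want <- oracle_complete_linkage(as.dist(d), k)
    expect_true(same_partition(unname(got), want), label = paste("k =", k))
  }
})

test_that("hierarchical clustering honours exact structure and degenerate profiles", {
  p <- rbind(a1 = c(1, 2, 3, 4), a2 = c(2, 3, 4, 5),
             b1 = c(4, 3, 2, 1), b2 = c(5, 4, 3, 2))
  cl <- hierarchical_cluster(p, k = 2)
  expect_equal(unname(cl["a1"]), unname(cl["a2"]))
  expect_equal(unname(cl["b1"]), unname(cl["b2"]))
  expect_false(cl["a1"] == cl["b1"])
  # opposite monotone profiles are at the maximal distance 2
  d <- 1 - cor(t(p), method = "spearman")
  expect_equal(d["a1", "b1"], 2)
  # constant profile goes to its own cluster with a warning
  pc <- rbind(p, flat = c(1, 1, 1, 1))
  expect_warning(clc <- hierarchical_cluster(pc, k = 2), "constant")
  expect_equal(unname(clc["flat"]), 3)
})

test_that("imputation rules replace missing values as specified", {
  x <- matrix(c(10, 12, NA, 14), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(impute_min(x)["a", "s2"], 10)
  expect_equal(impute_minprop(x, proportion = 0.9)["a", "s2"], 9)
  full <- matrix(1:4, 2, 2, dimnames = dimnames(x))
  expect_equal(impute_min(full), full)
  allna <- matrix(NA_real_, 2, 2, dimnames = dimnames(x))
  expect_error(impute_min(allna), "all-missing")
  expect_error(impute_minprop(allna), "all-missing")
})
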