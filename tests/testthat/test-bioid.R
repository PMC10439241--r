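make_silac <- function(ratios_by_construct, heavy = 20) {
  # one feature, explicit replicate ratios per construct
  rows <- do.call(rbind, lapply(names(ratios_by_construct), function(con) {
    r <- ratios_by_construct[[con]]
    data.frame(feature_id = "fx", construct = con,
               replicate = seq_along(r), light = heavy + r, heavy = heavy,
               stringsAsFactors = FALSE)
  }))
  # anchor feature so the global minimum is well below every ratio
  rbind(rows, data.frame(feature_id = "anchor", construct = rows$construct,
                         replicate = rows$replicate, light = 5, heavy = 20))
}

test_that("filter_valid keeps features with enough observed light values", {
  rec <- data.frame(
    feature_id = rep(c("a", "b", "c"), each = 6),
    construct = rep(rep(c("K", "SK"), each = 3), 3),
    replicate = rep(1:3, 6),
    light = c(21, NA, NA, NA, NA, NA,      # a: 1 valid overall
              21, 22, NA, NA, NA, NA,      # b: 2 valid in K
              NA, NA, NA, NA, NA, NA),     # c: none
    heavy = 20
  )
  f <- filter_valid(rec, min_valid = 2)
  expect_setequal(unique(f$feature_id), "b")
  expect_identical(filter_valid(rec, min_valid = 0), rec)
})

test_that("biotinylation calls need two replicate ratios above the cutoff", {
  rec <- make_silac(list(DSK = c(1.2, 0.8, 1.5), K = c(1.2, 0.8, 0.9)))
  calls <- call_biotinylated(rec)
  fx <- calls[calls$feature_id == "fx", ]
  expect_true(fx$called[fx$construct == "DSK"])   # two ratios > 1
  expect_false(fx$called[fx$construct == "K"])    # only one ratio > 1
  # monotonicity: raising any ratio never removes a call
  rec_up <- rec
  rec_up$light <- rec_up$light + 0.5
  calls_up <- call_biotinylated(rec_up)
  expect_true(all(calls_up$called[calls$called]))
})

test_that("missing light values are imputed before ratios, needing heavy present", {
  rec <- make_silac(list(SK = c(2, 2, 2)))
  rec$light[rec$feature_id == "fx"][1] <- NA     # imputed to global min 5
  rec$heavy[rec$feature_id == "fx"][2] <- NA     # no ratio for replicate 2
  calls <- call_biotinylated(rec)
  fx <- calls[calls$feature_id == "fx", ]
  # replicate 1 ratio = 5 - 20 < 1 (imputed), replicate 2 has no ratio,
  # replicate 3 ratio = 2: only one ratio above the cutoff
  expect_equal(fx$n_above, 1)
  expect_false(fx$called)
})

test_that("construct differential recovers planted effects and mirrors its sign", {
  cfg <- sim_config(n_features = 400, frac_regulated = 0.15, effect_log2 = 2,
                    noise_sd = 0.4, seed = 29)
  sim <- simulate_bioid(cfg)
  rec <- filter_valid(sim$records)
  res <- differential_constructs(rec, c("SK", "K"))
  tr <- sim$truth$interactor_of[match(res$feature_id, sim$truth$feature_id)]
  sk <- !is.na(tr) & tr == "SK"
  null_f <- is.na(tr)
  expect_gt(mean(res$significant[sk]), 0.8)
  fp <- sum(res$significant & null_f)
  expect_lt(fp / max(1, sum(res$significant)), 0.1)
  # estimates of true SK interactors are positive and near the effect
  expect_gt(median(res$estimate[sk]), 1.5)
  # mirrored comparison has the same significance set with opposite signs
  res_rev <- differential_constructs(rec, c("K", "SK"))
  m <- merge(res, res_rev, by = "feature_id")
  expect_equal(m$estimate.x, -m$estimate.y, tolerance = 1e-9)
  expect_identical(m$significant.x, m$significant.y)
  expect_error(differential_constructs(rec[rec$replicate == 1, ], c("SK", "K")),
               "at least 2 replicates")
})

test_that("differential uses only non-imputed light channels of the pair", {
  cfg <- sim_config(n_features = 150, frac_regulated = 0.1, effect_log2 = 2,
                    noise_sd = 0.4, seed = 31)
  sim <- simulate_bioid(cfg)
  rec <- filter_valid(sim$records)
  res <- differential_constructs(rec, c("SK", "K"))
  # heavy channel (used only for biotinylation ratios) is irrelevant here
  rec2 <- rec
  rec2$heavy <- rec2$heavy + rnorm(nrow(rec2))
  expect_equal(differential_constructs(rec2, c("SK", "K")), res)
  # identical groups: nothing significant
  rec_same <- rec[rec$construct == "SK", ]
  rec_dup <- rec_same
  rec_dup$construct <- "K"
  res0 <- differential_constructs(rbind(rec_same, rec_dup), c("SK", "K"))
  expect_equal(sum(res0$significant), 0)
  # a feature can fail on fold change alone
  expect_true(all(res$significant == (res$q_value < 0.05 &
                                        abs(res$estimate) > 0.58),
                  na.rm = TRUE))
})

test_that("ora flags planted terms and counts site-bearing proteins once", {
  bg <- sprintf("prot%02d", 1:40)
  set_f <- bg[1:8]
  ann <- setNames(lapply(bg, function(p)
    if (p %in% bg[1:8]) "axon" else "other"), bg)
  rows <- ora(set_f, bg, ann)
  expect_true(rows$pass[rows$term == "axon"])
  expect_false(rows$pass[rows$term == "other"])
  # set equal to background: nothing passes
  rows_all <- ora(bg, bg, ann)
  expect_false(any(rows_all$pass))
  expect_error(ora(c(bg[1], "zz"), bg, ann), "subset")
  # site-level features collapse to proteins before counting
  sites <- c("prot01_10", "prot01_20", "prot01_99", "prot02_5")
  pm <- setNames(sub("_\\d+$", "", sites), sites)
  bg_sites <- c(sites, "prot03_1", "prot04_1")
  pm_bg <- setNames(sub("_\\d+$", "", bg_sites), bg_sites)
  rows_site <- ora(sites, bg_sites, ann, protein_map = pm_bg)
  expect_equal(rows_site$k_in_set[rows_site$term == "axon"], 2)  # prot01+prot02
  expect_equal(rows_site$set_size[rows_site$term == "axon"], 2)
})

test_that("simplify_terms drops redundant terms keeping the best q", {
  rows <- data.frame(term = c("A", "B", "C"),
                     q_value = c(0.01, 0.02, 0.03))
  tf <- list(A = c("x", "y", "z"), B = c("x", "y", "z"),
             C = c("q", "r", "s"))
  out <- simplify_terms(rows, tf, jaccard_cut = 0.7)
  expect_setequal(out$term, c("A", "C"))      # duplicate B dropped
  # disjoint terms: identity
  tf2 <- list(A = "x", B = "y", C = "z")
  expect_equal(nrow(simplify_terms(rows, tf2)), 3)
  # chain A~B and B~C similar, A~C dissimilar: greedy by ascending q keeps
  # A (best), drops B (redundant with A), keeps C (dissimilar to A)
  tf3 <- list(A = c("1", "2", "3", "4", "5"),
              B = c("1", "2", "3", "4", "6"),
              C = c("4", "6", "7", "8", "9"))
  out3 <- simplify_terms(rows, tf3, jaccard_cut = 0.6)
  expect_setequal(out3$term, c("A", "C"))
})
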