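make_sites <- function() {
  data.frame(
    site_id = c("P1_10", "P1_40", "P2_5", "P3_7"),
    protein_id = c("P1", "P1", "P2", "P3"),
    position = c(10L, 40L, 5L, 7L),
    residue = c("S", "T", "S", "Y"),
    localization_probability = c(0.993, 0.74, 0.80, 0.75),
    sequence_window = c("AAAAAAASAAAAAAA", "AAAAAAATAAAAAAA",
                        "AAAAAAASAAAAAAA", "AAAAAAAYAAAAAAA"),
    contaminant = c(FALSE, FALSE, FALSE, FALSE),
    reverse = c(FALSE, FALSE, FALSE, FALSE),
    d7.d0_r1___1 = c(1.3, 0.2, NA, NA),
    d7.d0_r2___1 = c(1.1, 0.1, NA, NA),
    d7.d0_r1___2 = c(3.0, NA, NA, NA),
    d7.d0_r2___2 = c(3.0, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

test_that("class-I filtering is inclusive at the localization boundary", {
  rec <- make_sites()
  f <- filter_class1(rec)
  expect_false("P1_40" %in% f$site_id)   # 0.74 removed
  expect_true("P2_5" %in% f$site_id)     # 0.80 retained
  expect_true("P3_7" %in% f$site_id)     # 0.75 retained (inclusive)
  expect_equal(nrow(filter_class1(rec, threshold = 0)), 4)
  rec$contaminant[1] <- TRUE
  expect_false("P1_10" %in% filter_class1(rec)$site_id)
  rec2 <- make_sites()
  rec2$localization_probability[1] <- 1.3
  expect_error(filter_class1(rec2), "\\[0, 1\\]")
})

test_that("multiplicity splitting reshapes without altering any ratio", {
  rec <- make_sites()
  sp <- split_multiplicity(rec)
  # site 1 quantified at multiplicities 1 and 2 -> 2 rows; sites 3 and 4
  # carry no quantification -> dropped; site 2 only multiplicity 1
  expect_equal(sum(sp$site_id == "P1_10"), 2)
  expect_equal(sum(sp$site_id == "P2_5"), 0)
  expect_equal(nrow(sp), 3)
  # conservation: total rows = total quantified (site, multiplicity) combos
  expect_equal(nrow(sp), 3)
  r1 <- sp[sp$site_id == "P1_10" & sp$multiplicity == 1, ]
  expect_equal(r1$d7.d0_r1, 1.3)
  expect_equal(r1$d7.d0_r2, 1.1)
  r2 <- sp[sp$site_id == "P1_10" & sp$multiplicity == 2, ]
  expect_equal(c(r2$d7.d0_r1, r2$d7.d0_r2), c(3, 3))
})

test_that("regulation calls follow the both-replicate rule exactly", {
  rec <- split_multiplicity(make_sites())
  calls <- call_regulated(rec, cutoff = 1)
  up1 <- calls[calls$site_id == "P1_10" & calls$multiplicity == 1, ]
  expect_equal(up1$call, "up")            # (1.3, 1.1)
  up2 <- calls[calls$site_id == "P1_10" & calls$multiplicity == 2, ]
  expect_equal(up2$call, "up")            # (3.0, 3.0), ~eightfold
  ns <- calls[calls$site_id == "P1_40", ]
  expect_equal(ns$call, "ns")             # (0.2, 0.1)
  # one replicate below the cutoff: not called
  rec2 <- rec
  rec2$d7.d0_r2[rec2$site_id == "P1_10" & rec2$multiplicity == 1] <- 0.9
  calls2 <- call_regulated(rec2)
  expect_equal(calls2$call[calls2$site_id == "P1_10" &
                             calls2$multiplicity == 1], "ns")
  # antisymmetry: negating every ratio swaps up and down
  rec_neg <- rec
  for (cl in grep("_r\\d+$", names(rec_neg))) rec_neg[[cl]] <- -rec_neg[[cl]]
  calls_neg <- call_regulated(rec_neg)
  expect_identical(calls$call == "up", calls_neg$call == "down")
  expect_identical(calls$call == "down", calls_neg$call == "up")
})

test_that("keyword enrichment counts each protein once against the dataset", {
  set.seed(20)
  n <- 60
  rec <- data.frame(
    site_id = sprintf("P%02d_%d", rep(1:n, each = 2), rep(c(10, 20), n)),
    protein_id = sprintf("P%02d", rep(1:n, each = 2)),
    position = rep(c(10L, 20L), n),
    multiplicity = 1L,
    d7.d0_r1 = 0, d7.d0_r2 = 0,
    stringsAsFactors = FALSE
  )
  # proteins 1..10 down-regulated at both sites (5 regulated sites would
  # still count once); keyword planted on 8 of them and on 5 others
  down <- rec$protein_id %in% sprintf("P%02d", 1:10)
  rec$d7.d0_r1[down] <- -2
  rec$d7.d0_r2[down] <- -2
  ann <- setNames(lapply(sprintf("P%02d", 1:n), function(p)
    if (p %in% sprintf("P%02d", c(1:8, 30:34))) "membrane"
    else character(0)), sprintf("P%02d", 1:n))
  calls <- call_regulated(rec)
  enr <- keyword_enrichment(calls, rec, ann, fdr = 0.02)
  row <- enr[enr$term == "membrane" & enr$direction == "down", ]
  expect_equal(row$k_in_set, 8)       # protein counted once, not per site
  expect_equal(row$set_size, 10)
  expect_true(row$significant)
  # nothing regulated -> empty result
  rec0 <- rec
  rec0$d7.d0_r1 <- 0; rec0$d7.d0_r2 <- 0
  expect_equal(nrow(keyword_enrichment(call_regulated(rec0), rec0, ann)), 0)
})

test_that("motif analysis flags planted positions and rejects bad windows", {
  set.seed(21)
  mk <- function(n, p_plus1) {
    vapply(seq_len(n), function(i) {
      w <- sample(strsplit("ACDEFGHILMNQSTVWY", "")[[1]], 13, replace = TRUE)
      w[7] <- "S"
      if (runif(1) < p_plus1) w[8] <- "P"
      paste(w, collapse = "")
    }, character(1))
  }
  fg <- mk(200, 0.8); bg <- mk(200, 0.2)
  ma <- motif_analysis(fg, bg, half_width = 6)
  cell <- ma[ma$position == 1 & ma$residue == "P", ]
  expect_lt(cell$p_value, 0.01)
  expect_true(cell$significant)
  expect_gt(cell$diff, 0.4)
  expect_true(all(ma$position >= -6 & ma$position <= 6))
  # foreground identical to background: all differences zero
  ma0 <- motif_analysis(fg, fg)
  expect_true(all(ma0$diff == 0))
  expect_true(all(ma0$p_value == 1))
  expect_error(motif_analysis(c("AAASAAA", "AAAASAAAA"), fg), "same length")
  expect_error(motif_analysis(substr(fg, 1, 4), substr(bg, 1, 4)), "odd")
})

test_that("site matching collapses multiplicities and joins on protein+position", {
  a <- data.frame(protein_id = c("P1", "P1", "P2"),
                  position = c(10L, 10L, 5L),
                  multiplicity = c(1L, 2L, 1L))
  b <- data.frame(protein_id = c("P1", "P3"), position = c(10L, 9L),
                  multiplicity = 1L)
  m <- match_sites(a, b)
  expect_equal(nrow(m), 1)
  expect_equal(m$protein_id, "P1")
  expect_equal(nrow(match_sites(a, a)), 2)   # all unique sites of a
  disjoint <- data.frame(protein_id = "P9", position = 1L)
  expect_equal(nrow(match_sites(a, disjoint)), 0)
})

test_that("both-replicate calling is sensitive yet conservative on synthetic defaults", {
  cfg <- sim_config(n_features = 1000, frac_regulated = 0.1,
                    effect_log2 = 1.5, noise_sd = 0.3, seed = 23)
  sim <- simulate_phospho(cfg)
  rec <- split_multiplicity(filter_class1(sim$records))
  calls <- call_regulated(rec)
  cc <- calls[calls$comparison == "d14.d0", ]
  tr <- sim$truth$dir_d14.d0[match(cc$site_id, sim$truth$site_id)]
  sens <- mean(cc$call[tr != "null"] == tr[tr != "null"])
  false_rate <- mean(cc$call[tr == "null"] != "ns")
  expect_gte(sens, 0.85)
  expect_lte(false_rate, 0.02)
})
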