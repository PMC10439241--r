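#' Remove flagged features (contaminants, reverse hits)
#'
#' @param em an [expression_matrix()].
#' @param flags flag columns whose `TRUE` entries are removed.
#' @param verbose message per-category removal counts.
#' @return filtered ExpressionMatrix.
#' @export
filter_features <- function(em, flags = c("contaminant", "reverse"),
                            verbose = TRUE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  flags <- intersect(flags, names(em$flags))
  if (length(flags) == 0) return(em)
  drop <- Reduce(`|`, em$flags[flags])
  if (verbose) {
    counts <- vapply(em$flags[flags], sum, integer(1))
    message("removed ", sum(drop), " flagged features (",
            paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
            ")")
  }
  if (!any(drop)) return(em)
  subset_features(em, which(!drop))
}

#' Within-plex cyclic LOESS normalization of a TMT time course
#'
#' Each plex (one labeling batch, one biological replicate) is normalized
#' individually by [cyclic_loess_normalize()] across its channels;
#' between-plex offsets are left for [remove_batch_effects()].
#'
#' @param em [expression_matrix()] whose design has a `plex` column.
#' @param span,iterations passed to [cyclic_loess_normalize()].
#' @return normalized ExpressionMatrix.
#' @export
normalize_tmt <- function(em, span = 0.7, iterations = 3) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (!"plex" %in% names(em$design)) stop("design must provide `plex`")
  vals <- em$values
  for (p in unique(em$design$plex)) {
    cols <- em$design$plex == p
    vals[, cols] <- cyclic_loess_normalize(vals[, cols, drop = FALSE],
                                           span = span,
                                           iterations = iterations)
  }
  em$values <- vals
  em
}

#' Paired differential tests of each day against baseline
#'
#' For every non-baseline time point, a paired t-test of day-d versus day-0
#' log2 intensities across plexes, using only plexes where both members of
#' the pair are observed. Features with fewer than `min_pairs` complete
#' pairs are excluded from that comparison (no imputation). P-values are
#' Benjamini-Hochberg adjusted within each comparison; a feature is called
#' `up` when q < `q_threshold` and its mean paired log2 difference is at
#' least `log2(fc_threshold)` (`down` symmetrically), otherwise `ns`.
#'
#' @param em normalized, batch-corrected [expression_matrix()] whose design
#'   has `timepoint_days` and `plex` columns.
#' @param q_threshold BH-adjusted p-value cutoff.
#' @param fc_threshold fold-change cutoff on the linear scale (2 means
#'   |log2 FC| >= 1).
#' @param min_pairs minimum number of complete day/baseline pairs.
#' @return data.frame of `DifferentialCall`s: `feature_id`, `comparison`,
#'   `log2_fc`, `statistic`, `p_value`, `q_value`, `n_pairs`, `call`; the
#'   thresholds are attached as attributes `q_threshold`/`fc_threshold`.
#' @export
run_differential <- function(em, q_threshold = 0.05, fc_threshold = 2,
                             min_pairs = 3) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  des <- em$design
  if (!all(c("timepoint_days", "plex") %in% names(des)))
    stop("design must provide `timepoint_days` and `plex`")
  days <- sort(unique(des$timepoint_days))
  base_day <- days[1]
  if (length(days) < 2) stop("no non-baseline time point in the design")
  lfc_cut <- log2(fc_threshold)
  plexes <- sort(unique(des$plex))
  col_of <- function(day) {
    vapply(plexes, function(p) {
      w <- which(des$plex == p & des$timepoint_days == day)
      if (length(w) == 1) w else NA_integer_
    }, integer(1))
  }
  base_cols <- col_of(base_day)
  out <- list()
  for (d in days[-1]) {
    d_cols <- col_of(d)
    keep <- !is.na(d_cols) & !is.na(base_cols)
    xd <- em$values[, d_cols[keep], drop = FALSE]
    x0 <- em$values[, base_cols[keep], drop = FALSE]
    res <- lapply(seq_len(nrow(xd)), function(i) paired_t_test(xd[i, ], x0[i, ]))
    res <- do.call(rbind, res)
    res$feature_id <- rownames(em$values)
    res <- res[!is.na(res$p_value) & res$n_valid >= min_pairs, , drop = FALSE]
    if (nrow(res) == 0) next
    res$q_value <- bh_adjust(res$p_value)
    res$comparison <- sprintf("day%d_vs_day%d", d, base_day)
    res$call <- ifelse(res$q_value < q_threshold & res$estimate >= lfc_cut, "up",
                ifelse(res$q_value < q_threshold & res$estimate <= -lfc_cut,
                       "down", "ns"))
    out[[as.character(d)]] <- data.frame(
      feature_id = res$feature_id, comparison = res$comparison,
      log2_fc = res$estimate, statistic = res$statistic,
      p_value = res$p_value, q_value = res$q_value, n_pairs = res$n_valid,
      call = res$call, stringsAsFactors = FALSE
    )
  }
  calls <- do.call(rbind, out)
  if (is.null(calls)) stop("no comparison had any testable feature")
  rownames(calls) <- NULL
  attr(calls, "q_threshold") <- q_threshold
  attr(calls, "fc_threshold") <- fc_threshold
  calls
}

#' Cluster temporal profiles of significantly regulated features
#'
#' Features significant (q below threshold) in at least one comparison get
#' per-day mean log2 intensities across plexes, z-scored per feature, and
#' are clustered by complete-linkage agglomeration on 1 - Spearman
#' correlation distance.
#'
#' @param em [expression_matrix()] (normalized, batch-corrected).
#' @param calls output of [run_differential()].
#' @param k number of clusters.
#' @param q_threshold significance cutoff applied to `calls$q_value`.
#' @return list: `assignments` (named integer vector), `profiles` (z-scored
#'   feature x day matrix), `mean_profiles` (cluster x day means).
#' @export
profile_and_cluster <- function(em, calls, k = 7, q_threshold = 0.05) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  sig <- unique(calls$feature_id[calls$q_value < q_threshold])
  if (length(sig) < k)
    stop("only ", length(sig), " significant features; choose k <= ",
         length(sig))
  days <- sort(unique(em$design$timepoint_days))
  prof <- sapply(days, function(d) {
    cols <- em$design$timepoint_days == d
    rowMeans(em$values[sig, cols, drop = FALSE], na.rm = TRUE)
  })
  colnames(prof) <- sprintf("d%d", days)
  z <- t(apply(prof, 1, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) v - mean(v) else (v - mean(v)) / s
  }))
  dimnames(z) <- dimnames(prof)
  assignments <- hierarchical_cluster(z, k = k)
  mean_profiles <- do.call(rbind, lapply(sort(unique(assignments)), function(cl)
    colMeans(z[assignments == cl, , drop = FALSE])))
  rownames(mean_profiles) <- sort(unique(assignments))
  list(assignments = assignments, profiles = z, mean_profiles = mean_profiles)
}

#' Per-cluster annotation over-representation
#'
#' Each cluster's members are tested for term over-representation against
#' the full filtered dataset as background using the Fisher exact test.
#'
#' @param assignments named cluster vector from [profile_and_cluster()].
#' @param annotation_map named list feature -> terms.
#' @param background character vector of all features in the filtered
#'   dataset (the enrichment background).
#' @return named list (one data.frame of enrichment rows per cluster).
#' @export
cluster_enrichment <- function(assignments, annotation_map, background) {
  stopifnot(length(assignments) > 0)
  clusters <- sort(unique(assignments))
  out <- list()
  for (cl in clusters) {
    members <- names(assignments)[assignments == cl]
    if (length(members) == 0) {
      warning("cluster ", cl, " is empty; skipped")
      next
    }
    out[[as.character(cl)]] <-
      fisher_enrichment(members, background, annotation_map)
  }
  out
}

#' Average fold-change profile of a keyword's features
#'
#' Subsets features annotated with `keyword` and reports the per-day mean
#' log2 fold change versus baseline (paired within plex, averaged across
#' plexes), plus the most up- and down-regulated members at the final day.
#'
#' @param em [expression_matrix()] with keyword `annotations`.
#' @param keyword annotation keyword to profile.
#' @param top_n how many top up/down features to report at the final day.
#' @return list: `series` (feature x day matrix of mean log2 FC vs
#'   baseline), `mean_series` (per-day average over features), `top_up`,
#'   `top_down` (feature ids). Empty with a warning for an unknown keyword.
#' @export
keyword_profiles <- function(em, keyword, top_n = 10) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  has_kw <- vapply(em$annotations, function(v) keyword %in% v, logical(1))
  feats <- names(em$annotations)[has_kw]
  feats <- intersect(feats, rownames(em$values))
  days <- sort(unique(em$design$timepoint_days))
  if (length(feats) == 0) {
    warning("keyword '", keyword, "' matches no feature")
    return(list(series = matrix(numeric(0), 0, length(days) - 1),
                mean_series = numeric(0), top_up = character(0),
                top_down = character(0)))
  }
  base_day <- days[1]
  plexes <- sort(unique(em$design$plex))
  fc <- sapply(days[-1], function(d) {
    per_plex <- sapply(plexes, function(p) {
      cd <- which(em$design$plex == p & em$design$timepoint_days == d)
      c0 <- which(em$design$plex == p & em$design$timepoint_days == base_day)
      if (length(cd) != 1 || length(c0) != 1) return(rep(NA_real_, length(feats)))
      em$values[feats, cd] - em$values[feats, c0]
    })
    rowMeans(matrix(per_plex, nrow = length(feats)), na.rm = TRUE)
  })
  fc <- matrix(fc, nrow = length(feats),
               dimnames = list(feats, sprintf("d%d_vs_d%d", days[-1], base_day)))
  final <- fc[, ncol(fc)]
  ord <- order(final, decreasing = TRUE, na.last = NA)
  list(series = fc,
       mean_series = colMeans(fc, na.rm = TRUE),
       top_up = feats[utils::head(ord, top_n)],
       top_down = feats[utils::head(rev(ord), top_n)])
}
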