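# long SILAC records -> features x (construct.replicate) matrix of one channel
.silac_matrix <- function(records, channel = c("light", "heavy"),
                          constructs = NULL) {
  channel <- match.arg(channel)
  if (!is.null(constructs))
    records <- records[records$construct %in% constructs, , drop = FALSE]
  records$sample <- paste(records$construct, records$replicate, sep = ".")
  feats <- unique(records$feature_id)
  samps <- unique(records$sample)
  m <- matrix(NA_real_, length(feats), length(samps),
              dimnames = list(feats, samps))
  m[cbind(match(records$feature_id, feats), match(records$sample, samps))] <-
    records[[channel]]
  m
}

#' Filter SILAC features on valid light values
#'
#' Keeps features with at least `min_valid` observed light intensities in
#' at least one construct group.
#'
#' @param records long data.frame: `feature_id`, `construct`, `replicate`,
#'   `light`, `heavy` (log2; `NA` = not observed).
#' @param min_valid minimum observed light values required in some group.
#' @return filtered records.
#' @export
filter_valid <- function(records, min_valid = 2) {
  if (min_valid <= 0) return(records)
  counts <- stats::aggregate(
    !is.na(records$light),
    by = list(feature_id = records$feature_id, construct = records$construct),
    FUN = sum
  )
  ok_feats <- unique(counts$feature_id[counts$x >= min_valid])
  records[records$feature_id %in% ok_feats, , drop = FALSE]
}

#' Call biotinylated features per construct
#'
#' Missing light intensities are first imputed with the global minimum
#' observed light value; light/heavy log2 ratios are then formed per
#' replicate wherever the heavy (control) value is present, and a feature
#' is called biotinylated in a construct when at least `min_reps` of its
#' replicate ratios exceed `ratio_cutoff`.
#'
#' @param records long SILAC data.frame (see [filter_valid()]).
#' @param ratio_cutoff log2 ratio a replicate must exceed (strictly).
#' @param min_reps replicates that must exceed the cutoff.
#' @return data.frame of `BiotinylationCall`s: `feature_id`, `construct`,
#'   `n_above`, `called`.
#' @export
call_biotinylated <- function(records, ratio_cutoff = 1, min_reps = 2) {
  light <- .silac_matrix(records, "light")
  heavy <- .silac_matrix(records, "heavy")
  light_imp <- impute_min(light)
  ratio <- light_imp - heavy            # NA wherever heavy is missing
  construct <- sub("\\.\\d+$", "", colnames(ratio))
  out <- list()
  for (con in unique(construct)) {
    r <- ratio[, construct == con, drop = FALSE]
    n_above <- rowSums(r > ratio_cutoff, na.rm = TRUE)
    out[[con]] <- data.frame(feature_id = rownames(ratio), construct = con,
                             n_above = n_above, called = n_above >= min_reps,
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Moderated differential test between two BioID constructs
#'
#' Uses the non-imputed light log2 intensities of the two constructs:
#' between-sample normalization (cyclic LOESS for protein-level data, RLR
#' for phosphosite-level data), scaled-minimum ("MinProp") imputation of
#' remaining missing values, then an empirical-Bayes moderated t-test with
#' an intensity trend. A feature is significant when its BH-adjusted
#' p-value is below `q_cut` and its |mean log2 fold change| exceeds
#' `fc_cut`.
#'
#' @param records long SILAC data.frame.
#' @param pair character(2): the constructs to compare; the fold change is
#'   `pair[1] - pair[2]`.
#' @param level `"protein"` (cyclic LOESS) or `"site"` (RLR).
#' @param fc_cut absolute log2 fold-change cutoff (0.58 ~ 1.5-fold).
#' @param q_cut BH-adjusted p-value cutoff.
#' @param minprop_proportion proportion for [impute_minprop()].
#' @param trend passed to [moderated_t_test()].
#' @param min_valid_per_group features must have at least this many
#'   observed (non-imputed) light values in each compared construct;
#'   features failing it are excluded from the comparison rather than
#'   carried on imputed-only evidence.
#' @return data.frame: `feature_id`, `estimate` (log2 FC `pair[1]` vs
#'   `pair[2]`), `statistic`, `df`, `p_value`, `q_value`, `significant`.
#' @export
differential_constructs <- function(records, pair, level = c("protein", "site"),
                                    fc_cut = 0.58, q_cut = 0.05,
                                    minprop_proportion = 1.0, trend = TRUE,
                                    min_valid_per_group = 2) {
  level <- match.arg(level)
  stopifnot(length(pair) == 2)
  light <- .silac_matrix(records, "light", constructs = pair)
  construct <- factor(sub("\\.\\d+$", "", colnames(light)), levels = rev(pair))
  if (any(table(construct) < 2))
    stop("each construct in `pair` needs at least 2 replicates")
  n_obs1 <- rowSums(!is.na(light[, construct == pair[1], drop = FALSE]))
  n_obs2 <- rowSums(!is.na(light[, construct == pair[2], drop = FALSE]))
  light <- light[n_obs1 >= min_valid_per_group &
                   n_obs2 >= min_valid_per_group, , drop = FALSE]
  if (nrow(light) < 2) stop("fewer than 2 features pass the valid-value filter")
  norm <- if (level == "protein") cyclic_loess_normalize(light)
          else rlr_normalize(light)
  imp <- impute_minprop(norm, proportion = minprop_proportion)
  design <- stats::model.matrix(~construct)
  res <- moderated_t_test(imp, design, coef = 2, trend = trend)
  res$significant <- !is.na(res$q_value) & res$q_value < q_cut &
    abs(res$estimate) > fc_cut
  res
}

#' Over-representation analysis (hypergeometric upper tail)
#'
#' One-sided Fisher over-representation of annotation terms in a feature
#' set against an explicit background (global, or all biotinylated
#' features for construct comparisons). When `protein_map` is given,
#' site-level features are first collapsed to proteins so that a protein
#' with several sites counts once. Terms are flagged as passing at
#' `p_cut` and BH FDR `fdr_cut`.
#'
#' @param feature_set character vector (subset of `background`).
#' @param background character vector of eligible features.
#' @param annotation_map named list feature (or protein) -> terms.
#' @param protein_map optional named character vector feature -> protein.
#' @param p_cut raw p-value cutoff for the `pass` flag.
#' @param fdr_cut BH FDR cutoff for the `pass` flag.
#' @return data.frame of enrichment rows with a `pass` column, plus the
#'   per-term feature sets as attribute `term_features`.
#' @export
ora <- function(feature_set, background, annotation_map, protein_map = NULL,
                p_cut = 0.05, fdr_cut = 0.2) {
  if (!all(feature_set %in% background))
    stop("`feature_set` must be a subset of `background`")
  if (!is.null(protein_map)) {
    feature_set <- unique(unname(protein_map[feature_set]))
    background <- unique(unname(protein_map[background]))
  }
  rows <- fisher_enrichment(feature_set, background, annotation_map,
                            alternative = "greater")
  rows$pass <- rows$p_value < p_cut & rows$q_value < fdr_cut
  ann <- annotation_map[intersect(names(annotation_map), unique(background))]
  term_features <- lapply(rows$term, function(tm)
    intersect(unique(feature_set),
              names(ann)[vapply(ann, function(v) tm %in% v, logical(1))]))
  names(term_features) <- rows$term
  attr(rows, "term_features") <- term_features
  rows
}

#' Simplify redundant enrichment terms by Jaccard similarity
#'
#' Terms are considered redundant when the Jaccard similarity of their
#' feature sets exceeds `jaccard_cut`; of each redundant pair the term with
#' the larger adjusted p-value is dropped. Terms are processed in
#' ascending adjusted-p order (ties broken by term id), which reaches the
#' greedy fixpoint deterministically.
#'
#' @param rows enrichment data.frame with `term` and `q_value` columns.
#' @param term_features named list term -> feature set; defaults to the
#'   `term_features` attribute produced by [ora()].
#' @param jaccard_cut similarity above which two terms are redundant.
#' @return reduced data.frame (same columns, possibly fewer rows).
#' @export
simplify_terms <- function(rows, term_features = attr(rows, "term_features"),
                           jaccard_cut = 0.7) {
  if (is.null(term_features))
    stop("per-term feature sets required (attribute `term_features`)")
  ord <- order(rows$q_value, rows$term)
  kept <- character(0)
  for (i in ord) {
    tm <- rows$term[i]
    fs <- term_features[[tm]]
    redundant <- any(vapply(kept, function(kt) {
      ks <- term_features[[kt]]
      u <- length(union(fs, ks))
      if (u == 0) return(FALSE)
      length(intersect(fs, ks)) / u > jaccard_cut
    }, logical(1)))
    if (!redundant) kept <- c(kept, tm)
  }
  out <- rows[rows$term %in% kept, , drop = FALSE]
  attr(out, "term_features") <- term_features[out$term]
  out
}
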