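# A breakpoint is the position between residues b and b+1 (cut after
# residue b). A semi-tryptic peptide with tryptic N-terminus ending at e
# evidences breakpoint e; one with tryptic C-terminus starting at s
# evidences breakpoint s - 1.

.breakpoint_of <- function(peptides) {
  ifelse(peptides$specific_terminus == "N", peptides$end,
         peptides$start - 1L)
}

# intensity-weighted mean RT per (protein, start, end, terminus)
.weighted_rt <- function(peptides) {
  key <- paste(peptides$protein_id, peptides$start, peptides$end,
               peptides$specific_terminus, sep = ":")
  w <- peptides$intensity
  rt <- vapply(split(seq_along(key), key), function(i)
    stats::weighted.mean(peptides$retention_time[i], w[i]), numeric(1))
  rt
}

#' Detect semi-tryptic peptide ladders
#'
#' Semi-tryptic peptides sharing the same protein and the same tryptic
#' terminus side are grouped; a ladder is a maximal run of non-tryptic
#' termini at consecutive residue positions with at least `min_members`
#' members. Singleton termini are emitted as width-1 candidates. One
#' candidate row is produced per breakpoint, annotated with its ladder.
#'
#' @param peptides data.frame of `SemiTrypticPeptide`s: `protein_id`,
#'   `start`, `end`, `specific_terminus` ("N"/"C"; "both" rows are
#'   ignored), `retention_time`, `intensity`.
#' @param min_members minimum run length for a run to count as a ladder.
#' @param min_length peptides shorter than this are ignored.
#' @return data.frame of `CleavageCandidate`s: `protein_id`, `breakpoint`,
#'   `terminus`, `ladder_id`, `region_start`, `region_end`, `n_members`,
#'   `is_ladder`, `classification` (`NA`, to be assigned downstream).
#' @export
find_ladders <- function(peptides, min_members = 2, min_length = 7) {
  semi <- peptides[peptides$specific_terminus %in% c("N", "C") &
                     (peptides$end - peptides$start + 1) >= min_length, ,
                   drop = FALSE]
  if (nrow(semi) == 0)
    return(data.frame(protein_id = character(), breakpoint = integer(),
                      terminus = character(), ladder_id = integer(),
                      region_start = integer(), region_end = integer(),
                      n_members = integer(), is_ladder = logical(),
                      classification = character()))
  semi$breakpoint <- .breakpoint_of(semi)
  # anchor = the shared tryptic terminus coordinate
  semi$anchor <- ifelse(semi$specific_terminus == "N", semi$start, semi$end)
  out <- list()
  ladder_id <- 0L
  groups <- split(semi, list(semi$protein_id, semi$specific_terminus,
                             semi$anchor), drop = TRUE)
  for (g in groups) {
    bps <- sort(unique(g$breakpoint))
    run_id <- cumsum(c(1L, diff(bps) != 1L))
    for (r in unique(run_id)) {
      ladder_id <- ladder_id + 1L
      run <- bps[run_id == r]
      out[[ladder_id]] <- data.frame(
        protein_id = g$protein_id[1], breakpoint = run,
        terminus = g$specific_terminus[1], ladder_id = ladder_id,
        region_start = min(run), region_end = max(run),
        n_members = length(run), is_ladder = length(run) >= min_members,
        classification = NA_character_, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$protein_id, res$breakpoint, res$terminus), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Exclude breakpoints directly adjacent to proline
#'
#' Breakpoints with a proline on either side of the break (residue i or
#' i + 1) are reclassified `excluded_proline`: such breaks are the
#' signature of gas-phase fragmentation N-terminal to proline rather than
#' of proteolysis.
#'
#' @param candidates data.frame from [find_ladders()].
#' @param protein_seq amino-acid string of the candidates' protein.
#' @return candidates with updated `classification`.
#' @export
exclude_proline_adjacent <- function(candidates, protein_seq) {
  if (nrow(candidates) == 0) return(candidates)
  n <- nchar(protein_seq)
  if (any(candidates$breakpoint < 1 | candidates$breakpoint >= n))
    stop("breakpoint outside the protein sequence")
  aa <- strsplit(protein_seq, "")[[1]]
  adj_p <- aa[candidates$breakpoint] == "P" |
    aa[candidates$breakpoint + 1L] == "P"
  candidates$classification[adj_p] <- "excluded_proline"
  candidates
}

#' Classify candidates as in-source fragments or proteolytic products
#'
#' Each candidate breakpoint is compared with its fully tryptic parent
#' peptide (same tryptic terminus, spanning the breakpoint). If the
#' semi-tryptic evidence co-elutes with the parent (all members within
#' `rt_tolerance` minutes of the parent's retention time) the candidate is
#' an in-source fragment; otherwise it is proteolytic. Peptide retention
#' times are intensity-weighted means over repeated observations.
#' Candidates without an identified parent default to proteolytic with a
#' low-confidence flag. Proline-excluded candidates are left untouched.
#'
#' @param candidates data.frame from [find_ladders()] (optionally after
#'   [exclude_proline_adjacent()]).
#' @param peptides the full peptide evidence (semi-tryptic and fully
#'   tryptic rows, `specific_terminus == "both"` marking the latter).
#' @param rt_tolerance co-elution tolerance in minutes.
#' @return candidates with `classification` in
#'   `{proteolytic, in_source, excluded_proline}` and a `low_confidence`
#'   flag.
#' @export
classify_by_rt <- function(candidates, peptides, rt_tolerance = 1.0) {
  if (nrow(candidates) == 0) {
    candidates$low_confidence <- logical(0)
    return(candidates)
  }
  parents <- peptides[peptides$specific_terminus == "both", , drop = FALSE]
  semi <- peptides[peptides$specific_terminus %in% c("N", "C"), , drop = FALSE]
  semi$breakpoint <- .breakpoint_of(semi)
  parent_rt <- if (nrow(parents)) .weighted_rt(parents) else numeric(0)
  semi_rt <- .weighted_rt(semi)
  semi_key <- paste(semi$protein_id, semi$start, semi$end,
                    semi$specific_terminus, sep = ":")
  candidates$low_confidence <- FALSE
  for (i in seq_len(nrow(candidates))) {
    if (!is.na(candidates$classification[i])) next  # already excluded
    bp <- candidates$breakpoint[i]
    term <- candidates$terminus[i]
    prot <- candidates$protein_id[i]
    members <- semi[semi$protein_id == prot & semi$breakpoint == bp &
                      semi$specific_terminus == term, , drop = FALSE]
    par <- parents[parents$protein_id == prot & parents$start <= bp &
                     parents$end > bp, , drop = FALSE]
    if (nrow(par) == 0) {
      candidates$classification[i] <- "proteolytic"
      candidates$low_confidence[i] <- TRUE
      next
    }
    p_rt <- parent_rt[paste(par$protein_id[1], par$start[1], par$end[1],
                            "both", sep = ":")]
    m_rt <- semi_rt[unique(paste(members$protein_id, members$start,
                                 members$end, members$specific_terminus,
                                 sep = ":"))]
    candidates$classification[i] <-
      if (length(m_rt) > 0 && all(abs(m_rt - p_rt) <= rt_tolerance))
        "in_source" else "proteolytic"
  }
  candidates
}

#' Match proteolytic candidates to externally predicted cleavage sites
#'
#' A proteolytic candidate whose breakpoint lies within `window` residues
#' of a predicted position is annotated with that prediction; the nearest
#' prediction wins, ties going to the higher score. Predicted sites that
#' no candidate matches are additionally characterized when the protein
#' sequence is supplied: a prediction falling on a tryptic cut position
#' (after K/R) cannot be evidenced by a semi-tryptic peptide, and one whose
#' would-be semi-tryptic product is shorter than `min_peptide_length` is
#' below the detection floor.
#'
#' @param candidates data.frame from [classify_by_rt()].
#' @param predicted_sites data.frame: `position`, `score`, `p_value`.
#' @param window maximum |breakpoint - position| for a match.
#' @param protein_seq optional amino-acid string for unmatched-site context.
#' @param min_peptide_length minimal detectable peptide length.
#' @return list: `candidates` (with `matched_position`, `matched_score`,
#'   `matched_p` columns on proteolytic rows) and `predicted` (the input
#'   table with `matched` flag and `context` for unmatched sites).
#' @export
match_predicted <- function(candidates, predicted_sites, window = 2,
                            protein_seq = NULL, min_peptide_length = 7) {
  candidates$matched_position <- NA_integer_
  candidates$matched_score <- NA_real_
  candidates$matched_p <- NA_real_
  pred <- predicted_sites
  if (is.null(pred) || nrow(pred) == 0) {
    return(list(candidates = candidates,
                predicted = cbind(predicted_sites,
                                  matched = logical(0), context = character(0))))
  }
  pred$matched <- FALSE
  idx <- which(candidates$classification == "proteolytic")
  for (i in idx) {
    d <- abs(pred$position - candidates$breakpoint[i])
    near <- which(d <= window)
    if (length(near) == 0) next
    best <- near[order(d[near], -pred$score[near])][1]
    candidates$matched_position[i] <- pred$position[best]
    candidates$matched_score[i] <- pred$score[best]
    candidates$matched_p[i] <- pred$p_value[best]
    pred$matched[best] <- TRUE
  }
  pred$context <- ifelse(pred$matched, "matched", "no_semitryptic_evidence")
  if (!is.null(protein_seq)) {
    aa <- strsplit(protein_seq, "")[[1]]
    for (j in which(!pred$matched)) {
      pos <- pred$position[j]
      if (pos >= 1 && pos <= length(aa) && aa[pos] %in% c("K", "R")) {
        pred$context[j] <- "tryptic_cleavage_site"
      } else {
        # length of the shorter product between the prediction and the
        # nearest tryptic cut on either side
        cuts <- c(0L, which(aa %in% c("K", "R")), length(aa))
        left <- max(cuts[cuts < pos])
        right <- min(cuts[cuts >= pos])
        if (min(pos - left, right - pos) < min_peptide_length)
          pred$context[j] <- "below_min_peptide_length"
      }
    }
  }
  list(candidates = candidates, predicted = pred)
}

#' Full cleavage-site inference pipeline for one protein
#'
#' Runs [find_ladders()], [exclude_proline_adjacent()], [classify_by_rt()]
#' and [match_predicted()] in order.
#'
#' @param peptides peptide evidence data.frame.
#' @param protein_seq amino-acid string.
#' @param predicted_sites optional predicted-site data.frame.
#' @param min_members,rt_tolerance,window,min_length tuning parameters of
#'   the individual steps.
#' @return the [match_predicted()] result list.
#' @export
map_cleavage_sites <- function(peptides, protein_seq, predicted_sites = NULL,
                               min_members = 2, rt_tolerance = 1.0,
                               window = 2, min_length = 7) {
  cand <- find_ladders(peptides, min_members = min_members,
                       min_length = min_length)
  cand <- exclude_proline_adjacent(cand, protein_seq)
  cand <- classify_by_rt(cand, peptides, rt_tolerance = rt_tolerance)
  if (is.null(predicted_sites))
    predicted_sites <- data.frame(position = integer(), score = numeric(),
                                  p_value = numeric())
  match_predicted(cand, predicted_sites, window = window,
                  protein_seq = protein_seq,
                  min_peptide_length = min_length)
}
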