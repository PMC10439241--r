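# Ratio columns follow the site-table dialect: <comparison>_r<replicate>
# optionally suffixed ___<multiplicity> before splitting.
.ratio_cols <- function(records, split = FALSE) {
  pat <- if (split) "^(.+)_r(\\d+)___([123])$" else "^(.+)_r(\\d+)$"
  grep(pat, names(records), value = TRUE)
}

#' Filter phosphosites to class I
#'
#' Removes contaminant/reverse-flagged rows, then retains sites whose
#' phosphate localization probability is at least `threshold` (class I).
#'
#' @param records data.frame of site rows with a
#'   `localization_probability` column and logical `contaminant`/`reverse`
#'   columns (if present).
#' @param threshold localization probability cutoff (inclusive).
#' @return filtered data.frame.
#' @export
filter_class1 <- function(records, threshold = 0.75) {
  lp <- records$localization_probability
  if (is.null(lp)) stop("records lack a `localization_probability` column")
  if (any(lp < 0 | lp > 1, na.rm = TRUE))
    stop("localization probabilities must lie in [0, 1]")
  for (fl in c("contaminant", "reverse"))
    if (fl %in% names(records))
      records <- records[!isTRUE_vec(records[[fl]]), , drop = FALSE]
  records[!is.na(lp <- records$localization_probability) & lp >= threshold, ,
          drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Split phosphosite rows by multiplicity
#'
#' Expands each site into one row per phosphopeptide multiplicity (1-3)
#' that carries at least one quantified ratio; rows without any
#' quantification are removed. Ratio columns `<comp>_r<rep>___<m>` become
#' `<comp>_r<rep>` on the expanded rows. Pure reshaping: no ratio value is
#' altered.
#'
#' @param records data.frame of class-I site rows.
#' @return expanded data.frame with an added `multiplicity` column.
#' @export
split_multiplicity <- function(records) {
  mcols <- .ratio_cols(records, split = TRUE)
  if (length(mcols) == 0) stop("no multiplicity-suffixed ratio columns found")
  base <- sub("___[123]$", "", mcols)
  mult <- as.integer(sub("^.*___", "", mcols))
  keep_cols <- setdiff(names(records), mcols)
  out <- list()
  for (m in sort(unique(mult))) {
    cols_m <- mcols[mult == m]
    vals <- records[, cols_m, drop = FALSE]
    names(vals) <- base[mult == m]
    quant <- rowSums(!is.na(vals)) > 0
    if (!any(quant)) next
    block <- cbind(records[quant, keep_cols, drop = FALSE],
                   multiplicity = m, vals[quant, , drop = FALSE])
    out[[as.character(m)]] <- block
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- cbind(records[0, keep_cols, drop = FALSE],
                 multiplicity = integer(0))
  rownames(res) <- NULL
  res
}

#' Call regulated phosphosites by the both-replicate rule
#'
#' A (site, multiplicity) is called `up` in a comparison when all replicate
#' log2 ratios are at or beyond `+cutoff`, `down` when all are at or beyond
#' `-cutoff`, and `ns` otherwise (including when any replicate is missing).
#'
#' @param records multiplicity-split data.frame with ratio columns
#'   `<comparison>_r<replicate>`.
#' @param cutoff log2 fold-change cutoff applied per replicate.
#' @return long data.frame of `SiteRegulationCall`s: site identity columns,
#'   `multiplicity`, `comparison`, replicate ratios `r1`, `r2`, ... and
#'   `call`.
#' @export
call_regulated <- function(records, cutoff = 1.0) {
  rcols <- .ratio_cols(records)
  if (length(rcols) == 0) stop("no ratio columns of the form <comp>_r<rep>")
  comp <- sub("_r\\d+$", "", rcols)
  id_cols <- intersect(c("site_id", "protein_id", "position", "residue",
                         "multiplicity"), names(records))
  out <- list()
  for (cm in unique(comp)) {
    cols <- rcols[comp == cm]
    cols <- cols[order(as.integer(sub("^.*_r", "", cols)))]
    ratios <- as.matrix(records[, cols, drop = FALSE])
    all_up <- rowSums(ratios >= cutoff) == ncol(ratios) &
      rowSums(is.na(ratios)) == 0
    all_dn <- rowSums(ratios <= -cutoff) == ncol(ratios) &
      rowSums(is.na(ratios)) == 0
    call <- ifelse(all_up, "up", ifelse(all_dn, "down", "ns"))
    block <- records[, id_cols, drop = FALSE]
    block$comparison <- cm
    for (j in seq_along(cols)) block[[paste0("r", j)]] <- ratios[, j]
    block$call <- call
    out[[cm]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Keyword over-representation among regulated phosphoproteins
#'
#' For each comparison and direction, the proteins bearing at least one
#' regulated site (each protein counted once, however many of its sites
#' are regulated) are tested against all proteins in the dataset as
#' background with the Fisher exact test; terms are reported with
#' BH-adjusted q-values and a significance flag at `fdr`.
#'
#' @param calls output of [call_regulated()].
#' @param records the multiplicity-split records that produced `calls`
#'   (define the background protein universe).
#' @param annotation_map named list protein id -> terms.
#' @param fdr BH false-discovery cutoff for the `significant` flag.
#' @return data.frame of enrichment rows with `comparison`, `direction` and
#'   `significant` columns; empty when nothing is regulated.
#' @export
keyword_enrichment <- function(calls, records, annotation_map, fdr = 0.02) {
  background <- unique(records$protein_id)
  if (length(background) == 0) stop("empty background")
  out <- list()
  for (cm in unique(calls$comparison)) {
    for (dir in c("up", "down")) {
      prot <- unique(calls$protein_id[calls$comparison == cm &
                                        calls$call == dir])
      if (length(prot) == 0) next
      rows <- fisher_enrichment(prot, background, annotation_map)
      if (nrow(rows) == 0) next
      rows$comparison <- cm
      rows$direction <- dir
      rows$significant <- rows$q_value < fdr
      out[[paste(cm, dir)]] <- rows
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame()
  rownames(res) <- NULL
  res
}

#' Position-wise residue enrichment between window sets
#'
#' Sequence-logo style analysis: for every position within
#' `+-half_width` of the centered site and every residue, the difference in
#' relative frequency between foreground and background windows, with a
#' two-proportion z-test per cell and a significance flag at `p_cut`.
#'
#' @param foreground_windows,background_windows character vectors of
#'   equal-length, odd-width, site-centered sequence windows.
#' @param half_width positions analysed on each side of the site.
#' @param p_cut per-cell significance level.
#' @return data.frame: `position` (relative), `residue`, `fg_freq`,
#'   `bg_freq`, `diff`, `p_value`, `significant`.
#' @export
motif_analysis <- function(foreground_windows, background_windows,
                           half_width = 6, p_cut = 0.05) {
  wlen <- unique(c(nchar(foreground_windows), nchar(background_windows)))
  if (length(wlen) != 1)
    stop("all windows must have the same length")
  if (wlen %% 2 == 0) stop("window length must be odd (site-centered)")
  center <- (wlen + 1) / 2
  if (half_width > center - 1) stop("half_width exceeds window coverage")
  fg <- do.call(rbind, strsplit(foreground_windows, ""))
  bg <- do.call(rbind, strsplit(background_windows, ""))
  out <- list()
  for (pos in -half_width:half_width) {
    col <- center + pos
    f <- fg[, col]; b <- bg[, col]
    residues <- sort(unique(c(f, b)))
    for (res in residues) {
      k1 <- sum(f == res); n1 <- length(f)
      k2 <- sum(b == res); n2 <- length(b)
      p1 <- k1 / n1; p2 <- k2 / n2
      pp <- (k1 + k2) / (n1 + n2)
      se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
      p <- if (se == 0) 1 else 2 * stats::pnorm(-abs((p1 - p2) / se))
      out[[length(out) + 1]] <- data.frame(
        position = pos, residue = res, fg_freq = p1, bg_freq = p2,
        diff = p1 - p2, p_value = p, significant = p < p_cut
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Match phosphosites between two datasets
#'
#' Inner join on (protein, position); multiplicities are collapsed so a
#' site quantified at several multiplicities matches once.
#'
#' @param records_a,records_b class-I filtered site data.frames with
#'   `protein_id` and `position` columns.
#' @return data.frame of matched sites (`protein_id`, `position`).
#' @export
match_sites <- function(records_a, records_b) {
  a <- unique(records_a[, c("protein_id", "position")])
  b <- unique(records_b[, c("protein_id", "position")])
  res <- merge(a, b, by = c("protein_id", "position"))
  res[order(res$protein_id, res$position), , drop = FALSE]
}
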