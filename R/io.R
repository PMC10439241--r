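# TSV dialect: tab-separated, UTF-8, "." decimal, "#"-prefixed header lines
# carrying provenance (thresholds, seed). Flag columns use the "+"
# convention: "+" = flagged, empty = not.

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
}

#' Write a data.frame as TSV with provenance header
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param provenance named list serialized into `# key: value` comment
#'   lines at the top of the file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, provenance = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(provenance))
    writeLines(sprintf("# %s: %s", k,
                       paste(provenance[[k]], collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read the provenance header of a pipeline TSV
#'
#' @param path file written by [write_tsv()].
#' @return named character vector of `# key: value` entries.
#' @export
read_provenance <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- grep("^# ", lines, value = TRUE)
  if (length(hdr) == 0) return(character(0))
  kv <- regmatches(hdr, regexec("^# ([^:]+): (.*)$", hdr))
  vals <- vapply(kv, function(m) m[3], character(1))
  names(vals) <- vapply(kv, function(m) m[2], character(1))
  vals
}

.parse_flag <- function(x, n) {
  if (is.null(x)) return(logical(n))
  !is.na(x) & x == "+"
}

#' Read a protein-group table into an ExpressionMatrix
#'
#' Expects a TSV with a `feature_id` column, optional flag columns
#' (`contaminant`, `reverse`, `only_identified_by_site`; "+" = flagged), an
#' optional semicolon-separated `keywords` column, and one intensity column
#' per design sample. Intensities of 0 mean "not quantified" in this
#' dialect and are read as missing; malformed numeric cells become missing
#' with a logged count.
#'
#' @param path TSV path.
#' @param design data.frame with a `sample` column naming the intensity
#'   columns, plus design columns (`timepoint_days`, `plex`, ...).
#' @param log2_transform log2-transform intensities on read (default FALSE:
#'   values already on log2 scale).
#' @return an [expression_matrix()].
#' @export
read_protein_table <- function(path, design, log2_transform = FALSE) {
  df <- .read_tsv(path)
  if (!"feature_id" %in% names(df))
    stop("missing mandatory column: feature_id")
  if (anyDuplicated(df$feature_id))
    stop("duplicated feature ids in ", path)
  missing_cols <- setdiff(design$sample, names(df))
  if (length(missing_cols) > 0)
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  n_bad <- 0L
  vals <- sapply(design$sample, function(s) {
    v <- df[[s]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      n_bad <<- n_bad + sum(is.na(suppress) & !is.na(v) & v != "")
      v <- suppress
    }
    v[!is.na(v) & v == 0] <- NA_real_   # zero = not quantified
    v
  })
  if (n_bad > 0) message(n_bad, " malformed numeric cells read as missing")
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(df$feature_id, design$sample))
  if (log2_transform) vals <- log2(vals)
  flags <- data.frame(
    contaminant = .parse_flag(df$contaminant, nrow(df)),
    reverse = .parse_flag(df$reverse, nrow(df)),
    only_identified_by_site = .parse_flag(df$only_identified_by_site, nrow(df))
  )
  annotations <- list()
  if ("keywords" %in% names(df)) {
    annotations <- strsplit(ifelse(is.na(df$keywords), "", df$keywords), ";")
    annotations <- lapply(annotations, function(v) v[nzchar(v)])
    names(annotations) <- df$feature_id
  }
  expression_matrix(vals, design, flags, annotations)
}

#' Write an ExpressionMatrix as a protein-group TSV
#'
#' @param em [expression_matrix()].
#' @param path output path.
#' @param provenance named list for the `#` header.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(em, path, provenance = list()) {
  df <- data.frame(feature_id = rownames(em$values),
                   stringsAsFactors = FALSE)
  for (fl in names(em$flags))
    df[[fl]] <- ifelse(em$flags[[fl]], "+", "")
  if (length(em$annotations) > 0)
    df$keywords <- vapply(rownames(em$values), function(f)
      paste(em$annotations[[f]] %||% character(0), collapse = ";"),
      character(1))
  df <- cbind(df, as.data.frame(em$values, check.names = FALSE))
  write_tsv(df, path, provenance)
}

#' Read a phosphosite table
#'
#' Expects `protein_id`, `position`, `residue` (or `amino_acid`),
#' `localization_probability`, `sequence_window`, optional flag columns,
#' and per-multiplicity ratio columns suffixed `___1`/`___2`/`___3`.
#' Sequence windows must have odd length with the phosphorylated residue
#' at the center.
#'
#' @param path TSV path.
#' @return data.frame of site records (one row per site before
#'   multiplicity splitting).
#' @export
read_site_table <- function(path) {
  df <- .read_tsv(path)
  if ("amino_acid" %in% names(df) && !"residue" %in% names(df))
    names(df)[names(df) == "amino_acid"] <- "residue"
  mandatory <- c("protein_id", "position", "residue",
                 "localization_probability", "sequence_window")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0)
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  wlen <- nchar(df$sequence_window)
  if (any(wlen %% 2 == 0))
    stop("sequence windows must have odd length")
  center <- substr(df$sequence_window, (wlen + 1) / 2, (wlen + 1) / 2)
  if (any(center != df$residue))
    stop("sequence window center does not match the site residue")
  for (fl in c("contaminant", "reverse"))
    df[[fl]] <- .parse_flag(df[[fl]], nrow(df))
  if (!"site_id" %in% names(df))
    df$site_id <- sprintf("%s_%d", df$protein_id, df$position)
  df
}

#' Read semi-tryptic peptide evidence
#'
#' @param path TSV with columns `protein_id`, `start`, `end`,
#'   `specific_terminus`, `retention_time`, `intensity`.
#' @return data.frame of peptide evidence.
#' @export
read_peptide_table <- function(path) {
  df <- .read_tsv(path)
  mandatory <- c("protein_id", "start", "end", "specific_terminus",
                 "retention_time", "intensity")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0)
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  df
}

#' Read an externally predicted cleavage-site list
#'
#' @param path TSV with columns `position`, `score`, `p_value`.
#' @return data.frame of predicted sites.
#' @export
read_predicted_sites <- function(path) {
  df <- .read_tsv(path)
  missing_cols <- setdiff(c("position", "score", "p_value"), names(df))
  if (length(missing_cols) > 0)
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  df
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return named character vector (names = first word of each header).
#' @export
read_fasta_sequences <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  out
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path config file; format chosen by extension (.yaml/.yml/.json).
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Write a machine-readable run manifest
#'
#' Records inputs, thresholds, seed and package version so a run can be
#' reproduced exactly.
#'
#' @param path output JSON path.
#' @param inputs named list/vector of input file paths.
#' @param thresholds named list of thresholds in effect.
#' @param seed integer seed used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, inputs = list(), thresholds = list(),
                           seed = NA_integer_) {
  manifest <- list(
    package = "proteodiff",
    version = as.character(utils::packageVersion("proteodiff")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs, thresholds = thresholds, seed = seed
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
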