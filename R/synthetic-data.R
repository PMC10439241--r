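#' Simulation configuration
#'
#' Validated parameter set shared by all four synthetic-data generators.
#' Defaults mirror the study designs the pipelines were built for: a
#' six-timepoint (0-15 days, sampled every third day) TMT time course with
#' five 6plex batches (one plex per biological replicate), two-replicate
#' three-channel dimethyl phosphoproteomics, and four BioID constructs with
#' three replicates each.
#'
#' @param n_features number of simulated features (proteins or sites).
#' @param frac_regulated fraction of features carrying a true effect.
#' @param effect_log2 true absolute log2 fold change of regulated features.
#' @param noise_sd standard deviation of measurement noise (log2 scale).
#' @param n_plexes number of TMT plexes (= biological replicates).
#' @param timepoints_days strictly increasing integer time points.
#' @param batch_sd standard deviation of the additive per-plex offset.
#' @param missing_rate completely-at-random missingness rate (TMT arm).
#' @param seed integer seed; identical config + seed gives identical output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_features = 1000, frac_regulated = 0.1,
                       effect_log2 = 1.5, noise_sd = 0.3, n_plexes = 5,
                       timepoints_days = c(0L, 3L, 6L, 9L, 12L, 15L),
                       batch_sd = 0.5, missing_rate = 0.05, seed = 1L) {
  num_ok <- function(v) is.numeric(v) && all(is.finite(v))
  if (!num_ok(n_features) || n_features < 1)
    stop("`n_features` must be a finite count >= 1")
  if (!num_ok(n_plexes) || n_plexes < 1)
    stop("`n_plexes` must be a finite count >= 1")
  if (!num_ok(frac_regulated) || frac_regulated < 0 || frac_regulated > 1)
    stop("`frac_regulated` must be a fraction in [0, 1]")
  if (!num_ok(missing_rate) || missing_rate < 0 || missing_rate > 1)
    stop("`missing_rate` must be a fraction in [0, 1]")
  if (!num_ok(effect_log2) || effect_log2 < 0)
    stop("`effect_log2` must be a finite non-negative real")
  if (!num_ok(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be a finite non-negative real")
  if (!num_ok(batch_sd) || batch_sd < 0)
    stop("`batch_sd` must be a finite non-negative real")
  if (!num_ok(timepoints_days) || length(timepoints_days) < 2 ||
      any(diff(timepoints_days) <= 0))
    stop("`timepoints_days` must be >= 2 strictly increasing values")
  if (!num_ok(seed)) stop("`seed` must be a finite integer")
  structure(list(
    n_features = as.integer(n_features), frac_regulated = frac_regulated,
    effect_log2 = effect_log2, noise_sd = noise_sd,
    n_plexes = as.integer(n_plexes),
    timepoints_days = as.integer(timepoints_days), batch_sd = batch_sd,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

# Seven temporal archetypes: true deviation from baseline in units of
# effect_log2 at each time point. Each archetype reaches a full +-1 unit
# at its extreme and has a distinct, tie-free rank signature so that the
# archetypes are mutually separable under Spearman correlation distance
# (monotone shapes share a rank order, so only one per direction is used).
# Shapes are interpolated linearly when the design has more or fewer than
# six time points.
.tmt_archetype_shapes <- list(
  up_gradual     = c(0, 0.75, 0.80, 0.85, 0.90, 1),
  down_gradual   = c(0, -0.75, -0.80, -0.85, -0.90, -1),
  up_early       = c(0, 1, 0.90, 0.85, 0.80, 0.75),
  down_early     = c(0, -1, -0.90, -0.85, -0.80, -0.75),
  up_mid         = c(0, 0.85, 1, 0.90, 0.80, 0.75),
  down_mid       = c(0, -0.85, -1, -0.90, -0.80, -0.75),
  up_then_down   = c(0, 0.80, 1, -0.80, -0.90, -1)
)

.tmt_archetypes <- function(n_days) {
  lapply(.tmt_archetype_shapes, function(s) {
    if (n_days == length(s)) s
    else stats::approx(seq(0, 1, length.out = length(s)), s,
                       xout = seq(0, 1, length.out = n_days))$y
  })
}

#' Simulate a TMT differentiation time course with known truth
#'
#' Generates `n_plexes` x `length(timepoints_days)` samples of log2
#' intensities. A `frac_regulated` fraction of features follows one of
#' seven temporal archetypes (early/late monotone up or down, transient
#' up/down, biphasic) scaled to `effect_log2`; each plex carries an
#' additive batch offset drawn from Normal(0, batch_sd) shared by all its
#' channels; i.i.d. Normal(0, noise_sd) noise is added and values are
#' removed completely at random at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return list with elements `matrix` (an [expression_matrix()]) and
#'   `truth` (data.frame: `feature_id`, `true_cluster` archetype name or
#'   `NA`, and per non-baseline day the sign `dir_d<day>` in
#'   `{"up","down","null"}` and magnitude `mag_d<day>` (log2) of the true
#'   effect). The drawn per-plex offsets are attached as attribute
#'   `batch_offsets` of `truth`.
#' @export
simulate_tmt <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  days <- config$timepoints_days
  n_days <- length(days)
  nf <- config$n_features
  arch <- .tmt_archetypes(n_days)
  n_reg <- round(config$frac_regulated * nf)
  feature_id <- sprintf("prot%04d", seq_len(nf))
  reg_idx <- if (n_reg > 0) seq_len(n_reg) else integer(0)
  arch_id <- rep(NA_character_, nf)
  if (n_reg > 0)
    arch_id[reg_idx] <- names(arch)[((seq_len(n_reg) - 1) %% length(arch)) + 1]

  base <- stats::rnorm(nf, mean = 20, sd = 1.5)
  signal <- matrix(0, nf, n_days)
  for (i in reg_idx)
    signal[i, ] <- arch[[arch_id[i]]] * config$effect_log2

  samples <- expand.grid(plex = seq_len(config$n_plexes), day = days,
                         KEEP.OUT.ATTRS = FALSE)
  samples <- samples[order(samples$plex, samples$day), ]
  sample_id <- sprintf("plex%d_d%d", samples$plex, samples$day)
  offsets <- stats::rnorm(config$n_plexes, 0, config$batch_sd)

  vals <- matrix(NA_real_, nf, nrow(samples),
                 dimnames = list(feature_id, sample_id))
  for (s in seq_len(nrow(samples))) {
    di <- match(samples$day[s], days)
    vals[, s] <- base + signal[, di] + offsets[samples$plex[s]] +
      stats::rnorm(nf, 0, config$noise_sd)
  }
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(vals)) < config$missing_rate
    vals[drop] <- NA_real_
  }
  design <- data.frame(sample = sample_id, timepoint_days = samples$day,
                       plex = samples$plex,
                       channel = match(samples$day, days))
  truth <- data.frame(feature_id = feature_id, true_cluster = arch_id)
  for (di in seq_along(days)[-1]) {
    delta <- signal[, di] - signal[, 1]
    truth[[sprintf("dir_d%d", days[di])]] <-
      ifelse(delta > 0, "up", ifelse(delta < 0, "down", "null"))
    truth[[sprintf("mag_d%d", days[di])]] <- delta
  }
  attr(truth, "batch_offsets") <- offsets
  list(matrix = expression_matrix(vals, design), truth = truth)
}

.AA <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
         "T","V","W","Y")

# random sequence window of odd width centered on `residue`
.random_window <- function(width, residue, plant_motif = FALSE) {
  half <- (width - 1) / 2
  w <- sample(.AA, width, replace = TRUE)
  w[half + 1] <- residue
  if (plant_motif) {
    w[half + 2] <- "P"                     # +1 proline (S-P site)
    w[half + 1 - 3] <- sample(c("R", "K"), 1)  # basic residue at -3
  }
  paste(w, collapse = "")
}

#' Simulate a dimethyl phosphosite table with known truth
#'
#' Produces one row per phosphosite with localization probability,
#' a +/-15 residue sequence window, and per-comparison, per-replicate log2
#' ratios split by multiplicity (columns `<comparison>_r<rep>___<mult>`).
#' Regulated sites receive a shift of `+-effect_log2` in both replicates of
#' their regulated comparison(s); their sequence windows embed an S-P motif
#' (proline at +1, basic residue at -3) at `motif_excess` above the
#' background rate.
#'
#' @param config a [sim_config()]; `n_features` sites, `frac_regulated`,
#'   `effect_log2`, `noise_sd` and `seed` are used.
#' @param frac_below_loc fraction of sites drawn with localization
#'   probability below 0.75 (non-class-I).
#' @param motif_excess excess probability that a regulated site's window
#'   carries the planted motif (background rate is the random expectation).
#' @param n_replicates replicates per comparison.
#' @param comparisons character vector of ratio comparisons.
#' @param window_width odd width of the sequence window.
#' @return list with `records` (data.frame of site rows) and `truth`
#'   (data.frame: `site_id`, `protein_id`, `position`, direction per
#'   comparison).
#' @export
simulate_phospho <- function(config, frac_below_loc = 0.1, motif_excess = 0.6,
                             n_replicates = 2,
                             comparisons = c("d7.d0", "d14.d0", "d14.d7"),
                             window_width = 31) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot(frac_below_loc >= 0, frac_below_loc <= 1,
            motif_excess >= 0, motif_excess <= 1,
            window_width %% 2 == 1)
  set.seed(config$seed)
  nf <- config$n_features
  n_reg <- round(config$frac_regulated * nf)
  protein_id <- sprintf("P%04d", ceiling(seq_len(nf) / 3))
  position <- 10L + (seq_len(nf) - 1L) %% 3L * 25L +
    as.integer(50 * ceiling(seq_len(nf) / 3) %% 7)
  residue <- sample(c("S", "T", "Y"), nf, replace = TRUE,
                    prob = c(0.75, 0.2, 0.05))
  below <- stats::runif(nf) < frac_below_loc
  loc_prob <- ifelse(below, stats::runif(nf, 0, 0.7499),
                     stats::runif(nf, 0.75, 1))
  reg_idx <- if (n_reg > 0) seq_len(n_reg) else integer(0)
  direction <- rep("null", nf)
  if (n_reg > 0)
    direction[reg_idx] <- rep(c("up", "down"), length.out = n_reg)
  # regulated sites change in d14.d0 and (weaker pattern) d7.d0
  reg_comparison <- "d14.d0"

  has_motif <- stats::runif(nf) < ifelse(direction != "null",
                                         motif_excess, 0)
  windows <- vapply(seq_len(nf), function(i)
    .random_window(window_width, residue[i], has_motif[i]), character(1))

  n_mult <- sample(1:2, nf, replace = TRUE, prob = c(0.7, 0.3))
  records <- data.frame(
    site_id = sprintf("%s_%d", protein_id, position),
    protein_id = protein_id, position = position, residue = residue,
    localization_probability = loc_prob, sequence_window = windows,
    contaminant = FALSE, reverse = FALSE, stringsAsFactors = FALSE
  )
  for (cmp in comparisons) {
    for (r in seq_len(n_replicates)) {
      for (m in 1:3) {
        col <- sprintf("%s_r%d___%d", cmp, r, m)
        v <- rep(NA_real_, nf)
        quant <- m <= n_mult
        eff <- ifelse(direction == "up", config$effect_log2,
                      ifelse(direction == "down", -config$effect_log2, 0))
        mu <- if (cmp == reg_comparison) eff else rep(0, nf)
        v[quant] <- stats::rnorm(sum(quant), mu[quant], config$noise_sd)
        records[[col]] <- v
      }
    }
  }
  truth <- data.frame(site_id = records$site_id,
                      protein_id = protein_id, position = position,
                      stringsAsFactors = FALSE)
  for (cmp in comparisons)
    truth[[paste0("dir_", cmp)]] <- if (cmp == reg_comparison) direction
                                    else rep("null", nf)
  list(records = records, truth = truth)
}

#' Simulate a SILAC BioID experiment with known truth
#'
#' Four bait constructs plus a heavy-labeled control channel. True
#' interactors of a construct have light/heavy log2 ratios distributed
#' Normal(effect_log2, noise_sd) in that construct and Normal(0, noise_sd)
#' elsewhere. Missingness of light intensities is left-censored: the
#' probability that a value is missing rises along a logistic curve as the
#' intensity falls, emulating the detection-floor pattern that justifies
#' minimum-value imputation.
#'
#' @param config a [sim_config()].
#' @param constructs construct names; the first `frac_regulated * n_features`
#'   features are split between them as true interactors.
#' @param n_replicates replicates per construct.
#' @param censor_quantile intensity quantile at which the missingness
#'   probability is 50%; set <= 0 for no censoring.
#' @param censor_scale logistic scale (log2 units) of the censoring curve.
#' @return list with `records` (long data.frame: `feature_id`, `construct`,
#'   `replicate`, `light`, `heavy`, both log2) and `truth` (data.frame:
#'   `feature_id`, `interactor_of` = construct name or `NA`).
#' @export
simulate_bioid <- function(config, constructs = c("DSK", "DS", "SK", "K"),
                           n_replicates = 3, censor_quantile = 0.08,
                           censor_scale = 0.6) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_features
  n_reg <- round(config$frac_regulated * nf)
  feature_id <- sprintf("bp%04d", seq_len(nf))
  interactor_of <- rep(NA_character_, nf)
  if (n_reg > 0)
    interactor_of[seq_len(n_reg)] <-
      constructs[((seq_len(n_reg) - 1) %% length(constructs)) + 1]

  base <- stats::rnorm(nf, mean = 24, sd = 2)
  grid <- expand.grid(construct = constructs,
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    con <- grid$construct[g]
    is_int <- !is.na(interactor_of) & interactor_of == con
    # heavy is the pooled spike-in control: constant true abundance; the
    # light/heavy log2 ratio is Normal(effect, noise_sd) for interactors
    # in their construct and Normal(0, noise_sd) otherwise
    ratio <- stats::rnorm(nf, ifelse(is_int, config$effect_log2, 0),
                          config$noise_sd)
    heavy <- base
    light <- heavy + ratio
    data.frame(feature_id = feature_id, construct = con,
               replicate = grid$replicate[g], light = light, heavy = heavy,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  if (censor_quantile > 0) {
    mid <- stats::quantile(records$light, censor_quantile, na.rm = TRUE)
    p_miss <- stats::plogis((mid - records$light) / censor_scale)
    records$light[stats::runif(nrow(records)) < p_miss] <- NA_real_
    p_miss_h <- stats::plogis((mid - records$heavy) / censor_scale)
    records$heavy[stats::runif(nrow(records)) < p_miss_h] <- NA_real_
  }
  truth <- data.frame(feature_id = feature_id, interactor_of = interactor_of,
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Tryptic in-silico digestion (Trypsin/P)
#'
#' Cleaves C-terminal to K and R, including before proline, with up to
#' `missed` missed cleavages; peptides shorter than `min_length` are
#' discarded (standard minimal search length).
#'
#' @param protein_seq amino-acid string.
#' @param missed maximum missed cleavages.
#' @param min_length minimal peptide length retained.
#' @return data.frame: `start`, `end` (1-based inclusive), `peptide`,
#'   `n_missed`.
#' @export
digest_tryptic <- function(protein_seq, missed = 2, min_length = 7) {
  stopifnot(is.character(protein_seq), nchar(protein_seq) > 0)
  aa <- strsplit(protein_seq, "")[[1]]
  n <- length(aa)
  cuts <- which(aa %in% c("K", "R"))      # cut AFTER these positions
  cuts <- cuts[cuts < n]
  bounds <- c(0L, cuts, n)                # segment boundaries
  segs <- data.frame(start = bounds[-length(bounds)] + 1L,
                     end = bounds[-1])
  out <- list()
  for (m in 0:missed) {
    i <- seq_len(nrow(segs) - m)
    if (length(i) == 0) next
    st <- segs$start[i]; en <- segs$end[i + m]
    out[[m + 1]] <- data.frame(start = st, end = en, n_missed = m)
  }
  pep <- do.call(rbind, out)
  pep <- pep[pep$end - pep$start + 1 >= min_length, , drop = FALSE]
  pep$peptide <- vapply(seq_len(nrow(pep)), function(i)
    substr(protein_seq, pep$start[i], pep$end[i]), character(1))
  rownames(pep) <- NULL
  pep[, c("start", "end", "peptide", "n_missed")]
}

#' Simulate semi-tryptic peptide evidence for a protein
#'
#' Emits (i) fully tryptic parent peptides with reference retention times,
#' (ii) in-source fragment ladders that share their parent's retention time
#' within a small jitter (gas-phase fragmentation co-elutes with the intact
#' parent), optionally including breaks adjacent to proline, and (iii) true
#' proteolytic semi-tryptic peptides at the requested cleavage positions,
#' eluting far from any parent peptide.
#'
#' @param protein_seq amino-acid string.
#' @param true_cleavage_positions integer positions (cut after residue i);
#'   may be empty.
#' @param config a [sim_config()] (seed and noise_sd are used).
#' @param in_source_regions optional list of integer vectors, each a run of
#'   consecutive breakpoint positions to emit as a co-eluting in-source
#'   ladder (e.g. `list(313:316)`).
#' @param rt_jitter retention-time jitter (minutes) of in-source fragments
#'   around their parent.
#' @param min_length minimal peptide length retained.
#' @param parent_rt optional named numeric vector overriding the reference
#'   retention time of specific parents (`names` = "start-end").
#' @return data.frame of `SemiTrypticPeptide`s: `protein_id`, `start`,
#'   `end`, `specific_terminus` ("N", "C", or "both" for fully tryptic),
#'   `retention_time` (minutes), `intensity`.
#' @export
simulate_semitryptic <- function(protein_seq, true_cleavage_positions = integer(0),
                                 config = sim_config(),
                                 in_source_regions = NULL, rt_jitter = 0.1,
                                 min_length = 7, parent_rt = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- nchar(protein_seq)
  if (n == 0) stop("empty protein sequence")
  if (length(true_cleavage_positions) > 0 &&
      (any(true_cleavage_positions < 1) || any(true_cleavage_positions >= n)))
    stop("cleavage positions must lie inside the sequence")
  tryp <- digest_tryptic(protein_seq, missed = 0, min_length = min_length)
  if (nrow(tryp) == 0) stop("no tryptic peptides of sufficient length")
  tryp$retention_time <- stats::runif(nrow(tryp), 20, 90)
  if (!is.null(parent_rt)) {
    key <- sprintf("%d-%d", tryp$start, tryp$end)
    hit <- key %in% names(parent_rt)
    tryp$retention_time[hit] <- parent_rt[key[hit]]
  }
  peptides <- data.frame(
    protein_id = "PROT1", start = tryp$start, end = tryp$end,
    specific_terminus = "both", retention_time = tryp$retention_time,
    intensity = stats::rlnorm(nrow(tryp), log(1e6), 0.5),
    stringsAsFactors = FALSE
  )
  parent_for <- function(pos) {
    # fully tryptic peptide spanning a breakpoint between pos and pos+1
    hit <- which(tryp$start <= pos & tryp$end > pos)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  emit_semi <- function(bp, rt) {
    # two possible products per breakpoint: tryptic-N (start..bp) and
    # tryptic-C (bp+1..end); emit those meeting the length floor
    par <- parent_for(bp)
    if (is.na(par)) return(NULL)
    st <- tryp$start[par]; en <- tryp$end[par]
    out <- list()
    if (bp - st + 1 >= min_length)
      out$n <- data.frame(protein_id = "PROT1", start = st, end = bp,
                          specific_terminus = "N", retention_time = rt,
                          intensity = stats::rlnorm(1, log(1e5), 0.5),
                          stringsAsFactors = FALSE)
    if (en - bp >= min_length)
      out$c <- data.frame(protein_id = "PROT1", start = bp + 1L, end = en,
                          specific_terminus = "C", retention_time = rt,
                          intensity = stats::rlnorm(1, log(1e5), 0.5),
                          stringsAsFactors = FALSE)
    do.call(rbind, out)
  }
  for (reg in (in_source_regions %||% list())) {
    for (bp in reg) {
      par <- parent_for(bp)
      if (is.na(par)) next
      rt <- tryp$retention_time[par] + stats::runif(1, -rt_jitter, rt_jitter)
      peptides <- rbind(peptides, emit_semi(bp, rt))
    }
  }
  for (bp in true_cleavage_positions) {
    par <- parent_for(bp)
    if (is.na(par))
      stop("cleavage position ", bp, " falls outside any tryptic peptide")
    # elute well away from the parent: shift by 10-25 min, bounced into range
    shift <- stats::runif(1, 10, 25) * sample(c(-1, 1), 1)
    rt <- tryp$retention_time[par] + shift
    if (rt < 5 || rt > 110) rt <- tryp$retention_time[par] - shift
    peptides <- rbind(peptides, emit_semi(bp, rt))
  }
  rownames(peptides) <- NULL
  peptides
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic cleavage-mapping fixture
#'
#' Builds a fully synthetic 400-residue protein and the companion inputs
#' for exercising the cleavage mapper end to end: two true proteolytic
#' ladder regions (breakpoints 320-323 and 356-359, serine at the matched
#' positions), one co-eluting in-source ladder (313-316), one
#' proline-adjacent break (305, proline at 306), a tryptic cleavage site
#' at arginine 342, and a glutamine at 384 inside a tryptic peptide below
#' the minimal detectable length. The predicted-site list (positions 323,
#' 342, 357, 384) is a synthetic stand-in for an external protease
#' cleavage predictor's output.
#'
#' @return list: `sequence` (amino-acid string), `true_regions` (list of
#'   breakpoint runs), `in_source_regions` (list of breakpoint runs,
#'   including the proline-adjacent break), `predicted_sites` (data.frame
#'   `position`, `score`, `p_value`).
#' @export
synthetic_cleavage_protein <- function() {
  n <- 400
  alphabet <- strsplit("ACDEFGHILMNQSTVWY", "")[[1]]  # no K/R/P
  aa <- rep(alphabet, length.out = n)
  aa[seq(30, 270, by = 30)] <- "K"       # regular tryptic sites upstream
  aa[c(300, 330, 365, 380, 385)] <- "K"  # bound the analysed peptides
  aa[390] <- "K"
  aa[342] <- "R"                         # prediction on a tryptic site
  aa[306] <- "P"                         # in-source break next to proline
  aa[c(323, 357)] <- "S"                 # matched positions are serines
  aa[384] <- "Q"                         # prediction in a too-short peptide
  list(
    sequence = paste(aa, collapse = ""),
    true_regions = list(320:323, 356:359),
    in_source_regions = list(313:316, 305L),
    predicted_sites = data.frame(
      position = c(323L, 342L, 357L, 384L),
      score = c(0.96, 0.90, 0.96, 0.90),
      p_value = c(4.1e-5, 1e-3, 4.1e-5, 1e-3)
    )
  )
}
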