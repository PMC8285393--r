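# Orchestration: a validated run configuration plus the three stages
# (simulate, score + compare, metagene). Every output table carries a
# provenance header with the configuration hash, so results can be tied
# back to the exact settings that produced them.

CONFIG_FIELDS <- c("annotation", "footprints", "out_dir", "offsets",
                   "min_cds_reads", "min_read_length", "max_read_length",
                   "metagene_window_up", "metagene_window_down",
                   "comparisons", "simulate")

#' Build a validated run configuration
#'
#' @param annotation path to a transcript table (see
#'   [read_transcript_table()]).
#' @param footprints named list or vector: condition name -> footprint
#'   TSV path.
#' @param out_dir output directory.
#' @param offsets P-site offset table.
#' @param min_cds_reads eligibility threshold for both scores.
#' @param min_read_length,max_read_length size-selection bounds (nt).
#' @param metagene_window_up,metagene_window_down metagene window (nt).
#' @param comparisons list of comparisons, each a list with `reference`,
#'   `treatment` (condition names) and `rrts_alternative` (the
#'   Mann-Whitney alternative for treatment RRTS relative to reference:
#'   `"greater"`, `"less"` or `"two.sided"`). Pause scores are always
#'   compared with a two-sided signed-rank test on transcripts eligible
#'   in both arms. Nothing is inferred from file names.
#' @param simulate optional list with `params` ([simulation_params()]),
#'   `conditions` and `seed`, used by [run_simulate()].
#' @return list of class `run_config`.
#' @export
run_config <- function(annotation = NULL, footprints = NULL, out_dir = ".",
                       offsets = default_psite_offsets(),
                       min_cds_reads = 32L,
                       min_read_length = 15L, max_read_length = 35L,
                       metagene_window_up = 100L, metagene_window_down = 100L,
                       comparisons = list(), simulate = NULL) {
  cfg <- list(annotation = annotation, footprints = as.list(footprints),
              out_dir = out_dir, offsets = offsets,
              min_cds_reads = as.integer(min_cds_reads),
              min_read_length = as.integer(min_read_length),
              max_read_length = as.integer(max_read_length),
              metagene_window_up = as.integer(metagene_window_up),
              metagene_window_down = as.integer(metagene_window_down),
              comparisons = comparisons, simulate = simulate)
  for (cmp in cfg$comparisons) {
    if (!all(c("reference", "treatment", "rrts_alternative") %in% names(cmp))) {
      stop("each comparison needs reference, treatment and rrts_alternative",
           call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected rather than silently ignored.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(raw), CONFIG_FIELDS)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$offsets)) raw$offsets <- unlist(raw$offsets)
  if (!is.null(raw$simulate) && !is.null(raw$simulate$params)) {
    p <- raw$simulate$params
    if (!is.null(p$offsets)) p$offsets <- unlist(p$offsets)
    raw$simulate$params <- do.call(simulation_params, p)
  }
  do.call(run_config, raw)
}

# 32-bit FNV-1a over the canonical JSON of the analysis settings; small
# and dependency-free, used only to fingerprint settings in provenance.
# Path fields are excluded so the same settings hash identically
# regardless of where inputs and outputs live.
config_hash <- function(config) {
  settings <- unclass(config)
  settings[c("annotation", "footprints", "out_dir")] <- NULL
  json <- jsonlite::toJSON(settings, auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE)
  bytes <- as.integer(charToRaw(as.character(json)))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # multiply by the FNV prime mod 2^32, split to stay within double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

provenance_for <- function(config) {
  list(
    package = paste0("riboterm ", utils::packageVersion("riboterm")),
    config_hash = config_hash(config),
    min_cds_reads = config$min_cds_reads,
    read_length_range = paste0(config$min_read_length, "-", config$max_read_length),
    psite_offsets = paste(sprintf("%s:%s", names(config$offsets), config$offsets),
                          collapse = ",")
  )
}

#' Check a result file against a configuration
#'
#' Warns when the `config_hash` recorded in a `#`-prefixed provenance
#' header disagrees with the hash of `config` (the file was produced
#' under different settings).
#'
#' @param path a TSV written by [run_score()] or [run_metagene()].
#' @param config a [run_config()].
#' @return `TRUE` (hashes agree) or `FALSE` (mismatch or absent),
#'   invisibly.
#' @export
check_config_hash <- function(path, config) {
  prov <- attr(read_tsv_with_header(path), "provenance")
  ok <- !is.null(prov["config_hash"]) && !is.na(prov["config_hash"]) &&
    prov[["config_hash"]] == config_hash(config)
  if (!ok) {
    warning("provenance hash in ", path,
            " does not match the supplied configuration", call. = FALSE)
  }
  invisible(ok)
}

# shared ingest: records -> dedup -> size-select -> density tracks
condition_tracks <- function(path, models, config, condition) {
  rec <- read_footprints(path)
  dd <- deduplicate_by_umi(rec)
  fl <- filter_by_length(dd$records, config$min_read_length, config$max_read_length)
  tracks <- build_density(fl$records, models, config$offsets)
  message(sprintf(
    "[%s] %d records read, %d duplicates removed, %d outside %d-%d nt, dropped %s",
    condition, nrow(rec), dd$n_removed, fl$n_dropped,
    config$min_read_length, config$max_read_length,
    paste(sprintf("%s=%d", names(attr(tracks, "dropped")),
                  unlist(attr(tracks, "dropped"))), collapse = " ")))
  tracks
}

#' Score all conditions and run the configured comparisons
#'
#' For each condition: read footprints, deduplicate by UMI, size-select,
#' build P-site density tracks, and write a per-transcript score table.
#' Then, for each configured comparison: a two-sided Wilcoxon
#' signed-rank test on paired pause scores (transcripts eligible in both
#' arms) and a Mann-Whitney U test on RRTS values (transcripts eligible
#' per arm) with the configured alternative.
#'
#' @param config a [run_config()] with `annotation` and `footprints` set.
#' @return list with `scores` (named list of score tables),
#'   `comparisons` (data.table), `files` (paths written).
#' @export
run_score <- function(config) {
  models <- read_transcript_table(config$annotation)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenance_for(config)

  scores <- list()
  files <- character()
  for (condition in names(config$footprints)) {
    tracks <- condition_tracks(config$footprints[[condition]], models,
                               config, condition)
    tab <- score_table(tracks, models, min_cds_reads = config$min_cds_reads)
    if (!any(tab$eligible_pause | tab$eligible_rrts)) {
      stop("condition '", condition, "' has no eligible transcripts",
           call. = FALSE)
    }
    path <- file.path(config$out_dir, sprintf("scores_%s.tsv", condition))
    write_score_table(tab, path, c(prov, condition = condition))
    scores[[condition]] <- tab
    files[condition] <- path
    message(sprintf("[%s] %d transcripts scored (%d pause-eligible, %d RRTS-eligible)",
                    condition, nrow(tab), sum(tab$eligible_pause),
                    sum(tab$eligible_rrts)))
  }

  comparisons <- data.table::rbindlist(lapply(config$comparisons, function(cmp) {
    compare_conditions(scores[[cmp$reference]], scores[[cmp$treatment]],
                       cmp$reference, cmp$treatment, cmp$rrts_alternative)
  }))
  cmp_path <- NULL
  if (nrow(comparisons)) {
    cmp_path <- file.path(config$out_dir, "comparisons.tsv")
    write_tsv_with_header(comparisons, cmp_path, prov)
    files["comparisons"] <- cmp_path
  }
  list(scores = scores, comparisons = comparisons, files = files)
}

#' Compare two scored conditions
#'
#' @param reference_scores,treatment_scores [score_table()] results over
#'   the same transcriptome.
#' @param reference,treatment condition labels for the report.
#' @param rrts_alternative Mann-Whitney alternative for treatment RRTS
#'   relative to reference.
#' @return Two-row data.table: the paired pause-score signed-rank test
#'   and the RRTS Mann-Whitney test.
#' @export
compare_conditions <- function(reference_scores, treatment_scores,
                               reference, treatment,
                               rrts_alternative = "greater") {
  paired <- merge(
    reference_scores[eligible_pause == TRUE, .(transcript_id, ref = pause_score)],
    treatment_scores[eligible_pause == TRUE, .(transcript_id, trt = pause_score)],
    by = "transcript_id"
  )
  wsr <- wilcoxon_signed_rank(paired$trt, paired$ref, alternative = "two.sided")
  mwu <- mann_whitney_u(treatment_scores[eligible_rrts == TRUE, rrts],
                        reference_scores[eligible_rrts == TRUE, rrts],
                        alternative = rrts_alternative)
  data.table::data.table(
    comparison = paste0(treatment, "_vs_", reference),
    metric = c("pause_score", "rrts"),
    test = c(wsr$test_name, mwu$test_name),
    alternative = c(wsr$alternative, mwu$alternative),
    statistic = c(wsr$statistic, mwu$statistic),
    p_value = c(wsr$p_value, mwu$p_value),
    n = c(wsr$n, mwu$n),
    n2 = c(NA_integer_, mwu$n2),
    direction = c(wsr$direction, mwu$direction),
    mode = c(wsr$mode, mwu$mode)
  )
}

#' Stop-aligned metagene profile per condition
#'
#' @param config a [run_config()] with `annotation` and `footprints` set.
#' @return list with `profiles` (named list of [metagene()] tables) and
#'   `files`.
#' @export
run_metagene <- function(config) {
  models <- read_transcript_table(config$annotation)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenance_for(config)
  profiles <- list()
  files <- character()
  for (condition in names(config$footprints)) {
    tracks <- condition_tracks(config$footprints[[condition]], models,
                               config, condition)
    prof <- metagene(tracks, models,
                     window_up = config$metagene_window_up,
                     window_down = config$metagene_window_down,
                     min_cds_reads = config$min_cds_reads)
    path <- file.path(config$out_dir, sprintf("metagene_%s.tsv", condition))
    write_metagene(prof, path, c(prov, condition = condition))
    profiles[[condition]] <- prof
    files[condition] <- path
  }
  list(profiles = profiles, files = files)
}

#' Simulate an experiment described by a configuration
#'
#' Wraps [simulate_experiment()] and returns an updated configuration
#' whose `annotation` and `footprints` point at the simulated files, so
#' the result feeds [run_score()] and [run_metagene()] without edits.
#'
#' @param config a [run_config()] whose `simulate` entry holds `params`,
#'   optionally `conditions`, and `seed`.
#' @return The updated `run_config`, invisibly.
#' @export
run_simulate <- function(config) {
  sim <- config$simulate
  if (is.null(sim)) stop("config has no simulate entry", call. = FALSE)
  params <- if (inherits(sim$params, "simulation_params")) sim$params else {
    do.call(simulation_params, as.list(sim$params))
  }
  conditions <- if (is.null(sim$conditions)) default_conditions() else sim$conditions
  seed <- if (is.null(sim$seed)) 1L else as.integer(sim$seed)
  res <- simulate_experiment(params, conditions, seed = seed,
                             out_dir = config$out_dir)
  config$annotation <- res$transcript_table
  config$footprints <- as.list(res$footprints)
  invisible(config)
}
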