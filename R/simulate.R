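# Generative model of ribosome footprints around translation
# termination. Per-nucleotide P-site counts are Poisson with a
# per-transcript gamma-distributed rate (negative-binomial marginal,
# matching overdispersed ribo-seq counts); termination behavior enters
# through two multiplicative knobs: the terminal pause multiplier pi
# (expected NTC density = pi * lambda) and the readthrough fraction r
# (expected extension density = r * lambda). Footprint 5' ends are
# back-computed from the configured P-site offset table, so the
# pipeline recovers the intended P-sites exactly under the same table.

NON_STOP_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0)), c("A", "C", "G", "T"), paste0)),
  c("TAA", "TAG", "TGA")
)

# room reserved in the 3'UTR downstream of the designated second stop so
# that every footprint (<= 35 nt, P-site offset >= 12) fits in bounds
UTR3_TAIL_RESERVE <- 24L

#' Simulation parameters
#'
#' Defines one condition's generative model. Lengths are drawn uniformly
#' from the stated ranges (CDS lengths restricted to multiples of 3);
#' the per-transcript expression rate lambda is Gamma(shape, scale) in
#' expected counts per nucleotide.
#'
#' @param n_transcripts number of transcripts.
#' @param cds_length_range CDS length range in nt (multiples of 3 drawn).
#' @param utr5_length_range,utr3_length_range UTR length ranges in nt.
#' @param expression_shape,expression_scale gamma parameters of the
#'   per-transcript rate; the default mean is 2 counts per nt.
#' @param pause_multiplier expected NTC density relative to CDS density
#'   (pi >= 0); the quantity the stop-codon pause score estimates.
#' @param readthrough_fraction expected extension density relative to
#'   CDS density (r in \[0, 1\]); the quantity the RRTS estimates.
#' @param second_stop_pause pause multiplier applied (on top of r) at
#'   the second in-frame stop reached by readthrough ribosomes.
#' @param extension_fraction fraction of transcripts given an in-frame
#'   stop in the 3'UTR (the rest have none and are RRTS-ineligible).
#' @param read_lengths,read_length_probs footprint length distribution;
#'   default lengths 25-31 nt with a unimodal peak at 28.
#' @param umi_length UMI length in nt (5' 4-mer plus 3' 6-mer in the
#'   library design the default mirrors).
#' @param duplication_rate probability that a record gains one PCR
#'   duplicate (identical UMI).
#' @param offsets P-site offset table used to back-compute 5' ends.
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(n_transcripts = 2000L,
                              cds_length_range = c(300L, 900L),
                              utr5_length_range = c(15L, 60L),
                              utr3_length_range = c(120L, 300L),
                              expression_shape = 2,
                              expression_scale = 1,
                              pause_multiplier = 1,
                              readthrough_fraction = 0.005,
                              second_stop_pause = 1,
                              extension_fraction = 0.9,
                              read_lengths = 25:31,
                              read_length_probs = NULL,
                              umi_length = 10L,
                              duplication_rate = 0,
                              offsets = default_psite_offsets()) {
  if (is.null(read_length_probs)) {
    read_length_probs <- stats::dnorm(read_lengths, mean = 28, sd = 1.5)
    read_length_probs <- read_length_probs / sum(read_length_probs)
  }
  p <- list(
    n_transcripts = as.integer(n_transcripts),
    cds_length_range = as.integer(cds_length_range),
    utr5_length_range = as.integer(utr5_length_range),
    utr3_length_range = as.integer(utr3_length_range),
    expression_shape = expression_shape,
    expression_scale = expression_scale,
    pause_multiplier = pause_multiplier,
    readthrough_fraction = readthrough_fraction,
    second_stop_pause = second_stop_pause,
    extension_fraction = extension_fraction,
    read_lengths = as.integer(read_lengths),
    read_length_probs = read_length_probs,
    umi_length = as.integer(umi_length),
    duplication_rate = duplication_rate,
    offsets = offsets
  )
  stopifnot(
    p$n_transcripts >= 1,
    p$cds_length_range[1] >= 30, diff(p$cds_length_range) >= 0,
    p$utr5_length_range[1] >= max(p$offsets),
    p$utr3_length_range[1] >= UTR3_TAIL_RESERVE + 3L,
    p$expression_shape > 0, p$expression_scale > 0,
    p$pause_multiplier >= 0,
    p$readthrough_fraction >= 0, p$readthrough_fraction <= 1,
    p$second_stop_pause >= 0,
    p$extension_fraction >= 0, p$extension_fraction <= 1,
    all(as.integer(names(p$offsets)) %in% p$read_lengths),
    length(p$read_length_probs) == length(p$read_lengths),
    abs(sum(p$read_length_probs) - 1) < 1e-8,
    p$umi_length >= 1,
    p$duplication_rate >= 0, p$duplication_rate < 1
  )
  structure(p, class = "simulation_params")
}

sample_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

#' Simulate a transcriptome
#'
#' Random transcript models with (i) a guaranteed NTC as the last CDS
#' codon, (ii) for `extension_fraction` of transcripts, a second
#' in-frame stop placed uniformly within the usable 3'UTR with no
#' premature in-frame stop before it (extension codons are drawn from
#' the 61 non-stop codons, so the designated codon is provably the first
#' in-frame stop), and (iii) for the remainder, a 3'UTR with no in-frame
#' stop at all. Deterministic given `seed`.
#'
#' @param params a [simulation_params()] object.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return Named list of `transcript_model`.
#' @export
simulate_transcriptome <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_transcripts
  u5 <- sample_range(n, params$utr5_length_range)
  cds_len <- 3L * sample_range(n, round(params$cds_length_range / 3))
  u3 <- sample_range(n, params$utr3_length_range)
  has_ext <- runif(n) < params$extension_fraction
  nt <- c("A", "C", "G", "T")

  models <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("TX%05d", i)
    cds <- paste0("ATG",
                  paste(sample(NON_STOP_CODONS, cds_len[i] / 3L - 2L, replace = TRUE),
                        collapse = ""),
                  sample(STOP_CODONS, 1L))
    if (has_ext[i]) {
      max_ext <- ((u3[i] - UTR3_TAIL_RESERVE - 3L) %/% 3L) * 3L
      ext_len <- 3L * sample.int(max_ext / 3L + 1L, 1L) - 3L
      tail_len <- u3[i] - ext_len - 3L
      utr3 <- paste0(
        paste(sample(NON_STOP_CODONS, ext_len / 3L, replace = TRUE), collapse = ""),
        sample(STOP_CODONS, 1L),
        paste(sample(nt, tail_len, replace = TRUE), collapse = "")
      )
    } else {
      utr3 <- paste0(
        paste(sample(NON_STOP_CODONS, u3[i] %/% 3L, replace = TRUE), collapse = ""),
        paste(sample(nt, u3[i] %% 3L, replace = TRUE), collapse = "")
      )
    }
    seq <- paste0(paste(sample(nt, u5[i], replace = TRUE), collapse = ""), cds, utr3)
    models[[i]] <- transcript_model(id, u5[i], u5[i] + cds_len[i], seq)
  }
  names(models) <- vapply(models, `[[`, "", "transcript_id")
  models
}

random_umis <- function(n, umi_length) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * umi_length, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate footprint records for one condition
#'
#' Per-nucleotide P-site counts are Poisson(lambda_t * m(p)) with
#' m = 1 across the CDS, `pause_multiplier` at the 3 NTC positions,
#' `readthrough_fraction` over the extension,
#' `second_stop_pause * readthrough_fraction` at the second stop, and 0
#' elsewhere (5'UTR and beyond the second stop). Each count becomes one
#' footprint record: a read length is drawn from the configured
#' distribution and the 5' end back-computed from the offset table, so
#' P-site assignment under that table recovers the generating position
#' exactly. UMIs are random and unique within each
#' (transcript, 5' position, length) group; PCR duplicates are then
#' injected at `duplication_rate` with identical UMIs, so UMI
#' deduplication removes exactly the injected duplicates.
#'
#' @param models transcriptome from [simulate_transcriptome()].
#' @param params a [simulation_params()] object.
#' @param seed integer seed, or `NULL`.
#' @return data.table of footprint records (columns `transcript_id`,
#'   `five_prime_pos`, `read_length`, `umi`) with attribute
#'   `n_duplicates_injected`.
#' @export
simulate_footprints <- function(models, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(models)
  lambda <- rgamma(n, shape = params$expression_shape,
                   scale = params$expression_scale)
  pi_ <- params$pause_multiplier
  r <- params$readthrough_fraction
  pi2 <- params$second_stop_pause

  tx_ids <- character(0)
  psites <- vector("list", n)
  for (i in seq_len(n)) {
    tm <- models[[i]]
    nss <- find_next_inframe_stop(tm)
    pos <- tm$cds_start:(tm$cds_end - 1L)
    mu <- rep(lambda[i], length(pos))
    mu[(length(mu) - 2L):length(mu)] <- lambda[i] * pi_
    if (!is.na(nss)) {
      ext_pos <- if (nss > tm$cds_end) tm$cds_end:(nss - 1L) else integer()
      pos <- c(pos, ext_pos, nss:(nss + 2L))
      mu <- c(mu, rep(lambda[i] * r, length(ext_pos)),
              rep(lambda[i] * r * pi2, 3L))
    }
    counts <- rpois(length(mu), mu)
    psites[[i]] <- rep.int(pos, counts)
  }
  n_per_tx <- lengths(psites)
  rec <- data.table::data.table(
    transcript_id = rep.int(vapply(models, `[[`, "", "transcript_id"), n_per_tx),
    psite = unlist(psites, use.names = FALSE)
  )
  rec[, read_length := sample(params$read_lengths, .N, replace = TRUE,
                              prob = params$read_length_probs)]
  rec[, five_prime_pos := psite - as.integer(params$offsets[as.character(read_length)])]
  tx_len <- vapply(models, `[[`, 0L, "length")
  stopifnot(all(rec$five_prime_pos >= 0),
            all(rec$five_prime_pos + rec$read_length <= tx_len[rec$transcript_id]))
  rec[, psite := NULL]

  # fresh UMIs, re-drawn until unique within each duplicate-defining key
  rec[, umi := random_umis(.N, params$umi_length)]
  repeat {
    dup <- duplicated(rec, by = c("transcript_id", "five_prime_pos",
                                  "read_length", "umi"))
    if (!any(dup)) break
    rec[dup, umi := random_umis(sum(dup), params$umi_length)]
  }

  n_dup <- 0L
  if (params$duplication_rate > 0) {
    dup_rows <- which(runif(nrow(rec)) < params$duplication_rate)
    n_dup <- length(dup_rows)
    if (n_dup) rec <- rbind(rec, rec[dup_rows])
  }
  data.table::setorder(rec, transcript_id, five_prime_pos, read_length, umi)
  data.table::setcolorder(rec, c("transcript_id", "five_prime_pos",
                                 "read_length", "umi"))
  data.table::setattr(rec, "n_duplicates_injected", n_dup)
  rec[]
}

#' Condition specification
#'
#' Overrides of the termination knobs relative to a base parameter set,
#' modeling one treatment arm (e.g. a vehicle-, aminoglycoside- or
#' terminal-pause-inducer-like condition).
#'
#' @param name condition label.
#' @param pause_multiplier,readthrough_fraction,second_stop_pause
#'   optional overrides.
#' @return list of class `condition_spec`.
#' @export
condition_spec <- function(name, pause_multiplier = NULL,
                           readthrough_fraction = NULL,
                           second_stop_pause = NULL) {
  structure(
    list(name = as.character(name),
         pause_multiplier = pause_multiplier,
         readthrough_fraction = readthrough_fraction,
         second_stop_pause = second_stop_pause),
    class = "condition_spec"
  )
}

#' Default three-arm design
#'
#' A vehicle-like arm (no terminal effect, basal readthrough), an
#' aminoglycoside-like arm (reduced terminal pause, elevated
#' readthrough) and a pause-inducer-like arm (strong terminal pause,
#' basal readthrough).
#'
#' @return list of three [condition_spec()] objects.
#' @export
default_conditions <- function() {
  list(
    condition_spec("DMSO", pause_multiplier = 1, readthrough_fraction = 0.005),
    condition_spec("G418", pause_multiplier = 0.5, readthrough_fraction = 0.08),
    condition_spec("SRI", pause_multiplier = 3, readthrough_fraction = 0.005)
  )
}

apply_condition <- function(params, spec) {
  for (field in c("pause_multiplier", "readthrough_fraction", "second_stop_pause")) {
    if (!is.null(spec[[field]])) params[[field]] <- spec[[field]]
  }
  do.call(simulation_params, unclass(params))
}

#' Simulate a multi-condition experiment to disk
#'
#' One shared transcriptome (so per-transcript scores are paired across
#' arms, as a signed-rank contrast requires) with independent count
#' noise per condition. Writes the transcript table, one footprint TSV
#' per condition, and a manifest JSON recording all parameters and
#' seeds.
#'
#' @param params base [simulation_params()].
#' @param conditions list of [condition_spec()]; default the three-arm
#'   design of [default_conditions()].
#' @param seed integer seed; the transcriptome uses `seed`, condition
#'   arms use `seed + 1, seed + 2, ...`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, list with `models`, `transcript_table`,
#'   `footprints` (named paths), `manifest` (path).
#' @export
simulate_experiment <- function(params, conditions = default_conditions(),
                                seed = 1L, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- simulate_transcriptome(params, seed = seed)
  tx_path <- file.path(out_dir, "transcripts.tsv")
  write_transcript_table(models, tx_path)

  cond_names <- vapply(conditions, `[[`, "", "name")
  cond_seeds <- seed + seq_along(conditions)
  fp_paths <- stats::setNames(
    file.path(out_dir, sprintf("footprints_%s.tsv", cond_names)), cond_names)
  for (i in seq_along(conditions)) {
    cp <- apply_condition(params, conditions[[i]])
    rec <- simulate_footprints(models, cp, seed = cond_seeds[i])
    write_footprints(rec, fp_paths[i])
  }
  params_json <- unclass(params)
  params_json$offsets <- as.list(params_json$offsets)  # keep length names in JSON
  manifest <- list(
    generator = "riboterm::simulate_experiment",
    version = as.character(utils::packageVersion("riboterm")),
    seed = seed,
    condition_seeds = stats::setNames(as.list(cond_seeds), cond_names),
    params = params_json,
    conditions = lapply(conditions, unclass),
    files = list(transcripts = basename(tx_path),
                 footprints = as.list(stats::setNames(basename(fp_paths), cond_names)))
  )
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(models = models, transcript_table = tx_path,
                 footprints = fp_paths, manifest = man_path))
}

#' Read an experiment manifest
#'
#' Reconstructs the base [simulation_params()] and condition specs from
#' a manifest written by [simulate_experiment()].
#'
#' @param path manifest JSON path.
#' @return list with `params`, `conditions`, `seed`, `condition_seeds`,
#'   `files`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- m$params
  p$offsets <- unlist(p$offsets)
  params <- do.call(simulation_params, p)
  conds <- lapply(seq_len(nrow(m$conditions)), function(i) {
    row <- m$conditions[i, ]
    condition_spec(row$name,
                   pause_multiplier = row$pause_multiplier,
                   readthrough_fraction = row$readthrough_fraction,
                   second_stop_pause = row$second_stop_pause)
  })
  list(params = params, conditions = conds, seed = m$seed,
       condition_seeds = unlist(m$condition_seeds), files = m$files)
}
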