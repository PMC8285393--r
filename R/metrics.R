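# Termination metrics. All three statistics are ratios of mean
# per-nucleotide P-site densities over regions of one transcript, so they
# are invariant to sequencing depth on that transcript.

#' Mean P-site density over a transcript interval
#'
#' Sum of P-site counts over a 0-based half-open interval divided by its
#' length. A zero-length interval has density 0 by convention (it
#' contributes an empty numerator, not a division by zero).
#'
#' @param track a `density_track` from [build_density()].
#' @param interval `c(start, end)`, 0-based half-open.
#' @return Numeric density in counts per nucleotide.
#' @export
region_density <- function(track, interval) {
  s <- interval[1]; e <- interval[2]
  if (s < 0 || e > length(track$counts) || s > e) {
    stop("interval [", s, ", ", e, ") outside track for ",
         track$transcript_id, " (length ", length(track$counts), ")",
         call. = FALSE)
  }
  if (e == s) return(0)
  sum(track$counts[(s + 1L):e]) / (e - s)
}

#' Score one transcript: CDS density, pause score, RRTS
#'
#' The stop-codon pause score is the ratio of the mean P-site density
#' over the 3 nt of the normal termination codon (NTC) to the mean
#' density over the CDS body (the CDS excluding its first 15 and last 12
#' nucleotides). The Ribosome ReadThrough Score (RRTS) is the mean
#' density over the readthrough-extension region (NTC to first
#' downstream in-frame stop) divided by the mean density over the full
#' CDS. A score is reported only when its transcript is eligible:
#' ineligibility (too few CDS reads, zero denominator, no in-frame
#' downstream stop, CDS too short for a body) is recorded with a reason
#' code, never an error, and the densities themselves are always
#' reported.
#'
#' @param track a `density_track`.
#' @param tm the matching `transcript_model`.
#' @param regions optional precomputed [derive_regions()] result.
#' @param min_cds_reads minimum P-site count in the CDS for a transcript
#'   to enter either score (default 32; ratio estimates from fewer reads
#'   are unstable).
#' @return One-row data.table with fields `transcript_id`,
#'   `n_cds_reads`, `cds_density`, `cds_body_density`, `stop_density`,
#'   `extension_density`, `pause_score`, `rrts`, `eligible_pause`,
#'   `eligible_rrts`, `reason_pause`, `reason_rrts`.
#' @export
score_transcript <- function(track, tm, regions = derive_regions(tm),
                             min_cds_reads = 32L) {
  if (track$transcript_id != tm$transcript_id) {
    stop("track and model refer to different transcripts", call. = FALSE)
  }
  cds_density <- region_density(track, regions$cds)
  n_cds_reads <- as.integer(round(cds_density * (regions$cds[2] - regions$cds[1])))
  stop_density <- region_density(track, regions$stop_codon)
  body_density <- if (regions$pause_eligible_region) {
    region_density(track, regions$cds_body)
  } else NA_real_
  ext_density <- if (!is.null(regions$extension)) {
    region_density(track, regions$extension)
  } else NA_real_

  reason_pause <- ""
  if (!regions$pause_eligible_region) {
    reason_pause <- "short_cds"
  } else if (n_cds_reads < min_cds_reads) {
    reason_pause <- "low_cds_reads"
  } else if (body_density == 0) {
    reason_pause <- "zero_body_density"
  }
  eligible_pause <- reason_pause == ""

  reason_rrts <- ""
  if (is.null(regions$extension)) {
    reason_rrts <- "no_inframe_stop"
  } else if (n_cds_reads < min_cds_reads) {
    reason_rrts <- "low_cds_reads"
  } else if (cds_density == 0) {
    reason_rrts <- "zero_cds_density"
  }
  eligible_rrts <- reason_rrts == ""

  data.table::data.table(
    transcript_id = tm$transcript_id,
    n_cds_reads = n_cds_reads,
    cds_density = cds_density,
    cds_body_density = body_density,
    stop_density = stop_density,
    extension_density = ext_density,
    pause_score = if (eligible_pause) stop_density / body_density else NA_real_,
    rrts = if (eligible_rrts) ext_density / cds_density else NA_real_,
    eligible_pause = eligible_pause,
    eligible_rrts = eligible_rrts,
    reason_pause = reason_pause,
    reason_rrts = reason_rrts
  )
}

#' Score every transcript of one condition
#'
#' Applies [score_transcript()] over all models, in deterministic
#' (sorted transcript_id) row order.
#'
#' @param tracks named list of density tracks.
#' @param models named list of `transcript_model`.
#' @param min_cds_reads eligibility threshold, see [score_transcript()].
#' @return data.table (one row per model, sorted by transcript_id) with
#'   attribute `ineligible`: named counts of rows excluded from each
#'   score by reason.
#' @export
score_table <- function(tracks, models, min_cds_reads = 32L) {
  ids <- sort(vapply(models, `[[`, "", "transcript_id"))
  rows <- lapply(ids, function(id) {
    score_transcript(tracks[[id]], models[[id]], min_cds_reads = min_cds_reads)
  })
  tab <- data.table::rbindlist(rows)
  ineligible <- list(
    pause = table(tab$reason_pause[tab$reason_pause != ""]),
    rrts = table(tab$reason_rrts[tab$reason_rrts != ""])
  )
  data.table::setattr(tab, "ineligible", ineligible)
  data.table::setattr(tab, "min_cds_reads", as.integer(min_cds_reads))
  tab[]
}

#' Stop-aligned metagene profile
#'
#' Aligns all eligible transcripts at the first nucleotide of the NTC
#' (position 0) and averages their depth-normalized P-site densities
#' position-wise. Each transcript's track is divided by its own mean CDS
#' density, so a transcript with uniform density contributes exactly 1
#' at every position and every transcript carries equal weight
#' regardless of expression. Transcripts with zero CDS density or fewer
#' than `min_cds_reads` CDS reads are excluded; transcripts shorter than
#' the window contribute only to the positions they cover, tracked in
#' `n_transcripts`.
#'
#' @param tracks named list of density tracks.
#' @param models named list of `transcript_model`.
#' @param window_up,window_down window half-widths in nucleotides
#'   (positions `-window_up .. +window_down` relative to the NTC).
#' @param min_cds_reads eligibility threshold.
#' @return data.table with columns `position`, `mean_density`,
#'   `n_transcripts`.
#' @export
metagene <- function(tracks, models, window_up = 100L, window_down = 100L,
                     min_cds_reads = 32L) {
  offsets <- seq.int(-window_up, window_down)
  acc <- numeric(length(offsets))
  n <- integer(length(offsets))
  n_used <- 0L
  for (tm in models) {
    track <- tracks[[tm$transcript_id]]
    cds <- c(tm$cds_start, tm$cds_end)
    cds_density <- region_density(track, cds)
    n_cds_reads <- round(cds_density * (cds[2] - cds[1]))
    if (cds_density == 0 || n_cds_reads < min_cds_reads) next
    n_used <- n_used + 1L
    anchor <- tm$cds_end - 3L            # transcript coordinate of position 0
    pos <- anchor + offsets              # 0-based transcript coordinates
    covered <- pos >= 0L & pos < tm$length
    acc[covered] <- acc[covered] + track$counts[pos[covered] + 1L] / cds_density
    n[covered] <- n[covered] + 1L
  }
  if (n_used == 0L) stop("empty metagene: no eligible transcripts", call. = FALSE)
  data.table::data.table(
    position = offsets,
    mean_density = ifelse(n > 0L, acc / pmax(n, 1L), NA_real_),
    n_transcripts = n
  )
}

#' Write a score table as TSV with a provenance header
#'
#' @param tab a [score_table()] result.
#' @param path output path.
#' @param provenance named list written as `# key=value` header lines.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(tab, path, provenance = list()) {
  write_tsv_with_header(tab, path, provenance)
}

#' Write a metagene profile as TSV with a provenance header
#' @inheritParams write_score_table
#' @param profile a [metagene()] result.
#' @export
write_metagene <- function(profile, path, provenance = list()) {
  write_tsv_with_header(profile, path, provenance)
}

write_tsv_with_header <- function(tab, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(provenance)) {
    writeLines(sprintf("# %s=%s", key, format(provenance[[key]])), con)
  }
  lines <- c(paste(names(tab), collapse = "\t"),
             do.call(paste, c(lapply(tab, format_tsv_col), sep = "\t")))
  writeLines(lines, con)
  invisible(path)
}

format_tsv_col <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    out <- formatC(x, digits = 15, format = "g")
    out[is.na(x)] <- "NA"
    out
  } else {
    as.character(x)
  }
}

#' Read a TSV written with a provenance header
#' @param path file path.
#' @return data.table; `#`-prefixed header lines are returned in the
#'   `provenance` attribute as a named character vector.
#' @export
read_tsv_with_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  prov <- character()
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", lines[hdr])
    prov <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  }
  tab <- data.table::fread(text = lines[setdiff(seq_along(lines), hdr)], sep = "\t")
  data.table::setattr(tab, "provenance", prov)
  tab[]
}
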