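# Footprint records are data.tables with columns
# transcript_id (chr), five_prime_pos (int, 0-based), read_length (int),
# umi (chr; "" when the library carried no UMI).

#' Read footprint records from TSV
#'
#' The footprint TSV has header
#' `transcript_id, five_prime_pos, read_length, umi`, one aligned
#' ribosome-protected fragment per row, 5' end in 0-based transcript
#' coordinates. The `umi` column concatenates the 5' four-nt and 3'
#' six-nt unique molecular identifiers when present.
#'
#' @param path TSV path (may carry `#`-prefixed provenance header lines).
#' @return data.table of footprint records.
#' @export
read_footprints <- function(path) {
  rec <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c("transcript_id", "umi")))
  required <- c("transcript_id", "five_prime_pos", "read_length", "umi")
  missing <- setdiff(required, names(rec))
  if (length(missing)) {
    stop("footprint file ", path, " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rec[, umi := ifelse(is.na(umi), "", umi)]
  rec[]
}

#' Write footprint records to TSV
#' @param records footprint data.table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_footprints <- function(records, path) {
  data.table::fwrite(records, path, sep = "\t")
  invisible(path)
}

#' Collapse PCR duplicates by unique molecular identifier
#'
#' Retains exactly one record per unique
#' (transcript_id, five_prime_pos, read_length, umi) key: two reads that
#' agree in all four fields are PCR copies of one ribosome-protected
#' fragment. Records with an empty `umi` are all retained (no molecular
#' identity to collapse on). Output order is deterministic (sorted by
#' key), so the operation is order-independent and idempotent.
#'
#' @param records footprint data.table.
#' @return list with `records` (deduplicated, key-sorted data.table) and
#'   `n_removed` (number of duplicate rows dropped).
#' @export
deduplicate_by_umi <- function(records) {
  rec <- data.table::as.data.table(records)
  n_in <- nrow(rec)
  has_umi <- rec$umi != ""
  kept <- rbind(
    unique(rec[has_umi],
           by = c("transcript_id", "five_prime_pos", "read_length", "umi")),
    rec[!has_umi]
  )
  data.table::setorder(kept, transcript_id, five_prime_pos, read_length, umi)
  list(records = kept[], n_removed = n_in - nrow(kept))
}

#' Size-select footprints by read length
#'
#' Keeps fragments with `min_len <= read_length <= max_len` (closed
#' interval on both ends). Defaults mirror the 15-35 nt gel
#' size-selection window of a standard ribosome-profiling library.
#'
#' @param records footprint data.table.
#' @param min_len,max_len inclusive bounds in nucleotides.
#' @return list with `records` (kept rows) and `n_dropped`.
#' @export
filter_by_length <- function(records, min_len = 15L, max_len = 35L) {
  stopifnot(min_len <= max_len)
  rec <- data.table::as.data.table(records)
  keep <- rec$read_length >= min_len & rec$read_length <= max_len
  list(records = rec[keep], n_dropped = sum(!keep))
}

#' Default P-site offset table
#'
#' Maps read length to the number of nucleotides added to the fragment's
#' 5' end to obtain the first nucleotide of the P-site codon. The default
#' assigns the conventional mammalian +12 nt offset to 25-31 nt
#' footprints and drops all other lengths (a length with no offset has no
#' confident P-site).
#'
#' @param lengths read lengths covered by the table.
#' @param offset offset applied to each covered length.
#' @return Named integer vector: names are read lengths, values offsets.
#' @export
default_psite_offsets <- function(lengths = 25:31, offset = 12L) {
  stats::setNames(rep(as.integer(offset), length(lengths)), lengths)
}

#' Assign P-site coordinates to footprints
#'
#' Adds a `psite` column: `five_prime_pos + offset(read_length)`.
#' Records whose length is absent from the offset table, whose
#' transcript is unknown, or whose P-site falls outside the transcript
#' are dropped and tallied.
#'
#' @param records footprint data.table.
#' @param offsets named integer vector as [default_psite_offsets()].
#' @param models named list of `transcript_model` (for bounds checks).
#' @return list with `records` (with `psite` column), and drop counts
#'   `n_no_offset`, `n_unknown_transcript`, `n_out_of_bounds`.
#' @export
assign_psite <- function(records, offsets = default_psite_offsets(), models) {
  rec <- data.table::as.data.table(records)
  off <- offsets[as.character(rec$read_length)]
  no_offset <- is.na(off)
  tx_len <- vapply(models, `[[`, 0L, "length")
  len <- tx_len[rec$transcript_id]
  unknown <- is.na(len)
  psite <- rec$five_prime_pos + as.integer(off)
  oob <- !no_offset & !unknown & (psite < 0L | psite >= len)
  keep <- !no_offset & !unknown & !oob
  rec <- rec[keep]
  rec[, psite := psite[keep]]
  list(records = rec[],
       n_no_offset = sum(no_offset),
       n_unknown_transcript = sum(unknown & !no_offset),
       n_out_of_bounds = sum(oob))
}

#' Build per-nucleotide P-site density tracks
#'
#' Runs P-site assignment and tallies retained records into one integer
#' count vector per transcript (a zero track is emitted for models with
#' no records). Totals over all tracks equal the number of records
#' surviving offset assignment and bounds checks — the density unit is
#' raw P-site counts; all normalization happens downstream in the
#' metrics.
#'
#' @param records footprint data.table (already deduplicated and
#'   size-selected; this function does neither).
#' @param models named list of `transcript_model`.
#' @param offsets P-site offset table.
#' @return Named list of density tracks, one per model: each a list with
#'   `transcript_id`, `counts` (integer vector of transcript length,
#'   position `p` stored at index `p + 1`), `total`. Attribute `dropped`
#'   carries the assign_psite drop counts.
#' @export
build_density <- function(records, models, offsets = default_psite_offsets()) {
  asg <- assign_psite(records, offsets, models)
  rec <- asg$records
  tally <- rec[, .N, by = .(transcript_id, psite)]
  tracks <- lapply(models, function(tm) {
    counts <- integer(tm$length)
    sub <- tally[transcript_id == tm$transcript_id]
    if (nrow(sub)) counts[sub$psite + 1L] <- sub$N
    structure(list(transcript_id = tm$transcript_id,
                   counts = counts,
                   total = sum(counts)),
              class = "density_track")
  })
  names(tracks) <- vapply(models, `[[`, "", "transcript_id")
  attr(tracks, "dropped") <- asg[c("n_no_offset", "n_unknown_transcript", "n_out_of_bounds")]
  tracks
}

#' Read transcriptome-aligned footprints from BAM
#'
#' Interface for libraries aligned directly to a transcript FASTA: the
#' reference name is taken as the transcript_id, the leftmost aligned
#' position (0-based) as the fragment 5' end, and the UMI is parsed from
#' the read name after the last `_` (empty when absent). Reads with
#' indels or clipping (CIGAR other than a single match run) and
#' secondary/supplementary alignments are dropped with counts. Requires
#' the Rsamtools package.
#'
#' @param path BAM path.
#' @return list with `records` and drop counts `n_nonprimary`,
#'   `n_complex_cigar`.
#' @export
read_footprints_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("read_footprints_bam requires the Rsamtools package", call. = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  nonprimary <- bitwAnd(b$flag, 256L) > 0L | bitwAnd(b$flag, 2048L) > 0L
  simple <- grepl("^[0-9]+M$", b$cigar)
  keep <- !nonprimary & simple
  umi <- sub("^.*_", "", b$qname[keep])
  umi[umi == b$qname[keep]] <- ""
  rec <- data.table::data.table(
    transcript_id = as.character(b$rname[keep]),
    five_prime_pos = b$pos[keep] - 1L,
    read_length = as.integer(sub("M$", "", b$cigar[keep])),
    umi = umi
  )
  list(records = rec[],
       n_nonprimary = sum(nonprimary),
       n_complex_cigar = sum(!simple & !nonprimary))
}
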