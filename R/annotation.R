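# All transcript coordinates in this package are 0-based, half-open,
# transcript-space, running 5'->3'. Strand is resolved when models are
# loaded and never reappears downstream.

STOP_CODONS <- c("TAA", "TAG", "TGA")

normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Construct a transcript model
#'
#' A transcript model is the coordinate frame every termination metric is
#' computed in: the full transcript sequence plus the CDS interval in
#' 0-based half-open transcript coordinates. The CDS interval includes the
#' normal termination codon (NTC), which occupies
#' `[cds_end - 3, cds_end)`.
#'
#' @param transcript_id character scalar.
#' @param cds_start 0-based coordinate of the first nt of the start codon.
#' @param cds_end 0-based exclusive end of the CDS; the NTC is the last
#'   codon of the CDS.
#' @param sequence transcript sequence, RNA or DNA alphabet (U and T are
#'   treated as equivalent; stored as DNA).
#' @return An object of class `transcript_model`: a list with fields
#'   `transcript_id`, `length`, `cds_start`, `cds_end`, `sequence`.
#' @export
transcript_model <- function(transcript_id, cds_start, cds_end, sequence) {
  sequence <- normalize_seq(sequence)
  tm <- structure(
    list(
      transcript_id = as.character(transcript_id),
      length = nchar(sequence),
      cds_start = as.integer(cds_start),
      cds_end = as.integer(cds_end),
      sequence = sequence
    ),
    class = "transcript_model"
  )
  problems <- validate_transcript_model(tm)
  if (length(problems)) {
    stop("invalid transcript model '", transcript_id, "': ",
         paste(problems, collapse = "; "), call. = FALSE)
  }
  tm
}

#' Validate a transcript model
#'
#' Checks the structural invariants: CDS within bounds, CDS length a
#' multiple of 3 and at least 18 nt, and the last CDS codon a stop codon.
#'
#' @param tm a `transcript_model` (or a bare list with the same fields).
#' @return Character vector of violations; empty when the model is valid.
#' @export
validate_transcript_model <- function(tm) {
  problems <- character()
  if (!(tm$cds_start >= 0 && tm$cds_start < tm$cds_end && tm$cds_end <= tm$length)) {
    problems <- c(problems, "CDS interval out of bounds")
  }
  cds_len <- tm$cds_end - tm$cds_start
  if (cds_len %% 3L != 0L) problems <- c(problems, "CDS length not a multiple of 3")
  if (cds_len < 18L) problems <- c(problems, "CDS shorter than 18 nt")
  if (nchar(tm$sequence) != tm$length) {
    problems <- c(problems, "sequence length disagrees with length field")
    return(problems)
  }
  if (tm$cds_end >= 3L && tm$cds_end <= tm$length) {
    ntc <- substr(tm$sequence, tm$cds_end - 2L, tm$cds_end)
    if (!ntc %in% STOP_CODONS) problems <- c(problems, "CDS does not end in a stop codon")
  }
  problems
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s: %d nt, CDS [%d, %d)\n",
              x$transcript_id, x$length, x$cds_start, x$cds_end))
  invisible(x)
}

#' Find the first in-frame stop codon downstream of the NTC
#'
#' Scans codons starting at `cds_end` in steps of 3 (the CDS reading
#' frame) and returns the 0-based transcript coordinate of the first nt of
#' the first stop codon (UAA/UAG/UGA) fully contained in the transcript.
#' A readthrough ribosome that decodes the NTC elongates until this codon,
#' so the interval `[cds_end, next_stop)` is the readthrough-extension
#' region scored by the RRTS.
#'
#' @param tm a `transcript_model`.
#' @return Integer coordinate, or `NA_integer_` when no in-frame stop
#'   exists before the 3' end (a valid outcome: such transcripts are
#'   RRTS-ineligible but keep their pause score).
#' @export
find_next_inframe_stop <- function(tm) {
  pos <- tm$cds_end
  while (pos + 3L <= tm$length) {
    codon <- substr(tm$sequence, pos + 1L, pos + 3L)
    if (codon %in% STOP_CODONS) return(as.integer(pos))
    pos <- pos + 3L
  }
  NA_integer_
}

#' Derive the four analysis regions of a transcript
#'
#' Every termination metric is defined on one of four intervals (0-based,
#' half-open):
#' * `cds` — `[cds_start, cds_end)`, the full coding sequence including
#'   the NTC; denominator of the RRTS.
#' * `cds_body` — `[cds_start + 15, cds_end - 12)`, the CDS excluding its
#'   first 15 and last 12 nucleotides; denominator of the pause score.
#' * `stop_codon` — `[cds_end - 3, cds_end)`, the NTC.
#' * `extension` — `[cds_end, next_stop)`, the readthrough-extension
#'   region, present only when an in-frame downstream stop exists; may be
#'   empty (immediate in-frame stop), which yields RRTS 0 by convention.
#'
#' @param tm a `transcript_model`.
#' @return An object of class `region_set`: list with `cds`, `cds_body`,
#'   `stop_codon`, `extension` (each `c(start, end)` or `NULL`),
#'   `next_stop_start` (integer or `NA`) and `pause_eligible_region`
#'   (`FALSE` when the CDS is shorter than 30 nt so the body would be
#'   empty).
#' @export
derive_regions <- function(tm) {
  cds <- c(tm$cds_start, tm$cds_end)
  body <- c(tm$cds_start + 15L, tm$cds_end - 12L)
  pause_ok <- body[2] > body[1]
  nss <- find_next_inframe_stop(tm)
  extension <- if (!is.na(nss)) c(tm$cds_end, nss) else NULL
  structure(
    list(
      cds = as.integer(cds),
      cds_body = if (pause_ok) as.integer(body) else NULL,
      stop_codon = c(tm$cds_end - 3L, tm$cds_end),
      extension = if (!is.null(extension)) as.integer(extension) else NULL,
      next_stop_start = nss,
      pause_eligible_region = pause_ok
    ),
    class = "region_set"
  )
}

#' Read transcript models from a simplified transcript table
#'
#' The transcript table is a TSV with header
#' `transcript_id, length, cds_start, cds_end, sequence` and one row per
#' transcript, coordinates 0-based half-open. Rows violating the model
#' invariants are dropped and tallied in the load report.
#'
#' @param path path to the TSV.
#' @return Named list of `transcript_model` objects, with attribute
#'   `load_report`: list with `n_loaded`, `n_dropped`, `dropped` (named
#'   character vector of reasons).
#' @export
read_transcript_table <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c("transcript_id", "sequence")))
  required <- c("transcript_id", "length", "cds_start", "cds_end", "sequence")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("transcript table ", path, " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$transcript_id)) {
    stop("duplicate transcript_id in ", path, call. = FALSE)
  }
  models <- list()
  dropped <- character()
  for (i in seq_len(nrow(tab))) {
    tm <- tryCatch(
      transcript_model(tab$transcript_id[i], tab$cds_start[i], tab$cds_end[i],
                       tab$sequence[i]),
      error = function(e) conditionMessage(e)
    )
    if (is.character(tm)) {
      dropped[tab$transcript_id[i]] <- tm
      next
    }
    if (tm$length != tab$length[i]) {
      dropped[tab$transcript_id[i]] <- "stated length disagrees with sequence"
      next
    }
    models[[tm$transcript_id]] <- tm
  }
  structure(models,
            load_report = list(n_loaded = length(models),
                               n_dropped = length(dropped),
                               dropped = dropped))
}

#' Write transcript models to the simplified transcript-table format
#'
#' @param models named list of `transcript_model`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_transcript_table <- function(models, path) {
  tab <- data.table::data.table(
    transcript_id = vapply(models, `[[`, "", "transcript_id"),
    length = vapply(models, `[[`, 0L, "length"),
    cds_start = vapply(models, `[[`, 0L, "cds_start"),
    cds_end = vapply(models, `[[`, 0L, "cds_end"),
    sequence = vapply(models, `[[`, "", "sequence")
  )
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' Load transcript models from GTF + FASTA
#'
#' Flattens stranded, exon-split genomic annotation into contiguous
#' transcript coordinates: exons are concatenated 5'->3' (minus-strand
#' transcripts reverse-complemented) and the CDS span is mapped into the
#' resulting frame. A `stop_codon` feature, when annotated separately from
#' the CDS (the GENCODE convention), is merged into the CDS so that the
#' NTC is the last CDS codon. Transcripts violating the model invariants
#' (no terminal stop codon, CDS not a multiple of 3, CDS < 18 nt) are
#' dropped and tallied in the load report.
#'
#' @param gtf path to a GTF/GFF file with exon and CDS features carrying a
#'   `transcript_id` attribute.
#' @param fasta path to a FASTA file.
#' @param fasta_type `"genome"` (sequences named by chromosome; exon
#'   sequences are extracted and spliced) or `"transcript"` (sequences
#'   named by transcript_id, already spliced 5'->3').
#' @return Named list of `transcript_model` with a `load_report`
#'   attribute, as [read_transcript_table()].
#' @export
load_transcript_models <- function(gtf, fasta, fasta_type = c("genome", "transcript")) {
  fasta_type <- match.arg(fasta_type)
  gr <- rtracklayer::import(gtf)
  if (!"transcript_id" %in% names(S4Vectors::mcols(gr))) {
    stop("GTF ", gtf, " has no transcript_id attribute", call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  type <- as.character(gr$type)
  exons <- gr[type == "exon"]
  cds <- gr[type %in% c("CDS", "stop_codon")]
  tx_ids <- unique(as.character(exons$transcript_id))

  models <- list()
  dropped <- character()
  for (tx in tx_ids) {
    res <- tryCatch(
      flatten_transcript(tx, exons[exons$transcript_id == tx],
                         cds[cds$transcript_id == tx], seqs, fasta_type),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      dropped[tx] <- res
      next
    }
    models[[tx]] <- res
  }
  structure(models,
            load_report = list(n_loaded = length(models),
                               n_dropped = length(dropped),
                               dropped = dropped))
}

# Map one transcript's genomic exon/CDS ranges into transcript space.
flatten_transcript <- function(tx, ex, cd, seqs, fasta_type) {
  if (length(ex) == 0L) stop("no exons")
  if (length(cd) == 0L) stop("no CDS")
  strand <- unique(as.character(GenomicRanges::strand(ex)))
  if (length(strand) != 1L || !strand %in% c("+", "-")) {
    stop("exons not on a single stranded contig")
  }
  chrom <- unique(as.character(GenomicRanges::seqnames(ex)))
  if (length(chrom) != 1L) stop("exons span multiple contigs")

  # exons ordered 5'->3' along the transcript
  ord <- order(GenomicRanges::start(ex), decreasing = (strand == "-"))
  ex <- ex[ord]
  widths <- GenomicRanges::width(ex)
  offsets <- cumsum(c(0L, widths[-length(widths)]))  # transcript offset of each exon

  if (fasta_type == "transcript") {
    if (!tx %in% names(seqs)) stop("missing sequence")
    seq <- as.character(seqs[[tx]])
    if (nchar(seq) != sum(widths)) stop("transcript sequence length disagrees with exons")
  } else {
    if (!chrom %in% names(seqs)) stop("missing sequence")
    pieces <- Biostrings::DNAStringSet(seqs[[chrom]],
                                       start = GenomicRanges::start(ex),
                                       end = GenomicRanges::end(ex))
    if (strand == "-") pieces <- Biostrings::reverseComplement(pieces)
    seq <- paste(as.character(pieces), collapse = "")
  }

  # genomic position -> transcript coordinate (0-based)
  g2t <- function(gpos) {
    for (i in seq_along(ex)) {
      s <- GenomicRanges::start(ex)[i]; e <- GenomicRanges::end(ex)[i]
      if (gpos >= s && gpos <= e) {
        within <- if (strand == "+") gpos - s else e - gpos
        return(offsets[i] + within)
      }
    }
    stop("CDS coordinate outside exons")
  }
  # CDS (with any stop_codon feature merged) as transcript interval
  tpos <- unlist(lapply(seq_along(cd), function(i) {
    c(g2t(GenomicRanges::start(cd)[i]), g2t(GenomicRanges::end(cd)[i]))
  }))
  cds_start <- min(tpos)
  cds_end <- max(tpos) + 1L
  transcript_model(tx, cds_start, cds_end, seq)
}
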