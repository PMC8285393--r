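# Fixtures and independent oracles shared across the suite. Everything
# here is deliberately naive (explicit loops, hand arithmetic) so it
# stays independent of the package's vectorized implementations.

# hand-rolled reverse complement, independent of Biostrings
revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

# a 36-nt toy transcript: 3-nt 5'UTR, 24-nt CDS ending TAA, 9-nt 3'UTR
# whose first in-frame downstream stop (TGA) starts at position 30
toy_sequence <- function() {
  paste0("GCA", "ATGGCTGATAAACCCGGGTTCTAA", "AAATGAGGG")
}

toy_model <- function(id = "toy1") {
  transcript_model(id, 3L, 27L, toy_sequence())
}

# the same toy as a 2-exon minus-strand gene: exon1 = transcript 0..14
# at chr1:41-55, exon2 = transcript 15..35 at chr1:10-30; GENCODE-style
# CDS excludes the stop codon, which is annotated separately
write_toy_gtf_fasta <- function(dir) {
  tx <- toy_sequence()
  chr <- paste0(strrep("A", 9),
                revcomp(substr(tx, 16, 36)),   # chr1:10-30
                strrep("C", 10),               # chr1:31-40
                revcomp(substr(tx, 1, 15)),    # chr1:41-55
                strrep("G", 5))                # chr1:56-60
  stopifnot(nchar(chr) == 60)
  attrs <- 'gene_id "g1"; transcript_id "toy1";'
  gtf <- c(
    paste("chr1", "toy", "exon", 41, 55, ".", "-", ".", attrs, sep = "\t"),
    paste("chr1", "toy", "exon", 10, 30, ".", "-", ".", attrs, sep = "\t"),
    paste("chr1", "toy", "CDS", 41, 52, ".", "-", ".", attrs, sep = "\t"),
    paste("chr1", "toy", "CDS", 22, 30, ".", "-", ".", attrs, sep = "\t"),
    paste("chr1", "toy", "stop_codon", 19, 21, ".", "-", ".", attrs, sep = "\t")
  )
  gtf_path <- file.path(dir, "toy.gtf")
  fa_path <- file.path(dir, "toy.fa")
  writeLines(gtf, gtf_path)
  writeLines(c(">chr1", chr), fa_path)
  list(gtf = gtf_path, fasta = fa_path)
}

# density track with explicit counts (counts[p + 1] is position p)
make_track <- function(tm, counts) {
  stopifnot(length(counts) == tm$length)
  structure(list(transcript_id = tm$transcript_id,
                 counts = as.integer(counts), total = sum(counts)),
            class = "density_track")
}

uniform_track <- function(tm, level = 1L) {
  make_track(tm, rep(level, tm$length))
}

# brute-force per-nucleotide scorer: loops over every position of every
# region, no shared code with score_transcript()
naive_scores <- function(track, tm) {
  ct <- track$counts
  sum_over <- function(from, to) {       # 0-based half-open
    s <- 0
    p <- from
    while (p < to) { s <- s + ct[p + 1]; p <- p + 1 }
    s
  }
  cds_len <- tm$cds_end - tm$cds_start
  cds_density <- sum_over(tm$cds_start, tm$cds_end) / cds_len
  body_density <- sum_over(tm$cds_start + 15, tm$cds_end - 12) /
    (cds_len - 27)
  stop_density <- sum_over(tm$cds_end - 3, tm$cds_end) / 3

  # scan codons for the first downstream in-frame stop
  nss <- NA
  p <- tm$cds_end
  while (p + 3 <= tm$length) {
    if (substr(tm$sequence, p + 1, p + 3) %in% c("TAA", "TAG", "TGA")) {
      nss <- p
      break
    }
    p <- p + 3
  }
  rrts <- NA_real_
  if (!is.na(nss)) {
    ext_density <- if (nss > tm$cds_end) {
      sum_over(tm$cds_end, nss) / (nss - tm$cds_end)
    } else 0
    rrts <- ext_density / cds_density
  }
  list(pause_score = stop_density / body_density, rrts = rrts)
}

# small simulated dataset reused by several files
small_sim <- function(n = 60, pi_ = 2, r = 0.05, seed = 11) {
  p <- simulation_params(n_transcripts = n, pause_multiplier = pi_,
                         readthrough_fraction = r,
                         cds_length_range = c(150L, 300L),
                         utr3_length_range = c(90L, 150L))
  models <- simulate_transcriptome(p, seed = seed)
  records <- simulate_footprints(models, p, seed = seed + 1)
  list(params = p, models = models, records = records,
       tracks = build_density(records, models, p$offsets))
}
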