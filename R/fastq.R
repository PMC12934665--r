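# Read layout constants. Read 1 is 210 cycles: the UMI followed by a
# 200 nt transcript segment that starts a fixed 100 nt upstream of the
# exon 2 3' end, so it spans the diagnostic junction whatever the
# splicing outcome (for the default 10 nt UMI). Read 2 is 85 cycles and
# carries the guide sequence at a fixed offset.
READ1_LEN <- 210L
READ2_LEN <- 85L
READ1_SEGMENT_UPSTREAM <- 100L
READ2_GUIDE_OFFSET <- 25L

.read1_segment <- function(reporter, outcome, read_len, umi_len) {
  seg_len <- read_len - umi_len
  up <- READ1_SEGMENT_UPSTREAM
  e2 <- reporter$exon2_seq
  left <- substr(e2, nchar(e2) - up + 1L, nchar(e2))
  right_src <- if (outcome == "IE") reporter$intron_seq else reporter$exon3_seq
  paste0(left, substr(right_src, 1L, seg_len - up))
}

#' Emit paired FASTQ files for simulated molecules
#'
#' Each molecule is written `K` times where `K - 1` is geometric with mean
#' `duplication_rate - 1` (so `duplication_rate = 1` means no PCR
#' duplication); PCR copies share the molecule's UMI and outcome. Read 1
#' (210 nt) is the UMI followed by a transcript segment spanning the EE or
#' IE junction; read 2 (85 nt) embeds the guide sequence at offset
#' `READ2_GUIDE_OFFSET` within random flanking sequence. Qualities are the
#' constant Phred+33 "I". Records are paired by identifier and order.
#'
#' @param molecules Molecule records from [simulate_guide_molecules()].
#' @param reporter A `reporter_model`.
#' @param library Guide library (provides guide sequences).
#' @param config A [screen_sim_config()] (UMI length, duplication rate).
#' @param r1_path,r2_path Output FASTQ paths.
#' @param seed Optional seed for duplication and flank draws; defaults to
#'   `config$seed`.
#' @return Invisibly, a list with `n_molecules` and `n_reads`.
#' @export
emit_fastq <- function(molecules, reporter, library, config,
                       r1_path, r2_path, seed = config$seed) {
  stopifnot(inherits(reporter, "reporter_model"),
            inherits(config, "screen_sim_config"))
  set.seed(seed)
  n <- nrow(molecules)
  copies <- rgeom(n, prob = 1 / config$duplication_rate) + 1L
  idx <- rep(seq_len(n), copies)

  seg_ie <- .read1_segment(reporter, "IE", READ1_LEN, config$umi_len)
  seg_ee <- .read1_segment(reporter, "EE", READ1_LEN, config$umi_len)
  r1 <- paste0(molecules$umi[idx],
               ifelse(molecules$outcome[idx] == "IE", seg_ie, seg_ee))

  guide_seq <- library$sequence[match(molecules$guide_id, library$guide_id)]
  if (anyNA(guide_seq)) stop("molecule references a guide absent from library")
  glen <- nchar(library$sequence[1L])
  tail_len <- READ2_LEN - READ2_GUIDE_OFFSET - glen
  if (tail_len < 0L) stop("guide does not fit in read 2 at the fixed offset")
  # flanks are per molecule, so PCR copies are byte-identical reads
  left <- vapply(seq_len(n), function(i) random_dna(READ2_GUIDE_OFFSET),
                 character(1))
  right <- vapply(seq_len(n), function(i) random_dna(tail_len), character(1))
  r2 <- paste0(left[idx], guide_seq[idx], right[idx])

  ids <- sprintf("mol%07d:%s:copy%d", idx, molecules$guide_id[idx],
                 sequence(copies))
  .write_fastq(ids, r1, r1_path)
  .write_fastq(ids, r2, r2_path)
  invisible(list(n_molecules = n, n_reads = length(idx)))
}

.write_fastq <- function(ids, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(seqs)))
  )
  invisible(path)
}

#' Read a FASTQ file as a character vector of sequences
#'
#' Gzip-transparent (via Biostrings). Names are the read identifiers.
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub(" .*", "", names(x))
  out
}
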