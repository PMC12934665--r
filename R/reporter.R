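#' Random DNA sequence
#'
#' @param n Sequence length in nucleotides.
#' @return A single character string over {A, C, G, T}.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Reporter geometry: a minigene with a 161 nt upstream exon, a 1,943 nt
# intron and a 163 nt downstream exon. Splicing outcome is read from the
# junction formed in the mature transcript: exon-exon (EE, spliced) or
# exon-intron (IE, retained).
REPORTER_EXON2_LEN <- 161L
REPORTER_INTRON_LEN <- 1943L
REPORTER_EXON3_LEN <- 163L

#' Generate a synthetic splicing-reporter model
#'
#' Draws random exon 2 / intron 2 / exon 3 sequences with the reporter's
#' fixed geometry (161 / 1,943 / 163 nt) and verifies that the two junction
#' k-mers that diagnose the splicing outcome are unique: the exon2-exon3
#' (EE) k-mer must not occur anywhere in the unspliced sequence, the
#' exon2-intron (IE) k-mer must occur exactly once in it, and each must
#' occur exactly once in its own mature transcript. Resamples until the
#' uniqueness constraints hold (for random sequences the first draw
#' essentially always does).
#'
#' @param seed Integer seed; the model is deterministic given the seed.
#' @param junction_kmer_len Even k-mer length spanning each junction
#'   (`k/2` nt on either side), default 20.
#' @return An object of class `reporter_model`: a list with `exon2_seq`,
#'   `intron_seq`, `exon3_seq` and `junction_kmer_len`.
#' @examples
#' rep <- generate_reporter(seed = 1)
#' nchar(rep$intron_seq)
#' junction_kmers(rep)
#' @export
generate_reporter <- function(seed, junction_kmer_len = 20L) {
  junction_kmer_len <- as.integer(junction_kmer_len)
  if (junction_kmer_len < 2L || junction_kmer_len %% 2L != 0L) {
    stop("junction_kmer_len must be an even integer >= 2")
  }
  set.seed(seed)
  repeat {
    model <- structure(
      list(
        exon2_seq = random_dna(REPORTER_EXON2_LEN),
        intron_seq = random_dna(REPORTER_INTRON_LEN),
        exon3_seq = random_dna(REPORTER_EXON3_LEN),
        junction_kmer_len = junction_kmer_len
      ),
      class = "reporter_model"
    )
    if (.junctions_unique(model)) {
      return(model)
    }
  }
}

#' Junction k-mers of a reporter
#'
#' The EE k-mer is the last `k/2` nt of exon 2 followed by the first `k/2`
#' nt of exon 3 (spliced transcript); the IE k-mer is the last `k/2` nt of
#' exon 2 followed by the first `k/2` nt of the intron (retained
#' transcript).
#'
#' @param reporter A `reporter_model`.
#' @return Named character vector with elements `ee` and `ie`.
#' @export
junction_kmers <- function(reporter) {
  stopifnot(inherits(reporter, "reporter_model"))
  half <- reporter$junction_kmer_len %/% 2L
  e2 <- reporter$exon2_seq
  tail2 <- substr(e2, nchar(e2) - half + 1L, nchar(e2))
  c(
    ee = paste0(tail2, substr(reporter$exon3_seq, 1L, half)),
    ie = paste0(tail2, substr(reporter$intron_seq, 1L, half))
  )
}

#' Spliced / unspliced mature transcript sequences
#' @param reporter A `reporter_model`.
#' @return Named character vector with elements `spliced` (exon2 + exon3)
#'   and `unspliced` (exon2 + intron + exon3).
#' @export
reporter_transcripts <- function(reporter) {
  stopifnot(inherits(reporter, "reporter_model"))
  c(
    spliced = paste0(reporter$exon2_seq, reporter$exon3_seq),
    unspliced = paste0(reporter$exon2_seq, reporter$intron_seq,
                       reporter$exon3_seq)
  )
}

.count_occurrences <- function(pattern, subject) {
  Biostrings::countPattern(pattern, Biostrings::DNAString(subject))
}

.junctions_unique <- function(model) {
  km <- junction_kmers(model)
  if (km[["ee"]] == km[["ie"]]) return(FALSE)
  tx <- reporter_transcripts(model)
  # EE k-mer: once in the spliced transcript, absent from the unspliced
  # (genomic) sequence; IE k-mer: once in the unspliced, absent from the
  # spliced. Guarantees unambiguous outcome classification.
  .count_occurrences(km[["ee"]], tx[["spliced"]]) == 1L &&
    .count_occurrences(km[["ee"]], tx[["unspliced"]]) == 0L &&
    .count_occurrences(km[["ie"]], tx[["unspliced"]]) == 1L &&
    .count_occurrences(km[["ie"]], tx[["spliced"]]) == 0L
}
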