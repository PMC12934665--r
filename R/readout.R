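#' Classify the splicing outcome of read-1 sequences
#'
#' A read is `EE` if the exon2-exon3 junction k-mer occurs in it within
#' `max_mismatch` substitutions, `IE` if the exon2-intron junction k-mer
#' does, and `UNASSIGNED` otherwise or when both match (ambiguous). Reads
#' shorter than the k-mer are `UNASSIGNED`.
#'
#' @param reads Character vector of read sequences (UMI may be included;
#'   it cannot collide with a junction k-mer by construction).
#' @param reporter A `reporter_model`.
#' @param max_mismatch Maximum substitutions allowed in the k-mer match
#'   (default 0 = exact).
#' @return Character vector in `{IE, EE, UNASSIGNED}`.
#' @export
classify_outcome <- function(reads, reporter, max_mismatch = 0L) {
  km <- junction_kmers(reporter)
  if (max_mismatch == 0L) {
    ee <- grepl(km[["ee"]], reads, fixed = TRUE)
    ie <- grepl(km[["ie"]], reads, fixed = TRUE)
  } else {
    subj <- Biostrings::DNAStringSet(reads)
    ee <- Biostrings::vcountPattern(km[["ee"]], subj,
                                    max.mismatch = max_mismatch) > 0L
    ie <- Biostrings::vcountPattern(km[["ie"]], subj,
                                    max.mismatch = max_mismatch) > 0L
  }
  out <- rep("UNASSIGNED", length(reads))
  out[ee & !ie] <- "EE"
  out[ie & !ee] <- "IE"
  out
}

#' Assign read-2 sequences to guides
#'
#' Extracts the guide-length window at the configured offset of each read
#' and matches it against the library within `max_mismatch` substitutions.
#' A read matching no guide, or two or more guides (ambiguity), is
#' unassigned (`NA`).
#'
#' @param reads Character vector of read-2 sequences.
#' @param library Guide library data frame (`guide_id`, `sequence`).
#' @param max_mismatch Maximum substitutions (default 0 = exact).
#' @param guide_offset 0-based offset of the guide within read 2
#'   (default `READ2_GUIDE_OFFSET`).
#' @return Character vector of guide ids, `NA` where unassigned.
#' @export
assign_guide <- function(reads, library, max_mismatch = 0L,
                         guide_offset = READ2_GUIDE_OFFSET) {
  glen <- nchar(library$sequence[1L])
  window <- substr(reads, guide_offset + 1L, guide_offset + glen)
  if (max_mismatch == 0L) {
    hit <- match(window, library$sequence)
    out <- library$guide_id[hit]
    out[nchar(window) < glen] <- NA_character_
    return(out)
  }
  # mismatch-tolerant path: Hamming distance of each window to each guide
  ok <- nchar(window) == glen
  mat <- matrix(NA_character_, nrow = glen, ncol = length(window))
  if (any(ok)) {
    mat[, ok] <- vapply(strsplit(window[ok], ""), identity, character(glen))
  }
  n_hits <- integer(length(window))
  last_hit <- integer(length(window))
  for (j in seq_len(nrow(library))) {
    g <- strsplit(library$sequence[j], "")[[1L]]
    d <- glen - colSums(mat == g)
    within <- ok & d <= max_mismatch
    n_hits[within] <- n_hits[within] + 1L
    last_hit[within] <- j
  }
  ifelse(n_hits == 1L, library$guide_id[last_hit], NA_character_)
}

#' Deduplicate read records into per-guide molecule counts
#'
#' Collapses records to one molecule per distinct `(guide_id, umi)` key.
#' A key observed with conflicting outcomes is resolved by majority vote;
#' an exact tie drops the key. Records must already carry an assigned
#' guide and an IE/EE outcome.
#'
#' @param records Data frame with columns `guide_id`, `umi`, `outcome`.
#' @param replicate Replicate index recorded in the output.
#' @return Data frame `guide_id`, `replicate`, `ie`, `ee`, `total`,
#'   ordered by `guide_id`.
#' @export
deduplicate <- function(records, replicate = 1L) {
  stopifnot(all(c("guide_id", "umi", "outcome") %in% names(records)))
  if (!all(records$outcome %in% c("IE", "EE"))) {
    stop("records must be pre-filtered to IE/EE outcomes")
  }
  if (nrow(records) == 0L) {
    return(data.frame(guide_id = character(0), replicate = integer(0),
                      ie = integer(0), ee = integer(0), total = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(records$guide_id, records$umi, sep = "\r")
  ie_votes <- rowsum(as.integer(records$outcome == "IE"), key)
  ee_votes <- rowsum(as.integer(records$outcome == "EE"), key)
  call <- ifelse(ie_votes > ee_votes, "IE",
                 ifelse(ee_votes > ie_votes, "EE", NA_character_))
  keep <- !is.na(call)
  if (!any(keep)) {
    return(data.frame(guide_id = character(0),
                      replicate = as.integer(replicate)[0],
                      ie = integer(0), ee = integer(0), total = integer(0),
                      stringsAsFactors = FALSE))
  }
  guide <- sub("\r.*", "", rownames(ie_votes))[keep]
  call <- call[keep]
  ie <- rowsum(as.integer(call == "IE"), guide)
  ee <- rowsum(as.integer(call == "EE"), guide)
  out <- data.frame(
    guide_id = rownames(ie), replicate = as.integer(replicate),
    ie = as.integer(ie), ee = as.integer(ee),
    total = as.integer(ie + ee), stringsAsFactors = FALSE
  )
  out <- out[order(out$guide_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude guides with too few molecules
#'
#' Guides with fewer than `min_total` deduplicated molecules are removed
#' (strict "fewer than": a guide with exactly `min_total` is kept).
#'
#' @param counts Guide counts from [deduplicate()].
#' @param min_total Minimum total molecule count (default 10).
#' @return The retained rows; the number removed is reported via `message`.
#' @export
filter_min_reads <- function(counts, min_total = 10L) {
  drop <- counts$total < min_total
  if (any(drop)) {
    message(sum(drop), " guide-replicate entries below ", min_total,
            " molecules removed")
  }
  out <- counts[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantify a screen replicate from paired FASTQ
#'
#' End-to-end readout: parse the read pair, split read 1 into UMI and
#' transcript segment, classify the splicing outcome, assign the guide
#' from read 2, drop unassigned records, deduplicate by `(guide, UMI)`,
#' and apply the minimum-molecule filter.
#'
#' @param r1_path,r2_path Paired FASTQ paths (pairing by record order;
#'   identifiers are checked).
#' @param library Guide library.
#' @param reporter A `reporter_model`.
#' @param replicate Replicate index.
#' @param umi_len UMI length at the start of read 1 (default 10).
#' @param max_mismatch Substitutions tolerated in junction and guide
#'   matching (default 0).
#' @param guide_offset 0-based guide offset within read 2.
#' @param min_reads Minimum deduplicated molecules per guide (default 10);
#'   set to 0 to disable.
#' @return Filtered guide counts (see [deduplicate()]).
#' @export
quantify_screen <- function(r1_path, r2_path, library, reporter,
                            replicate = 1L, umi_len = 10L,
                            max_mismatch = 0L,
                            guide_offset = READ2_GUIDE_OFFSET,
                            min_reads = 10L) {
  r1 <- read_fastq(r1_path)
  r2 <- read_fastq(r2_path)
  if (length(r1) != length(r2)) stop("read 1 / read 2 record counts differ")
  if (!identical(names(r1), names(r2))) {
    stop("read 1 / read 2 identifiers do not pair")
  }
  umi <- substr(r1, 1L, umi_len)
  outcome <- classify_outcome(substr(r1, umi_len + 1L, nchar(r1)),
                              reporter, max_mismatch)
  guide <- assign_guide(r2, library, max_mismatch, guide_offset)
  keep <- !is.na(guide) & outcome != "UNASSIGNED"
  records <- data.frame(guide_id = guide[keep], umi = umi[keep],
                        outcome = outcome[keep], stringsAsFactors = FALSE)
  counts <- deduplicate(records, replicate)
  filter_min_reads(counts, min_reads)
}

#' Write / read guide counts as TSV
#' @param counts Guide counts data frame.
#' @param path File path.
#' @export
write_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
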