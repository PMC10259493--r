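#' Read processing: anchored trimming, cap classification, perfect-match
#' counting
#'
#' Merged reads are reduced to per-construct counts in three steps: removal of
#' the shared promoter/adapter prefix by anchored trimming (Hamming mismatches
#' only, cutadapt-style error rate), classification of RNA reads as 5'-capped
#' (leading NNG from cap reverse transcription) or uncapped, and exact
#' matching against the designed library sequences.
#'
#' @name read_processing
NULL

#' Anchored prefix trimming
#'
#' A read is trimmed iff it begins with the anchor within
#' `floor(max_error_rate * nchar(anchor))` Hamming mismatches; N in the anchor
#' matches any base. Non-matching (or too-short) reads are rejected (NA), the
#' cutadapt `--trimmed-only` convention.
#'
#' @param reads Character vector of reads.
#' @param anchor Anchor sequence (may contain N).
#' @param max_error_rate Allowed mismatch proportion (default 0.04).
#' @return Character vector: the suffix after the anchor, or NA if rejected.
#' @export
trim_anchored_prefix <- function(reads, anchor, max_error_rate = 0.04) {
  stopifnot(nchar(anchor) > 0)
  la <- nchar(anchor)
  allowed <- floor(max_error_rate * la)
  a <- strsplit(toupper(anchor), "")[[1]]
  fixed <- a != "N"
  vapply(reads, function(r) {
    if (nchar(r) < la) return(NA_character_)
    pre <- strsplit(toupper(substr(r, 1, la)), "")[[1]]
    if (sum(pre[fixed] != a[fixed]) > allowed) return(NA_character_)
    substr(r, la + 1, nchar(r))
  }, character(1), USE.NAMES = FALSE)
}

#' Classify RNA reads as capped or uncapped
#'
#' Reads beginning with the NNGAAGC pattern (two untemplated bases and the
#' reverse-transcribed cap G, followed by the shared AAGC leader start) are
#' capped and stripped of the 7-nt prefix; other reads are uncapped, with a
#' leading AAGC stripped when present so both branches land on the same
#' coordinate as the designed library sequences.
#'
#' @param reads Character vector of reads (3' adapter already removed).
#' @return data.frame(cap_status, trimmed)
#' @export
classify_cap <- function(reads) {
  up <- toupper(reads)
  capped <- nchar(up) >= 7 & substr(up, 3, 7) == "GAAGC"
  trimmed <- ifelse(capped, substr(up, 8, nchar(up)),
                    ifelse(startsWith(up, "AAGC"),
                           substr(up, 5, nchar(up)), up))
  data.frame(cap_status = ifelse(capped, "capped", "uncapped"),
             trimmed = trimmed, stringsAsFactors = FALSE)
}

#' Count perfect matches against the designed library
#'
#' @param reads Character vector of processed reads.
#' @param library_seqs Named character vector of designed sequences
#'   (construct_id -> sequence); duplicates are a hard error.
#' @return list(counts = named integer vector, unmatched = count)
#' @export
count_perfect_matches <- function(reads, library_seqs) {
  if (anyDuplicated(library_seqs)) stop("duplicate library sequences")
  idx <- match(toupper(reads), toupper(library_seqs))
  counts <- tabulate(idx, nbins = length(library_seqs))
  list(counts = stats::setNames(as.integer(counts), names(library_seqs)),
       unmatched = sum(is.na(idx)))
}
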