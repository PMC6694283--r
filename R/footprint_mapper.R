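# coerce DNAStringSet or character to character, keeping names
as_named_character <- function(x) {
  if (is.character(x)) x else as.character(x)
}

#' Exactly match a footprint read against a transcript
#'
#' Returns every forward-strand position where the read occurs verbatim in
#' the transcript (100% identity, no mismatches or gaps), the filter used to
#' retain transcript-specific ribosomal footprints. Overlapping occurrences
#' are all reported. Reads shorter than `min_len` never match.
#'
#' @param read Read sequence (character or [Biostrings::DNAString]).
#' @param transcript Transcript sequence (character or DNAString).
#' @param min_len Minimum footprint length (default 24 nt).
#' @return data.frame with columns `start`, `end` (1-based, closed), one
#'   row per occurrence; zero rows if none.
#' @export
exact_match_read <- function(read, transcript, min_len = 24L) {
  read <- as.character(read)
  if (nchar(read) < min_len || grepl("[^ACGT]", read))
    return(data.frame(start = integer(0), end = integer(0)))
  hits <- Biostrings::matchPattern(read, Biostrings::DNAString(as.character(transcript)))
  data.frame(start = IRanges::start(hits), end = IRanges::end(hits))
}

#' Assign the P-site of a footprint
#'
#' The P-site is estimated as the central nucleotide of the footprint. For
#' even lengths, where "central" is ambiguous, the left-central position
#' (offset `len/2 - 1` from the 5' end) is used so results are
#' deterministic.
#'
#' @param start,end Footprint span (1-based, closed); vectorized.
#' @return Integer vector of P-site positions.
#' @examples
#' assign_p_site(11, 39)  # length 29 -> 25
#' assign_p_site(1, 28)   # length 28 -> 14 (left-central)
#' @export
assign_p_site <- function(start, end) {
  len <- end - start + 1L
  stopifnot(all(len >= 1L))
  offset <- ifelse(len %% 2L == 1L, (len - 1L) %/% 2L, len %/% 2L - 1L)
  as.integer(start + offset)
}

#' Map footprint reads onto transcripts by exact matching
#'
#' Places each read on the transcript set wherever it occurs verbatim
#' (forward strand, zero mismatches or gaps, length >= `min_len`) and
#' assigns a P-site. Reads containing `N` cannot satisfy the 100%-identity
#' filter and are dropped. Reads matching more than one location across the
#' transcript set are ambiguous; by default they are discarded to avoid
#' double-counting density (`multi = "keep-all"` keeps every hit).
#'
#' @param reads Named character vector or [Biostrings::DNAStringSet] of
#'   read sequences (names become read ids; unnamed reads are numbered).
#' @param transcripts Named character vector or DNAStringSet of transcript
#'   sequences.
#' @param min_len Minimum footprint length (default 24).
#' @param multi Policy for multi-hit reads: `"discard"` (default) or
#'   `"keep-all"`.
#' @return data.frame of footprints: `read_id`, `transcript_id`, `start`,
#'   `end`, `length`, `p_site`. Attribute `n_dropped` records counts of
#'   reads dropped as short/malformed, unmapped, or multi-hit.
#' @export
map_reads <- function(reads, transcripts, min_len = 24L,
                      multi = c("discard", "keep-all")) {
  multi <- match.arg(multi)
  reads <- as_named_character(reads)
  if (is.null(names(reads)) || any(names(reads) == ""))
    names(reads) <- paste0("read", seq_along(reads))
  transcripts <- as_named_character(transcripts)
  stopifnot(!is.null(names(transcripts)))

  subjects <- lapply(transcripts, Biostrings::DNAString)
  bad <- nchar(reads) < min_len | grepl("[^ACGT]", reads)
  hits_per_read <- lapply(which(!bad), function(i) {
    out <- lapply(names(subjects), function(tx) {
      h <- Biostrings::matchPattern(reads[[i]], subjects[[tx]])
      if (length(h) == 0L) return(NULL)
      data.frame(read_id = names(reads)[i], transcript_id = tx,
                 start = IRanges::start(h), end = IRanges::end(h),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  n_hits <- vapply(hits_per_read, function(h) if (is.null(h)) 0L else nrow(h),
                   integer(1))
  n_unmapped <- sum(n_hits == 0L)
  n_multi <- sum(n_hits > 1L)
  if (multi == "discard") hits_per_read <- hits_per_read[n_hits == 1L]
  fp <- do.call(rbind, hits_per_read)
  if (is.null(fp))
    fp <- data.frame(read_id = character(0), transcript_id = character(0),
                     start = integer(0), end = integer(0))
  fp$length <- fp$end - fp$start + 1L
  fp$p_site <- if (nrow(fp)) assign_p_site(fp$start, fp$end) else integer(0)
  rownames(fp) <- NULL
  attr(fp, "n_dropped") <- c(
    short_or_malformed = sum(bad), unmapped = n_unmapped,
    multi_hit = if (multi == "discard") n_multi else 0L)
  fp
}

#' Ingest transcript-space alignments from SAM/BAM
#'
#' Reads alignments produced by an external aligner against the transcript
#' set and converts them to footprints. Keeps forward-strand records of
#' length >= `min_len`; with `require_perfect = TRUE` (default) only
#' ungapped, mismatch-free alignments (CIGAR all-M, `NM` tag 0 when
#' present) are kept, mirroring the 100%-identity filter. Records naming
#' transcripts absent from `transcripts` are skipped with a warning.
#'
#' @param file Path to a SAM or BAM file (SAM is converted on the fly).
#' @param transcripts Named character vector or DNAStringSet of the
#'   transcript set the alignments refer to.
#' @param min_len Minimum footprint length (default 24).
#' @param require_perfect Drop records with gaps or mismatches (default
#'   TRUE).
#' @return data.frame of footprints as in [map_reads()].
#' @export
ingest_alignments <- function(file, transcripts, min_len = 24L,
                              require_perfect = TRUE) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(bam))
  } else bam <- file
  par <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "cigar", "qwidth"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  rec <- Rsamtools::scanBam(bam, param = par)[[1]]

  df <- data.frame(read_id = rec$qname, transcript_id = as.character(rec$rname),
                   strand = as.character(rec$strand), pos = rec$pos,
                   cigar = rec$cigar, qwidth = rec$qwidth,
                   stringsAsFactors = FALSE)
  df$nm <- if (is.null(rec$tag$NM)) NA_integer_ else rec$tag$NM

  known <- names(as_named_character(transcripts))
  unknown <- !df$transcript_id %in% known
  if (any(unknown))
    warning("UnknownReference: skipped ", sum(unknown),
            " record(s) naming absent transcripts")
  df <- df[!unknown & df$strand == "+", , drop = FALSE]
  if (require_perfect) {
    perfect <- grepl("^[0-9]+M$", df$cigar) & (is.na(df$nm) | df$nm == 0L)
    df <- df[perfect, , drop = FALSE]
  }
  df <- df[df$qwidth >= min_len, , drop = FALSE]

  fp <- data.frame(read_id = df$read_id, transcript_id = df$transcript_id,
                   start = df$pos, end = df$pos + df$qwidth - 1L,
                   length = df$qwidth, stringsAsFactors = FALSE)
  fp$p_site <- if (nrow(fp)) assign_p_site(fp$start, fp$end) else integer(0)
  rownames(fp) <- NULL
  fp
}

#' Write / read a footprint table
#'
#' Footprints are exchanged as a TSV with columns `read_id`,
#' `transcript_id`, `start`, `end`, `length`, `p_site` (1-based, closed).
#'
#' @param footprints data.frame of footprints.
#' @param path File path.
#' @return `write_footprints_tsv` the path invisibly;
#'   `read_footprints_tsv` the data.frame.
#' @export
write_footprints_tsv <- function(footprints, path) {
  utils::write.table(footprints, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_footprints_tsv
#' @export
read_footprints_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
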