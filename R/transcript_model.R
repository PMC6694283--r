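#' Annotate the inter-stop codon region (ISR) of a transcript
#'
#' Scans downstream of the canonical stop codon for the first in-frame stop
#' codon. The segment between the two stops is the inter-stop codon region
#' (ISR); ribosomes reading through the canonical stop translate it into a
#' C-terminal protein extension, terminating at the downstream stop.
#'
#' All coordinates are 1-based and closed (the IRanges convention used
#' throughout this package); BED export converts to 0-based half-open.
#'
#' @param sequence Transcript sequence: a single character string or a
#'   [Biostrings::DNAString] (A/C/G/T, uppercase).
#' @param cds_start,cds_end First and last position of the CDS (1-based,
#'   closed). The last three nucleotides of the interval must be the
#'   canonical stop codon; the CDS length must be a multiple of 3 and at
#'   least 6 nt.
#' @param transcript_id Identifier carried through to reports.
#' @param check_start If `TRUE` (default), require `ATG` at `cds_start`.
#'
#' @return A `transcript_annotation` object: a list with elements
#'   `transcript_id`, `sequence`, `cds_start`, `cds_end`, `isr_start`,
#'   `isr_end` (the nominal ISR, between the two stops; `isr_end <
#'   isr_start` means a zero-length ISR), `stop2_start`, `stop2_end`,
#'   `isr_codons`, and `length`.
#'
#' @details Only the first downstream in-frame stop defines the ISR; any
#'   deeper in-frame stops are ignored. If no complete in-frame stop codon
#'   occurs before the transcript end, the function errors
#'   (`NoDownstreamStop`).
#'
#' @examples
#' ann <- annotate_isr("ATGAAATGACCCTAA", 1, 9)
#' ann$isr_codons  # 1
#' @export
annotate_isr <- function(sequence, cds_start, cds_end, transcript_id = "tx",
                         check_start = TRUE) {
  sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L)
  L <- nchar(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("InvalidCodon: sequence contains non-ACGT characters")

  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  cds_len <- cds_end - cds_start + 1L
  if (cds_start < 1L || cds_end > L || cds_len < 6L || cds_len %% 3L != 0L)
    stop("BadCds: CDS must lie within the transcript, span >= 6 nt and a multiple of 3")
  stop1 <- substr(sequence, cds_end - 2L, cds_end)
  if (!stop1 %in% STOP_CODONS)
    stop("BadCds: CDS does not end in a stop codon (", stop1, ")")
  if (check_start && substr(sequence, cds_start, cds_start + 2L) != "ATG")
    stop("BadCds: no ATG at cds_start")

  # in-frame scan downstream of the canonical stop
  stop2_start <- NA_integer_
  pos <- cds_end + 1L
  while (pos + 2L <= L) {
    if (substr(sequence, pos, pos + 2L) %in% STOP_CODONS) {
      stop2_start <- pos
      break
    }
    pos <- pos + 3L
  }
  if (is.na(stop2_start))
    stop("NoDownstreamStop: no complete in-frame stop codon downstream of the CDS")

  structure(list(
    transcript_id = transcript_id,
    sequence = sequence,
    cds_start = cds_start,
    cds_end = cds_end,
    isr_start = cds_end + 1L,
    isr_end = stop2_start - 1L,
    stop2_start = stop2_start,
    stop2_end = stop2_start + 2L,
    isr_codons = (stop2_start - cds_end - 1L) %/% 3L,
    length = L
  ), class = "transcript_annotation")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @export
print.transcript_annotation <- function(x, ...) {
  cat("Transcript", x$transcript_id, "(", x$length, "nt )\n")
  cat("  CDS:  ", x$cds_start, "-", x$cds_end, "\n")
  cat("  ISR:  ", x$isr_start, "-", x$isr_end,
      " (", x$isr_codons, "codons )\n")
  cat("  stop2:", x$stop2_start, "-", x$stop2_end, "\n")
  invisible(x)
}

#' Nominal ISR length in nucleotides
#'
#' Length of the region between the canonical and the downstream in-frame
#' stop codon, excluding both stops.
#'
#' @param annotation A `transcript_annotation`.
#' @return Integer nucleotide count (a multiple of 3).
#' @export
isr_length <- function(annotation) {
  annotation$isr_end - annotation$isr_start + 1L
}

#' Translate the C-terminal readthrough extension
#'
#' The extension produced by readthrough consists of the residue inserted at
#' the canonical stop codon (unknown in general, so a placeholder is used)
#' followed by the standard-genetic-code translation of the ISR codons.
#'
#' @param annotation A `transcript_annotation` from [annotate_isr()].
#' @param readthrough_residue Single amino-acid symbol decoded at the
#'   canonical stop, or `"X"` (default) as a placeholder.
#' @return A character string of length `isr_codons + 1`.
#' @examples
#' ann <- annotate_isr("ATGAAATGACCCTAA", 1, 9)
#' translate_extension(ann)  # "XP"
#' @export
translate_extension <- function(annotation, readthrough_residue = "X") {
  stopifnot(inherits(annotation, "transcript_annotation"),
            nchar(readthrough_residue) == 1L)
  n <- isr_length(annotation)
  if (n == 0L) return(readthrough_residue)
  isr_seq <- substr(annotation$sequence, annotation$isr_start, annotation$isr_end)
  if (grepl("[^ACGT]", isr_seq))
    stop("InvalidCodon: non-ACGT characters in ISR")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(isr_seq)))
  paste0(readthrough_residue, aa)
}

#' Partition a transcript into readthrough counting regions
#'
#' Splits the transcript into 5'UTR, CDS, ISR and distal 3'UTR counting
#' regions and defines the exclusion zones used when counting P-sites.
#' Following the region-assignment convention for readthrough analysis, the
#' CDS counting region includes the canonical stop codon and the ISR
#' counting region includes the downstream stop codon. P-sites in the first
#' `exclusion_nt` nucleotides after the start codon, after the canonical
#' stop and after the downstream stop are excluded, to avoid the initiation
#' and termination peaks; the excluded positions are also subtracted from
#' the density denominators (effective lengths), so counts and lengths
#' refer to identical position sets.
#'
#' @param annotation A `transcript_annotation`.
#' @param exclusion_nt Width of each exclusion zone (default 12 nt); zones
#'   are clipped at the transcript end.
#' @return A `region_map` object: list with `regions` (data.frame of
#'   region, start, end, nominal_length, effective_length), `excluded`
#'   (data.frame of start, end), `transcript_id` and `length`. Empty
#'   regions (e.g. a transcript with no 5'UTR) have zero length and
#'   `start > end`.
#' @examples
#' ann <- annotate_isr("ATGAAATGACCCTAA", 1, 9)
#' partition_regions(ann, exclusion_nt = 0)
#' @export
partition_regions <- function(annotation, exclusion_nt = 12L) {
  stopifnot(inherits(annotation, "transcript_annotation"), exclusion_nt >= 0L)
  a <- annotation
  L <- a$length

  regions <- data.frame(
    region = c("utr5", "cds", "isr", "utr3_rest"),
    start = c(1L, a$cds_start, a$cds_end + 1L, a$stop2_end + 1L),
    end = c(a$cds_start - 1L, a$cds_end, a$stop2_end, L),
    stringsAsFactors = FALSE
  )
  regions$nominal_length <- pmax(regions$end - regions$start + 1L, 0L)

  # exclusion zones: after the start codon, the canonical stop, the
  # downstream stop; clipped to the transcript end
  ex_start <- c(a$cds_start + 3L, a$cds_end + 1L, a$stop2_end + 1L)
  ex_end <- pmin(ex_start + exclusion_nt - 1L, L)
  keep <- ex_end >= ex_start
  excluded <- data.frame(start = ex_start[keep], end = ex_end[keep])
  if (exclusion_nt == 0L) excluded <- excluded[0L, , drop = FALSE]

  ex_pos <- excluded_positions(excluded)
  regions$effective_length <- vapply(seq_len(nrow(regions)), function(i) {
    if (regions$nominal_length[i] == 0L) return(0L)
    pos <- regions$start[i]:regions$end[i]
    sum(!pos %in% ex_pos)
  }, integer(1))

  structure(list(
    transcript_id = a$transcript_id,
    length = L,
    regions = regions,
    excluded = excluded
  ), class = "region_map")
}

excluded_positions <- function(excluded) {
  if (nrow(excluded) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(excluded)),
                function(i) excluded$start[i]:excluded$end[i]))
}

#' @export
print.region_map <- function(x, ...) {
  cat("Region map for", x$transcript_id, "(", x$length, "nt )\n")
  print(x$regions, row.names = FALSE)
  if (nrow(x$excluded))
    cat("Excluded zones:",
        paste0("[", x$excluded$start, "-", x$excluded$end, "]", collapse = " "),
        "\n")
  invisible(x)
}

#' Export regions and exclusion zones as BED
#'
#' Writes the counting regions and exclusion zones of a [partition_regions()]
#' map in BED format (0-based, half-open), with the transcript as the
#' "chromosome".
#'
#' @param region_map A `region_map`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_regions_bed <- function(region_map, path) {
  r <- region_map$regions
  r <- r[r$nominal_length > 0L, ]
  bed <- data.frame(chrom = region_map$transcript_id,
                    start = r$start - 1L, end = r$end, name = r$region)
  ex <- region_map$excluded
  if (nrow(ex))
    bed <- rbind(bed, data.frame(chrom = region_map$transcript_id,
                                 start = ex$start - 1L, end = ex$end,
                                 name = "excluded"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CDS coordinate table
#'
#' Reads a tab-separated table with columns `transcript_id`, `cds_start`,
#' `cds_end` (1-based, closed) and returns it as a data.frame. Lines
#' starting with `#` are treated as comments.
#'
#' @param path TSV file path.
#' @return data.frame with the three columns, types enforced.
#' @export
read_cds_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("transcript_id", "cds_start", "cds_end")
  if (!all(need %in% names(tab)))
    stop("CDS table must have columns: ", paste(need, collapse = ", "))
  tab$cds_start <- as.integer(tab$cds_start)
  tab$cds_end <- as.integer(tab$cds_end)
  tab
}
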