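AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Build the 20-variant readthrough protein database
#'
#' A readthrough product carries one of the 20 standard amino acids at the
#' position of the canonical stop codon, followed by the ISR-encoded
#' extension. Since the decoded residue is unknown a priori, the search
#' database contains all 20 possibilities: `base + X + extension` for X
#' over the standard amino acids.
#'
#' @param base_protein Canonical protein sequence (no stop symbol).
#' @param extension ISR-encoded extension (may be empty).
#' @param id_prefix Prefix for variant ids (default `"rt"`; ids are e.g.
#'   `rt_A` ... `rt_Y`).
#' @return A `readthrough_db` list: `base_protein`, `extension`,
#'   `variants` (named character vector of 20 sequences).
#' @export
build_readthrough_db <- function(base_protein, extension = "",
                                 id_prefix = "rt") {
  check_protein(base_protein)
  if (nchar(extension)) check_protein(extension)
  variants <- stats::setNames(paste0(base_protein, AA20, extension),
                              paste0(id_prefix, "_", AA20))
  structure(list(base_protein = base_protein, extension = extension,
                 variants = variants), class = "readthrough_db")
}

check_protein <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl(paste0("[^", paste(AA20, collapse = ""), "]"), x))
    stop("InvalidResidue: sequence contains non-standard amino-acid symbols")
  invisible(x)
}

#' Write a variant database (or any protein set) as FASTA
#'
#' @param db A `readthrough_db` or a named character vector of protein
#'   sequences.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_protein_fasta <- function(db, path) {
  seqs <- if (inherits(db, "readthrough_db")) db$variants else db
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' In silico tryptic digestion
#'
#' Cleaves after K or R, by default not when the next residue is proline
#' (the classical trypsin rule; `rule = "trypsin/p"` drops the proline
#' exception). Returns every peptide between cleavage points spanning at
#' most `max_missed` internal (missed) cleavage sites.
#'
#' @param protein Protein sequence.
#' @param max_missed Maximum missed cleavages (default 5, suited to K/R-
#'   rich extension sequences).
#' @param rule `"trypsin"` (no cleavage before P, default) or
#'   `"trypsin/p"`.
#' @return data.frame: `peptide`, `start`, `end` (1-based positions in the
#'   protein), `missed_cleavages`.
#' @examples
#' tryptic_digest("RQNAVTSLDRRKLSKP", max_missed = 0)$peptide
#' @export
tryptic_digest <- function(protein, max_missed = 5L,
                           rule = c("trypsin", "trypsin/p")) {
  rule <- match.arg(rule)
  check_protein(protein)
  n <- nchar(protein)
  stopifnot(n >= 1L, max_missed >= 0L)
  res <- strsplit(protein, "")[[1]]
  # cut after position i when residue i is K/R (and i+1 is not P for the
  # classical rule); boundaries include 0 and n
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  if (rule == "trypsin")
    cut_after <- cut_after[res[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)

  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    jmax <- min(i + 1L + max_missed, length(bounds))
    for (j in (i + 1L):jmax) {
      out[[length(out) + 1L]] <- c(bounds[i] + 1L, bounds[j], j - i - 1L)
    }
  }
  m <- do.call(rbind, out)
  data.frame(peptide = substring(protein, m[, 1], m[, 2]),
             start = m[, 1], end = m[, 2], missed_cleavages = m[, 3],
             stringsAsFactors = FALSE)
}

#' Find extension-specific tryptic peptides
#'
#' Digests all 20 readthrough variants and flags peptides that (a) overlap
#' the readthrough residue or the ISR-encoded extension and (b) occur
#' nowhere in the background proteome nor within the canonical protein
#' itself — the peptides whose detection by mass spectrometry uniquely
#' evidences readthrough. Uniqueness is exact substring matching; with
#' `il_equivalent = TRUE` isoleucine and leucine are treated as
#' indistinguishable (as they are by mass).
#'
#' @param db A `readthrough_db`.
#' @param proteome Named character vector or [Biostrings::AAStringSet] of
#'   background proteins.
#' @param max_missed Maximum missed cleavages (default 5).
#' @param min_len,max_len Peptide length bounds for reporting (defaults
#'   7 and 40, a typical search range); set `max_len = Inf` and
#'   `min_len = 1` for unbounded output.
#' @param rule Trypsin rule, see [tryptic_digest()].
#' @param il_equivalent Treat I and L as equivalent when matching
#'   (default FALSE).
#' @return data.frame: `peptide`, `parent` (variant id), `start`, `end`,
#'   `missed_cleavages`, `overlaps_extension`, `unique_to_extension`.
#' @export
find_extension_specific_peptides <- function(db, proteome,
                                             max_missed = 5L,
                                             min_len = 7L, max_len = 40L,
                                             rule = "trypsin",
                                             il_equivalent = FALSE) {
  stopifnot(inherits(db, "readthrough_db"))
  proteome <- as.character(proteome)
  base_len <- nchar(db$base_protein)

  per_variant <- lapply(names(db$variants), function(id) {
    d <- tryptic_digest(db$variants[[id]], max_missed = max_missed,
                        rule = rule)
    d$parent <- id
    d
  })
  pep <- do.call(rbind, per_variant)
  plen <- nchar(pep$peptide)
  pep <- pep[plen >= min_len & plen <= max_len, , drop = FALSE]
  # positions > base_len are the readthrough residue or the extension
  pep$overlaps_extension <- pep$end > base_len

  canon <- function(x) if (il_equivalent) gsub("I", "L", x) else x
  background <- canon(c(unname(proteome), base = db$base_protein))
  pep$unique_to_extension <- pep$overlaps_extension &
    !vapply(canon(pep$peptide), function(p)
      any(grepl(p, background, fixed = TRUE)), logical(1))
  rownames(pep) <- NULL
  pep[, c("peptide", "parent", "start", "end", "missed_cleavages",
          "overlaps_extension", "unique_to_extension")]
}
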