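#' Metagene profile around the start codon
#'
#' Pools P-site offsets relative to the A of the start codon (offset 0)
#' across transcripts, per fragment length, over a fixed window. Cell
#' values are log(count + 1), the transform used for heat-map display of
#' 3-nucleotide periodicity. In periodic (actively translated) data the
#' nonzero columns cluster on one residue class mod 3 for the ribosome-
#' protected fragment lengths.
#'
#' @param footprints data.frame with `transcript_id`, `p_site`, `length`.
#' @param annotations Named list of `transcript_annotation` objects (names
#'   are transcript ids), or a single annotation.
#' @param window Integer length-2 vector of offsets relative to the A of
#'   ATG, default `c(-24, 62)` (87 columns).
#' @return A `metagene_profile`: matrix of log1p counts, rows = fragment
#'   lengths (sorted), columns = offsets. Raw counts are kept in
#'   `attr(, "counts")`.
#' @export
metagene_start_profile <- function(footprints, annotations,
                                   window = c(-24L, 62L)) {
  if (inherits(annotations, "transcript_annotation"))
    annotations <- stats::setNames(list(annotations), annotations$transcript_id)
  offsets <- window[1]:window[2]
  lens <- if (nrow(footprints)) sort(unique(footprints$length)) else integer(0)
  counts <- matrix(0L, nrow = length(lens), ncol = length(offsets),
                   dimnames = list(lens, offsets))
  if (nrow(footprints)) {
    cds_start <- vapply(annotations, `[[`, integer(1), "cds_start")
    off <- footprints$p_site - cds_start[footprints$transcript_id]
    keep <- !is.na(off) & off >= window[1] & off <= window[2]
    if (any(keep)) {
      tab <- table(factor(footprints$length[keep], levels = lens),
                   factor(off[keep], levels = offsets))
      counts <- matrix(as.integer(tab), nrow = length(lens),
                       dimnames = dimnames(counts))
    }
  }
  structure(log1p(counts), counts = counts, class = c("metagene_profile", "matrix"))
}

#' Select fragment lengths showing 3-nt periodicity
#'
#' By default returns the fixed set 27-29 nt, the fragment lengths with
#' clear 3-nucleotide periodicity in typical ribosome profiling libraries.
#' With `auto = TRUE` the set is detected from a metagene profile instead:
#' a length is kept when, among its P-sites at in-CDS offsets (>= 0), more
#' than 40% fall in frame 0 (offset mod 3 == 0). The 0.4 cutoff is a
#' heuristic well above the frame-uniform expectation of 1/3.
#'
#' @param profile A `metagene_profile` (required for `auto = TRUE`).
#' @param default Fixed set returned when `auto = FALSE`.
#' @param auto Detect periodic lengths from the profile.
#' @param min_frame0 Frame-0 share threshold for auto mode (default 0.4).
#' @return Integer vector of fragment lengths; empty (with a warning) if
#'   auto mode finds none.
#' @export
select_periodic_lengths <- function(profile = NULL, default = 27:29,
                                    auto = FALSE, min_frame0 = 0.4) {
  if (!auto) return(as.integer(default))
  stopifnot(inherits(profile, "metagene_profile"))
  counts <- attr(profile, "counts")
  offs <- as.integer(colnames(counts))
  in_cds <- offs >= 0L
  share0 <- apply(counts[, in_cds, drop = FALSE], 1L, function(row) {
    tot <- sum(row)
    if (tot == 0) return(NA_real_)
    sum(row[offs[in_cds] %% 3L == 0L]) / tot
  })
  sel <- as.integer(rownames(counts))[!is.na(share0) & share0 > min_frame0]
  if (length(sel) == 0L)
    warning("no fragment length shows frame-0 enrichment above ", min_frame0)
  sel
}

#' Reading-frame proportions of P-sites in a region
#'
#' The frame of a P-site p is `(p - cds_start) mod 3`; offsets in the UTRs
#' inherit the CDS frame grid, which is what makes frame bias in the ISR
#' interpretable as continued translation in the CDS frame. Proportions
#' are computed over reads whose P-site lies in the region's counting
#' positions (exclusion zones applied) and whose fragment length passes
#' the filter.
#'
#' @param footprints data.frame with `p_site` and `length` columns.
#' @param region Region name (`"cds"`, `"isr"`, `"utr3_rest"`, `"utr5"`).
#' @param region_map A `region_map`.
#' @param cds_start CDS start position (1-based) defining frame 0.
#' @param lengths Optional fragment-length filter (e.g. `27:29`); `NULL`
#'   keeps all lengths.
#' @return A `frame_profile` list: `region`, `n`, `f0`, `f1`, `f2`, `cv`.
#'   With no reads in the region, proportions and cv are `NA`.
#' @export
frame_proportions <- function(footprints, region, region_map, cds_start,
                              lengths = NULL) {
  stopifnot(inherits(region_map, "region_map"))
  r <- region_map$regions
  row <- r[r$region == region, ]
  if (nrow(row) != 1L) stop("unknown region: ", region)
  p <- footprints$p_site
  keep <- p >= row$start & p <= row$end
  if (!is.null(lengths)) keep <- keep & footprints$length %in% lengths
  keep <- keep & !p %in% excluded_positions(region_map$excluded)
  p <- p[keep]
  n <- length(p)
  if (n == 0L)
    return(structure(list(region = region, n = 0L, f0 = NA_real_,
                          f1 = NA_real_, f2 = NA_real_, cv = NA_real_),
                     class = "frame_profile"))
  frames <- (p - cds_start) %% 3L
  props <- as.numeric(table(factor(frames, levels = 0:2)) / n)
  structure(list(region = region, n = n,
                 f0 = props[1], f1 = props[2], f2 = props[3],
                 cv = coefficient_of_variation(props)),
            class = "frame_profile")
}

#' Coefficient of variation of the three frame proportions
#'
#' CV = sample standard deviation (n - 1 divisor) of the three proportions
#' divided by their mean. When proportions sum to 1 the mean is exactly
#' 1/3, so CV = 3 * sd. A frame-uniform region gives CV 0; complete
#' confinement to one frame gives sqrt(3). With `population = TRUE` the
#' n-divisor standard deviation is used instead (smaller by sqrt(2/3)).
#'
#' @param proportions Numeric vector of three frame proportions.
#' @param population Use the population (divisor n) standard deviation.
#' @return Non-negative scalar.
#' @examples
#' coefficient_of_variation(c(1, 0, 0))  # sqrt(3)
#' @export
coefficient_of_variation <- function(proportions, population = FALSE) {
  stopifnot(length(proportions) == 3L, all(proportions >= 0))
  s <- stats::sd(proportions)
  if (population) s <- s * sqrt(2 / 3)
  s / mean(proportions)
}

#' Per-region frame table
#'
#' Runs [frame_proportions()] over the standard regions and returns a
#' data.frame (region, n, f0, f1, f2, cv) ready for TSV export.
#'
#' @param footprints data.frame of footprints on the transcript.
#' @param annotation A `transcript_annotation`.
#' @param lengths Fragment-length filter, default 27:29.
#' @param regions Regions to tabulate.
#' @return data.frame with one row per region.
#' @export
frame_table <- function(footprints, annotation, lengths = 27:29,
                        regions = c("cds", "isr", "utr3_rest")) {
  rm <- partition_regions(annotation)
  rows <- lapply(regions, function(rg) {
    fp <- frame_proportions(footprints, rg, rm, annotation$cds_start, lengths)
    data.frame(region = rg, n = fp$n, f0 = fp$f0, f1 = fp$f1, f2 = fp$f2,
               cv = fp$cv)
  })
  do.call(rbind, rows)
}
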