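#' Count P-sites by transcript region
#'
#' Assigns each footprint's P-site to exactly one counting region of the
#' transcript (5'UTR, CDS, ISR, distal 3'UTR) or to the excluded set. The
#' canonical stop codon counts towards the CDS and the downstream in-frame
#' stop towards the ISR; P-sites falling in an exclusion zone are counted
#' in no region.
#'
#' @param footprints data.frame with a `p_site` column (and optionally
#'   `transcript_id`, checked against the map if present).
#' @param region_map A `region_map` from [partition_regions()].
#' @return Named integer vector: `n_utr5`, `n_cds`, `n_isr`, `n_utr3_rest`,
#'   `n_excluded`.
#' @export
count_by_region <- function(footprints, region_map) {
  stopifnot(inherits(region_map, "region_map"))
  p <- footprints$p_site
  if (!is.null(footprints$transcript_id) && nrow(footprints) &&
      any(footprints$transcript_id != region_map$transcript_id))
    stop("footprints reference a different transcript than the region map")

  ex_pos <- excluded_positions(region_map$excluded)
  excluded <- p %in% ex_pos
  r <- region_map$regions
  counts <- vapply(seq_len(nrow(r)), function(i)
    sum(!excluded & p >= r$start[i] & p <= r$end[i]), integer(1))
  names(counts) <- paste0("n_", r$region)
  c(counts, n_excluded = sum(excluded))
}

#' Count footprints in the second half of the ISR
#'
#' The readthrough criteria require at least one read in the second half of
#' the inter-stop codon region, ruling out datasets whose ISR signal is
#' confined to termination-proximal positions. The split is on the nominal
#' ISR (between the two stops, excluding both): for an ISR of n nt the
#' second half begins ceiling(n/2) nt into it, and counting extends
#' through the downstream stop codon. Exclusion zones are not applied
#' here — the criterion asks whether such a read exists at all.
#'
#' @param footprints data.frame with a `p_site` column.
#' @param annotation A `transcript_annotation`.
#' @return Integer count.
#' @export
second_half_count <- function(footprints, annotation) {
  stopifnot(inherits(annotation, "transcript_annotation"))
  n <- isr_length(annotation)
  half_start <- annotation$isr_start + as.integer(ceiling(n / 2))
  p <- footprints$p_site
  sum(p >= half_start & p <= annotation$stop2_end)
}

#' Fraction of the ISR covered by footprints
#'
#' Computes the fraction of nominal ISR positions covered by the union of
#' full footprint spans (the criterion concerns coverage by footprints, not
#' P-site placement). A zero-length ISR has no defined coverage and the
#' transcript automatically fails the coverage criterion.
#'
#' @param footprints data.frame with `start` and `end` columns.
#' @param annotation A `transcript_annotation`.
#' @return Fraction in \[0, 1\].
#' @export
isr_coverage <- function(footprints, annotation) {
  stopifnot(inherits(annotation, "transcript_annotation"))
  n <- isr_length(annotation)
  if (n == 0L) stop("ZeroLengthIsr: coverage undefined for a 0-nt ISR")
  if (nrow(footprints) == 0L) return(0)
  spans <- IRanges::reduce(IRanges::IRanges(footprints$start, footprints$end))
  isr <- IRanges::IRanges(annotation$isr_start, annotation$isr_end)
  covered <- sum(IRanges::width(IRanges::intersect(spans, isr)))
  covered / n
}

#' Default thresholds for the four readthrough criteria
#'
#' @param min_cds_reads Minimum P-site count in the CDS (default 45).
#' @param min_second_half_reads Minimum reads in the second half of the ISR
#'   (default 1).
#' @param min_isr_coverage Minimum fraction of the ISR covered by
#'   footprints (default 0.10).
#' @param min_density_ratio Minimum ISR / distal-3'UTR footprint density
#'   ratio (default 3).
#' @return A `readthrough_thresholds` list.
#' @export
readthrough_thresholds <- function(min_cds_reads = 45L,
                                   min_second_half_reads = 1L,
                                   min_isr_coverage = 0.10,
                                   min_density_ratio = 3.0) {
  stopifnot(min_cds_reads > 0, min_second_half_reads > 0,
            min_isr_coverage > 0, min_density_ratio > 0)
  structure(list(min_cds_reads = min_cds_reads,
                 min_second_half_reads = min_second_half_reads,
                 min_isr_coverage = min_isr_coverage,
                 min_density_ratio = min_density_ratio),
            class = "readthrough_thresholds")
}

#' Per-region statistics for readthrough calling
#'
#' Convenience wrapper computing everything [call_readthrough()] needs:
#' region counts, footprint densities over effective lengths, the
#' second-half ISR count and the ISR coverage fraction. Densities divide
#' the P-site count of a region by its effective (exclusion-adjusted)
#' length; set `use_effective_lengths = FALSE` to divide by nominal region
#' lengths instead.
#'
#' @param footprints data.frame of footprints on one transcript.
#' @param annotation A `transcript_annotation`.
#' @param region_map Optional precomputed `region_map` (default:
#'   `partition_regions(annotation)`).
#' @param use_effective_lengths Use exclusion-adjusted denominators
#'   (default TRUE).
#' @return A `region_stats` list: `counts`, `densities`,
#'   `n_isr_second_half`, `isr_coverage_fraction`, `region_map`.
#' @export
region_stats <- function(footprints, annotation, region_map = NULL,
                         use_effective_lengths = TRUE) {
  if (is.null(region_map)) region_map <- partition_regions(annotation)
  counts <- count_by_region(footprints, region_map)
  r <- region_map$regions
  denom <- if (use_effective_lengths) r$effective_length else r$nominal_length
  densities <- ifelse(denom > 0,
                      counts[paste0("n_", r$region)] / denom, NA_real_)
  names(densities) <- r$region
  structure(list(
    counts = counts,
    densities = densities,
    n_isr_second_half = second_half_count(footprints, annotation),
    isr_coverage_fraction = if (isr_length(annotation) > 0)
      isr_coverage(footprints, annotation) else NA_real_,
    region_map = region_map
  ), class = "region_stats")
}

#' Apply the four-criterion readthrough filter
#'
#' A transcript/dataset is called positive for translational readthrough
#' when all four criteria hold:
#' 1. at least `min_cds_reads` P-sites in the coding sequence;
#' 2. at least one read in the second half of the ISR;
#' 3. at least 10% of the ISR covered by ribosomal footprints;
#' 4. at least a threefold higher footprint density in the ISR than in the
#'    rest of the 3'UTR.
#'
#' The density ratio is `+Inf` when the distal 3'UTR density is zero but
#' the ISR density is positive, and 0 when the ISR density is zero, so the
#' comparison never produces `NaN`. All comparisons are inclusive (>=).
#'
#' @param stats A `region_stats` object.
#' @param thresholds A `readthrough_thresholds` (defaults used if omitted).
#' @return A `readthrough_call` list: the four criterion booleans
#'   (`c1_cds_reads`, `c2_second_half`, `c3_coverage`, `c4_density_ratio`),
#'   `density_ratio`, and `verdict` (their conjunction).
#' @export
call_readthrough <- function(stats, thresholds = readthrough_thresholds()) {
  stopifnot(inherits(stats, "region_stats"),
            inherits(thresholds, "readthrough_thresholds"))
  d_isr <- stats$densities[["isr"]]
  d_utr3 <- stats$densities[["utr3_rest"]]
  ratio <- if (is.na(d_isr) || d_isr == 0) 0
           else if (is.na(d_utr3) || d_utr3 == 0) Inf
           else d_isr / d_utr3

  cov <- stats$isr_coverage_fraction
  crit <- c(
    c1_cds_reads = unname(stats$counts["n_cds"] >= thresholds$min_cds_reads),
    c2_second_half = stats$n_isr_second_half >= thresholds$min_second_half_reads,
    c3_coverage = !is.na(cov) && cov >= thresholds$min_isr_coverage,
    c4_density_ratio = ratio >= thresholds$min_density_ratio
  )
  structure(list(criteria = crit, density_ratio = ratio,
                 verdict = all(crit)), class = "readthrough_call")
}

#' @export
print.readthrough_call <- function(x, ...) {
  cat("Readthrough call:", if (x$verdict) "POSITIVE" else "negative", "\n")
  cat("  ISR/3'UTR density ratio:", format(x$density_ratio, digits = 4), "\n")
  for (nm in names(x$criteria))
    cat("  ", nm, ":", x$criteria[[nm]], "\n")
  invisible(x)
}

#' One-line readthrough report for a transcript
#'
#' Runs [region_stats()] and [call_readthrough()] and flattens the result
#' into a single-row data.frame suitable for a per-transcript TSV report.
#' Both exclusion-adjusted and nominal-length density ratios are reported.
#'
#' @param footprints data.frame of footprints on the transcript.
#' @param annotation A `transcript_annotation`.
#' @param thresholds A `readthrough_thresholds`.
#' @return One-row data.frame.
#' @export
readthrough_report <- function(footprints, annotation,
                               thresholds = readthrough_thresholds()) {
  st <- region_stats(footprints, annotation)
  st_nom <- region_stats(footprints, annotation, use_effective_lengths = FALSE)
  call <- call_readthrough(st, thresholds)
  call_nom <- call_readthrough(st_nom, thresholds)
  data.frame(
    transcript_id = annotation$transcript_id,
    t(st$counts),
    n_isr_second_half = st$n_isr_second_half,
    isr_coverage = st$isr_coverage_fraction,
    density_ratio = call$density_ratio,
    density_ratio_nominal = call_nom$density_ratio,
    t(call$criteria),
    verdict = call$verdict
  )
}
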