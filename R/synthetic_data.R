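#' Specification for a synthetic readthrough dataset
#'
#' Bundles the parameters of the synthetic transcript and footprint
#' generator. The defaults emulate a human AGO1-like mRNA — a 2,574-nt CDS
#' followed by a 99-nt inter-stop codon region — carrying a ribosome
#' profiling signal like the one seen in readthrough-positive libraries:
#' footprint density far higher in the CDS than anywhere else, a 20-fold
#' ISR vs distal-3'UTR density excess, a majority of translated-region
#' P-sites in frame 0, and fragment lengths uniform on 27-29 nt.
#'
#' @param utr5_len,cds_len,isr_len,utr3_rest_len Region lengths in nt.
#'   `cds_len` includes the canonical stop and must be a multiple of 3
#'   (>= 6); `isr_len` is the nominal inter-stop region (multiple of 3,
#'   may be 0); `utr3_rest_len` is the 3'UTR downstream of the second
#'   stop.
#' @param region_densities Named expected read weights per nt for `utr5`,
#'   `cds`, `isr`, `utr3_rest` (relative scale; reads are allocated with
#'   probability proportional to density x region length).
#' @param frame_probs P-site frame probabilities (frame 0, 1, 2) within
#'   the CDS and ISR; the distal 3'UTR and 5'UTR are frame-uniform.
#' @param fragment_lengths,fragment_probs Discrete footprint-length
#'   distribution; lengths must lie in 24-36.
#' @param n_reads Total footprints to simulate.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(utr5_len = 250L, cds_len = 2574L, isr_len = 99L,
                     utr3_rest_len = 1500L,
                     region_densities = c(utr5 = 0.05, cds = 1,
                                          isr = 0.1, utr3_rest = 0.005),
                     frame_probs = c(0.6, 0.2, 0.2),
                     fragment_lengths = 27:29,
                     fragment_probs = rep(1 / 3, 3),
                     n_reads = 20000L, seed = 1L) {
  stopifnot(cds_len >= 6L, cds_len %% 3L == 0L,
            isr_len >= 0L, isr_len %% 3L == 0L,
            utr5_len >= 0L, utr3_rest_len >= 0L,
            all(region_densities >= 0),
            all(c("utr5", "cds", "isr", "utr3_rest") %in%
                  names(region_densities)),
            length(frame_probs) == 3L, all(frame_probs >= 0),
            abs(sum(frame_probs) - 1) < 1e-9,
            all(fragment_lengths >= 24L), all(fragment_lengths <= 36L),
            length(fragment_probs) == length(fragment_lengths),
            abs(sum(fragment_probs) - 1) < 1e-9,
            n_reads >= 0L, seed == as.integer(seed))
  structure(list(utr5_len = as.integer(utr5_len),
                 cds_len = as.integer(cds_len),
                 isr_len = as.integer(isr_len),
                 utr3_rest_len = as.integer(utr3_rest_len),
                 region_densities = region_densities,
                 frame_probs = frame_probs,
                 fragment_lengths = as.integer(fragment_lengths),
                 fragment_probs = fragment_probs,
                 n_reads = as.integer(n_reads),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
                  c("A", "C", "G", "T"), paste0)),
  c("TAA", "TAG", "TGA"))

#' Generate a synthetic transcript with a designed ISR
#'
#' Builds a transcript with ATG at the CDS start, TGA as the canonical
#' stop, a stop-free ISR of the designed length, TAA as the downstream
#' in-frame stop, and random UTRs. CDS and ISR codons are drawn from the
#' sense codons only, so no unintended in-frame stop can arise. Every
#' 24-mer in the sequence is required to be unique (resampling if not), so
#' that exact matching of any footprint of length >= 24 is unambiguous.
#'
#' @param spec A [sim_spec()].
#' @param max_attempts Resampling attempts before giving up (tiny
#'   transcripts can be unsatisfiable).
#' @return List: `sequence` (character), `annotation`
#'   (`transcript_annotation`). Deterministic given `spec$seed`.
#' @export
make_transcript <- function(spec, max_attempts = 25L) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    for (attempt in seq_len(max_attempts)) {
      utr5 <- paste(sample(c("A", "C", "G", "T"), spec$utr5_len,
                           replace = TRUE), collapse = "")
      n_body <- spec$cds_len %/% 3L - 2L  # codons between ATG and stop
      cds <- paste0("ATG",
                    paste(sample(SENSE_CODONS, n_body, replace = TRUE),
                          collapse = ""),
                    "TGA")
      isr <- if (spec$isr_len > 0L)
        paste(sample(SENSE_CODONS, spec$isr_len %/% 3L, replace = TRUE),
              collapse = "") else ""
      utr3 <- paste(sample(c("A", "C", "G", "T"), spec$utr3_rest_len,
                           replace = TRUE), collapse = "")
      sequence <- paste0(utr5, cds, isr, "TAA", utr3)

      L <- nchar(sequence)
      if (L >= 24L) {
        kmers <- substring(sequence, 1:(L - 23L), 24:L)
        if (anyDuplicated(kmers)) next
      }
      ann <- annotate_isr(sequence,
                          cds_start = spec$utr5_len + 1L,
                          cds_end = spec$utr5_len + spec$cds_len,
                          transcript_id = paste0("synth_seed", spec$seed))
      return(list(sequence = sequence, annotation = ann))
    }
    stop("UnsatisfiableSpec: could not build a transcript with unique ",
         "24-mers in ", max_attempts, " attempts")
  })
}

#' Simulate ribosome footprints on a synthetic transcript
#'
#' Allocates `n_reads` footprints to the counting regions with probability
#' proportional to density x region length. Within the CDS and ISR the
#' P-site frame is drawn from `frame_probs` (positions on the CDS frame
#' grid); the UTRs are position-uniform. Each read's fragment length is
#' drawn from the configured distribution and the read is placed so that
#' its central-nucleotide P-site (left-central for even lengths) falls at
#' the drawn position; placements that would run off the transcript are
#' redrawn. Reads are emitted verbatim from the transcript, so mapping
#' them back is exact.
#'
#' @param transcript A list from [make_transcript()].
#' @param spec The [sim_spec()] used to build it.
#' @param seed Seed for the footprint draw; defaults to `spec$seed + 1`
#'   so that sequence and reads come from distinct streams of the same
#'   specification.
#' @return List: `reads` (named character vector) and `truth` (data.frame
#'   `read_id`, `region`, `frame`, `start`, `end`, `length`, `p_site`).
#' @export
simulate_footprints <- function(transcript, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  ann <- transcript$annotation
  rm <- partition_regions(ann, exclusion_nt = 0L)
  r <- rm$regions
  with_seed(seed, {
    dens <- spec$region_densities[r$region]
    w <- dens * r$nominal_length
    if (sum(w) == 0 || spec$n_reads == 0L)
      return(list(reads = character(0), truth = empty_truth()))
    n_region <- as.vector(stats::rmultinom(1, spec$n_reads, w / sum(w)))
    names(n_region) <- r$region

    parts <- lapply(seq_len(nrow(r)), function(i) {
      n <- n_region[i]
      if (n == 0L) return(NULL)
      pos_all <- r$start[i]:r$end[i]
      region <- r$region[i]
      if (region %in% c("cds", "isr")) {
        frame_of <- (pos_all - ann$cds_start) %% 3L
        nf <- as.vector(stats::rmultinom(1, n, spec$frame_probs))
        p <- unlist(lapply(0:2, function(f) {
          cand <- pos_all[frame_of == f]
          if (nf[f + 1L] == 0L || length(cand) == 0L) return(integer(0))
          cand[sample.int(length(cand), nf[f + 1L], replace = TRUE)]
        }))
        p <- p[sample.int(length(p))]
      } else {
        p <- pos_all[sample.int(length(pos_all), n, replace = TRUE)]
      }
      data.frame(region = region, p_site = p, stringsAsFactors = FALSE)
    })
    truth <- do.call(rbind, parts)

    n <- nrow(truth)
    len <- sample(spec$fragment_lengths, n, replace = TRUE,
                  prob = spec$fragment_probs)
    offset <- ifelse(len %% 2L == 1L, (len - 1L) %/% 2L, len %/% 2L - 1L)
    start <- truth$p_site - offset
    end <- start + len - 1L
    # redraw fragment lengths for placements running off the transcript
    bad <- which(start < 1L | end > ann$length)
    for (i in bad) {
      for (try in 1:100) {
        l2 <- sample(spec$fragment_lengths, 1L, prob = spec$fragment_probs)
        o2 <- if (l2 %% 2L == 1L) (l2 - 1L) %/% 2L else l2 %/% 2L - 1L
        s2 <- truth$p_site[i] - o2
        if (s2 >= 1L && s2 + l2 - 1L <= ann$length) {
          start[i] <- s2; end[i] <- s2 + l2 - 1L; len[i] <- l2
          break
        }
      }
    }
    keep <- start >= 1L & end <= ann$length
    truth <- truth[keep, , drop = FALSE]
    start <- start[keep]; end <- end[keep]; len <- len[keep]

    truth$read_id <- sprintf("sim%06d", seq_len(nrow(truth)))
    truth$start <- start
    truth$end <- end
    truth$length <- len
    truth$frame <- (truth$p_site - ann$cds_start) %% 3L
    truth <- truth[, c("read_id", "region", "frame", "start", "end",
                       "length", "p_site")]
    reads <- stats::setNames(substring(transcript$sequence, start, end),
                             truth$read_id)
    list(reads = reads, truth = truth)
  })
}

empty_truth <- function() {
  data.frame(read_id = character(0), region = character(0),
             frame = integer(0), start = integer(0), end = integer(0),
             length = integer(0), p_site = integer(0))
}

#' Simulate paired dual-luciferase readouts
#'
#' Generates a stop-containing test construct and a no-stop control with
#' multiplicative log-normal noise (luminescence is positive and
#' right-skewed), parameterized by a coefficient of variation. The
#' expected FLuc/RLuc ratio is `true_rt_fraction` for the test set and 1
#' for the control, so the expected percent readthrough is
#' `100 * true_rt_fraction`.
#'
#' @param true_rt_fraction True readthrough fraction (0 < x <= 1).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives noiseless readouts).
#' @param n_replicates Replicates per construct.
#' @param seed Integer seed.
#' @param rluc_scale Typical RLuc luminescence magnitude (arbitrary units).
#' @return List of two [reporter_set()]s: `test` and `control`.
#' @export
simulate_reporter <- function(true_rt_fraction, noise_cv = 0.1,
                              n_replicates = 3L, seed = 1L,
                              rluc_scale = 1e5) {
  stopifnot(true_rt_fraction > 0, true_rt_fraction <= 1, noise_cv >= 0,
            n_replicates >= 1L)
  sigma <- sqrt(log1p(noise_cv^2))
  with_seed(seed, {
    noise <- function(n) exp(stats::rnorm(n, -sigma^2 / 2, sigma))
    rluc_t <- rluc_scale * noise(n_replicates)
    rluc_c <- rluc_scale * noise(n_replicates)
    test <- reporter_set(rluc_t * true_rt_fraction * noise(n_replicates),
                         rluc_t, condition = "stop-ISR")
    control <- reporter_set(rluc_c * noise(n_replicates), rluc_c,
                            condition = "no-stop-ISR",
                            is_no_stop_control = TRUE)
    list(test = test, control = control)
  })
}
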