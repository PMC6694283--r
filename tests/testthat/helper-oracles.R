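# Independent oracles and small fixture builders used across the suite.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force sliding-window exact matcher (position-by-position compare)
oracle_match <- function(read, transcript, min_len = 24L) {
  l <- nchar(read)
  L <- nchar(transcript)
  if (l < min_len || l > L) return(integer(0))
  starts <- 1:(L - l + 1L)
  starts[substring(transcript, starts, starts + l - 1L) == read]
}

# brute-force tryptic peptide enumerator: every substring that starts and
# ends at a cleavage boundary and spans <= max_missed internal cut sites
oracle_digest <- function(protein, max_missed, proline_rule = TRUE) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  is_cut <- function(i) {  # cut between position i and i+1
    if (i < 1 || i >= n) return(FALSE)
    res[i] %in% c("K", "R") && (!proline_rule || res[i + 1] != "P")
  }
  out <- list()
  for (s in 1:n) for (e in s:n) {
    if (s > 1 && !is_cut(s - 1)) next
    if (e < n && !is_cut(e)) next
    internal <- if (e > s) sum(vapply(s:(e - 1), is_cut, logical(1))) else 0L
    if (internal > max_missed) next
    out[[length(out) + 1L]] <- data.frame(
      peptide = paste(res[s:e], collapse = ""), start = s, end = e,
      missed_cleavages = internal)
  }
  do.call(rbind, out)
}

# standard small transcript used by region/caller tests:
# 100 nt 5'UTR, 300 nt CDS, 99 nt ISR, 498 nt distal 3'UTR (L = 1000)
fixture_transcript <- function(seed = 7L) {
  make_transcript(sim_spec(utr5_len = 100L, cds_len = 300L, isr_len = 99L,
                           utr3_rest_len = 498L, seed = seed))
}

# footprint table from bare P-sites (spans irrelevant to counting tests)
fp_at <- function(p_sites, len = 29L) {
  p_sites <- as.integer(p_sites)
  start <- p_sites - (len - 1L) %/% 2L
  data.frame(read_id = sprintf("r%03d", seq_along(p_sites)),
             start = start, end = start + len - 1L,
             length = rep(len, length(p_sites)), p_site = p_sites)
}
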