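#' Construct a set of dual-luciferase replicate readouts
#'
#' @param fluc,rluc Positive luminescence readouts, one value per
#'   replicate (equal lengths).
#' @param condition Condition label.
#' @param is_no_stop_control Flag marking the no-stop (sense-codon)
#'   normalization construct.
#' @return A `reporter_set` list with a `ratio` element (`fluc / rluc`).
#' @export
reporter_set <- function(fluc, rluc, condition = "",
                         is_no_stop_control = FALSE) {
  stopifnot(length(fluc) == length(rluc), length(fluc) >= 1L)
  if (any(fluc <= 0) || any(rluc <= 0))
    stop("NonPositiveReadout: luminescence readouts must be positive")
  structure(list(condition = condition, fluc = fluc, rluc = rluc,
                 ratio = fluc / rluc,
                 is_no_stop_control = is_no_stop_control),
            class = "reporter_set")
}

#' Percent readthrough from a dual-luciferase assay
#'
#' Readthrough efficiency of a stop-containing reporter is the
#' RLuc-normalized FLuc activity relative to a matched no-stop construct
#' (a sense codon in place of the stop), in percent:
#' `100 * mean(fluc/rluc of test) / mean(fluc/rluc of control)`.
#' The default uses the ratio of replicate means (stable for small
#' replicate counts); `mode = "mean-of-ratios"` averages per-replicate
#' test/control pairings instead (requires equal replicate numbers). The
#' standard error is propagated from the replicate SEs of the two means by
#' the delta method.
#'
#' @param test `reporter_set` for the stop-containing construct.
#' @param control_no_stop `reporter_set` for the no-stop control.
#' @param mode `"ratio-of-means"` (default) or `"mean-of-ratios"`.
#' @return List: `percent`, `se`, `mode`.
#' @export
percent_readthrough <- function(test, control_no_stop,
                                mode = c("ratio-of-means", "mean-of-ratios")) {
  mode <- match.arg(mode)
  stopifnot(inherits(test, "reporter_set"),
            inherits(control_no_stop, "reporter_set"))
  rt <- test$ratio
  rc <- control_no_stop$ratio
  se_of <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  if (mode == "ratio-of-means") {
    est <- mean(rt) / mean(rc)
    # delta method for a ratio of independent means
    se <- est * sqrt((se_of(rt) / mean(rt))^2 + (se_of(rc) / mean(rc))^2)
  } else {
    stopifnot(length(rt) == length(rc))
    ratios <- rt / rc
    est <- mean(ratios)
    se <- se_of(ratios)
  }
  list(percent = 100 * est, se = 100 * se, mode = mode)
}

#' Percent change in normalized reporter activity
#'
#' For tethering-style assays where the regulated reporter is RLuc and
#' FLuc is the transfection control, the normalized activity of a
#' replicate is `rluc / fluc`; the result is
#' `100 * (mean(condition) / mean(reference) - 1)`.
#'
#' @param condition,reference `reporter_set` objects, or numeric vectors
#'   of already-normalized replicate activities.
#' @return Percent change (negative = repression relative to reference).
#' @export
normalized_reporter_change <- function(condition, reference) {
  norm <- function(x) {
    if (inherits(x, "reporter_set")) x$rluc / x$fluc
    else if (is.numeric(x) && length(x) >= 1L && all(x > 0)) x
    else stop("NonPositiveReadout: expected a reporter_set or positive numerics")
  }
  100 * (mean(norm(condition)) / mean(norm(reference)) - 1)
}

#' Overlap statistics for two identifier sets
#'
#' Exact intersection counts for e.g. the miRNA repertoires bound by two
#' protein isoforms, with the shared fraction expressed as a percentage of
#' each set. Duplicated identifiers within a set are counted once.
#'
#' @param set_a,set_b Vectors of identifiers.
#' @return An `overlap_result` list: `n_a`, `n_b`, `n_shared`, `pct_of_a`,
#'   `pct_of_b` (full precision; the print method rounds to the nearest
#'   integer percent).
#' @export
set_overlap_stats <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  shared <- length(intersect(a, b))
  structure(list(
    n_a = length(a), n_b = length(b), n_shared = shared,
    pct_of_a = if (length(a)) 100 * shared / length(a) else 0,
    pct_of_b = if (length(b)) 100 * shared / length(b) else 0
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("%d/%d (%d%%) of set A and %d/%d (%d%%) of set B shared\n",
              x$n_shared, x$n_a, round(x$pct_of_a),
              x$n_shared, x$n_b, round(x$pct_of_b)))
  invisible(x)
}

#' Read dual-luciferase readouts from TSV
#'
#' Expects columns `condition`, `replicate`, `fluc`, `rluc`; returns a
#' named list of [reporter_set()] objects, one per condition.
#'
#' @param path TSV file path.
#' @return Named list of `reporter_set`s.
#' @export
read_reporter_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition", "fluc", "rluc")
  if (!all(need %in% names(tab)))
    stop("reporter table must have columns: ", paste(need, collapse = ", "))
  sets <- lapply(split(tab, tab$condition), function(d)
    reporter_set(d$fluc, d$rluc, condition = d$condition[1]))
  sets
}
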