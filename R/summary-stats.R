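#' Total genome coverage of an annotation set
#'
#' Two coverage notions are supported: the sum of record lengths
#' (`"sum_lengths"`, the default reporting mode) and the number of
#' genomic base pairs covered by the union of the intervals per
#' chromosome (`"merged_union"`). The two agree exactly when no records
#' within the set overlap each other; `merged_union <= sum_lengths`
#' always.
#'
#' @param set An [annotation_set()].
#' @param mode `"sum_lengths"` or `"merged_union"`.
#' @return Coverage in bp (numeric scalar).
#' @export
total_coverage <- function(set, mode = c("sum_lengths", "merged_union")) {
  stopifnot(inherits(set, "annotation_set"))
  mode <- match.arg(mode)
  if (n_records(set) == 0L) return(0)
  if (mode == "sum_lengths")
    return(sum(as.numeric(record_lengths(set))))
  sum(as.numeric(IRanges::width(GenomicRanges::reduce(.as_granges(set)))))
}

#' Record-length histogram with an overflow bucket
#'
#' Bins record lengths into uniform half-open bins `[lo, hi)` of width
#' `bin_width`, starting at 0. Records strictly longer than
#' `overflow_threshold` go to a single overflow bucket (so a record of
#' exactly the threshold length stays in the histogram). Bin counts
#' plus the overflow always sum to the total record count.
#'
#' @param set An [annotation_set()].
#' @param bin_width Bin width in bp (default 100).
#' @param overflow_threshold Lengths strictly above this go to the
#'   overflow bucket (default 2500 bp).
#' @return A list of class `length_histogram`: `bin_start`, `bin_end`,
#'   `count` (parallel vectors), `overflow_threshold`, `n_overflow`,
#'   `n_total`.
#' @export
length_histogram <- function(set, bin_width = 100L,
                             overflow_threshold = 2500L) {
  stopifnot(inherits(set, "annotation_set"), bin_width >= 1)
  lens <- record_lengths(set)
  over <- lens > overflow_threshold
  kept <- lens[!over]
  n_bins <- floor(overflow_threshold / bin_width) + 1L
  idx <- pmin(floor(kept / bin_width), n_bins - 1L) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_start = (seq_len(n_bins) - 1L) * bin_width,
                 bin_end = seq_len(n_bins) * bin_width,
                 count = counts,
                 overflow_threshold = overflow_threshold,
                 n_overflow = sum(over),
                 n_total = length(lens)),
            class = "length_histogram")
}

#' Count records strictly longer than a threshold
#'
#' @param set An [annotation_set()].
#' @param threshold Length threshold in bp; records with
#'   `length > threshold` are counted ("longer than" is strict).
#' @return Integer count.
#' @export
long_record_count <- function(set, threshold = 2500L) {
  stopifnot(inherits(set, "annotation_set"), threshold >= 0)
  sum(record_lengths(set) > threshold)
}

#' Destruction-degree summaries per stratum
#'
#' Summarizes the per-record destruction degree (percentage of
#' consensus nucleotides lost) over the records that carry the
#' attribute, stratified by the given grouping columns. Quantiles use
#' linear interpolation between order statistics
#' (`stats::quantile(type = 7)`).
#'
#' @param set An [annotation_set()].
#' @param by Character vector of grouping columns among
#'   `"superfamily"`, `"chrom"`, `"family"`; `character(0)` for one
#'   global stratum.
#' @param min_length Optional minimum record length in bp, applied
#'   before summarizing (e.g. 250 to drop short degraded fragments).
#' @param bin_width Destruction-histogram bin width in percentage
#'   points (default 2).
#' @return A list of class `destruction_summary` with elements `stats`
#'   (`data.table`: strata, `n`, `mean`, `median`, `q1`, `q3`) and
#'   `histogram` (`data.table`: strata, `bin_start`, `count`; bins
#'   half-open, the final bin closed at 100).
#' @export
destruction_summary <- function(set, by = "superfamily",
                                min_length = NULL, bin_width = 2) {
  stopifnot(inherits(set, "annotation_set"))
  r <- set$records
  if (!is.null(min_length)) r <- r[(r$end - r$start) > min_length]
  r <- r[!is.na(r$destruction)]
  if (nrow(r) == 0L) {
    return(structure(list(stats = data.table::data.table(),
                          histogram = data.table::data.table()),
                     class = "destruction_summary"))
  }
  grp <- if (length(by)) by else NULL
  stats <- r[, .(n = .N,
                 mean = mean(destruction),
                 median = stats::median(destruction),
                 q1 = unname(stats::quantile(destruction, 0.25, type = 7)),
                 q3 = unname(stats::quantile(destruction, 0.75, type = 7))),
             by = grp]
  n_bins <- ceiling(100 / bin_width)
  r2 <- data.table::copy(r)
  r2[, .bin := pmin(floor(destruction / bin_width), n_bins - 1L)]
  histogram <- r2[, .(count = .N), by = c(grp, ".bin")]
  histogram[, bin_start := .bin * bin_width]
  histogram[, .bin := NULL]
  data.table::setorderv(histogram, c(grp, "bin_start"))
  structure(list(stats = stats, histogram = histogram),
            class = "destruction_summary")
}

#' Destruction quartiles across length bins
#'
#' For each record-length bin (uniform width), reports the count and
#' the median/quartiles of the destruction degree among records with
#' the attribute — the numeric table behind length-vs-destruction box
#' plots. Empty bins in the spanned range are emitted with `n = 0` and
#' `NA` statistics.
#'
#' @param set An [annotation_set()].
#' @param bin_width Length-bin width in bp (default 100).
#' @param max_length Only records up to this length are tabulated
#'   (default 3000 bp); longer ones are dropped from the table.
#' @return `data.table` with columns `bin_start`, `bin_end`, `n`,
#'   `median`, `q1`, `q3`.
#' @export
destruction_by_length <- function(set, bin_width = 100L,
                                  max_length = 3000L) {
  stopifnot(inherits(set, "annotation_set"), bin_width >= 1)
  r <- set$records[!is.na(set$records$destruction)]
  lens <- r$end - r$start
  keep <- lens <= max_length
  r <- r[keep]; lens <- lens[keep]
  n_bins <- ceiling(max_length / bin_width)
  out <- data.table::data.table(
    bin_start = (seq_len(n_bins) - 1L) * bin_width)
  out[, bin_end := bin_start + bin_width]
  if (nrow(r)) {
    bins <- pmin(floor(lens / bin_width), n_bins - 1L) + 1L
    agg <- data.table::data.table(bin = bins, d = r$destruction)[
      , .(n = .N, median = stats::median(d),
          q1 = unname(stats::quantile(d, 0.25, type = 7)),
          q3 = unname(stats::quantile(d, 0.75, type = 7))), by = bin]
    out[, n := 0L]
    out[agg$bin, c("n", "median", "q1", "q3") :=
          list(agg$n, agg$median, agg$q1, agg$q3)]
  } else {
    out[, n := 0L]
    out[, c("median", "q1", "q3") := NA_real_]
  }
  out[]
}

#' Per-source, per-superfamily record counts and coverage
#'
#' Tabulates, for each source and superfamily, the record count, the
#' coverage (in the configured mode) and — where any record carries a
#' destruction value — the mean destruction degree. Row sums per source
#' reproduce the whole-source totals exactly.
#'
#' @param sets A list of classified [annotation_set()] objects.
#' @param coverage_mode As in [total_coverage()].
#' @return `data.table` with columns `source`, `superfamily`, `n`,
#'   `coverage_bp`, `coverage_mb` (bp / 1e6 rounded to one decimal),
#'   `mean_destruction`.
#' @export
superfamily_table <- function(sets, coverage_mode = "sum_lengths") {
  stopifnot(is.list(sets), all(vapply(sets, inherits, logical(1L),
                                      "annotation_set")))
  rows <- lapply(sets, function(s) {
    r <- s$records
    if (nrow(r) == 0L) return(NULL)
    sf_levels <- unique(r$superfamily)
    data.table::rbindlist(lapply(sf_levels, function(sf) {
      sub <- s
      sub$records <- r[r$superfamily == sf]
      data.table::data.table(
        source = s$source_name, superfamily = sf,
        n = nrow(sub$records),
        coverage_bp = total_coverage(sub, coverage_mode),
        mean_destruction = if (all(is.na(sub$records$destruction))) NA_real_
        else mean(sub$records$destruction, na.rm = TRUE))
    }))
  })
  out <- data.table::rbindlist(rows)
  if (nrow(out)) out[, coverage_mb := round(coverage_bp / 1e6, 1)]
  data.table::setorder(out, source, superfamily)
  out[]
}
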