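#' Configuration of the Sov-based matching criterion
#'
#' Two overlapping records s1, s2 are scored with the segment overlap
#' statistic
#' \deqn{Sov = (minov + \delta) / maxov}
#' where `minov` is the intersection length, `maxov` the union span
#' (total extent) of the two intervals, and the allowance term
#' \eqn{\delta} is capped. Two variants of the cap are supported:
#'
#' * `"as_printed"`: \eqn{\delta = \min(maxov - minov,\ minov,\
#'   len(s_1),\ len(s_2))}. Under this variant `Sov = 1` exactly when
#'   the overlap reaches half the length of the longer segment.
#' * `"half_capped"` (default): \eqn{\delta = \min(maxov - minov,\
#'   minov,\ len(s_1)/2,\ len(s_2)/2)}, the cap used in the original
#'   secondary-structure segment-overlap literature (halves are kept
#'   real-valued, never floored).
#'
#' A record pair counts as matched when `Sov >= sov_match_threshold`
#' (primary criterion), or — when `use_secondary_criterion` is on — when
#' `minov >= shift_fraction * min(len(s1), len(s2))`, i.e. the overlap
#' covers at least 95% of the smaller record (allowing at most a 5%
#' coordinate shift). The secondary criterion rescues fragments of
#' elements that one source stores merged (defragmented) and another
#' stores as several short records, for which Sov alone is necessarily
#' below 1.
#'
#' @param delta_variant `"half_capped"` or `"as_printed"`.
#' @param sov_match_threshold Sov value at or above which the primary
#'   criterion fires; default 1.0.
#' @param shift_fraction Fraction of the smaller record that the overlap
#'   must cover for the secondary criterion; default 0.95.
#' @param use_secondary_criterion Logical; default `TRUE`.
#' @return A list of class `sov_config`.
#' @export
sov_config <- function(delta_variant = c("half_capped", "as_printed"),
                       sov_match_threshold = 1.0,
                       shift_fraction = 0.95,
                       use_secondary_criterion = TRUE) {
  delta_variant <- match.arg(delta_variant)
  stopifnot(is.numeric(sov_match_threshold), length(sov_match_threshold) == 1L,
            sov_match_threshold > 0, sov_match_threshold <= 1,
            is.numeric(shift_fraction), length(shift_fraction) == 1L,
            shift_fraction > 0, shift_fraction <= 1,
            is.logical(use_secondary_criterion))
  structure(list(delta_variant = delta_variant,
                 sov_match_threshold = sov_match_threshold,
                 shift_fraction = shift_fraction,
                 use_secondary_criterion = use_secondary_criterion),
            class = "sov_config")
}

#' Find all cross-source overlapping record pairs
#'
#' Enumerates every pair (a in A, b in B) on the same chromosome whose
#' intervals intersect by at least 1 bp, irrespective of strand and
#' family. Under the half-open convention, intervals that merely touch
#' (`end_a == start_b`) do not overlap. Each qualifying pair appears
#' exactly once; many-to-many relations are preserved.
#'
#' @param A,B [annotation_set()] objects with the same `genome_build`.
#' @return A `data.table` with one row per overlapping pair: ids,
#'   coordinates and per-record metadata of both members
#'   (`id_a`, `id_b`, `chrom`, `start_a`, `end_a`, `start_b`, `end_b`,
#'   `superfamily_a`, `superfamily_b`, `source_a`, `source_b`).
#' @export
find_overlaps <- function(A, B) {
  stopifnot(inherits(A, "annotation_set"), inherits(B, "annotation_set"))
  if (!identical(A$genome_build, B$genome_build))
    stop("genome build mismatch: '", A$genome_build, "' vs '",
         B$genome_build, "'")
  # sources legitimately cover different chromosome subsets; the
  # seqlevel-mismatch warning from GRanges comparison is expected noise
  hits <- withCallingHandlers(
    GenomicRanges::findOverlaps(.as_granges(A), .as_granges(B),
                                minoverlap = 1L, ignore.strand = TRUE),
    warning = function(w) {
      if (grepl("sequence levels", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ia <- S4Vectors::queryHits(hits)
  ib <- S4Vectors::subjectHits(hits)
  ra <- A$records
  rb <- B$records
  data.table::data.table(
    id_a = ra$record_id[ia], id_b = rb$record_id[ib],
    chrom = ra$chrom[ia],
    start_a = ra$start[ia], end_a = ra$end[ia],
    start_b = rb$start[ib], end_b = rb$end[ib],
    superfamily_a = ra$superfamily[ia], superfamily_b = rb$superfamily[ib],
    source_a = A$source_name, source_b = B$source_name)
}

#' Segment overlap score for interval pairs
#'
#' Vectorized computation of `minov`, `maxov`, the capped allowance
#' `delta` and `Sov` for pairs of overlapping intervals in the 0-based
#' half-open convention. See [sov_config()] for the formula and the two
#' delta variants.
#'
#' @param start_a,end_a,start_b,end_b Integer vectors of interval
#'   coordinates (recycled to common length); every pair must overlap by
#'   at least 1 bp ([find_overlaps()] guarantees this).
#' @param delta_variant `"half_capped"` (default) or `"as_printed"`.
#' @return A `data.table` with columns `minov`, `maxov`, `delta`, `sov`.
#' @examples
#' # the LOR1-int example: RepBase vs HERVd intervals
#' sov_score(48138333, 48140169, 48138680, 48141264)$sov          # ~0.821
#' sov_score(48138333, 48140169, 48138680, 48141264,
#'           delta_variant = "as_printed")$sov                    # 1
#' @export
sov_score <- function(start_a, end_a, start_b, end_b,
                      delta_variant = c("half_capped", "as_printed")) {
  delta_variant <- match.arg(delta_variant)
  n <- max(length(start_a), length(end_a), length(start_b), length(end_b))
  start_a <- rep_len(as.numeric(start_a), n)
  end_a <- rep_len(as.numeric(end_a), n)
  start_b <- rep_len(as.numeric(start_b), n)
  end_b <- rep_len(as.numeric(end_b), n)
  minov <- pmin(end_a, end_b) - pmax(start_a, start_b)
  if (any(minov < 1))
    stop("sov_score requires overlapping intervals (minov >= 1); ",
         "run find_overlaps first")
  maxov <- pmax(end_a, end_b) - pmin(start_a, start_b)
  len_a <- end_a - start_a
  len_b <- end_b - start_b
  cap_a <- if (delta_variant == "half_capped") len_a / 2 else len_a
  cap_b <- if (delta_variant == "half_capped") len_b / 2 else len_b
  delta <- pmin(maxov - minov, minov, cap_a, cap_b)
  data.table::data.table(minov = minov, maxov = maxov, delta = delta,
                         sov = (minov + delta) / maxov)
}

#' Apply the combined match criterion to scored pairs
#'
#' @param minov Overlap lengths.
#' @param len_a,len_b Lengths of the two records.
#' @param sov Sov scores.
#' @param cfg A [sov_config()].
#' @return Logical vector: matched under
#'   `(Sov >= threshold) | (secondary criterion)`.
#' @export
is_match <- function(minov, len_a, len_b, sov, cfg = sov_config()) {
  stopifnot(inherits(cfg, "sov_config"))
  primary <- sov >= cfg$sov_match_threshold
  if (!cfg$use_secondary_criterion) return(primary)
  secondary <- minov >= cfg$shift_fraction * pmin(len_a, len_b)
  primary | secondary
}

#' Score overlap pairs and attach match verdicts
#'
#' Takes the pair table from [find_overlaps()] and appends `minov`,
#' `maxov`, `delta`, `sov`, `matched_primary`, `matched_secondary` and
#' the combined `matched` verdict, plus a `cross_superfamily` diagnostic
#' flag for pairs whose two records carry different (assigned)
#' superfamilies — matching itself never looks at superfamily, strand or
#' family.
#'
#' @param pairs Pair table from [find_overlaps()].
#' @param cfg A [sov_config()].
#' @return The scored pair `data.table`.
#' @export
score_overlaps <- function(pairs, cfg = sov_config()) {
  stopifnot(inherits(cfg, "sov_config"))
  p <- data.table::copy(data.table::as.data.table(pairs))
  if (nrow(p) == 0L) {
    p[, c("minov", "maxov", "delta", "sov") := numeric(0)]
    p[, c("matched_primary", "matched_secondary", "matched",
          "cross_superfamily") := logical(0)]
    return(p)
  }
  sc <- sov_score(p$start_a, p$end_a, p$start_b, p$end_b,
                  delta_variant = cfg$delta_variant)
  p[, c("minov", "maxov", "delta", "sov") :=
      list(sc$minov, sc$maxov, sc$delta, sc$sov)]
  len_a <- p$end_a - p$start_a
  len_b <- p$end_b - p$start_b
  p[, matched_primary := sov >= cfg$sov_match_threshold]
  p[, matched_secondary := minov >= cfg$shift_fraction * pmin(len_a, len_b)]
  p[, matched := matched_primary |
      (cfg$use_secondary_criterion & matched_secondary)]
  p[, cross_superfamily := superfamily_a != superfamily_b &
      superfamily_a != "unassigned" & superfamily_b != "unassigned"]
  p[]
}

#' Pairwise matched counts and lengths between two sources
#'
#' For each of the two sources, counts the records that have at least
#' one matched partner in the other source (a record with several
#' partners is counted once) and sums their lengths in bp.
#'
#' @param A,B [annotation_set()] objects.
#' @param cfg A [sov_config()].
#' @return A list: `n_A_matched`, `bp_A_matched`, `n_B_matched`,
#'   `bp_B_matched`.
#' @export
pairwise_matched <- function(A, B, cfg = sov_config()) {
  scored <- score_overlaps(find_overlaps(A, B), cfg)
  m <- scored[scored$matched]
  ids_a <- unique(m$id_a)
  ids_b <- unique(m$id_b)
  ra <- A$records[A$records$record_id %in% ids_a]
  rb <- B$records[B$records$record_id %in% ids_b]
  list(n_A_matched = length(ids_a),
       bp_A_matched = sum(ra$end - ra$start),
       n_B_matched = length(ids_b),
       bp_B_matched = sum(rb$end - rb$start))
}

#' Three-way concordance decomposition
#'
#' Runs the pairwise matching across all three source pairs and
#' decomposes each source into records matched in both other sources
#' ("shared in all"), matched in exactly one, and matched in neither
#' ("unique"). Counts and summed record lengths (bp) are reported per
#' source and per superfamily.
#'
#' @param A,B,C [annotation_set()] objects (classified sets give
#'   meaningful superfamily breakdowns; classification is not required).
#' @param cfg A [sov_config()].
#' @return An object of class `concordance_report`: a list with
#'   \describe{
#'   \item{pairwise}{`data.table`, one row per ordered source pair:
#'     `source`, `other`, `n_matched`, `bp_matched`, `n_total`,
#'     `bp_total`, `pct_n`, `pct_bp` (percentages of the `source`
#'     totals, one decimal).}
#'   \item{per_source}{`data.table`: totals plus `n_shared_all`,
#'     `bp_shared_all`, `n_unique`, `bp_unique`, `n_one_other` and the
#'     corresponding percentages.}
#'   \item{by_superfamily}{same decomposition per
#'     (source, superfamily).}
#'   \item{config}{the [sov_config()] used.}}
#' @export
three_way <- function(A, B, C, cfg = sov_config()) {
  sets <- list(A, B, C)
  nm <- vapply(sets, `[[`, character(1L), "source_name")
  if (anyDuplicated(nm)) stop("source names must be distinct: ",
                              paste(nm, collapse = ", "))
  names(sets) <- nm

  # matched record-id sets for every ordered pair
  matched_in <- list()
  pairwise <- list()
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    X <- sets[[i]]; Y <- sets[[j]]
    scored <- score_overlaps(find_overlaps(X, Y), cfg)
    ids <- unique(scored$id_a[scored$matched])
    matched_in[[paste(nm[i], nm[j], sep = "|")]] <- ids
    rx <- X$records
    sel <- rx$record_id %in% ids
    pairwise[[length(pairwise) + 1L]] <- data.table::data.table(
      source = nm[i], other = nm[j],
      n_matched = sum(sel), bp_matched = sum(rx$end[sel] - rx$start[sel]),
      n_total = nrow(rx), bp_total = sum(rx$end - rx$start))
  }
  pairwise <- data.table::rbindlist(pairwise)
  pairwise[, pct_n := round(100 * n_matched / pmax(n_total, 1L), 1)]
  pairwise[, pct_bp := round(100 * bp_matched / pmax(bp_total, 1), 1)]

  decomp <- function(i) {
    others <- setdiff(1:3, i)
    rx <- sets[[i]]$records
    in1 <- rx$record_id %in%
      matched_in[[paste(nm[i], nm[others[1L]], sep = "|")]]
    in2 <- rx$record_id %in%
      matched_in[[paste(nm[i], nm[others[2L]], sep = "|")]]
    lens <- rx$end - rx$start
    data.table::data.table(
      source = nm[i], superfamily = rx$superfamily, length = lens,
      shared_all = in1 & in2, unique = !in1 & !in2,
      one_other = xor(in1, in2))
  }
  flags <- data.table::rbindlist(lapply(1:3, decomp))

  per_source <- flags[, .(
    n_total = .N, bp_total = sum(length),
    n_shared_all = sum(shared_all), bp_shared_all = sum(length[shared_all]),
    n_unique = sum(unique), bp_unique = sum(length[unique]),
    n_one_other = sum(one_other)), by = source]
  per_source[, pct_shared_all := round(100 * n_shared_all / pmax(n_total, 1L), 1)]
  per_source[, pct_unique := round(100 * n_unique / pmax(n_total, 1L), 1)]

  by_sf <- flags[, .(
    n_total = .N, bp_total = sum(length),
    n_shared_all = sum(shared_all), bp_shared_all = sum(length[shared_all]),
    n_unique = sum(unique), bp_unique = sum(length[unique])),
    by = .(source, superfamily)]
  by_sf[, pct_shared_all := round(100 * n_shared_all / pmax(n_total, 1L), 1)]
  by_sf[, pct_unique := round(100 * n_unique / pmax(n_total, 1L), 1)]

  structure(list(pairwise = pairwise, per_source = per_source,
                 by_superfamily = by_sf, config = cfg,
                 sources = nm),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> sources:", paste(x$sources, collapse = ", "),
      "| delta variant:", x$config$delta_variant,
      "| secondary criterion:",
      if (x$config$use_secondary_criterion) "on" else "off", "\n")
  cat("\nPairwise matched (per source record counts):\n")
  print(x$pairwise)
  cat("\nPer-source decomposition:\n")
  print(x$per_source)
  invisible(x)
}
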