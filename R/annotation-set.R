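#' Construct an annotation set
#'
#' An `annotation_set` holds all repeat records from one named annotation
#' source in a single coordinate convention: 0-based, half-open
#' (`start` inclusive, `end` exclusive), so that record length is always
#' `end - start`. Records are kept sorted by `(chrom, start, end, record_id)`
#' so that the same input always yields the same record order.
#'
#' @param records A data.frame with at least the columns `record_id`,
#'   `chrom`, `start`, `end`. Optional columns `strand` (`"+"`, `"-"` or
#'   `"*"` for unknown), `family`, `repeat_class`, `superfamily` and
#'   `destruction` (percentage of consensus nucleotides lost, in
#'   \[0, 100\]) are filled with defaults when absent. `superfamily`
#'   defaults to `"unassigned"` until [assign_superfamilies()] runs.
#' @param source_name Name of the annotation source (e.g. `"HERVd"`).
#' @param genome_build Informational genome build label; overlap
#'   operations refuse to mix sets with different labels.
#'
#' @return An object of class `annotation_set`: a list with elements
#'   `source_name`, `genome_build` and `records` (a `data.table`).
#'
#' @details Records with identical `(chrom, start, end, family)` are kept
#'   as distinct records (deduplication is never applied) but trigger a
#'   warning so that suspicious inputs are auditable.
#'
#' @examples
#' rec <- data.frame(record_id = "r1", chrom = "chr1",
#'                   start = 48138333L, end = 48140169L,
#'                   family = "LOR1-int")
#' s <- annotation_set(rec, source_name = "RepBase")
#' record_lengths(s)  # 1836
#' @export
annotation_set <- function(records, source_name, genome_build = "GRCh38") {
  stopifnot(is.character(source_name), length(source_name) == 1L)
  rec <- data.table::copy(data.table::as.data.table(records))
  required <- c("record_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols))
    stop("records is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(rec) == 0L) {
    rec <- .empty_records()
  } else {
    rec[, record_id := as.character(record_id)]
    rec[, chrom := trimws(as.character(chrom))]
    rec[, start := .to_int(start, "start")]
    rec[, end := .to_int(end, "end")]
    if (!"strand" %in% names(rec)) rec[, strand := "*"]
    rec[, strand := .norm_strand(strand)]
    if (!"family" %in% names(rec)) rec[, family := NA_character_]
    rec[, family := trimws(as.character(family))]
    if (!"repeat_class" %in% names(rec)) rec[, repeat_class := NA_character_]
    rec[, repeat_class := trimws(as.character(repeat_class))]
    if (!"superfamily" %in% names(rec)) rec[, superfamily := "unassigned"]
    rec[, superfamily := as.character(superfamily)]
    if (!"destruction" %in% names(rec)) rec[, destruction := NA_real_]
    rec[, destruction := as.numeric(destruction)]
    rec <- rec[, c("record_id", "chrom", "start", "end", "strand", "family",
                   "repeat_class", "superfamily", "destruction"), with = FALSE]

    bad <- which(is.na(rec$start) | is.na(rec$end) | rec$start < 0L |
                   rec$end <= rec$start)
    if (length(bad))
      stop("invalid coordinates (need 0 <= start < end) in record(s): ",
           paste(utils::head(rec$record_id[bad], 5L), collapse = ", "))
    bad_d <- which(!is.na(rec$destruction) &
                     (rec$destruction < 0 | rec$destruction > 100))
    if (length(bad_d))
      stop("destruction outside [0, 100] in record(s): ",
           paste(utils::head(rec$record_id[bad_d], 5L), collapse = ", "))
    if (anyDuplicated(rec$record_id))
      stop("duplicate record_id within source '", source_name, "': ",
           paste(utils::head(unique(rec$record_id[duplicated(rec$record_id)]), 5L),
                 collapse = ", "))
    ndup <- sum(duplicated(rec[, c("chrom", "start", "end", "family")]))
    if (ndup > 0L)
      warning(ndup, " record(s) in '", source_name,
              "' share (chrom, start, end, family) with another record; ",
              "kept as distinct records")
    data.table::setorder(rec, chrom, start, end, record_id)
  }
  structure(list(source_name = source_name,
                 genome_build = genome_build,
                 records = rec),
            class = "annotation_set")
}

.empty_records <- function() {
  data.table::data.table(record_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), family = character(),
                         repeat_class = character(), superfamily = character(),
                         destruction = numeric())
}

.to_int <- function(x, what) {
  xi <- suppressWarnings(as.integer(x))
  if (anyNA(xi) && !all(is.na(x)))
    stop("non-integer ", what, " value(s), e.g. '",
         utils::head(x[is.na(xi)], 1L), "'")
  xi
}

.norm_strand <- function(s) {
  s <- trimws(as.character(s))
  s[s %in% c("C", "-", "−")] <- "-"
  s[!(s %in% c("+", "-"))] <- "*"
  s
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s (%s): %d records on %d chromosome(s)\n",
              x$source_name, x$genome_build, nrow(x$records),
              length(unique(x$records$chrom))))
  if (nrow(x$records)) print(utils::head(x$records, 5L))
  invisible(x)
}

#' Number of records in an annotation set
#' @param set An [annotation_set()].
#' @return Integer record count.
#' @export
n_records <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  nrow(set$records)
}

#' Record lengths in base pairs
#'
#' Length is `end - start` under the package's 0-based half-open
#' convention.
#'
#' @param set An [annotation_set()].
#' @return Integer vector of per-record lengths, in record order.
#' @export
record_lengths <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  set$records$end - set$records$start
}

## Compare two sets field-for-field (used by round-trip tests and callers
## that need exact identity after write/read cycles).
#' Test two annotation sets for exact equality
#' @param a,b [annotation_set()] objects.
#' @return `TRUE` if source name, build and every record field agree.
#' @export
annotation_sets_equal <- function(a, b) {
  inherits(a, "annotation_set") && inherits(b, "annotation_set") &&
    identical(a$source_name, b$source_name) &&
    identical(a$genome_build, b$genome_build) &&
    isTRUE(all.equal(as.data.frame(a$records), as.data.frame(b$records),
                     check.attributes = FALSE))
}

## internal: GRanges view of a set (1-based inclusive for IRanges machinery)
.as_granges <- function(set) {
  r <- set$records
  GenomicRanges::GRanges(seqnames = r$chrom,
                         ranges = IRanges::IRanges(start = r$start + 1L,
                                                   end = r$end))
}
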