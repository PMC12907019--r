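#' Read a BED-like annotation table
#'
#' Reads a tab- or whitespace-separated BED-like file into an
#' [annotation_set()]. The minimal layout is four columns
#' (`chrom`, `start`, `end`, `record_id`); further columns, when present,
#' are interpreted as `score` (ignored), `strand`, `family`,
#' `repeat_class`, `superfamily` and `destruction` — the layout written
#' by [write_bed()].
#'
#' @param path Path to the file. An empty file yields an empty set.
#' @param coordinate_convention Either `"bed0_halfopen"` (coordinates are
#'   already 0-based half-open, the internal convention) or
#'   `"oneinclusive"` (1-based inclusive; converted by `start - 1`,
#'   `end` unchanged).
#' @param source_name Source label for the resulting set; defaults to the
#'   file name without extension.
#' @param genome_build Genome build label.
#'
#' @return An [annotation_set()].
#' @seealso [write_bed()] for the inverse operation.
#' @export
read_bed <- function(path,
                     coordinate_convention = c("bed0_halfopen", "oneinclusive"),
                     source_name = NULL, genome_build = "GRCh38") {
  coordinate_convention <- match.arg(coordinate_convention)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(source_name))
    source_name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  if (!length(lines))
    return(annotation_set(.empty_records(), source_name, genome_build))

  fields <- strsplit(lines, "[\t ]+")
  ncols <- lengths(fields)
  if (any(ncols < 4L))
    stop("line ", which(ncols < 4L)[1L],
         ": fewer than 4 columns (chrom, start, end, name required)")

  get_col <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[[i]] else NA_character_, character(1L))
  start_raw <- get_col(2L)
  end_raw <- get_col(3L)
  start <- suppressWarnings(as.integer(start_raw))
  end <- suppressWarnings(as.integer(end_raw))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("line ", bad[1L], ": malformed coordinate '",
         start_raw[bad[1L]], "'/'", end_raw[bad[1L]], "'")
  if (coordinate_convention == "oneinclusive") start <- start - 1L
  bad <- which(end <= start)
  if (length(bad))
    stop("line ", bad[1L], ": end <= start after convention conversion")

  destr <- suppressWarnings(as.numeric(get_col(10L)))
  rec <- data.table::data.table(
    record_id = get_col(4L),
    chrom = get_col(1L),
    start = start, end = end,
    strand = ifelse(is.na(get_col(6L)), "*", get_col(6L)),
    family = get_col(7L),
    repeat_class = get_col(8L),
    superfamily = get_col(9L),
    destruction = destr)
  rec[is.na(superfamily) | superfamily == "" | superfamily == ".",
      superfamily := "unassigned"]
  rec[family %in% c("", "."), family := NA_character_]
  rec[repeat_class %in% c("", "."), repeat_class := NA_character_]
  if (anyDuplicated(rec$record_id)) {
    first_dup <- rec$record_id[duplicated(rec$record_id)][1L]
    stop("duplicate record_id '", first_dup, "' in ", path)
  }
  annotation_set(rec, source_name, genome_build)
}

#' Write an annotation set as BED6+4
#'
#' Writes tab-separated columns `chrom`, `start`, `end`, `record_id`,
#' `score` (always 0), `strand`, then `family`, `repeat_class`,
#' `superfamily`, `destruction`, in the internal 0-based half-open
#' convention. Missing values are written as `"."` (destruction as an
#' empty field) so that [read_bed()] restores the set field-for-field.
#'
#' @param set An [annotation_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  r <- set$records
  if (nrow(r) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  na_dot <- function(x) ifelse(is.na(x), ".", x)
  out <- data.table::data.table(
    chrom = r$chrom, start = r$start, end = r$end,
    name = r$record_id, score = 0L, strand = r$strand,
    family = na_dot(r$family), repeat_class = na_dot(r$repeat_class),
    superfamily = r$superfamily,
    destruction = ifelse(is.na(r$destruction), "",
                         format(r$destruction, scientific = FALSE,
                                trim = TRUE)))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a RepeatMasker `.out` annotation file
#'
#' Parses the standard RepeatMasker `.out` layout: three header lines
#' followed by whitespace-delimited alignment rows whose columns include
#' the query sequence, 1-based inclusive begin/end positions, the strand
#' (`+` or `C` for the complement), the repeat name and the
#' class/family string. Coordinates are converted to the internal
#' 0-based half-open convention (`start = begin - 1`), `C` maps to `-`,
#' and `class/family` strings such as `"LTR/ERVL-MaLR"` are split on the
#' first `/` into `repeat_class` and kept whole as annotation; the
#' repeat name column supplies `family`.
#'
#' @param path Path to the `.out` file.
#' @param source_name Source label; defaults to the file name.
#' @param genome_build Genome build label.
#' @return An [annotation_set()].
#' @export
read_repeatmasker_out <- function(path, source_name = NULL,
                                  genome_build = "GRCh38") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(source_name))
    source_name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L ||
      !any(grepl("\\bscore\\b", utils::head(lines, 2L))))
    stop("not a RepeatMasker .out file (header line with 'score' missing): ",
         path)
  body <- lines[-seq_len(min(3L, length(lines)))]
  body <- body[nzchar(trimws(body))]
  if (!length(body))
    return(annotation_set(.empty_records(), source_name, genome_build))

  fields <- strsplit(trimws(body), "[[:space:]]+")
  ncols <- lengths(fields)
  if (any(ncols < 11L))
    stop("RepeatMasker row ", which(ncols < 11L)[1L] + 3L,
         " has ", min(ncols), " columns; >= 11 expected")
  col <- function(i) vapply(fields, `[[`, character(1L), i)
  begin <- suppressWarnings(as.integer(col(6L)))
  end <- suppressWarnings(as.integer(col(7L)))
  if (anyNA(begin) || anyNA(end))
    stop("non-integer begin/end in RepeatMasker body of ", path)
  classfam <- col(11L)
  rc <- sub("/.*$", "", classfam)
  rec <- data.table::data.table(
    record_id = sprintf("%s_%06d", source_name, seq_along(begin)),
    chrom = col(5L),
    start = begin - 1L, end = end,
    strand = col(9L),                       # '+' or 'C'; normalized below
    family = col(10L),
    repeat_class = rc,
    superfamily = "unassigned",
    destruction = NA_real_)
  annotation_set(rec, source_name, genome_build)
}

#' Read a HERVd-style TSV annotation table
#'
#' Reads a header-bearing tab-separated table that names at least
#' `chrom`, `start`, `end` and `family` columns (`record_id` is used
#' when present, otherwise generated), plus an optional per-record
#' quality column holding either the destruction degree directly or its
#' complement, completeness. When `quality_is` is `"completeness"` the
#' value is converted as `destruction = 100 - completeness`; the
#' conversion is reported via a message so that runs are auditable.
#'
#' @param path Path to the TSV file.
#' @param coordinate_convention As in [read_bed()].
#' @param quality_is Interpretation of the quality column:
#'   `"completeness"` (default; converted) or `"destruction"` (used
#'   as-is).
#' @param source_name,genome_build As in [read_bed()].
#' @return An [annotation_set()].
#' @export
read_hervd_tsv <- function(path,
                           coordinate_convention = c("oneinclusive", "bed0_halfopen"),
                           quality_is = c("completeness", "destruction"),
                           source_name = NULL, genome_build = "GRCh38") {
  coordinate_convention <- match.arg(coordinate_convention)
  quality_is <- match.arg(quality_is)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(source_name))
    source_name <- sub("\\.[^.]*$", "", basename(path))
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = 1L))
  names(tab) <- tolower(trimws(names(tab)))
  need <- c("chrom", "start", "end", "family")
  if (length(setdiff(need, names(tab))))
    stop("HERVd-style TSV must name columns ",
         paste(need, collapse = ", "), "; found: ",
         paste(names(tab), collapse = ", "))
  start <- suppressWarnings(as.integer(tab$start))
  if (coordinate_convention == "oneinclusive") start <- start - 1L
  destr <- NA_real_
  if ("destruction" %in% names(tab)) {
    destr <- as.numeric(tab$destruction)
  } else if ("completeness" %in% names(tab)) {
    qv <- as.numeric(tab$completeness)
    destr <- if (quality_is == "completeness") 100 - qv else qv
    message("read_hervd_tsv: 'completeness' column converted as ",
            "destruction = 100 - completeness")
  }
  rid <- if ("record_id" %in% names(tab)) as.character(tab$record_id) else
    sprintf("%s_%06d", source_name, seq_len(nrow(tab)))
  rec <- data.table::data.table(
    record_id = rid, chrom = tab$chrom, start = start,
    end = suppressWarnings(as.integer(tab$end)),
    strand = if ("strand" %in% names(tab)) tab$strand else "*",
    family = tab$family,
    repeat_class = if ("class" %in% names(tab)) tab$class else NA_character_,
    superfamily = "unassigned", destruction = destr)
  annotation_set(rec, source_name, genome_build)
}

#' Keep only records of one repeat class
#'
#' Reproduces the LTR-class retention step applied to raw RepeatMasker
#' downloads: only records whose `repeat_class` equals `keep_class`
#' (exact, case-sensitive, after whitespace trimming) are kept. Records
#' with a missing class never match and are counted separately.
#'
#' @param set An [annotation_set()].
#' @param keep_class Class string to retain, typically `"LTR"`.
#' @return The filtered [annotation_set()]; counts of removed and
#'   class-missing records are reported via `message()`.
#' @export
filter_ltr_class <- function(set, keep_class = "LTR") {
  stopifnot(inherits(set, "annotation_set"))
  r <- set$records
  cls <- trimws(r$repeat_class)
  keep <- !is.na(cls) & cls == trimws(keep_class)
  n_missing <- sum(is.na(cls))
  message(sprintf(
    "filter_ltr_class(%s): kept %d of %d records (removed %d, of which %d had no class)",
    set$source_name, sum(keep), nrow(r), sum(!keep), n_missing))
  out <- set
  out$records <- r[keep]
  out
}

#' Parse a printed genomic locus string
#'
#' Parses strings of the form `"chr1:48 138 333–48 140 169"` as printed
#' in figure captions and genome-browser displays: spaces (including
#' thin spaces) serve as digit-group separators and the range separator
#' may be a hyphen or en-dash. The coordinates are taken verbatim (no
#' \eqn{\pm}1 adjustment), so `end - start` equals the printed length.
#'
#' @param text Character vector of locus strings.
#' @return A `data.frame` with columns `chrom`, `start`, `end` and
#'   `length` (one row per input string).
#' @examples
#' parse_locus_string("chr1:48 138 333–48 140 169")$length  # 1836
#' @export
parse_locus_string <- function(text) {
  stopifnot(is.character(text))
  # strip regular, no-break, thin and narrow no-break spaces between digits
  cleaned <- gsub("[    ]", "", text)
  m <- regmatches(cleaned,
                  regexec("^([^:]+):([0-9]+)[-–—]([0-9]+)$", cleaned))
  bad <- which(lengths(m) != 4L)
  if (length(bad))
    stop("unparseable locus string: '", text[bad[1L]], "'")
  chrom <- vapply(m, `[[`, character(1L), 2L)
  start <- as.integer(vapply(m, `[[`, character(1L), 3L))
  end <- as.integer(vapply(m, `[[`, character(1L), 4L))
  if (any(end <= start))
    stop("locus string has end <= start: '", text[which(end <= start)[1L]], "'")
  data.frame(chrom = chrom, start = start, end = end,
             length = end - start, stringsAsFactors = FALSE)
}
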