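#' Configuration of an end-to-end comparison run
#'
#' @param sources List of per-source input specs, each a list with
#'   `path`, `format` (`"bed"`, `"repeatmasker"` or `"hervd"`),
#'   optional `convention` (`"bed0_halfopen"` / `"oneinclusive"`) and
#'   optional `name`. At least two sources are required and all paths
#'   must be distinct. Alternatively, already-loaded
#'   [annotation_set()] objects may be given directly.
#' @param family_map_path Optional path to the family mapping TSV; when
#'   given, records are classified before matching.
#' @param orphan_policy Passed to [assign_superfamilies()].
#' @param sov A [sov_config()].
#' @param coverage_mode As in [total_coverage()].
#' @param bin_width,overflow_threshold Length-histogram settings.
#' @param outdir Output directory (created if needed).
#' @return A list of class `run_config`.
#' @export
run_config <- function(sources, family_map_path = NULL,
                       orphan_policy = "unclassified",
                       sov = sov_config(),
                       coverage_mode = "sum_lengths",
                       bin_width = 100L, overflow_threshold = 2500L,
                       outdir = "results") {
  stopifnot(is.list(sources), length(sources) >= 2L)
  paths <- vapply(sources, function(s)
    if (inherits(s, "annotation_set")) s$source_name else s$path,
    character(1L))
  if (anyDuplicated(paths))
    stop("source paths/names must be distinct")
  structure(list(sources = sources, family_map_path = family_map_path,
                 orphan_policy = orphan_policy, sov = sov,
                 coverage_mode = coverage_mode, bin_width = bin_width,
                 overflow_threshold = overflow_threshold, outdir = outdir),
            class = "run_config")
}

.load_source <- function(spec) {
  if (inherits(spec, "annotation_set")) return(spec)
  fmt <- spec$format %||% "bed"
  nm <- spec$name %||% NULL
  switch(fmt,
         bed = read_bed(spec$path,
                        spec$convention %||% "bed0_halfopen",
                        source_name = nm),
         repeatmasker = read_repeatmasker_out(spec$path, source_name = nm),
         hervd = read_hervd_tsv(spec$path,
                                spec$convention %||% "oneinclusive",
                                source_name = nm),
         stop("unknown source format: ", fmt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full concordance analysis
#'
#' Orchestrates the pipeline stage by stage — read, (optionally)
#' classify, overlap, score, match, decompose, summarize — and writes
#' machine-readable outputs under `config$outdir`:
#'
#' * `scored_pairs_<A>_<B>.tsv` for every unordered source pair;
#' * `pairwise_matched.tsv`, `per_source.tsv`,
#'   `by_superfamily.tsv` (the three-way decomposition; only with
#'   exactly three sources);
#' * `superfamily_table.tsv`, `coverage.tsv`,
#'   `length_histogram_<src>.tsv`;
#' * `report.json` (everything above as one JSON object) and
#'   `manifest.json` (inputs, configuration flags and package version —
#'   enough to re-derive every reported number).
#'
#' On failure, partially written outputs are removed.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages?
#' @return Invisibly, a list with the loaded `sets`, `scored_pairs`,
#'   the `concordance_report` (or `NULL` when not exactly 3 sources),
#'   the `superfamily_table`, `coverage` table and `outdir`.
#' @export
run_compare <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[run_compare] ", ...)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  emit <- function(tab, file) {
    path <- file.path(outdir, file)
    data.table::fwrite(data.table::as.data.table(tab), path, sep = "\t")
    written <<- c(written, path)
    path
  }

  sets <- lapply(config$sources, .load_source)
  names(sets) <- vapply(sets, `[[`, character(1L), "source_name")
  for (s in sets) say("read ", s$source_name, ": ", n_records(s), " records")

  audits <- NULL
  if (!is.null(config$family_map_path)) {
    fmap <- load_family_map(config$family_map_path)
    res <- lapply(sets, assign_superfamilies, map = fmap,
                  orphan_policy = config$orphan_policy)
    sets <- lapply(res, `[[`, "set")
    audits <- lapply(res, `[[`, "audit")
    for (nm in names(sets))
      say("classified ", nm, ": ", audits[[nm]]$n_assigned, " assigned, ",
          audits[[nm]]$n_unmapped, " unmapped, ",
          audits[[nm]]$n_ignored_orphans, " ignored orphans")
  }

  combos <- utils::combn(length(sets), 2L)
  scored_pairs <- list()
  for (k in seq_len(ncol(combos))) {
    i <- combos[1L, k]; j <- combos[2L, k]
    sp <- score_overlaps(find_overlaps(sets[[i]], sets[[j]]), config$sov)
    key <- paste(names(sets)[i], names(sets)[j], sep = "_")
    scored_pairs[[key]] <- sp
    emit(sp, paste0("scored_pairs_", key, ".tsv"))
    say("scored ", key, ": ", nrow(sp), " overlapping pairs, ",
        sum(sp$matched), " matched")
  }

  report <- NULL
  if (length(sets) == 3L) {
    report <- three_way(sets[[1L]], sets[[2L]], sets[[3L]], config$sov)
    emit(report$pairwise, "pairwise_matched.tsv")
    emit(report$per_source, "per_source.tsv")
    emit(report$by_superfamily, "by_superfamily.tsv")
  }

  sft <- superfamily_table(sets, config$coverage_mode)
  emit(sft, "superfamily_table.tsv")
  cov <- data.table::data.table(
    source = names(sets),
    n_records = vapply(sets, n_records, integer(1L)),
    coverage_bp = vapply(sets, total_coverage, numeric(1L),
                         mode = config$coverage_mode),
    n_over_2500 = vapply(sets, long_record_count, integer(1L),
                         threshold = 2500L))
  emit(cov, "coverage.tsv")
  for (nm in names(sets)) {
    h <- length_histogram(sets[[nm]], config$bin_width,
                          config$overflow_threshold)
    emit(data.table::data.table(bin_start = h$bin_start,
                                count = h$count),
         paste0("length_histogram_", nm, ".tsv"))
  }

  payload <- list(
    pairwise = if (!is.null(report)) report$pairwise,
    per_source = if (!is.null(report)) report$per_source,
    by_superfamily = if (!is.null(report)) report$by_superfamily,
    superfamily_table = sft, coverage = cov,
    audits = audits)
  jpath <- file.path(outdir, "report.json")
  jsonlite::write_json(payload, jpath, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  written <- c(written, jpath)

  manifest <- list(
    package = "ervconcord",
    version = as.character(utils::packageVersion("ervconcord")),
    sources = lapply(config$sources, function(s)
      if (inherits(s, "annotation_set"))
        list(name = s$source_name, n_records = n_records(s),
             genome_build = s$genome_build)
      else s),
    family_map = config$family_map_path,
    orphan_policy = config$orphan_policy,
    sov = unclass(config$sov),
    coverage_mode = config$coverage_mode,
    bin_width = config$bin_width,
    overflow_threshold = config$overflow_threshold)
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  written <- c(written, mpath)
  ok <- TRUE
  say("wrote ", length(written), " file(s) to ", outdir)
  invisible(list(sets = sets, scored_pairs = scored_pairs, report = report,
                 superfamily_table = sft, coverage = cov, outdir = outdir))
}

#' Run the synthetic-data generator and write its outputs
#'
#' Thin wrapper over [simulate_annotations()]: writes each simulated
#' source as BED6+4 (see [write_bed()]), the truth table as TSV, and a
#' manifest recording the parameters (including the seed), so a run is
#' reproducible byte for byte.
#'
#' @param params A [sim_params()]; `seed` may be overridden.
#' @param outdir Output directory.
#' @param seed Optional seed override.
#' @return Invisibly, the [simulate_annotations()] result with an added
#'   `files` element.
#' @export
run_simulate <- function(params = sim_params(), outdir = "sim_out",
                         seed = NULL) {
  if (!is.null(seed)) params$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_annotations(params)
  files <- character()
  for (nm in names(sim$sources)) {
    f <- file.path(outdir, paste0(nm, ".bed"))
    write_bed(sim$sources[[nm]], f)
    files <- c(files, f)
  }
  tf <- file.path(outdir, "truth.tsv")
  data.table::fwrite(sim$truth, tf, sep = "\t")
  files <- c(files, tf)
  mpath <- file.path(outdir, "manifest.json")
  pj <- sim$params
  pj$genome <- as.data.frame(pj$genome)
  jsonlite::write_json(
    list(package = "ervconcord",
         version = as.character(utils::packageVersion("ervconcord")),
         params = unclass(pj)),
    mpath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(files, mpath)
  sim$files <- files
  invisible(sim)
}

#' Read simulation parameters from a YAML config file
#'
#' Flat YAML mapping of [sim_params()] argument names to values;
#' vectors are given as YAML maps (named) or sequences.
#'
#' @param path YAML file path.
#' @return A [sim_params()].
#' @export
read_sim_params <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("n_elements", "dropout", "archetype_weights", "solo_modes",
               "solo_sds", "fragment_range", "gap_range"))
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  if (!is.null(y$genome)) y$genome <- as.data.frame(
    lapply(as.data.frame(do.call(rbind, lapply(y$genome, as.data.frame))),
           unlist))
  do.call(sim_params, y)
}
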