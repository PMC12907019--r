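# Fixture builders and independent oracles shared by the test files.

# Build an annotation set from parallel coordinate vectors.
mk_set <- function(start, end, chrom = "chr1", source = "S",
                   family = NA_character_, superfamily = NULL,
                   destruction = NA_real_, build = "testbuild") {
  n <- length(start)
  rec <- data.frame(record_id = sprintf("%s_%03d", source, seq_len(n)),
                    chrom = rep_len(chrom, n),
                    start = start, end = end,
                    family = rep_len(family, n),
                    destruction = rep_len(destruction, n))
  if (!is.null(superfamily)) rec$superfamily <- rep_len(superfamily, n)
  suppressWarnings(annotation_set(rec, source, build))
}

# Random annotation set over a couple of chromosomes.
random_set <- function(n, seed, source = "R", build = "testbuild",
                       span = 20000L, max_len = 500L) {
  set.seed(seed)
  start <- sample.int(span, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  rec <- data.frame(record_id = sprintf("%s_%05d", source, seq_len(n)),
                    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                    start = start, end = start + len)
  suppressWarnings(annotation_set(rec, source, build))
}

# Independent all-pairs overlap oracle (>= 1 bp, half-open intervals).
brute_force_overlaps <- function(A, B) {
  ra <- A$records; rb <- B$records
  out <- list()
  for (cc in intersect(unique(ra$chrom), unique(rb$chrom))) {
    a <- ra[ra$chrom == cc]; b <- rb[rb$chrom == cc]
    if (nrow(a) == 0L || nrow(b) == 0L) next
    ia <- rep(seq_len(nrow(a)), each = nrow(b))
    ib <- rep(seq_len(nrow(b)), times = nrow(a))
    ov <- pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib])
    k <- ov >= 1L
    out[[cc]] <- data.table::data.table(id_a = a$record_id[ia[k]],
                                        id_b = b$record_id[ib[k]])
  }
  if (!length(out)) return(character())
  tab <- data.table::rbindlist(out)
  sort(paste(tab$id_a, tab$id_b, sep = "|"))
}

pair_keys <- function(pairs) sort(paste(pairs$id_a, pairs$id_b, sep = "|"))

# Cache expensive simulations across test blocks within one run.
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, params) {
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_annotations(params)
  .sim_cache[[key]]
}

# A small family map used by classification tests.
demo_map <- function() {
  family_map(data.frame(
    family = c("MER31B", "HERVL-int", "MLT1K", "THE1A-int", "LTR33-orph"),
    superfamily = c("ERV1", "ERV3", "ERV3", "ERV2", "ERV1"),
    group = c("MER31", "HERVL", "MaLR", "THE1", "LTR33"),
    role = c("LTR", "internal", "LTR", "internal", "LTR"),
    ignored = c(0L, 0L, 0L, 0L, 1L)))
}
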