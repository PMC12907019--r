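#' Parameters for the synthetic annotation generator
#'
#' Bundles everything [simulate_annotations()] needs to emit three
#' correlated annotation sources with planted ground truth: one
#' merged-style source ("M", records span all fragments of an element
#' including the gaps between them, and carry a destruction degree) and
#' two fragment-style sources ("F1", "F2", one record per fragment,
#' with boundary jitter and occasional whole-record shifts).
#'
#' The default length model is a three-archetype mixture chosen to give
#' the bimodal short-length structure typical of LTR-retroelement
#' annotation — peaks in the 200–300 and 400–500 bp ranges from solo
#' LTRs, a smaller mode near 1600 bp from well-preserved internal
#' regions, and a uniform 50–250 bp component of heavily degraded
#' fragments. Destruction is bimodal: records no longer than
#' `short_cutoff` draw from a high-destruction component, longer
#' records from a low one, so that filtering at `short_cutoff` removes
#' the second mode.
#'
#' @param seed Integer root seed; all stage randomness (archetypes,
#'   placement, fragmentation, jitter/shift, dropout, destruction,
#'   uniques) flows from it through named substreams.
#' @param n_elements Named integer vector of planted element counts per
#'   superfamily.
#' @param genome `data.frame(chrom, length)` describing the simulated
#'   genome; elements are placed without inter-element overlap and
#'   placement fails if the genome is too small.
#' @param archetype_weights Mixture weights for the `fragment`,
#'   `solo_ltr` and `provirus` archetypes (normalized internally).
#' @param solo_modes,solo_sds Means/sds (bp) of the two solo-LTR normal
#'   length components (equal weight).
#' @param fragment_range Length range (bp) of the short-fragment
#'   archetype (uniform).
#' @param provirus_meanlog,provirus_sdlog Log-normal parameters of the
#'   provirus archetype; lengths are clamped to \[600, 9000\] bp.
#' @param frag_prob Probability that an element of span >=
#'   `frag_min_span` is stored fragmented in the fragment-style
#'   sources.
#' @param frag_min_span Minimum element span (bp) eligible for
#'   fragmentation.
#' @param frag_extra_mean Mean of the Poisson number of fragments
#'   beyond the mandatory two.
#' @param gap_range Range (bp) of each inter-fragment gap (uniform);
#'   gaps are included in the merged record's span.
#' @param jitter_sd Standard deviation (bp) of per-boundary Gaussian
#'   jitter in fragment-style sources (0 disables).
#' @param shift_prob,shift_bp Probability and magnitude (bp) of a
#'   whole-record shift in fragment-style sources.
#' @param dropout Named per-source probabilities that an individual
#'   record is absent.
#' @param unique_frac Per-source fraction (of the planted element
#'   count) of injected source-only records; uniques are placed in
#'   their own genomic slots so they overlap nothing.
#' @param short_cutoff Length (bp) at or below which merged records
#'   draw high destruction (default 250).
#' @param destruction_low,destruction_high `c(shape1, shape2)` of the
#'   two Beta components of destruction / 100.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_elements = c(ERV1 = 3000L, ERV2 = 300L,
                                      ERV3 = 6500L, Gypsy = 500L,
                                      Unclassified = 400L),
                       genome = data.frame(
                         chrom = c("chr1", "chr2", "chr3"),
                         length = c(30e6, 25e6, 20e6)),
                       archetype_weights = c(fragment = 0.2,
                                             solo_ltr = 0.6,
                                             provirus = 0.2),
                       solo_modes = c(250, 450),
                       solo_sds = c(40, 60),
                       fragment_range = c(50, 250),
                       provirus_meanlog = log(1600),
                       provirus_sdlog = 0.45,
                       frag_prob = 0.3,
                       frag_min_span = 600,
                       frag_extra_mean = 0.6,
                       gap_range = c(30, 300),
                       jitter_sd = 10,
                       shift_prob = 0.02,
                       shift_bp = 300,
                       dropout = c(M = 0.02, F1 = 0.02, F2 = 0.02),
                       unique_frac = 0.05,
                       short_cutoff = 250,
                       destruction_low = c(2, 8),
                       destruction_high = c(8, 2)) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            all(n_elements >= 0), all(genome$length > 0),
            frag_prob >= 0, frag_prob <= 1,
            shift_prob >= 0, shift_prob <= 1,
            all(dropout >= 0), all(dropout <= 1),
            unique_frac >= 0, jitter_sd >= 0)
  p <- as.list(environment())
  p$seed <- as.integer(seed)
  structure(p, class = "sim_params")
}

## Stage seeds derived once from the root seed so that each stage's
## randomness is reproducible independently of the others.
.stage_seeds <- function(seed) {
  r <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, 8L))
  names(r) <- c("archetype", "length", "placement", "fragment",
                "jitter", "dropout", "destruction", "unique")
  r
}

## Run code under a local RNG state; the caller's RNG is untouched.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate three correlated synthetic annotation sources
#'
#' Plants `sum(n_elements)` retroelement loci on the simulated genome
#' (no two elements overlap), decides per element whether the
#' fragment-style sources store it as one record or as >= 2 fragments
#' separated by gaps, and emits:
#'
#' * source `"M"` (merged style): one record per surviving element
#'   spanning all fragments including gaps, carrying a destruction
#'   degree;
#' * sources `"F1"` and `"F2"` (fragment style): one record per
#'   surviving fragment, with boundary jitter and occasional
#'   whole-record shifts, no destruction attribute.
#'
#' Per-source unique records are injected into reserved genomic slots
#' so they overlap no other record in any source. The returned truth
#' table links every emitted record to its element.
#'
#' @param params A [sim_params()].
#' @return A list with elements `sources` (named list of three
#'   [annotation_set()]s), `truth` (`data.table`: `element_id`,
#'   `source`, `record_id`, `superfamily`, `archetype`) and `params`.
#' @export
simulate_annotations <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  ss <- .stage_seeds(params$seed)
  n_total <- sum(params$n_elements)
  src_names <- c("M", "F1", "F2")
  n_unique <- round(params$unique_frac * n_total)

  ## -- element archetypes and superfamilies ------------------------------
  superfam <- rep(names(params$n_elements), times = params$n_elements)
  arche <- .with_seed(ss[["archetype"]], {
    w <- params$archetype_weights / sum(params$archetype_weights)
    sample(names(w), n_total, replace = TRUE, prob = w)
  })

  ## -- element span lengths ---------------------------------------------
  span <- .with_seed(ss[["length"]], .draw_lengths(arche, params))

  ## -- unique-record lengths (short, degraded-looking) -------------------
  uniq <- .with_seed(ss[["unique"]], {
    if (n_unique == 0L) NULL else data.table::data.table(
      source = rep(src_names, each = n_unique),
      length = round(stats::runif(3L * n_unique, 50, 400)),
      superfamily = sample(names(params$n_elements), 3L * n_unique,
                           replace = TRUE,
                           prob = params$n_elements / n_total))
  })
  n_uni_total <- if (is.null(uniq)) 0L else nrow(uniq)

  ## -- genome placement of all slots (elements + uniques) ----------------
  slot_len <- c(span, if (n_uni_total) uniq$length)
  n_slots <- length(slot_len)
  placement <- .with_seed(ss[["placement"]], {
    chrom_p <- params$genome$length / sum(params$genome$length)
    chrom <- sample(as.character(params$genome$chrom), n_slots,
                    replace = TRUE, prob = chrom_p)
    start <- integer(n_slots)
    for (cc in unique(chrom)) {
      idx <- which(chrom == cc)
      idx <- idx[sample.int(length(idx))]           # random genomic order
      gaps <- round(stats::rexp(length(idx), 1 / 1500)) + 100L
      ends <- cumsum(as.numeric(slot_len[idx]) + gaps)
      clen <- params$genome$length[params$genome$chrom == cc]
      if (ends[length(ends)] > clen)
        stop("genome too small: need ", format(ends[length(ends)]),
             " bp on ", cc, " but only ", format(clen), " available")
      start[idx] <- as.integer(ends) - as.integer(slot_len[idx])
    }
    list(chrom = chrom, start = start)
  })
  el_chrom <- placement$chrom[seq_len(n_total)]
  el_start <- placement$start[seq_len(n_total)]
  el_end <- el_start + span

  ## -- fragmentation structure ------------------------------------------
  frags <- .with_seed(ss[["fragment"]],
                      .fragment_elements(span, arche, params))
  # frags: list per element of data.table(off_start, off_end) within span

  element_id <- sprintf("E%06d", seq_len(n_total))

  ## -- per-source record construction ------------------------------------
  # M: one record per element, full span, destruction attached below
  m_rec <- data.table::data.table(
    element_id = element_id, chrom = el_chrom,
    start = el_start, end = el_end,
    superfamily = superfam, archetype = arche)

  # F sources: one record per fragment at absolute coordinates
  n_frags <- vapply(frags, nrow, integer(1L))
  f_base <- data.table::data.table(
    element_id = rep(element_id, n_frags),
    chrom = rep(el_chrom, n_frags),
    start = rep(el_start, n_frags) +
      as.integer(unlist(lapply(frags, `[[`, "off_start"))),
    end = rep(el_start, n_frags) +
      as.integer(unlist(lapply(frags, `[[`, "off_end"))),
    superfamily = rep(superfam, n_frags),
    archetype = rep(arche, n_frags),
    frag_i = as.integer(unlist(lapply(n_frags, seq_len))))

  f_sets <- .with_seed(ss[["jitter"]], {
    lapply(c("F1", "F2"), function(sn) {
      f <- data.table::copy(f_base)
      n <- nrow(f)
      if (params$jitter_sd > 0) {
        f[, start := start + round(stats::rnorm(n, 0, params$jitter_sd))]
        f[, end := end + round(stats::rnorm(n, 0, params$jitter_sd))]
      }
      if (params$shift_prob > 0 && params$shift_bp > 0) {
        sh <- stats::rbinom(n, 1L, params$shift_prob) *
          params$shift_bp * sign(stats::runif(n) - 0.5)
        f[, start := start + as.integer(sh)]
        f[, end := end + as.integer(sh)]
      }
      f[, start := pmax(start, 0L)]
      f[, end := pmax(end, start + 10L)]   # keep records non-degenerate
      f
    })
  })
  names(f_sets) <- c("F1", "F2")

  ## -- destruction for M records -----------------------------------------
  m_len <- m_rec$end - m_rec$start
  m_rec[, destruction := .with_seed(ss[["destruction"]], {
    hi <- m_len <= params$short_cutoff
    d <- numeric(length(m_len))
    d[hi] <- 100 * stats::rbeta(sum(hi), params$destruction_high[1L],
                                params$destruction_high[2L])
    d[!hi] <- 100 * stats::rbeta(sum(!hi), params$destruction_low[1L],
                                 params$destruction_low[2L])
    round(d, 2)
  })]

  ## -- dropout ------------------------------------------------------------
  keep <- .with_seed(ss[["dropout"]], {
    list(M = stats::runif(nrow(m_rec)) >= params$dropout[["M"]],
         F1 = stats::runif(nrow(f_sets$F1)) >= params$dropout[["F1"]],
         F2 = stats::runif(nrow(f_sets$F2)) >= params$dropout[["F2"]])
  })

  ## -- assemble annotation sets + truth -----------------------------------
  truth <- list()
  sources <- list()

  mk <- m_rec[keep$M]
  mk[, record_id := paste0("M_", element_id)]
  sources$M <- .sim_set(mk, "M", destruction = TRUE)
  truth$M <- mk[, .(element_id, source = "M", record_id,
                    superfamily, archetype)]

  for (sn in c("F1", "F2")) {
    fk <- f_sets[[sn]][keep[[sn]]]
    fk[, record_id := sprintf("%s_%s_%d", sn, element_id, frag_i)]
    sources[[sn]] <- .sim_set(fk, sn, destruction = FALSE)
    truth[[sn]] <- fk[, .(element_id, source = sn, record_id,
                          superfamily, archetype)]
  }

  ## -- injected uniques ----------------------------------------------------
  if (n_uni_total) {
    uniq[, chrom := placement$chrom[n_total + seq_len(n_uni_total)]]
    uniq[, start := placement$start[n_total + seq_len(n_uni_total)]]
    uniq[, end := start + length]
    uniq[, uid := seq_len(.N), by = source]
    uniq[, element_id := sprintf("U_%s_%04d", source, uid)]
    uniq[, record_id := paste0(source, "_", element_id)]
    uniq[, archetype := "unique"]
    u_destr <- .with_seed(ss[["unique"]] + 1L,
                          round(100 * stats::rbeta(n_uni_total, 2, 2), 2))
    for (sn in src_names) {
      u <- uniq[source == sn]
      if (nrow(u) == 0L) next
      u2 <- data.table::data.table(
        element_id = u$element_id, chrom = u$chrom,
        start = u$start, end = u$end, superfamily = u$superfamily,
        archetype = u$archetype, record_id = u$record_id,
        destruction = if (sn == "M") u_destr[uniq$source == sn] else NA_real_)
      add <- .sim_set(u2, sn, destruction = sn == "M")
      merged <- data.table::rbindlist(list(sources[[sn]]$records,
                                           add$records))
      sources[[sn]] <- annotation_set(merged, sn, "sim1")
      truth[[sn]] <- data.table::rbindlist(list(
        truth[[sn]],
        u2[, .(element_id, source = sn, record_id, superfamily, archetype)]))
    }
  }

  truth <- data.table::rbindlist(truth)
  data.table::setorder(truth, element_id, source, record_id)
  list(sources = sources, truth = truth, params = params)
}

## build an annotation_set from a simulated record table
.sim_set <- function(tab, source_name, destruction = FALSE) {
  rec <- data.table::data.table(
    record_id = tab$record_id, chrom = tab$chrom,
    start = tab$start, end = tab$end, strand = "*",
    family = paste0(tab$superfamily, "_fam"),
    repeat_class = "LTR",
    superfamily = tab$superfamily,
    destruction = if (destruction && "destruction" %in% names(tab))
      tab$destruction else NA_real_)
  suppressWarnings(annotation_set(rec, source_name, "sim1"))
}

.draw_lengths <- function(arche, params) {
  n <- length(arche)
  len <- numeric(n)
  i_f <- arche == "fragment"
  i_s <- arche == "solo_ltr"
  i_p <- arche == "provirus"
  len[i_f] <- round(stats::runif(sum(i_f), params$fragment_range[1L],
                                 params$fragment_range[2L]))
  if (any(i_s)) {
    comp <- sample(c(1L, 2L), sum(i_s), replace = TRUE)
    len[i_s] <- round(stats::rnorm(sum(i_s),
                                   params$solo_modes[comp],
                                   params$solo_sds[comp]))
  }
  len[i_p] <- round(stats::rlnorm(sum(i_p), params$provirus_meanlog,
                                  params$provirus_sdlog))
  len[i_p] <- pmin(pmax(len[i_p], 600), 9000)
  pmax(len, 50)
}

## For each element decide its fragment decomposition within [0, span).
## Non-fragmented elements yield one fragment covering the whole span.
.fragment_elements <- function(span, arche, params) {
  n <- length(span)
  eligible <- span >= params$frag_min_span
  do_frag <- eligible & stats::runif(n) < params$frag_prob
  k <- rep(1L, n)
  k[do_frag] <- 2L + stats::rpois(sum(do_frag), params$frag_extra_mean)
  lapply(seq_len(n), function(i) {
    L <- span[i]
    ki <- k[i]
    if (ki == 1L)
      return(data.table::data.table(off_start = 0L, off_end = as.integer(L)))
    # draw gaps; drop a fragment if the gaps would eat over half the span
    repeat {
      gaps <- round(stats::runif(ki - 1L, params$gap_range[1L],
                                 params$gap_range[2L]))
      if (sum(gaps) <= 0.5 * L) break
      if (ki > 2L) ki <- ki - 1L
      else { gaps <- rep(floor(0.4 * L / (ki - 1L)), ki - 1L); break }
    }
    fl_total <- L - sum(gaps)
    w <- stats::runif(ki, 0.5, 1.5)
    fl <- floor(fl_total * w / sum(w))
    fl[ki] <- fl_total - sum(fl[-ki])
    if (any(fl < 30)) fl <- .equal_split(fl_total, ki)
    off_end <- cumsum(fl) + c(0, cumsum(gaps))
    off_start <- off_end - fl
    data.table::data.table(off_start = as.integer(off_start),
                           off_end = as.integer(off_end))
  })
}

.equal_split <- function(total, k) {
  base <- floor(total / k)
  out <- rep(base, k)
  out[k] <- total - base * (k - 1L)
  out
}

#' Family map covering the simulated families
#'
#' The generator names each record's family `"<superfamily>_fam"`; this
#' helper returns the matching [family_map()] so classification can run
#' on simulated data.
#'
#' @param params A [sim_params()].
#' @return A [family_map()].
#' @export
sim_family_map <- function(params = sim_params()) {
  sf <- names(params$n_elements)
  family_map(data.frame(family = paste0(sf, "_fam"),
                        superfamily = sf, group = sf, role = "LTR",
                        ignored = 0L))
}

#' Noise-free variant of simulation parameters
#'
#' Convenience wrapper: jitter, shifts, dropout and unique injections
#' are all disabled; fragmentation can be kept or disabled.
#'
#' @param seed Root seed.
#' @param fragmentation Keep fragmentation on? Default `TRUE`.
#' @param ... Further overrides passed to [sim_params()].
#' @return A [sim_params()].
#' @export
sim_params_noiseless <- function(seed = 1L, fragmentation = TRUE, ...) {
  sim_params(seed = seed,
             frag_prob = if (fragmentation) 0.3 else 0,
             jitter_sd = 0, shift_prob = 0,
             dropout = c(M = 0, F1 = 0, F2 = 0),
             unique_frac = 0, ...)
}
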