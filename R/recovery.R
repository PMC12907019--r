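#' Truth-based recovery metrics for cross-source matching
#'
#' Scores how well the Sov-based matching recovers the planted
#' cross-source element linkage of a simulation. For every source pair
#' present in the scored-pair table:
#'
#' * **sensitivity** — among truth elements represented by at least one
#'   record in *both* sources of the pair, the fraction for which at
#'   least one of their record pairs was matched;
#' * **precision** — among matched record pairs, the fraction linking
#'   two records of the same truth element.
#'
#' @param pairs Scored pair table from [score_overlaps()] (must carry
#'   `source_a`, `source_b`, `id_a`, `id_b`, `matched`).
#' @param truth Truth table from [simulate_annotations()].
#' @return `data.table` with one row per source pair: `source_a`,
#'   `source_b`, `n_elements_both`, `n_recovered`, `sensitivity`,
#'   `n_matched_pairs`, `n_true_pairs`, `precision`.
#' @export
recovery_metrics <- function(pairs, truth) {
  p <- data.table::as.data.table(pairs)
  tr <- data.table::as.data.table(truth)
  need <- c("source_a", "source_b", "id_a", "id_b", "matched")
  if (length(setdiff(need, names(p))))
    stop("pairs must carry columns ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(c(p$id_a, p$id_b)), tr$record_id)
  if (length(unknown))
    stop("record id(s) absent from truth table, e.g. '", unknown[1L], "'")

  el_of <- tr$element_id
  names(el_of) <- tr$record_id

  combos <- unique(p[, c("source_a", "source_b"), with = FALSE])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sa <- combos$source_a[i]; sb <- combos$source_b[i]
    pi <- p[source_a == sa & source_b == sb]
    ea <- unique(tr[tr$source == sa, c("element_id")])
    eb <- unique(tr[tr$source == sb, c("element_id")])
    both <- intersect(ea$element_id, eb$element_id)
    m <- pi[pi$matched]
    same <- el_of[m$id_a] == el_of[m$id_b]
    recovered <- unique(el_of[m$id_a][same])
    data.table::data.table(
      source_a = sa, source_b = sb,
      n_elements_both = length(both),
      n_recovered = sum(both %in% recovered),
      sensitivity = if (length(both)) sum(both %in% recovered) / length(both)
      else NA_real_,
      n_matched_pairs = nrow(m),
      n_true_pairs = sum(same),
      precision = if (nrow(m)) sum(same) / nrow(m) else NA_real_)
  })
  data.table::rbindlist(out)
}
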