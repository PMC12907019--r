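## Superfamily assignment via a family -> superfamily mapping table.
## The five top-level ERV categories used throughout the package:
SUPERFAMILIES <- c("ERV1", "ERV2", "ERV3", "Gypsy", "Unclassified")

#' Load a family-to-superfamily mapping table
#'
#' The mapping table is a TSV with header columns `family`,
#' `superfamily`, `group`, `role` and optionally `ignored` (0/1). Each
#' row associates one repeat family/subfamily name (LTR or internal
#' portion, e.g. `"MER31B"` or `"HERVL-int"`) with one of the five ERV
#' superfamilies (ERV1, ERV2, ERV3, Gypsy, Unclassified) and one of the
#' named groups within it (e.g. `"HERVL"`, `"MaLR"`). Rows flagged
#' `ignored = 1` mark orphan types — internal regions without associated
#' LTRs or LTR types without internal regions — that the classification
#' step sets aside.
#'
#' @param path Path to the mapping TSV.
#' @return A `data.table` of class `family_map` with columns `family`,
#'   `superfamily`, `group`, `role`, `ignored`.
#' @export
load_family_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  family_map(tab)
}

#' Construct/validate a family map from a data.frame
#'
#' @param df data.frame with columns `family`, `superfamily`, `group`,
#'   `role`; optional `ignored` (0/1, default 0).
#' @return Validated `family_map` data.table.
#' @export
family_map <- function(df) {
  tab <- data.table::copy(data.table::as.data.table(df))
  need <- c("family", "superfamily", "group", "role")
  if (length(setdiff(need, names(tab))))
    stop("family map must have columns ", paste(need, collapse = ", "))
  if (!"ignored" %in% names(tab)) tab[, ignored := 0L]
  tab[, family := trimws(as.character(family))]
  tab[, superfamily := trimws(as.character(superfamily))]
  tab[, group := trimws(as.character(group))]
  tab[, role := trimws(as.character(role))]
  tab[, ignored := as.integer(ignored)]
  if (anyDuplicated(tab$family))
    stop("duplicate family key(s) in map: ",
         paste(utils::head(unique(tab$family[duplicated(tab$family)]), 5L),
               collapse = ", "))
  bad_sf <- setdiff(unique(tab$superfamily), SUPERFAMILIES)
  if (length(bad_sf))
    stop("unknown superfamily label(s) in map: ",
         paste(bad_sf, collapse = ", "),
         " (allowed: ", paste(SUPERFAMILIES, collapse = ", "), ")")
  if (any(!nzchar(tab$group)))
    stop("empty group value(s) in map")
  if (any(!tab$role %in% c("LTR", "internal")))
    stop("role must be 'LTR' or 'internal'")
  tab <- tab[, c("family", "superfamily", "group", "role", "ignored"),
             with = FALSE]
  data.table::setattr(tab, "class", c("family_map", "data.table", "data.frame"))
  tab
}

#' Assign superfamilies to an annotation set
#'
#' Looks up each record's `family` in the mapping table (exact,
#' case-sensitive match after whitespace trimming; suffix conventions
#' such as `-int` are never auto-stripped, so the map must enumerate
#' LTR and internal names separately) and sets the record's
#' `superfamily`. Families absent from the map, and families flagged
#' `ignored` in the map, are handled per `orphan_policy`: either dropped
#' from the output or retained with superfamily `"Unclassified"`. The
#' returned audit reconciles exactly with the input:
#' `n_assigned + n_unmapped + n_ignored_orphans == n_records(set)`.
#'
#' @param set An [annotation_set()].
#' @param map A [family_map()] (or the result of [load_family_map()]).
#' @param orphan_policy `"unclassified"` (default) or `"drop"`.
#' @return A list with elements `set` (the classified
#'   [annotation_set()]) and `audit` (list with `n_assigned`,
#'   `n_unmapped`, `n_ignored_orphans`, `unmapped_families`).
#' @export
assign_superfamilies <- function(set, map,
                                 orphan_policy = c("unclassified", "drop")) {
  stopifnot(inherits(set, "annotation_set"))
  orphan_policy <- match.arg(orphan_policy)
  map <- family_map(map)
  r <- data.table::copy(set$records)
  idx <- match(r$family, map$family)
  mapped <- !is.na(idx)
  ignored <- mapped & map$ignored[idx] == 1L
  assigned <- mapped & !ignored

  r[, superfamily := "Unclassified"]
  r[assigned, superfamily := map$superfamily[idx[assigned]]]

  audit <- list(
    n_assigned = sum(assigned),
    n_unmapped = sum(!mapped),
    n_ignored_orphans = sum(ignored),
    unmapped_families = sort(unique(r$family[!mapped])))

  if (orphan_policy == "drop") r <- r[assigned]
  out <- set
  out$records <- r
  list(set = out, audit = audit)
}
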