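#' County-code harmonization map
#'
#' Census units from different vintages can disagree on county identity.
#' A `county_code_map` records the corrections to apply to unit ids whose
#' county prefix (the leading `XX-YYY` of the id) changed between vintages:
#' renames (a county got a new FIPS code) and merges (several county codes
#' collapsed into one surviving code).
#'
#' @param renames Data frame with character columns `old` and `new`
#'   (county-code prefixes), or NULL.
#' @param merges List of `list(members = c(...), survivor = "XX-YYY")`
#'   entries, or NULL.
#' @return An object of class `county_code_map`.
#' @seealso [default_county_code_map()] for the 2010-to-2016 corrections.
#' @export
county_code_map <- function(renames = NULL, merges = NULL) {
  if (is.null(renames)) {
    renames <- data.frame(old = character(0), new = character(0),
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(renames), all(c("old", "new") %in% names(renames)))
  if (is.null(merges)) merges <- list()
  rename_src <- renames$old
  merge_members <- unlist(lapply(merges, `[[`, "members"))
  both <- intersect(rename_src, merge_members)
  if (length(both)) {
    stop("county code(s) appear both as rename source and merge member: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  structure(list(renames = renames, merges = merges),
            class = "county_code_map")
}

#' The default 2010-to-2016 county corrections
#'
#' Two counties changed identity between the 2010 decennial blocks and the
#' 2016 block-group vintage: Shannon County, SD (46-113) was renamed Oglala
#' Lakota County (46-102), and the independent city of Bedford, VA (51-515)
#' merged into Bedford County (51-019). These FIPS codes are configuration,
#' not logic: pass your own map to [harmonize_county_codes()] to override.
#'
#' @return A [county_code_map()].
#' @export
default_county_code_map <- function() {
  county_code_map(
    renames = data.frame(old = "46-113", new = "46-102",
                         stringsAsFactors = FALSE),
    merges = list(list(members = c("51-515", "51-019"), survivor = "51-019"))
  )
}

unit_county_prefix <- function(ids) {
  # county prefix = first two hyphen-separated tokens ("XX-YYY")
  vapply(strsplit(ids, "-", fixed = TRUE), function(p) {
    if (length(p) < 2L) stop("zone id lacks an XX-YYY county prefix: ",
                             paste(p, collapse = "-"), call. = FALSE)
    paste(p[1:2], collapse = "-")
  }, character(1))
}

replace_county_prefix <- function(ids, old, new) {
  pref <- unit_county_prefix(ids)
  hit <- pref == old
  ids[hit] <- paste0(new, substring(ids[hit], nchar(old) + 1L))
  ids
}

#' Harmonize census-unit county codes across vintages
#'
#' Applies a [county_code_map()] to the unit ids of a zone set: renames
#' replace the county prefix of affected ids, merges re-parent every member
#' unit under the surviving county code. Populations are preserved
#' record-by-record, so the total population is unchanged exactly. The
#' operation is idempotent.
#'
#' @param blocks A [zone_set()] whose ids carry an `XX-YYY` county prefix.
#' @param map A [county_code_map()]; defaults to the shipped 2010-to-2016
#'   corrections.
#' @return The zone set with corrected ids.
#' @export
harmonize_county_codes <- function(blocks, map = default_county_code_map()) {
  stopifnot(inherits(blocks, "zone_set"), inherits(map, "county_code_map"))
  ids <- blocks$zone_id
  pref <- unit_county_prefix(ids)
  for (i in seq_len(nrow(map$renames))) {
    old <- map$renames$old[i]; new <- map$renames$new[i]
    if (any(pref == old) && any(pref == new)) {
      stop(sprintf("rename target %s collides with an existing distinct county (source %s also present)",
                   new, old), call. = FALSE)
    }
    ids <- replace_county_prefix(ids, old, new)
    pref <- unit_county_prefix(ids)
  }
  for (m in map$merges) {
    for (member in setdiff(m$members, m$survivor)) {
      ids <- replace_county_prefix(ids, member, m$survivor)
    }
    pref <- unit_county_prefix(ids)
  }
  out <- blocks
  out$zone_id <- ids
  if (anyDuplicated(ids)) {
    stop("county harmonization produced duplicate unit ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out
}
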