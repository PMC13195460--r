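#' Clean a text value
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space, and normalizes Unicode to the composed form (NFC) so that
#' visually identical names from different sources compare equal. The
#' function is total and idempotent.
#'
#' @param raw Character vector (may contain `NA`).
#' @return Character vector of the same length.
#' @examples
#' clean_text("  6:2   FTOH ")
#' @export
clean_text <- function(raw) {
  out <- stringi::stri_trans_nfc(raw)
  out <- gsub("\\s+", " ", out, perl = TRUE)
  trimws(out)
}

#' Count special characters in a name
#'
#' A "special character" is any character that is not an ASCII letter, digit
#' or space; hyphens, commas, colons, brackets and non-ASCII characters all
#' count. Heavily punctuated systematic names (locants, stereo-descriptors)
#' therefore accumulate high counts, which is what the display-name trimming
#' rule keys on.
#'
#' @param name Character vector.
#' @return Integer vector of counts (`NA` maps to `NA`).
#' @examples
#' count_special_chars("3,3,4,4,5,5,6,6,7,7,8,8,8-Tridecafluorooctan-1-ol")
#' @export
count_special_chars <- function(name) {
  n <- nchar(gsub("[A-Za-z0-9 ]", "", name))
  n[is.na(name)] <- NA_integer_
  as.integer(n)
}

#' Select a consensus display name by majority vote
#'
#' Given the candidate names collected for one compound across sources and
#' reaction rows, selects the single name to display. Candidates are ranked
#' by frequency of mention (descending), then by character length
#' (ascending, preferring shorter common names over systematic ones), then
#' lexicographically — so the choice is deterministic and independent of
#' input order. The common abbreviation wins over a rarely-used systematic
#' name: e.g. "6:2 FTOH" beats
#' "3,3,4,4,5,5,6,6,7,7,8,8,8-Tridecafluorooctan-1-ol" on both frequency and
#' length. All candidate names remain available for search; this choice only
#' affects display.
#'
#' @param candidates Data frame with columns `name` (character) and `freq`
#'   (positive counts), one row per distinct candidate.
#' @return The selected name (length-1 character).
#' @export
consensus_name <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    stop("consensus_name requires at least one candidate", call. = FALSE)
  }
  stopifnot(all(c("name", "freq") %in% names(candidates)))
  stopifnot(all(candidates$freq >= 1))
  ord <- order(-candidates$freq, nchar(candidates$name),
               candidates$name, method = "radix")
  candidates$name[ord[1L]]
}

#' Apply the display-name trimming rule
#'
#' Very long names (more than 100 characters) or names containing more than
#' 20 special characters (see [count_special_chars()]) are unreadable in
#' graph displays; they are replaced by the compound identifier in the form
#' `"CID <n>"`. Shorter names pass through unchanged. The replacement itself
#' is short and free of special characters, so the rule is stable under
#' re-application.
#'
#' @param selected Character vector of consensus names.
#' @param cid Integer vector of compound identifiers (recycled if length 1).
#' @param max_length Length threshold (default 100; strictly greater trims).
#' @param max_special Special-character threshold (default 20; strictly
#'   greater trims).
#' @return Character vector of display names.
#' @export
display_name <- function(selected, cid, max_length = 100L, max_special = 20L) {
  if (length(cid) == 1L) cid <- rep(cid, length(selected))
  stopifnot(length(cid) == length(selected))
  trim <- !is.na(selected) &
    (nchar(selected) > max_length | count_special_chars(selected) > max_special)
  out <- selected
  out[trim | is.na(selected)] <- paste("CID", cid[trim | is.na(selected)])
  out
}

#' Collect candidate names per compound
#'
#' For each compound, gathers its IUPAC name and title from the compound
#' table (once each, when present) plus every cleaned occurrence of its name
#' in the predecessor/successor columns of the reaction table, with
#' frequencies. Reactions referencing a CID absent from the compound table
#' are recorded as dangling references (graph validation resolves them).
#'
#' @param compounds Compound data frame ([read_compound_table()]).
#' @param reactions Reaction data frame ([read_reaction_table()]); may have
#'   zero rows.
#' @return A data frame `(cid, name, freq)` with one row per distinct
#'   (compound, name) pair, ordered by cid; attribute `dangling` holds the
#'   CIDs mentioned in reactions but missing from the compound table.
#' @export
collect_names <- function(compounds, reactions) {
  mention_cid <- c(reactions$predecessor_cid, reactions$successor_cid)
  mention_name <- clean_text(c(reactions$predecessor_name,
                               reactions$successor_name))
  keep <- !is.na(mention_cid) & !is.na(mention_name) & nzchar(mention_name)
  mention_cid <- mention_cid[keep]
  mention_name <- mention_name[keep]

  dangling <- sort(unique(mention_cid[!mention_cid %in% compounds$cid]))

  table_names <- rbind(
    data.frame(cid = compounds$cid, name = clean_text(compounds$iupac_name),
               stringsAsFactors = FALSE),
    data.frame(cid = compounds$cid, name = clean_text(compounds$title),
               stringsAsFactors = FALSE)
  )
  table_names <- table_names[!is.na(table_names$name) & nzchar(table_names$name), ]
  table_names <- unique(table_names)

  all_names <- rbind(
    table_names,
    data.frame(cid = mention_cid, name = mention_name,
               stringsAsFactors = FALSE)
  )
  all_names <- all_names[all_names$cid %in% compounds$cid, , drop = FALSE]
  if (nrow(all_names)) {
    agg <- stats::aggregate(list(freq = rep(1L, nrow(all_names))),
                            by = all_names[c("cid", "name")], FUN = sum)
  } else {
    agg <- data.frame(cid = integer(0), name = character(0), freq = integer(0))
  }
  agg <- agg[order(agg$cid, -agg$freq, nchar(agg$name), agg$name,
                   method = "radix"), ]
  rownames(agg) <- NULL
  attr(agg, "dangling") <- dangling
  agg
}

#' Normalize compounds: consensus naming and display names
#'
#' Convenience wrapper running the whole naming stage: collects candidate
#' names ([collect_names()]), picks one consensus name per compound
#' ([consensus_name()]) and applies the trimming rule ([display_name()]).
#' Compounds with no usable name anywhere fall back to `"CID <n>"`.
#'
#' @inheritParams collect_names
#' @return The compound data frame with two added columns: `consensus_name`
#'   and `display_name`; the name table is attached as attribute `names`.
#' @export
normalize_compounds <- function(compounds, reactions) {
  nt <- collect_names(compounds, reactions)
  # nt is sorted by (cid, -freq, length, name): the first row per cid is
  # already the majority-vote winner, so selection is a single lookup.
  first <- nt[!duplicated(nt$cid), , drop = FALSE]
  sel <- first$name[match(compounds$cid, first$cid)]
  compounds$consensus_name <- sel
  compounds$display_name <- display_name(sel, compounds$cid)
  attr(compounds, "names_table") <- nt
  attr(compounds, "dangling_cids") <- attr(nt, "dangling")
  compounds
}
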