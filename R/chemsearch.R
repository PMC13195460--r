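#' Validate SMARTS patterns
#'
#' Checks each pattern by attempting a match against a trivial molecule via
#' Open Babel. Invalid patterns are reported together, before any real
#' matching begins, so a batch never half-runs on a broken query set.
#'
#' @param patterns Character vector of SMARTS.
#' @return Logical vector, `TRUE` where the pattern parses.
#' @export
validate_smarts <- function(patterns) {
  probe <- ChemmineOB::forEachMol("SMILES", "C", identity)
  vapply(patterns, function(p) {
    ok <- tryCatch({
      ChemmineOB::smartsSearch_OB(probe, p, uniqueMatches = TRUE)
      TRUE
    }, error = function(e) FALSE)
    ok
  }, logical(1), USE.NAMES = FALSE)
}

.parse_mols <- function(smiles) {
  lapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    tryCatch(ChemmineOB::forEachMol("SMILES", s, identity),
             error = function(e) NULL)
  })
}

#' SMARTS substructure search over the compound set
#'
#' Screens every compound structure (parsed from its SMILES) against one or
#' more labelled SMARTS patterns, e.g. `c("PFAS" = "C(F)(F)F", "triazine" =
#' "c1ncncn1")`. A compound is returned iff at least one pattern matches,
#' annotated with all matching labels. Compounds whose SMILES cannot be
#' parsed are skipped and listed in the `"skipped"` attribute. Results are
#' ordered by CID, so repeated runs are identical.
#'
#' @param graph A `tp_graph` (or a compound data frame).
#' @param patterns Named character vector of SMARTS; unnamed patterns get
#'   their own string as label. Labels must be unique.
#' @return Data frame `(cid, matched_labels)` where `matched_labels` is a
#'   comma-separated label list; attribute `matches` holds the full logical
#'   matrix (compound x pattern), attribute `skipped` the unparseable CIDs.
#' @export
substructure_search <- function(graph, patterns) {
  comp <- if (inherits(graph, "tp_graph")) graph$compounds else graph
  stopifnot(length(patterns) >= 1L)
  labels <- names(patterns)
  if (is.null(labels)) labels <- patterns
  labels[!nzchar(labels)] <- patterns[!nzchar(labels)]
  if (anyDuplicated(labels)) {
    stop("duplicate pattern labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  ok <- validate_smarts(patterns)
  if (!all(ok)) {
    stop("invalid SMARTS pattern(s): ",
         paste(sprintf("'%s'", patterns[!ok]), collapse = ", "),
         call. = FALSE)
  }
  mols <- .parse_mols(comp$smiles)
  parseable <- !vapply(mols, is.null, logical(1))
  skipped <- comp$cid[!parseable]

  hit <- matrix(FALSE, nrow = nrow(comp), ncol = length(patterns),
                dimnames = list(NULL, labels))
  for (j in seq_along(patterns)) {
    for (i in which(parseable)) {
      n <- tryCatch(
        ChemmineOB::smartsSearch_OB(mols[[i]], patterns[[j]],
                                    uniqueMatches = TRUE),
        error = function(e) 0)
      hit[i, j] <- n > 0
    }
  }
  any_hit <- rowSums(hit) > 0
  res <- data.frame(
    cid = comp$cid[any_hit],
    matched_labels = apply(hit[any_hit, , drop = FALSE], 1,
                           function(r) paste(labels[r], collapse = ",")),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$cid), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "matches") <- hit[any_hit, , drop = FALSE][order(comp$cid[any_hit]), , drop = FALSE]
  attr(res, "skipped") <- skipped
  res
}

#' Batch SMARTS search from a pattern file
#'
#' Runs [substructure_search()] independently for every line of a pattern
#' file (one SMARTS per line). Invalid lines are reported but do not stop
#' the valid ones from running, matching interactive batch behavior.
#'
#' @param graph A `tp_graph`.
#' @param pattern_file Path to a text file, one SMARTS per line.
#' @return Named list keyed by line number (`"1"`, `"2"`, ...); each valid
#'   entry is the single-pattern result data frame, each invalid entry is
#'   `NULL`. Attribute `invalid` is a data frame `(line, pattern)` of parse
#'   failures.
#' @export
batch_substructure <- function(graph, pattern_file) {
  lines <- trimws(readLines(pattern_file, warn = FALSE))
  nonempty <- which(nzchar(lines))
  ok <- logical(length(lines))
  ok[nonempty] <- validate_smarts(lines[nonempty])
  out <- stats::setNames(vector("list", length(nonempty)),
                         as.character(nonempty))
  for (i in nonempty) {
    if (ok[i]) {
      out[[as.character(i)]] <-
        substructure_search(graph, stats::setNames(lines[i], lines[i]))
    }
  }
  attr(out, "invalid") <- data.frame(
    line = setdiff(nonempty, nonempty[ok[nonempty]]),
    pattern = lines[setdiff(nonempty, nonempty[ok[nonempty]])],
    stringsAsFactors = FALSE)
  out
}
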