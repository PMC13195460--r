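#' Construct the small-precursor / large-product display filter
#'
#' Aggregated transformation data contains biological reactions in which
#' very small molecules (CO2, acetate, formaldehyde) appear as precursors of
#' much larger compounds (coenzymes, conjugates). Such edges act as data
#' hubs that spuriously bridge otherwise unrelated regions of the network
#' and produce implausible "pathways". The display filter hides a reaction
#' from pathway searches and compound views when the predecessor's
#' monoisotopic mass is strictly below `small_mass_max` and the successor's
#' strictly above `large_mass_min`. The defaults (60 Da / 300 Da) exclude
#' CO2 and acetate while retaining environmentally relevant small molecules
#' such as triazole (69 Da). Edges with either mass missing are never
#' hidden, and the underlying data is never modified — hidden edges can
#' always be listed with [hidden_edges()] or the filter disabled.
#'
#' @param small_mass_max Predecessor mass threshold in Da (default 60).
#' @param large_mass_min Successor mass threshold in Da (default 300).
#' @param enabled Apply the filter? (`FALSE` shows everything.)
#' @return An object of class `tp_edge_filter`.
#' @export
edge_filter <- function(small_mass_max = 60, large_mass_min = 300,
                        enabled = TRUE) {
  stopifnot(is.numeric(small_mass_max), is.numeric(large_mass_min),
            small_mass_max < large_mass_min, is.logical(enabled))
  structure(list(small_mass_max = small_mass_max,
                 large_mass_min = large_mass_min,
                 enabled = enabled),
            class = "tp_edge_filter")
}

#' @export
print.tp_edge_filter <- function(x, ...) {
  cat(sprintf("<tp_edge_filter> %s: hide predecessor < %g Da -> successor > %g Da\n",
              if (x$enabled) "enabled" else "disabled",
              x$small_mass_max, x$large_mass_min))
  invisible(x)
}

.hidden_mask <- function(graph, filter) {
  if (is.null(filter) || !filter$enabled) {
    return(rep(FALSE, nrow(graph$reactions)))
  }
  pm <- graph$compounds$exact_mass[
    match(graph$reactions$predecessor_cid, graph$compounds$cid)]
  sm <- graph$compounds$exact_mass[
    match(graph$reactions$successor_cid, graph$compounds$cid)]
  !is.na(pm) & !is.na(sm) & pm < filter$small_mass_max & sm > filter$large_mass_min
}

#' List the edges hidden by the display filter
#'
#' Returns exactly the reactions matching the filter predicate, with their
#' endpoint display names and masses — the list shown on the statistics
#' page. The graph itself is untouched.
#'
#' @param graph A `tp_graph`.
#' @param filter A [edge_filter()] (default thresholds if omitted).
#' @return Data frame `(edge_id, predecessor_cid, predecessor_name,
#'   predecessor_mass, successor_cid, successor_name, successor_mass,
#'   datasetref)`, ordered by `edge_id`.
#' @export
hidden_edges <- function(graph, filter = edge_filter()) {
  # report what the predicate matches even when display filtering is off
  probe <- edge_filter(filter$small_mass_max, filter$large_mass_min, TRUE)
  mask <- .hidden_mask(graph, probe)
  e <- graph$reactions[mask, , drop = FALSE]
  nm <- .display_names_for(graph, e$predecessor_cid)
  nm2 <- .display_names_for(graph, e$successor_cid)
  out <- data.frame(
    edge_id = e$edge_id,
    predecessor_cid = e$predecessor_cid,
    predecessor_name = nm,
    predecessor_mass = graph$compounds$exact_mass[
      match(e$predecessor_cid, graph$compounds$cid)],
    successor_cid = e$successor_cid,
    successor_name = nm2,
    successor_mass = graph$compounds$exact_mass[
      match(e$successor_cid, graph$compounds$cid)],
    datasetref = e$datasetref,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$edge_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.display_names_for <- function(graph, cids) {
  if (length(cids) == 0L) return(character(0))
  if ("display_name" %in% names(graph$compounds)) {
    nm <- graph$compounds$display_name[match(cids, graph$compounds$cid)]
    ifelse(is.na(nm), paste("CID", cids), nm)
  } else {
    paste("CID", cids)
  }
}

# igraph over visible edges only (filter applied); edge attribute edge_id
.visible_igraph <- function(graph, filter) {
  mask <- .hidden_mask(graph, filter)
  if (!any(mask)) return(graph$igraph)
  hidden_ids <- graph$reactions$edge_id[mask]
  igraph::delete_edges(graph$igraph,
                       which(igraph::E(graph$igraph)$edge_id %in% hidden_ids))
}

#' All shortest directed pathways between two compounds
#'
#' Finds the minimum number of reaction steps from `source_cid` to
#' `target_cid` over the visible (filtered) graph, following edge
#' direction, and enumerates every distinct minimal node sequence. All
#' steps count equally; parallel reactions between the same pair are one
#' step, and each hop in a returned path carries all parallel edge ids as
#' alternative evidence. `source == target` yields a single zero-length
#' path; an unreachable target yields an empty path list with length `NA`.
#'
#' @param graph A `tp_graph`.
#' @param source_cid,target_cid Compound CIDs present in the graph.
#' @param filter A [edge_filter()]; pass `edge_filter(enabled = FALSE)` to
#'   search the unfiltered graph.
#' @return An object of class `tp_pathways`: list with `source_cid`,
#'   `target_cid`, `length` (steps, `NA` if unreachable), `paths` (list;
#'   each path is a list with `cids` — node sequence — and `edge_ids` — a
#'   list of per-hop edge-id vectors) and `filter`.
#' @export
shortest_pathways <- function(graph, source_cid, target_cid,
                              filter = edge_filter()) {
  .check_cid(graph, source_cid, "source")
  .check_cid(graph, target_cid, "target")
  res <- structure(list(source_cid = source_cid, target_cid = target_cid,
                        length = NA_integer_, paths = list(),
                        filter = filter),
                   class = "tp_pathways")
  if (source_cid == target_cid) {
    res$length <- 0L
    res$paths <- list(list(cids = source_cid, edge_ids = list()))
    return(res)
  }
  vg <- .visible_igraph(graph, filter)
  # collapse parallel edges for path enumeration; re-attach ids per hop after
  sg <- igraph::simplify(vg, remove.multiple = TRUE, remove.loops = TRUE)
  sp <- suppressWarnings(igraph::all_shortest_paths(
    sg, from = .cid_chr(source_cid), to = .cid_chr(target_cid),
    mode = "out"))
  if (length(sp$res) == 0L) return(res)

  # visible edge-id lookup keyed "from->to"
  ends <- igraph::ends(vg, igraph::E(vg), names = TRUE)
  key <- paste0(ends[, 1], "->", ends[, 2])
  ids_by_pair <- split(igraph::E(vg)$edge_id, key)

  paths <- lapply(sp$res, function(vp) {
    cids <- as.integer(names(vp))
    hops <- lapply(seq_len(length(cids) - 1L), function(i) {
      sort(ids_by_pair[[paste0(cids[i], "->", cids[i + 1L])]])
    })
    list(cids = cids, edge_ids = hops)
  })
  # deterministic ordering of equally short paths
  ord <- order(vapply(paths, function(p) paste(p$cids, collapse = ","),
                      character(1)), method = "radix")
  res$paths <- paths[ord]
  res$length <- length(res$paths[[1]]$cids) - 1L
  res
}

#' @export
print.tp_pathways <- function(x, ...) {
  cat("<tp_pathways>", x$source_cid, "->", x$target_cid, "\n")
  if (is.na(x$length)) {
    cat("  no directed pathway\n")
  } else {
    cat(" ", length(x$paths), "shortest pathway(s) of", x$length, "step(s)\n")
    for (p in x$paths) cat("  ", paste(p$cids, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Neighborhood views of a compound
#'
#' The four per-compound network views: `direct` (predecessors and
#' successors within one reaction step), `predecessor_path` (all visible
#' ancestors within `depth_limit` steps), `successor_path` (all visible
#' descendants), and `all_connections` (the compound's full weakly
#' connected component of the visible graph; `depth_limit` is ignored).
#' Traversal crosses visible edges only, so a hidden hub edge does not
#' leak an unrelated data island into the view.
#'
#' @param graph A `tp_graph`.
#' @param focus_cid Compound CID.
#' @param mode One of `"direct"`, `"predecessor_path"`, `"successor_path"`,
#'   `"all_connections"`.
#' @param depth_limit Maximum traversal depth for the path views
#'   (default 10).
#' @param filter A [edge_filter()].
#' @return An object of class `tp_neighborhood`: list with `focus_cid`,
#'   `mode`, `depth_limit`, `compounds` (node slice), `reactions` (visible
#'   induced edge slice) and `filter`.
#' @export
neighborhood <- function(graph, focus_cid,
                         mode = c("direct", "predecessor_path",
                                  "successor_path", "all_connections"),
                         depth_limit = 10L, filter = edge_filter()) {
  mode <- match.arg(mode)
  .check_cid(graph, focus_cid, "focus")
  if (mode != "all_connections") stopifnot(depth_limit >= 1L)
  vg <- .visible_igraph(graph, filter)
  focus <- .cid_chr(focus_cid)
  verts <- switch(mode,
    direct = igraph::ego(vg, order = 1L, nodes = focus, mode = "all")[[1]],
    predecessor_path = igraph::ego(vg, order = depth_limit, nodes = focus,
                                   mode = "in")[[1]],
    successor_path = igraph::ego(vg, order = depth_limit, nodes = focus,
                                 mode = "out")[[1]],
    all_connections = igraph::subcomponent(vg, focus, mode = "all")
  )
  cids <- as.integer(names(verts))
  sub <- igraph::induced_subgraph(vg, verts)
  edge_ids <- igraph::E(sub)$edge_id
  reac <- graph$reactions[graph$reactions$edge_id %in% edge_ids, ,
                          drop = FALSE]
  if (mode == "direct") {
    # direct view: only edges incident to the focus itself
    reac <- reac[reac$predecessor_cid == focus_cid |
                 reac$successor_cid == focus_cid, , drop = FALSE]
  }
  comp <- graph$compounds[graph$compounds$cid %in% cids, , drop = FALSE]
  rownames(comp) <- rownames(reac) <- NULL
  structure(list(focus_cid = focus_cid, mode = mode,
                 depth_limit = if (mode == "all_connections") NA_integer_
                               else as.integer(depth_limit),
                 compounds = comp, reactions = reac, filter = filter),
            class = "tp_neighborhood")
}

#' @export
print.tp_neighborhood <- function(x, ...) {
  cat("<tp_neighborhood>", x$mode, "view of CID", x$focus_cid, "-",
      nrow(x$compounds), "compounds,", nrow(x$reactions), "reactions\n")
  invisible(x)
}

#' Look up compounds by identifier or name
#'
#' Matches each query against CID, InChIKey, InChIKey first block, SMILES
#' (exact string) and every collected name (case-insensitive exact match;
#' collected names include the consensus/display names, IUPAC names, titles
#' and all reaction-row spellings when the graph was built from
#' [normalize_compounds()] output). Misses are reported per query, never
#' thrown. Results can be restricted to compounds with at least one
#' incident reaction in a given biosystem.
#'
#' @param graph A `tp_graph`.
#' @param queries Character vector of identifiers, or a file path (one
#'   query per line) if `batch_file` is `TRUE`.
#' @param biosystem Optional biosystem restriction.
#' @param batch_file Treat `queries` as a path to a text file?
#' @return Data frame `(query, cid, matched_by)`, one row per hit; queries
#'   with no hit get one row with `cid = NA` and `matched_by = "miss"`.
#' @export
lookup <- function(graph, queries, biosystem = NULL, batch_file = FALSE) {
  if (batch_file) {
    queries <- readLines(queries, warn = FALSE)
    queries <- trimws(queries)
    queries <- queries[nzchar(queries)]
  }
  comp <- graph$compounds
  idx <- list(
    cid = stats::setNames(comp$cid, as.character(comp$cid)),
    inchikey = comp$inchikey, ikfb = comp$ikfb, smiles = comp$smiles
  )
  nt <- attr(comp, "names_table")
  name_cid <- c(
    if (!is.null(nt)) nt$cid else integer(0),
    comp$cid, comp$cid, comp$cid
  )
  name_val <- tolower(c(
    if (!is.null(nt)) nt$name else character(0),
    ifelse(is.na(comp$iupac_name), "", comp$iupac_name),
    ifelse(is.na(comp$title), "", comp$title),
    if ("display_name" %in% names(comp))
      ifelse(is.na(comp$display_name), "", comp$display_name)
    else rep("", nrow(comp))
  ))
  keep <- nzchar(name_val)
  name_cid <- name_cid[keep]; name_val <- name_val[keep]

  allowed <- NULL
  if (!is.null(biosystem)) {
    bs <- tolower(graph$reactions$biosystem)
    hit <- !is.na(bs) & bs == tolower(biosystem)
    allowed <- unique(c(graph$reactions$predecessor_cid[hit],
                        graph$reactions$successor_cid[hit]))
  }

  one <- function(q) {
    qt <- trimws(q)
    hits <- integer(0); how <- character(0)
    if (grepl("^[0-9]+$", qt) && qt %in% names(idx$cid)) {
      hits <- c(hits, idx$cid[[qt]]); how <- c(how, "cid")
    }
    for (field in c("inchikey", "ikfb", "smiles")) {
      m <- which(!is.na(idx[[field]]) & idx[[field]] == qt)
      if (length(m)) { hits <- c(hits, comp$cid[m]); how <- c(how, rep(field, length(m))) }
    }
    m <- which(name_val == tolower(qt))
    if (length(m)) { hits <- c(hits, name_cid[m]); how <- c(how, rep("name", length(m))) }
    if (length(hits)) {
      dup <- duplicated(hits)
      hits <- hits[!dup]; how <- how[!dup]
      if (!is.null(allowed)) {
        k <- hits %in% allowed
        hits <- hits[k]; how <- how[k]
      }
    }
    if (!length(hits)) {
      data.frame(query = q, cid = NA_integer_, matched_by = "miss",
                 stringsAsFactors = FALSE)
    } else {
      ord <- order(hits)
      data.frame(query = q, cid = hits[ord], matched_by = how[ord],
                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, lapply(queries, one))
  rownames(out) <- NULL
  out
}
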