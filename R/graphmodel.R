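#' Build the directed transformation multigraph
#'
#' Each compound is a node; each reaction row is a directed edge from its
#' predecessor to its successor. Parallel edges between the same ordered
#' pair are retained (duplicate reports are evidence, not noise) and remain
#' distinguishable by a stable `edge_id` assigned in input row order.
#' Reactions referencing a CID absent from the compound table are quarantined
#' into a dangling-edge list rather than silently dropped; self-loops are
#' kept and flagged by [validate_graph()]. Source data is never modified.
#'
#' @param compounds Compound data frame; CIDs must be unique.
#' @param reactions Reaction data frame.
#' @param meta Optional named list of provenance (e.g. `version`, `doi`).
#' @return An object of class `tp_graph`: list with `compounds` (node
#'   table), `reactions` (edge table with `edge_id`), `dangling`
#'   (quarantined edge rows), `igraph` (the backing directed
#'   \pkg{igraph} multigraph, vertex name = CID) and `meta`.
#' @examples
#' fx <- generate_fixture(fixture_spec(seed = 1, n_compounds = 16))
#' g <- build_graph(fx$compounds, fx$reactions)
#' g
#' @export
build_graph <- function(compounds, reactions, meta = list()) {
  if (anyDuplicated(compounds$cid)) {
    stop("duplicate CID rows in compound table: ",
         paste(unique(compounds$cid[duplicated(compounds$cid)]), collapse = ", "),
         "; CIDs are unique node keys", call. = FALSE)
  }
  reactions$edge_id <- seq_len(nrow(reactions))
  known <- reactions$predecessor_cid %in% compounds$cid &
           reactions$successor_cid %in% compounds$cid
  dangling <- reactions[!known, , drop = FALSE]
  edges <- reactions[known, , drop = FALSE]
  rownames(dangling) <- rownames(edges) <- NULL

  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$predecessor_cid),
                   to = as.character(edges$successor_cid),
                   edge_id = edges$edge_id,
                   stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = as.character(compounds$cid),
                          stringsAsFactors = FALSE)
  )
  if (!"datasetref" %in% names(edges)) edges$datasetref <- NA_character_
  meta$datasets <- sort(unique(stats::na.omit(edges$datasetref)))
  structure(list(compounds = compounds, reactions = edges,
                 dangling = dangling, igraph = ig, meta = meta),
            class = "tp_graph")
}

#' @export
print.tp_graph <- function(x, ...) {
  cat("<tp_graph>", nrow(x$compounds), "compounds,",
      nrow(x$reactions), "directed reactions")
  if (nrow(x$dangling)) cat(" (", nrow(x$dangling), "dangling quarantined)")
  cat("\n")
  if (length(x$meta$datasets)) {
    cat("  datasets:", paste(x$meta$datasets, collapse = ", "), "\n")
  }
  invisible(x)
}

.cid_chr <- function(cid) as.character(cid)

.check_cid <- function(graph, cid, what = "compound") {
  if (!cid %in% graph$compounds$cid) {
    stop("unknown ", what, " CID: ", cid, call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify node roles
#'
#' Every compound is exactly one of: `predecessor_only` (has outgoing
#' reactions, none incoming — a parent never observed as a product),
#' `successor_only` (a terminal transformation product), `both`, or
#' `isolated` (listed in the compound table but in no reaction).
#'
#' @param graph A `tp_graph`.
#' @return Data frame `(cid, role)`; attribute `counts` is the named count
#'   vector over the four classes (a partition of the node set).
#' @export
classify_roles <- function(graph) {
  din <- igraph::degree(graph$igraph, mode = "in")
  dout <- igraph::degree(graph$igraph, mode = "out")
  role <- ifelse(din == 0 & dout == 0, "isolated",
          ifelse(din == 0, "predecessor_only",
          ifelse(dout == 0, "successor_only", "both")))
  out <- data.frame(cid = as.integer(igraph::V(graph$igraph)$name),
                    role = unname(role), stringsAsFactors = FALSE)
  counts <- c(predecessor_only = sum(role == "predecessor_only"),
              successor_only = sum(role == "successor_only"),
              both = sum(role == "both"),
              isolated = sum(role == "isolated"))
  attr(out, "counts") <- counts
  out
}

#' Per-compound reaction degree
#'
#' Counts reactions per compound in one direction. With `distinct = TRUE`
#' parallel edges to the same partner collapse, giving the number of
#' distinct direct TPs (out) or distinct direct predecessors (in); with
#' `distinct = FALSE` every edge counts.
#'
#' @param graph A `tp_graph`.
#' @param direction `"in"` or `"out"`.
#' @param distinct Count distinct neighbor CIDs instead of edges?
#' @return Named integer vector, one entry per compound (names are CIDs).
#' @export
degree_profile <- function(graph, direction = c("out", "in"),
                           distinct = TRUE) {
  direction <- match.arg(direction)
  if (distinct) {
    g2 <- igraph::simplify(graph$igraph, remove.multiple = TRUE,
                           remove.loops = FALSE)
    d <- igraph::degree(g2, mode = direction)
  } else {
    d <- igraph::degree(graph$igraph, mode = direction)
  }
  stats::setNames(as.integer(d), igraph::V(graph$igraph)$name)
}

#' Validate a transformation graph
#'
#' Runs the consistency checks of the processing stage: node/edge counts
#' (optionally against expected values from the source release), absence of
#' dangling endpoints, the role-partition identity, self-loop detection,
#' isolated-compound detection, and agreement of each reaction's recorded
#' mass difference with the difference of its endpoint masses (0.01 Da
#' tolerance; violations are flagged, never rejected).
#'
#' @param graph A `tp_graph`.
#' @param expected_nodes,expected_edges Optional expected counts.
#' @param expected_version Optional version tag to compare with
#'   `graph$meta$version`.
#' @return An object of class `tp_validation`: list of named checks, each
#'   with `ok` and `detail`, plus `ok` (overall) — a report, never an error.
#' @export
validate_graph <- function(graph, expected_nodes = NULL,
                           expected_edges = NULL, expected_version = NULL) {
  checks <- list()
  nn <- nrow(graph$compounds); ne <- nrow(graph$reactions)
  checks$node_count <- list(
    ok = is.null(expected_nodes) || nn == expected_nodes,
    detail = if (is.null(expected_nodes)) sprintf("%d nodes", nn)
             else sprintf("%d nodes (expected %d)", nn, expected_nodes))
  checks$edge_count <- list(
    ok = is.null(expected_edges) || ne == expected_edges,
    detail = if (is.null(expected_edges)) sprintf("%d edges", ne)
             else sprintf("%d edges (expected %d)", ne, expected_edges))
  checks$version <- list(
    ok = is.null(expected_version) ||
         identical(graph$meta$version, expected_version),
    detail = sprintf("version %s (expected %s)",
                     graph$meta$version %||% "<unset>",
                     expected_version %||% "<any>"))
  checks$no_missing_endpoints <- list(
    ok = nrow(graph$dangling) == 0L,
    detail = if (nrow(graph$dangling) == 0L) "all edges connect valid CIDs"
             else paste("dangling edge ids:",
                        paste(graph$dangling$edge_id, collapse = ", ")))
  roles <- classify_roles(graph)
  cnt <- attr(roles, "counts")
  checks$role_partition <- list(
    ok = sum(cnt) == nn,
    detail = sprintf("predecessor_only %d + successor_only %d + both %d + isolated %d = %d (nodes %d)",
                     cnt[["predecessor_only"]], cnt[["successor_only"]],
                     cnt[["both"]], cnt[["isolated"]], sum(cnt), nn))
  loops <- graph$reactions$edge_id[
    graph$reactions$predecessor_cid == graph$reactions$successor_cid]
  checks$self_loops <- list(
    ok = length(loops) == 0L,
    detail = if (length(loops)) paste("self-loop edge ids:",
                                      paste(loops, collapse = ", "))
             else "none")
  iso <- roles$cid[roles$role == "isolated"]
  checks$isolated_compounds <- list(
    ok = length(iso) == 0L,
    detail = if (length(iso)) paste(length(iso), "compounds in no reaction")
             else "none")

  mass <- graph$compounds$exact_mass[
    match(graph$reactions$successor_cid, graph$compounds$cid)] -
    graph$compounds$exact_mass[
      match(graph$reactions$predecessor_cid, graph$compounds$cid)]
  have <- !is.na(mass) & !is.na(graph$reactions$mass_diff)
  bad_mass <- graph$reactions$edge_id[have &
    abs(mass - graph$reactions$mass_diff) > 0.01]
  checks$mass_diff_consistency <- list(
    ok = length(bad_mass) == 0L,
    detail = if (length(bad_mass))
               paste("mass_diff mismatch (>0.01 Da) on edge ids:",
                     paste(bad_mass, collapse = ", "))
             else sprintf("%d reactions checked against endpoint masses",
                          sum(have)))
  # informational checks (loops/isolated) don't gate overall validity
  hard <- c("node_count", "edge_count", "version", "no_missing_endpoints",
            "role_partition")
  structure(list(checks = checks,
                 ok = all(vapply(checks[hard], `[[`, TRUE, "ok"))),
            class = "tp_validation")
}

#' @export
print.tp_validation <- function(x, ...) {
  cat("<tp_validation>", if (x$ok) "PASS" else "FAIL", "\n")
  for (nm in names(x$checks)) {
    ch <- x$checks[[nm]]
    cat(sprintf("  [%s] %-22s %s\n", if (ch$ok) "ok" else "!!", nm, ch$detail))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a graph to node-link JSON
#'
#' Writes the full graph (node table, edge table with payloads, quarantined
#' dangling edges, metadata) as a JSON node-link document. Reading the file
#' back with [read_graph_json()] reproduces the graph exactly, which makes
#' the file usable as a cache between pipeline stages.
#'
#' @param graph A `tp_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  doc <- list(
    directed = TRUE, multigraph = TRUE,
    meta = graph$meta,
    nodes = graph$compounds,
    links = graph$reactions,
    dangling = graph$dangling
  )
  jsonlite::write_json(doc, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = FALSE)
  invisible(path)
}

#' Load a graph from node-link JSON
#'
#' @param path Path written by [write_graph_json()].
#' @return A `tp_graph` identical to the serialized one.
#' @export
read_graph_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- as.data.frame(doc$nodes, stringsAsFactors = FALSE)
  reac <- as.data.frame(doc$links, stringsAsFactors = FALSE)
  dang <- as.data.frame(doc$dangling, stringsAsFactors = FALSE)
  # restore the original row order (edge ids were assigned by it), so that
  # rebuilding reassigns identical ids
  if (nrow(dang)) reac <- rbind(reac, dang[names(reac)])
  reac <- reac[order(reac$edge_id), , drop = FALSE]
  reac$edge_id <- NULL
  comp$cid <- as.integer(comp$cid)
  reac$predecessor_cid <- as.integer(reac$predecessor_cid)
  reac$successor_cid <- as.integer(reac$successor_cid)
  meta <- doc$meta
  meta$datasets <- NULL
  build_graph(comp, reac, meta = meta)
}
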