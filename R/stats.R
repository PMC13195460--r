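#' Per-dataset reaction-pair uniqueness
#'
#' For every source dataset: the raw number of reaction rows
#' (`total_entries`), the number of distinct directed (predecessor,
#' successor) CID pairs found in no other dataset (`unique_pairs`), and
#' their ratio as a percentage (`unique_pct`, one decimal). Small curated
#' datasets often contribute a disproportionately unique share of pairs,
#' which this table makes visible.
#'
#' @param reactions Reaction data frame.
#' @return Data frame `(datasetref, total_entries, unique_pairs,
#'   unique_pct)` sorted by `total_entries` descending.
#' @export
dataset_summaries <- function(reactions) {
  if (nrow(reactions) == 0L) {
    return(data.frame(datasetref = character(0), total_entries = integer(0),
                      unique_pairs = integer(0), unique_pct = numeric(0)))
  }
  ds <- reactions$datasetref
  pair <- paste0(reactions$predecessor_cid, "->", reactions$successor_cid)
  # number of datasets each distinct pair occurs in
  pd <- unique(data.frame(pair = pair, ds = ds, stringsAsFactors = FALSE))
  n_ds_per_pair <- table(pd$pair)
  uniq_pair <- names(n_ds_per_pair)[n_ds_per_pair == 1L]

  refs <- names(sort(table(ds), decreasing = TRUE))
  out <- do.call(rbind, lapply(refs, function(r) {
    rows <- ds == r
    total <- sum(rows)
    upairs <- length(intersect(unique(pair[rows]), uniq_pair))
    data.frame(datasetref = r, total_entries = total, unique_pairs = upairs,
               unique_pct = round(upairs / total * 100, 1),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$total_entries, out$datasetref), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top compounds by distinct reaction partners
#'
#' Ranks compounds by the number of distinct direct TPs
#' (`direction = "successors"`) or distinct direct predecessors
#' (`direction = "predecessors"`). Parallel edges and repeated datasets do
#' not inflate the counts; ties break by ascending CID.
#'
#' @param graph A `tp_graph`.
#' @param direction `"successors"` or `"predecessors"`.
#' @param n Number of compounds to return (default 10).
#' @return Data frame `(cid, name, count)` in rank order.
#' @export
top_compounds <- function(graph, direction = c("successors", "predecessors"),
                          n = 10L) {
  direction <- match.arg(direction)
  d <- degree_profile(graph,
                      direction = if (direction == "successors") "out" else "in",
                      distinct = TRUE)
  cid <- as.integer(names(d))
  ord <- order(-d, cid)
  top <- utils::head(ord, n)
  top <- top[d[top] > 0]
  data.frame(cid = cid[top],
             name = .display_names_for(graph, cid[top]),
             count = unname(d[top]),
             stringsAsFactors = FALSE)
}

#' Mass-difference distribution and mass-vs-XlogP pairs
#'
#' Groups reactions by their recorded mass difference (successor minus
#' predecessor, Da) after rounding to `bin_precision` decimals, so that
#' e.g. every +15.995 Da oxygen addition falls into one bin regardless of
#' source rounding. Each bin is annotated with its most frequent
#' transformation label. Also emits the paired (mass_diff, xlogp_diff)
#' values for plotting; reactions lacking a mass difference are excluded
#' and counted.
#'
#' @param reactions Reaction data frame.
#' @param bin_precision Decimals to round mass differences to (default 3).
#' @param top_n Number of top bins to return (default 10).
#' @return List with `bins` (data frame `mass_diff, count, example_label`,
#'   count-descending), `pairs` (data frame of complete
#'   `(mass_diff, xlogp_diff)` cases) and `n_missing_mass_diff`.
#' @export
mass_xlogp_distribution <- function(reactions, bin_precision = 3L,
                                    top_n = 10L) {
  md <- reactions$mass_diff
  have <- !is.na(md)
  binned <- round(md[have], bin_precision)
  labels <- reactions$transformation[have]
  if (length(binned)) {
    tab <- table(binned)
    bins <- data.frame(mass_diff = as.numeric(names(tab)),
                       count = as.integer(tab), stringsAsFactors = FALSE)
    bins$example_label <- vapply(bins$mass_diff, function(b) {
      lab <- labels[binned == b]
      lab <- lab[!is.na(lab)]
      if (!length(lab)) return(NA_character_)
      names(sort(table(lab), decreasing = TRUE))[1]
    }, character(1))
    bins <- bins[order(-bins$count, bins$mass_diff), , drop = FALSE]
    rownames(bins) <- NULL
  } else {
    bins <- data.frame(mass_diff = numeric(0), count = integer(0),
                       example_label = character(0))
  }
  ok_pair <- have & !is.na(reactions$xlogp_diff)
  list(bins = utils::head(bins, top_n),
       pairs = data.frame(mass_diff = md[ok_pair],
                          xlogp_diff = reactions$xlogp_diff[ok_pair]),
       n_missing_mass_diff = sum(!have))
}

#' Multistep pathway statistics
#'
#' An "original predecessor" is a compound with no incoming visible
#' reactions (in-degree 0 — a source of the network). For every other
#' compound the minimum directed distance from any original predecessor is
#' computed over the visible graph; compounds at distance 2 or more are the
#' ones whose provenance a single-step resource cannot show. For each such
#' compound, the number of distinct source datasets on the edges of its
#' visible ancestor subgraph measures how often multistep pathways cross
#' dataset boundaries.
#'
#' @param graph A `tp_graph`.
#' @param filter A [edge_filter()] applied before traversal.
#' @return List with `n_multistep` (compounds at >= 2 steps from every
#'   reachable source), `pct_multi_dataset` (whole-percent share of those
#'   whose ancestor subgraph spans >= 2 datasets), `multistep_cids` and
#'   `n_original_predecessors`.
#' @export
multistep_stats <- function(graph, filter = edge_filter()) {
  vg <- .visible_igraph(graph, filter)
  din <- igraph::degree(vg, mode = "in")
  sources <- igraph::V(vg)[din == 0]
  if (length(sources) == 0L || igraph::ecount(vg) == 0L) {
    return(list(n_multistep = 0L, pct_multi_dataset = NA_real_,
                multistep_cids = integer(0),
                n_original_predecessors = length(sources)))
  }
  # multi-source BFS via a virtual super-source
  aug <- igraph::add_vertices(vg, 1, name = ".super")
  aug <- igraph::add_edges(aug, rbind(".super", names(sources)))
  dist <- igraph::distances(aug, v = ".super",
                            to = igraph::V(vg)$name, mode = "out")[1, ] - 1
  multi <- names(dist)[is.finite(dist) & dist >= 2]
  multi_cids <- sort(as.integer(multi))

  if (length(multi)) {
    eid_tab <- graph$reactions
    spans <- vapply(multi, function(v) {
      anc <- igraph::subcomponent(vg, v, mode = "in")
      sub <- igraph::induced_subgraph(vg, anc)
      ids <- igraph::E(sub)$edge_id
      length(unique(stats::na.omit(
        eid_tab$datasetref[match(ids, eid_tab$edge_id)])))
    }, numeric(1))
    pct <- round(100 * mean(spans >= 2))
  } else {
    pct <- NA_real_
  }
  list(n_multistep = length(multi_cids), pct_multi_dataset = pct,
       multistep_cids = multi_cids,
       n_original_predecessors = length(sources))
}

#' Full statistics report
#'
#' Assembles the machine-readable statistics overview of a transformation
#' graph: node/edge totals, role partition, degree-threshold counts (>= 10
#' distinct TPs, exactly 1 TP, > 10 distinct predecessors, exactly 1
#' predecessor), top compounds in both directions, per-dataset uniqueness,
#' mass-difference bins and mass-vs-XlogP pairs, multistep pathway counts,
#' weakly connected component sizes, and the list of reactions hidden by
#' the display filter. Re-running on the same graph yields an identical
#' report.
#'
#' @param graph A `tp_graph`.
#' @param filter A [edge_filter()] (used for the hidden-edge list and
#'   multistep statistics).
#' @param top_n Length of the top-compound and mass-bin lists.
#' @return An object of class `tp_stats` (a named list).
#' @export
tp_summary <- function(graph, filter = edge_filter(), top_n = 10L) {
  roles <- classify_roles(graph)
  rc <- attr(roles, "counts")
  out_deg <- degree_profile(graph, "out", distinct = TRUE)
  in_deg <- degree_profile(graph, "in", distinct = TRUE)
  comp_sizes <- igraph::components(graph$igraph, mode = "weak")$csize
  md <- mass_xlogp_distribution(graph$reactions, top_n = top_n)
  ms <- multistep_stats(graph, filter)
  structure(list(
    n_compounds = nrow(graph$compounds),
    n_reactions = nrow(graph$reactions),
    n_dangling = nrow(graph$dangling),
    roles = rc,
    degree_thresholds = c(
      tp_ge10 = sum(out_deg >= 10),
      tp_eq1 = sum(out_deg == 1),
      pred_gt10 = sum(in_deg > 10),
      pred_eq1 = sum(in_deg == 1)
    ),
    top_successors = top_compounds(graph, "successors", top_n),
    top_predecessors = top_compounds(graph, "predecessors", top_n),
    datasets = dataset_summaries(graph$reactions),
    mass_diff_bins = md$bins,
    mass_xlogp_pairs = md$pairs,
    n_missing_mass_diff = md$n_missing_mass_diff,
    multistep = ms[c("n_multistep", "pct_multi_dataset",
                     "n_original_predecessors")],
    components = c(n = length(comp_sizes),
                   smallest = if (length(comp_sizes)) min(comp_sizes) else 0L,
                   largest = if (length(comp_sizes)) max(comp_sizes) else 0L),
    mean_reactions_per_compound =
      if (nrow(graph$compounds)) nrow(graph$reactions) / nrow(graph$compounds)
      else 0,
    hidden_edges = hidden_edges(graph, filter),
    filter = filter
  ), class = "tp_stats")
}

#' @export
print.tp_stats <- function(x, ...) {
  cat("<tp_stats>\n")
  cat(sprintf("  compounds: %d   reactions: %d\n", x$n_compounds, x$n_reactions))
  cat(sprintf("  roles: %d predecessor-only, %d successor-only, %d both, %d isolated\n",
              x$roles[["predecessor_only"]], x$roles[["successor_only"]],
              x$roles[["both"]], x$roles[["isolated"]]))
  cat(sprintf("  degree: %d compounds with >=10 distinct TPs, %d with >10 distinct predecessors\n",
              x$degree_thresholds[["tp_ge10"]], x$degree_thresholds[["pred_gt10"]]))
  cat(sprintf("  multistep: %d compounds >=2 steps from an original predecessor (%s%% spanning >=2 datasets)\n",
              x$multistep$n_multistep,
              ifelse(is.na(x$multistep$pct_multi_dataset), "-",
                     x$multistep$pct_multi_dataset)))
  cat(sprintf("  hidden by display filter: %d reactions\n", nrow(x$hidden_edges)))
  invisible(x)
}

#' Serialize a statistics report to JSON
#'
#' @param stats A `tp_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  x <- unclass(stats)
  x$filter <- unclass(x$filter)
  x$roles <- as.list(x$roles)
  x$degree_thresholds <- as.list(x$degree_thresholds)
  x$components <- as.list(x$components)
  jsonlite::write_json(x, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
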