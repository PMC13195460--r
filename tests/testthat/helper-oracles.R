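# Independent oracles and small table builders used across the suite.
# Everything here is deliberately brute-force and free of the package's
# graph machinery, so tests compare two independent routes.

make_compounds <- function(cids, masses = NULL, smiles = NULL,
                           titles = NULL) {
  n <- length(cids)
  data.frame(
    cid = as.integer(cids),
    smiles = if (is.null(smiles)) rep(NA_character_, n) else smiles,
    inchi = rep(NA_character_, n),
    inchikey = rep(NA_character_, n),
    ikfb = rep(NA_character_, n),
    formula = rep(NA_character_, n),
    exact_mass = if (is.null(masses)) rep(NA_real_, n) else masses,
    xlogp = rep(NA_real_, n),
    iupac_name = rep(NA_character_, n),
    title = if (!is.null(titles)) titles
            else if (n) paste0("cmpd", cids) else character(0),
    stringsAsFactors = FALSE
  )
}

make_reactions <- function(pred, succ, datasetref = "DS01",
                           mass_diff = NA_real_, biosystem = NA_character_,
                           transformation = NA_character_) {
  n <- length(pred)
  data.frame(
    predecessor_cid = as.integer(pred),
    successor_cid = as.integer(succ),
    predecessor_name = if (n) paste0("cmpd", pred) else character(0),
    successor_name = if (n) paste0("cmpd", succ) else character(0),
    reaction_smiles = rep(NA_character_, n),
    desc_reaction_smiles = rep(NA_character_, n),
    biosystem = rep_len(biosystem, n),
    enzyme = rep(NA_character_, n),
    transformation = rep_len(transformation, n),
    mass_diff = rep_len(mass_diff, n),
    xlogp_diff = rep(NA_real_, n),
    datasetref = rep_len(datasetref, n),
    datasetdoi = rep(NA_character_, n),
    evidenceref = rep(NA_character_, n),
    evidencedoi = rep(NA_character_, n),
    sourcecommentfull = rep(NA_character_, n),
    sourcecomment = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
}

# All simple directed paths from `from` to `to` over the collapsed pair
# set, by exhaustive depth-first enumeration; returns the minimal-length
# node sequences as sorted "a,b,c" strings (empty if unreachable).
oracle_min_paths <- function(pred, succ, from, to) {
  pairs <- unique(data.frame(p = pred, s = succ))
  pairs <- pairs[pairs$p != pairs$s, , drop = FALSE]
  adj <- split(pairs$s, pairs$p)
  found <- list()
  recurse <- function(path) {
    head <- path[length(path)]
    if (head == to) { found[[length(found) + 1L]] <<- path; return() }
    for (nxt in adj[[as.character(head)]]) {
      if (!nxt %in% path) recurse(c(path, nxt))
    }
  }
  if (from == to) return(as.character(from))
  recurse(from)
  if (!length(found)) return(character(0))
  lens <- vapply(found, length, integer(1))
  keep <- found[lens == min(lens)]
  sort(vapply(keep, paste, character(1), collapse = ","))
}

# Brute-force per-dataset uniqueness: a directed pair is unique to a
# dataset iff no other dataset contains it.
oracle_dataset_unique <- function(reactions) {
  ds <- unique(reactions$datasetref)
  sapply(ds, function(d) {
    mine <- unique(paste(reactions$predecessor_cid[reactions$datasetref == d],
                         reactions$successor_cid[reactions$datasetref == d]))
    others <- unique(paste(
      reactions$predecessor_cid[reactions$datasetref != d],
      reactions$successor_cid[reactions$datasetref != d]))
    sum(!mine %in% others)
  })
}

# Brute-force degree tally from the raw edge list.
oracle_degree <- function(cids, pred, succ, direction, distinct) {
  vapply(cids, function(v) {
    nb <- if (direction == "out") succ[pred == v] else pred[succ == v]
    if (distinct) length(unique(nb)) else length(nb)
  }, integer(1))
}

# Brute-force multi-source BFS distance from every in-degree-0 node.
oracle_min_source_distance <- function(cids, pred, succ) {
  sources <- cids[!cids %in% succ]
  dist <- stats::setNames(rep(Inf, length(cids)), cids)
  dist[as.character(sources)] <- 0
  repeat {
    changed <- FALSE
    for (i in seq_along(pred)) {
      d <- dist[[as.character(pred[i])]] + 1
      if (d < dist[[as.character(succ[i])]]) {
        dist[[as.character(succ[i])]] <- d
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  dist
}

# Random directed multigraph as compound/reaction tables (parallel edges
# and, optionally, self-loops allowed).
random_multigraph <- function(n_nodes, n_edges, loops = FALSE,
                              n_datasets = 1L) {
  cids <- 100L + seq_len(n_nodes)
  repeat {
    pred <- sample(cids, n_edges, replace = TRUE)
    succ <- sample(cids, n_edges, replace = TRUE)
    if (loops || !any(pred == succ)) break
    keep <- pred != succ
    pred <- pred[keep]; succ <- succ[keep]
    if (length(pred)) break
  }
  list(compounds = make_compounds(cids),
       reactions = make_reactions(pred, succ,
         datasetref = sample(sprintf("DS%02d", seq_len(n_datasets)),
                             length(pred), replace = TRUE)))
}

write_fixture_csvs <- function(fx, dir = tempfile("fx")) {
  write_source_tables(fx$compounds, fx$reactions, dir)
}
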