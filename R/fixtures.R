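# Fixed pool of hand-checked structures (monoisotopic masses verified with
# Open Babel). "small" members sit below the 60 Da display-filter threshold,
# "large" members above 300 Da; "mid" members can never trigger the filter.
.structure_pool <- data.frame(
  name = c("carbon dioxide", "formaldehyde", "methanol",
           "ethanol", "triazole", "benzene", "toluene", "phenol", "aniline",
           "pyridine", "catechol", "benzoic acid", "TFA", "atrazine",
           "caffeine", "dibutyl phthalate", "acetic acid",
           "6:2 FTOH", "PFOA", "sucrose"),
  smiles = c("O=C=O", "C=O", "CO",
             "CCO", "c1nc[nH]n1", "c1ccccc1", "Cc1ccccc1", "Oc1ccccc1",
             "Nc1ccccc1", "c1ccncc1", "Oc1ccccc1O", "OC(=O)c1ccccc1",
             "OC(=O)C(F)(F)F", "CCNc1nc(NC(C)C)nc(Cl)n1",
             "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "CCCCOC(=O)c1ccccc1C(=O)OCCCC",
             "CC(=O)O",
             "OCCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
             "OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
             "OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O"),
  formula = c("CO2", "CH2O", "CH4O", "C2H6O", "C2H3N3", "C6H6", "C7H8",
              "C6H6O", "C6H7N", "C5H5N", "C6H6O2", "C7H6O2", "C2HF3O2",
              "C8H14ClN5", "C8H10N4O2", "C16H22O4", "C2H4O2",
              "C8H5F13O", "C8HF15O2", "C12H22O11"),
  mass = c(43.989829, 30.010565, 32.026215, 46.041865, 69.032697,
           78.046950, 92.062600, 94.041865, 93.057849, 79.042199,
           110.036779, 122.036779, 113.992864, 215.093773, 194.080376,
           278.151809, 60.021129, 364.013282, 413.973703, 342.116212),
  xlogp = c(0.9, 0.4, -0.5, -0.1, -0.6, 2.1, 2.7, 1.5, 1.1, 0.7, 0.9,
            1.9, 0.5, 2.6, -0.1, 4.5, -0.2, 4.8, 4.9, -3.7),
  aromatic = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
               TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
               FALSE, FALSE),
  cf3 = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
          FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE,
          TRUE, FALSE),
  stringsAsFactors = FALSE
)
.structure_pool$class <- ifelse(.structure_pool$mass < 60, "small",
                         ifelse(.structure_pool$mass > 300, "large", "mid"))

# format-valid synthetic InChIKey, deterministic in the cid
.synthetic_inchikey <- function(cid) {
  blk <- function(n, width) {
    d <- (cid * n + seq_len(width) * 7L) %% 26L
    paste(LETTERS[d + 1L], collapse = "")
  }
  paste0(blk(3L, 14L), "-", blk(5L, 10L), "-N")
}

#' Specify a synthetic transformation dataset
#'
#' Describes a synthetic compound/reaction table pair with controlled
#' structure: designated probe chains with known shortest-path lengths,
#' hub compounds, cross-dataset duplicated pairs, name-spelling variants,
#' and injected small-precursor/large-product edges that the display
#' filter must hide. Generation from a spec is a pure function of the
#' seed: the same spec yields byte-identical tables.
#'
#' @param seed Integer RNG seed.
#' @param n_compounds Number of compounds (minimum 12).
#' @param n_reactions Approximate number of base reaction rows before
#'   duplicates.
#' @param n_datasets Number of source datasets (`DS01`, `DS02`, ...).
#' @param duplicate_pair_rate Fraction of base pairs re-reported in a
#'   second dataset, in `[0, 1]`.
#' @param hub_spec Optional list of hub requests, each a list with `out`
#'   and/or `in_` distinct-degree targets (hub compounds are chosen among
#'   mid-mass compounds).
#' @param name_variant_rate Fraction of compounds whose reaction-row names
#'   alternate between a short title and a longer spelling, in `[0, 1]`.
#' @param small_large_pairs Number of injected edges from a sub-60 Da
#'   compound to a super-300 Da compound (the filter's targets).
#' @param dag_only Restrict random edges to ascending CID order (acyclic)?
#' @return An object of class `tp_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_compounds = 60L, n_reactions = 120L,
                         n_datasets = 3L, duplicate_pair_rate = 0.1,
                         hub_spec = list(), name_variant_rate = 0.3,
                         small_large_pairs = 2L, dag_only = FALSE) {
  stopifnot(n_compounds >= 12L, n_reactions >= 0L, n_datasets >= 1L,
            duplicate_pair_rate >= 0, duplicate_pair_rate <= 1,
            name_variant_rate >= 0, name_variant_rate <= 1,
            small_large_pairs >= 0L)
  n_mid <- n_compounds - 2L * small_large_pairs
  if (n_mid < 10L) {
    stop("infeasible spec: need at least 10 mid-mass compounds after ",
         "reserving ", 2L * small_large_pairs, " for small/large pairs",
         call. = FALSE)
  }
  for (h in hub_spec) {
    want <- max(c(h$out, h$in_, 0L))
    if (want >= n_mid) {
      stop("infeasible spec: hub degree ", want, " >= ", n_mid,
           " available mid-mass compounds", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
                 n_reactions = as.integer(n_reactions),
                 n_datasets = as.integer(n_datasets),
                 duplicate_pair_rate = duplicate_pair_rate,
                 hub_spec = hub_spec, name_variant_rate = name_variant_rate,
                 small_large_pairs = as.integer(small_large_pairs),
                 dag_only = isTRUE(dag_only)),
            class = "tp_fixture_spec")
}

# shortest directed step count by plain breadth-first search over the
# collapsed pair list; independent of the graph machinery on purpose, so
# the ledger is ground truth rather than an echo of the implementation
.bfs_steps <- function(pred, succ, from, to) {
  if (from == to) return(0L)
  adj <- split(succ, pred)
  dist <- stats::setNames(0L, as.character(from))
  frontier <- from
  step <- 0L
  seen <- as.character(from)
  while (length(frontier)) {
    step <- step + 1L
    nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nxt <- nxt[!as.character(nxt) %in% seen]
    if (!length(nxt)) return(NA_integer_)
    if (to %in% nxt) return(step)
    seen <- c(seen, as.character(nxt))
    frontier <- nxt
  }
  NA_integer_
}

#' Generate synthetic compound and reaction tables
#'
#' Realizes a [fixture_spec()] into a compound table and a reaction table
#' in the source CSV schemas, plus a ledger of ground truth recorded at
#' construction time: the true role of every node, per-dataset unique-pair
#' counts, shortest-path lengths for designated probe pairs (a 3-step
#' chain and a 2-path diamond), the row positions of the injected
#' filter-target edges, and per-compound substructure flags (aromatic,
#' CF3). Structures come from a fixed pool of valid SMILES with verified
#' monoisotopic masses; `mass_diff`/`xlogp_diff` fields are consistent
#' with the endpoint values. The tables exercise contracts, not realistic
#' reaction chemistry.
#'
#' @param spec A [fixture_spec()].
#' @return List with `compounds`, `reactions` (canonical schemas) and
#'   `ledger` (list: `roles`, `dataset_unique`, `probes`,
#'   `hidden_edge_ids`, `structure_flags`, `hubs`).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "tp_fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed, kind = "Mersenne-Twister", sample.kind = "Rejection")

  pool <- .structure_pool
  n <- spec$n_compounds
  nsl <- spec$small_large_pairs
  cls <- c(rep("small", nsl), rep("large", nsl), rep("mid", n - 2L * nsl))
  pick <- integer(n)
  for (cl in c("small", "large", "mid")) {
    idx <- which(cls == cl)
    src <- which(pool$class == cl)
    pick[idx] <- src[((seq_along(idx) - 1L) %% length(src)) + 1L]
  }
  cid <- 1000L + seq_len(n)
  title <- paste0(pool$name[pick], " #", cid)
  long_name <- paste0("synthetic ", pool$formula[pick], " derivative no. ",
                      cid, " (", pool$name[pick], " series)")
  compounds <- data.frame(
    cid = cid,
    smiles = pool$smiles[pick],
    inchi = paste0("InChI=1S/", pool$formula[pick]),
    inchikey = vapply(cid, .synthetic_inchikey, character(1)),
    ikfb = NA_character_,
    formula = pool$formula[pick],
    exact_mass = pool$mass[pick],
    xlogp = pool$xlogp[pick],
    iupac_name = long_name,
    title = title,
    stringsAsFactors = FALSE
  )
  compounds$ikfb <- substr(compounds$inchikey, 1L, 14L)

  mid_cids <- cid[cls == "mid"]
  small_cids <- cid[cls == "small"]
  large_cids <- cid[cls == "large"]

  # name variants: reaction rows for these compounds alternate spellings;
  # the short title must still win the majority vote
  variant <- cid %in% sample(cid, round(spec$name_variant_rate * n))
  row_name <- function(cids, k) {
    nm <- title[match(cids, cid)]
    lv <- long_name[match(cids, cid)]
    v <- variant[match(cids, cid)] & (k %% 3L == 0L)  # minority spelling
    ifelse(v, lv, nm)
  }

  # --- edge construction (row order defines edge ids) -----------------
  pred <- integer(0); succ <- integer(0); tag <- character(0)

  add <- function(p, s, t) {
    pred <<- c(pred, p); succ <<- c(succ, s)
    tag <<- c(tag, rep(t, length(p)))
  }
  # probe chain m1 -> m2 -> m3 -> m4 and diamond m5 -> {m6,m7} -> m8
  m <- mid_cids[1:8]
  add(m[1:3], m[2:4], "chain")
  add(c(m[5], m[5], m[6], m[7]), c(m[6], m[7], m[8], m[8]), "diamond")

  # random edges among mid compounds, distinct pairs, no self-loops, and
  # no accidental shortcut into the probe chain/diamond pairs
  used <- paste0(pred, ">", succ)
  reserved <- c(paste0(m[1], ">", c(m[3], m[4])), paste0(m[2], ">", m[4]),
                paste0(m[5], ">", m[8]))
  n_random <- max(0L, spec$n_reactions - length(pred))
  tries <- 0L
  while (n_random > 0L && tries < 50L * spec$n_reactions) {
    tries <- tries + 1L
    p <- sample(mid_cids, 1L); s <- sample(mid_cids, 1L)
    if (p == s) next
    if (spec$dag_only && p > s) { tmp <- p; p <- s; s <- tmp }
    k <- paste0(p, ">", s)
    if (k %in% used || k %in% reserved) next
    add(p, s, "random"); used <- c(used, k)
    n_random <- n_random - 1L
  }

  # hubs: top up distinct out-/in-degree of chosen mid compounds
  hubs <- list()
  if (length(spec$hub_spec)) {
    hub_cids <- mid_cids[seq(9L, length.out = length(spec$hub_spec))]
    for (i in seq_along(spec$hub_spec)) {
      h <- spec$hub_spec[[i]]; hc <- hub_cids[i]
      if (!is.null(h$out)) {
        have <- unique(succ[pred == hc])
        cand <- setdiff(mid_cids, c(hc, have))
        cand <- cand[sample.int(length(cand))]
        need <- utils::head(cand, max(0L, h$out - length(have)))
        if (length(need)) {
          add(rep(hc, length(need)), need, "hub")
          used <- c(used, paste0(hc, ">", need))
        }
      }
      if (!is.null(h$in_)) {
        have <- unique(pred[succ == hc])
        cand <- setdiff(mid_cids, c(hc, have))
        cand <- cand[sample.int(length(cand))]
        need <- utils::head(cand, max(0L, h$in_ - length(have)))
        if (length(need)) {
          add(need, rep(hc, length(need)), "hub")
          used <- c(used, paste0(need, ">", hc))
        }
      }
      hubs[[i]] <- list(cid = hc, out = h$out, in_ = h$in_)
    }
  }

  # anchors keep the filter-target compounds connected through safe edges
  if (length(small_cids)) add(small_cids, sample(mid_cids, length(small_cids), replace = TRUE), "anchor")
  if (length(large_cids)) add(sample(mid_cids, length(large_cids), replace = TRUE), large_cids, "anchor")

  # injected filter targets: small predecessor -> large successor
  hidden_ids <- integer(0)
  if (nsl > 0L) {
    hidden_ids <- length(pred) + seq_len(nsl)
    add(small_cids[seq_len(nsl)], large_cids[seq_len(nsl)], "hidden")
  }

  ds_names <- sprintf("DS%02d", seq_len(spec$n_datasets))
  ds <- sample(ds_names, length(pred), replace = TRUE)

  # cross-dataset duplicates of existing pairs (retained as parallel edges)
  n_dup <- if (spec$n_datasets > 1L)
    round(spec$duplicate_pair_rate * length(pred)) else 0L
  if (n_dup > 0L) {
    dup_rows <- sample(setdiff(seq_along(pred), hidden_ids), n_dup)
    for (r in dup_rows) {
      add(pred[r], succ[r], "duplicate")
      ds <- c(ds, sample(setdiff(ds_names, ds[r]), 1L))
    }
  }

  ne <- length(pred)
  mass <- compounds$exact_mass[match(succ, cid)] -
          compounds$exact_mass[match(pred, cid)]
  xld <- compounds$xlogp[match(succ, cid)] -
         compounds$xlogp[match(pred, cid)]
  reactions <- data.frame(
    predecessor_cid = pred,
    successor_cid = succ,
    predecessor_name = row_name(pred, seq_len(ne)),
    successor_name = row_name(succ, seq_len(ne) + 1L),
    reaction_smiles = paste0(compounds$smiles[match(pred, cid)], ">>",
                             compounds$smiles[match(succ, cid)]),
    desc_reaction_smiles = NA_character_,
    biosystem = sample(c("human", "soil", "water", "rat"), ne, replace = TRUE),
    enzyme = NA_character_,
    transformation = ifelse(round(mass, 3) == 15.995, "oxygen addition",
                            "transformation"),
    mass_diff = round(mass, 6),
    xlogp_diff = round(xld, 2),
    datasetref = ds,
    datasetdoi = paste0("10.5072/synthetic.", match(ds, ds_names)),
    evidenceref = paste0("ref-", seq_len(ne)),
    evidencedoi = NA_character_,
    sourcecommentfull = tag,
    sourcecomment = NA_character_,
    stringsAsFactors = FALSE
  )

  # --- ledger: ground truth by plain tallies --------------------------
  din <- table(factor(succ, levels = cid))
  dout <- table(factor(pred, levels = cid))
  role <- ifelse(din == 0 & dout == 0, "isolated",
          ifelse(din == 0, "predecessor_only",
          ifelse(dout == 0, "successor_only", "both")))
  pairkey <- paste0(pred, ">", succ)
  pair_ds <- unique(data.frame(k = pairkey, d = ds, stringsAsFactors = FALSE))
  nds <- table(pair_ds$k)
  uniq_keys <- names(nds)[nds == 1L]
  dataset_unique <- do.call(rbind, lapply(ds_names, function(r) {
    rows <- ds == r
    data.frame(datasetref = r, total_entries = sum(rows),
               unique_pairs = length(intersect(unique(pairkey[rows]), uniq_keys)),
               stringsAsFactors = FALSE)
  }))
  probes <- data.frame(
    source = c(m[1], m[5]), target = c(m[4], m[8]),
    stringsAsFactors = FALSE)
  probes$length <- vapply(seq_len(nrow(probes)), function(i)
    .bfs_steps(pred, succ, probes$source[i], probes$target[i]), integer(1))

  ledger <- list(
    roles = data.frame(cid = cid, role = as.character(role),
                       stringsAsFactors = FALSE),
    dataset_unique = dataset_unique,
    probes = probes,
    hidden_edge_ids = hidden_ids,
    structure_flags = data.frame(cid = cid, aromatic = pool$aromatic[pick],
                                 cf3 = pool$cf3[pick],
                                 stringsAsFactors = FALSE),
    hubs = hubs,
    n_compounds = n, n_reactions = ne
  )
  list(compounds = compounds, reactions = reactions, ledger = ledger)
}
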