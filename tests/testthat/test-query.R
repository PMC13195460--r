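test_that("display filter hides exactly small->large edges, strictly", {
  comp <- make_compounds(1:6, masses = c(43.99, 60.0, 69.03, 301, 364, NA))
  reac <- make_reactions(c(1, 2, 3, 1, 6), c(4, 4, 5, 2, 4))
  g <- build_graph(comp, reac)
  h <- hidden_edges(g)
  # 1->4 (43.99 -> 301) and 3->5 (69.03 < 60? no...) check each:
  #   1->4 hidden (43.99 < 60, 301 > 300)
  #   2->4 not hidden (mass exactly 60 is not < 60)
  #   3->5 not hidden (triazole-like 69 Da predecessor is retained)
  #   1->2 not hidden (successor below 300)
  #   6->4 not hidden (predecessor mass missing)
  expect_equal(h$edge_id, 1L)
  expect_equal(h$predecessor_cid, 1L)

  # boundary: successor exactly at the threshold is kept
  comp2 <- make_compounds(1:2, masses = c(59.9, 300))
  expect_equal(nrow(hidden_edges(build_graph(comp2, make_reactions(1, 2)))), 0L)
  comp3 <- make_compounds(1:2, masses = c(59.9, 300.1))
  expect_equal(nrow(hidden_edges(build_graph(comp3, make_reactions(1, 2)))), 1L)

  # hidden list is invariant to input row order
  fx <- generate_fixture(fixture_spec(seed = 13, n_compounds = 20,
                                      n_reactions = 25,
                                      small_large_pairs = 3L))
  g1 <- build_graph(fx$compounds, fx$reactions)
  perm <- sample(nrow(fx$reactions))
  g2 <- build_graph(fx$compounds, fx$reactions[perm, ])
  pair1 <- with(hidden_edges(g1), paste(predecessor_cid, successor_cid))
  pair2 <- with(hidden_edges(g2), paste(predecessor_cid, successor_cid))
  expect_setequal(pair1, pair2)
  expect_equal(sort(match(hidden_edges(g2)$edge_id, seq_along(perm))),
               sort(which(perm %in% fx$ledger$hidden_edge_ids)))

  expect_error(edge_filter(300, 60), "small_mass_max < large_mass_min")
})

test_that("all equally short directed pathways are enumerated", {
  comp <- make_compounds(1:4)
  # diamond: 1->2->4 and 1->3->4, plus a parallel edge on 1->2
  reac <- make_reactions(c(1, 1, 1, 2, 3), c(2, 2, 3, 4, 4))
  g <- build_graph(comp, reac)
  p <- shortest_pathways(g, 1, 4)
  expect_equal(p$length, 2L)
  expect_equal(vapply(p$paths, function(x) paste(x$cids, collapse = ","),
                      character(1)),
               c("1,2,4", "1,3,4"))
  # the 1->2 hop carries both parallel edge ids as alternative evidence
  expect_equal(p$paths[[1]]$edge_ids[[1]], c(1L, 2L))

  same <- shortest_pathways(g, 3, 3)
  expect_equal(same$length, 0L)
  expect_equal(same$paths[[1]]$cids, 3)

  backwards <- shortest_pathways(g, 4, 1)  # direction is respected
  expect_true(is.na(backwards$length))
  expect_equal(length(backwards$paths), 0L)

  expect_error(shortest_pathways(g, 1, 999), "unknown target CID: 999")
})

test_that("path enumeration equals the brute-force oracle on random graphs", {
  set.seed(1234)
  for (trial in 1:60) {
    n <- sample(3:12, 1)
    rg <- random_multigraph(n, sample(n:(3 * n), 1))
    g <- build_graph(rg$compounds, rg$reactions)
    ends <- sample(rg$compounds$cid, 2)
    want <- oracle_min_paths(rg$reactions$predecessor_cid,
                             rg$reactions$successor_cid, ends[1], ends[2])
    got <- shortest_pathways(g, ends[1], ends[2],
                             filter = edge_filter(enabled = FALSE))
    got_str <- sort(vapply(got$paths, function(x)
      paste(x$cids, collapse = ","), character(1)))
    expect_identical(got_str, want)
  }
})

test_that("the filter never shortens a pathway and can sever hub bridges", {
  fx <- generate_fixture(fixture_spec(seed = 17, n_compounds = 24,
                                      n_reactions = 40,
                                      small_large_pairs = 2L))
  g <- build_graph(fx$compounds, fx$reactions)
  cids <- fx$compounds$cid
  set.seed(5)
  for (i in 1:25) {
    ends <- sample(cids, 2)
    free <- shortest_pathways(g, ends[1], ends[2],
                              filter = edge_filter(enabled = FALSE))
    filt <- shortest_pathways(g, ends[1], ends[2])
    if (!is.na(filt$length)) {
      expect_false(is.na(free$length))
      expect_gte(filt$length, free$length)
    }
  }

  # a hidden small->large edge must not be traversable
  he <- hidden_edges(g)
  p <- shortest_pathways(g, he$predecessor_cid[1], he$successor_cid[1])
  expect_true(is.na(p$length) || p$length > 1L)
})

test_that("neighborhood views follow their traversal contracts", {
  comp <- make_compounds(1:5)
  reac <- make_reactions(c(1, 2, 3), c(2, 3, 4))  # chain 1->2->3->4; 5 isolated
  g <- build_graph(comp, reac)

  pp <- neighborhood(g, 3, "predecessor_path", depth_limit = 10)
  expect_setequal(pp$compounds$cid, c(1, 2, 3))
  d <- neighborhood(g, 3, "direct")
  expect_setequal(d$compounds$cid, c(2, 3, 4))
  expect_equal(sort(d$reactions$edge_id), c(2L, 3L))
  sp <- neighborhood(g, 3, "successor_path", depth_limit = 1)
  expect_setequal(sp$compounds$cid, c(3, 4))
  ac <- neighborhood(g, 3, "all_connections")
  expect_setequal(ac$compounds$cid, 1:4)

  # direct nodes are a subset of the component, for every focus
  for (f in 1:5) {
    expect_true(all(neighborhood(g, f, "direct")$compounds$cid %in%
                    neighborhood(g, f, "all_connections")$compounds$cid))
  }
  expect_error(neighborhood(g, 999, "direct"), "unknown focus CID")
})

test_that("a hidden bridge keeps unrelated islands apart in all_connections", {
  # island A: 1->2; island B: 3->4; bridged only by a small->large edge 5->3
  comp <- make_compounds(1:5, masses = c(100, 150, 350, 380, 44))
  reac <- make_reactions(c(1, 3, 5, 1), c(2, 4, 3, 5))
  g <- build_graph(comp, reac)
  vis <- neighborhood(g, 1, "all_connections")
  expect_setequal(vis$compounds$cid, c(1, 2, 5))
  unfiltered <- neighborhood(g, 1, "all_connections",
                             filter = edge_filter(enabled = FALSE))
  expect_setequal(unfiltered$compounds$cid, 1:5)
})

test_that("lookup matches identifiers and names, reports misses, filters by biosystem", {
  fx <- generate_fixture(fixture_spec(seed = 2, n_compounds = 16,
                                      n_reactions = 22))
  comp <- normalize_compounds(fx$compounds, fx$reactions)
  g <- build_graph(comp, fx$reactions)

  target <- comp[3, ]
  hit <- lookup(g, target$title)
  expect_true(target$cid %in% hit$cid)
  expect_true(all(lookup(g, toupper(target$title))$cid == hit$cid[1]))

  expect_equal(lookup(g, as.character(target$cid))$cid[1], target$cid)
  expect_equal(lookup(g, target$inchikey)$cid[1], target$cid)
  expect_equal(lookup(g, target$ikfb)$cid[1], target$cid)

  f <- tempfile()
  writeLines(c(target$title, comp$title[5], "no-such-compound"), f)
  batch <- lookup(g, f, batch_file = TRUE)
  expect_equal(sum(batch$matched_by == "miss"), 1L)
  expect_true(all(c(target$cid, comp$cid[5]) %in% batch$cid))

  # biosystem restriction equals a linear scan over incident edges
  bs <- "human"
  want <- unique(c(
    fx$reactions$predecessor_cid[fx$reactions$biosystem == bs],
    fx$reactions$successor_cid[fx$reactions$biosystem == bs]))
  for (cid in comp$cid) {
    res <- lookup(g, as.character(cid), biosystem = bs)
    expect_equal(res$matched_by[1] != "miss", cid %in% want, info = cid)
  }
})
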