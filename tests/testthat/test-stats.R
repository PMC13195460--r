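test_that("per-dataset uniqueness counts distinct cross-dataset-unique pairs", {
  # single dataset: everything unique
  r1 <- make_reactions(c(1, 2, 3), c(2, 3, 4), datasetref = "A")
  s1 <- dataset_summaries(r1)
  expect_equal(s1$unique_pct, 100)

  # two datasets sharing exactly one pair lose one unique pair each
  r2 <- rbind(
    make_reactions(c(1, 2), c(2, 3), datasetref = "A"),
    make_reactions(c(1, 5), c(2, 6), datasetref = "B"))
  s2 <- dataset_summaries(r2)
  expect_equal(s2$unique_pairs[s2$datasetref == "A"], 1L)
  expect_equal(s2$unique_pairs[s2$datasetref == "B"], 1L)
  expect_equal(s2$total_entries, c(2L, 2L))

  # duplicated rows within one dataset count toward total, not uniqueness
  r3 <- rbind(make_reactions(c(1, 1), c(2, 2), datasetref = "A"),
              make_reactions(3, 4, datasetref = "B"))
  s3 <- dataset_summaries(r3)
  expect_equal(s3$total_entries[s3$datasetref == "A"], 2L)
  expect_equal(s3$unique_pairs[s3$datasetref == "A"], 1L)
  expect_equal(s3$unique_pct[s3$datasetref == "A"], 50.0)
})

test_that("uniqueness equals the brute-force intersection oracle, and totals sum", {
  set.seed(31)
  for (i in 1:20) {
    rg <- random_multigraph(sample(3:10, 1), sample(5:40, 1),
                            n_datasets = sample(2:4, 1))
    s <- dataset_summaries(rg$reactions)
    want <- oracle_dataset_unique(rg$reactions)
    expect_equal(stats::setNames(s$unique_pairs, s$datasetref),
                 want[s$datasetref])
    expect_equal(sum(s$total_entries), nrow(rg$reactions))
    expect_true(all(s$unique_pairs <= s$total_entries))
  }
})

test_that("top compounds rank by distinct partners with CID tie-breaks", {
  # star: hub 1 -> leaves 2..6, with parallel repeats that must not inflate
  reac <- make_reactions(c(1, 1, 1, 1, 1, 1, 2), c(2, 3, 4, 5, 6, 2, 3))
  g <- build_graph(make_compounds(1:6), reac)
  top <- top_compounds(g, "successors", 3)
  expect_equal(top$cid[1], 1L)
  expect_equal(top$count[1], 5L)

  # tie between 1 and 2 (one distinct TP each) resolves by ascending CID
  g2 <- build_graph(make_compounds(1:4), make_reactions(c(1, 2), c(3, 4)))
  t2 <- top_compounds(g2, "successors", 2)
  expect_equal(t2$cid, c(1L, 2L))

  # hub request in the generator yields the requested distinct in-degree
  fx <- generate_fixture(fixture_spec(seed = 77, n_compounds = 30,
                                      n_reactions = 10,
                                      hub_spec = list(list(out = 12),
                                                      list(in_ = 11))))
  g3 <- build_graph(fx$compounds, fx$reactions)
  expect_gte(top_compounds(g3, "successors", 1)$count, 12L)
  expect_gte(top_compounds(g3, "predecessors", 1)$count, 11L)
})

test_that("mass-difference bins group by rounded value with labels", {
  r <- make_reactions(1:4, 5:8, mass_diff = c(16.0, 16.0, 14.0, NA),
                      transformation = c("ox", "ox", "demeth", NA))
  d <- mass_xlogp_distribution(r)
  expect_equal(d$bins$mass_diff[1], 16.0)
  expect_equal(d$bins$count[1], 2L)
  expect_equal(d$bins$example_label[1], "ox")
  expect_equal(d$n_missing_mass_diff, 1L)

  # values agreeing to the binning precision share one bin
  r2 <- make_reactions(1:2, 3:4, mass_diff = c(15.9949, 15.9951))
  d2 <- mass_xlogp_distribution(r2, bin_precision = 3)
  expect_equal(nrow(d2$bins), 1L)
  expect_equal(d2$bins$count, 2L)
  expect_equal(d2$bins$mass_diff, 15.995)

  # xlogp pairs only where both differences are present
  r3 <- make_reactions(1:3, 4:6, mass_diff = c(1, 2, NA))
  r3$xlogp_diff <- c(0.5, NA, 1)
  expect_equal(nrow(mass_xlogp_distribution(r3)$pairs), 1L)
})

test_that("multistep counts match definitions and the BFS oracle", {
  # chain a->b->c: only c is >= 2 steps from the original predecessor a
  g <- build_graph(make_compounds(1:3), make_reactions(c(1, 2), c(2, 3)))
  ms <- multistep_stats(g)
  expect_equal(ms$n_multistep, 1L)
  expect_equal(ms$multistep_cids, 3L)
  expect_equal(ms$n_original_predecessors, 1L)

  # edges from two datasets along the pathway
  r2 <- rbind(make_reactions(1, 2, datasetref = "ds1"),
              make_reactions(2, 3, datasetref = "ds2"))
  ms2 <- multistep_stats(build_graph(make_compounds(1:3), r2))
  expect_equal(ms2$pct_multi_dataset, 100)
  ms1 <- multistep_stats(g)  # single dataset
  expect_equal(ms1$pct_multi_dataset, 0)

  # random DAGs against the brute-force multi-source relaxation oracle
  set.seed(55)
  for (i in 1:15) {
    n <- sample(4:12, 1)
    cids <- 100L + seq_len(n)
    ne <- sample(3:20, 1)
    pred <- sample(cids, ne, replace = TRUE)
    succ <- sample(cids, ne, replace = TRUE)
    keep <- pred < succ  # ascending CIDs: acyclic, sources guaranteed
    pred <- pred[keep]; succ <- succ[keep]
    if (!length(pred)) next
    g3 <- build_graph(make_compounds(cids), make_reactions(pred, succ))
    dist <- oracle_min_source_distance(cids, pred, succ)
    want <- sort(as.integer(names(dist)[is.finite(dist) & dist >= 2]))
    got <- multistep_stats(g3, edge_filter(enabled = FALSE))
    expect_equal(got$multistep_cids, want)
  }
})

test_that("the assembled report is internally consistent and deterministic", {
  fx <- generate_fixture(fixture_spec(seed = 41, n_compounds = 30,
                                      n_reactions = 45))
  g <- build_graph(normalize_compounds(fx$compounds, fx$reactions),
                   fx$reactions)
  st <- tp_summary(g)
  expect_equal(st$n_compounds, nrow(fx$compounds))
  expect_equal(st$n_reactions, nrow(fx$reactions))
  expect_identical(st$roles, attr(classify_roles(g), "counts"))
  expect_equal(sum(st$roles), st$n_compounds)
  expect_equal(nrow(st$hidden_edges), length(fx$ledger$hidden_edge_ids))
  expect_equal(sum(st$datasets$total_entries), st$n_reactions)

  st2 <- tp_summary(g)
  expect_identical(st, st2)

  # row-order permutation leaves the multistep count unchanged
  perm <- sample(nrow(fx$reactions))
  g_perm <- build_graph(g$compounds, fx$reactions[perm, ])
  expect_equal(multistep_stats(g_perm)$n_multistep,
               multistep_stats(g)$n_multistep)

  # degenerate graph: all zeros
  st0 <- tp_summary(build_graph(make_compounds(integer(0)),
                                make_reactions(integer(0), integer(0))))
  expect_equal(st0$n_compounds, 0L)
  expect_equal(st0$n_reactions, 0L)
  expect_equal(sum(st0$roles), 0L)
})
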