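test_that("tree simulation honours shape, depth and determinism", {
  bal <- simulate_tree(4, "balanced", depth = 0.01, seed = 1)
  expect_equal(sort(bal$tip.label), sprintf("G%02d", 1:4))
  expect_true(ape::is.monophyletic(bal, c("G01", "G02")))
  depths <- ape::node.depth.edgelength(bal)[1:4]
  expect_equal(depths, rep(0.01, 4)) # ultrametric with equal pendant depth
  flat <- simulate_tree(5, "yule", depth = 0, seed = 2)
  expect_true(all(flat$edge.length == 0))
  t1 <- simulate_tree(9, "yule", depth = 0.005, seed = 7)
  t2 <- simulate_tree(9, "yule", depth = 0.005, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(t1),
                         ape::write.tree(simulate_tree(9, "yule", depth = 0.005,
                                                       seed = 8))))
})

test_that("zero recombination reproduces the clonal simulator bit for bit", {
  tr <- simulate_tree(6, "yule", depth = 0.01, seed = 3)
  params <- simulation_params(0.5, 3000, 2, c(1, 0.5, 2.5), tr)
  clonal <- simulate_clonal(params, seed = 11)
  pop <- simulate_population(tr, params, recombination_rate = 0, seed = 11)
  expect_identical(pop$alignment$seq, clonal$seq)
  expect_equal(nrow(pop$truth$events), 0L)
})

test_that("populations are reproducible and their event logs complete", {
  a <- simulate_species(n_genomes = 8, length = 9999,
                        recombination_rate = 0.3, seed = 19)
  b <- simulate_species(n_genomes = 8, length = 9999,
                        recombination_rate = 0.3, seed = 19)
  expect_identical(a$alignment$seq, b$alignment$seq)   # replay from the seed
  expect_identical(a$truth$events, b$truth$events)
  ev <- a$truth$events
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$start >= 0 & ev$end <= a$alignment$length))
  expect_true(all(ev$end > ev$start))
  # recombination elevates homoplasy above the clonal level
  hm_rec <- coreflow:::.hm_pipeline(a$alignment, resamples = 8)$ratio
  clo <- simulate_species(n_genomes = 8, length = 9999,
                          recombination_rate = 0, seed = 19)
  hm_clo <- coreflow:::.hm_pipeline(clo$alignment, resamples = 8)$ratio
  expect_gt(hm_rec, 3 * hm_clo)
})

test_that("candidates reach their divergence and log exchange tracts", {
  pop <- cached_pop("cand", n_genomes = 8, length = 30000,
                    recombination_rate = 0.3, seed = 29)
  mc <- make_candidate(pop$alignment, divergence = 0.10, seed = 5)
  expect_equal(mc$truth$divergence_realized, 0.10, tolerance = 0.05)
  expect_equal(nchar(mc$sequence), pop$alignment$length)
  expect_equal(nrow(mc$truth$events), 0L)
  mex <- make_candidate(pop$alignment, divergence = 0.05, exchanging = TRUE,
                        exchange_rate = 0.1, seed = 5)
  expect_gt(nrow(mex$truth$events), 0)
  expect_true(all(mex$truth$events$donor %in% pop$alignment$ids))
  # exchange pulls the candidate toward the population relative to a clonal
  # candidate at the same model time
  p_clo <- mean(coreflow:::.encode_nt(strsplit(mc$sequence, "")[[1]]) !=
                  pop$alignment$seq[1, ])
  p_exc <- mean(coreflow:::.encode_nt(strsplit(mex$sequence, "")[[1]]) !=
                  pop$alignment$seq[1, ])
  expect_lt(p_exc, p_clo)
})

test_that("introgression injection writes the exact mask", {
  pop <- cached_pop("cand", n_genomes = 8, length = 30000,
                    recombination_rate = 0.3, seed = 29)
  mc <- make_candidate(pop$alignment, divergence = 0.10, seed = 6)
  sh <- shared_core_alignment(pop$alignment, mc$sequence, "CAND")
  inj <- inject_introgression(sh, fraction = 5, tract = 100, seed = 2)
  nw <- sh$length %/% 100
  expect_equal(nrow(inj$mask), round(0.05 * nw))
  expect_false(any(duplicated(inj$mask$window)))
  for (k in seq_len(nrow(inj$mask))) {
    idx <- (inj$mask$start[k] + 1):inj$mask$end[k]
    expect_equal(inj$alignment$seq[inj$mask$genome[k], idx],
                 inj$alignment$seq["CAND", idx])
  }
  # untouched genomes unchanged
  untouched <- setdiff(sh$ids, c("CAND", inj$mask$genome))
  expect_identical(inj$alignment$seq[untouched, ], sh$seq[untouched, ])
  expect_error(inject_introgression(sh, fraction = 0), "fraction")
})
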