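test_that("parameter estimation recovers kappa, codon rates and GC", {
  tr <- quartet_tree()
  # 10 transition-type biallelic sites + 5 transversion-type sites: the site
  # count ratio is kappa/2 under K2P, so the rate-ratio estimate is 2 * 10/5
  ts_col <- c("A", "A", "G", "G")  # A<->G transition pair
  tv_col <- c("A", "A", "C", "C")  # A<->C transversion pair
  inv <- c("A", "A", "A", "A")
  cols <- c(rep(list(ts_col), 10), rep(list(tv_col), 5), rep(list(inv), 30))
  mat <- do.call(cbind, lapply(cols, coreflow:::.encode_nt))
  rownames(mat) <- c("A", "B", "C", "D")
  aln <- core_alignment(mat, data.frame(gene_id = "g1", start = 0, end = 45))
  p <- estimate_params(aln, tr)
  expect_equal(p$kappa, 2 * 10 / 5)
  # codon-position polymorphism counts drive the relative rates
  expect_equal(p$codon_rates / sum(p$codon_rates),
               tabulate(rep_len(1:3, 45)[1:15], 3) / 15)
  # GC content of a known composition
  aln_gc <- aln_from(c(a = strrep("GCATT", 2), b = strrep("GCATT", 2)))
  expect_equal(suppressWarnings(estimate_params(aln_gc, tr))$gc_content, 0.4)
  # all-transition alignments cap kappa with a warning
  mat_ts <- do.call(cbind, c(rep(list(coreflow:::.encode_nt(ts_col)), 3),
                             rep(list(coreflow:::.encode_nt(inv)), 3)))
  rownames(mat_ts) <- c("A", "B", "C", "D")
  aln_ts <- core_alignment(mat_ts, data.frame(gene_id = "g1", start = 0, end = 6))
  expect_warning(pts <- estimate_params(aln_ts, tr), "capped")
  expect_equal(pts$kappa, 100)
})

test_that("clonal simulation honours rescale 0, K2P expectations and kappa bias", {
  tr <- ape::read.tree(text = "(X:0.05,Y:0.05);")
  params <- simulation_params(0.5, 30000, 2, c(1, 1, 1), tr)
  aln0 <- simulate_clonal(params, rescale = 0, seed = 1)
  expect_equal(unname(aln0$seq["X", ]), unname(aln0$seq["Y", ]))
  expect_equal(nucleotide_diversity(aln0), 0)
  # expected pairwise difference at path length t = 0.1 under K2P
  pr <- coreflow:::.k2p_probs(0.1, 2)
  exp_diff <- 1 - pr[["same"]]
  diffs <- vapply(1:30, function(s) {
    a <- simulate_clonal(params, seed = s)
    mean(a$seq["X", ] != a$seq["Y", ])
  }, 0.0)
  expect_lt(abs(mean(diffs) - exp_diff), 3 * sd(diffs) / sqrt(30))
  # kappa = 4: transitions should be 4/6 of all changes
  params4 <- simulation_params(0.5, 60000, 4, c(1, 1, 1), tr)
  a4 <- simulate_clonal(params4, seed = 2)
  ch <- a4$seq["X", ] != a4$seq["Y", ]
  is_ts <- coreflow:::.TS_PARTNER[a4$seq["X", ch]] == a4$seq["Y", ch]
  # a double hit along the two branches perturbs the ratio only slightly
  expect_lt(abs(mean(is_ts) - 4 / 6), 3.5 * sqrt(4 / 6 * 2 / 6 / sum(ch)) + 0.01)
})

test_that("kappa 1 with equal rates reduces to Jukes-Cantor", {
  tr <- ape::read.tree(text = "(X:0.1,Y:0.1);")
  params <- simulation_params(0.5, 60000, 1, c(1, 1, 1), tr)
  idents <- vapply(1:20, function(s) {
    a <- simulate_clonal(params, seed = s)
    mean(a$seq["X", ] == a$seq["Y", ])
  }, 0.0)
  jc <- 1 / 4 + 3 / 4 * exp(-4 * 0.2 / 3)
  expect_lt(abs(mean(idents) - jc), 3 * sd(idents) / sqrt(20))
})

test_that("rescale sweep matches diversity and flags grid boundaries", {
  pop <- cached_pop("sweep", n_genomes = 8, length = 9999,
                    recombination_rate = 0, seed = 13)
  aln <- pop$alignment
  tr <- build_guide_tree(corrected_distance_matrix(aln, "K2P"))
  params <- estimate_params(aln, tr)
  target <- nucleotide_diversity(aln)
  sw <- rescale_sweep(params, target, n_replicates = 33, seed = 11)
  expect_true(abs(log(sw$factor)) < log(1.6)) # near 1 for a self-match
  expect_equal(nrow(sw$log), 33L)
  expect_true(all(abs(sw$log$pi - target) >= min(abs(sw$log$pi - target))))
  expect_equal(abs(coreflow:::.pi_sim(sw$alignment) - target),
               min(abs(sw$log$pi - target)))
  expect_warning(rescale_sweep(params, 0, n_replicates = 9, seed = 1),
                 "grid edge")
})

test_that("the k-SD rule separates clonal from elevated ratios", {
  fake <- structure(list(ratio = 0.5, sd = 0.1,
                         resample_ratios = rep(0.5, 10)),
                    class = "hm_tally")
  expect_true(clonality_test(fake, null_ratio = 0.5)$clonal)
  expect_true(clonality_test(fake, null_ratio = 0.5 - 0.29)$clonal) # within 3 SD
  fake$ratio <- 0.5 + 3.01 * 0.1
  expect_false(clonality_test(fake, null_ratio = 0.5)$clonal)
  fake$sd <- 0
  expect_warning(v <- clonality_test(fake, null_ratio = 0.5), "degenerate")
  expect_false(v$clonal)
})

test_that("the convergent-mutation null hits the target divergence exactly", {
  cons <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE), collapse = "")
  expect_identical(convergent_mutation_null(cons, 0, seed = 1), cons)
  mut <- convergent_mutation_null(cons, 0.05, seed = 1)
  d <- mapply(function(a, b) a != b, strsplit(cons, "")[[1]], strsplit(mut, "")[[1]])
  expect_equal(sum(d), 500L)
  # N positions are preserved and excluded from the denominator
  consN <- paste0(strrep("N", 100), substr(cons, 101, 10000))
  mutN <- convergent_mutation_null(consN, 0.1, seed = 2)
  expect_equal(substr(mutN, 1, 100), strrep("N", 100))
  expect_equal(sum(strsplit(consN, "")[[1]] != strsplit(mutN, "")[[1]]),
               ceiling(0.1 * 9900))
  expect_error(convergent_mutation_null(cons, 0.8), "0.75")
})

test_that("introduced mutations are uniform over the three alternatives", {
  cons <- strrep("A", 2000)
  tab <- table(unlist(lapply(1:40, function(s) {
    m <- convergent_mutation_null(cons, 0.25, seed = s)
    strsplit(m, "")[[1]][strsplit(m, "")[[1]] != "A"]
  })))
  expect_gt(chisq.test(tab)$p.value, 1e-4)
})
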