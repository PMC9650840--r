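test_that("neighbor joining recovers an additive quartet exactly", {
  # known tree ((A:2,B:3):1,(C:4,D:5)); build its additive distance matrix
  ids <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(ids, ids))
  D["A", "B"] <- D["B", "A"] <- 5
  D["A", "C"] <- D["C", "A"] <- 7
  D["A", "D"] <- D["D", "A"] <- 8
  D["B", "C"] <- D["C", "B"] <- 8
  D["B", "D"] <- D["D", "B"] <- 9
  D["C", "D"] <- D["D", "C"] <- 9
  tr <- build_guide_tree(D)
  expect_true(ape::is.monophyletic(ape::root(tr, "D"), c("A", "B")))
  # total tree length of the additive tree is preserved
  expect_equal(sum(tr$edge.length), 15)
  expect_error(build_guide_tree(D[1:2, 1:2]), "at least 3")
  # equal off-diagonal distances give zero internal branches
  De <- matrix(6, 4, 4, dimnames = list(ids, ids)); diag(De) <- 0
  tre <- build_guide_tree(De)
  internal <- tre$edge[, 2] > length(tre$tip.label)
  expect_true(all(tre$edge.length[internal] == 0))
})

test_that("allele origins follow the carrier-set parsimony score", {
  tr <- quartet_tree()
  conc <- allele_origins(tr, c(A = "T", B = "T", C = "G", D = "G"))
  expect_equal(conc$origins, c(1L, 1L))
  expect_false(any(conc$homoplasic))
  disc <- allele_origins(tr, c(A = "T", B = "G", C = "T", D = "G"))
  expect_equal(disc$origins, c(2L, 2L))
  expect_true(all(disc$homoplasic))
  single <- allele_origins(tr, c(A = "T", B = "G", C = "G", D = "G"))
  expect_equal(single$origins[single$allele == "T"], 1L)
  # missing leaves are free: T carried by A with B missing stays single-origin
  miss <- allele_origins(tr, c(A = "T", B = "N", C = "T", D = "G"))
  expect_equal(miss$origins[miss$allele == "T"], 1L)
  expect_error(allele_origins(tr, c(A = "T", B = "T", C = "T", D = "T")),
               "at least 2 alleles")
})

test_that("origins equal the exhaustive enumeration oracle on random cases", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    states <- setNames(sample(0:4, n, replace = TRUE, prob = c(.1, rep(.225, 4))),
                       tr$tip.label)
    pres <- unique(states[states > 0])
    if (length(pres) < 2) next
    got <- allele_origins(tr, states)
    for (a in pres) {
      expect_equal(got$origins[got$allele == coreflow:::.NT[a]],
                   origins_oracle(tr, states, a),
                   info = sprintf("case %d allele %d", i, a))
    }
  }
})

test_that("h/m tally separates single-origin and convergent alleles", {
  tr <- quartet_tree()
  # 12 columns: 10 clade-compatible derived alleles (2 carriers), 1 discordant,
  # 1 invariant
  base <- c(A = "A", B = "A", C = "A", D = "A")
  cols <- c(rep(list(c(A = "T", B = "T", C = "A", D = "A")), 5),
            rep(list(c(A = "A", B = "A", C = "G", D = "G")), 5),
            list(c(A = "T", B = "A", C = "T", D = "A")),
            list(base))
  mat <- do.call(cbind, lapply(cols, function(x) coreflow:::.encode_nt(x[c("A", "B", "C", "D")])))
  rownames(mat) <- c("A", "B", "C", "D")
  aln <- core_alignment(mat, data.frame(gene_id = "g1", start = 0, end = 12))
  tl <- tally_hm(aln, tr, resamples = 10, seed = 1)
  expect_equal(tl$h, 1L)
  expect_equal(tl$m, 10L)
  expect_equal(tl$ratio, 0.1)
  # singleton policy: the carrier>=2 variant drops singletons from m
  aln2 <- core_alignment(cbind(mat, coreflow:::.encode_nt(c("C", "A", "A", "A"))),
                         data.frame(gene_id = "g1", start = 0, end = 12))
  expect_equal(tally_hm(aln2, tr, resamples = 10, seed = 1)$m, 11L)
  expect_equal(tally_hm(aln2, tr, resamples = 10, include_singletons = FALSE,
                        seed = 1)$m, 10L)
})

test_that("leave-one-out resampling enumerates the achievable ratios", {
  pop <- cached_pop("loo", n_genomes = 5, length = 3000,
                    recombination_rate = 0.3, depth = 0.02, seed = 21)
  aln <- pop$alignment
  tr <- build_guide_tree(corrected_distance_matrix(aln, "K2P"))
  tl <- tally_hm(aln, tr, resamples = 100, seed = 3)
  expect_length(tl$loo, 5L)
  expect_true(all(tl$resample_ratios %in% tl$loo))
  # first 5 draws cover every genome once (without replacement)
  expect_setequal(tl$resample_ratios[1:5], unname(tl$loo))
  expect_equal(tl$sd, sd(tl$resample_ratios))
  # h + m invariant to genome order and to re-rooting of the guide tree
  perm <- rev(aln$ids)
  aln2 <- core_alignment(aln$seq[perm, ], aln$gene_map)
  tl2 <- tally_hm(aln2, tr, resamples = 10, seed = 3)
  expect_equal(c(tl2$h, tl2$m), c(tl$h, tl$m))
  tl3 <- tally_hm(aln, ape::root(tr, aln$ids[1], resolve.root = TRUE),
                  resamples = 10, seed = 3)
  expect_equal(c(tl3$h, tl3$m), c(tl$h, tl$m))
})

test_that("masking a genome equals pruning it from the alignment", {
  pop <- cached_pop("loo", n_genomes = 5, length = 3000,
                    recombination_rate = 0.3, depth = 0.02, seed = 21)
  aln <- pop$alignment
  tr <- build_guide_tree(corrected_distance_matrix(aln, "K2P"))
  tl <- tally_hm(aln, tr, resamples = 10, seed = 1)
  drop <- aln$ids[2]
  sub <- core_alignment(aln$seq[setdiff(aln$ids, drop), ], aln$gene_map)
  trsub <- ape::drop.tip(tr, drop)
  tlsub <- tally_hm(sub, trsub, resamples = 10, seed = 1)
  expect_equal(unname(tl$loo[drop]), tlsub$ratio)
})

test_that("a clonal outlier genome is detected and excluded", {
  pop <- simulate_species(n_genomes = 14, length = 30000,
                          recombination_rate = 0.4, depth = 0.01, seed = 5)
  aln <- pop$alignment
  # outlier: clonally diverged sequence attached from outside the population
  out <- make_candidate(aln, divergence = 0.05, exchanging = FALSE, seed = 9)
  S <- rbind(aln$seq, OUTLIER = coreflow:::.encode_nt(strsplit(out$sequence, "")[[1]]))
  aln2 <- core_alignment(S, aln$gene_map)
  res <- detect_nonrecombining_genomes(aln2, resamples = 50, seed = 2)
  expect_true("OUTLIER" %in% res$excluded)
  expect_false("OUTLIER" %in% res$retained)
  # alpha = 0 disables exclusion entirely
  res0 <- detect_nonrecombining_genomes(aln2, alpha = 0, resamples = 20, seed = 2)
  expect_length(res0$excluded, 0L)
})

test_that("synonymous and non-synonymous homoplasies are classified by codon", {
  tr <- quartet_tree()
  # gene of 2 codons: GAT/GAC at codon 1 position 3 (Asp/Asp, synonymous),
  # GAT/GCT at codon 2 position 2 (Asp/Ala, non-synonymous)
  seqs <- c(A = "GATGAT", B = "GATGAT", C = "GACGCT", D = "GACGCT")
  aln <- aln_from(seqs, data.frame(gene_id = "g1", start = 0, end = 6))
  rec <- allele_origin_table(aln, tr)
  out <- classify_syn_nonsyn(aln, rec)
  expect_equal(out$m_syn, 1L)
  expect_equal(out$m_nonsyn, 1L)
  expect_equal(out$h_syn + out$h_nonsyn, 0L)
  expect_false(out$qualifying)
  # codons with two polymorphic sites are excluded from all counts
  seqs2 <- c(A = "GATAAA", B = "GATAAA", C = "GCCAAA", D = "GCCAAA")
  aln2 <- aln_from(seqs2, data.frame(gene_id = "g1", start = 0, end = 6))
  out2 <- classify_syn_nonsyn(aln2, allele_origin_table(aln2, tr))
  expect_equal(out2$h_syn + out2$h_nonsyn + out2$m_syn + out2$m_nonsyn, 0L)
})
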