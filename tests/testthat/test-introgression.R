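test_that("applicability requires the candidate to be the outgroup", {
  ids <- c("r1", "r2", "r3", "cand")
  D <- matrix(0.10, 4, 4, dimnames = list(ids, ids)); diag(D) <- 0
  D["r1", "r2"] <- D["r2", "r1"] <- 0.01
  D["r1", "r3"] <- D["r3", "r1"] <- 0.01
  D["r2", "r3"] <- D["r3", "r2"] <- 0.01
  expect_true(applicability_check(D, "cand"))
  # one reference closer to the candidate than to a fellow reference
  D2 <- D
  D2["r1", "cand"] <- D2["cand", "r1"] <- 0.005
  expect_false(applicability_check(D2, "cand"))
  # exact tie passes ("more related" is strict)
  D3 <- D
  D3["r1", "cand"] <- D3["cand", "r1"] <- 0.01
  expect_true(applicability_check(D3, "cand"))
})

# shared toy alignment: 2 references + candidate over `nw` 100-bp windows,
# built from per-window identity targets
toy_shared <- function(cand_vs_r1, r1_vs_r2, L = 100) {
  r1 <- strrep("A", L)
  mism <- function(s, k, base = "G") { # k mismatches at the window start
    if (k > 0) paste0(strrep(base, k), substr(s, k + 1, L)) else s
  }
  r2 <- mism(r1, round(L * (1 - r1_vs_r2 / 100)))
  cand <- mism(r1, round(L * (1 - cand_vs_r1 / 100)), base = "C")
  aln <- core_alignment(c(r1 = r1, r2 = r2),
                        data.frame(gene_id = "g1", start = 0, end = 99))
  shared_core_alignment(aln, cand, "cand")
}

test_that("window calls follow the more-similar-than-within rule", {
  # candidate identical to r1 (100%), r1 vs r2 at 97% -> introgressed everywhere
  sh <- toy_shared(cand_vs_r1 = 100, r1_vs_r2 = 97)
  for (th in c(90, 95, 98, 100)) {
    calls <- scan_windows(sh, threshold = th)
    expect_true(all(calls$introgressed), info = paste("threshold", th))
  }
  # candidate at 90% to both references, references at 99% -> not introgressed
  sh2 <- toy_shared(cand_vs_r1 = 90, r1_vs_r2 = 99)
  expect_false(any(scan_windows(sh2, threshold = 90)$introgressed))
  # ties are conservative: candidate at exactly the within-reference identity
  sh3 <- toy_shared(cand_vs_r1 = 97, r1_vs_r2 = 97)
  expect_false(any(scan_windows(sh3, threshold = 90)$introgressed))
})

test_that("'at least one' reference genome suffices for a call", {
  # r1 close to candidate, r1 far from r3: window introgressed even though
  # r2 and r3 are not close to the candidate
  L <- 100
  r1 <- strrep("A", L)
  r3 <- paste0(strrep("G", 10), strrep("A", L - 10))       # r1 vs r3 = 90%
  r2 <- paste0(strrep("T", 5), strrep("A", L - 5))         # r1 vs r2 = 95%
  cand <- paste0("C", strrep("A", L - 1))                  # cand vs r1 = 99%
  aln <- core_alignment(c(r1 = r1, r2 = r2, r3 = r3),
                        data.frame(gene_id = "g1", start = 0, end = 99))
  sh <- shared_core_alignment(aln, cand, "cand")
  calls <- scan_windows(sh, threshold = 90)
  expect_true(all(calls$introgressed))
  expect_equal(calls$best_cand_identity, 99)
  expect_equal(calls$min_within_ref, 90)
})

test_that("score, threshold monotonicity and ordering invariance hold", {
  calls <- data.frame(introgressed = c(rep(TRUE, 2), rep(FALSE, 8)))
  expect_equal(introgression_score(calls), 20)
  expect_equal(introgression_score(data.frame(introgressed = rep(FALSE, 5))), 0)
  expect_error(introgression_score(data.frame(introgressed = logical())),
               "no evaluated windows")

  pop <- cached_pop("intro", n_genomes = 8, length = 20001,
                    recombination_rate = 0.3, seed = 23)
  mc <- make_candidate(pop$alignment, divergence = 0.08, seed = 3)
  sh <- shared_core_alignment(pop$alignment, mc$sequence, "CAND")
  pr <- introgression_profile(sh)
  expect_true(all(diff(unname(pr$s_i)) <= 0)) # non-increasing in threshold
  # reference order does not change the calls
  perm <- c(rev(pop$alignment$ids), "CAND")
  sh2 <- core_alignment(sh$seq[perm, ], sh$gene_map)
  attr(sh2, "candidate_id") <- "CAND"
  pr2 <- introgression_profile(sh2)
  expect_equal(pr2$s_i, pr$s_i)
  expect_equal(pr2$windows$best_cand_identity, pr$windows$best_cand_identity)
})

test_that("sparse windows are skipped under the comparable-column floor", {
  sh <- toy_shared(cand_vs_r1 = 100, r1_vs_r2 = 97)
  S <- sh$seq
  S["r2", 1:60] <- 0L # 40 comparable columns < 50 for every r2 pair
  sh2 <- core_alignment(S, sh$gene_map)
  attr(sh2, "candidate_id") <- "cand"
  expect_error(introgression_profile(sh2), "no evaluated windows")
})
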