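test_that("construction validates lengths, ids and gene intervals", {
  seqs <- c(a = strrep("ACG", 100), b = strrep("ACG", 100), c = strrep("ACT", 100))
  gm <- data.frame(gene_id = "g1", start = 0, end = 300)
  aln <- core_alignment(seqs, gm)
  expect_s3_class(aln, "core_alignment")
  expect_equal(aln$length, 300L)
  expect_equal(length(aln$ids), 3L)

  bad <- c(seqs[1:2], c = strrep("ACT", 99))
  expect_error(core_alignment(bad, gm), "length mismatch")
  expect_error(core_alignment(seqs, data.frame(gene_id = "g1", start = 0, end = 301)),
               "exceeds alignment")
  expect_error(core_alignment(seqs, data.frame(gene_id = "g1", start = 0, end = 299)),
               "divisible by 3")
  expect_error(core_alignment(seqs[1], gm), "at least 2")
  expect_error(core_alignment(unname(seqs), gm), "unique genome ids")
})

test_that("FASTA + gene map round-trip reproduces the alignment exactly", {
  pop <- cached_pop("tiny", n_genomes = 5, length = 900, seed = 7)
  aln <- pop$alignment
  # introduce missing data to exercise gap handling
  aln$seq[1, 5:10] <- 0L
  fa <- tempfile(fileext = ".fasta"); gm <- tempfile(fileext = ".tsv")
  write_core_alignment(aln, fa, gm)
  back <- read_core_alignment(fa, gm)
  expect_identical(back$seq, aln$seq)
  expect_identical(back$gene_map, aln$gene_map)
  expect_identical(back$ids, aln$ids)
})

test_that("reader uppercases, maps U to T and ambiguity codes to missing", {
  fa <- tempfile(fileext = ".fa"); gm <- tempfile(fileext = ".tsv")
  writeLines(c(">s1", "acgu-r", ">s2", "ACGTNA"), fa)
  writeLines(c("#gene_id\tstart\tend", "g1\t0\t6"), gm)
  aln <- read_core_alignment(fa, gm)
  expect_equal(unname(aln$seq["s1", ]), c(1L, 2L, 3L, 4L, 0L, 0L))
  expect_equal(unname(aln$seq["s2", ]), c(1L, 2L, 3L, 4L, 0L, 1L))
})

test_that("consensus applies majority, alphabetical ties, and N for all-gap", {
  aln <- aln_from(c(x = "AT-AAA", y = "AC-TGC", z = "AC-ATT"),
                  data.frame(gene_id = "g1", start = 0, end = 6))
  cons <- consensus_sequence(aln)
  # col1 A; col2 C (majority); col3 all-gap -> N; col4 A; col5 tie A/G/T -> A
  expect_equal(substr(cons, 1, 4), "ACNA")
  expect_equal(substr(cons, 5, 5), "A") # three-way tie resolves alphabetically
  # consensus of identical sequences is that sequence
  aln2 <- aln_from(c(p = "ACGACG", q = "ACGACG"))
  expect_equal(consensus_sequence(aln2), "ACGACG")
})

test_that("nucleotide diversity matches hand-computed values", {
  expect_equal(nucleotide_diversity(aln_from(c(a = strrep("ACGTA", 2),
                                               b = strrep("ACGTA", 2)))), 0)
  # 10 columns, one difference
  expect_equal(nucleotide_diversity(aln_from(c(a = "ACGTACGTAC",
                                               b = "ACGTACGTAT"))), 0.1)
  # three sequences with pairwise fractions 0.1, 0.2, 0.3 -> mean 0.2
  aln <- aln_from(c(a = "AAAAAAAAAA", b = "CAAAAAAAAA", d = "CGGAAAAAAA"))
  # pairs: a-b 0.1, a-d 0.3, b-d 0.2 -> mean 0.2
  expect_equal(nucleotide_diversity(aln), 0.2)
  # pairwise deletion: missing columns excluded per pair
  alnx <- aln_from(c(a = "A-GTACGTAC", b = "ACGTACGTAT"))
  expect_equal(nucleotide_diversity(alnx), 1 / 9)
})

test_that("site table reports polymorphic columns with gap fractions", {
  aln <- aln_from(c(w = "AATA-G", x = "AATT-G", y = "AAAT-G", z = "AA-T-G"),
                  data.frame(gene_id = "g1", start = 0, end = 6))
  st <- site_table(aln)
  expect_equal(st$column, c(2L, 3L)) # 0-based; invariant and all-gap columns absent
  r3 <- st[st$column == 2L, ]
  expect_equal(r3$gap_fraction, 0.25)
  expect_equal(r3$A + r3$C + r3$G + r3$T + r3$n_missing, 4)
  r4 <- st[st$column == 3L, ]
  expect_equal(c(r4$A, r4$T), c(1, 3))
})

test_that("diversity and site statistics are invariant to genome order", {
  pop <- cached_pop("tiny", n_genomes = 5, length = 900, seed = 7)
  aln <- pop$alignment
  perm <- rev(aln$ids)
  aln2 <- core_alignment(aln$seq[perm, ], aln$gene_map)
  expect_equal(nucleotide_diversity(aln2), nucleotide_diversity(aln))
  expect_equal(consensus_sequence(aln2), consensus_sequence(aln))
  expect_equal(site_table(aln2), site_table(aln))
})
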