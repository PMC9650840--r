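#' Attach a candidate genome to a reference core alignment
#'
#' Builds the shared alignment of a reference species plus exactly one
#' candidate genome from an already-aligned candidate sequence (one character
#' per reference column; use [match_orthologs()] to produce such a sequence
#' from unaligned candidate genes).
#'
#' @param ref_aln reference [core_alignment()].
#' @param candidate_seq aligned candidate nucleotide string (length
#'   `ref_aln$length`).
#' @param candidate_id label for the candidate genome.
#' @return a [core_alignment()] with attribute `candidate_id`.
#' @export
shared_core_alignment <- function(ref_aln, candidate_seq, candidate_id = "candidate") {
  stopifnot(inherits(ref_aln, "core_alignment"),
            nchar(candidate_seq) == ref_aln$length,
            !candidate_id %in% ref_aln$ids)
  S <- rbind(ref_aln$seq,
             .encode_nt(strsplit(toupper(candidate_seq), "", fixed = TRUE)[[1L]]))
  rownames(S) <- c(ref_aln$ids, candidate_id)
  out <- core_alignment(S, ref_aln$gene_map)
  attr(out, "candidate_id") <- candidate_id
  out
}

#' Match candidate genes to reference core genes and thread them
#'
#' Simplified bidirectional-best-hit ortholog matching: candidate genes are
#' translated and compared to the translated per-gene consensus of the
#' reference alignment by global pairwise protein alignment (BLOSUM62).
#' Mutual best hits with at least `min_identity` percent protein identity
#' (computed over alignment columns, excluding terminal gaps) and at least
#' `min_length` percent length conservation (shorter/longer protein) are kept
#' if single-copy in the candidate; the candidate's nucleotides are threaded
#' codon-aware onto the reference columns through the protein alignment
#' (reference codons deleted in the candidate become gaps, candidate
#' insertions are dropped).
#'
#' @param ref_aln reference [core_alignment()] with a gene map.
#' @param cand_genes named character vector of unaligned candidate coding
#'   sequences (nucleotide, in frame).
#' @param min_identity,min_length thresholds in percent (defaults 70 and 80).
#' @param candidate_id label for the candidate genome.
#' @return a [shared_core_alignment()] restricted to the retained genes, with
#'   attribute `provenance` (data frame: gene_id, cand_gene, identity,
#'   length_ratio).
#' @export
match_orthologs <- function(ref_aln, cand_genes, min_identity = 70,
                            min_length = 80, candidate_id = "candidate") {
  stopifnot(inherits(ref_aln, "core_alignment"), nrow(ref_aln$gene_map) > 0L,
            !is.null(names(cand_genes)))
  gm <- ref_aln$gene_map
  cons <- strsplit(consensus_sequence(ref_aln), "", fixed = TRUE)[[1L]]
  ref_nt <- vapply(seq_len(nrow(gm)), function(k) {
    paste(cons[(gm$start[k] + 1L):gm$end[k]], collapse = "")
  }, "")
  names(ref_nt) <- gm$gene_id
  ref_aa <- vapply(ref_nt, .translate_nt, "")
  cand_aa <- vapply(toupper(cand_genes), .translate_nt, "")
  names(cand_aa) <- names(cand_genes)
  nr <- length(ref_aa)
  nc <- length(cand_aa)
  ident <- matrix(-Inf, nr, nc, dimnames = list(names(ref_aa), names(cand_aa)))
  alns <- vector("list", nr * nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(ref_aa[[i]]), Biostrings::AAString(cand_aa[[j]]),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    ident[i, j] <- .alignment_identity(al)
    alns[[(j - 1L) * nr + i]] <- al
  }
  lenr <- outer(nchar(ref_aa), nchar(cand_aa),
                function(a, b) 100 * pmin(a, b) / pmax(a, b))
  pass <- ident >= min_identity & lenr >= min_length
  best_for_cand <- apply(ident, 2L, which.max)
  best_for_ref <- apply(ident, 1L, which.max)
  hits <- data.frame(ref = integer(), cand = integer())
  for (j in seq_len(nc)) {
    i <- best_for_cand[j]
    if (pass[i, j] && best_for_ref[i] == j)
      hits <- rbind(hits, data.frame(ref = i, cand = j))
  }
  # single-copy in the candidate: a reference gene hit by >1 passing candidate
  # gene is dropped entirely
  multi <- names(which(table(vapply(seq_len(nc), function(j) {
    i <- best_for_cand[j]
    if (pass[i, j]) i else NA_integer_
  }, 0L)) > 1L))
  hits <- hits[!hits$ref %in% as.integer(multi), , drop = FALSE]
  if (!nrow(hits)) stop("no shared core: no candidate gene passed the ortholog criteria")
  hits <- hits[order(hits$ref), , drop = FALSE]
  # subset the reference alignment to retained genes and thread the candidate
  keep_cols <- integer()
  cand_cols <- character()
  new_gm <- data.frame(gene_id = character(), start = integer(), end = integer())
  off <- 0L
  prov <- data.frame(gene_id = character(), cand_gene = character(),
                     identity = numeric(), length_ratio = numeric())
  for (r in seq_len(nrow(hits))) {
    i <- hits$ref[r]; j <- hits$cand[r]
    cols <- (gm$start[i] + 1L):gm$end[i]
    keep_cols <- c(keep_cols, cols)
    al <- alns[[(j - 1L) * nr + i]]
    cand_cols <- c(cand_cols,
                   .thread_codons(al, toupper(cand_genes[[j]]),
                                  (gm$end[i] - gm$start[i]) / 3L))
    glen <- gm$end[i] - gm$start[i]
    new_gm <- rbind(new_gm, data.frame(gene_id = gm$gene_id[i], start = off,
                                       end = off + glen))
    off <- off + glen
    prov <- rbind(prov, data.frame(gene_id = gm$gene_id[i],
                                   cand_gene = names(cand_aa)[j],
                                   identity = ident[i, j],
                                   length_ratio = lenr[i, j]))
  }
  sub <- core_alignment(ref_aln$seq[, keep_cols, drop = FALSE], new_gm)
  out <- shared_core_alignment(sub, paste(cand_cols, collapse = ""),
                               candidate_id)
  attr(out, "provenance") <- prov
  out
}

.translate_nt <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3
  cod <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- .translate_codon(cod)
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  aa[aa == "*"] <- "X" # internal stops kept as X so they count as mismatches
  paste(aa, collapse = "")
}

# percent identity over alignment columns between first and last position
# where both sequences are non-gap (terminal gaps excluded)
.alignment_identity <- function(al) {
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  np <- which(p != "-")
  ns <- which(s != "-")
  lo <- max(min(np), min(ns))
  hi <- min(max(np), max(ns))
  if (hi < lo) return(0)
  100 * mean(p[lo:hi] == s[lo:hi])
}

# map candidate codons through the protein alignment onto the reference
# gene's codons; returns the threaded nucleotide string (3 * n_ref_codons)
.thread_codons <- function(al, cand_nt, n_ref_codons) {
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  out <- rep("---", n_ref_codons)
  rp <- 0L
  cp <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") rp <- rp + 1L
    if (s[k] != "-") cp <- cp + 1L
    if (p[k] != "-" && s[k] != "-" && rp <= n_ref_codons)
      out[rp] <- substr(cand_nt, 3L * cp - 2L, 3L * cp)
  }
  paste(out, collapse = "")
}

#' Normalized between-species gene-flow ratio
#'
#' `hm_norm = (hm_cand - hm_0) / (hm_ref - hm_0)`: 0 means the combined h/m is
#' fully explained by convergent mutation (no gene flow with the candidate), 1
#' means gene flow indistinguishable from within-species levels. Values
#' outside [0,1] are returned as-is.
#'
#' @param hm_cand h/m of reference + candidate.
#' @param hm_ref h/m of the reference species alone.
#' @param hm_0 h/m of reference + convergent-mutation null sequence.
#' @return the normalized ratio; `NA` with a warning when `hm_ref == hm_0`.
#' @export
hm_norm <- function(hm_cand, hm_ref, hm_0) {
  if (isTRUE(all.equal(hm_ref, hm_0))) {
    warning("hm_ref equals hm_0: hm_norm undefined")
    return(NA_real_)
  }
  (hm_cand - hm_0) / (hm_ref - hm_0)
}

#' Assess gene flow between a reference species and a candidate genome
#'
#' Computes, each with leave-one-out resampling: `hm_ref` (reference genomes
#' only), `hm_cand` (reference + candidate) and `hm_0` (reference + a
#' convergent-mutation null sequence evolved from the reference consensus to
#' the candidate's divergence). Verdict: `distinct_species` when the
#' candidate's inclusion causes a significant (one-sided rank-sum,
#' P < `alpha`) and substantial (median relative drop >= `min_drop`) reduction
#' of h/m; `same_species` when there is no such drop and `hm_cand` is
#' significantly higher than `hm_0`; `ambiguous` otherwise (and forced when
#' `hm_ref` and `hm_0` are within one resampling SD of each other, where
#' `hm_norm` is unstable).
#'
#' @param shared a [shared_core_alignment()] (reference genomes + one
#'   candidate, attribute `candidate_id` set).
#' @param alpha significance threshold (default 1e-4).
#' @param min_drop substantial-drop threshold (default 0.10).
#' @param resamples leave-one-out replicates (default 100).
#' @param include_singletons passed to [tally_hm()].
#' @param divergence aggregator for the candidate-vs-reference divergence fed
#'   to the null: `"mean"` (default) or `"max"` p-distance.
#' @param seed RNG seed.
#' @return object of class `gene_flow_assessment`.
#' @export
assess_gene_flow <- function(shared, alpha = 1e-4, min_drop = 0.10,
                             resamples = 100, include_singletons = TRUE,
                             divergence = c("mean", "max"), seed = 1) {
  divergence <- match.arg(divergence)
  cand <- attr(shared, "candidate_id")
  if (is.null(cand)) stop("shared alignment lacks a candidate_id attribute")
  ref_ids <- setdiff(shared$ids, cand)
  if (length(ref_ids) < 5L) stop("reference species needs at least 5 genomes")
  ref_aln <- .subset_alignment(shared, ref_ids)
  t_ref <- .hm_pipeline(ref_aln, resamples = resamples,
                        include_singletons = include_singletons, seed = seed)
  t_cand <- .hm_pipeline(shared, resamples = resamples,
                         include_singletons = include_singletons, seed = seed)
  # convergent-mutation null at the candidate's divergence from the reference
  P <- .pairwise_p(shared)
  dvec <- P[cand, ref_ids]
  div <- if (divergence == "mean") mean(dvec) else max(dvec)
  nullseq <- convergent_mutation_null(consensus_sequence(ref_aln), div,
                                      seed = seed + 7L)
  t_null <- .hm_pipeline(shared_core_alignment(ref_aln, nullseq, "nullseq"),
                         resamples = resamples,
                         include_singletons = include_singletons, seed = seed)
  p_drop <- suppressWarnings(stats::wilcox.test(
    t_cand$resample_ratios, t_ref$resample_ratios,
    alternative = "less", exact = FALSE)$p.value)
  p_null <- suppressWarnings(stats::wilcox.test(
    t_cand$resample_ratios, t_null$resample_ratios,
    alternative = "greater", exact = FALSE)$p.value)
  med_ref <- stats::median(t_ref$resample_ratios, na.rm = TRUE)
  med_cand <- stats::median(t_cand$resample_ratios, na.rm = TRUE)
  drop <- (med_ref - med_cand) / med_ref
  hmn <- suppressWarnings(hm_norm(t_cand$ratio, t_ref$ratio, t_null$ratio))
  unstable <- abs(t_ref$ratio - t_null$ratio) <= t_ref$sd
  verdict <- if (is.finite(p_drop) && p_drop < alpha && drop >= min_drop) {
    "distinct_species"
  } else if (unstable) {
    "ambiguous"
  } else if (is.finite(p_null) && p_null < alpha) {
    "same_species"
  } else "ambiguous"
  structure(list(candidate_id = cand, hm_ref = t_ref$ratio,
                 hm_cand = t_cand$ratio, hm_0 = t_null$ratio, hm_norm = hmn,
                 p_drop = p_drop, p_null = p_null, median_drop = drop,
                 divergence = div, verdict = verdict,
                 hm_norm_unstable = unstable,
                 tallies = list(ref = t_ref, cand = t_cand, null = t_null)),
            class = "gene_flow_assessment")
}

#' @export
print.gene_flow_assessment <- function(x, ...) {
  cat(sprintf("h/m_ref = %.4f, h/m_cand = %.4f, h/m_0 = %.4f\n",
              x$hm_ref, x$hm_cand, x$hm_0))
  cat(sprintf("h/m_norm = %.4f%s (candidate divergence %.4f)\n", x$hm_norm,
              if (x$hm_norm_unstable) " [unstable]" else "", x$divergence))
  cat(sprintf("p_drop = %.3g (median drop %.3f), p_null = %.3g\n",
              x$p_drop, x$median_drop, x$p_null))
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}

#' One-row summary of a gene-flow assessment
#' @param x a `gene_flow_assessment`.
#' @return data frame row mirroring the per-pair report table.
#' @export
as.data.frame.gene_flow_assessment <- function(x, ...) {
  data.frame(candidate = x$candidate_id, hm_ref = x$hm_ref,
             hm_cand = x$hm_cand, hm_0 = x$hm_0, hm_norm = x$hm_norm,
             p_drop = x$p_drop, p_null = x$p_null,
             median_drop = x$median_drop, verdict = x$verdict)
}
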