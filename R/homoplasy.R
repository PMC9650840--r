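#' Minimum mutational origins of each allele at a site
#'
#' For one alignment column, computes for every allele the minimum number of
#' independent mutational origins on the guide tree: the small-parsimony
#' (Fitch/Hartigan) score of the binary carrier-vs-rest character, floored at
#' one (missing leaves are treated as fully ambiguous; the score is invariant
#' to rooting). An allele whose carriers cannot be explained by a single
#' origin (origins >= 2) is homoplasic: its distribution is incompatible with
#' vertical inheritance from a single ancestor and signals recombination or
#' convergent mutation.
#'
#' @param tree guide tree (`phylo`) whose tip labels cover the genomes.
#' @param states named vector of nucleotide states per genome: single letters
#'   (`"A"`, ..., `"-"`/`"N"` for missing) or integer codes 0--4.
#' @return data frame with one row per allele present among non-missing
#'   genomes: `allele`, `carrier_count`, `origins`, `homoplasic`.
#' @export
allele_origins <- function(tree, states) {
  ta <- .tree_arrays(tree)
  if (is.character(states)) states <- stats::setNames(.encode_nt(states), names(states))
  if (is.null(names(states))) stop("states must be named by genome id")
  if (!all(ta$tips %in% names(states)))
    stop("states missing for tips: ",
         paste(setdiff(ta$tips, names(states)), collapse = ", "))
  st <- as.integer(states[ta$tips])
  present <- sort(unique(st[st > 0L]))
  if (length(present) < 2L)
    stop("site must have at least 2 alleles among non-missing genomes")
  out <- lapply(present, function(a) {
    res <- .origins_cpp(ta$parent, ta$child, ta$ntip, ta$nnode, st, a)
    data.frame(allele = .NT[a], carrier_count = sum(st == a),
               origins = as.integer(res[["origins"]]),
               homoplasic = res[["origins"]] >= 2)
  })
  do.call(rbind, out)
}

#' Allele-origin records for all polymorphic sites of an alignment
#'
#' Convenience wrapper running the parsimony origin count over every
#' non-modal allele of every polymorphic column. Used by
#' [classify_syn_nonsyn()].
#'
#' @param aln a [core_alignment()].
#' @param tree guide tree covering the alignment's genomes.
#' @return data frame with `column` (0-based), `allele`, `carrier_count`,
#'   `origins`, `homoplasic`.
#' @export
allele_origin_table <- function(aln, tree) {
  ta <- .tree_arrays(tree)
  S <- aln$seq[ta$tips, , drop = FALSE]
  st <- site_table(aln)
  rows <- list()
  for (k in seq_len(nrow(st))) {
    j <- st$column[k] + 1L
    col <- as.integer(S[, j])
    cnt <- c(st$A[k], st$C[k], st$G[k], st$T[k])
    modal <- which.max(cnt) # ties resolve to the alphabetically first allele
    for (a in which(cnt > 0L)) {
      if (a == modal) next
      if (cnt[a] == 1L) {
        org <- 1L
      } else {
        res <- .origins_cpp(ta$parent, ta$child, ta$ntip, ta$nnode, col, a)
        org <- as.integer(res[["origins"]])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        column = st$column[k], allele = .NT[a], carrier_count = cnt[a],
        origins = org, homoplasic = org >= 2L)
    }
  }
  if (!length(rows))
    return(data.frame(column = integer(), allele = character(),
                      carrier_count = integer(), origins = integer(),
                      homoplasic = logical()))
  do.call(rbind, rows)
}

#' Tally homoplasic (h) and non-homoplasic (m) alleles with resampling
#'
#' The central gene-flow statistic. Every non-modal allele of every
#' polymorphic column is classified by its minimum number of origins on the
#' guide tree: h counts alleles needing >= 2 origins, m the rest. By default
#' singleton alleles (one carrier) count toward m -- a single carrier has
#' trivially one origin -- which is what makes the inclusion of a diverged,
#' non-recombining genome dilute h/m; set `include_singletons = FALSE` to
#' restrict the tally to alleles with at least two carriers.
#'
#' The h/m ratio is re-computed `resamples` times by excluding exactly one
#' genome per replicate (chosen uniformly without replacement until all
#' genomes have been left out once, then with replacement); the sample
#' standard deviation of the resampled ratios is the SD used by the clonality
#' threshold. Exclusion masks the genome's states as missing, which under
#' parsimony is equivalent to pruning the leaf.
#'
#' @param aln a [core_alignment()].
#' @param tree guide tree covering the genomes of `aln`.
#' @param resamples number of leave-one-out replicates (default 100).
#' @param include_singletons count single-carrier alleles toward m
#'   (default TRUE).
#' @param seed RNG seed for the resampling order.
#' @return object of class `hm_tally`: `h`, `m`, `ratio` (`NA` and flagged
#'   when m = 0), `loo` (named vector of leave-one-out ratios), `resample_ratios`,
#'   `sd`.
#' @export
tally_hm <- function(aln, tree, resamples = 100, include_singletons = TRUE,
                     seed = 1) {
  stopifnot(inherits(aln, "core_alignment"))
  ta <- .tree_arrays(tree)
  if (!setequal(ta$tips, aln$ids))
    stop("tree tips and alignment genomes differ")
  S <- aln$seq[ta$tips, , drop = FALSE]
  cnt <- .allele_counts(S)
  S <- S[, rowSums(cnt > 0L) >= 2L, drop = FALSE] # polymorphic columns only
  n <- ta$ntip
  full <- .hm_count_cpp(ta$parent, ta$child, ta$ntip, ta$nnode, S, 0L,
                        include_singletons)
  loo <- vapply(seq_len(n), function(g) {
    r <- .hm_count_cpp(ta$parent, ta$child, ta$ntip, ta$nnode, S, g,
                       include_singletons)
    if (r[["m"]] == 0L) NA_real_ else r[["h"]] / r[["m"]]
  }, 0.0)
  names(loo) <- ta$tips
  .check_seed(seed)
  ord <- .sample_int(n, min(n, resamples))
  if (resamples > n)
    ord <- c(ord, .sample_int(n, resamples - n, replace = TRUE))
  res <- unname(loo[ord])
  ratio <- if (full[["m"]] == 0L) NA_real_ else full[["h"]] / full[["m"]]
  structure(list(h = as.integer(full[["h"]]), m = as.integer(full[["m"]]),
                 ratio = ratio, loo = loo, resample_ratios = res,
                 sd = stats::sd(res),
                 include_singletons = include_singletons),
            class = "hm_tally")
}

#' @export
print.hm_tally <- function(x, ...) {
  cat("h/m tally: h =", x$h, ", m =", x$m, "\n")
  if (is.na(x$ratio)) cat("ratio undefined (m = 0)\n")
  else cat(sprintf("h/m = %.4f (resampling SD %.4f, %d replicates)\n",
                   x$ratio, x$sd, length(x$resample_ratios)))
  invisible(x)
}

# subset an alignment to a set of genomes (columns kept as-is)
.subset_alignment <- function(aln, ids) {
  core_alignment(aln$seq[ids, , drop = FALSE], aln$gene_map)
}

# distance + NJ tree + tally in one go, as used throughout the pipeline
.hm_pipeline <- function(aln, resamples = 100, include_singletons = TRUE,
                         seed = 1, model = "K2P") {
  D <- tryCatch(corrected_distance_matrix(aln, model),
                error = function(e) .pairwise_p(aln))
  tree <- build_guide_tree(D)
  tally_hm(aln, tree, resamples = resamples,
           include_singletons = include_singletons, seed = seed)
}

#' Detect and exclude non-recombining genomes
#'
#' Iterative genome-exclusion criterion: at each step the genome whose removal
#' most increases the median resampled h/m is excluded if the resample
#' distributions with and without it differ (two-sided Wilcoxon rank-sum test,
#' P < `alpha`) and the median relative increase is at least `min_drop`.
#' Stops when no genome qualifies or when fewer than 4 genomes would remain.
#'
#' @param aln a [core_alignment()] with at least 5 genomes.
#' @param alpha significance threshold (default 1e-4, as used throughout the
#'   gene-flow tests).
#' @param min_drop minimum median relative change in h/m to call a drop
#'   "substantial" (default 0.10).
#' @param resamples,include_singletons,seed passed to [tally_hm()].
#' @return list with `retained`, `excluded` (character vectors) and `log`
#'   (data frame of per-step candidate, p-value and median change).
#' @export
detect_nonrecombining_genomes <- function(aln, alpha = 1e-4, min_drop = 0.10,
                                          resamples = 100,
                                          include_singletons = TRUE, seed = 1) {
  stopifnot(inherits(aln, "core_alignment"))
  if (length(aln$ids) < 5L) stop("need at least 5 genomes")
  current <- aln$ids
  excluded <- character()
  log <- data.frame(step = integer(), candidate = character(),
                    p_value = numeric(), median_change = numeric(),
                    excluded = logical())
  step <- 0L
  repeat {
    step <- step + 1L
    if (length(current) - 1L < 4L) {
      warning("stopping: fewer than 4 genomes would remain")
      break
    }
    with_t <- .hm_pipeline(.subset_alignment(aln, current),
                           resamples = resamples,
                           include_singletons = include_singletons,
                           seed = seed + step)
    med_with <- stats::median(with_t$resample_ratios, na.rm = TRUE)
    best <- NULL
    for (g in current) {
      wo <- .hm_pipeline(.subset_alignment(aln, setdiff(current, g)),
                         resamples = resamples,
                         include_singletons = include_singletons,
                         seed = seed + step)
      med_wo <- stats::median(wo$resample_ratios, na.rm = TRUE)
      if (is.null(best) || med_wo > best$med_wo)
        best <- list(g = g, med_wo = med_wo, dist = wo$resample_ratios)
    }
    change <- (best$med_wo - med_with) / med_with
    pv <- suppressWarnings(stats::wilcox.test(best$dist, with_t$resample_ratios,
                                              exact = FALSE)$p.value)
    hit <- alpha > 0 && is.finite(pv) && pv < alpha && change >= min_drop
    log <- rbind(log, data.frame(step = step, candidate = best$g,
                                 p_value = pv, median_change = change,
                                 excluded = hit))
    if (!hit) break
    excluded <- c(excluded, best$g)
    current <- setdiff(current, best$g)
  }
  list(retained = current, excluded = excluded, log = log)
}

#' Classify homoplasic and non-homoplasic alleles as synonymous or not
#'
#' Restricted, to avoid ambiguity, to codons with exactly one polymorphic
#' site whose polymorphism is biallelic. An allele is synonymous iff the two
#' codon variants (variant vs modal base at the polymorphic position, modal
#' bases elsewhere) translate to the same amino acid under the standard
#' genetic code, with the codon phase taken from the gene map. Counts are
#' split by the allele's homoplasy flag; the `qualifying` flag records the
#' ">= 100 h and >= 100 m alleles" reporting rule.
#'
#' @param aln a [core_alignment()] with a non-empty gene map.
#' @param records allele-origin records from [allele_origin_table()] (rows
#'   outside any gene are skipped with a warning).
#' @return list with counts `h_syn`, `h_nonsyn`, `m_syn`, `m_nonsyn` and
#'   logical `qualifying`.
#' @export
classify_syn_nonsyn <- function(aln, records) {
  stopifnot(inherits(aln, "core_alignment"), nrow(aln$gene_map) > 0L)
  cod_pos <- .codon_positions(aln)
  cnt <- .allele_counts(aln$seq)
  n_alleles <- rowSums(cnt > 0L)
  cons <- max.col(cnt, ties.method = "first") # modal code per column
  cons[rowSums(cnt) == 0L] <- 0L
  out <- c(h_syn = 0L, h_nonsyn = 0L, m_syn = 0L, m_nonsyn = 0L)
  skipped <- 0L
  for (k in seq_len(nrow(records))) {
    j <- records$column[k] + 1L
    if (is.na(cod_pos[j])) { skipped <- skipped + 1L; next }
    codon_cols <- j - cod_pos[j] + (1:3)
    # exactly one polymorphic site in the codon, and it must be biallelic
    if (sum(n_alleles[codon_cols] >= 2L) != 1L) next
    if (n_alleles[j] != 2L) next
    base <- cons[codon_cols]
    if (any(base == 0L)) next
    ref <- base
    alt <- base
    alt[cod_pos[j]] <- match(records$allele[k], .NT)
    if (all(ref == alt)) next # record is the modal allele itself
    aa <- .translate_codon(c(paste(.NT[ref], collapse = ""),
                             paste(.NT[alt], collapse = "")))
    syn <- aa[1L] == aa[2L]
    key <- paste0(if (records$homoplasic[k]) "h" else "m",
                  if (syn) "_syn" else "_nonsyn")
    out[key] <- out[key] + 1L
  }
  if (skipped) warning(skipped, " record(s) outside any gene were skipped")
  c(as.list(out),
    list(qualifying = (out[["h_syn"]] + out[["h_nonsyn"]] >= 100L) &&
           (out[["m_syn"]] + out[["m_nonsyn"]] >= 100L)))
}
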