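#' Simulation parameters for the clonal null model
#'
#' Bundles everything the forward-in-time clonal simulator needs: GC content,
#' alignment length, the transition/transversion ratio kappa, relative
#' substitution rates for the three codon positions, and the guide tree whose
#' topology and branch lengths drive the simulation.
#'
#' @param gc_content fraction of G+C in (0,1).
#' @param length number of alignment columns (multiple of 3).
#' @param kappa transition/transversion ratio (> 0).
#' @param codon_rates 3 non-negative relative rates (not all zero) for codon
#'   positions 1--3; only their ratios matter.
#' @param tree guide tree (`phylo`) with branch lengths in expected
#'   substitutions per site.
#' @param gene_map optional gene map; defaults to a single gene spanning the
#'   alignment.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(gc_content, length, kappa, codon_rates, tree,
                              gene_map = NULL) {
  stopifnot(gc_content > 0, gc_content < 1, length %% 3 == 0, kappa > 0,
            base::length(codon_rates) == 3L, all(codon_rates >= 0),
            any(codon_rates > 0), inherits(tree, "phylo"))
  if (is.null(gene_map))
    gene_map <- data.frame(gene_id = "g1", start = 0L, end = as.integer(length))
  structure(list(gc_content = gc_content, length = as.integer(length),
                 kappa = kappa, codon_rates = codon_rates, tree = tree,
                 gene_map = gene_map),
            class = "simulation_params")
}

#' Estimate simulation parameters from an alignment and its guide tree
#'
#' Summary statistics extracted from the data: kappa as the ratio of
#' transition- to transversion-type polymorphic biallelic sites (capped at 100
#' with a warning if no transversions are seen), codon-position rates
#' proportional to the counts of polymorphic sites at codon positions 1/2/3,
#' GC content over all non-missing characters, and the alignment length and
#' tree passed through.
#'
#' @param aln a [core_alignment()] with a gene map covering its columns.
#' @param tree guide tree for the same genomes.
#' @return a [simulation_params()].
#' @export
estimate_params <- function(aln, tree) {
  stopifnot(inherits(aln, "core_alignment"))
  st <- site_table(aln)
  cnt <- as.matrix(st[, c("A", "C", "G", "T")])
  bi <- rowSums(cnt > 0L) == 2L
  ts <- tv <- 0L
  if (any(bi)) {
    pairs <- apply(cnt[bi, , drop = FALSE] > 0L, 1L, which)
    is_ts <- apply(pairs, 2L, function(p) .TS_PARTNER[p[1L]] == p[2L])
    ts <- sum(is_ts)
    tv <- sum(!is_ts)
  }
  if (tv == 0L) {
    warning("no transversion-type sites; kappa capped at 100")
    kappa <- 100
  } else {
    # observed count ratio ts/tv equals kappa/2 under K2P (each of the two
    # transversion targets has rate beta); double it to recover the rate-ratio
    # kappa the simulator consumes, so that estimated parameters round-trip
    kappa <- min(2 * ts / tv, 100)
  }
  pos <- .codon_positions(aln)
  pcount <- tabulate(pos[st$column + 1L], 3L)
  if (all(pcount == 0L)) pcount <- c(1L, 1L, 1L)
  S <- aln$seq
  gc <- sum(S == 2L | S == 3L) / max(1L, sum(S > 0L))
  gc <- min(max(gc, 1e-6), 1 - 1e-6)
  simulation_params(gc, ncol(S) - ncol(S) %% 3L, max(kappa, 1e-6),
                    pmax(pcount, 0), tree, aln$gene_map)
}

# K2P endpoint probabilities at distance t (branch length in expected
# substitutions per site): alpha = kappa/(kappa+2), beta = 1/(kappa+2)
.k2p_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * t) - 0.5 * exp(-2 * (alpha + beta) * t)
  p_tv <- 0.5 - 0.5 * exp(-4 * beta * t)
  c(same = 1 - p_ts - p_tv, ts = p_ts, tv = p_tv)
}

# the two transversion targets for each base code
.TV1 <- c(2L, 1L, 2L, 1L)
.TV2 <- c(4L, 3L, 4L, 3L)

# evolve an integer-coded sequence along a branch; rates are per-column
# relative rates (mean 1); returns list(seq, changed columns)
.evolve_k2p <- function(seq, t, class_idx, class_rates, kappa) {
  changed <- integer()
  for (cl in seq_along(class_idx)) {
    idx <- class_idx[[cl]]
    if (!length(idx)) next
    tc <- t * class_rates[cl]
    if (tc <= 0) next
    pr <- .k2p_probs(tc, kappa)
    nch <- stats::rbinom(1L, length(idx), 1 - pr[["same"]])
    if (nch == 0L) next
    pos <- idx[.sample_int(length(idx), nch)]
    old <- seq[pos]
    is_ts <- stats::runif(nch) < pr[["ts"]] / (pr[["ts"]] + pr[["tv"]])
    new <- ifelse(is_ts, .TS_PARTNER[old],
                  ifelse(stats::runif(nch) < 0.5, .TV1[old], .TV2[old]))
    seq[pos] <- new
    changed <- c(changed, pos)
  }
  list(seq = seq, changed = changed)
}

# column rate classes from a gene map (codon positions; extra-genic columns
# get the average rate)
.rate_classes <- function(params) {
  pos <- rep(NA_integer_, params$length)
  gm <- params$gene_map
  for (k in seq_len(nrow(gm))) {
    cols <- (gm$start[k] + 1L):min(gm$end[k], params$length)
    pos[cols] <- rep_len(1:3, length(cols))
  }
  # class 4 = extra-genic columns, evolved at the average rate; rates are
  # normalized so the mean rate over all columns is 1
  cls <- ifelse(is.na(pos), 4L, pos)
  raw <- c(params$codon_rates, mean(params$codon_rates))
  colrate <- raw[cls]
  raw <- raw / mean(colrate)
  list(idx = lapply(1:4, function(k) which(cls == k)), rates = raw)
}

#' Simulate clonal core-genome evolution
#'
#' Forward simulation without recombination: a random root sequence is drawn
#' i.i.d. with P(G) = P(C) = gc/2, and each branch of length `b * rescale`
#' evolves every site as an independent K2P continuous-time Markov chain with
#' site rate proportional to its codon-position rate (the per-site Poisson
#' substitution process with K2P jump probabilities; branch end states are
#' drawn from the closed-form K2P transition probabilities, which is exact).
#'
#' @param params a [simulation_params()].
#' @param rescale multiplicative branch-length factor (default 1).
#' @param seed RNG seed.
#' @return a [core_alignment()] of the leaf sequences, with attributes
#'   `root` (integer-coded root sequence) and `variant_cols` (columns hit by
#'   at least one net change).
#' @export
simulate_clonal <- function(params, rescale = 1, seed = 1) {
  sim <- .simulate_along_tree(params, rescale, seed, recombination_rate = 0,
                              tract_mean = 1000)
  sim$alignment
}

# shared machinery for the clonal and recombining simulators; recombination
# events copy a contiguous tract from the most recent ancestral node of a
# contemporaneous donor branch
.simulate_along_tree <- function(params, rescale, seed, recombination_rate,
                                 tract_mean) {
  .check_seed(seed)
  tree <- ape::reorder.phylo(params$tree, "cladewise") # parents before children
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  L <- params$length
  rc <- .rate_classes(params)
  gc <- params$gc_content
  node_seq <- vector("list", nnode)
  node_seq[[root]] <- .sample_int(4L, L, replace = TRUE,
                                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  # node depths (start/end time of each branch) for contemporaneity
  depth <- rep(NA_real_, nnode)
  depth[root] <- 0
  E <- tree$edge
  elen <- tree$edge.length * rescale
  for (e in seq_len(nrow(E))) depth[E[e, 2L]] <- depth[E[e, 1L]] + elen[e]
  events <- list()
  variant <- logical(L)
  parent_of <- integer(nnode)
  parent_of[E[, 2L]] <- E[, 1L]
  # donor sequence: most recent ancestor of the donor branch whose sequence is
  # already available in the cladewise traversal (node-resolution donor)
  donor_seq_node <- function(node) {
    while (is.null(node_seq[[node]])) node <- parent_of[node]
    node
  }
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    s <- node_seq[[p]]
    b <- elen[e]
    if (recombination_rate > 0 && b > 0) {
      n_ev <- stats::rpois(1L, recombination_rate * L * b)
      if (n_ev > 0L) {
        times <- sort(stats::runif(n_ev, depth[p], depth[p] + b))
        for (tv in times) {
          # donor: a contemporaneous branch (alive at time tv), excluding this one
          alive <- which(depth[E[, 1L]] <= tv & depth[E[, 2L]] >= tv)
          alive <- setdiff(alive, e)
          if (!length(alive)) next
          de <- alive[.sample_int(length(alive), 1L)]
          donor_node <- donor_seq_node(E[de, 1L])
          tlen <- 1L + stats::rgeom(1L, 1 / tract_mean)
          start <- .sample_int(L, 1L)
          idx <- start:min(L, start + tlen - 1L)
          old <- s[idx]
          s[idx] <- node_seq[[donor_node]][idx]
          variant[idx[old != s[idx]]] <- TRUE
          events[[length(events) + 1L]] <- data.frame(
            recipient_edge = e, recipient_child = ch, time = tv,
            donor_node = donor_node, start = idx[1L] - 1L,
            end = idx[length(idx)])
        }
      }
    }
    ev <- .evolve_k2p(s, b, rc$idx, rc$rates, params$kappa)
    node_seq[[ch]] <- ev$seq
    variant[ev$changed] <- TRUE
  }
  S <- do.call(rbind, node_seq[seq_len(ntip)])
  rownames(S) <- tree$tip.label
  aln <- core_alignment(S, params$gene_map)
  attr(aln, "root") <- node_seq[[root]]
  attr(aln, "variant_cols") <- which(variant)
  list(alignment = aln,
       events = if (length(events)) do.call(rbind, events) else
         data.frame(recipient_edge = integer(), recipient_child = integer(),
                    time = numeric(), donor_node = integer(),
                    start = integer(), end = integer()))
}

# fast pi using the variant-column attribute (gap-free simulated alignments)
.pi_sim <- function(aln) {
  vc <- attr(aln, "variant_cols")
  if (is.null(vc)) return(nucleotide_diversity(aln))
  n <- nrow(aln$seq)
  npair <- n * (n - 1) / 2
  if (!length(vc)) return(0)
  cnt <- .allele_counts(aln$seq[, vc, drop = FALSE])
  same <- rowSums(cnt * (cnt - 1L)) / 2
  sum(npair - same) / (npair * aln$length)
}

#' Branch-length rescaling sweep with diversity matching
#'
#' Because recombination inflates tree branch lengths, the clonal null is
#' simulated once per rescaling factor on a geometric grid and the replicate
#' whose nucleotide diversity is closest to the target is kept. Replicate i
#' uses `seed + i`.
#'
#' @param params a [simulation_params()].
#' @param target_pi observed nucleotide diversity to match (> 0, or 0 with a
#'   boundary warning).
#' @param n_replicates number of grid points (default 99).
#' @param seed base RNG seed.
#' @param grid optional explicit factor grid; default geometric 0.05--5.
#' @return list with `alignment` (best replicate, re-simulated at its seed),
#'   `factor`, and `log` (data frame: factor, pi, abs_diff).
#' @export
rescale_sweep <- function(params, target_pi, n_replicates = 99, seed = 1,
                          grid = NULL) {
  if (is.null(grid))
    grid <- exp(seq(log(0.05), log(5), length.out = n_replicates))
  pis <- vapply(seq_along(grid), function(i) {
    .pi_sim(simulate_clonal(params, rescale = grid[i], seed = seed + i))
  }, 0.0)
  best <- which.min(abs(pis - target_pi))
  if (best %in% c(1L, length(grid)))
    warning("best rescaling factor at grid edge; consider a wider grid")
  list(alignment = simulate_clonal(params, rescale = grid[best],
                                   seed = seed + best),
       factor = grid[best],
       log = data.frame(factor = grid, pi = pis,
                        abs_diff = abs(pis - target_pi)))
}

#' The 3-SD clonality decision
#'
#' A species is called clonal when its real h/m ratio does not exceed the h/m
#' of the diversity-matched clonal simulation by more than `k` resampling
#' standard deviations: clonal iff `real_ratio <= null_ratio + k * sd`.
#'
#' @param real an [tally_hm()] result for the real alignment (carries the
#'   resampling SD).
#' @param null_ratio h/m ratio of the matched clonal simulation (compute it by
#'   running the simulated alignment through the homoplasy engine with its own
#'   re-estimated tree, e.g. via [clonality_by_simulation()]).
#' @param k SD multiplier (default 3, the conservative threshold).
#' @return object of class `clonality_verdict`.
#' @export
clonality_test <- function(real, null_ratio, k = 3) {
  stopifnot(inherits(real, "hm_tally"))
  if (is.na(real$ratio)) stop("real h/m ratio undefined (m = 0)")
  if (!is.na(real$sd) && real$sd == 0 && real$ratio > null_ratio)
    warning("degenerate resampling SD of 0; verdict non-clonal")
  clonal <- real$ratio <= null_ratio + k * real$sd
  structure(list(real_ratio = real$ratio, null_ratio = null_ratio,
                 sd = real$sd, k = k, clonal = clonal),
            class = "clonality_verdict")
}

#' @export
print.clonality_verdict <- function(x, ...) {
  cat(sprintf("real h/m = %.4f, clonal-null h/m = %.4f, SD = %.4f (k = %g)\n",
              x$real_ratio, x$null_ratio, x$sd, x$k))
  cat("verdict:", if (x$clonal) "clonal" else "non-clonal", "\n")
  invisible(x)
}

#' Full simulation-based clonality assessment of one alignment
#'
#' Runs the whole chain: K2P distances, NJ guide tree, real h/m with
#' leave-one-out resampling, parameter estimation, the 99-factor rescaling
#' sweep matched on nucleotide diversity, h/m of the selected clonal replicate
#' (with its own re-estimated tree), and the k-SD verdict.
#'
#' @param aln a [core_alignment()].
#' @param resamples leave-one-out replicates for the real h/m (default 100).
#' @param n_replicates rescaling grid size (default 99).
#' @param k SD multiplier (default 3).
#' @param include_singletons passed to [tally_hm()].
#' @param seed RNG seed.
#' @return a `clonality_verdict` with the real tally, the sweep log and the
#'   selected factor attached as attributes `real`, `sweep_factor`.
#' @export
clonality_by_simulation <- function(aln, resamples = 100, n_replicates = 99,
                                    k = 3, include_singletons = TRUE, seed = 1) {
  real <- .hm_pipeline(aln, resamples = resamples,
                       include_singletons = include_singletons, seed = seed)
  D <- corrected_distance_matrix(aln, "K2P")
  tree <- build_guide_tree(D)
  params <- estimate_params(aln, tree)
  target <- nucleotide_diversity(aln)
  sw <- suppressWarnings(rescale_sweep(params, target,
                                       n_replicates = n_replicates,
                                       seed = seed * 1000L))
  null <- .hm_pipeline(sw$alignment, resamples = length(aln$ids),
                       include_singletons = include_singletons, seed = seed)
  out <- clonality_test(real, null$ratio, k = k)
  attr(out, "real") <- real
  attr(out, "sweep_factor") <- sw$factor
  out
}

#' Convergent-mutation null sequence
#'
#' Copies the consensus and introduces random Jukes--Cantor point mutations
#' (uniform positions, uniform target among the 3 alternative bases, with
#' replacement) until the observed divergence from the consensus first reaches
#' the target. The stopped state is sampled directly: the mismatch set is a
#' uniform subset of `ceiling(target * n)` non-missing positions and each
#' mismatched base is uniform over the 3 alternatives, which is exactly the
#' first-crossing distribution under JC symmetry.
#'
#' @param consensus nucleotide string (e.g. from [consensus_sequence()]);
#'   `N` positions are left untouched and excluded from the divergence
#'   denominator.
#' @param target_divergence observed mismatch fraction to reach, in [0, 0.75).
#' @param seed RNG seed.
#' @return a nucleotide string of the same length.
#' @export
convergent_mutation_null <- function(consensus, target_divergence, seed = 1) {
  stopifnot(target_divergence >= 0, target_divergence < 0.75)
  .check_seed(seed)
  codes <- .encode_nt(strsplit(consensus, "", fixed = TRUE)[[1L]])
  ok <- which(codes > 0L)
  K <- ceiling(target_divergence * length(ok) - 1e-9) # guard binary fuzz
  if (K > length(ok)) stop("target divergence unreachable")
  if (K > 0L) {
    pos <- ok[.sample_int(length(ok), K)]
    shift <- .sample_int(3L, K, replace = TRUE)
    codes[pos] <- ((codes[pos] - 1L + shift) %% 4L) + 1L
  }
  paste(.decode_nt(codes, missing_char = "N"), collapse = "")
}
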