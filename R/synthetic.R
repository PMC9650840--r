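#' Simulate a guide tree for synthetic populations
#'
#' Either a Yule (pure-birth) tree via \pkg{ape} or a perfectly balanced
#' ultrametric topology, with branch lengths scaled so the root-to-tip depth
#' equals `depth` (expected substitutions per site).
#'
#' @param n_leaves number of genomes (>= 3).
#' @param model `"yule"` or `"balanced"`.
#' @param depth root-to-tip path length (substitutions/site).
#' @param seed RNG seed.
#' @param labels optional tip labels (default `G01`, `G02`, ...).
#' @return a `phylo` tree.
#' @export
simulate_tree <- function(n_leaves, model = c("yule", "balanced"),
                          depth = 0.0075, seed = 1, labels = NULL) {
  stopifnot(n_leaves >= 3)
  model <- match.arg(model)
  if (is.null(labels))
    labels <- sprintf("G%02d", seq_len(n_leaves))
  .check_seed(seed)
  if (model == "yule") {
    tr <- ape::rphylo(n_leaves, birth = 1, death = 0)
    md <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- if (md > 0) tr$edge.length * depth / md else
      tr$edge.length * 0
  } else {
    tr <- ape::read.tree(text = paste0("(", .balanced_newick(labels[seq_len(n_leaves)], depth), ");"))
  }
  tr$tip.label <- labels[seq_len(n_leaves)]
  tr
}

# ultrametric balanced topology by successive halving
.balanced_newick <- function(lbl, d) {
  if (length(lbl) == 1L) return(paste0(lbl, ":", format(d, digits = 12)))
  h <- ceiling(length(lbl) / 2)
  part <- function(x) {
    if (length(x) == 1L) paste0(x, ":", format(d, digits = 12))
    else paste0("(", .balanced_newick(x, d / 2), "):", format(d / 2, digits = 12))
  }
  paste0(part(lbl[seq_len(h)]), ",", part(lbl[-seq_len(h)]))
}

# gene map tiling the alignment with equal-sized in-frame genes
.default_gene_map <- function(length, gene_size = 999L) {
  gene_size <- gene_size - gene_size %% 3L
  starts <- seq(0L, length - 1L, by = gene_size)
  ends <- pmin(starts + gene_size, length)
  ends <- ends - (ends - starts) %% 3L
  keep <- ends > starts
  data.frame(gene_id = sprintf("g%04d", seq_len(sum(keep))),
             start = starts[keep], end = ends[keep])
}

#' Simulate a population with optional gene-conversion recombination
#'
#' Forward-in-time evolution along the tree exactly as [simulate_clonal()]
#' (shared code path: `recombination_rate = 0` reproduces it bit for bit at
#' the same seed), plus homologous recombination by gene conversion: along
#' each branch, tract-copy events arrive as a Poisson process with rate
#' `recombination_rate` per site per unit branch length; each event copies a
#' contiguous tract (geometric length, mean `tract_mean`) from a
#' contemporaneous donor lineage chosen uniformly (donor sequence taken at
#' its most recent ancestral node). All events are logged.
#'
#' @param tree guide tree (`phylo`); overrides `params$tree`.
#' @param params a [simulation_params()].
#' @param recombination_rate initiation events per site per unit branch
#'   length (default 0.3, giving r/m around 3 at 1 kb tracts and ~1% diversity
#'   -- a typically recombining bacterium; 0 = clonal).
#' @param tract_mean mean gene-conversion tract length in bp (default 1000).
#' @param seed RNG seed.
#' @return list with `alignment` (a [core_alignment()] carrying `root` and
#'   `variant_cols` attributes) and `truth` (tree, event log, generating
#'   parameters and seed; replaying the generator with the logged seed
#'   reconstructs the alignment exactly).
#' @export
simulate_population <- function(tree, params, recombination_rate = 0.3,
                                tract_mean = 1000, seed = 1) {
  if (!missing(tree) && !is.null(tree)) params$tree <- tree
  sim <- .simulate_along_tree(params, rescale = 1, seed = seed,
                              recombination_rate = recombination_rate,
                              tract_mean = tract_mean)
  truth <- list(tree = params$tree, events = sim$events,
                params = params, recombination_rate = recombination_rate,
                tract_mean = tract_mean, seed = seed)
  list(alignment = sim$alignment, truth = truth)
}

#' Convenience generator: one synthetic species under the default world
#'
#' A Yule tree of `n_genomes` scaled to `depth`, GC 0.5, kappa 2, codon-position
#' rate weights (1, 0.5, 2.5) (third position fastest, second slowest), genes
#' of 999 bp, and gene conversion at `recombination_rate` with 1-kb tracts.
#'
#' @param n_genomes,length population size and alignment length.
#' @param recombination_rate see [simulate_population()]; 0 = clonal.
#' @param depth root-to-tip tree depth (substitutions/site).
#' @param gc_content,kappa,codon_rates substitution model parameters.
#' @param tract_mean mean recombination tract (bp).
#' @param seed RNG seed.
#' @return as [simulate_population()].
#' @export
simulate_species <- function(n_genomes = 15, length = 99999,
                             recombination_rate = 0.3, depth = 0.0075,
                             gc_content = 0.5, kappa = 2,
                             codon_rates = c(1, 0.5, 2.5), tract_mean = 1000,
                             seed = 1) {
  length <- length - length %% 3L
  tree <- simulate_tree(n_genomes, "yule", depth = depth, seed = seed)
  params <- simulation_params(gc_content, length, kappa, codon_rates, tree,
                              .default_gene_map(length))
  simulate_population(tree, params, recombination_rate = recombination_rate,
                      tract_mean = tract_mean, seed = seed + 1L)
}

#' Evolve a candidate genome from a reference population
#'
#' The candidate starts from the reference's root sequence (attribute `root`
#' of a simulated alignment; the consensus is used as a stand-in for real
#' data) and accumulates substitutions under the same K2P + codon-rate model
#' until its expected distance from the start reaches `divergence`. With
#' `exchanging = TRUE`, gene-conversion events against extant reference
#' genomes (chosen uniformly) are interleaved along the way at rate
#' `exchange_rate` per site per unit branch length, emulating a candidate
#' that keeps engaging in gene flow with the reference species.
#'
#' @param reference a [core_alignment()] (ideally from the simulator, so the
#'   true root is available).
#' @param divergence target divergence (expected p-distance from the start),
#'   in (0, 0.3].
#' @param exchanging whether the candidate keeps exchanging with the
#'   reference.
#' @param exchange_rate gene-conversion initiation rate while diverging
#'   (default 0.3, the within-species default).
#' @param tract_mean mean exchanged tract (bp).
#' @param params optional [simulation_params()] for the substitution model;
#'   defaults to the synthetic world's defaults on the reference's gene map.
#' @param seed RNG seed.
#' @return list with `sequence` (candidate nucleotide string aligned to the
#'   reference columns) and `truth` (event log, realized divergence).
#' @export
make_candidate <- function(reference, divergence, exchanging = FALSE,
                           exchange_rate = 0.3, tract_mean = 1000,
                           params = NULL, seed = 1) {
  stopifnot(inherits(reference, "core_alignment"),
            divergence > 0, divergence <= 0.3)
  .check_seed(seed)
  root <- attr(reference, "root")
  if (is.null(root)) {
    root <- .encode_nt(strsplit(consensus_sequence(reference), "",
                                fixed = TRUE)[[1L]])
    root[root == 0L] <- .sample_int(4L, sum(root == 0L), replace = TRUE)
  }
  L <- reference$length
  if (is.null(params))
    params <- simulation_params(0.5, L - L %% 3L, 2, c(1, 0.5, 2.5),
                                structure(list(), class = "phylo"),
                                reference$gene_map)
  rc <- .rate_classes(params)
  # branch "time" t such that the expected mismatch fraction from the start
  # equals the target divergence
  pmis <- function(t) {
    cls_n <- lengths(rc$idx)
    sum(vapply(seq_along(rc$idx), function(k) {
      cls_n[k] * (1 - .k2p_probs(t * rc$rates[k], params$kappa)[["same"]])
    }, 0.0)) / sum(cls_n)
  }
  t_total <- stats::uniroot(function(t) pmis(t) - divergence, c(1e-9, 10))$root
  seqc <- root
  events <- list()
  n_ev <- if (exchanging) stats::rpois(1L, exchange_rate * L * t_total) else 0L
  times <- sort(stats::runif(n_ev, 0, t_total))
  bounds <- c(0, times, t_total)
  for (seg in seq_len(length(bounds) - 1L)) {
    dt <- bounds[seg + 1L] - bounds[seg]
    seqc <- .evolve_k2p(seqc, dt, rc$idx, rc$rates, params$kappa)$seq
    if (seg <= n_ev) {
      donor <- reference$ids[.sample_int(length(reference$ids), 1L)]
      tlen <- 1L + stats::rgeom(1L, 1 / tract_mean)
      start <- .sample_int(L, 1L)
      idx <- start:min(L, start + tlen - 1L)
      ok <- reference$seq[donor, idx] > 0L
      seqc[idx[ok]] <- reference$seq[donor, idx[ok]]
      events[[length(events) + 1L]] <- data.frame(
        time = bounds[seg + 1L], donor = donor, start = idx[1L] - 1L,
        end = idx[length(idx)])
    }
  }
  realized <- mean(seqc != root)
  list(sequence = paste(.NT[seqc], collapse = ""),
       truth = list(events = if (length(events)) do.call(rbind, events) else
         data.frame(time = numeric(), donor = character(),
                    start = integer(), end = integer()),
         divergence_target = divergence, divergence_realized = realized,
         t_model = t_total, seed = seed))
}

#' Inject ground-truth introgressed windows into a shared alignment
#'
#' Randomly chosen non-overlapping windows have one (randomly chosen)
#' reference genome's sequence overwritten with the candidate's window
#' sequence, creating perfect-identity introgressed tracts with a known mask.
#'
#' @param shared a [shared_core_alignment()].
#' @param fraction percent of windows to overwrite, in (0, 50].
#' @param tract window/tract size in bp (default 100, matching the scan).
#' @param seed RNG seed.
#' @return list with `alignment` (modified shared alignment) and `mask`
#'   (data frame: window index, start, end, genome overwritten).
#' @export
inject_introgression <- function(shared, fraction, tract = 100, seed = 1) {
  stopifnot(fraction > 0, fraction <= 50)
  cand <- attr(shared, "candidate_id")
  if (is.null(cand)) stop("shared alignment lacks a candidate_id attribute")
  .check_seed(seed)
  refs <- setdiff(shared$ids, cand)
  nw <- shared$length %/% tract
  nsel <- round(fraction / 100 * nw)
  if (nsel < 1L || nsel > nw) stop("requested fraction selects no or too many windows")
  wins <- sort(.sample_int(nw, nsel))
  genomes <- refs[.sample_int(length(refs), nsel, replace = TRUE)]
  S <- shared$seq
  for (k in seq_len(nsel)) {
    idx <- ((wins[k] - 1L) * tract + 1L):(wins[k] * tract)
    S[genomes[k], idx] <- S[cand, idx]
  }
  out <- core_alignment(S, shared$gene_map)
  attr(out, "candidate_id") <- cand
  list(alignment = out,
       mask = data.frame(window = wins - 1L, start = (wins - 1L) * tract,
                         end = wins * tract, genome = genomes))
}
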