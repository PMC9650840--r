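# Shared fixtures built in code.

# alignment from a named character vector with a single full-length gene
aln_from <- function(seqs, gene_map = NULL) {
  if (is.null(gene_map)) {
    L <- nchar(seqs[[1]])
    L3 <- L - L %% 3
    gene_map <- data.frame(gene_id = "g1", start = 0L, end = L3)
  }
  core_alignment(seqs, gene_map)
}

quartet_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# brute-force minimum-origins oracle: enumerate all X/not-X assignments of the
# internal nodes; cost of a leaf edge is 0 when the leaf is missing, else a
# mismatch indicator against the parent's binary state; floor at 1
origins_oracle <- function(tree, states, allele) {
  tt <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tt$tip.label)
  ni <- tt$Nnode
  st <- states[tt$tip.label]
  leaf_bin <- ifelse(st == 0L, NA_integer_, as.integer(st == allele))
  combos <- as.matrix(expand.grid(rep(list(0:1), ni)))
  cost <- numeric(nrow(combos))
  for (e in seq_len(nrow(tt$edge))) {
    p <- tt$edge[e, 1L] - ntip
    ch <- tt$edge[e, 2L]
    if (ch <= ntip) {
      b <- leaf_bin[ch]
      if (!is.na(b)) cost <- cost + (combos[, p] != b)
    } else {
      cost <- cost + (combos[, p] != combos[, ch - ntip])
    }
  }
  max(1L, min(cost))
}

# brute-force union-find oracle for single-linkage components
union_find_components <- function(ani, cutoff) {
  n <- nrow(ani)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (ani[i, j] >= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, 0L)
}

encode_states <- function(x) setNames(coreflow:::.encode_nt(x), names(x))

# small recombining / clonal populations reused across tests (cached)
.cache <- new.env()
cached_pop <- function(key, ...) {
  if (is.null(.cache[[key]])) .cache[[key]] <- simulate_species(...)
  .cache[[key]]
}
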