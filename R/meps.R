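#' Simulate a pair of diverged sequences at a target identity
#'
#' One random uniform-GC sequence and a copy diverged by Jukes--Cantor point
#' substitutions (no indels) until the observed identity first reaches the
#' target. The stopped state is sampled directly: exactly
#' `ceiling((1 - identity/100) * length)` mismatch positions, uniform along
#' the sequence, each differing by a uniform choice among the 3 alternative
#' bases (the exact first-crossing distribution under JC symmetry).
#'
#' @param identity target percent identity between 80 and 100.
#' @param length sequence length in bp (default 1e6).
#' @param seed RNG seed.
#' @return list with character strings `seq1` and `seq2`.
#' @export
simulate_pair <- function(identity, length = 1e6, seed = 1) {
  stopifnot(identity >= 80, identity <= 100, length >= 1)
  .check_seed(seed)
  s1 <- .sample_int(4L, length, replace = TRUE)
  s2 <- s1
  K <- ceiling((1 - identity / 100) * length - 1e-9) # guard binary fuzz
  if (K > 0L) {
    pos <- .sample_int(length, K)
    shift <- .sample_int(3L, K, replace = TRUE)
    s2[pos] <- ((s2[pos] - 1L + shift) %% 4L) + 1L
  }
  list(seq1 = paste(.NT[s1], collapse = ""), seq2 = paste(.NT[s2], collapse = ""))
}

#' Count strictly identical shared segments of length L
#'
#' The number of potential MEPS (minimal efficient processing segments): start
#' offsets at which the two sequences agree over L consecutive positions.
#' `overlap = TRUE` (default) slides by 1 bp; `overlap = FALSE` counts
#' non-overlapping grid windows instead.
#'
#' @param pair list with `seq1`, `seq2` (equal-length nucleotide strings), as
#'   from [simulate_pair()].
#' @param L segment length in bp.
#' @param overlap sliding (TRUE) or non-overlapping grid (FALSE).
#' @return integer count.
#' @export
count_identical_segments <- function(pair, L, overlap = TRUE) {
  a <- strsplit(pair$seq1, "", fixed = TRUE)[[1L]]
  b <- strsplit(pair$seq2, "", fixed = TRUE)[[1L]]
  stopifnot(length(a) == length(b))
  if (L > length(a)) stop("L exceeds sequence length")
  eq <- a == b
  if (overlap) {
    r <- rle(eq)
    runs <- r$lengths[r$values]
    return(sum(pmax(runs - L + 1L, 0L)))
  }
  nw <- length(eq) %/% L
  ends <- seq_len(nw) * L
  cs <- cumsum(eq)
  sum((cs[ends] - c(0, cs[ends[-nw]])) == L)
}

#' Expected number of identical L-bp segments under uniform divergence
#'
#' `(length - L + 1) * (1 - divergence)^L` under independent uniform mismatch
#' placement: the vertical-inheritance baseline for identical-fragment counts
#' between a genome pair.
#'
#' @param divergence mismatch fraction in [0, 1).
#' @param L segment length in bp.
#' @param length sequence length in bp.
#' @return expected count.
#' @export
expected_identical_fraction <- function(divergence, L, length) {
  stopifnot(divergence >= 0, divergence < 1)
  (length - L + 1) * (1 - divergence)^L
}

#' MEPS availability curve over identity and segment-length grids
#'
#' Mean identical-segment counts over replicate simulated pairs, for every
#' combination of target identity and scanning-window size. Replicate r uses
#' `seed + r`.
#'
#' @param identities percent-identity grid (default 80--100 by 5).
#' @param lengths segment sizes in bp (default 20--100 by 10).
#' @param length sequence length per pair (default 1e6; reduce for quick runs).
#' @param replicates replicate pairs per identity (default 3).
#' @param seed base RNG seed.
#' @param overlap see [count_identical_segments()].
#' @return object of class `meps_curve`: long data frame `counts`
#'   (identity, L, replicate, count, count_per_start) and the mean matrix
#'   `mean_counts` (identities x lengths).
#' @export
meps_curve <- function(identities = seq(80, 100, by = 5),
                       lengths = seq(20, 100, by = 10), length = 1e6,
                       replicates = 3, seed = 1, overlap = TRUE) {
  rows <- list()
  for (id in identities) for (r in seq_len(replicates)) {
    pair <- simulate_pair(id, length = length,
                          seed = seed + 1000L * match(id, identities) + r)
    for (L in lengths) {
      cnt <- count_identical_segments(pair, L, overlap = overlap)
      rows[[base::length(rows) + 1L]] <- data.frame(
        identity = id, L = L, replicate = r, count = cnt,
        count_per_start = cnt / (length - L + 1))
    }
  }
  counts <- do.call(rbind, rows)
  mean_counts <- stats::xtabs(count ~ identity + L,
                              stats::aggregate(count ~ identity + L, counts, mean))
  structure(list(counts = counts, mean_counts = mean_counts,
                 identities = identities, lengths = lengths,
                 length = length, replicates = replicates),
            class = "meps_curve")
}

#' @export
print.meps_curve <- function(x, ...) {
  cat("MEPS curve:", length(x$identities), "identities x", length(x$lengths),
      "segment sizes,", x$replicates, "replicate(s) of", x$length, "bp\n")
  print(round(unclass(x$mean_counts), 1))
  invisible(x)
}
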