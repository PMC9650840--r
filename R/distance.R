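#' Pairwise ANI of core genes
#'
#' Average nucleotide identity per genome pair on the aligned core-genome
#' concatenate: matching comparable columns / comparable columns x 100, where
#' comparable means both genomes non-missing. This is the "ANI of core genes"
#' metric (stricter than whole-genome ANI because core genes evolve slowly).
#'
#' @param aln a [core_alignment()].
#' @return symmetric matrix of percent identities with diagonal 100 and genome
#'   ids as dimnames.
#' @export
pairwise_ani <- function(aln) {
  100 * (1 - .pairwise_p(aln, what = "p"))
}

# pairwise mismatch fractions (and optionally ts/tv splits) with pairwise
# deletion of missing columns
.pairwise_p <- function(aln, what = c("p", "tstv")) {
  what <- match.arg(what)
  S <- aln$seq
  n <- nrow(S)
  P <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  TS <- P
  gapfree <- !any(S == 0L)
  for (i in seq_len(n - 1L)) {
    si <- S[i, ]
    for (j in (i + 1L):n) {
      sj <- S[j, ]
      if (gapfree) {
        comp <- ncol(S)
        diff <- si != sj
      } else {
        ok <- si > 0L & sj > 0L
        comp <- sum(ok)
        if (comp == 0L)
          stop("genomes ", aln$ids[i], " and ", aln$ids[j],
               " share no comparable columns")
        diff <- ok & si != sj
      }
      P[i, j] <- P[j, i] <- sum(diff) / comp
      if (what == "tstv")
        TS[i, j] <- TS[j, i] <- sum(diff & .TS_PARTNER[si] == sj) / comp
    }
  }
  if (what == "tstv") list(p = P, ts = TS, tv = P - TS) else P
}

#' Corrected pairwise distance matrix
#'
#' Closed-form evolutionary distances on the concatenate. `p-distance` is the
#' raw mismatch fraction; `JC` applies the Jukes--Cantor correction
#' \eqn{-3/4 \log(1 - 4p/3)}; `K2P` (the default) applies the Kimura
#' two-parameter correction from transition (`p`) and transversion (`q`)
#' fractions, \eqn{-\frac{1}{2}\log(1-2p-q) - \frac{1}{4}\log(1-2q)}.
#' K2P replaces the maximum-likelihood distances used on the full-scale data;
#' the homoplasy engine only consumes relative distances.
#'
#' @param aln a [core_alignment()].
#' @param model one of `"K2P"`, `"JC"`, `"p-distance"`.
#' @return symmetric distance matrix, zero diagonal.
#' @export
corrected_distance_matrix <- function(aln, model = c("K2P", "JC", "p-distance")) {
  model <- match.arg(model)
  if (model == "p-distance") return(.pairwise_p(aln))
  if (model == "JC") {
    p <- .pairwise_p(aln)
    arg <- 1 - 4 * p / 3
    if (any(arg <= 0))
      stop("JC correction undefined (log argument <= 0); use p-distance")
    return(-3 / 4 * log(arg))
  }
  pq <- .pairwise_p(aln, what = "tstv")
  a1 <- 1 - 2 * pq$ts - pq$tv
  a2 <- 1 - 2 * pq$tv
  if (any(a1 <= 0) || any(a2 <= 0))
    stop("K2P correction undefined (log argument <= 0); use p-distance")
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' Single-linkage species clustering at an ANI cutoff
#'
#' Clusters are the connected components of the graph joining genome pairs with
#' ANI at or above the cutoff (transitive single-linkage chaining, as used to
#' redefine named species into ANI species). Cluster labels are
#' `SP_<smallest member id>`, assigned deterministically.
#'
#' @param ani symmetric percent-identity matrix with genome ids as dimnames
#'   (e.g. from [pairwise_ani()]).
#' @param cutoff percent identity threshold (default 94, as used to delimit
#'   ANI species on core genes).
#' @return object of class `species_partition`: list with `assignment` (named
#'   character vector genome -> cluster label) and `cutoff`.
#' @export
single_linkage_species <- function(ani, cutoff = 94) {
  ids <- rownames(ani)
  stopifnot(!is.null(ids), nrow(ani) == ncol(ani))
  n <- length(ids)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(ani[v, ] >= cutoff & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  labels <- vapply(seq_len(max(comp)), function(k) {
    paste0("SP_", sort(ids[comp == k])[1L])
  }, "")
  assignment <- stats::setNames(labels[comp], ids)
  structure(list(assignment = assignment, cutoff = cutoff),
            class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  tab <- table(x$assignment)
  cat("species partition at ANI >=", x$cutoff, "%:", length(tab), "cluster(s)\n")
  for (k in names(tab)) cat(" ", k, ":", tab[[k]], "genome(s)\n")
  invisible(x)
}

#' Write a square matrix (ANI or distances) as TSV
#' @param m matrix with ids as dimnames.
#' @param path output path.
#' @export
write_square_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  .write_tsv(df, path)
}
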