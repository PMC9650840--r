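#' Core-genome alignment container
#'
#' A `core_alignment` holds an aligned core-genome concatenate: one equal-length
#' nucleotide sequence per genome plus an in-frame gene-boundary map. It is the
#' substrate of every downstream statistic (ANI, nucleotide diversity, the h/m
#' homoplasy tally, LD decay, introgression windows).
#'
#' Internally sequences are stored as an integer matrix (genomes x columns)
#' with codes 0 = missing (gap, `N`, or any other ambiguity code) and 1--4 =
#' `A`,`C`,`G`,`T`. Coordinates are 0-based half-open internally; human-readable
#' reports use 1-based inclusive positions.
#'
#' @param sequences named character vector of aligned sequences (identical
#'   lengths), or an integer code matrix with rownames.
#' @param gene_map data frame with columns `gene_id`, `start`, `end`
#'   (0-based half-open, sorted, non-overlapping, lengths divisible by 3).
#' @return an object of class `core_alignment` with elements `ids`, `seq`
#'   (integer matrix), `gene_map`, and `length`.
#' @export
core_alignment <- function(sequences, gene_map) {
  if (is.matrix(sequences)) {
    S <- sequences
    storage.mode(S) <- "integer"
    ids <- rownames(S)
  } else {
    ids <- names(sequences)
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) {
      off <- ids[which(lens != lens[1L])[1L]]
      stop("alignment length mismatch: record '", off, "' has length ",
           lens[ids == off][1L], ", expected ", lens[1L])
    }
    S <- do.call(rbind, lapply(sequences, function(s) {
      .encode_nt(strsplit(s, "", fixed = TRUE)[[1L]])
    }))
    rownames(S) <- ids
  }
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must carry unique genome ids")
  if (nrow(S) < 2L) stop("a core alignment needs at least 2 genomes")
  L <- ncol(S)
  gene_map <- .validate_gene_map(gene_map, L)
  structure(list(ids = ids, seq = S, gene_map = gene_map, length = L),
            class = "core_alignment")
}

.validate_gene_map <- function(gene_map, L) {
  gene_map <- as.data.frame(gene_map, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "start", "end") %in% names(gene_map)))
  gene_map$start <- as.integer(gene_map$start)
  gene_map$end <- as.integer(gene_map$end)
  gene_map <- gene_map[, c("gene_id", "start", "end")]
  if (nrow(gene_map)) {
    bad <- gene_map$end > L | gene_map$start < 0L
    if (any(bad))
      stop("gene interval exceeds alignment: ", gene_map$gene_id[which(bad)[1L]])
    if (any((gene_map$end - gene_map$start) %% 3L != 0L)) {
      g <- gene_map$gene_id[which((gene_map$end - gene_map$start) %% 3L != 0L)[1L]]
      stop("gene interval not divisible by 3: ", g)
    }
    if (any(gene_map$end <= gene_map$start))
      stop("empty or reversed gene interval: ",
           gene_map$gene_id[which(gene_map$end <= gene_map$start)[1L]])
    o <- order(gene_map$start)
    gene_map <- gene_map[o, , drop = FALSE]
    if (nrow(gene_map) > 1L &&
        any(gene_map$start[-1L] < gene_map$end[-nrow(gene_map)]))
      stop("gene intervals overlap")
    rownames(gene_map) <- NULL
  }
  gene_map
}

#' Read an aligned core-genome concatenate
#'
#' Reads an aligned multi-FASTA (optionally gzipped) and a 3-column
#' tab-separated gene map (`gene_id<TAB>start<TAB>end`, 0-based half-open; a
#' header line starting with `#` is tolerated). Characters are uppercased and
#' `U` is mapped to `T`; ambiguity codes other than `N` are treated as missing.
#'
#' @param fasta_path path to the aligned multi-FASTA.
#' @param gene_map_path path to the gene map TSV.
#' @return a [core_alignment()].
#' @export
read_core_alignment <- function(fasta_path, gene_map_path) {
  dss <- Biostrings::readBStringSet(fasta_path)
  seqs <- toupper(as.character(dss))
  names(seqs) <- sub("\\s.*$", "", names(dss))
  gm <- read_gene_map(gene_map_path)
  core_alignment(seqs, gm)
}

#' @rdname read_core_alignment
#' @export
read_gene_map <- function(gene_map_path) {
  ln <- readLines(gene_map_path)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("gene map lines need 3 tab-separated fields")
  data.frame(gene_id = vapply(parts, `[`, "", 1L),
             start = as.integer(vapply(parts, `[`, "", 2L)),
             end = as.integer(vapply(parts, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Write a core alignment back to FASTA + gene map
#'
#' Missing states are written as `-`. Re-reading the two files reproduces the
#' `core_alignment` exactly.
#'
#' @param aln a [core_alignment()].
#' @param fasta_path,gene_map_path output paths.
#' @export
write_core_alignment <- function(aln, fasta_path, gene_map_path) {
  stopifnot(inherits(aln, "core_alignment"))
  seqs <- apply(aln$seq, 1L, function(r) paste(.decode_nt(r), collapse = ""))
  dss <- Biostrings::BStringSet(seqs)
  names(dss) <- aln$ids
  Biostrings::writeXStringSet(dss, fasta_path)
  .write_tsv(stats::setNames(aln$gene_map, c("#gene_id", "start", "end")),
             gene_map_path)
  invisible(c(fasta_path, gene_map_path))
}

#' @export
print.core_alignment <- function(x, ...) {
  cat("core_alignment:", length(x$ids), "genomes x", x$length, "columns,",
      nrow(x$gene_map), "genes\n")
  invisible(x)
}

#' @export
summary.core_alignment <- function(object, ...) {
  st <- site_table(object)
  out <- list(n_genomes = length(object$ids), length = object$length,
              n_genes = nrow(object$gene_map),
              n_polymorphic = nrow(st),
              pi = nucleotide_diversity(object))
  class(out) <- "summary.core_alignment"
  out
}

#' @export
print.summary.core_alignment <- function(x, ...) {
  cat("core alignment:", x$n_genomes, "genomes x", x$length, "columns (",
      x$n_genes, "genes )\n")
  cat("polymorphic columns:", x$n_polymorphic, "\n")
  cat(sprintf("nucleotide diversity (pi): %.6f\n", x$pi))
  invisible(x)
}

#' Majority-rule consensus sequence
#'
#' One character per column: the modal non-missing nucleotide, ties broken in
#' fixed alphabetical order (A < C < G < T); all-missing columns emit `N`.
#'
#' @param aln a [core_alignment()].
#' @return a single character string of length `aln$length`.
#' @export
consensus_sequence <- function(aln) {
  stopifnot(inherits(aln, "core_alignment"))
  cnt <- .allele_counts(aln$seq)
  tot <- rowSums(cnt)
  cons <- .NT[max.col(cnt, ties.method = "first")]
  cons[tot == 0L] <- "N"
  paste(cons, collapse = "")
}

# columns x 4 matrix of allele counts
.allele_counts <- function(S) {
  cbind(A = colSums(S == 1L), C = colSums(S == 2L),
        G = colSums(S == 3L), T = colSums(S == 4L))
}

#' Average pairwise nucleotide diversity
#'
#' Mean over all unordered genome pairs of the fraction of differing comparable
#' columns (both genomes non-missing). Pairs with no comparable columns are
#' excluded; an error is raised if every pair is excluded.
#'
#' @param aln a [core_alignment()].
#' @return nucleotide diversity per site (a fraction).
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "core_alignment"))
  S <- aln$seq
  n <- nrow(S)
  if (!any(S == 0L)) {
    # gap-free fast path via per-column allele counts
    cnt <- .allele_counts(S)
    same <- rowSums(cnt * (cnt - 1L)) / 2
    npair <- n * (n - 1) / 2
    return(sum(npair - same) / (npair * ncol(S)))
  }
  vals <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- S[i, ] > 0L & S[j, ] > 0L
    nc <- sum(comp)
    if (nc == 0L) next
    vals <- c(vals, sum(S[i, comp] != S[j, comp]) / nc)
  }
  if (!length(vals)) stop("no genome pair has comparable columns")
  mean(vals)
}

#' Table of polymorphic sites
#'
#' One row per polymorphic column (at least two distinct non-missing
#' nucleotides present), with per-allele carrier counts and the fraction of
#' genomes missing (`-`/`N`) at the column, so callers can apply missingness
#' and singleton filters themselves.
#'
#' @param aln a [core_alignment()].
#' @return data frame with columns `column` (0-based), `A`, `C`, `G`, `T`,
#'   `n_missing`, `gap_fraction`.
#' @export
site_table <- function(aln) {
  stopifnot(inherits(aln, "core_alignment"))
  S <- aln$seq
  n <- nrow(S)
  cnt <- .allele_counts(S)
  poly <- rowSums(cnt > 0L) >= 2L
  idx <- which(poly)
  data.frame(column = idx - 1L,
             A = cnt[idx, 1L], C = cnt[idx, 2L],
             G = cnt[idx, 3L], T = cnt[idx, 4L],
             n_missing = n - rowSums(cnt)[idx],
             gap_fraction = (n - rowSums(cnt)[idx]) / n,
             row.names = NULL)
}

# codon position (1/2/3) per column; NA outside genes
.codon_positions <- function(aln) {
  pos <- rep(NA_integer_, aln$length)
  gm <- aln$gene_map
  for (k in seq_len(nrow(gm))) {
    cols <- (gm$start[k] + 1L):gm$end[k]
    pos[cols] <- rep_len(1:3, length(cols))
  }
  pos
}
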