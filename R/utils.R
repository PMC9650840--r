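# Internal helpers shared across modules.

# Nucleotide codes: 0 = missing (gap, N, any ambiguity), 1..4 = A,C,G,T.
.NT <- c("A", "C", "G", "T")

.encode_nt <- function(x) {
  # x: character vector of single letters (any case); returns integer codes
  m <- match(toupper(x), .NT)
  m[toupper(x) == "U"] <- 4L
  m[is.na(m)] <- 0L
  m
}

.decode_nt <- function(codes, missing_char = "-") {
  out <- rep(missing_char, length(codes))
  ok <- codes > 0L
  out[ok] <- .NT[codes[ok]]
  out
}

# Transition partner (A<->G, C<->T) for coded bases
.TS_PARTNER <- c(3L, 4L, 1L, 2L)

.codon_str <- function(codes3) {
  # codes3: integer matrix 3 x n of codes; returns codon strings, NA if missing
  bad <- colSums(codes3 == 0L) > 0L
  s <- paste0(.NT[codes3[1L, ]], .NT[codes3[2L, ]], .NT[codes3[3L, ]])
  s[bad] <- NA_character_
  s
}

.translate_codon <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

.check_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  invisible(NULL)
}

# sample() without the length-1 surprise
.sample_int <- function(n, size, replace = FALSE, prob = NULL) {
  sample.int(n, size = size, replace = replace, prob = prob)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
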