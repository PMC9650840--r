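#' Applicability check for the introgression score
#'
#' The window-based introgression score assumes every reference genome is more
#' closely related to its conspecifics than to the candidate. Returns `TRUE`
#' iff no reference genome is strictly closer to the candidate than to another
#' reference genome (exact ties pass: "more related" is strict).
#'
#' @param D symmetric distance matrix covering the reference genomes and the
#'   candidate, ids as dimnames.
#' @param candidate_id the candidate's id in `D`.
#' @return logical.
#' @export
applicability_check <- function(D, candidate_id) {
  ids <- rownames(D)
  stopifnot(candidate_id %in% ids)
  refs <- setdiff(ids, candidate_id)
  for (i in refs) {
    others <- setdiff(refs, i)
    if (any(D[i, candidate_id] < D[i, others])) return(FALSE)
  }
  TRUE
}

# per-window identity bookkeeping shared by scan_windows / introgression_profile:
# returns per-window best candidate-vs-reference identity, min/mean/max
# within-reference identity, and whether the window is evaluable
.window_identities <- function(shared, window, min_comparable) {
  cand <- attr(shared, "candidate_id")
  if (is.null(cand)) stop("shared alignment lacks a candidate_id attribute")
  refs <- setdiff(shared$ids, cand)
  S <- shared$seq
  L <- shared$length
  nw <- L %/% window
  if (nw < 1L) stop("alignment shorter than one window")
  ends <- seq_len(nw) * window
  wsum <- function(x) { # per-window sums of a length-L vector
    cs <- cumsum(x)
    cs[ends] - c(0, cs[ends[-nw]])
  }
  pair_ident <- function(a, b) {
    comp <- S[a, ] > 0L & S[b, ] > 0L
    nc <- wsum(comp)
    eq <- wsum(comp & S[a, ] == S[b, ])
    list(ident = ifelse(nc > 0, 100 * eq / nc, NA_real_), n = nc)
  }
  best_cand <- rep(-Inf, nw)
  ok <- rep(TRUE, nw)
  for (r in refs) {
    pi_ <- pair_ident(cand, r)
    ok <- ok & pi_$n >= min_comparable
    best_cand <- pmax(best_cand, pi_$ident, na.rm = TRUE)
  }
  min_within <- rep(Inf, nw)
  max_within <- rep(-Inf, nw)
  sum_within <- rep(0, nw)
  npairs <- 0L
  for (i in seq_along(refs)[-length(refs)]) for (j in (i + 1L):length(refs)) {
    pi_ <- pair_ident(refs[i], refs[j])
    ok <- ok & pi_$n >= min_comparable
    min_within <- pmin(min_within, pi_$ident, na.rm = TRUE)
    max_within <- pmax(max_within, pi_$ident, na.rm = TRUE)
    sum_within <- sum_within + pi_$ident
    npairs <- npairs + 1L
  }
  data.frame(window = seq_len(nw) - 1L, start = ends - window, end = ends,
             best_cand_identity = best_cand, min_within_ref = min_within,
             mean_within_ref = sum_within / npairs,
             max_within_ref = max_within, evaluated = ok)
}

#' Call introgressed windows between a candidate and a reference species
#'
#' Non-overlapping windows (default 100 bp; a trailing remainder shorter than
#' the window is dropped) are scanned along the shared core-genome
#' concatenate. A window is called introgressed when the candidate is strictly
#' more similar to at least one reference genome than that reference's least
#' similar conspecific (`best_cand_identity > min_within_ref`), and the
#' candidate identity also reaches `threshold`. Windows with fewer than
#' `min_comparable` comparable columns in any required pair are skipped.
#'
#' @param shared a [shared_core_alignment()].
#' @param window window size in bp (default 100).
#' @param threshold percent-identity floor on the candidate identity
#'   (the stratification thresholds are 90, 95, 98, 100).
#' @param min_comparable minimum comparable columns per pair per window
#'   (default 50).
#' @return data frame of window calls with identities and the `introgressed`
#'   flag (only evaluated windows).
#' @export
scan_windows <- function(shared, window = 100, threshold = 90,
                         min_comparable = 50) {
  wi <- .window_identities(shared, window, min_comparable)
  wi$threshold <- threshold
  wi$introgressed <- wi$best_cand_identity > wi$min_within_ref &
    wi$best_cand_identity >= threshold
  wi[wi$evaluated, setdiff(names(wi), "evaluated")]
}

#' Introgression score from window calls
#'
#' Percent of evaluated windows called introgressed (the fraction of the
#' shared core genome exchanged between the species).
#'
#' @param calls data frame from [scan_windows()].
#' @return percent in [0, 100].
#' @export
introgression_score <- function(calls) {
  if (!nrow(calls)) stop("no evaluated windows: introgression score undefined")
  100 * mean(calls$introgressed)
}

#' Full introgression profile across identity thresholds
#'
#' Runs the window scan once and derives calls and the introgression score
#' S_i at each identity threshold (default 90/95/98/100, representing
#' increasingly recent introgression events), together with the
#' applicability check on p-distances of the shared alignment.
#'
#' @param shared a [shared_core_alignment()].
#' @param thresholds identity thresholds in percent.
#' @param window,min_comparable see [scan_windows()].
#' @return object of class `introgression_profile`: `windows` (per-window
#'   identities), `s_i` (named vector per threshold), `applicable`,
#'   `n_evaluated`.
#' @export
introgression_profile <- function(shared, thresholds = c(90, 95, 98, 100),
                                  window = 100, min_comparable = 50) {
  wi <- .window_identities(shared, window, min_comparable)
  ev <- wi[wi$evaluated, , drop = FALSE]
  if (!nrow(ev)) stop("no evaluated windows")
  s_i <- vapply(thresholds, function(th) {
    100 * mean(ev$best_cand_identity > ev$min_within_ref &
                 ev$best_cand_identity >= th)
  }, 0.0)
  names(s_i) <- paste0("t", thresholds)
  D <- .pairwise_p(shared)
  structure(list(windows = wi, s_i = s_i, thresholds = thresholds,
                 applicable = applicability_check(D, attr(shared, "candidate_id")),
                 n_evaluated = nrow(ev)),
            class = "introgression_profile")
}

#' @export
print.introgression_profile <- function(x, ...) {
  cat("introgression profile:", x$n_evaluated, "evaluated windows;",
      if (x$applicable) "applicable" else "NOT applicable (reference genome closer to candidate)", "\n")
  for (k in seq_along(x$thresholds))
    cat(sprintf("  S_i at >=%g%% identity: %.2f%%\n", x$thresholds[k], x$s_i[k]))
  invisible(x)
}

#' Write per-window introgression calls as BED-like TSV
#'
#' Concatenate coordinates, 0-based half-open.
#' @param calls data frame from [scan_windows()].
#' @param path output path.
#' @export
write_window_calls <- function(calls, path) {
  .write_tsv(calls[, c("start", "end", "introgressed", "best_cand_identity",
                       "min_within_ref", "threshold")], path)
}
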