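#' Scramble one aligned sequence
#'
#' Uniformly permutes the non-gap residues of an aligned row among the
#' non-gap positions, leaving the gap mask untouched, so both the residue
#' multiset and the per-column support of the alignment are preserved.
#' Draws from the current RNG stream; seed management belongs to the
#' caller (see [derive_threshold()]).
#'
#' @param row aligned sequence string.
#' @return The scrambled sequence string.
#' @export
scramble_sequence <- function(row) {
  ch <- strsplit(toupper(row), "", fixed = TRUE)[[1L]]
  ch[ch == "."] <- GAP
  nong <- which(ch != GAP)
  if (length(nong) > 1L)
    ch[nong] <- ch[nong][sample.int(length(nong))]
  paste(ch, collapse = "")
}

#' Derive the binding-call threshold from a scrambled-sequence null
#'
#' Every sequence of the alignment is scrambled `n_replicates` times (one
#' pass by default) and scored with the RFC matrix over all columns.  The
#' threshold is the mean of the scrambled scores plus `k` sample standard
#' deviations (`k = 3` by default), above which a real sequence is called
#' a likely PIP binder.
#'
#' @param rfc an `rfc_matrix`.
#' @param alignment an `rfc_alignment` of matching width.
#' @param k SD multiplier (>= 0 for a threshold above the null mean).
#' @param n_replicates scrambles per sequence.
#' @param seed integer seed; the scramble is fully reproducible from it and
#'   it is recorded in the result.
#' @param scramble_gaps if `TRUE`, permute across all positions including
#'   gaps (sensitivity analysis) instead of preserving the gap mask.
#' @return An `rfc_null`: list with `scores`, `mean`, `sd` (sample SD,
#'   n - 1 denominator), `k`, `threshold = mean + k * sd`, `seed`,
#'   `n_replicates`, `scramble_gaps`.
#' @export
derive_threshold <- function(rfc, alignment, k = 3, n_replicates = 1L, seed,
                             scramble_gaps = FALSE) {
  stopifnot(inherits(rfc, "rfc_matrix"), inherits(alignment, "rfc_alignment"))
  if (alignment$L != nrow(rfc$values))
    stop("alignment width ", alignment$L, " does not match matrix width ",
         nrow(rfc$values), call. = FALSE)
  n <- length(alignment$ids) * n_replicates
  if (n < 2L)
    stop("need at least 2 scrambled scores to estimate an SD (got ", n, ")",
         call. = FALSE)
  scores <- with_seed(seed, {
    rows <- rep(alignment$rows, times = n_replicates)
    scr <- vapply(rows, function(r) {
      if (scramble_gaps) {
        ch <- strsplit(r, "", fixed = TRUE)[[1L]]
        paste(ch[sample.int(length(ch))], collapse = "")
      } else scramble_sequence(r)
    }, character(1L), USE.NAMES = FALSE)
    M <- do.call(rbind, strsplit(scr, "", fixed = TRUE))
    row_scores(rfc, M)
  })
  m <- mean(scores)
  s <- sd(scores)
  structure(list(scores = scores, mean = m, sd = s, k = k,
                 threshold = m + k * s, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 scramble_gaps = scramble_gaps),
            class = "rfc_null")
}

#' @export
print.rfc_null <- function(x, ...) {
  cat(sprintf(paste0("Scrambled-sequence null: %d scores, mean %.4f, ",
                     "sd %.4f\n  threshold (mean + %g x SD) = %.4f  ",
                     "[seed %d, %d replicate(s)]\n"),
              length(x$scores), x$mean, x$sd, x$k, x$threshold,
              x$seed, x$n_replicates))
  invisible(x)
}

#' Call binders from S_RFC scores at a threshold
#'
#' A sequence is called `PREDICTED_BINDER` iff its score is strictly
#' greater than the threshold; a score exactly at the threshold is a
#' non-binder call.
#'
#' @param scores an `rfc_scores` frame from [score_all()], or a named
#'   numeric vector of S_RFC scores.
#' @param threshold numeric cutoff, typically `rfc_null$threshold`.
#' @return Data frame with columns `id`, `s_rfc`, `call`.
#' @export
classify <- function(scores, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (inherits(scores, "rfc_scores")) {
    id <- scores$id; s <- scores$s_rfc
  } else {
    if (is.null(names(scores)))
      stop("scores must be an rfc_scores frame or a named numeric vector",
           call. = FALSE)
    id <- names(scores); s <- as.numeric(scores)
  }
  data.frame(id = id, s_rfc = s,
             call = ifelse(s > threshold, "PREDICTED_BINDER",
                           "PREDICTED_NONBINDER"),
             stringsAsFactors = FALSE)
}
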