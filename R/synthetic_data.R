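#' Specify a synthetic labelled PH-domain-like alignment
#'
#' Defines the generative model for [simulate_alignment()]: fixed-width
#' aligned sequences over the 20 standard amino acids, drawn
#' column-independently from a background distribution, with two labelled
#' groups whose distributions differ only at a chosen set of
#' "determinant" columns.  At a determinant column the binder group mixes
#' the background with probability mass `effect` placed on a
#' column-specific preferred residue; with `contrast = "both"` the
#' non-binder group is likewise enriched for its own (different) preferred
#' residue, mimicking positions that penalize binding.  Each position is
#' independently gapped with probability `gap_rate`.
#'
#' `effect = 0` makes the two groups generatively identical at every
#' column (the null model).
#'
#' @param n_binders,n_nonbinders sequences per group.
#' @param L alignment width in columns.
#' @param determinant_columns integer column indices (1-based) carrying
#'   the planted group difference.
#' @param effect probability mass in `[0, 1]` moved onto the preferred
#'   residue at determinant columns.
#' @param background length-20 probability vector over `ACDEFGHIKLMNPQRSTVWY`
#'   (default uniform).
#' @param gap_rate i.i.d. per-position gap probability in `[0, 1)`.
#' @param seed integer seed; generation is byte-reproducible from the spec.
#' @param contrast `"binder"` (default: only the binder group is enriched)
#'   or `"both"` (opposing preferred residues in the two groups).
#' @return An `rfc_synth_spec` list.
#' @export
synthetic_spec <- function(n_binders, n_nonbinders, L,
                           determinant_columns = integer(0), effect = 0,
                           background = NULL, gap_rate = 0, seed,
                           contrast = c("binder", "both")) {
  contrast <- match.arg(contrast)
  if (n_binders < 1L || n_nonbinders < 1L)
    stop("both groups need at least one sequence", call. = FALSE)
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  determinant_columns <- sort(unique(as.integer(determinant_columns)))
  if (length(determinant_columns) &&
      (min(determinant_columns) < 1L || max(determinant_columns) > L))
    stop("determinant_columns outside [1, L]", call. = FALSE)
  if (effect < 0 || effect > 1) stop("effect must be in [0, 1]", call. = FALSE)
  if (gap_rate < 0 || gap_rate >= 1)
    stop("gap_rate must be in [0, 1)", call. = FALSE)
  if (is.null(background)) background <- rep(1 / 20, 20L)
  if (length(background) != 20L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must be a length-20 probability vector", call. = FALSE)
  structure(list(n_binders = as.integer(n_binders),
                 n_nonbinders = as.integer(n_nonbinders), L = as.integer(L),
                 determinant_columns = determinant_columns,
                 effect = effect, background = as.numeric(background),
                 gap_rate = gap_rate, seed = as.integer(seed),
                 contrast = contrast),
            class = "rfc_synth_spec")
}

#' Empirical residue background of an alignment
#'
#' Overall non-gap residue frequencies, usable as the `background` of a
#' [synthetic_spec()] for more realistic simulations.
#'
#' @param alignment an `rfc_alignment`.
#' @return Length-20 named probability vector.
#' @export
empirical_background <- function(alignment) {
  M <- aln_matrix(alignment)
  counts <- tabulate(match(M, AA20), nbins = 20L)
  if (sum(counts) == 0L) stop("alignment is all gaps", call. = FALSE)
  setNames(counts / sum(counts), AA20)
}

#' Generate a labelled synthetic alignment with planted determinants
#'
#' Draws sequences under the model of [synthetic_spec()].  The returned
#' `truth` records the planted determinant columns and per-column
#' preferred residues; pass it back via the `truth` argument to generate
#' held-out sequences from the *same* ground truth under a different seed
#' (the spec's own seed still drives all sampling).
#'
#' @param spec an `rfc_synth_spec`.
#' @param truth optional truth from a previous call with the same `L`,
#'   determinant columns and contrast mode; if `NULL`, preferred residues
#'   are drawn from the spec's seed.
#' @return List with `alignment` (`rfc_alignment`, ids `b001...`/`n001...`),
#'   `labels` (`rfc_labels`) and `truth` (list: `determinant_columns`,
#'   `preferred` data frame, `spec`).
#' @export
simulate_alignment <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "rfc_synth_spec"))
  det <- spec$determinant_columns
  with_seed(spec$seed, {
    if (is.null(truth)) {
      pref_b <- if (length(det)) sample(AA20, length(det), replace = TRUE)
                else character(0)
      pref_n <- rep(NA_character_, length(det))
      if (spec$contrast == "both" && length(det))
        pref_n <- vapply(pref_b,
                         function(a) sample(setdiff(AA20, a), 1L),
                         character(1L), USE.NAMES = FALSE)
      preferred <- data.frame(column = det, binder = pref_b,
                              nonbinder = pref_n, stringsAsFactors = FALSE)
    } else {
      preferred <- truth$preferred
      if (!identical(preferred$column, det))
        stop("supplied truth does not match the spec's determinant columns",
             call. = FALSE)
    }

    draw_group <- function(n, group) {
      M <- matrix("", n, spec$L)
      for (j in seq_len(spec$L)) {
        p <- spec$background
        k <- match(j, preferred$column)
        if (!is.na(k)) {
          pref <- if (group == "BINDER") preferred$binder[k]
                  else preferred$nonbinder[k]
          if (!is.na(pref)) {
            p <- (1 - spec$effect) * p
            a <- match(pref, AA20)
            p[a] <- p[a] + spec$effect
          }
        }
        M[, j] <- sample(AA20, n, replace = TRUE, prob = p)
      }
      if (spec$gap_rate > 0)
        M[matrix(runif(n * spec$L) < spec$gap_rate, n, spec$L)] <- GAP
      M
    }

    Mb <- draw_group(spec$n_binders, "BINDER")
    Mn <- draw_group(spec$n_nonbinders, "NONBINDER")
    ids <- c(sprintf("b%03d", seq_len(spec$n_binders)),
             sprintf("n%03d", seq_len(spec$n_nonbinders)))
    rows <- apply(rbind(Mb, Mn), 1L, paste, collapse = "")
    alignment <- multiple_alignment(rows, ids = ids)
    labels <- label_table(ids, c(rep("BINDER", spec$n_binders),
                                 rep("NONBINDER", spec$n_nonbinders)),
                          alignment = alignment)
    list(alignment = alignment, labels = labels,
         truth = list(determinant_columns = det, preferred = preferred,
                      spec = spec))
  })
}

#' Label-stratified train/test split
#'
#' @param alignment an `rfc_alignment`.
#' @param labels an `rfc_labels` table over the alignment ids.
#' @param fraction training fraction in `(0, 1)`; per group,
#'   `round(fraction * n)` sequences go to the training side.
#' @param seed integer seed; the split is reproducible.
#' @return List of two lists `train` and `test`, each with `alignment` and
#'   `labels`.  Errors if either side would lose a whole label group.
#' @export
split_alignment <- function(alignment, labels, fraction, seed) {
  stopifnot(inherits(alignment, "rfc_alignment"),
            inherits(labels, "rfc_labels"))
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  with_seed(seed, {
    train_ids <- character(0)
    for (g in c("BINDER", "NONBINDER")) {
      ids <- labels$id[labels$label == g]
      n_train <- round(fraction * length(ids))
      if (n_train < 1L || n_train >= length(ids))
        stop("stratified split leaves group '", g,
             "' empty on one side (", n_train, " of ", length(ids),
             " in train)", call. = FALSE)
      train_ids <- c(train_ids, sample(ids, n_train))
    }
    take <- function(keep) {
      idx <- which(alignment$ids %in% keep)
      aln <- multiple_alignment(alignment$rows[idx],
                                ids = alignment$ids[idx])
      lab <- labels[labels$id %in% keep, , drop = FALSE]
      lab <- label_table(lab$id, lab$label, alignment = aln)
      list(alignment = aln, labels = lab)
    }
    list(train = take(train_ids),
         test = take(setdiff(alignment$ids, train_ids)))
  })
}
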