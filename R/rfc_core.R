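#' Build a per-group position x amino-acid probability matrix
#'
#' For one label group, counts each of the 20 standard amino acids at each
#' alignment column and converts counts to frequencies.  The default
#' denominator is the number of non-gap residues the group shows at that
#' column, so columns containing gaps still normalize to 1; the alternative
#' `"group-size"` divides by the number of sequences in the group
#' regardless of gaps.
#'
#' @param alignment an `rfc_alignment`.
#' @param labels an `rfc_labels` table over the alignment ids.
#' @param group `"BINDER"` or `"NONBINDER"`.
#' @param denominator `"nongap"` (default) or `"group-size"`.
#' @return An `rfc_prob_matrix`: list with `values` (L x 20 frequency
#'   matrix, columns in the fixed order `ACDEFGHIKLMNPQRSTVWY`), `counts`
#'   (L x 20 integer counts), `denom` (per-column denominator used),
#'   `column_support` (per-column non-gap count), `group`, `n_sequences`
#'   and `denominator`.
#' @export
build_probability_matrix <- function(alignment, labels,
                                     group = c("BINDER", "NONBINDER"),
                                     denominator = c("nongap", "group-size")) {
  stopifnot(inherits(alignment, "rfc_alignment"),
            inherits(labels, "rfc_labels"))
  group <- match.arg(group)
  denominator <- match.arg(denominator)
  ids <- labels$id[labels$label == group]
  if (length(ids) == 0L)
    stop("label group '", group, "' is empty", call. = FALSE)
  missing <- setdiff(ids, alignment$ids)
  if (length(missing))
    stop("labelled id(s) absent from alignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  M <- aln_matrix(alignment)[ids, , drop = FALSE]
  L <- alignment$L
  counts <- matrix(0L, nrow = L, ncol = 20L,
                   dimnames = list(NULL, AA20))
  for (j in seq_len(L))
    counts[j, ] <- tabulate(match(M[, j], AA20), nbins = 20L)
  support <- as.integer(rowSums(counts))
  denom <- if (denominator == "nongap") support else rep(nrow(M), L)
  values <- counts / ifelse(denom == 0L, 1L, denom)  # all-gap column -> zeros
  structure(list(values = values, counts = counts,
                 denom = as.integer(denom), column_support = support,
                 group = group, n_sequences = nrow(M),
                 denominator = denominator),
            class = "rfc_prob_matrix")
}

#' @export
print.rfc_prob_matrix <- function(x, ...) {
  cat("Group probability matrix (", x$group, "): ", nrow(x$values),
      " columns x 20 amino acids, ", x$n_sequences, " sequences, ",
      "denominator = ", x$denominator, "\n", sep = "")
  invisible(x)
}

#' Combine two group probability matrices into the RFC log-ratio matrix
#'
#' Entrywise `log(P^B / P^NB)` of the binder over the non-binder
#' probability matrix.  The ratio is undefined where either group has
#' frequency zero; two policies are provided:
#' \describe{
#'   \item{`"zero-out"` (default)}{the entry is set to 0 wherever either
#'     frequency is 0, treating group-absent residues as uninformative and
#'     keeping every score finite.  A query residue unseen in both groups
#'     therefore contributes 0 to its sequence score.}
#'   \item{`"pseudocount"`}{`pseudocount` (default 0.5) is added to every
#'     count and `20 * pseudocount` to every denominator before forming
#'     frequencies, making all entries finite.}
#' }
#'
#' @param pb,pnb `rfc_prob_matrix` objects for the BINDER and NONBINDER
#'   group, same alignment width.
#' @param zero_policy `"zero-out"` or `"pseudocount"`.
#' @param log_base `"natural"` (default) or `"10"`.
#' @param pseudocount additive count used under the pseudocount policy.
#' @return An `rfc_matrix`: list with `values` (L x 20), `log_base`,
#'   `zero_policy`, `pseudocount` and `provenance` (group sizes).
#' @export
build_rfc_matrix <- function(pb, pnb,
                             zero_policy = c("zero-out", "pseudocount"),
                             log_base = c("natural", "10"),
                             pseudocount = 0.5) {
  stopifnot(inherits(pb, "rfc_prob_matrix"), inherits(pnb, "rfc_prob_matrix"))
  zero_policy <- match.arg(zero_policy)
  log_base <- match.arg(log_base)
  if (!identical(dim(pb$values), dim(pnb$values)))
    stop("probability matrices have different shapes: ",
         nrow(pb$values), "x20 vs ", nrow(pnb$values), "x20", call. = FALSE)
  if (pb$group != "BINDER" || pnb$group != "NONBINDER")
    stop("expected pb from the BINDER group and pnb from the NONBINDER group",
         call. = FALSE)
  if (zero_policy == "zero-out") {
    ok <- pb$values > 0 & pnb$values > 0
    v <- matrix(0, nrow = nrow(pb$values), ncol = 20L,
                dimnames = dimnames(pb$values))
    v[ok] <- log(pb$values[ok] / pnb$values[ok])
  } else {
    eps <- pseudocount
    fb <- (pb$counts + eps) / (pb$denom + 20 * eps)
    fnb <- (pnb$counts + eps) / (pnb$denom + 20 * eps)
    v <- log(fb / fnb)
    dimnames(v) <- dimnames(pb$values)
  }
  if (log_base == "10") v <- v / log(10)
  structure(list(values = v, log_base = log_base, zero_policy = zero_policy,
                 pseudocount = if (zero_policy == "pseudocount") pseudocount else NA_real_,
                 provenance = list(n_binders = pb$n_sequences,
                                   n_nonbinders = pnb$n_sequences,
                                   denominator = pb$denominator)),
            class = "rfc_matrix")
}

#' @export
print.rfc_matrix <- function(x, ...) {
  cat("RFC log-ratio matrix: ", nrow(x$values), " columns x 20 amino acids",
      " (log base ", if (x$log_base == "natural") "e" else "10",
      ", ", x$zero_policy, " policy; ", x$provenance$n_binders, " binders vs ",
      x$provenance$n_nonbinders, " non-binders)\n", sep = "")
  invisible(x)
}

#' Fit the RFC matrix directly from a labelled alignment
#'
#' Convenience wrapper: builds both group probability matrices and combines
#' them with [build_rfc_matrix()].
#'
#' @inheritParams build_probability_matrix
#' @inheritParams build_rfc_matrix
#' @return An `rfc_matrix`.
#' @examples
#' sim <- simulate_alignment(synthetic_spec(10, 10, L = 40,
#'   determinant_columns = c(5, 9), effect = 0.8, seed = 1))
#' rfc <- build_rfc(sim$alignment, sim$labels)
#' @export
build_rfc <- function(alignment, labels,
                      zero_policy = c("zero-out", "pseudocount"),
                      log_base = c("natural", "10"),
                      denominator = c("nongap", "group-size"),
                      pseudocount = 0.5) {
  pb <- build_probability_matrix(alignment, labels, "BINDER",
                                 denominator = denominator)
  pnb <- build_probability_matrix(alignment, labels, "NONBINDER",
                                  denominator = denominator)
  build_rfc_matrix(pb, pnb, zero_policy = zero_policy, log_base = log_base,
                   pseudocount = pseudocount)
}

# vectorized scorer shared by score_sequence / score_all / derive_threshold:
# M is an n x L single-character matrix; returns per-row sums of matrix
# entries at (column, residue), gaps contributing 0
row_scores <- function(rfc, M, columns = NULL) {
  L <- nrow(rfc$values)
  if (ncol(M) != L)
    stop("sequence length ", ncol(M), " does not match matrix width ", L,
         call. = FALSE)
  cols <- if (is.null(columns)) seq_len(L) else as.integer(columns)
  if (length(cols) && (min(cols) < 1L || max(cols) > L))
    stop("column subset out of range [1, ", L, "]", call. = FALSE)
  if (length(cols) == 0L) return(rep(0, nrow(M)))
  A <- match(M[, cols, drop = FALSE], AA20)       # NA at gaps
  dim(A) <- c(nrow(M), length(cols))
  contrib <- matrix(0, nrow(M), length(cols))
  nz <- which(!is.na(A), arr.ind = TRUE)
  if (nrow(nz))
    contrib[nz] <- rfc$values[cbind(cols[nz[, 2L]], A[nz])]
  rowSums(contrib)
}

#' Score one aligned sequence against an RFC matrix
#'
#' `S_RFC` is the sum over (selected) alignment columns of the RFC-matrix
#' entry matching the sequence's residue at that column; gap positions
#' contribute 0.
#'
#' @param rfc an `rfc_matrix`.
#' @param row aligned sequence string of the matrix's width.
#' @param columns optional integer subset of columns (1-based) to restrict
#'   the sum to, e.g. one loop region.
#' @return A single numeric score.
#' @export
score_sequence <- function(rfc, row, columns = NULL) {
  stopifnot(inherits(rfc, "rfc_matrix"))
  aln <- multiple_alignment(row, ids = "query")
  row_scores(rfc, aln_matrix(aln), columns = columns)[[1L]]
}

#' Score every sequence of an alignment, optionally per region
#'
#' @param rfc an `rfc_matrix`.
#' @param alignment an `rfc_alignment` of the matrix's width.
#' @param regions optional `rfc_regions` map (or named list of column
#'   vectors); one score component per region is added.  When the regions
#'   partition all columns the components sum to the full score.
#' @param complement add the complement of the region union as a region
#'   (see [region_columns()]); default `TRUE` so a loop-only map yields a
#'   full partition.
#' @return An `rfc_scores` data frame: `id`, `s_rfc`, then one column per
#'   region.
#' @export
score_all <- function(rfc, alignment, regions = NULL, complement = TRUE) {
  stopifnot(inherits(rfc, "rfc_matrix"), inherits(alignment, "rfc_alignment"))
  M <- aln_matrix(alignment)
  out <- data.frame(id = alignment$ids, s_rfc = row_scores(rfc, M),
                    stringsAsFactors = FALSE)
  region_names <- character(0)
  if (!is.null(regions)) {
    cols <- if (inherits(regions, "rfc_regions"))
      region_columns(regions, complement = complement)
    else regions
    for (nm in names(cols))
      out[[nm]] <- row_scores(rfc, M, columns = cols[[nm]])
    region_names <- names(cols)
  }
  structure(out, region_names = region_names,
            class = c("rfc_scores", "data.frame"))
}

#' Relative contribution of each region to a sequence's score
#'
#' For each sequence, each region component divided by the sum of all
#' components.  When the component sum is exactly zero the fractions are
#' undefined and reported as `NA`.
#'
#' @param scores an `rfc_scores` frame carrying region components
#'   (from [score_all()] with `regions`).
#' @return Data frame `id` plus one fraction column per region.
#' @export
region_fractions <- function(scores) {
  stopifnot(inherits(scores, "rfc_scores"))
  rn <- attr(scores, "region_names")
  if (length(rn) == 0L)
    stop("scores carry no region components; run score_all() with regions",
         call. = FALSE)
  comp <- as.matrix(scores[, rn, drop = FALSE])
  total <- rowSums(comp)
  frac <- comp / total
  frac[total == 0, ] <- NA_real_
  out <- data.frame(id = scores$id, frac, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-column contribution profile of an RFC matrix
#'
#' The contribution of alignment column `j` is the mean of the squared
#' RFC-matrix entries across the 20 amino acids,
#' `c_j = (1/20) * sum_a rfc[j, a]^2`.  Columns are ranked by decreasing
#' contribution, ties broken by lower column index.
#'
#' @param rfc an `rfc_matrix`.
#' @param n_top how many leading positions to report in `top_positions`
#'   (default 12, the conventional number of marked determinant
#'   candidates); the full ranking is always in `ranking`.
#' @return An `rfc_contributions` list: `contribution` (length-L numeric),
#'   `ranking` (all columns, best first), `top_positions` (first `n_top`).
#' @export
position_contributions <- function(rfc, n_top = 12L) {
  stopifnot(inherits(rfc, "rfc_matrix"))
  cj <- rowMeans(rfc$values^2)
  ranking <- order(-cj, seq_along(cj))
  structure(list(contribution = cj, ranking = ranking,
                 top_positions = head(ranking, n_top)),
            class = "rfc_contributions")
}

#' @export
print.rfc_contributions <- function(x, ...) {
  cat("Position contribution profile over", length(x$contribution),
      "columns\n  top positions:", paste(x$top_positions, collapse = ", "),
      "\n")
  invisible(x)
}

#' Write / read an RFC matrix as headered TSV
#'
#' The TSV has a `column` index column followed by the 20 amino-acid
#' columns in fixed order; a JSON sidecar (`<path>.json`) records log base,
#' zero policy and group sizes so a matrix re-read with [read_rfc_matrix()]
#' scores identically.
#'
#' @param rfc an `rfc_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_rfc_matrix <- function(rfc, path) {
  stopifnot(inherits(rfc, "rfc_matrix"))
  d <- data.frame(column = seq_len(nrow(rfc$values)), rfc$values,
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(log_base = rfc$log_base, zero_policy = rfc$zero_policy,
               pseudocount = rfc$pseudocount, provenance = rfc$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_rfc_matrix
#' @export
read_rfc_matrix <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  stopifnot(identical(names(d)[1], "column"), all(AA20 %in% names(d)))
  v <- as.matrix(d[, AA20])
  dimnames(v) <- list(NULL, AA20)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
  else list(log_base = "natural", zero_policy = "zero-out",
            pseudocount = NA, provenance = list())
  structure(list(values = v, log_base = meta$log_base,
                 zero_policy = meta$zero_policy,
                 pseudocount = if (is.null(meta$pseudocount)) NA_real_
                               else as.numeric(meta$pseudocount),
                 provenance = meta$provenance),
            class = "rfc_matrix")
}
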