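#' Read an assay outcome table from TSV
#'
#' Expects a headered TSV (`#` comments allowed) with columns `id` and
#' `outcome`, outcome values in `BINDS`, `DOES_NOT_BIND`, `PROMISCUOUS`
#' (bound vesicles nonspecifically, including the lipid-free control) or
#' `EXCLUDED` (case insensitive).  Optional extra columns are kept, e.g. a
#' `pips_bound` detail column or a `predicted` column carrying the model
#' call the assay was validating.
#'
#' @param path TSV file path.
#' @return An `rfc_outcomes` data frame.
#' @export
read_outcomes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("id", "outcome") %in% names(d)))
    stop("outcome table must have columns 'id' and 'outcome'", call. = FALSE)
  outcome_table(d)
}

#' @rdname read_outcomes
#' @param d data frame with at least `id` and `outcome` columns.
#' @export
outcome_table <- function(d) {
  vocab <- c("BINDS", "DOES_NOT_BIND", "PROMISCUOUS", "EXCLUDED")
  d$id <- as.character(d$id)
  d$outcome <- toupper(trimws(d$outcome))
  if (anyDuplicated(d$id))
    stop("duplicate id(s) in outcome table: ",
         paste(unique(d$id[duplicated(d$id)]), collapse = ", "),
         call. = FALSE)
  bad <- which(!(d$outcome %in% vocab))
  if (length(bad))
    stop("unknown outcome '", d$outcome[bad[1L]], "' for id '",
         d$id[bad[1L]], "' (expected ", paste(vocab, collapse = "/"), ")",
         call. = FALSE)
  structure(d, class = c("rfc_outcomes", "data.frame"))
}

#' Confusion matrix and accuracy metrics for binding predictions
#'
#' Crosses predicted binder / non-binder calls with binary assay outcomes.
#' Ids with `PROMISCUOUS` or `EXCLUDED` outcomes are skipped (their count
#' is reported); every remaining predicted id must carry a `BINDS` or
#' `DOES_NOT_BIND` outcome.  Metrics with an undefined denominator (e.g.
#' precision with no predicted binders) are reported as `NA`, never as 0.
#'
#' @param predictions data frame from [classify()] (columns `id`, `call`)
#'   or a named character vector of calls (`PREDICTED_BINDER` /
#'   `PREDICTED_NONBINDER`; `binder`/`nonbinder` accepted).
#' @param outcomes an `rfc_outcomes` table.
#' @return An `rfc_evaluation`: list with `tp`, `fp`, `fn`, `tn`,
#'   `n_excluded`, `accuracy`, `precision`, `recall`, `f1`.
#' @examples
#' val <- read_outcomes(system.file("extdata", "fig7_validation.tsv",
#'                                  package = "rfcph"))
#' confusion(setNames(val$predicted, val$id), val)
#' @export
confusion <- function(predictions, outcomes) {
  stopifnot(inherits(outcomes, "rfc_outcomes"))
  if (is.data.frame(predictions)) {
    pred <- setNames(predictions$call, predictions$id)
  } else {
    pred <- predictions
    if (is.null(names(pred)))
      stop("predictions must be named by sequence id", call. = FALSE)
  }
  p <- toupper(trimws(as.character(pred)))
  p[p %in% c("PREDICTED_BINDER", "BINDER", "1")] <- "B"
  p[p %in% c("PREDICTED_NONBINDER", "NONBINDER", "0")] <- "N"
  bad <- which(!(p %in% c("B", "N")))
  if (length(bad))
    stop("unrecognized prediction '", pred[bad[1L]], "' for id '",
         names(pred)[bad[1L]], "'", call. = FALSE)
  oc <- setNames(outcomes$outcome, outcomes$id)
  missing <- setdiff(names(pred), names(oc))
  if (length(missing))
    stop("predicted id(s) with no assay outcome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  oc <- oc[names(pred)]
  skip <- oc %in% c("PROMISCUOUS", "EXCLUDED")
  n_excluded <- sum(skip)
  p <- p[!skip]; oc <- oc[!skip]
  if (length(p) == 0L)
    stop("no evaluable ids (all outcomes promiscuous/excluded)",
         call. = FALSE)
  tp <- sum(p == "B" & oc == "BINDS")
  fp <- sum(p == "B" & oc == "DOES_NOT_BIND")
  fn <- sum(p == "N" & oc == "BINDS")
  tn <- sum(p == "N" & oc == "DOES_NOT_BIND")
  total <- tp + fp + fn + tn
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 n_excluded = n_excluded,
                 accuracy = safe_div(tp + tn, total),
                 precision = precision, recall = recall, f1 = f1),
            class = "rfc_evaluation")
}

#' @export
print.rfc_evaluation <- function(x, ...) {
  cat("Confusion matrix (", x$tp + x$fp + x$fn + x$tn, " evaluated, ",
      x$n_excluded, " skipped):\n", sep = "")
  cat(sprintf("  TP %d  FP %d\n  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat("  Accuracy ", fmt(x$accuracy), "  Precision ", fmt(x$precision),
      "  Recall ", fmt(x$recall), "  F1 ", fmt(x$f1), "\n", sep = "")
  invisible(x)
}

#' Fraction of assayed proteins that bound a PIP specifically
#'
#' Counts `BINDS` outcomes over all assayed entries (`BINDS`,
#' `DOES_NOT_BIND` and `PROMISCUOUS`; `EXCLUDED` rows drop out of the
#' denominator too).  Promiscuous vesicle binders are in the denominator
#' but not the numerator: they were assayed, but did not bind PIPs with
#' specificity.
#'
#' @param outcomes an `rfc_outcomes` table.
#' @return List with `count`, `total` and `percent` (rounded to the
#'   nearest integer, half away from zero).
#' @export
binder_fraction <- function(outcomes) {
  stopifnot(inherits(outcomes, "rfc_outcomes"))
  count <- sum(outcomes$outcome == "BINDS")
  total <- sum(outcomes$outcome %in%
                 c("BINDS", "DOES_NOT_BIND", "PROMISCUOUS"))
  if (total == 0L)
    stop("no assayed entries in outcome table", call. = FALSE)
  list(count = count, total = total,
       percent = round_half_up(100 * count / total))
}

#' Project the overall binder percentage of a domain family
#'
#' Combines experimentally confirmed positives with model-predicted
#' positives over the whole family:
#' `100 * (assay_positive + predicted_positive) / total_domains`, rounded
#' to the nearest integer (half away from zero).
#'
#' @param assay_positive number of assayed domains that bound.
#' @param predicted_positive number of unassayed domains scoring above the
#'   threshold.
#' @param total_domains family size.
#' @return Integer percentage.
#' @examples
#' combined_projection(36, 86, 242)  # 50
#' @export
combined_projection <- function(assay_positive, predicted_positive,
                                total_domains) {
  stopifnot(assay_positive >= 0, predicted_positive >= 0)
  if (total_domains == 0)
    stop("total_domains must be positive", call. = FALSE)
  if (assay_positive + predicted_positive > total_domains)
    stop("positive counts exceed total_domains", call. = FALSE)
  round_half_up(100 * (assay_positive + predicted_positive) / total_domains)
}
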