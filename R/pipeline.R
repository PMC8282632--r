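#' Run the full RFC analysis and write all stage outputs
#'
#' Chains the pipeline stages -- group probability matrices, RFC log-ratio
#' matrix, S_RFC scores (training and optional query alignment),
#' scrambled-sequence threshold, binary calls and (when assay outcomes are
#' supplied) confusion-matrix evaluation -- and writes every stage output
#' plus a JSON run manifest into `out_dir`.  Every policy field has a
#' recorded value in the manifest; there are no silent defaults.
#'
#' Files written: `rfc_matrix.tsv` (+ `.json` sidecar), `scores.tsv`,
#' `contributions.tsv`, `null.json`, `predictions.tsv`, optionally
#' `evaluation.json`, and `manifest.json`.
#'
#' @param alignment training `rfc_alignment`.
#' @param labels `rfc_labels` over the training alignment.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed driving the scramble null.
#' @param regions optional `rfc_regions`; adds per-region score columns.
#' @param query optional `rfc_alignment` of additional sequences to score
#'   and classify (same width); the threshold always comes from scrambling
#'   the combined training + query sequences, mirroring a family-wide
#'   null.
#' @param outcomes optional `rfc_outcomes` for the classified sequences.
#' @inheritParams build_rfc
#' @inheritParams derive_threshold
#' @param include_null_scores store the individual scrambled scores in
#'   `null.json` (they are always used for mean/SD).
#' @param verbose log group sizes, all-gap columns and zeroed-entry
#'   fraction via `message()`.
#' @return Invisibly, a list with `rfc`, `scores`, `null`, `predictions`,
#'   `contributions`, `evaluation` (or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(alignment, labels, out_dir, seed,
                         regions = NULL, query = NULL, outcomes = NULL,
                         zero_policy = c("zero-out", "pseudocount"),
                         log_base = c("natural", "10"),
                         denominator = c("nongap", "group-size"),
                         pseudocount = 0.5, k = 3, n_replicates = 1L,
                         scramble_gaps = FALSE,
                         include_null_scores = FALSE, verbose = TRUE) {
  zero_policy <- match.arg(zero_policy)
  log_base <- match.arg(log_base)
  denominator <- match.arg(denominator)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  rfc <- stage("build", {
    nb <- sum(labels$label == "BINDER")
    nn <- sum(labels$label == "NONBINDER")
    say("build: ", nb, " binders vs ", nn, " non-binders over ",
        alignment$L, " columns")
    r <- build_rfc(alignment, labels, zero_policy = zero_policy,
                   log_base = log_base, denominator = denominator,
                   pseudocount = pseudocount)
    allgap <- sum(rowSums(abs(r$values)) == 0 &
                    colSums(aln_matrix(alignment) != GAP) == 0)
    if (allgap > 0) say("build: ", allgap, " all-gap column(s)")
    zfrac <- mean(r$values == 0)
    if (zero_policy == "zero-out" && zfrac > 0.2)
      say(sprintf("build: %.0f%% of matrix entries are zero under the %s policy",
                  100 * zfrac, zero_policy))
    r
  })

  target <- if (is.null(query)) alignment else query
  scores <- stage("score", score_all(rfc, target, regions = regions))

  null <- stage("threshold", {
    pool <- if (is.null(query)) alignment else
      multiple_alignment(c(alignment$rows, query$rows),
                         ids = c(alignment$ids, query$ids))
    derive_threshold(rfc, pool, k = k, n_replicates = n_replicates,
                     seed = seed, scramble_gaps = scramble_gaps)
  })
  say(sprintf("threshold: mean %.4f + %g x SD %.4f = %.4f",
              null$mean, k, null$sd, null$threshold))

  predictions <- stage("classify", classify(scores, null$threshold))
  contributions <- stage("contributions", position_contributions(rfc))

  evaluation <- NULL
  if (!is.null(outcomes)) {
    evaluation <- stage("evaluate", confusion(predictions, outcomes))
    if (evaluation$n_excluded > 0)
      say("evaluate: skipped ", evaluation$n_excluded,
          " promiscuous/excluded id(s)")
  }

  # --- write stage outputs -------------------------------------------------
  p <- function(f) file.path(out_dir, f)
  write_rfc_matrix(rfc, p("rfc_matrix.tsv"))
  write.table(as.data.frame(scores), p("scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(column = seq_along(contributions$contribution),
                         contribution = contributions$contribution),
              p("contributions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  null_out <- null[c("mean", "sd", "k", "threshold", "seed", "n_replicates",
                     "scramble_gaps")]
  null_out$n_scores <- length(null$scores)
  if (include_null_scores) null_out$scores <- null$scores
  jsonlite::write_json(null_out, p("null.json"), auto_unbox = TRUE,
                       digits = NA)
  pred_out <- predictions
  write.table(pred_out, p("predictions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(evaluation))
    jsonlite::write_json(unclass(evaluation), p("evaluation.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")

  manifest <- list(
    package = "rfcph",
    version = as.character(utils::packageVersion("rfcph")),
    config = list(zero_policy = zero_policy, log_base = log_base,
                  denominator = denominator, pseudocount = pseudocount,
                  k = k, n_replicates = n_replicates,
                  scramble_gaps = scramble_gaps, seed = as.integer(seed),
                  percent_rounding = "half-away-from-zero"),
    inputs = list(
      n_sequences = length(alignment$ids), L = alignment$L,
      n_binders = sum(labels$label == "BINDER"),
      n_nonbinders = sum(labels$label == "NONBINDER"),
      n_query = if (is.null(query)) 0L else length(query$ids),
      regions = if (is.null(regions)) NULL else
        as.data.frame(regions)),
    results = list(
      matrix_shape = c(nrow(rfc$values), 20L),
      threshold = null$threshold, null_mean = null$mean, null_sd = null$sd,
      n_predicted_binders = sum(predictions$call == "PREDICTED_BINDER"),
      n_classified = nrow(predictions),
      top_positions = contributions$top_positions,
      evaluation = if (is.null(evaluation)) NULL else unclass(evaluation)),
    output_digests = local({
      files <- setdiff(list.files(out_dir, pattern = "\\.(tsv|json)$"),
                       "manifest.json")
      setNames(as.list(unname(tools::md5sum(file.path(out_dir, files)))),
               files)
    })
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null")

  invisible(list(rfc = rfc, scores = scores, null = null,
                 predictions = predictions, contributions = contributions,
                 evaluation = evaluation, manifest = manifest))
}
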