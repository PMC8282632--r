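# small builders shared across test files

mk_aln <- function(rows, ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(rows))
  multiple_alignment(rows, ids = ids)
}

mk_labels <- function(aln, n_binders) {
  n <- length(aln$ids)
  label_table(aln$ids, c(rep("binder", n_binders),
                         rep("nonbinder", n - n_binders)),
              alignment = aln)
}

# binary ground-truth outcome table from synthetic labels
truth_outcomes <- function(labels) {
  outcome_table(data.frame(
    id = labels$id,
    outcome = ifelse(labels$label == "BINDER", "BINDS", "DOES_NOT_BIND"),
    stringsAsFactors = FALSE))
}

# random small alignment + labels over the full alphabet, gaps included
random_instance <- function(n = 6, L = 8, gap_rate = 0.15) {
  alpha <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  rows <- vapply(seq_len(n), function(i) {
    ch <- sample(alpha, L, replace = TRUE)
    ch[runif(L) < gap_rate] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  aln <- mk_aln(rows)
  list(alignment = aln, labels = mk_labels(aln, max(1, floor(n / 2))))
}

extdata <- function(f) system.file("extdata", f, package = "rfcph")
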