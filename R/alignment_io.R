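#' Construct a validated multiple alignment
#'
#' The pipeline's central container: an ordered set of equal-length aligned
#' rows over the 20 standard amino acids plus the gap character `-`.
#' Residues are upper-cased and `.` gaps are normalized to `-` on
#' construction.  Nonstandard residue codes (B, J, O, U, X, Z) are rejected
#' unless `mask_nonstandard = TRUE`, which converts them to gaps -- the
#' scoring matrices are strictly 20 amino acids wide.
#'
#' @param rows character vector of aligned sequences (equal length).
#' @param ids unique sequence identifiers; defaults to `names(rows)`.
#' @param mask_nonstandard convert nonstandard residue codes to gaps
#'   instead of raising an error.
#' @return An object of class `rfc_alignment` with fields `ids`, `rows`
#'   (normalized strings) and `L` (alignment width in columns).
#' @examples
#' aln <- multiple_alignment(c(s1 = "AC-W", s2 = "agw."))
#' aln$L
#' @export
multiple_alignment <- function(rows, ids = names(rows), mask_nonstandard = FALSE) {
  if (length(rows) == 0L) stop("alignment has no sequences", call. = FALSE)
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  rows <- toupper(as.character(rows))
  rows <- gsub(".", "-", rows, fixed = TRUE)
  L <- nchar(rows[1L])
  if (L < 1L) stop("alignment length must be >= 1", call. = FALSE)
  bad <- which(nchar(rows) != L)
  if (length(bad))
    stop("alignment rows have unequal lengths: '", ids[bad[1L]], "' has ",
         nchar(rows[bad[1L]]), " columns, expected ", L, call. = FALSE)
  nonstd <- c("B", "J", "O", "U", "X", "Z", "*")
  alphabet <- c(AA20, GAP)
  for (i in seq_along(rows)) {
    ch <- strsplit(rows[i], "", fixed = TRUE)[[1L]]
    if (mask_nonstandard) {
      ch[ch %in% nonstd] <- GAP
      rows[i] <- paste(ch, collapse = "")
    }
    off <- which(!(ch %in% alphabet))
    if (length(off))
      stop("invalid character '", ch[off[1L]], "' in sequence '", ids[i],
           "' at column ", off[1L], call. = FALSE)
  }
  structure(list(ids = ids, rows = unname(rows), L = L),
            class = "rfc_alignment")
}

#' @export
print.rfc_alignment <- function(x, ...) {
  cat("Multiple alignment:", length(x$ids), "sequences x", x$L, "columns\n")
  show <- head(seq_along(x$ids), 6L)
  for (i in show)
    cat(sprintf("  %-12s %s\n", x$ids[i],
                if (x$L > 60) paste0(substr(x$rows[i], 1, 57), "...") else x$rows[i]))
  if (length(x$ids) > 6L) cat("  ...", length(x$ids) - 6L, "more\n")
  invisible(x)
}

# n x L single-character matrix view, rownames = ids
aln_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$rows, "", fixed = TRUE))
  rownames(m) <- alignment$ids
  m
}

#' Read a multiple sequence alignment
#'
#' Parses aligned FASTA (canonical), Stockholm or Clustal files into a
#' validated [multiple_alignment()].  Parsing of the container formats is
#' delegated to Biostrings; validation (equal row lengths with the
#' offending id named, alphabet check, case and gap normalization) is done
#' here.
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"stockholm"`, `"clustal"`.
#' @inheritParams multiple_alignment
#' @return An `rfc_alignment`.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm", "clustal"),
                           mask_nonstandard = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
  } else {
    ma <- Biostrings::readAAMultipleAlignment(path, format = format)
    ss <- Biostrings::unmasked(ma)
  }
  multiple_alignment(as.character(ss), ids = names(ss),
                     mask_nonstandard = mask_nonstandard)
}

#' Write an alignment as aligned FASTA
#'
#' Records are written in input order with `-` as the canonical gap
#' character, one sequence line per record, so that
#' `read_alignment(write_alignment(x))` reproduces ids and rows exactly.
#'
#' @param alignment an `rfc_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "rfc_alignment"))
  ss <- Biostrings::BStringSet(setNames(alignment$rows, alignment$ids))
  Biostrings::writeXStringSet(ss, path, width = max(alignment$L, 20L))
  invisible(path)
}

#' Construct a binder / non-binder label table
#'
#' @param ids sequence identifiers.
#' @param labels character vector over `binder`/`nonbinder` (case
#'   insensitive; `1`/`0` accepted as synonyms).
#' @param alignment optional companion `rfc_alignment`; when supplied every
#'   labelled id must resolve to a row.
#' @return An `rfc_labels` data frame with columns `id` and `label`
#'   (values `"BINDER"` / `"NONBINDER"`).
#' @export
label_table <- function(ids, labels, alignment = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate id(s) in label table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  lab <- toupper(trimws(as.character(labels)))
  lab[lab %in% c("1", "B", "BINDS")] <- "BINDER"
  lab[lab %in% c("0", "NB", "NON-BINDER", "NON_BINDER")] <- "NONBINDER"
  bad <- which(!(lab %in% c("BINDER", "NONBINDER")))
  if (length(bad))
    stop("unrecognized label '", labels[bad[1L]], "' for id '", ids[bad[1L]],
         "' (expected binder/nonbinder or 1/0)", call. = FALSE)
  if (!is.null(alignment)) {
    missing <- setdiff(ids, alignment$ids)
    if (length(missing))
      stop("labelled id(s) absent from alignment: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!any(lab == "BINDER") || !any(lab == "NONBINDER"))
    stop("both label groups must be non-empty (got ",
         sum(lab == "BINDER"), " binder, ", sum(lab == "NONBINDER"),
         " nonbinder)", call. = FALSE)
  structure(data.frame(id = ids, label = lab, stringsAsFactors = FALSE),
            class = c("rfc_labels", "data.frame"))
}

#' Read a label table from TSV
#'
#' Expects a headered TSV with columns `id` and `label`; `#` lines are
#' comments.
#'
#' @param path TSV file path.
#' @inheritParams label_table
#' @return An `rfc_labels` data frame.
#' @export
read_labels <- function(path, alignment = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(d)))
    stop("label table must have columns 'id' and 'label'", call. = FALSE)
  label_table(d$id, d$label, alignment = alignment)
}

#' Construct a region map
#'
#' Named, non-overlapping-or-not intervals of alignment columns (for PH
#' domains typically the beta1-beta2, beta3-beta4 and beta6-beta7 variable
#' loops).  Coordinates are 1-based closed intervals, the R/IRanges
#' convention.
#'
#' @param name region names (unique).
#' @param start,end 1-based closed column bounds, `1 <= start <= end <= L`.
#' @param L alignment width the map refers to.
#' @return An `rfc_regions` data frame with attribute `L`.
#' @export
region_map <- function(name, start, end, L) {
  name <- as.character(name)
  start <- as.integer(start); end <- as.integer(end); L <- as.integer(L)
  if (anyDuplicated(name))
    stop("duplicate region name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "), call. = FALSE)
  bad <- which(start < 1L | end < start | end > L)
  if (length(bad))
    stop("invalid interval for region '", name[bad[1L]], "': [",
         start[bad[1L]], ", ", end[bad[1L]], "] with L = ", L, call. = FALSE)
  structure(data.frame(name = name, start = start, end = end,
                       stringsAsFactors = FALSE),
            L = L, class = c("rfc_regions", "data.frame"))
}

#' Read a region map from TSV
#'
#' Expects a headered TSV with columns `name`, `start`, `end`.  Coordinates
#' are 1-based closed by default; a header comment line
#' `# coords: 0-half-open` declares 0-based half-open input, which is
#' converted on read.
#'
#' @param path TSV file path.
#' @param L alignment width.
#' @return An `rfc_regions` data frame.
#' @export
read_regions <- function(path, L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- grep("^#", readLines(path, n = 20L), value = TRUE)
  zero_based <- any(grepl("coords:\\s*0-half-open", header))
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("name", "start", "end") %in% names(d)))
    stop("region map must have columns 'name', 'start', 'end'", call. = FALSE)
  if (zero_based) {
    d$start <- d$start + 1L   # [s, e) 0-based  ->  [s+1, e] 1-based
  }
  region_map(d$name, d$start, d$end, L = L)
}

#' Expand a region map into column index sets
#'
#' @param regions an `rfc_regions` map.
#' @param complement if `TRUE`, append the complement of the union of all
#'   regions as an extra region (the "rest of the domain"), making the
#'   result a partition of all `L` columns when the named regions are
#'   disjoint.
#' @param complement_name name for the complement region.
#' @return Named list of integer column vectors.
#' @export
region_columns <- function(regions, complement = FALSE,
                           complement_name = "rest") {
  stopifnot(inherits(regions, "rfc_regions"))
  L <- attr(regions, "L")
  cols <- setNames(
    lapply(seq_len(nrow(regions)),
           function(i) seq.int(regions$start[i], regions$end[i])),
    regions$name)
  if (complement) {
    rest <- setdiff(seq_len(L), unlist(cols, use.names = FALSE))
    if (complement_name %in% names(cols))
      stop("complement name '", complement_name,
           "' collides with a region name", call. = FALSE)
    cols[[complement_name]] <- rest
  }
  cols
}
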