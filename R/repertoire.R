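#' @keywords internal
"_PACKAGE"

# The 20 standard amino-acid one-letter codes. Anything else (B, J, O, U, Z,
# lowercase, digits, '*', '+', ...) counts as a special character for QC.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_REGEX <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

#' Construct a TCR repertoire
#'
#' A repertoire is one sample's list of CDR3 beta-chain clonotypes — the
#' "bag" of the multi-instance learning model. Each clonotype carries its
#' amino-acid sequence, clonal frequency and whether the V-gene locus call
#' was resolved.
#'
#' @param cdr3 Character vector of CDR3 amino-acid sequences (uppercase).
#' @param frequency Numeric vector of clonal fractions (or raw counts, which
#'   are normalized to fractions).
#' @param v_resolved Logical vector: is the V-gene call present and
#'   unambiguous? Recycled if length 1.
#' @param v_gene Optional character vector of V-gene names (kept for
#'   round-tripping to disk; `v_resolved` is what QC uses).
#' @param sample_id Sample identifier.
#' @param label Optional binary label: 1 = cancer, 0 = non-cancer, NA =
#'   unlabeled.
#' @param normalize Divide frequencies by their sum when they look like raw
#'   counts (sum > 1)? Default `TRUE`.
#' @return An object of class `"repertoire"`: a list with `sample_id`,
#'   `clonotypes` (data.frame with columns `cdr3`, `frequency`, `v_resolved`,
#'   `v_gene`) and `label`.
#' @examples
#' rep <- repertoire(c("CASSLAPGATNEKLFF", "CASSLGQAYEQYF"), c(6, 4))
#' rep$clonotypes$frequency  # 0.6 0.4
#' @export
repertoire <- function(cdr3, frequency, v_resolved = TRUE, v_gene = NA_character_,
                       sample_id = "sample", label = NA_integer_,
                       normalize = TRUE) {
  cdr3 <- as.character(cdr3)
  frequency <- as.numeric(frequency)
  if (length(cdr3) != length(frequency))
    stop("cdr3 and frequency must have the same length")
  if (any(!nzchar(cdr3)))
    stop("cdr3 sequences must be non-empty")
  if (any(is.na(frequency)) || any(frequency < 0))
    stop("frequencies must be non-negative and non-missing")
  v_resolved <- rep_len(as.logical(v_resolved), length(cdr3))
  v_gene <- rep_len(as.character(v_gene), length(cdr3))
  if (normalize && length(frequency) && sum(frequency) > 1) {
    frequency <- frequency / sum(frequency)
  }
  structure(
    list(
      sample_id = as.character(sample_id)[1],
      clonotypes = data.frame(
        cdr3 = cdr3, frequency = frequency,
        v_resolved = v_resolved, v_gene = v_gene,
        stringsAsFactors = FALSE
      ),
      label = if (is.na(label)) NA_integer_ else as.integer(label)
    ),
    class = "repertoire"
  )
}

#' @export
print.repertoire <- function(x, ...) {
  lab <- if (is.na(x$label)) "unlabeled"
         else if (x$label == 1L) "cancer" else "non-cancer"
  cat(sprintf("TCR repertoire '%s': %d clonotypes (%s)\n",
              x$sample_id, nrow(x$clonotypes), lab))
  print(utils::head(x$clonotypes, 5L))
  if (nrow(x$clonotypes) > 5L) cat("...\n")
  invisible(x)
}

#' @export
length.repertoire <- function(x) nrow(x$clonotypes)

# Column-name candidates per input dialect.
.dialect_columns <- list(
  simple = list(
    cdr3 = "cdr3",
    freq = c("count", "frequency"),
    v    = "v_gene"
  ),
  immuneaccess = list(
    cdr3 = c("amino_acid", "aminoAcid"),
    freq = c("productive_frequency", "frequencyCount (%)", "frequencyCount",
             "frequency", "templates", "count (templates/reads)", "count"),
    v    = c("v_gene", "vGeneName", "v_resolved")
  ),
  airr = list(
    cdr3 = "junction_aa",
    freq = c("duplicate_count", "duplicate_frequency", "consensus_count"),
    v    = "v_call"
  )
)

.pick_column <- function(header, candidates, what, path) {
  hit <- candidates[candidates %in% header]
  if (!length(hit))
    stop(sprintf("file '%s' lacks a %s column (looked for: %s)",
                 path, what, paste(candidates, collapse = ", ")),
         call. = FALSE)
  hit[1]
}

#' Read a repertoire table from disk
#'
#' Reads a tab-separated clonotype table in one of three dialects:
#' `"simple"` (columns `cdr3`, `count` or `frequency`, `v_gene`),
#' `"immuneaccess"` (`amino_acid`/`aminoAcid`, a frequency or template-count
#' column, `v_gene`/`vGeneName`) or `"airr"` (AIRR Rearrangement:
#' `junction_aa`, `duplicate_count`, `v_call`). Lines starting with `#` are
#' ignored. Frequencies are normalized to sum at most 1 (raw counts are
#' divided by their total). A clonotype whose V column is empty or flagged
#' unresolved/unknown is kept but marked `v_resolved = FALSE` so the QC
#' filter can drop it.
#'
#' @param path Path to a TSV file.
#' @param dialect One of `"simple"`, `"immuneaccess"`, `"airr"`.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param label Optional binary label.
#' @return A [repertoire()] object.
#' @export
parse_repertoire <- function(path, dialect = c("simple", "immuneaccess", "airr"),
                             sample_id = NULL, label = NA_integer_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path), call. = FALSE)
  tab <- tryCatch(
    utils::read.delim(path, comment.char = "#", check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("empty repertoire file '%s'", path), call. = FALSE)
  )
  if (nrow(tab) == 0L)
    stop(sprintf("empty repertoire file '%s'", path), call. = FALSE)
  cols <- .dialect_columns[[dialect]]
  cdr3_col <- .pick_column(names(tab), cols$cdr3, "CDR3 amino-acid", path)
  freq_col <- .pick_column(names(tab), cols$freq, "frequency/count", path)
  v_col    <- .pick_column(names(tab), cols$v, "V-gene", path)

  v_raw <- trimws(as.character(tab[[v_col]]))
  v_resolved <- !(is.na(v_raw) | v_raw == "" |
                    tolower(v_raw) %in% c("unresolved", "unknown", "na"))
  freq <- suppressWarnings(as.numeric(tab[[freq_col]]))
  if (any(is.na(freq)))
    stop(sprintf("non-numeric values in column '%s' of '%s'", freq_col, path),
         call. = FALSE)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  repertoire(
    cdr3 = toupper(trimws(as.character(tab[[cdr3_col]]))),
    frequency = freq,
    v_resolved = v_resolved,
    v_gene = v_raw,
    sample_id = sample_id,
    label = label
  )
}

#' Write a repertoire as a simple TSV
#'
#' Writes the three-column `simple` dialect (`cdr3`, `frequency`, `v_gene`)
#' with full double precision so that [parse_repertoire()] reproduces the
#' repertoire exactly.
#'
#' @param rep A [repertoire()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path) {
  stopifnot(inherits(rep, "repertoire"))
  cl <- rep$clonotypes
  v <- ifelse(is.na(cl$v_gene) | !nzchar(cl$v_gene),
              ifelse(cl$v_resolved, "TRBV", ""), cl$v_gene)
  out <- data.frame(
    cdr3 = cl$cdr3,
    frequency = sprintf("%.17g", cl$frequency),
    v_gene = v,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quality-filter clonotypes
#'
#' Applies the four CDR3 quality rules used throughout the pipeline: a
#' clonotype is removed when its sequence (1) is shorter than `min_len` or
#' longer than `max_len` residues, (2) contains any character outside the 20
#' standard amino-acid letters (X, `+`, `*`, B, Z, ... all count as special
#' characters), (3) does not start with cysteine (C) or does not end with
#' phenylalanine (F), or (4) has an unresolved V-gene locus call. Survivor
#' order is preserved; the operation is idempotent.
#'
#' @param x A [repertoire()] object or a clonotype data.frame with columns
#'   `cdr3` and `v_resolved`.
#' @param min_len,max_len Length bounds (defaults 10 and 24).
#' @return The same type as `x`, with failing clonotypes removed.
#' @export
qc_filter <- function(x, min_len = 10L, max_len = 24L) {
  if (inherits(x, "repertoire")) {
    x$clonotypes <- qc_filter(x$clonotypes, min_len, max_len)
    return(x)
  }
  stopifnot(is.data.frame(x))
  cdr3 <- x$cdr3
  n <- nchar(cdr3)
  keep <- n >= min_len & n <= max_len &
    grepl(AA_REGEX, cdr3) &
    startsWith(cdr3, "C") & endsWith(cdr3, "F") &
    x$v_resolved
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the shared-sequence reference set
#'
#' Sequences observed at high clonal frequency in both healthy individuals
#' and cancer patients are considered irrelevant to cancer and are removed
#' before scoring. The reference set collects every CDR3 that appears among
#' the `top_n` most frequent sequences of at least one cancer sample *and*
#' at least one non-cancer sample of the training cohort (`mode =
#' "intersect"`, the default). `mode = "union"` instead pools all top-`top_n`
#' sequences of every sample.
#'
#' @param samples List of labeled [repertoire()] objects.
#' @param top_n Number of top-frequency sequences taken per sample
#'   (default 20000).
#' @param mode `"intersect"` (default) or `"union"`.
#' @param qc Apply [qc_filter()] before ranking? Default `TRUE`.
#' @return An object of class `"reference_set"`: list with `sequences`
#'   (sorted unique character vector) and `top_n`.
#' @export
build_reference_set <- function(samples, top_n = 20000L,
                                mode = c("intersect", "union"), qc = TRUE) {
  mode <- match.arg(mode)
  stopifnot(top_n >= 1L, length(samples) >= 1L)
  labels <- vapply(samples, function(s) as.integer(s$label), integer(1))
  if (mode == "intersect" &&
      (!any(labels == 1L, na.rm = TRUE) || !any(labels == 0L, na.rm = TRUE)))
    stop("reference set needs at least one cancer and one non-cancer sample",
         call. = FALSE)
  top_seqs <- lapply(samples, function(s) {
    cl <- if (qc) qc_filter(s$clonotypes) else s$clonotypes
    if (nrow(cl) == 0L) return(character(0))
    cl <- cl[order(-cl$frequency, cl$cdr3), , drop = FALSE]
    unique(utils::head(cl$cdr3, top_n))
  })
  seqs <- if (mode == "union") {
    unique(unlist(top_seqs))
  } else {
    in_cancer <- unique(unlist(top_seqs[labels == 1L]))
    in_control <- unique(unlist(top_seqs[labels == 0L]))
    intersect(in_cancer, in_control)
  }
  structure(list(sequences = sort(seqs), top_n = as.integer(top_n)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("Reference set: %d shared CDR3 sequences (top_n = %d per sample)\n",
              length(x$sequences), x$top_n))
  invisible(x)
}

#' Write/read a reference set as plain text (one sequence per line)
#'
#' @param ref A `"reference_set"` object.
#' @param path File path.
#' @param top_n For [read_reference_set()], the `top_n` to record on the
#'   restored object.
#' @return `write_reference_set` returns `path` invisibly;
#'   `read_reference_set` returns a `"reference_set"`.
#' @export
write_reference_set <- function(ref, path) {
  stopifnot(inherits(ref, "reference_set"))
  writeLines(ref$sequences, path)
  invisible(path)
}

#' @rdname write_reference_set
#' @export
read_reference_set <- function(path, top_n = NA_integer_) {
  structure(list(sequences = sort(unique(readLines(path))),
                 top_n = as.integer(top_n)),
            class = "reference_set")
}

#' Select the top-k clonotypes of a repertoire
#'
#' Removes clonotypes whose CDR3 appears in the reference set, sorts the
#' survivors by clonal frequency in descending order (ties broken by
#' lexicographic CDR3 order, so the result is deterministic) and keeps the
#' first `min(k, n)` of them. No padding happens at this stage; bags shorter
#' than `k` are zero-filled later, at the score level.
#'
#' @param rep A [repertoire()] object (already quality-filtered).
#' @param k Number of clonotypes to keep.
#' @param reference Optional `"reference_set"`; `NULL` skips removal.
#' @return A [repertoire()] with at most `k` clonotypes.
#' @export
select_top_k <- function(rep, k, reference = NULL) {
  stopifnot(inherits(rep, "repertoire"), k >= 1L)
  cl <- rep$clonotypes
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "reference_set"))
    cl <- cl[!(cl$cdr3 %in% reference$sequences), , drop = FALSE]
  }
  cl <- cl[order(-cl$frequency, cl$cdr3), , drop = FALSE]
  cl <- utils::head(cl, k)
  rownames(cl) <- NULL
  rep$clonotypes <- cl
  rep
}
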