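# Amino-acid biochemical encodings and CDR3 -> matrix embedding.

#' Load an amino-acid biochemical encoding
#'
#' An encoding maps each of the 20 standard amino acids to a length-`d`
#' vector of biochemical feature values; a CDR3 of length `l` then becomes an
#' `l x d` matrix. Two published tables ship with the package: the Atchley
#' factors (`d = 5`, condensed from 494 property scales) and the Kidera
#' factors (`d = 10`, from 188 scales). A custom table can be read from a
#' TSV whose first column is the amino-acid letter followed by `d` numeric
#' columns (one row per amino acid, all 20 required).
#'
#' @param source `"atchley"`, `"kidera"`, or a file path.
#' @return An object of class `"aa_encoding"`: list with `name`, `d`, and
#'   `M`, a 20 x d numeric matrix with amino-acid rownames.
#' @seealso [derive_pca_encoding()] to build a PCA-reduced encoding from a
#'   raw property table.
#' @export
load_encoding <- function(source = "atchley") {
  if (inherits(source, "aa_encoding")) return(source)
  stopifnot(is.character(source), length(source) == 1L)
  path <- switch(source,
    atchley = system.file("extdata", "atchley_factors.tsv", package = "tcrmil"),
    kidera  = system.file("extdata", "kidera_factors.tsv", package = "tcrmil"),
    source
  )
  if (!file.exists(path))
    stop(sprintf("encoding file '%s' not found", path), call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  aa <- toupper(trimws(as.character(tab[[1]])))
  M <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(M) || anyNA(M))
    stop("encoding table must be fully numeric after the amino-acid column",
         call. = FALSE)
  missing_aa <- setdiff(AA_ALPHABET, aa)
  if (length(missing_aa))
    stop(sprintf("encoding table is missing amino acids: %s",
                 paste(missing_aa, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(aa)) stop("duplicated amino-acid rows in encoding table",
                              call. = FALSE)
  rownames(M) <- aa
  M <- M[AA_ALPHABET, , drop = FALSE]
  name <- if (source %in% c("atchley", "kidera")) source else basename(path)
  structure(list(name = name, d = ncol(M), M = M), class = "aa_encoding")
}

#' @export
print.aa_encoding <- function(x, ...) {
  cat(sprintf("Amino-acid encoding '%s': 20 x %d\n", x$name, x$d))
  invisible(x)
}

#' Derive a PCA-reduced amino-acid encoding from a raw property table
#'
#' Given a 20 x m table of raw amino-acid property scales (e.g. drawn from
#' the AAindex database), standardizes each column to zero mean and unit
#' variance over the 20 amino acids, fits a principal component analysis and
#' keeps the first `d` component scores per amino acid. This is the
#' procedure by which low-dimensional biochemical encodings (such as a
#' 20 x 15 matrix from several hundred scales) are condensed from the raw
#' database; constant columns carry no information and are dropped before
#' standardization. Each component's sign is fixed so that its
#' largest-magnitude loading is positive, making results reproducible across
#' linear-algebra backends.
#'
#' @param aaindex_table Numeric 20 x m matrix (rownames = amino-acid
#'   letters) or a data.frame/TSV path in [load_encoding()] layout.
#' @param d Number of components to keep (default 15).
#' @param name Name for the resulting encoding.
#' @return An `"aa_encoding"` with an `explained_variance` attribute: the
#'   fraction of total (standardized) variance captured by the `d`
#'   components.
#' @export
derive_pca_encoding <- function(aaindex_table, d = 15L, name = "pca") {
  if (is.character(aaindex_table) && length(aaindex_table) == 1L) {
    tab <- utils::read.delim(aaindex_table, stringsAsFactors = FALSE,
                             check.names = FALSE)
    aaindex_table <- as.matrix(tab[, -1, drop = FALSE])
    rownames(aaindex_table) <- toupper(trimws(as.character(tab[[1]])))
  }
  X <- as.matrix(aaindex_table)
  if (is.null(rownames(X))) stop("property table needs amino-acid rownames",
                                 call. = FALSE)
  missing_aa <- setdiff(AA_ALPHABET, rownames(X))
  if (length(missing_aa))
    stop(sprintf("property table is missing amino acids: %s",
                 paste(missing_aa, collapse = ", ")), call. = FALSE)
  X <- X[AA_ALPHABET, , drop = FALSE]
  if (anyNA(X)) stop("property table contains missing values", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  if (ncol(X) < d)
    stop(sprintf("need at least d = %d non-constant property columns, have %d",
                 d, ncol(X)), call. = FALSE)
  Xs <- scale(X)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(d), drop = FALSE]
  # sign convention: largest-magnitude loading of each component is positive
  for (j in seq_len(d)) {
    load_j <- pc$rotation[, j]
    if (load_j[which.max(abs(load_j))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("pc", seq_len(d))
  ev <- sum(pc$sdev[seq_len(d)]^2) / sum(pc$sdev^2)
  structure(list(name = name, d = as.integer(d), M = scores),
            class = "aa_encoding", explained_variance = ev)
}

#' Encode a CDR3 sequence as a padded numeric matrix
#'
#' Maps each residue to its encoding row and zero-pads at the C-terminal end
#' up to `l_max` rows, so that sequences of different lengths share one input
#' shape. Padding rows are exactly zero and are flagged in the `mask` so that
#' downstream pooling can exclude windows that overlap padding.
#'
#' @param cdr3 CDR3 amino-acid string (standard 20-letter alphabet).
#' @param enc An `"aa_encoding"` (or source accepted by [load_encoding()]).
#' @param l_max Padded length (default 24, the QC upper bound).
#' @return An object of class `"tcr_matrix"`: list with `values`
#'   (`l_max x d`), `true_length` and logical `mask` (`TRUE` = real residue).
#' @examples
#' m <- encode_sequence("CASSLGQAYEQYF", load_encoding("atchley"))
#' dim(m$values)     # 24 5
#' sum(m$mask)       # 13
#' @export
encode_sequence <- function(cdr3, enc = load_encoding("atchley"), l_max = 24L) {
  enc <- load_encoding(enc)
  stopifnot(is.character(cdr3), length(cdr3) == 1L)
  l <- nchar(cdr3)
  if (l > l_max)
    stop(sprintf("sequence length %d exceeds l_max = %d", l, l_max),
         call. = FALSE)
  if (!grepl(AA_REGEX, cdr3))
    stop("sequence contains letters outside the 20 standard amino acids",
         call. = FALSE)
  chars <- strsplit(cdr3, "", fixed = TRUE)[[1]]
  values <- matrix(0, nrow = l_max, ncol = enc$d)
  values[seq_len(l), ] <- enc$M[chars, , drop = FALSE]
  structure(list(values = values, true_length = l,
                 mask = seq_len(l_max) <= l),
            class = "tcr_matrix")
}
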