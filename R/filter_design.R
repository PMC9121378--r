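# Filter-bank design from contiguous contact-region size counts.
#
# X-ray structures of TCR-peptide-MHC complexes show that the contiguous
# runs of CDR3 residues in direct contact with peptide range from 2 to 8
# residues, with short runs most common. The convolutional filter bank
# mirrors that: one filter height per region size that occurs often enough,
# with the number of filters per height proportional to how often the size
# occurs.

#' Contact-region size table
#'
#' `region_table()` builds a table of contiguous contact-region sizes and
#' their observed counts; `contact_region_table()` returns the built-in
#' default (sizes 2-8 with counts 12, 12, 13, 8, 7, 5, 1, i.e. 58 regions
#' observed across 55 crystallographically annotated CDR3 sequences).
#'
#' @param sizes Strictly increasing integer region lengths.
#' @param counts Matching non-negative integer counts, at least one positive.
#' @return An object of class `"region_table"` (a data.frame with columns
#'   `size` and `count`).
#' @export
region_table <- function(sizes, counts) {
  sizes <- as.integer(sizes); counts <- as.integer(counts)
  stopifnot(length(sizes) == length(counts), length(sizes) >= 1L)
  if (is.unsorted(sizes, strictly = TRUE))
    stop("region sizes must be strictly increasing", call. = FALSE)
  if (any(counts < 0)) stop("region counts must be non-negative", call. = FALSE)
  if (sum(counts) == 0L) stop("all region counts are zero", call. = FALSE)
  structure(data.frame(size = sizes, count = counts),
            class = c("region_table", "data.frame"))
}

#' @rdname region_table
#' @export
contact_region_table <- function() {
  path <- system.file("extdata", "contact_regions.tsv", package = "tcrmil")
  tab <- utils::read.delim(path)
  region_table(tab$size, tab$count)
}

#' Occurrence frequency of each region size
#'
#' @param table A [region_table()].
#' @return Numeric vector `count / sum(count)`, in size order, named by size.
#' @examples
#' round(region_frequencies(contact_region_table()), 3)
#' @export
region_frequencies <- function(table) {
  stopifnot(inherits(table, "region_table"))
  stats::setNames(table$count / sum(table$count), table$size)
}

#' Design the multi-width convolution filter bank
#'
#' Region sizes whose occurrence frequency falls below `min_freq` are
#' excluded; the remaining frequencies are renormalized and `total_filters`
#' filter slots are apportioned to the surviving heights by largest-remainder
#' (Hamilton) allocation: each height gets the floor of its quota
#' `total_filters * frequency`, and leftover slots go to the largest
#' fractional remainders, ties broken toward the smaller height. Every
#' surviving height receives at least one filter. With the built-in region
#' table and defaults this yields heights 2-7 with 3, 3, 3, 2, 2, 1 filters
#' (14 in total); height 8 is excluded at frequency 0.017 < 0.05. Simple
#' rounding of the quotas (`method = "round"`) is available as an
#' alternative; it reproduces the same default bank but does not guarantee
#' an exact total in general.
#'
#' @param table A [region_table()].
#' @param d Feature dimension of the encoding the filters will act on.
#' @param min_freq Exclusion threshold on occurrence frequency (default 0.05).
#' @param total_filters Total number of filters to allocate (default 14).
#' @param method `"largest_remainder"` (default) or `"round"`.
#' @return An object of class `"filter_bank"`: list with `entries`
#'   (data.frame `h`, `n_filters`), `d` and `n_total`.
#' @examples
#' design_filter_bank(contact_region_table(), d = 5)
#' @export
design_filter_bank <- function(table, d, min_freq = 0.05, total_filters = 14L,
                               method = c("largest_remainder", "round")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "region_table"), d >= 1L)
  freq <- region_frequencies(table)
  keep <- freq >= min_freq
  if (!any(keep))
    stop("no region size survives the frequency threshold", call. = FALSE)
  h <- table$size[keep]
  if (total_filters < length(h))
    stop(sprintf("total_filters = %d is fewer than the %d surviving sizes",
                 total_filters, length(h)), call. = FALSE)
  q <- total_filters * freq[keep] / sum(freq[keep])  # quotas
  if (method == "round") {
    n <- pmax(1L, as.integer(round(q)))
  } else {
    n <- pmax(1L, as.integer(floor(q)))
    left <- total_filters - sum(n)
    if (left > 0L) {
      rem <- q - floor(q)
      # leftover slots to the largest remainders; ties toward smaller h
      take <- order(-rem, h)[seq_len(left)]
      n[take] <- n[take] + 1L
    } else if (left < 0L) {
      # floors plus the >=1 guarantee overshot: trim from smallest remainders
      rem <- q - floor(q)
      for (i in order(rem, -h)) {
        if (left == 0L) break
        if (n[i] > 1L) { n[i] <- n[i] - 1L; left <- left + 1L }
      }
    }
  }
  structure(list(entries = data.frame(h = as.integer(h), n_filters = n),
                 d = as.integer(d), n_total = sum(n)),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("Convolution filter bank: %d filters over %d heights (d = %d)\n",
              x$n_total, nrow(x$entries), x$d))
  cat(paste(sprintf("  %d x %d: %d", x$entries$h, x$d, x$entries$n_filters),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Read a region table from a two-column TSV (size, count)
#'
#' @param path TSV file path.
#' @return A [region_table()].
#' @export
read_region_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#")
  if (!all(c("size", "count") %in% names(tab)))
    stop("region table TSV needs 'size' and 'count' columns", call. = FALSE)
  region_table(tab$size, tab$count)
}
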