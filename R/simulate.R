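# Synthetic repertoire cohorts with planted variable-length motifs.
#
# The generator emulates the multi-instance structure the classifier
# assumes: a cancer sample's repertoire contains a fraction of sequences
# that share short cancer-specific motifs, while control samples contain
# none. It makes no attempt to model V(D)J recombination, real generation
# probabilities or HLA restriction — background residues are drawn i.i.d.

.default_length_dist <- function() {
  # realistic CDR3 length profile: unimodal around 15 residues
  w <- stats::dnorm(10:24, mean = 15, sd = 2)
  stats::setNames(w / sum(w), 10:24)
}

.default_motifs <- function() c("LQ", "WGQW", "RGNTEAF")

.trbv_names <- c("TRBV2", "TRBV5-1", "TRBV6-5", "TRBV7-9", "TRBV9",
                 "TRBV12-3", "TRBV19", "TRBV20-1", "TRBV28", "TRBV30")

#' Draw background CDR3-like sequences
#'
#' Each sequence starts with cysteine (C), ends with phenylalanine (F) and
#' has its total length drawn from `length_dist` (a named probability vector
#' over lengths 10-24); interior residues are drawn independently from
#' `bg_freqs` (uniform over the 20 amino acids by default).
#'
#' @param n Number of sequences.
#' @param length_dist Named probability vector over integer lengths in
#'   10-24; default is unimodal around 15.
#' @param bg_freqs Optional length-20 probability vector named by amino
#'   acid.
#' @return Character vector of length `n`.
#' @export
generate_background_cdr3 <- function(n = 1L, length_dist = NULL,
                                     bg_freqs = NULL) {
  if (is.null(length_dist)) length_dist <- .default_length_dist()
  lens <- as.integer(names(length_dist))
  stopifnot(all(lens >= 10L), all(lens <= 24L), all(length_dist >= 0))
  if (is.null(bg_freqs)) bg_freqs <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  L <- if (length(lens) == 1L) rep.int(lens, n)
       else sample(lens, n, replace = TRUE, prob = length_dist)
  inner <- sample(names(bg_freqs), sum(L - 2L), replace = TRUE,
                  prob = bg_freqs)
  stops <- cumsum(L - 2L)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  vapply(seq_len(n), function(i)
    paste0("C", paste(inner[starts[i]:stops[i]], collapse = ""), "F"),
    character(1))
}

#' Plant a motif into the interior of a sequence
#'
#' Overwrites a uniformly chosen interior window (never the first or last
#' residue) with `motif`; sequence length is unchanged.
#'
#' @param seq A CDR3 string.
#' @param motif Motif to plant; must fit the interior
#'   (`nchar(motif) <= nchar(seq) - 2`).
#' @return The modified sequence.
#' @export
plant_motif <- function(seq, motif) {
  L <- nchar(seq); m <- nchar(motif)
  if (m > L - 2L)
    stop(sprintf("motif of length %d does not fit the interior of a length-%d sequence",
                 m, L), call. = FALSE)
  start <- if (L - m == 2L) 2L else sample(2L:(L - m), 1L)
  paste0(substr(seq, 1L, start - 1L), motif, substr(seq, start + m, L))
}

#' Generate a labeled synthetic cohort with planted motifs
#'
#' Builds `n_cancer + n_control` repertoires of `seqs_per_sample` background
#' CDR3 sequences with clonal frequencies proportional to
#' `rank^(-freq_alpha)` (a heavy-tailed clone-size profile). In each cancer
#' sample, `round(witness_rate * seqs_per_sample)` sequences at uniformly
#' chosen ranks receive a motif drawn uniformly from `motif_set`, planted at
#' a random interior position; control samples receive none. The witness
#' assignments are returned as hidden ground truth for motif-recovery
#' scoring. Generation is fully seeded and bit-reproducible.
#'
#' @param n_cancer,n_control Sample counts (defaults 40 and 40).
#' @param seqs_per_sample Clonotypes per sample (default 100).
#' @param motif_set Character vector of motifs, lengths 2-7 in the standard
#'   alphabet; the default plants one short, one medium and one long motif
#'   (lengths 2, 4 and 7).
#' @param witness_rate Fraction of a cancer sample's sequences carrying a
#'   motif, in (0, 1] (default 0.2); 0 gives a null cohort with no signal.
#' @param length_dist,bg_freqs Passed to [generate_background_cdr3()].
#' @param freq_alpha Power-law exponent of the rank-frequency profile
#'   (default 1, Zipf-like).
#' @param seed Integer seed (default 1).
#' @return List with `repertoires` (labeled [repertoire()] objects, cancer
#'   first) and `truth` (data.frame: `sample_id`, `label`, `rank`, `cdr3`,
#'   `witness`, `motif`).
#' @examples
#' cohort <- generate_cohort(n_cancer = 3, n_control = 3,
#'                           seqs_per_sample = 20, seed = 7)
#' table(cohort$truth$witness, cohort$truth$label)
#' @export
generate_cohort <- function(n_cancer = 40L, n_control = 40L,
                            seqs_per_sample = 100L,
                            motif_set = .default_motifs(),
                            witness_rate = 0.2, length_dist = NULL,
                            bg_freqs = NULL, freq_alpha = 1, seed = 1L) {
  stopifnot(n_cancer >= 0L, n_control >= 0L, seqs_per_sample >= 1L,
            witness_rate >= 0, witness_rate <= 1)
  if (length(motif_set)) {
    ml <- nchar(motif_set)
    stopifnot(all(ml >= 2L), all(ml <= 7L),
              all(grepl(AA_REGEX, motif_set)))
  }
  set.seed(seed)
  n <- seqs_per_sample
  freq <- (seq_len(n))^(-freq_alpha)
  freq <- freq / sum(freq)
  n_witness <- round(witness_rate * n)
  labels <- rep(c(1L, 0L), c(n_cancer, n_control))
  ids <- c(sprintf("cancer_%02d", seq_len(n_cancer)),
           sprintf("control_%02d", seq_len(n_control)))
  reps <- vector("list", length(labels))
  truth <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    seqs <- generate_background_cdr3(n, length_dist, bg_freqs)
    witness <- rep(FALSE, n)
    motif <- rep(NA_character_, n)
    if (labels[i] == 1L && n_witness > 0L && length(motif_set)) {
      w_ix <- sample.int(n, n_witness)
      for (j in w_ix) {
        m <- motif_set[sample.int(length(motif_set), 1L)]
        if (nchar(m) <= nchar(seqs[j]) - 2L) {
          seqs[j] <- plant_motif(seqs[j], m)
          witness[j] <- TRUE
          motif[j] <- m
        }
      }
    }
    reps[[i]] <- repertoire(seqs, freq,
                            v_gene = sample(.trbv_names, n, replace = TRUE),
                            sample_id = ids[i], label = labels[i],
                            normalize = FALSE)
    truth[[i]] <- data.frame(sample_id = ids[i], label = labels[i],
                             rank = seq_len(n), cdr3 = seqs,
                             witness = witness, motif = motif,
                             stringsAsFactors = FALSE)
  }
  list(repertoires = reps, truth = do.call(rbind, truth))
}

#' Write or read a cohort as plain-text files
#'
#' `write_cohort()` writes one simple-dialect TSV per sample plus
#' `labels.tsv` (sample_id, label) and, when ground truth is present,
#' `truth.tsv`. `read_cohort()` restores the labeled repertoire list.
#'
#' @param cohort List with `repertoires` (and optionally `truth`), as
#'   returned by [generate_cohort()], or a plain list of repertoires.
#' @param dir Directory to write to / read from (created if missing).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` a list of
#'   labeled repertoires.
#' @export
write_cohort <- function(cohort, dir) {
  reps <- if (!is.null(cohort$repertoires)) cohort$repertoires else cohort
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in reps)
    write_repertoire(r, file.path(dir, paste0(r$sample_id, ".tsv")))
  labs <- data.frame(sample_id = vapply(reps, `[[`, character(1), "sample_id"),
                     label = vapply(reps, `[[`, integer(1), "label"))
  utils::write.table(labs, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  labs <- utils::read.delim(file.path(dir, "labels.tsv"),
                            stringsAsFactors = FALSE)
  lapply(seq_len(nrow(labs)), function(i) {
    parse_repertoire(file.path(dir, paste0(labs$sample_id[i], ".tsv")),
                     dialect = "simple", sample_id = labs$sample_id[i],
                     label = labs$label[i])
  })
}
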