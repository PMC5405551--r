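#' Quality-filter parameters for pileup construction
#'
#' Defaults reproduce a stringent mpileup-style filter: base quality >= 35,
#' mapping quality >= 50. `mapq_adjust` is the coefficient of the optional
#' mismatch-based mapping-quality downgrade hook (see
#' [adjusted_mapping_quality()]); the default hook is the identity, so the
#' mapping-quality cutoff operates on the aligner-reported values.
#'
#' @param min_base_quality phred cutoff for a base to be counted (default 35).
#' @param min_mapping_quality phred cutoff for a record to contribute
#'   anything (default 50).
#' @param mapq_adjust coefficient for the downgrade hook (default 50).
#' @param mapq_adjust_fun `NULL` for the identity, or a function
#'   `(alignments, ref, C) -> integer vector` of adjusted mapping qualities.
#' @return a list of class `filter_params`.
#' @export
filter_params <- function(min_base_quality = 35L, min_mapping_quality = 50L,
                          mapq_adjust = 50L, mapq_adjust_fun = NULL) {
  stopifnot(min_base_quality >= 0, min_mapping_quality >= 0, mapq_adjust >= 0)
  structure(list(min_base_quality = as.integer(min_base_quality),
                 min_mapping_quality = as.integer(min_mapping_quality),
                 mapq_adjust = as.integer(mapq_adjust),
                 mapq_adjust_fun = mapq_adjust_fun),
            class = "filter_params")
}

#' Adjusted mapping quality
#'
#' Pluggable hook for downgrading mapping qualities of mismatch-rich reads
#' before the mapping-quality cutoff is applied. The default (`hook = NULL`)
#' is the identity. The built-in `"mismatch"` hook counts mismatches over the
#' aligned (M) bases of each read and returns
#' `max(0, mapq - round(C * mismatches / aligned_length))`, a monotone
#' penalty in the mismatch fraction.
#'
#' @param alignments alignment tibble (see [read_sam()]).
#' @param ref a [circular_reference()] in the alignments' orientation.
#' @param C penalty coefficient (default 50).
#' @param hook `NULL` (identity) or `"mismatch"`.
#' @return integer vector of adjusted mapping qualities.
#' @export
adjusted_mapping_quality <- function(alignments, ref, C = 50L, hook = NULL) {
  if (is.null(hook)) return(alignments$mapq)
  if (is.function(hook)) return(as.integer(hook(alignments, ref, C)))
  if (!identical(hook, "mismatch")) stop("unknown mapping-quality hook")
  mism <- integer(nrow(alignments))
  alen <- integer(nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    cg <- alignments$cigar[i]
    len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
    op <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1L]]
    r <- alignments$pos[i]
    j <- 1L
    for (k in seq_along(op)) {
      if (op[k] %in% c("M", "=", "X")) {
        rd <- substr(alignments$seq[i], j, j + len[k] - 1L)
        rf <- substr(ref$sequence, r, r + len[k] - 1L)
        mism[i] <- mism[i] + sum(strsplit(rd, "")[[1L]] != strsplit(rf, "")[[1L]])
        alen[i] <- alen[i] + len[k]
        r <- r + len[k]; j <- j + len[k]
      } else if (op[k] == "I") j <- j + len[k]
      else if (op[k] == "S") j <- j + len[k]
      else if (op[k] == "D") r <- r + len[k]
    }
  }
  pmax(0L, alignments$mapq - as.integer(round(C * mism / pmax(alen, 1L))))
}

#' Build a strand-resolved, quality-filtered pileup
#'
#' Tallies per-position allele counts by strand, absolute and qualified
#' depth, and indel events from alignment records against one orientation of
#' a circular reference. Records below the mapping-quality cutoff contribute
#' nothing; bases below the base-quality cutoff are excluded from allele
#' counts and qualified depth. Deletion spans contribute to depth across
#' every deleted position; insertions are anchored at the preceding aligned
#' reference position and do not add depth. Indels are left-aligned against
#' reference homopolymers/repeats before aggregation. Overlapping mates are
#' counted independently.
#'
#' @param alignments alignment tibble (see [read_sam()], [simulate_reads()]).
#' @param ref a [circular_reference()] in the same orientation as the
#'   alignments.
#' @param params a [filter_params()].
#' @return an object of class `mitohet_pileup`: list with `positions`
#'   (tibble: `position`, `ref`, `covmp`, `qdepth`, `delspan`, per-strand
#'   counts of alignments terminating at each position, and eight
#'   strand-resolved allele-count columns) and `indels` (tibble: `anchor`,
#'   `type`, `seq`, `plus`, `minus`).
#' @export
build_pileup <- function(alignments, ref, params = filter_params()) {
  stopifnot(inherits(ref, "circular_reference"))
  mapq <- adjusted_mapping_quality(alignments, ref, params$mapq_adjust,
                                   params$mapq_adjust_fun)
  res <- build_pileup_cpp(alignments$pos, as.integer(mapq),
                          alignments$strand, alignments$cigar,
                          alignments$seq, alignments$qual,
                          ref$sequence, params$min_base_quality,
                          params$min_mapping_quality)
  counts <- res$counts
  colnames(counts) <- c("A_plus", "C_plus", "G_plus", "T_plus",
                        "A_minus", "C_minus", "G_minus", "T_minus")
  positions <- tibble::tibble(
    position = seq_len(ref$length),
    ref = strsplit(ref$sequence, "", fixed = TRUE)[[1L]],
    covmp = res$covmp, qdepth = res$qdepth, delspan = res$delspan,
    ends_plus = res$ends_plus, ends_minus = res$ends_minus)
  positions <- dplyr::bind_cols(positions, tibble::as_tibble(counts))
  indels <- tibble::tibble(anchor = res$indel_anchor, type = res$indel_type,
                           seq = res$indel_seq, plus = res$indel_plus,
                           minus = res$indel_minus)
  indels <- left_align_indels(indels, ref$sequence)
  structure(list(positions = positions, indels = indels,
                 ref = ref, params = params),
            class = "mitohet_pileup")
}

#' @export
print.mitohet_pileup <- function(x, ...) {
  cat("<mitohet_pileup> ", x$ref$length, " positions, mean depth ",
      round(mean(x$positions$covmp), 1), ", ", nrow(x$indels),
      " distinct indel event(s)\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mitohet_pileup <- function(x, ...) x$positions

# Left-align indel events against the reference: an insertion anchored at a
# whose sequence ends with ref[a] is equivalent to one anchored at a-1 with
# the sequence rotated; likewise for deletions. Normalizing to the leftmost
# anchor makes counts from reads entering a homopolymer at different offsets
# aggregate at one position.
left_align_indels <- function(indels, refseq) {
  if (nrow(indels) == 0L) return(indels)
  ref_at <- function(p) substr(refseq, p, p)
  for (i in seq_len(nrow(indels))) {
    a <- indels$anchor[i]
    s <- indels$seq[i]
    k <- nchar(s)
    while (a >= 2L && ref_at(a) == substr(s, k, k)) {
      s <- paste0(ref_at(a), substr(s, 1L, k - 1L))
      a <- a - 1L
    }
    indels$anchor[i] <- a
    indels$seq[i] <- s
  }
  dplyr::summarise(dplyr::group_by(indels, .data$anchor, .data$type, .data$seq),
                   plus = sum(.data$plus), minus = sum(.data$minus),
                   .groups = "drop")
}
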