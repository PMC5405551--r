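#' Circular reference objects
#'
#' A `circular_reference` holds a single circular nucleotide sequence together
#' with the bookkeeping the dual-orientation pipeline needs: the shift offset
#' of the current orientation (0 for the original) and a coordinate map from
#' internal positions (1..L, after optional N-stripping) to reported
#' positions in the numbering of the input sequence. Human rCRS-style
#' references carry a placeholder N (position 3107) that must be deleted
#' before alignment; stripping it while keeping the original numbering is what
#' the coordinate map is for.
#'
#' @param name sequence name.
#' @param sequence uppercase nucleotide string (A/C/G/T only).
#' @param shift_offset integer shift of this orientation, 0 for the original.
#' @param coord_map integer vector, internal position -> reported position.
#' @return an object of class `circular_reference`.
#' @export
circular_reference <- function(name, sequence, shift_offset = 0L,
                               coord_map = seq_len(nchar(sequence))) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L == 0L) stop("reference sequence is empty")
  if (grepl("[^ACGT]", sequence))
    stop("reference sequence contains characters other than A/C/G/T; ",
         "load with strip_n = TRUE to remove Ns")
  if (length(coord_map) != L) stop("coord_map length must equal sequence length")
  if (anyDuplicated(coord_map)) stop("coord_map must be injective")
  if (!(shift_offset == 0L || (shift_offset >= 1L && shift_offset < L)))
    stop("shift_offset must be 0 or in [1, L)")
  structure(
    list(name = name, sequence = sequence, length = L,
         shift_offset = as.integer(shift_offset),
         coord_map = as.integer(coord_map)),
    class = "circular_reference")
}

#' @export
print.circular_reference <- function(x, ...) {
  cat("<circular_reference> ", x$name, ": ", x$length, " bp",
      if (x$shift_offset > 0L) paste0(", shifted by ", x$shift_offset),
      if (!identical(x$coord_map, seq_len(x$length))) ", N-stripped",
      "\n", sep = "")
  invisible(x)
}

#' Load a circular reference from a single-record FASTA file
#'
#' @param path FASTA file with exactly one record.
#' @param strip_n if `TRUE` (default), remove every N from the sequence and
#'   record the original numbering of the retained positions in the
#'   coordinate map, so that downstream reports use the input numbering
#'   (e.g. rCRS positions despite the deleted 3107-N).
#' @return a [circular_reference()].
#' @export
load_reference <- function(path, strip_n = TRUE) {
  # read as raw strings first: DNA parsing would silently drop bad codes
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) != 1L)
    stop("expected exactly one FASTA record, found ", length(ss))
  seq <- toupper(as.character(ss[[1L]]))
  if (nchar(seq) == 0L) stop("reference sequence is empty")
  nm <- sub("\\s.*$", "", names(ss)[1L])
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (any(!chars %in% c("A", "C", "G", "T", "N")))
    stop("reference contains non-ACGTN characters")
  if (strip_n) {
    keep <- chars != "N"
    circular_reference(nm, paste(chars[keep], collapse = ""),
                       coord_map = which(keep))
  } else {
    if (any(chars == "N"))
      stop("sequence contains N; use strip_n = TRUE")
    circular_reference(nm, seq)
  }
}

#' Write a circular reference to FASTA
#'
#' @param ref a [circular_reference()].
#' @param path output path; the record is wrapped at 70 columns.
#' @export
write_reference <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(setNames(ref$sequence, reference_label(ref)))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

reference_label <- function(ref) {
  if (ref$shift_offset > 0L) paste0(ref$name, "_shift", ref$shift_offset)
  else ref$name
}

#' Rotate a circular reference so its origin moves to the sequence midpoint
#'
#' Reads spanning the original origin cannot align contiguously against the
#' original orientation; against the rotated copy they can, which is what the
#' dual-orientation merge exploits. The shift is `floor(L/2)`: original
#' position `s + 1` becomes shifted position 1.
#'
#' @param ref an unshifted [circular_reference()].
#' @return the shifted copy, with `shift_offset = floor(L/2)`.
#' @export
shift_reference <- function(ref) {
  stopifnot(inherits(ref, "circular_reference"))
  if (ref$shift_offset != 0L)
    stop("reference is already shifted (offset ", ref$shift_offset, ")")
  s <- ref$length %/% 2L
  rotated <- paste0(substr(ref$sequence, s + 1L, ref$length),
                    substr(ref$sequence, 1L, s))
  out <- circular_reference(ref$name, rotated, shift_offset = s,
                            coord_map = ref$coord_map[c((s + 1L):ref$length, 1L:s)])
  out
}

#' Map a position in the shifted orientation back to original numbering
#'
#' @param p_shifted 1-based position(s) in the shifted orientation.
#' @param s shift offset (bases).
#' @param L reference length.
#' @return 1-based position(s) in the original orientation.
#' @export
unshift_position <- function(p_shifted, s, L) {
  if (any(p_shifted < 1L | p_shifted > L))
    stop("position out of range [1, ", L, "]")
  ((p_shifted - 1L + s) %% L) + 1L
}
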