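#' Read alignment records from a SAM text file
#'
#' Parses the mandatory SAM fields into a tibble of alignment records.
#' Unmapped records (FLAG 0x4) and records whose reference name is absent
#' from the header are skipped; their counts are reported with a message.
#'
#' @param path SAM text file with an `@SQ` header line naming the reference.
#' @return a tibble with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`, `strand` and the header's reference
#'   name/length as attributes `reference_name`/`reference_length`.
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path)
  is_hdr <- startsWith(lines, "@")
  hdr <- lines[is_hdr]
  sq <- hdr[startsWith(hdr, "@SQ")]
  refs <- character(0)
  ref_len <- integer(0)
  for (h in sq) {
    f <- strsplit(h, "\t", fixed = TRUE)[[1L]]
    sn <- sub("^SN:", "", f[startsWith(f, "SN:")][1L])
    ln <- as.integer(sub("^LN:", "", f[startsWith(f, "LN:")][1L]))
    refs <- c(refs, sn)
    ref_len <- c(ref_len, ln)
  }
  body_idx <- which(!is_hdr & nzchar(lines))
  if (length(body_idx) == 0L) {
    out <- tibble::tibble(qname = character(), flag = integer(),
                          rname = character(), pos = integer(),
                          mapq = integer(), cigar = character(),
                          seq = character(), qual = character(),
                          strand = character())
  } else {
    fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11L)) {
      bad <- body_idx[which(nf < 11L)[1L]]
      stop("malformed SAM record at line ", bad, ": fewer than 11 fields")
    }
    m <- matrix(unlist(lapply(fields, `[`, 1:11)), ncol = 11L, byrow = TRUE)
    flag <- suppressWarnings(as.integer(m[, 2L]))
    pos <- suppressWarnings(as.integer(m[, 4L]))
    mapq <- suppressWarnings(as.integer(m[, 5L]))
    bad <- which(is.na(flag) | is.na(pos) | is.na(mapq))
    if (length(bad) > 0L)
      stop("malformed SAM record at line ", body_idx[bad[1L]],
           ": non-numeric FLAG/POS/MAPQ")
    out <- tibble::tibble(
      qname = m[, 1L], flag = flag, rname = m[, 3L], pos = pos, mapq = mapq,
      cigar = m[, 6L], seq = m[, 10L], qual = m[, 11L],
      strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"))
    unmapped <- bitwAnd(out$flag, 4L) > 0L | out$rname == "*"
    off_ref <- !unmapped & !(out$rname %in% refs)
    if (any(unmapped) || any(off_ref))
      message("read_sam: skipped ", sum(unmapped), " unmapped and ",
              sum(off_ref), " off-reference record(s)")
    out <- out[!unmapped & !off_ref, ]
    keep <- out$pos >= 1L
    out <- out[keep, ]
    bad_len <- cigar_query_length(out$cigar) != nchar(out$seq) |
      nchar(out$seq) != nchar(out$qual)
    if (any(bad_len))
      stop("SAM record '", out$qname[which(bad_len)[1L]],
           "': CIGAR query length does not match SEQ/QUAL length")
  }
  attr(out, "reference_name") <- if (length(refs)) refs[1L] else NA_character_
  attr(out, "reference_length") <- if (length(ref_len)) ref_len[1L] else NA_integer_
  out
}

cigar_query_length <- function(cigar) {
  vapply(cigar, function(cg) {
    len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
    op <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1L]]
    sum(len[op %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Write alignment records to a SAM text file
#'
#' @param alignments tibble as returned by [read_sam()] or
#'   [simulate_reads()]; must contain `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`.
#' @param reference_name,reference_length `@SQ` header values.
#' @param path output path.
#' @export
write_sam <- function(alignments, reference_name, reference_length, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", reference_name, "\tLN:", reference_length))
  body <- paste(alignments$qname, alignments$flag, alignments$rname,
                alignments$pos, alignments$mapq, alignments$cigar,
                "*", 0L, 0L, alignments$seq, alignments$qual, sep = "\t")
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

position_report_columns <- c(
  "Covmp", "PercentCov", "FilterCov", "Ref", "Var", "Cons", "FastA",
  "QDepth", "Reads1", "Reads2", "Freq", "Pvalue", "StrandFilter",
  "R1plus", "R1minus", "R2plus", "R2minus")

format_report_block <- function(rows) {
  tibble::tibble(
    Covmp = as.character(rows$Covmp),
    PercentCov = sprintf("%.2f", rows$PercentCov),
    FilterCov = rows$FilterCov,
    Ref = rows$Ref,
    Var = ifelse(is.na(rows$Var), "", rows$Var),
    Cons = rows$Cons,
    FastA = rows$FastA,
    QDepth = as.character(rows$QDepth),
    Reads1 = as.character(rows$Reads1),
    Reads2 = as.character(rows$Reads2),
    Freq = sprintf("%.2f", rows$Freq),
    Pvalue = sprintf("%.4g", rows$Pvalue),
    StrandFilter = rows$StrandFilter,
    R1plus = as.character(rows$R1plus),
    R1minus = as.character(rows$R1minus),
    R2plus = as.character(rows$R2plus),
    R2minus = as.character(rows$R2minus))
}

#' Write the per-position CSV report
#'
#' One line per reference position (reported numbering), with one block of
#' columns per sample in a fixed schema: coverage, relative coverage and its
#' flag, reference/variant/consensus symbols, quality depth, reference and
#' variant read counts with strand split, variant frequency (percent, two
#' decimals), the exact-test p-value and the strand filter.
#'
#' @param reports a single position report (from [call_sample()]) or a named
#'   list of reports for several samples sharing one reference.
#' @param path output CSV path.
#' @export
write_position_report <- function(reports, path) {
  if (inherits(reports, "data.frame")) {
    nm <- attr(reports, "sample")
    reports <- setNames(list(reports), if (is.null(nm)) "sample1" else nm)
  }
  if (is.null(names(reports)) || any(!nzchar(names(reports))))
    names(reports) <- paste0("sample", seq_along(reports))
  ok <- vapply(reports, function(r) identical(r$Position, reports[[1L]]$Position),
               logical(1))
  if (!all(ok)) stop("all samples must share one reference (same positions)")
  out <- tibble::tibble(Chrom = reports[[1L]]$Chrom,
                        Position = reports[[1L]]$Position)
  for (nm in names(reports)) {
    block <- format_report_block(reports[[nm]])
    names(block) <- paste(nm, names(block), sep = ".")
    out <- dplyr::bind_cols(out, block)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a per-position CSV report
#'
#' Inverse of [write_position_report()]; returns a named list of per-sample
#' tibbles with numeric columns restored.
#'
#' @param path CSV path written by [write_position_report()].
#' @export
read_position_report <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  samples <- unique(sub("\\.[^.]+$", "", setdiff(names(raw), c("Chrom", "Position"))))
  out <- lapply(samples, function(nm) {
    block <- raw[paste(nm, position_report_columns, sep = ".")]
    names(block) <- position_report_columns
    tibble::tibble(
      Chrom = raw$Chrom, Position = as.integer(raw$Position),
      Covmp = as.integer(block$Covmp),
      PercentCov = as.numeric(block$PercentCov),
      FilterCov = block$FilterCov, Ref = block$Ref,
      Var = ifelse(is.na(block$Var) | block$Var == "", NA_character_, block$Var),
      Cons = block$Cons, FastA = block$FastA,
      QDepth = as.integer(block$QDepth),
      Reads1 = as.integer(block$Reads1), Reads2 = as.integer(block$Reads2),
      Freq = as.numeric(block$Freq), Pvalue = as.numeric(block$Pvalue),
      StrandFilter = block$StrandFilter,
      R1plus = as.integer(block$R1plus), R1minus = as.integer(block$R1minus),
      R2plus = as.integer(block$R2plus), R2minus = as.integer(block$R2minus))
  })
  setNames(out, samples)
}

#' Consensus sequence from a position report
#'
#' Concatenates the per-position `FastA` symbols (major allele, or N where
#' the position is coverage-excluded). In the default substitution-only mode
#' the consensus length always equals the reference length, keeping
#' coordinates stable for downstream haplogroup tools; `apply_indels = TRUE`
#' additionally applies insertions/deletions whose frequency exceeds 50%.
#'
#' @param report a position report tibble.
#' @param apply_indels apply majority indels (changes sequence length).
#' @return a nucleotide string.
#' @export
consensus_seq <- function(report, apply_indels = FALSE) {
  chars <- report$FastA
  if (apply_indels) {
    idx <- order(report$Position, decreasing = TRUE)
    for (i in idx) {
      v <- report$Var[i]
      if (is.na(v) || report$Freq[i] <= 50 || report$FilterCov[i] == "EXCLUDE") next
      if (startsWith(v, "+")) {
        chars[i] <- paste0(chars[i], substring(v, 2L))
      } else if (startsWith(v, "-")) {
        del_len <- nchar(v) - 1L
        rm <- which(report$Position > report$Position[i])[seq_len(del_len)]
        chars[rm[!is.na(rm)]] <- ""
      }
    }
  }
  paste(chars, collapse = "")
}

#' Write the consensus FASTA for one sample
#'
#' @param report a position report tibble.
#' @param sample_name FASTA record name.
#' @param path output path.
#' @param apply_indels see [consensus_seq()].
#' @export
write_consensus <- function(report, sample_name, path, apply_indels = FALSE) {
  seq <- consensus_seq(report, apply_indels = apply_indels)
  ss <- Biostrings::DNAStringSet(setNames(seq, sample_name))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write simulated reads as a FASTQ pair
#'
#' Minus-strand reads are reverse-complemented back to sequencing
#' orientation. Qualities are phred+33.
#'
#' @param reads tibble with `qname`, `mate`, `strand`, `seq`, `qual`.
#' @param path_r1,path_r2 output FASTQ paths for mates 1 and 2.
#' @export
write_fastq_pair <- function(reads, path_r1, path_r2) {
  for (m in 1:2) {
    sub <- reads[reads$mate == m, ]
    seqs <- Biostrings::DNAStringSet(sub$seq)
    flip <- sub$strand == "-"
    seqs[flip] <- Biostrings::reverseComplement(seqs[flip])
    names(seqs) <- paste0(sub$qname, "/", m)
    q <- Biostrings::BStringSet(sub$qual)
    qs <- Biostrings::QualityScaledDNAStringSet(
      seqs, Biostrings::PhredQuality(q))
    Biostrings::writeQualityScaledXStringSet(qs, if (m == 1) path_r1 else path_r2)
  }
  invisible(c(path_r1, path_r2))
}
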