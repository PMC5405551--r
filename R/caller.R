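#' Variant-calling parameters
#'
#' Defaults reproduce the published calling setup: p-value threshold 0.001
#' and minimum variant frequency 0.1%, with a fixed per-base sequencing
#' error rate of 0.1% as the null model, a VarScan-like minimum of 2
#' variant-supporting reads, and a 90% strand-bias annotation threshold.
#'
#' @param min_var_freq minimum variant allele fraction (default 0.001).
#' @param p_threshold significance threshold (default 0.001).
#' @param error_rate null per-allele error rate `e` (default 0.001).
#' @param strand_bias_max maximum fraction of variant support on one strand
#'   before the strand filter reports `Fail` (default 0.90).
#' @param min_reads2 minimum variant-supporting reads (default 2).
#' @return a list of class `call_params`.
#' @export
call_params <- function(min_var_freq = 0.001, p_threshold = 0.001,
                        error_rate = 0.001, strand_bias_max = 0.90,
                        min_reads2 = 2L) {
  stopifnot(min_var_freq >= 0, min_var_freq <= 1, p_threshold >= 0,
            p_threshold <= 1, error_rate >= 0, error_rate <= 1,
            strand_bias_max >= 0, strand_bias_max <= 1, min_reads2 >= 0)
  structure(list(min_var_freq = min_var_freq, p_threshold = p_threshold,
                 error_rate = error_rate, strand_bias_max = strand_bias_max,
                 min_reads2 = as.integer(min_reads2)),
            class = "call_params")
}

#' Exact-test significance of variant support
#'
#' One-sided Fisher exact test that the observed variant support exceeds
#' what a fixed per-allele error rate `e` would produce: the observed counts
#' `(reads1, reads2)` are tested against expected counts
#' `(round(d*(1-e)), round(d*e))` with `d = reads1 + reads2`, right tail
#' (variant enrichment), computed as a hypergeometric tail. Returns 1 when
#' `reads2 = 0`. Vectorized over `reads1`/`reads2`.
#'
#' @param reads1 reference-supporting read count(s).
#' @param reads2 variant-supporting read count(s).
#' @param error_rate null per-allele error rate (default 0.001).
#' @return p-value(s) in `[0, 1]`.
#' @export
variant_significance <- function(reads1, reads2, error_rate = 0.001) {
  if (any(reads1 < 0) || any(reads2 < 0)) stop("read counts must be >= 0")
  n <- max(length(reads1), length(reads2))
  reads1 <- rep_len(reads1, n)
  reads2 <- rep_len(reads2, n)
  d <- reads1 + reads2
  e2 <- round(d * error_rate)
  e1 <- round(d * (1 - error_rate))
  # fixed-margin 2x2 [[reads1, reads2], [e1, e2]]; right tail on reads2
  total <- d + e1 + e2
  k <- reads2 + e2
  p <- phyper(reads2 - 1, k, total - k, d, lower.tail = FALSE)
  p[reads2 == 0] <- 1
  p[d == 0] <- 1
  pmin(pmax(p, 0), 1)
}

#' Strand-bias annotation for variant support
#'
#' @param r2_plus,r2_minus variant-supporting reads per strand.
#' @param strand_bias_max maximum tolerated fraction on one strand.
#' @return `"Pass"`, `"Fail"`, or `"NA"` (no variant support); vectorized.
#' @export
strand_bias_filter <- function(r2_plus, r2_minus, strand_bias_max = 0.90) {
  tot <- r2_plus + r2_minus
  out <- rep("Pass", length(tot))
  out[tot == 0] <- "NA"
  frac <- ifelse(tot > 0, pmax(r2_plus, r2_minus) / tot, 0)
  out[tot > 0 & frac > strand_bias_max] <- "Fail"
  out
}

#' Per-position variant calls from a pileup
#'
#' The mpileup2cns analogue: every position yields a row. The candidate
#' variant at a position is the non-reference allele (SNV, insertion or
#' deletion) with the highest qualified count; ties break deterministically
#' (A < C < G < T, SNV before insertion before deletion). The `pass` column
#' records whether the candidate clears the frequency, support and p-value
#' filters; counts and frequency are reported for every position regardless.
#' Insertions are reported as `+SEQ` anchored at the reported position,
#' deletions as `-SEQ` starting at the next position.
#'
#' @param pileup a [build_pileup()] result.
#' @param params a [call_params()].
#' @return a tibble with one row per position: `position`, `ref`, `var`,
#'   `type` (`SNV`/`INS`/`DEL`/`NONE`), `reads1`, `reads2`, strand splits,
#'   `freq` (fraction), `p_value`, `strand_filter`, `pass`, plus `covmp`,
#'   `qdepth` carried from the pileup.
#' @export
call_positions <- function(pileup, params = call_params()) {
  stopifnot(inherits(pileup, "mitohet_pileup"))
  pos <- pileup$positions
  L <- nrow(pos)
  base_cols <- c("A", "C", "G", "T")
  plus <- as.matrix(pos[paste0(base_cols, "_plus")])
  minus <- as.matrix(pos[paste0(base_cols, "_minus")])
  tot <- plus + minus
  ref_idx <- match(pos$ref, base_cols)
  ii <- cbind(seq_len(L), ref_idx)
  reads1 <- tot[ii]
  r1p <- plus[ii]
  r1m <- minus[ii]

  alt <- tot
  alt[ii] <- -1L
  alt_idx <- max.col(alt, ties.method = "first")
  ai <- cbind(seq_len(L), alt_idx)
  snv_count <- pmax(alt[ai], 0L)
  snv_p <- plus[ai]
  snv_m <- minus[ai]

  # best indel per anchor: highest count, then INS before DEL, then seq order
  ind <- pileup$indels
  if (nrow(ind) > 0L) {
    ind <- dplyr::mutate(ind, count = .data$plus + .data$minus)
    ind <- dplyr::arrange(ind, .data$anchor, dplyr::desc(.data$count),
                          .data$type, .data$seq)
    ind <- dplyr::slice_head(dplyr::group_by(ind, .data$anchor), n = 1L)
    ind <- dplyr::ungroup(ind)
  } else {
    ind <- dplyr::mutate(ind, count = integer(0))
  }
  ind_count <- integer(L)
  ind_type <- character(L)
  ind_seq <- character(L)
  ind_p <- integer(L)
  ind_m <- integer(L)
  if (nrow(ind) > 0L) {
    ind_count[ind$anchor] <- ind$count
    ind_type[ind$anchor] <- ind$type
    ind_seq[ind$anchor] <- ind$seq
    ind_p[ind$anchor] <- ind$plus
    ind_m[ind$anchor] <- ind$minus
  }

  use_snv <- snv_count >= ind_count  # tie goes to the SNV
  reads2 <- ifelse(use_snv, snv_count, ind_count)
  r2p <- ifelse(use_snv, snv_p, ind_p)
  r2m <- ifelse(use_snv, snv_m, ind_m)
  # for an indel candidate, reads1 must count only reads that genuinely
  # support the reference across the junction: an indel-carrying read also
  # matches the reference base at the anchor (do not double-count it), and a
  # read whose alignment terminates exactly at the anchor cannot witness the
  # junction at all (it is uninformative, not reference support)
  ends_p <- pos$ends_plus
  ends_m <- pos$ends_minus
  r1p <- ifelse(use_snv, r1p, pmax(r1p - ind_p - ends_p, 0L))
  r1m <- ifelse(use_snv, r1m, pmax(r1m - ind_m - ends_m, 0L))
  reads1 <- ifelse(use_snv, reads1, r1p + r1m)
  var <- ifelse(use_snv, base_cols[alt_idx],
                paste0(ifelse(ind_type == "INS", "+", "-"), ind_seq))
  type <- ifelse(use_snv, "SNV", ind_type)
  none <- reads2 == 0L
  var[none] <- NA_character_
  type[none] <- "NONE"

  denom <- reads1 + reads2
  freq <- ifelse(denom > 0, reads2 / denom, 0)
  p_value <- variant_significance(reads1, reads2, params$error_rate)
  strand_filter <- strand_bias_filter(r2p, r2m, params$strand_bias_max)
  pass <- !none & freq >= params$min_var_freq &
    reads2 >= params$min_reads2 & p_value <= params$p_threshold

  tibble::tibble(
    position = pos$position, ref = pos$ref, var = var, type = type,
    reads1 = as.integer(reads1), reads2 = as.integer(reads2),
    r1_plus = as.integer(r1p), r1_minus = as.integer(r1m),
    r2_plus = as.integer(r2p), r2_minus = as.integer(r2m),
    freq = freq, p_value = p_value, strand_filter = strand_filter,
    pass = pass, covmp = pos$covmp, qdepth = pos$qdepth)
}

#' Filter per-position calls to passing variants
#'
#' The mpileup2snp / mpileup2indel analogue: keeps rows whose candidate
#' passes all filters, optionally restricted by variant kind.
#'
#' @param calls output of [call_positions()] (or a position report).
#' @param kind `"all"`, `"snp"` (SNVs only) or `"indel"`.
#' @param hard_strand_filter drop calls whose strand filter is `Fail`
#'   (default `FALSE`: the strand filter annotates but does not remove).
#' @return the filtered tibble.
#' @export
call_variants <- function(calls, kind = c("all", "snp", "indel"),
                          hard_strand_filter = FALSE) {
  kind <- match.arg(kind)
  keep <- calls$pass & calls$type != "NONE"
  if (kind == "snp") keep <- keep & calls$type == "SNV"
  if (kind == "indel") keep <- keep & calls$type %in% c("INS", "DEL")
  if (hard_strand_filter) keep <- keep & calls$strand_filter != "Fail"
  calls[keep, ]
}
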