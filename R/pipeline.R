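#' Per-position rows for one reference orientation
#'
#' Runs pileup construction and per-position calling for alignments against
#' one orientation and assembles the report columns (positions still in that
#' orientation's coordinates).
#'
#' @param alignments alignment tibble for this orientation.
#' @param ref the [circular_reference()] in the same orientation.
#' @param filter a [filter_params()].
#' @param call a [call_params()].
#' @return tibble of per-position report rows.
#' @export
frame_rows <- function(alignments, ref, filter = filter_params(),
                       call = call_params()) {
  pu <- build_pileup(alignments, ref, filter)
  calls <- call_positions(pu, call)
  tibble::tibble(
    Position = calls$position,
    Covmp = calls$covmp,
    Ref = calls$ref,
    Var = calls$var,
    Type = calls$type,
    QDepth = calls$qdepth,
    Reads1 = calls$reads1, Reads2 = calls$reads2,
    Freq = 100 * calls$freq,
    Pvalue = calls$p_value,
    StrandFilter = calls$strand_filter,
    R1plus = calls$r1_plus, R1minus = calls$r1_minus,
    R2plus = calls$r2_plus, R2minus = calls$r2_minus,
    Pass = calls$pass)
}

#' Run the full per-sample pipeline
#'
#' Pileup and per-position calling against the original orientation and
#' (by default) the origin-shifted orientation, best-coverage merge of the
#' two, relative coverage and flags, coverage masking (EXCLUDE positions get
#' an N consensus and 0% frequency), and consensus symbols. Positions in the
#' result use reported numbering (the reference's coordinate map, e.g. rCRS
#' numbering when an rCRS-style N was stripped).
#'
#' @param aln_original alignments against the original orientation.
#' @param aln_shifted alignments against the shifted orientation, or `NULL`
#'   for single-orientation mode (origin-adjacent positions will be
#'   under-covered and flagged accordingly).
#' @param ref the unshifted [circular_reference()].
#' @param filter a [filter_params()].
#' @param call a [call_params()].
#' @param flags a [flag_thresholds()].
#' @param sample sample name recorded on the report.
#' @return a position report: tibble of class `mitohet_report` with one row
#'   per reference position and the Table-style columns (`Chrom`,
#'   `Position`, `Covmp`, `PercentCov`, `FilterCov`, `Ref`, `Var`, `Cons`,
#'   `FastA`, `QDepth`, `Reads1`, `Reads2`, `Freq`, `Pvalue`,
#'   `StrandFilter`, `R1plus`, `R1minus`, `R2plus`, `R2minus`) plus `Type`
#'   and `Pass`.
#' @export
call_sample <- function(aln_original, aln_shifted = NULL, ref,
                        filter = filter_params(), call = call_params(),
                        flags = flag_thresholds(), sample = "sample1") {
  stopifnot(inherits(ref, "circular_reference"), ref$shift_offset == 0L)
  rows <- frame_rows(aln_original, ref, filter, call)
  if (!is.null(aln_shifted)) {
    ref_s <- shift_reference(ref)
    rows_s <- frame_rows(aln_shifted, ref_s, filter, call)
    rows <- merge_dual(rows, rows_s, ref_s$shift_offset, ref$length)
  }
  rows <- relative_coverage(rows)
  rows$FilterCov <- flag_coverage(rows$PercentCov, flags)

  # consensus symbols: major allele, indels never alter the base column
  major_var <- !is.na(rows$Var) & rows$Freq > 50
  rows$Cons <- ifelse(major_var, rows$Var, rows$Ref)
  rows$FastA <- ifelse(major_var & rows$Type == "SNV", rows$Var, rows$Ref)

  # coverage masking
  excl <- rows$FilterCov == "EXCLUDE"
  rows$FastA[excl] <- "N"
  rows$Freq[excl] <- 0
  rows$Pass[excl] <- FALSE

  rows$Chrom <- ref$name
  rows$Position <- ref$coord_map[rows$Position]
  rows <- dplyr::arrange(rows, .data$Position)
  out <- rows[, c("Chrom", "Position", "Covmp", "PercentCov", "FilterCov",
                  "Ref", "Var", "Cons", "FastA", "QDepth", "Reads1",
                  "Reads2", "Freq", "Pvalue", "StrandFilter", "R1plus",
                  "R1minus", "R2plus", "R2minus", "Type", "Pass")]
  attr(out, "sample") <- sample
  attr(out, "reference_name") <- ref$name
  attr(out, "reference_length") <- ref$length
  class(out) <- c("mitohet_report", class(out))
  out
}

#' Run the pipeline from files
#'
#' File-level wrapper used by the command-line interface: reads the
#' reference and the two SAM files, runs [call_sample()], and writes the
#' per-position CSV report, the consensus FASTA and a config echo.
#'
#' @param sam_original,sam_shifted SAM paths; `sam_shifted` may be `NULL`
#'   for single-orientation mode.
#' @param reference_path single-record FASTA.
#' @param out_prefix output path prefix.
#' @param sample sample name.
#' @inheritParams call_sample
#' @param strip_n see [load_reference()].
#' @return the position report, invisibly; writes
#'   `<prefix>.positions.csv`, `<prefix>.consensus.fasta`,
#'   `<prefix>.config.txt`.
#' @export
call_sample_files <- function(sam_original, sam_shifted = NULL,
                              reference_path, out_prefix,
                              sample = "sample1", strip_n = TRUE,
                              filter = filter_params(),
                              call = call_params(),
                              flags = flag_thresholds()) {
  ref <- load_reference(reference_path, strip_n = strip_n)
  aln_o <- read_sam(sam_original)
  aln_s <- if (!is.null(sam_shifted)) read_sam(sam_shifted) else NULL
  report <- call_sample(aln_o, aln_s, ref, filter, call, flags, sample)
  write_position_report(report, paste0(out_prefix, ".positions.csv"))
  write_consensus(report, sample, paste0(out_prefix, ".consensus.fasta"))
  cfg <- c(
    paste0("mitohet_version=", as.character(utils::packageVersion("mitohet"))),
    paste0("reference=", reference_path),
    paste0("sam_original=", sam_original),
    paste0("sam_shifted=", if (is.null(sam_shifted)) "" else sam_shifted),
    paste0("sample=", sample),
    paste0("strip_n=", strip_n),
    paste0("min_base_quality=", filter$min_base_quality),
    paste0("min_mapping_quality=", filter$min_mapping_quality),
    paste0("mapq_adjust=", filter$mapq_adjust),
    paste0("min_var_freq=", call$min_var_freq),
    paste0("p_threshold=", call$p_threshold),
    paste0("error_rate=", call$error_rate),
    paste0("strand_bias_max=", call$strand_bias_max),
    paste0("min_reads2=", call$min_reads2),
    paste0("flag_good_min=", flags$good_min),
    paste0("flag_warn_min=", flags$warn_min))
  readr::write_lines(cfg, paste0(out_prefix, ".config.txt"))
  invisible(report)
}

#' @exportS3Method generics::tidy
tidy.mitohet_report <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @exportS3Method generics::glance
glance.mitohet_report <- function(x, ...) {
  tibble::tibble(
    sample = attr(x, "sample"),
    positions = nrow(x),
    mean_coverage = mean(x$Covmp),
    n_good = sum(x$FilterCov == "GOOD"),
    n_warning = sum(x$FilterCov == "WARNING"),
    n_exclude = sum(x$FilterCov == "EXCLUDE"),
    n_variants = sum(x$Pass))
}

#' Coverage plot for a position report
#'
#' Relative coverage along the genome, colored by flag, with the flag
#' thresholds drawn.
#'
#' @param object a `mitohet_report`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.mitohet_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Position, y = .data$PercentCov,
                                   color = .data$FilterCov)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::geom_hline(yintercept = c(1, 10), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(GOOD = "#2c7fb8",
                                           WARNING = "#fe9929",
                                           EXCLUDE = "#d7301f")) +
    ggplot2::labs(x = "position", y = "coverage (% of sample mean)",
                  color = "flag", title = attr(object, "sample"))
}
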