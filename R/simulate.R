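#' Random circular reference sequence
#'
#' Uniform base composition, with an 8-A homopolymer planted at
#' `homopolymer_at` (for benchmarking indel calling in the hardest common
#' context) unless `homopolymer_at = NULL`. Draws from the current RNG
#' stream; call `set.seed()` beforehand for reproducibility.
#'
#' @param length reference length in bases (default 16569, a human
#'   mitochondrial genome size).
#' @param name sequence name.
#' @param homopolymer_at 1-based start of a planted `AAAAAAAA` run, or
#'   `NULL`.
#' @return a [circular_reference()].
#' @export
random_circular_reference <- function(length = 16569L, name = "chrM_sim",
                                      homopolymer_at = round(0.59 * length)) {
  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  if (!is.null(homopolymer_at)) {
    run <- homopolymer_at:(homopolymer_at + 7L)
    chars[run] <- "A"
    # break up the run's borders so the planted homopolymer is exactly 8 A
    chars[homopolymer_at - 1L] <- "C"
    chars[homopolymer_at + 8L] <- "C"
  }
  circular_reference(name, paste(chars, collapse = ""))
}

#' Two-haplotype mixture design
#'
#' Describes the benchmark: one circular reference, a second haplotype
#' differing from it at a set of homoplasmic SNVs and small insertions, a
#' grid of mixture ratios, and sequencing parameters. Defaults reproduce the
#' published benchmark design: 88 SNVs, a +G insertion and a +AA insertion
#' immediately before an 8-A homopolymer, 12 mixture ratios spanning 0-100%
#' (including 0.4, 0.8, 1.6 and 50), 2x150 paired reads at 3,000X mean
#' coverage with 0.1% substitution and 0.01% one-base indel error at
#' phred-40 base quality.
#'
#' SNV positions are drawn at random (excluding the insertion contexts and
#' each other's immediate neighborhood) unless `snv_set` is supplied. Draws
#' from the current RNG stream; call `set.seed()` beforehand.
#'
#' @param reference a [circular_reference()], or `NULL` to generate one via
#'   [random_circular_reference()].
#' @param n_snv number of engineered SNVs (default 88).
#' @param snv_set optional tibble (`position`, `ref`, `alt`) overriding the
#'   random draw.
#' @param indel_set optional tibble (`anchor`, `seq`) of insertions; default
#'   `+G` at ~31% of the genome and `+AA` immediately before the planted
#'   8-A homopolymer. Use a zero-row tibble for no indels.
#' @param ratios minor-haplotype percentages (default
#'   `c(0, 0.4, 0.8, 1.6, 3.2, 6.25, 12.5, 25, 50, 75, 90, 100)`).
#' @param coverage mean sequencing depth (default 3000).
#' @param read_length read length in bases (default 150).
#' @param fragment_length fragment length; mates are adjacent (default 300).
#' @param substitution_error per-base substitution miscall rate
#'   (default 0.001).
#' @param indel_error per-base one-base indel error rate (default 1e-4).
#' @return a list of class `mixture_design`.
#' @export
mixture_design <- function(reference = NULL, n_snv = 88L, snv_set = NULL,
                           indel_set = NULL,
                           ratios = c(0, 0.4, 0.8, 1.6, 3.2, 6.25, 12.5,
                                      25, 50, 75, 90, 100),
                           coverage = 3000, read_length = 150L,
                           fragment_length = 300L,
                           substitution_error = 0.001, indel_error = 1e-4) {
  if (is.null(reference)) reference <- random_circular_reference()
  stopifnot(inherits(reference, "circular_reference"),
            reference$shift_offset == 0L)
  L <- reference$length
  if (read_length > L) stop("read length exceeds reference length")
  if (any(ratios < 0 | ratios > 100)) stop("ratios must be in [0, 100]")
  refc <- strsplit(reference$sequence, "", fixed = TRUE)[[1L]]

  if (is.null(indel_set)) {
    hp <- find_homopolymer(reference$sequence, "A", 8L)
    if (is.na(hp)) stop("reference has no 8-A homopolymer; supply indel_set ",
                        "or a reference with one")
    indel_set <- tibble::tibble(
      anchor = c(round(0.31 * L), hp - 1L),
      seq = c("G", "AA"))
  }
  if (is.null(snv_set)) {
    # keep SNVs away from the insertion contexts and distinct
    excluded <- unique(unlist(lapply(indel_set$anchor, function(a)
      (a - 10L):(a + nchar(indel_set$seq[indel_set$anchor == a][1L]) + 10L))))
    pool <- setdiff(seq_len(L), excluded)
    pos <- sort(sample(pool, n_snv))
    alt <- vapply(refc[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
      USE.NAMES = FALSE)
    snv_set <- tibble::tibble(position = pos, ref = refc[pos], alt = alt)
  }
  if (anyDuplicated(snv_set$position) ||
      length(intersect(snv_set$position, indel_set$anchor)) > 0L)
    stop("engineered variants overlap")
  if (any(refc[snv_set$position] != snv_set$ref))
    stop("snv_set reference bases do not match the reference sequence")
  structure(list(reference = reference, snv_set = snv_set,
                 indel_set = indel_set, ratios = ratios, coverage = coverage,
                 read_length = as.integer(read_length),
                 fragment_length = as.integer(fragment_length),
                 substitution_error = substitution_error,
                 indel_error = indel_error),
            class = "mixture_design")
}

find_homopolymer <- function(seq, base, len) {
  m <- regexpr(paste0(base, "{", len, ",}"), seq)
  if (m < 0) NA_integer_ else as.integer(m)
}

#' @export
print.mixture_design <- function(x, ...) {
  cat("<mixture_design> L=", x$reference$length, ", ", nrow(x$snv_set),
      " SNV + ", nrow(x$indel_set), " insertion(s), ",
      length(x$ratios), " ratio(s), ", x$coverage, "X\n", sep = "")
  invisible(x)
}

#' Build the two haplotype sequences and the truth table
#'
#' Haplotype A is the reference; haplotype B carries every engineered SNV
#' and insertion. The truth table reports each variant with its anchor in
#' reference coordinates, already left-aligned the same way the pileup
#' normalizes observed indels, so truth rows compare directly with calls.
#'
#' @param design a [mixture_design()].
#' @return list with `hap_a`, `hap_b` (strings), `map_b` (integer vector:
#'   haplotype-B position -> reference position, 0 for inserted bases), and
#'   `truth` (tibble: `position`, `type`, `ref`, `var`).
#' @export
make_haplotypes <- function(design) {
  ref <- design$reference
  refc <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
  hapc <- refc
  hapc[design$snv_set$position] <- design$snv_set$alt
  map <- seq_len(ref$length)
  # apply insertions right-to-left so earlier anchors stay valid
  ins <- design$indel_set[order(design$indel_set$anchor, decreasing = TRUE), ]
  for (i in seq_len(nrow(ins))) {
    a <- ins$anchor[i]
    s <- strsplit(ins$seq[i], "", fixed = TRUE)[[1L]]
    hapc <- append(hapc, s, after = a)
    map <- append(map, rep(0L, length(s)), after = a)
  }
  truth_snv <- tibble::tibble(position = design$snv_set$position,
                              type = "SNV", ref = design$snv_set$ref,
                              var = design$snv_set$alt)
  truth_ind <- tibble::tibble(position = integer(0), type = character(0),
                              ref = character(0), var = character(0))
  if (nrow(design$indel_set) > 0L) {
    la <- left_align_indels(
      tibble::tibble(anchor = design$indel_set$anchor, type = "INS",
                     seq = design$indel_set$seq, plus = 0L, minus = 0L),
      ref$sequence)
    truth_ind <- tibble::tibble(position = la$anchor, type = "INS",
                                ref = refc[la$anchor],
                                var = paste0("+", la$seq))
  }
  list(hap_a = ref$sequence, hap_b = paste(hapc, collapse = ""),
       map_b = as.integer(map),
       truth = dplyr::arrange(dplyr::bind_rows(truth_snv, truth_ind),
                              .data$position))
}

#' Simulate a sequencing run of one mixture
#'
#' Draws read pairs uniformly on the haplotype circle, assigns each fragment
#' to haplotype B with probability `ratio/100`, injects substitution and
#' one-base indel errors at the design rates (phred-40 qualities
#' throughout: errors model miscalls, not low-confidence calls), and emits
#' each read, with its ground-truth alignment at mapping quality 60, in
#' every orientation where its mapping is contiguous: reads spanning the
#' original origin appear only in the shifted alignments and vice versa.
#' Draws from the current RNG stream; call `set.seed()` beforehand.
#'
#' @param design a [mixture_design()].
#' @param ratio minor-haplotype percentage in `[0, 100]`.
#' @param write_dir if non-`NULL`, also write `reads_R1.fastq`,
#'   `reads_R2.fastq`, `original.sam`, `shifted.sam`, `reference.fasta`,
#'   `reference_shifted.fasta` and `truth.csv` into this directory.
#' @return list of class `mixture_run` with `original` and `shifted`
#'   alignment tibbles (ready for [call_sample()]), `reads` (all reads with
#'   both projections), `truth`, `ratio` and `design`.
#' @export
simulate_reads <- function(design, ratio, write_dir = NULL) {
  stopifnot(inherits(design, "mixture_design"), ratio >= 0, ratio <= 100)
  ref <- design$reference
  L <- ref$length
  hap <- make_haplotypes(design)
  n_pairs <- as.integer(round(design$coverage * L /
                                (2 * design$read_length)))
  s <- L %/% 2L
  raw <- sim_read_pairs_cpp(hap$hap_a, hap$hap_b, hap$map_b, L, n_pairs,
                            design$read_length, design$fragment_length,
                            ratio, design$substitution_error,
                            design$indel_error, s)
  reads <- tibble::as_tibble(raw)
  reads$qual <- strrep(rawToChar(as.raw(33L + 40L)), nchar(reads$seq))
  # SAM flags: paired, proper pair, mate strand, first/second in pair
  reads$flag <- 1L + 2L +
    ifelse(reads$strand == "-", 16L, 32L) +
    ifelse(reads$mate == 1L, 64L, 128L)

  frame <- function(ok, pos, cigar, rname) {
    sub <- reads[ok, ]
    tibble::tibble(qname = sub$qname, flag = sub$flag, rname = rname,
                   pos = pos[ok], mapq = 60L, cigar = cigar[ok],
                   seq = sub$seq, qual = sub$qual, strand = sub$strand)
  }
  ref_s <- shift_reference(ref)
  out <- structure(
    list(original = frame(reads$ok_orig, reads$pos_orig, reads$cigar_orig,
                          ref$name),
         shifted = frame(reads$ok_shift, reads$pos_shift, reads$cigar_shift,
                         reference_label(ref_s)),
         reads = reads, truth = hap$truth, ratio = ratio, design = design),
    class = "mixture_run")
  if (!is.null(write_dir)) {
    dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(write_dir, f)
    write_fastq_pair(reads, fp("reads_R1.fastq"), fp("reads_R2.fastq"))
    write_sam(out$original, ref$name, L, fp("original.sam"))
    write_sam(out$shifted, reference_label(ref_s), L, fp("shifted.sam"))
    write_reference(ref, fp("reference.fasta"))
    write_reference(ref_s, fp("reference_shifted.fasta"))
    readr::write_csv(hap$truth, fp("truth.csv"), progress = FALSE)
  }
  out
}

#' @export
print.mixture_run <- function(x, ...) {
  cat("<mixture_run> ratio ", x$ratio, "%: ", nrow(x$reads), " reads (",
      nrow(x$original), " original-frame, ", nrow(x$shifted),
      " shifted-frame)\n", sep = "")
  invisible(x)
}

#' Calibrate expected mixture frequencies from the 50/50 run
#'
#' The titration's expected frequencies are anchored on the measured mean
#' frequency of the 50/50 mixture: `expected(r) = r * measured_50 / 50`.
#' This absorbs any constant proportionality between nominal input ratio
#' and realized variant fraction.
#'
#' @param ratios theoretical ratios in percent; must contain 50.
#' @param measured_50 measured mean variant frequency (percent) at the
#'   50/50 run.
#' @return list with `expected` (tibble: `ratio`, `expected`) and `factor`.
#' @export
calibrate_ratios <- function(ratios, measured_50) {
  if (!any(ratios == 50)) stop("calibration requires a 50/50 run")
  if (measured_50 <= 0) stop("degenerate calibration: measured 50/50 frequency is not positive")
  factor <- measured_50 / 50
  list(expected = tibble::tibble(ratio = ratios,
                                 expected = ratios * factor),
       factor = factor)
}

#' Accuracy and sensitivity metrics over a titration
#'
#' Computes the benchmark quantities from per-ratio position reports:
#' per-ratio mean measured frequency over the engineered SNVs, calibrated
#' expected frequencies, their Pearson correlation and ordinary
#' least-squares slope (with standard error), per-ratio detection fraction
#' (engineered SNVs passing all default filters), the count of
#' passing-filter SNV calls at non-truth positions (false positives),
#' per-variant signed deviation from expectation, and each variant's local
#' variant density (engineered variants within a 300 bp window centered on
#' it, circular).
#'
#' @param truth truth tibble from [make_haplotypes()].
#' @param reports named list of position reports, one per ratio; names are
#'   the ratio values.
#' @param density_window window width in bases for variant density
#'   (default 300).
#' @return object of class `mitohet_benchmark`.
#' @export
benchmark_metrics <- function(truth, reports, density_window = 300L) {
  ratios <- as.numeric(names(reports))
  if (any(is.na(ratios))) stop("reports must be named by ratio")
  truth_snv <- truth[truth$type == "SNV", ]
  truth_ind <- truth[truth$type != "SNV", ]
  L <- attr(reports[[1L]], "reference_length")

  per_variant <- dplyr::bind_rows(lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    idx <- match(truth_snv$position, r$Position)
    measured <- ifelse(!is.na(r$Var[idx]) & r$Var[idx] == truth_snv$var,
                       r$Freq[idx], 0)
    tibble::tibble(ratio = ratios[i], position = truth_snv$position,
                   var = truth_snv$var, measured = measured,
                   detected = r$Pass[idx] & r$Type[idx] == "SNV" &
                     r$Var[idx] == truth_snv$var & !is.na(r$Var[idx]))
  }))
  per_ratio <- dplyr::summarise(
    dplyr::group_by(per_variant, .data$ratio),
    mean_measured = mean(.data$measured),
    detected_fraction = mean(.data$detected %in% TRUE),
    .groups = "drop")

  cal <- calibrate_ratios(ratios,
                          per_ratio$mean_measured[per_ratio$ratio == 50][1L])
  per_ratio <- dplyr::left_join(per_ratio, cal$expected, by = "ratio")
  per_variant <- dplyr::left_join(per_variant, cal$expected, by = "ratio")
  per_variant$deviation <- per_variant$measured - per_variant$expected

  if (nrow(per_ratio) >= 3L) {
    fit <- lm(mean_measured ~ expected, data = per_ratio)
    slope <- unname(coef(fit)[2L])
    slope_se_ols <- summary(fit)$coefficients[2L, 2L]
  } else {
    slope <- NA_real_
    slope_se_ols <- NA_real_
  }
  # the calibration anchor (mean measured frequency at 50/50) is itself an
  # estimate; its sampling error rescales every expected value and therefore
  # the slope, so it is propagated into the slope standard error
  m50 <- per_variant$measured[per_variant$ratio == 50]
  se_cal <- stats::sd(m50) / sqrt(length(m50)) / 50
  slope_se <- sqrt(slope_se_ols^2 + (slope * se_cal)^2)
  pearson_r <- if (nrow(per_ratio) >= 3L)
    cor(per_ratio$expected, per_ratio$mean_measured) else NA_real_

  # indel detection per ratio
  indel_detection <- dplyr::bind_rows(lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    if (nrow(truth_ind) == 0L) return(NULL)
    idx <- match(truth_ind$position, r$Position)
    tibble::tibble(ratio = ratios[i], position = truth_ind$position,
                   var = truth_ind$var,
                   measured = ifelse(!is.na(r$Var[idx]) &
                                       r$Var[idx] == truth_ind$var,
                                     r$Freq[idx], 0),
                   detected = r$Pass[idx] & r$Var[idx] == truth_ind$var &
                     !is.na(r$Var[idx]))
  }))

  fp <- dplyr::bind_rows(lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    calls <- r[r$Pass & r$Type == "SNV", ]
    calls <- calls[!calls$Position %in% truth_snv$position, ]
    if (nrow(calls) == 0L) return(NULL)
    tibble::tibble(ratio = ratios[i], position = calls$Position,
                   var = calls$Var, freq = calls$Freq)
  }))

  dens <- vapply(truth$position, function(p) {
    d <- abs(truth$position - p)
    d <- pmin(d, L - d)  # circular distance
    sum(d <= density_window / 2)
  }, integer(1))
  density <- tibble::tibble(position = truth$position, type = truth$type,
                            variant_density = dens)

  structure(list(per_ratio = per_ratio, per_variant = per_variant,
                 indel_detection = indel_detection,
                 false_positives = fp,
                 false_positive_count = nrow(fp),
                 pearson_r = pearson_r, slope = slope, slope_se = slope_se,
                 slope_se_ols = slope_se_ols,
                 calibration_factor = cal$factor,
                 variant_density = density),
            class = "mitohet_benchmark")
}

#' Run the full simulate-call-measure benchmark
#'
#' For each ratio in the design, simulates a mixture run, executes the full
#' dual-orientation pipeline, and computes the accuracy/sensitivity metrics.
#' Call `set.seed()` beforehand for reproducibility.
#'
#' @param design a [mixture_design()].
#' @param ratios ratios to run (default `design$ratios`).
#' @param filter,call,flags pipeline parameters.
#' @return a `mitohet_benchmark` (see [benchmark_metrics()]) with the
#'   per-ratio reports attached as `reports`.
#' @export
run_benchmark <- function(design, ratios = design$ratios,
                          filter = filter_params(), call = call_params(),
                          flags = flag_thresholds()) {
  reports <- lapply(ratios, function(r) {
    run <- simulate_reads(design, r)
    call_sample(run$original, run$shifted, design$reference,
                filter, call, flags, sample = paste0("ratio_", r))
  })
  names(reports) <- ratios
  truth <- make_haplotypes(design)$truth
  out <- benchmark_metrics(truth, reports)
  out$reports <- reports
  out
}

#' @export
print.mitohet_benchmark <- function(x, ...) {
  cat("<mitohet_benchmark> ", nrow(x$per_ratio), " ratios: Pearson r = ",
      format(x$pearson_r, digits = 6), ", slope = ",
      format(x$slope, digits = 6), " (se ",
      format(x$slope_se, digits = 3), "), ",
      x$false_positive_count, " false-positive SNV call(s)\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mitohet_benchmark <- function(x, ...) x$per_ratio

#' @exportS3Method generics::glance
glance.mitohet_benchmark <- function(x, ...) {
  tibble::tibble(pearson_r = x$pearson_r, slope = x$slope,
                 slope_se = x$slope_se,
                 calibration_factor = x$calibration_factor,
                 false_positive_count = x$false_positive_count,
                 n_ratios = nrow(x$per_ratio))
}

#' Titration plot for a benchmark result
#'
#' Mean measured SNV frequency versus calibrated expected frequency with
#' the identity line.
#'
#' @param object a `mitohet_benchmark`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.mitohet_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$per_ratio,
                  ggplot2::aes(x = .data$expected, y = .data$mean_measured)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_point(color = "#d7301f") +
    ggplot2::labs(x = "calibrated expected frequency (%)",
                  y = "mean measured frequency (%)",
                  title = sprintf("Pearson r = %.5f, slope = %.5f",
                                  object$pearson_r, object$slope))
}
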