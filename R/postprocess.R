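#' Relative-coverage flag thresholds
#'
#' Positions are flagged by their coverage relative to the sample mean:
#' `GOOD` at or above `good_min` percent, `WARNING` at or above `warn_min`
#' and below `good_min`, `EXCLUDE` below `warn_min`. Boundaries are
#' inclusive at the lower edge of each class.
#'
#' @param good_min percent of mean coverage for `GOOD` (default 10).
#' @param warn_min percent of mean coverage for `WARNING` (default 1).
#' @export
flag_thresholds <- function(good_min = 10, warn_min = 1) {
  stopifnot(warn_min >= 0, warn_min < good_min)
  structure(list(good_min = good_min, warn_min = warn_min),
            class = "flag_thresholds")
}

#' Relative coverage per position
#'
#' Normalizes absolute coverage by the mean coverage over the entire
#' reference (all positions, including zero-coverage ones) for the same
#' sample, in percent.
#'
#' @param rows tibble with a `Covmp` column (one row per reference position).
#' @return the tibble with a `PercentCov` column added/replaced.
#' @export
relative_coverage <- function(rows) {
  if (nrow(rows) == 0L) stop("no rows")
  mu <- mean(rows$Covmp)
  if (mu == 0) stop("all-zero coverage: relative coverage undefined")
  dplyr::mutate(rows, PercentCov = 100 * .data$Covmp / mu)
}

#' Coverage flag from relative coverage
#'
#' @param percent relative coverage in percent of the sample mean.
#' @param thresholds a [flag_thresholds()].
#' @return `"GOOD"`, `"WARNING"` or `"EXCLUDE"`; vectorized.
#' @export
flag_coverage <- function(percent, thresholds = flag_thresholds()) {
  ifelse(percent >= thresholds$good_min, "GOOD",
         ifelse(percent >= thresholds$warn_min, "WARNING", "EXCLUDE"))
}

#' Merge original- and shifted-orientation position rows
#'
#' Re-coordinates the shifted rows via [unshift_position()] and keeps, for
#' each reported position, the row with the larger coverage; all columns of
#' the winning row travel together. Ties keep the original-orientation row.
#'
#' @param rows_original,rows_shifted per-position tibbles of equal length
#'   with `Position` and `Covmp` columns; `rows_shifted` carries shifted
#'   coordinates.
#' @param s shift offset.
#' @param L reference length.
#' @return merged tibble sorted by reported position.
#' @export
merge_dual <- function(rows_original, rows_shifted, s, L) {
  if (nrow(rows_original) != nrow(rows_shifted))
    stop("original and shifted runs must cover the same number of positions")
  rows_shifted$Position <- unshift_position(rows_shifted$Position, s, L)
  rows_shifted <- dplyr::arrange(rows_shifted, .data$Position)
  rows_original <- dplyr::arrange(rows_original, .data$Position)
  if (!identical(rows_original$Position, rows_shifted$Position))
    stop("position sets of the two runs do not match after unshifting")
  take_shifted <- rows_shifted$Covmp > rows_original$Covmp
  out <- rows_original
  out[take_shifted, ] <- rows_shifted[take_shifted, ]
  out
}

#' Heteroplasmy classification
#'
#' Classifies variant frequencies into `HOMOPLASMIC` (> 98%),
#' `HIGH` (10-98%), `LOW` (1-10%) or `NOT_REPORTED`. A variant is not
#' reported when its position's coverage flag is below the reporting level
#' (default: anything but `GOOD`), when an SNV is below 1%, or when an indel
#' is below 10% -- the indel floor reflecting the higher indel error floor of
#' rolling-circle amplified libraries.
#'
#' @param freq variant frequency in percent.
#' @param type `"SNV"`, `"INS"`, `"DEL"` or `"NONE"`.
#' @param flag coverage flag (`GOOD`/`WARNING`/`EXCLUDE`).
#' @param snv_min,indel_min minimum reported frequencies in percent
#'   (defaults 1 and 10).
#' @param report_flags flags on which variants are reported
#'   (default `"GOOD"` only; add `"WARNING"` to restore suppressed rows).
#' @return character vector of classes; vectorized.
#' @export
classify_heteroplasmy <- function(freq, type, flag,
                                  snv_min = 1, indel_min = 10,
                                  report_flags = "GOOD") {
  n <- max(length(freq), length(type), length(flag))
  freq <- rep_len(freq, n)
  type <- rep_len(type, n)
  flag <- rep_len(flag, n)
  cls <- ifelse(freq > 98, "HOMOPLASMIC",
                ifelse(freq >= 10, "HIGH",
                       ifelse(freq >= 1, "LOW", "NOT_REPORTED")))
  cls[type == "NONE"] <- "NOT_REPORTED"
  cls[!flag %in% report_flags] <- "NOT_REPORTED"
  cls[type == "SNV" & freq < snv_min] <- "NOT_REPORTED"
  cls[type %in% c("INS", "DEL") & freq < indel_min] <- "NOT_REPORTED"
  cls
}

#' Reported variants from a position report
#'
#' Applies the reporting-layer defaults: passing-filter calls on
#' GOOD-flagged positions, SNVs at >= 1% and indels at >= 10%, with the
#' heteroplasmy class attached.
#'
#' @param report a position report (see [call_sample()]).
#' @param snv_min,indel_min,report_flags see [classify_heteroplasmy()].
#' @return tibble of reported variants with a `Class` column.
#' @export
reported_variants <- function(report, snv_min = 1, indel_min = 10,
                              report_flags = "GOOD") {
  cls <- classify_heteroplasmy(report$Freq, report$Type, report$FilterCov,
                               snv_min, indel_min, report_flags)
  out <- dplyr::mutate(report, Class = cls)
  out[out$Pass & out$Class != "NOT_REPORTED", ]
}

#' Read a pedigree table
#'
#' Tab-separated file with columns `sample`, `mother`, `father`,
#' `generation`; `NA`, `.` or empty for unknown parents.
#'
#' @param path TSV path.
#' @return tibble.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  stopifnot(all(c("sample", "mother", "father") %in% names(ped)))
  ped$mother[ped$mother %in% c("", ".")] <- NA_character_
  ped$father[ped$father %in% c("", ".")] <- NA_character_
  ped
}

#' Variant sharing and parental-transmission screens across a pedigree
#'
#' Builds, over the union of reported variants of all samples, a per-variant
#' sharing matrix (heteroplasmy class per sample), and two derived screens:
#' father-specific variants (reported in a father, not reported in the
#' corresponding mother) with their status in each offspring, and the
#' mother's variants with offspring status.
#'
#' @param samples named list of position reports (one per sample).
#' @param pedigree tibble with `sample`, `mother`, `father` columns
#'   (see [read_pedigree()]).
#' @param ... reporting options passed to [reported_variants()].
#' @return list of class `mitohet_transmission` with `sharing`, `paternal`
#'   and `maternal` tibbles.
#' @export
transmission_table <- function(samples, pedigree, ...) {
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("samples must be a named list of position reports")
  known <- names(samples)
  mentioned <- unique(stats::na.omit(c(pedigree$sample, pedigree$mother,
                                       pedigree$father)))
  if (!all(mentioned %in% known))
    stop("pedigree references unknown sample(s): ",
         paste(setdiff(mentioned, known), collapse = ", "))
  rep_list <- lapply(samples, reported_variants, ...)
  long <- dplyr::bind_rows(
    lapply(names(rep_list), function(nm) {
      r <- rep_list[[nm]]
      tibble::tibble(Sample = nm, Position = r$Position, Var = r$Var,
                     Type = r$Type, Freq = r$Freq, Class = r$Class)
    }))
  if (nrow(long) == 0L) {
    sharing <- tibble::tibble(Position = integer(), Var = character(),
                              Type = character())
  } else {
    sharing <- tidyr::pivot_wider(
      long, id_cols = c("Position", "Var", "Type"),
      names_from = "Sample", values_from = "Class",
      values_fill = "NOT_REPORTED")
    for (nm in setdiff(known, names(sharing)))
      sharing[[nm]] <- "NOT_REPORTED"
    sharing <- dplyr::arrange(sharing, .data$Position)
  }

  has <- function(nm, pos, var) {
    r <- rep_list[[nm]]
    any(r$Position == pos & r$Var == var)
  }
  screen <- function(parent_col, other_col) {
    rows <- list()
    fams <- pedigree[!is.na(pedigree[[parent_col]]), ]
    for (p in unique(fams[[parent_col]])) {
      kids <- fams$sample[fams[[parent_col]] == p]
      others <- unique(stats::na.omit(fams[[other_col]][fams[[parent_col]] == p]))
      pv <- rep_list[[p]]
      for (i in seq_len(nrow(pv))) {
        in_other <- length(others) > 0 &&
          any(vapply(others, has, logical(1), pv$Position[i], pv$Var[i]))
        for (k in kids) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            parent = p, offspring = k,
            Position = pv$Position[i], Var = pv$Var[i], Type = pv$Type[i],
            parent_freq = pv$Freq[i], parent_class = pv$Class[i],
            in_other_parent = in_other,
            in_offspring = has(k, pv$Position[i], pv$Var[i]))
        }
      }
    }
    dplyr::bind_rows(rows)
  }
  paternal <- screen("father", "mother")
  if (nrow(paternal) > 0L)
    paternal <- paternal[!paternal$in_other_parent, ]  # father-specific only
  maternal <- screen("mother", "father")
  structure(list(sharing = sharing, paternal = paternal, maternal = maternal),
            class = "mitohet_transmission")
}

#' @export
print.mitohet_transmission <- function(x, ...) {
  n_pat <- if (nrow(x$paternal)) sum(x$paternal$in_offspring) else 0L
  cat("<mitohet_transmission> ", nrow(x$sharing), " shared variant row(s); ",
      nrow(x$paternal), " father-specific screen row(s), ",
      n_pat, " transmitted paternally\n", sep = "")
  invisible(x)
}
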