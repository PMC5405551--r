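# Shared fixtures: small designs and hand-built alignment tibbles.

# A small mixture design on a short circular genome; cheap enough for loops.
small_design <- function(L = 2000L, n_snv = 8L, coverage = 200,
                         sub_error = 0.001, indel_error = 1e-4,
                         homopolymer_at = round(0.6 * L)) {
  ref <- random_circular_reference(L, homopolymer_at = homopolymer_at)
  read_len <- min(150L, L %/% 8L)
  mixture_design(reference = ref, n_snv = n_snv, coverage = coverage,
                 read_length = read_len, fragment_length = 2L * read_len,
                 substitution_error = sub_error, indel_error = indel_error)
}

# Minimal alignment tibble builder for hand-written pileup cases.
aln <- function(pos, cigar, seq, qual = NULL, strand = "+", mapq = 60L,
                qname = NULL) {
  n <- max(length(pos), length(cigar), length(seq))
  seq <- rep_len(seq, n)
  if (is.null(qual)) qual <- strrep("I", nchar(seq))  # phred 40
  if (is.null(qname)) qname <- paste0("r", seq_len(n))
  tibble::tibble(qname = qname, flag = ifelse(rep_len(strand, n) == "-", 16L, 0L),
                 rname = "ref", pos = rep_len(pos, n),
                 mapq = rep_len(mapq, n), cigar = rep_len(cigar, n),
                 seq = seq, qual = rep_len(qual, n),
                 strand = rep_len(strand, n))
}

# Independent brute-force pileup: walks every read base by base.
# Deliberately naive; the reference implementation for the fast engine.
brute_pileup <- function(alignments, refseq, min_bq = 35, min_mq = 50) {
  L <- nchar(refseq)
  counts <- matrix(0L, L, 8,
                   dimnames = list(NULL, c("A_plus", "C_plus", "G_plus",
                                           "T_plus", "A_minus", "C_minus",
                                           "G_minus", "T_minus")))
  covmp <- qdepth <- delspan <- integer(L)
  ins <- list()
  del <- list()
  for (i in seq_len(nrow(alignments))) {
    if (alignments$mapq[i] < min_mq) next
    minus <- alignments$strand[i] == "-"
    cg <- alignments$cigar[i]
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[A-Z]", cg))[[1]]
    r <- alignments$pos[i]
    j <- 1L
    for (k in seq_along(ops)) {
      if (ops[k] == "M") {
        for (b in seq_len(lens[k])) {
          covmp[r] <- covmp[r] + 1L
          q <- utf8ToInt(substr(alignments$qual[i], j, j)) - 33L
          base <- substr(alignments$seq[i], j, j)
          if (q >= min_bq && base %in% c("A", "C", "G", "T")) {
            col <- match(base, c("A", "C", "G", "T")) + if (minus) 4L else 0L
            counts[r, col] <- counts[r, col] + 1L
            qdepth[r] <- qdepth[r] + 1L
          }
          r <- r + 1L
          j <- j + 1L
        }
      } else if (ops[k] == "I") {
        if (r > 1) {
          key <- paste(r - 1L, substr(alignments$seq[i], j, j + lens[k] - 1L),
                       if (minus) "-" else "+")
          ins[[key]] <- (if (is.null(ins[[key]])) 0L else ins[[key]]) + 1L
        }
        j <- j + lens[k]
      } else if (ops[k] == "D") {
        if (r > 1) {
          key <- paste(r - 1L, substr(refseq, r, r + lens[k] - 1L),
                       if (minus) "-" else "+")
          del[[key]] <- (if (is.null(del[[key]])) 0L else del[[key]]) + 1L
        }
        for (b in seq_len(lens[k])) {
          covmp[r] <- covmp[r] + 1L
          qdepth[r] <- qdepth[r] + 1L
          delspan[r] <- delspan[r] + 1L
          r <- r + 1L
        }
      } else if (ops[k] == "S") {
        j <- j + lens[k]
      }
    }
  }
  list(counts = counts, covmp = covmp, qdepth = qdepth, delspan = delspan,
       ins = ins, del = del)
}

# Exact right-tail hypergeometric sum by direct enumeration over the
# fixed-margin 2x2 table; independent of stats::phyper.
hyper_tail_oracle <- function(reads1, reads2, e = 0.001) {
  d <- reads1 + reads2
  if (d == 0 || reads2 == 0) return(1)
  e2 <- round(d * e)
  e1 <- round(d * (1 - e))
  N <- d + e1 + e2
  K <- reads2 + e2
  xs <- reads2:min(K, d)
  sum(exp(lchoose(K, xs) + lchoose(N - K, d - xs) - lchoose(N, d)))
}

# Fabricate a minimal position report for postprocess-level tests.
fake_report <- function(positions, vars, types, freqs,
                        flags = "GOOD", L = 100L, sample = "s") {
  rep <- tibble::tibble(
    Chrom = "ref", Position = seq_len(L), Covmp = 1000L, PercentCov = 100,
    FilterCov = "GOOD", Ref = "A", Var = NA_character_, Cons = "A",
    FastA = "A", QDepth = 1000L, Reads1 = 1000L, Reads2 = 0L, Freq = 0,
    Pvalue = 1, StrandFilter = "NA", R1plus = 500L, R1minus = 500L,
    R2plus = 0L, R2minus = 0L, Type = "NONE", Pass = FALSE)
  idx <- match(positions, rep$Position)
  rep$Var[idx] <- vars
  rep$Type[idx] <- types
  rep$Freq[idx] <- freqs
  rep$FilterCov[idx] <- rep_len(flags, length(idx))
  rep$Pass[idx] <- TRUE
  rep$Reads2[idx] <- round(1000 * freqs / 100)
  attr(rep, "sample") <- sample
  attr(rep, "reference_length") <- L
  rep
}
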