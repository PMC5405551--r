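toy_ref <- function(L = 40L, seed = 5) {
  set.seed(seed)
  circular_reference("ref", paste(sample(c("A", "C", "G", "T"), L,
                                         replace = TRUE), collapse = ""))
}

test_that("bases are counted by strand at the right positions", {
  ref <- circular_reference("ref", strrep("C", 20))
  a <- aln(pos = 7L, cigar = "3M", seq = "AAA", qname = c("r1", "r2"))
  pu <- build_pileup(a, ref)
  expect_equal(pu$positions$A_plus[7:9], c(2L, 2L, 2L))
  expect_equal(pu$positions$qdepth[7:9], c(2L, 2L, 2L))
  expect_equal(sum(pu$positions$covmp), 6L)
})

test_that("mapping-quality and base-quality cutoffs exclude evidence", {
  ref <- circular_reference("ref", strrep("C", 20))
  low_mapq <- aln(pos = 5L, cigar = "4M", seq = "AAAA", mapq = 40L)
  pu <- build_pileup(low_mapq, ref)
  expect_equal(sum(pu$positions$covmp), 0L)  # q = 50 excludes the record
  # phred 30 ('?') is below Q = 35: no allele count, but still depth
  mixed_q <- aln(pos = 5L, cigar = "4M", seq = "AAAA", qual = "II?I")
  pu <- build_pileup(mixed_q, ref)
  expect_equal(pu$positions$covmp[5:8], rep(1L, 4))
  expect_equal(pu$positions$A_plus[5:8], c(1L, 1L, 0L, 1L))
  expect_equal(pu$positions$qdepth[7], 0L)
})

test_that("pileup counts equal a brute-force per-read tally on a random fixture", {
  set.seed(20)
  design <- small_design(L = 500L, n_snv = 4L, coverage = 24,
                         sub_error = 0.01, indel_error = 0.005)
  run <- simulate_reads(design, 50)
  a <- run$original
  expect_gte(nrow(a), 40L)
  pu <- build_pileup(a, design$reference)
  bf <- brute_pileup(a, design$reference$sequence)
  expect_identical(pu$positions$covmp, bf$covmp)
  expect_identical(pu$positions$qdepth, bf$qdepth)
  expect_identical(pu$positions$delspan, bf$delspan)
  for (col in colnames(bf$counts))
    expect_identical(pu$positions[[col]], bf$counts[, col])
  # indel events match after applying the same left-alignment to the oracle
  keys <- c(names(bf$ins), names(bf$del))
  if (length(keys) > 0) {
    parts <- do.call(rbind, strsplit(keys, " "))
    oracle <- tibble::tibble(
      anchor = as.integer(parts[, 1]),
      type = rep(c("INS", "DEL"), c(length(bf$ins), length(bf$del))),
      seq = parts[, 2],
      plus = ifelse(parts[, 3] == "+", unlist(c(bf$ins, bf$del)), 0L),
      minus = ifelse(parts[, 3] == "-", unlist(c(bf$ins, bf$del)), 0L))
    oracle <- mitohet:::left_align_indels(oracle, design$reference$sequence)
    oracle <- dplyr::arrange(oracle, anchor, type, seq)
    got <- dplyr::arrange(pu$indels, anchor, type, seq)
    expect_equal(as.data.frame(got), as.data.frame(oracle))
  }
})

test_that("qualified depth equals allele counts plus deletion spans everywhere", {
  set.seed(21)
  design <- small_design(L = 400L, coverage = 50, sub_error = 0.005,
                         indel_error = 0.01)
  run <- simulate_reads(design, 30)
  pu <- build_pileup(run$original, design$reference)
  base_sum <- rowSums(as.matrix(
    pu$positions[c("A_plus", "C_plus", "G_plus", "T_plus",
                   "A_minus", "C_minus", "G_minus", "T_minus")]))
  expect_identical(pu$positions$qdepth, as.integer(base_sum) +
                     pu$positions$delspan)
})

test_that("pileup is invariant to record order", {
  set.seed(22)
  design <- small_design(L = 300L, coverage = 40)
  run <- simulate_reads(design, 50)
  pu1 <- build_pileup(run$original, design$reference)
  shuffled <- run$original[sample(nrow(run$original)), ]
  pu2 <- build_pileup(shuffled, design$reference)
  expect_equal(pu1$positions, pu2$positions)
  expect_equal(dplyr::arrange(pu1$indels, anchor, type, seq),
               dplyr::arrange(pu2$indels, anchor, type, seq))
})

test_that("on error-free reads total qualified depth equals total aligned bases", {
  set.seed(23)
  design <- small_design(L = 1000L, coverage = 50, sub_error = 0,
                         indel_error = 0)
  run <- simulate_reads(design, 0)  # haplotype A only: pure M alignments
  pu <- build_pileup(run$original, design$reference)
  aligned_m <- sum(vapply(run$original$cigar, function(cg) {
    len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    op <- regmatches(cg, gregexpr("[A-Z]", cg))[[1]]
    sum(len[op == "M"])
  }, integer(1)))
  expect_equal(sum(pu$positions$qdepth), aligned_m)
})

test_that("alignments running past the reference end are refused", {
  ref <- circular_reference("ref", strrep("A", 20))
  a <- aln(pos = 18L, cigar = "5M", seq = "AAAAA")
  expect_error(build_pileup(a, ref), "past reference end")
})

test_that("insertions anchor at the preceding base and deletions span depth", {
  ref <- circular_reference("ref", paste0(strrep("A", 9), "CGT",
                                          strrep("A", 8)))
  a <- aln(pos = 5L, cigar = "5M2I5M", seq = "AAAAAGGCGTAA")
  pu <- build_pileup(a, ref)
  expect_equal(pu$indels$anchor, 9L)
  expect_equal(pu$indels$type, "INS")
  expect_equal(pu$indels$seq, "GG")
  d <- aln(pos = 5L, cigar = "5M3D4M", seq = "AAAAAAAAA")
  pu <- build_pileup(d, ref)
  expect_equal(pu$indels$type, "DEL")
  expect_equal(pu$indels$seq, "CGT")
  expect_equal(pu$positions$delspan[10:12], rep(1L, 3))
  expect_equal(pu$positions$covmp[10:12], rep(1L, 3))
})

test_that("homopolymer indels are left-aligned to the run's leftmost anchor", {
  # ref: ...C AAAAAAAA C...; insertion reported mid-run must normalize
  ref <- circular_reference("ref", paste0("GGGGC", strrep("A", 8), "CGGGG"))
  a <- aln(pos = 2L, cigar = "8M2I7M",
           seq = paste0("GGGC", strrep("A", 4), "AA", strrep("A", 4), "CGG"))
  pu <- build_pileup(a, ref)
  expect_equal(pu$indels$anchor, 5L)  # the C before the A-run
  expect_equal(pu$indels$seq, "AA")
})

test_that("the mismatch mapping-quality hook only ever downgrades", {
  set.seed(24)
  design <- small_design(L = 300L, coverage = 20, sub_error = 0.02,
                         indel_error = 0)
  run <- simulate_reads(design, 0)
  a <- run$original
  identity_q <- adjusted_mapping_quality(a, design$reference)
  expect_identical(identity_q, a$mapq)
  adj <- adjusted_mapping_quality(a, design$reference, hook = "mismatch")
  expect_true(all(adj <= a$mapq))
  # mismatch-free reads keep their quality
  design2 <- small_design(L = 300L, coverage = 5, sub_error = 0,
                          indel_error = 0)
  clean <- simulate_reads(design2, 0)$original
  expect_identical(adjusted_mapping_quality(clean, design2$reference,
                                            hook = "mismatch"),
                   clean$mapq)
})
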