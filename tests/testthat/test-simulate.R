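test_that("haplotype construction applies exactly the engineered variants", {
  set.seed(50)
  ref <- random_circular_reference(1000L, homopolymer_at = 600L)
  empty <- mixture_design(reference = ref,
                          snv_set = tibble::tibble(position = integer(0),
                                                   ref = character(0),
                                                   alt = character(0)),
                          indel_set = tibble::tibble(anchor = integer(0),
                                                     seq = character(0)))
  hap0 <- make_haplotypes(empty)
  expect_identical(hap0$hap_b, hap0$hap_a)
  design <- mixture_design(reference = ref, n_snv = 8L)
  hap <- make_haplotypes(design)
  expect_equal(nchar(hap$hap_b), 1000L + 3L)  # +G and +AA insertions
  a <- strsplit(hap$hap_a, "")[[1]]
  b <- strsplit(hap$hap_b, "")[[1]][hap$map_b > 0]
  expect_equal(sum(a != b), 8L)
  expect_setequal(which(a != b), design$snv_set$position)
  expect_equal(sum(hap$map_b == 0), 3L)
})

test_that("overlapping engineered variants are rejected", {
  set.seed(51)
  ref <- random_circular_reference(500L, homopolymer_at = 300L)
  refc <- strsplit(ref$sequence, "")[[1]]
  expect_error(mixture_design(
    reference = ref,
    snv_set = tibble::tibble(position = c(50L, 50L),
                             ref = refc[c(50, 50)], alt = c("A", "C")),
    indel_set = tibble::tibble(anchor = 299L, seq = "AA")),
    "overlap")
})

test_that("truth insertions are reported at left-aligned anchors", {
  set.seed(52)
  ref <- random_circular_reference(500L, homopolymer_at = 300L)
  # engineer the +AA inside the A-run; truth must normalize to the run start
  design <- mixture_design(
    reference = ref,
    snv_set = tibble::tibble(position = integer(0), ref = character(0),
                             alt = character(0)),
    indel_set = tibble::tibble(anchor = 303L, seq = "AA"))
  truth <- make_haplotypes(design)$truth
  expect_equal(truth$position, 299L)  # the C before the 8-A run
  expect_equal(truth$var, "+AA")
})

test_that("simulated depth matches the design coverage", {
  set.seed(53)
  design <- small_design(L = 2000L, coverage = 100)
  run <- simulate_reads(design, 50)
  report <- call_sample(run$original, run$shifted, design$reference)
  # per-position depth is Poisson(coverage); the mean over L positions
  # has standard error sqrt(coverage / L)
  se <- sqrt(100 / 2000)
  expect_lt(abs(mean(report$Covmp) - 100), 5 * se)
})

test_that("ratio 0 reads match haplotype A and ratio 100 haplotype B", {
  set.seed(54)
  design <- small_design(L = 800L, coverage = 20, sub_error = 0,
                         indel_error = 0)
  hap <- make_haplotypes(design)
  run0 <- simulate_reads(design, 0)
  doubled_a <- paste0(hap$hap_a, hap$hap_a)
  expect_true(all(vapply(seq_len(nrow(run0$reads)), function(i)
    grepl(run0$reads$seq[i], doubled_a, fixed = TRUE), logical(1))))
  run100 <- simulate_reads(design, 100)
  doubled_b <- paste0(hap$hap_b, hap$hap_b)
  expect_true(all(vapply(seq_len(nrow(run100$reads)), function(i)
    grepl(run100$reads$seq[i], doubled_b, fixed = TRUE), logical(1))))
  expect_true(all(run0$reads$from_b == FALSE))
  expect_true(all(run100$reads$from_b == TRUE))
})

test_that("origin-spanning reads appear only in the shifted orientation", {
  set.seed(55)
  design <- small_design(L = 1000L, coverage = 60, sub_error = 0,
                         indel_error = 0)
  run <- simulate_reads(design, 0)
  spans_origin <- !run$reads$ok_orig
  expect_gt(sum(spans_origin), 0)
  expect_true(all(run$reads$ok_shift[spans_origin]))
  spans_mid <- !run$reads$ok_shift
  expect_gt(sum(spans_mid), 0)
  expect_true(all(run$reads$ok_orig[spans_mid]))
  # reads contiguous in both frames appear in both
  both <- run$reads$ok_orig & run$reads$ok_shift
  expect_gt(sum(both), 0.9 * nrow(run$reads) * (1000 - 2 * 300) / 1000)
})

test_that("the simulator is deterministic under a fixed seed", {
  design_of <- function() {
    set.seed(56)
    small_design(L = 600L, coverage = 20)
  }
  d1 <- design_of()
  d2 <- design_of()
  expect_identical(d1$snv_set, d2$snv_set)
  set.seed(99)
  r1 <- simulate_reads(d1, 30)
  set.seed(99)
  r2 <- simulate_reads(d2, 30)
  expect_identical(r1$reads, r2$reads)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  set.seed(99)
  simulate_reads(d1, 30, write_dir = dir1)
  set.seed(99)
  simulate_reads(d2, 30, write_dir = dir2)
  for (f in c("reads_R1.fastq", "reads_R2.fastq", "original.sam",
              "shifted.sam", "truth.csv"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})

test_that("ratio calibration rescales expectations from the 50/50 anchor", {
  cal <- calibrate_ratios(c(0, 10, 50, 100), 50)
  expect_equal(cal$factor, 1)
  expect_equal(cal$expected$expected, c(0, 10, 50, 100))
  cal2 <- calibrate_ratios(c(10, 50), 49)
  expect_equal(cal2$expected$expected[1], 9.8)
  expect_error(calibrate_ratios(c(10, 25), 25), "50/50")
  expect_error(calibrate_ratios(c(10, 50), 0), "degenerate")
})

test_that("benchmark metrics recover a near-perfect titration without noise", {
  set.seed(57)
  design <- small_design(L = 1500L, n_snv = 6L, coverage = 400,
                         sub_error = 0, indel_error = 0)
  bm <- run_benchmark(design, ratios = c(10, 25, 50, 75, 100))
  expect_gt(bm$pearson_r, 0.999)
  expect_lt(abs(bm$slope - 1), 3 * bm$slope_se)
  expect_equal(bm$false_positive_count, 0L)
  expect_true(all(tidy(bm)$detected_fraction == 1))
})

test_that("false positives equal a brute-force set difference", {
  set.seed(58)
  design <- small_design(L = 1500L, n_snv = 6L, coverage = 150)
  run <- simulate_reads(design, 50)
  report <- call_sample(run$original, run$shifted, design$reference)
  bm <- benchmark_metrics(run$truth, setNames(list(report), "50"))
  truth_pos <- run$truth$position[run$truth$type == "SNV"]
  called_pos <- report$Position[report$Pass & report$Type == "SNV"]
  expect_equal(bm$false_positive_count, length(setdiff(called_pos, truth_pos)))
})

test_that("variant density counts neighbors in a circular 300 bp window", {
  set.seed(59)
  ref <- random_circular_reference(2000L, homopolymer_at = 1200L)
  refc <- strsplit(ref$sequence, "")[[1]]
  pos <- c(10L, 25L, 40L, 55L, 1990L)  # four clustered + one within the
  # window across the origin
  alt <- vapply(refc[pos], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  design <- mixture_design(
    reference = ref,
    snv_set = tibble::tibble(position = pos, ref = refc[pos], alt = alt),
    indel_set = tibble::tibble(anchor = integer(0), seq = character(0)))
  run <- simulate_reads(design, 50)
  report <- call_sample(run$original, run$shifted, ref)
  bm <- benchmark_metrics(run$truth, setNames(list(report), "50"))
  dens <- bm$variant_density
  expect_true(all(dens$variant_density[dens$position %in% c(10, 25, 40, 55)]
                  >= 4))
  # position 1990 is within 150 bp of positions 10..55 across the origin
  expect_gte(dens$variant_density[dens$position == 1990], 4)
})
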