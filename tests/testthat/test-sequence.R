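test_that("run_fraction counts maximal homopolymeric A/T runs", {
  expect_equal(run_fraction("AAAA"), 1)
  expect_equal(run_fraction("ATATATAT"), 0)
  expect_equal(run_fraction("AAAATTGCGTTTT"), 8 / 13)
  expect_equal(run_fraction("aaaattgcgtttt"), 8 / 13)   # case-insensitive
  expect_equal(run_fraction("GGGGCCCC"), 0)             # G/C runs don't count
  expect_equal(run_fraction("AAAAAAA"), 1)              # one 7-run: all 7 bp
  expect_equal(run_fraction("AAAA", min_run = 5), 0)
})

test_that("ambiguity codes error by default and can be skipped", {
  expect_error(run_fraction("AAAANAAAA"), "non-ACGT")
  expect_warning(rf <- run_fraction("AAAANAAAA", ambiguous = "skip"),
                 "ambiguous")
  expect_equal(rf, 1)    # two 4-runs over 8 unambiguous bp
})

test_that("run_stats spectrum accounts for exactly the run fraction", {
  set.seed(1)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE,
                      prob = c(.4, .1, .1, .4)), collapse = "")
    st <- run_stats(s)
    spec_bp <- sum(as.numeric(names(st$run_length_spectrum)) *
                     as.numeric(st$run_length_spectrum))
    expect_equal(spec_bp / st$length, st$run_fraction)
    expect_lte(st$run_fraction, st$at_fraction)
  }
})

test_that("run_fraction is invariant under reverse complement", {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  set.seed(2)
  for (i in 1:20) {
    s <- generate_cdeii_sequence(sequence_spec(84, 0.85, runif(1, 0.1, 0.6),
                                               seed = i))
    expect_equal(run_fraction(s), run_fraction(revcomp(s)))
  }
})

test_that("run_fraction is non-increasing in min_run", {
  set.seed(3)
  for (i in 1:10) {
    s <- generate_cdeii_sequence(sequence_spec(120, 0.9, 0.4, seed = i))
    rf <- vapply(1:9, function(m) run_fraction(s, min_run = m), numeric(1))
    expect_true(all(diff(rf) <= 0))
  }
})

test_that("generated sequences hit the requested composition", {
  ## all-run extreme
  s1 <- generate_cdeii_sequence(sequence_spec(84, 1, 1, seed = 4))
  expect_equal(nchar(s1), 84)
  expect_equal(run_fraction(s1), 1)
  ## run-free AT-rich
  s2 <- generate_cdeii_sequence(sequence_spec(84, 0.9, 0, seed = 4))
  expect_lte(run_fraction(s2), 0.05)
  ## intermediate target
  s3 <- generate_cdeii_sequence(sequence_spec(84, 0.9, 0.5, seed = 4))
  expect_gte(run_fraction(s3), 0.45)
  expect_lte(run_fraction(s3), 0.55)
  expect_lt(abs(mean(strsplit(s3, "")[[1]] %in% c("A", "T")) - 0.9), 0.02)
  ## deterministic given the seed
  expect_identical(s3, generate_cdeii_sequence(sequence_spec(84, 0.9, 0.5,
                                                             seed = 4)))
  ## a sweep of targets stays within the contract tolerance
  for (trf in seq(0.1, 0.8, by = 0.1)) {
    s <- generate_cdeii_sequence(sequence_spec(100, 0.9, trf, seed = 11))
    expect_lt(abs(run_fraction(s) - trf), 0.05)
  }
})

test_that("infeasible sequence specs are rejected", {
  expect_error(sequence_spec(84, 0.5, 0.6), "target_run_fraction")
  expect_error(generate_cdeii_sequence(sequence_spec(84, 0.9, 0.02)),
               "infeasible")
  expect_error(sequence_spec(0, 0.5, 0.2), "length")
})

test_that("FASTA round trip and BED-restricted statistics work", {
  tmp <- withr::local_tempdir()
  fa <- file.path(tmp, "seqs.fa")
  seqs <- c(cen_like = generate_cdeii_sequence(sequence_spec(84, 0.9, 0.5,
                                                             seed = 5)),
            flank = paste0("GGGCCC", generate_cdeii_sequence(
              sequence_spec(84, 0.9, 0.3, seed = 6)), "GGGCCC"))
  write_fasta(seqs, fa)
  st <- fasta_run_stats(fa)
  expect_equal(st$name, c("cen_like", "flank"))
  expect_equal(st$run_fraction[1], run_fraction(seqs[[1]]))
  ## BED restriction to the CDEII interior of the flanked record
  bed <- file.path(tmp, "cdeii.bed")
  writeLines("flank\t6\t90", bed)
  st2 <- fasta_run_stats(fa, bed = bed)
  expect_equal(st2$length, 84)
  expect_equal(st2$run_fraction,
               run_fraction(substr(seqs[[2]], 7, 90)))
})

test_that("recruitment correlation recovers known association", {
  expect_equal(recruitment_correlation(1:5, 2 * (1:5) + 3)$r, 1)
  expect_equal(recruitment_correlation(1:5, -3 * (1:5))$r, -1)
  ## simulated rho = 0.9, n = 50: r lands in the Fisher-z band for most seeds
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(50)
    y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(50)
    r <- recruitment_correlation(x, y)$r
    if (r >= 0.82 && r <= 0.95) hits <- hits + 1
  }
  expect_gte(hits, 9)
  expect_error(recruitment_correlation(1:2, 1:2), "n >= 3")
})

test_that("the published CDEII variant table correlates run content with recruitment", {
  tab <- cdeii_recruitment_table()
  rc <- recruitment_correlation(tab$run_fraction, tab$colocalization_pct)
  expect_gt(rc$r, 0.8)
  expect_lt(rc$p, 0.05)
})
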