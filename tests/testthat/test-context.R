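test_that("telomeric array detection handles exact, degenerate and null cases", {
  expect_error(detect_telomeric_arrays("ACGT", unit = "AC"), "at least 3")
  # exact tandem: one array, purity 1
  t1 <- detect_telomeric_arrays(strrep("TTAGGG", 10))
  expect_identical(nrow(t1), 1L)
  expect_identical(c(t1$start, t1$end), c(0L, 60L))
  expect_equal(t1$purity, 1)
  expect_false(t1$degenerate)
  # alternating exact / one-mismatch units: purity 0.5, degenerate
  t2 <- detect_telomeric_arrays(strrep(paste0("TTAGGG", "TTCGGG"), 5))
  expect_identical(nrow(t2), 1L)
  expect_identical(t2$unit_count, 10L)
  expect_equal(t2$purity, 0.5)
  expect_true(t2$degenerate)
  # two mismatches per unit break the run
  expect_identical(nrow(detect_telomeric_arrays(strrep("TTCGGC", 10))), 0L)
  # random sequence: no arrays at the default stringency
  set.seed(88)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
               collapse = "")
    expect_identical(nrow(detect_telomeric_arrays(s)), 0L)
  }
})

test_that("telomere detection is reverse-complement symmetric", {
  set.seed(99)
  s <- paste0(paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                    collapse = ""),
              strrep("TTAGGG", 8),
              paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                    collapse = ""))
  fwd <- detect_telomeric_arrays(s)
  rc <- detect_telomeric_arrays(geveR:::revcomp(s))
  L <- nchar(s)
  expect_identical(nrow(fwd), nrow(rc))
  expect_setequal(L - fwd$end, rc$start)
  expect_setequal(L - fwd$start, rc$end)
  expect_setequal(rc$orientation,
                  geveR:::revcomp(fwd$orientation[1]))
})

test_that("end-distance enrichment has the documented extreme and symmetry", {
  lens <- c(chr1 = 10000L, chr2 = 20000L)
  f0 <- data.frame(chrom = c("chr1", "chr2"), start = 0L, end = 100L)
  r <- end_distance_enrichment(f0, lens, 100, seed = 4)
  expect_equal(r$observed_mean, 0)
  expect_equal(r$p_value, 1 / 101)
  expect_true(all(r$distances$normalized >= 0 & r$distances$normalized <= 0.5))
  # reversing coordinates leaves distances unchanged
  f <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                  start = c(1000L, 7000L, 3000L), end = c(1400L, 7900L, 3100L))
  fr <- data.frame(chrom = f$chrom, start = lens[f$chrom] - f$end,
                   end = lens[f$chrom] - f$start)
  d1 <- end_distance_enrichment(f, lens, 100, seed = 1)$distances$normalized
  d2 <- end_distance_enrichment(fr, lens, 100, seed = 1)$distances$normalized
  expect_equal(d1, d2)
  expect_error(end_distance_enrichment(f, lens, 10), ">= 100")
  too_big <- data.frame(chrom = "chr1", start = 0L, end = 20000L)
  expect_error(end_distance_enrichment(too_big, lens, 100), "longer")
})

test_that("context chi-square matches closed forms and the distribution oracle", {
  tab <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE,
                dimnames = list(c("LTR", "DDE"), c("viral", "background")))
  r <- mobile_element_context_chisq(tab)
  expect_equal(round(r$statistic, 3), 6.667)
  expect_identical(r$df, 1)
  # proportional table: statistic 0, p 1
  prop <- matrix(c(10, 20, 30, 60), 2)
  rp <- mobile_element_context_chisq(prop, min_expected = 0)
  expect_equal(rp$statistic, 0)
  expect_equal(rp$p_value, 1)
  # random tables vs the chi-square distribution oracle (chisq.test)
  set.seed(111)
  for (rep in 1:60) {
    m <- matrix(rpois(12, 30) + 1, 4, 3)
    got <- mobile_element_context_chisq(m, min_expected = 0)
    ref <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
    # invariance under row/column permutation
    got2 <- mobile_element_context_chisq(m[sample(4), sample(3)],
                                         min_expected = 0)
    expect_equal(got2$statistic, got$statistic, tolerance = 1e-9)
  }
  # zero margins are dropped with a warning
  z <- rbind(tab, none = c(0, 0))
  expect_warning(rz <- mobile_element_context_chisq(z), "none")
  expect_equal(rz$statistic, r$statistic)
  expect_error(suppressWarnings(
    mobile_element_context_chisq(matrix(c(5, 0, 7, 0), 2))), "2x2")
  # sparse tables trigger the Monte Carlo route
  sp <- matrix(c(1, 9, 8, 2), 2)
  rs <- mobile_element_context_chisq(sp, monte_carlo_reps = 4000, seed = 2)
  expect_false(is.na(rs$p_monte_carlo))
  expect_lt(abs(rs$p_monte_carlo - rs$p_value), 0.05)
})

test_that("element context assignment uses region midpoints", {
  reg <- data.frame(chrom = "chr1", start = c(0L, 10000L),
                    end = c(5000L, 12000L), is_viral = c(TRUE, FALSE))
  reps <- data.frame(chrom = "chr1",
                     start = c(100L, 4400L, 10500L, 20000L),
                     end = c(600L, 4900L, 11000L, 20500L),
                     class = c("LTR", "LTR", "DDE", "MITE"))
  tab <- mobile_element_context_table(reps, reg)
  expect_identical(as.integer(tab["LTR", "viral_region"]), 2L)
  expect_identical(as.integer(tab["DDE", "other_divergent"]), 1L)
  expect_identical(as.integer(tab["MITE", "conserved_background"]), 1L)
})

test_that("GC windows match a counting oracle and flag composition shifts", {
  g <- gc_shift_track(strrep("G", 5000), 1000)
  expect_true(all(g$windows$gc == 1))
  expect_identical(nrow(g$shifts), 0L)
  half <- paste0(strrep("AT", 2500), strrep("GC", 2500))
  gh <- gc_shift_track(half, 1000)
  expect_equal(gh$shifts$boundary, 5000)
  set.seed(121)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 4321, replace = TRUE),
               collapse = "")
    gw <- gc_shift_track(s, 500)$windows
    ch <- strsplit(s, "")[[1]]
    want <- vapply(seq_len(nrow(gw)), function(k)
      mean(ch[(gw$start[k] + 1):gw$end[k]] %in% c("G", "C")), numeric(1))
    expect_equal(gw$gc, want, tolerance = 1e-12)
  }
})

test_that("similarity links recover identity, reject noise, and match an
           alignment oracle under substitution divergence", {
  set.seed(131)
  a <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")
  # identical pair: one full-length perfect link
  li <- region_similarity_links(c(r1 = a, r2 = a))
  expect_identical(nrow(li), 1L)
  expect_equal(li$identity, 100)
  expect_identical(li$span, 5000L)
  # independent random regions: nothing at defaults
  b <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")
  expect_identical(nrow(region_similarity_links(c(r1 = a, r2 = b))), 0L)
  # 10% substitution copy: identity near 90, agreeing with a global aligner
  mut <- geveR:::mutate_dna(a, 0.10)
  lm <- region_similarity_links(c(r1 = a, r2 = mut))
  expect_identical(nrow(lm), 1L)
  expect_lt(abs(lm$identity - 90), 3)
  al <- Biostrings::pairwiseAlignment(a, mut, type = "global")
  expect_lt(abs(lm$identity - Biostrings::pid(al)), 3)
  # short regions are skipped with a warning; a lone region is an error
  expect_warning(region_similarity_links(c(r1 = a, r2 = a, tiny = "ACGT")),
                 "tiny")
  expect_error(suppressWarnings(region_similarity_links(c(r1 = a, tiny = "AC"))),
               "at least 2")
})

test_that("O/E detrending removes the distance trend exactly", {
  # matrix depending only on |i-j|: O/E identically 1
  n <- 30
  m <- 100 / (1 + abs(outer(1:n, 1:n, "-")))
  oe <- detrend_contact_matrix(m)
  expect_true(all(abs(oe - 1) < 1e-12))
  # all-zero input: all-zero output, no division error
  expect_true(all(detrend_contact_matrix(matrix(0, 5, 5)) == 0))
  expect_error(detrend_contact_matrix(matrix(1:9, 3)), "symmetric")
  expect_error(detrend_contact_matrix(matrix(1, 2, 3)), "square")
  # random symmetric matrices: per-diagonal O/E means are 1; the explicit
  # double-loop oracle agrees entry-wise
  set.seed(141)
  for (rep in 1:10) {
    n <- sample(8:20, 1)
    r <- matrix(rpois(n * n, 20), n)
    m <- r + t(r)
    oe <- detrend_contact_matrix(m)
    expect_equal(unclass(oe), oracle_oe(m), tolerance = 1e-9,
                 ignore_attr = TRUE)
    d <- abs(row(m) - col(m))
    for (s in 0:(n - 1)) {
      vals <- oe[d == s]
      if (any(m[d == s] > 0)) expect_equal(mean(vals), 1, tolerance = 1e-9)
    }
  }
})

test_that("compaction score is 0 on trend-only maps and ~1 for doubled regions", {
  n <- 400
  m <- 100 / (1 + abs(outer(1:n, 1:n, "-")))
  oe <- detrend_contact_matrix(m)
  expect_equal(region_compaction_score(oe, 50 * 1000, 80 * 1000, 1000), 0,
               tolerance = 1e-9)
  # double the intra-region contacts of a 6-bin region
  m2 <- m
  idx <- 100:105
  m2[idx, idx] <- m2[idx, idx] * 2
  sc <- region_compaction_score(detrend_contact_matrix(m2),
                                99 * 1000, 105 * 1000, 1000)
  expect_lt(abs(sc - 1), 0.1)
  # sub-bin regions are undefined
  expect_message(
    expect_true(is.na(region_compaction_score(oe, 10, 20, 1000))),
    "fewer than 2")
})
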