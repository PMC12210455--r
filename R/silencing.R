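#' Gene-level CpG methylation classification
#'
#' Methylation level of a CpG site is the fraction of methylated reads
#' covering it; a gene's level is the unweighted mean over its usable sites,
#' and a gene is classified methylated when that mean reaches
#' `threshold` (default 0.05, inclusive: exactly 5% counts as methylated).
#' Genes with no usable site get an `NA` mean and are excluded from
#' classification.
#'
#' @param sites methylation table ([read_methylation()] layout: `chrom`,
#'   `position`, `coverage`, `methylated_count`, `level`).
#' @param genes gene table with `gene_id`, `chrom`, `start`, `end`.
#' @param min_coverage minimum reads at a site for it to be used (default 5;
#'   single-molecule per-site calls are unreliable below that depth).
#' @param threshold classification cutoff on the gene mean (inclusive).
#' @param pooled use pooled read counting (sum of methylated reads over sum
#'   of coverage) instead of site-wise averaging.
#' @return data.frame `gene_id`, `n_sites`, `mean_level`, `is_methylated`
#'   (`NA` for genes without usable sites).
#' @export
gene_methylation <- function(sites, genes, min_coverage = 5L,
                             threshold = 0.05, pooled = FALSE) {
  stopifnot(min_coverage >= 1)
  use <- sites[sites$coverage >= min_coverage, , drop = FALSE]
  n_sites <- integer(nrow(genes))
  mean_level <- rep(NA_real_, nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    s <- use[use$chrom == ch, , drop = FALSE]
    if (!nrow(s)) next
    ov <- IRanges::findOverlaps(
      iranges0(s$position, s$position + 1L),
      iranges0(genes$start[gi], genes$end[gi]))
    if (!length(ov)) next
    site_i <- S4Vectors::queryHits(ov)
    gene_i <- gi[S4Vectors::subjectHits(ov)]
    n_sites[gi] <- as.integer(table(factor(gene_i, levels = gi)))
    agg <- if (pooled) {
      tapply(s$methylated_count[site_i], gene_i, sum) /
        tapply(s$coverage[site_i], gene_i, sum)
    } else {
      tapply(s$level[site_i], gene_i, mean)
    }
    mean_level[as.integer(names(agg))] <- as.numeric(agg)
  }
  data.frame(gene_id = genes$gene_id, n_sites = n_sites,
             mean_level = mean_level,
             is_methylated = ifelse(is.na(mean_level), NA,
                                    mean_level >= threshold),
             stringsAsFactors = FALSE)
}

# shared sliding-window scaffold: windows anchored at multiples of step_bp,
# clipped at the chromosome end
window_frame <- function(chrom, chrom_len, window_bp, step_bp) {
  starts <- seq(0L, max(0L, chrom_len - 1L), by = step_bp)
  starts <- starts[starts < chrom_len]
  data.frame(chrom = chrom, start = starts,
             end = pmin(starts + window_bp, chrom_len))
}

#' Rolling-mean methylation track
#'
#' Sliding windows (default 5,000 bp, step 1,000 bp) of the mean per-site
#' methylation level; windows with no site carry `NA`.
#'
#' @param sites methylation table with `chrom`, `position`, `level`.
#' @param window_bp window size in bp.
#' @param step_bp window anchor spacing; must be positive and at most
#'   `window_bp`.
#' @param chrom_lengths named integer vector; defaults to the last covered
#'   position per chromosome.
#' @return data.frame `chrom`, `start`, `end`, `value`.
#' @export
methylation_track <- function(sites, window_bp = 5000L, step_bp = 1000L,
                              chrom_lengths = NULL) {
  if (step_bp <= 0) abort("step_bp must be positive")
  if (window_bp <= 0 || step_bp > window_bp)
    abort("need 0 < step_bp <= window_bp")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(sites$position, sites$chrom),
                            function(p) max(p) + 1L, numeric(1))
  }
  out <- list()
  for (ch in names(chrom_lengths)) {
    w <- window_frame(ch, chrom_lengths[[ch]], window_bp, step_bp)
    s <- sites[sites$chrom == ch, , drop = FALSE]
    w$value <- NA_real_
    if (nrow(s)) {
      ov <- IRanges::findOverlaps(iranges0(s$position, s$position + 1L),
                                  iranges0(w$start, w$end))
      if (length(ov)) {
        agg <- tapply(s$level[S4Vectors::queryHits(ov)],
                      S4Vectors::subjectHits(ov), mean)
        w$value[as.integer(names(agg))] <- as.numeric(agg)
      }
    }
    out[[ch]] <- w
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Transcripts per million from counts and effective lengths
#'
#' `TPM_g = 1e6 * (count_g / length_g[kbp]) / sum of rates`; when every count
#' is zero all TPM are zero (no normalization divide).
#'
#' @param counts data.frame `gene_id`, `count`, `length` (bp).
#' @return data.frame adding `tpm` and `log2_tpm1` = log2(TPM + 1).
#' @export
compute_tpm <- function(counts) {
  if (any(counts$length <= 0)) abort("effective lengths must be positive")
  rate <- counts$count / (counts$length / 1000)
  tot <- sum(rate)
  tpm <- if (tot > 0) 1e6 * rate / tot else rep(0, length(rate))
  data.frame(counts, tpm = tpm, log2_tpm1 = log2(tpm + 1),
             stringsAsFactors = FALSE)
}

#' Windowed log2 expression-coverage track
#'
#' Mean read coverage per window (intervals absent from the bedGraph count as
#' zero), transformed as `log2(mean + 1)`; the pseudocount keeps silent,
#' suppressed regions finite.
#'
#' @param bedgraph data.frame from [read_bedgraph()].
#' @param window_bp window size (default 2,500 bp; non-overlapping).
#' @param chrom_lengths named integer vector; defaults to the last covered
#'   position per chromosome.
#' @return data.frame `chrom`, `start`, `end`, `value`.
#' @export
coverage_track <- function(bedgraph, window_bp = 2500L, chrom_lengths = NULL) {
  if (window_bp <= 0) abort("window_bp must be positive")
  if (any(bedgraph$value < 0)) abort("coverage must be non-negative")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(bedgraph$end, bedgraph$chrom), max, numeric(1))
  }
  out <- list()
  for (ch in names(chrom_lengths)) {
    w <- window_frame(ch, chrom_lengths[[ch]], window_bp, window_bp)
    mass <- numeric(nrow(w))
    b <- bedgraph[bedgraph$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(b))) {
      w0 <- b$start[r] %/% window_bp + 1L
      w1 <- min(nrow(w), (b$end[r] - 1L) %/% window_bp + 1L)
      for (wi in w0:w1) {
        ovl <- min(b$end[r], w$end[wi]) - max(b$start[r], w$start[wi])
        if (ovl > 0) mass[wi] <- mass[wi] + ovl * b$value[r]
      }
    }
    w$value <- log2(mass / (w$end - w$start) + 1)
    out[[ch]] <- w
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Welch two-sample t-test from raw values (unequal variances,
# Welch-Satterthwaite degrees of freedom)
welch_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  degenerate <- FALSE
  if (se2 == 0) {
    # both groups constant: no evidence of difference unless means differ
    degenerate <- TRUE
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    df <- n1 + n2 - 2
  } else {
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  list(t = t, df = df, p = if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df),
       mean1 = m1, mean2 = m2, n1 = n1, n2 = n2, degenerate = degenerate)
}

#' Pairwise Welch t-tests across gene categories
#'
#' Compares every pair of categories (e.g. viral/non-viral crossed with
#' conserved/non-conserved) with an unequal-variance two-sided t-test.
#'
#' @param values numeric vector (e.g. log2(TPM+1) or gene methylation means).
#' @param category character/factor vector parallel to `values`.
#' @return data.frame with one row per category pair: group sizes, means,
#'   Welch `t`, `df`, two-sided `p`, and a `degenerate` flag for zero-variance
#'   guards.
#' @export
compare_categories <- function(values, category) {
  keep <- !is.na(values) & !is.na(category)
  values <- values[keep]; category <- as.character(category)[keep]
  groups <- split(values, category)
  small <- names(groups)[lengths(groups) < 2]
  if (length(small))
    abort("categories with fewer than 2 values: %s", paste(small, collapse = ", "))
  nm <- names(groups)
  rows <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (j <= i) next
    wt <- welch_test(groups[[i]], groups[[j]])
    rows[[length(rows) + 1L]] <- data.frame(
      category_a = nm[i], category_b = nm[j],
      n_a = wt$n1, n_b = wt$n2, mean_a = wt$mean1, mean_b = wt$mean2,
      t = wt$t, df = wt$df, p = wt$p, degenerate = wt$degenerate,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Fraction of methylated genes per category
#'
#' @param gene_meth output of [gene_methylation()].
#' @param category character vector parallel to `gene_meth` rows (e.g.
#'   viral/non-viral or conserved/non-conserved).
#' @return data.frame per category: `n_classified`, `n_methylated`,
#'   `pct_methylated` (100 x methylated / classified) and `n_excluded`
#'   (genes without usable CpG sites). Categories with no classifiable gene
#'   are omitted with a warning.
#' @export
methylated_fraction_by_category <- function(gene_meth, category) {
  stopifnot(length(category) == nrow(gene_meth))
  rows <- list()
  for (cat in unique(as.character(category))) {
    sel <- category == cat
    cls <- sel & !is.na(gene_meth$is_methylated)
    if (!any(cls)) {
      warn("category '%s' has no classifiable gene; row omitted", cat)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      category = cat, n_classified = sum(cls),
      n_methylated = sum(gene_meth$is_methylated[cls]),
      pct_methylated = 100 * sum(gene_meth$is_methylated[cls]) / sum(cls),
      n_excluded = sum(sel & is.na(gene_meth$is_methylated)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
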