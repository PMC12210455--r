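#' Detect telomeric repeat arrays (canonical and degenerate)
#'
#' Scans one sequence for maximal runs of at least `min_units` consecutive
#' unit-length windows, each within `max_mismatch_per_unit` of the telomeric
#' unit, in either orientation. Purity is the fraction of exact-unit windows
#' over the run; arrays with purity below 1 are flagged degenerate.
#'
#' @param sequence a [Biostrings::DNAString] or character scalar.
#' @param unit telomeric repeat unit (default TTAGGG).
#' @param max_mismatch_per_unit mismatches tolerated per unit-length window.
#' @param min_units minimum consecutive units forming an array.
#' @return data.frame `start`, `end` (0-based half-open), `orientation`
#'   (the unit or its reverse complement), `unit_count`, `purity`,
#'   `degenerate`.
#' @export
detect_telomeric_arrays <- function(sequence, unit = "TTAGGG",
                                    max_mismatch_per_unit = 1L,
                                    min_units = 3L) {
  u <- nchar(unit)
  if (u < 3) abort("telomeric unit must be at least 3 nt")
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  empty <- data.frame(start = integer(0), end = integer(0),
                      orientation = character(0), unit_count = integer(0),
                      purity = numeric(0), degenerate = logical(0))
  if (L < u * min_units) return(empty)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- list()
  for (ori in c(unit, revcomp(unit))) {
    ut <- strsplit(ori, "", fixed = TRUE)[[1]]
    n_win <- L - u + 1L
    mism <- integer(n_win)
    for (t in seq_len(u))
      mism <- mism + (chars[t:(L - u + t)] != ut[t])
    ok <- mism <= max_mismatch_per_unit
    for (phase in 0:(u - 1L)) {
      idx <- seq(1L + phase, n_win, by = u)
      if (length(idx) < min_units) next
      r <- rle(ok[idx])
      ends_i <- cumsum(r$lengths)
      starts_i <- ends_i - r$lengths + 1L
      keep <- which(r$values & r$lengths >= min_units)
      for (kk in keep) {
        win <- idx[starts_i[kk]:ends_i[kk]]
        out[[length(out) + 1L]] <- data.frame(
          start = win[1] - 1L, end = win[1] - 1L + u * length(win),
          orientation = ori, unit_count = length(win),
          purity = mean(mism[win] == 0),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  if (nrow(res)) {
    res <- res[order(res$start, res$end), , drop = FALSE]
    res$degenerate <- res$purity < 1
    rownames(res) <- NULL
  }
  res
}

#' Permutation test for sub-telomeric enrichment
#'
#' Distance to the nearest chromosome end is `min(start, length - end)`,
#' normalized by chromosome length (so values lie in \[0, 0.5\]). The null
#' keeps each feature on its chromosome with its width and redraws the start
#' uniformly; the one-sided p-value asks whether features sit closer to ends
#' than uniform placement predicts.
#'
#' @param features data.frame `chrom`, `start`, `end`.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param n_permutations at least 100.
#' @param seed RNG seed for the permutations.
#' @return list: `distances` (per-feature table), `observed_mean`, `p_value`,
#'   `n_permutations`, `null_means`.
#' @export
end_distance_enrichment <- function(features, chrom_lengths,
                                    n_permutations = 1000L, seed = 1L) {
  if (n_permutations < 100) abort("n_permutations must be >= 100")
  len <- chrom_lengths[features$chrom]
  if (any(is.na(len))) abort("feature chromosome missing from chrom_lengths")
  width <- features$end - features$start
  if (any(width > len)) abort("feature longer than its chromosome")
  dist <- pmin(features$start, len - features$end)
  norm <- dist / len
  obs <- mean(norm)
  set.seed(seed)
  nf <- nrow(features)
  null_means <- vapply(seq_len(n_permutations), function(i) {
    s <- floor(runif(nf) * (len - width + 1))
    mean(pmin(s, len - (s + width)) / len)
  }, numeric(1))
  list(distances = data.frame(chrom = features$chrom, start = features$start,
                              end = features$end, distance = dist,
                              normalized = norm),
       observed_mean = obs,
       p_value = (1 + sum(null_means <= obs)) / (n_permutations + 1),
       n_permutations = n_permutations,
       null_means = null_means)
}

#' Cross-tabulate mobile elements by class and genomic context
#'
#' Context of an element is decided by its midpoint: inside a viral region,
#' inside another (non-viral) divergent region, or conserved background.
#'
#' @param repeats data.frame `chrom`, `start`, `end`, `class`.
#' @param regions divergent-region table with `is_viral`.
#' @return class x context count matrix.
#' @export
mobile_element_context_table <- function(repeats, regions) {
  mid <- (repeats$start + repeats$end) %/% 2L
  ctx <- rep("conserved_background", nrow(repeats))
  for (k in seq_len(nrow(regions))) {
    sel <- repeats$chrom == regions$chrom[k] &
      mid >= regions$start[k] & mid < regions$end[k]
    ctx[sel] <- if (regions$is_viral[k]) "viral_region" else "other_divergent"
  }
  table(class = repeats$class,
        context = factor(ctx, levels = c("viral_region", "other_divergent",
                                         "conserved_background")))
}

#' Chi-square test of mobile-element composition across genomic contexts
#'
#' Pearson chi-square on the class x context table. When any expected count
#' falls below `min_expected`, a Monte Carlo p-value over tables with fixed
#' margins is computed in addition to the asymptotic one.
#'
#' @param tab count matrix (>= 2 rows and >= 2 columns after dropping
#'   zero-margin rows/columns).
#' @param min_expected threshold triggering the Monte Carlo computation.
#' @param monte_carlo_reps resamples for the Monte Carlo p-value.
#' @param seed RNG seed used only if Monte Carlo is triggered.
#' @return list: `statistic`, `df`, `p_value`, `expected`, `p_monte_carlo`
#'   (`NA` unless triggered), `dropped` (zero-margin dimnames removed).
#' @export
mobile_element_context_chisq <- function(tab, min_expected = 5,
                                         monte_carlo_reps = 2000L, seed = 1L) {
  tab <- as.matrix(tab)
  dropped <- character(0)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    dropped <- c(rownames(tab)[rs == 0], colnames(tab)[cs == 0])
    warn("dropping zero-margin rows/columns: %s", paste(dropped, collapse = ", "))
    tab <- tab[rs > 0, cs > 0, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    abort("need at least a 2x2 table after dropping zero margins")
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  E <- outer(rs, cs) / N
  X2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  p_mc <- NA_real_
  if (any(E < min_expected)) {
    set.seed(seed)
    sims <- stats::r2dtable(monte_carlo_reps, rs, cs)
    x2s <- vapply(sims, function(m) sum((m - E)^2 / E), numeric(1))
    p_mc <- (1 + sum(x2s >= X2)) / (monte_carlo_reps + 1)
  }
  list(statistic = X2, df = df,
       p_value = stats::pchisq(X2, df, lower.tail = FALSE),
       expected = E, p_monte_carlo = p_mc, dropped = dropped)
}

#' GC-content windows with flagged composition shifts
#'
#' Non-overlapping windows of GC fraction; a boundary between adjacent
#' windows is flagged when the GC fraction changes by more than
#' `shift_threshold`. Sudden GC shifts mark recombination joints between
#' viral insertions of distinct origin and support manual curation of region
#' boundaries.
#'
#' @param sequence a [Biostrings::DNAString] or character scalar.
#' @param window_bp window size.
#' @param shift_threshold absolute GC-fraction change flagging a boundary.
#' @return list: `windows` (`start`, `end`, `gc`), `shifts` (`boundary`,
#'   `delta`).
#' @export
gc_shift_track <- function(sequence, window_bp = 1000L, shift_threshold = 0.10) {
  if (window_bp <= 0) abort("window_bp must be positive")
  s <- Biostrings::DNAString(as.character(sequence))
  L <- length(s)
  starts <- seq(0L, max(0L, L - 1L), by = window_bp)
  ends <- pmin(starts + window_bp, L)
  v <- Biostrings::Views(s, start = starts + 1L, end = ends)
  counts <- Biostrings::letterFrequency(v, "GC")
  gc <- as.numeric(counts) / (ends - starts)
  delta <- diff(gc)
  flag <- which(abs(delta) > shift_threshold)
  list(windows = data.frame(start = starts, end = ends, gc = gc),
       shifts = data.frame(boundary = starts[flag + 1L], delta = delta[flag]))
}

# kmer -> position map keeping only kmers unique in the region and not
# low-complexity (at most 2 distinct letters approximates a DUST-style
# homopolymer/dinucleotide-run mask)
kmer_index <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(NULL)
  pos <- seq_len(L - k + 1L)
  km <- substring(s, pos, pos + k - 1L)
  tab <- table(km)
  uniq <- km %in% names(tab)[tab == 1L]
  lc <- vapply(strsplit(km, "", fixed = TRUE),
               function(x) length(unique(x)) <= 2L, logical(1))
  keep <- uniq & !lc
  stats::setNames(pos[keep] - 1L, km[keep])
}

#' Nucleotide-similarity links between divergent regions
#'
#' Desk-scale stand-in for an all-versus-all nucleotide search: shared
#' region-unique k-mers anchor each pair of regions, anchors on the same
#' alignment diagonal are chained, and each chained span of at least
#' `min_link_bp` is extended ungapped and scored by percent identity.
#' Low-complexity k-mers (at most two distinct letters) are masked before
#' anchoring. Substitution-diverged copies are recovered; indel-rich
#' relationships are out of reach of the single-diagonal chain and are a
#' documented limitation.
#'
#' @param region_seqs named character vector (or DNAStringSet) of region
#'   sequences.
#' @param k anchor k-mer size.
#' @param min_link_bp minimum chained span reported.
#' @param min_identity minimum percent identity of a reported link.
#' @return data.frame of links: region ids, matched spans on both regions
#'   (0-based half-open), `span`, `identity`, `n_anchors`.
#' @export
region_similarity_links <- function(region_seqs, k = 15L, min_link_bp = 500L,
                                    min_identity = 80) {
  seqs <- vapply(as.list(region_seqs), as.character, character(1))
  nm <- names(seqs)
  if (is.null(nm)) nm <- sprintf("region%03d", seq_along(seqs))
  short <- nchar(seqs) < k
  if (any(short)) {
    warn("skipping region(s) shorter than k: %s", paste(nm[short], collapse = ", "))
    seqs <- seqs[!short]; nm <- nm[!short]
  }
  if (length(seqs) < 2) abort("need at least 2 regions")
  idx <- lapply(seqs, kmer_index, k = k)
  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  rows <- list()
  for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
    if (j <= i) next
    shared <- intersect(names(idx[[i]]), names(idx[[j]]))
    if (!length(shared)) next
    pa <- idx[[i]][shared]; pb <- idx[[j]][shared]
    for (dg in unique(pa - pb)) {
      sel <- (pa - pb) == dg
      a0 <- min(pa[sel]); a1 <- max(pa[sel]) + k
      # ungapped extension along the diagonal to the shared overlap bounds
      lo <- max(0L, dg)                       # smallest a with b = a - dg >= 0
      hi <- min(nchar(seqs[i]), nchar(seqs[j]) + dg)
      ext <- 100L
      while (a0 - lo > 0) {
        step <- min(ext, a0 - lo)
        aa <- (a0 - step):(a0 - 1L)
        if (mean(chars[[i]][aa + 1L] == chars[[j]][aa - dg + 1L]) < 0.6) break
        a0 <- a0 - step
      }
      while (hi - a1 > 0) {
        step <- min(ext, hi - a1)
        aa <- a1:(a1 + step - 1L)
        if (mean(chars[[i]][aa + 1L] == chars[[j]][aa - dg + 1L]) < 0.6) break
        a1 <- a1 + step
      }
      span <- a1 - a0
      if (span < min_link_bp) next
      aa <- a0:(a1 - 1L)
      ident <- 100 * mean(chars[[i]][aa + 1L] == chars[[j]][aa - dg + 1L])
      if (ident < min_identity) next
      rows[[length(rows) + 1L]] <- data.frame(
        region_a = nm[i], region_b = nm[j],
        a_start = a0, a_end = a1, b_start = a0 - dg, b_end = a1 - dg,
        span = span, identity = ident, n_anchors = sum(sel),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(region_a = character(0), region_b = character(0),
                      a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      span = integer(0), identity = numeric(0),
                      n_anchors = integer(0))
  rownames(res) <- NULL
  res
}

#' Observed/expected detrending of a Hi-C contact matrix
#'
#' Expected contact frequency at separation `s` is the mean of the observed
#' matrix over all bin pairs at that separation (zeros included); the O/E
#' matrix divides each entry by the expected value of its diagonal, with 0
#' where the expected value is 0. Per-diagonal means of the result are 1 on
#' populated diagonals, i.e. the distance-dependent trend is removed.
#'
#' @param m square symmetric count matrix.
#' @param tol relative tolerance for the symmetry check.
#' @return O/E matrix; per-separation expected values in attribute
#'   `expected`.
#' @export
detrend_contact_matrix <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort("contact matrix must be square")
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m))))
    abort("contact matrix is not symmetric")
  d <- abs(row(m) - col(m))
  expected <- as.numeric(tapply(m, d, mean))
  oe <- m / expected[d + 1L]
  oe[!is.finite(oe)] <- 0
  attr(oe, "expected") <- expected
  oe
}

#' Self-contact compaction score of a genomic region
#'
#' `log2` of the mean off-diagonal O/E entry among the bins a region spans:
#' 0 means the region contacts itself exactly as often as its genomic
#' separations predict, positive values mean denser packaging.
#'
#' @param oe O/E matrix from [detrend_contact_matrix()].
#' @param start,end region coordinates (bp, 0-based half-open).
#' @param bin_bp matrix bin size.
#' @return scalar score, or `NA` when the region spans fewer than 2 bins or
#'   has no informative entries.
#' @export
region_compaction_score <- function(oe, start, end, bin_bp) {
  b0 <- start %/% bin_bp + 1L
  b1 <- min(nrow(oe), as.integer(ceiling(end / bin_bp)))
  if (b1 - b0 + 1L < 2L) {
    message("region spans fewer than 2 bins; compaction score undefined")
    return(NA_real_)
  }
  sub <- oe[b0:b1, b0:b1]
  off <- sub[row(sub) != col(sub)]
  if (!length(off) || all(off == 0)) return(NA_real_)
  log2(mean(off))
}

#' Permutation comparison of viral-region compaction against random regions
#'
#' @param oe_by_chrom named list of O/E matrices (one per chromosome).
#' @param regions region table (`chrom`, `start`, `end`); typically viral
#'   regions.
#' @param bin_bp Hi-C bin size.
#' @param chrom_lengths named integer vector.
#' @param n_permutations permutation count.
#' @param seed RNG seed.
#' @return list: `observed_mean`, `p_value`, `scores` per region,
#'   `null_means`.
#' @export
compaction_enrichment <- function(oe_by_chrom, regions, bin_bp, chrom_lengths,
                                  n_permutations = 200L, seed = 1L) {
  score_set <- function(reg) {
    s <- suppressMessages(mapply(function(ch, s0, e0)
      region_compaction_score(oe_by_chrom[[ch]], s0, e0, bin_bp),
      reg$chrom, reg$start, reg$end))
    mean(s, na.rm = TRUE)
  }
  scores <- suppressMessages(mapply(function(ch, s0, e0)
    region_compaction_score(oe_by_chrom[[ch]], s0, e0, bin_bp),
    regions$chrom, regions$start, regions$end))
  obs <- mean(scores, na.rm = TRUE)
  set.seed(seed)
  width <- regions$end - regions$start
  null_means <- vapply(seq_len(n_permutations), function(i) {
    s0 <- floor(runif(nrow(regions)) * (chrom_lengths[regions$chrom] - width))
    score_set(data.frame(chrom = regions$chrom, start = s0, end = s0 + width))
  }, numeric(1))
  list(observed_mean = obs, scores = scores,
       p_value = (1 + sum(null_means >= obs)) / (n_permutations + 1),
       null_means = null_means)
}
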