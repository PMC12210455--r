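# Independent brute-force oracles used by the unit and acceptance suites.
# Each is written as the most direct possible restatement of the rule it
# checks, with no code shared with the implementation path.

# -- ORF enumeration: explicit codon-by-codon scan ---------------------------
oracle_orfs_strand <- function(s, min_nt) {
  L <- nchar(s)
  out <- list()
  for (f in 0:2) {
    run_start <- NA_integer_
    i <- f + 1L
    while (i + 2L <= L) {
      codon <- substr(s, i, i + 2L)
      stop_here <- codon %in% c("TAA", "TAG", "TGA") || grepl("[^ACGT]", codon)
      if (stop_here) {
        if (!is.na(run_start) && i - run_start >= min_nt)
          out[[length(out) + 1L]] <- c(run_start - 1L, i - 1L, f)
        run_start <- NA_integer_
      } else if (is.na(run_start)) run_start <- i
      i <- i + 3L
    }
    if (!is.na(run_start) && i - run_start >= min_nt)
      out[[length(out) + 1L]] <- c(run_start - 1L, i - 1L, f)
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0),
                                      frame = integer(0)))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2], frame = m[, 3])
}

oracle_orfs <- function(s, min_nt = 150L) {
  fwd <- oracle_orfs_strand(s, min_nt)
  fwd$strand <- rep("+", nrow(fwd))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rev <- oracle_orfs_strand(rc, min_nt)
  L <- nchar(s)
  rev <- data.frame(start = L - rev$end, end = L - rev$start,
                    frame = rev$frame,
                    strand = rep("-", nrow(rev)))
  out <- rbind(fwd, rev)
  out[order(out$start, out$end, out$strand, out$frame), , drop = FALSE]
}

# -- conservation: per-base membership check ---------------------------------
oracle_conservation <- function(g_start, g_end, block_iv, gap_iv) {
  pos <- seq.int(g_start, g_end - 1L)
  in_any <- function(iv) {
    if (!nrow(iv)) return(rep(FALSE, length(pos)))
    Reduce(`|`, lapply(seq_len(nrow(iv)),
                       function(k) pos >= iv$start[k] & pos < iv$end[k]))
  }
  if (any(in_any(block_iv))) "conserved"
  else if (all(in_any(gap_iv))) "non_conserved"
  else "unresolved"
}

# -- region concatenation: iterate pairwise merges to fixpoint ---------------
oracle_regions <- function(iv, slack) {
  iv <- iv[order(iv$start), , drop = FALSE]
  spans <- Map(c, iv$start, iv$end)
  repeat {
    merged <- FALSE
    for (i in seq_along(spans)) {
      for (j in seq_along(spans)) {
        if (i >= j) next
        a <- spans[[i]]; b <- spans[[j]]
        if (max(a[1], b[1]) - min(a[2], b[2]) <= slack) {
          spans[[i]] <- c(min(a[1], b[1]), max(a[2], b[2]))
          spans[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  m <- do.call(rbind, spans)
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2])
}

# -- per-window mean oracle --------------------------------------------------
oracle_window_mean <- function(pos, val, w_start, w_end) {
  vapply(seq_along(w_start), function(k) {
    sel <- pos >= w_start[k] & pos < w_end[k]
    if (any(sel)) mean(val[sel]) else NA_real_
  }, numeric(1))
}

# -- per-bp coverage oracle --------------------------------------------------
oracle_coverage_windows <- function(bg, chrom_len, window_bp) {
  bp <- numeric(chrom_len)
  for (k in seq_len(nrow(bg))) bp[(bg$start[k] + 1):bg$end[k]] <- bg$value[k]
  starts <- seq(0, chrom_len - 1, by = window_bp)
  ends <- pmin(starts + window_bp, chrom_len)
  vapply(seq_along(starts), function(k)
    log2(mean(bp[(starts[k] + 1):ends[k]]) + 1), numeric(1))
}

# -- TPM closed form ---------------------------------------------------------
oracle_tpm <- function(count, len) {
  r <- count / len
  1e6 * r / sum(r)
}

# -- Hi-C O/E: explicit double loop ------------------------------------------
oracle_oe <- function(m) {
  n <- nrow(m)
  exp_s <- sapply(0:(n - 1), function(s) {
    vals <- c()
    for (i in 1:n) for (j in 1:n) if (abs(i - j) == s) vals <- c(vals, m[i, j])
    mean(vals)
  })
  oe <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    e <- exp_s[abs(i - j) + 1]
    oe[i, j] <- if (e > 0) m[i, j] / e else 0
  }
  oe
}

# -- random fixture helpers --------------------------------------------------
random_hits_df <- function(n, qid = "q1") {
  if (n == 0L)
    return(data.frame(qseqid = character(0), sseqid = character(0),
                      pident = numeric(0), length = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      evalue = numeric(0), bitscore = numeric(0)))
  data.frame(
    qseqid = qid,
    sseqid = sprintf("s%03d", sample.int(max(3, n), n, replace = TRUE)),
    pident = runif(n, 20, 90), length = sample(50:500, n, replace = TRUE),
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 10L, sstart = 1L,
    send = 10L,
    evalue = 10^-runif(n, 0, 40),
    bitscore = round(runif(n, 40, 400), 1),
    stringsAsFactors = FALSE)
}

random_taxonomy_df <- function(sseqids, p_viral = 0.4, self_genus = "Acanthamoeba",
                               p_self = 0.1) {
  u <- unique(sseqids)
  viral <- runif(length(u)) < p_viral
  genus <- ifelse(viral, "Medusavirus",
                  ifelse(runif(length(u)) < p_self, self_genus, "Dictyostelium"))
  data.frame(sseqid = u,
             superkingdom = ifelse(viral, "Viruses", "Eukaryota"),
             genus = genus, stringsAsFactors = FALSE)
}

# -- shared small simulation (cached across test files) ----------------------
.fixture_cache <- new.env(parent = emptyenv())

tiny_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    cfg <- simulation_config(seed = 7, n_chromosomes = 2,
                             chromosome_lengths = 300000L,
                             n_viral_insertions_per_strain = 3L,
                             insertion_length = c(15000L, 30000L),
                             hit_noise = 0)
    .fixture_cache$sim <- simulate_strain_pair(cfg)
  }
  .fixture_cache$sim
}

tiny_sim_dir <- function() {
  if (is.null(.fixture_cache$dir)) {
    d <- file.path(tempdir(), "gever-tiny-sim")
    emit_evidence_files(tiny_sim(), d)
    .fixture_cache$dir <- d
  }
  .fixture_cache$dir
}
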