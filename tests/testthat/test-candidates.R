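# assemble a one-chromosome assembly whose intergenic interval is exactly
# `inter`, flanked by two dummy genes
flanked_assembly <- function(inter) {
  left <- strrep("TAA", 40)
  right <- strrep("TAA", 40)
  seqs <- Biostrings::DNAStringSet(c(chr1 = paste0(left, inter, right)))
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(0L, nchar(left) + nchar(inter)),
                      end = c(nchar(left), nchar(left) + nchar(inter) + nchar(right)),
                      strand = "+", kind = "annotated_gene", intron_count = 0L)
  list(seqs = seqs, genes = genes)
}

test_that("a stop-free interval yields the forced ORF; 149 nt does not", {
  fx <- flanked_assembly(strrep("GCT", 100))       # 300 nt, no stop any frame
  orfs <- extract_intergenic_orfs(fx$seqs, fx$genes)
  plus0 <- orfs[orfs$strand == "+" & orfs$frame == 0, ]
  expect_identical(nrow(plus0), 1L)
  expect_identical(plus0$end - plus0$start, 300L)
  expect_identical(plus0$start, 120L)

  # one nucleotide below the threshold: no ORF anywhere
  fx149 <- flanked_assembly(substr(strrep("GCT", 50), 1, 149))
  expect_identical(nrow(extract_intergenic_orfs(fx149$seqs, fx149$genes)), 0L)
  # at the threshold the frame-0 stretch qualifies
  fx150 <- flanked_assembly(strrep("GCT", 50))
  orfs150 <- extract_intergenic_orfs(fx150$seqs, fx150$genes)
  expect_true(any(orfs150$strand == "+" & orfs150$frame == 0 &
                    orfs150$end - orfs150$start == 150L))
})

test_that("ambiguous codons are treated as stops and reported", {
  inter <- paste0(strrep("GCT", 60), "NNN", strrep("GCT", 60))
  fx <- flanked_assembly(inter)
  expect_message(orfs <- extract_intergenic_orfs(fx$seqs, fx$genes),
                 "ambiguous")
  plus0 <- orfs[orfs$strand == "+" & orfs$frame == 0, ]
  expect_identical(nrow(plus0), 2L)   # the N codon splits the open stretch
  expect_true(all(plus0$end - plus0$start == 180L))
})

test_that("ORF extraction equals the brute-force six-frame oracle", {
  set.seed(101)
  for (rep in 1:60) {
    L <- sample(300:2000, 1)
    inter <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")
    fx <- flanked_assembly(inter)
    got <- extract_intergenic_orfs(fx$seqs, fx$genes)
    got <- got[, c("start", "end", "strand")]
    off <- 120L
    exp <- oracle_orfs(inter)
    exp <- data.frame(start = exp$start + off, end = exp$end + off,
                      strand = exp$strand)
    rownames(got) <- rownames(exp) <- NULL
    expect_equal(got[order(got$start, got$end, got$strand), ],
                 exp[order(exp$start, exp$end, exp$strand), ],
                 ignore_attr = TRUE)
  }
})

test_that("hit ranking filters, deduplicates and sorts as specified", {
  thr <- calling_thresholds()
  tax <- data.frame(sseqid = c("a", "b", "c", "d"),
                    superkingdom = c("Eukaryota", "Eukaryota", "Viruses",
                                     "Eukaryota"),
                    genus = c("Acanthamoeba", "Dictyostelium", "Medusavirus",
                              "Homo"))
  h <- random_hits_df(4)
  h$sseqid <- c("a", "b", "c", "d")
  h$bitscore <- c(500, 100, 100, 90)
  h$evalue <- c(1e-50, 1e-5, 1e-10, 1e-4)
  r <- rank_hits(h, tax, thr)
  expect_identical(r$sseqid, c("c", "b", "d"))   # self-genus gone, tie by evalue

  # self-genus-only input gives an empty ranking
  h2 <- h[1, , drop = FALSE]
  expect_identical(nrow(rank_hits(h2, tax, thr)), 0L)

  # above-cutoff e-values are removed
  h$evalue <- c(1e-50, 0.5, 1e-10, 0.002)
  expect_identical(rank_hits(h, tax, thr)$sseqid, "c")

  # unknown subjects are excluded and counted
  h3 <- random_hits_df(3); h3$sseqid <- c("b", "zz", "c")
  r3 <- rank_hits(h3, tax, thr)
  expect_identical(attr(r3, "n_untaxed"), 1L)
  expect_false("zz" %in% r3$sseqid)
})

test_that("ranking equals a full-sort oracle on random hit sets", {
  set.seed(202)
  thr <- calling_thresholds()
  for (rep in 1:50) {
    h <- random_hits_df(50)
    tax <- random_taxonomy_df(h$sseqid)
    r <- rank_hits(h, tax, thr)
    # oracle: merge, filter, best per subject, then sort
    o <- merge(h, tax, by = "sseqid")
    o <- o[o$evalue <= thr$evalue_cutoff & o$genus != thr$self_genus, ]
    o <- o[order(-o$bitscore, o$evalue, o$sseqid), ]
    o <- o[!duplicated(o$sseqid), ]
    expect_identical(r$sseqid, o$sseqid)
    expect_identical(r$bitscore, o$bitscore)
  }
})

test_that("taxonomic vote matches the stated rule on boundary cases", {
  thr <- calling_thresholds()
  mk <- function(viral) {
    n <- length(viral)
    if (n == 0L)
      return(data.frame(qseqid = character(0), sseqid = character(0),
                        bitscore = numeric(0), evalue = numeric(0),
                        superkingdom = character(0), genus = character(0)))
    data.frame(qseqid = "q", sseqid = sprintf("s%02d", 1:n),
               bitscore = seq(300, by = -1, length.out = n),
               evalue = 10^-seq(30, by = -0.1, length.out = n),
               superkingdom = ifelse(viral, "Viruses", "Eukaryota"),
               genus = ifelse(viral, "Medusavirus", "Homo"))
  }
  # best hit viral, rest cellular
  c1 <- classify_viral_candidate(mk(c(TRUE, rep(FALSE, 9))), thr)
  expect_identical(c1$call_basis, "best_hit_viral")
  # quorum boundary: exactly 5 of 10, best hit cellular
  c2 <- classify_viral_candidate(mk(c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                                      FALSE, FALSE, FALSE, FALSE)), thr)
  expect_identical(c2$call_basis, "majority_vote")
  expect_identical(c2$n_viral_in_top_ten, 5L)
  # 4 of 10 is below quorum
  expect_null(classify_viral_candidate(mk(c(FALSE, TRUE, TRUE, TRUE, TRUE,
                                            rep(FALSE, 5))), thr))
  # short ranking: 2 of 3 passes ceil(3/2) = 2
  expect_identical(classify_viral_candidate(mk(c(FALSE, TRUE, TRUE)), thr)$call_basis,
                   "majority_vote")
  # empty ranking: none, not an error
  expect_null(classify_viral_candidate(mk(logical(0)), thr))
})

test_that("vote decisions equal a truth-table oracle on random rankings", {
  set.seed(303)
  thr <- calling_thresholds()
  for (rep in 1:2000) {
    n <- sample(0:15, 1)
    viral <- runif(n) < 0.4
    ranked <- data.frame(qseqid = rep("q", n),
                         sseqid = sprintf("s%02d", seq_len(n)),
                         bitscore = seq(300, by = -1, length.out = n),
                         evalue = rep(1e-20, n),
                         superkingdom = ifelse(viral, "Viruses", "Eukaryota"),
                         genus = rep("x", n))
    got <- classify_viral_candidate(ranked, thr)
    w <- min(10, n)
    want <- if (n == 0) NA
            else if (viral[1]) "best_hit_viral"
            else if (sum(viral[1:w]) >= ceiling(w / 2)) "majority_vote"
            else NA
    if (is.na(want)) expect_null(got) else expect_identical(got$call_basis, want)
    # a best-hit call would survive duplication of rank 1 (vote consistency)
    if (!is.null(got) && got$call_basis == "best_hit_viral") {
      dup <- rbind(ranked[1, ], ranked)
      dup$sseqid <- sprintf("s%02d", seq_len(nrow(dup)))
      expect_false(is.null(classify_viral_candidate(dup, thr)))
    }
  }
})

test_that("call_all_candidates: determinism, empty input, duplicate ids", {
  queries <- data.frame(gene_id = c("q1", "q2"), chrom = "chr1",
                        start = c(0L, 500L), end = c(300L, 900L))
  empty <- call_all_candidates(queries, random_hits_df(0),
                               random_taxonomy_df(character(0)))
  expect_identical(nrow(empty$candidates), 0L)
  expect_identical(empty$summary$n_candidates, 0L)

  dupq <- rbind(queries, queries[1, ])
  expect_error(call_all_candidates(dupq, random_hits_df(0),
                                   random_taxonomy_df(character(0))),
               "q1")

  set.seed(9)
  h <- rbind(random_hits_df(12, "q1"), random_hits_df(12, "q2"))
  tax <- random_taxonomy_df(h$sseqid)
  r1 <- call_all_candidates(queries, h, tax)
  r2 <- call_all_candidates(queries, h, tax)
  expect_identical(r1$candidates, r2$candidates)
})

test_that("e-value tightening shrinks rankings and cannot conjure viral calls", {
  # Full candidate-set monotonicity in the cutoff does NOT hold under the
  # ceil(n/2) short-ranking quorum: removing a rank-1 cellular hit, or
  # shrinking the vote window below 10, can create a candidate. The
  # properties that do hold:
  set.seed(404)
  queries <- data.frame(gene_id = sprintf("q%02d", 1:30), chrom = "chr1",
                        start = 0L, end = 300L)
  h <- do.call(rbind, lapply(queries$gene_id, function(q) {
    df <- random_hits_df(sample(3:15, 1), q)
    # one HSP per subject so filtering removes whole subjects
    df$sseqid <- sprintf("s%03d", seq_len(nrow(df)))
    df$evalue <- 10^-runif(nrow(df), 0, 10)
    df
  }))
  tax <- random_taxonomy_df(h$sseqid)
  thr_loose <- calling_thresholds(evalue_cutoff = 1e-2)
  thr_tight <- calling_thresholds(evalue_cutoff = 1e-6)
  for (q in queries$gene_id) {
    hq <- h[h$qseqid == q, ]
    rl <- rank_hits(hq, tax, thr_loose)
    rt <- rank_hits(hq, tax, thr_tight)
    # a tighter ranking is a subset of the looser one, in the same order
    expect_true(all(rt$sseqid %in% rl$sseqid))
    expect_identical(rt$sseqid, rl$sseqid[rl$sseqid %in% rt$sseqid])
  }
  # a query with no viral hit is never called at any cutoff
  tax_cell <- tax; tax_cell$superkingdom <- "Eukaryota"
  for (cut in c(1e-1, 1e-3, 1e-6, 1e-9)) {
    res <- call_all_candidates(queries, h, tax_cell,
                               calling_thresholds(evalue_cutoff = cut))
    expect_identical(nrow(res$candidates), 0L)
  }
  # an all-viral query stays a candidate until its ranking empties
  tax_vir <- tax; tax_vir$superkingdom <- "Viruses"; tax_vir$genus <- "Medusavirus"
  for (cut in c(1e-1, 1e-3, 1e-6)) {
    res <- call_all_candidates(queries, h, tax_vir,
                               calling_thresholds(evalue_cutoff = cut))
    with_hits <- unique(h$qseqid[h$evalue <= cut])
    expect_setequal(res$candidates$gene_id, with_hits)
  }
})

test_that("noise-free synthetic hits recover exactly the planted viral genes", {
  sim <- tiny_sim()
  for (st in sim$strains) {
    tg <- sim$truth$genes[sim$truth$genes$strain == st, ]
    res <- call_all_candidates(sim$genes[[st]],
                               sim$hits[sim$hits$strain == st, ],
                               sim$taxonomy, calling_thresholds())
    expect_setequal(res$candidates$gene_id, tg$gene_id[tg$origin == "viral"])
  }
})
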