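STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Thresholds for viral-candidate calling
#'
#' @param min_orf_nt minimum open reading frame length in nucleotides
#'   (default 150, i.e. 50 codons; no start codon required).
#' @param evalue_cutoff maximum e-value of a hit considered in the vote.
#' @param vote_window number of top-ranked hits entering the majority vote.
#' @param self_genus genus whose hits are excluded before ranking, so recent
#'   transfers into the host lineage are not masked by self-matches.
#' @return list of class `gever_thresholds`.
#' @export
calling_thresholds <- function(min_orf_nt = 150L, evalue_cutoff = 0.001,
                               vote_window = 10L, self_genus = "Acanthamoeba") {
  stopifnot(min_orf_nt > 0, evalue_cutoff > 0, vote_window > 0)
  structure(list(min_orf_nt = as.integer(min_orf_nt),
                 evalue_cutoff = evalue_cutoff,
                 vote_window = as.integer(vote_window),
                 self_genus = self_genus),
            class = "gever_thresholds")
}

# Scan one strand of one sequence string for maximal stop-to-stop open
# stretches >= min_nt, all three frames. Codons containing non-ACGT letters
# are treated as stops. Returns local 0-based half-open coordinates on the
# forward orientation of `s`.
scan_orfs_one_strand <- function(s, min_nt) {
  L <- nchar(s)
  out <- list()
  n_ambig <- 0L
  for (f in 0:2) {
    n_codon <- (L - f) %/% 3L
    if (n_codon * 3L < min_nt) next
    st <- f + 1L + 3L * (seq_len(n_codon) - 1L)
    codons <- substring(s, st, st + 2L)
    ambig <- grepl("[^ACGT]", codons)
    n_ambig <- n_ambig + sum(ambig)
    is_stop <- codons %in% STOP_CODONS | ambig
    r <- rle(!is_stop)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    keep <- r$values & (r$lengths * 3L >= min_nt)
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      start = f + 3L * (starts_i[keep] - 1L),
      end = f + 3L * ends_i[keep],
      frame = f, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), end = integer(0), frame = integer(0))
  attr(res, "n_ambiguous_codons") <- n_ambig
  res
}

#' Extract open reading frames from intergenic regions
#'
#' Finds all maximal stop-to-stop open stretches of at least `min_orf_nt`
#' nucleotides on both strands and all three frames of every intergenic
#' interval. No start codon is required, and stretches may abut interval
#' boundaries (degraded, pseudogenized viral fragments rarely retain intact
#' gene ends). Ambiguous codons are treated as stops and counted.
#'
#' @param assembly a [Biostrings::DNAStringSet] (one entry per chromosome).
#' @param genes annotated gene models (data.frame, 0-based half-open); their
#'   spans define the intergenic complement.
#' @param thresholds a [calling_thresholds()].
#' @return data.frame of gene models with `kind = "intergenic_orf"`, carrying
#'   `strand` and `frame` (frame is relative to the intergenic interval on the
#'   scanned strand).
#' @export
extract_intergenic_orfs <- function(assembly, genes,
                                    thresholds = calling_thresholds()) {
  min_nt <- thresholds$min_orf_nt
  out <- list()
  for (ch in names(assembly)) {
    L <- length(assembly[[ch]])
    g <- genes[genes$chrom == ch, , drop = FALSE]
    inter <- if (nrow(g)) {
      IRanges::setdiff(IRanges::IRanges(1L, L),
                       IRanges::reduce(iranges0(g$start, g$end)))
    } else IRanges::IRanges(1L, L)
    if (!length(inter)) next
    for (k in seq_along(inter)) {
      a <- IRanges::start(inter)[k] - 1L          # back to 0-based
      b <- IRanges::end(inter)[k]
      if (b - a < min_nt) next
      s <- as.character(Biostrings::subseq(assembly[[ch]], a + 1L, b))
      fwd <- scan_orfs_one_strand(s, min_nt)
      rev <- scan_orfs_one_strand(revcomp(s), min_nt)
      n_amb <- attr(fwd, "n_ambiguous_codons") + attr(rev, "n_ambiguous_codons")
      if (n_amb > 0)
        message(sprintf("%s:[%d,%d): %d ambiguous codons treated as stops",
                        ch, a, b, n_amb))
      rows <- list()
      if (nrow(fwd))
        rows$f <- data.frame(chrom = ch, start = a + fwd$start, end = a + fwd$end,
                             strand = "+", frame = fwd$frame)
      if (nrow(rev)) {
        Ls <- b - a
        rows$r <- data.frame(chrom = ch, start = a + (Ls - rev$end),
                             end = a + (Ls - rev$start),
                             strand = "-", frame = rev$frame)
      }
      if (length(rows)) out[[length(out) + 1L]] <- do.call(rbind, rows)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), frame = integer(0))
  res <- res[order(res$chrom, res$start, res$end, res$strand, res$frame), ,
             drop = FALSE]
  rownames(res) <- NULL
  data.frame(gene_id = if (nrow(res)) sprintf("orf_%s_%d_%s%d", res$chrom,
                                              res$start, res$strand, res$frame)
             else character(0),
             res[, c("chrom", "start", "end", "strand")],
             kind = rep("intergenic_orf", nrow(res)),
             intron_count = rep(0L, nrow(res)),
             frame = res$frame, stringsAsFactors = FALSE)
}

#' Rank the homology hits of one query
#'
#' Applies the e-value cutoff, removes self-genus hits (so recent transfers
#' into the host lineage are not masked), drops hits whose subject has no
#' taxonomy record, keeps the best hit per subject, and sorts by bitscore
#' (descending), then e-value (ascending), then subject id.
#'
#' @param hits data.frame of outfmt-6 hits sharing one `qseqid`.
#' @param taxonomy data.frame sseqid/superkingdom/genus.
#' @param thresholds a [calling_thresholds()].
#' @return ranked data.frame with taxonomy columns attached; the number of
#'   subjects lacking taxonomy is available as attribute `n_untaxed`.
#' @export
rank_hits <- function(hits, taxonomy, thresholds = calling_thresholds()) {
  if (nrow(hits) && length(unique(hits$qseqid)) > 1L)
    abort("rank_hits expects hits for a single query")
  ti <- match(hits$sseqid, taxonomy$sseqid)
  n_untaxed <- sum(is.na(ti) & !duplicated(hits$sseqid))
  df <- hits[!is.na(ti), , drop = FALSE]
  df$superkingdom <- taxonomy$superkingdom[ti[!is.na(ti)]]
  df$genus <- taxonomy$genus[ti[!is.na(ti)]]
  df <- df[df$evalue <= thresholds$evalue_cutoff &
             df$genus != thresholds$self_genus, , drop = FALSE]
  df <- df[order(-df$bitscore, df$evalue, df$sseqid), , drop = FALSE]
  df <- df[!duplicated(df$sseqid), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_untaxed") <- n_untaxed
  df
}

#' Classify one ranked hit list as a viral candidate (or not)
#'
#' A query is retained if its best remaining hit is viral, or if viruses make
#' up half or more of its top `vote_window` hits (quorum `ceiling(n/2)` when
#' fewer hits survive filtering).
#'
#' @param ranked output of [rank_hits()].
#' @param thresholds a [calling_thresholds()].
#' @return one-row data.frame (`gene_id`, `call_basis`, `best_viral_subject`,
#'   `best_viral_taxon`, `n_viral_in_top_ten`) or `NULL` when not retained.
#' @export
classify_viral_candidate <- function(ranked, thresholds = calling_thresholds()) {
  if (!nrow(ranked)) return(NULL)
  is_viral <- ranked$superkingdom == "Viruses"
  w <- min(thresholds$vote_window, nrow(ranked))
  n_top <- sum(is_viral[seq_len(w)])
  basis <- if (is_viral[1]) "best_hit_viral"
           else if (n_top >= ceiling(w / 2)) "majority_vote"
           else return(NULL)
  bv <- which(is_viral)[1]
  data.frame(gene_id = ranked$qseqid[1], call_basis = basis,
             best_viral_subject = ranked$sseqid[bv],
             best_viral_taxon = ranked$genus[bv],
             n_viral_in_top_ten = n_top, stringsAsFactors = FALSE)
}

#' Call viral candidates for a full query set
#'
#' @param queries gene models and intergenic ORFs (data.frame with unique
#'   `gene_id`, plus `chrom`, `start`, `end`).
#' @param hits all homology hits (outfmt-6 columns).
#' @param taxonomy subject taxonomy table.
#' @param thresholds a [calling_thresholds()].
#' @return list with `candidates` (one row per retained query, with
#'   coordinates), and `summary` (`n_queries`, `n_with_hits`, `n_candidates`,
#'   `basis` counts, `taxon_distribution` of best viral hits, `n_untaxed`).
#' @export
call_all_candidates <- function(queries, hits, taxonomy,
                                thresholds = calling_thresholds()) {
  dup <- unique(queries$gene_id[duplicated(queries$gene_id)])
  if (length(dup))
    abort("duplicate gene ids: %s", paste(head(dup, 5), collapse = ", "))
  hits <- hits[hits$qseqid %in% queries$gene_id, , drop = FALSE]
  by_q <- split(hits, hits$qseqid)
  n_untaxed <- 0L
  rows <- vector("list", length(by_q))
  for (i in seq_along(by_q)) {
    r <- rank_hits(by_q[[i]], taxonomy, thresholds)
    n_untaxed <- n_untaxed + attr(r, "n_untaxed")
    rows[[i]] <- classify_viral_candidate(r, thresholds)
  }
  cand <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(cand))
    cand <- data.frame(gene_id = character(0), call_basis = character(0),
                       best_viral_subject = character(0),
                       best_viral_taxon = character(0),
                       n_viral_in_top_ten = integer(0))
  qi <- match(cand$gene_id, queries$gene_id)
  cand$chrom <- queries$chrom[qi]
  cand$start <- queries$start[qi]
  cand$end <- queries$end[qi]
  cand <- cand[order(cand$chrom, cand$start), , drop = FALSE]
  rownames(cand) <- NULL
  list(candidates = cand,
       summary = list(
         n_queries = nrow(queries),
         n_with_hits = length(by_q),
         n_candidates = nrow(cand),
         basis = table(cand$call_basis),
         taxon_distribution = sort(table(cand$best_viral_taxon),
                                   decreasing = TRUE),
         n_untaxed = n_untaxed))
}
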