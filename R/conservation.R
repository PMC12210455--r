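HALLMARK_SET <- c("MCP", "A32_ATPase", "polB", "VLTF3", "SFII")
MERGEABLE_CATEGORIES <- c("GAP", "DUP", "JMP")
BREAKER_CATEGORIES <- c("INV", "BRK")

#' Classify cross-strain conservation of gene spans
#'
#' A gene is `conserved` if its span overlaps at least 1 bp of any confidently
#' aligned block ("wholly or partially" aligned), `non_conserved` if the span
#' lies entirely within the union of alignment GAP records, and `unresolved`
#' otherwise (e.g. beyond alignment termini, or chromosomes absent from the
#' alignment). When blocks and gaps overlap, conservation wins.
#'
#' @param genes data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param blocks aligned blocks in the same strain's coordinates (`chrom`,
#'   `start`, `end`).
#' @param diffs diff records for the same strain (`chrom`, `category`,
#'   `start`, `end`); only GAP records enter the non-conserved rule.
#' @return character vector of statuses, one per gene row.
#' @export
classify_conservation <- function(genes, blocks, diffs) {
  status <- rep("unresolved", nrow(genes))
  if (!nrow(genes)) return(character(0))
  missing_chr <- setdiff(unique(genes$chrom),
                         unique(c(blocks$chrom, diffs$chrom)))
  if (length(missing_chr))
    warn("chromosome(s) absent from the alignment: %s",
         paste(missing_chr, collapse = ", "))
  gaps <- diffs[diffs$category == "GAP", , drop = FALSE]
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    gr <- iranges0(genes$start[gi], genes$end[gi])
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    if (nrow(b)) {
      hit <- IRanges::overlapsAny(gr, iranges0(b$start, b$end))
      status[gi[hit]] <- "conserved"
    }
    g <- gaps[gaps$chrom == ch, , drop = FALSE]
    if (nrow(g)) {
      gu <- IRanges::reduce(iranges0(g$start, g$end))
      within <- IRanges::overlapsAny(gr, gu, type = "within")
      status[gi[within & status[gi] != "conserved"]] <- "non_conserved"
    }
  }
  status
}

#' Build divergent regions by concatenating contiguous diff records
#'
#' Concatenates GAP, DUP (duplication) and JMP (translocation) records whose
#' intervals overlap, abut, or fall within `merge_slack` bp of one another
#' into maximal divergent regions, separately per strain and chromosome.
#' INV and BRK records are never part of a region and terminate concatenation
#' when they span the junction between two otherwise mergeable records.
#' The operation is idempotent and order-independent.
#'
#' @param diffs diff records (`strain`, `chrom`, `category`, `start`, `end`).
#' @param merge_slack maximum gap in bp bridged between consecutive records
#'   (default 0: records must overlap or abut).
#' @return data.frame of regions: `region_id`, `strain`, `chrom`, `start`,
#'   `end`, `n_records`, `categories`.
#' @export
build_divergent_regions <- function(diffs, merge_slack = 0L) {
  if (merge_slack < 0) abort("merge_slack must be non-negative")
  bad <- setdiff(unique(diffs$category), DIFF_CATEGORIES)
  if (length(bad)) abort("unknown diff category: %s", paste(bad, collapse = ","))
  if (!"strain" %in% names(diffs)) diffs$strain <- "."
  out <- list()
  for (st in unique(diffs$strain)) for (ch in unique(diffs$chrom[diffs$strain == st])) {
    d <- diffs[diffs$strain == st & diffs$chrom == ch, , drop = FALSE]
    brk <- d[d$category %in% BREAKER_CATEGORIES, , drop = FALSE]
    d <- d[d$category %in% MERGEABLE_CATEGORIES, , drop = FALSE]
    if (!nrow(d)) next
    d <- d[order(d$start, d$end), , drop = FALSE]
    cur_s <- d$start[1]; cur_e <- d$end[1]
    cats <- d$category[1]; n_rec <- 1L
    flush <- function(s, e, n, cc) {
      out[[length(out) + 1L]] <<- data.frame(
        strain = st, chrom = ch, start = s, end = e, n_records = n,
        categories = paste(sort(unique(cc)), collapse = ","),
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(nrow(d))[-1]) {
      # a breaker blocks the join when it covers any part of the bridged
      # stretch [cur_e, start_k] (for abutting records: when it strictly
      # spans the junction point); overlapping records always merge
      blocked <- d$start[k] >= cur_e && nrow(brk) > 0 &&
        any(brk$start < d$start[k] & brk$end > cur_e)
      joinable <- (d$start[k] - cur_e <= merge_slack) && !blocked
      if (joinable) {
        cur_e <- max(cur_e, d$end[k])
        cats <- c(cats, d$category[k]); n_rec <- n_rec + 1L
      } else {
        flush(cur_s, cur_e, n_rec, cats)
        cur_s <- d$start[k]; cur_e <- d$end[k]
        cats <- d$category[k]; n_rec <- 1L
      }
    }
    flush(cur_s, cur_e, n_rec, cats)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(strain = character(0), chrom = character(0), start = integer(0),
               end = integer(0), n_records = integer(0),
               categories = character(0))
  res <- res[order(res$strain, res$chrom, res$start), , drop = FALSE]
  res <- data.frame(region_id = if (nrow(res))
    sprintf("dr_%s_%s_%d", res$strain, res$chrom, res$start) else character(0),
    res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Flag divergent regions containing at least one full viral candidate gene
#'
#' @param regions output of [build_divergent_regions()].
#' @param candidates candidate table with `chrom`, `start`, `end` (and
#'   optionally `strain`). A candidate counts only if its span is fully
#'   contained in the region; genes straddling a boundary do not count.
#' @return `regions` with `is_viral` and `n_full_viral_genes` columns.
#' @export
flag_viral_regions <- function(regions, candidates) {
  n <- integer(nrow(regions))
  has_strain <- "strain" %in% names(candidates) && "strain" %in% names(regions)
  if (nrow(regions) && nrow(candidates)) {
    for (k in seq_len(nrow(regions))) {
      sel <- candidates$chrom == regions$chrom[k] &
        candidates$start >= regions$start[k] &
        candidates$end <= regions$end[k]
      if (has_strain) sel <- sel & candidates$strain == regions$strain[k]
      n[k] <- sum(sel)
    }
  }
  regions$n_full_viral_genes <- n
  regions$is_viral <- n >= 1L
  regions
}

#' Summarize a conservation partition
#'
#' @param status character vector of per-candidate statuses in
#'   `{conserved, non_conserved, unresolved}`.
#' @return one-row data.frame: `total`, `conserved`, `non_conserved`,
#'   `unresolved`, and `pct_conserved` = 100 x conserved / total rounded to
#'   the nearest integer (`NA` when total is 0).
#' @export
summarize_conservation <- function(status) {
  bad <- setdiff(unique(status), c("conserved", "non_conserved", "unresolved"))
  if (length(bad)) abort("unknown status: %s", paste(bad, collapse = ", "))
  total <- length(status)
  cons <- sum(status == "conserved")
  data.frame(total = total, conserved = cons,
             non_conserved = sum(status == "non_conserved"),
             unresolved = sum(status == "unresolved"),
             pct_conserved = if (total > 0) as.integer(round(100 * cons / total))
                             else NA_integer_)
}

#' Score hallmark-gene completeness of viral regions
#'
#' Giant viruses carry a small set of highly conserved hallmark genes (major
#' capsid protein, A32 packaging ATPase, DNA polymerase B, VLTF3, superfamily
#' II helicase). Hits with e-value below `evalue_cutoff` (strictly) that fall
#' inside a viral region are tallied into a per-region presence/absence
#' matrix; a region has the full suite only if all five canonical hallmarks
#' are present. Unknown hallmark labels are kept under `other` but excluded
#' from the full-suite test.
#'
#' @param regions region table with `is_viral` (only viral regions scored).
#' @param hallmark_hits data.frame `chrom`, `start`, `end`, `hallmark`,
#'   `evalue` (and optionally `strain`).
#' @param evalue_cutoff strict upper bound on retained e-values.
#' @return data.frame: one row per viral region with logical columns for each
#'   hallmark, `other` (any non-canonical label), and `full_suite`.
#' @export
hallmark_completeness <- function(regions, hallmark_hits, evalue_cutoff = 1e-5) {
  vr <- regions[regions$is_viral, , drop = FALSE]
  hh <- hallmark_hits[hallmark_hits$evalue < evalue_cutoff, , drop = FALSE]
  has_strain <- "strain" %in% names(hh) && "strain" %in% names(vr)
  m <- matrix(FALSE, nrow(vr), length(HALLMARK_SET) + 1L,
              dimnames = list(NULL, c(HALLMARK_SET, "other")))
  for (k in seq_len(nrow(vr))) {
    sel <- hh$chrom == vr$chrom[k] & hh$start < vr$end[k] & hh$end > vr$start[k]
    if (has_strain) sel <- sel & hh$strain == vr$strain[k]
    lab <- hh$hallmark[sel]
    known <- lab[lab %in% HALLMARK_SET]
    m[k, unique(known)] <- TRUE
    if (any(!lab %in% HALLMARK_SET)) m[k, "other"] <- TRUE
  }
  out <- cbind(vr[, intersect(c("region_id", "strain", "chrom", "start", "end"),
                              names(vr)), drop = FALSE],
               as.data.frame(m))
  out$full_suite <- rowSums(m[, HALLMARK_SET, drop = FALSE]) == length(HALLMARK_SET)
  rownames(out) <- NULL
  out
}
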