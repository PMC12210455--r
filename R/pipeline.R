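PIPELINE_DEFAULTS <- list(
  seed = 1L,
  self_genus = "Acanthamoeba",
  min_orf_nt = 150L,            # minimum intergenic ORF length (nt)
  evalue_cutoff = 0.001,        # homology-hit e-value ceiling
  vote_window = 10L,            # top hits entering the taxonomic vote
  hallmark_evalue = 1e-5,       # strict ceiling for hallmark hits
  merge_slack = 0L,             # bp bridged when concatenating diff records
  methylation_threshold = 0.05, # gene mean classifying as methylated
  methylation_min_coverage = 5L,
  methylation_window = 5000L,   # rolling methylation window (bp)
  methylation_step = 1000L,
  coverage_window = 2500L,      # log2 expression-coverage window (bp)
  telomere_unit = "TTAGGG",
  telomere_max_mismatch = 1L,
  telomere_min_units = 3L,
  link_k = 15L,
  link_min_bp = 500L,
  link_min_identity = 80,
  gc_window = 1000L,
  gc_shift_threshold = 0.10,
  end_permutations = 1000L,
  compaction_permutations = 200L
)

#' Pipeline configuration
#'
#' All module thresholds in one flat, validated list. Unknown keys are
#' rejected outright: a silently ignored typo in a threshold corrupts an
#' analysis.
#'
#' @param ... named overrides of the documented defaults (see
#'   `geveR:::PIPELINE_DEFAULTS`).
#' @return list of class `gever_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown) || (length(over) && is.null(names(over))))
    abort("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, over)
  with(cfg, {
    stopifnot(min_orf_nt > 0, evalue_cutoff > 0, vote_window > 0,
              hallmark_evalue > 0, merge_slack >= 0,
              methylation_threshold > 0, methylation_threshold < 1,
              methylation_window > 0, methylation_step > 0,
              coverage_window > 0, telomere_min_units > 0,
              link_k > 3, end_permutations >= 100)
  })
  structure(cfg, class = "gever_pipeline_config")
}

# standard evidence-file layout produced by emit_evidence_files()
input_paths <- function(dir, strain) {
  list(fasta = file.path(dir, paste0(strain, ".fasta")),
       gff = file.path(dir, paste0(strain, ".gff3")),
       hits = file.path(dir, sprintf("hits_%s.tsv", strain)),
       methylation = file.path(dir, sprintf("methylation_%s.tsv", strain)),
       counts = file.path(dir, sprintf("counts_%s.tsv", strain)),
       coverage = file.path(dir, sprintf("coverage_%s.bedgraph", strain)),
       repeats = file.path(dir, sprintf("repeats_%s.gff3", strain)))
}

# alignment blocks in one strain's own coordinates (strainA = ref side,
# strainB = query side)
blocks_for_strain <- function(blocks, strain, ref_strain = "strainA") {
  if (strain == ref_strain) {
    data.frame(chrom = blocks$ref_chrom, start = blocks$ref_start,
               end = blocks$ref_end, pident = blocks$pident)
  } else {
    data.frame(chrom = blocks$query_chrom, start = blocks$query_start,
               end = blocks$query_end, pident = blocks$pident)
  }
}

#' Validate an evidence-file directory before running the pipeline
#'
#' Distinguishes fatal problems (missing or malformed required files) from
#' warnings (subjects without taxonomy records, methylation calls at non-CpG
#' reference positions, genes out of chromosome bounds).
#'
#' @param dir input directory in the standard layout.
#' @param strains strain names (default `strainA`/`strainB`).
#' @return list with `fatal` and `warnings` character vectors and `ok`.
#' @export
validate_inputs <- function(dir, strains = c("strainA", "strainB")) {
  fatal <- character(0); warns <- character(0)
  for (st in strains) {
    p <- input_paths(dir, st)
    for (nm in names(p)) {
      if (!file.exists(p[[nm]])) {
        fatal <- c(fatal, sprintf("missing %s file: %s", nm, p[[nm]]))
      }
    }
    if (length(fatal)) next
    genome <- tryCatch(read_genome(p$fasta), error = function(e) e)
    genes <- tryCatch(read_gene_models(p$gff), error = function(e) e)
    hits <- tryCatch(read_hits(p$hits), error = function(e) e)
    meth <- tryCatch(read_methylation(p$methylation), error = function(e) e)
    for (obj in list(genome, genes, hits, meth)) {
      if (inherits(obj, "error"))
        fatal <- c(fatal, sprintf("[%s] %s", st, conditionMessage(obj)))
    }
    if (length(fatal)) next
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    oob <- sum(is.na(lens[genes$chrom]) | genes$end > lens[genes$chrom] |
                 genes$start < 0)
    if (oob) warns <- c(warns, sprintf("[%s] %d gene(s) out of bounds", st, oob))
    # CpG check on a sample of methylation positions
    n_noncg <- 0L
    for (ch in intersect(unique(meth$chrom), names(genome))) {
      pos <- meth$position[meth$chrom == ch]
      if (length(pos) > 2000) pos <- pos[seq(1, length(pos), length.out = 2000)]
      pos <- pos[pos + 2 <= lens[[ch]]]
      di <- as.character(Biostrings::extractAt(
        genome[[ch]], IRanges::IRanges(pos + 1L, pos + 2L)))
      n_noncg <- n_noncg + sum(di != "CG")
    }
    if (n_noncg)
      warns <- c(warns, sprintf("[%s] %d sampled methylation site(s) not at a CpG",
                                st, n_noncg))
  }
  for (f in c("taxonomy.tsv", "blocks.tsv", "diffs.tsv", "hallmarks.tsv")) {
    if (!file.exists(file.path(dir, f)))
      fatal <- c(fatal, sprintf("missing %s", f))
  }
  if (!length(fatal)) {
    tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
    for (st in strains) {
      h <- read_hits(input_paths(dir, st)$hits)
      miss <- sum(!unique(h$sseqid) %in% tax$sseqid)
      if (miss) warns <- c(warns, sprintf("[%s] %d subject(s) without taxonomy",
                                          st, miss))
    }
  }
  list(fatal = fatal, warnings = warns, ok = length(fatal) == 0)
}

#' Run the full analysis on an evidence-file directory
#'
#' Executes candidate calling, conservation classification, divergent/viral
#' region construction, silencing profiling and genomic-context statistics
#' for each strain, writes all artifact tables plus a run manifest, and
#' returns the per-strain reports.
#'
#' @param dir input directory (layout of [emit_evidence_files()]).
#' @param out_dir output directory, created if needed.
#' @param config a [pipeline_config()].
#' @param strains strain names; the first is the alignment reference.
#' @return named list of per-strain reports (`candidates`, `conservation`,
#'   `regions`, `hallmarks`, `gene_methylation`, `methylated_fractions`,
#'   `expression`, `comparisons`, `telomeres`, `end_bias`,
#'   `mobile_elements`, `compaction`, `links`), invisibly.
#' @export
run_pipeline <- function(dir, out_dir, config = pipeline_config(),
                         strains = c("strainA", "strainB")) {
  stopifnot(inherits(config, "gever_pipeline_config"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    abort("cannot create %s", out_dir)
  stage <- "validate"
  res <- tryCatch({
    thr <- calling_thresholds(config$min_orf_nt, config$evalue_cutoff,
                              config$vote_window, config$self_genus)
    taxonomy <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
    blocks <- read_alignment_blocks(file.path(dir, "blocks.tsv"))
    diffs <- read_alignment_diffs(file.path(dir, "diffs.tsv"))
    hallmarks <- read_hallmarks(file.path(dir, "hallmarks.tsv"))
    reports <- list()
    for (si in seq_along(strains)) {
      st <- strains[si]
      p <- input_paths(dir, st)
      stage <- paste0(st, ":candidate_calling")
      genome <- read_genome(p$fasta)
      lens <- stats::setNames(Biostrings::width(genome), names(genome))
      genes <- read_gene_models(p$gff)
      orfs <- extract_intergenic_orfs(genome, genes, thr)
      queries <- rbind(genes[, c("gene_id", "chrom", "start", "end", "strand",
                                 "kind", "intron_count")],
                       orfs[, c("gene_id", "chrom", "start", "end", "strand",
                                "kind", "intron_count")])
      calls <- call_all_candidates(queries, read_hits(p$hits), taxonomy, thr)
      cand <- calls$candidates

      stage <- paste0(st, ":conservation_regions")
      bl <- blocks_for_strain(blocks, st, ref_strain = strains[1])
      dd <- diffs[diffs$strain == st, , drop = FALSE]
      cand$conservation_status <- classify_conservation(cand, bl, dd)
      conservation <- summarize_conservation(cand$conservation_status)
      regions <- flag_viral_regions(
        build_divergent_regions(dd, config$merge_slack), cand)
      hall <- hallmark_completeness(regions,
                                    hallmarks[hallmarks$strain == st, ],
                                    config$hallmark_evalue)

      stage <- paste0(st, ":silencing_profile")
      meth <- read_methylation(p$methylation)
      gm <- gene_methylation(meth, genes,
                             min_coverage = config$methylation_min_coverage,
                             threshold = config$methylation_threshold)
      is_cand <- genes$gene_id %in% cand$gene_id
      # category labels cover every annotated gene; the rare unresolved
      # status is lumped with conserved for the two-level summaries
      gene_status <- classify_conservation(genes, bl, dd)
      cons_lab <- ifelse(gene_status == "non_conserved",
                         "non_conserved", "conserved")
      meth_frac <- rbind(
        methylated_fraction_by_category(gm, ifelse(is_cand, "viral", "non_viral")),
        methylated_fraction_by_category(gm, cons_lab))
      mtrack <- methylation_track(meth, config$methylation_window,
                                  config$methylation_step, lens)
      expr <- compute_tpm(read_counts(p$counts))
      ei <- match(genes$gene_id, expr$gene_id)
      comparisons <- compare_categories(
        expr$log2_tpm1[ei], paste(ifelse(is_cand, "viral", "non_viral"),
                                  cons_lab, sep = "."))
      ctrack <- coverage_track(read_bedgraph(p$coverage),
                               config$coverage_window, lens)

      stage <- paste0(st, ":genome_context")
      telo <- do.call(rbind, lapply(names(genome), function(ch) {
        t <- detect_telomeric_arrays(genome[[ch]], config$telomere_unit,
                                     config$telomere_max_mismatch,
                                     config$telomere_min_units)
        if (nrow(t)) cbind(chrom = ch, t) else NULL
      }))
      vreg <- regions[regions$is_viral, , drop = FALSE]
      end_bias <- if (nrow(vreg))
        end_distance_enrichment(vreg, lens, config$end_permutations,
                                seed = derive_seed(config$seed, 10L + si))
      else NULL
      reps <- read_repeats(p$repeats)
      me_tab <- mobile_element_context_table(reps, regions)
      me_chisq <- tryCatch(
        mobile_element_context_chisq(me_tab,
                                     seed = derive_seed(config$seed, 20L + si)),
        error = function(e) NULL)
      gc_shifts <- lapply(stats::setNames(names(genome), names(genome)),
                          function(ch) gc_shift_track(genome[[ch]],
                                                      config$gc_window,
                                                      config$gc_shift_threshold))
      # links across all divergent regions: duplicate copies then link back
      # to the viral insertion they were lifted from
      lreg <- regions[regions$end - regions$start >= config$link_k, , drop = FALSE]
      links <- if (nrow(lreg) >= 2) {
        vseq <- stats::setNames(vapply(seq_len(nrow(lreg)), function(k)
          as.character(Biostrings::subseq(genome[[lreg$chrom[k]]],
                                          lreg$start[k] + 1L, lreg$end[k])),
          character(1)), lreg$region_id)
        region_similarity_links(vseq, config$link_k, config$link_min_bp,
                                config$link_min_identity)
      } else NULL
      hic_files <- Sys.glob(file.path(dir, sprintf("hic_%s_*.tsv", st)))
      oe <- list(); bin_bp <- NA_integer_
      for (hf in hic_files) {
        cm <- read_hic(hf)
        oe[[cm$chrom]] <- detrend_contact_matrix(cm$matrix)
        bin_bp <- cm$bin_bp
      }
      compaction <- if (length(oe) && nrow(vreg)) {
        vr_ok <- vreg[vreg$chrom %in% names(oe), , drop = FALSE]
        if (nrow(vr_ok))
          compaction_enrichment(oe, vr_ok, bin_bp, lens,
                                config$compaction_permutations,
                                seed = derive_seed(config$seed, 30L + si))
        else NULL
      } else NULL

      stage <- paste0(st, ":write_outputs")
      w <- function(df, name, ...) write_tsv(df, file.path(out_dir,
                                                           sprintf("%s_%s.tsv", name, st)), ...)
      w(cand, "candidates", comments = "0-based half-open coordinates")
      w(cbind(strain = st, conservation), "conservation_summary")
      w(regions, "regions", comments = "0-based half-open; is_viral per full-gene rule")
      w(hall, "hallmark_completeness")
      w(gm, "gene_methylation")
      w(meth_frac, "methylated_fractions")
      w(expr, "expression_tpm")
      w(comparisons, "category_comparisons")
      if (!is.null(telo)) w(telo, "telomeres")
      write_bedgraph(stats::setNames(mtrack[!is.na(mtrack$value), ],
                                     c("chrom", "start", "end", "value")),
                     file.path(out_dir, sprintf("methylation_track_%s.bedgraph", st)))
      write_bedgraph(ctrack, file.path(out_dir,
                                       sprintf("coverage_track_%s.bedgraph", st)))
      if (!is.null(links) && nrow(links)) w(links, "region_links")
      reports[[st]] <- list(
        strain = st, candidates = cand, candidate_summary = calls$summary,
        conservation = conservation, regions = regions, hallmarks = hall,
        gene_methylation = gm, methylated_fractions = meth_frac,
        methylation_track = mtrack, expression = expr,
        comparisons = comparisons, coverage_track = ctrack,
        telomeres = telo, end_bias = end_bias,
        mobile_elements = list(table = me_tab, chisq = me_chisq),
        gc_shifts = gc_shifts, links = links, compaction = compaction)
    }
    reports
  }, error = function(e) {
    abort("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  manifest <- list(
    package = "geveR",
    version = as.character(utils::packageVersion("geveR")),
    config = unclass(config),
    inputs = as.list(tools::md5sum(list.files(dir, full.names = TRUE))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
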