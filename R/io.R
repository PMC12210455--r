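## File dialects
##
## FASTA           : 80-column wrapped (Biostrings)
## GFF3            : 1-based closed on disk; converted to 0-based half-open
## hits TSV        : BLAST/DIAMOND outfmt-6 columns
## taxonomy TSV    : sseqid, superkingdom, genus
## blocks TSV      : ref_chrom ref_start ref_end query_chrom query_start
##                   query_end pident (0-based half-open)
## diff TSV        : strain chrom category start end, category in
##                   {GAP, DUP, JMP, INV, BRK} (0-based half-open)
## bedMethyl-like  : chrom position strand coverage methylated_count (0-based)
## bedGraph        : chrom start end value (0-based half-open)
## Hi-C triplet    : bin_i bin_j count, `# bin_bp=` and `# chrom=` header

HITS_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore")
DIFF_CATEGORIES <- c("GAP", "DUP", "JMP", "INV", "BRK")

# write a TSV with "# " comment header lines naming units and conventions
write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, colClasses = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) abort("empty table: %s", path)
  as.data.frame(data.table::fread(text = paste(lines, collapse = "\n"),
                                  sep = "\t", header = TRUE,
                                  colClasses = colClasses))
}

#' Read a genome assembly from FASTA
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' Write a genome assembly as 80-column wrapped FASTA
#' @param seqs a [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
write_genome <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based closed
#' convention GFF3 requires.
#' @param genes gene-model data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `kind`, `intron_count`).
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    lines <- sprintf("%s\tgeveR\tgene\t%d\t%d\t.\t%s\t.\tID=%s;kind=%s;intron_count=%d",
                     genes$chrom, genes$start + 1L, genes$end, genes$strand,
                     genes$gene_id, genes$kind, genes$intron_count)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read gene models from GFF3 into the internal 0-based representation
#' @param path GFF3 file.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `kind`, `intron_count`.
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), kind = character(0),
                      intron_count = integer(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad)) abort("malformed GFF3 line %d in %s", bad[1], path)
  f <- do.call(rbind, f)
  attr_field <- function(a, key) {
    m <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]*"), a))
    ifelse(lengths(regmatches(a, gregexpr(paste0("(^|;)", key, "="), a))) > 0,
           sub(paste0("^;?", key, "="), "", m), NA_character_)
  }
  at <- f[, 9]
  data.frame(
    gene_id = attr_field(at, "ID"),
    chrom = f[, 1],
    start = as.integer(f[, 4]) - 1L,
    end = as.integer(f[, 5]),
    strand = f[, 7],
    kind = {k <- attr_field(at, "kind"); ifelse(is.na(k), "annotated_gene", k)},
    intron_count = {ic <- attr_field(at, "intron_count")
                    as.integer(ifelse(is.na(ic), 0L, ic))},
    stringsAsFactors = FALSE
  )
}

#' Read ranked homology hits (outfmt-6 TSV)
#' @param path TSV with the 12 standard columns, no header row required; a
#'   header row naming the columns is tolerated.
#' @return data.frame with the 12 outfmt-6 columns.
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 12)), HITS_COLS))
  ncol1 <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  if (ncol1 != 12L)
    abort("hits TSV must have 12 outfmt-6 columns, found %d in %s", ncol1, path)
  has_header <- identical(strsplit(lines[1], "\t", fixed = TRUE)[[1]][1], "qseqid")
  df <- as.data.frame(data.table::fread(text = paste(lines, collapse = "\n"),
                                        sep = "\t", header = has_header))
  names(df) <- HITS_COLS
  df
}

#' Write homology hits as outfmt-6 TSV (with header row)
#' @export
#' @param hits data.frame containing at least the 12 outfmt-6 columns.
#' @param path output path.
write_hits <- function(hits, path) {
  write_tsv(hits[, HITS_COLS, drop = FALSE], path)
}

#' Read a subject-to-taxonomy mapping (sseqid, superkingdom, genus)
#' @param path TSV file.
#' @return data.frame.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv(path, colClasses = list(character = 1:3))
  need <- c("sseqid", "superkingdom", "genus")
  if (!all(need %in% names(df)))
    abort("taxonomy TSV must have columns %s", paste(need, collapse = ", "))
  df[, need]
}

#' Read whole-genome alignment blocks
#' @param path blocks TSV (dialect in the package's file-format notes).
#' @return data.frame with ref/query chromosome and 0-based half-open spans.
#' @export
read_alignment_blocks <- function(path) {
  df <- read_tsv(path)
  need <- c("ref_chrom", "ref_start", "ref_end", "query_chrom",
            "query_start", "query_end", "pident")
  if (!all(need %in% names(df))) abort("malformed blocks TSV: %s", path)
  df[, need]
}

#' Read alignment diff records (gaps, duplications, translocations, ...)
#' @param path diff TSV: strain, chrom, category, start, end.
#' @return data.frame; categories validated against the closed set.
#' @export
read_alignment_diffs <- function(path) {
  df <- read_tsv(path)
  need <- c("strain", "chrom", "category", "start", "end")
  if (!all(need %in% names(df))) abort("malformed diff TSV: %s", path)
  bad <- setdiff(unique(df$category), DIFF_CATEGORIES)
  if (length(bad)) abort("unknown diff category: %s", paste(bad, collapse = ", "))
  df[, need]
}

#' Read per-CpG methylation calls (bedMethyl-like TSV)
#' @param path TSV: chrom, position (0-based), strand, coverage,
#'   methylated_count.
#' @return data.frame with an added `level` column.
#' @export
read_methylation <- function(path) {
  df <- read_tsv(path)
  need <- c("chrom", "position", "strand", "coverage", "methylated_count")
  if (!all(need %in% names(df))) abort("malformed methylation TSV: %s", path)
  if (any(df$methylated_count > df$coverage))
    abort("methylated_count exceeds coverage in %s", path)
  df <- df[, need]
  df$level <- ifelse(df$coverage > 0, df$methylated_count / df$coverage, NA_real_)
  df
}

#' Read a per-gene count table (gene_id, count, length)
#' @param path TSV file.
#' @return data.frame.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "count", "length")
  if (!all(need %in% names(df))) abort("malformed count TSV: %s", path)
  df[, need]
}

#' Read a bedGraph coverage track
#'
#' Absent intervals are interpreted as zero coverage by downstream windowing.
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @return data.frame.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)
  out <- vector("list", sum(keep))
  idx <- which(keep)
  f <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 4L))
    abort("malformed bedGraph line %d in %s", idx[which(nf != 4L)[1]], path)
  m <- do.call(rbind, f)
  df <- data.frame(chrom = m[, 1], start = suppressWarnings(as.integer(m[, 2])),
                   end = suppressWarnings(as.integer(m[, 3])),
                   value = suppressWarnings(as.numeric(m[, 4])),
                   stringsAsFactors = FALSE)
  bad <- which(!stats::complete.cases(df))
  if (length(bad)) abort("malformed bedGraph line %d in %s", idx[bad[1]], path)
  df
}

#' Write a bedGraph track
#' @param df data.frame chrom/start/end/value.
#' @param path output path.
#' @export
write_bedgraph <- function(df, path) {
  data.table::fwrite(df[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read repeat/mobile-element annotations from GFF3 or BED
#' @param path GFF3 (attributes carry `class`) or 4+ column BED.
#' @return data.frame chrom/start/end/class (0-based half-open).
#' @export
read_repeats <- function(path) {
  lines <- readLines(path)
  if (any(startsWith(lines, "##gff-version"))) {
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    cls <- sub(".*class=([^;]*).*", "\\1", f[, 9])
    data.frame(chrom = f[, 1], start = as.integer(f[, 4]) - 1L,
               end = as.integer(f[, 5]), class = cls, stringsAsFactors = FALSE)
  } else {
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    data.frame(chrom = f[, 1], start = as.integer(f[, 2]),
               end = as.integer(f[, 3]),
               class = if (ncol(f) >= 4) f[, 4] else "repeat",
               stringsAsFactors = FALSE)
  }
}

write_repeats_gff3 <- function(reps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(reps)) {
    writeLines(sprintf("%s\tgeveR\tdispersed_repeat\t%d\t%d\t.\t+\t.\tclass=%s",
                       reps$chrom, reps$start + 1L, reps$end, reps$class), con)
  }
  invisible(path)
}

#' Read a binned Hi-C contact matrix from triplet TSV
#' @param path triplet TSV with `# bin_bp=` and `# chrom=` header comments.
#' @return list with `chrom`, `bin_bp` and the symmetric count `matrix`.
#' @export
read_hic <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  bin_bp <- as.integer(sub(".*bin_bp=([0-9]+).*", "\\1", hdr[grepl("bin_bp=", hdr)][1]))
  chrom <- sub(".*chrom=([^ ]+).*", "\\1", hdr[grepl("chrom=", hdr)][1])
  n_bins <- as.integer(sub(".*n_bins=([0-9]+).*", "\\1", hdr[grepl("n_bins=", hdr)][1]))
  df <- read_tsv(path)
  m <- matrix(0, n_bins, n_bins)
  m[cbind(df$bin_i, df$bin_j)] <- df$count
  m[cbind(df$bin_j, df$bin_i)] <- df$count
  list(chrom = chrom, bin_bp = bin_bp, matrix = m)
}

write_hic <- function(cm, path) {
  m <- cm$matrix
  up <- which(upper.tri(m, diag = TRUE) & m > 0, arr.ind = TRUE)
  df <- data.frame(bin_i = up[, 1], bin_j = up[, 2], count = m[up])
  df <- df[order(df$bin_i, df$bin_j), ]
  write_tsv(df, path, comments = c(
    sprintf("chrom=%s bin_bp=%d n_bins=%d", cm$chrom, cm$bin_bp, nrow(m))))
}

#' Read hallmark-gene hits (strain, chrom, start, end, hallmark, evalue)
#' @param path TSV file.
#' @return data.frame.
#' @export
read_hallmarks <- function(path) {
  df <- read_tsv(path)
  need <- c("strain", "chrom", "start", "end", "hallmark", "evalue")
  if (!all(need %in% names(df))) abort("malformed hallmark TSV: %s", path)
  df[, need]
}

#' Write the full synthetic evidence file set for a simulated strain pair
#'
#' Serializes every evidence table of a [simulate_strain_pair()] result into
#' the file dialects the analysis readers consume, plus the planted-truth
#' tables for validation.
#'
#' @param sim a `gever_sim` object.
#' @param dir output directory (created if missing).
#' @return invisibly, a named list of written paths.
#' @export
emit_evidence_files <- function(sim, dir) {
  stopifnot(inherits(sim, "gever_sim"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    abort("cannot create output directory %s", dir)
  p <- list()
  for (st in sim$strains) {
    p[[paste0("fasta_", st)]] <-
      write_genome(sim$sequences[[st]], file.path(dir, paste0(st, ".fasta")))
    p[[paste0("gff_", st)]] <-
      write_gene_models(sim$genes[[st]], file.path(dir, paste0(st, ".gff3")))
    h <- sim$hits[sim$hits$strain == st, , drop = FALSE]
    p[[paste0("hits_", st)]] <-
      write_hits(h, file.path(dir, paste0("hits_", st, ".tsv")))
    me <- sim$methylation[sim$methylation$strain == st,
                          c("chrom", "position", "strand", "coverage",
                            "methylated_count")]
    p[[paste0("methylation_", st)]] <-
      write_tsv(me, file.path(dir, paste0("methylation_", st, ".tsv")),
                comments = "positions 0-based; strand-combined CpG calls")
    cn <- sim$expression[sim$expression$strain == st,
                         c("gene_id", "count", "length")]
    p[[paste0("counts_", st)]] <-
      write_tsv(cn, file.path(dir, paste0("counts_", st, ".tsv")),
                comments = "length in bp")
    p[[paste0("coverage_", st)]] <-
      write_bedgraph(sim$coverage[sim$coverage$strain == st, ],
                     file.path(dir, paste0("coverage_", st, ".bedgraph")))
    p[[paste0("repeats_", st)]] <-
      write_repeats_gff3(sim$repeats[sim$repeats$strain == st, ],
                         file.path(dir, paste0("repeats_", st, ".gff3")))
    for (ch in names(sim$hic[[st]])) {
      cm <- sim$hic[[st]][[ch]]
      cm$chrom <- ch
      p[[paste0("hic_", st, "_", ch)]] <-
        write_hic(cm, file.path(dir, sprintf("hic_%s_%s.tsv", st, ch)))
    }
  }
  p$taxonomy <- write_tsv(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  p$blocks <- write_tsv(sim$blocks, file.path(dir, "blocks.tsv"),
                        comments = "0-based half-open; ref=strainA query=strainB")
  p$diffs <- write_tsv(sim$diffs, file.path(dir, "diffs.tsv"),
                       comments = "0-based half-open")
  p$hallmarks <- write_tsv(sim$hallmarks, file.path(dir, "hallmarks.tsv"))
  p$truth_insertions <- write_tsv(sim$truth$insertions,
                                  file.path(dir, "truth_insertions.tsv"))
  p$truth_genes <- write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  invisible(p)
}
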