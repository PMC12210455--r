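#' Simulation configuration for a synthetic two-strain genome pair
#'
#' Builds the parameter set for [simulate_strain_pair()]. Defaults describe the
#' biological situation the pipeline targets: two strains of a unicellular host
#' diverged at roughly 85% average nucleotide identity, each carrying its own
#' set of multi-gene giant-virus insertions biased toward chromosome ends,
#' hypermethylated and transcriptionally suppressed relative to a lowly
#' methylated, well-expressed host background, with host mobile elements
#' colonizing the viral regions.
#'
#' @param seed master seed; every random stream is derived from it.
#' @param n_chromosomes number of chromosomes per strain.
#' @param chromosome_lengths integer vector of chromosome lengths (bp);
#'   recycled to `n_chromosomes`.
#' @param background_divergence per-site substitution probability separating
#'   the two strains (Jukes-Cantor style uniform replacement). Default 0.15,
#'   i.e. ~85% background identity.
#' @param gene_density host genes per kbp of backbone.
#' @param n_viral_insertions_per_strain strain-specific viral insertions.
#' @param insertion_length length-2 vector `c(min, max)` bp; lengths drawn
#'   uniformly.
#' @param subtelomeric_bias probability an insertion point falls within the
#'   terminal `terminal_fraction` of a chromosome (either end).
#' @param terminal_fraction fraction of each chromosome counted as
#'   sub-telomeric for placement purposes.
#' @param duplication_fraction fraction of viral insertions that seed a
#'   partial, slightly diverged second copy elsewhere in the same genome.
#' @param mobile_element_rate expected mobile elements inserted per viral
#'   region (Poisson).
#' @param telomere_units copies of the TTAGGG unit written at each chromosome
#'   end of the ancestral sequence.
#' @param methylation_background_mean,methylation_viral_mean planted per-CpG
#'   methylated-read fractions for host background and viral regions.
#' @param methylation_coverage_mean Poisson mean of per-CpG read coverage.
#' @param expression_background,expression_viral negative-binomial mean read
#'   counts for host and viral/orphan genes.
#' @param hit_noise probability that a gene's emitted homology profile is
#'   mislabeled (host profile for a viral gene or vice versa).
#' @param gc_background,gc_viral GC content of host backbone and of viral
#'   insertion sequence; the contrast drives detectable GC shifts.
#' @param hic_bin_bp Hi-C matrix bin size.
#' @param self_genus genus label used for the host's own decoy hits.
#'
#' @return a validated list of class `gever_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 4L,
                              chromosome_lengths = 1250000L,
                              background_divergence = 0.15,
                              gene_density = 0.35,
                              n_viral_insertions_per_strain = 10L,
                              insertion_length = c(20000L, 80000L),
                              subtelomeric_bias = 0.8,
                              terminal_fraction = 0.1,
                              duplication_fraction = 0.3,
                              mobile_element_rate = 2,
                              telomere_units = 50L,
                              methylation_background_mean = 0.02,
                              methylation_viral_mean = 0.8,
                              methylation_coverage_mean = 20,
                              expression_background = 200,
                              expression_viral = 5,
                              hit_noise = 0.02,
                              gc_background = 0.58,
                              gc_viral = 0.45,
                              hic_bin_bp = 25000L,
                              self_genus = "Acanthamoeba") {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_lengths = as.integer(rep_len(chromosome_lengths, n_chromosomes)),
    background_divergence = background_divergence,
    gene_density = gene_density,
    n_viral_insertions_per_strain = as.integer(n_viral_insertions_per_strain),
    insertion_length = as.integer(insertion_length),
    subtelomeric_bias = subtelomeric_bias,
    terminal_fraction = terminal_fraction,
    duplication_fraction = duplication_fraction,
    mobile_element_rate = mobile_element_rate,
    telomere_units = as.integer(telomere_units),
    methylation_background_mean = methylation_background_mean,
    methylation_viral_mean = methylation_viral_mean,
    methylation_coverage_mean = methylation_coverage_mean,
    expression_background = expression_background,
    expression_viral = expression_viral,
    hit_noise = hit_noise,
    gc_background = gc_background,
    gc_viral = gc_viral,
    hic_bin_bp = as.integer(hic_bin_bp),
    self_genus = self_genus
  )
  probs <- c("background_divergence", "subtelomeric_bias", "terminal_fraction",
             "duplication_fraction", "hit_noise",
             "methylation_background_mean", "methylation_viral_mean",
             "gc_background", "gc_viral")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      abort("'%s' must be a probability in [0,1], got %s", p, format(v))
  }
  if (any(cfg$chromosome_lengths <= 0)) abort("chromosome lengths must be positive")
  if (length(cfg$insertion_length) != 2L || any(cfg$insertion_length <= 0) ||
      diff(cfg$insertion_length) < 0)
    abort("insertion_length must be c(min, max) with 0 < min <= max")
  if (cfg$n_viral_insertions_per_strain > 0 &&
      cfg$methylation_viral_mean <= cfg$methylation_background_mean)
    abort("viral methylation mean must exceed the background mean")
  if (cfg$n_viral_insertions_per_strain > 0 &&
      any(cfg$insertion_length[2] > cfg$chromosome_lengths))
    abort("insertion longer than a chromosome")
  structure(cfg, class = "gever_sim_config")
}

TELOMERE_UNIT <- "TTAGGG"

VIRAL_DONORS <- c("Medusavirus", "Pandoravirus", "Mollivirus", "Clandestinovirus")
CELL_GENERA <- c("Dictyostelium", "Entamoeba", "Physarum", "Naegleria",
                 "Homo", "Arabidopsis", "Saccharomyces", "Tetrahymena")
ME_CLASSES <- c("LTR_retro", "DDE_transposon", "MITE")

# Mutate a character DNA string: i.i.d. substitutions, uniform over the other
# three bases (Jukes-Cantor style). Returns the mutated string.
mutate_dna <- function(x, rate) {
  if (rate <= 0) return(x)
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  n <- length(v)
  hit <- which(runif(n) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    code <- match(v[hit], bases)
    keep <- !is.na(code)                      # leave non-ACGT untouched
    h <- hit[keep]
    code <- code[keep]
    v[h] <- bases[(code + sample.int(3, length(h), replace = TRUE) - 1L) %% 4L + 1L]
  }
  paste(v, collapse = "")
}

# Draw insertion anchor points on one chromosome's backbone with sub-telomeric
# bias, pairwise separation >= min_sep and clear of the telomeric margin.
# Errors after bounded rejection retries.
place_points <- function(n, chrom_len, margin, terminal_fraction, bias,
                         min_sep, existing = integer(0), max_tries = 2000L) {
  pts <- as.numeric(existing)
  out <- integer(0)
  lo <- margin
  hi <- chrom_len - margin
  if (hi <= lo) abort("chromosome too short for the configured margins")
  term <- max(1, round(chrom_len * terminal_fraction))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      if (runif(1) < bias) {
        p <- if (runif(1) < 0.5) {
          round(runif(1, lo, min(lo + term, hi)))
        } else {
          round(runif(1, max(lo, hi - term), hi))
        }
      } else {
        p <- round(runif(1, lo, hi))
      }
      if (!length(pts) || min(abs(pts - p)) >= min_sep) { ok <- TRUE; break }
    }
    if (!ok) abort("could not place %d non-overlapping insertions (chromosome %d bp)",
                   n, chrom_len)
    pts <- c(pts, p)
    out <- c(out, as.integer(p))
  }
  out
}

# Tile genes inside a viral insertion sequence; returns 0-based offsets.
tile_insertion_genes <- function(ins_len) {
  pos <- 300L
  starts <- integer(0); ends <- integer(0); origin <- character(0)
  while (TRUE) {
    glen <- as.integer(round(exp(rnorm(1, log(1200), 0.3))))
    if (pos + glen + 300L > ins_len) break
    starts <- c(starts, pos); ends <- c(ends, pos + glen)
    origin <- c(origin, if (runif(1) < 0.7) "viral" else "orphan")
    pos <- pos + glen + sample(200:800, 1)
  }
  data.frame(start = starts, end = ends, origin = origin,
             stringsAsFactors = FALSE)
}

# Sample per-CpG methylation evidence. levels is the planted fraction per
# site; coverage is Poisson(mean_coverage) unless poisson_coverage = FALSE,
# in which case coverage is exactly mean_coverage and, with sample_reads =
# FALSE, methylated counts are the deterministic expectation.
sim_methylation_sites <- function(chrom, positions, levels, mean_coverage,
                                  poisson_coverage = TRUE, sample_reads = TRUE) {
  n <- length(positions)
  cov <- if (poisson_coverage) rpois(n, mean_coverage) else rep(as.integer(mean_coverage), n)
  keep <- cov > 0
  cov <- cov[keep]
  m <- if (sample_reads) rbinom(length(cov), cov, levels[keep])
       else as.integer(round(cov * levels[keep]))
  data.frame(chrom = chrom, position = positions[keep], strand = "+",
             coverage = cov, methylated_count = m, stringsAsFactors = FALSE)
}

# Homology-hit profile for one gene. origin_eff is the (possibly noise-
# flipped) label driving the profile.
sim_hits_for_gene <- function(gene_id, origin_eff, donor, self_genus) {
  n <- 10L
  bits <- 300 - 15 * (seq_len(n) - 1) + round(runif(n, 0, 4), 1)
  bits <- sort(bits, decreasing = TRUE)
  ev <- signif(10^(-bits / 10), 3)
  if (origin_eff == "viral") {
    n_vir <- sample(6:9, 1)
    genus <- c(rep(donor, n_vir), sample(CELL_GENERA, n - n_vir, replace = TRUE))
    kingdom <- c(rep("Viruses", n_vir), rep("Eukaryota", n - n_vir))
  } else {
    n_vir <- if (runif(1) < 0.3) sample(1:3, 1) else 0L
    genus <- c(sample(CELL_GENERA, n - n_vir, replace = TRUE),
               rep(sample(VIRAL_DONORS, 1), n_vir))
    kingdom <- c(rep("Eukaryota", n - n_vir), rep("Viruses", n_vir))
  }
  df <- data.frame(
    qseqid = gene_id,
    sseqid = sprintf("%s|%s|h%02d", genus, gene_id, seq_len(n)),
    pident = round(runif(n, 30, 70), 1),
    length = sample(100:400, n, replace = TRUE),
    mismatch = sample(10:100, n, replace = TRUE),
    gapopen = sample(0:5, n, replace = TRUE),
    qstart = 1L, qend = 300L, sstart = 1L, send = 300L,
    evalue = ev, bitscore = bits,
    superkingdom = kingdom, genus = genus,
    stringsAsFactors = FALSE
  )
  # occasionally a decoy self-genus hit outranking everything: the self-genus
  # filter must remove it before the vote
  if (runif(1) < 0.3) {
    decoy <- df[1, ]
    decoy$sseqid <- sprintf("%s|%s|self", self_genus, gene_id)
    decoy$bitscore <- 400
    decoy$evalue <- 1e-40
    decoy$superkingdom <- "Eukaryota"
    decoy$genus <- self_genus
    df <- rbind(decoy, df)
  }
  df
}

#' Simulate a pair of related strain genomes with planted ground truth
#'
#' Strain A is the ancestral sequence plus A-specific insertions; strain B is
#' the ancestral sequence mutated at `background_divergence` per site plus
#' B-specific insertions. Each viral insertion carries tiled viral and orphan
#' genes, may seed a partial diverged duplicate elsewhere in the genome, and
#' is colonized by mobile elements. Telomeric TTAGGG arrays cap the ancestral
#' chromosome ends (so strain B's arrays are naturally degenerate). The
#' whole-genome "alignment" (blocks and per-strain diff records) is computed
#' analytically from the simulation history, as are all evidence tables:
#' homology hits with taxonomy, per-CpG methylation calls, expression counts
#' and coverage, mobile-element annotations, hallmark-gene hits, and binned
#' Hi-C contact matrices with elevated intra-insertion contact density.
#'
#' @param config a [simulation_config()].
#' @return an object of class `gever_sim`: a list with `config`, `sequences`
#'   (per-strain [Biostrings::DNAStringSet]), `genes` (per-strain annotation
#'   data.frame, 0-based half-open), `truth` (planted ground truth), `blocks`,
#'   `diffs`, `hits`, `taxonomy`, `methylation`, `expression`, `coverage`,
#'   `repeats`, `hallmarks`, and `hic`.
#' @export
simulate_strain_pair <- function(config = simulation_config()) {
  stopifnot(inherits(config, "gever_sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  strains <- c("strainA", "strainB")
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  lens <- config$chromosome_lengths
  tel_bp <- 6L * config$telomere_units

  ## ancestral backbone with telomere caps
  ancestor <- vapply(seq_along(chroms), function(i) {
    s <- random_dna(lens[i], config$gc_background)
    tel <- strrep(TELOMERE_UNIT, config$telomere_units)
    # chromosome start carries the reverse-complement orientation of the unit
    paste0(revcomp(tel), substr(s, tel_bp + 1L, lens[i] - tel_bp), tel)
  }, character(1))
  names(ancestor) <- chroms

  backbone <- list(strainA = ancestor,
                   strainB = vapply(ancestor, mutate_dna,
                                    character(1), rate = config$background_divergence))

  ## insertion events (viral insertions + partial duplicate copies)
  margin <- tel_bp + 10000L
  min_sep <- config$insertion_length[2] + 20000L
  events <- list()
  ev_id <- 0L
  for (st in strains) {
    # spread insertions across chromosomes as evenly as the count allows
    n_ins <- config$n_viral_insertions_per_strain
    chrom_of <- sample(rep_len(seq_len(config$n_chromosomes), n_ins))
    for (ci in seq_len(config$n_chromosomes)) {
      k <- sum(chrom_of == ci)
      if (k == 0) next
      pts <- place_points(k, lens[ci], margin, config$terminal_fraction,
                          config$subtelomeric_bias, min_sep)
      for (p in pts) {
        ev_id <- ev_id + 1L
        len <- as.integer(round(runif(1, config$insertion_length[1],
                                      config$insertion_length[2])))
        events[[ev_id]] <- list(strain = st, chrom = chroms[ci], point = p,
                                len = len, type = "viral",
                                id = sprintf("ins%03d", ev_id),
                                donor = sample(VIRAL_DONORS, 1),
                                seq = random_dna(len, config$gc_viral))
      }
    }
  }
  # duplicate copies: partial, lightly diverged, placed uniformly
  viral_events <- Filter(function(e) e$type == "viral", events)
  for (e in viral_events) {
    if (runif(1) >= config$duplication_fraction) next
    sub_len <- min(e$len - 100L, sample(1500:8000, 1))
    off <- sample.int(e$len - sub_len, 1)
    copy_seq <- mutate_dna(substr(e$seq, off, off + sub_len - 1L), 0.05)
    ci <- sample.int(config$n_chromosomes, 1)
    taken <- vapply(Filter(function(x) x$strain == e$strain && x$chrom == chroms[ci],
                           events), function(x) x$point, numeric(1))
    p <- place_points(1L, lens[ci], margin, config$terminal_fraction, 0,
                      min_sep, existing = taken)
    ev_id <- ev_id + 1L
    events[[ev_id]] <- list(strain = e$strain, chrom = chroms[ci], point = p,
                            len = nchar(copy_seq), type = "dup",
                            id = sprintf("dup_of_%s", e$id),
                            donor = e$donor, seq = copy_seq,
                            src = e$id, src_off = off - 1L)
  }

  ev_df <- do.call(rbind, lapply(events, function(e)
    data.frame(strain = e$strain, chrom = e$chrom, point = e$point,
               len = e$len, type = e$type, id = e$id, donor = e$donor,
               stringsAsFactors = FALSE)))
  if (is.null(ev_df)) {
    ev_df <- data.frame(strain = character(0), chrom = character(0),
                        point = integer(0), len = integer(0),
                        type = character(0), id = character(0),
                        donor = character(0), stringsAsFactors = FALSE)
  }

  # strain-coordinate start for every event (events sorted per strain/chrom)
  ev_df <- ev_df[order(ev_df$strain, ev_df$chrom, ev_df$point), , drop = FALSE]
  ev_df$strain_start <- rep(NA_integer_, nrow(ev_df))
  for (st in strains) for (ch in chroms) {
    sel <- ev_df$strain == st & ev_df$chrom == ch
    if (!any(sel)) next
    shift <- cumsum(c(0L, head(ev_df$len[sel], -1)))
    ev_df$strain_start[sel] <- ev_df$point[sel] + shift
  }
  ev_df$strain_end <- ev_df$strain_start + ev_df$len

  # map backbone position -> strain coordinate (position strictly after all
  # events whose point <= x)
  map_pos <- function(st, ch, x) {
    sel <- ev_df$strain == st & ev_df$chrom == ch
    if (!any(sel)) return(as.integer(x))
    pts <- ev_df$point[sel]; lns <- ev_df$len[sel]
    as.integer(x + vapply(x, function(xx) sum(lns[pts <= xx]), numeric(1)))
  }

  ## assemble strain sequences
  seqs <- list()
  for (st in strains) {
    ss <- character(length(chroms)); names(ss) <- chroms
    for (ch in chroms) {
      sel <- which(ev_df$strain == st & ev_df$chrom == ch)
      base <- backbone[[st]][[ch]]
      if (!length(sel)) { ss[ch] <- base; next }
      pts <- ev_df$point[sel]
      pieces <- character(0)
      prev <- 0L
      for (k in seq_along(sel)) {
        pieces <- c(pieces, substr(base, prev + 1L, pts[k]),
                    events[[which(vapply(events, function(e)
                      e$strain == st && e$id == ev_df$id[sel[k]] &&
                        e$chrom == ch && e$point == pts[k], logical(1)))[1]]]$seq)
        prev <- pts[k]
      }
      pieces <- c(pieces, substr(base, prev + 1L, nchar(base)))
      ss[ch] <- paste(pieces, collapse = "")
    }
    seqs[[st]] <- Biostrings::DNAStringSet(ss)
  }

  ## host genes on the backbone (shared ids, per-strain coordinates)
  spacing <- max(2000L, as.integer(round(1000 / config$gene_density)))
  host <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    pts_all <- ev_df$point[ev_df$chrom == ch]
    starts <- seq(margin, lens[ci] - margin - 2500L, by = spacing)
    for (s0 in starts) {
      glen <- as.integer(round(exp(rnorm(1, log(1500), 0.25))))
      e0 <- s0 + glen
      if (length(pts_all) && any(pts_all > s0 - 200L & pts_all < e0 + 200L)) next
      gi <- gi + 1L
      host[[gi]] <- data.frame(gene_id = sprintf("hostg%05d", gi), chrom = ch,
                               bb_start = s0, bb_end = e0,
                               strand = sample(c("+", "-"), 1),
                               intron_count = rpois(1, 5),
                               stringsAsFactors = FALSE)
    }
  }
  host <- if (length(host)) do.call(rbind, host) else
    data.frame(gene_id = character(0), chrom = character(0),
               bb_start = integer(0), bb_end = integer(0),
               strand = character(0), intron_count = integer(0))

  genes <- list()
  truth_genes <- list()
  for (st in strains) {
    gdf <- data.frame(
      gene_id = host$gene_id, chrom = host$chrom,
      start = NA_integer_, end = NA_integer_, strand = host$strand,
      kind = "annotated_gene", intron_count = host$intron_count,
      stringsAsFactors = FALSE)
    for (ch in unique(host$chrom)) {
      sel <- host$chrom == ch
      gdf$start[sel] <- map_pos(st, ch, host$bb_start[sel])
      gdf$end[sel] <- gdf$start[sel] + (host$bb_end[sel] - host$bb_start[sel])
    }
    tg <- data.frame(strain = st, gene_id = gdf$gene_id, origin = "host",
                     conserved = TRUE,
                     meth_state = "unmethylated", expr_tier = "high",
                     stringsAsFactors = FALSE)
    # genes inside this strain's viral insertions
    vsel <- which(ev_df$strain == st & ev_df$type == "viral")
    vg <- 0L
    for (k in vsel) {
      e <- ev_df[k, ]
      tiles <- tile_insertion_genes(e$len)
      if (!nrow(tiles)) next
      for (r in seq_len(nrow(tiles))) {
        vg <- vg + 1L
        pre <- if (tiles$origin[r] == "viral") "vg" else "og"
        gdf <- rbind(gdf, data.frame(
          gene_id = sprintf("%s_%s%04d", st, pre, vg), chrom = e$chrom,
          start = e$strain_start + tiles$start[r],
          end = e$strain_start + tiles$end[r],
          strand = sample(c("+", "-"), 1), kind = "annotated_gene",
          intron_count = rpois(1, 0.2), stringsAsFactors = FALSE))
        tg <- rbind(tg, data.frame(
          strain = st, gene_id = tail(gdf$gene_id, 1), origin = tiles$origin[r],
          conserved = FALSE, meth_state = "methylated", expr_tier = "low",
          stringsAsFactors = FALSE))
      }
    }
    gdf <- gdf[order(gdf$chrom, gdf$start), , drop = FALSE]
    rownames(gdf) <- NULL
    genes[[st]] <- gdf
    truth_genes[[st]] <- tg
  }
  truth_genes <- do.call(rbind, truth_genes)
  rownames(truth_genes) <- NULL

  ## analytic alignment: blocks per strain + diff records
  strain_len <- lapply(seqs, function(x) setNames(Biostrings::width(x), names(x)))
  blocks <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    pts <- sort(unique(c(0L, ev_df$point[ev_df$chrom == ch], lens[ci])))
    for (k in seq_len(length(pts) - 1L)) {
      a <- pts[k]; b <- pts[k + 1L]
      if (b <= a) next
      sa <- map_pos("strainA", ch, a)
      sb <- map_pos("strainB", ch, a)
      blocks[[length(blocks) + 1L]] <- data.frame(
        ref_chrom = ch, ref_start = sa, ref_end = sa + (b - a),
        query_chrom = ch, query_start = sb, query_end = sb + (b - a),
        pident = round(100 * (1 - config$background_divergence * 0.75), 2),
        stringsAsFactors = FALSE)
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(ref_chrom = character(0), ref_start = integer(0),
               ref_end = integer(0), query_chrom = character(0),
               query_start = integer(0), query_end = integer(0),
               pident = numeric(0))

  # diff records: each strain's own insertion intervals, fragmented into
  # abutting GAP/DUP/JMP pieces with GAP covering every gene-bearing piece
  diffs <- list()
  for (k in seq_len(nrow(ev_df))) {
    e <- ev_df[k, ]
    if (e$type == "dup") {
      diffs[[length(diffs) + 1L]] <- data.frame(
        strain = e$strain, chrom = e$chrom, category = "DUP",
        start = e$strain_start, end = e$strain_end, stringsAsFactors = FALSE)
      next
    }
    g <- genes[[e$strain]]
    g <- g[g$chrom == e$chrom & g$start >= e$strain_start & g$end <= e$strain_end, ]
    # candidate breakpoints: midpoints of intergenic gaps inside the insertion
    gaps <- if (nrow(g) > 1) {
      gg <- g[order(g$start), ]
      as.integer(round((head(gg$end, -1) + tail(gg$start, -1)) / 2))
    } else integer(0)
    nb <- min(length(gaps), sample(0:3, 1))
    bks <- sort(c(e$strain_start,
                  if (nb) gaps[sample.int(length(gaps), nb)], e$strain_end))
    for (f in seq_len(length(bks) - 1L)) {
      fs <- bks[f]; fe <- bks[f + 1L]
      has_gene <- nrow(g) > 0 && any(g$start >= fs & g$end <= fe)
      cat_f <- if (has_gene) "GAP" else sample(c("GAP", "DUP", "JMP"), 1)
      diffs[[length(diffs) + 1L]] <- data.frame(
        strain = e$strain, chrom = e$chrom, category = cat_f,
        start = fs, end = fe, stringsAsFactors = FALSE)
    }
  }
  diffs <- if (length(diffs)) do.call(rbind, diffs) else
    data.frame(strain = character(0), chrom = character(0),
               category = character(0), start = integer(0), end = integer(0))
  rownames(diffs) <- NULL

  ## mobile elements
  reps <- list()
  me_probs <- list(viral_region = c(0.2, 0.3, 0.5),
                   other_divergent = c(0.35, 0.3, 0.35),
                   conserved_background = c(0.55, 0.3, 0.15))
  set_me <- function(st, ch, s0, e0, context, n) {
    if (n <= 0) return(NULL)
    L <- e0 - s0
    mlen <- pmin(sample(300:2500, n, replace = TRUE), max(300L, L - 1L))
    ms <- s0 + vapply(mlen, function(l) sample.int(max(1L, L - l), 1), integer(1))
    data.frame(strain = st, chrom = ch, start = ms, end = ms + mlen,
               class = sample(ME_CLASSES, n, replace = TRUE,
                              prob = me_probs[[context]]),
               context = context, stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(ev_df))) {
    e <- ev_df[k, ]
    ctx <- if (e$type == "viral") "viral_region" else "other_divergent"
    n <- rpois(1, if (e$type == "viral") config$mobile_element_rate else 0.7)
    reps[[length(reps) + 1L]] <- set_me(e$strain, e$chrom, e$strain_start,
                                        e$strain_end, ctx, n)
  }
  for (st in strains) for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    n <- rpois(1, lens[ci] / 150000)
    # background placement on the backbone, clear of events
    ok_pts <- integer(0); tries <- 0L
    while (length(ok_pts) < n && tries < 50L * n + 50L) {
      tries <- tries + 1L
      p <- sample.int(lens[ci] - 3000L, 1)
      sel <- ev_df$strain == st & ev_df$chrom == ch
      if (any(sel) && any(abs(ev_df$point[sel] - p) < 4000)) next
      ok_pts <- c(ok_pts, p)
    }
    if (length(ok_pts)) {
      sp <- map_pos(st, ch, ok_pts)
      mlen <- sample(300:2500, length(sp), replace = TRUE)
      reps[[length(reps) + 1L]] <- data.frame(
        strain = st, chrom = ch, start = sp, end = sp + mlen,
        class = sample(ME_CLASSES, length(sp), replace = TRUE,
                       prob = me_probs$conserved_background),
        context = "conserved_background", stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, Filter(Negate(is.null), reps))
  if (is.null(reps))
    reps <- data.frame(strain = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       class = character(0), context = character(0))
  rownames(reps) <- NULL

  ## homology hits + taxonomy
  hit_rows <- list()
  flipped <- character(0)
  for (st in strains) {
    tg <- truth_genes[truth_genes$strain == st, ]
    for (r in seq_len(nrow(tg))) {
      if (tg$origin[r] == "orphan") next
      eff <- tg$origin[r]
      if (runif(1) < config$hit_noise) {
        eff <- if (eff == "viral") "host" else "viral"
        flipped <- c(flipped, tg$gene_id[r])
      }
      donor <- if (tg$origin[r] == "viral") {
        id <- tg$gene_id[r]
        # donor of the insertion the gene belongs to (lookup via coordinates)
        grow <- genes[[st]][genes[[st]]$gene_id == id, ]
        sel <- ev_df$strain == st & ev_df$type == "viral" &
          ev_df$chrom == grow$chrom & ev_df$strain_start <= grow$start &
          ev_df$strain_end >= grow$end
        if (any(sel)) ev_df$donor[which(sel)[1]] else sample(VIRAL_DONORS, 1)
      } else sample(VIRAL_DONORS, 1)
      hit_rows[[length(hit_rows) + 1L]] <-
        cbind(strain = st,
              sim_hits_for_gene(tg$gene_id[r], eff, donor, config$self_genus))
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(strain = character(0), qseqid = character(0), sseqid = character(0),
               pident = numeric(0), length = integer(0), mismatch = integer(0),
               gapopen = integer(0), qstart = integer(0), qend = integer(0),
               sstart = integer(0), send = integer(0), evalue = numeric(0),
               bitscore = numeric(0), superkingdom = character(0),
               genus = character(0))
  rownames(hits) <- NULL
  taxonomy <- unique(hits[, c("sseqid", "superkingdom", "genus")])
  rownames(taxonomy) <- NULL

  ## methylation sites from the actual strain sequences
  meth <- list()
  for (st in strains) {
    for (ch in chroms) {
      pos <- Biostrings::start(Biostrings::matchPattern("CG", seqs[[st]][[ch]])) - 1L
      lev <- rep(config$methylation_background_mean, length(pos))
      sel <- ev_df$strain == st & ev_df$chrom == ch
      for (k in which(sel)) {
        hit <- pos >= ev_df$strain_start[k] & pos < ev_df$strain_end[k]
        lev[hit] <- config$methylation_viral_mean
      }
      meth[[length(meth) + 1L]] <-
        cbind(strain = st,
              sim_methylation_sites(ch, pos, lev, config$methylation_coverage_mean))
    }
  }
  meth <- do.call(rbind, meth)
  rownames(meth) <- NULL

  ## expression: counts per gene + coverage intervals
  expr <- list(); covr <- list()
  for (st in strains) {
    g <- genes[[st]]
    tg <- truth_genes[truth_genes$strain == st, ]
    tier <- tg$expr_tier[match(g$gene_id, tg$gene_id)]
    mu <- ifelse(tier == "high", config$expression_background,
                 config$expression_viral)
    cnt <- rnbinom(nrow(g), mu = mu, size = 2)
    expr[[st]] <- data.frame(strain = st, gene_id = g$gene_id, count = cnt,
                             length = g$end - g$start, stringsAsFactors = FALSE)
    val <- round(cnt * 150 / (g$end - g$start), 3)
    keep <- val > 0
    covr[[st]] <- data.frame(strain = st, chrom = g$chrom[keep],
                             start = g$start[keep], end = g$end[keep],
                             value = val[keep], stringsAsFactors = FALSE)
    covr[[st]] <- covr[[st]][order(covr[[st]]$chrom, covr[[st]]$start), ]
  }
  expr <- do.call(rbind, expr); rownames(expr) <- NULL
  covr <- do.call(rbind, covr); rownames(covr) <- NULL

  ## hallmark hits inside viral insertions (VLTF3/SFII deliberately absent:
  ## endogenized fragments never carry the full replication suite)
  hall <- list()
  for (k in which(ev_df$type == "viral")) {
    e <- ev_df[k, ]
    nh <- sample(1:3, 1)
    hm <- sample(c("MCP", "A32_ATPase", "polB"), nh)
    s0 <- e$strain_start + sort(sample.int(max(2L, e$len - 1000L), nh))
    hall[[length(hall) + 1L]] <- data.frame(
      strain = e$strain, chrom = e$chrom, start = s0, end = s0 + 900L,
      hallmark = hm, evalue = 10^-runif(nh, 8, 30), stringsAsFactors = FALSE)
  }
  hall <- if (length(hall)) do.call(rbind, hall) else
    data.frame(strain = character(0), chrom = character(0), start = integer(0),
               end = integer(0), hallmark = character(0), evalue = numeric(0))
  rownames(hall) <- NULL

  ## Hi-C: distance decay + elevated intra-insertion contact density
  hic <- list()
  bs <- config$hic_bin_bp
  for (st in strains) {
    hic[[st]] <- list()
    for (ch in chroms) {
      L <- strain_len[[st]][[ch]]
      nb <- as.integer(ceiling(L / bs))
      d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
      mu <- 400 / (1 + d)
      sel <- ev_df$strain == st & ev_df$chrom == ch & ev_df$type == "viral"
      for (k in which(sel)) {
        b0 <- floor(ev_df$strain_start[k] / bs) + 1L
        b1 <- min(nb, ceiling(ev_df$strain_end[k] / bs))
        if (b1 > b0) mu[b0:b1, b0:b1] <- mu[b0:b1, b0:b1] * 3
      }
      up <- upper.tri(mu, diag = TRUE)
      m <- matrix(0, nb, nb)
      m[up] <- rpois(sum(up), mu[up])
      m <- m + t(m) - diag(diag(m))
      hic[[st]][[ch]] <- list(bin_bp = bs, matrix = m)
    }
  }

  truth <- list(
    insertions = ev_df[ev_df$type == "viral",
                       c("strain", "chrom", "strain_start", "strain_end",
                         "donor", "id")],
    duplications = ev_df[ev_df$type == "dup",
                         c("strain", "chrom", "strain_start", "strain_end",
                           "donor", "id")],
    genes = truth_genes,
    mobile_elements = reps,
    noise_flipped_genes = flipped
  )
  names(truth$insertions)[3:4] <- c("start", "end")
  names(truth$duplications)[3:4] <- c("start", "end")
  rownames(truth$insertions) <- rownames(truth$duplications) <- NULL

  structure(list(config = config, strains = strains,
                 sequences = seqs, genes = genes, truth = truth,
                 blocks = blocks, diffs = diffs, hits = hits,
                 taxonomy = taxonomy, methylation = meth,
                 expression = expr, coverage = covr, repeats = reps,
                 hallmarks = hall, hic = hic),
            class = "gever_sim")
}
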