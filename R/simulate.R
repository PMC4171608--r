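# Synthetic cohort generator: a stated world with planted case-enriched
# genotypes. Defaults describe the canonical discovery scenario used by the
# acceptance suite: 500 loci, 100 cases / 100 controls, 20 planted CAML
# genotypes with control carrier frequency 0.2 and case carrier frequency
# 0.6 (relative risk 3), depth ~ Poisson(30), 100-nt reads.
#
# All randomness flows from config$seed; each stage reseeds with a fixed
# offset so repeated runs are identical.

#' Simulation configuration
#'
#' @param seed Master seed (all stages derive from it; keep below 2^31 - 10).
#' @param n_loci Number of planted microsatellite loci.
#' @param n_case,n_control Cohort sizes.
#' @param motif_set Motifs sampled for planted loci.
#' @param n_caml Number of loci with a planted case-enriched genotype.
#' @param control_carrier_freq,case_carrier_freq Carrier frequency of the
#'   planted variant genotype in controls and cases (defaults 0.2 / 0.6,
#'   i.e. relative risk 3).
#' @param null_variant_freq_range Range of the per-locus variant-genotype
#'   frequency at unplanted loci (shared by both cohorts).
#' @param depth_mean Mean spanning-read depth per locus (Poisson).
#' @param read_length Read length in nucleotides (100, Illumina-style).
#' @param base_error_rate Per-base substitution probability in reads.
#' @param stutter_rate Per-read probability of a +/- 1 repeat-unit slip.
#' @param dropout_rate Per-sample, per-locus probability that the locus is
#'   uncallable (low coverage).
#' @param tract_length_range Reference tract lengths planted (nt).
#' @param spacer Unique-sequence separation between planted tracts (>= 300).
#' @param exon_fraction Fraction of loci placed inside a synthetic exon.
#' @param case_label,control_label Cohort labels.
#' @return A list of class `caml_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_loci = 500L, n_case = 100L,
                       n_control = 100L,
                       motif_set = c("A", "C", "AC", "AG", "AT",
                                     "AAC", "AAG", "AAT", "ATC"),
                       n_caml = 20L,
                       control_carrier_freq = 0.2,
                       case_carrier_freq = 0.6,
                       null_variant_freq_range = c(0.05, 0.30),
                       depth_mean = 30, read_length = 100L,
                       base_error_rate = 0, stutter_rate = 0,
                       dropout_rate = 0.02,
                       tract_length_range = c(12L, 20L),
                       spacer = 300L, exon_fraction = 0.3,
                       case_label = "CASE", control_label = "CONTROL") {
  cfg <- list(seed = as.integer(seed), n_loci = as.integer(n_loci),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              motif_set = motif_set, n_caml = as.integer(n_caml),
              control_carrier_freq = control_carrier_freq,
              case_carrier_freq = case_carrier_freq,
              null_variant_freq_range = null_variant_freq_range,
              depth_mean = depth_mean, read_length = as.integer(read_length),
              base_error_rate = base_error_rate,
              stutter_rate = stutter_rate, dropout_rate = dropout_rate,
              tract_length_range = as.integer(tract_length_range),
              spacer = as.integer(spacer), exon_fraction = exon_fraction,
              case_label = case_label, control_label = control_label)
  stopifnot(cfg$seed < 2^31 - 10, cfg$n_caml <= cfg$n_loci,
            cfg$depth_mean > 0, cfg$spacer >= cfg$read_length + 10L,
            all(c(cfg$base_error_rate, cfg$stutter_rate, cfg$dropout_rate,
                  cfg$control_carrier_freq, cfg$case_carrier_freq) >= 0),
            all(c(cfg$base_error_rate, cfg$stutter_rate, cfg$dropout_rate,
                  cfg$control_carrier_freq, cfg$case_carrier_freq) <= 1))
  structure(cfg, class = "caml_sim_config")
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Spacer that creates no tandem run >= 8 nt in the junction windows (last 7
# bases of the previous assembly, the spacer itself, first 7 bases of the
# next tract) and whose last base cannot extend the next tract leftward.
# Any run straddling a junction must recruit at least one spacer base, so a
# window run of >= 8 flags it while pure 7-base tract stubs stay below.
make_spacer <- function(len, prev_tail, next_tract) {
  next_head <- substr(next_tract, 1L, 7L)
  for (try in 1:100) {
    s <- random_bases(len)
    if (nzchar(next_tract)) {
      k <- attr(next_tract, "unit")
      last_forbidden <- substr(next_tract, k, k)
      if (substr(s, len, len) == last_forbidden) {
        repl <- sample(setdiff(c("A", "C", "G", "T"), last_forbidden), 1L)
        substr(s, len, len) <- repl
      }
    }
    window <- paste0(prev_tail, s, next_head)
    if (nrow(detect_repeats(window, "w", min_length = 8L)) == 0L) return(s)
  }
  stop("could not generate a repeat-free spacer")
}

#' Simulate a reference sequence with planted microsatellites
#'
#' Builds a single synthetic chromosome (`"sim1"`) of `n_loci` perfect
#' tandem tracts separated by at least `spacer` bases of repeat-free unique
#' sequence, together with the truth catalog (coordinates, motif, flanks,
#' region class) and a matching synthetic exon annotation.
#'
#' @param config A [sim_config()].
#' @return List: `reference` ([Biostrings::DNAStringSet]), `catalog`
#'   (truth catalog `data.frame`), `exons` (synthetic exon BED-like
#'   `data.frame`).
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  n <- config$n_loci
  motifs <- sample(config$motif_set, n, replace = TRUE)
  lens <- integer(n)
  tracts <- character(n)
  for (i in seq_len(n)) {
    k <- nchar(motifs[i])
    lo <- max(2L * k, config$tract_length_range[1L])
    units <- seq.int(ceiling(lo / k),
                     max(ceiling(lo / k),
                         floor(config$tract_length_range[2L] / k)))
    u <- if (length(units) == 1L) units else sample(units, 1L)
    lens[i] <- u * k
    tracts[i] <- strrep(motifs[i], u)
  }
  pieces <- character(2L * n + 1L)
  starts <- integer(n)
  pos <- 0L
  prev_tail <- ""
  for (i in seq_len(n)) {
    nt <- tracts[i]
    attr(nt, "unit") <- nchar(motifs[i])
    sp <- make_spacer(config$spacer, prev_tail, nt)
    pieces[2L * i - 1L] <- sp
    pos <- pos + nchar(sp)
    starts[i] <- pos
    pieces[2L * i] <- tracts[i]
    pos <- pos + lens[i]
    # keep only the last 7 assembled bases: a junction-spanning run that
    # recruits even one spacer base then shows up as a run of length >= 8 in
    # the spacer check window, while a pure tract tail alone stays below it
    tail_src <- paste0(sp, tracts[i])
    prev_tail <- substr(tail_src, nchar(tail_src) - 6L, nchar(tail_src))
  }
  pieces[2L * n + 1L] <- make_spacer(config$spacer, prev_tail, "")
  genome <- paste(pieces, collapse = "")
  reference <- Biostrings::DNAStringSet(genome)
  names(reference) <- "sim1"

  ends <- starts + lens
  catalog <- data.frame(
    locus_id = locus_id("sim1", starts, ends),
    chrom = "sim1", start = starts, end = ends,
    motif = motifs, ref_length = lens,
    left_flank = substring(genome, starts - 9L, starts),
    right_flank = substring(genome, ends + 1L, ends + 10L),
    region_class = "intergenic", gene = NA_character_,
    stringsAsFactors = FALSE
  )

  exonic <- sort(sample(n, round(config$exon_fraction * n)))
  exons <- data.frame(
    chrom = "sim1",
    start = pmax(0L, catalog$start[exonic] - 50L),
    end = catalog$end[exonic] + 50L,
    gene = sprintf("GENE%04d", exonic),
    stringsAsFactors = FALSE
  )
  catalog$region_class[exonic] <- "exon"
  catalog$gene[exonic] <- exons$gene
  list(reference = reference, catalog = catalog, exons = exons)
}

#' Simulate cohort genotypes at truth-catalog loci
#'
#' Controls draw the per-locus variant genotype (a one-unit expansion of the
#' reference tract) at the locus' variant frequency; cases draw it at the
#' same frequency except at the planted CAML loci, where the carrier
#' frequency is `case_carrier_freq` (vs `control_carrier_freq` in controls).
#' All other loci are exchangeable between cohorts. A `dropout_rate` fraction
#' of sample x locus calls is marked `low_coverage`.
#'
#' @param config A [sim_config()].
#' @param catalog Truth catalog from [simulate_reference()].
#' @return List: `genotypes` (long cohort genotype table), `labels`
#'   (`sample_id`, `cohort`), `truth` (planted loci with their case-enriched
#'   genotype and the carrier frequencies).
#' @export
simulate_cohort_genotypes <- function(config, catalog) {
  set.seed(config$seed + 1L)
  n <- nrow(catalog)
  k <- nchar(catalog$motif)
  L <- catalog$ref_length
  ref_gt <- paste0(L, "/", L)
  var_gt <- paste0(L, "/", L + k)

  planted <- sort(sample(n, config$n_caml))
  freq_control <- stats::runif(n, config$null_variant_freq_range[1L],
                               config$null_variant_freq_range[2L])
  freq_case <- freq_control
  freq_control[planted] <- config$control_carrier_freq
  freq_case[planted] <- config$case_carrier_freq

  samples <- data.frame(
    sample_id = c(sprintf("case%03d", seq_len(config$n_case)),
                  sprintf("ctrl%03d", seq_len(config$n_control))),
    cohort = c(rep(config$case_label, config$n_case),
               rep(config$control_label, config$n_control)),
    stringsAsFactors = FALSE
  )
  pieces <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    freq <- if (samples$cohort[s] == config$case_label) freq_case
            else freq_control
    carrier <- stats::runif(n) < freq
    drop <- stats::runif(n) < config$dropout_rate
    gt <- ifelse(carrier, var_gt, ref_gt)
    a <- ifelse(carrier, L, L)
    b <- ifelse(carrier, L + k, L)
    depth <- stats::rpois(n, config$depth_mean)
    depth[drop] <- pmin(depth[drop], 14L)
    status <- ifelse(drop, "low_coverage", "called")
    pieces[[s]] <- data.table::data.table(
      sample_id = samples$sample_id[s], cohort = samples$cohort[s],
      locus_id = catalog$locus_id,
      allele_a = ifelse(drop, NA_integer_, a),
      allele_b = ifelse(drop, NA_integer_, b),
      depth = depth, status = status,
      genotype = ifelse(drop, NA_character_, gt)
    )
  }
  genotypes <- data.table::rbindlist(pieces)
  truth <- data.frame(locus_id = catalog$locus_id[planted],
                      genotype = var_gt[planted],
                      control_freq = rep(config$control_carrier_freq,
                                         length(planted)),
                      case_freq = rep(config$case_carrier_freq,
                                      length(planted)),
                      stringsAsFactors = FALSE)
  list(genotypes = genotypes, labels = samples, truth = truth)
}

#' Simulate aligned reads realizing truth genotypes
#'
#' For each sample x locus, spanning-read depth is drawn from
#' `Poisson(depth_mean)` (a dropout locus instead gets sub-threshold depth);
#' each read is drawn from one of the two alleles uniformly, placed uniformly
#' among the offsets that span the tract plus 5 anchoring bases on each side,
#' stuttered by one repeat unit with probability `stutter_rate`, and
#' substituted per base at `base_error_rate`. Reads are written as one SAM
#' file per sample.
#'
#' @param config A [sim_config()].
#' @param reference Reference from [simulate_reference()].
#' @param catalog Truth catalog.
#' @param genotypes Truth genotype table from [simulate_cohort_genotypes()].
#' @param out_dir Output directory for SAM files.
#' @return Manifest `data.frame` (`sample_id`, `cohort`, `path`).
#' @export
simulate_reads <- function(config, reference, catalog, genotypes, out_dir) {
  set.seed(config$seed + 2L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- as.character(reference[[1L]])
  chrom <- names(reference)[1L]
  rl <- config$read_length
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, nchar(genome)))
  gt <- data.table::as.data.table(genotypes)
  samples <- unique(gt$sample_id)
  manifest <- data.frame(sample_id = samples,
                         cohort = gt$cohort[match(samples, gt$sample_id)],
                         path = file.path(out_dir, paste0(samples, ".sam")),
                         stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  for (s in seq_along(samples)) {
    sub <- gt[gt$sample_id == samples[s], ]
    sub <- sub[match(catalog$locus_id, sub$locus_id), ]
    lines <- vector("list", nrow(catalog))
    for (i in seq_len(nrow(catalog))) {
      loc <- catalog[i, ]
      k <- nchar(loc$motif)
      depth <- stats::rpois(1L, config$depth_mean)
      if (sub$status[i] != "called") depth <- min(depth, 14L)
      if (depth == 0L) next
      alleles <- c(sub$allele_a[i], sub$allele_b[i])
      if (any(is.na(alleles))) alleles <- c(loc$ref_length, loc$ref_length)
      pick <- sample(1:2, depth, replace = TRUE)
      a_len <- alleles[pick]
      stut <- stats::runif(depth) < config$stutter_rate
      a_len[stut] <- pmax(k, a_len[stut] +
                            sample(c(-k, k), sum(stut), replace = TRUE))
      left_ctx <- substring(genome, loc$start - rl + 1L, loc$start)
      right_ctx <- substring(genome, loc$end + 1L, loc$end + rl)
      reads <- character(depth)
      poss <- integer(depth)
      for (r in seq_len(depth)) {
        A <- a_len[r]
        tract <- substr(strrep(loc$motif, ceiling(A / k)), 1L, A)
        segment <- paste0(left_ctx, tract, right_ctx)
        ts <- rl + 1L; te <- rl + A
        o_min <- te + 5L - rl + 1L
        o_max <- ts - 5L
        if (o_max < o_min) next  # tract too long for the read length
        o <- sample(seq.int(o_min, o_max), 1L)
        read <- substr(segment, o, o + rl - 1L)
        if (config$base_error_rate > 0) {
          nerr <- stats::rbinom(1L, rl, config$base_error_rate)
          if (nerr > 0L) {
            posns <- sample(rl, nerr)
            rc <- strsplit(read, "", fixed = TRUE)[[1L]]
            rc[posns] <- vapply(rc[posns], function(x) {
              sample(setdiff(bases, x), 1L)
            }, character(1L))
            read <- paste(rc, collapse = "")
          }
        }
        reads[r] <- read
        # naive reference coordinate of the read start (left context is
        # reference-aligned)
        poss[r] <- loc$start - rl + o
      }
      keep <- nzchar(reads)
      if (!any(keep)) next
      lines[[i]] <- sprintf(
        "%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
        sprintf("r_%s_%d_%d", samples[s], i, seq_len(sum(keep))),
        chrom, poss[keep], rl, reads[keep], strrep("I", rl))
    }
    writeLines(c(header, unlist(lines)), manifest$path[s])
  }
  manifest
}

#' Generate a complete end-to-end pipeline fixture
#'
#' One call produces everything needed to exercise
#' catalog -> genotype -> association -> classification -> annotation:
#' reference FASTA, exon BED, truth catalog and genotype tables, per-sample
#' SAM files, a cohort manifest, and random CpG-island / TFBS tracks.
#'
#' @param config A [sim_config()].
#' @param out_dir Directory to write files into.
#' @return List of in-memory objects (`reference`, `catalog`, `exons`,
#'   `genotypes`, `labels`, `truth`, `manifest`, `cpg_track`, `tfbs_track`)
#'   and file paths (`fasta`, `exons_bed`, `manifest_tsv`, `cpg_bed`,
#'   `tfbs_bed`, `truth_tsv`).
#' @export
end_to_end_fixture <- function(config, out_dir = tempfile("camlfix")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(config)
  sim <- simulate_cohort_genotypes(config, ref$catalog)
  manifest <- simulate_reads(config, ref$reference, ref$catalog,
                             sim$genotypes, file.path(out_dir, "reads"))

  set.seed(config$seed + 3L)
  glen <- Biostrings::width(ref$reference)[1L]
  n_feat <- max(3L, round(nrow(ref$catalog) / 4))
  cpg <- sort(sample(glen - 200L, n_feat))
  tfbs <- sort(sample(glen - 30L, n_feat))
  cpg_track <- data.frame(chrom = "sim1", start = cpg, end = cpg + 200L)
  tfbs_track <- data.frame(chrom = "sim1", start = tfbs, end = tfbs + 20L)

  fasta <- file.path(out_dir, "reference.fa")
  Biostrings::writeXStringSet(ref$reference, fasta)
  exons_bed <- file.path(out_dir, "exons.bed")
  write_bed(ref$exons, exons_bed)
  cpg_bed <- file.path(out_dir, "cpg.bed")
  write_bed(cpg_track, cpg_bed)
  tfbs_bed <- file.path(out_dir, "tfbs.bed")
  write_bed(tfbs_track, tfbs_bed)
  manifest_tsv <- file.path(out_dir, "manifest.tsv")
  data.table::fwrite(manifest, manifest_tsv, sep = "\t")
  truth_tsv <- file.path(out_dir, "truth_caml.tsv")
  data.table::fwrite(sim$truth, truth_tsv, sep = "\t")

  c(ref, sim,
    list(manifest = manifest, cpg_track = cpg_track,
         tfbs_track = tfbs_track, fasta = fasta, exons_bed = exons_bed,
         manifest_tsv = manifest_tsv, cpg_bed = cpg_bed,
         tfbs_bed = tfbs_bed, truth_tsv = truth_tsv, out_dir = out_dir))
}
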