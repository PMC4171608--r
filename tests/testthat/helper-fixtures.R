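# Programmatic fixtures: a hand-audited toy genome for the catalog filters,
# SAM writers for the genotyper, and compact genotype-table builders.

BASES <- c("A", "C", "G", "T")

rand_bases <- function(n) paste(sample(BASES, n, TRUE), collapse = "")

# repeat-free spacer whose terminal bases cannot extend the flanking tracts
toy_spacer <- function(n, head_forbid = character(), tail_forbid = character()) {
  repeat {
    s <- rand_bases(n)
    if (substr(s, 1L, 1L) %in% head_forbid) next
    if (substr(s, n, n) %in% tail_forbid) next
    if (nrow(oracle_repeat_scan(s, "x", min_length = 7L)) > 0L) next
    return(s)
  }
}

# Toy genome with six planted repeats exercising each catalog filter:
#   L1 exonic AC x5 (10 nt)  -> kept only thanks to the exon rule
#   L2 poly-A 11 nt          -> dropped (< 12 outside exons)
#   L3 AC x7 (14 nt)         -> kept
#   L4 AG x6 (12 nt)         -> dropped (20-nt flank context duplicated)
#   L5 AT x6 (12 nt)         -> kept
#   L6 AAG x4 (12 nt)        -> kept
# Hand count of survivors: 4 (L1, L3, L5, L6).
toy_catalog_genome <- function() {
  set.seed(424242)
  tracts <- c(L1 = strrep("AC", 5L), L2 = strrep("A", 11L),
              L3 = strrep("AC", 7L), L4 = strrep("AG", 6L),
              L5 = strrep("AT", 6L), L6 = strrep("AAG", 4L))
  heads <- substr(tracts, 1L, 1L)                      # first char of motif
  tails <- c("C", "A", "C", "G", "T", "G")             # last char of motif
  sp <- character(7L)
  sp[1L] <- toy_spacer(60L, tail_forbid = tails[1L])
  for (i in 2:6) {
    sp[i] <- toy_spacer(60L, head_forbid = heads[i - 1L],
                        tail_forbid = tails[i])
  }
  sp[7L] <- toy_spacer(60L, head_forbid = heads[6L])

  pieces <- c(sp[1L], tracts["L1"], sp[2L], tracts["L2"], sp[3L],
              tracts["L3"], sp[4L], tracts["L4"], sp[5L], tracts["L5"],
              sp[6L], tracts["L6"], sp[7L])
  genome <- paste(pieces, collapse = "")

  starts <- integer(6L); pos <- 0L
  for (i in 1:6) {
    pos <- pos + nchar(pieces[2L * i - 1L])
    starts[i] <- pos
    pos <- pos + nchar(tracts[i])
  }
  ends <- starts + nchar(tracts)

  # duplicate L4's 20-nt flank context elsewhere (between two extra spacers)
  ctx4 <- paste0(substr(genome, starts[4L] - 9L, starts[4L]),
                 substr(genome, ends[4L] + 1L, ends[4L] + 10L))
  extra <- toy_spacer(40L)
  genome <- paste0(genome, ctx4, extra)

  exons <- data.frame(chrom = "chrT", start = starts[1L] - 20L,
                      end = ends[1L] + 20L, gene = "GENE1",
                      stringsAsFactors = FALSE)
  list(genome = c(chrT = genome), starts = starts, ends = ends,
       tracts = tracts, exons = exons,
       kept = c("L1", "L3", "L5", "L6"),
       locus_ids = camlscan::locus_id("chrT", starts, ends))
}

# --- SAM fixtures -----------------------------------------------------------

write_sam <- function(path, chrom, chrom_len, pos, seqs, flags = 0L) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  lines <- sprintf("r%04d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                   seq_along(seqs), rep_len(flags, length(seqs)), chrom,
                   pos, nchar(seqs), seqs, strrep("I", nchar(seqs)))
  writeLines(c(header, lines), path)
  path
}

# read string spanning a tract with the locus' true 5-nt anchors and
# arbitrary non-matching padding on the outside
spanning_read <- function(left_flank, tract, right_flank, pad = 20L) {
  paste0(rand_bases(pad),
         substr(left_flank, nchar(left_flank) - 4L, nchar(left_flank)),
         tract, substr(right_flank, 1L, 5L), rand_bases(pad))
}

# one-locus catalog row with explicit flanks (no reference needed)
toy_locus <- function(chrom = "chr1", start = 200L, motif = "AC",
                      units = 7L, left = "GGTCTGATTG", right = "CTTGAGGACT") {
  len <- nchar(motif) * units
  data.frame(locus_id = camlscan::locus_id(chrom, start, start + len),
             chrom = chrom, start = start, end = start + len,
             motif = motif, ref_length = len,
             left_flank = left, right_flank = right,
             region_class = "intergenic", gene = NA_character_,
             stringsAsFactors = FALSE)
}

# --- genotype-table builders ------------------------------------------------

gt_rows <- function(locus, cohort, genotype, n, status = "called",
                    prefix = cohort) {
  if (n == 0L) return(NULL)
  alleles <- if (!is.na(genotype)) {
    as.integer(strsplit(genotype, "/", fixed = TRUE)[[1L]])
  } else c(NA_integer_, NA_integer_)
  data.frame(sample_id = sprintf("%s%03d", prefix, seq_len(n)),
             cohort = cohort, locus_id = locus,
             allele_a = alleles[1L], allele_b = alleles[2L],
             depth = 30L, status = status, genotype = genotype,
             stringsAsFactors = FALSE)
}

# genotype table from a spec list: list(locus = list(cohortA = c("g1" = n1,
# ...), cohortB = ...)); every listed sample id exists in every locus (the
# same count layout must be used across loci for sample ids to line up).
gt_table <- function(spec) {
  rows <- list()
  for (locus in names(spec)) {
    for (cohort in names(spec[[locus]])) {
      counts <- spec[[locus]][[cohort]]
      offset <- 0L
      for (g in names(counts)) {
        n <- counts[[g]]
        if (n == 0L) next
        r <- gt_rows(locus, cohort, if (g == "NA") NA_character_ else g, n)
        r$sample_id <- sprintf("%s%03d", cohort, offset + seq_len(n))
        if (g == "NA") r$status <- "low_coverage"
        rows[[length(rows) + 1L]] <- r
        offset <- offset + n
      }
    }
  }
  do.call(rbind, rows)
}
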