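# Microsatellite catalog construction: perfect-tandem detection plus the
# locus-selection filters (length by region class, unique 20-nt flanking
# context, inter-tract proximity exclusion).

#' Detect perfect tandem repeats in a nucleotide sequence
#'
#' Scans a sequence for maximal perfect tandem runs of motifs with unit size
#' between `min_unit` and `max_unit`. Runs reported at a composite period are
#' collapsed to their smallest period (a poly-A run is reported as a
#' mononucleotide repeat, never as motif `"AA"`): only runs whose motif is
#' primitive (not itself a repetition of a shorter unit) are returned. Runs
#' containing `N` are excluded.
#'
#' @param sequence A single nucleotide string (A/C/G/T/N, case-insensitive),
#'   or a length-1 [Biostrings::DNAStringSet]/`DNAString`.
#' @param chrom Chromosome/sequence name used in coordinates and locus ids.
#' @param min_unit,max_unit Motif unit sizes to scan (1--6).
#' @param min_length Minimum tract length, in nucleotides, for a run to be
#'   reported as a candidate. Microsatellites of interest are typically
#'   10--15 nt, so the default keeps candidate lists free of incidental
#'   2--3 nt homopolymers; region-aware length filters are applied later by
#'   [apply_catalog_filters()].
#' @param max_impurity_frac Optional impurity tolerance: adjacent in-phase runs
#'   of the same motif are merged across mismatching bases as long as the
#'   mismatches account for at most `floor(max_impurity_frac * tract_length)`
#'   bases of the merged tract. The default 0 keeps only perfect repeats.
#'
#' @return A `data.frame` of candidate loci with columns `locus_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `motif`, `ref_length`,
#'   `left_flank`, `right_flank`, `region_class`, `gene` (the last four are
#'   `NA` until [apply_catalog_filters()] resolves them against a reference).
#'   `locus_id` is the human-readable `"chrom:start-end"` form with 1-based
#'   inclusive coordinates.
#' @export
detect_repeats <- function(sequence, chrom, min_unit = 1L, max_unit = 6L,
                           min_length = 10L, max_impurity_frac = 0) {
  if (inherits(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1L)
    sequence <- as.character(sequence[[1L]])
  } else if (inherits(sequence, "DNAString")) {
    sequence <- as.character(sequence)
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  stopifnot(min_unit >= 1L, min_unit <= max_unit, max_unit <= 6L)
  stopifnot(max_impurity_frac >= 0, max_impurity_frac < 1)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) return(empty_catalog())
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside the A/C/G/T/N alphabet")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]

  starts <- integer(0L); ends <- integer(0L); motifs <- character(0L)
  # with impurity merging, short pure runs must survive to the merge step
  pre_min <- if (max_impurity_frac > 0) 0L else min_length
  for (k in seq.int(min_unit, max_unit)) {
    if (n < 2L * k) next
    # s[j] == s[j + k] marks period-k continuation; a maximal TRUE run of
    # length L in this vector is a tandem tract of length L + k.
    eq <- chars[seq_len(n - k)] == chars[seq.int(k + 1L, n)]
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- r$values & r$lengths + k >= max(2L * k, pre_min)
    ts <- run_start[keep]                # 1-based tract starts
    te <- run_end[keep] + k              # 1-based tract ends (inclusive)
    if (length(ts) == 0L) next
    motif <- substring(sequence, ts, ts + k - 1L)
    if (k > 1L) {
      prim <- !vapply(motif, is_composite_motif, logical(1L))
      ts <- ts[prim]; te <- te[prim]; motif <- motif[prim]
    }
    starts <- c(starts, ts - 1L); ends <- c(ends, te)
    motifs <- c(motifs, motif)
  }
  if (length(starts) == 0L) return(empty_catalog())
  cand <- data.frame(chrom = chrom, start = starts, end = ends,
                     motif = motifs, ref_length = ends - starts,
                     stringsAsFactors = FALSE)

  if (max_impurity_frac > 0) {
    cand <- merge_impure_runs(cand, max_impurity_frac)
  }
  cand <- cand[cand$ref_length >= min_length, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_catalog())

  # drop runs containing N
  tracts <- substring(sequence, cand$start + 1L, cand$end)
  cand <- cand[!grepl("N", tracts, fixed = TRUE), , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_catalog())

  cand <- cand[order(cand$start, nchar(cand$motif)), , drop = FALSE]
  data.frame(
    locus_id = locus_id(cand$chrom, cand$start, cand$end),
    cand,
    left_flank = NA_character_, right_flank = NA_character_,
    region_class = NA_character_, gene = NA_character_,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# TRUE if motif is a whole-number repetition of a shorter unit.
is_composite_motif <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), k %/% d)) {
      return(TRUE)
    }
  }
  FALSE
}

# Merge same-motif, in-phase runs separated by a short mismatching gap,
# provided the gap bases stay within the impurity budget of the merged tract.
merge_impure_runs <- function(cand, frac) {
  out <- list()
  for (m in unique(cand$motif)) {
    sub <- cand[cand$motif == m, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    k <- nchar(m)
    i <- 1L
    while (i <= nrow(sub)) {
      cur <- sub[i, , drop = FALSE]
      j <- i + 1L
      while (j <= nrow(sub)) {
        gap <- sub$start[j] - cur$end
        in_phase <- (sub$start[j] - cur$start) %% k == 0L
        merged_len <- sub$end[j] - cur$start
        if (gap >= 0L && in_phase && gap <= floor(frac * merged_len)) {
          cur$end <- sub$end[j]
          cur$ref_length <- cur$end - cur$start
          j <- j + 1L
        } else break
      }
      out[[length(out) + 1L]] <- cur
      i <- j
    }
  }
  do.call(rbind, out)
}

empty_catalog <- function() {
  data.frame(
    locus_id = character(), chrom = character(),
    start = integer(), end = integer(),
    motif = character(), ref_length = integer(),
    left_flank = character(), right_flank = character(),
    region_class = character(), gene = character(),
    stringsAsFactors = FALSE
  )
}

#' Human-readable locus identifier
#'
#' Converts 0-based half-open coordinates into the `"chrom:start-end"` id with
#' 1-based inclusive coordinates used throughout reports.
#'
#' @param chrom,start,end Vectors of coordinates (0-based half-open).
#' @return Character vector of ids.
#' @export
locus_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, start + 1L, end)
}

#' Apply catalog-selection filters to candidate repeats
#'
#' Reproduces the locus-selection rules of the discovery pipeline:
#'
#' * tract length at least `min_len` nucleotides, relaxed to `min_len_exon`
#'   for loci overlapping an exon;
#' * 10-nt flanks extractable on both sides (loci too close to a sequence end
#'   are excluded with a warning);
#' * no other detected repeat tract within `proximity_gap` (< 5) non-repeat
#'   bases: both members of such a close pair are excluded;
#' * unique 20-nt flanking context: the concatenated left+right 10-mers
#'   (the tract elided) must occur exactly once, across both strands, in the
#'   tract-collapsed reference (every detected tract deleted). A context
#'   duplicated elsewhere in the genome fails the test.
#'
#' @param candidates Candidate loci from [detect_repeats()] (possibly from
#'   several chromosomes, concatenated).
#' @param reference Named character vector or [Biostrings::DNAStringSet] of
#'   reference sequences.
#' @param exons Optional exon annotation: a `data.frame` with columns `chrom`,
#'   `start`, `end` (0-based half-open) and `gene`; used to set
#'   `region_class` (`exon` for tract overlap, `intron` inside a gene span,
#'   otherwise `intergenic`) and the `gene` column.
#' @param min_len,min_len_exon Minimum tract lengths outside/inside exons.
#' @param flank_size Flank length stored and probed (10 nt; chosen so that a
#'   100-nt read can span tract plus anchors).
#' @param proximity_gap Loci separated from another tract by fewer than this
#'   many bases are excluded (both members of the pair).
#'
#' @return The retained loci (same columns as [detect_repeats()]) with
#'   `left_flank`, `right_flank`, `region_class` and `gene` resolved. A
#'   per-rule tally of exclusions is attached as `attr(x, "filter_report")`.
#' @export
apply_catalog_filters <- function(candidates, reference, exons = NULL,
                                  min_len = 12L, min_len_exon = 10L,
                                  flank_size = 10L, proximity_gap = 5L) {
  reference <- as_dnastringset(reference)
  report <- c(out_of_bounds = 0L, short_flank = 0L, min_length = 0L,
              proximity = 0L, flank_not_unique = 0L)
  x <- candidates
  if (nrow(x) == 0L) {
    attr(x, "filter_report") <- report
    return(x)
  }
  stopifnot(all(x$chrom %in% names(reference)))
  seqlen <- setNames(Biostrings::width(reference), names(reference))

  ok <- x$start >= 0L & x$end <= seqlen[x$chrom]
  if (any(!ok)) {
    warning(sum(!ok), " locus/loci beyond sequence bounds excluded")
    report["out_of_bounds"] <- sum(!ok)
    x <- x[ok, , drop = FALSE]
  }

  ok <- x$start >= flank_size & x$end + flank_size <= seqlen[x$chrom]
  if (any(!ok)) {
    warning(sum(!ok), " locus/loci without full ", flank_size,
            "-nt flanks excluded")
    report["short_flank"] <- sum(!ok)
    x <- x[ok, , drop = FALSE]
  }

  # region class + gene before the region-aware length filter
  x <- annotate_regions(x, exons)

  min_required <- ifelse(x$region_class == "exon", min_len_exon, min_len)
  report["min_length"] <- sum(x$ref_length < min_required)
  x <- x[x$ref_length >= min_required, , drop = FALSE]

  # proximity exclusion against the full candidate set (physical neighbours
  # count whether or not they survive other filters)
  if (nrow(x) > 0L) {
    close_ids <- proximity_excluded(candidates, proximity_gap)
    drop <- x$locus_id %in% close_ids
    report["proximity"] <- sum(drop)
    x <- x[!drop, , drop = FALSE]
  }

  if (nrow(x) > 0L) {
    x$left_flank <- extract_flank(reference, x$chrom, x$start - flank_size,
                                  x$start)
    x$right_flank <- extract_flank(reference, x$chrom, x$end,
                                   x$end + flank_size)
    uniq <- flank_context_unique(x, reference)
    report["flank_not_unique"] <- sum(!uniq)
    x <- x[uniq, , drop = FALSE]
  }

  rownames(x) <- NULL
  attr(x, "filter_report") <- report
  x
}

as_dnastringset <- function(reference) {
  if (inherits(reference, "DNAStringSet")) return(reference)
  if (is.character(reference)) {
    if (is.null(names(reference))) stop("reference sequences must be named")
    return(Biostrings::DNAStringSet(toupper(reference)))
  }
  stop("unsupported reference type")
}

extract_flank <- function(reference, chrom, start, end) {
  vapply(seq_along(chrom), function(i) {
    as.character(Biostrings::subseq(reference[[chrom[i]]],
                                    start[i] + 1L, end[i]))
  }, character(1L))
}

annotate_regions <- function(x, exons) {
  x$region_class <- rep("intergenic", nrow(x))
  x$gene <- rep(NA_character_, nrow(x))
  if (is.null(exons) || nrow(x) == 0L || nrow(exons) == 0L) return(x)
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(exons)))
  loci <- GenomicRanges::GRanges(x$chrom,
                                 IRanges::IRanges(x$start + 1L, x$end))
  ex <- GenomicRanges::GRanges(exons$chrom,
                               IRanges::IRanges(exons$start + 1L, exons$end))
  hit <- GenomicRanges::findOverlaps(loci, ex, select = "first")
  in_exon <- !is.na(hit)
  x$region_class[in_exon] <- "exon"
  x$gene[in_exon] <- exons$gene[hit[in_exon]]
  # gene span = min..max over each gene's exons; inside span but not exon
  spans <- do.call(rbind, lapply(split(exons, exons$gene), function(g) {
    data.frame(chrom = g$chrom[1L], start = min(g$start), end = max(g$end),
               gene = g$gene[1L], stringsAsFactors = FALSE)
  }))
  sp <- GenomicRanges::GRanges(spans$chrom,
                               IRanges::IRanges(spans$start + 1L, spans$end))
  hit2 <- GenomicRanges::findOverlaps(loci, sp, select = "first")
  in_span <- !is.na(hit2) & !in_exon
  x$region_class[in_span] <- "intron"
  x$gene[in_span] <- spans$gene[hit2[in_span]]
  x
}

# locus_ids of candidates with another tract closer than `gap` bases
proximity_excluded <- function(candidates, gap) {
  bad <- character(0L)
  for (chr in unique(candidates$chrom)) {
    sub <- candidates[candidates$chrom == chr, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    if (nrow(sub) < 2L) next
    g <- sub$start[-1L] - sub$end[-nrow(sub)]
    close <- which(g < gap)
    if (length(close)) {
      bad <- c(bad, sub$locus_id[close], sub$locus_id[close + 1L])
    }
  }
  unique(bad)
}

# TRUE for loci whose elided 20-nt context occurs exactly once (both strands)
# in the tract-collapsed reference.
flank_context_unique <- function(x, reference,
                                 min_unit = 1L, max_unit = 6L,
                                 min_length = 10L) {
  collapsed <- collapse_tracts(reference, min_unit, max_unit, min_length)
  probes <- Biostrings::DNAStringSet(paste0(x$left_flank, x$right_flank))
  counts <- integer(nrow(x))
  fwd <- Biostrings::PDict(probes)
  rev <- Biostrings::PDict(Biostrings::reverseComplement(probes))
  for (chr in seq_along(collapsed)) {
    subject <- collapsed[[chr]]
    counts <- counts + Biostrings::countPDict(fwd, subject) +
      Biostrings::countPDict(rev, subject)
  }
  counts == 1L
}

# Delete every detected repeat tract from the reference so each locus'
# left+right flank concatenation becomes a contiguous 20-mer at its own site.
collapse_tracts <- function(reference, min_unit, max_unit, min_length) {
  out <- lapply(names(reference), function(chr) {
    seq_chr <- as.character(reference[[chr]])
    det <- detect_repeats(seq_chr, chr, min_unit, max_unit, min_length)
    if (nrow(det) == 0L) return(Biostrings::DNAString(seq_chr))
    ir <- IRanges::reduce(IRanges::IRanges(det$start + 1L, det$end))
    keep <- IRanges::gaps(ir, start = 1L, end = nchar(seq_chr))
    pieces <- substring(seq_chr, IRanges::start(keep), IRanges::end(keep))
    Biostrings::DNAString(paste(pieces, collapse = ""))
  })
  names(out) <- names(reference)
  out
}
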