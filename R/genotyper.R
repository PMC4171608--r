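# Flank-anchored microsatellite genotyping from aligned reads.
#
# Mapping position is trusted only to shortlist reads near a locus; the
# authoritative filter is an exact match of the 5-nt flank windows inside the
# read, with the tract measured between the matched anchors. Base
# substitutions inside the tract change the binned repeat sequence but not
# the allele length, so SNPs inside tracts do not split length spectra.

#' Read alignments from a SAM or BAM file
#'
#' Loads mapped, primary, non-duplicate alignments. SAM input is converted to
#' BAM in a temporary location via [Rsamtools::asBam()].
#'
#' @param path Path to a SAM (`.sam`) or BAM file.
#' @return A [data.table::data.table] with columns `qname`, `rname`, `pos`
#'   (1-based leftmost), `seq` (read sequence as character).
#' @export
read_alignments <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- suppressMessages(
      Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE))
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("qname", "rname", "pos", "seq"))
  b <- Rsamtools::scanBam(path, param = param)[[1L]]
  data.table::data.table(
    qname = b$qname,
    rname = as.character(b$rname),
    pos = b$pos,
    seq = as.character(b$seq)
  )
}

#' Extract allele observations for catalog loci from aligned reads
#'
#' A read contributes an observation at a locus iff it contains an exact match
#' of the inner `flank_match` bases of both reference flanks, i.e. it spans
#' the whole tract plus at least `flank_match` anchoring bases on each side.
#' The tract between the matched anchors is the observed allele. Observations
#' are binned by identical repeat sequence.
#'
#' When a read contains several candidate anchor pairs (a 5-mer can recur by
#' chance), the pair whose implied tract best matches a periodic extension of
#' the locus motif is used; ties go to the leftmost pair.
#'
#' @param alignments A [data.table::data.table] from [read_alignments()], or a
#'   path to a SAM/BAM file.
#' @param catalog Catalog `data.frame` with resolved flanks
#'   (see [apply_catalog_filters()]).
#' @param flank_match Number of anchoring bases matched on each side
#'   (default 5).
#' @param max_flank_mismatch Mismatches tolerated per flank window (0 =
#'   exact, the validation default; 1 relaxes each window by one base).
#' @return A [data.table::data.table] of observations: `locus_id`,
#'   `allele_length`, `repeat_sequence`, `read_count`. Loci with no validated
#'   reads are absent (downstream callers treat them as `no_reads`).
#' @export
extract_observations <- function(alignments, catalog, flank_match = 5L,
                                 max_flank_mismatch = 0L) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  stopifnot(all(!is.na(catalog$left_flank)))
  seq <- pos <- rname <- NULL  # NSE notes
  out <- vector("list", nrow(catalog))
  read_len <- nchar(alignments$seq)
  for (i in seq_len(nrow(catalog))) {
    loc <- catalog[i, ]
    left <- substr(loc$left_flank, nchar(loc$left_flank) - flank_match + 1L,
                   nchar(loc$left_flank))
    right <- substr(loc$right_flank, 1L, flank_match)
    # loose positional shortlist; flank matching is authoritative
    max_rl <- if (length(read_len)) max(read_len) else 0L
    cand <- alignments$pos >= loc$start - max_rl + 1L &
      alignments$pos <= loc$start + 1L + 20L &
      alignments$rname == loc$chrom
    seqs <- alignments$seq[cand]
    if (length(seqs) == 0L) next
    tracts <- locate_tracts(seqs, left, right, loc$motif, max_flank_mismatch)
    tracts <- tracts[!is.na(tracts)]
    if (length(tracts) == 0L) next
    tab <- table(tracts)
    out[[i]] <- data.table::data.table(
      locus_id = loc$locus_id,
      allele_length = nchar(names(tab)),
      repeat_sequence = names(tab),
      read_count = as.integer(tab)
    )
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) {
    res <- data.table::data.table(locus_id = character(),
                                  allele_length = integer(),
                                  repeat_sequence = character(),
                                  read_count = integer())
  }
  res
}

# For each read sequence, return the tract string between matched flank
# anchors, or NA if the read does not validate. Vectorised over reads.
locate_tracts <- function(seqs, left, right, motif, max_mismatch = 0L) {
  if (max_mismatch == 0L) {
    lpos <- gregexpr(left, seqs, fixed = TRUE)
    rpos <- gregexpr(right, seqs, fixed = TRUE)
  } else {
    lpos <- lapply(seqs, fuzzy_window_matches, window = left,
                   max_mismatch = max_mismatch)
    rpos <- lapply(seqs, fuzzy_window_matches, window = right,
                   max_mismatch = max_mismatch)
  }
  w <- nchar(left)
  vapply(seq_along(seqs), function(i) {
    ls <- lpos[[i]]; rs <- rpos[[i]]
    ls <- ls[ls > 0L]; rs <- rs[rs > 0L]
    if (length(ls) == 0L || length(rs) == 0L) return(NA_character_)
    best <- NA_character_; best_score <- -1
    for (a in ls) {
      tstart <- a + w
      for (b in rs) {
        if (b < tstart + 1L) next  # tract of at least 1 base
        tract <- substr(seqs[i], tstart, b - 1L)
        score <- motif_purity(tract, motif)
        if (score > best_score + 1e-12) {
          best_score <- score; best <- tract
        }
      }
    }
    best
  }, character(1L))
}

# positions where `window` occurs in `s` with at most max_mismatch mismatches
fuzzy_window_matches <- function(s, window, max_mismatch) {
  n <- nchar(s); w <- nchar(window)
  if (n < w) return(integer(0L))
  sc <- strsplit(s, "", fixed = TRUE)[[1L]]
  wc <- strsplit(window, "", fixed = TRUE)[[1L]]
  mm <- integer(n - w + 1L)
  for (j in seq_len(w)) {
    mm <- mm + (sc[seq.int(j, n - w + j)] != wc[j])
  }
  which(mm <= max_mismatch)
}

# fraction of tract bases matching the periodic extension of motif
motif_purity <- function(tract, motif) {
  n <- nchar(tract)
  if (n == 0L) return(0)
  template <- substr(strrep(motif, ceiling(n / nchar(motif))), 1L, n)
  tc <- strsplit(tract, "", fixed = TRUE)[[1L]]
  mc <- strsplit(template, "", fixed = TRUE)[[1L]]
  mean(tc == mc)
}

#' Call a genotype from the allele spectrum of one locus
#'
#' Bins are aggregated by allele length; lengths supported by at least
#' `min_allele_fraction` of the validated depth are retained. One retained
#' allele gives a homozygous call, two a heterozygous call, more than two
#' marks the locus `multi_allelic` and it is excluded downstream. Loci below
#' `coverage_min` validated reads are `low_coverage`.
#'
#' @param observations Observations for a single locus
#'   (see [extract_observations()]); may be empty.
#' @param coverage_min Minimum validated depth for a call (default 15, the
#'   15x callability rule).
#' @param min_allele_fraction Minimum fraction of validated depth supporting
#'   an allele length for it to count (default 0.2); suppresses stutter bins.
#' @return A one-row `data.frame`: `locus_id`, `allele_a`, `allele_b`
#'   (`allele_a <= allele_b`), `depth`, `status` in
#'   `{called, low_coverage, multi_allelic, no_reads}`, and `genotype`
#'   (`"a/b"`, `NA` unless called).
#' @export
call_genotype <- function(observations, coverage_min = 15L,
                          min_allele_fraction = 0.2) {
  if (is.null(observations) || nrow(observations) == 0L) {
    return(genotype_row(NA_character_, NA_integer_, NA_integer_, 0L,
                        "no_reads"))
  }
  lid <- unique(observations$locus_id)
  stopifnot(length(lid) == 1L)
  depth <- sum(observations$read_count)
  if (depth < coverage_min) {
    return(genotype_row(lid, NA_integer_, NA_integer_, depth, "low_coverage"))
  }
  by_len <- tapply(observations$read_count, observations$allele_length, sum)
  lens <- as.integer(names(by_len))
  keep <- lens[by_len >= min_allele_fraction * depth]
  if (length(keep) == 0L || length(keep) > 2L) {
    return(genotype_row(lid, NA_integer_, NA_integer_, depth,
                        "multi_allelic"))
  }
  a <- min(keep); b <- max(keep)
  genotype_row(lid, a, b, depth, "called")
}

genotype_row <- function(locus_id, a, b, depth, status) {
  data.frame(locus_id = locus_id, allele_a = a, allele_b = b,
             depth = depth, status = status,
             genotype = if (status == "called") paste0(a, "/", b)
                        else NA_character_,
             stringsAsFactors = FALSE)
}

#' Genotype a cohort of samples at all catalog loci
#'
#' @param manifest `data.frame` with columns `sample_id`, `cohort`, `path`
#'   (SAM/BAM per sample), e.g. from [read_manifest()].
#' @param catalog Filtered catalog (see [apply_catalog_filters()]).
#' @param coverage_min,min_allele_fraction Passed to [call_genotype()].
#' @param flank_match,max_flank_mismatch Passed to [extract_observations()].
#' @return A [data.table::data.table] with one row per sample x locus:
#'   `sample_id`, `cohort`, `locus_id`, `allele_a`, `allele_b`, `depth`,
#'   `status`, `genotype`. Per-sample called-locus counts are attached as
#'   `attr(x, "called_per_sample")`.
#' @export
genotype_cohort <- function(manifest, catalog, coverage_min = 15L,
                            min_allele_fraction = 0.2, flank_match = 5L,
                            max_flank_mismatch = 0L) {
  stopifnot(all(c("sample_id", "cohort", "path") %in% names(manifest)))
  pieces <- vector("list", nrow(manifest))
  for (s in seq_len(nrow(manifest))) {
    obs <- extract_observations(manifest$path[s], catalog,
                                flank_match = flank_match,
                                max_flank_mismatch = max_flank_mismatch)
    calls <- lapply(catalog$locus_id, function(lid) {
      call_genotype(obs[obs$locus_id == lid, ],
                    coverage_min = coverage_min,
                    min_allele_fraction = min_allele_fraction)
    })
    calls <- data.table::rbindlist(calls)
    calls$locus_id <- catalog$locus_id  # no_reads rows carry NA locus ids
    pieces[[s]] <- data.table::data.table(
      sample_id = manifest$sample_id[s],
      cohort = manifest$cohort[s],
      calls
    )
  }
  tab <- data.table::rbindlist(pieces)
  attr(tab, "called_per_sample") <- called_loci_per_sample(tab)
  tab
}

#' Called-locus counts per sample
#'
#' @param table A cohort genotype table (long format with `sample_id` and
#'   `status` columns).
#' @return Named integer vector: number of loci with `status == "called"` per
#'   sample.
#' @export
called_loci_per_sample <- function(table) {
  tab <- base::table(table$sample_id[table$status == "called"])
  out <- setNames(as.integer(tab), names(tab))
  missing <- setdiff(unique(table$sample_id), names(out))
  if (length(missing)) out[missing] <- 0L
  out[unique(table$sample_id)]
}
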