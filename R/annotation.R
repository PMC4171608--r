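# Regulatory-element proximity annotation (CpG islands, TFBS) and
# driver-mutation co-occurrence tallies for signature loci.

#' Annotate loci with distance to nearest CpG island and TFBS
#'
#' Distances are gap distances between intervals: 0 when the locus overlaps
#' (or abuts) a feature, otherwise the number of bases separating the tract
#' from the nearest feature edge. The conventional windows are applied:
#' a CpG island within 10 kb, a TFBS within 40 bases.
#'
#' @param loci Catalog rows (`chrom`, `start`, `end`, `locus_id`; 0-based
#'   half-open).
#' @param cpg_track,tfbs_track Feature tracks: `data.frame`s with `chrom`,
#'   `start`, `end` (0-based half-open), as read from BED.
#' @param cpg_window,tfbs_window Proximity windows in bases (defaults 10000
#'   and 40).
#' @return `data.frame`: `locus_id`, `nearest_cpg_distance`,
#'   `nearest_tfbs_distance` (`NA` when the track has no feature on the
#'   locus' chromosome), `cpg_within_10kb`, `tfbs_within_40bp`.
#' @export
annotate_proximity <- function(loci, cpg_track, tfbs_track,
                               cpg_window = 10000L, tfbs_window = 40L) {
  dc <- nearest_feature_distance(loci, cpg_track)
  dt <- nearest_feature_distance(loci, tfbs_track)
  data.frame(locus_id = loci$locus_id,
             nearest_cpg_distance = dc,
             nearest_tfbs_distance = dt,
             cpg_within_10kb = !is.na(dc) & dc <= cpg_window,
             tfbs_within_40bp = !is.na(dt) & dt <= tfbs_window,
             stringsAsFactors = FALSE)
}

nearest_feature_distance <- function(loci, track) {
  if (is.null(track) || nrow(track) == 0L) return(rep(NA_real_, nrow(loci)))
  lev <- union(loci$chrom, track$chrom)
  q <- GenomicRanges::GRanges(factor(loci$chrom, levels = lev),
                              IRanges::IRanges(loci$start + 1L, loci$end))
  s <- GenomicRanges::GRanges(factor(track$chrom, levels = lev),
                              IRanges::IRanges(track$start + 1L, track$end))
  hits <- GenomicRanges::distanceToNearest(q, s)
  out <- rep(NA_real_, nrow(loci))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}

#' Driver mutation gene panel
#'
#' The configured panel of glioma driver and mismatch-repair genes. The
#' printed panel contains the apparent misspellings `MSF6` and `MLH2`;
#' `aliases = TRUE` substitutes the standard symbols `MSH6` and `PMS2`.
#'
#' @param aliases Substitute documented aliases for the two non-standard
#'   symbols.
#' @return Character vector of gene symbols.
#' @export
driver_gene_panel <- function(aliases = FALSE) {
  panel <- c("IDH1", "PTEN", "PIK3CA", "RB1", "MSH2", "MSH3", "MSH4",
             "MSH5", "MSF6", "MLH1", "MLH2")
  if (aliases) {
    panel[panel == "MSF6"] <- "MSH6"
    panel[panel == "MLH2"] <- "PMS2"
  }
  panel
}

#' Build per-sample driver-mutation profiles
#'
#' @param mutation_calls `data.frame` with columns `sample_id` and `gene`
#'   (one row per mutation call).
#' @param classification Per-sample scores from [score_samples()] (supplies
#'   `caml_fraction`).
#' @param panel Gene panel; calls outside the panel are ignored.
#' @return `data.frame`: `sample_id`, `driver_count` (distinct panel genes
#'   hit), `genes_hit` (comma-separated), `caml_fraction`.
#' @export
driver_profiles <- function(mutation_calls, classification,
                            panel = driver_gene_panel()) {
  hits <- mutation_calls[mutation_calls$gene %in% panel, , drop = FALSE]
  per <- lapply(split(hits$gene, hits$sample_id), unique)
  out <- data.frame(sample_id = classification$sample_id,
                    stringsAsFactors = FALSE)
  out$driver_count <- vapply(out$sample_id, function(s) {
    length(per[[s]])
  }, integer(1L))
  out$genes_hit <- vapply(out$sample_id, function(s) {
    paste(sort(per[[s]]), collapse = ",")
  }, character(1L))
  out$caml_fraction <- classification$fraction
  out
}

#' Cross-tabulate driver-mutation burden against CAML detection fraction
#'
#' Rows are driver-mutation counts 0--5 (counts above 5 fold into the `5`
#' row); columns are detection-fraction bins `(0,20]`, `(20,40]`, ...,
#' `(80,100]` percent (0 included in the first bin). Cells are the
#' percentage of that row's samples falling in the bin, so every occupied
#' row sums to 100; a `TOTAL` row tabulates all samples together.
#'
#' @param profiles Output of [driver_profiles()] (needs `driver_count` and
#'   `caml_fraction`).
#' @return `data.frame` with `driver_count` (`"0"`..`"5"`, `"TOTAL"`),
#'   one column per fraction bin, and `n_samples`. Empty input gives an
#'   empty table with a warning.
#' @export
driver_caml_crosstab <- function(profiles) {
  bin_labels <- c("0-20%", "20-40%", "40-60%", "60-80%", "80-100%")
  if (is.null(profiles) || nrow(profiles) == 0L) {
    warning("no driver profiles supplied; empty crosstab")
    out <- data.frame(driver_count = character(),
                      matrix(numeric(), 0L, length(bin_labels),
                             dimnames = list(NULL, bin_labels)),
                      n_samples = integer(), check.names = FALSE)
    return(out)
  }
  prof <- profiles[!is.na(profiles$caml_fraction), , drop = FALSE]
  dc <- pmin(prof$driver_count, 5L)
  bins <- cut(prof$caml_fraction * 100, breaks = seq(0, 100, by = 20),
              include.lowest = TRUE, labels = bin_labels)
  rows <- lapply(0L:5L, function(k) {
    sel <- dc == k
    crosstab_row(as.character(k), bins[sel])
  })
  rows[[length(rows) + 1L]] <- crosstab_row("TOTAL", bins)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

crosstab_row <- function(label, bins) {
  tab <- base::table(bins)
  n <- length(bins)
  pct <- if (n > 0L) 100 * as.numeric(tab) / n else rep(0, length(tab))
  out <- data.frame(driver_count = label, t(pct), n_samples = n,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[2L:(1L + length(tab))] <- names(tab)
  out
}

#' Methylation contrast between signature carriers and non-carriers
#'
#' For each methylation site linked to a signature gene, compares the mean
#' methylation value between samples classified as signature carriers and
#' non-carriers.
#'
#' @param methylation Long `data.frame`: `site`, `gene`, `sample_id`, `beta`.
#' @param loci Catalog rows for the signature loci (supplies the `gene`
#'   linkage); sites whose gene is not among these are ignored.
#' @param classification Output of [roc_cutoff()]'s `results` (needs
#'   `sample_id` and `predicted_positive`).
#' @return `data.frame`: `site`, `gene`, `mean_carrier`, `mean_noncarrier`,
#'   `difference`, `n_carrier`, `n_noncarrier`.
#' @export
methylation_contrast <- function(methylation, loci, classification) {
  stopifnot(all(c("site", "gene", "sample_id", "beta") %in%
                  names(methylation)))
  stopifnot("predicted_positive" %in% names(classification))
  genes <- unique(stats::na.omit(loci$gene))
  meth <- methylation[methylation$gene %in% genes, , drop = FALSE]
  carrier <- setNames(classification$predicted_positive,
                      classification$sample_id)
  meth$carrier <- carrier[meth$sample_id]
  meth <- meth[!is.na(meth$carrier), , drop = FALSE]
  rows <- lapply(split(meth, meth$site), function(s) {
    data.frame(site = s$site[1L], gene = s$gene[1L],
               mean_carrier = mean(s$beta[s$carrier]),
               mean_noncarrier = mean(s$beta[!s$carrier]),
               n_carrier = sum(s$carrier),
               n_noncarrier = sum(!s$carrier),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(site = character(), gene = character(),
                      mean_carrier = numeric(), mean_noncarrier = numeric(),
                      n_carrier = integer(), n_noncarrier = integer(),
                      stringsAsFactors = FALSE)
  }
  out$difference <- out$mean_carrier - out$mean_noncarrier
  rownames(out) <- NULL
  out
}
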