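# Bulk-segregant allele-frequency mapping: per-SNP reference-parent allele
# frequency, low-AF run detection, marker deserts, candidate-feature overlap.

#' Construct an allele count track
#'
#' @param records data.frame with columns `chrom`, `pos` (1-based),
#'   `ref_count`, `alt_count`.
#' @param ref_parent_label which parent the reference counts refer to.
#' @return data.frame of class `allele_count_track`, sorted by chromosome and
#'   position, with attribute `ref_parent_label`.
#' @export
allele_count_track <- function(records, ref_parent_label = "P1") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref_count", "alt_count") %in%
                  names(records)))
  if (any(records$ref_count < 0) || any(records$alt_count < 0))
    stop("negative read counts")
  if (anyDuplicated(records[, c("chrom", "pos")]))
    stop("duplicate (chrom, pos) records")
  ord <- order(match(records$chrom, unique(records$chrom)), records$pos)
  if (is.unsorted(ord)) {
    warning("input not sorted by position; sorting")
    records <- records[ord, , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(records, ref_parent_label = ref_parent_label,
            class = c("allele_count_track", "data.frame"))
}

#' Reference-parent allele frequencies from pooled counts
#'
#' Scores the reference parent's allele frequency at each polymorphic
#' position, `af_ref = ref_count / (ref_count + alt_count)`. Positions below
#' `min_depth` total reads are kept in the output but flagged
#' (`pass_depth = FALSE`) and ignored by region detection.
#'
#' @param counts an `allele_count_track` (or data.frame with the same
#'   columns).
#' @param min_depth minimum total depth for a usable AF estimate.
#' @return data.frame of class `allele_frequency_track` with columns `chrom`,
#'   `pos`, `af_ref`, `depth`, `pass_depth`.
#' @export
allele_frequencies <- function(counts, min_depth = 10) {
  counts <- allele_count_track(counts,
                               ref_parent_label =
                                 attr(counts, "ref_parent_label") %||% "P1")
  depth <- counts$ref_count + counts$alt_count
  out <- data.frame(chrom = counts$chrom, pos = counts$pos,
                    af_ref = ifelse(depth > 0, counts$ref_count / depth,
                                    NA_real_),
                    depth = depth, pass_depth = depth >= min_depth,
                    stringsAsFactors = FALSE)
  structure(out, ref_parent_label = attr(counts, "ref_parent_label"),
            class = c("allele_frequency_track", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect runs of depleted reference-parent allele frequency
#'
#' Finds, per chromosome, maximal runs of at least `min_run` consecutive
#' depth-passing markers with `af_ref` below `af_threshold` — the signature
#' of a region fixed for the alternate parent in the pool. Isolated
#' sub-threshold markers (runs shorter than `min_run`) are treated as
#' sequencing noise and dropped. With `max_violations > 0`, sub-threshold
#' runs separated by at most that many violating markers are merged, allowing
#' the occasional noisy marker inside a real region.
#'
#' @param track an `allele_frequency_track` from [allele_frequencies()].
#' @param af_threshold markers below this reference-parent AF count towards a
#'   run.
#' @param min_run minimum number of sub-threshold markers in a reported
#'   region.
#' @param max_violations violating markers tolerated between merged runs.
#' @return data.frame of class `mapped_regions`: columns `chrom`, `start`,
#'   `end` (1-based inclusive, first/last run marker), `kind`
#'   (`"low_af_run"`), `n_markers`, `mean_af`.
#' @export
detect_low_af_regions <- function(track, af_threshold = 0.1, min_run = 5,
                                  max_violations = 0) {
  stopifnot(inherits(track, "allele_frequency_track"))
  out <- list()
  for (ch in unique(track$chrom)) {
    t_ch <- track[track$chrom == ch & track$pass_depth &
                    !is.na(track$af_ref), , drop = FALSE]
    if (!nrow(t_ch)) next
    below <- t_ch$af_ref < af_threshold
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    if (!nrow(runs)) next
    if (max_violations > 0 && nrow(runs) > 1) {
      merged <- runs[1, , drop = FALSE]
      for (i in 2:nrow(runs)) {
        gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
        if (gap <= max_violations)
          merged$end[nrow(merged)] <- runs$end[i]
        else merged <- rbind(merged, runs[i, ])
      }
      runs <- merged
    }
    n_below <- vapply(seq_len(nrow(runs)), function(i)
      sum(below[runs$start[i]:runs$end[i]]), 0L)
    keep <- n_below >= min_run
    for (i in which(keep)) {
      idx <- runs$start[i]:runs$end[i]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = t_ch$pos[runs$start[i]],
        end = t_ch$pos[runs$end[i]], kind = "low_af_run",
        n_markers = n_below[i], mean_af = mean(t_ch$af_ref[idx]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               kind = character(), n_markers = integer(),
               mean_af = numeric(), stringsAsFactors = FALSE)
  structure(res, class = c("mapped_regions", "data.frame"))
}

#' Detect marker deserts (regions with no usable SNP markers)
#'
#' A pool fixed for the reference parent produces no SNP calls, leaving a
#' region with no mapped markers. Per chromosome, inter-marker gaps (and the
#' gaps to the chromosome ends) longer than `gap_factor` times the median
#' inter-marker spacing are reported.
#'
#' @param track an `allele_frequency_track`; only depth-passing markers
#'   anchor the gaps.
#' @param genome a `genome_map` supplying chromosome lengths.
#' @param gap_factor multiple of the chromosome's median spacing that
#'   qualifies a gap as a desert.
#' @param min_markers minimum markers per chromosome for a meaningful median
#'   spacing (chromosomes with fewer are skipped with a warning).
#' @return `mapped_regions` data.frame with `kind = "marker_desert"`,
#'   `n_markers = 0` and `mean_af = NA`.
#' @export
detect_marker_deserts <- function(track, genome, gap_factor = 10,
                                  min_markers = 10) {
  stopifnot(inherits(track, "allele_frequency_track"),
            inherits(genome, "genome_map"))
  out <- list()
  for (ch in unique(track$chrom)) {
    t_ch <- track[track$chrom == ch & track$pass_depth, , drop = FALSE]
    if (nrow(t_ch) < min_markers) {
      warning("chromosome ", ch, " has fewer than ", min_markers,
              " markers; skipped")
      next
    }
    len <- genome$chromosomes$length_bp[genome$chromosomes$name == ch]
    if (!length(len)) stop("chromosome ", ch, " absent from genome map")
    med <- stats::median(diff(t_ch$pos))
    cut <- gap_factor * med
    bounds <- c(0L, t_ch$pos, len + 1L)  # virtual markers at the ends
    gaps <- diff(bounds) - 1L
    for (i in which(gaps > cut)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = bounds[i] + 1L, end = bounds[i + 1L] - 1L,
        kind = "marker_desert", n_markers = 0L, mean_af = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               kind = character(), n_markers = integer(),
               mean_af = numeric(), stringsAsFactors = FALSE)
  structure(res, class = c("mapped_regions", "data.frame"))
}

#' Censor markers a reference-based SNP caller would not report
#'
#' Reference-based SNP calling only reports positions with credible evidence
#' for the alternate allele. Markers whose alternate-parent support falls
#' below `min_alt_reads` reads or `min_alt_frac` of the depth are dropped,
#' so regions where the pool is fixed for the reference parent become marker
#' deserts, as in real pooled-sequencing data.
#'
#' @param counts an `allele_count_track`.
#' @param min_alt_reads minimum alternate-supporting reads to keep a marker.
#' @param min_alt_frac minimum alternate read fraction to keep a marker.
#' @return The censored `allele_count_track`.
#' @export
drop_uncalled_markers <- function(counts, min_alt_reads = 2,
                                  min_alt_frac = 0.05) {
  counts <- allele_count_track(counts,
                               attr(counts, "ref_parent_label") %||% "P1")
  depth <- counts$ref_count + counts$alt_count
  frac <- ifelse(depth > 0, counts$alt_count / depth, 0)
  keep <- counts$alt_count >= min_alt_reads & frac >= min_alt_frac
  allele_count_track(as.data.frame(counts)[keep, , drop = FALSE],
                     attr(counts, "ref_parent_label"))
}

#' Features overlapping mapped regions
#'
#' Reports annotated features (e.g. ORFs) overlapping any mapped region,
#' using 1-based inclusive interval overlap.
#'
#' @param regions a `mapped_regions` data.frame (columns `chrom`, `start`,
#'   `end`).
#' @param annotations data.frame with columns `feature_id`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @return Character vector of overlapping `feature_id`s (input order,
#'   deduplicated).
#' @export
candidate_features <- function(regions, annotations) {
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  stopifnot(all(c("feature_id", "chrom", "start", "end") %in%
                  names(annotations)))
  if (any(annotations$start > annotations$end))
    stop("invalid annotation interval (start > end)")
  if (!nrow(regions) || !nrow(annotations)) return(character())
  reg <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start, regions$end))
  ann <- GenomicRanges::GRanges(annotations$chrom,
                                IRanges::IRanges(annotations$start,
                                                 annotations$end))
  hits <- GenomicRanges::findOverlaps(ann, reg)
  unique(annotations$feature_id[S4Vectors::queryHits(hits)])
}
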