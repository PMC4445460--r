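# Bulk-segregant allele-frequency mapping rules.

track_from <- function(af, chrom = "chr01", pos = NULL, depth = 50) {
  pos <- pos %||% (seq_along(af) * 1000L)
  ref <- round(af * depth)
  allele_frequencies(
    allele_count_track(data.frame(chrom = chrom, pos = pos, ref_count = ref,
                                  alt_count = depth - ref)),
    min_depth = 1)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("allele frequencies are counts ratios with a depth filter", {
  cnt <- allele_count_track(data.frame(
    chrom = "chr01", pos = c(1000L, 2000L, 3000L),
    ref_count = c(25L, 0L, 2L), alt_count = c(25L, 50L, 3L)))
  af <- allele_frequencies(cnt, min_depth = 10)
  expect_equal(af$af_ref, c(0.5, 0, 0.4))
  expect_equal(af$pass_depth, c(TRUE, TRUE, FALSE))
  expect_error(allele_count_track(data.frame(
    chrom = "chr01", pos = 1L, ref_count = -1L, alt_count = 5L)),
    "negative")
})

test_that("low-AF runs require min_run consecutive markers; isolated dips are noise", {
  flat <- track_from(rep(0.5, 30))
  expect_equal(nrow(detect_low_af_regions(flat)), 0)
  one_dip <- track_from(c(rep(0.5, 14), 0.02, rep(0.5, 15)))
  expect_equal(nrow(detect_low_af_regions(one_dip)), 0)
  af <- rep(0.5, 30)
  af[11:18] <- 0.02
  run <- detect_low_af_regions(track_from(af))
  expect_equal(nrow(run), 1)
  expect_equal(run$start, 11000)
  expect_equal(run$end, 18000)
  expect_equal(run$n_markers, 8)
  expect_equal(run$mean_af, 0.02, tolerance = 1e-9)
  # a short run below min_run is dropped
  af4 <- rep(0.5, 30)
  af4[11:14] <- 0.03
  expect_equal(nrow(detect_low_af_regions(track_from(af4))), 0)
})

test_that("one tolerated violation can bridge a split run", {
  af <- rep(0.5, 40)
  af[11:25] <- 0.02
  af[18] <- 0.4  # noisy marker inside the true region
  strict <- detect_low_af_regions(track_from(af))
  expect_equal(nrow(strict), 2)
  merged <- detect_low_af_regions(track_from(af), max_violations = 1)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, 11000)
  expect_equal(merged$end, 25000)
})

test_that("region detection is idempotent and unaffected by flanking chromosomes", {
  af <- rep(0.5, 30)
  af[11:18] <- 0.03
  base <- track_from(af)
  extra <- allele_count_track(data.frame(
    chrom = rep(c("chr00", "chr99"), each = 20),
    pos = rep(seq_len(20) * 1000L, 2),
    ref_count = 25L, alt_count = 25L))
  both <- allele_frequencies(
    allele_count_track(rbind(as.data.frame(extra)[1:20, ],
                             as.data.frame(base)[, c("chrom", "pos")] |>
                               transform(ref_count = round(af * 50),
                                         alt_count = 50 - round(af * 50)),
                             as.data.frame(extra)[21:40, ])),
    min_depth = 1)
  r1 <- detect_low_af_regions(base)
  r2 <- detect_low_af_regions(both)
  expect_equal(as.data.frame(r2[, c("start", "end", "n_markers")]),
               as.data.frame(r1[, c("start", "end", "n_markers")]))
})

test_that("marker deserts are reported from spacing outliers including chromosome ends", {
  g <- genome_map(data.frame(name = "chr01", length_bp = 100000L),
                  data.frame(chrom = "chr01", pos = seq_len(99) * 1000L))
  uniform <- track_from(rep(0.5, 99), pos = seq_len(99) * 1000L)
  expect_equal(nrow(detect_marker_deserts(uniform, g)), 0)
  # remove a 30 kb window of markers on an otherwise 1 kb-spaced chromosome
  pos <- setdiff(seq_len(99) * 1000L, seq(40000L, 70000L, by = 1000L))
  gap <- track_from(rep(0.5, length(pos)), pos = pos)
  des <- detect_marker_deserts(gap, g)
  expect_equal(nrow(des), 1)
  expect_equal(des$kind, "marker_desert")
  expect_equal(des$start, 39001)
  expect_equal(des$end, 70999)
  # few markers: chromosome is skipped with a warning
  sparse <- track_from(rep(0.5, 3), pos = c(1000L, 2000L, 3000L))
  expect_warning(out <- detect_marker_deserts(sparse, g), "fewer than")
  expect_equal(nrow(out), 0)
})

test_that("caller-style censoring turns reference-fixed regions into deserts", {
  design <- make_cross(make_genome(), two_locus_model(), seed = 2)
  pool <- simulate_spore_pool(design, "restrictive", 80, "inviable",
                              seed = 61)
  counts <- simulate_bsa_counts(pool, 50, 0.002, seed = 62)
  called <- allele_frequencies(drop_uncalled_markers(counts), min_depth = 10)
  deserts <- detect_marker_deserts(called, design$genome)
  rescuer <- deserts[deserts$chrom == "chr10", ]
  expect_gte(nrow(rescuer), 1)
  expect_true(any(rescuer$start <= 75500 & rescuer$end >= 75500))
})

test_that("the low-AF region covers the driver locus in a simulated pool", {
  design <- make_cross(make_genome(), two_locus_model(), seed = 2)
  pool <- simulate_spore_pool(design, "restrictive", 80, "inviable",
                              seed = 63)
  counts <- simulate_bsa_counts(pool, 50, 0.002, seed = 64)
  regions <- detect_low_af_regions(allele_frequencies(counts))
  driver <- regions[regions$chrom == "chr05", ]
  expect_true(any(driver$start <= 75500 & driver$end >= 75500))
  # error-free pool fixed for the alternate parent: AF exactly 0 at the locus
  noiseless <- simulate_bsa_counts(pool, 50, 0, seed = 65)
  af0 <- allele_frequencies(noiseless, min_depth = 1)
  locus <- af0$chrom == "chr05" & af0$pos == 75500
  expect_equal(af0$af_ref[locus], 0)
})

test_that("null pools produce no false-positive regions in 50 runs", {
  design <- make_cross(make_genome(), incompatibility_model("none"),
                       seed = 3)
  fp <- 0L
  for (i in 1:50) {
    pool <- simulate_spore_pool(design, "permissive", 80, "viable",
                                seed = 700 + i)
    counts <- simulate_bsa_counts(pool, 50, 0.002, seed = 800 + i)
    fp <- fp + (nrow(detect_low_af_regions(allele_frequencies(counts))) > 0)
  }
  expect_lte(fp, 2)  # 0 false positives in >= 95% of runs
})

test_that("candidate features overlap regions with 1-based inclusive bounds", {
  regions <- structure(data.frame(chrom = c("chr05", "chr10"),
                                  start = c(40000L, 60000L),
                                  end = c(90000L, 90000L),
                                  kind = "low_af_run", n_markers = 10L,
                                  mean_af = 0.02),
                       class = c("mapped_regions", "data.frame"))
  set.seed(4)
  inside <- data.frame(
    feature_id = paste0("IN", 1:5),
    chrom = c("chr05", "chr05", "chr05", "chr10", "chr10"),
    start = c(39000L, 50000L, 90000L, 59000L, 70000L),
    end = c(40000L, 52000L, 95000L, 60000L, 71000L))  # boundary overlaps count
  outside <- data.frame(
    feature_id = paste0("OUT", 1:20),
    chrom = sample(c("chr05", "chr10", "chr12"), 20, TRUE),
    start = rep(c(1000L, 95001L), 10))
  outside$end <- outside$start + 2000L
  outside$chrom[outside$start == 95001L] <- "chr12"  # keep them clear
  ann <- rbind(inside, outside)
  hits <- candidate_features(regions, ann)
  expect_setequal(hits, inside$feature_id)
  expect_error(candidate_features(regions, transform(ann, start = end + 1L)),
               "invalid annotation")
})
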