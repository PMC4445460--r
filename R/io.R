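# Shared table readers/writers with provenance headers, minimal-VCF
# ingestion, run configuration and the umbrella pipeline.

PKG_VERSION <- "0.1.0"

.provenance_line <- function(seed = NULL, params = list()) {
  extra <- if (length(params))
    paste(names(params), unlist(params), sep = "=", collapse = " ") else ""
  paste0("# dmiscreen ", PKG_VERSION,
         if (!is.null(seed)) paste0(" seed=", seed),
         if (nzchar(extra)) paste0(" ", extra))
}

#' Write a table as TSV with a provenance header
#'
#' The first line is a `#` comment recording the package version, the seed
#' and any parameters; readers in this package tolerate and preserve it.
#'
#' @param x data.frame.
#' @param path output file.
#' @param seed,params recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, seed = NULL, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_line(seed, params), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input file.
#' @return data.frame; any leading `#` comment lines are preserved in the
#'   `"provenance"` attribute.
#' @export
read_tsv <- function(path) {
  head <- readLines(path, n = 50)
  prov <- head[startsWith(head, "#")]
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(x, "provenance") <- prov
  x
}

#' Read pooled allele counts from TSV or minimal VCF
#'
#' TSV input must carry columns `chrom`, `pos`, `ref_count`, `alt_count`.
#' VCF input (detected from the `##fileformat` header or a `.vcf` suffix) is
#' parsed with `vcfR`; per-site ref/alt depths are taken from the first
#' sample's `AD` field. Duplicate positions are rejected; unsorted input is
#' sorted with a warning.
#'
#' @param path input file.
#' @return An `allele_count_track`.
#' @export
read_counts_table <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "##fileformat=VCF") || grepl("\\.vcf$", path)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    ad <- vcfR::extract.gt(vcf, element = "AD")[, 1]
    parts <- strsplit(ad, ",", fixed = TRUE)
    bad <- vapply(parts, length, 0L) < 2
    if (any(bad))
      stop("missing or malformed AD field at VCF record ",
           which(bad)[1])
    return(allele_count_track(data.frame(
      chrom = vcf@fix[, "CHROM"], pos = as.integer(vcf@fix[, "POS"]),
      ref_count = as.integer(vapply(parts, `[`, "", 1)),
      alt_count = as.integer(vapply(parts, `[`, "", 2)),
      stringsAsFactors = FALSE)))
  }
  x <- read_tsv(path)
  need <- c("chrom", "pos", "ref_count", "alt_count")
  if (!all(need %in% names(x)))
    stop("counts TSV must have columns: ", paste(need, collapse = ", "))
  for (col in c("pos", "ref_count", "alt_count")) {
    v <- suppressWarnings(as.integer(x[[col]]))
    if (anyNA(v))
      stop("malformed value in column '", col, "' at data line ",
           which(is.na(v))[1])
    x[[col]] <- v
  }
  allele_count_track(x[, need])
}

#' Write mapped regions as BED
#'
#' Internal coordinates are 1-based inclusive (as reported in tables and
#' logs); BED output converts to 0-based half-open.
#'
#' @param regions a `mapped_regions` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                    end = regions$end, name = regions$kind)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a segregation call as JSON
#'
#' @param call a `segregation_call`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_segregation_call <- function(call, path) {
  jsonlite::write_json(list(
    best_model = call$best_model,
    r_hat = if (is.na(call$r_hat)) NULL else call$r_hat,
    log_likelihoods = as.list(call$log_likelihoods),
    bic = as.list(call$bic),
    fit_pvalue = call$fit_pvalue,
    observed = as.list(call$observed), n = call$n),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read tetrad viable-count table
#'
#' @param path TSV with columns `viable_count`, `n_tetrads`.
#' @return Named vector suitable for [classify_segregation()].
#' @export
read_tetrad_counts <- function(path) {
  x <- read_tsv(path)
  stopifnot(all(c("viable_count", "n_tetrads") %in% names(x)))
  stats::setNames(x$n_tetrads, as.character(x$viable_count))
}

#' Write growth curves as CSV (time column plus one column per well)
#'
#' @param curves list of `growth_curve` objects sharing the same time grid.
#' @param path output CSV.
#' @return The well map data.frame (well, strain, plasmid), invisibly.
#' @export
write_growth_csv <- function(curves, path) {
  stopifnot(length(curves) >= 1)
  times <- curves[[1]]$times
  for (cv in curves)
    if (!isTRUE(all.equal(cv$times, times)))
      stop("all curves must share one time grid")
  mat <- data.frame(time_h = times)
  for (cv in curves) mat[[cv$well_id]] <- cv$od
  utils::write.csv(mat, path, row.names = FALSE, quote = FALSE)
  invisible(data.frame(
    well = vapply(curves, `[[`, "", "well_id"),
    strain = vapply(curves, `[[`, "", "strain"),
    plasmid = vapply(curves, `[[`, "", "plasmid"),
    stringsAsFactors = FALSE))
}

#' Read growth curves from CSV plus a well map
#'
#' @param path CSV with column `time_h` then one OD column per well.
#' @param well_map data.frame with columns `well`, `strain`, `plasmid`.
#' @return Named list of `growth_curve` objects.
#' @export
read_growth_csv <- function(path, well_map) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("time_h" %in% names(x))
  wells <- setdiff(names(x), "time_h")
  missing <- setdiff(wells, well_map$well)
  if (length(missing))
    stop("wells absent from well map: ", paste(missing, collapse = ", "))
  out <- lapply(wells, function(w) {
    i <- match(w, well_map$well)
    structure(list(times = x$time_h, od = x[[w]], well_id = w,
                   strain = well_map$strain[i],
                   plasmid = well_map$plasmid[i]),
              class = "growth_curve")
  })
  stats::setNames(out, wells)
}

#' Read a flat key=value run configuration file
#'
#' Lines are `key = value`; `#` comments and blank lines are ignored.
#' Numeric-looking values are converted.
#'
#' @param path configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  if (any(vapply(kv, length, 0L) != 3))
    stop("malformed config line: ", lines[vapply(kv, length, 0L) != 3][1])
  vals <- lapply(kv, function(p) {
    v <- trimws(p[3])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, function(p) trimws(p[2]), ""))
}

#' Synthetic ORF mirroring the worked nonsense-mutation case
#'
#' A synthetic in-frame ORF (ATG start, single terminal stop, no internal
#' stop codons) whose codon at `caa_codon_index` is CAA, so a C-to-T variant
#' at that codon's first base creates a premature TAA at ORF position
#' `3 * (caa_codon_index - 1) + 1`.
#'
#' @param n_codons total codons including start and terminal stop.
#' @param caa_codon_index codon index carrying CAA.
#' @return Character scalar DNA sequence.
#' @export
synthetic_cox15_orf <- function(n_codons = 162, caa_codon_index = 39) {
  stopifnot(n_codons >= caa_codon_index + 1, caa_codon_index >= 2)
  body <- rep(c("CTT", "GCT", "GAA", "TCC"), length.out = n_codons - 2)
  codons <- c("ATG", body, "TAA")
  codons[caa_codon_index] <- "CAA"
  paste(codons, collapse = "")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in the order of the study: synthetic cross and screen
#' simulation, screen scoring, segregation classification, bulk-segregant
#' mapping, nonsense/suppressor annotation and growth quantification, writing
#' every artifact (with seeds and thresholds in the provenance headers) under
#' `out_dir`. Stage-local seeds are derived from the single `seed` by fixed
#' offsets, so a rerun with the same configuration is bitwise reproducible.
#'
#' @param config named list (see [read_run_config()]); recognised keys with
#'   defaults: `seed` (1), `out_dir` ("dmiscreen_out"), `stages`
#'   (comma-separated subset of
#'   "simulate,screen,classify,bsa,annotate,growth"), `af_threshold` (0.1),
#'   `min_run` (5), `min_depth` (10), `epistasis_threshold` (0.01),
#'   `severe_threshold` (0.20), `coverage` (50), `error_rate` (0.002),
#'   `pool_size` (80).
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    seed = 1, out_dir = "dmiscreen_out",
    stages = "simulate,screen,classify,bsa,annotate,growth",
    af_threshold = 0.1, min_run = 5, min_depth = 10,
    epistasis_threshold = 0.01, severe_threshold = 0.20,
    coverage = 50, error_rate = 0.002, pool_size = 80), config)
  stages <- trimws(strsplit(as.character(cfg$stages), ",")[[1]])
  known <- c("simulate", "screen", "classify", "bsa", "annotate", "growth")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  p <- function(...) file.path(cfg$out_dir, ...)
  artifacts <- list()
  needs <- function(stage, files) {
    miss <- files[!file.exists(files)]
    if (length(miss))
      stop("stage '", stage, "' missing input(s): ",
           paste(miss, collapse = ", "), " (run the simulate stage first)")
  }
  run_stage <- function(name, body) {
    message("[", name, "] running")
    tryCatch(body(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  model <- incompatibility_model(
    "two_locus_unlinked",
    lethal_loci = data.frame(chrom = c("chr05", "chr10"),
                             pos = c(75500L, 75500L),
                             lethal_parent = c("P2", "P1")),
    conditions = "restrictive")

  if ("simulate" %in% stages) run_stage("simulate", function() {
    design <- make_cross(make_genome(), model, seed = seed)
    write_tsv(design$markers, p("markers.tsv"), seed = seed)
    scr <- simulate_screen(seed = seed + 1L)
    write_tsv(scr$spores, p("screen.tsv"), seed = seed + 1L)
    write_tsv(scr$parents, p("parents.tsv"), seed = seed + 1L)
    write_tsv(scr$instances, p("instances.tsv"), seed = seed + 1L)
    pool <- simulate_spore_pool(design, "restrictive", cfg$pool_size,
                                keep = "inviable", seed = seed + 2L)
    counts <- simulate_bsa_counts(pool, cfg$coverage, cfg$error_rate,
                                  seed = seed + 3L)
    write_tsv(as.data.frame(counts), p("counts.tsv"), seed = seed + 3L,
              params = list(coverage = cfg$coverage,
                            error_rate = cfg$error_rate))
    tet <- simulate_tetrads(design, 40, seed = seed + 4L)
    vc <- table(factor(viable_counts(tet, "restrictive"), levels = 4:0))
    write_tsv(data.frame(viable_count = names(vc),
                         n_tetrads = as.integer(vc)),
              p("tetrad_counts.tsv"), seed = seed + 4L)
    curves <- list()
    for (i in 1:6) {
      curves[[length(curves) + 1]] <- simulate_growth_curve(
        rate = 0.386, noise_sd = 0.005, well_id = sprintf("SUP%d", i),
        strain = "Y9", plasmid = "SUP", seed = seed + 10L + i)
      curves[[length(curves) + 1]] <- simulate_growth_curve(
        rate = 0.500, noise_sd = 0.005, well_id = sprintf("CTRL%d", i),
        strain = "Y9", plasmid = "Ctrl", seed = seed + 20L + i)
    }
    wm <- write_growth_csv(curves, p("growth.csv"))
    write_tsv(wm, p("well_map.tsv"), seed = seed)
    effects <- matrix(c(20, 0, -15), 1, 3,
                      dimnames = list("Y9", c("condA", "condB", "condC")))
    write_tsv(simulate_colony_grid("Y9", colnames(effects), effects,
                                   seed = seed + 30L),
              p("colony.tsv"), seed = seed + 30L)
    artifacts$simulate <<- p(c("markers.tsv", "screen.tsv", "parents.tsv",
                               "instances.tsv", "counts.tsv",
                               "tetrad_counts.tsv", "growth.csv",
                               "well_map.tsv", "colony.tsv"))
  })

  if ("screen" %in% stages) run_stage("screen", function() {
    needs("screen", p("instances.tsv"))
    inst <- read_tsv(p("instances.tsv"))
    summ <- summarize_screen(inst, cfg$epistasis_threshold,
                             cfg$severe_threshold)
    write_tsv(summ$instances, p("screen_instances.tsv"), seed = seed,
              params = list(epistasis_threshold = cfg$epistasis_threshold,
                            severe_threshold = cfg$severe_threshold))
    mat <- summ$matrix
    mat_out <- data.frame(cross_id = rownames(mat), mat,
                          check.names = FALSE)
    for (cond in colnames(mat))
      mat_out[[cond]] <- ifelse(summ$excluded_matrix[, cond], "excluded",
                                format(mat[, cond], digits = 4))
    write_tsv(mat_out, p("screen_matrix.tsv"), seed = seed)
    artifacts$screen <<- p(c("screen_instances.tsv", "screen_matrix.tsv"))
  })

  if ("classify" %in% stages) run_stage("classify", function() {
    needs("classify", p("tetrad_counts.tsv"))
    obs <- read_tetrad_counts(p("tetrad_counts.tsv"))
    call <- classify_segregation(obs, list("none", "two_locus_unlinked",
                                           "k_locus_3", "complex"))
    write_segregation_call(call, p("segregation.json"))
    artifacts$classify <<- p("segregation.json")
  })

  if ("bsa" %in% stages) run_stage("bsa", function() {
    needs("bsa", p("counts.tsv"))
    counts <- read_counts_table(p("counts.tsv"))
    afs <- allele_frequencies(counts, min_depth = cfg$min_depth)
    low <- detect_low_af_regions(afs, cfg$af_threshold, cfg$min_run)
    called <- allele_frequencies(drop_uncalled_markers(counts),
                                 min_depth = cfg$min_depth)
    deserts <- detect_marker_deserts(called, make_genome())
    regions <- rbind(as.data.frame(low), as.data.frame(deserts))
    write_tsv(regions, p("regions.tsv"), seed = seed,
              params = list(af_threshold = cfg$af_threshold,
                            min_run = cfg$min_run,
                            min_depth = cfg$min_depth))
    write_regions_bed(regions, p("regions.bed"))
    artifacts$bsa <<- p(c("regions.tsv", "regions.bed"))
  })

  if ("annotate" %in% stages) run_stage("annotate", function() {
    orf <- synthetic_cox15_orf()
    calls <- call_nonsense(orf, data.frame(orf_pos = 115, ref_base = "C",
                                           alt_base = "T"),
                           gene_id = "COX15like_synthetic")
    write_tsv(as.data.frame(calls), p("nonsense_calls.tsv"), seed = seed)
    trnas <- data.frame(trna_id = c("tY_GUA_synthetic", "tL_CAA_synthetic"),
                        anticodon = c("GTA", "CAA"),
                        stringsAsFactors = FALSE)
    sup <- scan_trnas(trnas, data.frame(trna_id = "tY_GUA_synthetic",
                                        pos = 1, ref = "G", alt = "T"))
    write_tsv(as.data.frame(sup), p("suppressor_calls.tsv"), seed = seed)
    artifacts$annotate <<- p(c("nonsense_calls.tsv", "suppressor_calls.tsv"))
  })

  if ("growth" %in% stages) run_stage("growth", function() {
    needs("growth", c(p("growth.csv"), p("well_map.tsv"), p("colony.tsv")))
    wm <- read_tsv(p("well_map.tsv"))
    curves <- read_growth_csv(p("growth.csv"), wm)
    rates <- vapply(curves, fit_growth_rate, 0)
    plasmid <- wm$plasmid[match(names(curves), wm$well)]
    gv <- growth_variation(rates[plasmid == "SUP"], rates[plasmid == "Ctrl"])
    write_tsv(data.frame(strain = wm$strain[1],
                         percent_variation = gv$percent_variation,
                         p_t = gv$p_t, n_sup = gv$n["sup"],
                         n_ctrl = gv$n["ctrl"]),
              p("growth_variation.tsv"), seed = seed)
    eff <- suppressor_effect(read_tsv(p("colony.tsv")))
    write_tsv(as.data.frame(eff), p("suppressor_effect.tsv"), seed = seed)
    artifacts$growth <<- p(c("growth_variation.tsv",
                             "suppressor_effect.tsv"))
  })

  invisible(artifacts)
}
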