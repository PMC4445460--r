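# Nonsense-mutation and tRNA-suppressor annotation.

test_that("a CAA codon gaining T at its first base yields a TAA call at +115", {
  orf <- synthetic_cox15_orf(n_codons = 162, caa_codon_index = 39)
  calls <- call_nonsense(orf, data.frame(orf_pos = 115, ref_base = "C",
                                         alt_base = "T"), gene_id = "g1")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$orf_nt_pos, 115)
  expect_equal(calls$codon_index, 39)
  expect_equal(calls$ref_codon, "CAA")
  expect_equal(calls$alt_codon, "TAA")
  expect_equal(calls$stop_class, "TAA")
})

test_that("nonsense calls obey codon arithmetic, stop membership and round-trip removal", {
  # codon 5 = CGA at nt 13-15; C->T gives TGA at position 13
  codons <- c("ATG", "CTT", "GCT", "GAA", "CGA", rep("TCC", 6), "TAA")
  orf <- paste(codons, collapse = "")
  calls <- call_nonsense(orf, data.frame(orf_pos = 13, ref_base = "C",
                                         alt_base = "T"))
  expect_equal(calls$orf_nt_pos, 13)
  expect_equal(calls$stop_class, "TGA")
  expect_equal(calls$orf_nt_pos, 3 * (calls$codon_index - 1) + 1)
  # synonymous change: no call
  expect_equal(nrow(call_nonsense(orf, data.frame(orf_pos = 6, ref_base = "T",
                                                  alt_base = "C"))), 0)
  # terminal stop codon is never a premature stop
  expect_equal(nrow(call_nonsense(orf, data.frame(
    orf_pos = length(codons) * 3 - 1, ref_base = "A", alt_base = "G"))), 0)
  # reverting the variant on the mutated sequence removes the call
  mutated <- orf
  substr(mutated, 13, 13) <- "T"
  expect_equal(nrow(suppressWarnings(
    call_nonsense(mutated, data.frame(orf_pos = 13, ref_base = "T",
                                      alt_base = "C")))), 0)
  # input validation
  expect_error(call_nonsense(orf, data.frame(orf_pos = 13, ref_base = "G",
                                             alt_base = "T")),
               "mismatch at ORF position 13")
  expect_error(call_nonsense(orf, data.frame(orf_pos = 999, ref_base = "C",
                                             alt_base = "T")),
               "outside ORF")
  expect_error(call_nonsense(substr(orf, 1, 10), data.frame(
    orf_pos = 1, ref_base = "A", alt_base = "T")), "divisible by 3")
})

test_that("stop-to-stop changes are not nonsense calls", {
  codons <- c("ATG", "TAA", "CTT", "TAA")  # internal TAA (constructed)
  orf <- paste(codons, collapse = "")
  calls <- call_nonsense(orf, data.frame(orf_pos = 6, ref_base = "A",
                                         alt_base = "G"))  # TAA -> TAG
  expect_equal(nrow(calls), 0)
})

test_that("genomic-coordinate annotation is strand-consistent", {
  orf_plus <- synthetic_cox15_orf(n_codons = 30, caa_codon_index = 10)
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  spacer <- paste(rep("A", 20), collapse = "")
  chrom_seq <- paste0(spacer, orf_plus, spacer)      # plus-strand gene
  chrom_seq2 <- paste0(spacer, rc(orf_plus), spacer)  # same gene, minus strand
  genes <- data.frame(
    gene_id = c("gP", "gM"), chrom = c("c1", "c2"),
    start = 21L, end = 20L + nchar(orf_plus), strand = c("+", "-"))
  # variant hits ORF position 28 (codon 10 first base, CAA -> TAA)
  gpos_plus <- 20L + 28L
  gpos_minus <- genes$end[2] - 28L + 1L
  variants <- data.frame(
    chrom = c("c1", "c2"), pos = c(gpos_plus, gpos_minus),
    ref = c("C", "G"), alt = c("T", "A"))
  calls <- call_nonsense_genomic(genes, c(c1 = chrom_seq, c2 = chrom_seq2),
                                 variants)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$orf_nt_pos, c(28, 28))
  expect_equal(calls$stop_class, c("TAA", "TAA"))
  expect_equal(calls$ref_codon, c("CAA", "CAA"))
})

test_that("per-strain stop-class counts and shared-gene tallies are exact", {
  mk <- function(genes, classes)
    structure(data.frame(gene_id = genes, stop_class = classes,
                         stringsAsFactors = FALSE),
              class = c("nonsense_calls", "data.frame"))
  calls <- list(
    s1 = mk(c("geneA", "geneA", "geneB", "geneC"),
            c("TAA", "TAA", "TAA", "TGA")),
    s2 = mk(c("geneA", "geneD"), c("TAG", "TGA")),
    s3 = mk(character(), character()))
  counts <- count_nonsense_by_class(calls)
  expect_equal(counts["s1", ], c(TAA = 3L, TAG = 0L, TGA = 1L))
  expect_equal(counts["s2", ], c(TAA = 0L, TAG = 1L, TGA = 1L))
  expect_equal(counts["s3", ], c(TAA = 0L, TAG = 0L, TGA = 0L))
  shared <- shared_nonsense_genes(calls)
  expect_equal(shared$n_shared, 1)       # geneA in two strains
  expect_equal(shared$n_total_genes, 4)  # A, B, C, D
  one <- shared_nonsense_genes(calls["s1"])
  expect_equal(one$n_shared, 0)
})

test_that("per-class nonsense counts concentrate around a planted mean", {
  set.seed(8)
  strains <- lapply(1:100, function(i) {
    n <- stats::rpois(3, 10)  # ~10 calls per stop class
    classes <- rep(c("TAA", "TAG", "TGA"), n)
    structure(data.frame(gene_id = sprintf("g%03d", seq_along(classes)),
                         orf_nt_pos = 1L, codon_index = 1L, ref_codon = "CAA",
                         alt_codon = classes, stop_class = classes,
                         stringsAsFactors = FALSE),
              class = c("nonsense_calls", "data.frame"))
  })
  names(strains) <- sprintf("s%03d", 1:100)
  counts <- count_nonsense_by_class(strains)
  expect_true(all(abs(colMeans(counts) - 10) < 1))
})

test_that("anticodon changes are classified against the suppressor enumeration oracle", {
  # the worked case: tyrosine GTA -> TTA reads TAA (ochre suppressor)
  hit <- detect_trna_suppressor("GTA", "TTA", trna_id = "tY")
  expect_equal(hit$suppressed_stop, "TAA")
  expect_null(detect_trna_suppressor("GTA", "GTA"))
  expect_equal(detect_trna_suppressor("GTA", "CTA")$suppressed_stop, "TAG")
  expect_error(detect_trna_suppressor("GXA", "TTA"), "A, C, G, T")
  # exhaustive single-base enumeration: 64 anticodons x 9 changes
  oracle <- oracle_suppressor_set()
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  found <- list()
  for (before in codons) for (p in 1:3) for (b in bases) {
    if (substr(before, p, p) == b) next
    after <- before
    substr(after, p, p) <- b
    hit <- detect_trna_suppressor(before, after)
    if (!is.null(hit))
      found[[length(found) + 1]] <- c(before = before, after = after,
                                      stop = hit$suppressed_stop)
  }
  found <- do.call(rbind, found)
  expect_equal(nrow(found), nrow(oracle))
  expect_setequal(paste(found[, 1], found[, 2], found[, 3]),
                  paste(oracle[, 1], oracle[, 2], oracle[, 3]))
})

test_that("tRNA table scans apply variants and report empty results cleanly", {
  trnas <- data.frame(trna_id = c("tY_GUA_J1", "tL_CAA", "tS_GCT"),
                      anticodon = c("GTA", "CAA", "GCT"))
  expect_equal(nrow(scan_trnas(trnas)), 0)  # no variants, no suppressors
  hits <- scan_trnas(trnas, data.frame(trna_id = "tY_GUA_J1", pos = 1,
                                       ref = "G", alt = "T"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$suppressed_stop, "TAA")
  expect_equal(hits$anticodon_after, "TTA")
  expect_error(scan_trnas(trnas, data.frame(trna_id = "missing", pos = 1,
                                            ref = "G", alt = "T")),
               "unknown tRNA")
  expect_error(scan_trnas(trnas, data.frame(trna_id = "tL_CAA", pos = 1,
                                            ref = "G", alt = "T")),
               "mismatch")
})
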