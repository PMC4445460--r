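# Nonsense-mutation and tRNA nonsense-suppressor annotation.

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

.check_dna <- function(x, what = "sequence") {
  if (!all(grepl("^[ACGT]+$", x)))
    stop(what, " must contain only A, C, G, T")
  invisible(x)
}

#' Call premature stop codons induced by ORF variants
#'
#' Applies each single-nucleotide variant independently to its codon and
#' emits a nonsense call when a non-stop codon becomes one of the stop codons
#' TAA (ochre), TAG (amber) or TGA (opal) before the terminal codon.
#' Coordinates are 1-based from the A of the start ATG; the reported
#' `orf_nt_pos` is the first base of the affected codon, so a stop gained in
#' codon 39 is reported at +115 regardless of which codon base mutated.
#' Variants converting one stop class to another, or hitting the terminal
#' stop codon, are not nonsense calls.
#'
#' @param orf_sequence in-frame ORF DNA sequence (character scalar); length
#'   must be divisible by 3; a warning is issued if it does not start with
#'   ATG or end with a stop codon.
#' @param variants data.frame with columns `orf_pos` (1-based), `ref_base`,
#'   `alt_base`.
#' @param gene_id label attached to the calls.
#' @return data.frame of class `nonsense_calls` with columns `gene_id`,
#'   `orf_nt_pos`, `codon_index`, `ref_codon`, `alt_codon`, `stop_class`.
#' @export
call_nonsense <- function(orf_sequence, variants, gene_id = "ORF") {
  orf_sequence <- toupper(orf_sequence)
  .check_dna(orf_sequence, "ORF sequence")
  n <- nchar(orf_sequence)
  if (n %% 3 != 0) stop("ORF length must be divisible by 3")
  n_codon <- n %/% 3
  if (substr(orf_sequence, 1, 3) != "ATG")
    warning("ORF does not start with ATG")
  if (!substr(orf_sequence, n - 2, n) %in% STOP_CODONS)
    warning("ORF does not end with a stop codon")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("orf_pos", "ref_base", "alt_base") %in% names(variants)))
  calls <- list()
  for (i in seq_len(nrow(variants))) {
    pos <- as.integer(variants$orf_pos[i])
    ref <- toupper(variants$ref_base[i])
    alt <- toupper(variants$alt_base[i])
    .check_dna(c(ref, alt), "variant alleles")
    if (pos < 1 || pos > n)
      stop("variant position ", pos, " outside ORF (length ", n, ")")
    if (substr(orf_sequence, pos, pos) != ref)
      stop("reference base mismatch at ORF position ", pos, ": sequence has ",
           substr(orf_sequence, pos, pos), ", variant claims ", ref)
    ci <- (pos - 1L) %/% 3L + 1L
    cstart <- 3L * (ci - 1L) + 1L
    ref_codon <- substr(orf_sequence, cstart, cstart + 2L)
    alt_codon <- ref_codon
    substr(alt_codon, pos - cstart + 1L, pos - cstart + 1L) <- alt
    if (ref_codon %in% STOP_CODONS) next
    if (!alt_codon %in% STOP_CODONS) next
    if (ci >= n_codon) next  # terminal codon: not a premature stop
    calls[[length(calls) + 1]] <- data.frame(
      gene_id = gene_id, orf_nt_pos = cstart, codon_index = ci,
      ref_codon = ref_codon, alt_codon = alt_codon, stop_class = alt_codon,
      stringsAsFactors = FALSE)
  }
  res <- if (length(calls)) do.call(rbind, calls) else
    data.frame(gene_id = character(), orf_nt_pos = integer(),
               codon_index = integer(), ref_codon = character(),
               alt_codon = character(), stop_class = character(),
               stringsAsFactors = FALSE)
  structure(res, class = c("nonsense_calls", "data.frame"))
}

#' Call nonsense mutations from genomic coordinates
#'
#' Extracts each gene's ORF from genomic sequence (reverse-complementing
#' minus-strand genes), maps genomic variants into ORF coordinates
#' (complementing alleles on the minus strand) and delegates to
#' [call_nonsense()]. Plus- and minus-strand representations of the same gene
#' yield identical calls.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand` (`"+"`/`"-"`).
#' @param genome_seqs named character vector (or `DNAStringSet`) of
#'   chromosome sequences.
#' @param variants data.frame with columns `chrom`, `pos` (genomic, 1-based),
#'   `ref`, `alt` (plus-strand alleles).
#' @return `nonsense_calls` data.frame over all genes.
#' @export
call_nonsense_genomic <- function(genes, genome_seqs, variants) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (inherits(genome_seqs, "DNAStringSet"))
    genome_seqs <- stats::setNames(as.character(genome_seqs),
                                   names(genome_seqs))
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    seq_chr <- genome_seqs[[g$chrom]]
    if (is.null(seq_chr)) stop("no sequence for chromosome ", g$chrom)
    orf <- substr(seq_chr, g$start, g$end)
    v <- variants[variants$chrom == g$chrom & variants$pos >= g$start &
                    variants$pos <= g$end, , drop = FALSE]
    if (g$strand == "-") {
      orf <- .revcomp(orf)
      ov <- data.frame(orf_pos = g$end - v$pos + 1L,
                       ref_base = .revcomp(v$ref), alt_base = .revcomp(v$alt),
                       stringsAsFactors = FALSE)
    } else {
      ov <- data.frame(orf_pos = v$pos - g$start + 1L,
                       ref_base = v$ref, alt_base = v$alt,
                       stringsAsFactors = FALSE)
    }
    out[[i]] <- call_nonsense(orf, ov, gene_id = g$gene_id)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(), orf_nt_pos = integer(),
                      codon_index = integer(), ref_codon = character(),
                      alt_codon = character(), stop_class = character(),
                      stringsAsFactors = FALSE)
  structure(res, class = c("nonsense_calls", "data.frame"))
}

#' Per-strain counts of nonsense mutations by stop-codon class
#'
#' @param calls_per_strain named list mapping strain name to a
#'   `nonsense_calls` data.frame; one gene may contribute several calls.
#' @return Integer matrix, strains x stop classes (TAA, TAG, TGA).
#' @export
count_nonsense_by_class <- function(calls_per_strain) {
  stopifnot(is.list(calls_per_strain))
  out <- matrix(0L, length(calls_per_strain), length(STOP_CODONS),
                dimnames = list(names(calls_per_strain), STOP_CODONS))
  for (s in seq_along(calls_per_strain)) {
    cl <- calls_per_strain[[s]]
    if (!is.null(cl) && nrow(cl))
      out[s, ] <- vapply(STOP_CODONS,
                         function(k) sum(cl$stop_class == k), 0L)
  }
  out
}

#' Genes with nonsense mutations shared across strains
#'
#' @inheritParams count_nonsense_by_class
#' @return List with `n_shared` (distinct genes carrying a nonsense call in
#'   at least two strains) and `n_total_genes` (distinct genes with at least
#'   one call in any strain).
#' @export
shared_nonsense_genes <- function(calls_per_strain) {
  genes_by_strain <- lapply(calls_per_strain, function(cl)
    if (is.null(cl) || !nrow(cl)) character() else unique(cl$gene_id))
  tab <- table(unlist(genes_by_strain, use.names = FALSE))
  list(n_shared = sum(tab >= 2), n_total_genes = length(tab))
}

#' Classify a tRNA anticodon change as a nonsense suppressor
#'
#' Anticodons are given as DNA trinucleotides 5'->3'; the codon a tRNA reads
#' is the reverse complement of its anticodon. A suppressor call is emitted
#' iff the mutated anticodon reads a stop codon while the original did not:
#' e.g. the tyrosine anticodon GTA (reading TAC) mutated to TTA reads TAA and
#' becomes an ochre suppressor.
#'
#' @param anticodon_before,anticodon_after DNA trinucleotides.
#' @param trna_id label for the tRNA gene.
#' @return A one-row data.frame of class `suppressor_calls` (`trna_id`,
#'   `anticodon_before`, `anticodon_after`, `suppressed_stop`), or NULL when
#'   the change does not create a suppressor.
#' @export
detect_trna_suppressor <- function(anticodon_before, anticodon_after,
                                   trna_id = "tRNA") {
  anticodon_before <- toupper(anticodon_before)
  anticodon_after <- toupper(anticodon_after)
  if (nchar(anticodon_before) != 3 || nchar(anticodon_after) != 3)
    stop("anticodons must be trinucleotides")
  .check_dna(c(anticodon_before, anticodon_after), "anticodons")
  read_before <- .revcomp(anticodon_before)
  read_after <- .revcomp(anticodon_after)
  if (read_before %in% STOP_CODONS) return(NULL)  # already stop-reading
  if (!read_after %in% STOP_CODONS) return(NULL)
  structure(data.frame(trna_id = trna_id,
                       anticodon_before = anticodon_before,
                       anticodon_after = anticodon_after,
                       suppressed_stop = read_after,
                       stringsAsFactors = FALSE),
            class = c("suppressor_calls", "data.frame"))
}

#' Scan a tRNA gene table for suppressor-creating anticodon variants
#'
#' Applies per-tRNA anticodon variants and collects suppressor calls. An
#' empty result is the expected outcome for natural isolates, where tRNA
#' suppressors are exceedingly rare.
#'
#' @param trna_table data.frame with columns `trna_id`, `anticodon`
#'   (DNA, 5'->3').
#' @param variants data.frame with columns `trna_id`, `pos` (1-3 within the
#'   anticodon), `ref`, `alt`; NULL or empty means no changes.
#' @return `suppressor_calls` data.frame (possibly 0 rows).
#' @export
scan_trnas <- function(trna_table, variants = NULL) {
  trna_table <- as.data.frame(trna_table, stringsAsFactors = FALSE)
  stopifnot(all(c("trna_id", "anticodon") %in% names(trna_table)))
  .check_dna(trna_table$anticodon, "anticodons")
  calls <- list()
  if (!is.null(variants) && nrow(variants)) {
    variants <- as.data.frame(variants, stringsAsFactors = FALSE)
    stopifnot(all(c("trna_id", "pos", "ref", "alt") %in% names(variants)))
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      j <- match(v$trna_id, trna_table$trna_id)
      if (is.na(j)) stop("variant for unknown tRNA: ", v$trna_id)
      if (v$pos < 1 || v$pos > 3)
        stop("anticodon variant position must be 1-3")
      before <- trna_table$anticodon[j]
      if (substr(before, v$pos, v$pos) != toupper(v$ref))
        stop("anticodon reference mismatch for ", v$trna_id,
             " at position ", v$pos)
      after <- before
      substr(after, v$pos, v$pos) <- toupper(v$alt)
      hit <- detect_trna_suppressor(before, after, trna_id = v$trna_id)
      if (!is.null(hit)) calls[[length(calls) + 1]] <- hit
    }
  }
  res <- if (length(calls)) do.call(rbind, calls) else
    data.frame(trna_id = character(), anticodon_before = character(),
               anticodon_after = character(), suppressed_stop = character(),
               stringsAsFactors = FALSE)
  structure(res, class = c("suppressor_calls", "data.frame"))
}
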