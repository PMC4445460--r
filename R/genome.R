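#' Construct a genome map of chromosomes and biallelic markers
#'
#' A genome map holds the chromosome sizes and the polymorphic positions
#' (markers) segregating in a haploid x haploid cross. Marker positions are
#' 1-based and must be unique within a chromosome.
#'
#' @param chromosomes data.frame with columns `name` (character) and
#'   `length_bp` (positive integer).
#' @param markers data.frame with columns `chrom`, `pos` (1-based integer)
#'   and optionally `id`; ids are generated as `chrom_pos` when absent.
#' @return An object of class `genome_map`: a list with elements
#'   `chromosomes` and `markers` (markers sorted by chromosome then position).
#' @export
genome_map <- function(chromosomes, markers) {
  chromosomes <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "length_bp") %in% names(chromosomes)),
            all(c("chrom", "pos") %in% names(markers)))
  if (anyDuplicated(chromosomes$name))
    stop("chromosome names must be unique")
  if (any(chromosomes$length_bp < 1))
    stop("chromosome lengths must be positive")
  bad <- !(markers$chrom %in% chromosomes$name)
  if (any(bad))
    stop("markers on unknown chromosome: ",
         paste(unique(markers$chrom[bad]), collapse = ", "))
  len <- chromosomes$length_bp[match(markers$chrom, chromosomes$name)]
  if (any(markers$pos < 1 | markers$pos > len))
    stop("marker positions must lie in [1, chromosome length]")
  if (anyDuplicated(markers[, c("chrom", "pos")]))
    stop("marker positions must be unique within a chromosome")
  if (is.null(markers$id))
    markers$id <- paste(markers$chrom, markers$pos, sep = "_")
  ord <- order(match(markers$chrom, chromosomes$name), markers$pos)
  markers <- markers[ord, c("chrom", "pos", "id")]
  rownames(markers) <- NULL
  structure(list(chromosomes = chromosomes, markers = markers),
            class = "genome_map")
}

#' Build a regular synthetic genome map
#'
#' Convenience constructor for simulation studies: `n_chrom` chromosomes of
#' equal size with evenly spaced markers. The defaults give a scaled yeast-like
#' genome (16 chromosomes, 150 kb each, 1 marker per kb) that preserves
#' realistic per-chromosome linkage while keeping simulations fast.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp length of every chromosome in bp.
#' @param marker_spacing_bp distance between adjacent markers in bp.
#' @return A `genome_map`.
#' @export
make_genome <- function(n_chrom = 16, chrom_length_bp = 150000,
                        marker_spacing_bp = 1000) {
  stopifnot(n_chrom >= 1, chrom_length_bp >= marker_spacing_bp)
  chroms <- data.frame(name = sprintf("chr%02d", seq_len(n_chrom)),
                       length_bp = chrom_length_bp,
                       stringsAsFactors = FALSE)
  pos <- seq(marker_spacing_bp %/% 2, chrom_length_bp, by = marker_spacing_bp)
  markers <- data.frame(chrom = rep(chroms$name, each = length(pos)),
                        pos = rep(pos, n_chrom), stringsAsFactors = FALSE)
  genome_map(chroms, markers)
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$markers), "markers\n")
  invisible(x)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
MODEL_KINDS <- c("none", "two_locus_unlinked", "two_locus_linked", "k_locus")

#' Specify a genetic incompatibility model
#'
#' Describes which allelic combination is lethal in offspring, how strongly
#' (penetrance), and under which culture conditions. The worked two-locus case
#' is a recessive Dobzhansky-Muller pair: a spore dies iff it inherits the
#' P2 allele at the first locus (a nonsense-disrupted gene) together with the
#' P1 allele at the second (absence of the tRNA suppressor).
#'
#' @param kind one of `"none"`, `"two_locus_unlinked"`, `"two_locus_linked"`,
#'   `"k_locus"`.
#' @param lethal_loci data.frame with columns `chrom`, `pos`, `lethal_parent`
#'   (`"P1"` or `"P2"`); the spore dies when it carries the lethal parent's
#'   allele at *every* listed locus. NULL for `kind = "none"`.
#' @param r recombination fraction in [0, 0.5] between the two loci
#'   (`two_locus_linked` only).
#' @param penetrance probability in [0, 1] that the lethal genotype kills.
#' @param conditions character vector of condition names where lethality acts.
#' @return An object of class `incompatibility_model`.
#' @export
incompatibility_model <- function(kind = c("none", "two_locus_unlinked",
                                           "two_locus_linked", "k_locus"),
                                  lethal_loci = NULL, r = NULL,
                                  penetrance = 1.0,
                                  conditions = "restrictive") {
  kind <- match.arg(kind)
  if (penetrance < 0 || penetrance > 1)
    stop("penetrance must lie in [0, 1]")
  if (kind == "none") {
    lethal_loci <- data.frame(chrom = character(), pos = integer(),
                              lethal_parent = character(),
                              stringsAsFactors = FALSE)
  } else {
    lethal_loci <- as.data.frame(lethal_loci, stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "pos", "lethal_parent") %in% names(lethal_loci)))
    if (!all(lethal_loci$lethal_parent %in% c("P1", "P2")))
      stop("lethal_parent must be 'P1' or 'P2'")
  }
  nl <- nrow(lethal_loci)
  if (kind %in% c("two_locus_unlinked", "two_locus_linked") && nl != 2)
    stop(kind, " requires exactly 2 lethal loci")
  if (kind == "k_locus" && nl < 1)
    stop("k_locus requires k >= 1 lethal loci")
  if (kind %in% c("two_locus_unlinked", "k_locus") &&
      anyDuplicated(lethal_loci$chrom))
    stop("unlinked lethal loci must lie on distinct chromosomes")
  if (kind == "two_locus_linked") {
    if (is.null(r) || r < 0 || r > 0.5)
      stop("two_locus_linked requires recombination fraction r in [0, 0.5]")
    if (length(unique(lethal_loci$chrom)) != 1)
      stop("linked loci must share a chromosome")
  } else r <- NULL
  structure(list(kind = kind, lethal_loci = lethal_loci, r = r,
                 penetrance = penetrance,
                 conditions = as.character(conditions)),
            class = "incompatibility_model")
}

#' @export
print.incompatibility_model <- function(x, ...) {
  cat("incompatibility_model:", x$kind,
      if (nrow(x$lethal_loci)) sprintf("(%d loci, penetrance %.2f)",
                                       nrow(x$lethal_loci), x$penetrance),
      "\n")
  invisible(x)
}

#' Assemble a reproducible cross design
#'
#' Combines a genome map with an incompatibility model into the design of a
#' single haploid x haploid cross. Model loci absent from the marker set are
#' added as markers; nominal parental alleles (bases) are drawn reproducibly
#' from `seed` for table output.
#'
#' @param genome a `genome_map` (or parameters accepted by [make_genome()]).
#' @param model an `incompatibility_model`.
#' @param seed integer seed; identical seeds give identical designs.
#' @return An object of class `cross_design`: the genome (with model loci
#'   merged in), the model, a marker table with `p1_allele`/`p2_allele`
#'   columns, and the marker indices of the lethal loci.
#' @export
make_cross <- function(genome = make_genome(), model = incompatibility_model("none"),
                       seed = 1L) {
  stopifnot(inherits(genome, "genome_map"),
            inherits(model, "incompatibility_model"))
  if (nrow(model$lethal_loci)) {
    unknown <- !(model$lethal_loci$chrom %in% genome$chromosomes$name)
    if (any(unknown))
      stop("lethal locus on unknown chromosome: ",
           paste(model$lethal_loci$chrom[unknown], collapse = ", "))
    key <- paste(genome$markers$chrom, genome$markers$pos)
    lkey <- paste(model$lethal_loci$chrom, model$lethal_loci$pos)
    missing <- !(lkey %in% key)
    if (any(missing)) {
      add <- data.frame(chrom = model$lethal_loci$chrom[missing],
                        pos = model$lethal_loci$pos[missing],
                        stringsAsFactors = FALSE)
      add$id <- paste(add$chrom, add$pos, sep = "_")
      genome <- genome_map(genome$chromosomes,
                           rbind(genome$markers, add))
    }
  }
  mk <- genome$markers
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    p1 <- sample(bases, nrow(mk), replace = TRUE)
    shift <- sample(1:3, nrow(mk), replace = TRUE)
    p2 <- bases[(match(p1, bases) - 1L + shift) %% 4L + 1L]
  })
  mk$p1_allele <- p1
  mk$p2_allele <- p2
  locus_idx <- integer(0)
  if (nrow(model$lethal_loci))
    locus_idx <- match(paste(model$lethal_loci$chrom, model$lethal_loci$pos),
                       paste(mk$chrom, mk$pos))
  structure(list(genome = genome, model = model, markers = mk,
                 lethal_idx = locus_idx, seed = seed),
            class = "cross_design")
}

#' @export
print.cross_design <- function(x, ...) {
  cat("cross_design:", nrow(x$markers), "markers on",
      nrow(x$genome$chromosomes), "chromosomes; model", x$model$kind, "\n")
  invisible(x)
}
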