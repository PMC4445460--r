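# Shared fixtures: models, genomes and independent enumeration oracles.

# the worked two-locus case geometry: driver on chr05, rescuer on chr10
two_locus_model <- function(penetrance = 1, conditions = "restrictive") {
  incompatibility_model(
    "two_locus_unlinked",
    lethal_loci = data.frame(chrom = c("chr05", "chr10"),
                             pos = c(75500L, 75500L),
                             lethal_parent = c("P2", "P1")),
    penetrance = penetrance, conditions = conditions)
}

k_locus_model <- function(k, penetrance = 1) {
  incompatibility_model(
    "k_locus",
    lethal_loci = data.frame(chrom = sprintf("chr%02d", seq_len(k)),
                             pos = 75500L,
                             lethal_parent = rep(c("P2", "P1"),
                                                 length.out = k)),
    penetrance = penetrance)
}

linked_model <- function(r, lethal_parent = c("P2", "P1")) {
  incompatibility_model(
    "two_locus_linked",
    lethal_loci = data.frame(chrom = "chr01", pos = c(10500L, 50500L),
                             lethal_parent = lethal_parent),
    r = r)
}

# small genome for fast tetrad-level tests
tiny_genome <- function(n_chrom = 4)
  make_genome(n_chrom = n_chrom, chrom_length_bp = 150000,
              marker_spacing_bp = 50000)

# independent oracle: distribution of tetrad viable counts for k unlinked
# loci, by direct enumeration of all 6^k joint choices of 2-subsets of the
# 4 spores (dead spores = intersection of the lethal-allele subsets)
oracle_k_locus_distribution <- function(k) {
  subsets <- utils::combn(4, 2, simplify = FALSE)
  grid <- expand.grid(rep(list(1:6), k))
  dead <- apply(grid, 1, function(row)
    length(Reduce(intersect, subsets[as.integer(row)])))
  counts <- table(factor(4 - dead, levels = c(4, 3, 2, 1, 0)))
  as.numeric(counts) / 6^k
}

# independent oracle: every single-base anticodon change whose mutated
# anticodon reads a stop codon while the original did not
oracle_suppressor_set <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  rc <- function(x) chartr("ACGT", "TGCA",
                           sapply(lapply(strsplit(x, ""), rev), paste,
                                  collapse = ""))
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (before in codons) for (p in 1:3) for (b in bases) {
    if (substr(before, p, p) == b) next
    after <- before
    substr(after, p, p) <- b
    if (!(rc(before) %in% stops) && rc(after) %in% stops)
      out[[length(out) + 1]] <- c(before = before, after = after,
                                  stop = rc(after))
  }
  do.call(rbind, out)
}

# Haldane recombination fraction for a physical distance on the simulated map
r_from_bp <- function(bp, cm_per_kb = 0.35) {
  d_morgans <- bp / 1000 * cm_per_kb / 100
  (1 - exp(-2 * d_morgans)) / 2
}
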