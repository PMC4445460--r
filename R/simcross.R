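# Synthetic cross simulator: meiosis into tetrads, condition-dependent
# lethality, pooled-sequencing counts, screen tables and phenotyping data.

with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# the 6 ways to pick which 2 of 4 spores receive P1-derived chromatids
.SPORE_PAIRS <- utils::combn(4L, 2L)
.SPORE_PAIRS_COMP <- apply(.SPORE_PAIRS, 2, function(p) setdiff(1:4, p))

# centimorgans per kb of physical distance (S. cerevisiae genome average)
CM_PER_KB_DEFAULT <- 0.35

#' Simulate meioses of a cross into tetrads
#'
#' Each meiosis produces four haploid spores segregating 2:2 at every marker.
#' Markers on distinct chromosomes assort independently (each chromosome's
#' chromatids are dealt to the four spores uniformly at random, so a single
#' marker gets one of the 6 possible 2:2 partitions with equal probability).
#' Markers on the same chromosome co-segregate through a four-chromatid
#' crossover model without interference: the number of crossovers in each
#' inter-marker interval is Poisson with mean twice the interval's map length
#' in Morgans (Haldane), and each crossover exchanges the distal segments of
#' one randomly chosen chromatid from each homolog.
#'
#' Spore viability per condition is determined by the design's
#' incompatibility model: a spore carrying the lethal parent's allele at every
#' lethal locus dies with probability `penetrance` on each condition where the
#' model acts; all spores are viable on `"permissive"`.
#'
#' @param design a `cross_design` from [make_cross()].
#' @param n number of tetrads to simulate.
#' @param seed optional integer seed for reproducibility.
#' @param cm_per_kb genetic map scaling, centimorgans per kb.
#' @return An object of class `tetrad_set`: list with `genotype` (integer
#'   matrix, `4*n` spore rows by marker columns, entries 1 = P1 origin,
#'   2 = P2), `viability` (logical matrix, spore rows by condition columns,
#'   first column `"permissive"`), `tetrad` and `spore` index vectors, and
#'   the `design`.
#' @export
simulate_tetrads <- function(design, n, seed = NULL,
                             cm_per_kb = CM_PER_KB_DEFAULT) {
  stopifnot(inherits(design, "cross_design"), n >= 1)
  n <- as.integer(n)
  mk <- design$markers
  M <- nrow(mk)
  with_opt_seed(seed, {
    G <- matrix(0L, nrow = 4L * n, ncol = M)
    for (ch in unique(mk$chrom)) {
      jj <- which(mk$chrom == ch)
      pos <- mk$pos[jj]
      # independent assortment: choose which 2 spores get the P1 sisters
      pick <- sample.int(6L, n, replace = TRUE)
      s1 <- cbind(.SPORE_PAIRS[1L, pick], .SPORE_PAIRS[2L, pick])
      s2 <- cbind(.SPORE_PAIRS_COMP[1L, pick], .SPORE_PAIRS_COMP[2L, pick])
      cur <- matrix(2L, n, 4L)
      cur[cbind(seq_len(n), s1[, 1L])] <- 1L
      cur[cbind(seq_len(n), s1[, 2L])] <- 1L
      G[, jj[1L]] <- as.vector(t(cur))
      if (length(jj) > 1L) {
        lam <- 2 * diff(pos) / 1000 * cm_per_kb / 100  # Poisson crossover mean
        for (i in seq_along(lam)) {
          k <- stats::rpois(n, lam[i])
          mx <- max(k)
          j <- 1L
          while (j <= mx) {
            act <- which(k >= j)
            a <- ifelse(stats::runif(length(act)) < 0.5,
                        s1[act, 1L], s1[act, 2L])
            b <- ifelse(stats::runif(length(act)) < 0.5,
                        s2[act, 1L], s2[act, 2L])
            ia <- cbind(act, a); ib <- cbind(act, b)
            tmp <- cur[ia]; cur[ia] <- cur[ib]; cur[ib] <- tmp
            j <- j + 1L
          }
          G[, jj[i + 1L]] <- as.vector(t(cur))
        }
      }
    }
    viab <- .spore_viability(G, design)
    structure(list(genotype = G, viability = viab,
                   tetrad = rep(seq_len(n), each = 4L),
                   spore = rep(1:4, n), design = design),
              class = "tetrad_set")
  })
}

# viability matrix for spore-genotype rows under the design's model;
# consumes RNG when penetrance < 1
.spore_viability <- function(G, design) {
  model <- design$model
  conds <- unique(c("permissive", model$conditions))
  viab <- matrix(TRUE, nrow(G), length(conds), dimnames = list(NULL, conds))
  if (model$kind != "none" && length(design$lethal_idx)) {
    lp <- match(model$lethal_loci$lethal_parent, c("P1", "P2"))
    lethal <- rep(TRUE, nrow(G))
    for (l in seq_along(design$lethal_idx))
      lethal <- lethal & (G[, design$lethal_idx[l]] == lp[l])
    for (cond in model$conditions) {
      dead <- lethal
      if (model$penetrance < 1)
        dead <- lethal & (stats::runif(nrow(G)) < model$penetrance)
      viab[, cond] <- !dead
    }
  }
  viab
}

#' Simulate a single tetrad
#'
#' @inheritParams simulate_tetrads
#' @param tetrad_id label for the tetrad.
#' @return An object of class `tetrad`: list with `genotype` (4 x markers),
#'   `viability` (4 x conditions) and `tetrad_id`.
#' @export
simulate_tetrad <- function(design, seed = NULL, tetrad_id = "tetrad1",
                            cm_per_kb = CM_PER_KB_DEFAULT) {
  ts <- simulate_tetrads(design, 1L, seed = seed, cm_per_kb = cm_per_kb)
  structure(list(genotype = ts$genotype, viability = ts$viability,
                 tetrad_id = tetrad_id, design = design),
            class = "tetrad")
}

#' Count viable spores per tetrad
#'
#' @param tetrads a `tetrad_set`.
#' @param condition condition name (a column of the viability matrix).
#' @return Integer vector, one viable-spore count (0-4) per tetrad.
#' @export
viable_counts <- function(tetrads, condition = "restrictive") {
  stopifnot(inherits(tetrads, "tetrad_set"))
  if (!condition %in% colnames(tetrads$viability))
    stop("unknown condition: ", condition)
  as.integer(rowsum(as.integer(tetrads$viability[, condition]),
                    tetrads$tetrad)[, 1L])
}

#' Draw a pool of segregants filtered on viability
#'
#' Emulates picking one random spore per independent tetrad and keeping those
#' matching the viability filter, until `n_target` spores are retained (e.g.
#' the 80 respiratory-deficient segregants pooled for bulk-segregant
#' sequencing).
#'
#' @inheritParams simulate_tetrads
#' @param condition condition on which the viability filter is evaluated.
#' @param n_target number of spores to retain.
#' @param keep `"viable"` or `"inviable"`.
#' @param max_tetrads bound on the number of tetrads attempted before an
#'   explicit no-progress error (e.g. `keep = "inviable"` under a model with
#'   no lethality).
#' @return An object of class `spore_pool`: list with `genotype` (n_target x
#'   markers integer matrix, 1 = P1, 2 = P2), `condition`, `keep`, `design`.
#' @export
simulate_spore_pool <- function(design, condition = "restrictive",
                                n_target = 80, keep = c("viable", "inviable"),
                                seed = NULL, max_tetrads = 200 * n_target,
                                cm_per_kb = CM_PER_KB_DEFAULT) {
  keep <- match.arg(keep)
  stopifnot(n_target >= 1)
  with_opt_seed(seed, {
    got <- matrix(0L, 0L, nrow(design$markers))
    attempted <- 0L
    while (nrow(got) < n_target) {
      if (attempted >= max_tetrads)
        stop("no progress after ", attempted, " tetrads: filter '", keep,
             "' on condition '", condition,
             "' may be impossible under this model")
      batch <- min(max(64L, 4L * (n_target - nrow(got))),
                   max_tetrads - attempted)
      ts <- simulate_tetrads(design, batch, cm_per_kb = cm_per_kb)
      attempted <- attempted + batch
      # one spore per tetrad, independently chosen
      rows <- (seq_len(batch) - 1L) * 4L + sample.int(4L, batch, replace = TRUE)
      ok <- if (keep == "viable") ts$viability[rows, condition]
            else !ts$viability[rows, condition]
      if (any(ok))
        got <- rbind(got, ts$genotype[rows[ok], , drop = FALSE])
    }
    structure(list(genotype = got[seq_len(n_target), , drop = FALSE],
                   condition = condition, keep = keep, design = design),
              class = "spore_pool")
  })
}

#' Simulate pooled-sequencing allele counts over a spore pool
#'
#' At each marker the total read depth is Poisson(`coverage`); every read is
#' drawn from a uniformly random pool member's allele and flipped to the other
#' parent's allele with probability `error_rate`.
#'
#' @param pool a `spore_pool`.
#' @param coverage mean sequencing depth per marker.
#' @param error_rate per-read probability of reporting the wrong parental
#'   allele.
#' @param seed optional integer seed.
#' @return An `allele_count_track` data.frame with columns `chrom`, `pos`,
#'   `ref_count` (reads supporting the reference parent P1), `alt_count`;
#'   attribute `ref_parent_label = "P1"`.
#' @export
simulate_bsa_counts <- function(pool, coverage = 50, error_rate = 0.002,
                                seed = NULL) {
  stopifnot(inherits(pool, "spore_pool"))
  if (coverage <= 0) stop("coverage must be positive")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must lie in [0, 1]")
  G <- pool$genotype
  if (nrow(G) == 0) stop("empty pool")
  M <- ncol(G)
  with_opt_seed(seed, {
    depth <- stats::rpois(M, coverage)
    total <- sum(depth)
    mk_of_read <- rep.int(seq_len(M), depth)
    sp <- sample.int(nrow(G), total, replace = TRUE)
    allele <- G[cbind(sp, mk_of_read)]
    flip <- stats::runif(total) < error_rate
    allele[flip] <- 3L - allele[flip]
    rc <- tabulate(mk_of_read[allele == 1L], nbins = M)
    ac <- tabulate(mk_of_read[allele == 2L], nbins = M)
  })
  allele_count_track(data.frame(chrom = pool$design$markers$chrom,
                                pos = pool$design$markers$pos,
                                ref_count = rc, alt_count = ac,
                                stringsAsFactors = FALSE),
                     ref_parent_label = "P1")
}

#' Simulate a cross x condition viability screen
#'
#' Emulates the screen design: `n_crosses` crosses each dissected into
#' `tetrads_per_instance` full tetrads (all spores viable on permissive
#' medium) and replica-tested on `n_conditions` conditions. Each instance
#' (cross x condition) is governed by an incompatibility model kind drawn
#' from `mix`; per-tetrad viable-spore counts are drawn from the model's
#' analytic tetrad-class distribution (`sampling = "binomial"`), or set to
#' their rounded expectation for noise-free round trips
#' (`sampling = "expected"`). A configurable number of instances receive a
#' non-viable parent to exercise the exclusion filter.
#'
#' @param n_crosses,n_conditions screen dimensions.
#' @param mix named numeric vector of proportions over model kinds
#'   (`none`, `two_locus_unlinked`, `k_locus`); must sum to 1.
#' @param tetrads_per_instance full tetrads scored per instance.
#' @param k number of lethal loci for the `k_locus` kind.
#' @param penetrance penetrance applied to non-`none` kinds.
#' @param parent_failure_rate fraction of instances with a non-viable parent.
#' @param n_parent_failures exact count of parent-failure instances
#'   (overrides the rate; default `round(rate * n_instances)`).
#' @param sampling `"binomial"` (multinomial tetrad-class sampling) or
#'   `"expected"` (deterministic expected counts).
#' @param seed optional integer seed.
#' @return List of class `screen_sim` with data.frames `instances`
#'   (per cross x condition: model kind, parent viability flags, spore
#'   counts), `spores` (per-spore records) and `parents`.
#' @export
simulate_screen <- function(n_crosses = 27, n_conditions = 20,
                            mix = c(none = 0.757, k_locus = 0.176,
                                    two_locus_unlinked = 0.067),
                            tetrads_per_instance = 20, k = 3, penetrance = 1,
                            parent_failure_rate = 0.1,
                            n_parent_failures = NULL,
                            sampling = c("binomial", "expected"),
                            seed = NULL) {
  sampling <- match.arg(sampling)
  if (abs(sum(mix) - 1) > 1e-8) stop("mix proportions must sum to 1")
  if (!all(names(mix) %in% c("none", "two_locus_unlinked", "k_locus")))
    stop("mix names must be among none, two_locus_unlinked, k_locus")
  n_inst <- n_crosses * n_conditions
  if (is.null(n_parent_failures))
    n_parent_failures <- round(parent_failure_rate * n_inst)
  dists <- lapply(names(mix), function(kind)
    expected_tetrad_distribution(.reference_model(kind, k = k,
                                                  penetrance = penetrance)))
  names(dists) <- names(mix)
  with_opt_seed(seed, {
    inst <- expand.grid(cross_id = sprintf("cross%02d", seq_len(n_crosses)),
                        condition = sprintf("cond%02d", seq_len(n_conditions)),
                        stringsAsFactors = FALSE)
    inst$model_kind <- sample(names(mix), n_inst, replace = TRUE, prob = mix)
    inst$p1_viable <- TRUE
    inst$p2_viable <- TRUE
    if (n_parent_failures > 0) {
      fail <- sample.int(n_inst, n_parent_failures)
      which_parent <- sample(c("p1_viable", "p2_viable"),
                             n_parent_failures, replace = TRUE)
      for (i in seq_along(fail)) inst[[which_parent[i]]][fail[i]] <- FALSE
    }
    n_spores <- 4L * tetrads_per_instance
    spore_rows <- vector("list", n_inst)
    viable_cond <- integer(n_inst)
    for (i in seq_len(n_inst)) {
      pr <- dists[[inst$model_kind[i]]]$probs
      vc <- if (sampling == "expected") {
        # deterministic: expected viable spores, dead spores spread evenly
        rep(4L, tetrads_per_instance) # placeholder, counts set below
      } else {
        sample(as.integer(names(pr)), tetrads_per_instance,
               replace = TRUE, prob = pr)
      }
      if (sampling == "expected") {
        total_viable <- round(sum(as.integer(names(pr)) * pr) *
                                tetrads_per_instance)
        dead <- n_spores - total_viable
        viab <- rep(TRUE, n_spores)
        if (dead > 0) viab[seq_len(dead)] <- FALSE
      } else {
        viab <- unlist(lapply(vc, function(v) {
          x <- rep(FALSE, 4L); x[sample.int(4L, v)] <- TRUE; x
        }), use.names = FALSE)
      }
      viable_cond[i] <- sum(viab)
      spore_rows[[i]] <- data.frame(
        cross_id = inst$cross_id[i], condition = inst$condition[i],
        tetrad_id = rep(sprintf("t%02d", seq_len(tetrads_per_instance)),
                        each = 4L),
        spore_id = rep(sprintf("s%d", 1:4), tetrads_per_instance),
        viable_permissive = 1L, viable_condition = as.integer(viab),
        stringsAsFactors = FALSE)
    }
    inst$spores_viable_permissive <- n_spores
    inst$spores_viable_condition <- viable_cond
    structure(list(instances = inst,
                   spores = do.call(rbind, spore_rows),
                   parents = inst[, c("cross_id", "condition",
                                      "p1_viable", "p2_viable")]),
              class = "screen_sim")
  })
}

# canonical model of a given kind on a generic genome (loci geometry is
# irrelevant for class distributions as long as 'unlinked' holds)
.reference_model <- function(kind, k = 3, penetrance = 1) {
  switch(kind,
    none = incompatibility_model("none"),
    two_locus_unlinked = incompatibility_model(
      "two_locus_unlinked",
      lethal_loci = data.frame(chrom = c("chr05", "chr10"),
                               pos = c(75500L, 75500L),
                               lethal_parent = c("P2", "P1")),
      penetrance = penetrance),
    k_locus = incompatibility_model(
      "k_locus",
      lethal_loci = data.frame(chrom = sprintf("chr%02d", seq_len(k)),
                               pos = 75500L,
                               lethal_parent = rep(c("P2", "P1"),
                                                   length.out = k)),
      penetrance = penetrance),
    stop("unknown model kind: ", kind))
}

#' Simulate an OD growth curve
#'
#' Logistic trajectory with an initial lag phase plus i.i.d. Gaussian read
#' noise, floored at 0 (blank-subtracted plate readings can dip below zero).
#'
#' @param rate maximum specific growth rate, per hour.
#' @param lag_h lag time in hours before growth starts.
#' @param carrying_capacity asymptotic OD.
#' @param noise_sd standard deviation of additive Gaussian noise on OD.
#' @param times sampling times in hours (increasing).
#' @param od0 inoculum OD at the end of the lag phase.
#' @param well_id,strain,plasmid labels carried on the curve.
#' @param seed optional integer seed.
#' @return An object of class `growth_curve`: list with `times`, `od` and the
#'   labels.
#' @export
simulate_growth_curve <- function(rate, lag_h = 0, carrying_capacity = 1.5,
                                  noise_sd = 0, times = seq(0, 24, by = 1 / 6),
                                  od0 = 0.05, well_id = "A1", strain = "strain",
                                  plasmid = "Ctrl", seed = NULL) {
  stopifnot(rate > 0, !is.unsorted(times, strictly = TRUE), od0 > 0,
            carrying_capacity > od0)
  K <- carrying_capacity
  t_eff <- pmax(times - lag_h, 0)
  od <- K * od0 / (od0 + (K - od0) * exp(-rate * t_eff))
  with_opt_seed(seed, {
    if (noise_sd > 0) od <- od + stats::rnorm(length(od), 0, noise_sd)
  })
  structure(list(times = times, od = pmax(od, 0), well_id = well_id,
                 strain = strain, plasmid = plasmid),
            class = "growth_curve")
}

#' Simulate a colony-size grid across conditions
#'
#' Generates colony sizes for each strain x plasmid x condition x replicate,
#' with a reference medium (default `"YPD"`) used downstream for pinning
#' normalization. The suppressor effect is planted as a percent change of the
#' SUP arm's normalized growth ratio relative to the Ctrl arm.
#'
#' @param strains character vector of strain names.
#' @param conditions character vector of test conditions (the reference medium
#'   is added automatically).
#' @param effects matrix (strains x conditions) of planted percent changes of
#'   the SUP normalized ratio vs Ctrl; 0 means no effect.
#' @param n_replicates replicates per arm.
#' @param base_size mean colony size (pixels) on the reference medium.
#' @param ratio_ctrl mean normalized growth ratio of the Ctrl arm on test
#'   conditions.
#' @param noise_cv coefficient of variation of multiplicative replicate noise.
#' @param reference name of the reference medium.
#' @param seed optional integer seed.
#' @return data.frame with columns `strain`, `plasmid` (`"SUP"`/`"Ctrl"`),
#'   `condition`, `replicate`, `colony_size`.
#' @export
simulate_colony_grid <- function(strains, conditions, effects = NULL,
                                 n_replicates = 12, base_size = 400,
                                 ratio_ctrl = 0.5, noise_cv = 0.05,
                                 reference = "YPD", seed = NULL) {
  if (is.null(effects))
    effects <- matrix(0, length(strains), length(conditions),
                      dimnames = list(strains, conditions))
  stopifnot(nrow(effects) == length(strains),
            ncol(effects) == length(conditions))
  grid <- expand.grid(strain = strains, plasmid = c("SUP", "Ctrl"),
                      condition = c(reference, conditions),
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  with_opt_seed(seed, {
    ratio <- ifelse(grid$condition == reference, 1, ratio_ctrl)
    is_sup <- grid$plasmid == "SUP" & grid$condition != reference
    eff <- effects[cbind(match(grid$strain, strains),
                         match(grid$condition, colnames(effects)))]
    eff[is.na(eff)] <- 0
    ratio[is_sup] <- ratio[is_sup] * (1 + eff[is_sup] / 100)
    noise <- exp(stats::rnorm(nrow(grid), 0, noise_cv))
    grid$colony_size <- base_size * ratio * noise
  })
  grid
}
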