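# Analytic tetrad-class expectations under incompatibility models and a
# classifier assigning observed viable-spore-count distributions to a model.

.CLASS_LEVELS <- c("4", "3", "2", "1", "0")

# distribution of the number of spores per tetrad carrying the full lethal
# genotype, for each model kind (penetrance applied downstream)
.lethal_count_distribution <- function(model) {
  kind <- model$kind
  if (kind == "none") return(c(`0` = 1))
  if (kind == "two_locus_unlinked")
    # overlap of two independent uniform 2-subsets of the 4 spores
    return(c(`0` = 1 / 6, `1` = 2 / 3, `2` = 1 / 6))
  if (kind == "k_locus")
    return(.enumerate_k_locus(nrow(model$lethal_loci)))
  if (kind == "two_locus_linked") {
    # no-interference four-chromatid model: crossover count Poisson(lambda),
    # Haldane r = (1 - exp(-lambda))/2; PD/TT/NPD mixture in closed form
    r <- model$r
    if (r >= 0.5) {
      pd <- 1 / 6; tt <- 2 / 3; npd <- 1 / 6
    } else {
      lam <- -log(1 - 2 * r)
      pd <- 1 / 6 + exp(-lam) / 2 + exp(-1.5 * lam) / 3
      npd <- 1 / 6 - exp(-lam) / 2 + exp(-1.5 * lam) / 3
      tt <- 2 / 3 - 2 / 3 * exp(-1.5 * lam)
    }
    # lethal combination parental (same lethal parent at both loci) =>
    # 2 lethal spores in PD tetrads; recombinant => 2 in NPD tetrads
    parental <- length(unique(model$lethal_loci$lethal_parent)) == 1L
    two <- if (parental) pd else npd
    zero <- if (parental) npd else pd
    out <- c(`0` = zero, `1` = tt, `2` = two)
    out <- pmax(out, 0)  # guard cancellation error near r = 0
    return(out / sum(out))
  }
  stop("unknown model kind: ", kind)
}

# exhaustive enumeration over the 6^k joint 2:2 partitions: the lethal spores
# are the intersection of the k lethal-allele spore pairs
.enumerate_k_locus <- function(k) {
  stopifnot(k >= 1)
  if (6^k > 2e6) stop("k too large for exhaustive enumeration: ", k)
  masks <- c(3L, 5L, 9L, 6L, 10L, 12L)  # bitmask of each 2-subset of 4 spores
  cur <- c(`0` = 0, `1` = 0, `2` = 0, `3` = 0, `4` = 0)
  inter <- 15L  # all four spores
  rec <- function(depth, inter) {
    if (depth == 0L) {
      n <- sum(bitwAnd(inter, c(1L, 2L, 4L, 8L)) > 0L)
      cur[as.character(n)] <<- cur[as.character(n)] + 1
      return(invisible())
    }
    for (m in masks) rec(depth - 1L, bitwAnd(inter, m))
  }
  rec(k, inter)
  out <- cur / 6^k
  out[out > 0 | names(out) %in% c("0", "1", "2")]
}

#' Expected tetrad viable-spore-class distribution under a model
#'
#' Returns the exact probability that a tetrad contains 4, 3, 2, 1 or 0
#' viable spores. For the recessive two-locus unlinked incompatibility with
#' full penetrance this is the classic 1:4:1 ratio over \{4, 3, 2\}: the
#' lethal allelic combination follows Mendelian segregation and the two
#' independent 2:2 partitions overlap in 0, 1 or 2 spores with probabilities
#' 1/6, 2/3 and 1/6. Linked loci use the no-interference tetrad model
#' (PD/NPD/TT as a function of the recombination fraction r); `k_locus`
#' models are solved by exhaustive enumeration of the `6^k` joint partitions.
#' Penetrance below 1 thins each lethal spore independently (Bernoulli).
#'
#' @param model an `incompatibility_model`, or a kind string accepted by
#'   `incompatibility_model()` for loci-free kinds (`"none"`,
#'   `"two_locus_unlinked"`).
#' @return Object of class `tetrad_class_distribution`: named numeric vector
#'   `probs` over viable counts `"4" ... "0"` summing to 1, plus the model.
#' @export
expected_tetrad_distribution <- function(model) {
  if (is.character(model)) model <- .reference_model(model)
  stopifnot(inherits(model, "incompatibility_model"))
  dcount <- .lethal_count_distribution(model)
  p <- model$penetrance
  probs <- stats::setNames(numeric(5), .CLASS_LEVELS)
  for (d in as.integer(names(dcount))) {
    # d lethal-genotype spores; each dies independently with prob p
    dead <- 0:d
    probs[as.character(4 - dead)] <- probs[as.character(4 - dead)] +
      dcount[[as.character(d)]] * stats::dbinom(dead, d, p)
  }
  structure(list(probs = probs, model = model),
            class = "tetrad_class_distribution")
}

#' @export
print.tetrad_class_distribution <- function(x, ...) {
  cat("tetrad class distribution (", x$model$kind, "):\n", sep = "")
  print(round(x$probs, 6))
  invisible(x)
}

#' Expected fraction of inviable spores under a model
#'
#' The mean spore loss, `sum_c (4 - c) P(c) / 4` over the tetrad class
#' distribution. For `k` unlinked lethal loci with penetrance `p` this equals
#' `p * 2^-k`; the worked two-locus case gives exactly one-fourth.
#'
#' @inheritParams expected_tetrad_distribution
#' @return Probability that a random spore is inviable on the restrictive
#'   condition.
#' @export
expected_spore_inviability <- function(model) {
  d <- expected_tetrad_distribution(model)
  sum((4 - as.integer(names(d$probs))) * d$probs) / 4
}

# candidate specification -> list(kind, label, n_params, dist(s))
.candidate_entry <- function(cand, r_grid) {
  if (inherits(cand, "incompatibility_model")) {
    if (cand$kind == "two_locus_linked") {
      dists <- lapply(r_grid, function(r) {
        m <- cand; m$r <- r; expected_tetrad_distribution(m)$probs
      })
      return(list(kind = "two_locus_linked", label = "two_locus_linked",
                  n_params = 1L, dists = dists, r_grid = r_grid))
    }
    return(list(kind = cand$kind, label = cand$kind, n_params = 0L,
                dists = list(expected_tetrad_distribution(cand)$probs)))
  }
  if (is.character(cand)) {
    if (cand == "complex")
      return(list(kind = "complex", label = "complex", n_params = 4L))
    if (cand == "two_locus_linked") {
      base <- incompatibility_model(
        "two_locus_linked",
        lethal_loci = data.frame(chrom = "chr01", pos = c(1000L, 50000L),
                                 lethal_parent = c("P2", "P1")),
        r = 0.25)
      return(.candidate_entry(base, r_grid))
    }
    if (cand %in% c("none", "two_locus_unlinked"))
      return(.candidate_entry(.reference_model(cand), r_grid))
    km <- regmatches(cand, regexec("^k_locus[_(]?([0-9]+)\\)?$", cand))[[1]]
    if (length(km) == 2)
      return(list(kind = "k_locus", label = cand, n_params = 0L,
                  dists = list(expected_tetrad_distribution(
                    .reference_model("k_locus", k = as.integer(km[2])))$probs)))
    stop("unknown candidate model: ", cand)
  }
  stop("candidates must be kind strings or incompatibility_model objects")
}

.multinom_loglik <- function(obs, probs) {
  keep <- obs > 0
  if (any(probs[keep] == 0)) return(-Inf)
  stats::dmultinom(obs, prob = probs, log = TRUE)
}

# exact multinomial goodness-of-fit p-value: total probability of outcomes no
# more likely than the observed one
.multinom_gof_pvalue <- function(obs, probs, n_mc = 1e5, mc_seed = 0L) {
  n <- sum(obs)
  k <- length(probs)
  lp_obs <- stats::dmultinom(obs, prob = probs, log = TRUE)
  if (n <= 30) {
    # full enumeration of all compositions of n into k categories
    comp <- .compositions(n, k)
    lp <- apply(comp, 1, function(x) stats::dmultinom(x, prob = probs,
                                                      log = TRUE))
    return(sum(exp(lp[lp <= lp_obs + 1e-9])))
  }
  if (n <= 200) {
    withr::with_seed(mc_seed, {
      draws <- stats::rmultinom(n_mc, n, probs)
      lp <- lfactorial(n) - colSums(lfactorial(draws)) +
        colSums(draws * ifelse(probs > 0, log(pmax(probs, 1e-300)), 0))
      lp[colSums(draws[probs == 0, , drop = FALSE]) > 0] <- -Inf
      (sum(lp <= lp_obs + 1e-9) + 1) / (n_mc + 1)
    })
  } else {
    keep <- probs > 0
    if (any(obs[!keep] > 0)) return(0)
    suppressWarnings(stats::chisq.test(obs[keep], p = probs[keep]))$p.value
  }
}

# all compositions of n into k non-negative parts
.compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- vector("list", n + 1)
  for (first in 0:n) {
    rest <- .compositions(n - first, k - 1)
    out[[first + 1]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Classify an observed tetrad viable-count distribution
#'
#' Fits each candidate incompatibility model to observed tetrad counts by
#' multinomial likelihood over the viable-spore classes \{4,3,2,1,0\}
#' (the linked model profiles its recombination fraction over a grid), and
#' selects the best model by BIC. Parameter counts: `none`, unlinked and
#' `k_locus` models are parameter-free, the linked model estimates r (1), and
#' `complex` is the saturated multinomial (4). BIC ties break toward the
#' simpler model, then lexicographic kind name, so the call is invariant to
#' candidate order. The goodness-of-fit p-value of the selected model comes
#' from an exact multinomial test (full enumeration for up to 30 tetrads,
#' Monte Carlo with a fixed internal seed up to 200, chi-square beyond).
#'
#' @param observed named vector or table mapping viable count (0-4) to number
#'   of tetrads, e.g. `c("4" = 3, "3" = 14, "2" = 3)`.
#' @param candidate_models list of kind strings (`"none"`,
#'   `"two_locus_unlinked"`, `"two_locus_linked"`, `"k_locus_3"`, `"complex"`)
#'   and/or `incompatibility_model` objects.
#' @param r_grid grid of recombination fractions profiled for the linked
#'   model.
#' @param compute_fit_pvalue set FALSE to skip the goodness-of-fit test
#'   (useful in large simulation studies).
#' @return Object of class `segregation_call`: `best_model` label,
#'   `r_hat` (linked model only), `log_likelihoods`, `bic`, `fit_pvalue`.
#' @export
classify_segregation <- function(observed,
                                 candidate_models = list(
                                   "none", "two_locus_unlinked", "complex"),
                                 r_grid = seq(0, 0.5, by = 0.025),
                                 compute_fit_pvalue = TRUE) {
  if (length(candidate_models) == 0) stop("empty candidate list")
  obs <- stats::setNames(numeric(5), .CLASS_LEVELS)
  cin <- unlist(observed)
  if (is.null(names(cin)) || !all(names(cin) %in% .CLASS_LEVELS))
    stop("observed must be named by viable counts 4..0")
  obs[names(cin)] <- cin
  n <- sum(obs)
  if (n < 1) stop("need at least one tetrad")
  entries <- lapply(candidate_models, .candidate_entry, r_grid = r_grid)
  labels <- vapply(entries, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate candidate models")
  ll <- bic <- stats::setNames(numeric(length(entries)), labels)
  rhat <- stats::setNames(rep(NA_real_, length(entries)), labels)
  best_probs <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (e$kind == "complex") {
      probs <- obs / n
      ll[i] <- .multinom_loglik(obs, probs)
    } else if (e$kind == "two_locus_linked") {
      lls <- vapply(e$dists, function(p) .multinom_loglik(obs, p), 0)
      j <- which.max(lls)
      ll[i] <- lls[j]
      rhat[i] <- e$r_grid[j]
      probs <- e$dists[[j]]
    } else {
      probs <- e$dists[[1]]
      ll[i] <- .multinom_loglik(obs, probs)
    }
    best_probs[[i]] <- probs
    bic[i] <- -2 * ll[i] + e$n_params * log(n)
  }
  n_params <- vapply(entries, `[[`, 0L, "n_params")
  ord <- order(bic, n_params, labels)
  best <- ord[1]
  fit_p <- NA_real_
  if (compute_fit_pvalue) {
    fit_p <- if (labels[best] == "complex") 1
             else .multinom_gof_pvalue(obs, best_probs[[best]])
  }
  structure(list(best_model = labels[best], r_hat = rhat[[best]],
                 log_likelihoods = ll, bic = bic, fit_pvalue = fit_p,
                 observed = obs, n = n),
            class = "segregation_call")
}

#' @export
print.segregation_call <- function(x, ...) {
  cat("segregation_call:", x$best_model,
      if (!is.na(x$r_hat)) sprintf("(r_hat = %.3f)", x$r_hat),
      sprintf("| n = %d tetrads, fit p = %s\n", x$n,
              format(x$fit_pvalue, digits = 3)))
  invisible(x)
}
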