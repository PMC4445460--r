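# Offspring-viability screen: viability ratios, parental-viability exclusion
# and severity classification across crosses x conditions.

#' Offspring viability of screen instances
#'
#' Viability is the ratio between the number of segregants viable on the test
#' condition and the number viable on permissive rich medium.
#'
#' @param instances data.frame with columns `spores_viable_permissive` and
#'   `spores_viable_condition` (one row per cross x condition instance).
#' @return Numeric vector of viabilities in [0, 1].
#' @export
compute_viability <- function(instances) {
  instances <- as.data.frame(instances)
  perm <- instances$spores_viable_permissive
  cond <- instances$spores_viable_condition
  if (any(perm < 1))
    stop("viability undefined: instance with zero permissive-viable spores")
  if (any(cond < 0) || any(cond > perm))
    stop("condition-viable spores must lie in [0, permissive-viable]")
  cond / perm
}

#' Split instances on parental viability
#'
#' Instances where either parental strain is non-viable on the tested
#' condition cannot be interpreted as offspring incompatibility and are
#' excluded.
#'
#' @param instances data.frame with logical columns `p1_viable`, `p2_viable`.
#' @return List with data.frames `kept` and `excluded` (an exhaustive
#'   partition of the input rows).
#' @export
filter_parental <- function(instances) {
  instances <- as.data.frame(instances)
  stopifnot(all(c("p1_viable", "p2_viable") %in% names(instances)))
  if (anyNA(instances$p1_viable) || anyNA(instances$p2_viable))
    stop("parent viability flags must be present for every instance")
  bad <- !(instances$p1_viable & instances$p2_viable)
  list(kept = instances[!bad, , drop = FALSE],
       excluded = instances[bad, , drop = FALSE])
}

#' Classify instance severity from offspring viability
#'
#' Loss is `1 - viability`. An instance is `severe` when at least
#' `severe_threshold` of the segregants are non-viable (closed boundary:
#' loss exactly at the threshold is severe), `potential_epistasis` when the
#' loss reaches `epistasis_threshold` but not the severe cut, else `none`.
#'
#' @param viability numeric vector in [0, 1].
#' @param epistasis_threshold minimum loss flagged as potential epistasis.
#' @param severe_threshold minimum loss flagged as moderate-to-severe
#'   incompatibility.
#' @return Factor with levels `none`, `potential_epistasis`, `severe`.
#' @export
classify_instance <- function(viability, epistasis_threshold = 0.01,
                              severe_threshold = 0.20) {
  if (epistasis_threshold < 0 || severe_threshold > 1 ||
      epistasis_threshold > severe_threshold)
    stop("thresholds must satisfy 0 <= epistasis <= severe <= 1")
  if (any(viability < 0 | viability > 1)) stop("viability must lie in [0, 1]")
  loss <- 1 - viability
  eps <- 1e-9  # keep a loss of exactly 20% severe despite rounding
  out <- ifelse(loss >= severe_threshold - eps, "severe",
                ifelse(loss >= epistasis_threshold - eps,
                       "potential_epistasis", "none"))
  factor(out, levels = c("none", "potential_epistasis", "severe"))
}

#' Summarize a viability screen
#'
#' Applies the parental-viability exclusion, computes per-instance offspring
#' viability and severity categories, aggregates counts, and lays the screen
#' out as a crosses x conditions matrix with excluded cells flagged.
#'
#' @param instances data.frame with columns `cross_id`, `condition`,
#'   `p1_viable`, `p2_viable`, `spores_viable_permissive`,
#'   `spores_viable_condition`.
#' @param epistasis_threshold,severe_threshold passed to
#'   [classify_instance()].
#' @param binomial_test if TRUE, add an exact binomial test of each kept
#'   instance's viability against 1 (alpha 0.05) as column `p_binom`.
#' @return Object of class `screen_summary`: counts `n_total`, `n_excluded`,
#'   `n_epistasis` (potential or severe), `n_severe`; `instances` data.frame
#'   with `viability` and `category` (`excluded` instances carry category
#'   `"excluded"`); `matrix` of viabilities (crosses x conditions, excluded
#'   cells NA) and logical `excluded_matrix`.
#' @export
summarize_screen <- function(instances, epistasis_threshold = 0.01,
                             severe_threshold = 0.20,
                             binomial_test = FALSE) {
  instances <- as.data.frame(instances)
  stopifnot(all(c("cross_id", "condition") %in% names(instances)))
  if (anyDuplicated(instances[, c("cross_id", "condition")]))
    stop("duplicate (cross_id, condition) pairs")
  parts <- filter_parental(instances)
  kept <- parts$kept
  kept$viability <- compute_viability(kept)
  kept$category <- as.character(
    classify_instance(kept$viability, epistasis_threshold, severe_threshold))
  if (binomial_test && nrow(kept)) {
    kept$p_binom <- mapply(function(x, n)
      stats::binom.test(x, n, p = 1, alternative = "less")$p.value,
      kept$spores_viable_condition, kept$spores_viable_permissive)
  }
  excl <- parts$excluded
  if (nrow(excl)) {
    excl$viability <- NA_real_
    excl$category <- "excluded"
    if (binomial_test) excl$p_binom <- NA_real_
  }
  all_inst <- rbind(kept, if (nrow(excl)) excl)
  all_inst$category <- factor(all_inst$category,
                              levels = c("excluded", "none",
                                         "potential_epistasis", "severe"))
  crosses <- unique(instances$cross_id)
  conds <- unique(instances$condition)
  viab_mat <- matrix(NA_real_, length(crosses), length(conds),
                     dimnames = list(crosses, conds))
  excl_mat <- matrix(FALSE, length(crosses), length(conds),
                     dimnames = list(crosses, conds))
  idx <- cbind(match(all_inst$cross_id, crosses),
               match(all_inst$condition, conds))
  viab_mat[idx] <- all_inst$viability
  excl_mat[idx] <- all_inst$category == "excluded"
  structure(list(
    n_total = nrow(instances), n_excluded = nrow(excl),
    n_epistasis = sum(kept$category %in% c("potential_epistasis", "severe")),
    n_severe = sum(kept$category == "severe"),
    instances = all_inst, matrix = viab_mat, excluded_matrix = excl_mat,
    epistasis_threshold = epistasis_threshold,
    severe_threshold = severe_threshold),
    class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  kept <- x$n_total - x$n_excluded
  cat(sprintf(paste0(
    "screen_summary: %d instances, %d excluded (non-viable parent)\n",
    "  potential epistasis: %d / %d (%.1f%%)\n",
    "  moderate-to-severe (loss >= %.0f%%): %d / %d (%.1f%%)\n"),
    x$n_total, x$n_excluded, x$n_epistasis, kept,
    100 * x$n_epistasis / max(kept, 1), 100 * x$severe_threshold,
    x$n_severe, kept, 100 * x$n_severe / max(kept, 1)))
  invisible(x)
}
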