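# Fitness quantification: exponential growth-rate fitting from microculture
# OD curves, percent growth variation, colony-size normalization and
# variance comparisons.

#' Maximum specific growth rate from an OD curve
#'
#' Exponential-phase fit: the OD series is floored at a small positive
#' constant, log-transformed, lightly smoothed with a centred rolling mean
#' (slope-preserving for a pure exponential), and the slope of an ordinary
#' least-squares line is computed over every sliding window of `window`
#' consecutive points; the maximum slope, per hour, is the growth rate.
#' Flat or all-zero curves return rate 0 with a warning rather than an
#' error.
#'
#' @param curve a `growth_curve` (from [simulate_growth_curve()]) or any
#'   list/data.frame with numeric elements `times` (hours) and `od`.
#' @param window number of consecutive points per regression window.
#' @param od_floor OD values are clipped below at this constant before the
#'   log transform (blank-subtracted readings can be <= 0).
#' @param smooth width (odd integer, in points) of the centred rolling mean
#'   applied to log-OD; 1 disables smoothing.
#' @param method `"window"` for the sliding log-slope fit; `"logistic"` for
#'   a full parametric logistic-with-lag fit on the OD scale
#'   (Levenberg-Marquardt), which gives markedly more precise per-curve rates
#'   when read noise is large relative to the inoculum OD.
#' @return Growth rate in 1/h (>= 0).
#' @export
fit_growth_rate <- function(curve, window = 8, od_floor = 1e-4, smooth = 5,
                            method = c("window", "logistic")) {
  method <- match.arg(method)
  times <- curve$times %||% curve$time_h
  od <- curve$od
  stopifnot(length(times) == length(od), length(od) >= window, window >= 3)
  if (method == "logistic")
    return(.fit_logistic_rate(times, od, od_floor))
  y <- log(pmax(od, od_floor))
  if (smooth %% 2 == 0) smooth <- smooth - 1
  if (smooth > 1 && length(y) >= smooth + window) {
    y <- stats::filter(y, rep(1 / smooth, smooth), sides = 2)
    keep <- !is.na(y)
    y <- as.numeric(y[keep])
    times <- times[keep]
  }
  if (length(y) < window || diff(range(y)) < 1e-12) {
    warning("flat or too-short curve: returning growth rate 0")
    return(0)
  }
  n <- length(y)
  best <- -Inf
  for (i in seq_len(n - window + 1L)) {
    tx <- times[i:(i + window - 1L)]
    ty <- y[i:(i + window - 1L)]
    slope <- stats::cov(tx, ty) / stats::var(tx)
    if (slope > best) best <- slope
  }
  max(best, 0)
}

# logistic-with-lag trajectory fitted on the OD scale; returns the maximum
# specific rate r (1/h), 0 for flat curves
.fit_logistic_rate <- function(times, od, od_floor = 1e-4) {
  od <- pmax(od, od_floor)
  if (diff(range(od)) < 1e-9) {
    warning("flat curve: returning growth rate 0")
    return(0)
  }
  K0 <- max(od)
  od0_0 <- max(stats::median(utils::head(od, 5)), od_floor)
  # crude rate start from the central log-slope
  mid <- which.min(abs(od - (K0 + od0_0) / 4))
  i0 <- max(1, mid - 3); i1 <- min(length(od), mid + 3)
  r0 <- max((log(od[i1]) - log(od[i0])) / (times[i1] - times[i0]), 0.05)
  fit <- try(minpack.lm::nlsLM(
    od ~ K * n0 / (n0 + (K - n0) * exp(-r * pmax(t - lag, 0))),
    data = list(od = od, t = times),
    start = list(K = K0, n0 = od0_0, r = r0, lag = 0),
    lower = c(K = od_floor, n0 = od_floor, r = 1e-6, lag = 0),
    upper = c(K = 100 * K0, n0 = K0, r = 20, lag = max(times)),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    warning("logistic fit failed; falling back to sliding-window estimate")
    return(fit_growth_rate(list(times = times, od = od), method = "window"))
  }
  unname(stats::coef(fit)["r"])
}

# two-sample t-test robust to zero-variance degenerate input
.safe_t_pvalue <- function(a, b) {
  if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b)$p.value
}

#' Percent growth variation between suppressor and control arms
#'
#' `percent_variation = 100 * (mean(sup) - mean(ctrl)) / mean(ctrl)`, with a
#' two-sided two-sample t-test on the rates.
#'
#' @param rates_sup,rates_ctrl numeric vectors of replicate growth rates
#'   (each of length >= 2).
#' @return List of class `fitness_comparison`: `percent_variation`, `p_t`,
#'   `n` (replicates per arm), `mean_sup`, `mean_ctrl`.
#' @export
growth_variation <- function(rates_sup, rates_ctrl) {
  stopifnot(length(rates_sup) >= 2, length(rates_ctrl) >= 2)
  m_ctrl <- mean(rates_ctrl)
  if (abs(m_ctrl) < 1e-12) stop("undefined variation: control mean is zero")
  structure(list(
    percent_variation = 100 * (mean(rates_sup) - m_ctrl) / m_ctrl,
    p_t = .safe_t_pvalue(rates_sup, rates_ctrl),
    n = c(sup = length(rates_sup), ctrl = length(rates_ctrl)),
    mean_sup = mean(rates_sup), mean_ctrl = m_ctrl),
    class = "fitness_comparison")
}

#' @export
print.fitness_comparison <- function(x, ...) {
  cat(sprintf("fitness_comparison: %+.1f%% (t-test p = %s)\n",
              x$percent_variation, format(x$p_t, digits = 3)))
  invisible(x)
}

#' Normalized growth ratio of a colony
#'
#' Colony size on a test condition divided by the same colony's size on the
#' reference rich medium, cancelling pinning-density and baseline-growth
#' effects. A non-positive reference size yields NA (flagged missing; the
#' record is excluded downstream).
#'
#' @param size_condition colony size on the test condition.
#' @param size_reference_medium colony size on the reference medium.
#' @return Numeric vector of ratios (NA where the reference is unusable).
#' @export
normalized_growth_ratio <- function(size_condition, size_reference_medium) {
  ifelse(is.na(size_reference_medium) | size_reference_medium <= 0,
         NA_real_, size_condition / size_reference_medium)
}

#' Suppressor fitness effect across strains and conditions
#'
#' For each strain x condition, computes per-replicate normalized growth
#' ratios (colony size over the matched reference-medium size of the same
#' strain, plasmid and replicate), then the percent variation of the
#' suppressor (SUP) arm's mean ratio versus the control (Ctrl) arm, a
#' two-sided t-test on the replicate ratios, and a display flag for
#' magnitude-significant variation (|variation| >= `flag_threshold` percent;
#' closed boundary).
#'
#' @param colonies data.frame with columns `strain`, `plasmid`
#'   (`"SUP"`/`"Ctrl"`), `condition`, `replicate`, `colony_size`.
#' @param reference name of the reference medium condition.
#' @param flag_threshold percent-variation magnitude flagged as significant.
#' @return data.frame of class `suppressor_effects`: one row per strain x
#'   test condition with `percent_variation`, `p_t`, `n_sup`, `n_ctrl`,
#'   `flagged`. Combinations missing an arm (or with < 2 usable replicates
#'   in either) are skipped with a message.
#' @export
suppressor_effect <- function(colonies, reference = "YPD",
                              flag_threshold = 10) {
  colonies <- as.data.frame(colonies, stringsAsFactors = FALSE)
  need <- c("strain", "plasmid", "condition", "replicate", "colony_size")
  stopifnot(all(need %in% names(colonies)))
  if (!any(colonies$condition == reference))
    stop("no measurements on the reference medium '", reference, "'")
  ref <- colonies[colonies$condition == reference, ]
  key <- function(d) paste(d$strain, d$plasmid, d$replicate, sep = "\r")
  ref_size <- stats::setNames(ref$colony_size, key(ref))
  test <- colonies[colonies$condition != reference, ]
  test$ratio <- normalized_growth_ratio(test$colony_size,
                                        ref_size[key(test)])
  out <- list()
  for (s in unique(test$strain)) for (cond in unique(test$condition)) {
    d <- test[test$strain == s & test$condition == cond & !is.na(test$ratio), ]
    sup <- d$ratio[d$plasmid == "SUP"]
    ctrl <- d$ratio[d$plasmid == "Ctrl"]
    if (length(sup) < 2 || length(ctrl) < 2) {
      message("skipping ", s, " / ", cond, ": missing or underpowered arm")
      next
    }
    pv <- 100 * (mean(sup) - mean(ctrl)) / mean(ctrl)
    out[[length(out) + 1]] <- data.frame(
      strain = s, condition = cond, percent_variation = pv,
      p_t = .safe_t_pvalue(sup, ctrl),
      n_sup = length(sup), n_ctrl = length(ctrl),
      flagged = abs(pv) >= flag_threshold, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(strain = character(), condition = character(),
               percent_variation = numeric(), p_t = numeric(),
               n_sup = integer(), n_ctrl = integer(), flagged = logical(),
               stringsAsFactors = FALSE)
  structure(res, class = c("suppressor_effects", "data.frame"))
}

#' Compare phenotypic variance between suppressor and control arms
#'
#' Two-sided F-test on the variance ratio plus the Brown-Forsythe version of
#' Levene's test (absolute deviations from the group medians). When both
#' arms have (numerically) zero variance, both p-values are 1 by convention.
#'
#' @param sup_values,ctrl_values numeric vectors (each of length >= 3).
#' @return List with elements `p_F` and `p_levene`.
#' @export
variance_comparison <- function(sup_values, ctrl_values) {
  stopifnot(length(sup_values) >= 3, length(ctrl_values) >= 3)
  if (stats::var(sup_values) < 1e-24 && stats::var(ctrl_values) < 1e-24)
    return(list(p_F = 1, p_levene = 1))
  p_f <- stats::var.test(sup_values, ctrl_values)$p.value
  grp <- factor(rep(c("SUP", "Ctrl"),
                    c(length(sup_values), length(ctrl_values))))
  lev <- car::leveneTest(c(sup_values, ctrl_values), grp, center = median)
  list(p_F = p_f, p_levene = lev[["Pr(>F)"]][1])
}
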