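#' Configuration of the synthetic measurement generator
#'
#' Describes the statistical structure emulating the study's replicate-level
#' experiments: ICP-MS uptake measurements at the 10^7 molecules-per-cell
#' scale with multiplicative noise and a small no-pulse baseline, and
#' clonogenic colony counts from ~100 cells plated per well in triplicate
#' wells, normalized by the control plating efficiency.
#'
#' @param protocols preset names covered by the synthetic experiment.
#' @param concentrations_uM extracellular cisplatin concentrations (uM).
#' @param n_replicates independent replicate measurements per condition.
#' @param uptake_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise (mean 1).
#' @param baseline_slope no-pulse uptake in molecules per cell per uM of
#'   extracellular cisplatin (passive/transporter route).
#' @param distortion per-protocol multiplier applied to the model truth
#'   before noise, emulating systematic model/measurement disagreement;
#'   either a single number or a named vector keyed by protocol (default 1).
#' @param kill_rate per-molecule log-kill rate `k` of the single-hit survival
#'   link `S = exp(-k * molecules)` used to generate colony counts.
#' @param plating_efficiency control plating efficiency `pe0` in (0, 1].
#' @param cells_plated cells seeded per well.
#' @param wells wells per condition.
#' @param seed integer RNG seed; generation is fully deterministic given the
#'   configuration.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(protocols = preset_names(),
                             concentrations_uM = c(0, 10, 30, 50),
                             n_replicates = 4,
                             uptake_cv = 0.2,
                             baseline_slope = 1e5,
                             distortion = 1,
                             kill_rate = 1e-7,
                             plating_efficiency = 0.8,
                             cells_plated = 100,
                             wells = 3,
                             seed = 1) {
  stopifnot(length(protocols) >= 1,
            n_replicates >= 2, n_replicates == round(n_replicates),
            uptake_cv > 0, baseline_slope >= 0, kill_rate >= 0,
            plating_efficiency > 0, plating_efficiency <= 1,
            cells_plated >= 1, wells >= 1)
  if (is.null(names(distortion))) {
    distortion <- stats::setNames(rep(distortion[1], length(protocols)), protocols)
  } else {
    full <- stats::setNames(rep(1, length(protocols)), protocols)
    full[names(distortion)] <- distortion
    distortion <- full
  }
  if (any(distortion <= 0)) stop("distortion factors must be positive")
  structure(list(protocols = protocols,
                 concentrations_uM = concentrations_uM,
                 n_replicates = as.integer(n_replicates),
                 uptake_cv = uptake_cv, baseline_slope = baseline_slope,
                 distortion = distortion, kill_rate = kill_rate,
                 plating_efficiency = plating_efficiency,
                 cells_plated = as.integer(cells_plated),
                 wells = as.integer(wells),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# lognormal with arithmetic mean 1 and coefficient of variation cv
.rlnorm_mean1 <- function(n, cv) {
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate replicate-level synthetic uptake measurements
#'
#' Each treated replicate is
#' `distortion * truth * lognormal(mean 1, cv) + baseline_slope * concentration`,
#' where `truth` is the model-predicted molecule count for the condition.
#' No-pulse control records (protocol label `"control"`) carry the
#' concentration-proportional baseline with the same multiplicative noise.
#' Generation is deterministic under a fixed configuration seed.
#'
#' @param cfg a `synthetic_config`.
#' @param model_truth prediction grid from [run_protocol_grid()] covering
#'   every (protocol, concentration) of `cfg`.
#' @return Replicate-level measurement table in the [read_measurements()]
#'   dialect with quantity `molecules_per_cell`.
#' @export
generate_uptake_measurements <- function(cfg, model_truth) {
  stopifnot(inherits(cfg, "synthetic_config"))
  stopifnot(all(c("protocol", "X_e_uM", "molecules") %in% names(model_truth)))
  grid <- expand.grid(protocol = cfg$protocols,
                      concentration_uM = cfg$concentrations_uM,
                      stringsAsFactors = FALSE)
  truth_key <- paste(model_truth$protocol, model_truth$X_e_uM)
  idx <- match(paste(grid$protocol, grid$concentration_uM), truth_key)
  if (anyNA(idx)) {
    miss <- grid[is.na(idx), ]
    stop("model_truth is missing condition(s): ",
         paste(sprintf("%s @ %g uM", miss$protocol, miss$concentration_uM),
               collapse = "; "))
  }
  grid$truth <- model_truth$molecules[idx]

  set.seed(cfg$seed)
  nrep <- cfg$n_replicates
  treated <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    noise <- .rlnorm_mean1(nrep, cfg$uptake_cv)
    data.frame(protocol = grid$protocol[i],
               concentration_uM = grid$concentration_uM[i],
               replicate = seq_len(nrep),
               quantity = "molecules_per_cell",
               value = cfg$distortion[[grid$protocol[i]]] * grid$truth[i] * noise +
                 cfg$baseline_slope * grid$concentration_uM[i])
  }))
  control <- do.call(rbind, lapply(cfg$concentrations_uM, function(conc) {
    noise <- .rlnorm_mean1(nrep, cfg$uptake_cv)
    data.frame(protocol = "control", concentration_uM = conc,
               replicate = seq_len(nrep),
               quantity = "molecules_per_cell",
               value = cfg$baseline_slope * conc * noise)
  }))
  out <- rbind(treated, control)
  rownames(out) <- NULL
  out
}

#' Generate synthetic clonogenic colony counts
#'
#' True survival for each condition follows the single-hit exponential link
#' `S = exp(-kill_rate * molecules)`; the colony count of each well is a
#' binomial draw with `cells_plated` trials and success probability
#' `plating_efficiency * S`. Control wells (no pulses, no drug) use the
#' plating efficiency alone. Deterministic under the configuration seed.
#'
#' @param cfg a `synthetic_config`.
#' @param molecules_table data.frame with `protocol`, `concentration_uM` and
#'   mean `molecules` per condition (model truth or aggregated measurements).
#' @return data.frame with columns `protocol`, `concentration_uM`, `well`,
#'   `cells_plated`, `colonies`, including control wells.
#' @export
generate_clonogenic_counts <- function(cfg, molecules_table) {
  stopifnot(inherits(cfg, "synthetic_config"))
  stopifnot(all(c("protocol", "concentration_uM", "molecules") %in%
                  names(molecules_table)))
  set.seed(cfg$seed)
  rows <- rbind(
    data.frame(protocol = "control", concentration_uM = 0,
               survival = 1),
    data.frame(protocol = molecules_table$protocol,
               concentration_uM = molecules_table$concentration_uM,
               survival = exp(-cfg$kill_rate * molecules_table$molecules)))
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    pr <- cfg$plating_efficiency * rows$survival[i]
    data.frame(protocol = rows$protocol[i],
               concentration_uM = rows$concentration_uM[i],
               well = seq_len(cfg$wells),
               cells_plated = cfg$cells_plated,
               colonies = stats::rbinom(cfg$wells, cfg$cells_plated, pr))
  }))
  rownames(out) <- NULL
  out
}

#' Survival fractions from colony counts
#'
#' The plating efficiency of each well is colonies over cells plated; per
#' condition these are averaged, and survival is the condition's mean plating
#' efficiency normalized to that of the control condition.
#'
#' @param counts colony-count table from [generate_clonogenic_counts()] (or
#'   real data in the same layout).
#' @param control protocol label of the control condition.
#' @return data.frame with `protocol`, `concentration_uM`,
#'   `survival_fraction`, `n_wells` for every non-control condition.
#' @export
clonogenic_survival <- function(counts, control = "control") {
  need <- c("protocol", "concentration_uM", "well", "cells_plated", "colonies")
  stopifnot(all(need %in% names(counts)))
  pe <- counts$colonies / counts$cells_plated
  key <- interaction(counts$protocol, counts$concentration_uM, drop = TRUE)
  grp <- data.frame(protocol = tapply(counts$protocol, key, `[`, 1),
                    concentration_uM = as.numeric(tapply(counts$concentration_uM, key, `[`, 1)),
                    pe = as.numeric(tapply(pe, key, mean)),
                    n_wells = as.integer(tapply(pe, key, length)),
                    row.names = NULL)
  ctl <- grp[grp$protocol == control, , drop = FALSE]
  if (nrow(ctl) == 0) stop("no control wells in colony-count table")
  pe0 <- mean(ctl$pe)
  if (pe0 <= 0) stop("control plating efficiency is zero; cannot normalize")
  trt <- grp[grp$protocol != control, , drop = FALSE]
  res <- data.frame(protocol = trt$protocol,
                    concentration_uM = trt$concentration_uM,
                    survival_fraction = trt$pe / pe0,
                    n_wells = trt$n_wells)
  res <- res[order(res$protocol, res$concentration_uM), ]
  rownames(res) <- NULL
  res
}

#' Fit the single-hit kill rate from paired survival and uptake
#'
#' Least-squares fit of `-log(survival)` against molecules per cell through
#' the origin, i.e. the exponent of `S = exp(-k * molecules)`. Only rows with
#' survival in (0, 1] and positive molecules enter the fit; a bootstrap over
#' the paired rows yields a percentile confidence interval.
#'
#' @param paired data.frame with columns `molecules` and `survival_fraction`
#'   (see [survival_vs_molecules()]).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level of the percentile interval.
#' @return List of class `kill_rate_fit`: `k` (per molecule), `ci`
#'   (two-sided percentile interval), `n` (points used).
#' @export
fit_kill_rate <- function(paired, n_boot = 200, conf = 0.95) {
  stopifnot(all(c("molecules", "survival_fraction") %in% names(paired)))
  use <- paired$survival_fraction > 0 & paired$survival_fraction <= 1 &
    paired$molecules > 0
  d <- paired[use, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 paired points with survival in (0, 1]")
  if (all(d$survival_fraction == 1)) {
    stop("degenerate fit: all survival fractions equal 1")
  }
  k_of <- function(dd) {
    y <- -log(dd$survival_fraction)
    sum(dd$molecules * y) / sum(dd$molecules^2)
  }
  k <- k_of(d)
  boots <- vapply(seq_len(n_boot), function(b) {
    k_of(d[sample.int(nrow(d), replace = TRUE), , drop = FALSE])
  }, numeric(1))
  a <- (1 - conf) / 2
  structure(list(k = k,
                 ci = stats::quantile(boots, c(a, 1 - a), names = FALSE),
                 n = nrow(d)),
            class = "kill_rate_fit")
}

#' @export
print.kill_rate_fit <- function(x, ...) {
  cat(sprintf("<kill_rate_fit> k = %.4g per molecule (CI %.4g..%.4g, n = %d)\n",
              x$k, x$ci[1], x$ci[2], x$n))
  invisible(x)
}
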