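#' Predict uptake over a protocol-by-concentration grid
#'
#' Simulates each protocol once and converts the final normalized uptake into
#' molecules per cell at every requested extracellular concentration. The
#' transport equation does not depend on the extracellular concentration, so
#' molecule counts are exactly proportional to it and each protocol is
#' integrated a single time.
#'
#' @param protocols character vector of preset names (see [preset_names()])
#'   or a named list of `pulse_train` objects.
#' @param concentrations_uM extracellular concentrations in micromolar.
#' @param p an `ep_params` object.
#' @param solver a `solver_config`.
#' @param t_end_min simulation horizon in minutes (see [simulate_train()]).
#' @return data.frame with one row per (protocol, concentration): columns
#'   `protocol`, `E_applied` (V/m), `X_e_uM`, `X_final`, `molecules`,
#'   `t_end_s`.
#' @examples
#' \donttest{
#' grid <- run_protocol_grid("ns_1x200", c(0, 10, 30, 50))
#' }
#' @export
run_protocol_grid <- function(protocols = preset_names(),
                              concentrations_uM = c(0, 10, 30, 50),
                              p = model_parameters(),
                              solver = solver_config(),
                              t_end_min = 25) {
  if (is.character(protocols)) {
    bad <- setdiff(protocols, preset_names())
    if (length(bad) > 0) {
      stop("unknown preset protocol(s): ", paste(bad, collapse = ", "))
    }
    trains <- lapply(protocols, preset_train)
  } else {
    stopifnot(all(vapply(protocols, inherits, logical(1), "pulse_train")))
    trains <- protocols
  }
  if (any(concentrations_uM < 0)) stop("concentrations must be >= 0")
  out <- lapply(trains, function(tr) {
    traj <- simulate_train(tr, p = p, solver = solver, t_end_min = t_end_min)
    fin <- final_state(traj)
    data.frame(protocol = tr$name,
               E_applied = attr(traj, "E_applied"),
               X_e_uM = concentrations_uM,
               X_final = fin[["X"]],
               molecules = molecules_per_cell(fin[["X"]],
                                              concentrations_uM * 1e-6,
                                              r = p$r),
               t_end_s = fin[["t_s"]])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Convert intracellular platinum mass to cisplatin molecules per cell
#'
#' ICP-MS reports picograms of platinum per cell; assuming 1 mol Pt per mol
#' cisplatin, the blank-subtracted mass divided by the molar mass of platinum
#' (195.084 g/mol) times the Avogadro constant gives molecules per cell.
#' Blank subtraction is floored at zero.
#'
#' @param pt_mass_pg measured Pt mass per cell in picograms (vectorised).
#' @param blank_pg Pt mass per cell of the unexposed control, in picograms.
#' @return Cisplatin molecules per cell.
#' @examples
#' pt_mass_to_molecules(0.0324)  # ~1e8 molecules
#' @export
pt_mass_to_molecules <- function(pt_mass_pg, blank_pg = 0) {
  if (any(!is.finite(pt_mass_pg)) || any(pt_mass_pg < 0) ||
      any(!is.finite(blank_pg)) || any(blank_pg < 0)) {
    stop("platinum masses must be finite and >= 0")
  }
  pmax(pt_mass_pg - blank_pg, 0) * 1e-12 / .M_PT * .AVOGADRO
}

# validate the long measurement-table dialect
.check_measurements <- function(m) {
  need <- c("protocol", "concentration_uM", "replicate", "quantity", "value")
  if (!is.data.frame(m) || !all(need %in% names(m))) {
    stop("measurement table must have columns ", paste(need, collapse = ", "))
  }
  ok <- c("pt_pg_per_cell", "molecules_per_cell", "survival_fraction")
  bad <- setdiff(unique(m$quantity), ok)
  if (length(bad) > 0) {
    stop("unknown measurement quantity: ", paste(bad, collapse = ", "))
  }
  invisible(m)
}

#' Read and write replicate-level measurement tables
#'
#' The on-disk dialect is a CSV with header
#' `protocol,concentration_uM,replicate,quantity,value` where `quantity` is
#' one of `pt_pg_per_cell`, `molecules_per_cell` or `survival_fraction`, and
#' the no-pulse condition carries the protocol label `"control"`.
#'
#' @param path file path.
#' @return `read_measurements()` returns the validated data.frame.
#' @export
read_measurements <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_measurements(m)
  m
}

#' @rdname read_measurements
#' @param measurements a measurement data.frame in the dialect above.
#' @export
write_measurements <- function(measurements, path) {
  .check_measurements(measurements)
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subtract the no-pulse uptake baseline
#'
#' Cells take up some cisplatin without pulsing (passive and
#' transporter-mediated routes); the electroporative uptake attributable to a
#' protocol is the mean treated uptake minus the mean no-pulse uptake at the
#' same extracellular concentration, floored at zero. Replicates are
#' aggregated by arithmetic mean with the sample standard deviation carried
#' through.
#'
#' @param measurements replicate-level table (see [read_measurements()])
#'   containing `molecules_per_cell` rows for treated protocols and for the
#'   control label at every concentration present.
#' @param control protocol label of the no-pulse condition.
#' @return data.frame with one row per (protocol, concentration): `protocol`,
#'   `concentration_uM`, `molecules` (baseline-subtracted mean), `sd`
#'   (treated replicate standard deviation), `n` (treated replicates).
#' @export
subtract_baseline <- function(measurements, control = "control") {
  .check_measurements(measurements)
  m <- measurements[measurements$quantity == "molecules_per_cell", , drop = FALSE]
  if (nrow(m) == 0) stop("no molecules_per_cell rows in measurement table")
  ctl <- m[m$protocol == control, , drop = FALSE]
  trt <- m[m$protocol != control, , drop = FALSE]
  if (nrow(trt) == 0) stop("no treated rows in measurement table")
  need <- unique(trt$concentration_uM)
  missing_c <- setdiff(need, unique(ctl$concentration_uM))
  if (length(missing_c) > 0) {
    stop("no control (no-pulse) records at concentration(s): ",
         paste(missing_c, collapse = ", "), " uM")
  }
  ctl_mean <- tapply(ctl$value, ctl$concentration_uM, mean)
  key <- interaction(trt$protocol, trt$concentration_uM, drop = TRUE)
  agg <- data.frame(
    protocol = tapply(trt$protocol, key, `[`, 1),
    concentration_uM = as.numeric(tapply(trt$concentration_uM, key, `[`, 1)),
    mean = as.numeric(tapply(trt$value, key, mean)),
    sd = as.numeric(tapply(trt$value, key, stats::sd)),
    n = as.integer(tapply(trt$value, key, length)),
    row.names = NULL)
  base <- ctl_mean[as.character(agg$concentration_uM)]
  net <- agg$mean - as.numeric(base)
  if (any(net < 0)) {
    warning(sum(net < 0), " baseline-subtracted value(s) were negative and ",
            "floored at 0")
    net <- pmax(net, 0)
  }
  res <- data.frame(protocol = agg$protocol,
                    concentration_uM = agg$concentration_uM,
                    molecules = net, sd = agg$sd, n = agg$n)
  res <- res[order(res$protocol, res$concentration_uM), ]
  rownames(res) <- NULL
  res
}

#' Compare model predictions with baseline-subtracted measurements
#'
#' Joins model predictions and measured electroporative uptake on
#' (protocol, concentration) and computes the per-condition ratio
#' model/measured. Conditions at zero concentration are skipped; a zero
#' measured mean at non-zero concentration yields an `NA` ratio, is flagged
#' in the `undefined_ratio` column and excluded from the per-protocol
#' aggregate. The per-protocol over/under-prediction factor is the geometric
#' mean of the ratios across concentrations (ratios compose
#' multiplicatively), available via [protocol_ratios()].
#'
#' @param model grid of predictions from [run_protocol_grid()].
#' @param measured baseline-subtracted table from [subtract_baseline()].
#' @return data.frame with columns `protocol`, `concentration_uM`,
#'   `model_molecules`, `measured_molecules`, `ratio`, `undefined_ratio`,
#'   carrying the per-protocol summary as attribute `"protocol_ratios"`.
#' @export
model_vs_measurement <- function(model, measured) {
  stopifnot(all(c("protocol", "X_e_uM", "molecules") %in% names(model)),
            all(c("protocol", "concentration_uM", "molecules") %in% names(measured)))
  mod <- model[model$X_e_uM > 0, c("protocol", "X_e_uM", "molecules")]
  names(mod) <- c("protocol", "concentration_uM", "model_molecules")
  mea <- measured[measured$concentration_uM > 0, , drop = FALSE]
  names(mea)[names(mea) == "molecules"] <- "measured_molecules"
  cmp <- merge(mod, mea, by = c("protocol", "concentration_uM"))
  if (nrow(cmp) == 0) stop("model and measurement tables share no (protocol, concentration) keys")
  cmp$undefined_ratio <- cmp$measured_molecules <= 0
  cmp$ratio <- ifelse(cmp$undefined_ratio, NA_real_,
                      cmp$model_molecules / cmp$measured_molecules)
  cmp <- cmp[order(cmp$protocol, cmp$concentration_uM), ]
  rownames(cmp) <- NULL

  ok <- cmp[!cmp$undefined_ratio, , drop = FALSE]
  ratios <- vapply(split(ok, ok$protocol), function(d) {
    exp(mean(log(d$ratio)))
  }, numeric(1))
  # delta-method standard error of the log geometric-mean ratio, when
  # replicate dispersion is available
  se <- rep(NA_real_, length(ratios))
  if (all(c("sd", "n") %in% names(ok))) {
    se <- vapply(split(ok, ok$protocol), function(d) {
      rel <- d$sd / (d$measured_molecules * sqrt(d$n))
      sqrt(sum(rel^2)) / nrow(d)
    }, numeric(1))
  }
  summ <- data.frame(protocol = names(ratios), ratio = as.numeric(ratios),
                     log_ratio_se = as.numeric(se),
                     n_concentrations = as.integer(table(ok$protocol)[names(ratios)]),
                     row.names = NULL)
  attr(cmp, "protocol_ratios") <- summ
  cmp
}

#' @rdname model_vs_measurement
#' @param comparison the data.frame returned by [model_vs_measurement()].
#' @return `protocol_ratios()` returns the per-protocol summary data.frame
#'   (`protocol`, `ratio`, `log_ratio_se`, `n_concentrations`).
#' @export
protocol_ratios <- function(comparison) {
  s <- attr(comparison, "protocol_ratios")
  if (is.null(s)) stop("`comparison` does not carry a protocol_ratios attribute")
  s
}

#' Pair uptake with survival across shared conditions
#'
#' Inner join of mean molecules per cell and survival fractions on
#' (protocol, concentration), for survival-versus-dose analysis.
#'
#' @param uptake data.frame with `protocol`, `concentration_uM`, `molecules`
#'   (e.g. from [subtract_baseline()]).
#' @param survival data.frame with `protocol`, `concentration_uM`,
#'   `survival_fraction` (e.g. from [clonogenic_survival()]).
#' @return Joined data.frame; errors if the key sets are disjoint.
#' @export
survival_vs_molecules <- function(uptake, survival) {
  stopifnot(all(c("protocol", "concentration_uM", "molecules") %in% names(uptake)),
            all(c("protocol", "concentration_uM", "survival_fraction") %in% names(survival)))
  paired <- merge(uptake, survival, by = c("protocol", "concentration_uM"))
  if (nrow(paired) == 0) {
    stop("uptake and survival tables share no (protocol, concentration) keys")
  }
  paired <- paired[order(paired$protocol, paired$concentration_uM), ]
  rownames(paired) <- NULL
  paired
}
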