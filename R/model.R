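#' Dimensionless source current for a given applied field
#'
#' The applied field charges the membrane through the extracellular medium;
#' in normalized form the forcing term is
#' `I_s = tau_RC * sigma_ext * h * E0 / (U0 * eps_m)`, linear and sign-
#' preserving in `E0`. With the default parameters, 1.2 kV/cm gives
#' `I_s ~ 30.7`.
#'
#' @param E0 applied field in V/m (signed; vectorised).
#' @param p an `ep_params` object.
#' @return Dimensionless source current.
#' @export
source_current <- function(E0, p = model_parameters()) {
  stopifnot(inherits(p, "ep_params"))
  p$tau_RC * p$sigma_ext * p$h * E0 / (p$U0 * p$eps_m)
}

#' Right-hand side of the pore-dynamics/transport system
#'
#' State variables (all dimensionless, time in units of `tau_RC`):
#' `U` the normalized induced transmembrane voltage, `N` the first pore state
#' (permeable to small ions only), `M` the second, expanded pore state
#' (permeable to small molecules), and `X` the intracellular concentration
#' normalized by the extracellular one. The rates are
#' \preformatted{
#'   dU/dtau = I_s - U (1 + gamma (N + M))
#'   dN/dtau = alpha U^2 - delta U^2 N - beta N + eta M
#'   dM/dtau = delta U^2 N - eta M
#'   dX/dtau = xi M (1 - X)
#' }
#' Pore formation depends on `U^2`, so the dynamics of `N`, `M`, `X` are
#' invariant under field polarity reversal.
#'
#' @param state named numeric vector with elements `U`, `N`, `M`, `X`.
#' @param I_s dimensionless source current (see [source_current()]).
#' @param p an `ep_params` object.
#' @return Named vector of rates `(dU, dN, dM, dX)` per unit normalized time.
#' @export
ep_derivatives <- function(state, I_s, p = model_parameters()) {
  U <- state[["U"]]; N <- state[["N"]]; M <- state[["M"]]; X <- state[["X"]]
  c(dU = I_s - U * (1 + p$gamma * (N + M)),
    dN = p$alpha * U^2 - p$delta * U^2 * N - p$beta * N + p$eta * M,
    dM = p$delta * U^2 * N - p$eta * M,
    dX = p$xi * M * (1 - X))
}

# deSolve-facing RHS and analytic Jacobian (parms = I_s); p bound via closure
# in .ode_step to avoid per-call list allocation in ep_derivatives.
.make_rhs <- function(p) {
  function(tau, y, parms) {
    U <- y[1L]; N <- y[2L]; M <- y[3L]; X <- y[4L]
    list(c(parms - U * (1 + p$gamma * (N + M)),
           p$alpha * U * U - p$delta * U * U * N - p$beta * N + p$eta * M,
           p$delta * U * U * N - p$eta * M,
           p$xi * M * (1 - X)))
  }
}

.make_jac <- function(p) {
  function(tau, y, parms) {
    U <- y[1L]; N <- y[2L]; M <- y[3L]; X <- y[4L]
    matrix(c(
      -(1 + p$gamma * (N + M)), 2 * p$alpha * U - 2 * p$delta * U * N, 2 * p$delta * U * N, 0,
      -p$gamma * U,             -p$delta * U * U - p$beta,             p$delta * U * U,     0,
      -p$gamma * U,             p$eta,                                 -p$eta,              p$xi * (1 - X),
      0,                        0,                                     0,                   -p$xi * M),
      nrow = 4L, ncol = 4L)
  }
}

#' Closed-form relaxation of the pore states during field-free intervals
#'
#' With the field off and the transmembrane voltage fully discharged
#' (`U = 0`), the pore system becomes linear and admits the exact solution
#' \preformatted{
#'   M(dt)       = M0 exp(-eta dt)
#'   N(dt)       = (N0 - eta M0/(beta - eta)) exp(-beta dt)
#'                 + eta M0/(beta - eta) exp(-eta dt)
#'   1 - X(dt)   = (1 - X0) exp(-xi M0 (1 - exp(-eta dt)) / eta)
#' }
#' (time in `tau_RC` units). The degenerate case `beta == eta` uses the
#' limiting form `N = (N0 + eta M0 dt) exp(-beta dt)`. The returned `U` is 0;
#' callers must only invoke this after `U` has decayed (its decay rate is at
#' least 1 per unit of normalized time, so this holds within ~100 tau_RC of
#' field switch-off).
#'
#' @param state named numeric vector `U`, `N`, `M`, `X` (the incoming `U` is
#'   discarded).
#' @param delta_tau interval length in normalized time (>= 0).
#' @param p an `ep_params` object.
#' @return The relaxed state as a named vector with `U = 0`.
#' @export
relax_closed_form <- function(state, delta_tau, p = model_parameters()) {
  if (!is.finite(delta_tau) || delta_tau < 0) stop("`delta_tau` must be >= 0")
  N0 <- state[["N"]]; M0 <- state[["M"]]; X0 <- state[["X"]]
  b <- p$beta; e <- p$eta
  M <- M0 * exp(-e * delta_tau)
  if (b == e) {
    N <- (N0 + e * M0 * delta_tau) * exp(-b * delta_tau)
  } else {
    w <- e * M0 / (b - e)
    N <- (N0 - w) * exp(-b * delta_tau) + w * exp(-e * delta_tau)
  }
  X <- 1 - (1 - X0) * exp(-p$xi * M0 * (1 - exp(-e * delta_tau)) / e)
  c(U = 0, N = N, M = M, X = X)
}

#' Integrator configuration
#'
#' @param rtol relative tolerance of the stiff solver.
#' @param atol absolute tolerance (applied to all four state variables).
#' @param gap_switch_tau field-free intervals longer than this many units of
#'   normalized time are handled by a short numeric burn-in (during which the
#'   transmembrane voltage discharges) followed by [relax_closed_form()];
#'   shorter gaps are integrated numerically throughout.
#' @param t_end_reference whether the default simulation horizon
#'   (`t_end_min` in [simulate_train()]) is measured from the end of the
#'   pulse train (`"train_end"`, matching samples processed a fixed time
#'   after pulse delivery) or from its start (`"train_start"`).
#' @param method `"hybrid"` (default) uses the closed-form shortcut for long
#'   gaps; `"numeric"` integrates every interval with the stiff solver
#'   end-to-end and exists as a brute-force cross-check of the hybrid path.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(rtol = 1e-8, atol = 1e-12, gap_switch_tau = 100,
                          t_end_reference = c("train_end", "train_start"),
                          method = c("hybrid", "numeric")) {
  stopifnot(rtol > 0, atol > 0, gap_switch_tau > 0)
  structure(list(rtol = rtol, atol = atol, gap_switch_tau = gap_switch_tau,
                 t_end_reference = match.arg(t_end_reference),
                 method = match.arg(method)),
            class = "solver_config")
}

# One numeric integration step over a constant-field interval.
# Returns the state at tau0 + dtau; errors identify the failing segment.
.ode_step <- function(y, dtau, I_s, p, solver, rhs, jac, seg_label) {
  if (dtau <= 0) return(y)
  out <- deSolve::ode(y = y, times = c(0, dtau), func = rhs, parms = I_s,
                      jacfunc = jac, jactype = "fullusr", method = "lsoda",
                      rtol = solver$rtol, atol = solver$atol)
  istate <- attr(out, "istate")[1]
  yend <- out[nrow(out), -1]
  if (is.null(istate) || istate < 0 || any(!is.finite(yend))) {
    stop("stiff integration failed at ", seg_label,
         " (istate = ", istate, ")")
  }
  # clamp solver-tolerance-level constraint violations
  for (v in c("N", "M")) if (yend[[v]] < 0 && yend[[v]] > -1e-9) yend[[v]] <- 0
  if (yend[["X"]] < 0 && yend[["X"]] > -1e-9) yend[["X"]] <- 0
  if (yend[["X"]] > 1 && yend[["X"]] < 1 + 1e-9) yend[["X"]] <- 1
  yend
}

#' Simulate the pore model over a pulse train
#'
#' Integrates the four-variable pore/transport system driven by the
#' piecewise-constant field of `train`, from an intact membrane
#' (`U = N = M = X = 0` at `tau = 0`) to the simulation horizon. Active
#' segments and short gaps use an adaptive stiff solver (lsoda with an
#' analytic Jacobian); field-free intervals longer than
#' `solver$gap_switch_tau` are integrated numerically only until the
#' transmembrane voltage has discharged (`|U| < 1e-6`) and then advanced with
#' the exact relaxation solution, which makes minute-to-hour horizons
#' (10^9 units of normalized time) tractable.
#'
#' @param train a `pulse_train`.
#' @param p an `ep_params` object.
#' @param solver a `solver_config`.
#' @param t_end_s explicit simulation horizon in seconds from train start;
#'   overrides `t_end_min` and must be at least the train duration.
#' @param t_end_min default horizon in minutes, measured from the train end
#'   or start per `solver$t_end_reference` (default 25 minutes after the end
#'   of the train, matching uptake quantification 25 minutes after pulse
#'   delivery).
#' @return An `ep_trajectory`: a data.frame with columns `t_s`, `tau`, `U`,
#'   `N`, `M`, `X` sampled at segment boundaries plus log-spaced points
#'   within long relaxation intervals, with attributes `protocol`,
#'   `E_applied` (peak absolute field, V/m), `params` and `solver`.
#' @examples
#' tr <- preset_train("ns_1x200")
#' traj <- simulate_train(tr)
#' tail(traj, 1)$X  # normalized uptake 25 min after the pulse
#' @export
simulate_train <- function(train, p = model_parameters(),
                           solver = solver_config(),
                           t_end_s = NULL, t_end_min = 25) {
  stopifnot(inherits(train, "pulse_train"), inherits(p, "ep_params"),
            inherits(solver, "solver_config"))
  dur <- train_duration(train)
  if (is.null(t_end_s)) {
    t_end_s <- t_end_min * 60 +
      if (solver$t_end_reference == "train_end") dur else 0
  }
  if (t_end_s < dur) {
    stop("`t_end_s` (", format(t_end_s),
         ") must be at least the train duration (", format(dur), " s)")
  }
  rhs <- .make_rhs(p)
  jac <- .make_jac(p)
  hybrid <- solver$method == "hybrid"

  y <- c(U = 0, N = 0, M = 0, X = 0)
  tau_now <- 0
  rows <- vector("list", 256L)
  n_rows <- 0L
  push <- function(tau, y) {
    n_rows <<- n_rows + 1L
    if (n_rows > length(rows)) length(rows) <<- 2L * n_rows
    rows[[n_rows]] <<- c(tau, y)
  }
  push(0, y)

  # advance over a field-free interval of dtau normalized time units
  advance_gap <- function(y, tau0, dtau, seg_label) {
    if (hybrid && dtau > solver$gap_switch_tau) {
      burn <- solver$gap_switch_tau
      y <- .ode_step(y, burn, 0, p, solver, rhs, jac, seg_label)
      if (abs(y[["U"]]) < 1e-6) {
        y[["U"]] <- 0
        rest <- dtau - burn
        # log-spaced interior samples through the relaxation interval
        if (rest > 1) {
          pts <- unique(10^seq(0, log10(rest), length.out = 9L))
          pts <- pts[pts < 0.99 * rest] # keep clear of the interval end
          for (q in pts) push(tau0 + burn + q, relax_closed_form(y, q, p))
        }
        y <- relax_closed_form(y, rest, p)
      } else {
        # voltage not yet discharged (pathological parameters): stay numeric
        y <- .ode_step(y, dtau - burn, 0, p, solver, rhs, jac, seg_label)
      }
    } else {
      y <- .ode_step(y, dtau, 0, p, solver, rhs, jac, seg_label)
    }
    y
  }

  segs <- train$segments
  for (i in seq_len(nrow(segs))) {
    dtau <- segs$duration[i] / p$tau_RC
    lab <- sprintf("segment %d/%d of '%s'", i, nrow(segs), train$name)
    if (segs$field[i] == 0) {
      y <- advance_gap(y, tau_now, dtau, lab)
    } else {
      y <- .ode_step(y, dtau, source_current(segs$field[i], p), p, solver,
                     rhs, jac, lab)
    }
    tau_now <- tau_now + dtau
    push(tau_now, y)
  }

  rem <- (t_end_s - dur) / p$tau_RC
  if (rem > 0) {
    y <- advance_gap(y, tau_now, rem, sprintf("post-train tail of '%s'", train$name))
    tau_now <- tau_now + rem
    push(tau_now, y)
  }

  m <- do.call(rbind, rows[seq_len(n_rows)])
  traj <- data.frame(t_s = m[, 1] * p$tau_RC, tau = m[, 1],
                     U = m[, 2], N = m[, 3], M = m[, 4], X = m[, 5])
  attr(traj, "protocol") <- train$name
  attr(traj, "E_applied") <- if (nrow(segs) > 0) max(abs(segs$field)) else 0
  attr(traj, "params") <- p
  attr(traj, "solver") <- solver
  class(traj) <- c("ep_trajectory", "data.frame")
  traj
}

#' Final state of a simulated trajectory
#'
#' @param traj an `ep_trajectory`.
#' @return Named numeric vector `t_s`, `tau`, `U`, `N`, `M`, `X` at the
#'   simulation horizon.
#' @export
final_state <- function(traj) {
  stopifnot(inherits(traj, "ep_trajectory"))
  unlist(traj[nrow(traj), c("t_s", "tau", "U", "N", "M", "X")])
}

#' Convert normalized uptake to molecules per cell
#'
#' The intracellular concentration is `X * X_e`; multiplying by the average
#' cell volume `(4/3) pi r^3` (converted to litres) and the Avogadro constant
#' gives the absolute number of internalized molecules. At full equilibration
#' (`X = 1`) this is the diffusive ceiling: ~5.32e7 molecules at 50 uM for a
#' 7.5 um cell radius.
#'
#' @param X_final normalized uptake in `[0, 1]` (vectorised).
#' @param X_e_molar extracellular concentration in mol/L.
#' @param r cell radius in metres.
#' @return Molecules per cell.
#' @examples
#' molecules_per_cell(1, 50e-6)  # equilibration ceiling at 50 uM
#' @export
molecules_per_cell <- function(X_final, X_e_molar, r = model_parameters()$r) {
  if (any(!is.finite(X_final)) || any(X_final < 0) || any(X_final > 1 + 1e-9)) {
    stop("`X_final` must lie in [0, 1]")
  }
  if (any(X_e_molar < 0)) stop("`X_e_molar` must be >= 0")
  cell_volume_L <- 4 / 3 * pi * r^3 * 1000
  X_final * X_e_molar * cell_volume_L * .AVOGADRO
}

#' Write a trajectory as a tab-separated table
#'
#' Columns: `t_s`, `tau`, `U`, `N`, `M`, `X`.
#'
#' @param traj an `ep_trajectory`.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ep_trajectory"))
  utils::write.table(format(as.data.frame(traj), digits = 10, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
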