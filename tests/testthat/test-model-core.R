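# independent numeric oracle for the field-free pore system: adaptive
# integration of the (N, M, X) equations at U = 0 with deSolve
relax_numeric <- function(state, delta_tau, p) {
  rhs <- function(tau, y, parms) {
    list(c(-p$beta * y[1] + p$eta * y[2],
           -p$eta * y[2],
           p$xi * y[2] * (1 - y[3])))
  }
  out <- deSolve::ode(y = c(state[["N"]], state[["M"]], state[["X"]]),
                      times = c(0, delta_tau), func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-14)
  y <- out[nrow(out), -1]
  c(U = 0, N = y[[1]], M = y[[2]], X = y[[3]])
}

test_that("source current scales linearly with the applied field", {
  p <- model_parameters()
  # frozen from direct evaluation of tau_RC sigma h E0 / (U0 eps_m)
  expect_equal(source_current(1.2e5, p), 30.657382, tolerance = 1e-6)
  expect_equal(source_current(0, p), 0)
  expect_equal(source_current(2.4e5, p), 2 * source_current(1.2e5, p))
  expect_equal(source_current(-1.2e5, p), -source_current(1.2e5, p))
})

test_that("rate equations have the expected structure", {
  p <- model_parameters()
  zero <- c(U = 0, N = 0, M = 0, X = 0)
  expect_equal(unname(ep_derivatives(zero, 0, p)), rep(0, 4)) # fixed point

  s <- c(U = 1, N = 0, M = 0, X = 0)
  expect_equal(ep_derivatives(s, 0, p)[["dN"]], p$alpha)

  s2 <- c(U = 3, N = 1e-4, M = 2e-5, X = 0.1)
  d_pos <- ep_derivatives(s2, 5, p)
  d_neg <- ep_derivatives(c(U = -3, s2[-1]), -5, p)
  expect_equal(d_neg[["dN"]], d_pos[["dN"]]) # U^2 symmetry
  expect_equal(d_neg[["dM"]], d_pos[["dM"]])
  expect_equal(d_neg[["dX"]], d_pos[["dX"]])
  expect_equal(d_neg[["dU"]], -d_pos[["dU"]])
})

test_that("closed-form relaxation matches adaptive numeric integration", {
  p <- model_parameters()
  set.seed(7)
  for (i in 1:8) {
    s0 <- c(U = 0, N = stats::runif(1, 0, 2), M = stats::runif(1, 0, 1e-4),
            X = stats::runif(1, 0, 0.8))
    dtau <- 10^stats::runif(1, 2, 9)
    got <- relax_closed_form(s0, dtau, p)
    want <- relax_numeric(s0, dtau, p)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("relaxation limits and degenerate rate constants are exact", {
  p <- model_parameters()
  # decoupled N decay when no expanded pores are present
  s <- c(U = 0, N = 0.5, M = 0, X = 0.3)
  out <- relax_closed_form(s, 1e7, p)
  expect_equal(out[["N"]], 0.5 * exp(-p$beta * 1e7))
  expect_equal(out[["X"]], 0.3)

  # infinite-time uptake from the expanded-pore reservoir
  M0 <- 2e-5
  out_inf <- relax_closed_form(c(U = 0, N = 0, M = M0, X = 0), 1e12, p)
  expect_equal(out_inf[["X"]], 1 - exp(-p$xi * M0 / p$eta), tolerance = 1e-9)

  # beta == eta limiting form against the numeric oracle
  pd <- model_parameters(beta = 4e-9, eta = 4e-9)
  s0 <- c(U = 0, N = 0.2, M = 1e-5, X = 0.1)
  expect_equal(relax_closed_form(s0, 5e8, pd), relax_numeric(s0, 5e8, pd),
               tolerance = 1e-6)

  expect_error(relax_closed_form(s0, -1, p), ">= 0")
})

test_that("a zero-field train stays at the intact-membrane fixed point", {
  tr <- pulse_train(data.frame(duration = c(0.5, 0.5), field = 0),
                    name = "sham")
  fin <- final_state(simulate_train(tr, t_end_s = 120))
  expect_equal(unname(fin[c("U", "N", "M", "X")]), rep(0, 4))
  expect_equal(fin[["t_s"]], 120)
})

test_that("reversing pulse polarity leaves pore states and uptake unchanged", {
  tr <- preset_train("ns_25x400")
  neg <- pulse_train(transform(tr$segments, field = -field), name = "neg")
  solver <- solver_config()
  f_pos <- final_state(simulate_train(tr, solver = solver, t_end_s = 30))
  f_neg <- final_state(simulate_train(neg, solver = solver, t_end_s = 30))
  expect_equal(f_neg[["N"]], f_pos[["N"]], tolerance = 1e-8)
  expect_equal(f_neg[["M"]], f_pos[["M"]], tolerance = 1e-8)
  expect_equal(f_neg[["X"]], f_pos[["X"]], tolerance = 1e-8)
})

test_that("halving solver tolerances leaves the final uptake unchanged", {
  tr <- preset_train("ns_25x400")
  x1 <- final_state(simulate_train(tr, solver = solver_config(), t_end_s = 60))[["X"]]
  x2 <- final_state(simulate_train(
    tr, solver = solver_config(rtol = 5e-9, atol = 5e-13), t_end_s = 60))[["X"]]
  expect_lt(abs(x1 - x2) / x1, 1e-3)
})

test_that("the simulation horizon must cover the train", {
  tr <- preset_train("mono_8x100us")
  expect_error(simulate_train(tr, t_end_s = 1), "train duration")
})

test_that("molecule conversion respects the equilibration ceiling and linearity", {
  expect_equal(molecules_per_cell(0, 50e-6), 0)
  # frozen from direct evaluation of X_e (4/3) pi r^3 N_A at full equilibration
  expect_equal(molecules_per_cell(1, 50e-6), 5.321001e7, tolerance = 1e-6)
  expect_equal(molecules_per_cell(0.4, 100e-6),
               2 * molecules_per_cell(0.4, 50e-6))
  expect_error(molecules_per_cell(1.5, 50e-6), "\\[0, 1\\]")
  expect_error(molecules_per_cell(0.5, -1), ">= 0")
})

test_that("trajectories expose metadata and serialize as TSV", {
  traj <- simulate_train(preset_train("ns_1x200"), t_end_s = 10)
  expect_s3_class(traj, "ep_trajectory")
  expect_equal(attr(traj, "protocol"), "ns_1x200")
  expect_equal(attr(traj, "E_applied"), 12.6e5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(traj, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(names(back), c("t_s", "tau", "U", "N", "M", "X"))
  expect_equal(nrow(back), nrow(traj))
  expect_equal(back$X[nrow(back)], final_state(traj)[["X"]], tolerance = 1e-8)
})
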