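# Shared cache of preset simulations: the long-horizon integrations are the
# expensive part of the suite, so each (protocol, horizon, method) is
# simulated once and reused across test files.
.traj_cache <- new.env(parent = emptyenv())

cached_traj <- function(protocol, t_end_s = NULL, method = "hybrid") {
  key <- paste(protocol, method, if (is.null(t_end_s)) "default" else t_end_s)
  if (is.null(.traj_cache[[key]])) {
    .traj_cache[[key]] <- simulate_train(
      preset_train(protocol),
      solver = solver_config(method = method),
      t_end_s = t_end_s)
  }
  .traj_cache[[key]]
}

# prediction grid assembled from cached default-horizon trajectories
cached_grid <- function(protocols, concentrations_uM = c(0, 10, 30, 50)) {
  out <- lapply(protocols, function(pn) {
    traj <- cached_traj(pn)
    fin <- final_state(traj)
    data.frame(protocol = pn,
               E_applied = attr(traj, "E_applied"),
               X_e_uM = concentrations_uM,
               X_final = fin[["X"]],
               molecules = molecules_per_cell(fin[["X"]],
                                              concentrations_uM * 1e-6),
               t_end_s = fin[["t_s"]])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# small replicate-level measurement table in the package CSV dialect
toy_measurements <- function(treated, control, concentration_uM = 50,
                             protocol = "mono_8x100us", n = 3) {
  rbind(
    data.frame(protocol = protocol, concentration_uM = concentration_uM,
               replicate = seq_len(n), quantity = "molecules_per_cell",
               value = treated),
    data.frame(protocol = "control", concentration_uM = concentration_uM,
               replicate = seq_len(n), quantity = "molecules_per_cell",
               value = control))
}
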