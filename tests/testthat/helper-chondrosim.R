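# Shared fixtures: everything is generated in code at test time.

# Small, fast scenario for machinery tests (not the canonical calibration).
small_spec <- function(..., horizon = 120) {
  scenario_spec(n_nodes = 60, r_max = 2.5, horizon = horizon, ...)
}

# A strictly positive random parameter set for oracle comparisons.
random_params <- function() {
  draws <- stats::runif(28, 0.05, 2)
  names(draws) <- c("D_R", "D_M", "D_F", "D_P", "delta_R", "delta_M",
                    "delta_F", "delta_P", "sigma_R", "sigma_M", "sigma_F",
                    "sigma_P", "delta_U", "lambda_R", "lambda_M", "lambda_F",
                    "lambda_P", "Lambda", "alpha", "beta_1", "beta_2",
                    "gamma", "nu", "mu_SA", "mu_DN", "tau_1", "tau_2", "P_c")
  draws["tau_1"] <- stats::runif(1, 4, 12)
  draws["tau_2"] <- draws["tau_1"] + stats::runif(1, 1, 12)
  do.call(chondro_params, as.list(draws))
}

# Random positive state on a grid.
random_state <- function(grid, t = 0) {
  s <- system_state(grid, t = t)
  s$fields[, ] <- matrix(stats::runif(grid$n_nodes * 10, 0, 3),
                         grid$n_nodes, 10)
  s
}

# Independent term-by-term transcription of the model reaction equations,
# written directly from the chemical/cell-state balance laws as a second
# path (no reuse of the package's saturation helper or rhs code).
oracle_rhs <- function(now, lag1, lag2, p) {
  n <- nrow(now)
  out <- matrix(NA_real_, n, 10,
                dimnames = list(NULL, colnames(now)))
  for (i in seq_len(n)) {
    R <- now[i, "R"]; M <- now[i, "M"]; F <- now[i, "F"]; P <- now[i, "P"]
    C <- now[i, "C"]; ST <- now[i, "S_T"]; SA <- now[i, "S_A"]
    DN <- now[i, "D_N"]; U <- now[i, "U"]
    ST1 <- lag1[i, "S_T"]; F1 <- lag1[i, "F"]; R2 <- lag2[i, "R"]
    H <- if (P - p$P_c < 0) 1 else 0
    out[i, "R"] <- -p$delta_R * R + p$sigma_R * ST
    out[i, "M"] <- -p$delta_M * M + p$sigma_M * DN +
      p$delta_U * U * F / (p$lambda_F + F)
    out[i, "F"] <- -p$delta_F * F + p$sigma_F * ST
    out[i, "P"] <- -p$delta_P * P +
      p$sigma_P * C * (R2 / (p$lambda_R + R2)) * (p$Lambda / (p$Lambda + F))
    out[i, "U"] <- -p$delta_U * U * F / (p$lambda_F + F)
    conv <- p$beta_1 * C * (M / (p$lambda_M + M)) * H +
      p$beta_2 * C * (F / (p$lambda_F + F)) * H
    act <- p$gamma * ST1 * F1 / (p$lambda_F + F1)
    rev <- p$alpha * SA * P / (p$lambda_P + P)
    apo_T <- p$nu * ST * (F / (p$lambda_F + F)) * (M / (p$lambda_M + M))
    apo_A <- p$mu_SA * SA * F / (p$lambda_F + F)
    out[i, "C"] <- rev - conv
    out[i, "S_T"] <- conv - act - apo_T
    out[i, "S_A"] <- act - rev - apo_A
    out[i, "D_N"] <- -p$mu_DN * DN
    out[i, "D_A"] <- apo_T + apo_A
  }
  out
}
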