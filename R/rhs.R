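# Reaction (non-diffusive) part of the model right-hand side.
#
# Chemical species: ROS (R) and TNF-alpha (F) are produced by catabolic
# cells; DAMPs (M) are released by necrotic cells and by TNF-degraded
# matrix; EPO (P) is produced by the *current* healthy population under
# delayed ROS signaling and is inhibited by TNF-alpha. Cell states: DAMPs
# and TNF-alpha convert healthy cells to catabolic while local EPO is below
# its critical level; catabolic cells signaled by TNF-alpha tau_1 hours ago
# become EPOR-active; EPOR-active cells revert to healthy under EPO;
# apoptosis of catabolic cells requires TNF-alpha and DAMPs jointly, that
# of EPOR-active cells TNF-alpha alone; necrotic cells decay to inert.

# Fast path used by the integrator: operates on bare field matrices.
.reaction_rhs_matrix <- function(now, lag1, lag2, p) {
  satF  <- now[, "F"] / (p$lambda_F + now[, "F"])
  satM  <- now[, "M"] / (p$lambda_M + now[, "M"])
  satP  <- now[, "P"] / (p$lambda_P + now[, "P"])
  satF1 <- lag1[, "F"] / (p$lambda_F + lag1[, "F"])    # F(t - tau_1)
  satR2 <- lag2[, "R"] / (p$lambda_R + lag2[, "R"])    # R(t - tau_2)
  H <- threshold_gate(now[, "P"] - p$P_c, p$h_sharpness)

  convert <- (p$beta_1 * satM + p$beta_2 * satF) * now[, "C"] * H
  activate <- p$gamma * lag1[, "S_T"] * satF1          # S_T(t - tau_1) gated by F(t - tau_1)
  revert <- p$alpha * now[, "S_A"] * satP
  apop_T <- p$nu * now[, "S_T"] * satF * satM
  apop_A <- p$mu_SA * now[, "S_A"] * satF
  degrade <- p$delta_U * now[, "U"] * satF

  d <- matrix(0, nrow(now), length(CHONDRO_FIELDS),
              dimnames = list(NULL, CHONDRO_FIELDS))
  d[, "R"]   <- -p$delta_R * now[, "R"] + p$sigma_R * now[, "S_T"]
  d[, "M"]   <- -p$delta_M * now[, "M"] + p$sigma_M * now[, "D_N"] + degrade
  d[, "F"]   <- -p$delta_F * now[, "F"] + p$sigma_F * now[, "S_T"]
  d[, "P"]   <- -p$delta_P * now[, "P"] +
    p$sigma_P * now[, "C"] * satR2 * p$Lambda / (p$Lambda + now[, "F"])
  d[, "C"]   <- revert - convert
  d[, "S_T"] <- convert - activate - apop_T
  d[, "S_A"] <- activate - revert - apop_A
  d[, "D_N"] <- -p$mu_DN * now[, "D_N"]
  d[, "U"]   <- -degrade
  d[, "D_A"] <- apop_T + apop_A
  d
}

#' Reaction part of the model time derivative
#'
#' Evaluates, node by node, the non-diffusive right-hand side of the full
#' model: chemical production/decay, matrix degradation, cell-state
#' switching with its two discrete delays, and the apoptosis ledger. The
#' diffusion terms are applied separately (see [apply_diffusion()]); cell
#' fields do not diffuse at all.
#'
#' Delay wiring: the catabolic-to-EPOR-active flux uses the catabolic
#' density and TNF-alpha saturation at `t - tau_1`; EPO production uses the
#' *current* healthy density with ROS saturation at `t - tau_2`.
#'
#' @param state_now `chondro_state` at time `t`.
#' @param state_tau1 `chondro_state` at `t - tau_1` (same grid).
#' @param state_tau2 `chondro_state` at `t - tau_2` (same grid).
#' @param params A [chondro_params()] set.
#' @return An `n_nodes` x 10 matrix of field time-derivatives (columns in
#'   model field order).
#' @export
reaction_rhs <- function(state_now, state_tau1, state_tau2, params) {
  stopifnot(inherits(state_now, "chondro_state"),
            inherits(state_tau1, "chondro_state"),
            inherits(state_tau2, "chondro_state"))
  params <- validate_params(params)
  n <- state_now$grid$n_nodes
  if (state_tau1$grid$n_nodes != n || state_tau2$grid$n_nodes != n ||
      !isTRUE(all.equal(state_tau1$grid$node_centers, state_now$grid$node_centers)) ||
      !isTRUE(all.equal(state_tau2$grid$node_centers, state_now$grid$node_centers))) {
    stop("the three states must share one grid", call. = FALSE)
  }
  for (s in list(state_now, state_tau1, state_tau2)) {
    bad <- !is.finite(s$fields)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop("non-finite value in field `", CHONDRO_FIELDS[idx[2]],
           "` at node ", idx[1], call. = FALSE)
    }
  }
  .reaction_rhs_matrix(state_now$fields, state_tau1$fields, state_tau2$fields,
                       params)
}
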