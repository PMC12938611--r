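#' Default latent-trait distribution of a simulated cohort
#'
#' Means and spreads on the 1-5 Likert scale typical of young-adult community
#' samples, with modest positive correlations among openness,
#' conscientiousness, extraversion and agreeableness and a mild negative
#' correlation of neuroticism with the others.
#'
#' @return A list with `means`, `sds` (named over O, C, E, A, N) and `cor`
#'   (5x5 correlation matrix).
#' @export
trait_config_default <- function() {
  traits <- c("O", "C", "E", "A", "N")
  R <- diag(5)
  dimnames(R) <- list(traits, traits)
  pos <- c("O", "C", "E", "A")
  R[pos, pos] <- 0.25
  diag(R) <- 1
  R["N", pos] <- R[pos, "N"] <- -0.2
  list(
    means = c(O = 3.5, C = 3.6, E = 3.3, A = 3.7, N = 2.9),
    sds = c(O = 0.55, C = 0.55, E = 0.6, A = 0.5, N = 0.6),
    cor = R
  )
}

# Attenuation between an agent's produce-utility signal and its realized
# producer's index under the default low-cost condition, estimated once by
# Monte Carlo (see the methods vignette) and frozen. Couplings are calibrated
# through it: a requested trait-index correlation c is mapped to a target
# signal correlation c / INDEX_ATTENUATION.
INDEX_ATTENUATION <- 0.72

#' Generate a cohort of simulated foragers
#'
#' Draws `n_participants` agents whose latent Big Five traits follow a
#' multivariate normal distribution (clamped to the 1-5 scale), plus a
#' nonnegative antisociality level driving the psychopathy-screen items, and
#' equips each agent with a produce-vs-scrounge policy.
#'
#' The policy's trait weights are set so that the correlation between a trait
#' and the producer's index realized in a default low-cost session matches
#' the requested `coupling` in expectation. Writing the produce signal as
#' `S = w'z + e`, with `z` the standardized traits, `e ~ N(0, policy_noise_sd^2)`
#' an agent-level strategy preference unrelated to personality, and `lambda`
#' the frozen Monte-Carlo attenuation between signal and realized index, the
#' weights solve `corr(z, S) = coupling / lambda` in closed form:
#' `w = beta * solve(R, u)` with `u = coupling / lambda`,
#' `beta = policy_noise_sd / sqrt(1 - u' solve(R) u)`. Couplings with
#' `u' solve(R) u >= 1` are infeasible and rejected.
#'
#' @param n_participants Number of agents (>= 2).
#' @param trait_config List with `means`, `sds`, `cor` as in
#'   [trait_config_default()].
#' @param coupling Named numeric of target trait-index correlations over any
#'   of O, C, E, A, N (missing entries are 0).
#' @param antisociality_coupling Target correlation between the latent
#'   antisociality and the producer's index (default 0).
#' @param baseline_logit Produce-utility intercept shared by all agents.
#' @param policy_noise_sd SD of the agent-level strategy preference.
#' @param cost_sensitivity Produce-utility penalty per second of search cost.
#' @param scrounge_opportunism Utility of joining an open discovery.
#' @param scrounge_cost_spillover Reduction of the scrounge utility per second
#'   of search cost: a costly-production ecology suppresses opportunities to
#'   express either strategy, not just producing.
#' @param antisociality_mean,antisociality_sd Location/spread of the latent
#'   antisociality on the 0-2 per-item scale (truncated at 0).
#' @param antisociality_trait_cor Correlation of the antisociality latent with
#'   standardized agreeableness and conscientiousness (each).
#' @param seed Integer seed.
#' @return A tibble, one row per agent: `agent_id`, latent traits `O`-`N`,
#'   `antisociality`, and policy columns `baseline_logit`, `produce_signal`,
#'   `cost_sensitivity`, `scrounge_opportunism`.
#' @export
#' @examples
#' generate_cohort(8, coupling = c(A = 0.45), seed = 7)
generate_cohort <- function(n_participants,
                            trait_config = trait_config_default(),
                            coupling = c(O = 0, C = 0, E = 0, A = 0, N = 0),
                            antisociality_coupling = 0,
                            baseline_logit = 1.4,
                            policy_noise_sd = 0.8,
                            cost_sensitivity = 0.36,
                            scrounge_opportunism = -1.6,
                            scrounge_cost_spillover = 0.15,
                            antisociality_mean = 0.20,
                            antisociality_sd = 0.22,
                            antisociality_trait_cor = -0.35,
                            seed = 1L) {
  check_number(n_participants, "n_participants", lo = 2, integer = TRUE)
  check_number(policy_noise_sd, "policy_noise_sd", lo = 1e-8)
  check_number(cost_sensitivity, "cost_sensitivity", lo = 0)
  check_number(baseline_logit, "baseline_logit")
  check_number(scrounge_opportunism, "scrounge_opportunism")
  check_number(scrounge_cost_spillover, "scrounge_cost_spillover", lo = 0)
  traits <- c("O", "C", "E", "A", "N")

  mu <- trait_config$means[traits]
  sds <- trait_config$sds[traits]
  R <- trait_config$cor[traits, traits]
  if (any(is.na(mu)) || any(is.na(sds)) || any(is.na(R))) {
    abort_validation("`trait_config` must provide means, sds and cor over O, C, E, A, N")
  }
  if (any(mu < 1 | mu > 5) || any(sds <= 0)) {
    abort_validation("trait means must lie in [1, 5] and sds be positive")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort_validation("trait correlation matrix is not positive semidefinite")
  }

  cpl <- stats::setNames(rep(0, 5), traits)
  if (length(coupling)) {
    if (is.null(names(coupling)) || !all(names(coupling) %in% traits)) {
      abort_validation("`coupling` must be named over O, C, E, A, N")
    }
    cpl[names(coupling)] <- coupling
  }
  if (any(abs(cpl) >= 1) || abs(antisociality_coupling) >= 1) {
    abort_validation("couplings must lie in (-1, 1)")
  }
  u <- cpl / INDEX_ATTENUATION
  Ri_u <- solve(R, u)
  q <- sum(u * Ri_u)
  u_anti <- antisociality_coupling / INDEX_ATTENUATION
  if (q + u_anti^2 >= 0.95) {
    abort_validation(
      "requested couplings are infeasible (explained signal fraction %.2f >= 0.95)", q + u_anti^2
    )
  }
  beta <- policy_noise_sd / sqrt(1 - q - u_anti^2)
  w <- beta * Ri_u
  w_anti <- beta * u_anti

  withr::with_seed(as.integer(seed), {
    Sigma <- diag(sds) %*% R %*% diag(sds)
    lat <- MASS::mvrnorm(n_participants, mu = mu, Sigma = Sigma)
    lat <- clamp(lat, 1, 5)
    colnames(lat) <- traits
    z <- sweep(sweep(lat, 2, mu), 2, sds, "/")

    # antisociality latent: correlated with low A and C, truncated at 0
    rho <- antisociality_trait_cor
    resid_sd <- sqrt(max(1 - 2 * rho^2 * (1 + R["A", "C"]), 0.05))
    z_anti <- rho * z[, "A"] + rho * z[, "C"] + stats::rnorm(n_participants, 0, resid_sd)
    anti <- clamp(antisociality_mean + antisociality_sd * z_anti, 0, 2)

    signal <- as.numeric(z %*% w) + w_anti * z_anti +
      stats::rnorm(n_participants, 0, policy_noise_sd)

    tibble::tibble(
      agent_id = sprintf("p%03d", seq_len(n_participants)),
      O = lat[, "O"], C = lat[, "C"], E = lat[, "E"], A = lat[, "A"], N = lat[, "N"],
      antisociality = anti,
      baseline_logit = baseline_logit,
      produce_signal = signal,
      cost_sensitivity = cost_sensitivity,
      scrounge_opportunism = scrounge_opportunism,
      scrounge_cost_spillover = scrounge_cost_spillover
    )
  })
}

#' Build a single agent profile by hand
#'
#' Mainly for tests and small worked examples; [generate_cohort()] is the
#' usual entry point. Trait weights are applied to traits standardized
#' against the default trait configuration.
#'
#' @param agent_id Identifier.
#' @param O,C,E,A,N Latent traits on 1-5.
#' @param antisociality Latent antisociality on the 0-2 per-item scale.
#' @param baseline_logit,cost_sensitivity,scrounge_opportunism,scrounge_cost_spillover
#'   Policy parameters, see [generate_cohort()].
#' @param trait_weights Named numeric mapping standardized traits into the
#'   produce signal.
#' @param produce_noise Extra additive produce-signal offset (default 0).
#' @return A one-row agent tibble.
#' @export
agent_profile <- function(agent_id, O = 3, C = 3, E = 3, A = 3, N = 3,
                          antisociality = 0.3,
                          baseline_logit = 1.4,
                          cost_sensitivity = 0.36,
                          scrounge_opportunism = -1.6,
                          scrounge_cost_spillover = 0.15,
                          trait_weights = c(O = 0, C = 0, E = 0, A = 0, N = 0),
                          produce_noise = 0) {
  for (t in c(O = O, C = C, E = E, A = A, N = N)) check_number(t, "trait", lo = 1, hi = 5)
  cfg <- trait_config_default()
  traits <- c("O", "C", "E", "A", "N")
  w <- stats::setNames(rep(0, 5), traits)
  if (length(trait_weights)) w[names(trait_weights)] <- trait_weights
  z <- (c(O, C, E, A, N) - cfg$means) / cfg$sds
  tibble::tibble(
    agent_id = as.character(agent_id),
    O = O, C = C, E = E, A = A, N = N,
    antisociality = antisociality,
    baseline_logit = baseline_logit,
    produce_signal = sum(w * z) + produce_noise,
    cost_sensitivity = cost_sensitivity,
    scrounge_opportunism = scrounge_opportunism,
    scrounge_cost_spillover = scrounge_cost_spillover
  )
}
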