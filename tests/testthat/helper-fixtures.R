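# Fixtures built in code: tiny deterministic cohorts and reference
# computations independent of the package internals.

# Cohort where every subject grows exactly exponentially at rate `lambda`
# (per year) in both diameter and volume (volume rate 3 * lambda on the log
# scale via the cube law), no noise of any kind.
make_exponential_cohort <- function(n_subjects = 10, lambda = 0.1,
                                    n_visits = 4, interval = 0.5,
                                    d0 = seq(35, 60, length.out = n_subjects),
                                    slope = 0.0926) {
  rows <- lapply(seq_len(n_subjects), function(i) {
    tt <- (seq_len(n_visits) - 1) * interval
    d <- d0[i] * exp(lambda * tt)
    v <- (slope * d0[i])^3 * exp(3 * lambda * tt)
    data.frame(subject_id = sprintf("E%02d", i), time_years = tt,
               diameter_mm = d, volume_ml = v)
  })
  as_cohort(do.call(rbind, rows))
}

# Reference multivariate-normal log-density computed from first principles
# (used as an oracle against the compiled likelihood).
ref_mvn_logdens <- function(x, mean, Sigma) {
  L <- t(chol(Sigma))
  u <- forwardsolve(L, x - mean)
  -0.5 * sum(u^2) - sum(log(diag(L))) - length(x) / 2 * log(2 * pi)
}

# Reference marginal log-likelihood of one subject by adaptive quadrature
# over the lognormal rate (independent of Gauss-Hermite).
ref_subject_marginal <- function(dt, dz, mu, tau, sigma_w, sigma_m) {
  f <- function(lam) {
    vapply(lam, function(l) {
      S <- sigma_w^2 * outer(dt, dt, pmin) +
        sigma_m^2 * (1 + diag(length(dt)))
      exp(ref_mvn_logdens(dz, (l - sigma_w^2 / 2) * dt, S)) *
        stats::dlnorm(l, mu, tau)
    }, numeric(1))
  }
  log(stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value)
}
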