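# Shared fixtures, computed once per test run. The reference scenario is
# the noise-free chemostat-1 preset simulation and its 12-h sampled table.

.fixtures <- new.env()

fixture_preset <- function() {
  if (is.null(.fixtures$preset)) .fixtures$preset <- load_preset("chemostat-1")
  .fixtures$preset
}

fixture_sim <- function() {
  if (is.null(.fixtures$sim)) {
    p <- fixture_preset()
    .fixtures$sim <- simulate_culture(p$config, p$producer, p$nonproducer)
  }
  .fixtures$sim
}

fixture_table <- function() {
  if (is.null(.fixtures$table))
    .fixtures$table <- sample_timeseries(fixture_sim(),
                                         noise_model(relative_sd = 0))
  .fixtures$table
}

# Monte-Carlo parameter recovery at the study's conditions (f0 = 0.15,
# 3% measurement noise, 25 measurement-noise seeds), fitted through the
# full generate -> estimate -> fit pipeline. Shared by the recovery and
# bias checks.
fixture_recovery_mc <- function() {
  if (is.null(.fixtures$mc)) {
    p <- fixture_preset()
    .fixtures$mc <- t(vapply(1:25, function(s) {
      tab <- generate_dataset("chemostat-1", seed = s, noise_sd = 0.03)
      prof <- estimate_rates(tab)
      obs <- prof[seq(1, nrow(prof), length.out = 31), c("time", "qp")]
      fit <- fit_f0(obs, p$config, p$producer, p$nonproducer)
      c(f0 = fit$f0, lo = fit$conf_int[1], hi = fit$conf_int[2])
    }, numeric(3)))
  }
  .fixtures$mc
}

# a minimal hand-built reaction_network (skips file parsing) for solver
# property tests
make_network <- function(S, measured) {
  structure(list(S = S, metabolites = NULL, reactions = NULL,
                 balanced = rownames(S), measured = measured),
            class = "reaction_network")
}

# random sparse stoichiometric system with a known steady-state flux
# vector and a spanning measured subset; used as the exact-recovery oracle
random_flux_case <- function(seed) {
  set.seed(seed)
  repeat {
    nm <- sample(3:8, 1)            # balanced metabolites
    nr <- nm + sample(1:3, 1)       # reactions
    S <- matrix(sample(c(-2, -1, 0, 0, 1, 2), nm * nr, replace = TRUE),
                nm, nr, dimnames = list(paste0("M", seq_len(nm)),
                                        paste0("R", seq_len(nr))))
    sv <- svd(S, nu = 0, nv = nr)
    d <- c(sv$d, rep(0, nr - length(sv$d)))
    K <- sv$v[, d <= max(d, 1e-12) * 1e-10, drop = FALSE]
    if (ncol(K) == 0) next
    v_true <- drop(K %*% stats::rnorm(ncol(K), sd = 2))
    names(v_true) <- colnames(S)
    # greedily pick reactions until the measured rows span the null space
    ord <- sample(nr)
    meas <- integer(0)
    for (j in ord) {
      cand <- c(meas, j)
      if (qr(K[cand, , drop = FALSE])$rank > qr(K[meas, , drop = FALSE])$rank)
        meas <- cand
      if (length(meas) == ncol(K)) break
    }
    if (length(meas) < ncol(K)) next
    return(list(net = make_network(S, colnames(S)[meas]),
                v_true = v_true,
                measured = data.frame(reaction_id = colnames(S)[meas],
                                      value = v_true[meas], se = 1)))
  }
}
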