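# Shared model builders for the test suite. All fixtures are built in code.

birth_death_network <- function(lambda = 2, gamma = 1) {
  reaction_network(
    "X",
    list(reaction(c(X = 1), "lambda"), reaction(c(X = -1), "gamma * X")),
    parameters = list(lambda = lambda, gamma = gamma))
}

# gene expression with a constant induced transcription rate u (open loop)
open_loop_gene_expression <- function(u, Delta = 0, k1 = 1, gamma1 = 1,
                                      gamma2 = 1) {
  proc <- gene_expression_process(k1, gamma1, gamma2, Delta)
  reaction_network(
    proc$species,
    c(proc$reactions, list(reaction(c(X1 = 1), function(x, t, p) u))),
    parameters = proc$parameters)
}

# canonical unsaturated antithetic loop (unit rates, setpoint 10)
basic_aif_loop <- function(Delta = 0) {
  closed_loop_aif(gene_expression_process(Delta = Delta),
                  mu = 10, theta = 1, eta = 100, k = 1)
}

hill_sats <- function() {
  make_saturations("hill", "hill", kappa_a = 5, kappa_s = 5)
}

# canonical saturated antithetic loop (theta = 15, k = 8, kappas = 5)
saturated_aif_loop <- function(mu = 10, Delta = 5) {
  closed_loop_aif(gene_expression_process(Delta = Delta),
                  mu = mu, theta = 15, eta = 100, k = 8, sats = hill_sats())
}

# canonical fast-sequestration spec of the unsaturated loop
basic_aif_spec <- function(Delta = 0, eta = 100) {
  aif_fast_seq_spec(gene_expression_process(Delta = Delta),
                    mu = 10, theta = 1, eta = eta, k = 1)
}

# random stable unimolecular network: per-species degradation plus sparse
# first-order conversions; column sums of SW stay negative, so SW is
# Metzler and Hurwitz by construction
random_unimolecular <- function(L, seed) {
  set.seed(seed)
  S <- NULL; W <- NULL; b <- numeric(0)
  add <- function(scol, wrow, basal) {
    S <<- cbind(S, scol); W <<- rbind(W, wrow); b <<- c(b, basal)
  }
  for (i in seq_len(L)) {
    scol <- numeric(L); scol[i] <- -1
    wrow <- numeric(L); wrow[i] <- runif(1, 0.5, 2)
    add(scol, wrow, 0)
  }
  n_conv <- sample(1:(2 * L), 1)
  for (r in seq_len(n_conv)) {
    ij <- sample(L, 2)
    scol <- numeric(L); scol[ij[1]] <- -1; scol[ij[2]] <- 1
    wrow <- numeric(L); wrow[ij[1]] <- runif(1, 0.1, 1)
    add(scol, wrow, 0)
  }
  # basal production into a random species
  scol <- numeric(L); scol[sample(L, 1)] <- 1
  add(scol, numeric(L), runif(1, 0, 1))
  unimolecular_process(S, W, b)
}
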