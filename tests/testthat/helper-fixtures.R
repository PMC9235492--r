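# Small deterministic fixtures and brute-force oracles shared across tests.

# All permutations of a vector (for exhaustive assignment oracles; n <= 8).
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
  }
  out
}

# Exact optimal transport between equal-size uniform clouds by exhaustive
# enumeration of assignments.
brute_force_ot <- function(a, b, p = 2) {
  C <- cost_matrix(a, b, p)
  n <- nrow(C)
  min(vapply(perms(seq_len(n)),
             function(pp) sum(C[cbind(seq_len(n), pp)]) / n, numeric(1)))
}

# A tiny survival dataset with both arms, events and censoring.
tiny_dataset <- function(n = 10, d = 3, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n)
  y <- round(runif(n, 0.5, 5), 3)
  e <- rbinom(n, 1, 0.8)
  t <- rep(c(0L, 1L), length.out = n)
  if (!any(e[t == 0] == 1)) e[which(t == 0)[1]] <- 1L
  if (!any(e[t == 1] == 1)) e[which(t == 1)[1]] <- 1L
  survival_dataset(x, y, e, t)
}

# A model whose every parameter is zero: all log-hazards are exactly 0 and
# the latent representation is constant.
zero_model <- function(cfg, d) {
  m <- build_model(cfg, d)
  m$params <- lapply(m$params, function(p) p * 0)
  m
}

# Nelson-Aalen cumulative hazard computed by a direct per-event-time loop.
nelson_aalen <- function(y, e) {
  ev <- sort(unique(y[e == 1]))
  cum <- cumsum(vapply(ev, function(u) sum(y == u & e == 1) / sum(y >= u),
                       numeric(1)))
  list(times = ev, cum_hazard = cum)
}
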