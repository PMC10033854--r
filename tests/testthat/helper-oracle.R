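# Independent scalar oracle: a literal, step-by-step R transcription of the
# tissue recurrences and the demographic sums, kept deliberately naive so it
# cannot share bugs with the package's compiled engine.

oracle_step <- function(S, D, t, alpha, gamma, sigma, r_damage) {
  a_t <- min(1, alpha * t)
  pool <- 1 - S - D
  feedback <- if (S > 0) S^r_damage else 0
  delta <- pool * a_t * (1 + feedback)
  if (delta > pool) delta <- pool
  if (pool <= 0) delta <- 0
  repl <- if (S < 1) gamma * (D + delta) * D / (1 - S) else 0
  list(
    S = S + (D + delta) * (1 - gamma) * sigma,
    D = (D + delta) * (1 - gamma) * (1 - sigma) + repl,
    delta = delta
  )
}

oracle_path <- function(alpha, gamma, sigma, r_damage, n_steps,
                        t0 = 0, S0 = 0, D0 = 0) {
  S <- numeric(n_steps + 1)
  D <- numeric(n_steps + 1)
  delta <- numeric(n_steps + 1)
  S[1] <- S0
  D[1] <- D0
  for (i in seq_len(n_steps + 1)) {
    t <- t0 + i - 1
    st <- oracle_step(S[i], D[i], t, alpha, gamma, sigma, r_damage)
    delta[i] <- st$delta
    if (i <= n_steps) {
      S[i + 1] <- st$S
      D[i + 1] <- st$D
    }
  }
  data.frame(t = t0 + 0:n_steps, S = S, D = D, delta = delta)
}

# spreadsheet-style demographic sums from an oracle path
oracle_demography <- function(path, r_cancer, r_senesc, ext_m, senesc_repro) {
  pC <- 1 - ifelse(path$D > 0, path$D^r_cancer, 0)
  pS <- 1 - ifelse(path$S > 0, path$S^r_senesc, 0)
  pE <- 1 - ext_m
  n <- nrow(path)
  lx <- numeric(n)
  lx[1] <- 1
  for (i in seq_len(n - 1)) lx[i + 1] <- lx[i] * pC[i] * pS[i] * pE
  Bx <- pmax(0, 1 - senesc_repro * path$t)
  list(pC = pC, pS = pS, lx = lx, Bx = Bx,
       lrs = sum(lx * Bx),
       prev = sum(lx * (1 - pC)))
}

# random valid cell/organism parameter draws for property sweeps
random_params <- function(n, seed) {
  set.seed(seed)
  data.frame(
    alpha = runif(n, 0, 0.05),
    gamma = runif(n),
    sigma = runif(n),
    r_damage = runif(n, 0, 10),
    r_cancer = runif(n, 0.5, 4),
    r_senesc = runif(n, 0, 8),
    ext_m = runif(n, 0, 0.2),
    senesc_repro = runif(n, 0, 0.05)
  )
}
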