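# Independent oracles used by the tests. These deliberately re-derive the
# quantities from first principles, without calling the package internals
# they are checking.

# Brute-force hydrogen-bond evaluation: reconstruct amide H positions and
# evaluate the electrostatic criterion over every donor/acceptor residue
# pair, with no neighbour bookkeeping shared with the implementation.
oracle_hbonds <- function(chain) {
  at <- chain$atoms
  get_atom <- function(r, e) {
    row <- at[at$resno == r & at$elety == e, c("x", "y", "z")]
    if (nrow(row) != 1) return(NULL)
    as.numeric(row)
  }
  n <- length(chain$resno)
  res <- list()
  for (j in seq_len(n)) {             # donor NH
    if (j == 1 || chain$resname[j] == "PRO") next
    if (!chain$complete[j] || !chain$complete[j - 1]) next
    Nj <- get_atom(j, "N")
    Cp <- get_atom(j - 1, "C"); Op <- get_atom(j - 1, "O")
    v <- Cp - Op
    Hj <- Nj + v / sqrt(sum(v^2))
    for (i in seq_len(n)) {           # acceptor C=O
      if (!chain$complete[i] || i == j || i == j - 1) next
      Ci <- get_atom(i, "C"); Oi <- get_atom(i, "O")
      E <- 27.888 * (1 / sqrt(sum((Oi - Nj)^2)) + 1 / sqrt(sum((Ci - Hj)^2)) -
                       1 / sqrt(sum((Oi - Hj)^2)) - 1 / sqrt(sum((Ci - Nj)^2)))
      if (E < -0.5)
        res[[length(res) + 1L]] <- c(donor = j, acceptor = i, energy = E)
    }
  }
  if (!length(res))
    return(data.frame(donor = integer(), acceptor = integer(),
                      energy = numeric()))
  out <- as.data.frame(do.call(rbind, res))
  out[order(out$donor, out$acceptor), ]
}

# Exact two-tailed Mann-Whitney p-value by full enumeration of all
# choose(n + m, n) rank assignments.
oracle_mw_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_stat(x, y)
  pooled <- c(x, y)
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Single-site isotherm oracle: solves the binding mass balance
# Kd = (N*M - B)(X - B)/B for bound-site concentration B by bisection at
# each injection, using the same perfusion bookkeeping the model states.
oracle_titration_heats <- function(k_d, n_sites, delta_h, schedule,
                                   cell_conc, syringe_conc, cell_vol = 200) {
  v <- cumsum(schedule)
  M <- cell_conc * (1 - v / (2 * cell_vol)) / (1 + v / (2 * cell_vol))
  X <- syringe_conc * (v / cell_vol) / (1 + v / (2 * cell_vol))
  bound <- vapply(seq_along(v), function(i) {
    s <- n_sites * M[i]
    f <- function(B) B * k_d - (s - B) * (X[i] - B)
    lo <- 0; hi <- min(s, X[i])
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  Q <- bound * cell_vol * delta_h * 1e-3
  Qprev <- c(0, Q[-length(Q)])
  Q - Qprev + (schedule / cell_vol) * (Q + Qprev) / 2
}

# random rigid-body transform (deterministic in seed)
random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  qr.Q(qr(m)) * sign(det(qr.Q(qr(m))))
}

h3_wt <- "ARTKQTARKS"
h3_aa <- "ARTAATARKS"
h3_gg <- "ARTGGTARKS"
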