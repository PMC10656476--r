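# Independent oracles, written directly from the definitions and kept free
# of any package internals they are used to check.

# life expectancy by explicit year-by-year bookkeeping
oracle_e0 <- function(q) {
  l <- 1
  total <- 0
  n <- length(q)
  for (i in seq_len(n)) {
    if (i < n) {
      d <- l * q[i]
      total <- total + (l - 0.5 * d)
      l <- l - d
    } else if (l > 0 && q[i] > 0) {
      total <- total + l * (1 - 0.5 * q[i]) / q[i]
    }
  }
  total
}

# proportional cutback of the surplus side, straight from the ratio
# definition, for one vector of provincial flows
oracle_cutback <- function(x) {
  sp <- sum(x[x > 0])
  sn <- -sum(x[x < 0])
  if (sp == 0 && sn == 0) return(x)
  f <- min(sp, sn) / max(sp, sn)
  if (sp > sn) {
    ifelse(x > 0, x * f, x)
  } else if (sn > sp) {
    ifelse(x < 0, x * f, x)
  } else {
    x
  }
}

# two-sex Leslie matrix for a single closed city: state vector
# [F ages 0..100, M ages 0..100]; births from previous-year females with no
# infant survival factor; survivors of the open interval stay in it.
oracle_leslie <- function(asfr_by_age, qx_f, qx_m, srb) {
  n <- 101
  A <- matrix(0, 2 * n, 2 * n)
  bf <- 1 / (1 + srb)
  bm <- srb / (1 + srb)
  for (a in 15:49) {
    A[1, a + 1] <- asfr_by_age[as.character(a)] * bf
    A[n + 1, a + 1] <- asfr_by_age[as.character(a)] * bm
  }
  for (a in 0:99) {
    A[a + 2, a + 1] <- 1 - qx_f[a + 1]
    A[n + a + 2, n + a + 1] <- 1 - qx_m[a + 1]
  }
  A[n, n] <- A[n, n] + (1 - qx_f[n])
  A[2 * n, 2 * n] <- A[2 * n, 2 * n] + (1 - qx_m[n])
  A
}

# state vector for oracle_leslie from a population_state with one city
leslie_vec <- function(state) {
  d <- tibble::as_tibble(state)
  d <- d[order(d$sex, d$age), ]  # F block first (F < M alphabetically)
  d$population
}
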