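# Period life table from single-year death probabilities, and the inverse
# problem: scale a mortality schedule so its life expectancy hits a target.

# Full life-table columns for a q_x schedule whose last entry is the open
# interval.  a_x = 0.5 throughout; the open interval uses L = l / m with the
# central rate m recovered from q via m = q / (1 - 0.5 q).
.life_table <- function(qx) {
  qx <- as.numeric(qx)
  if (anyNA(qx) || any(qx < 0 | qx > 1)) {
    abort_validation("death probabilities q must lie in [0, 1]")
  }
  n <- length(qx)
  lx <- cumprod(c(1, 1 - qx))        # length n + 1; lx[n] reaches open age
  dx <- lx[seq_len(n)] * qx
  Lx <- numeric(n)
  closed <- seq_len(n - 1L)
  Lx[closed] <- lx[closed] - 0.5 * dx[closed]
  l_open <- lx[n]
  q_open <- qx[n]
  if (l_open <= 0) {
    Lx[n] <- 0
  } else if (q_open <= 0) {
    Lx[n] <- Inf                      # nobody ever dies in the open interval
  } else {
    m_open <- q_open / (1 - 0.5 * q_open)
    Lx[n] <- l_open / m_open
  }
  list(qx = qx, lx = lx[seq_len(n)], dx = dx, Lx = Lx)
}

#' Life expectancy at birth from a single-year mortality schedule
#'
#' Standard period life table: survivorship `l_{x+1} = l_x (1 - q_x)`,
#' person-years `L_x = l_{x+1} + 0.5 d_x` in closed intervals, and for the
#' final open interval `L = l / m` with the central death rate `m` derived
#' from `q`.  `e0` is total person-years per birth.
#'
#' @param qx Numeric vector of annual death probabilities in `[0, 1]`; the
#'   last element is the open age interval (by convention `100+`).
#' @return Life expectancy at birth in years.
#' @examples
#' life_expectancy(c(1, rep(0, 100)))  # everyone dies in year one -> 0.5
#' @export
life_expectancy <- function(qx) {
  lt <- .life_table(qx)
  sum(lt$Lx)
}

#' Scale a mortality schedule to hit a life-expectancy target
#'
#' Finds a scalar multiplier `k > 0` such that the schedule
#' `q'_x = min(1, k q_x)` has `life_expectancy(q')` within `tol` years of
#' `target` (proportional scaling of death probabilities, a one-parameter
#' monotone family; `k < 1` raises life expectancy).  `k` is solved by
#' bisection.
#'
#' @param qx Baseline death probabilities (last element open interval).
#' @param target Target life expectancy at birth, years.
#' @param tol Convergence tolerance on achieved `e0`, years (default 0.01).
#' @param k_range Search bracket for the multiplier.
#' @return The scaled schedule, with attributes `k` (the multiplier) and
#'   `e0` (the achieved life expectancy).
#' @examples
#' q <- 1 - exp(-5e-5 * exp(0.1 * (0:100)))
#' q2 <- mortality_for_target(q, life_expectancy(q) + 5)
#' attr(q2, "k") < 1
#' @export
mortality_for_target <- function(qx, target, tol = 0.01,
                                 k_range = c(1e-6, 1e3)) {
  target <- .check_scalar_number(target, "target", min = 0)
  e_at <- function(k) life_expectancy(pmin(1, k * qx))
  lo <- k_range[1]; hi <- k_range[2]
  e_lo <- e_at(lo); e_hi <- e_at(hi)   # e is decreasing in k
  if (target > e_lo || target < e_hi) {
    abort_citypop(sprintf(
      paste0("life-expectancy target %.2f is outside the achievable range ",
             "[%.2f, %.2f] for multipliers in [%g, %g]"),
      target, e_hi, e_lo, lo, hi))
  }
  k <- 1; e_k <- e_at(k)
  if (!(e_k <= e_lo && e_k >= e_hi)) k <- sqrt(lo * hi)
  for (i in 1:200) {
    e_k <- e_at(k)
    if (is.finite(e_k) && abs(e_k - target) <= tol) break
    if (e_k > target) lo <- k else hi <- k
    k <- (lo + hi) / 2
    if ((hi - lo) < 1e-14 * hi) {
      e_k <- e_at(k)
      if (abs(e_k - target) > tol) {
        abort_citypop("bisection for the mortality multiplier failed to converge")
      }
      break
    }
  }
  out <- pmin(1, k * qx)
  attr(out, "k") <- k
  attr(out, "e0") <- e_k
  out
}
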