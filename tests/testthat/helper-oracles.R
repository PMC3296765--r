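## Independent re-implementations used as oracles. These deliberately
## take different computational routes from the package code (explicit
## loops, geometric construction, finite differences, closed forms) so
## that agreement is informative.

## Midpoint of the segment of the line y = m x bounded by the two
## projections of the observation (C, T): constructed point-wise.
oracleMidpoint <- function(C, T, m) {
  p1 <- c(x = C, y = C * m)
  p2 <- c(x = T / m, y = T)
  mid <- (p1 + p2) / 2
  c(mu_C = unname(mid["x"]), mu_T = unname(mid["y"]))
}

## Literal sum over the two observations of (x - mu)^2 / sigma^2 with
## the Poisson + relative non-Poisson composition.
oracleChi2 <- function(C, T, m, sC, sT) {
  mu <- oracleMidpoint(C, T, m)
  x <- c(C, T)
  sig <- c(sC, sT)
  tot <- 0
  for (i in 1:2) {
    v <- mu[i] + (sig[i] * mu[i])^2
    tot <- tot + (x[i] - mu[i])^2 / v
  }
  if (mu[1] == 0 && mu[2] == 0) 0 else unname(tot)
}

## Sample variance via the explicit n-1 sum, then the clamped split.
oracleRepSD <- function(counts) {
  n <- length(counts)
  R <- sum(counts) / n
  ss <- 0
  for (x in counts) ss <- ss + (x - R)^2
  v <- ss / (n - 1)
  s2 <- max(0, v - R)
  c(sigma_m = if (R > 0) sqrt(s2) / R else 0, R = R)
}

## Error propagation through f(C, T) = log2(T / C) by central finite
## differences instead of the analytic derivative.
oracleFoldChangeSigma <- function(Cn, Tn, sC, sT, h = 1e-5) {
  f <- function(C, T) log2(T / C)
  dT <- (f(Cn, Tn + h) - f(Cn, Tn - h)) / (2 * h)
  dC <- (f(Cn + h, Tn) - f(Cn - h, Tn)) / (2 * h)
  sdT <- sqrt(Tn + (sT * Tn)^2)
  sdC <- sqrt(Cn + (sC * Cn)^2)
  sqrt((dT * sdT)^2 + (dC * sdC)^2)
}

## Fisher's method for k = 2 via the closed form P(1 - ln P), P = p1 p2
## (the survival function of the product of two uniforms).
oracleFisher2 <- function(p1, p2) {
  P <- p1 * p2
  P * (1 - log(P))
}
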