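# Independent transcription of the disease-model equations, written
# directly from the model table, term by term.  Used to pin lupus_rhs().
oracle_rhs <- function(t, st, p, poly_on, poly_off,
                       m_tilc = 1, m_vnk = 1, xon = 0) {
  h <- function(x, K) x^3 / (K^3 + x^3)
  x1 <- st[1]; x2 <- st[2]; x3 <- st[3]; x4 <- st[4]; x5 <- st[5]
  x6 <- st[6]; x7 <- st[7]; x8 <- st[8]; x9 <- st[9]
  n <- p$n_ic
  y <- st[9 + 1:n]
  c1 <- st[10 + n]; c2 <- st[11 + n]; c3 <- st[12 + n]; c4 <- st[13 + n]
  ind <- as.numeric(t >= poly_on & t <= poly_off)
  cifn <- min(p$q0 + p$q1 * ind +
                p$q2 * (p$zeta4 * h(x9, p$K2) + p$zeta1 * h(x8, p$K2)), 1)
  act <- p$alpha * min(h(cifn, p$K1) + p$zeta2 * h(x8, p$K2), 1)
  c(p$gamma * (1 - (x1 + x2) / (p$omega * m_tilc)) * (x1 + x2) -
      act * x1 - p$delta * x1,
    act * x1 - p$delta * x2,
    p$beta * min(h(x2, p$K2) + p$zeta3 * h(x9, p$K2), 1) +
      p$gamma * h(c2, p$K2) * x3 - p$delta * x3,
    (p$beta + p$gamma * h(c1, p$K2) * x4) * (1 - x4 / p$omega) - p$delta * x4,
    p$beta * h(x6, p$K3) * m_vnk - p$delta * x5,
    p$beta * min(p$zeta5 * h(x9, p$K2) + p$vartheta * h(cifn, p$K1), 1) +
      p$gamma * h(c4, p$K2) * x6 - p$delta * x6,
    (p$beta + p$gamma * h(c3, p$K2) * x7) * (1 - x7 / p$omega) - p$delta * x7,
    p$mu1 * (x3 + x5 + x6) - p$nu1 * x8,
    p$mu2 * (xon + y[n]) - p$nu2 * x9,
    p$mu2 * (c(x8, y[-n]) - y),
    p$q * x3 - p$lambda * h(c1, p$K2) * x4 - p$eta * c1,
    p$q * x4 - p$lambda * h(c2, p$K2) * x3 - p$eta * c2,
    p$q * x6 - p$lambda * h(c3, p$K2) * x7 - p$eta * c3,
    p$q * x7 - p$lambda * h(c4, p$K2) * x6 - p$eta * c4)
}
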