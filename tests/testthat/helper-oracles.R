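# Independent naive-loop oracles for the feature formulas. These deliberately
# avoid vectorised shortcuts so they share no code path with the package.

oracle_time_domain <- function(rr) {
  n <- length(rr)
  s <- 0
  for (v in rr) s <- s + v
  m <- s / n
  ss <- 0
  for (v in rr) ss <- ss + (v - m)^2
  sdnn <- sqrt(ss / n)
  sd2sum <- 0
  cnt50 <- 0
  for (i in 1:(n - 1)) {
    d <- rr[i + 1] - rr[i]
    sd2sum <- sd2sum + d^2
    if (abs(d) > 50) cnt50 <- cnt50 + 1
  }
  list(mean_nn = m, sdnn = sdnn, rmssd = sqrt(sd2sum / (n - 1)),
       pnn50 = 100 * cnt50 / n)
}

oracle_poincare <- function(rr) {
  n <- length(rr)
  d <- numeric(n - 1)
  for (i in 1:(n - 1)) d[i] <- rr[i] - rr[i + 1]
  md <- 0
  for (v in d) md <- md + v
  md <- md / length(d)
  vd <- 0
  for (v in d) vd <- vd + (v - md)^2
  vd <- vd / length(d)
  sd1 <- sqrt(vd / 2)
  m <- 0
  for (v in rr) m <- m + v
  m <- m / n
  vv <- 0
  for (v in rr) vv <- vv + (v - m)^2
  vv <- vv / n
  rad <- 2 * vv - sd1^2
  if (rad < 0) rad <- 0
  list(sd1 = sd1, sd2 = sqrt(rad))
}

oracle_qrs_shape <- function(areas, amps) {
  n <- length(areas)
  am <- 0
  for (a in areas) am <- am + abs(a)
  am <- am / n
  av <- 0
  for (a in areas) av <- av + (abs(a) - am)^2
  pm <- 0
  for (a in amps) pm <- pm + a
  pm <- pm / n
  pv <- 0
  for (a in amps) pv <- pv + (a - pm)^2
  list(qrsam = am, qrsasd = sqrt(av / n),
       rpampm = pm, rpampsd = sqrt(pv / n))
}

# Rank-based (Mann-Whitney) AUC, the independent cross-check for the
# trapezoidal ROC integration.
oracle_rank_auc <- function(scores, truth) {
  pos <- scores[truth == "VF"]
  neg <- scores[truth != "VF"]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Small helper: a trimmed synthetic record with its truth attribute.
make_test_record <- function(seed = 1, duration = 125, fs = 250,
                             params = group_params(mean_rr = 800,
                                                   r_amp_base = 1000)) {
  rr <- generate_rr(params, duration = duration, seed = seed)
  synthesize_ecg(rr, params, fs = fs, seed = seed + 1)
}
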