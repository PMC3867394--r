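# Independent brute-force oracles for the pooling formulas, written as
# plain loops over the printed definitions. They share no code with the
# package implementation.

oracle_mh <- function(tables) {
  num <- 0
  den <- 0
  for (i in seq_len(nrow(tables))) {
    n <- tables$a[i] + tables$b[i] + tables$c[i] + tables$d[i]
    num <- num + tables$a[i] * tables$d[i] / n
    den <- den + tables$b[i] * tables$c[i] / n
  }
  num / den
}

oracle_iv <- function(y, se) {
  sw <- 0
  swy <- 0
  for (i in seq_along(y)) {
    w <- 1 / se[i]^2
    sw <- sw + w
    swy <- swy + w * y[i]
  }
  list(log_or = swy / sw, se = sqrt(1 / sw))
}

oracle_q <- function(y, se) {
  mu <- oracle_iv(y, se)$log_or
  q <- 0
  s1 <- 0
  s2 <- 0
  for (i in seq_along(y)) {
    w <- 1 / se[i]^2
    q <- q + w * (y[i] - mu)^2
    s1 <- s1 + w
    s2 <- s2 + w^2
  }
  tau2 <- (q - (length(y) - 1)) / (s1 - s2 / s1)
  list(q = q, tau2 = max(0, tau2))
}

oracle_dl <- function(y, se) {
  tau2 <- oracle_q(y, se)$tau2
  sw <- 0
  swy <- 0
  for (i in seq_along(y)) {
    w <- 1 / (se[i]^2 + tau2)
    sw <- sw + w
    swy <- swy + w * y[i]
  }
  list(log_or = swy / sw, se = sqrt(1 / sw))
}

# Effect-estimate data frame from raw vectors, for pooling/bias inputs.
make_effects <- function(log_or, se, ids = sprintf("s%02d", seq_along(log_or))) {
  data.frame(study_id = ids, log_or = log_or, se = se,
             or = exp(log_or),
             ci_low = exp(log_or - 1.96 * se),
             ci_high = exp(log_or + 1.96 * se),
             corrected = FALSE, stringsAsFactors = FALSE)
}

# Small random 2x2 table sets with single-digit-capable cells (no zeros).
random_tables <- function(k, max_cell = 9L) {
  data.frame(
    study_id = sprintf("r%02d", seq_len(k)),
    a = sample.int(max_cell, k, replace = TRUE),
    b = sample.int(max_cell, k, replace = TRUE),
    c = sample.int(max_cell, k, replace = TRUE),
    d = sample.int(max_cell, k, replace = TRUE),
    corrected = FALSE,
    stringsAsFactors = FALSE
  )
}

fixture_studies <- function() mcp1_studies()
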