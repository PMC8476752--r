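# Independent oracles: literal transcriptions of the defining formulas,
# deliberately written as plain loops so they share no code path with the
# package implementations they check.

# running-sum enrichment score, position by position
ssgsea_oracle <- function(expr, genes, alpha = 0.25) {
  N <- length(expr)
  ord <- order(expr, decreasing = TRUE)
  r <- N + 1 - rank(expr, ties.method = "average")
  in_set <- names(expr) %in% genes
  m <- sum(in_set)
  denom_in <- sum(r[in_set]^alpha)
  es <- 0
  cum_in <- 0
  cum_out <- 0
  for (i in seq_len(N)) {
    g <- ord[i]
    if (in_set[g]) cum_in <- cum_in + unname(r[g])^alpha else cum_out <- cum_out + 1
    es <- es + (cum_in / denom_in - cum_out / (N - m))
  }
  es
}

# Breslow log partial likelihood evaluated on a grid of beta values
breslow_loglik_grid <- function(beta_grid, x, time, event) {
  ll <- numeric(length(beta_grid))
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    for (k in seq_along(beta_grid)) {
      b <- beta_grid[k]
      ll[k] <- ll[k] + b * x[i] - log(sum(exp(b * x[risk])))
    }
  }
  ll
}

cox_grid_oracle <- function(x, time, event, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  grid[which.max(breslow_loglik_grid(grid, x, time, event))]
}

# concordance by exhaustive pair enumeration
brute_c_index <- function(risk, time, event) {
  num <- 0
  den <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      earlier <- event[i] == 1 &&
        (time[i] < time[j] || (time[i] == time[j] && event[j] == 0))
      if (!earlier) next
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# AUC by exhaustive positive/negative pair counting
brute_auc <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + (p > q) + 0.5 * (p == q)
    }
  }
  s / (length(pos) * length(neg))
}

# exhaustive cutpoint scan driven by survival::survdiff
cutpoint_scan_oracle <- function(score, time, event, minprop = 0.1) {
  n <- length(score)
  us <- sort(unique(score))
  cand <- (us[-length(us)] + us[-1]) / 2
  cand <- cand[vapply(cand, function(cc)
    min(sum(score <= cc), sum(score > cc)) >= minprop * n, logical(1))]
  chi <- vapply(cand, function(cc) {
    survival::survdiff(survival::Surv(time, event) ~ (score > cc))$chisq
  }, numeric(1))
  best <- which.max(chi) # which.max takes the first maximum = lowest candidate
  list(cutoff = cand[best], max_stat = sqrt(chi[best]))
}

# random right-censored survival instance
rand_surv <- function(n, cens_frac = 0.3, tie_free = TRUE) {
  time <- if (tie_free) rexp(n) else sample(1:4, n, replace = TRUE)
  event <- as.integer(runif(n) > cens_frac)
  if (sum(event) == 0) event[sample(n, 1)] <- 1L
  list(time = time, event = event)
}
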