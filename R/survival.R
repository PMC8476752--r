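#' Validate a clinical table
#'
#' Checks the package's clinical-table contract: columns `sample` (unique
#' IDs), `time` (overall-survival time, positive and finite, in
#' cohort-local units), `event` (1 = death observed, 0 = censored). Any extra
#' columns are carried along as per-sample annotations.
#'
#' @param df A data.frame.
#' @return `df`, with `sample` as character and `event` as integer.
#' @export
clinicalTable <- function(df) {
  req <- c("sample", "time", "event")
  if (!is.data.frame(df) || !all(req %in% names(df))) {
    stop("clinical table needs columns 'sample', 'time', 'event'")
  }
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) stop("duplicate sample identifiers in clinical table")
  if (any(!is.finite(df$time)) || any(df$time <= 0)) {
    stop("survival times must be positive and finite")
  }
  ev <- df$event
  if (!all(ev %in% c(0, 1))) stop("event must be 0 (censored) or 1 (death)")
  df$event <- as.integer(ev)
  df
}

#' Read a clinical table from TSV
#'
#' Tab-delimited with header; required columns `sample`, `time`, `event`;
#' extra columns become annotations.
#'
#' @param path Input path.
#' @return A validated clinical data.frame.
#' @export
readClinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  clinicalTable(utils::read.delim(path, sep = "\t", header = TRUE,
                                  check.names = FALSE, stringsAsFactors = FALSE))
}

# log partial likelihood, score vector and observed information at beta;
# risk-set sums come from reverse-time cumulative sums, O(n p^2 + n log n)
cox_partial <- function(beta, x, time, event, ties) {
  p <- ncol(x)
  n <- nrow(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ord <- order(time, decreasing = TRUE)
  tt <- time[ord]; ee <- event[ord]
  xx <- x[ord, , drop = FALSE]
  ww <- w[ord]; et <- eta[ord]
  cs0 <- cumsum(ww)
  cs1 <- apply(ww * xx, 2L, cumsum)
  if (is.null(dim(cs1))) cs1 <- matrix(cs1, nrow = n)
  cs2 <- array(0, c(n, p, p))
  for (a in seq_len(p)) {
    for (b in a:p) {
      v <- cumsum(ww * xx[, a] * xx[, b])
      cs2[, a, b] <- v
      cs2[, b, a] <- v
    }
  }
  ll <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  # times sorted descending => equal times are contiguous blocks
  grp <- split(seq_len(n), match(tt, unique(tt)))
  for (g in grp) {
    D <- g[ee[g] == 1L]
    d <- length(D)
    if (d == 0L) next
    last <- g[length(g)] # risk set = positions 1..last (time >= this time)
    s0 <- cs0[last]
    s1 <- cs1[last, ]
    s2 <- matrix(cs2[last, , ], p, p)
    xD <- xx[D, , drop = FALSE]
    ll <- ll + sum(et[D])
    U <- U + colSums(xD)
    if (ties == "breslow") {
      ll <- ll - d * log(s0)
      U <- U - d * s1 / s0
      I <- I + d * (s2 / s0 - tcrossprod(s1 / s0))
    } else { # efron
      wD <- ww[D]
      s0d <- sum(wD)
      s1d <- colSums(wD * xD)
      s2d <- crossprod(xD, wD * xD)
      for (l in seq_len(d) - 1L) {
        f <- l / d
        s0l <- s0 - f * s0d
        s1l <- s1 - f * s1d
        s2l <- s2 - f * s2d
        ll <- ll - log(s0l)
        U <- U - s1l / s0l
        I <- I + s2l / s0l - tcrossprod(s1l / s0l)
      }
    }
  }
  list(loglik = ll, score = U, info = I)
}

#' Cox proportional hazards regression by Newton-Raphson
#'
#' Maximizes the Cox partial likelihood with the Efron (default) or Breslow
#' correction for tied death times. Convergence when the score vector's
#' largest component falls below 1e-9 or the log-likelihood change below
#' 1e-12. Standard errors come from the inverse observed information;
#' p-values are two-sided Wald. A monotone likelihood (perfect separation,
#' diverging coefficient) is flagged via `converged = FALSE` with a warning,
#' never silently.
#'
#' @param x Numeric covariate vector or samples-by-p matrix; no covariate may
#'   be constant.
#' @param time,event Survival time and event indicator (1 = death), parallel
#'   to the rows of `x`. At least one event is required.
#' @param ties `"efron"` or `"breslow"`. Efron is the default: ICP scores are
#'   small integers, so death-time ties among equal scores are common and
#'   Efron's correction is markedly less biased.
#' @return A list of class `"coxFit"`: `beta`, `hr = exp(beta)`, `se`, `z`,
#'   `wald_p`, `loglik`, `loglik_null`, `n`, `n_events`, `iter`, `converged`.
#' @examples
#' set.seed(7)
#' xx <- rnorm(60)
#' tt <- rexp(60, exp(0.8 * xx))
#' coxFit(xx, tt, rep(1, 60))$hr
#' @export
coxFit <- function(x, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  event <- as.integer(event)
  n <- nrow(x)
  if (length(time) != n || length(event) != n) stop("length mismatch")
  if (sum(event) == 0L) stop("no events; Cox model cannot be fitted")
  if (any(apply(x, 2L, function(v) max(v) == min(v)))) {
    stop("constant covariate; Cox model cannot be fitted")
  }
  p <- ncol(x)
  # center covariates for numerical stability; beta is unaffected
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  beta <- numeric(p)
  fit0 <- cox_partial(beta, xc, time, event, ties)
  ll_null <- fit0$loglik
  cur <- fit0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(100L)) {
    step <- tryCatch(solve(cur$info, cur$score), error = function(e) NULL)
    if (is.null(step)) break
    cand <- beta + step
    new <- cox_partial(cand, xc, time, event, ties)
    halvings <- 0L
    while ((!is.finite(new$loglik) || new$loglik < cur$loglik) && halvings < 30L) {
      cand <- (beta + cand) / 2
      new <- cox_partial(cand, xc, time, event, ties)
      halvings <- halvings + 1L
    }
    delta_ll <- new$loglik - cur$loglik
    beta <- cand
    cur <- new
    if (max(abs(cur$score)) < 1e-9 || abs(delta_ll) < 1e-12) {
      converged <- TRUE
      break
    }
  }
  if (any(abs(beta) > 15)) converged <- FALSE
  if (!converged) {
    warning("Cox fit did not converge (possible monotone likelihood / separation)")
  }
  vcov <- tryCatch(solve(cur$info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  z <- beta / se
  out <- list(beta = beta, hr = exp(beta), se = se, z = z,
              wald_p = 2 * stats::pnorm(-abs(z)),
              loglik = cur$loglik, loglik_null = ll_null,
              n = n, n_events = sum(event), iter = iter,
              converged = converged, ties = ties)
  class(out) <- "coxFit"
  out
}

#' @export
print.coxFit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): n=%d, events=%d, loglik=%.4f%s\n",
              x$ties, x$n, x$n_events, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(data.frame(beta = x$beta, hr = x$hr, se = x$se, p = x$wald_p))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Over all comparable pairs — subject i usable as the earlier subject only
#' if `event_i = 1` and either `time_i < time_j`, or `time_i = time_j` with
#' `event_j = 0` — a pair is concordant when the earlier-failing subject has
#' the higher risk; tied risks count 0.5. C = 0.5 is uninformative, 1 is
#' perfect risk ordering.
#'
#' @param risk Per-sample risk score (higher = worse predicted outcome).
#' @param time,event Survival data parallel to `risk`.
#' @return C in `[0, 1]`.
#' @export
harrellC <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  concordance_with_mask(risk, concordance_mask(time, event))
}

# comparable-pair mask: [i, j] TRUE when i is usable as the earlier subject
concordance_mask <- function(time, event) {
  n <- length(time)
  event <- as.integer(event)
  lt <- outer(time, time, "<")
  eqt <- outer(time, time, "==")
  comp <- (event == 1L) & (lt | (eqt & outer(rep(TRUE, n), event == 0L, "&")))
  diag(comp) <- FALSE
  comp
}

concordance_with_mask <- function(risk, comp) {
  npairs <- sum(comp)
  if (npairs == 0L) stop("no comparable pairs; concordance is undefined")
  gt <- outer(risk, risk, ">")
  eq <- outer(risk, risk, "==")
  (sum(comp & gt) + 0.5 * sum(comp & eq)) / npairs
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square with the hypergeometric variance at each
#' distinct death time. Also returns the signed standardized statistic
#' `z = (O - E)/sqrt(V)` for the group labelled `TRUE`/second level
#' (positive z: that group dies faster), which is what maximally selected
#' cutpoint scanning uses.
#'
#' @param group Logical (or two-level coercible) group membership.
#' @param time,event Survival data parallel to `group`.
#' @return List: `chi2`, `p`, `z`, `obs`, `expected` (observed/expected
#'   deaths in the `TRUE` group).
#' @export
logrankTest <- function(group, time, event) {
  if (!is.logical(group)) {
    lv <- unique(group)
    if (length(lv) > 2L) stop("log-rank test supports exactly two groups")
    group <- group == sort(lv)[length(lv)]
  }
  event <- as.integer(event)
  if (sum(group) == 0L || sum(!group) == 0L) stop("both groups must be non-empty")
  if (sum(event) == 0L) stop("no events; log-rank test is undefined")
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1L]))) {
    at <- time >= t
    nt <- sum(at)
    n1 <- sum(at & group)
    dd <- (time == t) & (event == 1L)
    d <- sum(dd)
    d1 <- sum(dd & group)
    O <- O + d1
    E <- E + d * n1 / nt
    if (nt > 1L) {
      V <- V + d * (n1 / nt) * (1 - n1 / nt) * (nt - d) / (nt - 1)
    }
  }
  if (V <= 0) return(list(chi2 = 0, p = 1, z = 0, obs = O, expected = E))
  z <- (O - E) / sqrt(V)
  chi2 <- z^2
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       z = z, obs = O, expected = E)
}

# product-limit estimator; `event` marks the terminating event of interest
product_limit <- function(time, event) {
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1L), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event, surv = surv)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator. Censored-only times appear in the risk-set
#' accounting but do not change the survival estimate; at tied
#' death/censoring times deaths are counted first (standard risk-set
#' convention).
#'
#' @param time,event Survival data.
#' @return A list of class `"kmCurve"`: `time` (distinct observed times,
#'   ascending), `n_risk`, `n_event`, `surv` (step-function values; S(0)=1).
#' @export
kmCurve <- function(time, event) {
  if (length(time) == 0L) stop("empty survival data")
  event <- as.integer(event)
  if (sum(event) == 0L) stop("no events; Kaplan-Meier curve is degenerate")
  tab <- product_limit(time, event)
  out <- list(time = tab$time, n_risk = tab$n_risk,
              n_event = tab$n_event, surv = tab$surv)
  class(out) <- "kmCurve"
  out
}

#' @export
print.kmCurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d distinct time(s), final S = %.3f\n",
              length(x$time), x$surv[length(x$surv)]))
  invisible(x)
}

# evaluate a KM step function at arbitrary times; left = left-continuous limit
km_eval <- function(km, t, left = FALSE) {
  vapply(t, function(tt) {
    idx <- if (left) which(km$time < tt) else which(km$time <= tt)
    if (length(idx) == 0L) 1 else km$surv[max(idx)]
  }, numeric(1))
}

#' Maximally selected log-rank cutpoint
#'
#' Scans midpoints between consecutive distinct score values that leave at
#' least `minprop * n` samples on each side, computes the standardized
#' two-group log-rank statistic for each split (low: `score <= c`, high:
#' `score > c`), and returns the candidate maximizing the absolute
#' statistic; ties are broken toward the lower candidate. This is the
#' survminer/maxstat-style dichotomization used to split cohorts into
#' high/low score groups.
#'
#' @param score Per-sample numeric score (>= 2 distinct values).
#' @param time,event Survival data parallel to `score`.
#' @param minprop Minimum fraction of samples on each side of the cut, in
#'   (0, 0.5). Default 0.1, the cutpoint tool's conventional default.
#' @return A list of class `"cutpointResult"`: `cutoff`, `max_stat` (the
#'   maximal absolute standardized statistic), `candidates` (data.frame of
#'   candidate cutoffs and their signed statistics).
#' @export
maxSelCutpoint <- function(score, time, event, minprop = 0.1) {
  n <- length(score)
  stopifnot(length(time) == n, length(event) == n)
  if (!(minprop > 0 && minprop < 0.5)) stop("'minprop' must be in (0, 0.5)")
  us <- sort(unique(score))
  if (length(us) < 2L) stop("need >= 2 distinct score values to find a cutpoint")
  cand <- (us[-length(us)] + us[-1]) / 2
  ok <- vapply(cand, function(cc) {
    min(sum(score <= cc), sum(score > cc)) >= minprop * n
  }, logical(1))
  cand <- cand[ok]
  if (length(cand) == 0L) {
    stop(sprintf("no candidate cutpoint leaves >= %g%% of samples on each side",
                 100 * minprop))
  }
  stat <- vapply(cand, function(cc) logrankTest(score > cc, time, event)$z,
                 numeric(1))
  best <- which.max(abs(stat)) # first (lowest candidate) wins ties
  out <- list(cutoff = cand[best], max_stat = abs(stat[best]),
              candidates = data.frame(cutoff = cand, stat = stat))
  class(out) <- "cutpointResult"
  out
}

#' @export
print.cutpointResult <- function(x, ...) {
  cat(sprintf("Maximally selected cutpoint: %.4g (|standardized log-rank| = %.3f, %d candidate(s))\n",
              x$cutoff, x$max_stat, nrow(x$candidates)))
  invisible(x)
}

#' ROC AUC by the Mann-Whitney statistic
#'
#' Probability that a randomly chosen positive sample scores above a randomly
#' chosen negative one, with 0.5 credit for ties; equivalently the area under
#' the empirical ROC curve.
#'
#' @param score Per-sample numeric score.
#' @param label Binary labels (logical or 0/1); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(score, label) {
  label <- as.logical(label)
  if (anyNA(label)) stop("labels must be binary (0/1 or logical)")
  n1 <- sum(label)
  n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(score, ties.method = "average")
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Time-dependent AUC at a horizon (cumulative/dynamic, IPCW)
#'
#' Cases are subjects with an observed death by time `t`; controls are
#' subjects still at risk beyond `t`. Pairs are weighted by inverse
#' probabilities of censoring from the Kaplan-Meier estimate of the censoring
#' distribution (cases at the left limit of their death time, controls at
#' `t`), which removes the bias censored-before-`t` subjects would otherwise
#' induce. With no censoring every weight is 1 and the estimate reduces to
#' [rocAuc()] against the event-by-`t` label.
#'
#' @param score Per-sample risk score (higher = earlier death predicted).
#' @param time,event Survival data.
#' @param t Horizon, in the cohort's time units.
#' @return Weighted AUC in `[0, 1]`.
#' @export
aucAtHorizon <- function(score, time, event, t) {
  event <- as.integer(event)
  cases <- which(time <= t & event == 1L)
  controls <- which(time > t)
  if (length(cases) == 0L) stop(sprintf("no events observed by horizon t=%g", t))
  if (length(controls) == 0L) stop(sprintf("no subjects at risk beyond horizon t=%g", t))
  cens_km <- product_limit(time, 1L - event)
  g_case <- km_eval(cens_km, time[cases], left = TRUE)
  g_ctrl <- km_eval(cens_km, t, left = FALSE)
  if (any(g_case <= 0) || g_ctrl <= 0) {
    stop(sprintf("censoring survival reaches 0 before horizon t=%g; AUC undefined", t))
  }
  wi <- 1 / g_case
  wj <- rep(1 / g_ctrl, length(controls))
  si <- score[cases]
  sj <- score[controls]
  conc <- outer(si, sj, ">") + 0.5 * outer(si, sj, "==")
  sum(outer(wi, wj) * conc) / (sum(wi) * sum(wj))
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y Numeric vectors, length >= 3, both non-constant.
#' @return List: `r` (Pearson correlation), `p` (two-sided t-distribution
#'   p-value).
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need n >= 3")
  if (max(x) == min(x) || max(y) == min(y)) stop("constant input; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Compare a numeric value between groups
#'
#' Wilcoxon rank-sum (normal approximation with tie correction, no
#' continuity correction; exactly two groups) or Kruskal-Wallis (two or
#' more groups).
#'
#' @param values Per-sample numeric values.
#' @param groups Per-sample group labels.
#' @param test `"wilcoxon"` or `"kruskal"`.
#' @return The test p-value.
#' @export
groupCompare <- function(values, groups, test = c("wilcoxon", "kruskal")) {
  test <- match.arg(test)
  groups <- as.factor(as.character(groups))
  if (any(table(groups) == 0L)) stop("empty group")
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (test == "wilcoxon") {
    if (nlevels(groups) != 2L) stop("wilcoxon requires exactly 2 groups")
    sp <- split(values, groups)
    stats::wilcox.test(sp[[1]], sp[[2]], exact = FALSE, correct = FALSE)$p.value
  } else {
    stats::kruskal.test(values, groups)$p.value
  }
}
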