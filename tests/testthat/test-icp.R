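toy_enrichment <- function() {
  matrix(c(5, 3, 1,   # s1
           3, 5, 1,   # s2
           2, 2, 1),  # s3 (tie between A and B)
         nrow = 3, dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
}

test_that("pair indicators encode strict within-sample dominance, ties score 0", {
  enr <- toy_enrichment()
  psm <- pairIndicatorMatrix(enr, anchors = "A")
  expect_equal(psm["A|B", ], c(s1 = 1, s2 = 0, s3 = 0))
  expect_equal(psm["A|C", ], c(s1 = 1, s2 = 1, s3 = 1))
  expect_error(pairIndicatorMatrix(enr, anchors = "Z"), "unknown")
})

test_that("Score_ij + Score_ji is 1 exactly when enrichments differ", {
  set.seed(41)
  enr <- matrix(sample(1:3, 40, replace = TRUE), nrow = 4,
                dimnames = list(LETTERS[1:4], paste0("s", 1:10)))
  psm <- pairIndicatorMatrix(enr, anchors = LETTERS[1:4])
  for (a in LETTERS[1:4]) {
    for (b in setdiff(LETTERS[1:4], a)) {
      s <- psm[paste(a, b, sep = "|"), ] + psm[paste(b, a, sep = "|"), ]
      expect_true(all(s %in% c(0, 1)))
      expect_equal(unname(s), as.numeric(enr[a, ] != enr[b, ]))
    }
  }
})

test_that("evaluatePairs scores indicators and drops degenerate rows", {
  skip_if_not_installed("survival")
  # a binary indicator that perfectly separates early from late deaths: all 9
  # cross-group comparable pairs are concordant and the 6 within-group pairs
  # are risk ties, so C = (9 + 0.5*6)/15 = 0.8 — the maximum any binary
  # indicator can reach on 3+3 all-event data. The Cox fit on it is a flagged
  # monotone likelihood, hence the warning.
  enr <- matrix(rep(c(2, 1, 1, 2), 3), nrow = 2,
                dimnames = list(c("A", "B"), paste0("s", 1:6)))
  cl <- data.frame(sample = paste0("s", 1:6),
                   time = c(1, 4, 2, 5, 3, 6), event = 1L)
  psm <- pairIndicatorMatrix(enr, "A", c("A", "B"))
  expect_warning(st <- evaluatePairs(psm, cl), "converge")
  expect_equal(st$c_index, 0.8)
  expect_gt(st$hr, 1)

  # with one sample per group the single comparable pair is concordant: C = 1
  enr1 <- enr[, 1:2]
  cl1 <- cl[1:2, ]
  psm1 <- pairIndicatorMatrix(enr1, "A", c("A", "B"))
  expect_warning(st1 <- evaluatePairs(psm1, cl1), "converge")
  expect_equal(st1$c_index, 1.0)

  # constant indicator rows are excluded and reported
  enr2 <- rbind(enr, C = 0)
  psm2 <- pairIndicatorMatrix(enr2, "A", c("A", "B", "C"))
  expect_message(st2 <- suppressWarnings(evaluatePairs(psm2, cl)), "constant")
  expect_equal(attr(st2, "dropped"), "A|C")
  expect_equal(nrow(st2), 1L)

  # random indicators: stats equal the independent oracles
  set.seed(42)
  for (rep in 1:5) {
    n <- 8
    d <- rand_surv(n, cens_frac = 0.3, tie_free = TRUE)
    ind <- rbind(X = sample(0:1, n, replace = TRUE),
                 Y = 1)
    ind["Y", ] <- 1 - ind["X", ]
    clr <- data.frame(sample = paste0("s", 1:n), time = d$time, event = d$event)
    colnames(ind) <- clr$sample
    psm3 <- ind[1, , drop = FALSE]
    rownames(psm3) <- "X|Y"
    attr(psm3, "pair_ci") <- "X"
    attr(psm3, "pair_cj") <- "Y"
    if (max(psm3) == min(psm3)) next
    st3 <- evaluatePairs(psm3, clr, ties = "breslow")
    expect_equal(st3$c_index, brute_c_index(psm3[1, ], d$time, d$event))
    expect_lt(abs(st3$beta - cox_grid_oracle(psm3[1, ], d$time, d$event)), 1e-3)
  }
})

test_that("selectPairs applies the four selection steps in order", {
  stats <- data.frame(
    ci = c("A", "A", "B", "B", "C"),
    cj = c("B", "C", "A", "D", "D"),
    c_index = c(0.70, 0.65, 0.72, 0.60, 0.68),
    hr = c(2.0, 1.8, 2.2, 1.5, 0.8),
    p = c(0.01, 0.01, 0.01, 0.01, 0.001),
    beta = log(c(2.0, 1.8, 2.2, 1.5, 0.8)), se = 0.1)
  m <- selectPairs(stats, alpha = 0.05, cellOrder = c("A", "B", "C", "D"))
  sel <- selectedPairs(m)
  # anchor A keeps (A,B): highest C-index; anchor B keeps (B,A): same unordered
  # pair, removed as duplicate; anchor C's best pair has HR < 1, removed
  expect_equal(sel$ci, "A")
  expect_equal(sel$cj, "B")
  cnt <- m@provenance$selection_counts
  expect_equal(cnt$evaluated, 5L)
  expect_equal(cnt$after_best_per_anchor, 3L)
  expect_equal(cnt$after_hr_filter, 2L)
  expect_equal(cnt$after_dedup, 1L)

  # p-filter removes non-significant pairs before anything else: with (A,B)
  # gone, anchor A falls back to (A,C) and anchor B's (B,A) is no longer a
  # duplicate of anything
  stats2 <- stats
  stats2$p[1] <- 0.5
  m2 <- selectPairs(stats2, alpha = 0.05, cellOrder = c("A", "B", "C", "D"))
  expect_equal(selectedPairs(m2)$ci, c("A", "B"))
  expect_equal(selectedPairs(m2)$cj, c("C", "A"))

  # everything filtered out: error reports per-step counts
  stats3 <- stats
  stats3$hr <- 0.5
  expect_error(selectPairs(stats3, 0.05), "after_hr_filter=0")
})

test_that("selectPairs tie-breaks are deterministic (HR, then partner label)", {
  stats <- data.frame(
    ci = c("A", "A", "A"), cj = c("D", "C", "B"),
    c_index = c(0.7, 0.7, 0.7), hr = c(2.0, 2.5, 2.5),
    p = 0.01, beta = 0.7, se = 0.1)
  sel <- selectedPairs(selectPairs(stats, 0.05, cellOrder = c("A", "B", "C", "D")))
  expect_equal(sel$cj, "B") # equal C; max HR subset {C,B}; lexicographic first
})

test_that("model invariants are machine-checked by the class validity", {
  bad <- data.frame(ci = "A", cj = "B", c_index = 0.6, hr = 0.9, p = 0.01,
                    beta = -0.1, se = 0.1)
  expect_error(new("ICPModel", pairs = bad, cellTypes = c("A", "B"),
                   parameters = list(alpha_pairs = 0.05), provenance = list()),
               "hr > 1")
  dup <- data.frame(ci = c("A", "B"), cj = c("B", "A"),
                    c_index = 0.6, hr = 2, p = 0.01, beta = 0.7, se = 0.1)
  expect_error(new("ICPModel", pairs = dup, cellTypes = c("A", "B"),
                   parameters = list(alpha_pairs = 0.05), provenance = list()),
               "duplicate")
})

test_that("scoreSamples sums recomputed indicators; empty model scores 0", {
  enr <- matrix(c(3, 2, 1,  1, 2, 3), nrow = 3,
                dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  m <- new("ICPModel",
           pairs = data.frame(ci = c("A", "B"), cj = c("B", "C"),
                              c_index = 0.6, hr = 2, p = 0.01,
                              beta = 0.7, se = 0.1),
           cellTypes = c("A", "B", "C"),
           parameters = list(alpha_pairs = 0.05), provenance = list())
  expect_equal(scoreSamples(m, enr), c(s1 = 2L, s2 = 0L))
  empty <- new("ICPModel",
               pairs = data.frame(ci = character(), cj = character(),
                                  c_index = numeric(), hr = numeric(),
                                  p = numeric()),
               cellTypes = c("A", "B"), parameters = list(), provenance = list())
  expect_equal(scoreSamples(empty, enr), c(s1 = 0L, s2 = 0L))
  expect_error(scoreSamples(m, enr[1:2, ]), "absent.*C")
})

test_that("dichotomize splits bimodal scores between the modes", {
  set.seed(43)
  n <- 100
  scores <- setNames(rep(c(1L, 2L, 8L, 9L), each = n / 4), paste0("s", 1:n))
  hazard <- ifelse(scores > 5, 1, 0.1)
  cl <- data.frame(sample = names(scores), time = rexp(n, hazard),
                   event = 1L)
  res <- dichotomize(scores, cl)
  expect_gt(icpCutoff(res), 2)
  expect_lt(icpCutoff(res), 8)
  expect_equal(unname(icpGroups(res) == "high"), unname(scores > 5))
  expect_gte(min(table(icpGroups(res))), 0.1 * n)
  expect_error(dichotomize(setNames(rep(1L, n), names(scores)), cl), "distinct")
})

test_that("fitICP recovers the constructed pair in a single-cohort toy design", {
  # cell A drives hazard (high A = early death), B is A's mirror so the
  # indicator A > B splits the cohort at A's median, C is pure noise. The
  # traceable outcome: A is an anchor, its best partner is B (the sharpest
  # split), the retained pair is hazardous and significant; B's own pairs are
  # protective (HR < 1) and fall at the HR filter.
  set.seed(47)
  n <- 60
  samples <- paste0("s", 1:n)
  enrA <- runif(n)
  enr <- rbind(A = enrA, B = 1 - enrA, C = runif(n))
  colnames(enr) <- samples
  cl <- data.frame(sample = samples,
                   time = rexp(n, exp(4 * (enrA - 0.5))), event = 1L)
  model <- fitICP(list(list(enrichment = enr, clinical = cl)))
  sel <- selectedPairs(model)
  expect_true("A" %in% model@provenance$anchors)
  expect_true(any(sel$ci == "A" & sel$cj == "B"))
  expect_false(any(sel$ci == "B")) # all of B's pairs are protective
  expect_true(all(sel$hr > 1 & sel$p < 0.05))
  expect_gt(sel$c_index[sel$ci == "A"], 0.6)
})

test_that("model JSON round-trips exactly", {
  stats <- data.frame(ci = c("A", "B"), cj = c("C", "D"),
                      c_index = c(0.71, 0.66), hr = c(2.31, 1.87),
                      p = c(0.001, 0.02), beta = log(c(2.31, 1.87)),
                      se = c(0.2, 0.3))
  m <- selectPairs(stats, 0.05, cellOrder = LETTERS[1:4],
                   provenance = list(note = "round-trip"))
  f <- withr::local_tempfile(fileext = ".json")
  writeICPModel(m, f)
  back <- readICPModel(f)
  expect_equal(selectedPairs(back), selectedPairs(m))
  expect_equal(cellTypes(back), cellTypes(m))
  expect_equal(back@parameters$alpha_pairs, 0.05)
  # schema violations are rejected
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(schema_version = "1.0"), bad, auto_unbox = TRUE)
  expect_error(readICPModel(bad), "missing field")
})

test_that("end-to-end ICP scores are invariant to monotone expression transforms", {
  cfg <- small_config(seed = 44, n_cohorts = 1L)
  co <- simulateCohort(cfg, 1)
  sc <- co$signatures
  m <- new("ICPModel",
           pairs = data.frame(ci = c("cell01", "cell02"),
                              cj = c("cell03", "cell04"),
                              c_index = 0.6, hr = 2, p = 0.01,
                              beta = 0.7, se = 0.1),
           cellTypes = cellTypes(sc),
           parameters = list(alpha_pairs = 0.05), provenance = list())
  s1 <- scoreSamples(m, ssgsea(co$expression, sc))
  s2 <- scoreSamples(m, ssgsea(log1p(co$expression), sc))
  s3 <- scoreSamples(m, ssgsea(co$expression^3, sc))
  expect_identical(s1, s2)
  expect_identical(s1, s3)
  # affine transforms of the enrichment matrix leave scores unchanged too
  enr <- ssgsea(co$expression, sc)
  expect_identical(scoreSamples(m, 3 * enr + 17), s1)
})

test_that("validation on a discovery cohort reproduces fit-time statistics", {
  cfg <- small_config(seed = 45)
  study <- simulateStudy(cfg)
  cohorts <- enrich_study(study)
  model <- fitICP(cohorts)
  val <- validateICP(model, cohorts[[1]]$enrichment, cohorts[[1]]$clinical,
                     horizons = c(1, 3))
  # the report is self-consistent with direct calls on the same cohort
  scores <- scoreSamples(model, cohorts[[1]]$enrichment)
  expect_equal(setNames(val$samples$icp_score, val$samples$sample), scores)
  direct <- dichotomize(scores, cohorts[[1]]$clinical)
  expect_equal(val$cutoff, icpCutoff(direct))
  lr <- logrankTest(icpGroups(direct) == "high",
                    cohorts[[1]]$clinical$time, cohorts[[1]]$clinical$event)
  expect_equal(val$logrank$chi2, lr$chi2)
  expect_equal(val$c_index,
               harrellC(as.numeric(scores), cohorts[[1]]$clinical$time,
                        cohorts[[1]]$clinical$event))
})

test_that("validation reports annotation statistics by type", {
  cfg <- small_config(seed = 46)
  study <- simulateStudy(cfg)
  cohorts <- enrich_study(study)
  model <- fitICP(cohorts)
  co <- study[[2]]
  cl <- co$clinical
  set.seed(1)
  cl$tmb <- rnorm(nrow(cl)) + co$truth$lp       # numeric annotation
  cl$mut <- ifelse(co$truth$lp > 0, "b_mut", "a_wt") # binary; 2nd level = mutant
  cl$resp <- sample(c("CR", "PR", "SD", "PD"), nrow(cl), replace = TRUE)
  val <- validateICP(model, cohorts[[2]]$enrichment, cl)
  expect_equal(val$annotations$tmb$type, "numeric")
  expect_true(is.numeric(val$annotations$tmb$r))
  expect_equal(val$annotations$mut$type, "binary")
  expect_gt(val$annotations$mut$auc, 0.5) # lp drives both score and label
  expect_equal(val$annotations$resp$type, "categorical")
})
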