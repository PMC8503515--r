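test_that("loading vectors follow the MAF-weighted and equal-weight forms", {
  # mu = (0.2, 0.4): sum mu^2 = 0.2 -> b = (1, 2); sum mu = 0.6 -> d = 1/0.6
  panel <- rbind(tiny_panel(c(0.1, 0.2), "PA"), tiny_panel(c(0.15), "PB"))
  class(panel) <- c("snp_panel", "data.frame")
  L <- make_loadings(panel)
  expect_equal(unname(L$b[, "PA"]), c(1, 2, 0))
  expect_equal(unname(L$d[, "PA"]), c(1 / 0.6, 1 / 0.6, 0))
  expect_equal(unname(L$b[, "PB"]), c(0, 0, 0.3 / 0.09))
  # expected score of a population member is exactly 1: sum(mu * b) = 1
  expect_equal(sum(L$mu[panel$pop == "PA"] * L$b[panel$pop == "PA", "PA"]), 1)

  # unit-norm variant: b is the unit-length singular-vector direction
  Lu <- make_loadings(panel, loading_norm = "unit-norm")
  expect_equal(sum(Lu$b[, "PA"]^2), 1)
  expect_equal(unname(Lu$b[, "PA"]), c(c(0.2, 0.4) / sqrt(0.2), 0))
})

test_that("principal scores are X b with alignment checking", {
  panel <- tiny_panel(c(0.1, 0.2))
  L <- make_loadings(panel)
  X <- matrix(c(1L, 0L), 1, dimnames = list("i1", panel$id))
  expect_equal(principal_scores(X, L)[1, "POP1"], 1)
  expect_equal(ancestral_information(X, L)[1, "POP1"], 1 / 0.6)

  expect_true(all(principal_scores(matrix(0L, 2, 2), L) == 0))

  bad <- X[, 2:1, drop = FALSE]
  expect_error(principal_scores(bad, L), "misaligned")
  expect_error(ancestral_information(matrix(0L, 1, 5), L), "do not match")
})

test_that("ancestral information matches the ratio form row by row", {
  panel <- simulate_panel(c(PA = 40, PB = 60), seed = 41)
  design <- admixture_design(c(PA = 0.7, PB = 0.5), n = 25)
  X <- simulate_genotypes(panel, design, seed = 42)
  L <- make_loadings(panel)
  info <- ancestral_information(X, L)
  for (k in c("PA", "PB")) {
    in_k <- panel$pop == k
    manual <- rowSums(X[, in_k, drop = FALSE]) / sum(2 * panel$maf[in_k])
    expect_equal(unname(info[, k]), unname(manual), tolerance = 1e-12)
  }
  # p_hat is 0 exactly when no population-specific allele is carried
  expect_equal(unname(info[, "PA"]) == 0,
               unname(rowSums(X[, panel$pop == "PA"]) == 0))
  expect_true(all(info >= 0))
})

test_that("reference members score one on average, zero elsewhere", {
  panel <- simulate_panel(c(PA = 5000, PB = 5000), seed = 43)
  design <- admixture_design(c(PA = 1, PB = 0), n = 100)
  X <- simulate_genotypes(panel, design, seed = 44)
  fit <- ancestral_spectrum(X, panel)
  a <- fit$scores
  se <- sd(a[, "PA"]) / sqrt(nrow(a))
  expect_lt(abs(mean(a[, "PA"]) - 1), 3 * se)
  expect_true(all(a[, "PB"] == 0))        # exact zeros: disjoint support
  expect_true(all(fit$info[, "PB"] == 0))
})

test_that("maximum likelihood estimate solves the score equation", {
  # all-zero genotypes: MLE exactly 0
  panel <- tiny_panel(c(0.02, 0.02))
  L <- make_loadings(panel)
  X0 <- matrix(0L, 1, 2, dimnames = list("i", panel$id))
  expect_equal(unname(mle_ancestral_information(X0, L)[1, 1]), 0)

  # two SNPs, mu1 = mu2 = 0.04, X = (1, 0): root is 12.5 = 1/(2 mu),
  # identical to the moment estimate
  X1 <- matrix(c(1L, 0L), 1, dimnames = list("i", panel$id))
  mle <- mle_ancestral_information(X1, L)
  expect_equal(unname(mle[1, 1]), 12.5, tolerance = 1e-9)
  expect_equal(unname(mle[1, 1]), unname(ancestral_information(X1, L)[1, 1]),
               tolerance = 1e-9)
  expect_false(attr(mle, "boundary")[1, 1])

  # all alleles observed: no interior root, boundary flag raised
  X2 <- matrix(c(1L, 1L), 1, dimnames = list("i", panel$id))
  mle2 <- mle_ancestral_information(X2, L)
  expect_true(attr(mle2, "boundary")[1, 1])
  expect_equal(unname(mle2[1, 1]), (1 - 1e-9) / 0.04)

  # diploid counts are truncated for the 0/1 likelihood, with a warning
  X3 <- matrix(c(2L, 0L), 1, dimnames = list("i", panel$id))
  expect_warning(mle3 <- mle_ancestral_information(X3, L), "truncated")
  expect_equal(unname(mle3[1, 1]), 12.5, tolerance = 1e-9)
})

test_that("moment and likelihood estimates agree for small MAFs", {
  panel <- simulate_panel(c(PA = 10000), maf = c(0.01, 0.025), seed = 45)
  design <- admixture_design(c(PA = 0.8), n = 30)
  X <- simulate_genotypes(panel, design, seed = 46)
  X[X > 1L] <- 1L    # feed the likelihood its own 0/1 domain
  L <- make_loadings(panel)
  p_mom <- ancestral_information(X, L)
  p_mle <- mle_ancestral_information(X, L)
  expect_lt(mean(abs(p_mle - p_mom)), 0.01)
})

test_that("scores of one individual do not depend on the batch", {
  panel <- simulate_panel(c(PA = 200, PB = 200), seed = 47)
  design <- admixture_design(c(PA = 0.5, PB = 0.5), n = 8)
  X <- simulate_genotypes(panel, design, seed = 48)
  full <- ancestral_spectrum(X, panel, mle = TRUE)
  alone <- ancestral_spectrum(X[3, , drop = FALSE], panel, mle = TRUE)
  expect_identical(full$scores[3, ], alone$scores[1, ])   # bitwise
  expect_identical(full$info[3, ], alone$info[1, ])
  expect_identical(full$mle[3, ], alone$mle[1, ])
})

test_that("missing genotypes contribute zero copies and a call-rate column", {
  panel <- tiny_panel(c(0.1, 0.2))
  X <- matrix(c(1L, NA), 1, dimnames = list("i1", panel$id))
  fit <- ancestral_spectrum(X, panel)
  expect_equal(unname(fit$info[1, 1]), 1 / 0.6)  # denominator NOT rescaled
  expect_equal(unname(fit$call_rate), 0.5)
})

test_that("group summaries flag constructed genetic outliers", {
  panel <- simulate_panel(c(PA = 1000, PB = 1000), seed = 49)
  design <- admixture_design(c(PA = 1, PB = 0), n = 30, label = "grp")
  design[30, "PA"] <- 8    # ~10+ group SDs above the mean information
  X <- simulate_genotypes(panel, design, seed = 50)
  fit <- ancestral_spectrum(X, panel)
  assign <- data.frame(sample = rownames(X), pop = "grp")
  s <- summary(fit, assign)
  expect_true(rownames(X)[30] %in% s$outliers$sample)

  # single-individual group: sd undefined, no outlier calls
  s1 <- summary(ancestral_spectrum(X[1, , drop = FALSE], panel))
  expect_true(all(is.na(s1$stats$sd)))
  expect_equal(nrow(s1$outliers), 0)

  # two identical individuals: zero sd, never flagged
  X2 <- X[c(1, 1), ]
  rownames(X2) <- c("a", "b")
  s2 <- summary(ancestral_spectrum(X2, panel))
  expect_true(all(s2$stats$sd == 0))
  expect_equal(nrow(s2$outliers), 0)
})

test_that("equal weights give lower variance than MAF weights (BLUE)", {
  panel <- simulate_panel(c(PA = 20000), maf = c(0.01, 0.05), seed = 51)
  design <- admixture_design(c(PA = 1), n = 300)
  X <- simulate_genotypes(panel, design, seed = 52)
  fit <- ancestral_spectrum(X, panel)
  expect_lt(var(fit$info[, "PA"]), var(fit$scores[, "PA"]))
})

test_that("thinning a panel degrades information by the retained mu share", {
  panel <- simulate_panel(c(PA = 20000), seed = 53)
  X <- simulate_drifted_population(panel, n = 100, scale = 1, retain = 0.4,
                                  seed = 54)
  fit <- ancestral_spectrum(X, panel)
  expected <- attr(X, "expected_info")[["PA"]]
  expect_equal(expected, 0.4, tolerance = 0.05)
  se <- sd(fit$info[, "PA"]) / sqrt(100)
  expect_lt(abs(mean(fit$info[, "PA"]) - expected), 3 * se)
})

test_that("results tables flatten in input order", {
  panel <- simulate_panel(c(PA = 50, PB = 50), seed = 55)
  design <- admixture_design(c(PA = 0.3, PB = 0.7), n = 6)
  X <- simulate_genotypes(panel, design, seed = 56)
  fit <- ancestral_spectrum(X, panel, mle = TRUE)
  df <- as.data.frame(fit)
  expect_equal(df$SAMPLE, rownames(X))
  expect_named(df, c("SAMPLE", "SCORE_PA", "SCORE_PB", "INFO_PA", "INFO_PB",
                     "MLE_PA", "MLE_PB", "TOTAL_INFO", "CALLRATE"))
  expect_equal(df$TOTAL_INFO, unname(rowSums(fit$info)))
})
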