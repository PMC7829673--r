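test_that("one-sample t matches the textbook closed form", {
  m <- matrix(1:5, 5, 1)
  map <- groupTest(m, "one_sample")
  expect_equal(statValues(map), 3 / sqrt(2.5 / 5), tolerance = 1e-10)
  expect_equal(map@df, 4)
  expect_equal(pValues(map), 2 * pt(-statValues(map), 4), tolerance = 1e-12)
  # against mu0
  map2 <- groupTest(m, "one_sample", mu0 = 3)
  expect_equal(statValues(map2), 0, tolerance = 1e-12)
  # cross-check t.test on a random fixture
  set.seed(81)
  y <- rnorm(9)
  ref <- t.test(y)
  expect_equal(statValues(groupTest(matrix(y), "one_sample")),
               unname(ref$statistic), tolerance = 1e-10)
})

test_that("two-sample and paired t match stats:: closed forms", {
  set.seed(82)
  a <- matrix(rnorm(18), 6, 3); b <- matrix(rnorm(18) + 1, 6, 3)
  g <- rep(c("x", "y"), each = 6)
  map <- groupTest(rbind(a, b), "two_sample", groups = g)
  for (j in 1:3) {
    ref <- t.test(b[, j], a[, j], var.equal = TRUE)
    expect_equal(abs(statValues(map)[j]), abs(unname(ref$statistic)),
                 tolerance = 1e-10)
    expect_equal(pValues(map)[j], ref$p.value, tolerance = 1e-10)
  }
  # identical groups: t = 0, p = 1
  map0 <- groupTest(rbind(a, a), "two_sample", groups = g)
  expect_equal(statValues(map0), rep(0, 3), tolerance = 1e-12)
  expect_equal(pValues(map0), rep(1, 3), tolerance = 1e-12)
  pm <- groupTest(list(a, b), "paired")
  for (j in 1:3) {
    ref <- t.test(a[, j], b[, j], paired = TRUE)
    expect_equal(statValues(pm)[j], unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("correlation model returns (partial) r with valid p", {
  set.seed(83)
  x <- rnorm(12)
  Y <- cbind(x, 0.5 * x + rnorm(12), rnorm(12))
  map <- groupTest(Y, "correlation", x = x)
  expect_equal(statValues(map)[1], 1, tolerance = 1e-6)
  expect_lt(pValues(map)[1], 1e-10)
  ref <- cor.test(x, Y[, 2])
  expect_equal(statValues(map)[2], unname(ref$estimate), tolerance = 1e-10)
  expect_equal(pValues(map)[2], ref$p.value, tolerance = 1e-10)
  # partial correlation controls the covariate
  z <- rnorm(12)
  mapP <- groupTest(Y, "correlation", x = x, covariates = z)
  fullT <- summary(lm(Y[, 2] ~ x + z))$coefficients["x", "t value"]
  expect_equal(statValues(mapP)[2], fullT / sqrt(fullT^2 + 9),
               tolerance = 1e-10)
})

test_that("independent and repeated-measures ANOVA match aov", {
  set.seed(84)
  g <- factor(rep(c("a", "b", "c"), each = 5))
  Y <- matrix(rnorm(15 * 2), 15, 2)
  Y[g == "b", 1] <- Y[g == "b", 1] + 1
  map <- groupTest(Y, "anova_indep", groups = g)
  for (j in 1:2) {
    ref <- summary(aov(Y[, j] ~ g))[[1]]
    expect_equal(statValues(map)[j], ref$`F value`[1], tolerance = 1e-10)
    expect_equal(pValues(map)[j], ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_equal(map@df, c(2, 12))
  # covariate-adjusted F
  covar <- rnorm(15)
  mapC <- groupTest(Y, "anova_indep", groups = g, covariates = covar)
  refC <- anova(lm(Y[, 1] ~ covar + g))
  expect_equal(statValues(mapC)[1], refC["g", "F value"], tolerance = 1e-10)
  # repeated measures: one-way within-subject F equals aov with Error(subject)
  conds <- lapply(1:3, function(k) matrix(rnorm(8 * 2) + k / 4, 8, 2))
  rm <- groupTest(conds, "anova_rm")
  long <- data.frame(y = unlist(lapply(conds, function(m) m[, 1])),
                     cond = factor(rep(1:3, each = 8)),
                     subj = factor(rep(1:8, 3)))
  ref <- summary(aov(y ~ cond + Error(subj), data = long))
  refF <- ref[["Error: Within"]][[1]]["cond", "F value"]
  expect_equal(statValues(rm)[1], refF, tolerance = 1e-10)
  expect_equal(rm@df, c(2, 14))
})

test_that("mean_only returns group means without inference", {
  m <- matrix(1:10, 5, 2)
  map <- groupTest(m, "mean_only")
  expect_equal(statValues(map), c(3, 8))
  expect_true(all(is.na(pValues(map))))
})

test_that("missing subjects reduce per-channel degrees of freedom", {
  set.seed(85)
  m <- matrix(rnorm(30), 10, 3)
  m[1:2, 2] <- NA
  map <- groupTest(m, "one_sample")
  expect_equal(map@df[1], 9)
  expect_equal(map@df[2], 7)
  ref <- t.test(m[!is.na(m[, 2]), 2])
  expect_equal(statValues(map)[2], unname(ref$statistic), tolerance = 1e-10)
})

test_that("BH and Bonferroni flags match brute-force definitions", {
  # the worked example: p = {0.01, 0.02, 0.30} at q = 0.05
  map <- new("ChannelStatMap", channelIds = 1:3, stat = c(3, 2.5, 1),
             p = c(0.01, 0.02, 0.30), df = 4, model = "one_sample",
             mask = rep(TRUE, 3), corrected = list(method = "none"))
  bh <- correctMultiple(map, "fdr_bh", q = 0.05)
  expect_identical(significanceFlags(bh), c(TRUE, TRUE, FALSE))
  bf <- correctMultiple(map, "bonferroni", q = 0.05)
  expect_identical(significanceFlags(bf), c(TRUE, FALSE, FALSE))
  # random p-vectors up to n = 12 against brute force
  set.seed(86)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    p <- round(runif(n), 3)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    mp <- new("ChannelStatMap", channelIds = seq_len(n), stat = rnorm(n),
              p = p, df = 5, model = "one_sample", mask = rep(TRUE, n),
              corrected = list(method = "none"))
    fBH <- significanceFlags(correctMultiple(mp, "fdr_bh", q = q))
    fBF <- significanceFlags(correctMultiple(mp, "bonferroni", q = q))
    expect_identical(fBH, bruteBH(p, q))
    expect_identical(fBF, bruteBonferroni(p, q))
    expect_true(all(!fBF | fBH))   # Bonferroni set within BH set
    # agreement with p.adjust as an independent oracle
    expect_identical(fBH, unname(p.adjust(p, "BH") <= q))
  }
})

test_that("correction respects the mask and family size", {
  p <- c(0.012, 0.5, 0.012, 0.9)
  mp <- new("ChannelStatMap", channelIds = 1:4, stat = rnorm(4), p = p,
            df = 5, model = "one_sample", mask = rep(TRUE, 4),
            corrected = list(method = "none"))
  # full family of 4: 0.05/4 = 0.0125 still flags the 0.012s
  f4 <- significanceFlags(correctMultiple(mp, "bonferroni", q = 0.05))
  expect_identical(f4, c(TRUE, FALSE, TRUE, FALSE))
  # mask of channels 1-2: family of 2, threshold 0.025
  f2 <- significanceFlags(correctMultiple(mp, "bonferroni", q = 0.05,
                                          mask = c(1L, 2L)))
  expect_identical(f2, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(correctMultiple(mp, "fdr_bh", q = 0.05,
                               mask = rep(FALSE, 4)), "empty mask")
  # nothing flagged when all p = 1
  mp1 <- new("ChannelStatMap", channelIds = 1:4, stat = rnorm(4),
             p = rep(1, 4), df = 5, model = "one_sample",
             mask = rep(TRUE, 4), corrected = list(method = "none"))
  expect_false(any(significanceFlags(correctMultiple(mp1, "fdr_bh"))))
  expect_false(any(significanceFlags(correctMultiple(mp1, "bonferroni"))))
})

test_that("BH flags are monotone in the p-values", {
  set.seed(87)
  p <- runif(8)
  mk <- function(pv) new("ChannelStatMap", channelIds = 1:8, stat = rnorm(8),
                         p = pv, df = 5, model = "one_sample",
                         mask = rep(TRUE, 8),
                         corrected = list(method = "none"))
  f0 <- significanceFlags(correctMultiple(mk(p), "fdr_bh", q = 0.2))
  p2 <- p; p2[3] <- p2[3] / 10
  f1 <- significanceFlags(correctMultiple(mk(p2), "fdr_bh", q = 0.2))
  expect_true(all(!f0 | f1))   # lowering one p never removes flags
})

test_that("error control holds under a simulated global null", {
  set.seed(88)
  nRep <- 500; S <- 10; C <- 8; q <- 0.05
  fwe <- 0; fdpSum <- 0
  for (r in seq_len(nRep)) {
    Y <- matrix(rnorm(S * C), S, C)
    tstat <- sqrt(S) * colMeans(Y) / apply(Y, 2, sd)
    p <- 2 * pt(-abs(tstat), S - 1)
    if (any(bruteBonferroni(p, q))) fwe <- fwe + 1
    nBH <- sum(bruteBH(p, q))
    if (nBH > 0) fdpSum <- fdpSum + 1   # all discoveries false under the null
  }
  mc <- 3 * sqrt(q * (1 - q) / nRep)
  expect_lt(fwe / nRep, q + mc)
  expect_lt(fdpSum / nRep, q + mc)
  # the package implementation agrees with the brute force used above
  Y <- matrix(rnorm(S * C), S, C)
  map <- groupTest(Y, "one_sample")
  expect_identical(significanceFlags(correctMultiple(map, "fdr_bh", q = q)),
                   bruteBH(pValues(map), q))
})
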