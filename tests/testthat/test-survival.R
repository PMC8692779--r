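test_that("prepareEndpoint applies the 10-year horizon inclusively", {
  ep <- prepareEndpoint(c(12, 8, 10, 10), c(1, 0, 1, 0))
  expect_equal(ep$time, c(10, 8, 10, 10))
  # event beyond horizon censored; event at exactly 10 retained
  expect_equal(ep$event, c(0L, 0L, 1L, 0L))
  expect_error(prepareEndpoint(c(0, 5), c(1, 0)), "positive")
  expect_error(prepareEndpoint(5, 2), "0/1")
})

test_that("quartileStratify follows the ceiling rule and is rank-invariant", {
  expect_identical(as.integer(table(quartileStratify(c(8, 1, 5, 3, 7, 2, 6, 4)))),
                   rep(2L, 4))
  ten <- c(0.1, 0.9, 0.4, 0.7, 0.2, 1.0, 0.6, 0.3, 0.8, 0.5)
  expect_identical(as.integer(table(quartileStratify(ten))), c(3L, 2L, 3L, 2L))
  expect_identical(quartileStratify(ten), quartileStratify(exp(ten)))
  expect_error(quartileStratify(1:3), "at least 4")
})

test_that("kmLogrank produces valid curves and a null statistic on copies", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 0, 1, 1, 0, 1)
  km <- kmLogrank(c(time, time), c(event, event), rep(c("a", "b"), each = 6))
  expect_equal(km$chi2, 0)
  expect_equal(km$p, 1)
  # curves start at/below 1 and are non-increasing per group
  for (g in unique(km$curves$group)) {
    s <- km$curves$survival[km$curves$group == g]
    expect_true(all(s <= 1))
    expect_true(!is.unsorted(rev(s)))
  }
  expect_error(kmLogrank(time, event, rep("a", 6)), "2 non-empty groups")
})

test_that("kmLogrank matches the hand-computed observed/expected log-rank", {
  time <- c(1, 2, 3, 4, 4, 5, 6, 7, 8, 9)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1)
  group <- rep(c("x", "y"), 5)
  km <- kmLogrank(time, event, group)
  orc <- oracleLogrank2(time, event, group)
  expect_equal(km$chi2, orc$chi2)
  expect_equal(km$p, orc$p)
})

test_that("kmLogrank detects a planted hazard ratio of 2", {
  withr::with_seed(13, {
    n <- 500
    t1 <- rexp(n, 0.1); t2 <- rexp(n, 0.2)
    cens <- runif(2 * n, 0, 15)
    time <- pmin(c(t1, t2), cens)
    event <- as.integer(c(t1, t2) <= cens)
    km <- kmLogrank(time, event, rep(c("lo", "hi"), each = n))
    expect_lt(km$p, 1e-6)
  })
})

test_that("coxFit matches direct Efron partial-likelihood maximization", {
  withr::with_seed(17, {
    for (i in 1:5) {
      n <- 40
      x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
      t <- rexp(n, 0.2 * exp(0.5 * x1 - 0.4 * x2))
      cens <- runif(n, 0, 8)
      time <- round(pmin(t, cens), 1) + 0.05  # induce ties
      event <- as.integer(t <= cens)
      if (sum(event) < 3) next
      fit <- coxFit(time, event, data.frame(x1 = x1, x2 = x2))
      betaHat <- oracleCoxML(time, event, cbind(x1, x2))
      expect_equal(fit$terms$coef, betaHat, tolerance = 1e-4)
    }
  })
})

test_that("coxFit recovers a planted hazard ratio of 1.5", {
  x <- rep(c(0, 1), each = 1000)   # two arms of 1,000
  surv <- makeSurvival(cbind(x = x), c(x = log(1.5)), seed = 1)
  fit <- coxFit(surv$time, surv$event, data.frame(x = x))
  expect_equal(fit$terms$hr, 1.5, tolerance = 0.1)
  expect_true(fit$terms$ci_low <= fit$terms$hr & fit$terms$hr <= fit$terms$ci_high)
  expect_true(all(fit$terms$hr > 0))
})

test_that("coxFit flags constant and collinear covariates and needs events", {
  withr::with_seed(23, {
    x <- rnorm(50)
    t <- rexp(50, 0.2 * exp(0.5 * x))
    event <- rep(1L, 50)
  })
  dup <- coxFit(t, event, data.frame(x = x, xCopy = x, const = 1))
  expect_true(any(grepl("aliased", dup$flagged)))
  expect_true(any(grepl("constant", dup$flagged)))
  expect_false("xCopy" %in% dup$terms$term || !"x" %in% dup$terms$term)
  expect_error(coxFit(t, rep(0L, 50), data.frame(x = x)), "at least one event")
})

test_that("splitCohort halves deterministically", {
  ids <- sprintf("P%04d", 1:1954)
  sp <- splitCohort(ids, seed = 42)
  expect_length(sp$A, 977)
  expect_length(sp$B, 977)
  expect_length(intersect(sp$A, sp$B), 0)
  expect_setequal(c(sp$A, sp$B), ids)
  expect_identical(splitCohort(ids, seed = 42), sp)
  expect_false(identical(splitCohort(ids, seed = 43), sp))
  # odd n: sizes differ by one
  spOdd <- splitCohort(ids[1:11], seed = 1)
  expect_equal(abs(length(spOdd$A) - length(spOdd$B)), 1)
})

test_that("dmfsGeneScreen flags a planted prognostic gene and is reproducible", {
  withr::with_seed(29, {
    n <- 900
    planted <- rnorm(n)
    expr <- rbind(PLANTED = planted,
                  matrix(rnorm(30 * n), 30, n,
                         dimnames = list(paste0("N", 1:30), NULL)))
  })
  surv <- makeSurvival(cbind(g = planted), c(g = 0.5), seed = 30)
  ep <- prepareEndpoint(surv$time, surv$event)
  res <- dmfsGeneScreen(expr, ep$time, ep$event)
  expect_true(res$significant[res$gene == "PLANTED"])
  # noise genes: few false positives under BH at 0.1
  expect_lte(sum(res$significant[res$gene != "PLANTED"]), 3)
  # permutation of sample order leaves per-gene results unchanged
  perm <- withr::with_seed(31, sample(n))
  res2 <- dmfsGeneScreen(expr[, perm], ep$time[perm], ep$event[perm])
  expect_equal(res, res2)
  # bit-identical on repeat
  expect_identical(res, dmfsGeneScreen(expr, ep$time, ep$event))
})

test_that("stratifiedTrem1Analysis localizes a planted within-stratum effect", {
  withr::with_seed(37, {
    n <- 600
    expr <- rnorm(n)
    frac <- runif(n)
    benefit <- rep(c("IBE", "IBD"), each = n / 2)
    fracHigh <- quantileBin(frac, 4) >= 3
    inStratum <- benefit == "IBE" & fracHigh
    # hazard doubles with high expression only inside IBE x fraction-high
    rate <- 0.15 * exp(log(2.5) * (expr > median(expr)) * inStratum)
    t <- rexp(n, rate)
    cens <- runif(n, 0, 12)
    time <- pmin(t, cens); event <- as.integer(t <= cens)
  })
  out <- stratifiedTrem1Analysis(expr, time, event, frac, benefit)
  expect_setequal(names(out),
                  c("IBE.fraction_low", "IBE.fraction_high",
                    "IBD.fraction_low", "IBD.fraction_high"))
  expect_lt(out$IBE.fraction_high$p, 0.01)
  expect_gt(min(out$IBD.fraction_low$p, out$IBD.fraction_high$p,
                out$IBE.fraction_low$p), 0.01)
  # stratum sizes account for every sample
  expect_equal(sum(vapply(out, `[[`, 1.0, "n")), n)
})

test_that("quartileCellFractionSummary centers means and tracks gradients", {
  withr::with_seed(41, {
    n <- 200
    q <- quantileBin(runif(n), 4)
    up <- q / 4 + rnorm(n, sd = 0.01)      # monotone in quartile
    flat <- runif(n)
    fractions <- cbind(gradient = up, flat = flat)
  })
  res <- quartileCellFractionSummary(fractions, q)
  expect_equal(unname(rowSums(res$means)), c(0, 0))
  expect_equal(res$correlation$rho[res$correlation$cell_type == "gradient"],
               cor(rank(up), rank(q)))
  # direct group-mean oracle
  manual <- as.vector(tapply(up, q, mean))
  expect_equal(unname(res$means["gradient", ]), manual - mean(manual))
  # missing fractions dropped with warning
  fractions[1:5, "flat"] <- NA
  expect_warning(quartileCellFractionSummary(fractions, q), "dropped 5")
})
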