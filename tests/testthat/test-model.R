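test_that("simple contrasts and centering follow the coding scheme", {
  cm <- simpleContrasts(c("sham", "a", "b"))
  expect_true(all(cm %in% c(2 / 3, -1 / 3)))
  expect_equal(colSums(cm), c(a = 0, b = 0))
  tab <- glmBlockTable(nP = 4, seed = 2)
  fr <- hbcModelFrame(tab)
  expect_lt(abs(mean(fr$mt_c)), 1e-12)
  expect_lt(abs(mean(fr$pain_c)), 1e-12)
  expect_identical(levels(fr$target_f)[1], "sham")
  d <- buildDesign(fr)
  expect_true(all(d$X[, "target_ftA"] %in% c(2 / 3, -1 / 3)))
  # missing sham level
  expect_error(hbcModelFrame(tab[tab$target != "sham", ]), "sham")
})

test_that("the B-spline basis is a partition of unity", {
  x <- sort(runif(200, -3, 7))
  B <- bsplineBasis(x, df = 5)
  expect_equal(rowSums(B), rep(1, 200), tolerance = 1e-12)
  B8 <- bsplineBasis(x, df = 8)
  expect_equal(rowSums(B8), rep(1, 200), tolerance = 1e-12)
  expect_error(bsplineBasis(x, df = 3), "df")
})

test_that("BH adjustment matches hand-derived values and its properties", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(0.37), 0.37)
  set.seed(5)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1))
    q <- fdrAdjust(p)
    expect_equal(q, bhOracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_warning(out <- fdrAdjust(c(0.01, NA, 0.5)), "NA")
  expect_true(is.na(out[2]) && !anyNA(out[-2]))
})

test_that("mixed fit collapses to the single-level Gamma IRLS oracle", {
  tab <- glmBlockTable(nP = 19, seed = 7, shape = 8)
  fr <- hbcModelFrame(tab)
  # variance parameters started at the boundary: the mixed model evaluated
  # at zero random-effect variance must reduce to the single-level GLM
  fit <- suppressWarnings(fitGammaMixed(fr, "glmm",
                                        start = list(theta = c(-8, -8, 0, -8))))
  X <- buildDesign(fr)$X
  oracle <- irlsGammaOracle(X, fr$hbc_power)
  est <- log(fit$coefTable$estimate)
  names(oracle) <- colnames(X)
  expect_true(all(unlist(fit$ranefVar) < 1e-4))
  shared <- intersect(fit$coefTable$term, colnames(X))
  expect_equal(length(shared), ncol(X))
  for (term in shared) {
    o <- oracle[[term]]
    e <- est[match(term, fit$coefTable$term)]
    expect_lt(abs(e - o) / max(abs(o), 0.05), 1e-3)
  }
})

test_that("a known multiplicative target effect is recovered with calibrated CIs", {
  # exp(beta) = 1.5 for the single active target; 19 x 3 x 16 rows
  hits <- 0
  nullHits <- 0
  nRep <- 100
  for (r in seq_len(nRep)) {
    tab <- glmBlockTable(nP = 19, targets = c("sham", "tA"),
                         beta = list(intercept = 0,
                                     target = c(tA = log(1.5)), mt = 0.005),
                         seed = 1000 + r, participantSd = 0.25,
                         sessionSlopeSd = 0.1, blockSd = 0.1)
    fr <- hbcModelFrame(tab)
    fit <- suppressWarnings(fitGammaMixed(fr, "glmm"))
    i <- match("target_ftA", fit$coefTable$term)
    b <- log(fit$coefTable$estimate[i])
    se <- fit$coefTable$se[i] / fit$coefTable$estimate[i]
    if (is.finite(se) && b - 1.96 * se <= log(1.5) &&
        log(1.5) <= b + 1.96 * se)
      hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("null simulations keep the ratio-scale CI around 1", {
  cover <- 0
  nRep <- 100
  for (r in seq_len(nRep)) {
    tab <- glmBlockTable(nP = 19, targets = c("sham", "tA"),
                         beta = list(intercept = 0, target = c(tA = 0),
                                     mt = 0),
                         seed = 3000 + r, participantSd = 0.25,
                         sessionSlopeSd = 0.1, blockSd = 0.1)
    fr <- hbcModelFrame(tab)
    fit <- suppressWarnings(fitGammaMixed(fr, "glmm"))
    i <- match("target_ftA", fit$coefTable$term)
    b <- log(fit$coefTable$estimate[i])
    se <- fit$coefTable$se[i] / fit$coefTable$estimate[i]
    if (is.finite(se) && abs(b) <= 1.96 * se) cover <- cover + 1
  }
  expect_gte(cover, 88)  # ~95% nominal
})

test_that("marginal contrasts vanish under the null and detect dose effects", {
  tabNull <- glmBlockTable(nP = 14, targets = c("sham", "tA", "tB"),
                           beta = list(intercept = 0,
                                       target = c(tA = 0, tB = 0), mt = 0),
                           seed = 42, participantSd = 0.25,
                           sessionSlopeSd = 0.1, blockSd = 0.1)
  frNull <- hbcModelFrame(tabNull)
  fitNull <- suppressWarnings(fitGammaMixed(frNull, "glmm"))
  mc <- suppressWarnings(
    marginalContrasts(fitNull, atMt = c(60, 100, "average")))
  expect_true(all(mc$ci_low <= 0 & mc$ci_high >= 0))
  expect_true(all(mc$pred > 0))

  # effect only above 90 %MT: positive and significant at 100, null at 60
  tab <- glmBlockTable(nP = 14, targets = c("sham", "tA"),
                       beta = list(intercept = 0, target = c(tA = 0),
                                   mt = 0),
                       seed = 43, participantSd = 0.25,
                       sessionSlopeSd = 0.1, blockSd = 0.1)
  # saturating dose effect that only materializes above ~90 %MT
  act <- tab$target == "tA"
  tab$hbc_power[act] <- tab$hbc_power[act] *
    exp(log(3) * stats::plogis(0.4 * (tab$intensity_pct_mt[act] - 105)))
  fr <- hbcModelFrame(tab)
  fit <- suppressWarnings(fitGammaMixed(fr, "gam"))
  mc2 <- suppressWarnings(marginalContrasts(fit, atMt = c(60, 100)))
  at100 <- mc2[mc2$at == "100", ]
  at60 <- mc2[mc2$at == "60", ]
  expect_gt(at100$estimate, 0)
  expect_lt(at100$p_raw, 0.05)
  # the low-intensity contrast is negligible next to the high-intensity one
  expect_lt(abs(at60$estimate), 0.2 * at100$estimate)
})

test_that("Johnson-Neyman boundaries match the closed-form quadratic", {
  fake <- structure(list(variant = "glmm", converged = TRUE,
                         centers = c(mt = 0, pain = 3),
                         frame = data.frame(pain_c = seq(-3, 3, 0.1))),
                    class = "HbcFit")
  b1 <- 0.02; b3 <- 0.015
  V <- matrix(c(4e-4, 1e-5, 1e-5, 1e-4), 2,
              dimnames = list(c("mt_c", "mt_c:pain_c"),
                              c("mt_c", "mt_c:pain_c")))
  beta <- c(mt_c = b1, `mt_c:pain_c` = b3)
  # stub the coefficient accessors through a minimal glmmTMB-like object
  fakeEnv <- fake
  fakeEnv$fit <- NULL
  with_mocked_bindings(
    fixedCoef = function(fit) beta,
    fixedVcov = function(fit) V,
    .package = "CardioTMS",
    {
      jn <- johnsonNeyman(fakeEnv)
      roots <- jnQuadOracle(b1, b3, V[1, 1], V[2, 2], V[1, 2],
                            qnorm(0.975))
      inRange <- roots[roots > -3 & roots < 3] + 3  # original pain scale
      bounds <- sort(unique(c(jn$intervals$mod_low, jn$intervals$mod_high)))
      interior <- setdiff(round(bounds, 6), round(c(0, 6), 6))
      expect_equal(sort(interior), sort(round(inRange, 6)), tolerance = 1e-5)
    })
})

test_that("Johnson-Neyman degenerate cases behave as specified", {
  mkFake <- function() structure(
    list(variant = "glmm", converged = TRUE, centers = c(mt = 0, pain = 0),
         frame = data.frame(pain_c = seq(-2, 2, 0.1)), fit = NULL),
    class = "HbcFit")
  # zero interaction, strongly significant main slope -> whole range
  with_mocked_bindings(
    fixedCoef = function(fit) c(mt_c = 0.05, `mt_c:pain_c` = 0),
    fixedVcov = function(fit) diag(c(1e-6, 1e-6)) |>
      (\(m) {dimnames(m) <- list(c("mt_c", "mt_c:pain_c"),
                                 c("mt_c", "mt_c:pain_c")); m})(),
    .package = "CardioTMS",
    {
      jn <- johnsonNeyman(mkFake())
      expect_equal(nrow(jn$intervals), 1)
      expect_equal(jn$intervals$mod_low, -2)
      expect_equal(jn$intervals$mod_high, 2)
    })
  # nothing significant anywhere -> empty set, not an error
  with_mocked_bindings(
    fixedCoef = function(fit) c(mt_c = 1e-4, `mt_c:pain_c` = 1e-5),
    fixedVcov = function(fit) diag(c(1, 1)) |>
      (\(m) {dimnames(m) <- list(c("mt_c", "mt_c:pain_c"),
                                 c("mt_c", "mt_c:pain_c")); m})(),
    .package = "CardioTMS",
    expect_equal(nrow(johnsonNeyman(mkFake())$intervals), 0))
  # missing interaction
  with_mocked_bindings(
    fixedCoef = function(fit) c(mt_c = 0.1),
    fixedVcov = function(fit) matrix(1, dimnames = list("mt_c", "mt_c")),
    .package = "CardioTMS",
    expect_error(johnsonNeyman(mkFake()), "interaction"))
})

test_that("model comparison ranks by AIC and is stable for identical fits", {
  tab <- glmBlockTable(nP = 8, seed = 77)
  fr <- hbcModelFrame(tab)
  fit <- suppressWarnings(fitGammaMixed(fr, "glmm"))
  cmp <- compareModels(a = fit, b = fit)
  expect_identical(cmp$model, c("a", "b"))
  expect_equal(cmp$dAIC, c(0, 0))
  expect_error(compareModels(a = fit,
                             b = suppressWarnings(fitGammaMixed(
                               hbcModelFrame(glmBlockTable(nP = 4)),
                               "glmm"))),
               "identical rows")
})

test_that("the spline variant wins AIC under a nonlinear dose-response", {
  wins <- 0
  nRep <- 15
  for (r in seq_len(nRep)) {
    tab <- glmBlockTable(nP = 10, targets = c("sham", "tA", "tB"),
                         beta = list(intercept = 0,
                                     target = c(tA = 0.2, tB = 0.3),
                                     mt = 0),
                         seed = 5000 + r, participantSd = 0.25)
    # strong logistic (saturating) dose effect: not linear in %MT
    act <- tab$target != "sham"
    tab$hbc_power[act] <- tab$hbc_power[act] *
      exp(1.5 / (1 + exp(-0.25 * (tab$intensity_pct_mt[act] - 100))))
    fr <- hbcModelFrame(tab)
    fitL <- suppressWarnings(fitGammaMixed(fr, "glmm"))
    fitS <- suppressWarnings(fitGammaMixed(fr, "gam"))
    if (is.finite(fitS$AIC) && is.finite(fitL$AIC) &&
        fitS$AIC < fitL$AIC) wins <- wins + 1
  }
  expect_gte(wins, ceiling(0.9 * nRep))
})
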