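#' Simple (deviation-from-reference) contrast matrix
#'
#' Contrast coding in which each column compares one level against the
#' reference while the intercept estimates the grand mean of level means:
#' entries are \code{(k-1)/k} for the coded level and \code{-1/k}
#' elsewhere.
#'
#' @param levels character vector of factor levels; the first is the
#'   reference.
#' @return A k x (k-1) contrast matrix with informative dimnames.
#' @examples
#' simpleContrasts(c("sham", "a", "b"))  # entries 2/3 and -1/3
#' @export
simpleContrasts <- function(levels) {
  k <- length(levels)
  if (k < 2L) stop("simpleContrasts: need at least 2 levels")
  cm <- matrix(-1 / k, nrow = k, ncol = k - 1L,
               dimnames = list(levels, levels[-1L]))
  for (j in seq_len(k - 1L)) cm[j + 1L, j] <- (k - 1) / k
  cm
}

#' Partition-of-unity cubic B-spline basis
#'
#' Full cubic B-spline basis (including the intercept column) whose rows
#' sum to exactly 1 at every evaluation point; interior knots at quantiles.
#'
#' @param x evaluation points.
#' @param df basis dimension (number of columns), >= 4.
#' @param boundary optional boundary knots (range of \code{x} by default).
#' @return Matrix with \code{df} columns and attributes \code{knots},
#'   \code{boundary}.
#' @export
bsplineBasis <- function(x, df = 5, boundary = range(x)) {
  if (df < 4L) stop("bsplineBasis: df must be >= 4 for a cubic basis")
  B <- splines::bs(x, df = df, intercept = TRUE, Boundary.knots = boundary)
  out <- unclass(B)
  attributes(out) <- list(dim = dim(B),
                          dimnames = list(NULL, paste0("bs", seq_len(df))),
                          knots = attr(B, "knots"),
                          boundary = attr(B, "Boundary.knots"))
  out
}

#' Prepare an HBC block table for modeling
#'
#' Restricts to retained, valid rows with positive power, sets the target
#' factor with sham as reference level, the session factor, the block
#' factor, and mean-centers the continuous predictors (\%MT, pain,
#' side-effect sum) within the modeled rows.
#'
#' @param table block table from \code{\link{studyHbcTable}} (or matching
#'   schema).
#' @param shamLabel label of the sham target (reference level).
#' @param response response column name.
#' @return A data.frame with added columns \code{mt_c}, \code{pain_c},
#'   \code{se_c}, \code{session_f}, \code{session_num}, \code{target_f},
#'   \code{block_f}, \code{participant_f}; centers stored in
#'   \code{attr(, "centers")}.
#' @export
hbcModelFrame <- function(table, shamLabel = "sham", response = "hbc_power") {
  need <- c("participant", "session", "target", "intensity_pct_mt", "pain",
            "side_effects_sum", "retained", "valid", response)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("hbcModelFrame: missing columns: ", paste(miss, collapse = ", "))
  if (!(shamLabel %in% table$target))
    stop("hbcModelFrame: sham level '", shamLabel, "' absent from target")
  d <- table[table$retained & table$valid & !is.na(table[[response]]) &
             table[[response]] > 0, , drop = FALSE]
  lev <- c(shamLabel, sort(setdiff(unique(d$target), shamLabel)))
  d$target_f <- factor(d$target, levels = lev)
  d$session_f <- factor(d$session)
  d$session_num <- as.numeric(d$session) - mean(as.numeric(d$session))
  d$block_f <- factor(d$block_index)
  d$participant_f <- factor(d$participant)
  centers <- c(mt = mean(d$intensity_pct_mt), pain = mean(d$pain),
               se = mean(d$side_effects_sum))
  d$mt_c <- d$intensity_pct_mt - centers[["mt"]]
  d$pain_c <- d$pain - centers[["pain"]]
  d$se_c <- d$side_effects_sum - centers[["se"]]
  rownames(d) <- NULL
  attr(d, "centers") <- centers
  attr(d, "response") <- response
  d
}

#' Fixed-effect design matrices for the HBC model
#'
#' Builds the fixed-effect design: simple contrasts for session and target,
#' mean-centered continuous covariates, target-by-intensity and
#' pain-by-intensity interactions, and (optionally) partition-of-unity
#' cubic B-spline expansions of the continuous terms with by-target
#' replication of the intensity smooth.
#'
#' @param frame output of \code{\link{hbcModelFrame}}.
#' @param smooth expand continuous terms as B-spline bases (dimension
#'   \code{df}) instead of linear columns.
#' @param df spline basis dimension.
#' @return list with \code{X} (design matrix), \code{contrasts},
#'   \code{centers}, \code{terms} (assign map), and for the smooth design
#'   the spline attributes.
#' @export
buildDesign <- function(frame, smooth = FALSE, df = 5) {
  ctr <- list(target_f = simpleContrasts(levels(frame$target_f)),
              session_f = simpleContrasts(levels(frame$session_f)))
  if (!smooth) {
    X <- model.matrix(~ session_f + target_f + mt_c + pain_c + se_c +
                        target_f:mt_c + pain_c:mt_c,
                      data = frame, contrasts.arg = ctr)
    return(list(X = X, contrasts = ctr, centers = attr(frame, "centers"),
                smooth = FALSE))
  }
  Xpar <- model.matrix(~ session_f + target_f, data = frame,
                       contrasts.arg = ctr)
  Bmt <- bsplineBasis(frame$mt_c, df = df)
  Bpain <- bsplineBasis(frame$pain_c, df = df)
  Bse <- bsplineBasis(frame$se_c, df = df)
  # drop one column of each centered basis to avoid intercept confounding
  Xs <- cbind(Xpar,
              mt = Bmt[, -1L, drop = FALSE],
              pain = Bpain[, -1L, drop = FALSE],
              se = Bse[, -1L, drop = FALSE])
  # by-target replication of the intensity basis
  tf <- model.matrix(~ target_f - 1, data = frame)
  for (lv in colnames(tf)) {
    blk <- Bmt[, -1L, drop = FALSE] * tf[, lv]
    colnames(blk) <- paste0(lv, ":", colnames(blk))
    Xs <- cbind(Xs, blk)
  }
  list(X = Xs, contrasts = ctr, centers = attr(frame, "centers"),
       smooth = TRUE, df = df,
       bases = list(mt = Bmt, pain = Bpain, se = Bse))
}

reTermsGam <- c("s(participant_f)", "s(participant_f,session_num)",
                "s(block_f)")

#' Fit the Gamma log-link mixed-effects HBC model
#'
#' Fits the block-level model
#' \code{hbc_power ~ session + target + intensity + pain + side effects +
#' target:intensity + pain:intensity + (1 + session | participant) +
#' (1 | block)} with Gamma errors and a log link, in two variants:
#' \describe{
#'   \item{\code{"glmm"}}{linear continuous terms, fitted with glmmTMB
#'     (Laplace-approximated maximum likelihood).}
#'   \item{\code{"gam"}}{cubic B-spline smooths (basis dimension \code{k})
#'     of intensity, pain and side effects, a by-target intensity smooth
#'     and an intensity-by-pain tensor interaction, with random effects as
#'     penalized ("re") smooths, fitted with mgcv by REML.}
#' }
#' Simple contrasts are used for session and target (sham reference) and
#' continuous predictors are mean-centered. Coefficients are reported on
#' the multiplicative response-ratio scale (exponentiated), and all summary
#' p-values receive a Benjamini-Hochberg FDR column.
#'
#' @param frame output of \code{\link{hbcModelFrame}}.
#' @param variant \code{"glmm"} or \code{"gam"}.
#' @param k spline basis dimension for the GAM variant.
#' @param engine estimation engine for the GLMM variant:
#'   \code{"glmmTMB"} (maximum likelihood with Laplace-approximated random
#'   effects, the default) or \code{"bam"} (mgcv's fast fREML estimation of
#'   the identical model with random effects as penalized "re" smooths;
#'   useful for simulation studies with many refits).
#' @param start optional starting values passed to the GLMM optimizer
#'   (list with elements such as \code{theta}); the fit is deterministic
#'   given data and starting values. Starting the variance parameters at
#'   the boundary evaluates the model at zero random-effect variance,
#'   where it reduces to a single-level Gamma GLM.
#' @return An object of class \code{HbcFit}: list with \code{fit} (the
#'   engine object), \code{variant}, \code{coefTable} (term, estimate
#'   [ratio scale], se, statistic, p_raw, p_fdr), \code{smoothTable} (gam
#'   only: term, edf, statistic, p_raw, p_fdr), \code{logLik}, \code{AIC},
#'   \code{condR2}, \code{ranefVar}, \code{converged}, \code{frame},
#'   \code{centers}.
#' @export
fitGammaMixed <- function(frame, variant = c("glmm", "gam"), k = 5,
                          engine = c("glmmTMB", "bam"), start = NULL) {
  variant <- match.arg(variant)
  engine <- match.arg(engine)
  response <- attr(frame, "response")
  if (is.null(response)) response <- "hbc_power"
  if (any(frame[[response]] <= 0))
    stop("fitGammaMixed: Gamma family requires a strictly positive response")
  ctr <- list(target_f = simpleContrasts(levels(frame$target_f)),
              session_f = simpleContrasts(levels(frame$session_f)))
  if (variant == "glmm" && engine == "glmmTMB") {
    fml <- as.formula(paste(response,
      "~ session_f + target_f + mt_c + pain_c + se_c + target_f:mt_c +",
      "pain_c:mt_c + (1 + session_num | participant_f) + (1 | block_f)"))
    fit <- glmmTMB::glmmTMB(fml, data = frame,
                            family = stats::Gamma(link = "log"),
                            contrasts = ctr,
                            start = if (is.null(start)) list() else start)
    converged <- isTRUE(fit$sdr$pdHess) &&
      fit$fit$convergence == 0
    sm <- summary(fit)$coefficients$cond
    p <- sm[, "Pr(>|z|)"]
    coefTable <- data.frame(
      term = rownames(sm),
      estimate = exp(sm[, "Estimate"]),
      se = exp(sm[, "Estimate"]) * sm[, "Std. Error"],  # delta method
      statistic = sm[, "z value"],
      p_raw = p, p_fdr = fdrAdjust(p), row.names = NULL)
    vc <- glmmTMB::VarCorr(fit)$cond
    ranefVar <- c(participant_intercept = unname(vc$participant_f[1L, 1L]),
                  participant_session = unname(vc$participant_f[2L, 2L]),
                  block = unname(vc$block_f[1L, 1L]))
    smoothTable <- NULL
    mu <- predict(fit, type = "response")
  } else if (variant == "glmm") {  # engine == "bam"
    fml <- as.formula(paste(response,
      "~ session_f + target_f + mt_c + pain_c + se_c + target_f:mt_c +",
      "pain_c:mt_c + s(participant_f, bs = 're') +",
      "s(participant_f, session_num, bs = 're') + s(block_f, bs = 're')"))
    fit <- mgcv::bam(fml, data = frame, family = stats::Gamma(link = "log"),
                     discrete = TRUE, contrasts = ctr)
    converged <- isTRUE(fit$converged)
    sm <- summary(fit)
    pt <- sm$p.table
    p <- pt[, 4L]
    coefTable <- data.frame(
      term = rownames(pt),
      estimate = exp(pt[, "Estimate"]),
      se = exp(pt[, "Estimate"]) * pt[, "Std. Error"],
      statistic = pt[, 3L],
      p_raw = p, p_fdr = fdrAdjust(p), row.names = NULL)
    smoothTable <- NULL
    vcomp <- tryCatch({
      tmp <- NULL
      utils::capture.output(tmp <- mgcv::gam.vcomp(fit, rescale = TRUE))
      tmp
    }, error = function(e) NULL)
    ranefVar <- if (!is.null(vcomp) && is.matrix(vcomp)) {
      sel <- rownames(vcomp) %in% reTermsGam
      setNames(vcomp[sel, "std.dev"]^2, rownames(vcomp)[sel])
    } else NULL
    mu <- predict(fit, type = "response")
  } else {
    fml <- as.formula(paste(response,
      "~ session_f + target_f +",
      sprintf("s(mt_c, k = %d, bs = 'bs') +", k),
      sprintf("s(mt_c, by = target_f, k = %d, bs = 'bs') +", k),
      sprintf("s(pain_c, k = %d, bs = 'bs') +", k),
      sprintf("s(se_c, k = %d, bs = 'bs') +", k),
      sprintf("ti(mt_c, pain_c, k = c(%d, %d), bs = 'bs') +", k, k),
      "s(participant_f, bs = 're') + s(participant_f, session_num, bs = 're') +",
      "s(block_f, bs = 're')"))
    fit <- mgcv::gam(fml, data = frame, family = stats::Gamma(link = "log"),
                     method = "REML",
                     contrasts = ctr)
    converged <- isTRUE(fit$converged)
    sm <- summary(fit)
    pt <- sm$p.table
    p <- pt[, 4L]  # "Pr(>|t|)" (Gamma scale estimated) or "Pr(>|z|)"
    coefTable <- data.frame(
      term = rownames(pt),
      estimate = exp(pt[, "Estimate"]),
      se = exp(pt[, "Estimate"]) * pt[, "Std. Error"],
      statistic = pt[, 3L],
      p_raw = p, p_fdr = NA_real_, row.names = NULL)
    st <- sm$s.table
    keep <- !(rownames(st) %in% reTermsGam)
    smoothTable <- data.frame(
      term = rownames(st)[keep],
      edf = st[keep, "edf"],
      statistic = st[keep, 3L],
      p_raw = st[keep, "p-value"], p_fdr = NA_real_, row.names = NULL)
    # joint FDR over parametric and smooth p-values, as in a single summary
    allP <- fdrAdjust(c(coefTable$p_raw, smoothTable$p_raw))
    coefTable$p_fdr <- allP[seq_len(nrow(coefTable))]
    smoothTable$p_fdr <- allP[-seq_len(nrow(coefTable))]
    vcomp <- tryCatch({
      tmp <- NULL
      utils::capture.output(tmp <- mgcv::gam.vcomp(fit, rescale = TRUE))
      tmp
    }, error = function(e) NULL)
    ranefVar <- if (!is.null(vcomp) && is.matrix(vcomp)) {
      sel <- rownames(vcomp) %in% reTermsGam
      setNames(vcomp[sel, "std.dev"]^2, rownames(vcomp)[sel])
    } else NULL
    mu <- predict(fit, type = "response")
  }
  y <- frame[[response]]
  out <- list(fit = fit, variant = variant,
              coefTable = coefTable, smoothTable = smoothTable,
              logLik = as.numeric(logLik(fit)), AIC = AIC(fit),
              condR2 = cor(mu, y)^2,
              ranefVar = ranefVar, converged = converged,
              frame = frame, centers = attr(frame, "centers"),
              contrasts = ctr, k = k, response = response)
  class(out) <- "HbcFit"
  out
}

#' @method print HbcFit
#' @export
print.HbcFit <- function(x, ...) {
  cat("HbcFit (", x$variant, "): Gamma log-link,", nrow(x$frame), "rows,",
      "AIC", round(x$AIC, 1), ", conditional R2", round(x$condR2, 3),
      if (!x$converged) ", NOT CONVERGED" else "", "\n")
  print(transform(x$coefTable, estimate = round(estimate, 3),
                  se = round(se, 3), statistic = round(statistic, 2),
                  p_raw = signif(p_raw, 3), p_fdr = signif(p_fdr, 3)),
        row.names = FALSE)
  if (!is.null(x$smoothTable)) {
    cat("Smooth terms (edf):\n")
    print(transform(x$smoothTable, edf = round(edf, 2),
                    statistic = round(statistic, 2),
                    p_raw = signif(p_raw, 3), p_fdr = signif(p_fdr, 3)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR correction preserving input order; NaN/NA p-values propagate
#' to the output with a warning and do not influence the other adjustments.
#'
#' @param p numeric vector of p-values in [0, 1] (NA/NaN allowed).
#' @return Adjusted p-values, same length and order.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdrAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  bad <- is.na(p)
  if (any(bad)) warning("fdrAdjust: ", sum(bad), " NA/NaN p-value(s) propagated")
  ok <- p[!bad]
  if (any(ok < 0 | ok > 1)) stop("fdrAdjust: p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[!bad] <- p.adjust(ok, method = "BH")
  out
}

#' Marginal contrasts of each target versus sham
#'
#' Population-level predictions (random effects excluded, covariates at
#' their centered means, session at its grand mean via simple contrasts)
#' for every target at the requested intensities, and the response-scale
#' difference target - sham with delta-method CIs and FDR-adjusted
#' p-values. \code{"average"} averages the response-scale predictions over
#' the observed active-ramp intensities.
#'
#' @param fit an \code{HbcFit}.
#' @param atMt numeric \%MT values and/or the string \code{"average"}.
#' @param level confidence level.
#' @return data.frame: target, at, pred, pred_sham, estimate (difference),
#'   se, ci_low, ci_high, statistic, p_raw, p_fdr.
#' @export
marginalContrasts <- function(fit, atMt = c(60, 100, "average"),
                              level = 0.95) {
  stopifnot(inherits(fit, "HbcFit"))
  if (!fit$converged) warning("marginalContrasts: fit did not converge")
  frame <- fit$frame
  mtObs <- sort(unique(frame$intensity_pct_mt[frame$phase == "active"]))
  targets <- levels(frame$target_f)
  sham <- targets[1L]
  spec <- lapply(atMt, function(a) {
    if (identical(a, "average")) list(label = "average", mt = mtObs)
    else {
      a <- as.numeric(a)
      if (a < min(mtObs) || a > max(mtObs))
        warning("marginalContrasts: requested ", a,
                " %MT outside observed range [", min(mtObs), ", ",
                max(mtObs), "]; extrapolating")
      list(label = as.character(a), mt = a)
    }
  })
  beta <- fixedCoef(fit)
  V <- fixedVcov(fit)
  zc <- qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (sp in spec) {
    # response-scale prediction per target, averaged over sp$mt
    predOne <- function(tg) {
      nd <- data.frame(
        target_f = factor(tg, levels = targets),
        session_f = factor(levels(frame$session_f)[1L],
                           levels = levels(frame$session_f)),
        session_num = 0,
        mt_c = sp$mt - fit$centers[["mt"]],
        pain_c = 0, se_c = 0,
        participant_f = factor(levels(frame$participant_f)[1L],
                               levels = levels(frame$participant_f)),
        block_f = factor(levels(frame$block_f)[1L],
                         levels = levels(frame$block_f)))
      X <- populationLp(fit, nd)
      eta <- drop(X %*% beta)
      mu <- exp(eta)
      list(pred = mean(mu), grad = colMeans(mu * X))
    }
    ps <- predOne(sham)
    for (tg in setdiff(targets, sham)) {
      pt <- predOne(tg)
      est <- pt$pred - ps$pred
      g <- pt$grad - ps$grad
      se <- sqrt(drop(t(g) %*% V %*% g))
      z <- est / se
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg, at = sp$label, pred = pt$pred, pred_sham = ps$pred,
        estimate = est, se = se,
        ci_low = est - zc * se, ci_high = est + zc * se,
        statistic = z, p_raw = 2 * pnorm(-abs(z)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- fdrAdjust(out$p_raw)
  rownames(out) <- NULL
  out
}

# fixed-effect coefficient vector / vcov / population-level design matrix
fixedCoef <- function(fit) {
  if (inherits(fit$fit, "gam")) coef(fit$fit)
  else glmmTMB::fixef(fit$fit)$cond
}

fixedVcov <- function(fit) {
  if (inherits(fit$fit, "gam")) vcov(fit$fit) else vcov(fit$fit)$cond
}

populationLp <- function(fit, newdata) {
  if (inherits(fit$fit, "gam")) {
    predict(fit$fit, newdata = newdata, type = "lpmatrix",
            exclude = reTermsGam, newdata.guaranteed = TRUE)
  } else {
    tt <- stats::delete.response(stats::terms(
      lme4::nobars(stats::formula(fit$fit))))
    model.matrix(tt, newdata, contrasts.arg = fit$contrasts)
  }
}

#' Johnson-Neyman intervals for an intensity-by-moderator interaction
#'
#' Finds the moderator values at which the simple slope of the focal
#' continuous predictor stops/starts being significant, by evaluating
#' slope(m)/SE(m) on a dense grid over the observed moderator range and
#' refining each boundary crossing by root finding. Applies to fits with a
#' linear focal-by-moderator product term (the GLMM variant).
#'
#' @param fit an \code{HbcFit} with variant \code{"glmm"}.
#' @param focal name of the focal centered predictor (default
#'   \code{"mt_c"}).
#' @param moderator name of the centered moderator (default
#'   \code{"pain_c"}).
#' @param alpha significance level.
#' @param gridN grid resolution.
#' @return list with \code{intervals}: data.frame (mod_low, mod_high, on
#'   the original moderator scale) of significance regions within the
#'   observed range, and \code{grid}: data.frame (moderator, slope, se,
#'   statistic, significant).
#' @export
johnsonNeyman <- function(fit, focal = "mt_c", moderator = "pain_c",
                          alpha = 0.05, gridN = 512L) {
  stopifnot(inherits(fit, "HbcFit"))
  if (!fit$converged) warning("johnsonNeyman: fit did not converge")
  beta <- fixedCoef(fit)
  V <- fixedVcov(fit)
  if (!all(is.finite(V)))
    stop("johnsonNeyman: coefficient covariance unavailable (fit did not converge)")
  iF <- match(focal, names(beta))
  iI <- match(paste0(focal, ":", moderator), names(beta))
  if (is.na(iI)) iI <- match(paste0(moderator, ":", focal), names(beta))
  if (is.na(iF) || is.na(iI))
    stop("johnsonNeyman: model lacks the ", focal, " x ", moderator,
         " interaction")
  modObs <- fit$frame[[moderator]]
  centerKey <- sub("_c$", "", moderator)
  center <- fit$centers[[centerKey]]
  if (is.null(center) || is.na(center)) center <- 0
  mGrid <- seq(min(modObs), max(modObs), length.out = gridN)
  tFun <- function(m) {
    sl <- beta[iF] + beta[iI] * m
    se <- sqrt(V[iF, iF] + m^2 * V[iI, iI] + 2 * m * V[iF, iI])
    sl / se
  }
  crit <- qnorm(1 - alpha / 2)
  tv <- vapply(mGrid, tFun, numeric(1))
  sig <- abs(tv) > crit
  # refine boundaries where significance flips
  bounds <- numeric(0)
  flips <- which(diff(sig) != 0L)
  for (i in flips) {
    f <- function(m) abs(tFun(m)) - crit
    r <- stats::uniroot(f, c(mGrid[i], mGrid[i + 1L]), tol = 1e-10)
    bounds <- c(bounds, r$root)
  }
  edges <- c(min(modObs), bounds, max(modObs))
  intervals <- list()
  for (i in seq_len(length(edges) - 1L)) {
    mid <- (edges[i] + edges[i + 1L]) / 2
    if (abs(tFun(mid)) > crit)
      intervals[[length(intervals) + 1L]] <-
        data.frame(mod_low = edges[i] + center,
                   mod_high = edges[i + 1L] + center)
  }
  intervals <- if (length(intervals)) do.call(rbind, intervals)
               else data.frame(mod_low = numeric(0), mod_high = numeric(0))
  list(intervals = intervals,
       grid = data.frame(moderator = mGrid + center, slope = beta[iF] +
                           beta[iI] * mGrid,
                         se = vapply(mGrid, function(m)
                           sqrt(V[iF, iF] + m^2 * V[iI, iI] +
                                2 * m * V[iF, iI]), numeric(1)),
                         statistic = tv, significant = sig))
}

#' Compare fitted models by AIC
#'
#' @param ... named \code{HbcFit} objects fitted to identical rows.
#' @return data.frame sorted by ascending AIC with \code{dAIC}, \code{df},
#'   \code{logLik}, \code{condR2}.
#' @export
compareModels <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) &&
      !inherits(fits[[1L]], "HbcFit")) fits <- fits[[1L]]
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  ns <- vapply(fits, function(f) nrow(f$frame), integer(1))
  if (length(unique(ns)) != 1L)
    stop("compareModels: fits are not on identical rows (n = ",
         paste(ns, collapse = ", "), ")")
  out <- data.frame(
    model = names(fits),
    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
    df = vapply(fits, function(f) as.numeric(attr(logLik(f$fit), "df")),
                numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    condR2 = vapply(fits, function(f) f$condR2, numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$AIC), ]
  out$dAIC <- out$AIC - out$AIC[1L]
  rownames(out) <- NULL
  out
}
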