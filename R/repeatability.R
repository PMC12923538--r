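#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Absolute-agreement, single-measures ICC from the two-way ANOVA mean
#' squares of a subjects x raters matrix:
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' with the standard F-based confidence interval. Rows containing missing
#' cells are dropped (listwise) with a message. Negative estimates are
#' reported as computed. The consistency form ICC(C,1) is available via
#' \code{type = "consistency"}.
#'
#' @param m numeric matrix, subjects in rows, raters (sessions) in
#'   columns.
#' @param level confidence level.
#' @param type \code{"agreement"} (ICC(2,1), default) or
#'   \code{"consistency"} (ICC(C,1)).
#' @return list of class \code{IccResult}: icc, ci_low, ci_high, ms_rows,
#'   ms_cols, ms_error, n_subjects, k_raters, type, level.
#' @export
iccTwoWay <- function(m, level = 0.95, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  m <- as.matrix(m)
  complete <- complete.cases(m)
  if (any(!complete)) {
    message("iccTwoWay: dropping ", sum(!complete), " incomplete row(s)")
    m <- m[complete, , drop = FALSE]
  }
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("iccTwoWay: need at least 2 complete rows and 2 columns")
  rowMean <- rowMeans(m)
  colMean <- colMeans(m)
  grand <- mean(m)
  ssRows <- k * sum((rowMean - grand)^2)
  ssCols <- n * sum((colMean - grand)^2)
  ssTot <- sum((m - grand)^2)
  ssErr <- ssTot - ssRows - ssCols
  msr <- ssRows / (n - 1)
  msc <- ssCols / (k - 1)
  mse <- ssErr / ((n - 1) * (k - 1))
  icc <- if (type == "agreement")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
  # F-based CI (two-way random, single measures; agreement form uses the
  # Satterthwaite approximation of McGraw & Wong)
  alpha <- 1 - level
  if (!is.finite(icc) || mse <= 0 || icc >= 1 - 1e-12) {
    # degenerate: no residual variance; the interval collapses
    ciLow <- icc
    ciHigh <- icc
  } else if (type == "agreement") {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    Fstar1 <- qf(1 - alpha / 2, n - 1, v)
    Fstar2 <- qf(1 - alpha / 2, v, n - 1)
    ciLow <- n * (msr - Fstar1 * mse) /
      (Fstar1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    ciHigh <- n * (Fstar2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * Fstar2 * msr)
  } else {
    Fobs <- msr / mse
    FL <- Fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    FU <- Fobs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ciLow <- (FL - 1) / (FL + k - 1)
    ciHigh <- (FU - 1) / (FU + k - 1)
  }
  out <- list(icc = icc, ci_low = ciLow, ci_high = ciHigh,
              ms_rows = msr, ms_cols = msc, ms_error = mse,
              n_subjects = n, k_raters = k, type = type, level = level)
  class(out) <- "IccResult"
  out
}

#' @method print IccResult
#' @export
print.IccResult <- function(x, ...) {
  cat(sprintf("ICC(%s,1) = %.3f  [%.3f, %.3f]  (n = %d subjects, k = %d)\n",
              if (x$type == "agreement") "2" else "C",
              x$icc, x$ci_low, x$ci_high, x$n_subjects, x$k_raters))
  invisible(x)
}

#' Block-wise ICC across sessions, per target
#'
#' For every (target, retained block index) cell, forms the participants x
#' sessions matrix of HBC power and computes ICC(2,1). A
#' moderate-repeatability flag marks ICC >= 0.4.
#'
#' @param table block table (see \code{\link{studyHbcTable}}).
#' @param minSubjects minimum complete participants per cell.
#' @param type passed to \code{\link{iccTwoWay}}.
#' @return data.frame: target, block_index, intensity_pct_mt, icc, ci_low,
#'   ci_high, n, k, moderate (icc >= 0.4).
#' @export
iccByTargetBlock <- function(table, minSubjects = 2L,
                             type = "agreement") {
  stopifnot(all(c("participant", "session", "target", "block_index",
                  "hbc_power", "retained", "valid") %in% names(table)))
  sessions <- sort(unique(table$session))
  if (length(sessions) < 2L) stop("iccByTargetBlock: need >= 2 sessions")
  d <- table[table$retained & table$valid, , drop = FALSE]
  out <- list()
  for (tg in sort(unique(d$target))) {
    for (bi in sort(unique(d$block_index[d$target == tg]))) {
      cell <- d[d$target == tg & d$block_index == bi, , drop = FALSE]
      m <- crossTab(cell, sessions)
      m <- m[complete.cases(m), , drop = FALSE]
      if (nrow(m) < minSubjects) {
        message("iccByTargetBlock: skipping ", tg, " block ", bi,
                " (", nrow(m), " complete participants)")
        next
      }
      r <- iccTwoWay(m, type = type)
      out[[length(out) + 1L]] <- data.frame(
        target = tg, block_index = bi,
        intensity_pct_mt = cell$intensity_pct_mt[1L],
        icc = r$icc, ci_low = r$ci_low, ci_high = r$ci_high,
        n = r$n_subjects, k = r$k_raters, moderate = r$icc >= 0.4,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

crossTab <- function(cell, sessions) {
  parts <- sort(unique(cell$participant))
  m <- matrix(NA_real_, nrow = length(parts), ncol = length(sessions),
              dimnames = list(parts, paste0("S", sessions)))
  for (i in seq_len(nrow(cell)))
    m[match(cell$participant[i], parts),
      match(cell$session[i], sessions)] <- cell$hbc_power[i]
  m
}

#' Pairwise between-session ICCs
#'
#' ICC(2,1) with k = 2 for each requested session pair, per (target,
#' retained block index) cell.
#'
#' @param table block table.
#' @param sessionPairs list of length-2 session-id vectors; defaults to
#'   all pairs of the sessions present.
#' @param minSubjects minimum complete participants per cell.
#' @return data.frame: target, block_index, pair, icc, ci_low, ci_high,
#'   n, k.
#' @export
pairwiseSessionIcc <- function(table, sessionPairs = NULL, minSubjects = 2L) {
  sessions <- sort(unique(table$session))
  if (is.null(sessionPairs)) {
    cmb <- utils::combn(sessions, 2L)
    sessionPairs <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  }
  d <- table[table$retained & table$valid, , drop = FALSE]
  out <- list()
  for (pr in sessionPairs) {
    if (!all(pr %in% sessions))
      stop("pairwiseSessionIcc: unknown session id in pair (",
           paste(pr, collapse = ", "), ")")
    lab <- paste(pr, collapse = "-")
    for (tg in sort(unique(d$target))) {
      for (bi in sort(unique(d$block_index[d$target == tg]))) {
        cell <- d[d$target == tg & d$block_index == bi &
                  d$session %in% pr, , drop = FALSE]
        m <- crossTab(cell, pr)
        m <- m[complete.cases(m), , drop = FALSE]
        if (nrow(m) < minSubjects) next
        r <- iccTwoWay(m)
        out[[length(out) + 1L]] <- data.frame(
          target = tg, block_index = bi, pair = lab,
          icc = r$icc, ci_low = r$ci_low, ci_high = r$ci_high,
          n = r$n_subjects, k = r$k_raters, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
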