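#' Stepwise linear regression by partial F tests
#'
#' Classic forward-entry / backward-removal stepwise selection: at each step
#' the candidate with the smallest partial-F p-value enters if p <= p_enter
#' (ties broken by smaller p then lexicographic column name), then selected
#' predictors with partial-F p >= p_remove are removed (largest p first).
#' Candidates numerically collinear with the selected set (residual norm
#' ratio < 1e-10) are skipped. The procedure terminates: a visited selection
#' state is never re-entered.
#'
#' @param X numeric predictor matrix with unique column names (rows = lines).
#' @param y response (final yield, g/plant).
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10; must exceed p_enter).
#' @return list of class "stepwiseModel": selected (in entry order),
#'   coefficients (named, intercept first), r2, r2_percent, steps
#'   (data.frame of entry/removal events with F and p), n.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(50 * 5), 50, dimnames = list(NULL, paste0("x", 1:5)))
#' m <- stepwiseSelect(X, 3 * X[, 2] + rnorm(50, 0, .1))
#' m$selected
#' @export
stepwiseSelect <- function(X, y, p_enter = 0.05, p_remove = 0.10) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (nrow(X) < 10) stop("need at least 10 observations")
  if (p_enter >= p_remove) stop("p_enter must be smaller than p_remove")
  if (anyDuplicated(colnames(X))) stop("column names must be unique")
  n <- nrow(X)
  sel <- character(0)
  visited <- character(0)
  steps <- list()
  repeat {
    state <- paste(sort(sel), collapse = "|")
    if (state %in% visited) break
    visited <- c(visited, state)
    changed <- FALSE
    # --- forward entry ---
    cand <- setdiff(colnames(X), sel)
    if (length(cand)) {
      Q <- qr.Q(qr(cbind(1, X[, sel, drop = FALSE])))
      ry <- y - Q %*% crossprod(Q, y)
      Xc <- X[, cand, drop = FALSE]
      Rc <- Xc - Q %*% crossprod(Q, Xc)
      nres <- colSums(Rc^2)
      keep <- nres / pmax(colSums(Xc^2), .Machine$double.eps) > 1e-10
      if (any(keep)) {
        cn <- cand[keep]
        Rc <- Rc[, keep, drop = FALSE]; nres <- nres[keep]
        cross <- drop(crossprod(Rc, ry))
        ssr <- cross^2 / nres
        rss0 <- sum(ry^2)
        df2 <- n - length(sel) - 2
        if (df2 > 0) {
          Fv <- ssr * df2 / pmax(rss0 - ssr, .Machine$double.eps)
          pv <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
          ord <- order(pv, cn)
          if (pv[ord[1]] <= p_enter) {
            pick <- cn[ord[1]]
            sel <- c(sel, pick)
            steps[[length(steps) + 1L]] <-
              data.frame(action = "enter", term = pick,
                         F = Fv[ord[1]], p = pv[ord[1]])
            changed <- TRUE
          }
        }
      }
    }
    # --- backward removal ---
    repeat {
      if (length(sel) == 0L) break
      fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, sel, drop = FALSE]), y)
      df2 <- n - length(sel) - 1
      if (df2 <= 0) break
      s2 <- sum(fit$residuals^2) / df2
      R <- qr.R(fit$qr)
      XtXinv <- chol2inv(R)
      tstat <- fit$coefficients / sqrt(diag(XtXinv) * s2)
      Fv <- tstat[-1]^2
      pv <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
      worst <- which.max(pv)
      if (pv[worst] >= p_remove) {
        drop_term <- sel[worst]
        sel <- setdiff(sel, drop_term)
        steps[[length(steps) + 1L]] <-
          data.frame(action = "remove", term = drop_term,
                     F = unname(Fv[worst]), p = unname(pv[worst]))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, sel, drop = FALSE]), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("response has zero variance")
  structure(list(selected = sel,
                 coefficients = stats::setNames(
                   fit$coefficients, c("(Intercept)", sel)),
                 r2 = 1 - rss / tss,
                 r2_percent = 100 * (1 - rss / tss),
                 steps = if (length(steps)) do.call(rbind, steps)
                         else data.frame(action = character(0),
                                         term = character(0),
                                         F = numeric(0), p = numeric(0)),
                 n = n),
            class = "stepwiseModel")
}

#' @export
print.stepwiseModel <- function(x, ...) {
  cat(sprintf("Stepwise yield model: %d term(s), R2 = %.1f%% (n = %d)\n",
              length(x$selected), x$r2_percent, x$n))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Predict from a stepwise model
#' @param object a "stepwiseModel".
#' @param newdata matrix with the selected columns.
#' @param ... unused.
#' @export
predict.stepwiseModel <- function(object, newdata, ...) {
  drop(cbind(1, newdata[, object$selected, drop = FALSE]) %*%
         object$coefficients)
}

#' Percentage of yield variance explained
#'
#' R2 = 1 - RSS/TSS of the fitted stepwise model, reported in percent.
#'
#' @param model a "stepwiseModel".
#' @param X predictor matrix, \code{y} response (to recompute on given data;
#'   defaults to the in-sample value stored in the model).
#' @param y response vector.
#' @return R2 in percent.
#' @export
varianceExplained <- function(model, X = NULL, y = NULL) {
  if (is.null(X) || is.null(y)) return(model$r2_percent)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("response has zero variance")
  yhat <- predict.stepwiseModel(model, X)
  100 * (1 - sum((y - yhat)^2) / tss)
}

#' Repeated k-fold cross-validation of the stepwise yield model
#'
#' Stepwise selection is re-run inside every training fold (no leakage);
#' fold assignment is reshuffled per repeat from the seed. Out-of-fold
#' predictions are pooled per repeat to give an honest R2 and MAPE.
#'
#' @param X predictor matrix (lines x trait-time-point candidates).
#' @param y final yield per line.
#' @param k folds (paper protocol: 5).
#' @param repeats random instances of the k-fold split (paper protocol: 10).
#' @param seed integer seed.
#' @param p_enter,p_remove stepwise thresholds.
#' @return list: per_repeat (data.frame repeat_id, r2_percent, mape_percent),
#'   pooled (mean across repeats), k, repeats, seed.
#' @export
crossvalYield <- function(X, y, k = 5, repeats = 10, seed,
                          p_enter = 0.05, p_remove = 0.10) {
  n <- nrow(X)
  if (k > n) stop("k exceeds n")
  set.seed(seed)
  rows <- lapply(seq_len(repeats), function(rep_i) {
    ord <- sample.int(n)
    foldId <- integer(n)
    foldId[ord] <- rep(seq_len(k), length.out = n)
    pred <- rep(NA_real_, n)
    flagged <- FALSE
    for (f in seq_len(k)) {
      tr <- foldId != f
      if (stats::var(y[tr]) == 0) { flagged <- TRUE; next }
      m <- stepwiseSelect(X[tr, , drop = FALSE], y[tr], p_enter, p_remove)
      pred[!tr] <- predict.stepwiseModel(m, X[!tr, , drop = FALSE])
    }
    ok <- is.finite(pred)
    r2 <- 100 * (1 - sum((y[ok] - pred[ok])^2) / sum((y[ok] - mean(y[ok]))^2))
    mape <- if (all(y[ok] > 0)) mean(100 * abs(pred[ok] - y[ok]) / y[ok])
            else NA_real_
    data.frame(repeat_id = rep_i, r2_percent = r2, mape_percent = mape,
               flagged = flagged)
  })
  per <- do.call(rbind, rows)
  list(per_repeat = per,
       pooled = c(r2_percent = mean(per$r2_percent),
                  mape_percent = mean(per$mape_percent)),
       k = k, repeats = repeats, seed = seed)
}

#' Build the line-by-(trait, time point) predictor matrix
#'
#' Aggregates the long trait table to line means (across replicates and
#' within the given season), producing columns named e.g. "FDNIC_TV_7".
#' Constant and all-missing columns are screened out; lines with any missing
#' retained predictor are dropped listwise.
#'
#' @param traits long trait table.
#' @param season season to use (default: all rows pooled).
#' @param time_points integer subset of time points (default all present).
#' @return numeric matrix with rownames = line.
#' @export
predictorMatrix <- function(traits, season = NULL, time_points = NULL) {
  d <- traits
  if (!is.null(season)) d <- d[d$season %in% season, ]
  if (!is.null(time_points)) d <- d[d$time_point %in% time_points, ]
  d$col <- paste(d$trait, d$time_point, sep = "_")
  agg <- stats::aggregate(value ~ line + col, data = d, FUN = mean,
                          na.action = stats::na.omit)
  lines <- sort(unique(agg$line))
  cols <- sort(unique(agg$col))
  M <- matrix(NA_real_, length(lines), length(cols),
              dimnames = list(lines, cols))
  M[cbind(match(agg$line, lines), match(agg$col, cols))] <- agg$value
  keep <- apply(M, 2, function(x) sum(is.finite(x)) > 1 &&
                  stats::sd(x, na.rm = TRUE) > 0)
  M <- M[, keep, drop = FALSE]
  M[stats::complete.cases(M), , drop = FALSE]
}
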