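#' Growth-curve families
#'
#' Six families describe digital biomass (projected area) accumulation over
#' the inspection index t = 1..12: linear y = a + b t; quadratic
#' y = a + b t + c t^2; exponential y = a exp(b t); power y = a t^b;
#' logarithmic y = a + b ln t; sinusoidal y = a sin(b t + c) + d. Two views
#' times (2+3+2+2+2+4) parameters give the 30 growth-related traits.
#'
#' @return character vector of family codes.
#' @export
growthFamilies <- function() c("Lin", "Qua", "Exp", "Pow", "Log", "Sin")

.growthNPar <- c(Lin = 2L, Qua = 3L, Exp = 2L, Pow = 2L, Log = 2L, Sin = 4L)

# metrics on the original scale; constant series => adjusted R2 = 0 by
# convention; MAPE is NA when any y <= 0 (percentage error undefined)
.growthMetrics <- function(y, yhat, p) {
  n <- length(y)
  rss <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  adj <- if (tss <= 0 || n - p - 1 <= 0) 0
         else 1 - (rss / tss) * (n - 1) / (n - p - 1)
  if (all(y > 0)) {
    ape <- 100 * abs(yhat - y) / y
    mape <- mean(ape); sdape <- stats::sd(ape)
  } else mape <- sdape <- NA_real_
  c(adjusted_r2 = adj, mape_percent = mape, sd_ape_percent = sdape, n = n)
}

.nlsRefine <- function(y, t, form, start, lower, upper, seed = 1L) {
  best <- NULL
  starts <- list(start)
  set.seed(seed)
  for (i in seq_len(5L))            # seeded random restarts around the init
    starts[[i + 1L]] <- lapply(start, function(v) v * stats::runif(1, 0.7, 1.3))
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = data.frame(t = t, y = y), start = s,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(coef = stats::coef(fit), rss = rss)
    }
  }
  best
}

#' Fit one growth-curve family to a series
#'
#' Linear, quadratic and logarithmic families are fitted by least squares;
#' exponential and power families by nonlinear least squares initialised from
#' the log-linear fit; the sinusoid by a b-grid linear solve (for fixed b the
#' model is linear in A, B, d via y = A sin(bt) + B cos(bt) + d) followed by
#' nonlinear refinement. Metrics are computed on the original scale.
#'
#' @param t time-point index vector (strictly increasing).
#' @param y series values (projected area, px).
#' @param model one of \code{\link{growthFamilies}}.
#' @param seed seed for the bounded nonlinear restarts.
#' @return list: model, coef (named a, b, (c, d)), metrics, converged.
#' @examples
#' t <- 1:12
#' fitGrowthModel(t, 50 * exp(0.3 * t), "Exp")$coef
#' @export
fitGrowthModel <- function(t, y, model = growthFamilies(), seed = 1L) {
  model <- match.arg(model)
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  npar <- .growthNPar[[model]]
  fail <- list(model = model,
               coef = stats::setNames(rep(NA_real_, npar),
                                      letters[seq_len(npar)]),
               metrics = c(adjusted_r2 = NA_real_, mape_percent = NA_real_,
                           sd_ape_percent = NA_real_, n = length(y)),
               converged = FALSE)
  if (length(y) < npar + 2) return(fail)
  res <- switch(model,
    Lin = {
      cf <- stats::coef(stats::lm(y ~ t))
      list(coef = c(a = unname(cf[1]), b = unname(cf[2])),
           yhat = cf[1] + cf[2] * t)
    },
    Qua = {
      cf <- stats::coef(stats::lm(y ~ t + I(t^2)))
      list(coef = c(a = unname(cf[1]), b = unname(cf[2]), c = unname(cf[3])),
           yhat = cf[1] + cf[2] * t + cf[3] * t^2)
    },
    Log = {
      cf <- stats::coef(stats::lm(y ~ log(t)))
      list(coef = c(a = unname(cf[1]), b = unname(cf[2])),
           yhat = cf[1] + cf[2] * log(t))
    },
    Exp = {
      if (any(y <= 0)) return(fail)
      init <- stats::coef(stats::lm(log(y) ~ t))
      b <- .nlsRefine(y, t, y ~ a * exp(b * t),
                      list(a = exp(unname(init[1])), b = unname(init[2])),
                      lower = c(1e-12, -10), upper = c(Inf, 10), seed = seed)
      if (is.null(b)) return(fail)
      list(coef = c(a = unname(b$coef["a"]), b = unname(b$coef["b"])),
           yhat = b$coef["a"] * exp(b$coef["b"] * t))
    },
    Pow = {
      if (any(y <= 0)) return(fail)
      init <- stats::coef(stats::lm(log(y) ~ log(t)))
      b <- .nlsRefine(y, t, y ~ a * t^b,
                      list(a = exp(unname(init[1])), b = unname(init[2])),
                      lower = c(1e-12, -10), upper = c(Inf, 10), seed = seed)
      if (is.null(b)) return(fail)
      list(coef = c(a = unname(b$coef["a"]), b = unname(b$coef["b"])),
           yhat = b$coef["a"] * t^b$coef["b"])
    },
    Sin = {
      span <- diff(range(t))
      bgrid <- seq(0.05, pi, length.out = 60)
      best <- NULL
      for (bb in bgrid) {
        X <- cbind(1, sin(bb * t), cos(bb * t))
        cf <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
        if (is.null(cf) || anyNA(cf)) next
        rss <- sum((y - drop(X %*% cf))^2)
        if (is.null(best) || rss < best$rss)
          best <- list(b = bb, d = cf[1], A = cf[2], B = cf[3], rss = rss)
      }
      if (is.null(best)) return(fail)
      a0 <- sqrt(best$A^2 + best$B^2)
      c0 <- atan2(best$B, best$A)
      b <- .nlsRefine(y, t, y ~ a * sin(b * t + c) + d,
                      list(a = a0, b = best$b, c = c0, d = best$d),
                      lower = c(-Inf, 1e-6, -2 * pi, -Inf),
                      upper = c(Inf, pi + 0.5, 2 * pi, Inf), seed = seed)
      if (is.null(b)) return(fail)
      cf <- b$coef
      list(coef = c(a = unname(cf["a"]), b = unname(cf["b"]),
                    c = unname(cf["c"]), d = unname(cf["d"])),
           yhat = cf["a"] * sin(cf["b"] * t + cf["c"]) + cf["d"])
    })
  list(model = model, coef = res$coef,
       metrics = .growthMetrics(y, res$yhat, npar), converged = TRUE)
}

#' Compare the six growth families on one series
#'
#' @inheritParams fitGrowthModel
#' @return data.frame: model, adjusted_r2, mape_percent, sd_ape_percent,
#'   converged; ordered best adjusted R2 first (ties favour fewer parameters).
#' @export
compareGrowthModels <- function(t, y, seed = 1L) {
  fits <- lapply(growthFamilies(), function(m) fitGrowthModel(t, y, m, seed))
  out <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    n_par = .growthNPar[vapply(fits, `[[`, "", "model")],
    adjusted_r2 = vapply(fits, function(f) f$metrics[["adjusted_r2"]], 0),
    mape_percent = vapply(fits, function(f) f$metrics[["mape_percent"]], 0),
    sd_ape_percent = vapply(fits, function(f) f$metrics[["sd_ape_percent"]], 0),
    converged = vapply(fits, `[[`, TRUE, "converged"))
  out[order(-out$adjusted_r2, out$n_par), ]
}

#' The 30 growth-related trait names
#' @return character vector: {a,b}_{Lin,Exp,Pow,Log}_{SV,TV},
#'   {a,b,c}_Qua_{SV,TV}, {a,b,c,d}_Sin_{SV,TV}.
#' @export
growthTraitNames <- function() {
  unlist(lapply(c("SV", "TV"), function(v)
    unlist(lapply(growthFamilies(), function(m)
      paste(letters[seq_len(.growthNPar[[m]])], m, v, sep = "_")))))
}

#' Fit growth models per line and emit the 30 growth-related traits
#'
#' @param series long data.frame with columns line, season, view ("SV"/"TV"),
#'   t (1..12) and value (projected area). Lines with fewer than 6
#'   non-missing points in a view get NA for that view's traits.
#' @param seed nonlinear-restart seed.
#' @return wide data.frame: line, season, then the 30 named parameter columns.
#' @export
growthTraitTable <- function(series, seed = 1L) {
  keys <- unique(series[c("line", "season")])
  keys <- keys[order(keys$season, keys$line), , drop = FALSE]
  cols <- growthTraitNames()
  out <- cbind(keys, as.data.frame(
    matrix(NA_real_, nrow(keys), length(cols), dimnames = list(NULL, cols))))
  for (i in seq_len(nrow(keys))) {
    for (v in c("SV", "TV")) {
      s <- series[series$line == keys$line[i] & series$season == keys$season[i] &
                  series$view == v & is.finite(series$value), ]
      if (nrow(s) < 6L) next
      s <- s[order(s$t), ]
      for (m in growthFamilies()) {
        f <- fitGrowthModel(s$t, s$value, m, seed)
        out[i, paste(names(f$coef), m, v, sep = "_")] <- unname(f$coef)
      }
    }
  }
  out
}

#' Correlate growth-related traits with final yield
#'
#' Pairwise-complete Pearson correlation of each growth trait with yield.
#'
#' @param growth wide growth-trait table (see \code{\link{growthTraitTable}}).
#' @param yield data.frame with columns line and yield_g.
#' @return data.frame: trait, r, r2 (NA for zero-variance traits).
#' @export
correlateWithYield <- function(growth, yield) {
  d <- merge(growth, yield[c("line", "yield_g")], by = "line")
  if (nrow(d) < 3) stop("need at least 3 lines with yield")
  traits <- intersect(growthTraitNames(), names(d))
  r <- vapply(traits, function(tr) {
    x <- d[[tr]]; y <- d$yield_g
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok])
  }, 0)
  data.frame(trait = traits, r = unname(r), r2 = unname(r)^2)
}
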