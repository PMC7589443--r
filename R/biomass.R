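#' BiomassFit: a fitted biomass calibration model
#'
#' One entry of the 11-model catalogue fitted to destructive calibration
#' data. Linear-in-parameters families are fitted by ordinary least squares;
#' exponential and power families are fitted in log space (no smearing
#' correction on back-transform) and all reported metrics are computed on the
#' original scale.
#'
#' @slot modelId integer 1..11.
#' @slot family character description of the family.
#' @slot target "FW_g" or "DW_g".
#' @slot coef named numeric coefficient vector (intercept first).
#' @slot logY logical: model fitted on the log scale of the target.
#' @slot m character: the predictor used as "m" by the power model (id 9).
#' @slot metrics named numeric: adjusted_r2, mape_percent, sd_ape_percent, n.
#' @exportClass BiomassFit
setClass("BiomassFit",
  representation(modelId = "integer", family = "character",
                 target = "character", coef = "numeric", logY = "logical",
                 m = "character", metrics = "numeric"))

setMethod("show", "BiomassFit", function(object) {
  cat(sprintf("BiomassFit model %d (%s) for %s: adj R2 = %.4f, MAPE = %.2f%%\n",
              object@modelId, object@family, object@target,
              object@metrics["adjusted_r2"], object@metrics["mape_percent"]))
})

#' The 11-model biomass catalogue
#'
#' Families 1-4 are univariate in TPA_SV (linear, quadratic, exponential,
#' power), 5-8 the same in TPA_TV, 9 is the power model
#' ln(target) = a + b ln(m) with configurable m, 10 is bivariate linear in
#' (TPA_SV, TPA_TV) and 11 is the power model on m = TPA_SV + TPA_TV.
#'
#' @param m predictor used by model 9 ("TPA_SV" by default).
#' @return list of model descriptors (id, family, logY, design function).
#' @export
biomassCatalogue <- function(m = "TPA_SV") {
  d <- function(f) f
  list(
    list(id = 1L, family = "linear(TPA_SV)", logY = FALSE,
         design = d(function(x) cbind(TPA_SV = x$TPA_SV))),
    list(id = 2L, family = "quadratic(TPA_SV)", logY = FALSE,
         design = d(function(x) cbind(TPA_SV = x$TPA_SV, TPA_SV2 = x$TPA_SV^2))),
    list(id = 3L, family = "exponential(TPA_SV)", logY = TRUE,
         design = d(function(x) cbind(TPA_SV = x$TPA_SV))),
    list(id = 4L, family = "power(TPA_SV)", logY = TRUE,
         design = d(function(x) cbind(lnTPA_SV = log(x$TPA_SV)))),
    list(id = 5L, family = "linear(TPA_TV)", logY = FALSE,
         design = d(function(x) cbind(TPA_TV = x$TPA_TV))),
    list(id = 6L, family = "quadratic(TPA_TV)", logY = FALSE,
         design = d(function(x) cbind(TPA_TV = x$TPA_TV, TPA_TV2 = x$TPA_TV^2))),
    list(id = 7L, family = "exponential(TPA_TV)", logY = TRUE,
         design = d(function(x) cbind(TPA_TV = x$TPA_TV))),
    list(id = 8L, family = "power(TPA_TV)", logY = TRUE,
         design = d(function(x) cbind(lnTPA_TV = log(x$TPA_TV)))),
    list(id = 9L, family = sprintf("power(m=%s)", m), logY = TRUE,
         design = d(function(x) cbind(lnm = log(x[[m]])))),
    list(id = 10L, family = "linear(TPA_SV,TPA_TV)", logY = FALSE,
         design = d(function(x) cbind(TPA_SV = x$TPA_SV, TPA_TV = x$TPA_TV))),
    list(id = 11L, family = "power(TPA_SV+TPA_TV)", logY = TRUE,
         design = d(function(x) cbind(lnsum = log(x$TPA_SV + x$TPA_TV)))))
}

#' Which catalogue models belong to the power family
#' @return integer vector of model ids.
#' @export
powerFamilyIds <- function() c(4L, 8L, 9L, 11L)

#' Regression accuracy metrics on the original scale
#'
#' APE_i = 100 |yhat_i - y_i| / y_i; MAPE is the mean and SD_APE the sample
#' standard deviation of the APEs; adjusted R2 = 1 - (1 - R2)(n-1)/(n-p-1).
#'
#' @param y observed positive values.
#' @param yhat predictions (original scale).
#' @param p number of predictors (excluding the intercept).
#' @return named numeric: adjusted_r2, mape_percent, sd_ape_percent, n.
#' @examples
#' regressionMetrics(c(100, 200), c(110, 180), p = 1)
#' @export
regressionMetrics <- function(y, yhat, p) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  if (length(y) < p + 2) stop("need at least p + 2 observations")
  if (any(y <= 0)) stop("percentage error undefined: nonpositive y")
  ape <- 100 * abs(yhat - y) / y
  rss <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  n <- length(y)
  c(adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
    mape_percent = mean(ape),
    sd_ape_percent = stats::sd(ape),
    n = n)
}

.fitBiomassOLS <- function(model, data, target) {
  y <- data[[target]]
  if (any(y <= 0)) stop("nonpositive target values for model ", model$id)
  X <- model$design(data)
  if (model$logY && any(!is.finite(X)))
    stop("nonpositive areas under log model ", model$id)
  Xi <- cbind(`(Intercept)` = 1, X)
  q <- qr(Xi)
  if (q$rank < ncol(Xi))
    stop("singular design for biomass model ", model$id,
         " (", model$family, ")")
  yy <- if (model$logY) log(y) else y
  beta <- qr.coef(q, yy)
  yhat <- drop(Xi %*% beta)
  if (model$logY) yhat <- exp(yhat)
  list(coef = beta, yhat = yhat, p = ncol(X))
}

#' Fit one biomass model from the catalogue
#'
#' @param modelId integer 1..11 (see \code{\link{biomassCatalogue}}).
#' @param data data.frame with columns TPA_SV, TPA_TV and the target.
#' @param target "FW_g" or "DW_g".
#' @param m predictor used by model 9.
#' @return a \linkS4class{BiomassFit}.
#' @examples
#' d <- data.frame(TPA_SV = 1:20 * 100, TPA_TV = 1:20 * 60)
#' d$FW_g <- exp(1.2) * d$TPA_SV^0.8
#' fitBiomassModel(4, d, "FW_g")
#' @export
fitBiomassModel <- function(modelId, data, target = c("FW_g", "DW_g"),
                            m = "TPA_SV") {
  target <- match.arg(target)
  if (nrow(data) < 10)
    stop("need at least 10 calibration plants")
  model <- biomassCatalogue(m)[[modelId]]
  fit <- .fitBiomassOLS(model, data, target)
  new("BiomassFit", modelId = model$id, family = model$family,
      target = target, coef = fit$coef, logY = model$logY, m = m,
      metrics = regressionMetrics(data[[target]], fit$yhat, fit$p))
}

#' Predict biomass from projected areas
#'
#' @param fit a \linkS4class{BiomassFit}.
#' @param data data.frame with the predictor columns (TPA_SV and/or TPA_TV).
#' @return numeric predictions on the original (gram) scale; positive for
#'   log-scale families.
#' @export
predictBiomass <- function(fit, data) {
  model <- biomassCatalogue(fit@m)[[fit@modelId]]
  X <- cbind(1, model$design(data))
  yhat <- drop(X %*% fit@coef)
  if (fit@logY) exp(yhat) else yhat
}

#' k-fold cross-validation of a biomass model
#'
#' Plants are shuffled with the seed and split into k near-equal groups;
#' each group serves once as the test set. Reported metrics are the mean
#' adjusted R2, MAPE and SD_APE across folds, computed on the original scale.
#'
#' @param data calibration data.frame.
#' @param modelId catalogue model id.
#' @param k number of folds (paper protocol: 10).
#' @param seed integer RNG seed (mandatory, for reproducible folds).
#' @param target "FW_g" or "DW_g".
#' @param m predictor used by model 9.
#' @return list with \code{fold_metrics} (k x 4 matrix) and \code{mean}
#'   (named numeric: mean metrics across folds).
#' @export
kfoldCV <- function(data, modelId, k = 10, seed, target = c("FW_g", "DW_g"),
                    m = "TPA_SV") {
  target <- match.arg(target)
  n <- nrow(data)
  if (k > n) stop("k exceeds the number of plants")
  set.seed(seed)
  ord <- sample.int(n)
  foldId <- integer(n)
  foldId[ord] <- rep(seq_len(k), length.out = n)
  model <- biomassCatalogue(m)[[modelId]]
  fm <- t(vapply(seq_len(k), function(f) {
    tr <- data[foldId != f, , drop = FALSE]
    te <- data[foldId == f, , drop = FALSE]
    fit <- .fitBiomassOLS(model, tr, target)
    X <- cbind(1, model$design(te))
    yhat <- drop(X %*% fit$coef)
    if (model$logY) yhat <- exp(yhat)
    regressionMetrics(te[[target]], yhat, fit$p)
  }, numeric(4)))
  list(fold_metrics = fm, mean = colMeans(fm))
}

#' Rank the 11-model catalogue on calibration data
#'
#' Fits every catalogue model and orders them by adjusted R2 (descending).
#'
#' @inheritParams kfoldCV
#' @return data.frame: model_id, family, adjusted_r2, mape_percent,
#'   sd_ape_percent, ordered best first.
#' @export
rankBiomassModels <- function(data, target = c("FW_g", "DW_g"), m = "TPA_SV") {
  target <- match.arg(target)
  fits <- lapply(seq_len(11L), function(i)
    fitBiomassModel(i, data, target, m = m))
  out <- data.frame(
    model_id = vapply(fits, function(f) f@modelId, 0L),
    family = vapply(fits, function(f) f@family, ""),
    adjusted_r2 = vapply(fits, function(f) f@metrics[["adjusted_r2"]], 0),
    mape_percent = vapply(fits, function(f) f@metrics[["mape_percent"]], 0),
    sd_ape_percent = vapply(fits, function(f) f@metrics[["sd_ape_percent"]], 0))
  out[order(-out$adjusted_r2), ]
}

#' Append FW/DW i-traits to a long trait table
#'
#' Uses fitted fresh- and dry-weight models to predict biomass for every
#' (line, replicate, season, time_point) from its TPA_SV/TPA_TV rows,
#' completing the 43-trait set.
#'
#' @param traits long trait table (see \code{\link{writeTraitTable}}).
#' @param fwFit,dwFit \linkS4class{BiomassFit} objects for FW and DW.
#' @return the trait table with FW and DW rows appended.
#' @export
completeTraitTable <- function(traits, fwFit, dwFit) {
  keys <- c("line", "replicate", "season", "time_point")
  wide <- stats::reshape(
    traits[traits$trait %in% c("TPA_SV", "TPA_TV"), ],
    idvar = keys, timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  ok <- stats::complete.cases(wide[c("TPA_SV", "TPA_TV")]) &
    wide$TPA_SV > 0 & wide$TPA_TV > 0
  pred <- wide[ok, , drop = FALSE]
  add <- rbind(
    cbind(pred[keys], trait = "FW", value = predictBiomass(fwFit, pred)),
    cbind(pred[keys], trait = "DW", value = predictBiomass(dwFit, pred)))
  miss <- wide[!ok, , drop = FALSE]
  if (nrow(miss))
    add <- rbind(add,
                 cbind(miss[keys], trait = "FW", value = NA_real_),
                 cbind(miss[keys], trait = "DW", value = NA_real_))
  rbind(traits, add)
}
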