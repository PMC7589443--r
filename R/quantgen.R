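#' Phenotypic fold change per trait and time point
#'
#' For each (trait, time_point, season) cell, computes line means across
#' replicates and reports FC = max(line mean) / min(line mean). Cells whose
#' minimum line mean is not strictly positive (e.g. sign-indefinite third
#' moments) are reported NA with a flag, never zero.
#'
#' @param traits long trait table (line, replicate, season, time_point,
#'   trait, value).
#' @return list: \code{table} (data.frame trait, time_point, season,
#'   fold_change, flagged) and \code{mean_fold_change} (grand mean over
#'   unflagged cells).
#' @examples
#' tt <- expand.grid(line = c("L1", "L2", "L3"), replicate = 1:2,
#'                   season = "G1", time_point = 1, trait = "TPA_SV")
#' tt$value <- rep(c(2, 3, 5), 2)
#' foldChange(tt)$table$fold_change  # 2.5
#' @export
foldChange <- function(traits) {
  lm_ <- stats::aggregate(value ~ line + trait + time_point + season,
                          data = traits, FUN = mean, na.action = stats::na.omit)
  cells <- unique(lm_[c("trait", "time_point", "season")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    v <- lm_$value[lm_$trait == cells$trait[i] &
                   lm_$time_point == cells$time_point[i] &
                   lm_$season == cells$season[i]]
    v <- v[is.finite(v)]
    if (!length(v) || min(v) <= 0)
      data.frame(cells[i, ], fold_change = NA_real_, flagged = TRUE)
    else
      data.frame(cells[i, ], fold_change = max(v) / min(v), flagged = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       mean_fold_change = mean(tab$fold_change[!tab$flagged]))
}

#' Variance components of a line x environment x replicate layout
#'
#' Random-effects decomposition value = mu + G + GxE + error. The default
#' estimator is REML (lme4::lmer with environment as a fixed effect and
#' random line and line:environment terms); \code{method = "anova"} gives the
#' closed-form expected-mean-squares solution for balanced designs, to which
#' REML is equivalent there. Negative estimates are truncated at 0 and
#' flagged. With a single environment the GxE component is fixed at 0.
#'
#' @param data data.frame with columns line, env, replicate, value.
#' @param method "reml" or "anova".
#' @return list: sigma2_G, sigma2_GE, sigma2_e, n_env, n_rep (mean replicates
#'   per line x env cell), truncated (logical flag).
#' @export
varianceComponents <- function(data, method = c("reml", "anova")) {
  method <- match.arg(method)
  stopifnot(all(c("line", "env", "replicate", "value") %in% names(data)))
  data <- data[is.finite(data$value), ]
  if (length(unique(data$line)) < 2) stop("need at least 2 lines")
  nEnv <- length(unique(data$env))
  nRep <- mean(table(data$line, data$env)[table(data$line, data$env) > 0])
  truncated <- FALSE
  if (stats::var(data$value) == 0)
    return(list(sigma2_G = 0, sigma2_GE = 0, sigma2_e = 0,
                n_env = nEnv, n_rep = nRep, truncated = FALSE))
  if (nEnv == 1L) {
    if (method == "anova") {
      a <- stats::anova(stats::lm(value ~ factor(line), data = data))
      msG <- a[["Mean Sq"]][1]; msE <- a[["Mean Sq"]][2]
      sG <- (msG - msE) / nRep; sE <- msE
    } else {
      fit <- lme4::lmer(value ~ (1 | line), data = data,
                        control = lme4::lmerControl(calc.derivs = FALSE))
      vc <- as.data.frame(lme4::VarCorr(fit))
      sG <- vc$vcov[vc$grp == "line"]
      sE <- vc$vcov[vc$grp == "Residual"]
    }
    if (sG < 0) { sG <- 0; truncated <- TRUE }
    return(list(sigma2_G = sG, sigma2_GE = 0, sigma2_e = sE,
                n_env = 1L, n_rep = nRep, truncated = truncated))
  }
  if (method == "anova") {
    a <- stats::anova(stats::lm(value ~ factor(env) + factor(line) +
                                  factor(line):factor(env), data = data))
    ms <- stats::setNames(a[["Mean Sq"]], rownames(a))
    msG <- ms[["factor(line)"]]
    msGE <- ms[["factor(env):factor(line)"]]
    msE <- ms[["Residuals"]]
    sE <- msE
    sGE <- (msGE - msE) / nRep
    sG <- (msG - msGE) / (nRep * nEnv)
  } else {
    fit <- lme4::lmer(value ~ factor(env) + (1 | line) + (1 | line:env),
                      data = data,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sG <- vc$vcov[vc$grp == "line"]
    sGE <- vc$vcov[vc$grp == "line:env"]
    sE <- vc$vcov[vc$grp == "Residual"]
  }
  if (sG < 0) { sG <- 0; truncated <- TRUE }
  if (sGE < 0) { sGE <- 0; truncated <- TRUE }
  list(sigma2_G = sG, sigma2_GE = sGE, sigma2_e = sE,
       n_env = nEnv, n_rep = nRep, truncated = truncated)
}

#' Broad-sense heritability from variance components
#'
#' H2 = sigma2_G / (sigma2_G + sigma2_GE/n + sigma2_e/(n r)), with n the
#' number of environments and r the number of replicates per environment:
#' the fraction of line-mean variance attributable to genotype.
#'
#' @param vc list as returned by \code{\link{varianceComponents}} (or any list
#'   with sigma2_G, sigma2_GE, sigma2_e, n_env, n_rep).
#' @return H2 in [0, 1]; NA when all components are zero.
#' @examples
#' broadSenseHeritability(list(sigma2_G = 1, sigma2_GE = 0.5, sigma2_e = 1,
#'                             n_env = 2, n_rep = 5))  # 0.7407...
#' @export
broadSenseHeritability <- function(vc) {
  den <- vc$sigma2_G + vc$sigma2_GE / vc$n_env +
    vc$sigma2_e / (vc$n_env * vc$n_rep)
  if (den <= 0) return(NA_real_)
  vc$sigma2_G / den
}

#' Per-trait, per-time-point heritability of a trait table
#'
#' @param traits long trait table with seasons as environments.
#' @param method estimator passed to \code{\link{varianceComponents}}.
#' @return data.frame: trait, time_point, H2.
#' @export
heritabilityTable <- function(traits, method = "reml") {
  cells <- unique(traits[c("trait", "time_point")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- traits[traits$trait == cells$trait[i] &
                traits$time_point == cells$time_point[i], ]
    d <- data.frame(line = d$line, env = d$season,
                    replicate = d$replicate, value = d$value)
    h2 <- tryCatch(
      broadSenseHeritability(varianceComponents(d, method)),
      error = function(e) NA_real_)
    data.frame(trait = cells$trait[i], time_point = cells$time_point[i],
               H2 = h2)
  })
  do.call(rbind, rows)
}
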