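#' Rank fitted robust-design models by AICc
#'
#' @param fits list of [rd_fit()] objects (non-converged fits are dropped
#'   with a warning), or a numeric vector of AICc values together with `K`.
#' @param K optional parameter counts when `fits` is a numeric AICc vector.
#' @param names_ optional model labels.
#' @return data frame ordered by AICc with columns `model, AICc, dAICc,
#'   weight, model_lik, K`: `dAICc_i = AICc_i - min AICc`, relative model
#'   likelihood `exp(-dAICc/2)`, Akaike weight
#'   `exp(-dAICc/2) / sum_j exp(-dAICc_j/2)`.
#' @export
#' @examples
#' rd_rank(c(1779.2, 1779.4, 1780.8), K = c(12, 18, 16))
rd_rank <- function(fits, K = NULL, names_ = NULL) {
  if (is.numeric(fits)) {
    aicc <- fits
    stopifnot(!is.null(K), length(K) == length(aicc))
    if (is.null(names_)) names_ <- sprintf("Model %d", seq_along(aicc))
  } else {
    conv <- vapply(fits, function(f) isTRUE(f$convergence), logical(1))
    if (any(!conv)) {
      warning(sum(!conv), " non-converged model(s) excluded from ranking")
    }
    fits <- fits[conv]
    aicc <- vapply(fits, function(f) f$AICc, numeric(1))
    K <- vapply(fits, function(f) f$K, numeric(1))
    if (is.null(names_)) {
      names_ <- if (!is.null(names(fits)) && all(nzchar(names(fits))))
        names(fits) else sprintf("Model %d", seq_along(fits))
    } else {
      names_ <- names_[conv]
    }
  }
  d <- aicc - min(aicc)
  lik <- exp(-d / 2)
  out <- data.frame(model = names_, AICc = aicc, dAICc = d,
                    weight = lik / sum(lik), model_lik = lik, K = K,
                    stringsAsFactors = FALSE)
  out <- out[order(out$AICc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the most informative models
#'
#' The study's selection rule: keep models with relative model likelihood
#' above `min_lik` AND Akaike weight above `min_weight`. Falls back to the
#' single best model when the rule selects nothing.
#'
#' @param ranking an [rd_rank()] table (any table with `model_lik` and
#'   `weight` columns works, e.g. printed values from a publication).
#' @param min_lik,min_weight the thresholds (defaults 0.2 and 0.05).
#' @return the selected rows of `ranking`, with a `cum_weight` attribute
#'   giving the cumulative (unrenormalized) weight of the selection.
#' @export
select_models <- function(ranking, min_lik = 0.2, min_weight = 0.05) {
  keep <- ranking$model_lik > min_lik & ranking$weight > min_weight
  if (!any(keep)) keep <- seq_len(nrow(ranking)) == which.min(ranking$AICc)
  out <- ranking[keep, , drop = FALSE]
  attr(out, "cum_weight") <- sum(out$weight)
  out
}

#' Model-averaged parameter estimates
#'
#' Weighted means of real-scale parameter estimates across the selected
#' models, with weights renormalized over the selection. The reported SE is
#' the weighted mean of the per-model SEs (the study's convention;
#' `se_method = "unconditional"` switches to the Burnham-Anderson
#' unconditional-variance formula). 95% CIs use the link-scale normal
#' approximation around the averaged estimate. Averages are formed on the
#' full sex-by-season grid so models of different structure contribute
#' comparable cells; occasion-structured families cannot be averaged on
#' that grid and raise an error.
#'
#' @param fits named list of converged [rd_fit()] objects (same data).
#' @param min_lik,min_weight selection thresholds, see [select_models()].
#' @param se_method `"weighted_mean"` (default) or `"unconditional"`.
#' @return object of class `rd_average`: `estimates` (parameter, sex,
#'   season, weighted mean, SE, CI), `ranking`, `selected`, `weights`
#'   (renormalized).
#' @export
rd_average <- function(fits, min_lik = 0.2, min_weight = 0.05,
                       se_method = c("weighted_mean", "unconditional")) {
  se_method <- match.arg(se_method)
  stopifnot(length(fits) >= 1)
  ranking <- rd_rank(fits)
  sel <- select_models(ranking, min_lik, min_weight)
  idx <- match(sel$model, ranking$model)
  keep_names <- sel$model
  conv <- vapply(fits, function(f) isTRUE(f$convergence), logical(1))
  fits <- fits[conv]
  if (is.null(names(fits)) || !all(nzchar(names(fits)))) {
    names(fits) <- sprintf("Model %d", seq_along(fits))
  }
  fsel <- fits[keep_names]
  w <- sel$weight / sum(sel$weight)

  groups <- fsel[[1]]$parmap$groups
  seasons <- unique(fsel[[1]]$parmap$seasons)
  fams <- names(fsel[[1]]$parmap$model)
  rows <- list()
  for (fam in fams) {
    structs <- lapply(fsel, function(f) f$parmap$model[[fam]])
    if (any(vapply(structs, identical, logical(1), "occasion"))) {
      stop("cannot average occasion-structured family '", fam,
           "' on the sex-by-season grid")
    }
    for (g in groups) {
      for (sn in seasons) {
        est <- se <- numeric(length(fsel))
        for (m in seq_along(fsel)) {
          f <- fsel[[m]]
          cell <- .rd_cell_estimate(f, fam, g, sn)
          est[m] <- cell["estimate"]; se[m] <- cell["se"]
        }
        avg <- sum(w * est)
        avg_se <- if (se_method == "weighted_mean") sum(w * se) else
          sum(w * sqrt(se^2 + (est - avg)^2))
        ci <- .rd_link_ci(avg, avg_se, log_link = fam == "f0")
        rows[[length(rows) + 1]] <- data.frame(
          parameter = fam, sex = g, season = sn, estimate = avg,
          se = avg_se, lcl = ci[1], ucl = ci[2], stringsAsFactors = FALSE)
      }
    }
  }
  est <- do.call(rbind, rows)
  rownames(est) <- NULL
  out <- list(estimates = est, ranking = ranking, selected = sel,
              weights = stats::setNames(w, keep_names), fits = fsel)
  class(out) <- "rd_average"
  out
}

# real-scale estimate and SE of one (family, sex, season) cell of a fit
.rd_cell_estimate <- function(fit, fam, g, season) {
  pm <- fit$parmap
  s <- pm$model[[fam]]
  if (inherits(s, "rd_fixed")) {
    return(c(estimate = s$value, se = 0))
  }
  if (identical(s, "equal_p")) {
    return(.rd_cell_estimate(fit, "p", g, season))
  }
  lev <- .rd_level(s, g, season)
  k <- pm$idx[[fam]][[lev]]
  b <- unname(fit$par[k]); sb <- unname(sqrt(diag(fit$vcov))[k])
  if (fam == "f0") {
    c(estimate = exp(b), se = exp(b) * sb)
  } else {
    e <- stats::plogis(b)
    c(estimate = e, se = e * (1 - e) * sb)
  }
}

.rd_link_ci <- function(est, se, log_link = FALSE, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (!is.finite(se) || se <= 0 || !is.finite(est)) return(c(NA_real_, NA_real_))
  if (log_link) {
    if (est <= 0) return(c(NA_real_, NA_real_))
    sl <- se / est
    exp(log(est) + c(-z, z) * sl)
  } else {
    if (est <= 0 || est >= 1) return(c(NA_real_, NA_real_))
    sl <- se / (est * (1 - est))
    stats::plogis(stats::qlogis(est) + c(-z, z) * sl)
  }
}

#' @export
print.rd_average <- function(x, ...) {
  cat(sprintf("Model-averaged estimates over %d model(s), cumulative weight %.2f\n",
              nrow(x$selected), attr(x$selected, "cum_weight")))
  tab <- x$estimates
  tab[, 4:7] <- lapply(tab[, 4:7], function(z) round(z, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Derived abundance, density and sex ratio per primary occasion
#'
#' For each session and sex the abundance estimate is the number of true
#' individuals estimated to have been detected (genotypes with repeated
#' detections plus the model's expected real fraction of single-detection
#' genotypes, i.e. singletons discounted by the ghost expectation) plus the
#' estimated undetected count `f0`. Per-model values are combined as
#' weighted means over the selected models. Density divides total
#' abundance by the sampled area; the sex ratio is male over female
#' abundance.
#'
#' @param avg an [rd_average()] object (or a single [rd_fit()]).
#' @param area_km2 sampled area in square kilometres.
#' @return data frame per session: `session, pso, season, N_F, N_M,
#'   se_N_F, se_N_M, N_total, density, sex_ratio`.
#' @export
derived_abundance <- function(avg, area_km2) {
  stopifnot(area_km2 > 0)
  if (inherits(avg, "rd_fit")) {
    fits <- list(`Model 1` = avg)
    w <- c(`Model 1` = 1)
  } else {
    stopifnot(inherits(avg, "rd_average"))
    fits <- avg$fits
    w <- avg$weights
  }
  f1 <- fits[[1]]
  T <- f1$prep$T
  groups <- f1$prep$groups
  sessions <- f1$histories$sessions
  res <- data.frame(session = sessions, pso = seq_len(T),
                    season = f1$prep$seasons, stringsAsFactors = FALSE)
  for (g in groups) {
    Nm <- SEm <- matrix(0, T, length(fits))
    for (m in seq_along(fits)) {
      cells <- fits[[m]]$cells
      cg <- cells[cells$group == g, , drop = FALSE]
      cg <- cg[order(cg$pso), , drop = FALSE]
      if (nrow(cg) == 0) {
        warning("no detections for group ", g, "; abundance = f0 only")
        next
      }
      detected <- cg$C + cg$E_real_singletons
      Nm[, m] <- detected + cg$f0
      # SE: undetected-count uncertainty via the delta method on log(f0)
      sef0 <- vapply(seq_len(T), function(t) {
        cell <- .rd_cell_estimate(fits[[m]], "f0", g, cg$season[t])
        cell["se"]
      }, numeric(1))
      SEm[, m] <- sef0
    }
    res[[paste0("N_", g)]] <- as.vector(Nm %*% w)
    res[[paste0("se_N_", g)]] <- as.vector(SEm %*% w)
  }
  ncols <- paste0("N_", groups)
  res$N_total <- rowSums(res[, ncols, drop = FALSE])
  res$density <- res$N_total / area_km2
  res$sex_ratio <- if (all(c("N_F", "N_M") %in% names(res)))
    res$N_M / res$N_F else NA_real_
  res
}
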