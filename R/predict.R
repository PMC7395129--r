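## ---------------------------------------------------------------------------
## Predictability of workload targets from physiological features:
## per-feature Pearson r, multivariate regression R_adj = sqrt(|adjusted
## R^2|), quadratic fits with a U-shape flag, and the repeated five-fold
## cross-validated correlation R_CV of the cascade-forward network.
## ---------------------------------------------------------------------------

#' Pearson correlation between a feature and a target
#'
#' Pairwise-complete Pearson r with the two-sided p-value from the t
#' distribution. `NA` (with zero-variance or short input) is the
#' undefined marker.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, `n` (complete pairs used).
#' @export
pearson_feature_target <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Multivariate linear regression summarised as R_adj
#'
#' Ordinary least squares of the target on all features (with intercept).
#' The adjusted coefficient of determination `R2_adj = 1 - (1 - R2) *
#' (n - 1) / (n - p - 1)` can be negative; `R_adj = sqrt(|R2_adj|)` puts
#' it on a scale comparable to a Pearson r.
#'
#' @param X feature matrix or data.frame.
#' @param y numeric target.
#' @return list with `R_adj`, `R2_adj`, `R2`, `n`, `p` (predictors
#'   actually used; collinear columns are dropped with a warning).
#' @export
fit_linear_multi <- function(X, y) {
  X <- as.matrix(X)
  ok <- stats::complete.cases(X) & is.finite(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  fit <- lm(y ~ X)
  aliased <- is.na(coef(fit))[-1]
  if (any(aliased))
    warnf("dropping %d collinear feature(s)", sum(aliased))
  p <- sum(!aliased)
  if (n <= p + 1) stopf("need n > p + 1 observations")
  r2 <- summary(fit)$r.squared
  r2adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  list(R_adj = sqrt(abs(r2adj)), R2_adj = r2adj, R2 = r2, n = n, p = p)
}

#' Quadratic regression with a U-shape flag
#'
#' Ordinary least squares of `y` on `1, x, x^2`. `p2` is the p-value of
#' the overall F test of the quadratic model against the intercept-only
#' model. The U-shape flag is raised when the quadratic coefficient is
#' positive and the vertex `-b/(2a)` lies inside the observed range of
#' `x` (a within-range performance optimum).
#'
#' @param x predictor vector.
#' @param y response vector.
#' @return list with `coefficients` (`c0`, `c1`, `c2`), `p2`, `vertex`,
#'   `u_shape`, `n`.
#' @export
fit_quadratic <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stopf("need at least 4 complete observations")
  if (sd(x) == 0) stopf("degenerate predictor (zero variance)")
  fit <- lm(y ~ x + I(x^2))
  cf <- coef(fit)
  if (anyNA(cf)) stopf("degenerate predictor (collinear terms)")
  fs <- summary(fit)$fstatistic
  p2 <- unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  vertex <- -cf[[2]] / (2 * cf[[3]])
  list(coefficients = c(c0 = cf[[1]], c1 = cf[[2]], c2 = cf[[3]]),
       p2 = p2, vertex = vertex,
       u_shape = cf[[3]] > 0 && vertex >= min(x) && vertex <= max(x),
       n = length(x))
}

#' Repeated k-fold cross-validated correlation
#'
#' Per repeat: a random partition into `k` folds; for each fold the model
#' is trained on the remaining folds (all scaling fitted on training rows
#' only) and predicts the held-out rows, so every row receives exactly one
#' out-of-fold prediction; one Pearson correlation between predictions
#' and actual values is computed over all rows. `R_CV` is the mean of
#' these correlations over repeats.
#'
#' @param spec a [cf_net_spec()], or `"linear"` for a least-squares
#'   baseline model.
#' @param X feature matrix.
#' @param y target vector.
#' @param k number of folds, default 5.
#' @param repeats number of repeated partitions (1000 reproduces
#'   full-scale runs; 100 is the reduced default).
#' @param seed integer seed driving fold assignment and net
#'   initialisation.
#' @return list with `R_CV` (mean), `sd`, `r_values` (per repeat),
#'   `n_excluded` (repeats with degenerate constant predictions).
#' @export
cross_validated_correlation <- function(spec, X, y, k = 5, repeats = 100,
                                        seed = 1L) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 2 * k) stopf("need at least 2k observations")
  linear <- identical(spec, "linear")
  with_seed_if(seed, {
    rvals <- vapply(seq_len(repeats), function(rep_i) {
      folds <- sample(rep(seq_len(k), length.out = n))
      yhat <- numeric(n)
      for (f in seq_len(k)) {
        tr <- folds != f
        if (linear) {
          df <- data.frame(y = y[tr], X[tr, , drop = FALSE])
          m <- lm(y ~ ., data = df)
          yhat[!tr] <- predict(m, data.frame(X[!tr, , drop = FALSE]))
        } else {
          sp <- spec; sp$seed <- sample.int(2^30, 1)
          m <- train_cf_net(sp, X[tr, , drop = FALSE], y[tr])
          yhat[!tr] <- predict(m, X[!tr, , drop = FALSE])
        }
      }
      if (sd(yhat) == 0) return(NA_real_)
      cor(yhat, y)
    }, numeric(1))
    list(R_CV = mean(rvals, na.rm = TRUE),
         sd = sd(rvals, na.rm = TRUE),
         r_values = rvals,
         n_excluded = sum(is.na(rvals)))
  })
}

#' Build the prediction-performance table
#'
#' For every target: the Pearson correlation (with a significance star at
#' p < 0.05, no multiplicity correction) between each physiological
#' feature and the target, the multivariate regression `R_adj` over all
#' features, and the cascade-forward network `R_CV` from repeated
#' five-fold cross-validation.
#'
#' @param features aligned feature data.frame (see
#'   [assemble_feature_target_tables()]).
#' @param targets aligned target data.frame.
#' @param target_cols target column names; defaults to the workload
#'   measures present.
#' @param feature_cols feature column names (the nine physiological
#'   features).
#' @param spec a [cf_net_spec()] for the network column.
#' @param repeats cross-validation repeats.
#' @param seed integer seed.
#' @return a `prediction_result`: data.frame with one row per target,
#'   columns `<feature>_r`, `<feature>_p`, `R_adj`, `R_CV`, `R_CV_sd`;
#'   attribute `stars` marks p < 0.05 cells.
#' @export
build_prediction_table <- function(features, targets,
                                   target_cols = intersect(
                                     c("nasa_tlx_avg", "reaction_time",
                                       "non_response_rate", "completion_time",
                                       "error_rate"),
                                     names(targets)),
                                   feature_cols = c("hr_mean", "hr_std", "hr_max",
                                                    "hr_min", "hrv_mean", "hrv_std",
                                                    "hrv_max", "hrv_min", "br_mean"),
                                   spec = cf_net_spec(), repeats = 100,
                                   seed = 1L) {
  if (nrow(features) != nrow(targets)) stopf("tables are not aligned")
  Xall <- as.matrix(features[feature_cols])
  rows <- lapply(target_cols, function(tc) {
    y <- targets[[tc]]
    row <- list(target = tc)
    for (fc in feature_cols) {
      pr <- pearson_feature_target(features[[fc]], y)
      row[[paste0(fc, "_r")]] <- pr$r
      row[[paste0(fc, "_p")]] <- pr$p
    }
    ok <- stats::complete.cases(Xall) & is.finite(y)
    row$R_adj <- fit_linear_multi(Xall[ok, , drop = FALSE], y[ok])$R_adj
    cv <- cross_validated_correlation(spec, Xall[ok, , drop = FALSE], y[ok],
                                      repeats = repeats,
                                      seed = derive_seed(seed, tc))
    row$R_CV <- cv$R_CV
    row$R_CV_sd <- cv$sd
    as.data.frame(row)
  })
  out <- do.call(rbind, rows)
  pcols <- grep("_p$", names(out), value = TRUE)
  stars <- as.matrix(out[pcols] < 0.05)
  attr(out, "stars") <- stars
  class(out) <- c("prediction_result", "data.frame")
  out
}
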