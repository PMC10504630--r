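# Generalized estimating equations for repeated binary outcomes.
#
# Marginal logistic model fitted by Fisher scoring on the GEE score
# equations, with an exchangeable or independence working correlation
# (moment estimator for the common correlation) and robust sandwich
# standard errors clustered on the subject. Written for the modest model
# sizes of perioperative prevalence trajectories (a handful of
# coefficients, hundreds to thousands of subjects).

#' Fit a logistic GEE
#'
#' @param y Binary (0/1 or logical) outcome vector.
#' @param X Design matrix (including the intercept column).
#' @param id Cluster (subject) identifier, same length as `y`.
#' @param corstr Working correlation: `"exchangeable"` (default) or
#'   `"independence"`.
#' @param maxit Maximum Fisher-scoring iterations.
#' @param tol Convergence tolerance on the largest coefficient change.
#' @return Object of class `perisym_gee`: `coefficients`, `robust_se`,
#'   `naive_se`, `z`, `p`, `alpha` (estimated working correlation),
#'   `vcov_robust`, `niter`, `converged`, `n_clusters`, `n_obs`.
#' @examples
#' set.seed(1)
#' x <- rnorm(200); y <- rbinom(200, 1, plogis(-0.5 + x))
#' f <- gee_fit(y, cbind(1, x), id = seq_along(y), corstr = "independence")
#' coef(f)
#' @export
gee_fit <- function(y, X, id, corstr = c("exchangeable", "independence"),
                    maxit = 50L, tol = 1e-9) {
  corstr <- match.arg(corstr)
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[
      seq_len(ncol(X))]
  }
  stopifnot(length(y) == nrow(X), length(id) == length(y),
            all(y %in% c(0, 1)))
  p <- ncol(X)
  cl <- split(seq_along(y), id)
  K <- length(cl)

  # start from the ordinary logistic fit (independence estimate)
  beta <- suppressWarnings(coef(glm.fit(X, y, family = binomial())))
  alpha <- 0
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    v <- mu * (1 - mu)
    res <- (y - mu) / sqrt(v)   # Pearson residuals

    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (ix in cl) {
        ni <- length(ix)
        if (ni < 2) next
        ri <- res[ix]
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
      phi <- sum(res^2) / (length(y) - p)
      alpha <- if (den > p) num / ((den - p) * phi) else 0
      alpha <- max(min(alpha, 0.99), -0.99)
    }

    A <- matrix(0, p, p)   # sum_i X_i' D_i' V_i^{-1} D_i X_i (model-based)
    u <- numeric(p)        # sum_i X_i' D_i' V_i^{-1} (y_i - mu_i)
    for (ix in cl) {
      ni <- length(ix)
      Xi <- X[ix, , drop = FALSE]
      si <- sqrt(v[ix])
      Di <- Xi * v[ix]                        # d mu / d beta
      if (corstr == "independence" || ni == 1 || alpha == 0) {
        Vinv_r <- (y[ix] - mu[ix]) / v[ix]
        A <- A + crossprod(Di, Di / v[ix])
        u <- u + drop(crossprod(Di, Vinv_r))
      } else {
        # R^{-1} = c1 I + c2 J for exchangeable correlation
        c1 <- 1 / (1 - alpha)
        c2 <- -alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
        Vinv <- function(M) {
          Ms <- M / si                        # A^{-1/2} M
          Rm <- c1 * Ms + c2 * matrix(colSums(Ms), ni, ncol(M), byrow = TRUE)
          Rm / si                             # A^{-1/2} R^{-1} A^{-1/2} M
        }
        A <- A + crossprod(Di, Vinv(Di))
        u <- u + drop(crossprod(Di, Vinv(cbind(y[ix] - mu[ix]))))
      }
    }
    step <- solve(A, u)
    beta <- beta + step
    trace[iter] <- max(abs(step))
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged && maxit > 1 && trace[length(trace)] > 1e-4) {
    stop_data("GEE did not converge in ", maxit, " iterations; ",
              "max |step| trace: ",
              paste(signif(utils::tail(trace, 5), 3), collapse = ", "))
  }

  # sandwich covariance at the solution
  eta <- drop(X %*% beta); mu <- plogis(eta); v <- mu * (1 - mu)
  A <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ix in cl) {
    ni <- length(ix)
    Xi <- X[ix, , drop = FALSE]
    si <- sqrt(v[ix])
    Di <- Xi * v[ix]
    if (corstr == "independence" || ni == 1 || alpha == 0) {
      gi <- drop(crossprod(Di, (y[ix] - mu[ix]) / v[ix]))
      A <- A + crossprod(Di, Di / v[ix])
    } else {
      c1 <- 1 / (1 - alpha)
      c2 <- -alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
      Vinv <- function(M0) {
        Ms <- M0 / si
        Rm <- c1 * Ms + c2 * matrix(colSums(Ms), ni, ncol(M0), byrow = TRUE)
        Rm / si
      }
      gi <- drop(crossprod(Di, Vinv(cbind(y[ix] - mu[ix]))))
      A <- A + crossprod(Di, Vinv(Di))
    }
    M <- M + tcrossprod(gi)
  }
  Ainv <- solve(A)
  Vrob <- Ainv %*% M %*% Ainv
  se <- sqrt(diag(Vrob))
  z <- beta / se
  out <- list(coefficients = setNames(drop(beta), colnames(X)),
              robust_se = setNames(se, colnames(X)),
              naive_se = setNames(sqrt(diag(Ainv)), colnames(X)),
              z = setNames(z, colnames(X)),
              p = setNames(2 * pnorm(-abs(z)), colnames(X)),
              alpha = alpha, vcov_robust = Vrob, niter = iter,
              converged = converged, corstr = corstr,
              n_clusters = K, n_obs = length(y))
  class(out) <- "perisym_gee"
  out
}

#' @export
coef.perisym_gee <- function(object, ...) object$coefficients

#' @export
print.perisym_gee <- function(x, ...) {
  cat(sprintf("Logistic GEE (%s working correlation, alpha = %.3f)\n",
              x$corstr, x$alpha))
  cat(sprintf("%d observations in %d clusters; %d iterations\n",
              x$n_obs, x$n_clusters, x$niter))
  tab <- data.frame(estimate = x$coefficients, robust_se = x$robust_se,
                    z = x$z, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' GEE prevalence trend over the perioperative windows
#'
#' Fits a logistic GEE of symptom presence on the time-window index
#' (PREOP = 0 through M4_6 = 4, entered as a linear term) plus optional
#' patient-level covariates, clustered on the patient with an exchangeable
#' working correlation and robust standard errors.
#'
#' @param presence Long-format data frame with `patient_key`, `window`
#'   (or a numeric `time` column) and `present`.
#' @param covariates Optional data frame of patient-level covariates with a
#'   `patient_key` column; every non-key column enters the model.
#' @param corstr Working correlation structure.
#' @return A `perisym_gee` fit; the time coefficient is named `"time"`.
#' @export
gee_trend <- function(presence, covariates = NULL,
                      corstr = "exchangeable") {
  df <- as.data.frame(presence)
  if (!"time" %in% names(df)) {
    df$time <- match(df$window, PERISYM_WINDOWS) - 1L
    if (any(is.na(df$time))) stop_data("unknown window label in presence data")
  }
  X <- cbind("(Intercept)" = rep(1, nrow(df)), time = df$time)
  if (!is.null(covariates)) {
    idx <- match(df$patient_key, covariates$patient_key)
    if (any(is.na(idx))) stop_data("covariates missing for some patients")
    for (v in setdiff(names(covariates), "patient_key")) {
      X <- cbind(X, as.numeric(covariates[[v]][idx]))
      colnames(X)[ncol(X)] <- v
    }
  }
  gee_fit(as.numeric(df$present), X, df$patient_key, corstr = corstr)
}

#' Piecewise prevalence trends around the one-month knot
#'
#' Two segment fits: from the preoperative window to one month after
#' surgery (PREOP, M1) and from one month to 4-6 months (M1, M2, M3,
#' M4_6), each a [gee_trend()] on the sub-range with time re-indexed from
#' zero. Captures fall-then-plateau and rise-then-fall patterns that a
#' single linear trend misses.
#'
#' @param presence Long-format presence data (as for [gee_trend()]).
#' @param covariates Optional covariates passed to both segments.
#' @param corstr Working correlation structure.
#' @return List of class `perisym_piecewise` with `segment1` and
#'   `segment2` (`perisym_gee` fits) and `knot = "M1"`.
#' @export
piecewise_trend <- function(presence, covariates = NULL,
                            corstr = "exchangeable") {
  df <- as.data.frame(presence)
  seg1 <- df[df$window %in% c("PREOP", "M1"), , drop = FALSE]
  seg2 <- df[df$window %in% c("M1", "M2", "M3", "M4_6"), , drop = FALSE]
  if (nrow(seg1) == 0 || nrow(seg2) == 0) {
    stop_data("piecewise fit needs data on both sides of the M1 knot")
  }
  seg2$time <- match(seg2$window, PERISYM_WINDOWS) - 2L  # M1 = 0
  structure(list(segment1 = gee_trend(seg1, covariates, corstr),
                 segment2 = gee_trend(seg2, covariates, corstr),
                 knot = "M1"),
            class = "perisym_piecewise")
}

#' @export
print.perisym_piecewise <- function(x, ...) {
  s1 <- x$segment1; s2 <- x$segment2
  cat("Piecewise GEE trends (knot at M1)\n")
  cat(sprintf("  PREOP -> M1 : estimate %.4f (SE %.4f), p = %.3g\n",
              s1$coefficients["time"], s1$robust_se["time"], s1$p["time"]))
  cat(sprintf("  M1 -> M4_6  : estimate %.4f (SE %.4f), p = %.3g\n",
              s2$coefficients["time"], s2$robust_se["time"], s2$p["time"]))
  invisible(x)
}
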