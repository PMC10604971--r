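#' Restricted log-likelihood of the multi-component mixed model
#'
#' The model is y = Xb + sum_i u_i + e with Var(u_i) = sigma_i^2 S_i and
#' Var(e) = sigma_e^2 I, one observation per individual, so
#' V = sum_i sigma_i^2 S_i + sigma_e^2 I.  The restricted log-likelihood is
#' -(log|V| + log|X'V^-1 X| + y'Py)/2 up to an additive constant, with
#' P = V^-1 - V^-1 X (X'V^-1 X)^-1 X' V^-1.
#'
#' @param theta Numeric vector of f + 1 variance components, the residual
#'   last; all must be positive.
#' @param y Phenotype vector (length n).
#' @param X n x c fixed-effect design matrix of full column rank.
#' @param S_list List of f `grm` objects (or plain n x n matrices).
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(theta, y, X, S_list) {
  st <- .reml_state(theta, y, X, .as_matrices(S_list))
  st$loglik
}

.as_matrices <- function(S_list) {
  lapply(S_list, function(s) if (inherits(s, "grm")) s$matrix else as.matrix(s))
}

# V, its Cholesky pieces, P y, log-likelihood, and per-component quantities
.reml_state <- function(theta, y, X, S_mats) {
  n <- length(y)
  f <- length(S_mats)
  stopifnot(length(theta) == f + 1L, all(theta > 0))
  V <- diag(theta[f + 1L], n)
  for (i in seq_len(f)) V <- V + theta[i] * S_mats[[i]]
  R <- tryCatch(chol(V), error = function(e)
    stop("phenotypic covariance V is not positive definite at theta = ",
         paste(format(theta), collapse = ", ")))
  logdetV <- 2 * sum(log(diag(R)))
  Vinv <- chol2inv(R)
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  Rx <- tryCatch(chol(XtVinvX), error = function(e)
    stop("X'V^-1X is singular; design matrix not full rank?"))
  logdetXtVinvX <- 2 * sum(log(diag(Rx)))
  XtVinvX_inv <- chol2inv(Rx)
  P <- Vinv - VinvX %*% XtVinvX_inv %*% t(VinvX)
  Py <- P %*% y
  loglik <- -0.5 * (logdetV + logdetXtVinvX + sum(y * Py))
  list(V = V, Vinv = Vinv, P = P, Py = Py, loglik = loglik,
       XtVinvX_inv = XtVinvX_inv, VinvX = VinvX)
}

#' Fit variance components by AI-REML with EM-REML fallback
#'
#' Average-information REML updates, falling back to an EM-REML step whenever
#' the AI step would leave the feasible region or decrease the restricted
#' log-likelihood (EM steps never decrease it).  Components that the
#' iteration pushes to zero are clamped at `1e-6 * var(y)` and flagged as
#' boundary solutions (printed heritabilities of 0.000 correspond to such
#' components).  Convergence: |change in restricted log-likelihood| <
#' `tol` between accepted iterates.
#'
#' @param y,X,S_list As in [reml_loglik()].  GRMs should be pre-normalized to
#'   mean diagonal 1 so components are on the phenotypic-variance scale.
#' @param labels Component labels (defaults to the GRM labels).
#' @param start Starting values; default splits var(y) equally across all
#'   f + 1 components.
#' @param tol Convergence tolerance on the restricted log-likelihood change.
#' @param max_iter Maximum iterations; non-convergence returns
#'   `converged = FALSE` rather than an error.
#' @param em_start Number of initial EM-only iterations before AI steps are
#'   attempted (default 3).  EM steps are conservative and move the iterate
#'   into the basin where the quadratic AI approximation is trustworthy;
#'   with many near-collinear components an immediate AI step can jump along
#'   a weakly identified direction.
#' @param verbose Print per-iteration progress.
#' @return An object of class `vc_estimate`: `sigma2` (named, per effect
#'   type), `sigma2_e`, `heritability` (per type, denominator = total
#'   phenotypic variance), `total_heritability`, `loglik`, `loglik_trace`,
#'   `n_iterations`, `converged`, `boundary` flags, and `ai_covariance`
#'   (inverse AI matrix at the optimum; sampling covariance of the
#'   estimates).
#' @export
fit_greml <- function(y, X, S_list, labels = NULL, start = NULL,
                      tol = 1e-6, max_iter = 200L, em_start = 3L,
                      verbose = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  S_mats <- .as_matrices(S_list)
  f <- length(S_mats)
  stopifnot(f >= 1L, nrow(X) == n,
            all(vapply(S_mats, function(s) all(dim(s) == n), TRUE)))
  if (n < f + ncol(X) + 2L)
    stop("too few observations (", n, ") for ", f, " components + ",
         ncol(X), " fixed effects")
  for (i in seq_len(f))
    if (max(abs(S_mats[[i]] - diag(n))) < 1e-8)
      stop("component ", i, " has an identity relationship matrix; ",
           "indistinguishable from the residual (non-identifiable)")
  if (is.null(labels)) {
    labels <- vapply(seq_len(f), function(i) {
      s <- S_list[[i]]
      if (inherits(s, "grm")) s$label else paste0("V", i)
    }, "")
  }
  vy <- stats::var(y)
  lower <- 1e-6 * vy
  theta <- if (is.null(start)) rep(vy / (f + 1L), f + 1L) else as.numeric(start)
  stopifnot(length(theta) == f + 1L, all(theta > 0))

  st <- .reml_state(theta, y, X, S_mats)
  trace <- st$loglik
  converged <- FALSE
  iter <- 0L
  ai_cov <- NULL
  lambda <- 0.1 # AI damping, adapted across iterations
  while (iter < max_iter) {
    iter <- iter + 1L
    # per-component quantities: t_i = S_i P y ; residual uses S = I
    ti <- vector("list", f + 1L)
    for (i in seq_len(f)) ti[[i]] <- S_mats[[i]] %*% st$Py
    ti[[f + 1L]] <- st$Py
    grad <- numeric(f + 1L)
    yPSPy <- numeric(f + 1L)
    for (i in seq_len(f)) {
      trPS <- sum(st$P * S_mats[[i]]) # tr(P S_i), S symmetric
      yPSPy[i] <- sum(st$Py * ti[[i]])
      grad[i] <- -0.5 * (trPS - yPSPy[i])
    }
    trP <- sum(diag(st$P))
    yPSPy[f + 1L] <- sum(st$Py * st$Py)
    grad[f + 1L] <- -0.5 * (trP - yPSPy[f + 1L])
    AI <- matrix(0, f + 1L, f + 1L)
    Pti <- lapply(ti, function(v) st$P %*% v)
    for (i in seq_len(f + 1L))
      for (j in i:(f + 1L))
        AI[i, j] <- AI[j, i] <- 0.5 * sum(ti[[i]] * Pti[[j]])

    # Levenberg-damped AI step: solve (AI + lambda diag(AI)) step = grad.
    # Damping protects against wild steps along nearly flat (weakly
    # identified) directions, where the raw AI matrix is close to singular;
    # lambda shrinks after every accepted step and grows on rejection.
    accepted <- FALSE
    if (iter > em_start) for (attempt in 1:6) {
      D_ai <- diag(pmax(diag(AI), 1e-12 * max(diag(AI), 1)), f + 1L)
      step_ai <- tryCatch(solve(AI + lambda * D_ai, grad),
                          error = function(e) NULL)
      if (is.null(step_ai)) break
      cand <- pmax(theta + step_ai, lower)
      stc <- tryCatch(.reml_state(cand, y, X, S_mats),
                      error = function(e) NULL)
      if (!is.null(stc) && stc$loglik >= st$loglik - 1e-10) {
        new_theta <- cand; new_st <- stc; accepted <- TRUE
        lambda <- max(lambda / 10, 1e-3)
        ai_cov <- tryCatch(solve(AI), error = function(e) NULL)
        break
      }
      lambda <- lambda * 10
    }
    if (!accepted) {
      # EM-REML step: sigma_i^2 <- sigma_i^2 + sigma_i^4 (y'PS_iPy - tr(PS_i))/n
      em <- theta
      for (i in seq_len(f)) {
        trPS <- sum(st$P * S_mats[[i]])
        em[i] <- theta[i] + theta[i]^2 * (yPSPy[i] - trPS) / n
      }
      em[f + 1L] <- theta[f + 1L] +
        theta[f + 1L]^2 * (yPSPy[f + 1L] - trP) / n
      new_theta <- pmax(em, lower)
      new_st <- .reml_state(new_theta, y, X, S_mats)
    }
    delta <- new_st$loglik - st$loglik
    theta <- new_theta
    st <- new_st
    trace <- c(trace, st$loglik)
    if (verbose)
      message(sprintf("iter %3d  logL %.6f  dlogL %.2e  [%s]", iter,
                      st$loglik, delta,
                      paste(format(theta, digits = 4), collapse = " ")))
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  sigma2 <- theta[seq_len(f)]
  names(sigma2) <- labels
  sigma2_e <- theta[f + 1L]
  # each component's contribution to the phenotypic variance is
  # sigma_i^2 * mean(diag S_i); the mean diagonal is 1 for normalized GRMs,
  # and carrying it keeps heritabilities invariant to rescaling any S_i
  dbar <- vapply(S_mats, function(s) mean(diag(s)), 0)
  contrib <- sigma2 * dbar
  total_var <- sum(contrib) + sigma2_e
  h2 <- contrib / total_var
  boundary <- theta <= lower * (1 + 1e-12)
  vce <- list(sigma2 = sigma2, sigma2_e = sigma2_e,
              heritability = h2, total_heritability = sum(h2),
              loglik = st$loglik, loglik_trace = trace,
              n_iterations = iter, converged = converged,
              boundary = boundary, ai_covariance = ai_cov,
              labels = labels, n = n)
  class(vce) <- "vc_estimate"
  vce
}

#' @export
print.vc_estimate <- function(x, ...) {
  cat("<vc_estimate> n =", x$n, if (x$converged) "(converged" else
    "(NOT converged", "in", x$n_iterations, "iterations)\n")
  tab <- data.frame(component = c(x$labels, "residual"),
                    sigma2 = c(x$sigma2, x$sigma2_e),
                    h2 = c(round(x$heritability, 4), NA),
                    boundary = x$boundary)
  print(tab, row.names = FALSE)
  cat("total heritability:", round(x$total_heritability, 4), "\n")
  invisible(x)
}

#' Heritability table for a fitted model
#'
#' One row per effect type with its heritability (variance component over
#' total phenotypic variance), plus a closing `Total` row equal to the sum of
#' the component heritabilities.  Given per-component heritabilities directly
#' (a named numeric vector), tabulates those instead — useful for published
#' estimates.
#'
#' @param vce A `vc_estimate`, or a named numeric vector of per-type
#'   heritabilities.
#' @param digits Rounding for the printed values (default 3, as conventional
#'   in heritability tables).
#' @return Data frame with columns `effect_type` and `h2`, last row `Total`.
#' @export
heritability_table <- function(vce, digits = 3) {
  h2 <- if (inherits(vce, "vc_estimate")) vce$heritability else {
    stopifnot(is.numeric(vce))
    vce
  }
  labels <- names(h2)
  if (is.null(labels)) labels <- paste0("V", seq_along(h2))
  data.frame(effect_type = c(labels, "Total"),
             h2 = round(c(h2, sum(h2)), digits))
}
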