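# Bivariate GREML on a local GRM.
#
# Model, for one feature's phenotype measured in two tissues:
#   y = X mu + a + e,   a ~ N(0, [vg1 G, g12 G; g12 G, vg2 G]),
#                       e ~ N(0, [ve1 I, e12 S; e12 S', ve2 I])
# where G is the local GRM over the union sample set and S marks
# observations of the same individual in both tissues. The restricted
# likelihood is maximised by average-information (AI) updates with
# step-halving and an EM fallback for the variances; a simplex polish on
# the transformed scale (log variances, atanh-bounded covariances) rescues
# fits that stall near the correlation boundary. Variances are clamped at
# a small positive floor and covariances inside their Cauchy-Schwarz
# bounds.

chol_solve <- function(ch, b) backsolve(ch, forwardsolve(t(ch), b))

# covariances are kept strictly inside their Cauchy-Schwarz bound so V
# stays invertible even when the true correlation is 1
COV_BOUND <- 0.99995

reml_loglik <- function(theta, comps, X, y, need_P = FALSE) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (k in seq_along(comps)) V <- V + theta[k] * comps[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  rhs <- chol_solve(ch, cbind(X, y))          # V^{-1} [X y]
  ViX <- rhs[, seq_len(ncol(X)), drop = FALSE]
  Viy <- rhs[, ncol(X) + 1]
  XtViX <- crossprod(X, ViX)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(list(ll = -Inf))
  B <- chol2inv(chx)
  XtViy <- crossprod(X, Viy)
  yPy <- sum(y * Viy) - drop(crossprod(XtViy, B %*% XtViy))
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) + yPy)
  out <- list(ll = ll)
  if (need_P) {
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    out$P <- Vi - crossprod(XtVi, B %*% XtVi)
    out$Py <- out$P %*% y
  }
  out
}

# one AI-REML maximisation over the given components
ai_reml_fit <- function(comps, X, y, theta0, is_var, bound_pairs,
                        max_iter = 200, tol = 1e-8) {
  lb <- 1e-6 * var(y)
  clamp <- function(th) {
    th[is_var] <- pmax(th[is_var], lb)
    for (bp in bound_pairs) {
      lim <- COV_BOUND * sqrt(th[bp[1]] * th[bp[2]])
      th[bp[3]] <- sign(th[bp[3]]) * min(abs(th[bp[3]]), lim)
    }
    th
  }
  theta <- clamp(theta0)
  st <- reml_loglik(theta, comps, X, y, need_P = TRUE)
  if (!is.finite(st$ll)) abort("REML: initial variance structure not positive definite")
  ll_path <- st$ll
  converged <- FALSE
  stalled <- 0L
  for (it in seq_len(max_iter)) {
    K <- length(comps)
    grad <- numeric(K)
    W <- matrix(0, length(y), K)
    for (k in seq_len(K)) {
      Vk_Py <- comps[[k]] %*% st$Py
      W[, k] <- Vk_Py
      grad[k] <- -0.5 * (sum(st$P * comps[[k]]) - sum(st$Py * Vk_Py))
    }
    AI <- 0.5 * crossprod(W, st$P %*% W)
    delta <- tryCatch(solve(AI + diag(1e-10, K), grad),
                      error = function(e) grad / max(abs(grad), 1))
    step <- 1
    cand <- NULL
    for (h in seq_len(20)) {
      prop <- clamp(theta + step * delta)
      st_new <- reml_loglik(prop, comps, X, y, need_P = TRUE)
      if (is.finite(st_new$ll) && st_new$ll >= st$ll - 1e-12) {
        cand <- prop
        break
      }
      step <- step / 2
    }
    if (is.null(cand)) {
      # EM fallback for the variance components
      prop <- theta
      nn <- length(y)
      for (k in which(is_var)) {
        prop[k] <- theta[k] + theta[k]^2 / nn *
          (sum(st$Py * (comps[[k]] %*% st$Py)) - sum(st$P * comps[[k]]))
      }
      prop <- clamp(prop)
      st_new <- reml_loglik(prop, comps, X, y, need_P = TRUE)
      if (!is.finite(st_new$ll) || st_new$ll < st$ll - 1e-8) break
      cand <- prop
      step <- 0
    }
    dll <- st_new$ll - st$ll
    stalled <- if (step < 1e-3) stalled + 1L else 0L
    theta <- cand
    st <- st_new
    ll_path <- c(ll_path, st$ll)
    if (abs(dll) < tol && stalled == 0L) {
      converged <- TRUE
      break
    }
    if (stalled >= 3L) break  # boundary stall; leave to the polish
  }
  list(theta = theta, loglik = st$ll, converged = converged,
       ll_path = ll_path, n_iter = length(ll_path) - 1)
}

# information matrix at a solution (for delta-method SEs)
ai_matrix <- function(theta, comps, X, y) {
  st <- reml_loglik(theta, comps, X, y, need_P = TRUE)
  if (!is.finite(st$ll)) return(NULL)
  K <- length(comps)
  W <- matrix(0, length(y), K)
  for (k in seq_len(K)) W[, k] <- comps[[k]] %*% st$Py
  0.5 * crossprod(W, st$P %*% W)
}

build_bivar_model <- function(y1, y2, grm, est_resid_cov = NULL) {
  if (is.data.frame(y1)) y1 <- setNames(y1$value, y1$sample_id)
  if (is.data.frame(y2)) y2 <- setNames(y2$value, y2$sample_id)
  id1 <- names(y1)
  id2 <- names(y2)
  if (is.null(id1) || is.null(id2)) abort("y1/y2 must carry sample ids")
  i1 <- match(id1, grm$samples)
  i2 <- match(id2, grm$samples)
  if (anyNA(i1) || anyNA(i2)) abort("phenotype samples missing from the GRM")
  n1 <- length(y1); n2 <- length(y2); n <- n1 + n2
  shared <- intersect(id1, id2)
  if (is.null(est_resid_cov)) est_resid_cov <- length(shared) > 0
  if (est_resid_cov && !length(shared)) {
    inform("no shared individuals: residual covariance fixed at 0")
    est_resid_cov <- FALSE
  }
  G <- grm$G
  zero <- matrix(0, n, n)
  blk <- function(fill11 = NULL, fill22 = NULL, fill12 = NULL) {
    M <- zero
    if (!is.null(fill11)) M[1:n1, 1:n1] <- fill11
    if (!is.null(fill22)) M[(n1 + 1):n, (n1 + 1):n] <- fill22
    if (!is.null(fill12)) {
      M[1:n1, (n1 + 1):n] <- fill12
      M[(n1 + 1):n, 1:n1] <- t(fill12)
    }
    M
  }
  S12 <- matrix(0, n1, n2)
  if (length(shared)) {
    S12[cbind(match(shared, id1), match(shared, id2))] <- 1
  }
  comps <- list(vg1 = blk(fill11 = G[i1, i1]),
                vg2 = blk(fill22 = G[i2, i2]),
                g12 = blk(fill12 = G[i1, i2, drop = FALSE]),
                ve1 = blk(fill11 = diag(n1)),
                ve2 = blk(fill22 = diag(n2)))
  if (est_resid_cov) comps$e12 <- blk(fill12 = S12)
  X <- cbind(trait1 = rep(c(1, 0), c(n1, n2)),
             trait2 = rep(c(0, 1), c(n1, n2)))
  list(comps = comps, X = X, y = c(y1, y2), n1 = n1, n2 = n2,
       est_resid_cov = est_resid_cov)
}

theta_init <- function(model) {
  v1 <- var(model$y[seq_len(model$n1)])
  v2 <- var(model$y[-seq_len(model$n1)])
  th <- c(vg1 = v1 / 2, vg2 = v2 / 2, g12 = 0.1 * sqrt(v1 * v2) / 2,
          ve1 = v1 / 2, ve2 = v2 / 2)
  if (model$est_resid_cov) th <- c(th, e12 = 0)
  th
}

# simplex maximisation on the transformed scale; r_fix = NA leaves the
# genetic correlation free (atanh-parameterised), otherwise it is held at
# r_fix with the covariance tied to the variances.
transformed_reml <- function(model, start, r_fix = NA, maxit = 800,
                             reltol = 1e-10) {
  has_e12 <- model$est_resid_cov
  free_r <- is.na(r_fix)
  make_theta <- function(phi) {
    i <- 0
    nxt <- function() { i <<- i + 1; phi[i] }
    vg1 <- exp(nxt()); vg2 <- exp(nxt())
    rho_g <- if (free_r) tanh(nxt()) * COV_BOUND else r_fix
    ve1 <- exp(nxt()); ve2 <- exp(nxt())
    th <- c(vg1 = vg1, vg2 = vg2, g12 = rho_g * sqrt(vg1 * vg2),
            ve1 = ve1, ve2 = ve2)
    if (has_e12) th <- c(th, e12 = tanh(nxt()) * COV_BOUND * sqrt(ve1 * ve2))
    th
  }
  phi0 <- c(log(max(start["vg1"], 1e-8)), log(max(start["vg2"], 1e-8)))
  if (free_r) {
    r0 <- start["g12"] / sqrt(max(start["vg1"] * start["vg2"], 1e-16))
    phi0 <- c(phi0, atanh(min(max(r0 / COV_BOUND, -0.999), 0.999)))
  }
  phi0 <- c(phi0, log(max(start["ve1"], 1e-8)), log(max(start["ve2"], 1e-8)))
  if (has_e12) {
    rho_e <- start["e12"] / (COV_BOUND * sqrt(max(start["ve1"] * start["ve2"],
                                                1e-16)))
    phi0 <- c(phi0, atanh(min(max(rho_e, -0.999), 0.999)))
  }
  negll <- function(phi) {
    ll <- reml_loglik(make_theta(phi), model$comps, model$X, model$y)$ll
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- optim(phi0, negll, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = reltol))
  list(loglik = -opt$value, theta = make_theta(opt$par),
       converged = opt$convergence == 0)
}

#' Bivariate REML on a local GRM
#'
#' Estimates the local additive genetic (co)variances of one feature's
#' phenotype measured in two tissues, and the local genetic correlation
#' `r_lg = cov_g / sqrt(var_g1 * var_g2)`, by AI-REML over the union
#' sample set (with step-halving, an EM fallback and a transformed-scale
#' simplex polish for fits that stall at the correlation boundary). Sample
#' sets may overlap fully, partially or not at all; a residual covariance
#' is estimated only for individuals observed in both tissues
#' (structurally forced to 0 for disjoint designs).
#'
#' @param y1,y2 named numeric vectors (names = sample ids) or tibbles
#'   `sample_id`, `value`: the feature's normalised phenotype in the two
#'   tissues.
#' @param grm a [build_lgrm()] object covering all samples.
#' @param est_resid_cov estimate the residual covariance for shared
#'   individuals? Default: yes when any individual is shared.
#' @param max_iter,tol AI-REML iteration cap and log-likelihood tolerance.
#' @return An object of class `bivar_fit`: variance components, `r_lg`,
#'   delta-method `se_r`, restricted `loglik`, `converged` flag, iteration
#'   diagnostics and the model internals needed by [test_rg()].
#' @export
bivariate_reml <- function(y1, y2, grm, est_resid_cov = NULL,
                           max_iter = 200, tol = 1e-8) {
  model <- build_bivar_model(y1, y2, grm, est_resid_cov)
  is_var <- names(model$comps) %in% c("vg1", "vg2", "ve1", "ve2")
  bound_pairs <- list(c(1, 2, 3))  # g12 bounded by vg1, vg2
  if (model$est_resid_cov) bound_pairs <- c(bound_pairs, list(c(4, 5, 6)))
  fit <- ai_reml_fit(model$comps, model$X, model$y, theta_init(model),
                     is_var, bound_pairs, max_iter = max_iter, tol = tol)
  converged <- fit$converged
  if (!converged) {
    pol <- transformed_reml(model, fit$theta)
    if (is.finite(pol$loglik) && pol$loglik >= fit$loglik - 1e-8) {
      if (pol$loglik > fit$loglik) {
        fit$theta <- pol$theta
        fit$ll_path <- c(fit$ll_path, pol$loglik)
        fit$loglik <- pol$loglik
      }
      converged <- pol$converged
    }
  }
  th <- fit$theta
  K <- length(model$comps)
  lb <- 2e-6 * var(model$y)
  at_boundary <- th["vg1"] <= lb || th["vg2"] <= lb
  r_lg <- if (at_boundary) NA_real_ else
    unname(th["g12"] / sqrt(th["vg1"] * th["vg2"]))
  se_r <- NA_real_
  if (!at_boundary) {
    AI <- ai_matrix(th, model$comps, model$X, model$y)
    Ct <- if (is.null(AI)) NULL else
      tryCatch(solve(AI), error = function(e) NULL)
    if (!is.null(Ct)) {
      h <- numeric(K)
      h[1] <- -r_lg / (2 * th["vg1"])
      h[2] <- -r_lg / (2 * th["vg2"])
      h[3] <- 1 / sqrt(th["vg1"] * th["vg2"])
      se_r <- sqrt(max(drop(t(h) %*% Ct %*% h), 0))
    }
  }
  structure(list(var_g1 = unname(th["vg1"]), var_g2 = unname(th["vg2"]),
                 cov_g = unname(th["g12"]),
                 var_e1 = unname(th["ve1"]), var_e2 = unname(th["ve2"]),
                 cov_e = if (model$est_resid_cov) unname(th["e12"]) else 0,
                 r_lg = r_lg, se_r = se_r,
                 loglik = fit$loglik, converged = converged,
                 n_iter = fit$n_iter, ll_path = fit$ll_path,
                 at_boundary = at_boundary,
                 model = model, max_iter = max_iter, tol = tol),
            class = "bivar_fit")
}

#' @export
print.bivar_fit <- function(x, ...) {
  cat(sprintf("<bivar_fit> r_lg = %.3f (se %.3f), vg = (%.3f, %.3f), loglik = %.3f, %s\n",
              x$r_lg, x$se_r, x$var_g1, x$var_g2, x$loglik,
              if (x$converged) sprintf("converged in %d iter", x$n_iter)
              else "NOT converged"))
  invisible(x)
}

#' Likelihood-ratio test of the genetic correlation against 0 or 1
#'
#' Refits the bivariate model with the genetic covariance constrained so
#' that `r_lg` equals the null value and refers twice the log-likelihood
#' difference to chi-square with 1 df. At the `r = 1` boundary the
#' reference distribution is the 50:50 mixture of a point mass at 0 and
#' chi-square(1). The `r = 0` null drops the genetic-covariance component
#' and refits by AI-REML; the `r = 1` null ties the covariance to the
#' variances and maximises on the transformed scale.
#'
#' @param fit a converged [bivariate_reml()] fit.
#' @param null_value 0 or 1.
#' @return One-row tibble: `null_value`, `loglik_null`, `lrt`, `p`,
#'   `converged_null`.
#' @export
test_rg <- function(fit, null_value = c(0, 1)) {
  null_value <- as.numeric(match.arg(as.character(null_value[1]),
                                     c("0", "1")))
  model <- fit$model
  start <- c(vg1 = fit$var_g1, vg2 = fit$var_g2, g12 = fit$cov_g,
             ve1 = fit$var_e1, ve2 = fit$var_e2)
  if (model$est_resid_cov) start <- c(start, e12 = fit$cov_e)
  if (null_value == 0) {
    keep <- setdiff(names(model$comps), "g12")
    comps0 <- model$comps[keep]
    is_var <- keep %in% c("vg1", "vg2", "ve1", "ve2")
    bp <- if (model$est_resid_cov) {
      list(match(c("ve1", "ve2", "e12"), keep))
    } else list()
    cfit <- ai_reml_fit(comps0, model$X, model$y,
                        start[keep], is_var, bp,
                        max_iter = fit$max_iter, tol = fit$tol)
    if (!cfit$converged) {
      pol <- transformed_reml(model, start, r_fix = 0)
      if (pol$loglik > cfit$loglik) cfit <- pol
    }
  } else {
    cfit <- transformed_reml(model, start, r_fix = 1)
  }
  if (!is.finite(cfit$loglik)) {
    warn("constrained fit did not converge; p reported missing")
    return(tibble(null_value = null_value, loglik_null = NA_real_,
                  lrt = NA_real_, p = NA_real_, converged_null = FALSE))
  }
  lrt <- max(2 * (fit$loglik - cfit$loglik), 0)
  p <- if (null_value == 1) {
    if (lrt <= 0) 1 else 0.5 * pchisq(lrt, 1, lower.tail = FALSE)
  } else {
    pchisq(lrt, 1, lower.tail = FALSE)
  }
  tibble(null_value = null_value, loglik_null = cfit$loglik, lrt = lrt,
         p = p, converged_null = TRUE)
}
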