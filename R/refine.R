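#' Fit a refinement model on the pooled matched sample
#'
#' The score model is fitted once per direction, pooled over all matched
#' treated events and the distinct control events appearing in at least one
#' matched set (per-set fits would be underdetermined). Features are
#' standardised internally for numerical conditioning; coefficients are
#' mapped back to the raw scale. Constant columns are dropped with a
#' warning. For `"mahalanobis"` the per-lag covariance matrices are
#' estimated on the pooled event sample; a singular covariance falls back to
#' its diagonal with a warning.
#'
#' @param msets a `matched_sets` object from [build_matched_sets()].
#' @param X covariate matrix from [build_covariates()] (one row per event in
#'   `msets$events`).
#' @param method one of `"none"`, `"mahalanobis"`, `"ps_match"`,
#'   `"ps_weight"`, `"cbps_weight"` (the default, the best-balancing method
#'   for this design).
#' @param size_match J, number of nearest controls kept by the matching-type
#'   refinements (default 5).
#' @param tol,max_iter CBPS root-finder controls: convergence when the
#'   largest absolute mean balance moment falls below `tol`.
#' @return object of class `refinement_model`.
#' @export
fit_refinement <- function(msets, X,
                           method = c("cbps_weight", "ps_weight",
                                      "ps_match", "mahalanobis", "none"),
                           size_match = 5L, tol = 1e-8, max_iter = 200L) {
  method <- match.arg(method)
  stopifnot(inherits(msets, "matched_sets"), size_match >= 1L)
  info <- attr(X, "feature_info")
  model <- list(method = method, size_match = as.integer(size_match),
                feature_names = colnames(X), feature_info = info)

  matched <- vapply(msets$sets, function(s) length(s$members) > 0L,
                    logical(1))
  t_rows <- vapply(msets$sets, `[[`, integer(1), "event_row")[matched]
  c_rows <- sort(unique(unlist(lapply(msets$sets[matched], `[[`,
                                      "members"))))
  rows <- c(t_rows, c_rows)
  y <- c(rep(1, length(t_rows)), rep(0, length(c_rows)))

  if (method %in% c("ps_match", "ps_weight", "cbps_weight")) {
    Z <- X[rows, , drop = FALSE]
    sds <- apply(Z, 2, stats::sd)
    keep <- sds > 0
    if (any(!keep)) {
      warning("dropping constant covariate column(s): ",
              paste(colnames(X)[!keep], collapse = ", "))
    }
    ctr <- colMeans(Z[, keep, drop = FALSE])
    scl <- sds[keep]
    Zs <- sweep(sweep(Z[, keep, drop = FALSE], 2, ctr), 2, scl, "/")
    theta_mle <- fit_logistic_mle(y, Zs)
    theta <- if (method == "cbps_weight") {
      fit_cbps_std(y, Zs, start = theta_mle, tol = tol,
                   max_iter = max_iter)
    } else theta_mle
    model$keep <- keep
    model$center <- ctr
    model$scale <- scl
    model$coefficients <- theta          # on the standardised scale
    model$coefficients_raw <- unstandardise_coef(theta, ctr, scl)
  } else if (method == "mahalanobis") {
    model$cov_inv <- mahalanobis_slices(X, info, rows)
  }
  class(model) <- "refinement_model"
  model
}

# Internal: logistic MLE via iteratively reweighted least squares.
fit_logistic_mle <- function(y, Zs) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, Zs), y, family = stats::binomial()))
  if (!fit$converged) {
    warning("logistic score fit did not converge ",
            "(possible separation / boundary solution)")
  }
  theta <- fit$coefficients
  theta[is.na(theta)] <- 0
  theta
}

unstandardise_coef <- function(theta, center, scale) {
  b <- theta[-1] / scale
  c(theta[1] - sum(center * b), b)
}

# Internal: per-lag covariance inverses for average Mahalanobis distance.
# Features are grouped into slices: the time-invariant block and one block
# per lag; each slice gets its own covariance from the pooled sample.
mahalanobis_slices <- function(X, info, rows) {
  lag_key <- ifelse(is.na(info$lag), 0L, info$lag)
  slices <- split(seq_len(ncol(X)), lag_key)
  lapply(slices, function(j) {
    S <- stats::cov(X[rows, j, drop = FALSE])
    inv <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(inv)) {
      warning("singular covariance in Mahalanobis slice; ",
              "falling back to diagonal (variances only)")
      d <- diag(S)
      d[d == 0] <- 1
      inv <- diag(1 / d, nrow = length(d))
    }
    list(cols = j, inv = inv)
  })
}

#' Solve the just-identified covariate-balancing score equations
#'
#' Finds logistic-score coefficients `theta` such that the inverse
#' propensity weighted covariate means of treated and control groups agree
#' exactly: the sample mean of `(T - pi) / (pi (1 - pi)) * (1, x)` is driven
#' to zero, with `pi = plogis((1, x) theta)`. Solved by a damped Newton
#' root-finder initialised at the logistic MLE.
#'
#' @param treated 0/1 vector.
#' @param X numeric covariate matrix (no intercept column; constant columns
#'   are rejected).
#' @param tol convergence threshold on the max absolute mean moment.
#' @param max_iter maximum Newton iterations.
#' @return named coefficient vector (intercept first) on the raw scale of
#'   `X`.
#' @export
fit_cbps <- function(treated, X, tol = 1e-8, max_iter = 200L) {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant covariate column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  ctr <- colMeans(X)
  Zs <- sweep(sweep(X, 2, ctr), 2, sds, "/")
  start <- fit_logistic_mle(treated, Zs)
  theta <- fit_cbps_std(treated, Zs, start = start, tol = tol,
                        max_iter = max_iter)
  unstandardise_coef(theta, ctr, sds)
}

# Internal CBPS solver on standardised features.
#
# The just-identified balance condition
#   mean[ (y - pi) / (pi (1 - pi)) * x ] = 0,   pi = plogis(x' theta)
# is the exact gradient of the strictly concave criterion
#   mean[ (2y - 1) eta - y exp(-eta) - (1 - y) exp(eta) ],  eta = x' theta,
# so the root is found as the unique maximiser, by damped Newton ascent
# with step halving (globally convergent when a finite solution exists;
# separable data make the criterion unbounded and the fit fails cleanly).
fit_cbps_std <- function(y, Zs, start, tol = 1e-8, max_iter = 200L) {
  Xt <- cbind(`(Intercept)` = 1, Zs)
  n <- nrow(Xt)
  # Whiten the design: eta = U beta with U orthonormal. This keeps the
  # Newton system well conditioned when covariate histories are nearly
  # collinear (age with age squared, lagged values of a slow covariate),
  # and directions outside the column space (rank deficiency) drop out.
  sv <- svd(Xt)
  keep <- sv$d > max(sv$d) * 1e-10
  U <- sv$u[, keep, drop = FALSE]
  # original-scale moments: g_X = V diag(d) g_U (V orthogonal), so the
  # spec-level criterion max|g_X| < tol is evaluated exactly
  VD <- sv$v[, keep, drop = FALSE] %*% diag(sv$d[keep],
                                            nrow = sum(keep))
  state <- function(beta) {
    eta <- drop(U %*% beta)
    # |eta| = 30 is already complete saturation (odds 1e13); capping keeps
    # the criterion finite when the root lies on the boundary
    eta <- pmin(pmax(eta, -30), 30)
    em <- exp(-eta); ep <- exp(eta)
    u <- (2 * y - 1) + y * em - (1 - y) * ep
    gU <- colMeans(U * u)
    gX <- drop(VD %*% gU)
    list(gU = gU, gmax = max(abs(gX)), phi = sum(gU * gU),
         w = y * em + (1 - y) * ep, eta = eta)
  }
  beta <- drop(crossprod(U, drop(Xt %*% start)))  # project MLE start
  st <- state(beta)
  if (!all(is.finite(st$gU))) {
    beta <- rep(0, ncol(U))
    st <- state(beta)
  }
  # Damped Newton with merit function phi = |g|^2: the Newton direction
  # d = -J^{-1} g has d' grad(phi) = -2 |g|^2 < 0 (J symmetric negative
  # definite), so it is a descent direction for phi everywhere and step
  # halving converges globally when a finite root exists (it does not for
  # separable groups, where the criterion is unbounded).
  for (it in seq_len(max_iter)) {
    if (st$gmax < tol) break
    dg <- pmax(st$w, 1e-12)
    H <- -crossprod(U, U * dg) / n
    step <- tryCatch(solve(H, st$gU),
                     error = function(e)
                       solve(H - diag(max(abs(diag(H))) * 1e-10,
                                      ncol(U)), st$gU))
    # cap the initial step so no unit's log odds moves more than ~20
    deta <- drop(U %*% step)
    lambda <- min(1, 20 / max(abs(deta)))
    accepted <- FALSE
    while (lambda >= 1e-14) {
      cand <- beta - lambda * step
      sc <- state(cand)
      if (all(is.finite(sc$gU)) && sc$phi < st$phi) {
        accepted <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!accepted) break                # stationary plateau of |g|^2
    beta <- cand
    st <- sc
  }
  if (st$gmax >= tol) {
    # The balance system has no finite root when a feature combination
    # separates the groups or saturates (for example an indicator constant
    # among treated events): the criterion optimum then lies on the
    # boundary. Return the norm-minimising coefficients, as the reference
    # GMM implementations of this estimator do, and say so.
    warning("CBPS balance not exact (max |moment| = ",
            signif(st$gmax, 3), "); groups are separable or saturated ",
            "on some feature combination - returning the ",
            "balance-criterion optimum (boundary solution)")
  }
  # map back: beta parametrises eta = U beta = Xt (V D^{-1} beta)
  theta <- drop(sv$v[, keep, drop = FALSE] %*% (beta / sv$d[keep]))
  stats::setNames(theta, colnames(Xt))
}

#' Refine matched sets with a fitted refinement model
#'
#' Updates the member weights of every matched set. Weighting methods
#' (`ps_weight`, `cbps_weight`) give each control weight proportional to its
#' fitted odds `e / (1 - e)`, renormalised within the set; matching methods
#' (`mahalanobis`, `ps_match`) keep the J nearest controls with equal
#' weights (ties broken by unit id, then event order, so runs are
#' reproducible); `none` restores equal weights. Weights always sum to 1
#' within a nonempty set. The operation depends only on the fitted model,
#' never on the incoming weights, so it is idempotent.
#'
#' @param msets a `matched_sets` object.
#' @param X covariate matrix aligned with `msets$events`.
#' @param model a `refinement_model` from [fit_refinement()].
#' @return `matched_sets` with updated weights and `refinement` tag.
#' @export
refine <- function(msets, X, model) {
  stopifnot(inherits(msets, "matched_sets"),
            inherits(model, "refinement_model"))
  ev <- msets$events
  method <- model$method
  if (method %in% c("ps_weight", "cbps_weight", "ps_match")) {
    Zs <- sweep(sweep(X[, model$keep, drop = FALSE], 2, model$center),
                2, model$scale, "/")
    score <- stats::plogis(drop(cbind(1, Zs) %*% model$coefficients))
    score <- pmin(pmax(score, 1e-6), 1 - 1e-6)
  }
  msets$sets <- lapply(msets$sets, function(s) {
    m <- length(s$members)
    if (m == 0L) return(s)
    if (method == "none") {
      s$weights <- rep(1 / m, m)
    } else if (method %in% c("ps_weight", "cbps_weight")) {
      odds <- score[s$members] / (1 - score[s$members])
      s$weights <- odds / sum(odds)
    } else if (method == "ps_match") {
      d <- abs(score[s$members] - score[s$event_row])
      s <- keep_nearest(s, d, ev, model$size_match)
    } else if (method == "mahalanobis") {
      d <- rep(0, m)
      for (sl in model$cov_inv) {
        diff <- X[s$members, sl$cols, drop = FALSE] -
          matrix(X[s$event_row, sl$cols], m, length(sl$cols), byrow = TRUE)
        d <- d + sqrt(pmax(rowSums((diff %*% sl$inv) * diff), 0))
      }
      d <- d / length(model$cov_inv)   # average distance over slices
      s <- keep_nearest(s, d, ev, model$size_match)
    }
    s
  })
  msets$refinement <- method
  msets
}

# Internal: keep the J nearest members, equal weights; deterministic ties.
keep_nearest <- function(s, d, ev, J) {
  ord <- order(d, ev$unit_id[s$members], s$members)
  keep <- ord[seq_len(min(J, length(ord)))]
  s$members <- s$members[keep]
  s$weights <- rep(1 / length(keep), length(keep))
  s
}
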