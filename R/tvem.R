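#' B-spline basis with clamped, equally spaced knots
#'
#' Evaluates the B-spline basis used by the P-spline time-varying effect
#' model: `n_interior_knots` interior knots equally spaced over
#' `[range_lo, range_hi]`, boundary knots repeated `degree + 1` times
#' (clamped), so the basis spans constants and sums to one at every age.
#' Basis dimension is `n_interior_knots + degree + 1`.
#'
#' @param ages Evaluation points; must lie within the knot span.
#' @param degree Spline degree (default 3, cubic).
#' @param n_interior_knots Number of interior knots (default 10).
#' @param range_lo,range_hi Knot span; defaults to `range(ages)`.
#' @return Matrix, `length(ages)` x basis dimension.
#' @export
bspline_basis <- function(ages, degree = 3, n_interior_knots = 10,
                          range_lo = min(ages), range_hi = max(ages)) {
  stopifnot(degree >= 0, n_interior_knots >= 1)
  if (any(ages < range_lo - 1e-10) || any(ages > range_hi + 1e-10))
    stop("evaluation error: age outside the knot span [",
         range_lo, ", ", range_hi, "]")
  interior <- seq(range_lo, range_hi, length.out = n_interior_knots + 2L)
  interior <- interior[-c(1L, n_interior_knots + 2L)]
  knots <- c(rep(range_lo, degree + 1L), interior, rep(range_hi, degree + 1L))
  # splineDesign drops points equal to the right boundary unless clamped
  x <- pmin(pmax(ages, range_lo), range_hi)
  b <- splines::splineDesign(knots, x, ord = degree + 1L, outer.ok = FALSE)
  b
}

greville_sites <- function(knots, degree) {
  if (degree == 0) return((knots[-length(knots)] + knots[-1]) / 2)
  K <- length(knots) - degree - 1L
  vapply(seq_len(K), function(i) mean(knots[(i + 1):(i + degree)]), numeric(1))
}

bspline_greville <- function(degree, n_interior_knots, lo, hi) {
  interior <- seq(lo, hi, length.out = n_interior_knots + 2L)
  interior <- interior[-c(1L, n_interior_knots + 2L)]
  greville_sites(c(rep(lo, degree + 1L), interior, rep(hi, degree + 1L)), degree)
}

# r-th order divided-difference matrix over (possibly unequally spaced)
# sites; its null space is exactly polynomials of degree < r in the sites,
# so a heavy order-2 penalty shrinks each coefficient function to its best
# linear-in-age fit even with clamped boundary knots
divided_difference_matrix <- function(sites, order) {
  K <- length(sites)
  D <- diag(K)
  for (r in seq_len(order)) {
    L <- nrow(D)
    scale <- 1 / (sites[(1 + r):K] - sites[seq_len(K - r)])
    D <- scale * (D[-1L, , drop = FALSE] - D[-L, , drop = FALSE])
  }
  # normalize to the magnitude of plain differences on a unit-mean spacing,
  # so lambda has a comparable scale across knot configurations
  h <- mean(diff(sites))
  D * h^order
}

#' Specification of a time-varying effect model
#'
#' @param time_varying Names of predictors whose coefficients vary with age
#'   (the intercept is always time-varying and need not be listed).
#' @param invariant Names of time-invariant covariates (scalar coefficients).
#' @param degree,n_interior_knots B-spline settings (defaults 3 and 10).
#' @param penalty_order Difference-penalty order (default 2: deviations from
#'   a linear trend are penalized).
#' @param lambda_grid Candidate smoothing parameters; default 25 log-spaced
#'   values from 1e-4 to 1e6. Selection is by AIC with effective df equal to
#'   the trace of the smoother matrix; one lambda is shared across all
#'   coefficient functions.
#' @param ci_level Pointwise confidence level (default 0.95).
#' @param n_grid Evaluation grid size over the observed age range
#'   (default 101).
#' @return List of class `tvem_spec`.
#' @export
tvem_spec <- function(time_varying = character(), invariant = character(),
                      degree = 3, n_interior_knots = 10, penalty_order = 2,
                      lambda_grid = 10^seq(-4, 6, length.out = 25),
                      ci_level = 0.95, n_grid = 101) {
  stopifnot(degree >= 1, n_interior_knots >= 1, penalty_order >= 1,
            ci_level > 0, ci_level < 1, all(lambda_grid >= 0))
  structure(list(time_varying = time_varying, invariant = invariant,
                 degree = degree, n_interior_knots = n_interior_knots,
                 penalty_order = penalty_order, lambda_grid = lambda_grid,
                 ci_level = ci_level, n_grid = n_grid),
            class = "tvem_spec")
}

#' Fit a penalized B-spline time-varying effect model
#'
#' Fits `y_ij = sum_v B(t_ij)' theta_v x_vij + gamma' z_i + e_ij` by
#' penalized least squares with a difference penalty `lambda * ||D theta_v||^2`
#' on each coefficient function. The coefficient of every time-varying
#' predictor (including the intercept) is an unrestricted smooth function of
#' age; time-invariant covariates enter with scalar coefficients and no
#' penalty. Within-subject correlation is handled by working independence
#' with cluster-robust (sandwich) standard errors by subject. `lambda` is
#' chosen from the grid by AIC (`n log(RSS/n) + 2 edf`), with effective df
#' the trace of the smoother matrix. Pointwise confidence bands are
#' `beta(t) +/- z * se(t)` on an equally spaced age grid.
#'
#' @param records Long-format `data.frame` as from [read_long_phenotypes()]
#'   (columns `subject_id`, `age`, `phenotype`, plus predictor/covariate
#'   columns).
#' @param spec A [tvem_spec()].
#' @return List of class `tvem_fit`: `age_grid`, `curves` (long
#'   `data.frame`: `age`, `predictor`, `beta`, `se`, `ci_lo`, `ci_hi`),
#'   `invariant` (`data.frame`: `term`, `estimate`, `se`), `lambda`, `edf`,
#'   `aic`, `condition_number` (of the unpenalized design), `spec`,
#'   `age_range`, `n_subjects`, `n_obs`.
#' @export
fit_tvem <- function(records, spec = tvem_spec()) {
  if (length(unique(records$subject_id)) < 2L) stop("need >= 2 subjects")
  for (v in c(spec$time_varying, spec$invariant)) {
    if (!v %in% names(records)) stop("column '", v, "' not found in records")
  }
  age <- records$age
  lo <- min(age); hi <- max(age)
  B <- bspline_basis(age, spec$degree, spec$n_interior_knots, lo, hi)
  nb <- ncol(B)
  tv <- c(".intercept", spec$time_varying)
  blocks <- lapply(tv, function(v) {
    x <- if (v == ".intercept") rep(1, nrow(records)) else records[[v]]
    B * x
  })
  X <- do.call(cbind, c(blocks,
                        if (length(spec$invariant))
                          list(as.matrix(records[spec$invariant])) else NULL))
  p_tv <- nb * length(tv)
  p_all <- ncol(X)
  y <- records$phenotype
  n <- length(y)

  D <- divided_difference_matrix(bspline_greville(spec$degree,
                                                  spec$n_interior_knots,
                                                  lo, hi),
                                 spec$penalty_order)
  DtD <- crossprod(D)
  P <- matrix(0, p_all, p_all)
  for (j in seq_along(tv)) {
    ix <- (j - 1L) * nb + seq_len(nb)
    P[ix, ix] <- DtD
  }

  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  cn <- kappa(XtX, exact = FALSE)

  best <- NULL
  for (lam in spec$lambda_grid) {
    A <- XtX + lam * P
    ok <- TRUE
    R <- tryCatch(chol(A + diag(1e-10 * mean(diag(XtX)), p_all)),
                  error = function(e) { ok <<- FALSE; NULL })
    if (!ok) next
    theta <- backsolve(R, forwardsolve(t(R), Xty))
    fitted <- X %*% theta
    rss <- sum((y - fitted)^2)
    Ainv <- chol2inv(R)
    edf <- sum(Ainv * XtX)                  # trace(Ainv %*% XtX)
    aic <- n * log(rss / n) + 2 * edf
    if (is.null(best) || aic < best$aic)
      best <- list(lambda = lam, theta = theta, rss = rss, Ainv = Ainv,
                   edf = edf, aic = aic, fitted = fitted)
  }
  if (is.null(best))
    stop("singular fit: design rank-deficient over the whole lambda grid")

  # cluster-robust sandwich covariance of the coefficient vector, plus the
  # Bayesian smoothing-bias term lambda * sigma^2 * P (Nychka-type): in the
  # independent-error case this reduces to the usual P-spline posterior
  # covariance, whose pointwise bands attain near-nominal coverage where
  # sandwich-only bands undercover at high-curvature ages
  e <- as.numeric(y - best$fitted)
  Xe <- X * e
  U <- rowsum(Xe, group = records$subject_id)  # per-subject score sums
  sigma2 <- best$rss / max(1, n - best$edf)
  meat <- crossprod(U) + best$lambda * sigma2 * P
  V <- best$Ainv %*% meat %*% best$Ainv

  grid <- seq(lo, hi, length.out = spec$n_grid)
  Bg <- bspline_basis(grid, spec$degree, spec$n_interior_knots, lo, hi)
  zq <- stats::qnorm((1 + spec$ci_level) / 2)
  curves <- do.call(rbind, lapply(seq_along(tv), function(j) {
    ix <- (j - 1L) * nb + seq_len(nb)
    beta <- as.numeric(Bg %*% best$theta[ix])
    se <- sqrt(pmax(0, rowSums((Bg %*% V[ix, ix]) * Bg)))
    data.frame(age = grid,
               predictor = if (tv[j] == ".intercept") "intercept" else tv[j],
               beta = beta, se = se,
               ci_lo = beta - zq * se, ci_hi = beta + zq * se,
               stringsAsFactors = FALSE)
  }))
  invariant <- if (p_all > p_tv) {
    ix <- (p_tv + 1L):p_all
    data.frame(term = spec$invariant,
               estimate = as.numeric(best$theta[ix]),
               se = sqrt(diag(V)[ix]),
               stringsAsFactors = FALSE)
  } else data.frame(term = character(), estimate = numeric(), se = numeric())

  structure(list(age_grid = grid, curves = curves, invariant = invariant,
                 lambda = best$lambda, edf = best$edf, aic = best$aic,
                 condition_number = cn, spec = spec,
                 age_range = c(lo, hi),
                 n_subjects = length(unique(records$subject_id)), n_obs = n),
            class = "tvem_fit")
}

#' @export
print.tvem_fit <- function(x, ...) {
  cat("tvem_fit:", x$n_obs, "observations,", x$n_subjects, "subjects\n")
  cat(sprintf("  lambda = %.4g, edf = %.2f, AIC = %.2f\n", x$lambda, x$edf, x$aic))
  cat("  time-varying:", paste(unique(x$curves$predictor), collapse = ", "), "\n")
  invisible(x)
}

#' Maximal age intervals where a coefficient is significant
#'
#' Scans each predictor's pointwise confidence band on the age grid and
#' reports maximal runs of grid points whose band excludes zero
#' (`ci_lo > 0` or `ci_hi < 0`), as `[age_start, age_end]` at grid
#' resolution.
#'
#' @param fit A `tvem_fit` (grid of at least 50 points recommended).
#' @return `data.frame`: `predictor`, `age_start`, `age_end`, `sign`.
#' @export
significant_intervals <- function(fit) {
  out <- list()
  for (pred in unique(fit$curves$predictor)) {
    cv <- fit$curves[fit$curves$predictor == pred, , drop = FALSE]
    sig <- cv$ci_lo > 0 | cv$ci_hi < 0
    if (!any(sig)) next
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        predictor = pred,
        age_start = cv$age[starts[i]],
        age_end = cv$age[ends[i]],
        sign = if (cv$ci_lo[starts[i]] > 0) "positive" else "negative",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(predictor = character(), age_start = numeric(),
               age_end = numeric(), sign = character())
}

#' Fit the model separately within subgroups
#'
#' Independent fits per level of a grouping column; no cross-model test is
#' performed (the varying-coefficient framework supplies none). Levels with
#' fewer than 2 subjects are skipped with a warning.
#'
#' @param records Long-format data as for [fit_tvem()].
#' @param spec A [tvem_spec()].
#' @param group_column Name of the grouping column in `records`.
#' @return Named list of `tvem_fit` objects, one per usable level.
#' @export
subgroup_fit <- function(records, spec, group_column) {
  lv <- unique(records[[group_column]])
  if (length(lv) < 2L) stop("group column has fewer than 2 levels")
  fits <- list()
  for (g in lv) {
    sub <- records[records[[group_column]] == g, , drop = FALSE]
    if (length(unique(sub$subject_id)) < 2L) {
      warning("group '", g, "' has fewer than 2 subjects; skipped")
      next
    }
    fits[[as.character(g)]] <- fit_tvem(sub, spec)
  }
  fits
}
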