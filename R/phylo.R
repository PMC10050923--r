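#' Phylogenetic comparative statistics
#'
#' Species-level performance values are not independent: close relatives
#' resemble each other. Under Brownian-motion (BM) trait evolution the
#' expected covariance of two tips is proportional to their shared
#' root-to-ancestor path length, collected in the phylogenetic covariance
#' matrix C. Pagel's lambda scales the off-diagonal of C, interpolating
#' between independence (lambda = 0) and full BM structure (lambda = 1).
#'
#' @name phylo_stats
#' @keywords internal
NULL

#' Read a phylogeny from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] that enforces the requirements of
#' the downstream statistics: branch lengths present and finite, tip labels
#' unique.
#'
#' @param path path to a Newick file (or a Newick string via `text`).
#' @param text optional Newick string instead of a file.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("Newick tree must have branch lengths on every edge")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Phylogenetic covariance matrix
#'
#' Shared root-to-ancestor path lengths between all tip pairs; the diagonal
#' holds root-to-tip distances. Delegates to [ape::vcv.phylo()].
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return an n x n symmetric matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) ape::vcv.phylo(tree)

# Pagel's lambda transform: off-diagonal entries scaled by lambda
lambda_transform <- function(C, lambda) {
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

# align a named vector to tree tip order; unnamed vectors are taken as
# already ordered
align_to_tree <- function(x, tree, what = "data") {
  n <- length(tree$tip.label)
  if (length(x) != n)
    stop(what, " length (", length(x), ") does not match number of tips (", n, ")")
  if (!is.null(names(x))) {
    if (!setequal(names(x), tree$tip.label))
      stop(what, " names do not match tree tip labels")
    x <- x[tree$tip.label]
  }
  unname(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value is exact for
#' small untied samples (n <= 10) and uses the t approximation otherwise
#' (delegating to [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return an object of class `correlation_result` with elements `rho`,
#'   `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  ties <- anyDuplicated(x) || anyDuplicated(y)
  exact <- !ties && length(x) <= 10
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x),
                 method = if (exact) "exact" else "t-approximation"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman's rho = %.3f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}

# profile log-likelihood of the GLS model y = X beta + e, e ~ N(0, s2 V(lambda))
pgls_loglik <- function(lambda, y, X, C) {
  V <- lambda_transform(C, lambda)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(ll = -Inf))
  n <- length(y)
  Ly <- backsolve(R, y, transpose = TRUE)
  LX <- backsolve(R, X, transpose = TRUE)
  fit <- stats::lm.fit(LX, Ly)
  rss <- sum(fit$residuals^2)
  s2 <- rss / n
  if (!is.finite(s2) || s2 <= 0) return(list(ll = -Inf))
  ll <- -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(R))) + n)
  list(ll = ll, beta = fit$coefficients, rss = rss, R = R, LX = LX, Ly = Ly)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Simple GLS regression of `y` on `x` (or an intercept-only model if `x`
#' is `NULL`) under residual covariance `sigma^2 * V(lambda)`, where
#' `V(lambda)` is the tree covariance with its off-diagonal multiplied by
#' lambda. `lambda_mode = "ml"` maximizes the profile likelihood over
#' lambda in `[0, 1]` (grid search plus local refinement); `"fixed0"`
#' reduces to ordinary least squares and `"fixed1"` to the full BM model.
#' For the ML fit, likelihood-ratio tests against both bounds are reported
#' using the boundary-corrected half-chi-squared(1) reference; when the
#' estimate itself sits on the tested bound the p-value is 1.
#'
#' @param y response, named by species or in tip order.
#' @param x predictor (or `NULL` for intercept-only, which estimates
#'   phylogenetic signal of `y` alone).
#' @param tree an `ape::phylo` tree.
#' @param lambda_mode `"ml"`, `"fixed0"` or `"fixed1"`.
#' @return an object of class `pgls_result`: coefficients, `lambda`,
#'   `p_value` (slope, t test with n - k df), `adjusted_R2`,
#'   `lambda_bounds` (p-values against lambda = 0 and 1, ML mode only) and
#'   `log_likelihood`.
#' @export
pgls <- function(y, x = NULL, tree, lambda_mode = c("ml", "fixed0", "fixed1")) {
  lambda_mode <- match.arg(lambda_mode)
  C <- phylo_vcv(tree)
  y <- align_to_tree(y, tree, "y")
  n <- length(y)
  X <- if (is.null(x)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
       else cbind("(Intercept)" = 1, x = align_to_tree(x, tree, "x"))
  k <- ncol(X)
  if (n <= k + 1) stop("too few tips for the number of coefficients")

  lambda_bounds <- c(vs0 = NA_real_, vs1 = NA_real_)
  if (lambda_mode == "ml") {
    grid <- seq(0, 1, by = 0.01)
    ll_grid <- vapply(grid, function(l) pgls_loglik(l, y, X, C)$ll, numeric(1))
    if (all(!is.finite(ll_grid))) stop("non-finite likelihood over the lambda grid")
    i0 <- which.max(ll_grid)
    lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
    opt <- stats::optimize(function(l) pgls_loglik(l, y, X, C)$ll,
                           interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    lambda <- if (opt$objective >= ll_grid[i0]) opt$maximum else grid[i0]
    ll_hat <- max(opt$objective, ll_grid[i0])
    for (bnd in c(0, 1)) {
      nm <- if (bnd == 0) "vs0" else "vs1"
      if (abs(lambda - bnd) < 1e-6) {
        lambda_bounds[nm] <- 1
      } else {
        lr <- 2 * (ll_hat - pgls_loglik(bnd, y, X, C)$ll)
        lambda_bounds[nm] <- 0.5 * stats::pchisq(max(lr, 0), df = 1,
                                                 lower.tail = FALSE)
      }
    }
  } else {
    lambda <- if (lambda_mode == "fixed0") 0 else 1
  }

  fit <- pgls_loglik(lambda, y, X, C)
  if (!is.finite(fit$ll)) stop("non-finite likelihood at lambda = ", lambda)
  beta <- fit$beta
  s2_hat <- fit$rss / (n - k)          # unbiased residual variance
  XtVX_inv <- chol2inv(qr.R(qr(fit$LX)))
  se <- sqrt(s2_hat * diag(XtVX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)

  # GLS R^2 against the GLS intercept-only model under the same V
  fit0 <- pgls_loglik(lambda, y, matrix(1, n, 1), C)
  R2 <- 1 - fit$rss / fit0$rss
  adjR2 <- 1 - (1 - R2) * (n - 1) / (n - 2)

  structure(list(coefficients = beta, se = se, t = tval, p_value = pval,
                 slope = if (k == 2) unname(beta[2]) else NA_real_,
                 slope_p = if (k == 2) unname(pval[2]) else NA_real_,
                 lambda = lambda, lambda_mode = lambda_mode,
                 lambda_bounds = lambda_bounds,
                 adjusted_R2 = adjR2, R2 = R2,
                 log_likelihood = fit$ll, n = n, df_residual = n - k),
            class = "pgls_result")
}

#' @export
print.pgls_result <- function(x, ...) {
  cat(sprintf("PGLS (lambda %s = %.3f)\n",
              switch(x$lambda_mode, ml = "ML", fixed0 = "fixed", fixed1 = "fixed"),
              x$lambda))
  tab <- cbind(Estimate = x$coefficients, `Std.Error` = x$se,
               t = x$t, `p` = x$p_value)
  print(signif(tab, 4))
  cat(sprintf("adjusted R2 = %.3f, logLik = %.3f, n = %d\n",
              x$adjusted_R2, x$log_likelihood, x$n))
  if (x$lambda_mode == "ml" && all(is.finite(x$lambda_bounds)))
    cat(sprintf("LR tests: lambda=0 p = %.3g; lambda=1 p = %.3g\n",
                x$lambda_bounds["vs0"], x$lambda_bounds["vs1"]))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test on the paired differences, with zero
#' differences dropped. The exact null distribution is used for n <= 25
#' untied differences; otherwise the normal approximation with continuity
#' correction (delegating to [stats::wilcox.test()]).
#'
#' @param x,y paired numeric vectors.
#' @return list with `statistic` (W+), `p_value`, `n_used`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  if (length(d) < 3) stop("fewer than 3 nonzero paired differences")
  exact <- length(d) <= 25 && !anyDuplicated(abs(d))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_used = length(d),
       method = if (exact) "exact" else "normal approximation")
}

# restricted (REML) log-likelihood of the intercept-only GLS model
# d ~ N(mu 1, sigma^2 V(lambda)); REML is preferred here because the
# variance parameter lambda is estimated from few species and its ML
# estimate is biased downwards, which anticonservatively shrinks the
# standard error of the mean difference
paired_remll <- function(lambda, d, C) {
  n <- length(d)
  V <- lambda_transform(C, lambda)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(ll = -Inf))
  Ld <- backsolve(R, d, transpose = TRUE)
  L1 <- backsolve(R, rep(1, n), transpose = TRUE)
  it11 <- sum(L1^2)                     # 1' V^-1 1
  mu <- sum(L1 * Ld) / it11
  rss <- sum((Ld - mu * L1)^2)
  s2 <- rss / (n - 1)
  if (!is.finite(s2) || s2 <= 0) return(list(ll = -Inf))
  ll <- -0.5 * ((n - 1) * log(2 * pi * s2) + 2 * sum(log(diag(R))) +
                log(it11) + (n - 1))
  list(ll = ll, mu = mu, s2 = s2, it11 = it11)
}

#' Phylogenetic paired t-test
#'
#' Tests whether the mean of the paired differences d = y1 - y2 across
#' species is zero, allowing the differences to covary phylogenetically:
#' d ~ N(mu 1, sigma^2 V(lambda)), with Pagel's lambda profiled on the
#' differences by restricted maximum likelihood. The GLS mean and its
#' standard error give a t statistic on n - 2 degrees of freedom (one lost
#' to the mean, one to the estimated lambda). On a star phylogeny lambda
#' is inestimable (the covariance has no off-diagonal), so the test
#' reduces exactly to the ordinary paired t-test with n - 1 degrees of
#' freedom.
#'
#' @param y1,y2 paired tip values, named by species or in tip order.
#' @param tree an `ape::phylo` tree.
#' @return list with `t`, `df`, `p_value`, `mean_diff`, `lambda`.
#' @export
phyl_paired_ttest <- function(y1, y2, tree) {
  d <- align_to_tree(y1, tree, "y1") - align_to_tree(y2, tree, "y2")
  n <- length(d)
  if (n < 3) stop("need at least 3 species")
  if (stats::sd(d) < 1e-12 * (abs(mean(d)) + 1e-300))
    stop("degenerate paired differences: essentially zero variance")
  C <- phylo_vcv(tree)
  off <- C; diag(off) <- 0
  lambda_estimable <- max(abs(off)) > 1e-12 * max(diag(C))

  if (lambda_estimable) {
    grid <- seq(0, 1, by = 0.02)
    ll <- vapply(grid, function(l) paired_remll(l, d, C)$ll, numeric(1))
    i0 <- which.max(ll)
    opt <- stats::optimize(function(l) paired_remll(l, d, C)$ll,
                           interval = c(grid[max(1, i0 - 1)],
                                        grid[min(length(grid), i0 + 1)]),
                           maximum = TRUE, tol = 1e-6)
    lambda <- if (opt$objective >= ll[i0]) opt$maximum else grid[i0]
    df <- n - 2
  } else {
    lambda <- 0
    df <- n - 1
  }
  fit <- paired_remll(lambda, d, C)
  se <- sqrt(fit$s2 / fit$it11)
  tval <- fit$mu / se
  p <- 2 * stats::pt(-abs(tval), df = df)
  list(t = tval, df = df, p_value = p, mean_diff = fit$mu, lambda = lambda)
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Draws one or more correlated traits at the tips from the matrix-normal
#' BM model: `vec(X) ~ N(root, kron(rate_matrix, C))` with C the tree
#' covariance. Used both to build synthetic clades and to calibrate the
#' statistics.
#'
#' @param tree an `ape::phylo` tree.
#' @param rate_matrix scalar rate (one trait) or p x p positive
#'   semi-definite evolutionary rate matrix.
#' @param root root state(s), recycled to p.
#' @param seed optional integer seed for reproducibility.
#' @return an n_tips x p matrix with tip labels as rownames.
#' @export
bm_simulate <- function(tree, rate_matrix, root = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- as.matrix(rate_matrix)
  p <- nrow(R)
  if (any(R != t(R))) stop("rate_matrix must be symmetric")
  ev <- eigen(R, symmetric = TRUE)
  if (any(ev$values < -1e-12 * max(abs(ev$values), 1)))
    stop("rate_matrix must be positive semi-definite")
  C <- phylo_vcv(tree)
  n <- nrow(C)
  Lc <- t(chol(C))
  # matrix square root of R (handles semidefinite zero-rate cases)
  Lr <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p) %*% t(ev$vectors)
  Z <- matrix(stats::rnorm(n * p), n, p)
  X <- Lc %*% Z %*% Lr
  X <- sweep(X, 2, rep_len(root, p), `+`)
  rownames(X) <- rownames(C)
  X
}

#' Run the full correlation and regression suite
#'
#' The comparative analysis: for each of the five predictor/response pairs
#' (torsion peak VM vs impact peak VM; critical buckling stress vs impact
#' peak VM; maximum shear stress vs torsion peak VM; body length vs each
#' regime's peak VM) it reports the Spearman rank correlation and PGLS fits
#' under the three lambda treatments (ML, 0, 1).
#'
#' @param table a data.frame with one row per species (rownames = species
#'   labels) and columns `peak_vm_impact`, `peak_vm_torsion`, `sigma_cr`,
#'   `tau_max`, `body_length`.
#' @param tree an `ape::phylo` tree whose tips match the table rows.
#' @return a data.frame of class `correlation_suite` with 15 rows (5 pairs
#'   x 3 lambda treatments).
#' @export
run_correlation_suite <- function(table, tree) {
  need <- c("peak_vm_impact", "peak_vm_torsion", "sigma_cr", "tau_max",
            "body_length")
  miss <- setdiff(need, colnames(table))
  if (length(miss)) stop("table is missing columns: ", paste(miss, collapse = ", "))
  if (!setequal(rownames(table), tree$tip.label))
    stop("table species labels do not match tree tip labels")
  table <- table[tree$tip.label, , drop = FALSE]

  pairs <- list(
    c(pred = "peak_vm_torsion", resp = "peak_vm_impact"),
    c(pred = "sigma_cr",        resp = "peak_vm_impact"),
    c(pred = "tau_max",         resp = "peak_vm_torsion"),
    c(pred = "body_length",     resp = "peak_vm_impact"),
    c(pred = "body_length",     resp = "peak_vm_torsion"))
  modes <- c("ml", "fixed0", "fixed1")

  rows <- list()
  for (pr in pairs) {
    x <- table[[pr["pred"]]]
    yv <- table[[pr["resp"]]]
    names(x) <- names(yv) <- rownames(table)
    sp <- spearman_cor(x, yv)
    for (m in modes) {
      fit <- pgls(yv, x, tree, lambda_mode = m)
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = unname(pr["pred"]), response = unname(pr["resp"]),
        spearman_rho = sp$rho, spearman_p = sp$p_value,
        lambda_mode = m, lambda = fit$lambda,
        slope = fit$slope, slope_p = fit$slope_p,
        adjusted_R2 = fit$adjusted_R2,
        p_lambda_vs0 = fit$lambda_bounds["vs0"],
        p_lambda_vs1 = fit$lambda_bounds["vs1"],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_suite", "data.frame")
  out
}
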