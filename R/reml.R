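#' Build a fixed-effects design matrix from covariates
#'
#' One-hot encodes categorical covariates with a first-level reference,
#' appends continuous columns (e.g. genetic PCs), and drops aliased
#' columns so the result has full column rank.
#'
#' @param covariates data.frame of factors/characters (may be `NULL`).
#' @param pcs optional numeric matrix of continuous covariates.
#' @param n number of observations (required when both are `NULL`).
#' @return numeric design matrix including an intercept.
#' @export
build_design <- function(covariates = NULL, pcs = NULL, n = NULL) {
  if (is.null(covariates) && is.null(pcs)) {
    stopifnot(!is.null(n))
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covariates[] <- lapply(covariates, function(x) {
      if (is.character(x)) factor(x) else x
    })
    X <- stats::model.matrix(~ ., data = covariates)
  } else {
    X <- matrix(1, nrow(pcs), 1, dimnames = list(NULL, "(Intercept)"))
  }
  if (!is.null(pcs)) X <- cbind(X, as.matrix(pcs))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  X
}

# Restricted log-likelihood at given variance components, by direct dense
# evaluation. Used by the fitter and, independently, as the oracle the
# fitter's reported logL is checked against.
#   logL = -1/2 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ]
#' Evaluate the restricted log-likelihood directly
#'
#' @param y response vector.
#' @param X full-rank design matrix.
#' @param K list of covariance (relationship) matrices, one per genetic /
#'   microbial random term; the residual identity term is implicit.
#' @param sigma2 variance components: one per element of `K`, then the
#'   residual.
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(y, X, K, sigma2) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(sigma2[length(sigma2)], n)
  for (k in seq_along(K)) V <- V + sigma2[k] * K[[k]]
  Vc <- chol(V)
  Vi <- chol2inv(Vc)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  Xc <- chol(XtViX)
  P <- Vi - ViX %*% chol2inv(Xc) %*% t(ViX)
  yPy <- drop(crossprod(y, P %*% y))
  -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(Vc))) +
            2 * sum(log(diag(Xc))) + yPy)
}

# P matrix, score vector and average-information matrix at sigma2.
# Terms: K[[1]], ..., K[[m]], I (residual last).
reml_derivs <- function(y, X, K, sigma2) {
  n <- length(y)
  p <- ncol(X)
  m <- length(K)
  V <- diag(sigma2[m + 1], n)
  for (k in seq_len(m)) V <- V + sigma2[k] * K[[k]]
  Vc <- chol(V)
  Vi <- chol2inv(Vc)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  Xc <- chol(XtViX)
  P <- Vi - ViX %*% chol2inv(Xc) %*% t(ViX)
  Py <- drop(P %*% y)
  logl <- -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(Vc))) +
                    2 * sum(log(diag(Xc))) + sum(y * Py))
  KPy <- vector("list", m + 1)
  trPK <- numeric(m + 1)
  for (k in seq_len(m)) {
    KPy[[k]] <- drop(K[[k]] %*% Py)
    trPK[k] <- sum(P * K[[k]])       # tr(PK) for symmetric K
  }
  KPy[[m + 1]] <- Py
  trPK[m + 1] <- sum(diag(P))
  score <- numeric(m + 1)
  AI <- matrix(0, m + 1, m + 1)
  PKPy <- lapply(KPy, function(v) drop(P %*% v))
  for (k in seq_len(m + 1)) {
    score[k] <- -0.5 * (trPK[k] - sum(Py * KPy[[k]]))
    for (l in seq_len(k)) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(KPy[[k]] * PKPy[[l]])
    }
  }
  list(logl = logl, score = score, AI = AI, trPK = trPK, Py = Py)
}

#' AI-REML variance-component estimation
#'
#' Fits `y = Xb + sum_k u_k + e` with `u_k ~ N(0, sigma2_k K_k)` and
#' `e ~ N(0, sigma2_e I)` by restricted maximum likelihood:
#' expectation-maximisation steps for the first `n_em` iterations
#' (stability far from the optimum), then average-information updates
#' with step halving. Components are constrained non-negative: proposals
#' below a small floor are clamped there and flagged.
#'
#' @param y response vector.
#' @param X fixed-effects design matrix (full column rank; see
#'   [build_design()]).
#' @param K a single relationship matrix or a list of them
#'   ([relationship_matrix] or plain symmetric matrices).
#' @param term_names labels for the random terms.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param tol_logl,tol_par convergence tolerances on the restricted
#'   log-likelihood change and the relative parameter change.
#' @param n_em number of EM warm-start iterations.
#' @return object of class `varcomp_result`: `sigma2` (named; residual
#'   last), `ratios` (each term's share of total variance; for a GRM term
#'   this is h2, for an MRM term m2), `se` (approximate SEs of components
#'   and ratios from the inverse AI matrix), `logL`, `converged`,
#'   `n_iter`, `fixed_at_boundary`, `n`.
#' @export
reml_fit <- function(y, X, K, term_names = NULL, max_iter = 100L,
                     tol_logl = 1e-8, tol_par = 1e-6, n_em = 3L) {
  if (inherits(K, "relationship_matrix") || is.matrix(K)) K <- list(K)
  K <- lapply(K, function(k) if (inherits(k, "relationship_matrix")) k$values else k)
  n <- length(y)
  m <- length(K)
  for (k in K) {
    if (nrow(k) != n) stop("relationship matrix not aligned with y", call. = FALSE)
  }
  stopifnot(nrow(X) == n, n > ncol(X) + m)
  if (is.null(term_names)) term_names <- sprintf("term%d", seq_len(m))

  vy <- stats::var(y)
  floor_v <- 1e-6 * vy
  sigma2 <- rep(vy / (m + 1), m + 1)
  d0 <- reml_derivs(y, X, K, sigma2)
  logl <- d0$logl
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d <- if (iter == 1L) d0 else reml_derivs(y, X, K, sigma2)
    old <- sigma2
    old_logl <- d$logl
    if (iter <= n_em) {
      # EM update per component
      for (k in seq_len(m + 1)) {
        yPKPy <- if (k <= m) sum(d$Py * drop(K[[k]] %*% d$Py)) else sum(d$Py^2)
        sigma2[k] <- (sigma2[k]^2 * yPKPy + n * sigma2[k] -
                        sigma2[k]^2 * d$trPK[k]) / n
      }
      sigma2 <- pmax(sigma2, floor_v)
      logl <- old_logl
      next
    }
    step <- tryCatch(solve(d$AI, d$score), error = function(e) NULL)
    if (is.null(step)) step <- d$score / max(diag(d$AI), 1)
    new_logl <- -Inf
    for (half in 0:10) {
      prop <- pmax(old + step / 2^half, floor_v)
      new_logl <- tryCatch(reml_loglik(y, X, K, prop), error = function(e) -Inf)
      if (new_logl >= old_logl - 1e-10) break
    }
    if (!is.finite(new_logl) || new_logl < old_logl - 1e-8) {
      # fall back to one EM step
      prop <- old
      for (k in seq_len(m + 1)) {
        yPKPy <- if (k <= m) sum(d$Py * drop(K[[k]] %*% d$Py)) else sum(d$Py^2)
        prop[k] <- (old[k]^2 * yPKPy + n * old[k] - old[k]^2 * d$trPK[k]) / n
      }
      prop <- pmax(prop, floor_v)
      new_logl <- reml_loglik(y, X, K, prop)
    }
    sigma2 <- prop
    if (abs(new_logl - old_logl) < tol_logl ||
        max(abs(sigma2 - old) / pmax(old, 1e-8)) < tol_par) {
      logl <- new_logl
      converged <- TRUE
      break
    }
    logl <- new_logl
  }

  fixed <- sigma2 <= floor_v * (1 + 1e-9)
  dfin <- reml_derivs(y, X, K, sigma2)
  se <- ratio_se <- rep(NA_real_, m + 1)
  AIi <- tryCatch(solve(dfin$AI), error = function(e) NULL)
  total <- sum(sigma2)
  ratios <- sigma2 / total
  if (!is.null(AIi)) {
    se <- sqrt(pmax(diag(AIi), 0))
    for (k in seq_len(m + 1)) {
      g <- -sigma2[k] / total^2
      gvec <- rep(g, m + 1)
      gvec[k] <- (total - sigma2[k]) / total^2
      ratio_se[k] <- sqrt(max(drop(t(gvec) %*% AIi %*% gvec), 0))
    }
  }
  names(sigma2) <- names(ratios) <- names(se) <- names(ratio_se) <-
    c(term_names, "residual")
  structure(list(
    sigma2 = sigma2, ratios = ratios, se = se, ratio_se = ratio_se,
    logL = dfin$logl, converged = converged, n_iter = iter,
    fixed_at_boundary = fixed, n = n, n_fixed_effects = ncol(X),
    term_names = term_names
  ), class = "varcomp_result")
}

#' @export
print.varcomp_result <- function(x, ...) {
  cat("REML variance components (n =", x$n, ")\n")
  for (k in seq_along(x$sigma2)) {
    cat(sprintf("  %-10s sigma2 = %8.4f  share = %6.3f (se %5.3f)\n",
                names(x$sigma2)[k], x$sigma2[k], x$ratios[k],
                x$ratio_se[k]))
  }
  cat(sprintf("  logL = %.4f, %sconverged in %d iterations\n",
              x$logL, if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}

#' Eigendecomposition of a relationship matrix for the fast REML path
#'
#' @param rel a [relationship_matrix] or symmetric matrix.
#' @return list with `vectors`, `values` (small negatives clamped to 0).
#' @export
rel_eigen <- function(rel) {
  V <- if (inherits(rel, "relationship_matrix")) rel$values else rel
  e <- eigen(V, symmetric = TRUE)
  e$values <- pmax(e$values, 0)
  e[c("values", "vectors")]
}

#' Single-random-term REML via eigendecomposition (fast path)
#'
#' Rotating by the eigenvectors of `K` makes the covariance diagonal,
#' `V = s (h D + (1 - h) I)` with `h = sigma2_k / (sigma2_k + sigma2_e)`;
#' the scale `s` is profiled out and the restricted likelihood maximised
#' over `h` in `[0, 1)` by golden-section/Brent search (with explicit
#' boundary evaluation). Gives estimates identical to the general AI-REML
#' path, at one matrix diagonalisation per relationship matrix, reusable
#' across any number of traits.
#'
#' @param y response vector.
#' @param X design matrix.
#' @param eig eigendecomposition from [rel_eigen()] (or a matrix /
#'   [relationship_matrix], decomposed on the fly).
#' @param term_name label for the random term.
#' @param compute_se also compute AI-based standard errors (one dense
#'   evaluation); skip for bulk scans.
#' @return a `varcomp_result` (see [reml_fit()]).
#' @export
reml_fit_eigen <- function(y, X, eig, term_name = "genetic",
                           compute_se = TRUE) {
  if (!is.list(eig) || is.null(eig$vectors)) eig <- rel_eigen(eig)
  n <- length(y)
  stopifnot(length(eig$values) == n, nrow(X) == n)
  p <- ncol(X)
  yt <- drop(crossprod(eig$vectors, y))
  Xt <- crossprod(eig$vectors, X)
  d <- eig$values

  prof <- function(h) {
    w <- 1 / (h * d + (1 - h))
    XtW <- Xt * w
    A <- crossprod(Xt, XtW)
    Ac <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(Ac)) return(list(logl = -Inf))
    b <- backsolve(Ac, forwardsolve(t(Ac), crossprod(XtW, yt)))
    r <- yt - drop(Xt %*% b)
    q <- sum(w * r^2)
    s <- q / (n - p)
    logl <- -0.5 * ((n - p) * (log(2 * pi) + log(s) + 1) -
                      sum(log(w)) + 2 * sum(log(diag(Ac))))
    list(logl = logl, s = s, b = b)
  }
  obj <- function(h) prof(h)$logl
  opt <- stats::optimize(obj, c(0, 1 - 1e-8), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  cand_h <- c(opt$maximum, 0, 1 - 1e-8)
  cand_l <- c(opt$objective, obj(0), obj(1 - 1e-8))
  best <- which.max(cand_l)
  h <- cand_h[best]
  fit <- prof(h)
  s <- fit$s
  sigma2 <- c(h * s, (1 - h) * s)

  se <- ratio_se <- rep(NA_real_, 2)
  if (compute_se) {
    Kd <- eig$vectors %*% (eig$values * t(eig$vectors))
    dfin <- reml_derivs(y, X, list(Kd), sigma2)
    AIi <- tryCatch(solve(dfin$AI), error = function(e) NULL)
    if (!is.null(AIi)) {
      se <- sqrt(pmax(diag(AIi), 0))
      total <- sum(sigma2)
      for (k in 1:2) {
        gvec <- rep(-sigma2[k] / total^2, 2)
        gvec[k] <- (total - sigma2[k]) / total^2
        ratio_se[k] <- sqrt(max(drop(t(gvec) %*% AIi %*% gvec), 0))
      }
    }
  }
  ratios <- sigma2 / sum(sigma2)
  names(sigma2) <- names(ratios) <- names(se) <- names(ratio_se) <-
    c(term_name, "residual")
  structure(list(
    sigma2 = sigma2, ratios = ratios, se = se, ratio_se = ratio_se,
    logL = cand_l[best], converged = TRUE, n_iter = NA_integer_,
    fixed_at_boundary = c(h <= 1e-8, FALSE), n = n, n_fixed_effects = p,
    term_names = term_name
  ), class = "varcomp_result")
}

#' Restricted log-likelihood of the fixed-effects-only null model
#'
#' @param y response vector.
#' @param X design matrix.
#' @return scalar restricted log-likelihood (same convention as
#'   [reml_fit()], so differences are valid LRT statistics).
#' @export
reml_null_loglik <- function(y, X) {
  n <- length(y)
  p <- ncol(X)
  f <- stats::lm.fit(X, y)
  rss <- sum(f$residuals^2)
  s <- rss / (n - p)
  Ac <- chol(crossprod(X))
  -0.5 * ((n - p) * (log(2 * pi) + log(s) + 1) + 2 * sum(log(diag(Ac))))
}

#' Heritability (model with GRM as the single random term)
#'
#' @param y phenotype vector.
#' @param X design matrix (see [build_design()]).
#' @param G GRM ([relationship_matrix], matrix, or [rel_eigen()] output).
#' @param ... passed to [reml_fit_eigen()].
#' @return a `varcomp_result`; `ratios["genetic"]` is h2.
#' @export
estimate_h2 <- function(y, X, G, ...) {
  reml_fit_eigen(y, X, G, term_name = "genetic", ...)
}

#' Microbiability (model with MRM as the single random term)
#'
#' @param y phenotype vector.
#' @param X design matrix.
#' @param M MRM ([relationship_matrix], matrix, or [rel_eigen()] output).
#' @param ... passed to [reml_fit_eigen()].
#' @return a `varcomp_result`; `ratios["microbial"]` is m2.
#' @export
estimate_m2 <- function(y, X, M, ...) {
  reml_fit_eigen(y, X, M, term_name = "microbial", ...)
}

#' Joint model: GRM and MRM as simultaneous random terms
#'
#' @param y phenotype vector.
#' @param X design matrix.
#' @param G GRM; @param M MRM.
#' @param ... passed to [reml_fit()].
#' @return a `varcomp_result` with both `genetic` (h2) and `microbial`
#'   (m2) shares.
#' @export
estimate_joint <- function(y, X, G, M, ...) {
  reml_fit(y, X, list(G, M), term_names = c("genetic", "microbial"), ...)
}

#' Likelihood-ratio test for a variance component
#'
#' `stat = max(0, 2 (logL_full - logL_reduced))`; because the component
#' is tested on the boundary of its parameter space the reference
#' distribution is the 50:50 mixture of a point mass at 0 and chi-square
#' with 1 df, so `p = 0.5 P(chisq_1 >= stat)`.
#'
#' @param full a `varcomp_result` (or its logL).
#' @param reduced the nested model's `varcomp_result` or log-likelihood
#'   (e.g. [reml_null_loglik()]).
#' @return list with `stat` and `p_value`.
#' @export
lrt <- function(full, reduced) {
  lf <- if (inherits(full, "varcomp_result")) full$logL else full
  lr <- if (inherits(reduced, "varcomp_result")) reduced$logL else reduced
  if (lf < lr - 1e-6) {
    stop("full-model logL below reduced-model logL: optimisation failure",
         call. = FALSE)
  }
  stat <- max(0, 2 * (lf - lr))
  list(stat = stat, p_value = 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Heritability scan over a microbial feature set
#'
#' Fits the single-GRM model to every community trait, CLR quantitative
#' trait and 0/1 binary trait (on the observed scale), with a
#' boundary-corrected LRT against the fixed-effects-only null. Constant
#' features are skipped with a warning. The GRM is diagonalised once and
#' reused across all features.
#'
#' @param features named list of numeric matrices/data.frames (columns =
#'   features), e.g. `list(community = ..., quantitative = ...,
#'   binary = ...)`, or the output of [build_feature_set()].
#' @param X design matrix shared by all features.
#' @param G GRM (any form accepted by [rel_eigen()]).
#' @param alpha LRT significance threshold used for the `heritable` flag.
#' @return data.frame: feature, class, h2, se, logL, lrt_stat, lrt_p,
#'   heritable.
#' @export
feature_h2_scan <- function(features, X, G, alpha = 0.05) {
  if (!is.null(features$traits)) {
    comm <- features$community
    cn <- setdiff(colnames(comm), "sample_id")
    features <- list(
      community = as.matrix(comm[, cn, drop = FALSE]),
      quantitative = features$traits$quantitative,
      binary = features$traits$binary
    )
  }
  eig <- rel_eigen(G)
  out <- list()
  for (cls in names(features)) {
    mat <- as.matrix(features[[cls]])
    for (j in seq_len(ncol(mat))) {
      yv <- mat[, j]
      nm <- colnames(mat)[j] %||% sprintf("%s_%d", cls, j)
      keep <- is.finite(yv)
      if (sum(keep) < 10 || isTRUE(stats::sd(yv[keep]) == 0)) {
        warning("constant or near-empty feature skipped: ", nm)
        next
      }
      Xk <- X[keep, , drop = FALSE]
      if (all(keep)) {
        fit <- reml_fit_eigen(yv, X, eig, compute_se = TRUE)
      } else {
        Gk <- eig$vectors %*% (eig$values * t(eig$vectors))
        fit <- reml_fit_eigen(yv[keep], Xk, Gk[keep, keep], compute_se = TRUE)
      }
      l0 <- reml_null_loglik(yv[keep], Xk)
      tst <- lrt(fit, l0)
      out[[length(out) + 1L]] <- data.frame(
        feature = nm, class = cls,
        h2 = unname(fit$ratios[1]), se = unname(fit$ratio_se[1]),
        logL = fit$logL, lrt_stat = tst$stat, lrt_p = tst$p_value,
        heritable = tst$p_value < alpha,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
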