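# --- linear regression (least squares via QR on the normal problem) -------

fit_lr_core <- function(X, y) {
  A <- cbind(`(Intercept)` = 1, X)
  beta <- qr.coef(qr(A), y)
  beta[is.na(beta)] <- 0 # rank-deficient columns contribute nothing
  list(coef = beta)
}

predict_lr_core <- function(fit, X) {
  as.vector(cbind(1, X) %*% fit$coef)
}

# --- lasso via coordinate descent ------------------------------------------
# objective: (1/2n) sum (y - b0 - X b)^2 + penalty * sum |b_j|,
# on internally standardized predictors (coefficients returned on the
# original scale)

fit_lasso_core <- function(X, y, penalty = 0.01, tol = 1e-8, max_iter = 10000L) {
  n <- nrow(X)
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd) * sqrt((n - 1) / n)
  sg[sg == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  ym <- mean(y)
  yc <- y - ym
  p <- ncol(Z)
  b <- rep(0, p)
  r <- yc
  zss <- colSums(Z^2) / n # = 1 for non-constant columns
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (zss[j] == 0) next
      rho <- sum(Z[, j] * r) / n + zss[j] * b[j]
      bj <- soft(rho, penalty) / zss[j]
      if (bj != b[j]) {
        r <- r - Z[, j] * (bj - b[j])
        delta <- max(delta, abs(bj - b[j]))
        b[j] <- bj
      }
    }
    if (delta < tol) break
  }
  coef <- b / sg
  list(coef = c(ym - sum(coef * mu), coef), penalty = penalty)
}

# --- kernel ridge regression ------------------------------------------------

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

fit_krr_core <- function(X, y, penalty = 0.1, kernel = c("rbf", "linear"),
                         gamma = NULL) {
  kernel <- match.arg(kernel)
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  gamma <- gamma %||% (1 / ncol(Z))
  K <- if (kernel == "rbf") rbf_kernel(Z, Z, gamma) else Z %*% t(Z)
  ym <- mean(y)
  alpha <- solve(K + penalty * diag(nrow(Z)), y - ym)
  list(alpha = alpha, Z = Z, mu = mu, sg = sg, ym = ym,
       kernel = kernel, gamma = gamma, penalty = penalty)
}

predict_krr_core <- function(fit, X) {
  Z <- sweep(sweep(X, 2, fit$mu), 2, fit$sg, "/")
  K <- if (fit$kernel == "rbf") rbf_kernel(Z, fit$Z, fit$gamma) else Z %*% t(fit$Z)
  as.vector(K %*% fit$alpha) + fit$ym
}

# --- neural-network adapters (delegated to nnet) ---------------------------

fit_nnet_core <- function(X, y, size, decay, maxit, seed) {
  if (!requireNamespace("nnet", quietly = TRUE))
    stop("the MLP/BP registry entries need the 'nnet' package", call. = FALSE)
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  yr <- range(y)
  span <- max(yr[2] - yr[1], 1e-12)
  ys <- (y - yr[1]) / span
  net <- local_seed(seed, nnet::nnet(Z, ys, size = size, decay = decay,
                                     maxit = maxit, linout = TRUE,
                                     trace = FALSE))
  list(net = net, mu = mu, sg = sg, y0 = yr[1], span = span)
}

predict_nnet_core <- function(fit, X) {
  Z <- sweep(sweep(X, 2, fit$mu), 2, fit$sg, "/")
  as.vector(stats::predict(fit$net, Z)) * fit$span + fit$y0
}

# --- support vector regression adapter (delegated to e1071) ----------------

fit_svr_core <- function(X, y, cost = 10, epsilon = 0.1, seed = 1) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("the SVR registry entry needs the 'e1071' package", call. = FALSE)
  m <- local_seed(seed, e1071::svm(X, y, type = "eps-regression",
                                   kernel = "radial", cost = cost,
                                   epsilon = epsilon, scale = TRUE))
  list(svm = m)
}

predict_svr_core <- function(fit, X) as.vector(stats::predict(fit$svm, X))

# --- stacking ----------------------------------------------------------------
# base learners produce out-of-fold predictions on the training set; a
# linear meta-learner combines them; bases are refit on the full data

fit_stacking_core <- function(X, y, k = 5, seed = 1,
                              base_params = list()) {
  n <- nrow(X)
  seeds <- child_seeds(seed, 4L)
  folds <- make_folds(n, k, seeds[1])
  bases <- list(
    RFR = function(Xa, ya, s) fit_random_forest(Xa, ya, n_trees = base_params$rfr_trees %||% 100, seed = s),
    XGBoost = function(Xa, ya, s) fit_gboost(Xa, ya, rounds = base_params$gboost_rounds %||% 150, seed = s),
    KRR = function(Xa, ya, s) new_model(fit_krr_core(Xa, ya), "krr", "KRR", colnames(Xa))
  )
  oof <- matrix(NA_real_, n, length(bases),
                dimnames = list(NULL, names(bases)))
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    for (b in seq_along(bases)) {
      m <- bases[[b]](X[tr, , drop = FALSE], y[tr], seeds[2])
      oof[te, b] <- predict(m, X[te, , drop = FALSE])
    }
  }
  meta <- fit_lr_core(oof, y)
  full <- lapply(seq_along(bases), function(b) bases[[b]](X, y, seeds[3]))
  names(full) <- names(bases)
  list(bases = full, meta = meta)
}

predict_stacking_core <- function(fit, X) {
  B <- vapply(fit$bases, function(m) predict(m, X), numeric(nrow(X)))
  predict_lr_core(fit$meta, matrix(B, nrow = nrow(X)))
}

# seeded k-fold assignment with sizes differing by at most one
make_folds <- function(n, k, seed) {
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (n < k) stop("fewer rows than folds", call. = FALSE)
  local_seed(seed, sample(rep_len(seq_len(k), n)))
}
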