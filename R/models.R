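#' Gaussian naive Bayes active/inactive classifier
#'
#' Fits per-class, per-feature Gaussian class-conditionals with a variance
#' floor, and class priors from label frequencies. Used to screen out
#' sequences predicted to be catalytically dead before regression and
#' acquisition.
#'
#' @param X numeric feature matrix (rows = sequences).
#' @param active logical vector of activity labels.
#' @param smoothing variance floor; default `1e-9 * max feature variance`
#'   (an absolute floor of 1e-12 guards all-constant features).
#' @return object of class `gnb_model`.
#' @export
gnb_fit <- function(X, active, smoothing = NULL) {
  X <- as.matrix(X)
  active <- as.logical(active)
  stopifnot(nrow(X) == length(active))
  if (is.null(smoothing)) {
    fv <- apply(X, 2L, stats::var)
    fv[is.na(fv)] <- 0
    smoothing <- max(1e-9 * max(fv, 0), 1e-12)
  }
  classes <- c(`FALSE` = FALSE, `TRUE` = TRUE)
  present <- unique(active)
  if (length(present) < 2L) {
    warning("single-class training data: classifier will always predict ",
            if (present) "active" else "inactive")
  }
  stats_for <- function(cls) {
    sub <- X[active == cls, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    mu <- colMeans(sub)
    v <- apply(sub, 2L, function(x) {
      if (length(x) < 2L) 0 else stats::var(x)
    })
    list(mean = mu, var = pmax(v, smoothing), prior = nrow(sub) / nrow(X))
  }
  structure(
    list(classes = classes,
         stats = list(`FALSE` = stats_for(FALSE), `TRUE` = stats_for(TRUE)),
         smoothing = smoothing, n_features = ncol(X)),
    class = "gnb_model"
  )
}

#' @rdname gnb_fit
#' @param model a fitted `gnb_model`.
#' @param newX encodings to score (same feature dimension as training).
#' @return `gnb_predict`: numeric vector, posterior probability of the
#'   active class for each row.
#' @export
gnb_predict <- function(model, newX) {
  newX <- as.matrix(newX)
  if (ncol(newX) != model$n_features) {
    stop("encoding dimension ", ncol(newX), " does not match training (",
         model$n_features, ")")
  }
  loglik <- function(st) {
    if (is.null(st)) return(rep(-Inf, nrow(newX)))
    centered <- sweep(newX, 2L, st$mean)
    ll <- -0.5 * sweep(centered^2, 2L, st$var, "/") -
      0.5 * matrix(log(2 * pi * st$var), nrow(newX), ncol(newX),
                   byrow = TRUE)
    rowSums(ll) + log(st$prior)
  }
  la <- loglik(model$stats$`TRUE`)
  li <- loglik(model$stats$`FALSE`)
  if (all(is.infinite(li))) return(rep(1, nrow(newX)))
  if (all(is.infinite(la))) return(rep(0, nrow(newX)))
  m <- pmax(la, li)
  exp(la - m) / (exp(la - m) + exp(li - m))
}

#' Gaussian-process regression with a homogeneous linear kernel
#'
#' Covariance between sequences i and j is \eqn{k_{ij} = \sigma^2 x_i \cdot
#' x_j} on their one-hot encodings. The posterior mean and variance follow
#' the standard Cholesky factorize-and-solve route. Targets are
#' mean-centered by default and the mean restored at prediction; with an
#' empty training set the prior (mean 0, variance \eqn{\sigma^2 \|x\|^2})
#' is returned.
#'
#' @param X training encodings (n x d matrix; 0 rows allowed).
#' @param y training targets (titers, mg/L, optionally transformed).
#' @param sigma2 kernel variance hyperparameter (> 0).
#' @param noise_var observation noise variance; when 0 a jitter of
#'   `1e-8 * mean(diag(K))` keeps the factorization well posed.
#' @param center subtract the training mean from `y` (default TRUE).
#' @return object of class `gp_model` caching the Cholesky factor.
#' @export
gp_fit <- function(X, y, sigma2 = 1, noise_var = 1, center = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), sigma2 > 0, noise_var >= 0)
  if (any(!is.finite(y))) stop("non-finite targets")
  n <- nrow(X)
  mu0 <- if (center && n > 0) mean(y) else 0
  yc <- y - mu0
  if (n > 0) {
    K <- sigma2 * tcrossprod(X)
    jitter <- if (noise_var > 0) 0 else 1e-8 * max(mean(diag(K)), 1)
    L <- t(chol(K + diag(noise_var + jitter, n)))
    alpha <- backsolve(t(L), forwardsolve(L, yc))
  } else {
    L <- matrix(0, 0L, 0L)
    alpha <- numeric(0)
  }
  structure(list(X = X, y = y, mu0 = mu0, sigma2 = sigma2,
                 noise_var = noise_var, center = center,
                 L = L, alpha = alpha),
            class = "gp_model")
}

#' @rdname gp_fit
#' @param model a fitted `gp_model`.
#' @param newX query encodings.
#' @return `gp_predict`: list with numeric vectors `mean`, `var`, `sd`.
#' @export
gp_predict <- function(model, newX) {
  newX <- as.matrix(newX)
  prior_var <- model$sigma2 * rowSums(newX^2)
  if (nrow(model$X) == 0L) {
    return(list(mean = rep(model$mu0, nrow(newX)), var = prior_var,
                sd = sqrt(prior_var)))
  }
  if (ncol(newX) != ncol(model$X)) stop("query encoding dimension mismatch")
  Ks <- model$sigma2 * tcrossprod(newX, model$X)   # n* x n
  mean <- model$mu0 + as.vector(Ks %*% model$alpha)
  V <- forwardsolve(model$L, t(Ks))                # n x n*
  var <- pmax(prior_var - colSums(V^2), 0)
  list(mean = mean, var = var, sd = sqrt(var))
}

# Default hyperparameter grid: half-decade log spacing over 1e-6..1e5.
default_sigma2_grid <- function() 10^seq(-6, 5, by = 0.5)

#' Leave-one-out cross-validation scan of the kernel variance
#'
#' For every grid value of \eqn{\sigma^2}, computes leave-one-out
#' predictions, their Pearson correlation with the held-out targets and
#' their mean squared error, then picks the value minimizing the summed
#' ranks of (-r, MSE) — a deterministic balance of the two objectives.
#'
#' @param X,y training data (n >= 3).
#' @param grid candidate \eqn{\sigma^2} values; default 23 points
#'   log-spaced from 1e-6 to 1e5.
#' @param noise_var observation noise variance used throughout.
#' @param method `"closed_form"` (fast LOO identities) or `"refit"`
#'   (n explicit refits); both agree to numerical precision.
#' @return object of class `cv_report`: data.frame with `sigma2`, `r`,
#'   `mse` and attribute `chosen` (the selected \eqn{\sigma^2}).
#' @export
loo_cv_scan <- function(X, y, grid = default_sigma2_grid(), noise_var = 1,
                        method = c("closed_form", "refit")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out scan needs n >= 3")
  res <- lapply(grid, function(s2) {
    pred <- loo_predictions(X, y, s2, noise_var, method)
    mse <- mean((pred - y)^2)
    r <- if (stats::sd(y) == 0 || stats::sd(pred) == 0) NA_real_
         else stats::cor(pred, y)
    c(r = r, mse = mse)
  })
  tab <- data.frame(sigma2 = grid,
                    r = vapply(res, `[[`, numeric(1), "r"),
                    mse = vapply(res, `[[`, numeric(1), "mse"))
  if (all(is.na(tab$r))) {
    warning("correlation undefined (constant targets); selecting on MSE only")
    score <- rank(tab$mse, ties.method = "first")
  } else {
    score <- rank(-tab$r, ties.method = "first", na.last = "keep") +
      rank(tab$mse, ties.method = "first")
    score[is.na(score)] <- Inf
  }
  chosen <- tab$sigma2[which.min(score)]
  structure(tab, chosen = chosen, class = c("cv_report", "data.frame"))
}

#' @rdname loo_cv_scan
#' @param sigma2 a single kernel variance.
#' @return `loo_predictions`: numeric vector of leave-one-out predictions.
#' @export
loo_predictions <- function(X, y, sigma2, noise_var = 1,
                            method = c("closed_form", "refit")) {
  method <- match.arg(method)
  n <- nrow(X)
  if (method == "refit") {
    return(vapply(seq_len(n), function(i) {
      fit <- gp_fit(X[-i, , drop = FALSE], y[-i], sigma2, noise_var)
      gp_predict(fit, X[i, , drop = FALSE])$mean
    }, numeric(1)))
  }
  # Closed form via the standard LOO identity pred_i = z_i - [A^-1 z]_i /
  # A^-1_ii (A = K + noise I), applied to targets centered on the
  # leave-one-out mean mu_i = mean(y[-i]); the i-dependent centering is a
  # constant shift handled with one extra solve against the ones vector.
  K <- sigma2 * tcrossprod(X)
  jitter <- if (noise_var > 0) 0 else 1e-8 * max(mean(diag(K)), 1)
  Ainv <- chol2inv(chol(K + diag(noise_var + jitter, n)))
  ybar <- mean(y)
  a_y <- as.vector(Ainv %*% (y - ybar))
  a_1 <- as.vector(Ainv %*% rep(1, n))
  d <- diag(Ainv)
  mu_i <- (n * ybar - y) / (n - 1)
  shift <- ybar - mu_i
  z_i <- y - mu_i
  az_i <- a_y + shift * a_1
  mu_i + z_i - az_i / d
}

#' Per-block, per-parent contribution to predicted titer
#'
#' For each recombined block and each donor label, the mean model-predicted
#' change in titer when that block is substituted to the label, relative to
#' a reference parent's label, averaged over a background sample of
#' chimeras. Labels donating identical block sequences get identical
#' effects; the reference label's effects are zero by construction.
#'
#' @param model a fitted `gp_model` on `scheme` encodings.
#' @param parents a [parent_set].
#' @param partition a [block_partition].
#' @param scheme,contact_map encoding scheme used for the model.
#' @param background character vector of block strings to average over;
#'   default the full enumerated space when it has at most
#'   `max_background` members, else a seeded uniform sample of that size.
#' @param reference reference donor label (default the first parent).
#' @param max_background background cap before sampling (default 4374).
#' @param seed seed for background sampling.
#' @return data.frame with columns `block`, `label`, `effect`.
#' @export
block_contributions <- function(model, parents, partition,
                                scheme = "hamming", contact_map = NULL,
                                background = NULL,
                                reference = parents$names[1L],
                                max_background = 4374L, seed = 1L) {
  if (is.null(background)) {
    background <- enumerate_space(parents, partition)
    if (length(background) > max_background) {
      background <- withr_seed(seed, sample(background, max_background))
    }
  }
  labs <- chimera_label_matrix(background, parents, partition)
  out <- list()
  for (b in seq_len(partition$n_blocks)) {
    ref_labs <- labs
    ref_labs[, b + 1L] <- reference
    ref_chim <- paste0(ref_labs[, 1L], "-",
                       apply(ref_labs[, -1L, drop = FALSE], 1L,
                             paste, collapse = ""))
    ref_pred <- gp_predict(model, encode_chimeras(
      ref_chim, parents, partition, scheme, contact_map))$mean
    for (p in parents$names) {
      sub_labs <- labs
      sub_labs[, b + 1L] <- p
      sub_chim <- paste0(sub_labs[, 1L], "-",
                         apply(sub_labs[, -1L, drop = FALSE], 1L,
                               paste, collapse = ""))
      pred <- gp_predict(model, encode_chimeras(
        sub_chim, parents, partition, scheme, contact_map))$mean
      out[[length(out) + 1L]] <- data.frame(
        block = b, label = p, effect = mean(pred - ref_pred))
    }
  }
  do.call(rbind, out)
}

# Run expr with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
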