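#' Configuration of the time-delay embedded HMM
#'
#' Defaults follow the standard TDE parameterisation for parcel-level
#' electrophysiology: a symmetric +/-7 sample lag window and PCA to twice the
#' number of parcels, with K = 4 states.
#'
#' @param K number of states.
#' @param lags integer lag window, symmetric about 0.
#' @param pca_dim PCA dimension; default `2 * parcels`, `NA` disables PCA.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood change declaring convergence.
#' @param n_restarts randomised initialisations; the best short run is
#'   continued to convergence.
#' @param cov_reg ridge added to state covariances, as a fraction of the
#'   average eigenvalue (`cov_reg * trace/dim`).
#' @param seed seed controlling initialisation.
#' @return an object of class `hmm_config`.
#' @export
hmm_config <- function(K = 4, lags = -7:7, pca_dim = NULL, max_iter = 100,
                       tol = 1e-5, n_restarts = 5, cov_reg = 1e-3, seed = 1) {
  if (K < 1) abort("K must be >= 1")
  lags <- sort(unique(as.integer(lags)))
  if (!isTRUE(all.equal(lags, -rev(lags)))) abort("lags must be symmetric about 0")
  structure(list(K = as.integer(K), lags = lags, pca_dim = pca_dim,
                 max_iter = max_iter, tol = tol, n_restarts = n_restarts,
                 cov_reg = cov_reg, seed = seed), class = "hmm_config")
}

#' Time-delay embedding
#'
#' Augments each sample with lagged copies of all parcels, so that a
#' zero-mean Gaussian state covariance on the embedded space encodes the
#' state's autocovariance (hence spectral) structure. The embedding never
#' crosses segment boundaries: samples whose lag window leaves the segment
#' are masked out. Columns are ordered lag-major (all parcels at the most
#' negative lag first).
#'
#' @param x a [concat_data()] or plain matrix (treated as one segment).
#' @param lags integer lag window.
#' @return list with `X` (valid samples x `parcels * n_lags`), `valid`
#'   (logical over original samples), `seg` (segment id per original
#'   sample) and `lags`.
#' @export
embed_timedelay <- function(x, lags = -7:7) {
  dat <- if (inherits(x, "concat_data")) x$data else as.matrix(x)
  n <- nrow(dat)
  if (inherits(x, "concat_data")) {
    starts <- concat_segment_starts(x)
    seg <- cumsum(seq_len(n) %in% starts)
  } else {
    seg <- rep(1L, n)
    starts <- 1L
  }
  ends <- c(starts[-1] - 1L, n)
  lo <- min(lags); hi <- max(lags)
  t_idx <- seq_len(n)
  valid <- (t_idx + lo >= starts[seg]) & (t_idx + hi <= ends[seg])
  if (any(tabulate(seg[valid], max(seg)) == 0 & tabulate(seg, max(seg)) > 0)) {
    warn("segment(s) shorter than the lag window were dropped")
  }
  rows <- t_idx[valid]
  X <- do.call(cbind, lapply(lags, function(l) dat[rows + l, , drop = FALSE]))
  list(X = X, valid = valid, seg = seg, lags = lags)
}

#' PCA reduction with a stored projection
#'
#' Projects embedded data onto the leading principal axes of its covariance;
#' the projection (and centring) is kept so held-out data can be mapped into
#' the same space.
#'
#' @param X numeric matrix.
#' @param pca_dim number of components.
#' @return list with `scores`, `projection`, `center`, `eigenvalues`,
#'   `var_explained`.
#' @export
pca_reduce <- function(X, pca_dim) {
  if (pca_dim > ncol(X)) abort("pca_dim exceeds the embedded width")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(X) - 1)
  ev <- eigen(C, symmetric = TRUE)
  if (ev$values[pca_dim] <= max(ev$values) * 1e-12) {
    abort("pca_dim exceeds the numerical rank of the data")
  }
  proj <- ev$vectors[, seq_len(pca_dim), drop = FALSE]
  list(scores = Xc %*% proj, projection = proj, center = mu,
       eigenvalues = ev$values,
       var_explained = sum(ev$values[seq_len(pca_dim)]) / sum(pmax(ev$values, 0)))
}

#' Forward-backward posteriors for fixed parameters
#'
#' Computes per-sample state posteriors, pooled two-slice counts and the data
#' log-likelihood for a hidden Markov chain with the given emission
#' log-densities, restarting the chain at every segment boundary. Emission
#' rows are max-shifted before the scaled recursion, so the computation is
#' safe against underflow.
#'
#' @param logdens T x K matrix of emission log-densities.
#' @param transition K x K row-stochastic transition matrix.
#' @param initial length-K initial distribution.
#' @param seg_starts 1-based first sample of each independent segment.
#' @return list with `gamma` (T x K posteriors), `xi` (K x K pooled two-slice
#'   counts) and `loglik`.
#' @export
forward_backward <- function(logdens, transition, initial = NULL, seg_starts = 1L) {
  logdens <- as.matrix(logdens)
  K <- ncol(logdens)
  initial <- initial %||% rep(1 / K, K)
  check_prob_rows(transition, what = "transition")
  stopifnot(length(initial) == K, abs(sum(initial) - 1) < 1e-8)
  stopifnot(seg_starts[1] == 1, !is.unsorted(seg_starts))
  forward_backward_cpp(logdens, transition, initial, as.integer(seg_starts))
}

# T x K log-densities of zero-mean Gaussians given upper Cholesky factors
gaussian_logdens <- function(X, chols) {
  d <- ncol(X)
  Rinv <- lapply(chols, function(R) backsolve(R, diag(d)))
  logdet <- vapply(chols, function(R) 2 * sum(log(diag(R))), numeric(1))
  gauss_logdens_cpp(X, Rinv, logdet)
}

regularise_cov <- function(S, cov_reg) {
  S + diag(cov_reg * sum(diag(S)) / ncol(S), ncol(S))
}

# one EM run from given parameters; returns updated parameters + posteriors
em_run <- function(X, seg_starts, params, max_iter, tol, cov_reg) {
  K <- nrow(params$transition)
  trace <- numeric(0)
  fb <- NULL
  for (it in seq_len(max_iter)) {
    chols <- lapply(params$covariances, chol)
    logB <- gaussian_logdens(X, chols)
    fb <- forward_backward(logB, params$transition, params$initial, seg_starts)
    trace <- c(trace, fb$loglik)
    if (it > 1 && abs(trace[it] - trace[it - 1]) <
        tol * (abs(trace[it - 1]) + 1e-10)) break
    g <- fb$gamma
    Nk <- colSums(g)
    if (any(Nk / nrow(X) < 1e-6)) warn("degenerate state: near-zero posterior mass")
    params$covariances <- lapply(weighted_scatter_cpp(X, g),
                                 regularise_cov, cov_reg = cov_reg)
    if (K > 1) {
      A <- fb$xi / pmax(rowSums(fb$xi), .Machine$double.eps)
      params$transition <- A / rowSums(A)
      pi0 <- colMeans(g[seg_starts, , drop = FALSE])
      params$initial <- pi0 / sum(pi0)
    }
  }
  list(params = params, gamma = fb$gamma, loglik = fb$loglik,
       trace = trace, converged = length(trace) < max_iter)
}

# k-means-seeded initial parameters
init_params_kmeans <- function(X, K, seed, cov_reg) {
  with_seed(seed, {
    n <- nrow(X)
    idx <- if (n > 5000) sample.int(n, 5000) else seq_len(n)
    km <- suppressWarnings(stats::kmeans(X[idx, , drop = FALSE], centers = K,
                                         iter.max = 20, nstart = 1))
    # squared distances via the expansion ||x - c||^2 = ||x||^2 - 2 x'c + ||c||^2
    d2 <- -2 * X %*% t(km$centers)
    d2 <- sweep(d2, 2, rowSums(km$centers^2), "+")
    lab <- max.col(-d2, ties.method = "first")
    g <- matrix(0.1 / K, n, K)
    g[cbind(seq_len(n), lab)] <- 0.9 + 0.1 / K
    covs <- lapply(weighted_scatter_cpp(X, g), regularise_cov, cov_reg = cov_reg)
    A <- matrix(0.1 / max(K - 1, 1), K, K)
    diag(A) <- if (K > 1) 0.9 else 1
    list(transition = A, initial = rep(1 / K, K), covariances = covs)
  })
}

#' Fit a time-delay embedded Gaussian HMM
#'
#' Runs the full inference stack: time-delay embedding (masking segment
#' edges), PCA reduction, and maximum-likelihood EM (Baum-Welch with scaled
#' forward-backward recursions) for a zero-mean full-covariance Gaussian
#' observation model. `n_restarts` k-means-seeded short runs are scored by
#' log-likelihood and the best is continued to convergence. Posterior rows at
#' embedding-masked samples are set to the uniform distribution so the
#' posterior stays aligned with the input time axis.
#'
#' @param x a [concat_data()] or a plain numeric matrix (one segment).
#' @param config an [hmm_config()].
#' @return an object of class `tde_hmm` with elements `model` (transition,
#'   initial, state covariances, PCA map, log-likelihood trace), `gamma`
#'   (T x K posteriors aligned to the input samples), `path` (posterior
#'   decoding), `valid` (embedding mask), and the input index/fs when
#'   available.
#' @export
fit_hmm <- function(x, config = hmm_config()) {
  emb <- embed_timedelay(x, config$lags)
  emb_valid <- list(valid = emb$valid, seg = emb$seg)
  P <- if (inherits(x, "concat_data")) ncol(x$data) else ncol(as.matrix(x))
  pca_dim <- config$pca_dim %||% min(2L * P, ncol(emb$X))
  pca <- NULL
  if (!is.na(pca_dim) && pca_dim < ncol(emb$X)) {
    pca <- pca_reduce(emb$X, pca_dim)
    X <- pca$scores
    pca$scores <- NULL
  } else {
    X <- sweep(emb$X, 2, colMeans(emb$X))
  }
  rm(emb) # drop the wide embedding early
  seg_valid <- emb_valid$seg[emb_valid$valid]
  seg_starts <- which(seg_valid != dplyr::lag(seg_valid, default = -1L))

  K <- config$K
  short_iter <- min(10, config$max_iter)
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    init <- init_params_kmeans(X, K, derive_seed(config$seed, 31L, r), config$cov_reg)
    run <- em_run(X, seg_starts, init, short_iter, config$tol, config$cov_reg)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (config$max_iter > short_iter && !best$converged) {
    cont <- em_run(X, seg_starts, best$params, config$max_iter, config$tol,
                   config$cov_reg)
    cont$trace <- c(best$trace, cont$trace[-1])
    best <- cont
  }
  if (!best$converged) warn("EM did not converge within max_iter")

  n_total <- length(emb_valid$valid)
  gamma <- matrix(1 / K, n_total, K)
  gamma[emb_valid$valid, ] <- best$gamma

  structure(list(
    model = list(transition = best$params$transition,
                 initial = best$params$initial,
                 covariances = best$params$covariances,
                 pca = pca, lags = config$lags,
                 loglik_trace = best$trace, converged = best$converged,
                 config = config),
    gamma = gamma,
    path = decode_states(gamma),
    valid = emb_valid$valid,
    index = if (inherits(x, "concat_data")) x$index,
    fs = if (inherits(x, "concat_data")) x$fs
  ), class = "tde_hmm")
}

#' Posterior decoding
#'
#' Assigns each sample to the state with the highest posterior probability;
#' ties are broken towards the lowest state index.
#'
#' @param posterior T x K matrix of state probabilities (or a `tde_hmm`).
#' @return integer vector of state labels.
#' @export
decode_states <- function(posterior) {
  if (inherits(posterior, "tde_hmm")) posterior <- posterior$gamma
  max.col(posterior, ties.method = "first")
}

#' Best label permutation between two state paths
#'
#' Exhaustively finds the relabelling of `b` maximising agreement with `a`
#' (HMM state labels are arbitrary). Suitable for small K.
#'
#' @param a,b integer label vectors of equal length.
#' @param K number of states.
#' @return list with `perm` (`perm[j]` is the `a`-label assigned to `b`-label
#'   `j`) and `agreement` (fraction of samples matching after relabelling).
#' @export
best_label_permutation <- function(a, b, K) {
  stopifnot(length(a) == length(b))
  C <- matrix(0, K, K)
  tab <- table(factor(a, levels = seq_len(K)), factor(b, levels = seq_len(K)))
  C[] <- tab
  perms <- all_permutations(K)
  scores <- vapply(perms, function(p) sum(C[cbind(p, seq_len(K))]), numeric(1))
  best <- which.max(scores)
  list(perm = perms[[best]], agreement = scores[best] / length(a))
}

all_permutations <- function(K) {
  rec <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(rec(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  rec(seq_len(K))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.tde_hmm <- function(x, ...) {
  fs <- x$fs %||% 1
  lt <- state_lifetimes(x$path[x$valid], fs)
  lt_sum <- dplyr::summarise(dplyr::group_by(lt, .data$state),
                             mean_lifetime_s = mean(.data$duration_s),
                             n_visits = dplyr::n())
  out <- tibble(state = seq_len(ncol(x$gamma)),
                fo = colMeans(x$gamma[x$valid, , drop = FALSE]))
  dplyr::left_join(out, lt_sum, by = "state")
}

#' @export
glance.tde_hmm <- function(x, ...) {
  cfg <- x$model$config
  tibble(K = cfg$K, n_lags = length(cfg$lags),
         pca_dim = if (is.null(x$model$pca)) NA_integer_ else ncol(x$model$pca$projection),
         loglik = x$model$loglik_trace[length(x$model$loglik_trace)],
         iterations = length(x$model$loglik_trace),
         converged = x$model$converged)
}

#' @export
print.tde_hmm <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<tde_hmm> K = %d, %d lags, pca_dim = %s, loglik = %.1f (%d EM iterations%s)\n",
              g$K, g$n_lags, as.character(g$pca_dim), g$loglik, g$iterations,
              if (g$converged) ", converged" else ", NOT converged"))
  invisible(x)
}
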