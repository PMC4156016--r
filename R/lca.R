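#' Fitting configuration for the latent class EM algorithm
#'
#' @param n_starts Number of random EM starts; the best final log-likelihood
#'   wins.
#' @param max_iter Maximum EM iterations per start.
#' @param tol Convergence threshold on the absolute change in log-likelihood
#'   between iterations.
#' @param seed Integer seed; identical configuration and data give
#'   bitwise-identical fits.
#' @param prob_floor Smallest allowed probability; estimates are clamped to
#'   `[prob_floor, 1]` and renormalized so the log-likelihood stays finite.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 20L, max_iter = 5000L, tol = 1e-8,
                       seed = 1L, prob_floor = 1e-10) {
  stopifnot(n_starts >= 1, max_iter >= 1, tol > 0, prob_floor > 0)
  structure(list(n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed),
                 prob_floor = prob_floor),
            class = "fit_config")
}

# collapse an integer code matrix to unique response patterns with weights
aggregate_patterns <- function(codes) {
  key <- apply(codes, 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  u_codes <- codes[first, , drop = FALSE]
  w <- as.numeric(table(factor(key, levels = key[first])))
  list(codes = u_codes, w = w, n = nrow(codes))
}

# U x K matrix of log P(pattern_u | class_c) under `rho`; only the small
# K x k_j tables are transposed, the U x K accumulator is indexed row-wise
pattern_loglik <- function(codes, rho, floor) {
  K <- nrow(rho[[1]])
  L <- matrix(0, nrow(codes), K)
  for (j in seq_along(rho)) {
    lr <- t(log(pmax(rho[[j]], floor)))       # k_j x K
    L <- L + lr[codes[, j], , drop = FALSE]
  }
  L
}

# as pattern_loglik but with log(gamma) folded into the initialization
pattern_logjoint <- function(codes, rho, gamma, floor) {
  K <- length(gamma)
  L <- matrix(log(pmax(gamma, floor)), nrow(codes), K, byrow = TRUE)
  for (j in seq_along(rho)) {
    lr <- t(log(pmax(rho[[j]], floor)))
    L <- L + lr[codes[, j], , drop = FALSE]
  }
  L
}

model_dims <- function(spec) spec_nlevels(spec)

check_model_spec <- function(model, spec) {
  kj <- model_dims(spec)
  if (length(model$rho) != length(spec$items) ||
      !all(names(model$rho) == spec$items))
    stop2("model items do not match the indicator spec")
  ok <- vapply(seq_along(kj), function(j)
    nrow(model$rho[[j]]) == model$K && ncol(model$rho[[j]]) == kj[j],
    logical(1))
  if (!all(ok) || length(model$gamma) != model$K)
    stop2("model dimensions do not match the indicator spec")
  invisible(model)
}

#' Observed-data log-likelihood of a latent class model
#'
#' The standard multinomial mixture log-likelihood
#' \eqn{\ell = \sum_i \log \sum_c \gamma_c \prod_j \rho_{j,c,y_{ij}}}.
#' Probabilities are clamped at `prob_floor` before logs are taken, so the
#' result is finite even for boundary estimates.
#'
#' @param data Data frame containing the indicator columns of `spec`.
#' @param model An `lca_model` (or a list with `K`, `gamma`, `rho`).
#' @param spec The [indicator_spec()] the model was built for.
#' @param prob_floor Probability floor (default `1e-10`).
#' @return The log-likelihood (a single number).
#' @export
lca_log_likelihood <- function(data, model, spec, prob_floor = 1e-10) {
  check_model_spec(model, spec)
  codes <- spec_encode(data, spec)
  agg <- aggregate_patterns(codes)
  Lg <- pattern_logjoint(agg$codes, model$rho, model$gamma, prob_floor)
  sum(agg$w * row_logsumexp(Lg))
}

# one EM run from given starting values on aggregated patterns;
# returns params, final ll (evaluated at the returned params), iterations
em_run <- function(agg, ind, gamma, rho, config) {
  floor <- config$prob_floor
  ll_prev <- -Inf
  iter <- 0L
  trace <- numeric(0)
  repeat {
    Lg <- pattern_logjoint(agg$codes, rho, gamma, floor)
    ll_u <- row_logsumexp(Lg)
    ll <- sum(agg$w * ll_u)
    trace <- c(trace, ll)
    if (abs(ll - ll_prev) < config$tol || iter >= config$max_iter) {
      return(list(gamma = gamma, rho = rho, loglik = ll, n_iter = iter,
                  converged = abs(ll - ll_prev) < config$tol,
                  ll_trace = trace))
    }
    ll_prev <- ll
    iter <- iter + 1L
    post <- exp(Lg - ll_u)                    # U x K responsibilities
    wp <- post * agg$w
    class_mass <- colSums(wp)
    gamma <- clamp_vec(class_mass / agg$n, floor)
    for (j in seq_along(rho)) {
      num <- crossprod(wp, ind[[j]])          # K x k_j
      rho[[j]][] <- clamp_rows(num / class_mass, floor)
    }
  }
}

# per-item one-hot indicator matrices for the M-step
indicator_matrices <- function(codes, kj) {
  lapply(seq_along(kj), function(j) {
    m <- matrix(0, nrow(codes), kj[j])
    m[cbind(seq_len(nrow(codes)), codes[, j])] <- 1
    m
  })
}

new_lca_model <- function(K, gamma, rho, loglik, spec, config = NULL,
                          converged = NA, n_iter = NA_integer_, n = NA_integer_) {
  names(gamma) <- paste0("class", seq_len(K))
  for (j in seq_along(rho)) {
    rownames(rho[[j]]) <- names(gamma)
    colnames(rho[[j]]) <- spec$levels[[j]]
  }
  names(rho) <- spec$items
  structure(list(K = K, gamma = gamma, rho = rho, log_likelihood = loglik,
                 spec = spec, config = config, converged = converged,
                 n_iter = n_iter, n = n),
            class = "lca_model")
}

#' Fit a latent class model by EM with multiple random starts
#'
#' Maximum-likelihood estimation of a `K`-class model for categorical
#' indicators under the usual local-independence assumption. Each start draws
#' class prevalences uniformly on the simplex and item-response rows from a
#' symmetric Dirichlet(1); the E-step applies Bayes' rule, the M-step sets
#' prevalences to mean posterior membership and response probabilities to
#' posterior-weighted response frequencies. The run with the best final
#' log-likelihood is returned, with classes relabeled in order of decreasing
#' prevalence. `K = 1` has the closed-form solution (observed marginals) and
#' is computed directly.
#'
#' @param data Data frame with the indicator columns of `spec`.
#' @param K Number of latent classes (>= 1).
#' @param spec An [indicator_spec()].
#' @param config A [fit_config()].
#' @return An object of class `lca_model`: `K`, `gamma` (prevalences, sorted
#'   decreasing), `rho` (per-item class-by-level probability matrices),
#'   `log_likelihood`, `converged`, `n_iter`, `n`, `ll_trace` (the winning
#'   run's per-iteration log-likelihood), plus the spec and config.
#' @export
lca_fit <- function(data, K, spec, config = fit_config()) {
  stopifnot(is_scalar_int(K), K >= 1)
  codes <- spec_encode(data, spec)
  if (nrow(codes) < K) stop2("need at least K observations")
  kj <- model_dims(spec)
  agg <- aggregate_patterns(codes)

  if (K == 1L) {
    # closed form: one class, response probabilities = observed marginals
    rho <- lapply(seq_along(kj), function(j) {
      p <- vapply(seq_len(kj[j]), function(k)
        sum(agg$w[agg$codes[, j] == k]), numeric(1)) / agg$n
      matrix(clamp_vec(p, config$prob_floor), nrow = 1)
    })
    names(rho) <- spec$items
    model <- new_lca_model(1L, 1, rho, NA_real_, spec, config,
                           converged = TRUE, n_iter = 1L, n = agg$n)
    model$log_likelihood <- sum(agg$w * row_logsumexp(
      pattern_loglik(agg$codes, model$rho, config$prob_floor)))
    return(model)
  }

  ind <- indicator_matrices(agg$codes, kj)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) .GlobalEnv$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)
  best <- NULL
  for (s in seq_len(config$n_starts)) {
    gamma0 <- drop(rdirichlet(1, K))
    rho0 <- lapply(kj, function(k) rdirichlet(K, k))
    run <- em_run(agg, ind, gamma0, rho0, config)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  ord <- order(best$gamma, decreasing = TRUE)
  model <- new_lca_model(K, best$gamma[ord],
                         lapply(best$rho, function(m) m[ord, , drop = FALSE]),
                         best$loglik, spec, config,
                         converged = best$converged, n_iter = best$n_iter,
                         n = agg$n)
  model$ll_trace <- best$ll_trace  # per-iteration log-likelihood of best run
  model
}

#' @export
print.lca_model <- function(x, digits = 3, ...) {
  cat("Latent class model: K =", x$K, "classes, n =", x$n, "\n")
  cat("log-likelihood:", format(x$log_likelihood, digits = 8),
      if (isFALSE(x$converged)) "(EM not converged)", "\n")
  cat("class prevalences:\n")
  print(round(x$gamma, digits))
  invisible(x)
}

#' Goodness-of-fit statistics for a fitted latent class model
#'
#' Computes the likelihood-ratio chi-square statistic
#' \eqn{G^2 = 2\sum O \ln(O/E)} over response-pattern cells (cells with zero
#' observed count contribute nothing), the residual degrees of freedom
#' \eqn{(\prod_j k_j - 1) - p}, and information criteria on the
#' \eqn{G^2} scale: \eqn{AIC = G^2 + 2p}, \eqn{BIC = G^2 + p\ln n}, where
#' \eqn{p = (K-1) + K\sum_j (k_j - 1)} is the number of free parameters.
#' These differ from the deviance-scale criteria only by a data-dependent
#' constant that cancels when models on the same data are compared.
#'
#' @param model A fitted `lca_model`.
#' @param data The data the model was fitted on.
#' @param spec The [indicator_spec()].
#' @return A list of class `lca_fit_stats`: `G2`, `df`, `AIC`, `BIC`,
#'   `n_params`, `log_likelihood`, `n`, and `df_unreliable` (TRUE when the
#'   nominal df is negative, i.e. the model is not identified from the
#'   contingency table alone).
#' @export
compute_fit_stats <- function(model, data, spec = model$spec) {
  check_model_spec(model, spec)
  codes <- spec_encode(data, spec)
  agg <- aggregate_patterns(codes)
  floor <- (model$config %||% fit_config())$prob_floor
  Lg <- pattern_logjoint(agg$codes, model$rho, model$gamma, floor)
  ll <- sum(agg$w * row_logsumexp(Lg))
  # saturated log-likelihood: each observed pattern at its empirical freq
  ll_sat <- sum(agg$w * log(agg$w / agg$n))
  G2 <- max(0, 2 * (ll_sat - ll))
  kj <- model_dims(spec)
  n_params <- (model$K - 1L) + model$K * sum(kj - 1L)
  df <- prod(kj) - 1L - n_params
  structure(list(G2 = G2, df = df, AIC = G2 + 2 * n_params,
                 BIC = G2 + log(agg$n) * n_params,
                 n_params = as.integer(n_params),
                 log_likelihood = ll, n = agg$n,
                 df_unreliable = df < 0),
            class = "lca_fit_stats")
}

#' @export
print.lca_fit_stats <- function(x, ...) {
  cat(sprintf("G2 = %.3f on df = %d (p = %d params, n = %d)\n",
              x$G2, x$df, x$n_params, x$n))
  cat(sprintf("AIC = %.3f  BIC = %.3f\n", x$AIC, x$BIC))
  if (x$df_unreliable) cat("note: negative df, model not identified\n")
  invisible(x)
}

#' Sweep over the number of latent classes and select a model
#'
#' Fits models for each `K` in `k_range`, starting from the one-class model,
#' and tabulates log-likelihood, G2, df, AIC and BIC. The selected model
#' minimizes BIC by default (AIC optional); rows whose nominal df is negative
#' are retained but flagged.
#'
#' @param data Data frame with the indicator columns of `spec`.
#' @param spec An [indicator_spec()].
#' @param k_range Integer vector of class counts to try, e.g. `1:8`.
#' @param config A [fit_config()]; each `K` derives its start seed from
#'   `config$seed` so the sweep is reproducible.
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @return A list of class `lca_sweep`: `table` (one row per `K`),
#'   `selected_k`, `selected_model`, `models` (all fits), `criterion`.
#' @export
select_model <- function(data, spec, k_range, config = fit_config(),
                         criterion = c("BIC", "AIC")) {
  criterion <- match.arg(criterion)
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(all(k_range >= 1))
  models <- list()
  rows <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    cfg_k <- config
    cfg_k$seed <- config$seed + K
    fit <- lca_fit(data, K, spec, cfg_k)
    st <- compute_fit_stats(fit, data, spec)
    models[[as.character(K)]] <- fit
    rows[[i]] <- data.frame(K = K, log_likelihood = fit$log_likelihood,
                            G2 = st$G2, df = st$df, AIC = st$AIC,
                            BIC = st$BIC, n_params = st$n_params,
                            df_unreliable = st$df_unreliable,
                            converged = fit$converged)
  }
  tab <- do.call(rbind, rows)
  sel <- tab$K[which.min(tab[[criterion]])]
  structure(list(table = tab, selected_k = sel,
                 selected_model = models[[as.character(sel)]],
                 models = models, criterion = criterion),
            class = "lca_sweep")
}

#' @export
print.lca_sweep <- function(x, ...) {
  cat("Latent class sweep (selected K =", x$selected_k, "by",
      x$criterion, "):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Posterior class membership and modal assignment
#'
#' Bayes-rule posterior probabilities of class membership for each row of
#' `data` under a fitted model, plus the modal (highest-posterior) class.
#' Posterior ties break toward the lowest class index.
#'
#' @param model A fitted `lca_model`.
#' @param data Data frame with the indicator columns of `spec`.
#' @param spec The [indicator_spec()].
#' @return A list of class `lca_posterior`: `posterior` (n x K matrix, rows
#'   summing to 1) and `modal_class` (integer vector).
#' @export
posterior_classify <- function(model, data, spec = model$spec) {
  check_model_spec(model, spec)
  codes <- spec_encode(data, spec)
  floor <- (model$config %||% fit_config())$prob_floor
  Lg <- pattern_logjoint(codes, model$rho, model$gamma, floor)
  post <- exp(Lg - row_logsumexp(Lg))
  colnames(post) <- names(model$gamma)
  structure(list(posterior = post,
                 modal_class = max.col(post, ties.method = "first")),
            class = "lca_posterior")
}

# all permutations of 1..k (k! rows); used for optimal label alignment
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
          if (pos <= k - 1L) sub[, pos:(k - 1L), drop = FALSE])
  }))
}

#' Resolve label switching between two latent class models
#'
#' Latent class labels are arbitrary; to compare a refitted model with a
#' reference (e.g. the generating truth in a recovery study) the classes
#' must first be matched. This returns the permutation `p` minimizing the
#' total L1 distance between item-response tables, found by exhaustive search
#' over all `K!` permutations, so that candidate class `p[c]` corresponds to
#' reference class `c`.
#'
#' @param reference,candidate `lca_model` objects (or lists with `K` and
#'   `rho`) with identical `K` and indicator structure.
#' @return Integer permutation of `1:K` with attribute `"distance"` (the
#'   minimized total L1 distance).
#' @seealso [permute_classes()]
#' @export
align_classes <- function(reference, candidate) {
  if (reference$K != candidate$K)
    stop2("models have different numbers of classes")
  K <- reference$K
  if (K > 8L) stop2("exhaustive alignment supported for K <= 8")
  # cost[c, d] = L1 distance between reference class c and candidate class d
  cost <- matrix(0, K, K)
  for (j in seq_along(reference$rho)) {
    rr <- reference$rho[[j]]
    rc <- candidate$rho[[j]]
    for (cc in seq_len(K))
      cost[cc, ] <- cost[cc, ] +
        colSums(abs(t(rc) - rr[cc, ]))
  }
  perms <- all_permutations(K)
  total <- vapply(seq_len(nrow(perms)), function(r)
    sum(cost[cbind(seq_len(K), perms[r, ])]), numeric(1))
  best <- perms[which.min(total), ]
  attr(best, "distance") <- min(total)
  best
}

#' Reorder the classes of a latent class model
#'
#' @param model An `lca_model`.
#' @param perm Integer permutation of `1:K`; class `i` of the result is class
#'   `perm[i]` of `model` (as returned by [align_classes()]).
#' @return The relabeled model.
#' @export
permute_classes <- function(model, perm) {
  stopifnot(length(perm) == model$K, setequal(perm, seq_len(model$K)))
  model$gamma <- model$gamma[perm]
  model$rho <- lapply(model$rho, function(m) m[perm, , drop = FALSE])
  model
}
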