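#' Generative label model
#'
#' Aggregates the noisy LF votes into one probabilistic frame-element label
#' per candidate pair by estimating the unobserved accuracy of each LF. The
#' model is a one-coin Dawid-Skene-style conditional-independence model: a
#' latent true label per pair drawn from class priors, and each non-abstaining
#' LF voting the true label with its own accuracy or a uniformly chosen wrong
#' label otherwise. Fitting is by EM with a pseudo-count pull of every
#' accuracy toward `precision_init`, controlled by `l2`.
#'
#' @name radspatial-labelmodel
NULL

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

votes_matrix <- function(votes) {
  v <- if (inherits(votes, "rs_votes")) votes$votes else votes
  if (!is.matrix(v)) stop("votes must be an rs_votes object or a matrix")
  v
}

# integer coding: 0 = abstain, 1..9 = fe_labels() index
code_votes <- function(v) {
  labs <- fe_labels()
  m <- matrix(match(v, labs), nrow = nrow(v), ncol = ncol(v))
  bad <- !is.na(v) & is.na(m)
  if (any(bad)) stop("unknown label in vote matrix: ",
                     paste(unique(v[bad]), collapse = ", "))
  m[is.na(m)] <- 0L
  m
}

#' Label-model configuration
#'
#' Hyperparameters follow the tuned values of the reference pipeline:
#' `epochs` 100 (maximum EM iterations), `l2` 0.01 (pseudo-count strength of
#' the pull toward `precision_init`), `precision_init` 0.7 (accuracy
#' initialization and prior center), `tol` 1e-6 (parameter-change stopping
#' rule). `learning_rate` is retained for interface parity with SGD-trained
#' implementations; the EM backend does not use it.
#'
#' @param epochs maximum EM iterations.
#' @param learning_rate unused by the EM backend; kept in the config.
#' @param l2 regularization strength (pseudo-count fraction).
#' @param precision_init initial/prior LF accuracy in (0, 1).
#' @param seed stored with the fit for provenance (EM itself is
#'   deterministic).
#' @param tol convergence tolerance on the maximum parameter change.
#' @param estimate_priors re-estimate the class priors inside EM instead of
#'   keeping them fixed uniform. Off by default: with target-pure LFs whose
#'   frame element is covered by a single heuristic, freely estimated priors
#'   admit a label-switching degeneracy (the rare class's prior and its LF's
#'   accuracy spiral to zero together); a fixed uniform class balance — also
#'   the default of SGD-trained data-programming label models — removes it.
#' @return list of class `rs_lm_config`.
#' @export
label_model_config <- function(epochs = 100L, learning_rate = 1e-4,
                               l2 = 0.01, precision_init = 0.7, seed = 1L,
                               tol = 1e-6, estimate_priors = FALSE) {
  stopifnot(epochs >= 1, precision_init > 0, precision_init < 1, l2 >= 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 l2 = l2, precision_init = precision_init,
                 seed = as.integer(seed), tol = tol,
                 estimate_priors = isTRUE(estimate_priors)),
            class = "rs_lm_config")
}

# row posteriors under (alpha, prior); returns list(post n x 9, loglik)
lm_posterior <- function(V, alpha, prior) {
  n <- nrow(V); K <- length(prior)
  logA <- log(alpha)
  logB <- log((1 - alpha) / (K - 1))
  lp <- matrix(rep(log(prior), each = n), nrow = n)
  voted <- V != 0L
  for (k in seq_len(K)) {
    agree <- (V == k)
    lp[, k] <- lp[, k] + agree %*% logA + (voted & !agree) %*% logB
  }
  mx <- apply(lp, 1, max)
  w <- exp(lp - mx)
  s <- rowSums(w)
  list(post = w / s, loglik = sum((log(s) + mx)[rowSums(voted) > 0]))
}

#' Majority-vote baseline aggregator
#'
#' Per pair, the label distribution is proportional to the vote counts;
#' all-abstain rows are flagged `abstained`. Argmax ties break by the fixed
#' label enum order.
#'
#' @param votes an `rs_votes` or character vote matrix.
#' @return data.frame with `label`, `prob`, `abstained`; the full n x 9
#'   distribution matrix is attached as attribute `"distribution"`.
#' @export
fit_majority <- function(votes) {
  v <- votes_matrix(votes)
  V <- code_votes(v)
  labs <- fe_labels()
  K <- length(labs)
  n <- nrow(V)
  dist <- matrix(0, n, K, dimnames = list(NULL, labs))
  for (k in seq_len(K)) dist[, k] <- rowSums(V == k)
  tot <- rowSums(dist)
  abst <- tot == 0
  dist[!abst, ] <- dist[!abst, , drop = FALSE] / tot[!abst]
  dist[abst, ] <- 1 / K
  arg <- apply(dist, 1, which.max)   # which.max breaks ties by first index
  out <- data.frame(label = labs[arg],
                    prob = dist[cbind(seq_len(max(n, 0)), arg)],
                    abstained = abst, stringsAsFactors = FALSE)
  if (n == 0) out <- data.frame(label = character(), prob = numeric(),
                                abstained = logical())
  attr(out, "distribution") <- dist
  out
}

#' Fit the generative label model
#'
#' EM for the one-coin model. E-step: posterior over the true label per pair
#' from the current accuracies and priors. M-step: each LF accuracy becomes
#' (expected correct votes + l2 * precision_init * n_j) / (n_j + l2 * n_j)
#' where n_j is the LF's non-abstain count, and priors become the mean
#' posterior. Accuracies start at `precision_init`, priors uniform. Stops
#' after `epochs` iterations or when the maximum parameter change drops
#' below `tol`. The penalized log-likelihood is recorded per iteration and is
#' non-decreasing.
#'
#' @param votes an `rs_votes` or character vote matrix (`NA` = abstain);
#'   must contain at least one non-abstain cell.
#' @param config an `rs_lm_config`.
#' @return an object of class `felabel_model` with components `accuracy`
#'   (per-LF), `prior` (per-label), `loglik` (trace), `n_iter`, `converged`,
#'   `config`, `lf_names`.
#' @export
fit_label_model <- function(votes, config = label_model_config()) {
  v <- votes_matrix(votes)
  if (nrow(v) < 1) stop("cannot fit label model on an empty vote matrix")
  V <- code_votes(v)
  if (all(V == 0L)) stop("cannot fit label model: all labeling functions abstain")
  labs <- fe_labels()
  K <- length(labs)
  m <- ncol(V)
  nj <- colSums(V != 0L)
  alpha <- rep(config$precision_init, m)
  prior <- rep(1 / K, K)
  eps <- 1e-6
  # pseudo-counts implementing the pull toward precision_init
  a_j <- config$l2 * config$precision_init * nj
  b_j <- config$l2 * (1 - config$precision_init) * nj
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  active <- rowSums(V != 0L) > 0
  for (it in seq_len(config$epochs)) {
    iter <- it
    es <- lm_posterior(V, alpha, prior)
    pen <- sum(a_j * log(alpha) + b_j * log(1 - alpha))
    ll_trace <- c(ll_trace, es$loglik + pen)
    correct <- vapply(seq_len(m), function(j) {
      idx <- which(V[, j] != 0L)
      if (length(idx) == 0) return(0)
      sum(es$post[cbind(idx, V[idx, j])])
    }, numeric(1))
    new_alpha <- ifelse(nj > 0, (correct + a_j) / (nj + config$l2 * nj),
                        config$precision_init)
    new_alpha <- pmin(pmax(new_alpha, eps), 1 - eps)
    if (config$estimate_priors) {
      new_prior <- colSums(es$post[active, , drop = FALSE])
      new_prior <- pmax(new_prior / sum(new_prior), 1e-12)
      new_prior <- new_prior / sum(new_prior)
    } else {
      new_prior <- prior
    }
    delta <- max(abs(new_alpha - alpha), abs(new_prior - prior))
    alpha <- new_alpha
    prior <- new_prior
    if (delta < config$tol) { converged <- TRUE; break }
  }
  lf_names <- colnames(v)
  if (is.null(lf_names)) lf_names <- paste0("lf", seq_len(m))
  structure(list(accuracy = stats::setNames(alpha, lf_names),
                 prior = stats::setNames(prior, labs),
                 loglik = ll_trace, n_iter = iter, converged = converged,
                 config = config, lf_names = lf_names),
            class = "felabel_model")
}

#' @export
print.felabel_model <- function(x, digits = 3, ...) {
  cat("Generative label model (one-coin EM)\n")
  cat("  LFs:", length(x$accuracy), " iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(max epochs)", "\n")
  cat("  penalized log-likelihood:",
      format(x$loglik[length(x$loglik)], digits = digits + 3), "\n")
  cat("  estimated LF accuracies:\n")
  print(round(x$accuracy, digits))
  cat("  class priors:\n")
  print(round(x$prior, digits))
  invisible(x)
}

#' @export
coef.felabel_model <- function(object, ...) object$accuracy

#' @export
summary.felabel_model <- function(object, ...) {
  structure(list(model = object), class = "summary.felabel_model")
}

#' @export
print.summary.felabel_model <- function(x, ...) print(x$model)

#' Predict probabilistic labels
#'
#' Posterior distribution over the nine frame elements per candidate pair
#' under a fitted model. All-abstain rows are flagged `abstained` and carry
#' the class prior as their distribution. Argmax ties break by the label
#' enum order.
#'
#' @param object a fitted `felabel_model`.
#' @param votes an `rs_votes` or character vote matrix with the same LF
#'   columns the model was fitted on.
#' @param ... unused.
#' @return data.frame with `label`, `prob`, `abstained`; distribution matrix
#'   in attribute `"distribution"`.
#' @export
predict.felabel_model <- function(object, votes, ...) {
  v <- votes_matrix(votes)
  if (ncol(v) != length(object$accuracy))
    stop("vote matrix has ", ncol(v), " columns but the model was fitted on ",
         length(object$accuracy))
  if (!is.null(colnames(v)) &&
      !identical(colnames(v), object$lf_names))
    stop("vote matrix columns do not match the fitted labeling functions")
  labs <- fe_labels()
  if (nrow(v) == 0)
    return(structure(data.frame(label = character(), prob = numeric(),
                                abstained = logical()),
                     distribution = matrix(0, 0, length(labs),
                                           dimnames = list(NULL, labs))))
  V <- code_votes(v)
  es <- lm_posterior(V, object$accuracy, object$prior)
  dist <- es$post
  colnames(dist) <- labs
  abst <- rowSums(V != 0L) == 0
  dist[abst, ] <- rep(object$prior, each = sum(abst))
  arg <- apply(dist, 1, which.max)
  out <- data.frame(label = labs[arg],
                    prob = dist[cbind(seq_len(nrow(dist)), arg)],
                    abstained = abst, stringsAsFactors = FALSE)
  attr(out, "distribution") <- dist
  out
}

#' Simulate labeling-function votes
#'
#' Test oracle for the label model: draws true labels from `priors`; each LF
#' abstains with its abstain rate, otherwise votes the true label with its
#' accuracy or a uniformly chosen wrong label.
#'
#' @param n number of candidate rows.
#' @param accuracies per-LF accuracies in (0, 1).
#' @param abstain_rates per-LF abstain probabilities in [0, 1).
#' @param priors distribution over the nine labels.
#' @param seed RNG seed (reproducible; the caller's RNG state is untouched).
#' @return list with `votes` (character matrix with `NA` abstains) and
#'   `truth` (character vector of true labels).
#' @export
simulate_votes <- function(n, accuracies, abstain_rates,
                           priors = rep(1 / 9, 9), seed = 1L) {
  m <- length(accuracies)
  stopifnot(length(abstain_rates) == m)
  if (any(accuracies <= 0 | accuracies >= 1))
    stop("accuracies must lie in (0, 1)")
  if (any(abstain_rates < 0 | abstain_rates >= 1))
    stop("abstain rates must lie in [0, 1)")
  labs <- fe_labels()
  if (length(priors) != length(labs) || any(priors < 0) ||
      abs(sum(priors) - 1) > 1e-8)
    stop("priors must be a distribution over the nine labels")
  with_seed(seed, {
    truth_idx <- sample.int(length(labs), n, replace = TRUE, prob = priors)
    votes <- matrix(NA_character_, n, m,
                    dimnames = list(NULL, paste0("lf", seq_len(m))))
    for (j in seq_len(m)) {
      speaks <- stats::runif(n) >= abstain_rates[j]
      correct <- stats::runif(n) < accuracies[j]
      wrong <- vapply(truth_idx, function(k)
        sample(setdiff(seq_along(labs), k), 1L), integer(1))
      vote_idx <- ifelse(correct, truth_idx, wrong)
      votes[speaks, j] <- labs[vote_idx[speaks]]
    }
    list(votes = votes, truth = labs[truth_idx])
  })
}
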