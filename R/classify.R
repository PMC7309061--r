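## Classification layer: base-learner registry behind a predict_proba
## contract, AdaBoost.M1, 13-member probability fusion, metric suite,
## cross-validation and feature selection.

CLASS_LEVELS <- c("0", "1")

#' Base learner specification
#'
#' @param name learner name; one of the registry entries
#'   (`svm_linear`, `svm_rbf`, `svm_sigmoid`, `smo`, `knn`, `random_forest`,
#'   `mlp`, `decision_stump`, `lwl`, `bayes_net`, `naive_bayes`, `j48_tree`,
#'   `lmt`, `flda`, `lda`, `logistic`, `voted_perceptron`, `sgd_linear`,
#'   `lstm_seq`).
#' @param hyper named list of hyperparameters (learner-specific).
#' @param pca_vc optional PCA preprocessor: retain the minimal leading
#'   components reaching this cumulative explained-variance fraction.
#' @return list of class `cogscreen_spec`.
#' @export
base_learner_spec <- function(name, hyper = list(), pca_vc = NULL) {
  if (!name %in% names(learner_registry()))
    abort_validation(sprintf("unknown learner '%s'", name))
  if (!is.null(pca_vc) && (pca_vc <= 0 || pca_vc > 1))
    abort_validation("pca_vc must be in (0, 1]")
  structure(list(name = name, hyper = hyper, pca_vc = pca_vc),
            class = "cogscreen_spec")
}

# registry: fit(X, y, w, hyper, seed) -> fit object;
# prob(fit, X) -> n x 2 matrix; weights: native case-weight support
learner_registry <- function() list(
  svm_linear = list(weights = FALSE, fit = function(X, y, w, h, seed)
    svm_fit(X, y, kernel = "linear", h), prob = svm_prob),
  svm_rbf = list(weights = FALSE, fit = function(X, y, w, h, seed)
    svm_fit(X, y, kernel = "radial", h), prob = svm_prob),
  svm_sigmoid = list(weights = FALSE, fit = function(X, y, w, h, seed)
    svm_fit(X, y, kernel = "sigmoid", h), prob = svm_prob),
  smo = list(weights = FALSE, fit = fit_smo, prob = prob_smo),
  knn = list(weights = FALSE, fit = fit_knn, prob = prob_knn),
  random_forest = list(weights = FALSE, fit = function(X, y, w, h, seed) {
    set.seed(seed)
    randomForest::randomForest(X, factor(y, CLASS_LEVELS),
                               ntree = h$ntree %||% 200)
  }, prob = function(f, X) unclass(stats::predict(f, X, type = "prob"))),
  mlp = list(weights = TRUE, fit = fit_mlp, prob = prob_mlp),
  decision_stump = list(weights = TRUE, fit = function(X, y, w, h, seed)
    fit_rpart(X, y, w, maxdepth = 1), prob = prob_rpart),
  j48_tree = list(weights = TRUE, fit = function(X, y, w, h, seed)
    fit_rpart(X, y, w, maxdepth = h$maxdepth %||% 30, cp = h$cp %||% 0.01),
    prob = prob_rpart),
  lwl = list(weights = FALSE, fit = fit_lwl, prob = prob_lwl),
  bayes_net = list(weights = FALSE, fit = function(X, y, w, h, seed)
    fit_gnb(X, y, var_floor = h$var_floor %||% 1e-3), prob = prob_gnb),
  naive_bayes = list(weights = FALSE, fit = function(X, y, w, h, seed)
    e1071::naiveBayes(X, factor(y, CLASS_LEVELS)),
    prob = function(f, X) unclass(stats::predict(f, X, type = "raw"))),
  lmt = list(weights = FALSE, fit = fit_lmt, prob = prob_lmt),
  flda = list(weights = FALSE, fit = fit_flda, prob = prob_flda),
  lda = list(weights = FALSE, fit = function(X, y, w, h, seed)
    MASS::lda(X, grouping = factor(y, CLASS_LEVELS)),
    prob = function(f, X) {
      p <- stats::predict(f, X)$posterior
      p[, CLASS_LEVELS, drop = FALSE]
    }),
  logistic = list(weights = TRUE, fit = fit_logistic, prob = prob_logistic),
  voted_perceptron = list(weights = FALSE, fit = fit_voted_perceptron,
                          prob = prob_voted_perceptron),
  sgd_linear = list(weights = FALSE, fit = fit_sgd, prob = prob_sgd),
  lstm_seq = list(weights = FALSE, fit = fit_lstm_tabular, prob = prob_lstm_tabular)
)

## ---- individual learners -------------------------------------------------

svm_fit <- function(X, y, kernel, h) {
  f <- factor(y, CLASS_LEVELS)
  fit <- tryCatch(
    e1071::svm(X, f, kernel = kernel, probability = TRUE,
               cost = h$cost %||% 1, gamma = h$gamma %||% (1 / ncol(X))),
    error = function(e) NULL)
  if (is.null(fit) || is.null(attr(stats::predict(fit, X[1, , drop = FALSE],
                                                  probability = TRUE), "probabilities"))) {
    # probability model can fail on tiny folds; calibrate decision values
    fit <- e1071::svm(X, f, kernel = kernel,
                      cost = h$cost %||% 1, gamma = h$gamma %||% (1 / ncol(X)))
    attr(fit, "platt") <- TRUE
  }
  fit
}

svm_prob <- function(fit, X) {
  if (isTRUE(attr(fit, "platt"))) {
    d <- as.numeric(attr(stats::predict(fit, X, decision.values = TRUE),
                         "decision.values"))
    lev <- strsplit(colnames(attr(stats::predict(fit, X[1, , drop = FALSE],
                                                 decision.values = TRUE),
                                  "decision.values")), "/")[[1]]
    p_first <- 1 / (1 + exp(-3 * d))
    p <- cbind(p_first, 1 - p_first)
    colnames(p) <- lev
    return(p[, CLASS_LEVELS, drop = FALSE])
  }
  pr <- attr(stats::predict(fit, X, probability = TRUE), "probabilities")
  pr[, CLASS_LEVELS, drop = FALSE]
}

# sequential-minimal-optimization linear SVM. libsvm (e1071) trains by an
# SMO-type decomposition; kernlab::ksvm is the alternative backend for
# non-default kernels via hyper$backend = "kernlab".
fit_smo <- function(X, y, w, h, seed) {
  set.seed(seed)
  if (identical(h$backend, "kernlab")) {
    fit <- tryCatch(
      kernlab::ksvm(X, factor(y, CLASS_LEVELS), kernel = "vanilladot",
                    prob.model = TRUE, C = h$C %||% 1, kpar = list()),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  # single SMO solve; probabilities by a fixed sigmoid on decision values
  # (libsvm's probability model would re-solve five internal CV folds)
  fit <- e1071::svm(X, factor(y, CLASS_LEVELS), kernel = "linear",
                    cost = h$C %||% 1, tolerance = h$tolerance %||% 0.01)
  attr(fit, "platt") <- TRUE
  fit
}

prob_smo <- function(fit, X) {
  if (inherits(fit, "svm")) return(svm_prob(fit, X))
  p <- tryCatch(kernlab::predict(fit, X, type = "probabilities"),
                error = function(e) NULL)
  if (is.null(p)) {
    d <- as.numeric(kernlab::predict(fit, X, type = "decision"))
    lev <- kernlab::lev(fit)
    p1 <- 1 / (1 + exp(-3 * d))
    p <- cbind(p1, 1 - p1); colnames(p) <- lev
  }
  p[, CLASS_LEVELS, drop = FALSE]
}

standardizer <- function(X) {
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv,
       apply = function(Z) sweep(sweep(Z, 2, mu), 2, sdv, `/`))
}

fit_knn <- function(X, y, w, h, seed) {
  st <- standardizer(X)
  list(X = st$apply(X), y = y, k = h$k %||% 5L, st = st)
}

prob_knn <- function(fit, X) {
  Z <- fit$st$apply(X)
  k <- min(fit$k, length(fit$y))
  t(apply(Z, 1, function(z) {
    d <- sqrt(colSums((t(fit$X) - z)^2))
    nn <- order(d)[seq_len(k)]
    p1 <- mean(fit$y[nn] == 1)
    c(`0` = 1 - p1, `1` = p1)
  }))
}

fit_lwl <- function(X, y, w, h, seed) {
  st <- standardizer(X)
  Z <- st$apply(X)
  bw <- stats::median(stats::dist(Z[sample.int(nrow(Z), min(60, nrow(Z))), ,
                                    drop = FALSE]))
  if (!is.finite(bw) || bw <= 0) bw <- 1
  list(X = Z, y = y, bw = bw * (h$bw_scale %||% 0.5), st = st)
}

prob_lwl <- function(fit, X) {
  Z <- fit$st$apply(X)
  t(apply(Z, 1, function(z) {
    d2 <- colSums((t(fit$X) - z)^2)
    w <- exp(-d2 / (2 * fit$bw^2))
    if (sum(w) <= 0) w <- rep(1, length(w))
    p1 <- sum(w * (fit$y == 1)) / sum(w)
    c(`0` = 1 - p1, `1` = p1)
  }))
}

fit_mlp <- function(X, y, w, h, seed) {
  set.seed(seed)
  st <- standardizer(X)
  fit <- nnet::nnet(st$apply(X), as.numeric(y == 1),
                    size = h$size %||% 8, decay = h$decay %||% 1e-3,
                    maxit = h$maxit %||% 150, trace = FALSE, MaxNWts = 20000,
                    weights = if (is.null(w)) rep(1, length(y)) else w * length(y))
  list(net = fit, st = st)
}

prob_mlp <- function(fit, X) {
  p1 <- as.numeric(stats::predict(fit$net, fit$st$apply(X)))
  p1 <- pmin(1 - 1e-12, pmax(1e-12, p1))
  cbind(`0` = 1 - p1, `1` = p1)
}

fit_rpart <- function(X, y, w, maxdepth, cp = 0) {
  df <- data.frame(.y = factor(y, CLASS_LEVELS), X, check.names = FALSE)
  rpart::rpart(.y ~ ., df, weights = if (is.null(w)) rep(1, length(y)) else w * length(y),
               method = "class",
               control = rpart::rpart.control(maxdepth = maxdepth, cp = cp,
                                              minsplit = 2, xval = 0))
}

prob_rpart <- function(fit, X) {
  p <- stats::predict(fit, data.frame(X, check.names = FALSE), type = "prob")
  p[, CLASS_LEVELS, drop = FALSE]
}

fit_gnb <- function(X, y, var_floor = 1e-3) {
  cls <- lapply(c(0, 1), function(c) {
    Z <- X[y == c, , drop = FALSE]
    list(mu = colMeans(Z),
         var = pmax(apply(Z, 2, stats::var), var_floor),
         prior = nrow(Z) / nrow(X))
  })
  names(cls) <- CLASS_LEVELS
  cls
}

prob_gnb <- function(fit, X) {
  ll <- vapply(fit, function(cl) {
    rowSums(sweep(-(sweep(X, 2, cl$mu))^2, 2, 2 * cl$var, `/`) -
              matrix(0.5 * log(2 * pi * cl$var), nrow(X), ncol(X), byrow = TRUE)) +
      log(cl$prior)
  }, numeric(nrow(X)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  m <- apply(ll, 1, max)
  p <- exp(ll - m)
  p / rowSums(p)
}

fit_logistic <- function(X, y, w, h, seed) {
  df <- data.frame(.y = as.numeric(y == 1), X, check.names = FALSE)
  suppressWarnings(stats::glm(.y ~ ., binomial(), df,
                              weights = if (is.null(w)) NULL else w * length(y)))
}

prob_logistic <- function(fit, X) {
  p1 <- stats::predict(fit, data.frame(X, check.names = FALSE), type = "response")
  p1 <- pmin(1 - 1e-12, pmax(1e-12, as.numeric(p1)))
  cbind(`0` = 1 - p1, `1` = p1)
}

# logistic-model-tree: shallow rpart partition with a logistic model per leaf
fit_lmt <- function(X, y, w, h, seed) {
  tree <- fit_rpart(X, y, w, maxdepth = h$maxdepth %||% 2)
  leaves <- stats::predict(tree, data.frame(X, check.names = FALSE), type = "vector")
  leaf_ids <- unique(leaves)
  models <- lapply(leaf_ids, function(l) {
    idx <- which(leaves == l)
    if (length(unique(y[idx])) < 2 || length(idx) < 8)
      return(list(const = mean(y[idx] == 1)))
    list(glm = suppressWarnings(fit_logistic(X[idx, , drop = FALSE], y[idx], NULL, h, seed)))
  })
  names(models) <- as.character(leaf_ids)
  list(tree = tree, models = models)
}

prob_lmt <- function(fit, X) {
  leaves <- stats::predict(fit$tree, data.frame(X, check.names = FALSE), type = "vector")
  p1 <- numeric(nrow(X))
  for (l in unique(leaves)) {
    idx <- which(leaves == l)
    m <- fit$models[[as.character(l)]]
    p1[idx] <- if (!is.null(m$const)) m$const
               else prob_logistic(m$glm, X[idx, , drop = FALSE])[, "1"]
  }
  p1 <- pmin(1 - 1e-12, pmax(1e-12, p1))
  cbind(`0` = 1 - p1, `1` = p1)
}

# Fisher's linear discriminant: pooled within-class scatter direction with
# 1-D Gaussian class-conditionals on the projection
fit_flda <- function(X, y, w, h, seed) {
  st <- standardizer(X)
  Z <- st$apply(X)
  z0 <- Z[y == 0, , drop = FALSE]; z1 <- Z[y == 1, , drop = FALSE]
  sw <- crossprod(sweep(z0, 2, colMeans(z0))) + crossprod(sweep(z1, 2, colMeans(z1)))
  sw <- sw + diag(1e-3 * mean(diag(sw)) + 1e-8, ncol(Z))
  wvec <- solve(sw, colMeans(z1) - colMeans(z0))
  proj <- as.numeric(Z %*% wvec)
  list(st = st, w = wvec,
       g0 = list(mu = mean(proj[y == 0]), sd = max(stats::sd(proj[y == 0]), 1e-6),
                 prior = mean(y == 0)),
       g1 = list(mu = mean(proj[y == 1]), sd = max(stats::sd(proj[y == 1]), 1e-6),
                 prior = mean(y == 1)))
}

prob_flda <- function(fit, X) {
  proj <- as.numeric(fit$st$apply(X) %*% fit$w)
  ll0 <- stats::dnorm(proj, fit$g0$mu, fit$g0$sd, log = TRUE) + log(fit$g0$prior)
  ll1 <- stats::dnorm(proj, fit$g1$mu, fit$g1$sd, log = TRUE) + log(fit$g1$prior)
  m <- pmax(ll0, ll1)
  p0 <- exp(ll0 - m); p1 <- exp(ll1 - m)
  cbind(`0` = p0 / (p0 + p1), `1` = p1 / (p0 + p1))
}

fit_voted_perceptron <- function(X, y, w, h, seed) {
  set.seed(seed)
  st <- standardizer(X)
  Z <- cbind(1, st$apply(X))
  yy <- ifelse(y == 1, 1, -1)
  epochs <- h$epochs %||% 10
  wk <- numeric(ncol(Z)); surv <- 0
  ws <- list(); cs <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nrow(Z))
    for (i in ord) {
      if (yy[i] * sum(wk * Z[i, ]) <= 0) {
        ws[[length(ws) + 1]] <- wk; cs <- c(cs, surv)
        wk <- wk + yy[i] * Z[i, ]; surv <- 1
      } else surv <- surv + 1
    }
  }
  ws[[length(ws) + 1]] <- wk; cs <- c(cs, surv)
  keep <- cs > 0
  list(st = st, W = do.call(rbind, ws[keep]), c = cs[keep])
}

prob_voted_perceptron <- function(fit, X) {
  Z <- cbind(1, fit$st$apply(X))
  score <- colSums(sign(fit$W %*% t(Z)) * fit$c) / sum(fit$c)
  p1 <- 1 / (1 + exp(-3 * score))
  cbind(`0` = 1 - p1, `1` = p1)
}

fit_sgd <- function(X, y, w, h, seed) {
  set.seed(seed)
  st <- standardizer(X)
  Z <- cbind(1, st$apply(X))
  yy <- as.numeric(y == 1)
  beta <- numeric(ncol(Z))
  lr <- h$lr %||% 0.05; epochs <- h$epochs %||% 30; lambda <- h$lambda %||% 1e-4
  for (ep in seq_len(epochs)) {
    for (i in sample.int(nrow(Z))) {
      p <- 1 / (1 + exp(-sum(beta * Z[i, ])))
      beta <- beta + lr * ((yy[i] - p) * Z[i, ] - lambda * beta)
    }
  }
  list(st = st, beta = beta)
}

prob_sgd <- function(fit, X) {
  p1 <- 1 / (1 + exp(-as.numeric(cbind(1, fit$st$apply(X)) %*% fit$beta)))
  cbind(`0` = 1 - p1, `1` = p1)
}

# tabular adapter for the recurrent sequence learner: rows as 1-step sequences
fit_lstm_tabular <- function(X, y, w, h, seed) {
  seqs <- lapply(seq_len(nrow(X)), function(i) X[i, , drop = FALSE])
  train_sequence_classifier(seqs, y, units = h$units %||% 100,
                            epochs = h$epochs %||% 10, seed = seed)
}

prob_lstm_tabular <- function(fit, X) {
  seqs <- lapply(seq_len(nrow(X)), function(i) X[i, , drop = FALSE])
  predict_sequence_proba(fit, seqs)
}

## ---- train/predict contract ---------------------------------------------

apply_pca <- function(pca, X) {
  stats::predict(pca$rot, X[, pca$keep, drop = FALSE])[, seq_len(pca$ncomp), drop = FALSE]
}

#' Train a base learner
#'
#' Fits the named learner (optionally behind its PCA preprocessor) and
#' returns a model exposing the per-class probability contract:
#' probabilities are non-negative and sum to 1 for every instance.
#'
#' @param spec a [base_learner_spec()].
#' @param X numeric feature matrix (finite after imputation).
#' @param y binary labels (0 healthy, 1 impaired).
#' @param weights optional instance weights (used natively where the
#'   learner supports them).
#' @param seed RNG seed for stochastic learners.
#' @return object of class `cogscreen_model`.
#' @export
train_base <- function(spec, X, y, weights = NULL, seed = 1L) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort_validation("training labels contain a single class")
  if (any(!is.finite(X))) abort_validation("X must be finite after imputation")
  pca <- NULL
  if (!is.null(spec$pca_vc)) {
    keep <- which(apply(X, 2, stats::sd) > 0)
    rot <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
    cum <- cumsum(rot$sdev^2) / sum(rot$sdev^2)
    pca <- list(rot = rot, keep = keep,
                ncomp = max(1L, which(cum >= spec$pca_vc)[1]))
    X <- apply_pca(pca, X)
  }
  entry <- learner_registry()[[spec$name]]
  fit <- entry$fit(X, y, weights, spec$hyper, seed)
  structure(list(spec = spec, fit = fit, pca = pca, entry_name = spec$name),
            class = "cogscreen_model")
}

#' Per-class probabilities from any fitted model
#'
#' @param model a fitted `cogscreen_model`, `cogscreen_boost`,
#'   `cogscreen_ensemble` or sequence/WST model.
#' @param X feature matrix (or sequences/clips for the sequence models).
#' @return matrix `n x 2` with columns `"0"` and `"1"` summing to 1.
#' @export
predict_proba <- function(model, X) UseMethod("predict_proba")

#' @export
predict_proba.cogscreen_model <- function(model, X) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  if (!is.null(model$pca)) X <- apply_pca(model$pca, X)
  p <- learner_registry()[[model$entry_name]]$prob(model$fit, X)
  p <- pmax(p, 0)
  p / rowSums(p)
}

## ---- AdaBoost.M1 ----------------------------------------------------------

#' AdaBoost.M1 boosting
#'
#' Standard AdaBoost.M1: uniform initial weights; per round the weak
#' learner is fitted on the weighted sample (natively weighted where
#' supported, otherwise by weighted resampling), the weighted error
#' `eps` computed, and training stops early when `eps` is 0 (the single
#' perfect model is kept) or `eps >= 0.5`. Correctly classified instances
#' are down-weighted by `beta = eps / (1 - eps)` and weights renormalized;
#' the model's vote weight is `log(1 / beta)`. Prediction converts the
#' weighted vote into per-class probabilities.
#'
#' @param spec weak learner specification.
#' @param X,y training data.
#' @param rounds maximum boosting rounds (>= 1).
#' @param seed RNG seed.
#' @return object of class `cogscreen_boost`.
#' @export
adaboost_m1 <- function(spec, X, y, rounds = 10L, seed = 1L) {
  if (rounds < 1) abort_domain("rounds must be >= 1")
  X <- as.matrix(X); y <- as.integer(y)
  n <- nrow(X)
  w <- rep(1 / n, n)
  supports_w <- learner_registry()[[spec$name]]$weights
  models <- list(); alphas <- numeric(0)
  for (r in seq_len(rounds)) {
    rs <- derive_seed(seed, r)
    if (supports_w) {
      m <- train_base(spec, X, y, weights = w, seed = rs)
    } else {
      set.seed(rs)
      idx <- sample.int(n, n, replace = TRUE, prob = w)
      if (length(unique(y[idx])) < 2) idx <- c(idx[-1], which(y != y[idx[1]])[1])
      m <- train_base(spec, X[idx, , drop = FALSE], y[idx], seed = rs)
    }
    pred <- as.integer(predict_proba(m, X)[, "1"] >= 0.5)
    miss <- pred != y
    eps <- sum(w[miss])
    if (eps == 0) {
      models <- list(m); alphas <- 1
      break
    }
    if (eps >= 0.5) {
      if (length(models) == 0) {
        warning("weak learner no better than chance in round 1; keeping single model")
        models <- list(m); alphas <- 1
      }
      break
    }
    beta <- eps / (1 - eps)
    models[[length(models) + 1]] <- m
    alphas <- c(alphas, log(1 / beta))
    w[!miss] <- w[!miss] * beta
    w <- w / sum(w)
  }
  structure(list(spec = spec, models = models, alphas = alphas, rounds = rounds),
            class = "cogscreen_boost")
}

#' The AdaBoost.M1 weight update for one round
#'
#' Exposed separately so the update arithmetic is testable on paper:
#' given current weights and the round's miss indicator, returns
#' `eps`, `beta`, the vote weight and the renormalized weights.
#'
#' @param w current instance weights (sum 1).
#' @param miss logical miss indicator per instance.
#' @return list with `eps`, `beta`, `alpha`, `w_new`.
#' @export
adaboost_weight_update <- function(w, miss) {
  eps <- sum(w[miss])
  if (eps <= 0 || eps >= 0.5) abort_domain("update defined for 0 < eps < 0.5")
  beta <- eps / (1 - eps)
  w_new <- w
  w_new[!miss] <- w_new[!miss] * beta
  list(eps = eps, beta = beta, alpha = log(1 / beta), w_new = w_new / sum(w_new))
}

#' @export
predict_proba.cogscreen_boost <- function(model, X) {
  X <- as.matrix(X)
  votes <- matrix(0, nrow(X), 2, dimnames = list(NULL, CLASS_LEVELS))
  for (k in seq_along(model$models)) {
    pred <- as.integer(predict_proba(model$models[[k]], X)[, "1"] >= 0.5)
    votes[cbind(seq_len(nrow(X)), pred + 1L)] <-
      votes[cbind(seq_len(nrow(X)), pred + 1L)] + model$alphas[k]
  }
  votes / rowSums(votes)
}

## ---- ensembles and fusion --------------------------------------------------

#' Ensemble configuration
#'
#' @param members list of members, each `list(spec = base_learner_spec,
#'   boost_rounds = NULL or integer)`.
#' @param fusion `"average_of_probabilities"` or `"majority_vote"`.
#' @return list of class `cogscreen_ensemble_config`.
#' @export
ensemble_config <- function(members,
                            fusion = c("average_of_probabilities", "majority_vote")) {
  fusion <- match.arg(fusion)
  if (!length(members)) abort_validation("ensemble needs >= 1 member")
  structure(list(members = members, fusion = fusion),
            class = "cogscreen_ensemble_config")
}

#' The 13-member hybrid ensemble preset
#'
#' Seven AdaBoost.M1-wrapped learners (decision stump, random forest, MLP,
#' SMO, kNN, locally weighted learning, Bayes net), a sigmoid-kernel SVM
#' with PCA, two linear SVMs with PCA, Fisher's LDA, a recurrent neural
#' learner and a voted perceptron with PCA, fused by the average of
#' probabilities.
#'
#' @param boost_rounds AdaBoost rounds for the boosted members (default 10).
#' @param pca_vc explained-variance fraction for the PCA members (0.95).
#' @return a [ensemble_config()] with exactly 13 members.
#' @export
hybrid13_config <- function(boost_rounds = 10L, pca_vc = 0.95) {
  boosted <- function(name, hyper = list())
    list(spec = base_learner_spec(name, hyper), boost_rounds = boost_rounds)
  plain <- function(name, hyper = list(), vc = NULL)
    list(spec = base_learner_spec(name, hyper, pca_vc = vc), boost_rounds = NULL)
  ensemble_config(list(
    boosted("decision_stump"),
    boosted("random_forest", list(ntree = 100)),
    boosted("mlp", list(size = 6, maxit = 80)),
    boosted("smo"),
    boosted("knn", list(k = 5)),
    boosted("lwl"),
    boosted("bayes_net"),
    plain("svm_sigmoid", vc = pca_vc),
    plain("svm_linear", vc = pca_vc),
    plain("svm_linear", vc = pca_vc),
    plain("flda"),
    plain("lstm_seq", list(units = 40, epochs = 10)),
    plain("voted_perceptron", vc = pca_vc)
  ), fusion = "average_of_probabilities")
}

#' Train an ensemble
#'
#' @param config an [ensemble_config()].
#' @param X,y training data.
#' @param seed RNG seed (each member gets a derived seed).
#' @return object of class `cogscreen_ensemble`.
#' @export
train_ensemble <- function(config, X, y, seed = 1L) {
  fits <- lapply(seq_along(config$members), function(i) {
    m <- config$members[[i]]
    s <- derive_seed(seed, 100 + i)
    if (!is.null(m$boost_rounds)) adaboost_m1(m$spec, X, y, m$boost_rounds, s)
    else train_base(m$spec, X, y, seed = s)
  })
  structure(list(config = config, fits = fits), class = "cogscreen_ensemble")
}

#' Fuse member probabilities into a prediction
#'
#' `average_of_probabilities` averages the member probability rows and
#' predicts the argmax; `majority_vote` lets each member vote its argmax
#' and predicts the modal class. Exact ties go to class 0 (healthy), the
#' conservative screening default.
#'
#' @param proba_list list of `n x 2` member probability matrices.
#' @param rule fusion rule.
#' @return tibble: `pred`, `confidence` (probability of the emitted
#'   class), `p0`, `p1`.
#' @export
fuse <- function(proba_list, rule = c("average_of_probabilities", "majority_vote")) {
  rule <- match.arg(rule)
  if (!length(proba_list)) abort_validation("need >= 1 member")
  if (rule == "average_of_probabilities") {
    p <- Reduce(`+`, proba_list) / length(proba_list)
    pred <- as.integer(p[, "1"] > p[, "0"])   # tie -> class 0
    conf <- p[cbind(seq_len(nrow(p)), pred + 1L)]
    tibble::tibble(pred = pred, confidence = unname(conf),
                   p0 = unname(p[, "0"]), p1 = unname(p[, "1"]))
  } else {
    votes1 <- Reduce(`+`, lapply(proba_list, function(p)
      as.integer(p[, "1"] > p[, "0"])))
    n_mem <- length(proba_list)
    pred <- as.integer(votes1 > n_mem / 2)    # tie -> class 0
    frac <- ifelse(pred == 1, votes1 / n_mem, 1 - votes1 / n_mem)
    p <- Reduce(`+`, proba_list) / n_mem
    tibble::tibble(pred = pred, confidence = unname(frac),
                   p0 = unname(p[, "0"]), p1 = unname(p[, "1"]))
  }
}

#' @export
predict_proba.cogscreen_ensemble <- function(model, X) {
  pl <- lapply(model$fits, function(f) predict_proba(f, X))
  fused <- fuse(pl, model$config$fusion)
  out <- cbind(`0` = fused$p0, `1` = fused$p1)
  attr(out, "members") <- pl
  out
}

#' @export
predict.cogscreen_ensemble <- function(object, newdata, ...) {
  pl <- lapply(object$fits, function(f) predict_proba(f, newdata))
  fuse(pl, object$config$fusion)
}

## ---- metric suite ----------------------------------------------------------

auc_trapezoid <- function(y_bin, score) {
  if (length(unique(y_bin)) < 2) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  yy <- y_bin[ord]
  tpr <- c(0, cumsum(yy) / sum(yy))
  fpr <- c(0, cumsum(1 - yy) / sum(1 - yy))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

auc_pr <- function(y_bin, score) {
  if (length(unique(y_bin)) < 2) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  yy <- y_bin[ord]
  tp <- cumsum(yy)
  prec <- tp / seq_along(yy)
  rec <- tp / sum(yy)
  sum(diff(c(0, rec)) * prec)
}

#' Full metric suite from predictions
#'
#' Confusion counts plus accuracy, per-class one-vs-rest rates aggregated
#' support-weighted (TPR/recall, TNR, precision, F1), Cohen's kappa,
#' Matthews correlation, ROC and precision-recall AUCs (trapezoid, when
#' probabilities are given), and the probability-error family MAE / RMSE /
#' RAE / RRSE (per-class probability residuals, relative to the
#' class-prior constant predictor; RAE/RRSE in percent).
#'
#' @param y_true,y_pred integer class vectors (0/1).
#' @param y_proba optional `n x 2` probability matrix.
#' @return one-row tibble of class `cogscreen_metrics`; the 2x2 confusion
#'   table is kept in attribute `confusion`.
#' @export
evaluate <- function(y_true, y_pred, y_proba = NULL) {
  if (length(y_true) != length(y_pred)) abort_validation("length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  n <- length(y_true)
  cm <- table(factor(y_true, 0:1), factor(y_pred, 0:1))
  acc <- sum(diag(cm)) / n

  per_class <- lapply(0:1, function(c) {
    tp <- sum(y_true == c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    fp <- sum(y_true != c & y_pred == c)
    tn <- sum(y_true != c & y_pred != c)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    list(support = tp + fn,
         tpr = rec,
         tnr = if (tn + fp > 0) tn / (tn + fp) else 0,
         fpr = if (tn + fp > 0) fp / (tn + fp) else 0,
         precision = prec,
         f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
  })
  wavg <- function(field) {
    s <- vapply(per_class, `[[`, numeric(1), "support")
    v <- vapply(per_class, `[[`, numeric(1), field)
    sum(s * v) / sum(s)
  }

  p_true <- rowSums(cm) / n; p_pred <- colSums(cm) / n
  pe <- sum(p_true * p_pred)
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 1
  tp <- cm[2, 2]; tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]
  denom <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0

  auc_roc <- auc_prc <- mae <- rmse <- rae <- rrse <- NA_real_
  if (!is.null(y_proba)) {
    y_proba <- as.matrix(y_proba)
    s <- vapply(per_class, `[[`, numeric(1), "support")
    aucs <- c(auc_trapezoid(as.integer(y_true == 0), y_proba[, 1]),
              auc_trapezoid(as.integer(y_true == 1), y_proba[, 2]))
    prcs <- c(auc_pr(as.integer(y_true == 0), y_proba[, 1]),
              auc_pr(as.integer(y_true == 1), y_proba[, 2]))
    auc_roc <- sum(s * aucs) / sum(s)
    auc_prc <- sum(s * prcs) / sum(s)
    Y <- cbind(as.integer(y_true == 0), as.integer(y_true == 1))
    R <- y_proba - Y
    mae <- mean(abs(R)); rmse <- sqrt(mean(R^2))
    prior <- matrix(p_true, n, 2, byrow = TRUE)
    R0 <- prior - Y
    rae <- 100 * sum(abs(R)) / sum(abs(R0))
    rrse <- 100 * sqrt(sum(R^2) / sum(R0^2))
  }

  out <- tibble::tibble(
    n = n, accuracy = acc, accuracy_pct = 100 * acc,
    tpr = wavg("tpr"), tnr = wavg("tnr"), fpr = wavg("fpr"),
    precision = wavg("precision"), recall = wavg("tpr"), f1 = wavg("f1"),
    kappa = kappa, mcc = mcc,
    auc_roc = auc_roc, auc_prc = auc_prc,
    mae = mae, rmse = rmse, rae = rae, rrse = rrse
  )
  class(out) <- c("cogscreen_metrics", class(out))
  attr(out, "confusion") <- cm
  out
}

#' Metric suite from printed confusion counts
#'
#' Rebuilds prediction vectors from per-class correct/incorrect counts and
#' runs [evaluate()]; the analytic check that the metric definitions
#' reproduce a published confusion table's derived values.
#'
#' @param correct0,wrong0 records of true class 0 classified right / wrong.
#' @param correct1,wrong1 records of true class 1 classified right / wrong.
#' @return a `cogscreen_metrics` tibble.
#' @export
metrics_from_confusion <- function(correct0, wrong0, correct1, wrong1) {
  y_true <- c(rep(0L, correct0 + wrong0), rep(1L, correct1 + wrong1))
  y_pred <- c(rep(0L, correct0), rep(1L, wrong0), rep(1L, correct1), rep(0L, wrong1))
  evaluate(y_true, y_pred)
}

## ---- cross-validation -------------------------------------------------------

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (c in unique(y)) {
    idx <- sample(which(y == c))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of an ensemble
#'
#' Deterministic given the seed; metrics are pooled over the held-out
#' predictions of all folds.
#'
#' @param config an [ensemble_config()] (or a single [base_learner_spec()]).
#' @param X,y data.
#' @param k folds (default 10); `k = n` gives leave-one-out.
#' @param seed RNG seed.
#' @return a `cogscreen_metrics` tibble; attribute `predictions` holds the
#'   pooled per-record tibble.
#' @export
kfold_cv <- function(config, X, y, k = 10L, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  if (k > length(y)) abort_domain("k must not exceed n")
  if (inherits(config, "cogscreen_spec"))
    config <- ensemble_config(list(list(spec = config, boost_rounds = NULL)))
  if (k == length(y)) {
    fold <- seq_along(y)   # leave-one-out
  } else {
    for (attempt in 1:10) {
      fold <- stratified_folds(y, k, derive_seed(seed, attempt))
      ok <- all(vapply(seq_len(k), function(f)
        length(unique(y[fold != f])) == 2, logical(1)))
      if (ok) break
    }
  }
  pred <- integer(length(y)); proba <- matrix(NA_real_, length(y), 2)
  conf <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    ens <- train_ensemble(config, X[tr, , drop = FALSE], y[tr],
                          seed = derive_seed(seed, 200 + f))
    res <- predict(ens, X[te, , drop = FALSE])
    pred[te] <- res$pred
    proba[te, ] <- cbind(res$p0, res$p1)
    conf[te] <- res$confidence
  }
  out <- evaluate(y, pred, proba)
  attr(out, "predictions") <- tibble::tibble(
    index = seq_along(y), fold = fold, y_true = y, y_pred = pred,
    p1 = proba[, 2], confidence = conf)
  out
}

#' Leave-subjects-out split and hold-out report
#'
#' Removes all records of the held-out subjects from training and
#' partitions their records into a healthy and an impaired test set; no
#' subject contributes to both training and testing. The report gives the
#' error count (EC) and mean prediction confidence (PrC) per test set.
#'
#' @param table feature table with `subject_id` and `label` columns.
#' @param held_out_subject_ids subject ids to hold out.
#' @return list with `train`, `test_healthy`, `test_impaired` tibbles.
#' @export
leave_subjects_out_split <- function(table, held_out_subject_ids) {
  if (!all(held_out_subject_ids %in% table$subject_id))
    abort_validation("held-out subject id not present")
  test <- table[table$subject_id %in% held_out_subject_ids, ]
  train <- table[!table$subject_id %in% held_out_subject_ids, ]
  if (length(unique(train$label)) < 2)
    abort_validation("hold-out empties a training class")
  list(train = train,
       test_healthy = test[test$label == 0, ],
       test_impaired = test[test$label == 1, ])
}

#' @rdname leave_subjects_out_split
#' @param config ensemble configuration.
#' @param seed RNG seed.
#' @param schema feature schema.
#' @export
holdout_report <- function(table, held_out_subject_ids, config = hybrid13_config(),
                           seed = 1L, schema = feature_schema()) {
  sp <- leave_subjects_out_split(table, held_out_subject_ids)
  tr <- feature_matrix(sp$train, schema)
  ens <- train_ensemble(config, tr$X, tr$y, seed = seed)
  one <- function(tab, target) {
    if (!nrow(tab)) return(tibble::tibble(n = 0L, ec = NA_integer_, mean_prc = NA_real_))
    m <- feature_matrix(tab, schema)
    res <- predict(ens, m$X)
    tibble::tibble(n = nrow(tab), ec = sum(res$pred != target),
                   mean_prc = mean(res$confidence))
  }
  dplyr::bind_rows(
    dplyr::mutate(one(sp$test_healthy, 0L), set = "healthy", .before = 1),
    dplyr::mutate(one(sp$test_impaired, 1L), set = "impaired", .before = 1)
  )
}

## ---- feature selection -------------------------------------------------------

cv_accuracy_repeated <- function(spec, X, y, k = 5L, seed = 1L, reps = 3L) {
  mean(vapply(seq_len(reps), function(r)
    cv_accuracy_spec(spec, X, y, k, derive_seed(seed, 17L * r)), numeric(1)))
}

cv_accuracy_spec <- function(spec, X, y, k = 5L, seed = 1L) {
  fold <- stratified_folds(y, k, seed)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (!any(te) || length(unique(y[tr])) < 2) next
    pred <- tryCatch({
      m <- train_base(spec, X[tr, , drop = FALSE], y[tr], seed = derive_seed(seed, f))
      as.integer(predict_proba(m, X[te, , drop = FALSE])[, "1"] >= 0.5)
    }, error = function(e) rep(-1L, sum(te)))  # degenerate fold scores 0
    correct <- correct + sum(pred == y[te])
  }
  correct / length(y)
}

#' Feature selection
#'
#' Four strategies: `correlation_rank` (top-k absolute Pearson correlation
#' with the class), `pca_vc` (minimal leading principal components
#' reaching the cumulative explained-variance target), `wrapper_subset`
#' (greedy best-first forward search scored by cross-validated accuracy of
#' a given learner) and `bgwopso` (binary hybrid grey-wolf / particle
#' swarm search with a sigmoid transfer function and a small cardinality
#' penalty on the CV-accuracy fitness).
#'
#' @param X,y data.
#' @param method selection method.
#' @param k number of features for `correlation_rank`.
#' @param vc variance fraction for `pca_vc`.
#' @param spec learner scored by the wrapper / BGWOPSO fitness
#'   (default LDA).
#' @param max_features wrapper search cap.
#' @param n_agents,n_iter BGWOPSO population and iterations.
#' @param penalty cardinality penalty weight for BGWOPSO.
#' @param cv_k,seed fitness cross-validation folds and seed.
#' @param cv_reps repeated-CV averages per wrapper step (default 3).
#' @return for `pca_vc` a transform list, otherwise an integer vector of
#'   selected column indices.
#' @export
select_features <- function(X, y,
                            method = c("correlation_rank", "pca_vc",
                                       "wrapper_subset", "bgwopso"),
                            k = 10L, vc = 0.95,
                            spec = base_learner_spec("lda"),
                            max_features = 10L, n_agents = 12L, n_iter = 20L,
                            penalty = 0.01, cv_k = 5L, seed = 1L, cv_reps = 3L) {
  method <- match.arg(method)
  X <- as.matrix(X); y <- as.integer(y)
  p <- ncol(X)
  if (p < 1) abort_domain("need >= 1 feature")
  if (method == "correlation_rank") {
    if (k > p) abort_domain("k exceeds the number of features")
    r <- abs(suppressWarnings(stats::cor(X, y)))
    r[is.na(r)] <- 0
    return(order(r, decreasing = TRUE)[seq_len(k)])
  }
  if (method == "pca_vc") {
    keep <- apply(X, 2, stats::sd) > 0
    rot <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
    cum <- cumsum(rot$sdev^2) / sum(rot$sdev^2)
    ncomp <- max(1L, which(cum >= vc)[1])
    return(list(rot = rot, ncomp = ncomp, keep = which(keep),
                transform = function(Z)
                  stats::predict(rot, Z[, keep, drop = FALSE])[, seq_len(ncomp), drop = FALSE]))
  }
  if (method == "wrapper_subset") {
    # greedy best-first forward search; the step score is a repeated
    # stratified CV average, which damps the max-selection bias over many
    # noise candidates
    selected <- integer(0)
    best_acc <- -Inf
    repeat {
      cand <- setdiff(seq_len(p), selected)
      if (!length(cand) || length(selected) >= max_features) break
      accs <- vapply(cand, function(j)
        cv_accuracy_repeated(spec, X[, c(selected, j), drop = FALSE], y,
                             cv_k, seed, cv_reps),
        numeric(1))
      j_best <- cand[which.max(accs)]
      if (max(accs) <= best_acc + 1e-9) break
      best_acc <- max(accs)
      selected <- c(selected, j_best)
    }
    return(sort(selected))
  }
  # bgwopso
  set.seed(seed)
  fitness <- function(mask) {
    if (!any(mask)) return(-Inf)
    cv_accuracy_spec(spec, X[, mask, drop = FALSE], y, cv_k, seed) -
      penalty * sum(mask) / p
  }
  pos <- matrix(stats::runif(n_agents * p) < 0.3, n_agents, p)
  vel <- matrix(0, n_agents, p)
  fit <- apply(pos, 1, fitness)
  sig <- function(z) 1 / (1 + exp(-10 * (z - 0.5)))
  for (it in seq_len(n_iter)) {
    ord <- order(fit, decreasing = TRUE)
    alpha <- pos[ord[1], ]; beta <- pos[ord[2], ]; delta <- pos[ord[3], ]
    a <- 2 - 2 * it / n_iter
    for (i in seq_len(n_agents)) {
      lead <- (alpha + beta + delta) / 3
      r1 <- stats::runif(p); r2 <- stats::runif(p)
      vel[i, ] <- 0.5 * vel[i, ] + a * r1 * (lead - pos[i, ]) +
        0.5 * r2 * (alpha - pos[i, ])
      prob_bit <- sig(lead + vel[i, ])
      pos[i, ] <- stats::runif(p) < prob_bit
      f <- fitness(pos[i, ])
      if (f > fit[i]) fit[i] <- f else pos[i, ] <- pos[i, ]  # greedy keep
    }
    fit <- apply(pos, 1, fitness)
  }
  best <- pos[which.max(fit), ]
  sort(which(best))
}

## ---- recurrent sequence classifier -----------------------------------------

random_orthogonal <- function(n, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(n * n), n)))
}

# each sequence is summarized by the final, time-averaged and
# time-dispersion (sd) hidden states of both recurrent directions; the sd
# pooling is what carries temporal-variability cues (jitter-like signal)
# through the fixed encoder
encode_sequences <- function(seqs, enc) {
  t(vapply(seqs, function(s) {
    s <- as.matrix(s)
    n <- nrow(s); u <- enc$units
    hf <- numeric(u); hb <- numeric(u)
    sf <- numeric(u); sb <- numeric(u)      # running sums
    qf <- numeric(u); qb <- numeric(u)      # running sums of squares
    for (t in seq_len(n)) {
      hf <- tanh(enc$win %*% s[t, ] + enc$wrec %*% hf)
      sf <- sf + hf; qf <- qf + hf^2
    }
    hlast_f <- hf
    for (t in rev(seq_len(n))) {
      hb <- tanh(enc$win_b %*% s[t, ] + enc$wrec_b %*% hb)
      sb <- sb + hb; qb <- qb + hb^2
    }
    mf <- sf / n; mb <- sb / n
    vf <- sqrt(pmax(qf / n - mf^2, 0)); vb <- sqrt(pmax(qb / n - mb^2, 0))
    c(hlast_f, hb, mf, mb, vf, vb)
  }, numeric(6 * enc$units)))
}

#' Bidirectional recurrent sequence classifier
#'
#' Encodes each (frames x features) sequence with a fixed bidirectional
#' tanh recurrent layer (orthogonal recurrent weights scaled to spectral
#' radius 0.9, `units` per direction) and trains a two-layer fully
#' connected softmax readout (100 neurons each by default) with RMSProp:
#' max 10 epochs, mini-batch 128, shuffling every epoch and a piecewise
#' learning-rate schedule (drop factor 0.1). Deterministic given the seed.
#'
#' @param sequences list of numeric matrices (frames x features, z-scored).
#' @param labels binary labels, one per sequence.
#' @param units recurrent units per direction (default 100).
#' @param hidden neurons in each fully connected layer (default 100).
#' @param epochs maximum epochs (default 10).
#' @param batch_size mini-batch size (default 128).
#' @param lr initial learning rate; dropped by `lr_drop` at 70% of epochs.
#' @param lr_drop piecewise drop factor (default 0.1).
#' @param patience early-stopping patience on training loss (default 3).
#' @param seed RNG seed.
#' @return object of class `cogscreen_seqmodel`.
#' @export
train_sequence_classifier <- function(sequences, labels, units = 100L,
                                      hidden = 100L, epochs = 10L,
                                      batch_size = 128L, lr = 0.01,
                                      lr_drop = 0.1, patience = 3L, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort_validation("need both classes to train")
  if (!length(sequences) || any(vapply(sequences, nrow, integer(1)) == 0))
    abort_validation("sequences must be non-empty")
  d <- ncol(sequences[[1]])
  set.seed(derive_seed(seed, 1))
  scale_sr <- function(W) {
    sr <- max(Mod(eigen(W, only.values = TRUE)$values))
    W * 0.9 / sr
  }
  enc <- list(units = as.integer(units),
              win = matrix(stats::rnorm(units * d, sd = 1 / sqrt(d)), units),
              wrec = scale_sr(random_orthogonal(units, derive_seed(seed, 2))),
              win_b = matrix(stats::rnorm(units * d, sd = 1 / sqrt(d)), units),
              wrec_b = scale_sr(random_orthogonal(units, derive_seed(seed, 3))))
  H <- encode_sequences(sequences, enc)
  st <- standardizer(H)
  H <- st$apply(H)
  n <- nrow(H); din <- ncol(H)
  Y <- cbind(labels == 0, labels == 1) * 1

  set.seed(derive_seed(seed, 4))
  W1 <- matrix(stats::rnorm(din * hidden, sd = sqrt(2 / din)), din)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(hidden * hidden, sd = sqrt(2 / hidden)), hidden)
  b2 <- numeric(hidden)
  W3 <- matrix(stats::rnorm(hidden * 2, sd = sqrt(2 / hidden)), hidden)
  b3 <- numeric(2)
  cache <- lapply(list(W1, b1, W2, b2, W3, b3), function(p) p * 0)
  rho <- 0.9; eps <- 1e-8
  best_loss <- Inf; stall <- 0L
  cur_lr <- lr
  drop_at <- ceiling(0.7 * epochs)
  for (ep in seq_len(epochs)) {
    if (ep == drop_at) cur_lr <- cur_lr * lr_drop
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      Xb <- H[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      A1 <- tanh(sweep(Xb %*% W1, 2, b1, `+`))
      A2 <- tanh(sweep(A1 %*% W2, 2, b2, `+`))
      Zs <- sweep(A2 %*% W3, 2, b3, `+`)
      Zs <- Zs - apply(Zs, 1, max)
      P <- exp(Zs) / rowSums(exp(Zs))
      dZ <- (P - Yb) / nrow(Xb)
      gW3 <- t(A2) %*% dZ; gb3 <- colSums(dZ)
      dA2 <- dZ %*% t(W3) * (1 - A2^2)
      gW2 <- t(A1) %*% dA2; gb2 <- colSums(dA2)
      dA1 <- dA2 %*% t(W2) * (1 - A1^2)
      gW1 <- t(Xb) %*% dA1; gb1 <- colSums(dA1)
      grads <- list(gW1, gb1, gW2, gb2, gW3, gb3)
      params <- list(W1, b1, W2, b2, W3, b3)
      for (j in seq_along(params)) {
        cache[[j]] <- rho * cache[[j]] + (1 - rho) * grads[[j]]^2
        params[[j]] <- params[[j]] - cur_lr * grads[[j]] / (sqrt(cache[[j]]) + eps)
      }
      W1 <- params[[1]]; b1 <- params[[2]]; W2 <- params[[3]]
      b2 <- params[[4]]; W3 <- params[[5]]; b3 <- params[[6]]
    }
    A1 <- tanh(sweep(H %*% W1, 2, b1, `+`))
    A2 <- tanh(sweep(A1 %*% W2, 2, b2, `+`))
    Zs <- sweep(A2 %*% W3, 2, b3, `+`)
    Zs <- Zs - apply(Zs, 1, max)
    P <- exp(Zs) / rowSums(exp(Zs))
    loss <- -mean(log(pmax(P[cbind(seq_len(n), labels + 1L)], 1e-12)))
    if (loss < best_loss - 1e-5) { best_loss <- loss; stall <- 0L }
    else { stall <- stall + 1L; if (stall >= patience) break }
  }
  structure(list(enc = enc, st = list(mu = st$mu, sd = st$sd),
                 W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3),
            class = "cogscreen_seqmodel")
}

#' @rdname train_sequence_classifier
#' @param model fitted `cogscreen_seqmodel`.
#' @param sequences list of sequences to score.
#' @export
predict_sequence_proba <- function(model, sequences) {
  H <- encode_sequences(sequences, model$enc)
  H <- sweep(sweep(H, 2, model$st$mu), 2, model$st$sd, `/`)
  A1 <- tanh(sweep(H %*% model$W1, 2, model$b1, `+`))
  A2 <- tanh(sweep(A1 %*% model$W2, 2, model$b2, `+`))
  Zs <- sweep(A2 %*% model$W3, 2, model$b3, `+`)
  Zs <- Zs - apply(Zs, 1, max)
  P <- exp(Zs) / rowSums(exp(Zs))
  colnames(P) <- CLASS_LEVELS
  P
}

#' @export
predict_proba.cogscreen_seqmodel <- function(model, X) {
  if (is.list(X) && !is.data.frame(X)) predict_sequence_proba(model, X)
  else predict_sequence_proba(model, lapply(seq_len(nrow(X)), function(i)
    as.matrix(X)[i, , drop = FALSE]))
}

#' Majority vote over a subject's clip-level decisions
#'
#' @param preds integer vector of clip predictions (0/1).
#' @return the modal class; exact ties go to 0.
#' @export
fuse_clip_votes <- function(preds) as.integer(sum(preds == 1) > length(preds) / 2)

## ---- wavelet scattering classifier ------------------------------------------

#' SVM on wavelet-scattering windows
#'
#' Extracts scattering features per clip, treats each scattering window as
#' one training instance (label inherited from the clip), trains a
#' third-order polynomial-kernel SVM, and classifies a clip by majority
#' vote over its windows.
#'
#' @param clips list of [audio_clip()]s.
#' @param labels binary clip labels.
#' @param config a [wst_config()].
#' @param seed RNG seed.
#' @return object of class `cogscreen_wstmodel`.
#' @export
train_wst_classifier <- function(clips, labels, config = wst_config(), seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort_validation("need both classes to train")
  feats <- lapply(clips, wst_features, config = config)
  X <- do.call(rbind, lapply(feats, t))   # one row per scattering window
  y <- rep(labels, vapply(feats, ncol, integer(1)))
  set.seed(seed)
  fit <- svm_fit(X, y, "polynomial", list(cost = 1))
  fit$degree <- 3
  structure(list(fit = fit, config = config), class = "cogscreen_wstmodel")
}

#' @rdname train_wst_classifier
#' @param model fitted `cogscreen_wstmodel`.
#' @export
predict_wst <- function(model, clips) {
  vapply(clips, function(cl) {
    Xw <- t(wst_features(cl, model$config))
    p <- svm_prob(model$fit, Xw)
    fuse_clip_votes(as.integer(p[, "1"] > p[, "0"]))
  }, integer(1))
}
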