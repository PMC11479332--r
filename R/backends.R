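#' Classifier backend specification
#'
#' The feature-based model roster: three gradient-boosted tree variants
#' (`LGB` histogram-based with deep trees, `XGB` exact-split, `GBC`
#' shallow-tree slow-learning-rate), AdaBoost (`ADA`, SAMME on depth-limited
#' CART trees), multinomial logistic regression (`LR`), an RBF support
#' vector machine (`SVM`), and three single-hidden-layer perceptrons of
#' increasing width (`MLP1`, `MLP2`, `MLP3`). Hyperparameters default to
#' library defaults with fixed seeds; any entry can be overridden through
#' `hyperparameters`.
#'
#' @param backend Backend label.
#' @param hyperparameters Named list of overrides.
#' @param seed Integer seed fixed for the fit.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(backend = c("LGB", "GBC", "ADA", "XGB", "LR",
                                        "SVM", "MLP1", "MLP2", "MLP3"),
                            hyperparameters = list(), seed = 1L) {
  backend <- match.arg(backend)
  structure(list(backend = backend, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# column means/sds for standardisation of scale-sensitive backends
feature_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}
apply_scaler <- function(x, sc) sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")

#' Fit a classifier backend
#'
#' @param x Numeric feature matrix (rows = windows).
#' @param y Class labels (coerced to factor).
#' @param spec A [classifier_spec()].
#' @return A `fitted_backend` usable with [predict_backend()].
#' @export
fit_backend <- function(x, y, spec = classifier_spec("LGB")) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- factor(y)
  if (nlevels(y) < 2) {
    stop("training data must contain at least 2 classes", call. = FALSE)
  }
  x <- as.matrix(x)
  x[!is.finite(x)] <- 0
  hp <- spec$hyperparameters
  seed <- spec$seed
  fit <- with_local_seed(seed, switch(
    spec$backend,
    LGB = fit_xgb(x, y, seed, tree_method = "hist", max_depth = hp$max_depth %||% 8,
                  eta = hp$eta %||% 0.1, nrounds = hp$nrounds %||% 100,
                  grow_policy = "lossguide"),
    XGB = fit_xgb(x, y, seed, tree_method = "exact",
                  max_depth = hp$max_depth %||% 6,
                  eta = hp$eta %||% 0.3, nrounds = hp$nrounds %||% 100),
    GBC = fit_xgb(x, y, seed, tree_method = "exact",
                  max_depth = hp$max_depth %||% 3,
                  eta = hp$eta %||% 0.1, nrounds = hp$nrounds %||% 100),
    ADA = fit_ada(x, y, n_estimators = hp$n_estimators %||% 50,
                  max_depth = hp$max_depth %||% 1),
    LR = fit_lr(x, y),
    SVM = fit_svm(x, y, cost = hp$cost %||% 1, gamma = hp$gamma),
    MLP1 = fit_mlp(x, y, size = hp$size %||% 8, maxit = hp$maxit %||% 300),
    MLP2 = fit_mlp(x, y, size = hp$size %||% 16, maxit = hp$maxit %||% 300),
    MLP3 = fit_mlp(x, y, size = hp$size %||% 32, maxit = hp$maxit %||% 300)))
  structure(list(backend = spec$backend, fit = fit, levels = levels(y),
                 spec = spec),
            class = "fitted_backend")
}

#' Predict class labels from a fitted backend
#'
#' The class with the highest posterior probability wins; ties break to the
#' lowest class index for determinism.
#'
#' @param model A `fitted_backend` from [fit_backend()].
#' @param x Numeric feature matrix.
#' @return Factor of predicted labels with the training levels.
#' @export
predict_backend <- function(model, x) {
  stopifnot(inherits(model, "fitted_backend"))
  x <- as.matrix(x)
  x[!is.finite(x)] <- 0
  prob <- model$fit$predict_prob(x)
  idx <- apply(prob, 1, which.max)  # which.max breaks ties at lowest index
  factor(model$levels[idx], levels = model$levels)
}

fit_xgb <- function(x, y, seed, tree_method, max_depth, eta, nrounds,
                    grow_policy = "depthwise") {
  k <- nlevels(y)
  params <- list(objective = if (k > 2) "multi:softprob" else
    "binary:logistic", max_depth = max_depth, eta = eta,
    tree_method = tree_method, grow_policy = grow_policy, nthread = 1,
    seed = as.integer(seed))
  if (k > 2) params$num_class <- k
  dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds)
  list(predict_prob = function(newx) {
    p <- predict(booster, xgboost::xgb.DMatrix(newx))
    if (k > 2) {
      if (is.matrix(p)) p else matrix(p, ncol = k, byrow = TRUE)
    } else cbind(1 - p, p)
  })
}

# SAMME AdaBoost on depth-limited CART trees.
fit_ada <- function(x, y, n_estimators, max_depth) {
  k <- nlevels(y)
  n <- nrow(x)
  d <- as.data.frame(x)
  d$.y <- y
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = d, weights = w,
                        method = "class",
                        control = rpart::rpart.control(
                          maxdepth = max_depth, cp = 0, minsplit = 2,
                          xval = 0))
    pred <- predict(fit, d, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / k || err <= 0) {
      if (err <= 0) { trees <- c(trees, list(fit)); alphas <- c(alphas, 10) }
      break
    }
    alpha <- log((1 - err) / err) + log(k - 1)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    trees <- c(trees, list(fit)); alphas <- c(alphas, alpha)
  }
  lv <- levels(y)
  list(predict_prob = function(newx) {
    nd <- as.data.frame(newx)
    votes <- matrix(0, nrow(nd), k, dimnames = list(NULL, lv))
    for (m in seq_along(trees)) {
      p <- predict(trees[[m]], nd, type = "class")
      votes[cbind(seq_len(nrow(nd)), as.integer(p))] <-
        votes[cbind(seq_len(nrow(nd)), as.integer(p))] + alphas[m]
    }
    votes / pmax(rowSums(votes), .Machine$double.eps)
  })
}

fit_lr <- function(x, y) {
  sc <- feature_scaler(x)
  d <- as.data.frame(apply_scaler(x, sc))
  d$.y <- y
  fit <- nnet::multinom(.y ~ ., data = d, trace = FALSE, maxit = 200,
                        MaxNWts = 5000)
  k <- nlevels(y)
  list(predict_prob = function(newx) {
    nd <- as.data.frame(apply_scaler(as.matrix(newx), sc))
    p <- predict(fit, nd, type = "probs")
    if (k == 2) cbind(1 - p, p) else
      matrix(p, ncol = k, byrow = FALSE)
  })
}

fit_svm <- function(x, y, cost, gamma) {
  sc <- feature_scaler(x)
  xs <- apply_scaler(x, sc)
  args <- list(x = xs, y = y, kernel = "radial", cost = cost,
               probability = TRUE)
  if (!is.null(gamma)) args$gamma <- gamma
  fit <- do.call(e1071::svm, args)
  lv <- levels(y)
  list(predict_prob = function(newx) {
    xs2 <- apply_scaler(as.matrix(newx), sc)
    p <- attr(predict(fit, xs2, probability = TRUE), "probabilities")
    p[, lv, drop = FALSE]
  })
}

fit_mlp <- function(x, y, size, maxit) {
  sc <- feature_scaler(x)
  xs <- apply_scaler(x, sc)
  ymat <- nnet::class.ind(y)
  fit <- nnet::nnet(xs, ymat, size = size, softmax = TRUE, maxit = maxit,
                    trace = FALSE, MaxNWts = 20000, decay = 1e-4)
  lv <- levels(y)
  list(predict_prob = function(newx) {
    xs2 <- apply_scaler(as.matrix(newx), sc)
    p <- predict(fit, xs2)
    p[, lv, drop = FALSE]
  })
}
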