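#' The nine-classifier registry
#'
#' Names of the nine classical classifiers evaluated by the pipeline:
#' an entropy-split decision tree (C4.5-style), k-nearest neighbors, a
#' radial-kernel SVM, Gaussian naive Bayes, random forest, logistic
#' regression, depth-wise gradient boosting, discrete AdaBoost on decision
#' stumps, and a leaf-wise histogram gradient-boosting configuration
#' (LightGBM-style growth on the xgboost engine).
#'
#' @return Character vector of the nine registry names.
#' @export
classifier_names <- function() {
  c("decision_tree_c45", "knn", "svm", "naive_bayes", "random_forest",
    "logistic_regression", "gradient_boosting", "adaboost", "lightgbm")
}

#' Classifier specification
#'
#' @param name One of [classifier_names()].
#' @param hyperparameters Named list overriding the defaults below.
#' @param seed Integer seed used for any randomness in fitting.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, hyperparameters = list(), seed = 1L) {
  if (!name %in% classifier_names()) {
    pdb_stop("input_error",
             paste0("unknown classifier '", name, "'; see classifier_names()"))
  }
  defaults <- switch(name,
    decision_tree_c45 = list(cp = 0.01, minsplit = 10),
    knn = list(k = 5),
    svm = list(cost = 1, gamma = NULL),
    naive_bayes = list(laplace = 0),
    random_forest = list(ntree = 300),
    logistic_regression = list(),
    gradient_boosting = list(nrounds = 100, eta = 0.1, max_depth = 3),
    adaboost = list(n_stumps = 50),
    lightgbm = list(nrounds = 100, eta = 0.1, max_leaves = 31)
  )
  defaults[names(hyperparameters)] <- hyperparameters
  structure(list(name = name, hyperparameters = defaults,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

## Scale-sensitive models get train-fold standardization; trees consume raw.
needs_standardization <- function(name) {
  name %in% c("knn", "svm", "logistic_regression")
}

standardizer <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

apply_standardizer <- function(x, st) sweep(sweep(x, 2L, st$mu), 2L, st$sd, "/")

#' Fit a registry classifier
#'
#' @param spec A [classifier_spec()].
#' @param x Numeric feature matrix (subjects x features).
#' @param y Label factor with levels `control`, `PD`.
#' @return A fitted model wrapper consumed by [predict_classifier()].
#' @export
fit_classifier <- function(spec, x, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  if (nlevels(droplevels(y)) < 2L) {
    pdb_stop("input_error", "training labels contain a single class")
  }
  hp <- spec$hyperparameters
  st <- NULL
  if (needs_standardization(spec$name)) {
    st <- standardizer(x)
    x <- apply_standardizer(x, st)
  }
  fit <- with_seed(spec$seed, switch(spec$name,
    decision_tree_c45 = {
      df <- data.frame(x, .y = y, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = "information"),
                   control = rpart::rpart.control(cp = hp$cp, minsplit = hp$minsplit))
    },
    knn = list(train = x, y = y, k = hp$k),
    svm = e1071::svm(x, y, probability = TRUE, kernel = "radial",
                     cost = hp$cost,
                     gamma = if (is.null(hp$gamma)) 1 / ncol(x) else hp$gamma),
    naive_bayes = e1071::naiveBayes(x, y, laplace = hp$laplace),
    random_forest = randomForest::randomForest(x, y, ntree = hp$ntree),
    logistic_regression = {
      df <- data.frame(x, .y = y, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = hp$eta,
                    max_depth = hp$max_depth, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = as.integer(y == "PD")),
      nrounds = hp$nrounds, verbose = 0),
    adaboost = fit_adaboost(x, y, n_stumps = hp$n_stumps),
    lightgbm = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = hp$eta,
                    tree_method = "hist", grow_policy = "lossguide",
                    max_leaves = hp$max_leaves, max_depth = 0, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = as.integer(y == "PD")),
      nrounds = hp$nrounds, verbose = 0)
  ))
  structure(list(spec = spec, fit = fit, standardizer = st,
                 features = colnames(x)),
            class = "pdb_classifier")
}

#' Predict PD probability
#'
#' @param model A fitted model from [fit_classifier()].
#' @param x Numeric feature matrix with the training columns.
#' @return Numeric vector of predicted PD probabilities.
#' @export
predict_classifier <- function(model, x) {
  stopifnot(inherits(model, "pdb_classifier"))
  x <- as.matrix(x)[, model$features, drop = FALSE]
  if (!is.null(model$standardizer)) x <- apply_standardizer(x, model$standardizer)
  spec <- model$spec
  fit <- model$fit
  with_seed(derive_seed(spec$seed, 1L), switch(spec$name,
    decision_tree_c45 = {
      p <- stats::predict(fit, data.frame(x, check.names = FALSE))
      as.numeric(p[, "PD"])
    },
    knn = {
      k <- min(fit$k, nrow(fit$train))
      pr <- class::knn(fit$train, x, fit$y, k = k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "PD", win, 1 - win)
    },
    svm = {
      p <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
      as.numeric(p[, "PD"])
    },
    naive_bayes = as.numeric(stats::predict(fit, x, type = "raw")[, "PD"]),
    random_forest = as.numeric(stats::predict(fit, x, type = "prob")[, "PD"]),
    logistic_regression = as.numeric(stats::predict(
      fit, data.frame(x, check.names = FALSE), type = "response")),
    gradient_boosting = as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x))),
    adaboost = predict_adaboost(fit, x),
    lightgbm = as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x)))
  ))
}

## ---- discrete AdaBoost (SAMME) on depth-1 rpart stumps -----------------
## No installed package provides AdaBoost, so the classical reweighting loop
## is implemented directly: at round m fit a stump under case weights, set
## alpha_m = log((1-err)/err), up-weight misclassified cases, and score by
## the weighted vote. The margin is mapped through a logistic link so the
## 0.5 probability cutoff coincides with the zero-margin vote.
fit_adaboost <- function(x, y, n_stumps = 50L) {
  n <- nrow(x)
  yy <- ifelse(y == "PD", 1, -1)
  w <- rep(1 / n, n)
  df <- data.frame(x, check.names = FALSE)
  stumps <- vector("list", n_stumps)
  alphas <- numeric(n_stumps)
  used <- 0L
  for (m in seq_len(n_stumps)) {
    fit <- rpart::rpart(factor(yy) ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- ifelse(stats::predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != yy))
    if (err >= 0.5) break                 # weak learner no better than chance
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    used <- used + 1L
    stumps[[used]] <- fit
    alphas[used] <- alpha
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (err < 1e-9) break                 # perfect stump: voting is settled
  }
  if (used == 0L) {
    # degenerate data: fall back to the class prior as a constant score
    return(list(stumps = list(), alphas = numeric(0), prior = mean(yy == 1)))
  }
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)], prior = NULL)
}

predict_adaboost <- function(model, x) {
  if (!length(model$stumps)) return(rep(model$prior, nrow(x)))
  df <- data.frame(x, check.names = FALSE)
  margin <- rep(0, nrow(x))
  for (m in seq_along(model$stumps)) {
    pred <- ifelse(stats::predict(model$stumps[[m]], df, type = "class") == "1", 1, -1)
    margin <- margin + model$alphas[m] * pred
  }
  stats::plogis(2 * margin)
}
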