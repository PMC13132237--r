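#' The nine candidate classifiers
#'
#' Identifiers accepted by [fit_classifier()]:
#' `logreg_l2_cv` (ridge-penalised logistic regression, inner-CV lambda),
#' `lda_cv_shrinkage` (LDA, covariance shrinkage tuned by inner CV),
#' `lda_ledoit_wolf`, `lda_oas` (LDA with analytic shrinkage),
#' `nsc_manhattan`, `nsc_euclidean` (nearest shrunken centroid),
#' `gnb_empirical`, `gnb_fixed_priors` (Gaussian naive Bayes; fixed priors
#' use an 80-20 positive-negative split), and `decision_tree`.
#'
#' @return Character vector of classifier ids.
#' @export
classifier_ids <- function() {
  c("logreg_l2_cv", "lda_cv_shrinkage", "lda_ledoit_wolf", "lda_oas",
    "nsc_manhattan", "nsc_euclidean", "gnb_empirical", "gnb_fixed_priors",
    "decision_tree")
}

as_binary_factor <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), c("negative", "positive"))
  if (length(bad)) stop("labels must be 'positive'/'negative', got: ",
                        paste(bad, collapse = ", "))
  factor(y, levels = c("negative", "positive"))
}

# ---- LDA with shrunken pooled covariance --------------------------------

shrunken_cov <- function(S, gamma) {
  p <- ncol(S)
  (1 - gamma) * S + gamma * (sum(diag(S)) / p) * diag(p)
}

lda_core_fit <- function(X, y, gamma) {
  y <- as_binary_factor(y)
  pos <- y == "positive"
  mu1 <- colMeans(X[pos, , drop = FALSE])
  mu0 <- colMeans(X[!pos, , drop = FALSE])
  n <- nrow(X)
  Xc <- X
  Xc[pos, ] <- sweep(X[pos, , drop = FALSE], 2, mu1)
  Xc[!pos, ] <- sweep(X[!pos, , drop = FALSE], 2, mu0)
  S <- crossprod(Xc) / n  # pooled within-class covariance (MLE)
  Sg <- shrunken_cov(S, gamma)
  w <- tryCatch(solve(Sg, mu1 - mu0), error = function(e)
    solve(Sg + 1e-8 * mean(diag(Sg)) * diag(ncol(Sg)), mu1 - mu0))
  b <- -0.5 * sum((mu1 + mu0) * w) + log(mean(pos) / mean(!pos))
  list(w = w, b = b, centered = Xc, S = S, gamma = gamma)
}

# Ledoit-Wolf shrinkage intensity toward the scaled identity, computed on
# the within-class-centered rows.
ledoit_wolf_gamma <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - mu * diag(p))^2) / p
  if (d2 == 0) return(0)
  acc <- 0
  for (i in seq_len(n)) {
    M <- tcrossprod(Xc[i, ]) - S
    acc <- acc + sum(M^2)
  }
  b2 <- min(d2, acc / (n^2 * p))
  b2 / d2
}

# Oracle-approximating shrinkage intensity.
oas_gamma <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  trS <- sum(diag(S)); trS2 <- sum(S^2)
  num <- (1 - 2 / p) * trS2 + trS^2
  den <- (n + 1 - 2 / p) * (trS2 - trS^2 / p)
  if (den <= 0) return(1)
  min(1, num / den)
}

# ---- Gaussian naive Bayes -----------------------------------------------

gnb_fit <- function(X, y, priors = NULL) {
  y <- as_binary_factor(y)
  classes <- levels(y)
  stats_by <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    list(mu = colMeans(Xi), var = apply(Xi, 2, stats::var))
  })
  names(stats_by) <- classes
  eps <- 1e-9 * max(vapply(stats_by, function(s) max(s$var, 0),
                           numeric(1)), 1e-12)
  for (cl in classes) stats_by[[cl]]$var <- stats_by[[cl]]$var + eps
  if (is.null(priors))
    priors <- c(negative = mean(y == "negative"),
                positive = mean(y == "positive"))
  list(stats = stats_by, priors = priors)
}

gnb_score <- function(model, X) {
  ll <- sapply(c("negative", "positive"), function(cl) {
    s <- model$stats[[cl]]
    rowSums(sapply(seq_len(ncol(X)), function(j)
      stats::dnorm(X[, j], s$mu[j], sqrt(s$var[j]), log = TRUE))) +
      log(model$priors[[cl]])
  })
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  1 / (1 + exp(ll[, 1] - ll[, 2]))
}

# ---- Nearest (shrunken) centroid ----------------------------------------

nsc_fit <- function(X, y, metric, shrink_threshold = 0) {
  y <- as_binary_factor(y)
  centre_fun <- if (metric == "manhattan") function(m)
    apply(m, 2, stats::median) else colMeans
  cents <- t(sapply(c("negative", "positive"), function(cl)
    centre_fun(X[y == cl, , drop = FALSE])))
  if (shrink_threshold > 0) {
    overall <- colMeans(X)
    n <- nrow(X)
    pooled_var <- colSums((X - cents[as.integer(y), , drop = FALSE])^2) /
      (n - 2)
    s <- sqrt(pooled_var) + stats::median(sqrt(pooled_var))
    for (cl in rownames(cents)) {
      nk <- sum(y == cl)
      m <- sqrt(1 / nk - 1 / n)
      dev <- (cents[cl, ] - overall) / (m * s)
      dev <- sign(dev) * pmax(abs(dev) - shrink_threshold, 0)
      cents[cl, ] <- overall + m * s * dev
    }
  }
  list(centroids = cents, metric = metric)
}

nsc_score <- function(model, X) {
  dist_to <- function(cent) {
    if (model$metric == "manhattan")
      rowSums(abs(sweep(X, 2, cent)))
    else sqrt(rowSums(sweep(X, 2, cent)^2))
  }
  dist_to(model$centroids["negative", ]) -
    dist_to(model$centroids["positive", ])
}

# ---- Uniform interface --------------------------------------------------

#' Fit one of the nine classifiers
#'
#' All classifiers share a uniform surface: a numeric feature matrix, a
#' `positive`/`negative` label vector, and a continuous positive-class
#' score from [score_classifier()]. Classifiers with hyperparameter tuning
#' (`logreg_l2_cv`, `lda_cv_shrinkage`) run an internal stratified
#' cross-validation on the training data only, seeded for determinism.
#'
#' @param id Classifier id (see [classifier_ids()]).
#' @param X Numeric matrix (rows = sessions).
#' @param y Labels.
#' @param params Optional list: `maxdepth` (decision tree),
#'   `shrink_threshold` (NSC), `priors` (GNB fixed priors),
#'   `gamma_grid` (LDA CV), `inner_folds`.
#' @param seed Integer seed for internal tuning randomness.
#' @return A `tbs_classifier` model object.
#' @export
fit_classifier <- function(id, X, y, params = list(), seed = 1L) {
  X <- as.matrix(X)
  y <- as_binary_factor(y)
  if (length(unique(y)) < 2) stop("training labels are single-class")
  inner_k <- params$inner_folds %||% 5L
  fit <- switch(id,
    logreg_l2_cv = {
      if (ncol(X) >= 2) {
        set.seed(seed)
        foldid <- stratified_folds(y, min(inner_k, min(table(y))))
        cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0,
                                foldid = foldid, type.measure = "auc")
        list(kind = "glmnet", model = cv)
      } else {
        # ridge needs >= 2 predictors; single predictor: plain logistic
        df <- data.frame(y = y, X)
        list(kind = "glm", model = stats::glm(y ~ ., data = df,
                                              family = stats::binomial()))
      }
    },
    lda_cv_shrinkage = {
      grid <- params$gamma_grid %||% seq(0, 1, by = 0.1)
      set.seed(seed)
      foldid <- stratified_folds(y, min(inner_k, min(table(y))))
      auc_for <- function(g) {
        aucs <- vapply(unique(foldid), function(f) {
          tr <- foldid != f
          if (length(unique(y[tr])) < 2) return(NA_real_)
          m <- lda_core_fit(X[tr, , drop = FALSE], y[tr], g)
          sc <- as.vector(X[!tr, , drop = FALSE] %*% m$w + m$b)
          roc_auc(as.character(y[!tr]), sc)
        }, numeric(1))
        mean(aucs, na.rm = TRUE)
      }
      best <- grid[which.max(vapply(grid, auc_for, numeric(1)))]
      list(kind = "lda", model = lda_core_fit(X, y, best), gamma = best)
    },
    lda_ledoit_wolf = {
      m0 <- lda_core_fit(X, y, 0)
      g <- ledoit_wolf_gamma(m0$centered)
      list(kind = "lda", model = lda_core_fit(X, y, g), gamma = g)
    },
    lda_oas = {
      m0 <- lda_core_fit(X, y, 0)
      g <- oas_gamma(m0$centered)
      list(kind = "lda", model = lda_core_fit(X, y, g), gamma = g)
    },
    nsc_manhattan = list(kind = "nsc",
                         model = nsc_fit(X, y, "manhattan",
                                         params$shrink_threshold %||% 0)),
    nsc_euclidean = list(kind = "nsc",
                         model = nsc_fit(X, y, "euclidean",
                                         params$shrink_threshold %||% 0)),
    gnb_empirical = list(kind = "gnb", model = gnb_fit(X, y)),
    gnb_fixed_priors = list(kind = "gnb",
                            model = gnb_fit(X, y,
                                            priors = params$priors %||%
                                              c(negative = 0.2,
                                                positive = 0.8))),
    decision_tree = {
      df <- data.frame(y = y, X)
      ctl <- rpart::rpart.control(maxdepth = params$maxdepth %||% 30L,
                                  cp = 0, minsplit = 2L, minbucket = 1L,
                                  xval = 0L)
      list(kind = "rpart", model = rpart::rpart(y ~ ., data = df,
                                                method = "class",
                                                control = ctl))
    },
    stop("unknown classifier id: ", id))
  structure(c(fit, list(id = id, features = colnames(X))),
            class = "tbs_classifier")
}

#' Positive-class score of a fitted classifier
#'
#' Posterior probability where the model defines one (logistic, LDA, GNB,
#' tree); a signed distance margin for nearest-centroid models. Higher is
#' more positive; probability-type scores use a 0.5 decision threshold,
#' margin-type scores use 0.
#'
#' @param model A `tbs_classifier`.
#' @param X Feature matrix (same columns as training).
#' @return Numeric score vector.
#' @export
score_classifier <- function(model, X) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  switch(model$kind,
    glmnet = as.vector(predict(model$model, X, s = "lambda.min",
                               type = "response")),
    glm = as.vector(predict(model$model, newdata = data.frame(X),
                            type = "response")),
    lda = stats::plogis(as.vector(X %*% model$model$w + model$model$b)),
    gnb = gnb_score(model$model, X),
    nsc = nsc_score(model$model, X),
    rpart = predict(model$model, newdata = data.frame(X),
                    type = "prob")[, "positive"])
}

#' Predicted labels of a fitted classifier
#'
#' @inheritParams score_classifier
#' @return Character vector of `"positive"`/`"negative"`.
#' @export
predict_classifier <- function(model, X) {
  sc <- score_classifier(model, X)
  thr <- if (model$kind == "nsc") 0 else 0.5
  ifelse(sc >= thr, "positive", "negative")
}
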