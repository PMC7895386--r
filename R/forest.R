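#' Configuration for the random-forest ranking stage
#'
#' @param n_keep number of features kept per feature type by recursive
#'   feature elimination (default 600).
#' @param rfe_step features removed per elimination iteration (default 10).
#' @param n_forests number of train/test repetitions (default 100).
#' @param n_estimators trees per forest (default 500).
#' @param train_fraction fraction of genomes in each training split
#'   (default 3/4; the remainder is the held-out test set).
#' @param seed master seed; per-repetition seeds are derived as
#'   `seed + repetition`, so a single repetition is re-runnable.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(n_keep = 600, rfe_step = 10, n_forests = 100,
                          n_estimators = 500, train_fraction = 3 / 4,
                          seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_keep >= rfe_step,
            n_forests >= 1, n_estimators >= 1)
  structure(list(n_keep = as.integer(n_keep), rfe_step = as.integer(rfe_step),
                 n_forests = as.integer(n_forests),
                 n_estimators = as.integer(n_estimators),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "forest_config")
}

#' Recursive feature elimination with a ridge logistic classifier
#'
#' Repeatedly fits an L2-penalized logistic regression on the raw counts
#' and drops the `rfe_step` features with the smallest absolute
#' coefficients until exactly `n_keep` features remain. Constant feature
#' columns carry no signal and are dropped first (with a message). If the
#' input already has `n_keep` features or fewer, all are retained
#' untouched. The procedure is deterministic.
#'
#' @param matrix genomes x features count matrix (one feature type).
#' @param labels trait statuses (`"positive"`/`"negative"`) per genome.
#' @param config a [forest_config()].
#' @return Character vector of selected feature ids.
#' @export
rfe_select <- function(matrix, labels, config) {
  stopifnot(inherits(config, "forest_config"),
            nrow(matrix) == length(labels))
  y <- as.integer(labels == "positive")
  feats <- colnames(matrix)
  const <- apply(matrix, 2, function(col) length(unique(col)) == 1)
  if (any(const) && ncol(matrix) > config$n_keep) {
    message(sum(const), " constant feature column(s) dropped before RFE")
    feats <- feats[!const]
  }
  while (length(feats) > config$n_keep) {
    x <- matrix[, feats, drop = FALSE]
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = 1 / nrow(x), standardize = FALSE)
    beta <- abs(as.numeric(fit$beta))
    drop_n <- min(config$rfe_step, length(feats) - config$n_keep)
    ord <- order(beta, feats)   # smallest |coef| first; ties by feature id
    feats <- sort(setdiff(feats, feats[ord[seq_len(drop_n)]]))
  }
  feats
}

#' Train repeated random forests and average feature importances
#'
#' For each repetition a random `train_fraction` of the genomes is used to
#' train a classification forest (impurity importance) and the remainder
#' measures held-out accuracy. Importances are normalized to sum to 1
#' within each forest, then averaged over repetitions. A split that lacks
#' a class in the training set is resampled (with a message).
#'
#' @param matrix genomes x features count matrix (selected features).
#' @param labels trait statuses per genome; both classes must be present.
#' @param config a [forest_config()].
#' @return A list: `importance` (data frame `Feature`, `Importance`,
#'   `CV_Importance`, `Rank`) and `accuracy` (mean held-out accuracy).
#' @export
train_forests <- function(matrix, labels, config) {
  stopifnot(inherits(config, "forest_config"),
            nrow(matrix) == length(labels))
  y <- factor(labels, levels = c("negative", "positive"))
  if (length(unique(y)) < 2) stop("both trait classes must be present")
  n <- nrow(matrix)
  n_train <- max(1L, floor(config$train_fraction * n))
  if (n_train >= n) stop("train fraction leaves no held-out genomes")
  df <- as.data.frame(matrix)
  colnames(df) <- paste0("f", seq_len(ncol(matrix)))  # safe names for ranger
  imp <- matrix(NA_real_, config$n_forests, ncol(matrix))
  acc <- numeric(config$n_forests)
  for (rep in seq_len(config$n_forests)) {
    seed_r <- (config$seed + rep) %% 2147483629L
    set.seed(seed_r)
    repeat {
      idx <- sample.int(n, n_train)
      if (length(unique(y[idx])) == 2) break
      message("training split missing a class; resampling")
    }
    fit <- ranger::ranger(x = df[idx, , drop = FALSE], y = y[idx],
                          num.trees = config$n_estimators,
                          importance = "impurity", seed = seed_r,
                          num.threads = 1)
    iv <- fit$variable.importance
    iv <- pmax(iv, 0)
    imp[rep, ] <- iv / sum(iv)
    pred <- predict(fit, data = df[-idx, , drop = FALSE],
                    num.threads = 1)$predictions
    acc[rep] <- mean(pred == y[-idx])
  }
  mean_imp <- colMeans(imp)
  cv_imp <- apply(imp, 2, sd) / mean_imp
  out <- data.frame(Feature = colnames(matrix), Importance = mean_imp,
                    CV_Importance = cv_imp, stringsAsFactors = FALSE)
  out$Rank <- rank(-out$Importance, ties.method = "average")
  out <- out[order(out$Rank, out$Feature), ]
  rownames(out) <- NULL
  list(importance = out, accuracy = mean(acc))
}

#' Run the random-forest ranking stage per feature type
#'
#' EC and Pfam features are processed entirely separately: recursive
#' feature elimination down to `n_keep` features of each type, then
#' repeated forests with held-out accuracy. Importance values are only
#' comparable within a type, so ranks are per type.
#'
#' @param matrix genomes x features count matrix (both types).
#' @param labels trait statuses per genome.
#' @param config a [forest_config()].
#' @param exclude_features feature ids removed before selection (defaults
#'   to the trait-marker features, as in the enrichment stage).
#' @return A list: `importance` (combined data frame with `Feature_Type`)
#'   and `accuracy` (named vector, mean held-out accuracy per type).
#' @export
run_forest <- function(matrix, labels, config = forest_config(),
                       exclude_features = .DEFAULT_EXCLUDE) {
  excl <- unique(c(exclude_features, paste("EC", exclude_features)))
  m <- matrix[, setdiff(colnames(matrix), excl), drop = FALSE]
  types <- feature_types(colnames(m))
  res <- list(); accs <- c()
  for (ty in unique(types)) {
    mt <- m[, types == ty, drop = FALSE]
    sel <- rfe_select(mt, labels, config)
    tr <- train_forests(mt[, sel, drop = FALSE], labels, config)
    tr$importance$Feature_Type <- ty
    res[[ty]] <- tr$importance
    accs[ty] <- tr$accuracy
  }
  imp <- do.call(rbind, res)
  rownames(imp) <- NULL
  list(importance = imp[, c("Rank", "Feature_Type", "Feature", "Importance",
                            "CV_Importance")],
       accuracy = accs)
}
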