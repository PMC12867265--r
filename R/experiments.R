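# Selection and comparison protocols: per-descriptor benchmarking with a
# gradient-boosted-tree classifier, branch-combination and classical-baseline
# comparisons on an 80/20 validation split, ablation, hyperparameter grid
# search, and the paired nonparametric tests used to compare configurations.
# Every experiment records a manifest (seeds, split, settings) sufficient to
# re-create its table.

metric_names <- function() {
  c("SN", "SP", "ACC", "BACC", "PREC", "F1", "MCC", "AUC", "AUPR")
}

make_experiment_table <- function(rows, n, manifest = list()) {
  mnames <- metric_names()
  tab <- do.call(rbind, lapply(names(rows), function(nm) {
    reps <- do.call(rbind, lapply(rows[[nm]], function(r) unclass(r)[mnames]))
    means <- colMeans(reps, na.rm = TRUE)
    sds <- apply(reps, 2L, stats::sd, na.rm = TRUE)
    if (nrow(reps) == 1L) sds[] <- 0
    df <- data.frame(name = nm, stringsAsFactors = FALSE)
    for (m in mnames) {
      df[[paste0(m, "_mean")]] <- means[[m]]
      df[[paste0(m, "_sd")]] <- sds[[m]]
    }
    df
  }))
  rownames(tab) <- NULL
  tab$n <- as.integer(n)
  structure(tab, manifest = manifest,
            class = c("experiment_table", "data.frame"))
}

#' @export
print.experiment_table <- function(x, ...) {
  mnames <- metric_names()
  disp <- data.frame(name = x$name, stringsAsFactors = FALSE)
  for (m in mnames) {
    disp[[m]] <- sprintf("%.3f±%.3f", x[[paste0(m, "_mean")]],
                         x[[paste0(m, "_sd")]])
  }
  disp$n <- x$n
  print(disp, row.names = FALSE)
  invisible(x)
}

## ---- classical classifiers -------------------------------------------------

# Shared wrapper: fit one classical model and return test-set probabilities.
# Hyperparameters are fixed defaults (RBF-kernel SVM, k = 5 neighbours,
# 100-round depth-6 boosted trees, unpenalized logistic regression) recorded
# in experiment manifests.
fit_classical <- function(method, x_train, y_train, x_test, seed = 1L) {
  with_seed(derive_seed(seed, paste0("clf_", method)), {
    switch(method,
      xgb = {
        bst <- xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = 6L,
                        eta = 0.3, nthread = 1L),
          data = xgboost::xgb.DMatrix(x_train, label = y_train,
                                      nthread = 1L),
          nrounds = 100L, verbose = 0L)
        stats::predict(bst, xgboost::xgb.DMatrix(x_test, nthread = 1L))
      },
      svm = {
        fit <- e1071::svm(x_train, factor(y_train, levels = c(0L, 1L)),
                          kernel = "radial", probability = TRUE)
        pr <- stats::predict(fit, x_test, probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      },
      lr = {
        df <- as.data.frame(x_train)
        names(df) <- paste0("f", seq_len(ncol(x_train)))
        df$y <- y_train
        fit <- suppressWarnings(
          stats::glm(y ~ ., data = df, family = stats::binomial()))
        nd <- as.data.frame(x_test)
        names(nd) <- paste0("f", seq_len(ncol(x_test)))
        suppressWarnings(
          as.numeric(stats::predict(fit, nd, type = "response")))
      },
      knn = {
        pr <- class::knn(x_train, x_test,
                         cl = factor(y_train, levels = c(0L, 1L)),
                         k = 5L, prob = TRUE)
        win <- attr(pr, "prob")
        ifelse(pr == "1", win, 1 - win)
      },
      stop("unknown classical method: ", method)
    )
  })
}

baseline_manifest <- function() {
  list(svm = "RBF kernel, e1071 defaults, Platt probabilities",
       xgb = "binary:logistic, 100 rounds, max_depth 6, eta 0.3",
       lr = "unpenalized logistic regression (glm, binomial)",
       knn = "k = 5 neighbours, vote share as probability")
}

## ---- experiments -----------------------------------------------------------

#' Benchmark feature descriptors under cross-validated boosted trees
#'
#' Trains one gradient-boosted-tree classifier per descriptor under
#' stratified k-fold cross-validation and tabulates mean and standard
#' deviation of the nine metrics. The pseudo-descriptor name
#' `"embeddings"` benchmarks mean-pooled provider embeddings alongside the
#' sequence descriptors.
#'
#' @param data A [sample_set()].
#' @param descriptors Character vector of registry names (and/or
#'   `"embeddings"`).
#' @param k Number of CV folds.
#' @param seed Fold-assignment and classifier seed.
#' @param provider Required when `"embeddings"` is requested.
#' @return An `experiment_table` with one row per descriptor.
#' @export
descriptor_benchmark <- function(data, descriptors, k = 10L, seed = 1L,
                                 provider = NULL) {
  reg <- descriptor_registry()
  unknown <- setdiff(descriptors, c(names(reg), "embeddings"))
  if (length(unknown) > 0L) {
    stop("unknown descriptor(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  folds <- stratified_kfold(data, k = k, seed = seed)
  rows <- lapply(descriptors, function(nm) {
    X <- if (nm == "embeddings") {
      if (is.null(provider)) {
        stop("descriptor 'embeddings' requires a provider", call. = FALSE)
      }
      t(vapply(embed_set(provider, data), mean_pool,
               numeric(provider$dim)))
    } else {
      descriptor_matrix(data, nm)
    }
    lapply(seq_along(folds), function(f) {
      tr <- folds[[f]]$train; te <- folds[[f]]$test
      probs <- fit_classical("xgb", X[tr, , drop = FALSE], data$label[tr],
                             X[te, , drop = FALSE],
                             seed = derive_seed(seed, paste0(nm, "_f", f)))
      compute_metrics(data$label[te], probs)
    })
  })
  names(rows) <- descriptors
  make_experiment_table(rows, n = k,
                        manifest = list(protocol = "stratified k-fold CV",
                                        k = k, seed = seed,
                                        classifier = baseline_manifest()$xgb))
}

validation_split <- function(data, fraction = 0.8, seed = 1L) {
  split_dataset(data, split_spec(fraction, seed = seed),
                tags = c("train", "validation"))
}

#' Compare branch-architecture combinations
#'
#' For each (branch1, branch2) pair, trains the dual model on a stratified
#' 80/20 split of `data` and evaluates on the held-out 20%, repeated with
#' training seeds `1..repeats` (the split itself is fixed by `split_seed`).
#' Branch 1 consumes word embeddings of the integer-encoded sequence,
#' branch 2 the provider embeddings.
#'
#' @param data A [sample_set()].
#' @param combos List of 2-element character vectors
#'   (e.g. `list(c("inception", "transformer"))`).
#' @param provider An `embedding_provider`.
#' @param cfg Template [model_config()] (branch types overridden per combo).
#' @param repeats Number of seeded repeats.
#' @param split_seed Seed of the 80/20 split.
#' @param fraction Training fraction of the split.
#' @return An `experiment_table` with one row per combination.
#' @export
branch_combination_experiment <- function(data, combos, provider,
                                          cfg = model_config(),
                                          repeats = 20L, split_seed = 1L,
                                          fraction = 0.8) {
  sp <- validation_split(data, fraction, seed = split_seed)
  seeds <- seq_len(repeats)
  rows <- lapply(combos, function(cb) {
    stopifnot(length(cb) == 2L)
    cfg_i <- cfg
    cfg_i$branch1_type <- cb[1L]
    cfg_i$branch2_type <- cb[2L]
    cfg_i$branch_mode <- "dual"
    lapply(seeds, function(s) {
      tr <- train_model(sp$first, provider, cfg_i, seed = s)
      compute_metrics(sp$second$label,
                      predict(tr, sp$second, provider),
                      threshold = cfg_i$threshold)
    })
  })
  names(rows) <- vapply(combos, paste, character(1), collapse = "+")
  make_experiment_table(rows, n = repeats,
                        manifest = list(protocol = "80/20 validation",
                                        split_seed = split_seed,
                                        fraction = fraction, seeds = seeds))
}

#' Compare classical baselines on mean-pooled embeddings
#'
#' Trains SVM, XGB, logistic-regression and k-nearest-neighbour classifiers
#' on mean-pooled provider embeddings under the same 80/20 split/repeat
#' protocol as the branch comparison, so the rows are comparable to the deep
#' model's.
#'
#' @inheritParams branch_combination_experiment
#' @return An `experiment_table` with rows svm, xgb, lr, knn.
#' @export
ml_baseline_experiment <- function(data, provider, repeats = 20L,
                                   split_seed = 1L, fraction = 0.8) {
  sp <- validation_split(data, fraction, seed = split_seed)
  X <- t(vapply(embed_set(provider, data), mean_pool, numeric(provider$dim)))
  tr_idx <- match(sp$first$id, data$id)
  te_idx <- match(sp$second$id, data$id)
  seeds <- seq_len(repeats)
  methods <- c("svm", "xgb", "lr", "knn")
  rows <- lapply(methods, function(m) {
    lapply(seeds, function(s) {
      probs <- fit_classical(m, X[tr_idx, , drop = FALSE],
                             data$label[tr_idx],
                             X[te_idx, , drop = FALSE], seed = s)
      compute_metrics(data$label[te_idx], probs)
    })
  })
  names(rows) <- methods
  make_experiment_table(rows, n = repeats,
                        manifest = list(protocol = "80/20 validation",
                                        split_seed = split_seed,
                                        fraction = fraction, seeds = seeds,
                                        hyperparameters = baseline_manifest()))
}

#' Ablation: single branches versus the dual model
#'
#' Trains the inception-only, transformer-only and dual configurations on
#' `train` and evaluates on `test`, using one identical seed list for all
#' three so the comparison is controlled.
#'
#' @param train,test Disjoint [sample_set()]s.
#' @param provider An `embedding_provider`.
#' @param cfg Template [model_config()].
#' @param seeds Integer vector of training seeds shared by all rows.
#' @return An `experiment_table` with rows inception_only,
#'   transformer_only, dual.
#' @export
ablation_experiment <- function(train, test, provider, cfg = model_config(),
                                seeds = 1:5) {
  if (length(intersect(train$id, test$id)) > 0L) {
    stop("train and test sets overlap", call. = FALSE)
  }
  modes <- c("inception_only", "transformer_only", "dual")
  rows <- lapply(modes, function(md) {
    cfg_i <- cfg
    cfg_i$branch_mode <- md
    lapply(seeds, function(s) {
      tr <- train_model(train, provider, cfg_i, seed = s)
      compute_metrics(test$label, predict(tr, test, provider),
                      threshold = cfg_i$threshold)
    })
  })
  names(rows) <- modes
  make_experiment_table(rows, n = length(seeds),
                        manifest = list(protocol = "train/test ablation",
                                        seeds = seeds))
}

#' Specify the hyperparameter grid
#'
#' @param epochs,dropout_inception,dropout_other Candidate values.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(epochs = c(15L, 18L, 20L),
                      dropout_inception = c(0.3, 0.4, 0.5),
                      dropout_other = c(0.3, 0.4, 0.5)) {
  if (length(epochs) == 0L || length(dropout_inception) == 0L ||
      length(dropout_other) == 0L) {
    stop("grid candidate lists must be non-empty", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs),
                 dropout_inception = dropout_inception,
                 dropout_other = dropout_other), class = "grid_spec")
}

#' Grid search over epochs and dropout rates
#'
#' Evaluates every grid combination on an internal stratified 80/20
#' validation split of `train` and selects the combination with the best
#' joint ranking across F1, MCC, AUC and AUPR (minimum rank-sum;
#' ties broken by F1, then MCC).
#'
#' @param train A [sample_set()].
#' @param grid A [grid_spec()].
#' @param provider An `embedding_provider`.
#' @param cfg Template [model_config()].
#' @param seed Training and split seed.
#' @return List with `best_config` (a [model_config()]), `best` (its grid
#'   row) and `table` (data.frame of all combinations and their metrics).
#' @export
grid_search <- function(train, grid, provider, cfg = model_config(),
                        seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  combos <- expand.grid(epochs = grid$epochs,
                        dropout_inception = grid$dropout_inception,
                        dropout_other = grid$dropout_other,
                        KEEP.OUT.ATTRS = FALSE)
  sp <- validation_split(train, 0.8, seed = seed)
  scores <- lapply(seq_len(nrow(combos)), function(i) {
    cfg_i <- cfg
    cfg_i$epochs <- combos$epochs[i]
    cfg_i$dropout_inception <- combos$dropout_inception[i]
    cfg_i$dropout_other <- combos$dropout_other[i]
    tr <- train_model(sp$first, provider, cfg_i, seed = seed)
    compute_metrics(sp$second$label, predict(tr, sp$second, provider),
                    threshold = cfg_i$threshold)
  })
  tab <- cbind(combos, do.call(rbind, lapply(scores, function(s) {
    as.data.frame(t(unclass(s)[metric_names()]))
  })))
  best_idx <- rank_select_best(tab)
  best <- tab[best_idx, , drop = FALSE]
  cfg_best <- cfg
  cfg_best$epochs <- best$epochs
  cfg_best$dropout_inception <- best$dropout_inception
  cfg_best$dropout_other <- best$dropout_other
  list(best_config = cfg_best, best = best,
       table = structure(tab, manifest = list(seed = seed,
                                              split = "80/20 internal")))
}

# Pure selection rule on a grid-score table: minimum rank-sum over
# F1/MCC/AUC/AUPR, ties by F1 then MCC. Re-applying it to a stored table
# reproduces the choice.
rank_select_best <- function(tab) {
  sel <- c("F1", "MCC", "AUC", "AUPR")
  ranks <- sapply(sel, function(m) rank(-tab[[m]], ties.method = "average"))
  rs <- if (is.matrix(ranks)) rowSums(ranks) else sum(ranks)
  ord <- order(rs, -tab$F1, -tab$MCC)
  ord[1L]
}

## ---- statistical tests -----------------------------------------------------

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (standard convention). The null distribution is enumerated
#' exactly over all sign assignments when at most 14 non-zero pairs remain
#' (which also handles rank ties exactly); larger samples use the normal
#' approximation with tie correction. If all differences are zero the
#' p-value is reported as 1 with a degenerate flag.
#'
#' @param scores_a,scores_b Equal-length paired score vectors.
#' @return List with `p_value`, `direction` (`"a>b"`, `"a<b"` or
#'   `"none"`), `statistic` (signed-rank sum V of positive differences),
#'   `n_effective`, and `degenerate` flag.
#' @export
wilcoxon_compare <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired score vectors must have equal length", call. = FALSE)
  }
  if (length(scores_a) < 5L) {
    stop("need at least 5 paired observations", call. = FALSE)
  }
  d <- scores_a - scores_b
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0L) {
    return(list(p_value = 1, direction = "none", statistic = NA_real_,
                n_effective = 0L, degenerate = TRUE))
  }
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  mu <- n * (n + 1) / 4
  if (n <= 14L) {
    # exact: enumerate the 2^n sign assignments of the observed ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vdist <- as.numeric(signs %*% r)
    p_low <- mean(vdist <= v)
    p_high <- mean(vdist >= v)
    p <- min(1, 2 * min(p_low, p_high))
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(p_value = p,
       direction = if (v > mu) "a>b" else if (v < mu) "a<b" else "none",
       statistic = v, n_effective = n, degenerate = FALSE)
}

#' Friedman test across folds
#'
#' Nonparametric test of whether any of several conditions (columns)
#' systematically outranks the others across folds (rows).
#'
#' @param fold_metrics Numeric matrix, folds x conditions.
#' @return List with `statistic` (Friedman chi-square), `df` and `p_value`.
#' @export
friedman_across_folds <- function(fold_metrics) {
  m <- as.matrix(fold_metrics)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 folds and 2 conditions", call. = FALSE)
  }
  if (all(apply(m, 1L, function(r) length(unique(r)) == 1L))) {
    return(list(statistic = 0, df = ncol(m) - 1L, p_value = 1))
  }
  ft <- stats::friedman.test(m)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = ft$p.value)
}
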