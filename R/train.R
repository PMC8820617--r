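## Model training: feature selection by repeated-forest mean Gini
## importance, then random-forest and SVM-RBF classifiers tuned over
## the reference hyperparameter grids under repeated stratified
## cross-validation (10 folds x 5 repeats by default).

#' Upper bound for the forest's mtry parameter
#'
#' The number of descriptors sampled at each split is capped at
#' floor(sqrt(p)) where p is the descriptor count (the standard rule;
#' e.g. p = 177 gives 13), clamped to at least 1.
#'
#' @param p Descriptor count (>= 1).
#' @return An integer.
#' @export
#' @examples
#' mtry_upper_bound(177)
mtry_upper_bound <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p < 1) abort("`p` must be >= 1.")
  max(1L, as.integer(floor(sqrt(p))))
}

#' Default hyperparameter grids
#'
#' Random forest: ntree over {25, 50, 100, 200, 300, 400, 500} (the
#' scanned range is 25-500) and mtry from 5 (or lower for small p) up
#' to floor(sqrt(p)). SVM-RBF: cost over the ten powers of two from
#' 2^-2 to 2^7, and a median-heuristic sigma with multipliers
#' {0.5, 1, 2}.
#'
#' @param p Descriptor count.
#' @param ntree,mtry,cost,sigma_mult Optional overrides.
#' @return A `hyper_grid` list with `rf` and `svm` components.
#' @export
#' @examples
#' default_hyper_grid(177)$rf$mtry
default_hyper_grid <- function(p, ntree = c(25, 50, 100, 200, 300, 400, 500),
                               mtry = NULL, cost = 2^(-2:7),
                               sigma_mult = c(0.5, 1, 2)) {
  m_max <- mtry_upper_bound(p)
  if (is.null(mtry)) mtry <- seq(min(5L, m_max), m_max)
  if (any(mtry > p)) abort("mtry cannot exceed the descriptor count.")
  structure(
    list(rf = list(ntree = as.integer(ntree), mtry = as.integer(mtry)),
         svm = list(cost = cost, sigma_mult = sigma_mult)),
    class = "hyper_grid"
  )
}

#' Cross-validation control
#'
#' @param folds Number of folds (default 10).
#' @param repeats Number of repeats (default 5).
#' @return A `cv_control` list.
#' @export
cv_control <- function(folds = 10, repeats = 5) {
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats)),
            class = "cv_control")
}

## Stratified fold assignment, one list of test-index vectors per
## repeat. Repeat r is seeded with seed + r, so folds are reproducible
## and shared across every hyperparameter point of a scan (paired
## comparisons).
make_cv_folds <- function(labels, cv, seed) {
  classes <- unique(as.character(labels))
  if (length(classes) < 2L) abort("stratification error: both classes must be present.")
  if (min(table(labels)) < cv$folds) {
    abort("stratification error: a class has fewer members than folds.")
  }
  lapply(seq_len(cv$repeats), function(r) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(seed, r))
    fold_of <- integer(length(labels))
    for (cl in sort(classes)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(cv$folds), length(idx))
    }
    lapply(seq_len(cv$folds), function(k) which(fold_of == k))
  })
}

## Run one CV evaluation: `fit_fun(train_x, train_y, fold_seed)` must
## return an object usable by `pred_fun(fit, test_x)` -> labels.
cv_accuracy <- function(x, y, folds, fit_fun, pred_fun) {
  accs <- numeric(0)
  for (r in seq_along(folds)) {
    for (k in seq_along(folds[[r]])) {
      test_idx <- folds[[r]][[k]]
      fit <- fit_fun(x[-test_idx, , drop = FALSE], y[-test_idx],
                     fold_seed = r * 1000L + k)
      pred <- pred_fun(fit, x[test_idx, , drop = FALSE])
      accs <- c(accs, mean(pred == as.character(y[test_idx])))
    }
  }
  accs
}

descriptor_values <- function(matrix) {
  as.matrix(matrix[, setdiff(names(matrix), "id"), drop = FALSE])
}

as_class_factor <- function(labels) {
  factor(as.character(labels), levels = cyp_labels())
}

new_cv_result <- function(table, winner, cv, seed) {
  structure(list(table = table, winner = winner, cv = cv, seed = seed),
            class = "cv_result")
}

#' Scan the random-forest hyperparameter grid under repeated CV
#'
#' Evaluates every (ntree, mtry) point with 10-fold x 5-repeat
#' stratified cross-validation (folds shared across points). The
#' winner has the highest mean CV accuracy; ties are broken by the
#' smaller ntree, then the smaller mtry.
#'
#' @param matrix Descriptor tibble (id column first).
#' @param labels Class labels aligned with the matrix rows.
#' @param grid A [default_hyper_grid()]; its `rf` component is used.
#' @param cv A [cv_control()].
#' @param seed Integer seed.
#' @return A `cv_result`: per-point table (`ntree`, `mtry`,
#'   `mean_accuracy`, `sd_accuracy`, `n_folds`) plus the winning row.
#' @export
scan_rf_hyperparams <- function(matrix, labels, grid = NULL,
                                cv = cv_control(), seed = 2022) {
  x <- descriptor_values(matrix)
  y <- as_class_factor(labels)
  if (is.null(grid)) grid <- default_hyper_grid(ncol(x))
  folds <- make_cv_folds(y, cv, seed)
  pts <- expand.grid(ntree = grid$rf$ntree, mtry = grid$rf$mtry)
  rows <- purrr::pmap(pts, function(ntree, mtry) {
    accs <- cv_accuracy(
      x, y, folds,
      fit_fun = function(tx, ty, fold_seed) {
        fit_ranger(tx, ty, ntree, mtry, derive_seed(seed, fold_seed))
      },
      pred_fun = predict_ranger_labels
    )
    tibble::tibble(ntree = ntree, mtry = mtry,
                   mean_accuracy = mean(accs), sd_accuracy = sd(accs),
                   n_folds = length(accs))
  })
  tab <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$mean_accuracy), .data$ntree, .data$mtry)
  new_cv_result(tab, winner = tab[1, , drop = FALSE], cv = cv, seed = seed)
}

fit_ranger <- function(x, y, ntree, mtry, seed) {
  ranger::ranger(
    x = x, y = y, num.trees = ntree, mtry = min(mtry, ncol(x)),
    importance = "none", seed = seed, num.threads = 1,
    classification = TRUE
  )
}

predict_ranger_labels <- function(fit, x) {
  as.character(predict(fit, data = x, num.threads = 1)$predictions)
}

#' Mean decrease-in-Gini importance over repeated forests
#'
#' Builds `n_runs` independently seeded forests (run r uses
#' seed + r) at fixed hyperparameters and averages each descriptor's
#' decrease-in-Gini-impurity importance. Averaging over many runs
#' stabilizes the ranking, which single forests leave noisy.
#'
#' @param matrix Descriptor tibble.
#' @param labels Class labels.
#' @param params List with `ntree` and `mtry` (e.g. the scan winner).
#'   `mtry = NULL` uses [mtry_upper_bound()] of the descriptor count.
#' @param n_runs Number of forests (reference procedure: 2000; scale
#'   down for exploratory work).
#' @param seed Integer base seed.
#' @return An `importance_profile`: tibble `descriptor`, `importance`
#'   (mean decrease in Gini), sorted descending with alphabetical
#'   tie-break, plus run metadata attributes.
#' @export
mean_gini_importance <- function(matrix, labels,
                                 params = list(ntree = 100, mtry = NULL),
                                 n_runs = 2000, seed = 2022) {
  if (n_runs < 1) abort("`n_runs` must be >= 1.")
  x <- descriptor_values(matrix)
  y <- as_class_factor(labels)
  mtry <- params$mtry %||% mtry_upper_bound(ncol(x))
  total <- numeric(ncol(x))
  for (r in seq_len(n_runs)) {
    fit <- ranger::ranger(
      x = x, y = y, num.trees = params$ntree, mtry = min(mtry, ncol(x)),
      importance = "impurity", seed = derive_seed(seed, r), num.threads = 1
    )
    total <- total + fit$variable.importance
  }
  imp <- total / n_runs
  out <- tibble::tibble(descriptor = colnames(x), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$descriptor)
  structure(out, class = c("importance_profile", class(out)),
            n_runs = n_runs, params = list(ntree = params$ntree, mtry = mtry),
            seed = seed)
}

#' Select descriptors from an importance profile
#'
#' Either the `top_k` highest-importance names, or every name with
#' importance strictly above `above_threshold`; both orders are by
#' descending importance with alphabetical tie-break.
#'
#' @param profile An [mean_gini_importance()] result (or any tibble
#'   with `descriptor` and `importance`).
#' @param top_k Number of descriptors to keep.
#' @param above_threshold Importance cutoff (strict).
#' @return Ordered character vector of descriptor names.
#' @export
select_descriptors <- function(profile, top_k = NULL, above_threshold = NULL) {
  if (nrow(profile) == 0L) abort("empty importance profile.")
  if (is.null(top_k) == is.null(above_threshold)) {
    abort("supply exactly one of `top_k` or `above_threshold`.")
  }
  ord <- profile |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$descriptor)
  if (!is.null(top_k)) {
    if (top_k > nrow(ord)) abort("`top_k` exceeds the descriptor count.")
    ord$descriptor[seq_len(top_k)]
  } else {
    ord$descriptor[ord$importance > above_threshold]
  }
}

new_cyp_model <- function(algorithm, fit, params, features, scaling, seed,
                          cv_result, resub, extra = list()) {
  structure(
    c(list(algorithm = algorithm, fit = fit, params = params,
           features = features, scaling = scaling, seed = seed,
           cv_result = cv_result, resub = resub,
           version = 1L), extra),
    class = "cyp_model"
  )
}

#' Train the random-forest classifier
#'
#' Scans the (ntree, mtry) grid under repeated stratified CV, then
#' refits a single forest on the full training set at the winning
#' point. The forest consumes unscaled descriptor values.
#'
#' @inheritParams scan_rf_hyperparams
#' @return A `cyp_model` bundle (fit, winning hyperparameters,
#'   descriptor list, seed, CV table, resubstitution predictions).
#' @export
train_rf <- function(matrix, labels, grid = NULL, cv = cv_control(),
                     seed = 2022) {
  x <- descriptor_values(matrix)
  if (ncol(x) < 2L) abort("need at least 2 descriptors.")
  y <- as_class_factor(labels)
  scan <- scan_rf_hyperparams(matrix, labels, grid, cv, seed)
  w <- scan$winner
  fit <- ranger::ranger(
    x = x, y = y, num.trees = w$ntree, mtry = w$mtry,
    importance = "impurity", seed = derive_seed(seed, 999983L),
    num.threads = 1
  )
  model <- new_cyp_model(
    "rf", fit, params = list(ntree = w$ntree, mtry = w$mtry),
    features = colnames(x), scaling = NULL, seed = seed,
    cv_result = scan, resub = NULL
  )
  model$resub <- predict(model, matrix)
  model
}

## Median-heuristic RBF sigma (kernlab parameterization,
## k(x, y) = exp(-sigma * |x - y|^2)): inverse of the median pairwise
## squared euclidean distance, computed on up to 500 seeded sample rows.
median_sigma <- function(x, seed) {
  n <- nrow(x)
  idx <- seq_len(n)
  if (n > 500L) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(seed, 424243L))
    idx <- sort(sample(n, 500L))
  }
  d2 <- as.numeric(stats::dist(x[idx, , drop = FALSE]))^2
  d2 <- d2[d2 > 0]
  if (length(d2) == 0L) abort("degenerate data: all rows identical.")
  1 / median(d2)
}

#' Train the RBF-kernel support vector classifier
#'
#' Requires standardized inputs (each column mean 0, sd 1) with the
#' fitted scaling parameters attached, so that screening data can be
#' scaled identically at prediction time. The cost parameter is tuned
#' over 2^-2 ... 2^7 and the kernel width over a median-heuristic
#' sigma with multipliers {0.5, 1, 2}, under the same repeated
#' stratified CV as the forest; ties go to the smaller cost, then the
#' smaller sigma.
#'
#' @param matrix Standardized descriptor tibble.
#' @param labels Class labels.
#' @param scaling The [standardize()] parameters used on `matrix`.
#' @param grid A [default_hyper_grid()]; its `svm` component is used.
#' @param cv A [cv_control()].
#' @param seed Integer seed.
#' @return A `cyp_model` bundle storing the scaling parameters.
#' @export
train_svm_rbf <- function(matrix, labels, scaling, grid = NULL,
                          cv = cv_control(), seed = 2022) {
  x <- descriptor_values(matrix)
  y <- as_class_factor(labels)
  mu <- colMeans(x); sds <- apply(x, 2, sd)
  if (any(abs(mu) > 1e-6) || any(abs(sds - 1) > 1e-6)) {
    abort("inputs are not standardized; run standardize() first.")
  }
  if (is.null(scaling) || !all(colnames(x) %in% scaling$column)) {
    abort("`scaling` must provide the ScalingParams fitted on this matrix.")
  }
  if (is.null(grid)) grid <- default_hyper_grid(ncol(x))
  folds <- make_cv_folds(y, cv, seed)
  sigma0 <- median_sigma(x, seed)
  pts <- expand.grid(cost = grid$svm$cost, sigma = sigma0 * grid$svm$sigma_mult)
  rows <- purrr::pmap(pts, function(cost, sigma) {
    accs <- cv_accuracy(
      x, y, folds,
      fit_fun = function(tx, ty, fold_seed) {
        fit_ksvm(tx, ty, cost, sigma, derive_seed(seed, fold_seed))
      },
      pred_fun = function(fit, nx) as.character(kernlab::predict(fit, nx))
    )
    tibble::tibble(cost = cost, sigma = sigma,
                   mean_accuracy = mean(accs), sd_accuracy = sd(accs),
                   n_folds = length(accs))
  })
  tab <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$mean_accuracy), .data$cost, .data$sigma)
  scan <- new_cv_result(tab, winner = tab[1, , drop = FALSE], cv = cv, seed = seed)
  w <- scan$winner
  fit <- fit_ksvm(x, y, w$cost, w$sigma, derive_seed(seed, 999983L))
  ## logistic link on training decision values, for auxiliary scores
  dec <- kernlab::predict(fit, x, type = "decision")[, 1]
  calib <- suppressWarnings(glm((y == cyp_labels()[1]) ~ dec, family = binomial()))
  model <- new_cyp_model(
    "svm_rbf", fit, params = list(cost = w$cost, sigma = w$sigma),
    features = colnames(x), scaling = scaling, seed = seed,
    cv_result = scan, resub = NULL,
    extra = list(calibration = unname(coef(calib)))
  )
  model$resub <- predict_cyp(model, matrix, apply_scaling = FALSE)
  model
}

fit_ksvm <- function(x, y, cost, sigma, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  kernlab::ksvm(
    x = x, y = y, type = "C-svc", kernel = "rbfdot",
    kpar = list(sigma = sigma), C = cost, scaled = FALSE
  )
}

#' Predict class labels and scores with a trained bundle
#'
#' The matrix must contain every descriptor the bundle was trained on;
#' extra columns are ignored, missing ones raise an error naming them.
#' For the SVM path the bundle's stored scaling is applied internally,
#' so raw (unscaled) values are expected. Scores are the fraction of
#' tree votes (forest) or a logistic transform of the decision value
#' (SVM).
#'
#' @param object A `cyp_model`.
#' @param matrix Descriptor tibble (id column first).
#' @param ... Unused.
#' @return Tibble `id`, `.pred_label`, `.pred_score` (row order
#'   preserved; score = probability-like support for the inhibitor
#'   class).
#' @export
predict.cyp_model <- function(object, matrix, ...) {
  missing_cols <- setdiff(object$features, names(matrix))
  if (length(missing_cols) > 0L) {
    abort(sprintf("matrix lacks descriptor column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  predict_cyp(object, matrix, apply_scaling = TRUE)
}

## Internal prediction; `apply_scaling = FALSE` is used when the input
## is already on the standardized scale (training resubstitution).
predict_cyp <- function(object, matrix, apply_scaling = TRUE) {
  x <- as.matrix(matrix[, object$features, drop = FALSE])
  if (object$algorithm == "svm_rbf") {
    if (apply_scaling) {
      sc <- object$scaling
      sc <- sc[match(object$features, sc$column), ]
      x <- sweep(sweep(x, 2, sc$mean), 2, sc$sd, "/")
    }
    labels <- as.character(kernlab::predict(object$fit, x))
    dec <- kernlab::predict(object$fit, x, type = "decision")[, 1]
    eta <- object$calibration[1] + object$calibration[2] * dec
    score <- 1 / (1 + exp(-eta))
  } else {
    # fits restored from disk need the backend's S3 methods registered
    requireNamespace("ranger", quietly = TRUE)
    pred <- predict(object$fit, data = x, num.threads = 1)
    labels <- as.character(pred$predictions)
    all_votes <- predict(object$fit, data = x, predict.all = TRUE,
                         num.threads = 1)$predictions
    ## ranger encodes classes as integers in factor-level order
    score <- rowMeans(all_votes == 1L)
  }
  tibble::tibble(id = matrix$id, .pred_label = labels, .pred_score = score)
}

#' Save / load a model bundle
#'
#' Bundles persist as a versioned RDS archive; loading refuses a
#' bundle whose schema version differs from the current one.
#'
#' @param object A `cyp_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the
#'   restored `cyp_model`.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "cyp_model"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "cyp_model")) abort("file does not contain a model bundle.")
  if (!identical(obj$version, 1L)) {
    abort(sprintf("bundle schema version %s is not supported.", obj$version))
  }
  obj
}

#' @export
print.cyp_model <- function(x, ...) {
  cat(sprintf("<cyp_model: %s>\n", x$algorithm))
  cat("  features:", length(x$features), "\n")
  cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                         collapse = ", "), "\n")
  cat(sprintf("  CV accuracy: %.4f (sd %.4f)\n",
              x$cv_result$winner$mean_accuracy, x$cv_result$winner$sd_accuracy))
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d x %d CV, %d grid points>\n",
              x$cv$folds, x$cv$repeats, nrow(x$table)))
  print(x$winner)
  invisible(x)
}
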