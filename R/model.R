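FEATURE_ENCODING_VERSION <- "1"

sequence_feature_names <- function() {
  c("mm_total",
    sprintf("mm_pos_%02d", 1:23),
    "n_transition", "n_transversion",
    "pam_NGG", "pam_NAG_NGA", "pam_other",
    sprintf("sub_%s_%s",
            rep(DNA_BASES, each = 4)[rep(DNA_BASES, each = 4) !=
                                       rep(DNA_BASES, 4)],
            rep(DNA_BASES, 4)[rep(DNA_BASES, each = 4) !=
                                rep(DNA_BASES, 4)]),
    "gc_site",
    "mm_pos_min", "mm_pos_max", "mm_pos_mean",
    "seed_mm", "pam_mm",
    "max_homopolymer", "cpg_count",
    "win_A", "win_C",
    "mm_weight",
    sprintf("reserved_%02d", 1:10))
}

#' Names and layout of the 75 model input features
#'
#' The model consumes a fixed, versioned 75-feature encoding per site: a
#' 62-feature sequence block (total mismatch count; per-position mismatch
#' indicators over positions 1-23; transition and transversion counts; a
#' 3-way PAM one-hot over NGG / NAG- or NGA-like / other; counts of the 12
#' ordered base substitutions target->site; site GC; min/max/mean mismatch
#' position; seed-region (11-20) and PAM-region (21-23) mismatch counts;
#' maximum homopolymer run; CpG dinucleotide count; editing-window A and C
#' counts; a distance-weighted mismatch score `sum(1/position)`; and ten
#' reserved zero-filled slots) followed by the 13 chromatin feature scores.
#'
#' @return Character vector of length 75 in encoding order.
#' @export
model_feature_names <- function() {
  c(sequence_feature_names(), chromatin_feature_names())
}

max_run_length <- function(seqs) {
  vapply(strsplit(seqs, NULL), function(s) max(rle(s)$lengths), integer(1))
}

#' Encode sites into the 75-feature model input
#'
#' Deterministically encodes each site's mismatch profile (relative to
#' `target23`), sequence composition, and chromatin scores into the fixed
#' 75-column layout of [model_feature_names()].
#'
#' @param sites Site tibble from [enumerate_offtargets()].
#' @param feature_matrix Chromatin feature tibble from [score_sites()] with
#'   all 13 features; sites missing from it (or missing features) raise an
#'   error unless `impute_zero = TRUE`.
#' @param target23 The target sequence the sites were enumerated against.
#' @param edit_window_start,edit_window_width Editing window (within the
#'   protospacer, 1-based) used for the window A/C counts.
#' @param impute_zero Fill missing chromatin scores with 0 instead of
#'   erroring.
#' @return Tibble with `site_id` plus 75 numeric columns; encoding version
#'   in the `encoding_version` attribute.
#' @export
encode_features <- function(sites, feature_matrix, target23,
                            edit_window_start = 4L, edit_window_width = 5L,
                            impute_zero = FALSE) {
  target23 <- assert_dna(target23)
  tl <- nchar(target23)
  tchars <- strsplit(target23, NULL)[[1]]
  n <- nrow(sites)
  plist <- parse_mismatch_positions(sites$mismatch_positions)
  schars <- strsplit(sites$site23, NULL)

  pos_ind <- matrix(0, n, 23, dimnames = list(NULL, sprintf("mm_pos_%02d", 1:23)))
  for (i in seq_len(n)) pos_ind[i, plist[[i]]] <- 1

  is_transition <- function(a, b) {
    (a == "A" & b == "G") | (a == "G" & b == "A") |
      (a == "C" & b == "T") | (a == "T" & b == "C")
  }
  sub_names <- grep("^sub_", sequence_feature_names(), value = TRUE)
  subs <- matrix(0, n, 12, dimnames = list(NULL, sub_names))
  n_ts <- numeric(n); n_tv <- numeric(n)
  for (i in seq_len(n)) {
    p <- plist[[i]]
    if (length(p) == 0) next
    fr <- tchars[p]; to <- schars[[i]][p]
    ts <- is_transition(fr, to)
    n_ts[i] <- sum(ts); n_tv[i] <- sum(!ts)
    key <- sprintf("sub_%s_%s", fr, to)
    tab <- table(key)
    subs[i, names(tab)] <- as.numeric(tab)
  }

  pam2 <- substr(sites$site23, tl - 1L, tl - 1L)
  pam3 <- substr(sites$site23, tl, tl)
  pam_ngg <- as.numeric(pam2 == "G" & pam3 == "G")
  pam_nag <- as.numeric((pam2 == "A" & pam3 == "G") |
                          (pam2 == "G" & pam3 == "A"))
  pam_other <- as.numeric(pam_ngg == 0 & pam_nag == 0)

  mm_min <- vapply(plist, function(p) if (length(p)) min(p) else 0L, integer(1))
  mm_max <- vapply(plist, function(p) if (length(p)) max(p) else 0L, integer(1))
  mm_mean <- vapply(plist, function(p) if (length(p)) mean(p) else 0, numeric(1))
  seed_mm <- vapply(plist, function(p) sum(p >= 11 & p <= 20), numeric(1))
  pam_mm <- vapply(plist, function(p) sum(p >= 21), numeric(1))
  mm_weight <- vapply(plist, function(p) sum(1 / p), numeric(1))

  win <- substr(sites$site23, edit_window_start,
                edit_window_start + edit_window_width - 1L)

  seq_block <- tibble(
    mm_total = as.numeric(sites$mismatch_count)
  ) %>%
    dplyr::bind_cols(as_tibble(pos_ind)) %>%
    mutate(n_transition = n_ts, n_transversion = n_tv,
           pam_NGG = pam_ngg, pam_NAG_NGA = pam_nag, pam_other = pam_other) %>%
    dplyr::bind_cols(as_tibble(subs)) %>%
    mutate(
      gc_site = gc_content(sites$site23),
      mm_pos_min = as.numeric(mm_min), mm_pos_max = as.numeric(mm_max),
      mm_pos_mean = mm_mean,
      seed_mm = seed_mm, pam_mm = pam_mm,
      max_homopolymer = as.numeric(max_run_length(sites$site23)),
      cpg_count = stringr::str_count(sites$site23, "(?=CG)"),
      win_A = stringr::str_count(win, "A"),
      win_C = stringr::str_count(win, "C"),
      mm_weight = mm_weight
    )
  for (r in sprintf("reserved_%02d", 1:10)) seq_block[[r]] <- 0

  chrom_cols <- chromatin_feature_names()
  fm <- feature_matrix[match(sites$site_id, feature_matrix$site_id), , drop = FALSE]
  missing_sites <- is.na(fm$site_id)
  missing_cols <- setdiff(chrom_cols, names(fm))
  if ((any(missing_sites) || length(missing_cols) > 0) && !impute_zero) {
    stop("chromatin features missing for ",
         sum(missing_sites), " site(s)",
         if (length(missing_cols) > 0)
           paste0(" and feature(s): ", paste(missing_cols, collapse = ", ")),
         "; set impute_zero = TRUE to zero-fill", call. = FALSE)
  }
  chrom_block <- as_tibble(setNames(
    lapply(chrom_cols, function(f) {
      v <- if (f %in% names(fm)) as.numeric(fm[[f]]) else rep(NA_real_, n)
      v[is.na(v)] <- 0
      v
    }),
    chrom_cols))

  out <- dplyr::bind_cols(tibble(site_id = sites$site_id), seq_block,
                          chrom_block)
  stopifnot(identical(setdiff(names(out), "site_id"), model_feature_names()),
            ncol(out) == 76L)
  attr(out, "encoding_version") <- FEATURE_ENCODING_VERSION
  out
}

#' Stratified train/test split
#'
#' Splits the data into a training fraction and its complement, stratified
#' by the label so class proportions in the training set stay within one
#' sample of the global proportions. The training size is exactly
#' `round(train_fraction * n)`. With degenerate strata (a class with a
#' single row), the split falls back to unstratified sampling with a
#' warning.
#'
#' @param data Tibble with a label column.
#' @param label_col Name of the (logical or two-level) label column.
#' @param train_fraction Fraction in the training set (default 0.8).
#' @param seed Integer seed; recorded in the result.
#' @return List with `train`, `test`, `seed`, `train_fraction`.
#' @export
split_data <- function(data, label_col = "edited", train_fraction = 0.8,
                       seed = 1L) {
  stopifnot(label_col %in% names(data), nrow(data) >= 5)
  n <- nrow(data)
  n_train <- round(train_fraction * n)
  lab <- data[[label_col]]
  classes <- unique(lab)
  idx <- withr::with_seed(seed, {
    if (any(table(lab) < 2)) {
      warning("a class has fewer than 2 rows; falling back to an ",
              "unstratified split", call. = FALSE)
      sample(n, n_train)
    } else {
      # per-class counts via largest remainder so the total is exact
      quota <- train_fraction * table(lab)[as.character(classes)]
      take <- floor(quota)
      rem <- n_train - sum(take)
      if (rem > 0) {
        ord <- order(quota - take, decreasing = TRUE)
        take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
      } else if (rem < 0) {
        ord <- order(quota - take)
        take[ord[seq_len(-rem)]] <- take[ord[seq_len(-rem)]] - 1
      }
      unlist(lapply(seq_along(classes), function(k) {
        pool <- which(lab == classes[k])
        sample(pool, take[k])
      }))
    }
  })
  list(train = data[sort(idx), , drop = FALSE],
       test = data[setdiff(seq_len(n), idx), , drop = FALSE],
       seed = seed, train_fraction = train_fraction)
}

#' Hyperparameter grids for the off-target model
#'
#' `"full"` is the reference boosting grid (`n_estimators` 50/100/150/200/
#' 250/500, `max_depth` 3/5/7/9/12/15, `learning_rate` 0.001/0.01/0.05/0.1/
#' 0.2, `subsample` 0.6/0.8/1.0, `colsample_bytree` 0.6/0.8/1.0; 1620
#' combinations). `"fast"` is a small grid for interactive use and tests.
#'
#' @param type `"full"` or `"fast"`.
#' @return Named list of candidate values per hyperparameter.
#' @export
model_grid <- function(type = c("fast", "full")) {
  type <- match.arg(type)
  if (type == "full") {
    list(n_estimators = c(50, 100, 150, 200, 250, 500),
         max_depth = c(3, 5, 7, 9, 12, 15),
         learning_rate = c(0.001, 0.01, 0.05, 0.1, 0.2),
         subsample = c(0.6, 0.8, 1.0),
         colsample_bytree = c(0.6, 0.8, 1.0))
  } else {
    list(n_estimators = c(50, 100),
         max_depth = c(3, 5),
         learning_rate = 0.1,
         subsample = 1.0,
         colsample_bytree = 1.0)
  }
}

#' Number of combinations in a hyperparameter grid
#'
#' @param grid A grid from [model_grid()] (or any named list of vectors).
#' @return Integer product of the per-parameter candidate counts.
#' @export
grid_cardinality <- function(grid) {
  prod(vapply(grid, length, integer(1)))
}

fit_one <- function(X, y, params, method, seed, nthread = 1L) {
  if (method == "gbdt") {
    withr::with_seed(seed, {
      xgboost::xgb.train(
        data = xgboost::xgb.DMatrix(X, label = as.numeric(y), nthread = nthread),
        nrounds = params$n_estimators,
        params = list(
          objective = "binary:logistic",
          max_depth = params$max_depth,
          eta = params$learning_rate,
          subsample = params$subsample,
          colsample_bytree = params$colsample_bytree,
          nthread = nthread
        ),
        verbose = 0
      )
    })
  } else {
    withr::with_seed(seed, {
      randomForest::randomForest(
        x = as.data.frame(X), y = factor(y, levels = c(FALSE, TRUE)),
        ntree = params$n_estimators,
        maxnodes = if (is.null(params$max_depth)) NULL
                   else 2^params$max_depth,
        importance = FALSE
      )
    })
  }
}

predict_prob <- function(fit, method, X) {
  if (method == "gbdt") {
    predict(fit, X)
  } else {
    predict(fit, as.data.frame(X), type = "prob")[, "TRUE"]
  }
}

#' Train the off-target prediction model
#'
#' Grid-searches the hyperparameters on a held-out validation fold carved
#' from the training data (stratified), refits the best combination
#' (highest validation accuracy; ties broken by grid order) on the full
#' training set, and returns the fitted model. The primary backend is
#' gradient-boosted trees (the grid is a boosting grid); a random-forest
#' backend is available with the grid restricted to its applicable
#' parameters.
#'
#' @param train Tibble of encoded features (from [encode_features()], with
#'   or without `site_id`) plus the label column.
#' @param label_col Name of the logical label column (default `"edited"`).
#' @param grid Hyperparameter grid (see [model_grid()]).
#' @param method `"gbdt"` (gradient boosting, default) or `"rf"` (random
#'   forest).
#' @param valid_fraction Fraction of `train` held out for model selection.
#' @param seed Integer seed controlling the validation split and the
#'   stochastic parts of fitting.
#' @param nthread Threads for the boosting backend (default 1, which also
#'   makes fits reproducible).
#' @return Object of class `offtarget_model`: list with `fit`, `method`,
#'   `best_params`, `search` (per-combination validation accuracy),
#'   `feature_names`, `label_col`, `seed`, `n_train`, `class_balance`.
#' @export
train_offtarget_model <- function(train, label_col = "edited",
                                  grid = model_grid("fast"),
                                  method = c("gbdt", "rf"),
                                  valid_fraction = 0.25, seed = 1L,
                                  nthread = 1L) {
  method <- match.arg(method)
  stopifnot(label_col %in% names(train))
  y <- as.logical(train[[label_col]])
  if (length(unique(y)) < 2) {
    stop("training data contains a single class; cannot fit a classifier",
         call. = FALSE)
  }
  feature_names <- setdiff(names(train), c(label_col, "site_id"))
  X <- as.matrix(train[, feature_names, drop = FALSE])
  storage.mode(X) <- "double"

  if (method == "rf") {
    grid <- grid[intersect(names(grid), c("n_estimators", "max_depth"))]
  }
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)

  sp <- split_data(tibble(.row = seq_len(nrow(X)), lab = y),
                   label_col = "lab", train_fraction = 1 - valid_fraction,
                   seed = seed)
  fit_idx <- sp$train$.row
  val_idx <- sp$test$.row

  acc <- numeric(nrow(combos))
  for (k in seq_len(nrow(combos))) {
    fit <- fit_one(X[fit_idx, , drop = FALSE], y[fit_idx],
                   as.list(combos[k, ]), method, seed, nthread)
    p <- predict_prob(fit, method, X[val_idx, , drop = FALSE])
    acc[k] <- mean((p > 0.5) == y[val_idx])
  }
  best <- which.max(acc)
  best_params <- as.list(combos[best, ])
  final <- fit_one(X, y, best_params, method, seed, nthread)

  structure(
    list(fit = final, method = method, best_params = best_params,
         search = as_tibble(combos) %>% mutate(validation_accuracy = acc),
         feature_names = feature_names, label_col = label_col, seed = seed,
         n_train = nrow(X),
         class_balance = c(edited = sum(y), unedited = sum(!y))),
    class = "offtarget_model"
  )
}

#' @export
predict.offtarget_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  predict_prob(object$fit, object$method, X)
}

#' Evaluate a fitted off-target model on held-out data
#'
#' Computes test accuracy (percent, two decimals, half-up), the ROC curve
#' and its area, and normalised feature importances (gain for boosting,
#' Gini decrease for random forest; zero for unused features; sums to 1).
#' The aggregate importance of the 13-chromatin-feature block is reported
#' alongside. A one-class test set yields a defined accuracy but `NA` AUC.
#'
#' @param model An `offtarget_model` from [train_offtarget_model()].
#' @param test Tibble of encoded features plus the label column.
#' @return Object of class `model_report`: list with `accuracy_pct`, `auc`,
#'   `roc` (tibble of `threshold`, `fpr`, `tpr`), `importance` (tibble of
#'   `feature`, `importance`), `chromatin_block_importance`, `n_test`,
#'   `confusion`.
#' @export
evaluate_model <- function(model, test) {
  stopifnot(nrow(test) > 0, model$label_col %in% names(test))
  y <- as.logical(test[[model$label_col]])
  p <- predict(model, test)
  pred <- p > 0.5
  accuracy <- round_half_up(100 * mean(pred == y), 2)

  if (length(unique(y)) == 2) {
    roc_obj <- pROC::roc(response = y, predictor = p, quiet = TRUE,
                         direction = "<", levels = c(FALSE, TRUE))
    auc <- as.numeric(pROC::auc(roc_obj))
    roc_tbl <- tibble(
      threshold = roc_obj$thresholds,
      fpr = 1 - roc_obj$specificities,
      tpr = roc_obj$sensitivities
    ) %>% arrange(.data$fpr, .data$tpr)
  } else {
    auc <- NA_real_
    roc_tbl <- tibble(threshold = numeric(), fpr = numeric(), tpr = numeric())
  }

  imp <- setNames(numeric(length(model$feature_names)), model$feature_names)
  if (model$method == "gbdt") {
    it <- xgboost::xgb.importance(model = model$fit)
    imp[it$Feature] <- it$Gain
  } else {
    gi <- randomForest::importance(model$fit)[, "MeanDecreaseGini"]
    imp[names(gi)] <- gi
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp_tbl <- tibble(feature = names(imp), importance = as.numeric(imp)) %>%
    arrange(desc(.data$importance))

  structure(
    list(accuracy_pct = accuracy, auc = auc, roc = roc_tbl,
         importance = imp_tbl,
         chromatin_block_importance =
           sum(imp[intersect(chromatin_feature_names(), names(imp))]),
         n_test = nrow(test),
         confusion = table(predicted = pred, observed = y)),
    class = "model_report"
  )
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report>  n_test = ", x$n_test, "\n", sep = "")
  cat("  accuracy: ", sprintf("%.2f%%", x$accuracy_pct),
      "   AUC: ", ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)), "\n",
      sep = "")
  cat("  chromatin block importance: ",
      sprintf("%.4f", x$chromatin_block_importance), "\n", sep = "")
  cat("  top features:\n")
  print(as.data.frame(head(x$importance, 5)), row.names = FALSE)
  invisible(x)
}

#' @export
print.offtarget_model <- function(x, ...) {
  cat("<offtarget_model> method = ", x$method, ", n_train = ", x$n_train,
      "\n  best params: ",
      paste(names(x$best_params), unlist(x$best_params), sep = "=",
            collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy the feature importances of a fitted model
#'
#' Requires the model to have been evaluated; pass the `model_report`.
#'
#' @param x A `model_report` from [evaluate_model()].
#' @param ... Unused.
#' @return Tibble of `feature`, `importance` (descending).
#' @export
tidy.model_report <- function(x, ...) x$importance

#' @export
glance.model_report <- function(x, ...) {
  tibble(accuracy_pct = x$accuracy_pct, auc = x$auc, n_test = x$n_test,
         chromatin_block_importance = x$chromatin_block_importance)
}

#' @export
glance.offtarget_model <- function(x, ...) {
  as_tibble(x$best_params) %>%
    mutate(method = x$method, n_train = x$n_train, seed = x$seed,
           .before = 1)
}

#' @export
tidy.offtarget_model <- function(x, ...) {
  x$search %>% arrange(desc(.data$validation_accuracy))
}
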