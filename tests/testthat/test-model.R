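fake_sites <- function(n, target, seed) {
  withr::with_seed(seed, {
    tch <- strsplit(target, NULL)[[1]]
    rows <- lapply(seq_len(n), function(i) {
      k <- sample(0:6, 1)
      pos <- sort(sample(23, k))
      sc <- tch
      for (p in pos) sc[p] <- sample(setdiff(c("A", "C", "G", "T"), sc[p]), 1)
      s23 <- paste(sc, collapse = "")
      tibble::tibble(
        site_id = sprintf("s%05d", i), chrom = "chr1",
        start = i * 100L, end = i * 100L + 23L, strand = "+",
        site23 = s23, mismatch_count = length(pos),
        mismatch_positions = paste(pos, collapse = ","),
        pam_class = ifelse(substr(s23, 22, 23) == "GG", "NGG", "non-NGG")
      )
    })
    dplyr::bind_rows(rows)
  })
}

fake_chromatin <- function(site_ids, seed) {
  withr::with_seed(seed, {
    out <- tibble::tibble(site_id = site_ids)
    for (f in chromatin_feature_names()) out[[f]] <- rnorm(length(site_ids))
    out
  })
}

test_that("the encoding has exactly 75 deterministic features", {
  target <- random_target(301)
  sites <- fake_sites(40, target, seed = 302)
  fm <- fake_chromatin(sites$site_id, seed = 303)
  enc <- encode_features(sites, fm, target)
  expect_equal(setdiff(names(enc), "site_id"), model_feature_names())
  expect_equal(length(model_feature_names()), 75)
  expect_identical(attr(enc, "encoding_version"), "1")
  # bit-identical across calls
  expect_identical(enc, encode_features(sites, fm, target))
})

test_that("encoding values follow the documented layout", {
  target <- random_target(311)
  tch <- strsplit(target, NULL)[[1]]
  # 0-mismatch NGG site
  on <- paste(c(tch[1:21], "G", "G"), collapse = "")
  # site with mismatches at positions 2 and 19
  sc <- tch
  sc[2] <- setdiff(c("A", "C", "G", "T"), sc[2])[1]
  sc[19] <- setdiff(c("A", "C", "G", "T"), sc[19])[1]
  two <- paste(sc, collapse = "")
  sites <- tibble::tibble(
    site_id = c("on", "two"), chrom = "chr1", start = c(0L, 100L),
    end = c(23L, 123L), strand = "+",
    site23 = c(on, two),
    mismatch_count = c(sum(strsplit(on, NULL)[[1]] != tch), 2L),
    mismatch_positions = c(paste(which(strsplit(on, NULL)[[1]] != tch),
                                 collapse = ","), "2,19"),
    pam_class = c("NGG", ifelse(substr(two, 22, 23) == "GG", "NGG", "non-NGG"))
  )
  fm <- fake_chromatin(sites$site_id, seed = 312)
  enc <- encode_features(sites, fm, target)
  on_row <- enc[enc$site_id == "on", ]
  if (sites$mismatch_count[1] == 0) {
    expect_equal(on_row$mm_total, 0)
    expect_true(all(as.numeric(on_row[sprintf("mm_pos_%02d", 1:23)]) == 0))
    expect_equal(as.numeric(on_row[c("pam_NGG", "pam_NAG_NGA", "pam_other")]),
                 c(1, 0, 0))
  }
  two_row <- enc[enc$site_id == "two", ]
  expect_equal(two_row$mm_total, 2)
  expect_equal(as.numeric(two_row[c("mm_pos_02", "mm_pos_19")]), c(1, 1))
  expect_equal(sum(as.numeric(two_row[sprintf("mm_pos_%02d", 1:23)])), 2)
  expect_equal(two_row$mm_pos_min, 2)
  expect_equal(two_row$mm_pos_max, 19)
  expect_equal(two_row$mm_pos_mean, 10.5)
  expect_equal(two_row$mm_weight, 1 / 2 + 1 / 19)
  expect_equal(two_row$seed_mm, 1)   # only position 19 is in 11-20
  expect_equal(two_row$pam_mm, 0)
  expect_equal(two_row$n_transition + two_row$n_transversion, 2)
  expect_equal(sum(as.numeric(two_row[grep("^sub_", names(enc))])), 2)
  expect_true(all(as.numeric(two_row[sprintf("reserved_%02d", 1:10)]) == 0))
  expect_equal(two_row$gc_site, gc_content(two))
  # chromatin block carries the scores through unchanged
  expect_equal(two_row$DNase, fm$DNase[fm$site_id == "two"])
  # missing chromatin features error unless zero-imputation is requested
  expect_error(encode_features(sites, fm[, 1:5], target), "missing")
  enc0 <- encode_features(sites, fm[, 1:5], target, impute_zero = TRUE)
  expect_equal(enc0$FPKM, c(0, 0))
})

test_that("the stratified split has exact sizes and is reproducible", {
  withr::with_seed(1, {
    ds <- tibble::tibble(x = rnorm(100),
                         edited = rep(c(TRUE, FALSE), c(30, 70)))
  })
  sp <- split_data(ds, "edited", 0.8, seed = 5)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_equal(sum(sp$train$edited), 24)  # 30 * 0.8
  sp2 <- split_data(ds, "edited", 0.8, seed = 5)
  expect_identical(sp$train, sp2$train)
  sp3 <- split_data(ds, "edited", 0.8, seed = 6)
  expect_false(identical(sp$train, sp3$train))
  # n = 10 splits 8/2 deterministically
  small <- ds[c(1:5, 31:35), ]
  sps <- split_data(small, "edited", 0.8, seed = 3)
  expect_equal(nrow(sps$train), 8)
  # stratification keeps train proportions within one sample of global
  p_global <- mean(ds$edited)
  expect_lte(abs(sum(sp$train$edited) - p_global * 80), 1)
})

test_that("the full grid has 1620 combinations and fast grids stay inside", {
  expect_equal(grid_cardinality(model_grid("full")), 1620)
  g <- model_grid("fast")
  expect_true(all(names(g) %in% names(model_grid("full"))))
})

test_that("a linearly separable rule is learned perfectly", {
  target <- random_target(401)
  sites <- fake_sites(400, target, seed = 402)
  fm <- fake_chromatin(sites$site_id, seed = 403)
  enc <- encode_features(sites, fm, target)
  # planted rule: edited iff the site is DNase-accessible and <= 3
  # mismatches; accessibility is discretised so the rule is separable with
  # no test point inside the decision gap
  enc$DNase <- as.numeric(enc$DNase > 0.2)
  enc$edited <- enc$DNase > 0.5 & enc$mm_total <= 3
  sp <- split_data(enc, "edited", 0.8, seed = 404)
  mod <- train_offtarget_model(sp$train, grid = model_grid("fast"), seed = 405)
  rep <- evaluate_model(mod, sp$test)
  expect_equal(rep$accuracy_pct, 100)
  expect_equal(rep$auc, 1)
  # best hyperparameters come from the searched grid
  expect_true(mod$best_params$n_estimators %in% model_grid("fast")$n_estimators)
  expect_true(mod$best_params$max_depth %in% model_grid("fast")$max_depth)
  expect_equal(nrow(mod$search), grid_cardinality(model_grid("fast")))
  # importances normalise to 1
  expect_equal(sum(rep$importance$importance), 1, tolerance = 1e-9)
  # tidy/glance accessors
  expect_equal(nrow(tidy(rep)), 75)
  expect_true(all(c("accuracy_pct", "auc") %in% names(glance(rep))))
  expect_true("validation_accuracy" %in% names(tidy(mod)))
})

test_that("training is deterministic under a fixed seed", {
  target <- random_target(411)
  sites <- fake_sites(150, target, seed = 412)
  fm <- fake_chromatin(sites$site_id, seed = 413)
  enc <- encode_features(sites, fm, target)
  enc$edited <- enc$DNase + 0.5 * enc$mm_total + withr::with_seed(414, rnorm(150)) > 0
  sp <- split_data(enc, "edited", 0.8, seed = 1)
  m1 <- train_offtarget_model(sp$train, grid = model_grid("fast"), seed = 2)
  m2 <- train_offtarget_model(sp$train, grid = model_grid("fast"), seed = 2)
  expect_identical(m1$best_params, m2$best_params)
  expect_identical(predict(m1, sp$test), predict(m2, sp$test))
  r1 <- evaluate_model(m1, sp$test)
  r2 <- evaluate_model(m2, sp$test)
  expect_identical(r1$accuracy_pct, r2$accuracy_pct)
  expect_identical(r1$importance, r2$importance)
})

test_that("degenerate labels are handled explicitly", {
  target <- random_target(421)
  sites <- fake_sites(30, target, seed = 422)
  fm <- fake_chromatin(sites$site_id, seed = 423)
  enc <- encode_features(sites, fm, target)
  enc$edited <- TRUE
  expect_error(train_offtarget_model(enc), "single class")
  # one-class test set: accuracy defined, AUC NA
  enc$edited <- enc$DNase > 0
  mod <- train_offtarget_model(enc, grid = model_grid("fast"), seed = 1)
  one_class <- enc[enc$edited, ]
  rep <- evaluate_model(mod, one_class)
  expect_true(is.finite(rep$accuracy_pct))
  expect_true(is.na(rep$auc))
})

test_that("random scores against random labels give AUC near 0.5", {
  withr::with_seed(431, {
    ds <- tibble::tibble(noise = rnorm(2000), edited = sample(c(TRUE, FALSE),
                                                              2000, TRUE))
  })
  mod <- structure(
    list(fit = NULL, method = "gbdt", feature_names = "noise",
         label_col = "edited"),
    class = "offtarget_model")
  # bypass the fit: score = the noise feature itself
  p <- ds$noise
  roc <- pROC::roc(response = factor(ds$edited, c(FALSE, TRUE)),
                   predictor = p, quiet = TRUE, direction = "<")
  expect_gt(as.numeric(pROC::auc(roc)), 0.45)
  expect_lt(as.numeric(pROC::auc(roc)), 0.55)
})

test_that("random-forest mode trains under the restricted grid", {
  target <- random_target(441)
  sites <- fake_sites(120, target, seed = 442)
  fm <- fake_chromatin(sites$site_id, seed = 443)
  enc <- encode_features(sites, fm, target)
  enc$edited <- enc$DNase > 0
  mod <- train_offtarget_model(enc, grid = model_grid("fast"), method = "rf",
                               seed = 7)
  expect_setequal(names(mod$best_params), c("n_estimators", "max_depth"))
  rep <- evaluate_model(mod, enc)
  expect_gt(rep$auc, 0.9)
  expect_equal(sum(rep$importance$importance), 1, tolerance = 1e-9)
})
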