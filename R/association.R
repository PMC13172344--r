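# exact two-sided rank-sum p-value by subset-sum DP over doubled midranks.
# Counts, among all C(n, n1) equally likely assignments of the observed
# (mid)ranks to group 1, those whose rank sum deviates from its null mean by
# at least the observed deviation. Handles ties exactly.
rank_sum_exact_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r2 <- as.integer(round(2 * rank(c(x, y))))  # doubled midranks: integers
  S <- sum(r2)
  cnt <- matrix(0, nrow = n1 + 1L, ncol = S + 1L)
  cnt[1L, 1L] <- 1
  for (v in r2) {
    for (j in n1:1) {
      # shift row j by v and add into row j+1 (0/1 knapsack, high-to-low)
      cnt[j + 1L, (v + 1L):(S + 1L)] <-
        cnt[j + 1L, (v + 1L):(S + 1L)] + cnt[j, 1L:(S + 1L - v)]
    }
  }
  dist <- cnt[n1 + 1L, ]
  total <- choose(n, n1)
  stopifnot(abs(sum(dist) - total) < 1e-6)
  mu2 <- n1 * (S / n)
  w2 <- sum(r2[seq_len(n1)])
  dev <- abs(w2 - mu2)
  sums <- 0:S
  sum(dist[abs(sums - mu2) >= dev - 1e-9]) / total
}

# normal approximation with tie correction and continuity correction,
# matching the classical large-sample Mann-Whitney test
rank_sum_normal_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U
  mu <- n1 * n2 / 2
  nt <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)  # all observations identical
  z <- W - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Wilcoxon rank-sum test between edited and unedited scores
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) comparison of a chromatin
#' feature between edited and unedited sites of one off-target type. For
#' combined sample sizes up to `exact_max_n` the p-value is computed from
#' the exact permutation distribution of the rank sum (ties handled exactly
#' via midranks); above that, a normal approximation with tie and continuity
#' corrections is used. Direction is the sign of the median difference
#' (edited minus unedited), falling back to the mean difference on a median
#' tie and to `"positive"` (flagged) when both are zero.
#'
#' @param edited_scores,unedited_scores Numeric vectors of feature scores.
#' @param exact_max_n Largest combined sample size for the exact mode
#'   (default 25).
#' @return One-row tibble: `n_edited`, `n_unedited`, `p_value`, `direction`
#'   (`"positive"`/`"negative"`), `method` (`"exact"`/`"normal"`), `note`
#'   (`NA`, `"empty_group"`, or `"degenerate_direction"`). An empty group is
#'   reported with `p_value = NA`, not an error.
#' @examples
#' test_type_feature(c(10, 11, 12), c(1, 2, 3))
#' @export
test_type_feature <- function(edited_scores, unedited_scores,
                              exact_max_n = 25L) {
  x <- edited_scores[!is.na(edited_scores)]
  y <- unedited_scores[!is.na(unedited_scores)]
  if (length(x) == 0 || length(y) == 0) {
    return(tibble(n_edited = length(x), n_unedited = length(y),
                  p_value = NA_real_, direction = NA_character_,
                  method = NA_character_, note = "empty_group"))
  }
  n <- length(x) + length(y)
  if (n <= exact_max_n) {
    p <- rank_sum_exact_p(x, y)
    method <- "exact"
  } else {
    p <- rank_sum_normal_p(x, y)
    method <- "normal"
  }
  d <- median(x) - median(y)
  note <- NA_character_
  if (d == 0) {
    d <- mean(x) - mean(y)
    if (d == 0) {
      note <- "degenerate_direction"
      d <- 1
    }
  }
  tibble(n_edited = length(x), n_unedited = length(y), p_value = p,
         direction = if (d > 0) "positive" else "negative",
         method = method, note = note)
}

#' Screen off-target types for chromatin associations
#'
#' Within each off-target type with at least `min_edits` edited sites and at
#' least one unedited site, tests every chromatin feature between edited and
#' unedited sites with [test_type_feature()]. Significance is called on the
#' raw p-value at `alpha` (no multiple-testing correction, so per-type
#' "influenced" fractions are comparable with raw-threshold reports); a
#' Benjamini-Hochberg `bh_q` column is emitted alongside for reference but
#' does not drive `significant`.
#'
#' @param site_features Tibble with one row per site: `type_id`, logical
#'   `edited`, and one numeric column per feature.
#' @param features Character vector of feature columns to test; default is
#'   every column of [chromatin_feature_names()] present, or all numeric
#'   non-id columns if none match.
#' @param min_edits Minimum edited sites per tested type (default 10).
#' @param alpha Significance level (default 0.05).
#' @param exact_max_n Passed to [test_type_feature()].
#' @return Tibble with one row per (type, feature): `type_id`, `feature`,
#'   `n_edited`, `n_unedited`, `p_value`, `direction`, `method`, `note`,
#'   `bh_q`, `significant`. Types excluded from testing (too few edits or no
#'   unedited site) are listed in the `untested` attribute with a reason.
#' @export
screen_types <- function(site_features, features = NULL, min_edits = 10L,
                         alpha = 0.05, exact_max_n = 25L) {
  stopifnot(all(c("type_id", "edited") %in% names(site_features)))
  if (is.null(features)) {
    features <- intersect(chromatin_feature_names(), names(site_features))
    if (length(features) == 0) {
      features <- setdiff(names(site_features)[vapply(site_features,
                                                      is.numeric, logical(1))],
                          c("start", "end", "mismatch_count", "win_start",
                            "win_end", "win_len"))
    }
  }
  stopifnot(length(features) > 0)

  by_type <- split(site_features, site_features$type_id)
  untested <- list()
  rows <- list()
  for (tid in names(by_type)) {
    d <- by_type[[tid]]
    ne <- sum(d$edited)
    nu <- sum(!d$edited)
    if (ne < min_edits) {
      untested[[tid]] <- tibble(type_id = tid, n_edited = ne, n_unedited = nu,
                                reason = "too_few_edits")
      next
    }
    if (nu < 1) {
      untested[[tid]] <- tibble(type_id = tid, n_edited = ne, n_unedited = nu,
                                reason = "no_unedited_sites")
      next
    }
    for (f in features) {
      res <- test_type_feature(d[[f]][d$edited], d[[f]][!d$edited],
                               exact_max_n = exact_max_n)
      rows[[length(rows) + 1L]] <- res %>%
        mutate(type_id = tid, feature = f, .before = 1)
    }
  }
  if (length(rows) == 0) {
    out <- tibble(type_id = character(), feature = character(),
                  n_edited = integer(), n_unedited = integer(),
                  p_value = numeric(), direction = character(),
                  method = character(), note = character(), bh_q = numeric(),
                  significant = logical())
  } else {
    out <- bind_rows(rows) %>%
      mutate(bh_q = p.adjust(.data$p_value, method = "BH"),
             significant = !is.na(.data$p_value) & .data$p_value < alpha)
  }
  attr(out, "untested") <- bind_rows(untested)
  attr(out, "thresholds") <- list(min_edits = min_edits, alpha = alpha)
  out
}

#' Percentage of influenced off-target types
#'
#' A type is "influenced" by chromatin context when any feature is
#' significant for it. The percentage is rounded half-up to two decimals.
#'
#' @param n_influenced,n_tested Counts.
#' @return Percentage (0-100), `NA` when nothing was tested.
#' @examples
#' percent_influenced(21, 32)
#' @export
percent_influenced <- function(n_influenced, n_tested) {
  percent2(n_influenced, n_tested)
}

#' Aggregate association results into an influence summary
#'
#' Rolls per-(type, feature) test results up to the quantities reported for
#' editor panels: per editor, the number and percentage of tested types
#' influenced (significant for at least one feature); per (editor, feature),
#' whether the feature was significant for at least one of that editor's
#' types; per feature, the fraction of editors (and of types) it influenced
#' and its dominant direction among significant tests; and the direction map
#' restricted to types with at least `min_edits_direction` edited sites.
#'
#' @param results Association tibble from [screen_types()]; may carry an
#'   `editor` column (added by the caller when screening several editors) --
#'   without one, a single editor `"editor"` is assumed.
#' @param min_edits_direction Edited-site threshold for the direction-map
#'   subset (default 50).
#' @return A list of class `influence_summary`: `per_editor`,
#'   `per_editor_feature`, `per_feature`, `heatmap` (long p-value table),
#'   `direction_map`, `thresholds`.
#' @export
summarize_influence <- function(results, min_edits_direction = 50L) {
  if (!"editor" %in% names(results)) {
    results <- results %>% mutate(editor = "editor")
  }
  tested <- results %>% filter(!is.na(.data$p_value))

  per_type <- tested %>%
    group_by(.data$editor, .data$type_id) %>%
    summarise(influenced = any(.data$significant), .groups = "drop")
  per_editor <- per_type %>%
    group_by(.data$editor) %>%
    summarise(n_types_tested = dplyr::n(),
              n_types_influenced = sum(.data$influenced), .groups = "drop") %>%
    mutate(percent_influenced =
             purrr::map2_dbl(.data$n_types_influenced, .data$n_types_tested,
                             percent2))

  per_editor_feature <- tested %>%
    group_by(.data$editor, .data$feature) %>%
    summarise(n_types_tested = dplyr::n_distinct(.data$type_id),
              n_types_significant =
                dplyr::n_distinct(.data$type_id[.data$significant]),
              significant = any(.data$significant),
              dominant_direction = dominant_direction(
                .data$direction[.data$significant]),
              .groups = "drop")

  per_feature <- per_editor_feature %>%
    group_by(.data$feature) %>%
    summarise(n_editors = dplyr::n(),
              n_editors_significant = sum(.data$significant),
              .groups = "drop") %>%
    mutate(percent_editors = purrr::map2_dbl(.data$n_editors_significant,
                                             .data$n_editors, percent2)) %>%
    left_join(
      tested %>%
        group_by(.data$feature) %>%
        summarise(n_types_tested = dplyr::n_distinct(.data$type_id),
                  n_types_significant =
                    dplyr::n_distinct(.data$type_id[.data$significant]),
                  dominant_direction = dominant_direction(
                    .data$direction[.data$significant]),
                  .groups = "drop"),
      by = "feature"
    )

  heatmap <- tested %>%
    select("editor", "type_id", "feature", "p_value", "direction",
           "significant")
  direction_map <- tested %>%
    filter(.data$n_edited >= min_edits_direction, .data$significant) %>%
    select("editor", "type_id", "feature", "n_edited", "direction", "p_value")

  structure(
    list(per_editor = per_editor,
         per_editor_feature = per_editor_feature,
         per_feature = per_feature,
         heatmap = heatmap,
         direction_map = direction_map,
         thresholds = c(attr(results, "thresholds"),
                        list(min_edits_direction = min_edits_direction))),
    class = "influence_summary"
  )
}

dominant_direction <- function(dirs) {
  dirs <- dirs[!is.na(dirs)]
  if (length(dirs) == 0) return(NA_character_)
  if (sum(dirs == "positive") >= sum(dirs == "negative")) "positive"
  else "negative"
}

#' @export
print.influence_summary <- function(x, ...) {
  cat("<influence_summary>\n")
  cat("  per-editor influenced types:\n")
  print(as.data.frame(x$per_editor), row.names = FALSE)
  cat("  per-feature (editors influenced):\n")
  print(as.data.frame(x$per_feature %>%
                        select("feature", "n_editors_significant",
                               "n_editors", "percent_editors",
                               "dominant_direction")),
        row.names = FALSE)
  invisible(x)
}
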