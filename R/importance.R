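#' Permutation importance from a bootstrap tree ensemble
#'
#' Ranks candidate predictors of annual stranding counts by mean decrease
#' in accuracy: the increase in out-of-bag squared error when a predictor's
#' values are permuted, averaged over the trees of a random forest
#' (regression mode, bootstrap sample size n, `ceiling(p/3)` predictors
#' tried per split). Deterministic given `seed`.
#'
#' @param data A data frame with the response column and predictor columns
#'   (e.g. a [build_covariate_table()] result); `year` is ignored.
#' @param n_trees Number of trees (default 2000).
#' @param seed Integer seed.
#' @param response Name of the response column.
#' @param predictors Predictor column names; defaults to every column other
#'   than the response and `year`.
#' @return A tibble (`predictor`, `importance`, `rank`), most important
#'   first, with attributes `n_trees` and `seed`.
#' @export
fit_importance <- function(data, n_trees = 2000L, seed = 1L,
                           response = "count",
                           predictors = setdiff(names(data),
                                                c(response, "year"))) {
  if (length(predictors) < 2) abort("need at least 2 predictors")
  X <- as.data.frame(data[, predictors, drop = FALSE])
  if (anyNA(X)) abort("missing cells among predictors")
  y <- data[[response]]
  if (sd(y) == 0) abort("constant response: importance undefined")
  rf <- withr::with_seed(seed, randomForest::randomForest(
    x = X, y = y, ntree = n_trees, importance = TRUE,
    mtry = max(1L, ceiling(length(predictors) / 3))))
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  out <- tibble::tibble(predictor = names(imp), importance = unname(imp))
  out <- dplyr::arrange(out, dplyr::desc(.data$importance))
  out$rank <- seq_len(nrow(out))
  attr(out, "n_trees") <- as.integer(n_trees)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Group predictors by pairwise collinearity
#'
#' Predictors whose absolute Pearson correlation meets the threshold are
#' linked; groups are the connected components of that graph. Only groups
#' with two or more members are returned.
#'
#' @param data Data frame of predictor columns (non-numeric columns and
#'   `year`/`count` are excluded).
#' @param threshold Absolute-correlation cutoff (default 0.7).
#' @param predictors Columns to consider.
#' @return A list of character vectors, one per collinear group.
#' @export
collinear_groups <- function(data, threshold = 0.7,
                             predictors = setdiff(names(data),
                                                  c("year", "count"))) {
  X <- as.data.frame(data[, predictors, drop = FALSE])
  X <- X[, vapply(X, is.numeric, logical(1)), drop = FALSE]
  p <- ncol(X)
  if (p < 2) return(list())
  cm <- abs(suppressWarnings(stats::cor(X)))
  cm[is.na(cm)] <- 0
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (cm[i, j] >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(p), find, integer(1))
  groups <- split(colnames(X), roots)
  unname(groups[lengths(groups) > 1])
}

#' Two-stage predictor selection with a collinearity screen
#'
#' Stage 1 ranks all candidate predictors by permutation importance.
#' Collinear groups among the aggregate-SST predictors are then collapsed,
#' keeping only each group's highest-importance member (non-SST predictors
#' always survive the screen). Stage 2 re-ranks the reduced set and the top
#' two predictors are returned for the count model.
#'
#' With only two predictors the screen is skipped and both are returned
#' from a single stage.
#'
#' @inheritParams fit_importance
#' @param threshold Absolute-correlation cutoff for the SST screen.
#' @param sst_prefix Prefix identifying aggregate-SST columns.
#' @return A list of class `"stage_selection"`: `stage1`, `stage2`
#'   (importance tibbles), `kept` (stage-2 predictor set), `dropped`
#'   (collinearity casualties), `top_two`.
#' @export
two_stage_select <- function(data, n_trees = 2000L, threshold = 0.7,
                             seed = 1L, response = "count",
                             predictors = setdiff(names(data),
                                                  c(response, "year")),
                             sst_prefix = "sst_") {
  if (length(predictors) == 2) {
    st <- fit_importance(data, n_trees, seed, response, predictors)
    out <- list(stage1 = st, stage2 = st, kept = predictors,
                dropped = character(0), top_two = st$predictor[1:2])
    return(structure(out, class = "stage_selection"))
  }
  stage1 <- fit_importance(data, n_trees, seed, response, predictors)
  sst_cols <- grep(paste0("^", sst_prefix), predictors, value = TRUE)
  groups <- collinear_groups(data, threshold, predictors = sst_cols)
  dropped <- character(0)
  for (g in groups) {
    ranks <- stage1[stage1$predictor %in% g, ]
    dropped <- c(dropped, setdiff(g, ranks$predictor[which.max(ranks$importance)]))
  }
  kept <- setdiff(predictors, dropped)
  stage2 <- fit_importance(data, n_trees, seed + 1L, response, kept)
  structure(list(stage1 = stage1, stage2 = stage2, kept = kept,
                 dropped = dropped, top_two = stage2$predictor[1:2]),
            class = "stage_selection")
}

#' @export
print.stage_selection <- function(x, ...) {
  cat("Two-stage permutation-importance selection\n")
  cat("  stage 1 ranking:", paste(x$stage1$predictor, collapse = " > "), "\n")
  if (length(x$dropped) > 0) {
    cat("  dropped (collinear):", paste(x$dropped, collapse = ", "), "\n")
  }
  cat("  stage 2 ranking:", paste(x$stage2$predictor, collapse = " > "), "\n")
  cat("  top two:", paste(x$top_two, collapse = ", "), "\n")
  invisible(x)
}
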