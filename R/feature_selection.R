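# Two-stage feature selection: the expert week-window filter, then
# permutation importance under a random forest, keeping the top k.

new_featureset <- function(names, provenance) {
  stopifnot(!anyDuplicated(names), length(provenance) == length(names))
  structure(list(names = names, provenance = provenance),
            class = "yc_featureset")
}

#' @export
print.yc_featureset <- function(x, ...) {
  cat("<yc_featureset> ", length(x$names), " features (",
      paste(sprintf("%s: %d", names(table(x$provenance)),
                    as.integer(table(x$provenance))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Expert week-window feature filter
#'
#' Drops weekly weather columns outside the agronomically informative
#' window (weeks 16-43: late-season and pre-planting weeks carry no signal
#' for the current crop) and planting-progress columns outside weeks 12-29
#' (planting is essentially complete afterwards). All crop-model, soil,
#' quarterly, auxiliary-weather and trend columns are retained. Purely
#' manifest-driven: row order and values never matter.
#'
#' @param panel a preprocessed feature panel.
#' @param weather_window,planting_window inclusive week ranges to keep.
#' @param manifest optional precomputed [column_manifest()].
#' @return a `yc_featureset` with provenance `"expert-retained"`.
#' @export
expert_filter <- function(panel, weather_window = c(16, 43),
                          planting_window = c(12, 29), manifest = NULL) {
  if (is.null(manifest)) manifest <- column_manifest(panel)
  if (any(manifest$source %in% c("weather", "planting") &
          is.na(manifest$week)))
    stop_config("schema error: weekly column without a week annotation")
  keep <- manifest[
    (source == "weather" & week >= weather_window[1] &
       week <= weather_window[2]) |
      (source == "planting" & week >= planting_window[1] &
         week <= planting_window[2]) |
      source %in% c("weather_aux", "quarterly", "soil", "apsim", "trend"),
    column]
  new_featureset(keep, rep("expert-retained", length(keep)))
}

#' Rank features by permutation importance under a random forest
#'
#' The most recent year of the (training) panel is held out as the
#' validation set, respecting temporal order. A forest is fit on the
#' remaining rows — with its tree count either pinned (default 300) or
#' grid-searched under cross-validation — and each feature's importance is
#' the mean increase in validation MSE over `n_repeats` independent
#' shuffles of that feature's validation values. A shuffled feature that
#' the model never relied on leaves the error unchanged, so its importance
#' converges to zero.
#'
#' @param panel training feature panel (contains `yield`).
#' @param featureset a `yc_featureset` (e.g. from [expert_filter()]).
#' @param forest_config list: `ntree` (default 300), `tune` (grid-search
#'   the tree count, default FALSE), `grid` (default 100/200/300/500),
#'   `cv_folds` (default 10), `mtry_frac`, `max_depth`, `n_repeats`
#'   (default 10 shuffles per feature).
#' @param seed integer seed.
#' @return a `yc_ranking` data.table: `name`, `importance` (validation MSE
#'   increase), `impurity` (forest split-gain, diagnostic only), `rank`.
#'   Ties are broken by lexicographic name.
#' @export
rank_features_permutation <- function(panel, featureset,
                                      forest_config = list(), seed = 0L) {
  fc <- utils::modifyList(
    list(ntree = 300, tune = FALSE, grid = c(100, 200, 300, 500),
         cv_folds = 10, mtry_frac = 1 / 3, max_depth = 14, n_repeats = 10),
    forest_config)
  feats <- featureset$names
  val_year <- max(panel$year)
  tr <- panel[year < val_year]
  va <- panel[year == val_year]
  if (nrow(tr) == 0 || nrow(va) == 0)
    stop_config("validation split empty")

  Xtr <- panel_matrix(tr, feats); ytr <- tr$yield
  Xva <- panel_matrix(va, feats); yva <- va$yield

  ntree <- fc$ntree
  if (isTRUE(fc$tune)) {
    scores <- vapply(fc$grid, function(B)
      cv_mse("rf", Xtr, ytr,
             list(ntree = B, mtry_frac = fc$mtry_frac,
                  max_depth = fc$max_depth),
             fc$cv_folds, derive_seed(seed, paste0("rfgrid", B))),
      numeric(1))
    ntree <- fc$grid[which.min(scores)]
  }

  forest <- rf_fit(Xtr, ytr, ntree = ntree, mtry_frac = fc$mtry_frac,
                   max_depth = fc$max_depth,
                   seed = derive_seed(seed, "permforest"))
  base_mse <- mean((yva - predict(forest, Xva))^2)

  imp <- with_seed(derive_seed(seed, "shuffle"), {
    vapply(seq_along(feats), function(j) {
      inc <- vapply(seq_len(fc$n_repeats), function(r) {
        Xp <- Xva
        Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
        mean((yva - predict(forest, Xp))^2) - base_mse
      }, numeric(1))
      mean(inc)
    }, numeric(1))
  })

  rk <- data.table::data.table(name = feats, importance = imp,
                               impurity = forest$importance[feats])
  data.table::setorderv(rk, c("importance", "name"), order = c(-1L, 1L))
  rk[, rank_ := seq_len(.N)]
  data.table::setnames(rk, "rank_", "rank")
  structure(rk[], class = c("yc_ranking", class(rk)))
}

#' Keep the top-k ranked features
#'
#' @param ranking a `yc_ranking`.
#' @param k number of features to keep (default 100).
#' @return a `yc_featureset` with provenance `"permutation-rank"`.
#' @export
select_top_k <- function(ranking, k = 100) {
  if (k > nrow(ranking))
    stop_config("k = ", k, " exceeds the ", nrow(ranking),
                " ranked features")
  sel <- ranking[order(rank)][seq_len(k), name]
  new_featureset(sel, rep("permutation-rank", k))
}
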