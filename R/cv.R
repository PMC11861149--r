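# 10-fold cross-validation protocol, the 4-model x 7-dataset experiment
# grid, and speed-stratified validation.

#' Split indices into K shuffled, disjoint, near-equal folds
#'
#' Indices `1..n` are shuffled by `seed` and divided into `K` subsets whose
#' sizes differ by at most one (exactly equal when `K` divides `n`, e.g.
#' 530 trials into 10 folds of 53). Each subset serves once as the test
#' set.
#'
#' @param n number of samples (must be >= K).
#' @param K number of folds (default 10).
#' @param seed shuffle seed.
#' @return list of K integer vectors.
#' @export
kfold_split <- function(n, K = 10, seed = 1) {
  if (n < K) stop("n (", n, ") must be at least K (", K, ")", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  idx <- sample.int(n)
  sizes <- rep(n %/% K, K)
  extra <- n %% K
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  unname(split(idx, rep(seq_len(K), times = sizes)))
}

#' Cross-validate a vGRF model on one design matrix
#'
#' Runs the K-fold protocol on a design from [assemble_designs()]: for each
#' fold, min-max scaling is fit on the training rows only (features and
#' targets) and reused on the test rows, a model is trained on the scaled
#' training fold, and R^2, MAPE and rMSE are computed on the scaled test
#' fold. Reported as per-fold values plus mean and sample (n-1) standard
#' deviation.
#'
#' By default the model is [grfnet()] with the given `architecture`;
#' `fit_fun` substitutes any other regressor (it receives the scaled
#' training `x`, `y` and a fold seed, and must return a
#' `function(newx) -> predicted matrix`), which keeps the protocol testable
#' with cheap reference models.
#'
#' @param design a `grf_design` (or any list with matrices `X` and `y`).
#' @param architecture passed to [grfnet()].
#' @param K number of folds.
#' @param seed seed for the fold split and the per-fold model seeds.
#' @param mape_floor passed to [mape()], on the `metrics_scale` scale.
#' @param metrics_scale scale on which the metrics are computed: `"bw"`
#'   (default) inverts the target scaling so R^2/MAPE/rMSE are reported on
#'   the body-weight curves, whose shape variance makes the per-curve R^2
#'   meaningful; `"normalized"` evaluates on the min-max scale the model is
#'   trained on.
#' @param fit_fun optional replacement trainer (see Details).
#' @param keep_history also return each fold's training-loss history.
#' @param ... further arguments to [grfnet()] (e.g. `epochs`, `lr`).
#' @return object of class `grf_cv`: list with `folds` (data.frame of
#'   per-fold metrics), `summary` (mean and sd per metric), `K`, `seed`,
#'   and the label fields `model` and `dataset`.
#' @export
cv_grfnet <- function(design, architecture = "xlstm", K = 10, seed = 1,
                      mape_floor = 0.05,
                      metrics_scale = c("bw", "normalized"),
                      fit_fun = NULL, keep_history = FALSE, ...) {
  metrics_scale <- match.arg(metrics_scale)
  X <- as.matrix(design$X); y <- as.matrix(design$y)
  folds <- kfold_split(nrow(X), K = K, seed = seed)
  res <- vector("list", K)
  histories <- vector("list", K)
  for (k in seq_len(K)) {
    test <- folds[[k]]
    train <- setdiff(seq_len(nrow(X)), test)
    sx <- minmax_fit_transform(X[train, , drop = FALSE])
    sy <- minmax_fit_transform(y[train, , drop = FALSE])
    xte <- minmax_fit_transform(X[test, , drop = FALSE], sx$params)$x
    yte <- minmax_fit_transform(y[test, , drop = FALSE], sy$params)$x
    fold_seed <- seed * 1000L + k
    pred_fun <- if (is.null(fit_fun)) {
      fit <- grfnet(sx$x, sy$x, architecture = architecture,
                    seed = fold_seed, ...)
      if (keep_history) histories[[k]] <- fit$history
      function(newx) predict(fit, newx)
    } else {
      fit_fun(sx$x, sy$x, fold_seed)
    }
    y_hat <- pred_fun(xte)
    if (metrics_scale == "bw") {
      y_hat <- minmax_inverse(y_hat, sy$params)
      y_true <- y[test, , drop = FALSE]
    } else {
      y_true <- yte
    }
    res[[k]] <- data.frame(
      fold = k,
      r2 = r_squared(y_true, y_hat),
      mape = mape(y_true, y_hat, floor = mape_floor),
      rmse = rmse(y_true, y_hat)
    )
  }
  folds_df <- do.call(rbind, res)
  summ <- data.frame(
    metric = c("r2", "mape", "rmse"),
    mean = vapply(folds_df[c("r2", "mape", "rmse")], mean, 0, na.rm = TRUE),
    sd = vapply(folds_df[c("r2", "mape", "rmse")], stats::sd, 0, na.rm = TRUE),
    row.names = NULL
  )
  structure(list(folds = folds_df, summary = summ, K = K, seed = seed,
                 metrics_scale = metrics_scale,
                 histories = if (keep_history) histories,
                 model = if (is.null(fit_fun)) architecture else "custom",
                 dataset = design$name %||% "design"),
            class = "grf_cv")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.grf_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV of %s on %s (seed %d)\n", x$K, x$model, x$dataset,
              x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Run the model x dataset experiment grid with speed-stratified validation
#'
#' Evaluates every requested architecture on every requested design via
#' [cv_grfnet()] (the full grid is 4 models x 7 datasets = 28 cells), then
#' re-evaluates the best-performing configuration cases -- by default the
#' xLSTM on M1, M2, M5 and M6 -- separately at each running speed
#' (4 x 5 = 20 cells) by subsetting trials on the design's `speed_kmh`
#' metadata.
#'
#' @param designs named list from [assemble_designs()].
#' @param architectures models to evaluate.
#' @param datasets names of the designs to use (default: all).
#' @param K folds per cell.
#' @param seed base seed; each cell derives its own fold/model seeds.
#' @param speed_cases dataset names for the speed-stratified stage
#'   (`character(0)` skips it); evaluated with the first architecture.
#' @param fit_fun,... passed to [cv_grfnet()].
#' @return object of class `grf_grid`: `grid` and `per_speed` data.frames
#'   in tidy (model, dataset, speed, metric, mean, sd) form, plus `cells`
#'   (the underlying `grf_cv` objects).
#' @export
experiment_grid <- function(designs,
                            architectures = c("xlstm", "slstm", "mlstm", "lstm"),
                            datasets = names(designs), K = 10, seed = 1,
                            speed_cases = c("M1", "M2", "M5", "M6"),
                            fit_fun = NULL, ...) {
  rows <- list(); cells <- list()
  cell_i <- 0
  for (arch in architectures) {
    for (ds in datasets) {
      cell_i <- cell_i + 1
      if (is.null(designs[[ds]])) {
        rows[[length(rows) + 1]] <- data.frame(
          model = arch, dataset = ds, speed = "all",
          metric = c("r2", "mape", "rmse"), mean = NA_real_, sd = NA_real_)
        next
      }
      cv <- cv_grfnet(designs[[ds]], architecture = arch, K = K,
                      seed = seed + cell_i, fit_fun = fit_fun, ...)
      cells[[paste(arch, ds, sep = ".")]] <- cv
      rows[[length(rows) + 1]] <- data.frame(
        model = arch, dataset = ds, speed = "all",
        metric = cv$summary$metric, mean = cv$summary$mean,
        sd = cv$summary$sd)
    }
  }
  grid <- do.call(rbind, rows)

  speed_rows <- list()
  speed_cases <- intersect(speed_cases, names(designs))
  arch1 <- architectures[1]
  for (ds in speed_cases) {
    d <- designs[[ds]]
    for (sp in sort(unique(d$speed_kmh))) {
      cell_i <- cell_i + 1
      sel <- which(d$speed_kmh == sp)
      sub <- d
      sub$X <- d$X[sel, , drop = FALSE]
      sub$y <- d$y[sel, , drop = FALSE]
      sub$speed_kmh <- d$speed_kmh[sel]
      sub$trial_id <- d$trial_id[sel]
      Ksp <- min(K, nrow(sub$X))
      cv <- cv_grfnet(sub, architecture = arch1, K = Ksp,
                      seed = seed + cell_i, fit_fun = fit_fun, ...)
      speed_rows[[length(speed_rows) + 1]] <- data.frame(
        model = arch1, dataset = ds, speed = as.character(sp),
        metric = cv$summary$metric, mean = cv$summary$mean,
        sd = cv$summary$sd)
    }
  }
  per_speed <- if (length(speed_rows)) do.call(rbind, speed_rows) else
    data.frame(model = character(), dataset = character(),
               speed = character(), metric = character(),
               mean = numeric(), sd = numeric())
  structure(list(grid = grid, per_speed = per_speed, cells = cells,
                 K = K, seed = seed),
            class = "grf_grid")
}

#' @export
print.grf_grid <- function(x, ...) {
  cat(sprintf("Experiment grid: %d cells (+%d speed-stratified)\n",
              nrow(x$grid) / 3, nrow(x$per_speed) / 3))
  wide <- stats::reshape(x$grid[x$grid$metric == "r2",
                                c("model", "dataset", "mean")],
                         idvar = "model", timevar = "dataset",
                         direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  cat("mean R^2:\n")
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a tidy CSV report of an experiment grid
#'
#' @param grid a `grf_grid` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_report <- function(grid, path) {
  out <- rbind(grid$grid, grid$per_speed)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
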