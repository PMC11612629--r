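# Modified binary particle swarm feature selection with a constriction
# factor, wrapper fitness (cross-validated classifier accuracy), and a
# Pearson redundancy filter over the top-ranked features.

#' Swarm configuration for the feature selector
#'
#' Defaults honour the constriction-factor precondition `c1 + c2 > 4`
#' (`c1 = c2 = 2.05` gives the classical factor 0.7298) with a linearly
#' decaying inertia weight.
#'
#' @param n_particles Swarm size.
#' @param max_iters Iteration budget.
#' @param c1,c2 Cognitive and social learning factors.
#' @param inertia_start,inertia_end Linear inertia schedule endpoints.
#' @param v_max Elementwise velocity clamp.
#' @param seed Master seed for the swarm's random draws.
#' @param fitness A [fitness_spec].
#' @param top_k Number of top-ranked features retained for the
#'   redundancy stage.
#' @param delta Pearson threshold: a candidate feature is dropped when
#'   `|r|` with an already-kept feature exceeds `delta`.
#' @param stall_window Stop early when the global best has not improved
#'   for this many iterations.
#' @param constriction If `FALSE` the constriction factor is forced to 1
#'   (the plain binary-PSO baseline).
#' @return Object of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 30, max_iters = 50,
                         c1 = 2.05, c2 = 2.05,
                         inertia_start = 0.9, inertia_end = 0.4,
                         v_max = 4, seed = 1L,
                         fitness = fitness_spec(),
                         top_k = 10, delta = 0.6,
                         stall_window = 15, constriction = TRUE) {
  if (n_particles < 2) stop("need at least 2 particles")
  if (max_iters < 1) stop("need at least 1 iteration")
  if (delta <= 0 || delta >= 1) stop("'delta' must be in (0, 1)")
  structure(list(n_particles = n_particles, max_iters = max_iters,
                 c1 = c1, c2 = c2, inertia_start = inertia_start,
                 inertia_end = inertia_end, v_max = v_max, seed = seed,
                 fitness = fitness, top_k = top_k, delta = delta,
                 stall_window = stall_window, constriction = constriction),
            class = "swarm_config")
}

#' Wrapper-fitness specification
#'
#' The fitness of a feature subset is the stratified internal
#' cross-validated accuracy of a classifier trained on the masked
#' columns; the evaluation is fully deterministic for fixed seeds.
#'
#' @param classifier Only `"rf"` (a seeded random forest) is currently
#'   provided.
#' @param folds Internal CV folds.
#' @param seed Seed for fold assignment and the classifier.
#' @param num_trees Trees in the forest.
#' @return Object of class `fitness_spec`.
#' @export
fitness_spec <- function(classifier = "rf", folds = 3, seed = 42L,
                         num_trees = 100) {
  classifier <- match.arg(classifier, "rf")
  structure(list(classifier = classifier, folds = folds, seed = seed,
                 num_trees = num_trees),
            class = "fitness_spec")
}

#' Constriction factor of the velocity update
#'
#' The Clerc--Kennedy closed form `phi = 2 / |2 - c - sqrt(c^2 - 4c)|`
#' with `c = c1 + c2`, which bounds the swarm dynamics when `c > 4` and
#' limits the effective range of the learning factors. When `c <= 4` the
#' factor is inactive and 1 is returned with a warning.
#'
#' @param c1,c2 Learning factors.
#' @return The factor, in `(0, 1)` when `c1 + c2 > 4`.
#' @export
#' @examples
#' constriction_factor(2.05, 2.05)  # ~0.7298
constriction_factor <- function(c1, c2) {
  cc <- c1 + c2
  if (cc <= 4) {
    warning("constriction factor requires c1 + c2 > 4; returning 1 (inactive)")
    return(1.0)
  }
  2 / abs(2 - cc - sqrt(cc^2 - 4 * cc))
}

#' Velocity update of one particle
#'
#' `v' = w v + phi * (c1 r1 (pbest - x) + c2 r2 (gbest - x))`, with
#' `r1, r2` drawn per-dimension uniform on `[0, 1)` from the current RNG
#' stream, then clamped elementwise to `[-v_max, v_max]`.
#'
#' @param position,velocity Real vectors of length d.
#' @param pbest_mask,gbest_mask Binary attractors of length d.
#' @param w Inertia weight.
#' @param phi Constriction factor.
#' @param c1,c2 Learning factors.
#' @param v_max Velocity clamp.
#' @return New velocity vector.
#' @export
update_velocity <- function(position, velocity, pbest_mask, gbest_mask,
                            w, phi, c1, c2, v_max) {
  d <- length(position)
  r1 <- runif(d)
  r2 <- runif(d)
  v <- w * velocity + phi * (c1 * r1 * (pbest_mask - position) +
                             c2 * r2 * (gbest_mask - position))
  pmin(pmax(v, -v_max), v_max)
}

#' Map a real-valued particle position to a binary feature mask
#'
#' Stochastic sigmoid transfer: dimension j is selected with probability
#' `1 / (1 + exp(-position_j))`. An all-zero mask is re-drawn once and,
#' if still empty, the dimension with the largest position value is
#' forced on, so the fitness is always defined on a non-empty subset.
#'
#' @param position Real vector.
#' @return Integer 0/1 vector of the same length.
#' @export
binarize_position <- function(position) {
  draw <- function() as.integer(runif(length(position)) < 1 / (1 + exp(-position)))
  mask <- draw()
  if (sum(mask) == 0L) mask <- draw()
  if (sum(mask) == 0L) mask[which.max(position)] <- 1L
  mask
}

# Stratified fold assignment, deterministic for a seed.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (lv in unique(labels)) {
      rows <- which(labels == lv)
      if (length(rows) < k) {
        stop("class '", lv, "' has fewer samples (", length(rows),
             ") than folds (", k, ")")
      }
      folds[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
  })
  folds
}

rf_fit_predict <- function(x_train, y_train, x_eval, num_trees, seed) {
  fit <- ranger::ranger(x = as.data.frame(x_train),
                        y = factor(y_train),
                        num.trees = num_trees, seed = seed,
                        num.threads = 1)
  # predict() is seeded too: ranger otherwise draws a tie-breaking seed
  # from the global RNG, which would make fitness depend on ambient state
  as.character(predict(fit, data = as.data.frame(x_eval),
                       seed = seed, num.threads = 1)$predictions)
}

#' Fitness of a feature mask
#'
#' Mean internal-CV accuracy of the fitness classifier on the selected
#' columns, paired with the subset size. An empty mask has defined
#' fitness 0 (the classifier is never trained).
#'
#' @param mask Binary vector over feature columns.
#' @param x Numeric feature matrix.
#' @param labels Class labels, one per row.
#' @param spec A [fitness_spec].
#' @param folds Optional precomputed fold assignment (from the spec seed
#'   if omitted).
#' @return List with `accuracy` and `size`.
#' @export
evaluate_fitness <- function(mask, x, labels, spec = fitness_spec(),
                             folds = NULL) {
  size <- sum(mask)
  if (size == 0L) return(list(accuracy = 0, size = 0L))
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  if (is.null(folds)) folds <- stratified_folds(labels, spec$folds, spec$seed)
  xs <- x[, mask == 1L, drop = FALSE]
  correct <- 0L
  for (f in sort(unique(folds))) {
    tr <- folds != f
    pred <- rf_fit_predict(xs[tr, , drop = FALSE], labels[tr],
                           xs[!tr, , drop = FALSE],
                           spec$num_trees, spec$seed)
    correct <- correct + sum(pred == labels[!tr])
  }
  list(accuracy = correct / length(labels), size = as.integer(size))
}

#' Best-so-far comparison with subset-size tie-break
#'
#' A candidate replaces the incumbent when its accuracy is strictly
#' higher, or equal (within 1e-12) with a strictly smaller subset.
#'
#' @param candidate,incumbent Lists with `accuracy` and `size`.
#' @return Logical.
#' @export
better_than <- function(candidate, incumbent) {
  if (candidate$accuracy > incumbent$accuracy + 1e-12) return(TRUE)
  if (abs(candidate$accuracy - incumbent$accuracy) <= 1e-12 &&
      candidate$size < incumbent$size) return(TRUE)
  FALSE
}

#' Run the modified binary particle swarm over feature subsets
#'
#' Positions start uniform on `[-1, 1]` with zero velocities. Each
#' iteration binarises every particle, evaluates the wrapper fitness
#' (memoised per mask), updates personal and global bests under the
#' accuracy-then-size rule, and moves the swarm with the
#' constriction-factor velocity update and linearly decaying inertia.
#' Stops at `max_iters` or when the global best has stalled for
#' `stall_window` iterations. Fully reproducible from `cfg$seed`.
#'
#' @param x Numeric feature matrix (d >= 2 columns).
#' @param labels Class labels, one per row.
#' @param cfg A [swarm_config].
#' @return List with `gbest_mask`, `gbest_fitness`, `gbest_size`,
#'   `history` (per-iteration pbest masks and fitnesses), `iterations`,
#'   `n_evals` (distinct masks evaluated), and `phi`.
#' @export
run_mpso <- function(x, labels, cfg = swarm_config()) {
  stopifnot(inherits(cfg, "swarm_config"))
  d <- ncol(x)
  if (d < 2) stop("need at least 2 feature columns")
  phi <- if (cfg$constriction) constriction_factor(cfg$c1, cfg$c2) else 1.0
  folds <- stratified_folds(labels, cfg$fitness$folds, cfg$fitness$seed)

  cache <- new.env(parent = emptyenv())
  fit_of <- function(mask) {
    key <- paste(mask, collapse = "")
    got <- get0(key, envir = cache)
    if (!is.null(got)) return(got)
    val <- evaluate_fitness(mask, x, labels, cfg$fitness, folds = folds)
    assign(key, val, envir = cache)
    val
  }

  history <- vector("list", cfg$max_iters)
  res <- with_seed(cfg$seed, {
    position <- matrix(runif(cfg$n_particles * d, -1, 1), nrow = cfg$n_particles)
    velocity <- matrix(0, nrow = cfg$n_particles, ncol = d)
    pbest_mask <- matrix(0L, nrow = cfg$n_particles, ncol = d)
    pbest <- replicate(cfg$n_particles, list(accuracy = -Inf, size = d + 1L),
                       simplify = FALSE)
    gbest <- list(accuracy = -Inf, size = d + 1L)
    gbest_mask <- rep(0L, d)
    stall <- 0L
    iters <- 0L
    for (it in seq_len(cfg$max_iters)) {
      iters <- it
      w <- cfg$inertia_start +
        (cfg$inertia_end - cfg$inertia_start) *
          (it - 1) / max(cfg$max_iters - 1, 1)
      improved <- FALSE
      for (i in seq_len(cfg$n_particles)) {
        mask <- binarize_position(position[i, ])
        f <- fit_of(mask)
        if (better_than(f, pbest[[i]])) {
          pbest[[i]] <- f
          pbest_mask[i, ] <- mask
        }
        if (better_than(f, gbest)) {
          gbest <- f
          gbest_mask <- mask
          improved <- TRUE
        }
      }
      history[[it]] <- list(
        pbest_masks = pbest_mask,
        pbest_fitness = vapply(pbest, `[[`, numeric(1), "accuracy"),
        gbest_fitness = gbest$accuracy)
      for (i in seq_len(cfg$n_particles)) {
        velocity[i, ] <- update_velocity(position[i, ], velocity[i, ],
                                         pbest_mask[i, ], gbest_mask,
                                         w, phi, cfg$c1, cfg$c2, cfg$v_max)
        position[i, ] <- position[i, ] + velocity[i, ]
      }
      stall <- if (improved) 0L else stall + 1L
      if (stall >= cfg$stall_window) break
    }
    list(gbest = gbest, gbest_mask = gbest_mask, iters = iters)
  })
  list(gbest_mask = res$gbest_mask,
       gbest_fitness = res$gbest$accuracy,
       gbest_size = res$gbest$size,
       history = history[!vapply(history, is.null, logical(1))],
       iterations = res$iters,
       n_evals = length(ls(cache)),
       phi = phi)
}

#' Feature importance from the swarm history
#'
#' The importance of feature j is its fitness-weighted selection
#' frequency among all personal-best masks recorded over all iterations,
#' normalised so the largest weight is 1. This is the package's
#' aggregation convention for turning a swarm trajectory into per-feature
#' weights.
#'
#' @param history The `history` element returned by [run_mpso].
#' @param names Feature names in canonical column order.
#' @return Named numeric vector of weights in `[0, 1]`.
#' @export
feature_importance <- function(history, names = NULL) {
  stopifnot(length(history) >= 1)
  d <- ncol(history[[1]]$pbest_masks)
  acc <- numeric(d)
  for (h in history) {
    wts <- pmax(h$pbest_fitness, 0)
    acc <- acc + colSums(h$pbest_masks * wts)
  }
  if (max(acc) > 0) acc <- acc / max(acc)
  if (!is.null(names)) names(acc) <- names
  acc
}

#' Top-k features by importance
#'
#' Descending weight; ties broken by canonical (input) order.
#'
#' @param importance Named weight vector.
#' @param k Number of features to retain.
#' @return Character vector of k feature names.
#' @export
top_k_features <- function(importance, k) {
  if (k <= 0) stop("'k' must be positive")
  if (k > length(importance)) stop("'k' exceeds the number of features")
  ord <- order(-importance, seq_along(importance))
  names(importance)[ord][seq_len(k)]
}

#' Pearson correlation coefficient
#'
#' `r = sum((x - mean(x)) (y - mean(y))) / sqrt(sum((x - mean(x))^2)
#' sum((y - mean(y))^2))`, in `[-1, 1]`.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return The coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("'x' and 'y' must have equal length >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: zero variance input")
  }
  cor(x, y)
}

#' Pearson redundancy filter over a ranked feature list
#'
#' Greedy scan in ranked order: a feature is kept iff its absolute
#' correlation with every already-kept feature is at most `delta`. The
#' first (top-ranked) feature is always kept. Zero-variance columns are
#' dropped with a warning. All examined pairs are recorded.
#'
#' @param x Numeric feature matrix with named columns.
#' @param ranked Character vector of feature names, importance order.
#' @param delta Correlation threshold in `(0, 1)`.
#' @return List with `final_subset` (kept names, ranked order) and
#'   `r_table` (data frame `feature_X`, `feature_Y`, `r` of examined
#'   pairs).
#' @export
redundancy_filter <- function(x, ranked, delta = 0.6) {
  stopifnot(length(ranked) >= 1, all(ranked %in% colnames(x)))
  if (delta <= 0 || delta >= 1) stop("'delta' must be in (0, 1)")
  degenerate <- ranked[vapply(ranked, function(f) sd(x[, f]) == 0, logical(1))]
  if (length(degenerate) > 0) {
    warning("dropping zero-variance feature(s): ",
            paste(degenerate, collapse = ", "))
    ranked <- setdiff(ranked, degenerate)
  }
  kept <- character(0)
  rows <- list()
  for (f in ranked) {
    ok <- TRUE
    for (g in kept) {
      r <- pearson_r(x[, f], x[, g])
      rows[[length(rows) + 1L]] <- data.frame(feature_X = g, feature_Y = f, r = r)
      if (abs(r) > delta) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, f)
  }
  r_table <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(feature_X = character(0), feature_Y = character(0),
               r = numeric(0))
  list(final_subset = kept, r_table = r_table)
}

#' Two-stage swarm + correlation feature selection
#'
#' Stage 1 runs the modified binary swarm ([run_mpso]), aggregates the
#' history into per-feature importance weights, and retains the `top_k`
#' features. Stage 2 removes redundant features from that list with the
#' Pearson filter at threshold `delta`.
#'
#' @param features A `feature_matrix` (or numeric matrix with named
#'   columns, in which case `labels` must be supplied).
#' @param labels Class labels (ignored when `features` is a
#'   `feature_matrix`).
#' @param cfg A [swarm_config].
#' @return Object of class `selection_result`: `importance`,
#'   `ranked_top_k`, `r_table`, `final_subset`, `gbest_mask`,
#'   `gbest_fitness`, `swarm` (iteration/evaluation counts and phi).
#' @export
pmpso <- function(features, labels = NULL, cfg = swarm_config()) {
  if (inherits(features, "feature_matrix")) {
    labels <- features$labels
    x <- features$x
  } else {
    x <- as.matrix(features)
  }
  if (is.null(labels)) stop("'labels' required")
  run <- run_mpso(x, labels, cfg)
  imp <- feature_importance(run$history, names = colnames(x))
  ranked <- top_k_features(imp, min(cfg$top_k, length(imp)))
  filt <- redundancy_filter(x, ranked, cfg$delta)
  structure(list(importance = imp, ranked_top_k = ranked,
                 r_table = filt$r_table, final_subset = filt$final_subset,
                 gbest_mask = run$gbest_mask,
                 gbest_fitness = run$gbest_fitness,
                 swarm = list(iterations = run$iterations,
                              n_evals = run$n_evals, phi = run$phi,
                              gbest_size = run$gbest_size)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> gbest accuracy %.4f (%d features), phi=%.4f\n",
              x$gbest_fitness, x$swarm$gbest_size, x$swarm$phi))
  cat("  top-ranked:", paste(x$ranked_top_k, collapse = ", "), "\n")
  cat("  final subset:", paste(x$final_subset, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise / load a selection result
#'
#' The importance map, ranked list and final subset go to JSON; the
#' examined correlation pairs to `<path>_rtable.csv`.
#'
#' @param result A `selection_result`.
#' @param path JSON path.
#' @export
write_selection_result <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  jsonlite::write_json(list(importance = as.list(result$importance),
                            ranked_top_k = result$ranked_top_k,
                            final_subset = result$final_subset,
                            gbest_fitness = result$gbest_fitness,
                            swarm = result$swarm),
                       path, auto_unbox = TRUE, digits = NA)
  write.csv(result$r_table, sub("\\.json$", "_rtable.csv", path),
            row.names = FALSE)
  invisible(path)
}
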