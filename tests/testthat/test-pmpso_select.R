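test_that("constriction factor matches the closed form and deactivates at c <= 4", {
  expect_equal(constriction_factor(2.05, 2.05),
               2 / abs(2 - 4.1 - sqrt(4.1^2 - 4 * 4.1)))
  expect_equal(constriction_factor(2.05, 2.05), 0.7298, tolerance = 1e-4)

  phi5 <- constriction_factor(3, 2)
  expect_equal(phi5, 2 / abs(2 - 5 - sqrt(25 - 20)))
  expect_true(phi5 > 0 && phi5 < 1)
  # monotone decreasing in c on c > 4
  expect_gt(constriction_factor(2.05, 2.05), constriction_factor(3, 2))
  expect_gt(phi5, constriction_factor(3, 3))

  expect_warning(phi_off <- constriction_factor(1, 1), "c1 \\+ c2 > 4")
  expect_equal(phi_off, 1.0)
})

test_that("velocity update follows the constricted formula and clamps", {
  # fixed point: x = pbest = gbest leaves only the inertia term
  set.seed(1)
  v <- update_velocity(position = rep(1, 4), velocity = c(1, -2, 0.5, 0),
                       pbest_mask = rep(1, 4), gbest_mask = rep(1, 4),
                       w = 0.5, phi = 0.73, c1 = 2.05, c2 = 2.05, v_max = 4)
  expect_equal(v, 0.5 * c(1, -2, 0.5, 0))

  # phi = 0 degenerates to pure inertia regardless of the bests
  set.seed(1)
  v0 <- update_velocity(c(0, 0), c(2, -1), c(1, 0), c(0, 1),
                        w = 0.9, phi = 0, c1 = 2.05, c2 = 2.05, v_max = 4)
  expect_equal(v0, 0.9 * c(2, -1))

  # replayed draws reproduce the hand formula, then the clamp binds
  set.seed(42)
  vv <- update_velocity(0, 0, 1, 1, w = 0.5, phi = 0.7298,
                        c1 = 2.05, c2 = 2.05, v_max = 4)
  set.seed(42)
  r1 <- runif(1); r2 <- runif(1)
  expect_equal(vv, 0.7298 * (2.05 * r1 * 1 + 2.05 * r2 * 1))

  set.seed(42)
  vc <- update_velocity(0, 0, 1, 1, w = 0.5, phi = 50,
                        c1 = 2.05, c2 = 2.05, v_max = 4)
  expect_equal(vc, 4)
})

test_that("sigmoid binarisation saturates and repairs empty masks", {
  set.seed(1)
  expect_equal(binarize_position(rep(20, 10)), rep(1L, 10))
  expect_equal(binarize_position(rep(-20, 10)),
               c(1L, rep(0L, 9)))  # forced single selection at the argmax
  pos <- c(-20, -20, 5e-9, -20)
  set.seed(2)
  m <- binarize_position(pos)
  expect_equal(sum(m), 1)
  expect_equal(which(m == 1L), 3L)
})

test_that("wrapper fitness is accuracy on the masked columns, with contracts", {
  fm <- separable_features(n_per_class = 20)
  f <- evaluate_fitness(c(1L, 0L), fm$x, fm$labels)
  expect_equal(f$accuracy, 1.0)
  expect_equal(f$size, 1L)

  # pure-noise features score near chance (3 classes)
  set.seed(13)
  noise <- feature_matrix(matrix(rnorm(120 * 2), 120,
                                 dimnames = list(NULL, c("n1", "n2"))),
                          rep(c("a", "b", "c"), each = 40))
  fn <- evaluate_fitness(c(1L, 1L), noise$x, noise$labels)
  expect_lt(abs(fn$accuracy - 1 / 3), 0.18)

  expect_equal(evaluate_fitness(c(0L, 0L), fm$x, fm$labels),
               list(accuracy = 0, size = 0L))
  expect_error(evaluate_fitness(c(1L, 0L), fm$x, rep("a", nrow(fm$x))),
               "2 classes")

  # deterministic for fixed spec seeds
  tb <- small_table()
  f1 <- evaluate_fitness(rep(1L, 8), tb$features$x, tb$labels)
  f2 <- evaluate_fitness(rep(1L, 8), tb$features$x, tb$labels)
  expect_identical(f1, f2)
})

test_that("best-so-far comparison prefers accuracy then smaller subsets", {
  expect_true(better_than(list(accuracy = 0.95, size = 10),
                          list(accuracy = 0.93, size = 3)))
  expect_true(better_than(list(accuracy = 0.95, size = 4),
                          list(accuracy = 0.95, size = 7)))
  expect_false(better_than(list(accuracy = 0.95, size = 7),
                           list(accuracy = 0.95, size = 7)))
  expect_false(better_than(list(accuracy = 0.93, size = 1),
                           list(accuracy = 0.95, size = 9)))
})

test_that("the swarm is reproducible and its global best never degrades", {
  tb <- small_table()
  cfg <- fast_swarm(seed = 21)
  a <- run_mpso(tb$features$x, tb$labels, cfg)
  b <- run_mpso(tb$features$x, tb$labels, cfg)
  expect_identical(a$gbest_mask, b$gbest_mask)
  expect_identical(a$gbest_fitness, b$gbest_fitness)

  gb <- vapply(a$history, `[[`, numeric(1), "gbest_fitness")
  expect_true(all(diff(gb) >= 0))
  expect_equal(sum(a$gbest_mask), a$gbest_size)
})

test_that("identical columns collapse to a single feature via the size tie-break", {
  set.seed(31)
  cls <- rep(c("a", "b", "c"), each = 30)
  base <- as.integer(factor(cls)) * 2 + rnorm(90, sd = 0.3)
  x <- matrix(rep(base, 4), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  run <- run_mpso(x, cls, swarm_config(n_particles = 12, max_iters = 15,
                                       seed = 5, stall_window = 15,
                                       fitness = fitness_spec(folds = 3,
                                                              num_trees = 60)))
  expect_equal(run$gbest_size, 1L)
})

test_that("importance aggregation weights selection frequency by fitness", {
  h <- list(
    list(pbest_masks = rbind(c(1L, 0L, 1L), c(1L, 0L, 0L)),
         pbest_fitness = c(0.8, 0.6), gbest_fitness = 0.8),
    list(pbest_masks = rbind(c(1L, 0L, 1L), c(1L, 1L, 0L)),
         pbest_fitness = c(0.8, 0.7), gbest_fitness = 0.8))
  imp <- feature_importance(h, names = c("a", "b", "c"))
  # raw: a = .8+.6+.8+.7 = 2.9, b = .7, c = .8+.8 = 1.6; max-normalised
  expect_equal(unname(imp), c(2.9, 0.7, 1.6) / 2.9)
  expect_equal(imp[["a"]], 1.0)

  h0 <- list(list(pbest_masks = rbind(c(1L, 0L), c(1L, 0L)),
                  pbest_fitness = c(0.5, 0.5), gbest_fitness = 0.5))
  imp0 <- feature_importance(h0, names = c("x", "y"))
  expect_equal(imp0[["y"]], 0)  # never selected
  expect_equal(imp0[["x"]], 1)  # present in every pbest
})

test_that("top-k ranks by weight with canonical-order tie-breaks", {
  w <- c(a = 0.9, b = 0.5, c = 0.1)
  expect_equal(top_k_features(w, 2), c("a", "b"))
  expect_equal(top_k_features(w, 3), c("a", "b", "c"))
  tie <- c(p = 0.4, q = 0.9, r = 0.4)
  expect_equal(top_k_features(tie, 2), c("q", "p"))
  expect_error(top_k_features(w, 0), "positive")
  expect_error(top_k_features(w, 5), "exceeds")
})

test_that("Pearson r matches hand arithmetic and rejects degenerate input", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 3), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 5)), -0.5)
  expect_error(pearson_r(c(1, 2), c(3, 4)), "length")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("redundancy filter keeps first and drops |r| > delta against kept set", {
  set.seed(17)
  n <- 400
  f1 <- rnorm(n)
  f2 <- 0.97 * f1 + sqrt(1 - 0.97^2) * rnorm(n)  # |r| ~ 0.97 with f1
  f3 <- rnorm(n)                                  # independent
  x <- cbind(f1 = f1, f2 = f2, f3 = f3)
  out <- redundancy_filter(x, c("f1", "f2", "f3"), delta = 0.6)
  expect_equal(out$final_subset, c("f1", "f3"))
  expect_true(all(c("feature_X", "feature_Y", "r") %in% names(out$r_table)))
  expect_true(all(abs(out$r_table$r) <= 1))

  # nothing removed when all |r| <= delta
  weak <- redundancy_filter(x[, c("f1", "f3")], c("f1", "f3"), delta = 0.6)
  expect_equal(weak$final_subset, c("f1", "f3"))

  expect_equal(redundancy_filter(x, "f2", delta = 0.6)$final_subset, "f2")

  xz <- cbind(x, f4 = rep(1, n))
  expect_warning(rz <- redundancy_filter(xz, c("f4", "f1", "f3"), delta = 0.6),
                 "zero-variance")
  expect_equal(rz$final_subset, c("f1", "f3"))
})

test_that("the two-stage selector is deterministic and honours its contracts", {
  tb <- gen_feature_table(synth_table_spec(n_samples = 150, n_features = 12,
                                           informative_idx = 1:3,
                                           effect_size = 1.5, seed = 2))
  cfg <- fast_swarm(seed = 9, top_k = 6)
  r1 <- pmpso(tb$features, cfg = cfg)
  r2 <- pmpso(tb$features, cfg = cfg)
  expect_identical(r1$final_subset, r2$final_subset)
  expect_identical(r1$importance, r2$importance)

  expect_length(r1$ranked_top_k, 6)
  expect_true(all(r1$final_subset %in% r1$ranked_top_k))
  expect_true(all(abs(r1$importance) <= 1))
  # post-hoc: every retained pair satisfies the delta bound
  kept <- r1$final_subset
  if (length(kept) > 1) {
    combs <- combn(kept, 2)
    rr <- apply(combs, 2, function(p) pearson_r(tb$features$x[, p[1]],
                                                tb$features$x[, p[2]]))
    expect_true(all(abs(rr) <= cfg$delta))
  }

  path <- tempfile(fileext = ".json")
  write_selection_result(r1, path)
  blob <- jsonlite::read_json(path)
  expect_equal(unlist(blob$final_subset), r1$final_subset)
  expect_true(file.exists(sub("\\.json$", "_rtable.csv", path)))
})

test_that("velocities stay clamped and positions bounded under the constriction", {
  tb <- small_table(n = 90, d = 6)
  cfg <- swarm_config(n_particles = 8, max_iters = 25, seed = 12, v_max = 4,
                      stall_window = 25,
                      fitness = fitness_spec(folds = 3, num_trees = 40))
  run <- run_mpso(tb$features$x, tb$labels, cfg)
  expect_true(run$phi < 1)
  expect_lte(run$iterations, 25)
  # reproducible single-iteration degenerate case
  cfg1 <- swarm_config(n_particles = 2, max_iters = 1, seed = 3,
                       fitness = fitness_spec(folds = 3, num_trees = 40))
  expect_identical(run_mpso(tb$features$x, tb$labels, cfg1)$gbest_mask,
                   run_mpso(tb$features$x, tb$labels, cfg1)$gbest_mask)
})
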