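test_that("parameter genes decode onto the 2^-7 .. 2^8 grid", {
  expect_equal(decode_parameter(0), 2^-7)
  expect_equal(decode_parameter(15), 256)
  expect_equal(decode_parameter(7), 1)
  expect_length(unique(decode_parameter(0:15)), 16)
  expect_error(decode_parameter(16), "0, 15")
  expect_error(decode_parameter(-1), "0, 15")
  expect_error(decode_parameter(2.5), "integer")
})

test_that("fold assignment is stratified, deterministic, and LOO-degenerate", {
  labels <- rep(c("high", "low"), each = 30)
  f1 <- make_folds(labels, 10, seed = 4)
  f2 <- make_folds(labels, 10, seed = 4)
  expect_identical(f1, f2)
  for (k in 1:10) {
    expect_equal(sum(f1 == k & labels == "high"), 3)
    expect_equal(sum(f1 == k & labels == "low"), 3)
  }
  expect_false(identical(f1, make_folds(labels, 10, seed = 5)))
  expect_equal(make_folds(labels, 60, seed = 1), 1:60)   # leave-one-out
  expect_error(make_folds(rep(c("high", "low"), c(5, 55)), 10, seed = 1),
               "fewer members")
})

test_that("fitness is CV accuracy with deterministic folds", {
  sep <- separable_data(n = 60, d = 5)
  chrom <- new_chromosome(rep(TRUE, 5), c_gene = 10, gamma_gene = 5)
  fit <- evaluate_fitness(chrom, sep$x, sep$labels, folds = 10, seed = 2)
  expect_s3_class(fit, "ibcga_fitness")
  expect_equal(fit$cv_accuracy, 100)
  expect_equal(fit$num_features, 5)
  expect_identical(fit, evaluate_fitness(chrom, sep$x, sep$labels,
                                         folds = 10, seed = 2))
  empty <- chrom; empty$mask <- rep(FALSE, 5)
  expect_error(evaluate_fitness(empty, sep$x, sep$labels), "zero features")
})

test_that("fitness on permuted labels is near chance", {
  set.seed(77)
  accs <- replicate(20, {
    x <- matrix(stats::rnorm(200 * 5), 200, 5,
                dimnames = list(NULL, sprintf("F%d", 1:5)))
    labels <- sample(rep(c("high", "low"), 100))
    chrom <- new_chromosome(rep(TRUE, 5), 9, 5)
    evaluate_fitness(chrom, x, labels, folds = 10,
                     seed = sample.int(1e6, 1))$cv_accuracy
  })
  expect_gt(mean(accs), 45)
  expect_lt(mean(accs), 55)
})

test_that("tournament selection picks the better of two uniform draws", {
  mk <- function(acc) {
    ch <- new_chromosome(c(TRUE, FALSE), 1, 1)
    ch$fitness <- structure(list(cv_accuracy = acc, num_features = 1),
                            class = "ibcga_fitness")
    ch
  }
  single <- list(mk(50))
  expect_equal(tournament_select(single)$fitness$cv_accuracy, 50)

  pop <- list(mk(90), mk(80), mk(70))
  set.seed(123)
  wins <- replicate(10000, tournament_select(pop)$fitness$cv_accuracy)
  # P(best of two uniform-with-replacement draws is A) = 1 - (2/3)^2 = 5/9
  expect_equal(mean(wins == 90), 5 / 9, tolerance = 0.04)
  expect_equal(mean(wins == 70), 1 / 9, tolerance = 0.04)
})

test_that("fitness ordering is lexicographic (accuracy, then fewer features)", {
  f <- function(a, m) structure(list(cv_accuracy = a, num_features = m),
                                class = "ibcga_fitness")
  expect_true(fitness_better(f(90, 20), f(89, 10)))
  expect_true(fitness_better(f(90, 10), f(90, 20)))
  expect_false(fitness_better(f(90, 20), f(90, 10)))
})

test_that("OA crossover returns the additive-fitness optimum and is frugal", {
  set.seed(31)
  n_bits <- 12
  for (trial in 1:25) {
    w <- stats::rnorm(n_bits)
    wc <- stats::rnorm(1); wg <- stats::rnorm(1)
    additive <- function(ch) {
      structure(list(cv_accuracy = sum(w[ch$mask]) + wc * ch$c_gene +
                       wg * ch$gamma_gene,
                     num_features = sum(ch$mask)),
                class = "ibcga_fitness")
    }
    m1 <- sample(c(TRUE, FALSE), n_bits, replace = TRUE)
    m2 <- m1
    flip <- sample.int(n_bits, sample(1:5, 1))
    m2[flip] <- !m2[flip]
    p1 <- new_chromosome(m1, sample(0:15, 1), sample(0:15, 1))
    p2 <- new_chromosome(m2, sample(0:15, 1), sample(0:15, 1))

    n_evals <- 0L
    counting <- function(ch) { n_evals <<- n_evals + 1L; additive(ch) }
    child <- oa_crossover(p1, p2, counting, target_r = NULL)
    expect_lte(n_evals, 9)

    # brute force over every parent-level combination of the differing units
    units <- c(as.list(which(m1 != m2)),
               if (p1$c_gene != p2$c_gene) list("C"),
               if (p1$gamma_gene != p2$gamma_gene) list("G"))
    combos <- expand.grid(rep(list(1:2), length(units)))
    best <- -Inf
    for (r in seq_len(nrow(combos))) {
      cand <- p1
      for (j in seq_along(units)) {
        if (combos[r, j] == 2) {
          u <- units[[j]]
          if (identical(u, "C")) cand$c_gene <- p2$c_gene
          else if (identical(u, "G")) cand$gamma_gene <- p2$gamma_gene
          else cand$mask[u] <- p2$mask[u]
        }
      }
      best <- max(best, additive(cand)$cv_accuracy)
    }
    expect_equal(child$fitness$cv_accuracy, best, tolerance = 1e-9)
  }
})

test_that("OA crossover with identical parents costs no evaluations", {
  p <- new_chromosome(c(TRUE, TRUE, FALSE, FALSE), 3, 4)
  n_evals <- 0L
  child <- oa_crossover(p, p, function(ch) { n_evals <<- n_evals + 1L },
                        target_r = 2)
  expect_equal(n_evals, 0L)
  expect_identical(child$mask, p$mask)
})

test_that("mask repair restores the exact selection size", {
  set.seed(6)
  m <- rep(FALSE, 20); m[1:12] <- TRUE
  expect_identical(repair_mask(m, 12), m)          # already on target
  down <- repair_mask(m, 10)
  expect_equal(sum(down), 10)
  expect_true(all(which(down) %in% which(m)))      # only clears set bits
  up <- repair_mask(m, 15)
  expect_equal(sum(up), 15)
  expect_true(all(which(m) %in% which(up)))
  expect_error(repair_mask(m, 21), "exceeds the mask length")
})

test_that("mutation preserves selection size and never touches the elite", {
  set.seed(14)
  chrom <- new_chromosome(rep(c(TRUE, FALSE), each = 10), 7, 7)
  expect_identical(mutate_chromosome(chrom, 1, is_elite = TRUE), chrom)
  for (i in 1:20) {
    mut <- mutate_chromosome(chrom, 1)
    expect_equal(sum(mut$mask), 10)
    expect_true(mut$c_gene %in% 0:15 && mut$gamma_gene %in% 0:15)
  }
  # all-ones mask: no swap possible, parameter genes still mutate
  full <- new_chromosome(rep(TRUE, 5), 0, 15)
  muts <- replicate(50, {
    m <- mutate_chromosome(full, 1)
    c(sum(m$mask), m$c_gene, m$gamma_gene)
  })
  expect_true(all(muts[1, ] == 5))
  expect_true(any(muts[2, ] != 0 | muts[3, ] != 15))
  expect_true(all(muts[2, ] >= 0 & muts[2, ] <= 15))
})

test_that("a single-stage run keeps the selection size fixed and is reproducible", {
  set.seed(99)
  ds <- generate_dataset(n_complexes = 60, n_properties = 30,
                         n_informative = 3, effect_size = 2, seed = 12)
  x <- fit_scaling(encode_dataset(ds$records, ds$tables))
  cfg <- search_config(population_size = 10, generations_per_stage = 6,
                       r_start = 4, r_end = 4, cv_folds = 5, seed = 3)
  res <- run_ibcga(x, ds$records$label, cfg)
  expect_length(res$stage_bests, 1)
  expect_equal(res$fitness$num_features, 4)
  for (ch in res$stage_bests) expect_equal(sum(ch$mask), 4)

  res2 <- run_ibcga(x, ds$records$label, cfg)
  expect_identical(res$selected, res2$selected)
  expect_identical(res$log, res2$log)
  expect_identical(res$fitness, res2$fitness)
})

test_that("the stage-best fitness never decreases within a stage", {
  set.seed(100)
  ds <- generate_dataset(n_complexes = 60, n_properties = 25,
                         n_informative = 2, effect_size = 2, seed = 8)
  x <- fit_scaling(encode_dataset(ds$records, ds$tables))
  cfg <- search_config(population_size = 8, generations_per_stage = 8,
                       r_start = 3, r_end = 5, cv_folds = 5, seed = 21)
  res <- run_ibcga(x, ds$records$label, cfg)
  for (r in unique(res$log$r)) {
    trace <- res$log$best_accuracy[res$log$r == r]
    expect_true(all(diff(trace) >= 0))
  }
  expect_length(res$stage_bests, 3)
  expect_equal(vapply(res$stage_bests, function(ch) sum(ch$mask), 1L),
               c(`3` = 3L, `4` = 4L, `5` = 5L))
  # the overall best dominates every stage best
  for (ch in res$stage_bests) {
    expect_false(fitness_better(ch$fitness, res$fitness))
  }
})

test_that("search_config validates its fields", {
  expect_error(search_config(r_start = 0), "r_start")
  expect_error(search_config(r_start = 10, r_end = 5), "r_end")
  expect_error(search_config(tournament_size = 3), "fixed at 2")
  expect_error(search_config(mutation_rate = 1.5), "probability")
  sep <- separable_data(n = 20, d = 3)
  expect_error(run_ibcga(sep$x, sep$labels,
                         search_config(r_start = 2, r_end = 5)),
               "exceeds the number of candidate features")
})
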