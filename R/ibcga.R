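# Inheritable bi-objective combinatorial GA for joint feature and SVM
# parameter selection. Chromosomes carry a fixed-size feature mask plus two
# 4-bit genes decoding the SVM cost and kernel width; the search proceeds
# in stages of fixed subset size r, inheriting solutions from r to r + 1.

#' Decode a 4-bit parameter gene
#'
#' Genes 0..15 decode to the geometric grid `2^-7, 2^-6, ..., 2^8` shared
#' by the SVM cost C and the RBF width gamma.
#'
#' @param gene integer in 0..15.
#' @return the decoded parameter value `2^(gene - 7)`.
#' @examples
#' decode_parameter(0)   # 2^-7
#' decode_parameter(15)  # 256
#' @export
decode_parameter <- function(gene) {
  if (any(gene != round(gene)) || any(gene < 0) || any(gene > 15)) {
    fail("parameter gene must be an integer in [0, 15]")
  }
  2^(gene - 7)
}

#' Construct a chromosome
#'
#' @param mask logical feature-selection vector over the candidate
#'   properties.
#' @param c_gene,gamma_gene 4-bit parameter genes (integers in 0..15).
#' @return list of class `chromosome` (fields `mask`, `c_gene`,
#'   `gamma_gene`, and `fitness` once evaluated).
#' @export
new_chromosome <- function(mask, c_gene, gamma_gene) {
  stopifnot(is.logical(mask), length(mask) >= 1)
  decode_parameter(c(c_gene, gamma_gene))  # range check
  structure(list(mask = mask, c_gene = as.integer(c_gene),
                 gamma_gene = as.integer(gamma_gene), fitness = NULL),
            class = "chromosome")
}

chromosome_key <- function(chrom) {
  paste(c(which(chrom$mask), "C", chrom$c_gene, "G", chrom$gamma_gene),
        collapse = ",")
}

#' Fitness of a chromosome
#'
#' Repeated stratified k-fold cross-validation accuracy (in percent) of
#' the RBF-SVM classifier trained on the masked feature columns with the
#' decoded C and gamma, paired with the number of selected features. The
#' accuracy is averaged over two independent fold assignments derived
#' deterministically from the seed, which doubles the resolution of the
#' fitness and halves the single-partition luck that wrapper selection
#' would otherwise latch onto. Both assignments are pure functions of
#' `(labels, folds, seed)`, so re-evaluating the same chromosome always
#' returns the identical fitness. The matrix is expected to be scaled to
#' [-1, 1] already; no per-fold rescaling is done here (the full
#' evaluation protocol in [cross_validate()] does rescale).
#'
#' @param chrom a [new_chromosome()] with at least one selected feature.
#' @param x scaled feature matrix (complexes x candidate properties).
#' @param labels class labels per row.
#' @param folds number of CV folds.
#' @param seed fold-assignment seed.
#' @return list of class `ibcga_fitness` with `cv_accuracy` (percent) and
#'   `num_features`.
#' @export
evaluate_fitness <- function(chrom, x, labels, folds = 10, seed = 1L) {
  if (sum(chrom$mask) < 1) fail("chromosome selects zero features")
  labels <- as_affinity_factor(labels)
  sel <- which(chrom$mask)
  cost <- decode_parameter(chrom$c_gene)
  gamma <- decode_parameter(chrom$gamma_gene)
  correct <- 0L
  n_pred <- 0L
  for (fold_seed in c(seed, seed + 1000003L)) {
    fold_id <- make_folds(labels, folds, fold_seed)
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f
      fit <- e1071::svm(x[tr, sel, drop = FALSE], labels[tr],
                        type = "C-classification", kernel = "radial",
                        cost = cost, gamma = gamma, scale = FALSE,
                        shrinking = FALSE, fitted = FALSE, cachesize = 4)
      pred <- stats::predict(fit, x[!tr, sel, drop = FALSE])
      correct <- correct + sum(pred == labels[!tr])
    }
    n_pred <- n_pred + nrow(x)
  }
  structure(list(cv_accuracy = 100 * correct / n_pred,
                 num_features = length(sel)),
            class = "ibcga_fitness")
}

#' Compare two fitness values
#'
#' Lexicographic bi-objective ordering: higher cross-validation accuracy
#' wins; ties are broken in favour of fewer selected features.
#'
#' @param a,b `ibcga_fitness` values.
#' @return `TRUE` if `a` is strictly better than `b`.
#' @export
fitness_better <- function(a, b) {
  if (a$cv_accuracy != b$cv_accuracy) return(a$cv_accuracy > b$cv_accuracy)
  a$num_features < b$num_features
}

#' Binary tournament selection
#'
#' Draws two individuals uniformly with replacement and returns the better
#' one under [fitness_better()]. All individuals must carry an evaluated
#' `$fitness`. Uses the current RNG stream.
#'
#' @param population nonempty list of evaluated chromosomes.
#' @return the winning chromosome.
#' @export
tournament_select <- function(population) {
  if (length(population) == 0) fail("population is empty")
  idx <- sample.int(length(population), 2, replace = TRUE)
  a <- population[[idx[1]]]; b <- population[[idx[2]]]
  if (is.null(a$fitness) || is.null(b$fitness)) {
    fail("tournament_select requires evaluated individuals")
  }
  if (fitness_better(b$fitness, a$fitness)) b else a
}

#' Orthogonal-array crossover
#'
#' Recombines two parents through a small orthogonal design instead of a
#' random cut: (1) the positions where the parents differ (mask bits, and
#' each 4-bit parameter gene as one atomic unit) are grouped in order into
#' at most 7 contiguous factors; (2) each row of the two-level L8
#' orthogonal array defines a candidate child taking every factor from
#' parent 1 (level 1) or parent 2 (level 2); (3) candidates are repaired
#' to `target_r` selected features (if requested) and evaluated; (4) each
#' factor's main effect (mean fitness at level 1 minus level 2) composes a
#' predicted-best child from the better level per factor; (5) the best of
#' the evaluated rows and the composed child is returned. At most 9
#' distinct fitness evaluations are issued; identical parents return a
#' copy of parent 1 with no evaluations.
#'
#' @param p1,p2 parent chromosomes with equal mask length.
#' @param fitness_fn function(chromosome) -> `ibcga_fitness`.
#' @param target_r required number of selected features after repair, or
#'   `NULL` to leave candidate masks unrepaired.
#' @return the best child found, with its `$fitness` attached.
#' @export
oa_crossover <- function(p1, p2, fitness_fn, target_r = NULL) {
  if (length(p1$mask) != length(p2$mask)) {
    fail("parents must have masks of equal length")
  }
  diff_bits <- which(p1$mask != p2$mask)
  units <- c(as.list(diff_bits),
             if (p1$c_gene != p2$c_gene) list("C"),
             if (p1$gamma_gene != p2$gamma_gene) list("G"))
  k <- length(units)
  if (k == 0) return(p1)
  n_fac <- min(7L, k)
  # contiguous near-equal blocks of the ordered differing units
  fac_of <- floor((seq_len(k) - 1) * n_fac / k) + 1L
  oa <- oa_two_level(7L)[, seq_len(n_fac), drop = FALSE]

  build <- function(levels_per_factor) {
    child <- p1
    child$fitness <- NULL
    for (j in seq_len(k)) {
      if (levels_per_factor[fac_of[j]] == 2L) {
        u <- units[[j]]
        if (identical(u, "C")) {
          child$c_gene <- p2$c_gene
        } else if (identical(u, "G")) {
          child$gamma_gene <- p2$gamma_gene
        } else {
          child$mask[u] <- p2$mask[u]
        }
      }
    }
    if (!is.null(target_r)) child$mask <- repair_mask(child$mask, target_r)
    child
  }

  memo <- new.env(parent = emptyenv())
  evaluate <- function(child) {
    key <- chromosome_key(child)
    if (!is.null(memo[[key]])) return(memo[[key]])
    child$fitness <- fitness_fn(child)
    memo[[key]] <- child
    child
  }

  rows <- lapply(seq_len(nrow(oa)), function(i) evaluate(build(oa[i, ])))
  acc <- vapply(rows, function(ch) ch$fitness$cv_accuracy, numeric(1))
  best_levels <- vapply(seq_len(n_fac), function(f) {
    me <- mean(acc[oa[, f] == 1L]) - mean(acc[oa[, f] == 2L])
    if (me >= 0) 1L else 2L
  }, integer(1))
  composed <- evaluate(build(best_levels))

  best <- composed
  for (ch in rows) {
    if (fitness_better(ch$fitness, best$fitness)) best <- ch
  }
  best
}

#' Repair a feature mask to an exact selection size
#'
#' Randomly clears surplus selected bits or sets additional unselected
#' bits until exactly `target_r` features are selected. Uses the current
#' RNG stream.
#'
#' @param mask logical mask.
#' @param target_r required number of `TRUE` bits.
#' @return repaired mask.
#' @export
repair_mask <- function(mask, target_r) {
  if (target_r > length(mask)) {
    fail("target_r (%d) exceeds the mask length (%d)", target_r, length(mask))
  }
  if (target_r < 0) fail("target_r must be nonnegative")
  pc <- sum(mask)
  if (pc > target_r) {
    ones <- which(mask)
    mask[ones[sample.int(length(ones), pc - target_r)]] <- FALSE
  } else if (pc < target_r) {
    zeros <- which(!mask)
    mask[zeros[sample.int(length(zeros), target_r - pc)]] <- TRUE
  }
  mask
}

#' Mutate a chromosome
#'
#' Non-elite individuals are mutated in two independent ways, each with
#' probability `mutation_rate`: a feature swap exchanging one randomly
#' chosen selected bit with one unselected bit (selection size preserved),
#' and a +-1 perturbation of one parameter gene, reflected at the [0, 15]
#' grid boundary. The elite individual is returned unchanged so the best
#' fitness never deteriorates. Uses the current RNG stream.
#'
#' @param chrom chromosome to mutate.
#' @param mutation_rate per-individual mutation probability.
#' @param is_elite if `TRUE`, return `chrom` untouched.
#' @return the (possibly) mutated chromosome; its fitness is cleared if
#'   anything changed.
#' @export
mutate_chromosome <- function(chrom, mutation_rate = 0.05, is_elite = FALSE) {
  if (is_elite) return(chrom)
  changed <- FALSE
  if (stats::runif(1) < mutation_rate) {
    ones <- which(chrom$mask)
    zeros <- which(!chrom$mask)
    if (length(ones) > 0 && length(zeros) > 0) {
      chrom$mask[ones[sample.int(length(ones), 1)]] <- FALSE
      chrom$mask[zeros[sample.int(length(zeros), 1)]] <- TRUE
      changed <- TRUE
    }
  }
  if (stats::runif(1) < mutation_rate) {
    gene <- if (stats::runif(1) < 0.5) "c_gene" else "gamma_gene"
    delta <- if (stats::runif(1) < 0.5) -1L else 1L
    val <- chrom[[gene]] + delta
    if (val < 0L || val > 15L) val <- chrom[[gene]] - delta
    chrom[[gene]] <- val
    changed <- TRUE
  }
  if (changed) chrom$fitness <- NULL
  chrom
}

#' Search configuration for [run_ibcga()]
#'
#' @param population_size number of individuals.
#' @param generations_per_stage generations run at each subset size r.
#' @param tournament_size tournament size (fixed at 2).
#' @param mutation_rate per-individual mutation probability.
#' @param crossovers_per_generation mean number of orthogonal-array
#'   crossovers per generation (each costs up to 9 fitness evaluations);
#'   fractional rates spread crossovers evenly across the stage.
#' @param r_start,r_end inclusive range of feature-subset sizes searched.
#' @param cv_folds folds of the fitness cross-validation.
#' @param seed master seed; two runs with identical configuration are
#'   byte-identical.
#' @return list of class `search_config`.
#' @export
search_config <- function(population_size = 50L, generations_per_stage = 60L,
                          tournament_size = 2L, mutation_rate = 0.05,
                          crossovers_per_generation = 0.5,
                          r_start = 10L, r_end = 20L, cv_folds = 10L,
                          seed = 1L) {
  cfg <- list(population_size = as.integer(population_size),
              generations_per_stage = as.integer(generations_per_stage),
              tournament_size = as.integer(tournament_size),
              mutation_rate = mutation_rate,
              crossovers_per_generation = crossovers_per_generation,
              r_start = as.integer(r_start), r_end = as.integer(r_end),
              cv_folds = as.integer(cv_folds), seed = as.integer(seed))
  if (cfg$tournament_size != 2L) fail("tournament_size is fixed at 2")
  if (cfg$population_size < 2) fail("population_size must be at least 2")
  if (cfg$r_start < 1) fail("r_start must be at least 1")
  if (cfg$r_end < cfg$r_start) fail("r_end must be >= r_start")
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 1) {
    fail("mutation_rate must be a probability")
  }
  if (cfg$crossovers_per_generation < 0) {
    fail("crossovers_per_generation must be nonnegative")
  }
  structure(cfg, class = "search_config")
}

#' Run the inheritable bi-objective combinatorial GA
#'
#' Searches feature subsets of size `r = r_start, ..., r_end` jointly with
#' the SVM parameter genes. Each stage runs a steady-state GA: every
#' generation produces a few offspring --- orthogonal-array crossovers of
#' binary-tournament-selected parents, plus size-preserving swap mutants
#' spawned from randomly chosen individuals --- and truncates the pool
#' back to the best `population_size` individuals, so the best fitness
#' never deteriorates and distinct lineages persist until crossover merges
#' them. The stage best is recorded, then every individual inherits its
#' solution with one random unselected feature switched on and the search
#' continues at r + 1. Fitness values are cached per distinct chromosome, so copies and
#' re-encounters cost nothing. The entire run is reproducible from
#' `config$seed`.
#'
#' @param x feature matrix scaled to [-1, 1] (see [fit_scaling()]).
#' @param labels class labels per row, near-balanced.
#' @param config a [search_config()].
#' @return object of class `ibcga_result`: `stage_bests` (one evaluated
#'   chromosome per r), `best` (the overall winner), `cost`, `gamma`,
#'   `selected` (property ids), `fitness`, `log` (per-generation best
#'   fitness trace) and `n_evaluations`.
#' @export
run_ibcga <- function(x, labels, config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  if (config$r_end > ncol(x)) {
    fail("r_end (%d) exceeds the number of candidate features (%d)",
         config$r_end, ncol(x))
  }
  labels <- as_affinity_factor(labels)

  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  fit_fn <- function(chrom) {
    key <- chromosome_key(chrom)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- evaluate_fitness(chrom, x, labels, config$cv_folds, config$seed)
    n_evals <<- n_evals + 1L
    cache[[key]] <- val
    val
  }
  ensure_evaluated <- function(pop) {
    for (i in seq_along(pop)) {
      if (is.null(pop[[i]]$fitness)) pop[[i]]$fitness <- fit_fn(pop[[i]])
    }
    pop
  }
  best_index <- function(pop) {
    b <- 1L
    for (i in seq_along(pop)[-1]) {
      if (fitness_better(pop[[i]]$fitness, pop[[b]]$fitness)) b <- i
    }
    b
  }

  n_feat <- ncol(x)
  stage_bests <- list()
  log_rows <- list()

  with_seed(config$seed, {
    population <- lapply(seq_len(config$population_size), function(i) {
      mask <- rep(FALSE, n_feat)
      mask[sample.int(n_feat, config$r_start)] <- TRUE
      new_chromosome(mask, sample.int(16L, 1) - 1L, sample.int(16L, 1) - 1L)
    })

    for (r in config$r_start:config$r_end) {
      if (r > config$r_start) {
        # inheritance: switch one random unselected feature on per individual
        population <- lapply(population, function(ch) {
          zeros <- which(!ch$mask)
          ch$mask[zeros[sample.int(length(zeros), 1)]] <- TRUE
          ch$fitness <- NULL
          ch
        })
      }
      for (g in seq_len(config$generations_per_stage)) {
        population <- ensure_evaluated(population)
        # offspring: orthogonal-array crossovers of tournament-selected
        # parents, plus mutants spawned from randomly selected individuals
        # (parents are retained, so lineages carrying different informative
        # features coexist until crossover merges them)
        offspring <- list()
        # a fractional crossover rate spreads crossovers evenly over the
        # stage (0.5 means every other generation)
        n_cx <- floor(g * config$crossovers_per_generation) -
          floor((g - 1) * config$crossovers_per_generation)
        for (cx in seq_len(n_cx)) {
          p1 <- tournament_select(population)
          p2 <- tournament_select(population)
          child <- oa_crossover(p1, p2, fit_fn, target_r = r)
          if (is.null(child$fitness)) child$fitness <- fit_fn(child)
          offspring[[length(offspring) + 1L]] <- child
        }
        for (i in seq_along(population)) {
          if (stats::runif(1) < config$mutation_rate) {
            mut <- mutate_chromosome(population[[i]], 1)
            mut$fitness <- fit_fn(mut)
            offspring[[length(offspring) + 1L]] <- mut
          }
        }
        # (mu + lambda) truncation over distinct chromosomes; stable order
        # keeps incumbents on ties and the best can never be displaced
        # (elitism). Slots freed by duplicates are refilled with random
        # immigrants so the population size and diversity are maintained.
        pool <- c(population, offspring)
        pool <- pool[!duplicated(vapply(pool, chromosome_key, character(1)))]
        acc <- vapply(pool, function(ch) ch$fitness$cv_accuracy, numeric(1))
        keep <- order(-acc)[seq_len(min(length(pool),
                                        config$population_size))]
        population <- pool[keep]
        while (length(population) < config$population_size) {
          mask <- rep(FALSE, n_feat)
          mask[sample.int(n_feat, r)] <- TRUE
          imm <- new_chromosome(mask, sample.int(16L, 1) - 1L,
                                sample.int(16L, 1) - 1L)
          imm$fitness <- fit_fn(imm)
          population[[length(population) + 1L]] <- imm
        }
        b <- population[[best_index(population)]]
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(r = r, generation = g,
                     best_accuracy = b$fitness$cv_accuracy,
                     n_evaluations = n_evals)
      }
      stage_bests[[as.character(r)]] <- population[[best_index(population)]]
    }
  })

  best <- stage_bests[[1]]
  for (ch in stage_bests) {
    if (fitness_better(ch$fitness, best$fitness)) best <- ch
  }
  structure(
    list(stage_bests = stage_bests, best = best,
         cost = decode_parameter(best$c_gene),
         gamma = decode_parameter(best$gamma_gene),
         selected = colnames(x)[best$mask],
         fitness = best$fitness,
         log = do.call(rbind, log_rows),
         n_evaluations = n_evals,
         config = config),
    class = "ibcga_result"
  )
}

#' @export
print.ibcga_result <- function(x, ...) {
  cat(sprintf(
    "<ibcga_result> best r=%d  CV accuracy %.2f%%  C=%g  gamma=%g  (%d evaluations)\n",
    x$fitness$num_features, x$fitness$cv_accuracy, x$cost, x$gamma,
    x$n_evaluations))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
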