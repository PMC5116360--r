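#' Genetic-algorithm configuration for feature-subset selection
#'
#' Defaults follow the reference protocol: binary population of 300, up to
#' 100 generations, crossover probability 0.7 with a double (two-point)
#' string crossover, per-bit mutation probability 0.05, rank-based selection
#' with the two best chromosomes surviving unchanged, and early stopping
#' when the best fitness has not decreased for 30 consecutive generations.
#'
#' @param pop_size Population size (>= 2 * `elitism`).
#' @param generations Generation cap.
#' @param crossover_prob Probability that a selected pair is crossed.
#' @param mutation_prob Per-bit flip probability.
#' @param elitism Number of best chromosomes copied unchanged (default 2).
#' @param patience Stop after this many generations without strict
#'   improvement of the best-ever fitness.
#' @param selection_pressure Linear-ranking selection pressure in `(1, 2]`.
#' @param seed Integer seed; the whole run is deterministic in it.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 300, generations = 100,
                      crossover_prob = 0.7, mutation_prob = 0.05,
                      elitism = 2, patience = 30,
                      selection_pressure = 2, seed = 1) {
  stopifnot(
    pop_size >= 2 * elitism,
    crossover_prob >= 0, crossover_prob <= 1,
    mutation_prob >= 0, mutation_prob <= 1,
    generations >= 1, patience >= 1,
    selection_pressure > 1, selection_pressure <= 2
  )
  structure(
    list(pop_size = as.integer(pop_size),
         generations = as.integer(generations),
         crossover_prob = crossover_prob, mutation_prob = mutation_prob,
         elitism = as.integer(elitism), patience = as.integer(patience),
         selection_pressure = selection_pressure, seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Random initial population of feature-inclusion masks
#'
#' Each bit is Bernoulli(0.5); all-zero chromosomes (empty feature sets)
#' are redrawn.
#'
#' @param pop_size Number of chromosomes.
#' @param n_features Bits per chromosome (default 16).
#' @return 0/1 integer matrix, `pop_size` x `n_features`.
#' @export
init_population <- function(pop_size, n_features = 16) {
  pop <- matrix(stats::rbinom(pop_size * n_features, 1, 0.5),
                nrow = pop_size)
  empty <- rowSums(pop) == 0
  while (any(empty)) {
    pop[empty, ] <- stats::rbinom(sum(empty) * n_features, 1, 0.5)
    empty <- rowSums(pop) == 0
  }
  pop
}

#' Linear-ranking selection probabilities
#'
#' Ranks chromosomes by fitness (lower error = better = higher rank) and
#' assigns probability proportional to
#' `2 - SP + 2 (SP - 1) (rank - 1) / (N - 1)` with the best chromosome at
#' rank `N`; with the default pressure `SP = 2` the worst chromosome has
#' probability zero.
#'
#' @param fitness Numeric vector of error rates (lower is better).
#' @param selection_pressure `SP` in `(1, 2]`.
#' @return Probability vector summing to 1.
#' @export
rank_probabilities <- function(fitness, selection_pressure = 2) {
  n <- length(fitness)
  if (n == 1) return(1)
  # rank n = best (lowest fitness); ties share order arbitrarily but
  # deterministically via stable ordering
  rk <- n + 1 - rank(fitness, ties.method = "first")
  p <- (2 - selection_pressure) +
    2 * (selection_pressure - 1) * (rk - 1) / (n - 1)
  p / sum(p)
}

#' Double (two-point) string crossover
#'
#' With probability `pc`, two cut points `i < j` are drawn uniformly and the
#' segment `[i, j)` is swapped between the parents; otherwise the children
#' are exact copies.
#'
#' @param a,b Equal-length 0/1 parent vectors.
#' @param pc Crossover probability.
#' @return List of two children.
#' @export
double_point_crossover <- function(a, b, pc = 0.7) {
  if (length(a) != length(b)) stop("parents must have equal length")
  if (stats::runif(1) < pc) {
    cuts <- sort(sample.int(length(a) + 1, 2) - 1)
    if (cuts[1] < cuts[2]) {
      seg <- seq(cuts[1] + 1, cuts[2])
      tmp <- a[seg]
      a[seg] <- b[seg]
      b[seg] <- tmp
    }
  }
  list(a, b)
}

#' Per-bit mutation
#'
#' Flips each bit independently with probability `pm`.
#'
#' @param bits 0/1 vector.
#' @param pm Per-bit flip probability.
#' @return Mutated 0/1 vector.
#' @export
mutate_bits <- function(bits, pm = 0.05) {
  flip <- stats::runif(length(bits)) < pm
  bits[flip] <- 1L - bits[flip]
  bits
}

#' GA-driven feature-subset selection with KNN cross-validation fitness
#'
#' Evolves a population of binary feature-inclusion masks; each mask's
#' fitness is the pooled 23-fold cross-validated KNN error rate
#' `theta = 1 - Ac/100` from [cross_validate()] on `table`. Generations
#' apply elitism (best `elitism` survive unchanged), linear-rank parent
#' selection, double-point crossover and per-bit mutation, stopping at the
#' generation cap or when the best-ever fitness has not strictly decreased
#' for `patience` generations. Children with an empty mask receive the worst
#' fitness (1) rather than being redrawn. Fitness values are memoised per
#' unique mask, so the run cost is bounded by the number of distinct masks
#' visited.
#'
#' @param table Feature table (scale first with [minmax_scale()] for the
#'   standard configuration).
#' @param k Neighbour count for the KNN fitness (default 5).
#' @param cfg A [ga_config()].
#' @param folds Fold assignment from [make_folds()], or a fold count
#'   (default 23; a plan is built with `cfg$seed`). The same folds are used
#'   for every fitness evaluation.
#' @return An object of class `ga_run`: `best_mask`, `best_features`,
#'   `best_theta`, full `best_metrics` (an `hrv_cv`), per-generation
#'   `history` tibble, `generations_run`, `n_evaluated` distinct masks and
#'   the `config`.
#' @examples
#' \donttest{
#' tab <- minmax_scale(toy_feature_table(seed = 1))
#' run <- run_ga(tab, cfg = ga_config(pop_size = 30, generations = 10))
#' glance(run)
#' }
#' @export
run_ga <- function(table, k = 5, cfg = ga_config(), folds = 23) {
  stopifnot(inherits(cfg, "ga_config"))
  n <- nrow(table)
  n_features <- length(table_feature_cols(table))
  set.seed(cfg$seed)
  if (length(folds) == 1) folds <- make_folds(n, k = folds, seed = cfg$seed)

  cache <- new.env(parent = emptyenv())
  fitness_of <- function(bits) {
    if (sum(bits) == 0) return(1)
    key <- paste(bits, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    th <- cross_validate(table, mask = bits, k = k, folds = folds)$theta
    cache[[key]] <- th
    th
  }

  pop <- init_population(cfg$pop_size, n_features)
  best_bits <- NULL
  best_theta <- Inf
  stall <- 0L
  hist_gen <- hist_best <- hist_best_ever <- hist_mean <- numeric(0)
  gen <- 0L

  for (gen in seq_len(cfg$generations)) {
    fit <- apply(pop, 1, fitness_of)
    ord <- order(fit)
    gen_best <- fit[ord[1]]
    if (gen_best < best_theta - 1e-15) {
      best_theta <- gen_best
      best_bits <- pop[ord[1], ]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    hist_gen <- c(hist_gen, gen)
    hist_best <- c(hist_best, gen_best)
    hist_best_ever <- c(hist_best_ever, best_theta)
    hist_mean <- c(hist_mean, mean(fit))
    if (stall >= cfg$patience || gen == cfg$generations) break

    prob <- rank_probabilities(fit, cfg$selection_pressure)
    nxt <- matrix(0L, cfg$pop_size, n_features)
    nxt[seq_len(cfg$elitism), ] <- pop[ord[seq_len(cfg$elitism)], ]
    filled <- cfg$elitism
    while (filled < cfg$pop_size) {
      parents <- sample.int(cfg$pop_size, 2, replace = TRUE, prob = prob)
      kids <- double_point_crossover(pop[parents[1], ], pop[parents[2], ],
                                     pc = cfg$crossover_prob)
      for (kid in kids) {
        if (filled < cfg$pop_size) {
          filled <- filled + 1L
          nxt[filled, ] <- mutate_bits(kid, cfg$mutation_prob)
        }
      }
    }
    pop <- nxt
  }

  metrics <- cross_validate(table, mask = best_bits, k = k, folds = folds)
  structure(
    list(
      best_mask = best_bits,
      best_features = table_feature_cols(table)[as.logical(best_bits)],
      best_theta = best_theta,
      best_metrics = metrics,
      history = tibble::tibble(
        generation = hist_gen, best_theta = hist_best,
        best_ever_theta = hist_best_ever, mean_theta = hist_mean
      ),
      generations_run = gen,
      n_evaluated = length(ls(cache)),
      config = cfg
    ),
    class = "ga_run"
  )
}

#' @export
print.ga_run <- function(x, ...) {
  cat(
    "GA feature-subset selection\n",
    "  generations run: ", x$generations_run,
    " (distinct masks evaluated: ", x$n_evaluated, ")\n",
    "  best theta: ", sprintf("%.6f", x$best_theta),
    "  (Ac = ", sprintf("%.2f%%", x$best_metrics$Ac), ")\n",
    "  selected features (", sum(x$best_mask), "): ",
    paste(x$best_features, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-generation history of a GA run
#'
#' @param x A `ga_run`.
#' @param ... Unused.
#' @return Tibble with `generation`, `best_theta`, `best_ever_theta`,
#'   `mean_theta`.
#' @export
tidy.ga_run <- function(x, ...) x$history

#' One-row summary of a GA run
#'
#' @param x A `ga_run`.
#' @param ... Unused.
#' @return Tibble with the best fitness and its classification metrics.
#' @export
glance.ga_run <- function(x, ...) {
  tibble::tibble(
    best_theta = x$best_theta,
    Ac = x$best_metrics$Ac,
    Se = x$best_metrics$Se,
    Sp = x$best_metrics$Sp,
    n_features = sum(x$best_mask),
    generations_run = x$generations_run
  )
}

#' Fitness-history plot of a GA run
#'
#' @param object A `ga_run`.
#' @param ... Unused.
#' @return A ggplot object showing best and mean error rate by generation.
#' @export
autoplot.ga_run <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, -"generation",
                           names_to = "series", values_to = "theta")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation, y = .data$theta,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = expression(theta),
                  colour = NULL,
                  title = "GA feature-subset selection fitness history") +
    ggplot2::theme_minimal()
}

#' Small synthetic labelled feature table
#'
#' Builds an `n`-row table with `n_informative` feature columns whose class
#' means are separated by `effect` (in SD units) and the remaining columns
#' pure noise — a controlled fixture for exercising the classifier and the
#' subset-selection machinery without the signal pipeline.
#'
#' @param n_nsr,n_chf Rows per class.
#' @param n_features Total feature columns.
#' @param n_informative How many columns carry the class difference.
#' @param effect Class-mean separation in noise-SD units.
#' @param seed Integer seed.
#' @return Tibble with `subject_id`, `label` and `n_features` numeric
#'   columns named `f1..fp`.
#' @export
toy_feature_table <- function(n_nsr = 40, n_chf = 29, n_features = 16,
                              n_informative = 1, effect = 6, seed = 1) {
  set.seed(seed)
  n <- n_nsr + n_chf
  labels <- c(rep("NSR", n_nsr), rep("CHF", n_chf))
  X <- matrix(stats::rnorm(n * n_features), n, n_features)
  shift <- ifelse(labels == "CHF", effect, 0)
  for (j in seq_len(n_informative)) X[, j] <- X[, j] + shift
  colnames(X) <- paste0("f", seq_len(n_features))
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("s%02d", seq_len(n)), label = labels),
    tibble::as_tibble(X)
  )
}
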