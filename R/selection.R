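#' Genetic-algorithm configuration
#'
#' Hyperparameters for [ga_select()].  The defaults (population 100,
#' 300 generations, crossover 0.9, mutation 0.05, tournament size 3, one
#' elite) converge reliably on descriptor pools of up to a few hundred
#' columns; subset sizes are constrained to `[min_vars, max_vars]` and
#' candidates whose descriptors are pairwise correlated above
#' `collinearity_r` are rejected outright.
#'
#' @param population,generations GA size and length.
#' @param crossover_rate,mutation_rate Per-mating and per-bit probabilities.
#' @param max_vars,min_vars Subset size bounds (1 to 5 by default).
#' @param fitness `"Q2"` (leave-one-out, the default) or `"R2"`.
#' @param tournament Tournament size for parent selection.
#' @param elitism Number of top individuals copied unchanged.
#' @param collinearity_r Pairwise |r| at or above which a subset is rejected.
#' @param seed Integer seed; a fixed seed makes [ga_select()] bit-reproducible.
#' @return A list of class `"ga_config"`.
#' @export
ga_config <- function(population = 100, generations = 300,
                      crossover_rate = 0.9, mutation_rate = 0.05,
                      max_vars = 5, min_vars = 1, fitness = c("Q2", "R2"),
                      tournament = 3, elitism = 1, collinearity_r = 0.95,
                      seed = 1) {
  fitness <- match.arg(fitness)
  stopifnot(min_vars >= 1, min_vars <= max_vars,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            population >= 2, generations >= 1)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 max_vars = as.integer(max_vars),
                 min_vars = as.integer(min_vars),
                 fitness = fitness, tournament = as.integer(tournament),
                 elitism = as.integer(elitism),
                 collinearity_r = collinearity_r,
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Subset fitness with rejection of collinear subsets; memoised per call site.
.subset_evaluator <- function(X, y, fitness, collinearity_r) {
  cache <- new.env(parent = emptyenv())
  cm <- abs(suppressWarnings(cor(X)))
  function(idx) {
    idx <- sort(idx)
    key <- paste(idx, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (length(idx) > 1L &&
               max(cm[idx, idx][upper.tri(cm[idx, idx])], na.rm = TRUE) >=
                 collinearity_r) {
      -Inf
    } else {
      ans <- tryCatch({
        f <- fit_ols(X[, idx, drop = FALSE], y, loo = (fitness == "Q2"))
        if (fitness == "Q2") f$stats$Q2 else f$stats$R2
      }, error = function(e) -Inf)
      if (!is.finite(ans)) -Inf else ans
    }
    cache[[key]] <- val
    val
  }
}

# Deterministic tie-break: higher fitness, then smaller subset, then
# lexicographically earlier sorted descriptor names.
.better_than <- function(fit_a, names_a, fit_b, names_b) {
  if (fit_a != fit_b) return(fit_a > fit_b)
  if (length(names_a) != length(names_b)) return(length(names_a) < length(names_b))
  a <- paste(sort(names_a), collapse = ","); b <- paste(sort(names_b), collapse = ",")
  a < b
}

#' Genetic-algorithm descriptor subset selection
#'
#' Evolves binary subset masks over the descriptor pool, maximizing
#' leave-one-out Q2 (or training R2) of the corresponding MLR model, and
#' returns the best candidate found at each subset size from
#' `config$min_vars` to `config$max_vars`.  Collinear subsets (pairwise |r| at
#' or above `config$collinearity_r`) are excluded.  The run is deterministic
#' for a fixed `config$seed` and never disturbs the caller's RNG state.
#'
#' @param X Descriptor pool: a [descriptor_matrix()] or plain data.frame (an
#'   `id` column, if present, is dropped).  Training rows only.
#' @param y Response vector aligned with `X`.
#' @param config A [ga_config()].
#' @return A list of class `"ga_result"`, one element per subset size, each a
#'   list with `subset` (descriptor names), `fitness` and `model` (the
#'   refitted `mlr_fit`).  Sizes for which no feasible subset was found are
#'   `NULL`.
#' @export
ga_select <- function(X, y, config = ga_config()) {
  X <- as.data.frame(X)
  X <- X[setdiff(names(X), "id")]
  pool <- ncol(X)
  if (pool < config$min_vars)
    stop("descriptor pool (", pool, ") smaller than min_vars (",
         config$min_vars, ")")
  maxv <- min(config$max_vars, pool)
  evalf <- .subset_evaluator(X, y, config$fitness, config$collinearity_r)
  best <- vector("list", maxv)  # per size: list(idx, fitness)

  consider <- function(idx, fit) {
    k <- length(idx)
    if (k < config$min_vars || k > maxv || !is.finite(fit)) return(invisible())
    cur <- best[[k]]
    if (is.null(cur) ||
        .better_than(fit, names(X)[idx], cur$fitness, names(X)[cur$idx]))
      best[[k]] <<- list(idx = sort(idx), fitness = fit)
  }

  repair <- function(mask) {
    size <- sum(mask)
    while (size > maxv) {
      mask[sample(which(mask), 1L)] <- FALSE; size <- size - 1L
    }
    while (size < config$min_vars) {
      mask[sample(which(!mask), 1L)] <- TRUE; size <- size + 1L
    }
    mask
  }

  with_seed(config$seed, {
    popn <- config$population
    pop <- lapply(seq_len(popn), function(i) {
      mask <- logical(pool)
      k <- sample(config$min_vars:maxv, 1L)
      mask[sample.int(pool, k)] <- TRUE
      mask
    })
    for (gen in seq_len(config$generations)) {
      fits <- vapply(pop, function(m) evalf(which(m)), numeric(1))
      for (i in seq_len(popn)) consider(which(pop[[i]]), fits[i])
      ord <- order(fits, decreasing = TRUE)
      nextpop <- pop[ord[seq_len(min(config$elitism, popn))]]
      pick <- function() {
        cand <- sample.int(popn, config$tournament, replace = TRUE)
        pop[[cand[which.max(fits[cand])]]]
      }
      while (length(nextpop) < popn) {
        p1 <- pick(); p2 <- pick()
        child <- if (runif(1) < config$crossover_rate) {
          take1 <- runif(pool) < 0.5
          (p1 & take1) | (p2 & !take1)
        } else p1
        flip <- runif(pool) < config$mutation_rate
        child <- xor(child, flip)
        nextpop[[length(nextpop) + 1L]] <- repair(child)
      }
      pop <- nextpop
    }
    fits <- vapply(pop, function(m) evalf(which(m)), numeric(1))
    for (i in seq_len(popn)) consider(which(pop[[i]]), fits[i])
  })

  out <- lapply(best, function(b) {
    if (is.null(b)) return(NULL)
    list(subset = names(X)[b$idx], fitness = b$fitness,
         model = fit_ols(X[, b$idx, drop = FALSE], y))
  })
  names(out) <- paste0("size", seq_along(out))
  structure(out, class = "ga_result", fitness_type = config$fitness)
}

#' @export
print.ga_result <- function(x, ...) {
  cat("GA selection (fitness: ", attr(x, "fitness_type"), ")\n", sep = "")
  for (k in seq_along(x)) {
    b <- x[[k]]
    if (is.null(b)) next
    cat(sprintf("  %d var: %-40s %s = %.4f\n", k,
                paste(b$subset, collapse = ", "),
                attr(x, "fitness_type"), b$fitness))
  }
  invisible(x)
}

#' Exhaustive best-subset selection (oracle for the GA)
#'
#' Enumerates every subset of each size and returns the global optimum under
#' the same fitness and collinearity rule as [ga_select()].  Refuses pools
#' where the enumeration would exceed `budget` model fits.
#'
#' @param X Descriptor pool (id column dropped if present).
#' @param y Response vector.
#' @param max_vars,min_vars Subset size range.
#' @param fitness `"Q2"` or `"R2"`.
#' @param collinearity_r Pairwise |r| rejection threshold.
#' @param budget Maximum number of subsets to evaluate.
#' @return Same shape as [ga_select()]'s result.
#' @export
exhaustive_select <- function(X, y, max_vars = 5, min_vars = 1,
                              fitness = c("Q2", "R2"), collinearity_r = 0.95,
                              budget = 1e6) {
  fitness <- match.arg(fitness)
  X <- as.data.frame(X)
  X <- X[setdiff(names(X), "id")]
  pool <- ncol(X)
  if (pool < 1L) stop("empty descriptor pool")
  maxv <- min(max_vars, pool)
  sizes <- min_vars:maxv
  total <- sum(choose(pool, sizes))
  if (total > budget)
    stop("exhaustive search needs ", format(total, big.mark = ","),
         " fits (> budget); use ga_select()")
  evalf <- .subset_evaluator(X, y, fitness, collinearity_r)
  out <- vector("list", maxv)
  for (k in sizes) {
    combos <- combn(pool, k)
    bi <- NULL; bf <- -Inf
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      f <- evalf(idx)
      if (is.finite(f) &&
          (is.null(bi) || .better_than(f, names(X)[idx], bf, names(X)[bi]))) {
        bi <- idx; bf <- f
      }
    }
    if (!is.null(bi))
      out[[k]] <- list(subset = names(X)[bi], fitness = bf,
                       model = fit_ols(X[, bi, drop = FALSE], y))
  }
  names(out) <- paste0("size", seq_along(out))
  structure(out, class = "ga_result", fitness_type = fitness)
}
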