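#' Generate random molecular graphs
#'
#' Produces connected, chemically plausible carbon skeletons (maximum degree
#' 4): random trees grown by preferential-free sequential attachment, and
#' with probability `odd_ring_probability` a graph seeded with one
#' five-membered ring (the feature that makes odd-order self-returning walk
#' counts nonzero).  All vertices are carbon with single bonds, which is the
#' regime descriptor oracles need; heteroatoms and multiple bonds are
#' exercised by the packaged SMILES fixtures instead.
#'
#' @param count Number of graphs.
#' @param size_range Integer vector `c(min, max)` of heavy-atom counts
#'   (min >= 2; >= 5 is required for a five-ring to be possible).
#' @param odd_ring_probability Probability that a graph contains one
#'   5-cycle.
#' @param seed Integer seed; generation is deterministic and leaves the
#'   caller's RNG state untouched.
#' @return A list of [molecular_graph()] objects.
#' @export
generate_random_graphs <- function(count, size_range = c(4, 8),
                                   odd_ring_probability = 0.3, seed = 1) {
  stopifnot(count >= 1, length(size_range) == 2L, size_range[1] >= 2,
            size_range[1] <= size_range[2],
            odd_ring_probability >= 0, odd_ring_probability <= 1)
  with_seed(seed, {
    lapply(seq_len(count), function(i) {
      n <- sample(size_range[1]:size_range[2], 1L)
      ring <- runif(1) < odd_ring_probability && n >= 5L
      if (ring) {
        bonds <- data.frame(i = 1:5, j = c(2:5, 1L), order = 1L)
        deg <- c(rep(2L, 5L), rep(0L, n - 5L))
        start <- 6L
      } else {
        bonds <- data.frame(i = integer(), j = integer(), order = integer())
        deg <- rep(0L, n)
        start <- 2L
      }
      if (start <= n) {
        for (v in start:n) {
          open <- which(deg[seq_len(v - 1L)] < 4L)
          anchor <- if (length(open) == 1L) open else sample(open, 1L)
          bonds <- rbind(bonds, data.frame(i = anchor, j = v, order = 1L))
          deg[anchor] <- deg[anchor] + 1L
          deg[v] <- deg[v] + 1L
        }
      }
      molecular_graph(rep("C", n), bonds)
    })
  })
}

#' Generate a descriptor matrix with a known sparse linear response
#'
#' Emulates the statistical structure assumed by GA-MLRA modeling: a pool of
#' descriptor columns with deliberately heterogeneous scales, a sparse true
#' coefficient vector, and a homoscedastic Gaussian response.  Column types
#' cycle through count-like (non-negative, in the hundreds, mimicking walk
#' counts), unit-interval (mimicking averaged connectivity indices) and
#' signed (mimicking dipole components); the scale heterogeneity is
#' intentional, since real descriptor pools are never standardized by the
#' reference workflow and coefficient magnitudes must absorb it.
#'
#' @param n_compounds Number of rows (must exceed `length(true_subset) + 2`).
#' @param pool_size Number of descriptor columns, named `D01`, `D02`, ...
#' @param true_subset Character vector of column names carrying signal.
#' @param true_coefficients Coefficients for `true_subset` (same length).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param intercept True intercept.
#' @param seed Integer seed.
#' @return list with `X` (data.frame), `y`, and `truth`
#'   (`subset`, `coefficients`, `intercept`, `noise_sd`).
#' @export
generate_linear_dataset <- function(n_compounds, pool_size, true_subset,
                                    true_coefficients, noise_sd = 0,
                                    intercept = 0, seed = 1) {
  stopifnot(length(true_subset) == length(true_coefficients))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_compounds <= length(true_subset) + 2L)
    stop("n_compounds must exceed |true_subset| + 2")
  nm <- sprintf("D%02d", seq_len(pool_size))
  if (!all(true_subset %in% nm))
    stop("true_subset must be a subset of the pool columns ",
         nm[1], "..", nm[pool_size])
  with_seed(seed, {
    X <- as.data.frame(lapply(seq_len(pool_size), function(jcol) {
      switch((jcol - 1L) %% 3L + 1L,
             round(abs(rnorm(n_compounds, 300, 180))),   # count-like
             runif(n_compounds, 0.3, 1),                 # unit-interval
             rnorm(n_compounds, 0, 1.2))                 # signed
    }))
    names(X) <- nm
    beta <- setNames(true_coefficients, true_subset)
    y <- intercept + as.matrix(X[true_subset]) %*% beta +
      rnorm(n_compounds, 0, noise_sd)
    list(X = X, y = drop(y),
         truth = list(subset = true_subset, coefficients = beta,
                      intercept = intercept, noise_sd = noise_sd))
  })
}

#' Generate a study-shaped synthetic dataset
#'
#' Mimics the design of the packaged dispersibility study: 29 compounds split
#' 22/7 into training and test, six descriptor columns with the marginal
#' ranges of the packaged reference table (a sparse walk count concentrated
#' on a few levels, a signed dipole component, count-valued path and
#' branching indices, a unit-interval connectivity average, and a
#' non-negative mass autocorrelation), and a known sparse generating model.
#' The generating coefficients (0.002 on the walk count, 0.4 on the dipole
#' column, -1.5 on the connectivity average, intercept -0.9) and noise
#' sd 0.45 are fixed so that the simulated response spans roughly the 4 log
#' units and residual scatter of the packaged endpoint.
#'
#' @param seed Integer seed.
#' @param noise_sd Gaussian noise on the response; the default 0.45 mimics
#'   the residual scatter of the packaged models, a small value gives a
#'   nearly deterministic response for recovery tests.
#' @return list with `records` (a solvent-table-shaped data.frame with
#'   `id`, `name`, `conc`, `log_conc`, `split`), `matrix` (a
#'   [descriptor_matrix()]), and `truth` as in [generate_linear_dataset()].
#' @export
generate_study_dataset <- function(seed = 1, noise_sd = 0.45) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- 29L
  with_seed(seed, {
    cols <- data.frame(
      SRW09  = sample(c(0L, 504L, 684L, 702L), n, replace = TRUE,
                      prob = c(0.62, 0.12, 0.22, 0.04)),
      DipoleZ = round(rnorm(n, 0, 1.1), 3),
      piPC05 = rpois(n, 18),
      Ram    = sample(0:3, n, replace = TRUE),
      X0Av   = round(runif(n, 0.52, 0.76), 3),
      ATS6m  = round(ifelse(runif(n) < 0.45, 0, runif(n, 0.7, 7.8)), 3)
    )
    truth <- list(subset = c("SRW09", "DipoleZ", "X0Av"),
                  coefficients = c(SRW09 = 0.002, DipoleZ = 0.4, X0Av = -1.5),
                  intercept = -0.9, noise_sd = noise_sd)
    y <- truth$intercept +
      as.matrix(cols[truth$subset]) %*% truth$coefficients +
      rnorm(n, 0, noise_sd)
    split <- rep("train", n)
    split[sample.int(n, 7L)] <- "test"
    records <- data.frame(id = seq_len(n),
                          name = sprintf("synthetic-%02d", seq_len(n)),
                          conc = 10^drop(y), log_conc = drop(y),
                          split = split)
    mat <- descriptor_matrix(records$id, cols,
                             provenance = setNames(rep("computed", 6L),
                                                   names(cols)))
    list(records = records, matrix = mat, truth = truth)
  })
}

#' @importFrom stats rpois
NULL
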