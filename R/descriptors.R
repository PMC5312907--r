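#' Self-returning walk count
#'
#' Number of closed walks of length `k` in the hydrogen-depleted molecular
#' graph, i.e. the trace of the k-th power of the adjacency matrix.  Odd-order
#' counts (such as SRW09, `k = 9`) are nonzero only in the presence of
#' odd-membered rings, so they act as sensors for e.g. five-membered lactam
#' rings; on any bipartite graph (trees, even cycles) every odd-order count
#' is exactly 0.
#'
#' @param g A [molecular_graph()].
#' @param k Walk length, integer >= 1.
#' @return Non-negative integer count.
#' @export
srw_count <- function(g, k) {
  stopifnot(inherits(g, "molgraph"))
  if (length(k) != 1L || k < 1 || k != round(k)) stop("k must be an integer >= 1")
  Ak <- diag(nrow(g$A))
  P <- g$A * 1.0
  # binary exponentiation; counts stay exact in doubles for molecule-sized k
  k <- as.integer(k)
  while (k > 0L) {
    if (k %% 2L == 1L) Ak <- Ak %*% P
    k <- k %/% 2L
    if (k > 0L) P <- P %*% P
  }
  round(sum(diag(Ak)))
}

#' Ramification (branching) index
#'
#' Sum over heavy atoms of the degree excess over 2, `sum(max(0, deg - 2))`.
#' Zero for any simple path or cycle; each branch point contributes its number
#' of "extra" edge endpoints.
#'
#' @param g A [molecular_graph()].
#' @return Non-negative integer.
#' @export
ram_index <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  sum(pmax(0L, graph_degrees(g) - 2L))
}

#' Kier-Hall valence degrees
#'
#' Per heavy atom: `Zv - h` for second-row atoms and `(Zv - h) / (Z - Zv - 1)`
#' for higher rows, where `Zv` is the valence-electron count, `h` the number
#' of attached hydrogens and `Z` the atomic number.  The higher-row correction
#' makes e.g. chlorine contribute 7/9 rather than 7.
#'
#' @param g A [molecular_graph()].
#' @return Numeric vector, one valence degree per heavy atom.
#' @export
valence_degrees <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  dv <- ifelse(g$z <= 10L, g$zv - g$hcount,
               (g$zv - g$hcount) / (g$z - g$zv - 1L))
  bad <- which(dv <= 0)
  if (length(bad))
    stop("atom ", bad[1L], " (", g$elements[bad[1L]],
         ") has non-positive valence degree")
  dv
}

#' Average zeroth-order valence connectivity index (X0Av)
#'
#' Mean over heavy atoms of the reciprocal square roots of the Kier-Hall
#' valence degrees: `sum(dv^(-1/2)) / n_heavy`.  Small, heteroatom-poor
#' molecules score high; the packaged models use it as a molecular-size proxy.
#'
#' @param g A [molecular_graph()].
#' @return A real number, in (0, 1] whenever all valence degrees are >= 1.
#' @export
chi0v_average <- function(g) {
  dv <- valence_degrees(g)
  mean(1 / sqrt(dv))
}

#' Bond-order weighted multiple path count
#'
#' Sum over all undirected simple paths of exactly `k` edges of the product of
#' bond orders along the path (piPC05 is order `k = 5`).  With the Kekule
#' convention stored in [molecular_graph()], aromatic rings contribute through
#' alternating orders 1 and 2.
#'
#' @param g A [molecular_graph()].
#' @param k Path length in edges, integer >= 1.
#' @return Non-negative real; an integer when all bond orders are integers.
#' @export
multiple_path_count <- function(g, k) {
  stopifnot(inherits(g, "molgraph"))
  if (length(k) != 1L || k < 1 || k != round(k)) stop("k must be an integer >= 1")
  n <- nrow(g$A)
  W <- matrix(0, n, n)
  if (nrow(g$bonds)) {
    W[cbind(g$bonds$i, g$bonds$j)] <- g$bonds$order
    W[cbind(g$bonds$j, g$bonds$i)] <- g$bonds$order
  }
  nbrs <- lapply(seq_len(n), function(a) which(W[a, ] > 0))
  total <- 0
  walk <- function(v, left, visited, w) {
    if (left == 0L) { total <<- total + w; return(invisible()) }
    for (u in nbrs[[v]]) {
      if (!visited[u]) {
        visited[u] <- TRUE
        walk(u, left - 1L, visited, w * W[v, u])
        visited[u] <- FALSE
      }
    }
  }
  visited <- logical(n)
  for (s in seq_len(n)) {
    visited[s] <- TRUE
    walk(s, as.integer(k), visited, 1)
    visited[s] <- FALSE
  }
  total / 2  # each undirected path traversed once from either end
}

#' Broto-Moreau autocorrelation
#'
#' Topological autocorrelation of an atomic weighting at lag `k` (ATS6m is
#' lag 6 weighted by atomic mass).  The `raw-sum` dialect is
#' `sum(w_i * w_j)` over unordered heavy-atom pairs at topological distance
#' exactly `k`; it is 0 whenever the graph diameter is below `k`.  Two further
#' dialects are provided for calibration against descriptor tables produced by
#' other software: `log1p` reports `log(1 + raw)`, and `include-H` adds
#' explicit hydrogen vertices (mass 1.008) before measuring distances.
#'
#' @param g A [molecular_graph()].
#' @param k Topological lag, integer >= 1.
#' @param weight `"mass"` (atomic mass, u) or `"scaled-mass"` (mass relative
#'   to carbon).
#' @param dialect One of `"raw-sum"`, `"log1p"`, `"include-H"`.
#' @return Non-negative real.
#' @export
ats_autocorrelation <- function(g, k, weight = c("mass", "scaled-mass"),
                                dialect = c("raw-sum", "log1p", "include-H")) {
  stopifnot(inherits(g, "molgraph"))
  if (length(k) != 1L || k < 1 || k != round(k)) stop("k must be an integer >= 1")
  weight <- match.arg(weight)
  dialect <- match.arg(dialect)
  if (dialect == "include-H") {
    D <- .distances_with_h(g)
    w <- c(g$mass, rep(1.008, sum(g$hcount)))
  } else {
    D <- g$D
    w <- g$mass
  }
  if (weight == "scaled-mass") w <- w / 12.011
  sel <- upper.tri(D) & D == k
  raw <- sum((w %o% w)[sel])
  if (dialect == "log1p") log1p(raw) else raw
}

# Distance matrix of the graph with explicit hydrogens appended.
.distances_with_h <- function(g) {
  n <- nrow(g$A)
  nh <- sum(g$hcount)
  m <- n + nh
  A <- matrix(0L, m, m)
  A[seq_len(n), seq_len(n)] <- g$A
  hidx <- n
  for (a in seq_len(n)) {
    if (g$hcount[a] > 0L) {
      for (ii in seq_len(g$hcount[a])) {
        hidx <- hidx + 1L
        A[a, hidx] <- A[hidx, a] <- 1L
      }
    }
  }
  igraph::distances(igraph::graph_from_adjacency_matrix(A, mode = "undirected"))
}

#' Compute the packaged descriptor family for a set of structures
#'
#' Convenience wrapper computing SRW09, piPC05, Ram, X0Av and ATS6m for each
#' graph.
#'
#' @param graphs List of [molecular_graph()] objects.
#' @param ats_dialect Dialect passed to [ats_autocorrelation()].
#' @return data.frame with one row per graph.
#' @export
compute_descriptors <- function(graphs, ats_dialect = "raw-sum") {
  data.frame(
    SRW09  = vapply(graphs, srw_count, numeric(1), k = 9),
    piPC05 = vapply(graphs, multiple_path_count, numeric(1), k = 5),
    Ram    = vapply(graphs, ram_index, numeric(1)),
    X0Av   = vapply(graphs, chi0v_average, numeric(1)),
    ATS6m  = vapply(graphs, ats_autocorrelation, numeric(1), k = 6,
                    dialect = ats_dialect)
  )
}

#' Build a descriptor matrix for solvent records
#'
#' Computes the structural descriptor family from each record's SMILES and
#' merges externally supplied columns (e.g. the quantum-chemical DipoleZ,
#' which this package never computes).  Supplied columns must be keyed by
#' compound id and complete.
#'
#' @param records A solvent table with `id` and `smiles` columns.
#' @param supplied Named list of numeric vectors, each named by compound id,
#'   or a data.frame with an `id` column.
#' @param ats_dialect Dialect for the ATS6m column.
#' @return A [descriptor_matrix()]; computed columns carry provenance
#'   `"computed"`, supplied columns `"supplied"`.
#' @export
build_descriptor_matrix <- function(records, supplied = list(),
                                    ats_dialect = "raw-sum") {
  if (nrow(records) == 0L)
    return(descriptor_matrix(integer(), list(),
                             provenance = setNames(character(), character())))
  graphs <- lapply(records$smiles, parse_structure)
  cols <- compute_descriptors(graphs, ats_dialect = ats_dialect)
  prov <- setNames(rep("computed", ncol(cols)), names(cols))
  if (is.data.frame(supplied)) {
    ids <- supplied$id
    supplied <- as.list(supplied[setdiff(names(supplied), "id")])
    supplied <- lapply(supplied, function(v) setNames(v, ids))
  }
  for (nm in names(supplied)) {
    v <- supplied[[nm]]
    hit <- match(as.character(records$id), names(v))
    if (anyNA(hit))
      stop("supplied column '", nm, "' is missing id ",
           records$id[which(is.na(hit))[1L]])
    cols[[nm]] <- unname(v[hit])
    prov[nm] <- "supplied"
  }
  descriptor_matrix(records$id, cols, provenance = prov)
}

#' Compare a computed descriptor matrix against a reference table
#'
#' Cell-by-cell absolute differences between two descriptor matrices over
#' their shared columns, flagged against a per-column tolerance.  Cells listed
#' in `known_discrepancies` (a data.frame with columns `id` and `column`) are
#' reported separately rather than flagged: use this for reference-table
#' entries documented as irreproducible.
#'
#' @param computed,reference [descriptor_matrix()] objects with matching ids.
#' @param tolerance Named numeric vector of per-column tolerances; columns
#'   without an entry use `default_tol`.
#' @param default_tol Fallback tolerance.
#' @param known_discrepancies Optional data.frame (`id`, `column`).
#' @return A list of class `"descriptor_check"`: `cells` (long data.frame with
#'   `id`, `column`, `computed`, `reference`, `abs_diff`, `flag`, `known`),
#'   `skipped` (columns absent from the reference), and `n_flagged`.
#' @export
verify_against_reference <- function(computed, reference, tolerance = NULL,
                                     default_tol = 0.002,
                                     known_discrepancies = NULL) {
  if (!identical(as.integer(computed$id), as.integer(reference$id)))
    stop("compound ids differ between computed and reference matrices")
  shared <- intersect(setdiff(names(computed), "id"),
                      setdiff(names(reference), "id"))
  skipped <- setdiff(setdiff(names(computed), "id"), shared)
  if (!length(shared)) stop("no shared descriptor columns to compare")
  rows <- lapply(shared, function(nm) {
    tol <- if (!is.null(tolerance) && nm %in% names(tolerance))
      tolerance[[nm]] else default_tol
    d <- abs(computed[[nm]] - reference[[nm]])
    data.frame(id = computed$id, column = nm, computed = computed[[nm]],
               reference = reference[[nm]], abs_diff = d, flag = d > tol)
  })
  cells <- do.call(rbind, rows)
  cells$known <- FALSE
  if (!is.null(known_discrepancies)) {
    key <- paste(cells$id, cells$column)
    cells$known <- key %in% paste(known_discrepancies$id,
                                  known_discrepancies$column)
  }
  structure(list(cells = cells, skipped = skipped,
                 n_flagged = sum(cells$flag & !cells$known)),
            class = "descriptor_check")
}

#' @export
print.descriptor_check <- function(x, ...) {
  cat("Descriptor verification: ", nrow(x$cells), " cells, ",
      sum(x$cells$flag & !x$cells$known), " flagged, ",
      sum(x$cells$flag & x$cells$known), " known-discrepant\n", sep = "")
  if (length(x$skipped))
    cat("  skipped (absent from reference): ",
        paste(x$skipped, collapse = ", "), "\n", sep = "")
  bad <- x$cells[x$cells$flag & !x$cells$known, ]
  if (nrow(bad)) print(bad, row.names = FALSE)
  invisible(x)
}

#' Autocorrelation dialect calibration report
#'
#' Computes every ATS dialect/weight combination for a set of structures and
#' tabulates the absolute discrepancy against a reference column.  No dialect
#' is asserted to match: the report exists to document how far each
#' convention lands from an externally produced table.
#'
#' @param graphs List of [molecular_graph()] objects.
#' @param reference Numeric vector of reference ATS values (same order).
#' @param k Topological lag.
#' @return data.frame with one row per dialect/weight combination:
#'   `dialect`, `weight`, `mean_abs_diff`, `max_abs_diff`, `n_exact`.
#' @export
ats_dialect_report <- function(graphs, reference, k = 6) {
  stopifnot(length(graphs) == length(reference))
  grid <- expand.grid(dialect = c("raw-sum", "log1p", "include-H"),
                      weight = c("mass", "scaled-mass"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    v <- vapply(graphs, ats_autocorrelation, numeric(1), k = k,
                weight = grid$weight[r], dialect = grid$dialect[r])
    d <- abs(v - reference)
    data.frame(dialect = grid$dialect[r], weight = grid$weight[r],
               mean_abs_diff = mean(d), max_abs_diff = max(d),
               n_exact = sum(d < 5e-4))
  })
  do.call(rbind, res)
}
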