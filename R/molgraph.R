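# Element data used for implicit hydrogens and Kier-Hall valence degrees.
# columns: atomic number Z, valence electrons Zv, standard valence, mass (u)
.elements <- data.frame(
  symbol  = c("B",  "C",  "N",  "O",  "F",  "Si", "P",  "S",  "Cl", "Br", "I"),
  z       = c(5L,   6L,   7L,   8L,   9L,   14L,  15L,  16L,  17L,  35L,  53L),
  zv      = c(3L,   4L,   5L,   6L,   7L,   4L,   5L,   6L,   7L,   7L,   7L),
  valence = c(3L,   4L,   3L,   2L,   1L,   4L,   3L,   2L,   1L,   1L,   1L),
  mass    = c(10.81, 12.011, 14.007, 15.999, 18.998, 28.085, 30.974, 32.06,
              35.45, 79.904, 126.904),
  stringsAsFactors = FALSE
)

#' Construct a molecular graph
#'
#' The substrate of every descriptor in the package: a hydrogen-depleted
#' labeled graph.  Vertices are heavy atoms carrying an element symbol, an
#' implicit hydrogen count, atomic mass and valence-electron count; edges
#' carry integer bond orders in a fixed Kekule assignment (aromatic rings are
#' stored as alternating single/double bonds, never as order 1.5).
#'
#' @param elements Character vector of element symbols, one per heavy atom.
#' @param bonds Two- or three-column matrix/data.frame: atom index, atom
#'   index, bond order (order defaults to 1).
#' @param hcount Optional integer vector of attached hydrogens per atom; when
#'   `NULL` it is derived as standard valence minus the bond-order sum
#'   (floored at 0).
#' @return An object of class `"molgraph"`: a list with `elements`, `hcount`,
#'   `mass`, `z`, `zv`, `bonds` (data.frame `i`, `j`, `order`), the 0/1
#'   adjacency matrix `A`, and the topological distance matrix `D`
#'   (shortest-path edge counts on the hydrogen-depleted graph).
#' @export
molecular_graph <- function(elements, bonds, hcount = NULL) {
  n <- length(elements)
  if (n < 1L) stop("graph needs at least one atom")
  idx <- match(elements, .elements$symbol)
  if (anyNA(idx))
    stop("unsupported element(s): ",
         paste(unique(elements[is.na(idx)]), collapse = ", "))
  bonds <- as.data.frame(bonds)
  if (ncol(bonds) == 2L) bonds$order <- 1L
  names(bonds) <- c("i", "j", "order")
  if (nrow(bonds)) {
    bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
    if (any(bonds$i == bonds$j)) stop("self-loop bond")
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond references an atom outside the graph")
    if (any(!bonds$order %in% 1:3)) stop("bond orders must be 1, 2 or 3")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond")
  }
  A <- matrix(0L, n, n)
  if (nrow(bonds)) {
    A[cbind(bonds$i, bonds$j)] <- 1L
    A[cbind(bonds$j, bonds$i)] <- 1L
  }
  # connectivity + distances in one BFS pass per component
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  if (igraph::components(ig)$no != 1L && n > 1L)
    stop("molecular graph is disconnected")
  D <- igraph::distances(ig)
  bosum <- vapply(seq_len(n), function(a) {
    sum(bonds$order[bonds$i == a | bonds$j == a])
  }, numeric(1))
  if (is.null(hcount)) {
    hcount <- pmax(0L, .elements$valence[idx] - as.integer(bosum))
  } else {
    hcount <- as.integer(hcount)
    if (length(hcount) != n || any(hcount < 0L)) stop("invalid hcount")
  }
  structure(list(elements = elements, hcount = hcount,
                 mass = .elements$mass[idx], z = .elements$z[idx],
                 zv = .elements$zv[idx], bonds = bonds, A = A, D = D),
            class = "molgraph")
}

#' Parse a SMILES string into a molecular graph
#'
#' Uses the OpenBabel toolkit (through ChemmineR) to interpret the SMILES and
#' kekulize any aromatic rings, then rebuilds the hydrogen-depleted graph with
#' implicit hydrogen counts derived from standard valences.  Kekulization is
#' deterministic for a fixed input string; every descriptor this package
#' computes on the packaged structures is invariant to the particular Kekule
#' assignment of their (benzenoid) rings.
#'
#' @param smiles A single SMILES string for a neutral, connected organic
#'   molecule.
#' @return A [molecular_graph()] object.
#' @export
parse_structure <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  # single-atom molecules carry no bond block, which the SDF round trip
  # cannot represent faithfully; build them directly
  bare <- sub("^\\[([A-Za-z]{1,2})H?[0-9]?\\]$", "\\1", smiles)
  if (bare %in% .elements$symbol ||
      (nchar(bare) == 1L && toupper(bare) %in% .elements$symbol)) {
    sym <- if (bare %in% .elements$symbol) bare else toupper(bare)
    return(molecular_graph(sym,
                           data.frame(i = integer(), j = integer(),
                                      order = integer())))
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("cannot parse SMILES '", smiles, "': ",
                             conditionMessage(e), call. = FALSE))
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0L)
    stop("cannot parse SMILES '", smiles, "': no atoms", call. = FALSE)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  bb <- ChemmineR::bondblock(mol)
  bonds <- if (is.null(bb) || NROW(bb) == 0L || NCOL(bb) < 3L) {
    data.frame(i = integer(), j = integer(), order = integer())
  } else {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  if (any(bonds$order == 4L))
    stop("aromatic bond order survived kekulization in '", smiles, "'")
  molecular_graph(elements, bonds)
}

#' @export
print.molgraph <- function(x, ...) {
  cat("Molecular graph: ", length(x$elements), " heavy atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  comp <- table(x$elements)
  cat("  composition: ",
      paste(names(comp), comp, sep = "", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Heavy-atom degrees of a molecular graph
#' @param g A `molgraph`.
#' @return Integer vector of vertex degrees.
#' @export
graph_degrees <- function(g) as.integer(rowSums(g$A))

#' Topological distance matrix accessor
#' @param g A `molgraph`.
#' @return Matrix of shortest-path edge counts between heavy atoms.
#' @export
distance_matrix <- function(g) g$D

#' Adjacency matrix accessor
#' @param g A `molgraph`.
#' @return Symmetric 0/1 matrix.
#' @export
adjacency_matrix <- function(g) g$A
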