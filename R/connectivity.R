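#' Perceive molecular connectivity from interatomic distances
#'
#' Two atoms are bonded when their distance does not exceed
#' `scale * (r_i + r_j)`, with covalent radii from the packaged table.
#' The result is deterministic given the geometry and scale. Besides the
#' edge list, the graph reports connected fragments, ring sizes (from
#' the fundamental cycles of a spanning forest) and, for every hydrogen,
#' the element of its attachment atom.
#'
#' @param geometry a `mol_geom` tibble.
#' @param scale dimensionless cutoff multiplier, in (0.8, 1.6);
#'   default 1.2.
#' @return a `connectivity_graph`: list with `n_atoms`, `edges`
#'   (tibble `i`, `j`, `length`), `n_fragments`, `fragment` (membership
#'   vector), `ring_sizes`, `h_attachment` (tibble `h`, `attached_to`)
#'   and the atom `element` vector.
#' @export
perceive_connectivity <- function(geometry, scale = 1.2) {
  if (scale <= 0.8 || scale >= 1.6) {
    stop("scale must be in (0.8, 1.6)")
  }
  n <- nrow(geometry)
  p <- coords(geometry)
  r <- covalent_radius(geometry$element)
  d <- as.matrix(stats::dist(p))
  cutoff <- outer(r, r, `+`) * scale
  adj <- d <= cutoff & upper.tri(d)
  idx <- which(adj, arr.ind = TRUE)
  edges <- tibble::tibble(
    i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
    length = d[idx]
  )
  edges <- dplyr::arrange(edges, .data$i, .data$j)

  frag <- components_from_edges(n, edges)
  ring_sizes <- fundamental_ring_sizes(n, edges)

  nbr <- neighbour_list(n, edges)
  is_h <- geometry$element == "H"
  h_idx <- which(is_h)
  h_attachment <- tibble::tibble(
    h = h_idx,
    attached_to = vapply(h_idx, function(i) {
      nb <- nbr[[i]]
      if (length(nb) == 0L) NA_character_
      else paste(sort(geometry$element[nb]), collapse = ",")
    }, character(1))
  )

  structure(
    list(n_atoms = n, element = geometry$element, edges = edges,
         n_fragments = max(frag), fragment = frag,
         ring_sizes = ring_sizes, h_attachment = h_attachment,
         scale = scale),
    class = "connectivity_graph"
  )
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf(
    "<connectivity_graph: %d atoms, %d bonds, %d fragment(s), %d ring(s)%s>\n",
    x$n_atoms, nrow(x$edges), x$n_fragments, length(x$ring_sizes),
    if (length(x$ring_sizes))
      paste0(" [", paste(x$ring_sizes, collapse = ","), "]") else ""
  ))
  invisible(x)
}

neighbour_list <- function(n, edges) {
  nbr <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  nbr
}

# connected-component membership by breadth-first search
components_from_edges <- function(n, edges) {
  nbr <- neighbour_list(n, edges)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nbr[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  comp
}

# Sizes of the fundamental cycles: build a BFS spanning forest, then each
# non-tree edge closes one ring whose size follows from tree depths. For
# the 3- and 4-membered rings this workflow screens for, fundamental
# cycles and chemical rings coincide.
fundamental_ring_sizes <- function(n, edges) {
  nbr <- neighbour_list(n, edges)
  parent <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  in_tree <- matrix(FALSE, 0, 0) # placeholder; use edge key set
  tree_edges <- character(0)
  for (s in seq_len(n)) {
    if (!is.na(depth[s])) next
    depth[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nbr[[v]]) if (is.na(depth[w])) {
        depth[w] <- depth[v] + 1L
        parent[w] <- v
        tree_edges <- c(tree_edges, edge_key(v, w))
        queue <- c(queue, w)
      }
    }
  }
  sizes <- integer(0)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]
    if (edge_key(i, j) %in% tree_edges) next
    # walk both endpoints up to their common ancestor
    pi_ <- path_to_root(i, parent)
    pj <- path_to_root(j, parent)
    common <- intersect(pi_, pj)[1]
    li <- which(pi_ == common) - 1L
    lj <- which(pj == common) - 1L
    sizes <- c(sizes, li + lj + 1L)
  }
  sort(sizes)
}

edge_key <- function(i, j) paste(min(i, j), max(i, j), sep = "-")

path_to_root <- function(v, parent) {
  path <- v
  while (!is.na(parent[v])) {
    v <- parent[v]
    path <- c(path, v)
  }
  path
}

#' Classify a candidate structure against a reference topology
#'
#' Systematic torsional searches occasionally converge to structures
#' that are no longer the target molecule: a detached SH2/OH2/NH3-type
#' fragment ("broken"), a new small ring ("cyclized"), or a hydrogen /
#' heavy-group migration that keeps the molecule connected and acyclic
#' ("rearranged"). The decision is purely graph-topological — energy
#' gaps between target conformers and byproducts are not reliable
#' separators.
#'
#' @param candidate,reference `connectivity_graph` objects sharing atom
#'   count and element multiset.
#' @return one of `"target"`, `"broken"`, `"rearranged"`, `"cyclized"`.
#' @export
classify_byproduct <- function(candidate, reference) {
  stopifnot(inherits(candidate, "connectivity_graph"),
            inherits(reference, "connectivity_graph"))
  if (candidate$n_atoms != reference$n_atoms ||
      !identical(sort(candidate$element), sort(reference$element))) {
    stop("incomparable species: atom count or element multiset differs")
  }
  if (candidate$n_fragments > reference$n_fragments) return("broken")
  new_rings <- !identical(candidate$ring_sizes, reference$ring_sizes) &&
    length(candidate$ring_sizes) > length(reference$ring_sizes)
  if (new_rings) return("cyclized")
  if (!identical(atom_signature(candidate), atom_signature(reference))) {
    return("rearranged")
  }
  "target"
}

# multiset of per-atom environments: element plus sorted neighbour
# elements; invariant under atom renumbering
atom_signature <- function(g) {
  nbr <- neighbour_list(g$n_atoms, g$edges)
  sig <- vapply(seq_len(g$n_atoms), function(i) {
    paste0(g$element[i], ":",
           paste(sort(g$element[nbr[[i]]]), collapse = ""))
  }, character(1))
  sort(sig)
}
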