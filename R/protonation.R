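#' Attach a proton to a functional group
#'
#' Builds a protonated starting structure by adding one hydrogen at a
#' trial bond length along the site's lone-pair direction and raising
#' the total charge by one. Each site offers two variants so that the
#' subsequent torsional search starts from genuinely distinct guesses:
#'
#' * `amino`: the new N-H completes the tetrahedron; variant 2 is
#'   rotated by 60 degrees about the C-N axis.
#' * `hydroxyl` / `thiol`: variant 1 places the new hydrogen in the
#'   C-X-H plane, variant 2 rotates it 90 degrees about the C-X axis so
#'   the two H-X-H planes are mutually perpendicular.
#' * `carbonyl`: variants differ in the cis-trans alignment of the new
#'   O-H with respect to the other C-O bond.
#'
#' Placement is a starting guess for downstream optimisation, not a
#' refined geometry.
#'
#' @param geometry a neutral `mol_geom` tibble.
#' @param site one of `"amino"`, `"carbonyl"`, `"hydroxyl"`, `"thiol"`.
#' @param variant 1 or 2.
#' @param bond_length trial X-H distance in Angstrom; defaults to
#'   1.02 (N-H), 0.98 (O-H) or 1.35 (S-H) by site.
#' @param scale connectivity cutoff passed to [perceive_connectivity()].
#' @return a `mol_geom` with one more atom and charge incremented by +1.
#' @export
attach_proton <- function(geometry,
                          site = c("amino", "carbonyl", "hydroxyl", "thiol"),
                          variant = 1L, bond_length = NULL, scale = 1.2) {
  site <- match.arg(site)
  variant <- as.integer(variant)
  stopifnot(variant %in% c(1L, 2L))
  if (is.null(bond_length)) {
    bond_length <- switch(site, amino = 1.02, carbonyl = 0.98,
                          hydroxyl = 0.98, thiol = 1.35)
  }
  g <- perceive_connectivity(geometry, scale = scale)
  nbr <- neighbour_list(g$n_atoms, g$edges)
  el <- geometry$element
  p <- coords(geometry)

  loc <- locate_site(site, el, nbr)
  s <- loc$site_atom
  r <- loc$heavy_neighbor

  unit <- function(v) v / sqrt(sum(v^2))
  vs <- p[s, ]

  if (site == "carbonyl") {
    # in the O=C-O plane, tilted ~110 deg from the C=O bond; variant
    # picks the side facing (cis) or opposing (trans) the other C-O bond
    u <- unit(p[s, ] - p[r, ])
    w0 <- p[loc$other_o, ] - p[r, ]
    w <- unit(w0 - sum(w0 * u) * u)
    side <- if (variant == 1L) 1 else -1
    d <- cos(70 * pi / 180) * u + side * sin(70 * pi / 180) * w
  } else {
    # lone-pair direction: opposite the mean of the existing bonds
    bonded <- nbr[[s]]
    d0 <- -unit(rowSums(vapply(bonded,
                               function(i) unit(p[i, ] - vs), numeric(3))))
    d <- d0
    axis <- unit(p[s, ] - p[r, ])
    if (site == "amino" && variant == 2L) {
      d <- as.vector(rotate_about_axis(matrix(vs + d0, 1), vs, axis,
                                       60 * pi / 180)) - vs
    }
    if (site %in% c("hydroxyl", "thiol") && variant == 2L) {
      d <- as.vector(rotate_about_axis(matrix(vs + d0, 1), vs, axis,
                                       90 * pi / 180)) - vs
    }
    d <- unit(d)
  }

  new_pos <- vs + bond_length * d
  out <- mol_geom(
    c(el, "H"),
    rbind(p, new_pos),
    charge = geom_charge(geometry) + 1L,
    label = trimws(paste(geom_label(geometry),
                         sprintf("[%s-protonated v%d]", site, variant)))
  )
  attr(out, "proton_index") <- nrow(out)
  attr(out, "site_atom") <- s
  out
}

# find the site atom and its heavy anchor from element/connectivity
locate_site <- function(site, el, nbr) {
  elem_of <- function(idx) el[idx]
  n_h <- function(i) sum(el[nbr[[i]]] == "H")
  heavy <- function(i) nbr[[i]][el[nbr[[i]]] != "H"]

  if (site == "amino") {
    cand <- which(el == "N" & vapply(seq_along(el),
                                     function(i) el[i] == "N" && n_h(i) >= 2L,
                                     logical(1)))
    if (!length(cand)) stop("missing site: no amino group found")
    s <- cand[1]
    return(list(site_atom = s, heavy_neighbor = heavy(s)[1]))
  }
  if (site == "thiol") {
    cand <- which(el == "S" & vapply(seq_along(el),
                                     function(i) el[i] == "S" && n_h(i) >= 1L,
                                     logical(1)))
    if (!length(cand)) stop("missing site: no thiol group found")
    s <- cand[1]
    return(list(site_atom = s, heavy_neighbor = heavy(s)[1]))
  }
  # carboxyl oxygens: both bonded to the same carbon; the carbonyl O has
  # no hydrogen, the hydroxyl O has one
  o_idx <- which(el == "O")
  for (o1 in o_idx) {
    cs <- heavy(o1)
    for (cc in cs) {
      if (el[cc] != "C") next
      partners <- setdiff(intersect(nbr[[cc]], o_idx), o1)
      if (!length(partners)) next
      o2 <- partners[1]
      carbonyl <- if (n_h(o1) == 0L) o1 else if (n_h(o2) == 0L) o2 else NA
      hydroxyl <- if (n_h(o1) >= 1L) o1 else if (n_h(o2) >= 1L) o2 else NA
      if (site == "carbonyl" && !is.na(carbonyl)) {
        return(list(site_atom = carbonyl, heavy_neighbor = cc,
                    other_o = setdiff(c(o1, o2), carbonyl)))
      }
      if (site == "hydroxyl" && !is.na(hydroxyl)) {
        return(list(site_atom = hydroxyl, heavy_neighbor = cc))
      }
    }
  }
  stop("missing site: no ", site, " group found")
}

#' Enumerate all protonation candidates of a seed structure
#'
#' Convenience wrapper producing the full 4-site x 2-variant candidate
#' set used to seed a protonated conformer search.
#'
#' @param geometry a neutral `mol_geom`.
#' @param sites character vector of sites to try.
#' @return a tibble with columns `site`, `variant` and a `geometry`
#'   list-column.
#' @export
protonation_candidates <- function(geometry,
                                   sites = c("amino", "carbonyl",
                                             "hydroxyl", "thiol")) {
  tidyr::expand_grid(site = sites, variant = 1:2) |>
    dplyr::mutate(geometry = purrr::map2(
      .data$site, .data$variant,
      function(s, v) attach_proton(geometry, s, v)
    ))
}
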