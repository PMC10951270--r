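#' Enumerate glycosidic cleavage sites
#'
#' One cleavage per tree edge (splitting the tree into the lost non-reducing
#' part and the retained reducing part), plus the attachment site between
#' the glycan root and the peptide, whose cleavage loses the whole glycan
#' and yields the naked-peptide Y0 ion.
#'
#' @param tree A [glycan_tree()].
#' @return List of cleavage sites, each a list with `kind`
#'   (`"edge"`/`"root_attachment"`), `parent`, `child`, `lost`, `retained`
#'   (integer node index vectors).
#' @export
enumerate_cleavages <- function(tree) {
  n <- length(tree$code)
  all_nodes <- seq_len(n)
  sites <- list()
  for (child in all_nodes) {
    p <- tree$parent[child]
    if (is.na(p)) next
    lost <- .subtree_nodes(tree, child)
    sites[[length(sites) + 1L]] <- list(
      kind = "edge", parent = p, child = child,
      lost = sort(lost), retained = sort(setdiff(all_nodes, lost))
    )
  }
  sites[[length(sites) + 1L]] <- list(
    kind = "root_attachment", parent = NA_integer_, child = tree$root,
    lost = all_nodes, retained = integer(0)
  )
  sites
}

## All retained node sets of Y fragments including node v, within v's
## subtree; returns list of integer vectors. The closed-form count is
## f(v) = prod over children (1 + f(child)).
.retained_sets_below <- function(tree, v) {
  sets <- list(v)
  for (ch in tree$children[[v]]) {
    child_sets <- .retained_sets_below(tree, ch)
    ext <- list()
    for (s in sets) {
      for (cs in child_sets) ext[[length(ext) + 1L]] <- c(s, cs)
    }
    sets <- c(sets, ext) # 'sets' alone = edge to ch cleaved
  }
  sets
}

.boundary_cleavage_ids <- function(sites, retained) {
  # edges with exactly one endpoint in the retained set; the peptide
  # attachment site is the (sole) boundary of the empty Y0 fragment
  which(vapply(sites, function(s) {
    if (s$kind == "root_attachment") return(length(retained) == 0L)
    xor(s$parent %in% retained, s$child %in% retained)
  }, logical(1)))
}

.make_fragment <- function(tree, sites, retained, ion_class) {
  retained <- sort(retained)
  list(
    ion_class = ion_class,
    retained = retained,
    cleavages = .boundary_cleavage_ids(sites, retained),
    comp = glycan_composition(tree, retained)
  )
}

#' Enumerate Y (reducing-end) structure fragments
#'
#' All connected, root-containing proper subtrees of the glycan (the intact
#' glycan is not a fragment: a fragment requires at least one cleavage),
#' plus the empty fragment Y0 produced by cleaving the glycan off the
#' peptide. Each fragment records the cleavage sites on its boundary.
#'
#' @param tree A [glycan_tree()].
#' @param sites Optional precomputed [enumerate_cleavages()] result.
#' @return List of structure fragments (`ion_class`, `retained`,
#'   `cleavages`, `comp`).
#' @export
enumerate_Y_fragments <- function(tree, sites = enumerate_cleavages(tree)) {
  n <- length(tree$code)
  sets <- .retained_sets_below(tree, tree$root)
  sets <- Filter(function(s) length(s) < n, sets) # exclude intact glycan
  frags <- lapply(sets, function(s) .make_fragment(tree, sites, s, "Y"))
  c(frags, list(.make_fragment(tree, sites, integer(0), "Y")))
}

#' Enumerate B (non-reducing-end branch) structure fragments
#'
#' For complex and hybrid glycans, B ions comprise, per branch hanging off
#' an arm mannose: every complete subtree rooted at a branch node, and each
#' such subtree together with the adjacent arm mannose. Oligomannose
#' (all-hexose) branches are excluded, and high-mannose glycans yield no B
#' ions. Fragments are deduplicated by retained node set.
#'
#' @param tree A [glycan_tree()].
#' @param core Optional precomputed [detect_core()] annotation.
#' @param sites Optional precomputed [enumerate_cleavages()] result.
#' @return List of structure fragments (possibly empty).
#' @export
enumerate_B_fragments <- function(tree, core = detect_core(tree),
                                  sites = enumerate_cleavages(tree)) {
  if (!core$glycan_class %in% c("complex", "hybrid")) return(list())
  frags <- list()
  seen <- character(0)
  for (b in core$branch_roots) {
    branch_nodes <- .subtree_nodes(tree, b)
    if (all(tree$code[branch_nodes] == "H")) next # oligomannose branch
    arm <- core$arm_of[[as.character(b)]]
    for (v in branch_nodes) {
      for (retained in list(.subtree_nodes(tree, v),
                            c(arm, .subtree_nodes(tree, v)))) {
        key <- paste(sort(retained), collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        frags[[length(frags) + 1L]] <-
          .make_fragment(tree, sites, retained, "B")
      }
    }
  }
  frags
}

#' Group isomeric structure fragments by composition
#'
#' Structure-specific fragments with the same monosaccharide composition
#' are indistinguishable by mass; their intensities are summed. This
#' operation defines the grouping.
#'
#' @param frags List of structure fragments sharing one `ion_class`.
#' @return A tibble with columns `ion_class`, `comp` (composition string),
#'   `members` (list of indices into `frags`).
#' @export
merge_isomeric_fragments <- function(frags) {
  if (length(frags) == 0L) {
    return(tibble::tibble(ion_class = character(0), comp = character(0),
                          members = list()))
  }
  classes <- vapply(frags, `[[`, character(1), "ion_class")
  if (length(unique(classes)) != 1L) {
    stop("fragments of mixed ion class cannot be merged")
  }
  keys <- vapply(frags, function(f) .comp_key(f$comp), character(1))
  split_idx <- split(seq_along(frags), keys)
  # stable order: by first appearance
  ord <- order(vapply(split_idx, min, integer(1)))
  split_idx <- split_idx[ord]
  tibble::tibble(
    ion_class = classes[1],
    comp = names(split_idx),
    members = unname(split_idx)
  )
}

#' Build the tripartite fragmentation graph
#'
#' Layers: cleavage sites, structure-specific fragments, and
#' composition-level fragments. Edges connect each structure fragment to
#' the cleavages on its boundary and to the single composition node it
#' belongs to. The graph is the scaffold on which the neural model
#' aggregates cleavage features and on which attention weights and isomer
#' proportions are reported.
#'
#' @param tree A [glycan_tree()].
#' @param with_B Also enumerate B fragments (requires a complex/hybrid
#'   glycan to be non-empty).
#' @return A `fragmentation_graph` object: list with `tree`, `cleavages`,
#'   `fragments`, `groups` (tibble from [merge_isomeric_fragments()], Y
#'   then B), and index vectors.
#' @export
build_fragmentation_graph <- function(tree, with_B = FALSE) {
  sites <- enumerate_cleavages(tree)
  # canonical cleavage ordering used by the aggregation LSTM in
  # evaluation mode: ascending depth of the cleaved edge, ties broken by
  # the canonical serialization of the lost subtree
  depth <- integer(length(tree$code))
  for (v in seq_along(tree$code)) {
    d <- 0L; u <- v
    while (!is.na(tree$parent[u])) { u <- tree$parent[u]; d <- d + 1L }
    depth[v] <- d
  }
  # the marked serialization distinguishes cleavages whose lost subtrees
  # are isomorphic but whose surrounding context differs; cleavages with
  # equal keys are related by a tree automorphism and therefore have
  # identical features, so their relative order cannot matter
  mark_serialize <- function(cut_child) {
    ser <- function(v) {
      kids <- tree$children[[v]]
      pre <- if (!is.na(cut_child) && v == cut_child) "*" else ""
      if (length(kids) == 0L) {
        return(paste0(pre, "(", tree$code[v], ")"))
      }
      sub <- sort(vapply(kids, ser, character(1)), method = "radix")
      paste0(pre, "(", tree$code[v], paste(sub, collapse = ""), ")")
    }
    ser(tree$root)
  }
  site_key <- vapply(sites, function(s) {
    if (s$kind == "root_attachment") {
      sprintf("%03d:", 0L)
    } else {
      sprintf("%03d:%s", depth[s$child], mark_serialize(s$child))
    }
  }, character(1))
  site_rank <- order(order(site_key))
  yfr <- enumerate_Y_fragments(tree, sites)
  bfr <- if (with_B) enumerate_B_fragments(tree, sites = sites) else list()
  frags <- c(yfr, bfr)
  frags <- lapply(frags, function(f) {
    f$cleavages <- f$cleavages[order(site_rank[f$cleavages])]
    f
  })
  groups_y <- merge_isomeric_fragments(yfr)
  groups_b <- merge_isomeric_fragments(bfr)
  if (nrow(groups_b) > 0) {
    groups_b$members <- lapply(groups_b$members, function(i) i + length(yfr))
  }
  groups <- dplyr::bind_rows(groups_y, groups_b)
  structure(
    list(tree = tree, cleavages = sites, fragments = frags,
         groups = groups, n_Y = length(yfr), n_B = length(bfr)),
    class = "fragmentation_graph"
  )
}

#' @export
print.fragmentation_graph <- function(x, ...) {
  cat("<fragmentation_graph> ", length(x$cleavages), " cleavages / ",
      length(x$fragments), " structure fragments / ",
      nrow(x$groups), " compositions (",
      x$n_Y, " Y, ", x$n_B, " B structures)\n", sep = "")
  invisible(x)
}

## ---- peptide backbone fragments -------------------------------------

.pep_series <- c("b", "y", "bN1", "yN1", "bX", "yX")

#' Theoretical peptide fragment ions
#'
#' For each backbone cleavage of a glycopeptide: naked b and y ions, b/y
#' carrying one HexNAc (b-N(1)/y-N(1)), and b/y carrying a cross-ring
#' remnant of the site HexNAc (b$/y$), at charges 1-2. The glycan-carrying
#' variants exist only on the side containing the glycosite.
#'
#' @param gp A [glycopeptide()].
#' @param charges Fragment charge states considered (default 1:2).
#' @return Tibble: `series`, `pos` (cleavage index, 1-based), `charge`,
#'   `mz`.
#' @export
peptide_fragments <- function(gp, charges = 1:2) {
  aa <- strsplit(gp$peptide, "")[[1]]
  L <- length(aa)
  if (L < 2L) {
    return(tibble::tibble(series = character(0), pos = integer(0),
                          charge = integer(0), mz = numeric(0)))
  }
  res_m <- .aa_mass[aa]
  mod_m <- numeric(L)
  if (nrow(gp$mods) > 0) {
    for (k in seq_len(nrow(gp$mods))) {
      mod_m[gp$mods$pos[k]] <- mod_m[gp$mods$pos[k]] + gp$mods$mass[k]
    }
  }
  cum <- unname(cumsum(res_m + mod_m))
  total <- cum[L]
  hexnac <- residue_mass("N")
  rows <- list()
  for (i in seq_len(L - 1L)) {
    b_neutral <- cum[i]
    y_neutral <- total - cum[i] + .water_mass
    b_site <- gp$glycosite <= i    # b fragment contains the glycosite
    for (z in charges) {
      add <- function(series, neutral) {
        rows[[length(rows) + 1L]] <<- tibble::tibble(
          series = series, pos = i, charge = z,
          mz = (neutral + z * .proton_mass) / z
        )
      }
      add("b", b_neutral)
      add("y", y_neutral)
      if (b_site) {
        add("bN1", b_neutral + hexnac)
        add("bX", b_neutral + .cross_ring_mass)
      } else {
        add("yN1", y_neutral + hexnac)
        add("yX", y_neutral + .cross_ring_mass)
      }
    }
  }
  dplyr::bind_rows(rows)
}

## ---- glycan fragment m/z --------------------------------------------

#' m/z of a glycan fragment
#'
#' Y ions retain the peptide: m/z = (peptide neutral mass + retained
#' residue masses + z protons) / z; Y0 is the naked peptide. B ions are
#' oxonium-type: m/z = retained residue masses + one proton, charge 1.
#'
#' @param gp A [glycopeptide()].
#' @param comp Composition string (or named count vector) of the retained
#'   monosaccharides; `""` for Y0.
#' @param ion_class `"Y"` or `"B"`.
#' @param charge Fragment charge.
#' @return m/z in Th.
#' @export
glycan_fragment_mz <- function(gp, comp, ion_class = "Y", charge = 1L) {
  if (is.character(comp)) comp <- parse_composition(comp)
  gmass <- if (length(comp) == 0) 0 else
    sum(residue_mass(names(comp)) * comp)
  if (ion_class == "Y") {
    pm <- peptide_mass(gp$peptide, gp$mods$mass)
    (pm + gmass + charge * .proton_mass) / charge
  } else if (ion_class == "B") {
    if (charge != 1L) stop("B ions are considered at charge 1 only")
    gmass + .proton_mass
  } else {
    stop("ion_class must be 'Y' or 'B'")
  }
}

## ---- theoretical fragment index -------------------------------------

#' Theoretical fragment index of a glycopeptide
#'
#' The full annotation index used to extract intensities from experimental
#' spectra: six peptide ion series at charges 1-2, Y ions (including Y0) at
#' charges 1-3 labelled by retained composition, and (optionally) B ions at
#' charge 1.
#'
#' @param gp A [glycopeptide()].
#' @param with_B Include B-ion rows (non-empty only for complex/hybrid
#'   glycans).
#' @param graph Optional precomputed [build_fragmentation_graph()].
#' @return Tibble: `part` (`"pep"`, `"Y"`, `"B"`), `series`, `pos`, `comp`,
#'   `charge`, `mz`.
#' @export
theoretical_fragments <- function(gp, with_B = FALSE,
                                  graph = build_fragmentation_graph(
                                    gp$glycan, with_B = with_B)) {
  pep <- peptide_fragments(gp)
  pep$part <- "pep"
  pep$comp <- NA_character_

  ycomp <- glycan_comp_index(graph, "Y")
  yrows <- tidyr::expand_grid(comp = ycomp, charge = 1:3)
  yrows$part <- "Y"
  yrows$series <- "Y"
  yrows$pos <- NA_integer_
  yrows$mz <- mapply(function(cp, z) glycan_fragment_mz(gp, cp, "Y", z),
                     yrows$comp, yrows$charge)

  out <- dplyr::bind_rows(pep, yrows)
  if (with_B) {
    bcomp <- glycan_comp_index(graph, "B")
    if (length(bcomp) > 0) {
      brows <- tibble::tibble(part = "B", series = "B", pos = NA_integer_,
                              comp = bcomp, charge = 1L)
      brows$mz <- vapply(brows$comp, function(cp)
        glycan_fragment_mz(gp, cp, "B", 1L), numeric(1))
      out <- dplyr::bind_rows(out, brows)
    }
  }
  dplyr::select(out, "part", "series", "pos", "comp", "charge", "mz")
}

#' Composition index of a fragmentation graph
#'
#' @param graph A [build_fragmentation_graph()] result.
#' @param ion_class `"Y"` or `"B"`.
#' @return Character vector of composition strings in graph order (`""` is
#'   Y0).
#' @export
glycan_comp_index <- function(graph, ion_class = "Y") {
  graph$groups$comp[graph$groups$ion_class == ion_class]
}
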