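#' Glycan trees
#'
#' An N-glycan is represented as a rooted, unordered tree of monosaccharide
#' nodes, with the reducing end (the residue attached to the peptide) at the
#' root. Branch order carries no information: HCD identification methods
#' cannot establish it, so two trees that differ only by permutation of
#' children are the same glycan.
#'
#' Trees are serialized with a nested-parenthesis grammar: each node is
#' `(X...children...)` where `X` is the one-letter code (H, N, A, G, F) and
#' the children follow immediately, e.g. `"(N(N(H(H)(H))))"` for the
#' trimannosyl chitobiose stub without the two outer arm positions filled.
#' [glycan_canonical()] emits the unique representative with children sorted
#' lexicographically by their own canonical serialization.
#'
#' @param symbols Character vector of monosaccharide codes or symbols, one
#'   per node.
#' @param parent Integer vector of parent node indices; `NA` marks the root
#'   (exactly one).
#' @return A `glycan_tree` object.
#' @examples
#' g <- parse_glycan("(N(N(H(H)(H))))")
#' glycan_composition(g)
#' @export
glycan_tree <- function(symbols, parent) {
  code <- .mono_table$code[match(symbols, .mono_table$symbol)]
  code[is.na(code)] <- symbols[is.na(code)]
  if (!all(code %in% .mono_table$code)) {
    stop("unknown monosaccharide code: ",
         paste(setdiff(code, .mono_table$code), collapse = ", "))
  }
  n <- length(code)
  parent <- as.integer(parent)
  if (length(parent) != n) stop("symbols and parent lengths differ")
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("tree must have exactly one root")
  children <- lapply(seq_len(n), function(i) which(parent == i))
  # connectivity / acyclicity: every node must reach the root
  for (i in seq_len(n)) {
    v <- i; steps <- 0L
    while (!is.na(parent[v])) {
      v <- parent[v]; steps <- steps + 1L
      if (steps > n) stop("cycle in glycan tree")
    }
    if (v != root) stop("glycan tree is not connected")
  }
  structure(
    list(code = code, parent = parent, children = children, root = root),
    class = "glycan_tree"
  )
}

#' @export
print.glycan_tree <- function(x, ...) {
  cat("<glycan_tree> ", glycan_canonical(x), "  [",
      format_composition(glycan_composition(x)), "]\n", sep = "")
  invisible(x)
}

#' @export
length.glycan_tree <- function(x) length(x$code)

#' Parse a glycan structure string
#'
#' @param text A structure string in the nested-parenthesis grammar, e.g.
#'   `"(N(N(H(H)(H))))"`.
#' @return A [glycan_tree()].
#' @export
parse_glycan <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(trimws(text), "")[[1]]
  if (length(chars) == 0L) stop("empty glycan structure string")
  code <- character(0)
  parent <- integer(0)
  stack <- integer(0) # open node indices
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      if (i == length(chars)) stop("malformed glycan string: trailing '('")
      sym <- chars[i + 1L]
      if (!sym %in% .mono_table$code) {
        stop("unknown monosaccharide code '", sym, "' in glycan string")
      }
      if (length(stack) == 0L && length(code) > 0L) {
        stop("malformed glycan string: multiple roots")
      }
      code <- c(code, sym)
      parent <- c(parent,
                  if (length(stack) == 0L) NA_integer_
                  else stack[length(stack)])
      stack <- c(stack, length(code))
      i <- i + 2L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in glycan string")
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in glycan string")
    }
  }
  if (length(stack) > 0L) stop("unbalanced '(' in glycan string")
  glycan_tree(code, parent)
}

#' Canonical serialization of a glycan tree
#'
#' Children at every node are ordered lexicographically by their own
#' canonical serialization, so any two isomorphic unordered trees yield the
#' same string and distinct topologies yield distinct strings.
#'
#' @param tree A [glycan_tree()].
#' @return A structure string.
#' @export
glycan_canonical <- function(tree) {
  ser <- function(v) {
    kids <- tree$children[[v]]
    if (length(kids) == 0L) return(paste0("(", tree$code[v], ")"))
    sub <- sort(vapply(kids, ser, character(1)), method = "radix")
    paste0("(", tree$code[v], paste(sub, collapse = ""), ")")
  }
  ser(tree$root)
}

#' Monosaccharide composition of a node set
#'
#' @param tree A [glycan_tree()].
#' @param nodes Integer vector of node indices; defaults to all nodes.
#' @return Named integer vector of counts over the codes present, in
#'   canonical order H, N, F, A, G.
#' @export
glycan_composition <- function(tree, nodes = seq_along(tree$code)) {
  tab <- table(factor(tree$code[nodes], levels = .comp_code_order))
  counts <- as.integer(tab)
  names(counts) <- .comp_code_order
  counts[counts > 0L]
}

#' Render a composition as text
#'
#' @param comp Named integer vector as returned by [glycan_composition()].
#' @return String such as `"H(5)N(4)F(1)"`; the empty composition renders
#'   as `""`.
#' @export
format_composition <- function(comp) {
  comp <- comp[comp > 0]
  codes <- intersect(.comp_code_order, names(comp))
  paste0(vapply(codes, function(k) paste0(k, "(", comp[[k]], ")"),
                character(1)),
         collapse = "")
}

#' Parse a composition string
#'
#' @param text String such as `"H(5)N(4)F(1)"`.
#' @return Named integer vector of counts.
#' @export
parse_composition <- function(text) {
  if (!nzchar(text)) return(integer(0))
  m <- gregexpr("([HNFAG])\\((\\d+)\\)", text)[[1]]
  pieces <- regmatches(text, gregexpr("([HNFAG])\\((\\d+)\\)", text))[[1]]
  if (sum(nchar(pieces)) != nchar(text)) {
    stop("malformed composition string: ", text)
  }
  counts <- as.integer(sub("^[HNFAG]\\((\\d+)\\)$", "\\1", pieces))
  names(counts) <- substr(pieces, 1, 1)
  counts[counts > 0L]
}

.comp_key <- function(comp) format_composition(comp)

#' Nodes of the subtree rooted at a node
#' @noRd
.subtree_nodes <- function(tree, v) {
  out <- v
  todo <- tree$children[[v]]
  while (length(todo) > 0L) {
    out <- c(out, todo)
    todo <- unlist(tree$children[todo], use.names = FALSE)
  }
  out
}

#' Annotate the N-glycan core
#'
#' Identifies the chitobiose core (reducing-end HexNAc, its HexNAc child,
#' the branching core mannose and its mannose children), flags core
#' fucosylation (Fuc on either core HexNAc) and bisecting HexNAc (HexNAc on
#' the central core mannose), locates the branch roots hanging off the arm
#' mannoses, and classifies the glycan as high-mannose, complex, hybrid or
#' other. Trees lacking the HexNAc-HexNAc-Hex core prefix are classified
#' `"other"` with an empty annotation rather than raising an error, so
#' degenerate synthetic trees remain usable.
#'
#' @param tree A [glycan_tree()].
#' @return A list with elements `core_nodes`, `branch_roots`, `arm_of`
#'   (named by branch root, the arm mannose it sits on), `core_fucose`,
#'   `bisecting`, `glycan_class`.
#' @export
detect_core <- function(tree) {
  other <- list(core_nodes = integer(0), branch_roots = integer(0),
                arm_of = integer(0), core_fucose = FALSE, bisecting = FALSE,
                glycan_class = "other")
  root <- tree$root
  if (tree$code[root] != "N") return(other)
  n2 <- tree$children[[root]][tree$code[tree$children[[root]]] == "N"]
  if (length(n2) != 1L) return(other)
  h1 <- tree$children[[n2]][tree$code[tree$children[[n2]]] == "H"]
  if (length(h1) != 1L) return(other)
  core <- c(root, n2, h1)
  kids_h1 <- tree$children[[h1]]
  arm_mannoses <- kids_h1[tree$code[kids_h1] == "H"]
  bisect <- any(tree$code[kids_h1] == "N")
  core <- c(core, arm_mannoses)
  fuc <- any(tree$code[unlist(tree$children[c(root, n2)])] == "F")

  branch_roots <- integer(0)
  arm_of <- integer(0)
  for (a in arm_mannoses) {
    for (b in tree$children[[a]]) {
      branch_roots <- c(branch_roots, b)
      arm_of <- c(arm_of, a)
    }
  }
  names(arm_of) <- branch_roots

  cls <- if (length(branch_roots) == 0L) {
    "other" # bare core (paucimannose-like); keep out of the three classes
  } else {
    branch_all_hex <- vapply(branch_roots, function(b) {
      all(tree$code[.subtree_nodes(tree, b)] == "H")
    }, logical(1))
    if (all(branch_all_hex)) "high_mannose"
    else if (any(branch_all_hex)) "hybrid"
    else "complex"
  }
  list(core_nodes = core, branch_roots = branch_roots, arm_of = arm_of,
       core_fucose = fuc, bisecting = bisect, glycan_class = cls)
}

#' Structural isomers of a composition within a glycan space
#'
#' Filters a glycan database for structures whose monosaccharide
#' composition equals `comp`, deduplicated by canonical serialization.
#'
#' @param comp Named integer composition vector (see
#'   [glycan_composition()]).
#' @param space List of [glycan_tree()] objects (a parsed glycan database).
#' @return List of distinct `glycan_tree` objects matching `comp`.
#' @export
enumerate_isomers <- function(comp, space) {
  key <- .comp_key(comp)
  hits <- Filter(function(g) .comp_key(glycan_composition(g)) == key, space)
  if (length(hits) == 0L) return(list())
  hits[!duplicated(vapply(hits, glycan_canonical, character(1)))]
}

#' Read a glycan structure database
#'
#' Plain-text database: one structure string per line, `#` comments and
#' blank lines ignored.
#'
#' @param path File path.
#' @return List of [glycan_tree()] objects.
#' @export
read_glycan_db <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lapply(lines[nzchar(lines)], parse_glycan)
}

#' Write a glycan structure database
#'
#' @param space List of [glycan_tree()] objects.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_glycan_db <- function(space, path) {
  writeLines(vapply(space, glycan_canonical, character(1)), path)
  invisible(path)
}
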