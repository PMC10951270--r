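## Shared fixtures and independent oracles used across the test files.

## The trimannosyl core stub: HexNAc-HexNAc-Hex(Hex)(Hex)
core_struct <- "(N(N(H(H)(H))))"

tiny_model <- function(hidden = 4, with_B = FALSE, seed = 11,
                       dropout = 0) {
  glyco_model(glyco_config(hidden = hidden, dropout = dropout,
                           with_B = with_B, max_charge = 6),
              seed = seed)
}

tiny_precursor <- function(glycan = core_struct, peptide = "ANSTLK",
                           glycosite = 2, charge = 2, mods = NULL) {
  glycopeptide(peptide, glycan, glycosite, charge, mods = mods)
}

## Random unordered tree over the monosaccharide alphabet.
random_tree <- function(n_nodes, codes = c("H", "N", "A", "G", "F")) {
  parent <- c(NA_integer_,
              if (n_nodes > 1) vapply(2:n_nodes,
                                      function(i) sample.int(i - 1L, 1),
                                      integer(1)))
  glycan_tree(sample(codes, n_nodes, replace = TRUE), parent)
}

## Random relabeling + child-order permutation of a tree: an isomorphic
## tree whose node indexing and serialization input order differ.
permute_tree <- function(tree) {
  n <- length(tree$code)
  perm <- sample.int(n) # new id of old node i is perm[i]
  code <- character(n)
  parent <- integer(n)
  code[perm] <- tree$code
  parent[perm] <- ifelse(is.na(tree$parent), NA_integer_,
                         perm[tree$parent])
  glycan_tree(code, parent)
}

## Brute-force oracle for Y fragments: all connected, root-containing
## proper subsets of the node set, by exhaustive subset enumeration.
brute_force_Y_sets <- function(tree) {
  n <- length(tree$code)
  sets <- list()
  for (mask in 1:(2^n - 1)) {
    nodes <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!(tree$root %in% nodes) || length(nodes) == n) next
    # connected to root within the subset?
    ok <- all(vapply(nodes, function(v) {
      while (!is.na(tree$parent[v])) {
        v <- tree$parent[v]
        if (!(v %in% nodes)) return(FALSE)
      }
      TRUE
    }, logical(1)))
    if (ok) sets[[length(sets) + 1L]] <- sort(nodes)
  }
  sets
}

## Closed-form count of non-empty Y fragments:
## f(v) = prod over children (1 + f(child)); count = f(root) - 1.
closed_form_Y_count <- function(tree) {
  f <- function(v) {
    prod(vapply(tree$children[[v]], function(ch) 1 + f(ch), numeric(1)))
  }
  f(tree$root) - 1
}

set_key <- function(s) paste(sort(s), collapse = ",")

## Deterministic simulated dataset used by several test files.
sim_dataset_cached <- local({
  env <- new.env()
  function(n = 40, seed = 71, with_B = FALSE) {
    key <- paste(n, seed, with_B)
    if (is.null(env[[key]])) {
      env[[key]] <- generate_dataset(sim_config(n_precursors = n),
                                     seed = seed, with_B = with_B)
    }
    env[[key]]
  }
})

## All permutations of a small vector (tiny n only).
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}
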