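#' Generate candidate glycopeptides with isomeric glycans
#'
#' Replaces the glycan of a glycopeptide spectral match with every
#' structural isomer of its monosaccharide composition found in the glycan
#' space; peptide, modifications, glycosite and charge are unchanged.
#'
#' @param gp The originally assigned [glycopeptide()].
#' @param space List of [glycan_tree()] objects (the glycan database).
#' @return List of candidate [glycopeptide()] objects (may exclude the
#'   original structure if it is absent from the space).
#' @export
generate_candidates <- function(gp, space) {
  isomers <- enumerate_isomers(glycan_composition(gp$glycan), space)
  lapply(isomers, function(g) {
    glycopeptide(gp$peptide, g, gp$glycosite, gp$charge,
                 mods = if (nrow(gp$mods)) gp$mods else NULL)
  })
}

#' Rank candidate glycan structures against a query spectrum
#'
#' For each candidate, the query peak list is annotated against the
#' candidate's theoretical fragments, the spectral angles of the glycan Y
#' part (and B part, when the model predicts it) are computed between the
#' observed and predicted intensities, and candidates are ranked by the
#' combined score `alpha (1 - SA_Y) + beta (1 - SA_B)` in descending
#' order. Query peaks matching no candidate's predicted fragments never
#' enter any intensity vector and therefore cannot affect any score. The
#' peptide-part spectral angle is reported but not scored. Ties are broken
#' by the canonical glycan string.
#'
#' @param query A [spectrum()] peak list, or an `annotated_spectrum` whose
#'   fragment table will be re-matched per candidate.
#' @param candidates List of candidate [glycopeptide()] objects.
#' @param model A trained `glyco_model`.
#' @param tol_ppm Peak-matching tolerance.
#' @param alpha,beta Score weights (default 0.5 / 0.5).
#' @return A `glyco_ranking` tibble: `glycan`, `sa_Y`, `sa_B`, `sa_pep`,
#'   `score`, `rank`, `core_fucose`, `bisecting`.
#' @export
rank_candidates <- function(query, candidates, model, tol_ppm = 20,
                            alpha = 0.5, beta = 0.5) {
  stopifnot(length(candidates) >= 1)
  cfg <- model$config
  if (inherits(query, "annotated_spectrum")) {
    pk <- query$fragments[query$fragments$intensity > 0, ]
    query <- spectrum(pk$mz, pk$intensity)
  }
  rows <- purrr::map_dfr(candidates, function(cand) {
    ann <- match_peaks(query, cand, tol_ppm = tol_ppm,
                       with_B = cfg$with_B)
    obs <- spectrum_parts(ann)
    fw <- .model_fwd(model$params, cfg, cand, training = FALSE,
                     keep_cache = FALSE)
    sa_part <- function(p, o) {
      if (sum(p) == 0 || sum(o) == 0) return(NA_real_)
      spectral_angle(p, o)
    }
    oY <- obs$Y[match(rownames(fw$Y), rownames(obs$Y)), , drop = FALSE]
    sa_Y <- sa_part(as.vector(fw$Y), as.vector(oY))
    sa_B <- if (cfg$with_B && length(fw$B) > 0) {
      oB <- obs$B[match(names(fw$B), names(obs$B))]
      oB[is.na(oB)] <- 0
      sa_part(as.vector(fw$B), oB)
    } else NA_real_
    sa_pep <- sa_part(as.vector(fw$pep), as.vector(obs$pep))
    core <- detect_core(cand$glycan)
    tibble::tibble(
      glycan = glycan_canonical(cand$glycan),
      sa_Y = sa_Y, sa_B = sa_B, sa_pep = sa_pep,
      core_fucose = core$core_fucose, bisecting = core$bisecting
    )
  })
  if (all(is.na(rows$sa_Y))) {
    stop("query spectrum shares no matchable glycan fragments with any ",
         "candidate")
  }
  rows$score <- ranking_score(rows$sa_Y, rows$sa_B,
                              alpha = alpha, beta = beta)
  ord <- order(-rows$score, rows$glycan)
  rows <- rows[ord, ]
  rows$rank <- seq_len(nrow(rows))
  class(rows) <- c("glyco_ranking", class(rows))
  rows
}

#' Summarize isomer-recognition performance over a dataset
#'
#' The top-k rate counts
#' queries whose correct structure ranked within the first k, out of the
#' queries with more than k candidates. Confusion matrices for core
#' fucosylation and bisecting HexNAc compare the top-1 candidate's flag
#' with the true flag, excluding queries whose candidates all share the
#' category.
#'
#' @param rankings List of `glyco_ranking` tibbles (one per query).
#' @param truth Character vector of the true canonical glycan strings.
#' @return List with `topk` (tibble of k, numerator, denominator, rate),
#'   `confusion_fucose` and `confusion_bisecting` (2x2 tables), and
#'   `n_queries`.
#' @export
summarize_recognition <- function(rankings, truth) {
  stopifnot(length(rankings) == length(truth))
  true_rank <- vapply(seq_along(rankings), function(i) {
    r <- rankings[[i]]$rank[rankings[[i]]$glycan == truth[i]]
    if (length(r) == 0) NA_integer_ else as.integer(r[1])
  }, integer(1))
  n_cand <- vapply(rankings, nrow, integer(1))
  topk <- purrr::map_dfr(1:3, function(k) {
    elig <- n_cand > k
    tibble::tibble(
      k = k,
      hits = sum(elig & !is.na(true_rank) & true_rank <= k),
      eligible = sum(elig),
      rate = ifelse(sum(elig) > 0,
                    sum(elig & !is.na(true_rank) & true_rank <= k) /
                      sum(elig), NA_real_)
    )
  })
  confusion <- function(flag) {
    lv <- c(FALSE, TRUE)
    tab <- table(factor(logical(0), levels = lv),
                 factor(logical(0), levels = lv))
    for (i in seq_along(rankings)) {
      r <- rankings[[i]]
      if (length(unique(r[[flag]])) < 2) next # category uninformative
      truth_flag <- r[[flag]][r$glycan == truth[i]]
      if (length(truth_flag) == 0) next
      pred_flag <- r[[flag]][r$rank == 1]
      tab <- tab + table(factor(truth_flag, levels = lv),
                         factor(pred_flag, levels = lv))
    }
    dimnames(tab) <- list(truth = c("absent", "present"),
                          predicted = c("absent", "present"))
    tab
  }
  list(topk = topk,
       confusion_fucose = confusion("core_fucose"),
       confusion_bisecting = confusion("bisecting"),
       n_queries = length(rankings))
}

#' Explain a prediction through its fragmentation graph
#'
#' Annotates the candidate's fragmentation graph with (a) the attention
#' weights of each structure fragment over its boundary cleavages and (b)
#' the proportion each structure-specific isomer contributes to its
#' composition-level intensity (summed over charge states). Weights into
#' any target node sum to one; compositions with zero total intensity get
#' uniform member weights and a flag.
#'
#' @param gp A [glycopeptide()] candidate.
#' @param model A `glyco_model`.
#' @return A `glyco_explanation`: list with the graph, `cleavage_edges`
#'   (tibble: fragment, cleavage, attention) and `member_edges` (tibble:
#'   composition, fragment, proportion, degenerate).
#' @export
explain_candidate <- function(gp, model) {
  cfg <- model$config
  fw <- .model_fwd(model$params, cfg, gp, training = FALSE,
                   keep_cache = TRUE)
  graph <- fw$graph
  frag_attention <- function(j) {
    if (graph$fragments[[j]]$ion_class == "Y") {
      run <- fw$cache$yrun; k <- j
    } else {
      run <- fw$cache$brun; k <- j - graph$n_Y
    }
    seg <- (run$off[k] + 1):run$off[k + 1]
    list(cleavage = run$idx[seg] + 1L, attention = run$alpha[seg])
  }
  cl_edges <- purrr::map_dfr(seq_along(graph$fragments), function(j) {
    at <- frag_attention(j)
    tibble::tibble(
      fragment = j,
      ion_class = graph$fragments[[j]]$ion_class,
      cleavage = at$cleavage,
      attention = at$attention
    )
  })
  mem_edges <- purrr::map_dfr(seq_len(nrow(graph$groups)), function(gi) {
    grp <- graph$groups[gi, ]
    members <- grp$members[[1]]
    ints <- vapply(members, function(j) {
      if (grp$ion_class == "Y") sum(fw$y_struct[j, ])
      else fw$b_struct[j - graph$n_Y]
    }, numeric(1))
    tot <- sum(ints)
    degenerate <- tot <= 0
    prop <- if (degenerate) rep(1 / length(members), length(members)) else
      ints / tot
    tibble::tibble(
      composition = grp$comp, ion_class = grp$ion_class,
      fragment = members, proportion = prop, degenerate = degenerate
    )
  })
  structure(list(graph = graph, cleavage_edges = cl_edges,
                 member_edges = mem_edges,
                 precursor = precursor_id(gp)),
            class = "glyco_explanation")
}

#' Export an explanation as node/edge tables
#'
#' @param x A `glyco_explanation`.
#' @param path Base file path; writes `<path>_nodes.tsv` and
#'   `<path>_edges.tsv`.
#' @return `path`, invisibly.
#' @export
write_explanation <- function(x, path) {
  g <- x$graph
  nodes <- dplyr::bind_rows(
    tibble::tibble(
      id = paste0("c", seq_along(g$cleavages)), layer = "cleavage",
      label = vapply(g$cleavages, function(s) {
        if (s$kind == "root_attachment") "peptide|glycan"
        else paste0(s$parent, "-", s$child)
      }, character(1))
    ),
    tibble::tibble(
      id = paste0("s", seq_along(g$fragments)), layer = "structure",
      label = vapply(g$fragments, function(f)
        paste0(f$ion_class, ":", format_composition(f$comp)),
        character(1))
    ),
    tibble::tibble(
      id = paste0("g", seq_len(nrow(g$groups))), layer = "composition",
      label = paste0(g$groups$ion_class, ":", g$groups$comp)
    )
  )
  edges <- dplyr::bind_rows(
    dplyr::transmute(x$cleavage_edges,
                     from = paste0("c", .data$cleavage),
                     to = paste0("s", .data$fragment),
                     weight = .data$attention, type = "attention"),
    dplyr::transmute(
      dplyr::mutate(x$member_edges,
                    group = match(paste(.data$ion_class,
                                        .data$composition),
                                  paste(g$groups$ion_class,
                                        g$groups$comp))),
      from = paste0("s", .data$fragment),
      to = paste0("g", .data$group),
      weight = .data$proportion, type = "isomer_proportion")
  )
  utils::write.table(nodes, paste0(path, "_nodes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(edges, paste0(path, "_edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
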