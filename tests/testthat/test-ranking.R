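## Shared small glycan space with isomer groups.
ranking_space <- lapply(c(
  "(N(N(H(H(N))(H))))",        # H3N3 antenna on arm 1
  "(N(N(H(N)(H)(H))))",        # H3N3 bisecting isomer
  "(N(N(H(H)(H(N)))))",        # H3N3 antenna on arm 2 (same canonical
                               # as arm 1 after sorting: distinct only if
                               # arms differ) -- kept for dedup behavior
  "(N(N(H(H(N(H)))(H))))",     # H4N3
  "(N(N(H(H(H))(H(N)))))",     # H4N3 isomer
  "(N(F)(N(H(H(N))(H))))",     # H3N3F1 core-fucosylated
  "(N(N(H(H(N(F)))(H))))"      # H3N3F1 antenna-fucosylated isomer
), parse_glycan)

test_that("candidate generation swaps isomeric glycans only", {
  gp <- tiny_precursor(glycan = "(N(N(H(H(N))(H))))", charge = 2)
  cands <- generate_candidates(gp, ranking_space)
  expect_length(cands, 2) # the two distinct H3N3 topologies
  for (cand in cands) {
    expect_equal(format_composition(glycan_composition(cand$glycan)),
                 "H(3)N(3)")
    expect_equal(cand$peptide, gp$peptide)
    expect_equal(cand$charge, gp$charge)
  }
  lone <- tiny_precursor(glycan = "(N(N(H(H(N(H)))(H))))")
  expect_length(generate_candidates(lone, ranking_space), 2)
  none <- tiny_precursor(glycan = "(N(N(H(H)(H))))") # H3N2 not in space
  expect_length(generate_candidates(none, ranking_space), 0)
})

test_that("a model's own prediction ranks its structure first with score 1", {
  m <- tiny_model(hidden = 6, with_B = TRUE, seed = 21)
  gp <- tiny_precursor(glycan = "(N(N(H(H(N))(H))))", charge = 2)
  pred <- predict(m, gp)
  query <- spectrum(pred$mz[pred$intensity > 0],
                    pred$intensity[pred$intensity > 0])
  cands <- generate_candidates(gp, ranking_space)
  res <- rank_candidates(query, cands, m, tol_ppm = 10)
  expect_s3_class(res, "glyco_ranking")
  top <- res[res$rank == 1, ]
  expect_equal(top$glycan, glycan_canonical(gp$glycan))
  expect_equal(top$score, 1, tolerance = 1e-6)
  expect_equal(top$sa_Y, 0, tolerance = 1e-6)
  # ranking is invariant to global intensity scaling of the query
  res_scaled <- rank_candidates(
    spectrum(query$peaks$mz, 1e3 * query$peaks$intensity), cands, m,
    tol_ppm = 10)
  expect_equal(res$score, res_scaled$score, tolerance = 1e-6)
  expect_equal(res$glycan, res_scaled$glycan)
  # a peak matching no candidate's predicted fragments is discarded and
  # cannot change any score
  res_junk <- rank_candidates(
    spectrum(c(query$peaks$mz, 9999.9), c(query$peaks$intensity, 1e6)),
    cands, m, tol_ppm = 10)
  expect_equal(res$score, res_junk$score, tolerance = 1e-12)
})

test_that("scores order candidates by the combined Y/B similarity", {
  # direct arithmetic check of the score ordering contract
  expect_gt(ranking_score(0.1, 0.1), ranking_score(0.3, 0.3))
  # and deterministic tie-break by canonical string through the ranking
  m <- tiny_model(hidden = 6, seed = 22)
  gp <- tiny_precursor(glycan = "(N(N(H(H(N))(H))))", charge = 2)
  cands <- generate_candidates(gp, ranking_space)
  pred <- predict(m, gp)
  query <- spectrum(pred$mz[pred$intensity > 0],
                    pred$intensity[pred$intensity > 0])
  r1 <- rank_candidates(query, cands, m)
  r2 <- rank_candidates(query, rev(cands), m)
  expect_equal(r1$glycan, r2$glycan) # candidate order cannot matter
})

test_that("recognition summaries use the eligible-query denominators", {
  mk <- function(glycans, scores, fuc, bis) {
    tibble::tibble(glycan = glycans, sa_Y = 0, sa_B = 0, sa_pep = 0,
                   core_fucose = fuc, bisecting = bis,
                   score = scores, rank = rank(-scores))
  }
  rankings <- list(
    mk(c("a", "b"), c(0.9, 0.8), c(TRUE, FALSE), c(FALSE, FALSE)),
    mk(c("a", "b", "c", "d"), c(0.9, 0.8, 0.7, 0.6),
       c(TRUE, TRUE, TRUE, TRUE), c(FALSE, TRUE, FALSE, FALSE)),
    mk(c("a", "b", "c", "d"), c(0.6, 0.7, 0.8, 0.9),
       c(FALSE, TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE, FALSE))
  )
  truth <- c("a", "a", "a")
  s <- summarize_recognition(rankings, truth)
  # top-1: all three queries have > 1 candidate; correct in queries 1, 2
  expect_equal(s$topk$eligible[s$topk$k == 1], 3)
  expect_equal(s$topk$hits[s$topk$k == 1], 2)
  # top-3: only queries 2 and 3 have > 3 candidates
  expect_equal(s$topk$eligible[s$topk$k == 3], 2)
  expect_equal(s$topk$hits[s$topk$k == 3], 1) # query 3: "a" is rank 4
  # fucose matrix: query 2 excluded (all candidates fucosylated)
  expect_equal(sum(s$confusion_fucose), 2)
  # query 1: truth fuc TRUE, top-1 fuc TRUE -> present/present
  expect_equal(s$confusion_fucose["present", "present"], 1)
  # query 3: truth fuc FALSE, top-1 ("d") fuc TRUE
  expect_equal(s$confusion_fucose["absent", "present"], 1)
})

test_that("explanations carry normalized attention and member proportions", {
  m <- tiny_model(hidden = 6, with_B = TRUE, seed = 23)
  gp <- tiny_precursor(glycan = "(N(N(H(H(N))(H(N)))))", charge = 2)
  ex <- explain_candidate(gp, m)
  # attention into every structure fragment sums to 1
  sums <- tapply(ex$cleavage_edges$attention,
                 ex$cleavage_edges$fragment, sum)
  expect_equal(as.vector(sums), rep(1, length(sums)),
               tolerance = 1e-9)
  # member proportions per composition sum to 1
  psums <- tapply(ex$member_edges$proportion,
                  paste(ex$member_edges$ion_class,
                        ex$member_edges$composition), sum)
  expect_equal(as.vector(psums), rep(1, length(psums)),
               tolerance = 1e-9)
  # single-member compositions have proportion exactly 1
  singles <- ex$member_edges[!duplicated(ex$member_edges$composition) &
                               !(ex$member_edges$composition %in%
                                   ex$member_edges$composition[
                                     duplicated(ex$member_edges$composition)]), ]
  expect_true(all(abs(singles$proportion - 1) < 1e-12 |
                    singles$degenerate))
  # graph files export as node/edge tables
  base <- file.path(withr::local_tempdir(), "expl")
  write_explanation(ex, base)
  nodes <- read.delim(paste0(base, "_nodes.tsv"))
  edges <- read.delim(paste0(base, "_edges.tsv"))
  expect_setequal(unique(nodes$layer),
                  c("cleavage", "structure", "composition"))
  expect_true(all(edges$weight >= 0 & edges$weight <= 1))
})
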