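test_that("cleavage enumeration yields one site per edge plus the peptide attachment", {
  core <- parse_glycan(core_struct)
  sites <- enumerate_cleavages(core)
  expect_length(sites, 5) # 4 edges + root attachment
  expect_equal(sum(vapply(sites, function(s)
    s$kind == "root_attachment", logical(1))), 1)
  ra <- sites[[which(vapply(sites, function(s)
    s$kind == "root_attachment", logical(1)))]]
  expect_equal(ra$lost, 1:5)
  expect_length(ra$retained, 0)

  expect_length(enumerate_cleavages(parse_glycan("(N)")), 1)

  set.seed(41)
  tr <- random_tree(8)
  expect_length(enumerate_cleavages(tr), 8)
  for (s in enumerate_cleavages(tr)) {
    expect_setequal(c(s$lost, s$retained), seq_len(8))
  }
})

test_that("Y fragments match the brute-force and closed-form oracles", {
  core <- parse_glycan(core_struct)
  fr <- enumerate_Y_fragments(core)
  nonempty <- Filter(function(f) length(f$retained) > 0, fr)
  expect_length(nonempty, 5)
  expect_length(fr, 6) # + Y0
  comps <- sort(vapply(nonempty, function(f)
    format_composition(f$comp), character(1)))
  expect_equal(comps, sort(c("N(1)", "N(2)", "H(1)N(2)",
                             "H(2)N(2)", "H(2)N(2)")))

  expect_length(enumerate_Y_fragments(parse_glycan("(N)")), 1) # Y0 only

  chain <- glycan_tree(c("N", "N", "H", "H"), c(NA, 1, 2, 3))
  expect_length(Filter(function(f) length(f$retained) > 0,
                       enumerate_Y_fragments(chain)), 3)

  set.seed(42)
  for (i in 1:20) {
    tr <- random_tree(sample(2:12, 1))
    fr <- enumerate_Y_fragments(tr)
    nonempty <- Filter(function(f) length(f$retained) > 0, fr)
    oracle <- brute_force_Y_sets(tr)
    expect_setequal(vapply(nonempty, function(f) set_key(f$retained),
                           character(1)),
                    vapply(oracle, set_key, character(1)))
    expect_equal(length(nonempty), closed_form_Y_count(tr))
  }
})

test_that("Y fragment boundary cleavages are consistent with the retained set", {
  set.seed(43)
  for (i in 1:10) {
    tr <- random_tree(sample(3:10, 1))
    sites <- enumerate_cleavages(tr)
    for (f in enumerate_Y_fragments(tr, sites)) {
      # reconstruct boundary from retained set, must match
      expected <- which(vapply(sites, function(s) {
        if (s$kind == "root_attachment") return(length(f$retained) == 0)
        xor(s$parent %in% f$retained, s$child %in% f$retained)
      }, logical(1)))
      expect_setequal(f$cleavages, expected)
      if (length(f$retained) > 0) {
        expect_true(tr$root %in% f$retained)
      }
    }
  }
})

test_that("B fragments follow the branch rule", {
  # core + single GlcNAc branch on one arm mannose
  g <- parse_glycan("(N(N(H(H(N))(H))))")
  bf <- enumerate_B_fragments(g)
  comps <- sort(vapply(bf, function(f) format_composition(f$comp),
                       character(1)))
  expect_equal(comps, sort(c("N(1)", "H(1)N(1)")))

  # branch GlcNAc-Gal: subtrees {H}, {N,H}; with the adjacent mannose
  # {H,H} and {N,H,H}
  g2 <- parse_glycan("(N(N(H(H(N(H)))(H))))")
  bf2 <- enumerate_B_fragments(g2)
  comps2 <- sort(vapply(bf2, function(f) format_composition(f$comp),
                        character(1)))
  expect_equal(comps2, sort(c("H(1)", "H(1)N(1)", "H(2)",
                              "H(2)N(1)")))

  # high-mannose: no B ions
  hm <- parse_glycan("(N(N(H(H(H)(H))(H(H)))))")
  expect_length(enumerate_B_fragments(hm), 0)

  # hybrid: the oligomannose arm contributes nothing
  hy <- parse_glycan("(N(N(H(H(H))(H(N)))))")
  bfh <- enumerate_B_fragments(hy)
  compsh <- vapply(bfh, function(f) format_composition(f$comp),
                   character(1))
  expect_setequal(compsh, c("N(1)", "H(1)N(1)"))

  # B fragments never contain the root
  for (f in c(bf, bf2, bfh)) {
    expect_false(1 %in% f$retained)
  }
})

test_that("isomeric fragments merge by composition with conserved membership", {
  core <- parse_glycan(core_struct)
  fr <- enumerate_Y_fragments(core)
  groups <- merge_isomeric_fragments(fr)
  expect_equal(nrow(groups), 5) # 4 distinct non-empty comps + Y0
  expect_equal(sum(lengths(groups$members)), length(fr))
  two <- groups$members[[which(groups$comp == "H(2)N(2)")]]
  expect_length(two, 2)

  y0 <- merge_isomeric_fragments(enumerate_Y_fragments(
    parse_glycan("(N)")))
  expect_equal(nrow(y0), 1)
  expect_equal(y0$comp, "")

  expect_equal(nrow(merge_isomeric_fragments(list())), 0)
  mixed <- c(enumerate_Y_fragments(core)[1],
             enumerate_B_fragments(parse_glycan("(N(N(H(H(N))(H))))"))[1])
  expect_error(merge_isomeric_fragments(mixed), "mixed ion class")
})

test_that("the tripartite graph has the expected layers and degrees", {
  g <- build_fragmentation_graph(parse_glycan(core_struct))
  expect_length(g$cleavages, 5)
  expect_length(g$fragments, 6)
  expect_equal(nrow(g$groups), 5)
  for (f in g$fragments) {
    expect_gte(length(f$cleavages), 1)
  }
  # every structure fragment belongs to exactly one composition group
  membership <- unlist(g$groups$members)
  expect_setequal(membership, seq_along(g$fragments))
  expect_equal(length(membership), length(g$fragments))

  single <- build_fragmentation_graph(parse_glycan("(N)"))
  expect_equal(c(length(single$cleavages), length(single$fragments),
                 nrow(single$groups)), c(1, 1, 1))
})

test_that("peptide fragments cover the six series with site-aware variants", {
  gp <- glycopeptide("GG", core_struct, glycosite = 1, charge = 2)
  pf <- peptide_fragments(gp)
  y1 <- pf[pf$series == "y" & pf$pos == 1 & pf$charge == 1, ]
  expect_equal(y1$mz, 76.0393, tolerance = 1e-4)
  # glycosite at residue 1: b1 carries the variants, y1 does not
  expect_setequal(pf$series[pf$pos == 1 & pf$charge == 1],
                  c("b", "y", "bN1", "bX"))

  gp2 <- tiny_precursor(peptide = "ANSTLK", glycosite = 2)
  pf2 <- peptide_fragments(gp2)
  L <- 6
  expect_equal(sum(pf2$series %in% c("b", "y")), 2 * (L - 1) * 2)
  # fragments containing the glycosite carry exactly the b or y variants
  for (i in seq_len(L - 1)) {
    sub <- pf2[pf2$pos == i & pf2$charge == 1, ]
    if (2 <= i) {
      expect_setequal(sub$series, c("b", "y", "bN1", "bX"))
    } else {
      expect_setequal(sub$series, c("b", "y", "yN1", "yX"))
    }
  }
  # modification masses shift the containing fragments
  gpm <- glycopeptide("ACNSTK", core_struct, 3, 2,
                      mods = tibble::tibble(pos = 2,
                                            formula = "C2H3NO"))
  pfm <- peptide_fragments(gpm)
  pfu <- peptide_fragments(glycopeptide("ACNSTK", core_struct, 3, 2))
  b2m <- pfm$mz[pfm$series == "b" & pfm$pos == 2 & pfm$charge == 1]
  b2u <- pfu$mz[pfu$series == "b" & pfu$pos == 2 & pfu$charge == 1]
  expect_equal(b2m - b2u, 57.02146, tolerance = 1e-4)
})

test_that("glycan fragment m/z follows the Y and B formulas", {
  expect_equal(glycan_fragment_mz(tiny_precursor(), "N(1)", "B", 1),
               204.08666, tolerance = 1e-5)
  gp <- tiny_precursor()
  pm <- peptide_mass(gp$peptide)
  expect_equal(glycan_fragment_mz(gp, "", "Y", 2),
               (pm + 2 * 1.007276) / 2, tolerance = 1e-5)
  expect_equal(glycan_fragment_mz(gp, "H(3)N(2)", "Y", 1),
               pm + 2 * 203.07937 + 3 * 162.05282 + 1.007276,
               tolerance = 1e-4)
  expect_error(glycan_fragment_mz(gp, "N(2)", "B", 2), "charge 1")

  # m/z strictly increasing in retained composition at fixed charge
  mzs <- vapply(c("", "N(1)", "N(2)", "H(1)N(2)", "H(2)N(2)", "H(3)N(2)"),
                function(cp) glycan_fragment_mz(gp, cp, "Y", 1),
                numeric(1))
  expect_true(all(diff(mzs) > 0))
})

test_that("the theoretical fragment index is complete and well-formed", {
  gp <- tiny_precursor(glycan = "(N(N(H(H(N))(H))))", charge = 3)
  theo <- theoretical_fragments(gp, with_B = TRUE)
  expect_true(all(theo$mz > 0))
  expect_setequal(unique(theo$part), c("pep", "Y", "B"))
  expect_true(all(theo$charge[theo$part == "pep"] %in% 1:2))
  expect_true(all(theo$charge[theo$part == "Y"] %in% 1:3))
  expect_true(all(theo$charge[theo$part == "B"] == 1))
  expect_true("" %in% theo$comp[theo$part == "Y"]) # Y0 present
})
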