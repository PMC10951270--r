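#' Simulator configuration
#'
#' The ground-truth fragmentation simulator emulates stepped-CE HCD
#' glycopeptide spectra with a known intensity rule, so that peak
#' matching, training, isomer rescoring and library building can all be
#' tested end to end without any experimental download.
#'
#' The glycan intensity rule encodes the empirical observation that
#' cleavages within the trimannosyl core are less likely than cleavages in
#' the antennae at the relatively low collision energies that preserve Y
#' ions: a Y structure fragment bounded by cleavages `c1..ck` receives
#' intensity `exp(-sum(lambda(ci)))` with `lambda_core > lambda_branch`.
#'
#' @param n_precursors Number of simulated glycopeptide precursors.
#' @param peptide_length Range of tryptic-like peptide lengths.
#' @param glycan_size Target range of glycan node counts.
#' @param class_mix Named probabilities for complex / hybrid /
#'   high-mannose glycans.
#' @param p_core_fucose,p_bisecting Decoration probabilities.
#' @param lambda_branch,lambda_core Cleavage propensities (branch edges
#'   are more labile; both > 0).
#' @param oxonium_boost Multiplier for B ions of 1-2 monosaccharides.
#' @param ratio_mean,ratio_conc Beta-distribution parameters (mean,
#'   concentration) of the peptide intensity fraction; the default mean
#'   0.25 reflects that peptide fragments are usually much less intense
#'   than glycan fragments in stepped-CE HCD.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal peak noise.
#' @param missing_rate Probability that an individual fragment ion drops
#'   out of the observed spectrum.
#' @param charges Precursor charge states sampled uniformly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_precursors = 300, peptide_length = c(7, 14),
                       glycan_size = c(7, 12),
                       class_mix = c(complex = 0.6, hybrid = 0.2,
                                     high_mannose = 0.2),
                       p_core_fucose = 0.3, p_bisecting = 0.2,
                       lambda_branch = 0.4, lambda_core = 1.2,
                       oxonium_boost = 5,
                       ratio_mean = 0.25, ratio_conc = 20,
                       noise_cv = 0.10, missing_rate = 0.05,
                       charges = 2:4) {
  stopifnot(lambda_branch > 0, lambda_core > 0, noise_cv >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "sim_config")
}

## Amino acids without N (sequon placement is explicit)
.sim_aa_pool <- c("A", "D", "E", "F", "G", "H", "I", "L", "M", "P", "Q",
                  "S", "T", "V", "W", "Y")

.sim_peptide <- function(config) {
  L <- sample(seq(config$peptide_length[1], config$peptide_length[2]), 1)
  aa <- sample(.sim_aa_pool, L, replace = TRUE)
  site <- sample(2:(L - 2), 1)
  aa[site] <- "N"
  aa[site + 2] <- sample(c("S", "T"), 1)
  aa[L] <- sample(c("K", "R"), 1) # tryptic-like C terminus
  list(peptide = paste(aa, collapse = ""), glycosite = site)
}

## Grow a random N-glycan on the chitobiose + trimannosyl core.
.sim_glycan <- function(config) {
  cls <- sample(names(config$class_mix), 1, prob = config$class_mix)
  code <- c("N", "N", "H", "H", "H")
  parent <- c(NA, 1L, 2L, 3L, 3L)
  add <- function(sym, par) {
    code <<- c(code, sym)
    parent <<- c(parent, par)
    length(code)
  }
  if (stats::runif(1) < config$p_core_fucose) add("F", 1L)
  if (cls != "high_mannose" && stats::runif(1) < config$p_bisecting) {
    add("N", 3L)
  }
  target <- sample(seq(config$glycan_size[1], config$glycan_size[2]), 1)
  arms <- c(4L, 5L)
  grow_branch <- function(arm) {
    # complex-type antenna: GlcNAc, optionally extended by Gal and NeuAc
    b <- add("N", arm)
    if (length(code) < target && stats::runif(1) < 0.7) {
      h <- add("H", b)
      if (length(code) < target && stats::runif(1) < 0.4) add("A", h)
    }
  }
  grow_mannose <- function(arm) {
    h <- add("H", arm)
    if (length(code) < target && stats::runif(1) < 0.5) add("H", h)
  }
  if (cls == "high_mannose") {
    while (length(code) < target) grow_mannose(sample(arms, 1))
  } else if (cls == "complex") {
    grow_branch(arms[1])
    grow_branch(arms[2])
    while (length(code) < target) grow_branch(sample(arms, 1))
  } else { # hybrid: one oligomannose arm, one complex arm
    grow_mannose(arms[1])
    grow_branch(arms[2])
    while (length(code) < target) {
      if (stats::runif(1) < 0.5) grow_mannose(arms[1])
      else grow_branch(arms[2])
    }
  }
  glycan_tree(code, parent)
}

#' Simulate glycopeptide precursors
#'
#' Random tryptic-like peptides (C-terminal K/R) with one N-X-S/T sequon
#' and random N-glycans grown on the canonical core, at charges 2-4.
#' All glycans carry the HexNAc-HexNAc-Hex core, so [detect_core()]
#' classifies every simulated structure.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return List of [glycopeptide()] objects.
#' @export
simulate_precursors <- function(config = sim_config(), seed = 1L) {
  withr::with_seed(seed, {
    lapply(seq_len(config$n_precursors), function(i) {
      pep <- .sim_peptide(config)
      glycopeptide(pep$peptide, .sim_glycan(config), pep$glycosite,
                   sample(config$charges, 1))
    })
  })
}

## Edge classification for the intensity rule: edges with both endpoints
## in the core (and the peptide attachment) are "core" cleavages.
.cleavage_lambda <- function(site, core, config) {
  if (site$kind == "root_attachment") return(config$lambda_core)
  if (site$parent %in% core$core_nodes && site$child %in% core$core_nodes) {
    config$lambda_core
  } else if (site$parent %in% core$core_nodes &&
             site$child %in% core$branch_roots) {
    config$lambda_branch # antenna falling off an arm mannose
  } else if (site$parent %in% core$core_nodes) {
    config$lambda_core # core decorations (fucose, bisecting HexNAc)
  } else {
    config$lambda_branch
  }
}

.node_depths <- function(tree) {
  depth <- integer(length(tree$code))
  for (v in seq_along(tree$code)) {
    d <- 0L; u <- v
    while (!is.na(tree$parent[u])) { u <- tree$parent[u]; d <- d + 1L }
    depth[v] <- d
  }
  depth
}

## Charge distribution of Y ions across 1-3, by precursor charge.
.y_charge_profile <- function(z) {
  if (z <= 2) c(0.7, 0.3, 0)
  else if (z == 3) c(0.5, 0.4, 0.1)
  else c(0.3, 0.45, 0.25)
}

#' Simulate the fragment spectrum of one precursor
#'
#' Ground truth: Y structure fragments receive
#' `exp(-sum(lambda))` over their boundary cleavages (core cleavages less
#' likely than branch cleavages), summed per composition and spread over
#' charges 1-3 by a precursor-charge-dependent profile; B fragments decay
#' with the depth of their shallowest node with an oxonium boost for mono-
#' and disaccharides; peptide b/y ions follow a smooth positional profile
#' with 70/20/10% of each channel on the naked/HexNAc/cross-ring variant;
#' parts are combined with a Beta-distributed peptide fraction. The
#' observed copy applies multiplicative log-normal noise and random ion
#' dropout.
#'
#' @param gp A [glycopeptide()].
#' @param config A [sim_config()].
#' @param with_B Simulate B ions (only effective for complex/hybrid
#'   glycans).
#' @return List with `truth` and `observed` `annotated_spectrum` objects.
#' @export
simulate_spectrum <- function(gp, config = sim_config(), with_B = TRUE) {
  core <- detect_core(gp$glycan)
  graph <- build_fragmentation_graph(gp$glycan, with_B = with_B)
  theo <- theoretical_fragments(gp, with_B = with_B, graph = graph)
  theo$intensity <- 0

  lam <- vapply(graph$cleavages, .cleavage_lambda, numeric(1),
                core = core, config = config)
  depth <- .node_depths(gp$glycan)

  ## glycan Y part
  zprof <- .y_charge_profile(gp$charge)
  frag_int <- vapply(seq_along(graph$fragments), function(j) {
    fr <- graph$fragments[[j]]
    if (fr$ion_class == "Y") {
      exp(-sum(lam[fr$cleavages]))
    } else {
      base <- exp(-config$lambda_branch * min(depth[fr$retained]))
      if (length(fr$retained) <= 2) base * config$oxonium_boost else base
    }
  }, numeric(1))
  for (gi in seq_len(nrow(graph$groups))) {
    grp <- graph$groups[gi, ]
    tot <- sum(frag_int[grp$members[[1]]])
    if (grp$ion_class == "Y") {
      for (z in 1:3) {
        sel <- which(theo$part == "Y" & theo$comp %in% grp$comp &
                       theo$charge == z)
        theo$intensity[sel] <- tot * zprof[z]
      }
    } else {
      sel <- which(theo$part == "B" & theo$comp %in% grp$comp)
      theo$intensity[sel] <- tot
    }
  }

  ## peptide part: smooth positional profile
  L <- nchar(gp$peptide)
  pos <- seq_len(L - 1)
  prof <- exp(-((pos - L / 2)^2) / (2 * (L / 4)^2))
  z2_share <- if (gp$charge >= 3) 0.3 else 0.1
  variant_share <- c(b = 0.7, bN1 = 0.2, bX = 0.1,
                     y = 0.7, yN1 = 0.2, yX = 0.1)
  pt <- theo$part == "pep"
  for (k in which(pt)) {
    base <- prof[theo$pos[k]] *
      (if (grepl("^b", theo$series[k])) 0.6 else 1.0)
    base <- base * (if (theo$charge[k] == 2) z2_share else 1.0)
    theo$intensity[k] <- base * variant_share[[theo$series[k]]]
  }

  ## combine parts with the peptide fraction
  r <- stats::rbeta(1, config$ratio_mean * config$ratio_conc,
                    (1 - config$ratio_mean) * config$ratio_conc)
  sp <- sum(theo$intensity[pt])
  sg <- sum(theo$intensity[!pt])
  theo$intensity[pt] <- theo$intensity[pt] / sp * r
  theo$intensity[!pt] <- theo$intensity[!pt] / sg * (1 - r)

  truth <- .new_annotated(gp, theo, with_B)

  obs <- theo
  nz <- obs$intensity > 0
  sigma <- sqrt(log(1 + config$noise_cv^2))
  noise <- exp(stats::rnorm(sum(nz), -sigma^2 / 2, sigma))
  keep <- stats::runif(sum(nz)) >= config$missing_rate
  obs$intensity[nz] <- obs$intensity[nz] * noise * keep
  observed <- .new_annotated(gp, obs, with_B)

  list(truth = truth, observed = observed,
       structure_intensities = frag_int, graph = graph)
}

#' Generate a complete simulated dataset
#'
#' Simulates precursors and spectra, applies the standard spectrum
#' filters, and packages everything with a manifest (seed + configuration)
#' from which the dataset regenerates bit-identically.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @param with_B Simulate and require B ions where the glycan class
#'   provides them (the B filter is applied only to complex/hybrid
#'   precursors).
#' @return List with `spectra` (observed, filtered), `truth` (aligned
#'   noiseless spectra) and `manifest`.
#' @export
generate_dataset <- function(config = sim_config(), seed = 1L,
                             with_B = FALSE) {
  precursors <- simulate_precursors(config, seed = seed)
  sims <- withr::with_seed(seed + 1L, {
    lapply(precursors, simulate_spectrum, config = config,
           with_B = with_B)
  })
  keep <- vapply(sims, function(s) {
    req_b <- with_B &&
      detect_core(s$observed$precursor$glycan)$glycan_class %in%
        c("complex", "hybrid")
    passes_filters(s$observed, require_B = req_b)
  }, logical(1))
  sims <- sims[keep]
  manifest <- c(list(seed = seed, with_B = with_B),
                lapply(unclass(config), function(x) x))
  list(spectra = lapply(sims, `[[`, "observed"),
       truth = lapply(sims, `[[`, "truth"),
       manifest = manifest)
}
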