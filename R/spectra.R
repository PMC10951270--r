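#' Construct a peak-list spectrum
#'
#' @param mz,intensity Numeric vectors of equal length; peaks are stored
#'   sorted by m/z, intensities must be non-negative.
#' @param precursor_mz,precursor_charge Optional precursor information.
#' @param title,run,scan,ce Optional metadata.
#' @return A `spectrum` object wrapping a peak tibble.
#' @export
spectrum <- function(mz, intensity, precursor_mz = NA_real_,
                     precursor_charge = NA_integer_, title = "",
                     run = "", scan = NA_integer_, ce = "") {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  ord <- order(mz)
  structure(
    list(peaks = tibble::tibble(mz = mz[ord], intensity = intensity[ord]),
         precursor_mz = precursor_mz,
         precursor_charge = as.integer(precursor_charge),
         title = title, run = run, scan = as.integer(scan), ce = ce),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> ", nrow(x$peaks), " peaks",
      if (!is.na(x$precursor_mz))
        paste0(", precursor ", round(x$precursor_mz, 4), " (",
               x$precursor_charge, "+)"),
      if (nzchar(x$title)) paste0(", '", x$title, "'"), "\n", sep = "")
  invisible(x)
}

#' Read / write MGF peak lists
#'
#' Minimal Mascot Generic Format support: `BEGIN IONS`/`END IONS` blocks
#' with `PEPMASS`, `CHARGE`, `TITLE`, optional `RTINSECONDS`, and one
#' `m/z intensity` pair per line.
#'
#' @param path File path.
#' @return `read_mgf()`: list of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      meta <- list(pepmass = NA_real_, charge = NA_integer_, title = "")
      mzs <- numeric(0); ints <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (grepl("^PEPMASS=", ln)) {
          meta$pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln),
                                              "\\s+")[[1]][1])
        } else if (grepl("^CHARGE=", ln)) {
          meta$charge <- as.integer(gsub("[^0-9]", "",
                                         sub("^CHARGE=", "", ln)))
        } else if (grepl("^TITLE=", ln)) {
          meta$title <- sub("^TITLE=", "", ln)
        } else if (grepl("^[0-9]", ln)) {
          xy <- as.numeric(strsplit(ln, "[\\s\t]+", perl = TRUE)[[1]][1:2])
          mzs <- c(mzs, xy[1]); ints <- c(ints, xy[2])
        }
        i <- i + 1L
      }
      out[[length(out) + 1L]] <- spectrum(
        mzs, ints, precursor_mz = meta$pepmass,
        precursor_charge = meta$charge, title = meta$title
      )
    }
    i <- i + 1L
  }
  out
}

#' @rdname read_mgf
#' @param spectra List of [spectrum()] objects.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (nzchar(sp$title)) writeLines(paste0("TITLE=", sp$title), con)
    if (!is.na(sp$precursor_mz)) {
      writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    }
    if (!is.na(sp$precursor_charge)) {
      writeLines(paste0("CHARGE=", sp$precursor_charge, "+"), con)
    }
    writeLines(sprintf("%.6f %.6g", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

## ---- annotated spectra ----------------------------------------------

.count_matched <- function(frag_tab) {
  c(pep = sum(frag_tab$part == "pep" & frag_tab$intensity > 0),
    Y = sum(frag_tab$part == "Y" & frag_tab$intensity > 0),
    B = sum(frag_tab$part == "B" & frag_tab$intensity > 0))
}

.new_annotated <- function(gp, frag_tab, with_B) {
  pep_sum <- sum(frag_tab$intensity[frag_tab$part == "pep"])
  tot <- sum(frag_tab$intensity)
  structure(
    list(precursor = gp, fragments = frag_tab, with_B = with_B,
         counts = .count_matched(frag_tab),
         ratio = if (tot > 0) pep_sum / tot else NA_real_),
    class = "annotated_spectrum"
  )
}

#' @export
print.annotated_spectrum <- function(x, ...) {
  cat("<annotated_spectrum> ", precursor_id(x$precursor), "\n  matched: ",
      x$counts[["pep"]], " peptide / ", x$counts[["Y"]], " Y / ",
      x$counts[["B"]], " B ions; peptide fraction ",
      round(x$ratio, 3), "\n", sep = "")
  invisible(x)
}

#' Annotate a spectrum against a glycopeptide's theoretical fragments
#'
#' Each theoretical fragment receives the intensity of the closest peak
#' within the ppm tolerance (zero if none); when several fragments claim
#' the same peak, the fragment with the smallest m/z error keeps it and the
#' others get zero, so a peak contributes to at most one fragment.
#'
#' @param spec A [spectrum()].
#' @param gp The [glycopeptide()] the spectrum is attributed to.
#' @param tol_ppm Matching tolerance in parts per million (default 20).
#' @param with_B Include B ions in the theoretical index.
#' @return An `annotated_spectrum`: the theoretical fragment table with an
#'   `intensity` column, matched-ion counts per class and the observed
#'   peptide intensity fraction.
#' @export
match_peaks <- function(spec, gp, tol_ppm = 20, with_B = FALSE) {
  stopifnot(tol_ppm > 0)
  theo <- theoretical_fragments(gp, with_B = with_B)
  theo$intensity <- 0
  pk <- spec$peaks
  if (nrow(pk) > 0) {
    nearest <- findInterval(theo$mz, pk$mz)
    lo <- pmax(nearest, 1L)
    hi <- pmin(nearest + 1L, nrow(pk))
    d_lo <- abs(theo$mz - pk$mz[lo])
    d_hi <- abs(theo$mz - pk$mz[hi])
    peak_idx <- ifelse(d_lo <= d_hi, lo, hi)
    err <- abs(theo$mz - pk$mz[peak_idx])
    ok <- err / theo$mz * 1e6 <= tol_ppm
    # resolve peak contention: smallest absolute error wins
    keep <- rep(FALSE, nrow(theo))
    for (p in unique(peak_idx[ok])) {
      cand <- which(ok & peak_idx == p)
      keep[cand[which.min(err[cand])]] <- TRUE
    }
    theo$intensity[keep] <- pk$intensity[peak_idx[keep]]
  }
  .new_annotated(gp, theo, with_B)
}

#' Merge low- and high-energy spectra into a pseudo stepped-CE spectrum
#'
#' For instruments acquiring individual collision energies, the two
#' annotated spectra of one precursor are merged by averaging the aligned
#' fragment intensities.
#'
#' @param low,high `annotated_spectrum` objects of the same precursor.
#' @return An `annotated_spectrum` with element-wise mean intensities.
#' @export
merge_stepped_ce <- function(low, high) {
  if (!identical(precursor_id(low$precursor),
                 precursor_id(high$precursor))) {
    stop("cannot merge spectra of different precursors")
  }
  stopifnot(nrow(low$fragments) == nrow(high$fragments))
  merged <- low$fragments
  merged$intensity <- (low$fragments$intensity +
                         high$fragments$intensity) / 2
  .new_annotated(low$precursor, merged, low$with_B)
}

#' Build a consensus spectrum from replicate annotated spectra
#'
#' Each replicate is normalized to unit total intensity within each part
#' (peptide, Y, B) and the normalized vectors are averaged element-wise.
#' The consensus peptide-fraction ratio is the mean of the replicate
#' ratios. The result is invariant to replicate order and to per-replicate
#' global scaling.
#'
#' @param replicates Non-empty list of `annotated_spectrum` objects of one
#'   precursor.
#' @return A consensus `annotated_spectrum`.
#' @export
build_consensus <- function(replicates) {
  if (length(replicates) == 0L) stop("no replicate spectra supplied")
  ids <- vapply(replicates, function(a) precursor_id(a$precursor),
                character(1))
  if (length(unique(ids)) != 1L) {
    stop("replicates must share one precursor")
  }
  ref <- replicates[[1]]
  acc <- numeric(nrow(ref$fragments))
  ratios <- numeric(0)
  for (a in replicates) {
    v <- a$fragments$intensity
    for (p in unique(ref$fragments$part)) {
      sel <- ref$fragments$part == p
      s <- sum(v[sel])
      if (s > 0) v[sel] <- v[sel] / s
    }
    acc <- acc + v
    ratios <- c(ratios, a$ratio)
  }
  out <- ref$fragments
  out$intensity <- acc / length(replicates)
  ann <- .new_annotated(ref$precursor, out, ref$with_B)
  ann$ratio <- mean(ratios, na.rm = TRUE)
  ann
}

#' Dataset quality filters
#'
#' A spectrum is kept when it has at least 5 matched peptide b/y ions and
#' at least 5 matched glycan Y ions; the branch-fragment model additionally
#' requires at least 2 matched B ions.
#'
#' @param ann An `annotated_spectrum`.
#' @param require_B Apply the B-ion filter.
#' @return Logical.
#' @export
passes_filters <- function(ann, require_B = FALSE) {
  ok <- ann$counts[["pep"]] >= 5 && ann$counts[["Y"]] >= 5
  if (require_B) ok <- ok && ann$counts[["B"]] >= 2
  ok
}

## ---- model-index intensity vectors ----------------------------------

#' Collapse an annotated spectrum onto the model's output index
#'
#' The model predicts 4 peptide channels per backbone cleavage (b and y at
#' charges 1-2): intensities of the HexNAc-carrying and cross-ring variants
#' are summed into their parent b/y channel. Y intensities are indexed by
#' composition and charge 1-3; B intensities by composition at charge 1.
#'
#' @param ann An `annotated_spectrum`.
#' @return List with `pep` (matrix cleavages x 4, columns b1+, b2+, y1+,
#'   y2+), `Y` (matrix compositions x 3), `B` (numeric vector, possibly
#'   length 0), `ratio`, plus the composition indices.
#' @export
spectrum_parts <- function(ann) {
  ft <- ann$fragments
  L1 <- max(ft$pos, na.rm = TRUE) # number of backbone cleavages
  pep <- matrix(0, L1, 4,
                dimnames = list(NULL, c("b1", "b2", "y1", "y2")))
  pt <- ft[ft$part == "pep", ]
  col <- paste0(ifelse(grepl("^b", pt$series), "b", "y"), pt$charge)
  for (k in seq_len(nrow(pt))) {
    pep[pt$pos[k], col[k]] <- pep[pt$pos[k], col[k]] + pt$intensity[k]
  }
  yt <- ft[ft$part == "Y", ]
  ycomp <- unique(yt$comp)
  Y <- matrix(0, length(ycomp), 3, dimnames = list(ycomp, NULL))
  Y[cbind(match(yt$comp, ycomp), yt$charge)] <- yt$intensity
  bt <- ft[ft$part == "B", ]
  B <- bt$intensity
  names(B) <- bt$comp
  list(pep = pep, Y = Y, B = B, ratio = ann$ratio,
       y_comp = ycomp, b_comp = bt$comp)
}

## ---- tabular dataset I/O --------------------------------------------

#' Write / read a spectral dataset as plain-text tables
#'
#' A dataset directory holds `precursors.tsv` (one row per precursor),
#' `spectra.tsv` (one row per theoretical fragment with its matched
#' intensity) and `manifest.json` (generator configuration and seed, when
#' the dataset came from the simulator).
#'
#' @param dataset A list with elements `spectra` (list of
#'   `annotated_spectrum`) and optional `manifest`.
#' @param dir Directory path (created if needed).
#' @return `dir` (write) or the dataset list (read).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prec <- purrr::map_dfr(dataset$spectra, function(a) {
    gp <- a$precursor
    tibble::tibble(
      id = precursor_id(gp), peptide = gp$peptide,
      mods = if (nrow(gp$mods)) paste0(gp$mods$pos, ":", gp$mods$formula,
                                       collapse = ",") else "",
      glycosite = gp$glycosite,
      glycan_struct = glycan_canonical(gp$glycan),
      charge = gp$charge, ratio = a$ratio, with_B = a$with_B
    )
  })
  utils::write.table(prec, file.path(dir, "precursors.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  frags <- purrr::map_dfr(seq_along(dataset$spectra), function(i) {
    a <- dataset$spectra[[i]]
    cbind(tibble::tibble(id = precursor_id(a$precursor)), a$fragments)
  })
  utils::write.table(frags, file.path(dir, "spectra.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$manifest)) {
    jsonlite::write_json(dataset$manifest,
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  prec <- utils::read.table(file.path(dir, "precursors.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  prec$mods <- as.character(prec$mods)
  prec$mods[is.na(prec$mods)] <- ""
  frags <- utils::read.table(file.path(dir, "spectra.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             na.strings = "NA")
  frags$comp[is.na(frags$comp)] <- NA_character_
  spectra <- lapply(seq_len(nrow(prec)), function(i) {
    p <- prec[i, ]
    mods <- NULL
    if (nzchar(p$mods)) {
      kv <- strsplit(strsplit(p$mods, ",")[[1]], ":")
      mods <- tibble::tibble(pos = as.integer(vapply(kv, `[`, "", 1)),
                             formula = vapply(kv, `[`, "", 2))
    }
    gp <- glycopeptide(p$peptide, p$glycan_struct, p$glycosite, p$charge,
                       mods = mods)
    ft <- tibble::as_tibble(frags[frags$id == p$id,
                                  c("part", "series", "pos", "comp",
                                    "charge", "mz", "intensity")])
    # Y0 renders as an empty string; read.table turns it into NA
    ft$comp[ft$part != "pep" & is.na(ft$comp)] <- ""
    ann <- .new_annotated(gp, ft, isTRUE(p$with_B))
    ann$ratio <- p$ratio
    ann
  })
  manifest <- NULL
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) manifest <- jsonlite::read_json(mf)
  list(spectra = spectra, manifest = manifest)
}
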