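## Kyte-Doolittle hydropathy, used only for the retention-time proxy.
.kd_hydropathy <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Linear retention-time proxy
#'
#' Sum of Kyte-Doolittle hydropathies of the peptide, linearly rescaled.
#' A clearly tagged stand-in used when no experimental retention times are
#' supplied (the package does not model retention time).
#'
#' @param peptide Peptide string.
#' @return Proxy retention time (arbitrary units).
#' @export
rt_proxy <- function(peptide) {
  vapply(strsplit(peptide, ""), function(aa)
    10 + 2 * sum(.kd_hydropathy[aa]), numeric(1))
}

#' Build a predicted spectral library
#'
#' One entry per precursor: predicted fragment intensities (normalized to
#' maximum 1 per entry), the top-N most intense fragments retained, plus a
#' retention time. In `PredMS2` mode the retention times come from the
#' supplied table (experimental values are preserved exactly); in
#' `PredLib` mode the hydropathy proxy is used.
#'
#' @param precursors List of [glycopeptide()] objects.
#' @param model A trained `glyco_model`.
#' @param rt Optional tibble with columns `precursor` (id) and `rt`;
#'   required for `mode = "PredMS2"`.
#' @param mode `"PredMS2"` (experimental RT) or `"PredLib"` (proxy RT).
#' @param top_n Fragments kept per entry (by intensity; default 20).
#' @return A `glyco_library` tibble, one row per fragment: precursor
#'   columns (`precursor`, `peptide`, `mods`, `glycosite`,
#'   `glycan_struct`, `glycan_comp`, `precursor_charge`, `precursor_mz`,
#'   `rt`, `provenance`) and fragment columns (`part`, `series`, `pos`,
#'   `comp`, `charge`, `mz`, `intensity`).
#' @export
build_library <- function(precursors, model, rt = NULL,
                          mode = c("PredMS2", "PredLib"), top_n = 20) {
  mode <- match.arg(mode)
  if (mode == "PredMS2" && is.null(rt)) {
    stop("PredMS2 mode requires an experimental retention-time table")
  }
  skipped <- 0L
  entries <- purrr::map(precursors, function(gp) {
    tab <- tryCatch(predict(model, gp), error = function(e) NULL)
    if (is.null(tab)) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    tab <- tab[tab$intensity > 0, ]
    tab <- tab[order(-tab$intensity), ]
    tab <- tab[seq_len(min(top_n, nrow(tab))), ]
    tab$intensity <- tab$intensity / max(tab$intensity)
    id <- precursor_id(gp)
    this_rt <- if (mode == "PredMS2") {
      v <- rt$rt[match(id, rt$precursor)]
      if (is.na(v)) {
        skipped <<- skipped + 1L
        return(NULL)
      }
      v
    } else {
      rt_proxy(gp$peptide)
    }
    tibble::tibble(
      precursor = id, peptide = gp$peptide,
      mods = if (nrow(gp$mods)) paste0(gp$mods$pos, ":",
                                       gp$mods$formula, collapse = ",")
             else "",
      glycosite = gp$glycosite,
      glycan_struct = glycan_canonical(gp$glycan),
      glycan_comp = format_composition(glycan_composition(gp$glycan)),
      precursor_charge = gp$charge, precursor_mz = precursor_mz(gp),
      rt = this_rt, provenance = "predicted",
      part = tab$part, series = tab$series, pos = tab$pos,
      comp = tab$comp, charge = tab$charge, mz = tab$mz,
      intensity = tab$intensity
    )
  })
  out <- dplyr::bind_rows(entries)
  attr(out, "skipped") <- skipped
  class(out) <- c("glyco_library", class(out))
  out
}

#' Generate entrapment entries for a predicted library
#'
#' Entrapment glycopeptides gauge false-positive rates: they must be
#' absent from the sample, so every entrapment glycan has a
#' monosaccharide composition that does not occur anywhere in the original
#' library. One entrapment precursor is generated per library precursor
#' (keeping peptide, charge and retention time) by swapping its glycan for
#' a foreign-composition structure from the glycan space, so the
#' entrapment entry count matches the library within the +-10% contract.
#'
#' @param library A `glyco_library` from [build_library()].
#' @param space List of [glycan_tree()] objects to draw foreign glycans
#'   from.
#' @param model The `glyco_model` used to predict entrapment spectra.
#' @param seed RNG seed.
#' @param top_n Passed to [build_library()].
#' @return A `glyco_library` of entrapment entries with
#'   `provenance = "entrapment"`.
#' @export
generate_entrapment <- function(library, space, model, seed = 1L,
                                top_n = 20) {
  lib_prec <- dplyr::distinct(
    tibble::as_tibble(library[, c("precursor", "peptide", "mods",
                                  "glycosite", "precursor_charge",
                                  "rt", "glycan_comp")])
  )
  lib_comps <- unique(library$glycan_comp)
  foreign <- Filter(function(g) {
    !(format_composition(glycan_composition(g)) %in% lib_comps)
  }, space)
  if (length(foreign) == 0) {
    stop("glycan space contains no structures with compositions outside ",
         "the library (achievable entrapment entries: 0)")
  }
  swapped <- withr::with_seed(seed, {
    lapply(seq_len(nrow(lib_prec)), function(i) {
      p <- lib_prec[i, ]
      g <- foreign[[sample(length(foreign), 1)]]
      mods <- NULL
      if (nzchar(p$mods)) {
        kv <- strsplit(strsplit(p$mods, ",")[[1]], ":")
        mods <- tibble::tibble(pos = as.integer(vapply(kv, `[`, "", 1)),
                               formula = vapply(kv, `[`, "", 2))
      }
      glycopeptide(p$peptide, g, p$glycosite, p$precursor_charge,
                   mods = mods)
    })
  })
  rt_tab <- tibble::tibble(
    precursor = vapply(swapped, precursor_id, character(1)),
    rt = lib_prec$rt
  )
  out <- build_library(swapped, model, rt = rt_tab, mode = "PredMS2",
                       top_n = top_n)
  out$provenance <- "entrapment"
  if (length(intersect(unique(out$glycan_comp), lib_comps)) > 0) {
    stop("internal error: entrapment compositions overlap the library")
  }
  out
}

#' Read / write spectral libraries
#'
#' Flat TSV, one fragment per row, with the column schema of
#' [build_library()].
#'
#' @param library A `glyco_library`.
#' @param path File path.
#' @return `write_library()`: `path` invisibly; `read_library()`: a
#'   `glyco_library` tibble.
#' @export
write_library <- function(library, path) {
  utils::write.table(library, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = "NA",
                         colClasses = NA, check.names = FALSE)
  x <- tibble::as_tibble(x)
  x$pos <- suppressWarnings(as.integer(x$pos))
  x$comp <- as.character(x$comp)
  x$comp[x$part == "pep"] <- NA_character_
  x$comp[x$part != "pep" & is.na(x$comp)] <- ""
  x$mods <- as.character(x$mods)
  x$mods[is.na(x$mods)] <- ""
  class(x) <- c("glyco_library", class(x))
  x
}
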