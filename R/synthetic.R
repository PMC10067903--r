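# Compound parameter library and synthetic-data generators.
#
# The shipped library transcribes the hERG binding parameters of the 12
# reference compounds of the published state-dependent block model (the
# CiPA training set fitted by Li et al. 2017). The dofetilide entry is the
# trapped "example drug T", the verapamil entry the non-trapped "example
# drug N". EC50 is stored in nM as halfmax^(1/n) of the original
# parameterisation, so that binding uses D^n / (D^n + EC50^n).

#' Load a compound parameter library
#'
#' Reads a CSV with columns `drug`, `Kmax`, `Ku`, `n`, `EC50`,
#' `Vhalf_trap` (and optionally `provenance`) and returns a validated
#' library with per-parameter min/max ranges (used by the virtual-drug
#' sweep).
#'
#' @param path CSV path; defaults to the 12-compound library shipped with
#'   the package.
#' @return An object of class `drug_library`: a named list of
#'   [drug_params()] with attributes `ranges` (min/max per parameter) and
#'   `provenance`.
#' @export
#' @examples
#' lib <- load_drug_library()
#' names(lib)
#' attr(lib, "ranges")
load_drug_library <- function(path = system.file("extdata", "drug_library.csv",
                                                 package = "hergblock")) {
  if (!nzchar(path) || !file.exists(path))
    stop("drug library file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "Kmax", "Ku", "n", "EC50", "Vhalf_trap")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("drug library is missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(tab[need]))
    stop("drug library contains missing values")
  lib <- lapply(seq_len(nrow(tab)), function(i)
    drug_params(Kmax = tab$Kmax[i], Ku = tab$Ku[i], n = tab$n[i],
                EC50 = tab$EC50[i], Vhalf_trap = tab$Vhalf_trap[i],
                name = tab$drug[i]))
  names(lib) <- tab$drug
  ranges <- sapply(c("Kmax", "Ku", "n", "EC50", "Vhalf_trap"),
                   function(p) range(vapply(lib, `[[`, numeric(1), p)))
  rownames(ranges) <- c("min", "max")
  structure(lib, ranges = ranges,
            provenance = if ("provenance" %in% names(tab)) tab$provenance
                         else rep(NA_character_, nrow(tab)),
            class = c("drug_library", "list"))
}

#' @export
print.drug_library <- function(x, ...) {
  cat(sprintf("hERG compound library: %d entries\n", length(x)))
  cat(" ", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Write a compound library back to CSV
#'
#' Inverse of [load_drug_library()]; the round trip is lossless.
#'
#' @param lib A `drug_library`.
#' @param path Output CSV path.
#' @export
write_drug_library <- function(lib, path) {
  stopifnot(inherits(lib, "drug_library"))
  tab <- data.frame(
    drug = names(lib),
    Kmax = vapply(lib, `[[`, numeric(1), "Kmax"),
    Ku = vapply(lib, `[[`, numeric(1), "Ku"),
    n = vapply(lib, `[[`, numeric(1), "n"),
    EC50 = vapply(lib, `[[`, numeric(1), "EC50"),
    Vhalf_trap = vapply(lib, `[[`, numeric(1), "Vhalf_trap"),
    provenance = attr(lib, "provenance"))
  utils::write.csv(format(tab, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Fetch a compound from the library, honouring the example-drug aliases
#'
#' `"example drug T"` (or `"T"`) maps to the dofetilide parameterisation
#' (trapped), `"example drug N"` (or `"N"`) to the verapamil one
#' (non-trapped).
#'
#' @param lib A `drug_library` (default: the shipped one).
#' @param name Compound name or alias.
#' @return A [drug_params()] object.
#' @export
get_drug <- function(name, lib = load_drug_library()) {
  key <- tolower(trimws(name))
  if (key %in% c("t", "example drug t", "drug t")) key <- "dofetilide"
  if (key %in% c("n", "example drug n", "drug n")) key <- "verapamil"
  hit <- match(key, tolower(names(lib)))
  if (is.na(hit))
    stop("unknown compound: ", name, " (available: ",
         paste(names(lib), collapse = ", "), ")")
  lib[[hit]]
}

#' A virtual drug: a point in (Vhalf_trap, Kmax, Ku) space
#'
#' Virtual drugs parameterise the simplified state-dependent model used in
#' the sensitivity sweep: concentration is expressed in units of EC50
#' (normalised concentration), and the Hill coefficient is fixed at 1.
#'
#' @param Vhalf_trap,Kmax,Ku The three free parameters.
#' @param n Hill coefficient (fixed at 1 for the sweep).
#' @return A [drug_params()] object with `EC50 = 1` (so concentration is
#'   the normalised concentration) and a descriptive name.
#' @export
virtual_drug <- function(Vhalf_trap, Kmax, Ku, n = 1) {
  drug_params(Kmax = Kmax, Ku = Ku, n = n, EC50 = 1,
              Vhalf_trap = Vhalf_trap,
              name = sprintf("virtual(Vhalf=%.3g,Kmax=%.3g,Ku=%.3g)",
                             Vhalf_trap, Kmax, Ku))
}

#' Sample virtual drugs from library-derived parameter ranges
#'
#' Draws `count` virtual drugs with `Kmax` and `Ku` log-uniform and
#' `Vhalf_trap` uniform over the given ranges (by default the min/max of
#' the 12-compound library), reproducibly under a fixed seed.
#'
#' @param count Number of virtual drugs (>= 0).
#' @param ranges A 2-row min/max matrix as in `attr(lib, "ranges")`.
#' @param seed Integer seed.
#' @return A list of [virtual_drug()] objects.
#' @export
sample_virtual_drugs <- function(count, ranges = NULL, seed = 1L) {
  if (is.null(ranges)) ranges <- attr(load_drug_library(), "ranges")
  for (p in c("Kmax", "Ku", "Vhalf_trap")) {
    rg <- ranges[, p]
    if (!all(is.finite(rg)) || rg[1] > rg[2] ||
        (p != "Vhalf_trap" && rg[1] <= 0))
      stop("invalid range for ", p)
    if (rg[1] == rg[2]) stop("empty (degenerate) range for ", p)
  }
  if (count < 0) stop("count must be >= 0")
  if (count == 0) return(list())
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km <- exp(stats::runif(count, log(ranges["min", "Kmax"]),
                         log(ranges["max", "Kmax"])))
  ku <- exp(stats::runif(count, log(ranges["min", "Ku"]),
                         log(ranges["max", "Ku"])))
  vh <- stats::runif(count, ranges["min", "Vhalf_trap"],
                     ranges["max", "Vhalf_trap"])
  lapply(seq_len(count), function(i) virtual_drug(vh[i], km[i], ku[i]))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate noisy Hill-shaped dose-response data
#'
#' Synthetic-data oracle for the Hill-fitting stage: responses
#' `IC50^h / (IC50^h + D^h)` plus Gaussian noise, clipped to `[0, 1.05]`.
#'
#' @param h Hill coefficient.
#' @param IC50 Half-inhibitory concentration (nM).
#' @param concs Concentrations (nM), strictly increasing.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return A `dose_response` data.frame (columns `conc`, `response`).
#' @export
#' @examples
#' dr <- generate_hill_data(1, 50, 10^seq(0, 4, length.out = 8))
#' fit <- fit_hill(dr)
#' coef(fit)
generate_hill_data <- function(h, IC50, concs, noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(h > 0, IC50 > 0, all(concs > 0), !is.unsorted(concs, strictly = TRUE))
  resp <- IC50^h / (IC50^h + concs^h)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    resp <- resp + stats::rnorm(length(concs), 0, noise_sd)
  }
  resp <- pmin(pmax(resp, 0), 1.05)
  structure(data.frame(conc = concs, response = resp),
            drug = "synthetic", protocol = "synthetic",
            class = c("dose_response", "data.frame"))
}
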