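#' Read a plain-text key-value parameter file
#'
#' Parameter sets ship as versioned text files (`key = value` lines, `#`
#' comments) under `inst/extdata/params/`. Values must parse as numbers.
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
read_param_file <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed line in ", path, ": ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  if (anyNA(vals)) stop("non-numeric value for key '", keys[is.na(vals)][1],
                        "' in ", path)
  stats::setNames(vals, keys)
}

param_dir <- function() system.file("extdata", "params", package = "cardalt")

#' Ionic model parameters for a transmural cell variant
#'
#' Loads the shared constants plus the variant-specific conductances
#' (`I_to` and `I_Ks` differ across endo/mid/epi; the endocardial variant also
#' uses slower recovery kinetics for the `s` inactivation gate). The shipped
#' set is the steep APD-restitution ("slope 1.8") parameterization.
#'
#' @param variant `"endo"`, `"mid"` or `"epi"`.
#' @param overrides optional named numeric vector overriding entries.
#' @return named numeric vector with attributes `cell_variant` and
#'   `restitution_variant`.
#' @export
ionic_params <- function(variant = c("endo", "mid", "epi"), overrides = NULL) {
  variant <- match.arg(variant)
  p <- c(read_param_file(file.path(param_dir(), "ionic_common_v1.txt")),
         read_param_file(file.path(param_dir(),
                                   sprintf("ionic_%s_v1.txt", variant))))
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be a named numeric vector")
    p[names(overrides)] <- overrides
  }
  must_pos <- c("Cm", "F", "Vc", "Vsr", "Vss", "Vmaxup", "Kup", "Vrel",
                "Vleak", "Vxfer", "GNa", "GK1", "Gto", "GKr", "GKs", "GCaL")
  bad <- must_pos[p[must_pos] <= 0]
  if (length(bad)) stop("ionic parameters must be strictly positive: ",
                        paste(bad, collapse = ", "))
  attr(p, "cell_variant") <- variant
  attr(p, "restitution_variant") <- "steep_slope_1.8"
  p
}

#' Myofilament mechanics parameters
#'
#' @param overrides optional named numeric vector overriding entries
#'   (e.g. `c(force_scale = 80)`).
#' @return named numeric vector.
#' @export
mech_params <- function(overrides = NULL) {
  p <- read_param_file(file.path(param_dir(), "mech_default_v1.txt"))
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be a named numeric vector")
    p[names(overrides)] <- overrides
  }
  if (any(p[c("fapp", "gapp", "hf", "hb", "gxb", "knp", "kpn", "kon",
              "koff")] < 0))
    stop("mechanics rate constants must be non-negative")
  if (p["SL0"] < p["SLmin"] || p["SL0"] > p["SLmax"])
    stop("SL0 must lie within [SLmin, SLmax]")
  p
}
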