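#' Van der Waals radius table
#'
#' Bondi-style van der Waals radii (Angstrom) used whenever a distance
#' criterion subtracts atomic size from a centre-to-centre distance.  The
#' table can be overridden entry-wise; elements absent from the table fall
#' back to `default` (carbon-like 1.7 A) unless `default = NA`, in which
#' case an unknown element is an error at assignment time.
#'
#' @param override named numeric vector of element -> radius (A) replacing or
#'   extending the built-in values.  Names are matched case-insensitively.
#' @param default fallback radius (A) for elements not in the table, or `NA`
#'   to forbid unknown elements.
#' @return named numeric vector of radii with attribute `default`.
#' @examples
#' vdw_radii()[c("C", "N", "CL")]
#' vdw_radii(override = c(C = 1.9))["C"]
#' @export
vdw_radii <- function(override = NULL, default = 1.7) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
           NA. = 2.27, K = 2.75, MG = 1.73, CA. = 2.31, ZN = 1.39, FE = 1.63)
  names(tab) <- sub("\\.$", "", names(tab))
  if (!is.null(override)) {
    if (is.null(names(override)) || any(!nzchar(names(override))))
      stop_ip("config_error", "radius override must be a named vector")
    tab[toupper(names(override))] <- as.numeric(override)
  }
  if (any(tab <= 0)) stop_ip("config_error", "vdW radii must be > 0")
  attr(tab, "default") <- default
  tab
}

# map element symbols to radii using a vdw_radii() table
assign_vdw <- function(elements, radius_table) {
  el <- toupper(elements)
  r <- unname(radius_table[el])
  if (anyNA(r)) {
    def <- attr(radius_table, "default")
    missing_el <- unique(el[is.na(r)])
    if (is.null(def) || is.na(def))
      stop_ip("config_error", "no vdW radius for element(s): %s",
              paste(missing_el, collapse = ", "))
    r[is.na(r)] <- def
  }
  r
}

# crude element inference from a PDB atom name when the element column is
# absent; two-letter ions and metals first, otherwise the first letter
guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CU")
  el <- substr(nm, 1, 1)
  hit <- substr(nm, 1, 2) %in% two & nchar(nm) <= 2
  el[hit] <- substr(nm[hit], 1, 2)
  # names like "1HB" start with a digit
  digit <- grepl("^[0-9]", el)
  el[digit] <- substr(sub("^[0-9]+", "", nm[digit]), 1, 1)
  el
}
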