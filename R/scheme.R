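## Rotamer taxonomy: which chi angles each residue type carries, and how each
## angle is discretised into bins. Only chi1 and chi2 are considered.

# chi-defining atom quadruples (IUPAC). chi2_kind controls the chi2 binning:
# "sp3" for tetrahedral branches (3 staggered bins), "flip" for aromatic
# rings and planar amide/acid groups (2 bins split at +/-90 deg).
.chi_defs <- list(
  VAL = list(chi1 = c("N", "CA", "CB", "CG1")),
  LEU = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG",  "CD1"), chi2_kind = "sp3"),
  ILE = list(chi1 = c("N", "CA", "CB", "CG1"), chi2 = c("CA", "CB", "CG1", "CD1"), chi2_kind = "sp3"),
  MET = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG",  "SD"),  chi2_kind = "sp3"),
  GLN = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG",  "CD"),  chi2_kind = "sp3"),
  GLU = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG",  "CD"),  chi2_kind = "sp3"),
  LYS = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG",  "CD"),  chi2_kind = "sp3"),
  ARG = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG",  "CD"),  chi2_kind = "sp3"),
  TRP = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG",  "CD1"), chi2_kind = "flip"),
  PHE = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG",  "CD1"), chi2_kind = "flip"),
  TYR = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG",  "CD1"), chi2_kind = "flip"),
  HIS = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG",  "ND1"), chi2_kind = "flip"),
  ASN = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG",  "OD1"), chi2_kind = "flip"),
  ASP = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG",  "OD1"), chi2_kind = "flip"),
  SER = list(chi1 = c("N", "CA", "CB", "OG")),
  THR = list(chi1 = c("N", "CA", "CB", "OG1")),
  CYS = list(chi1 = c("N", "CA", "CB", "SG"))
)

.excluded_restypes <- c("ALA", "GLY", "PRO")

.bin_sp3  <- list(edges = c(-120, 0, 120), labels = c("g-", "g+", "t"),
                  centers = c(-60, 60, 180))
.bin_flip <- list(edges = c(-90, 90), labels = c("0", "180"),
                  centers = c(0, 180))

#' Default rotamer-state discretisation scheme
#'
#' Bins chi1 into the three staggered wells g- (-120, 0], g+ (0, 120] and
#' t (120, 180] U (-180, -120]; chi2 likewise for sp3 branches, or into two
#' ring-flip bins split at +/-90 deg for aromatic rings and planar
#' amide/acid groups. A residue's state count is the product of its
#' per-angle bin counts: Val 3, Leu/Ile 9, Trp/Phe/Tyr/His/Asn/Asp 6,
#' Ser/Thr/Cys 3, Met/Gln/Glu/Lys/Arg 9 (chi3 and beyond are not
#' considered). Ala, Gly and Pro carry no discrete rotamer states and are
#' excluded.
#'
#' @return An object of class `rotamer_scheme`: a named list with one entry
#'   per residue type, each holding the chi angles used, their bin edges,
#'   labels and bin-centre angles.
#' @examples
#' sch <- build_default_scheme()
#' scheme_n_states(sch, "VAL")  # 3
#' scheme_n_states(sch, "LEU")  # 9
#' scheme_n_states(sch, "TRP")  # 6
#' @export
build_default_scheme <- function() {
  residues <- lapply(.chi_defs, function(def) {
    angles <- list(chi1 = .bin_sp3)
    if (!is.null(def$chi2)) {
      angles$chi2 <- if (def$chi2_kind == "flip") .bin_flip else .bin_sp3
    }
    list(angles = angles, atoms = def[intersect(names(def), c("chi1", "chi2"))])
  })
  structure(list(residues = residues, excluded = .excluded_restypes),
            class = "rotamer_scheme")
}

#' Number of rotamer states for a residue type under a scheme
#'
#' @param scheme a `rotamer_scheme`, e.g. from [build_default_scheme()].
#' @param restype three-letter residue type, e.g. `"VAL"`.
#' @return integer state count (product of per-angle bin counts).
#' @export
scheme_n_states <- function(scheme, restype) {
  r <- scheme$residues[[toupper(restype)]]
  if (is.null(r)) {
    stop("residue type '", restype, "' has no rotamer states under this scheme",
         call. = FALSE)
  }
  as.integer(prod(vapply(r$angles, function(a) length(a$labels), integer(1))))
}

#' State labels for a residue type (mixed-radix order, chi1 fastest-varying
#' last)
#' @inheritParams scheme_n_states
#' @return character vector of `n_states` labels like `"g-/t"`.
#' @export
scheme_state_labels <- function(scheme, restype) {
  r <- scheme$residues[[toupper(restype)]]
  if (is.null(r)) return(character(0))
  labs <- r$angles$chi1$labels
  if (!is.null(r$angles$chi2)) {
    labs <- as.vector(t(outer(labs, r$angles$chi2$labels, paste, sep = "/")))
  }
  labs
}

# Map angles to 1-based bin indices under a bin definition. Bins are
# half-open (lo, hi]; the wrap-around bin (beyond the last edge) is the last
# label. Angles outside (-180, 180] are wrapped, never rejected.
bin_angle <- function(x, bins) {
  e <- bins$edges
  n <- length(bins$labels)
  y <- wrap_angle(x)
  lo <- y <= e[1]
  y[lo] <- y[lo] + 360  # rotate so all bins are contiguous: (e1, e1 + 360]
  idx <- rep.int(1L, length(y))
  for (k in seq_len(n - 1)) idx <- idx + (y > e[k + 1])
  idx
}

#' @export
print.rotamer_scheme <- function(x, ...) {
  counts <- vapply(names(x$residues), function(r) scheme_n_states(x, r), integer(1))
  cat("<rotamer_scheme> chi1/chi2 binning,", length(counts), "residue types\n")
  cat("  states:", paste0(names(counts), "=", counts, collapse = " "), "\n")
  cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
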