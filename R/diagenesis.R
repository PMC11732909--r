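#' PAAS reference concentrations for the lanthanides
#'
#' Post-Archean Australian Shale (PAAS) rare-earth-element concentrations
#' (ppm), the standard normalisation reference that removes the
#' Oddo-Harkins even-odd abundance effect from REE profiles. Values are the
#' widely used PAAS compilation.
#'
#' @return named numeric vector of 14 lanthanide concentrations in ppm.
#' @export
paas_reference <- function() {
  c(La = 38.2, Ce = 79.6, Pr = 8.83, Nd = 33.9, Sm = 5.55, Eu = 1.08,
    Gd = 4.66, Tb = 0.774, Dy = 4.68, Ho = 0.991, Er = 2.85, Tm = 0.405,
    Yb = 2.82, Lu = 0.433)
}

# Non-REE analytes carried in ICP-MS runs; parsed for provenance but never
# part of the REE index.
non_ree_analytes <- function() c("Ca", "Sc", "Sr", "Y", "Ba", "Pb", "U", "In")

#' Normalise an REE profile against PAAS
#'
#' Elementwise division of measured concentrations by the reference.
#'
#' @param concentrations named numeric vector, element -> ppm; all >= 0.
#' @param ref named numeric reference, default [paas_reference()].
#' @return named numeric vector of dimensionless normalised abundances.
#' @export
normalize_paas <- function(concentrations, ref = paas_reference()) {
  stopifnot(is.numeric(concentrations), !is.null(names(concentrations)))
  if (any(concentrations < 0, na.rm = TRUE)) stop("negative concentration")
  missing_el <- setdiff(names(concentrations), names(ref))
  if (length(missing_el)) {
    stop("element(s) absent from reference: ", paste(missing_el, collapse = ", "))
  }
  concentrations / ref[names(concentrations)]
}

#' Classify an REE dentine:bone ratio
#'
#' Alteration classes: `significant` (> 1), `mild_moderate` (0.5, 1],
#' `low` \[0.35, 0.5\] and `minimal` (< 0.35). Every finite non-negative
#' ratio maps to exactly one class.
#'
#' @param ratio non-negative REE index ratio.
#' @return character vector of classes.
#' @export
classify_ree_ratio <- function(ratio) {
  stopifnot(is.numeric(ratio))
  if (any(!is.finite(ratio) | ratio < 0)) stop("ratio must be finite and >= 0")
  ifelse(ratio > 1, "significant",
         ifelse(ratio > 0.5, "mild_moderate",
                ifelse(ratio >= 0.35, "low", "minimal")))
}

#' Diagenesis index from orthodentine and cortical bone REE profiles
#'
#' The index is the sum of PAAS-normalised REE in orthodentine divided by
#' the sum of PAAS-normalised REE in cortical bone from the same specimen
#' or locality. Orthodentine resists diagenetic REE uptake far better than
#' bone, so unaltered teeth give small ratios; a ratio above 1 signals
#' significant geochemical alteration. Elements measured in only one
#' tissue are dropped pairwise from both sums; non-REE analytes are
#' excluded.
#'
#' @param dentine,bone named numeric vectors, element -> ppm.
#' @param ref PAAS reference, default [paas_reference()].
#' @return list with `ratio`, `alteration_class`, `n_elements`,
#'   `n_dropped`.
#' @export
ree_index <- function(dentine, bone, ref = paas_reference()) {
  dentine <- dentine[!names(dentine) %in% non_ree_analytes()]
  bone <- bone[!names(bone) %in% non_ree_analytes()]
  shared <- intersect(names(dentine), names(bone))
  shared <- shared[is.finite(dentine[shared]) & is.finite(bone[shared])]
  n_dropped <- length(union(names(dentine), names(bone))) - length(shared)
  if (length(shared) == 0L) stop("no shared REE measurements between tissues")
  if (n_dropped > 0L) {
    message(n_dropped, " element(s) dropped pairwise (missing in one tissue)")
  }
  num <- sum(normalize_paas(dentine[shared], ref))
  den <- sum(normalize_paas(bone[shared], ref))
  if (den == 0) stop("cortical bone normalised sum is zero: ratio undefined")
  ratio <- num / den
  list(ratio = ratio,
       alteration_class = classify_ree_ratio(ratio),
       n_elements = length(shared),
       n_dropped = n_dropped)
}

#' Carbonate-phosphate d18O offset screen
#'
#' The carbonate moiety of bioapatite is more susceptible to diagenetic
#' alteration than the phosphate moiety, so a carbonate-phosphate d18O
#' offset outside the range observed in extant vertebrates indicates
#' preferential alteration of the carbonate. The default band (7-10
#' permil) is a literature-informed placeholder and should be configured
#' against the comparative dataset in use; the interval is closed.
#'
#' @param d18O_carb_vsmow carbonate d18O (permil, V-SMOW).
#' @param d18O_phos_vsmow phosphate d18O (permil, V-SMOW).
#' @param band length-2 numeric, acceptable offset interval in permil.
#' @return list with `offset` (carb - phos) and `within_band`.
#' @export
offset_screen <- function(d18O_carb_vsmow, d18O_phos_vsmow, band = c(7, 10)) {
  stopifnot(length(band) == 2L)
  if (band[1L] >= band[2L]) stop("band lower bound must be below upper bound")
  offset <- d18O_carb_vsmow - d18O_phos_vsmow
  list(offset = offset,
       within_band = offset >= band[1L] & offset <= band[2L])
}
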