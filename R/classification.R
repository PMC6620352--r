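#' Classify species by seed-disperser guild
#'
#' `is_lbf()` flags species dispersed by at least one large-bodied frugivore
#' group (gibbon, macaque, hornbills/large pigeons, terrestrial mammals).
#' `is_primate_dispersed()` flags species dispersed by gibbon or macaque.
#' Both operate on the whole trait table and return one logical per species.
#' The LBF definition is an explicit whitelist: `unknown_animals` and
#' `unclassified` do not count.
#'
#' @param traits Traits data frame with a `dispersal_groups` list-column
#'   (see [read_traits()]), or a bare list of group-code vectors.
#' @return Logical vector, one element per species.
#' @export
#' @examples
#' tr <- data.frame(species = c("A", "B"))
#' tr$dispersal_groups <- list(c("gibbon", "smaller_birds"), "wind")
#' is_lbf(tr)                 # TRUE FALSE
#' is_primate_dispersed(tr)   # TRUE FALSE
is_lbf <- function(traits) {
  groups_any(traits, lbf_groups())
}

#' @rdname is_lbf
#' @export
is_primate_dispersed <- function(traits) {
  groups_any(traits, primate_groups())
}

groups_any <- function(traits, which) {
  gl <- if (is.data.frame(traits)) traits$dispersal_groups else traits
  if (is.character(gl)) gl <- list(gl)
  stopifnot(all(lengths(gl) > 0))
  vapply(gl, function(g) any(g %in% which), logical(1))
}

#' Assign the carbon-share dispersal category
#'
#' Partitions species into the three mutually exclusive categories used to
#' break down above-ground carbon: `P` (primate-dispersed), `TB`
#' (large-bodied terrestrial mammals and birds), `O` (all other agents,
#' mostly smaller birds and abiotic). Species with several disperser groups
#' are assigned by the priority P > TB > O, so the categories always
#' partition the species list. `primates = "alone"` switches to the stricter
#' reading in which `P` requires primates to be the only LBF dispersers.
#'
#' @inheritParams is_lbf
#' @param primates `"any"` (default): `P` if any primate group is present;
#'   `"alone"`: `P` only if primates are present and no other LBF group is.
#' @return Factor with levels `P`, `TB`, `O`, one per species.
#' @export
share_category <- function(traits, primates = c("any", "alone")) {
  primates <- match.arg(primates)
  gl <- if (is.data.frame(traits)) traits$dispersal_groups else traits
  if (is.character(gl)) gl <- list(gl)
  tb_groups <- c("hornbills_large_pigeons", "terrestrial_mammals")
  cat <- vapply(gl, function(g) {
    p <- any(g %in% primate_groups())
    tb <- any(g %in% tb_groups)
    if (p && (primates == "any" || !tb)) "P" else if (tb) "TB" else "O"
  }, character(1))
  factor(cat, levels = c("P", "TB", "O"))
}
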