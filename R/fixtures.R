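# Packaged Magnoliaceae worked example -----------------------------------------
#
# A 39-taxon fixture: chronogram topology for the two genera and the
# sections/subsections of Magnolia, with the 14 published clade ages
# constrained and the remaining internal nodes interpolated (see
# interpolate_ages); tip geography coded from collection localities into ten
# operational areas.  The within-subsection resolution and per-species area
# coding are a documented best-effort transcription -- illustrative fixture
# data, not a reproduction of the original posterior tree.

#' Operational areas of the Magnolia example
#'
#' Eight Neotropical areas plus the Nearctic and Asia, in the fixed order
#' that defines geography-file encodings.
#' @return Character vector of 10 area names.
#' @export
magnolia_areas <- function() {
  c("Andes-North", "Brazil-Atlantic", "Brazil-Boreal", "Brazil-South",
    "Caribbean", "Mesoamerica", "Mexican-Transition-Zone", "Pacific",
    "Nearctic", "Asia")
}

#' State space of the Magnolia example
#'
#' Ten areas with at most two areas per range: 56 states including the null
#' range.
#' @return A `state_space`.
#' @export
magnolia_state_space <- function() build_state_space(magnolia_areas(), 2L)

#' Area connectivity of the Magnolia example
#'
#' Editable classification of area pairs used to derive baseline dispersal
#' multipliers (adjacent land 0.5, across water 0.25).  The Caribbean is
#' across water from every mainland area; the Nearctic-Asia route (Beringia)
#' is across water; continental neighbours share land.  Derived from the
#' area map, not printed in any source, hence exposed as data the user can
#' replace.
#' @return A `connectivity` object over [magnolia_areas()].
#' @export
magnolia_connectivity <- function() {
  areas <- magnolia_areas()
  adjacent <- rbind(
    c("Andes-North", "Pacific"),
    c("Andes-North", "Brazil-Boreal"),
    c("Andes-North", "Brazil-South"),
    c("Brazil-Boreal", "Brazil-South"),
    c("Brazil-South", "Brazil-Atlantic"),
    c("Mesoamerica", "Pacific"),
    c("Mesoamerica", "Mexican-Transition-Zone"),
    c("Mexican-Transition-Zone", "Nearctic"))
  water <- rbind(
    cbind("Caribbean", setdiff(areas, "Caribbean")),
    c("Nearctic", "Asia"))
  connectivity_spec(areas, adjacent, water)
}

# nested topology; num = constrained crown age (mya), chr = tip label
mag_topology <- function() {
  tip <- function(x) paste0("Magnolia_", x)
  cat_clade <- function(age, tips) {
    node <- tip(tips[length(tips)])
    for (i in rev(seq_len(length(tips) - 1L)))
      node <- list(age = if (i == 1L) age else NA_real_,
                   kids = list(tip(tips[i]), node))
    node
  }
  talauma_tips <- c("allenii", "dodecapetala", "kichuana", "lacandonica",
                    "macrocarpa", "mexicana", "ofeliae", "ovata",
                    "pastazaensis", "rimachii", "silvioi", "virolinensis",
                    "wetteri", "wolfii", "zamorana", "zoquepopolucae")
  sub_talauma <- cat_clade(13.26, talauma_tips)
  cubenses <- list(age = 10.9, kids = list(tip("emarginata"), tip("splendens")))
  dugandiodendron <- cat_clade(10.33, c("bankardiorum", "coronata",
                                        "jaenensis", "ptaritepuiana"))
  cub_dug <- list(age = 14.08, kids = list(cubenses, dugandiodendron))
  clade_I <- list(age = 35.97, kids = list(sub_talauma, cub_dug))
  sect_magnolia <- cat_clade(13.83, c("sharpii", "iltisiana", "panamensis"))
  sect_macrophylla <- cat_clade(6.0, c("grandiflora", "macrophylla",
                                       "dealbata", "rzedowskiana", "vovidesii"))
  mag_mac <- list(age = 22.98, kids = list(sect_magnolia, sect_macrophylla))
  yulania <- list(age = 9.7, kids = list(tip("acuminata"), tip("biondii")))
  krmgmy <- list(age = 14.69, kids = list(
    tip("septentrionalis"), list(age = NA_real_, kids = list(
      tip("obovata"), list(age = NA_real_, kids = list(
        tip("grandis"), list(age = NA_real_, kids = list(
          tip("kachirachirai"), list(age = NA_real_, kids = list(
            tip("foveolata"), yulania))))))))))
  clade_II <- list(age = 30.26, kids = list(mag_mac, krmgmy))
  clade_I_II <- list(age = 38.91, kids = list(clade_I, clade_II))
  genus <- list(age = 44.02, kids = list(tip("henryi"), clade_I_II))
  list(age = 92.92, kids = list("Liriodendron_tulipifera", genus))
}

# fill unconstrained internal node ages: a node between a constrained
# ancestor of age A and its oldest constrained descendant of age B (tips at
# 0) is placed by even division of [B, A] along the longest unconstrained
# chain through it
interpolate_ages <- function(node) {
  max_constrained_below <- function(nd) {
    if (is.character(nd)) return(0)
    if (!is.na(nd$age)) return(nd$age)
    max(vapply(nd$kids, max_constrained_below, 0))
  }
  chain_below <- function(nd) {                  # unconstrained internal chain
    if (is.character(nd)) return(0L)
    if (!is.na(nd$age)) return(0L)
    1L + max(vapply(nd$kids, chain_below, 0L))
  }
  fill <- function(nd, anc_age, up) {
    if (is.character(nd)) return(nd)
    if (!is.na(nd$age)) {
      nd$kids <- lapply(nd$kids, fill, anc_age = nd$age, up = 1L)
      return(nd)
    }
    B <- max_constrained_below(nd)
    k_below <- max(vapply(nd$kids, chain_below, 0L))
    nd$age <- anc_age - up * (anc_age - B) / (up + k_below + 1L)
    nd$kids <- lapply(nd$kids, fill, anc_age = anc_age, up = up + 1L)
    nd
  }
  fill(node, NA, 1L)
}

node_to_newick <- function(node) {
  emit <- function(nd, parent_age) {
    if (is.character(nd)) return(sprintf("%s:%.10g", nd, parent_age))
    sprintf("(%s,%s):%.10g", emit(nd$kids[[1]], nd$age),
            emit(nd$kids[[2]], nd$age), parent_age - nd$age)
  }
  root <- node
  sprintf("(%s,%s);", emit(root$kids[[1]], root$age),
          emit(root$kids[[2]], root$age))
}

#' The 39-taxon Magnoliaceae fixture chronogram
#'
#' Rooted ultrametric tree over the 39 sampled taxa with the 14 published
#' clade ages (root 92.92 mya, crown Magnolia 44.02 mya, crown section
#' Talauma 35.97 mya, ...) constrained and remaining internal nodes
#' interpolated deterministically.
#'
#' @return A validated `phylo` (see [as_chronogram()]).
#' @export
magnolia_chronogram <- function() {
  read_chronogram(node_to_newick(interpolate_ages(mag_topology())))
}

magnolia_codings <- function() {
  list(
    Magnolia_henryi = "Asia", Magnolia_kachirachirai = "Asia",
    Magnolia_septentrionalis = "Asia", Magnolia_grandis = "Asia",
    Magnolia_foveolata = "Asia", Magnolia_obovata = "Asia",
    Magnolia_biondii = "Asia",
    Magnolia_grandiflora = "Nearctic", Magnolia_macrophylla = "Nearctic",
    Magnolia_acuminata = "Nearctic", Liriodendron_tulipifera = "Nearctic",
    Magnolia_dealbata = "Mexican-Transition-Zone",
    Magnolia_rzedowskiana = "Mexican-Transition-Zone",
    Magnolia_vovidesii = "Mexican-Transition-Zone",
    Magnolia_iltisiana = "Mexican-Transition-Zone",
    Magnolia_ofeliae = "Mexican-Transition-Zone",
    Magnolia_zoquepopolucae = "Mexican-Transition-Zone",
    Magnolia_mexicana = c("Mesoamerica", "Mexican-Transition-Zone"),
    Magnolia_panamensis = "Mesoamerica", Magnolia_sharpii = "Mesoamerica",
    Magnolia_allenii = "Mesoamerica", Magnolia_lacandonica = "Mesoamerica",
    Magnolia_macrocarpa = "Mesoamerica", Magnolia_wetteri = "Mesoamerica",
    Magnolia_emarginata = "Caribbean", Magnolia_splendens = "Caribbean",
    Magnolia_dodecapetala = "Caribbean",
    Magnolia_bankardiorum = "Andes-North", Magnolia_coronata = "Andes-North",
    Magnolia_jaenensis = "Andes-North", Magnolia_kichuana = "Andes-North",
    Magnolia_pastazaensis = "Andes-North",
    Magnolia_virolinensis = "Andes-North", Magnolia_zamorana = "Andes-North",
    Magnolia_silvioi = "Pacific", Magnolia_wolfii = "Pacific",
    Magnolia_ptaritepuiana = "Brazil-Boreal", Magnolia_rimachii = "Brazil-Boreal",
    Magnolia_ovata = c("Brazil-Atlantic", "Brazil-South"))
}

#' Tip geography of the Magnoliaceae fixture
#'
#' All 39 taxa coded into the ten operational areas from their collection
#' localities / native distributions; every range has at most two areas.
#' The per-species coding is an editable best-effort transcription (see the
#' gazetteer shipped in `inst/extdata`).
#'
#' @return A `geography` over [magnolia_state_space()].
#' @export
magnolia_geography <- function() {
  geography(magnolia_codings(), magnolia_state_space())
}

#' Materialize the packaged fixture files
#'
#' Writes the Magnolia chronogram (Newick), geography (presence-absence and
#' CSV dialects), area list, connectivity CSV and the four scenario config
#' files into a directory, so analyses can be driven from plain files.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture_files <- function(dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- character(0)
  tr <- magnolia_chronogram()
  write_chronogram(tr, p("magnolia_chronogram.nwk"))
  geo <- magnolia_geography()
  write_geography(geo, p("magnolia_geography.txt"))
  write_geography_csv(geo, p("magnolia_geography.csv"))
  writeLines(magnolia_areas(), p("magnolia_areas.txt"))
  conn <- magnolia_connectivity()
  cd <- as.data.frame(as.table(unclass(conn)), stringsAsFactors = FALSE)
  names(cd) <- c("from", "to", "relation")
  utils::write.csv(cd[cd$from != cd$to, ], p("magnolia_connectivity.csv"),
                   row.names = FALSE)
  for (nm in scenario_names())
    write_scenario(build_scenario(nm, magnolia_areas(), conn),
                   p(paste0("scenario_", nm, ".txt")))
  paths <- c("magnolia_chronogram.nwk", "magnolia_geography.txt",
             "magnolia_geography.csv", "magnolia_areas.txt",
             "magnolia_connectivity.csv",
             paste0("scenario_", scenario_names(), ".txt"))
  invisible(file.path(dir, paths))
}
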