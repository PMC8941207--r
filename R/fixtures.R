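# Bundled networks and fragment sets.

.extdata <- function(name) {
  system.file("extdata", name, package = "betaflux", mustWork = TRUE)
}

#' Bundled beta-cell reaction network
#'
#' The oxidative beta-cell network: glycolysis, oxidative pentose
#' phosphate pathway with transketolase/transaldolase return, the
#' serine/glycine branch, glycerol release, the pyruvate node
#' (LDH/ALT/PDH/PC/malic enzyme), a citric acid cycle with reversible
#' isocitrate dehydrogenase (reductive carboxylation), glutamine
#' anaplerosis, and the medium exchange reactions. Succinate and fumarate
#' are symmetric; CO2 is an unbalanced natural-abundance pool. The
#' glucose-entry flux `GK` is the *net* glucokinase flux (glucokinase
#' minus glucose-6-phosphatase), the only glucose-entry parameter
#' identifiable from 13C data.
#'
#' @return A `network_model`.
#' @export
beta_cell_network <- function() {
  read_network(.extdata("betacell_network.tsv"))
}

#' Bundled beta-cell fragment-ion set
#'
#' Stand-in set of 21 GC-MS fragment ions (Mox-TBDMS derivatives of
#' organic/amino acids, DiO-derivatized glucose) spanning pyruvate,
#' lactate, alanine, serine, glycine, aspartate, glutamate, glutamine,
#' citrate, malate, succinate, glycerol, glycerol-3-phosphate and medium
#' glucose.
#'
#' @return A `fragment_table`.
#' @export
beta_cell_fragments <- function() {
  read_fragments(.extdata("betacell_fragments.tsv"))
}

#' Reduced core network and fragments
#'
#' A lumped glycolysis + citric acid cycle + glutamine anaplerosis network
#' (15 reactions, 6 free net fluxes, 3 exchange fluxes) used for fast
#' simulation studies such as coverage and calibration experiments.
#'
#' @return A `network_model` / `fragment_table`.
#' @export
core_network <- function() {
  read_network(.extdata("core_network.tsv"))
}

#' @rdname core_network
#' @export
core_fragments <- function() {
  read_fragments(.extdata("core_fragments.tsv"))
}
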