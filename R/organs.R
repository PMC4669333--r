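# Controlled organ vocabulary for the adult reference phantom, with
# masses (g, hermaphrodite adult ~70 kg) and an approximate cranio-caudal
# position (cm from the vertex) used only by the synthetic S-value
# generator. Masses follow the standard stylised adult phantom.
phantom_targets <- function() {
  data.frame(
    organ = c("adrenals", "brain", "breasts", "gallbladder_wall",
              "lli_wall", "small_intestine", "stomach_wall", "uli_wall",
              "heart_wall", "kidneys", "liver", "lungs", "muscle",
              "ovaries", "pancreas", "red_marrow", "osteogenic_cells",
              "skin", "spleen", "testes", "thymus", "thyroid",
              "urinary_bladder_wall", "uterus", "total_body"),
    mass_g = c(16.3, 1420, 351, 10.5, 160, 677, 158, 220, 316, 299, 1910,
               1000, 28000, 8.7, 94.3, 1120, 120, 3010, 183, 39.1, 20.9,
               20.7, 47.6, 79, 70000),
    position_cm = c(42, 8, 27, 40, 55, 48, 38, 50, 25, 42, 38, 25, 35, 57,
                    40, 35, 35, 35, 38, 65, 20, 15, 60, 58, 35),
    stringsAsFactors = FALSE)
}

# source organs the pipeline can feed into an S-value matrix, the matching
# self-irradiated target, the source-region mass (contents where relevant)
# and axial position
phantom_sources <- function() {
  data.frame(
    organ = c("brain", "stomach", "heart_contents", "kidneys", "lungs",
              "thyroid", "urinary_bladder_contents", "spleen",
              "red_marrow", "remainder"),
    self_target = c("brain", "stomach_wall", "heart_wall", "kidneys",
                    "lungs", "thyroid", "urinary_bladder_wall", "spleen",
                    "red_marrow", "total_body"),
    mass_g = c(1420, 250, 454, 299, 1000, 20.7, 200, 183, 1120, 70000),
    position_cm = c(8, 38, 25, 42, 25, 15, 60, 38, 35, 35),
    stringsAsFactors = FALSE)
}

organ_aliases <- function() {
  c("heart" = "heart_contents",
    "heart contents" = "heart_contents",
    "urinary bladder" = "urinary_bladder_contents",
    "urinary bladder contents" = "urinary_bladder_contents",
    "bladder" = "urinary_bladder_contents",
    "bladder contents" = "urinary_bladder_contents",
    "urinary bladder wall" = "urinary_bladder_wall",
    "bladder wall" = "urinary_bladder_wall",
    "lli wall" = "lli_wall",
    "lower large intestine wall" = "lli_wall",
    "uli wall" = "uli_wall",
    "upper large intestine wall" = "uli_wall",
    "stomach wall" = "stomach_wall",
    "gallbladder wall" = "gallbladder_wall",
    "heart wall" = "heart_wall",
    "red marrow" = "red_marrow",
    "osteogenic cells" = "osteogenic_cells",
    "bone surfaces" = "osteogenic_cells",
    "small intestine" = "small_intestine",
    "total body" = "total_body",
    "remainder of body" = "remainder",
    "rest of body" = "remainder",
    "parotid gland" = "parotid_gland",
    "submandibular gland" = "submandibular_gland",
    "sublingual gland" = "sublingual_gland",
    "olfactory mucosa" = "olfactory_mucosa")
}

#' Canonicalise organ names
#'
#' Lower-cases, strips punctuation to underscores and resolves common
#' aliases ("Urinary bladder wall" -> `urinary_bladder_wall`, "Heart" ->
#' `heart_contents`, "Osteogenic cells" / "Bone surfaces" ->
#' `osteogenic_cells`, ...).
#'
#' @param x Character vector of organ names.
#' @return Canonical snake_case names.
#' @export
canonical_organ <- function(x) {
  key <- tolower(trimws(gsub("[^[:alnum:]]+", " ", x)))
  al <- organ_aliases()
  hit <- al[key]
  out <- ifelse(is.na(hit), gsub(" ", "_", key), hit)
  unname(out)
}
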