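#' Tissue-weighting schemes
#'
#' Weighting factors and combination rules for the effective dose
#' (ICRP Publication 60) and the effective dose equivalent (ICRP
#' Publication 26), following the conventions of standard internal-
#' dosimetry codes for the stylised adult phantom:
#' \itemize{
#'   \item colon (ICRP-60) = 0.57 x ULI wall + 0.43 x LLI wall (mass
#'     weights);
#'   \item esophagus dose is surrogated by the thymus;
#'   \item gonads follow a configurable rule over testes/ovaries;
#'   \item ICRP-60 remainder (w = 0.05) is the mass-weighted mean dose of
#'     adrenals, brain, small intestine, kidneys, muscle, pancreas,
#'     spleen, thymus and uterus;
#'   \item ICRP-26 remainder is the five highest-dosed organs not already
#'     weighted (skin excluded), at 0.06 each.
#' }
#'
#' @param name `"ICRP60"` or `"ICRP26"`.
#' @return Object of class `tissue_weighting` with `name`, `weights`
#'   (named vector, remainder weight included for ICRP-60) and rule
#'   descriptors.
#' @export
tissue_weighting <- function(name = c("ICRP60", "ICRP26")) {
  name <- match.arg(name)
  w <- switch(name,
    ICRP60 = c(gonads = 0.20, red_marrow = 0.12, colon = 0.12,
               lungs = 0.12, stomach_wall = 0.12,
               urinary_bladder_wall = 0.05, breasts = 0.05, liver = 0.05,
               esophagus = 0.05, thyroid = 0.05, skin = 0.01,
               osteogenic_cells = 0.01, remainder = 0.05),
    ICRP26 = c(gonads = 0.25, breasts = 0.15, red_marrow = 0.12,
               lungs = 0.12, thyroid = 0.03, osteogenic_cells = 0.03,
               remainder = 0.30))
  stopifnot(abs(sum(w) - 1) < 1e-12)
  structure(list(
    name = name,
    weights = w,
    colon_weights = c(uli_wall = 0.57, lli_wall = 0.43),
    esophagus_surrogate = "thymus",
    remainder_rule = if (name == "ICRP60") "mass_average" else "five_highest_0.06",
    remainder_organs = c("adrenals", "brain", "small_intestine", "kidneys",
                         "muscle", "pancreas", "spleen", "thymus", "uterus")
  ), class = "tissue_weighting")
}

#' Effective dose / effective dose equivalent
#'
#' Tissue-weighted sum of organ absorbed doses, `E = sum_T w_T D_T`, with
#' the scheme's colon combination, esophagus surrogate, gonad rule and
#' remainder rule. For pure beta/photon emitters the radiation weighting
#' factor is 1, so mGy/MBq in gives mSv/MBq out.
#'
#' @param doses Named numeric vector of organ absorbed doses (mGy/MBq);
#'   names are canonicalised. Must include the organs the scheme needs
#'   (testes/ovaries, ULI/LLI walls, thymus, ...). Non-phantom entries
#'   such as sphere-model salivary glands are ignored.
#' @param scheme A [tissue_weighting()] object or scheme name.
#' @param gonad Gonad rule: `"mean"` (default), `"testes"`, `"ovaries"`
#'   or `"max"`.
#' @return List with `value` (mSv/MBq), `scheme`, `gonad`, and
#'   `contributions` (named vector, `w_T * D_T`).
#' @export
effective_dose <- function(doses, scheme = tissue_weighting("ICRP60"),
                           gonad = c("mean", "testes", "ovaries", "max")) {
  if (is.character(scheme)) scheme <- tissue_weighting(scheme)
  stopifnot(inherits(scheme, "tissue_weighting"))
  gonad <- match.arg(gonad)
  names(doses) <- canonical_organ(names(doses))
  if (any(doses < 0)) stop("doses must be non-negative")
  get_dose <- function(org) {
    if (!org %in% names(doses))
      stop(sprintf("tissue '%s' missing from doses and has no surrogate", org))
    unname(doses[org])
  }
  tissue_dose <- function(tissue) {
    switch(tissue,
      gonads = {
        tst <- get_dose("testes"); ov <- get_dose("ovaries")
        switch(gonad, mean = (tst + ov) / 2, testes = tst, ovaries = ov,
               max = max(tst, ov))
      },
      colon = sum(scheme$colon_weights *
                    vapply(names(scheme$colon_weights), get_dose, numeric(1))),
      esophagus = if ("esophagus" %in% names(doses)) get_dose("esophagus")
                  else get_dose(scheme$esophagus_surrogate),
      get_dose(tissue))
  }
  named <- setdiff(names(scheme$weights), "remainder")
  contrib <- vapply(named, function(ts) scheme$weights[[ts]] * tissue_dose(ts),
                    numeric(1))
  if (scheme$remainder_rule == "mass_average") {
    tg <- phantom_targets()
    mass <- tg$mass_g[match(scheme$remainder_organs, tg$organ)]
    d <- vapply(scheme$remainder_organs, get_dose, numeric(1))
    contrib <- c(contrib,
                 remainder = scheme$weights[["remainder"]] *
                   sum(d * mass) / sum(mass))
  } else {
    # five highest-dosed phantom organs not carrying an explicit weight;
    # skin and total body are excluded, as are non-phantom (sphere) organs
    explicit <- c("testes", "ovaries", "breasts", "red_marrow", "lungs",
                  "thyroid", "osteogenic_cells", "skin", "total_body")
    eligible <- doses[names(doses) %in%
                        setdiff(phantom_targets()$organ, explicit)]
    top5 <- sort(eligible, decreasing = TRUE)[seq_len(min(5L, length(eligible)))]
    contrib <- c(contrib, remainder = 0.06 * sum(top5))
  }
  list(value = sum(contrib), scheme = scheme$name, gonad = gonad,
       contributions = contrib)
}
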