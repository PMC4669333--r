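#' S-value matrix
#'
#' Target-by-source table of mean absorbed dose to a target region per
#' unit time-integrated activity in a source region, in mGy/(MBq·h), for a
#' given reference phantom. Row names are target organs, column names are
#' source organs (canonicalised with [canonical_organ()]).
#'
#' @param values Numeric matrix (targets x sources) with dimnames.
#' @param phantom_label Free-text phantom description.
#' @return Object of class `svalue_matrix`.
#' @export
svalue_matrix <- function(values, phantom_label = "unspecified phantom") {
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must be a matrix with target row names and source column names")
  if (any(values < 0)) stop("S values must be non-negative")
  rownames(values) <- canonical_organ(rownames(values))
  colnames(values) <- canonical_organ(colnames(values))
  structure(list(values = values, targets = rownames(values),
                 sources = colnames(values), phantom_label = phantom_label),
            class = "svalue_matrix")
}

#' @export
print.svalue_matrix <- function(x, ...) {
  cat(sprintf("<svalue_matrix> %d targets x %d sources, mGy/(MBq*h), phantom: %s\n",
              length(x$targets), length(x$sources), x$phantom_label))
  invisible(x)
}

#' Read / write an S-value matrix as CSV
#'
#' The CSV schema has the target organ in the first column and one column
#' per source organ; values in mGy/(MBq·h). Lines starting with `#` are
#' treated as comments.
#'
#' @param path CSV file path.
#' @param phantom_label Phantom description for the read matrix.
#' @return [read_svalue_matrix()] returns an `svalue_matrix`.
#' @export
read_svalue_matrix <- function(path, phantom_label = basename(path)) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  svalue_matrix(m, phantom_label)
}

#' @rdname read_svalue_matrix
#' @param S An `svalue_matrix`.
#' @export
write_svalue_matrix <- function(S, path) {
  df <- data.frame(target = S$targets, S$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthetic S-value matrix for a 70-kg adult (fixture)
#'
#' A deterministic, physically plausible stand-in for a proprietary
#' reference-phantom S-value table, suitable for exercising and testing
#' the dose engine; it is NOT a reproduction of any published phantom.
#' Self-dose entries use the unit-density-sphere coefficient at the source
#' mass (halved for wall/contents pairs, the wall receiving roughly half
#' the equilibrium dose); cross-dose entries carry only the
#' annihilation-photon component, attenuated exponentially with the
#' inter-organ distance along the body axis; every source also deposits a
#' whole-body photon background. The `remainder` source irradiates all
#' targets uniformly at the total-body scale.
#'
#' @param nuclide A [nuclide] object.
#' @return An `svalue_matrix` labelled as synthetic.
#' @export
synthetic_svalue_matrix <- function(nuclide = nuclide_f18()) {
  nuclide <- as_nuclide(nuclide)
  tg <- phantom_targets()
  sr <- phantom_sources()
  delta_gamma <- nuclide$photon_energy_mev * nuclide$photons_per_decay
  mu <- 0.096  # linear attenuation of 511 keV in soft tissue, 1/cm
  # whole-body photon background per unit cumulated activity anywhere
  bg <- MEV_TO_MGY_G_PER_MBQ_H * (nuclide$mean_beta_energy_mev *
          nuclide$positron_yield + delta_gamma * 0.34) / 70000
  m <- matrix(0, nrow(tg), nrow(sr),
              dimnames = list(tg$organ, sr$organ))
  for (j in seq_len(nrow(sr))) {
    src <- sr[j, ]
    if (src$organ == "remainder") { m[, j] <- bg; next }
    for (i in seq_len(nrow(tg))) {
      t <- tg[i, ]
      if (t$organ == "total_body") { m[i, j] <- bg; next }
      if (t$organ == src$self_target) {
        d_self <- sphere_dose_coefficient(src$mass_g, nuclide)
        wall_pair <- src$organ %in% c("stomach", "heart_contents",
                                      "urinary_bladder_contents")
        m[i, j] <- if (wall_pair) 0.5 * d_self else d_self
      } else {
        # photon-only cross dose: energy fluence at the target from a
        # compact source, times the mass energy-absorption coefficient
        dist <- abs(t$position_cm - src$position_cm)
        r_t <- (3 * t$mass_g / (4 * pi))^(1 / 3)
        r_s <- (3 * src$mass_g / (4 * pi))^(1 / 3)
        d_eff <- max(dist, r_t + r_s, 5)
        cross <- MEV_TO_MGY_G_PER_MBQ_H * delta_gamma * MU_EN_511_CM2_G *
          exp(-mu * dist) / (4 * pi * d_eff^2)
        m[i, j] <- cross + bg
      }
    }
  }
  svalue_matrix(m, "synthetic 70-kg adult (not a published phantom)")
}

#' Organ absorbed doses from residence times and S values
#'
#' The MIRD schema: `D(target) = sum_source tau(source) * S(target <- source)`,
#' in mGy/MBq when `tau` is in hours and `S` in mGy/(MBq·h).
#'
#' @param taus Named numeric vector of residence times (h), or a
#'   `residence_set` (whose remainder is included as source `remainder`).
#' @param S An [svalue_matrix()]. Every source in `taus` must be a column.
#' @return Named numeric vector of target doses, mGy/MBq.
#' @export
organ_doses <- function(taus, S) {
  stopifnot(inherits(S, "svalue_matrix"))
  if (inherits(taus, "residence_set"))
    taus <- c(taus$entries, remainder = taus$remainder)
  if (is.null(names(taus))) stop("taus must be named by source organ")
  src <- canonical_organ(names(taus))
  missing <- setdiff(src, S$sources)
  if (length(missing))
    stop("source organ(s) missing from the S-value matrix: ",
         paste(missing, collapse = ", "))
  if (any(taus < 0)) stop("residence times must be non-negative")
  drop(S$values[, src, drop = FALSE] %*% unname(taus))
}
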