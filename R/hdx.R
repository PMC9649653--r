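# Hydrogen-deuterium exchange MS: percent exchange, residue-level mapping,
# bimodal envelope deconvolution and EX1/EX2 regime classification.

#' Percent deuterium exchange of a peptic peptide
#'
#' Computes, per labelling timepoint,
#' %Ex = (m_t - m_0) / (m_f - m_0) x 100,
#' where m_t is the centroid mass at exposure time t, m_0 the undeuterated
#' centroid and m_f the fully-deuterated reference centroid. Replicates are
#' aggregated to mean +/- SD. The record carries the median residue number
#' of the peptide, used for plotting exchange against sequence position.
#'
#' @param timepoints Exposure times (s).
#' @param m_t Centroid masses (Da): either a vector (one replicate) or a
#'   matrix with one row per replicate and one column per timepoint.
#' @param m_0 Undeuterated centroid mass (Da).
#' @param m_f Fully-deuterated reference centroid mass (Da).
#' @param start_res,end_res Precursor residue bounds of the peptide
#'   (optional; needed for residue mapping).
#' @param peptide_id Identifier carried through to residue mapping.
#' @return Object of class `exchange_record`: list with `timepoints`,
#'   `percent` (mean %Ex per timepoint), `sd`, `median_residue`,
#'   `start_res`, `end_res`, `peptide_id`.
#' @examples
#' percent_exchange(c(10, 60), c(1004, 1008), m_0 = 1000, m_f = 1010)$percent
#' @export
percent_exchange <- function(timepoints, m_t, m_0, m_f,
                             start_res = NA_integer_, end_res = NA_integer_,
                             peptide_id = NA_character_) {
  if (m_f == m_0) {
    stop("degenerate reference: fully-deuterated and undeuterated centroids are equal")
  }
  if (is.null(dim(m_t))) m_t <- matrix(m_t, nrow = 1L)
  if (ncol(m_t) != length(timepoints)) {
    stop("m_t must have one column per timepoint")
  }
  pex <- (m_t - m_0) / (m_f - m_0) * 100
  structure(list(timepoints = timepoints,
                 percent = colMeans(pex),
                 sd = apply(pex, 2, stats::sd),
                 median_residue = stats::median(c(start_res, end_res)),
                 start_res = start_res, end_res = end_res,
                 peptide_id = peptide_id),
            class = "exchange_record")
}

#' Theoretical fully-deuterated centroid mass
#'
#' Convenience estimate of m_f when no fully-deuterated reference was
#' measured, following the standard HDX convention: exchangeable backbone
#' amides = peptide length - 1 (fast-back-exchanging N-terminal residue)
#' minus prolines after the first position, each contributing one deuteron
#' at 95% maximal labelling.
#'
#' @param sequence Peptide amino-acid sequence.
#' @param m_0 Undeuterated centroid mass (Da).
#' @param max_d_fraction Maximal labelling fraction (default 0.95, the D2O
#'   content typical of labelling buffers).
#' @return Theoretical m_f (Da).
#' @export
theoretical_mf <- function(sequence, m_0, max_d_fraction = 0.95) {
  sequence <- toupper(gsub("\\s", "", sequence))
  aa <- strsplit(sequence, "")[[1]]
  n_amides <- length(aa) - 1L - sum(aa[-1] == "P")
  m_0 + max_d_fraction * n_amides * 1.00628
}

#' Number of exchangeable backbone amides of a peptide
#' @param sequence Peptide amino-acid sequence.
#' @return Integer count: length - 1 - prolines after position 1.
#' @export
exchangeable_amides <- function(sequence) {
  aa <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  length(aa) - 1L - sum(aa[-1] == "P")
}

#' Assign peptide-level exchange to residues
#'
#' For each covered residue, the percent exchange of the shortest peptide
#' containing it is assigned; among equally short covering peptides the one
#' whose C-terminus extends furthest (retaining the overlapping region at
#' its C-terminus) is used, with any remaining tie broken by the leftmost
#' start for determinism. Uncovered residues within `residues` are flagged
#' rather than interpolated. The assignment is independent of the order in
#' which peptides are supplied.
#'
#' @param records List of `exchange_record` objects with valid
#'   `start_res`/`end_res`.
#' @param timepoint_index Which timepoint's percent exchange to map
#'   (default 1).
#' @param residues Residue range to map; defaults to the union span of the
#'   peptides.
#' @return Data frame with columns `residue`, `percent`, `peptide_id`,
#'   `covered`.
#' @export
map_to_residues <- function(records, timepoint_index = 1L, residues = NULL) {
  if (length(records) == 0L) {
    return(data.frame(residue = integer(0), percent = numeric(0),
                      peptide_id = character(0), covered = logical(0)))
  }
  starts <- vapply(records, function(r) as.integer(r$start_res), integer(1))
  ends <- vapply(records, function(r) as.integer(r$end_res), integer(1))
  if (any(is.na(starts) | is.na(ends))) stop("all records need start_res/end_res")
  if (is.null(residues)) residues <- seq(min(starts), max(ends))
  lens <- ends - starts + 1L
  rows <- lapply(residues, function(res) {
    cov <- which(starts <= res & ends >= res)
    if (!length(cov)) {
      return(data.frame(residue = res, percent = NA_real_,
                        peptide_id = NA_character_, covered = FALSE,
                        stringsAsFactors = FALSE))
    }
    # shortest peptide; tie -> furthest-right C-terminus; tie -> leftmost start
    ord <- cov[order(lens[cov], -ends[cov], starts[cov])]
    best <- records[[ord[1]]]
    data.frame(residue = res,
               percent = unname(best$percent[timepoint_index]),
               peptide_id = as.character(best$peptide_id),
               covered = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Deconvolve a mass envelope into one or two Gaussian components
#'
#' Least-squares fit of one- and two-component Gaussian models to an
#' intensity envelope on the m/z axis, with model selection by the
#' small-sample-corrected Akaike criterion (AICc) with a 2-point margin in
#' favour of the simpler model. In a two-component fit the lower-mass
#' component is reported as the folded (exchange-incompetent) population
#' and the higher-mass component as the unfolded population; fractions are
#' component areas over total area. Components whose mean separation falls
#' below `fused_factor` times the pooled width are reported as a
#' "fused-bimodal" envelope: two populations present but not resolved. A
#' separation below one pooled width carries no evidence of a second
#' population at all and degenerates to the unimodal model, as does a
#' component carrying under 1% of the area.
#'
#' Isotope-resolved combs should be smoothed before fitting; `smooth_sd`
#' applies a Gaussian kernel (in m/z units) on a uniform grid for this
#' purpose.
#'
#' @param mz m/z values (ascending).
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param max_components 1 or 2.
#' @param fused_factor Separation threshold (in pooled-width units) below
#'   which a two-component fit is called fused (default 1.5).
#' @param smooth_sd Optional Gaussian smoothing kernel SD (m/z units)
#'   applied before fitting.
#' @return Object of class `bimodal_fit`: list with `n_components`,
#'   `means`, `widths`, `areas`, `folded_fraction`, `unfolded_fraction`,
#'   `regime` ("unimodal", "bimodal" or "fused-bimodal"), `aicc` (per
#'   model), `centroid` (intensity-weighted mean of the input envelope).
#' @export
fit_envelope <- function(mz, intensity, max_components = 2L,
                         fused_factor = 1.5, smooth_sd = NULL) {
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (length(mz) < 10L) stop("need at least 10 envelope sample points")
  if (any(intensity < 0) || sum(intensity) <= 0) {
    stop("intensities must be non-negative with positive sum")
  }
  if (!is.null(smooth_sd)) {
    sm <- .smooth_envelope(mz, intensity, smooth_sd)
    mz <- sm$mz; intensity <- sm$intensity
  }
  centroid <- sum(mz * intensity) / sum(intensity)
  w_sd <- sqrt(sum(intensity * (mz - centroid)^2) / sum(intensity))
  n <- length(mz)
  df <- data.frame(x = mz, y = intensity)

  fit1 <- tryCatch(
    minpack.lm::nlsLM(y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)), data = df,
                      start = list(a1 = max(intensity), m1 = centroid,
                                   s1 = max(w_sd, diff(range(mz)) / 20)),
                      lower = c(a1 = 0, m1 = min(mz), s1 = diff(range(mz)) / 1e4),
                      upper = c(a1 = Inf, m1 = max(mz), s1 = diff(range(mz))),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  fits <- list(`1` = fit1)

  if (max_components >= 2L) {
    rng <- diff(range(mz))
    w_max <- rng / 3  # a wider "component" would be fitting the baseline
    try2 <- function(start) {
      tryCatch(
        minpack.lm::nlsLM(y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
                            a2 * exp(-(x - m2)^2 / (2 * s2^2)), data = df,
                          start = start,
                          lower = c(a1 = 0, m1 = min(mz), s1 = rng / 1e4,
                                    a2 = 0, m2 = min(mz), s2 = rng / 1e4),
                          upper = c(a1 = Inf, m1 = max(mz), s1 = w_max,
                                    a2 = Inf, m2 = max(mz), s2 = w_max),
                          control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
    }
    s_start <- max(w_sd / 2, rng / 40)
    # start A: split the envelope at its weighted median
    cum <- cumsum(intensity) / sum(intensity)
    split <- mz[which.min(abs(cum - 0.5))]
    lo <- intensity * (mz <= split); hi <- intensity * (mz > split)
    m1s <- if (sum(lo) > 0) sum(mz * lo) / sum(lo) else centroid - w_sd
    m2s <- if (sum(hi) > 0) sum(mz * hi) / sum(hi) else centroid + w_sd
    cands <- list(list(a1 = max(lo), m1 = m1s, s1 = s_start,
                       a2 = max(hi), m2 = m2s, s2 = s_start))
    # start B: main component from the 1-component fit, second component at
    # the largest positive residual (recovers a minor well-separated peak)
    if (!is.null(fit1)) {
      co1 <- stats::coef(fit1)
      res <- intensity - stats::fitted(fit1)
      j <- which.max(res)
      if (res[j] > 0.02 * max(intensity)) {
        cands[[2]] <- list(a1 = unname(co1["a1"]), m1 = unname(co1["m1"]),
                           s1 = unname(co1["s1"]),
                           a2 = res[j], m2 = mz[j], s2 = s_start)
      }
    }
    # start C: the two most intense local maxima of the envelope
    n_pts <- length(intensity)
    is_max <- c(FALSE, intensity[2:(n_pts - 1)] >= intensity[1:(n_pts - 2)] &
                  intensity[2:(n_pts - 1)] >= intensity[3:n_pts], FALSE) &
      intensity > 0.05 * max(intensity)
    pk <- which(is_max)
    if (length(pk) >= 2L) {
      pk <- pk[order(intensity[pk], decreasing = TRUE)]
      p1 <- pk[1]
      p2 <- pk[which(abs(mz[pk] - mz[p1]) > 2 * s_start)[1]]
      if (!is.na(p2)) {
        cands[[length(cands) + 1L]] <- list(
          a1 = intensity[min(p1, p2)], m1 = mz[min(p1, p2)], s1 = s_start,
          a2 = intensity[max(p1, p2)], m2 = mz[max(p1, p2)], s2 = s_start)
      }
    }
    fits2 <- Filter(Negate(is.null), lapply(cands, try2))
    fits$`2` <- if (length(fits2)) {
      fits2[[which.min(vapply(fits2, function(f) sum(stats::residuals(f)^2),
                              numeric(1)))]]
    } else NULL
  }
  if (is.null(fits$`1`) && is.null(fits$`2`)) stop("envelope fit failed to converge")

  aicc <- vapply(fits, function(f) {
    if (is.null(f)) return(Inf)
    rss <- sum(stats::residuals(f)^2)
    k <- length(stats::coef(f)) + 1
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
  }, numeric(1))
  # prefer the simpler model unless the 2-component AICc wins by > 2 points
  use2 <- length(fits) > 1L && !is.null(fits$`2`) &&
    (is.null(fits$`1`) || aicc["2"] < aicc["1"] - 2)

  if (!use2) {
    co <- stats::coef(fits$`1`)
    out <- list(n_components = 1L,
                means = unname(co["m1"]), widths = unname(co["s1"]),
                areas = unname(co["a1"] * co["s1"] * sqrt(2 * pi)),
                folded_fraction = NA_real_, unfolded_fraction = NA_real_,
                regime = "unimodal", aicc = aicc, centroid = centroid)
  } else {
    co <- stats::coef(fits$`2`)
    comp <- data.frame(mean = c(co["m1"], co["m2"]),
                       width = c(co["s1"], co["s2"]),
                       area = c(co["a1"] * co["s1"], co["a2"] * co["s2"]) * sqrt(2 * pi))
    comp <- comp[order(comp$mean), ]
    total <- sum(comp$area)
    pooled_w <- sqrt(mean(comp$width^2))
    sep <- diff(comp$mean)
    # a vanished component, or two components closer than one pooled width
    # (no resolvable second population), degenerates to a unimodal call
    if (total <= 0 || any(comp$area / total < 0.01) || sep < pooled_w) {
      if (!is.null(fits$`1`)) {
        co1 <- stats::coef(fits$`1`)
        out <- list(n_components = 1L, means = unname(co1["m1"]),
                    widths = unname(co1["s1"]),
                    areas = unname(co1["a1"] * co1["s1"] * sqrt(2 * pi)),
                    folded_fraction = NA_real_, unfolded_fraction = NA_real_,
                    regime = "unimodal", aicc = aicc, centroid = centroid)
      } else {
        keep <- which.max(comp$area)
        out <- list(n_components = 1L, means = comp$mean[keep],
                    widths = comp$width[keep], areas = comp$area[keep],
                    folded_fraction = NA_real_, unfolded_fraction = NA_real_,
                    regime = "unimodal", aicc = aicc, centroid = centroid)
      }
    } else {
      out <- list(n_components = 2L,
                  means = comp$mean, widths = comp$width, areas = comp$area,
                  folded_fraction = comp$area[1] / total,
                  unfolded_fraction = comp$area[2] / total,
                  regime = if (sep < fused_factor * pooled_w) "fused-bimodal" else "bimodal",
                  aicc = aicc, centroid = centroid)
    }
  }
  structure(out, class = "bimodal_fit")
}

.smooth_envelope <- function(mz, intensity, sd) {
  grid <- seq(min(mz), max(mz), length.out = max(length(mz), 512L))
  dx <- grid[2] - grid[1]
  sm <- vapply(grid, function(g) {
    w <- exp(-(g - mz)^2 / (2 * sd^2))
    sum(w * intensity)
  }, numeric(1))
  list(mz = grid, intensity = sm / max(sm) * max(intensity))
}

#' Classify the exchange regime of a peptide across timepoints
#'
#' EX1 exchange (long-lived local unfolding) produces a persistent bimodal
#' envelope whose component means stay fixed while the area shifts from the
#' folded (low-mass) to the unfolded (high-mass) population over time. EX2
#' exchange (transient opening) produces a single envelope whose centroid
#' drifts upward. Envelopes with two insufficiently separated components
#' are called "fused-bimodal": partial EX1 character without full
#' resolution.
#'
#' @param fits List of `bimodal_fit` objects, one per timepoint, from the
#'   same peptide/charge state (at least 2 timepoints).
#' @param mean_tolerance Maximum drift of a component mean (as a multiple
#'   of the pooled component width) still considered time-invariant
#'   (default 0.5).
#' @return One of `"EX1"`, `"EX2"`, `"fused-bimodal"`.
#' @export
classify_exchange_regime <- function(fits, mean_tolerance = 0.5) {
  if (length(fits) < 2L) {
    stop("regime classification needs fits from at least 2 timepoints")
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "bimodal_fit")))
  regimes <- vapply(fits, function(f) f$regime, character(1))
  n2 <- sum(regimes %in% c("bimodal", "fused-bimodal"))
  if (n2 < length(fits) / 2) return("EX2")
  if (sum(regimes == "fused-bimodal") >= sum(regimes == "bimodal")) {
    return("fused-bimodal")
  }
  bi <- fits[regimes == "bimodal"]
  if (length(bi) >= 2L) {
    lo <- vapply(bi, function(f) f$means[1], numeric(1))
    hi <- vapply(bi, function(f) f$means[2], numeric(1))
    w <- mean(vapply(bi, function(f) sqrt(mean(f$widths^2)), numeric(1)))
    drift <- max(diff(range(lo)), diff(range(hi)))
    if (drift > mean_tolerance * w) return("EX2")
  }
  "EX1"
}

#' Differential exchange between a variant and wild type
#'
#' Matches peptides by residue span, computes the per-timepoint difference
#' in mean percent exchange (variant minus wild type) and flags peptides
#' whose variant mean lies outside the wild-type mean +/- SD band.
#' Unmatched peptides are dropped with a message.
#'
#' @param variant_records,wildtype_records Lists of `exchange_record`
#'   objects.
#' @return Data frame with columns `peptide_id`, `start_res`, `end_res`,
#'   `median_residue`, `timepoint`, `delta_percent`, `wt_sd`,
#'   `outside_band`.
#' @export
differential_exchange <- function(variant_records, wildtype_records) {
  key <- function(r) sprintf("%d-%d", r$start_res, r$end_res)
  wt_keys <- vapply(wildtype_records, key, character(1))
  rows <- list()
  for (vr in variant_records) {
    j <- match(key(vr), wt_keys)
    if (is.na(j)) {
      message("no wild-type match for peptide ", key(vr), "; excluded")
      next
    }
    wr <- wildtype_records[[j]]
    delta <- vr$percent - wr$percent
    rows[[length(rows) + 1L]] <- data.frame(
      peptide_id = as.character(vr$peptide_id),
      start_res = vr$start_res, end_res = vr$end_res,
      median_residue = vr$median_residue,
      timepoint = vr$timepoints,
      delta_percent = delta,
      wt_sd = wr$sd,
      outside_band = abs(delta) > wr$sd,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(peptide_id = character(0), start_res = integer(0),
                      end_res = integer(0), median_residue = numeric(0),
                      timepoint = numeric(0), delta_percent = numeric(0),
                      wt_sd = numeric(0), outside_band = logical(0)))
  }
  do.call(rbind, rows)
}

#' Equilibrium fraction of protein bound by a ligand
#'
#' Exact two-state binding equilibrium (quadratic solution, no
#' excess-ligand approximation): fraction of total protein in complex for
#' given total protein, total ligand and dissociation constant. Used e.g.
#' to verify inhibitor occupancy of the kinase under HDX labelling
#' conditions after dilution.
#'
#' @param protein_uM Total protein concentration (uM).
#' @param ligand_uM Total ligand concentration (uM).
#' @param kd_uM Dissociation constant (uM).
#' @return Fraction of protein bound, in \[0, 1\].
#' @examples
#' ligand_occupancy(0.39, 0.78, 0.005) # ~0.987
#' @export
ligand_occupancy <- function(protein_uM, ligand_uM, kd_uM) {
  if (protein_uM <= 0 || kd_uM <= 0 || ligand_uM < 0) {
    stop("protein and Kd must be positive, ligand non-negative")
  }
  if (ligand_uM == 0) return(0)
  s <- protein_uM + ligand_uM + kd_uM
  bound <- (s - sqrt(s^2 - 4 * protein_uM * ligand_uM)) / 2
  bound / protein_uM
}
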