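#' Accumulate per-plane secondary-ion counts
#'
#' nanoSIMS records a stack of planes per region of interest (ROI); counts
#' arrive drift-corrected and are summed per ion species before ratio
#' calculation. Splitting or merging planes never changes the accumulated
#' isotope fraction.
#'
#' @param planes data.frame or matrix with one row per plane and one numeric
#'   column per ion species (e.g. `n15`, `n14`, `c13`, `c12`); counts are
#'   non-negative.
#' @return named numeric vector of summed counts per species.
#' @export
accumulate_planes <- function(planes) {
  planes <- as.data.frame(planes)
  if (nrow(planes) == 0L) stop("ROI has no recorded planes")
  if (any(unlist(planes) < 0)) stop("ion counts must be non-negative")
  colSums(planes)
}

#' Isotope fraction from minor/major ion counts
#'
#' fraction = minor / (minor + major), the quantity the rate equations use
#' (15N/(15N+14N), 13C/(13C+12C)); atom% is 100 x fraction.
#'
#' @param minor_counts,major_counts accumulated counts of the heavy (minor)
#'   and light (major) isotope species.
#' @return fraction in `[0, 1]`; `NA` with a warning when the total is zero.
#' @export
isotope_fraction <- function(minor_counts, major_counts) {
  total <- minor_counts + major_counts
  out <- minor_counts / total
  if (any(total == 0)) {
    warning("zero total counts: isotope fraction undefined")
    out[total == 0] <- NA_real_
  }
  out
}

#' Relative Poisson error of an isotope count ratio
#'
#' Standard counting-statistics error of the minor/major ratio:
#' sqrt(1/N_minor + 1/N_major). Quality control passes only when this error is
#' strictly below the threshold (default 5%), computed on counts accumulated
#' over all planes of a cell.
#'
#' @param minor_counts,major_counts accumulated counts; both must be positive
#'   for the error to be defined (zero minor counts fail QC outright).
#' @return relative error (dimensionless); `Inf` when a total is zero.
#' @export
ratio_poisson_error <- function(minor_counts, major_counts) {
  err <- sqrt(1 / minor_counts + 1 / major_counts)
  err[minor_counts <= 0 | major_counts <= 0] <- Inf
  err
}

#' Poisson-error quality-control decision
#'
#' @param minor_counts,major_counts accumulated counts.
#' @param threshold relative-error threshold; pass iff error < threshold
#'   (strict).
#' @return logical.
#' @export
passes_poisson_qc <- function(minor_counts, major_counts, threshold = 0.05) {
  ratio_poisson_error(minor_counts, major_counts) < threshold
}

#' Cell biovolume from width and length
#'
#' Prolate-spheroid formula BV = (pi/6) * width^2 * length, with width the
#' cell cross-section. Reduces to the sphere volume when width equals length.
#'
#' @param width_um,length_um cell dimensions, um; `0 < width <= length`.
#' @return biovolume, um^3.
#' @export
biovolume <- function(width_um, length_um) {
  if (any(width_um <= 0) || any(length_um <= 0)) stop("cell dimensions must be positive")
  if (any(width_um > length_um))
    stop("width (cross-section) must not exceed length")
  pi / 6 * width_um^2 * length_um
}

#' Cellular carbon content from biovolume
#'
#' Allometric carbon-density relation for large protist-sized cells:
#' C (pg) = 0.433 * BV^0.863, converted to fmol with the molar mass of carbon
#' (12 g mol^-1), i.e. C_cell (fmol) = 0.433 * BV^0.863 * 1000 / 12.
#'
#' @param bv_um3 biovolume, um^3 (>= 0).
#' @return carbon content, fmol C cell^-1.
#' @export
carbon_content <- function(bv_um3) {
  if (any(bv_um3 < 0)) stop("biovolume must be non-negative")
  0.433 * bv_um3^0.863 * 1000 / 12
}

#' Cellular nitrogen content from carbon content
#'
#' @param c_cell_fmol carbon content, fmol C.
#' @param cn_ratio molar C:N ratio of the biomass (> 0), e.g. 8.6 for bulk
#'   chemocline biomass.
#' @return nitrogen content, fmol N cell^-1.
#' @export
nitrogen_content <- function(c_cell_fmol, cn_ratio = 8.6) {
  if (any(cn_ratio <= 0)) stop("C:N ratio must be positive")
  c_cell_fmol / cn_ratio
}

#' Cell-specific fixation rate from isotope enrichment
#'
#' rate = (at%excess_cell / at%excess_medium) * content / time: the fraction
#' of the cell's element pool replaced by labelled substrate, relative to the
#' label strength of the medium, times the cellular element content per unit
#' time. Same form for N (N_cell, 15N excess) and C (C_cell, 13C excess).
#'
#' @param at_excess_cell atom% excess of the cell above natural abundance.
#' @param at_excess_medium atom% excess of the labelled medium pool (> 0).
#' @param content_fmol cellular element content, fmol (> 0).
#' @param time_d incubation time, days (> 0).
#' @return rate, fmol cell^-1 d^-1.
#' @export
cell_rate <- function(at_excess_cell, at_excess_medium, content_fmol, time_d) {
  if (any(at_excess_medium <= 0)) stop("medium excess enrichment must be positive")
  if (any(content_fmol <= 0)) stop("cellular content must be positive")
  if (any(time_d <= 0)) stop("incubation time must be positive")
  (at_excess_cell / at_excess_medium) * content_fmol / time_d
}

#' Enrichment significance against counting statistics
#'
#' A cell counts as significantly enriched when its excess fraction exceeds
#' `multiplier` times the propagated Poisson error of its isotope ratio,
#' evaluated on accumulated counts. Cells failing this are candidates for the
#' "inactive cell" designation but stay in all downstream calculations.
#'
#' @param fraction measured isotope fraction of the cell.
#' @param reference_fraction natural-abundance fraction.
#' @param minor_counts,major_counts accumulated counts behind `fraction`.
#' @param multiplier significance multiplier (default 3).
#' @return logical.
#' @export
is_significantly_enriched <- function(fraction, reference_fraction,
                                      minor_counts, major_counts,
                                      multiplier = 3) {
  rel_err <- ratio_poisson_error(minor_counts, major_counts)
  abs_err <- fraction * rel_err
  (fraction - reference_fraction) > multiplier * abs_err
}

#' Running-mean convergence check for single-cell sampling depth
#'
#' Assesses whether enough cells of a population were measured: the
#' cumulative mean of the per-cell isotope fractions is tracked in measurement
#' order, and the adequate sample size is the smallest n after which the
#' relative change of the running mean stays below the threshold for every
#' subsequently added cell.
#'
#' @param fractions per-cell isotope fractions, in acquisition order (or a
#'   bootstrap reshuffle thereof).
#' @param threshold relative-change threshold (default 0.05).
#' @return list with `running_mean`, `rel_change` (NA for the first cell),
#'   `adequate_n` (NA if never reached or < 2 cells) and `converged`.
#' @export
convergence_check <- function(fractions, threshold = 0.05) {
  n <- length(fractions)
  if (n < 2L) {
    warning("fewer than 2 cells: convergence cannot be assessed")
    return(list(running_mean = fractions, rel_change = rep(NA_real_, n),
                adequate_n = NA_integer_, converged = FALSE))
  }
  run_mean <- cumsum(fractions) / seq_len(n)
  rel_change <- c(NA_real_, abs(diff(run_mean)) / abs(run_mean[-n]))
  ok <- rel_change < threshold
  ok[is.na(ok)] <- FALSE            # undefined change (mean 0) counts as unstable
  adequate_n <- NA_integer_
  for (k in 2:n) {
    if (all(ok[k:n])) { adequate_n <- k; break }
  }
  list(running_mean = run_mean, rel_change = rel_change,
       adequate_n = adequate_n, converged = !is.na(adequate_n))
}

#' Compare FISH-treated and untreated cell enrichments
#'
#' Rank-based (Wilcoxon rank-sum) two-sample comparison of single-cell
#' isotope fractions, used to test whether FISH treatment diluted the
#' isotopic signal. Robust for the small group sizes typical of nanoSIMS
#' datasets.
#'
#' @param treated,untreated numeric vectors of per-cell fractions; each group
#'   needs at least 3 cells.
#' @return list with `statistic`, `p_value`, `median_treated`,
#'   `median_untreated`, `median_difference`, or a flagged result when a group
#'   is too small or degenerate.
#' @export
fish_effect_compare <- function(treated, untreated) {
  if (length(treated) < 3L || length(untreated) < 3L) {
    warning("fewer than 3 cells in a group: comparison not performed")
    return(list(statistic = NA_real_, p_value = NA_real_,
                median_treated = stats::median(treated),
                median_untreated = stats::median(untreated),
                median_difference = NA_real_, flag = "insufficient_n"))
  }
  wt <- suppressWarnings(stats::wilcox.test(treated, untreated, exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_treated = stats::median(treated),
       median_untreated = stats::median(untreated),
       median_difference = stats::median(treated) - stats::median(untreated),
       flag = NA_character_)
}

#' Single-cell rate table from a long-format ROI count table
#'
#' Full per-cell pipeline: accumulate planes, compute isotope fractions and
#' Poisson errors for both isotope pairs, apply the QC filter, convert
#' geometry to biovolume and elemental contents, and compute N and C fixation
#' rates. An optional multiplicative FISH isotope-dilution correction hook is
#' provided but defaults to 1 (no correction).
#'
#' @param rois long-format data.frame: `cell_id`, `population`, `plane_index`,
#'   `species` (one of "15N", "14N", "13C", "12C"), `counts`.
#' @param geometry data.frame: `cell_id` (or `population` for cluster-formers
#'   measured per population), `width_um`, `length_um`.
#' @param at_excess_15N_medium,at_excess_13C_medium medium excess
#'   enrichments, atom%.
#' @param time_d incubation time, days.
#' @param cn_ratio molar C:N for nitrogen content (default 8.6).
#' @param qc_threshold Poisson relative-error QC threshold (default 0.05).
#' @param na_15n,na_13c natural-abundance atom% references.
#' @param fish_dilution_factor multiplicative correction applied to measured
#'   excesses (default 1: no isotope-dilution correction).
#' @return data.frame, one row per cell, with fractions, atom% excesses,
#'   Poisson errors, QC flags, geometry-derived contents and rates (fmol
#'   cell^-1 d^-1). Rates of QC-failing cells are reported but flagged via
#'   `passed_qc = FALSE`.
#' @export
cell_rate_table <- function(rois, geometry,
                            at_excess_15N_medium, at_excess_13C_medium,
                            time_d, cn_ratio = 8.6, qc_threshold = 0.05,
                            na_15n = NAT_ABUNDANCE_15N,
                            na_13c = NAT_ABUNDANCE_13C,
                            fish_dilution_factor = 1) {
  req <- c("cell_id", "population", "plane_index", "species", "counts")
  if (!all(req %in% names(rois)))
    stop("ROI table lacks columns: ", paste(setdiff(req, names(rois)), collapse = ", "))
  rows <- lapply(split(rois, rois$cell_id), function(cr) {
    wide <- do.call(cbind, lapply(c("15N", "14N", "13C", "12C"), function(sp) {
      sub <- cr[cr$species == sp, ]
      sub$counts[order(sub$plane_index)]
    }))
    colnames(wide) <- c("n15", "n14", "c13", "c12")
    acc <- accumulate_planes(wide)

    f15 <- isotope_fraction(acc[["n15"]], acc[["n14"]])
    f13 <- isotope_fraction(acc[["c13"]], acc[["c12"]])
    err_n <- ratio_poisson_error(acc[["n15"]], acc[["n14"]])
    err_c <- ratio_poisson_error(acc[["c13"]], acc[["c12"]])
    qc_n <- err_n < qc_threshold
    qc_c <- err_c < qc_threshold

    geo <- geometry[!is.na(geometry$cell_id) & geometry$cell_id == cr$cell_id[1], ]
    if (nrow(geo) == 0L && "population" %in% names(geometry))
      geo <- geometry[!is.na(geometry$population) &
                        geometry$population == cr$population[1], ]
    if (nrow(geo) == 0L)
      stop("no geometry for cell ", cr$cell_id[1])
    bv <- biovolume(geo$width_um[1], geo$length_um[1])
    c_cell <- carbon_content(bv)
    n_cell <- nitrogen_content(c_cell, cn_ratio)

    ex_n <- max(100 * f15 - na_15n, 0) * fish_dilution_factor
    ex_c <- max(100 * f13 - na_13c, 0) * fish_dilution_factor
    data.frame(cell_id = cr$cell_id[1], population = cr$population[1],
               n_planes = nrow(wide),
               fraction_15N = f15, fraction_13C = f13,
               at_excess_15N = ex_n, at_excess_13C = ex_c,
               poisson_error_N = err_n, poisson_error_C = err_c,
               passed_qc_N = qc_n, passed_qc_C = qc_c,
               passed_qc = qc_n && qc_c,
               enriched_15N = is_significantly_enriched(f15, na_15n / 100,
                                                        acc[["n15"]], acc[["n14"]]),
               biovolume_um3 = bv, c_content_fmol = c_cell,
               n_content_fmol = n_cell,
               rate_N_fmol_d = cell_rate(ex_n, at_excess_15N_medium, n_cell, time_d),
               rate_C_fmol_d = cell_rate(ex_c, at_excess_13C_medium, c_cell, time_d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Equivalent-ellipse cell dimensions from an ROI pixel outline
#'
#' For single (non-cluster-forming) cells whose geometry is taken from the
#' nanoSIMS ROI itself rather than from epifluorescence images: width and
#' length are the minor and major axis lengths of the ellipse with the same
#' second moments as the ROI pixel set.
#'
#' @param x,y pixel coordinates of the ROI, in um.
#' @return list with `width_um`, `length_um` (minor/major axes).
#' @export
roi_equivalent_ellipse <- function(x, y) {
  if (length(x) < 3L || length(y) != length(x))
    stop("need at least 3 ROI pixels")
  cv <- stats::cov(cbind(x, y))
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values)
  # full axis length of the equal-second-moment ellipse: 4*sqrt(eigenvalue)
  list(width_um = 4 * sqrt(max(ev[1], 0)), length_um = 4 * sqrt(max(ev[2], 0)))
}
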