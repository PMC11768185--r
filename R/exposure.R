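# Non-compartmental exposure metrics and compartment aggregation.

#' Area under the curve to the last time point
#'
#' Linear-up/log-down trapezoid: linear rule where the concentration is
#' rising, flat, or touches zero; log-trapezoid on strictly declining
#' positive intervals. Exact for piecewise-linear rising data.
#'
#' @param time strictly increasing times, min (>= 2 points).
#' @param conc concentrations, umol/L (>= 0).
#' @return AUC, umol*min/L.
#' @export
auc_0_t <- function(time, conc) {
  if (length(time) < 2L) stop("need at least 2 points")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  dt <- diff(time)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  lin <- dt * (c1 + c2) / 2
  dn <- c2 < c1 & c2 > 0
  lin[dn] <- dt[dn] * (c1[dn] - c2[dn]) / log(c1[dn] / c2[dn])
  sum(lin)
}

#' Terminal slope by best-tail log-linear regression
#'
#' Unweighted regression of log concentration on time over the terminal
#' tail; all candidate tails of >= `min_points` points ending at the last
#' positive observation (and starting after Cmax) are tried and the tail
#' maximising the adjusted R-squared is kept.
#'
#' @param time,conc profile (conc >= 0).
#' @param min_points minimum tail length (default 3).
#' @return List `lambda_z` (1/min), `intercept` (log conc), `n_tail`,
#'   `adj_r2`.
#' @export
terminal_slope <- function(time, conc, min_points = 3L) {
  pos <- conc > 0
  if (sum(pos) < min_points) stop("no terminal decline: too few positive points")
  t <- time[pos]; c <- conc[pos]
  i_max <- which.max(c)
  last <- length(c)
  starts <- seq_len(max(last - min_points + 1L, 0L))
  after_cmax <- starts[starts > i_max]
  starts <- if (length(after_cmax) > 0) after_cmax else starts[starts >= i_max]
  if (length(starts) < 1L) stop("no terminal decline")
  best <- NULL
  for (s in starts) {
    idx <- s:last
    fit <- lm(log(c[idx]) ~ t[idx])
    lz <- -unname(coef(fit)[2])
    if (!is.finite(lz) || lz <= 0) next
    # adjusted R-squared, computed directly (tails can fit exactly)
    yy <- log(c[idx])
    sst <- sum((yy - mean(yy))^2)
    ar2 <- if (sst == 0) 1 else {
      r2 <- 1 - sum(fit$residuals^2) / sst
      1 - (1 - r2) * (length(idx) - 1) / (length(idx) - 2)
    }
    if (is.null(best) || isTRUE(ar2 > best$adj_r2)) {
      best <- list(lambda_z = lz, intercept = unname(coef(fit)[1]),
                   n_tail = length(idx), adj_r2 = ar2)
    }
  }
  if (is.null(best)) stop("no terminal decline")
  best
}

#' AUC extrapolated to infinity
#'
#' `auc_0_t + C_last / lambda_z` with the terminal slope from
#' [terminal_slope()]. An all-zero profile returns zero exposure; a profile
#' with no terminal decline is an error.
#'
#' @inheritParams auc_0_t
#' @param min_points minimum tail length for the terminal regression.
#' @return List with `auc_0_t`, `auc_inf`, `extrapolated_fraction`,
#'   `lambda_z`, `cmax`, `tmax` (an `exposure_summary`).
#' @export
auc_inf <- function(time, conc, min_points = 3L) {
  a0 <- auc_0_t(time, conc)
  cm <- cmax(time, conc)
  if (all(conc == 0)) {
    return(structure(list(auc_0_t = 0, auc_inf = 0,
                          extrapolated_fraction = 0, lambda_z = NA_real_,
                          cmax = 0, tmax = cm$tmax),
                     class = "exposure_summary"))
  }
  ts <- terminal_slope(time, conc, min_points)
  c_last <- conc[max(which(conc > 0))]
  ainf <- a0 + c_last / ts$lambda_z
  structure(list(auc_0_t = a0, auc_inf = ainf,
                 extrapolated_fraction = (ainf - a0) / ainf,
                 lambda_z = ts$lambda_z, cmax = cm$cmax, tmax = cm$tmax),
            class = "exposure_summary")
}

#' Maximum concentration
#' @inheritParams auc_0_t
#' @return List `cmax`, `tmax` (earliest time attaining the maximum).
#' @export
cmax <- function(time, conc) {
  if (length(time) < 1L) stop("empty profile")
  i <- which.max(conc)          # which.max returns the first maximum
  list(cmax = conc[i], tmax = time[i])
}

#' Hematocrit-weighted vascular exposure
#'
#' Blood (vascular) AUC as the hematocrit-weighted mean of the blood-cell
#' and plasma AUCs: `hct * auc_blood_cells + (1 - hct) * auc_plasma`.
#'
#' @param auc_blood_cells,auc_plasma component AUCs (>= 0), umol*min/L.
#' @param hematocrit in (0, 1); 0.47 by default.
#' @return Vascular AUC, umol*min/L.
#' @export
vascular_auc <- function(auc_blood_cells, auc_plasma, hematocrit = 0.47) {
  if (any(auc_blood_cells < 0) || any(auc_plasma < 0)) {
    abort_field("auc", "component AUCs must be >= 0")
  }
  if (any(hematocrit <= 0) || any(hematocrit >= 1)) {
    abort_field("hematocrit", "must be in (0, 1)")
  }
  hematocrit * auc_blood_cells + (1 - hematocrit) * auc_plasma
}

#' Composition-weighted total tissue exposure
#'
#' Total-organ AUC as the volume-fraction-weighted mean of the vascular,
#' interstitial and intracellular AUCs. The default fractions are the colon
#' values 0.13 (vascular), 0.73 (interstitial) and 0.14 (intracellular).
#'
#' @param auc_vascular,auc_interstitial,auc_intracellular component AUCs.
#' @param fractions length-3 vector (vascular, interstitial, intracellular)
#'   summing to 1.
#' @return Total tissue AUC, umol*min/L.
#' @export
total_tissue_auc <- function(auc_vascular, auc_interstitial,
                             auc_intracellular,
                             fractions = c(0.13, 0.73, 0.14)) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort_field("fractions", "must sum to 1")
  }
  fractions[1] * auc_vascular + fractions[2] * auc_interstitial +
    fractions[3] * auc_intracellular
}

#' Colon exposure report
#'
#' AUC_inf per colon segment for the blood-cell, plasma, interstitial and
#' intracellular sub-compartments, with the derived vascular
#' (hematocrit-weighted) and total (volume-fraction-weighted) columns, plus
#' a venous-plasma row and the colon/plasma exposure ratio.
#'
#' @param result a `simulation_result` containing the four colon segments.
#' @param compound compound id.
#' @param min_points terminal-tail minimum for the extrapolation.
#' @return data.frame with one row per colon segment (and one venous-plasma
#'   row): columns `segment`, `blood_cells`, `plasma`, `vascular`,
#'   `interstitial`, `intracellular`, `total`, `colon_plasma_ratio`.
#' @export
colon_exposure_report <- function(result, compound, min_points = 3L) {
  segs <- colon_segments()
  have <- unique(result$model$layout$organ)
  missing <- setdiff(segs, have)
  if (length(missing) > 0) {
    stop(sprintf("missing colon segment(s): %s",
                 paste(missing, collapse = ", ")))
  }
  h <- result$model$individual$hematocrit
  org <- result$model$individual$organs
  venous <- get_profile(result, compound, "venous_blood", "plasma")
  auc_ven <- auc_inf(venous$time, venous$conc, min_points)$auc_inf
  rows <- lapply(segs, function(s) {
    a <- vapply(c("blood_cells", "plasma", "interstitial", "intracellular"),
                function(sub) {
                  pr <- get_profile(result, compound, s, sub)
                  auc_inf(pr$time, pr$conc, min_points)$auc_inf
                }, numeric(1))
    fr <- unlist(org[org$organ == s,
                     c("frac_vascular", "frac_interstitial",
                       "frac_intracellular")])
    vas <- vascular_auc(a[["blood_cells"]], a[["plasma"]], h)
    tot <- total_tissue_auc(vas, a[["interstitial"]], a[["intracellular"]],
                            fractions = unname(fr))
    data.frame(segment = s, blood_cells = a[["blood_cells"]],
               plasma = a[["plasma"]], vascular = vas,
               interstitial = a[["interstitial"]],
               intracellular = a[["intracellular"]], total = tot,
               colon_plasma_ratio = tot / auc_ven,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(segment = "venous_plasma", blood_cells = NA,
                               plasma = auc_ven, vascular = NA,
                               interstitial = NA, intracellular = NA,
                               total = NA, colon_plasma_ratio = NA,
                               stringsAsFactors = FALSE))
  out
}
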