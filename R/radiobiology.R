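#' Oxygen-dependent cell-survival parameters
#'
#' Linear-quadratic parameters for the beta emitter (177Lu) and the
#' log-linear `D0` for the alpha emitter (225Ac), anchored at two
#' oxygenation states: physoxic tissue (`P >= 15` mmHg) and
#' radiobiologically hypoxic tissue (`P < 3` mmHg). Hypoxic cells are
#' radioresistant: lower `alpha` and `beta`, higher `D0`.
#'
#' The two intermediate oxygenation classes have no tabulated parameters;
#' by default `alpha`, `beta`, and `1/D0` are interpolated linearly in the
#' local oxygen tension between the anchors at 3 and 15 mmHg (clamped
#' outside), with a `class_step` mode (anchor values only, switching at
#' 3 mmHg) available for sensitivity analysis.
#'
#' @param alpha_phys,alpha_hyp Linear coefficients, 1/Gy.
#' @param beta_phys,beta_hyp Quadratic coefficients, 1/Gy^2.
#' @param D0_phys,D0_hyp Mean lethal dose of the log-linear alpha model, Gy.
#' @param interpolation `"linear_in_pO2"` (default) or `"class_step"`.
#' @param anchors_mmHg Oxygen tensions of the hypoxic and physoxic anchors.
#' @return An object of class `lq_params`.
#' @export
lq_params <- function(alpha_phys = 0.15, alpha_hyp = 0.107,
                      beta_phys = 0.048, beta_hyp = 0.024,
                      D0_phys = 0.7, D0_hyp = 1.18,
                      interpolation = c("linear_in_pO2", "class_step"),
                      anchors_mmHg = c(3, 15)) {
  interpolation <- match.arg(interpolation)
  stopifnot(alpha_phys >= 0, alpha_hyp >= 0, beta_phys >= 0, beta_hyp >= 0,
            D0_phys > 0, D0_hyp > 0,
            alpha_hyp <= alpha_phys, beta_hyp <= beta_phys,
            D0_hyp >= D0_phys, anchors_mmHg[1] < anchors_mmHg[2])
  structure(
    list(alpha_phys = alpha_phys, alpha_hyp = alpha_hyp,
         beta_phys = beta_phys, beta_hyp = beta_hyp,
         D0_phys = D0_phys, D0_hyp = D0_hyp,
         interpolation = interpolation, anchors_mmHg = anchors_mmHg),
    class = "lq_params"
  )
}

#' Linear-quadratic cell survival
#'
#' `PS = exp(-alpha * D - beta * D^2)`, the survival model for low-LET
#' (beta) irradiation.
#'
#' @param D Absorbed dose, Gy (`>= 0`; vectorized).
#' @param alpha Linear coefficient, 1/Gy.
#' @param beta Quadratic coefficient, 1/Gy^2.
#' @return Survival probability in `(0, 1]`.
#' @export
survival_lq <- function(D, alpha, beta) {
  if (any(D < 0, na.rm = TRUE)) stop("dose must be non-negative")
  exp(-alpha * D - beta * D^2)
}

#' Log-linear cell survival for high-LET alpha irradiation
#'
#' `PS = exp(-D / D0)`, where `D0` is the dose yielding 37% survival.
#'
#' @param D Absorbed dose, Gy (`>= 0`; vectorized).
#' @param D0 Mean lethal dose, Gy (`> 0`).
#' @return Survival probability in `(0, 1]`.
#' @export
survival_alpha <- function(D, D0) {
  if (any(D0 <= 0, na.rm = TRUE)) stop("D0 must be positive")
  if (any(D < 0, na.rm = TRUE)) stop("dose must be non-negative")
  exp(-D / D0)
}

#' Assign oxygen-dependent survival parameters per pixel
#'
#' @param P Oxygen tension, mmHg (matrix or vector; `NA` allowed on vessel
#'   pixels).
#' @param params An [lq_params()].
#' @param interpolation Override of the mode stored in `params`.
#' @return A list of `alpha`, `beta`, `D0` with the shape of `P`.
#' @export
assign_lq_parameters <- function(P, params = lq_params(),
                                 interpolation = params$interpolation) {
  if (any(P < 0, na.rm = TRUE)) stop("oxygen tension must be non-negative")
  if (!interpolation %in% c("linear_in_pO2", "class_step")) {
    stop("unknown interpolation mode: ", interpolation)
  }
  a <- params$anchors_mmHg
  w <- if (interpolation == "linear_in_pO2") {
    pmin(pmax((P - a[1]) / (a[2] - a[1]), 0), 1)
  } else {
    (P >= a[1]) * 1
  }
  alpha <- params$alpha_hyp + w * (params$alpha_phys - params$alpha_hyp)
  beta <- params$beta_hyp + w * (params$beta_phys - params$beta_hyp)
  inv_d0 <- 1 / params$D0_hyp + w * (1 / params$D0_phys - 1 / params$D0_hyp)
  list(alpha = alpha, beta = beta, D0 = 1 / inv_d0)
}

#' Per-voxel cell survival map
#'
#' Applies the linear-quadratic model (177Lu) or the log-linear alpha
#' model (225Ac) pixel-wise, with survival parameters assigned from the
#' local oxygen tension.
#'
#' @param dose A [compute_dose()] result.
#' @param P Oxygen tension matrix on the same grid (mmHg, `NA` on vessel
#'   pixels), e.g. the `P` field of [solve_oxygen()].
#' @param nuclide `"Lu177"` or `"Ac225"`.
#' @param params An [lq_params()].
#' @param seg Optional [segment_tissue()] result for per-class summaries.
#' @return An object of class `survival_map`: `PS` matrix (`NA` on vessel
#'   pixels), `mean`, `sd` over tissue pixels, and optionally
#'   `class_summary`.
#' @export
survival_map <- function(dose, P, nuclide = c("Lu177", "Ac225"),
                         params = lq_params(), seg = NULL) {
  nuclide <- match.arg(nuclide)
  stopifnot(inherits(dose, "dose_map"))
  if (!all(dim(dose$D) == dim(P))) stop("dose/oxygen grid mismatch")
  lp <- assign_lq_parameters(P, params)
  PS <- if (nuclide == "Lu177") {
    survival_lq(dose$D, lp$alpha, lp$beta)
  } else {
    survival_alpha(dose$D, lp$D0)
  }
  PS[is.na(P)] <- NA_real_
  out <- list(PS = PS, nuclide = nuclide,
              mean = mean(PS, na.rm = TRUE),
              sd = stats::sd(as.numeric(PS), na.rm = TRUE))
  if (!is.null(seg)) {
    out$class_summary <- do.call(rbind, lapply(seg$classes, function(cl) {
      v <- PS[!is.na(seg$labels) & seg$labels == cl]
      data.frame(class = cl, mean_PS = mean(v), sd_PS = stats::sd(v),
                 n = length(v))
    }))
  }
  structure(out, class = "survival_map")
}

#' @export
print.survival_map <- function(x, ...) {
  cat(sprintf("survival_map (%s): mean PS %.3g (sd %.3g)\n",
              x$nuclide, x$mean, x$sd))
  invisible(x)
}
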