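#' Parameters of the tissue oxygenation model
#'
#' Oxygen tension `P` (mmHg) obeys a reaction-diffusion equation,
#' `dP/dt = div(D_O2 grad P) - M0 * P / (P + P0)`, with Michaelis-Menten
#' consumption on tissue and a permeability flux `J_O2 = L_O2 * (P_ie - P)`
#' across vessel walls. Defaults are literature values for tumor tissue.
#'
#' @param L_O2 Vessel-wall permeability to oxygen, cm/s.
#' @param D_O2 Oxygen diffusivity, cm^2/s.
#' @param P_ie Intraerythrocyte oxygen tension, mmHg.
#' @param M0 Maximum consumption rate, mmHg/s (`>= 0`; `0` turns
#'   consumption off, a useful analytic limit).
#' @param P0 Michaelis-Menten coefficient, mmHg.
#' @return An object of class `oxygen_params`.
#' @export
oxygen_params <- function(L_O2 = 4.1e-2, D_O2 = 2.0e-5, P_ie = 40,
                          M0 = 15, P0 = 2.0) {
  stopifnot(L_O2 > 0, D_O2 > 0, P_ie > 0, M0 >= 0, P0 > 0)
  structure(list(L_O2 = L_O2, D_O2 = D_O2, P_ie = P_ie, M0 = M0, P0 = P0),
            class = "oxygen_params")
}

#' McKeown oxygenation class thresholds (mmHg)
#'
#' Band edges 40/15/8/3 mmHg delimiting physoxia, physiological hypoxia,
#' pathological hypoxia, and radiobiological hypoxia.
#' @export
hypoxia_thresholds <- c(physoxia = 40, physiological = 15,
                        pathological = 8, radiobiological = 3)

#' Solve the steady-state oxygen reaction-diffusion equation
#'
#' Computes the quasi-static oxygen tension field on the tissue subdomain
#' of a vessel map by damped Picard (fixed-point) iteration on the
#' nonlinear steady problem: at each iterate the Michaelis-Menten rate is
#' frozen at the current field and the resulting linear SPD system (5-point
#' Laplacian, Robin vessel-wall flux, no-flux outer edges) is solved with a
#' sparse Cholesky factorization whose symbolic analysis is reused across
#' iterations.
#'
#' Stationarity is declared when the instantaneous temporal variation of
#' the solution, `|dP/dt| / max(P, P0)` evaluated pixel-wise from the PDE
#' right-hand side, falls below `criterion` everywhere (default 0.1% per
#' second).
#'
#' @param map A [vessel_map()] with at least one vessel pixel.
#' @param params An [oxygen_params()].
#' @param criterion Stationarity threshold on the normalized residual
#'   rate, 1/s.
#' @param max_iter Iteration safety cap.
#' @return An object of class `oxygen_field`: `P` (matrix, mmHg, `NA` on
#'   vessel pixels), `converged`, `residual_rate` (1/s), `iterations`,
#'   `params`, and `flux_balance` (total wall influx and consumption,
#'   mmHg/s summed over tissue pixels).
#' @examples
#' vm <- generate_synthetic_map(synthetic_vessel_spec(0.02, seed = 1),
#'                              shape = c(64, 64), pixel_size_um = 25)
#' ox <- solve_oxygen(vm)
#' ox$converged
#' @export
solve_oxygen <- function(map, params = oxygen_params(), criterion = 1e-3,
                         max_iter = 200L) {
  stopifnot(inherits(map, "vessel_map"), criterion > 0)
  op <- tissue_operator(map, D = params$D_O2, L_perm = params$L_O2)
  b0 <- op$robin * params$P_ie

  P <- rep(params$P_ie, op$n)
  ch <- NULL
  theta <- 1
  res <- Inf
  iter <- 0L
  residual_rate <- function(P) {
    # dP/dt = -(A0 P - b0) - M0 P/(P+P0); A0 holds -D Lap + robin
    rate <- b0 - as.numeric(op$A0 %*% P) - params$M0 * P / (P + params$P0)
    max(abs(rate) / pmax(P, params$P0))
  }
  while (iter < max_iter) {
    iter <- iter + 1L
    mm <- params$M0 / (P + params$P0)
    A <- op$A0 + Matrix::Diagonal(op$n, x = mm)
    ch <- if (is.null(ch)) Matrix::Cholesky(A) else Matrix::update(ch, A)
    P_new <- as.numeric(Matrix::solve(ch, b0))
    P_try <- theta * P_new + (1 - theta) * P
    res_try <- residual_rate(P_try)
    if (res_try > res && theta > 0.125) {
      theta <- theta / 2
      P_try <- theta * P_new + (1 - theta) * P
      res_try <- residual_rate(P_try)
    }
    P <- P_try
    res <- res_try
    if (res <= criterion) break
  }
  if (res > criterion) {
    stop(sprintf(
      "oxygen solver did not reach stationarity in %d iterations (residual rate %.3g /s > %.3g /s)",
      max_iter, res, criterion))
  }
  influx <- sum(op$robin * (params$P_ie - P))
  consumption <- sum(params$M0 * P / (P + params$P0))
  structure(
    list(
      P = tissue_to_matrix(op, P),
      converged = TRUE,
      residual_rate = res,
      iterations = iter,
      criterion = criterion,
      params = params,
      flux_balance = c(influx = influx, consumption = consumption)
    ),
    class = "oxygen_field"
  )
}

#' @export
print.oxygen_field <- function(x, ...) {
  cat(sprintf(
    "oxygen_field: median pO2 %.2f mmHg, converged in %d iterations (residual %.2g /s)\n",
    stats::median(x$P, na.rm = TRUE), x$iterations, x$residual_rate))
  invisible(x)
}

#' Segment tissue into McKeown oxygenation classes
#'
#' Classifies each tissue pixel of a converged oxygen field by its steady
#' oxygen tension: physoxia (`P >= 15`, including the rare near-vessel
#' values above 40), physiological hypoxia (`[8, 15)`), pathological
#' hypoxia (`[3, 8)`), and radiobiological hypoxia (`P < 3`). Bands are
#' half-open: a boundary value belongs to the class whose lower bound it
#' is. Vessel pixels are labelled `"vessel"` and excluded from class
#' fractions.
#'
#' @param field A converged [solve_oxygen()] result.
#' @param map The [vessel_map()] the field was solved on.
#' @return An object of class `tissue_segmentation`: `labels` (character
#'   matrix), `class_fractions` (named vector over tissue pixels, summing
#'   to 1), and `thresholds`.
#' @export
segment_tissue <- function(field, map) {
  stopifnot(inherits(field, "oxygen_field"), inherits(map, "vessel_map"))
  if (!isTRUE(field$converged)) stop("oxygen field has not converged")
  P <- field$P
  stopifnot(all(dim(P) == dim(map$mask)))
  labels <- matrix(NA_character_, nrow(P), ncol(P))
  labels[map$mask] <- "vessel"
  tis <- !map$mask
  pv <- P[tis]
  cls <- ifelse(pv >= 15, "physoxia",
         ifelse(pv >= 8, "physiological_hypoxia",
         ifelse(pv >= 3, "pathological_hypoxia", "radiobiological_hypoxia")))
  labels[tis] <- cls
  lev <- c("physoxia", "physiological_hypoxia", "pathological_hypoxia",
           "radiobiological_hypoxia")
  fr <- vapply(lev, function(l) mean(cls == l), numeric(1))
  structure(
    list(labels = labels, class_fractions = fr,
         thresholds = hypoxia_thresholds, classes = lev),
    class = "tissue_segmentation"
  )
}

#' @export
print.tissue_segmentation <- function(x, ...) {
  cat("tissue_segmentation (fractions over tissue pixels):\n")
  print(round(x$class_fractions, 4))
  invisible(x)
}

#' Summary statistics of a tissue oxygenation simulation
#'
#' @param field A converged [solve_oxygen()] result.
#' @param seg The matching [segment_tissue()] result.
#' @return A list with `median_po2` (mmHg, over tissue pixels),
#'   `mean_po2`, and `class_fractions`.
#' @export
oxygen_statistics <- function(field, seg) {
  stopifnot(inherits(field, "oxygen_field"),
            inherits(seg, "tissue_segmentation"))
  pv <- field$P[!is.na(field$P)]
  list(
    median_po2 = stats::median(pv),
    mean_po2 = mean(pv),
    class_fractions = seg$class_fractions
  )
}
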