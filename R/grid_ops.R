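# Sparse finite-difference operators on the tissue subdomain.
#
# Tissue pixels (non-vessel) carry the simulated fields; vessel pixels are
# holes in the mesh. The 5-point Laplacian couples tissue-tissue neighbor
# pairs; faces shared with vessel pixels carry a Robin (permeability) term
# L/h per face; faces on the domain edge are no-flux.
#
# tissue_operator() returns, for diffusivity D (cm^2/s) and wall
# permeability L (cm/s):
#   L_op      : n x n sparse PSD matrix, -D*Lap (tissue-tissue coupling
#               only, no-flux edges)                                 [1/s]
#   A0        : L_op + diag(robin), the steady-transport operator    [1/s]
#   robin     : per-pixel vessel-face rate, n_faces * L / h          [1/s]
#   index     : linear pixel index (into the nr x nc grid) of each tissue dof
#   n, h_cm   : dof count and pixel size in cm

tissue_operator <- function(map, D, L_perm) {
  stopifnot(inherits(map, "vessel_map"))
  V <- map$mask
  if (!any(V)) stop("domain is source-free: vessel map has no vessel pixel")
  Tm <- !V
  nr <- nrow(V); nc <- ncol(V)
  h_cm <- map$pixel_size_um * 1e-4
  idm <- matrix(0L, nr, nc)
  n <- sum(Tm)
  if (n == 0L) stop("vessel map has no tissue pixel")
  idm[Tm] <- seq_len(n)

  # tissue-tissue neighbor pairs (each pair once: down and right shifts)
  a_d <- idm[-nr, , drop = FALSE]; b_d <- idm[-1, , drop = FALSE]
  sel <- a_d > 0L & b_d > 0L
  pi_ <- a_d[sel]; pj_ <- b_d[sel]
  a_r <- idm[, -nc, drop = FALSE]; b_r <- idm[, -1, drop = FALSE]
  sel <- a_r > 0L & b_r > 0L
  pi_ <- c(pi_, a_r[sel]); pj_ <- c(pj_, b_r[sel])

  # vessel-adjacent face count per tissue pixel
  nv <- matrix(0L, nr, nc)
  nv[-nr, ] <- nv[-nr, ] + (Tm[-nr, ] & V[-1, ])
  nv[-1, ]  <- nv[-1, ]  + (Tm[-1, ]  & V[-nr, ])
  nv[, -nc] <- nv[, -nc] + (Tm[, -nc] & V[, -1])
  nv[, -1]  <- nv[, -1]  + (Tm[, -1]  & V[, -nc])
  nfaces <- nv[Tm]

  w <- D / h_cm^2
  deg <- tabulate(c(pi_, pj_), nbins = n)
  # wall conductance in series with the half-cell diffusion resistance
  # (finite-volume correction; restores near-second-order convergence of
  # the wall flux under grid refinement)
  L_eff <- 1 / (1 / L_perm + h_cm / (2 * D))
  robin <- nfaces * L_eff / h_cm

  L_op <- Matrix::sparseMatrix(
    i = c(seq_len(n), pmin(pi_, pj_)),
    j = c(seq_len(n), pmax(pi_, pj_)),
    x = c(deg * w, rep(-w, length(pi_))),
    dims = c(n, n), symmetric = TRUE
  )
  list(L_op = L_op, A0 = L_op + Matrix::Diagonal(n, x = robin),
       robin = robin, index = which(Tm), n = n, h_cm = h_cm,
       dim = c(nr, nc))
}

# Expand a vector on tissue dofs to a full nr x nc matrix (vessel pixels
# get `fill`).
tissue_to_matrix <- function(op, x, fill = NA_real_) {
  m <- matrix(fill, op$dim[1], op$dim[2])
  m[op$index] <- x
  m
}
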