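# Macroscopic photon dose stage: Monte Carlo transport on the voxel grid
# with Woodcock (delta) tracking, photoelectric absorption and Klein-Nishina
# incoherent scattering, kerma scoring (energy transferred is deposited at
# the interaction site; electron transport is deferred to the microbeam
# profile reconstruction stage).  The microbeam structure itself is NOT
# simulated here: the fluence through the aperture is scaled by the
# collimator's mean transmittance, matching the unit-period-mean convention
# of the fluence pattern.

KEV_TO_J <- 1.602176634e-16

# precomputed per-(material, energy-bin) lookup tables for one engine run
engine_tables <- function(phantom, geometry, spectrum) {
  mats <- sort(unique(as.vector(phantom$material)))
  e <- spectrum$energy_kev
  emin <- 10
  emax <- max(e)
  egrid <- seq(emin, emax)
  nE <- length(egrid)
  mu_tot <- mu_kn <- mu_pe <- mu_tr <- matrix(0, nE, length(mats))
  for (j in seq_along(mats)) {
    tab <- mass_attenuation(mats[j], egrid)                 # cm^2/g
    kn <- kn_mu_over_rho(mats[j], egrid)
    kn <- pmin(kn, tab)        # keep KN within the tabulated total
    pe <- tab - kn
    f_tr <- kn_mean_transfer_fraction(egrid)
    mu_tot[, j] <- tab
    mu_kn[, j] <- kn
    mu_pe[, j] <- pe
    mu_tr[, j] <- pe + kn * f_tr
  }
  mat_idx <- array(match(phantom$material, mats), dim = dim(phantom$density))
  max_rho <- vapply(seq_along(mats),
                    function(j) max(phantom$density[mat_idx == j]), numeric(1))
  # majorant linear attenuation per energy bin, 1/mm
  mu_max <- apply(sweep(mu_tot, 2, max_rho, `*`), 1, max) / 10
  # mean aperture transmittance per energy bin (duty cycle + septum leakage)
  col <- geometry$collimator
  centers <- slit_centers_mm(col, geometry$field_mm[1])
  duty <- length(centers) * col$slit_um / 1000 / geometry$field_mm[1]
  duty <- min(duty, 1)
  leak <- vapply(egrid, function(E) collimator_leakage(col, E), numeric(1))
  wbar <- duty + (1 - duty) * leak
  list(mats = mats, egrid = egrid, emin = emin, nE = nE,
       mu_tot = mu_tot, mu_kn = mu_kn, mu_pe = mu_pe, mu_tr = mu_tr,
       mat_idx = mat_idx, mu_max = mu_max, wbar = wbar, duty = duty)
}

# vectorised Kahn sampling of x = E/E' for Compton scattering
sample_kahn <- function(alpha) {
  n <- length(alpha)
  x <- numeric(n)
  todo <- seq_len(n)
  p1 <- (1 + 2 * alpha) / (9 + 2 * alpha)
  while (length(todo)) {
    a <- alpha[todo]
    r1 <- runif(length(todo)); r2 <- runif(length(todo)); r3 <- runif(length(todo))
    b1 <- r1 <= p1[todo]
    xx <- ifelse(b1, 1 + 2 * a * r2, (1 + 2 * a) / (1 + 2 * a * r2))
    ct <- 1 - (xx - 1) / a
    ok <- ifelse(b1, r3 <= 4 * (1 / xx - 1 / xx^2), r3 <= 0.5 * (ct^2 + 1 / xx))
    x[todo[ok]] <- xx[ok]
    todo <- todo[!ok]
  }
  x
}

# rotate unit direction (u, v, w) by polar angle with cosine ct and uniform
# azimuth phi
rotate_direction <- function(u, v, w, ct, phi) {
  st <- sqrt(pmax(0, 1 - ct^2))
  cp <- cos(phi); sp <- sin(phi)
  denom <- sqrt(pmax(1e-20, 1 - w^2))
  near_axis <- abs(w) > 0.999999
  u2 <- u * ct + st * (u * w * cp - v * sp) / denom
  v2 <- v * ct + st * (v * w * cp + u * sp) / denom
  w2 <- w * ct - denom * st * cp
  # photons travelling almost exactly along +/-z
  u2[near_axis] <- (st * cp)[near_axis]
  v2[near_axis] <- (st * sp)[near_axis]
  w2[near_axis] <- (sign(w) * ct)[near_axis]
  nrm <- sqrt(u2^2 + v2^2 + w2^2)
  list(u = u2 / nrm, v = v2 / nrm, w = w2 / nrm)
}

#' Monte Carlo photon dose on the voxel grid
#'
#' Samples photon histories from the focal spot and tube spectrum, directs
#' them through the field aperture (fluence scaled by the collimator's mean
#' transmittance), and transports them through the phantom with Woodcock
#' tracking.  Physics: photoelectric absorption and incoherent
#' (Klein-Nishina) scattering; coherent scattering is omitted.  Energy
#' transferred to electrons is scored at the interaction site (kerma
#' approximation).  Dose deposited at a photon's first interaction is scored
#' as primary, all later interactions as scatter.
#'
#' @param phantom A [voxel_phantom()].
#' @param geometry A [beam_geometry()].
#' @param spectrum An [generate_spectrum()] result.
#' @param n_histories Number of photon histories (>= 1).
#' @param seed Integer seed; the same seed and inputs give bit-identical
#'   output.
#' @param gap_mm Distance from the collimator exit plane to the phantom
#'   entrance, mm.  The air gap is treated as non-attenuating.
#' @param batches Number of batches used for the statistical uncertainty
#'   estimate.
#' @return An object of class `photon_dose_grid`: arrays `d_primary` and
#'   `d_scatter` in Gy per history, `rel_uncertainty` (relative standard
#'   error of the total dose), and metadata (`n_histories`, `seed`,
#'   `gap_mm`, `voxel_mm`).
#' @export
#' @examples
#' ph <- make_slab_phantom(c(30, 30, 20), "pmma", voxel_mm = 2)
#' sp <- generate_spectrum(225, 1)
#' dg <- simulate_photon_dose(ph, beam_geometry(), sp, 2e4, seed = 1)
simulate_photon_dose <- function(phantom, geometry, spectrum, n_histories,
                                 seed, gap_mm = 4, batches = 10) {
  if (prod(dim(phantom$density)) == 0) abort("empty phantom")
  if (n_histories < 1) abort("`n_histories` must be >= 1")
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  set.seed(as.integer(seed))

  tb <- engine_tables(phantom, geometry, spectrum)
  dims <- dim(phantom$density)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  vox <- phantom$voxel_mm
  x0 <- -nx * vox / 2; y0 <- -ny * vox / 2
  z_entry <- geometry$sd_mm + gap_mm
  rho_vec <- as.vector(phantom$density)
  mat_vec <- as.vector(tb$mat_idx)
  nvox <- length(rho_vec)
  emin <- tb$emin

  sigma <- geometry$focal_spot$sigma_mm
  fx <- geometry$field_mm[1]; fy <- geometry$field_mm[2]
  sd_mm <- geometry$sd_mm

  prim_sum <- numeric(nvox); scat_sum <- numeric(nvox)
  tot_batch_sum <- numeric(nvox); tot_batch_sq <- numeric(nvox)

  per_batch <- rep(floor(n_histories / batches), batches)
  per_batch[batches] <- n_histories - sum(per_batch[-batches])

  for (b in seq_len(batches)) {
    n <- per_batch[b]
    if (n == 0) next
    # --- source and aperture sampling ---------------------------------
    ebin <- sample.int(length(spectrum$energy_kev), n, replace = TRUE,
                       prob = spectrum$fluence)
    E <- spectrum$energy_kev[ebin]
    eb <- pmin(pmax(as.integer(round(E)) - emin + 1L, 1L), tb$nE)
    w <- tb$wbar[eb]
    sx <- if (sigma > 0) rnorm(n, sd = sigma) else numeric(n)
    sy <- if (sigma > 0) rnorm(n, sd = sigma) else numeric(n)
    ax <- runif(n, -fx / 2, fx / 2)
    ay <- runif(n, -fy / 2, fy / 2)
    nn <- sqrt((ax - sx)^2 + (ay - sy)^2 + sd_mm^2)
    du <- (ax - sx) / nn; dv <- (ay - sy) / nn; dw <- sd_mm / nn
    t_entry <- z_entry / dw
    px <- sx + du * t_entry; py <- sy + dv * t_entry
    pz <- rep(z_entry, n)
    # nudge inside the first slab so the entry voxel is well defined
    pz <- pz + 1e-9

    alive <- px >= x0 & px < -x0 & py >= y0 & py < -y0
    px <- px[alive]; py <- py[alive]; pz <- pz[alive]
    du <- du[alive]; dv <- dv[alive]; dw <- dw[alive]
    eb <- eb[alive]; E <- E[alive]; w <- w[alive]
    first <- rep(TRUE, length(px))

    dep_idx <- vector("list", 0); dep_e <- vector("list", 0)
    dep_first <- vector("list", 0)

    # --- Woodcock tracking --------------------------------------------
    while (length(px)) {
      mu_maj <- tb$mu_max[eb]
      s <- rexp(length(px)) / mu_maj
      px <- px + du * s; py <- py + dv * s; pz <- pz + dw * s
      ix <- floor((px - x0) / vox); iy <- floor((py - y0) / vox)
      iz <- floor((pz - z_entry) / vox)
      inside <- ix >= 0 & ix < nx & iy >= 0 & iy < ny & iz >= 0 & iz < nz
      if (!all(inside)) {
        px <- px[inside]; py <- py[inside]; pz <- pz[inside]
        du <- du[inside]; dv <- dv[inside]; dw <- dw[inside]
        eb <- eb[inside]; E <- E[inside]; w <- w[inside]
        first <- first[inside]; mu_maj <- mu_maj[inside]
        ix <- ix[inside]; iy <- iy[inside]; iz <- iz[inside]
        if (!length(px)) break
      }
      idx <- 1L + ix + nx * (iy + ny * iz)
      m <- mat_vec[idx]
      mu_here <- pmax(tb$mu_tot[cbind(eb, m)], tb$mu_kn[cbind(eb, m)]) *
        rho_vec[idx] / 10
      hit <- runif(length(px)) < mu_here / mu_maj
      if (any(hit)) {
        hit_w <- which(hit)
        h_idx <- idx[hit_w]; h_m <- m[hit_w]; h_eb <- eb[hit_w]
        h_E <- E[hit_w]; h_w <- w[hit_w]; h_first <- first[hit_w]
        kn <- tb$mu_kn[cbind(h_eb, h_m)]
        pe <- tb$mu_pe[cbind(h_eb, h_m)]
        p_c <- kn / pmax(kn + pe, 1e-30)
        is_c <- runif(length(h_idx)) < p_c
        edep <- h_E                     # photoelectric: all energy local
        keep <- !hit
        if (any(is_c)) {
          ci <- hit_w[is_c]             # positions in the full state vectors
          a <- h_E[is_c] / ELECTRON_REST_KEV
          xk <- sample_kahn(a)
          Ep <- h_E[is_c] / xk
          low <- Ep < emin              # below-cutoff photons absorb locally
          edep[is_c] <- ifelse(low, h_E[is_c], h_E[is_c] - Ep)
          surv <- ci[!low]
          if (length(surv)) {
            Ep_s <- Ep[!low]
            ct <- 1 + ELECTRON_REST_KEV / E[surv] - ELECTRON_REST_KEV / Ep_s
            ct <- pmin(pmax(ct, -1), 1)
            phi <- runif(length(surv)) * 2 * pi
            rot <- rotate_direction(du[surv], dv[surv], dw[surv], ct, phi)
            du[surv] <- rot$u; dv[surv] <- rot$v; dw[surv] <- rot$w
            E[surv] <- Ep_s
            eb[surv] <- pmin(pmax(as.integer(round(Ep_s)) - emin + 1L, 1L),
                             tb$nE)
            first[surv] <- FALSE
            keep[surv] <- TRUE
          }
        }
        dep_idx[[length(dep_idx) + 1L]] <- h_idx
        dep_e[[length(dep_e) + 1L]] <- edep * h_w
        dep_first[[length(dep_first) + 1L]] <- h_first
        px <- px[keep]; py <- py[keep]; pz <- pz[keep]
        du <- du[keep]; dv <- dv[keep]; dw <- dw[keep]
        eb <- eb[keep]; E <- E[keep]; w <- w[keep]; first <- first[keep]
      }
    }

    # --- batch aggregation --------------------------------------------
    di <- unlist(dep_idx); de <- unlist(dep_e); df <- unlist(dep_first)
    bp <- numeric(nvox); bs <- numeric(nvox)
    if (length(di)) {
      if (any(df)) {
        agg <- rowsum(de[df], di[df])
        bp[as.integer(rownames(agg))] <- agg[, 1]
      }
      if (any(!df)) {
        agg <- rowsum(de[!df], di[!df])
        bs[as.integer(rownames(agg))] <- agg[, 1]
      }
    }
    prim_sum <- prim_sum + bp
    scat_sum <- scat_sum + bs
    bt <- (bp + bs) / n
    tot_batch_sum <- tot_batch_sum + bt
    tot_batch_sq <- tot_batch_sq + bt^2
  }

  mass_kg <- rho_vec * (vox / 10)^3 * 1e-3       # g -> kg
  to_gy <- KEV_TO_J / pmax(mass_kg, 1e-30)
  d_primary <- array(prim_sum / n_histories * to_gy, dim = dims)
  d_scatter <- array(scat_sum / n_histories * to_gy, dim = dims)
  nb <- sum(per_batch > 0)
  mean_b <- tot_batch_sum / nb
  var_b <- pmax(tot_batch_sq / nb - mean_b^2, 0) / pmax(nb - 1, 1)
  rel_unc <- array(sqrt(var_b) / pmax(mean_b, 1e-300), dim = dims)
  rel_unc[mean_b <= 0] <- NA_real_

  structure(list(d_primary = d_primary, d_scatter = d_scatter,
                 rel_uncertainty = rel_unc, n_histories = n_histories,
                 seed = as.integer(seed), gap_mm = gap_mm,
                 voxel_mm = vox, geometry = geometry),
            class = "photon_dose_grid")
}

#' @export
print.photon_dose_grid <- function(x, ...) {
  d <- dim(x$d_primary)
  cat(sprintf("<photon_dose_grid> %d x %d x %d voxels | %g histories | seed %d\n",
              d[1], d[2], d[3], x$n_histories, x$seed))
  cat(sprintf("  max primary %.3g Gy/hist, max scatter %.3g Gy/hist\n",
              max(x$d_primary), max(x$d_scatter)))
  invisible(x)
}

#' Deterministic (noise-free) primary dose
#'
#' Polyenergetic Beer-Lambert ray trace of the first-interaction dose with
#' inverse-square fluence fall-off and energy-transfer weighting, consistent
#' with the Monte Carlo primary component (same cross sections, same mean
#' aperture transmittance), to which it converges as the number of histories
#' grows.  Attenuation paths are computed along the depth axis of each voxel
#' column (the small slant of the divergent rays is neglected).
#'
#' @inheritParams simulate_photon_dose
#' @param e_step_kev Energy resampling step for the polyenergetic sum, keV.
#' @return Array of primary dose in Gy per history, same shape as the
#'   phantom.
#' @export
primary_dose_deterministic <- function(phantom, geometry, spectrum,
                                       gap_mm = 4, e_step_kev = 5) {
  tb <- engine_tables(phantom, geometry, spectrum)
  dims <- dim(phantom$density)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  vox <- phantom$voxel_mm
  rho <- phantom$density
  sd_mm <- geometry$sd_mm
  z_entry <- sd_mm + gap_mm
  # voxel-centre coordinates
  xc <- (seq_len(nx) - 0.5) * vox - nx * vox / 2
  yc <- (seq_len(ny) - 0.5) * vox - ny * vox / 2
  zc <- z_entry + (seq_len(nz) - 0.5) * vox
  fx <- geometry$field_mm[1]; fy <- geometry$field_mm[2]
  area_cm2 <- fx * fy / 100

  # resampled spectrum
  e_all <- spectrum$energy_kev
  grp <- round(e_all / e_step_kev) * e_step_kev
  fl <- tapply(spectrum$fluence, grp, sum)
  eg <- as.numeric(names(fl))
  keep <- eg >= tb$egrid[1] & eg <= max(tb$egrid)
  eg <- eg[keep]; fl <- as.numeric(fl[keep]); fl <- fl / sum(fl)

  dose <- array(0, dim = dims)
  inv_sq <- (sd_mm / zc)^2
  # beam aperture mask per depth (field edges projected by magnification)
  for (i in seq_along(eg)) {
    ebi <- pmin(pmax(as.integer(round(eg[i])) - tb$emin + 1L, 1L), tb$nE)
    mu_rho_tot <- pmax(tb$mu_tot[ebi, ], tb$mu_kn[ebi, ])   # cm^2/g per mat
    mu_vox <- array(mu_rho_tot[as.vector(tb$mat_idx)], dim = dims) * rho / 10
    # cumulative optical depth to voxel centre along z
    tau <- apply(mu_vox * vox, c(1, 2), cumsum)       # dim (nz, nx, ny)
    tau <- aperm(tau, c(2, 3, 1)) - mu_vox * vox / 2
    mtr <- tb$mu_tr[ebi, ]                            # cm^2/g per mat
    mtr_vox <- array(mtr[as.vector(tb$mat_idx)], dim = dims)
    # fluence per cm^2 per history at each voxel centre
    phi <- tb$wbar[ebi] / area_cm2
    contrib <- exp(-tau) * mtr_vox * eg[i] * fl[i] * phi
    contrib <- sweep(contrib, 3, inv_sq, `*`)
    # zero outside the diverging field edges
    mag <- zc / sd_mm
    inx <- outer(abs(xc), mag * fx / 2, `<=`)         # nx x nz
    iny <- outer(abs(yc), mag * fy / 2, `<=`)         # ny x nz
    mask <- array(0, dim = dims)
    for (k in seq_len(nz)) mask[, , k] <- outer(inx[, k], iny[, k], `&`)
    dose <- dose + contrib * mask
  }
  dose * KEV_TO_J * 1000    # keV/g -> Gy
}

#' Approximate deterministic scatter dose
#'
#' Single-scatter kernel superposition: the energy scattered out of the
#' primary beam in each voxel is spread with an isotropic point kernel
#' `mu_en * exp(-mu r) / (4 pi r^2)` evaluated at the spectrum's mean
#' scattered energy and the phantom's mean density.  This is a fast,
#' lower-fidelity surrogate for the Monte Carlo scatter component and is
#' flagged `approximate` in its attributes.
#'
#' @inheritParams simulate_photon_dose
#' @param kernel_radius_mm Truncation radius of the point kernel, mm.
#' @return Array of scatter dose in Gy per history with attribute
#'   `approximate = TRUE`.
#' @export
scatter_kernel_estimate <- function(phantom, geometry, spectrum, gap_mm = 4,
                                    kernel_radius_mm = 40) {
  tb <- engine_tables(phantom, geometry, spectrum)
  dims <- dim(phantom$density)
  vox <- phantom$voxel_mm
  rho <- phantom$density
  if (all(rho <= 1e-6)) {
    out <- array(0, dim = dims)
    attr(out, "approximate") <- TRUE
    return(out)
  }
  # energy emitted into scattered photons per voxel, per history (keV):
  # reuse the deterministic primary machinery with scatter-release weighting
  prim <- primary_dose_deterministic(phantom, geometry, spectrum, gap_mm)
  # convert primary dose (Gy) back to locally released scatter energy by the
  # ratio of scattered-out to transferred energy, energy-averaged
  e_mean <- spectrum_mean_energy(spectrum)
  ebi <- pmin(pmax(as.integer(round(e_mean)) - tb$emin + 1L, 1L), tb$nE)
  ratio_mat <- (tb$mu_kn[ebi, ] * (1 - kn_mean_transfer_fraction(e_mean))) /
    pmax(tb$mu_tr[ebi, ], 1e-12)
  ratio <- array(ratio_mat[as.vector(tb$mat_idx)], dim = dims)
  mass_g <- rho * (vox / 10)^3
  src_kev <- prim / (KEV_TO_J * 1000) * mass_g * ratio   # keV per voxel

  # point kernel at the mean scattered energy in the mean medium
  e_sc <- 0.85 * e_mean
  rho_bar <- mean(rho[rho > 1e-3])
  mat_main <- names(which.max(table(as.vector(phantom$material)[rho > 1e-3])))
  mu_bar <- mass_attenuation(mat_main, max(e_sc, tb$egrid[1])) * rho_bar / 10
  mu_en_bar <- mass_attenuation(mat_main, max(e_sc, tb$egrid[1]), "mu_en") *
    rho_bar / 10

  rad_vox <- min(ceiling(kernel_radius_mm / vox), max(dims))
  off <- (-rad_vox):rad_vox
  kg <- expand.grid(i = off, j = off, k = off)
  r <- sqrt(kg$i^2 + kg$j^2 + kg$k^2) * vox
  kv <- mu_en_bar * exp(-mu_bar * r) / (4 * pi * pmax(r, vox / 2)^2) * vox^3
  # self-voxel: energy absorbed within a sphere of equal volume
  a_eq <- (3 * vox^3 / (4 * pi))^(1 / 3)
  kv[r == 0] <- mu_en_bar / mu_bar * (1 - exp(-mu_bar * a_eq))
  kern <- array(kv, dim = rep(2 * rad_vox + 1, 3))

  # 3D linear convolution via FFT with zero padding
  pad <- dims + dim(kern) - 1L
  pad <- vapply(pad, function(p) stats::nextn(p, 2), integer(1))
  A <- array(0, pad); A[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- src_kev
  B <- array(0, pad)
  B[seq_len(dim(kern)[1]), seq_len(dim(kern)[2]), seq_len(dim(kern)[3])] <- kern
  conv <- Re(fft(fft(A) * fft(B), inverse = TRUE)) / prod(pad)
  sel <- lapply(seq_len(3), function(d) rad_vox + seq_len(dims[d]))
  absorbed_kev <- conv[sel[[1]], sel[[2]], sel[[3]]]
  out <- absorbed_kev * KEV_TO_J / pmax(rho * (vox / 10)^3 * 1e-3, 1e-30)
  out[rho <= 1e-6] <- 0
  attr(out, "approximate") <- TRUE
  out
}
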