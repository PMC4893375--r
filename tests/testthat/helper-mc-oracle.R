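# Independent single-slab Monte Carlo reference, written against the same
# physics but with a different algorithmic structure than the package
# kernel: vectorized over photons, R RNG, and the step to a boundary is
# resampled after every internal reflection (statistically identical by the
# memorylessness of the exponential step law, but a different code path).
# Used to validate the package's transport kernel on slab benchmarks.
mc_slab_oracle <- function(mu_a, mu_s, g, n_refr, d_cm, n_photons,
                           ambient_n = 1, chunk = 5e4, seed = 1,
                           weight_threshold = 1e-4, roulette_survival = 0.1) {
  mu_t <- mu_a + mu_s
  fresnel_r <- function(n1, n2, cos_i) {
    if (n1 == n2) return(rep(0, length(cos_i)))
    sin2_t <- (n1 / n2)^2 * (1 - cos_i^2)
    r <- rep(1, length(cos_i))
    ok <- sin2_t < 1
    ct <- sqrt(pmax(1 - sin2_t[ok], 0))
    ci <- cos_i[ok]
    rs <- (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct)
    rp <- (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci)
    r[ok] <- 0.5 * (rs^2 + rp^2)
    r
  }
  set.seed(seed)
  rsp <- ((ambient_n - n_refr) / (ambient_n + n_refr))^2
  rd_w <- 0; tt_w <- 0; ab_w <- 0
  done <- 0
  while (done < n_photons) {
    n <- min(chunk, n_photons - done)
    done <- done + n
    pz <- rep(0, n); uz <- rep(1, n)
    ux <- rep(0, n); uy <- rep(0, n)
    w <- rep(1 - rsp, n)
    scattered <- rep(FALSE, n)
    alive <- rep(TRUE, n)
    iter <- 0
    while (any(alive) && iter < 1e5) {
      iter <- iter + 1
      idx <- which(alive)
      s <- -log(runif(length(idx))) / mu_t
      db <- ifelse(uz[idx] > 0, (d_cm - pz[idx]) / uz[idx],
                   ifelse(uz[idx] < 0, pz[idx] / (-uz[idx]), Inf))
      hit <- s >= db
      # boundary arrivals: Fresnel decides reflect vs escape
      if (any(hit)) {
        ih <- idx[hit]
        top <- uz[ih] < 0
        pz[ih] <- ifelse(top, 0, d_cm)
        R <- fresnel_r(n_refr, ambient_n, abs(uz[ih]))
        refl <- runif(length(ih)) < R
        uz[ih[refl]] <- -uz[ih[refl]]
        esc <- ih[!refl]
        esc_top <- top[!refl]
        rd_w <- rd_w + sum(w[esc[esc_top & scattered[esc]]])
        tt_w <- tt_w + sum(w[esc[!esc_top]])
        alive[esc] <- FALSE
      }
      # interior interactions: absorb, roulette, Henyey-Greenstein spin
      if (any(!hit)) {
        ii <- idx[!hit]
        pz[ii] <- pz[ii] + uz[ii] * s[!hit]
        dw <- w[ii] * mu_a / mu_t
        ab_w <- ab_w + sum(dw)
        w[ii] <- w[ii] - dw
        low <- w[ii] < weight_threshold
        if (any(low)) {
          il <- ii[low]
          surv <- runif(length(il)) < roulette_survival
          w[il[surv]] <- w[il[surv]] / roulette_survival
          alive[il[!surv]] <- FALSE
        }
        ii <- ii[alive[ii]]
        if (length(ii) > 0) {
          if (abs(g) > 1e-12) {
            tmp <- (1 - g^2) / (1 - g + 2 * g * runif(length(ii)))
            cost <- pmin(1, pmax(-1, (1 + g^2 - tmp^2) / (2 * g)))
          } else {
            cost <- 2 * runif(length(ii)) - 1
          }
          sint <- sqrt(1 - cost^2)
          phi <- 2 * pi * runif(length(ii))
          cosp <- cos(phi); sinp <- sin(phi)
          near_vert <- abs(uz[ii]) > 0.99999
          iv <- ii[near_vert]; io <- ii[!near_vert]
          if (length(iv) > 0) {
            ux[iv] <- sint[near_vert] * cosp[near_vert]
            uy[iv] <- sint[near_vert] * sinp[near_vert]
            uz[iv] <- sign(uz[iv]) * cost[near_vert]
          }
          if (length(io) > 0) {
            st <- sint[!near_vert]; ct2 <- cost[!near_vert]
            cp <- cosp[!near_vert]; sp <- sinp[!near_vert]
            tmp2 <- sqrt(1 - uz[io]^2)
            ux2 <- st * (ux[io] * uz[io] * cp - uy[io] * sp) / tmp2 + ux[io] * ct2
            uy2 <- st * (uy[io] * uz[io] * cp + ux[io] * sp) / tmp2 + uy[io] * ct2
            uz[io] <- -st * cp * tmp2 + uz[io] * ct2
            ux[io] <- ux2; uy[io] <- uy2
          }
          scattered[ii] <- TRUE
        }
      }
    }
  }
  list(r_d = rd_w / n_photons, r_spec = rsp,
       transmittance = tt_w / n_photons, absorbed = ab_w / n_photons)
}
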