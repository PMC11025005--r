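# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with R/.

# --- occurrence-pattern counts by exhaustive per-taxon scan ----------------
# pres: logical taxa x intervals matrix of sampled presences
oracle_counts <- function(pres, i) {
  n_int <- ncol(pres)
  first <- apply(pres, 1, function(r) min(which(r)))
  last <- apply(pres, 1, function(r) max(which(r)))
  count_if <- function(f) sum(apply(pres, 1, f))
  tt <- if (i - 1 >= 1) count_if(function(r) r[i - 1] && r[i]) else NA
  t3 <- if (i - 1 >= 1 && i + 1 <= n_int) {
    count_if(function(r) r[i - 1] && r[i] && r[i + 1])
  } else NA
  pt <- if (i - 1 >= 1 && i + 1 <= n_int) {
    count_if(function(r) r[i - 1] && !r[i] && r[i + 1])
  } else NA
  gf <- if (i - 1 >= 1 && i + 2 <= n_int) {
    count_if(function(r) r[i - 1] && r[i + 2] && !r[i + 1])
  } else NA
  list(
    two_timer_prev = tt, three_timer = t3, part_timer = pt, gap_filler = gf,
    n_bt = sum(first < i & last > i),
    n_bL = sum(first < i & last == i),
    sampled_in_bin = sum(pres[, i])
  )
}

oracle_ps <- function(pres) {
  n_int <- ncol(pres)
  t3 <- pt <- 0
  for (i in 2:(n_int - 1)) {
    cc <- oracle_counts(pres, i)
    t3 <- t3 + cc$three_timer
    pt <- pt + cc$part_timer
  }
  t3 / (t3 + pt)
}

# turn a presence matrix into the package's genus-summary layout
pres_to_summaries <- function(pres, stages, clade = "cladeA") {
  nm <- respsel::stage_names(stages)
  occ <- do.call(rbind, lapply(seq_len(nrow(pres)), function(g) {
    idx <- which(pres[g, ])
    data.frame(genus = sprintf("g%03d", g), clade = clade,
               interval = nm[idx], locality = "L1")
  }))
  respsel::build_genus_summaries(tibble::as_tibble(occ), stages)
}

random_presence <- function(n_taxa, n_int, p = 0.5) {
  # ensure every taxon occurs somewhere
  repeat {
    m <- matrix(runif(n_taxa * n_int) < p, nrow = n_taxa)
    if (all(rowSums(m) > 0)) return(m)
  }
}

# --- Mann-Whitney by full enumeration of the exact U distribution ----------
# two-sided exact p for untied samples, by complete distribution of U
oracle_mwu <- function(x, y) {
  m <- length(x)
  n <- length(y)
  combined <- c(x, y)
  stopifnot(!anyDuplicated(combined))
  rk <- rank(combined)
  u_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  us <- apply(combs, 2, function(ix) sum(seq_len(m + n)[ix]) - m * (m + 1) / 2)
  dist <- table(us) / ncol(combs)
  u_vals <- as.numeric(names(dist))
  p_low <- sum(dist[u_vals <= u_obs])
  p_high <- sum(dist[u_vals >= u_obs])
  list(U = u_obs, p = min(1, 2 * min(p_low, p_high)))
}

# --- logistic log-likelihood and coordinate-ascent maximizer ---------------
oracle_loglik <- function(beta, x, y) {
  eta <- drop(x %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# maximize the binomial log-likelihood by cyclic one-dimensional Brent
# searches; independent of IRLS
oracle_logistic_max <- function(x, y, lower = -20, upper = 20, sweeps = 200) {
  beta <- rep(0, ncol(x))
  for (s in seq_len(sweeps)) {
    old <- beta
    for (j in seq_along(beta)) {
      f <- function(bj) {
        bb <- beta
        bb[j] <- bj
        -oracle_loglik(bb, x, y)
      }
      beta[j] <- stats::optimize(f, c(lower, upper), tol = 1e-10)$minimum
    }
    if (max(abs(beta - old)) < 1e-9) break
  }
  list(beta = beta, loglik = oracle_loglik(beta, x, y))
}

# --- OLS by explicit normal equations ---------------------------------------
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- drop(X %*% beta)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = 1 - sse / sst)
}

# --- great-circle distance (haversine, R = 6371 km) -------------------------
oracle_gcd_km <- function(lat1, lng1, lat2, lng2) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lng2 - lng1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

oracle_max_gcd <- function(lat, lng) {
  best <- 0
  n <- length(lat)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      best <- max(best, oracle_gcd_km(lat[i], lng[i], lat[j], lng[j]))
    }
  }
  best
}
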