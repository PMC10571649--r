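# Independent oracles and fixture builders. These deliberately use naive
# enumeration / brute force, not the package's code paths.

# exhaustive all-pairs longest in-plane center distance over every slice
oracle_ld <- function(voxels, spacing) {
  best <- 0
  for (s in seq_len(dim(voxels)[1])) {
    idx <- which(voxels[s, , , drop = FALSE] == 1L, arr.ind = TRUE)
    if (nrow(idx) < 2) next
    for (i in seq_len(nrow(idx) - 1)) {
      for (j in (i + 1):nrow(idx)) {
        dx <- (idx[i, 2] - idx[j, 2]) * spacing[2]
        dy <- (idx[i, 3] - idx[j, 3]) * spacing[3]
        d <- sqrt(dx * dx + dy * dy)
        if (d > best) best <- d
      }
    }
  }
  unname(best)
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank_p <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# exact two-tailed rank-sum p by enumerating all C(m+n, m) group assignments
oracle_ranksum_p <- function(a, b) {
  m <- length(a)
  pool <- c(a, b)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pool), m)
  u_all <- apply(combos, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# all permutations of 1..n, iteratively (independent of the package's
# recursive generator)
oracle_perms <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- do.call(rbind, lapply(seq_len(k), function(pos) {
      left <- if (pos > 1) out[, 1:(pos - 1), drop = FALSE] else NULL
      right <- if (pos < k) out[, pos:(k - 1), drop = FALSE] else NULL
      cbind(left, k, right)
    }))
  }
  out
}

# exact two-sided permutation p for Spearman's rho
oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  perms <- oracle_perms(length(x))
  rho_all <- apply(perms, 1, function(p) cor(rx, ry[p]))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

# one lesion's rows in the cohort schema
make_lesion_df <- function(patient = "P1", lesion = "L1", days,
                           ld = NA_real_, perp = NA_real_,
                           edema = NA_real_, core_present = TRUE,
                           edema_resolved = FALSE, confluent = FALSE,
                           steroids = FALSE, thickness = 1,
                           flair = TRUE, histology = "NSCLC") {
  n <- length(days)
  data.frame(patient_id = patient, lesion_id = lesion,
             days_from_srt = as.integer(days),
             ld_mm = rep_len(ld, n), perp_mm = rep_len(perp, n),
             edema_cm3 = rep_len(edema, n),
             core_present = rep_len(core_present, n),
             edema_resolved = rep_len(edema_resolved, n),
             confluent_edema = rep_len(confluent, n),
             on_steroids = rep_len(steroids, n),
             slice_thickness_mm = rep_len(thickness, n),
             flair_available = rep_len(flair, n),
             histology = rep_len(histology, n))
}

# random small blob mask for oracle-equivalence checks
random_mask <- function(max_slices = 3, max_rc = 12, spacing = NULL) {
  dims <- c(sample(max_slices, 1), sample(4:max_rc, 1), sample(4:max_rc, 1))
  vox <- array(0L, dims)
  n <- sample(2:min(40, prod(dims)), 1)
  vox[sample(prod(dims), n)] <- 1L
  if (is.null(spacing)) spacing <- c(3, runif(2, 0.5, 2))
  mask_volume(vox, spacing, "core")
}
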