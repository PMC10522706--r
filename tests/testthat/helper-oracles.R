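# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's distance-transform code path.

random_mask <- function(dim, spacing = c(1, 1, 1), p_fg = 0.4) {
  seg_mask(array(runif(prod(dim)) < p_fg, dim = dim), spacing)
}

cuboid_mask <- function(dim, from, to, spacing = c(1, 1, 1)) {
  a <- array(0, dim = dim)
  a[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- 1
  seg_mask(a, spacing)
}

# all-pairs directed nearest-neighbour distances between index matrices
brute_directed <- function(a_idx, b_idx, spacing) {
  pa <- t(t(a_idx - 1) * spacing)
  pb <- t(t(b_idx - 1) * spacing)
  vapply(seq_len(nrow(pa)), function(i) {
    sqrt(min(colSums((t(pb) - pa[i, ])^2)))
  }, 0)
}

# brute-force surface voxels: 6-connected neighbour check by enumeration
brute_surface <- function(mask) {
  d <- mask$shape
  idx <- which(mask$voxels, arr.ind = TRUE)
  on_surface <- vapply(seq_len(nrow(idx)), function(r) {
    v <- idx[r, ]
    for (ax in 1:3) {
      for (s in c(-1L, 1L)) {
        nb <- v
        nb[ax] <- nb[ax] + s
        if (nb[ax] < 1 || nb[ax] > d[ax]) return(TRUE)
        if (!mask$voxels[nb[1], nb[2], nb[3]]) return(TRUE)
      }
    }
    FALSE
  }, TRUE)
  idx[on_surface, , drop = FALSE]
}

brute_hd95 <- function(pred, ref, percentile = 0.95) {
  sa <- brute_surface(pred)
  sb <- brute_surface(ref)
  d_ab <- brute_directed(sa, sb, pred$spacing_mm)
  d_ba <- brute_directed(sb, sa, pred$spacing_mm)
  max(quantile(d_ab, percentile, names = FALSE, type = 7),
      quantile(d_ba, percentile, names = FALSE, type = 7))
}

brute_sdt <- function(pred, ref, tol) {
  sa <- brute_surface(pred)
  sb <- brute_surface(ref)
  d_ab <- brute_directed(sa, sb, pred$spacing_mm)
  d_ba <- brute_directed(sb, sa, pred$spacing_mm)
  (sum(d_ab <= tol) + sum(d_ba <= tol)) / (nrow(sa) + nrow(sb))
}

# exact one-sided signed-rank p by enumerating all 2^n sign assignments of
# the observed absolute differences (zeros discarded first)
enum_wilcoxon_p <- function(deltas) {
  x <- deltas[deltas != 0]
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(v_all >= v_obs - 1e-12)
}

# long agreement table from paired per-case metric values
make_agreement <- function(values_inter, values_model, metric = "Dice") {
  n <- length(values_inter)
  tibble::tibble(
    case_id = rep(sprintf("case_%03d", seq_len(n)), 2),
    pairing = rep(c("inter_expert", "model_expert"), each = n),
    metric = metric,
    value = c(values_inter, values_model),
    defined = !is.na(c(values_inter, values_model))
  )
}
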